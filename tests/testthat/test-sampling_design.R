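test_that("accumulation means equal the exact all-orderings average (K <= 7)", {
  set.seed(301)
  sizes <- c(rep(2:5, each = 6), 6, 6, 7)
  for (K in sizes) {
    mat <- random_small_matrix(n_species = sample(1:6, 1), n_events = K)
    ac <- accumulation_curve(mat, n_permutations = 5)
    expect_true(attr(ac, "exhaustive"))
    expect_equal(ac$mean, oracle_accum_mean(mat), tolerance = 1e-12)
    # mean at K is the overall richness, exactly
    expect_equal(ac$mean[K], sum(rowSums(incidence(mat)) > 0L))
    expect_true(all(diff(ac$mean) >= -1e-12))
    expect_true(all(ac$lower <= ac$mean + 1e-12 &
                      ac$mean <= ac$upper + 1e-12))
  }
})

test_that("accumulation means agree with the independent rarefaction cross-check", {
  set.seed(302)
  mat <- random_small_matrix(n_species = 8, n_events = 6)
  ac <- accumulation_curve(mat)
  ref <- suppressWarnings(
    vegan::specaccum(t(incidence(mat) * 1L), method = "exact"))
  expect_equal(ac$mean, as.numeric(ref$richness), tolerance = 1e-10)
})

test_that("permutation curves are reproducible and anchored at overall richness", {
  set.seed(303)
  mat <- random_small_matrix(n_species = 10, n_events = 10)
  a1 <- accumulation_curve(mat, n_permutations = 200, seed = 7)
  a2 <- accumulation_curve(mat, n_permutations = 200, seed = 7)
  expect_identical(as.data.frame(a1), as.data.frame(a2))
  expect_false(attr(a1, "exhaustive"))
  expect_equal(a1$mean[10], sum(rowSums(incidence(mat)) > 0L))
  expect_error(accumulation_curve(mat, ci_level = 1.5), "ci_level")
})

test_that("degenerate curves: single event and identical events", {
  sv <- tiny_survey()
  mat <- pool_by_event(sv$detections, sv$samples)
  one <- subset_events(mat, 1L)
  ac <- accumulation_curve(one)
  expect_equal(nrow(ac), 1L)
  expect_equal(ac$mean, ac$lower)
  expect_equal(ac$mean, ac$upper)
  # all events identical in composition: flat curve at the shared richness
  pos <- matrix(1L, 3, 4, dimnames = list(paste0("sp", 1:3), paste0("e", 1:4)))
  ev <- data.frame(event_id = paste0("e", 1:4), location = "L",
                   substrate = "water", season = "wet", date = "2023-01-01",
                   n_replicates = 8L)
  flat <- accumulation_curve(detection_matrix(pos, ev))
  expect_equal(flat$mean, rep(3, 4))
})

test_that("accumulation mean converges to the iid closed form", {
  # iid events: species s detected per event with probability d_s, so the
  # expected curve is sum_s (1 - (1 - d_s)^k)
  set.seed(304)
  d <- c(0.8, 0.5, 0.2, 0.05)
  E <- 400
  inc <- sapply(seq_len(E), function(e) stats::runif(4) < d)
  pos <- matrix(as.integer(inc), nrow = 4,
                dimnames = list(paste0("sp", 1:4), paste0("e", seq_len(E))))
  ev <- data.frame(event_id = colnames(pos), location = "L",
                   substrate = "water", season = "wet", date = "2023-01-01",
                   n_replicates = 8L)
  ac <- accumulation_curve(detection_matrix(pos, ev),
                           n_permutations = 400, seed = 1)
  ks <- c(1, 3, 10, 25)
  for (k in ks) {
    expected <- sum(1 - (1 - d)^k)
    # MC tolerance: binomial spread of each species' first-detection state
    mc_se <- sqrt(sum((1 - d)^k * (1 - (1 - d)^k))) / sqrt(400) + 0.15
    expect_lt(abs(ac$mean[k] - expected), 3 * mc_se)
  }
})

test_that("paired days require full replicate sets in both substrates", {
  sv <- tiny_survey()
  pd <- paired_days(sv$samples, min_replicates = 8)
  expect_equal(nrow(pd), 1L)
  # drop one sediment replicate: the day no longer qualifies at 8+8
  short <- sv$samples[-9, ]
  expect_equal(nrow(paired_days(short, min_replicates = 8)), 0L)
  expect_equal(nrow(paired_days(short, min_replicates = 7)), 1L)
})

test_that("mixed design k_sub at full replicate count equals the union", {
  set.seed(305)
  cfg <- paper_like_config(n_species = 25, events_per_combo = 4,
                           include_soil = FALSE)
  sim <- generate_survey(cfg, seed = 17)
  pd <- paired_days(sim$samples)
  b <- build_mixed_design(sim$assignments, sim$samples, pd, k_sub = 8,
                          seed = 17)
  mixed_rich <- sum(rowSums(incidence(b$mixed)) > 0L)
  union_rich <- length(union(
    b$water$species[rowSums(incidence(b$water)) > 0L],
    b$sediment$species[rowSums(incidence(b$sediment)) > 0L]))
  expect_equal(mixed_rich, union_rich)
  singles <- c(sum(rowSums(incidence(b$water)) > 0L),
               sum(rowSums(incidence(b$sediment)) > 0L))
  expect_true(all(mixed_rich >= singles))
  # per-day mixed events contain exactly 2 * k_sub replicates
  expect_true(all(b$mixed$events$n_replicates == 16L))
  expect_error(build_mixed_design(sim$assignments, sim$samples, pd,
                                  k_sub = 9, seed = 1), "k_sub")
})

test_that("mixed draws are reproducible under a fixed seed", {
  set.seed(306)
  cfg <- paper_like_config(n_species = 15, events_per_combo = 3,
                           include_soil = FALSE)
  sim <- generate_survey(cfg, seed = 3)
  pd <- paired_days(sim$samples)
  b1 <- build_mixed_design(sim$assignments, sim$samples, pd, seed = 11)
  b2 <- build_mixed_design(sim$assignments, sim$samples, pd, seed = 11)
  expect_identical(b1$mixed$positives, b2$mixed$positives)
})

test_that("compare_designs summarizes identical matrices identically", {
  set.seed(307)
  cfg <- paper_like_config(n_species = 15, events_per_combo = 3,
                           include_soil = FALSE)
  sim <- generate_survey(cfg, seed = 5)
  pd <- paired_days(sim$samples)
  b <- build_mixed_design(sim$assignments, sim$samples, pd, seed = 5)
  cmp <- compare_designs(b$mixed, b$mixed, b$mixed, n_permutations = 50,
                         seed = 5)
  expect_equal(cmp$summary$mean_event_richness[1],
               cmp$summary$mean_event_richness[2])
  expect_equal(cmp$summary$overall_richness[1],
               cmp$summary$overall_richness[3])
  # mismatched day sets are a hard error
  sub <- subset_events(b$sediment, -1L)
  expect_error(compare_designs(b$mixed, sub, b$water, 10, 1), "identical")
})

test_that("compare_designs matches a hand-computed three-day toy", {
  # three paired days; water detects {A,B}, {A}, {C}; sediment {A}, {D}, {}
  mk <- function(sub, sets) {
    species <- c("A", "B", "C", "D")
    pos <- sapply(sets, function(s) as.integer(species %in% s))
    dimnames(pos) <- list(species,
                          paste("L1", sub, paste0("2023-03-1", 0:2),
                                sep = "_"))
    ev <- data.frame(event_id = colnames(pos), location = "L1",
                     substrate = sub, season = "wet",
                     date = paste0("2023-03-1", 0:2), n_replicates = 8L)
    detection_matrix(pos, ev)
  }
  water <- mk("water", list(c("A", "B"), "A", "C"))
  sed <- mk("sediment", list("A", "D", character()))
  mixed <- mk("water", list(c("A", "B"), c("A", "D"), "C"))
  cmp <- compare_designs(mixed, sed, water, n_permutations = 10, seed = 1)
  s <- cmp$summary
  expect_equal(s$mean_event_richness[s$design == "water_only"], 4 / 3)
  expect_equal(s$mean_event_richness[s$design == "sediment_only"], 2 / 3)
  expect_equal(s$mean_event_richness[s$design == "mixed"], 5 / 3)
  expect_equal(s$overall_richness, c(4, 2, 3))
})

test_that("volume-richness table sums replicate volumes per water event", {
  sv <- tiny_survey()
  mat <- pool_by_event(sv$detections, sv$samples)
  vt <- volume_richness_table(mat, sv$samples)
  expect_equal(nrow(vt), 1L)  # only the water event carries volumes
  expect_equal(vt$volume_ml, 8 * 450)
  expect_equal(vt$richness, 2L)
  # no water events -> empty table
  sed_only <- subset_events(mat, mat$events$substrate == "sediment")
  expect_equal(nrow(volume_richness_table(sed_only, sv$samples)), 0L)
})

test_that("volume-dependent capture induces a positive volume-richness correlation", {
  sp <- data.frame(species = sprintf("Sp%02d", 1:30), psi = 1,
                   p_water = 0.3, p_sediment = 0, p_soil = 0,
                   m_wet = 1, m_dry = 1, a_12SV5 = 1, a_MiMammal = 1)
  lay <- data.frame(location = "L1", substrate = "water", season = "wet",
                    n_events = 40L, n_replicates = 8L)
  cfg <- synthetic_config(sp, lay, volume = list(mean = 460, sd = 200,
                                                 slope = 2))
  sim <- generate_survey(cfg, seed = 23)
  mat <- pool_by_event(sim$assignments, sim$samples, "combined")
  vt <- volume_richness_table(mat, sim$samples)
  expect_gt(stats::cor(vt$volume_ml, vt$richness, method = "spearman"), 0)
})
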