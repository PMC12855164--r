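cats <- challenge_catalogs()

test_that("canonicalization truncates trinomials and applies aliases", {
  expect_equal(canonicalize_name("Canis  lupus   familiaris"), "Canis lupus")
  expect_equal(canonicalize_name("Canis mesomelas", aliases =
                                   c("Canis mesomelas" = "Lupulella mesomelas")),
               "Lupulella mesomelas")
  expect_equal(canonicalize_name("Anas", rank = "genus"), "Anas")
})

test_that("decision precedence: blocklist, override, documented, congeners", {
  occ <- cats$occ; ref <- cats$ref; rules <- cats$rules
  # anthropogenic-input contaminant on the blocklist is always excluded
  d <- classify_taxon("Thunnus albacares", "species", occ, ref, rules)
  expect_equal(d$action, "exclude")
  expect_equal(d$reason_code, "blocklisted")
  expect_true(is.na(d$final_name))
  # the shipped wolf-to-jackal override reassigns
  d <- classify_taxon("Canis lupus", "species", occ, ref, rules)
  expect_equal(d$action, "reassign")
  expect_equal(d$reason_code, "override")
  expect_equal(d$final_name, "Lupulella mesomelas")
  # a documented species is accepted as itself
  d <- classify_taxon("Plaingenus sp1", "species", occ, ref, rules)
  expect_equal(d$action, "accept")
  expect_equal(d$final_name, "Plaingenus sp1")
  # genus with exactly one documented species: forced reassignment
  d <- classify_taxon("Unigenus01", "genus", occ, ref, rules)
  expect_equal(d$action, "reassign")
  expect_equal(d$reason_code, "unique_congener")
  expect_equal(d$final_name, "Unigenus01 sp1")
  # non-documented species with 3 documented congeners: ambiguous
  d <- classify_taxon("Ambigenus01 novus", "species", occ, ref, rules)
  expect_equal(d$action, "exclude")
  expect_equal(d$reason_code, "ambiguous_congeners")
  expect_equal(d$n_congeners_documented, 3L)
  # unknown genus: nothing to match
  d <- classify_taxon("Ghostgenus nemo", "species", occ, ref, rules)
  expect_equal(d$reason_code, "no_congener")
})

test_that("ambiguity modes differ exactly on the reference-gap case", {
  occ <- cats$occ; ref <- cats$ref
  # Gapgenus: 3 documented congeners, exactly one lacking a reference
  doc_mode <- curation_rules(ambiguity_mode = "documented_congener_unique")
  gap_mode <- curation_rules(ambiguity_mode = "unreferenced_congener_unique")
  d1 <- classify_taxon("Gapgenus01 novus", "species", occ, ref, doc_mode)
  expect_equal(d1$action, "exclude")
  expect_equal(d1$reason_code, "ambiguous_congeners")
  d2 <- classify_taxon("Gapgenus01 novus", "species", occ, ref, gap_mode)
  expect_equal(d2$action, "reassign")
  expect_equal(d2$final_name, "Gapgenus01 sp3")
  expect_equal(d2$n_congeners_unreferenced, 1L)
})

test_that("classify_taxon agrees with a brute-force re-derivation on random cases", {
  set.seed(101)
  occ <- cats$occ; ref <- cats$ref
  documented <- occ$documented_species
  genera <- unique(sub(" .*", "", documented))
  ref_map <- stats::setNames(has_reference(ref, documented), documented)
  for (i in 1:300) {
    mode <- sample(c("documented_congener_unique",
                     "unreferenced_congener_unique"), 1)
    blocklist <- sample(documented, sample(0:2, 1))
    ov_src <- sample(setdiff(c(documented, "Novel species"), blocklist), 1)
    overrides <- stats::setNames(sample(documented, 1), ov_src)
    rules <- curation_rules(blocklist, overrides, mode)
    rank <- sample(c("species", "genus"), 1)
    name <- if (rank == "genus") {
      sample(c(genera, "Ghostgenus"), 1)
    } else {
      sample(c(documented, paste(sample(genera, 1), "novus"),
               "Ghostgenus nemo"), 1)
    }
    got <- classify_taxon(name, rank, occ, ref, rules)
    want <- oracle_classify(name, rank, documented, ref_map,
                            rules$blocklist, rules$overrides, mode)
    expect_equal(got$action, want$action, info = paste(name, rank, mode))
    expect_equal(got$reason_code, want$reason, info = paste(name, rank, mode))
    expect_equal(got$final_name, want$final, info = paste(name, rank, mode))
  }
})

test_that("blocklisting a name can only turn its action into exclude", {
  set.seed(102)
  occ <- cats$occ; ref <- cats$ref
  documented <- occ$documented_species
  for (i in 1:50) {
    name <- sample(c(documented, "Gapgenus01 novus", "Unigenus02 novus"), 1)
    base <- curation_rules()
    with_block <- curation_rules(blocklist = name)
    d <- classify_taxon(name, "species", occ, ref, with_block)
    expect_equal(d$action, "exclude")
    expect_equal(d$reason_code, "blocklisted")
    # an unrelated name's decision is untouched by the new blocklist entry
    other <- setdiff(c("Plaingenus sp2", "Plaingenus sp3"), name)[1]
    expect_equal(classify_taxon(other, "species", occ, ref, with_block),
                 classify_taxon(other, "species", occ, ref, base))
  }
})

test_that("apply_filter merges reassigned taxa and conserves retained reads", {
  occ <- occurrence_catalog(c("Lupulella mesomelas", "Unigenus sp1"))
  ref <- reference_catalog(c("Lupulella mesomelas", "Unigenus sp1"),
                           c(TRUE, FALSE))
  rules <- curation_rules(
    blocklist = "Homo sapiens",
    overrides = c("Canis lupus" = "Lupulella mesomelas"))
  det <- data.frame(
    sample_id = "s1", primer = "12SV5",
    taxon_name = c("Canis lupus", "Lupulella mesomelas", "Unigenus novus",
                   "Homo sapiens"),
    rank = "species", read_count = c(10L, 5L, 3L, 99L),
    stringsAsFactors = FALSE)
  res <- apply_filter(det, occ, ref, rules)
  expect_equal(nrow(res$audit), 4L)
  # wolf reads merged into the jackal detection in the same sample
  jackal <- res$detections[res$detections$taxon_name == "Lupulella mesomelas", ]
  expect_equal(nrow(jackal), 1L)
  expect_equal(jackal$read_count, 15L)
  # reads conserved up to the excluded taxon's reads, reconciled by the audit
  excluded <- res$audit$original_name[res$audit$action == "exclude"]
  expect_equal(sum(res$detections$read_count),
               sum(det$read_count) -
                 sum(det$read_count[det$taxon_name %in% excluded]))
  # every final name is documented
  expect_true(all(res$detections$taxon_name %in% occ$documented_species))
})

test_that("apply_filter on an all-documented input is the identity", {
  occ <- cats$occ; ref <- cats$ref; rules <- cats$rules
  det <- data.frame(sample_id = "s1", primer = "MiMammal",
                    taxon_name = "Plaingenus sp1", rank = "species",
                    read_count = 4L)
  res <- apply_filter(det, occ, ref, rules)
  expect_equal(res$detections$taxon_name, "Plaingenus sp1")
  expect_equal(res$audit$action, "accept")
  expect_equal(nrow(res$audit), 1L)
})

test_that("empty input yields empty outputs", {
  res <- apply_filter(data.frame(sample_id = character(), primer = character(),
                                 taxon_name = character(), rank = character(),
                                 read_count = integer()),
                      cats$occ, cats$ref, cats$rules)
  expect_equal(nrow(res$detections), 0L)
  expect_equal(nrow(res$audit), 0L)
})

test_that("summarize_decisions counts sum to distinct taxa and are idempotent", {
  set.seed(103)
  ch <- generate_challenge(
    challenge_spec(documented_accept = 3, nondoc_ambiguous = 2,
                   blocklisted = 2, override = 1),
    cats$occ, cats$ref, cats$rules, seed = 9)
  res <- apply_filter(ch$assignments, cats$occ, cats$ref, cats$rules)
  tab <- summarize_decisions(res$audit)
  expect_equal(sum(tab$n), nrow(res$audit))
  expect_identical(tab, summarize_decisions(res$audit))
  # hand tally: 3 accepts, 2 ambiguous excludes, 2 blocklist excludes, 1 override
  expect_equal(tab$n[tab$reason_code == "documented"], 3L)
  expect_equal(tab$n[tab$reason_code == "ambiguous_congeners"], 2L)
  expect_equal(tab$n[tab$reason_code == "blocklisted"], 2L)
  expect_equal(tab$n[tab$reason_code == "override"], 1L)
})

test_that("classification is deterministic and audits are exhaustive", {
  occ <- cats$occ; ref <- cats$ref; rules <- cats$rules
  d1 <- classify_taxon("Gapgenus02 novus", "species", occ, ref, rules)
  d2 <- classify_taxon("Gapgenus02 novus", "species", occ, ref, rules)
  expect_identical(d1, d2)
  det <- data.frame(sample_id = rep("s1", 4), primer = "12SV5",
                    taxon_name = c("Plaingenus sp1", "Plaingenus sp1",
                                   "Ambigenus01 novus", "Unigenus01"),
                    rank = c("species", "species", "species", "genus"),
                    read_count = 1L, stringsAsFactors = FALSE)
  res <- apply_filter(det, occ, ref, rules)
  expect_equal(nrow(res$audit), 3L)  # one decision per distinct (name, rank)
})

test_that("shipped example catalogs and rules classify the canonical cases", {
  occ <- read_occurrence_catalog(system.file("extdata",
                                             "example_occurrences.csv",
                                             package = "ednasurvey"))
  ref <- read_reference_catalog(system.file("extdata",
                                            "example_references.csv",
                                            package = "ednasurvey"))
  rules <- read_curation_rules(system.file("extdata", "example_rules.yaml",
                                           package = "ednasurvey"))
  # wolf assignment re-classified to the resident jackal via the override
  d <- classify_taxon("Canis lupus", "species", occ, ref, rules)
  expect_equal(d$final_name, "Lupulella mesomelas")
  expect_equal(d$reason_code, "override")
  # the synonym alias lands on the accepted documented name
  d <- classify_taxon("Canis mesomelas", "species", occ, ref, rules)
  expect_equal(d$final_name, "Lupulella mesomelas")
  expect_equal(d$action, "accept")
  # a non-documented duck with three documented congeners is ambiguous
  d <- classify_taxon("Anas platyrhynchos", "species", occ, ref, rules)
  expect_equal(d$action, "exclude")
  expect_equal(d$n_congeners_documented, 3L)
  expect_equal(d$n_congeners_unreferenced, 2L)
  # anthropogenic food input is blocklisted
  d <- classify_taxon("Salmo salar", "species", occ, ref, rules)
  expect_equal(d$reason_code, "blocklisted")
  # unknown reference status is distinct from FALSE
  expect_true(is.na(has_reference(ref, "Ghostgenus nemo")))
  expect_false(has_reference(ref, "Anas undulata"))
})
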