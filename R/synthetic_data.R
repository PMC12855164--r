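# Synthetic survey generator: a two-level Bernoulli detection model (event
# availability x replicate capture) plus taxonomy-challenge tables with known
# ground truth, so every pipeline stage is testable without sequencing data.

#' Construct a synthetic survey configuration
#'
#' The generative model has two levels. At the event level, species `s` has
#' detectable DNA present with probability `psi_s * m_{s,season}`. Given
#' presence, each replicate sample and primer yields a detection with
#' probability `p_{s,substrate} * a_{s,primer} * v(replicate)`, where `v` is
#' an optional filtered-volume effect for water replicates (1 otherwise).
#' Read counts are decorative (shifted geometric): downstream analyses are
#' incidence-based.
#'
#' @param species data frame with one row per species: `species`, `psi`,
#'   `p_water`, `p_sediment`, `p_soil`, `m_wet`, `m_dry`, `a_12SV5`,
#'   `a_MiMammal`, all probabilities in \eqn{[0, 1]}.
#' @param layout data frame with one row per (location, substrate, season)
#'   block: `location`, `substrate`, `season`, `n_events`, `n_replicates`.
#' @param volume list with `mean`, `sd` (ml, water replicates) and `slope`
#'   (exponent of the volume effect `v = min(1, (vol/mean)^slope)`; 0 = no
#'   effect).
#' @return an object of class `synthetic_config`.
#' @export
synthetic_config <- function(species, layout,
                             volume = list(mean = 460, sd = 100, slope = 0)) {
  species <- as.data.frame(species, stringsAsFactors = FALSE)
  prob_cols <- c("psi", "p_water", "p_sediment", "p_soil", "m_wet", "m_dry",
                 "a_12SV5", "a_MiMammal")
  stopifnot(all(c("species", prob_cols) %in% names(species)))
  for (col in prob_cols) {
    v <- species[[col]]
    if (any(is.na(v) | v < 0 | v > 1)) {
      stop("species parameter '", col, "' must lie in [0, 1]")
    }
  }
  if (anyDuplicated(species$species) > 0L) stop("duplicate species names")
  layout <- as.data.frame(layout, stringsAsFactors = FALSE)
  stopifnot(all(c("location", "substrate", "season", "n_events",
                  "n_replicates") %in% names(layout)),
            all(layout$substrate %in% SUBSTRATES),
            all(layout$season %in% SEASONS),
            all(layout$n_events >= 1L), all(layout$n_replicates >= 1L))
  stopifnot(is.numeric(volume$mean), volume$mean > 0, volume$sd >= 0)
  structure(list(species = species, layout = layout, volume = volume),
            class = "synthetic_config")
}

#' The paper-like survey preset
#'
#' A fixed ~95-species vertebrate community with a long-tailed detectability
#' profile over a two-season, three-waterhole survey: 8 water and 8 sediment
#' replicates per event, soil trail events (6 replicates) in the dry season
#' only. Species parameters are drawn once from fixed hyperdistributions
#' under an internal seed, so the preset is a deterministic object. Low
#' per-replicate capture probabilities reproduce the patchiness signature of
#' waterhole eDNA surveys (most detections positive in a single replicate).
#'
#' @param n_species community size (default 95).
#' @param events_per_combo sampling days per (location, substrate, season)
#'   block for water/sediment (default 8; raise to scale the survey up).
#' @param include_soil include the dry-season soil trail blocks.
#' @param param_seed internal seed for the one-off parameter draw.
#' @return a `synthetic_config`.
#' @export
paper_like_config <- function(n_species = 95L, events_per_combo = 8L,
                              include_soil = TRUE, param_seed = 20230310L) {
  sp <- with_preserved_seed(param_seed, {
    repeat {
      a1 <- stats::rbinom(n_species, 1L, 0.8)
      a2 <- stats::rbinom(n_species, 1L, 0.8)
      if (all(a1 + a2 >= 1L)) break
    }
    pref_wet <- stats::runif(n_species) < 0.5
    data.frame(
      species = sprintf("Genus%03d species%03d", seq_len(n_species),
                        seq_len(n_species)),
      psi = stats::rbeta(n_species, 2, 1),
      p_base = stats::rbeta(n_species, 0.8, 8),
      aff_water = stats::runif(n_species, 0.5, 1),
      aff_sediment = stats::runif(n_species, 0.5, 1),
      aff_soil = stats::runif(n_species, 0.1, 0.7),
      m_wet = ifelse(pref_wet, 1, stats::runif(n_species, 0.4, 1)),
      m_dry = ifelse(pref_wet, stats::runif(n_species, 0.4, 1), 1),
      a_12SV5 = a1 * stats::runif(n_species, 0.6, 1),
      a_MiMammal = a2 * stats::runif(n_species, 0.6, 1),
      stringsAsFactors = FALSE)
  })
  species <- data.frame(
    species = sp$species, psi = sp$psi,
    p_water = pmin(1, sp$p_base * sp$aff_water),
    p_sediment = pmin(1, sp$p_base * sp$aff_sediment),
    p_soil = pmin(1, sp$p_base * sp$aff_soil),
    m_wet = sp$m_wet, m_dry = sp$m_dry,
    a_12SV5 = sp$a_12SV5, a_MiMammal = sp$a_MiMammal,
    stringsAsFactors = FALSE)
  waterholes <- c("Kolobe", "Mofela", "Monong")
  layout <- expand.grid(location = waterholes,
                        substrate = c("water", "sediment"),
                        season = SEASONS, stringsAsFactors = FALSE)
  layout$n_events <- as.integer(events_per_combo)
  layout$n_replicates <- 8L
  if (include_soil) {
    soil <- data.frame(location = paste0("Trail", 1:3), substrate = "soil",
                       season = "dry", n_events = 4L, n_replicates = 6L,
                       stringsAsFactors = FALSE)
    layout <- rbind(layout, soil)
  }
  synthetic_config(species, layout)
}

# evaluate `expr` under `seed` without disturbing the caller's RNG stream
with_preserved_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Load a synthetic configuration from YAML
#'
#' The YAML either spells out per-species parameters (`species` as a list of
#' records) or names the shipped preset (`preset: paper_like` with optional
#' `n_species`, `events_per_combo`, `include_soil`).
#'
#' @param path YAML path.
#' @return a `synthetic_config`.
#' @export
read_synthetic_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$preset)) {
    stopifnot(y$preset == "paper_like")
    return(paper_like_config(
      n_species = as.integer(y$n_species %||% 95L),
      events_per_combo = as.integer(y$events_per_combo %||% 8L),
      include_soil = y$include_soil %||% TRUE))
  }
  species <- do.call(rbind, lapply(y$species, as.data.frame))
  layout <- do.call(rbind, lapply(y$layout, as.data.frame))
  vol <- y$volume %||% list(mean = 460, sd = 100, slope = 0)
  synthetic_config(species, layout, vol)
}

season_start <- c(wet = "2023-03-10", dry = "2023-09-09")

#' Generate a synthetic survey
#'
#' Draws a survey from the two-level detection model of a
#' [synthetic_config()]. All uniform variates are drawn in a fixed order that
#' depends only on the survey layout, never on parameter values, so that
#' raising a capture probability under the same seed can only add detections
#' (shared-randomness monotonicity). Sampling days are shared across
#' substrates of a location, so paired water/sediment days exist by design.
#'
#' @param config a `synthetic_config`.
#' @param seed integer seed.
#' @return list with `samples` (metadata table), `assignments` (detection
#'   table in the dialect [pool_by_event()] reads), and `truth` (list:
#'   `config`, `seed`, `events`, `availability` species-by-event logical
#'   matrix, `detections` logical array species x sample x primer).
#' @export
generate_survey <- function(config, seed) {
  stopifnot(inherits(config, "synthetic_config"))
  lay <- config$layout
  events <- do.call(rbind, lapply(seq_len(nrow(lay)), function(i) {
    day <- seq_len(lay$n_events[i])
    date <- as.Date(season_start[[lay$season[i]]]) + 6L * (day - 1L)
    data.frame(location = lay$location[i], substrate = lay$substrate[i],
               season = lay$season[i], date = as.character(date),
               n_replicates = lay$n_replicates[i], stringsAsFactors = FALSE)
  }))
  events$event_id <- paste(events$location, events$substrate, events$date,
                           sep = "_")
  samples <- do.call(rbind, lapply(seq_len(nrow(events)), function(e) {
    r <- seq_len(events$n_replicates[e])
    data.frame(sample_id = paste0(events$event_id[e], "_r", r),
               event_id = events$event_id[e],
               location = events$location[e], substrate = events$substrate[e],
               season = events$season[e], date = events$date[e],
               replicate_index = r, volume_ml = NA_real_,
               stringsAsFactors = FALSE)
  }))
  sp <- config$species
  S <- nrow(sp); E <- nrow(events); N <- nrow(samples)
  set.seed(as.integer(seed))
  # fixed draw order: volumes, availability, detection; dims depend only on
  # the layout so parameter changes re-use the same uniforms
  is_water <- samples$substrate == "water"
  u_vol <- stats::rnorm(sum(is_water), config$volume$mean, config$volume$sd)
  samples$volume_ml[is_water] <- pmax(50, u_vol)
  u_avail <- matrix(stats::runif(S * E), nrow = S)
  u_det <- array(stats::runif(S * N * 2L), dim = c(S, N, 2L))

  m_season <- as.matrix(sp[c("m_wet", "m_dry")])
  avail_p <- sp$psi * m_season[, match(events$season, SEASONS), drop = FALSE]
  Z <- u_avail < avail_p
  dimnames(Z) <- list(sp$species, events$event_id)

  p_sub <- as.matrix(sp[c("p_water", "p_sediment", "p_soil")])
  p_rep <- p_sub[, match(samples$substrate, SUBSTRATES), drop = FALSE]
  v <- rep(1, N)
  if (config$volume$slope != 0) {
    v[is_water] <- pmin(1, (samples$volume_ml[is_water] /
                              config$volume$mean)^config$volume$slope)
  }
  ev_of_sample <- match(samples$event_id, events$event_id)
  amp <- as.matrix(sp[c("a_12SV5", "a_MiMammal")])
  det <- array(FALSE, dim = c(S, N, 2L),
               dimnames = list(sp$species, samples$sample_id, PRIMERS))
  for (q in 1:2) {
    p_eff <- pmin(1, p_rep * rep(v, each = S) * amp[, q])
    det[, , q] <- Z[, ev_of_sample, drop = FALSE] & (u_det[, , q] < p_eff)
  }
  idx <- which(det, arr.ind = TRUE)
  assignments <- data.frame(
    sample_id = samples$sample_id[idx[, 2L]],
    primer = PRIMERS[idx[, 3L]],
    taxon_name = sp$species[idx[, 1L]],
    rank = "species",
    read_count = stats::rgeom(nrow(idx), prob = 0.02) + 1L,
    stringsAsFactors = FALSE)
  o <- order(assignments$sample_id, assignments$primer,
             assignments$taxon_name)
  assignments <- assignments[o, , drop = FALSE]
  rownames(assignments) <- NULL
  list(samples = samples, assignments = assignments,
       truth = list(config = config, seed = as.integer(seed),
                    events = events, availability = Z, detections = det))
}

#' Analytic event-level detection frequency of the generative model
#'
#' For species `s` in a (substrate, season) stratum with `R` replicates, the
#' probability that an event detects the species (either primer, any
#' replicate) is `psi * m * (1 - (1 - p_rep)^R)` with
#' `p_rep = 1 - (1 - p*a1)(1 - p*a2)`. Assumes no volume effect
#' (`slope = 0`).
#'
#' @param config a `synthetic_config`.
#' @return data frame: `species`, `substrate`, `season`, `n_replicates`,
#'   `d_analytic`.
#' @export
analytic_detection_frequency <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  strata <- unique(config$layout[c("substrate", "season", "n_replicates")])
  sp <- config$species
  out <- do.call(rbind, lapply(seq_len(nrow(strata)), function(i) {
    p <- sp[[paste0("p_", strata$substrate[i])]]
    m <- sp[[paste0("m_", strata$season[i])]]
    p_rep <- 1 - (1 - pmin(1, p * sp$a_12SV5)) *
      (1 - pmin(1, p * sp$a_MiMammal))
    data.frame(species = sp$species, substrate = strata$substrate[i],
               season = strata$season[i],
               n_replicates = strata$n_replicates[i],
               d_analytic = sp$psi * m *
                 (1 - (1 - p_rep)^strata$n_replicates[i]),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Compare empirical detection frequencies against the generative model
#'
#' Per species and (substrate, season) stratum, compares the empirical
#' event-level detection frequency observed in a pooled matrix with the
#' analytic expectation of the two-level Bernoulli model, reporting the bias
#' and the Monte Carlo standard error `sqrt(d(1-d)/n_events)`. Strata with a
#' single event have no usable standard error (`mc_se = NA`).
#'
#' @param x a combined-scope `detection_matrix` pooled from the generated
#'   survey.
#' @param truth the `truth` element returned by [generate_survey()].
#' @return data frame: `species`, `substrate`, `season`, `n_events`,
#'   `d_analytic`, `d_empirical`, `bias`, `mc_se`, `within_3se`.
#' @export
recover_detection_params <- function(x, truth) {
  stopifnot(inherits(x, "detection_matrix"))
  ana <- analytic_detection_frequency(truth$config)
  inc <- incidence(x)
  strat_key <- paste(x$events$substrate, x$events$season)
  out <- do.call(rbind, lapply(unique(paste(ana$substrate, ana$season)),
                               function(k) {
    cols <- which(strat_key == k)
    a <- ana[paste(ana$substrate, ana$season) == k, , drop = FALSE]
    sp_idx <- match(a$species, x$species)
    emp <- rep(0, nrow(a))
    present <- !is.na(sp_idx)
    if (length(cols) > 0L) {
      emp[present] <- rowSums(inc[sp_idx[present], cols, drop = FALSE]) /
        length(cols)
    }
    se <- sqrt(a$d_analytic * (1 - a$d_analytic) / length(cols))
    se[length(cols) <= 1L] <- NA_real_
    data.frame(species = a$species, substrate = a$substrate,
               season = a$season, n_events = length(cols),
               d_analytic = a$d_analytic, d_empirical = emp,
               bias = emp - a$d_analytic, mc_se = se,
               within_3se = ifelse(is.na(se),
                                   NA,
                                   abs(emp - a$d_analytic) <=
                                     pmax(3 * se, 1e-12)),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Specify a taxonomy-challenge table
#'
#' Counts of injected curation scenarios, mirroring the decision paths of the
#' occurrence-catalog filter.
#'
#' @param documented_accept labels that are documented species (accepted).
#' @param missing_reference_congener non-documented labels whose genus has
#'   several documented congeners of which exactly one lacks a reference
#'   sequence (the classic misassignment driven by a reference gap: excluded
#'   as ambiguous under the documented-congener criterion, reassigned to the
#'   unreferenced congener under the reference-gap criterion).
#' @param nondoc_unique_congener non-documented labels (species- or
#'   genus-rank) whose genus has exactly one documented congener, itself
#'   lacking a reference (reassigned under both criteria).
#' @param nondoc_ambiguous non-documented labels whose genus has several
#'   documented congeners lacking references (excluded under both criteria).
#' @param blocklisted labels on the blocklist.
#' @param override labels with a configured override target.
#' @return an object of class `challenge_spec`.
#' @export
challenge_spec <- function(documented_accept = 0L,
                           missing_reference_congener = 0L,
                           nondoc_unique_congener = 0L,
                           nondoc_ambiguous = 0L,
                           blocklisted = 0L,
                           override = 0L) {
  counts <- c(documented_accept = documented_accept,
              missing_reference_congener = missing_reference_congener,
              nondoc_unique_congener = nondoc_unique_congener,
              nondoc_ambiguous = nondoc_ambiguous,
              blocklisted = blocklisted, override = override)
  stopifnot(all(counts >= 0L))
  structure(list(counts = counts), class = "challenge_spec")
}

#' Generate a taxonomy-challenge assignment table with ground truth
#'
#' Emits one assignment row per injected label (synthetic sample ids), plus a
#' ground-truth table giving, for each label, the expected action and reason
#' under both ambiguity criteria of [classify_taxon()].
#'
#' @param spec a [challenge_spec()].
#' @param occ an [occurrence_catalog()].
#' @param ref a [reference_catalog()].
#' @param rules a [curation_rules()] (supplies blocklist/override labels).
#' @param seed integer seed for label sampling and read counts.
#' @return list with `assignments` and `truth` (data frame: `taxon_name`,
#'   `rank`, `scenario`, `action_documented_mode`, `reason_documented_mode`,
#'   `final_documented_mode`, and the three `_unreferenced_mode`
#'   counterparts).
#' @export
generate_challenge <- function(spec, occ, ref, rules, seed = 1L) {
  stopifnot(inherits(spec, "challenge_spec"),
            inherits(occ, "occurrence_catalog"))
  set.seed(as.integer(seed))
  cnt <- spec$counts
  g_sizes <- vapply(occ$genus_index, length, integer(1L))
  g_unref <- vapply(occ$genus_index, function(s) {
    sum(!isTRUE_vec(has_reference(ref, s)))
  }, integer(1L))
  take <- function(pool, n, scenario) {
    if (length(pool) < n) {
      stop("catalogs cannot realize scenario '", scenario, "': need ", n,
           " case(s), found ", length(pool))
    }
    if (n == 0L) character() else sample(pool, n)
  }
  rows <- list()
  add <- function(name, rank, scenario,
                  act_doc, rea_doc, fin_doc, act_unr, rea_unr, fin_unr) {
    rows[[length(rows) + 1L]] <<- data.frame(
      taxon_name = name, rank = rank, scenario = scenario,
      action_documented_mode = act_doc, reason_documented_mode = rea_doc,
      final_documented_mode = fin_doc,
      action_unreferenced_mode = act_unr,
      reason_unreferenced_mode = rea_unr,
      final_unreferenced_mode = fin_unr, stringsAsFactors = FALSE)
  }
  plain <- setdiff(occ$documented_species,
                   c(rules$blocklist, names(rules$overrides)))
  for (nm in take(plain, cnt[["documented_accept"]], "documented_accept")) {
    add(nm, "species", "documented_accept",
        "accept", "documented", nm, "accept", "documented", nm)
  }
  mrg_pool <- names(g_sizes)[g_sizes >= 2L & g_unref == 1L]
  for (g in take(mrg_pool, cnt[["missing_reference_congener"]],
                 "missing_reference_congener")) {
    congs <- occ$genus_index[[g]]
    target <- congs[!isTRUE_vec(has_reference(ref, congs))]
    label <- fabricate_epithet(g, occ)
    add(label, "species", "missing_reference_congener",
        "exclude", "ambiguous_congeners", NA_character_,
        "reassign", "unique_congener", target)
  }
  uniq_pool <- names(g_sizes)[g_sizes == 1L & g_unref == 1L]
  uniq <- take(uniq_pool, cnt[["nondoc_unique_congener"]],
               "nondoc_unique_congener")
  for (i in seq_along(uniq)) {
    g <- uniq[i]
    target <- occ$genus_index[[g]]
    # alternate species-rank and genus-rank labels across cases
    if (i %% 2L == 1L) {
      add(fabricate_epithet(g, occ), "species", "nondoc_unique_congener",
          "reassign", "unique_congener", target,
          "reassign", "unique_congener", target)
    } else {
      add(g, "genus", "nondoc_unique_congener",
          "reassign", "unique_congener", target,
          "reassign", "unique_congener", target)
    }
  }
  amb_pool <- names(g_sizes)[g_sizes >= 2L & g_unref >= 2L]
  for (g in take(amb_pool, cnt[["nondoc_ambiguous"]], "nondoc_ambiguous")) {
    add(fabricate_epithet(g, occ), "species", "nondoc_ambiguous",
        "exclude", "ambiguous_congeners", NA_character_,
        "exclude", "ambiguous_congeners", NA_character_)
  }
  for (nm in take(rules$blocklist, cnt[["blocklisted"]], "blocklisted")) {
    add(nm, "species", "blocklisted",
        "exclude", "blocklisted", NA_character_,
        "exclude", "blocklisted", NA_character_)
  }
  for (nm in take(names(rules$overrides), cnt[["override"]], "override")) {
    tgt <- unname(rules$overrides[[nm]])
    add(nm, "species", "override",
        "reassign", "override", tgt, "reassign", "override", tgt)
  }
  truth <- if (length(rows) == 0L) {
    data.frame(taxon_name = character(), rank = character(),
               scenario = character(), stringsAsFactors = FALSE)
  } else {
    do.call(rbind, rows)
  }
  assignments <- if (nrow(truth) == 0L) {
    data.frame(sample_id = character(), primer = character(),
               taxon_name = character(), rank = character(),
               read_count = integer(), stringsAsFactors = FALSE)
  } else {
    data.frame(
      sample_id = sprintf("CH_s%02d", (seq_len(nrow(truth)) %% 4L) + 1L),
      primer = PRIMERS[(seq_len(nrow(truth)) %% 2L) + 1L],
      taxon_name = truth$taxon_name, rank = truth$rank,
      read_count = stats::rgeom(nrow(truth), 0.02) + 1L,
      stringsAsFactors = FALSE)
  }
  list(assignments = assignments, truth = truth)
}

# a species epithet of `genus` guaranteed not to be documented
fabricate_epithet <- function(genus, occ) {
  i <- 0L
  repeat {
    i <- i + 1L
    cand <- paste(genus, paste0("fictus", i))
    if (!cand %in% occ$documented_species) return(cand)
  }
}

#' Example catalogs and rules that realize every challenge scenario
#'
#' A small synthetic occurrence catalog, reference catalog, and rule set
#' (with a wolf-to-jackal style override and an anthropogenic blocklist)
#' sufficient to instantiate each scenario of [challenge_spec()] several
#' times over.
#'
#' @param n_genera number of synthetic genera per structural class.
#' @return list with `occ`, `ref`, `rules`.
#' @export
challenge_catalogs <- function(n_genera = 4L) {
  mk <- function(prefix, i, n_sp) {
    paste(sprintf("%s%02d", prefix, i), paste0("sp", seq_len(n_sp)))
  }
  docs <- character(); refs <- character(); refd <- logical()
  for (i in seq_len(n_genera)) {
    # genera with exactly one documented, unreferenced species
    s1 <- mk("Unigenus", i, 1L)
    # genera with 3 documented congeners, exactly one lacking a reference
    s2 <- mk("Gapgenus", i, 3L)
    # genera with 3 documented congeners, all lacking references
    s3 <- mk("Ambigenus", i, 3L)
    docs <- c(docs, s1, s2, s3)
    refs <- c(refs, s1, s2, s3)
    refd <- c(refd, FALSE, c(TRUE, TRUE, FALSE), rep(FALSE, 3L))
  }
  plain <- paste("Plaingenus", paste0("sp", seq_len(3L * n_genera)))
  docs <- c(docs, plain, "Lupulella mesomelas")
  refs <- c(refs, plain, "Lupulella mesomelas")
  refd <- c(refd, rep(TRUE, length(plain)), TRUE)
  rules <- curation_rules(
    blocklist = c("Homo sapiens", "Bos taurus", "Ovis aries",
                  "Thunnus albacares", "Salmo salar"),
    overrides = c("Canis lupus" = "Lupulella mesomelas"))
  list(occ = occurrence_catalog(docs),
       ref = reference_catalog(refs, refd),
       rules = rules)
}
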