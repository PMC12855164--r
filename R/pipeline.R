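# Pipeline orchestration: wire simulate -> filter -> pool -> stats ->
# design-compare -> report into one reproducible run with a provenance
# manifest.

PIPELINE_STAGES <- c("simulate", "filter", "pool", "stats", "design",
                     "report")

#' Run the survey post-processing pipeline
#'
#' Executes the requested stages in dependency order against one output
#' directory and writes a `manifest.json` with package version, seeds,
#' per-stage parameters, timestamps, and md5 digests of every artifact.
#' Failure of a stage leaves the completed artifacts plus an `error` record
#' in the manifest.
#'
#' The configuration is a list (or YAML file) with optional entries:
#' `stages` (subset of simulate/filter/pool/stats/design/report),
#' `simulate` (a [synthetic_config()] spec: `preset`, `n_species`,
#' `events_per_combo`, `include_soil`), `inputs` (paths `metadata`,
#' `assignments` when not simulating), `filter` (paths `occurrences`,
#' `references`, `rules`; omit to use [challenge_catalogs()] defaults),
#' `pool` (`primer_scope`), `design` (`k_sub`, `min_replicates`,
#' `n_permutations`).
#'
#' @param config list or path to a YAML file.
#' @param out_dir output directory (created if needed).
#' @param seed integer master seed; stage seeds are derived from it and
#'   recorded in the manifest.
#' @return invisibly, the manifest list. Stops on stage failure after
#'   writing the manifest.
#' @export
run_pipeline <- function(config, out_dir, seed = 1L) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stages <- config$stages %||% PIPELINE_STAGES
  unknown <- setdiff(stages, PIPELINE_STAGES)
  if (length(unknown) > 0L) {
    stop("unknown stage(s): ", paste(unknown, collapse = ", "),
         "; valid stages: ", paste(PIPELINE_STAGES, collapse = ", "))
  }
  stages <- PIPELINE_STAGES[PIPELINE_STAGES %in% stages]
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(seed)
  stage_seeds <- seed + seq_along(PIPELINE_STAGES) * 1000L
  names(stage_seeds) <- PIPELINE_STAGES
  manifest <- list(tool = "ednasurvey",
                   version = as.character(utils::packageVersion("ednasurvey")),
                   started = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                   seed = seed, stage_seeds = as.list(stage_seeds),
                   stages = stages, parameters = list(), artifacts = list())
  path_of <- function(name) file.path(out_dir, name)
  register <- function(name) {
    manifest$artifacts[[name]] <<- unname(tools::md5sum(path_of(name)))
  }
  finish <- function(error = NULL) {
    manifest$finished <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
    if (!is.null(error)) manifest$error <- error
    jsonlite::write_json(manifest, path_of("manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  run_stage <- function(stage, fun) {
    tryCatch(fun(), error = function(e) {
      finish(list(stage = stage, message = conditionMessage(e)))
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  if ("simulate" %in% stages) {
    run_stage("simulate", function() {
      sim_cfg <- config$simulate %||% list(preset = "paper_like")
      sc <- if (!is.null(sim_cfg$preset)) {
        paper_like_config(
          n_species = as.integer(sim_cfg$n_species %||% 95L),
          events_per_combo = as.integer(sim_cfg$events_per_combo %||% 8L),
          include_soil = sim_cfg$include_soil %||% TRUE)
      } else {
        synthetic_config(sim_cfg$species, sim_cfg$layout,
                         sim_cfg$volume %||% list(mean = 460, sd = 100,
                                                  slope = 0))
      }
      sim <- generate_survey(sc, seed = stage_seeds[["simulate"]])
      utils::write.table(sim$samples, path_of("metadata.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      utils::write.table(sim$assignments, path_of("assignments.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      register("metadata.tsv"); register("assignments.tsv")
      manifest$parameters$simulate <<- list(
        n_species = nrow(sc$species), n_events = sum(sc$layout$n_events))
    })
  }
  samples <- NULL
  detections <- NULL
  if (any(c("filter", "pool", "stats", "design") %in% stages)) {
    metadata_path <- if ("simulate" %in% stages) path_of("metadata.tsv") else
      config$inputs$metadata
    assign_path <- if ("simulate" %in% stages) path_of("assignments.tsv") else
      config$inputs$assignments
    samples <- read_sample_metadata(metadata_path)
    detections <- read_assignments(assign_path)
  }

  if ("filter" %in% stages) {
    run_stage("filter", function() {
      fc <- config$filter
      if (is.null(fc)) {
        cats <- challenge_catalogs()
        # simulated labels are unknown to the example catalogs; document the
        # survey's own species so the filter passes them through
        cats$occ <- occurrence_catalog(
          c(cats$occ$documented_species, unique(detections$taxon_name)))
        occ <- cats$occ; ref <- cats$ref; rules <- cats$rules
      } else {
        occ <- read_occurrence_catalog(fc$occurrences)
        ref <- read_reference_catalog(fc$references)
        rules <- read_curation_rules(fc$rules)
      }
      res <- apply_filter(detections, occ, ref, rules)
      detections <<- res$detections
      write_audit(res$audit, path_of("audit.tsv"))
      utils::write.table(res$detections, path_of("filtered.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      register("audit.tsv"); register("filtered.tsv")
    })
  }

  mat <- NULL
  if ("pool" %in% stages) {
    run_stage("pool", function() {
      scope <- (config$pool %||% list())$primer_scope %||% "combined"
      mat <<- pool_by_event(detections, samples, scope)
      write_matrix(mat, path_of("matrix.tsv"))
      register("matrix.tsv")
      manifest$parameters$pool <<- list(primer_scope = scope)
    })
  }

  if ("stats" %in% stages) {
    run_stage("stats", function() {
      if (is.null(mat)) stop("stats requires the pool stage")
      freqs <- classify_rarity(detection_frequency(mat))
      utils::write.table(freqs, path_of("frequencies.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      rich <- list(overall = richness(mat),
                   by_location = richness(mat, "location"),
                   by_substrate = richness(mat, "substrate"),
                   by_season = richness(mat, "season"))
      jsonlite::write_json(rich, path_of("richness.json"),
                           dataframe = "rows", auto_unbox = TRUE,
                           digits = NA)
      ov <- if (length(unique(mat$events$substrate)) >= 2L) {
        ovv <- overlap(mat, "substrate")
        ovv[c("levels", "richness", "exclusive", "shared_all", "union",
              "pct_shared_all")]
      } else NULL
      pd <- positives_distribution(mat, by_substrate = TRUE)
      jsonlite::write_json(list(overlap_substrate = ov, positives = pd),
                           path_of("overlap.json"), auto_unbox = TRUE,
                           digits = NA)
      dj <- community_distance(mat, "jaccard")
      utils::write.table(data.frame(event_id = rownames(dj), dj,
                                    check.names = FALSE),
                         path_of("distance_jaccard.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      register("frequencies.tsv"); register("richness.json")
      register("overlap.json"); register("distance_jaccard.tsv")
    })
  }

  if ("design" %in% stages) {
    run_stage("design", function() {
      dc <- config$design %||% list()
      k_sub <- as.integer(dc$k_sub %||% 4L)
      min_rep <- as.integer(dc$min_replicates %||% 8L)
      n_perm <- as.integer(dc$n_permutations %||% 200L)
      paired <- paired_days(samples, min_replicates = min_rep)
      if (nrow(paired) == 0L) stop("no paired water/sediment days")
      built <- build_mixed_design(detections, samples, paired, k_sub = k_sub,
                                  seed = stage_seeds[["design"]])
      cmp <- compare_designs(built$mixed, built$sediment, built$water,
                             n_permutations = n_perm,
                             seed = stage_seeds[["design"]])
      jsonlite::write_json(cmp$summary, path_of("design_summary.json"),
                           dataframe = "rows", auto_unbox = TRUE,
                           digits = NA)
      utils::write.table(cmp$curves, path_of("design_curves.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      register("design_summary.json"); register("design_curves.tsv")
      manifest$parameters$design <<- list(k_sub = k_sub,
                                          n_paired_days = nrow(paired),
                                          n_permutations = n_perm)
    })
  }

  finish()
  register("manifest.json")
  if ("report" %in% stages) {
    run_stage("report", function() {
      report_run(out_dir)
    })
    finish()
  }
  invisible(manifest)
}

#' Write a human-readable run report
#'
#' Summarizes the artifacts of a pipeline run directory into
#' `report.md`: filter decisions by reason, richness by grouping, substrate
#' overlap, detection-frequency/rarity counts, positives-per-event
#' distribution, and the design comparison when present.
#'
#' @param out_dir a directory written by [run_pipeline()].
#' @return the report path, invisibly.
#' @export
report_run <- function(out_dir) {
  need <- file.path(out_dir, c("frequencies.tsv", "richness.json",
                               "overlap.json"))
  missing_files <- need[!file.exists(need)]
  if (length(missing_files) > 0L) {
    stop("cannot build report; missing: ",
         paste(basename(missing_files), collapse = ", "))
  }
  lines <- c("# Survey post-processing report", "")
  audit_path <- file.path(out_dir, "audit.tsv")
  if (file.exists(audit_path)) {
    audit <- utils::read.delim(audit_path, stringsAsFactors = FALSE)
    tab <- summarize_decisions(audit)
    lines <- c(lines, "## Filter decisions", "",
               sprintf("- %s / %s: %d", tab$action, tab$reason_code, tab$n),
               "")
  }
  rich <- jsonlite::read_json(file.path(out_dir, "richness.json"),
                              simplifyVector = TRUE)
  lines <- c(lines, "## Species richness", "",
             sprintf("- overall: %d species over %d sampling events",
                     rich$overall$richness, rich$overall$n_events),
             sprintf("- %s (%s): %d species", "substrate",
                     rich$by_substrate$substrate, rich$by_substrate$richness),
             sprintf("- %s (%s): %d species", "season",
                     rich$by_season$season, rich$by_season$richness), "")
  ov <- jsonlite::read_json(file.path(out_dir, "overlap.json"),
                            simplifyVector = TRUE)
  if (!is.null(ov$overlap_substrate)) {
    o <- ov$overlap_substrate
    lines <- c(lines, "## Substrate overlap", "",
               sprintf("- union: %d species; shared by all substrates: %d (%d%%)",
                       o$union, o$shared_all, o$pct_shared_all), "")
  }
  freqs <- utils::read.delim(file.path(out_dir, "frequencies.tsv"),
                             stringsAsFactors = FALSE)
  lines <- c(lines, "## Detection frequency", "",
             sprintf("- %d species; frequency range %.3f-%.3f",
                     nrow(freqs), min(freqs$freq_overall),
                     max(freqs$freq_overall)),
             sprintf("- rare (< 0.1): %d; abundant: %d",
                     sum(freqs$rarity == "rare"),
                     sum(freqs$rarity == "abundant")), "")
  if (!is.null(ov$positives)) {
    md <- vapply(ov$positives, function(p) {
      if (is.null(p$mode) || length(p$mode) == 0L) NA_integer_ else
        as.integer(p$mode)
    }, integer(1L))
    lines <- c(lines, "## Positive replicates per detection", "",
               sprintf("- %s: mode %s", names(md), md), "")
  }
  ds_path <- file.path(out_dir, "design_summary.json")
  if (file.exists(ds_path)) {
    ds <- jsonlite::read_json(ds_path, simplifyVector = TRUE)
    lines <- c(lines, "## Sampling-design comparison", "",
               sprintf("- %s: mean event richness %.1f +/- %.1f, overall %d",
                       ds$design, ds$mean_event_richness,
                       ds$sd_event_richness, as.integer(ds$overall_richness)),
               "")
  }
  path <- file.path(out_dir, "report.md")
  writeLines(lines, path)
  invisible(path)
}
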