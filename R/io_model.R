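# Data model and IO: sample metadata, taxonomic assignment tables, and the
# pooling of replicate samples into sampling-event detection matrices.

SUBSTRATES <- c("water", "sediment", "soil")
SEASONS <- c("wet", "dry")
PRIMERS <- c("12SV5", "MiMammal")
PRIMER_SCOPES <- c(PRIMERS, "combined")

#' Read a sample metadata table
#'
#' Reads a delimited table of replicate samples. Each row is one field sample;
#' a sampling event is the set of replicates of one substrate collected at one
#' location on one day. If no `event_id` column is present, event identifiers
#' are synthesized as `location_substrate_date`.
#'
#' Required columns: `sample_id`, `location`, `substrate` (water/sediment/soil),
#' `season` (wet/dry), `date` (ISO 8601), `replicate_index`. Optional:
#' `event_id`, `volume_ml` (water samples only; soil must not carry a volume).
#'
#' @param path path to a tab-separated file (set `delim = ","` for CSV).
#' @param delim field delimiter, `"\t"` by default.
#' @return a `data.frame` of validated sample records, one row per sample.
#' @export
read_sample_metadata <- function(path, delim = "\t") {
  stopifnot(file.exists(path))
  df <- utils::read.delim(path, sep = delim, stringsAsFactors = FALSE,
                          colClasses = "character", check.names = FALSE)
  validate_sample_metadata(df)
}

#' Validate an in-memory sample metadata table
#'
#' Applies the same checks as [read_sample_metadata()] to a data frame that was
#' built in code (e.g., by [generate_survey()]).
#'
#' @param df data frame with the columns documented in [read_sample_metadata()].
#' @return the validated, type-normalized data frame.
#' @export
validate_sample_metadata <- function(df) {
  req <- c("sample_id", "location", "substrate", "season", "date",
           "replicate_index")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols) > 0L) {
    stop("metadata is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  df$sample_id <- trimws(as.character(df$sample_id))
  dup <- df$sample_id[duplicated(df$sample_id)]
  if (length(dup) > 0L) {
    stop("duplicate sample_id in metadata: ",
         paste(unique(dup), collapse = ", "))
  }
  df$substrate <- trimws(as.character(df$substrate))
  bad <- which(!df$substrate %in% SUBSTRATES)
  if (length(bad) > 0L) {
    stop("unknown substrate '", df$substrate[bad[1L]], "' at row ", bad[1L],
         " (expected one of: ", paste(SUBSTRATES, collapse = ", "), ")")
  }
  df$season <- trimws(as.character(df$season))
  bad <- which(!df$season %in% SEASONS)
  if (length(bad) > 0L) {
    stop("unknown season '", df$season[bad[1L]], "' at row ", bad[1L],
         " (expected one of: ", paste(SEASONS, collapse = ", "), ")")
  }
  df$date <- as.character(as.Date(df$date))
  df$replicate_index <- as.integer(df$replicate_index)
  if (anyNA(df$replicate_index) || any(df$replicate_index < 1L)) {
    stop("replicate_index must be a positive integer for every sample")
  }
  if (!"volume_ml" %in% names(df)) {
    df$volume_ml <- NA_real_
  } else {
    df$volume_ml <- suppressWarnings(as.numeric(df$volume_ml))
    if (any(!is.na(df$volume_ml) & df$volume_ml < 0)) {
      stop("volume_ml must be nonnegative")
    }
  }
  if (any(df$substrate == "soil" & !is.na(df$volume_ml))) {
    stop("soil samples must not carry volume_ml")
  }
  if (!"event_id" %in% names(df) || all(is.na(df$event_id)) ||
      all(trimws(df$event_id) == "")) {
    df$event_id <- paste(df$location, df$substrate, df$date, sep = "_")
  }
  df$event_id <- trimws(as.character(df$event_id))
  # all samples of an event must agree on its annotations
  key <- df$event_id
  for (col in c("location", "substrate", "season", "date")) {
    n_per_event <- tapply(df[[col]], key, function(x) length(unique(x)))
    if (any(n_per_event > 1L)) {
      stop("event '", names(n_per_event)[which(n_per_event > 1L)[1L]],
           "' has inconsistent ", col)
    }
  }
  rownames(df) <- NULL
  df[c("sample_id", "event_id", "location", "substrate", "season", "date",
       "replicate_index", "volume_ml")]
}

#' Read a taxonomic assignment table
#'
#' Reads per-sample taxonomic detections. Required columns: `sample_id`,
#' `primer` (12SV5/MiMammal), `taxon_name`, `rank` (species/genus),
#' `read_count`. Rows with `read_count` 0 are dropped (with a message giving
#' the count); taxon names are whitespace-normalized.
#'
#' @inheritParams read_sample_metadata
#' @return a `data.frame` of detections.
#' @export
read_assignments <- function(path, delim = "\t") {
  stopifnot(file.exists(path))
  df <- utils::read.delim(path, sep = delim, stringsAsFactors = FALSE,
                          check.names = FALSE)
  validate_assignments(df)
}

#' Validate an in-memory assignment table
#'
#' @param df data frame with the columns documented in [read_assignments()].
#' @return the validated data frame, zero-read rows removed.
#' @export
validate_assignments <- function(df) {
  req <- c("sample_id", "primer", "taxon_name", "rank", "read_count")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols) > 0L) {
    stop("assignments are missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  df$sample_id <- trimws(as.character(df$sample_id))
  df$primer <- trimws(as.character(df$primer))
  bad <- which(!df$primer %in% PRIMERS)
  if (length(bad) > 0L) {
    stop("unknown primer '", df$primer[bad[1L]], "' at row ", bad[1L])
  }
  df$taxon_name <- gsub("\\s+", " ", trimws(as.character(df$taxon_name)))
  if (any(df$taxon_name == "")) stop("empty taxon_name")
  df$rank <- trimws(as.character(df$rank))
  bad <- which(!df$rank %in% c("species", "genus"))
  if (length(bad) > 0L) {
    stop("unknown rank '", df$rank[bad[1L]], "' at row ", bad[1L])
  }
  df$read_count <- as.integer(df$read_count)
  if (anyNA(df$read_count) || any(df$read_count < 0L)) {
    stop("read_count must be a nonnegative integer")
  }
  n_zero <- sum(df$read_count == 0L)
  if (n_zero > 0L) {
    message("dropping ", n_zero, " assignment row(s) with read_count 0")
    df <- df[df$read_count > 0L, , drop = FALSE]
  }
  rownames(df) <- NULL
  df[req]
}

#' Construct a detection matrix
#'
#' Low-level constructor for the species-by-event container used throughout
#' the package. `positives[s, e]` counts the replicate samples of event `e`
#' in which species `s` was detected; incidence is `positives >= 1`.
#'
#' @param positives integer matrix, species in rows (rownames = species names),
#'   events in columns (colnames = event ids).
#' @param events data frame with one row per event: `event_id`, `location`,
#'   `substrate`, `season`, `date`, `n_replicates`.
#' @param primer_scope `"12SV5"`, `"MiMammal"` or `"combined"`.
#' @return an object of class `detection_matrix`.
#' @export
detection_matrix <- function(positives, events, primer_scope = "combined") {
  stopifnot(is.matrix(positives))
  primer_scope <- match.arg(primer_scope, PRIMER_SCOPES)
  positives <- matrix(as.integer(positives), nrow = nrow(positives),
                      dimnames = dimnames(positives))
  if (is.null(rownames(positives))) stop("positives needs species rownames")
  if (anyDuplicated(rownames(positives)) > 0L) {
    stop("duplicate species in detection matrix")
  }
  events <- as.data.frame(events, stringsAsFactors = FALSE)
  req <- c("event_id", "location", "substrate", "season", "date",
           "n_replicates")
  stopifnot(all(req %in% names(events)))
  events$n_replicates <- as.integer(events$n_replicates)
  if (is.null(colnames(positives))) colnames(positives) <- events$event_id
  if (!identical(colnames(positives), as.character(events$event_id))) {
    events <- events[match(colnames(positives), events$event_id), ,
                     drop = FALSE]
    if (anyNA(events$event_id)) stop("event annotations do not match columns")
  }
  if (any(positives < 0L)) stop("positives must be nonnegative")
  over <- sweep(positives, 2L, events$n_replicates, ">")
  if (any(over)) stop("positives exceed n_replicates for some event")
  rownames(events) <- NULL
  structure(list(species = rownames(positives), events = events,
                 positives = positives, primer_scope = primer_scope),
            class = "detection_matrix")
}

#' @export
print.detection_matrix <- function(x, ...) {
  cat("detection_matrix:", length(x$species), "species x",
      nrow(x$events), "sampling events (scope:", x$primer_scope, ")\n")
  cat("  substrates:",
      paste(names(table(x$events$substrate)), table(x$events$substrate),
            sep = ":", collapse = "  "), "\n")
  cat("  total detections (incidences):", sum(x$positives >= 1L), "\n")
  invisible(x)
}

#' Incidence matrix of a detection matrix
#'
#' @param x a `detection_matrix`.
#' @return logical species-by-event matrix (`TRUE` = detected in the event).
#' @export
incidence <- function(x) {
  stopifnot(inherits(x, "detection_matrix"))
  x$positives >= 1L
}

#' Pool replicate-level detections into sampling events
#'
#' Implements the event-pooling rule: a species is incident in a sampling
#' event if at least one replicate sample of that event detects it under the
#' requested primer scope, and the positive-replicate count is the number of
#' distinct replicates detecting it. Under the combined scope a replicate
#' counts once if either primer detects the species in it (union at replicate
#' level, then count).
#'
#' Detections must already be species-level: genus-rank rows are rejected, so
#' assignment tables must pass [apply_filter()] first.
#'
#' @param detections assignment data frame (see [read_assignments()]).
#' @param samples sample metadata data frame (see [read_sample_metadata()]).
#' @param primer_scope `"combined"` (default), `"12SV5"` or `"MiMammal"`.
#' @return a [detection_matrix()] whose columns are every sampling event in
#'   `samples` (events with no detections yield all-zero columns).
#' @export
pool_by_event <- function(detections, samples,
                          primer_scope = c("combined", "12SV5", "MiMammal")) {
  primer_scope <- match.arg(primer_scope)
  samples <- validate_sample_metadata(samples)
  detections <- validate_assignments(detections)
  if (any(detections$rank != "species")) {
    stop("pool_by_event requires species-level detections; ",
         sum(detections$rank != "species"),
         " genus-rank row(s) present (run apply_filter first)")
  }
  orphans <- setdiff(detections$sample_id, samples$sample_id)
  if (length(orphans) > 0L) {
    stop("detections reference sample_id(s) absent from metadata: ",
         paste(utils::head(sort(orphans), 10L), collapse = ", "))
  }
  if (primer_scope == "combined" &&
      length(unique(detections$primer)) == 1L && nrow(detections) > 0L) {
    warning("primer_scope = 'combined' but input carries a single primer (",
            detections$primer[1L], "); proceeding")
  }
  if (primer_scope != "combined") {
    detections <- detections[detections$primer == primer_scope, ,
                             drop = FALSE]
  }
  events <- unique(samples[c("event_id", "location", "substrate", "season",
                             "date")])
  reps <- table(samples$event_id)
  events$n_replicates <- as.integer(reps[events$event_id])
  species <- sort(unique(detections$taxon_name))
  pos <- matrix(0L, nrow = length(species), ncol = nrow(events),
                dimnames = list(species, events$event_id))
  if (nrow(detections) > 0L) {
    idx <- match(detections$sample_id, samples$sample_id)
    # count distinct replicates per (species, event): primer union collapses
    # multiple detections of the same species in the same replicate to one
    hits <- unique(data.frame(species = detections$taxon_name,
                              event = samples$event_id[idx],
                              sample = detections$sample_id,
                              stringsAsFactors = FALSE))
    tab <- table(factor(hits$species, levels = species),
                 factor(hits$event, levels = events$event_id))
    pos <- matrix(as.integer(tab), nrow = length(species),
                  dimnames = list(species, events$event_id))
  }
  detection_matrix(pos, events, primer_scope)
}

#' Write a detection matrix to disk
#'
#' Writes a TSV with species rows and event columns (cells are
#' positive-replicate counts) plus a JSON sidecar `<path>.events.json` with
#' the event annotations and primer scope.
#'
#' @param x a `detection_matrix`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(x, path) {
  stopifnot(inherits(x, "detection_matrix"))
  df <- data.frame(species = x$species, x$positives, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  sidecar <- list(primer_scope = x$primer_scope, events = x$events)
  jsonlite::write_json(sidecar, paste0(path, ".events.json"),
                       dataframe = "columns", auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a detection matrix written by [write_matrix()]
#'
#' @param path TSV path previously written by [write_matrix()].
#' @return a `detection_matrix`.
#' @export
read_matrix <- function(path) {
  stopifnot(file.exists(path), file.exists(paste0(path, ".events.json")))
  df <- utils::read.delim(path, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE)
  sidecar <- jsonlite::read_json(paste0(path, ".events.json"),
                                 simplifyVector = TRUE)
  pos <- as.matrix(df[, -1L, drop = FALSE])
  rownames(pos) <- df$species
  events <- as.data.frame(sidecar$events, stringsAsFactors = FALSE)
  detection_matrix(pos, events, sidecar$primer_scope)
}

#' Restrict a detection matrix to a subset of events
#'
#' @param x a `detection_matrix`.
#' @param keep logical or index vector over events, or event ids.
#' @param drop_empty_species drop species never detected in the kept events.
#' @return a `detection_matrix` over the kept events.
#' @export
subset_events <- function(x, keep, drop_empty_species = FALSE) {
  stopifnot(inherits(x, "detection_matrix"))
  if (is.character(keep)) keep <- match(keep, x$events$event_id)
  pos <- x$positives[, keep, drop = FALSE]
  ev <- x$events[keep, , drop = FALSE]
  if (drop_empty_species) {
    pos <- pos[rowSums(pos) > 0L, , drop = FALSE]
  }
  detection_matrix(pos, ev, x$primer_scope)
}
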