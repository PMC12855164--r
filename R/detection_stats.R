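# Descriptive statistics on a detection matrix: richness by grouping,
# shared/exclusive species, detection frequency, rarity classes,
# positives-per-event distributions, community distances.

EVENT_FACTORS <- c("location", "substrate", "season", "date")

#' Species richness by grouping
#'
#' A species counts toward a group if it is incident in at least one sampling
#' event of that group.
#'
#' @param x a `detection_matrix`.
#' @param group_by `NULL` for overall richness, `"event"` for per-event
#'   richness, or a vector of event annotation names (any of `location`,
#'   `substrate`, `season`, `date`).
#' @return a data frame with the grouping columns, `n_events`, and `richness`.
#' @export
richness <- function(x, group_by = NULL) {
  stopifnot(inherits(x, "detection_matrix"))
  inc <- incidence(x)
  if (is.null(group_by)) {
    return(data.frame(n_events = nrow(x$events),
                      richness = sum(rowSums(inc) > 0L)))
  }
  if (identical(group_by, "event")) {
    return(data.frame(event_id = x$events$event_id,
                      n_events = 1L,
                      richness = as.integer(colSums(inc)),
                      stringsAsFactors = FALSE))
  }
  bad <- setdiff(group_by, EVENT_FACTORS)
  if (length(bad) > 0L) {
    stop("unknown grouping factor(s): ", paste(bad, collapse = ", "),
         "; valid factors: event, ", paste(EVENT_FACTORS, collapse = ", "))
  }
  key <- interaction(x$events[group_by], drop = TRUE, sep = "\r")
  groups <- levels(key)
  rich <- vapply(groups, function(g) {
    cols <- which(key == g)
    sum(rowSums(inc[, cols, drop = FALSE]) > 0L)
  }, integer(1L))
  nev <- as.integer(table(key)[groups])
  lab <- do.call(rbind, strsplit(groups, "\r", fixed = TRUE))
  out <- data.frame(lab, stringsAsFactors = FALSE)
  names(out) <- group_by
  out$n_events <- nev
  out$richness <- rich
  rownames(out) <- NULL
  out
}

#' Shared and exclusive species across the levels of a factor
#'
#' Exact set arithmetic on the incident-species sets of each factor level:
#' per-level richness, species exclusive to each level, all pairwise
#' intersections, the all-level intersection, and the union, with percentages
#' of the union rounded to the nearest integer (ties away from zero).
#'
#' @param x a `detection_matrix`, or a named list of character vectors of
#'   species (e.g., the species sets of two primer datasets).
#' @param factor_name event annotation to split on when `x` is a matrix
#'   (`substrate`, `season`, ...); ignored for a list input.
#' @return an object of class `overlap_summary`: list with `levels`,
#'   `richness`, `exclusive`, `pairwise` (data frame), `shared_all`, `union`,
#'   and `pct` (percent of union shared, per pair and for all levels).
#' @export
overlap <- function(x, factor_name = NULL) {
  if (inherits(x, "detection_matrix")) {
    stopifnot(!is.null(factor_name), factor_name %in% EVENT_FACTORS)
    lv <- unique(x$events[[factor_name]])
    if (length(lv) < 2L) {
      stop("factor '", factor_name, "' has fewer than 2 levels in the matrix")
    }
    inc <- incidence(x)
    sets <- lapply(lv, function(l) {
      cols <- which(x$events[[factor_name]] == l)
      x$species[rowSums(inc[, cols, drop = FALSE]) > 0L]
    })
    names(sets) <- lv
  } else {
    sets <- x
    stopifnot(is.list(sets), !is.null(names(sets)), length(sets) >= 2L)
    sets <- lapply(sets, unique)
  }
  lv <- names(sets)
  uni <- unique(unlist(sets))
  rich <- vapply(sets, length, integer(1L))
  excl <- vapply(lv, function(l) {
    length(setdiff(sets[[l]], unlist(sets[setdiff(lv, l)])))
  }, integer(1L))
  pairs <- utils::combn(lv, 2L, simplify = FALSE)
  pw <- data.frame(
    level_a = vapply(pairs, `[`, character(1L), 1L),
    level_b = vapply(pairs, `[`, character(1L), 2L),
    shared = vapply(pairs, function(p) {
      length(intersect(sets[[p[1L]]], sets[[p[2L]]]))
    }, integer(1L)),
    stringsAsFactors = FALSE)
  shared_all <- length(Reduce(intersect, sets))
  pw$pct_of_union <- round_half_away(100 * pw$shared / length(uni))
  structure(list(levels = lv, richness = rich, exclusive = excl,
                 pairwise = pw, shared_all = shared_all,
                 union = length(uni),
                 pct_shared_all = round_half_away(100 * shared_all /
                                                    length(uni))),
            class = "overlap_summary")
}

#' @export
print.overlap_summary <- function(x, ...) {
  cat("overlap over", length(x$levels), "levels; union =", x$union,
      "species\n")
  print(data.frame(level = x$levels, richness = x$richness,
                   exclusive = x$exclusive, row.names = NULL))
  cat("shared by all levels:", x$shared_all,
      paste0("(", x$pct_shared_all, "% of union)\n"))
  invisible(x)
}

# nearest integer, ties away from zero (round() in R rounds half to even)
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Species detection frequencies
#'
#' Detection frequency is the proportion of sampling events in which a
#' species is detected. The overall denominator is every event in the matrix
#' regardless of substrate; per-substrate frequencies use the events of that
#' substrate.
#'
#' @param x a `detection_matrix`.
#' @return data frame with one row per species: `species`, `n_events_overall`,
#'   `freq_overall`, and `n_events_<substrate>` / `freq_<substrate>` for each
#'   substrate present.
#' @export
detection_frequency <- function(x) {
  stopifnot(inherits(x, "detection_matrix"), nrow(x$events) > 0L)
  inc <- incidence(x)
  out <- data.frame(species = x$species,
                    n_events_overall = nrow(x$events),
                    freq_overall = rowSums(inc) / nrow(x$events),
                    stringsAsFactors = FALSE)
  for (sub in intersect(SUBSTRATES, unique(x$events$substrate))) {
    cols <- which(x$events$substrate == sub)
    out[[paste0("n_events_", sub)]] <- length(cols)
    out[[paste0("freq_", sub)]] <-
      rowSums(inc[, cols, drop = FALSE]) / length(cols)
  }
  rownames(out) <- NULL
  out
}

#' Classify species as rare or abundant
#'
#' A species is rare when its overall detection frequency is strictly below
#' the threshold; a frequency exactly at the threshold is abundant.
#'
#' @param freqs data frame from [detection_frequency()].
#' @param threshold rarity threshold on the overall frequency, default 0.1.
#' @return `freqs` with an added `rarity` column (`"rare"`/`"abundant"`) and
#'   the threshold attached as attribute `threshold`.
#' @export
classify_rarity <- function(freqs, threshold = 0.1) {
  stopifnot(is.numeric(threshold), threshold > 0, threshold < 1)
  freqs$rarity <- ifelse(freqs$freq_overall < threshold, "rare", "abundant")
  attr(freqs, "threshold") <- threshold
  freqs
}

#' Distribution of positive replicates per detection
#'
#' For every (species, event) cell with at least one positive replicate, the
#' positive-replicate count contributes one observation. The mode of 1
#' typical of eDNA surveys reflects the patchy distribution of eDNA across
#' replicate samples.
#'
#' @param x a `detection_matrix`.
#' @param by_substrate tabulate separately per substrate.
#' @return for `by_substrate = FALSE`, a list with `histogram` (named integer
#'   vector over positive counts), `median`, and `mode` (smallest value in
#'   case of a tied maximum); otherwise a named list of such lists.
#' @export
positives_distribution <- function(x, by_substrate = FALSE) {
  stopifnot(inherits(x, "detection_matrix"))
  one <- function(pos) {
    v <- pos[pos >= 1L]
    if (length(v) == 0L) {
      return(list(histogram = integer(0L), median = NA_real_,
                  mode = NA_integer_))
    }
    h <- table(v)
    hist <- stats::setNames(as.integer(h), names(h))
    list(histogram = hist,
         median = stats::median(v),
         mode = as.integer(names(hist)[which.max(hist)]))
  }
  if (!by_substrate) return(one(x$positives))
  subs <- intersect(SUBSTRATES, unique(x$events$substrate))
  out <- lapply(subs, function(s) {
    one(x$positives[, x$events$substrate == s, drop = FALSE])
  })
  stats::setNames(out, subs)
}

#' Community distance matrix between sampling events
#'
#' Jaccard distance (1 - shared/union) on species incidence, or Bray-Curtis
#' dissimilarity on positive-replicate counts. Pairs of events with no
#' species at all are assigned distance 0 with a warning.
#'
#' @param x a `detection_matrix` with at least two events.
#' @param metric `"jaccard"` or `"bray_curtis"`.
#' @return symmetric numeric matrix over events (zero diagonal, values in
#'   \eqn{[0, 1]}).
#' @export
community_distance <- function(x, metric = c("jaccard", "bray_curtis")) {
  stopifnot(inherits(x, "detection_matrix"), nrow(x$events) >= 2L)
  metric <- match.arg(metric)
  comm <- t(x$positives)  # events as rows, as vegan expects
  empty <- rowSums(comm) == 0L
  # vegdist warns on empty rows; empties are handled by the convention below
  d <- suppressWarnings(switch(metric,
    jaccard = vegan::vegdist(comm, method = "jaccard", binary = TRUE),
    bray_curtis = vegan::vegdist(comm, method = "bray")))
  m <- as.matrix(d)
  if (sum(empty) >= 2L) {
    warning(sum(empty), " events with no detections; ",
            "their mutual distances are set to 0 by convention")
    m[empty, empty] <- 0
  }
  m[is.na(m)] <- 0
  diag(m) <- 0
  dimnames(m) <- list(x$events$event_id, x$events$event_id)
  m
}
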