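# Occurrence-catalog plausibility filtering of taxonomic assignments.
#
# Each distinct assigned taxon is accepted, reassigned to the unique
# documented congener, or excluded, with an audit row recording the decision
# and the congener counts that drove it.

#' Canonicalize a taxon name
#'
#' Collapses whitespace, truncates trinomials (subspecies) to the binomial,
#' and applies a flat alias table (e.g., outdated synonyms).
#'
#' @param name character vector of taxon names.
#' @param rank `"species"` or `"genus"` (vectorized).
#' @param aliases named character vector mapping old names to current names.
#' @return canonicalized character vector.
#' @export
canonicalize_name <- function(name, rank = "species", aliases = NULL) {
  name <- gsub("\\s+", " ", trimws(name))
  rank <- rep_len(rank, length(name))
  is_sp <- rank == "species"
  parts <- strsplit(name, " ", fixed = TRUE)
  name[is_sp] <- vapply(parts[is_sp], function(p) {
    paste(p[seq_len(min(2L, length(p)))], collapse = " ")
  }, character(1L))
  name[!is_sp] <- vapply(parts[!is_sp], `[`, character(1L), 1L)
  if (!is.null(aliases) && length(aliases) > 0L) {
    hit <- match(name, names(aliases))
    name[!is.na(hit)] <- unname(aliases[hit[!is.na(hit)]])
  }
  name
}

#' Build an occurrence catalog
#'
#' A regional occurrence catalog lists the species with documented records in
#' the study region (e.g., retrieved from GBIF). Species names are
#' canonicalized and indexed by genus so that congener sets can be resolved.
#'
#' @param species character vector of documented species names (binomials), or
#'   a data frame with columns `species` and optional `documented`
#'   (logical/0-1; non-documented rows are ignored).
#' @return an object of class `occurrence_catalog`.
#' @export
occurrence_catalog <- function(species) {
  if (is.data.frame(species)) {
    df <- species
    stopifnot("species" %in% names(df))
    if ("documented" %in% names(df)) {
      keep <- as.logical(df$documented) |
        df$documented %in% c("1", "true", "TRUE", "yes")
      df <- df[keep, , drop = FALSE]
    }
    species <- df$species
  }
  species <- unique(canonicalize_name(species))
  if (length(species) == 0L) stop("occurrence catalog is empty")
  genus <- vapply(strsplit(species, " ", fixed = TRUE), `[`, character(1L), 1L)
  structure(list(documented_species = species,
                 genus_index = split(species, genus)),
            class = "occurrence_catalog")
}

#' Read an occurrence catalog from CSV
#'
#' Expects columns `species` and optionally `genus` (ignored; derived from the
#' binomial) and `documented`.
#'
#' @param path CSV path.
#' @return an `occurrence_catalog`.
#' @export
read_occurrence_catalog <- function(path) {
  occurrence_catalog(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Build a marker reference-sequence catalog
#'
#' Records, per species, whether a reference sequence for the metabarcoding
#' marker is available. Querying a species absent from the catalog returns
#' `NA` ("unknown"), which is distinct from `FALSE`.
#'
#' @param species character vector of species names, or a data frame with
#'   columns `species` and `has_reference`.
#' @param has_reference logical vector aligned with `species` (ignored when a
#'   data frame is given).
#' @return an object of class `reference_catalog`.
#' @export
reference_catalog <- function(species, has_reference = NULL) {
  if (is.data.frame(species)) {
    stopifnot(all(c("species", "has_reference") %in% names(species)))
    has_reference <- as.logical(species$has_reference) |
      species$has_reference %in% c("1", "true", "TRUE", "yes")
    species <- species$species
  }
  species <- canonicalize_name(species)
  stopifnot(length(species) == length(has_reference))
  map <- as.logical(has_reference)
  names(map) <- species
  structure(list(has_reference = map), class = "reference_catalog")
}

#' Read a reference catalog from CSV
#'
#' Expects columns `species` and `has_reference` (an optional `marker` column
#' is collapsed: a species has a reference if any marker row says so).
#'
#' @param path CSV path.
#' @return a `reference_catalog`.
#' @export
read_reference_catalog <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("species", "has_reference") %in% names(df)))
  hr <- tapply(as.logical(df$has_reference) |
                 df$has_reference %in% c("1", "true", "TRUE", "yes"),
               canonicalize_name(df$species), any)
  reference_catalog(names(hr), unname(hr))
}

#' Query reference availability
#'
#' @param ref a `reference_catalog`.
#' @param species species names.
#' @return logical vector; `NA` for species unknown to the catalog.
#' @export
has_reference <- function(ref, species) {
  stopifnot(inherits(ref, "reference_catalog"))
  unname(ref$has_reference[canonicalize_name(species)])
}

#' Curation rules: blocklist, overrides, ambiguity mode
#'
#' @param blocklist character vector of taxa to exclude outright (domestic
#'   animals, humans, anthropogenic input such as food species).
#' @param overrides named character vector mapping an original name to the
#'   documented species it is re-classified to (e.g., a wolf assignment
#'   re-classified to the resident black-backed jackal).
#' @param ambiguity_mode how a unique congener is selected for non-documented
#'   taxa: `"documented_congener_unique"` (unique among all documented
#'   congeners) or `"unreferenced_congener_unique"` (unique among documented
#'   congeners lacking a marker reference sequence).
#' @param aliases named character vector of name synonyms applied during
#'   canonicalization.
#' @return an object of class `curation_rules`.
#' @export
curation_rules <- function(blocklist = character(),
                           overrides = character(),
                           ambiguity_mode = c("documented_congener_unique",
                                              "unreferenced_congener_unique"),
                           aliases = character()) {
  ambiguity_mode <- match.arg(ambiguity_mode)
  blocklist <- canonicalize_name(unique(blocklist))
  if (length(overrides) > 0L) {
    stopifnot(!is.null(names(overrides)))
    names(overrides) <- canonicalize_name(names(overrides))
    overrides <- stats::setNames(canonicalize_name(unname(overrides)),
                                 names(overrides))
  }
  clash <- intersect(blocklist, names(overrides))
  if (length(clash) > 0L) {
    stop("blocklist and overrides must be disjoint: ",
         paste(clash, collapse = ", "))
  }
  structure(list(blocklist = blocklist, overrides = overrides,
                 ambiguity_mode = ambiguity_mode, aliases = aliases),
            class = "curation_rules")
}

#' Read curation rules from YAML
#'
#' Expected keys: `blocklist` (list of names), `overrides` (map original ->
#' final), `ambiguity_mode`, `aliases` (map old -> new).
#'
#' @param path YAML path.
#' @return a `curation_rules` object.
#' @export
read_curation_rules <- function(path) {
  y <- yaml::read_yaml(path)
  curation_rules(
    blocklist = as.character(unlist(y$blocklist %||% character())),
    overrides = unlist(y$overrides %||% character()),
    ambiguity_mode = y$ambiguity_mode %||% "documented_congener_unique",
    aliases = unlist(y$aliases %||% character())
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Classify one assigned taxon against the catalogs
#'
#' Decision precedence: (1) blocklisted names are excluded; (2) override names
#' are reassigned to their configured target; (3) a documented species-rank
#' name is accepted; (4) otherwise the congener set of the genus is resolved
#' (all documented species of the genus for genus-rank input; documented
#' congeners for a non-documented species) and the ambiguity criterion is
#' applied: exactly one candidate reassigns to it, zero or several exclude the
#' taxon. Congener counts are always recorded.
#'
#' @param name taxon name (species binomial or genus).
#' @param rank `"species"` or `"genus"`.
#' @param occ an [occurrence_catalog()].
#' @param ref a [reference_catalog()] (used by the unreferenced-congener
#'   ambiguity mode).
#' @param rules a [curation_rules()] object.
#' @return one-row data frame: `original_name`, `original_rank`, `action`
#'   (accept/reassign/exclude), `final_name` (`NA` iff exclude),
#'   `reason_code`, `n_congeners_documented`, `n_congeners_unreferenced`.
#' @export
classify_taxon <- function(name, rank, occ, ref, rules) {
  stopifnot(inherits(occ, "occurrence_catalog"),
            inherits(ref, "reference_catalog"),
            inherits(rules, "curation_rules"),
            rank %in% c("species", "genus"))
  if (length(occ$documented_species) == 0L) stop("empty occurrence catalog")
  name <- canonicalize_name(name, rank, rules$aliases)
  decision <- function(action, final, reason, nd = 0L, nu = 0L) {
    data.frame(original_name = name, original_rank = rank, action = action,
               final_name = if (is.na(final)) NA_character_ else final,
               reason_code = reason,
               n_congeners_documented = as.integer(nd),
               n_congeners_unreferenced = as.integer(nu),
               stringsAsFactors = FALSE)
  }
  genus <- strsplit(name, " ", fixed = TRUE)[[1L]][1L]
  congeners <- occ$genus_index[[genus]] %||% character()
  if (rank == "species") congeners <- setdiff(congeners, name)
  unref <- congeners[!isTRUE_vec(has_reference(ref, congeners))]
  nd <- length(congeners)
  nu <- length(unref)

  if (name %in% rules$blocklist) {
    return(decision("exclude", NA, "blocklisted", nd, nu))
  }
  if (name %in% names(rules$overrides)) {
    target <- unname(rules$overrides[[name]])
    if (!target %in% occ$documented_species) {
      stop("override target '", target, "' is not a documented species")
    }
    return(decision("reassign", target, "override", nd, nu))
  }
  if (rank == "species" && name %in% occ$documented_species) {
    return(decision("accept", name, "documented", nd, nu))
  }
  if (rank == "species" && !grepl(" ", name)) {
    warning("species-rank name '", name, "' is not a binomial; excluding")
    return(decision("exclude", NA, "no_congener", 0L, 0L))
  }
  candidates <- switch(rules$ambiguity_mode,
                       documented_congener_unique = congeners,
                       unreferenced_congener_unique = unref)
  if (length(candidates) == 1L) {
    return(decision("reassign", candidates, "unique_congener", nd, nu))
  }
  if (length(candidates) == 0L) {
    return(decision("exclude", NA, "no_congener", nd, nu))
  }
  decision("exclude", NA, "ambiguous_congeners", nd, nu)
}

# TRUE where x is TRUE; FALSE where FALSE or NA (unknown reference status is
# treated as lacking a reference, mirroring how gap lists are compiled)
isTRUE_vec <- function(x) !is.na(x) & x

#' Filter an assignment table against the catalogs
#'
#' Classifies every distinct (name, rank) in the input once, removes
#' detections of excluded taxa, substitutes reassigned names, and merges
#' detections that land on the same final species within a sample/primer
#' (read counts summed).
#'
#' @param detections assignment data frame (see [read_assignments()]).
#' @inheritParams classify_taxon
#' @return list with `detections` (filtered, species-rank table) and `audit`
#'   (one `FilterDecision` row per distinct input taxon).
#' @export
apply_filter <- function(detections, occ, ref, rules) {
  detections <- validate_assignments(detections)
  if (nrow(detections) == 0L) {
    return(list(detections = detections,
                audit = classify_taxon("x y", "species", occ, ref, rules)[0, ]))
  }
  detections$taxon_name <- canonicalize_name(detections$taxon_name,
                                             detections$rank, rules$aliases)
  taxa <- unique(detections[c("taxon_name", "rank")])
  audit <- do.call(rbind, lapply(seq_len(nrow(taxa)), function(i) {
    classify_taxon(taxa$taxon_name[i], taxa$rank[i], occ, ref, rules)
  }))
  key_in <- paste(detections$taxon_name, detections$rank)
  key_audit <- paste(audit$original_name, audit$original_rank)
  idx <- match(key_in, key_audit)
  keep <- audit$action[idx] != "exclude"
  out <- detections[keep, , drop = FALSE]
  out$taxon_name <- audit$final_name[idx][keep]
  out$rank <- "species"
  if (nrow(out) > 0L) {
    agg <- stats::aggregate(read_count ~ sample_id + primer + taxon_name + rank,
                            data = out, FUN = sum)
    out <- agg[c("sample_id", "primer", "taxon_name", "rank", "read_count")]
  }
  rownames(out) <- NULL
  list(detections = out, audit = audit)
}

#' Tabulate filter decisions
#'
#' @param audit audit data frame from [apply_filter()].
#' @return data frame of counts by (`action`, `reason_code`); counts sum to
#'   the number of distinct input taxa.
#' @export
summarize_decisions <- function(audit) {
  stopifnot(nrow(audit) > 0L)
  tab <- stats::aggregate(list(n = seq_len(nrow(audit))),
                          by = audit[c("action", "reason_code")],
                          FUN = length)
  tab <- tab[order(tab$action, tab$reason_code), ]
  rownames(tab) <- NULL
  tab
}

#' Write the filter audit trail
#'
#' @param audit audit data frame from [apply_filter()].
#' @param path TSV output path.
#' @return `path`, invisibly.
#' @export
write_audit <- function(audit, path) {
  utils::write.table(audit, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}
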