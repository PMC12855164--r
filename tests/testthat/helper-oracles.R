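# Independent brute-force oracles. These re-derive every statistic by direct
# enumeration over raw cells, deliberately avoiding the package's code paths.

# random small detection matrix with annotations
random_small_matrix <- function(n_species = sample(1:10, 1),
                                n_events = sample(2:10, 1)) {
  n_rep <- sample(4:8, n_events, replace = TRUE)
  pos <- sapply(seq_len(n_events), function(e) {
    sample(0:n_rep[e], n_species, replace = TRUE)
  })
  pos <- matrix(as.integer(pos), nrow = n_species)
  rownames(pos) <- sprintf("sp%02d", seq_len(n_species))
  colnames(pos) <- sprintf("ev%02d", seq_len(n_events))
  events <- data.frame(
    event_id = colnames(pos),
    location = sample(c("A", "B"), n_events, replace = TRUE),
    substrate = sample(c("water", "sediment", "soil"), n_events,
                       replace = TRUE),
    season = sample(c("wet", "dry"), n_events, replace = TRUE),
    date = as.character(as.Date("2023-03-10") + seq_len(n_events)),
    n_replicates = n_rep, stringsAsFactors = FALSE)
  detection_matrix(pos, events)
}

# richness per group by explicit set union over events
oracle_richness_by_group <- function(mat, factor_name) {
  inc <- mat$positives >= 1L
  lv <- sort(unique(mat$events[[factor_name]]))
  sapply(lv, function(l) {
    sp <- character()
    for (e in which(mat$events[[factor_name]] == l)) {
      sp <- union(sp, rownames(inc)[inc[, e]])
    }
    length(sp)
  })
}

# overlap counts by enumerating each species' membership pattern
oracle_overlap <- function(mat, factor_name) {
  inc <- mat$positives >= 1L
  lv <- sort(unique(mat$events[[factor_name]]))
  membership <- sapply(lv, function(l) {
    apply(inc[, mat$events[[factor_name]] == l, drop = FALSE], 1L, any)
  })
  membership <- matrix(membership, ncol = length(lv),
                       dimnames = list(rownames(inc), lv))
  detected <- rowSums(membership) > 0L
  list(richness = colSums(membership),
       exclusive = sapply(lv, function(l) {
         sum(membership[, l] & rowSums(membership[, setdiff(lv, l),
                                                  drop = FALSE]) == 0L)
       }),
       shared_all = sum(rowSums(membership) == length(lv)),
       union = sum(detected))
}

oracle_frequency <- function(mat) {
  inc <- mat$positives >= 1L
  sapply(rownames(inc), function(s) sum(inc[s, ]) / ncol(inc))
}

oracle_jaccard <- function(pos, i, j) {
  a <- rownames(pos)[pos[, i] >= 1L]
  b <- rownames(pos)[pos[, j] >= 1L]
  u <- length(union(a, b))
  if (u == 0L) return(0)
  1 - length(intersect(a, b)) / u
}

oracle_bray <- function(pos, i, j) {
  x <- pos[, i]; y <- pos[, j]
  if (sum(x) + sum(y) == 0) return(0)
  sum(abs(x - y)) / sum(x + y)
}

# exact all-orderings accumulation mean via the hypergeometric closed form:
# E[richness at k] = sum_s (1 - C(K - n_s, k) / C(K, k))
oracle_accum_mean <- function(mat) {
  inc <- mat$positives >= 1L
  K <- ncol(inc)
  n_s <- rowSums(inc)
  sapply(seq_len(K), function(k) {
    sum(1 - choose(K - n_s, k) / choose(K, k))
  })
}

# independent re-derivation of the curation decision rule as one flat table
# of conditions evaluated in order
oracle_classify <- function(name, rank, documented, ref_map, blocklist,
                            overrides, mode) {
  genus <- strsplit(name, " ")[[1]][1]
  congeners <- documented[sub(" .*", "", documented) == genus]
  if (rank == "species") congeners <- congeners[congeners != name]
  lacking <- congeners[vapply(congeners, function(s) {
    is.na(ref_map[s]) || !ref_map[s]
  }, logical(1))]
  if (name %in% blocklist) {
    return(list(action = "exclude", reason = "blocklisted",
                final = NA_character_))
  }
  if (name %in% names(overrides)) {
    return(list(action = "reassign", reason = "override",
                final = unname(overrides[name])))
  }
  if (rank == "species" && name %in% documented) {
    return(list(action = "accept", reason = "documented", final = name))
  }
  cand <- if (mode == "documented_congener_unique") congeners else lacking
  if (length(cand) == 1L) {
    return(list(action = "reassign", reason = "unique_congener",
                final = cand))
  }
  if (length(cand) == 0L) {
    return(list(action = "exclude", reason = "no_congener",
                final = NA_character_))
  }
  list(action = "exclude", reason = "ambiguous_congeners",
       final = NA_character_)
}
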