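# Counterpart accession: target <-> decoy-prefixed accession (involution).
counterpart_accession <- function(accession, decoy_prefix = "REV__") {
  stripped <- strip_decoy_prefix(accession, decoy_prefix)
  ifelse(stripped == accession, paste0(decoy_prefix, accession), stripped)
}

apply_tds <- function(scored, tds, decoy_prefix = "REV__") {
  switch(tds,
         classic = scored,
         picked = picked_tds(scored, decoy_prefix = decoy_prefix),
         picked_group = picked_group_tds(scored, decoy_prefix = decoy_prefix),
         stop("unknown target-decoy strategy: ", tds))
}

#' Target-decoy competition strategies for protein (group) lists
#'
#' `picked_tds()` performs the protein-level competition for ungrouped
#' (singleton) lists: for each target/decoy pair observed on both sides only
#' the higher-scoring member is retained; unpaired entries and exact score
#' ties are retained.
#'
#' `picked_group_tds()` extends the competition to protein groups. Walking
#' down the list sorted by decreasing score, the member proteins of every
#' retained group are accumulated; a group is eliminated when the counterpart
#' of one of its leading proteins was observed among the members of a
#' strictly higher-scoring retained group. Checking candidate leading
#' proteins against retained members (rather than leading against leading)
#' keeps the competition symmetric when a protein is observed only as a
#' subsumed, non-leading group member. On singleton groups the rule reduces
#' exactly to `picked_tds()`.
#'
#' @param scored A scored group table from [score_groups()], sorted by
#'   decreasing score.
#' @param decoy_prefix Accession prefix defining target/decoy counterparts.
#' @return The scored group table with eliminated rows removed; scores are
#'   never altered.
#' @name target_decoy_competition
#' @export
picked_tds <- function(scored, decoy_prefix = "REV__") {
  if (nrow(scored) == 0L) return(scored)
  if (any(lengths(scored$members) != 1L)) {
    stop("picked_tds requires singleton protein groups; use picked_group_tds")
  }
  acc <- vapply(scored$members, `[`, character(1L), 1L)
  pair <- strip_decoy_prefix(acc, decoy_prefix)
  keep <- rep(TRUE, nrow(scored))
  for (p in unique(pair[duplicated(pair)])) {
    idx <- which(pair == p)
    best <- max(scored$score[idx])
    keep[idx[scored$score[idx] < best]] <- FALSE
  }
  scored[keep]
}

#' @rdname target_decoy_competition
#' @export
picked_group_tds <- function(scored, decoy_prefix = "REV__") {
  if (nrow(scored) == 0L) return(scored)
  if (is.unsorted(-scored$score)) stop("picked_group_tds requires a score-sorted list")
  n <- nrow(scored)
  keep <- rep(TRUE, n)
  seen <- new.env(hash = TRUE, parent = emptyenv())
  block_start <- 1L
  scores <- scored$score
  leading <- scored$leading
  members <- scored$members
  while (block_start <= n) {
    block_end <- block_start
    while (block_end < n && scores[block_end + 1L] == scores[block_start]) {
      block_end <- block_end + 1L
    }
    idx <- block_start:block_end
    for (i in idx) {
      cp <- counterpart_accession(leading[[i]], decoy_prefix)
      if (any(vapply(cp, exists, logical(1L), envir = seen, inherits = FALSE))) {
        keep[i] <- FALSE
      }
    }
    for (i in idx) {
      if (keep[i]) {
        for (a in members[[i]]) assign(a, TRUE, envir = seen)
      }
    }
    block_start <- block_end + 1L
  }
  scored[keep]
}

#' Estimate protein group-level FDR and q-values
#'
#' For a score-sorted group list, the FDR at a group is the ratio of decoy to
#' target groups with a score at least as good (the group counting itself in
#' its own class); entries before the first target get an infinite FDR. The
#' q-value is the minimum FDR at this or any worse score, reported capped at
#' 1. Calling this directly on a scored list without a competition step is
#' the classic target-decoy strategy. Contaminant groups are excluded from
#' both counts but still receive q-values.
#'
#' @param scored A scored group table sorted by decreasing score.
#' @return The table with `fdr` and `q_value` columns appended.
#' @export
estimate_group_fdr <- function(scored) {
  if (nrow(scored) == 0L) {
    out <- data.table::copy(scored)
    out[, `:=`(fdr = numeric(0), q_value = numeric(0))]
    return(out[])
  }
  if (is.unsorted(-scored$score)) stop("estimate_group_fdr requires a score-sorted list")
  out <- data.table::copy(scored)
  counted <- !out$is_contaminant
  d <- cumsum(out$is_decoy & counted)
  t <- cumsum(!out$is_decoy & counted)
  # groups tied on score share the counts at the end of their tie block
  r <- rle(out$score)
  tie_end <- rep(cumsum(r$lengths), r$lengths)
  d <- d[tie_end]
  t <- t[tie_end]
  fdr <- ifelse(t == 0L, Inf, d / t)
  out[, fdr := fdr]
  out[, q_value := pmin(rev(cummin(rev(fdr))), 1)]
  out[]
}

#' Evidence-level score cutoff equivalent to a group-level FDR
#'
#' With best-PEP scoring, a group's score is a monotone function of its best
#' peptide's PEP, so the lowest group score with q-value at or below
#' `threshold` doubles as an evidence-level cutoff: evidence passes when its
#' \eqn{-\log_{10}(\mathrm{PEP})} is at least the returned value.
#'
#' @param scored A scored group table with q-values.
#' @param threshold Group-level FDR threshold.
#' @return The score cutoff, or `NA` if no group reaches the threshold.
#' @export
psm_cutoff_for_group_fdr <- function(scored, threshold = 0.01) {
  pass <- scored$q_value <= threshold
  if (!any(pass)) return(NA_real_)
  min(scored$score[pass])
}
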