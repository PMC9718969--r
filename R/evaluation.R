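# Truth table from a simulated PSM table: per peptide, the union of present
# source proteins over all experiments where it was correct.
#' Collapse simulated truth labels to peptide level
#'
#' @param sim A simulated PSM table from [simulate_dataset()].
#' @return A `data.table` with one row per peptide that was ever correct:
#'   `peptide`, `true_sources` (character vector list column).
#' @export
collapse_truth <- function(sim) {
  tr <- sim[sim$truth_label == "correct", c("peptide", "true_sources")]
  tr <- tr[, list(src = unlist(strsplit(true_sources, ";", fixed = TRUE))),
           by = "peptide"]
  tr[, list(true_sources = list(unique(src))), by = "peptide"]
}

# TRUE/FALSE per group row: does the group contain a protein with a correct
# observation among its assigned peptides? Vectorized via a long join of
# (group row, assigned peptide) against (peptide, true source), with the
# member test delegated to the accession -> group map (groups partition the
# observed proteins, so src is a member of row i iff it maps to i's group).
group_truth <- function(fit, truth) {
  g <- fit$groups
  peps <- fit$peptides[g$group_id]
  gp <- data.table::data.table(row = rep(seq_len(nrow(g)), lengths(peps)),
                               peptide = unlist(peps, use.names = FALSE))
  tr <- truth[, list(src = unlist(true_sources)), by = "peptide"]
  hits <- gp[tr, on = "peptide", nomatch = NULL, allow.cartesian = TRUE]
  if (nrow(hits) == 0L) return(rep(FALSE, nrow(g)))
  amap <- fit$grouping$accession_map
  src_gid <- amap$group_id[match(hits$src, amap$accession)]
  good <- unique(hits$row[!is.na(src_gid) & src_gid == g$group_id[hits$row]])
  seq_len(nrow(g)) %in% good
}

#' Empirical false discovery proportion from simulation truth
#'
#' Among reported target (non-contaminant) groups with q-value at or below
#' `threshold`, a group counts as false when none of its assigned peptides is
#' a correct observation of a protein in the group -- the group-level null
#' hypothesis that none of the group's proteins had a correct observation.
#'
#' @param fit A [picked_group_fdr()] fit.
#' @param truth Peptide truth from [collapse_truth()], or a precomputed
#'   per-group logical correctness vector (one entry per reported group).
#' @param threshold Reported q-value threshold.
#' @return The false/total fraction, or `NA` when no group is accepted.
#' @export
empirical_fdp <- function(fit, truth, threshold = 0.01) {
  g <- fit$groups
  sel <- !g$is_decoy & !g$is_contaminant & g$q_value <= threshold
  if (!any(sel)) return(NA_real_)
  correct <- if (is.logical(truth)) truth else group_truth(fit, truth)
  sum(!correct[sel]) / sum(sel)
}

#' Number of groups acceptable at a true-FDR threshold
#'
#' Walks the reported target groups in score order and returns the largest
#' list length whose empirical false discovery proportion (from truth
#' labels) is at or below `threshold`.
#'
#' @inheritParams empirical_fdp
#' @return An integer count (0 when even the top of the list exceeds the
#'   threshold).
#' @export
n_groups_at_true_fdr <- function(fit, truth, threshold = 0.01) {
  g <- fit$groups
  sel <- !g$is_decoy & !g$is_contaminant
  if (!any(sel)) return(0L)
  correct <- if (is.logical(truth)) truth[sel] else group_truth(fit, truth)[sel]
  fdp <- cumsum(!correct) / seq_along(correct)
  ok <- which(fdp <= threshold)
  if (length(ok) == 0L) 0L else max(ok)
}

#' Entrapment-based observed FDR
#'
#' Among accepted target-side groups, a group whose leading proteins are all
#' entrapment-class is observed-false. The count is scaled by the correction
#' factor `1 + n_targets / n_entrapment`, accounting for false positives
#' hitting the original target database, and divided by the number of
#' accepted groups. Groups with a mix of original and entrapment leading
#' proteins count as not observed-false (conservative).
#'
#' @param fit A [picked_group_fdr()] fit over an entrapment-extended database.
#' @param db The entrapment-extended `protein_db` the analysis used.
#' @param threshold Reported q-value threshold.
#' @param correction Apply the multiplicative correction (set `FALSE` for the
#'   raw entrapment ratio).
#' @return The observed FDR estimate, or `NA` when no group is accepted.
#' @export
entrapment_fdr <- function(fit, db, threshold = 0.01, correction = TRUE) {
  n_ent <- sum(db$entry_class == "entrapment")
  if (n_ent == 0L) stop("database contains no entrapment entries")
  n_tgt <- sum(db$entry_class == "target")
  g <- fit$groups
  sel <- !g$is_decoy & !g$is_contaminant & g$q_value <= threshold
  if (!any(sel)) return(NA_real_)
  ent <- vapply(g$leading[sel], function(a) all(grepl("^ENTRAP[0-9]+__", a)),
                logical(1L))
  factor <- if (correction) 1 + n_tgt / n_ent else 1
  sum(ent) * factor / sum(sel)
}

#' Reported FDR attained by the accepted list at a q-value threshold
#'
#' The largest q-value among accepted target groups: the FDR the method
#' actually reports for the list cut at `threshold`. When the list is
#' exhausted before the threshold is reached, this is below the nominal
#' threshold, and it is the quantity an observed FDR should be compared to.
#'
#' @param fit A [picked_group_fdr()] fit.
#' @param threshold Nominal q-value threshold.
#' @return The attained reported FDR, or `NA` when nothing is accepted.
#' @export
reported_fdr_attained <- function(fit, threshold = 0.01) {
  g <- fit$groups
  q <- g$q_value[!g$is_decoy & !g$is_contaminant & g$q_value <= threshold]
  if (length(q) == 0L) return(NA_real_)
  max(q)
}

#' Calibration curve: reported versus observed FDR
#'
#' Evaluates the observed FDR (from simulation truth or entrapment classes)
#' over a grid of q-value cutoffs. Each curve point pairs the reported FDR
#' actually attained by the accepted list (see [reported_fdr_attained()])
#' with the observed FDR of that same list. The observed/reported ratio at a
#' named cutoff is recorded; ratios inside the band \[0.67, 1.5\] are
#' conventionally deemed well-calibrated.
#'
#' @param fit A [picked_group_fdr()] fit.
#' @param truth Peptide truth from [collapse_truth()], or `NULL` to use
#'   entrapment classes.
#' @param db Entrapment-extended database (only when `truth` is `NULL`).
#' @param thresholds Grid of nominal q-value cutoffs.
#' @param at Cutoff at which the summary ratio is taken.
#' @return A `data.frame` with columns `threshold`, `reported` (attained) and
#'   `observed`, with the summary ratio in attribute `"ratio_at"`.
#' @export
calibration_curve <- function(fit, truth = NULL, db = NULL,
                              thresholds = 10^seq(-3, 0, length.out = 25),
                              at = 0.01) {
  obs_fun <- if (!is.null(truth)) {
    flags <- if (is.logical(truth)) truth else group_truth(fit, truth)
    function(thr) empirical_fdp(fit, flags, thr)
  } else {
    if (is.null(db)) stop("provide either truth labels or an entrapment database")
    function(thr) entrapment_fdr(fit, db, thr)
  }
  observed <- vapply(thresholds, obs_fun, numeric(1L))
  reported <- vapply(thresholds, function(t) reported_fdr_attained(fit, t),
                     numeric(1L))
  curve <- data.frame(threshold = thresholds, reported = reported,
                      observed = observed)
  attr(curve, "ratio_at") <- obs_fun(at) / reported_fdr_attained(fit, at)
  curve
}
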