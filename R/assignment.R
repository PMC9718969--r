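# Map each peptide of the evidence to the group ids of its accessions.
peptide_group_map <- function(groups, evidence) {
  long <- evidence_long(evidence)
  long <- long[groups$accession_map, on = "accession", nomatch = NULL]
  unique(long[, c("peptide", "group_id")])
}

new_assignment <- function(tab, evidence) {
  ev <- evidence[, c("peptide", "best_pep"), with = FALSE]
  out <- tab[ev, on = "peptide", nomatch = NULL]
  data.table::setorderv(out, c("group_id", "peptide"))
  out[]
}

#' Shared-peptide handling between protein groups
#'
#' After grouping, each peptide whose accessions all fall within one protein
#' group is assigned to that group. For peptides spanning two or more groups:
#'
#' * `discard_shared()` drops them from every group.
#' * `assign_razor()` (Occam's razor) force-assigns each to the candidate
#'   group with the highest number of peptides unique to it (counted on the
#'   pre-assignment evidence); ties are broken by a seeded uniform draw among
#'   the tied groups. Decoy groups compete exactly like target groups.
#'
#' @param groups A `grouping_result`.
#' @param evidence Collapsed peptide evidence.
#' @param seed Integer seed for razor tie-breaking; required.
#' @return A `data.table` of assignments: `peptide`, `group_id`, `is_razor`,
#'   `best_pep`. Groups that end up with no peptides simply do not appear.
#' @name peptide_assignment
#' @export
discard_shared <- function(groups, evidence) {
  pg <- peptide_group_map(groups, evidence)
  pg[, n_groups := .N, by = "peptide"]
  out <- pg[n_groups == 1L][, n_groups := NULL]
  out[, is_razor := FALSE]
  new_assignment(out, evidence)
}

#' @rdname peptide_assignment
#' @export
assign_razor <- function(groups, evidence, seed = NULL) {
  if (is.null(seed)) stop("a seed is required for reproducible razor tie-breaking")
  pg <- peptide_group_map(groups, evidence)
  pg[, n_groups := .N, by = "peptide"]
  unique_counts <- pg[n_groups == 1L, .N, by = "group_id"]
  n_unique <- integer(length(groups$members))
  n_unique[unique_counts$group_id] <- unique_counts$N

  within <- pg[n_groups == 1L][, n_groups := NULL]
  within[, is_razor := FALSE]

  shared <- pg[n_groups > 1L]
  if (nrow(shared) > 0L) {
    data.table::setorderv(shared, c("peptide", "group_id"))
    set.seed(seed)
    razor <- shared[, {
      u <- n_unique[group_id]
      best <- group_id[u == max(u)]
      list(group_id = if (length(best) == 1L) best else best[sample.int(length(best), 1L)])
    }, by = "peptide"]
    razor[, is_razor := TRUE]
    within <- rbind(within, razor, use.names = TRUE)
  }
  new_assignment(within, evidence)
}
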