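# Long-format (accession, peptide) pairs from collapsed peptide evidence.
evidence_long <- function(evidence) {
  acc <- strsplit(evidence$proteins, ";", fixed = TRUE)
  data.table::data.table(accession = unlist(acc, use.names = FALSE),
                         peptide = rep(evidence$peptide, lengths(acc)))
}

new_grouping_result <- function(leading, members) {
  stopifnot(length(leading) == length(members))
  o <- order(vapply(leading, `[`, character(1L), 1L))
  leading <- leading[o]
  members <- members[o]
  map <- data.table::data.table(
    accession = unlist(members, use.names = FALSE),
    group_id = rep(seq_along(members), lengths(members)))
  if (anyDuplicated(map$accession)) stop("internal error: groups do not partition proteins")
  structure(list(leading = leading, members = members, accession_map = map),
            class = "grouping_result")
}

#' @export
print.grouping_result <- function(x, ...) {
  sizes <- lengths(x$members)
  cat("Protein grouping:", length(x$members), "groups over",
      sum(sizes), "proteins (largest group:", if (length(sizes)) max(sizes) else 0, ")\n")
  invisible(x)
}

#' @rdname protein_grouping
#' @export
no_grouping <- function(evidence) {
  long <- evidence_long(evidence)
  acc <- sort(unique(long$accession))
  new_grouping_result(as.list(acc), as.list(acc))
}

#' Protein grouping strategies
#'
#' Forms protein groups from the observed peptides of collapsed evidence.
#'
#' * `no_grouping()`: every observed protein is its own group.
#' * `subset_grouping()`: a protein whose observed peptide set is a subset of
#'   another protein's peptides joins that protein's group. Proteins with
#'   identical observed peptide sets are merged and become co-leading
#'   (alphabetical order). A strict-subset protein that fits under several
#'   maximal proteins is assigned to the one with the most observed peptides
#'   (ties broken alphabetically), so groups always partition the observed
#'   proteins. The leading proteins of a group are exactly the members whose
#'   peptides cover all peptides observed for the group.
#' * `rescued_subset_grouping()`: two-pass subset grouping that prevents
#'   low-confidence evidence from splitting groups, see below.
#'
#' Rescued subset grouping first computes PG1 = `subset_grouping(evidence)`,
#' runs the default downstream pipeline (discard shared peptides, best-PEP
#' scoring, picked group competition) on PG1, and derives the evidence-level
#' score cutoff equivalent to a group-level FDR of `fdr_threshold`. Evidence
#' with \eqn{-\log_{10}(\mathrm{PEP})} at or above that cutoff is regrouped
#' into PG2, and PG2 is supplemented with every PG1 group none of whose
#' proteins occurs in any PG2 group. If no PG1 group reaches the FDR
#' threshold, PG1 is returned with a warning.
#'
#' @param evidence Collapsed peptide evidence from [collapse_to_peptides()].
#' @param fdr_threshold Group-level FDR defining the internal rescue cutoff.
#' @param decoy_prefix Decoy accession prefix used by the internal
#'   picked-group competition.
#' @param pep_floor Lower clamp for PEPs in the internal best-PEP scoring.
#' @return A `grouping_result`: lists `leading` and `members` (one character
#'   vector per group, leading proteins first) and an `accession_map` table.
#' @name protein_grouping
#' @export
subset_grouping <- function(evidence) {
  long <- evidence_long(evidence)
  data.table::setorderv(long, c("accession", "peptide"))
  sets <- long[, list(key = paste(peptide, collapse = "\r")), by = "accession"]
  # distinct observed peptide sets; proteins with identical sets share a set id
  setkeys <- unique(sets$key)
  set_id <- match(sets$key, setkeys)
  set_members <- split(sets$accession, set_id)           # alphabetical within set
  set_peps <- strsplit(setkeys, "\r", fixed = TRUE)
  set_size <- lengths(set_peps)

  # peptide -> set ids containing it
  pep_sets <- data.table::data.table(
    peptide = unlist(set_peps, use.names = FALSE),
    sid = rep(seq_along(set_peps), set_size))
  by_pep <- split(pep_sets$sid, pep_sets$peptide)

  n_sets <- length(set_peps)
  supersets <- vector("list", n_sets)
  for (s in seq_len(n_sets)) {
    cand <- by_pep[set_peps[[s]]]
    # intersect starting from the rarest peptide
    cand <- cand[order(lengths(cand))]
    sup <- Reduce(intersect, cand)
    supersets[[s]] <- setdiff(sup, s)
  }
  maximal <- which(lengths(supersets) == 0L)
  parent <- integer(n_sets)
  parent[maximal] <- maximal
  lead_acc <- vapply(set_members, `[`, character(1L), 1L)
  for (s in setdiff(seq_len(n_sets), maximal)) {
    cand <- intersect(supersets[[s]], maximal)
    cand <- cand[order(-set_size[cand], lead_acc[cand])]
    parent[s] <- cand[1L]
  }
  leading <- vector("list", length(maximal))
  members <- vector("list", length(maximal))
  for (i in seq_along(maximal)) {
    m <- maximal[i]
    subs <- setdiff(which(parent == m), m)
    leading[[i]] <- set_members[[m]]
    members[[i]] <- c(set_members[[m]], sort(unlist(set_members[subs], use.names = FALSE)))
  }
  new_grouping_result(leading, members)
}

#' @rdname protein_grouping
#' @export
rescued_subset_grouping <- function(evidence, fdr_threshold = 0.01,
                                    decoy_prefix = "REV__", pep_floor = 1e-20) {
  pg1 <- subset_grouping(evidence)
  # internal pass with the method's own defaults: discard shared, best PEP,
  # picked group competition
  assigned <- discard_shared(pg1, evidence)
  scored <- score_groups(pg1, assigned, scoring = "best_pep", pep_floor = pep_floor)
  scored <- picked_group_tds(scored, decoy_prefix = decoy_prefix)
  scored <- estimate_group_fdr(scored)
  cutoff <- psm_cutoff_for_group_fdr(scored, fdr_threshold)
  if (is.na(cutoff)) {
    warning("no protein group reaches the rescue FDR threshold; ",
            "falling back to plain subset grouping")
    return(pg1)
  }
  high <- evidence[-log10(pmax(evidence$best_pep, pep_floor)) >= cutoff]
  if (nrow(high) == 0L) return(pg1)
  pg2 <- subset_grouping(high)
  seen <- unique(pg2$accession_map$accession)
  rescue <- which(vapply(pg1$members, function(m) !any(m %in% seen), logical(1L)))
  new_grouping_result(c(pg2$leading, pg1$leading[rescue]),
                      c(pg2$members, pg1$members[rescue]))
}
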