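#' Method presets for protein group-level FDR estimation
#'
#' Expands a named method preset into its option combination. Available
#' presets (grouping / shared peptides / scoring / target-decoy strategy):
#'
#' * `maxquant`: subset grouping, razor, PEP product (with divisor grid
#'   search), classic.
#' * `savitski`: no grouping, discard, best PEP, picked.
#' * `picked_protein_group_fdr`: rescued subset grouping, discard, best PEP,
#'   picked group.
#' * `savitski_classic`: no grouping, discard, best PEP, classic.
#' * `discard_picked_group`: subset grouping, discard, best PEP, picked group.
#' * `razor_picked_group`: subset grouping, razor, best PEP, picked group.
#' * `classic_protein_group_fdr`: rescued subset grouping, discard, best PEP,
#'   classic.
#'
#' @param preset Preset name.
#' @return A named list with elements `grouping`, `shared_peptides`,
#'   `scoring`, `tds`.
#' @export
method_preset <- function(preset) {
  presets <- list(
    maxquant = list(grouping = "subset", shared_peptides = "razor",
                    scoring = "multiply_pep", tds = "classic"),
    savitski = list(grouping = "none", shared_peptides = "discard",
                    scoring = "best_pep", tds = "picked"),
    picked_protein_group_fdr = list(grouping = "rescued_subset",
                                    shared_peptides = "discard",
                                    scoring = "best_pep", tds = "picked_group"),
    savitski_classic = list(grouping = "none", shared_peptides = "discard",
                            scoring = "best_pep", tds = "classic"),
    discard_picked_group = list(grouping = "subset", shared_peptides = "discard",
                                scoring = "best_pep", tds = "picked_group"),
    razor_picked_group = list(grouping = "subset", shared_peptides = "razor",
                              scoring = "best_pep", tds = "picked_group"),
    classic_protein_group_fdr = list(grouping = "rescued_subset",
                                     shared_peptides = "discard",
                                     scoring = "best_pep", tds = "classic"))
  if (!preset %in% names(presets)) {
    stop("unknown preset '", preset, "'; valid presets: ",
         paste(names(presets), collapse = ", "))
  }
  presets[[preset]]
}

#' Estimate protein group-level FDRs from peptide evidence
#'
#' The central estimator. Takes one or more PSM/peptide evidence tables
#' (merged before collapsing, giving a single consistent protein-group list
#' across searches) and runs: peptide remapping against the database, the
#' per-raw-file peptide-level FDR filter, collapse to best evidence per
#' peptide, protein grouping, shared-peptide handling, protein-group scoring,
#' target-decoy competition, and group-level FDR/q-value estimation.
#'
#' @param psms A PSM `data.table` ([read_psm_table()], [simulate_dataset()]),
#'   or a list of such tables to merge.
#' @param db A `protein_db`, or a FASTA path readable by [read_fasta()].
#' @param preset A [method_preset()] name, or `NULL` to set the four options
#'   explicitly.
#' @param grouping,shared_peptides,scoring,tds Method options (overridden by
#'   `preset` when given).
#' @param peptide_fdr Per-raw-file peptide-level FDR threshold applied before
#'   grouping.
#' @param digest A [digest_params()] object used to build the peptide index.
#' @param index Optional prebuilt `peptide_index` (skips digestion).
#' @param remap Remap peptide accessions against the index; set `FALSE` when
#'   the input's `proteins` column already comes from the analysis database.
#' @param divisor PEP divisor for `multiply_pep` scoring; `NULL` runs the
#'   grid search of [optimize_pep_divisor()].
#' @param pep_floor Lower clamp for PEPs.
#' @param seed Integer seed for razor tie-breaking (required with razor).
#' @param decoy_prefix,contaminant_prefix Accession prefixes.
#' @return An object of class `picked_group_fdr` with components `groups`
#'   (scored, competed, FDR-annotated group table), `peptides` (assigned
#'   peptide sequences per group id), `grouping`, `evidence`, `config` and
#'   `counts`. Methods: `print`, `summary`, `plot`.
#' @examples
#' db <- add_decoys(make_synthetic_database(60, seed = 1))
#' idx <- build_peptide_index(db, digest_params("trypsin/p"))
#' sim <- simulate_dataset(db, idx, simulation_config(
#'   n_exp = 3, n_prot_mean = 30, n_prot_stdev = 5, seed = 2))
#' fit <- picked_group_fdr(sim, db, preset = "picked_protein_group_fdr",
#'                         index = idx, remap = FALSE)
#' fit
#' @export
picked_group_fdr <- function(psms, db, preset = NULL,
                             grouping = c("rescued_subset", "subset", "none"),
                             shared_peptides = c("discard", "razor"),
                             scoring = c("best_pep", "multiply_pep"),
                             tds = c("picked_group", "picked", "classic"),
                             peptide_fdr = 0.01,
                             digest = digest_params("trypsin", missed_cleavages = 2L),
                             index = NULL, remap = TRUE,
                             divisor = NULL, pep_floor = 1e-20, seed = NULL,
                             decoy_prefix = "REV__", contaminant_prefix = "CON__") {
  if (!is.null(preset)) {
    opts <- method_preset(preset)
    grouping <- opts$grouping
    shared_peptides <- opts$shared_peptides
    scoring <- opts$scoring
    tds <- opts$tds
  } else {
    grouping <- match.arg(grouping)
    shared_peptides <- match.arg(shared_peptides)
    scoring <- match.arg(scoring)
    tds <- match.arg(tds)
  }
  if (is.character(db)) db <- read_fasta(db, decoy_prefix, contaminant_prefix)
  if (data.table::is.data.table(psms) || is.data.frame(psms)) psms <- list(psms)
  psms <- data.table::rbindlist(lapply(psms, data.table::as.data.table),
                                use.names = TRUE, fill = TRUE)
  counts <- list(psms_in = nrow(psms))

  if (remap) {
    if (is.null(index)) index <- build_peptide_index(db, digest)
    psms <- remap_peptides(psms, index)
  }
  counts$psms_mapped <- nrow(psms)
  psms <- filter_peptide_fdr_per_file(psms, peptide_fdr)
  counts$psms_after_peptide_fdr <- nrow(psms)
  ev <- collapse_to_peptides(psms)
  counts$peptides <- nrow(ev)

  pg <- switch(grouping,
               none = no_grouping(ev),
               subset = subset_grouping(ev),
               rescued_subset = rescued_subset_grouping(
                 ev, fdr_threshold = 0.01, decoy_prefix = decoy_prefix,
                 pep_floor = pep_floor))
  counts$groups <- length(pg$members)

  assigned <- switch(shared_peptides,
                     discard = discard_shared(pg, ev),
                     razor = assign_razor(pg, ev, seed = seed))
  counts$peptides_assigned <- nrow(assigned)
  counts$peptides_discarded <- nrow(ev) - nrow(assigned)

  if (scoring == "multiply_pep" && is.null(divisor)) {
    divisor <- optimize_pep_divisor(pg, assigned, tds = tds,
                                    pep_floor = pep_floor,
                                    decoy_prefix = decoy_prefix,
                                    contaminant_prefix = contaminant_prefix)
  }
  scored <- score_groups(pg, assigned, scoring = scoring,
                         divisor = if (is.null(divisor)) 1 else divisor,
                         pep_floor = pep_floor, decoy_prefix = decoy_prefix,
                         contaminant_prefix = contaminant_prefix)
  counts$groups_scored <- nrow(scored)
  scored <- apply_tds(scored, tds, decoy_prefix)
  counts$groups_after_tds <- nrow(scored)
  scored <- estimate_group_fdr(scored)

  peptides <- vector("list", length(pg$members))
  split_peps <- split(assigned$peptide, assigned$group_id)
  peptides[as.integer(names(split_peps))] <- split_peps

  structure(list(groups = scored, peptides = peptides, grouping = pg,
                 evidence = ev, counts = counts,
                 config = list(grouping = grouping,
                               shared_peptides = shared_peptides,
                               scoring = scoring, tds = tds,
                               peptide_fdr = peptide_fdr, divisor = divisor,
                               pep_floor = pep_floor, seed = seed,
                               preset = preset,
                               decoy_prefix = decoy_prefix,
                               contaminant_prefix = contaminant_prefix)),
            class = "picked_group_fdr")
}

#' @export
print.picked_group_fdr <- function(x, ...) {
  cfg <- x$config
  cat("Picked protein group FDR fit",
      if (!is.null(cfg$preset)) paste0("(preset: ", cfg$preset, ")"), "\n")
  cat("  options: grouping =", cfg$grouping, "| shared peptides =",
      cfg$shared_peptides, "| scoring =", cfg$scoring, "| TDS =", cfg$tds, "\n")
  g <- x$groups
  tgt <- !g$is_decoy & !g$is_contaminant
  cat("  reported groups:", nrow(g), sprintf("(%d target, %d decoy)\n",
                                             sum(tgt), sum(g$is_decoy)))
  cat("  target groups at 1% FDR:", sum(tgt & g$q_value <= 0.01), "\n")
  invisible(x)
}

#' @method summary picked_group_fdr
#' @export
summary.picked_group_fdr <- function(object, thresholds = c(0.01, 0.05, 0.1), ...) {
  g <- object$groups
  tgt <- !g$is_decoy & !g$is_contaminant
  accepted <- vapply(thresholds, function(t) sum(tgt & g$q_value <= t), integer(1L))
  out <- list(config = object$config, counts = object$counts,
              accepted = data.frame(threshold = thresholds, target_groups = accepted))
  class(out) <- "summary.picked_group_fdr"
  out
}

#' @export
print.summary.picked_group_fdr <- function(x, ...) {
  cat("Method:", paste(unlist(x$config[c("grouping", "shared_peptides",
                                         "scoring", "tds")]), collapse = " / "), "\n")
  cat("Stage counts:\n")
  for (nm in names(x$counts)) cat(sprintf("  %-24s %d\n", nm, x$counts[[nm]]))
  cat("Accepted target groups:\n")
  print(x$accepted, row.names = FALSE)
  invisible(x)
}

#' Plot a protein-group FDR fit
#'
#' Draws the number of accepted target groups as a function of the q-value
#' threshold, with the decoy-group score distribution available as a rug.
#'
#' @param x A `picked_group_fdr` fit.
#' @param threshold Reference threshold drawn as a vertical line.
#' @param ... Passed to [graphics::plot()].
#' @method plot picked_group_fdr
#' @export
plot.picked_group_fdr <- function(x, threshold = 0.01, ...) {
  g <- x$groups
  tgt <- !g$is_decoy & !g$is_contaminant
  q <- sort(g$q_value[tgt])
  graphics::plot(q, seq_along(q), type = "s", log = "x",
                 xlab = "q-value threshold", ylab = "accepted target groups", ...)
  graphics::abline(v = threshold, lty = 2)
  invisible(x)
}

#' Write a protein-groups report
#'
#' Tab-separated report with one row per reported group: member and leading
#' proteins (semicolon-joined), unique/total peptide counts, score, FDR,
#' q-value, decoy and contaminant marks, and summed intensity per experiment
#' where the evidence carried intensities. Rows are ordered by descending
#' score with accession tie-break.
#'
#' @param fit A [picked_group_fdr()] fit.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_protein_groups <- function(fit, path) {
  g <- fit$groups
  out <- data.table::data.table(
    `Protein IDs` = vapply(g$members, paste, character(1L), collapse = ";"),
    `Leading proteins` = vapply(g$leading, paste, character(1L), collapse = ";"),
    `Unique peptides` = g$n_unique,
    `Total peptides` = g$n_total,
    Score = g$score,
    FDR = g$fdr,
    `Q-value` = g$q_value,
    Reverse = ifelse(g$is_decoy, "+", ""),
    `Potential contaminant` = ifelse(g$is_contaminant, "+", ""))
  intens <- attr(fit$evidence, "intensity")
  if (!is.null(intens) && nrow(intens) > 0L) {
    pep2group <- data.table::data.table(
      peptide = unlist(fit$peptides, use.names = FALSE),
      row = rep(seq_along(fit$peptides), lengths(fit$peptides)))
    # fit$peptides is indexed by group id; map to report rows
    pep2group[, row := match(row, g$group_id)]
    pep2group <- pep2group[!is.na(row)]
    gi <- intens[pep2group, on = "peptide", nomatch = NULL]
    sums <- gi[, list(intensity = sum(intensity)), by = c("row", "experiment")]
    for (e in sort(unique(sums$experiment))) {
      col <- numeric(nrow(out))
      se <- sums[experiment == e]
      col[se$row] <- se$intensity
      out[, (paste0("Intensity ", e)) := col]
    }
  }
  data.table::fwrite(out, path, sep = "\t", quote = FALSE)
  invisible(path)
}
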