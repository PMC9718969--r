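#' @import data.table
NULL

.maxquant_cols <- c(peptide = "Sequence", modified_peptide = "Modified sequence",
                    proteins = "Proteins", raw_file = "Raw file",
                    experiment = "Experiment", pep = "PEP", score = "Score",
                    intensity = "Intensity", reverse = "Reverse",
                    contaminant = "Potential contaminant")
.generic_cols <- c(peptide = "peptide", modified_peptide = "modified_peptide",
                   proteins = "proteins", raw_file = "raw_file",
                   experiment = "experiment", pep = "pep", score = "score",
                   intensity = "intensity", reverse = "reverse",
                   contaminant = "contaminant")
.required_fields <- c("peptide", "proteins", "raw_file", "pep")

#' Read a PSM/peptide evidence table
#'
#' Reads tab-separated peptide evidence in either the MaxQuant `evidence.txt`
#' dialect or a documented generic dialect (lowercase column names). Rows with
#' a missing/unparsable posterior error probability (PEP) or an empty peptide
#' sequence are dropped with a message stating the count. The decoy flag is
#' parsed from the dialect's reverse column (`"+"`) or, if absent, from the
#' decoy accession prefix.
#'
#' @param path Path to a tab-separated file with a header row.
#' @param dialect `"maxquant_evidence"` or `"generic_tsv"`.
#' @param decoy_prefix Accession prefix used when no reverse column exists.
#' @return A `data.table` with columns `peptide`, `modified_peptide`,
#'   `proteins` (semicolon-separated accessions), `raw_file`, `experiment`,
#'   `pep`, `score`, `intensity`, `is_decoy`, `is_contaminant`.
#' @export
read_psm_table <- function(path, dialect = c("maxquant_evidence", "generic_tsv"),
                           decoy_prefix = "REV__") {
  dialect <- match.arg(dialect)
  cols <- if (dialect == "maxquant_evidence") .maxquant_cols else .generic_cols
  raw <- data.table::fread(path, sep = "\t", header = TRUE, colClasses = "character",
                           showProgress = FALSE)
  missing_req <- setdiff(cols[.required_fields], names(raw))
  if (length(missing_req)) {
    stop("missing required column(s): ", paste(missing_req, collapse = ", "))
  }
  get_col <- function(field, default = NA_character_) {
    if (cols[[field]] %in% names(raw)) raw[[cols[[field]]]] else rep(default, nrow(raw))
  }
  tab <- data.table::data.table(
    peptide = toupper(get_col("peptide")),
    modified_peptide = get_col("modified_peptide"),
    proteins = get_col("proteins"),
    raw_file = get_col("raw_file"),
    experiment = get_col("experiment"),
    pep = suppressWarnings(as.numeric(get_col("pep"))),
    score = suppressWarnings(as.numeric(get_col("score"))),
    intensity = suppressWarnings(as.numeric(get_col("intensity"))),
    reverse = get_col("reverse", ""))
  tab[is.na(experiment) | experiment == "", experiment := raw_file]
  contam <- get_col("contaminant", "")
  tab[, is_contaminant := !is.na(contam) & contam == "+"]
  if (cols[["reverse"]] %in% names(raw)) {
    tab[, is_decoy := !is.na(reverse) & reverse == "+"]
  } else {
    tab[, is_decoy := all_decoy_accessions(proteins, decoy_prefix)]
  }
  tab[, reverse := NULL]
  bad <- is.na(tab$pep) | is.na(tab$peptide) | tab$peptide == ""
  if (any(bad)) {
    message("read_psm_table: dropped ", sum(bad),
            " row(s) with missing PEP or empty peptide")
    tab <- tab[!bad]
  }
  tab[]
}

all_decoy_accessions <- function(proteins, decoy_prefix) {
  vapply(strsplit(proteins, ";", fixed = TRUE), function(a) {
    a <- a[nzchar(a)]
    length(a) > 0L && all(startsWith(a, decoy_prefix))
  }, logical(1L))
}

#' Write a PSM table
#'
#' Emits the same tab-separated dialects accepted by [read_psm_table()].
#'
#' @param table A PSM `data.table` as returned by [read_psm_table()].
#' @param path Output path.
#' @param dialect Output dialect.
#' @return `path`, invisibly.
#' @export
write_psm_table <- function(table, path,
                            dialect = c("maxquant_evidence", "generic_tsv")) {
  dialect <- match.arg(dialect)
  cols <- if (dialect == "maxquant_evidence") .maxquant_cols else .generic_cols
  out <- data.table::data.table(
    peptide = table$peptide,
    modified_peptide = if ("modified_peptide" %in% names(table)) table$modified_peptide else table$peptide,
    proteins = table$proteins,
    raw_file = table$raw_file,
    experiment = if ("experiment" %in% names(table)) table$experiment else table$raw_file,
    pep = table$pep,
    score = if ("score" %in% names(table)) table$score else -log10(table$pep),
    intensity = if ("intensity" %in% names(table)) table$intensity else NA_real_,
    reverse = ifelse(table$is_decoy, "+", ""),
    contaminant = if ("is_contaminant" %in% names(table)) ifelse(table$is_contaminant, "+", "") else "")
  data.table::setnames(out, names(out), unname(cols[names(out)]))
  data.table::fwrite(out, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Remap peptides to a database via a peptide index
#'
#' Replaces each record's protein accessions by the accession set of its
#' peptide in `index`. Records whose peptide is absent from the index are
#' discarded (not rescued), mirroring the construction of PSM lists filtered
#' to a reduced database. Decoy and contaminant flags are recomputed from the
#' mapped accessions: a record is a decoy only if all its accessions are
#' decoy-class.
#'
#' @param table A PSM `data.table`.
#' @param index A `peptide_index` built from the analysis database.
#' @return The remapped PSM table (possibly fewer rows).
#' @export
remap_peptides <- function(table, index) {
  if (nrow(table) == 0L) return(table)
  peps <- unique(table$peptide)
  hits <- lookup_peptides(index, peps)
  mapped <- data.table::data.table(
    peptide = names(hits),
    proteins = vapply(hits, function(a) paste(sort(a), collapse = ";"), character(1L)))
  out <- table[mapped, on = "peptide", nomatch = NULL]
  out[, proteins := i.proteins][, i.proteins := NULL]
  cls <- index$accession_class
  acc_list <- strsplit(out$proteins, ";", fixed = TRUE)
  out[, is_decoy := vapply(acc_list, function(a) all(cls[a] == "decoy"), logical(1L))]
  out[, is_contaminant := vapply(acc_list, function(a) all(cls[a] == "contaminant"),
                                 logical(1L))]
  out[]
}

#' Filter peptides at a target-decoy FDR threshold, per raw file
#'
#' Within each raw file, PSMs are collapsed to the best (lowest-PEP) PSM per
#' peptide and ranked by ascending PEP (stable ties). The q-value at rank i is
#' the decoy/target count ratio among ranks 1..i, monotonized by a cumulative
#' minimum from worst to best rank. All PSMs of peptides with q-value at or
#' below `threshold` in their file are retained.
#'
#' @param table A PSM `data.table`.
#' @param threshold FDR threshold in (0, 1\]; the conventional cutoff is 0.01.
#' @return The filtered PSM table.
#' @export
filter_peptide_fdr_per_file <- function(table, threshold = 0.01) {
  stopifnot(threshold > 0, threshold <= 1)
  if (nrow(table) == 0L) return(table)
  tab <- data.table::copy(table)
  tab[, .row := .I]
  best <- tab[order(pep, .row), .SD[1L], by = c("raw_file", "peptide")]
  qv <- best[, {
    o <- order(pep, .row)
    d <- cumsum(is_decoy[o])
    t <- cumsum(!is_decoy[o])
    if (d[length(d)] == 0L) {
      warning("no decoys in raw file '", raw_file[1L], "'; q-values set to 0")
      q <- rep(0, length(o))
    } else {
      fdr <- ifelse(t == 0L, Inf, d / t)
      q <- rev(cummin(rev(fdr)))
    }
    list(peptide = peptide[o], q_value = q)
  }, by = "raw_file"]
  keep <- qv[q_value <= threshold, c("raw_file", "peptide")]
  out <- tab[keep, on = c("raw_file", "peptide"), nomatch = NULL]
  out[order(.row)][, .row := NULL][]
}

#' Collapse a PSM table to best evidence per peptide
#'
#' Produces one record per distinct plain peptide sequence with
#' `best_pep = min(pep)` over all its PSMs and intensities summed per
#' experiment (kept in the `intensity` attribute table). Set
#' `by_modified = TRUE` to collapse on the modified sequence instead.
#'
#' @param table A PSM `data.table` (after remapping).
#' @param by_modified Collapse on modified peptide sequence.
#' @return A `data.table` of peptide evidence: `peptide`, `best_pep`,
#'   `proteins`, `is_decoy`, `is_contaminant`; per-experiment intensity sums
#'   attached as attribute `"intensity"`.
#' @export
collapse_to_peptides <- function(table, by_modified = FALSE) {
  tab <- data.table::copy(table)
  if (by_modified && "modified_peptide" %in% names(tab)) {
    tab[, peptide := modified_peptide]
  }
  data.table::setorderv(tab, c("peptide", "pep"))
  ev <- tab[, list(best_pep = pep[1L], proteins = proteins[1L],
                   is_decoy = is_decoy[1L],
                   is_contaminant = if ("is_contaminant" %in% names(tab)) is_contaminant[1L] else FALSE),
            by = "peptide"]
  data.table::setorderv(ev, "peptide")
  if ("intensity" %in% names(tab) && "experiment" %in% names(tab)) {
    intens <- tab[!is.na(intensity),
                  list(intensity = sum(intensity)), by = c("peptide", "experiment")]
    data.table::setattr(ev, "intensity", intens)
  }
  ev[]
}
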