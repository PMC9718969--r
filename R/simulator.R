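#' Simulation configuration for multi-experiment peptide evidence
#'
#' Bundles the parameters of the peptide-evidence simulator. The defaults are
#' the settings used throughout the calibration analyses: experiments of
#' about 10,000 present proteins, true-positive scores (on a
#' \eqn{-\log_{10}(\mathrm{PEP})} scale) from N(2.5, 0.7), false-positive
#' scores from N(0, 0.7), an incorrect-peptide ratio of 0.6 before any FDR
#' threshold, and a peptide-level FDR of 1%.
#'
#' @param n_exp Number of experiments.
#' @param n_prot_mean,n_prot_stdev Mean/stdev of the number of proteins
#'   present per experiment.
#' @param tp_score_mean,tp_score_stdev Normal score distribution of correct
#'   peptides.
#' @param fp_score_mean,fp_score_stdev Normal score distribution of incorrect
#'   peptides.
#' @param incorrect_ratio Proportion of incorrect peptides without any FDR
#'   threshold, in (0, 1).
#' @param peptide_fdr Peptide-level FDR the simulated lists are controlled
#'   at, in (0, 1).
#' @param seed Integer seed; required by [simulate_dataset()].
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(n_exp = 10L, n_prot_mean = 10000, n_prot_stdev = 1000,
                              tp_score_mean = 2.5, tp_score_stdev = 0.7,
                              fp_score_mean = 0, fp_score_stdev = 0.7,
                              incorrect_ratio = 0.6, peptide_fdr = 0.01,
                              seed = NULL) {
  stopifnot(n_exp >= 1L, n_prot_stdev > 0, tp_score_stdev > 0, fp_score_stdev > 0,
            incorrect_ratio > 0, incorrect_ratio < 1,
            peptide_fdr > 0, peptide_fdr < 1)
  structure(list(n_exp = as.integer(n_exp), n_prot_mean = n_prot_mean,
                 n_prot_stdev = n_prot_stdev,
                 tp_score_mean = tp_score_mean, tp_score_stdev = tp_score_stdev,
                 fp_score_mean = fp_score_mean, fp_score_stdev = fp_score_stdev,
                 incorrect_ratio = incorrect_ratio, peptide_fdr = peptide_fdr,
                 seed = seed),
            class = "simulation_config")
}

#' Minimum peptide score implied by an FDR threshold
#'
#' The score cutoff at which a peptide list with incorrect-peptide proportion
#' `incorrect_ratio` is controlled at `peptide_fdr`:
#' \deqn{\Phi^{-1}\!\left(1 - \mathrm{peptide\_fdr}\,
#'   \frac{1 - \mathrm{incorrect\_ratio}}{\mathrm{incorrect\_ratio}};\,
#'   \mu_{fp}, \sigma_{fp}\right)}
#' evaluated under the false-positive score distribution. All simulated
#' scores are truncated below at this value.
#'
#' @param cfg A [simulation_config()].
#' @return The minimum score (numeric scalar).
#' @export
min_score_for_fdr <- function(cfg) {
  p <- cfg$peptide_fdr * (1 - cfg$incorrect_ratio) / cfg$incorrect_ratio
  if (p <= 0 || p >= 1) stop("implied quantile outside (0, 1)")
  stats::qnorm(1 - p, mean = cfg$fp_score_mean, sd = cfg$fp_score_stdev)
}

rtruncnorm_lower <- function(n, lower, mean, sd) {
  p0 <- stats::pnorm(lower, mean, sd)
  stats::qnorm(stats::runif(n, p0, 1), mean, sd)
}

#' Default protein and peptide detection probabilities
#'
#' In production use these heterogeneity profiles would be estimated from a
#' repository of real experiments; here they are synthetic. Per-protein
#' presence probabilities are drawn from the U-shaped Beta(0.3, 0.7) and
#' per-peptide conditional detection probabilities (proteotypicities) from
#' Beta(1.2, 3). The U-shape reproduces the qualitative pattern of repository
#' data: some proteins appear in almost every experiment while a large
#' fraction are present in only one or a few -- the regime in which
#' protein-level error control is actually at stake. A symmetric,
#' zero-avoiding choice would make every protein correctly identified
#' somewhere once a handful of experiments are combined, leaving no false
#' protein groups to estimate an FDR over.
#'
#' @param db A `protein_db`.
#' @param index A `peptide_index` over `db`.
#' @param seed Integer seed.
#' @return A list with named numeric vectors `protein_probs` (per target
#'   accession) and `peptide_probs` (per indexed peptide).
#' @export
default_detection_probs <- function(db, index, seed) {
  set.seed(seed)
  targets <- db$accession[db$entry_class == "target"]
  protein_probs <- stats::setNames(stats::rbeta(length(targets), 0.3, 0.7), targets)
  peps <- unique(index$map$peptide)
  peptide_probs <- stats::setNames(stats::rbeta(length(peps), 1.2, 3), peps)
  list(protein_probs = protein_probs, peptide_probs = peptide_probs)
}

#' Simulate multi-experiment peptide evidence with truth labels
#'
#' Per experiment: the number of present proteins is drawn from
#' N(`n_prot_mean`, `n_prot_stdev`) (rounded, clamped to the target count);
#' that many target proteins are sampled without replacement with
#' probabilities proportional to `protein_probs`; each peptide of a present
#' protein is detected independently with its `peptide_probs` value, and a
#' peptide shared between proteins is correct when any of its source proteins
#' is present. Correct peptides draw scores from the truncated normal
#' trunc(min_score, Inf; tp parameters). The number of incorrect peptides is
#' `round(2 * n_tp * peptide_fdr / (1 - peptide_fdr))`; they are drawn
#' uniformly from all peptides of the target-plus-decoy index (so decoy hits
#' arise naturally) with scores from the truncated false-positive normal.
#'
#' Scores are interpreted on the \eqn{-\log_{10}(\mathrm{PEP})} scale, so the
#' emitted table carries `pep = 10^(-score)` and feeds the standard pipeline
#' unchanged.
#'
#' @param db A `protein_db` including decoy entries.
#' @param index A `peptide_index` over the full database.
#' @param cfg A [simulation_config()] with a seed.
#' @param probs Optional detection probabilities as returned by
#'   [default_detection_probs()]; generated from `cfg$seed` when `NULL`.
#' @return A PSM `data.table` in the generic dialect (one row per simulated
#'   peptide observation) with extra truth columns: `truth_label`
#'   (`"correct"`/`"incorrect"`) and `true_sources` (semicolon-joined present
#'   source proteins of a correct observation).
#' @export
simulate_dataset <- function(db, index, cfg, probs = NULL) {
  if (is.null(cfg$seed)) stop("simulation requires a seed")
  if (nrow(index$map) == 0L) stop("empty peptide index")
  if (cfg$n_exp < 1L) stop("n_exp must be positive")
  if (is.null(probs)) probs <- default_detection_probs(db, index, cfg$seed)

  targets <- db$accession[db$entry_class == "target"]
  target_map <- index$map[accession %in% targets]
  all_peptides <- unique(index$map$peptide)
  decoy_class <- index$accession_class
  min_score <- min_score_for_fdr(cfg)

  prot_probs <- probs$protein_probs[targets]
  pep_probs <- probs$peptide_probs

  set.seed(cfg$seed)
  per_exp <- vector("list", cfg$n_exp)
  for (e in seq_len(cfg$n_exp)) {
    n_prot <- round(stats::rnorm(1L, cfg$n_prot_mean, cfg$n_prot_stdev))
    n_prot <- min(max(n_prot, 1L), length(targets))
    # exponential-race weighted sampling without replacement (equivalent in
    # distribution to successive draws proportional to prot_probs)
    key <- stats::rexp(length(targets)) / prot_probs
    present <- targets[order(key)[seq_len(n_prot)]]
    cand <- target_map[accession %in% present]
    # one detection draw per (protein, peptide) pair; peptide correct if any hits
    hit <- stats::runif(nrow(cand)) < pep_probs[cand$peptide]
    tp <- cand[hit, list(true_sources = paste(sort(unique(accession)), collapse = ";")),
               by = "peptide"]
    n_tp <- nrow(tp)
    n_fp <- round(2 * n_tp * cfg$peptide_fdr / (1 - cfg$peptide_fdr))
    exp_id <- sprintf("exp%04d", e)
    tp_rows <- if (n_tp > 0L) data.table::data.table(
      peptide = tp$peptide,
      score = rtruncnorm_lower(n_tp, min_score, cfg$tp_score_mean, cfg$tp_score_stdev),
      truth_label = "correct",
      true_sources = tp$true_sources) else NULL
    fp_rows <- if (n_fp > 0L) data.table::data.table(
      peptide = sample(all_peptides, n_fp, replace = TRUE),
      score = rtruncnorm_lower(n_fp, min_score, cfg$fp_score_mean, cfg$fp_score_stdev),
      truth_label = "incorrect",
      true_sources = "") else NULL
    rows <- rbind(tp_rows, fp_rows)
    rows[, `:=`(raw_file = exp_id, experiment = exp_id)]
    per_exp[[e]] <- rows
  }
  out <- data.table::rbindlist(per_exp)
  acc <- lookup_peptides(index, unique(out$peptide))
  prot_str <- vapply(acc, function(a) paste(sort(a), collapse = ";"), character(1L))
  dec <- vapply(acc, function(a) all(decoy_class[a] == "decoy"), logical(1L))
  out[, proteins := prot_str[peptide]]
  out[, pep := 10^(-score)]
  out[, is_decoy := dec[peptide]]
  out[, `:=`(modified_peptide = peptide, intensity = NA_real_,
             is_contaminant = FALSE)]
  data.table::setcolorder(out, c("peptide", "modified_peptide", "proteins",
                                 "raw_file", "experiment", "pep", "score",
                                 "intensity", "is_decoy", "is_contaminant",
                                 "truth_label", "true_sources"))
  out[]
}
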