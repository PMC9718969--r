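#' Protein group scores from peptide posterior error probabilities
#'
#' `score_best_pep()` scores a group by \eqn{-\log_{10}} of the smallest
#' best-PEP among its assigned peptides; larger is better. `score_multiply_pep()`
#' implements PEP-product scoring: each peptide's best PEP is first divided by
#' the constant `divisor`, and the score is \eqn{-\log_{10}} of the product,
#' so peptides with PEP above the divisor lower the score. PEPs of zero (or
#' below `pep_floor`) are clamped to `pep_floor` with a warning.
#'
#' @param peps Numeric vector of best PEPs of a group's assigned peptides.
#' @param divisor Positive constant the PEPs are divided by.
#' @param pep_floor Lower clamp for PEPs.
#' @return The group score (numeric scalar).
#' @name group_scoring
#' @export
score_best_pep <- function(peps, pep_floor = 1e-20) {
  stopifnot(length(peps) >= 1L)
  if (any(peps < pep_floor)) {
    warning("PEP below floor clamped to ", pep_floor)
    peps <- pmax(peps, pep_floor)
  }
  -log10(min(peps))
}

#' @rdname group_scoring
#' @export
score_multiply_pep <- function(peps, divisor = 1, pep_floor = 1e-20) {
  stopifnot(length(peps) >= 1L, divisor > 0)
  if (any(peps < pep_floor)) {
    warning("PEP below floor clamped to ", pep_floor)
    peps <- pmax(peps, pep_floor)
  }
  sum(log10(divisor) - log10(peps))
}

#' Score all protein groups of a grouping result
#'
#' Builds the scored group list consumed by the target-decoy competition and
#' FDR stages. A group is decoy-class when all of its member proteins carry
#' the decoy prefix and contaminant-class when all leading proteins carry the
#' contaminant prefix (after stripping a decoy prefix). Groups without
#' assigned peptides receive no score and are not reported.
#'
#' @param groups A `grouping_result`.
#' @param assigned Peptide assignments from [discard_shared()] or
#'   [assign_razor()].
#' @param scoring `"best_pep"` or `"multiply_pep"`.
#' @param divisor PEP divisor for `"multiply_pep"`.
#' @param pep_floor Lower clamp for PEPs.
#' @param decoy_prefix,contaminant_prefix Accession prefixes.
#' @return A `data.table` (one row per scored group, sorted by decreasing
#'   score, ties by first leading accession): `group_id`, `leading` and
#'   `members` (list columns), `n_unique`, `n_total`, `score`, `is_decoy`,
#'   `is_contaminant`.
#' @export
score_groups <- function(groups, assigned, scoring = c("best_pep", "multiply_pep"),
                         divisor = 1, pep_floor = 1e-20,
                         decoy_prefix = "REV__", contaminant_prefix = "CON__") {
  scoring <- match.arg(scoring)
  if (any(assigned$best_pep < pep_floor)) {
    warning("PEP below floor clamped to ", pep_floor)
  }
  stat <- assigned[, list(
    score = if (scoring == "best_pep") -log10(min(pmax(best_pep, pep_floor)))
            else sum(log10(divisor) - log10(pmax(best_pep, pep_floor))),
    n_unique = sum(!is_razor),
    n_total = .N), by = "group_id"]
  leading <- groups$leading[stat$group_id]
  members <- groups$members[stat$group_id]
  lead1 <- vapply(leading, `[`, character(1L), 1L)
  out <- data.table::data.table(
    group_id = stat$group_id,
    leading = leading,
    members = members,
    n_unique = stat$n_unique,
    n_total = stat$n_total,
    score = stat$score,
    is_decoy = vapply(members, function(m) all(startsWith(m, decoy_prefix)), logical(1L)),
    is_contaminant = vapply(leading, function(m) {
      all(startsWith(strip_decoy_prefix(m, decoy_prefix), contaminant_prefix))
    }, logical(1L)))
  data.table::setorderv(out[, .lead1 := lead1], c("score", ".lead1"), order = c(-1L, 1L))
  out[, .lead1 := NULL]
  out[]
}

#' Optimize the PEP divisor of the product score by grid search
#'
#' Evaluates a logarithmic grid of divisor constants; for each, groups are
#' scored with [score_multiply_pep()], passed through the chosen target-decoy
#' strategy and FDR estimation, and the number of accepted target groups at
#' `threshold` is counted. The divisor maximizing that count is returned,
#' with ties resolved toward the largest divisor.
#'
#' @param groups A `grouping_result`.
#' @param assigned Peptide assignments.
#' @param tds `"classic"`, `"picked"` or `"picked_group"`.
#' @param threshold Group-level FDR threshold the count is taken at.
#' @param grid Positive divisor candidates (default `10^seq(-4, 0)` in 13
#'   steps).
#' @param pep_floor,decoy_prefix,contaminant_prefix Passed to [score_groups()].
#' @return The selected divisor (numeric scalar).
#' @export
optimize_pep_divisor <- function(groups, assigned,
                                 tds = c("classic", "picked", "picked_group"),
                                 threshold = 0.01,
                                 grid = 10^seq(-4, 0, length.out = 13),
                                 pep_floor = 1e-20, decoy_prefix = "REV__",
                                 contaminant_prefix = "CON__") {
  tds <- match.arg(tds)
  if (length(grid) == 0L) stop("empty divisor grid")
  counts <- vapply(grid, function(cdiv) {
    scored <- score_groups(groups, assigned, scoring = "multiply_pep",
                           divisor = cdiv, pep_floor = pep_floor,
                           decoy_prefix = decoy_prefix,
                           contaminant_prefix = contaminant_prefix)
    scored <- apply_tds(scored, tds, decoy_prefix)
    scored <- estimate_group_fdr(scored)
    sum(!scored$is_decoy & !scored$is_contaminant & scored$q_value <= threshold)
  }, numeric(1L))
  best <- which(counts == max(counts))
  max(grid[best])
}
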