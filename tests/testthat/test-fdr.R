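# Quadratic oracle for FDR/q-values: for each group, count decoys and targets
# with a score at least as good, then take the minimum FDR at any worse-or-
# equal score.
oracle_fdr_q <- function(score, is_decoy) {
  n <- length(score)
  fdr <- vapply(seq_len(n), function(i) {
    d <- sum(is_decoy[score >= score[i]])
    t <- sum(!is_decoy[score >= score[i]])
    if (t == 0) Inf else d / t
  }, numeric(1))
  q <- vapply(seq_len(n), function(i) min(fdr[score <= score[i]]), numeric(1))
  list(fdr = fdr, q = pmin(q, 1))
}

test_that("picked competition retains the better of each target/decoy pair", {
  sc <- toy_scored(list("P", "REV__P", "REV__Q"), scores = c(5, 2, 1))
  out <- picked_tds(sc)
  expect_equal(unlist(out$members), c("P", "REV__Q"))  # unpaired decoy kept
  # equal scores retain both
  sc2 <- toy_scored(list("P", "REV__P"), scores = c(3, 3))
  expect_equal(nrow(picked_tds(sc2)), 2L)
  # grouped input is rejected
  sc3 <- toy_scored(list(c("A", "B")), scores = 1)
  expect_error(picked_tds(sc3), "singleton")
})

test_that("picked group competition eliminates counterpart-bearing lower groups", {
  sc <- toy_scored(list(c("D", "E", "F"), c("REV__D", "REV__F", "REV__H")),
                   scores = c(5, 2))
  out <- picked_group_tds(sc)
  expect_equal(length(out$members), 1L)
  expect_equal(out$members[[1]], c("D", "E", "F"))
  # no overlaps anywhere: list unchanged
  sc2 <- toy_scored(list(c("A", "B"), c("REV__C", "REV__D")), scores = c(5, 2))
  expect_equal(nrow(picked_group_tds(sc2)), 2L)
  # elimination is based on leading proteins only
  sc3 <- toy_scored(list(c("D", "E"), c("REV__X", "REV__E")),
                    scores = c(5, 2),
                    leading = list("D", "REV__X"))
  expect_equal(nrow(picked_group_tds(sc3)), 2L)
  # unsorted input errors
  sc4 <- data.table::copy(sc)[c(2, 1)]
  expect_error(picked_group_tds(sc4), "sorted")
})

test_that("picked group competition equals picked competition on singletons", {
  for (seed in 1:25) {
    set.seed(seed)
    n <- 40L
    base <- sprintf("P%02d", 1:12)
    accs <- unique(c(sample(base, n, TRUE), paste0("REV__", sample(base, n, TRUE))))
    sc <- toy_scored(as.list(accs), scores = round(runif(length(accs)), 2))
    expect_equal(picked_group_tds(sc), picked_tds(sc))
  }
})

test_that("group FDR counts match direct and oracle computation", {
  # 100 targets, then 2 decoys, then 1 target by score
  sc <- toy_scored(as.list(c(sprintf("T%03d", 1:100), "REV__A", "REV__B", "T101")),
                   scores = c(seq(200, 101), 50, 49, 10))
  out <- estimate_group_fdr(sc)
  expect_equal(out$fdr[nrow(out)], 2 / 101)
  expect_equal(out$fdr[1], 0)
  # no decoys -> all zero
  sc2 <- toy_scored(as.list(sprintf("T%02d", 1:10)), scores = 10:1)
  expect_true(all(estimate_group_fdr(sc2)$fdr == 0))
  # empty list stays empty
  expect_equal(nrow(estimate_group_fdr(sc2[0])), 0L)
})

test_that("q-values equal the quadratic oracle on random fixtures, with ties", {
  for (seed in 1:5) {
    set.seed(seed)
    n <- 500L
    accs <- c(sprintf("T%03d", 1:350), sprintf("REV__T%03d", 1:150))
    # coarse scores force plenty of exact ties across the decoy boundary
    sc <- toy_scored(as.list(accs), scores = sample(seq(0, 5, by = 0.25), n, TRUE))
    out <- estimate_group_fdr(sc)
    orc <- oracle_fdr_q(out$score, out$is_decoy)
    expect_equal(out$fdr, orc$fdr)
    expect_equal(out$q_value, orc$q)
    # monotone non-decreasing down the sorted list
    expect_true(!is.unsorted(out$q_value))
    # competition never changes scores, only membership
    kept <- picked_group_tds(sc)
    expect_true(all(kept$score %in% sc$score))
  }
})

test_that("contaminant groups are excluded from counts but receive q-values", {
  sc <- toy_scored(list("T1", "CON__X", "REV__T1", "T2"),
                   scores = c(5, 4, 3, 2))
  out <- estimate_group_fdr(sc)
  con <- which(out$is_contaminant)
  expect_equal(out$fdr[out$score == 2], 1 / 2)  # decoy counted over T1, T2 only
  expect_false(is.na(out$q_value[con]))
})

test_that("evidence cutoff for a group FDR threshold matches an exhaustive scan", {
  accs <- c(sprintf("T%02d", 1:60), sprintf("REV__T%02d", 1:10))
  set.seed(3)
  sc <- toy_scored(as.list(accs),
                   scores = c(runif(60, 1, 6), runif(10, 0, 2.2)))
  out <- estimate_group_fdr(sc)
  cut <- psm_cutoff_for_group_fdr(out, 0.05)
  # exhaustive scan oracle
  expect_equal(cut, min(out$score[out$q_value <= 0.05]))
  # evidence passes iff -log10(PEP) >= cutoff: counts are monotone in threshold
  cuts <- vapply(c(0.01, 0.05, 0.2), function(t) {
    c0 <- psm_cutoff_for_group_fdr(out, t)
    if (is.na(c0)) Inf else c0
  }, numeric(1))
  expect_true(all(diff(cuts) <= 0))
  # all groups passing -> minimum score; none passing -> NA
  expect_equal(psm_cutoff_for_group_fdr(out, 1), min(out$score))
  sc_dec <- toy_scored(list("REV__Z", "T1"), scores = c(5, 1))
  expect_true(is.na(psm_cutoff_for_group_fdr(estimate_group_fdr(sc_dec), 0.01)))
  # exactly one passing group -> its score
  sc_one <- toy_scored(list("T1", "REV__A", "T2"), scores = c(6, 3, 1))
  out_one <- estimate_group_fdr(sc_one)
  expect_equal(psm_cutoff_for_group_fdr(out_one, 0.01), 6)
})
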