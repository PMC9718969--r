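test_that("no grouping yields one singleton group per observed protein", {
  ev <- toy_evidence(c("AAAAAAK", "CCCCCCR", "DDDDDDK"),
                     c("P1", "P2;P3", "P2"))
  gr <- no_grouping(ev)
  expect_equal(length(gr$members), 3L)
  expect_equal(unlist(gr$members), c("P1", "P2", "P3"))
  # a protein observed only via shared peptides still gets its own group
  expect_true("P3" %in% unlist(gr$members))
  # empty evidence -> empty result
  expect_equal(length(no_grouping(toy_evidence(character(0), character(0)))$members), 0L)
})

test_that("subset grouping merges nested and identical peptide sets", {
  # A = {p1, p2} subset of B = {p1, p2, p3}
  ev <- toy_evidence(c("PPPPPP1K", "PPPPPP2K", "PPPPPP3K"),
                     c("A;B", "A;B", "B"))
  gr <- subset_grouping(ev)
  expect_equal(length(gr$members), 1L)
  expect_equal(gr$leading[[1]], "B")
  expect_equal(gr$members[[1]], c("B", "A"))

  # disjoint sets stay apart
  ev2 <- toy_evidence(c("PPPPPP1K", "PPPPPP2K"), c("A", "B"))
  expect_equal(length(subset_grouping(ev2)$members), 2L)

  # identical sets are merged and co-leading, alphabetical
  ev3 <- toy_evidence(c("PPPPPP1K", "PPPPPP2K"), c("B;A", "A;B"))
  gr3 <- subset_grouping(ev3)
  expect_equal(length(gr3$members), 1L)
  expect_equal(gr3$leading[[1]], c("A", "B"))
})

test_that("subset grouping matches the brute-force oracle on random instances", {
  for (seed in 1:5) {
    set.seed(seed)
    n_prot <- 30L
    peps <- sprintf("RNDPEP%02dK", 1:60)
    # random observed sets with deliberate nesting
    sets <- lapply(seq_len(n_prot), function(i) sample(peps, sample(1:8, 1)))
    # force some exact duplicates and subsets
    sets[[5]] <- sets[[1]]
    sets[[6]] <- sets[[2]][seq_len(max(1, length(sets[[2]]) - 1))]
    accs <- sprintf("PR%02d", seq_len(n_prot))
    long <- data.frame(peptide = unlist(sets),
                       accession = rep(accs, lengths(sets)))
    by_pep <- split(long$accession, long$peptide)
    ev <- toy_evidence(names(by_pep),
                       vapply(by_pep, function(a) paste(sort(unique(a)), collapse = ";"),
                              character(1)))
    gr <- subset_grouping(ev)
    expect_equal(canon(gr), oracle_subset_grouping(ev))
    # partition: each observed protein in exactly one group
    expect_equal(sort(unlist(gr$members)), sort(unique(long$accession)))
    # input order invariance
    gr2 <- subset_grouping(ev[sample(nrow(ev))])
    expect_equal(canon(gr2), canon(gr))
  }
})

# Shared high-confidence peptide between two isoform-like proteins that are
# kept apart by low-confidence unique peptides; a background of confident
# proteins and decoys defines the 1% rescue cutoff.
split_group_fixture <- function() {
  bg_peps <- sprintf("BCKGRND%03dK", 1:200)
  bg_prots <- sprintf("BG%03d", 1:200)
  dec_peps <- sprintf("DECOYPP%03dK", 1:5)
  toy_evidence(
    c("SHAREDHIK", "LOWCONFAK", "LOWCONFBK", "LOWCONFCK", bg_peps, dec_peps),
    c("A;B", "A", "B", "B", bg_prots, paste0("REV__BG", 901:905)),
    best_pep = c(1e-6, 0.3, 0.3, 0.35, rep(1e-4, 200), rep(0.2, 5)))
}

test_that("rescued subset grouping reunites groups split by low-confidence peptides", {
  ev <- split_group_fixture()
  plain <- subset_grouping(ev)
  # the low-confidence unique peptides keep A and B apart under plain grouping
  gA <- which(vapply(plain$members, function(m) "A" %in% m, logical(1)))
  gB <- which(vapply(plain$members, function(m) "B" %in% m, logical(1)))
  expect_true(gA != gB)
  # and the shared high-confidence peptide is then discarded
  asg <- discard_shared(plain, ev)
  expect_false("SHAREDHIK" %in% asg$peptide)

  rescued <- rescued_subset_grouping(ev)
  gAB <- which(vapply(rescued$members, function(m) "A" %in% m, logical(1)))
  expect_equal(sort(rescued$leading[[gAB]]), c("A", "B"))
  asg2 <- discard_shared(rescued, ev)
  expect_true("SHAREDHIK" %in% asg2$peptide)
})

test_that("rescued grouping is a fixed point on uniformly confident evidence", {
  ev <- toy_evidence(c(sprintf("CONFPEP%02dK", 1:20), "DECOYPEPK"),
                     c(sprintf("T%02d", 1:20), "REV__T01"),
                     best_pep = c(rep(1e-5, 20), 0.5))
  expect_equal(canon(rescued_subset_grouping(ev)), canon(subset_grouping(ev)))
})

test_that("PG1 groups absent from PG2 are re-appended", {
  ev <- split_group_fixture()
  # one extra protein observed only through a low-confidence peptide: it
  # vanishes from PG2 entirely and must be rescued from PG1
  extra <- toy_evidence("WEAKONLYK", "LONER", best_pep = 0.4)
  ev2 <- rbind(ev, extra)
  rescued <- rescued_subset_grouping(ev2)
  expect_true(any(vapply(rescued$members, function(m) identical(m, "LONER"),
                         logical(1))))
})

test_that("rescued grouping falls back to plain grouping when nothing passes", {
  ev <- toy_evidence(c("WEAKPEPAK", "WEAKPEPBK", "DECOYPELK"),
                     c("A", "B", "REV__A"),
                     best_pep = c(0.5, 0.6, 0.01))
  expect_warning(gr <- rescued_subset_grouping(ev), "falling back")
  expect_equal(canon(gr), canon(subset_grouping(ev)))
})
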