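# Brute-force oracle: q-value of peptide i = min over all score cutoffs at or
# below its PEP rank of (decoys retained / targets retained). Quadratic walk,
# independent of the cumulative-sum implementation.
oracle_peptide_q <- function(pep, is_decoy) {
  o <- order(pep)
  q <- numeric(length(pep))
  for (i in seq_along(o)) {
    fdrs <- vapply(i:length(o), function(j) {
      kept <- o[1:j]
      d <- sum(is_decoy[kept]); t <- sum(!is_decoy[kept])
      if (t == 0) Inf else d / t
    }, numeric(1))
    q[o[i]] <- min(fdrs)
  }
  q
}

test_that("PSM tables round-trip through both dialects", {
  tab <- toy_psms(peptide = c("AAAAAAK", "CCCCCCR", "DDDDDDK", "EEEEEER", "FFFFFFK"),
                  proteins = c("P1", "P2", "REV__P1", "P1;P2", "P3"),
                  pep = c(0.001, 0.01, 0.2, 0.05, 0.9),
                  intensity = c(100, 200, NA, 50, 10))
  for (dialect in c("maxquant_evidence", "generic_tsv")) {
    f <- withr::local_tempfile(fileext = ".txt")
    write_psm_table(tab, f, dialect = dialect)
    back <- read_psm_table(f, dialect = dialect)
    expect_equal(nrow(back), 5L)
    expect_equal(back$peptide, tab$peptide)
    expect_equal(back$pep, tab$pep)
    expect_equal(back$is_decoy, c(FALSE, FALSE, TRUE, FALSE, FALSE))
    expect_equal(back$intensity, tab$intensity)
  }
})

test_that("reader drops unparsable rows with a message and validates columns", {
  f <- withr::local_tempfile(fileext = ".txt")
  rows <- data.frame(peptide = sprintf("PEPTIDE%dK", 1:10),
                     proteins = "P1", raw_file = "f1",
                     pep = c("0.01", "oops", 0.02, "", rep("0.03", 6)))
  write.table(rows, f, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_message(tab <- read_psm_table(f, dialect = "generic_tsv"),
                 "dropped 2 row")
  expect_equal(nrow(tab), 8L)

  f2 <- withr::local_tempfile(fileext = ".txt")
  write.table(rows[, c("peptide", "proteins", "pep")], f2, sep = "\t",
              quote = FALSE, row.names = FALSE)
  expect_error(read_psm_table(f2, dialect = "generic_tsv"), "raw_file")
})

test_that("remapping replaces accessions from the index and discards unmapped peptides", {
  db <- protein_db(c("P1", "P2", "P3"),
                   c("AAAAAAKCCCCCCR", "AAAAAAKDDDDDDR", "AAAAAAKEEEEEER"))
  idx <- build_peptide_index(db, digest_params("trypsin/p"))
  tab <- toy_psms(peptide = c("AAAAAAK", "CCCCCCR", "ZZZZZZK"),
                  proteins = c("XX", "XX", "XX"), pep = c(0.01, 0.02, 0.03))
  out <- remap_peptides(tab, idx)
  expect_equal(nrow(out), 2L)  # unmapped peptide discarded
  expect_equal(out[out$peptide == "AAAAAAK", ]$proteins, "P1;P2;P3")
  expect_equal(out[out$peptide == "CCCCCCR", ]$proteins, "P1")
  # empty index -> empty table
  idx0 <- idx
  idx0$map <- idx0$map[0]
  expect_equal(nrow(remap_peptides(tab, idx0)), 0L)
})

test_that("per-file peptide FDR filtering matches the brute-force rank walk", {
  # 150 targets with ascending PEPs and one decoy ranked 51st: the worst-rank
  # ratio 1/150 is below 1%, so monotonization lets every peptide through
  pep <- c(seq_len(150) / 1000, 0.0505)
  dec <- c(rep(FALSE, 150), TRUE)
  tab <- toy_psms(peptide = sprintf("PEP%03dAAK", seq_along(pep)),
                  proteins = ifelse(dec, "REV__P1", "P1"), pep = pep,
                  is_decoy = dec)
  out <- filter_peptide_fdr_per_file(tab, 0.01)
  q <- oracle_peptide_q(pep, dec)
  expect_equal(sort(out$peptide), sort(tab$peptide[q <= 0.01]))
  expect_equal(nrow(out), 151L)

  # smaller list, decoy still ranked 51st: now 1/59 > 1% and exactly the 50
  # better-ranked targets pass
  pep2 <- c(seq_len(59) / 1000, 0.0505)
  dec2 <- c(rep(FALSE, 59), TRUE)
  tab2 <- toy_psms(peptide = sprintf("PEP%03dAAK", seq_along(pep2)),
                   proteins = ifelse(dec2, "REV__P1", "P1"), pep = pep2,
                   is_decoy = dec2)
  out2 <- filter_peptide_fdr_per_file(tab2, 0.01)
  q2 <- oracle_peptide_q(pep2, dec2)
  expect_equal(sort(out2$peptide), sort(tab2$peptide[q2 <= 0.01]))
  expect_equal(nrow(out2), 50L)
  expect_true(all(out2$pep <= 0.050))

  # random fixture, several files, against the oracle per file
  set.seed(8)
  rtab <- toy_psms(peptide = sprintf("RND%03dK", 1:120),
                   proteins = ifelse(runif(120) < 0.3, "REV__P1", "P1"),
                   pep = runif(120), raw_file = sample(c("f1", "f2"), 120, TRUE))
  rtab$is_decoy <- startsWith(rtab$proteins, "REV__")
  out3 <- filter_peptide_fdr_per_file(rtab, 0.3)
  keep_oracle <- unlist(lapply(split(rtab, rtab$raw_file), function(ff) {
    ff$peptide[oracle_peptide_q(ff$pep, ff$is_decoy) <= 0.3]
  }))
  expect_setequal(out3$peptide, keep_oracle)
})

test_that("peptide FDR filtering edge cases and monotonicity", {
  tab <- toy_psms(peptide = sprintf("PEP%03dAAK", 1:20),
                  proteins = rep(c("P1", "REV__P1"), 10),
                  pep = seq(0.001, 0.8, length.out = 20))
  # threshold 1.0 keeps everything
  expect_equal(nrow(filter_peptide_fdr_per_file(tab, 1.0)), 20L)
  # a file without decoys gets q = 0 everywhere, with a warning
  tgt <- tab[!tab$is_decoy]
  expect_warning(out <- filter_peptide_fdr_per_file(tgt, 0.01), "no decoys")
  expect_equal(nrow(out), 10L)
  # an all-decoy file passes nothing at any finite threshold
  dec <- tab[tab$is_decoy]
  expect_equal(nrow(filter_peptide_fdr_per_file(dec, 1.0)), 0L)
  # monotone in the threshold
  n_kept <- vapply(c(0.05, 0.1, 0.3, 0.6, 1.0),
                   function(t) nrow(filter_peptide_fdr_per_file(tab, t)),
                   integer(1))
  expect_true(all(diff(n_kept) >= 0))
})

test_that("collapse keeps the best evidence per peptide and is order-independent", {
  tab <- toy_psms(peptide = c("AAAAAAK", "AAAAAAK", "AAAAAAK", "CCCCCCR"),
                  proteins = c("P1", "P1", "P1", "P2"),
                  pep = c(0.01, 0.001, 0.1, 0.05),
                  raw_file = c("f1", "f2", "f3", "f1"),
                  intensity = c(10, 20, 30, 5))
  ev <- collapse_to_peptides(tab)
  expect_equal(nrow(ev), 2L)
  expect_equal(ev$best_pep[ev$peptide == "AAAAAAK"], 0.001)
  expect_true(all(vapply(seq_len(nrow(ev)), function(i) {
    ev$best_pep[i] <= min(tab$pep[tab$peptide == ev$peptide[i]])
  }, logical(1))))
  # permuting rows yields identical output
  set.seed(2)
  ev2 <- collapse_to_peptides(tab[sample(nrow(tab))])
  expect_equal(ev, ev2, ignore_attr = TRUE)
  # per-experiment intensity sums
  intens <- attr(ev, "intensity")
  expect_equal(sum(intens[intens$peptide == "AAAAAAK", ]$intensity), 60)
  # merging a table with itself changes nothing
  ev3 <- collapse_to_peptides(rbind(tab, tab))
  expect_equal(ev3, ev, ignore_attr = TRUE)
})
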