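# Residues used inside synthetic tryptic peptides: no K/R (would create
# internal cleavage sites) and no P at position 1 (would suppress the
# upstream cleavage under plain trypsin).
.aa_interior <- c("A", "C", "D", "E", "F", "G", "H", "I", "L", "M",
                  "N", "Q", "S", "T", "V", "W", "Y")

random_tryptic_peptide <- function(len) {
  first <- sample(.aa_interior, 1L)
  mid <- if (len > 2L) sample(c(.aa_interior, "P"), len - 2L, replace = TRUE) else character(0)
  paste(c(first, mid, sample(c("K", "R"), 1L)), collapse = "")
}

#' Generate a synthetic protein database with isoform-like redundancy
#'
#' Builds target proteins as concatenations of random tryptic peptides
#' (each ending in K or R, no internal cleavage sites), so the in-silico
#' digest recovers the generating peptides exactly. A fraction of genes
#' additionally gets an isoform entry that shares a random subset of the
#' parent's peptides and carries a few isoform-specific ones, emulating the
#' high shared-peptide fraction of isoform-containing databases.
#'
#' @param n_proteins Total number of target entries to generate.
#' @param seed Integer seed.
#' @param isoform_fraction Fraction of entries that are isoforms of another
#'   entry (0 gives an isoform-free database).
#' @param peptides_per_protein Mean number of peptides per parent protein
#'   (Poisson, minimum 3).
#' @param peptide_length Range of peptide lengths sampled uniformly.
#' @param share_range Range of the fraction of parent peptides an isoform
#'   reuses.
#' @return A `protein_db` of target entries with accessions `SYNP<i>` and
#'   isoforms `SYNP<i>-2`.
#' @export
make_synthetic_database <- function(n_proteins, seed, isoform_fraction = 0,
                                    peptides_per_protein = 10,
                                    peptide_length = c(8L, 20L),
                                    share_range = c(0.4, 0.8)) {
  stopifnot(n_proteins >= 1L, isoform_fraction >= 0, isoform_fraction <= 1)
  set.seed(seed)
  n_iso <- round(n_proteins * isoform_fraction)
  n_parent <- n_proteins - n_iso
  stopifnot(n_parent >= n_iso)
  acc <- character(n_proteins)
  seqs <- character(n_proteins)
  parent_peps <- vector("list", n_parent)
  for (i in seq_len(n_parent)) {
    k <- max(3L, stats::rpois(1L, peptides_per_protein))
    lens <- sample(peptide_length[1L]:peptide_length[2L], k, replace = TRUE)
    parent_peps[[i]] <- vapply(lens, random_tryptic_peptide, character(1L))
    acc[i] <- sprintf("SYNP%05d", i)
    seqs[i] <- paste(parent_peps[[i]], collapse = "")
  }
  if (n_iso > 0L) {
    parents <- sample.int(n_parent, n_iso)
    for (j in seq_len(n_iso)) {
      p <- parents[j]
      peps <- parent_peps[[p]]
      n_shared <- max(1L, round(stats::runif(1L, share_range[1L], share_range[2L]) *
                                  length(peps)))
      shared <- sample(peps, n_shared)
      n_unique <- sample(1:3, 1L)
      lens <- sample(peptide_length[1L]:peptide_length[2L], n_unique, replace = TRUE)
      uniq <- vapply(lens, random_tryptic_peptide, character(1L))
      iso <- sample(c(shared, uniq))
      acc[n_parent + j] <- paste0(acc[p], "-2")
      seqs[n_parent + j] <- paste(iso, collapse = "")
    }
  }
  protein_db(acc, seqs)
}
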