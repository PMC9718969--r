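#' Shuffle a peptide, keeping the C-terminal residue fixed
#'
#' Draws a uniform random permutation of all residues except the last, which
#' stays in place so that the tryptic cleavage site is preserved. Inputs
#' shorter than two residues are returned unchanged.
#'
#' @param peptide Amino-acid string.
#' @return A shuffled amino-acid string of the same length and residue
#'   composition.
#' @export
shuffle_peptide <- function(peptide) {
  n <- nchar(peptide)
  if (n < 2L) return(peptide)
  ch <- strsplit(peptide, "")[[1L]]
  head <- ch[-n]
  paste(c(head[sample.int(n - 1L)], ch[n]), collapse = "")
}

#' Build an entrapment database by peptide-level shuffling
#'
#' Constructs known-false entrapment proteins from the target entries of a
#' database. Each target is in-silico digested (Trypsin/P-style cleavage, no
#' missed cleavages); retained peptides (longer than six residues) are each
#' either kept verbatim with probability `shared_fraction` -- creating
#' peptides shared between target and entrapment databases -- or replaced in
#' place by a shuffled version that keeps the C-terminal residue. Short
#' peptides are left untouched, so an entrapment protein has the same length
#' and cleavage structure as its source. The keep-or-shuffle pass runs once
#' and is then repeated a further `num_repeats` times, so the entrapment
#' database holds `1 + num_repeats` entries per target (default: a five-fold
#' entrapment database).
#'
#' A shuffled peptide that collides with a peptide of the target index is
#' re-shuffled up to `max_reshuffle_attempts` times, then accepted.
#'
#' @param db A `protein_db` with at least one target entry.
#' @param shared_fraction Fraction S in \[0, 1\] of peptides kept shared.
#' @param num_repeats Number of additional passes after the first (default 4,
#'   giving `1 + num_repeats = 5` entrapment entries per target).
#' @param seed Integer seed; required, the build must be reproducible.
#' @param max_reshuffle_attempts Re-shuffles allowed on collision with a
#'   target peptide.
#' @param exact_count If `TRUE`, exactly `round(S * k)` of a protein's k
#'   retained peptides are kept shared (sampled without replacement) instead
#'   of independent Bernoulli(S) draws per peptide.
#' @param enzyme Cleavage rule used for the peptide tiling.
#' @return A `protein_db` containing the original entries followed by
#'   entrapment entries with accessions `ENTRAP<r>__<accession>` and
#'   `entry_class = "entrapment"`.
#' @export
build_entrapment_database <- function(db, shared_fraction, num_repeats = 4L,
                                      seed = NULL, max_reshuffle_attempts = 10L,
                                      exact_count = FALSE, enzyme = "trypsin/p") {
  if (is.null(seed)) stop("a seed is required for a reproducible entrapment build")
  if (!is.numeric(shared_fraction) || shared_fraction < 0 || shared_fraction > 1) {
    stop("shared_fraction must lie in [0, 1]")
  }
  targets <- db[db$entry_class == "target", , drop = FALSE]
  if (nrow(targets) == 0L) stop("database contains no target entries")

  # target peptide set for collision checks (length > 6, no missed cleavages)
  tiling <- lapply(targets$sequence, function(s) {
    digest_boundaries(strsplit(s, "")[[1L]], enzyme)
  })
  target_peptides <- new.env(hash = TRUE, parent = emptyenv())
  for (i in seq_len(nrow(targets))) {
    b <- tiling[[i]]
    len <- b$end - b$start + 1L
    for (j in which(len > 6L)) {
      assign(substr(targets$sequence[i], b$start[j], b$end[j]), TRUE,
             envir = target_peptides)
    }
  }

  set.seed(seed)
  acc <- character(0)
  seqs <- character(0)
  for (r in seq_len(num_repeats + 1L)) {
    for (i in seq_len(nrow(targets))) {
      b <- tiling[[i]]
      len <- b$end - b$start + 1L
      s <- targets$sequence[i]
      idx <- which(len > 6L)
      k <- length(idx)
      if (k > 0L) {
        if (exact_count) {
          keep <- logical(k)
          keep[sample.int(k, round(shared_fraction * k))] <- TRUE
        } else {
          keep <- stats::runif(k) < shared_fraction
        }
        for (m in which(!keep)) {
          j <- idx[m]
          pep <- substr(s, b$start[j], b$end[j])
          shuf <- shuffle_peptide(pep)
          attempts <- 0L
          while (exists(shuf, envir = target_peptides, inherits = FALSE) &&
                 attempts < max_reshuffle_attempts) {
            shuf <- shuffle_peptide(pep)
            attempts <- attempts + 1L
          }
          substr(s, b$start[j], b$end[j]) <- shuf
        }
      }
      acc <- c(acc, paste0("ENTRAP", r, "__", targets$accession[i]))
      seqs <- c(seqs, s)
    }
  }
  protein_db(c(db$accession, acc), c(db$sequence, seqs),
             entry_class = c(db$entry_class, rep("entrapment", length(acc))),
             decoy_prefix = attr(db, "decoy_prefix"),
             contaminant_prefix = attr(db, "contaminant_prefix"))
}

#' Measure the realized shared-peptide fraction of an entrapment database
#'
#' Digests every entrapment entry (no missed cleavages, peptides longer than
#' six residues) and reports the fraction of peptide occurrences found
#' verbatim in the target-entry peptide index -- the empirical counterpart of
#' the builder's `shared_fraction`.
#'
#' @param db An entrapment-extended `protein_db`.
#' @param enzyme Cleavage rule, matching the builder.
#' @return A list with `fraction` (shared occurrences / total occurrences)
#'   and `n` (total entrapment peptide occurrences counted).
#' @export
measure_entrapment_shared_fraction <- function(db, enzyme = "trypsin/p") {
  ent <- db[db$entry_class == "entrapment", , drop = FALSE]
  if (nrow(ent) == 0L) stop("database contains no entrapment entries")
  params <- digest_params(enzyme = enzyme, missed_cleavages = 0L,
                          min_length = 7L, max_length = .Machine$integer.max)
  target_index <- build_peptide_index(db, params, classes = "target")
  target_set <- new.env(hash = TRUE, parent = emptyenv())
  for (p in unique(target_index$map$peptide)) assign(p, TRUE, envir = target_set)
  total <- 0L
  shared <- 0L
  for (s in ent$sequence) {
    for (p in digest_protein(s, params)) {
      total <- total + 1L
      if (exists(p, envir = target_set, inherits = FALSE)) shared <- shared + 1L
    }
  }
  list(fraction = shared / total, n = total)
}
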