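# Shared fixture builders for the test suite. Everything is generated in
# code; no binary fixtures.

# Collapsed peptide evidence straight from its fields.
toy_evidence <- function(peptide, proteins, best_pep = rep(1e-3, length(peptide)),
                         is_decoy = NULL, decoy_prefix = "REV__") {
  if (is.null(is_decoy)) {
    is_decoy <- vapply(strsplit(proteins, ";", fixed = TRUE),
                       function(a) all(startsWith(a, decoy_prefix)), logical(1L))
  }
  data.table::data.table(peptide = peptide, best_pep = best_pep,
                         proteins = proteins, is_decoy = is_decoy,
                         is_contaminant = FALSE)
}

# PSM rows with sensible defaults for the columns the pipeline expects.
toy_psms <- function(peptide, proteins, pep, raw_file = "f1",
                     experiment = raw_file, intensity = NA_real_,
                     is_decoy = NULL, decoy_prefix = "REV__") {
  if (is.null(is_decoy)) {
    is_decoy <- vapply(strsplit(proteins, ";", fixed = TRUE),
                       function(a) all(startsWith(a, decoy_prefix)), logical(1L))
  }
  data.table::data.table(peptide = peptide, modified_peptide = peptide,
                         proteins = proteins, raw_file = raw_file,
                         experiment = experiment, pep = pep, score = -log10(pep),
                         intensity = intensity, is_decoy = is_decoy,
                         is_contaminant = FALSE)
}

# A scored group table (sorted by decreasing score) from accession vectors.
toy_scored <- function(members, scores, leading = members,
                       decoy_prefix = "REV__") {
  members <- lapply(members, as.character)
  leading <- lapply(leading, as.character)
  out <- data.table::data.table(
    group_id = seq_along(members),
    leading = leading, members = members,
    n_unique = lengths(members), n_total = lengths(members),
    score = scores,
    is_decoy = vapply(members, function(m) all(startsWith(m, decoy_prefix)),
                      logical(1L)),
    is_contaminant = vapply(leading, function(m) {
      all(startsWith(sub(paste0("^", decoy_prefix), "", m), "CON__"))
    }, logical(1L)))
  lead1 <- vapply(leading, `[`, character(1L), 1L)
  out[order(-score, lead1)]
}

# Random amino-acid string without K/R (a single synthetic tryptic context).
random_seq <- function(n) {
  paste(sample(c("A", "C", "D", "E", "F", "G", "H", "I", "L", "M",
                 "N", "Q", "S", "T", "V", "W", "Y", "K", "R"), n, replace = TRUE),
        collapse = "")
}

# Independent quadratic oracle for subset grouping: plain double loops over
# observed peptide sets, same merge/assignment conventions as documented
# (identical sets co-lead; strict subsets go to the largest maximal superset,
# alphabetical tie-break).
oracle_subset_grouping <- function(evidence) {
  accs <- sort(unique(unlist(strsplit(evidence$proteins, ";", fixed = TRUE))))
  sets <- lapply(accs, function(a) {
    sort(unique(evidence$peptide[vapply(strsplit(evidence$proteins, ";", fixed = TRUE),
                                        function(x) a %in% x, logical(1))]))
  })
  names(sets) <- accs
  key <- vapply(sets, paste, character(1), collapse = "|")
  reps <- accs[!duplicated(key)]
  is_subset <- function(a, b) all(sets[[a]] %in% sets[[b]])
  maximal <- reps[vapply(reps, function(a) {
    !any(vapply(reps, function(b) {
      !identical(key[[a]], key[[b]]) && is_subset(a, b)
    }, logical(1)))
  }, logical(1))]
  assign_to <- function(a) {
    cand <- maximal[vapply(maximal, function(m) is_subset(a, m), logical(1))]
    cand[order(-lengths(sets[cand]), cand)][1]
  }
  groups <- lapply(maximal, function(m) {
    members <- accs[vapply(accs, function(a) assign_to(a) == m, logical(1))]
    leading <- sort(members[key[members] == key[[m]]])
    list(leading = leading, members = sort(members))
  })
  groups[order(vapply(groups, function(g) g$leading[1], character(1)))]
}

canon <- function(gr) {
  out <- lapply(seq_along(gr$members), function(i) {
    list(leading = sort(gr$leading[[i]]), members = sort(gr$members[[i]]))
  })
  out[order(vapply(out, function(g) g$leading[1], character(1)))]
}
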