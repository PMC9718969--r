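#' Read a protein FASTA database
#'
#' Reads a (possibly line-wrapped) amino-acid FASTA file into a protein
#' database. The entry class of each record (target, decoy, entrapment,
#' contaminant) is inferred from its accession prefix: decoys carry
#' `decoy_prefix` (MaxQuant-style `"REV__"` by default), contaminants carry
#' `contaminant_prefix` (`"CON__"`), and entrapment entries carry an
#' `"ENTRAP<r>__"` prefix as written by [build_entrapment_database()].
#' Everything else is a target. Sequences are uppercased on read.
#'
#' @param path Path to a FASTA file.
#' @param decoy_prefix Accession prefix marking decoy entries.
#' @param contaminant_prefix Accession prefix marking contaminant entries.
#' @return A `protein_db` object: a `data.frame` with columns `accession`,
#'   `sequence` and `entry_class`, in file order, with the prefixes stored as
#'   attributes.
#' @seealso [write_fasta()], [build_peptide_index()], [add_decoys()]
#' @export
read_fasta <- function(path, decoy_prefix = "REV__", contaminant_prefix = "CON__") {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(nzchar(trimws(lines)))
  if (length(nonblank) == 0L) stop("no records in FASTA file: ", path)
  first <- nonblank[1L]
  if (!startsWith(trimws(lines[first]), ">")) {
    stop("malformed FASTA: expected header line starting with '>' at line ", first)
  }
  seqs <- Biostrings::readAAStringSet(path)
  if (length(seqs) == 0L) stop("no records in FASTA file: ", path)
  acc <- vapply(strsplit(names(seqs), "[ \t]"), `[`, character(1L), 1L)
  if (anyDuplicated(acc)) {
    stop("duplicate accession(s) in FASTA: ",
         paste(unique(acc[duplicated(acc)]), collapse = ", "))
  }
  sq <- toupper(as.character(seqs))
  if (any(!nzchar(sq))) {
    stop("malformed FASTA: empty sequence for record ",
         paste(acc[!nzchar(sq)], collapse = ", "))
  }
  protein_db(acc, sq,
             decoy_prefix = decoy_prefix,
             contaminant_prefix = contaminant_prefix)
}

#' Construct a protein database object
#'
#' @param accession Character vector of unique accessions.
#' @param sequence Character vector of amino-acid sequences (uppercased).
#' @param entry_class Optional character vector of classes; inferred from
#'   accession prefixes when `NULL`.
#' @param decoy_prefix,contaminant_prefix Accession prefixes used for class
#'   inference and kept as attributes for downstream counterpart mapping.
#' @return A `protein_db` data.frame.
#' @export
protein_db <- function(accession, sequence, entry_class = NULL,
                       decoy_prefix = "REV__", contaminant_prefix = "CON__") {
  stopifnot(length(accession) == length(sequence))
  if (anyDuplicated(accession)) stop("duplicate accession in database")
  if (any(!nzchar(sequence))) stop("empty sequence in database")
  if (is.null(entry_class)) {
    entry_class <- infer_entry_class(accession, decoy_prefix, contaminant_prefix)
  }
  db <- data.frame(accession = as.character(accession),
                   sequence = toupper(as.character(sequence)),
                   entry_class = entry_class,
                   stringsAsFactors = FALSE)
  attr(db, "decoy_prefix") <- decoy_prefix
  attr(db, "contaminant_prefix") <- contaminant_prefix
  class(db) <- c("protein_db", "data.frame")
  db
}

infer_entry_class <- function(accession, decoy_prefix, contaminant_prefix) {
  cls <- rep("target", length(accession))
  stripped <- strip_decoy_prefix(accession, decoy_prefix)
  is_decoy <- stripped != accession
  cls[grepl("^ENTRAP[0-9]+__", stripped)] <- "entrapment"
  cls[startsWith(stripped, contaminant_prefix)] <- "contaminant"
  cls[is_decoy] <- "decoy"
  cls
}

strip_decoy_prefix <- function(accession, decoy_prefix) {
  sub(paste0("^", decoy_prefix), "", accession)
}

#' @export
print.protein_db <- function(x, ...) {
  cat("Protein database:", nrow(x), "entries\n")
  print(table(x$entry_class))
  invisible(x)
}

#' Write a protein database to FASTA
#'
#' @param db A `protein_db` object.
#' @param path Output path.
#' @param width Line-wrap width for sequences.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(db, path, width = 60L) {
  seqs <- Biostrings::AAStringSet(db$sequence)
  names(seqs) <- db$accession
  Biostrings::writeXStringSet(seqs, path, width = width)
  invisible(path)
}

#' Append reversed decoy entries to a database
#'
#' Each non-decoy entry gets a sequence-reversed counterpart whose accession is
#' the original prefixed with the database's decoy prefix, mirroring the
#' MaxQuant convention. Entrapment entries receive reversed decoys too, so an
#' entrapment-extended search database is complete.
#'
#' @param db A `protein_db` without decoy entries.
#' @return A `protein_db` with the original entries followed by their decoys.
#' @export
add_decoys <- function(db) {
  if (any(db$entry_class == "decoy")) stop("database already contains decoy entries")
  prefix <- attr(db, "decoy_prefix")
  rev_seq <- vapply(strsplit(db$sequence, ""), function(ch) paste(rev(ch), collapse = ""),
                    character(1L))
  protein_db(c(db$accession, paste0(prefix, db$accession)),
             c(db$sequence, rev_seq),
             decoy_prefix = prefix,
             contaminant_prefix = attr(db, "contaminant_prefix"))
}

#' Digestion parameters
#'
#' @param enzyme `"trypsin"` (cleaves after K/R, not before P) or `"trypsin/p"`
#'   (cleaves after K/R regardless of a following proline).
#' @param missed_cleavages Maximum number of internal missed cleavage sites.
#' @param min_length,max_length Peptide length bounds in residues. The default
#'   minimum of 7 implements the "longer than six amino acids" retention rule.
#' @return A `digest_params` list.
#' @export
digest_params <- function(enzyme = c("trypsin", "trypsin/p"),
                          missed_cleavages = 0L,
                          min_length = 7L, max_length = 50L) {
  enzyme <- match.arg(enzyme)
  missed_cleavages <- as.integer(missed_cleavages)
  stopifnot(missed_cleavages >= 0L, min_length >= 1L, min_length <= max_length)
  structure(list(enzyme = enzyme, missed_cleavages = missed_cleavages,
                 min_length = min_length, max_length = max_length),
            class = "digest_params")
}

# 0-missed-cleavage fragment boundaries (start/end positions) for one protein.
# Unknown residues (X, U, B, Z, ...) never act as cleavage sites.
digest_boundaries <- function(chars, enzyme) {
  n <- length(chars)
  sites <- which(chars == "K" | chars == "R")
  sites <- sites[sites < n]
  if (enzyme == "trypsin" && length(sites)) sites <- sites[chars[sites + 1L] != "P"]
  list(start = c(1L, sites + 1L), end = c(sites, n))
}

#' In-silico proteolytic digestion of one protein
#'
#' Cleaves after lysine (K) and arginine (R); with enzyme `"trypsin"` a
#' following proline suppresses cleavage, with `"trypsin/p"` it does not.
#' Peptides containing up to `missed_cleavages` internal sites are generated,
#' the length filter applied, and duplicates within the protein returned once,
#' in order of first occurrence.
#'
#' @param sequence Amino-acid string.
#' @param params A [digest_params()] object.
#' @return Character vector of peptide sequences.
#' @export
digest_protein <- function(sequence, params = digest_params()) {
  stopifnot(nzchar(sequence))
  chars <- strsplit(toupper(sequence), "")[[1L]]
  b <- digest_boundaries(chars, params$enzyme)
  k <- length(b$start)
  out <- character(0)
  for (i in seq_len(k)) {
    jmax <- min(k, i + params$missed_cleavages)
    for (j in i:jmax) {
      len <- b$end[j] - b$start[i] + 1L
      if (len < params$min_length) next
      if (len > params$max_length) break
      out <- c(out, substr(sequence, b$start[i], b$end[j]))
    }
  }
  unique(out)
}

#' Build a peptide-to-protein index by in-silico digestion
#'
#' Digests every entry of a database (optionally restricted to a subset of
#' entry classes) and records, for each distinct peptide, the set of
#' accessions whose digest contains it. Peptides mapping to more than one
#' accession are flagged as shared.
#'
#' @param db A `protein_db`.
#' @param params A [digest_params()] object.
#' @param classes Optional character vector of entry classes to index
#'   (default: all).
#' @param il_equivalent Treat isoleucine and leucine as equivalent when
#'   matching peptides (both collapsed to `"L"` in the index key). Off by
#'   default; intended for peptide remapping only.
#' @return A `peptide_index` object with elements `map` (data.table of
#'   `peptide`/`accession` pairs), `decoy_prefix` and `params`.
#' @export
build_peptide_index <- function(db, params = digest_params(), classes = NULL,
                                il_equivalent = FALSE) {
  stopifnot(nrow(db) > 0L)
  if (!is.null(classes)) db <- db[db$entry_class %in% classes, , drop = FALSE]
  peps <- lapply(db$sequence, digest_protein, params = params)
  map <- data.table::data.table(
    peptide = unlist(peps, use.names = FALSE),
    accession = rep(db$accession, lengths(peps)))
  if (il_equivalent) map[, peptide := gsub("I", "L", peptide, fixed = TRUE)]
  map <- unique(map)
  data.table::setkeyv(map, "peptide")
  acc_class <- db$entry_class
  names(acc_class) <- db$accession
  structure(list(map = map,
                 accession_class = acc_class,
                 decoy_prefix = attr(db, "decoy_prefix") %||% "REV__",
                 il_equivalent = il_equivalent,
                 params = params),
            class = "peptide_index")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.peptide_index <- function(x, ...) {
  np <- data.table::uniqueN(x$map$peptide)
  cat("Peptide index:", np, "peptides over",
      data.table::uniqueN(x$map$accession), "proteins;",
      sprintf("shared fraction %.3f", shared_fraction(x)), "\n")
  invisible(x)
}

#' Fraction of peptides mapping to more than one protein
#'
#' @param index A `peptide_index`.
#' @return Fraction in \[0, 1\]; unique fraction is its complement.
#' @export
shared_fraction <- function(index) {
  counts <- index$map[, .N, by = "peptide"]$N
  mean(counts > 1L)
}

# Accession sets for a vector of peptides; unmapped peptides yield NULL.
lookup_peptides <- function(index, peptides) {
  if (index$il_equivalent) peptides <- gsub("I", "L", peptides, fixed = TRUE)
  hits <- index$map[data.table::data.table(peptide = peptides), on = "peptide",
                    nomatch = NULL]
  split(hits$accession, hits$peptide)
}
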