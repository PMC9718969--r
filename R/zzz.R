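#' @keywords internal
"_PACKAGE"

#' @importFrom data.table := .N .I .SD data.table
NULL

.datatable.aware <- TRUE

utils::globalVariables(c(
  ".row", "accession", "best_pep", "experiment", "group_id", "i.proteins",
  "intensity", "is_contaminant", "is_decoy", "is_razor", "modified_peptide",
  "n_groups", "pep", "peptide", "proteins", "q_value", "raw_file", "reverse",
  "score", "src", "true_sources", "truth_label", ".lead1", "fdr", "sid", "row"))
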