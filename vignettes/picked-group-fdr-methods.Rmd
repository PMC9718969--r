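---
title: "Protein group-level FDR estimation: models, choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Protein group-level FDR estimation: models, choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pickedgroupfdr)
```

## The problem

Bottom-up proteomics identifies peptides, not proteins. Rolling peptide
identifications up to proteins runs into two coupled difficulties. First,
many peptides map to several protein sequences — above 50% of tryptic
peptides once isoforms and unreviewed sequences are in the database — so
proteins must be combined into *protein groups* before error rates are
meaningful. Second, the standard target–decoy machinery does not transfer
directly to groups: the decoy counterparts of the proteins in a target group
are generally not grouped the same way, and popular heuristics for shared
peptides (Occam's razor) create false target groups that no decoy models,
which destroys error control precisely in the large, merged datasets where
it matters most.

`pickedgroupfdr` implements a group-level FDR estimator that stays
calibrated at scale, together with the machinery needed to *demonstrate*
calibration on purely synthetic data: an entrapment-database builder and a
multi-experiment peptide-evidence simulator.

## The estimation pipeline

`picked_group_fdr()` runs the following stages; each stage is an exported
function and each option is independently selectable (named presets bundle
the published combinations):

1. **Remapping** (`remap_peptides()`): peptide sequences are looked up in an
   in-silico digest index of the analysis database; peptides absent from the
   index are discarded rather than rescued.
2. **Peptide-level filtering** (`filter_peptide_fdr_per_file()`): within
   each raw file, the best PSM per peptide is ranked by posterior error
   probability (PEP) and a decoy/target q-value is computed (targets-only
   denominator, no pseudo-count); peptides at q ≤ 1% are kept. Filtering per
   raw file, before grouping, removes the low-confidence evidence that would
   otherwise distort both grouping and product scores.
3. **Collapse** (`collapse_to_peptides()`): best evidence per plain peptide
   sequence across all files and searches; intensities are summed per
   experiment and passed through unchanged.
4. **Grouping** (`no_grouping()`, `subset_grouping()`,
   `rescued_subset_grouping()`): subset grouping merges a protein into
   another's group when its observed peptides are a subset of the other's;
   identical sets co-lead. Rescued subset grouping repeats the grouping
   after removing evidence below the score equivalent to a 1% group-level
   FDR (computed with the method's own defaults on the first-pass groups)
   and re-appends first-pass groups whose proteins vanished entirely — so
   low-confidence peptides cannot split a group, yet every group still gets
   an FDR estimate.
5. **Shared peptides** (`discard_shared()`, `assign_razor()`): peptides
   spanning several groups are either dropped or razor-assigned to the
   candidate group with the most unique peptides (seeded random
   tie-breaking; decoy groups compete identically to target groups).
6. **Scoring** (`score_best_pep()`, `score_multiply_pep()`,
   `optimize_pep_divisor()`): −log10 of the best peptide PEP, or the
   PEP-product score in which PEPs are first divided by a constant chosen by
   grid search (13 logarithmic steps over 1e−4…1) to maximize accepted
   groups — peptides with PEP above the constant then reduce a group's
   score.
7. **Competition** (`picked_tds()`, `picked_group_tds()`): the picked
   strategy keeps the better of each target/decoy counterpart pair. The
   picked *group* strategy walks the score-sorted group list and eliminates
   a group when the counterpart of one of its leading proteins was already
   observed among the members of a retained, strictly higher-scoring group.
   Checking candidate *leading* proteins against retained *members* is
   deliberate: a protein observed only as a subsumed, non-leading member of
   an isoform group must still eliminate its lower-scoring decoy, otherwise
   surviving decoys systematically outnumber the false target groups they
   are meant to model and the estimate becomes several-fold conservative on
   isoform-rich data. With no grouping the rule reduces exactly to the
   protein-level picked strategy.
8. **FDR** (`estimate_group_fdr()`): at each group, FDR = (decoy groups at
   or above its score)/(target groups at or above its score), q-values by
   running minimum from the worst score upward, reported capped at 1. Ties
   share the counts at the end of their tie block; contaminant groups are
   reported with q-values but excluded from both counts. Score ties in the
   competition retain both parties (conservative; ties have measure zero for
   continuous PEPs) and sorting ties are broken by accession for
   determinism.

The null hypothesis attached to a reported group is that none of its member
proteins produced a correct peptide observation; accepting a group at q ≤ 1%
claims that at least one member did.

### Presets

| preset | grouping | shared | scoring | competition |
|---|---|---|---|---|
| `maxquant` | subset | razor | PEP product | classic |
| `savitski` | none | discard | best PEP | picked |
| `picked_protein_group_fdr` | rescued subset | discard | best PEP | picked group |
| `savitski_classic` | none | discard | best PEP | classic |
| `discard_picked_group` | subset | discard | best PEP | picked group |
| `razor_picked_group` | subset | razor | best PEP | picked group |
| `classic_protein_group_fdr` | rescued subset | discard | best PEP | classic |

The PEP source (search engine native or rescored) is a property of the input
table, not of the scorer, so "best PEP" covers both variants without
separate code paths.

## Entrapment databases

`build_entrapment_database()` manufactures known-false proteins: each target
is tiled into tryptic peptides (Trypsin/P cleavage, no missed cleavages);
peptides longer than six residues are kept verbatim with probability S —
creating controlled target/entrapment sharing — or replaced in place by a
shuffle that fixes the C-terminal residue; shorter peptides stay untouched.
One initial pass plus four repeats yield a five-fold entrapment database.
S = 0.5 mirrors the shared-peptide ratio of an isoform-containing database
and S = 0.04 that of a canonical one. Keep-versus-shuffle is an independent
Bernoulli(S) draw per peptide occurrence (an exact-count mode is available
when strict per-protein control is wanted), and a shuffle that collides with
an existing target peptide is re-drawn up to 10 times, then accepted —
collisions are rare for peptides of seven or more residues.
`measure_entrapment_shared_fraction()` digests the entrapment entries and
reports the realized shared fraction, which converges to S with binomial
error.

## The simulator

`simulate_dataset()` generates multi-experiment peptide lists with
correct/incorrect truth labels. Per experiment: the number of present
proteins is drawn from N(`n_prot_mean`, `n_prot_stdev`); presence is sampled
without replacement proportionally to per-protein probabilities; each
peptide of a present protein is detected independently with its
proteotypicity; correct scores come from a normal N(2.5, 0.7) truncated
below at the score `min_score` corresponding to the configured peptide-level
FDR (1%) and incorrect-fraction (0.6); the number of incorrect peptides is
`round(2 · n_tp · fdr/(1 − fdr))`, drawn uniformly from all target *and*
decoy index peptides with scores from truncated N(0, 0.7). Scores live on
the −log10(PEP) scale, so the output feeds the standard pipeline with no
simulation-specific code path.

Two aspects deserve emphasis:

* **Detection heterogeneity.** Per-protein presence probabilities default to
  the U-shaped Beta(0.3, 0.7) and per-peptide proteotypicities to
  Beta(1.2, 3); both can be overridden with measured profiles. The U-shape
  matters: repository data contain proteins seen in nearly every experiment
  *and* a large mass seen in only one or a few. A zero-avoiding symmetric
  choice would make every protein correctly identified somewhere once a
  handful of experiments are merged — no false target group could exist at
  all, and there would be nothing for an FDR method to be tested against.
* **What the simulator does not model.** Spectra, retention time, intensity
  realism, modified peptides, and any dependence of incorrect matches on
  sequence composition. Passing calibration tests on simulated data
  therefore demonstrates the combinatorial/statistical correctness of the
  estimator, not robustness to the score-calibration problems of real
  search engines.

## Measuring calibration

`empirical_fdp()` labels an accepted group false when none of its assigned
peptides is a correct observation of one of its member proteins — a
razor-misassigned correct peptide does *not* rescue the receiving group,
matching the mechanism by which razor peptides break error control.
`entrapment_fdr()` counts accepted groups whose leading proteins are all
entrapment entries, scaled by 1 + n_target/n_entrapment to account for false
positives landing in the original database (mixed groups count as not
observed-false; both choices are configurable). `calibration_curve()` pairs
each observed value with the reported FDR *attained* by the accepted list
(its largest q-value) rather than the nominal threshold: at desk scale the
decoy reservoir is small and a whole list can sit below 1% reported FDR, in
which case dividing by the nominal threshold would measure list exhaustion,
not calibration. Ratios within [0.67, 1.5] at 1% are treated as
well-calibrated.

## Numerical and degenerate-input choices

* PEPs at or below zero are clamped to 1e-20 with a warning before taking
  logarithms.
* A raw file without decoys gets q = 0 for all its peptides, with a warning;
  an all-decoy file passes nothing.
* Peptide identity for collapsing uses the plain sequence by default
  (modified-sequence collapsing is available); I and L are distinct
  residues, with an I/L-equivalence option for remapping only.
* Records mapping to both target and decoy accessions count as target;
  decoy status requires an all-decoy mapping.
* Non-standard residues (X, U, B, Z) never act as cleavage sites.
* Razor tie-breaking and entrapment shuffling require explicit seeds; a
  seedless call errors rather than silently producing irreproducible
  output.
* If no group reaches the rescue threshold, rescued grouping falls back to
  plain subset grouping with a warning.

## Problem sizes used by the shipped tests

The test suite exercises the estimator end to end on generated data: unit
fixtures of tens to hundreds of proteins; a calibration run with 10
experiments of ~10,000 present proteins against a 20,000-protein
isoform-rich database; and a 400-experiment run at ~2,000 present proteins
against the same database for the razor breakdown. These sizes keep the full
suite comfortably within a coffee break while reproducing the qualitative
regime of repository-scale analyses; all quantities scale with the inputs,
and nothing in the implementation is specific to these sizes.

## Known limitations

* The picked group competition is a heuristic: adversarial group
  compositions (a one-protein incorrect target group eliminating a
  ten-protein decoy group that happens to share a peptide) can be
  constructed, and no mitigation is attempted.
* Calibration of any picked-style estimator degrades when a large fraction
  of the database is correctly identified: surviving decoys then undercount
  the false target groups formed by proteins that are observed only through
  incorrect or shared evidence. The estimator is designed for — and should
  be judged in — the regime where the searched database is several times
  larger than any single experiment's proteome.
* Quantification is pass-through only (per-experiment intensity sums over a
  group's assigned peptides); no normalization or inference-aware
  apportionment.
* Only trypsin and Trypsin/P digestion rules are implemented, without
  semi-enzymatic peptides or modified-peptide expansion.
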