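---
title: "Benchmarking missense pathogenicity scores: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking missense pathogenicity scores}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(missbench)
```

## The evaluation model

`missbench` evaluates continuous pathogenicity scores in [0, 1] — one per
amino-acid substitution — against binary clinical labels. Three ingredients
define the evaluation:

1. **Three-class thresholding.** A score is *likely benign* strictly below
   the lower cutoff, *ambiguous* from the lower cutoff up to (but not
   including) the upper cutoff, and *likely pathogenic* at or above the
   upper cutoff. The defaults, 0.340 and 0.564, are the published
   AlphaMissense band edges. The boundary conventions matter: a score of
   exactly 0.340 is ambiguous and 0.564 is pathogenic. We fixed them this
   way because the one published score that sits essentially on the upper
   edge (0.5637, for a clinically pathogenic variant) is reported as a
   misprediction, which it only is if values just below the cutoff are
   ambiguous rather than pathogenic.

2. **Ambiguity policy.** `ambiguous_as_error` (default) counts an
   ambiguous call against the predictor: a false negative on a pathogenic
   label, a false positive on a benign one. This is the only convention
   under which the reconstructed gold-standard single-protein row (102
   pathogenic / 17 evaluated benign variants, 4 mispredictions on each
   side) reproduces PPV = TPR = F1 = 0.961 with TPR = 98/102.
   `ambiguous_excluded` removes ambiguous calls before counting and
   tallies them per label side, matching the alternative convention used
   for prediction-distribution summaries.

3. **Metrics.** PPV, TPR, F1 and MCC from the confusion table; aucROC from
   the continuous scores by the rank-sum formulation with midrank ties,
   which equals P(score_pathogenic > score_benign) + ½P(equal). AUC is
   therefore invariant under strictly increasing transforms of the scores.

**Zero-denominator convention.** Sparse subsets (a handful of variants in
a small region set) routinely produce confusion tables where a metric's
denominator vanishes. Those metrics are reported as 0 and named in a
`degenerate` column instead of raising, so batch runs never abort. One
subtlety: the all-wrong table TP = TN = 0, FP = FN = 1 is *not* degenerate
— all four marginals equal 1 and the MCC formula evaluates cleanly to −1.
Only genuinely empty marginals (e.g. an empty input, or single-class
labels for AUC) trigger the flag.

## Restrictions and frequencies

Filters apply in a fixed order — protein set → region → confidence — so
reports are comparable across runs; any stage can be omitted. Region
membership is evaluated at the variant's residue position, with both
boundary residues inclusive (no boundary convention is standard for
segment annotations, so we fixed inclusivity and test it). Accessions
without any region annotation of the requested type are excluded from both
the inside and the outside subset — a residue of an unannotated protein is
neither "in a TM segment" nor meaningfully "outside" one. The confidence
filter keeps residues with pLDDT ≥ cutoff (default 50): "lower than 50" is
excluded, so 50.0 itself survives.

Mutation frequencies divide variant counts by the summed length of the
protein set, giving counts per residue. Clinical counts use the labels;
predicted counts use the three-way class, with ambiguous predictions
counted in neither class. With `snv_restrict` the predicted counts keep
only substitutions reachable by a single nucleotide change — predicted
score tables cover all 19 alternates per residue, while clinical variants
arise from SNVs, so the restriction makes the two sides commensurable.

## Genetic-code reachability

An ordered pair (ref, alt) is SNV-reachable when some sense codon of ref
differs at exactly one nucleotide from a sense codon of alt (standard
nuclear code; stop codons never participate). This *generic* per-pair mode
is the default because the package deliberately consumes no genomic
coordinates; a codon-specific mode (`snv_reachable_from_codon()`) is
available when the actual codon is known, and is what the synthetic
generator uses. The reachable set — 150 of the 380 ordered pairs — is
verified in the tests against an independent exhaustive enumeration of all
61 × 9 codon transitions, and is symmetric because single-nucleotide
changes are reversible.

## Substitution-matrix analytics

Cell means are unweighted arithmetic means over substitution records (each
instance counts once, no per-protein reweighting). Asymmetric pairs are
flagged when |mean(a→b) − mean(b→a)| ≥ 0.2, *inclusive*; the comparison
subtracts a square-root-machine-epsilon guard so that deltas that are
exactly 0.2 in real arithmetic but land a few ulps short in floating point
are still flagged. Label flips require strictly opposite non-ambiguous
classes on the two directions. The BLOSUM62 correlation treats each
defined ordered cell as one point against the symmetric BLOSUM62 value of
its unordered pair, so both directions contribute; Pearson r with the
standard t-distribution p-value, and an ordinary least-squares line.
BLOSUM62 is embedded as a constant (it is a fixed published matrix) and
cross-checked against an independent copy in the tests.

## Structure annotation

Per-residue profiles carry two means per position: over SNV-reachable
records and over all records. Region means average the *per-residue
means*, not the raw records — the two differ when coverage is uneven
across positions, and the two-stage average is the one that matches
per-residue structure colouring. Annotation rewrites only columns 55–60
(occupancy) and 61–66 (B-factor) of ATOM/HETATM records, `%6.2f`, leaving
every other byte untouched; this makes the operation idempotent and lets
coordinates round-trip exactly, which the tests assert byte-for-byte.
Residues absent from the profile are written as 0.00 in both fields (and
counted in a report attribute) rather than left as-is, so downstream
colouring is deterministic. Two layouts are supported: `qb` (default;
B-factor = SNV mean, occupancy = all-substitution mean) and `snv_both`.
Only single-model, single-chain files — the AlphaFold monomer convention —
are accepted.

## The synthetic cohort generator

The generator emulates the *shape* of the real inputs, not their content:

- residues get a uniformly sampled sense codon, so sequences have a
  genetic-code-induced composition and each residue's score records cover
  exactly the SNV-reachable alternates of its codon (all 19 alternates in
  `all_substitutions` mode);
- a fraction φ of residues (default 0.3, consistent with the observation
  that roughly a third of possible missense variants are predicted
  pathogenic) is functionally critical; substitutions there are pathogenic
  in truth, all others benign;
- scores are drawn per truth class from Beta components (default
  Beta(2, 8) benign / Beta(8, 2) pathogenic, bounded support matching
  [0, 1] scores) or from Gaussians truncated to [0, 1] — the Gaussian
  model exists because it admits the closed-form AUC
  Φ((μ_p − μ_b)/√(σ_b² + σ_p²));
- clinical labels equal the truth with probability κ (default 0.9), with
  review stars drawn from a fixed distribution concentrated on 1–2 stars,
  mirroring the long tail of single-submitter clinical records;
- TM-like segments of 21 residues (a canonical membrane-spanning helix)
  are placed in half the proteins; disordered stretches get pLDDT ~
  Uniform(20, 49) against Uniform(60, 95) elsewhere, so the pLDDT-50
  filter has real work to do;
- structures are CA traces on an ideal helical path with pLDDT in the
  B-factor column.

All randomness flows from one `set.seed()` call at the top of
`generate_cohort()`; identical seeds give byte-identical cohorts.

What the generator does *not* emulate: mutational spectra and codon usage
bias, ascertainment bias in clinical databases, per-protein score
correlation structure, and any dependence of scores on the substitution
pair. Consequences worth knowing: passing parameter-recovery tests shows
the *pipeline arithmetic* is right, not that any predictor is good; and
the synthetic BLOSUM62 correlation is flat by construction, so the
strongly negative correlation seen on real predictor output is a property
of the data, not of this code.

**Truncation and the AUC oracle.** The closed form ignores the [0, 1]
truncation. Numerical integration of the truncated model at the default
recovery settings (μ = 0.2/0.8, σ = 0.15) puts the true AUC about 5 × 10⁻⁴
below the closed form — an order of magnitude inside the three-standard-
error acceptance band at the cohort sizes used — so the closed form serves
as the oracle unchanged.

## Input conventions

Positions are 1-based everywhere, matching protein-variant notation
(`F508C`); there is no 0-based interface. Clinical significance text maps
"Likely benign"/"Likely pathogenic" into the binary labels (the merge is
configurable via `label_map`); unmappable significances are dropped *and
counted*, never silently. Review status maps to stars by the standard
convention (practice guideline = 4, expert panel = 3, multiple concordant
submitters = 2, single submitter or conflicting = 1, no assertion = 0),
shipped as an overridable table since clinical exports restate the text,
not the stars. Duplicate clinical rows for one substitution keep the
highest star count. The genomic columns of proteome-scale score tables are
carried through with a `genome_` prefix and never interpreted.

## Problem sizes

The test suite and acceptance script run entirely on generated data:
cohorts of 3–40 proteins of 40–400 residues. The parameter-recovery check
uses 40 proteins of 200–400 residues at a 25 % clinical sampling rate,
giving roughly 3,000 joined variants — enough that the Hanley–McNeil
standard error of the AUC is ~10⁻³ and the three-standard-error band is a
meaningful test. Property-style checks (AUC pair-counting oracle,
confusion-metric formula oracle, codon enumeration) use inputs of ≤ 400
records, where brute force is exact and fast. The full suite completes in
well under a minute.

## Known limitations

- Whole-proteome statistics (full benchmark tables across real protein
  groups, the negative BLOSUM62 correlation, per-region structure means of
  a real protein) require the external score and clinical downloads; the
  readers accept those file dialects, but no test depends on the
  downloads.
- Accession mapping between genomic and protein namespaces is out of
  scope: all inputs must already be keyed by a common accession.
- No mmCIF output, no multi-chain structures, no calibration or threshold
  re-optimisation, and no confidence intervals on metrics — point
  estimates only.
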