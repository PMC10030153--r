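---
title: "Curating and quantifying the cell-surface N-glycoproteome"
author: "glycoCSC"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Curating and quantifying the cell-surface N-glycoproteome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glycoCSC)
```

# The evidence model

Cell-surface capture (CSC) chemistry tags oxidized glycans on intact cells,
so only proteins with extracellular glycosylated residues are enriched.
Enzymatic deglycosylation converts each glycosylated asparagine to
aspartate, a +0.98402 Da deamidation. The package treats a deamidated N
inside the N-glycosylation sequon N-X-S/T (X ≠ P) — the *sequence consensus
motif*, SCM — as the atomic unit of surface evidence, and everything else
as bookkeeping around it:

1. map each PSM's deamidated N to protein coordinates and test the sequon
   **in protein context** (the two residues after the N are read from the
   protein, so a sequon truncated by the peptide's C-terminus still counts);
2. resolve master proteins by peptide uniqueness;
3. score each protein's in-silico detectability (below);
4. classify: surface ⇔ detectability score > 0, or score 0 with
   surface-prediction consensus (SPC) 3–4, or score 0 with a predicted
   signal peptide. The reported branch is the first clause that fires; the
   order affects only the recorded rationale, never the verdict.

The rationale for the two rescue clauses: a score of 0 says no
extracellular sequon peptide of the protein is MS-detectable, so its
presence in the enriched fraction is suspicious — unless topology
prediction failed (transmembrane-helix predictors misclassify a few percent
of helices; SPC 3–4 restores confidence) or the protein is secreted (signal
peptide, no membrane anchor).

## Detectability scoring

The per-protein score counts distinct tryptic peptides that (a) contain at
least one sequon whose N lies in a region called extracellular by **at
least one** predictor and (b) have length ≥ 6 with a 2+ or 3+ charge-state
m/z below 2,000. Choices behind this:

* **Cleavage rule.** Combined trypsin/Lys-C: cleave after every K
  (Lys-C ignores the proline rule) and after R unless followed by P.
  Missed cleavages default to 0 (configurable 0–2): each extra level only
  adds concatenations of adjacent fully cleaved peptides, so the score is
  monotone in this setting.
* **"More than five amino acids"** is read strictly as length ≥ 6. There
  is no lower m/z bound; only the 2,000 upper bound is applied, and since
  m/z at 3+ is always below m/z at 2+ for the same mass, the 3+ value is
  the binding constraint.
* **Predictor union.** Topology calls from multiple predictors are merged
  by union. Predictors disagree on real proteins; requiring consensus
  would silently discard genuine surface proteins, which is the worse
  error for a curation tool whose downstream filter is evidence-based
  anyway.
* **Secreted proteins.** A protein with a signal peptide and no
  transmembrane segment exposes its whole mature chain (from the end of
  the annotated signal peptide, or position 1 if only a boolean call
  exists).
* **Unknown residues.** X carries no mass and matches no motif position;
  a sequon window containing X never fires (conservative calling), and a
  peptide containing X is simply not mass-computable.
* **Constants.** Monoisotopic residue masses from standard atomic masses;
  water 18.010565 Da; proton 1.007276 Da; carbamidomethyl-C +57.02146 Da
  applied as the default fixed modification; deamidation +0.98402 Da.
* **Missing annotation is worst case**: no topology and no signal peptide
  means zero extracellular residues and score 0; proteins absent from the
  surface-prediction table get SPC 0 and no signal-peptide call.

Open points resolved as package decisions: the SPC score is treated as an
opaque 0–4 integer (its backing resources are not modelled); the sequon's
N itself must fall inside the extracellular region (not merely any motif
residue); the signal-peptide criterion is "any of the three predictors"
by default, with a majority-of-three option.

## PSM parsing and master proteins

Deamidation is recognized by modification name (case-insensitive match on
"deamid") **or** by a delta within ±0.01 Da of +0.98402 on an N — search
engines differ in how they spell modifications, and the delta route makes
the generic dialect robust. Peptides mapping to several positions of one
protein contribute evidence at every position, flagged ambiguous.

Master resolution groups proteins by the observed peptides their sequences
can explain (whole-database subsequence search; I and L are distinct
residues unless the I=L option is set). Identical peptide sets collapse to
one group represented by the lexicographically smallest accession; groups
without a unique peptide are folded into the master sharing the most
peptides. Capture specificity is reported over PSMs and over master
proteins only — grouped accessions are not counted in either denominator,
since they are not independent identifications.

## Orientation from glycosite parity

N-glycosylation happens in the ER lumen, topologically equivalent to the
extracellular space, so an observed glycosite pins its loop to the outside.
Numbering the inter-segment loops 0 (N-terminal side), 1, 2, … across the
sorted transmembrane segments, a glycosite in an even loop implies N-out,
an odd loop N-in. Sites on both parities are topologically impossible and
yield a conflict verdict; sites falling inside a transmembrane segment are
excluded from the vote and reported. The inference assumes the segment
annotation is complete — a missed membrane pass flips the parity of
everything downstream, which is exactly the failure mode the conflict
status is meant to surface.

# Marker scoring

Scores combine up to three components in [0, 1], multiplied:

* **Gini dispersion** across groups, population form
  \(G = \sum_i \sum_j |x_i - x_j| / (2 n^2 \bar x)\) — no sample-size
  correction, so the one-hot closed form \((n-1)/n\) is exact and the test
  values are rational numbers. Scale-invariant by construction.
* **Signal strength** `min(log2(1 + max(x)), cap) / cap` with a default
  cap of 30 log2 units, saturating around raw intensities of 1e9 — the
  upper end of typical Orbitrap precursor areas. The published tool this
  mirrors does not print its scaling constants, so the cap is exposed as a
  parameter.
* **SPC/4** — included in the full score, omitted by the "omni" variant so
  unannotated proteins are not structurally excluded from ranking.

Ranking is descending with ties broken by accession, making output order
deterministic. Group-restricted candidates must be present in the target
group, absent from every other group, and absent from every supplied
external catalog; isoform suffixes are stripped by default so catalogs in
different namespaces can be compared.

# Quantification

The workflow follows the standard label-free chain: elementwise log2
(non-positive intensities become missing, with a count), equalize-median
normalization (each run shifted so all run medians equal the median of the
original run medians — a pure shift that preserves within-run structure),
per-protein Tukey median polish (tolerance 1e-6, at most 100 iterations,
missing entries ignored; the run summary is overall + column effect;
even-length medians use the midpoint convention throughout), and an
equal-variance two-sample t-test on the run summaries with
Benjamini–Hochberg adjustment.

Significance defaults to |log2 FC| ≥ 1.5 **and** adjusted p < 0.05. The
fold-change wording is ambiguous between the log2 and the raw-ratio scale
in common usage; the log2 reading is the default here because volcano-plot
conventions draw the cut at log2 FC = ±1.5, and a ratio-scale mode
(`fcScale = "ratio"`, i.e. |log2 FC| ≥ log2 1.5) is available. The
t-test is a deliberate simplification of the mixed linear models some
quantification packages fit; with run-level summaries and a two-group
design the two coincide up to variance pooling, and the equal-variance form
keeps the null behaviour analytically checkable.

## Censored imputation

Below-detection-limit missingness is left-censored, not missing at random.
Per protein, a gaussian accelerated failure time (AFT) regression on the
log2 scale — feature and run covariates — is fitted with each missing entry
entered as left-censored at its feature's threshold (the feature's minimum
observed value, the conservative and configurable choice). Censored cells
are replaced by model predictions truncated at the threshold, so an imputed
value can never exceed what the censoring admits. Numerical safeguards:

* if a run has **no** observed value in a protein block, its AFT
  coefficient is unbounded below (only censored terms mention it); the run
  covariate is dropped for that block and the feature model plus truncation
  carry the imputation;
* model formulas degrade gracefully (feature+run → feature → run →
  intercept) when a fit fails or produces non-finite coefficients;
* proteins with fewer than two observed values are left untouched and
  reported, and a complete matrix is returned unchanged.

# The synthetic fixtures

The generators exist so every stage is testable with known truth and no
raw-data downloads.

**Proteomes.** Sequences are weighted random draws over the 19 non-N
residues, with asparagine admitted only where the design wants sequons:
surface proteins of the "detectability" branch carry one planted tryptic
peptide (length 8, sequon at its third residue, C-terminal K, preceded by
K) inside an extracellular region; branch mixture 60% detectability / 25%
SPC-consensus / 15% signal-peptide; non-surface proteins get no
extracellular exposure, SPC ≤ 2 and no signal-peptide call. This makes the
classifier's expected output exact by construction — the point of the
fixture — at the price of unrealistic sequence composition.

**PSM tables.** A binomial fraction (the requested specificity) of PSMs
are deamidated at a planted sequon; the rest are background tryptic
peptides, a configurable fraction of which carry a spurious deamidation on
an N verified *not* to sit in a sequon, so the motif check is exercised by
negatives as well.

**Intensity matrices.** log2 intensities are protein mean (N(20, 2)) +
feature offset (N(0, 1)) + run shift (N(0, 0.5), so normalization has real
work) + group effect (±effect for the differential fraction, random sign)
+ N(0, σ) noise; defaults mirror a two-condition comparison with three and
four biological replicates, 10% differential proteins at |log2 effect| 2
and σ = 0.3. Left-censoring removes entries below each feature's 15%
quantile by default. Note an intentional consequence of this design:
because run shifts are shared across all features, the per-feature
quantile censoring concentrates missingness in the lowest-shifted run
(which can lose most of its entries) — a hard but informative regime for
the normalization and imputation steps.

What the simulations do **not** emulate: glycan heterogeneity, retention
time and spectral properties, search-engine identification errors and FDR,
shared-peptide-rich homology structure, intensity-dependent (MAR)
missingness mixed with censoring, and natural sequence composition.
Passing tests therefore demonstrate correctness of the algorithms under
their stated models, not performance on any particular instrument or
organism.

# Problem sizes and determinism

The validation suite runs the digestion oracle on 1,000 random sequences
(lengths 10–2,000), the detectability closed form on 1,000 peptides,
specificity on 10,000 simulated PSMs, differential recovery on 500
proteins (with a 1,000-protein null), imputation on 200 proteins, and the
end-to-end pipeline on a 100-protein bundle — sizes at which every
statistical check has narrow sampling error while the suite stays quick to
run. All generators are pure functions of their parameters and a seed;
the pipeline writes no timestamps into tables, so repeated runs under the
same inputs are byte-identical, and the provenance header records the
package version and a configuration hash instead.

# Known limitations

* Classification consumes external topology/SPC/signal-peptide calls; it
  is only as good as those inputs, and the worst-case defaults mean
  un-annotated proteins can only be rescued by the evidence-based branches.
* Protein-level specificity counts masters only; pipelines that count
  grouped accessions will report different denominators.
* The AFT imputation is per-protein and assumes gaussian log2 errors; very
  sparse blocks fall back to progressively simpler models.
* Orientation inference presumes strict side alternation and a complete
  transmembrane annotation.
* The t-test requires at least two summarized runs per group; proteins
  quantified in fewer runs get NA p-values and are never flagged
  significant.
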