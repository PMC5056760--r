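---
title: "Predicting m6A sites with m6Ascan: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting m6A sites with m6Ascan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(m6Ascan)
```

## The problem

N6-methyladenosine is deposited co- and post-transcriptionally on adenosines
that sit, almost always, in the DRACH consensus (D = A/G/U, R = A/G, the
methylated A, C, H = A/C/U). Only a small minority of DRACH adenosines are
methylated, so the consensus alone is nearly uninformative: a predictor has
to separate methylated from unmethylated DRACH contexts using the sequence
and structural neighborhood. m6Ascan trains an RBF-kernel SVM on labeled
DRACH sites and scores every candidate in new sequence.

Two modes exist because users hold two kinds of sequence. In **mature mode**
(spliced mRNA) the transcript's ends are meaningful, so the relative
position of a site (m6A is 3'-enriched, especially near stop codons) and
the local secondary-structure context are informative, and the positional
window is short (11 nt). In **full mode** (pre-mRNA / genomic transcripts)
introns dilute positional meaning; only the two sequence features are used
with a longer 31-nt window. The mode changes the feature set and the model
applied — never how sequences are read.

## Features

Every candidate is encoded in a fixed block order, recorded in the model
file so a model can refuse a mismatched matrix:

| block | mature | full | notes |
|---|---|---|---|
| positional one-hot | 44 | 124 | A→0001, T→0010, C→0100, G→1000; N→0000 |
| 3-mer frequencies | 64 | 64 | 101-nt window, lexicographic order |
| 4-mer frequencies | 256 | 256 | same window, normalized per k |
| relative position | 1 | — | pos/(len−1) ∈ [0,1] |
| structure Z-score | 1 | — | 101-nt window vs 100 shuffles |
| total | **366** | **444** | |

Windows that overrun a transcript end are filled with the gap character
`N`: it contributes no one-hot bit, is excluded from k-mer counts and their
denominators, and cannot base-pair. Whether windows at transcript ends
should instead be clipped is not determinable from first principles; N-fill
keeps every vector the same length and treats the positional and k-mer
encoders consistently.

The relative-position denominator is `len − 1` so the first and last base
map exactly to 0 and 1. k-mers are reported as frequencies (counts divided
by the number of k-mers actually counted), so each k-block sums to one for
N-free windows and remains a distribution after N-skipping.

## Secondary structure

The structure feature asks: is this 101-nt window more stably folded than
expected for its composition? The window is folded once, then 100
mononucleotide shuffles of it are folded, and the Z-score
(MFE − mean)/sd uses the sample (n−1) sd. Stable windows give negative z.
Two degenerate-case conventions: if the shuffle MFEs are constant (e.g. a
homopolymer) z is defined as 0; requesting fewer than 2 shuffles is an
error. A dinucleotide-preserving shuffle is available behind a flag for
users who consider stacking composition part of the null; the default is
the plain permutation, the simplest reading of "shuffled".

Folding itself uses a built-in deterministic dynamic program over
pseudoknot-free structures — pair weights GC = −3, AT = −2, GU = −1
(arbitrary fixed units), hairpin loops of at least 3 unpaired bases —
verified in the tests against exhaustive structure enumeration for short
sequences. This is a Nussinov-class model, not a thermodynamic one: its MFE
values are not kcal/mol and should only be compared within a backend. The
`backend` argument accepts a function wrapping an external folder (e.g.
RNAfold); the contract is only that a fragment and its shuffles are folded
by the same backend, since the Z-score is scale-free under any monotone
energy model.

## Classifier and thresholds

Features are standardized per column (training mean/sd; constant columns
pass through) — necessary for a sane γ range given binary, frequency and
unbounded Z-score features in one kernel. The C-SVC dual is solved by SMO
with second-order working-set selection; the solver is deterministic, so a
fixed seed reproduces scores bit-identically, and the decision function at
the optimum is unique even though the SMO path depends on row order (the
tests check score agreement under permutation at a tight stopping
tolerance). The ranking score is the raw decision value: probabilities are
never needed for ROC analysis or threshold logic, and omitting a Platt fit
removes one data-dependent calibration step.

Grid search maximizes mean out-of-fold AUROC over C ∈ {2⁻⁵…2¹⁵},
γ ∈ {2⁻¹⁵…2³} (steps of ×4), ties broken toward smaller C then smaller γ —
the smallest model among equals. With standardized features the expected
squared distance between two random vectors is ≈ 2p (p = feature count), so
informative γ values sit near 1/(2p) ≈ 2⁻¹⁰; the compact grids used in the
package's own tests bracket that value.

Stringency levels are decision-score cutoffs calibrated to target
specificities (mature 90.0/85.2/80.0 %, full 93.0/88.0/83.0 %): for each
target the smallest threshold whose empirical specificity on the
calibration negatives reaches the target, reported with the specificity
achieved. By default the calibration negatives are the training negatives.
This default has a known failure mode that users should understand: a
strongly-fit RBF model pushes its own training negatives below the margin,
while unseen sequence concentrates near the decision-offset plateau, so
thresholds calibrated in-sample can pass nearly everything out-of-sample.
`train_predictor(calibration_sites = ...)` calibrates on a held-out split
instead, and the test suite demonstrates that this recovers the target
specificities on independent data. Threshold nesting (high ⊆ moderate ⊆
low) holds by construction for any calibration set.

## Datasets and evaluation

Negative sites are DRACH adenosines sampled uniformly after excluding known
positives and any supplied exclusion intervals (e.g. curated methylation
peaks, since a "negative" inside a peak is likely mislabeled). Site
identity is (transcript, position); duplicates collapse; train/test
disjointness is asserted at every build. Training sets are balanced 1:1;
independent test sets keep a 1:10 positive:negative ratio mirroring the
true scarcity of methylated DRACH sites, which is why AUPR — far more
sensitive to false positives at low prevalence — is reported beside AUROC.

AUROC is computed by the rank statistic with half-credit for ties (equal to
the trapezoidal area under the empirical ROC); AUPR by step-wise,
non-interpolated summation. Cross-validation is stratified; the scaler and
any grid search are refit inside each training fold, and out-of-fold scores
are pooled into one curve rather than averaging per-fold areas, which is
more stable at modest fold sizes. The default is 5 folds, adjustable by
argument/flag.

## Peaks

MeRIP-seq reports 100–200-nt peaks, not sites. `assign_peak_sites()` takes
a 200-nt window centered on the peak summit (interval midpoint when no
summit is recorded — the natural fallback), drops peaks with no DRACH
candidate, scores the rest in mature mode at the moderate level by default,
and summarizes the fraction of peaks with ≥1 and ≥2 predicted sites. When
only peak sequence is available, relative position and structure are
computed on the window's own coordinates; the output flags this
(`context = "peak_window"`) because those two features are then
approximations of their transcript-level values.

## The synthetic world

The generator exists so every stage is testable offline; its defaults are a
stated world, chosen once. 200 transcripts of 300–1500 nt, uniform base
composition; three planted sites per transcript on average (mammalian
mRNAs carry 3–5 m6A sites on average); placement drawn from Beta(1+b, 1)
on the eligible range with b = 1 (mean relative position 2/3, emulating 3'
enrichment); at least 50 nt between planted sites so truth labels never
share a feature window. Each planted site writes an 11-nt context drawn
from a per-position categorical profile (a PWM — the generative counterpart
of the positional one-hot feature) whose center is always DRACH-conformant;
`profile_strength` interpolates between background flanks with a uniform
DRACH center (0, no learnable signal) and a concentrated GGACT-consensus
profile (1). An optional structure signal writes an 8-nt complementary stem
around a fraction of sites so their windows fold more stably than shuffled
background.

What a green end-to-end test does establish: the scanner, encoder, solver,
calibration and evaluation compose correctly, recover a strong planted
signal (held-out AUROC > 0.85 at the default strength) and find nothing in
a signal-free world (AUROC ≈ 0.5). What it does not establish: performance
on real miCLIP-derived data, whose motif context, positional bias and
structure are far richer than a PWM — the published performance numbers of
sequence-based m6A predictors cannot be checked from a synthetic world, and
the package does not claim them.

## Numerical choices and limitations

* SMO stopping tolerance 1e-3 (the libsvm convention); scores agree across
  row orders to about the same tolerance, tightening as eps shrinks.
* MCC is defined as 0 when any confusion-matrix margin is empty; its
  products are computed in double precision (integer counts overflow at
  test sizes above ~46k).
* Model files are JSON with all decision-relevant doubles stored as
  `%.17g` strings, because standard JSON number printing at 15 significant
  digits does not round-trip doubles bit-identically.
* Thresholds between tied negative scores fall at the midpoint to the next
  distinct score; with a 100% target the threshold sits just above the
  maximum negative.
* CV folds with a single class are skipped with a warning during grid
  search (error if all folds degenerate); k greater than a class count is
  an error.
* Candidates whose 5-mer would overrun a transcript end are never emitted,
  on either label side; IUPAC ambiguity codes become `N` and suppress any
  candidate whose motif touches them.
* The built-in folder ignores temperature, loop-length penalties and
  stacking; it is a structure-strength proxy adequate for a Z-score, not a
  thermodynamic predictor.
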