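---
title: "Predicting copy-number alterations from expression profiles: model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting copy-number alterations from expression profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hmmCNA)
```

## The problem

DNA copy-number alterations (CNAs) — chromosomal gains and losses — are a
central mutational mechanism in cancer, and they leave a transcriptional
footprint: genes inside a gained region tend to be over-expressed, genes
inside a lost region under-expressed (the dosage effect).  Expression
microarray data exist for far more tumors than genome-wide CGH does.
`hmmCNA` exploits cohorts where both measurements exist on the same
samples: it learns the statistical coupling between discretized
expression and CGH state, then predicts gains and losses for samples with
expression alone.

This vignette is the package's own account of the model, the tunable
parameters, the numerical choices, what the synthetic data generator does
and does not emulate, and the design decisions that were genuinely open.

## Model structure

Expression is reduced per probe to a three-letter alphabet H/L/M by a
fold-change cut against the probe's cohort median (`fold_threshold`,
default 1.5, unitless ratio).  CGH truth is reduced to per-probe labels
+/−/o by projecting gain/loss segments onto probes; when segments arrive
as tumor/normal signal ratios they are thresholded at `gain_ratio` (1.25)
and `loss_ratio` (0.75).  These defaults are the standard operating
points for median-normalized expression arrays and metaphase-CGH ratio
profiles; all are configurable through `discretization_config()`.

Each chromosome receives its own hidden Markov model over the nine
composite states (symbol, label) ∈ {H,L,M} × {+,−,o}, in the canonical
order H+, L+, M+, H−, L−, M−, Ho, Lo, Mo.  The composite construction
makes the coupling between expression and copy number a property of the
*state space*: a state deterministically emits its own symbol, so the
emission matrix is structurally degenerate.  Three consequences follow.

* **Training is fully supervised.**  Superimposing observed symbols on
  known labels yields complete state paths, so transitions and initial
  probabilities are closed-form maximum-likelihood counts.  No
  expectation-maximization (Baum–Welch) is used anywhere: with 81
  transition parameters per chromosome and a single observation per
  probe position, iterative re-estimation of both states and parameters
  is poorly constrained, and paired training data make it unnecessary.
* **The emission matrix is never estimated.**  The emission MLE on
  superimposed paths is identically the degenerate matrix, and
  hard-coding it avoids 0/0 rows for states absent from training.
* **Decoding is cheap.**  At each position only the three states
  compatible with the observed symbol are reachable, and the posterior
  marginal of a CNA label equals the posterior of the single compatible
  composite state — so thresholding composite-state posteriors and
  label marginals coincide, and no separate choice between them arises.

Probes are treated as a pure sequence: inter-probe distances do not
enter the transition model, and probes are the atomic unit (no
within-gene averaging).  Chromosomes never share parameters; decoding
never crosses a chromosome boundary.

## Tunable parameters

| parameter | default | units | role |
|---|---|---|---|
| `fold_threshold` | 1.5 | ratio | H/L/M cut against the probe's cohort median |
| `gain_ratio`, `loss_ratio` | 1.25, 0.75 | ratio | CGH segment thresholds |
| `pseudocount` | 0.5 | counts | additive smoothing of transition/initial MLE |
| `cutoff` (posterior) | 0.5 | probability | marginal threshold for posterior calls, in [0.5, 1] |
| `lod_cutoff` | 2 | log10 odds | cytoband call threshold |
| `n_perm` | 1000 | — | permutations in the association test |
| `min_aberrant` | 3 | samples | LOOCV warning threshold for sparse training signal |

The pseudocount exists because a cohort never exhibits all 81
transitions; without smoothing, an unseen transition makes every
compatible path of a new sample impossible (−∞ log probability).  One
half — Jeffreys-style additive smoothing — perturbs well-estimated rows
negligibly while keeping all paths decodable; `pseudocount = 0`
reproduces the raw MLE and is used in the parameter-recovery tests.

## Smoothing, baselines, and validation

Cytoband-level calls use a multinomial likelihood-ratio score: with
label counts `n = (n_+, n_−, n_o)` on a cytoband and `N` genome-wide in
the same sample, `LOD = Σ_j n_j log10((n_j/n)/(N_j/N))`, with the
`0·log(·) = 0` convention; multinomial coefficients cancel between the
two hypotheses and are omitted.  The score is a likelihood ratio against
the sample's own genome background (not a cohort-pooled background), so a
sample with many alterations needs a proportionally stronger local
enrichment.  Because the alternative is the MLE on the same counts,
LOD ≥ 0 always, with equality exactly at background proportions.  The
alternative hypothesis is omnibus ("this cytoband is aberrant"), so a
direction must be attached separately: the majority aberrant probe label
decides it, and an exact tie yields no call — the conservative reading.
A cytoband call is single-valued; a region harboring both a gain and a
loss at segment resolution will show as one call or none at cytoband
resolution.

Two comparators calibrate how much the HMM adds: `rgep` maps symbols to
labels directly (H→+, L→−, M→o) and `sgep` applies LOD smoothing on top
of `rgep`.  Leave-one-out cross-validation drives all three through the
same folds.  Two leakage controls matter: per-probe reference medians
are recomputed on each fold's training cohort, and the held-out sample
is symbolized against those training medians.  Metrics come from
one-vs-rest contingency tables per label (gain, loss), reported per
chromosome and genome-wide; because the natural averaging unit is
ambiguous, both fold-averaged (mean ± sd across held-out samples) and
pooled (counts summed over folds, then metrics) versions are reported.
A metric with an empty denominator (e.g. sensitivity on a chromosome
with no true aberration) is marked undefined and excluded from
averaging rather than imputed as zero.

## The association test

For a recurrent predicted abnormality, the test asks whether samples
harboring it shift expression of the region's genes in the dosage
direction.  Per probe, a one-sided two-sample t-test compares aberrant
vs wild-type samples (aberrant > wild-type for gains, < for losses); the
region statistic is the sum of natural-log p-values; group labels are
permuted preserving group sizes; the empirical p-value is
`(1 + #{perm ≤ obs}) / (n_perm + 1)`.  Three choices were open:

* **Welch by default.**  The unequal-variance t-test is the robust
  default for expression group comparisons; `var_equal = TRUE` restores
  the pooled-variance form.
* **Add-one correction.**  The permutation p-value can never be exactly
  zero, which keeps it valid at finite `n_perm`.
* **Two-group permutation.**  Only the analysed groups (aberrant,
  wild-type) are permuted; samples carrying both a gain and a loss in
  the region are marked `excluded` and touch neither the statistic nor
  the permutations.

The base of the log only scales the statistic monotonically, so the
empirical p-value is base-invariant (asserted in the tests).  Probes
with zero variance in both groups are uninformative and get p = 1.

## Numerical choices and tie-breaks

* All decoding runs in natural-log space; forward–backward uses
  per-position scaling, and the row-normalization of the smoothed
  posteriors is checked against 1 at 1e−9.
* Viterbi ties break toward the earliest state in canonical order, so
  decoded paths are identical across platforms.
* All discretization inequalities are strict; boundary values (a ratio
  of exactly 1.5, 1.25 or 0.75; a posterior of exactly the cutoff is
  called, but a 0.5/0.5 gain/loss tie at cutoff 0.5) resolve to the
  neutral class.
* Segment-to-probe projection uses midpoint containment: a probe gets a
  segment's label iff its midpoint lies inside the segment.  Where
  opposite-label segments both contain the midpoint, the larger
  base-pair overlap with the probe wins and an exact tie gives `o`.
  Midpoint containment was chosen over any-overlap because a probe is
  the atomic unit: it receives exactly one label, with no partial
  credit.
* Chromosome exclusion lists (small or sex chromosomes are commonly
  dropped in CGH studies for technical reasons) are a configuration
  choice (`--exclude-chrom`), default empty: the method itself is
  agnostic.
* Model files serialize probabilities with `%.17g`, so
  `read_model(write_model(m))` reproduces `m` bit for bit.

## The synthetic cohort generator

`simulate_cohort()` emulates the paired-data regime the model is built
for: a genome of several chromosomes partitioned into equal cytobands;
recurrent hotspots, each independently present per sample with a
configured population frequency, realized as one segment whose ends
jitter uniformly by up to half a cytoband; and linear-scale expression
`baseline × dosage × noise`, where the dosage factor (default 2, i.e.
one extra copy of a diploid locus; reciprocal under loss) applies to a
probe inside a CNA with probability `concordance` (default 0.7), and
noise is multiplicative log-normal (`noise_sd` 0.25 on the natural-log
scale).  Baselines are log-normal with median 100.  The default genome —
six chromosomes × 120 probes, eight cytobands each — carries gains on
chr1 (30%) and chr3 (20%) and losses on chr5 (25%) and chr6 (15%).
These frequencies and effect sizes are this package's choices for a
realistic recurrent-CNA regime in a lymphoid tumor cohort; they are not
measurements of any real dataset.

What the generator does **not** emulate: copy-neutral events that mimic
dosage signatures (uniparental disomy), epigenetic silencing, tumor
purity dilution, correlated probe-level array artifacts, distance
dependence of breakpoints, or focal amplifications at sub-cytoband
scale.  Passing tests on synthetic cohorts therefore demonstrate the
correctness of the machinery and the qualitative ordering of methods
under a dosage-effect regime; they do not certify performance numbers on
real tumor data, where concordance is weaker and noise is structured.

One degeneracy is worth knowing about: the fold-change reference is the
cohort median, so a locus aberrant in about half the cohort or more
pulls the median toward the aberrant level and the discretization loses
the contrast.  That is a property of median-referenced discretization in
general, not of the generator; hotspot frequencies in the defaults stay
well below that regime.

## Problem sizes

The test suite decodes sequences up to length 8 against exhaustive
3^n-path enumeration (100 random instances at tolerance 1e−10), recovers
transition matrices from 200 sampled paths of length 500 (max error
< 0.02), cross-validates the default 100-sample, 720-probe cohort, and
calibrates the permutation test with 200 null replicates of 200
permutations each.  The acceptance script repeats these end to end;
every random quantity derives from a single `--seed`.

## Known limitations

* Training needs every (chromosome, label) combination it will predict
  to be reasonably represented; the LOOCV report flags combinations
  with fewer than `min_aberrant` aberrant training samples, where
  sensitivity estimates are unstable.
* The per-chromosome homogeneous transition matrix cannot express
  position-specific breakpoint preferences within a chromosome.
* Cytoband calls inherit whatever cytoband granularity the annotation
  provides; no sub-band refinement is attempted.
* The three-level discretization discards magnitude information by
  design; probes whose dosage response is below the fold threshold are
  invisible to the model.
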