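---
title: "Scoring regulatory activity from chromatin marks: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring regulatory activity from chromatin marks: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chromscore)
```

This vignette is the package's own account of its models: what is being
estimated, under which assumptions, which knobs matter, and where we made
design decisions that the underlying methodology leaves open.

## The problem

Functional characterization assays measure whether a genomic sequence can
drive transcription: plasmid-based reporter assays (MPRA, STARR-seq,
HiDRA) test sequences episomally, CRISPRi screens perturb elements in
their native context and read out target-gene expression. Each assay
covers a small, biased portion of the genome in one cell type, with its
own readout scale. Chromatin-mark data (signal tracks, peak calls,
chromatin-state segmentations), in contrast, are available uniformly
across the genome and across many cell types. The package's premise is to
learn, per assay dataset, the mapping from local chromatin configuration
to assay-measured activating potential, and then to evaluate that mapping
anywhere — including cell types with no characterization data at all.

Everything operates on a fixed 25 bp bin grid: position `p` belongs to bin
`floor(p / 25)`, and a bin's representative position is its center (13th)
nucleotide, `25 * i + 12`. Coordinates are 0-based half-open throughout;
the only place 1-based arithmetic occurs is on wiggle fixedStep input,
which is converted on read.

## Label harmonization

Each dataset family has a labeling rule that reduces its native readout to
binary activating/neutral labels at a single reference nucleotide — the
base judged most representative of the region's activity:

* **Tiled MPRA with per-5 bp activity scores** (`label_sharpr()`): a
  region's summary score is the signed value at the position of maximum
  absolute score. Above +1 is activating; within the closed band [−1, 1]
  neutral; below −1 the region is dropped as likely repressive, since
  repressive regulation is outside the binary task. The reference
  nucleotide is the center base of the extremal 5 bp interval. The
  source methodology's wording on the sign convention is ambiguous (an
  absolute-value reading would make the sub-−1 filter vacuous); we
  implement the signed-extremum reading, which makes the filter
  meaningful, and break ties by first position.
* **Construct p-values** (`label_by_pvalue()`): activating strictly below
  α = 0.05, reference nucleotide at the construct center.
* **Peak scores** (`label_top_fraction()`, `label_threshold_peaks()`):
  activating for the top `ceiling(f * N)` peaks by score (f = 10% by
  default) or strictly above a fixed readout cutoff (fold-enrichment > 4,
  RNA/DNA ratio > 1). Boundary ties are included — inclusive behavior is
  stable under small score jitter. Neutral backgrounds are sampled
  uniformly from the genome (3 per activating region), rejecting excluded
  regions, optionally restricted to an assay's tiled universe.
* **CRISPRi element–gene records** (`label_crispr_elements()`): an element
  is activating if any surviving record is significant (adjusted p < 0.05).
  Records are filtered to negative expression effects (and non-outliers,
  or records with ≥ 80% power to detect a 25% effect, depending on the
  dataset family); elements left with no surviving records are labeled
  neutral in the first family and dropped in the second, following each
  family's published filtering.

Threshold strictness follows the wording of each rule ("exceeding",
"under", "above", "below"); where tie handling at a threshold is not
specified we use strict inequalities and say so here rather than in the
code. "Center" of an even-length interval is `start + floor(length / 2)`,
applied uniformly.

## Features

Per reference nucleotide and mark, the signal in a 2 kb window is sampled
at 25 bp offsets (−1000, …, 0, …, +1000), giving 81 values per mark and
972 intermediate features for 12 marks. Off-chromosome offsets read 0,
matching the zero-fill contract of the track reader. Per mark, a PCA
fitted on the training rows (mean-centered, unscaled) reduces the 81
window values to 3 components; the raw center value is kept, so each mark
contributes 4 signal features. With a per-mark peak indicator and a one-hot
encoding of a K-state chromatin annotation, the matrix has `5M + K`
columns — 85 for 12 marks and 25 states, in a frozen, named order.

Design decisions here: the PCA centers but does not scale, because the
whole assembled matrix is standardized afterwards (training-partition
means and variances; binary and one-hot columns included; zero-variance
columns are flagged and map to 0). PCA loading signs are fixed by making
each component's largest-magnitude entry positive so fits are reproducible
across linear-algebra backends. No transform is ever fitted on test rows;
the evaluation functions refit PCA and standardizer per training
partition, and a test asserts that held-out rows are transformed with
training moments.

## Expert ensembles

Each dataset's expert is a bagging ensemble of 100 binary logistic
regressions with an L2 penalty (regularization strength C = 1), each
member fitted on a bootstrap resample of the training set (with
replacement, original size). Per-sample class weights implement
w(activating) = n_neutral and w(neutral) = 3·n_activating, which fixes the
weighted activating share at exactly 1/4 for any label counts — an
intentional tilt away from balance so scores highlight high-potential
regions. The members are fitted by a damped Newton (IRLS) solver
minimizing the weighted penalized negative log-likelihood with an
unpenalized intercept (convergence tolerance 1e-6 on the coefficient
change, 1000-iteration cap); a member that fails to converge is refit once
on a fresh resample and flagged. The solver is cross-checked in the tests
against an independent general-purpose optimizer on the same objective.
The ensemble score is the mean of member probabilities — the aggregation
rule is our decision; probability averaging (rather than vote counting) is
what makes the bagged score a usable activity probability.

Evaluation schemes:

* **Within-dataset** — 20 random stratified 4:1 train/test partitions;
  the whole pipeline (PCA, standardizer, ensemble) refits per partition;
  single-class test draws are redrawn with a logged message.
* **Cell-type holdout** — experts are trained on all datasets outside the
  held-out cell type and averaged (the combined score restricted to the
  surviving experts) on the held-out datasets' loci. Train and test loci
  are separated spatially: the genome is cut into 5 kb chunks, each
  assigned to testing with probability 0.25, and a locus inherits its
  chunk's assignment, which prevents leakage between overlapping feature
  windows. 20 repetitions redraw the partition.
* **Baselines** — a single mark's signal value used directly as a score,
  and a chromatin-state baseline mapping each state to its training
  activating fraction (unseen states fall back to the global fraction).

## Genome-wide scores

`score_genome()` evaluates an expert at every bin center; `chromscore()`
averages expert tracks per bin. Quantile normalization makes expert score
distributions comparable: scores are computed at a large uniform sample of
non-excluded positions (configurable `n_sample`; the method's reference
configuration uses 10 million, our desk-scale tests use 1e4–1e5 through
the same code path), each expert's sample is sorted, the reference
distribution is the per-rank median across experts, and each expert gets
1000 equal-mass quantile bins mapped to the reference median of the bin.
Values outside an expert's sampled range clamp to the edge bins — the
reference methodology does not specify edge handling, so clamping is our
declared choice. Normalization preserves within-expert ordering up to bin
resolution and equalizes cross-expert distributions to within ~2/1000 in
Kolmogorov–Smirnov distance.

## The genome-annotation HMM

Expert tracks are binarized at the top-2% threshold: the cutoff is the
`ceiling(0.02 N)`-th largest score, bins at or above it are 1 (so tie-free
tracks mark exactly that many bins, and boundary ties are all included).
The annotation model is a K-state hidden Markov model whose state `k`
emits an M-vector of independent Bernoulli observations with parameters
`E[k, m]` — the probability that state `k` shows a top-scoring call for
expert `m`. Training uses the concatenated approach: all cell-type ×
chromosome sequences share one parameter set. The scaled forward–backward
recursions are implemented in C++ (Rcpp); Baum–Welch runs for exactly
`max_iter` iterations with no likelihood-change stopping criterion,
mirroring the reference segmentation workflow, and emissions are clamped
to [1e-6, 1 − 1e-6] to avoid log-domain degeneracies. With full-batch EM
the total log-likelihood is non-decreasing (asserted per iteration in the
tests); the optional random-subset mode (e.g. 128 sequences per iteration)
trades that guarantee for throughput on large sequence collections.

Initialization is seeded-random (uniform stochastic π and A with a
self-transition bump, emissions in (0.05, 0.95)); the reference
implementation's initializer is not documented, so ours is declared rather
than inferred. Because EM is sensitive to initialization, `fit_hmm()` runs
a small number of random restarts (default 3) and keeps the highest final
likelihood. Decoding is per-bin posterior argmax (ties to the lowest state
index), not Viterbi — the two differ, and posterior decoding matches the
reference annotation behavior. States are renumbered by decreasing mean
emission (stable under ties) and grouped by their emission pattern:
multi-expert (≥ 2 experts with E ≥ 0.20), single-expert (exactly one
expert ≥ 0.90, no other ≥ 0.10), no-expert (all < 0.001); states matching
no rule are labeled "unclassified" rather than forced into a group. The
default is K = 15 states at the 2% threshold; both are configurable (the
methodology explored K ∈ {10, 15, 25} and thresholds of 1–10%).

## Enrichment analyses

Overlap fold enrichment works in bin units: an annotation overlaps a bin
if it covers ≥ 1 bp of it, and `fold(state) = overlap fraction within the
state / genome-wide overlap fraction`. The per-state folds satisfy the
mixture identity `sum_k genome%k · fold(k) = 1`, which the tests assert to
1e-9. Undefined enrichments (empty annotation) are reported missing, never
as 0. TSS profiles sample a segmentation or track at 200 bp offsets in 24
kb windows centered on TSSs, flipping offsets for minus-strand genes so
positive offsets always point into the gene body. Expression correlations
compute per-offset Pearson r between track values and log2(RPKM + 1)
across genes, per cell type, then average over cell types; r on fewer than
3 points is missing, not 0. Repeat enrichments group sampled positions
into 200 equal-mass score quantiles (0.5% each) and compute per-quantile
overlap folds per repeat class against the sampled background. All
sampling operations take explicit seeds and honor excluded-region lists.

## The synthetic world

`make_world()` emulates the statistical structure of the real inputs:
planted elements with strengths in [0, 1] and per-cell-type activity
masks; activating marks carry Gaussian signal bumps (sd ≈ 500 bp, matching
the informative scale of the 2 kb window) at active elements over
half-normal background noise; a repressive mark is elevated at planted
repressive elements; peak calls cover active bumps; chromatin states
follow a fixed rule from the dominant local mark so the state features are
informative. `render_assay()` emits each labeler's schema with readouts
that are monotone in planted strength plus noise — at zero noise every
labeler recovers the planted truth exactly, and label accuracy degrades
monotonically with noise.

What the world does *not* emulate: sequence content (the framework is
deliberately sequence-free), correlated mark-specific background
structure, copy-number and mappability artifacts, assay-specific coverage
biases, and the scale of real genomes. Passing tests on this world
demonstrate that the pipeline's machinery is correct and leak-free — that
experts recover a planted chromatin→activity rule across cell types
(held-out AUROC > 0.9 at low noise, chance on permuted labels) — not that
any particular real-data performance level would be reached.

## Problem sizes and numerical choices

The test suite and the acceptance script run at desk scale by choice:
worlds of 1–2 chromosomes of 0.1–2 Mb, 10–200 elements, ensembles of 5–25
members in evaluation loops (the training default remains 100), HMM
recovery at T = 50,000 bins, normalization samples of 1e4–2e4. All code
paths are identical to full-scale runs; only the sizes differ, and every
size is an explicit argument. Remaining numerical conventions: uncovered
track bins read 0 (dense imputed tracks make this moot in practice;
sparse synthetic fixtures rely on it); bedGraph writers merge equal-value
runs and print doubles with `%.17g` so write/read round-trips are exact;
chromosome order follows the assembly declaration, not file order; the
per-bin emission products for up to ~12 binary tracks stay far above
double underflow, so likelihoods are computed in the scaled (not log)
domain inside the recursions.

## Known limitations

Repressive regulation is excluded by construction (dropped or diluted at
labeling time), so scores near 0 mean "no activating evidence", not
"repressed". The expert combination is an unweighted mean; locus- or
dataset-weighted combinations are deliberately out of scope. Binarization
at a global top fraction makes the HMM's input, and hence the annotation,
relative to each track's genome-wide score distribution. And the package
reads text formats only (bedGraph, wiggle fixedStep, BED, TSV); binary
track formats would slot in behind the same reader contracts but are not
implemented.
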