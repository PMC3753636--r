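---
title: "Predicting TSSs from DNA physical deformability: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting TSSs from DNA physical deformability: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prostar)
library(dplyr)
```

## The physical model

Core promoters carry a distinctive mechanical signature: the stiffness of
the double helix against its six elementary deformations — twist, tilt and
roll rotations, shift, slide and rise translations — deviates from bulk
genomic background in the kilobase around a transcription start site
(TSS). `prostar` exploits this signature to predict TSSs from sequence
alone, without motif models or CpG-content heuristics.

The model is deliberately simple. Each dinucleotide step `XY` is assigned
the six *diagonal* force constants of its stiffness matrix — the quadratic
energy coefficients for pure deformations, in kcal/(mol·deg²) for the
rotational channels and kcal/(mol·Å²) for the translational ones.
Off-diagonal (coupled) terms are intentionally ignored. Because the
diagonal stiffness of a step is identical read from either strand, a valid
parameter table must satisfy `K(XY) = K(revcomp(XY))` channel-wise;
`stiffness_table()` enforces this to 1e-9 and will complete a table given
only the 10 symmetry-unique steps.

The package ships a **synthetic** parameter table
(`default_stiffness_path()`), randomly drawn at physically plausible
magnitudes, so that every example and test is self-contained. It is a
stand-in, not a measured parameter set: analyses of real genomes should
substitute a published molecular-dynamics-derived table via
`load_stiffness_table()`, which accepts any TSV with columns
`step twist tilt roll shift slide rise`.

A sequence is annotated step by step (`step_series()`), giving a
six-channel profile of length `n - 1`. Ambiguous bases (N and other IUPAC
codes) are *masked*, not errors: genome scans must tolerate assembly gaps.
Lowercase (soft-masked) bases are ordinary bases at this stage; repeat
content matters only to the candidate filter, never to the physics.
Profiles are then averaged over 500-bp windows (`window_average()`), the
unweighted arithmetic mean of the unmasked steps a window owns. Windows
are 0-based half-open bp intervals; a window `[s, s + w)` owns steps
`s .. s + w - 2`, which keeps every interval BED-compatible. A window with
fewer than `min_valid = 0.9` of its steps unmasked is flagged invalid; the
threshold is a package choice, as is reading "linear averaging" as an
unweighted mean rather than a linear smoother.

## The comparative Mahalanobis classifier

The discriminative span is −250/+900 bp around the TSS, tiled with 500-bp
windows every 50 bp (14 windows, feature dimension D = 84; the stride and
overlap are package choices, the span and window size are the method's).
Two reference profiles are trained on feature vectors extracted at known
TSSs (`build_reference_profile()`): a *promoter* class and a *background*
class of randomly selected sequence, each summarised by its mean and
covariance. Antisense examples are reverse-complemented before
extraction, so one model serves both strands.

A candidate position `x` is scored by its Mahalanobis distance to each
class, `d_c(x) = sqrt((x - mu_c)' Sigma_c^{-1} (x - mu_c))`, and the
comparative score is

```
score(x) = d_background(x) - d_promoter(x)
```

with the label `promoter` iff `score > 0`; an exact tie is conservatively
`background`.

Numerical choices that matter:

* **Covariance shrinkage.** The 84 features are window means of heavily
  overlapping windows and are strongly correlated; with training sets of
  a few hundred examples the sample covariance is near-singular and its
  inverse amplifies sampling noise into the metric. The default ridge is
  therefore substantial — `lambda = 0.2 × trace/D`, i.e. 20% of the mean
  feature variance (floored at 1e-8 so degenerate training sets still
  invert). We verified on planted-promoter genomes that a near-zero ridge
  destroys recovery (recall drops from ~0.94 to ~0.2) while the 20% ridge
  is stable over a wide neighbourhood. `lambda` remains a parameter.
* **Diagonal fallback.** With fewer than `D + 2` usable examples a full
  covariance is not estimable; the diagonal is used, with a warning.
* **No-calls.** Candidates whose grid touches an invalid window are
  emitted as `no_call` rather than silently skipped, so masked regions
  are visible in the output.

## Genome scanning and TSS calling

`scan_genome()` slides the grid along both strands at a 50-bp stride.
Minus-strand features are obtained by mirroring window coordinates, which
is exact because the parameter table is strand-symmetric. `call_tss()`
then selects TSSs greedily: local score maxima above `tau` are visited in
decreasing score order (ties to the leftmost coordinate) and accepted
unless within `min_separation = 1200` bp of an accepted call — the same
isolation distance used to select experimentally testable candidates.

One subtlety is documented rather than hidden: because the grid span is
asymmetric (−250/+900) while the discriminative material concentrates
near the TSS, the *comparative* score peaks slightly upstream of the best
grid alignment (the background distance keeps growing as promoter-like
material is centred in the grid). Accepted peaks are therefore refined to
the minimum of `d_promoter` within 400 bp, the position where the local
profile best matches the promoter reference. With refinement the median
localisation error on synthetic plants is under one stride.

Candidate post-filters (`filter_candidates()`) reproduce the selection
rules for *de novo* candidates: at least 1200 bp from every annotated TSS
(position-to-position, strand-ignored; exactly 1200 bp passes), and at
most 70% repeat content in the 1200-bp tested region (strictly more is
rejected), read from soft-masking or an explicit mask BED. Running a
repeat masker, and PCR-primer uniqueness screens, are out of scope.

Candidate regions come in three strand-aware roles (`make_regions()`):
the −1000/+200 core-promoter window, the equivalent 1200-bp tested
region (TSS 1000 bp from the biological 5′ end), and the 2000-bp
expanded region centred on the TSS.

## Tag 5′-end profiling

Orthogonal validation asks whether independent evidence of transcription
initiation — CAGE or RNA-seq 5′-ends — piles up where the predictor put
the TSS. The pipeline is: deduplicate tags to distinct
(chromosome, position, strand) records per cell line
(`dedupe_5prime()`; removing amplification artifacts), match tags to
regions on the *same strand* only, measure the distance from the region's
biological 5′ end (plus strand: `start`; minus strand: `end - 1`, a
convention this package fixes), and accumulate counts into 100
percent-distance bins.

Bins are left-open right-closed multiples of `region_length / 100`, with
distance 0 in bin 1: `bin = max(1, ceiling(distance / w))`. This is the
single convention consistent with all three printed geometry anchors at
once — 1000 bp → bin 84 and 750 bp → bin 63 in 1200-bp regions (12-bp
bins), and 1000 bp → bin 50 in 2000-bp regions (20-bp bins):

```{r bins}
c(bin_index(1000, 1200), bin_index(750, 1200), bin_index(1000, 2000))
```

Counts are raw increments; `n_matched` and `n_regions` are carried as
attributes so per-region normalisation can be applied downstream if a
display calls for it. `relocate_tss()` shifts every region's TSS along
its own strand (default 500 bp upstream) and rebuilds the expanded
region, the operation used to test whether a tag peak sitting at bin ~25
of the 2000-bp profile re-centres onto bin 50.

## Enrichment and track statistics

TFBS enrichment uses Fisher's exact test on 2×2 incidence tables (region
set vs a background transcript list, with/without the feature). The
two-sided p is the minimum-likelihood hypergeometric summation — the
p-value is always exact — while the reported effect size is the sample
odds ratio `(a·d)/(b·c)` with Haldane's +0.5 on every cell if and only if
some cell is zero, so reported ORs are finite. Family-wise error is
controlled by Bonferroni: `alpha / m` over the `m` features tested
(0.05/885 ≈ 5.65e-5 for the full TFBS catalogue). Degenerate feature
tables are reported with NA rather than aborting the family.

Track summaries follow fixed conventions: per-base averages over a region
treat uncovered bases as zero; a cluster counts for a region when the
half-open intervals intersect in at least 1 bp; a region passes an
intensity threshold when it exceeds it in *any* cell line (reference
thresholds 10 and 50). `assign_subsets()` cross-tabulates predictor
confidence (PS±) with luciferase activity (L±, active iff strictly above
3-fold; a 10-fold cut is available as a flag) into the four canonical
subsets PS+L+ … PS−L−.

## The synthetic-data generators

Every input has a seeded generator with known truth, so the entire
pipeline is exercised without external data. What they emulate — and
what they do not — determines what a passing test means.

* `gen_stiffness_table()` draws valid, symmetric tables at plausible
  magnitudes, so no published constants are required anywhere in tests.
* `gen_genome()` draws background from a first-order Markov chain
  (AT-rich with CpG depletion, loosely mimicking bulk vertebrate
  composition) and replaces each planted −250/+900 span with structured
  sequence: a 500-bp core mixed toward a GC-rich composition and a 650-bp
  downstream tail mixed toward a CpG-enriched one. The two-segment
  structure is essential, not decorative: under a strand-symmetric
  parameter table, a compositionally homogeneous plant has a
  strand-symmetric expected profile, and no classifier could recover
  strand. First-order composition is the right resolution because the
  physics model itself is dinucleotide-level.
* **Effect size** is defined in profile space: the per-channel
  standardised distance between the expected 500-bp window-mean vectors
  of plant and background, in units of the background window-mean SD
  (estimated by a small seeded simulation). The mixing weight is solved
  by `uniroot` to hit the requested effect; requests beyond the pure
  target composition cap at weight 1 with a warning, and the achieved
  effect is recorded on the truth table. The default effect of 16 models
  strongly promoter-like plants (typical synthetic tables top out around
  9–22), so the default benchmark asks "does the method work where it
  should work", while `promoter_effect = 0` gives an exact null.
* `gen_tags()` plants a tag peak at a chosen offset plus uniform noise,
  with optional opposite-strand decoys; `gen_incidence()` draws null
  features hypergeometrically around a background rate with one inflated
  feature; `gen_track()` makes piecewise-constant signal tracks.

Not emulated: real promoter sequence content (TATA boxes, CpG islands as
such), transcription-unit structure, mappability artifacts, or any
correlation between repeats and promoters. Passing recovery tests shows
the inference machinery is correct under the stated statistical model;
it does not certify performance on real genomes with a real parameter
set.

## Problem sizes and reproducibility

The shipped tests train on 200 examples per class and scan three 80-kb
genomes with 16 plants each for the recovery benchmark (tau = 1, matches
counted within 100 bp on the correct strand), plus twenty 30-kb null
genomes for the chance-level calibration; these sizes give stable
statistics while keeping the full suite around a minute. The ±100-bp
match radius — one fifth of the averaging window — reflects the intrinsic
resolution of 500-bp window features: localisation is limited by
sequence-sampling noise of window means, not by the caller, and the
method's own field treats ~500-bp TSS displacements as re-locatable
rather than wrong. All randomness flows through explicit integer seeds;
identical seeds give byte-identical genomes, tags, tables and BED output
on any platform.

## Known limitations

* The shipped stiffness table is synthetic; scientific use requires a
  published parameter set.
* Scores of overlapping 500-bp windows are strongly correlated; the
  comparative score is a classifier, not a calibrated probability.
* `call_tss()` localisation below ~100 bp is noise-limited by design of
  the features (500-bp averages).
* The enrichment module consumes incidence tables; motif scanning and
  TFBS annotation are upstream concerns.
* Conservation and chromatin statistics summarise user-supplied tracks;
  the package computes no alignments or peak calls.
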