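---
title: "Methods: DamID LAD calling, envelope heterogeneity, and nuclear stiffness"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: DamID LAD calling, envelope heterogeneity, and nuclear stiffness}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`laminatools` implements three quantitative procedures used to characterize
nuclear-lamina organization in *Drosophila* larval muscle: a DamID-seq
pipeline that maps lamina-associated domains (LADs) and compares them
between genotypes, an image-analysis pipeline that quantifies the spatial
heterogeneity of nuclear-envelope proteins as a Distribution Index, and a
micromanipulation pipeline that estimates nuclear stiffness from
force-deformation measurements. This vignette explains each model, the
parameters that matter, the numerical choices made where the procedure
left them open, and what the synthetic-data generators do and do not
emulate.

## The DamID model

DamID fuses the *E. coli* Dam methyltransferase to Lamin Dm0; chromatin
that contacts the lamina is adenine-methylated at GATC motifs, and a
parallel sample expressing untethered Dam controls for accessibility. The
unit of signal is the **GATC fragment**: the interval between two
consecutive motifs, derived by `build_gatc_map()` as half-open
`[motif_i, motif_{i+1})` intervals. This convention makes the fragments a
partition of the span between the first and last motif; the sub-motif
stretches outside that span are not flanked by two motifs and are
excluded from counting.

### Read structure and trimming

A DamID amplicon begins with a 17-nt adaptor whose final four bases are
the GATC motif itself. `preprocess_reads()` keeps only mates that start
with the adaptor (exact match; `N` never matches), removes the first 13
bases so the read begins with `GATC` and aligns exactly at a genomic
motif, quality-trims the 3' end at Q20, removes any 3' occurrence of the
complementary adaptor, and drops reads shorter than 22 nt. Quality
trimming runs before 3' adaptor removal; the published command line does
not fix the order, and this one is the stricter of the two (an adaptor
fragment hidden behind low-quality tails is still found).

### Counting

`count_fragments()` excludes alignments with MAPQ of 10 or below (the
filter is strictly "quality > 10"). The default `anchored` mode uses the
biochemistry: a trimmed read must start at a motif, so a forward
alignment whose start equals a motif start is counted for the fragment
beginning there, and a reverse alignment whose end equals a motif end is
counted for the fragment ending there — in both cases the fragment the
read physically extends into. A `containment` mode (5'-most aligned base
inside the fragment) is provided because the original command-level
counting is not printed; on perfectly anchored reads the two agree.
Whether reads were assigned to sites or fragments, and whether PCR
duplicates were collapsed, are not stated in the source protocol; this
package counts per fragment and does not deduplicate.

### Scores

`score_track()` computes the DamID score `log2(Dam-Lam/Dam)` per 100-kb
bin or per fragment (binless). Per replicate, each library is scaled to
counts per million, fragment values are summed into bins by fragment
midpoint, a pseudocount `c = 1` (in scaled units) is added to both
channels, and the per-replicate log ratios are averaged arithmetically.
Choices worth knowing:

* **Pseudocount** (`norm_config(pseudocount=)`): the upstream pipeline's
  exact normalization is not restated in the protocol; `c = 1` scaled
  unit is this package's default, and the score shrinks monotonically
  toward 0 as `c` grows (a property the tests assert).
* **Sum-then-ratio**: bins sum scaled fragment counts before forming the
  ratio, rather than averaging per-fragment ratios — more stable for
  low counts.
* **Missing data**: an interval whose raw counts are zero in both
  channels of any replicate is reported `NA`. This feeds the HMM's
  missing-observation path; the rule is configurable.
* Per-million scaling makes scores invariant to library rescaling, so
  only the enrichment contrast (about `delta_in - delta_out` after a
  constant shift) is interpretable, not the absolute level.

### Segmentation: two-state Student-t HMM

`fit_segment_hmm()` fits a two-state hidden Markov model in which state 2
(the LAD state, relabeled after fitting so that it has the larger
location) emits scores from a Student-t distribution `t(mu_2, sigma_2,
nu)` and state 1 from `t(mu_1, sigma_1, nu)` with a shared `nu`
(default 5, optionally estimated numerically). The heavy-tailed emission
is what makes the segmentation robust to score outliers, the same reason
the robust-HMM approach is standard for this data type. Details:

* Baum-Welch EM in log space; each chromosome is an independent
  observation sequence of one shared model. The Student-t M-step uses the
  standard auxiliary-scale weights `u = (nu+1)/(nu + z^2)`, which makes
  every iteration a generalized EM step; the observed log-likelihood is
  checked to be non-decreasing at every iteration and the fit aborts if
  it ever is not.
* Missing scores contribute emission likelihood 1 (they are marginalized)
  while the transition chain runs through them.
* Initialization: `mu` at the 25th/75th percentiles of the observed
  scores, `sigma` at half the interquartile range, self-transitions 0.9,
  uniform initial state probabilities. Initial label order does not
  affect the final segmentation (asserted by test).
* Convergence at an absolute log-likelihood change below `1e-6`, at most
  200 iterations.
* Boundaries come from the Viterbi path (exact maximum-probability path;
  verified against exhaustive enumeration for short sequences), not from
  posterior thresholding — the protocol does not say which the original
  analysis used, and Viterbi gives contiguous, reproducible domains.
* Constant (zero-variance) observations raise a degenerate-fit error;
  all-missing chromosomes are skipped with a warning.

`call_lads()` merges maximal runs of LAD-state intervals; runs never
cross chromosome boundaries, and runs of missing intervals flanked by
LAD-state intervals are bridged by default (domains are continuous
rectangles over short data gaps; `bridge_missing = FALSE` splits them).
Binless LAD length is the genomic span of the merged fragments.

### Regions and differential classification

`region_partition()` maps a UCSC-dialect cytoband table to
arm / centromere / telomere labels. The cytoband source defines band
coordinates but not which bands constitute the functional
peri-centromere, so the mapping is an explicit configuration: bands
stained `acen` or whose name matches `"cen"` become centromere, and a
configurable span (default 200 kb) at each chromosome end becomes
telomere. `region_comparison()` assigns score intervals to regions by
midpoint and compares all region pairs with the Wilcoxon rank-sum test.

`classify_lads()` compares two genotypes by any-overlap (at least 1 bp by
default, configurable): WT LADs with no mutant overlap are fLADs (lost),
mutant LADs with no WT overlap are fiLADs (ectopic), and shared LADs are
cLADs. Because "shared" can be counted on either genotype's intervals,
the cLAD count is reported on three bases — WT (the default, matching
the "fraction of WT LADs conserved" reading), mutant, and
merged-intersection — so any downstream reading is reproducible. The
identities `fLAD + cLAD(WT basis) = |WT|` and
`fiLAD + cLAD(mutant basis) = |mutant|` hold exactly.

`annotate_lads()` is LAD-wise (each domain contributes one feature
combination, matching per-site category counts): a domain's combination
contains `intron`, `CDS`, `5UTR`, `3UTR` for any 1-bp overlap with that
feature in any transcript, `inter_gene` if any base lies outside all gene
bodies, and `no_CDS` if it overlaps a gene without coding sequence (the
"no CDS" category is interpreted as overlap with a non-coding gene). The
intron set is the union over transcripts.

## The Distribution Index

The D.I. of a nucleus is the standard deviation of the fluorescence
intensity within its region of interest divided by the mean — the
coefficient of variation of the nuclear-envelope signal. A perfectly
homogeneous lamin meshwork gives D.I. = 0; clustering or patchiness of
lamin, NPCs, or lamin-binding proteins raises it.

The ROI construction re-implements the published ImageJ macro steps with
their exact semantics:

* `to_8bit()`: linear min-max scaling to 0-255 (the interactive
  display-range dependence of the original tool cannot be reproduced;
  min-max is the documented choice). Measurement is performed on the
  8-bit converted image, as the macro converts before duplicating; for
  the NPC protocol, on the median-filtered 8-bit image.
* `auto_threshold()`: Huang's fuzzy threshold (minimizing the Shannon
  entropy of fuzzy membership over the 256-bin histogram) or the Mean
  threshold, both with dark background (foreground strictly above the
  threshold). The macro shows a `Default dark` call immediately
  overwritten by `Huang dark`; the second is operative here. Degenerate
  results (empty fore- or background) are flagged, not silently empty.
* `median_filter()`: disc neighborhood of Euclidean radius 2
  (13 pixels), edge replication.
* `binary_morph()`: 8-neighborhood erode/dilate with the `count`
  semantics of the macro's binary options (a pixel flips when at least
  `count` of its 8 neighbors are of the opposite phase), off-image
  neighbors background.
* `analyze_particles()`: 8-connected components, holes filled before
  measurement (`include`), border-touching components removed
  (`exclude`), and a minimum **calibrated** area (30 square micrometers for
  the lamin protocol at 0.1-um pixels; whether the original used
  calibrated or pixel units is unstated, and a pixel-unit mode is
  available via `pixel_size = 1`).

`make_roi()` chains these into the three protocols: `lamin` (Huang
threshold, particle filter, erode x5), `npc` (median filter, Mean
threshold, dilate x5 to bridge the NPC-free patches, erode x10), and
`costain` (ROI from a co-stained reference channel, transferred to the
measured channel — used when the measured signal itself segments
poorly). `compute_di()` uses the sample SD (n-1); at ROI sizes of ~10^4
pixels the estimator choice is negligible, but it is documented.
`aggregate_individuals()` makes the individual the unit of analysis
(means of 10-12 nuclei; a warning flags counts outside that design),
comparing two groups by the unpaired two-tailed Student's t test and
more by one-way ANOVA with Tukey's multiple comparison.

## Nuclear stiffness from microneedle traces

A stiff needle presses the nucleus against a flexible, stiffness-
calibrated needle (k_tip = 11.3 or 12.0 nN/um in the modeled setup);
frames arrive at 0.5-s intervals. Per press cycle, once deformation
reaches equilibrium, the deformation is the baseline nuclear span minus
the equilibrium span and the force is the flexible-tip deflection times
k_tip. `fit_stiffness()` regresses force on deformation by ordinary
least squares **with intercept** (through-origin fitting is available but
not the default, since the protocol does not state it); the slope is the
stiffness, and fits with R^2 below 0.96 warn. The non-nuclear
contribution is removed by `net_stiffness()` as a slope-wise subtraction
of the **matched** cell-only measurement (same needle geometry, adjacent
location); subtracting a group-mean cell-only slope instead is possible
by passing that estimate.

The plateau criterion is this package's operationalization of "reached an
equilibrium": on the moving-average-smoothed span (window =
`plateau_window`, default 4 frames = 2 s), the first frame after which
successive changes stay below `plateau_eps` (default 0.1 um) for a full
window, and whose level differs from the cycle baseline by more than
`2 * plateau_eps` — the second clause keeps the pre-press baseline, which
is trivially stable, from qualifying. Deformation and force are averaged
over the detected window; without smoothing and averaging, frame-to-frame
differences of a span observed with realistic 0.1-um noise would exceed
the 0.1-um tolerance about half the time and genuine plateaus would be
rejected. The baseline is re-taken from the first `plateau_window` frames
of each cycle, and the post-release residual deformation is reported per
cycle as an elastic-recovery check. Display binning of force-deformation
points (2-um bins, mean +/- SD) is for plots only; the regression always
uses unbinned points.

## Statistics

All group tests route through one module so that every p-value is
verifiable: pooled-variance Student's t (the unpaired default, matching
the protocol's naming and its F-test variance screening; Welch available),
paired t on differences, one-way ANOVA with Tukey HSD via the studentized
range distribution, Pearson correlation, and the Mann-Whitney U /
Wilcoxon rank-sum test (both names are exported). The two-sided exact
Mann-Whitney p is defined as `min(1, 2 * min(P(U <= u), P(U >= u)))`
under the permutation null; for combined samples up to 16 it is computed
exactly — from the Wilcoxon distribution when untied and by direct
enumeration over group labelings when ties are present, since the
closed-form distribution does not cover ties but enumeration does — and
beyond that by a tie- and continuity-corrected normal approximation.
Degenerate inputs (zero variance) resolve explicitly: equal means give
`t = 0, p = 1`; unequal means are flagged degenerate rather than
producing numeric noise.

## What the synthetic generators emulate

Every pipeline input has a seeded generator that returns its ground truth
alongside the data; all generators are deterministic given (parameters,
seed) and restore the caller's RNG state.

* `synth_damid_counts()`: GATC positions with exponential spacing (mean
  400 bp), Dam counts negative-binomial around a uniform rate, Dam-Lam
  counts with the rate scaled `2^delta` per fragment (`delta_in = +1.5`
  inside planted LADs, `delta_out = -0.5` outside, so the contrast is 2.0
  log2 units), dispersion 0.2, two replicates of two million reads over a
  dm6-like 120-Mb toy genome of five arms (~1200 100-kb bins). Planted
  domains are 100-kb-aligned blocks covering ~30% of each chromosome.
  Negative-binomial noise emulates sequencing overdispersion; the
  generator does not emulate GC or mappability bias, copy-number
  variation, or fragment-length-dependent amplification — passing
  recovery tests therefore demonstrates the statistical machinery, not
  robustness to those artifacts.
* `synth_damid_fastq()`: read pairs whose informative mates carry the
  adaptor and read inward from the two fragment ends; a fragment with
  count `c` emits `floor(c/2)` fully informative pairs plus, for odd
  `c`, one pair whose second mate is a non-adaptor filler (the adaptor
  is present "in read 1 or read 2"). Anchored counting of perfectly
  aligned survivors reproduces the input counts exactly.
* `synth_nucleus_image()`: nuclei as filled ellipses of base intensity on
  a dark background (the en-face view of the envelope sheet), intensity
  multiplied inside by `exp(h G)` with `G` a Gaussian-smoothed
  unit-variance field; `h = 0` gives a perfectly homogeneous envelope and
  the coefficient of variation grows monotonically with `h`
  (approximately `sqrt(exp(h^2) - 1)`, i.e. close to `h` for small
  amplitudes — which is how group amplitudes are calibrated to the
  D.I. scale of interest). Default radii of 38-46 px at 0.1-um pixels
  keep nuclei above the 30-um^2 particle filter even after the 5-px ROI
  erosion. No point-spread function, z-structure, or staining artifacts
  are simulated.
* `synth_gene_model()`: genes with exons, derived introns, CDS and
  terminal UTRs consistent by construction; a stated fraction lacks CDS.
  Written and re-read as GFF3.
* `synth_force_trace()`: per cycle, baseline frames, a loading ramp, a
  plateau of 8 frames at the target deformation (tip deflection = slope x
  deformation / k_tip), a release ramp, and settle frames; the
  nucleus+cell trace uses slope `k_nucleus + k_cell`, the matched
  cell-only trace `k_cell`. Defaults: 7 cycles of 1-7 um, k_tip = 12
  nN/um, 0.5-s frames. Gaussian noise on span and tip displacement; no
  viscoelastic relaxation, drift, or blebbing.

## Problem sizes and runtime

The test-suite and acceptance problem sizes are chosen so every property
runs comfortably on one CPU: the full DamID recovery uses the 120-Mb /
~1200-bin toy genome (about 300,000 fragments), EM monotonicity is
checked over 50 fits of 120-bin tracks, Viterbi is verified against
exhaustive enumeration up to length 12 (4096 paths), image properties use
150-320-px canvases, the read round trip uses two chromosomes of 6-8 kb,
and stiffness recovery uses 20 seeded trace pairs.

## Known limitations

* The HMM is strictly two-state; weak/intermediate contact states would
  need a larger model (out of scope).
* Scores are relative (per-million + pseudocount), so absolute score
  levels are not comparable across normalization settings.
* The exact Mann-Whitney enumeration is O(C(n, n_x)) and intentionally
  capped at combined n = 16.
* `analyze_particles()` measures filled areas; for ring-shaped signals
  the filled convention is what the macro's `include` flag does, but it
  means "area" is the nuclear area, not the rim area.
* The plateau detector assumes press cycles are annotated with a few
  pre-press baseline frames; traces without baseline frames need
  explicit baselines.
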