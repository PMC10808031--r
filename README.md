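# laminatools

Quantitative pipelines for studying nuclear-lamina organization in
*Drosophila* muscle. The nuclear lamina — the lamin meshwork under the
inner nuclear membrane — tethers large heterochromatic genomic regions
(lamina-associated domains, LADs), and its spatial organization shapes
both chromatin positioning and the mechanical stiffness of the nucleus.
`laminatools` re-implements, as tested reusable functions, the three
bespoke procedures such a study needs:

1. **DamID-seq LAD pipeline** — from adaptor-anchored read preprocessing
   and per-GATC-fragment counting, through replicate-averaged
   `log2(Dam-Lam/Dam)` score tracks (100-kb bins or binless), two-state
   hidden Markov model segmentation with Student-t emissions, LAD
   calling and summary statistics, differential cLAD/fLAD/fiLAD
   classification between genotypes, gene-model feature annotation
   (UpSet-style combination counts), and chromosome-region score
   comparisons against a cytoband partition.
2. **Distribution Index imaging** — the published ImageJ macro recipe
   rebuilt step by step (8-bit conversion, Huang/Mean auto-thresholds,
   disc median filter, count-based binary erosion/dilation, particle
   analysis) to construct eroded nuclear ROIs, plus
   `D.I. = SD/mean` of intensity within each ROI and per-individual
   aggregation with group testing.
3. **Nuclear mechanics** — extraction of equilibrium force-deformation
   points from microneedle press-release traces
   (force = tip deflection x k_tip), stiffness as the linear-regression
   slope in nN/um, and subtraction of the matched non-nuclear
   contribution.

Every input has a seeded synthetic generator with ground truth
(`synth_damid_counts()`, `synth_damid_fastq()`, `synth_nucleus_image()`,
`synth_gene_model()`, `synth_force_trace()`), so all pipelines are
exercisable at desk scale with known answers.

## The models in brief

* **DamID score** of an interval: `log2((L + c) / (D + c))` per
  replicate, averaged across replicates, where `L` and `D` are
  per-million-scaled Dam-Lam and Dam counts summed over the interval and
  `c` is a pseudocount (default 1).
* **Segmentation**: a two-state HMM with emissions
  `x_t | s_t ~ t_nu(mu_s, sigma_s)` (`nu = 5` shared), fitted by
  Baum-Welch in log space with missing scores marginalized; the LAD
  state is the one with larger `mu`, and boundaries come from the
  Viterbi path.
* **Distribution Index**: `D.I. = SD(I_ROI) / mean(I_ROI)`, the
  coefficient of variation of envelope fluorescence within the
  macro-defined eroded nuclear ROI.
* **Stiffness**: `F = k d + b` by ordinary least squares over
  equilibrium press points; the nuclear contribution is
  `k_total - k_cell_only` from matched traces.

See `vignettes/lamina-organization-methods.Rmd` for assumptions,
parameter meanings, and numerical choices.

## Worked example

```r
library(laminatools)

sim <- synth_damid_counts(chrom_lengths = c(chr2L = 10e6, chr2R = 10e6),
                          seed = 42)
tr  <- score_track(sim$damlam, sim$dam)                     # 100-kb bins
rc  <- replicate_correlation(replicate_track(tr, 1), replicate_track(tr, 2))
fit <- fit_segment_hmm(tr)
lads <- call_lads(fit)
st  <- lad_stats(lads)
f1  <- lad_recovery_f1(lads, sim$truth$planted_lads, tr)
print(fit)
cat(sprintf("replicate Pearson r = %.3f over %d bins\n", rc$r, rc$n_used))
cat(sprintf("%d LADs, mean length %.0f kb, bin-level F1 vs planted truth = %.3f\n",
            st$count, st$mean_length_kb, f1$f1))

s  <- synth_force_trace(noise_sd = 0.1, seed = 3)
kt <- fit_stiffness(extract_points(s$total))
kc <- fit_stiffness(extract_points(s$cell_only))
print(kt)
cat(sprintf("net nuclear stiffness = %.2f nN/um (true %.1f)\n",
            net_stiffness(kt, kc), s$truth$k_nucleus))
```

```
Two-state Student-t HMM fit
  mu    = -0.9982 / 0.9953
  sigma = 0.0348 / 0.0351
  nu    = 5.000
  iterations = 11 (converged: TRUE)
replicate Pearson r = 0.996 over 200 bins
8 LADs, mean length 838 kb, bin-level F1 vs planted truth = 1.000
Stiffness 4.637 nN/um (intercept 0.624 nN, R^2 0.9954, n 7, nucleus+cell)
net nuclear stiffness = 3.79 nN/um (true 4.0)
```

The fitted emission locations sit near the planted log2 enrichments
(after the per-million shift), both replicates of the simulated
experiment agree almost perfectly, the called domains coincide with the
planted ones bin for bin, and the regression slope of the noisy
force-deformation trace recovers the generating stiffness to within a
few percent after subtracting the cell-only contribution.

## Analysis workflow

Numbered drivers under `analysis/` run the study end to end on synthetic
data and write tables under `results/`:

```sh
Rscript analysis/01_simulate_damid.R     # two genotypes, score tracks
Rscript analysis/02_call_lads.R          # HMM, LAD stats, cLAD/fLAD/fiLAD,
                                         # feature annotation, regions
Rscript analysis/03_imaging_di.R         # D.I. groups + t test
Rscript analysis/04_nuclear_mechanics.R  # stiffness cohort + Mann-Whitney
```

Steps 1 and 2 share state through `scratch/damid_sim.rds`; run them in
order.

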