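# casptrace

Multi-omics kinetic profiling of caspase substrates during endoplasmic
reticulum (ER) stress.

Prolonged ER stress drives cells from the adaptive unfolded protein response
into caspase-dependent death. Caspases act on two fronts at once: they cleave
substrates directly (post-translational regulation, visible as neo-C-terminal
aspartate peptides and falling protein levels), and they silence
transcription factors whose target genes would otherwise rise (transcriptional
regulation, visible only when caspases are inhibited). Demonstrating this
dual role requires integrating three kinetic layers measured over the same
tunicamycin time course — caspase substrate profiling (CSP), global protein
profiling (GPP), and RNA-seq — plus a stress ± pan-caspase-inhibitor
(z-VAD-FMK) RNA-seq comparison. `casptrace` implements that integration as a
tested, reusable R pipeline for proteomics/transcriptomics analysts, with a
synthetic-data module that plants ground truth at every stage so the whole
workflow is exercisable (and falsifiable) at desk scale.

## What the package computes

* **TMT6plex quantification** — reporter-ion extraction takes, per channel,
  the highest peak within 20 ppm of the theoretical reporter m/z
  (126.12773 … 131.13818, computed from isotope masses); PSMs with combined
  reporter intensity ≤ 2000 are discarded; peptide abundances are PSM sums
  expressed relative to the maximal channel; protein abundances are
  unweighted means of peptide profiles.
* **Target-decoy confidence** — Fisher linear discriminant scoring of PSM
  features (score, delta score, |mass error|, missed cleavages, charge),
  thresholded at the most permissive score with estimated
  FDR = decoys/targets ≤ 5% (PSM level) and 2% (protein level,
  best-peptide scoring).
* **Cleavage-site mapping** — digest validation under the protease + caspase
  rule (C-terminal Asp, tryptic/chymotryptic N-boundary, ≤ 4 internal missed
  cleavages), collapse of supporting peptides onto (accession, P1) sites,
  overlap with known-site lists, and P5…P6′ residue-probability motif
  matrices (P1 is definitionally Asp).
* **Fuzzy c-means trajectory clustering** — Bezdek alternating optimization
  of J = Σᵢⱼ uᵢⱼᵐ ‖xⱼ − vᵢ‖², with m = 1.5, on row-standardized (mean 0,
  SD 1) six-point trajectories; c = 5 for cleavage peptides, 6 for proteins
  (two down-regulated classes), 9 for transcripts; best of 10 random starts.
* **Three-layer overlay and regulatory modes** — cleavage/protein/transcript
  triads are joined per gene; Pearson correlations and rank-based trend
  statistics classify each substrate as `caspase_degradation` (transcript
  up, protein down, cleavage up), `co_upregulated`, `direct_caspase`
  (transcript flat, protein down), `transcription_coupled` (both down), or
  `ambiguous`.
* **Differential expression** — RPKM, voom precision weights and moderated t
  statistics (limma), BH adjustment, strict significance filters
  (adjusted p < 0.05, fold change > 2), and Ward clustering of samples on
  the 500 most variable variance-stabilized genes.
* **TF dual-regulation calls** — a competitive gene-set test with variance
  inflation factor VIF = 1 + (m − 1)·ρ̄ (the camera construction, ρ̄ = 0.01
  by default) over TF target sets; a TF is called dual-regulated when its
  target set is significantly up under caspase inhibition while its own
  transcript stays below 2-fold.

## Worked example

Cluster 600 synthetic cleavage trajectories drawn from the five planted
kinetic archetypes (early, post-24 h, post-72 h, two bimodal), then classify
planted substrate triads:

```r
library(casptrace)

tr  <- sim_trajectories(600, noise_sd = 0.3, seed = 1)
fit <- fuzzy_cmeans(tr, centers = 5, m = 1.5, seed = 2)
fit
#> Fuzzy c-means fit: 600 features, 5 clusters, m = 1.5, J = 195.311 (20 iter)
#> cluster sizes: 129, 102, 126, 113, 130
mclust::adjustedRandIndex(tr$archetype, fit$cluster)
#> [1] 0.9955185

triads <- sim_triads(400, noise_sd = 0.25, seed = 3)
calls  <- classify_mode(triads)
mean(as.character(calls$mode) == calls$true_mode)
#> [1] 0.945
substrate_regression(calls)
#> # A tibble: 1 × 5
#>       r  p_value slope intercept n_obs
#>   <dbl>    <dbl> <dbl>     <dbl> <int>
#> 1 0.240 1.01e-32 0.240  1.38e-17  2400
```

The adjusted Rand index of 0.996 says the five planted kinetic classes are
recovered almost perfectly at this noise level; the 94.5% mode accuracy is
limited mainly by genuinely flat transcript layers that six noisy time
points occasionally read as trending. `autoplot(fit)`, `plot_triad()` and
`plot_volcano()` draw the corresponding figures, and

```r
res <- run_pipeline(pipeline_config(seed = 1), "run1")
```

executes every stage end to end on synthetic data (deterministically for a
fixed seed), writing tables, a checksummed manifest and a planted-truth
recovery report under `run1/`.

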