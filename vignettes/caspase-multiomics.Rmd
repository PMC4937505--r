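---
title: "Methods: multi-omics kinetic profiling of caspase substrates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-omics kinetic profiling of caspase substrates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(casptrace)
```

# The scientific setting

Chronic ER stress (modelled with tunicamycin over 0–72 h) activates
caspases, which both cleave substrates directly and — by degrading
transcription factors — reshape the transcriptional program. `casptrace`
implements the computational side of a design that detects both effects:

1. **CSP** (caspase substrate profiling): neo-C-terminal Asp peptides,
   enriched by motif antibodies after tryptic or chymotryptic digestion,
   quantified across six TMT6plex channels mapped to the six time points.
2. **GPP** (global protein profiling): whole-proteome TMT quantification on
   the same time grid.
3. **RNA-seq**: the same time course, plus a stress ± pan-caspase-inhibitor
   comparison (0/8/24/72 h, three replicates per condition) whose contrast
   at a late time point exposes genes whose expression caspase activity
   suppresses.

The package's claim structure is deliberately property-based: none of the
original study's headline counts can be recomputed without its deposited raw
data, search engine and database snapshots, so the tests assert the
*behaviour* of each method — calibration, exact recovery of planted truth,
agreement with independent oracles — on synthetic data at stated noise
levels.

# Quantification model

Reporter extraction takes, per channel, the *maximum* peak intensity within
a ±20 ppm window around the theoretical reporter m/z, tolerance measured
relative to the theoretical value. The reporter masses are derived in code
from isotope masses (the reporter cation is C8H16N+ with 13C/15N
substitutions), not hard-coded. PSMs with combined (summed) reporter
intensity ≤ 2000 are removed — a strict inequality, so a PSM at exactly
2000 is excluded. Peptide quantities are channel-wise PSM sums re-expressed
relative to the maximal channel; protein quantities are unweighted means of
peptide relative profiles. Peptides shared between accessions count toward
every accession by default (`shared = "unique"` restricts to unique
peptides); this symmetric convention is simple and transparent, at the cost
of double-counting genuinely shared peptides. No isotopic-impurity
correction or channel-loading normalisation is applied by default; loading
normalisation is a known omission rather than an oversight — row
standardization downstream absorbs per-feature scale anyway.

The channel→time mapping (126→0 h … 131→72 h) is a configuration default;
nothing downstream depends on which channel carries which time point beyond
this declared mapping.

# Confidence estimation

Targets and decoys are scored with a Fisher linear discriminant,
`w = Sw⁻¹(μ_target − μ_decoy)` on the features (score, delta score,
|ppm error|, missed cleavages, charge). The closed form keeps the scoring
auditable; a singular pooled covariance (collinear features) falls back to a
ridge-regularised solve with a warning. The FDR estimator is
`decoys_kept / targets_kept` — the convention for a concatenated
target-decoy search of equal size; the `2d/(t+d)` variant is available. The
threshold returned is the most permissive score whose estimated FDR is at
or below the requested level (5% at PSM level, 2% at protein level), ties
kept inclusively with a deterministic ordering. Protein-level filtering
scores each accession by its best surviving peptide (picked-best
surrogate), since the original protein-inference tool is unpublished.
Because the estimated FDR is not monotone in the threshold, the scan
considers every tie-group boundary, and a property test checks that
survivor sets grow monotonically with the level.

# Cleavage-site mapping

A captured peptide is digest-valid when it ends in Asp (the caspase P1),
its N-terminal boundary follows the digestion protease (after K/R for
trypsin, F/Y/W/L for chymotrypsin, or the protein N-terminus), and it
carries at most four internal missed-cleavage sites. Internal missed sites
count protease residues (not before proline) *and* internal aspartates,
since the search space treats Asp as a cleavage residue too. Peptides from
both digests ending at the same aspartate collapse into one site; a peptide
matching several positions is emitted at all of them and flagged ambiguous
rather than silently dropped. Coordinates are 1-based on the supplied FASTA
sequence. Motif matrices cover the 11 positions P5…P1·P1′…P6′; windows
truncated at a terminus are padded with `-`, which is excluded from the
per-position denominators, so every informative column sums to 1 and the P1
column is a point mass on D by construction of the capture chemistry.
Overlap with known-site lists uses exact (accession, position) matching by
default, with protein-level matching as an option, because legacy
repositories mix coordinate conventions.

# Fuzzy c-means

The clustering is the standard Bezdek alternating optimization (Euclidean
distance, objective J = Σ uᵐ d²), re-implemented rather than wrapped so
that the objective trace is observable and testable: J is recorded at every
iteration and asserted non-increasing; membership rows sum to 1; a point
coinciding with a center takes membership 1 by the limit convention; empty
clusters (possible only in degenerate inputs) retain their previous
center. Convergence is |ΔJ| < 1e-9 with a 1000-iteration cap. Because the
problem is non-convex the fit runs 10 random membership initialisations and
keeps the best J; tests verify that on tiny instances this matches a
dense-restart reference optimum computed with the independent `e1071`
implementation (the engine behind the tool the original analysis used) to
1e-6, and that J values agree when recomputed from the reference fit.
Parameters follow the emulated analysis: fuzzifier m = 1.5; c = 5 (CSP),
6 (GPP), 9 (RNA). Trajectories are clustered at peptide granularity for
CSP. Hard labels are argmax memberships with ties to the lowest index.

# Overlay and regulatory modes

The overlay joins each clustered cleavage peptide to its protein and
transcript trajectories through an id map. When configured, the protein
side is restricted to the down-regulated GPP clusters (identified by a
negative trend of the cluster center); unmapped peptides are retained with
missing layers and counted. Each complete triad is reduced to three trend
statistics — the Pearson correlation of the trajectory with the time-point
*rank*, not raw hours, because the 0–72 h grid is strongly non-uniform and
raw-hour correlation would be dominated by the 24–72 h gap. With
`trend_cut = 0.5` (|r| above it = up/down, else flat) the decision table is:

| transcript | protein | cleavage | mode |
|---|---|---|---|
| up | down | up | `caspase_degradation` |
| up | up | — | `co_upregulated` |
| flat | down | — | `direct_caspase` |
| down | down | — | `transcription_coupled` |
| otherwise | | | `ambiguous` |

The cutoffs are artifact parameters: the source analysis describes these
categories qualitatively through exemplar substrates and prints no
thresholds. `trend_cut = 0.5` was chosen once so that the four idealized
exemplar patterns classify correctly and a genuinely flat six-point
trajectory is miscalled only when noise induces |r| > 0.5 (about a 30%
event for pure noise at n = 6 — the dominant error mode in the recovery
benchmarks, and an honest reflection of how little six time points
constrain a trend). `r_cut` feeds only an advisory `high_confidence` flag.
The classification is invariant to positive affine rescaling of any layer.
The substrate-level scatter summary pools all (substrate × time) pairs of
standardized protein and transcript values into one Pearson correlation and
least-squares line.

# Differential expression and enrichment

RPKM is the closed form count/(kb × millions mapped). The linear-model
layer stands on limma: genes with no reads in any sample are removed, voom
supplies log2-CPM and precision weights, and empirical-Bayes moderation
yields the t statistics; "adjusted p" is Benjamini–Hochberg (limma's
default; the source names no procedure). Significance uses strict
inequalities: adjusted p < 0.05 and linear fold change > 2 in either
direction. The inhibitor-vs-stress contrast is taken at matched time
(default 72 h) rather than as an interaction — the simpler reading of the
design. Sample clustering uses `log2(count + 1)` as the default variance
stabilizer (the full DESeq2 VST is behind a flag, since the clustering is
qualitative), the 500 most variable genes, Euclidean distances and Ward
linkage.

The competitive gene-set test follows the published camera construction:
in-set versus out-set mean of the moderated statistics, variance inflated
by VIF = 1 + (m − 1)·ρ̄ with ρ̄ = 0.01 by default ("default parameters" in
the emulated analysis), two-sided p on G − 2 df, BH across the collection.
It is implemented in-package (setting ρ̄ = 0 yields the naive test needed
for the calibration comparison) and cross-checked against `limma::cameraPR`
to 1e-12 in the tests. A TF is called dual-regulated when its target set is
significantly up (adjusted p < 0.05) while its own transcript's fold change
stays below 2; TFs breaching 2-fold are reported but excluded, mirroring
the exclusion of strongly auto-regulated factors. "Multiple target genes
up" is operationalized as the set-level test; a per-set count of
individually significant targets (adjusted p < 1e-4, FC > 2, the volcano
highlight filter) is reported for transparency.

# The synthetic-data generator

The generator is first-class, tested code; its defaults *are* the study
conditions the package claims to handle:

* **Design**: 0/4/8/24/48/72 h TMT6 time course; RNA 0/8/24/72 h,
  stress-only and stress + inhibitor arms, 3 replicates.
* **Cleavage kinetics**: five piecewise-linear archetypes (early, post-24 h,
  post-72 h, two bimodal with a 48 h dip) matching the verbal cluster
  descriptions; exact shapes are generator parameters chosen once for
  visual and numerical distinctness (pairwise correlations of the
  standardized templates range −0.1 to 0.77).
* **Reporter intensities**: positive affine images of the standardized
  archetypes scaled by a lognormal per-peptide factor with multiplicative
  lognormal noise — TMT intensities are positive and right-skewed, and the
  affine form makes the zero-noise limit standardize back to the archetype
  exactly, which the tests exploit.
* **Decoys**: reversed sequences keeping the C-terminal residue (the
  degradomics-compatible convention), score features from a lower-scoring
  distribution, deterministic decoy count `round(n · fraction)`.
* **Counts**: negative-binomial with lognormal baseline means
  (log-mean log 200, log-SD 1.5) and dispersion 0.05 — typical for cell-line
  biological triplicates; dispersion 0 degrades to Poisson for null checks.
  Planted TF target sets rise `target_up_fc = 4`-fold in the inhibitor arm
  at ≥ 72 h while TF own-genes stay flat in expectation.
* **Noise levels for the recovery claims**: trajectory noise SD 0.3
  (clustering), triad noise SD 0.25 (mode calls) on the standardized scale.
  The source reports no per-archetype effect sizes or noise levels, so
  these are configuration, not claims about the original data.

What the generator does **not** emulate — and what passing tests therefore
do not show about real data: chromatographic artefacts, isotopic impurity
leakage between channels, ratio compression from co-isolation, shared
homologous peptides at realistic frequency, correlated gene–gene expression
structure beyond the planted sets, or search-engine score distributions
with realistic tails. The recovery rates on synthetic data are upper bounds
under a well-specified noise model, not estimates of field performance.

# Numerical and reproducibility choices

All randomness funnels through one root seed; stage seeds are derived
deterministically, so `run_pipeline()` is bit-reproducible (the manifest
stores a config hash and per-table checksums and deliberately excludes
timestamps). Tie-breaks are deterministic everywhere (argmax to lowest
index, FDR ties kept inclusively). Benchmarks in the tests and the
acceptance script use problem sizes chosen as the smallest at which the
statistical claims are meaningful: 600 trajectories for cluster recovery,
10,000 PSMs for FDR calibration, 2000 genes for DE calibration, 2000
simulations for set-test type-I error, 400 triads for mode recovery, and
the default pipeline scale (300 proteins, 1200 PSMs, 2000 genes, 50 TF
sets) end to end.

# Known limitations

* The trend statistic has little power at six time points; `direct_caspase`
  (flat transcript) is intrinsically the hardest call, and the observed
  ~90% mode accuracy at noise 0.25 is dominated by that limit.
* Protein inference is best-peptide only; no razor-peptide or parsimony
  model.
* The pooled protein–transcript correlation mixes regulatory modes by
  design; its value depends on the planted mode composition and is not
  comparable across different generator settings.
* User-data mode expects the documented TSV/FASTA/GMT interfaces and maps
  peptides to the first listed accession; real pipelines with richer
  protein groups need a curated id map.
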