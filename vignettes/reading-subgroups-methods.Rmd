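---
title: "Modelling individual differences in single-word reading: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling individual differences in single-word reading}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(readerclust)
```

## The scientific problem

Skilled adult readers are usually modelled as a homogeneous population, yet
dual-route accounts of reading allow the lexical/semantic and the
sublexical/phonological pathway to carry different weight in different
people. `readerclust` implements a complete analysis chain for detecting such
latent reader subgroups from task-based fMRI and validating them on
independent data: a Bayesian multi-subject activation model that clusters
readers by their whole-brain response to written words, second-level
word-versus-pseudoword contrasts with cluster-extent thresholding,
representational similarity analysis (RSA) against phonological and semantic
model matrices, and the classic behavioral effect battery (pseudohomophone,
lexicality and regularity effects).

Because raw data for studies of this kind are rarely deposited, the package
treats its synthetic-data generator as a first-class module: every stage is
exercised, and its statistical behaviour quantified, on cohorts simulated
under the study design the package targets — 30 subjects in two latent
subgroups of 10 and 20, 90 atlas regions of interest (ROIs), event-related
runs of 280 volumes at TR = 2 s with 30 stimuli (20 words, 10 pseudowords)
presented for 2 s at a 12–20 s onset asynchrony.

## The activation model

For subject $i$ and ROI $j$, the projected time series is modelled as

$$y_{ij} = x\,\gamma_{ij}\beta_{ij} + \varepsilon_{ij},\qquad
\varepsilon_{ij}\sim N(0,\sigma^2_{ij}),$$

where $x$ is the stimulus regressor (events convolved with the canonical
HRF) after nuisance columns are projected out, $\gamma_{ij}\in\{0,1\}$ is an
activation indicator and $\beta_{ij}$ an amplitude. Two priors encode the
model's substance:

* **Spatial prior on $\gamma$.** Within each subject the indicators follow
  an Ising (autologistic) distribution on an ROI neighbor network:
  $\log p(\gamma_i) \propto \sum_j \gamma_{ij}\,(d + e\sum_{j'\sim j}
  \gamma_{ij'})$. The external field $d$ (`mrf_sparsity`, default −2.5)
  keeps maps sparse a priori; the interaction $e$ (`mrf_smoothing`, default
  0.5, dimensionless) makes neighboring ROIs co-activate. The network is
  built by thresholding pairwise centroid distances at the smallest value
  whose induced mean degree reaches a target (default 5 neighbors on
  average).
* **Shared amplitude mixture.** Active amplitudes are allocated to a
  discrete set of atoms shared across *all* subjects — a truncated
  stick-breaking (Dirichlet-process-style) mixture with concentration 1 and
  truncation at the number of subjects. Subjects with similar activation
  borrow strength by occupying the same atoms, which is what later lets the
  thresholded amplitude maps separate subject subgroups.

Atoms have a $N(0, \text{slab sd}^2)$ prior (slab sd 10, amplitude units);
noise variances have an inverse-gamma (2, 1) prior per subject and ROI.
All updates are conjugate Gibbs steps; allocations use the Gumbel-max trick,
and indicator updates marginalize the amplitude over the current mixture.
Seeded chains are bitwise reproducible. The sampler reports the trace of the
active fraction and a split-half stability z-score as convergence
diagnostics rather than failing silently.

Posterior activation probabilities are thresholded by Bayesian false
discovery rate: probabilities are sorted descending and the largest prefix
whose mean posterior error $(1-p)$ stays below $\alpha$ (default 0.01) is
declared active. Subjects are then clustered by average-linkage hierarchical
clustering on the Euclidean distances between their *thresholded* posterior
mean amplitude vectors (values zeroed outside the declared set), and the
number of clusters is chosen by maximum average silhouette width (singleton
silhouettes are 0 by convention; a degenerate all-identical feature matrix
short-circuits to $k=1$), with within-cluster sums of squares reported for
the elbow diagnostic.

## First-level GLM

The canonical HRF is a difference of gamma densities (shapes 6 and 16, unit
rate, undershoot ratio 1/6), peak-normalized; stimuli are modelled as 2-s
boxcars convolved on a 0.1-s grid and sampled at the TR (delta coding is a
switch). Designs add optional motion columns, a linear drift term and an
intercept. Estimation is ordinary least squares without prewhitening —
temporal autocorrelation is a generator property, not corrected at first
level; this is a documented simplification, adequate at the slow
event-related timing the design uses. Per-word beta maps are estimated with
stimulus-granularity designs, averaged across runs (the default when a
stimulus appears in several runs), and mean-centered across words within
subject before RSA.

## RSA

Phonological dissimilarity between two phoneme strings is the minimal-cost
alignment where substituting segments costs the number of differing
phonological features and insertion/deletion costs `indel_cost` (default:
the number of feature dimensions, on the view that an inserted segment
changes every feature from "absent"; configurable). The packaged inventory
is a small binary feature table over ARPAbet-style English segments — the
original study's exact feature system is not published, and only ranks enter
the downstream statistics, so any reasonable feature system that preserves
gross phonological similarity serves. Distances become similarities by
negation, which is rank-preserving; semantic similarity is the cosine of
supplied word vectors (no corpus training — semantic similarities are an
input). Brain similarity is the tie-corrected (average-rank) Spearman
correlation between per-word voxel patterns; pairs involving a constant
pattern are undefined, flagged, and excluded pairwise. The RSA statistic is
the Spearman correlation between the lower triangles of the brain and model
matrices; group inference uses a one-tailed one-sample t test (the
directional hypothesis that a region carries model information) and
pooled-variance two-sample t tests between subgroups (dof $n_1+n_2-2$,
matching the 10/20 split's dof of 28).

## Second-level contrasts

Subgroup differences in the pseudoword-versus-word contrast are tested
voxelwise with pooled two-sample t maps, thresholded at a primary
uncorrected p (two-sided on |t| by default), with connected components
(26-neighbour connectivity by default; 6 and 18 available) retained above an
extent threshold k. Cluster records report the peak and up to two further
local maxima chosen greedily in descending statistic order under an 8-mm
exclusion radius, plus per-group simple-effect directions at the peak voxel.
The analytic Gaussian-random-field extent calibration is replaced by a
Monte-Carlo estimator: null Gaussian fields of stated smoothness are
simulated over the search volume and k is the smallest extent whose
family-wise exceedance proportion stays below the target. Published (p, k)
pairs depend on a particular data set's smoothness and search volume and are
not reproduction targets; users may also supply k directly.

## Behavioral battery

Effects are computed from per-subject condition means over correct trials
(no outlier trimming): pseudohomophone = pseudohomophone −
matched-pseudoword (lexical decision); regularity = irregular − regular;
lexicality = pseudoword − the *trial-weighted* mean over all word trials in
reading aloud. The trial-weighted word mean is a deliberate fixed choice:
with the study's published condition means (regular 492 ms over 49 items,
irregular 515 ms over 47, pseudowords 591 ms) it yields 87.7 ms, and no
weighting reproduces a rounder figure exactly. The mixed ANOVA is the
standard two-way mixed-design decomposition on subject-level condition means
(`aov` with a subject error stratum); for 2 groups × 2 conditions its
interaction F provably equals the squared pooled t on difference scores,
which the tests verify on random designs. Measure correlations are Pearson
by default (Spearman by flag) with pairwise deletion and two-sided flags at
0.10/0.05/0.01/0.001.

## The synthetic generator: what it emulates, and what it does not

ROI time series are HRF-convolved designs scaled by subgroup amplitude
profiles plus stationary AR(1) Gaussian noise (lag-1 coefficient 0.3 by
default, marginal sd `noise_sd`). The study preset encodes subgroups that
differ *by degree*: both activate a common set of 20 reading ROIs, the
second subgroup with amplitude 2.5 versus 1.0 plus 20 further ROIs at 1.5,
against noise sd 0.5 — an amplitude gap of at least three noise sd, the
"high-SNR" regime in which subgroup recovery is quantified (a
double-dissociation switch exists for power studies). Voxel patterns embed a
target representational geometry exactly in their sample second moment: the
model similarity matrix is rescaled into a positive-definite correlation
band, mixed with the identity by `signal_weight`, and realized through an
orthonormalized Gaussian basis, so the expected similarity structure is the
specified mixture by construction. Behavioral trials are condition mean +
subgroup shift + subject intercept + Gaussian residual, with defaults at the
study's published means, SDs and item counts; preset subgroup shifts
reproduce the published subgroup condition means while keeping the pooled
means intact.

The generator does **not** model motion, physiological noise, susceptibility
artifacts, scanner drift beyond a linear term, spatial noise correlation
between ROIs, hemodynamic variability across regions or subjects, or
response-time-dependent BOLD amplitude. Passing recovery tests therefore
shows the *estimators* are correct and well calibrated under the stated
generative assumptions; it does not certify performance on real data, where
the unmodelled structure above is the main hazard.

## Numerical and design choices

* Lattice parcellations tile disjoint cuboid blocks; a `carve` option
  removes a few random corner voxels per block. This exists because exact
  block lattices produce massively tied centroid distances, and a distance
  threshold then cannot realize a fractional target mean degree (the mean
  degree jumps from ~4.6 to ~11 for 90 ROIs); carving preserves
  disjointness and the centroid-of-voxels invariant while making the
  distance spectrum generic. The study preset uses `carve = 2`.
* The neighbor threshold is chosen from the sorted observed distances —
  minimal subject to reaching the target mean degree.
* An exact first-level fit makes a contrast t statistic unbounded; it is
  reported as signed infinity with a flag, never an error or an
  astronomical float.
* BFDR on an empty input returns an empty declared set; `alpha` must lie in
  (0, 1).
* Degenerate inputs to t tests (zero variance) return flagged `NA`
  statistics rather than errors, matching how the battery must behave on
  pathological subjects.
* Simulation sizes in the tests and the acceptance script: MCMC chains run
  700–1200 iterations with half discarded as burn-in (the module default is
  4000/2000), chosen as the package's own desk-scale setting — at the
  study's signal-to-noise the chain forgets its initialization within a few
  dozen sweeps, and recovery results are identical to longer runs.
* All randomness flows from per-call seeds; cohort, chain and pipeline
  outputs are bitwise reproducible given a seed, and the pipeline manifest
  records every derived stage seed.

## The run-partition guard

The pipeline clusters subjects on dedicated run(s) (run 1 by default) and
validates on the remaining runs, mirroring the circularity-avoidance logic
of split-session designs. `run_pipeline()` refuses a configuration that
assigns a run to both roles, and the manifest records which runs each stage
read, so the disjointness is auditable after the fact.

## Known limitations

* ROI-level inference only: no voxel-level MCMC, no searchlight RSA, no
  noise ceilings, no TFCE, no analytic random-field smoothness estimation.
* OLS first level without prewhitening mildly miscalibrates first-level t
  statistics under strong autocorrelation; downstream analyses use betas or
  group-level statistics, which are unbiased regardless.
* The silhouette criterion considers k ≥ 2; a single homogeneous population
  is only reported via the degeneracy flag, not inferred statistically.
* No outlier-subject handling is implemented for the dendrogram; an
  outlying subject joins whichever cluster it is nearest.
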