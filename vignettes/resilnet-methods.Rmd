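---
title: "Methods: functional network resilience analysis on synthetic cohorts"
author: "resilnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: functional network resilience analysis on synthetic cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The analysis

`resilnet` implements a complete functional-connectome resilience
analysis for presymptomatic genetic frontotemporal dementia (FTD): from
parcellated fMRI-like time series to wavelet-band connectivity, weighted
graph metrics normalized against degree-preserving null graphs, hub
analysis, and a statistical layer of mixed-effects group contrasts,
piecewise breakpoint regression at expected symptom onset, and per-group
associations with brain volume and cognition. Because multi-site family
cohorts of genetic FTD are not publicly distributable, the package ships
a first-class synthetic cohort generator that emulates the statistical
structure of such a study — three groups (gene-negative relatives,
presymptomatic mutation carriers, symptomatic patients; 80/68/24 by
default), per-family expected onset ages, TR ≈ 2.2 s echo-planar
acquisitions, hub-structured connectivity, and disease effects expressed
along the years-to-expected-onset axis — so that every stage of the
analysis is exercisable and testable end-to-end without any data
download.

## Connectivity estimation

Each subject contributes a region × time signal matrix. The analysis
band (default 0.0675–0.125 Hz, the low-frequency band in which
resting-state correlations concentrate) is mapped to a dyadic wavelet
scale by maximal frequency overlap: for sampling frequency
$f_s = 1/\mathrm{TR}$, scale $j$ covers $[f_s/2^{j+1},\, f_s/2^j]$ Hz,
and at TR = 2.2 s scale 2 (0.057–0.114 Hz) wins by a wide margin. The
scale is computed from the TR rather than hard-coded because repetition
times vary across sites (2.2–3.0 s in the emulated study).

Connectivity is the Pearson correlation, for every region pair, of the
maximal-overlap discrete wavelet transform (MODWT) detail coefficients
at the selected scale. The MODWT is implemented in the package with
Daubechies-4 filters and a reflection boundary; the
filter-width-dependent boundary coefficients
($L_j - 1 = 3(2^j - 1)$ at scale $j$) are discarded before correlating,
avoiding boundary bias on ~300 s acquisitions. The transform is verified
in the test suite against a naive direct-convolution oracle, and its
band behaviour against a pure sinusoid (a 0.1 Hz tone at TR 2 s places
over 70% of its detail variance at scale 2). Degenerate (constant)
regional signals raise an error naming the region rather than silently
producing NaN. Subjects whose despiking spike percentage exceeds 10%
(strict inequality) are excluded before connectivity estimation.

## Graphs, metrics and null models

Weighted graphs are built from the correlation matrices with negative
correlations set to zero by default (absolute value available as a
policy). Two graphs are used per subject:

* **Connection strength** — the sum of nodal strengths (weighted
  degrees) — is computed on the *full* positive-weighted graph. A weight
  sum needs no backbone, and computing it on a thresholded graph would
  confound it with topology: which edges survive a fixed-density
  threshold depends on how heterogeneous the weight distribution is.
* **Path-length metrics** — global efficiency (mean over ordered node
  pairs of the inverse shortest-path length), per-node farness (the mean
  shortest-path length, the quantity this literature calls closeness
  centrality; lower = better integrated) and nodal efficiency — are
  computed on a graph thresholded to a configurable edge density
  (default 10%) over a maximum-spanning-tree backbone that guarantees
  connectedness. Path lengths use the standard reciprocal transform
  $d = 1/w$. Efficiency is reported as a mean rather than a literal sum
  (they differ by the constant $n(n-1)$), which keeps values comparable
  across region counts.

Efficiency and farness are normalized against the mean of a
degree-preserving null ensemble (500 nulls at study scale, 50 in
desk-scale runs): each null keeps the graph's binary degree sequence
(degree-preserving edge swaps) and its exact edge-weight multiset
(randomly permuted onto the rewired topology). Swapping is batched, with
connectivity checked per batch and further rewiring applied until the
null is connected; per-swap connectivity checks would be prohibitively
slow in interpreted code and the batch-level rejection preserves the
same ensemble invariants, which the test suite checks null-by-null. A
complete graph admits no swap, so only its weights are permuted. The
thresholding itself exists partly *because* of this normalization:
degree-preserving nulls are undefined on a complete topology, so a fully
weighted analysis cannot be normalized this way.

Hubs are regions whose reference connection strength exceeds the
across-region mean by more than two sample standard deviations, with the
reference computed in the gene-negative group only — the hub set is
therefore invariant to anything that happens in the carrier or patient
groups.

## Inference

Group contrasts fit `outcome ~ group + age + (1|site) + (1|gene)` with
all three groups in the model (the gene-negative group anchors the age
effect), and test pairwise contrasts with Satterthwaite degrees of
freedom. Random intercepts observed at fewer than two levels are
dropped with a note, in which case the fit reduces to ordinary least
squares ANCOVA — the test suite checks the reduction against a
closed-form OLS oracle.

The breakpoint model is fitted on carriers and patients only
(years-to-onset is not meaningful for relatives who will never convert;
a flag includes them if desired):
$$y = \beta_0 + \beta_1 t + \beta_2 (t - k)_+ + \beta_3 \mathbf{1}[t > k]
      + \beta_4\,\mathrm{age} + u_{site} + u_{gene} + \varepsilon$$
with knot $k = 0$ (expected onset). Both a slope change and a level
discontinuity are included; the headline test is the joint test of
$\beta_2, \beta_3$ — an exact F test in the OLS case, a
maximum-likelihood likelihood-ratio test for mixed fits (estimates
reported from the REML fit). A numerically perfect (noiseless) fit is
reported as no evidence of a breakpoint. The hub analysis fits
`outcome ~ hub × group + age + (1|subject)` on subject × region rows
and reports the interaction. Per-group associations report raw Pearson
correlations plus a group × slope interaction from
`y ~ x * group + age`. No multiple-comparison correction is applied
anywhere — network measures are not independent — and the run report
records this.

# The synthetic cohort generator

The generator reduces each subject's network state to two scalars and
builds everything else from them:

* $\gamma$ — overall connectivity scale. The subject's correlation
  matrix has mean off-diagonal correlation exactly
  $\rho_0 \gamma$ ($\rho_0 = 0.22$), so $\gamma$ *is* latent connection
  strength (reported as `true_strength` $= 100\gamma$).
* $g$ — global-vs-local mixing of the correlation kernel, the
  topological organization parameter. Correlations follow
  $(1-g)\,e^{-d_{ij}/\lambda} + g$ on a ring of regions
  ($\lambda = 0.1$ of the ring): at low $g$ the network is
  lattice-like (normalized efficiency well below 1), at high $g$
  random-like (normalized efficiency near 1). The matrix is
  renormalized so that the mean correlation — hence strength — is
  *independent of $g$ by construction*; organization and connectivity
  are decoupled at the source, mirroring the dissociation the analysis
  is designed to detect.

A fraction (12%) of regions are hubs whose rows are multiplicatively
boosted (×1.5 on hub-incident pairs), strong enough that the 2-SD rule
recovers exactly the planted set. Entrywise jitter is added and the
matrix is projected to the nearest correlation-like positive
semi-definite matrix (eigenvalue clipping), then the mean correlation is
restored exactly by shrinking toward the identity — which preserves
positive semi-definiteness.

BOLD-like signals are temporally white multivariate Gaussian draws with
the target covariance, bandpass-filtered (order-2 Butterworth,
zero-phase) into the analysis band, plus a small white noise floor.
Because every region passes the identical filter, wavelet-scale
correlations converge to the target as the series lengthens — the test
suite checks this at T ∈ {128, 512, 2048} — with no hemodynamic
modeling, which wavelet-correlation recovery does not need.

## Imposed disease effects and their defaults

All effects are expressed along years-to-expected-onset $t$ (negative
before onset; carriers drawn uniformly on [−25, −1], patients on
[0, +10], gene-negative relatives on [−25, +5] with no effect — the
covariate must exist for them). Expected onset age is drawn per family
(N(58, 7²) years), and age = onset age + $t$, which reproduces the
characteristic group age structure (patients oldest, carriers
youngest).

* **Connectivity decline**: $\gamma = 1 + s\,t$ with
  $s = -0.01/\mathrm{yr}$ for carriers and patients — a *continuous*
  decline through onset. A step deficit at diagnosis
  (`ftdStrengthScale` < 1) is available and is what the
  parameter-recovery simulations impose, but the default is 1: a group
  step would register as an onset discontinuity in the piecewise model,
  contradicting the emulated observation of a clear group deficit
  *without* a strength breakpoint. A by-product is that carriers sit
  somewhat above gene-negatives in mean strength; the emulated study
  saw the same ordering, more weakly.
* **Organization trajectory**: the score driving $g$ rises slightly
  toward onset (+0.0015/yr), offset upward in all mutation carriers
  (+0.03), then falls after onset (−0.004/yr). The pre-onset rise and
  post-onset fall are sized so the carrier and patient group *means*
  nearly cancel: the breakpoint test, which exploits the years
  gradient, detects the trajectory while the group contrast does not —
  exactly the dissociation of interest. The net linear years-trend is
  near zero, consistent with the absence of simple linear
  relationships in the emulated study.
* **FTD heterogeneity**: patients carry extra log-normal connectivity
  spread (sd 0.12 vs 0.04 for everyone else), emulating the clinical
  heterogeneity of the symptomatic stage. This is also what makes the
  within-patient strength–volume coupling survive measurement (below).
* **Volume**: % of total intracranial volume, declining with age, with
  an atrophy shift in patients. Within the patient group only, volume
  is coupled to latent strength at target correlation 0.8; after
  wavelet-estimation attenuation the *measured* association lands near
  0.5, and the carrier group's raw correlation stays at chance.
* **Cognition**: z-scores loading on standardized latent strength
  (loadings 0.25–0.35) with a −2 shift in patients, emulating the
  impaired-patients / normal-carriers profile. No language correction
  is modeled.
* **Spike percentages**: 100 × Beta(1, 25.2), giving
  P(spike > 10%) = $0.9^{25.2}$ = 7.0% — the exclusion rate of the
  emulated study (13 of 185) — so the QC stage is genuinely exercised.

Site and gene random intercepts are injected into both outcomes (sds
2 and 1.5 strength units; 0.004 and 0.003 score units) so the random
effects of the inference layer have something real to absorb.

## Effect-size calibration

The desk-scale demo (90 regions, T = 384, 50 nulls; `demoRunConfig()`)
was used to size the effects. The binding constraint is that
wavelet-correlation estimation error is *common-mode* across the edges
of one subject — the realized variance of the latent factors fluctuates
as $1/\sqrt{T_{\mathrm{eff}}}$, with $T_{\mathrm{eff}} \approx T/2^j$ —
so a subject's total measured strength carries an irreducible ~10%
noise that no amount of edge-averaging removes. The default effect
sizes are chosen so the imposed pattern clears this noise floor at the
emulated group sizes, and the demo acquisitions are longer than the
emulated study's median scan for the same reason; both choices are the
package's scale decisions for reproducible desk-scale analysis, stated
here once. The same coupling makes measured normalized efficiency
weakly dependent on $\gamma$ (higher signal-to-noise preserves the true
topology better), which is why raw group means of normalized efficiency
need not reproduce the latent score ordering even though the
age-adjusted inferential pattern does.

## What the generator does not emulate

No hemodynamic response, no head-motion structure beyond the scalar
spike percentage, no family pedigrees (each subject is its own family;
per-family onset clustering is not modeled), no multi-echo or field
strength effects, no regional specificity of atrophy, and cognitive
scores are driven by a single latent axis. Passing tests therefore show
that the *analysis* recovers what the generator imposes under realistic
noise — they do not certify performance on real acquisitions, where
nuisance structure is richer.

# Numerical choices

* CVT parcellation: Lloyd iterations with BLAS-based nearest-centroid
  assignment; empty parcels reseeded at the worst-assigned voxel (which
  cannot increase the quantization energy); ties in assignment broken
  toward the lower parcel index; stops on label convergence.
* Graph build: target edge count `round(density · n(n−1)/2)`, never
  below the n−1 backbone edges; edge ties broken by order (measure-zero
  for continuous weights).
* Hub rule: strict ">" at mean + 2 SD, sample (n−1) standard
  deviation; zero variance yields an empty hub set, not an error.
* Mixed models: lme4 REML with singular fits tolerated (variance
  components may legitimately be zero in synthetic data); LRTs refit by
  ML; Satterthwaite df via lmerTest.
* PSD projection: eigenvalues clipped at 1e−8, diagonal restored, then
  exact mean-correlation restoration by identity-shrinkage.
* Determinism: every stochastic stage takes a seed; sub-seeds are
  derived arithmetically (kept below 2³¹), and RNG state is always
  restored, so library calls never perturb the caller's stream.

# Known limitations

* The years-to-onset distributions are artifact choices (the emulated
  study does not publish them); uniform windows are transparent but
  unrealistic in the tails.
* The ring-kernel correlation model has one spatial scale; real
  connectomes mix modular, hierarchical and distance structure.
* At desk scale the single-subject estimator noise dominates individual
  differences; regional analyses at the full 471-region scale are
  supported by the same code paths but not exercised by default.
* "Non-significant" assertions in the end-to-end qualitative pattern
  are inherently α-level events: under the generator's null they fail
  with probability ≈ 0.05 per assertion for any fixed seed.
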