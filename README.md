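# resilnet

Functional network resilience analysis for presymptomatic genetic
frontotemporal dementia (FTD).

## The problem

In families carrying pathogenic C9orf72, MAPT or GRN variants,
neurodegeneration begins years before symptoms, yet carriers remain
cognitively well. One candidate explanation is *functional network
resilience*: the brain maintains an efficient topological organization
of its functional connectome even as brain volume and raw connectivity
decline, and symptom onset coincides with the collapse of that
organization. Testing this requires a pipeline that (i) estimates
frequency-band-specific functional connectivity from parcellated fMRI
time series, (ii) summarizes the resulting weighted graphs with
strength and path-length metrics normalized against degree-preserving
null models, and (iii) asks the statistical questions — group deficits,
a breakpoint at expected symptom onset, hub vulnerability, and
associations with atrophy and cognition — with the mixed-effects
machinery a multi-site family study needs.

`resilnet` implements that pipeline for computational neuroscientists
and methodologists. Because genetic-FTD cohort data are not publicly
distributable, the package includes a first-class seeded synthetic
cohort generator that emulates the statistical structure of such a
study (three groups of 80/68/24, per-family expected onset ages,
TR ≈ 2.2 s acquisitions, hub-structured covariance, disease effects
along the years-to-onset axis), so every stage is testable end-to-end.

## The measures

For a subject's weighted graph with correlations `w_ij`:

- **connection strength** (weighted degree): `s_i = Σ_j w_ij`; global
  strength is `Σ_i s_i`, computed on the full positive-weighted graph;
- **global efficiency**: `E = mean_{i≠j} 1/d_ij` with path lengths
  `d = 1/w` on a density-thresholded graph (maximum-spanning-tree
  backbone, default 10% density), normalized by the mean of 500
  degree-preserving, weight-multiset-preserving null graphs;
- **closeness (farness)**: `mean_j d_ij` per node, null-normalized;
- **hubs**: regions more than 2 SD above the mean reference strength,
  defined in the gene-negative group;
- wavelet connectivity: Pearson correlation of MODWT (Daubechies-4)
  detail coefficients at the dyadic scale best overlapping
  0.0675–0.125 Hz (scale 2 at TR 2.2 s), boundary coefficients
  discarded; subjects with > 10% motion spikes excluded.

Inference: `outcome ~ group + age + (1|site) + (1|gene)` with
Satterthwaite degrees of freedom; piecewise regression
`outcome ~ t + (t−k)₊ + 1[t>k] + age` at knot `k = 0` years from
expected onset (joint F/likelihood-ratio test of the breakpoint terms);
`outcome ~ hub × group + age + (1|subject)` for hub vulnerability; and
per-group Pearson correlations with a `x × group` interaction for
volume/cognition associations. No multiple-comparison correction is
applied (network measures are not independent).

## Worked example

```r
library(resilnet)

selectWaveletScale(2.2)
#> WaveletBand: scale 2 (0.05682-0.1136 Hz, d4)

# a synthetic cohort at the emulated study's size (metadata level:
# subject table + latent network state, no signal synthesis)
cohort <- generateCohort(cohortConfig(seed = 42), detail = "metadata")
tbl <- analysisTable(cohort$subjects,
                     cohort$groundTruth$perSubject[
                       , c("subject_id", "true_strength",
                           "true_efficiency_score")])

fitGroupContrast(tbl, "true_strength", c("ftd", "carrier"))
#> ContrastResult [lmm] ftd - carrier: estimate = -17.58 (se 2.069),
#>   t(166.6) = -8.494, p = 1.063e-14

fitBreakpointModel(tbl, "true_efficiency_score")
#> BreakpointResult [lmm] knot at 0 years (n = 92):
#>   pre slope 0.001646/yr, post slope -0.002826/yr (change -0.004472),
#>   level change 0.004562
#>   joint breakpoint p = 1.28e-05
```

The contrast says symptomatic patients sit ~17.6 strength units (about
18% of the baseline 100) below presymptomatic carriers after adjusting
for age, with site and gene as random intercepts and Satterthwaite
df ≈ 167. The breakpoint fit recovers the generator's imposed
trajectory: organization rises slightly toward expected onset
(+0.0016/yr), then declines after it (−0.0028/yr), a significant
breakpoint (p ≈ 1e−5) — the resilience-then-collapse signature.

The full measurement pipeline (BOLD synthesis → wavelet connectivity →
graphs → null normalization → inference) runs end-to-end with

```r
report <- runPipeline(demoRunConfig(seed = 1))   # ~2 min, 1 CPU
report
```

writing `subjects.tsv`, per-subject connectivity matrices,
`metrics.tsv`, `nodal_metrics.tsv`, `contrasts.tsv`, `breakpoints.tsv`,
`associations.tsv` and `run.log` under the configured output directory.
A thin command-line wrapper is installed at
`inst/cli/resilnet.R` (`Rscript resilnet.R run --seed 1`).

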