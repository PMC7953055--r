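---
title: "Lesion-modulated language-network connectivity: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Lesion-modulated language-network connectivity: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(langnet)
```

## The scientific problem

Gliomas infiltrating language-related cortex do not merely silence the tissue
they occupy: they perturb the synchrony of the whole distributed language
network (LN). On the core–periphery view of language organisation, the left
frontotemporal subsystems are the network's indispensable core and their
right-hemisphere homologues its periphery, so a lesion's *position* — not only
its size — should determine how far its functional footprint spreads.
`langnet` implements a complete, testable analysis pipeline for this question:
from (synthetic) BOLD time series, through edge-wise functional connectivity
over ten canonical LN modules, to hemispheric mean-network-connectivity (mNC)
statistics and tumor-volume associations.

Because real patient imaging of this kind is not publicly accessible, the
package pairs every analysis stage with a synthetic-cohort generator whose
covariance structure *encodes* the core–periphery lesion model. Every group
inference the pipeline makes can therefore be exercised against data whose
ground truth is known, and the generator itself is first-class, tested code.

## The network and its indices

The ten LN modules (shipped as `ln_rois()`, with MNI peak coordinates and
cluster sizes) are the bilateral inferior frontal (IFG), middle frontal (MFG)
and superior temporal (STG) gyri, midline superior frontal gyrus (SFG) and
precuneus (PC), and the two cerebellar posterior lobes (CPL). All
`choose(10, 2) = 45` unordered pairs are the network's edges; each edge value
is the Pearson correlation of the two node time series after Fisher's
variance-stabilising transform, `z = atanh(r)`.

Four lesion subsystems partition the six core nodes: LF = {lIFG, lMFG},
LT = {lSTG}, RF = {rIFG, rMFG}, RT = {rSTG}; midline and cerebellar nodes
belong to none. The mNC indices are averages of Fisher-z edges over the six
core homotopic nodes:

* `lFCw`, `rFCw` — the three within-hemisphere edges on each side,
* `FCb` — the nine interhemispheric edges,
* `FCg` — all fifteen core edges, so identically
  `FCg = (3·lFCw + 3·rFCw + 9·FCb) / 15`.

Whether the "global" index should span all ten nodes is ambiguous in the
field's usage; both are implemented (`compute_mnc(scope = "core" | "all")`)
and the six-node form is the default, because the homotopic balancing that
motivates the indices is defined on the core nodes. Averages are taken on the
z scale, not the r scale: every downstream statistic operates on z, and
averaging before back-transforming avoids the bias of averaging bounded
correlations.

## The synthetic lesion model

`cohort_config()` fixes the study conditions; `generate_cohort()` draws the
cohort. Defaults encode a five-group design — LFG (27), LTG (26), RFG (29),
RTG (27) patients by lesioned subsystem plus 42 healthy controls (HC) — with
200 time points per subject at TR = 2 s.

The HC baseline correlation matrix is hemispherically symmetric:
within-hemisphere pairs at 0.45, homotopic pairs at 0.50, all remaining pairs
(including everything touching midline nodes) at 0.25 — plausible
resting-state magnitudes that bracket reported patient-range means. Lesion
effects act additively on the Fisher-z scale and scale linearly with tumor
volume V (cm³):

* **Left-hemisphere lesions** (LFG, LTG): edges incident to the lesioned
  subsystem lose `a_dir · V`; *every other edge* loses `a_ind · V`. The
  near-global `a_ind` term is the model's core claim — damage to core
  subsystems disturbs communication among remote, structurally intact
  modules.
* **Right-hemisphere lesions** (RFG, RTG): only edges incident to the
  lesioned subsystem lose `a_dir · V`; the contralesional left core triangle
  *gains* `b_con · V`, a volume-coupled compensation of the intact core.

After the shifts, `tanh` maps back to correlations and an eigenvalue-clipping
repair (floor 1e-6, always reported) restores positive definiteness when the
largest left-hemisphere lesions push many edges strongly negative. Tumor
volumes are log-normal with mean 105 and SD 62 cm³, truncated to [10, 300] —
the reported per-group ranges in spirit. A per-subject random intercept
(SD 0.06 on z) models trait-level connectivity differences; it shifts all
edges of a subject equally, so the HC ground truth keeps `lFCw = rFCw`
exactly.

### Choosing the slopes

The slope magnitudes are the one place where the generator's design had to
balance several published effects at once. `b_con = 0.8e-3` per cm³ makes the
positive lFCw–volume correlation in right-lesion groups strong enough to be
recovered reliably at n ≈ 27–29 without producing a significant lFCw
*increase* against HC (the published pattern shows no lFCw difference for
right-lesion groups). `a_dir = 3.2e-3` is set so that even the single-node
subsystems (LT, RT), which touch only five of the fifteen core edges, produce
the reported strong interhemispheric and global reductions at these group
sizes; an initial purely analytic choice of 2.4e-3 underestimated the
volume-slope contribution to patient-group variance and left the
right-temporal global reduction under-powered, so the value was recalibrated
once against a 50-replicate design run and frozen. `a_ind = 2.9e-3` sits
deliberately close to `a_dir`: left-lesion patients show near-equal ipsi- and
contralesional decline (their paired ipsi-vs-contra tests are mostly null),
while the large `a_dir`-only asymmetry in right-lesion groups makes their
paired tests the reliably significant ones.

With these defaults, 50 seeded replicate cohorts recover the qualitative
published structure in the proportions the test suite asserts: the
tumor-volume correlation sign pattern in 98% of replicates, the group-level
reduction pattern in 88%, the hemispheric direct/indirect typology in 100%,
and a null HC hemispheric-balance test in 96%.

### What the generator does not emulate

The synthetic cohort is multivariate normal with temporally white signals:
no autocorrelation, no physiological noise spectra, no motion artefacts, no
spatial smoothness beyond the phantom blobs, and lesion effects that are
exactly linear in volume with a single global dose for all edges of a class.
Passing tests therefore demonstrate that the *pipeline* recovers the encoded
structure at realistic sample sizes — not that real BOLD data satisfy the
model. In particular the edge-wise t tests inherit exact normality here,
so their calibration on real, autocorrelated data would be somewhat more
conservative or liberal depending on the effective degrees of freedom.

## Statistics kernel

All procedures are implemented from their defining forms and cross-checked
in the test suite against independent references:

* **Two-sample t** — Student pooled-variance by default
  (`df = n_a + n_b − 2`), the conventional reading of an unqualified
  "independent two-sample t test"; Welch behind `var_equal = FALSE`. The
  one-tailed direction for edge tests is *patient < HC*: the hypothesis is
  reduction, and gains are deliberately not tested by default.
* **One-way ANOVA** — from raw data or directly from printed
  mean ± SD / n summaries (`anova_oneway_summary()`), the form needed to
  recompute published demographics tables.
* **Tukey HSD** — studentized-range p values via R's `ptukey` (numerical
  integration; accurate to well beyond 4 decimals), Tukey–Kramer harmonic
  form for unbalanced groups.
* **Two-level repeated-measures ANOVA** — computed exactly through
  difference scores: with a two-level within factor the main-effect
  F(1, N − k) needs no sphericity machinery, and the single-group case
  reduces to the squared paired t. The error df is N − k; reports that quote
  N instead of N − k for this design differ only in that convention.
* **Pearson chi-square** — no Yates continuity correction: recomputation of
  the published 5×2, 3×4 and 2×4 demographic tables (4.524, 5.66, 0.692)
  matches the uncorrected statistic.
* **Benjamini–Hochberg FDR** — step-up with inclusive boundary
  (`p_adj ≤ α`), as the step-up definition requires; Benjamini–Yekutieli
  behind a flag for arbitrary dependence. The FDR family for edge tests is
  the 45 edges within one subgroup-vs-HC comparison, matching a
  per-comparison correction; a pooled variant is available.

One published value resisted recomputation: the age ANOVA prints 0.842 where
the printed summaries give 1.04. The discrepancy is noted and age is simply
not used as a numeric anchor; education and tumor volume, which do
recompute, are.

## Image-space stages

The phantom path exists to validate the volumetric stages at desk scale.
`simulate_phantom()` embeds Gaussian spatial blobs (SD 10 mm) at the ROI
coordinates on a configurable grid (default 24³ voxels of 8 mm), carves an
ellipsoidal tumor of the requested volume into the lesioned subsystem's
parcel, and attenuates the signal inside it. `group_ica()` is a deliberately
small group spatial ICA: temporal concatenation, per-voxel centring with a
single variance scale per subject (per-voxel z-scoring would promote
pure-noise voxels to source-level variance), PCA via the time-by-time Gram
matrix, and fixed-point ICA with symmetric decorrelation under a fixed seed.
Component maps are standardised weights; thresholding them at T-like values
(default 5 cerebral, 3 within a supplied cerebellar mask) is a documented
approximation to software that thresholds voxelwise T maps. Cluster
formation uses 26-connectivity (6 behind a flag), discards clusters under 10
voxels, and breaks exact peak ties by lowest linear index with a warning.
Sphere ROIs contain every voxel whose centre lies within the radius, so a
6 mm sphere on a 3 mm grid holds 33 voxels and a radius below the voxel size
degenerates to the peak voxel.

Subsystem assignment of a lesion is by maximal parcel overlap, with two
safeguards the clinical-reading origin of the labels makes necessary: exact
ties break toward the larger overlap *fraction* of the parcel (then
lexicographically, with a warning), and any lesion whose top-two overlaps
differ by less than 10% is flagged ambiguous rather than silently assigned.

## Numerical choices and degenerate inputs

Band-pass filtering is a zero-phase (forward–backward) 4th-order Butterworth
design over 0.01–0.08 Hz; the test suite verifies ≥ 95% amplitude
preservation at 0.04 Hz and ≥ 90% rejection at 0.2 Hz with TR = 2 s. Global
signal regression is deliberately not performed by default. Degenerate
inputs fail loudly and by name: zero-variance nodes, correlations at ±1,
zero pooled variance with unequal means, missing within-subject levels, and
zero contingency margins all raise errors that identify the offending node,
edge, subject or margin.

## Problem sizes in the shipped checks

The test suite and acceptance script use full-size cohorts (151 subjects,
T = 200) for single-run signatures, 50 seeded replicates for pattern
recovery, 500 replicates for FDR null calibration (at reduced per-replicate
size: 20 vs 20 subjects, T = 60, where the property is size-free), and
4-replicate means over a 3-point slope grid for the dose–response
monotonicity check, whose grid sits deliberately below the 64-edge detection
ceiling.

## A worked example

```{r example, eval = FALSE}
library(langnet)

result <- run_pipeline(pipeline_config(cohort = cohort_config(seed = 1)))
result
glance(result$mnc_anova)     # one-way ANOVA per mNC index
tidy(result$mnc_anova)       # all Tukey pairwise comparisons
result$tv_correlation        # per-subgroup mNC-volume correlations
autoplot(result$mnc_anova)   # group-means figure
plot_tv_correlation(result$mnc[result$mnc$group != "HC", ])
```

## Known limitations

The ICA path is validated on phantoms only and the default pipeline uses the
shipped canonical ROI set; real-data ICA would add back-reconstruction and
stability analysis that are out of scope. The typology chi-square is
reported on the synthetic cohort's own counts — the corresponding published
statistic depends on unavailable patient data, so no numeric match is
claimed. Dynamic connectivity, partial correlations and graph-theoretic
summaries beyond the mNC indices are out of scope.
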