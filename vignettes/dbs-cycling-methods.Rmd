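---
title: "Methods: DBS On/Off cycling fMRI and stimulation-field connectivity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: DBS On/Off cycling fMRI and stimulation-field connectivity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stimcycle)
```

# The problem

Deep brain stimulation (DBS) of the anterior limb of the internal capsule
is used for severe, refractory OCD, but which brain networks therapeutic
stimulation actually engages is hard to observe. One way to measure it is
a cycling paradigm: the implanted device alternates stimulation On and Off
in one-minute blocks while BOLD fMRI is acquired, and the On-Off response
is mapped per stimulation configuration. This package implements the full
analysis chain for such experiments — run-level GLM contrasts, group
mixed-effects comparison of therapeutic versus non-therapeutic
configurations, spatial permutation statistics over a network parcellation,
and structural connectivity from the estimated stimulation field — together
with a synthetic-data generator so every stage is testable without any
patient data.

The default study layout mirrors the experiment the workflow targets: five
subjects, three of them treatment responders; 23 six-minute runs at
TR = 2 s; six therapeutic runs spread over the responders and seventeen
non-therapeutic runs over all five subjects; stimulation at 5–6 mA through
adjacent bipolar contact pairs; the On/Off cycle is 60 s per state with an
8-s amplitude ramp at the start of each block, and every run starts at the
beginning of an Off block.

# Run-level model

## Design

The stimulus regressors are On and Off boxcars that are 1 during the
respective plateau and 0 during the 8-s ramps, each convolved with a
canonical double-gamma HRF (positive lobe peaking at 6 s, undershoot at
16 s, peak-to-undershoot ratio 6, kernel normalised to maximum 1 and
sampled at TR). Modelling *both* states and contrasting the parameter
estimates, rather than a single On regressor, matches how cycling
experiments are conventionally analysed; leaving the ramps out of both
boxcars is what keeps On + Off from being a constant column. Whether ramps
should instead carry a linearly interpolated level is genuinely open — both
modes are implemented (`ramp_mode`), ramps-excluded is the default, and the
design-matrix constructor rejects near-collinear designs (multiple
correlation of a condition column on the rest above 0.9), which is exactly
what happens at `ramp_s = 0`.

Drift is modelled by Legendre polynomials of orders 0–3 over the run (the
AFNI `polort` convention): an intercept plus three drift terms. The
default design is therefore 180 frames × 6 columns.

## Scaling and units

Each voxel's time series is scaled to a mean of 100 before fitting, so with
unit-peak regressors the betas read directly as percent signal change and
the `[On] − [Off]` contrast is in percent units. Scaling is per voxel (the
AFNI convention) rather than by a global mean, so the interpretation holds
voxel by voxel. Voxels with non-positive means are masked out with a
warning rather than silently rescaled.

## Censoring

Framewise displacement is the absolute sum of relative motions: the
frame-to-frame absolute deltas of the three translations plus the three
rotation deltas converted to arc length on a 50-mm sphere (the Power
convention; the radius is configurable). DVARS is the root-mean-square
frame-to-frame intensity difference over in-mask voxels. The "standardized"
rescaling is not uniquely defined across tools; here raw DVARS is divided
by its within-run median, which is robust, dimensionless and gives a
stationary run a median of 1, so the conventional censoring threshold of
1.5 retains its meaning. Frames with FD > 0.5 mm *or* standardized
DVARS > 1.5 (both strict inequalities) are censored by row deletion at fit
time; the first frame of a run, which has no predecessor, gets FD = DVARS
= 0 and is never censored by these metrics alone.

# Group inference

Run-level contrasts are aggregated to parcel means and each parcel is fit
with the REML mixed model

    contrast ~ therapeutic + responder + (1 | subject)

reporting the therapeutic fixed effect with Satterthwaite degrees of
freedom. Therapeutic runs occur only in responders, so the two fixed
effects are partially confounded; the model keeps both by default and a
reduced single-factor mode exists. With five subjects the random-intercept
variance frequently estimates to the boundary; such singular fits fall
back to OLS on the fixed effects — a documented, logged behaviour rather
than a failure, and on balanced data the fallback estimate is exactly the
difference of condition means.

For voxel-wise maps the package reproduces the cluster-extent *procedure*:
Monte-Carlo simulation of smoothed Gaussian noise fields on the analysis
grid, two-sided voxel thresholding at `voxel_p`, connected components
under face adjacency (NN = 1; edge and corner adjacency available), and
the smallest cluster size whose family-wise chance probability is at most
alpha. A cluster-size threshold is specific to the grid, smoothness and
software that produced it, so no particular voxel count is treated as a
reference value; the testable properties are monotonicity (larger with
more smoothness, no larger with stricter voxel thresholds) and agreement
of the component labelling with a flood-fill oracle.

# Network permutation statistics

The core statistic asks: is the average suppression (negated mean On-Off
contrast) across the parcels of one network larger than chance, where
"chance" preserves the parcel values and the network sizes but permutes
which parcels belong to which network? Parcel vectors are first averaged
across the runs of a condition (equal run weights), giving one observed
vector per condition; parcels are weighted equally regardless of voxel
count.

Surrogates are uniform random permutations of the assignment vector
(sampling with replacement from the permutation group, identity not
excluded), 10,000 by default. The one-tailed p-value for a network is the
proportion of surrogates whose suppression reaches the observed value,
floored at `1/n_perm`. Ties count as exceedances — the conservative
permutation convention — which gives the two behaviours a correct test
must have: a constant parcel vector (no network structure at all) yields
p = 1, while a network whose observed suppression no surrogate can beat
reports the test's resolution, `1/n_perm = 1.0e-4` at 10,000 surrogates,
because a random permutation essentially never reproduces the full member
set. Comparisons use a small floating-point tolerance so surrogates that
differ from the observed value only by summation order are treated as
ties. A Bonferroni correction over the seven networks is applied
(`min(1, 7p)`).

The two-sided condition-difference test applies the same machinery to the
per-parcel difference of the condition means, comparing absolute network
means. The one-sided test is deliberately *not* shift-invariant — the
suppression statistic is absolute, and the test answers "is this network's
suppression large", not "larger than the map average"; the two-sided
difference test applied to a difference vector is shift-invariant. The
streamline-connectivity test reuses the one-sided machinery with the sign
convention flipped: larger mean member-parcel streamline count = more
connected.

# Stimulation field and structural connectivity

The stimulation field (volume of activated tissue, VAT) of a bipolar
configuration is modelled as the union of two spheres centred at the
active contact centres with radius `r = k * sqrt(amplitude_mA)`,
`k = 1.8 mm/sqrt(mA)` by default. This is a declared geometric surrogate,
not a fitted conductor model: its only role downstream is to select
streamlines, every statistic is agnostic to how the VAT was produced, and
an externally computed binary mask can be supplied instead
(`vat_from_mask()`).

Streamline filtering keeps a streamline if any vertex lies inside the VAT
or any segment intersects it — an exact segment-sphere test, verified in
the test suite against dense 0.05-mm resampling, so trajectories that
cross a sphere between two outside vertices are not missed. Each filtered
streamline is assigned to a parcel by its endpoint farther from the VAT
centroid (its distal termination); endpoints in background count as
"unassigned". Per-network fractions are counts over all filtered
streamlines, so network fractions plus the unassigned fraction sum to 1; a
traversal-count mode and a cortical-only denominator are provided as
options since tractography pipelines differ on both conventions.

# The synthetic-data generator

The generator exists so that the statistical machinery can be validated
against known truth. A voxel time series is

    y(t) = 100 + drift~(t) + a_v * r~_on(t) + e(t)

where `r_on` is the same HRF-convolved On regressor the GLM uses, `a_v` is
the per-network On-Off amplitude of the voxel's parcel in percent units
(default therapeutic profile: −0.3% in the default mode network, 0
elsewhere; non-therapeutic: 0 everywhere), drift is a Legendre polynomial,
and `e` is AR(1) noise (marginal SD 1%, lag-1 coefficient 0.3 by default).
The tilde denotes within-run mean-centering: it makes every noiseless
voxel mean exactly 100, so the mean-100 scaling step is the identity and
the GLM — whose intercept absorbs centering constants — recovers the
injected amplitudes to machine precision. This exactness is a deliberate
design invariant (simulator and GLM share one regressor constructor);
model-mismatch experiments (e.g. linear-ramp effect against a
ramps-excluded design) are available by setting the two `ramp_mode`
options apart, and are not the default. Motion traces are slow random
walks with occasional 1-mm spikes that also perturb the volume so DVARS
sees them.

Atlases are grown by seeded region growing inside an ellipsoidal brain
mask — 100 parcels in 7 networks by default, with the parcel-to-network
assignment in contiguous blocks. No spatial realism is attempted or
needed: every permutation statistic depends only on the labels. Per-network
effect sizes are free parameters of the generator, not literature values;
−0.3% was chosen as a plausible block-design effect that the 23-run design
detects without being trivial. Tractograms are generated per subject by
drawing each streamline's destination from a configurable probability
vector over networks plus an "elsewhere" bucket (defaults: therapeutic
fields weighted towards the default mode and limbic networks,
non-therapeutic flat), with VAT-passing streamlines terminating exactly at
parcel voxel centres — so the filtered network fractions recover the
weights up to binomial error, which is the tested parameter-recovery
property.

What the generator does *not* emulate: anatomy, surface geometry, EPI
distortion, physiological noise, electrode artifacts, spatial noise
correlations, and realistic streamline curvature. Passing tests therefore
demonstrate the correctness and calibration of the *statistics* under the
stated model, not robustness to every property of real data.

# Numerical and scale choices

* All randomness flows through explicit integer seeds (`withr::with_seed`,
  so the caller's RNG state is untouched); per-run and per-stage seeds are
  small offsets of a master seed, kept far below 2^31. Identical
  configurations produce byte-identical outputs, including gzipped NIfTI.
* The workflow's synthetic volumes default to a 24-voxel cube at 4 mm
  (16-voxel cube in the analysis scripts) and tractograms to a few
  thousand streamlines; these are the package's desk-scale study sizes,
  chosen so the whole workflow and its tests run in minutes while leaving
  all statistical structure intact. The generator accepts the real-data
  scale (e.g. 200,000 streamlines) unchanged.
* Permutation tests default to 10,000 surrogates (resolution 1.0e-4);
  cluster Monte-Carlo uses at least 1,000 iterations for stable
  thresholds (fewer warns).
* Degenerate inputs are handled explicitly: empty parcels give NaN means
  with a warning, non-positive-mean voxels are masked, singular mixed fits
  fall back to OLS, rank-deficient or near-collinear designs error with
  the offending columns named, and empty VATs error.

# Known limitations

* The mixed model with five subjects is at the edge of what random-effect
  estimation supports; the OLS fallback keeps estimates sensible but the
  reported parcel-level p-values inherit small-sample approximations
  (Satterthwaite). The type-I calibration test holds at the 5% level
  under the generator's conditions.
* The sphere-pair VAT is a stand-in with a configurable radius law; no
  claim is made that it approximates tissue activation physics.
* Streamline-to-parcel assignment by distal endpoint, and the
  all-filtered-streamlines denominator, are conventions; both switches
  exist because tractography pipelines disagree on them.
* The cluster-extent null uses stationary Gaussian smoothness, not an
  estimated autocorrelation function.
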