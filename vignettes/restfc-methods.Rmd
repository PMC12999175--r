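---
title: "restfc: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{restfc: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(restfc)
```

# The analysis problem

Resting-state functional connectivity (FC) — the Pearson correlation
between the spontaneous BOLD fluctuations of two brain regions — is one
of the few measures comparable across populations as different as
adults and neonates. The design this package serves contrasts the
long-range connectivity of visual cortices in three groups: sighted
adults, congenitally blind adults, and 2-week-old infants. The
scientific contrasts are (i) whether occipital seeds couple more
strongly with prefrontal cortex (PFC) or with non-visual sensorimotor
cortex (A1, S1/M1); (ii) whether that coupling is lateralized (within-
vs between-hemisphere); and (iii) how similar whole connectivity
matrices are across groups.

Everything downstream of ROI extraction is implemented here: QC,
denoising, connectivity summaries, and group inference. Image-level
processing and ROI definition are upstream; the ROI catalog (18
bilateral regions: three secondary-visual seeds defined by language,
math, and executive task responses, V1, three matching PFC targets, A1,
S1/M1) is treated as given metadata.

# Quality control

**DVARS.** At frame $t \ge 2$, $\mathrm{DVARS}_t = \sqrt{\tfrac1R
\sum_r (x_{t,r} - x_{t-1,r})^2}$. The first frame has no predecessor;
we set it to 0 and it can never be flagged on its own — the source
procedure leaves this boundary undefined, so the convention is fixed
and documented here. DVARS is computed on the channels available at
this data level (ROI series), not on image volumes.

**Outlier flagging.** A frame is an outlier when DVARS *strictly*
exceeds $Q_{75} + 1.5\,(Q_{75} - Q_{25})$. Quantiles use linear
interpolation between order statistics (R type 7); this matters — flag
sets depend on the quantile convention, so it is part of the contract.
Thresholds are computed per run per subject (pooling runs within
subject is possible by concatenating before calling the flagger, but
per-run is the default).

**Window selection.** For infant-length runs, the contiguous window of
exactly $W$ frames (default $\min(1600, T)$) minimising the flagged
count is retained; ties break to the earliest start (the procedure's
tie rule is unstated; earliest-start is deterministic and simple).

**Exclusion.** Infants: excluded when the outlier count inside the
retained window strictly exceeds 10% of it (160 of 1600 by default —
"more than 160" is read as a strict inequality, so 160 is retained).
Adults: excluded when maximum translation strictly exceeds 2 mm or
rotation 2°. Any group: excluded on signal dropout, an ROI whose mean
intensity falls strictly below $\mu - 3\sigma$, with $\mu,\sigma$
computed across the subject's 100 parcel means ($\sigma = 0$ yields no
dropout).

# Denoising

Default order: **detrend → CompCor regression → temporal filter →
censor**. The source procedure does not state whether censoring
precedes filtering; we filter first so the IIR filter never runs across
gaps created by frame deletion, and expose `censor_before_filter` for
the alternate order. The order actually applied is recorded in the
provenance strings of every `clean_series`, so a change is never
silent.

**Filter.** Zero-phase (forward–backward) 4th-order Butterworth,
low-pass 0.08 Hz; adult runs add a 1/150 Hz high-pass as a second
zero-phase stage cascaded in the same call — equivalent to a band-pass
at those edges, with each stage a standard design. The filter type is
not stated by the source ("low-pass filtered (0.08 Hz)" only);
zero-phase Butterworth is the common choice in rs-fMRI toolchains, and
order/type are configurable. No `signal`-style package is available in
the target environment, so the design (bilinear transform of the
analog prototype) and `filtfilt` (odd-reflection padding plus
steady-state initial conditions) are implemented in-package; both were
validated against SciPy's implementations to ~1e-14 during
development.

**CompCor.** CSF- and WM-like channels are standardized and the first
$k = 5$ principal-component time courses (ordered by explained
variance, mutually orthogonal) are regressed out of every ROI series,
with an intercept always included. Zero-variance channels are dropped
with a warning. For infants, the original study relied on upstream ICA
denoising instead of CompCor; at this artifact's data level the
generator emulates physiological artifact as shared compartment
sources, so compartment-PC regression is the appropriate analogue and
is applied to all groups by default (`compcor_k = 0` disables it).

**Censoring.** Flagged frames are deleted outright — no interpolation;
correlations use retained frames only. Fewer than 10 retained frames is
an error, not a silent degenerate FC.

# Connectivity summaries

Block averages are arithmetic means of raw $r$ over all seed×target
pairs, because the group summaries being emulated are reported as mean
$r$; Fisher-z averaging is available behind `fisher = TRUE`. Laterality
splits the seed–PFC block into same- and opposite-hemisphere pairs.
Matrix-to-matrix similarity is the Pearson correlation of the
vectorized strict lower triangles of the two group-mean matrices over a
common ROI subset (which cells enter is unstated in the source; the
strict lower triangle of the designated subset is fixed here).
Group-mean matrices average subject-level $r$ (not $z$), consistent
with the raw-$r$ default.

The split-half noise ceiling divides the retained series into two
*contiguous* halves (an odd frame goes to the first half), computes
each ROI's FC profile per half, and correlates the two profiles. A
contiguous split was chosen over odd/even frames because the source
describes "two equal halves" of the time series; odd/even splitting
would share slow fluctuations across halves and bias ceilings upward.

# Group statistics

The 2×2 mixed-design interaction (between: group; within: target
category or laterality) is computed via per-subject difference scores:
the pooled two-sample $t$ between groups, squared, is exactly the
interaction $F$ with dof $(1, N-2)$. For two-level factors this is
exact, unambiguous under unbalanced groups (50/30/475), and avoids
sum-of-squares-type choices. Partial $\eta^2 = F/(F + \mathrm{df}_2)$.
Paired contrasts report Cohen's $d = \bar d / s_d$ and are
Bonferroni-corrected within the family executed together
($p_\mathrm{adj} = \min(1, m p)$). All tests are two-sided.

Dependent overlapping correlations (each group's matrix correlated
with the shared infant matrix) are compared with the Pearson–Filon
$z$:
$$z = \frac{\sqrt{n}\,(r_{jk} - r_{hk})}
{\sqrt{(1-r_{jk}^2)^2 + (1-r_{hk}^2)^2 - 2\kappa}},\quad
\kappa = r_{jh}(1 - r_{jk}^2 - r_{hk}^2) -
\tfrac12 r_{jk} r_{hk} (1 - r_{jk}^2 - r_{hk}^2 - r_{jh}^2),$$
with $n$ = number of vectorized cells (the source does not state its
$n$; this is the natural sample size of the correlated quantities and
is documented as a package decision). Its type-I error is verified by
simulation to sit in $[0.03, 0.07]$ at $\alpha = 0.05$ with $n = 45$.
The three-way specialization analysis (group × occipital × PFC
subregions) is out of scope beyond cell-means machinery; no
sphericity correction is applied anywhere.

# The synthetic world

The generator's defaults state the emulated world; they are not tuned
to tests.

* **Cohort sizes** 50 sighted / 30 blind / 475 infants; **acquisition**
  2300 frames at TR = 0.392 s (infants), 355 frames at TR = 2 s
  (adults — the average emulated session length of ~710 s).
* **Templates.** All unstructured ROI pairs sit at baseline $r = 0.2$;
  the planted block difference (PFC-vs-sensorimotor, per seed set) is
  ±`effect_size` (default 0.15, split symmetrically around baseline);
  the seed–PFC laterality increment is 0.2 (blind-like) or 0.05
  (sighted- and infant-like), applied ±half to within/between pairs so
  block means are preserved. Infant-like V1 is balanced (difference 0).
  These values were chosen once as qualitatively faithful magnitudes
  for group-level FC contrasts: block differences of ~0.15 r and a
  clearly larger blind lateralization, detectable at the stated group
  sizes without being trivially large. Indefinite block constructions
  are repaired by Higham alternating projections (tolerance 1e-10) to
  the nearest correlation matrix; the repair distance is reported and
  bounds every entry's movement.
* **Signal model.** Stationary correlated Gaussian frames (optional
  AR(1) via `ar_phi`, off by default; no fidelity to real BOLD
  autocorrelation is claimed). No hemodynamic model, no voxel level.
* **Artifacts.** Linear drift (`drift_slope`, default 0.001/frame);
  shared nuisance: two latent sources mixed into every ROI at
  `nuisance_weight` (default 0.3) of variance and into 3 CSF + 3 WM
  channels with independent channel noise; motion spikes: common-mode
  jumps of `spike_amplitude` (default 6) × the clean frame-to-frame RMS
  added to all channels at sampled frames, so DVARS responds by
  construction. Spike fractions: 0.005 for ordinary subjects, 0.12 for
  planted high-motion subjects — far on either side of the 10%
  exclusion rule, and below the ~12.5% ceiling above which the
  per-subject IQR threshold itself would migrate into the spike
  distribution (each spike elevates DVARS at two frames).
* **Parcel intensities.** Parcel means sit at 1000 ± 20 (a.u.), with
  chance variation clamped at ±2 SD and planted dropout at −8 SD, so
  the −3 SD rule fires on planted subjects and only on them. The first
  ±2.5 SD calibration left a small chance-firing probability
  (the sample SD across 100 parcels can undershoot); the clamp was
  tightened to honour the generator's stated contract.

**What a green test does and does not establish.** The generator
reproduces correlation structure, drift, compartment nuisance,
DVARS-visible spikes, and parcel dropout. It does not reproduce BOLD
autocorrelation and spectra, spatially structured motion, registration
or alignment error, or real inter-subject variability (all subjects in
a group share one template). Green recovery tests therefore validate
the *pipeline's statistics and bookkeeping*, not claims about real
data; the study's printed results are not reproducible here and are
never asserted.

# Numerical choices and degenerate inputs

Strict inequalities at every threshold (DVARS, 160-outlier rule,
−3 SD rule). Window ties break earliest. All-equal DVARS traces yield
zero flags. Zero parcel SD yields no dropout. Zero-variance ROIs make
FC an error naming the ROI; fewer than 10 frames after censoring is an
error. Min–max normalization rejects all-equal profiles. The 2×2
interaction rejects groups of size < 2 and drops subjects with missing
cells with a warning. Pearson–Filon rejects |r| = 1 and non-positive
variance terms with diagnostics. PSD repair preserves the unit diagonal
exactly and reports its Frobenius distance. Everything is deterministic
given seeds; per-subject seeds derive from the master seed.

# Noise-ceiling consistency at finite T

The split-half ceiling is attenuated by the sampling error of the
half-profiles: with profile spread $\sigma_p$ and per-correlation error
$\sigma_e \approx (1-r^2)/\sqrt{T/2}$, the expected ceiling is roughly
$\sigma_p^2/(\sigma_p^2+\sigma_e^2)$. The acceptance check that
noiseless simulations at $T = 20000$ give a mean ceiling > 0.99 is
therefore run on a dispersed factor-structure `custom` template
(profile SD ≈ 0.3, like real FC profiles); the near-flat study
templates (profile SD ≈ 0.05) measure ≈ 0.98 at the same $T$ — a
property of the statistic, not an implementation defect. The
independent-noise null (3 ROIs, ceilings of ±1 centered at 0 across
seeds) is checked unchanged.

# Known limitations

Single-template groups (no inter-subject correlation variability);
white-noise default signal; CLI config is JSON (no YAML parser in the
target environment); no graph metrics, seed-to-voxel maps, volumetric
ingestion, or figure replication; the optional 4D-image adapter
described in the interface is not implemented (out of the acceptance
path and requiring imaging I/O unavailable at this data level — the
TSV layout is its target contract).
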