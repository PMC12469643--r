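---
title: "Validating MD conformational ensembles against amide 15N relaxation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating MD conformational ensembles against amide 15N relaxation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(relaxsel)
```

## The problem

Unconstrained molecular dynamics (MD) trajectories of a protein explore a
sequence of conformational basins, and there is no guarantee that any given
stretch of the trajectory represents the ensemble the molecule actually
populates in solution.  Amide ^15^N spin relaxation provides a per-residue
experimental fingerprint of backbone dynamics on the ps-ns timescale:
the longitudinal rate R~1~, the steady-state heteronuclear NOE, and the
CSA/dipole-dipole cross-correlated relaxation rate eta~xy~.  relaxsel
implements the workflow that connects the two: it back-calculates these
observables from candidate trajectory segments (selected on RMSD plateaus)
and asks, statistically, which segments are indistinguishable from
experiment.

eta~xy~ plays the role usually given to R~2~.  Both are dominated by J(0)
and therefore sensitive to the amplitude of slow internal motion, but
eta~xy~ — the interconversion rate of the TROSY and anti-TROSY doublet
components — carries no chemical-exchange (R~ex~) contribution, no
water-saturation artefacts and no CPMG off-resonance effects, which
otherwise bias R~2~ upward in exchange-broadened regions.

## Spectral densities and rates

All observables are linear combinations of an orientational spectral
density J(omega) evaluated at fixed frequencies.  Three parameterizations
are provided:

* **Simple Lipari-Szabo** (`J_simple`): J = S^2^ tau~c~ / (1 + (omega
  tau~c~)^2^).  Used for the inverse problem (below), where its key
  property is that J is proportional to S^2^ at every frequency.
* **Extended Lipari-Szabo** (`J_extended`): two Lorentzians with
  S^2^~fast~, S^2^~slow~, tau~e~ and tau~c~; used for parameter-profile
  grids (`relaxation_profile_grid`).
* **Multi-exponential** (`J_multiexp`): the form produced from an MD
  segment, a Lorentzian at tau~c~ with weight A~0~ plus one Lorentzian at
  each effective internal time tau~j~' = tau~c~ tau~j~ / (tau~c~ + tau~j~).

The spectral density convention carries no 2/5 prefactor (J(0) = S^2^
tau~c~); the rate expressions absorb it into their numerical factors.  The
rate functions (`rate_R1`, `rate_R2`, `rate_NOE`, `rate_eta_xy`) accept any
of the three objects or a bare function of omega, which is how the test
suite substitutes a numerical cosine-transform oracle for the analytic
forms.

Two formula-level choices deserve a note:

* `rate_eta_xy` evaluates the secular combination 4J(0) + 3J(omega~N~) by
  default.  Variant formulations replace J(0) by J(omega~H~ - omega~N~);
  at slow tumbling that combination is two orders of magnitude too small to
  reproduce the observed rigid-limit plateau of about 14 s^-1^ at tau~c~ =
  14.7 ns and 600 MHz, and it would also destroy the characteristic
  R~2~-like dependence of eta~xy~ on S^2^.  The variant remains available
  via `j_zero = FALSE` for transparency.
* `rate_NOE` uses the standard heteronuclear expression
  1 + (gamma~H~/gamma~N~) d^2^/(10 R~1~) [6J(omega~H~+omega~N~) -
  J(omega~H~-omega~N~)], validated against the extreme-narrowing limit
  1 + gamma~H~/(2 gamma~N~) = -3.93 (dipolar-only relaxation).

Default interaction constants (all overridable in
`interaction_constants()`): r~NH~ = 1.023 A, Delta-sigma = -166 ppm,
Delta-sigma P~2~(cos theta) = -145 ppm, ^1^H frequency 600.13 MHz.  The
exact spectrometer frequency (600.00 vs 600.13 MHz) changes the rates by
well under 0.1%; 600.13 is the common hardware value and is the default.
Signs: gamma~N~ < 0 is kept in the NOE (which is signed), while R~1~, R~2~
and eta~xy~ are reported as magnitudes and all J evaluations use frequency
magnitudes.

## The inverse problem: tau~c~ and S^2^ from R~1~ and eta~xy~

Under the simple Lipari-Szabo model the ratio eta~xy~/R~1~ is independent
of S^2^ and strictly monotone in tau~c~ (verified numerically on a grid in
the test suite), so `solve_s2_tauc` brackets tau~c~ in [0.5, 100] ns and
bisects on log tau~c~ to a relative tolerance of 1e-8 — a derivative-free
choice that cannot be thrown off by the flat gradient at small tau~c~.
S^2^ then follows as the ratio of the observed R~1~ to the rigid-limit
R~1~(tau~c~, S^2^ = 1).

`estimate_global_tauc` applies this inversion per residue and averages
tau~c~ over a rigid subset: recovered S^2^ above a threshold (default 0.8)
and relative experimental errors on both rates at or below a cut (default
10%).  The error cut quantifies the otherwise qualitative requirement of
"minimal experimental errors"; it is configurable because no canonical
value exists.  Noise can push recovered S^2^ slightly above 1; values up
to 1.05 are accepted with a warning but excluded from the rigid set, and
larger values are flagged unphysical.  Both the SD across selected
residues and the SEM are reported; the SD is the headline uncertainty
since residue-to-residue dispersion, not counting statistics, dominates.

## From trajectory segment to rates

1. **Alignment** (`align_trajectory`): every frame is superposed (Kabsch)
   on the backbone heavy atoms N, CA, C, O of user-specified rigid residue
   ranges — two passes, first onto frame 1, then onto the resulting mean
   structure.  This removes overall tumbling so the remaining N-H motion
   is internal.
2. **Vector extraction** (`extract_nh_vectors`): normalized N-to-H unit
   vectors per residue and frame; prolines and residues without an amide
   proton are skipped and reported.  (P~2~ is even, so the N-to-H vs
   H-to-N orientation convention is immaterial.)
3. **P~2~ autocorrelation** (`compute_p2_acf`): C(t) =
   \<P~2~(mu(s)·mu(s+t))\> over all time origins.  The default lag bound is
   7 tau~c~, beyond which the overall-tumbling factor e^-t/tau~c~ has
   suppressed the total correlation function to under 0.1% and longer lags
   carry noise only; segments should be at least about 10 tau~c~ long
   (a warning enforces this guidance).  Two numerically identical paths
   exist: an explicit all-origin loop (default, with exact pair
   bookkeeping) and an FFT path over the six coordinate-product series,
   required to agree to 1e-10 in the tests and used wherever speed matters.
4. **Multi-exponential reduction** (`fit_acf_multiexp`): C(t) = A~0~ +
   sum A~j~ e^-t/tau~j~ with amplitudes on the unit simplex — enforced
   exactly by a softmax parameterization rather than by penalty — and
   log-parameterized time constants, minimized by BFGS with an analytic
   gradient from deterministic log-spaced starts.  The number of
   exponentials m (up to 4) is chosen by corrected AIC; m = 0 is the rigid
   model C = 1.  Four exponentials suffice for the timescales resolvable
   in a 500 ns segment.  Dense ACFs are thinned to at most 400 lag points
   before fitting: the ACF varies over a handful of timescales, so the
   thinning changes the estimates negligibly while bounding the cost of
   the bootstrap.
5. **Rates** (`backcalc_segment_rates`): the fit becomes a
   `multiexp_spectrum` with the experimental tau~c~, and the rate
   functions are evaluated.  The tests verify the rigid limit (A~0~ = 1
   reproduces the S^2^ = 1 analytics to 1e-10) and 1% agreement with the
   quadrature oracle on random spectra.
6. **Errors** (`bootstrap_rate_errors`): a moving-block bootstrap —
   contiguous frame blocks, default length equal to the lag bound,
   resampled with replacement to the original length; ACF, fit (with m
   frozen at the full-segment choice, one deterministic start) and rates
   are recomputed per replicate, and the SD across replicates (default
   100) is the reported error.  Block resampling preserves the
   within-block time correlation that an i.i.d. bootstrap would destroy.

## Segment selection and comparison

`compute_rmsd_series` gives the best-fit backbone RMSD to a reference over
a residue selection (by default the same rigid ranges used for alignment,
since those are the "dynamically stable" residues).
`detect_plateau_segments` scans it with a sliding window (default 500 ns,
the segment length needed for stable C(t) averages at tau~c~ around 15 ns)
and keeps windows with internal SD at or below `sd_max` (default 0.3 A)
and no frame-to-frame jump above `jump_max` (default 1.0 A); overlapping
candidates merge into plateau regions.  Plateau selection by eye is
common practice and unavoidably arbitrary; the defaults here simply make
the choice explicit and reproducible, and all thresholds are embedded in
the output metadata.  A merged plateau may be longer than one window
(a constant series yields a single region covering the whole scan), while
the candidate windows themselves are always exactly one window long.  An
equilibration prefix (e.g. the first 700 ns of a production run) can be
excluded.

For each candidate segment, `delta_in_sigma` reports (calc - exp)/sigma
per residue, with sigma the experimental error by default (combined in
quadrature on request), plus maximal runs of consecutive residues beyond
1, 2 and 3 sigma — systematic misfits appear as contiguous stretches, not
isolated outliers.  Residues with non-positive or missing errors are
dropped with a warning.

`rank_segments` applies the Mann-Whitney U test between the experimental
and back-calculated rate samples over matched residues (the two rate sets
are compared directly; comparing per-residue differences between segments
is available via `on_deltas`).  The rank test is preferred over a
chi-squared statistic because residue-correlated systematic deviations
violate the independence assumption chi-squared needs, while the rank
statistic degrades gracefully.  The exact null distribution is used for
min(n, m) <= 8 without ties (verified against exhaustive enumeration);
otherwise the normal approximation with tie and continuity corrections.
Segments are ordered by descending p-value and annotated at alpha = 0.05;
pairwise segment-vs-segment p-values are included.  No multiplicity
correction is applied across segments — the p-values are reported as such.

## Rate extraction from intensity series

`fit_exp_decay` fits I(t) = I~0~ e^-Rt (Levenberg-Marquardt from a
log-linear start; optional baseline term).  `eta_from_ct_series` fits the
constant-time TROSY/anti-TROSY modulation I(zeta) = A e^-c eta zeta on a
zeta grid symmetric about zero; the exponent factor c defaults to 4 but is
exposed (`ct_exponent_factor`) because published delay lists and the
+/- T/4 description do not pin down the normalization unambiguously — the
fitter accepts any consistent zeta grid.  `noe_from_ratio` divides
saturated by reference intensities with first-order error propagation.
All three floor the reported relative error at 5%, reading the customary
"cut-off at 5%" on fitted relaxation errors as a conservative floor rather
than a cap.

## Synthetic data and what it does (not) show

`simulate_nh_vectors` generates unit-vector paths with known ground truth:

* **rigid** (S^2^ = 1), **two-site jump** (S^2^ = (1 + P~2~(cos
  beta))/2), and **diffusion in a cone** (S^2^ = [cos theta~0~ (1 + cos
  theta~0~)/2]^2^).
* The cone walk is a Metropolis chain: spherical-Gaussian proposals whose
  density depends only on the angular displacement (hence symmetric), with
  moves leaving the cone rejected.  Its stationary distribution is
  therefore exactly uniform on the spherical cap at any step size, so the
  analytic S^2^ holds without discretization bias; the step size only
  sets the mixing time, i.e. the effective internal correlation time,
  which has no closed form and is calibrated from the fitted ACF when a
  reference value is needed.
* Optional isotropic tumbling multiplies all vectors by a common rotation
  random walk with per-axis angular variance 2 D~r~ dt, D~r~ = 1/(6
  tau~c~).

`build_synthetic_trajectory_files` realizes the vectors as the amide
geometry of a poly-alanine-like chain and writes a topology PDB plus a
multi-model PDB trajectory, so the whole pipeline — file reading,
alignment (a rigid whole-body rotation ramp can be switched on), vector
extraction — is exercised end to end.  `synth_relaxation_table` and
`synth_intensity_series` forward-generate noisy rate tables and intensity
series.  All generators require a seed and restore the caller's RNG state.

The default verification conditions use 1 ps frames, 2e5-frame (200 ns)
segments, cone semi-angles of 20-60 degrees and a per-frame angular step
of 0.1 rad, giving internal correlation times of tens of ps — typical of
fast backbone librations — and leaving the segment two thousand times
longer than the internal correlation time.  The tests then require the
fitted plateau within 0.03 of the analytic S^2^ and the back-calculated
eta~xy~ within 2 bootstrap SDs of the value obtained from the analytic
order parameter with the fitted internal spectrum shape.  Passing these
tests shows that the estimator chain (ACF, fit, spectral density, rates,
bootstrap) is unbiased and correctly calibrated for motions inside the
model class.  It does not show that a force field is accurate, that real
internal motion is cone-like, that anisotropic tumbling is negligible, or
that a single trajectory segment samples its basin ergodically — those
questions are exactly what the comparison against experimental data is
for.

## Numerical choices, edge cases, limitations

* Bisection tolerance 1e-8 (relative, on tau~c~); solver errors explicitly
  when the rate ratio is outside the attainable range, rather than
  returning a boundary value.
* The ACF at lag 0 equals 1 identically (unit vectors), and the FFT and
  direct estimators are interchangeable to 1e-10.
* Multi-exponential fitting is deterministic: fixed initial grids, no
  random restarts; ties in AICc resolve to the smaller m by evaluation
  order.  Amplitude non-negativity and unit sum hold exactly by
  construction, so downstream spectral densities are always valid.
* The bootstrap requires a seed; identical seeds give identical errors.
  A static residue yields zero bootstrap SD, and such residues are
  dropped from delta/sigma comparisons with a warning.
* Test and verification problem sizes (200 ns synthetic segments, 50
  bootstrap replicates, 500-residue noise studies) were chosen as the
  smallest sizes at which the statistical claims are comfortably
  resolved.
* Isotropic overall tumbling only; anisotropic diffusion tensors and
  side-chain or ^13^C relaxation are out of scope.  XTC/TRR trajectories
  are not read directly (no R reader exists); convert to DCD or
  multi-model PDB first.  The NMR-STAR reader handles per-residue
  relaxation loops by tag name and is intentionally minimal — it is not a
  general STAR parser.
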