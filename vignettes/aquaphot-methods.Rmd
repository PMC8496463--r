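---
title: "From multi-color fluorescence to spectral photoacclimation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From multi-color fluorescence to spectral photoacclimation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`aquaphot` turns raw multi-color pulse-amplitude-modulated (PAM) chlorophyll
fluorescence measurements of natural phytoplankton into wavelength-dependent
photosynthetic parameters, and then asks how those parameters vary across
measuring wavelengths and stations, and what features of the underwater light
climate explain that variation. This vignette describes the measurement
models, the statistical chain and the numerical choices, in the order the
pipeline runs them.

## The underwater light climate

Vertical PAR profiles give the diffuse attenuation coefficient. The two-point
definition Kd = [ln(I0) − ln(Iz)]/Z generalizes, when more than two depths
are available, to the negative least-squares slope of ln(PAR) on depth; the
regression uses all measurements and reduces exactly to the two-point form
at two depths. From Kd follow the euphotic depth Zeu = 4.6/Kd (the 1% light
depth) and, together with the upper-mixed-layer depth Zumixl, the vertically
averaged irradiance Eavg = I0(1 − exp(−Kd·Z))/(Kd·Z). A water column counts
as stratified when the density at the bottom of the profile exceeds the mean
density of the 0–1.5 m surface layer by more than 0.086 kg m⁻³; the
comparison is a strict inequality, so the boundary value counts as mixed.
For mixed columns Zumixl is the bottom depth. For stratified columns the
within-profile location of Zumixl is not uniquely defined by the threshold
criterion alone; the package adopts the convention that Zumixl is the
shallowest depth at which the density excess over the surface mean first
exceeds the threshold. This is a stated convention of the package, and the
only part of the light-climate module that is not a direct formula.

Hyperspectral profiles (400–700 nm, 3 nm grid) are integrated by trapezoid
over three quantum bands — blue 410–490 nm, green 480–580 nm, red
600–700 nm; the blue and green bands deliberately overlap — to form the
light-quality ratios R/B, G/B and G/R. Band limits need not fall on the
grid: the integrand is linearly interpolated at the edges, so a flat
spectrum yields exactly the band-width ratios (R/B = 100/80). Ratios are
averaged over replicate casts at each depth, then over depths down to
2.5 m.

## Fluorescence-based photophysiology

**Absorption cross section.** The O–I1 phase of the fast fluorescence rise
under a ~1 ms actinic pulse reflects light-driven reduction of the primary
quinone acceptor QA. The package models the rise as a single saturating
exponential F(t) = F_O + (F_I1 − F_O)(1 − exp(−t/τ)); single-exponential
QA-reduction kinetics is the standard reading of this phase and is stated
here as the package's measurement model (instrument software fits the same
phase with proprietary trigger files). Each subsample is measured three
consecutive times; τ is fitted per repeat by nonlinear least squares and the
three estimates averaged. The functional absorption cross section of PSII
follows as σPSII = 1/(τ·L·PAR) with L the Avogadro constant and PAR in
mol quanta m⁻² s⁻¹; results are reported in nm². Six subsamples per sample
give a mean (used downstream) and a variance (kept for quality control).
Unit constants are centralized: L = 6.02214076e23 mol⁻¹, µmol→mol = 1e-6,
m²→nm² = 1e18.

**Rapid light curves.** A 14-step rapid light curve starts with a dark step
(defining Fv/Fm = (Fm − F0)/Fm) and applies increasing actinic light. Per
step the package derives the effective quantum yield Y(II) = (Fm′ − F)/Fm′,
the relative electron transport rate r.ETR = Y(II)·PAR·0.5 (the fixed 0.5
expresses equal excitation partitioning between the photosystems), the
PSII-specific quantum absorption rate PAR(II) = σPSII·L·PAR, the absolute
rate ETR(II) = PAR(II)·Y(II)/(Fv/Fm), and the Stern–Volmer quenching
NPQ = Fm/Fm′ − 1 with Fm taken from the dark step (quenching persisting
after dark acclimation is thereby folded into NPQ rather than into a
redefined Fm).

**PE fitting.** Both r.ETR vs PAR and ETR(II) vs PAR(II) curves, pooled over
the three replicates (pooled as points, not averaged per step), are fitted
with the Eilers–Peeters model P = E/(aE² + bE + c), which represents
photoinhibition at supra-optimal irradiance. The familiar parameters are
algebraic in the coefficients: α = 1/c, Pmax = 1/(b + 2√(ac)),
Eop = √(c/a), Ek = Pmax/α. Fitting minimizes the residual sum of squares
over strictly positive coefficients with a multi-start strategy
(moment-based starting values, deterministic log-scale perturbations from a
fixed seed, Nelder–Mead, then Levenberg–Marquardt refinement); acceptance
of an optimum is judged on the residual sum of squares alone, so the result
does not depend on the optimizer trajectory. One genuine identifiability
issue deserves note: when noise swamps the photoinhibited branch, the
least-squares optimum can sit at a → 0, i.e. infinite Eop — beyond the
sampled irradiance range the data simply carry no information about the
optimum. Fits whose Eop exceeds `eop_max_factor` (default 5) times the
largest measured irradiance are therefore refitted on the constraint
boundary (a tied to c/Eop_max²) and flagged `eop_censored`. This keeps
downstream standardized analyses finite while making the censoring explicit;
scattered Eop estimates remain an expected feature of field data.

**NPQ light response.** NPQ vs PAR is fitted with two candidate models: a
Michaelis–Menten saturation curve NPQmax·E/(k½ + E) and a straight line
through the origin. The field practice of switching to the linear model
"when the kinetics differ" from saturation is qualitative; the package's
decided rule is a small-sample-corrected AIC comparison, with the
Michaelis–Menten candidate disqualified outright on non-convergence or
non-positive parameters, and a zero model (with a warning) when no positive
NPQ is observed. The selected model is evaluated at 300 and 1200
µmol quanta m⁻² s⁻¹ (sub-saturating and saturating reporting irradiances),
which also guarantees NPQ300 ≤ NPQ1200 since both candidates are
non-decreasing.

## The three-stage statistical chain

**Stage 1 — population trend and detrending.** For each parameter the model
`value ~ 1 + wl_t + (1 + wl_t | station)` is fitted, with wl_t the
wavelength transposed so 440 nm maps to 0 (440–625 nm becomes 0–185 nm;
the transposition keeps the intercept interpretable and reduces its
uncertainty). Fixed effects (the population trend) are estimated by REML;
their t tests use Satterthwaite degrees of freedom (the choice of df method
is open in this design; Satterthwaite is the package's default and p-values
near a decision threshold deserve a second look). The significance of the
random intercept and random slope is assessed by likelihood-ratio tests
between maximum-likelihood fits of the nested models (χ² with 1 and 2 df
respectively). Singular fits trigger an automatic refit without the
intercept–slope correlation; degenerate data with no residual variability
fall back to ordinary least squares, which the mixed model equals in that
limit anyway. Detrending subtracts only the fixed-effect line — station
departures (including their random-effect component) are precisely the
signal the later stages analyze. Each parameter is fitted independently,
one model per parameter.

**Stage 2 — partial triadic analysis.** The detrended values of eight
parameters (ETRmax(II), Ek, α(II), Eop(II), σPSII, Fv/Fm, NPQ300, NPQ1200;
whether Ek enters in relative or absolute units is genuinely ambiguous in
this design, so it is a configuration key, `ek_unit`, defaulting to
relative) form one table per wavelength with stations as rows. Stations
missing any cell are dropped (and logged). "Centred and reduced on the
overall range of all tables" is read as global standardization: each column
is centred and scaled by the mean and SD computed over the stacked rows of
all tables — scaling per table would erase exactly the between-table
differences the analysis targets. Because "reduced" (centré-réduit)
conventionally means SD scaling, SD is the default; a `scale = "range"`
switch divides by the global max − min instead. The analysis itself runs in
the classical three steps. The interstructure computes the RV coefficient
between every pair of tables, RV = tr(XkXkᵀXlXlᵀ)/√(tr((XkXkᵀ)²)tr((XlXlᵀ)²)),
and eigendecomposes the K×K RV matrix; the first eigenvector (oriented
positive — the RV matrix is positive, so its leading eigenvector has one
sign) gives the table weights, reported unit-norm so the squared weights
sum to one, and cos² is each table's share of squared coordinates on
axis 1. The compromise is the convex combination ΣαkXk with αk = wk/Σw (the
inertia shares are invariant to that renormalization); its cross-product
matrix is eigendecomposed into principal axes, with signs fixed by making
each axis's dominant variable loading positive. The intrastructure projects
every table's rows and columns onto the compromise axes; the weighted
average of per-table projections reproduces the compromise coordinates
exactly, which the tests assert. Per station, the K projected positions on
the first two axes form a "wavelength polygon" whose (shoelace) area
summarizes how wavelength-dependent that station's parameter pattern is.
The cos² convention and all other outputs are checked against an
independent brute-force implementation that follows the definitions
literally, not against any particular reference software.

**Stage 3 — redundancy analysis with forward selection.** Per wavelength,
the detrended 8-parameter table is regressed on explanatory variables
(centred and scaled on both sides); the constrained variance is the
variance of the fitted values, R² its share of the total, and adjusted R²
uses the Ezekiel correction 1 − (1 − R²)(n − 1)/(n − m − 1). Abiotic and
biotic candidates are analyzed as two separate pools (matching the
set-wise reporting such designs use); a combined pool is just a different
candidate data frame. Forward selection is driven solely by adjusted R² and
permutation p-values, with the double stopping rule: a candidate enters
only if its marginal permutation p (response residualized on the already
selected variables, rows freely permuted, p = (1 + #{perm ≥ obs})/(1 + nperm),
so the smallest attainable p at 199 permutations is 0.005) is below α and
the cumulative adjusted R² does not exceed the adjusted R² of the
all-candidates model. Selection starts only if a global permutation test of
the full candidate pool is itself significant; without that gate the
best-of-m step test inflates the type-I error several-fold, and with it the
null selection rate stays at the nominal level (the test suite measures
≲5% at α = 0.05). Ties in the gain are broken by candidate order, and the
procedure is otherwise invariant to candidate ordering. The permutation
scheme is unrestricted row permutation — the design has one row per
station, so there is no block structure to respect. Missing explanatory
cells are completed beforehand by a deterministic single-imputation EM
under a multivariate normal model (the bootstrap-EM of common imputation
software reduces to this when a single deterministic completion is
required); the EM update includes the conditional-covariance correction
and iterates to a 1e-10 fixed point.

**Photoacclimation indices.** From the fitted parameters and station
records the package forms Ek,440/Eavg (values near 1 indicate light
saturation tuned to the average mixed-layer irradiance), the Ek wavelength
ratios 625/440, 540/440 and 540/625 in both unit systems, and pairs them
with R/B (as E625/440), G/B, G/R, Zeu/Zumixl and time since sunrise;
`index_regression()` provides the OLS line and Pearson correlation for any
index pair, optionally split by the stratification flag.

## The synthetic campaign generator

Because raw field campaigns of this kind are not redistributable, the
package carries a generator that emulates all four data streams — rapid
light curves, induction kinetics, light and density profiles, station
tables — from a fully known truth, so that every downstream stage is
testable end to end. The generative model mirrors the statistical model the
pipeline fits: each base parameter (Fv/Fm, σPSII, r.α, r.ETRmax, r.Eop,
NPQmax) follows a population line over transposed wavelength plus
station-level random intercepts and slopes. The default population lines
are the field-scale values a spring coastal campaign shows (Fv/Fm
0.61 − 0.00012·wl_t; σPSII 6.08 − 0.0241·wl_t nm²; r.ETRmax rising
41 → 120; r.α 0.21 + 0.00029·wl_t; r.Eop ≈ 2000 µmol quanta m⁻² s⁻¹), and
between-station SDs are set at the scale those campaigns report (e.g.
Fv/Fm intercept SD 0.02). Two structural choices matter:

* **Absolute-unit parameters are derived, not drawn.** α(II), ETRmax(II),
  Ek(II) and Eop(II) follow physically from the relative Eilers–Peeters
  triple, σPSII and Fv/Fm (e.g. α(II) = 2α/(Fv/Fm),
  ETRmax(II) = 2k·ETRmax/(Fv/Fm) with k = σ·L·1e-24 per µmol). A zero-noise
  campaign is therefore exactly self-consistent, and the tests demand
  recovery of every parameter to 1e-6 relative.
* **NPQ truth is (NPQmax, k½), not (NPQ300, NPQ1200).** Field-scale
  NPQ300/NPQ1200 trend lines are not jointly representable by a single
  Michaelis–Menten curve at the red end of the spectrum (their ratio
  exceeds the saturation-model limit of 4 — the very reason a linear
  fallback exists in practice). The generator therefore parameterizes the
  truth as NPQmax = 3.16 − 0.014·wl_t with k½ = 750 µmol quanta m⁻² s⁻¹,
  chosen once to reproduce the blue-end values NPQ300 ≈ 0.90 and
  NPQ1200 ≈ 1.94 and the red-end magnitudes; NPQ300/1200 are then derived
  quantities.

Measurement noise is additive Gaussian on the fluorescence readings,
truncated at zero (the simplest model that preserves positivity), with
default SD 0.01 relative units on rapid-light-curve readings (instrument
gain is set so dark fluorescence sits near 0.5) and 0.005 on induction
readings. The per-wavelength actinic ladders actually delivered by
instruments are sample-specific and not standardized; the default is a
14-step, roughly geometric 0–2000 µmol quanta m⁻² s⁻¹ ladder, tunable per
scenario. Station draws that would be physically inconsistent (non-positive
Eilers–Peeters coefficients, effective yield exceeding Fv/Fm at the lowest
actinic step) are rejected and redrawn, deterministically under the seed.
A fixed seed reproduces the whole campaign byte for byte, and the generator
restores the caller's RNG state.

What the generator does **not** emulate: coupling between the abiotic
environment and photophysiology (so forward selection on a synthetic
campaign should select nothing — the tests use this as a null check);
taxonomic composition effects beyond fixed biomass numbers; vertical
structure in the plankton; instrument drift, gain changes or zero-offset
errors; non-exponential light profiles. Passing tests on synthetic
campaigns therefore demonstrate correctness of the computational chain
under the stated generative model, not robustness to every pathology of
field data.

## Problem sizes and runtime choices

The test suite exercises the full pipeline at field scale (19 stations ×
5 wavelengths, triplicate curves, six induction subsamples of three repeats
each — about 23,000 raw induction rows) and uses smaller campaigns (2–6
stations) where only plumbing is under test. Simulation studies use 200
replicates for estimator calibration (PE-fit error under 5% multiplicative
noise; mixed-model CI coverage) and 500 replicates for the selection-rate
null study; these sizes put the Monte-Carlo standard error comfortably
inside the asserted bands while keeping a full test run around two minutes.
Permutation tests default to 199 permutations (p-floor 0.005), reduced to
49–99 in plumbing tests.

## Known limitations

* The saturating-exponential induction model ignores the I1–I2–P phases of
  the full fluorescence transient; τ estimates are only as good as the
  single-exponential approximation of the O–I1 phase.
* Eop is weakly identified by 14-step curves whenever photoinhibition is
  mild; the censoring bound makes this explicit rather than solving it.
* Satterthwaite p-values with 19 stations are approximate; coverage sits
  near 94–95%, slightly below nominal, which the calibration test
  documents.
* The EM imputation assumes multivariate normality of the explanatory
  variables and reports no imputation uncertainty.
* The stratified-column Zumixl rule is a convention; profiles with density
  inversions or thin interleaved layers deserve manual inspection.
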