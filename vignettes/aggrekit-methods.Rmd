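---
title: "Models and methods behind aggrekit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind aggrekit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aggrekit)
```

aggrekit analyses the four assay families used to characterise small-molecule
inhibitors of amylin (hIAPP) aggregation: ThT aggregation kinetics,
tyrosine-fluorescence quenching and binding thermodynamics, endpoint
inhibition / IC50 dose-response, and DLS particle sizing.  This vignette
explains each model, its assumptions, the tunable parameters, and the design
choices made where the methodology left genuine freedom.  Every number shown
here is computed by the chunk that prints it.

## Autocatalytic aggregation kinetics

Amyloid formation is modelled as a two-step scheme: slow primary nucleation
(rate constant $k_n$, h$^{-1}$) followed by fast autocatalytic elongation
(rate constant $k_e$, M$^{-1}$h$^{-1}$).  With $a$ the initial peptide
concentration, $k = k_e a$ and $\rho = k_n / k$, the fibrillar fraction has
the closed form

$$
f(t) \;=\; \frac{\rho\left(e^{(1+\rho)kt} - 1\right)}
                {1 + \rho\, e^{(1+\rho)kt}},
$$

a sigmoid with $f(0)=0$, a lag phase whose length is controlled mainly by
$\rho$, and an asymptote at 1.  `autocatalytic_fraction()` evaluates the
algebraically equivalent form $\rho(1-e^{-x})/(e^{-x}+\rho)$ with
$x=(1+\rho)kt$, which cannot overflow for any $x \ge 0$; at very large $x$
it returns the asymptote analytically.  `invert_autocatalytic()` is the
exact closed-form inverse, used for model-implied threshold times.

```{r}
invert_autocatalytic(0.5, rho = 0.0068, k = 0.29)   # model halftime, h
```

**Fitting.** `fit_autocatalytic()` estimates $(\rho, k)$ by
Levenberg–Marquardt nonlinear least squares (via minpack.lm) on normalized
traces.  Two numerical choices matter:

* *Multi-start in $\rho$.*  The loss surface is nearly flat in $\rho$, which
  spans decades between compounds; the optimizer is started from
  $\rho_0 \in \{10^{-3}, 10^{-2}, 10^{-1}\}$ and the lowest-RSS solution is
  kept.
* *Slope-based $k$ start.*  The model's maximal slope is $(1+\rho)k/4$, so
  $k_0 = 4\,\max(\Delta f/\Delta t)/(1+\rho_0)$.
* Both parameters are fitted on the log scale, making positivity structural
  rather than a constraint.

$\rho$ is weakly identified: at the 2% trace noise typical of plate readers
its relative error is an order of magnitude larger than that of $k$ (the
package's property tests document a <3% median error for $k$ and accept up
to 25% for $\rho$ over 200 simulated traces).  Interpret fitted $\rho$ (and
hence $k_n$) with that caveat.

**Normalization and threshold times.**  Traces are blank-corrected, clipped
at zero and divided by the highest blank-corrected signal of the replicate
group (`normalize_trace()`), so only the brightest replicate reaches exactly
1.  The characteristic times $t_0$, $t_{1/2}$, $t_1$ are the first upward
crossings of 10%, 50% and 90% of that shared maximum, located on the *data*
by linear interpolation — not on the fitted curve — with exact hits counting
as crossings and the first upward crossing winning on non-monotone traces.
A replicate that plateaus below a threshold reports `NA` rather than an
error.  Thresholds are taken on the blank-corrected (normalized) scale.  A
model-based alternative is always available through
`invert_autocatalytic()`.

**Replicates.**  Each replicate is fitted separately;
`fit_aggregation_replicates()` reports parameters as mean ± SD across
replicates, the convention used when kinetic constants are quoted as the
average of three independent trials.  Defaults: time in hours, $a = 15$ µM.

## Fluorescence quenching and binding

Tyrosine emission spectra are integrated over 290–450 nm
(`integrate_spectrum()`, trapezoidal).  Observed areas are corrected for the
inner-filter effect with the standard 1 cm cuvette formula
$F_\mathrm{corr} = F_\mathrm{obs}\,10^{(A_\mathrm{ex}+A_\mathrm{em})/2}$;
the formula is a package choice, since only the fact of correction — not its
form — is usually reported.

**Stern–Volmer.**  $F_0/F = 1 + K_{sv}[Q]$.  `fit_stern_volmer()` reports
the slope with the intercept *fixed at 1* (the form the relation dictates)
and keeps a free-intercept fit for diagnostics and $R^2$.  The bimolecular
quenching constant is $K_q = K_{sv}/\tau_0$.  The unquenched lifetime
$\tau_0$ is a configuration input with default 5.91 ns — the constant ratio
implied by published $K_{sv}$/$K_q$ pairs for this system; override it via
`aggrekit_config(tau0_s = )` when an independent lifetime measurement
exists.

**Mechanism classification** (`classify_quenching()`): static quenching
(ground-state complex) when $K_{sv}$ strictly decreases with temperature
*and* every $K_q$ exceeds the diffusion-controlled ceiling
$2\times10^{10}$ M$^{-1}$s$^{-1}$; dynamic when $K_{sv}$ increases and all
$K_q$ sit at or below that ceiling; anything conflicting is
`indeterminate`.

**Binding.**  $\log_{10}\frac{F_0-F}{F} = \log_{10}K_b + n\log_{10}[Q]$.
The slope $n$ is an *apparent* exponent reflecting heterogeneous
populations and partial fluorophore accessibility — never a literal site
count.  Points with $F \ge F_0$ (undefined logarithm) are dropped with a
warning.  Note a structural caveat: $K_b$ is $10^{\text{intercept}}$, an
extrapolation of the fitted line to $[Q] = 1$ M, five decades below a 2–20
µM titration window.  Slope noise is therefore amplified about twelvefold
in $\log_{10}K_b$, and under 5% proportional fluorescence noise the
single-titration $K_b$ is only order-of-magnitude reliable even though the
noiseless round trip is exact.  Averaging across replicate titrations, or
narrowing the quoted quantity to $n$ and $K_{sv}$, is advisable with noisy
data.

**Thermodynamics.**  `fit_vant_hoff()` regresses $\ln K_b$ on $1/T$:
$\ln K_b = -\Delta H^\circ/(RT) + \Delta S^\circ/R$, $R = 8.314$
J mol$^{-1}$K$^{-1}$.  Two conventions deserve a note:

* *Kelvin offset.*  The thermodynamic chain uses $T_K = T_{°C} + 273$
  (integer offset).  This is deliberate: it is the convention under which a
  reported $(\Delta H, \Delta S)$ pair reproduces its tabulated
  $\Delta G$ values exactly at 25/30/37 °C.  The DLS module uses the
  physical 273.15, where no such consistency constraint exists.
* *Two routes to $\Delta G$.*  `gibbs_from_enthalpy()` computes
  $\Delta H - T\Delta S$; `gibbs_from_kb()` computes $-RT\ln K_b$.  With
  self-consistent inputs they agree; with independently measured $K_b$ they
  generally do not, and the package reports both, never an average.

```{r}
gibbs_from_enthalpy(53.31, 199.00, 310)   # kJ/mol
gibbs_from_kb(9.33e4, 310)                # kJ/mol, independent route
```

## Inhibition metrics

`percent_inhibition()` is $100(1 - S_\mathrm{sample}/S_\mathrm{control})$
on blank-corrected endpoint signals (default endpoint 36 h).  The same
formula is applied to ThT fluorescence and to total scattered intensity in
DLS; for DLS this is an explicit assumption, flagged here because "percent
inhibition by DLS" has no single standard definition.

`fit_ic50()` fits the four-parameter log-logistic
$y = b + (t-b)/(1+(d/\mathrm{IC}_{50})^h)$ with all four parameters free
($\mathrm{IC}_{50}$ and $h$ on the log scale), multi-started over hill
slopes $\{0.5, 1, 2\}$.  The reported IC50 is the inflection dose.  The 4PL
is a package choice — endpoint dose-response data of this kind are routinely
summarised this way when no mechanistic model is claimed.

## DLS particle sizing

`fit_cumulant()` implements second-order cumulant analysis: a quadratic fit
of $\ln(g_2-1) = \ln\beta - 2\Gamma\tau + \mu_2\tau^2$ over the initial
decay (lags with $g_2-1$ above 5% of its maximum), giving the mean decay
rate $\Gamma$, the diffusion coefficient $D = \Gamma/q^2$ with
$q = 4\pi n \sin(\theta/2)/\lambda$, and the polydispersity index
$\mu_2/\Gamma^2$.  Cumulant analysis deliberately replaces regularised
inverse-Laplace distribution recovery (CONTIN/Sedfit-style): it is exact for
monodisperse samples, robust for modest polydispersity, and sufficient for
per-peak means; multimodal samples are summarised at the distribution level
with `intensity_weighted_mean_rh()` over per-peak windows instead.  The
Stokes–Einstein relation $R_h = k_BT/(6\pi\eta D)$
(`stokes_einstein_radius()`) uses $k_B = 1.380649\times10^{-23}$ J/K and
per-temperature water viscosity (default $8.9\times10^{-4}$ Pa s at 25 °C).

```{r}
s <- simulate_dls_sample(list(c(10, 0, 1)))   # monodisperse 10 nm
fit_cumulant(s$curve)$rh_nm
```

## The synthetic-data generators

Because raw instrument data for this assay family are rarely deposited, the
package ships seedable generators that emulate each assay's statistical
structure; all pipeline tests run against them.

* `simulate_aggregation_trace()`: the autocatalytic sigmoid plus additive
  Gaussian noise, default SD 2% of the dynamic range on an hourly 0–36 h
  grid — the visual noise level of plate-reader ThT assays, and the level at
  which simulated parameter SDs match the scale of published
  replicate SDs for the kinetic constants.
* `simulate_quench_titration()`: the static-quenching forward model
  $F = F_0/(1+K_b[Q]^n)$, under which both the Stern–Volmer line (at
  $n=1$) and the double-log plot are *exactly* recoverable; optional
  inner-filter attenuation with $A = \epsilon[Q]$, constructed so the
  correction restores the ideal signal exactly at zero noise.  Default
  noise: proportional, 5%.
* `simulate_temperature_series()`: $K_b(T)$ generated exactly from
  $(\Delta H, \Delta S)$, so the full chain titration → binding fit → Van't
  Hoff regression is an exact round trip at zero noise.
* `simulate_dose_response()`: the 4PL with proportional noise (default 5%)
  at 8 log-spaced doses, 0.1–30 µM.
* `simulate_dls_sample()`: intensity-weighted log-normal mixtures over
  $R_h$ (defaults emulate the 2 nm native / ~10 nm inhibited-oligomer /
  ~1000 nm fibril regimes) and the matching autocorrelation curve
  $g_2-1 = \sum_i w_i e^{-2\Gamma_i\tau}$.

Every generator is a pure function of (parameters, seed): identical seeds
give identical output, the caller's RNG state is untouched, and zero noise
puts the output exactly on the forward model.

**What the generators do not emulate:** baseline drift and photobleaching
in kinetic traces; spectral shape changes (only integrated areas are
modelled); scattering and volume-change artifacts in titrations beyond the
inner-filter term; correlated (non-Gaussian) instrument noise; number
fluctuations and multiple scattering in DLS.  Passing tests therefore
demonstrate correctness of the estimators under clean, well-specified noise
— not robustness to every artifact of real instruments.

## Recovery performance at the default noise levels

Measured over repeated simulations at the defaults (these figures are
reproduced by the test suite):

* kinetics $k$: median relative error < 3% (200 traces, 2% noise);
* $\rho$: weakly identified, median error within 25%;
* IC50: median error ≈ 9% (300 curves, 5% noise) — a *single* noisy
  8-point curve carries roughly ±10% information about IC50;
* $K_{sv}$: ≈ 11% median at 5% titration noise, scaling roughly linearly
  with the noise level;
* $K_b$: order-of-magnitude only at 5% noise (see the extrapolation caveat
  above); exact at zero noise.

## Degenerate inputs and tie-breaks

* Flat traces (dynamic range < 0.1) are rejected as unfittable, as are
  flat dose-response tables; titrations with no quenching return
  $K_{sv}=0$ with a `low_signal` flag rather than an error.
* All-zero traces after blank subtraction raise a degenerate-input error.
* Threshold crossing ties: first upward crossing wins; exact hits count.
* Non-decaying autocorrelation curves are rejected before the Stokes–
  Einstein conversion can produce a nonsensical radius.
* Typed conditions (`aggrekit_validation_error`, `aggrekit_domain_error`,
  `aggrekit_insufficient_data_error`, `aggrekit_fit_rejected_error`,
  `aggrekit_degenerate_input_error`, `aggrekit_convergence_error`) let
  callers distinguish bad inputs from failed fits programmatically.

## Interfaces

The package's surface is its R functions; CSV readers
(`read_trace_csv()`, `read_titration_csv()`, `read_spectrum_csv()`,
`read_dose_response_csv()`, `read_dls_distribution_csv()`,
`read_dls_autocorrelation_csv()`, or `validate_and_load()` generically)
accept the plain-text formats documented in their help pages (comma
separator, period decimal, UTF-8, `#` metadata lines), and
`full_report()` ties all stages into one reproducible, provenance-stamped
bundle.  `scripts/acceptance.R` recomputes the pipeline's headline numbers
end to end from a single seed.
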