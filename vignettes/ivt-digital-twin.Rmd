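---
title: "A kinetic digital twin for mRNA in vitro transcription"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A kinetic digital twin for mRNA in vitro transcription}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ivtwin)
library(ggplot2)
```

## The process and the model

In vitro transcription (IVT) synthesizes mRNA from a linearized DNA template
with a phage RNA polymerase (T7 here). The four nucleoside triphosphates are
the substrates; each incorporated NTP releases one pyrophosphate (PPi), a
competitive inhibitor that supplemented inorganic pyrophosphatase removes.
`ivtwin` implements a lumped kinetic model of this reaction, the workflow that
calibrates its parameters from initial-rate experiments, Monte Carlo
propagation of the calibration precision, the scheduling arithmetic of
segmented (slug) flow operation in a plug flow reactor (PFR), and the
response-surface screening stage used to optimize reaction conditions — plus
synthetic-data generators so all of it is testable without laboratory data.

### Rate law

The transcription rate (`rate_full()`) is an extended Michaelis–Menten law:

$$
v = v_{max}\;
\frac{c_D}{c_D + K_{M,D}\!\left[1 + \frac{K_{d,GTP}}{c_{GTP}}\right]}\;
\prod_{i \in \{A,C,G,U\}}
\frac{c_i}{c_i + K_{M,i}\left(1 + \sum_{j \neq i} \frac{c_j}{K_{I,j}}
 + \frac{c_{PPi}}{K_{I,PPi}}\right)}
$$

Runoff transcription makes termination kinetics irrelevant, and the template
is recycled, so the model needs no elementary initiation/elongation/
termination scheme: initiation appears only as the square bracket in the
promoter fraction (template binding is unproductive without GTP, the
initiating nucleotide), and elongation as the product of per-NTP saturation
terms with competitive inhibition by the other NTPs and by PPi. The exact
algebraic form lives behind the single function `rate_full()` so it can be
swapped without touching anything else.

Two conventions matter in practice:

* **Apparent-constant mode (the default).** Michaelis constants calibrated by
  initial-rate experiments with the other NTPs in excess are *apparent*
  constants: they already absorb the cross-NTP competition present during
  their determination, so the explicit competitive terms must then be left
  out. `kinetic_params()` therefore defaults all four `ki` to `Inf`; finite
  values are accepted for intrinsic-mode work. PPi inhibition stays active
  either way, because pyrophosphatase kept PPi near zero during calibration —
  it is not absorbed into the apparent constants.
* **Saturated promoter (the default).** The template is dosed in excess
  (0.05 µg/µL in the reference recipe) and its molar concentration is not
  well defined without the template length, so the promoter fraction defaults
  to 1; passing a molar `c_d` engages the full fraction including the
  GTP-initiation bracket.

With three NTPs fixed in excess and PPi controlled, the law collapses to
simple Michaelis–Menten kinetics in the varied NTP (`rate_simple()`).
`km_apparent()` performs that reduction: the varied fraction's denominator
gives $K_{M,app} = K_M (1 + \sum_j c_j^{exc}/K_{I,j} + c_{PPi}/K_{I,PPi})$,
and the frozen excess fractions collapse into an apparent plateau
$v_{max,app} \le v_{max}$. At 100× $K_M$ excess that plateau sits about 3%
below the true $v_{max}$ — which is exactly why initial-rate fits deliver
apparent constants.

### Mass balances

`simulate_batch()` integrates (`ode_rhs()`):

$$
\frac{dc_{mRNA}}{dt} = v, \qquad
\frac{dc_{NTP,i}}{dt} = -f_i\, n_{mRNA}\, v, \qquad
\frac{dc_{PPi}}{dt} = n_{mRNA}\, v - v_{PPiase}, \qquad
\frac{dc_D}{dt} = 0,
$$

where $f_i$ is the fraction of base $i$ in the transcript and $n_{mRNA}$ its
length (a `transcript_spec()`); the pyrophosphatase term is simple
Michaelis–Menten, $v_{PPiase} = k_{PPiase} c_{PPase} c_{PPi} / (K_{M,PPi} +
c_{PPi})$. Two conservation laws follow and are enforced by the test suite:
$\sum_i c_{NTP,i} + n_{mRNA} c_{mRNA}$ is constant, and with pyrophosphatase
off, $c_{PPi} = n_{mRNA}\, c_{mRNA}$ exactly.

## Parameters, units, defaults

Units are fixed package-wide: time in minutes, concentrations in µM, mass
yields in g/L (`molar_to_mass()` / `mass_to_molar()` are the only places unit
constants appear).

| parameter | meaning | default | why |
|---|---|---|---|
| `vmax` | max mRNA production rate, µM/min | 0.358 | reference calibration; the 8 U/µL polymerase dose is folded into it |
| `km` (A/C/G/U) | apparent Michaelis constants, µM | 140.4 / 71.5 / 165.5 / 101.5 | reference calibration by initial-rate experiments |
| `ki` (A/C/G/U) | NTP cross-inhibition, µM | `Inf` | apparent-constant mode (see above) |
| `ki_ppi` | PPi inhibition constant, µM | 1000 | literature-scale package default; not calibrated here |
| `km_d`, `kd_gtp` | promoter constant; initiation GTP binding, µM | 1; 600 | active only with molar `c_d`; 600 µM is the reported initiation-binding affinity scale |
| `k_ppiase`, `km_ppi` | pyrophosphatase constants | 2·10⁶ µM/min/(U/µL); 50 µM | literature-scale defaults (1 U = 1 µmol/min at µL scale); chosen so PPi stays below 1% of its uncatalyzed level in the reference run; `ppiase_params()` announces them loudly |

`ivt_reference_params()` bundles the calibrated set with its standard errors
(±0.001 µM/min; ±2.9/1.9/6.4/3.8 µM). `vmax` is expressed per mRNA molecule,
not per incorporated nucleotide — the progress curves it reproduces are mRNA
concentrations — and that convention is assumed everywhere.

## Parameter determination

`extract_initial_rate()` takes the slope of the early, still-linear part of a
progress curve. "Early" is made precise by a documented window policy: the
longest prefix of at least 3 points with OLS $R^2 \ge 0.99$ whose endpoint
has consumed under 10% of the varied substrate, falling back to the first 3
points with a warning. Four estimators then map initial rates to
$(K_{M,app}, v_{max})$:

* `fit_lineweaver_burk()` — OLS of $1/v$ on $1/c$;
* `fit_hanes_woolf()` — OLS of $c/v$ on $c$;
* `fit_eadie_hofstee()` — OLS of $v$ on $v/c$;
* `fit_nonlinear()` — Levenberg–Marquardt on the untransformed law, started
  from Hanes–Woolf, with a profiled-grid restart and a profiled Brent search
  as fallbacks so weakly identified data still return the least-squares
  optimum.

The headline estimate is the nonlinear fit; the linearizations are
diagnostics (all four agree exactly on noise-free data, and the suite checks
that). Linearizations use unweighted OLS, the convention of the calibration
workflow they mirror; the nonlinear fit accepts an optional $1/v^2$
weighting. Standard errors of transformed parameters come from the delta
method applied to the regression covariance; reported ± values are labelled
as per-method standard errors (`estimate_all()` also exposes the spread
across methods, since published ± values can be either).

**A caution on identifiability.** The standard assay varies the substrate
over 2.5–10 mM while $K_M$ is 50–200 µM, so every observation sits at 94–99%
saturation and the relative sensitivity of the rate to $K_M$ is only
$K_M/(K_M+c) \approx$ 1.5–7%. With 2% multiplicative measurement noise the
Cramér–Rao bound puts the achievable relative precision of a single
12-observation experiment near sd(log $K_M$) ≈ 0.4 at $K_M$ = 140 µM; the
package's estimator attains that bound (it is unbiased and matches a
brute-force grid search) but nothing can beat it at these levels. Noise-free
recovery is exact; noisy single-experiment $K_M$ values should be read with
that design limitation in mind.

## Monte Carlo envelopes

`param_distribution()` + `mc_envelope()` propagate the calibration precision:
each draw perturbs $v_{max}$ and the four $K_M$ independently (no covariance
is estimated by the workflow) by truncated normal sampling (floor
$10^{-6}\times$ mean), simulates the batch, and the band is the pointwise
min/max across draws (30 by default; a 5–95% quantile mode is available).
The nominal parameter set is always included as draw 0, so the band contains
the nominal trajectory by construction. Draws consume a fixed per-draw block
of the random stream, which gives three useful properties the suite asserts:
fixed seed ⇒ bit-identical bands; the first $n$ draws of a longer run are
unchanged, so an envelope is nested in one with extra draws; and scaling all
standard errors under common random numbers widens the band monotonically.
Only parameters with reported standard errors are perturbed — the
pyrophosphatase constants are configuration, not calibration.

## Segmented-flow scheduling

In segmented flow, aqueous reaction slugs separated by an oil phase transit
the PFR in the residence time τ and behave as independent batches, so a new
candidate can be injected every Δt minutes instead of every τ minutes. The
counting convention: the reactor is pre-filled with oil, so the first slug
enters at t = Δt; injections continue at kΔt, each slug leaves at kΔt + τ,
and a slug is produced iff its outlet time is within the horizon T — giving
⌊(T − τ)/Δt⌋ produced slugs versus ⌊T/τ⌋ sequential batches
(`build_schedule()`, `productivity_factor()`). With Δt = 6.6 min, τ = 135 min
and T = 270 min that is 20 slugs versus 2 batches, a factor of 10. At the
degenerate corner Δt = τ the pre-fill convention charges the segmented
schedule one residence time of lead-in that the sequential count does not
pay, so the factor is (k−1)/k on a horizon of k·τ rather than exactly 1;
the package keeps the one consistent convention rather than special-casing
the corner. τ is a direct input: the reference tube geometry (18 m of
1/16 in. tubing at 0.2 mL/min) does not reconcile to a unique residence time,
and the measured value is what matters.

`detect_slugs()` finds slugs in a conductivity/UV trace by threshold crossing
with hysteresis: threshold midway between a robust baseline (median) and a
robust peak (95th percentile), hysteresis 10% of that span, and a minimum
slug duration (default 0.5 min) to reject spikes. `residence_stats()` pairs
inlet and outlet events into residence times and transit jitter;
`consumption_pct()` and `relative_change()` cover the yield bookkeeping.

## Response-surface screening

The screening stage varies temperature (37–40 °C), urea (0.4–1.2 M — urea
suppresses dsRNA formation but costs yield) and a reaction-enhancing additive
(0.1–1 mg/mL, treated as an abstract factor). `generate_design()` defaults to
a Box–Behnken layout: 12 edge midpoints plus 3 center replicates = 15 runs.
A 15-run design with 3 centers that supports pure quadratic terms is
Box–Behnken arithmetic (a full 2³ factorial with 3 centers has 11 runs and
aliases the quadratics, and a full three-level factorial has 27); the
factorial template remains available behind a flag for main-effect screening.
Run-level responses from the original campaign are not published, so no
run-level reproduction is attempted — inference is validated against
synthetic surfaces with known truth.

`fit_quadratic()` fits the full second-order model on coded units;
`stepwise_reduce()` performs backward elimination at α = 0.05 (a package
default — the reduction threshold is not part of the published workflow),
keeping the term set closed under hierarchy (parents of retained interactions
and quadratics stay). An exact-fit guard treats coefficients below
$10^{-8}\times$ the response scale as noise so degenerate zero-residual fits
reduce cleanly. `desirability_optimize()` uses Derringer–Suich linear ramps
anchored at the min/max of each model's predictions over the coded cube
(ramp anchors are not published either), a geometric-mean composite, and grid
search (21³ default). `contour_eval()`/`plot_contour()` evaluate the surface
over factor pairs in physical units.

## Synthetic data: what it emulates and what it does not

Every input the pipeline consumes can be generated with known truth attached
as a `truth` attribute (or a JSON sidecar via `write_with_truth()`):
progress curves (`gen_progress_curves()`), initial-rate datasets
(`gen_initial_rate_dataset()`, including the `ref-ATP/CTP/GTP/UTP` fixtures
at the calibrated constants), DoE response tables (`gen_doe_dataset()`) and
detector traces (`gen_trace()`: smoothed rectangular pulses with drift and
noise). The default measurement noise is multiplicative with cv = 2%,
matching the segmented-flow run-to-run reproducibility of the reference
system; the true experimental noise structure (additive vs multiplicative)
is not identified by that workflow, so this is a documented choice.

What passing tests on these generators shows is that the *inference
machinery* is correct: estimators recover generator truth, envelopes have
their stated coverage construction, detection recovers the generating
schedule. What they cannot show is that the rate law is the right model for
any particular enzyme batch — the generators draw from the model itself.
They also emulate no abortive/truncated-transcript mechanism (truncated-mRNA
fractions enter only as peak-area arithmetic, `truncated_fraction()`), no
dsRNA formation, no Mg₂PPi precipitation, and no temperature dependence
inside the rate law (temperature is a DoE factor only).

## Numerical choices

* ODE integration: `deSolve::lsoda` (stiffness-switching), rtol 1e-8, atol
  1e-10 µM; negative excursions are clipped to zero in the output, counted,
  and warned about only beyond 10³ × atol (within-tolerance undershoot of
  PPi at quasi-steady state is numerically zero).
* Test problem sizes are chosen for tight oracles at interactive runtimes:
  a 500-nt transcript for simulator checks (the closed-form and conservation
  oracles are length-invariant), 10–30 Monte Carlo draws on coarse grids,
  and 500-repeat recovery studies for estimator distributions.
* Ties and degeneracies: duplicate substrate levels are replicates; 2-point
  datasets fit but are flagged (standard errors undefined); a flat detector
  trace yields zero slugs, not an error; a constant DoE response reduces to
  the intercept-only model.

## A worked batch

```{r batch, fig.width = 7, fig.height = 4}
ref <- ivt_reference_params()
ts <- fixture_transcript("bnt-like")
pp <- ppiase_params(quiet = TRUE)

traj <- simulate_batch(c(A = 10000, C = 10000, G = 10000, U = 10000),
                       ref$params, pp, ts, t_grid = seq(0, 600, by = 10))
tail(traj, 1)
molar_to_mass(max(traj$c_mRNA_uM), ts)  # g/L at plateau

dist <- param_distribution(ref$params, ref$se$km, ref$se$vmax)
band <- mc_envelope(c(A = 10000, C = 10000, G = 10000, U = 10000), dist,
                    pp, ts, seq(0, 600, by = 20), n = 30, seed = 1)
autoplot(band)
```

## Known limitations

* The kinetic constants are lumped: enzyme dose, magnesium, pH and
  temperature are folded into `vmax` at the reference conditions; changing
  them invalidates the calibration rather than entering the model.
* $K_M$ values calibrated at 2.5–10 mM substrate are weakly identified (see
  above); they matter most, and are most trustworthy, below ~100 × $K_M$ —
  i.e. late in a batch or under feeding strategies.
* The scheduler is bookkeeping, not fluid mechanics: no Taylor dispersion,
  slug coalescence or pump dynamics; detection assumes a roughly uniform
  sampling rate and slug-scale pulses.
* Parameter draws are independent normals; if a calibration ever reports
  covariances, the envelope should use them.
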