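---
title: "Multi-process dielectric relaxation analysis with bdsfit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-process dielectric relaxation analysis with bdsfit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bdsfit)
```

## The physical problem

Broadband dielectric spectroscopy of a semicrystalline, water-retaining
biopolymer film probes several superposed polarization mechanisms at once.
At low temperatures a local secondary (β) relaxation of the saccharide rings
dominates; on heating, the structural (α) relaxation of the amorphous
fraction — the process whose slowing defines the glass transition — enters
the window, followed by an interfacial Maxwell–Wagner–Sillars (MWS)
polarization at amorphous/crystalline boundaries ("slow") and finally by
electrode polarization (EP). Ionic conduction through residual water adds a
strong background that often overwhelms the loss ε″ at high temperature, and
the film itself thins during thermal cycling, rescaling the apparent
permittivity. `bdsfit` implements an analysis chain designed for exactly
this regime.

## Model and representations

Each process is a Havriliak–Negami (HN) term
$\Delta\varepsilon_j / (1 + (i f/f_{0,j})^{a_j})^{b_j}$ with the principal
branch for the complex power, so $a=b=1$ reduces exactly to the Debye form.
Conduction contributes
$\varepsilon_c = \sigma_0/(\varepsilon_0 (i 2\pi f)^n)$; for $n<1$ its
loss/storage ratio is frequency independent, which is why the loss tangent
of a conductive sample saturates at $\tan(n\pi/2)$ at low frequency
(`tan_delta_plateau()`). Internally $\varepsilon^* = \varepsilon' -
i\varepsilon''$ with the loss stored positive, frequencies are in Hz,
temperatures in kelvin (Celsius only at the I/O boundary, offset 273.15),
and $\sigma_0$ is carried in S/m.

Two fitting representations are supported. Fitting ε″ is convenient because
process contributions add linearly, but it inherits any sample-thickness
drift and is frequently buried under conduction. The loss tangent
$\tan\delta = \varepsilon''/\varepsilon'$ mixes every term into both
numerator and denominator; it is no longer a sum of contributions, but a
common rescaling of all permittivities cancels exactly, so thickness drift
does not bias it. The generator's drift factor `g(T)` multiplies ε′ and ε″
jointly, and the test suite asserts both sides of this algebra: tan-δ fits
of drifted and undrifted data agree parameter by parameter, while ε″ fits
report strengths biased by exactly `g(T)`.

## The staged fitting protocol

`fit_dataset()` executes the protocol a practitioner uses on such films:

1. the unrelaxed permittivity ε∞ is read off the coldest spectrum at the
   highest frequency (`estimate_eps_inf()`);
2. isotherms are fitted in ascending temperature order with warm-started
   initial values, the symmetry exponent held at $b = 1$ and the
   conductivity term included;
3. a process whose relaxation frequency leaves the window above 1 MHz is
   pinned at the Arrhenius extrapolation of its lower-temperature fits
   (`fix_process_frequency()`), with provenance `"fixed:arrhenius"` recorded
   so those entries never feed back into the law fits;
4. per-parameter provenance, standard errors, at-bound flags and
   `unresolved` flags are kept for every isotherm.

Optimisation is bounded Levenberg–Marquardt (`minpack.lm`), with
$\Delta\varepsilon$, $f_0$, $\sigma_0$ optimised in log10. Residuals are
evaluated at the measured frequencies, either unweighted
(`weighting = "none"`) or divided by the measured value
(`weighting = "relative"`). Plans derived for synthetic studies default to
relative weighting: BDS measurement error is multiplicative to good
approximation (and the generator's noise model is multiplicative lognormal),
and an unweighted objective lets the large low-frequency loss-tangent values
— where relative noise produces large absolute deviations — dominate the sum
of squares at the expense of the small high-frequency values where weak
processes live.

### Keeping process identities straight

A sum of like-structured HN terms is invariant under permuting the terms, so
nothing inside a single isotherm fit anchors which fitted component is
"alpha_a" and which is "slow" — and in these films the two genuinely cross
in temperature. The package maintains identity the way an analyst reads a
relaxation map:

* candidate starts include pairwise swaps of the parameter blocks of
  confusable processes (same $b$, initial frequencies within 2.5 decades),
  so permutation-type local minima are actually visited;
* after each isotherm, labels are re-matched by closeness of
  $(\log_{10} f_0, \log_{10}\Delta\varepsilon, a)$ to a short linear
  extrapolation of each label's track in $1/T$ — trend information carries
  identity through crossings;
* a process that comes out with its strength at a bound, or sitting under a
  stronger process (within 0.3 decades of any stronger term, or 0.5 decades
  of one at least twice as strong), is flagged `unresolved`: two HN terms
  that close cannot be discriminated, which is also why such entries are
  excluded from the relaxation map;
* a fit whose process was flagged lost is retried once from the frequency
  where the model-without-that-process underfits the data most, and kept
  only if the deviance improves;
* at the end of a sweep, whole tracks are assigned to labels by which
  declared temperature law (Arrhenius versus VFT) fits them best, using a
  robust capped-residual cost so stray points cannot drown the curvature
  signal; ties between labels sharing a law are broken by the declared
  slowness ordering (electrode polarization is the slowest apparent
  process).

A second sweep then refits every isotherm with initial values predicted from
the first sweep's fitted laws, pinning each process's width exponent at its
median when the first-pass estimate was stable (HN shapes are temperature
independent to good approximation, and freeing them trades against the
frequency of weak shoulder processes).

### Global law-constrained refinement

Per-isotherm estimates of a weak process overlapping a stronger one carry
appreciable single-isotherm uncertainty even when the staged protocol
behaves perfectly. Because the relaxation frequencies follow smooth laws and
the shapes are constant, the statistically efficient estimator fits those
laws against all isotherms simultaneously. `fit_global_laws()` therefore
refines, per process, the law parameters, one dielectric strength and one
width exponent — together with the per-isotherm conductivity pairs — by
least squares on the stacked residuals of the whole series, starting from
the staged results. Co-estimating the conductivity matters: freezing the
per-isotherm $(\sigma_0, n)$ values pushes their errors into the law
parameters. On the shipped chitosan-like preset this stage reduces the
median error of the recovered relaxation frequencies to a few hundredths of
a decade and the glass-transition error to well under a kelvin.

## Relaxation maps, Tg and fragility

`build_relaxation_map()` collects the fitted `(T, f0)` pairs per label with
provenance and an `in_window` flag. Temperature-law fits
(`fit_arrhenius()`, `fit_vft()`, or `fit_relaxation_laws()` for a whole map)
use only entries whose relaxation frequency lies inside the measured window
— an extrapolated peak position is not a measurement — and apply an iterated
3-MAD outlier trim. The VFT fit profiles the Vogel temperature on a grid
(the remaining parameters are then linear), polishes with bounded
Levenberg–Marquardt, and flags fits whose asymptote collides with the data
range. The $f_\infty$ of a structural process can be fixed to that of the
secondary relaxation when the two merge at high temperature
(`fixed_log10_f_inf`).

The glass-transition convention is a relaxation time of 100 s, i.e.
$f = 1/(2\pi\,100)$ Hz (log10 f ≈ −2.8, `dielectric_tg_crossing()`). The
conventional prefactor "2.3" in the Tg and fragility formulas is implemented
as $\ln 10$: recomputing published fragilities from their own printed VFT
parameters reproduces them only with the exact value (235.74 versus 235.5
with 2.3, for the most fragile tabulated state). Published-value comparisons
in the tests use ±0.2 °C for Tg and ±1% for m to absorb the tables' own
parameter rounding. One tabulated row (the non-neutralized film's structural
process without annealing) prints a fragility of 9.7 that is inconsistent
with its own printed parameters (the closed form gives ≈ 26); it is excluded
from the checks.

## Conductivity regimes and interfacial polarization

`fit_conductivity_regimes()` fits separate Arrhenius laws to
$\log_{10}\sigma_0$ versus $1/T$ below and above a breakpoint (scanned
automatically by total residual), reproducing the hopping-to-ohmic
transition near the glass transition: moderate activation energy
(~20 kJ/mol) with fractional exponent n ≈ 0.3–0.4 below, steep
(~70 kJ/mol) with n ≈ 0.9–1 above. `mws_relaxation_time()` implements the
interfacial-polarization time
$\tau = \varepsilon_0(\varepsilon_2' + A\phi(\varepsilon_1' -
\varepsilon_2'))/(\sigma_2 + A\phi(\sigma_1 - \sigma_2))$ for inclusions of
depolarization factor A (1/3 for spheres) and volume fraction φ; when the
crystalline phase conducts negligibly the time is inversely proportional to
the matrix conductivity, so the slow-process frequency tracks σ0 with
log–log slope 1 (`sigma_slow_correlation()`).

## The synthetic generator

`synthetic_protocol()`/`generate_dataset()` emulate temperature-stepped BDS
runs: 0.1 Hz–1 MHz log grids at 10 points per decade (71 points), 5 or 10 K
steps from −100 °C upward, up to four HN processes with Arrhenius or VFT
laws, a two-regime conductivity law with an n-step at the breakpoint,
independent multiplicative lognormal noise per point on ε′ and ε″ (default
1%), and a thickness-drift factor ramping linearly in temperature (the
shipped magnitude 51/32 matches a measured 51 µm → 32 µm thinning). Presets
named after the neutralized (`A90_*`) and non-neutralized (`A0_*`) chitosan
films carry the published Arrhenius/VFT parameters of their processes; the
quantities the sources do not print are this package's own choices, made
once: dielectric strengths β ≈ 1, α_a ≈ 2, slow ≈ 8, EP ≈ 50 (mimicking the
qualitative size ordering of measured loss contributions), width exponents
0.35/0.6/0.8/1.0, ε∞ = 3, and σ0(230 K) = 10⁻¹⁴ S/m (10⁻¹³ for the more
conductive non-neutralized film). The default study grid is −100…160 °C in
10 K steps; that size keeps a ten-seed recovery study of the full pipeline
at about a minute per seed.

What the generator does **not** emulate: cold-crystallization kinetics (the
annealing-dependent plateaus of the slow process), temperature-dependent
shape exponents, strength dispersion beyond a linear trend, instrument
artifacts other than multiplicative noise, and any coupling between
processes. Passing recovery tests therefore demonstrate that the pipeline
inverts data of this statistical structure — not that it is robust to every
pathology of measured film spectra.

`derive_plan()` automates the analyst's by-inspection windowing for
synthetic studies, from the generating laws: a process joins the fit when
its law frequency enters the window (0.05 Hz), is pinned above 1 MHz, and is
dropped two decades above the top. Initial strengths and shapes are
deliberately generic (Δε = 1, a = 0.5; entering processes start at the
low-frequency edge), so recovery remains a genuine optimisation result
rather than an echo of the truth.

## Numerical choices and limitations

* Bounds: Δε ∈ (10⁻⁴, 10⁴), f₀ ∈ (10⁻⁶, 10⁹) Hz, a, b ∈ (0.05, 1],
  σ₀ ∈ [10⁻²⁰, 10²] S/m, n ∈ (0.05, 1]; a/b/n = 1 and σ₀ at its floor are
  meaningful boundary values and not warned about.
* Multi-start: five seeded starts by default (one nominal plus jittered),
  plus the swap starts; ties in residual norm keep the first, lowest-count
  solution. All randomness flows from explicit seeds; identical inputs and
  seeds give identical results.
* Electrode polarization is modelled as one more HN process with b = 1 and
  an Arrhenius-tracked frequency, not a separate formalism.
* Degenerate inputs: empty datasets, single-point maps, asymptotes inside
  the data range, non-relaxing MWS configurations and divergent (n = 1)
  plateaus raise errors or return flagged/NA results rather than numbers.
* Process count is configuration, never model selection: choosing how many
  processes to fit, and what to call them, is the analyst's interpretive
  decision; the package only keeps the chosen labels consistent.
* The spectral dialects are plain delimited text and JSON; proprietary
  instrument formats are out of scope.
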