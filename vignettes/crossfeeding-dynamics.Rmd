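---
title: "Modelling a synthetic cross-feeding mutualism under nutrient disturbance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling a synthetic cross-feeding mutualism under nutrient disturbance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crossfeedr)
```

## The system and the model

Two engineered *Saccharomyces cerevisiae* strains form an obligate
mutualism: a lysine overproducer that cannot synthesise adenine (LYS-up)
and an adenine overproducer that cannot synthesise lysine (ADE-up). Each
strain can only grow on the metabolite its partner secretes, so the pair
cross-feed. `crossfeedr` models this culture as a consumer-resource
system of intermediate complexity: strain densities `xL`, `xA` (and
optionally an "ultimate overproducer" `xO`, see below) plus the free
metabolite pools `cA` (adenine) and `cL` (lysine).

Strain growth is logistic with a Monod (Michaelis-Menten) factor in the
required metabolite:

$$\dot x_L = x_L\, r_1 \frac{c_A}{c_A + k_{cA}}
  \Big(1 - \frac{x_L + x_A + x_O}{K}\Big), \qquad
  \dot x_A = x_A\, r_2 \frac{c_L}{c_L + k_{cL}}
  \Big(1 - \frac{x_L + x_A + x_O}{K}\Big)$$

and metabolites are produced constitutively and consumed with saturating
uptake:

$$\dot c_A = \beta_1 (x_A + x_O) - \gamma_1 \frac{c_A}{c_A + k_{cA}} x_L,
  \qquad
  \dot c_L = \beta_2 (x_L + x_O) - \gamma_2 \frac{c_L}{c_L + k_{cL}} x_A.$$

Everything is in normalized, dimensionless units with carrying capacity
$K = 1$; conversion to cells/ml or ug/ml is confined to the
synthetic-data generators. Death is deliberately absent from these
equations (over the experimental time window strain viability is
essentially constant); an explicit death rate appears only in the minimal
reduction below.

Two parameter presets ship with the package. The **neutral** preset is
fully symmetric ($r_1 = r_2 = 1$, $k_{cA} = k_{cL} = 1$). The
**informed** preset encodes what single-strain growth assays show: the
ADE-up strain's maximum growth rate and half-saturation constant are both
about twice those of the LYS-up strain ($r_1 = 1, r_2 = 2, k_{cA} = 2,
k_{cL} = 1$). Both use $\beta_i = 0.1$ (production an order of magnitude
below growth), $\gamma_i = 1$.

```{r equilibrium}
p <- cf_preset("informed")
tr <- cf_simulate(p, cf_init(frac_ade = 0.2), t_end = 300)
tail(fractions(tr)[c("t", "frac_ADE", "frac_LYS")], 2)
detect_equilibration(tr)
```

Unsupplemented cultures settle, from a wide range of starting ratios,
at an ADE-up fraction close to 0.6 — the baseline against which every
disturbance is measured. The equilibration rule is the one used
throughout: strain densities changing by no more than $10^{-4}$ between
consecutive unit reporting steps.

Note a structural property of this batch-culture model: growth stops
when the culture reaches carrying capacity, which freezes the strain
ratio. The converged fraction therefore retains a weak dependence on the
initial ratio (about $\pm 0.015$ around 0.6 across starts 0.1–0.9 at
initial total density 0.2). Tests assert the band $|f - 0.6| \le 0.05$
for every start; they do **not** assert exact mutual agreement, which
the model does not possess.

## Supplementation regimes

`cf_regime()` encodes how nutrients are added from outside:

* **initial** — one dose folded into the state at $t = 0$ (batch
  enrichment);
* **intermittent** — impulsive doses every `period` steps starting at
  `start` (a hybrid dynamical system: smooth flow punctuated by jumps);
* **continuous** — a dose at every unit reporting step.

Doses are applied as exact state jumps between integration segments,
not as stiff source terms; this is numerically exact and matches the
discrete framing "metabolites provided at every time step". A
constant-influx formulation of the continuous regime
(`continuous_as = "influx"`) is available for sensitivity checks. The
"time step" is always the unit reporting grid, fixed independently of
the adaptive integrator's internal steps — the equilibration criterion
and schedules such as "every 25th step" are only meaningful on a fixed
grid. For comparability with the initial regime, intermittent schedules
apply the dose at $t = 0$ too (`include_initial_dose = TRUE`, the
default); delayed-intervention sweeps disable it.

```{r phase, eval = FALSE}
pd_ini <- phase_diagram(p, cf_regime("initial"))
pd_cont <- phase_diagram(p, cf_regime("continuous"))
coexistence_zone(pd_ini)  # fraction of grid cells with 0.2 <= f <= 0.8
coexistence_zone(pd_cont) # smaller: continuous feeding erodes coexistence
```

Sweeps evaluate the state at a fixed snapshot time (default $t = 300$)
for *all* regimes rather than detecting equilibrium, because recurring
disturbances keep the system permanently out of equilibrium; comparing
at the same time point is the only fair cross-regime comparison. The
coexistence zone — the fraction of dose/ratio cells whose snapshot
ADE-up fraction lies in $[0.2, 0.8]$ — summarises the resilience of the
mutualism, and shrinks from initial to intermittent to continuous
supplementation. Default dose axes are logarithmic over $10^{-2}$ to
$10^{1}$ (doses) and $10^{-1}$ to $10^{1}$ (lysine-to-adenine ratio),
bracketing the experimentally used doses 0.1, 1 and 10; the figure
sources do not print their exact ranges, so the axes are configurable.

Timing matters more than magnitude once doses are large: a high-dose
schedule started early (during the transient, e.g. $t = 5$) preserves
the ordering of outcomes by initial strain ratio, whereas the same
schedule started after the transient ($t = 25$) scrambles or inverts
it — by then all starts have converged near the baseline and the doses
dominate.

## The ultimate overproducer

The three-strain extension adds a hypothetical strain that overproduces
*both* metabolites and grows at a flat, metabolite-independent rate
$r_o$ ($\dot x_O = x_O r_o (1 - (x_O + x_L + x_A)/K)$), while feeding
both pools. `overproducer_grid()` maps which strain dominates (highest
relative fraction) over $r_o$, intervention time and lysine dose; the
default $r_o$ set $\{0.1, 0.14, 0.16, 0.17, 0.2, 0.4, 0.5, 0.7\}$ spans
the transition from ADE-up dominance (low $r_o$: the overproducer's
early growth spurt feeds the mutualists, which then outgrow it) to
overproducer takeover (high $r_o$). The paper-style intervention
schedule doses lysine at $\tau, 2\tau, 3\tau, \dots$ with nothing at
$t = 0$. The initial condition for three-strain runs is not printed in
the source material; the package default is total density 0.2 split
equally among the three strains, a neutral choice that lets relative
growth decide dominance.

## Minimal eco-evolutionary reduction

For mathematical tractability the package also implements a
two-dimensional reduction in total density $z$ and ADE-up fraction $f$
with an explicit uniform death rate $d$:

$$\dot z = (r_1 + r_2) f (1 - f)\, z^2 (1 - z) - d z, \qquad
  \dot f = z (1 - z) f (1 - f) \big(r_2 - f (r_1 + r_2)\big).$$

The precise equations of the source supplement are in a PDF not
available to this implementation; the forms above are the unique
reduction consistent with every printed property — the fraction
nullcline is set by $r_1, r_2$ alone and is independent of $d$
($f^* = r_2/(r_1 + r_2)$, $= 2/3$ for the informed rates, on the same
side of 1/2 as the full model's 0.6); nontrivial density equilibria
solve $g^* z (1 - z) = d$ with $g^* = r_1 r_2/(r_1 + r_2)$, giving a
stable upper and an unstable lower (Allee-threshold) branch; and the
branches coalesce at $z^* = 1/2$ — structurally, for any rates — in a
saddle-node bifurcation at $d^* = r_1 r_2 / (4 (r_1 + r_2))$, beyond
which extinction is the only stable state.

```{r bifurcation}
find_bifurcation(1, 2)                 # d* = 1/6, z* = 0.5
equilibrium_branches(c(0, 0.1), 1, 2)  # stable ~0.816 / unstable ~0.184 at d = 0.1
```

The bifurcation is located analytically (vanishing discriminant) and
cross-checked against an independent numeric route (maximizing the
density nullcline by golden-section search) to $10^{-8}$. Branch
stability is verified dynamically in the tests by integrating perturbed
initial conditions. One numerical subtlety: at $d = 0$ the density
reaches the $z = 1$ boundary where $z(1-z) = 0$, so the fraction freezes
short of $f^*$; interior convergence is checked at $d > 0$.

## Growth-curve fitting

`fit_monod()` estimates $(V_{max}, K)$ of
$\mathrm{rate}(s) = V_{max}\, s / (s + K)$ from single-strain
growth-rate tables by unweighted nonlinear least squares (Gauss-Newton
via `nls`, port algorithm with positivity bounds). Choices worth
stating:

* The curve is anchored at the origin — auxotrophs cannot grow without
  supplement — so $s = 0$ records are kept with model value 0 and no
  basal offset is fitted.
* Replicates are fitted jointly (not as means) so the residual spread
  reflects biological replication; `use_means = TRUE` is available.
* The loss is unweighted least squares; the data source does not state
  a weighting, so this is a declared package convention.
* Initialization is $V_{max,0} = $ the largest observed rate and
  $K_0 = $ the concentration whose mean rate is nearest
  $V_{max,0}/2$ — standard, and sufficient for this well-conditioned
  two-parameter problem.
* Flat (saturated) data drive $K$ to the 0 boundary; the fit is
  returned with a `k_boundary` flag and a warning instead of a spurious
  interior estimate.

`normalize_params()` converts two strain fits into model parameters
relative to the LYS-up strain: with the tabulated values
$V_{max} = 25.4$ vs $13$ and $K = 32.9$ vs $15.3$ ug/ml, the ratios are
1.95 and 2.15, rounded to the preset values 2 only when explicitly
requested.

## Synthetic data: what it does and does not establish

`generate_growth_dataset()` and `generate_coculture_counts()` emulate
the *statistical shape* of the experiments so the whole pipeline is
testable without downloads: Monod-shaped growth rates at concentrations
$\{0, 0.1, 1, 10, 25, 50, 100, 200\}$ ug/ml in triplicate with Gaussian
noise (SD a fraction of $V_{max}$, truncated at 0; default 5%, a typical
replicate CV for plate-based growth assays), and coculture time courses
sampled every 24 h with Poisson total-CFU noise around
density $\times$ $5 \times 10^7$ cells and multinomial colony typing of
`plate_count_depth` colonies (default 100 — a realistic countable plate;
the true per-sample depth is not stated in the source material).
Multinomial-on-counts rather than Gaussian noise is deliberate: it gives
the correct behaviour when one strain is rare. The model-time-to-hours
mapping defaults to 1 h per time unit and is a generator parameter only;
no inference module consumes it.

Generators are pure functions of their inputs and a seed (they restore
the caller's RNG state). What a green test on synthetic data
establishes is *self-consistency* — the fitter recovers known truth,
the estimator is unbiased for trajectory fractions — not agreement with
wet-lab measurements; real data feature batch effects, lag phases and
death-phase artefacts that the generators do not emulate, and the
experimentally observed ratios (e.g. 0.53/0.57/0.056 after 120 h under
initial supplementation) are only qualitatively mirrored by the model.

## Numerics

Integration uses an adaptive Dormand-Prince 5(4) scheme with
`rtol = atol = 1e-9`, implemented in compiled code, with an identical
pure-R reference path (`method = "r"`) and an independent fixed-step
Euler oracle used by the test-suite. The system is smooth but
trajectories skirt zero concentrations, where the Monod fraction is
defined as 0 at $c = 0$ ($k = 0$ is rejected to avoid 0/0). Tiny
negative undershoots (within $100 \times$ `atol`) are clipped to 0 at
reporting points; anything larger raises an error, since it would
signal an integrator bug rather than biology. Dose events are segment
boundaries, so impulses are exact; `t_end` must sit on the unit
reporting grid. Dominance ties are declared only within $10^{-12}$.

## Limitations

* Batch culture only: no chemostat dilution or waste efflux, so an
  initial dose permanently shifts the frozen equilibrium.
* No demographic noise, no spatial structure, no death term in the full
  model.
* No calibration of model time to hours for inference (the 1 h default
  is a generator convenience).
* The minimal model is a qualitative reduction; its $f^* = 2/3$ is not
  expected to equal the full model's 0.6, only to fall on the same side
  of 1/2.
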