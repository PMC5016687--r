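---
title: "Binding thermodynamics of tetrameric DNA sensors: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Binding thermodynamics of tetrameric DNA sensors: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(anisofit)
```

This vignette is the package's own account of the science it
implements: the equilibrium models, the numerical choices behind them,
and what the tests do and do not establish about real data.

## The speciation model

A binding scheme is a set of components with total (analytical)
concentrations and a set of complexes, each carrying an *overall*
dissociation constant defined by
$$[\mathrm{complex}] = \prod_i [\mathrm{free}_i]^{\nu_i} / K_{\rm overall},$$
so a complex of total stoichiometry $\sum\nu$ has $K_{\rm overall}$ in
units of $\mathrm{M}^{\sum\nu - 1}$. Equilibrium requires every
component's mass balance to close:
$x_j + \sum_c \nu_{cj}[\mathrm{c}](x) = T_j$.

`solve_speciation()` solves these equations by damped Newton iteration
on $u = \log x$. The log transform guarantees positivity without
constraints; the Jacobian
$J_{jk} = \delta_{jk}x_j + \sum_c \nu_{cj}\nu_{ck}[\mathrm{c}]$ is
symmetric and assembled analytically; a halving line search enforces
monotone decrease of the scaled residual, and a Jacobi fallback covers
the rare singular step. Iteration starts at $x = T$ (free = total),
which is on the correct side of the solution for dissociation-constant
parameterisations. Components with zero totals are eliminated exactly,
together with every complex that contains them, so the empty system
returns all zeros with zero residual. Numerical guard rails: the
default relative mass-balance tolerance is $10^{-9}$ (user-settable in
$(0, 10^{-3}]$), and a concentration floor of $10^{-30}$ M keeps
relative residuals defined at zero totals. Non-convergence raises an
error naming the component with the worst residual rather than
returning a bad solution.

### The two-tetramer operator-binding mechanism

The repressors modelled here are homotetramers, two of which bind one
operator–promoter DNA fragment. `build_two_tetramer_scheme()` encodes

$$T + D \rightleftharpoons TD \;(K_1 = K_{\rm DNA}), \qquad
  T + TD \rightleftharpoons T_2D \;(K_2 = K_{\rm DNA}),$$

with *equal stepwise macroscopic constants* and no statistical-factor
corrections — "equal affinity" is taken at face value, which makes the
overall constant of the doubly bound state exactly $K_{\rm DNA}^2$.

The tetramer is treated as nondissociable: titrant entered as monomer
is divided by four and the tetramer becomes an elementary component.
The alternative device — declaring the assembly step
$4M \rightleftharpoons T$ with a vanishingly small constant — is kept
as a cross-check (`explicit_assembly = TRUE`), but it hides a unit
trap: an overall assembly constant $[M]^4/[T]$ carries units of
M$^3$, so a numeric value like $10^{-20}$ is only "vanishingly small"
in some concentration units. At $10^{-20}$ in molar$^3$ units and
$4\times10^{-7}$ M total monomer, roughly 40% of the protein would sit
as free monomer — not nondissociable at all. Mechanism-fitting scripts
that use this device typically work in µM or nM units, where the same
numeral is deep in the assembled regime. The preassembled formulation
is therefore the default (it is exact by construction and unit-safe),
and the explicit mode defaults to $k_{\rm tet} = 10^{-38}$ M$^3$,
where the two agree to solver tolerance (this is property-tested).

### Fast path for titration curves

`simulate_curve()` evaluates the two-site scheme thousands of times
inside a fit, so by default it uses an exact algebraic reduction: free
probe follows from free tetramer $t$ as
$d = D_{\rm tot}/(1 + t/K + t^2/K^2)$, leaving a single monotone scalar
balance for $t$ that is solved by 62 vectorised bisection steps
(machine precision on the bracket $[0, T_{\rm tot}]$). The general
solver path (`engine = "speciation"`) remains available and the two are
property-tested to agree; bisection was chosen over Newton here because
it is branch-free across a whole titration schedule and indifferent to
the stiffness of the stoichiometric regime ($D_{\rm tot} \gg K$).

## The anisotropy response and the fit

Fluorescence anisotropy rises as the labelled probe is bound because
the protein–DNA complexes tumble more slowly. The response model maps
speciation to signal as
$$\Delta r = \Delta r_{\max}\,\bigl(w_{TD}[TD] + w_{T_2D}[T_2D]\bigr)/D_{\rm tot},$$
with default weights $w_{TD} = 0.5$, $w_{T_2D} = 1$: the response is
linear in the number of bound tetramers, the standard molar-response
convention of mechanism-fitting software, under which the normalised
signal equals the probe's site occupancy and half-saturation gives
exactly $\Delta r_{\max}/2$. Per-species responses are rarely reported
for these systems, so the weights are a declared assumption and are
configurable.

`fit_kdna()` minimises untransformed least squares (constant noise
assumption) over $\log_{10}K$ — the natural scale for a quantity
identified over orders of magnitude — and over $\Delta r_{\max}$ unless
it is fixed. Optimisation is Levenberg–Marquardt (`minpack.lm`) from
seven log-spaced starts across the K bounds (default
$[10^{-12}, 10^{-3}]$ M); the best local optimum wins, with ties broken
toward smaller K. Multistart matters because a non-saturating curve has
a long, flat SSE valley in K.

Two reporting conventions handle weakly binding designs:

* **Lower bounds.** If the best fit's model saturation at the final
  titration point is below 80% of $\Delta r_{\max}$ (configurable), or
  K presses against the upper bound, the estimate is flagged
  `is_lower_bound` and printed as "≥ K" — only a bound is identifiable
  when the titration cannot approach saturation. For such fits
  $\Delta r_{\max}$ should be fixed to the average fitted maximum from
  saturating (apo) experiments, which is what `delta_r_max_fixed` is
  for.
* **No detectable binding.** A titration flat to within the noise
  floor (default 0.005 anisotropy units) is not a fitting failure: the
  K is reported at the design's detection limit — the largest tetramer
  concentration reached — with the bound flag set.

Replicates are fit independently and summarised as mean ± SD of K,
matching how apparent affinities are usually averaged across
experiments; a pooled fit with shared parameters is available via
`joint = TRUE` but is not the default, since independent fits expose
replicate scatter instead of hiding it.

### Stoichiometric breakpoints

At probe concentrations far above K every added tetramer binds until
the sites fill, so the curve is nearly two straight lines. The
`stoichiometry_breakpoint()` procedure: the plateau is the mean of the
trailing 20% of points (which must agree to within 5% of the plateau,
else the titration is declared unsaturated and an error advises
extending it); the rising phase is the points at or below half the
plateau; the least-squares line through the rising phase intersects the
plateau at the equivalence point, expressed as monomer equivalents per
DNA. Two tetramers of four monomers give 8. At finite $D_{\rm tot}/K$
(≈ 17 for the 2.5 µM probe design at $K = 1.5\times10^{-7}$ M) the
curve rounds and the breakpoint lands near 8.1 — the procedure is
deliberately the simple graphical one, not a fit of the full model,
because that is what the experimental analysis it mirrors does.

## Coupling free energies

Effector binding weakens operator binding; the linkage is quantified as
$$\Delta G_C = RT\ln K_C, \qquad
  K_C = K_{\rm DNA}^{\rm effector}/K_{\rm DNA}^{\rm apo},$$
with $R = 1.987\times10^{-3}$ kcal mol⁻¹ K⁻¹ and T defaulting to
298.15 K (the 25 °C assay condition). With replicate estimates on both
sides, every (apo, effector) pair contributes one equally weighted
$\Delta G_C$; mean and SD over all $n \times m$ pairs are reported.

One genuinely open choice is whether "equally weighted pairwise
permutations" averages the per-pair *energies* or the per-pair *ratios*
$K_C$. The package defaults to the energy domain (each permutation
contributes one energy, and the mean energy is then exactly
$RT\,\overline{\ln K_C}$ — the same computation, asserted bitwise in
the tests); the ratio-domain alternative (`average = "kc"`), which by
Jensen's inequality can only be larger, is provided so the difference
can be reported rather than argued about. For the magnitudes involved
here the two differ by far less than the replicate SD. Lower-bound
K's propagate: a "≥" on any input makes the coupling energy itself a
bound, never an exact number.

## The cytosolic competition model

Inside the cell, formaldehyde partitions between a trace sensor and
the enormous glutathione pool. Both arms are modelled as reversible
equilibria with effective dissociation constants — covalent chemistry
(methylene-bridge formation on the sensor, hemithioacetal formation on
GSH) collapsed to an equilibrium affinity, which is exactly what an
occupancy model needs and all the available constants support. The one
unknown, free formaldehyde $F$, solves
$$F + G_{\rm tot}\frac{F}{K_{\rm GSH}+F} + S_{\rm tot}\frac{F}{K_s+F}
  = F_{\rm tot},$$
a strictly monotone scalar balance handled by `uniroot` on
$[0, F_{\rm tot}]$ at $10^{-13}$ relative tolerance. Defaults (all
molar): sensor affinity $K_s = 10^{-5}$ (FrmR) or $10^{-4}$ (RcnR — a
tighter-limit estimate, so RcnR outputs are themselves bounds),
$K_{\rm GSH} = 1.77\times10^{-3}$, $G_{\rm tot} = 1.2\times10^{-3}$
(the anaerobic glutathione level, taken as fully reduced),
sensor tetramer $1.61\times10^{-8}$ with 4 formaldehyde sites per
tetramer, cell volume 1 fl.

Because both pools see the same free formaldehyde, their occupancies
obey the exact odds-ratio identity
$$\frac{f_s/(1-f_s)}{f_g/(1-f_g)} = \frac{K_{\rm GSH}}{K_s}
  = 177 \;({\rm FrmR})\ \mathrm{or}\ 17.7\;({\rm RcnR}),$$
which the tests assert on every grid. Two consequences the model makes
quantitative: the tighter sensor is always ahead of the GSH pool
($f_s > f_g$ whenever $K_s < K_{\rm GSH}$), and the sensor pool itself
is thermodynamically invisible — removing the sensor term shifts free
formaldehyde by under $10^{-3}$ relative, which is also why the
1-vs-4-sites choice is immaterial (both are supported; 4 is the
default as the physically motivated count).

The curve's abscissa is *total* formaldehyde (free plus both bound
pools), since occupancy data are usually plotted against the added
amount; free formaldehyde is returned alongside so either convention
can be plotted. `formaldehyde_at_gsh_fraction()` inverts the GSH arm in
closed form ($F = \tfrac{f}{1-f}K_{\rm GSH}$, bound pools added back by
arithmetic), giving exact landmarks such as $f_g = 0.5$ at
$F = K_{\rm GSH}$. `copies_per_cell()` is the Avogadro conversion
(16.1 nM ≈ 9.7 copies at 1 fl).

## The synthetic-data generator

`gen_titration()` simulates the model curve and adds i.i.d. Gaussian
noise of constant standard deviation (default convention: 5% of
$\Delta r_{\max}$), in replicate sets under a strict seed contract
(identical seed ⇒ identical data; the caller's RNG stream is restored
afterwards). The default schedules mirror the two experimental
designs: 20 points over 0–2 µM monomer at 10 nM probe (trace regime,
where K is identifiable) and 20 points over 0–30 µM at 2.5 µM probe
(stoichiometric regime, where the breakpoint is). Constant Gaussian
noise matches the fitter's least-squares assumption by design — the
generator-fitter pair is self-consistent, which is what closed-loop
recovery tests require.

What passing the closed loop shows: the estimator is unbiased at zero
noise, recovers K to $|\log_{10}$ error$| < 0.1$ in ≥95% of seeded
5%-noise replicates (calibrated over 200 seeds before being frozen as
a test), and degrades honestly to lower-bound reporting when the design
cannot saturate. What it does not show: robustness to the features real
titrations have and the generator omits — signal drift, dilution
errors, heteroscedastic or correlated noise, probe depletion artefacts,
nonspecific binding at high protein. Conclusions about instrument data
still require the usual experimental controls.

## Problem sizes and runtime

All shipped computations are desk-scale by construction: titrations
are 20 points, speciation systems have 2–3 unknowns, the Monte-Carlo
recovery study uses 200 single-replicate fits (a few seconds in
total), and the full test suite runs in well under a minute. These
sizes were chosen as the smallest at which each property is
informative.

## Known limitations

* Equilibrium only — no kinetics, time courses, or irreversibility;
  the covalent sensor chemistry appears solely as an effective
  affinity.
* Equal stepwise affinities are the default and only fitted mechanism;
  cooperative ($K_1 \neq K_2$) fits are out of scope.
* The response weights (0.5/1.0) are an assumption, not a measurement;
  if a system's singly bound complex responds differently, set the
  weights accordingly.
* Error propagation uses replicate scatter, not fit covariance;
  temperature dependence of $\Delta G_C$ (van 't Hoff) is not
  modelled.
* The RcnR formaldehyde affinity is a tighter-limit estimate, so every
  RcnR competition output should be read as a bound, as the printed
  flags indicate.
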