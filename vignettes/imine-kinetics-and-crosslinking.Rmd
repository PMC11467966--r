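---
title: "From kinetic traces to hydrogel stiffness: the models behind dynimine"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From kinetic traces to hydrogel stiffness: the models behind dynimine}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dynimine)
```

## The scientific problem

Dynamic covalent hydrogels cross-linked by imine chemistry (oximes,
hydrazones, semicarbazones) owe their mechanics to a reversible
condensation: an amine and an aldehyde form an imine with forward rate
constant $k_1$ (L mol$^{-1}$ s$^{-1}$) and hydrolyse back with reverse
rate $k_{-1}$ (s$^{-1}$). The equilibrium constant
$K_{eq} = k_1/k_{-1}$ (L mol$^{-1}$) sets the bound fraction of
cross-linker at equilibrium and, through it, the cross-link density and
shear modulus of the network. `dynimine` implements the computational
chain from raw spectroscopic kinetics to these rate and equilibrium
constants (RECs), and from RECs to predicted cross-link fractions and
moduli — including the counterintuitive regime in which *adding* a second
cross-linker *softens* the gel.

## The kinetic model

For equimolar amine and aldehyde, both starting at $x_0$, the remaining
amine $x(t)$ obeys

$$\frac{dx}{dt} = -k_1 x^2 + k_{-1}(x_0 - x), \qquad x(0) = x_0 .$$

Factoring the right-hand side as $-k_1 (x-a)(x-b)$, with $a > 0 > b$ the
roots of $x^2 + (k_{-1}/k_1)x - (k_{-1}/k_1)x_0 = 0$, gives the closed
form implemented by `reversible_equimolar_solution()`:

$$x(t) = \frac{a(x_0-b) - b(x_0-a)\,e^{-k_1(a-b)t}}
              {(x_0-b) - (x_0-a)\,e^{-k_1(a-b)t}} .$$

$a$ is the equilibrium amine concentration (`equilibrium_amine()`), and
the irreversible limit $k_{-1}=0$ collapses to
$x(t) = x_0/(1+k_1 x_0 t)$. The test suite validates the closed form
against adaptive ODE integration to better than $10^{-8}$ relative over a
grid spanning the experimentally relevant parameter ranges.

## From spectra to concentration traces

The measured quantity is a UV-Vis absorbance series $A(\lambda, t)$,
sampled every 30 s for 7200 s with a 25 s dead time after mixing, with
detection at 240 nm (just above the solvent cutoff; the nearest
instrument grid point is used, never an interpolated one). The
processing chain is:

1. `preprocess_uvvis()` — subtract the first spectrum, removing the
   static reactant background so the trace reports imine formation only;
2. `absorbance_to_concentration()` — invert the Beer-Lambert law
   $A = \varepsilon c \ell$ using a molar absorptivity calibrated by
   `fit_molar_absorptivity()` (ordinary least squares; the intercept is
   estimated, reported, and warned about when significant rather than
   forced to zero, since a significant intercept usually signals an
   uncorrected background). Negative concentrations produced by noise
   are clipped to zero and counted, because the kinetic model requires
   $x \in [0, x_0]$;
3. `amine_consumption_trace()` — the model fits amine disappearance, so
   the measured imine is subtracted from the known initial amine:
   $x(t) = x_0 - [\mathrm{Im}](t)$.

Supporting calibrations follow the same conventions as the laboratory
workflow: `schiff_standard_concentrations()` does serial-dilution
bookkeeping for aldehyde quantification standards;
`degree_of_oxidation()` converts a measured aldehyde concentration to
the fraction of oxidized polysaccharide units, counting **two** aldehydes
per oxidized unit; `macromer_aldehyde_concentration()` computes the
reactive aldehyde concentration of a macromer solution as
$c = m D_f /(M_{Unit} V)$ with **one** reactive equivalent per
functionalized unit and a default $M_{Unit} = 198$ g mol$^{-1}$, the
only reading under which a 2 wt% solution at 10% functionalization gives
the 10.1 mM used throughout the prediction modules. Both counting
conventions are explicit parameters precisely because they differ by a
factor of two.

## Fitting and its failure modes

`fit_kinetics()` estimates $(k_1, k_{-1})$ by bounded
Levenberg-Marquardt least squares (via `minpack.lm`), restarted from a
small deterministic grid of scaled starting values; starts come from a
linearized irreversible fit of the first 10% of the trace ($k_1$) and a
detailed-balance estimate from the final plateau ($k_{-1}$). Standard
errors come from the fit covariance; $K_{eq}$ and its uncertainty are
propagated to first order.

Two failure modes get dedicated pathways:

* **Unidentifiable reverse rate.** When hydrolysis is too slow to leave a
  signature within the 2 h window, the free fit returns $k_{-1}$ with a
  relative standard error far above 100%. The `"auto"` pathway then
  switches to the constrained two-step fit: $k_1$ from the irreversible
  model, then $k_{-1}$ alone with $k_1$ held fixed. The escalation
  threshold (100% relative SE) is configurable. If $k_{-1}$ collapses
  onto its lower bound the fit is flagged `possibly_irreversible`.
  In the constrained step 1 we fit the irreversible model to the *early
  15% window* of the trace rather than its full length: the
  irreversible approximation is only valid before the reverse flux
  matters, and quantifying on the forward model shows the full-trace
  variant biases $k_{-1}$ by 30-90% (the small $k_1$ error swamps the
  weak reverse-flux signal) while the early-window variant keeps both
  parameters within ~15% even for strongly reversible traces.

* **Common-mode offset from background subtraction.** Subtracting the
  first *measured* spectrum anchors every point of the converted trace
  to that spectrum's noise realization. The strict two-parameter model
  cannot absorb a constant concentration offset, and Monte-Carlo
  simulation at the instrument noise level (0.002 a.u.) shows its
  standard errors then understate the estimator scatter roughly
  tenfold. `fit_kinetics(..., offset = "free")` therefore profiles out
  a constant offset analytically (the centred-residual projection,
  whose Jacobian yields the correct covariance of the remaining
  parameters). With the offset profiled, 3-SE intervals recover
  nominal coverage (98-100% observed at 200 seeds). The strict model
  stays the default for traces that were not background-anchored; the
  pipeline and the synthetic recovery study default to `"free"`.

Replicates are combined by `aggregate_replicates()`, and the aggregation
convention always travels with the result because the conventions
genuinely disagree: the mean of per-replicate $k_1/k_{-1}$ ratios can
differ from the ratio of the means by tens of percent when replicates
scatter. `per_replicate_mean` (the tabulation convention for the shipped
REC fixtures) is the default; `ratio_of_means` and a simultaneous
`global` fit are available.

## Equilibrium cross-linking and the softening regime

For a bifunctional amine cross-linker dosed at amine-function ratio
$\chi_{Am} = [Am]_0/[Ald]_0$, the equilibrium imine concentration is the
smaller root of $x^2 - (A_0 + B_0 + 1/K_{eq})x + A_0 B_0 = 0$
(`single_ligand_equilibrium()`, evaluated in the numerically stable
product form). An aldehyde only contributes a cross-link when the amine
bound to it has its sibling arm bound too; treating arm occupancies as
independent gives the ideal maximum cross-linked fraction

$$\chi_{XL}^{Ald} = \frac{[\mathrm{Im}]}{[Ald]_0}\cdot
                    \frac{[\mathrm{Im}]}{[Am]_0}.$$

At $[Ald]_0 = 10.1$ mM and $\chi_{Am} = 1$ this reproduces the
characteristic sensitivity window: $\chi_{XL}^{Ald} \approx 0.82$ at
$K_{eq} = 10^4$ falling to $\approx 0.15$ at $10^2$, with little to gain
above $10^4$ and little left below $10^2$.

With two competing amines, the free aldehyde concentration solves a
cubic whose coefficients are built from the two dissociation constants
$K_i = 1/K_{eq,i}$ and the initial concentrations — the exact closed
form for two ligands competing for one partner
(`competitive_equilibrium()`). We evaluate the trigonometric
three-real-root form, fall back to general polynomial root finding in
degenerate coefficient regimes, and polish with Newton iterations on the
aldehyde mass balance until it closes to $10^{-14}$ relative; all public
interfaces accept association constants and convert internally, to keep
the inversion in one place. Ligands are ordered canonically inside the
solver so relabelling the amines swaps the outputs exactly. The total
cross-linked fraction applies the per-amine form to each amine's imine
and sums, which encodes that imines of different cross-linkers cannot
pair with each other.

`softening_map()` evaluates
$\Delta\chi(K_1, K_2) = \chi_{total}(0.5 + 0.5) - \chi(0.5\ \text{only})$
over 121-point log-spaced grids spanning $10^1$-$10^7$ L mol$^{-1}$ and
refines the most negative cell by local regridding to two significant
figures. The refined argmin lands at
$K_{eq}(A_1) = 4.5\times 10^2$, $K_{eq}(A_2) = 2.0\times 10^1$
L mol$^{-1}$: a moderately bound network softens most when the
competitor binds weakly — strongly enough to steal aldehydes from
cross-links, too weakly to form its own.

A deliberate caveat, documented rather than hidden: the oxime/hydrazone
pair used for experimental validation
($K_{eq} \approx 1.3\times10^3$ and $1.0\times10^2$) sits marginally
*outside* the ideal model's softening regime
($\Delta\chi \approx +0.018$ at full addition), at the edge of the
negative region. Real networks carry loop defects that the ideal model
ignores, which shifts the actual regime towards higher $K_{eq}$ — the
measured titration softens even though the ideal surface predicts a
slight stiffening at that exact coordinate. Tests of the softening
*direction* therefore use $(4.5\times10^2, 2\times10^1)$, squarely
inside the regime, while the experimental pair is exercised for
forward-model consistency.

`bound_fraction_isotherm()` exposes the equimolar bound fraction
$[\mathrm{Im}]/[X]_0$ against $K_{eq}$; only the product $K_{eq}[X]_0$
matters, so changing the concentration regime shifts the isotherm along
the $\log K_{eq}$ axis without changing its shape. Alternative isotherm
expressions (e.g. force-sensitive or distribution-based treatments from
transient-network theories) plug in through
`register_isotherm_model()`; none are bundled, since their functional
forms belong to their respective theories.

`correlate_descriptor_vs_log_rec()` regresses $\log_{10}$ RECs on
dimensionless computed free energies (shipped in `dft_descriptors()`,
converted from kcal mol$^{-1}$ at 298.15 K). For the oxidized-alginate
aldehyde series the breakdown free energy of the tetrahedral
intermediate against $\log k_1$ gives $r^2 \approx 0.9$; most other
descriptor/constant pairs correlate only weakly, which is the expected
outcome of the simplified energy landscape behind those descriptors.

## Network mechanics

`ve_from_modulus()` and `modulus_from_ve()` convert between the shear
storage modulus and the concentration of elastically active chain
segments under the affine ($G' = v_e RT$) and phantom
($G' = (1-2/f)\,v_e RT$) models, with temperature explicit everywhere
(default 293.15 K, the rheometry temperature). The affine convention is
fixed by the anchor $G' = 2200\ \mathrm{Pa} \rightarrow v_e \approx
0.90$ mM; for the high junction functionalities of side-chain
functionalized macromers the phantom correction approaches affine
behaviour. `relative_softening_prediction()` scales an anchor modulus
by the ratio of cross-linked fractions ($G' \propto \chi_{XL}^{Ald}$,
the default) or by the per-amine squared-bound-fraction index
(`per_amine_crosslink_index()`); the two modes differ in how strictly
"cross-link" is counted and neither is claimed exact.

## The synthetic-data generator

Every pipeline stage is testable without instrument data because
`generate_absorbance_trace()` emulates the acquisition end to end:
$A(t) = \text{baseline} + \varepsilon \ell\,(x_0 - x(t)) +
\mathcal{N}(0, \sigma^2)$, sampled every 30 s for 7200 s starting 25 s
after mixing. Choices that matter:

* **Noise is additive on absorbance**, not on concentration — the
  concentration noise arises through the $\varepsilon$ division exactly
  as in the real pathway, which is also what makes the background
  subtraction inject the common-mode offset discussed above. Default
  $\sigma = 0.002$ a.u., a realistic scatter for imine signals below
  0.1 a.u.
* **Replicate jitter is lognormal** on the rate constants (CV 0.1 by
  default), keeping them positive, as `generate_replicate_set()` uses to
  emulate day-to-day variation.
* **Determinism**: a seed is mandatory for any stochastic output and
  identical seeds give byte-identical CSVs.
* Defaults mirror the oxime-on-oxidized-alginate measurement
  ($k_1 = 0.058$, $k_{-1} = 5.2\times10^{-5}$, $x_0 = 0.5$ mM,
  $\varepsilon = 950$); `synthetic_gel_spec()` defaults to the
  experimental titration (10.1 mM aldehyde, $K_{eq}$ pair
  $1.3\times10^3 / 1.0\times10^2$, anchor 2200 Pa, triplicates with
  80 Pa measurement noise, a typical rheometer repeatability at 2 kPa).

What passing these tests shows — and does not. The generator reproduces
the sampling, noise structure and dead time of the acquisition, so
parameter-recovery results (bias ~1%, calibrated 3-SE coverage at 200
seeds) are evidence about the estimator under those conditions. It does
not emulate side reactions, hemiacetal speciation, salt-dependent rate
shifts, baseline drift, or loop defects in gels; conclusions about real
data carry the usual caveats for those effects.

`parameter_recovery_study()` runs the full generate → preprocess →
convert → fit chain over a grid of conditions and seeds and reports
bias, RMSE, 3-SE coverage and how often the constrained pathway
engaged. Problem sizes used by the shipped tests — 200 seeds for the
coverage study, 1000 instances for the cubic-versus-bisection check,
a 121$^2$ softening grid — were chosen as the smallest sizes at which the
Monte-Carlo error is comfortably below the tolerances being asserted.

## Orchestration

`run_rec_pipeline()` drives batches of spectral-series CSVs through the
chain with per-trace logging of every decision (wavelength actually
used, clipped points, constrained-fit escalations) and writes a REC
table plus JSON fit dumps and the resolved configuration;
`run_prediction_pipeline()` emits the figure-level artifacts (fraction
curves, the softening map and its argmin, isotherms, predicted modulus
series). Both are plain R functions configured by lists or JSON files —
this package is an analysis library, so its programmatic surface and
this vignette are the interface; no shell executable is shipped.
Re-running either pipeline with the same inputs produces byte-identical
outputs.

## Numerical choices and degenerate inputs, collected

* Quadratics are solved in the $2c/(b+\sqrt{b^2-4c})$ form; the cubic by
  the trigonometric form with clamped cosine argument, polyroot
  fallback, and Newton polish. Mass balances are asserted to $10^{-10}$
  relative at the API boundary.
* $K_{eq} = 0$ and $K_{eq} = \infty$ are handled explicitly (no binding /
  complete binding); $k_1 = k_{-1} = 0$ is a valid no-reaction input,
  not an error; a flat trace fits as $k_1 = 0$ flagged `degenerate`.
* Optimizer: tolerance $10^{-12}$, at most 10 000 evaluations, three
  deterministic restarts; ties are not expected for this 2-parameter
  monotone-residual model.
* Amine excess in competitive systems ($\chi_{Am} > 1$) is rejected by
  default and available behind `allow_excess`, because past saturation
  the cross-linked-fraction interpretation changes regime.

## Known limitations

The cross-link model is ideal: no loops, no dangling ends, no
entanglement contribution, arm-independence assumed. $G' \propto \chi$
is a proportionality, not an absolute prediction — the macromer-derived
chain concentration overpredicts the measured modulus about fivefold,
which is typical for heterogeneous side-chain functionalized networks.
Kinetics are single-condition: no pH, salt or temperature dependence is
modelled. NMR-derived concentration traces are accepted pre-integrated;
peak processing is out of scope.
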