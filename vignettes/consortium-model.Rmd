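---
title: "Modelling a reciprocally cross-feeding two-strain consortium"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling a reciprocally cross-feeding two-strain consortium}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(syntrophr)
```

## The system and the model

Two engineered *Pseudomonas putida* strains are made obligately mutual by
reciprocal substrate processing: CP-X metabolizes xylose and expresses the
β-glucosidase BglC that hydrolyses cellobiose into glucose; CP-G
metabolizes glucose and expresses the β-xylosidase Xyl43A that hydrolyses
xylobiose into xylose. On a cellobiose + xylobiose medium each strain's
growth substrate is produced by its partner, so neither grows alone.

The model tracks only the two optical densities $X$ (CP-X) and $G$ (CP-G);
sugars and enzymes are not state variables. Each strain grows logistically
at a maximum specific rate ($r_{mx}$, $r_{mg}$, in h$^{-1}$), gated by a
Monod-type saturation in the *partner's* density, and both share one
carrying capacity $K$:

$$\frac{dX}{dt} = \frac{r_{mx}}{\alpha_{Bx}}
  \frac{\alpha_{Dg}\,G}{C_g+G}\left(1-\frac{G+X}{\alpha_K K}\right) X,
  \qquad
  \frac{dG}{dt} = r_{mg}
  \frac{\alpha_{Dx}\,X}{C_x/\alpha_{Ex}+X}\left(1-\frac{G+X}{\alpha_K K}\right) G.$$

The factor $G/(C_g+G)$ stands for xylobiose-to-xylose conversion by CP-G,
and $X/(C_x+X)$ for cellobiose-to-glucose conversion by CP-X. $C_x$ and
$C_g$ (OD units) are inversely proportional to the amounts of BglC and
Xyl43A: more enzyme means the factor saturates at lower partner density.
The model assumes well-mixed wells, no explicit sugar depletion (the
capacity term absorbs resource exhaustion), and no spatial structure.

The dimensionless $\alpha$ factors project the fitted baseline onto new
scenarios: $\alpha_{Dx}$ and $\alpha_{Dg}$ scale the cross-feeding factors
proportionally to the initial cellobiose and xylobiose amounts (reference
1 g/l each — the cultivation on which the baseline was fitted);
$\alpha_{Bx}$ divides $r_{mx}$ to express BglC expression/degradation
burden; $\alpha_{Ex}$ divides $C_x$ to express BglC amount. The capacity
is scaled by the most restrictive resource,
$\alpha_K=\min\{\alpha_{Ex},\alpha_{Dx},\alpha_{Dg}\}$; the burden factor
deliberately does not enter the minimum (burden slows CP-X but does not
remove resources), and no symmetric burden factor for CP-G is introduced:
in this consortium the heterologous load falls almost entirely on CP-X,
and the model keeps that asymmetry as-is.

The baseline parameter set, fitted on the cooperating consortium, is
`baseline_parameters()`: $r_{mx}=0.12$, $r_{mg}=0.34$ h$^{-1}$,
$C_x=0.04$, $C_g=0.02$, $K=0.82$.

Two structural consequences are worth noting, because the test suite
leans on them: (i) *mutual obligacy* — if either strain starts at zero,
both derivatives vanish and the trajectory is frozen; (ii) the total
$X+G$ converges to $\alpha_K K$ from any positive initial state, so the
long-run total measures the effective capacity, not the growth rates.

## Numerical choices

Integration uses `deSolve::lsoda` with `rtol = 1e-8`, `atol = 1e-10`; the
dynamics are only mildly stiff, and an independent fixed-step RK4
implementation (kept in the test helpers, sharing no code with the
package) agrees with the adaptive solution to better than $10^{-5}$ OD.
Round-off can push a component a hair below zero; values down to
$-10^{-8}$ are clipped to 0 at output and anything lower is treated as an
integrator failure. Default output grid: 72 h every 0.5 h, mirroring the
plate-reader protocol (145 points); equilibrium checks use longer
horizons (300 h for the baseline).

## Parameter fitting

Fitting uses bounded multistart least squares. The residual is the
concatenation of (simulated total OD − observed total OD) and (simulated
CP-X OD − observed CP-X OD) over all replicate wells, equally weighted:
the total comes straight from the plate reader, the CP-X series from the
GFP calibration, and neither is privileged over the other.
Optimisation runs in log-parameter space under box bounds
($r \in [10^{-3}, 2]$ h$^{-1}$, $C \in [10^{-4}, 1]$ OD,
$K \in [0.05, 5]$ OD — generous brackets around plausible values) with
`minpack.lm::nls.lm`, 8 starts by default: the first at the centre of the
log-bounds box, the rest drawn log-uniformly under a fixed seed, best
residual norm wins. Flat series (max/min total OD below 1.2) are rejected
as degenerate rather than fitted.

The initial state defaults to the first observed time point (CP-X from
the calibrated GFP series, CP-G by subtraction). When the experiment's
inoculation densities are known — always true for synthetic-data studies,
and usually true in practice — they should be passed explicitly via
`initial`: at an inoculum of 0.01 OD a single read with 0.01 OD noise is
a poor state estimate, and the recovery experiments in this package pass
the known `X0 = G0 = 0.01`.

Identifiability is uneven: with 3 replicates of 145 points at 0.01 OD
noise, $r_{mx}$, $r_{mg}$ and $K$ recover tightly (the acceptance checks
require $\pm 0.02$ and $\pm 0.03$ on the rates), while $C_x$ and $C_g$
are weakly identified from OD-only data — they shape mainly the early
transition, where the signal sits near the noise floor. They are fitted
and reported, but downstream conclusions should not lean on their point
estimates.

## Fluorescence calibration and deconvolution

Continuous calibration curves map channel fluorescence (AU) to
single-strain OD using monoculture wells grown on the strain's
monosaccharide. Fluorescence–OD relationships are near-linear at low
density and flatten as absorbance and quenching set in, so the curve is a
two-segment model — linear at low signal, quadratic above, continuous at
a breakpoint chosen to minimise in-sample RMSE — accepted only if the
fitted map is monotone non-decreasing over its range, with a plain linear
fit as fallback. Raw relationships with Spearman correlation below 0.9
are rejected outright. Predictions outside the calibrated range are
clamped to boundary ODs and flagged, never extrapolated.

CP-X is quantified from its GFP channel. CP-G is quantified as
`total − CP-X` rather than from its mScarlet channel, because mScarlet's
slow chromophore maturation makes the red signal lag biomass; the
subtraction is clamped at zero, and clamping events are counted and
reported rather than dropped.

## Growth and conversion metrics

* **Maximum specific growth rate**: the largest least-squares slope of
  $\ln(\mathrm{OD})$ over a sliding window of 5 samples (2.5 h at the
  half-hour cadence) restricted to ODs above a 0.02 floor; window and
  floor are configurable, chosen to suppress read noise near the
  detection limit. On model trajectories the estimate respects the bound
  $\mu_{\max} \le \max(r_{mx}/\alpha_{Bx},\, r_{mg})$ since the gating
  factors never exceed 1.
* **Lag time**: the tangent construction — extrapolate the log-space
  tangent at the $\mu_{\max}$ window back to the initial OD level. Chosen
  over threshold crossing because it is standard in growth-curve analysis
  and robust to the noise floor.
* **Conversion rate**: magnitude of the least-squares slope of a
  disaccharide HPLC series over its depletion segment, which ends when
  the concentration first falls below 10% of its initial value — both the
  HPLC quantification floor and late-time evaporation (which concentrates
  the remaining sugars and can make them *rise*) corrupt the tail.

## Synthetic data: what it emulates, what it does not

The generators exist so that every pipeline stage is testable without any
instrument files. `generate_plate_reader()` converts a simulated
trajectory to the three measured channels: OD600 $= X+G$, GFP
$= \mathrm{yield}_x X$, and mScarlet $= \mathrm{yield}_g M(G)$ where $M$
is a first-order low-pass (`mature_lag()`) with a 40 min default half
time standing in for slow chromophore maturation; the filter initialises
at $M(0)=G(0)$, i.e. a pre-equilibrated overnight inoculum. Gaussian read
noise (defaults: 0.01 OD, 20 AU) and an optional multiplicative
evaporation drift $(1+r)^{t-t_0}$ after $t_0 = 48$ h are applied, then
signals are clipped at zero. Fluorescence yields (10000 and 8000 AU/OD)
are free parameters — real AU scales depend on instrument gain settings.

`generate_hplc()` depletes each disaccharide linearly at a given rate
(zero-order hydrolysis by a fixed resting-cell enzyme pool, clipped at
zero) and credits the monosaccharide with the hydration mass gain of
hydrolysis — glucose gains $360.32/342.30$ g per g cellobiose, xylose
$300.26/282.25$ g per g xylobiose, from the molar masses (cellobiose
342.30, glucose 180.16, xylobiose 282.25, xylose 150.13 g/mol) — minus
linear consumption, clipped at zero. Mass balance is exact at zero noise.
All generators are pure functions of their inputs and a seed, and leave
the caller's RNG stream untouched.

What passing tests on these fixtures shows: the estimators and the
fitting machinery are correct against known generating truth under
realistic noise. What it does not show: agreement with real plate-reader
curves — real cultures add lag-phase physiology, oxygen limitation,
clumping, instrument drift and calibration bias that the generators do
not emulate, so conclusions about a real consortium still require the
corresponding wet-lab measurements.

## Problem sizes and defaults used in the shipped checks

The recovery experiments use the study's own conditions: 3 replicate
wells, 0–72 h at 0.5 h (145 points), Gaussian noise sd 0.01 OD for
growth curves; 16 HPLC points over 48 h from 2 g/l at noise sd
0.02 g/l for the conversion rates; 8 multistart draws for each fit.
Equilibrium is assessed at 300 h. These sizes were fixed once, before the
checks were run, as the realistic desk-scale rendering of the protocol.

## Known limitations

* No substrate state variables: scenarios where sugar kinetics decouple
  from biomass (e.g. enzyme leakage into the medium, extracellular
  hydrolysis) are outside the model; no extracellular-conversion terms
  are implemented.
* $C_x$, $C_g$ weakly identifiable from OD-only data (above).
* The burden scaling enters only CP-X; consortia with appreciable burden
  on the partner strain need a model extension, not a scaling factor.
* Continuous (chemostat) cultivation, stochastic and spatial dynamics are
  out of scope.
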