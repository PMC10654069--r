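---
title: "Growth under phosphorus limitation: model, calibration and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Growth under phosphorus limitation: model, calibration and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cfmphyto)
```

## The problem

Culture experiments across phytoplankton taxa show the same pattern: as the
phosphate concentration of the medium rises, the specific growth rate first
climbs steeply and then flattens onto a plateau. The Monod equation

$$\mu = \mu_{max}\,\frac{S}{K_S + S}$$

describes that saturating shape with two empirical constants but says
nothing about *why* growth saturates. `cfmphyto` implements a coarse-grained
cell flux model that produces the same curve from the inside: the rise is
phosphorus limitation, the plateau is carbon limitation, and the shape of
the transition follows from how the cell allocates carbon and phosphorus
among its macromolecules.

## The allocation model

Cellular composition is tracked as quotas — amounts per unit cellular
carbon. The carbon budget must close (storage `Q_C_Csto` takes the slack):

$$1 = Q^{C}_{Pro} + Q^{C}_{RNA} + Q^{C}_{DNA} + Q^{C}_{Chl}
    + Q^{C}_{Plip\text{-}Thy} + Q^{C}_{Csto} + Q^{C}_{Other}$$

with the growth-rate dependences

* **chlorophyll** $Q^C_{Chl} = (1+E)\,\mu / P_I$, where
  $P_I = P_{max}(1 - e^{-O_I I})$ is the light-saturating photosynthesis
  rate: faster growth needs proportionally more carbon fixation, inflated
  by the respiration/excretion overhead $E$;
* **protein** $Q^C_{Pro} = A_{Pho} Q^C_{Chl} + A_{Bio}\,\mu +
  Q^C_{Pro,other}$: photosynthetic machinery scales with chlorophyll (the
  ratio $A_{Pho}$ is a species property), biosynthetic enzymes scale with
  growth, and a constant term covers essential protein — linear in $\mu$;
* **RNA** $Q^C_{RNA} = Q^C_{RNA,min} + A_{RNA}\,\mu\, Q^C_{Pro}$:
  ribosome demand scales with the protein synthesis flux, i.e. with
  $\mu \times$ protein, making RNA *quadratic* in $\mu$ — the single most
  consequential structural feature of the model;
* thylakoid phospholipid proportional to chlorophyll
  ($A_{Plip} Q^C_{Chl}$); DNA and "other" constant.

Phosphorus rides on the carbon quotas through fixed stoichiometry,

$$Q_P = Y_{RNA} Q^C_{RNA} + Y_{DNA} Q^C_{DNA}
      + Y_{Plip} Q^C_{Plip\text{-}Thy} + Q_{P,other},$$

so $Q_P(\mu)$ inherits RNA's quadratic term. Uptake is diffusion limited
and linear in the medium concentration, $V_P = A_P[\mathrm{PO_4^{3-}}]$;
at steady state uptake balances dilution by growth, $V_P = \mu Q_P(\mu)$.

Two closure conditions then determine growth:

* **Carbon limitation** — set $Q^C_{Csto} = 0$ in the carbon budget;
  collecting powers of $\mu$ gives a quadratic
  $a_C \mu^2 + b_C \mu + c_C = 0$ whose positive root $\mu_C$ is the
  plateau.
* **Phosphorus limitation** — substitute $Q_P(\mu)$ into the steady-state
  balance; because the balance multiplies the quadratic quota by another
  factor of $\mu$, the result is a cubic
  $a_P \mu^3 + b_P \mu^2 + c_P \mu + d_P = 0$ with $d_P = -A_P[\mathrm{PO_4^{3-}}]$.

The realized rate is $\mu = \min(\mu_P, \mu_C)$. Below the crossover
concentration the cell is phosphorus limited and stores surplus carbon;
above it growth is *exactly* constant at $\mu_C$ — the plateau is a hard
ceiling, not an asymptote, which is the qualitative difference from Monod.

The nitrogen variant replaces the P stoichiometry with N:C ratios
(protein and RNA dominate the N budget) and `A_N`; everything else,
including the carbon-limited plateau, is shared.

## Parameters

All concentrations are µM, rates d⁻¹, quotas mol (mol C)⁻¹; `A_P` carries
(mol P (mol C)⁻¹ d⁻¹) µM⁻¹ so the uptake law is dimensionally closed. The
`default` profile ships as annotated YAML (`inst/params/default.yaml`) and
is loaded by `default_cell_params()`; alternative profiles go through
`read_cell_params()` so values are versioned in files, never hard-coded.

The stoichiometric ratios are fixed by molecular composition and were set
from it: one phosphate bridge per ~9.5 ribonucleotide carbons gives
`Y_RNA = Y_DNA = 0.105`; a glycerophospholipid carries one P per ~40 C
(`Y_Plip = 0.025`); mean amino-acid composition gives protein N:C of 0.27
and chlorophyll *a* contains 4 N per 55 C (`Y_Chl_N = 0.073`). The
allocation coefficients (`E = 0.6`, `A_Bio = 0.25` d, `A_RNA = 0.18` d,
`A_Plip = 0.12`, the constant quotas, `P_max = 260` d⁻¹,
`O_I = 0.00863` (µmol photons m⁻² s⁻¹)⁻¹) are of the magnitude used across
the cell-flux-model literature and growth-law studies. The two parameters
that calibration varies per species are the phosphate affinity `A_P`
(slope of the uptake line) and the machinery-to-chlorophyll ratio `A_Pho`
(which sets how expensive photosynthesis is in carbon, and with it the
plateau). At the profile's reference irradiance of 200 µmol photons
m⁻² s⁻¹ and `A_Pho = 3.0` the profile saturates at

```{r}
solve_c_limited(cfm_env(0, 200), default_cell_params())
```

the example-run plateau the profile is anchored to. The thylakoid
phospholipid is scaled to chlorophyll (`A_Plip · Q_C_Chl`): membrane lipid
area tracks the pigment bed it houses; scaling it to total machinery would
only rescale `A_Plip` by roughly `A_Pho` and is not separately
identifiable. A µ-independent RNA floor `Q_C_RNA_min` is kept (transcripts
a cell maintains at zero growth) and is configurable; it only shifts the
constant terms of the polynomials.

## Solving the polynomials

Closed-form roots of cubics are numerically fragile near discriminant
boundaries, so every root is treated with suspicion: candidates come from
`polyroot()`, are polished by Newton steps on the residual, validated
against the defining balance, and a guarded bisection on the residual
function is the fallback. For the cubic the *smallest* non-negative real
root is the physical one — it is the branch continuously connected to
$\mu = 0$ at zero phosphate; since every coefficient of $\mu Q_P(\mu)$ is
non-negative the balance is monotone and that root is in fact unique, which
the test suite exploits by cross-checking both solvers against an
independent bisection oracle (10⁻⁸ agreement over 1000 random parameter
draws spanning wide physiological ranges). Inside calibration, where the
cubic is solved tens of thousands of times, a vectorized damped-Newton
iteration bracketed on $[0, \mu_C]$ does the same job ~30× faster and
falls back to the guarded solver whenever its residual check fails.

A growth rate whose carbon budget cannot close (negative storage) raises a
typed condition (`cfm_infeasible`) rather than being clamped: silent
clamping would let calibration wander through impossible parameter regions
unnoticed. The sampler maps the condition to a log-likelihood of $-\infty$,
i.e. a clean rejection.

## Calibration

The likelihood is iid Gaussian on growth-rate residuals with fixed
`noise_sigma` (default 0.05 d⁻¹) — the simplest defensible objective for
digitized growth measurements, and configurable. Priors are independent
uniforms on $(0, \text{upper})$; the posterior is then proportional to the
likelihood inside the box and the MAP is the maximum-likelihood fit.
Sampling is random-walk Metropolis–Hastings with symmetric Gaussian
proposals per parameter: initial values are config-supplied (a coarse
log-spaced grid scan over the prior box is the automatic fallback), chains
are bit-reproducible given a seed, and diagnostics warn — never silently
pass — on acceptance rates outside 0.10–0.60, on chains that never move,
and on split-half mean drift. Point estimates report the posterior mean
with the MAP alongside; multimodality, if any, stays visible in the
returned samples. Only `A_P` and `A_Pho` vary for the allocation model
(`fit_cfm()`); all other parameters stay at the profile, and each dataset
is fit at its own culture irradiance.

## The synthetic-data generator

`generate_dataset()` emulates what the real calibration inputs look like:
5–20 concentrations (log-spaced by default), a clean curve from either
generator, and additive Gaussian noise with σ = 0.05 d⁻¹ truncated at zero
— truncation rather than resampling keeps a dataset a pure function of its
seed. For clean rates ≥ 0.2 d⁻¹ the truncation moves the mean by under
10⁻⁴ d⁻¹ (tested), so the noise is effectively unbiased where data carry
information. `fixture_suite()` draws organisms with affinities 0.01–0.1
µM⁻¹, `A_Pho` 2–4.5 and irradiances 50–400, and sizes each grid around the
organism's own crossover so both phases are sampled. A third generator
multiplies the clean curve by an exponential decline above a threshold to
mimic the high-phosphate growth inhibition some species show; it exists
purely as a negative control, since neither model is meant to capture it.

What passing tests on synthetic data do **not** show: the generator's noise
is iid and Gaussian, its grids are well placed, and its truth lives inside
the model family. Real digitized datasets have correlated digitization
error, irregular grids that may miss the plateau, and organisms whose
fixed-profile constants differ from the default — so parameter recovery
here bounds sampler and identifiability error, not biological accuracy.

## Problem sizes

The shipped checks run the oracle comparison at 1000 random draws, the
two-phase sweep at 100 parameter sets, recovery at 10 seeds × 20 000
iterations (n = 20, σ = 0.05), and model-equivalence at 4 fixtures with
6 000-iteration chains — sizes at which every Monte-Carlo margin in the
suite is several times its observed spread.

## Known limitations

* No phosphorus storage: luxury uptake under carbon limitation is real but
  outside this model; predicted P quotas on the plateau are lower bounds.
* No growth inhibition at high phosphate; the inhibition generator exists
  only to test that the models *fail* on such data.
* No temperature dependence, and no dynamic (non-steady-state) quota
  simulation — the balance is solved at `dQ_P/dt = 0` only.
* The N variant is the simplified comparison form (shared carbon side,
  N stoichiometry on protein/RNA/DNA/chlorophyll), intended for the
  P-vs-N contrast rather than as a full nitrogen-limitation treatment.
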