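---
title: "Modelling osteoarthritis progression and treatment with oasim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling osteoarthritis progression and treatment with oasim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oasim)
```

## The model

`oasim` simulates the progression of osteoarthritis (OA) in an aging cohort
(ages 50–90) as a system of reaction–diffusion equations on the articular
cartilage strip $\Omega = [0, h]$, $h = 0.2$ cm. Seven species are tracked,
all in g/cm³:

* $C$ — healthy chondrocytes, sourced at rate $A$ and lost to death
  ($\mu_C$), senescence ($\lambda_{CC_s}$) and hypertrophy;
* $C_s$ — senescent chondrocytes, cleared by the immune system at the
  age-dependent rate $\mu_{C_s}(t)$ and secreting MMP13;
* $C_h$ — hypertrophic chondrocytes, produced from $C$ at rate
  $\lambda_{CC_h}/(1 + L_2/K_{L_2})$ — collagen II blocks hypertrophy — and
  turning over in about a day ($\mu_{C_h} = 2.77$ d⁻¹);
* $C_c$ — calcified cartilage, the disease-severity readout, driven by
  hypertrophy dynamics through the bookkeeping term
  $\lambda_{C_hC_c}\,\partial C_h/\partial t$;
* $M_P$ — MMP13, produced by senescent cells, degrading collagen II;
* $L_2$ — collagen type II, secreted by chondrocytes, degraded
  intrinsically, by MMP13, and (in women) by the postmenopausal term;
* $D$ — the senolytic fisetin, when administered.

The male/female switch adds two terms for women: $+\,dp_{M_P}(t)\,M_P$ in
the MMP13 equation and $-\,dp_{L_2}(t)\,L_2$ in the collagen II equation,
with $dp_X(t) = \alpha_{wX}/(1 + t^2/T_{wX}^2)$ ($t$, $T_{wX}$ in years
since age 50, $T_{wX} = 12$ y). Integrated over the postmenopausal decade
this drains collagen II roughly six-fold in women, which is what makes the
simulated disease more severe in women.

Cells satisfy zero-flux boundary conditions; proteins and drug leak through
both boundaries via a Robin condition $\partial X/\partial n + \alpha X = 0$.
Two drugs are modelled: UC-II (undenatured collagen II), a constant-rate
collagen source $\alpha_{U_2}\gamma_{U_2}$ on dosing days; and fisetin,
whose administration days contribute exponentially decaying impulses
$h_D(t) = \sum_{t_d \le t} e^{-\mu_D (t - t_d)}$ feeding the drug equation
at rate $\gamma_D h_D(t)$. Fisetin kills senescent cells
($\mu_{C_sD} C_s D$) and suppresses MMP13 production by the factor
$1/(1 + \alpha_D D)$.

All parameter defaults are the published estimates; `regenerate_table()`
re-derives every derivable entry from its primary sources (molecular
weights, half-lives, doses, steady-state tissue levels) and flags agreement
at printed precision. Two estimation details matter for exact agreement:
the steady-state chain propagates the degradation rates at the precision
they are reported with (e.g. $\mu_{L_2} = 1.62\times10^{-5}$ d⁻¹, not
$\ln 2 / 42705$ to machine precision), and the senescent level entering the
MMP13 balance is $C_s^0 = 4.1\times10^{-3}$ g/cm³. One published constant
is not reproducible from its own stated formula:
$\lambda_{CC_h}$ evaluates to $3.23\times10^{-2}$ d⁻¹ while the table
prints $3.26\times10^{-2}$; the package keeps the printed value as the
simulation default and reports the recomputed one alongside it.

## Structural choices

**The calcification term.** The hypertrophy equation as printed contains
$-\lambda_{C_hC_c}\,\partial C_h/\partial t$ on its right-hand side with
$\lambda_{C_hC_c} = 10^4$. Moving the term to the left-hand side
("algebraic elimination") divides the whole $C_h$ rate by
$1 + \lambda_{C_hC_c}$, turning hypertrophic chondrocytes into a
~10-year-lag variable. That reading contradicts the model's own parameter
estimation, which derives $\mu_{C_h} = 2.77$ d⁻¹ from a one-day lifespan
and calibrates $\lambda_{CC_h}$ from a quasi-steady hypertrophy balance
without the term; it also pins male calcification at zero for decades
(no steady state of the default parameters puts $C_h$ above its initial
value), making every treatment-efficacy ratio undefined. The package
therefore defaults to the fast reading: $C_h$ relaxes at rate $\mu_{C_h}$,
and $\lambda_{C_hC_c}\,\partial C_h/\partial t$ acts purely as the source
of calcified cartilage (discretely, $C_c$ gains
$\lambda_{C_hC_c}\,\Delta C_h$ per step, including the diffusive part of
$\Delta C_h$). The eliminated variant remains available:
`oa_params(ch_calcification_sink = "algebraic")`.

**Initial hypertrophy transient.** The published initial state sets
$C_h(50) = 2.7\times10^{-4}$ g/cm³, the OA-average level, which lies above
the hypertrophy equilibrium at healthy collagen levels. In the first day or
two of every run $C_h$ relaxes downward, so the literal calcification
source is negative; the solver's positivity clip holds $C_c$ at zero until
collagen II has declined enough for hypertrophy to grow. A clamp that
discards negative calcification increments explicitly is available
(`cc_source_clamp = TRUE`) and changes nothing after the first days.

**Senescent-cell clearance.** $\mu_{C_s}(t) = \mu_{C_s0}(1 + t/90\,\text{y})$
increases with age by default, following the source's explicit statement,
even though the biological motivation (immune decline) reads the other way;
`oa_params(mu_cs_aging = "decreasing")` selects
$\mu_{C_s0}/(1 + t/90\,\text{y})$.

**The boundary leak rate.** The Robin constant $\alpha$ is stated only as
"some $\alpha > 0$". It is not a free dial: for $\alpha \gtrsim 10^{-2}$
cm⁻¹ the leak rate $2\delta_{L_2}\alpha/h$ dwarfs every calibrated collagen
loss channel, collapsing $L_2$ within days and erasing all drug effects,
while for $\alpha \to 0$ male collagen II never declines and men never
develop calcification. The package calibrates $\alpha$ once, by
root-finding the value at which the untreated male collagen II average
falls to the reported OA level ($1.7\times10^{-4}/6 = 2.83\times10^{-5}$
g/cm³, the ~six-fold degradation reported beyond age 70) at age 70:
$\alpha = 4.9\times10^{-4}$ cm⁻¹ (two significant figures;
`calibrate_leak_rate()` reproduces the computation). The value is exposed
as `bc_leak_alpha` and recorded in all output metadata.

**Calendar and evaluation conventions.** Month = 30 d, week = 7 d,
6 months = 182 d, on/off year = 364 d; dosing windows are half-open
`[start, end)`. Ages convert at 365 days/year with age 50 as $t = 0$;
every simulation starts at age 50 from the single published initial state,
so any treated run is reproducible from printed inputs alone. Trial-matrix
cells are evaluated at their end age (matching the narrative reading of
the published efficacy tables, e.g. "efficacy achieved by age 70");
`trial_matrix(evaluate_at = 90)` provides the fixed-age caption reading.

## Numerics

Uniform grid (41 nodes by default, $\Delta x = h/40$), centred second
differences, ghost-node boundary rows. Time stepping is first-order IMEX
with $\Delta t = 0.05$ d: diffusion is integrated implicitly (backward
Euler, prefactored tridiagonal solves; the Robin rows make the system an
M-matrix, so positivity survives the solve), and reactions use a
production–destruction split that is semi-implicit in each species' own
loss terms, $X \leftarrow (X + \Delta t\,P)/(1 + \Delta t\,\Lambda)$ —
unconditionally stable and positivity-preserving for the stiff MMP13
kinetics ($\Lambda \approx 22$ d⁻¹ at healthy collagen levels). The
fisetin impulse input is advanced by exact exponential decay and averaged
exactly over each step, so the integrated dose is independent of
$\Delta t$. Any residual negativity (never observed beyond rounding for
the defaults) is clipped, tracked per species and reported.

Verification, all in the test suite: diffusion-only runs conserve cell
mass to $10^{-8}$ relative and lose protein mass monotonically; the
discrete operator converges at order 2 on the zero-flux eigenfunction
$\cos(\pi x/h)$; refining 21→41 nodes moves recorded averages by <1% and
halving $\Delta t$ by <0.1%; and an 11-day two-dose run agrees with an
independent integration of the same method-of-lines system by
`deSolve::lsoda` to a fraction of a percent per species. The solver path
is deterministic: identical inputs give bitwise-identical output.

Problem sizes used by the tests were chosen to exercise every claim at
desk scale: structural trial-matrix checks run on initiation/end ages
{50, 60, 70} at the default grid, and the sensitivity analysis uses 200
LHS samples on a 21-node grid for its one-year horizon.

## Treatment trials

`efficacy()` is the relative reduction of the calcified-cartilage spatial
average against the matched untreated run; `e_efficacy()` weights the two
sexes by cohort counts. `run_treatment_scenario()` reproduces the four
published 90-day UC-II studies (T1–T4: 30/22, 89/97, 36/69 and 0/39
male/female participants, evaluated at average ages 63, 63, 70 and 65),
and `trial_matrix()` sweeps initiation × end ages for the UC-II, fisetin
and combination arms with monthly, weekly or 7-on/7-off fisetin patterns.

Two quantitative caveats, both consequences of the published parameter
set rather than of the numerics. First, the fisetin-only arm is bounded
near zero here: fisetin acts solely by suppressing MMP13, and the tenfold
dominance assumption built into the calibration caps MMP13-mediated
collagen loss at a tenth of intrinsic degradation, so the arm cannot move
calcification by more than a fraction of a percent — far below the
published double-digit fisetin efficacies. Consequently the synergy
inequality (combination > sum of single arms), while holding in most
cells, can fail marginally (interaction ~$10^{-3}$ percentage points) in
short windows. Second, absolute efficacy levels depend on the leak
calibration above; the package's 90-day scenario efficacies come out an
order of magnitude above the published fractions of a percent, while
multi-decade UC-II efficacies land in the published tens-of-percent range
with the correct orderings (earlier initiation dominates, males above
females, more frequent fisetin dosing never worse).

## Sensitivity analysis

`oa_sensitivity()` perturbs the 13 kinetic constants uniformly within
±50% of baseline by Latin Hypercube Sampling (one draw per equiprobable
stratum; `lhs::randomLHS` under a recorded seed, 200 samples by default)
and computes partial rank correlation coefficients of the
calcified-cartilage average after one untreated male year, with p-values
from the t-statistic on $n - p - 2$ degrees of freedom. PRCC is computed
from residual correlations after rank-regression on all other parameters
and is verified in the tests against the precision-matrix form of partial
correlation, and for invariance under monotone input transformations.

Because the one-year output sits on the initial hypertrophy transient
(see above), the strongest signals at the defaults are the chondrocyte
source ($A$, positive) and the death rates $\mu_C$, $\mu_{C_h}$
(negative); the hypertrophy transition $\lambda_{CC_h}$ is positive but
weak at this horizon, and the collagen secretion rate $\lambda_{CL_2}$
can flip sign. On the signed (unclipped) calcification bookkeeping the
pattern shifts toward $\lambda_{CC_h}$ strongly positive and $\mu_{C_h}$
most negative. Neither readout reproduces the full published ranking;
the discrepancy is inherent to the published initial state and is left
visible in the acceptance suite rather than smoothed over.

## What the simulator does and does not capture

The model is one-dimensional, purely diffusive–kinetic cartilage: no
mechanical loading, no inflammation or immune compartments, no
subchondral-bone or MSC dynamics, and severity is proxied entirely by
calcified-cartilage density. Drug action is a single-compartment
exponential-impulse pharmacokinetic; there are no dose–response curves
beyond the printed constants, several of which ($\lambda_{C_hC_c}$,
$\alpha_D$, $\alpha_{U_2}$, $\mu_{C_sD}$, $\mu_{DC_s}$) have no
experimental anchor. Passing tests demonstrate internal consistency of
the implementation and reproduction of the published model's structure,
not clinical validity.
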