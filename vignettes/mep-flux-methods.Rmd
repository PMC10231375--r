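---
title: "Methods: MEP pathway flux, pool sizes and HDR kinetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: MEP pathway flux, pool sizes and HDR kinetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mepflux)
```

## The labeling model

When a leaf's CO₂ supply is switched to ¹³CO₂ at $t = 0$, newly fixed
carbon enters the plastidial MEP pathway and the fraction of isoprene
molecules carrying label rises toward a plateau $m < 1$ (some carbon in
isoprene derives from stores that never label within a run). We model the
pathway as four well-mixed pools in series — DXP ($A$), MEcDP ($B$),
HMBDP ($C$) and the combined IDP+DMADP pool ($D$), in nmol gFW⁻¹ — each
flushed by the same steady-state flux $J$ (nmol gFW⁻¹ min⁻¹). The labeled
fraction $\ell_i$ of pool $i$ obeys the linear chain

$$\frac{d\ell_1}{dt} = \frac{J}{A}(1-\ell_1), \qquad
  \frac{d\ell_{i}}{dt} = \frac{J}{P_i}(\ell_{i-1}-\ell_{i}),$$

and isoprene reports the last pool: $f(t) = m\,\ell_4(t)$. For distinct
pools the solution is

$$f(t) = m\Big(1 - \sum_{i} c_i e^{-(J/P_i)t}\Big), \qquad
  c_i = \frac{P_i^3}{\prod_{j\neq i}(P_i - P_j)},$$

where $\sum_i c_i = 1$ enforces $f(0) = 0$. Equivalently, $f(t)/m$ is the
CDF of a hypoexponential lag — the sum of four independent exponential
residence times with means $P_i/J$ — so the mean lag is
$(A+B+C+D)/J$ (`mean_transit_time()`), a fact we use both to initialize
fits and as a quadrature identity in the tests.

**Assumptions.** Steady state (pools and flux constant over the run),
well-mixed pools, irreversible forward flux, and a single plastidial
isoprene source. Isotopologue structure is ignored: "labeled" is binary.

**Numerical choices.** The exponents of the closed form span the rates
$J/P_i$; when two pools agree to better than a relative $10^{-9}$ the
partial fractions cancel catastrophically, so `chain_coefficients()`
refuses (error class `mepflux_degenerate_pools`) and
`fractional_labeling()` silently reroutes to `integrate_chain_ode()` — an
adaptive Cash–Karp RK4(5) integrator at `atol = rtol = 1e-9` that is also
the independent oracle for the closed form. We integrate rather than
ε-perturb the pools because correctness beats speed at this problem size.
Equal pools reduce to an Erlang CDF, which the tests exploit.

## Pool-size estimation

Total (whole-tissue) pools of the four intermediates are measured by MS,
but only their plastidial share participates in the chain. Since isoprene
is assumed purely plastidial, its final labeling fraction is the fully
plastidial reference, and
`plastidial fraction = metabolite final fraction / isoprene final fraction`.
Noise can push this ratio marginally above 1; we clamp to 1 with a warning
rather than error, because a plastidial pool cannot exceed its total and
the excursion is a measurement artifact. No extraction-recovery correction
is applied (none is defined for these data). `build_pool_sizes()` assembles
the fixed $(A,B,C,D)$ ordering and insists on strictly positive pools,
which the flux model requires.

## Flux fitting

`fit_flux()` minimizes $\sum_k (f_k - f(t_k; J, m))^2$ with pools fixed.
Two plateau modes exist because "maximal fractional labeling at the end of
the run" is genuinely ambiguous:

- default: $m$ fixed to the mean of the last `k_last = 3` points
  (`estimate_plateau()`), the end-of-run reading;
- `fit_m = TRUE`: $m$ co-fitted in $(0,1]$ via a logistic transform;
- `m =` value: a known plateau supplied directly.

On a finite grid the end-of-run mean sits slightly below the true
asymptote (about $7\times10^{-4}$ on the 0–20 min default grid), and that
bias propagates into $J$ at the $10^{-3}$ relative level. Exact noiseless
recovery therefore requires the true plateau (fixed or co-fitted); with
noisy data the difference is far below the noise floor. This is why the
`m` override exists.

$J$ is optimized on the log scale, multi-started (5 starts over a
$\pm1$ decade log grid) around $J_0 = (A+B+C+D)/t_{50}$ — the mean-lag
relation evaluated at the first time the data reach $m/2$ — because the
objective flattens at large $J$. Standard errors come from the
Gauss–Newton Jacobian at the optimum; `bootstrap_flux()` adds a
residual-resampling percentile interval, reproducible under a fixed seed.
Least squares is unweighted by default; per-point weights are accepted.
An all-but-flat curve (every fraction < 0.01) errors as "no label
incorporation" instead of returning a meaningless fit.

## HDR kinetics

Progress curves of combined DMADP+IDP product are fit with the Box-Lucas
model $y = a(1 - e^{-bt})$; the initial velocity is the analytic origin
slope $v_0 = ab$. Internally the fit is parameterized as $(v_0, b)$ with
$a = v_0/b$: short assay windows far below the asymptote make $a$ and $b$
individually unidentifiable (an $ab$ ridge), while $v_0$ — the quantity of
interest — stays well determined, and the $(v_0, b)$ form has a smooth
$b \to 0$ (purely linear) limit.

Initial velocities across substrate levels are fit with
$v = V_{max} S/(K_m + S)$ by `fit_mm_nls()` — `stats::nls` followed by an
analytic Levenberg–Marquardt polish, because the relative-offset stopping
rule of `nls` halts about $10^{-6}$ short of the optimum on
(near-)zero-residual data. `fit_lineweaver_burk()` implements the
double-reciprocal regression ($K_m$ = slope/intercept,
$V_{max}$ = 1/intercept) used historically for these assays; it is exactly
equivalent on noiseless data but reciprocal transformation inflates the
leverage of the smallest velocities under noise, so the nonlinear fit is
the default and a negative intercept (non-physical $V_{max}$) is an error.
$k_{cat} = V_{max}/[E]$ requires the user-supplied enzyme molarity — the
package does not guess molecular weights. `efficiency_fold()` compares
$k_{cat}/K_m$ between enzymes; `dmadp_idp_ratio()` keeps the exact float
and prints the field's integer "1:x" style by default.

## Precursor stoichiometry

Chain elongation starts from one DMADP and adds one IDP per C5 unit:
GDP (C10) needs 1 IDP, FDP (C15) 2, GGDP (C20) 3, isoprene none.
Carotenoid and chlorophyll side chains are attributed to their C20
precursor, and C40 tetraterpenes count as two GGDP. `supply_vs_demand()`
is plain limiting-reagent arithmetic per unit of C5 flux: the formation
rate is $\min(\text{supply}_D/\text{demand}_D,
\text{supply}_I/\text{demand}_I)$ and exactly one species is left over
(mass conservation is exact by construction). An optional IDI step
converts a chosen fraction of the leftover species before the balance; it
is off by default because isomerase activity in vivo is known
qualitatively, not quantitatively — the calculator reports arithmetic and
takes no position on in vivo ratios.

## The synthetic world

The generators emulate the statistical structure the analysis assumes,
with defaults fixed once:

- `simulate_labeling()`: closed-form curve plus additive Gaussian noise
  truncated to $[0,1]$, default `noise_sd = 0.02` and a 25-point 0–20 min
  grid with pools $(1,2,3,4)$, $J = 2$, $m = 0.95$ — the recovery-study
  world. PTR-MS fractional labeling is a ratio of ion counts with roughly
  symmetric error at moderate fractions, hence additive noise.
- `simulate_assay()`: true Michaelis–Menten substrate depletion
  ($dP/dt = V_{max}(S_0-P)/(K_m+S_0-P)$) integrated by fixed Euler steps
  of (min sampling interval)/100, proportional (constant-CV, default 5%)
  noise as typical for LC-MS/MS, and a fixed DMADP:IDP split 1:r. The
  depletion curve is Box-Lucas-shaped only for $S_0 \ll K_m$, which makes
  the tested property — $v_0$ bias shrinking monotonically as the sampling
  window shrinks — meaningful rather than circular.
- `simulate_pool_table()`: exact inverse of the pool estimator, so the
  noiseless round trip is exact by construction and tests the plumbing,
  not the science.

What a green test does **not** establish: real PTR-MS drift and
autocorrelation, partial isotopologue labeling, day-to-day biological
variation between leaves, enzyme inactivation during assays (the
iron-sulfur cluster of HDR decays in air), or the absolute flux scale of
any particular experiment. The recovery studies certify the estimators on
data that satisfy the model's own assumptions — nothing more.

## Known limitations

- Chains of length other than four are out of scope (the Erlang case
  appears only as an oracle).
- Pool sizes and flux are not fit jointly; pools enter as fixed knowns
  with no propagated uncertainty.
- The demand calculator ignores enzyme-level competition, thermodynamics
  and compartmentation beyond the plastid/cytosol split implied by the
  isoprene reference.
- Reported standard errors are asymptotic; for small noisy time courses
  prefer the bootstrap interval.
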