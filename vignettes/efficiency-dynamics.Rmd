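---
title: "Distribution dynamics of regional healthcare-system efficiency"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Distribution dynamics of regional healthcare-system efficiency}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(effdyn)
```

## The question and the method

Regional healthcare systems convert inputs — practicing physicians,
registered nurses, hospital beds — into services: outpatient visits and
inpatient admissions. Whether the *relative* efficiency of that conversion
converges across regions over time, or instead settles into persistent
tiers ("efficiency clubs"), is a distribution-dynamics question. This
package implements the full chain of analysis:

1. **Efficiency measurement.** Input-oriented radial DEA. For evaluated
   unit $o$ with inputs $x_o$ and outputs $y_o$,
   $$\theta^\ast = \min\{\theta : X'\lambda \le \theta x_o,\;
   Y'\lambda \ge y_o,\; \lambda \ge 0,\; (\mathbf{1}'\lambda = 1)\},$$
   with the convexity constraint $\mathbf 1'\lambda=1$ under variable
   returns to scale (BCC; the score is pure technical efficiency, PTE) and
   without it under constant returns (CCR; overall technical efficiency,
   TE). Scale efficiency is the ratio $SE = TE/PTE$. Scores are radial:
   the largest equiproportionate input contraction feasible at the unit's
   outputs. We report radial scores only; residual slacks are reflected in
   the projection itself and no second-stage slack maximization is done,
   which keeps scores comparable across the downstream state analysis.

2. **State discretization.** PTE is pooled over all region-years and cut
   at its 33rd and 67th percentiles into low / medium / high relative
   states (a quartile variant serves as robustness). Pooled thresholds
   make states comparable across years: a state change is a move in the
   overall distribution, not relative to an annually shifting yardstick.

3. **Markov dynamics.** One-step transitions between consecutive years are
   pooled across regions into a $K\times K$ count matrix; row-normalizing
   gives the MLE $\hat P$. The stationary distribution solves
   $\pi P = \pi$, $\sum_i \pi_i = 1$; high diagonal persistence plus a
   multi-modal $\pi$ is the signature of club formation rather than
   convergence.

4. **Spatial conditioning.** Each region-year's neighbourhood context is
   the tercile class of the unweighted mean state of its contiguity
   neighbours in the same year; transition matrices are re-estimated within
   each origin-year context. Differences across contexts — e.g. lower
   low-state self-retention in high-efficiency neighbourhoods — indicate
   spatially conditional dynamics.

5. **Transition equations.** Linear probability models relate upward /
   downward state moves to origin-year resource-structure covariates
   (doctor–nurse ratio, staff per 10k population, beds per staff, log GDP
   per capita) with year and region-group fixed effects and region-clustered
   CR1 standard errors. These are descriptive associations, not causal
   estimates.

## Numerical choices

**The LP core.** The envelopment programs are solved by a package-internal
dense two-phase primal simplex (`R/simplex.R`) using Dantzig pivoting with
a switch to Bland's rule, which rules out cycling. The tableaux are tiny
(rows = inputs + outputs + 1), so the dense method is both fast (a 620-unit
panel scores in under a second) and transparent. Columns are normalized to
unit maxima before solving — radial scores are invariant to positive column
scaling, and normalization conditions the tableau. Scores are clipped into
$(0,1]$ at tolerance $10^{-9}$; a CCR score exceeding its BCC score by more
than $10^{-7}$ aborts with a diagnostic, since the CRS frontier must
envelop the VRS frontier. When the optimal intensity vector $\lambda$ is
degenerate, any optimal vertex is reported; $\theta$ itself is unique.
The test suite cross-checks the solver against an independent
bisection-on-$\theta$ feasibility oracle built on a separate LP
implementation.

**Frontier scope.** Annual scores are computed against the cross-section of
the same year (`per_year`, the default): each year's frontier is the
contemporaneous best practice, which matches the idea of tracking a
region's *relative* position year by year. A pooled frontier across all
region-years is available as a sensitivity flag.

**Quantiles and ties.** Thresholds use linear-interpolation empirical
quantiles (type 7). Classification intervals are lower-closed at the top:
state 1 iff $s < t_1$, state 2 iff $t_1 \le s < t_2$, state $K$ iff
$s \ge t_{K-1}$. The rule is deterministic and monotone and sends frontier
ties ($s = 1$, common in DEA panels — well over a third of observations can
sit at 1) to the top state. Consequently, when more than a third of pooled
scores equal 1, the upper threshold itself is 1 and the top state contains
exactly the frontier; and in the fully degenerate case of identical scores,
all mass lands in the *top* state, the only classification consistent with
the boundary rule.

**Stationary solve.** $\pi$ comes from a direct linear solve on
$(P^\top - I)$ augmented with the normalization row, after checking
irreducibility via strong connectivity of the positive-entry digraph.
Reducible chains (e.g. an identity matrix from frozen sequences, or subsets
whose top state is never revisited) get an absorbing-structure report — the
closed communicating classes — instead of a spurious $\pi$. Rows of the
transition matrix with zero observed origins are reported as undefined,
never imputed, and block the stationary solve with a clear diagnostic.
Power iteration is used in tests as an independent cross-check of the
linear solve.

**Transition counting.** Only consecutive-year pairs within a region count;
gaps break the chain rather than bridging it. Counts over a partition of
regions add up exactly to the pooled counts, and per-context counts add up
exactly to the pooled counts over regions with defined contexts — both are
asserted as exact integer identities in the tests.

**Spatial details.** Neighbour means are unweighted; a region is never part
of its own neighbourhood; islands (regions without neighbours) are excluded
from the conditional analysis with a logged count rather than silently
zero-filled. The context of the *origin* year conditions each transition.
The same-region robustness scheme replaces geographic neighbours with
fellow members of a region group (excluding self) before lagging.

**Cluster-robust covariance.** CR1 scaling
$\frac{G}{G-1}\,\frac{N-1}{N-k}$ on the clustered sandwich, implemented
directly; the test suite verifies exact agreement with
`sandwich::vcovCL(type = "HC1", cadjust = TRUE)` and the collapse to
heteroskedasticity-robust HC1 when every cluster is a singleton. The
upward model drops origins already in the top state, the downward model
drops bottom-state origins: the moves are otherwise logically impossible,
and the two models therefore have different sample sizes. Region-group
fixed effects are the default (province dummies with ~30 clusters would
absorb most covariate variation; they remain available via
`fe_region = "province"`).

## The synthetic generator: what it emulates and what it does not

No region-level production dataset ships with the package, so
`generate_panel()` provides the study conditions synthetically, with every
layer's ground truth exposed:

- **Panel shape.** 31 regions, 20 years — matching the provincial panel
  scale on which this style of analysis is run (589 one-step transitions).
- **Latent dynamics.** A 3-state Markov chain per region, initialized at
  the stationary distribution of the configured kernel. The default kernel
  is the bundled published provincial matrix (high diagonal persistence
  0.72–0.89, zero low-to-high leap), so simulated dynamics have the same
  persistence signature the method is meant to detect.
- **Efficiency levels.** States map to radial efficiency
  $(0.78, 0.90, 1.00)$. The top state sits exactly on the frontier — a DEA
  frontier only exists if frontier units exist — and the pooled mean lands
  near the published mean PTE of 0.884.
- **Production.** Outputs are log-normal with region-level scale
  heterogeneity. The frontier input requirement is
  $x_k(y) = a_k + \sum_r b_{kr}(y_r/\bar y_r)^{1.2}$: increasing and
  *convex* in outputs, so the implied technology set is convex and
  noise-free frontier units provably score $\theta_{BCC} = 1$ (the
  production correspondence is concave; its input requirement is convex —
  a concave input-requirement function would make the technology set
  non-convex and DEA would cut inside its own frontier). The intercepts
  $a_k > 0$ make the technology non-CRS, so BCC and CCR scores separate.
  Inputs are the frontier requirement divided by true efficiency (radial
  inefficiency on the input side, matching the input orientation) times
  log-normal noise (default sd 0.02).
- **Spatial coupling.** With probability `spatial_coupling` a region copies
  a uniformly chosen neighbour's previous state instead of drawing from its
  own kernel row. This is the simplest mechanism that produces conditional
  transition matrices varying with neighbourhood context; it is a stand-in,
  not a claim about the real diffusion mechanism.
- **Covariate effects.** When configured, exogenous covariates (region
  random intercepts + mild trends + noise, on empirically plausible scales)
  are drawn first and the kernel's adjacent-cell transition mass is tilted
  by the demeaned covariates, so a linear probability model on the upward
  indicator has the configured coefficient as its estimand. Shifts are
  clipped to keep rows stochastic, which mildly attenuates large effects.

What the generator does **not** emulate: real provincial geography or
magnitudes beyond orders of magnitude, serially correlated measurement
error, technology change over time, or feedback from realized efficiency
to inputs. Passing tests on synthetic data therefore show the *estimators*
are correct under a known DGP, not that any particular real-world finding
is right.

One behaviour of the full pipeline on synthetic data is worth flagging:
states classified from *DEA scores* are noisier than the latent states
(finite cross-sections inflate some scores; noise moves units near
thresholds), so the estimated state persistence from scored panels is lower
than the latent kernel's. Ground-truth recovery checks therefore target the
latent states, while the DEA stage is validated separately (oracle
equivalence, frontier consistency, invariance properties).

## Problem sizes used in validation

The test suite validates at the study's own scale where that matters
(31×20 panels for kernel recovery, 100 seeds; 200 random instances for
oracle equivalence; 500 for invariance properties; 50 seeds for
covariate-effect recovery; 40 each for the spatial null and signal) and at
long-chain scales (up to $10^5$ steps) for asymptotic checks. One caveat
found while calibrating: at 589 transitions the stationary vector of an
estimated kernel has per-component sampling error (RMS 0.04–0.065) larger
than a ±0.05 recovery band, so per-seed stationary recovery at that band
is not achievable by any correct estimator at this panel size — the test
documenting this is expected to flag it.

## Worked example

```{r example}
cfg <- synth_config(n_regions = 12, n_years = 8, seed = 42)
g <- generate_panel(cfg)
eff <- dea_score_panel(g$panel)
summary(eff$pte)

st <- classify_states(eff, efficiency_thresholds(eff$pte))
est <- estimate_transitions(st)
est

stationary_distribution(est)
```

```{r reference}
# the bundled published 3-state dynamics verify against their printed
# stationary shares
verify_reference_dynamics()[c("pi", "max_abs_diff", "mobility_index", "pass")]
```

## Known limitations

- Radial DEA only: no slack-based (SBM), output-oriented, directional, or
  Malmquist variants; no super-efficiency or bootstrap confidence
  intervals.
- Discrete-state dynamics only: no continuous stochastic-kernel
  distribution dynamics, no higher-order chains, no confidence intervals
  on $\pi$.
- The transition equations are linear probability models with two-way
  fixed effects — descriptive by design; no instruments, no dynamic-panel
  estimators.
- Quantile and tie conventions matter when a large share of scores sits at
  the frontier; both are fixed and documented above so results are exactly
  reproducible, but other software making other choices will classify
  boundary observations differently.
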