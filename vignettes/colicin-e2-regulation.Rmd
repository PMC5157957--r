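---
title: "Modeling hierarchical post-transcriptional regulation of colicin E2"
author: "ColE2sim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling hierarchical post-transcriptional regulation of colicin E2}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ColE2sim)
```

## The system and the reduced model

Colicin E2 is a plasmid-encoded DNase toxin of *Escherichia coli* that is
released by cell lysis under DNA-damage (SOS) stress. The operon produces
two transcripts from one SOS promoter: a short mRNA encoding the toxin and
its immunity protein, and a long mRNA that additionally carries the lysis
gene *cel*. Whether a cell lyses is decided post-transcriptionally: the
carbon storage regulator CsrA binds the long mRNA's ribosome binding site
(blocking translation and promoting decay), and CsrA itself is sequestered
by the small RNAs CsrB/CsrC — the "regulator's regulator".

`ColE2sim` models this hierarchy as three free species — long mRNA $M$,
CsrA dimers $A$, and an effective one-site sRNA $S$ — with mass-action
rate equations

$$\dot M = \alpha_M - \delta_M M - k_M M A,$$
$$\dot A = \alpha_A - \delta_A A - k_M p_M M A - k_S p_S A S,$$
$$\dot S = N\alpha_S - \delta_S S - k_S A S,$$

where $k_M, k_S$ are effective coupled-degradation rates (complex
formation, dissociation and decay collapsed into a single bimolecular
loss) and $1 - p_M$, $1 - p_S$ are the probabilities that the CsrA dimer
survives the encounter. Bound molecules are functionally inert and leave
the model.

Two model reductions stand behind these equations, both exposed as
operations:

* **Promoter elimination** (`effectiveTranscriptionRate()`): SOS-promoter
  binding kinetics are fast compared with mRNA turnover, so transcription
  is replaced by $\alpha_M = n_{sos} \cdot r \cdot
  k_{off}/(k_{off} + k_{on} \mathrm{Le})$ over the $n_{sos} = 20$ plasmid
  copies (adiabatic elimination of the promoter state).
* **Multi-site sRNA reduction** (`effectiveSrnaReduction()`): an sRNA
  molecule carries $N$ CsrA binding sites (default $N = 22$). Tracking
  every occupancy state adds $N+1$ species; because complex
  binding/unbinding is much faster than production and degradation, the
  occupancy equilibrates and the system behaves like a one-site species
  whose unit is a *free binding site*, produced at $N\alpha_S$ and lost
  either freely ($\delta_S$) or jointly with a CsrA dimer at
  $k_S = \delta_S\, v_+ / v_-$. The `detailed` simulation variant keeps
  all $C_0 \dots C_N$ occupancy species, and `reducedVsDetailed()`
  verifies the convergence as complex rates are accelerated.

### What the printed sRNA production rate means

The production term of the sRNA equation is $N\alpha_S$. Quoted working
points (CsrA production 58.52, sRNA production 57.5, both molecules/min)
are only consistent with the threshold law below, and with an uninduced
cell sitting *just below* threshold, if they refer to the **effective**
production $N\alpha_S$. The package therefore stores $\alpha_S$ and $N$
separately, always forms the product explicitly
(`srnaProduction()`), and ships defaults with
$N \alpha_S = 22 \times 57.5/22 = 57.5$. Run manifests record this
convention.

## Default parameters

All rates are per cell per minute (cell volume 0.65 µm³ is bookkeeping
only). The printed working point fixes $\alpha_A = 58.52$,
$N\alpha_S = 57.5$, $n_{sos} = 20$, the signal schedule
$c_p: 0 \to 6 \to 0$ at 200/500 min, and the 8-molecule first-peak rule.
The remaining rates are package defaults chosen once, on these grounds:

| parameter | default | rationale |
|---|---|---|
| $\delta_M$ | 0.2 /min | ~5 min mRNA lifetime, typical for *E. coli* transcripts |
| $\delta_S$ | 0.25 /min | sRNAs turn over a few times faster than stable proteins; minutes-scale lifetime |
| $\delta_A$ | 0.0014 /min | CsrA is highly stable (dilution-limited). This rate sets the pre-SOS free CsrA pool ($A^* \approx (\alpha_A - N\alpha_S)/\delta_A \approx 600$ dimers) and therefore the titration time after induction; it is anchored so the deterministic rate equations delay long-mRNA expression by ≈40 min |
| $k_M = k_S$ | 1.0 /(molecule·min) | near the diffusion-limited association scale for strong RNA–protein binders; makes repression essentially stoichiometric, so free CsrA and free mRNA exclude one another outside a narrow threshold band (the displayed phase behavior) |
| $p_M = p_S$ | 1 | coupled degradation removes the dimer with its partner; survival probabilities can be set freely in the reduced variant |
| LexA/RecA rates | see `sosParameters()` | chosen so the uninduced cell has ~400 LexA dimers, ~99% bound promoters, a few short mRNAs, and a basal long-mRNA rate far below the threshold margin; under $c_p = 6$ LexA collapses within minutes and the effective long-mRNA rate rises to ≈18 /min |

These constants are a coherent working set reproducing the documented
regime, not literature measurements; sensitivity to them is exactly what
`stressSweep()` and the phase/heatmap functions are for.

## Stationary states and the expression threshold

Setting the rate equations to zero and eliminating $M$ and $S$ leaves a
cubic $c_3 A^3 + c_2 A^2 + c_1 A + c_0 = 0$ in the free CsrA abundance.
`steadyStateExact()` solves it with a numerical polynomial root finder,
back-substitutes, and keeps the unique root with all abundances
non-negative (if several qualify, the one reached by forward integration
from the empty state; stationary residuals are verified below
$10^{-9}$ of the largest production rate).

`steadyStateApprox()` implements the two-regime simplification: for small
$A$ the cubic term is negligible, for large $A$ the constant term is.
Each case is a quadratic; equating the omitted terms
($|c_3| A^3 = c_0$) gives the transition criterion, and the branch whose
omitted term is smaller at its own root is selected and recorded. Across
the reference cuts the approximation stays within a fraction of a percent
of the exact root except inside a ±2 molecules/min band around the
threshold.

The **threshold** follows from the high-abundance branch: abundant free
CsrA requires its production to outrun the total production of its
titrating targets. The locus implemented in `thresholdCondition()` is

$$p_M\,\alpha_M + p_S\,N\alpha_S \;=\;
  \alpha_A - \delta_A\!\left(\tfrac{\delta_M}{k_M} +
  \tfrac{\delta_S}{k_S}\right),$$

which for slow CsrA decay and $p = 1$ reduces to
$\alpha_M + N\alpha_S = \alpha_A$ — the threshold sits exactly where CsrA
production balances combined target production. The $\delta_A$ correction
is kept because the sharpness argument relies on *slow*, not zero, CsrA
degradation (with the defaults it shifts the locus by < 0.01). Abundances
below $10^{-3}$ molecules are displayed as zero in `phaseSurface()` maps;
raw values remain accessible.

## Fluctuations: linear noise approximation

`lnaMoments()` expands the chemical master equation around the
macroscopic fixed point (van Kampen system-size expansion). Keeping the
dominant (first-order) terms for second moments, fluctuations are
Gaussian with stationary covariance $C$ solving
$J C + C J^\top + D = 0$, with $J$ the Jacobian and
$D = \sum_j a_j \nu_j \nu_j^\top$ the diffusion matrix assembled from the
same reaction list the simulator uses (including the split
coupled-degradation channels, whose joint removals contribute *positive*
off-diagonal diffusion). The 3×3 Lyapunov equation is solved directly via
its Kronecker vectorization. The long-mRNA Fano factor is
$\mathrm{Var}(M)/\langle M\rangle$; in the unregulated limit
$k_M = k_S = 0$ it equals 1 exactly (independent birth–death processes),
which is the package's primary correctness anchor.

Two properties of the heatmap (`fanoHeatmap()`) mirror the titration
physics: fluctuations are maximal in a band just above the threshold
(small copy numbers, anti-correlated species with slow effective
relaxation), and increasing sRNA production dampens them pointwise.
Where $\langle M\rangle < 5$ molecules the expansion is known to
overestimate fluctuations; such cells are flagged `LNA-unreliable`, and
only first-order moments are implemented — higher-order corrections are
deliberately out of scope (`order > 1` errors).

`empiricalFano()` is the estimator used for cross-checks: pooled
time-and-ensemble variance/mean with a bootstrap standard error over
realizations and a split-half stationarity flag.

## Exact stochastic simulation

`simulateSSA()` is a direct-method Gillespie implementation (Rcpp): two
uniforms per event, propensities recomputed from sparse reactant lists,
falling-factorial combinatorics for molecule counts. Design points:

* **Survival probabilities** are reaction splits, not post-event coin
  flips: the $M{+}A$ encounter fires as two channels with propensities
  $k_M p_M M A$ (dimer removed) and $k_M (1-p_M) M A$ (dimer survives),
  so the propensity sum remains the only source of randomness accounting.
* **Time-dependent $c_p(t)$** is piecewise constant; a waiting time is
  never allowed to cross a schedule breakpoint (the exponential clock is
  memoryless, so capping and redrawing preserves exactness).
* **Output** is sampled onto a uniform grid (default 1 min) by
  last-value-carried-forward for ensemble statistics; event streams are
  reproducible byte-for-byte from (system, initial state, seed).
* **Seeding**: `childSeed()` derives per-realization seeds from a base
  seed through a counter-based congruential map, so any single
  realization of an ensemble can be re-run in isolation.

## The SOS response module

`fullNetworkSystem()` couples the LexA–RecA layer to the titration motif:
auto-repressed *lexA* and *recA* (mRNA and protein species), LexA-dimer
binding/unbinding on the two chromosomal promoters and on the 20 SOS
promoters (modeled as free/bound *counts* with combinatorial propensities
rather than distinguishable sites — identical kinetics, much smaller
state space), transcription of short and long mRNA proportional to open
SOS promoters, RecA-mediated LexA auto-cleavage with mass-action
propensity $c_p(t)\, R\, \mathrm{Le}$ acting on free dimers
(promoter-bound LexA is assumed protected), the reduced
post-transcriptional reactions on the long mRNA, and lysis-protein
translation from free long mRNA (tracked for sensitivity analysis; the
first long-mRNA burst is the lysis proxy).

Runs start from `sosInitialState()` — integer abundances near the
uninduced deterministic fixed point — and the 200 min before signal onset
serve as stochastic burn-in. `detectFirstPeak()` implements the
first-peak rule: onset when $M$ first exceeds 8 molecules, peak at the
maximum of the contiguous excursion above the threshold, censored if
never exceeded. `lysisTimeDistribution()`, `peakTimeHistogram()` (10-min
left-closed bins anchored at signal onset, bootstrap CI on the mode) and
`survivalFunction()` (fraction of cells with no peak yet; censored cells
survive throughout) summarize ensembles. `stressSweep()` varies $c_p$
over 1–90 to emulate stress levels; `poissonPlasmidVariant()` redraws the
plasmid number per cell from Poisson(20).

## What the default conditions emulate — and what they do not

The default configuration reproduces, from a single parameter set: the
repressed uninduced state with complete filtering of promoter-activity
bursts (no long-mRNA excursion above 8 molecules in 500 × 200 min of
uninduced simulation); a deterministic expression delay of ≈40 min after
induction; a stochastic ensemble mean that rises later and saturates
below the deterministic curve; strong anti-correlation between free long
mRNA and free CsrA; a broad first-peak distribution (tens of minutes
spread, mode within the first ~1.5 h after induction); survival decaying
to ≈0 by the end of a 300-min signal; and earlier mean lysis under
stronger signals.

Passing these checks does **not** establish quantitative agreement with
any real strain: the constructed rate set is one coherent point in a
large admissible space. Known deviations worth naming:

* In this parameterization the post-induction titration margin is small
  (a few tens of molecules/min), so the lysis-time spread is
  margin-dominated. A consequence is a measurable sensitivity to
  plasmid-copy noise: Poisson(20) plasmid numbers widen the lysis-time
  distribution beyond statistical indistinguishability from the
  fixed-copy protocol (the law-of-total-variance direction of the effect
  is, of course, preserved). An insensitive-yet-broad regime requires
  slow, bursty LexA–RecA promoter kinetics with a large margin, which
  this rate set does not attempt to represent.
* The stochastic ensemble's mean onset lags the deterministic rise here,
  whereas burst-dominated parameterizations can show the opposite order;
  both are consistent with the qualitative claims the package asserts
  (a delay exists; the stochastic mean saturates lower).
* No cell growth, division, or extrinsic noise; plasmid number is fixed
  within a cell's lifetime; colicin itself and the short mRNA's products
  are not modeled beyond the short transcript as a promoter-activity
  proxy.

## Numerical choices

* Deterministic integration: `deSolve::lsoda`, rtol $10^{-8}$, atol
  $10^{-10}$ (absolute tolerance far below one molecule because
  near-threshold abundances are $O(1)$); schedules integrated segment by
  segment so discontinuities never cross a solver step.
* Cubic roots: `polyroot` with degenerate-degree trimming (the limits
  $k = 0$ or $\delta_A = 0$ lower the polynomial degree), a damped-Newton
  polish, and a residual check.
* Tie-breaks: first-peak ties resolve to the earliest time; branch ties
  in the quadratic approximation resolve to the smaller omitted term.
* Degenerate inputs: zero-plasmid cells are censored without simulation;
  all-censored ensembles warn and flag; empty excursions are censored.

## Problem sizes used by the test suite

The reference ensemble in the acceptance-style tests uses 500
realizations × 700 min (matching the published protocol); the stress
sweep uses 100 realizations per $c_p$ value over 600 min and the
Poisson-plasmid comparison 150 realizations; steady-state and noise
cross-checks use single long runs (≥ 4000 min) or 30–40-run ensembles.
These sizes were chosen so Monte-Carlo error is comfortably below each
assertion's tolerance.
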