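---
title: "Inferring substrate inhibition networks from batch growth curves"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring substrate inhibition networks from batch growth curves}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(diauxnet)
```

## The model and its assumptions

`diauxnet` describes a well-mixed batch culture of a single heterotrophic
population growing on $N$ substitutable substrates. The state is
$(S_1,\dots,S_N, E, V)$: substrate concentrations (mM), a total energy
reserve $E$, and structural biomass $V$ (g CDW/L). Assimilated substrate
fills the reserve with fixed energy yields $y_{E,i}$; the reserve is
mobilized at rate $r_E$ into growth (yield $y_V$) and maintenance ($m$ per
unit biomass per hour):

$$\dot S_i = -f_i(S)\,V,\quad
  \dot E = \textstyle\sum_i y_{E,i} f_i(S)\,V - r_E E,\quad
  \dot V = y_V (r_E E - m V).$$

Uptake is Monod-type with inhibition entering the half-saturation
denominator,

$$f_i(S) = \frac{\mu_i S_i}{K_i + S_i + \sum_{j\neq i} a_{i,j} S_j},$$

so a present inhibitor ($a_{i,j} > 0$) lowers substrate $i$'s uptake in
proportion to its own concentration, and releases it as it is consumed — the
mechanism behind diauxic shifts in this framework. The key structural
assumptions are: inhibition relief is immediate (no acclimation lag); one
common effective functional form covers all mechanisms (enzyme repression,
allosteric inhibition, transporter competition); and the inhibition network
is a directed acyclic graph — no self-inhibition, no mutually inhibitory
pair, no directed cycle, since a cycle would create a regulatory deadlock.
`validate_network()` enforces this, `partial_order()` extracts the induced
substrate priority ranking, and `is_strict_prioritization()` tests whether
every ordered pair is backed by a direct edge (when it is not, the observed
utilization sequence can change with the supplied substrate combination —
`four_substrate_demo_spec()` demonstrates this with a four-substrate chain
whose sequence breaks when the intermediate substrate is withheld).

## Identifiability and substrate clustering

Two substrates whose depletion curves are proportional,
$s_\ell(t_k) \approx \beta s_j(t_k)$, cannot be distinguished as inhibitors:
swapping their coefficients leaves every model trajectory unchanged. Before
any fitting, substrates are therefore grouped by the scale-invariant
dissimilarity

$$d(x, y) = \inf_{\beta>0}
  \frac{2\sum_k (x_k - \beta y_k)^2}
       {\beta^2 \sum_k (y_k-\bar y)^2 + \sum_k (x_k-\bar x)^2},$$

which is symmetric and invariant under rescaling of either curve. The
minimizing $\beta$ is computed in closed form (the stationarity condition is
a quadratic with a single positive root under the preconditions); the test
suite arbitrates this against a dense grid search. Per-replicate
dissimilarities are averaged across replicates, and complete-linkage
(farthest-point) hierarchical clustering is cut at a fixed height. Members of
one cluster are replaced by their summed concentration (preserving total
substrate mass) and share one interaction coefficient per target.

**Cut height.** The default 0.075 is appropriate for replicated experimental
data with a few percent measurement noise, where smaller dissimilarities are
not resolvable. It is a problem-specific choice: the guiding rule is to cut
just above the dissimilarity noise floor, low enough to resolve the
substrates whose individual influence matters. For noise-free synthetic data
the floor is numerical, and the acceptance analyses use 0.01.

## Decoupled uptake fitting

Fitting all $3N+3$ model parameters at once is ill-conditioned, so each
substrate (or cluster) is fitted alone: every other state variable in its
uptake ODE is replaced by an interpolant of its observations, leaving the
scalar equation
$\dot S_i = -f_i(s_1(t),\dots,S_i,\dots,s_N(t))\,v(t)$ with 2 + (number of
candidate inhibitors) free parameters.

**Interpolation.** Observed curves are interpolated with a monotone cubic
(Fritsch–Carlson) scheme, constant beyond the window ends. Piecewise-linear
interpolation was tried first and rejected: its $O(\Delta t^2)$ bias on the
convex biomass ramp and around depletion corners propagated into parameter
estimates (several percent to tens of percent on $K$ at realistic sampling
densities). The monotone cubic preserves the shape of monotone depletion and
growth curves — no overshoot even on noisy data — and removes most of that
bias.

**Objective.** Per replicate, $F = w_1 F_1 + w_2 F_2$, where $F_1$ is the sum
of squared concentration residuals at the observation times and $F_2$ the sum
of squared differences between the model's specific uptake rate at interval
midpoints, $2\dot S_i(\mathrm{mid}_k)/(v_k + v_{k+1})$, and the observed
finite-difference rates
$2(s_{k+1}-s_k)/((v_k+v_{k+1})\Delta t_k)$, from index $k_0$ on. The weights
$w_1 = 1/\max_k s_i(t_k)$ and $w_2 = 1/\max_{k\ge k_0} |[\Delta s_i]_k|$
balance the two scales; the absolute value in $w_2$ matters because depletion
rates are negative and a signed maximum would sit near zero. $k_0$ defaults
to the first index at which biomass reaches 5% of its maximum: below that,
finite-difference rates divide by tiny, noisy biomass values. Replicates are
fitted jointly with one shared parameter set (the objective sums over
replicates). Integration failures inside the search return a large finite
penalty instead of an error, keeping derivative-free optimization alive in
hostile regions.

**Optimizer.** A Nelder–Mead simplex over $(\log\mu, \log K, a)$ with soft
box penalties (bounds $\mu \in [10^{-4}, 10^2]$, $K \in [10^{-6}, 10^2]$ mM,
$a \in [0, 10^4]$), multi-started from a data-driven guess ($\mu$ from the
largest observed specific rate, since $f_i \le \mu_i$) plus log-uniform
random draws under a fixed seed; all starts get a cheap screening pass and
the winner a full polish. A modified Powell direction-set method would be the
closest classical alternative; no installed library provides one, and the
simplex performs equivalently here at these dimensions (2–4 parameters per
decoupled fit).

**Fit quality** is summarized by the concentration-only coefficient of
determination, pooled over replicates around the pooled mean. Specific-rate
residuals steer the optimizer but are excluded from $R^2$, keeping the
summary comparable across substrates of different kinetics.

## The interaction scan and network assembly

For each target the scan fits the interaction-free baseline, then one model
per candidate inhibitor cluster, each seeded from the baseline optimum so a
richer model never scores worse (nesting). The fit improvement
$\Delta R^2$ ranks candidates; thresholds 0.1 (strong) and 0.025 (weak)
classify the retained edges. Candidate pairs (two simultaneous inhibitors)
are scanned only for targets whose best single candidate already clears the
weak threshold — the incremental protocol.

Near-equal candidates (within a margin, default 0.02) are retained as an
explicitly marked group of alternatives rather than resolved arbitrarily:
one claimed inhibition with several possible sources. This mirrors a genuine
property of the inference problem. Because the coefficient $a$ is free, a
candidate whose curve clears *earlier* than the true inhibitor can often
mimic the observed release by sliding the release point along its own decay
tail ($S$ is released when $a\,S_j(t)$ falls below $\sim K_i + S_i$), and a
later-clearing candidate can partially compensate with a moderate $a$. Even
noise-free data may therefore leave several candidates within the margin;
distinguishing them requires experiments in which the candidates clear at
well-separated times (e.g. pairwise cultures).

Per-target scans are independent by construction, so global constraints can
only be enforced at assembly: `build_network()` validates the primary edge
set as a DAG and fails loudly, listing the conflict, if independent
selections form a cycle or mutual pair. Stability is quantified by
`resample_replicates()`: the scan is rerun on every replicate subset of size
≥ 2 (11 subsets for 4 replicates), warm-started from the full-data optimum,
and the standard deviations of $\Delta R^2$ and of $a$ across subsets are
attached to the edges. `blockade_diagnostic()` checks the mechanistic
signature of a fitted inhibition — target uptake below a rate threshold
(default 0.1/h) for as long as the inhibitor exceeds a concentration
threshold (default 0.05 mM).

## Full model fit

With the network's sparsity fixed, `fit_full()` refits all
$2N + |\mathrm{edges}| + 3 + R$ parameters jointly (uptake $\mu_i, K_i$; one
$a$ per edge; $r_E, y_V, m$; one initial biomass per replicate). Initial
concentrations are pinned to the first observations, the reserve starts empty
($E(0) = 0$: inoculated cells equilibrate their reserve quickly relative to
the growth curve), and energy yields $y_{E,i}$ are supplied, not fitted —
they are known from catabolic stoichiometry far more precisely than a growth
curve could determine them. The objective adds a biomass error
$\sum_k (V(t_k) - \mathrm{cdw}_k)^2 / \max_k \mathrm{cdw}_k$ per replicate to
the summed per-substrate errors. A joint search of this size only converges
from a good start, so the operation requires an initial value, normally the
decoupled optima plus `prefit_growth()` (which fits $r_E, y_V, m, V_0$ to the
CDW curves with substrates pinned to their observed interpolants); the
simplex is restarted once from its own optimum, which reliably escapes the
degenerate simplex shapes that appear at 15+ dimensions.

Two identifiability caveats, visible in the synthetic studies: maintenance
$m$ and, to a lesser degree, $r_E$ sit on a soft ridge when the observation
window ends at substrate depletion (biomass barely decays inside the window,
so $m$ trades freely against the other growth parameters); and the
*pooled* $R^2$ improvement from including an interaction is much smaller than
the per-target decoupled $\Delta R^2$, because the pooled variance of all
substrates dilutes a single target's misfit. Interaction detection therefore
belongs to the decoupled stage; the full fit is a consistency check and a
parameter refinement.

## The synthetic worlds

`generate_experiment()` simulates a stated world and samples it with
measurement noise: multiplicative Gaussian ($x(1+\varepsilon)$,
$\varepsilon \sim N(0,\sigma^2)$) plus a small additive floor
($\mathrm{sd} = 0.01\,\sigma\,x_0$ with $x_0$ the series' initial value),
clamped at zero — the error structure of concentration assays, whose error is
mostly relative. One master seed derives per-replicate child seeds, making
datasets bit-reproducible. The default sampling grid is 25 points, denser
early; the two canonical worlds override it:

- `recovery_demo_spec()` — the consistency regime. Four substrates, four
  replicates, no noise, 60 samples over 72 h, half-saturation constants
  1–2 mM so depletion corners span several samples, clearing times staggered,
  one planted edge ($a = 60$). Here the decoupled estimator recovers $\mu$
  and $K$ to within 1% and $a$ to within 20%, and the pipeline's primary
  edge set equals the planted set. The remaining estimator bias is the
  $O(\Delta t^2)$ discretization of the observed specific rates at depletion
  corners, which is also why sharp-cornered (low-$K$) kinetics cannot be
  recovered to 1% at realistic sampling.
- `surrogate_spec()` — the detection regime. Seed-randomized six-substrate
  worlds anchored to the observable features of real mixed-substrate
  bioreactor experiments: inoculum 0.02 g CDW/L growing to ~0.5 g/L,
  depletion window a few tens of hours with clearing times spread up to
  ~4-fold, high-affinity uptake ($K$ = 0.05–0.5 mM, so depletion ends in
  sharp corners), roughly hourly sampling, 5% multiplicative noise, and one
  planted strong inhibition ($a = 110$) between the two fastest substrates
  with both starting abundant — the catabolite-repression configuration in
  which diauxie is actually observable. An inhibitor that outlasts its
  target, or one that clears before biomass ramps up, plants an edge the data
  cannot express; a slow target's inhibition lag is confounded with its own
  slow kinetics. The acceptance suite requires the planted edge to be the
  top-ranked candidate in ≥ 80% of 20 seeded worlds and classed strong in
  ≥ 60%, with false strong edges in ≤ 10% of 20 interaction-free worlds.

What the noise does, empirically, is degrade *discrimination*: the true
candidate's own $\Delta R^2$ is nearly noise-robust up to ~30% noise, but the
top-hit rate falls steeply as competing candidates' noisy curves become
equally good explanations. The property suite asserts that recall trend on
matched seeds.

What a green synthetic suite does **not** establish: correctness under
acclimation lags (the model assumes immediate inhibition relief), under
non-monotone or replenished substrate regimes, for non-Gaussian or
autocorrelated assay errors, or for biomass phenomena outside the DEB
idealization (cell-shape shifts, biofilm, stationary-phase decay). Real-data
analyses should lean on the replicate-subset spreads and the blockade
diagnostic rather than on single $\Delta R^2$ values.

## Numerical choices

- **Integrator:** adaptive embedded Dormand–Prince 5(4), rtol $10^{-8}$,
  atol $10^{-10}$, in compiled code. Depletion corners are locally stiff;
  the error controller resolves them by step shrinkage, and output-time
  clipping is kept out of the controller so it cannot fake a step-size
  collapse. Concentrations are clamped at zero inside the right-hand side,
  which prevents sign-flip blow-ups just past depletion without event
  detection. Mass balance ($S_i(0) - S_i(T)$ vs. the quadrature of
  $f_i V$) holds to $10^{-6}$ relative, verified in the tests together with
  agreement with an independently coded fixed-step integrator.
- **Units:** hours, mM, g CDW/L; the energy unit is fixed by the $y_E$
  scale.
- **Edge convention:** $a_{i,j}$ means "$j$ inhibits $i$"; edges are always
  rendered inhibitor → inhibited.
- **Tie-breaks and determinism:** clustering uses `hclust`'s deterministic
  merge order; all stochastic stages consume the configuration seed; rerunning
  a pipeline with the same config is bit-identical.
- **Degenerate inputs:** constant series have no defined dissimilarity
  (error); all-zero target series cannot be fitted (error); a single-cluster
  dataset runs baseline-only; biomass that vanishes at both ends of an
  interval yields an undefined observed rate (flagged `NA`, excluded from
  $F_2$).

## Known limitations

Confidence intervals are out of scope (the resampling spread is a stability
diagnostic, not a standard error). The scan's thresholds are descriptive,
not significance tests. Cluster-level inhibition attributes one coefficient
to possibly several distinct mechanisms. The full fit's growth parameters
are weakly identified without post-depletion observations. And the DAG
constraint, while biologically motivated, is enforced — a system with a true
regulatory cycle would be mis-summarized by this framework.
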