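---
title: "Stochastic representation of risky choice: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stochastic representation of risky choice: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(srdt)
```

## The model

`srdt` models a decision between lotteries as the absorption of a single
diffusing particle on a *star* of one-dimensional branches joined at a
junction.  Every outcome–probability pair $(o_k, p_k)$ of every lottery
on offer contributes one branch:

* the branch **length** is $\ell_k = 1/p_k$ — likelier outcomes sit
  closer to the junction;
* the branch **drift** is the outcome's utility $u(o_k)$ — gains attract
  the particle toward the absorbing wall at the branch end, losses repel
  it;
* a diffusion coefficient $D$ sets how much the stochastic exploration
  overrides the drifts.

The particle starts at the junction and is eventually absorbed at the
end of some branch; choosing a lottery means being absorbed on one of
*its* branches.  The splitting probabilities of this process give each
branch the **effective utility**

$$\tilde U_p(u) \;=\; \frac{u}{1 - e^{-2u/(pD)}},$$

a strictly positive weight for any real $u$, with the removable
singularity $\tilde U_p(0) = pD/2$.  A lottery's worth is the sum of its
branch weights, $U(L) = \sum_k \tilde U_{p_k}(u(o_k))$, and choice
follows the Luce ratio rule

$$P(L_j) = \frac{U(L_j)}{\sum_i U(L_i)},$$

which structurally implies independence from irrelevant alternatives and
strong stochastic transitivity.  Probability and utility are *entangled*
in $\tilde U$: the weight is not a product of a probability weight and a
utility, and this non-separability is what produces the package's
headline behaviours (probability weighting, loss-side convexity,
dominance violations).

Two limits anchor the interpretation of $D$: as $D \to \infty$ every
weight tends to $p_k D/2$, so only probabilities matter and complete
lotteries become indistinguishable; as $D \to 0$ a gain branch
contributes its bare utility while losses are exponentially suppressed,
so only values matter.

### Finite deliberation time

Conditioning the decision on being reached before a time budget $T$
replaces each weight by its Laplace-domain absorption flux at
$s = 1/T$:

$$\tilde U_p(u \mid T) = \frac{\lambda\, e^{u/(pD)}}{\sinh(\lambda/p)},
\qquad \lambda = \sqrt{(u/D)^2 + 2/(DT)}.$$

As $T \to \infty$ this recovers $(2/D)\,\tilde U_p(u)$ (the constant
cancels in ratios).  For any finite $T$ the weight of a
vanishing-probability branch goes to zero — the finite budget removes
the singular $p \to 0$ limit of the unconstrained model, in which a
branch of vanishing probability still retains weight $u$.  This is an
*approximation* to the exact conditional probability (the time integral
of the flux is replaced by its Laplace transform at $s = 1/T$); against
the lattice simulator it agrees to within about 0.01–0.015 in
probability in the reversal region of the worked time-pressure example,
and the package's tests allow 0.03.

Timed and untimed weights carry different overall normalizations and
are never mixed inside one choice distribution.

## Parameters and their meaning

| Parameter | Units | Default | Role |
|---|---|---|---|
| `D` | utility | — | value-vs-probability trade-off; large `D` = probability-only chooser |
| `T` | time (sets $\tau$ scale) | `Inf` | deliberation budget; `Inf` is an exact sentinel, not a big number |
| `r` | 1/currency | 0 | CARA coefficient of $u(o) = (1-e^{-ro})/r$; 0 = linear |
| `outcome_scale` | 1/currency | 1 | rescaling applied before $u$; *never* a free parameter |

Only the products of `outcome_scale` with `r` and `D` are identifiable
(rescaling all outcomes by $k$ while rescaling `D` by $k$ leaves
linear-utility choice probabilities unchanged), so the scale is a fixed
modelling choice; the fitting module refuses to free it.

## Numerical choices

* All weights are computed and aggregated in log space
  (`log_effective_utility()`, log-sum-exp), so utilities of magnitude
  $10^6$ and probabilities of $10^{-9}$ never overflow.  The $u = 0$
  singularity switches to a series when $|2u/(pD)| < 10^{-8}$;
  $\log\sinh x$ uses $x - \log 2$ beyond $x = 30$.
* The exponent convention ($\ell = 1/p$, exponent $2u/(pD)$) is the only
  reading of the flattened source equations that simultaneously yields
  the gain-branch $p \to 0$ limit $\tilde U_p \to u$, the timed limit
  $\tilde U_p(\cdot|T) \to 0$, the subjective-probability limit
  $\pi(p) \to p$ as $D \to \infty$, and the closed-form identity between
  `transformed_utility()` (with $D_p = pD/2$) and the effective utility
  of a CARA decision maker.  All five are pinned by unit tests.
* Inflection points of the transformed utility are located by a
  curvature scan plus root bracketing at tolerance $10^{-8}$; the
  weighting-shape classifier counts sign changes of $\pi(p|T) - p$ with
  a dead band of $10^{-9}$ to ignore machine-precision crossings.
* Zero-probability branches are removed at construction (an impossible
  outcome has no branch; this is *not* the same as the $p \to 0$ limit)
  and duplicate outcomes are kept as distinct branches — merging them
  would change the predictions, and editing-phase heuristics are out of
  scope.

## The Monte Carlo oracle

`build_star_geometry()` + `run_star_walk()` realize the star as a
lattice walk: branch $k$ gets $\ell_k/h$ sites at spacing $h$, outward
step probability $q_k = \tfrac12(1 + u_k h/D)$, and time
$\tau = h^2/D$ per step, so lattice variance and drift per unit time
match the continuum process to $O(h)$.  At the junction a branch is
chosen uniformly and an outward step is taken with probability $q_k$
(otherwise the walker stays put for that step).  A renewal argument
gives absorption odds proportional to
$(u_k h/D)\,/\,(1 - e^{-2u_k \ell_k/D}) \propto \tilde U_k$ uniformly
over branches, so the walk is an *independent* realization of the same
splitting problem — it is the package's oracle for every closed form,
including absorption times, and is written in C++ with R's RNG so a
fixed seed is bit-reproducible.

The default spacing takes the larger of what two constraints allow:
$\max_k |u_k| h / D \le 0.1$ (drift bias per step) and at least 20 sites
on the shortest branch.  Oracle-agreement tests run 20 random stars of
2–5 branches with mixed-sign drifts at $2\times 10^4$ walkers each
(3 binomial SE $\approx 0.01$), with drift magnitudes capped at $2D$ so
the lattices stay below a thousand sites; these sizes are the package's
own accuracy/runtime balance and are stated here so they can be scaled
up (`n_walkers = 10^5` reproduces the same agreements with tighter
errors).

## What the experiment pipelines show

* **Fourfold pattern** (`fourfold_curves()`, `fourfold_classify()`):
  risky lottery vs its expected value paid for sure, gains and losses.
  The bundled regime `fourfold_preset()` (CARA $r = 6$ on outcomes
  scaled by $1/100$, $D = 10$, $T = 2000$) reproduces all four cells of
  the classic table.  Two findings fix that choice.  First, the
  gain-side certainty cell holds only under a *finite* budget: at
  $T = \infty$ the risky option's probability approaches $1/2$ from
  above as $p \to 1$ (a perturbative expansion of the weights shows the
  risky sum always exceeds the sure weight to second order), while the
  timed weights penalize the $p = 0.95$ branches relative to the sure
  thing.  Second, the loss-side certainty cell (preferring the risky
  $\{-100, .95;\, 0, .05\}$ to a sure $-95$) requires $r \gtrsim 5$ at
  $D = 10$: the zero branch must dominate the exponentially crushed
  loss branches, which needs strongly magnified loss utilities.  Below
  that threshold the cell fails, so the often-quoted smaller
  coefficients do not reproduce the table here.  In the working regime,
  raising `r` increases gain-side risk aversion *and* loss-side risk
  seeking together.
* **Probability weighting** (`weighting_shape()`): the conditional
  branch weight $\pi(p|T)$ crosses the identity once from above
  (inverse-S) for generous budgets, once from below (S) under extreme
  pressure, and three times (inverse double-S) in between — with
  $u_A = u_B = D = 10$ the double-S window sits near $T \approx 0.3$.
* **Stochastic dominance** (`dominance_suite()`): with linear utility
  the dominated lottery of the Birnbaum–Navarrete pair is chosen with
  probability $198/320 = 0.61875$ in the small-$D$ limit (the
  branch-utility sums $96+90+12$ vs $96+14+12$), a violation that
  persists, shrinking toward $1/2$, at every finite $D$; the two
  "evident" dominance tasks are never violated at any tested $D$.
* **Time pressure** (`time_pressure_curve()`): for the
  $\{180,.5;20,.5\}$ vs $\{180,.5;30,.25;15,.25\}$ pair at $D = 10$ the
  unconstrained model prefers the riskier, higher-mean lottery
  ($P = 0.4706$); shrinking $T$ reverses the preference, crossing $1/2$
  near $T^\* \approx 0.08$ in model time units.
* **Response times** (`response_time_report()`): across random pairs,
  options chosen more often are chosen *faster* (negative rank
  correlation of closed-form probability with simulated conditional
  mean absorption time).  Two candidate closed-form identities relating
  the conditional mean time to the choice probability (product and
  quotient readings) were measured against simulation; neither holds
  quantitatively, so the package asserts only the inverse monotone
  relation and reports both readings' errors.

### A negative result, kept honest

For the equal-mean pair $\{0,.75;\,2,.25\}$ vs $\{0,.5;\,1,.5\}$ with
CARA $r = 1$, the safer lottery is *not* preferred at any finite $D$:
its probability rises monotonically with $D$ (0.430 at $D = 1$, 0.4994
at $D = 100$) but approaches the large-$D$ indifference boundary
strictly from below, because the spread's single larger payoff earns a
branch weight the two smaller payoffs cannot match.  The independent
lattice oracle confirms the closed form ($0.433 \pm 0.003$ at $D = 1$).
`strong_risk_aversion_check()` reports these probabilities as computed;
one acceptance-suite assertion of the opposite inequality is left
failing by design rather than silently weakened.

## The synthetic-data generator

`generate_random_lotteries()` draws choice sets with outcomes uniform
on a user interval and branch probabilities uniform on the simplex
(normalized exponentials), reproducibly by seed.  It emulates the
*structure* of lottery-choice designs — small finite menus of mixed-sign
outcome–probability pairs — and is the input for the property tests and
for parameter recovery (`simulate_choices()` then `fit_srdt()`).  It
does not emulate features of real experiments such as correlated menu
construction, repeated subjects, attention lapses, or response-time
noise; passing tests therefore show internal consistency and
recoverability of the model on clean data, not that the model fits
human data.

Recovery studies in the test suite use 30–40 binary-or-ternary sets at
120–150 trials each with free $(r, D)$, truth $r = 1$, $D = 10$, and
8-fold (tests: 4-fold) multi-start `L-BFGS-B` in log space from a
seeded Latin hypercube; estimates land within 25% of truth in seconds.
`T` is fit only when the design varies time pressure — from static
choices alone it is weakly identified.

## Known limitations

* Luce structure: the model cannot produce similarity, attraction or
  compromise (IIA-violating) effects, and a choice between two sure
  outcomes is excluded from valid choice sets.
* The finite-$T$ probabilities are Laplace approximations, not exact
  conditionals; exactness claims are always tested against the
  simulator with the tolerance stated above.
* The junction rule of the lattice oracle is one consistent $O(h)$
  realization of the continuum matching condition, not the only one;
  only the continuum limit is pinned.
* The mean-preserving-spread inequality discussed above does not hold
  in this parameterization; treat strong risk aversion as an open
  empirical question for this model family rather than a prediction.
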