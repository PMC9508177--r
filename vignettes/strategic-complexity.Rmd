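---
title: "Strategic complexity in repeated games against automata: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Strategic complexity in repeated games against automata: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stratcomplex)
```

## The decision problem

A player repeatedly faces one of two stage games — a Prisoner's Dilemma (PD)
or a Battle of the Sexes (BoS) — against one of three pre-programmed opponent
strategies implemented as finite automata:

* **AD** (Always Defect): always plays the aggressive action;
* **GT** (Grim Trigger): cooperates until provoked, then retaliates forever;
* **TfT** (Tit-for-Tat): same provocation triggers, but retaliation lasts one
  round.

Both players choose between two abstract actions, `C` (cooperative: Cooperate
in PD, one's own Worst option in BoS) and `A` (aggressive: Defect in PD, one's
own Best option in BoS). In BoS the players coordinate exactly when their
abstract actions differ. Payoffs are in ECU: PD pays 48/48 for mutual
cooperation, 25/25 for mutual defection, 50 against 12 for unilateral
defection; BoS pays 48 to the player whose Best option is coordinated on, 25
to the other, and 0/0 on a clash.

Between trials, Nature decides whether the experiment continues (probability
$\delta$), whether the opponent changes (probability $1-\xi$), and — staying
with the same opponent — whether the stage game switches (probability
$1-\rho$). The defaults $\delta = 0.9$, $\xi = 0.75$, $\rho = 0.67$ mirror the
experimental design this package models (48-trial runs in which half the
trials keep both game and partner, a quarter switch only the game, and a
quarter switch only the partner).

## The reduced state space

Everything the decision-maker needs to predict the opponent is summarized by
a state $s = (\theta, g, x, y, z)$: the opponent type, the active game, and
the automaton's internal flags — $x$, whether a BoS coordination has occurred
in this relationship; $y$, whether the automaton is retaliating; $z$, the
option (Best `b` / Worst `w`) it will play in the next BoS stage. Two
reductions shrink the naive product space to 26 states:

* AD has a single internal state, so only the game matters (2 states);
* a retaliating GT behaves exactly like AD and never recovers, so GT's
  retaliation is *canonicalized into the AD block* rather than stored in a
  flag (8 GT-specific states, sharing the 2 AD states);
* TfT needs the full flag set (16 states).

No transition crosses the AD/GT block and the TfT block while the partner
stays, so the transition matrix is block diagonal. The canonical state order
is lexicographic in (type block, game, $x$, $y$, $z$) — types AD, GT, TfT;
games PD, BoS; `b` before `w` — and every array, log and export in the
package uses it. `enumerate_states()` is the single source of that order.

One representational consequence matters downstream: when a GT opponent
retaliates, the *state* lies in the AD block, but the *condition* the subject
faces is still "GT in game $g$". Trial logs therefore carry both the reduced
state and the opponent type, and the analysis attaches complexity scores by
condition, not by state block.

## Transitions, values and the per-trial loss

For each participant action $a$, the transition map $T_a(s', s)$ combines the
deterministic flag update of the automaton with the probabilistic game
switch: mass $\xi\rho$ on the same-game successor and $\xi(1-\rho)$ on the
changed-game successor. Opponent changes and termination are excluded from
$T_a$, so rows sum to $\xi$; this is deliberate. The continuation probability
$\delta$ is applied in the Bellman operator,

$$B(\phi)(s) = \max_a \Big[ (1-\delta)\,u(s,a) +
  \delta \sum_{s'} T_a(s', s)\, \phi(s') \Big],$$

so the effective modulus of contraction is $\delta\xi$. An equivalent
formulation folds $\delta$ into the transition weights ($\delta\xi\rho$ and
$\delta\xi(1-\rho)$); the two agree term by term, and the package's tests pin
the transition maps cell-for-cell against the worked matrix example at
$a = C$, $g = \mathrm{BoS}$.

Value iteration runs to a sup-norm residual below `tol` (default $10^{-10}$,
far below any payoff gap; convergence is geometric, about 64 iterations at
defaults). From the fixed point $V$ we compute
$Q(s,a) = (1-\delta)u(s,a) + \delta \sum_{s'} T_a(s',s) V(s')$, the greedy
policy, and the per-trial loss

$$L(s,a) = V(s) - Q(s,a) \ge 0,$$

the cost of choosing $a$ in $s$. A subject's *total loss* is the sum of
$L(s_t, a_t)$ over trials; it is zero exactly under the optimal policy. Note
the $(1-\delta)$ normalization: values and losses are on a per-period ECU
scale, not raw ECU (a flat payoff shift of $c$ moves $V$ by
$(1-\delta)c/(1-\delta\xi)$ and leaves $L$ unchanged).

Two independent checks guard the solver. First, $V$ is compared against a
finite-horizon expectimax that steps the automaton engine over the explicit
game tree (horizon 50, truncation error below $(\delta\xi)^{50}\cdot 50 <
10^{-6}$) — a route that never touches the transition matrices. Second,
reinstating the opponent-change mass (uniform over the six fresh-relationship
states) and re-solving shifts $V$ by a single constant and changes neither
$Q$-differences, nor losses, nor the policy; this licenses dropping that mass
from the default model.

Argmax ties would be reported as sets (none occur at the default parameters —
asserted by test); the single-action export orders `C` before `A`, which is
inconsequential because tied actions have zero loss.

## The complexity index

The environment's difficulty is ordered along two dimensions: opponent
strategies by the size of the machinery one must track
($TfT \succeq GT \succeq AD$) and games by what sustaining the good outcome
demands ($BoS \succeq PD$: coordination requires alternation, cooperation a
constant action). Against AD the games are equally hard — the opponent
ignores you — giving the equivalence $(AD, PD) \sim (AD, BoS)$. Taking the
transitive closure of the componentwise order yields a partial order on the
six (strategy, game) pairs; $(TfT, PD)$ and $(GT, BoS)$ stay incomparable.
Each vertex scores *(number it strictly dominates) − (number strictly
dominating it)*; equivalent vertices count in neither direction (either
symmetric convention cancels — asserted by test). The resulting scores,

| condition | score |
|---|---|
| (AD, PD), (AD, BoS) | −4 |
| (GT, PD) | −1 |
| (GT, BoS), (TfT, PD) | 2 |
| (TfT, BoS) | 5 |

sum to zero and give the four complexity levels used as the regressor
throughout. The closure is verified against an explicit Floyd–Warshall
reachability oracle written independently in the test helpers.

## Simulating sessions and synthetic cohorts

`generate_sequence()` supports two modes. The default *constrained-run* mode
reproduces the scanner design: 48-trial runs containing exactly 24 no-change,
12 game-change and 12 partner-change trials in seeded random order, the two
change types never coinciding (partner-stay fraction 0.75; same-game given
same-partner 24/36). The *iid* mode draws changes independently with the
model's probabilities, for model-validation tests. Termination ($1-\delta$)
is not simulated in fixed-length runs; $\delta$ enters only the solver. Each
run starts from a uniformly drawn opponent and game with the automaton at its
initial condition; on a partner change the new opponent is drawn uniformly
from the other five names (a config flag allows self-redraw) and the
automaton reinitializes, while the game is kept.

`generate_cohort()` produces the synthetic stand-in for a 42-subject study:
ability groups low/medium/high of sizes 16/14/12, one session set of 6 runs ×
48 trials per subject, a single root seed with per-subject substreams. The
choice model is a *state-blind error rate*

$$\varepsilon_g(c) = \mathrm{logit}^{-1}(\alpha_g + \beta_g c), \qquad
  \text{capped at } 0.5,$$

where $c$ is the condition's complexity score: with probability
$1-\varepsilon$ the agent plays an optimal action, otherwise the other one.
Defaults $\alpha = (-1.6, -1.9, -2.1)$ and $\beta = (0.25, 0.15, 0.12)$ for
(low, medium, high) were chosen once so that (i) overall optimal-choice rates
land in the mid-80% range typical of trained participants, (ii) error rates
stay below 0.5 even in the hardest condition, and (iii) the low-ability group
is disproportionately affected by complexity ($\beta_{low} > \beta_{high}$),
the qualitative structure the analysis stage is meant to detect. A
softmax-on-$Q$ agent is available behind `choice_model = "softmax"`; the
ε-error model is the default because it maps directly onto the loss
regression and keeps the generative interaction interpretable.

RTs are linear in normalized complexity with Gaussian noise, truncated to the
(0, 3000] ms response window: intercept 800 ms, slope 150 ms *across the
whole complexity range*, noise SD 250 ms. The 150 ms span echoes the order of
magnitude reported for human data in this paradigm; it is a generator
default, not a claim of reproducing a human estimate. Group-specific RT
intercepts are exposed (`rt_intercept`) but equal by default; real subjects
show patterns (fast-and-inaccurate low scorers, slow-and-accurate medium
scorers) that this generator does not attempt to reproduce.

The ability score is a synthetic Raven-like integer (group-dependent normal,
rounded, clipped to 0–36). It exists so that `assign_groups()` — the tertile
split at the 33rd/66th percentiles, ties to the lower group — can be
exercised end-to-end; group membership in the generator is fixed by
configuration, mirroring how the study's uneven groups (16/14/12) arose from
a tied score distribution.

`expected_loss_curve()` is the generator's analytic oracle: it computes, per
group and complexity level, the expected per-trial loss implied by the error
model and the state distribution induced by near-optimal play. Because a
retaliating GT occupies AD-block states while the condition is still GT, the
chain is built over 28 (state, opponent-type) pairs. The default
`dist = "run_average"` averages the chain over a 48-trial run started from a
fresh relationship, matching the constrained design; `"stationary"` gives the
long-run distribution. Simulated cohort cell means agree with the curve
within Monte-Carlo error (asserted at 3 SEs per cell).

## What passing tests do and do not show

The cohort generator emulates the *statistical structure the analysis
assumes*: error rates rising with complexity, steeper for low ability, RTs
rising with complexity, subject-level clustering. It does not emulate
learning within a session, trial-order effects, post-error slowing, lapses,
or the fast/slow trade-offs of real subjects. Green tests therefore certify
that the pipeline recovers what the generator put in — parameter-recovery
power, sign recovery of the group × complexity interaction, calibration under
a true null — not that human data would show these effects.

## Analysis choices

`score_dataset()` validates a log by replaying every subject × run through
the automaton engine (rejecting any inconsistency with its coordinates),
fills in $L(s_t, a_t)$, attaches the complexity score of the trial's
(strategy, game) condition, and reports per-subject totals and the %-optimal
summary statistic.

`fit_loss_model()` / `fit_rt_model()` regress the per-trial outcome on
complexity. The default engine is OLS with standard errors clustered at the
subject level (CR1), each coefficient tested with a Wald chi-square whose
p-value uses a t reference with $G-1$ degrees of freedom ($G$ = subjects) —
the simpler of the two formulations quoted for this design, and conservative
at 42 clusters. `method = "mixed"` fits the random-intercept model (lme4, ML)
and tests the complexity effect by likelihood ratio; the two agree in sign
and significance on default cohorts (asserted by test). Random slopes are not
fitted by default: the mixed-model specification is deliberately minimal, and
the calibration test guards against gross miscalibration. `with_groups = TRUE`
adds group main effects and group × complexity interactions under treatment
coding with `low` as reference, so `complexity:grouphigh` estimates how much
flatter the complexity effect is among high-ability subjects. Subsets by
change type (`"change"` / `"no_change"`) mirror the paradigm's switch/stay
contrasts. No multiple-testing correction is applied to the primary
complexity test.

One property of the ε-error generator deserves emphasis: *zeroing*
$\beta_g$ does **not** make the loss–complexity regression null. Errors are
then equally frequent everywhere, but an error in a more complex environment
still costs more (the mean $L$ of the suboptimal action rises with
complexity), leaving a structural positive slope of about a third of the
default-generator effect. The package asserts this property explicitly. Test
calibration is therefore checked where the null actually holds: on outcomes
simulated from the fitted model's own null (random subject intercepts plus
noise, no complexity dependence) over a real cohort design, the nominal-5%
clustered test rejects at close to 5% (bounded at 7% in the test suite). Permutation-style nulls were considered and rejected: permuting
complexity within subject freezes each subject's mean complexity and turns
chance between-subject correlation into a fixed slope offset, while global
permutation leaves the Wald t slightly heavy-tailed under the very skewed
loss distribution.

Losses are analyzed on the solver's per-period ECU scale; multiply by
$1/(1-\delta)$ if raw-ECU magnitudes are wanted.

## Numerical choices and degenerate inputs

* Solver tolerance $10^{-10}$ (sup norm); iteration cap at the analytic
  geometric bound plus slack — exceeding it is an internal error.
* Argmax ties declared at $10^{-9}$; reported as sets.
* Probabilities must lie strictly in (0, 1); a non-positive tolerance, an
  impossible run composition, an all-equal ability distribution, a
  single-complexity-level or single-subject regression design are rejected
  up front with informative errors.
* RT truncation clamps to [1, 3000] ms (at default noise the bounds are
  essentially never hit).
* Reproducibility: every stochastic function takes a seed; cohorts derive
  per-subject substreams from the root seed; the pipeline echoes a config
  hash and seed into every artifact header.

## Problem sizes used in the test-suite

The solver and state-space checks are exact and instantaneous. The
stochastic guarantees are checked at: 100 seeded default cohorts (42 × 288
trials each) for detection power and interaction sign recovery, 200
null-model replicates for calibration, and 10,000 iid trials for sequence
frequencies — sizes chosen so the Monte-Carlo error of each check is small
relative to the margin it asserts.

## Limitations

* The state-space reduction is specific to the AD/GT/TfT triple; arbitrary
  user-defined automata are out of scope.
* Only the two stage games, with the fixed payoff tables, are supported.
* The generator's choice model is memoryless given the state; it cannot
  produce sequential dependencies in errors.
* Neural data and their analyses are entirely outside this package's scope.
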