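---
title: "The collective-risk dilemma with recurrent and uncertain losses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The collective-risk dilemma with recurrent and uncertain losses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

```{r setup, message = FALSE}
library(collrisk)
```

## The game

`collrisk` simulates a threshold public-goods game in which contributions do
not produce a benefit but *reduce the probability of a collective loss* —
the standard stylization of climate-change mitigation. A group of $m$
players starts with endowments $W_{i,0}$ and plays $\Omega$ rounds. In
round $r$ each player simultaneously contributes $c_{i,r}$ from their
remaining wealth to a cumulative pot

$$C_r = \sum_{j \le r} \sum_{i=1}^m c_{i,j}.$$

In every *loss-capable* round, each player independently suffers a loss
with probability $p_i[C_r]$, in which case a fraction $\alpha_i$ of their
remaining wealth is destroyed:

$$W_{i,r} = (1 - \alpha_i)\,(W_{i,r-1} - c_{i,r})$$

with probability $p_i[C_r]$, and $W_{i,r} = W_{i,r-1} - c_{i,r}$ otherwise.
The contribution is committed before the loss strikes, and the loss
probability is evaluated at the pot *including* the current round's
contributions (contributing in a round still protects you within that
round). The final payoff is $\pi_i = W_{i,\Omega}$; wealth can never go
negative because contributions are capped by remaining wealth.

### Risk curves

`risk_curve()` provides three monotone-decreasing families, all normalized
by the total initial group wealth $W_0$ so only the invested fraction
$C/W_0$ matters:

| family    | form                                         | shape parameter |
|-----------|----------------------------------------------|-----------------|
| `linear`  | $1 - \lambda_1 C/W_0$, clamped to $[0,1]$    | decline speed   |
| `power`   | $1 - (C/W_0)^{\lambda_2}$, clamped           | convexity       |
| `sigmoid` | $1/(e^{\lambda_3(C/W_0 - 1/2)} + 1)$         | threshold steepness |

The sigmoid family has its inflection fixed at $C = W_0/2$, where the loss
probability is exactly $1/2$; large $\lambda_3$ approximates a hard
threshold ("step-like" risk). The linear and power forms are clamped into
$[0,1]$ so that steep curves ($\lambda_1 > 1$) reach *zero* risk before the
whole endowment is pooled — the clamped branch is exactly the piecewise
"and 0 beyond" behavior that the heterogeneous analysis uses.

Loss timing is a separate axis (`loss_timing()`): a potential loss in
*every* round, only the *first*, only the *last*, or in one *random* round
drawn uniformly per game. The random draw is per game (not per generation
or per player), which keeps games exchangeable within a generation.

### Strategies

Players are not rational planners; each carries a hard-coded rule
(`strategy()`): per round a triple $(\tau_r; a_r, b_r)$ meaning "contribute
$a_r$ if the observed pot is at most $\tau_r$, else $b_r$", with the pot
observed *before* the round's simultaneous moves. The tie ($C = \tau_r$)
plays $a_r$. This is deliberately minimal: it can express unconditional
giving ($a_r = b_r$), top-up behavior ($a_r$ high, $b_r$ low), and
free-riding ($a_r = b_r = 0$), while keeping the trait space
$3\Omega$-dimensional.

```{r}
s1 <- strategy(tau = c(0.0, 0.2), a = c(0.1, 0.1), b = c(0.0, 0.5))
s2 <- strategy(tau = c(0.1, 0.7), a = c(0.5, 0.2), b = c(0.1, 0.5))
cfg <- game_config(m = 2, rounds = 2, wealth = 1, alpha = 0,
                   risk = risk_curve("linear", 1))
play_game(list(s1, s2), cfg)$trace
```

## Exact expectations and Monte-Carlo play

`expected_payoffs()` enumerates all $2^{\text{slots}}$ joint outcomes of
the independent Bernoulli losses along the game tree (one slot per player
per loss-capable round), applying wealth caps on every path, and so is
exact for any configuration small enough to enumerate (a guard rejects
more than 20 slots). For two rounds and cap-free paths it reduces to the
closed product form

$$\pi_i = (1 - \alpha_i p_i[C_2])\left((1 - \alpha_i p_i[C_1])(W_{i,0} -
c_{i,1}) - c_{i,2}\right),$$

which the test suite verifies to $10^{-12}$. `play_games()` draws seeded
Monte-Carlo replicates, vectorized across games; agreement between the two
routes (within three standard errors at $10^4$ replicates over randomized
configurations) is a standing test. Losses are modelled as *independent*
per player per round — the reading consistent with the product form above;
a common group-wide shock would correlate outcomes and is out of scope.

## Evolutionary dynamics

`run_evolution()` iterates a Wright–Fisher process: each generation plays
`games_per_generation` games between randomly drawn groups (uniform,
without replacement within a game), averages each individual's payoffs,
maps payoff to fitness $f_i = e^{\pi_i}$, samples $N$ offspring
multinomially in proportion to fitness, and mutates each trait
independently with probability $\mu$ — Gaussian noise with standard
deviation $\sigma$ for thresholds (clamped at zero, no upper bound: a huge
threshold just means "always play $a_r$"), uniform resampling on $[0, W_{i,0}]$
for contribution levels. Defaults follow the study conditions throughout:
$N = 100$, $\mu = 0.03$, $\sigma = 0.15$, 1000 games per generation.
Individuals that happen to be drawn into no game receive the mean payoff
of those that played, which keeps the step well defined and neutral.
Burn-in defaults to 10% of the run and is discarded before averaging.
The inner loop is compiled (Rcpp) but consumes R's RNG stream, so a seed
makes whole runs bit-reproducible.

`run_two_populations()` coevolves a rich and a poor population over a
shared pairwise game: every game draws one individual from each,
selection and mutation stay within each population (the poor imitate only
the poor), and mutated contributions are resampled on each population's
own endowment scale — the choice that keeps poor strategies feasible where
a shared scale would mostly propose infeasible contributions. Summaries
report contributions both in wealth units and as fractions of each
population's own endowment, since "half your wealth" is the comparable
quantity across unequal endowments.

```{r, eval = FALSE}
game <- game_config(2, 4, wealth = c(4, 1), alpha = 1,
                    risk = risk_curve("sigmoid", 10), timing = "every_round")
cfg <- evolution_config(game, generations = 20000, seed = 1)
fit <- run_two_populations(cfg)
glance(fit)
autoplot(fit)
```

## One-round analysis: best responses and stable states

For one round, two players, full losses and *linear* risk the model is
solvable. With endowments $W_R \ge W_P$, combined wealth $W = W_R + W_P$,
the poor face $p_P = 1 - C/W$ while the rich's risk declines faster,
$p_R = 1 - \lambda_R C/W$ for $C < W/\lambda_R$ and zero beyond
($\lambda_R \ge 1$). Payoffs are $\pi_f = (W_f - c_f)(1 - p_f)$. Setting
$\partial \pi_f / \partial c_f = 0$ in the positive-risk region gives the
linear best responses $c_R = (W_R - c_P)/2$ and $c_P = (W_P - c_R)/2$;
where the rich's optimum falls into their zero-risk region the best
response switches to the *cheapest* zero-risk contribution
$\max(0, W/\lambda_R - c_P)$ (anything more is wasted). `analytical_ess()`
intersects these curves piecewise: the regimes dispatch on $W_R$ versus
$2 W_P$ and on $\lambda_R$, adjacent formulas agree at every boundary, and
in the interior regime the total pins to $C^* = W/3$. At the overlap
$W_R = 2 W_P$ both dispatch branches give identical values; we use the
first. `iterated_best_response()` is the numerical counterpart — zoomed
grid search per player, alternated to a fixed point — and works for any
continuous one-round payoff, so it both cross-checks every closed-form
regime and extends the analysis to, e.g., sigmoid risk.

```{r}
ess_table(w_rich = 4, w_poor = 1, lambda_rich = c(1, 2, 4, 7, 12))
```

## Numerical and design choices

* **Zoomed grid search** (`iterated_best_response()`): 1001 points, three
  refinement levels, i.e. a resolution of $\approx 8 \times 10^{-9}$ of the
  endowment; payoff ties resolve to the *smallest* contribution, matching
  the "contribute as little as necessary" convention at zero-risk
  boundaries. Non-convergence within `max_iter` is reported in the result,
  not raised.
* **Enumeration guard**: `expected_payoffs()` refuses more than 20
  loss-capable player-round slots with an explicit size message.
* **Random-round expectation** averages the $\Omega$ fixed-round
  expectations with weight $1/\Omega$, mirroring the per-game uniform draw.
* **Degenerate inputs**: zero pots are legal (linear risk gives $p = 1$),
  $\alpha = 0$ makes losses harmless, and strategies prescribing more than
  the remaining wealth are capped, never rejected.

## What the simulations do and do not show

The synthetic dynamics emulate the study conditions exactly: pairwise (or
small-group) games, the three risk families, the four timing scenarios,
wealth and loss-fraction heterogeneity, and the stated population
parameters. They do not emulate features of real experimental data —
human subjects, communication, learning within a lifetime, or more than
two wealth classes — so a passing suite validates the *model dynamics*,
not behavioral predictions about people.

Problem sizes in the shipped tests and in `scripts/acceptance.R` are
desk-scale choices: evolutionary checks run 1,500–20,000 generations
(with 10% burn-in) and 1,000 games per generation, which reproduces the
stationary quantities that matter here; the command-line `evolve
--full-scale` flag switches to $10^5$ generations for full-scale runs.

Two known limitations are worth stating plainly. First, under last-round
timing with a steep threshold curve the dynamics settle on near-equal
per-round contributions (the Schelling pattern) rather than a last-round
peak, even at $10^5$ generations: a seeded population of last-round
"top-up" players erodes within a few thousand generations because the
conditional traits that implement it are nearly neutral once the
population is monomorphic, and drift degrades them faster than selection
restores them — although head-to-head expected payoffs do favor such
top-up behavior against flat contributors. Second, long-run averages at
these scales retain seed-to-seed variability of a few percent of the
endowment; all stochastic checks therefore aggregate several seeds.
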