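---
title: "Instance-based learning in the Sugar Factory: model, smoothing, and optimization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Instance-based learning in the Sugar Factory: model, smoothing, and optimization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(iblopt)
```

## The task and the cognitive model

The Sugar Factory is a turn-based control task: a participant sets a
workforce $x_j \in \{1,\dots,12\}$ each round and the sugar production
responds as

$$p_{j+1} = \operatorname{clip}(2 x_j - p_j + u^r_j,\; 1,\; 12),$$

with environment noise $u^r_j$ uniform on $\{-1, 0, 1\}$. The goal is to
hold production at $p^\* = 9$ (thousand tons); a round counts as *on
target* when $p_{j+1} \in \{8, 9, 10\}$, and the episode score $R$ is the
number of on-target rounds out of $N_r = 40$. People control this system
above chance yet far from optimally, and typically cannot verbalize the
rule — the signature of *instance-based learning* (IBL): storing
situation–response–outcome instances and retrieving the most active
similar one.

`iblopt` implements an IBL model of this task in the style of the ACT-R
declarative memory. An instance is a chunk $(c_1, c_2, c_3)$ — workforce
applied, production before, production after. All $12^3 = 1{,}728$
possible chunks are preallocated; a never-presented chunk sits at a
sentinel activation $-M$ (default $-1000$, far below every reachable
activation and every threshold of interest). The activation of a
populated chunk $i$ at round $j$ for the retrieval request $(p_j, 9)$ is

$$A_i = \underbrace{\ln\frac{n_i}{1-d} - d \ln L_i}_{B_i\ \text{(base level)}}
      + \underbrace{P\,(M_{i1} + M_{i2})}_{C_i\ \text{(partial matching)}}
      + u^n_{ij},$$

with presentation count $n_i$, lifetime $L_i = j - t_i + T$ (creation
round $t_i$, offset $T = 0.05$), decay $d$ (default $0.5$), similarity
weighting $P$, ratio similarities
$M_{i1} = -|p_j - c_{i2}|/\max(p_j, c_{i2})$ and
$M_{i2} = -|9 - c_{i3}|/\max(9, c_{i3})$, and transient logistic noise
$u^n_{ij}$ with scale $s$ (default $0.2$; disabled by default in the
simulations, where it has no noticeable effect on mean scores). The chunk
with the highest activation is retrieved if that activation reaches the
threshold $\tau$; ties break toward the lowest chunk index so retrieval
is reproducible. On retrieval the agent applies the chunk's stored
workforce $c_1$; otherwise it explores.

Exploration follows the empirical human choice rules: start at
$x_1 \in \{7,8,9\}$; then move the workforce by an increment drawn a
priori — $u^{on}_j$ uniform on $\{-1,0,1\}$ after an on-target round,
$u^{off}_j$ uniform on $\{-2,\dots,2\}$ otherwise — and clip to
$\{1,\dots,12\}$. At the end of every round the experience triple
$(x_j, p_j, p_{j+1})$ is stored: a new chunk with $n=1$, or a merge
($n \mathrel{+}= 1$, creation round kept) if that triple already exists.

### Two readings of the exploration walk

The formal round loop can be written with a *decoupled* exploration
state $u_w$ that evolves by $u^{on}/u^{off}$ increments regardless of
what the agent actually did. The human choice rules, however, anchor the
next exploration at the *previous actual workforce*,
$x_j = x_{j-1} + u$. The difference matters: an anchored walk continues
exploring from retrieved good choices, a decoupled walk wanders off on
its own. We examined both and found that only the anchored reading
reproduces the model's published performance surface (mean score
$\approx 20.2$ at $\tau = -4$, $P = 27$, versus $\approx 17.8$ for the
decoupled walk, which depresses the whole surface by 2–3 rounds); the
same holds for the best fit to human reference performance and for the
spread-penalized optimum. `sim_config()` therefore defaults to
`walk_anchor = "previous_choice"` together with the on-target band rule
`on_target_rule_for_walk = "band_8_10"` (the rule the human data
describe), and keeps the decoupled walk and the exact
$p_{j+1} = 9$ branch available as options.

A related switch, `count_retrieval_as_presentation` (default `FALSE`),
controls whether a successful retrieval strengthens the retrieved chunk.
Only the end-of-round storage counts as a presentation by default: that
is the operational definition in the formal loop, and enabling the
switch changes mean scores by well under one round.

## Frozen input streams

All randomness enters through `make_streams()` /
`make_batch()`: per-replicate sequences $u^{on}, u^{off}, u^r$, the
initial workforce, and (when enabled) the $N_r \times N_c$ activation
noise matrix. Streams are a pure function of an integer seed; batch
replicate $i$ derives its sub-seed from the master seed and $i$ alone
(an affine map modulo the prime $2^{31}-1$, injective in $i$), so
replicate $i$ is identical whether you generate 5 or 500 replicates.
Freezing the streams is what makes every objective below a
*deterministic* function of the parameters (common random numbers) —
repeated evaluation at the same $(\tau, P)$ is bit-identical, which
derivative-free optimizers require to behave sanely.

The generator emulates exactly the stochastic structure of the study
conditions: uniform discrete supports, logistic activation noise, 40
rounds, initial production 6. It does not emulate human data in any
richer sense — no individual differences, no learning-rate drift, no
response times — so passing tests say the *model mathematics* are right,
not that the model fits any particular participant sample.

## The smoothed reformulation

Optimization with derivative-based methods needs a continuously
differentiable model, so every discrete operation in the round loop has
a smooth counterpart built from

$$H(x) = \tfrac{1}{\pi}\arctan(h x) + \tfrac12, \qquad
  \delta(x) = \exp(-x^2/a^2).$$

If-then branches become $H(s)\,a + (1-H(s))\,b$; $\max$ and
$|x-y|/\max(x,y)$ get the corresponding $H$-blends; clipping composes
two such branches. Sharpness is tunable per model part
(`smoothing_params()`): `h_sim` for the similarity terms, `h_argmax` for
chunk selection and the threshold comparison, `h_env` for the
environment (clipping and scoring), defaults $10$, $10^7$, $10$, and
$a = 0.01$ for the Delta kernel. The selection itself replaces the
argmax: with $A^\* $ the smoothed maximum (a pairwise `smooth_max` fold
in ascending index order — the fold order is fixed and documented,
because at finite $h$ each fold step against a dominated element leaves
a deficit of order $1/(\pi h)$),

$$x_j = \frac{\sum_i H(A_i - A^\*)\,\bigl(H(A^\* - \tau)\, c_{i1} +
        (1 - H(A^\* - \tau))\, u_w\bigr)}{\sum_i H(A_i - A^\*)}.$$

Design choices in this runner, made where the formulation is genuinely
open:

* **Normalized selection weights.** The raw weight sum degenerates when
  many activations are equal: on a fresh memory every chunk sits at the
  sentinel, every weight is $H(0) = \tfrac12$, and the raw sum would
  multiply the fallback choice by $\sim 864$. Normalizing makes the
  selection a proper convex combination; at sharp `h_argmax` it is
  numerically indistinguishable from the raw sum. The raw form stays
  available (`select_normalize = FALSE`) for studying the degradation of
  the unnormalized formulation. The empty memory itself is handled as an
  empty candidate set (the choice *is* the exploration workforce).
* **Discrete chunk bookkeeping.** The chunk store is by construction a
  grid of integer triples; the real-valued experience triple is stored
  at the nearest slot. Similarities, in contrast, are evaluated on the
  raw real values.
* **Walk-branch test on the grid.** The walk's on/off-target test picks
  between two discrete input streams. Evaluated on the raw smoothed
  production it is fragile: the arctan clip has fat tails, so state
  values drift $O(10^{-2})$ off the integer grid and a Delta kernel of
  width $0.01$ then flips branches against the discrete model. The test
  is therefore evaluated on the nearest-grid production ($\delta$ kernel
  for the exact-nine rule, band indicator for the band rule), which
  keeps the walk reproducing the discrete branch in the sharp regime.
* **Smoothed score.** The on-target indicator uses the integer-midpoint
  band, $H(p - 7.5)\,H(10.5 - p)$ at `h_env`, so each on-target round
  contributes $\approx 0.93$–$0.96$ and off-target rounds
  $\approx 0.06$; summed over an episode these nearly cancel and the
  smoothed score tracks the discrete one closely in the mean.

### What sharpness does — and the limits of equivalence

With `h_argmax` $= 10^7$ and `h_sim = h_env` $= 10$ the smoothed model
tracks the discrete model closely: batch means agree to a fraction of a
round, and a large share of replicates reproduce the discrete episode
exactly. Exact per-replicate equivalence is, however, *not* attainable
with these formulas: at `h_sim` $= 10$ the $H$-blended ratio similarity
under-penalizes mismatched slots by up to $\approx 0.02$, i.e. up to
$\approx 0.4$ activation units at $P = 20$, so retrieval competitions
whose maximum lands within that margin below $\tau$ retrieve in the
smoothed model but not in the discrete one (a couple of rounds per
episode at $\tau \approx -3.14$). This one-directional leak also leaves
the smoothed batch mean a few tenths of a round below the discrete
mean. Softening the selection to `h_argmax` $= 10^3$ degrades the
learning loop — the smoothed maximum's fold deficit widens to
$\sim 0.3$ activation units, several chunks can share near-full
selection weight, and under the raw (unnormalized) weight sum the
workforce choice is then scaled by the fluctuating total weight, which
visibly disrupts learning. With normalized weights the low-sharpness
model blends near-maximal chunks instead, and its mean score degrades
only mildly; the deep collapse reported for unnormalized
implementations depends on internals (fold order, handling of tied
activations) that the printed formulas do not determine.

Gradient-based optimization *through* the smoothed model is out of
scope: at the sharpness needed to match the discrete model the response
surface is effectively piecewise constant, so the package optimizes the
discrete model with derivative-free methods instead.

## Objectives, sweeps, and solvers

Two optimization targets are built in (`optimize_model()`), both over
$(\tau, P)$ with $d$ fixed at $0.5$ and both evaluated on a frozen
100-replicate batch:

* **Fit**: minimize the RMSD between per-replicate scores and a human
  reference score $R_{\mathrm{ref}} = 7.9$,
  $\sqrt{\tfrac1n \sum_i (R_i(\theta) - R_{\mathrm{ref}})^2}$.
* **Performance**: maximize $a \cdot \mathrm{mean}(R_i) + b \cdot
  \mathrm{sd}(R_i)$ (sample standard deviation, $n-1$; with one
  replicate the spread is reported as 0 with a warning).

`run_optimizer()` delegates to four NLopt algorithms via \pkg{nloptr}:
Nelder–Mead and BOBYQA (local, derivative-free; stopping rule
`xtol_rel = 0.1` on the parameters), and ESCH and CRS2 with local
mutation (heuristic global). Local solvers are multi-started from four
corner-biased points of the box $\tau \in [-8.5, 1]$,
$P \in [0.5, 35]$ (the sweep ranges, which contain all published
optima); global solvers are budgeted by evaluation count rather than
wall-clock so runs are hardware-independent. Each best objective
carries an upward winner's-curse fluctuation of roughly the standard
error of a 100-replicate mean ($\approx 0.7$ rounds), so replicated
comparisons should aggregate across several master seeds.

`grid_sweep()` evaluates the mean, spread, and learned-only mean (rounds
on target in which a retrieved instance drove the choice) over an
inclusive $(\tau, P)$ lattice; the fine lattice of the sensitivity study
($\tau$ step $0.05$, $P$ step $0.1$) has $191 \times 346 = 66{,}086$
points. Loose retrieval criteria (low $\tau$, moderate $P$) learn
effectively; high $\tau$ with strong mismatch weighting suppresses
recall and the learned share of the score collapses toward the
random-walk baseline.

## Problem sizes used in tests and the acceptance script

The shipped tests exercise the optimizations at $n = 100$ replicates
and 40 rounds (the study conditions) with the simplex solver and four
starts; property-style tests run hundreds of randomized episodes and a
thousand randomized retrieval states against a naive linear-scan
oracle; smoothing comparisons use 60–100 replicates. The acceptance
script aggregates each optimization target over three independent
master seeds. A full test run takes a couple of minutes on one core.

## Known limitations

* The model covers the declarative-memory route only: no spreading
  activation, no production-rule utilities, no response-time modeling.
* Per-replicate smoothed/discrete equivalence is approximate for the
  structural reasons above.
* Reported single-input results (score heatmaps for one fixed stream)
  are reproducible only qualitatively: they depend on the exact
  pseudo-random realization, which is not published.
* The parallelization of `grid_sweep()` is left to the caller (the
  computation is embarrassingly parallel over lattice points and its
  results are order-independent); the built-in loop is serial.
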