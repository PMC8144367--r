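---
title: "Modelling the group-formation swap game: payoffs, agents, and behavioural metrics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the group-formation swap game}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(groupswap)
```

## The game

Thirty players sit on the nodes of a 5×6 torus (every node has four
lattice neighbours) to which a configurable number of random small-world
links is added, subject to a total degree cap of 5. Players are split into
`m = 3` colour groups of `l = 10`. A *cluster* is a connected component of
same-coloured nodes; the object of the game is to grow clusters by
swapping seats with neighbours.

Play proceeds in rounds (`r = 15` by default). In round `t` (0-based) the
colour `(t mod m) + 1` may send requests: each eligible player — one with
at least one differently coloured neighbour — may ask exactly one such
neighbour to swap. Receivers then accept at most one incoming request
(they can only vacate one seat), and accepted swaps execute. Over a full
game each colour therefore gets `r/m = 5` request turns, and each player
at most `2r/m = 10` receive turns. Information is masked: a player sees
only their own cluster size, the colour and cluster size of direct
neighbours, their group's current points, and the largest cluster of each
colour.

Players are distinct from seats: a player keeps their colour and
controller for the whole game and physically moves on a swap. The engine
tracks this with an occupant permutation, which is what makes per-player
opportunity counts respect the `r/m` and `2r/m` caps.

## Payoff schemes

Two schemes are implemented.

**Collective (ACP).** The average collective progress is the mean over
colours of (largest cluster)/`l`. It is `1/l` on a properly coloured mesh
and 1.0 when every group is a single cluster; the collective game ends at
ACP = 1.

**Point-based.** Points attach to groups and are recomputed from the
board every round (they are lost if a requirement stops holding):

| requirement | points |
|---|---|
| own group's largest cluster ≥ 6 | 5 |
| own group's largest cluster ≥ 9 | 7 (cumulative) |
| each *other* group with largest cluster ≥ 9 | 4 |

Two readings of the table are possible; we apply the 4-point row once per
other group and treat the 5- and 7-point rows as cumulative, because only
that reading yields the documented per-game maximum of 20 (5 + 7 + 4 + 4),
which `max_scheme_points()` confirms by brute force over all largest-
cluster triples in `{1..10}^3`. A consequence worth noting: every group
holds 20 points as soon as all three largest clusters reach 9, so the
points objective triggers slightly before full clusters of 10 — the engine
terminates on "every group at the scheme maximum", the scheme's own
fixed point, rather than on complete clusters.

Start configurations are resampled until no group holds more than 6
points, and sessions of up to three games grant the full reward at 27
cumulative points, skipping the third game if the first two suffice.

## The agent decision model

At each opportunity a player weighs each available option ω (a
differently coloured neighbour, or an incoming requester) against doing
nothing. The utility ratio is log-linear,

$$P_\omega / P_0 = \exp\{\lambda + \alpha s_i + \beta s_j + \delta \langle s(c_j)\rangle\},$$

with $s_i$ the player's own cluster size, $s_j$ the option's, and
$\langle s(c_j)\rangle$ the mean cluster size of the player's *other*
neighbours sharing the option's colour (when the option is the only
neighbour of its colour the exclusive mean is defined as $s_j$ itself, so
the comparison term vanishes). Choice follows probability matching:

$$p_\omega = \frac{P_\omega/P_0}{1 + \sum_{\omega'} P_{\omega'}/P_0},
\qquad p_0 = \frac{1}{1 + \sum_{\omega'} P_{\omega'}/P_0}.$$

A *stability rule* removes any option for which both $s_i$ and $s_j$
strictly exceed 60% of `l` (sizes ≥ 7 when `l = 10`), preventing agents
from dismantling two already-large clusters. We apply it to both request
and accept decisions by default — whether the original agents constrained
accepts too is not documented, so a flag (`apply_stability_accept`)
disables it.

The parameter defaults (λ = −1, α = −0.3, β = 0.2, δ = −0.2) are
*placeholders with qualitatively cooperative signs* — reluctant to move a
large own cluster, inclined toward small target clusters — chosen once;
the originating experiments' fitted values were never published, so every
quantitative agent-behaviour output (trajectories, interaction counts)
is parameter-dependent and should be read as such.

### Fitting

`fit_params()` maximises the exact probability-matching likelihood
(multinomial with an opt-out baseline; binary logistic in the
single-option case, which we cross-check against `glm()` in the tests).
Standard errors come from the observed information. Identifiability
requires variation in the covariates and both acted and unacted
opportunities; degenerate records raise an error rather than returning a
boundary fit. Parameter recovery on synthetic records (20 replicates of
5,000 opportunities) keeps every estimate within 3 SE of truth with mean
absolute bias below 0.05 — the scale at which the analysis scripts run it.

## Behavioural metrics

* **Activity** $a_i = N_i/\mathcal{N}_i$: acted fraction of a player's
  opportunities, computed separately for requests and accepts. An accept
  opportunity is counted once per round per receiver with at least one
  incoming request (not once per request), matching the `2r/m` receive
  bound. Players with no opportunities get `NA`, never 0.
* **Risk-averseness** $a_i(s)$: the same ratio restricted to
  opportunities where the player's cluster size was $s$; empty cells are
  reported missing (small samples genuinely lack some sizes).
* **Strategy value** $U_j = \langle s(c_j)\rangle - s_j$ for each acted
  decision. Here the mean is *inclusive* of the chosen neighbour: under
  that convention a uniformly random chooser has expectation exactly 0,
  which makes 0 the natural null reference. The exclusive variant (used
  by the decision model) is stored alongside, since the two conventions
  differ and both are defensible; tables expose both columns.
* **Interaction matrices**: initiated requests counted by (initiator
  controller type → receiver controller type), optionally averaged per
  game.
* **Point trajectories**: per-round group points averaged over games,
  with games that ended early padded at their final value (truncation is
  a switch; padding keeps every game represented at every round index).

## Synthetic data and what it does (not) show

`gen_decision_records()` draws opportunities directly from the choice
model: cluster sizes uniform on 1..10 and 1–4 options per opportunity,
spanning the game's reachable states; each option carries a small
neighbour-size set so the inclusive and exclusive means stay mutually
consistent. It exists so the fitting and metric pipelines are testable
without any empirical data, and it is also the null-model generator
(uniform chooser) for the strategy metric.

"Human" players in simulated setups A–C are stood in by behavioural
profiles; the stock `point_seeking_profile()` adds a leniency bonus to
the accept intercept once the player's group has banked the small-cluster
award, mimicking the observed relaxation of accepting after a threshold
is reached. This is a modelling choice of this package — no fitted human
model exists for the point-based payoff — so A–C summaries are
profile-dependent stand-ins, while setup D (all agents) is
parameter-complete. Passing tests demonstrate internal consistency of the
machinery, not fidelity to human behaviour.

## Numerical and design choices

* Cluster computation is a hand-written weighted union-find; tests
  compare it against an independent BFS flood-fill oracle on hundreds of
  random boards and against `igraph::components()`.
* Small-world links are rejection-sampled under the degree cap with a
  bounded retry budget (default 1000 per link), then a constraint error —
  the cap is a hard invariant, the sampler is not prescribed.
* The number of added links per game is not documented for the original
  boards; the default is 10 and it is a configuration parameter. Links
  may connect same-colour nodes (start snapshots show clusters as large
  as 7, so they evidently could).
* Within a round, decisions use the round-start cluster sizes and the
  accepted, vertex-disjoint swaps execute in a uniformly shuffled order:
  all same-round decisions rest on identical information and no seat is
  positionally favoured.
* Choice sampling is inverse-CDF over the ordered option list using the
  game's seeded RNG, so whole games replay bit-identically.
* `board_with_largest()` builds boards with prescribed largest clusters
  by laying colour blocks along a boustrophedon path and, when off-path
  adjacencies frustrate every block order, falling back to a seeded
  hill-climb; the result is verified against the target before use.
* Analysis problem sizes: setups A/B/C at their session game counts
  (4/5/4), setup D at 100 realizations, fitting at 5,000 opportunities ×
  20 replicates — the sizes the reported tables are computed at.

## Known limitations

Agents are memoryless and homogeneous up to explicit jitter; no learning
or adaptation occurs during a game. The human stand-in profile is
deliberately parsimonious. Empirical quantities that depend on the
unpublished fitted parameters (e.g. per-setup interaction averages) are
reproduced qualitatively, not numerically. Network topology is limited to
the torus-plus-links family the game was played on.
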