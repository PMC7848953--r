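---
title: "Motivated reinforcement learning: models, tasks, and analyses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Motivated reinforcement learning: models, tasks, and analyses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

Animals weigh the same physical outcome differently depending on internal
need: salt is aversive to a sated rat and attractive to a sodium-depleted
one. `motivrl` models this *motivational salience* as a multiplicative
modulation of reward. The agent carries a drive vector $\mu$ alongside its
external state $s$; the physical reward vector $r$ is converted into a
scalar subjective reward

$$\tilde r = \mu \cdot r,$$

and the agent learns an action-value function that is explicitly a function
of both state and motivation,

$$Q(s_t, a_t, \mu_t) = E\Big[\sum_{\tau \ge 0} \gamma^\tau\,
\tilde r(s_{t+\tau}, \mu_{t+\tau} \mid a_t)\Big],$$

by semi-gradient temporal-difference (Q-) learning: after each transition
the Bellman mismatch

$$\delta = \tilde r + \gamma \max_{a'} Q(s', a', \mu') - Q(s, a, \mu)$$

is backpropagated through a small feedforward network, but only through the
output unit of the action actually taken, and with $\delta$ held constant
(`update_selected()`). Because $\mu$ is an input rather than part of the
loss, a single set of weights can express different behavioral policies for
different motivational states, and the policy can switch instantly when the
drives change — no re-learning of synaptic weights is required. That claim,
and its neural signature, are what the package's tasks exercise.

Motivation is kept distinct from state throughout: drives evolve by their
own rules (growth, saturation, reset on consumption), are typically slow
relative to actions, and — in the hierarchical setting — are supplied by a
separate, higher-level controller.

## Shared learning machinery (`init_mlp`, `forward`, `td_error`, ...)

All agents use small fully connected networks initialized by the Xavier
rule (normal, variance $2/(\text{fan}_{in}+\text{fan}_{out})$) unless noted.
Learning rates and exploration anneal geometrically between their endpoints
(`anneal()`); behavior policies are epsilon-greedy or softmax with inverse
temperature $\beta$ over the available actions only. Design choices worth
stating explicitly:

* **Semi-gradient TD.** The TD error is treated as a constant in the
  gradient; the finite-difference tests pin the implementation to
  $\partial Q_a/\partial w$ exactly.
* **Q-learning targets everywhere.** Even when behavior is softmax, the
  bootstrap uses the max over the successor's available actions.
* **Reference semantics in the hot path.** `update_selected()` mutates the
  weight arrays in place (the training loops discard the previous
  parameters); `mlp_clone()` provides value-semantics snapshots where
  needed. The inner kernels are compiled (Rcpp), everything else is plain R.
* **Annealing granularity.** The grid-world task is continuing, so its
  learning and exploration rates anneal per environment step. The
  episodic transport and manager tasks anneal per episode, which is the
  natural reading of a schedule quoted per task episode; total step counts
  are not knowable in advance there.

## The Four Demands grid world

A 6×6 grid is split into four 3×3 rooms, one resource each (think water,
food, sleep, play). Drive $n$ grows by 1 per step while unconsumed,
saturating at a cap $\theta_n$; occupying room $n$ pays $\mu_n$ and resets
that drive. Internal room boundaries are open — only the outer wall blocks
movement. Open boundaries are forced by the task's own arithmetic: the
two-room binge alternates rooms on *every* step, which interior walls with
doorways would make impossible.

The update order (read reward, reset the consumed drive, grow all drives
that paid nothing, capped) is the unique order reproducing the canonical
sequences: staying put pays 0, 1, 0, 1, ...; a 12-step migration cycle pays
9, 0, 1 per room. The canonical strategies have closed-form rates
(`strategy_rate()`), e.g. one-room binge $1/2$, two-room binge $1$,
migration $(\min(\theta, 9)+1)/3$ (so $10/3$ once $\theta \ge 9$ and $2/3$
at $\theta = 1$), delayed migration $47/14$ at $\theta = 15$; the test
suite replays every strategy through `fd_step()` and requires exact
agreement with the formulas.

The Q-network is 40–100–100–100–5 (three sigmoid hidden layers, linear
outputs; 41 inputs when the cap is itself an input). The position block is
a centered one-hot scaled to total variance 1 and the motivation block to
total variance 9, balancing the 36:4 channel ratio. Position centering is
analytic (uniform mean $1/36$); motivation moments are estimated from a
$10^4$-step random-walk rollout at the configured cap when the
configuration is created, because the drive distribution depends on
$\theta$ in a way with no convenient closed form. The cap input channel is
standardized by the moments of the training caps $1..10$.

Training runs $4\times10^5$ steps at full scale (learning rate
$3\times10^{-3} \to 3\times10^{-5}$, epsilon $0.5 \to 0.05$,
$\gamma = 0.9$); the test suite and acceptance script use $10^5$ steps,
which is already past the point where the low- and high-cap strategies
stabilize in our runs. Post-training behavior is read out from a greedy
500-step rollout with a 100-step burn-in, classified against the periodic
room templates (periods 1, 2, 3, 12, 14, checked in increasing order;
anything else is "other"). The "addiction" variant sets caps $(1,1,1,10)$;
the discount factor then controls how long the agent's excursions away
from the high-cap room last, summarized by `consumption_intervals()`.

The motivation-blinded control zeroes the network's motivation *input*
while the true drives keep driving rewards. Blinded agents reliably settle
on two-room binging (the only strategy whose next reward is predictable
one step ahead without drive information), which is what makes the
motivated-vs-blinded comparison at high caps informative about temporal
credit assignment.

## The transport network

Ten cities are drawn from the standard normal distribution in the plane and
connected by the edges of their Delaunay triangulation, with Euclidean
lengths. No installed package provides a Delaunay triangulation, so the
package carries a small Bowyer–Watson implementation; for Euclidean
weights a Delaunay edge is itself a shortest path (triangle inequality), a
property the tests exploit. All-pairs shortest distances come from igraph.

Each episode starts at a uniform random city with three distinct target
cities (excluded from coinciding with the start, so "3 cities to be
visited" is unambiguous); each target's binary drive is on. Entering a city
with its drive on pays $+5$ and clears it; every move costs its road
length; the episode ends when all drives are clear. The episode return is
therefore $15 - L$ with $L$ the traveled length, so maximizing return is
exactly minimizing length. The reference solution (`shortest_tour()`)
minimizes over the $3!$ target orderings of chained shortest paths, with
ties broken lexicographically, and is verified against exhaustive route
enumeration on small worlds.

The agent is a 20–200–10 network, leaky ReLU ($\alpha = 0.2$) throughout,
trained for $10^5$ episodes (softmax $\beta = 0.5$, $\gamma = 0.9$,
learning rate $10^{-2} \to 10^{-4}$); non-adjacent cities are masked at
action selection and in the TD target. Evaluation uses $\beta = 10$ on 100
fresh test sets against the shortest-tour oracle (equality within $10^{-9}$
relative; both lengths are sums over the same edge table). Evaluation
episodes are capped at 200 steps; an uncompleted episode counts as
non-optimal. Two properties of this benchmark are worth knowing when
reading results: near-greedy softmax still samples, so a handful of
episodes per hundred take one excess edge even under a correct Q-function;
and the fraction of exactly-optimal routes varies noticeably with the
sampled world's geometry (worlds with near-tied tours are harder), while
the mean percent excess is much more stable across worlds.

## The manager–agent hierarchy

The hierarchy replaces the agent's true drive vector with an estimate
maintained by a second, higher-level Q-network. The manager observes the
agent's position (the city just entered) and the current estimate, and has
11 actions: zero any one of the 10 components, or do nothing. It acts once
before each agent step; the agent then acts on the edited estimate. Because
the manager can only clear components, the estimate is binary and
non-increasing within an episode — an invariant the tests check. With an
oracle manager (true dynamics), the hierarchy consumes the same RNG draws
as the flat agent and is bit-identical to it; the shared rollout harness
makes this an exact, not approximate, statement.

The manager network is 20–200–200–200–11 (leaky ReLU, $\alpha = 0.2$),
epsilon-greedy ($\epsilon = 0.1$), $\gamma = 0.9$. Two reward schedules:

* **Supervised** ($+2 / -2$, softened to $-1$ for a wrong *do nothing*):
  the manager replays prerecorded episodes of the trained agent under the
  true dynamics and is scored on whether its action reproduces the recorded
  drive transition. The schedule is a proper scoring rule — enumerating all
  11 actions shows the expected-reward maximizer is the true transition —
  so a converged manager is an accurate dynamics model. Recording uses the
  agent's training policy ($\beta = 0.5$) for broad state coverage.
  Learning rate $10^{-3} \to 10^{-6}$.
* **Unsupervised** ($+5$ on a positive agent reward, else $-2$, softened to
  $-1$ after *do nothing*; the asymmetry compensates for positive steps
  being rarer): the manager learns in closed loop from the *sign* of the
  agent's reward only. Episodes are capped at 50 manager steps;
  semi-gradients are accumulated over minibatches of 50 steps and applied
  once, averaging over diverse exploratory behavior. The learning rate
  anneals $10^{-2} \to 10^{-5}$ and is clipped from above at $10^{-3}$
  (the clip binds early in training, when the annealed value is larger).
  The closed-loop agent runs at its evaluation temperature $\beta = 10$.

Full-scale manager training is $2\times10^5$ episodes, and the
supervised manager genuinely needs it: on worlds with a high-traffic hub
city, transitions at the hub are dominated many-to-one by pass-through
visits where "do nothing" is correct, and the rarer "zero the hub" rule
is the last thing the network learns — at a quarter of the episodes the
held-out transition accuracy can stall near 0.97, and because a single
missed edit strands an evaluation episode, mean route excess explodes
even at that accuracy. At full length the accuracy reaches 1 and the
closed-loop route quality matches the flat agent's (in our runs slightly
better, since the learned dynamics model never mis-edits the estimate
while occasionally smoothing over the agent's own softmax slips). The
shipped checks therefore train the supervised manager at full length and
the unsupervised one at one quarter.

**A known limitation: the unsupervised manager under-performs.** The
sign-only reward gives the manager a much weaker learning signal than the
supervised scoring: the action value of the correct edit ("zero the city
just entered") exceeds "do nothing" only through a delayed, bootstrapped
difference of a few tenths, versus an immediate +2/-2 contrast in the
supervised case. In our experiments — spanning per-step, minibatch-sum
and minibatch-mean updates, closed-loop agent temperatures from 0.5 to
10, and episode counts up to the full $2\times10^5$ — the unsupervised
manager learns the correct ranking at typical states but retains a
residual per-decision error rate of order 10%. A single missed edit
leaves a stale estimate component (the agent keeps circling a consumed
city) and a single spurious edit deletes an unvisited target (the agent
never goes), so errors compound to roughly half of evaluation episodes
failing to terminate within the step cap, and the mean excess over the
shortest tour stays two orders of magnitude above the supervised
hierarchy's. The shipped implementation and checks report this outcome
as measured rather than masking it; closing the gap (e.g., with double
Q-learning to reduce maximization bias, or reward shaping) is left
open.

## The Pavlovian conditioning network

Trials are 20 steps: a cue (conditioned stimulus) on steps 6–10, the
subjective outcome (unconditioned stimulus, numerically equal to the cue:
$\pm1$, $\pm0.5$, or 0) on steps 14–18, and a constant motivation input
equal to the block sign ($+1$ reward block, $-1$ punishment block). The two
zero-magnitude trial types have identical cue and outcome traces and differ
*only* in motivation.

The value network is recurrent: 40 sigmoid units, $h_t = \sigma(W_{in} x_t
+ W_{rec} h_{t-1})$ with $h_0 = 0$ and a linear readout $v_t = w_{out}
h_t$; no bias terms (the constant motivation input plays that role through
the input weights). $W_{in}$ is Xavier-initialized and *frozen*; $W_{rec}$
and $w_{out}$ start uniform on $\pm 10^{-5}$ and are trained by TD(0):
$\delta_t = r_t + \gamma v_{t+1} - v_t$ (with $v_{21} := 0$), each error
held constant (semi-gradient) and credited backward through the trial's
stored activations (backpropagation through time), averaged over batches
of 20 uniformly sampled trials. Full within-trial credit is the default
for a demonstrated reason: the task *requires* the recurrent weights to
bridge the cue (steps 6–10) to the outcome (steps 14–18) and to clock the
trial from its zero initial state, and with credit truncated to a single
step the recurrent matrix never escapes its $10^{-5}$-scale
initialization — even a full-length run stays at a value function of the
current input symbol only. A `truncate` argument restores shorter credit
windows for comparison. Convergence has a characteristic two-phase shape:
a long plateau while the recurrent weight norm grows, then a rapid descent
toward the fixed point once the dynamics become slow enough to carry
memory; the learning-rate schedule must still be high when the escape
happens, which is why scaled runs keep the endpoint ratio but need on the
order of $10^5$ batches. The value convention includes the current step's
reward in $v_t$; this is the convention under which the recursive target
and the exact discounted sum `v_star()` agree, and it is isolated behind
that one function. The full-scale run is $3\times10^5$ batches (learning rate
$10^{-2} \to 10^{-4}$); the shipped checks use $10^5$.

**An observability floor on the value error.** Before the cue (steps 1–5),
all trials of a block are input-identical, so any deterministic value
function must output the block-average value there; the reachable TD fixed
point equals $V^*$ from the cue onward but averages the three magnitudes
pre-cue. Computing that fixed point exactly gives a mean squared error of
about 0.072 against $V^*$ over the six trial types — no training schedule
can do better on this task as specified. The tests therefore check
convergence *toward the aliased fixed point* (and the stricter
sub-0.01 claim, kept for completeness, documents this limit by failing).
What the trained network does recover is the full structure that motivation
makes available: a positive baseline expectation in reward blocks, negative
in punishment blocks, magnitude-resolved values from the cue onward, and —
for the motivation-blinded control — *exactly* identical value traces for
the two zero-magnitude trial types, since its inputs coincide.

## Population analysis of model units

The unit-level pipeline mirrors what one would do with recorded neurons:
concatenate each unit's activity traces in the strong-reward and
strong-punishment conditions, z-score per unit, take the first three
principal components across the population, and cluster hierarchically
(Euclidean distance, complete linkage). The default cut is three clusters
— positively tuned, negatively tuned, and mixed; the cut level is a
parameter because recorded populations have been described with four
types. z-scoring is across the concatenated conditions (per-condition
z-scoring would erase exactly the baseline shift between blocks that the
analysis is after). Constant-rate units are excluded with a warning.

The two largest clusters should show opposite-signed differences between
the conditions (positive- and negative-valence populations). The
connectivity summary then averages recurrent weights within each cluster
(diagonal excluded) and between clusters: a push-pull circuit —
within-cluster excitation, between-cluster inhibition, the classic wiring
for persistent activity maintained by mutual disinhibition — shows
`mean_within > 0 > mean_between`. "Postsynaptic weights" are read as each
unit's *outgoing* recurrent weight vector (with `w_rec[i, j]` the weight
from unit $j$ onto unit $i$, unit $j$'s outgoing vector is column $j$); the
incoming alternative is a switch. The t-SNE embedding of the
weight-correlation structure is visualization-only and deliberately
excluded from quantitative assertions; the package includes a compact exact
t-SNE since none is available in the environment.

## What the generators do and do not emulate

All inputs are generated internally: the grid world and its drive dynamics,
random transport worlds, trial tensors. The generator defaults *are* the
study conditions (network sizes, schedules, caps, reward constants, trial
windows). What passing tests show is that the algorithms recover the
analytic optima and population structure under these synthetic conditions;
they do not show anything about recorded neural data, licking behavior,
inter-trial dynamics, or block-transition kinetics, none of which are
modeled. The recorded-neuron analyses that motivated the pipeline are out
of scope (those data are available only on request), so the clustering is
exercised on model units and on constructed synthetic populations whose
ground truth is known.

## Numerical choices and degenerate inputs

* Argmax ties break to the lowest index; equal-length tours break
  lexicographically on the city sequence — both for reproducibility.
* Delaunay degeneracies (collinear triples, cocircular quadruples) are
  handled by resampling the world and by the insertion-order determinism of
  the incremental construction.
* Fraction-optimal equality uses $10^{-9}$ relative tolerance; both sides
  are sums over the same edge-length table, so this is a pure guard against
  float accumulation.
* RNN training raises an informative error if weights go non-finite
  (divergence), rather than returning garbage.
* All randomness flows through R's global RNG; every top-level run is
  reproducible from the recorded seed, and `run_experiment()` writes the
  resolved configuration next to its artifacts.

## Problem sizes used by the shipped checks

The test suite trains the grid-world agents for $10^5$ steps ($4\times
10^5$ where the low-cap and high-discount claims need the full schedule),
the transport agents for $10^5$ episodes, the supervised manager for
$2\times10^5$ episodes, the unsupervised manager for $5\times10^4$, and
the conditioning RNN on a $2\times10^5$-batch prefix of the reference
schedule; the acceptance script uses the same sizes. These are the
package's own scaled defaults for its checks; the full-scale schedules
remain the documented defaults of the training functions themselves.

## Known limitations

* The exact phase boundaries of the cap sweep (which strategy wins at
  intermediate caps) depend on stochastic training and are reported, not
  asserted. Low-cap (theta = 1) runs converge to the optimal two-room
  binge only in a fraction of seeds even at full length; others settle on
  the one-room strategy.
* The fraction of exactly-optimal transport routes depends on the sampled
  world's geometry; expect meaningful spread across world seeds even with
  a well-trained agent.
* The conditioning network's value error is bounded below by the pre-cue
  observability floor described above.
* Hierarchies deeper than two levels and actor–critic extensions are out
  of scope.
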