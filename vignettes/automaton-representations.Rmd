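---
title: "Automaton representations of repeated-game strategies: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automaton representations of repeated-game strategies: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(autostrat)
```

## The setting

`autostrat` analyses deterministic strategies of iterated n-person social
dilemmas. In each round every player chooses to cooperate (`c`) or defect
(`d`); payoffs follow the linear public-goods rule: a cooperator contributes
one unit, contributions are multiplied by $\rho$ (with $1 < \rho < n$) and
shared equally, and a defector keeps the unit. With $n_c$ cooperators among
all $n$ players, an action $a$ earns

$$\pi(a) = [a = d] + \rho\, n_c / n .$$

The two-player case is the iterated prisoner's dilemma. The package does not
parameterise the PD by separate (T, R, P, S) constants: every comparison the
package makes rests on the identity
$\pi_j - \pi_i = [a_j = d] - [a_i = d]$, which the linear rule satisfies
exactly for every action profile and every $\rho$, so a single payoff model
covers both games with no arbitrary constants. This identity is also what
makes the defensibility check below exact and $\rho$-free.

A **memory-m strategy** maps the *history profile* — the last $m$ actions of
all $n$ players — to the next action. Profiles are labelled by the integer
whose binary digits are the focal player's actions (oldest first, most
significant), then each co-player's, with `c` = 0 and `d` = 1. The
convention is pinned by its fixed points: `cdcc` is 4, `ddcc` is 12,
`ccd ccd ccc` is 72. Each player views the group in cyclic order starting
with itself, so one shared history gives each player its own profile code.

## From tables to automata

A memory-m table is also an automaton whose $2^{nm}$ states are the profiles
themselves. Each node of this *naive transition graph* carries $2^{n-1}$
outgoing links — one per co-player action tuple — because the focal action
is fixed by the table (`build_transition_graph()`, `"coplayer"` alphabet).
With the `"full"` alphabet the focal player's realized action is part of the
input ($2^n$ links), which also covers the player's own misimplemented
actions.

`minimize()` reduces the graph by Moore-style partition refinement: start
from the two-block partition by prescribed action and, each round, split
simultaneously every block containing two states whose successors lie in
different blocks for some input; stop at the fixed point. The result is the
Myhill–Nerode partition: the coarsest action-preserving bisimulation. Two
implementation notes matter:

* **Simultaneous splitting.** All blocks are split per round against the
  previous round's partition, so the result is independent of processing
  order (the `order` argument exists purely so the test suite can verify
  this with shuffled node orders). A Hopcroft-style worklist would be faster
  asymptotically but is unnecessary at these sizes.
* **All nodes are minimized**, including profiles unreachable from full
  cooperation; a strategy's behaviour after *any* history is part of its
  identity (defensibility quantifies over adversarial histories), and the
  result stays start-state independent. States are labelled by the minimum
  profile code of their block, and the block containing code 0 (full
  cooperation) is the designated start used for traces and DOT layout only.

The `"coplayer"` minimization deliberately discards how the strategy reacts
to the focal player's own errors; it is the readable picture. The `"full"`
minimization (`minimize_full()`) loses nothing: `reconstruct_table()` feeds
every length-$m$ action word into it from every state and recovers the
original table exactly, erroring if the automaton is not memory-m realizable
(the action after the word must not depend on the start state). Contrite
tit-for-tat is the stock example of a non-realizable automaton: its standing
bookkeeping remembers unbounded history, and `reconstruct_table()` refuses
it for every finite $m$.

Equivalence checking (`are_equivalent()`) is the standard product
construction over reachable state pairs; when the automaton carries its
blocks the check starts from every (profile, block) pair, making it
start-state independent.

## Implementation errors and exact chains

With probability $e$ per player per round, the prescribed action is
replaced by its opposite; all players observe realized actions correctly
(implementation error, not perception error). Errors are independent across
players, so a simultaneous two-player error has probability $e^2$.
`joint_system()` builds the joint Markov chain — over the shared history
profile when all players are history strategies, or over tuples of internal
states (closed under all realized action profiles) when all players are
full-alphabet automata — and `stationary_distribution()` solves
$\pi P = \pi$ by a dense linear solve up to 4096 states (power iteration
above), with residual tolerance $10^{-10}$. Long-run payoffs are stationary
expectations of the one-round payoffs under the error kernel.

`trace_recovery()` runs the deterministic $e = 0$ orbit with errors injected
at chosen rounds and players. A deterministic orbit on a finite joint space
either returns to full cooperation before revisiting any joint state or
never does, so the recovery verdict uses exact cycle detection rather than a
round bound.

## The three criteria

A strategy is **successful** when all three hold; **partially successful**
when defensible, distinguishable and partially efficient.

**Defensibility** — the focal player's long-run payoff is never below any
co-player's, whatever the co-players do. By the payoff-difference identity
this reduces to a graph property: for each co-player $j$, the co-player-input
transition graph over *all* states must contain no cycle with positive total
weight $[a_j = d] - [a_\mathrm{focal} = d]$. `check_defensibility()` runs a
max-plus Bellman–Ford relaxation from a virtual source attached to every
node; improvement after $|V|$ rounds certifies a positive cycle, and walking
the parent pointers returns the exploiting cycle as a witness. The test
suite cross-checks the verdict two independent ways: exhaustive simple-cycle
enumeration, and round-robin play against all $2^{16}$ memory-two adversary
tables from all initial histories.

**Efficiency** — a homogeneous group reaches full cooperation with
probability one as $e \to 0^+$. Decided numerically on the error grid
$e \in \{10^{-2}, 10^{-3}, 10^{-4}\}$ (defaults; overridable): the
stationary mass $p(e)$ on the full-cooperation state must have $1 - p(e)$
shrinking at least linearly in $e$, tested as a ratio between successive
grid points within a factor of two of the grid ratio. *Partial efficiency*
means $p(e)$ stabilises at a limit $q$ strictly inside $(0, 1)$ (tit-for-tat
has $q = 1/4$: its recurrent classes `cc`, `{cd, dc}`, `dd` are linked only
by single errors and carry masses 1/4, 1/2, 1/4). When neither pattern
fits and the limit is not zero, the verdict is flagged inconclusive rather
than silently false. The grid decision rule is a numerical surrogate for a
perturbation analysis of the $e \to 0$ chain; it is exact in order of $e$
for every strategy whose recurrent structure is resolved by $e = 10^{-4}$,
which covers all spaces scanned here.

**Distinguishability** — against unconditional cooperators the strategy
earns strictly more than they do in the small-error limit. The payoff gap
from the exact stationary chain is $O(1)$ when present and $O(e)$ when
absent, so a fixed threshold of $10^{-3}$ at the smallest grid rate
separates the two cases; the gap must also be non-decreasing as $e$ shrinks,
up to a 10% relative slack that absorbs the $O(e)$ corrections visible at
$e = 10^{-2}$.

## Error recovery

`verify_error_recovery()` enumerates every implementation-error pattern of
at most one or two bits from full cooperation — a single error; the same
player twice in consecutive rounds; two players in consecutive rounds; two
players simultaneously — and requires the deterministic orbit to return to
full cooperation in each case. Two-bit tolerance is what separates full from
partial efficiency in the three-person game: a two-bit pattern that strands
the group in a class escapable only by further coincident errors leaves an
$O(1)$ stationary share outside cooperation.

## The synthetic PS2 and FUSS fixtures

The published 6-state partially-successful (PS2) and 10-state fully
successful (FUSS) automata for the three-person game are derived from 64-
and 512-entry action tables that are external artifacts; this package does
not ship them. `ps2_automaton()` and `fuss_automaton()` are **synthetic
reconstructions**: full-alphabet automata over the published state sets
(`0, 1, 4, 5, 16, 18` and `0, 1, 8, 9, 64, 65, 66, 67, 72, 76`) that
reproduce every printed transition and joint recovery path exactly — the
single-error path through $(8, 64, 1)$, the repeated-error path through
$(76, 64, 67)$, the consecutive- and simultaneous-error paths through
$(66, 0, 0)$ and $(64, 1, 8)$, and the despair detour through
$(9, 72, 65)$ — while transitions the text leaves unstated follow the
states' situational meaning (trust, distrust of a named co-player, despair,
apology, provocation) and were chosen once, then validated against the
criteria.

Two structural facts did the real design work:

* **Despair may only soften toward provocation.** A despair state that
  moves to a cooperative state when merely one co-player cooperates creates
  a positive payoff cycle (cooperate-while-they-defect), destroying
  defensibility. Exit from joint despair therefore runs through the
  defecting provocation state, exactly as the published recovery paths do.
* **Order of error coincidences decides the efficiency class.** In the FUSS
  fixture, entering joint despair takes at least three coincident errors
  while two suffice to leave it, so its stationary share vanishes as
  $e \to 0$ and efficiency is full. The PS2 architecture, lacking the
  transient apology-together states (`72`/`65`), falls into joint despair
  after a simultaneous two-bit error and also needs two coincident errors
  to leave — entry and exit at the same order, hence a limit $q$ strictly
  between 0 and 1 (the fixture's $q$ is 1/3; the source text prints no
  value, and any interior limit is consistent with partial efficiency).

These fixtures are stand-ins with the published interface and properties,
not the published strategies; analyses that depend on unprinted transition
details should not treat them as ground truth.

## Scan sizes and other fixed choices

* The built-in library covers the named two-player repertoire; tit-for-two-
  tats and the all-or-none strategies are stored as their memory-two/three
  tables and verified against their definitional sentences and minimized
  state counts (3 each). Contrite TFT uses the standard standing rule:
  cooperation always restores good standing; defection earns bad standing
  unless prescribed (own standing good, opponent's bad). The exact
  transition labelling of its published 4-state picture is not fully printed
  anywhere, so the standing rule is the package's normative choice.
* Strategy-space scans run at desk scale: the full two-player memory-one
  (16 tables) and memory-two (65,536 tables) spaces and the three-person
  memory-one space (256 tables). The pruned scan is a depth-first search
  assigning profile codes in ascending order with incremental positive-cycle
  detection; pruned and unpruned scans are verified to return identical
  survivor sets. The three-person memory-two space ($> 10^{12}$ tables) is
  cluster work and out of scope.
* Property suites use 200 seeded random strategies for bisimulation-
  equivalence and reconstruction round-trips, smaller seeded samples for
  state-count comparisons, idempotence and minimality, and ten shuffles per
  order-independence check.
* Monte-Carlo cross-checks inflate the binomial standard error by
  $\sqrt{1 + 1/e}$, the dwell-time bound on the chain's integrated
  autocorrelation.

## A worked example

```{r example}
taa <- builtin_strategy("TFT-ATFT")
minimize(build_transition_graph(taa))

sys <- joint_system(list(taa, taa), e = 0)
trace_recovery(sys, list(c(1, 1)))

classify(taa)
```

## Known limitations

* Only deterministic strategies: mixed or zero-determinant strategy algebra
  is out of scope, as are perception errors and evolutionary population
  dynamics.
* The efficiency and distinguishability verdicts are numerical, on an error
  grid; a strategy whose recurrent structure only resolves below
  $e = 10^{-4}$ would need a finer grid (both the grid and thresholds are
  arguments).
* The joint chain for automaton players requires full-alphabet automata; a
  co-player-alphabet automaton does not define behaviour after the owner's
  own error and is rejected.
* The synthetic PS2/FUSS fixtures match the published behaviour only where
  the text constrains it (see above).
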