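# autostrat

Finite-state analysis of deterministic strategies for iterated social
dilemmas — the two-player prisoner's dilemma and its n-person public-goods
generalisation — for researchers in evolutionary game theory and direct
reciprocity who work with history-based action tables and want to see, test
and search the automata behind them.

A memory-m strategy is a table prescribing `c` or `d` for each of the
2^(nm) *history profiles* (every player's last m actions, labelled by a
binary code with the focal player's bits most significant: `cdcc` ↦ 4,
`ddcc` ↦ 12). Such tables grow exponentially and hide their own logic; the
package converts them into minimal deterministic finite automata and decides
the three criteria that define a *successful* strategy under implementation
error (each round every player misimplements its action independently with
probability e):

* **Efficiency** — a homogeneous group reaches full cooperation with
  probability → 1 as e → 0⁺ (*partial* efficiency: the limit is strictly
  between 0 and 1);
* **Defensibility** — the focal player's long-run payoff is never below any
  co-player's, against arbitrary co-player strategies and initial
  histories — equivalent, by the exact payoff-difference identity
  π_j − π_i = [a_j = d] − [a_i = d] of the linear public-goods payoff
  π(a) = [a = d] + ρ·n_c/n, to the absence of positive-weight cycles in the
  strategy's transition graph, found here by max-plus Bellman–Ford;
* **Distinguishability** — against unconditional cooperators the strategy
  earns strictly more than they do.

The toolkit: Moore partition-refinement DFA minimization over all history
profiles, with the co-player input alphabet (the readable, error-free
picture) or the full alphabet (lossless — `reconstruct_table()` recovers the
original table exactly); exact joint Markov chains, stationary distributions
and long-run payoffs under error; deterministic recovery traces with
injected one- and two-bit errors; a built-in library (TFT, TF2T, WSLS, GRIM,
AON2, TFT-ATFT, contrite TFT as a standing automaton, …); synthetic
transcriptions of the published 6-state partially-successful (PS2) and
10-state fully-successful (FUSS) automata of the three-person game; strategy
enumeration with defensibility pruning; plain-text `.str` files and
Graphviz DOT export; and a command-line front end
(`inst/cli/autostrat.R`: `minimize`, `check`, `classify`, `simulate`,
`trace`, `enumerate`, `export-dot`, `gen-fixture`).

## A worked example

```r
library(autostrat)
taa <- builtin_strategy("TFT-ATFT")   # the 16-entry memory-two table
minimize(build_transition_graph(taa))
#> <automaton TFT-ATFT> n=2, coplayer alphabet, 4 states
#>   states: 0(c) 1(d) 4(d) 5(c)
```

The 16-node history graph collapses to four states labelled by the smallest
profile code they contain: `0`/`1` are the tit-for-tat core, `4` (the block
{`cdcc`, `ddcc`}) is entered by the player's own erroneous defection, and
`5` accepts the co-player's punishment. After one error the pair walks back
to mutual cooperation in four rounds:

```r
trace_recovery(joint_system(list(taa, taa), e = 0), list(c(1, 1)))
#>   round state realized
#> 1     1  cccc       dc
#> 2     2  cdcc       dd
#> 3     3  ddcd       cd
#> 4     4  dcdd       cc
#> 5     5  ccdc       cc

classify(taa)
#> <criteria report> successful
#>   defensible:       TRUE
#>   efficient:        TRUE (p(e) -> 0.9989)
#>   distinguishable:  TRUE (payoff gap 0.3333)
```

`p(e)` is the stationary mass on full cooperation at the smallest grid
error rate (e = 10⁻⁴); the payoff gap is the focal player's stationary
advantage over unconditional cooperators. The same machinery runs the
three-person fixtures — here the simultaneous two-error recovery of the
FUSS automaton, through despair (`9`), joint apology (`72`, `65`) and
provocation (`66`):

```r
fuss <- fuss_automaton()
trace_recovery(joint_system(rep(list(fuss), 3), e = 0),
               list(c(1, 2), c(1, 3)))
#>   round     state realized
#> 1     1   (0,0,0)      cdd
#> 2     2 (9,72,65)      dcc
#> 3     3  (66,0,0)      dcc
#> 4     4  (64,1,8)      cdd
verify_error_recovery(fuss, max_error_bits = 2)$ok
#> [1] TRUE
```

See `vignettes/automaton-representations.Rmd` for the models, decision
rules and design choices, including how the synthetic PS2/FUSS fixtures
were reconstructed and what they do and do not guarantee.

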