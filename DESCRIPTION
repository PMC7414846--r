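Package: autostrat
Title: Automaton Representations and Success Criteria for Repeated-Game Strategies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing deterministic memory-m strategies of iterated
    n-person social dilemmas (the prisoner's dilemma and its public-goods
    generalisation). Converts history-based action tables into minimal
    finite-state automata by partition-refinement DFA minimisation, with or
    without error-caused transitions; reconstructs action tables from
    full-alphabet automata; computes exact joint Markov chains, stationary
    distributions and payoffs under implementation error; decides the three
    criteria of successful strategies (efficiency, defensibility,
    distinguishability); verifies recovery from one- and two-bit implementation
    errors; and enumerates small strategy spaces with defensibility-based
    pruning. Ships a library of named strategies (TFT, TF2T, WSLS, AON2,
    TFT-ATFT, contrite TFT, ...) and plain-text strategy file and Graphviz DOT
    interfaces.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
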