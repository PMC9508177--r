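Package: stratcomplex
Title: Strategic Complexity and Performance in Repeated Games Against Automata
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models strategic decision-making in a stochastic game where a
    player faces finite-automaton opponents (Always Defect, Grim Trigger,
    Tit-for-Tat) across two stage games (Prisoner's Dilemma, Battle of the
    Sexes). Provides the reduced 26-state environment space, action-conditional
    transition maps, value iteration yielding the optimal policy and a
    per-trial loss function, a dominance-based index of strategic complexity,
    simulators for experiment-like trial sequences and synthetic subject
    cohorts, and regression tools (cluster-robust and mixed-effects) linking
    loss and reaction time to complexity and cognitive-ability group.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    sandwich,
    lmtest,
    lme4,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
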