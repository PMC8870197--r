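Package: ganglia
Title: Rate-Coded Basal Ganglia Network Simulation of Probabilistic
    Reinforcement Learning Tasks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates action selection and dopamine-modulated learning in a
    coarse, rate-coded network model of the basal ganglia.  Each nucleus
    (striatal Go/NoGo populations, external and internal globus pallidus,
    thalamus, premotor cortex) is a small set of static rate units; choices
    arise from disinhibition of the thalamo-cortical route, and synaptic
    weights adapt from the activity difference between a decision phase under
    tonic dopamine and a feedback phase under a phasic dopamine burst or dip.
    Ships generative definitions of the probabilistic selection, probabilistic
    reversal learning and instructed probabilistic selection tasks, a seeded
    replicate-experiment harness with behavioral metrics (switch latency,
    instruction adherence, punishment counts), and CSV/JSON/YAML readers and
    writers with a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
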