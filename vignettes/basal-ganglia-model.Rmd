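---
title: "A rate-coded basal ganglia model for probabilistic selection tasks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A rate-coded basal ganglia model for probabilistic selection tasks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ganglia)
```

## The model

`ganglia` simulates action selection and reinforcement learning in a
deliberately coarse model of the basal ganglia.  Every nucleus is reduced
to one static rate unit per represented stimulus; a unit's value is the
average firing rate of the population it stands for, on a `[0, 1]` scale.
For a task with $N$ stimuli the network has:

* an **input** layer of $N$ binary units (1 = stimulus on screen);
* a **striatum** of $2N$ units: $N$ *Go* units (the D1, direct pathway)
  and $N$ *NoGo* units (the D2, indirect pathway);
* an **SNc** dopamine node emitting one of three levels: dip $0$,
  tonic $0.5$, burst $1$;
* **GPe**, **GPi** and **thalamus** layers of $N$ units each;
* a **premotor cortex (PMC)** of $N$ units, whose maximal unit defines the
  choice, and a one-hot **output** layer;
* an optional **PFC/HC** node that injects an instruction bias.

All units share the activation
$$\varphi(x) = \exp\{-a\,(1 - x)^2\}, \qquad a = 8,$$
a sharp sigmoid-like curve on $x \le 1$ with its maximum
$\varphi(1) = 1$; it is symmetric about $x = 1$, so drive beyond the peak
*reduces* activity again.  The layer equations, per stimulus $k$:

$$y^{stria}_k = \varphi\!\Big(w^{snc}_k\,y^{snc}_k
  + \sum_i w^{in\_stria}_{i,k}\,y^{in}_i + w^{pfc\_stria}\,y^{pfc}\Big),$$

with the fixed dopaminergic sign $w^{snc}_k = +1$ for Go and $-1$ for
NoGo units (a burst excites the direct and suppresses the indirect
pathway; a dip does the opposite), and the PFC/HC term present only on
the instructed Go unit;

$$y^{gpe}_k = 1 - y^{striaNoGo}_k, \qquad
  y^{gpi}_k = \max\{1 - \tfrac12 y^{striaGo}_k - \tfrac12 y^{gpe}_k,\, 0\},
  \qquad y^{thal}_k = 1 - y^{gpi}_k.$$

The thalamic relay is driven by the GPi (the tonically active GPi gates
the thalamus; a silenced GPi unit disinhibits its thalamic partner).  The
PMC averages its thalamic gate with its direct sensory drive,

$$x^{pmc}_k = \tfrac12 y^{thal}_k
  + \tfrac12 \sum_i w^{in\_pmc}_{i,k}\,y^{in}_i + w^{pfc\_pmc}\,y^{pfc},$$

rescaled by $\max_k x^{pmc}_k$ only when that maximum exceeds 1 (so a
sub-peak preactivation vector is never perturbed), and
$y^{pmc}_k = \varphi(x^{pmc}_k)$.  The network's choice is the presented
stimulus with the largest PMC activity; ties break deterministically
toward the lowest stimulus index (they have probability ~0 under random
initialization, and a deterministic rule keeps sessions exactly
reproducible).  Stimuli not on screen are masked from the decision: in
multi-pair sessions a choice between absent stimuli would be meaningless.

## Two-phase learning

Each trial has two phases.  In the **minus phase** the SNc is tonic
everywhere, the cascade above runs once, and the choice is read out.
Feedback is then sampled: the chosen stimulus $S$ rewards with its
contingency $p_S$ and punishes otherwise.  In the **plus phase** the same
cascade runs again, with a single change: the Go and NoGo units of the
*chosen* stimulus see the phasic dopamine level (burst $1$ after a
reward, dip $0$ after a punishment) while all other striatal units stay
tonic.  The PFC/HC drive, when present, is identical in both phases.

Learning is driven by the per-unit activity difference
$\Delta y_k = y_k(\text{plus}) - y_k(\text{minus})$ in the striatum and
the PMC.  Because only the chosen stimulus' striatal units change their
drive between phases, their $\Delta$ is the only non-zero striatal
signal — credit assignment is anatomical, not algorithmic.  Weights
update as

$$w_{i,k} \leftarrow \max\{w_{i,k} + \alpha\,\Delta y_k,\ 0\}
  \quad\text{for presented inputs } i,$$

with $\alpha^{stria} = \alpha^{pmc} = 0.1$, followed once per trial by
multiplicative forgetting $w \leftarrow \beta w$ with $\beta = 0.98$
(memory half-life $\ln 2 / \ln(1/\beta) \approx 34$ trials).  Gating the
update on presynaptic activity ($y^{in}_i = 1$) is the standard delta
rule with its presynaptic term and keeps absent stimuli's associations
untouched; the ungated variant, which updates every row by the same
$\Delta$, is available via `bg_params(presynaptic_gating = FALSE)` for
sensitivity analysis.  Weights are nonnegative throughout: initialization
draws i.i.d. Gaussian values (mean $0.05$, variance $0.01$) and clips
negatives to zero — the expected initial weight is therefore the censored
normal mean $\mu\Phi(\mu/\sigma) + \sigma\phi(\mu/\sigma) \approx 0.0698$,
not $0.05$ — and the update rule clips at zero as well.

## Parameters

| parameter | default | units / meaning |
|---|---|---|
| `a` | 8 | activation sharpness (dimensionless) |
| `lr_striatum`, `lr_pmc` | 0.1 | weight change per unit activity difference |
| `forgetting` | 0.98 | per-trial multiplicative decay, in (0, 1] |
| `w_pfc_stria` | 0.3 | instruction drive onto the instructed Go unit |
| `w_pfc_pmc` | 0.3 | instruction drive onto the instructed PMC unit |
| `snc_dip`, `snc_tonic`, `snc_burst` | 0, 0.5, 1 | dopamine levels |
| `init_mean`, `init_var` | 0.05, 0.01 | Gaussian weight initialization |

All are exposed through `bg_params()` and the `model:` section of a run
configuration.  `w_pfc_pmc` deserves a note: the two instruction weights
are stated both as 0.3 (the value said to match human unlearning speed)
and, in one place, as 0.05 for the PMC projection.  The package defaults
to 0.3 for both and accepts either through configuration; the limitations
section below shows why the choice matters less than one would hope.

## The three task protocols

`pst_task()` builds the probabilistic selection task: stimuli appear in
fixed pairs with reward contingencies, by default AB (80 %/20 %),
CD (70 %/30 %), EF (60 %/40 %); the two-stimulus demonstration game is
`pst_task(list(c(0.9, 0.2)), n_trials = 10)`.  Pairs are drawn uniformly
i.i.d. per trial; an optional bounded-gap scheduler
(`pair_sampling = "bounded_gap"`) forces the most overdue pair whenever
one has been absent for `max_gap` (default 7) trials, emulating the
block-balanced schedules of human protocols.  Which side of the screen a
stimulus lands on is drawn and recorded but never enters the dynamics:
the input layer codes stimulus identity, not position.

`reversal_task()` plays a single 90 %/20 % pair whose contingencies swap,
unannounced, after every block of 20 trials (the swapped contingencies
first apply at trials 21, 41, 61, 81) for 100 trials.

`instructed_task()` is the 30-trial two-stimulus game with the PFC/HC
active: the instruction (by default pointing at the worse, 20 %-rewarded
stimulus) adds `w_pfc_stria` to the instructed Go unit and `w_pfc_pmc` to
the instructed PMC unit on every trial the stimulus is shown, in both
phases.

Each session consumes one RNG stream in a fixed, documented order —
weight initialization, then per trial: pair draw, side draw, feedback
draw — so a `(task, params, seed)` triple reproduces every number in the
trace, and adding new metrics can never perturb trajectories.

## Behavioral metrics

`compute_metrics()` operationalizes the standard readouts:

* **Sustained-switch latency** after a reversal whose last pre-reversal
  trial is $r$: the smallest $t \ge 1$ such that the choice at trial
  $r + t$ is the newly better stimulus *and* stays the strict-majority
  choice over the following $\min(5, \text{trials left})$ trials.  The
  search is confined to the block played under the reversed
  contingencies; a session that never switches there reports `NA`
  (replicate summaries right-censor these at the block length).  The
  5-trial window is a choice this package makes explicit — "changed its
  response" has no standard quantitative definition.
* **Adherence duration**: length of the initial run of trials choosing
  the instructed stimulus.
* **Terminal-preference trial**: the earliest trial choosing the better
  stimulus from which the better stimulus remains a (weak) majority of
  every remaining suffix of the session — the start of the terminal run
  of better-stimulus modal choice.  Sessions that never get there report
  `NA` (censored at `n_trials + 1` in summaries).
* **Punishment counts**, overall and before the terminal preference.

Replicate-level summaries (`summarize_replicates()`, the `replicates` CLI
subcommand, and `scripts/acceptance.R`) use medians and IQRs: switch
latencies have a heavy right tail and a censored mass, for which means
are misleading.

## What the generator emulates — and what it does not

The trial streams are fully synthetic: abstract stimulus indices,
Bernoulli feedback, uniform pair and side draws.  That matches the
information content a human participant receives in these tasks, but none
of the nuisance structure of real experiments — no reaction times, no
perceptual difficulty, no instruction text, no session fatigue, no
block-balanced stimulus schedules (unless the bounded-gap option is on).
Passing tests therefore certify the *model dynamics and harness*, not
fidelity to any human dataset.

## Numerical choices

* Exact ties in the decision break toward the lowest index; exact ties
  in `which.max` of the bounded-gap scheduler likewise.
* The activation rejects non-finite preactivations loudly rather than
  propagating `NaN`s.
* The PMC rescaling divides by the maximum only when it exceeds 1; a
  compliant preactivation vector is returned bit-for-bit unchanged.
* Degenerate configurations are legal where they are meaningful:
  `forgetting = 1` disables decay, zero learning rates give an identity
  learner (used by the test suite as a self-check), `init_var = 0` gives
  a deterministic blank network.
* Trace files serialize floating point at 9 significant digits — enough
  to regenerate the scalar series exactly at double precision for this
  model's dynamic range.
* Replicate experiments in the test suite and the acceptance script use
  200 seeded sessions per condition (10-, 30- and 100-trial sessions),
  which puts the Monte-Carlo error of the reported medians well inside
  the tolerances being checked while keeping a full run in tens of
  seconds on one core.

## Known limitations

The implementation follows the model equations as stated, and two of
their consequences deserve to be called out, because they bound what the
behavioral simulations can reproduce.

**The indirect pathway is nearly silent at baseline.**  A NoGo unit's
preactivation under tonic dopamine is $S - 0.5$, where $S$ is its summed
input weight (about $0.14$ at initialization).  Its activity is then
$\varphi(-0.36) \approx e^{-15}$: effectively zero, and too small for
punishment-driven learning to bootstrap, since the plus-minus difference
under a dip, $\varphi(S) - \varphi(S - 0.5)$, is of order $10^{-3}$ —
less than one trial's forgetting loss.  In practice the NoGo/GPe arm
stays inert and punishment acts only by shrinking Go and PMC weights.

**Dips are weaker than bursts downstream.**  With the NoGo arm silent,
the GPi cannot exceed $0.5$ under a dip, so a punishment can push a
thalamic gate only to $0.5$, while a burst pushes it to $1$.  An
occasionally rewarded wrong choice therefore re-inflates its PMC weights
faster than frequent punishments deflate them.  Two behavioral
consequences, both visible in the acceptance suite, follow:

* In the reversal task roughly half of the seeds never achieve a
  sustained switch within a 20-trial reversed block (the others switch
  within a few trials), so the median latency is dominated by the
  censoring convention rather than by a well-centered distribution.
* In the instructed task the recovery from a misleading instruction is
  unreachable: the instructed Go unit's drive has a floor of
  $0.5 + w^{pfc\_stria} = 0.8$, keeping its thalamic gate high, while
  the non-instructed stimulus — never chosen — has exactly zero learning
  signal and can only decay.  The instructed stimulus' PMC preactivation
  therefore retains a permanent advantage for any nonnegative
  `w_pfc_pmc`, and simulated sessions adhere to the instruction for all
  30 trials.  The corresponding acceptance checks are intentionally left
  failing rather than weakened: they document the gap between these
  equations and the recovery behavior this task family is meant to show.

Alternative readings of the model (a saturating activation, an inverted
dopamine sign for the NoGo drive, unconditional PMC rescaling) repair
parts of this picture but none reproduces the full behavioral pattern,
so the package keeps the equations as stated and reports the
discrepancies honestly.

## A worked session

```{r}
demo <- pst_task(list(c(0.9, 0.2)), n_trials = 10)
session <- run_session(demo, bg_params(), seed = 42)
session
compute_metrics(session)
```

Replicate experiments and file I/O are shown in the README; the
`ganglia` executable exposes the same functionality from a shell.
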