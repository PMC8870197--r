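# ganglia

Rate-coded basal ganglia network simulation of probabilistic
reinforcement learning tasks.

`ganglia` is for computational and clinical neuroscientists who want a
basal ganglia model simple enough to read end-to-end: every nucleus
(striatal Go/NoGo populations, GPe, GPi, thalamus, premotor cortex) is a
handful of static rate units, and the entire learnable state is `3N²`
nonnegative synaptic weights for `N` stimuli.  The package implements the
forward dynamics, the dopamine-modulated two-phase learning rule, the
three standard task protocols the model family is evaluated on
(probabilistic selection, probabilistic reversal learning, instructed
probabilistic selection), and a seeded replicate-experiment harness with
behavioral metrics and file I/O.

## The model in one paragraph

Unit activities live in `[0, 1]` and pass through the activation
φ(x) = exp{−a(1 − x)²} with a = 8.  Per stimulus *k*:

    y_stria[k] = φ( w_snc[k]·y_snc + Σ_i w_in_stria[i,k]·y_in[i] + w_pfc_stria·y_pfc )
    y_gpe[k]   = 1 − y_nogo[k]
    y_gpi[k]   = max(1 − ½·y_go[k] − ½·y_gpe[k], 0)
    y_thal[k]  = 1 − y_gpi[k]
    x_pmc[k]   = ½·y_thal[k] + ½·Σ_i w_in_pmc[i,k]·y_in[i] + w_pfc_pmc·y_pfc

with `w_snc = +1` for Go and `−1` for NoGo units, `x_pmc` rescaled by its
maximum when that exceeds 1, `y_pmc = φ(x_pmc)`, and the choice the
presented stimulus with maximal PMC activity.  Each trial runs a *minus*
(decision) phase under tonic dopamine (0.5) and a *plus* (feedback) phase
in which only the chosen stimulus' striatal units see the phasic level —
a burst (1) after a reward, a dip (0) after a punishment.  Weights update
by the delta rule on the plus−minus activity differences
(α = 0.1, clipped at 0) and decay by a forgetting factor β = 0.98 per
trial.  See the methods vignette
(`vignettes/basal-ganglia-model.Rmd`) for the full account, parameter
table and known limitations.

## A worked example

```r
library(ganglia)

demo <- pst_task(list(c(0.9, 0.2)), n_trials = 10)  # 90%/20% pair
session <- run_session(demo, bg_params(), seed = 42)
session
#> Session of 10 trials (seed 42)
#> probabilistic selection task: 2 stimuli, 10 trials
#>   pair 1: stimulus 1 (p = 0.90) vs stimulus 2 (p = 0.20)
#>   choices : 2 2 1 1 1 2 1 1 1 1
#>   rewarded: 0 0 1 1 0 0 1 1 1 1

compute_metrics(session)
#> Session metrics
#>   accuracy            : 0.700
#>   punishments         : 4
#>   stable preference from trial 3 (2 punishments before)
```

The network starts with random weights, prefers the worse stimulus for
two punished trials, and from trial 3 settles permanently on the better
one: `accuracy` is the fraction of trials choosing the
higher-contingency stimulus, and the "stable preference" line reports
the first trial of the terminal run of better-stimulus choices together
with the punishments received before it.

Replicate experiments fan one task over many seeds:

```r
tab <- summarize_replicates(run_replicates(reversal_task(), seeds = 1:20))
print(tab$summary, digits = 3)
#>                           metric median  q25    q75 n_valid
#> 1                       accuracy  0.565  0.4  0.585      20
#> 2               punishment_count 42.000 38.0 51.000      20
#> ...
#> 7                      latency_1  1.000  1.0  1.500      11
#> 8                      latency_2  1.000  1.0  1.000       9
```

`latency_1 … latency_4` are the sustained-switch latencies after the four
contingency reversals; `n_valid` counts the sessions that switched at all
within the reversed block (see the vignette on why many do not).

Everything is also reachable from a shell through the `exec/ganglia`
script:

```sh
ganglia run --config inst/extdata/pst_demo.yaml --seed 1 --out out/
ganglia replicates --config inst/extdata/reversal.yaml --seeds 1:200 --out out/
ganglia metrics --trace out/ --out out/metrics.csv
ganglia snapshot --config inst/extdata/instructed.yaml --seed 1 \
    --trial 1 --phase minus --out state.json
```

`run` writes `trials.csv`, a long-format `weights.csv` (with a trial-0
row for the initial weights) and `provenance.json`; `snapshot` exports
every unit's activity and the active connections of one phase of one
trial as JSON.

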