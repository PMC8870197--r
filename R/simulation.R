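#' Run one learning trial
#'
#' Executes the full trial cycle: sample the pair and sides, run the minus
#' phase under tonic dopamine, read out the choice, sample probabilistic
#' feedback, run the plus phase with the phasic dopamine level routed to the
#' chosen stimulus' striatal units, compute the plus-minus activity
#' differences, apply the delta-rule update gated by the presented inputs,
#' and finally apply the forgetting factor.  The PFC/HC drive, when the task
#' carries an instruction and the instructed stimulus is on screen, is
#' identical in both phases.
#'
#' @param weights Current [bg_weights].
#' @param params A [bg_params] object.
#' @param task A `bg_task`.
#' @param trial_index Trial number in `1..n_trials`.
#' @param last_seen Optional per-pair last-appearance vector (see
#'   [sample_trial()]).
#' @return An object of class `bg_trial`: the sampled pair and side, the
#'   `chosen` stimulus, `rewarded`, both `bg_phase` states (`minus`,
#'   `plus`), the `bg_delta`, and `weights_after`.
#' @export
run_trial <- function(weights, params, task, trial_index, last_seen = NULL) {
  trial <- sample_trial(task, trial_index, last_seen)
  n <- weights$n_stimuli
  y_in <- rep(0, n)
  y_in[c(trial$first, trial$second)] <- 1
  pfc_index <- NULL
  if (!is.null(task$instructed) &&
      task$instructed %in% c(trial$first, trial$second)) {
    pfc_index <- task$instructed
  }

  minus <- run_phase(weights, params, y_in, phase = "minus",
                     pfc_index = pfc_index)
  fb <- sample_feedback(trial, minus$chosen, params)
  plus <- run_phase(weights, params, y_in, phase = "plus",
                    snc_level = fb$snc_level, chosen = minus$chosen,
                    pfc_index = pfc_index)
  delta <- phase_difference(minus, plus)
  weights <- apply_update(weights, delta, y_in, params)
  weights <- apply_forgetting(weights, params)

  structure(
    list(
      trial = as.integer(trial_index),
      pair_id = trial$pair_id,
      first = trial$first,
      second = trial$second,
      p_first = trial$p_first,
      p_second = trial$p_second,
      side = trial$side,
      chosen = minus$chosen,
      rewarded = fb$rewarded,
      snc_level = fb$snc_level,
      minus = minus,
      plus = plus,
      delta = delta,
      weights_after = weights
    ),
    class = "bg_trial"
  )
}

#' Run a complete seeded session
#'
#' Seeds the RNG, draws the initial weights, and plays `task$n_trials`
#' trials with [run_trial()].  The RNG stream is consumed in a fixed order
#' (initialization, then per trial: pair, side, feedback), so a
#' `(task, params, seed)` triple fully determines every number in the
#' returned trace.
#'
#' @inheritParams run_trial
#' @param seed Integer seed for the session.
#' @return An object of class `bg_session`: the `task`, `params`, `seed`,
#'   the initial weights (`weights_initial`), the per-trial `records` list,
#'   and the final weights (`weights_final`).
#' @examples
#' demo <- pst_task(list(c(0.9, 0.2)), n_trials = 10)
#' s <- run_session(demo, bg_params(), seed = 42)
#' vapply(s$records, `[[`, integer(1), "chosen")
#' @export
run_session <- function(task, params = bg_params(), seed = 1L) {
  set.seed(seed)
  weights <- init_weights(task$n_stimuli, params)
  weights_initial <- weights
  n_pairs <- nrow(task$pairs)
  last_seen <- rep(0L, n_pairs)
  records <- vector("list", task$n_trials)
  for (t in seq_len(task$n_trials)) {
    rec <- run_trial(weights, params, task, t, last_seen)
    last_seen[rec$pair_id] <- t
    weights <- rec$weights_after
    records[[t]] <- rec
  }
  structure(
    list(
      task = task,
      params = params,
      seed = as.integer(seed),
      weights_initial = weights_initial,
      records = records,
      weights_final = weights
    ),
    class = "bg_session"
  )
}

#' @export
print.bg_session <- function(x, ...) {
  cat(sprintf("Session of %d trials (seed %d)\n", length(x$records), x$seed))
  print(x$task)
  ch <- vapply(x$records, `[[`, integer(1), "chosen")
  rw <- vapply(x$records, `[[`, logical(1), "rewarded")
  cat("  choices :", paste(ch, collapse = " "), "\n")
  cat("  rewarded:", paste(as.integer(rw), collapse = " "), "\n")
  invisible(x)
}

#' Run independent replicate sessions
#'
#' One fully independent session per seed; results depend only on the
#' individual seeds, never on their order.
#'
#' @inheritParams run_session
#' @param seeds Nonempty integer vector of session seeds.  Duplicates are
#'   allowed (they reproduce the same session) but draw a warning.
#' @return A list of `bg_session` objects, one per seed.
#' @export
run_replicates <- function(task, params = bg_params(), seeds) {
  if (length(seeds) == 0L) {
    stop("`seeds` must be nonempty", call. = FALSE)
  }
  if (anyDuplicated(seeds)) {
    warning("duplicate seeds: the corresponding sessions are identical")
  }
  lapply(seeds, function(s) run_session(task, params, s))
}

#' Behavioral metrics of a session
#'
#' Derives the readouts used to characterize task performance:
#'
#' * `accuracy` — fraction of trials on which the stimulus with the higher
#'   current contingency was chosen;
#' * `punishment_count` — number of unrewarded trials;
#' * `switch_latencies` — for each reversal, the number of trials elapsed
#'   after the last pre-reversal trial until the newly better stimulus is
#'   chosen and remains the majority choice over the following
#'   `min(window, trials remaining)` trials; the search is confined to the
#'   block played under the reversed contingencies, `NA` if the network
#'   never switches within it;
#' * `adherence_duration` — length of the initial run of trials choosing
#'   the instructed stimulus (instructed tasks only, else `NA`);
#' * `preference_trial` — first trial of the terminal run of
#'   better-stimulus choices: the earliest trial `t` choosing the better
#'   stimulus such that from every later trial onward the better stimulus
#'   is chosen at least half the remaining time (single-pair tasks without
#'   reversals only, else `NA`);
#' * `punishments_before_preference` — punishments received before
#'   `preference_trial`.
#'
#' @param session A `bg_session`.
#' @param window Forward window (trials) over which a switch must stay the
#'   majority choice to count as sustained; default 5.
#' @return An object of class `bg_metrics`.
#' @export
compute_metrics <- function(session, window = 5L) {
  task <- session$task
  n <- task$n_trials
  ch <- vapply(session$records, `[[`, integer(1), "chosen")
  rw <- vapply(session$records, `[[`, logical(1), "rewarded")
  better <- vapply(seq_len(n), function(t) {
    r <- session$records[[t]]
    if (r$p_first >= r$p_second) as.integer(r$first) else as.integer(r$second)
  }, integer(1))

  metrics <- list(
    choices = ch,
    rewarded = rw,
    better = better,
    accuracy = mean(ch == better),
    punishment_count = sum(!rw),
    switch_latencies = NA,
    adherence_duration = NA,
    preference_trial = NA,
    punishments_before_preference = NA
  )

  single_pair <- nrow(task$pairs) == 1L
  rev_at <- task$reversal_trials

  if (single_pair && length(rev_at) > 0L) {
    block_ends <- c(rev_at - 1L, n)
    lat <- vapply(seq_along(rev_at), function(j) {
      r <- rev_at[j] - 1L # last trial under the old contingencies
      target <- better[rev_at[j]]
      horizon <- block_ends[j + 1L] - r
      for (t in seq_len(horizon)) {
        if (ch[r + t] == target && sustained_majority(ch, r + t, target,
                                                      n, window)) {
          return(t)
        }
      }
      NA_integer_
    }, integer(1))
    names(lat) <- paste0("reversal_", rev_at)
    metrics$switch_latencies <- lat
  }

  if (!is.null(task$instructed)) {
    runs <- rle(ch == task$instructed)
    metrics$adherence_duration <-
      if (runs$values[1]) runs$lengths[1] else 0L
  }

  if (single_pair && length(rev_at) == 0L) {
    pref <- terminal_preference_trial(ch, better)
    metrics$preference_trial <- pref
    if (!is.na(pref)) {
      metrics$punishments_before_preference <- sum(!rw[seq_len(pref - 1L)])
    }
  }

  structure(metrics, class = "bg_metrics")
}

#' @export
print.bg_metrics <- function(x, ...) {
  cat("Session metrics\n")
  cat(sprintf("  accuracy            : %.3f\n", x$accuracy))
  cat(sprintf("  punishments         : %d\n", x$punishment_count))
  if (!all(is.na(x$switch_latencies))) {
    cat("  switch latencies    :",
        paste(x$switch_latencies, collapse = " "), "\n")
  }
  if (!is.na(x$adherence_duration)) {
    cat(sprintf("  adherence duration  : %d trials\n", x$adherence_duration))
  }
  if (!is.na(x$preference_trial)) {
    cat(sprintf("  stable preference from trial %d (%d punishments before)\n",
                x$preference_trial, x$punishments_before_preference))
  }
  invisible(x)
}

# the choice at trial t must stay the strict-majority choice over the next
# min(window, n - t) trials; an empty window passes
sustained_majority <- function(ch, t, target, n, window) {
  upper <- min(t + window, n)
  if (upper <= t) return(TRUE)
  w <- ch[(t + 1L):upper]
  2L * sum(w == target) > length(w)
}

# earliest trial t with ch[t] == better[t] such that the better stimulus is
# chosen at least half the time in every suffix starting at or after t
terminal_preference_trial <- function(ch, better) {
  n <- length(ch)
  good <- ch == better
  suffix_ok <- logical(n)
  cnt <- 0L
  for (u in n:1) {
    cnt <- cnt + as.integer(good[u])
    suffix_ok[u] <- 2L * cnt >= (n - u + 1L)
  }
  start <- if (all(suffix_ok)) 1L else max(which(!suffix_ok)) + 1L
  if (start > n) return(NA_integer_)
  cand <- which(good & seq_len(n) >= start)
  if (length(cand) == 0L) NA_integer_ else cand[1L]
}

#' Summarize metrics over replicate sessions
#'
#' Computes [compute_metrics()] for every session and tabulates the per-seed
#' values together with median/IQR summaries.  Replicate-level summaries use
#' medians because switch latencies have a heavy right tail.
#'
#' @param sessions List of `bg_session` objects (see [run_replicates()]).
#' @param window Passed to [compute_metrics()].
#' @return A list with `per_seed` (one row per session: seed, accuracy,
#'   punishments, final-trial correctness, adherence, preference trial,
#'   punishments before preference, and one column per reversal latency)
#'   and `summary` (median and IQR of each numeric column).
#' @export
summarize_replicates <- function(sessions, window = 5L) {
  rows <- lapply(sessions, function(s) {
    m <- compute_metrics(s, window)
    n <- s$task$n_trials
    row <- data.frame(
      seed = s$seed,
      accuracy = m$accuracy,
      punishment_count = m$punishment_count,
      final_correct = m$choices[n] == m$better[n],
      adherence_duration = as.numeric(m$adherence_duration),
      preference_trial = as.numeric(m$preference_trial),
      punishments_before_preference =
        as.numeric(m$punishments_before_preference)
    )
    if (!is.logical(m$switch_latencies)) {  # task defines reversals
      lat <- as.list(as.numeric(m$switch_latencies))
      names(lat) <- paste0("latency_", seq_along(lat))
      row <- cbind(row, as.data.frame(lat))
    }
    row
  })
  per_seed <- do.call(rbind, rows)
  num <- per_seed[, setdiff(names(per_seed), "seed"), drop = FALSE]
  num[] <- lapply(num, as.numeric)
  summary <- data.frame(
    metric = names(num),
    median = vapply(num, stats::median, numeric(1), na.rm = TRUE),
    q25 = vapply(num, stats::quantile, numeric(1), probs = 0.25,
                 na.rm = TRUE, names = FALSE),
    q75 = vapply(num, stats::quantile, numeric(1), probs = 0.75,
                 na.rm = TRUE, names = FALSE),
    n_valid = vapply(num, function(v) sum(!is.na(v)), numeric(1)),
    row.names = NULL
  )
  list(per_seed = per_seed, summary = summary)
}
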