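#' Task specifications
#'
#' A task specification is the generative definition of one experiment: the
#' stimulus set, the pairs with their reward contingencies (each stimulus
#' `S` pays off with probability `p_S`, punishes with `1 - p_S`), the number
#' of trials, the trials at which all contingencies swap within each pair
#' (reversal events), and an optional instructed stimulus targeted by the
#' PFC/HC.  Use the constructors [pst_task()], [reversal_task()] and
#' [instructed_task()] rather than calling `bg_task()` directly.
#'
#' @param pairs Data frame with columns `first`, `second` (stimulus
#'   indices) and `p_first`, `p_second` (reward probabilities in `[0, 1]`).
#' @param n_trials Positive number of trials.
#' @param reversal_trials Strictly increasing integer vector of trial
#'   indices at which the swapped contingencies take effect (the named trial
#'   is the first one played under the new contingencies).
#' @param instructed Stimulus index biased by the PFC/HC, or `NULL`.
#' @param pair_sampling `"uniform"` for i.i.d. uniform pair draws, or
#'   `"bounded_gap"` to force the most overdue pair whenever one has been
#'   absent for `max_gap` trials.
#' @param max_gap Maximum number of trials a pair may go unseen under
#'   `"bounded_gap"` sampling.
#' @return An object of class `bg_task`.
#' @export
bg_task <- function(pairs, n_trials, reversal_trials = integer(0),
                    instructed = NULL,
                    pair_sampling = c("uniform", "bounded_gap"),
                    max_gap = 7L) {
  pair_sampling <- match.arg(pair_sampling)
  pairs <- as.data.frame(pairs)
  need <- c("first", "second", "p_first", "p_second")
  if (!all(need %in% names(pairs)) || nrow(pairs) == 0L) {
    stop("`pairs` needs at least one row with columns ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  pairs <- pairs[, need]
  if (any(pairs$first == pairs$second)) {
    stop("a pair must contain two distinct stimuli", call. = FALSE)
  }
  probs <- c(pairs$p_first, pairs$p_second)
  if (any(!is.finite(probs)) || any(probs < 0 | probs > 1)) {
    stop("contingencies must be probabilities in [0, 1]", call. = FALSE)
  }
  n_stimuli <- max(pairs$first, pairs$second)
  idx <- c(pairs$first, pairs$second)
  if (any(idx < 1) || any(idx != round(idx))) {
    stop("stimulus indices must be positive integers", call. = FALSE)
  }
  check_number(n_trials, "n_trials", lower = 1)
  n_trials <- as.integer(n_trials)
  reversal_trials <- as.integer(reversal_trials)
  if (length(reversal_trials) > 0L) {
    if (any(diff(reversal_trials) <= 0L) ||
        any(reversal_trials < 1L | reversal_trials > n_trials)) {
      stop("`reversal_trials` must be strictly increasing within 1..n_trials",
           call. = FALSE)
    }
  }
  if (!is.null(instructed)) {
    instructed <- as.integer(instructed)
    if (!(instructed %in% idx)) {
      stop("`instructed` must name a stimulus occurring in some pair",
           call. = FALSE)
    }
  }
  structure(
    list(
      n_stimuli = as.integer(n_stimuli),
      pairs = pairs,
      n_trials = n_trials,
      reversal_trials = reversal_trials,
      instructed = instructed,
      pair_sampling = pair_sampling,
      max_gap = as.integer(max_gap)
    ),
    class = "bg_task"
  )
}

#' @export
print.bg_task <- function(x, ...) {
  kind <- if (!is.null(x$instructed)) {
    "instructed probabilistic selection"
  } else if (length(x$reversal_trials) > 0L) {
    "probabilistic reversal learning"
  } else {
    "probabilistic selection"
  }
  cat(sprintf("%s task: %d stimuli, %d trials\n", kind, x$n_stimuli,
              x$n_trials))
  for (i in seq_len(nrow(x$pairs))) {
    p <- x$pairs[i, ]
    cat(sprintf("  pair %d: stimulus %d (p = %.2f) vs stimulus %d (p = %.2f)\n",
                i, p$first, p$p_first, p$second, p$p_second))
  }
  if (length(x$reversal_trials) > 0L) {
    cat("  contingencies swap at trials:",
        paste(x$reversal_trials, collapse = ", "), "\n")
  }
  if (!is.null(x$instructed)) {
    cat(sprintf("  PFC/HC instruction on stimulus %d\n", x$instructed))
  }
  invisible(x)
}

#' Probabilistic selection task
#'
#' Stimuli appear only in fixed pairs, the pair shown on each trial is drawn
#' at random, and choosing stimulus `S` pays off with probability `p_S`.
#' The default is the classic three-pair composition AB (80%/20%),
#' CD (70%/30%), EF (60%/40%); pass a single pair such as
#' `list(c(0.9, 0.2))` for the two-stimulus demonstration game.
#'
#' @param contingencies List of length-2 numeric vectors, one per pair,
#'   giving the reward probabilities of the pair's two stimuli.  Pair `j`
#'   uses stimulus indices `2j - 1` and `2j`.
#' @param n_trials Number of trials; defaults to 20 per pair.
#' @inheritParams bg_task
#' @return A `bg_task` with no reversals and no instruction.
#' @examples
#' pst_task()                              # AB/CD/EF
#' pst_task(list(c(0.9, 0.2)), n_trials = 10) # two-stimulus demo
#' @export
pst_task <- function(contingencies = list(c(0.8, 0.2), c(0.7, 0.3),
                                          c(0.6, 0.4)),
                     n_trials = 20L * length(contingencies),
                     pair_sampling = c("uniform", "bounded_gap"),
                     max_gap = 7L) {
  if (!is.list(contingencies) || length(contingencies) == 0L) {
    stop("`contingencies` must be a nonempty list of probability pairs",
         call. = FALSE)
  }
  k <- length(contingencies)
  pairs <- data.frame(
    first = 2L * seq_len(k) - 1L,
    second = 2L * seq_len(k),
    p_first = vapply(contingencies, `[`, numeric(1), 1L),
    p_second = vapply(contingencies, `[`, numeric(1), 2L)
  )
  bg_task(pairs, n_trials, pair_sampling = match.arg(pair_sampling),
          max_gap = max_gap)
}

#' Probabilistic reversal learning task
#'
#' A single stimulus pair whose contingencies swap, unannounced, at the end
#' of every block of `block` trials.  With the defaults the pair starts at
#' 90%/20%, the swap first takes effect at trial 21, then at 41, 61 and 81,
#' and the session ends at trial 100.
#'
#' @param p_first,p_second Initial reward probabilities of the two stimuli.
#' @param block Block length in trials between reversals.
#' @param n_trials Session length.
#' @return A `bg_task` with `reversal_trials = block + 1, 2 * block + 1, ...`.
#' @examples
#' reversal_task()$reversal_trials # 21 41 61 81
#' @export
reversal_task <- function(p_first = 0.9, p_second = 0.2,
                          block = 20L, n_trials = 100L) {
  check_number(block, "block", lower = 1)
  if (block > n_trials) {
    stop("`block` cannot exceed `n_trials`", call. = FALSE)
  }
  rev_at <- seq.int(block + 1L, by = block, length.out = n_trials %/% block)
  rev_at <- rev_at[rev_at <= n_trials]
  pairs <- data.frame(first = 1L, second = 2L,
                      p_first = p_first, p_second = p_second)
  bg_task(pairs, n_trials, reversal_trials = rev_at)
}

#' Instructed probabilistic selection task
#'
#' The two-stimulus selection game preceded by a (typically misleading)
#' instruction: the PFC/HC biases the striatal Go unit and the PMC unit of
#' the instructed stimulus on every trial it is shown.  With the defaults
#' the instruction targets the worse (20%-rewarded) stimulus and the session
#' runs for 30 trials.
#'
#' @inheritParams reversal_task
#' @param instructed Index (1 or 2) of the instructed stimulus.
#' @param n_trials Session length.
#' @return A `bg_task` with `instructed` set.
#' @export
instructed_task <- function(p_first = 0.9, p_second = 0.2,
                            instructed = 2L, n_trials = 30L) {
  if (!(instructed %in% c(1L, 2L))) {
    stop("`instructed` must be stimulus 1 or 2", call. = FALSE)
  }
  pairs <- data.frame(first = 1L, second = 2L,
                      p_first = p_first, p_second = p_second)
  bg_task(pairs, n_trials, instructed = instructed)
}

#' Contingencies in force at a given trial
#'
#' Applies every reversal event scheduled at or before `trial_index`:
#' each swap exchanges `p_first` and `p_second` within every pair, so two
#' swaps restore the original contingencies.
#'
#' @param task A `bg_task`.
#' @param trial_index Trial number in `1..n_trials`.
#' @return The task's `pairs` data frame with current `p_first`/`p_second`.
#' @export
task_contingencies <- function(task, trial_index) {
  if (trial_index < 1 || trial_index > task$n_trials) {
    stop("`trial_index` out of range", call. = FALSE)
  }
  pairs <- task$pairs
  if (sum(task$reversal_trials <= trial_index) %% 2L == 1L) {
    tmp <- pairs$p_first
    pairs$p_first <- pairs$p_second
    pairs$p_second <- tmp
  }
  pairs
}

#' Draw the stimulus pair and screen sides for one trial
#'
#' Samples which pair appears (uniformly, or forced when a pair is overdue
#' under bounded-gap scheduling) and on which side of the screen each
#' stimulus lands.  The side assignment is metadata only: the input layer
#' codes stimulus identity, so screen position never enters the dynamics.
#' Consumes exactly two RNG draws (pair, then side) regardless of the
#' scheduling mode, keeping trial streams reproducible.
#'
#' @param task A `bg_task`.
#' @param trial_index Trial number in `1..n_trials`.
#' @param last_seen Optional integer vector, one entry per pair, giving the
#'   trial at which each pair last appeared (0 for never); used only by
#'   bounded-gap scheduling.
#' @return A list with `pair_id`, `first`, `second`, the contingencies
#'   `p_first`/`p_second` in force at this trial, and `side` (1 if `first`
#'   is on the left, 2 if on the right).
#' @export
sample_trial <- function(task, trial_index, last_seen = NULL) {
  if (trial_index < 1 || trial_index > task$n_trials) {
    stop("`trial_index` out of range", call. = FALSE)
  }
  n_pairs <- nrow(task$pairs)
  pair_id <- sample.int(n_pairs, 1L)
  if (task$pair_sampling == "bounded_gap" && !is.null(last_seen)) {
    gap <- trial_index - last_seen
    if (any(gap > task$max_gap)) {
      pair_id <- which.max(gap)
    }
  }
  side <- sample.int(2L, 1L)
  cur <- task_contingencies(task, trial_index)[pair_id, ]
  list(
    pair_id = pair_id,
    first = cur$first,
    second = cur$second,
    p_first = cur$p_first,
    p_second = cur$p_second,
    side = side
  )
}

#' Probabilistic feedback for a choice
#'
#' Rewards the chosen stimulus with its current contingency and maps the
#' outcome to the dopamine level delivered in the plus phase: a burst after
#' a reward, a dip after a punishment.  Consumes one RNG draw.
#'
#' @param pair A sampled pair as returned by [sample_trial()].
#' @param chosen Index of the chosen stimulus; must belong to the pair.
#' @param params A [bg_params] object (source of the burst/dip levels).
#' @return List with `rewarded` (logical) and `snc_level`.
#' @export
sample_feedback <- function(pair, chosen, params = bg_params()) {
  if (chosen == pair$first) {
    p <- pair$p_first
  } else if (chosen == pair$second) {
    p <- pair$p_second
  } else {
    stop("`chosen` is not a member of the presented pair", call. = FALSE)
  }
  rewarded <- stats::runif(1L) < p
  list(
    rewarded = rewarded,
    snc_level = if (rewarded) params$snc_burst else params$snc_dip
  )
}
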