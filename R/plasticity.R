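#' Random initialization of the learnable weights
#'
#' Draws every input-to-striatum and input-to-PMC weight i.i.d. from a
#' Gaussian with mean `params$init_mean` and variance `params$init_var`
#' (defaults 0.05 and 0.01, i.e. standard deviation 0.1) and clips negative
#' draws to zero, since all learnable weights in the model are nonnegative.
#' The fixed SNc-to-striatum signs are set to +1 for the Go block and -1 for
#' the NoGo block.  Draws consume the R RNG stream in a fixed order
#' (striatal matrix column-major, then PMC matrix), so a given seed always
#' yields the same network.
#'
#' @param n_stimuli Number of stimuli `N >= 1`; the network has `3 N^2`
#'   learnable weights.
#' @param params A [bg_params] object.
#' @return A [bg_weights] object.
#' @examples
#' set.seed(1)
#' w <- init_weights(2, bg_params())
#' dim(w$w_in_stria) # 2 x 4
#' @export
init_weights <- function(n_stimuli, params = bg_params()) {
  if (!is.numeric(n_stimuli) || length(n_stimuli) != 1L ||
      n_stimuli < 1 || n_stimuli != round(n_stimuli)) {
    stop("`n_stimuli` must be a positive integer", call. = FALSE)
  }
  n <- as.integer(n_stimuli)
  sdv <- sqrt(params$init_var)
  ws <- matrix(pmax(stats::rnorm(n * 2L * n, params$init_mean, sdv), 0),
               nrow = n, ncol = 2L * n)
  wp <- matrix(pmax(stats::rnorm(n * n, params$init_mean, sdv), 0),
               nrow = n, ncol = n)
  bg_weights(ws, wp)
}

#' Plus-minus activity differences
#'
#' The learning signal of the model: the elementwise difference between the
#' striatal and PMC activities in the feedback (plus) phase and the decision
#' (minus) phase of the same trial.  Units whose drive did not change
#' between phases — every striatal unit not belonging to the chosen
#' stimulus — have a difference of exactly zero, so dopamine-driven learning
#' is confined to the chosen stimulus' units.
#'
#' @param minus,plus `bg_phase` states of the same trial.
#' @return An object of class `bg_delta` with `d_stria` (length `2 N`) and
#'   `d_pmc` (length `N`), entries in `[-1, 1]`.
#' @export
phase_difference <- function(minus, plus) {
  if (length(minus$y_stria) != length(plus$y_stria) ||
      length(minus$y_pmc) != length(plus$y_pmc)) {
    stop("phase states come from networks of different size", call. = FALSE)
  }
  structure(
    list(
      d_stria = plus$y_stria - minus$y_stria,
      d_pmc = plus$y_pmc - minus$y_pmc
    ),
    class = "bg_delta"
  )
}

#' Delta-rule weight update
#'
#' Adds `lr * delta` to the weights of each updated unit and clips the
#' result at zero: for striatal unit `k`,
#' `w[i, k] <- max(w[i, k] + lr_striatum * d_stria[k], 0)`, and likewise for
#' the PMC with `lr_pmc`.  With presynaptic gating (the default) only rows
#' `i` of presented stimuli (`y_in[i] == 1`) are touched, so associations of
#' absent stimuli stay put; with `params$presynaptic_gating = FALSE` every
#' row is updated.
#'
#' @param weights A [bg_weights] object.
#' @param delta A `bg_delta` from [phase_difference()].
#' @param y_in Binary input vector of the trial.
#' @param params A [bg_params] object.
#' @return The updated [bg_weights]; all entries remain nonnegative.
#' @export
apply_update <- function(weights, delta, y_in, params) {
  n <- weights$n_stimuli
  check_binary_input(y_in, n)
  if (length(delta$d_stria) != 2L * n || length(delta$d_pmc) != n) {
    stop("`delta` does not match the network size", call. = FALSE)
  }
  rows <- if (params$presynaptic_gating) which(y_in == 1) else seq_len(n)
  if (length(rows) > 0L) {
    ws <- weights$w_in_stria
    ws[rows, ] <- pmax(ws[rows, , drop = FALSE] +
                         rep(params$lr_striatum * delta$d_stria,
                             each = length(rows)), 0)
    wp <- weights$w_in_pmc
    wp[rows, ] <- pmax(wp[rows, , drop = FALSE] +
                         rep(params$lr_pmc * delta$d_pmc,
                             each = length(rows)), 0)
    weights$w_in_stria <- ws
    weights$w_in_pmc <- wp
  }
  weights
}

#' Per-trial forgetting
#'
#' Multiplies every learnable weight by the forgetting factor `beta`
#' (`params$forgetting`), once per trial after the delta-rule update.  The
#' fixed SNc signs are untouched.  At `beta = 0.98` the memory trace has a
#' half-life of `log(2) / log(1 / 0.98)` (about 34 trials), long enough to
#' bridge the gaps between reappearances of a stimulus pair.
#'
#' @inheritParams apply_update
#' @return The decayed [bg_weights].
#' @export
apply_forgetting <- function(weights, params) {
  weights$w_in_stria <- weights$w_in_stria * params$forgetting
  weights$w_in_pmc <- weights$w_in_pmc * params$forgetting
  weights
}
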