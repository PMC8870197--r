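#' Model parameters of the basal ganglia rate network
#'
#' Bundles every fixed parameter of the model: the shape of the activation
#' function, the striatal and premotor learning rates, the per-trial
#' forgetting factor, the strength of the instruction (PFC/HC) projections,
#' the three dopamine output levels of the SNc, and the Gaussian from which
#' learnable weights are initialized.
#'
#' The defaults are the values used throughout the simulations shipped with
#' the package: `a = 8`, both learning rates `0.1`, forgetting `0.98`, both
#' instruction weights `0.3`, dopamine dip/tonic/burst levels `0 / 0.5 / 1`,
#' and initial weights drawn from a Gaussian with mean `0.05` and variance
#' `0.01` (negative draws clipped to zero, see [init_weights()]).
#'
#' @param a Shape of the activation function
#'   \eqn{\phi(x) = \exp\{-a(1 - x)^2\}}; dimensionless, must be positive.
#' @param lr_striatum,lr_pmc Learning rates of the input-to-striatum and
#'   input-to-PMC weights, in weight change per unit of plus-minus activity
#'   difference; nonnegative.
#' @param forgetting Multiplicative decay \eqn{\beta} applied to every
#'   learnable weight once per trial; must lie in `(0, 1]` (`1` disables
#'   forgetting).
#' @param w_pfc_stria,w_pfc_pmc Strength of the PFC/HC projection onto the
#'   instructed stimulus' striatal Go unit and PMC unit; nonnegative. Active
#'   only in the instructed task.
#' @param snc_dip,snc_tonic,snc_burst Dopamine levels emitted by the SNc for
#'   a dip (negative prediction error), tonic baseline, and burst (positive
#'   prediction error); must satisfy `snc_dip < snc_tonic < snc_burst`.
#' @param init_mean,init_var Mean and variance of the Gaussian used to draw
#'   initial learnable weights; `init_var` must be nonnegative.
#' @param presynaptic_gating If `TRUE` (default) a weight from input `i` to
#'   unit `k` is updated only on trials where stimulus `i` is presented
#'   (standard delta rule with a presynaptic term); if `FALSE` every weight
#'   to unit `k` is updated regardless of the input's activity.
#'
#' @return An object of class `bg_params`: a named list of the parameters
#'   above.
#' @seealso [init_weights()], [run_phase()], [run_session()]
#' @examples
#' p <- bg_params()
#' p$a
#' bg_params(forgetting = 1, lr_striatum = 0) # a non-learning network
#' @export
bg_params <- function(a = 8,
                      lr_striatum = 0.1,
                      lr_pmc = 0.1,
                      forgetting = 0.98,
                      w_pfc_stria = 0.3,
                      w_pfc_pmc = 0.3,
                      snc_dip = 0,
                      snc_tonic = 0.5,
                      snc_burst = 1,
                      init_mean = 0.05,
                      init_var = 0.01,
                      presynaptic_gating = TRUE) {
  check_number(a, "a", lower = 0, strict = TRUE)
  check_number(lr_striatum, "lr_striatum", lower = 0)
  check_number(lr_pmc, "lr_pmc", lower = 0)
  check_number(forgetting, "forgetting", lower = 0, upper = 1, strict = TRUE,
               strict_upper = FALSE)
  check_number(w_pfc_stria, "w_pfc_stria", lower = 0)
  check_number(w_pfc_pmc, "w_pfc_pmc", lower = 0)
  check_number(snc_dip, "snc_dip")
  check_number(snc_tonic, "snc_tonic")
  check_number(snc_burst, "snc_burst")
  if (!(snc_dip < snc_tonic && snc_tonic < snc_burst)) {
    stop("SNc levels must be ordered: snc_dip < snc_tonic < snc_burst",
         call. = FALSE)
  }
  check_number(init_mean, "init_mean")
  check_number(init_var, "init_var", lower = 0)
  if (!is.logical(presynaptic_gating) || length(presynaptic_gating) != 1L ||
      is.na(presynaptic_gating)) {
    stop("`presynaptic_gating` must be TRUE or FALSE", call. = FALSE)
  }
  structure(
    list(
      a = a,
      lr_striatum = lr_striatum,
      lr_pmc = lr_pmc,
      forgetting = forgetting,
      w_pfc_stria = w_pfc_stria,
      w_pfc_pmc = w_pfc_pmc,
      snc_dip = snc_dip,
      snc_tonic = snc_tonic,
      snc_burst = snc_burst,
      init_mean = init_mean,
      init_var = init_var,
      presynaptic_gating = presynaptic_gating
    ),
    class = "bg_params"
  )
}

#' @export
print.bg_params <- function(x, ...) {
  cat("Basal ganglia model parameters\n")
  cat(sprintf("  activation shape a        : %g\n", x$a))
  cat(sprintf("  learning rates (stria/pmc): %g / %g\n",
              x$lr_striatum, x$lr_pmc))
  cat(sprintf("  forgetting beta           : %g\n", x$forgetting))
  cat(sprintf("  PFC/HC weights (stria/pmc): %g / %g\n",
              x$w_pfc_stria, x$w_pfc_pmc))
  cat(sprintf("  SNc dip / tonic / burst   : %g / %g / %g\n",
              x$snc_dip, x$snc_tonic, x$snc_burst))
  cat(sprintf("  weight init               : Gaussian(%g, var %g), clipped at 0\n",
              x$init_mean, x$init_var))
  cat(sprintf("  presynaptic gating        : %s\n", x$presynaptic_gating))
  invisible(x)
}

# scalar validation used across constructors; strict => exclusive lower bound
check_number <- function(x, name, lower = -Inf, upper = Inf,
                         strict = FALSE, strict_upper = strict) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  }
  low_ok <- if (strict) x > lower else x >= lower
  up_ok <- if (strict_upper) x < upper else x <= upper
  if (!low_ok || !up_ok) {
    stop(sprintf("`%s` = %g is outside its allowed range", name, x),
         call. = FALSE)
  }
  invisible(x)
}
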