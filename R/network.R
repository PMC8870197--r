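#' Activation function of the rate units
#'
#' The sigmoid-like activation \eqn{\phi(x) = \exp\{-a(1 - x)^2\}} maps a
#' unit's summed input to a firing rate in `(0, 1]`.  It increases strictly
#' on \eqn{x \le 1}, peaks at \eqn{\phi(1) = 1}, and is symmetric about
#' \eqn{x = 1}.  Unlike the logistic function its shape is nearly invariant
#' for large `a`, which keeps the model's behavior insensitive to the exact
#' value of the shape parameter.
#'
#' @param x Preactivation (summed input); any finite numeric vector.
#' @param a Positive shape parameter.
#' @return `exp(-a * (1 - x)^2)`, elementwise.
#' @examples
#' bg_phi(1, 8)    # 1
#' bg_phi(0.5, 8)  # exp(-2)
#' @export
bg_phi <- function(x, a) {
  check_number(a, "a", lower = 0, strict = TRUE)
  if (!is.numeric(x) || any(!is.finite(x))) {
    stop("preactivation `x` must be finite numeric", call. = FALSE)
  }
  exp(-a * (1 - x)^2)
}

#' Network weights
#'
#' Container for the learnable synaptic weights of the model: the
#' input-to-striatum matrix (`n_stimuli` inputs by `2 * n_stimuli` striatal
#' units, Go units first, then NoGo units) and the input-to-PMC matrix
#' (`n_stimuli` by `n_stimuli`), both nonnegative, plus the fixed SNc signs
#' (+1 for Go units, -1 for NoGo units — dopamine excites the direct and
#' inhibits the indirect pathway).  For `N` stimuli the model therefore has
#' `3 N^2` learnable weights.
#'
#' @param w_in_stria Numeric matrix, `N` rows (inputs) by `2 N` columns
#'   (striatal units), entries `>= 0`.
#' @param w_in_pmc Numeric matrix, `N` by `N`, entries `>= 0`.
#' @return An object of class `bg_weights` with elements `n_stimuli`,
#'   `w_in_stria`, `w_in_pmc` and the fixed sign vector `w_snc_stria`.
#' @seealso [init_weights()] for random initialization.
#' @examples
#' w <- bg_weights(matrix(0, 2, 4), matrix(0, 2, 2)) # a blank 2-stimulus net
#' w$w_snc_stria
#' @export
bg_weights <- function(w_in_stria, w_in_pmc) {
  w_in_stria <- as.matrix(w_in_stria)
  w_in_pmc <- as.matrix(w_in_pmc)
  n <- nrow(w_in_stria)
  if (n < 1L) stop("at least one stimulus is required", call. = FALSE)
  if (ncol(w_in_stria) != 2L * n) {
    stop(sprintf("`w_in_stria` must be %d x %d (Go block then NoGo block)",
                 n, 2L * n), call. = FALSE)
  }
  if (nrow(w_in_pmc) != n || ncol(w_in_pmc) != n) {
    stop(sprintf("`w_in_pmc` must be %d x %d", n, n), call. = FALSE)
  }
  if (!is.numeric(w_in_stria) || !is.numeric(w_in_pmc) ||
      any(!is.finite(w_in_stria)) || any(!is.finite(w_in_pmc))) {
    stop("weights must be finite numeric", call. = FALSE)
  }
  if (any(w_in_stria < 0) || any(w_in_pmc < 0)) {
    stop("learnable weights must be nonnegative", call. = FALSE)
  }
  dimnames(w_in_stria) <- list(paste0("in", seq_len(n)),
                               c(paste0("Go", seq_len(n)),
                                 paste0("NoGo", seq_len(n))))
  dimnames(w_in_pmc) <- list(paste0("in", seq_len(n)),
                             paste0("pmc", seq_len(n)))
  structure(
    list(
      n_stimuli = n,
      w_in_stria = w_in_stria,
      w_in_pmc = w_in_pmc,
      w_snc_stria = rep(c(1, -1), each = n)
    ),
    class = "bg_weights"
  )
}

#' @export
print.bg_weights <- function(x, ...) {
  cat(sprintf("Network weights for %d stimuli (%d learnable entries)\n",
              x$n_stimuli, 3L * x$n_stimuli^2))
  cat("input -> striatum (Go | NoGo):\n")
  print(round(x$w_in_stria, 4))
  cat("input -> PMC:\n")
  print(round(x$w_in_pmc, 4))
  invisible(x)
}

#' Striatal layer activity
#'
#' Each striatal unit sums its dopaminergic drive (SNc level times the fixed
#' +1/-1 sign), the weighted input-layer drive, and — for the instructed Go
#' unit only — the PFC/HC instruction drive, then passes the total through
#' [bg_phi()].  A dopamine burst therefore excites Go units and suppresses
#' NoGo units of the stimulus it is routed to, and a dip does the opposite.
#'
#' @param weights A [bg_weights] object.
#' @param params A [bg_params] object.
#' @param y_in Binary vector of length `n_stimuli`; 1 for each presented
#'   stimulus.
#' @param y_snc Dopamine level seen by each striatal unit; vector of length
#'   `2 * n_stimuli` (Go block first).
#' @param pfc_index Index of the instructed stimulus, or `NULL` when the
#'   PFC/HC is disconnected.  The instruction targets the Go unit of that
#'   stimulus.
#' @param y_pfc PFC/HC output, 0 or 1.
#' @return Vector of `2 * n_stimuli` activities in `[0, 1]`.
#' @export
striatum_activity <- function(weights, params, y_in, y_snc,
                              pfc_index = NULL, y_pfc = 0) {
  n <- weights$n_stimuli
  check_binary_input(y_in, n)
  if (length(y_snc) != 2L * n) {
    stop("`y_snc` must give one dopamine level per striatal unit",
         call. = FALSE)
  }
  x <- weights$w_snc_stria * y_snc +
    as.vector(y_in %*% weights$w_in_stria)
  if (!is.null(pfc_index) && y_pfc > 0) {
    x[pfc_index] <- x[pfc_index] + params$w_pfc_stria * y_pfc
  }
  bg_phi(x, params$a)
}

#' External pallidum activity
#'
#' GPe units are tonically active and inhibited one-to-one by the striatal
#' NoGo units: `1 - y_nogo`.
#'
#' @param y_stria_nogo NoGo activities, length `n_stimuli`, in `[0, 1]`.
#' @return Vector of GPe activities.
#' @export
gpe_activity <- function(y_stria_nogo) {
  check_unit_range(y_stria_nogo, "y_stria_nogo")
  1 - y_stria_nogo
}

#' Internal pallidum activity
#'
#' GPi units fire tonically and are inhibited both directly by the striatal
#' Go units and by the GPe: `max(1 - go/2 - gpe/2, 0)`.  The clamp at zero
#' enforces nonnegative firing.  NoGo activity, by silencing the GPe,
#' disinhibits the GPi — the indirect pathway.
#'
#' @param y_stria_go Go activities, length `n_stimuli`, in `[0, 1]`.
#' @param y_gpe GPe activities, same length, in `[0, 1]`.
#' @return Vector of GPi activities in `[0, 1]`.
#' @export
gpi_activity <- function(y_stria_go, y_gpe) {
  check_unit_range(y_stria_go, "y_stria_go")
  check_unit_range(y_gpe, "y_gpe")
  if (length(y_stria_go) != length(y_gpe)) {
    stop("Go and GPe vectors must have equal length", call. = FALSE)
  }
  pmax(1 - 0.5 * y_stria_go - 0.5 * y_gpe, 0)
}

#' Thalamic activity
#'
#' The tonically firing GPi inhibits the thalamus one-to-one; a silenced GPi
#' unit releases ("disinhibits") its thalamic partner: `1 - y_gpi`.
#'
#' @param y_gpi GPi activities in `[0, 1]`.
#' @return Vector of thalamic activities.
#' @export
thalamus_activity <- function(y_gpi) {
  check_unit_range(y_gpi, "y_gpi")
  1 - y_gpi
}

#' Premotor cortex activity
#'
#' Each PMC unit averages its thalamic gate and its direct weighted input
#' drive, `x_k = y_thal_k / 2 + (sum_i w_ik y_in_i) / 2`, plus the PFC/HC
#' instruction drive on the instructed unit.  If any preactivation exceeds 1
#' the whole vector is divided by its maximum, so the most driven unit sits
#' exactly at the peak of the activation function; activities are then
#' `phi(x)`.
#'
#' @inheritParams striatum_activity
#' @param y_thal Thalamic activities, length `n_stimuli`, in `[0, 1]`.
#' @param pfc_index Index of the instructed PMC unit, or `NULL`.
#' @return List with `x` (preactivations after the conditional
#'   normalization, `max(x) <= 1`) and `y = phi(x)`.
#' @export
pmc_activity <- function(weights, params, y_thal, y_in,
                         pfc_index = NULL, y_pfc = 0) {
  n <- weights$n_stimuli
  check_binary_input(y_in, n)
  check_unit_range(y_thal, "y_thal")
  if (length(y_thal) != n) {
    stop("`y_thal` must have one entry per stimulus", call. = FALSE)
  }
  x <- 0.5 * y_thal + 0.5 * as.vector(y_in %*% weights$w_in_pmc)
  if (!is.null(pfc_index) && y_pfc > 0) {
    x[pfc_index] <- x[pfc_index] + params$w_pfc_pmc * y_pfc
  }
  m <- max(x)
  if (m > 1) x <- x / m
  list(x = x, y = bg_phi(x, params$a))
}

#' Decision readout
#'
#' The network's choice is the presented stimulus whose PMC unit is most
#' active; all other output units are inhibited.  Ties are broken
#' deterministically in favor of the lowest stimulus index (exact ties have
#' probability ~0 under random initialization).  Stimuli absent from the
#' screen can never be chosen.
#'
#' @param y_pmc PMC activities, length `n_stimuli`.
#' @param presented Integer vector of presented stimulus indices; nonempty.
#' @return List with `chosen` (stimulus index) and `y_out` (one-hot vector).
#' @export
decide_action <- function(y_pmc, presented) {
  n <- length(y_pmc)
  presented <- sort(unique(as.integer(presented)))
  if (length(presented) == 0L) {
    stop("no stimuli presented: the decision set is empty", call. = FALSE)
  }
  if (any(presented < 1L | presented > n)) {
    stop("`presented` indices must lie in 1..n_stimuli", call. = FALSE)
  }
  chosen <- presented[which.max(y_pmc[presented])]
  y_out <- rep(0, n)
  y_out[chosen] <- 1
  list(chosen = chosen, y_out = y_out)
}

#' One feed-forward pass through the network
#'
#' Runs a single phase of a trial: input -> striatum -> GPe -> GPi ->
#' thalamus -> PMC -> output.  In the minus (decision) phase every striatal
#' unit sees the tonic dopamine level and the choice is read out from the
#' PMC.  In the plus (feedback) phase the phasic level (`snc_burst` after a
#' reward, `snc_dip` after a punishment) is routed only to the Go and NoGo
#' units of the already-chosen stimulus — all other units stay at the tonic
#' level — and the output is held at the choice made in the minus phase.
#'
#' @inheritParams striatum_activity
#' @param phase `"minus"` or `"plus"`.
#' @param snc_level Phasic dopamine level; required in the plus phase.
#' @param chosen Stimulus chosen in the minus phase; required in the plus
#'   phase.
#' @param pfc_index Instructed stimulus index or `NULL`; when non-`NULL` the
#'   PFC/HC is active (`y_pfc = 1`) and drives the matching Go and PMC
#'   units in both phases.
#' @return An object of class `bg_phase`: the full set of layer activities
#'   (`y_in`, `y_snc`, `y_stria`, `y_gpe`, `y_gpi`, `y_thal`, `x_pmc`,
#'   `y_pmc`, `y_out`), the `chosen` index, `phase`, `pfc_index` and
#'   `y_pfc`.
#' @examples
#' w <- bg_weights(matrix(0, 2, 4), matrix(0, 2, 2))
#' st <- run_phase(w, bg_params(), c(1, 1))
#' st$y_gpi  # ~0.432 for a blank network under tonic dopamine
#' @export
run_phase <- function(weights, params, y_in,
                      phase = c("minus", "plus"),
                      snc_level = NULL, chosen = NULL, pfc_index = NULL) {
  phase <- match.arg(phase)
  n <- weights$n_stimuli
  check_binary_input(y_in, n)
  presented <- which(y_in == 1)
  if (length(presented) == 0L) {
    stop("`y_in` must present at least one stimulus", call. = FALSE)
  }
  if (!is.null(pfc_index)) {
    if (!(pfc_index %in% seq_len(n))) {
      stop("`pfc_index` must name a stimulus", call. = FALSE)
    }
    y_pfc <- 1
  } else {
    y_pfc <- 0
  }

  y_snc <- rep(params$snc_tonic, 2L * n)
  if (phase == "plus") {
    if (is.null(chosen) || is.null(snc_level)) {
      stop("the plus phase requires `chosen` and a phasic `snc_level`",
           call. = FALSE)
    }
    if (!(chosen %in% presented)) {
      stop("`chosen` must be one of the presented stimuli", call. = FALSE)
    }
    y_snc[c(chosen, n + chosen)] <- snc_level
  }

  y_stria <- striatum_activity(weights, params, y_in, y_snc,
                               pfc_index = pfc_index, y_pfc = y_pfc)
  y_gpe <- gpe_activity(y_stria[(n + 1L):(2L * n)])
  y_gpi <- gpi_activity(y_stria[seq_len(n)], y_gpe)
  y_thal <- thalamus_activity(y_gpi)
  pmc <- pmc_activity(weights, params, y_thal, y_in,
                      pfc_index = pfc_index, y_pfc = y_pfc)
  if (phase == "minus") {
    dec <- decide_action(pmc$y, presented)
  } else {
    y_out <- rep(0, n)
    y_out[chosen] <- 1
    dec <- list(chosen = as.integer(chosen), y_out = y_out)
  }

  structure(
    list(
      phase = phase,
      y_in = y_in,
      presented = presented,
      pfc_index = pfc_index,
      y_pfc = y_pfc,
      y_snc = y_snc,
      y_stria = y_stria,
      y_gpe = y_gpe,
      y_gpi = y_gpi,
      y_thal = y_thal,
      x_pmc = pmc$x,
      y_pmc = pmc$y,
      y_out = dec$y_out,
      chosen = dec$chosen
    ),
    class = "bg_phase"
  )
}

#' @export
print.bg_phase <- function(x, digits = 4, ...) {
  n <- length(x$y_in)
  cat(sprintf("%s phase | presented: %s | chosen: %d\n",
              x$phase, paste(x$presented, collapse = ", "), x$chosen))
  cat(sprintf("  SNc (per striatal unit): %s\n",
              paste(round(x$y_snc, digits), collapse = " ")))
  lay <- rbind(Go = x$y_stria[seq_len(n)],
               NoGo = x$y_stria[(n + 1L):(2L * n)],
               GPe = x$y_gpe, GPi = x$y_gpi, thalamus = x$y_thal,
               PMC = x$y_pmc, output = x$y_out)
  colnames(lay) <- paste0("s", seq_len(n))
  print(round(lay, digits))
  invisible(x)
}

check_binary_input <- function(y_in, n) {
  if (!is.numeric(y_in) || length(y_in) != n ||
      !all(y_in %in% c(0, 1))) {
    stop(sprintf("`y_in` must be a binary vector of length %d", n),
         call. = FALSE)
  }
  invisible(y_in)
}

check_unit_range <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0 | x > 1)) {
    stop(sprintf("`%s` must lie in [0, 1]", name), call. = FALSE)
  }
  invisible(x)
}
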