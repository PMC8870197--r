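#' Load a run configuration
#'
#' Reads a YAML (or JSON) document with up to three sections — `task`,
#' `model` and `execution` — validates it, and fills every omitted field
#' with its default.  An empty document yields the default configuration:
#' the two-stimulus demonstration game (single 0.9/0.2 pair, 10 trials),
#' default model parameters, one session with seed 1.  Unknown keys at any
#' level are rejected, and validation errors name the offending key.
#'
#' The `task` section carries `type` (`"pst"`, `"reversal"` or
#' `"instructed"`) plus the arguments of the matching constructor
#' ([pst_task()], [reversal_task()], [instructed_task()]; for `pst`,
#' `contingencies` is a list of two-element probability vectors).  The
#' `model` section accepts any [bg_params()] argument.  The `execution`
#' section accepts `seeds` (integer vector), `out_dir` and
#' `snapshot_trials`.
#'
#' @param path Path to the configuration file, or `NULL` for the defaults.
#' @return An object of class `bg_config`: list with `task` (a `bg_task`),
#'   `params` (a [bg_params]), `execution`, and the canonical document
#'   under `$document`.
#' @seealso [save_config()] for the inverse.
#' @export
load_config <- function(path = NULL) {
  doc <- if (is.null(path)) list() else yaml::read_yaml(path)
  if (is.null(doc)) doc <- list()
  if (!is.list(doc)) stop("configuration must be a mapping", call. = FALSE)
  reject_unknown(doc, c("task", "model", "execution"), "top level")

  task_doc <- doc$task %||% list()
  reject_unknown(task_doc,
                 c("type", "contingencies", "n_trials", "p_first", "p_second",
                   "block", "instructed", "pair_sampling", "max_gap"),
                 "task")
  type <- task_doc$type %||% "pst"
  if (!type %in% c("pst", "reversal", "instructed")) {
    stop("task$type must be one of pst, reversal, instructed", call. = FALSE)
  }
  task <- switch(type,
    pst = pst_task(
      contingencies = lapply(task_doc$contingencies %||% list(c(0.9, 0.2)),
                             as.numeric),
      n_trials = task_doc$n_trials %||% 10L,
      pair_sampling = task_doc$pair_sampling %||% "uniform",
      max_gap = task_doc$max_gap %||% 7L
    ),
    reversal = reversal_task(
      p_first = task_doc$p_first %||% 0.9,
      p_second = task_doc$p_second %||% 0.2,
      block = task_doc$block %||% 20L,
      n_trials = task_doc$n_trials %||% 100L
    ),
    instructed = instructed_task(
      p_first = task_doc$p_first %||% 0.9,
      p_second = task_doc$p_second %||% 0.2,
      instructed = task_doc$instructed %||% 2L,
      n_trials = task_doc$n_trials %||% 30L
    )
  )

  model_doc <- doc$model %||% list()
  reject_unknown(model_doc, names(formals(bg_params)), "model")
  params <- do.call(bg_params, model_doc)

  exec_doc <- doc$execution %||% list()
  reject_unknown(exec_doc, c("seeds", "out_dir", "snapshot_trials"),
                 "execution")
  execution <- list(
    seeds = as.integer(exec_doc$seeds %||% 1L),
    out_dir = exec_doc$out_dir %||% ".",
    snapshot_trials = as.integer(exec_doc$snapshot_trials %||% integer(0))
  )

  structure(
    list(
      task = task,
      params = params,
      execution = execution,
      document = list(task = c(list(type = type),
                               task_doc[setdiff(names(task_doc), "type")]),
                      model = model_doc,
                      execution = exec_doc)
    ),
    class = "bg_config"
  )
}

#' Save a run configuration
#'
#' Writes the canonical document of a `bg_config` back to YAML, so that
#' [load_config()] on the result reproduces the same configuration.
#'
#' @param config A `bg_config` from [load_config()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  yaml::write_yaml(config$document, path)
  invisible(path)
}

#' Write a session trace to disk
#'
#' Produces three text artifacts in `directory`:
#'
#' * `trials.csv` — one row per trial with the pair, contingencies, side
#'   assignment, choice and feedback;
#' * `weights.csv` — long-format trajectories of every learnable weight
#'   (`trial`, `matrix`, `source`, `target`, `value`), including a trial-0
#'   row for the initial values;
#' * `provenance.json` — the task, parameters and seed that reproduce the
#'   trace.
#'
#' Floating-point values are serialized at 9 significant digits.
#'
#' @param session A `bg_session`.
#' @param directory Output directory; created if missing.
#' @return Named character vector of the written paths, invisibly.
#' @seealso [read_trace()]
#' @export
write_trace <- function(session, directory) {
  if (!dir.exists(directory)) {
    dir.create(directory, recursive = TRUE)
  }
  trials <- data.frame(
    trial = vapply(session$records, `[[`, integer(1), "trial"),
    pair_id = vapply(session$records, `[[`, integer(1), "pair_id"),
    first = vapply(session$records, function(r) as.integer(r$first),
                   integer(1)),
    second = vapply(session$records, function(r) as.integer(r$second),
                    integer(1)),
    p_first = signif(vapply(session$records, `[[`, numeric(1), "p_first"), 9),
    p_second = signif(vapply(session$records, `[[`, numeric(1), "p_second"), 9),
    side = vapply(session$records, function(r) as.integer(r$side),
                  integer(1)),
    chosen = vapply(session$records, `[[`, integer(1), "chosen"),
    rewarded = vapply(session$records, `[[`, logical(1), "rewarded")
  )
  trials_path <- file.path(directory, "trials.csv")
  utils::write.csv(trials, trials_path, row.names = FALSE)

  weight_rows <- function(trial, weights) {
    long <- function(mat, label) {
      data.frame(
        trial = trial,
        matrix = label,
        source = rownames(mat)[row(mat)],
        target = colnames(mat)[col(mat)],
        value = signif(as.vector(mat), 9)
      )
    }
    rbind(long(weights$w_in_stria, "in_stria"),
          long(weights$w_in_pmc, "in_pmc"))
  }
  wtab <- do.call(rbind, c(
    list(weight_rows(0L, session$weights_initial)),
    lapply(session$records,
           function(r) weight_rows(r$trial, r$weights_after))
  ))
  weights_path <- file.path(directory, "weights.csv")
  utils::write.csv(wtab, weights_path, row.names = FALSE)

  prov <- list(
    seed = session$seed,
    n_stimuli = session$task$n_stimuli,
    task = list(
      pairs = session$task$pairs,
      n_trials = session$task$n_trials,
      reversal_trials = session$task$reversal_trials,
      instructed = session$task$instructed,
      pair_sampling = session$task$pair_sampling,
      max_gap = session$task$max_gap
    ),
    params = unclass(session$params)
  )
  prov_path <- file.path(directory, "provenance.json")
  jsonlite::write_json(prov, prov_path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)

  invisible(c(trials = trials_path, weights = weights_path,
              provenance = prov_path))
}

#' Read a stored session trace
#'
#' Reconstructs the per-trial scalar table, the weight trajectories and the
#' provenance (task, parameters, seed) written by [write_trace()].
#'
#' @param directory Directory holding `trials.csv`, `weights.csv` and
#'   `provenance.json`.
#' @return List with `trials` (data frame), `weights` (long data frame),
#'   `task` (a `bg_task`), `params` (a [bg_params]) and `seed`.
#' @export
read_trace <- function(directory) {
  trials <- utils::read.csv(file.path(directory, "trials.csv"))
  weights <- utils::read.csv(file.path(directory, "weights.csv"))
  prov <- jsonlite::read_json(file.path(directory, "provenance.json"),
                              simplifyVector = TRUE)
  task <- bg_task(
    pairs = as.data.frame(prov$task$pairs),
    n_trials = prov$task$n_trials,
    reversal_trials = unlist(prov$task$reversal_trials),
    instructed = prov$task$instructed,
    pair_sampling = prov$task$pair_sampling,
    max_gap = prov$task$max_gap
  )
  params <- do.call(bg_params, prov$params)
  list(trials = trials, weights = weights, task = task, params = params,
       seed = prov$seed)
}

#' Write a machine-readable network-state snapshot
#'
#' Serializes one phase of one trial — every unit's activity by layer, the
#' dopamine level per striatal unit, the decision, and the active
#' input connections with their current weights — as a JSON document.
#' Activities are printed at 9 significant digits.
#'
#' @param record A `bg_trial` from [run_trial()] or a session's `records`.
#' @param phase `"minus"` or `"plus"`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_state_snapshot <- function(record, phase = c("minus", "plus"), path) {
  phase <- match.arg(phase)
  st <- record[[phase]]
  if (is.null(st)) {
    stop("the requested phase is not stored in this record", call. = FALSE)
  }
  n <- length(st$y_in)
  w <- record$weights_after
  active <- which(st$y_in == 1)
  conns <- list(
    in_stria = lapply(active, function(i) {
      list(source = paste0("in", i),
           weights = as.list(signif(w$w_in_stria[i, ], 9)))
    }),
    in_pmc = lapply(active, function(i) {
      list(source = paste0("in", i),
           weights = as.list(signif(w$w_in_pmc[i, ], 9)))
    })
  )
  snap <- list(
    trial = record$trial,
    phase = phase,
    presented = st$presented,
    chosen = st$chosen,
    rewarded = if (phase == "plus") record$rewarded else NULL,
    layers = list(
      input = st$y_in,
      pfc = st$y_pfc,
      snc = signif(st$y_snc, 9),
      striatum_go = signif(st$y_stria[seq_len(n)], 9),
      striatum_nogo = signif(st$y_stria[(n + 1L):(2L * n)], 9),
      gpe = signif(st$y_gpe, 9),
      gpi = signif(st$y_gpi, 9),
      thalamus = signif(st$y_thal, 9),
      pmc_preactivation = signif(st$x_pmc, 9),
      pmc = signif(st$y_pmc, 9),
      output = st$y_out
    ),
    connections = conns
  )
  jsonlite::write_json(snap, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

reject_unknown <- function(doc, allowed, where) {
  if (length(doc) > 0L && (is.null(names(doc)) || any(names(doc) == ""))) {
    stop(sprintf("all entries in the %s section must be named", where),
         call. = FALSE)
  }
  bad <- setdiff(names(doc), allowed)
  if (length(bad) > 0L) {
    stop(sprintf("unknown configuration key%s in %s: %s",
                 if (length(bad) > 1L) "s" else "", where,
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  invisible(doc)
}
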