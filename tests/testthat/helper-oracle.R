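# Independent straight-line transcription of the network equations,
# evaluated scalar-by-scalar with explicit loops.  Deliberately shares no
# code with the package: it is the oracle the vectorized implementation is
# checked against.
oracle_phase <- function(w_in_stria, w_in_pmc, params, y_in,
                         phase = "minus", snc_level = NULL, chosen = NULL,
                         pfc_index = NULL) {
  n <- nrow(w_in_stria)
  a <- params$a
  phi1 <- function(x) exp(-a * (1 - x)^2)
  y_pfc <- if (is.null(pfc_index)) 0 else 1

  snc <- numeric(2 * n)
  for (k in seq_len(2 * n)) snc[k] <- params$snc_tonic
  if (phase == "plus") {
    snc[chosen] <- snc_level
    snc[n + chosen] <- snc_level
  }

  y_stria <- numeric(2 * n)
  for (k in seq_len(2 * n)) {
    w_snc <- if (k <= n) 1 else -1
    s <- w_snc * snc[k]
    for (i in seq_len(n)) s <- s + w_in_stria[i, k] * y_in[i]
    if (y_pfc == 1 && k == pfc_index) s <- s + params$w_pfc_stria
    y_stria[k] <- phi1(s)
  }

  y_gpe <- numeric(n)
  for (k in seq_len(n)) y_gpe[k] <- 1 - y_stria[n + k]
  y_gpi <- numeric(n)
  for (k in seq_len(n)) {
    y_gpi[k] <- max(1 - 0.5 * y_stria[k] - 0.5 * y_gpe[k], 0)
  }
  y_thal <- numeric(n)
  for (k in seq_len(n)) y_thal[k] <- 1 - y_gpi[k]

  x_pmc <- numeric(n)
  for (k in seq_len(n)) {
    s <- 0.5 * y_thal[k]
    acc <- 0
    for (i in seq_len(n)) acc <- acc + w_in_pmc[i, k] * y_in[i]
    s <- s + 0.5 * acc
    if (y_pfc == 1 && k == pfc_index) s <- s + params$w_pfc_pmc
    x_pmc[k] <- s
  }
  m <- max(x_pmc)
  if (m > 1) for (k in seq_len(n)) x_pmc[k] <- x_pmc[k] / m
  y_pmc <- numeric(n)
  for (k in seq_len(n)) y_pmc[k] <- phi1(x_pmc[k])

  presented <- which(y_in == 1)
  if (phase == "minus") {
    best <- presented[1]
    for (j in presented) if (y_pmc[j] > y_pmc[best]) best <- j
  } else {
    best <- chosen
  }
  y_out <- numeric(n)
  y_out[best] <- 1

  list(y_stria = y_stria, y_gpe = y_gpe, y_gpi = y_gpi, y_thal = y_thal,
       x_pmc = x_pmc, y_pmc = y_pmc, y_out = y_out, chosen = best)
}

# closed-form mean of max(X, 0) for X ~ N(mu, sd^2)
censored_gaussian_mean <- function(mu, sd) {
  mu * stats::pnorm(mu / sd) + sd * stats::dnorm(mu / sd)
}

# blank network of n stimuli (all learnable weights zero)
zero_weights <- function(n) {
  bg_weights(matrix(0, n, 2 * n), matrix(0, n, n))
}

# random nonnegative weights for property tests
random_weights <- function(n, scale = 1) {
  bg_weights(matrix(stats::runif(n * 2 * n, 0, scale), n, 2 * n),
             matrix(stats::runif(n * n, 0, scale), n, n))
}

# session stub with prescribed choices/feedback, for metric definitions
fake_session <- function(task, choices, rewarded) {
  records <- lapply(seq_along(choices), function(t) {
    cur <- task_contingencies(task, t)[1L, ]
    list(trial = as.integer(t), pair_id = 1L,
         first = cur$first, second = cur$second,
         p_first = cur$p_first, p_second = cur$p_second, side = 1L,
         chosen = as.integer(choices[t]),
         rewarded = as.logical(rewarded[t]))
  })
  structure(list(task = task, params = bg_params(), seed = 0L,
                 records = records),
            class = "bg_session")
}

# compare run_phase output against the oracle on one random instance
expect_phase_matches_oracle <- function(seed, tol = 1e-12) {
  pick <- function(x) x[sample.int(length(x), 1)]  # safe scalar sampling
  set.seed(seed)
  n <- pick(2:4)
  w <- random_weights(n)
  params <- bg_params()
  y_in <- rep(0, n)
  presented <- sort(sample(n, pick(2:n)))
  y_in[presented] <- 1
  pfc <- if (stats::runif(1) < 0.3) pick(presented) else NULL
  if (stats::runif(1) < 0.5) {
    st <- run_phase(w, params, y_in, "minus", pfc_index = pfc)
    or <- oracle_phase(w$w_in_stria, w$w_in_pmc, params, y_in, "minus",
                       pfc_index = pfc)
  } else {
    chosen <- pick(presented)
    lvl <- pick(c(params$snc_burst, params$snc_dip))
    st <- run_phase(w, params, y_in, "plus", snc_level = lvl,
                    chosen = chosen, pfc_index = pfc)
    or <- oracle_phase(w$w_in_stria, w$w_in_pmc, params, y_in, "plus",
                       snc_level = lvl, chosen = chosen, pfc_index = pfc)
  }
  for (f in c("y_stria", "y_gpe", "y_gpi", "y_thal", "x_pmc", "y_pmc",
              "y_out")) {
    expect_lt(max(abs(st[[f]] - or[[f]])), tol)
  }
  expect_identical(st$chosen, as.integer(or$chosen))
}
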