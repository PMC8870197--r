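test_that("weight initialization has the right shape, signs and determinism", {
  p <- bg_params()
  set.seed(11)
  w <- init_weights(2, p)
  expect_equal(dim(w$w_in_stria), c(2L, 4L))
  expect_equal(dim(w$w_in_pmc), c(2L, 2L))
  expect_equal(length(w$w_in_stria) + length(w$w_in_pmc), 3L * 2L^2)
  expect_equal(w$w_snc_stria, c(1, 1, -1, -1))
  expect_true(all(w$w_in_stria >= 0) && all(w$w_in_pmc >= 0))
  set.seed(11)
  expect_identical(init_weights(2, p), w)
  expect_error(init_weights(0, p), "positive integer")
})

test_that("clipped-Gaussian draws match the censored-normal mean", {
  p <- bg_params()  # mean 0.05, variance 0.01 (sd 0.1)
  expected <- censored_gaussian_mean(0.05, 0.1)
  expect_equal(expected, 0.0697796557, tolerance = 1e-8)
  set.seed(5)
  w <- init_weights(60, p)  # 3 * 60^2 = 10800 draws
  draws <- c(w$w_in_stria, w$w_in_pmc)
  se <- stats::sd(draws) / sqrt(length(draws))
  expect_lt(abs(mean(draws) - expected), 4 * se)
})

test_that("the learning signal is the plus-minus activity difference", {
  w <- zero_weights(2)
  p <- bg_params()
  minus <- run_phase(w, p, c(1, 1))
  plus <- run_phase(w, p, c(1, 1), "plus", snc_level = p$snc_burst,
                    chosen = minus$chosen)
  d <- phase_difference(minus, plus)
  # chosen Go with zero drive: phi(1) - phi(0.5) after a reward
  expect_equal(d$d_stria[minus$chosen], 1 - exp(-2))
  expect_equal(round(d$d_stria[minus$chosen], 5), 0.86466)
  # units of the non-chosen stimulus saw identical drive in both phases
  other <- setdiff(1:2, minus$chosen)
  expect_identical(d$d_stria[c(other, 2 + other)], c(0, 0))
  expect_identical(phase_difference(minus, minus)$d_stria, rep(0, 4))
  expect_true(all(abs(c(d$d_stria, d$d_pmc)) <= 1))
})

test_that("the delta rule updates gated weights and clips at zero", {
  p <- bg_params()
  w <- bg_weights(matrix(0.05, 2, 4), matrix(0.01, 2, 2))
  delta <- structure(list(d_stria = c(0.2, -0.5, 0, 0),
                          d_pmc = c(0.2, -0.5)),
                     class = "bg_delta")
  up <- apply_update(w, delta, c(1, 0), p)
  expect_equal(up$w_in_stria[1, 1], 0.05 + 0.1 * 0.2)  # 0.07
  expect_equal(up$w_in_stria[1, 2], 0)                 # clipped
  expect_equal(up$w_in_pmc[1, 2], 0)                   # clipped
  # inactive input rows are untouched
  expect_identical(up$w_in_stria[2, ], w$w_in_stria[2, ])
  expect_identical(up$w_in_pmc[2, ], w$w_in_pmc[2, ])
  # ungated variant updates every row
  p_ungated <- bg_params(presynaptic_gating = FALSE)
  up2 <- apply_update(w, delta, c(1, 0), p_ungated)
  expect_equal(unname(up2$w_in_stria[2, 1]), 0.07)
})

test_that("forgetting is geometric decay of the learnable weights only", {
  p <- bg_params()
  w <- bg_weights(matrix(0.5, 2, 4), matrix(0.5, 2, 2))
  dec <- apply_forgetting(w, p)
  expect_equal(unname(dec$w_in_stria[1, 1]), 0.49)
  expect_identical(dec$w_snc_stria, w$w_snc_stria)
  expect_identical(apply_forgetting(w, bg_params(forgetting = 1)), w)
  # 20 idle trials: w0 * beta^20
  for (i in 1:20) w <- apply_forgetting(w, p)
  expect_equal(unname(w$w_in_stria[1, 1]), 0.5 * 0.98^20)
  expect_equal(round(0.98^20, 4), 0.6676)
  # memory half-life implied by the decay
  expect_equal(log(2) / log(1 / 0.98), 34.3, tolerance = 0.01)
})

test_that("nonnegativity survives adversarial updates", {
  set.seed(23)
  p <- bg_params()
  for (i in 1:30) {
    n <- sample(2:4, 1)
    w <- random_weights(n, scale = 0.3)
    delta <- structure(list(d_stria = stats::runif(2 * n, -1, 1),
                            d_pmc = stats::runif(n, -1, 1)),
                       class = "bg_delta")
    y_in <- rep(0, n)
    y_in[sample(n, sample(n, 1))] <- 1
    w <- apply_forgetting(apply_update(w, delta, y_in, p), p)
    expect_true(all(w$w_in_stria >= 0) && all(w$w_in_pmc >= 0))
  }
})
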