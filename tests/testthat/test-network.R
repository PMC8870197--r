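test_that("activation function matches its closed form and shape", {
  expect_equal(bg_phi(1, 8), 1)
  expect_equal(bg_phi(0.5, 8), exp(-2))
  expect_equal(bg_phi(0, 8), exp(-8))
  # strictly increasing below the peak, symmetric about x = 1
  x <- seq(-1, 1, by = 0.05)
  expect_true(all(diff(bg_phi(x, 8)) > 0))
  expect_equal(bg_phi(x, 8), bg_phi(2 - x, 8))
  expect_error(bg_phi(NaN, 8), "finite")
  expect_error(bg_phi(Inf, 8), "finite")
  expect_error(bg_phi(0.5, -1), "range")
})

test_that("striatal opponency under tonic dopamine", {
  w <- zero_weights(2)
  p <- bg_params()
  y <- striatum_activity(w, p, c(1, 1), rep(p$snc_tonic, 4))
  expect_equal(y[1:2], rep(exp(-2), 2))        # Go: phi(0.5)
  expect_equal(y[3:4], rep(exp(-18), 2))       # NoGo: phi(-0.5)
  expect_true(all(y[1:2] > y[3:4]))
  # burst drives a blank Go unit exactly to the activation peak
  y_burst <- striatum_activity(w, p, c(1, 1), c(1, 0.5, 0.5, 0.5))
  expect_equal(y_burst[1], 1)
  # the instruction adds drive to exactly one Go unit
  y_pfc <- striatum_activity(w, p, c(1, 1), rep(0.5, 4),
                             pfc_index = 2, y_pfc = 1)
  expect_equal(y_pfc[2], bg_phi(0.5 + p$w_pfc_stria, p$a))
  expect_equal(y_pfc[c(1, 3, 4)], y[c(1, 3, 4)])
  expect_error(striatum_activity(w, p, c(1, 1), rep(0.5, 3)), "striatal")
})

test_that("pallidal and thalamic relays follow their algebra", {
  expect_equal(gpe_activity(c(0, 1, 0.3)), c(1, 0, 0.7))
  expect_equal(gpi_activity(c(1, 0, 0), c(1, 1, 0)), c(0, 0.5, 1))
  expect_equal(thalamus_activity(c(1, 0, 0.5)), c(0, 1, 0.5))
  # clamp: GPi never goes negative on the unit square
  g <- expand.grid(go = seq(0, 1, 0.1), gpe = seq(0, 1, 0.1))
  expect_true(all(gpi_activity(g$go, g$gpe) >= 0))
  expect_error(gpe_activity(c(-0.1, 0.5)), "0, 1")
})

test_that("PMC normalization rescales only above-peak preactivations", {
  p <- bg_params()
  w <- bg_weights(matrix(0, 2, 4), matrix(c(3, 0, 1.5, 0), 2, 2))
  # thalamus zero, single active input: x = (1.5, 0.75) -> (1.0, 0.5)
  res <- pmc_activity(w, p, c(0, 0), c(1, 0))
  expect_equal(res$x, c(1, 0.5))
  expect_equal(res$y[1], 1)
  # below the peak the preactivation is untouched bit-for-bit
  w0 <- zero_weights(2)
  res0 <- pmc_activity(w0, p, c(1, 0), c(1, 1))
  expect_identical(res0$x, c(0.5, 0))
  expect_equal(res0$y, c(exp(-2), exp(-8)))
  expect_true(max(pmc_activity(random_weights(3, 2), p,
                               c(1, 0.2, 0.9), c(1, 1, 1))$x) <= 1)
})

test_that("the decision is the maximal presented PMC unit", {
  expect_equal(decide_action(c(0.8, 0.3), c(1, 2))$chosen, 1L)
  # absent stimuli are masked even when more active
  d <- decide_action(c(0.8, 0.3, 0.9), c(1, 2))
  expect_equal(d$chosen, 1L)
  expect_equal(d$y_out, c(1, 0, 0))
  # deterministic lowest-index tie break
  expect_equal(decide_action(c(0.5, 0.5), c(1, 2))$chosen, 1L)
  expect_error(decide_action(c(0.5, 0.5), integer(0)), "empty")
})

test_that("a blank network under tonic dopamine sits at its baseline state", {
  st <- run_phase(zero_weights(2), bg_params(), c(1, 1))
  expect_equal(st$y_gpi,
               rep(max(1 - 0.5 * exp(-2) - 0.5 * (1 - exp(-18)), 0), 2),
               tolerance = 1e-12)
  expect_equal(round(st$y_gpi[1], 4), 0.4323)
  expect_equal(st$chosen, 1L)  # exact tie broken toward stimulus 1
})

test_that("the plus phase routes phasic dopamine only to the chosen units", {
  w <- zero_weights(3)
  p <- bg_params()
  y_in <- c(1, 1, 0)
  st <- run_phase(w, p, y_in, "plus", snc_level = p$snc_burst, chosen = 2)
  expect_equal(st$y_snc[c(2, 5)], c(1, 1))
  expect_equal(st$y_snc[c(1, 3, 4, 6)], rep(0.5, 4))
  expect_equal(st$chosen, 2L)
  expect_equal(st$y_out, c(0, 1, 0))
  # punishment with zero weights: chosen Go falls to phi(0)
  st_dip <- run_phase(w, p, y_in, "plus", snc_level = p$snc_dip, chosen = 2)
  expect_equal(st_dip$y_stria[2], exp(-8))
  expect_error(run_phase(w, p, y_in, "plus"), "requires")
  expect_error(run_phase(w, p, y_in, "plus", snc_level = 1, chosen = 3),
               "presented")
})

test_that("forward dynamics equal the term-by-term oracle transcription", {
  for (seed in 1:100) expect_phase_matches_oracle(seed)
})

test_that("every layer activity stays in [0, 1] for arbitrary weights", {
  set.seed(71)
  for (i in 1:50) {
    n <- sample(2:4, 1)
    w <- random_weights(n, scale = 3)
    y_in <- rep(0, n)
    y_in[sample(n, 2)] <- 1
    st <- run_phase(w, bg_params(), y_in)
    acts <- c(st$y_stria, st$y_gpe, st$y_gpi, st$y_thal, st$y_pmc, st$y_out)
    expect_true(all(acts >= 0 & acts <= 1))
    expect_true(max(st$x_pmc) <= 1)
  }
})

test_that("a burst raises chosen Go activity whenever its drive is below 0.25", {
  p <- bg_params()
  for (s in seq(0, 0.24, by = 0.02)) {
    expect_gt(bg_phi(1 + s, p$a), bg_phi(0.5 + s, p$a))
  }
  # at the symmetry point the effect vanishes; beyond it, it reverses
  expect_equal(bg_phi(1.25, p$a), bg_phi(0.75, p$a))
  expect_lt(bg_phi(1.4, p$a), bg_phi(0.9, p$a))
})
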