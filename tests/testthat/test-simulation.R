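test_that("sessions have the scheduled length and are seed-deterministic", {
  demo <- pst_task(list(c(0.9, 0.2)), n_trials = 10)
  s <- run_session(demo, bg_params(), seed = 7)
  expect_length(s$records, 10L)
  expect_identical(run_session(demo, bg_params(), seed = 7), s)
  expect_false(identical(run_session(demo, bg_params(), seed = 8), s))
  expect_length(run_session(reversal_task(), seed = 1)$records, 100L)
  expect_length(run_session(instructed_task(), seed = 1)$records, 30L)
  # each record couples decision and feedback phases to the same choice
  for (r in s$records) {
    expect_identical(r$minus$chosen, r$chosen)
    expect_identical(r$plus$chosen, r$chosen)
    expect_true(all(r$weights_after$w_in_stria >= 0))
  }
})

test_that("a non-learning configuration leaves the weights untouched", {
  p <- bg_params(lr_striatum = 0, lr_pmc = 0, forgetting = 1)
  demo <- pst_task(list(c(0.9, 0.2)), n_trials = 10)
  s <- run_session(demo, p, seed = 5)
  expect_identical(s$weights_final, s$weights_initial)
})

test_that("replicates are independent of seed order and warn on duplicates", {
  demo <- pst_task(list(c(0.9, 0.2)), n_trials = 5)
  a <- run_replicates(demo, seeds = c(1, 2, 3))
  b <- run_replicates(demo, seeds = c(3, 1, 2))
  expect_identical(a[[1]], b[[2]])
  expect_identical(a[[3]], b[[1]])
  expect_warning(run_replicates(demo, seeds = c(1, 1)), "duplicate")
  expect_error(run_replicates(demo, seeds = integer(0)), "nonempty")
})

test_that("instruction biases the very first choice in most sessions", {
  # before any learning the PFC/HC drive on the instructed PMC unit
  # dominates the random initial weights
  firsts <- vapply(1:50, function(s) {
    run_session(instructed_task(n_trials = 1), seed = s)$records[[1]]$chosen
  }, integer(1))
  expect_gt(mean(firsts == 2L), 0.5)
})

test_that("switch latency measures the sustained post-reversal switch", {
  task <- bg_task(data.frame(first = 1L, second = 2L,
                             p_first = 0.9, p_second = 0.2),
                  n_trials = 10, reversal_trials = 5L)
  # switch on the 3rd trial after the last pre-reversal trial (trial 4)
  m <- compute_metrics(fake_session(task, c(1, 1, 1, 1, 1, 1, 2, 2, 2, 2),
                                    rep(TRUE, 10)))
  expect_equal(unname(m$switch_latencies["reversal_5"]), 3L)
  # an immediate switch has latency 1
  m1 <- compute_metrics(fake_session(task, c(1, 1, 1, 1, 2, 2, 2, 2, 2, 2),
                                     rep(TRUE, 10)))
  expect_equal(unname(m1$switch_latencies["reversal_5"]), 1L)
  # a transient flip that does not hold the majority window is ignored
  m2 <- compute_metrics(fake_session(task, c(1, 1, 1, 1, 2, 1, 1, 1, 1, 1),
                                     rep(TRUE, 10)))
  expect_true(is.na(m2$switch_latencies["reversal_5"]))
  # never switching within the block is an explicit NA
  m3 <- compute_metrics(fake_session(task, rep(1, 10), rep(TRUE, 10)))
  expect_true(is.na(m3$switch_latencies["reversal_5"]))
})

test_that("adherence and terminal-preference metrics follow their definitions", {
  ins <- instructed_task(n_trials = 8)
  ch <- c(2, 2, 2, 1, 1, 1, 1, 1)
  rw <- c(TRUE, FALSE, FALSE, TRUE, TRUE, TRUE, TRUE, TRUE)
  m <- compute_metrics(fake_session(ins, ch, rw))
  expect_equal(m$adherence_duration, 3L)
  expect_equal(m$preference_trial, 4L)
  expect_equal(m$punishments_before_preference, 2L)
  expect_equal(m$punishment_count, 2L)
  expect_equal(m$accuracy, 5 / 8)
  # never choosing the instructed stimulus gives zero adherence
  m0 <- compute_metrics(fake_session(ins, rep(1, 8), rep(TRUE, 8)))
  expect_equal(m0$adherence_duration, 0L)
  expect_equal(m0$preference_trial, 1L)
  # a single lapse does not break the terminal run (weak-majority suffixes)
  mlapse <- compute_metrics(fake_session(ins, c(2, 1, 1, 1, 1, 2, 1, 1),
                                         rep(TRUE, 8)))
  expect_equal(mlapse$preference_trial, 2L)
  # metrics not defined for a task are explicit NA markers
  demo <- pst_task(list(c(0.9, 0.2)), n_trials = 4)
  mdemo <- compute_metrics(fake_session(demo, c(1, 1, 1, 1), rep(TRUE, 4)))
  expect_true(is.na(mdemo$adherence_duration))
  expect_true(all(is.na(mdemo$switch_latencies)))
  expect_equal(mdemo$preference_trial, 1L)
})

test_that("replicate summaries tabulate one row per seed with medians", {
  demo <- pst_task(list(c(0.9, 0.2)), n_trials = 10)
  tab <- summarize_replicates(run_replicates(demo, seeds = 1:5))
  expect_equal(nrow(tab$per_seed), 5L)
  expect_true(all(c("seed", "accuracy", "punishment_count", "final_correct")
                  %in% names(tab$per_seed)))
  expect_true(all(c("metric", "median", "q25", "q75") %in%
                  names(tab$summary)))
  rev <- reversal_task(n_trials = 40)
  tabr <- summarize_replicates(run_replicates(rev, seeds = 1:3))
  expect_true("latency_1" %in% names(tabr$per_seed))
})
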