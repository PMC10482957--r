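test_that("PETH counting follows bin arithmetic", {
  events <- seq(10, 100, by = 10)
  p0 <- build_peth(numeric(0), events)
  expect_true(all(p0$rate == 0))
  # one spike exactly at each event: 50 Hz in the event bin before smoothing
  p1 <- build_peth(events, events, span = c(-1, 1))
  expect_equal(p1$raw_rate[which.min(abs(p1$raw_centers - 0.01))], 50)
  expect_equal(sum(p1$raw_rate > 0), 1)
  # integration: raw PETH integrates to spikes per trial
  expect_equal(sum(p1$raw_rate) * p1$bin, 1)
  expect_error(build_peth(1, numeric(0)), "non-empty")
})

test_that("PETH of a homogeneous Poisson process estimates the true rate", {
  lambda <- 10
  withr::with_seed(13, {
    n_sp <- stats::rpois(1, lambda * 3000)
    spikes <- sort(stats::runif(n_sp, 0, 3000))
  })
  events <- seq(5, 2995, by = 6)[1:500]
  p <- build_peth(spikes, events, span = c(-1, 1))
  se <- sqrt(lambda / (500 * 2))
  expect_lt(abs(mean(p$raw_rate) - lambda), 3 * se)
  # smoothing preserves the mean rate over the span
  expect_equal(mean(p$rate), mean(p$raw_rate), tolerance = 0.02)
})

test_that("window rates and z-scoring follow their definitions", {
  s <- make_session(rep("push", 6), rep(TRUE, 6))
  go <- s$trials$go_time
  # two spikes inside each Go window of trial 1..3, none elsewhere
  spikes <- sort(c(go[1:3] + 0.05, go[1:3] + 0.25))
  ws <- unit_window_stats(spikes, s)
  expect_equal(ws$rates$go, c(2, 2, 2, 0, 0, 0) / 0.3)
  expect_equal(ws$rates$baseline, rep(0, 6))
  expect_false(ws$z_defined) # baseline SD is zero
  expect_true(all(is.na(ws$z$go)))
})

test_that("task-relatedness rank-sum test has the designed power and null behavior", {
  base <- rep(2, 50)
  rates <- data.frame(baseline = base, go = base, movement = base,
                      outcome = base)
  res <- task_related_test(rates)
  expect_true(res$testable)
  expect_false(res$task_related)
  # doubled Poisson rate in the go window, 200 trials: essentially always detected
  withr::with_seed(19, {
    hits <- replicate(20, {
      r2 <- data.frame(baseline = stats::rpois(200, 2 * 1) / 1,
                       go = stats::rpois(200, 4 * 0.3) / 0.3,
                       movement = stats::rpois(200, 2 * 0.3) / 0.3,
                       outcome = stats::rpois(200, 2 * 0.5) / 0.5)
      tt <- task_related_test(r2)
      tt$task_related && tt$table$significant[tt$table$window == "go"]
    })
  })
  expect_gte(mean(hits), 0.99)
  expect_false(task_related_test(rates[1, ])$testable)
})

test_that("action preference applies the 5% relative-difference rule", {
  expect_equal(action_preference(rep(10, 20), rep(9, 20)), "push")
  expect_equal(action_preference(rep(9, 20), rep(10, 20)), "pull")
  expect_equal(action_preference(rep(10, 20), rep(9.8, 20)), "none")
  expect_equal(action_preference(rep(0, 5), rep(0, 5)), "none")
  expect_error(action_preference(numeric(0), 1), "at least one")
})

test_that("reward-rate correlation recovers a planted slope and excludes degenerates", {
  withr::with_seed(21, {
    rr <- sample(seq(0, 1, by = 0.2), 300, replace = TRUE)
    z <- 2 * rr + stats::rnorm(300, 0, 0.1)
  })
  res <- reward_rate_correlation(z, rr)
  expect_gt(res$r, 0.9)
  expect_lt(res$p, 1e-10)
  expect_false(res$excluded)
  # constant activity is excluded
  expect_true(reward_rate_correlation(rep(1, 50), rr[1:50])$excluded)
  # undefined reward rates are dropped from n
  rr2 <- c(rep(NA, 5), rr[6:300])
  expect_equal(reward_rate_correlation(z, rr2)$n, 295)
  expect_true(reward_rate_correlation(z[1:3], rr[1:3])$excluded)
})

test_that("population r test is signed-rank against zero", {
  expect_lt(population_r_test(rep(0.3, 20))$p, 0.05)
  expect_error(population_r_test(0.5), "at least 5")
  withr::with_seed(22, r_null <- stats::rnorm(40, 0, 0.1))
  expect_gt(population_r_test(r_null)$p, 0.05)
  deg <- population_r_test(rep(0.2, 10))
  expect_true(deg$flagged)
})

test_that("Fisher z comparison matches its closed form and caps the Bonferroni p", {
  expect_equal(fisher_z_compare(0.4, 30, 0.4, 50)$z, 0)
  expect_equal(fisher_z_compare(0.4, 30, 0.4, 50)$p, 1)
  res <- fisher_z_compare(0.5, 50, 0, 50)
  z_oracle <- (atanh(0.5) - atanh(0)) / sqrt(1 / 47 + 1 / 47)
  expect_equal(res$z, z_oracle, tolerance = 1e-12)
  expect_equal(res$p, 2 * (1 - stats::pnorm(abs(z_oracle))), tolerance = 1e-12)
  # Bonferroni cap at 1
  res2 <- fisher_z_compare(0.31, 50, 0.3, 50, m_comparisons = 3)
  expect_gt(res2$p, 1 / 3)
  expect_equal(res2$p_adjusted, 1)
  expect_error(fisher_z_compare(1, 50, 0, 50), "diverges")
  expect_error(fisher_z_compare(0.5, 3, 0, 50), "exceed 3")
})

test_that("outcome contrast flags only genuinely different bins", {
  ev_r <- seq(10, 300, by = 10)
  ev_n <- seq(310, 600, by = 10)
  # identical response at every event: empty mask
  spikes0 <- sort(c(outer(c(ev_r, ev_n), c(0.05, 0.15, 0.25), `+`)))
  res0 <- outcome_contrast(spikes0, ev_r, ev_n)
  expect_false(any(res0$significant))
  # strong extra outcome response after rewarded events only
  withr::with_seed(23, {
    bg <- sort(stats::runif(3000, 0, 650)) # ~4.6 Hz background
    extra <- unlist(lapply(ev_r, function(e) e + stats::runif(15, 0, 0.5)))
  })
  res1 <- outcome_contrast(sort(c(bg, extra)), ev_r, ev_n)
  in_win <- res1$bin_centers > 0 & res1$bin_centers < 0.5
  expect_gt(mean(res1$significant[in_win]), 0.8)
  expect_lt(mean(res1$significant[!in_win]), 0.1)
  expect_error(outcome_contrast(spikes0, ev_r[1], ev_n), "at least 2")
})
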