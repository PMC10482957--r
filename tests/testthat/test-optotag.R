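test_that("response-window search finds the dissociation and prefers the wider run", {
  fs <- 20000
  si <- 200
  n <- 1200
  withr::with_seed(8, {
    base <- stats::rnorm(n, 0, 0.5)
    ctrl <- base + 0
    tst <- base + 0
    # control-only spike at 12 ms: 240 samples post-stim
    ctrl[(si + 230):(si + 250)] <- ctrl[(si + 230):(si + 250)] - 40
  })
  win <- find_response_window(ctrl, tst, fs, si)
  expect_lte(win["start"], 12)
  expect_gte(win["end"], 12)
  expect_error(find_response_window(tst, tst, fs, si),
               "no candidate antidromic response")
  # two dissociation intervals: the wider one wins (brute-force over runs)
  ctrl2 <- tst
  ctrl2[(si + 60):(si + 64)] <- ctrl2[(si + 60):(si + 64)] + 30   # 5 samples
  ctrl2[(si + 300):(si + 308)] <- ctrl2[(si + 300):(si + 308)] - 30 # 9 samples
  win2 <- find_response_window(ctrl2, tst, fs, si)
  d <- abs(ctrl2 - tst)
  thr <- 3 * stats::sd((ctrl2 - tst)[1:(si - 1)])
  runs <- rle(d[(si + 1):(si + 500)] > thr)
  widest <- max(runs$lengths[runs$values])
  expect_equal((win2["end"] - win2["start"]) / 1000 * fs, widest,
               ignore_attr = TRUE)
  expect_gte(win2["start"], 300 / fs * 1000 - 0.1)
})

test_that("ROC cutoff maximises Youden's J and matches an exhaustive scan", {
  r <- roc_spike_cutoff(c(-10, -9), c(-1, 0))
  expect_equal(r$threshold, -5)
  expect_equal(r$J, 1)
  expect_false(r$flagged)
  # identical distributions are degenerate
  r2 <- roc_spike_cutoff(c(-3, -2, -1), c(-3, -2, -1))
  expect_true(r2$flagged)
  # oracle equivalence on random instances: scan every possible threshold
  withr::with_seed(12, {
    for (i in 1:25) {
      spk <- stats::rnorm(30, -8, 2)
      noi <- stats::rnorm(40, -2, 2)
      res <- roc_spike_cutoff(spk, noi)
      cand <- sort(c(unique(c(spk, noi)),
                     unique(c(spk, noi)) - 1e-9, unique(c(spk, noi)) + 1e-9))
      J_all <- vapply(cand, function(th) {
        mean(spk < th) + mean(noi >= th) - 1
      }, numeric(1))
      expect_equal(res$J, max(J_all), tolerance = 1e-12)
    }
  })
})

test_that("spike-count test matches the textbook chi-square formula", {
  res <- spike_count_test(45, 50, 4, 50)
  a <- 45; b <- 5; c <- 4; d <- 46; n <- 100
  chi2 <- n * (a * d - b * c)^2 / ((a + b) * (c + d) * (a + c) * (b + d))
  expect_equal(res$statistic, chi2, tolerance = 1e-12)
  expect_equal(res$p, stats::pchisq(chi2, df = 1, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_false(res$flagged)
  # small expected counts fall back to the exact test, flagged
  res2 <- spike_count_test(3, 10, 1, 10)
  expect_true(res2$flagged)
  expect_equal(res2$method, "fisher_exact")
})

test_that("collision test identifies a true antidromic unit", {
  ens <- gen_collision_ensemble(collision_spec(antidromic = TRUE,
                                               conduction_latency_ms = 12,
                                               latency_jitter_ms = 0.1),
                                50, 50, seed = 2)
  res <- collision_test(ens)
  expect_true(res$passed)
  expect_gt(res$p_control, 0.5)
  expect_lt(res$p_test, res$p_control / 2)
  expect_lt(res$chi2_p, 0.05)
  expect_equal(res$latency_ms, 12, tolerance = 0.05)
  expect_lt(res$jitter_ms, 0.5)
})

test_that("collision test rejects non-projecting and partially colliding units", {
  ens <- gen_collision_ensemble(collision_spec(antidromic = FALSE), 50, 50,
                                seed = 3)
  expect_false(collision_test(ens)$passed)
  # collisions that mostly fail leave the evoked spike in test trials, so
  # either the dissociation never qualifies or the probability ratio fails
  ens2 <- gen_collision_ensemble(collision_spec(collision_fidelity = 0.2),
                                 50, 50, seed = 4)
  res2 <- collision_test(ens2)
  expect_false(res2$passed)
  if (!is.na(res2$p_test)) expect_gte(res2$p_test, res2$p_control / 2)
  # buried in noise: graceful non-identification, not an error
  ens3 <- gen_collision_ensemble(collision_spec(noise_sd = 1e5), 30, 30,
                                 seed = 5)
  res3 <- collision_test(ens3)
  expect_false(res3$passed)
  expect_equal(res3$reason, "no candidate antidromic response")
})

test_that("zero-jitter conduction gives quartile jitter exactly zero", {
  ens <- gen_collision_ensemble(collision_spec(latency_jitter_ms = 0),
                                30, 30, seed = 6)
  res <- collision_test(ens)
  expect_equal(res$jitter_ms, 0)
  expect_equal(res$latency_ms, 12, tolerance = 0.05)
})

test_that("collision verdict is invariant to channel permutation and scaling", {
  ens <- gen_collision_ensemble(collision_spec(), 30, 30, seed = 7)
  res <- collision_test(ens)
  perm <- c(3, 1, 4, 2)
  ens2 <- stim_trial_ensemble(ens$control_traces[, perm, ] * 5,
                              ens$test_traces[, perm, ] * 5,
                              fs = ens$fs, stim_index = ens$stim_index)
  res2 <- collision_test(ens2)
  expect_equal(res2$passed, res$passed)
  expect_equal(res2$window, res$window)
  expect_equal(res2$latency_ms, res$latency_ms)
})

test_that("direct tagging applies waveform, latency and pathway criteria", {
  withr::with_seed(9, wf <- matrix(stats::rnorm(4 * 61), nrow = 4))
  wf[2, 31] <- -40 # dominant peak mid-waveform
  lat5 <- rep(c(4.9, 5.0, 5.1), 10)
  res <- direct_tag(wf, lat5, wf, pathway = "striatonigral")
  expect_equal(res$waveform_r, 1)
  expect_true(res$passed)
  res_flip <- direct_tag(-wf, lat5, wf, pathway = "striatonigral")
  expect_equal(res_flip$waveform_r, -1)
  expect_false(res_flip$passed)
  # latency 9 ms fails the striatonigral limit but passes striatopallidal
  lat9 <- rep(c(8.9, 9.0, 9.1), 10)
  expect_false(direct_tag(wf, lat9, wf, pathway = "striatonigral")$passed)
  expect_true(direct_tag(wf, lat9, wf, pathway = "striatopallidal")$passed)
  # excessive jitter fails
  expect_false(direct_tag(wf, c(rep(2, 15), rep(6, 15)), wf,
                          pathway = "striatonigral")$passed)
  expect_error(direct_tag(wf[1:3, , drop = FALSE], lat5,
                          wf[1:3, , drop = FALSE]), "4 channels")
})

test_that("frequency-following and evoked-energy helpers behave", {
  ff <- frequency_following_test(rep(TRUE, 10), c(rep(TRUE, 6), rep(FALSE, 4)))
  expect_true(ff$passed)
  expect_equal(ff$p2, 0.6)
  expect_false(frequency_following_test(rep(TRUE, 10),
                                        rep(c(TRUE, FALSE), 5))$passed)
  expect_error(frequency_following_test(logical(0), logical(0)), "trials")
  expect_equal(evoked_energy(matrix(c(1, -2, 2, 0), 2)), 9)
})
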