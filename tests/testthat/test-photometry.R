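test_that("decay removal recovers exponential + linear parameters on clean input", {
  t <- seq(0, 600, by = 0.01)
  x <- 100 * exp(-t / 300) - 0.01 * t + 50
  fit <- remove_decay(x, fs = 100)
  expect_equal(unname(fit$coefficients["a"]), 100, tolerance = 0.01)
  expect_equal(unname(fit$coefficients["tau"]), 300, tolerance = 0.01)
  expect_equal(unname(fit$coefficients["b"]), -0.01, tolerance = 0.01)
  expect_lt(max(abs(fit$detrended)), 1e-3)
})

test_that("decay removal of a constant leaves a ~zero residual", {
  fit <- remove_decay(rep(7.5, 5000), fs = 1000)
  expect_lt(max(abs(fit$detrended)), 1e-8)
})

test_that("decay removal preserves injected transient amplitudes within 5%", {
  fs <- 100
  t <- seq(0, 400, by = 1 / fs)
  decay <- 80 * exp(-t / 250) - 0.02 * t + 100
  kern <- function(lag) ifelse(lag >= 0 & lag < 5,
                               (1 - exp(-lag / 0.05)) * exp(-lag / 0.4), 0)
  pk <- max(kern(seq(0, 2, by = 1e-3)))
  events <- seq(20, 380, by = 8)
  transients <- Reduce(`+`, lapply(events, function(e) 5 * kern(t - e) / pk))
  fit <- remove_decay(decay + transients, fs = fs)
  # peak height of the detrended trace relative to its local pre-event level
  peaks <- vapply(events, function(e) {
    i <- which(t >= e & t < e + 2)
    j <- which(t >= e - 2 & t < e)
    max(fit$detrended[i]) - mean(fit$detrended[j])
  }, numeric(1))
  expect_lt(abs(mean(peaks) - 5) / 5, 0.05)
})

test_that("isosbestic dF/F obeys its closed forms", {
  withr::with_seed(5, x <- 100 + stats::rnorm(2000))
  expect_equal(isosbestic_dff(x, x), rep(0, 2000))
  # ratio invariance under common scaling
  withr::with_seed(6, {
    iso <- 80 + stats::rnorm(2000)
    sig <- 100 + 0.5 * (iso - 80) + stats::rnorm(2000, 0, 0.1)
  })
  expect_equal(isosbestic_dff(sig, iso), isosbestic_dff(3 * sig, 3 * iso),
               tolerance = 1e-10)
  # flat isosbestic at F0, one transient of height h: peak ~= h / F0
  n <- 10000
  sig2 <- rep(50, n)
  sig2[5000] <- 50 + 8
  dff <- isosbestic_dff(sig2, rep(50, n))
  expect_equal(max(dff), 8 / 50, tolerance = 2e-3)
  expect_equal(which.max(dff), 5000)
  # fitted values crossing zero abort the division
  ramp <- seq(-1, 1, length.out = 101)
  expect_error(isosbestic_dff(ramp, ramp), "unstable")
})

test_that("block-mean downsampling follows its arithmetic", {
  expect_equal(downsample(rep(3.2, 1000), 1000, 40), rep(3.2, 40))
  # alternating +/-1 cancels exactly over even blocks ...
  expect_equal(downsample(rep(c(1, -1), 500), 1000, 50), rep(0, 50))
  # ... and leaves the odd sample over 25-sample blocks
  expect_equal(downsample(rep(c(1, -1), 500), 1000, 40),
               rep(c(1, -1) / 25, 20))
  imp <- c(1, rep(0, 999))
  expect_equal(downsample(imp, 1000, 40)[1], 1 / 25)
  expect_error(downsample(1:10, 1000, 300), "integer multiple")
})

test_that("event alignment equals direct index arithmetic", {
  x <- seq_len(400) / 10
  mat <- align_to_events(x, events = 5, window = c(1, 2), fs = 40, t0 = 0)
  i0 <- 5 * 40 + 1
  expect_equal(unname(mat[1, ]), x[(i0 - 40):(i0 + 80)])
  tm <- attr(mat, "time")
  expect_equal(tm[41], 0)
  # constant signal gives a constant matrix
  m2 <- align_to_events(rep(2, 400), events = c(3, 5), window = c(1, 1),
                        fs = 40, t0 = 0)
  expect_true(all(m2 == 2))
  # out-of-span events are dropped with a warning
  expect_warning(
    m3 <- align_to_events(x, events = c(5, 9.9), window = c(1, 2), fs = 40,
                          t0 = 0),
    "dropped")
  expect_equal(nrow(m3), 1)
  expect_error(align_to_events(x, numeric(0), fs = 40), "empty")
})

test_that("window values average the named interval per trial", {
  mat <- matrix(1, nrow = 3, ncol = 5)
  attr(mat, "time") <- seq(-0.1, 0.3, by = 0.1)
  expect_equal(window_values(mat, c(0, 0.3)), rep(1, 3))
  mat2 <- matrix(c(0, 1), nrow = 1, ncol = 2)
  attr(mat2, "time") <- c(0, 0.1)
  expect_equal(window_values(mat2, c(0, 0.2)), 0.5)
  expect_error(window_values(mat, c(2, 3)), "outside")
})

test_that("full chain recovers injected dF/F transients within 10%", {
  s <- run_session(n_trials = 60, seed = 3)
  spec <- photometry_spec(amplitude = c(movement = 0.05, go = 0,
                                        outcome_reward = 0,
                                        outcome_noreward = 0),
                          noise_sd = 0.2)
  ns <- process_photometry(gen_photometry(spec, s, seed = 5))
  al <- align_to_events(ns, s$trials$movement_onset_time,
                        window = c(0.5, 1), channel = "dff")
  avg <- colMeans(al)
  tm <- attr(al, "time")
  peak <- max(avg) - mean(avg[tm < -0.1])
  expect_lt(abs(peak - 0.05) / 0.05, 0.10)
  # z-scored trace is standardised over the session
  expect_equal(mean(ns$z), 0, tolerance = 1e-10)
  expect_equal(stats::sd(ns$z), 1, tolerance = 1e-10)
})

test_that("processing a flat trace introduces no spurious structure", {
  tr <- photometry_trace(rep(200, 20000), rep(160, 20000), fs = 1000)
  ns <- process_photometry(tr)
  expect_lt(max(abs(ns$dff)), 1e-6)
})
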