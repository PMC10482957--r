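test_that("reward rate uses only the previous five trials", {
  rr <- compute_reward_rate(c(TRUE, FALSE, TRUE, FALSE, FALSE, TRUE))
  expect_true(all(is.na(rr[1:5])))
  expect_equal(rr[6], 0.4) # 2 of the previous 5
  expect_equal(compute_reward_rate(c(rep(TRUE, 5), FALSE))[6], 1.0)
  expect_equal(compute_reward_rate(c(rep(FALSE, 5), TRUE))[6], 0.0)
  expect_true(is.na(attr(compute_reward_rate(rep(TRUE, 4)), "valid_from")))
})

test_that("reward rate lies on the 6-point grid and shifts with the sequence", {
  withr::with_seed(3, {
    for (rep in 1:5) {
      x <- stats::runif(60) < 0.5
      rr <- compute_reward_rate(x)
      ok <- !is.na(rr)
      expect_true(all(abs(rr[ok] * 5 - round(rr[ok] * 5)) < 1e-12))
      # no leakage of the current outcome: prepending one trial shifts the series
      rr2 <- compute_reward_rate(c(FALSE, x))
      expect_equal(rr2[-1][ok], rr[ok])
    }
  })
})

test_that("choice regression attains the brute-force likelihood optimum", {
  # 12-trial hand-built session, one-lag model; oracle = grid scan of the
  # independent likelihood implementation
  ch <- c("push", "push", "pull", "push", "pull", "pull", "push", "push",
          "pull", "push", "push", "pull")
  rw <- c(TRUE, FALSE, TRUE, TRUE, FALSE, TRUE, TRUE, TRUE, FALSE, FALSE,
          TRUE, FALSE)
  s <- make_session(ch, rw)
  fit <- fit_choice_regression(s, n_past = 1)
  grid <- seq(-4, 4, length.out = 51)
  best <- -Inf
  for (br in grid) for (bn in grid) {
    ll <- vapply(grid, function(b0) {
      session_loglik(s$trials, br, bn, b0, n_past = 1)
    }, numeric(1))
    best <- max(best, max(ll))
  }
  expect_gte(fit$log_lik + 1e-8, best)
  # and the glm solution itself scores the same under the oracle likelihood
  expect_equal(session_loglik(s$trials, fit$beta_reward, fit$beta_noreward,
                              fit$beta0, 1),
               fit$log_lik, tolerance = 1e-8)
})

test_that("choice regression is invariant to push/pull relabelling", {
  s <- run_session(n_trials = 1500, seed = 21)
  f1 <- fit_choice_regression(s, n_past = 4)
  flipped <- s
  swap <- c(push = "pull", pull = "push")
  flipped$trials$choice <- unname(swap[flipped$trials$choice])
  f2 <- fit_choice_regression(flipped, n_past = 4)
  expect_equal(f1$beta_reward, f2$beta_reward, tolerance = 1e-6)
  expect_equal(f1$beta_noreward, f2$beta_noreward, tolerance = 1e-6)
  expect_equal(f1$beta0, -f2$beta0, tolerance = 1e-6)
})

test_that("perfect predictability is flagged as separation, not silently fit", {
  # deterministic win-stay/lose-switch agent: the one-lag model predicts
  # every choice exactly, so the likelihood has no finite optimum
  withr::with_seed(1, {
    n <- 120
    ch <- character(n)
    rw <- stats::runif(n) < 0.5
    ch[1] <- "push"
    for (i in 2:n) {
      ch[i] <- if (rw[i - 1]) ch[i - 1] else setdiff(c("push", "pull"), ch[i - 1])
    }
  })
  fit <- fit_choice_regression(make_session(ch, rw), n_past = 1)
  expect_true(fit$separation)
})

test_that("switch probability tables reflect the acting policy", {
  # always-repeat agent
  ch <- rep("push", 80)
  withr::with_seed(2, rw <- stats::runif(80) < 0.6)
  tab <- switch_probability_by_reward_rate(make_session(ch, rw))
  expect_true(all(tab$p_switch[tab$n > 0] == 0))
  expect_true(all(is.na(tab$p_switch[tab$n == 0])))
  # strict win-stay/lose-switch agent
  withr::with_seed(4, {
    ch2 <- character(120)
    rw2 <- logical(120)
    ch2[1] <- "push"
    rw2[1] <- TRUE
    for (i in 2:120) {
      ch2[i] <- if (rw2[i - 1]) ch2[i - 1] else setdiff(c("push", "pull"), ch2[i - 1])
      rw2[i] <- stats::runif(1) < 0.5
    }
  })
  tab2 <- switch_probability_by_reward_rate(make_session(ch2, rw2))
  expect_true(all(tab2$p_switch[tab2$n > 0 & tab2$outcome == "nonrewarded"] == 1))
  expect_true(all(tab2$p_switch[tab2$n > 0 & tab2$outcome == "rewarded"] == 0))
})

test_that("lose-switch probability declines with reward rate for the stay-biased agent", {
  s <- run_session(n_trials = 4000, seed = 31)
  tab <- switch_probability_by_reward_rate(s)
  nr <- tab[tab$outcome == "nonrewarded" & tab$n >= 20, ]
  expect_gte(nrow(nr), 4)
  expect_lt(stats::cor(nr$reward_rate, nr$p_switch, method = "spearman"), 0)
  # and at matched reward rate, switching is likelier after no reward
  merged <- merge(tab[tab$outcome == "rewarded", ],
                  tab[tab$outcome == "nonrewarded", ],
                  by = "reward_rate", suffixes = c("_r", "_n"))
  merged <- merged[merged$n_r >= 20 & merged$n_n >= 20, ]
  expect_true(all(merged$p_switch_n > merged$p_switch_r))
})

test_that("movement onset detection handles flat, step and ramp trajectories", {
  withr::with_seed(11, base <- stats::rnorm(100))
  mu <- mean(base)
  sigma <- stats::sd(base)
  # flat at baseline mean: never crosses
  flat <- c(base, rep(mu, 200))
  res <- detect_movement_onset(flat, 1:100, go_index = 100)
  expect_false(res$detected)
  expect_true(is.na(res$onset))
  # noiseless step of 10 SD at sample 151 crosses immediately
  stepped <- c(base, rep(mu, 50), rep(mu + 10 * sigma, 100))
  res2 <- detect_movement_onset(stepped, 1:100, go_index = 100)
  expect_equal(res2$onset, 151)
  # target zone entry gives the movement time
  res3 <- detect_movement_onset(stepped, 1:100, go_index = 100,
                                target_zone = c(mu + 5 * sigma, Inf))
  expect_equal(res3$target_index, 151)
})

test_that("ramp onset is localised within 3 samples (median over replicates)", {
  t0 <- 40
  withr::with_seed(17, {
    errs <- replicate(200, {
      hold <- stats::rnorm(100)
      post <- stats::rnorm(200)
      post[t0:200] <- post[t0:200] + 5 * (seq_len(200 - t0 + 1))
      res <- detect_movement_onset(c(hold, post), 1:100, go_index = 100)
      res$onset - 100 - t0
    })
  })
  expect_lte(abs(stats::median(errs)), 3)
})

test_that("onset false-alarm rate on pure noise is at most 1%", {
  withr::with_seed(23, {
    fa <- replicate(1000, {
      x <- stats::rnorm(400)
      detect_movement_onset(x, 1:100, go_index = 100)$detected
    })
  })
  expect_lte(mean(fa), 0.01)
})
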