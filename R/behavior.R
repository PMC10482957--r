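#' Trailing reward rate
#'
#' The reward rate at trial i is the number of rewards obtained over the
#' `window` trials immediately preceding i (the current trial is excluded),
#' divided by `window`. With the default window of 5 the value lies on the
#' grid 0, 0.2, ..., 1. Trials without a full history are `NA`.
#'
#' @param outcomes Logical (or 0/1) vector of per-trial reward outcomes.
#' @param window History length; default 5.
#' @return Numeric vector of the same length as `outcomes`, `NA` for the first
#'   `window` trials, with attribute `valid_from` giving the first defined
#'   1-based index (`NA` when the sequence is shorter than the window).
#' @export
#' @examples
#' compute_reward_rate(c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE))
compute_reward_rate <- function(outcomes, window = 5L) {
  window <- as.integer(window)
  if (window < 1L) stop("window must be >= 1")
  x <- as.numeric(outcomes)
  n <- length(x)
  out <- rep(NA_real_, n)
  if (n > window) {
    cs <- c(0, cumsum(x))
    i <- (window + 1L):n
    out[i] <- (cs[i] - cs[i - window]) / window
  }
  attr(out, "valid_from") <- if (n > window) window + 1L else NA_integer_
  out
}

#' Fit the choice-on-recent-outcomes logistic regression
#'
#' Maximum-likelihood logistic regression of the push choice on the signed
#' outcome regressors of the preceding `n_past` trials (coding as in
#' [choice_regressors()]). The first `n_past` trials, which lack a full
#' history, are excluded from the fit.
#'
#' @param session A `session_log`, or a data frame with `choice` and
#'   `rewarded` columns.
#' @param n_past Number of past trials in the model; default 8.
#' @return Object of class `choice_fit`: coefficient vectors `beta_reward`,
#'   `beta_noreward`, scalar `beta0`, matching `se_*`/`p_*` (Wald),
#'   `n_trials_used`, `log_lik`, and a `separation` flag set when the fit is
#'   (quasi-)separated and coefficients are unreliable.
#' @export
fit_choice_regression <- function(session, n_past = 8L) {
  trials <- if (inherits(session, "session_log")) session$trials else session
  n_past <- as.integer(n_past)
  n <- nrow(trials)
  if (n <= n_past + 1L) stop("session must have more than n_past + 1 trials")
  if (length(unique(trials$choice)) < 2L) {
    stop("both choices must be represented in the session")
  }
  rows <- (n_past + 1L):n
  X <- t(vapply(rows, function(i) {
    choice_regressors(trials$choice[seq_len(i - 1L)],
                      trials$rewarded[seq_len(i - 1L)], n_past)
  }, numeric(2L * n_past)))
  colnames(X) <- c(paste0("reward_lag", seq_len(n_past)),
                   paste0("noreward_lag", seq_len(n_past)))
  y <- as.integer(trials$choice[rows] == "push")
  dat <- data.frame(y = y, X)
  sep <- FALSE
  fit <- withCallingHandlers(
    stats::glm(y ~ ., family = stats::binomial(), data = dat),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1|did not converge",
                conditionMessage(w))) {
        sep <<- TRUE
        invokeRestart("muffleWarning")
      }
    }
  )
  cf <- summary(fit)$coefficients
  if (any(abs(cf[, "Estimate"]) > 15) || any(cf[, "Std. Error"] > 100)) sep <- TRUE
  est <- cf[, "Estimate"]; se <- cf[, "Std. Error"]; p <- cf[, "Pr(>|z|)"]
  ir <- 1L + seq_len(n_past)
  inr <- 1L + n_past + seq_len(n_past)
  structure(list(
    beta_reward = unname(est[ir]), beta_noreward = unname(est[inr]),
    beta0 = unname(est[1L]),
    se_reward = unname(se[ir]), se_noreward = unname(se[inr]),
    se0 = unname(se[1L]),
    p_reward = unname(p[ir]), p_noreward = unname(p[inr]),
    p0 = unname(p[1L]),
    n_past = n_past, n_trials_used = length(y),
    log_lik = as.numeric(stats::logLik(fit)),
    separation = sep
  ), class = "choice_fit")
}

#' @export
print.choice_fit <- function(x, ...) {
  cat("Choice regression (n_past =", x$n_past, ",", x$n_trials_used, "trials)\n")
  if (x$separation) cat("  WARNING: (quasi-)separated fit; coefficients unreliable\n")
  tab <- data.frame(lag = seq_len(x$n_past),
                    beta_reward = round(x$beta_reward, 3),
                    beta_noreward = round(x$beta_noreward, 3))
  print(tab, row.names = FALSE)
  cat(sprintf("  intercept %.3f, logLik %.2f\n", x$beta0, x$log_lik))
  invisible(x)
}

#' Switch probability by reward rate and current outcome
#'
#' For every combination of reward-rate level (the six grid values for a
#' 5-trial window) and current-trial outcome, the proportion of trials whose
#' next-trial choice differed from the current choice. Trials without a
#' defined reward rate or without a following trial are excluded. Empty cells
#' are reported with `NA` probability, not 0.
#'
#' @param session A `session_log` or a trial data frame with `choice` and
#'   `rewarded`.
#' @param window Reward-rate history length; default 5.
#' @return Data frame with columns `reward_rate`, `outcome`
#'   (`"rewarded"`/`"nonrewarded"`), `n`, `p_switch`.
#' @export
switch_probability_by_reward_rate <- function(session, window = 5L) {
  trials <- if (inherits(session, "session_log")) session$trials else session
  n <- nrow(trials)
  rr <- compute_reward_rate(trials$rewarded, window)
  levels_rr <- seq(0, 1, by = 1 / window)
  grid <- expand.grid(reward_rate = levels_rr,
                      outcome = c("rewarded", "nonrewarded"),
                      stringsAsFactors = FALSE)
  grid$n <- 0L
  grid$p_switch <- NA_real_
  if (n >= 2L) {
    i <- which(!is.na(rr) & seq_len(n) < n)
    sw <- trials$choice[i + 1L] != trials$choice[i]
    oc <- ifelse(trials$rewarded[i], "rewarded", "nonrewarded")
    for (k in seq_len(nrow(grid))) {
      sel <- abs(rr[i] - grid$reward_rate[k]) < 1e-9 & oc == grid$outcome[k]
      grid$n[k] <- sum(sel)
      if (any(sel)) grid$p_switch[k] <- mean(sw[sel])
    }
  }
  grid
}

#' Detect movement onset in a lever trajectory by CUSUM
#'
#' Baseline mean and SD are taken from the hold interval; a one-sided CUSUM
#' of absolute deviations from the baseline mean, reset at the Go sample, is
#' compared against a bound of `n_sd` baseline SDs:
#' `S_t = max(0, S_{t-1} + |x_t - mu| - k_ref * sigma)`, onset at the first
#' sample after Go with `S_t > n_sd * sigma`. The reference offset `k_ref`
#' controls how much ordinary noise is discounted before the sum can grow; at
#' the default of 2 baseline SDs the detector's false-alarm rate on pure
#' noise is well below 1% over hold-period-length windows, while a genuine
#' lever movement (many SDs of sustained deviation) still crosses the bound
#' within a sample or two of onset.
#'
#' @param trajectory Numeric vector, uniformly sampled lever position.
#' @param hold_interval Integer indices of the hold (baseline) period.
#' @param go_index Sample index of the Go cue; accumulation starts at the next
#'   sample. Defaults to the last hold sample.
#' @param n_sd Bound in baseline SDs; default 3.
#' @param k_ref Reference offset in baseline SDs subtracted from each
#'   deviation before accumulation; default 2.
#' @param target_zone Optional numeric `c(lo, hi)`; if given, `target_index`
#'   is the first post-onset sample with position inside the zone, and
#'   `movement_samples = target_index - onset`.
#' @return List with `detected` (logical), `onset` (sample index, `NA` when
#'   the bound is never crossed — "no movement detected"),
#'   `reaction_samples`, `target_index`, `movement_samples`, `baseline_mean`,
#'   `baseline_sd`.
#' @export
detect_movement_onset <- function(trajectory, hold_interval,
                                  go_index = max(hold_interval),
                                  n_sd = 3, target_zone = NULL, k_ref = 2) {
  if (length(hold_interval) == 0L) stop("hold_interval must be non-empty")
  base <- trajectory[hold_interval]
  mu <- mean(base)
  sigma <- stats::sd(base)
  if (is.na(sigma)) sigma <- 0
  n <- length(trajectory)
  onset <- NA_integer_
  s <- 0
  t <- go_index + 1L
  while (t <= n) {
    s <- max(0, s + abs(trajectory[t] - mu) - k_ref * sigma)
    if (s > n_sd * sigma) {
      onset <- t
      break
    }
    t <- t + 1L
  }
  target_index <- NA_integer_
  if (!is.na(onset) && !is.null(target_zone)) {
    zone <- range(target_zone)
    hit <- which(trajectory[onset:n] >= zone[1] & trajectory[onset:n] <= zone[2])
    if (length(hit)) target_index <- onset + hit[1L] - 1L
  }
  list(detected = !is.na(onset), onset = onset,
       reaction_samples = if (is.na(onset)) NA_integer_ else onset - go_index,
       target_index = target_index,
       movement_samples = if (is.na(target_index)) NA_integer_ else target_index - onset,
       baseline_mean = mu, baseline_sd = sigma)
}
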