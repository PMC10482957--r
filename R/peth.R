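#' Peri-event time histogram
#'
#' Trial-averaged firing rate aligned to an event. Spike counts are collected
#' in 20 ms bins and smoothed by averaging across a 20 ms sliding window
#' advanced in 10 ms steps, i.e. overlapping 20 ms windows evaluated every
#' 10 ms.
#'
#' @param spikes Spike times, seconds on the session clock.
#' @param events Event times, seconds; must be non-empty.
#' @param span `c(pre, post)` seconds relative to the event (`pre` <= 0).
#' @param bin Bin width, seconds; default 0.02.
#' @param step Sliding-window step, seconds; default 0.01. `bin` must be an
#'   integer multiple of `step`.
#' @param event Optional label for the aligning event.
#' @return Object of class `peth`: `bin_centers` and `rate` (smoothed, Hz) on
#'   the `step` grid; `raw_centers` and `raw_rate` for the non-overlapping
#'   `bin` grid; `n_trials`, `bin`, `step`, `event`.
#' @export
build_peth <- function(spikes, events, span = c(-1, 1), bin = 0.02,
                       step = 0.01, event = NA_character_) {
  if (length(events) == 0L) stop("events must be non-empty")
  w <- bin / step
  if (abs(w - round(w)) > 1e-9) stop("bin must be an integer multiple of step")
  w <- as.integer(round(w))
  n_trials <- length(events)
  rel <- unlist(lapply(events, function(e) {
    s <- spikes[spikes >= e + span[1] & spikes < e + span[2]]
    s - e
  }), use.names = FALSE)
  fine_breaks <- seq(span[1], span[2], by = step)
  nf <- length(fine_breaks) - 1L
  fine <- if (length(rel)) {
    tabulate(findInterval(rel, fine_breaks, rightmost.closed = FALSE,
                          left.open = FALSE), nbins = nf)
  } else {
    integer(nf)
  }
  # overlapping windows of w fine bins, advanced one fine bin at a time
  nwin <- nf - w + 1L
  win_counts <- vapply(seq_len(nwin), function(i) sum(fine[i:(i + w - 1L)]),
                       numeric(1))
  rate <- win_counts / (n_trials * bin)
  centers <- fine_breaks[seq_len(nwin)] + bin / 2
  # raw non-overlapping PETH at the stated bin width
  raw_idx <- seq(1L, nf - w + 1L, by = w)
  raw_rate <- vapply(raw_idx, function(i) sum(fine[i:(i + w - 1L)]),
                     numeric(1)) / (n_trials * bin)
  raw_centers <- fine_breaks[raw_idx] + bin / 2
  structure(list(bin_centers = centers, rate = rate,
                 raw_centers = raw_centers, raw_rate = raw_rate,
                 n_trials = n_trials, bin = bin, step = step, event = event),
            class = "peth")
}

#' @export
print.peth <- function(x, ...) {
  cat(sprintf("PETH (%s): %d trials, %d bins of %g ms (step %g ms)\n",
              ifelse(is.na(x$event), "unlabelled", x$event), x$n_trials,
              length(x$rate), x$bin * 1000, x$step * 1000))
  cat(sprintf("  rate range [%.2f, %.2f] Hz\n", min(x$rate), max(x$rate)))
  invisible(x)
}

#' Per-trial firing rate in a window around events
#'
#' Raw spike counts in the half-open window `[event + window[1],
#' event + window[2])`, divided by the window width.
#'
#' @param spikes Spike times, seconds.
#' @param events Event times, seconds.
#' @param window `c(start, end)` seconds relative to each event.
#' @return Numeric vector of rates (Hz), one per event.
#' @export
window_rates <- function(spikes, events, window) {
  width <- window[2] - window[1]
  if (width <= 0) stop("window must have positive width")
  vapply(events, function(e) {
    sum(spikes >= e + window[1] & spikes < e + window[2]) / width
  }, numeric(1))
}

#' Per-trial window statistics for one unit
#'
#' Computes per-trial firing rates in the baseline (2--3 s before the Go
#' cue), Go (0.3 s post Go), movement (0.3 s post onset) and outcome (0.5 s
#' post tone) windows, and z-scores each task window against the baseline
#' distribution: `z = (rate - mean(baseline)) / sd(baseline)`.
#'
#' @param spikes Spike times, seconds on the session clock.
#' @param session A `session_log`.
#' @return Object of class `window_stats`: `rates` (data frame with one row
#'   per trial: `baseline`, `go`, `movement`, `outcome`), `z` (data frame of
#'   z-scored task windows), `baseline_mean`, `baseline_sd`, and
#'   `z_defined` (`FALSE` when the baseline SD is zero, in which case `z` is
#'   all `NA` and the unit is excluded from z-based analyses).
#' @export
unit_window_stats <- function(spikes, session) {
  tr <- session$trials
  wins <- event_windows()
  rates <- data.frame(
    baseline = window_rates(spikes, tr$go_time, wins$baseline),
    go = window_rates(spikes, tr$go_time, wins$go),
    movement = window_rates(spikes, tr$movement_onset_time, wins$movement),
    outcome = window_rates(spikes, tr$outcome_tone_time, wins$outcome)
  )
  bm <- mean(rates$baseline)
  bs <- stats::sd(rates$baseline)
  z_defined <- is.finite(bs) && bs > 0
  z <- if (z_defined) {
    data.frame(go = (rates$go - bm) / bs,
               movement = (rates$movement - bm) / bs,
               outcome = (rates$outcome - bm) / bs)
  } else {
    data.frame(go = rep(NA_real_, nrow(rates)),
               movement = NA_real_, outcome = NA_real_)
  }
  structure(list(rates = rates, z = z, baseline_mean = bm, baseline_sd = bs,
                 z_defined = z_defined),
            class = "window_stats")
}

#' Task-relatedness test
#'
#' Wilcoxon rank-sum test of each task window's per-trial rates against the
#' baseline per-trial rates; a unit is task-related when any window differs
#' significantly.
#'
#' @param stats A `window_stats` object (or a data frame shaped like its
#'   `rates` element).
#' @param alpha Significance level; default 0.05 (two-sided).
#' @return List with `table` (data frame: window, p, significant),
#'   `task_related`, `testable` (`FALSE` with fewer than 2 trials).
#' @export
task_related_test <- function(stats, alpha = 0.05) {
  rates <- if (inherits(stats, "window_stats")) stats$rates else stats
  if (nrow(rates) < 2L) {
    return(list(table = NULL, task_related = NA, testable = FALSE))
  }
  wins <- setdiff(names(rates), "baseline")
  p <- vapply(wins, function(w) {
    if (all(rates[[w]] == rates$baseline)) return(1)
    suppressWarnings(
      stats::wilcox.test(rates[[w]], rates$baseline, exact = FALSE)$p.value
    )
  }, numeric(1))
  tab <- data.frame(window = wins, p = unname(p),
                    significant = unname(p) < alpha)
  list(table = tab, task_related = any(tab$significant), testable = TRUE)
}

#' Action preference of a unit
#'
#' The preferred action is the one with the larger mean movement-window rate,
#' provided the relative difference `|m_push - m_pull| / max(m_push, m_pull)`
#' is at least `min_rel_diff` (default 5%); otherwise the unit has no
#' preference. Downstream reward-rate analyses use only preferred-action
#' trials.
#'
#' @param push_movement_rates,pull_movement_rates Per-trial movement-window
#'   rates for push and pull trials.
#' @param min_rel_diff Relative-difference criterion; default 0.05.
#' @return `"push"`, `"pull"`, or `"none"`.
#' @export
action_preference <- function(push_movement_rates, pull_movement_rates,
                              min_rel_diff = 0.05) {
  if (length(push_movement_rates) < 1L || length(pull_movement_rates) < 1L) {
    stop("both conditions need at least one trial")
  }
  mp <- mean(push_movement_rates)
  ml <- mean(pull_movement_rates)
  top <- max(mp, ml)
  if (top == 0) return("none")
  if (abs(mp - ml) / top >= min_rel_diff) {
    if (mp > ml) "push" else "pull"
  } else {
    "none"
  }
}

#' Correlation of z-scored activity with reward rate
#'
#' Pearson correlation between the per-trial reward rate and the per-trial
#' z-scored window activity of one unit. Trials with an undefined reward
#' rate are excluded; a unit with zero variance in either variable has an
#' undefined r and is excluded from population statistics.
#'
#' @param z_values Per-trial z-scored activity.
#' @param reward_rates Per-trial reward rates (`NA` where undefined).
#' @param min_trials Minimum usable trials; default 4.
#' @return List with `r`, `p` (two-sided), `n`, `excluded` (logical),
#'   `reason` when excluded.
#' @export
reward_rate_correlation <- function(z_values, reward_rates, min_trials = 4L) {
  if (length(z_values) != length(reward_rates)) {
    stop("z_values and reward_rates must have equal length")
  }
  keep <- !is.na(reward_rates) & !is.na(z_values)
  z <- z_values[keep]
  rr <- reward_rates[keep]
  if (length(z) < min_trials) {
    return(list(r = NA_real_, p = NA_real_, n = length(z),
                excluded = TRUE, reason = "fewer than min_trials usable trials"))
  }
  if (stats::sd(z) == 0 || stats::sd(rr) == 0) {
    return(list(r = NA_real_, p = NA_real_, n = length(z),
                excluded = TRUE, reason = "zero variance"))
  }
  ct <- stats::cor.test(rr, z, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(z),
       excluded = FALSE, reason = NULL)
}

#' Population test of per-unit correlation coefficients against zero
#'
#' One-sample Wilcoxon signed-rank test of a population's r values against 0.
#'
#' @param r_values Per-unit correlation coefficients; needs at least 5 finite
#'   values.
#' @return List with `p`, `statistic`, `n`, `flagged` (degenerate when all r
#'   are identical).
#' @export
population_r_test <- function(r_values) {
  r <- r_values[is.finite(r_values)]
  if (length(r) < 5L) stop("need at least 5 finite r values, got ", length(r))
  if (length(unique(r)) == 1L) {
    return(list(p = if (r[1] == 0) 1 else 0, statistic = NA_real_,
                n = length(r), flagged = TRUE))
  }
  wt <- suppressWarnings(stats::wilcox.test(r, mu = 0, exact = FALSE))
  list(p = wt$p.value, statistic = unname(wt$statistic),
       n = length(r), flagged = FALSE)
}

#' Fisher z comparison of two correlation coefficients
#'
#' Tests the difference of two independent Pearson correlations via the
#' Fisher transform: `z = (atanh(r1) - atanh(r2)) / sqrt(1/(n1-3) +
#' 1/(n2-3))`, with a two-sided normal p-value multiplied by the number of
#' comparisons (Bonferroni) and capped at 1.
#'
#' @param r1,n1 First correlation and its sample size.
#' @param r2,n2 Second correlation and its sample size.
#' @param m_comparisons Bonferroni multiplier; default 1.
#' @return List with `z`, `p` (raw), `p_adjusted`.
#' @export
fisher_z_compare <- function(r1, n1, r2, n2, m_comparisons = 1L) {
  if (n1 <= 3 || n2 <= 3) stop("sample sizes must exceed 3")
  if (abs(r1) >= 1 || abs(r2) >= 1) {
    stop("|r| must be < 1 (the Fisher transform diverges at 1)")
  }
  z <- (atanh(r1) - atanh(r2)) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  p <- 2 * stats::pnorm(-abs(z))
  list(z = z, p = p, p_adjusted = min(1, m_comparisons * p))
}

#' Per-bin contrast of rewarded versus non-rewarded responses
#'
#' Two-sample Student's t-test on per-trial per-bin firing rates at each PETH
#' bin; returns the mask of bins where the two outcome conditions differ at
#' the stated level.
#'
#' @param spikes Spike times, seconds.
#' @param events_rewarded,events_nonrewarded Aligning event times for the two
#'   outcome conditions; each needs at least 2 trials.
#' @param span `c(pre, post)` seconds relative to the event.
#' @param bin Bin width, seconds; default 0.02.
#' @param alpha Per-bin significance level; default 0.01.
#' @return List with `bin_centers`, `p` (per bin; `NA` where both conditions
#'   are constant), `significant` (logical mask), `alpha`.
#' @export
outcome_contrast <- function(spikes, events_rewarded, events_nonrewarded,
                             span = c(-0.5, 1), bin = 0.02, alpha = 0.01) {
  if (length(events_rewarded) < 2L || length(events_nonrewarded) < 2L) {
    stop("both conditions need at least 2 trials")
  }
  breaks <- seq(span[1], span[2], by = bin)
  nb <- length(breaks) - 1L
  count_mat <- function(events) {
    t(vapply(events, function(e) {
      s <- spikes[spikes >= e + span[1] & spikes < e + span[2]] - e
      tabulate(findInterval(s, breaks, rightmost.closed = FALSE), nbins = nb)
    }, numeric(nb))) / bin
  }
  a <- count_mat(events_rewarded)
  b <- count_mat(events_nonrewarded)
  p <- vapply(seq_len(nb), function(j) {
    x <- a[, j]; y <- b[, j]
    if (stats::sd(x) == 0 && stats::sd(y) == 0) {
      return(if (mean(x) == mean(y)) NA_real_ else 0)
    }
    stats::t.test(x, y, var.equal = TRUE)$p.value
  }, numeric(1))
  list(bin_centers = breaks[-length(breaks)] + bin / 2, p = p,
       significant = !is.na(p) & p < alpha, alpha = alpha)
}
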