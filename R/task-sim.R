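#' Configuration of the probabilistic push/pull choice task
#'
#' Describes one instance of the head-fixed push/pull lever task with
#' probabilistic reward and block reversals. In each block one action
#' ("correct") is rewarded at a high probability and the other at a low
#' probability; the block reverses once the animal has accumulated enough
#' correct choices and a high correct rate over the most recent trials.
#'
#' @param p_reward_correct Reward probability for the correct (block-matching)
#'   action. Default 0.70.
#' @param p_reward_incorrect Reward probability for the incorrect action.
#'   Default 0.10.
#' @param switch_min_correct Minimum number of correct choices that must be
#'   accumulated within a block before it can reverse. Default 30.
#' @param switch_rate_threshold Correct-rate threshold over the last
#'   `switch_window` trials; the comparison is strict (rate must exceed the
#'   threshold). Default 0.79.
#' @param switch_window Number of most recent trials over which the correct
#'   rate is evaluated. Default 10.
#' @param hold_duration_s Mean centre-hold duration before the Go cue,
#'   seconds. Default 0.4.
#' @param hold_jitter_s Half-width of the uniform jitter on the hold duration,
#'   seconds. Default 0.1.
#' @param outcome_tone_delay_s Delay from outcome-tone onset to reward
#'   delivery on rewarded trials, seconds. Default 0.3.
#' @param iti_s Inter-trial interval from outcome tone to the start of the
#'   next trial's hold, seconds. Default 4. Chosen so that the 2--3 s pre-Go
#'   baseline window is free of the previous trial's events.
#' @param reaction_median_s,reaction_sdlog Median and log-scale SD of the
#'   log-normal reaction-time distribution (Go cue to movement onset).
#'   Placeholder kinematics, not empirical claims.
#' @param movement_median_s,movement_sdlog Median and log-scale SD of the
#'   log-normal movement-time distribution (movement onset to target entry).
#'
#' @return An object of class `task_config` (a named list).
#' @export
#' @examples
#' cfg <- task_config()
#' cfg$p_reward_correct
task_config <- function(p_reward_correct = 0.70,
                        p_reward_incorrect = 0.10,
                        switch_min_correct = 30L,
                        switch_rate_threshold = 0.79,
                        switch_window = 10L,
                        hold_duration_s = 0.4,
                        hold_jitter_s = 0.1,
                        outcome_tone_delay_s = 0.3,
                        iti_s = 4,
                        reaction_median_s = 0.218,
                        reaction_sdlog = 0.25,
                        movement_median_s = 0.143,
                        movement_sdlog = 0.4) {
  cfg <- list(
    p_reward_correct = p_reward_correct,
    p_reward_incorrect = p_reward_incorrect,
    switch_min_correct = as.integer(switch_min_correct),
    switch_rate_threshold = switch_rate_threshold,
    switch_window = as.integer(switch_window),
    hold_duration_s = hold_duration_s,
    hold_jitter_s = hold_jitter_s,
    outcome_tone_delay_s = outcome_tone_delay_s,
    iti_s = iti_s,
    reaction_median_s = reaction_median_s,
    reaction_sdlog = reaction_sdlog,
    movement_median_s = movement_median_s,
    movement_sdlog = movement_sdlog
  )
  validate_task_config(cfg)
  structure(cfg, class = "task_config")
}

validate_task_config <- function(cfg) {
  for (f in c("p_reward_correct", "p_reward_incorrect", "switch_rate_threshold")) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1) {
      stop("task_config field '", f, "' must be a probability in [0, 1], got ", v)
    }
  }
  if (cfg$switch_min_correct < 1L) stop("task_config field 'switch_min_correct' must be >= 1")
  if (cfg$switch_window < 1L) stop("task_config field 'switch_window' must be >= 1")
  for (f in c("hold_duration_s", "outcome_tone_delay_s", "iti_s",
              "reaction_median_s", "movement_median_s")) {
    if (cfg[[f]] <= 0) stop("task_config field '", f, "' must be positive")
  }
  invisible(cfg)
}

#' Parameters of the logistic choice policy
#'
#' The policy sets the log-odds of choosing push on trial i as a weighted sum
#' of signed outcome regressors over the `n_past` preceding trials, plus an
#' intercept. The coding (see [choice_regressors()]) makes positive reward
#' weights mean "stay after a reward" and negative no-reward weights mean
#' "switch after a non-reward".
#'
#' @param beta_reward Numeric vector of length `n_past`: weights on the signed
#'   rewarded-trial regressors (lag 1 first).
#' @param beta_noreward Numeric vector of length `n_past`: weights on the
#'   signed unrewarded-trial regressors.
#' @param beta0 Intercept; intrinsic bias toward push.
#' @param n_past Number of past trials entering the model. Default 8.
#'
#' @return An object of class `policy_params`.
#' @seealso [default_policy()] for a stay-biased agent that masters the task.
#' @export
policy_params <- function(beta_reward = rep(0, n_past),
                          beta_noreward = rep(0, n_past),
                          beta0 = 0, n_past = 8L) {
  n_past <- as.integer(n_past)
  if (n_past < 1L) stop("n_past must be >= 1")
  if (length(beta_reward) != n_past || length(beta_noreward) != n_past) {
    stop("beta_reward and beta_noreward must have length n_past = ", n_past)
  }
  structure(list(beta_reward = as.numeric(beta_reward),
                 beta_noreward = as.numeric(beta_noreward),
                 beta0 = as.numeric(beta0), n_past = n_past),
            class = "policy_params")
}

#' Stay-biased win-stay/lose-switch agent
#'
#' A logistic policy whose reward weights decay geometrically over the past
#' eight trials (strong win-stay) and whose no-reward weights are negative
#' (lose-switch). With the default task configuration this agent tracks block
#' reversals and completes blocks, so simulated sessions contain the full
#' block structure.
#'
#' @param scale Multiplies both weight vectors; 1 gives the default strength.
#' @param n_past Number of past trials in the model.
#' @return A `policy_params` object.
#' @export
default_policy <- function(scale = 1, n_past = 8L) {
  decay <- 0.6^(seq_len(n_past) - 1)
  policy_params(beta_reward = scale * 2.5 * decay,
                beta_noreward = scale * -1.2 * decay,
                beta0 = 0, n_past = n_past)
}

#' Draw a trial outcome
#'
#' Returns whether a trial is rewarded: with probability `p_reward_correct`
#' when the choice matches the block's correct action, else with probability
#' `p_reward_incorrect`. Consumes the ambient RNG stream.
#'
#' @param choice,block `"push"` or `"pull"`.
#' @param config A [task_config()].
#' @return Logical scalar.
#' @export
draw_outcome <- function(choice, block, config = task_config()) {
  stopifnot(choice %in% c("push", "pull"), block %in% c("push", "pull"))
  p <- if (choice == block) config$p_reward_correct else config$p_reward_incorrect
  stats::runif(1) < p
}

#' Block-reversal predicate
#'
#' A block reverses once it contains at least `switch_min_correct` correct
#' choices and the correct rate over the last `switch_window` trials strictly
#' exceeds `switch_rate_threshold`.
#'
#' @param trials_in_block Data frame of the current block's trials with a
#'   logical `correct` column (possibly zero rows), or a logical vector of
#'   per-trial correctness.
#' @param config A [task_config()].
#' @return Logical scalar.
#' @export
should_switch_block <- function(trials_in_block, config = task_config()) {
  correct <- if (is.data.frame(trials_in_block)) trials_in_block$correct else trials_in_block
  correct <- as.logical(correct)
  n <- length(correct)
  if (n == 0L) return(FALSE)
  if (sum(correct) < config$switch_min_correct) return(FALSE)
  recent <- correct[max(1L, n - config$switch_window + 1L):n]
  mean(recent) > config$switch_rate_threshold
}

#' Signed outcome regressors for the choice model
#'
#' For each lag j in 1..n_past, the rewarded regressor is +1 if trial i-j was
#' rewarded and the choice was push, -1 if rewarded and pull, and 0 if
#' unrewarded; the no-reward regressor codes unrewarded trials the same way.
#' Lags reaching before the session start are 0.
#'
#' @param choice Character vector of choices (`"push"`/`"pull"`) for trials
#'   1..m (the history preceding the trial being predicted).
#' @param rewarded Logical vector of outcomes, same length.
#' @param n_past Number of lags.
#' @return Numeric vector `c(R1..Rn, N1..Nn)` of length `2 * n_past`.
#' @export
choice_regressors <- function(choice, rewarded, n_past = 8L) {
  m <- length(choice)
  stopifnot(length(rewarded) == m)
  signed <- ifelse(choice == "push", 1, -1)
  r <- numeric(n_past)
  nr <- numeric(n_past)
  for (j in seq_len(n_past)) {
    idx <- m - j + 1L
    if (idx >= 1L) {
      if (rewarded[idx]) r[j] <- signed[idx] else nr[j] <- signed[idx]
    }
  }
  c(r, nr)
}

#' Push probability under a logistic policy
#'
#' Inverse-logit of the weighted signed-regressor sum; histories shorter than
#' `n_past` contribute zero regressors for the missing lags.
#'
#' @param history Data frame with `choice` and `rewarded` columns (the trials
#'   before the one being predicted); may have zero rows.
#' @param params A [policy_params()].
#' @return Probability of choosing push.
#' @export
choice_push_probability <- function(history, params) {
  x <- choice_regressors(history$choice, history$rewarded, params$n_past)
  eta <- sum(params$beta_reward * x[seq_len(params$n_past)]) +
    sum(params$beta_noreward * x[params$n_past + seq_len(params$n_past)]) +
    params$beta0
  stats::plogis(eta)
}

#' Sample a choice from the logistic policy
#'
#' @inheritParams choice_push_probability
#' @return `"push"` or `"pull"`.
#' @export
logistic_policy_choice <- function(history, params) {
  p <- choice_push_probability(history, params)
  if (stats::runif(1) < p) "push" else "pull"
}

#' Simulate a session of the push/pull task
#'
#' Runs `n_trials` trials of the task under a logistic choice policy.
#' Reversals follow [should_switch_block()] exactly, so every internal block
#' boundary satisfies the switch rule by construction. Event times (hold
#' onset, Go cue, movement onset, outcome tone, reward) follow the delays in
#' the configuration; reaction and movement times are drawn from log-normal
#' distributions. The run is a deterministic function of `seed`.
#'
#' @param config A [task_config()].
#' @param params A [policy_params()]; defaults to [default_policy()].
#' @param n_trials Number of trials (>= 1).
#' @param seed Integer RNG seed.
#' @return An object of class `session_log`: a list with elements `trials` (a
#'   data frame with 0-based `index`, `block`, `choice`, `correct`,
#'   `rewarded`, `go_time`, `movement_onset_time`, `outcome_tone_time`,
#'   `reward_time` in seconds from session start, `reward_time` `NA` when
#'   unrewarded), `config`, `params`, and `block_boundaries` (0-based indices
#'   of the first trial of each new block).
#' @export
#' @examples
#' s <- run_session(n_trials = 200, seed = 1)
#' head(s$trials)
#' s$block_boundaries
run_session <- function(config = task_config(), params = default_policy(),
                        n_trials, seed = 1L) {
  if (!is.numeric(n_trials) || length(n_trials) != 1L || n_trials < 1) {
    stop("n_trials must be a positive count")
  }
  n_trials <- as.integer(n_trials)
  withr::with_seed(seed, {
    block <- if (stats::runif(1) < 0.5) "push" else "pull"
    choice <- character(n_trials)
    blocks <- character(n_trials)
    correct <- logical(n_trials)
    rewarded <- logical(n_trials)
    go <- numeric(n_trials)
    mo <- numeric(n_trials)
    tone <- numeric(n_trials)
    rew <- rep(NA_real_, n_trials)
    boundaries <- integer(0)
    block_start <- 1L
    t_cursor <- config$iti_s
    hist_choice <- character(n_trials)
    hist_rewarded <- logical(n_trials)
    for (i in seq_len(n_trials)) {
      # only the last n_past trials enter the policy's regressors
      h0 <- max(1L, i - params$n_past)
      h <- if (i > 1L) {
        data.frame(choice = hist_choice[h0:(i - 1L)],
                   rewarded = hist_rewarded[h0:(i - 1L)])
      } else {
        data.frame(choice = character(0), rewarded = logical(0))
      }
      ch <- logistic_policy_choice(h, params)
      co <- ch == block
      rw <- draw_outcome(ch, block, config)
      hold <- config$hold_duration_s +
        stats::runif(1, -config$hold_jitter_s, config$hold_jitter_s)
      g <- t_cursor + hold
      m <- g + stats::rlnorm(1, log(config$reaction_median_s), config$reaction_sdlog)
      o <- m + stats::rlnorm(1, log(config$movement_median_s), config$movement_sdlog)
      choice[i] <- ch; blocks[i] <- block
      correct[i] <- co; rewarded[i] <- rw
      go[i] <- g; mo[i] <- m; tone[i] <- o
      if (rw) rew[i] <- o + config$outcome_tone_delay_s
      hist_choice[i] <- ch; hist_rewarded[i] <- rw
      t_cursor <- o + config$iti_s
      if (should_switch_block(correct[block_start:i], config)) {
        block <- if (block == "push") "pull" else "push"
        block_start <- i + 1L
        if (i < n_trials) boundaries <- c(boundaries, i) # 0-based index of next trial
      }
    }
    trials <- data.frame(
      index = seq_len(n_trials) - 1L,
      block = blocks, choice = choice,
      correct = correct, rewarded = rewarded,
      go_time = go, movement_onset_time = mo,
      outcome_tone_time = tone, reward_time = rew,
      stringsAsFactors = FALSE
    )
    structure(list(trials = trials, config = config, params = params,
                   block_boundaries = boundaries, seed = as.integer(seed)),
              class = "session_log")
  })
}

#' @export
print.session_log <- function(x, ...) {
  tr <- x$trials
  cat("Push/pull choice session:", nrow(tr), "trials,",
      length(x$block_boundaries), "block reversals\n")
  cat(sprintf("  correct rate %.2f, rewarded rate %.2f\n",
              mean(tr$correct), mean(tr$rewarded)))
  invisible(x)
}

#' Split a session into completed blocks
#'
#' @param session A `session_log`.
#' @return List of data frames, one per completed block (blocks ended by a
#'   reversal); the trailing unfinished block is excluded.
#' @export
session_blocks <- function(session) {
  b <- session$block_boundaries
  if (length(b) == 0L) return(list())
  starts <- c(0L, b[-length(b)])
  ends <- b # exclusive, 0-based
  lapply(seq_along(b), function(k) {
    session$trials[(starts[k] + 1L):ends[k], , drop = FALSE]
  })
}
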