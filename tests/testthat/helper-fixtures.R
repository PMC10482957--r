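# hand-built session with regular event spacing; choices/outcomes supplied
make_session <- function(choice, rewarded, block = choice, iti = 6) {
  n <- length(choice)
  go <- iti * seq_len(n)
  mo <- go + 0.2
  tone <- mo + 0.15
  trials <- data.frame(
    index = seq_len(n) - 1L, block = block, choice = choice,
    correct = choice == block, rewarded = rewarded,
    go_time = go, movement_onset_time = mo, outcome_tone_time = tone,
    reward_time = ifelse(rewarded, tone + 0.3, NA_real_),
    stringsAsFactors = FALSE
  )
  structure(list(trials = trials, config = task_config(), params = NULL,
                 block_boundaries = integer(0), seed = NA_integer_),
            class = "session_log")
}

# independent log-likelihood of a push/pull session under the signed-regressor
# logistic model (used as a brute-force oracle against the glm fit)
session_loglik <- function(trials, beta_r, beta_n, beta0, n_past) {
  n <- nrow(trials)
  ll <- 0
  for (i in (n_past + 1):n) {
    eta <- beta0
    for (j in seq_len(n_past)) {
      prev <- i - j
      s <- if (trials$choice[prev] == "push") 1 else -1
      if (trials$rewarded[prev]) eta <- eta + beta_r[j] * s
      else eta <- eta + beta_n[j] * s
    }
    p <- 1 / (1 + exp(-eta))
    y <- trials$choice[i] == "push"
    ll <- ll + log(ifelse(y, p, 1 - p))
  }
  ll
}
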