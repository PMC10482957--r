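#' Specification of a synthetic task-modulated neuron
#'
#' Describes an inhomogeneous-Poisson unit whose firing rate is a baseline
#' plus event-locked double-exponential kernels (Go cue, movement onset,
#' rewarded and unrewarded outcome tones). Each kernel's gain is scaled by
#' `1 + coupling * reward_rate` on trials with a defined trailing reward
#' rate, so positive couplings make event responses grow with reward
#' expectation and negative couplings make them shrink.
#'
#' @param baseline_hz Baseline rate, Hz. Default 5.
#' @param kernels Named list (`go`, `movement`, `outcome_reward`,
#'   `outcome_noreward`) of lists with `gain` (peak rate above baseline, Hz),
#'   `rise` and `decay` (seconds) of the kernel
#'   `(1 - exp(-t/rise)) * exp(-t/decay)`, peak-normalised.
#' @param coupling Named numeric vector of reward-rate slopes per event
#'   (dimensionless, applied as `1 + coupling * reward_rate`).
#' @param refractory_s Absolute dead time after each spike, seconds; 0
#'   disables it. A 2 ms dead time produces the sub-Poisson ISI regularity
#'   typical of tonically active interneurons.
#' @return Object of class `neuron_spec`.
#' @export
neuron_spec <- function(baseline_hz = 5,
                        kernels = list(
                          go = list(gain = 15, rise = 0.02, decay = 0.10),
                          movement = list(gain = 20, rise = 0.03, decay = 0.15),
                          outcome_reward = list(gain = 15, rise = 0.03, decay = 0.20),
                          outcome_noreward = list(gain = 5, rise = 0.03, decay = 0.20)
                        ),
                        coupling = c(go = 0, movement = 0,
                                     outcome_reward = 0, outcome_noreward = 0),
                        refractory_s = 0) {
  if (baseline_hz < 0) stop("baseline_hz must be >= 0")
  for (k in kernels) {
    if (k$rise <= 0 || k$decay <= 0) stop("kernel rise and decay must be positive")
    if (k$gain < 0) stop("kernel gains must be >= 0")
  }
  cp <- c(go = 0, movement = 0, outcome_reward = 0, outcome_noreward = 0)
  cp[names(coupling)] <- coupling
  structure(list(baseline_hz = baseline_hz, kernels = kernels,
                 coupling = cp, refractory_s = refractory_s),
            class = "neuron_spec")
}

# peak-normalised double-exponential kernel evaluated at lag t (vectorised)
.kernel_eval <- function(t, rise, decay) {
  tpk <- rise * log(1 + decay / rise)
  pk <- (1 - exp(-tpk / rise)) * exp(-tpk / decay)
  out <- numeric(length(t))
  pos <- t >= 0
  out[pos] <- (1 - exp(-t[pos] / rise)) * exp(-t[pos] / decay) / pk
  out
}

#' Generate a spike train for a synthetic unit
#'
#' Samples an inhomogeneous Poisson process by thinning: the intensity is the
#' baseline plus the sum of event kernels, each scaled by
#' `gain * (1 + coupling * reward_rate)` for the trial it belongs to (trials
#' without a defined reward rate use the unscaled gain), rectified at zero.
#' Deterministic given the seed.
#'
#' @param spec A [neuron_spec()].
#' @param session A `session_log`.
#' @param seed Integer seed.
#' @return Sorted numeric vector of spike times, seconds.
#' @export
gen_spike_train <- function(spec, session, seed = 1L) {
  tr <- session$trials
  rr <- compute_reward_rate(tr$rewarded)
  mult <- function(event) ifelse(is.na(rr), 1, 1 + spec$coupling[[event]] * rr)
  ev <- list(
    go = list(times = tr$go_time, m = mult("go"), k = spec$kernels$go),
    movement = list(times = tr$movement_onset_time, m = mult("movement"),
                    k = spec$kernels$movement),
    outcome_reward = list(times = tr$outcome_tone_time[tr$rewarded],
                          m = mult("outcome_reward")[tr$rewarded],
                          k = spec$kernels$outcome_reward),
    outcome_noreward = list(times = tr$outcome_tone_time[!tr$rewarded],
                            m = mult("outcome_noreward")[!tr$rewarded],
                            k = spec$kernels$outcome_noreward)
  )
  t_end <- max(tr$outcome_tone_time) + 2
  lambda_at <- function(t) {
    lam <- rep(spec$baseline_hz, length(t))
    for (e in ev) {
      if (length(e$times) == 0L || e$k$gain == 0) next
      support <- e$k$rise + 10 * e$k$decay
      idx <- findInterval(t, e$times)
      for (back in 0:1) { # at most two kernels of one event type can overlap t
        j <- idx - back
        use <- j >= 1L
        if (!any(use)) next
        lag <- t[use] - e$times[pmax(j[use], 1L)]
        contrib <- numeric(length(t))
        inwin <- use
        inwin[use] <- lag >= 0 & lag <= support
        if (!any(inwin)) next
        lag2 <- t[inwin] - e$times[j[inwin]]
        contrib[inwin] <- e$k$gain * e$m[j[inwin]] *
          .kernel_eval(lag2, e$k$rise, e$k$decay)
        lam <- lam + contrib
      }
    }
    pmax(lam, 0)
  }
  total_gain <- sum(vapply(ev, function(e) e$k$gain, numeric(1)))
  max_mult <- 1 + max(abs(spec$coupling))
  lambda_max <- spec$baseline_hz + total_gain * max_mult
  if (lambda_max <= 0) return(numeric(0))
  withr::with_seed(seed, {
    n_cand <- stats::rpois(1, lambda_max * t_end)
    if (n_cand == 0L) {
      numeric(0)
    } else {
      cand <- sort(stats::runif(n_cand, 0, t_end))
      keep <- stats::runif(n_cand) < lambda_at(cand) / lambda_max
      spikes <- cand[keep]
      if (spec$refractory_s > 0 && length(spikes) > 1L) {
        out <- spikes[1]
        last <- spikes[1]
        for (s in spikes[-1]) {
          if (s - last >= spec$refractory_s) {
            out <- c(out, s)
            last <- s
          }
        }
        spikes <- out
      }
      spikes
    }
  })
}

#' Specification of a synthetic photometry recording
#'
#' The 470 nm channel is a baseline fluorescence plus an exponential + linear
#' bleaching trend, event-locked dopamine-release transients (double-
#' exponential kernel, amplitude given per event in dF/F units), a slow
#' shared motion artifact, and white noise. A transient's absolute amplitude
#' is its dF/F amplitude times the instantaneous baseline `f0 + bleach(t)`:
#' the fluorophore pool that bleaches is the same one that reports dopamine,
#' so the fractional change is what stays constant. The 405 nm isosbestic
#' channel shares the bleaching (scaled by `iso_gain`) and a fraction of the
#' artifact but carries no transients.
#'
#' @param f0 Baseline fluorescence, a.u. Default 100.
#' @param bleach_a,bleach_tau,bleach_b Exponential amplitude (a.u.), time
#'   constant (s) and linear slope (a.u./s) of the decay.
#' @param kernel `list(rise, decay)` of the transient kernel, seconds.
#' @param amplitude Named dF/F amplitudes per event (`go`, `movement`,
#'   `outcome_reward`, `outcome_noreward`); multiplied by the instantaneous
#'   baseline fluorescence.
#' @param rr_coupling Named reward-rate slopes per event, applied as
#'   `1 + coupling * reward_rate` on the transient amplitude.
#' @param noise_sd White-noise SD, a.u.
#' @param iso_gain Isosbestic baseline/bleach gain. Default 0.8.
#' @param artifact_sd SD of the slow shared artifact, a.u. Default 0.
#' @param shared_fraction Fraction of the artifact entering the 405 channel.
#' @param fs Sampling rate, Hz. Default 1000.
#' @return Object of class `photometry_spec`.
#' @export
photometry_spec <- function(f0 = 100, bleach_a = 30, bleach_tau = 300,
                            bleach_b = -0.005,
                            kernel = list(rise = 0.05, decay = 0.4),
                            amplitude = c(go = 0.03, movement = 0.02,
                                          outcome_reward = 0.05,
                                          outcome_noreward = -0.02),
                            rr_coupling = c(go = 0, movement = 0,
                                            outcome_reward = 0,
                                            outcome_noreward = 0),
                            noise_sd = 0.3, iso_gain = 0.8,
                            artifact_sd = 0, shared_fraction = 1,
                            fs = 1000) {
  if (f0 <= 0) stop("f0 must be positive")
  if (bleach_tau <= 0) stop("bleach_tau must be positive")
  amp <- c(go = 0, movement = 0, outcome_reward = 0, outcome_noreward = 0)
  amp[names(amplitude)] <- amplitude
  cp <- c(go = 0, movement = 0, outcome_reward = 0, outcome_noreward = 0)
  cp[names(rr_coupling)] <- rr_coupling
  structure(list(f0 = f0, bleach_a = bleach_a, bleach_tau = bleach_tau,
                 bleach_b = bleach_b, kernel = kernel, amplitude = amp,
                 rr_coupling = cp, noise_sd = noise_sd, iso_gain = iso_gain,
                 artifact_sd = artifact_sd, shared_fraction = shared_fraction,
                 fs = fs),
            class = "photometry_spec")
}

#' Generate a dual-channel photometry trace for a session
#'
#' @param spec A [photometry_spec()].
#' @param session A `session_log`.
#' @param seed Integer seed.
#' @return A [photometry_trace()] covering the session (t0 = 0).
#' @export
gen_photometry <- function(spec, session, seed = 1L) {
  tr <- session$trials
  fs <- spec$fs
  t_end <- max(tr$outcome_tone_time) + 3
  n <- as.integer(ceiling(t_end * fs))
  t <- (seq_len(n) - 1) / fs
  bleach <- spec$bleach_a * exp(-t / spec$bleach_tau) + spec$bleach_b * t
  rr <- compute_reward_rate(tr$rewarded)
  add_transients <- function(base, times, amps) {
    support <- spec$kernel$rise + 10 * spec$kernel$decay
    for (i in seq_along(times)) {
      if (amps[i] == 0) next
      i0 <- as.integer(floor(times[i] * fs)) + 1L
      i1 <- min(n, i0 + as.integer(ceiling(support * fs)))
      if (i0 > n) next
      lag <- t[i0:i1] - times[i]
      base[i0:i1] <- base[i0:i1] +
        amps[i] * .kernel_eval(lag, spec$kernel$rise, spec$kernel$decay)
    }
    base
  }
  ev_times <- list(go = tr$go_time, movement = tr$movement_onset_time,
                   outcome_reward = tr$outcome_tone_time[tr$rewarded],
                   outcome_noreward = tr$outcome_tone_time[!tr$rewarded])
  ev_rr <- list(go = rr, movement = rr,
                outcome_reward = rr[tr$rewarded],
                outcome_noreward = rr[!tr$rewarded])
  baseline_at <- function(times) {
    spec$f0 + spec$bleach_a * exp(-times / spec$bleach_tau) +
      spec$bleach_b * times
  }
  withr::with_seed(seed, {
    transients <- numeric(n)
    for (e in names(ev_times)) {
      amp <- spec$amplitude[[e]] * baseline_at(ev_times[[e]]) *
        ifelse(is.na(ev_rr[[e]]), 1, 1 + spec$rr_coupling[[e]] * ev_rr[[e]])
      transients <- add_transients(transients, ev_times[[e]], amp)
    }
    artifact <- if (spec$artifact_sd > 0) {
      w <- as.integer(fs / 2)
      raw <- stats::rnorm(n + w)
      sm <- stats::filter(raw, rep(1 / w, w), sides = 1)[(w + 1):(n + w)]
      as.numeric(sm) / stats::sd(sm) * spec$artifact_sd
    } else {
      numeric(n)
    }
    s470 <- spec$f0 + bleach + transients + artifact +
      stats::rnorm(n, 0, spec$noise_sd)
    s405 <- spec$iso_gain * (spec$f0 + bleach) +
      spec$shared_fraction * artifact + stats::rnorm(n, 0, spec$noise_sd)
    photometry_trace(s470, s405, fs = fs, t0 = 0)
  })
}

#' Specification of a synthetic collision-test unit
#'
#' @param conduction_latency_ms Antidromic conduction latency, ms. Default 12.
#' @param latency_jitter_ms SD of the evoked-spike latency, ms. Default 0.1.
#' @param spike_amplitude Peak (negative) amplitude on the strongest channel,
#'   in noise-SD units times `noise_sd`. Default 60.
#' @param noise_sd Trace noise SD, a.u. Default 8.
#' @param spontaneous_rate_hz Spontaneous firing rate. Default 2.
#' @param antidromic Logical; `FALSE` generates a non-projecting control unit
#'   with no stimulus-locked response.
#' @param collision_fidelity Probability that a preceding spontaneous spike
#'   actually deletes the evoked spike; 1 is the idealised physics.
#' @return Object of class `collision_spec`.
#' @export
collision_spec <- function(conduction_latency_ms = 12, latency_jitter_ms = 0.1,
                           spike_amplitude = 60, noise_sd = 8,
                           spontaneous_rate_hz = 2, antidromic = TRUE,
                           collision_fidelity = 1) {
  if (conduction_latency_ms <= 0) stop("conduction_latency_ms must be positive")
  if (latency_jitter_ms < 0) stop("latency_jitter_ms must be >= 0")
  structure(list(conduction_latency_ms = conduction_latency_ms,
                 latency_jitter_ms = latency_jitter_ms,
                 spike_amplitude = spike_amplitude, noise_sd = noise_sd,
                 spontaneous_rate_hz = spontaneous_rate_hz,
                 antidromic = antidromic,
                 collision_fidelity = collision_fidelity),
            class = "collision_spec")
}

# biphasic extracellular spike template across 4 channels; returns a
# [channel, sample] matrix of length ~1.5 ms
.spike_template <- function(fs, amplitude) {
  t <- seq(0, 1.5e-3, by = 1 / fs)
  shape <- -exp(-((t - 4e-4) / 1.2e-4)^2) + 0.35 * exp(-((t - 8e-4) / 2.5e-4)^2)
  chan_gain <- c(1, 0.7, 0.45, 0.25)
  outer(chan_gain, shape * amplitude)
}

#' Generate a stimulation-trial ensemble for the collision test
#'
#' Control snippets contain (for a true antidromic unit) a stimulus-locked
#' evoked spike at the conduction latency; test snippets emulate
#' spontaneous-spike-triggered stimulation, in which the orthodromic
#' spontaneous spike collides with the antidromic volley and the evoked spike
#' is deleted (with probability `collision_fidelity`). Non-antidromic units
#' fire only spontaneously in both conditions.
#'
#' @param spec A [collision_spec()].
#' @param n_control,n_test Trial counts (>= 1).
#' @param seed Integer seed.
#' @param fs Sampling rate, Hz. Default 20000.
#' @param pre_ms,post_ms Snippet extent around light onset, ms. Defaults
#'   30 / 30.
#' @return A [stim_trial_ensemble()].
#' @export
gen_collision_ensemble <- function(spec, n_control, n_test, seed = 1L,
                                   fs = 20000, pre_ms = 30, post_ms = 30) {
  stopifnot(n_control >= 1L, n_test >= 1L)
  npre <- as.integer(round(pre_ms / 1000 * fs))
  npost <- as.integer(round(post_ms / 1000 * fs))
  nsamp <- npre + npost + 1L
  stim_index <- npre + 1L
  template <- .spike_template(fs, spec$spike_amplitude)
  tlen <- ncol(template)
  insert_spike <- function(trace, at_sample) {
    i0 <- as.integer(round(at_sample))
    i1 <- min(nsamp, i0 + tlen - 1L)
    if (i0 < 1L || i0 > nsamp) return(trace)
    trace[, i0:i1] <- trace[, i0:i1] + template[, seq_len(i1 - i0 + 1L)]
    trace
  }
  lat_samp <- spec$conduction_latency_ms / 1000 * fs
  span_s <- nsamp / fs
  gen_trial <- function(kind) {
    tr <- matrix(stats::rnorm(4L * nsamp, 0, spec$noise_sd), nrow = 4L)
    # spontaneous background spikes, kept out of the pre-stimulus conduction
    # window on control trials (that is the experimental selection rule)
    n_sp <- stats::rpois(1, spec$spontaneous_rate_hz * span_s)
    sp_times <- sort(stats::runif(n_sp, 1, nsamp - tlen))
    collided <- FALSE
    if (kind == "control" && spec$antidromic) {
      guard <- c(stim_index - lat_samp, stim_index + lat_samp)
      sp_times <- sp_times[sp_times < guard[1] | sp_times > guard[2]]
    }
    if (kind == "test") {
      # triggering spontaneous spike just before light onset
      trig <- stim_index - stats::runif(1, 0, 1e-3 * fs)
      sp_times <- c(sp_times, trig)
      collided <- stats::runif(1) < spec$collision_fidelity
    }
    for (s in sp_times) tr <- insert_spike(tr, s)
    if (spec$antidromic && !(kind == "test" && collided)) {
      at <- stim_index + lat_samp +
        stats::rnorm(1, 0, spec$latency_jitter_ms / 1000 * fs)
      # peak of the template sits ~0.4 ms after its start
      tr <- insert_spike(tr, at - 4e-4 * fs)
    }
    tr
  }
  withr::with_seed(seed, {
    ctr <- array(0, dim = c(n_control, 4L, nsamp))
    tst <- array(0, dim = c(n_test, 4L, nsamp))
    for (i in seq_len(n_control)) ctr[i, , ] <- gen_trial("control")
    for (i in seq_len(n_test)) tst[i, , ] <- gen_trial("test")
    stim_trial_ensemble(ctr, tst, fs = fs, stim_index = stim_index)
  })
}

#' Generate a synthetic striatal unit-feature population
#'
#' Draws unit features (ongoing rate, spike duration, ISI CV) from
#' class-typical distributions for projection neurons (SPN: slow, wide,
#' irregular), tonically active interneurons (TAN: moderate-rate, regular)
#' and fast-spiking interneurons (FSI: fast, narrow). Default class
#' proportions follow the recorded striatal population (716 SPN, 1224 TAN,
#' 62 FSI of 2002); dispersions are set so the three clusters are clearly
#' separable but overlap moderately, as in real recordings.
#'
#' @param n Number of units. Default 300.
#' @param proportions Named class proportions; normalised internally.
#' @param separation Multiplier > 0 shrinking (`> 1`) or inflating (`< 1`)
#'   the class dispersions. Default 1.
#' @param seed Integer seed.
#' @return Data frame with `true_class`, `ongoing_rate`, `spike_duration_us`,
#'   `cv_isi`.
#' @export
gen_unit_features <- function(n = 300L,
                              proportions = c(SPN = 716, TAN = 1224, FSI = 62),
                              separation = 1, seed = 1L) {
  pr <- proportions / sum(proportions)
  pars <- list( # rate meanlog/sdlog (log-normal), duration mean/sd, cv mean/sd
    SPN = list(rate = c(log(0.9), 0.45), dur = c(650, 55), cv = c(1.5, 0.16)),
    TAN = list(rate = c(log(5.5), 0.25), dur = c(480, 45), cv = c(0.7, 0.10)),
    FSI = list(rate = c(log(14), 0.30), dur = c(210, 30), cv = c(1.05, 0.12))
  )
  withr::with_seed(seed, {
    cls <- sample(names(pr), n, replace = TRUE, prob = pr)
    s <- 1 / separation
    rate <- numeric(n); dur <- numeric(n); cv <- numeric(n)
    for (k in names(pars)) {
      i <- cls == k
      m <- pars[[k]]
      rate[i] <- stats::rlnorm(sum(i), m$rate[1], m$rate[2] * s)
      dur[i] <- pmax(80, stats::rnorm(sum(i), m$dur[1], m$dur[2] * s))
      cv[i] <- pmax(0.05, stats::rnorm(sum(i), m$cv[1], m$cv[2] * s))
    }
    data.frame(true_class = cls, ongoing_rate = rate,
               spike_duration_us = dur, cv_isi = cv,
               stringsAsFactors = FALSE)
  })
}
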