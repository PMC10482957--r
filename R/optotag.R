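#' Stimulation-trial trace ensemble
#'
#' Control and test trace snippets around optical stimulation for one
#' candidate unit. Control snippets had no spontaneous spike of the candidate
#' cluster immediately before the stimulus; test snippets are those in which
#' a spontaneous spike triggered the stimulus, so a true antidromic spike
#' collides on its way up the axon and never arrives.
#'
#' @param control_traces,test_traces 3-d arrays `[trial, channel, sample]` of
#'   filtered voltage snippets, identical channel and sample dimensions.
#' @param fs Sampling rate, Hz.
#' @param stim_index Sample index (1-based) of light onset within a snippet.
#' @return Object of class `stim_trial_ensemble`.
#' @export
stim_trial_ensemble <- function(control_traces, test_traces, fs, stim_index) {
  dc <- dim(control_traces)
  dt <- dim(test_traces)
  if (length(dc) != 3L || length(dt) != 3L) {
    stop("traces must be 3-d arrays [trial, channel, sample]")
  }
  if (!all(dc[2:3] == dt[2:3])) {
    stop("control and test snippets must share channel and sample dimensions")
  }
  if (stim_index < 2L || stim_index > dc[3]) stop("stim_index outside snippet")
  structure(list(control_traces = control_traces, test_traces = test_traces,
                 fs = fs, stim_index = as.integer(stim_index)),
            class = "stim_trial_ensemble")
}

#' Find the antidromic response window
#'
#' Searches the first `max_ms` after the stimulus for contiguous intervals
#' where the averaged control and test traces dissociate by more than
#' `k` pre-stimulus noise SDs for at least `min_dur_ms`; the widest such
#' interval is returned (ties: the earliest).
#'
#' @param avg_control,avg_test Trial-averaged traces (numeric vectors, equal
#'   length, aligned).
#' @param fs Sampling rate, Hz.
#' @param stim_index Sample index of light onset.
#' @param k Dissociation threshold in noise SDs; default 3.
#' @param max_ms Search horizon after the stimulus, ms; default 25.
#' @param min_dur_ms Minimum dissociation duration, ms; default 0.2.
#' @param min_start_ms Dead time after the stimulus excluded from the search
#'   (photostimulation artifact / triggering-spike afterwave); default 0.
#' @param max_gap_ms Sub-threshold gaps up to this long are bridged before
#'   runs are measured, so the two lobes of one biphasic spike count as a
#'   single dissociation interval; default 0.
#' @return `c(start, end)` in ms post-stimulus (half-open sample interval).
#'   Errors with "no candidate antidromic response" when no interval
#'   qualifies.
#' @export
find_response_window <- function(avg_control, avg_test, fs, stim_index,
                                 k = 3, max_ms = 25, min_dur_ms = 0.2,
                                 min_start_ms = 0, max_gap_ms = 0) {
  if (length(avg_control) != length(avg_test)) {
    stop("averaged traces must have equal length")
  }
  d <- avg_control - avg_test
  pre <- d[seq_len(stim_index - 1L)]
  noise_sd <- stats::sd(pre)
  if (is.na(noise_sd) || noise_sd == 0) noise_sd <- .Machine$double.eps
  first <- stim_index + 1L + as.integer(round(min_start_ms / 1000 * fs))
  last <- min(length(d), stim_index + as.integer(round(max_ms / 1000 * fs)))
  if (first > last) stop("no candidate antidromic response")
  post <- first:last
  mask <- abs(d[post]) > k * noise_sd
  gap <- as.integer(round(max_gap_ms / 1000 * fs))
  if (gap > 0L && any(mask)) {
    # bridge short sub-threshold gaps between supra-threshold samples
    on <- which(mask)
    for (j in seq_len(length(on) - 1L)) {
      if (on[j + 1L] - on[j] - 1L <= gap) mask[on[j]:on[j + 1L]] <- TRUE
    }
  }
  runs <- rle(mask)
  min_len <- max(1L, as.integer(round(min_dur_ms / 1000 * fs)))
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  ok <- which(runs$values & runs$lengths >= min_len)
  if (length(ok) == 0L) stop("no candidate antidromic response")
  best <- ok[which.max(runs$lengths[ok])]
  s <- post[starts[best]]
  e <- post[ends[best]]
  c(start = (s - stim_index) / fs * 1000,
    end = (e + 1L - stim_index) / fs * 1000)
}

#' ROC-based spike amplitude cutoff
#'
#' Spikes are negative deflections, so a trial contains a spike when its
#' in-window minimum falls below the threshold. Candidate thresholds are the
#' midpoints between consecutive pooled sorted values; the returned threshold
#' maximises Youden's J = sensitivity + specificity - 1, where sensitivity is
#' the fraction of spike-class minima below the threshold and specificity the
#' fraction of noise-class minima at or above it. Ties take the middle tied
#' candidate. Identical distributions are degenerate: the pooled median is
#' returned, flagged.
#'
#' @param minima_spike Minima from trials expected to contain spikes
#'   (e.g. control in-window minima).
#' @param minima_noise Minima from spike-free segments of the same width.
#' @return List with `threshold`, `J`, `flagged`.
#' @export
roc_spike_cutoff <- function(minima_spike, minima_noise) {
  if (length(minima_spike) == 0L || length(minima_noise) == 0L) {
    stop("both amplitude lists must be non-empty")
  }
  pooled <- sort(unique(c(minima_spike, minima_noise)))
  if (length(pooled) == 1L) {
    return(list(threshold = pooled, J = 0, flagged = TRUE))
  }
  cand <- (pooled[-1] + pooled[-length(pooled)]) / 2
  J <- vapply(cand, function(th) {
    mean(minima_spike < th) + mean(minima_noise >= th) - 1
  }, numeric(1))
  if (max(J) <= 0) {
    return(list(threshold = stats::median(c(minima_spike, minima_noise)),
                J = max(J), flagged = TRUE))
  }
  best <- which(J == max(J))
  pick <- best[ceiling(length(best) / 2)]
  list(threshold = cand[pick], J = J[pick], flagged = FALSE)
}

#' Chi-square justification of spike/no-spike counts
#'
#' 2 x 2 test (no continuity correction) of spike versus no-spike counts in
#' control and test conditions. When any expected cell count is below 5 the
#' test falls back to Fisher's exact test and is flagged.
#'
#' @param spikes_control,n_control Spike count and trial count, control.
#' @param spikes_test,n_test Spike count and trial count, test.
#' @return List with `p`, `statistic` (`NA` for the exact fallback),
#'   `method`, `flagged`.
#' @export
spike_count_test <- function(spikes_control, n_control, spikes_test, n_test) {
  tab <- rbind(c(spikes_control, n_control - spikes_control),
               c(spikes_test, n_test - spikes_test))
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected < 5)) {
    ft <- stats::fisher.test(tab)
    return(list(p = ft$p.value, statistic = NA_real_,
                method = "fisher_exact", flagged = TRUE))
  }
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(p = ct$p.value, statistic = unname(ct$statistic),
       method = "chi_square", flagged = FALSE)
}

# quartiles with linear interpolation between order statistics (type 7)
latency_quartiles <- function(times_ms) {
  q <- stats::quantile(times_ms, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  list(latency_ms = q[2], jitter_ms = q[3] - q[1])
}

#' Antidromic spike-collision test
#'
#' Identifies a projection neuron from stimulus-aligned trace snippets: the
#' response window is located by dissociation of the averaged control and
#' test traces, a spike amplitude cutoff is derived from an ROC over
#' in-window minima versus pre-stimulus noise minima, spike/no-spike counts
#' are justified by a 2 x 2 chi-square test, and the latency (median of
#' in-window spike peak times) and jitter (inter-quartile range) must be
#' compatible with fixed-latency antidromic conduction. The unit passes when
#' control spike probability exceeds 50%, the test probability is less than
#' half the control (the collision deletes the evoked spike), the count test
#' gives p < `alpha`, latency < `max_latency_ms`, and jitter <
#' `max_jitter_ms`.
#'
#' @param ensemble A [stim_trial_ensemble()].
#' @param k Dissociation threshold for [find_response_window()].
#' @param alpha Significance level of the count test. Default 0.05.
#' @param max_latency_ms Latency criterion, ms. Default 25.
#' @param max_jitter_ms Jitter criterion, ms. Default 0.5.
#' @param min_trials Below this many trials per condition the result is
#'   flagged underpowered. Default 10.
#' @param min_start_ms Post-stimulus dead time excluded from the window
#'   search; the test condition contains the triggering spontaneous spike
#'   around the stimulus, so the first couple of milliseconds cannot index
#'   the antidromic response. Default 2.
#' @param max_gap_ms Gap-bridging span for the window search, so a biphasic
#'   spike forms one dissociation interval. Default 0.25.
#' @return Object of class `collision_result`: `window`, `cutoff`,
#'   `p_control`, `p_test`, `chi2_p`, `latency_ms`, `jitter_ms`, `passed`,
#'   `flags` (character), and `reason` when no response window was found
#'   (then `passed` is `FALSE`, not an error).
#' @export
collision_test <- function(ensemble, k = 3, alpha = 0.05,
                           max_latency_ms = 25, max_jitter_ms = 0.5,
                           min_trials = 10L, min_start_ms = 2,
                           max_gap_ms = 0.25) {
  stopifnot(inherits(ensemble, "stim_trial_ensemble"))
  ctr <- ensemble$control_traces
  tst <- ensemble$test_traces
  fs <- ensemble$fs
  si <- ensemble$stim_index
  n_ctr <- dim(ctr)[1]
  n_tst <- dim(tst)[1]
  flags <- character(0)
  if (n_ctr < min_trials || n_tst < min_trials) flags <- c(flags, "underpowered")
  avg_c <- apply(ctr, c(2, 3), mean)
  avg_t <- apply(tst, c(2, 3), mean)
  # channel with the largest post-stimulus dissociation energy
  post <- (si + 1L):min(dim(ctr)[3], si + as.integer(round(max_latency_ms / 1000 * fs)))
  energy <- rowSums((avg_c[, post, drop = FALSE] - avg_t[, post, drop = FALSE])^2)
  ch <- which.max(energy)
  win <- tryCatch(
    find_response_window(avg_c[ch, ], avg_t[ch, ], fs, si, k = k,
                         max_ms = max_latency_ms,
                         min_start_ms = min_start_ms,
                         max_gap_ms = max_gap_ms),
    error = function(e) NULL
  )
  if (is.null(win)) {
    return(structure(list(window = c(NA_real_, NA_real_), cutoff = NA_real_,
                          p_control = NA_real_, p_test = NA_real_,
                          chi2_p = NA_real_, latency_ms = NA_real_,
                          jitter_ms = NA_real_, passed = FALSE,
                          channel = ch, flags = flags,
                          reason = "no candidate antidromic response"),
                     class = "collision_result"))
  }
  start_off <- as.integer(round(win[1] / 1000 * fs))
  end_off <- as.integer(round(win[2] / 1000 * fs))
  w_samp <- si + seq(start_off, end_off - 1L)
  w_samp <- w_samp[w_samp <= dim(ctr)[3]]
  width <- length(w_samp)
  in_min <- function(traces) {
    apply(traces[, ch, w_samp, drop = FALSE], 1, min)
  }
  in_argmin <- function(traces) {
    idx <- apply(traces[, ch, w_samp, drop = FALSE], 1, which.min)
    (w_samp[idx] - si) / fs * 1000
  }
  # noise minima from pre-stimulus window-width chunks of the same trials
  pre_span <- seq_len(si - 1L)
  n_chunks <- length(pre_span) %/% width
  noise_min <- c()
  if (n_chunks >= 1L) {
    for (b in seq_len(n_chunks)) {
      cols <- pre_span[((b - 1L) * width + 1L):(b * width)]
      noise_min <- c(noise_min,
                     apply(ctr[, ch, cols, drop = FALSE], 1, min),
                     apply(tst[, ch, cols, drop = FALSE], 1, min))
    }
  }
  roc <- roc_spike_cutoff(in_min(ctr), noise_min)
  if (roc$flagged) flags <- c(flags, "degenerate_roc")
  cutoff <- roc$threshold
  spk_c <- in_min(ctr) < cutoff
  spk_t <- in_min(tst) < cutoff
  p_control <- mean(spk_c)
  p_test <- mean(spk_t)
  ct <- spike_count_test(sum(spk_c), n_ctr, sum(spk_t), n_tst)
  if (ct$flagged) flags <- c(flags, "exact_test")
  peaks <- in_argmin(ctr)[spk_c]
  lq <- if (length(peaks)) latency_quartiles(peaks) else
    list(latency_ms = NA_real_, jitter_ms = NA_real_)
  passed <- isTRUE(p_control > 0.5 && p_test < p_control / 2 &&
                     ct$p < alpha &&
                     !is.na(lq$latency_ms) && lq$latency_ms < max_latency_ms &&
                     lq$jitter_ms < max_jitter_ms)
  structure(list(window = unname(win), cutoff = cutoff,
                 p_control = p_control, p_test = p_test,
                 chi2_p = ct$p, latency_ms = lq$latency_ms,
                 jitter_ms = lq$jitter_ms, passed = passed,
                 channel = ch, flags = flags, reason = NULL),
            class = "collision_result")
}

#' @export
print.collision_result <- function(x, ...) {
  cat("Antidromic collision test:", if (x$passed) "PASSED" else "failed", "\n")
  if (!is.null(x$reason)) cat("  reason:", x$reason, "\n")
  if (!is.na(x$p_control)) {
    cat(sprintf("  window %.2f-%.2f ms, p_control %.2f, p_test %.2f, chi2 p %.3g\n",
                x$window[1], x$window[2], x$p_control, x$p_test, x$chi2_p))
    cat(sprintf("  latency %.2f ms, jitter %.3f ms\n", x$latency_ms, x$jitter_ms))
  }
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Direct optogenetic tagging of striatal projection neurons
#'
#' A unit is directly tagged when light-evoked spikes occur at short latency
#' with small jitter and the evoked waveform matches the spontaneous one.
#' The waveform correlation is the Pearson correlation of the concatenated
#' four-channel segments within 0.125 ms before and after the spike peak.
#' The latency limit depends on the pathway: 8 ms for striatonigral (direct
#' pathway, stimulated near the recording site) and 10 ms for striatopallidal
#' (indirect pathway, stimulated at the pallidal target).
#'
#' @param evoked_waveform Mean light-evoked waveform, matrix
#'   `[channel, sample]` (4 channels).
#' @param peak_times_ms Peak times of individual light-evoked spikes, ms
#'   after light onset.
#' @param spont_waveform Mean spontaneous waveform, same dimensions and
#'   sampling as `evoked_waveform`.
#' @param fs Waveform sampling rate, Hz. Default 20000.
#' @param pathway `"striatonigral"` or `"striatopallidal"`.
#' @param max_jitter_ms Jitter criterion, ms. Default 1.
#' @param min_r Waveform correlation criterion. Default 0.9.
#' @return Object of class `direct_tag_result`: `latency_ms`, `jitter_ms`,
#'   `waveform_r`, `latency_limit_ms`, `passed`.
#' @export
direct_tag <- function(evoked_waveform, peak_times_ms, spont_waveform,
                       fs = 20000, pathway = c("striatonigral", "striatopallidal"),
                       max_jitter_ms = 1, min_r = 0.9) {
  pathway <- match.arg(pathway)
  if (!is.matrix(evoked_waveform) || !is.matrix(spont_waveform) ||
      !all(dim(evoked_waveform) == dim(spont_waveform))) {
    stop("evoked and spontaneous waveforms must be matrices of equal dimensions")
  }
  if (nrow(evoked_waveform) != 4L) stop("waveforms must have 4 channels")
  half <- as.integer(round(0.125e-3 * fs))
  dom <- which.max(apply(abs(spont_waveform), 1, max))
  peak <- which.max(abs(spont_waveform[dom, ]))
  if (peak - half < 1L || peak + half > ncol(spont_waveform)) {
    stop("waveform window of 0.125 ms around the peak is not available")
  }
  cols <- (peak - half):(peak + half)
  r <- stats::cor(as.vector(t(evoked_waveform[, cols])),
                  as.vector(t(spont_waveform[, cols])))
  lq <- latency_quartiles(peak_times_ms)
  limit <- if (pathway == "striatonigral") 8 else 10
  passed <- isTRUE(lq$latency_ms < limit && lq$jitter_ms < max_jitter_ms &&
                     r > min_r)
  structure(list(latency_ms = lq$latency_ms, jitter_ms = lq$jitter_ms,
                 waveform_r = r, latency_limit_ms = limit,
                 pathway = pathway, passed = passed),
            class = "direct_tag_result")
}

#' @export
print.direct_tag_result <- function(x, ...) {
  cat("Direct optogenetic tag (", x$pathway, "): ",
      if (x$passed) "PASSED" else "failed", "\n", sep = "")
  cat(sprintf("  latency %.2f ms (limit %g), jitter %.3f ms, waveform r %.3f\n",
              x$latency_ms, x$latency_limit_ms, x$jitter_ms, x$waveform_r))
  invisible(x)
}

#' Frequency-following check for paired-pulse stimulation
#'
#' Advisory criterion for antidromic identification: with two light pulses
#' delivered at 100--250 Hz, a projection neuron should follow both. The
#' check passes when each pulse evokes an in-window spike in more than half
#' of the paired-pulse trials.
#'
#' @param spike_pulse1,spike_pulse2 Logical vectors (one element per trial):
#'   did an in-window spike follow the first / second pulse.
#' @param min_p Follow-probability criterion per pulse; default 0.5 (strict).
#' @return List with `p1`, `p2`, `passed`.
#' @export
frequency_following_test <- function(spike_pulse1, spike_pulse2, min_p = 0.5) {
  if (length(spike_pulse1) != length(spike_pulse2)) {
    stop("pulse vectors must have one element per paired-pulse trial")
  }
  if (length(spike_pulse1) == 0L) stop("no paired-pulse trials")
  p1 <- mean(spike_pulse1)
  p2 <- mean(spike_pulse2)
  list(p1 = p1, p2 = p2, passed = p1 > min_p && p2 > min_p)
}

#' Energy of a light-evoked response
#'
#' Sum of squared samples of the mean evoked waveform across channels; a
#' summary magnitude used for plotting identified units. The exact quantity
#' is not standardised in the field; this definition is the plain signal
#' energy and is intended for display only.
#'
#' @param waveform Numeric matrix `[channel, sample]` (or vector).
#' @return Scalar energy.
#' @export
evoked_energy <- function(waveform) {
  sum(as.numeric(waveform)^2)
}
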