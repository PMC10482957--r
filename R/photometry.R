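#' Dual-channel fiber-photometry trace
#'
#' Container for a dopamine-sensor recording: the 470 nm signal channel and
#' the 405 nm isosbestic control channel, sampled at a common rate.
#'
#' @param signal_470,isosbestic_405 Numeric fluorescence series (a.u.), equal
#'   length.
#' @param fs Acquisition sampling rate, Hz. Default 1000.
#' @param t0 Session-clock time of the first sample, seconds. Default 0.
#' @return Object of class `photometry_trace`.
#' @export
photometry_trace <- function(signal_470, isosbestic_405, fs = 1000, t0 = 0) {
  if (length(signal_470) != length(isosbestic_405)) {
    stop("signal and isosbestic channels must have equal length")
  }
  if (fs <= 0) stop("fs must be positive")
  structure(list(signal_470 = as.numeric(signal_470),
                 isosbestic_405 = as.numeric(isosbestic_405),
                 fs = fs, t0 = t0),
            class = "photometry_trace")
}

#' @export
print.photometry_trace <- function(x, ...) {
  cat(sprintf("Photometry trace: %d samples at %g Hz (%.1f s), t0 = %.3f s\n",
              length(x$signal_470), x$fs, length(x$signal_470) / x$fs, x$t0))
  invisible(x)
}

#' Remove exponential and linear decay from a fluorescence channel
#'
#' Least-squares fit of `a * exp(-t / tau) + b * t + c`, subtracted from the
#' channel. The time constant is profiled: for any fixed tau the remaining
#' parameters are linear, so the fit reduces to a one-dimensional
#' minimisation of the residual sum of squares over log-tau, which is robust
#' where a joint nonlinear fit would need delicate starting values. If the
#' exponential term is degenerate (collinear with the linear trend), the fit
#' falls back to linear-only and is flagged.
#'
#' @param channel Numeric fluorescence series.
#' @param fs Sampling rate, Hz.
#' @return List with `detrended` (channel minus fitted curve), `fitted`,
#'   `coefficients` (`a`, `tau`, `b`, `c`; `a`/`tau` `NA` for the linear
#'   fallback), `method` (`"exp_linear"` or `"linear"`), `flagged`.
#' @export
remove_decay <- function(channel, fs = 1000) {
  x <- as.numeric(channel)
  n <- length(x)
  if (n < 4L) stop("series too short to fit exponential + linear decay")
  t <- (seq_len(n) - 1) / fs
  span <- t[n]
  fit_at <- function(tau) {
    e <- exp(-t / tau)
    f <- stats::lm.fit(cbind(e = e, t = t, c = 1), x)
    list(rss = sum(f$residuals^2), coef = f$coefficients, fitted = x - f$residuals)
  }
  lin <- stats::lm.fit(cbind(t = t, c = 1), x)
  lin_rss <- sum(lin$residuals^2)
  opt <- stats::optimize(function(lt) fit_at(exp(lt))$rss,
                         interval = log(c(span / 200, span * 5)))
  best <- fit_at(exp(opt$minimum))
  degenerate <- any(is.na(best$coef)) ||
    (lin_rss > 0 && (lin_rss - best$rss) / lin_rss < 1e-10 &&
       abs(opt$minimum - log(span * 5)) < 1e-3)
  if (degenerate) {
    fitted <- x - lin$residuals
    return(list(detrended = x - fitted, fitted = fitted,
                coefficients = c(a = NA_real_, tau = NA_real_,
                                 b = unname(lin$coefficients["t"]),
                                 c = unname(lin$coefficients["c"])),
                method = "linear", flagged = TRUE))
  }
  list(detrended = x - best$fitted, fitted = best$fitted,
       coefficients = c(a = unname(best$coef["e"]), tau = exp(opt$minimum),
                        b = unname(best$coef["t"]), c = unname(best$coef["c"])),
       method = "exp_linear", flagged = FALSE)
}

#' Isosbestic correction and dF/F
#'
#' An ordinary least-squares line maps the isosbestic channel onto the signal
#' channel; dF/F is the residual divided by the fitted value:
#' `(sig - fit(iso)) / fit(iso)`. Fitted values must be bounded away from
#' zero, otherwise the ratio is numerically meaningless and the function
#' aborts.
#'
#' @param sig Detrended 470 nm series (with its DC level retained).
#' @param iso Detrended 405 nm series, same length.
#' @param eps Magnitude floor for the fitted isosbestic values. Default 1e-6.
#' @return Numeric dF/F series.
#' @export
isosbestic_dff <- function(sig, iso, eps = 1e-6) {
  if (length(sig) != length(iso)) stop("sig and iso must have equal length")
  f <- stats::lm.fit(cbind(1, iso), sig)
  fitted <- sig - f$residuals
  if (any(abs(fitted) < eps)) {
    stop("fitted isosbestic signal approaches zero (|fit| < ", eps,
         "); dF/F division is unstable")
  }
  (sig - fitted) / fitted
}

#' Downsample by block averaging
#'
#' @param series Numeric vector sampled at `fs_in`.
#' @param fs_in,fs_out Input and output rates, Hz; `fs_in` must be an integer
#'   multiple of `fs_out`.
#' @return Numeric vector at `fs_out`; a trailing partial block is dropped.
#' @export
downsample <- function(series, fs_in, fs_out) {
  k <- fs_in / fs_out
  if (abs(k - round(k)) > 1e-9) stop("fs_in must be an integer multiple of fs_out")
  k <- as.integer(round(k))
  n <- (length(series) %/% k) * k
  if (n == 0L) return(numeric(0))
  colMeans(matrix(series[seq_len(n)], nrow = k))
}

#' Full photometry processing chain
#'
#' Detrends both channels (exponential + linear), restores each channel's DC
#' level (mean of its fitted decay curve) so the subsequent ratio is taken
#' against the channel's baseline fluorescence rather than a zero-mean
#' residual, applies the isosbestic correction and dF/F, downsamples by block
#' mean to the analysis rate, and z-scores over the whole session.
#'
#' @param trace A [photometry_trace()].
#' @param fs_analysis Analysis sampling rate, Hz. Default 40.
#' @param eps Floor for the fitted isosbestic values, see [isosbestic_dff()].
#' @return Object of class `normalized_signal`: `dff` and `z` series at
#'   `fs_analysis`, `fs`, `t0`, and the per-channel detrend fits
#'   (`fit_470`, `fit_405`).
#' @export
process_photometry <- function(trace, fs_analysis = 40, eps = 1e-6) {
  stopifnot(inherits(trace, "photometry_trace"))
  f470 <- remove_decay(trace$signal_470, trace$fs)
  f405 <- remove_decay(trace$isosbestic_405, trace$fs)
  sig <- f470$detrended + mean(f470$fitted)
  iso <- f405$detrended + mean(f405$fitted)
  dff <- isosbestic_dff(sig, iso, eps)
  dff_ds <- downsample(dff, trace$fs, fs_analysis)
  s <- stats::sd(dff_ds)
  z <- if (is.finite(s) && s > 0) (dff_ds - mean(dff_ds)) / s else dff_ds * 0
  structure(list(dff = dff_ds, z = z, fs = fs_analysis, t0 = trace$t0,
                 fit_470 = f470, fit_405 = f405),
            class = "normalized_signal")
}

#' @export
print.normalized_signal <- function(x, ...) {
  cat(sprintf("Normalized photometry signal: %d samples at %g Hz\n",
              length(x$dff), x$fs))
  cat(sprintf("  dF/F range [%.4f, %.4f]\n", min(x$dff), max(x$dff)))
  invisible(x)
}

#' Align a signal to behavioral events
#'
#' Extracts per-event snippets of the normalized signal on the analysis
#' clock. Events whose window falls outside the recorded span are dropped
#' with a warning.
#'
#' @param signal A `normalized_signal`, or a plain numeric series (then `fs`
#'   and `t0` must be supplied).
#' @param events Event times, seconds on the session clock.
#' @param window `c(pre, post)` seconds around each event (`pre` >= 0 extends
#'   before the event).
#' @param channel For `normalized_signal` input, `"z"` (default) or `"dff"`.
#' @param fs,t0 Sampling rate and start time for plain-series input.
#' @return Matrix, one row per retained event; column times (seconds relative
#'   to the event) in attribute `"time"`, retained event times in attribute
#'   `"events"`. Column `pre * fs + 1` is the event sample.
#' @export
align_to_events <- function(signal, events, window = c(1, 2), channel = "z",
                            fs = NULL, t0 = NULL) {
  if (inherits(signal, "normalized_signal")) {
    x <- signal[[match.arg(channel, c("z", "dff"))]]
    fs <- signal$fs
    t0 <- signal$t0
  } else {
    x <- as.numeric(signal)
    if (is.null(fs)) stop("fs must be supplied for plain-series input")
    if (is.null(t0)) t0 <- 0
  }
  if (length(events) == 0L) stop("event list is empty")
  npre <- as.integer(round(window[1] * fs))
  npost <- as.integer(round(window[2] * fs))
  i0 <- as.integer(round((events - t0) * fs)) + 1L
  ok <- (i0 - npre) >= 1L & (i0 + npost) <= length(x)
  if (!all(ok)) {
    warning(sum(!ok), " event(s) outside the recorded span dropped")
  }
  if (!any(ok)) stop("no events fall within the recorded span")
  i0 <- i0[ok]
  mat <- t(vapply(i0, function(i) x[(i - npre):(i + npost)],
                  numeric(npre + npost + 1L)))
  attr(mat, "time") <- (seq_len(npre + npost + 1L) - npre - 1L) / fs
  attr(mat, "events") <- events[ok]
  mat
}

#' Per-trial mean over a named window of an aligned matrix
#'
#' @param aligned Matrix from [align_to_events()].
#' @param interval `c(start, end)` seconds relative to the event; the window
#'   is half-open `[start, end)`.
#' @return Numeric vector, one value per trial (row mean over the window).
#' @export
window_values <- function(aligned, interval) {
  tm <- attr(aligned, "time")
  if (is.null(tm)) stop("aligned matrix lacks a time attribute")
  cols <- tm >= interval[1] - 1e-9 & tm < interval[2] - 1e-9
  if (!any(cols)) stop("window [", interval[1], ", ", interval[2],
                       ") lies outside the snippet span")
  rowMeans(aligned[, cols, drop = FALSE])
}

#' Event-window intervals used throughout the analyses
#'
#' Go window 0--0.3 s after the Go cue, movement window 0--0.3 s after
#' movement onset, outcome window 0--0.5 s after outcome-tone onset, baseline
#' 2--3 s before the Go cue.
#'
#' @return Named list of `c(start, end)` intervals in seconds relative to the
#'   aligning event.
#' @export
event_windows <- function() {
  list(baseline = c(-3, -2), go = c(0, 0.3),
       movement = c(0, 0.3), outcome = c(0, 0.5))
}
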