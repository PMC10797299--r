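#' Construct a photometry trace
#'
#' A uniformly sampled two-channel fiber-photometry recording: the
#' calcium-dependent 470 nm signal channel, the isosbestic 410 nm
#' reference channel, and the event onset times.
#'
#' @param t sample times, s (uniform grid starting at 0).
#' @param f470,f410 channel samples, same length as `t`.
#' @param events event onset times, s, inside `[t[1], t[n]]`.
#' @param fs sampling rate, Hz.
#' @return An object of class `photometry_trace`.
#' @export
photometry_trace <- function(t, f470, f410 = NULL, events = numeric(0),
                             fs = 1 / diff(t[1:2])) {
  stopifnot(is.numeric(t))
  if (length(f470) != length(t) ||
      (!is.null(f410) && length(f410) != length(t)))
    stop("channels must have the same length as t", call. = FALSE)
  if (fs <= 0) stop("fs must be positive", call. = FALSE)
  if (length(events) && any(events < t[1] | events > t[length(t)]))
    stop("events outside the recording", call. = FALSE)
  structure(list(t = t, f470 = f470, f410 = f410,
                 events = sort(events), fs = fs),
            class = "photometry_trace")
}

#' @export
print.photometry_trace <- function(x, ...) {
  cat(sprintf("Photometry trace: %.1f s @ %g Hz, %d event(s)%s\n",
              x$t[length(x$t)], x$fs, length(x$events),
              if (is.null(x$f410)) "" else ", 410 nm reference present"))
  invisible(x)
}

#' Extract event-locked epochs from a trace
#'
#' One row per retained event, sampled on the half-open relative window
#' `[pre, post)` (so a `(-2, 5)` s window at 100 Hz gives 700 columns).
#' Events whose window leaves the recording are dropped with a message.
#' For consummatory events such as licking, only the first `first_k`
#' events of a session are conventionally analyzed.
#'
#' @param trace a [photometry_trace()].
#' @param window_s numeric length-2, window relative to event onset, s.
#' @param events event times (default the trace's events).
#' @param first_k keep only the first k events (NULL = all; the lick
#'   convention is 4).
#' @param channel `"f470"` or `"f410"`.
#' @return An `epoch_matrix`: numeric matrix (events x samples) with the
#'   relative time axis in `attr(, "time_s")`.
#' @export
epoch <- function(trace, window_s = c(-2, 5), events = trace$events,
                  first_k = NULL, channel = c("f470", "f410")) {
  channel <- match.arg(channel)
  f <- trace[[channel]]
  if (is.null(f)) stop(sprintf("trace has no %s channel", channel),
                      call. = FALSE)
  if (!is.null(first_k)) events <- utils::head(sort(events), first_k)
  fs <- trace$fs
  n_rel <- round((window_s[2] - window_s[1]) * fs)
  rel <- window_s[1] + (seq_len(n_rel) - 1) / fs
  i0 <- round(events * fs) + 1L          # sample index of event onset
  off <- round(window_s[1] * fs)
  ok <- (i0 + off) >= 1L & (i0 + off + n_rel - 1L) <= length(f)
  if (any(!ok))
    message(sum(!ok), " event(s) dropped: window exceeds the recording")
  events <- events[ok]
  m <- t(vapply(i0[ok], function(i) f[i + off + seq_len(n_rel) - 1L],
                numeric(n_rel)))
  if (length(events) == 0) m <- matrix(numeric(0), 0, n_rel)
  structure(m, class = c("epoch_matrix", "matrix"),
            time_s = rel, events = events, fs = fs, channel = channel)
}

#' Event-locked dF/F
#'
#' For each retained event, the baseline F0 is the mean of the channel
#' over the pre-event window `[-baseline_s, 0)`, and every sample of the
#' epoch is converted to dF/F. The default formula is `(F - F0) / F`
#' ("printed" variant); `variant = "conventional"` selects the usual
#' `(F - F0) / F0`. Under the printed variant a sample with F = 0 is
#' undefined and reported missing (NA), with a message giving the count.
#' Both variants are invariant to rescaling the raw fluorescence by any
#' positive constant. The 410 nm reference channel is processed
#' identically (`channel = "f410"`) as the motion control.
#'
#' @param trace a [photometry_trace()].
#' @param baseline_s pre-event baseline length, s (lick convention 2 s,
#'   tail-suspension convention 30 s).
#' @param window_s epoch window relative to the event, s.
#' @param variant dF/F denominator: `"printed"` (F) or `"conventional"`
#'   (F0).
#' @param events,first_k,channel passed to [epoch()].
#' @return An `epoch_matrix` of dF/F values with the per-event baselines
#'   in `attr(, "f0")` and the baseline window in
#'   `attr(, "baseline_window_s")`.
#' @examples
#' tr <- photometry_trace(t = (0:999) / 100, f470 = rep(2, 1000),
#'                        events = 5, fs = 100)
#' range(dff(tr, baseline_s = 2, window_s = c(-2, 3)))
#' @export
dff <- function(trace, baseline_s = 2, window_s = c(-2, 5),
                variant = c("printed", "conventional"),
                events = trace$events, first_k = NULL,
                channel = c("f470", "f410")) {
  variant <- match.arg(variant)
  channel <- match.arg(channel)
  stopifnot(baseline_s > 0)
  win <- c(min(window_s[1], -baseline_s), window_s[2])
  ep <- epoch(trace, window_s = win, events = events, first_k = first_k,
              channel = channel)
  rel <- attr(ep, "time_s")
  base_cols <- rel >= -baseline_s & rel < 0
  f0 <- rowMeans(ep[, base_cols, drop = FALSE])
  denom <- if (variant == "printed") unclass(ep) else
    matrix(f0, nrow(ep), ncol(ep))
  out <- (unclass(ep) - f0) / denom
  n_undef <- sum(denom == 0)
  if (n_undef > 0) {
    out[denom == 0] <- NA_real_
    message(n_undef, " sample(s) with F = 0 reported missing under the printed formula")
  }
  keep_cols <- rel >= window_s[1]
  structure(out[, keep_cols, drop = FALSE],
            class = c("epoch_matrix", "matrix"),
            time_s = rel[keep_cols], events = attr(ep, "events"),
            fs = attr(ep, "fs"), channel = channel, variant = variant,
            f0 = f0, baseline_window_s = c(-baseline_s, 0))
}

epoch_window_cols <- function(epochs, window_s) {
  rel <- attr(epochs, "time_s")
  sel <- rel >= window_s[1] - 1e-12 & rel <= window_s[2] + 1e-12
  if (!any(sel)) stop("window outside the epoch", call. = FALSE)
  sel
}

#' Area under the event-locked curve
#'
#' Trapezoidal integral of dF/F over a window relative to the event, per
#' event, on the native sample grid (no resampling), plus the mean across
#' events. Conventional windows: 0-5 s for sucrose consumption, 0-40 s for
#' tail suspension.
#'
#' @param epochs an `epoch_matrix` (typically from [dff()]).
#' @param window_s numeric length-2 integration window `[a, b]`, s.
#' @return list with `per_event` (numeric vector) and `mean`.
#' @export
epoch_auc <- function(epochs, window_s = c(0, 5)) {
  sel <- epoch_window_cols(epochs, window_s)
  rel <- attr(epochs, "time_s")[sel]
  m <- unclass(epochs)[, sel, drop = FALSE]
  per <- apply(m, 1, function(y)
    sum(diff(rel) * (utils::head(y, -1) + utils::tail(y, -1)) / 2))
  list(per_event = as.numeric(per), mean = mean(per))
}

#' Event-locked peak response
#'
#' Per-event extremum of dF/F in a window relative to the event: the
#' maximum by default, or the minimum for suppression analyses, plus the
#' mean across events.
#'
#' @param epochs an `epoch_matrix`.
#' @param window_s numeric length-2 search window, s.
#' @param type `"max"` or `"min"`.
#' @return list with `per_event` and `mean`.
#' @export
epoch_peak <- function(epochs, window_s = c(0, 5),
                       type = c("max", "min")) {
  type <- match.arg(type)
  sel <- epoch_window_cols(epochs, window_s)
  m <- unclass(epochs)[, sel, drop = FALSE]
  per <- apply(m, 1, if (type == "max") max else min)
  list(per_event = as.numeric(per), mean = mean(per))
}
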