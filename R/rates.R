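# Event-rate series, the iterated moving-average (Kolmogorov-Zurbenko)
# filter, and the steady-state hit-rate detector.
#
# The detector mirrors the standard analysis of these tasks: smooth the
# target creation and target hit rates with two KZ iterations of a 5 s
# window, find the last 5 s window in which the median difference between
# the two smoothed rates stays below 0.1 Hz (the participant still keeping
# pace), and call the start of that window the overwhelmed-phase onset. The
# steady-state rate is then the raw target hit count from that onset to the
# end of the trial divided by the elapsed time.

#' Steady-state detection settings
#'
#' @param rate_bin_width Width of the counting bins for the rate series, s.
#'   The default 1 s makes the 5 s KZ window five samples wide.
#' @param kz_window KZ moving-average window, s (must discretise to an odd
#'   number of samples).
#' @param kz_iterations Number of KZ iterations.
#' @param median_threshold Keeping-pace criterion on the median
#'   creation-minus-hit rate difference, Hz.
#' @return A `steady_state_config` list.
#' @export
steady_state_config <- function(rate_bin_width = 1, kz_window = 5,
                                kz_iterations = 2, median_threshold = 0.1) {
  if (kz_window <= 0 || rate_bin_width <= 0) {
    stop("window and bin width must be positive")
  }
  m <- round(kz_window / rate_bin_width)
  if (m %% 2 == 0) {
    stop("kz_window must span an odd number of rate bins (got ", m, ")")
  }
  structure(list(rate_bin_width = rate_bin_width, kz_window = kz_window,
                 kz_iterations = kz_iterations,
                 median_threshold = median_threshold),
            class = "steady_state_config")
}

#' Event times to a binned rate series
#'
#' Counts events in consecutive bins of `bin_width` seconds over
#' `[0, t_end]` and divides by the bin width, giving a piecewise-constant
#' rate estimate in Hz centred on each bin.
#'
#' @param times Event times, s (any order; empty allowed).
#' @param t_end End of the observation interval, s; defaults to the last
#'   event.
#' @param bin_width Bin width, s.
#' @return Data frame with `t` (bin centres) and `rate` (Hz).
#' @examples
#' event_rate_series(seq(0, 59.9, by = 0.1), t_end = 60)$rate  # flat 10 Hz
#' @export
event_rate_series <- function(times, t_end = NULL, bin_width = 1) {
  if (is.null(t_end)) t_end <- if (length(times)) max(times) else 0
  n_bins <- max(1L, ceiling(t_end / bin_width))
  counts <- tabulate(pmin(floor(times / bin_width) + 1L, n_bins), n_bins)
  data.frame(t = (seq_len(n_bins) - 0.5) * bin_width,
             rate = counts / bin_width)
}

#' Kolmogorov-Zurbenko filter
#'
#' `k` iterations of a centred moving average of window `m` samples. At the
#' series edges the window shrinks to the available samples (truncated-
#' window convention), so constant series pass through unchanged and the
#' interior of a linear ramp is preserved.
#'
#' @param x Numeric series.
#' @param m Window length in samples (odd).
#' @param k Number of iterations.
#' @return Filtered series, same length as `x`.
#' @examples
#' kz_filter(rep(3, 10), m = 5, k = 2)  # unchanged
#' @export
kz_filter <- function(x, m = 5, k = 2) {
  if (m %% 2 == 0) stop("KZ window length 'm' must be odd")
  n <- length(x)
  if (n == 0) return(x)
  if (m > n) {
    warning("KZ window longer than series; returning the overall mean")
    return(rep(mean(x), n))
  }
  half <- (m - 1) / 2
  for (iter in seq_len(k)) {
    cs <- cumsum(c(0, x))
    lo <- pmax(seq_len(n) - half, 1)
    hi <- pmin(seq_len(n) + half, n)
    x <- (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
  }
  x
}

#' Detect the overwhelmed-phase onset and steady-state hit rate
#'
#' Smooths the target creation and target hit rate series, slides a window
#' of `kz_window` seconds in steps of one rate bin, and finds the last
#' window whose median (creation - hit) rate difference is below
#' `median_threshold`: its start is the overwhelmed-phase onset. The
#' steady-state rate is the raw count of target hits from the onset to the
#' end of the trial divided by that duration.
#'
#' Degenerate trials are flagged rather than rejected: if no window
#' qualifies (overwhelmed from the start) the onset is 0 and
#' `degenerate = "never_kept_pace"`; if the last qualifying window runs to
#' the trial end (never overwhelmed) the rate is computed over that final
#' window and `degenerate = "never_overwhelmed"`.
#'
#' @param trial A `trial_recording`, or a list with numeric `created` and
#'   `hit` target event times plus `t_end`.
#' @param cfg A [steady_state_config()].
#' @return List with `rate` (Hz), `onset_time` (s), `degenerate`
#'   (`"none"`, `"never_kept_pace"`, `"never_overwhelmed"`, or `"no_hits"`).
#' @examples
#' tr <- simulate_trial(oh_task(), participant_spec("p1", 60, rng_seed = 4))
#' steady_state_rate(tr)
#' @export
steady_state_rate <- function(trial, cfg = steady_state_config()) {
  ev <- target_event_times(trial)
  t_end <- ev$t_end
  if (!length(ev$hit)) {
    return(list(rate = 0, onset_time = 0, degenerate = "no_hits"))
  }
  bw <- cfg$rate_bin_width
  created <- event_rate_series(ev$created, t_end = t_end, bin_width = bw)
  hit <- event_rate_series(ev$hit, t_end = t_end, bin_width = bw)
  m <- round(cfg$kz_window / bw)
  diff_rate <- kz_filter(created$rate, m, cfg$kz_iterations) -
    kz_filter(hit$rate, m, cfg$kz_iterations)

  n <- length(diff_rate)
  win <- m                       # window length in bins = kz_window seconds
  if (n < win) {
    return(list(rate = length(ev$hit) / t_end, onset_time = 0,
                degenerate = "never_kept_pace"))
  }
  n_win <- n - win + 1
  med <- vapply(seq_len(n_win), function(i) {
    median(diff_rate[i:(i + win - 1)])
  }, numeric(1))
  ok <- which(med < cfg$median_threshold)

  if (!length(ok)) {
    return(list(rate = length(ev$hit) / t_end, onset_time = 0,
                degenerate = "never_kept_pace"))
  }
  last <- ok[length(ok)]
  onset <- (last - 1) * bw       # start of the last keeping-pace window
  degenerate <- "none"
  if (last == n_win) {
    degenerate <- "never_overwhelmed"
  }
  span <- t_end - onset
  rate <- sum(ev$hit >= onset) / span
  list(rate = rate, onset_time = onset, degenerate = degenerate)
}

target_event_times <- function(trial) {
  if (inherits(trial, "trial_recording")) {
    obj <- trial$objects
    tgt <- obj[obj$role == "target", ]
    t_end <- trial$metadata$trial_end
    if (is.null(t_end) || !is.finite(t_end)) t_end <- max(obj$t_outcome)
    list(created = tgt$t_created,
         hit = tgt$t_outcome[tgt$outcome == "hit"],
         t_end = t_end)
  } else {
    stopifnot(is.list(trial), !is.null(trial$created), !is.null(trial$hit))
    t_end <- trial$t_end
    if (is.null(t_end)) t_end <- max(c(trial$created, trial$hit))
    list(created = trial$created, hit = trial$hit, t_end = t_end)
  }
}

#' Per-bin target accuracy by trial phase
#'
#' For each drop bin, the fraction of targets created before (early phase)
#' and after (overwhelmed phase) the given onset that were hit. Cells with
#' no targets are `NA`.
#'
#' @param trial A `trial_recording`.
#' @param onset_time Overwhelmed-phase onset, s (from
#'   [steady_state_rate()]).
#' @return A 2 x n_bins matrix with rows `early` and `overwhelmed`.
#' @export
per_bin_accuracy <- function(trial, onset_time) {
  obj <- trial$objects
  tgt <- obj[obj$role == "target", ]
  n_bins <- trial$metadata$n_bins
  if (is.null(n_bins) || !is.finite(n_bins)) n_bins <- max(obj$bin)
  out <- matrix(NA_real_, 2, n_bins,
                dimnames = list(c("early", "overwhelmed"), NULL))
  phase <- ifelse(tgt$t_created < onset_time, 1L, 2L)
  for (ph in 1:2) {
    sub <- tgt[phase == ph, ]
    if (!nrow(sub)) next
    acc <- tapply(sub$outcome == "hit", factor(sub$bin, levels = 1:n_bins),
                  mean)
    out[ph, ] <- as.numeric(acc)
  }
  out
}
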