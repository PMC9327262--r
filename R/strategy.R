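# Movement-strategy summaries: do participants couple their paddles (or
# move them in strict alternation), and do they alternate between
# preparation and action? Two checks: the distribution of per-second mean
# cosine similarities between the two paddle velocity vectors, and a
# short-history prediction model for the gaps between successive
# object/paddle contacts.

#' Cosine similarity of two 2-vectors
#'
#' `dot(v1, v2) / (|v1| |v2|)`: 1 for proportional vectors, -1 for opposite
#' ones, 0 for orthogonal. Undefined (NA) if either vector is zero.
#'
#' @param v1,v2 Numeric 2-vectors.
#' @return Dimensionless value in `[-1, 1]`, or `NA`.
#' @examples
#' cosine_similarity(c(1, 0), c(2, 0))   # 1
#' cosine_similarity(c(1, 0), c(0, 5))   # 0
#' @export
cosine_similarity <- function(v1, v2) {
  n1 <- sqrt(sum(v1^2))
  n2 <- sqrt(sum(v2^2))
  if (n1 == 0 || n2 == 0) return(NA_real_)
  s <- sum(v1 * v2) / (n1 * n2)
  min(1, max(-1, s))
}

#' Per-second paddle-velocity similarity summary
#'
#' For each whole second `[k, k+1)` of the trial, the mean cosine
#' similarity between the left and right paddle velocity vectors over that
#' second's samples (samples where either paddle is exactly stationary are
#' excluded, the cosine being undefined there); then the 50th percentile
#' and interquartile range of those per-second means. Values of `p50` near
#' 1 would indicate paddles moved as one unit, near -1 strict alternation
#' or mirroring, near 0 with a wide IQR independent control.
#'
#' @param trial A `trial_recording` with samples.
#' @return List with `series` (data frame `second`, `mean_similarity`),
#'   `p50` and `iqr`.
#' @export
paddle_similarity_summary <- function(trial) {
  smp <- require_samples(trial)
  t_end <- max(smp$t)
  if (t_end < 2) stop("trial too short for a similarity summary (< 2 s)")
  lx <- smp$left_vx; ly <- smp$left_vy
  rx <- smp$right_vx; ry <- smp$right_vy
  nl <- sqrt(lx^2 + ly^2)
  nr <- sqrt(rx^2 + ry^2)
  cs <- (lx * rx + ly * ry) / (nl * nr)
  cs[nl == 0 | nr == 0] <- NA
  sec <- floor(smp$t)
  keep <- sec < floor(t_end)             # whole seconds only
  means <- tapply(cs[keep], sec[keep], mean, na.rm = TRUE)
  means[is.nan(means)] <- NA
  series <- data.frame(second = as.integer(names(means)),
                       mean_similarity = as.numeric(means))
  vals <- series$mean_similarity[!is.na(series$mean_similarity)]
  list(series = series,
       p50 = median(vals),
       iqr = IQR(vals, type = 7))
}

#' Inter-contact gap prediction model
#'
#' Models each gap between successive object/paddle contacts as a scaled
#' running mean of the preceding ten gaps,
#' `gap_i = scaling * mean(gap_(i-10) ... gap_(i-1))`, the scaling factor
#' (default 0.965) absorbing the steadily accelerating object creation.
#' Prediction errors are `(predicted - actual)` expressed as a percentage
#' of the trial's average inter-contact gap; their median and IQR summarise
#' how far the participant departs from steadily maximising their contact
#' rate. Small errors mean there is no alternation between preparation and
#' action phases.
#'
#' @param contact_times Times of successive object/paddle contacts, s
#'   (targets and, in OHA, struck distractors). May be passed unsorted.
#' @param window Number of preceding gaps in the running mean.
#' @param scaling Scaling factor applied to the running mean.
#' @return A `gap_model_result`: list with `predicted` (s), `errors_pct`,
#'   `median_error_pct`, `iqr_pct`, `scaling`, `window`. With fewer than
#'   `window + 2` contacts the summaries are `NA` (with a warning).
#' @examples
#' gap_prediction(cumsum(rep(0.5, 30)))$median_error_pct  # -3.5
#' @export
gap_prediction <- function(contact_times, window = 10, scaling = 0.965) {
  ct <- sort(contact_times)
  gaps <- diff(ct)
  n <- length(gaps)
  res <- list(predicted = numeric(0), errors_pct = numeric(0),
              median_error_pct = NA_real_, iqr_pct = NA_real_,
              scaling = scaling, window = window)
  class(res) <- "gap_model_result"
  if (n < window + 1) {
    warning("need at least ", window + 2, " contacts for gap prediction")
    return(res)
  }
  idx <- (window + 1):n
  cs <- cumsum(c(0, gaps))
  pred <- scaling * (cs[idx] - cs[idx - window]) / window
  avg_gap <- mean(gaps)
  err <- 100 * (pred - gaps[idx]) / avg_gap
  res$predicted <- pred
  res$errors_pct <- err
  res$median_error_pct <- median(err)
  res$iqr_pct <- IQR(err, type = 7)
  res
}

#' @export
print.gap_model_result <- function(x, ...) {
  cat(sprintf(
    "<gap_model_result> %d predicted gaps; median error %.2f%%, IQR %.2f%%\n",
    length(x$predicted), x$median_error_pct, x$iqr_pct))
  invisible(x)
}

#' Strategy summary for one trial
#'
#' Bundles [paddle_similarity_summary()] and [gap_prediction()] (contacts =
#' all hit events, targets and distractors) into one row.
#'
#' @param trial A `trial_recording` with samples.
#' @return One-row data frame.
#' @export
strategy_summary <- function(trial) {
  sim <- paddle_similarity_summary(trial)
  contacts <- trial$objects$t_outcome[trial$objects$outcome == "hit"]
  gp <- suppressWarnings(gap_prediction(contacts))
  data.frame(
    participant_id = trial$metadata$participant_id,
    task = trial$metadata$task_name,
    similarity_p50 = sim$p50,
    similarity_iqr = sim$iqr,
    gap_median_error_pct = gp$median_error_pct,
    gap_iqr_pct = gp$iqr_pct,
    stringsAsFactors = FALSE
  )
}
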