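# Per-trial performance parameters: the standard battery computed from one
# trial recording (kinematic summaries, bilateral biases, spatial measures,
# error timing, OHA-specific rates) plus the steady-state quantities from
# rates.R. Every function here is a pure function of the recording.

hand_cols <- function(hand) {
  hand <- match.arg(hand, c("left", "right"))
  paste0(hand, c("_x", "_y", "_vx", "_vy"))
}

#' Mean hand speed
#'
#' Time-average of the Euclidean speed of one hand over the trial,
#' trapezoidal in time (equivalent to the plain mean on a regular grid up
#' to half-weighting of the end samples).
#'
#' @param trial A `trial_recording` with samples.
#' @param hand `"left"` or `"right"`.
#' @return Speed in cm/s.
#' @export
mean_hand_speed <- function(trial, hand) {
  smp <- require_samples(trial)
  cols <- hand_cols(hand)
  if (!all(cols[3:4] %in% names(smp))) {
    stop("samples lack velocity columns for the ", hand, " hand")
  }
  if (nrow(smp) < 2) stop("need at least 2 samples")
  sp <- sqrt(smp[[cols[3]]]^2 + smp[[cols[4]]]^2)
  tt <- smp$t
  sum(diff(tt) * (head(sp, -1) + tail(sp, -1)) / 2) / (tt[length(tt)] - tt[1])
}

require_samples <- function(trial) {
  stopifnot(inherits(trial, "trial_recording"))
  if (is.null(trial$samples)) {
    stop("this recording has no kinematic samples ",
         "(simulated with include_samples = FALSE?)")
  }
  trial$samples
}

#' Bilateral bias
#'
#' `(right - left) / (right + left)`: -1 means all left hand, +1 all right
#' hand, 0 symmetric. Both inputs must be non-negative; if both are zero
#' the bias is undefined and `NA` is returned with a warning.
#'
#' @param left,right Non-negative magnitudes (speeds, areas, counts).
#' @return Value in `[-1, 1]`, or `NA`.
#' @examples
#' bilateral_bias(2, 1)   # -1/3
#' bilateral_bias(0, 5)   # 1
#' @export
bilateral_bias <- function(left, right) {
  stopifnot(left >= 0, right >= 0)
  if (left + right == 0) {
    warning("bilateral bias undefined: both sides are zero")
    return(NA_real_)
  }
  (right - left) / (right + left)
}

#' Movement area of one hand
#'
#' Area of the convex hull enclosing the complete sampled hand path, cm^2.
#' Degenerate (collinear or near-point) paths give 0.
#'
#' @inheritParams mean_hand_speed
#' @return Area in cm^2.
#' @export
movement_area <- function(trial, hand) {
  smp <- require_samples(trial)
  cols <- hand_cols(hand)
  convex_hull_area(smp[[cols[1]]], smp[[cols[2]]])
}

# Shoelace area of the convex hull of a point set.
convex_hull_area <- function(x, y) {
  pts <- unique(cbind(x, y))
  if (nrow(pts) < 3) return(0)
  h <- chull(pts[, 1], pts[, 2])
  hx <- pts[h, 1]; hy <- pts[h, 2]
  if (length(h) < 3) return(0)
  abs(sum(hx * c(hy[-1], hy[1]) - c(hx[-1], hx[1]) * hy)) / 2
}

#' Hand bias of hits
#'
#' [bilateral_bias()] applied to the left/right counts of target hits:
#' which hand does more of the hitting.
#'
#' @param trial A `trial_recording`.
#' @return Value in `[-1, 1]`, `NA` when nothing was hit.
#' @export
hand_bias_of_hits <- function(trial) {
  hits <- target_hits(trial)
  if (!nrow(hits)) {
    warning("no target hits; hand bias undefined")
    return(NA_real_)
  }
  bilateral_bias(sum(hits$hand == "left"), sum(hits$hand == "right"))
}

target_hits <- function(trial) {
  obj <- trial$objects
  obj[obj$role == "target" & obj$outcome == "hit", ]
}

#' Hand selection overlap
#'
#' Within each drop bin, order that bin's target hits chronologically and
#' count adjacent left/right alternations ("hand switches"); the overlap is
#' the total count over bins divided by the task's number of targets, as a
#' percentage. 0 means each bin is owned by one hand.
#'
#' @param trial A `trial_recording`.
#' @return Percentage in `[0, 100]`.
#' @export
hand_selection_overlap <- function(trial) {
  hits <- target_hits(trial)
  n_targets <- trial$metadata$n_targets
  if (is.null(n_targets) || !is.finite(n_targets)) {
    n_targets <- sum(trial$objects$role == "target")
  }
  if (!nrow(hits)) return(0)
  switches <- 0L
  for (b in unique(hits$bin)) {
    hb <- hits$hand[hits$bin == b][order(hits$t_outcome[hits$bin == b])]
    if (length(hb) > 1) switches <- switches + sum(hb[-1] != hb[-length(hb)])
  }
  100 * switches / n_targets
}

#' Miss bias
#'
#' Mean signed x position (cm, workspace midline = 0) at which missed
#' targets left the workspace: where in the workspace the misses
#' concentrate.
#'
#' @param trial A `trial_recording`.
#' @return cm; `NA` when there are no misses.
#' @export
miss_bias <- function(trial) {
  obj <- trial$objects
  miss <- obj[obj$role == "target" & obj$outcome == "missed", ]
  if (!nrow(miss)) {
    warning("no missed targets; miss bias undefined")
    return(NA_real_)
  }
  mean(miss$x_outcome)
}

#' Hand transition point
#'
#' The workspace x at which the preference for one hand over the other
#' switches, estimated from the per-bin fraction of target hits made with
#' the right hand: the fractions are made monotone non-decreasing in x
#' (isotonic fit) and the crossing of 0.5 is located by linear
#' interpolation between bin centres. Deterministic even on sparse trials.
#'
#' @param trial A `trial_recording`.
#' @return cm; `NA` for one-handed trials.
#' @export
hand_transition <- function(trial) {
  hits <- target_hits(trial)
  if (!nrow(hits) || length(unique(hits$hand)) < 2) {
    warning("hand transition undefined: hits from fewer than two hands")
    return(NA_real_)
  }
  n_bins <- trial$metadata$n_bins
  if (is.null(n_bins) || !is.finite(n_bins)) n_bins <- max(trial$objects$bin)
  w <- trial$metadata$workspace_width
  centres <- -w / 2 + w / n_bins * (seq_len(n_bins) - 0.5)
  frac <- tapply(hits$hand == "right", factor(hits$bin, levels = 1:n_bins),
                 mean)
  keep <- !is.na(frac)
  xs <- centres[keep]
  fr <- as.numeric(frac[keep])
  if (length(xs) < 2) return(NA_real_)
  fr <- isoreg(xs, fr)$yf
  if (all(fr >= 0.5)) return(xs[1])
  if (all(fr < 0.5)) return(xs[length(xs)])
  i <- max(which(fr < 0.5))
  if (i == length(xs)) return(xs[i])
  x0 <- xs[i]; x1 <- xs[i + 1]
  f0 <- fr[i]; f1 <- fr[i + 1]
  if (f1 == f0) return((x0 + x1) / 2)
  x0 + (0.5 - f0) / (f1 - f0) * (x1 - x0)
}

#' Median error position
#'
#' How far through the task (percent of the target sequence, by creation
#' order, not time) the participant is when half of their misses have
#' occurred: the creation-order index of the miss at which cumulative
#' misses first reach half the total, over the number of targets, x100.
#'
#' @param trial A `trial_recording`.
#' @return Percentage in `(0, 100]`; `NA` with zero misses.
#' @export
median_error <- function(trial) {
  obj <- trial$objects
  tgt <- obj[obj$role == "target", ]
  tgt <- tgt[order(tgt$t_created), ]
  miss_idx <- which(tgt$outcome == "missed")
  if (!length(miss_idx)) {
    warning("no missed targets; median error undefined")
    return(NA_real_)
  }
  half <- ceiling(length(miss_idx) / 2)
  100 * miss_idx[half] / nrow(tgt)
}

#' Distractor proportion (OHA)
#'
#' Distractors hit as a percentage of all objects hit (targets plus
#' distractors).
#'
#' @param trial An OHA `trial_recording`.
#' @return Percentage in `[0, 100]`; `NA` when nothing was hit.
#' @export
distractor_proportion <- function(trial) {
  obj <- trial$objects
  hit <- obj[obj$outcome == "hit", ]
  if (!nrow(hit)) {
    warning("nothing hit; distractor proportion undefined")
    return(NA_real_)
  }
  100 * sum(hit$role == "distractor") / nrow(hit)
}

#' Object processing rate (OHA)
#'
#' Correctly processed objects per second at the point where 80% of the
#' task's objects have been created: targets hit by that time plus
#' distractors that had fully exited the workspace unhit, divided by the
#' elapsed time.
#'
#' @param trial An OHA `trial_recording`.
#' @return Rate in Hz.
#' @export
object_processing_rate <- function(trial) {
  obj <- trial$objects
  obj <- obj[order(obj$t_created), ]
  n <- nrow(obj)
  k80 <- ceiling(0.8 * n)
  t80 <- obj$t_created[k80]
  targets_hit <- sum(obj$role == "target" & obj$outcome == "hit" &
                       obj$t_outcome <= t80)
  distractors_cleared <- sum(obj$role == "distractor" &
                               obj$outcome == "avoided" &
                               obj$t_outcome <= t80)
  (targets_hit + distractors_cleared) / t80
}

#' Hand kinematic summaries
#'
#' Maximum and median speed plus maximum and mean absolute acceleration for
#' each hand. Speeds come from the sampled velocity series; accelerations
#' from central differences of the velocities.
#'
#' @param trial A `trial_recording` with samples.
#' @return Data frame with one row per hand.
#' @export
hand_kinematic_summaries <- function(trial) {
  smp <- require_samples(trial)
  if (nrow(smp) < 3) stop("need at least 3 samples")
  out <- lapply(c("left", "right"), function(hand) {
    cols <- hand_cols(hand)
    vx <- smp[[cols[3]]]; vy <- smp[[cols[4]]]
    sp <- sqrt(vx^2 + vy^2)
    n <- length(vx)
    dt2 <- smp$t[3:n] - smp$t[1:(n - 2)]
    ax <- (vx[3:n] - vx[1:(n - 2)]) / dt2
    ay <- (vy[3:n] - vy[1:(n - 2)]) / dt2
    acc <- sqrt(ax^2 + ay^2)
    data.frame(hand = hand, max_speed = max(sp), median_speed = median(sp),
               max_acceleration = max(acc), mean_acceleration = mean(acc),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Extract the full per-trial parameter battery
#'
#' Computes every standard parameter for one trial: kinematic means and
#' movement areas with their bilateral biases, hit-hand measures, miss
#' timing and location, the OHA-only distractor proportion and object
#' processing rate, targets hit, the steady-state rate with its
#' overwhelmed-phase onset, and per-bin accuracies by phase. Parameters
#' whose preconditions fail (no misses, one-handed trials, ...) are `NA`.
#' The task score is a cohort-level quantity and is filled in by
#' [add_task_scores()] once a normative model exists.
#'
#' @param trial A `trial_recording`.
#' @param cfg A [steady_state_config()].
#' @return One-row data frame.
#' @examples
#' tr <- simulate_trial(oh_task(), participant_spec("p1", 25, rng_seed = 8))
#' extract_parameters(tr)[, c("targets_hit", "steady_state_rate")]
#' @export
extract_parameters <- function(trial, cfg = steady_state_config()) {
  stopifnot(inherits(trial, "trial_recording"))
  meta <- trial$metadata
  obj <- trial$objects
  has_samples <- !is.null(trial$samples)
  is_oha <- any(obj$role == "distractor")

  suppress_na <- function(expr) {
    tryCatch(suppressWarnings(expr), error = function(e) NA_real_)
  }

  msl <- if (has_samples) mean_hand_speed(trial, "left") else NA_real_
  msr <- if (has_samples) mean_hand_speed(trial, "right") else NA_real_
  mal <- if (has_samples) movement_area(trial, "left") else NA_real_
  mar <- if (has_samples) movement_area(trial, "right") else NA_real_

  ss <- steady_state_rate(trial, cfg)
  acc <- per_bin_accuracy(trial, ss$onset_time)

  row <- data.frame(
    participant_id = if (!is.null(meta$participant_id))
      meta$participant_id else NA_character_,
    task = if (!is.null(meta$task_name)) meta$task_name else NA_character_,
    mean_hand_speed_left = msl,
    mean_hand_speed_right = msr,
    mean_hand_speed_bias = if (has_samples)
      suppress_na(bilateral_bias(msl, msr)) else NA_real_,
    movement_area_left = mal,
    movement_area_right = mar,
    movement_area_bias = if (has_samples)
      suppress_na(bilateral_bias(mal, mar)) else NA_real_,
    hand_bias_of_hits = suppress_na(hand_bias_of_hits(trial)),
    hand_selection_overlap = hand_selection_overlap(trial),
    miss_bias = suppress_na(miss_bias(trial)),
    hand_transition = suppress_na(hand_transition(trial)),
    median_error = suppress_na(median_error(trial)),
    distractor_proportion = if (is_oha)
      suppress_na(distractor_proportion(trial)) else NA_real_,
    object_processing_rate = if (is_oha)
      object_processing_rate(trial) else NA_real_,
    steady_state_rate = ss$rate,
    overwhelmed_onset_time = ss$onset_time,
    steady_state_flag = ss$degenerate,
    targets_hit = nrow(target_hits(trial)),
    task_score = NA_real_,
    stringsAsFactors = FALSE
  )
  n_bins <- ncol(acc)
  for (b in seq_len(n_bins)) {
    row[[sprintf("bin_acc_early_%02d", b)]] <- acc["early", b]
    row[[sprintf("bin_acc_overwhelmed_%02d", b)]] <- acc["overwhelmed", b]
  }
  row
}

#' Extract parameters for a list of trials
#'
#' @param trials List of `trial_recording`s (e.g. from
#'   [simulate_cohort()]), or a directory written by the pipeline.
#' @param manifest Optional manifest; when given, its `trial` column is
#'   carried onto the rows.
#' @inheritParams extract_parameters
#' @return Data frame with one row per trial.
#' @export
extract_all_parameters <- function(trials, manifest = NULL,
                                   cfg = steady_state_config()) {
  rows <- lapply(trials, extract_parameters, cfg = cfg)
  out <- do.call(rbind, rows)
  if (!is.null(manifest) && nrow(out) == nrow(manifest) &&
      "trial" %in% names(manifest)) {
    out$trial <- manifest$trial
  }
  rownames(out) <- NULL
  out
}
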