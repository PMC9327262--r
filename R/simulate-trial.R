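# Trial simulator: a capacity-limited agent playing an Object-Hit style task.
#
# The agent is deliberately minimal. A single serial processing bottleneck
# commits one object decision at a time, each commitment occupying the
# processor for a Gamma-distributed time with mean 1/capacity_lambda
# (shape 3: moderately regular, as human inter-hit intervals are); paddles
# travel at max_hand_speed and strike objects on a fixed interception line.
# When the creation rate is below capacity the agent engages every target as
# it appears (early phase, near-perfect accuracy); once creation outpaces
# capacity the engagement rate saturates at capacity_lambda and, because the
# agent greedily picks the nearest feasible object, unengaged lateral targets
# slip through (overwhelmed phase with central-bin preference).

# y of the last-chance interception line, cm from the near workspace edge:
# an object not struck by the time it falls past this line is gone
HIT_LINE_Y <- 12
# objects become strikeable once they fall below this y; contact happens
# wherever in the band [HIT_LINE_Y, STRIKE_ZONE_TOP_Y] the hand meets them
STRIKE_ZONE_TOP_Y <- 40
# cm scale of the soft hand-preference boundary around hand_transition_x
HAND_OVERLAP_SCALE <- 4
# Gamma shape of the serial processing time (mean stays 1/capacity_lambda)
SERVICE_SHAPE <- 3

#' Simulate one Object-Hit / Object-Hit-and-Avoid trial
#'
#' Runs the capacity-limited agent through a full trial and returns the
#' recording: 200 Hz bimanual hand kinematics plus an object event log with
#' one outcome per object. Object creation times follow the task's linear
#' rate ramp deterministically; bins are assigned by fresh random
#' permutations of all bins for every round of drops; object speeds ramp
#' linearly over the trial. In OHA, each distractor is misclassified as a
#' target with probability `distractor_error_prob` and only misclassified
#' distractors are ever struck.
#'
#' The simulation is fully reproducible: the participant's `rng_seed` drives
#' all randomness, and the caller's RNG state is left untouched.
#'
#' @param task A [task_config()].
#' @param participant A [participant_spec()].
#' @param include_samples If `FALSE`, skip synthesis of the kinematic sample
#'   table (the event log alone supports the event-based parameters); the
#'   returned recording then has `samples = NULL`.
#'
#' @return A `trial_recording`: a list with `metadata` (task name,
#'   participant id, sampling rate, workspace dimensions, flags), `samples`
#'   (data frame `t, left_x, left_y, left_vx, left_vy, right_x, right_y,
#'   right_vx, right_vy`; cm and cm/s) and `objects` (data frame
#'   `object_id, bin, shape, role, t_created, outcome, t_outcome, x_outcome,
#'   hand`).
#' @examples
#' tr <- simulate_trial(oh_task(), participant_spec("p1", 40, rng_seed = 11))
#' table(tr$objects$outcome)
#' @export
simulate_trial <- function(task, participant, include_samples = TRUE) {
  validate_task_config(task)
  validate_participant_spec(participant)

  old_seed <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old_seed, envir = globalenv())
    }
  })
  set.seed(participant$rng_seed)

  sched <- object_schedule(task)
  eng <- run_agent(task, participant, sched)
  objects <- assemble_objects(sched, eng)

  trial_end <- max(sched$t_exit)
  samples <- NULL
  if (include_samples) {
    contact_y <- task$workspace_depth -
      sched$speed * (eng$hit_time - sched$t_created)
    samples <- synthesize_kinematics(task, participant, objects, contact_y,
                                     trial_end)
    trial_end <- max(samples$t)
  }

  rec <- list(
    metadata = list(
      task_name = task$task_name,
      participant_id = participant$participant_id,
      sampling_rate = task$sampling_rate,
      workspace_width = task$workspace_width,
      workspace_depth = task$workspace_depth,
      paddle_diameter = task$paddle_diameter,
      object_diameter = task$object_diameter,
      n_targets = task$n_targets,
      n_distractors = task$n_distractors,
      n_bins = task$n_bins,
      trial_end = trial_end,
      all_miss = !any(objects$outcome == "hit")
    ),
    samples = samples,
    objects = objects
  )
  class(rec) <- "trial_recording"
  rec
}

# Creation schedule: times, bins (per-round permutations), speeds, roles,
# shapes, crossing and exit times. Called with the trial RNG active.
object_schedule <- function(task) {
  n <- task$n_targets + task$n_distractors
  t_created <- creation_times(task)
  span <- creation_span(task)

  rounds <- n / task$n_bins
  bins <- unlist(lapply(seq_len(rounds), function(r) sample.int(task$n_bins)))

  speed <- task$object_speed_start +
    (task$object_speed_end - task$object_speed_start) *
      pmin(t_created / span, 1)

  role <- rep("target", n)
  shape <- rep("circle", n)
  if (task$n_distractors > 0) {
    idx <- sample.int(n, task$n_distractors)
    role[idx] <- "distractor"
    target_shapes <- c("circle", "square")
    distractor_shapes <- c("triangle", "diamond", "star", "cross",
                           "pentagon", "hexagon")
    shape[role == "target"] <- sample(target_shapes, task$n_targets,
                                      replace = TRUE)
    shape[idx] <- sample(distractor_shapes, task$n_distractors,
                         replace = TRUE)
  }

  depth <- task$workspace_depth
  list(
    n = n,
    t_created = t_created,
    bin = bins,
    x = bin_centres(task)[bins],
    speed = speed,
    role = role,
    shape = shape,
    t_enter = t_created + pmax(depth - STRIKE_ZONE_TOP_Y, 0) / speed,
    t_cross = t_created + (depth - HIT_LINE_Y) / speed,
    t_exit = t_created + depth / speed
  )
}

# Event-driven agent loop. Returns hit times and hands for engaged objects.
# Maintains a small active set of engageable objects so each decision costs
# O(objects in flight), not O(objects in trial).
run_agent <- function(task, participant, sched) {
  n <- sched$n
  lambda <- participant$capacity_lambda
  vmax <- participant$max_hand_speed
  rd <- participant$reaction_delay
  htx <- participant$hand_transition_x
  lapse_p <- participant$lapse_prob

  # distractor misclassification decided up front, one draw per distractor
  candidate <- sched$role == "target"
  if (any(!candidate)) {
    mis <- runif(sum(!candidate)) < participant$distractor_error_prob
    candidate[!candidate][mis] <- TRUE
  }

  hit <- logical(n)
  hit_hand <- integer(n)        # 1 = left, 2 = right

  hit_time <- rep(NA_real_, n)

  cand <- which(candidate)      # already in creation order
  m <- length(cand)
  tc <- sched$t_created[cand]
  tn <- sched$t_enter[cand]
  tx <- sched$t_cross[cand]
  cx <- sched$x[cand]

  home <- c(-task$workspace_width / 8, task$workspace_width / 8)
  xh <- home
  t_hand <- c(0, 0)
  t <- 0
  eps <- 1e-9
  act <- integer(0)             # indices into cand arrays, currently in flight
  nxt <- 1L                     # next candidate (by creation) not yet active

  repeat {
    while (nxt <= m && tc[nxt] <= t) {
      act <- c(act, nxt)
      nxt <- nxt + 1L
    }
    if (length(act)) act <- act[tx[act] >= t]
    if (!length(act) && nxt > m) break

    pick <- 0L
    if (length(act)) {
      x <- cx[act]
      base_l <- if (t_hand[1] > t) t_hand[1] else t
      base_r <- if (t_hand[2] > t) t_hand[2] else t
      d_l <- abs(x - xh[1])
      d_r <- abs(x - xh[2])
      feas_l <- base_l + rd + d_l / vmax <= tx[act]
      feas_r <- base_r + rd + d_r / vmax <= tx[act]
      d_l[!feas_l] <- Inf
      d_r[!feas_r] <- Inf
      trav <- pmin(d_l, d_r)
      if (any(trav < Inf)) {
        best <- which(trav == min(trav))
        if (length(best) > 1) best <- best[which.min(tx[act][best])]
        pick <- act[best]
        # soft lateralised hand choice, constrained to feasibility
        p_right <- stats::plogis((cx[pick] - htx) / HAND_OVERLAP_SCALE)
        h <- if (runif(1) < p_right) 2L else 1L
        if (h == 1L && !feas_l[best]) h <- 2L
        if (h == 2L && !feas_r[best]) h <- 1L
      }
    }
    if (pick == 0L) {
      # nothing engageable now: advance to the next creation or past the
      # next crossing, whichever comes first
      t_next <- Inf
      if (nxt <= m) t_next <- tc[nxt]
      if (length(act)) t_next <- min(t_next, min(tx[act]) + eps)
      if (!is.finite(t_next) || t_next <= t) break
      t <- t_next
      next
    }

    service <- stats::rgamma(1, shape = SERVICE_SHAPE,
                             rate = SERVICE_SHAPE * lambda)
    lapse <- runif(1) < lapse_p
    act <- act[act != pick]
    if (!lapse) {
      # contact when the hand arrives, but no sooner than the object
      # entering the strike zone
      base <- if (t_hand[h] > t) t_hand[h] else t
      arrival <- base + rd + abs(cx[pick] - xh[h]) / vmax
      contact <- max(arrival, tn[pick])
      i <- cand[pick]
      hit[i] <- TRUE
      hit_hand[i] <- h
      hit_time[i] <- contact
      t_hand[h] <- contact
      xh[h] <- cx[pick]
    }
    t <- t + service
  }

  list(hit = hit, hand = hit_hand, hit_time = hit_time)
}

assemble_objects <- function(sched, eng) {
  outcome <- ifelse(eng$hit, "hit",
                    ifelse(sched$role == "target", "missed", "avoided"))
  t_outcome <- ifelse(eng$hit, eng$hit_time, sched$t_exit)
  hand <- c("none", "left", "right")[eng$hand + 1L]
  hand[!eng$hit] <- "none"
  data.frame(
    object_id = seq_len(sched$n),
    bin = sched$bin,
    shape = sched$shape,
    role = sched$role,
    t_created = sched$t_created,
    outcome = outcome,
    t_outcome = t_outcome,
    x_outcome = sched$x,
    hand = hand,
    stringsAsFactors = FALSE
  )
}

# Piecewise dwell-then-dash hand paths through the contact points, sampled
# on the regular 1/sampling_rate grid; velocities are the analytic segment
# slopes plus the derivative of a small smooth sway, so positions and
# velocities are mutually consistent and the paddle really is at each
# object when it is struck.
synthesize_kinematics <- function(task, participant, objects, contact_y,
                                  trial_end) {
  fs <- task$sampling_rate
  n_samp <- ceiling(trial_end * fs) + 1L
  tt <- (seq_len(n_samp) - 1L) / fs
  vmax <- participant$max_hand_speed
  home_x <- c(-task$workspace_width / 8, task$workspace_width / 8)
  sway_phase <- runif(2, 0, 2 * pi)
  sway_amp <- 1.0    # cm; below half the paddle radius, so contact holds
  sway_f <- 0.4      # Hz

  out <- list(t = tt)
  for (h in 1:2) {
    hand_lab <- c("left", "right")[h]
    sel <- objects$outcome == "hit" & objects$hand == hand_lab
    ord <- order(objects$t_outcome[sel])
    wt <- c(0, objects$t_outcome[sel][ord])
    wx <- c(home_x[h], objects$x_outcome[sel][ord])
    wy <- c(HIT_LINE_Y, contact_y[sel][ord])
    # expand each leg into dwell + dash breakpoints
    bt <- wt[1]; bx <- wx[1]; by <- wy[1]
    if (length(wt) > 1) {
      for (i in 2:length(wt)) {
        d <- sqrt((wx[i] - wx[i - 1])^2 + (wy[i] - wy[i - 1])^2)
        depart <- max(wt[i - 1], wt[i] - d / vmax)
        bt <- c(bt, depart, wt[i])
        bx <- c(bx, wx[i - 1], wx[i])
        by <- c(by, wy[i - 1], wy[i])
      }
    }
    bt <- c(bt, trial_end + 1 / fs)
    bx <- c(bx, bx[length(bx)])
    by <- c(by, by[length(by)])
    keep <- c(TRUE, diff(bt) > 1e-12)
    bt <- bt[keep]; bx <- bx[keep]; by <- by[keep]
    px <- approx(bt, bx, xout = tt, rule = 2)$y
    py0 <- approx(bt, by, xout = tt, rule = 2)$y
    seg <- pmin(pmax(findInterval(tt, bt), 1L), length(bt) - 1L)
    vx <- (diff(bx) / diff(bt))[seg]
    vy0 <- (diff(by) / diff(bt))[seg]
    sway <- sway_amp * sin(2 * pi * sway_f * tt + sway_phase[h])
    dsway <- sway_amp * 2 * pi * sway_f *
      cos(2 * pi * sway_f * tt + sway_phase[h])
    out[[paste0(hand_lab, "_x")]] <- px
    out[[paste0(hand_lab, "_y")]] <- py0 + sway
    out[[paste0(hand_lab, "_vx")]] <- vx
    out[[paste0(hand_lab, "_vy")]] <- vy0 + dsway
    out
  }
  as.data.frame(out)
}

#' @export
print.trial_recording <- function(x, ...) {
  m <- x$metadata
  tab <- table(x$objects$outcome)
  cat(sprintf("<trial_recording> %s, participant %s\n", m$task_name,
              m$participant_id))
  cat(sprintf("  %d objects (%s), trial end %.1f s\n", nrow(x$objects),
              paste(sprintf("%s %d", names(tab), as.integer(tab)),
                    collapse = ", "),
              m$trial_end))
  if (is.null(x$samples)) {
    cat("  kinematic samples: not synthesised\n")
  } else {
    cat(sprintf("  kinematic samples: %d at %g Hz\n", nrow(x$samples),
                m$sampling_rate))
  }
  invisible(x)
}
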