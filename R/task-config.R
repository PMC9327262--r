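#' Task configuration for Object-Hit family tasks
#'
#' Describes the geometry and schedule of a bimanual object-interception
#' trial: how many targets and distractors are released, from how many bins,
#' the workspace dimensions, paddle and object sizes, and the creation-rate
#' and object-speed ramps that make the trial progressively harder.
#'
#' Objects are dropped from `n_bins` invisible bins spread across the
#' workspace width, `objects_per_bin` objects per bin, each round of
#' `n_bins` drops using a fresh random permutation of the bins. The creation
#' rate ramps linearly from `creation_rate_start` to `creation_rate_end`
#' over the creation span, and object speeds ramp linearly from
#' `object_speed_start` to `object_speed_end`.
#'
#' @param task_name `"OH"` (300 targets, no distractors) or `"OHA"`
#'   (200 targets plus 100 distractors).
#' @param n_targets,n_distractors Object counts by role.
#' @param n_bins Number of drop bins across the workspace width.
#' @param objects_per_bin Objects released from each bin over the trial.
#' @param workspace_width,workspace_depth Workspace extent in cm. The x
#'   origin is the workspace midline (positive right); y is distance from
#'   the near (participant) edge, and objects travel in -y.
#' @param paddle_diameter,object_diameter Effector and object sizes, cm.
#' @param creation_rate_start,creation_rate_end Object creation rate ramp, Hz.
#' @param object_speed_start,object_speed_end Object speed ramp, cm/s.
#' @param sampling_rate Kinematic sampling frequency, Hz.
#'
#' @return A `task_config` object (named list).
#' @examples
#' oh_task()
#' oha_task()
#' @export
task_config <- function(task_name = c("OH", "OHA"),
                        n_targets = 300,
                        n_distractors = 0,
                        n_bins = 10,
                        objects_per_bin = 30,
                        workspace_width = 80,
                        workspace_depth = 65,
                        paddle_diameter = 5,
                        object_diameter = 2,
                        creation_rate_start = 0.5,
                        creation_rate_end = 3.5,
                        object_speed_start = 10,
                        object_speed_end = 50,
                        sampling_rate = 200) {
  task_name <- match.arg(task_name)
  cfg <- list(
    task_name = task_name,
    n_targets = as.integer(n_targets),
    n_distractors = as.integer(n_distractors),
    n_bins = as.integer(n_bins),
    objects_per_bin = as.integer(objects_per_bin),
    workspace_width = workspace_width,
    workspace_depth = workspace_depth,
    paddle_diameter = paddle_diameter,
    object_diameter = object_diameter,
    creation_rate_start = creation_rate_start,
    creation_rate_end = creation_rate_end,
    object_speed_start = object_speed_start,
    object_speed_end = object_speed_end,
    sampling_rate = sampling_rate
  )
  class(cfg) <- "task_config"
  validate_task_config(cfg)
  cfg
}

#' @rdname task_config
#' @param ... Overrides passed on to [task_config()].
#' @export
oh_task <- function(...) {
  task_config(task_name = "OH", n_targets = 300, n_distractors = 0, ...)
}

#' @rdname task_config
#' @export
oha_task <- function(...) {
  task_config(task_name = "OHA", n_targets = 200, n_distractors = 100, ...)
}

validate_task_config <- function(cfg) {
  stopifnot(inherits(cfg, "task_config"))
  bad <- character(0)
  pos <- c("n_bins", "objects_per_bin", "workspace_width", "workspace_depth",
           "paddle_diameter", "object_diameter", "creation_rate_start",
           "object_speed_start", "object_speed_end", "sampling_rate")
  for (f in pos) {
    if (!is.numeric(cfg[[f]]) || length(cfg[[f]]) != 1 || !is.finite(cfg[[f]]) ||
        cfg[[f]] <= 0) {
      bad <- c(bad, sprintf("'%s' must be a single positive number", f))
    }
  }
  if (cfg$n_targets < 1) bad <- c(bad, "'n_targets' must be >= 1")
  if (cfg$n_distractors < 0) bad <- c(bad, "'n_distractors' must be >= 0")
  if (cfg$n_targets + cfg$n_distractors != cfg$n_bins * cfg$objects_per_bin) {
    bad <- c(bad, sprintf(
      "n_targets + n_distractors (%d) must equal n_bins * objects_per_bin (%d)",
      cfg$n_targets + cfg$n_distractors, cfg$n_bins * cfg$objects_per_bin))
  }
  if (!is.finite(cfg$creation_rate_end) ||
      cfg$creation_rate_end < cfg$creation_rate_start) {
    bad <- c(bad, "'creation_rate_end' must be >= 'creation_rate_start'")
  }
  if (length(bad)) {
    stop("invalid task configuration:\n  ", paste(bad, collapse = "\n  "),
         call. = FALSE)
  }
  invisible(cfg)
}

#' @export
print.task_config <- function(x, ...) {
  cat(sprintf("<task_config> %s: %d targets + %d distractors, %d bins x %d\n",
              x$task_name, x$n_targets, x$n_distractors, x$n_bins,
              x$objects_per_bin))
  cat(sprintf("  workspace %g x %g cm; creation %g -> %g Hz; speed %g -> %g cm/s\n",
              x$workspace_width, x$workspace_depth,
              x$creation_rate_start, x$creation_rate_end,
              x$object_speed_start, x$object_speed_end))
  invisible(x)
}

# Bin centres across the workspace width (x = 0 at the midline, bin 1 leftmost)
bin_centres <- function(cfg) {
  w <- cfg$workspace_width
  -w / 2 + w / cfg$n_bins * (seq_len(cfg$n_bins) - 0.5)
}

# Duration of the creation schedule: total count / mean rate of the linear ramp
creation_span <- function(cfg) {
  n <- cfg$n_targets + cfg$n_distractors
  2 * n / (cfg$creation_rate_start + cfg$creation_rate_end)
}

# Deterministic creation times following the linear rate ramp: the k-th object
# is created when the integrated rate reaches k - 1 (first object at t = 0).
creation_times <- function(cfg) {
  n <- cfg$n_targets + cfg$n_distractors
  r0 <- cfg$creation_rate_start
  r1 <- cfg$creation_rate_end
  span <- creation_span(cfg)
  k <- seq_len(n) - 1
  if (r1 == r0) return(k / r0)
  a <- (r1 - r0) / span
  # solve (a/2) t^2 + r0 t = k
  (-r0 + sqrt(r0^2 + 2 * a * k)) / a
}

#' Ground-truth specification of one simulated participant
#'
#' Holds the latent capabilities that drive the capacity-limited agent:
#' `capacity_lambda` is the maximum sustainable rate (Hz) at which the
#' participant can commit correct object-processing decisions (the
#' generative counterpart of the steady-state hit rate), `max_hand_speed`
#' bounds paddle travel, `reaction_delay` is the per-engagement latency,
#' `distractor_error_prob` the probability of misclassifying a distractor
#' as a target, `hand_transition_x` the workspace x at which hand
#' preference switches, and `lapse_prob` the chance an engaged target is
#' nevertheless missed.
#'
#' @param participant_id Identifier string.
#' @param age Age in years, 18-93.
#' @param sex `"male"` or `"female"`.
#' @param handedness `"left"`, `"right"` or `"mixed"`.
#' @param capacity_lambda Max sustainable correct-processing rate, Hz (> 0).
#' @param max_hand_speed Paddle travel speed bound, cm/s.
#' @param reaction_delay Engagement latency, s.
#' @param distractor_error_prob Probability in `[0, 1]`.
#' @param hand_transition_x Hand-preference switch point, cm.
#' @param lapse_prob Probability in `[0, 1]`.
#' @param rng_seed Integer seed making the participant's trials reproducible.
#'
#' @return A `participant_spec` object.
#' @examples
#' participant_spec("p001", age = 35, sex = "female", rng_seed = 1)
#' @export
participant_spec <- function(participant_id,
                             age,
                             sex = c("female", "male"),
                             handedness = c("right", "left", "mixed"),
                             capacity_lambda = 2.2,
                             max_hand_speed = 80,
                             reaction_delay = 0.25,
                             distractor_error_prob = 0.08,
                             hand_transition_x = 0,
                             lapse_prob = 0.02,
                             rng_seed = 1L) {
  sex <- match.arg(sex)
  handedness <- match.arg(handedness)
  p <- list(
    participant_id = as.character(participant_id),
    age = age,
    sex = sex,
    handedness = handedness,
    capacity_lambda = capacity_lambda,
    max_hand_speed = max_hand_speed,
    reaction_delay = reaction_delay,
    distractor_error_prob = distractor_error_prob,
    hand_transition_x = hand_transition_x,
    lapse_prob = lapse_prob,
    rng_seed = as.integer(rng_seed)
  )
  class(p) <- "participant_spec"
  validate_participant_spec(p)
  p
}

validate_participant_spec <- function(p) {
  bad <- character(0)
  if (!is.numeric(p$age) || p$age < 18 || p$age > 93) {
    bad <- c(bad, "'age' must lie in [18, 93]")
  }
  if (!is.numeric(p$capacity_lambda) || p$capacity_lambda <= 0) {
    bad <- c(bad, "'capacity_lambda' must be > 0")
  }
  if (p$max_hand_speed <= 0) bad <- c(bad, "'max_hand_speed' must be > 0")
  if (p$reaction_delay < 0) bad <- c(bad, "'reaction_delay' must be >= 0")
  for (f in c("distractor_error_prob", "lapse_prob")) {
    if (p[[f]] < 0 || p[[f]] > 1) {
      bad <- c(bad, sprintf("'%s' must lie in [0, 1]", f))
    }
  }
  if (length(bad)) {
    stop("invalid participant specification:\n  ",
         paste(bad, collapse = "\n  "), call. = FALSE)
  }
  invisible(p)
}

#' @export
print.participant_spec <- function(x, ...) {
  cat(sprintf(
    "<participant_spec> %s: age %g, %s, %s-handed; capacity %.2f Hz\n",
    x$participant_id, x$age, x$sex, x$handedness, x$capacity_lambda))
  invisible(x)
}

#' Cohort specification with injectable age and sex effects
#'
#' Defines how a synthetic cohort is drawn. Each participant's latent
#' parameters are generated as linear-in-age means (`intercepts` at age 0
#' plus `age_slopes` times age, plus a `sex_offsets` shift for males) with
#' Gaussian between-subject noise (`between_subject_sd`), then clipped to
#' their valid domains. Ages are drawn from per-decade weights emulating a
#' typical healthy-control recruitment profile (heaviest in the 18-29
#' stratum), and sex from `sex_ratio`.
#'
#' @param n_participants Cohort size (>= 1).
#' @param age_range Two ages bounding the cohort, default `c(18, 93)`.
#' @param age_weights Optional per-decade weights, one per decade bracket
#'   `18-29, 30-39, ..., 80-93`; `NULL` means the built-in recruitment
#'   profile.
#' @param sex_ratio Proportion of female participants.
#' @param intercepts,age_slopes,sex_offsets,between_subject_sd Named numeric
#'   vectors over the latent participant parameters
#'   (`capacity_lambda`, `max_hand_speed`, `reaction_delay`,
#'   `distractor_error_prob`, `hand_transition_x`, `lapse_prob`); units per
#'   year for `age_slopes`. Omitted names default to 0 (and to the
#'   `participant_spec()` defaults for intercepts).
#' @param trials_per_participant Number of trials recorded per participant.
#' @param global_seed Integer seed; identical seeds give identical cohorts.
#'
#' @return A `cohort_spec` object.
#' @examples
#' cohort_spec(20, age_slopes = c(capacity_lambda = -0.0099), global_seed = 7)
#' @export
cohort_spec <- function(n_participants,
                        age_range = c(18, 93),
                        age_weights = NULL,
                        sex_ratio = 0.55,
                        intercepts = NULL,
                        age_slopes = NULL,
                        sex_offsets = NULL,
                        between_subject_sd = NULL,
                        trials_per_participant = 1L,
                        global_seed = 1L) {
  if (n_participants < 1) stop("cohort must contain at least one participant")
  if (age_range[1] < 18 || age_range[2] > 93 || age_range[1] > age_range[2]) {
    stop("'age_range' must be an ordered pair within [18, 93]")
  }
  base_int <- c(capacity_lambda = 2.6, max_hand_speed = 80,
                reaction_delay = 0.25, distractor_error_prob = 0.05,
                hand_transition_x = 0, lapse_prob = 0.02)
  base_sd <- c(capacity_lambda = 0.3, max_hand_speed = 8,
               reaction_delay = 0.04, distractor_error_prob = 0.03,
               hand_transition_x = 2, lapse_prob = 0.01)
  zero <- setNames(numeric(length(base_int)), names(base_int))
  merge_named <- function(base, user) {
    if (is.null(user)) return(base)
    if (length(user) == 1 && is.null(names(user))) {
      base[] <- user   # unnamed scalar applies to every parameter
      return(base)
    }
    unknown <- setdiff(names(user), names(base))
    if (length(unknown)) {
      stop("unknown participant parameter(s): ", paste(unknown, collapse = ", "))
    }
    base[names(user)] <- user
    base
  }
  spec <- list(
    n_participants = as.integer(n_participants),
    age_range = age_range,
    age_weights = age_weights,
    sex_ratio = sex_ratio,
    intercepts = merge_named(base_int, intercepts),
    age_slopes = merge_named(zero, age_slopes),
    sex_offsets = merge_named(zero, sex_offsets),
    between_subject_sd = merge_named(base_sd, between_subject_sd),
    trials_per_participant = as.integer(trials_per_participant),
    global_seed = as.integer(global_seed)
  )
  class(spec) <- "cohort_spec"
  spec
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat(sprintf("<cohort_spec> n = %d, ages %g-%g, seed %d\n",
              x$n_participants, x$age_range[1], x$age_range[2], x$global_seed))
  nz <- x$age_slopes[x$age_slopes != 0]
  if (length(nz)) {
    cat("  age slopes:",
        paste(sprintf("%s %+g/yr", names(nz), nz), collapse = ", "), "\n")
  }
  invisible(x)
}
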