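# Default per-decade recruitment weights for synthetic cohorts, shaped like
# a typical healthy-control pool for these tasks: heaviest in the youngest
# stratum, a secondary mode in the 60s, thin above 80.
DECADE_BREAKS <- c(18, 30, 40, 50, 60, 70, 80, 93)
DECADE_WEIGHTS <- c(203, 65, 72, 79, 101, 71, 27)

#' Simulate a whole cohort of trials with known ground truth
#'
#' Draws `n_participants` participants whose latent capabilities follow the
#' linear age/sex structure encoded in the [cohort_spec()] (mean =
#' intercept + age slope x age + sex offset, plus Gaussian between-subject
#' noise, clipped to valid domains), then simulates
#' `trials_per_participant` trials per participant. The entire draw is a
#' deterministic function of `global_seed`.
#'
#' @param cohort A [cohort_spec()].
#' @param task A [task_config()].
#' @param include_samples Passed to [simulate_trial()]; event-log-only
#'   cohorts are much faster to generate and support every event-based
#'   parameter.
#' @return A list with `manifest` (one row per trial: `participant_id`,
#'   `trial`, `age`, `sex`, `handedness`, `task`), `trials` (list of
#'   `trial_recording`s in manifest order) and `ground_truth` (one row per
#'   participant with the latent parameter values actually drawn).
#' @examples
#' co <- simulate_cohort(cohort_spec(3, global_seed = 1), oh_task(),
#'                       include_samples = FALSE)
#' co$manifest
#' @export
simulate_cohort <- function(cohort, task, include_samples = TRUE) {
  stopifnot(inherits(cohort, "cohort_spec"))
  validate_task_config(task)

  old_seed <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old_seed, envir = globalenv())
    }
  })
  set.seed(cohort$global_seed)

  drawn <- draw_participants_impl(cohort)
  ground_truth <- drawn$ground_truth
  gt <- drawn$gt
  ids <- ground_truth$participant_id
  ages <- ground_truth$age
  sex <- ground_truth$sex
  handedness <- ground_truth$handedness
  n <- cohort$n_participants
  trial_seeds <- matrix(
    sample.int(.Machine$integer.max,
               n * cohort$trials_per_participant),
    nrow = n)

  manifest <- data.frame(
    participant_id = rep(ids, each = cohort$trials_per_participant),
    trial = rep(seq_len(cohort$trials_per_participant), times = n),
    age = rep(ages, each = cohort$trials_per_participant),
    sex = rep(sex, each = cohort$trials_per_participant),
    handedness = rep(handedness, each = cohort$trials_per_participant),
    task = task$task_name,
    stringsAsFactors = FALSE
  )

  trials <- vector("list", nrow(manifest))
  k <- 0L
  for (i in seq_len(n)) {
    for (j in seq_len(cohort$trials_per_participant)) {
      k <- k + 1L
      p <- participant_spec(
        participant_id = ids[i],
        age = ages[i],
        sex = sex[i],
        handedness = handedness[i],
        capacity_lambda = gt[i, "capacity_lambda"],
        max_hand_speed = gt[i, "max_hand_speed"],
        reaction_delay = gt[i, "reaction_delay"],
        distractor_error_prob = gt[i, "distractor_error_prob"],
        hand_transition_x = gt[i, "hand_transition_x"],
        lapse_prob = gt[i, "lapse_prob"],
        rng_seed = trial_seeds[i, j]
      )
      trials[[k]] <- simulate_trial(task, p, include_samples = include_samples)
    }
  }

  list(manifest = manifest, trials = trials, ground_truth = ground_truth)
}

# Participant-level draw, using whatever RNG stream is active.
draw_participants_impl <- function(cohort) {
  n <- cohort$n_participants
  ages <- draw_ages(n, cohort)
  sex <- ifelse(runif(n) < cohort$sex_ratio, "female", "male")
  handedness <- sample(c("right", "left", "mixed"), n, replace = TRUE,
                       prob = c(0.895, 0.102, 0.003))

  par_names <- names(cohort$intercepts)
  gt <- matrix(NA_real_, nrow = n, ncol = length(par_names),
               dimnames = list(NULL, par_names))
  for (pn in par_names) {
    mu <- cohort$intercepts[[pn]] +
      cohort$age_slopes[[pn]] * ages +
      cohort$sex_offsets[[pn]] * (sex == "male")
    gt[, pn] <- mu + rnorm(n, 0, cohort$between_subject_sd[[pn]])
  }
  gt[, "capacity_lambda"] <- pmax(gt[, "capacity_lambda"], 0.2)
  gt[, "max_hand_speed"] <- pmax(gt[, "max_hand_speed"], 10)
  gt[, "reaction_delay"] <- pmax(gt[, "reaction_delay"], 0.05)
  gt[, "distractor_error_prob"] <- pmin(pmax(gt[, "distractor_error_prob"], 0), 1)
  gt[, "lapse_prob"] <- pmin(pmax(gt[, "lapse_prob"], 0), 1)

  ids <- sprintf("p%04d", seq_len(n))
  ground_truth <- data.frame(participant_id = ids, age = ages, sex = sex,
                             handedness = handedness,
                             as.data.frame(gt),
                             stringsAsFactors = FALSE)
  list(ground_truth = ground_truth, gt = gt)
}

#' Draw a cohort's participant-level ground truth without simulating trials
#'
#' Performs exactly the participant draw of [simulate_cohort()] (same ages,
#' sexes and latent parameters for the same `global_seed`) but skips trial
#' simulation; useful for studying the injected age/sex structure itself.
#'
#' @param cohort A [cohort_spec()].
#' @return Data frame of participant covariates and latent parameters.
#' @export
cohort_ground_truth <- function(cohort) {
  stopifnot(inherits(cohort, "cohort_spec"))
  old_seed <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old_seed, envir = globalenv())
    }
  })
  set.seed(cohort$global_seed)
  draw_participants_impl(cohort)$ground_truth
}

draw_ages <- function(n, cohort) {
  lo <- cohort$age_range[1]
  hi <- cohort$age_range[2]
  w <- cohort$age_weights
  if (is.null(w)) w <- DECADE_WEIGHTS
  breaks <- pmin(pmax(DECADE_BREAKS, lo), hi)
  widths <- diff(breaks)
  keep <- widths > 0
  if (!any(keep)) return(rep(lo, n))
  w <- w[keep]
  dec <- sample.int(sum(keep), n, replace = TRUE, prob = w)
  lo_k <- breaks[-length(breaks)][keep]
  hi_k <- breaks[-1][keep]
  round(runif(n, lo_k[dec], hi_k[dec]), 1)
}
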