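# Hand-built trial fixtures with fully controlled contents, for unit tests
# that need exact expected values rather than simulator output.

make_trial <- function(objects = NULL, samples = NULL,
                       task_name = "OH", n_targets = 300, n_distractors = 0,
                       n_bins = 10, workspace_width = 80,
                       sampling_rate = 200, trial_end = NULL) {
  if (is.null(trial_end)) {
    trial_end <- max(c(objects$t_outcome, samples$t, 0), na.rm = TRUE)
  }
  rec <- list(
    metadata = list(task_name = task_name, participant_id = "fixture",
                    sampling_rate = sampling_rate,
                    workspace_width = workspace_width, workspace_depth = 65,
                    paddle_diameter = 5, object_diameter = 2,
                    n_targets = n_targets, n_distractors = n_distractors,
                    n_bins = n_bins, trial_end = trial_end,
                    all_miss = is.null(objects) ||
                      !any(objects$outcome == "hit")),
    samples = samples,
    objects = objects
  )
  class(rec) <- "trial_recording"
  rec
}

# Object event log rows with defaults for the irrelevant columns.
make_objects <- function(bin, outcome, hand = "none",
                         role = "target", t_created = NULL,
                         t_outcome = NULL, x_outcome = NULL,
                         workspace_width = 80, n_bins = 10) {
  n <- length(bin)
  centres <- -workspace_width / 2 +
    workspace_width / n_bins * (seq_len(n_bins) - 0.5)
  if (is.null(t_created)) t_created <- seq_len(n)
  if (is.null(t_outcome)) t_outcome <- t_created + 2
  if (is.null(x_outcome)) x_outcome <- centres[bin]
  data.frame(object_id = seq_len(n), bin = bin,
             shape = "circle", role = rep_len(role, n),
             t_created = t_created, outcome = rep_len(outcome, n),
             t_outcome = t_outcome, x_outcome = x_outcome,
             hand = rep_len(hand, n), stringsAsFactors = FALSE)
}

# Kinematic sample table from velocity functions of time (positions by
# cumulative integration, so positions and velocities are consistent).
make_samples <- function(t_end = 10, fs = 200,
                         lvx = function(t) 0 * t, lvy = function(t) 0 * t,
                         rvx = function(t) 0 * t, rvy = function(t) 0 * t) {
  tt <- seq(0, t_end, by = 1 / fs)
  cumint <- function(v) c(0, cumsum((v[-1] + v[-length(v)]) / 2 * diff(tt)))
  data.frame(t = tt,
             left_x = cumint(lvx(tt)), left_y = cumint(lvy(tt)),
             left_vx = lvx(tt), left_vy = lvy(tt),
             right_x = cumint(rvx(tt)), right_y = cumint(rvy(tt)),
             right_vx = rvx(tt), right_vy = rvy(tt))
}

default_participant <- function(seed = 1, ...) {
  participant_spec("tp", age = 40, rng_seed = seed, ...)
}
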