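# Readers, writers and validation for trial recordings, manifests and
# parameter tables. All files are plain UTF-8 delimited text with header
# rows; numerics are written with 6 significant digits, which round-trips
# every quantity at better than the task's native resolution (1/200 s).

SAMPLE_COLS <- c("t", "left_x", "left_y", "left_vx", "left_vy",
                 "right_x", "right_y", "right_vx", "right_vy")
OBJECT_COLS <- c("object_id", "bin", "shape", "role", "t_created",
                 "outcome", "t_outcome", "x_outcome", "hand")

fmt_num <- function(x) {
  out <- formatC(x, digits = 6, format = "g")
  out[is.na(x)] <- "NA"
  out
}

write_delim6 <- function(df, path) {
  out <- df
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) out[[j]] <- fmt_num(out[[j]])
  }
  write.csv(out, path, row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
}

#' Write / read a trial recording
#'
#' A trial is stored as two CSV files sharing a stem: `<stem>_samples.csv`
#' (the 200 Hz kinematic table) and `<stem>_objects.csv` (the object event
#' log), plus `<stem>_meta.csv` holding the scalar metadata. `read_trial()`
#' validates the files and reports every violation it finds (missing
#' columns, non-monotone time stamps, unknown outcome labels, role/outcome
#' combinations that cannot occur, hand labels inconsistent with outcomes)
#' with row context.
#'
#' @param trial A `trial_recording` from [simulate_trial()].
#' @param stem Path stem (without the `_samples.csv` / `_objects.csv`
#'   suffix).
#' @return `write_trial()` returns `stem` invisibly; `read_trial()` returns
#'   a `trial_recording`.
#' @examples
#' tr <- simulate_trial(oh_task(), participant_spec("p1", 30, rng_seed = 2))
#' stem <- file.path(tempdir(), "p1_oh")
#' write_trial(tr, stem)
#' tr2 <- read_trial(stem)
#' @export
write_trial <- function(trial, stem) {
  stopifnot(inherits(trial, "trial_recording"))
  meta <- trial$metadata
  meta_df <- data.frame(field = names(meta),
                        value = vapply(meta, function(v) as.character(v), ""),
                        stringsAsFactors = FALSE)
  write_delim6(meta_df, paste0(stem, "_meta.csv"))
  if (!is.null(trial$samples)) {
    write_delim6(trial$samples, paste0(stem, "_samples.csv"))
  }
  write_delim6(trial$objects, paste0(stem, "_objects.csv"))
  invisible(stem)
}

#' @rdname write_trial
#' @export
read_trial <- function(stem) {
  meta_path <- paste0(stem, "_meta.csv")
  obj_path <- paste0(stem, "_objects.csv")
  samp_path <- paste0(stem, "_samples.csv")
  for (p in c(meta_path, obj_path)) {
    if (!file.exists(p)) stop("trial file not found: ", p, call. = FALSE)
  }
  meta_df <- read.csv(meta_path, stringsAsFactors = FALSE,
                      colClasses = "character")
  meta <- as.list(meta_df$value)
  names(meta) <- meta_df$field
  num_fields <- c("sampling_rate", "workspace_width", "workspace_depth",
                  "paddle_diameter", "object_diameter", "n_targets",
                  "n_distractors", "n_bins", "trial_end")
  for (f in intersect(num_fields, names(meta))) meta[[f]] <- as.numeric(meta[[f]])
  if ("all_miss" %in% names(meta)) meta$all_miss <- as.logical(meta$all_miss)

  objects <- read.csv(obj_path, stringsAsFactors = FALSE)
  samples <- NULL
  if (file.exists(samp_path)) {
    samples <- read.csv(samp_path, stringsAsFactors = FALSE)
  }
  rec <- list(metadata = meta, samples = samples, objects = objects)
  class(rec) <- "trial_recording"
  validate_trial(rec)
  rec
}

#' Validate a trial recording
#'
#' Checks the structural invariants of a recording and, on failure, raises
#' one error listing every violation. Checked: required columns; strictly
#' increasing, regularly spaced sample times; finite velocities; outcome
#' labels in `hit/missed/avoided`; targets never `avoided` and distractors
#' never `missed`; `hand` is `none` exactly for non-hits; bins within range;
#' outcome times within the trial.
#'
#' @param trial A `trial_recording`.
#' @return The trial, invisibly, if valid.
#' @export
validate_trial <- function(trial) {
  bad <- character(0)
  obj <- trial$objects
  missing_cols <- setdiff(OBJECT_COLS, names(obj))
  if (length(missing_cols)) {
    bad <- c(bad, paste("objects table missing column(s):",
                        paste(missing_cols, collapse = ", ")))
  } else {
    unknown <- !obj$outcome %in% c("hit", "missed", "avoided")
    if (any(unknown)) {
      bad <- c(bad, paste("unknown outcome label at object row(s):",
                          paste(head(which(unknown), 5), collapse = ", ")))
    }
    ta <- obj$role == "target" & obj$outcome == "avoided"
    if (any(ta)) {
      bad <- c(bad, paste("target marked 'avoided' at object row(s):",
                          paste(head(which(ta), 5), collapse = ", ")))
    }
    dm <- obj$role == "distractor" & obj$outcome == "missed"
    if (any(dm)) {
      bad <- c(bad, paste("distractor marked 'missed' at object row(s):",
                          paste(head(which(dm), 5), collapse = ", ")))
    }
    hb <- (obj$hand == "none") != (obj$outcome != "hit")
    if (any(hb, na.rm = TRUE)) {
      bad <- c(bad, paste("hand label inconsistent with outcome at row(s):",
                          paste(head(which(hb), 5), collapse = ", ")))
    }
    nb <- trial$metadata$n_bins
    if (!is.null(nb) && is.finite(nb) &&
        any(obj$bin < 1 | obj$bin > nb)) {
      bad <- c(bad, "object bin outside 1..n_bins")
    }
    if (any(obj$t_outcome < 0, na.rm = TRUE)) {
      bad <- c(bad, "negative outcome time")
    }
    te <- trial$metadata$trial_end
    if (!is.null(te) && is.finite(te) &&
        any(obj$t_outcome > te + 1e-6, na.rm = TRUE)) {
      bad <- c(bad, "object outcome time beyond trial end")
    }
  }
  smp <- trial$samples
  if (!is.null(smp)) {
    missing_cols <- setdiff(SAMPLE_COLS, names(smp))
    if (length(missing_cols)) {
      bad <- c(bad, paste("samples table missing column(s):",
                          paste(missing_cols, collapse = ", ")))
    } else {
      dt <- diff(smp$t)
      if (any(dt <= 0)) {
        bad <- c(bad, paste("non-increasing sample time at row(s):",
                            paste(head(which(dt <= 0) + 1, 5), collapse = ", ")))
      } else {
        fs <- trial$metadata$sampling_rate
        if (!is.null(fs) && is.finite(fs) &&
            any(abs(dt - 1 / fs) > 1e-4)) {
          bad <- c(bad, "sample spacing differs from 1/sampling_rate")
        }
      }
      vel <- as.matrix(smp[, c("left_vx", "left_vy", "right_vx", "right_vy")])
      if (any(!is.finite(vel))) bad <- c(bad, "non-finite velocity sample")
    }
  }
  if (length(bad)) {
    stop("invalid trial recording:\n  ", paste(bad, collapse = "\n  "),
         call. = FALSE)
  }
  invisible(trial)
}

#' Write / read a cohort manifest
#'
#' The manifest holds one row per trial: `participant_id`, `trial`, `age`,
#' `sex`, `handedness`, `task`.
#'
#' @param manifest Data frame as produced by [simulate_cohort()].
#' @param path CSV path.
#' @export
write_manifest <- function(manifest, path) {
  write_delim6(manifest, path)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}

#' Write / read a per-trial parameters table
#'
#' One row per trial, one column per extracted performance parameter
#' (see [extract_parameters()]), keyed by `participant_id` and `trial`.
#'
#' @param params Data frame of parameter rows.
#' @param path CSV path.
#' @export
write_parameters <- function(params, path) {
  write_delim6(params, path)
  invisible(path)
}

#' @rdname write_parameters
#' @export
read_parameters <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}

#' Join participant covariates onto per-trial parameter rows
#'
#' Inner-joins the cohort manifest (participant covariates) to extracted
#' parameter rows on `participant_id` (and `trial` when both carry it),
#' producing the cohort table consumed by the statistical layer: one row
#' per trial with age, sex, handedness, task and all performance
#' parameters.
#'
#' @param manifest Manifest data frame (`participant_id`, `age`, `sex`,
#'   `handedness`, `task`, optionally `trial`).
#' @param params Parameter rows with `participant_id` (optionally `trial`).
#' @return Data frame with one row per parameter row.
#' @export
build_cohort_table <- function(manifest, params) {
  stopifnot(is.data.frame(manifest), is.data.frame(params))
  if (!"participant_id" %in% names(params)) {
    stop("parameter rows must carry 'participant_id'")
  }
  if (nrow(params) == 0) {
    cov_cols <- setdiff(names(manifest), names(params))
    out <- cbind(params,
                 manifest[integer(0), cov_cols, drop = FALSE])
    return(out)
  }
  orphans <- setdiff(unique(params$participant_id),
                     unique(manifest$participant_id))
  if (length(orphans)) {
    stop("parameter rows reference participant(s) absent from manifest: ",
         paste(orphans, collapse = ", "), call. = FALSE)
  }
  keys <- "participant_id"
  if ("trial" %in% names(manifest) && "trial" %in% names(params)) {
    keys <- c(keys, "trial")
  }
  cov <- unique(manifest[, c(keys, setdiff(names(manifest),
                                           c(keys, names(params))))])
  if (anyDuplicated(cov[, keys, drop = FALSE])) {
    stop("manifest has duplicated keys: ", paste(keys, collapse = " + "))
  }
  params$.row <- seq_len(nrow(params))
  merged <- merge(params, cov, by = keys, all.x = TRUE, sort = FALSE)
  merged <- merged[order(merged$.row), , drop = FALSE]
  merged$.row <- NULL
  rownames(merged) <- NULL
  merged
}
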