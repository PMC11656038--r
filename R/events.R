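#' Read a trial events file
#'
#' Reads a delimited event table with columns `participant, task,
#' trial_index, t_target_ms, rt_ms, correct, cue, target_type`. An empty
#' `rt_ms` field denotes a miss (no response).
#'
#' @param path Path to a CSV/TSV events file.
#' @return A data.frame ordered by participant and trial_index, with a
#'   `trial_id` column (`participant:trial_index`).
#' @export
read_events <- function(path) {
  if (!file.exists(path)) stop("events file not found: ", path)
  ev <- as.data.frame(data.table::fread(path))
  need <- c("participant", "task", "trial_index", "t_target_ms", "rt_ms")
  miss <- setdiff(need, names(ev))
  if (length(miss))
    stop("events file ", path, " lacks column(s): ", paste(miss, collapse = ", "))
  ev <- ev[order(ev$participant, ev$trial_index), , drop = FALSE]
  if (!"trial_id" %in% names(ev))
    ev$trial_id <- paste(ev$participant, ev$trial_index, sep = ":")
  rownames(ev) <- NULL
  ev
}

#' Write a trial events file
#'
#' @param events Event data.frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path) {
  data.table::fwrite(events, path)
  invisible(path)
}

round_half_up <- function(x) floor(x + 0.5)

#' Flag excluded trials
#'
#' Applies the standard exclusion rules per participant: misses (absent
#' RT), anticipations/false alarms (RT at or below `anticipation_ms`),
#' incorrect responses (when a `correct` column is present), and the first
#' `round(first_fraction * N)` trials of each participant's session
#' (round-half-up; N = that participant's total trial count), which absorb
#' task-initiation artefacts such as dark adaptation. Trials are flagged,
#' never deleted, so later contrasts can re-admit them (the accuracy
#' contrast re-admits incorrect trials).
#'
#' @param events Event data.frame (see [read_events()]), ordered by
#'   trial_index within participant.
#' @param first_fraction Fraction of initial trials to drop per participant
#'   (default 0.05).
#' @param anticipation_ms RT threshold in ms; responses at or below it are
#'   excluded (default 150).
#' @return `events` with logical `excluded` and character `reason` columns
#'   (first matching reason of miss > false_alarm > anticipation >
#'   incorrect > startup; `false_alarm` only when the table carries that
#'   column, e.g. responses emitted before target onset in the vigilance
#'   task).
#' @export
exclude_trials <- function(events, first_fraction = 0.05,
                           anticipation_ms = 150) {
  if (!nrow(events)) stop("no trials")
  events$excluded <- FALSE
  events$reason <- NA_character_
  flag <- function(idx, why) {
    new <- idx & is.na(events$reason)
    events$reason[new] <<- why
    events$excluded <<- events$excluded | idx
  }
  rt <- events$rt_ms
  flag(is.na(rt), "miss")
  if ("false_alarm" %in% names(events))
    flag(!is.na(events$false_alarm) & events$false_alarm, "false_alarm")
  flag(!is.na(rt) & rt <= anticipation_ms, "anticipation")
  if ("correct" %in% names(events))
    flag(!is.na(events$correct) & !events$correct, "incorrect")
  for (p in unique(events$participant)) {
    rows <- which(events$participant == p)
    k <- round_half_up(first_fraction * length(rows))
    if (k > 0) {
      first <- rows[order(events$trial_index[rows])][seq_len(k)]
      idx <- rep(FALSE, nrow(events)); idx[first] <- TRUE
      flag(idx, "startup")
    }
  }
  events
}

#' Join trend values onto trials
#'
#' Inner join of the event table and a trend table on `trial_id`. Rows
#' whose trend quality is not `complete` are dropped for that method and
#' scale only, mirroring the loss of edge trials whose smoothing windows
#' extend past the recording.
#'
#' @param events Event data.frame with unique `trial_id`.
#' @param trends Trend table from [compute_trend_table()] (binocular rows
#'   are selected when an `eye` column is present).
#' @return Joined data.frame, one row per trial x method x scale.
#' @export
attach_trends <- function(events, trends) {
  if (anyDuplicated(events$trial_id))
    stop("duplicate trial_id in event table")
  if ("eye" %in% names(trends)) trends <- trends[trends$eye == "binocular", ]
  key <- paste(trends$trial_id, trends$method, trends$scale_ms)
  if (anyDuplicated(key))
    stop("duplicate trial/method/scale rows in trend table")
  if (!nrow(trends)) {
    warning("empty trend table: join is empty")
    return(merge(events, trends, by = "trial_id")[0, ])
  }
  ok <- trends$quality == "complete"
  merge(events, trends[ok, setdiff(names(trends), "participant")],
        by = "trial_id")
}

#' Split trials by reaction time
#'
#' Per-participant RT categorisation of valid trials. `mean_split`: trials
#' with RT strictly below the participant's mean are `short`, the rest
#' `long`. `quartile_split`: RT strictly below the participant's 25th
#' percentile is `short`, strictly above the 75th is `long`, the middle
#' half unassigned; percentiles use the linear-interpolation definition
#' (`stats::quantile` type 7).
#'
#' @param events Event data.frame carrying `excluded` flags (see
#'   [exclude_trials()]).
#' @param scheme `"mean_split"` or `"quartile_split"`.
#' @param min_trials Minimum valid RT trials per participant (default 2 for
#'   mean_split, 4 for quartile_split); participants below it are omitted
#'   with a message.
#' @return data.frame `participant`, `trial_id`, `group`
#'   (`short`/`long`), `scheme`.
#' @export
split_by_rt <- function(events, scheme = c("mean_split", "quartile_split"),
                        min_trials = NULL) {
  scheme <- match.arg(scheme)
  if (is.null(min_trials))
    min_trials <- if (scheme == "mean_split") 2L else 4L
  valid <- !events$excluded & !is.na(events$rt_ms)
  out <- list()
  for (p in unique(events$participant)) {
    rows <- which(valid & events$participant == p)
    if (length(rows) < min_trials) {
      message("split_by_rt: participant ", p, " has fewer than ", min_trials,
              " valid RT trials; omitted")
      next
    }
    rt <- events$rt_ms[rows]
    if (scheme == "mean_split") {
      grp <- ifelse(rt < mean(rt), "short", "long")
      keep <- rep(TRUE, length(rt))
    } else {
      q <- stats::quantile(rt, c(0.25, 0.75), type = 7, names = FALSE)
      grp <- rep(NA_character_, length(rt))
      grp[rt < q[1]] <- "short"
      grp[rt > q[2]] <- "long"
      keep <- !is.na(grp)
    }
    if (any(keep))
      out[[p]] <- data.frame(participant = p,
                             trial_id = events$trial_id[rows][keep],
                             group = grp[keep], scheme = scheme,
                             stringsAsFactors = FALSE)
  }
  if (!length(out)) stop("no participant has enough valid RT trials")
  do.call(rbind, c(out, make.row.names = FALSE))
}

#' Split trials by response accuracy
#'
#' Groups non-excluded-for-other-reasons trials into `correct` vs
#' `incorrect`. Incorrect trials (normally excluded) are re-admitted for
#' this contrast; misses and anticipations stay out. Participants without
#' any incorrect trial are omitted with a message.
#'
#' @param events Event data.frame with a logical `correct` column and
#'   `reason` flags from [exclude_trials()].
#' @return data.frame `participant`, `trial_id`, `group`, `scheme`.
#' @export
split_by_accuracy <- function(events) {
  if (!"correct" %in% names(events) || all(is.na(events$correct)))
    stop("accuracy split requires a correct/incorrect column")
  reason <- if ("reason" %in% names(events)) events$reason else
    rep(NA_character_, nrow(events))
  eligible <- !is.na(events$correct) &
    (is.na(reason) | reason == "incorrect")
  out <- list()
  for (p in unique(events$participant)) {
    rows <- which(eligible & events$participant == p)
    grp <- ifelse(events$correct[rows], "correct", "incorrect")
    if (!any(grp == "incorrect")) {
      message("split_by_accuracy: participant ", p,
              " has no incorrect trials; omitted")
      next
    }
    out[[p]] <- data.frame(participant = p,
                           trial_id = events$trial_id[rows],
                           group = grp, scheme = "accuracy",
                           stringsAsFactors = FALSE)
  }
  if (!length(out)) stop("no participant has both correct and incorrect trials")
  do.call(rbind, c(out, make.row.names = FALSE))
}

#' Split cued-flanker trials by condition
#'
#' Condition contrasts for the cued flanker task (ANT). `alerting`: trials
#' with a center cue vs no cue, regardless of target type (double and
#' spatial cues unassigned, avoiding the cue-luminance confound).
#' `executive`: congruent vs incongruent targets irrespective of cue type
#' (neutral targets unassigned).
#'
#' @param events Event data.frame with `cue` and/or `target_type` columns
#'   and exclusion flags.
#' @param contrast `"alerting"` or `"executive"`.
#' @return data.frame `participant`, `trial_id`, `group`, `scheme`.
#' @export
split_by_condition <- function(events, contrast = c("alerting", "executive")) {
  contrast <- match.arg(contrast)
  col <- if (contrast == "alerting") "cue" else "target_type"
  if (!col %in% names(events) || all(is.na(events[[col]])))
    stop(contrast, " contrast requires a '", col, "' column")
  valid <- !events$excluded
  lab <- events[[col]]
  grp <- rep(NA_character_, nrow(events))
  if (contrast == "alerting") {
    grp[lab == "center"] <- "center_cue"
    grp[lab == "none"] <- "no_cue"
  } else {
    grp[lab == "congruent"] <- "congruent"
    grp[lab == "incongruent"] <- "incongruent"
  }
  keep <- valid & !is.na(grp)
  data.frame(participant = events$participant[keep],
             trial_id = events$trial_id[keep],
             group = grp[keep], scheme = contrast,
             stringsAsFactors = FALSE)
}
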