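#' Read a pipeline configuration file
#'
#' YAML (or JSON) configuration with optional sections: `seed`;
#' `synthetic` (arguments to [synthetic_config()]) or `input`
#' (`samples_dir`, `events` file); `trend` (`windows_s`, `conservative`
#' with `window_s`/`span_s`, `scales_ms`, `max_interp_frac`); `analysis`
#' (`schemes`: any of `mean_split`, `quartile_split`, `accuracy`,
#' `alerting`, `executive`; `alpha_level`).
#'
#' @param path Path to the config file.
#' @return Config list with defaults filled in.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  cfg$seed <- if (is.null(cfg$seed)) 1L else as.integer(cfg$seed)
  tr <- cfg$trend
  if (is.null(tr)) tr <- list()
  # keys explicitly set to null in the file disable that method
  if (!"windows_s" %in% names(tr)) tr$windows_s <- c(5, 10, 15)
  if (!"conservative" %in% names(tr)) tr$conservative <-
      list(window_s = 10, span_s = 14)
  if (!"scales_ms" %in% names(tr)) tr$scales_ms <- c(4096, 8192, 16384, 32768)
  if (is.null(tr$max_interp_frac)) tr$max_interp_frac <- 0.5
  cfg$trend <- tr
  an <- cfg$analysis
  if (is.null(an)) an <- list()
  if (is.null(an$schemes)) an$schemes <- c("mean_split", "quartile_split")
  if (is.null(an$alpha_level)) an$alpha_level <- 0.05
  cfg$analysis <- an
  cfg
}

#' Simulate and write a synthetic cohort to disk
#'
#' Writes one samples file (`<id>_samples.csv`) and one events file
#' (`<id>_events.csv`) per synthetic participant. Refuses to overwrite
#' existing outputs unless `force = TRUE`.
#'
#' @param config A [synthetic_config()] (or a config list with a
#'   `synthetic` section and `seed`).
#' @param out_dir Output directory (created if missing).
#' @param force Overwrite existing files.
#' @return Invisibly, a data.frame listing the written files.
#' @export
cmd_simulate <- function(config, out_dir, force = FALSE) {
  if (!inherits(config, "synthetic_config")) {
    args <- config$synthetic
    if (is.null(args)) stop("config has no 'synthetic' section")
    args$seed <- config$seed
    config <- do.call(synthetic_config, args)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sessions <- simulate_cohort(config)
  files <- lapply(names(sessions), function(id) {
    sp <- file.path(out_dir, paste0(id, "_samples.csv"))
    ep <- file.path(out_dir, paste0(id, "_events.csv"))
    if (!force && (file.exists(sp) || file.exists(ep)))
      stop("output exists (use force = TRUE): ", sp)
    write_samples(sessions[[id]]$recording, sp)
    write_events(sessions[[id]]$events, ep)
    data.frame(participant = id, samples = sp, events = ep,
               stringsAsFactors = FALSE)
  })
  invisible(do.call(rbind, files))
}

#' Preprocess a samples file to clean per-eye series
#'
#' Runs blink detection and interpolation for both eyes of one samples
#' file and writes the clean series, the blink-segment table, and a short
#' quality log.
#'
#' @param samples_path Path to a samples CSV (see [read_samples()]).
#' @param out_dir Output directory.
#' @param margin_ms,noise_k Blink-detection parameters.
#' @return Invisibly, a list with the clean series and blink tables.
#' @export
cmd_preprocess <- function(samples_path, out_dir, margin_ms = 200,
                           noise_k = 5) {
  rec <- read_samples(samples_path)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stem <- sub("\\.[^.]*$", "", basename(samples_path))
  out <- list(blinks = list(), clean = list())
  for (eye in c("left", "right")) {
    seg <- detect_blinks(rec, eye, margin_ms, noise_k)
    cl <- tryCatch(interpolate_blinks(rec, seg, eye), error = function(e) {
      warning("eye unusable (", eye, "): ", conditionMessage(e))
      NULL
    })
    out$blinks[[eye]] <- seg
    out$clean[[eye]] <- cl
    if (!is.null(cl)) {
      data.table::fwrite(data.table::data.table(
        t_ms = cl$t, value_px = cl$value, interpolated = cl$interpolated),
        file.path(out_dir, paste0(stem, "_clean_", eye, ".csv")))
      message(sprintf("%s %s eye: %d blink segment(s), %.2f%% interpolated",
                      stem, eye, nrow(seg), 100 * mean(cl$interpolated)))
    }
  }
  blinks <- do.call(rbind, out$blinks)
  data.table::fwrite(blinks, file.path(out_dir, paste0(stem, "_blinks.csv")))
  invisible(out)
}

exclusion_counts <- function(events) {
  counts <- lapply(split(events, events$participant), function(e) {
    tab <- table(factor(e$reason[!is.na(e$reason)]))
    list(trials_in = nrow(e),
         trials_analyzed = sum(!e$excluded),
         excluded = as.list(tab))
  })
  counts
}

#' Run the full analysis pipeline from a configuration
#'
#' Executes simulate/load, preprocess, trend computation, trial exclusion,
#' group splits, and contrasts; writes the trend table, the comparison
#' table, and a JSON run manifest under `out_dir`.
#'
#' @param config_path Path to a YAML config (see [read_config()]), or an
#'   already-loaded config list.
#' @param out_dir Output directory (default from the config's `out_dir`,
#'   else `"pupiltrend_out"`).
#' @return Invisibly, a list with `results` (comparison table), `trends`,
#'   `events`, and `manifest`. Degenerate contrasts are reported in the
#'   manifest and raised as warnings.
#' @export
cmd_run_all <- function(config_path, out_dir = NULL) {
  cfg <- if (is.character(config_path)) read_config(config_path) else config_path
  if (is.null(out_dir)) out_dir <- if (!is.null(cfg$out_dir)) cfg$out_dir else
    "pupiltrend_out"
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  input_files <- character(0)
  if (!is.null(cfg$synthetic)) {
    args <- cfg$synthetic
    args$seed <- cfg$seed
    scfg <- do.call(synthetic_config, args)
    sessions <- simulate_cohort(scfg)
  } else if (!is.null(cfg$input)) {
    ev_all <- read_events(cfg$input$events)
    sample_files <- list.files(cfg$input$samples_dir,
                               pattern = "_samples\\.csv$", full.names = TRUE)
    if (!length(sample_files)) stop("no *_samples.csv files in ",
                                    cfg$input$samples_dir)
    input_files <- c(cfg$input$events, sample_files)
    sessions <- lapply(sample_files, function(f) {
      rec <- read_samples(f)
      pid <- sub("_samples$", "", rec$participant_id)
      rec$participant_id <- pid
      list(recording = rec, events = ev_all[ev_all$participant == pid, ])
    })
    names(sessions) <- vapply(sessions, function(s) s$recording$participant_id, "")
    empty <- vapply(sessions, function(s) nrow(s$events) == 0L, TRUE)
    if (any(empty)) stop("no events for participant(s): ",
                         paste(names(sessions)[empty], collapse = ", "))
  } else stop("config needs a 'synthetic' or 'input' section")

  tr <- cfg$trend
  events <- do.call(rbind, lapply(sessions, `[[`, "events"))
  rownames(events) <- NULL
  events <- exclude_trials(events)
  trends <- do.call(rbind, lapply(sessions, session_trend_df,
                                  windows_s = tr$windows_s,
                                  scales_ms = tr$scales_ms,
                                  conservative = tr$conservative,
                                  max_interp_frac = tr$max_interp_frac))
  rownames(trends) <- NULL
  joined <- attach_trends(events, trends)

  task <- events$task[1]
  results <- list()
  for (scheme in cfg$analysis$schemes) {
    assignment <- switch(scheme,
      mean_split = ,
      quartile_split = suppressMessages(split_by_rt(events, scheme)),
      accuracy = suppressMessages(split_by_accuracy(events)),
      alerting = ,
      executive = split_by_condition(events, scheme),
      stop("unknown scheme: ", scheme))
    results[[scheme]] <- run_contrast(joined, assignment,
                                      contrast_label = paste(task, scheme))
  }
  results <- do.call(rbind, c(results, make.row.names = FALSE))
  if (any(results$degenerate))
    warning("degenerate contrast(s) present; see manifest")

  trend_path <- file.path(out_dir, "trend_table.csv")
  res_path <- file.path(out_dir, "comparison_results.csv")
  data.table::fwrite(trends, trend_path)
  write_comparison(results, res_path)

  manifest <- list(
    package_version = as.character(utils::packageVersion("pupiltrend")),
    seed = cfg$seed,
    config = cfg[setdiff(names(cfg), "out_dir")],
    input_checksums = if (length(input_files))
      as.list(tools::md5sum(input_files)) else list(),
    counts = exclusion_counts(events),
    degenerate_contrasts = sum(results$degenerate),
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(results = results, trends = trends, events = events,
                 manifest = manifest))
}
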