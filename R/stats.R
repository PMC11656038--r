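#' Per-participant mean trends by group
#'
#' Aggregates a joined trial-by-trend table to one mean trend value per
#' participant x group x method x scale. Participants lacking a complete
#' trend in every group of the assignment scheme are dropped from that
#' contrast (with a message), keeping the later pairing balanced.
#'
#' @param joined Output of [attach_trends()].
#' @param assignment Group assignment table (`participant`, `trial_id`,
#'   `group`, `scheme`) from one of the `split_by_*` functions.
#' @return data.frame `participant`, `group`, `method`, `scale_ms`,
#'   `mean_px`, `n_trials`.
#' @export
participant_means <- function(joined, assignment) {
  if (!nrow(assignment)) stop("empty group assignment")
  d <- merge(joined, assignment[, c("trial_id", "group")], by = "trial_id")
  if (!nrow(d)) stop("comparison impossible: no trial has both a trend and a group")
  agg <- stats::aggregate(
    value_px ~ participant + group + method + scale_ms, data = d,
    FUN = mean)
  cnt <- stats::aggregate(
    value_px ~ participant + group + method + scale_ms, data = d,
    FUN = length)
  names(agg)[names(agg) == "value_px"] <- "mean_px"
  agg$n_trials <- cnt$value_px
  groups <- sort(unique(assignment$group))
  # keep only participants present in every group, per method/scale
  keep <- rep(TRUE, nrow(agg))
  split_key <- paste(agg$method, agg$scale_ms)
  for (k in unique(split_key)) {
    sel <- split_key == k
    tab <- table(agg$participant[sel])
    bad <- names(tab)[tab < length(groups)]
    if (length(bad)) {
      message("participant_means: dropping ", length(bad),
              " participant(s) missing a group for ", k)
      keep[sel & agg$participant %in% bad] <- FALSE
    }
  }
  out <- agg[keep, ]
  if (!nrow(out)) stop("comparison impossible: no participant has every group")
  rownames(out) <- NULL
  out
}

#' Paired one-tailed t test
#'
#' Paired t statistic on the per-participant differences `a - b`, with the
#' one-tailed p-value for the alternative `mean(a - b) < 0` (direction
#' `"a_less"`) or `> 0` (`"a_greater"`). When the differences have zero
#' variance the test is degenerate: p is 0 or 1 by the sign of the mean
#' (0.5 when the mean is also zero) and `degenerate = TRUE`.
#'
#' @param a,b Numeric vectors of per-participant means, paired by position,
#'   length >= 2.
#' @param direction `"a_less"` (default) or `"a_greater"`.
#' @return List with `t`, `dof`, `p`, `degenerate`.
#' @export
paired_t_one_tailed <- function(a, b, direction = c("a_less", "a_greater")) {
  direction <- match.arg(direction)
  stopifnot(length(a) == length(b), length(a) >= 2)
  d <- a - b
  n <- length(d)
  m <- mean(d)
  s <- stats::sd(d)
  dof <- n - 1L
  if (s == 0) {
    p <- if (m == 0) 0.5 else if ((m < 0) == (direction == "a_less")) 0 else 1
    return(list(t = if (m == 0) 0 else sign(m) * Inf, dof = dof, p = p,
                degenerate = TRUE))
  }
  t <- m / (s / sqrt(n))
  p <- if (direction == "a_less") stats::pt(t, dof) else
    stats::pt(t, dof, lower.tail = FALSE)
  list(t = t, dof = dof, p = p, degenerate = FALSE)
}

#' Paired Cohen's d
#'
#' Effect size for a paired design: `mean(a - b) / sd(a - b)` with the
#' sample (n - 1) standard deviation, so `|d| = |t| / sqrt(n)`. The pooled
#' variant `mean(a - b) / sd_pooled(a, b)` is also returned for
#' comparability with reports that use it.
#'
#' @inheritParams paired_t_one_tailed
#' @return List with `d` (sd-of-differences), `d_pooled`, `degenerate`.
#' @export
cohens_d_paired <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 2)
  d <- a - b
  m <- mean(d)
  s <- stats::sd(d)
  sp <- sqrt((stats::var(a) + stats::var(b)) / 2)
  ratio <- function(num, den) {
    if (den > 0) num / den else if (num == 0) 0 else sign(num) * Inf
  }
  list(d = ratio(m, s), d_pooled = ratio(m, sp), degenerate = s == 0)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment over one family of tests (here,
#' the set of smoothing windows within a single contrast, which are
#' strongly correlated).
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, same length and order as `p`.
#' @export
bh_fdr <- function(p) {
  if (any(!is.finite(p) | p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Run one group contrast over the full method/scale grid
#'
#' For each method and scale present in the joined table, aggregates
#' per-participant group means, runs the paired one-tailed test
#' (alternative: group `a` below group `b`), and computes paired effect
#' sizes. BH-FDR adjustment is applied across the family of smoothing
#' windows (method `"smoothed"`) within the contrast; conservative and
#' decomposed p-values are reported uncorrected.
#'
#' @param joined Output of [attach_trends()].
#' @param assignment Group assignment table from a `split_by_*` function.
#' @param group_a,group_b Group labels; the one-tailed alternative is
#'   `mean(a) < mean(b)`. Defaults to the alphabetically ordered pair for
#'   the scheme's two groups when omitted.
#' @param contrast_label Label stored in the result rows (defaults to the
#'   assignment scheme).
#' @return data.frame of class `comparison_result`, one row per method x
#'   scale: `contrast`, `method`, `scale_ms`, `n_participants`, `mean_a`,
#'   `mean_b`, `mean_diff_px`, `t_stat`, `dof`, `p_one_tailed`, `p_fdr`,
#'   `cohens_d`, `cohens_d_pooled`, `direction`, `degenerate`.
#' @export
run_contrast <- function(joined, assignment, group_a = NULL, group_b = NULL,
                         contrast_label = NULL) {
  groups <- sort(unique(assignment$group))
  if (is.null(group_a) || is.null(group_b)) {
    pairs <- list(c("short", "long"), c("correct", "incorrect"),
                  c("center_cue", "no_cue"), c("congruent", "incongruent"))
    hit <- Filter(function(p) setequal(p, groups), pairs)
    if (length(hit) != 1)
      stop("cannot infer group pair from assignment; give group_a/group_b")
    group_a <- hit[[1]][1]; group_b <- hit[[1]][2]
  }
  if (is.null(contrast_label)) contrast_label <- assignment$scheme[1]
  pm <- participant_means(joined, assignment)
  grid <- unique(pm[, c("method", "scale_ms")])
  grid <- grid[order(grid$method, grid$scale_ms), ]
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    sel <- pm$method == grid$method[i] & pm$scale_ms == grid$scale_ms[i]
    wide <- merge(pm[sel & pm$group == group_a, c("participant", "mean_px")],
                  pm[sel & pm$group == group_b, c("participant", "mean_px")],
                  by = "participant", suffixes = c("_a", "_b"))
    if (nrow(wide) < 2) {
      stop("comparison impossible for ", grid$method[i], "/",
           grid$scale_ms[i], ": fewer than 2 complete participants")
    }
    tt <- paired_t_one_tailed(wide$mean_px_a, wide$mean_px_b, "a_less")
    dd <- cohens_d_paired(wide$mean_px_a, wide$mean_px_b)
    data.frame(contrast = contrast_label, method = grid$method[i],
               scale_ms = grid$scale_ms[i], n_participants = nrow(wide),
               mean_a = mean(wide$mean_px_a), mean_b = mean(wide$mean_px_b),
               mean_diff_px = mean(wide$mean_px_a) - mean(wide$mean_px_b),
               t_stat = tt$t, dof = tt$dof, p_one_tailed = tt$p,
               p_fdr = NA_real_, cohens_d = dd$d,
               cohens_d_pooled = dd$d_pooled,
               direction = paste0(group_a, "<", group_b),
               degenerate = tt$degenerate,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  sm <- res$method == "smoothed"
  if (any(sm)) res$p_fdr[sm] <- bh_fdr(res$p_one_tailed[sm])
  class(res) <- c("comparison_result", class(res))
  res
}

#' Write a comparison-result table
#'
#' @param result Output of [run_contrast()] (rows from several contrasts
#'   may be bound together).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_comparison <- function(result, path) {
  data.table::fwrite(as.data.frame(result), path)
  invisible(path)
}
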