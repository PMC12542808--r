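# Per-sample recovery statistics (the capture-assembly summary table),
# column summaries, heatmap matrices and the simple age-trend fit.

#' Per-sample capture recovery statistics
#'
#' Collapses a long-format recovery table (one row per sample x locus) into
#' one summary row per sample: read counts, on-target percentage, locus
#' counts at the recovery thresholds, paralog-warning counts and total bases
#' recovered. Threshold counts use strict greater-than comparison
#' (`recovered > threshold x mean target length`), matching the ">50%" /
#' ">75%" column convention; set `inclusive = TRUE` for a `>=` sensitivity
#' analysis.
#'
#' @param records Tibble with columns `sample`, `locus`, `recovered_len`,
#'   `target_len`, `reads`, `mapped`, `paralog_len`, `paralog_depth`;
#'   optional logicals `has_reads` (default `TRUE`) and `has_seq` (default
#'   `recovered_len > 0`).
#' @param config A [design_config()] (supplies `recovery_thresholds`).
#' @param inclusive Use `>=` instead of `>` at the thresholds.
#' @return A tibble with one row per sample: `sample`, `n_reads`,
#'   `n_on_target`, `pct_on_target` (1 decimal), `n_loci_with_reads`,
#'   `n_loci_with_seq`, `n_loci_50`, `n_loci_75`, `n_paralog_len`,
#'   `n_paralog_depth`, `total_bases`.
#' @export
build_sample_stats <- function(records, config = design_config(),
                               inclusive = FALSE) {
  if (any(records$target_len <= 0)) {
    abort("Every locus needs a positive mean target length.",
          class = "exonbaits_data_error")
  }
  if (!"has_reads" %in% names(records)) records$has_reads <- TRUE
  if (!"has_seq" %in% names(records)) records$has_seq <- records$recovered_len > 0
  if (any(records$mapped > records$reads)) {
    abort("Mapped reads exceed total reads for some sample.",
          class = "exonbaits_data_error")
  }
  thr <- sort(config$recovery_thresholds)
  cmp <- if (inclusive) `>=` else `>`
  records %>%
    group_by(.data$sample) %>%
    summarise(
      n_reads = .data$reads[1],
      n_on_target = .data$mapped[1],
      pct_on_target = round_half_away(.data$mapped[1] / .data$reads[1] * 100, 1),
      n_loci_with_reads = sum(.data$has_reads),
      n_loci_with_seq = sum(.data$has_seq),
      n_loci_50 = sum(cmp(.data$recovered_len, thr[1] * .data$target_len)),
      n_loci_75 = sum(cmp(.data$recovered_len, thr[2] * .data$target_len)),
      n_paralog_len = sum(.data$paralog_len),
      n_paralog_depth = sum(.data$paralog_depth),
      total_bases = sum(.data$recovered_len),
      .groups = "drop"
    )
}

#' Column summaries of a sample-statistics table
#'
#' Computes, for every numeric column, the arithmetic mean (1 decimal, half
#' away from zero), the exact sum, and the min/max with the attaining sample
#' ids. The on-target percentage is summarized as the pooled ratio
#' `sum(on-target) / sum(reads) x 100` (the convention used in published
#' capture summary tables), not as a mean of per-sample percentages.
#'
#' @param stats Sample-statistics tibble from [build_sample_stats()].
#' @return A tibble with one row per column: `column`, `mean`, `sum`,
#'   `min`, `min_sample`, `max`, `max_sample`.
#' @export
summarize_stats <- function(stats) {
  if (nrow(stats) == 0) {
    abort("No sample rows to summarize.", class = "exonbaits_empty_input_error")
  }
  num_cols <- names(stats)[vapply(stats, is.numeric, logical(1))]
  rows <- lapply(num_cols, function(col) {
    v <- stats[[col]]
    if (col == "pct_on_target") {
      m <- round_half_away(sum(stats$n_on_target) / sum(stats$n_reads) * 100, 1)
      s <- NA_real_
    } else {
      m <- round_half_away(mean(v), 1)
      s <- sum(v)
    }
    tibble(
      column = col, mean = m, sum = s,
      min = min(v), min_sample = stats$sample[which.min(v)],
      max = max(v), max_sample = stats$sample[which.max(v)]
    )
  })
  bind_rows(rows)
}

#' Sample-by-locus recovery and paralog matrices
#'
#' @param records Long-format recovery tibble (see [build_sample_stats()]).
#' @param cap Cap recovery fractions at 1.0 for display.
#' @return A list of two matrices (rows = samples in input order, columns =
#'   loci in ascending id order): `recovery` (recovered/target fraction,
#'   missing loci 0.0) and `paralogs` (depth-based paralog flags/counts).
#' @export
recovery_matrix <- function(records, cap = TRUE) {
  samples <- unique(records$sample)
  loci <- sort(unique(records$locus))
  rec <- matrix(0, nrow = length(samples), ncol = length(loci),
                dimnames = list(samples, loci))
  par <- rec
  i <- match(records$sample, samples)
  j <- match(records$locus, loci)
  frac <- records$recovered_len / records$target_len
  if (cap) frac <- pmin(frac, 1.0)
  rec[cbind(i, j)] <- frac
  par[cbind(i, j)] <- records$paralog_depth
  list(recovery = rec, paralogs = par)
}

#' Coefficient of determination of a simple linear trend
#'
#' Ordinary least squares of `y` on `x`; returns `R^2 = 1 - SS_res/SS_tot`
#' to 3 decimals. A constant response returns 0 by convention (no variance
#' to explain); a constant predictor is a degenerate fit and errors.
#'
#' @param x,y Numeric vectors (at least 3 points).
#' @return R-squared, rounded to 3 decimals.
#' @export
linear_r2 <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 3) {
    abort("Need at least 3 points.", class = "exonbaits_data_error")
  }
  if (var(x) == 0) {
    abort("Constant predictor: degenerate fit.",
          class = "exonbaits_degenerate_fit_error")
  }
  if (var(y) == 0) return(0.0)
  fit <- lm(y ~ x)
  # summary() warns on an exactly collinear fit; R^2 = 1 is still well defined
  round(suppressWarnings(summary(fit)$r.squared), 3)
}

#' Fit a recovery-vs-covariate trend
#'
#' Thin wrapper around [stats::lm()] for the usual "does specimen age
#' predict recovery?" question, with [tidy()] and [glance()] methods.
#'
#' @param data A data frame.
#' @param x,y Column names (strings) of predictor and response.
#' @return An object of class `recovery_trend`.
#' @export
fit_recovery_trend <- function(data, x, y) {
  stopifnot(x %in% names(data), y %in% names(data))
  fit <- lm(stats::reformulate(x, y), data = data)
  structure(list(fit = fit, x = x, y = y, n = nrow(data)),
            class = "recovery_trend")
}

#' @export
print.recovery_trend <- function(x, ...) {
  cat(sprintf("<recovery_trend> %s ~ %s (n = %d), R^2 = %.3f\n",
              x$y, x$x, x$n, summary(x$fit)$r.squared))
  invisible(x)
}

#' @rdname fit_recovery_trend
#' @param x A `recovery_trend`.
#' @param ... Unused.
#' @export
tidy.recovery_trend <- function(x, ...) {
  cf <- summary(x$fit)$coefficients
  tibble(
    term = rownames(cf),
    estimate = cf[, "Estimate"],
    std.error = cf[, "Std. Error"],
    statistic = cf[, "t value"],
    p.value = cf[, "Pr(>|t|)"]
  )
}

#' @rdname fit_recovery_trend
#' @export
glance.recovery_trend <- function(x, ...) {
  s <- summary(x$fit)
  tibble(
    r.squared = round(s$r.squared, 3),
    adj.r.squared = s$adj.r.squared,
    sigma = s$sigma,
    nobs = x$n
  )
}

#' Published capture-experiment statistics fixture
#'
#' The per-sample capture-assembly summary for the 23 Astragalean herbarium
#' samples used to validate the 819-exon panel, shipped as a plain-text
#' fixture. Columns follow the [build_sample_stats()] schema.
#'
#' @return A 23-row sample-statistics tibble.
#' @export
astragalean_capture_stats <- function() {
  path <- system.file("extdata", "astragalean_capture_stats.tsv",
                      package = "exonbaits", mustWork = TRUE)
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          check.names = FALSE)
  as_tibble(df)
}
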