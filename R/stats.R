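# Reliability and accuracy statistics: two-way random-effects single-rater
# absolute-agreement ICC -- ICC(2,1) in the Shrout-Fleiss numbering, ICC(A,1)
# in McGraw-Wong -- with its F-based 95% confidence interval, paired
# differences against the reference standard, and the builders for the
# reliability/accuracy summary tables.

#' Intraclass correlation coefficient, two-way random effects, single rater,
#' absolute agreement
#'
#' Computes ICC(2,1) from the two-way ANOVA decomposition
#' `ICC = (MSR - MSE) / (MSR + (k-1) MSE + k (MSC - MSE) / n)` with the
#' McGraw-Wong F-based confidence interval.
#'
#' @param m numeric matrix, subjects x raters, no missing cells, >= 2
#'   subjects and >= 2 raters.
#' @param conf_level confidence level (default 0.95).
#' @return an `icc_result` list: `icc`, `ci_low`, `ci_high`, `design`,
#'   `n_subjects`, `n_raters`, and the mean squares.
#' @export
#' @examples
#' m <- cbind(1:6, 1:6 + 0.1)
#' icc(m)$icc
icc <- function(m, conf_level = 0.95) {
  m <- as.matrix(m)
  if (anyNA(m)) stop("ICC requires complete data (no missing cells)", call. = FALSE)
  n <- nrow(m); k <- ncol(m)
  if (n < 2 || k < 2) stop("ICC needs >= 2 subjects and >= 2 raters", call. = FALSE)
  grand <- mean(m)
  row_m <- rowMeans(m); col_m <- colMeans(m)
  ss_total <- sum((m - grand)^2)
  ss_rows <- k * sum((row_m - grand)^2)
  ss_cols <- n * sum((col_m - grand)^2)
  ss_err <- ss_total - ss_rows - ss_cols
  if (ss_total < 1e-12) stop("zero total variance: ICC undefined", call. = FALSE)
  msr <- ss_rows / (n - 1)
  msc <- ss_cols / (k - 1)
  mse <- ss_err / ((n - 1) * (k - 1))
  val <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)

  # McGraw & Wong (1996) interval for ICC(A,1)
  alpha <- 1 - conf_level
  a <- k * val / (n * (1 - val))
  b <- 1 + k * val * (n - 1) / (n * (1 - val))
  v <- (a * msc + b * mse)^2 /
    ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
  f_l <- stats::qf(1 - alpha / 2, n - 1, v)
  f_u <- stats::qf(1 - alpha / 2, v, n - 1)
  ci_low <- n * (msr - f_l * mse) /
    (f_l * (k * msc + (k * n - k - n) * mse) + n * msr)
  ci_high <- n * (f_u * msr - mse) /
    (k * msc + (k * n - k - n) * mse + n * f_u * msr)
  structure(list(icc = val, ci_low = min(ci_low, val), ci_high = max(ci_high, val),
                 design = "two-way random, single rater, absolute agreement (ICC(2,1))",
                 n_subjects = n, n_raters = k,
                 ms = c(msr = msr, msc = msc, mse = mse),
                 conf_level = conf_level),
            class = "icc_result")
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("<icc_result> ICC(2,1) = %.3f (%d%% CI %.3f to %.3f), %d subjects x %d raters\n",
              x$icc, round(100 * x$conf_level), x$ci_low, x$ci_high,
              x$n_subjects, x$n_raters))
  invisible(x)
}

#' Paired accuracy of a method against the reference standard
#'
#' Mean and range of the method's readings, mean paired difference from the
#' reference, and the paired t statistic with its two-sided p-value.
#'
#' @param readings numeric vector of per-patient method values.
#' @param reference numeric vector of per-patient reference values, paired
#'   by position.
#' @param method method id label.
#' @return an `accuracy_row` list.
#' @export
paired_accuracy <- function(readings, reference, method = "method") {
  if (length(readings) != length(reference)) {
    stop("readings and reference must be paired (equal length)", call. = FALSE)
  }
  n <- length(readings)
  if (n < 2) stop("need >= 2 pairs", call. = FALSE)
  d <- readings - reference
  sd_d <- stats::sd(d)
  if (sd_d < 1e-12) {
    tstat <- 0; p <- 1
  } else {
    tstat <- mean(d) / (sd_d / sqrt(n))
    p <- 2 * stats::pt(-abs(tstat), df = n - 1)
  }
  structure(list(method = method, n = n,
                 mean_deg = mean(readings), range_deg = range(readings),
                 mean_diff_vs_reference_deg = mean(d),
                 t_statistic = tstat, p_value = p),
            class = "accuracy_row")
}

#' @export
print.accuracy_row <- function(x, ...) {
  cat(sprintf("<accuracy_row> %s: mean %.2f (%.2f to %.2f), diff vs reference %+.2f, t = %.2f, p = %.4g\n",
              x$method, x$mean_deg, x$range_deg[1], x$range_deg[2],
              x$mean_diff_vs_reference_deg, x$t_statistic, x$p_value))
  invisible(x)
}

record_matrix <- function(records, method, by = c("observer", "session"),
                          session = NULL, observer = NULL) {
  rec <- records[records$method == method, ]
  if (!is.null(session)) rec <- rec[rec$session == session, ]
  if (!is.null(observer)) rec <- rec[rec$observer == observer, ]
  by <- match.arg(by)
  pats <- sort(unique(rec$patient_id))
  cols <- sort(unique(rec[[by]]))
  out <- matrix(NA_real_, length(pats), length(cols))
  for (j in seq_along(cols)) {
    sub <- rec[rec[[by]] == cols[j], ]
    idx <- match(pats, sub$patient_id)
    if (anyNA(idx) || nrow(sub) != length(pats)) {
      stop("incomplete or duplicated design for method '", method, "'", call. = FALSE)
    }
    out[, j] <- sub$value_deg[idx]
  }
  out
}

methods_present <- function(records) {
  intersect(METHOD_IDS, unique(records$method))
}

#' Intra- and inter-observer reliability per method
#'
#' Intra-observer: for each observer, the subjects x sessions matrix gives
#' an ICC(2,1); these are averaged across observers (point estimate and CI
#' bounds). Inter-observer: the subjects x observers matrix of session-1
#' readings.
#'
#' @param records a measurement record table.
#' @return data frame with one row per method: intra/inter ICCs and CIs.
#' @export
reliability_table <- function(records) {
  methods <- methods_present(records)
  n_obs <- length(unique(records$observer))
  n_ses <- length(unique(records$session))
  out <- lapply(methods, function(m) {
    intra <- c(icc = NA_real_, lo = NA_real_, hi = NA_real_)
    if (n_ses >= 2) {
      per_obs <- lapply(unique(records$observer), function(o) {
        icc(record_matrix(records, m, by = "session", observer = o))
      })
      intra <- c(icc = mean(vapply(per_obs, `[[`, 0, "icc")),
                 lo = mean(vapply(per_obs, `[[`, 0, "ci_low")),
                 hi = mean(vapply(per_obs, `[[`, 0, "ci_high")))
    }
    inter <- c(icc = NA_real_, lo = NA_real_, hi = NA_real_)
    if (n_obs >= 2) {
      ii <- icc(record_matrix(records, m, by = "observer", session = 1))
      inter <- c(icc = ii$icc, lo = ii$ci_low, hi = ii$ci_high)
    }
    data.frame(method = m,
               icc_intra = intra[["icc"]], intra_ci_low = intra[["lo"]],
               intra_ci_high = intra[["hi"]],
               icc_inter = inter[["icc"]], inter_ci_low = inter[["lo"]],
               inter_ci_high = inter[["hi"]],
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  if (n_ses < 2) warning("single session: intra-observer reliability not estimable")
  if (n_obs < 2) warning("single observer: inter-observer reliability not estimable")
  res
}

#' Accuracy table against the reference standard
#'
#' Per-patient method values are the mean over observers and sessions; each
#' method is compared with the reference by a paired t-test (raw two-sided
#' p-values, no multiplicity correction, following the source design).
#'
#' @param records a measurement record table containing a `reference` method.
#' @return data frame with one row per method (reference first).
#' @export
accuracy_table <- function(records) {
  methods <- methods_present(records)
  if (!"reference" %in% methods) {
    stop("records contain no 'reference' method: accuracy table unavailable",
         call. = FALSE)
  }
  per_patient <- function(m) {
    rec <- records[records$method == m, ]
    agg <- stats::aggregate(value_deg ~ patient_id, data = rec, FUN = mean)
    agg[order(agg$patient_id), ]
  }
  ref <- per_patient("reference")
  out <- lapply(methods, function(m) {
    pp <- per_patient(m)
    if (!identical(pp$patient_id, ref$patient_id)) {
      stop("method '", m, "' is missing patients present in the reference",
           call. = FALSE)
    }
    acc <- paired_accuracy(pp$value_deg, ref$value_deg, method = m)
    data.frame(method = m, mean_deg = acc$mean_deg,
               min_deg = acc$range_deg[1], max_deg = acc$range_deg[2],
               mean_diff_vs_reference_deg = acc$mean_diff_vs_reference_deg,
               t_statistic = acc$t_statistic,
               p_value = ifelse(m == "reference", NA_real_, acc$p_value),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Build the reliability and accuracy summary tables
#'
#' Produces the two study-shaped tables (one reliability row-set and one
#' accuracy row per method, reference column first) and optionally writes
#' them as CSV plus a Markdown rendering.
#'
#' @param dataset a `cohort_dataset` (or a record data frame).
#' @param dir optional output directory for `table2_reliability.csv`,
#'   `table3_accuracy.csv` and `tables.md`.
#' @return list with `reliability` and `accuracy` data frames.
#' @export
build_tables <- function(dataset, dir = NULL) {
  records <- if (inherits(dataset, "cohort_dataset")) dataset$records else dataset
  methods <- methods_present(records)
  complete <- expand.grid(method = methods,
                          observer = unique(records$observer),
                          session = unique(records$session),
                          stringsAsFactors = FALSE)
  got <- unique(records[, c("method", "observer", "session")])
  gaps <- merge(complete, cbind(got, present = TRUE), all.x = TRUE)
  gaps <- gaps[is.na(gaps$present), ]
  if (nrow(gaps) > 0) {
    stop("incomplete design; missing cells:\n",
         paste(utils::capture.output(print(gaps[, 1:3])), collapse = "\n"),
         call. = FALSE)
  }
  rel <- reliability_table(records)
  acc <- if ("reference" %in% methods) accuracy_table(records) else {
    warning("reference column absent: accuracy table skipped")
    NULL
  }
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(rel, file.path(dir, "table2_reliability.csv"), row.names = FALSE)
    if (!is.null(acc)) {
      utils::write.csv(acc, file.path(dir, "table3_accuracy.csv"), row.names = FALSE)
    }
    writeLines(render_tables_md(rel, acc), file.path(dir, "tables.md"))
  }
  list(reliability = rel, accuracy = acc)
}

render_tables_md <- function(rel, acc) {
  fmt <- function(x, d = 3) formatC(x, digits = d, format = "f")
  lines <- c("# Statistical comparison (reliability)", "",
             "| method | intra ICC (95% CI) | inter ICC (95% CI) |",
             "|---|---|---|")
  for (i in seq_len(nrow(rel))) {
    r <- rel[i, ]
    lines <- c(lines, sprintf("| %s | %s (%s to %s) | %s (%s to %s) |",
                              r$method, fmt(r$icc_intra), fmt(r$intra_ci_low),
                              fmt(r$intra_ci_high), fmt(r$icc_inter),
                              fmt(r$inter_ci_low), fmt(r$inter_ci_high)))
  }
  if (!is.null(acc)) {
    lines <- c(lines, "", "# Statistical comparison (accuracy)", "",
               "| method | mean anteversion (range) | p value (paired t) |",
               "|---|---|---|")
    for (i in seq_len(nrow(acc))) {
      a <- acc[i, ]
      pv <- if (is.na(a$p_value)) "-" else {
        if (a$p_value < 0.001) "< 0.001" else fmt(a$p_value)
      }
      lines <- c(lines, sprintf("| %s | %s (%s to %s) | %s |",
                                a$method, fmt(a$mean_deg, 2), fmt(a$min_deg, 2),
                                fmt(a$max_deg, 2), pv))
    }
  }
  lines
}
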