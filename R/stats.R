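#' Group summary statistics
#'
#' Per-group descriptive statistics in the layout of an SPSS "group
#' statistics" table: n, mean, sample standard deviation (n - 1 divisor) and
#' standard error of the mean.
#'
#' @param values numeric measurements (n >= 2).
#' @param method group identifier (1 = screw-retained guide,
#'   2 = mucosa-supported, in the packaged study).
#' @return An object of class `group_summary`: list with `method`, `n`,
#'   `mean`, `sd`, `sem`.
#' @export
group_summary <- function(values, method = NA) {
  values <- as.numeric(values)
  if (length(values) < 2 || anyNA(values)) {
    stop("insufficient data: need at least 2 non-missing values",
         call. = FALSE)
  }
  s <- stats::sd(values)
  structure(list(method = method, n = length(values), mean = mean(values),
                 sd = s, sem = s / sqrt(length(values))),
            class = "group_summary")
}

#' @export
print.group_summary <- function(x, ...) {
  cat(sprintf("method %s: n = %d, mean = %.4f, sd = %.4f, sem = %.4f\n",
              as.character(x$method), x$n, x$mean, x$sd, x$sem))
  invisible(x)
}

#' Levene's test for equality of variances (two groups)
#'
#' One-way ANOVA F statistic on the absolute deviations of each observation
#' from its group centre, with p-value from F(1, n1 + n2 - 2). The default
#' centre is the group mean (the SPSS default); `center = "median"` gives
#' the Brown-Forsythe variant.
#'
#' @param g1,g2 numeric vectors (each n >= 2).
#' @param center `"mean"` (default) or `"median"`.
#' @return A list with `F`, `p`, `df1`, `df2` and `center`.
#' @export
levene_test <- function(g1, g2, center = c("mean", "median")) {
  center <- match.arg(center)
  g1 <- as.numeric(g1); g2 <- as.numeric(g2)
  if (length(g1) < 2 || length(g2) < 2 || anyNA(g1) || anyNA(g2)) {
    stop("insufficient data: each group needs at least 2 non-missing values",
         call. = FALSE)
  }
  cf <- if (center == "mean") mean else stats::median
  z1 <- abs(g1 - cf(g1))
  z2 <- abs(g2 - cf(g2))
  n1 <- length(z1); n2 <- length(z2); n <- n1 + n2
  zbar <- mean(c(z1, z2))
  ssb <- n1 * (mean(z1) - zbar)^2 + n2 * (mean(z2) - zbar)^2
  ssw <- sum((z1 - mean(z1))^2) + sum((z2 - mean(z2))^2)
  df2 <- n - 2
  f <- if (ssb <= 0) 0 else (ssb / 1) / (ssw / df2)
  list(F = f, p = stats::pf(f, 1, df2, lower.tail = FALSE),
       df1 = 1, df2 = df2, center = center)
}

#' Independent-samples t test (pooled and Welch)
#'
#' Both rows of an SPSS independent-samples t-test table: the
#' pooled-variance (Student) test and the unpooled Welch test with
#' Welch-Satterthwaite degrees of freedom, each with two-sided p-value,
#' mean difference (`g1 - g2`), standard error of the difference and 95%
#' confidence interval from the corresponding t quantile.
#'
#' @param g1,g2 numeric vectors (each n >= 2).
#' @param conf.level confidence level for the intervals (default 0.95).
#' @return An object of class `ttest_report`: list with `n1`, `n2`,
#'   `mean_difference`, and sub-lists `equal` and `welch`, each holding
#'   `t`, `df`, `p`, `se`, `ci_low`, `ci_high`.
#' @export
t_test_independent <- function(g1, g2, conf.level = 0.95) {
  g1 <- as.numeric(g1); g2 <- as.numeric(g2)
  if (length(g1) < 2 || length(g2) < 2 || anyNA(g1) || anyNA(g2)) {
    stop("insufficient data: each group needs at least 2 non-missing values",
         call. = FALSE)
  }
  if (stats::var(g1) == 0 && stats::var(g2) == 0 && mean(g1) == mean(g2)) {
    stop(errorCondition("t statistic undefined: both groups constant and equal",
                        class = "implacc_undefined_t"))
  }
  eq <- stats::t.test(g1, g2, var.equal = TRUE, conf.level = conf.level)
  we <- stats::t.test(g1, g2, var.equal = FALSE, conf.level = conf.level)
  md <- mean(g1) - mean(g2)
  row <- function(ht) list(t = unname(ht$statistic),
                           df = unname(ht$parameter),
                           p = ht$p.value,
                           se = unname(ht$stderr),
                           ci_low = ht$conf.int[1],
                           ci_high = ht$conf.int[2])
  structure(list(n1 = length(g1), n2 = length(g2), mean_difference = md,
                 conf.level = conf.level, equal = row(eq), welch = row(we)),
            class = "ttest_report")
}

#' @export
print.ttest_report <- function(x, ...) {
  cat(sprintf("mean difference %.4f (n = %d, %d)\n",
              x$mean_difference, x$n1, x$n2))
  for (nm in c("equal", "welch")) {
    r <- x[[nm]]
    cat(sprintf("  %-5s t = %.4f, df = %.2f, p = %.4g, se = %.4f, %d%% CI [%.4f, %.4f]\n",
                nm, r$t, r$df, r$p, r$se, round(100 * x$conf.level),
                r$ci_low, r$ci_high))
  }
  invisible(x)
}

#' Default block-to-method assignment
#'
#' The lower half of the sorted block numbers is method 1, the upper half
#' method 2. For the canonical ten-model study this is the published
#' assignment: blocks 1-5 screw-retained guide (method 1), blocks 6-10
#' mucosa-supported guide (method 2).
#'
#' @param blocks block identifiers present in the data.
#' @return Named integer vector mapping block -> method.
#' @export
default_grouping <- function(blocks = 1:10) {
  b <- sort(unique(as.integer(blocks)))
  stats::setNames(ifelse(b <= b[ceiling(length(b) / 2)], 1L, 2L),
                  as.character(b))
}

#' Two-method comparison for every deviation metric
#'
#' Runs the full statistical comparison on a table of per-implant deviation
#' records: for each metric (coronal deviation A, apical deviation B,
#' angular deviation) it produces both group summaries, the Levene variance
#' screen and the Student/Welch t-test report. Both t-test rows are always
#' computed, regardless of the Levene outcome, as an SPSS table does. A
#' metric whose t statistic is undefined (e.g. all deviations zero) carries
#' an `error` message instead of a test report.
#'
#' @param records data frame with columns `block`, `deviation_a`,
#'   `deviation_b`, `angle_error` (see [compare_implants()],
#'   [read_deviation_table()]).
#' @param grouping named vector mapping block identifier -> method id
#'   (exactly two methods); default [default_grouping()].
#' @param levene_center centre for [levene_test()] (default "mean").
#' @return An object of class `deviation_reports`: a named list (one entry
#'   per metric), each with `metric`, `summaries` (list of two
#'   [group_summary()]), `levene`, `ttest` (or `error`).
#' @examples
#' rep <- build_reports(example_deviation_table())
#' rep$deviation_a$ttest
#' @export
build_reports <- function(records, grouping = NULL,
                          levene_center = c("mean", "median")) {
  levene_center <- match.arg(levene_center)
  metrics <- c("deviation_a", "deviation_b", "angle_error")
  need <- c("block", metrics)
  if (!all(need %in% names(records))) {
    stop("records must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(grouping)) grouping <- default_grouping(unique(records$block))
  bl <- as.character(records$block)
  if (!all(bl %in% names(grouping))) {
    stop("grouping is missing blocks: ",
         paste(unique(bl[!bl %in% names(grouping)]), collapse = ", "),
         call. = FALSE)
  }
  method <- unname(grouping[bl])
  ids <- sort(unique(unname(grouping)))
  if (length(ids) != 2) {
    stop("grouping must define exactly two methods", call. = FALSE)
  }
  out <- lapply(metrics, function(m) {
    x1 <- records[[m]][method == ids[1]]
    x2 <- records[[m]][method == ids[2]]
    entry <- list(metric = m,
                  summaries = list(group_summary(x1, ids[1]),
                                   group_summary(x2, ids[2])),
                  levene = levene_test(x1, x2, center = levene_center))
    tt <- tryCatch(t_test_independent(x1, x2), implacc_undefined_t = identity)
    if (inherits(tt, "condition")) {
      entry$ttest <- NULL
      entry$error <- conditionMessage(tt)
    } else {
      entry$ttest <- tt
    }
    entry
  })
  structure(stats::setNames(out, metrics), class = "deviation_reports")
}

#' @export
print.deviation_reports <- function(x, ...) {
  labels <- c(deviation_a = "Coronal deviation A (mm)",
              deviation_b = "Apical deviation B (mm)",
              angle_error = "Angular deviation (degrees)")
  for (entry in x) {
    cat(labels[[entry$metric]], "\n")
    for (s in entry$summaries) print(s)
    cat(sprintf("  Levene (%s-centred) F = %.4f, p = %.4g\n",
                entry$levene$center, entry$levene$F, entry$levene$p))
    if (!is.null(entry$ttest)) print(entry$ttest) else
      cat("  t test: ", entry$error, "\n")
  }
  invisible(x)
}

metric_labels <- c(deviation_a = "Deviation A (mm)",
                   deviation_b = "Deviation B (mm)",
                   angle_error = "Long Axis Angulation Deviation (Degrees)")

#' Write the group-statistics table
#'
#' Writes the per-metric group summaries of a [build_reports()] result as a
#' CSV in the layout of an SPSS group-statistics table (one row per metric
#' and method: Mean, Std. Deviation, Std. Error Mean).
#'
#' @param reports a `deviation_reports` object.
#' @param path output CSV path.
#' @param digits rounding for the written values (default 2, matching the
#'   published tables); use `NA` for full precision.
#' @return `path`, invisibly.
#' @export
write_group_statistics <- function(reports, path, digits = 2) {
  stopifnot(inherits(reports, "deviation_reports"))
  rows <- do.call(rbind, lapply(reports, function(e) {
    do.call(rbind, lapply(e$summaries, function(s) {
      data.frame(Metric = metric_labels[[e$metric]], Method = s$method,
                 N = s$n, Mean = s$mean, `Std. Deviation` = s$sd,
                 `Std. Error Mean` = s$sem, check.names = FALSE)
    }))
  }))
  if (!is.na(digits)) {
    num <- vapply(rows, is.numeric, logical(1)) & names(rows) != "N"
    rows[num] <- lapply(rows[num], round, digits = digits)
  }
  utils::write.csv(rows, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Write the independent-samples-test table
#'
#' Writes the Levene and t-test results of a [build_reports()] result as a
#' CSV mirroring an SPSS independent-samples-test table: per metric, one
#' "equal variances assumed" and one "equal variances not assumed" row with
#' F, Sig., t, df, two-sided Sig., mean difference, SE difference and the
#' 95% CI bounds.
#'
#' @inheritParams write_group_statistics
#' @return `path`, invisibly.
#' @export
write_independent_samples_test <- function(reports, path, digits = 2) {
  stopifnot(inherits(reports, "deviation_reports"))
  rows <- do.call(rbind, lapply(reports, function(e) {
    if (is.null(e$ttest)) {
      return(data.frame(Metric = metric_labels[[e$metric]],
                        Variances = NA, F = e$levene$F, `Sig.` = e$levene$p,
                        t = NA, df = NA, `Sig. (2-tailed)` = NA,
                        `Mean Difference` = NA, `Std. Error Difference` = NA,
                        Lower = NA, Upper = NA, check.names = FALSE))
    }
    mk <- function(label, r, lev_f, lev_p) {
      data.frame(Metric = metric_labels[[e$metric]], Variances = label,
                 F = lev_f, `Sig.` = lev_p, t = r$t, df = r$df,
                 `Sig. (2-tailed)` = r$p,
                 `Mean Difference` = e$ttest$mean_difference,
                 `Std. Error Difference` = r$se,
                 Lower = r$ci_low, Upper = r$ci_high, check.names = FALSE)
    }
    rbind(mk("Equal variances assumed", e$ttest$equal,
             e$levene$F, e$levene$p),
          mk("Equal variances not assumed", e$ttest$welch, NA, NA))
  }))
  if (!is.na(digits)) {
    num <- vapply(rows, is.numeric, logical(1))
    rows[num] <- lapply(rows[num], round, digits = digits)
  }
  utils::write.csv(rows, path, row.names = FALSE, quote = TRUE, na = "")
  invisible(path)
}
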