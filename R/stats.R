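# Group-comparison statistics: Kolmogorov-Smirnov (Lilliefors) normality
# routing between Student's t and Mann-Whitney U, and linear regression of
# flow parameters against QRS duration.

#' Normality-routed choice of two-group test
#'
#' Tests each group for normality with the one-sample Kolmogorov-Smirnov
#' test against a normal with estimated parameters (Lilliefors correction)
#' at `alpha`. Both groups normal routes to the unpaired Student's t test;
#' otherwise the Mann-Whitney U test is used. Degenerate groups (zero
#' variance) and groups too small for the Lilliefors test (n < 5) cannot be
#' assessed and route to Mann-Whitney with a flag.
#'
#' @param x,y numeric samples for the two groups (n >= 3 each).
#' @param alpha normality-test significance level (default 0.05).
#' @return A list: `test` ("t" or "mwu"), per-group `normal` verdicts,
#'   `ks_p` values, and `flags`.
#' @export
normality_route <- function(x, y, alpha = 0.05) {
  check <- function(v, nm) {
    if (length(v) < 3)
      vf_stop(sprintf("group %s has fewer than 3 observations", nm),
              "vf_stats_error")
    if (sd(v) == 0)
      return(list(normal = FALSE, p = NA_real_,
                  flag = sprintf("%s: zero variance, normality undefined", nm)))
    if (length(v) < 5)
      return(list(normal = FALSE, p = NA_real_,
                  flag = sprintf("%s: n < 5, too small for Lilliefors KS", nm)))
    p <- nortest::lillie.test(v)$p.value
    list(normal = p >= alpha, p = p, flag = NULL)
  }
  cx <- check(x, "1"); cy <- check(y, "2")
  list(test = if (cx$normal && cy$normal) "t" else "mwu",
       normal = c(cx$normal, cy$normal),
       ks_p = c(cx$p, cy$p),
       flags = c(cx$flag, cy$flag),
       alpha = alpha)
}

#' Two-group comparison with normality routing
#'
#' Applies [normality_route()] and then the routed test: pooled-variance
#' unpaired Student's t (Welch by flag) or the Mann-Whitney U test.
#'
#' @param x,y numeric samples.
#' @param welch use Welch's t instead of pooled-variance Student's t when the
#'   t branch is taken.
#' @param alpha normality-routing level.
#' @return A list: `test`, `statistic`, `p_value`, and the routing details.
#' @export
routed_two_group_test <- function(x, y, welch = FALSE, alpha = 0.05) {
  route <- normality_route(x, y, alpha)
  if (route$test == "t") {
    ht <- t.test(x, y, var.equal = !welch)
  } else {
    ht <- suppressWarnings(wilcox.test(x, y, exact = NULL))
  }
  c(list(statistic = unname(ht$statistic), p_value = ht$p.value), route)
}

#' Pooled t test from printed summary statistics
#'
#' Group mean, SD and n are sufficient statistics for the pooled-variance
#' Student's t test, so published tables can be re-tested directly.
#'
#' @param mean1,sd1,n1,mean2,sd2,n2 group summaries.
#' @param welch use the Welch-Satterthwaite approximation instead of pooling.
#' @return A list: `t`, `df`, `p_value`.
#' @examples
#' summary_t_test(7.2, 3.3, 11, 12.0, 4.3, 11) # p ~= 0.008
#' @export
summary_t_test <- function(mean1, sd1, n1, mean2, sd2, n2, welch = FALSE) {
  if (welch) {
    se2 <- sd1^2 / n1 + sd2^2 / n2
    tval <- (mean1 - mean2) / sqrt(se2)
    df <- se2^2 / ((sd1^2 / n1)^2 / (n1 - 1) + (sd2^2 / n2)^2 / (n2 - 1))
  } else {
    sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2)
    tval <- (mean1 - mean2) / sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  }
  list(t = tval, df = df, p_value = 2 * pt(-abs(tval), df))
}

#' Compare all parameters between two groups of subjects
#'
#' Consumes a tidy per-subject table (one row per subject, a `group` column
#' with exactly two levels, numeric parameter columns) and produces one
#' comparison row per parameter: group means and SDs, the normality-routed
#' test, and its two-sided P value.
#'
#' @param table data.frame of subject records.
#' @param parameters character vector of parameter column names; defaults to
#'   all numeric columns except `qrs_duration`.
#' @param group_col name of the group column.
#' @param welch,alpha passed to [routed_two_group_test()].
#' @return A data.frame with one row per parameter.
#' @export
compare_groups <- function(table, parameters = NULL, group_col = "group",
                           welch = FALSE, alpha = 0.05) {
  if (!group_col %in% names(table))
    vf_stop(sprintf("missing column '%s'", group_col), "vf_stats_error")
  groups <- sort(unique(as.character(table[[group_col]])))
  if (length(groups) != 2)
    vf_stop("exactly two groups are required", "vf_stats_error")
  if (is.null(parameters)) {
    num <- vapply(table, is.numeric, logical(1))
    parameters <- setdiff(names(table)[num], c("qrs_duration", "subject"))
  }
  missing_cols <- setdiff(parameters, names(table))
  if (length(missing_cols))
    vf_stop(sprintf("missing parameter column(s): %s",
                    paste(missing_cols, collapse = ", ")), "vf_stats_error")
  rows <- lapply(parameters, function(p) {
    x <- table[[p]][table[[group_col]] == groups[1]]
    y <- table[[p]][table[[group_col]] == groups[2]]
    res <- routed_two_group_test(x, y, welch = welch, alpha = alpha)
    data.frame(parameter = p,
               group1 = groups[1], mean1 = mean(x), sd1 = sd(x), n1 = length(x),
               group2 = groups[2], mean2 = mean(y), sd2 = sd(y), n2 = length(y),
               test = res$test,
               normal1 = res$normal[1], normal2 = res$normal[2],
               p_value = res$p_value,
               p_formatted = format_p_value(res$p_value),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Simple linear regression of a parameter against QRS duration
#'
#' Ordinary least squares of `parameter ~ qrs_duration` over subjects with
#' both values present.
#'
#' @param table data.frame of subject records.
#' @param parameter name of the response column.
#' @param qrs_col name of the QRS-duration column (ms).
#' @return A list: `slope`, `intercept`, `r_squared`, `p_value` (two-sided,
#'   for the slope), `n`.
#' @export
regress_vs_qrs <- function(table, parameter, qrs_col = "qrs_duration") {
  for (cc in c(parameter, qrs_col)) if (!cc %in% names(table))
    vf_stop(sprintf("missing column '%s'", cc), "vf_stats_error")
  ok <- is.finite(table[[parameter]]) & is.finite(table[[qrs_col]])
  if (sum(ok) < 3)
    vf_stop("at least 3 subjects with both values are required",
            "vf_stats_error")
  x <- table[[qrs_col]][ok]; y <- table[[parameter]][ok]
  if (sd(x) == 0)
    vf_stop("zero variance in QRS duration: regression undefined",
            "vf_stats_error")
  fit <- lm(y ~ x)
  sm <- summary(fit)
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       r_squared = sm$r.squared,
       p_value = unname(sm$coefficients[2, 4]),
       n = sum(ok))
}

#' Format a P value the way clinical tables print it
#'
#' Three decimals, `"< 0.001"` below that.
#'
#' @param p numeric P value.
#' @return Character.
#' @export
format_p_value <- function(p) {
  ifelse(p < 0.001, "< 0.001", sprintf("%.3f", p))
}
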