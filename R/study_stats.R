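#' Validate a long-format study table
#'
#' A study table has one row per (sheep, lung, timepoint, variable)
#' measurement, with lung labelled `Rx` (radio-exposed) or `CON`
#' (contralateral control).
#'
#' @param table data.frame with columns `sheep_id`, `lung_label`,
#'   `timepoint_days`, `variable_name`, `value`.
#' @return The validated data.frame (invisibly classed `study_table`).
#' @export
study_table <- function(table) {
  need <- c("sheep_id", "lung_label", "timepoint_days", "variable_name",
            "value")
  if (!all(need %in% names(table)))
    stop("study_table: missing columns: ",
         paste(setdiff(need, names(table)), collapse = ", "))
  if (!all(table$lung_label %in% c("Rx", "CON")))
    stop("study_table: lung_label must be 'Rx' or 'CON'")
  key <- interaction(table$sheep_id, table$lung_label, table$timepoint_days,
                     table$variable_name, drop = TRUE)
  if (anyDuplicated(key))
    stop("study_table: duplicate (sheep, lung, timepoint, variable) rows")
  class(table) <- unique(c("study_table", class(table)))
  table
}

#' Paired-lung differences (Rx minus CON)
#'
#' Expresses each variable as the within-animal difference between the
#' radio-exposed and contralateral control lung, removing between-animal
#' variation. Rows without a measurement from both lungs are dropped with a
#' warning.
#'
#' @param table a [study_table()].
#' @return data.frame with columns `sheep_id`, `timepoint_days`,
#'   `variable_name`, `diff_value` (= Rx - CON).
#' @export
rx_con_difference <- function(table) {
  table <- study_table(table)
  rx <- table[table$lung_label == "Rx", ]
  con <- table[table$lung_label == "CON", ]
  m <- merge(rx[c("sheep_id", "timepoint_days", "variable_name", "value")],
             con[c("sheep_id", "timepoint_days", "variable_name", "value")],
             by = c("sheep_id", "timepoint_days", "variable_name"),
             suffixes = c("_rx", "_con"))
  n_unpaired <- nrow(rx) + nrow(con) - 2L * nrow(m)
  if (nrow(m) == 0L) stop("rx_con_difference: no paired Rx/CON rows")
  if (n_unpaired > 0L)
    warning("rx_con_difference: dropped ", n_unpaired, " unpaired row(s)")
  out <- data.frame(sheep_id = m$sheep_id,
                    timepoint_days = m$timepoint_days,
                    variable_name = m$variable_name,
                    diff_value = m$value_rx - m$value_con)
  out[order(out$variable_name, out$sheep_id, out$timepoint_days), ,
      drop = FALSE]
}

#' Map study days to study phases
#'
#' The longitudinal design has three occasions per animal: baseline
#' (before irradiation), acute (~3 weeks after), and chronic (just before
#' necropsy, whose exact day varies by animal, e.g. d171 or d227). Pooling
#' days into phases makes the repeated-measures design balanced.
#'
#' @param timepoint_days numeric study days.
#' @param acute_max latest day still counted as acute (default 90).
#' @return Ordered factor with levels baseline < acute < chronic.
#' @export
study_phase <- function(timepoint_days, acute_max = 90) {
  factor(ifelse(timepoint_days < 0, "baseline",
                ifelse(timepoint_days <= acute_max, "acute", "chronic")),
         levels = c("baseline", "acute", "chronic"), ordered = TRUE)
}

ks_reject <- function(x, alpha = 0.05) {
  ok <- length(unique(x)) > 1L && length(x) >= 4L
  ok && ks_normality(x)$p_value < alpha
}

#' Repeated-measures ANOVA on paired-lung differences
#'
#' Two-way balanced partition of the Rx-CON differences into time, sheep
#' (random blocking factor) and error sums of squares, computed in closed
#' form. The time effect is tested with `F = MS_time / MS_error` on
#' `(t - 1, (t - 1)(s - 1))` degrees of freedom. Requires a complete
#' balanced design (every sheep measured at every timepoint). When
#' `transform = "auto"`, a `log10(x - min + 1)` transform is applied first
#' if a Kolmogorov-Smirnov test rejects normality at 0.05; the decision is
#' recorded in the result.
#'
#' @param diffs data.frame from [rx_con_difference()].
#' @param variable variable to analyse (defaults to the only one present).
#' @param transform `"auto"`, `"none"`, or `"log"`.
#' @param time_factor `"phase"` pools study days into
#'   baseline/acute/chronic via [study_phase()] (the necropsy day varies by
#'   animal, so raw days are unbalanced); `"days"` uses the raw days.
#' @return An `anova_result`: list with `table` (df/SS/MS per term),
#'   `f_value`, `p_value`, `df`, `transform_applied`.
#' @export
rm_anova <- function(diffs, variable = NULL,
                     transform = c("auto", "none", "log"),
                     time_factor = c("phase", "days")) {
  transform <- match.arg(transform)
  time_factor <- match.arg(time_factor)
  if (!is.null(variable)) diffs <- diffs[diffs$variable_name == variable, ]
  if (length(unique(diffs$variable_name)) > 1L)
    stop("rm_anova: several variables present; pick one with `variable`")
  sheep <- factor(diffs$sheep_id)
  time <- if (time_factor == "phase")
    factor(study_phase(diffs$timepoint_days), ordered = FALSE)
  else factor(diffs$timepoint_days)
  s <- nlevels(sheep); t <- nlevels(time)
  if (s < 2L || t < 2L) stop("rm_anova: need >= 2 sheep and >= 2 timepoints")
  if (nrow(diffs) != s * t || anyDuplicated(interaction(sheep, time)))
    stop("rm_anova: design must be balanced and complete ",
         "(every sheep at every timepoint, once)")
  y <- diffs$diff_value
  applied <- "none"
  if (transform == "log" || (transform == "auto" && ks_reject(y))) {
    y <- log10(y - min(y) + 1)
    applied <- "log"
  }
  gm <- mean(y)
  t_means <- tapply(y, time, mean)
  s_means <- tapply(y, sheep, mean)
  ss_time <- s * sum((t_means - gm)^2)
  ss_sheep <- t * sum((s_means - gm)^2)
  ss_total <- sum((y - gm)^2)
  ss_error <- ss_total - ss_time - ss_sheep
  df_time <- t - 1L; df_sheep <- s - 1L; df_error <- df_time * df_sheep
  ms_time <- ss_time / df_time
  ms_error <- ss_error / df_error
  f <- if (ms_error > 0) ms_time / ms_error else {
    if (ss_time == 0) 0 else NA_real_
  }
  p <- if (is.na(f)) NA_real_ else stats::pf(f, df_time, df_error,
                                             lower.tail = FALSE)
  structure(list(
    table = data.frame(
      term = c("time", "sheep", "error"),
      df = c(df_time, df_sheep, df_error),
      ss = c(ss_time, ss_sheep, ss_error),
      ms = c(ms_time, ss_sheep / df_sheep, ms_error)),
    f_value = f, p_value = p, df = c(df_time, df_error),
    transform_applied = applied), class = "anova_result")
}

#' One-way ANOVA across named groups
#'
#' Standard between/within partition, delegated to a linear-model fit.
#' Used to compare subject-level histologic indices between the chronic
#' Rx lung, the chronic CON lung, and archived acute-cohort control lungs.
#'
#' @param groups named list of numeric vectors (>= 2 groups, each n >= 2).
#' @return An `anova_result` (see [rm_anova()]); `f_value` is `NA` when all
#'   values are identical (zero variance everywhere).
#' @export
one_way_anova <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2L)
  if (any(vapply(groups, length, 1L) < 2L))
    stop("one_way_anova: every group needs n >= 2")
  y <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names(groups) %||% seq_along(groups),
                  vapply(groups, length, 1L)))
  tab <- stats::anova(stats::lm(y ~ g))
  ss_b <- tab$`Sum Sq`[1]; ss_w <- tab$`Sum Sq`[2]
  f <- tab$`F value`[1]; p <- tab$`Pr(>F)`[1]
  if (ss_w == 0 && ss_b == 0) { f <- NA_real_; p <- NA_real_ }
  structure(list(
    table = data.frame(term = c("between", "within"), df = tab$Df,
                       ss = tab$`Sum Sq`, ms = tab$`Mean Sq`),
    f_value = f, p_value = p, df = tab$Df,
    transform_applied = "none"), class = "anova_result")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.anova_result <- function(x, ...) {
  print(x$table, row.names = FALSE)
  cat(sprintf("F(%d, %d) = %.4g, p = %.4g (transform: %s)\n",
              x$df[1], x$df[2], x$f_value, x$p_value, x$transform_applied))
  invisible(x)
}

#' Pearson product-moment correlation
#'
#' @param x,y paired numeric vectors (n >= 3, both with nonzero variance).
#' @return List: `r`, `p_value` (two-sided, via the t distribution), `n`.
#' @export
pearson_correlation <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("pearson_correlation: need n >= 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(r = NA_real_, p_value = NA_real_, n = length(x),
                degenerate = TRUE))
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value, n = length(x),
       degenerate = FALSE)
}

#' One-sample Kolmogorov-Smirnov normality test
#'
#' Tests the sample against a normal distribution with the sample mean and
#' SD. Because the parameters are estimated from the same data, the p-value
#' is conservative; `params_estimated = TRUE` flags this.
#'
#' @param values numeric vector, n >= 4.
#' @return List: `statistic`, `p_value`, `n`, `params_estimated`,
#'   `degenerate` (constant sample).
#' @export
ks_normality <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) < 4L) stop("ks_normality: need n >= 4")
  if (length(unique(values)) == 1L)
    return(list(statistic = NA_real_, p_value = NA_real_, n = length(values),
                params_estimated = TRUE, degenerate = TRUE))
  kt <- suppressWarnings(
    stats::ks.test(values, "pnorm", mean(values), stats::sd(values)))
  list(statistic = unname(kt$statistic), p_value = kt$p.value,
       n = length(values), params_estimated = TRUE, degenerate = FALSE)
}
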