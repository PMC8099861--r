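# Plan-summary metrics: PTV-to-lung volume fraction and planning-goal
# checks against the prescription constraints.

round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

check_plan_records <- function(records) {
  need <- c("sheep_id", "ptv_cm3", "ll_vol_cm3", "rl_vol_cm3")
  if (!all(need %in% names(records)))
    stop("plan records missing columns: ",
         paste(setdiff(need, names(records)), collapse = ", "))
  vols <- c("ctv_cm3", "ptv_cm3", "ll_vol_cm3", "rl_vol_cm3")
  vols <- intersect(vols, names(records))
  if (any(unlist(records[vols]) <= 0)) stop("plan volumes must be > 0")
  for (s in c("ctv", "ptv", "ll", "rl", "rmb")) {
    cols <- paste0(s, c("_min_gy", "_mean_gy", "_max_gy"))
    if (all(cols %in% names(records))) {
      if (any(records[[cols[1]]] > records[[cols[2]]] |
              records[[cols[2]]] > records[[cols[3]]]))
        stop("plan record violates min <= mean <= max for ", s)
    }
  }
  invisible(records)
}

#' PTV volume as a percentage of total lung volume
#'
#' Total lung volume is taken as the sum of the left and right lung
#' volumes. The plan constraint is that this fraction stays below 15%.
#'
#' @param records plan-record data.frame (see [table1()]).
#' @param digits decimal places for half-up rounding; `NULL` for the exact
#'   value.
#' @return Numeric vector of percentages, named by sheep.
#' @export
ptv_lung_fraction <- function(records, digits = 1) {
  check_plan_records(records)
  total <- records$ll_vol_cm3 + records$rl_vol_cm3
  if (any(total <= 0)) stop("ptv_lung_fraction: zero total lung volume")
  pct <- 100 * records$ptv_cm3 / total
  if (!is.null(digits)) pct <- round_half_up(pct, digits)
  stats::setNames(pct, records$sheep_id)
}

#' Cohort summary of the PTV/lung-volume fraction
#'
#' Mean and range of the per-sheep PTV fractions, computed from exact
#' volumes and rounded (half-up, one decimal) only at the end.
#'
#' @param records plan-record data.frame.
#' @return List: `mean_pct`, `min_pct`, `max_pct`, `per_sheep_pct`.
#' @export
cohort_summary <- function(records) {
  stopifnot(nrow(records) >= 1L)
  pct <- ptv_lung_fraction(records, digits = NULL)
  list(mean_pct = round_half_up(mean(pct), 1),
       min_pct = round_half_up(min(pct), 1),
       max_pct = round_half_up(max(pct), 1),
       per_sheep_pct = round_half_up(pct, 1))
}

#' Check a radiotherapy plan against the planning goals
#'
#' Evaluates, per sheep: mean PTV dose > 29 Gy; mean right-lung dose
#' < 1 Gy; right-lung V1 (volume receiving >= 1 Gy) < 10%; maximum right
#' mainstem bronchus dose <= 1 Gy (with 0.05 Gy rounding tolerance, since
#' the table reports one decimal); PTV < 15% of total lung volume. The
#' 95%-of-PTV-covered-by-27-Gy goal needs the dose-volume histogram, which
#' the summary table does not contain, so it is reported as not evaluable.
#'
#' @param records plan-record data.frame.
#' @return data.frame with one row per (sheep, goal): `sheep_id`, `goal`,
#'   `threshold`, `observed`, `pass` (`NA` = not evaluable).
#' @export
check_planning_goals <- function(records) {
  check_plan_records(records)
  frac <- ptv_lung_fraction(records, digits = NULL)
  one <- function(sheep, goal, threshold, observed, pass)
    data.frame(sheep_id = sheep, goal = goal, threshold = threshold,
               observed = observed, pass = pass)
  out <- NULL
  for (i in seq_len(nrow(records))) {
    r <- records[i, ]
    out <- rbind(
      out,
      one(r$sheep_id, "ptv_mean_gt_29gy", 29, r$ptv_mean_gy,
          r$ptv_mean_gy > 29),
      one(r$sheep_id, "rl_mean_lt_1gy", 1, r$rl_mean_gy, r$rl_mean_gy < 1),
      one(r$sheep_id, "rl_v1_lt_10pct", 10, r$rl_v1_pct, r$rl_v1_pct < 10),
      one(r$sheep_id, "rmb_max_le_1gy", 1, r$rmb_max_gy,
          r$rmb_max_gy <= 1 + 0.05),
      one(r$sheep_id, "ptv_lung_fraction_lt_15pct", 15, unname(frac[i]),
          frac[i] < 15),
      one(r$sheep_id, "ptv_95pct_covered_by_27gy", 27, NA_real_, NA))
  }
  rownames(out) <- NULL
  out
}
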