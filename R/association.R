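# Dyadic analysis table and grouped Spearman rank correlations between the
# (square-root transformed) duration a focal animal spent with each
# satellite and a dyadic covariate (MHCpat by default), with the
# t-approximation for the two-sided p-value.

#' Build the dyadic analysis table
#'
#' Joins per-dyad satellite dwell durations with dyadic covariates and focal
#' grouping labels: sex, paternal population background (`xF`/`xG`, the
#' second letter of the cross code) and purity (`pure` for FF/GG, `mixed`
#' for FG/GF). Durations are square-root transformed (the transform used
#' for the correlation analysis; Spearman r itself is rank-based and
#' unaffected).
#'
#' @param durations Tibble with one row per (focal, satellite): `focal_id`,
#'   `satellite_id`, `hours`.
#' @param covariates Tibble of dyadic covariates as from
#'   [dyadic_covariates()] (keyed by `focal_id`, `satellite_id`).
#' @param cohort Cohort tibble supplying `sex` and `cross` per focal id.
#' @return Tibble of dyad records with `sqrt_hours`, covariates and group
#'   labels; rows with a missing correlation covariate are kept but flagged
#'   (`covariate_missing`).
#' @export
build_dyad_table <- function(durations, covariates, cohort) {
  need <- c("focal_id", "satellite_id", "hours")
  if (!all(need %in% names(durations))) {
    abort("`durations` needs columns focal_id, satellite_id, hours")
  }
  covariates <- covariates[, setdiff(names(covariates), c("hours", "sqrt_hours"))]
  out <- durations |>
    left_join(covariates, by = c("focal_id", "satellite_id")) |>
    left_join(cohort |> select("id", focal_sex = "sex", focal_cross = "cross"),
              by = c(focal_id = "id")) |>
    mutate(
      sqrt_hours = sqrt(.data$hours),
      paternal_bg = paste0("x", substr(.data$focal_cross, 2, 2)),
      purity = ifelse(.data$focal_cross %in% c("FF", "GG"), "pure", "mixed"),
      covariate_missing = is.na(.data$mhc_pat)
    )
  n_missing <- sum(out$covariate_missing)
  if (n_missing > 0) {
    warn(sprintf("%d dyad(s) have a missing MHCpat covariate and will be excluded from correlations",
                 n_missing))
  }
  out
}

#' Spearman rank correlation coefficient
#'
#' Pearson correlation of mid-ranks (average ranks on ties).
#'
#' @param x,y Numeric vectors of equal length, n >= 3.
#' @return r in \[-1, 1\], or `NA` when either variable has zero rank
#'   variance.
#' @export
spearman_r <- function(x, y) {
  if (length(x) != length(y)) abort("`x` and `y` must have equal length")
  if (length(x) < 3) abort("need n >= 3 pairs")
  if (length(unique(x)) < 2 || length(unique(y)) < 2) return(NA_real_)
  cor(x, y, method = "spearman")
}

#' t statistic for a Spearman coefficient
#'
#' `t = r * sqrt(df / (1 - r^2))` with `df = n - 2`.
#'
#' @param r Correlation coefficient.
#' @param n Number of pairs (n >= 3).
#' @return One-row tibble (`t`, `df`); `|r| = 1` yields infinite t.
#' @export
t_from_r <- function(r, n) {
  if (!is.numeric(n) || n < 3) abort("need n >= 3")
  df <- n - 2
  t <- if (abs(r) >= 1) sign(r) * Inf else r * sqrt(df / (1 - r^2))
  tibble(t = t, df = df)
}

#' Two-sided p-value from a central t statistic
#'
#' @param t Statistic.
#' @param df Degrees of freedom (>= 1).
#' @return `2 * (1 - F_t(|t|; df))`.
#' @export
p_two_sided <- function(t, df) {
  if (any(df < 1)) abort("`df` must be >= 1")
  2 * pt(abs(t), df, lower.tail = FALSE)
}

#' Grouped Spearman correlations of dwell time with a dyadic covariate
#'
#' For each group of dyad records, the Spearman correlation between the
#' square-root transformed duration and the covariate, the t-approximation
#' `t = r * sqrt((n - 2) / (1 - r^2))` and its two-sided p. Records with a
#' missing covariate are excluded (exclusion counts are reported). Groups
#' below the minimum size get an `NA` row rather than a fragile estimate.
#'
#' @param records Dyad table from [build_dyad_table()].
#' @param grouping One of `"all"`, `"purity"` (pure vs mixed) or
#'   `"sex_paternal"` (sex x paternal population background).
#' @param covariate Name of the covariate column (default `"mhc_pat"`).
#' @param min_n Minimum usable records per group (default 5).
#' @return Tibble with `group`, `r`, `t`, `df`, `p`, `n`, `n_excluded`.
#' @export
grouped_correlations <- function(records, grouping = c("all", "purity", "sex_paternal"),
                                 covariate = "mhc_pat", min_n = 5) {
  grouping <- match.arg(grouping)
  if (!covariate %in% names(records)) {
    abort(sprintf("covariate column '%s' not found", covariate))
  }
  records$group <- switch(
    grouping,
    all = "All mice",
    purity = ifelse(records$purity == "pure",
                    "Pure population background", "Mixed population background"),
    sex_paternal = paste0(records$paternal_bg, " ",
                          ifelse(records$focal_sex == "F", "females", "males"))
  )
  lev <- switch(grouping,
                all = "All mice",
                purity = c("Pure population background", "Mixed population background"),
                sex_paternal = c("xF females", "xG females", "xF males", "xG males"))
  purrr::map_dfr(lev, function(g) {
    sub <- records[records$group == g, , drop = FALSE]
    x <- sub[["sqrt_hours"]]
    y <- sub[[covariate]]
    ok <- !is.na(x) & !is.na(y)
    n <- sum(ok)
    if (n < max(min_n, 3)) {
      return(tibble(group = g, r = NA_real_, t = NA_real_, df = NA_real_,
                    p = NA_real_, n = n, n_excluded = nrow(sub) - n))
    }
    r <- spearman_r(x[ok], y[ok])
    if (is.na(r)) {
      return(tibble(group = g, r = NA_real_, t = NA_real_, df = n - 2,
                    p = NA_real_, n = n, n_excluded = nrow(sub) - n))
    }
    td <- t_from_r(r, n)
    tibble(group = g, r = r, t = td$t, df = td$df,
           p = p_two_sided(td$t, td$df), n = n,
           n_excluded = nrow(sub) - n)
  })
}
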