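#' Lap-to-lap drift
#'
#' Physiological drift (HR, VO2, TSI) is the difference in lap means, lap 7
#' minus lap 2 -- lap 1 is skipped as baseline to compensate for the delayed
#' kinetic response when starting from rest. Kinetic/kinematic drift (power,
#' CL, CR) uses lap 7 minus lap 1, since breaks are already excluded there
#' by the sub-technique labelling. Significance is a two-sided paired t-test
#' across skiers.
#'
#' @param lap_means matrix or data.frame, skiers x laps (7 columns)
#' @param kind `"physiological"` (baseline lap 2) or `"kinematic"`
#'   (baseline lap 1)
#' @return list: `drift` (mean difference), `per_skier`, `p`
#' @export
lap_drift <- function(lap_means, kind = c("physiological", "kinematic")) {
  kind <- match.arg(kind)
  lap_means <- as.matrix(lap_means)
  if (anyNA(lap_means)) stop("missing lap means")
  if (ncol(lap_means) < 7) stop("need all 7 lap means")
  base <- if (kind == "physiological") 2 else 1
  d <- lap_means[, 7] - lap_means[, base]
  p <- if (nrow(lap_means) < 2 || stats::sd(d) == 0) {
    if (all(d == d[1]) && d[1] == 0) 1 else NA_real_
  } else {
    stats::t.test(lap_means[, 7], lap_means[, base], paired = TRUE)$p.value
  }
  list(drift = mean(d), per_skier = d, p = p)
}

#' Between-segment contrasts
#'
#' One-way ANOVA over per-skier segment means with Tukey's HSD post hoc
#' test; the caller excludes lap 1 before averaging (delayed kinetics).
#'
#' @param seg_means data.frame with columns `skier`, `segment`, `value`
#' @return list: `f`, `p`, `tukey` (pairwise table)
#' @export
segment_contrasts <- function(seg_means) {
  stopifnot(all(c("segment", "value") %in% names(seg_means)))
  if (length(unique(seg_means$segment)) < 2)
    stop("need at least two segments")
  fit <- stats::aov(value ~ factor(segment), data = seg_means)
  an <- summary(fit)[[1]]
  tk <- stats::TukeyHSD(fit)[[1]]
  list(f = an[1, "F value"], p = an[1, "Pr(>F)"],
       tukey = data.frame(pair = rownames(tk), diff = tk[, "diff"],
                          p_adj = tk[, "p adj"], row.names = NULL))
}

#' Spearman rank correlation with magnitude label
#'
#' Ties get mid-ranks; the coefficient is the Pearson correlation of the
#' two rank vectors (the convention of standard statistical packages). The
#' p-value uses the t approximation on the rank correlation.
#'
#' @param x,y equal-length numeric vectors, n >= 3
#' @return list of class `correlation_result`: `coefficient`, `p_value`,
#'   `n`, `method`, `magnitude`
#' @export
spearman_cor <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]
  y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(correlation_result(NA_real_, NA_real_, n, "spearman"))
  r <- stats::cor(rank(x), rank(y))
  correlation_result(r, t_approx_p(r, n), n, "spearman")
}

#' Pearson correlation (TTE analysis of the no-break subset)
#'
#' Used between TTE and the other variables for the skiers who completed
#' the whole initial part without breaks; incomplete pairs (e.g. missing
#' power data) are deleted pairwise.
#'
#' @inheritParams spearman_cor
#' @export
pearson_cor <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]
  y <- y[ok]
  n <- length(x)
  if (n < 3)
    return(correlation_result(NA_real_, NA_real_, n, "pearson"))
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(correlation_result(NA_real_, NA_real_, n, "pearson"))
  ct <- stats::cor.test(x, y, method = "pearson")
  correlation_result(unname(ct$estimate), ct$p.value, n, "pearson")
}

correlation_result <- function(r, p, n, method) {
  structure(list(coefficient = r, p_value = p, n = n, method = method,
                 magnitude = if (is.na(r)) NA_character_
                             else magnitude_label(r)),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("%s correlation: r = %.3f (%s), p = %.4f, n = %d%s\n",
              x$method, x$coefficient, x$magnitude, x$p_value, x$n,
              significance_band(x$p_value)))
  invisible(x)
}

t_approx_p <- function(r, n) {
  if (abs(r) >= 1) return(0)
  tt <- r * sqrt((n - 2) / (1 - r^2))
  2 * stats::pt(-abs(tt), df = n - 2)
}

#' Magnitude label for a correlation coefficient
#'
#' Bands on the absolute value: trivial < 0.1, small < 0.3, moderate < 0.5,
#' large < 0.7, very large < 0.9, extremely large up to 1.
#'
#' @param r correlation coefficient, |r| <= 1
#' @export
magnitude_label <- function(r) {
  if (is.na(r) || abs(r) > 1 + 1e-12) stop("|r| must be <= 1")
  a <- abs(r)
  if (a < 0.1) "trivial"
  else if (a < 0.3) "small"
  else if (a < 0.5) "moderate"
  else if (a < 0.7) "large"
  else if (a < 0.9) "very large"
  else "extremely large"
}

# alpha = 0.05; 0.05-0.10 is reported as a trend
significance_band <- function(p) {
  if (is.na(p)) ""
  else if (p < 0.05) " *"
  else if (p < 0.10) " (trend)"
  else ""
}

#' Performance-correlation battery on the embedded summary tables
#'
#' Recomputes the Spearman correlations between performance rank and the
#' per-skier summary variables, plus the Pearson correlations between TTE
#' and the same variables for the nine skiers without breaks, and the
#' cohort means. The peak-reserve variables (`hr_reserve`, `vo2_reserve`)
#' are the raw differences between the peak reached in the AOS and in the
#' initial part (bpm, mL/min/kg): individual HRMax is not part of the
#' summary tables, and rank correlations of the max-normalised VO2 variant
#' differ by about 0.01 because the printed inputs are rounded to one
#' decimal.
#'
#' @param summaries output of [skier_summaries()] (default: the embedded
#'   tables)
#' @param reserve `"raw"` (default) for raw peak differences, or
#'   `"normalized"` to express the VO2 reserve as percent of personal
#'   VO2Max (its rank correlation differs by about 0.01 from the raw
#'   variant because the table inputs carry one decimal)
#' @return list with `spearman` (data.frame: variable, coefficient,
#'   p_value, n, magnitude), `pearson_tte` (same for the no-break subset)
#'   and `cohort_means`
#' @export
reproduce_correlations <- function(summaries = skier_summaries(),
                                   reserve = c("raw", "normalized")) {
  reserve <- match.arg(reserve)
  s <- summaries
  s$hr_reserve <- s$peak_hr_aos - s$peak_hr_ip
  s$vo2_reserve <- s$peak_vo2_aos - s$peak_vo2_ip
  if (reserve == "normalized")
    s$vo2_reserve <- 100 * s$vo2_reserve / s$vo2max
  vars <- c("pct_hrmax_ip", "pct_vo2max_ip", "vo2_ip", "rpe_ip", "bla_aos",
            "tsi_arm_ip", "tsi_leg_ip", "hr_reserve", "vo2_reserve",
            "vo2max", "ge_g2", "ge_g3", "ge_g4", "ge_oa",
            "g2_ip", "g3_ip", "g4_ip",
            "p_cycle_ip", "pct_pole_ip", "pct_pole_left_ip",
            "cl_aos", "cr_aos")
  sp <- do.call(rbind, lapply(vars, function(v) {
    r <- spearman_cor(s$rank, s[[v]])
    data.frame(variable = v, coefficient = r$coefficient,
               p_value = r$p_value, n = r$n, magnitude = r$magnitude,
               stringsAsFactors = FALSE)
  }))
  g1 <- s[s$breaks == 0, ]
  pe <- do.call(rbind, lapply(vars, function(v) {
    r <- pearson_cor(g1$tte, g1[[v]])
    data.frame(variable = v, coefficient = r$coefficient,
               p_value = r$p_value, n = r$n, magnitude = r$magnitude,
               stringsAsFactors = FALSE)
  }))
  list(spearman = sp, pearson_tte = pe,
       cohort_means = c(vo2max = mean(s$vo2max),
                        ge_oa = mean(s$ge_oa),
                        tte = mean(s$tte)))
}
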