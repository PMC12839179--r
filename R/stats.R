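# Condition comparison: baseline (BL), exoskeleton without actuation
# (EXO-NA), and two chosen exoskeleton settings (EXO-S1, EXO-S2), over the
# cohort of foot contacts.

CONDITION_LEVELS <- c("BL", "EXO-NA", "EXO-S1", "EXO-S2")

#' Assemble a paired condition table
#'
#' @param bl,exo_na,exo_s1,exo_s2 Numeric vectors of per-contact energy
#'   expenditure [J/kg]; equal lengths (paired foot contacts).
#' @return A long data frame of class `condition_table` with columns
#'   `condition` (factor), `contact` and `energy_per_kg`.
#' @export
condition_table <- function(bl, exo_na, exo_s1, exo_s2) {
  vals <- list(bl, exo_na, exo_s1, exo_s2)
  n <- unique(lengths(vals))
  if (length(n) != 1L) stop_invalid("conditions must have equal n (paired)")
  if (!all(vapply(vals, function(v) all(is.finite(v)), logical(1L)))) {
    stop_invalid("condition values must be finite")
  }
  out <- data.frame(
    condition = factor(rep(CONDITION_LEVELS, each = n),
                       levels = CONDITION_LEVELS),
    contact = rep(seq_len(n), times = 4L),
    energy_per_kg = unlist(vals)
  )
  class(out) <- c("condition_table", "data.frame")
  out
}

#' Extract the condition table from a sweep result
#'
#' EXO-S1 and EXO-S2 default to the two settings reported as the first and
#' second energy minima of the source study: 5.5 kN/m at 15\% of stance and
#' 12 kN/m at 25\% of stance.
#'
#' @param result A `sweep_result`.
#' @param s1,s2 Length-2 vectors `c(stiffness_k, timing_tau)` naming the
#'   grid cells for EXO-S1 and EXO-S2.
#' @return A [condition_table()].
#' @export
conditions_from_sweep <- function(result, s1 = c(5500, 15),
                                  s2 = c(12000, 25)) {
  pick <- function(s) {
    rows <- result$per_contact$stiffness_k == s[1L] &
      result$per_contact$timing_tau == s[2L]
    if (!any(rows)) {
      stop_invalid("setting (%g N/m, %g%%) is not a grid cell", s[1L], s[2L])
    }
    d <- result$per_contact[rows, ]
    d$energy_per_kg[order(d$contact)]
  }
  condition_table(
    bl = result$baseline_per_contact,
    exo_na = result$no_actuation_per_contact,
    exo_s1 = pick(s1),
    exo_s2 = pick(s2)
  )
}

#' Shapiro-Wilk normality check
#'
#' Delegates to [stats::shapiro.test()].
#'
#' @param values Numeric sample, 3 <= n <= 50, non-constant.
#' @return A list with `W` and `p`.
#' @export
normality_check <- function(values) {
  n <- length(values)
  if (n < 3 || n > 50) stop_invalid("sample size must be in [3, 50]")
  if (stats::sd(values) == 0) stop_invalid("sample is constant (zero variance)")
  t <- stats::shapiro.test(values)
  list(W = unname(t$statistic), p = t$p.value)
}

#' One-way analysis of variance across conditions
#'
#' Classical between/within decomposition (`F = MS_between / MS_within`),
#' delegated to [stats::oneway.test()] with equal variances.
#'
#' @param table A [condition_table()] (or any data frame with `condition`
#'   and `energy_per_kg` columns).
#' @return A list with `F`, `df_between`, `df_within` and `p`.
#' @export
anova_oneway <- function(table) {
  if (nlevels(droplevels(table$condition)) < 2L) {
    stop_invalid("need at least 2 conditions")
  }
  t <- stats::oneway.test(energy_per_kg ~ condition, data = table,
                          var.equal = TRUE)
  list(
    F = unname(t$statistic),
    df_between = unname(t$parameter[["num df"]]),
    df_within = unname(t$parameter[["denom df"]]),
    p = t$p.value
  )
}

#' Tukey honestly-significant-difference post hoc comparisons
#'
#' All pairwise condition comparisons on the studentized-range
#' distribution, using the ANOVA's within-group mean square (delegated to
#' [stats::TukeyHSD()]).
#'
#' @param table A [condition_table()].
#' @param alpha Family-wise significance level (default 0.05).
#' @return A data frame with one row per pair: `pair`, `difference`
#'   (difference of means), `q` (studentized-range statistic), `p_adj` and
#'   `significant`.
#' @export
tukey_hsd <- function(table, alpha = 0.05) {
  if (alpha <= 0 || alpha >= 1) stop_invalid("alpha must lie in (0, 1)")
  table$condition <- droplevels(table$condition)
  fit <- stats::aov(energy_per_kg ~ condition, data = table)
  tk <- stats::TukeyHSD(fit, conf.level = 1 - alpha)$condition
  ms_within <- summary(fit)[[1L]]["Residuals", "Mean Sq"]
  n_per <- table(table$condition)
  # TukeyHSD rows follow combn() order over the factor levels; build the
  # pair index directly (labels themselves may contain hyphens).
  cmb <- utils::combn(levels(table$condition), 2L)
  pairs <- paste(cmb[2L, ], cmb[1L, ], sep = " - ")
  # harmonic mean group size per pair (equal n in the paired design)
  nh <- as.numeric(2 / (1 / n_per[cmb[1L, ]] + 1 / n_per[cmb[2L, ]]))
  data.frame(
    pair = pairs,
    difference = unname(tk[, "diff"]),
    q = abs(unname(tk[, "diff"])) / sqrt(ms_within / nh),
    p_adj = unname(tk[, "p adj"]),
    significant = unname(tk[, "p adj"]) < alpha
  )
}

#' Per-condition summary (mean +/- standard deviation)
#'
#' @param table A [condition_table()].
#' @return Data frame with `condition`, `n`, `mean`, `sd`.
#' @export
condition_summary <- function(table) {
  agg <- stats::aggregate(energy_per_kg ~ condition, table, function(v) {
    c(n = length(v), mean = mean(v), sd = stats::sd(v))
  })
  data.frame(
    condition = agg$condition,
    n = agg$energy_per_kg[, "n"],
    mean = agg$energy_per_kg[, "mean"],
    sd = agg$energy_per_kg[, "sd"]
  )
}
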