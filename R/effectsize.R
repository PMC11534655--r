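#' Percent change between group means
#'
#' `100 * (post - pre) / pre`, the ratio-of-means convention.  For the
#' per-participant (mean-of-ratios) convention see
#' [percent_change_by_participant()].
#'
#' @param pre_mean,post_mean Pre- and post-training group means (vectorised).
#' @return Percent change (not rounded; round at rendering time).
#' @export
#' @examples
#' percent_change(1071, 1186)  # 10.7 % to one decimal
percent_change <- function(pre_mean, post_mean) {
  if (any(!is.finite(pre_mean)) || any(!is.finite(post_mean))) {
    stop("means must be finite", call. = FALSE)
  }
  if (any(pre_mean == 0)) {
    stop("`pre_mean` must be non-zero", call. = FALSE)
  }
  100 * (post_mean - pre_mean) / pre_mean
}

#' Mean per-participant percent change
#'
#' The mean-of-ratios convention: each participant's percent change is
#' computed on their own baseline, then averaged.
#'
#' @param pre,post Paired vectors of participant values.
#' @return Mean per-participant percent change.
#' @export
percent_change_by_participant <- function(pre, post) {
  if (length(pre) != length(post)) {
    stop("`pre` and `post` must be paired vectors of equal length",
         call. = FALSE)
  }
  if (any(pre == 0)) stop("baseline values must be non-zero", call. = FALSE)
  mean(100 * (post - pre) / pre)
}

#' Bias-corrected Hedge's g from summary statistics
#'
#' Standardised mean difference with small-sample bias correction, treating
#' pre and post as two groups of size `n_per_group` with pooled SD:
#' `s_p = sqrt(((n1-1) s1^2 + (n2-1) s2^2) / (n1 + n2 - 2))`,
#' `d = (post_mean - pre_mean) / s_p`, and
#' `g = d * J` with `J = 1 - 3 / (4 (n1 + n2 - 2) - 1)`.
#'
#' @param pre_mean,pre_sd,post_mean,post_sd Group means and SDs (vectorised).
#' @param n_per_group Participants per group (n1 = n2).
#' @return Hedge's g.
#' @export
#' @examples
#' hedges_g(1071, 250, 1186, 246, 14)  # 0.45
hedges_g <- function(pre_mean, pre_sd, post_mean, post_sd, n_per_group) {
  check_number(n_per_group, "n_per_group", lower = 2)
  if (any(pre_sd < 0) || any(post_sd < 0)) {
    stop("standard deviations must be non-negative", call. = FALSE)
  }
  n <- n_per_group
  sp <- sqrt(((n - 1) * pre_sd^2 + (n - 1) * post_sd^2) / (2 * n - 2))
  if (any(sp == 0)) stop("pooled SD is zero", call. = FALSE)
  d <- (post_mean - pre_mean) / sp
  j <- 1 - 3 / (4 * (2 * n - 2) - 1)
  d * j
}

#' Confidence interval for Hedge's g
#'
#' Normal-approximation interval with
#' `SE = sqrt((n1 + n2) / (n1 n2) + g^2 / (2 (n1 + n2)))`.
#'
#' @param g Hedge's g (vectorised).
#' @param n_per_group Participants per group.
#' @param level Confidence level (default 0.95).
#' @return A tibble with columns `ci_low` and `ci_high`.
#' @export
#' @examples
#' hedges_ci(hedges_g(1071, 250, 1186, 246, 14), 14)  # (-0.30, 1.20)
hedges_ci <- function(g, n_per_group, level = 0.95) {
  check_number(n_per_group, "n_per_group", lower = 2)
  check_number(level, "level", lower = 0, upper = 1,
               allow_equal_lower = FALSE)
  n <- n_per_group
  se <- sqrt((2 * n) / (n * n) + g^2 / (2 * (2 * n)))
  z <- stats::qnorm((1 + level) / 2)
  tibble::tibble(ci_low = g - z * se, ci_high = g + z * se)
}

#' Magnitude label for an effect size
#'
#' Maps `|g|` through half-open magnitude bins with lower-edge inclusion:
#' trivial `[0, 0.2)`, small `[0.2, 0.6)`, moderate `[0.6, 1.2)`, large
#' `[1.2, 2.0)`, very large `[2.0, 4.0)`, extremely large `[4.0, Inf)`.
#'
#' @param g Effect size(s).
#' @return Character vector of labels.
#' @export
label_effect <- function(g) {
  as.character(cut(abs(g),
                   breaks = c(0, 0.2, 0.6, 1.2, 2, 4, Inf),
                   labels = c("trivial", "small", "moderate", "large",
                              "very large", "extremely large"),
                   right = FALSE, include.lowest = TRUE))
}

#' Magnitude label for a correlation coefficient
#'
#' Hopkins-modified Cohen scale on `|r|`, half-open bins with lower-edge
#' inclusion: trivial `[0, 0.1)`, small `[0.1, 0.3)`, moderate `[0.3, 0.5)`,
#' large `[0.5, 0.7)`, very large `[0.7, 0.9)`, almost perfect `[0.9, 1]`.
#'
#' @param r Correlation coefficient(s).
#' @return Character vector of labels.
#' @export
label_correlation <- function(r) {
  if (any(abs(r) > 1 + 1e-12, na.rm = TRUE)) {
    stop("|r| must not exceed 1", call. = FALSE)
  }
  as.character(cut(pmin(abs(r), 1),
                   breaks = c(0, 0.1, 0.3, 0.5, 0.7, 0.9, Inf),
                   labels = c("trivial", "small", "moderate", "large",
                              "very large", "almost perfect"),
                   right = FALSE, include.lowest = TRUE))
}

#' Pearson correlation with two-tailed p-value and magnitude label
#'
#' Product-moment correlation; the two-tailed p-value comes from
#' `t = r * sqrt((n - 2) / (1 - r^2))` on n - 2 degrees of freedom.
#'
#' @param x,y Numeric vectors of equal length (n >= 3), finite, non-constant.
#' @return A one-row tibble: `r`, `p`, `n`, `label`.
#' @export
#' @examples
#' pearson_corr(1:10, 2 * (1:10) + 1)
pearson_corr <- function(x, y) {
  if (length(x) != length(y)) {
    stop("`x` and `y` must have equal length", call. = FALSE)
  }
  if (length(x) < 3L) stop("need n >= 3 observations", call. = FALSE)
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    stop("`x` and `y` must be finite", call. = FALSE)
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance in `x` or `y`", call. = FALSE)
  }
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  r <- unname(ct$estimate)
  tibble::tibble(r = r, p = ct$p.value, n = length(x),
                 label = label_correlation(r))
}

#' Paired pre/post comparison
#'
#' Paired t statistic on the within-participant differences, two-tailed.  A
#' simple paired comparison utility for pre/post designs.
#'
#' @param pre,post Paired numeric vectors (n >= 3).
#' @return A one-row tibble: `mean_diff`, `t`, `df`, `p`, `n`.
#' @export
paired_comparison <- function(pre, post) {
  if (length(pre) != length(post)) {
    stop("`pre` and `post` must be paired vectors of equal length",
         call. = FALSE)
  }
  if (length(pre) < 3L) stop("need n >= 3 pairs", call. = FALSE)
  d <- post - pre
  if (stats::sd(d) == 0) {
    stop("zero variance in the paired differences", call. = FALSE)
  }
  tt <- stats::t.test(post, pre, paired = TRUE)
  tibble::tibble(mean_diff = unname(tt$estimate), t = unname(tt$statistic),
                 df = unname(tt$parameter), p = tt$p.value, n = length(pre))
}

# Long (participant, timepoint, metric, value) table -> wide per-participant
# pre/post values for one metric, complete pairs only.
paired_values <- function(table, metric_name) {
  sub <- table[table$metric == metric_name, c("participant", "timepoint", "value")]
  wide <- tidyr::pivot_wider(sub, names_from = "timepoint",
                             values_from = "value")
  if (!all(c("pre", "post") %in% names(wide))) {
    stop(sprintf("metric `%s` lacks a pre or post timepoint", metric_name),
         call. = FALSE)
  }
  ok <- is.finite(wide$pre) & is.finite(wide$post)
  if (any(!ok)) {
    warning(sprintf("dropping %d participant(s) missing a timepoint for `%s`",
                    sum(!ok), metric_name), call. = FALSE)
  }
  wide[ok, ]
}

#' Correlations between per-participant relative changes
#'
#' For every (predictor, outcome) metric pair, computes each participant's
#' relative change `100 * (post - pre) / pre` in both metrics and correlates
#' them across participants.  Participants missing a timepoint are dropped
#' with a warning.
#'
#' @param table Tidy metric table: columns `participant`, `timepoint`
#'   (`"pre"`/`"post"`), `metric`, `value`.
#' @param predictors,outcomes Character vectors of metric names.
#' @return A tibble with one row per pair: `predictor`, `outcome`, `r`, `p`,
#'   `n`, `label`.
#' @export
change_correlation_matrix <- function(table, predictors, outcomes) {
  deltas <- lapply(unique(c(predictors, outcomes)), function(m) {
    pv <- paired_values(table, m)
    tibble::tibble(participant = pv$participant,
                   metric = m,
                   delta = 100 * (pv$post - pv$pre) / pv$pre)
  })
  deltas <- dplyr::bind_rows(deltas)
  rows <- list()
  for (p_m in predictors) {
    for (o_m in outcomes) {
      dp <- deltas[deltas$metric == p_m, ]
      do_ <- deltas[deltas$metric == o_m, ]
      merged <- dplyr::inner_join(dp, do_, by = "participant",
                                  suffix = c("_p", "_o"))
      res <- pearson_corr(merged$delta_p, merged$delta_o)
      rows[[length(rows) + 1L]] <- dplyr::bind_cols(
        tibble::tibble(predictor = p_m, outcome = o_m), res)
    }
  }
  dplyr::bind_rows(rows)
}

#' Effect-size columns from summary statistics
#'
#' Vectorised convenience wrapper combining [percent_change()], [hedges_g()],
#' [hedges_ci()] and [label_effect()] for tables of printed means and SDs.
#'
#' @param stats_tbl Data frame with columns `pre_mean`, `pre_sd`,
#'   `post_mean`, `post_sd` (one row per metric; other columns are kept).
#' @param n Participants per timepoint.
#' @param level Confidence level.
#' @return `stats_tbl` with `pct_change`, `g`, `ci_low`, `ci_high` and
#'   `label` columns appended.
#' @export
#' @examples
#' summary_effects(tibble::tibble(metric = "ppo_w", pre_mean = 1071,
#'                                pre_sd = 250, post_mean = 1186,
#'                                post_sd = 246), n = 14)
summary_effects <- function(stats_tbl, n, level = 0.95) {
  need <- c("pre_mean", "pre_sd", "post_mean", "post_sd")
  if (!all(need %in% names(stats_tbl))) {
    stop(sprintf("`stats_tbl` must have columns %s",
                 paste(need, collapse = ", ")), call. = FALSE)
  }
  g <- hedges_g(stats_tbl$pre_mean, stats_tbl$pre_sd,
                stats_tbl$post_mean, stats_tbl$post_sd, n)
  ci <- hedges_ci(g, n, level = level)
  out <- tibble::as_tibble(stats_tbl)
  out$pct_change <- percent_change(stats_tbl$pre_mean, stats_tbl$post_mean)
  out$g <- g
  out$ci_low <- ci$ci_low
  out$ci_high <- ci$ci_high
  out$label <- label_effect(g)
  out
}

#' Build a pre/post summary table from a cohort metric table
#'
#' Produces a training-response summary with one row per metric: pre and
#' post mean and SD, percent change, paired-comparison p-value, and
#' bias-corrected Hedge's g with confidence interval and magnitude label.
#' Only participants with both timepoints contribute.
#'
#' @param table Tidy metric table: `participant`, `timepoint`, `metric`,
#'   `value`.
#' @param pct_convention `"ratio-of-means"` (percent change of the group
#'   means; default) or `"mean-of-ratios"` (mean per-participant percent
#'   change).
#' @param ci_level Confidence level for the effect-size interval.
#' @return A tibble with one row per metric (input order preserved).
#' @export
build_summary_table <- function(table,
                                pct_convention = c("ratio-of-means",
                                                   "mean-of-ratios"),
                                ci_level = 0.95) {
  pct_convention <- match.arg(pct_convention)
  if (!all(c("participant", "timepoint", "metric", "value") %in% names(table))) {
    stop("`table` must have columns participant, timepoint, metric, value",
         call. = FALSE)
  }
  metrics <- unique(table$metric)
  rows <- lapply(metrics, function(m) {
    pv <- paired_values(table, m)
    if (nrow(pv) == 0) return(NULL)
    n <- nrow(pv)
    pct <- if (pct_convention == "ratio-of-means") {
      percent_change(mean(pv$pre), mean(pv$post))
    } else {
      percent_change_by_participant(pv$pre, pv$post)
    }
    p <- tryCatch(paired_comparison(pv$pre, pv$post)$p,
                  error = function(e) NA_real_)
    g <- hedges_g(mean(pv$pre), stats::sd(pv$pre),
                  mean(pv$post), stats::sd(pv$post), n)
    ci <- hedges_ci(g, n, level = ci_level)
    tibble::tibble(
      metric = m, n = n,
      pre_mean = mean(pv$pre), pre_sd = stats::sd(pv$pre),
      post_mean = mean(pv$post), post_sd = stats::sd(pv$post),
      pct_change = pct, p = p, g = g,
      ci_low = ci$ci_low, ci_high = ci$ci_high,
      label = label_effect(g))
  })
  dplyr::bind_rows(rows)
}
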