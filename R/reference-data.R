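#' Published training-response summary statistics
#'
#' Summary statistics (mean and SD, n = 14 per timepoint) from a six-week
#' sprint-cycling plus resistance-training study in strength-trained novice
#' cyclists, as printed in the study's results table: sprint-cycling power,
#' cadence and torque measures, isometric mid-thigh pull force measures, and
#' three-repetition-maximum gym lifts, pre- and post-training, together with
#' the printed percent change, bias-corrected Hedge's g and its 95%
#' confidence interval.
#'
#' Two printed percent-change cells (relative PPO and observed peak cadence)
#' are inconsistent with the ratio-of-means convention that reproduces the
#' other 17 rows and were most likely computed per participant; they are
#' flagged by `pct_consistent = FALSE`.  One printed effect size (IMTP peak
#' RFD, printed g = 0.35) is not reproducible from the row's printed means
#' and SDs under the pooled-SD bias-corrected formula that reproduces the
#' other 18 rows exactly (which gives 0.43); it is flagged by
#' `g_consistent = FALSE`.
#'
#' @return A tibble with one row per measure: `group`, `metric`, `unit`,
#'   `pre_mean`, `pre_sd`, `post_mean`, `post_sd`, `pct_change_printed`,
#'   `g_printed`, `ci_low_printed`, `ci_high_printed`, `n`,
#'   `pct_consistent`, `g_consistent`.
#' @export
#' @examples
#' ref <- reference_training_summary()
#' summary_effects(ref, n = 14)[, c("metric", "pct_change", "g")]
reference_training_summary <- function() {
  tbl <- tibble::tribble(
    ~group,    ~metric,        ~unit,     ~pre_mean, ~pre_sd, ~post_mean, ~post_sd, ~pct_change_printed, ~g_printed, ~ci_low_printed, ~ci_high_printed,
    "cycling", "ppo_w",        "W",          1071,     250,     1186,      246,      10.7,               0.45,      -0.30,            1.20,
    "cycling", "ppo_per_bm",   "W/kg",       13.9,     2.3,     15.4,      2.0,      10.5,               0.68,      -0.09,            1.44,
    "cycling", "rpm_peak",     "rpm",        185,      15,      192,       14,       4.3,                0.47,      -0.28,            1.22,
    "cycling", "t_peak_nm",    "Nm",         207.1,    37.8,    231.4,     35.1,     11.7,               0.65,      -0.11,            1.41,
    "cycling", "rtd_0_100",    "Nm/s",       291.2,    111.4,   456.4,     171.9,    56.7,               1.11,       0.31,            1.90,
    "cycling", "rtd_0_200",    "Nm/s",       522.9,    176.9,   716.1,     224.7,    36.9,               0.93,       0.15,            1.71,
    "cycling", "rtd_avg",      "Nm/s",       507.0,    151.9,   657.5,     186.3,    29.7,               0.86,       0.09,            1.63,
    "cycling", "rtd_peak",     "Nm/s",       864.9,    252.0,   1106.2,    296.2,    27.9,               0.85,       0.08,            1.63,
    "cycling", "t0_nm",        "Nm",         165.2,    25.0,    182.0,     29.2,     10.2,               0.60,      -0.16,            1.36,
    "cycling", "pmax_w",       "W",          1066.6,   255.4,   1171.9,    265.7,    9.9,                0.39,      -0.36,            1.14,
    "cycling", "rpmmax_rpm",   "rpm",        232.2,    19.4,    234.1,     19.1,     0.8,                0.10,      -0.65,            0.84,
    "cycling", "rpmopt_rpm",   "rpm",        118,      10,      119,       9,        0.8,                0.10,      -0.64,            0.84,
    "imtp",    "imtp_pf",      "N",          1811.7,   573.6,   2049.8,    608.4,    13.1,               0.39,      -0.36,            1.14,
    "imtp",    "rfd_0_100",    "N/s",        3303.4,   1862.0,  4246.6,    1828.5,   28.6,               0.50,      -0.26,            1.25,
    "imtp",    "rfd_0_200",    "N/s",        2786.7,   1146.9,  3520.1,    1179.2,   26.3,               0.61,      -0.15,            1.37,
    "imtp",    "rfd_avg",      "N/s",        2852.5,   1465.4,  3778.8,    2364.0,   32.5,               0.46,      -0.29,            1.21,
    "imtp",    "rfd_peak",     "N/s",        11344.2,  5608.7,  14030.1,   6419.9,   23.7,               0.35,      -0.40,            1.09,
    "3rm",     "back_squat",   "kg",         96,       25,      108,       25,       12.5,               0.47,      -0.28,            1.22,
    "3rm",     "deadlift",     "kg",         106,      35,      119,       36,       12.3,               0.36,      -0.39,            1.10)
  tbl$n <- 14L
  tbl$pct_consistent <- !(tbl$metric %in% c("ppo_per_bm", "rpm_peak"))
  tbl$g_consistent <- tbl$metric != "rfd_peak"
  tbl
}
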