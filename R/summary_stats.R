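#' Two-sample Student t-test from group summaries
#'
#' Computes the pooled-variance Student t-test directly from per-group
#' summaries (mean, SD, n), as needed when only a summary table is available.
#' The pooled variance is
#' \deqn{s_p^2 = \frac{(n_1-1)s_1^2 + (n_2-1)s_2^2}{n_1+n_2-2},}
#' the statistic \eqn{t = (m_1-m_2)/(s_p\sqrt{1/n_1+1/n_2})} with
#' \eqn{n_1+n_2-2} degrees of freedom, and the p-value is two-sided.
#'
#' If both SDs are zero and the means are equal, `t = 0`, `p = 1`; if both SDs
#' are zero but the means differ, the difference is certain given the
#' summaries, so `p = 0` is returned with a warning and the `degenerate` flag
#' set.
#'
#' @param mean_x,sd_x,n_x Summary of the first group (`sd >= 0`, `n >= 2`).
#' @param mean_y,sd_y,n_y Summary of the second group.
#' @return A one-row tibble with columns `t`, `df`, `p`, `method`
#'   (`"student_pooled"`) and `degenerate`.
#' @examples
#' # a cytokine panel row: wild type 201 (31.7), mutant 211 (24.6), n = 4 each
#' ttest_summary(201, 31.7, 4, 211, 24.6, 4)
#' @export
ttest_summary <- function(mean_x, sd_x, n_x, mean_y, sd_y, n_y) {
  n_x <- assert_count(n_x, "n_x", lower = 2)
  n_y <- assert_count(n_y, "n_y", lower = 2)
  assert_scalar_number(sd_x, "sd_x", lower = 0)
  assert_scalar_number(sd_y, "sd_y", lower = 0)
  assert_scalar_number(mean_x, "mean_x")
  assert_scalar_number(mean_y, "mean_y")

  df <- n_x + n_y - 2
  sp <- sqrt(((n_x - 1) * sd_x^2 + (n_y - 1) * sd_y^2) / df)
  degenerate <- FALSE
  if (sp == 0) {
    if (mean_x == mean_y) {
      t <- 0; p <- 1
    } else {
      t <- sign(mean_x - mean_y) * Inf; p <- 0
      degenerate <- TRUE
      warning("both group SDs are zero with differing means; p = 0 is degenerate",
              call. = FALSE)
    }
  } else {
    t <- (mean_x - mean_y) / (sp * sqrt(1 / n_x + 1 / n_y))
    p <- 2 * stats::pt(-abs(t), df)
  }
  tibble::tibble(t = t, df = df, p = p, method = "student_pooled",
                 degenerate = degenerate)
}

#' Standardized mean difference (Cohen's d) from group summaries
#'
#' Computes \eqn{d = (m_y - m_x)/s_p} with the pooled SD of
#' [ttest_summary()], and a normal-approximation confidence interval with
#' \deqn{se(d) = \sqrt{\frac{n_x+n_y}{n_x n_y} + \frac{d^2}{2(n_x+n_y-2)}}.}
#'
#' @inheritParams ttest_summary
#' @param conf_level Confidence level for the interval (default 0.95).
#' @return A one-row tibble with columns `d`, `se`, `ci_low`, `ci_high`.
#' @examples
#' cohens_d_summary(10, 2, 9, 14, 2, 9) # d = 2
#' @export
cohens_d_summary <- function(mean_x, sd_x, n_x, mean_y, sd_y, n_y,
                             conf_level = 0.95) {
  n_x <- assert_count(n_x, "n_x", lower = 2)
  n_y <- assert_count(n_y, "n_y", lower = 2)
  assert_scalar_number(sd_x, "sd_x", lower = 0)
  assert_scalar_number(sd_y, "sd_y", lower = 0)
  assert_scalar_number(conf_level, "conf_level", lower = 0, upper = 1)

  df <- n_x + n_y - 2
  sp <- sqrt(((n_x - 1) * sd_x^2 + (n_y - 1) * sd_y^2) / df)
  if (sp == 0) {
    stop("pooled SD is zero: standardized effect size is undefined",
         call. = FALSE)
  }
  d <- (mean_y - mean_x) / sp
  se <- sqrt((n_x + n_y) / (n_x * n_y) + d^2 / (2 * df))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  tibble::tibble(d = d, se = se, ci_low = d - z * se, ci_high = d + z * se)
}

#' Censor analytes below the assay's lower limit of quantification
#'
#' Analytes whose raw values fall below the lower limit of quantification
#' (LLoQ) in every animal are marked `below_lloq` and are excluded from
#' downstream testing; all other analytes are retained unchanged with status
#' `quantified`. Analytes with no LLoQ recorded (`NA`) are treated as
#' assay-quantified.
#'
#' @param data A long tibble of raw analyte measurements.
#' @param value,lloq,analyte Columns of `data` holding the measured value, the
#'   per-analyte LLoQ and the analyte identifier (tidy-eval).
#' @return `data` with an added `status` column (`"quantified"` or
#'   `"below_lloq"`).
#' @export
censor_lloq <- function(data, value = value, lloq = lloq, analyte = analyte) {
  stopifnot(is.data.frame(data))
  if (nrow(data) == 0) {
    data$status <- character(0)
    return(data)
  }
  lloq_vals <- dplyr::pull(data, {{ lloq }})
  if (any(!is.na(lloq_vals) & lloq_vals < 0)) {
    stop("LLoQ values must be nonnegative", call. = FALSE)
  }
  dplyr::mutate(
    dplyr::group_by(data, {{ analyte }}),
    status = ifelse(
      all(!is.na({{ lloq }})) && all({{ value }} < {{ lloq }}, na.rm = TRUE),
      "below_lloq", "quantified"),
    .after = dplyr::last_col()
  ) |>
    dplyr::ungroup()
}

#' Analyze a summary analyte panel
#'
#' Runs the summary-statistics pooled t-test and standardized effect size
#' ([ttest_summary()], [cohens_d_summary()]) for every quantified analyte of
#' a wide summary panel, one row per analyte. P-values are reported
#' unadjusted. Analytes whose summaries cannot be tested (e.g. n < 2, or an
#' undefined effect size) are returned as flagged rows (`note` column) rather
#' than aborting the panel.
#'
#' @param panel A tibble with columns `analyte`, `mean_wt`, `sd_wt`, `n_wt`,
#'   `mean_het`, `sd_het`, `n_het`, and optionally `units`, `lloq`, `status`
#'   (rows with `status != "quantified"` are dropped).
#' @param conf_level Confidence level for effect-size intervals.
#' @return A tibble with one row per tested analyte: `analyte`, `units`, `t`,
#'   `df`, `p`, `d`, `ci_low`, `ci_high`, `note` (`NA` when clean). The
#'   effect sign convention is mutant minus wild type.
#' @examples
#' panel <- tibble::tibble(analyte = "EGF", units = "pg/mL",
#'   mean_wt = 201, sd_wt = 31.7, n_wt = 4,
#'   mean_het = 211, sd_het = 24.6, n_het = 4)
#' analyze_panel(panel)
#' @export
analyze_panel <- function(panel, conf_level = 0.95) {
  stopifnot(is.data.frame(panel))
  needed <- c("analyte", "mean_wt", "sd_wt", "n_wt", "mean_het", "sd_het",
              "n_het")
  miss <- setdiff(needed, names(panel))
  if (length(miss)) {
    stop("panel is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if ("status" %in% names(panel)) {
    panel <- panel[is.na(panel$status) | panel$status == "quantified", ]
  }
  if (!"units" %in% names(panel)) panel$units <- NA_character_

  purrr::pmap_dfr(
    panel[c("analyte", "units", "mean_wt", "sd_wt", "n_wt", "mean_het",
            "sd_het", "n_het")],
    function(analyte, units, mean_wt, sd_wt, n_wt, mean_het, sd_het, n_het) {
      base <- tibble::tibble(analyte = analyte, units = units,
                             t = NA_real_, df = NA_real_, p = NA_real_,
                             d = NA_real_, ci_low = NA_real_,
                             ci_high = NA_real_, note = NA_character_)
      tt <- tryCatch(
        suppressWarnings(ttest_summary(mean_wt, sd_wt, n_wt,
                                       mean_het, sd_het, n_het)),
        error = function(e) e)
      if (inherits(tt, "error")) {
        base$note <- conditionMessage(tt)
        return(base)
      }
      base$t <- tt$t; base$df <- tt$df; base$p <- tt$p
      if (tt$degenerate) base$note <- "degenerate: both group SDs zero"
      es <- tryCatch(
        cohens_d_summary(mean_wt, sd_wt, n_wt, mean_het, sd_het, n_het,
                         conf_level = conf_level),
        error = function(e) e)
      if (inherits(es, "error")) {
        base$note <- paste(stats::na.omit(c(base$note, conditionMessage(es))),
                           collapse = "; ")
      } else {
        base$d <- es$d; base$ci_low <- es$ci_low; base$ci_high <- es$ci_high
      }
      base
    })
}

#' Built-in 12-month plasma analyte summary panel
#'
#' The published 12-month plasma panel of the Q111 knock-in natural-history
#' study: cytokine/chemokine analytes from a multiplexed immunoassay and
#' clinical chemistry analytes, as per-genotype summaries (mean, SD) at n = 4
#' male animals per genotype, plus the analytes reported below the assay's
#' LLoQ (with their limits). Analyte values are transcribed from the printed
#' summary table; they are the worked input for [analyze_panel()].
#'
#' @return A tibble with columns `analyte`, `units`, `panel_source`,
#'   `mean_wt`, `sd_wt`, `n_wt`, `mean_het`, `sd_het`, `n_het`, `printed_p`,
#'   `lloq`, `status`.
#' @export
q111_plasma_panel <- function() {
  path <- system.file("extdata", "q111_plasma_panel.csv",
                      package = "rescuepower", mustWork = TRUE)
  readr::read_csv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    analyte = "c", units = "c", panel_source = "c",
                    status = "c", .default = "d"))
}
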