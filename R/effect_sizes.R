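#' Genotype effect sizes by age from a cohort
#'
#' The natural-history effect-size report: for each endpoint and age, the
#' standardized mean difference (heterozygote minus wild type, pooled SD)
#' with its 95% confidence interval, computed from the baseline arms via
#' [cohens_d_summary()].
#'
#' @param cohort A cohort tibble with `genotype` and `age_months` columns.
#' @param endpoints Character vector of endpoint columns; default: every
#'   column after the cohort metadata columns.
#' @param conf_level Confidence level (default 0.95).
#' @return A tibble of class `effect_size_table`: `endpoint`, `age_months`,
#'   `n_wt`, `n_het`, `d`, `se`, `ci_low`, `ci_high`.
#' @examples
#' cohort <- sample_cohort(config_moments(q111_config()), 9, seed = 1)
#' effect_sizes(cohort)
#' @export
effect_sizes <- function(cohort, endpoints = NULL, conf_level = 0.95) {
  stopifnot(is.data.frame(cohort))
  meta_cols <- c("animal_id", "genotype", "age_months", "sex", "arm")
  if (is.null(endpoints)) endpoints <- setdiff(names(cohort), meta_cols)
  if ("arm" %in% names(cohort)) {
    cohort <- cohort[is.na(cohort$arm) | cohort$arm == "baseline", ]
  }
  ages <- sort(unique(cohort$age_months))
  grid <- tidyr::expand_grid(endpoint = endpoints, age_months = ages)
  out <- purrr::pmap_dfr(grid, function(endpoint, age_months) {
    sub <- cohort[cohort$age_months == age_months, ]
    x <- sub[[endpoint]][sub$genotype == "WT"]
    y <- sub[[endpoint]][sub$genotype == "HET"]
    x <- x[!is.na(x)]; y <- y[!is.na(y)]
    row <- tibble::tibble(endpoint = endpoint, age_months = age_months,
                          n_wt = length(x), n_het = length(y),
                          d = NA_real_, se = NA_real_, ci_low = NA_real_,
                          ci_high = NA_real_)
    es <- tryCatch(
      cohens_d_summary(mean(x), stats::sd(x), length(x),
                       mean(y), stats::sd(y), length(y),
                       conf_level = conf_level),
      error = function(e) NULL)
    if (!is.null(es)) {
      row$d <- es$d; row$se <- es$se
      row$ci_low <- es$ci_low; row$ci_high <- es$ci_high
    }
    row
  })
  class(out) <- c("effect_size_table", class(out))
  out
}

#' Plot genotype effect sizes by age
#'
#' Point-and-whisker display of the standardized genotype effect per
#' endpoint, faceted by age, in the style of natural-history effect-size
#' panels: whiskers are the confidence interval, the dashed line marks the
#' null.
#'
#' @param object An `effect_size_table` from [effect_sizes()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.effect_size_table <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(
    x = stats::reorder(.data$endpoint, .data$d), y = .data$d)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$ci_low,
                                          ymax = .data$ci_high)) +
    ggplot2::coord_flip() +
    ggplot2::facet_wrap(~age_months, labeller = ggplot2::label_both) +
    ggplot2::labs(x = NULL, y = "standardized genotype effect (HET - WT)")
}

#' Plot a power grid
#'
#' Power against rescue fraction, one curve per per-arm sample size, with a
#' ribbon of +/- 2 Monte-Carlo standard errors and the conventional 80%
#' power threshold.
#'
#' @param object A `power_grid` from [power_grid()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.power_grid <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(
    x = .data$r, y = .data$power,
    colour = factor(.data$n_per_arm), group = factor(.data$n_per_arm))) +
    ggplot2::geom_hline(yintercept = 0.8, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_ribbon(ggplot2::aes(
      ymin = pmax(0, .data$power - 2 * .data$mc_se),
      ymax = pmin(1, .data$power + 2 * .data$mc_se),
      fill = factor(.data$n_per_arm)), alpha = 0.15, colour = NA) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "rescue fraction r", y = "estimated power",
                  colour = "n per arm", fill = "n per arm") +
    ggplot2::ylim(0, 1)
}

#' Plot composite-model weights
#'
#' Bar chart of the per-endpoint regression coefficients (weights) of a
#' fitted elastic-net composite model; positive and negative weights indicate
#' endpoints elevated and reduced in the positive class, respectively.
#'
#' @param object An `enet_model` from [fit_enet()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.enet_model <- function(object, ...) {
  td <- tidy(object)
  ggplot2::ggplot(td, ggplot2::aes(
    x = stats::reorder(.data$endpoint, .data$weight), y = .data$weight)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = 0) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL,
                  y = sprintf("weight (standardized scale, positive class %s)",
                              object$positive_class))
}
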