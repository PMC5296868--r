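#' Partial-rescue treatment model
#'
#' A hypothetical treatment that moves the mutant (heterozygote) mean toward
#' wild type by a fraction `r` on each endpoint: `r` of 0 is no effect,
#' `r` of 1 full normalization. The fraction can be global or per-endpoint.
#'
#' @param r Rescue fraction in `[0, 1]`.
#' @param scope Optional named numeric vector of per-endpoint rescue
#'   fractions overriding `r` for those endpoints.
#' @return An object of class `rescue_model`.
#' @examples
#' rescue_model(0.5)
#' @export
rescue_model <- function(r = 0.5, scope = NULL) {
  assert_scalar_number(r, "r", lower = 0, upper = 1)
  if (!is.null(scope)) {
    stopifnot(is.numeric(scope), !is.null(names(scope)))
    if (any(scope < 0 | scope > 1)) {
      stop("per-endpoint rescue fractions must lie in [0, 1]", call. = FALSE)
    }
  }
  structure(list(r = r, scope = scope), class = "rescue_model")
}

rescue_fractions <- function(model, endpoints) {
  r <- rep(model$r, length(endpoints))
  names(r) <- endpoints
  if (!is.null(model$scope)) {
    hit <- intersect(names(model$scope), endpoints)
    r[hit] <- model$scope[hit]
  }
  r
}

#' Apply a partial rescue to baseline moments
#'
#' For every age with both baseline cells present, adds the two treated
#' cells of the 2x2 factorial design:
#' * treated heterozygote: mean `mu_HET + r * (mu_WT - mu_HET)` per endpoint,
#'   covariance inherited unchanged from the baseline heterozygote;
#' * treated wild type: identical to baseline wild type (treatment assumed
#'   inert in wild-type animals).
#'
#' Rescue acts on means only. Applying a further rescue with zero `r` to an
#' already-rescued set changes nothing.
#'
#' @param moments A [moments_set()] with baseline WT and HET cells.
#' @param model A [rescue_model()].
#' @param age_months Optional ages to rescue; default every age with both
#'   baseline cells.
#' @return A `moments_set` including the treated cells.
#' @export
apply_rescue <- function(moments, model, age_months = NULL) {
  stopifnot(inherits(moments, "moments_set"), inherits(model, "rescue_model"))
  cells <- moments$cells
  base <- cells[cells$arm == "baseline", ]
  ages <- age_months %||% sort(unique(base$age_months))
  eps <- moments$endpoints$endpoint
  r <- rescue_fractions(model, eps)

  new_cells <- purrr::map(ages, function(age) {
    wt <- moments_cell(moments, "WT", age, "baseline")
    het <- moments_cell(moments, "HET", age, "baseline")
    mu_t <- het$mean + r * (wt$mean - het$mean)
    list(
      cell_moments("HET", age, "treated", mean = mu_t, cov = het$cov,
                   n_source = 0L),
      cell_moments("WT", age, "treated", mean = wt$mean, cov = wt$cov,
                   n_source = 0L)
    )
  })
  new_cells <- purrr::flatten(new_cells)
  keep <- !(cells$arm == "treated" & cells$age_months %in% ages)
  old_cells <- purrr::pmap(cells[keep, ], function(genotype, age_months, arm,
                                                   n_source, mean, cov) {
    cell_moments(genotype, age_months, arm, mean = mean, cov = cov,
                 n_source = n_source)
  })
  moments_set(moments$endpoints, c(old_cells, new_cells))
}

#' Trial design for the 2x2 factorial rescue experiment
#'
#' @param n_per_arm Animals per arm (>= 2); four arms in total.
#' @param alpha Two-sided test level in (0, 1), default 0.05.
#' @param age_months Age cell the trial samples from (default 12).
#' @return An object of class `trial_design`.
#' @export
trial_design <- function(n_per_arm = 10, alpha = 0.05, age_months = 12) {
  n_per_arm <- assert_count(n_per_arm, "n_per_arm", lower = 2)
  assert_scalar_number(alpha, "alpha")
  if (alpha <= 0 || alpha >= 1) stop("`alpha` must lie in (0, 1)", call. = FALSE)
  assert_scalar_number(age_months, "age_months", lower = 0)
  structure(list(n_per_arm = n_per_arm, alpha = alpha,
                 age_months = age_months,
                 test = "treated_vs_untreated_het"),
            class = "trial_design")
}

#' Simulate one 2x2 factorial trial
#'
#' Applies the rescue model to the baseline moments at the design age and
#' samples the four arms (genotype x treatment) with [sample_cohort()],
#' `n_per_arm` animals each.
#'
#' @param moments A [moments_set()] with baseline cells at the design age.
#' @param design A [trial_design()].
#' @param model A [rescue_model()].
#' @param seed Integer seed; the same seed reproduces the identical table.
#' @return A cohort tibble with `4 * n_per_arm` rows.
#' @export
simulate_trial <- function(moments, design, model, seed) {
  stopifnot(inherits(design, "trial_design"))
  rescued <- apply_rescue(moments, model, age_months = design$age_months)
  cells <- tidyr::expand_grid(genotype = c("WT", "HET"),
                              age_months = design$age_months,
                              arm = c("baseline", "treated"))
  sample_cohort(rescued, design$n_per_arm, seed, cells = cells)
}

#' Detection test on a simulated trial
#'
#' The primary contrast: a two-sided pooled-variance Student t-test of the
#' endpoint between the treated and baseline heterozygote arms (wild-type
#' arms are reserved for moment estimation and classifier training).
#' Detection means `p < alpha`.
#'
#' @param trial A cohort tibble containing baseline and treated HET arms.
#' @param endpoint Endpoint column name (string) or tidy-eval column.
#' @param design A [trial_design()] (supplies `alpha`).
#' @return `TRUE` if the rescue is detected, with the p-value attached as
#'   attribute `p_value`.
#' @export
detect_rescue <- function(trial, endpoint, design) {
  stopifnot(is.data.frame(trial), inherits(design, "trial_design"))
  v <- dplyr::pull(trial, {{ endpoint }})
  het <- trial$genotype == "HET"
  x <- v[het & trial$arm == "treated"]
  y <- v[het & trial$arm == "baseline"]
  if (length(x) < 2 || length(y) < 2) {
    stop("trial must contain baseline and treated HET arms (n >= 2 each)",
         call. = FALSE)
  }
  tt <- suppressWarnings(
    ttest_summary(mean(x), stats::sd(x), length(x),
                  mean(y), stats::sd(y), length(y)))
  structure(tt$p < design$alpha, p_value = tt$p)
}

#' Monte-Carlo power for a single endpoint
#'
#' Estimates the probability that [detect_rescue()] rejects at level `alpha`
#' over `reps` independently simulated trials ([simulate_trial()]). Each
#' replicate's seed is derived from `(seed, n_per_arm, replicate)`, so
#' rescue-fraction sweeps at a fixed `n_per_arm` share common random numbers
#' (a fixed seed ladder). The moments are first marginalized to the tested
#' endpoint, which leaves the test distribution unchanged.
#'
#' @param moments A [moments_set()].
#' @param endpoint Endpoint name (string).
#' @param model A [rescue_model()].
#' @param design A [trial_design()].
#' @param reps Number of Monte-Carlo replicates (>= 100).
#' @param seed Integer seed.
#' @return A one-row `power_estimate` tibble: `power`, `reps`, `mc_se`
#'   (`sqrt(power * (1 - power) / reps)`), `seed`, plus design descriptors.
#' @examples
#' \donttest{
#' m <- config_moments(q111_config())
#' estimate_power(m, "scn4b", rescue_model(0.5), trial_design(10),
#'                reps = 200, seed = 1)
#' }
#' @export
estimate_power <- function(moments, endpoint, model, design, reps = 1000,
                           seed = 1) {
  reps <- assert_count(reps, "reps", lower = 100)
  stopifnot(is.character(endpoint), length(endpoint) == 1)
  marg <- subset_moments(moments, endpoint)
  # rescue the moments once; each replicate then redraws the trial arms from
  # per-cell streams identical to those of simulate_trial() with that seed
  rescued <- apply_rescue(marg, model, age_months = design$age_months)
  age <- design$age_months
  n <- design$n_per_arm
  treated <- moments_cell(rescued, "HET", age, "treated")
  baseline <- moments_cell(rescued, "HET", age, "baseline")

  hits <- vapply(seq_len(reps), function(i) {
    rep_seed <- derive_seed(seed, "trial", n, i)
    x <- draw_cell(treated, n, rep_seed)[, 1]
    y <- draw_cell(baseline, n, rep_seed)[, 1]
    pooled_t_p(x, y) < design$alpha
  }, logical(1))
  power_estimate(mean(hits), reps, seed, endpoint = endpoint,
                 age_months = design$age_months, r = model$r,
                 n_per_arm = design$n_per_arm, alpha = design$alpha,
                 method = "univariate_t")
}

# Draw one cell's animals on its (seed, cell-label) stream; identical values
# to the matching rows of sample_cohort(moments, n, seed).
draw_cell <- function(cell, n, seed) {
  set.seed(derive_seed(seed, "cell", cell$genotype, cell$age_months, cell$arm))
  out <- MASS::mvrnorm(n = n, mu = cell$mean, Sigma = cell$cov)
  if (n == 1) out <- matrix(out, nrow = 1)
  out
}

# Two-sided pooled-variance t-test p-value, no tibble overhead.
pooled_t_p <- function(x, y) {
  nx <- length(x); ny <- length(y)
  df <- nx + ny - 2
  sp2 <- ((nx - 1) * stats::var(x) + (ny - 1) * stats::var(y)) / df
  dm <- mean(x) - mean(y)
  if (sp2 == 0) return(if (dm == 0) 1 else 0)
  2 * stats::pt(-abs(dm / sqrt(sp2 * (1 / nx + 1 / ny))), df)
}

power_estimate <- function(power, reps, seed, endpoint = NA_character_,
                           age_months = NA_real_, r = NA_real_,
                           n_per_arm = NA_integer_, alpha = NA_real_,
                           method = NA_character_) {
  out <- tibble::tibble(
    endpoint = endpoint, age_months = age_months, r = r,
    n_per_arm = as.integer(n_per_arm), alpha = alpha, method = method,
    power = power, reps = as.integer(reps),
    mc_se = sqrt(power * (1 - power) / reps), seed = as.integer(seed))
  class(out) <- c("power_estimate", class(out))
  out
}

#' Exact two-sample t-test power via the noncentral t distribution
#'
#' Closed-form power of the two-sided pooled t-test for a standardized mean
#' difference `d_effective` with `n_per_arm` per group: noncentrality
#' `ncp = d * sqrt(n / 2)` on `2n - 2` degrees of freedom. Serves as the
#' analytic oracle for [estimate_power()]: a rescue of fraction `r` on an
#' endpoint with standardized genotype effect `d_g` corresponds to
#' `d_effective = r * d_g`.
#'
#' @param d_effective Standardized mean difference (vectorized).
#' @param n_per_arm Animals per arm (>= 2).
#' @param alpha Two-sided level (default 0.05).
#' @return Power in `[0, 1]`, same length as `d_effective`.
#' @examples
#' analytic_power(1, 10)    # ~0.562
#' analytic_power(0, 10)    # = alpha
#' @export
analytic_power <- function(d_effective, n_per_arm, alpha = 0.05) {
  n_per_arm <- assert_count(n_per_arm, "n_per_arm", lower = 2)
  assert_scalar_number(alpha, "alpha")
  df <- 2 * n_per_arm - 2
  ncp <- abs(d_effective) * sqrt(n_per_arm / 2)
  tcrit <- stats::qt(1 - alpha / 2, df)
  1 - stats::pt(tcrit, df, ncp) + stats::pt(-tcrit, df, ncp)
}
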