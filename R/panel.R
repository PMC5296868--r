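#' Define an endpoint panel
#'
#' An endpoint panel declares the numeric outcome measures of a natural-history
#' or trial cohort: each endpoint has a unique name, an assay class, and the
#' expected sign of the mutant-minus-wild-type difference at late ages
#' (`direction`; 0 for endpoints with no expected genotype effect).
#'
#' @param name Character vector of unique endpoint names (valid column names).
#' @param assay_class Character vector (recycled) drawn from
#'   `"transcript"`, `"histology"`, `"plasma"`, `"behavior"`.
#' @param direction Integer vector (recycled) in `{-1, 0, 1}`: expected sign of
#'   the heterozygote-minus-wild-type effect at late ages.
#'
#' @return A tibble with columns `endpoint`, `assay_class`, `direction`.
#' @examples
#' endpoint_panel(c("scn4b", "cell_count"), "transcript", c(-1L, 0L))
#' @export
endpoint_panel <- function(name, assay_class = "transcript", direction = 0L) {
  if (anyDuplicated(name)) {
    stop("endpoint names must be unique within a panel", call. = FALSE)
  }
  classes <- c("transcript", "histology", "plasma", "behavior")
  assay_class <- rep_len(as.character(assay_class), length(name))
  if (!all(assay_class %in% classes)) {
    stop("`assay_class` must be one of: ", paste(classes, collapse = ", "),
         call. = FALSE)
  }
  direction <- rep_len(as.integer(direction), length(name))
  if (!all(direction %in% c(-1L, 0L, 1L))) {
    stop("`direction` must be -1, 0 or +1", call. = FALSE)
  }
  tibble::tibble(endpoint = as.character(name), assay_class = assay_class,
                 direction = direction)
}

#' Built-in striatal endpoint panel of the Q111 knock-in parameterization
#'
#' Ten striatal endpoints of the heterozygous Q111 knock-in mouse: five
#' QRT-PCR relative-expression transcripts (Scn4b, Drd1a, Cnr1, Darpp32,
#' Homer1), all reduced in aged mutants, and five immunohistochemistry
#' measures (mutant-huntingtin aggregate fraction and aggregate area, both
#' increased; somatic DARPP32 intensity, reduced; neuronal cell count and
#' neuronal ratio, unaffected).
#'
#' @return A tibble as returned by [endpoint_panel()].
#' @seealso [q111_config()]
#' @export
q111_panel <- function() {
  endpoint_panel(
    name = c("scn4b", "drd1a", "cnr1", "darpp32", "homer1",
             "mhtt_aggregates", "mhtt_area", "darpp32_intensity",
             "cell_count", "neuronal_ratio"),
    assay_class = c(rep("transcript", 5), rep("histology", 5)),
    direction = c(-1L, -1L, -1L, -1L, -1L, 1L, 1L, -1L, 0L, 0L)
  )
}

#' Synthetic generator configuration emulating a Q111 natural-history study
#'
#' Returns the package's built-in cohort-generator configuration: the ten
#' striatal endpoints of [q111_panel()], cross-sectional cells at 3, 9 and 12
#' months with 9 animals per genotype cell, and standardized genotype effects
#' that are absent at 3 months and large at 9-12 months. The aggregate-fraction
#' endpoint (`mhtt_aggregates`, the percentage of neurons carrying a large
#' intranuclear inclusion) uses the published natural-history effect sizes of
#' the Q111 model (Cohen's d of 0, 1.6 and 6.7 at 3, 9 and 12 months); all
#' other effect magnitudes are synthetic placeholders chosen to be plausible
#' for this model, not estimates from any real cohort. Endpoints whose
#' expected effects share a sign are given a moderate positive correlation
#' (`correlation`, default 0.3) so that the multivariate composite endpoint is
#' non-trivial.
#'
#' @param correlation Correlation between same-direction endpoint pairs, in
#'   `[-1, 1]`; endpoints with differing (or zero) expected direction are
#'   uncorrelated.
#' @param n_per_cell Animals per genotype-by-age cell (default 9).
#'
#' @return An object of class `generator_config`: a list with elements
#'   `panel`, `ages`, `n_per_cell`, `effects` (tibble of standardized
#'   genotype effects by endpoint and age), `wt_mean`, `sd` (named numeric
#'   vectors) and `correlation` (matrix).
#' @examples
#' cfg <- q111_config()
#' moments <- config_moments(cfg)
#' @export
q111_config <- function(correlation = 0.3, n_per_cell = 9) {
  assert_scalar_number(correlation, "correlation", -1, 1)
  n_per_cell <- assert_count(n_per_cell, "n_per_cell", lower = 1)
  panel <- q111_panel()
  ages <- c(3, 9, 12)

  # Standardized genotype effect magnitudes |d| by age; signs come from the
  # panel's direction column. Only mhtt_aggregates is anchored to published
  # effect sizes; the rest are synthetic placeholders.
  mag <- rbind(
    scn4b             = c(0, 2.0, 2.6),
    drd1a             = c(0, 1.4, 1.8),
    cnr1              = c(0, 1.2, 1.6),
    darpp32           = c(0, 1.3, 1.7),
    homer1            = c(0, 1.0, 1.4),
    mhtt_aggregates   = c(0, 1.6, 6.7),
    mhtt_area         = c(0, 1.2, 1.5),
    darpp32_intensity = c(0, 0.6, 1.0),
    cell_count        = c(0, 0.0, 0.0),
    neuronal_ratio    = c(0, 0.0, 0.0)
  )
  colnames(mag) <- as.character(ages)
  effects <- tibble::as_tibble(mag, rownames = "endpoint")
  effects <- tidyr::pivot_longer(effects, -"endpoint", names_to = "age_months",
                                 values_to = "magnitude")
  effects$age_months <- as.numeric(effects$age_months)
  effects <- dplyr::left_join(effects, panel[c("endpoint", "direction")],
                              by = "endpoint")
  effects$d <- effects$magnitude * effects$direction
  effects <- effects[c("endpoint", "age_months", "d")]

  wt_mean <- c(scn4b = 1, drd1a = 1, cnr1 = 1, darpp32 = 1, homer1 = 1,
               mhtt_aggregates = 0, mhtt_area = 0, darpp32_intensity = 1000,
               cell_count = 150, neuronal_ratio = 0.55)
  sdv <- c(scn4b = 0.15, drd1a = 0.15, cnr1 = 0.15, darpp32 = 0.15,
           homer1 = 0.15, mhtt_aggregates = 0.04, mhtt_area = 0.3,
           darpp32_intensity = 150, cell_count = 15, neuronal_ratio = 0.05)

  k <- nrow(panel)
  dir <- panel$direction
  corr <- diag(k)
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (i != j && dir[i] != 0 && dir[i] == dir[j]) corr[i, j] <- correlation
  }
  dimnames(corr) <- list(panel$endpoint, panel$endpoint)
  ev <- eigen(corr, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10) {
    stop("endpoint correlation matrix is not positive semidefinite", call. = FALSE)
  }

  structure(
    list(panel = panel, ages = ages, n_per_cell = n_per_cell,
         effects = effects, wt_mean = wt_mean, sd = sdv, correlation = corr),
    class = "generator_config"
  )
}

#' Build a moments set from a generator configuration
#'
#' Expands a [q111_config()]-style configuration into the per-cell mean
#' vectors and covariance matrices used by the trial simulator. For each age,
#' the wild-type baseline cell uses the configured wild-type means; the
#' heterozygote baseline cell shifts each endpoint by `d * sd`, where `d` is
#' the configured (signed) standardized genotype effect. The covariance is
#' shared across cells: `diag(sd) %*% correlation %*% diag(sd)`.
#'
#' @param config A `generator_config` object.
#' @return A [moments_set()] with baseline wild-type and heterozygote cells at
#'   every configured age.
#' @export
config_moments <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  panel <- config$panel
  eps <- panel$endpoint
  sdv <- config$sd[eps]
  cov <- diag(sdv, nrow = length(eps)) %*% config$correlation[eps, eps] %*%
    diag(sdv, nrow = length(eps))
  dimnames(cov) <- list(eps, eps)

  cells <- purrr::map(config$ages, function(age) {
    d <- config$effects[config$effects$age_months == age, ]
    d <- d$d[match(eps, d$endpoint)]
    mu_wt <- config$wt_mean[eps]
    mu_het <- mu_wt + d * sdv
    list(
      cell_moments("WT", age, "baseline", mean = mu_wt, cov = cov, n_source = 0L),
      cell_moments("HET", age, "baseline", mean = mu_het, cov = cov, n_source = 0L)
    )
  })
  moments_set(panel, purrr::flatten(cells))
}
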