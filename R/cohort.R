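#' Draw a synthetic cohort from per-cell moments
#'
#' For each requested design cell, draws `n_per_cell` animals from the
#' multivariate normal distribution with that cell's mean vector and
#' covariance matrix (via [MASS::mvrnorm()]). Each cell is sampled from its
#' own RNG stream derived deterministically from `(seed, cell label)`, so the
#' same seed reproduces the same table byte-for-byte regardless of cell order.
#'
#' @param moments A [moments_set()].
#' @param n_per_cell Number of animals to draw per cell (>= 0; 0 returns an
#'   empty table with the full header).
#' @param seed Integer seed.
#' @param cells Optional tibble with columns `genotype`, `age_months`, `arm`
#'   selecting which cells to sample; default all cells in `moments`.
#'
#' @return A cohort tibble: one row per animal with columns `animal_id`,
#'   `genotype`, `age_months`, `sex` (`NA` for synthetic animals), `arm`, and
#'   one numeric column per endpoint.
#' @examples
#' m <- config_moments(q111_config())
#' cohort <- sample_cohort(m, n_per_cell = 9, seed = 1)
#' @export
sample_cohort <- function(moments, n_per_cell, seed, cells = NULL) {
  stopifnot(inherits(moments, "moments_set"))
  n_per_cell <- assert_count(n_per_cell, "n_per_cell", lower = 0)
  eps <- moments$endpoints$endpoint
  if (is.null(cells)) {
    cells <- moments$cells[c("genotype", "age_months", "arm")]
  }
  rows <- purrr::pmap(cells, function(genotype, age_months, arm, ...) {
    cl <- moments_cell(moments, genotype, age_months, arm) # errors if absent
    meta <- tibble::tibble(
      animal_id = sprintf("%s_%s_%gmo_%03d", genotype, arm, age_months,
                          seq_len(n_per_cell)),
      genotype = genotype, age_months = age_months,
      sex = NA_character_, arm = arm
    )
    if (n_per_cell == 0) {
      vals <- matrix(numeric(0), nrow = 0, ncol = length(eps),
                     dimnames = list(NULL, eps))
    } else {
      set.seed(derive_seed(seed, "cell", genotype, age_months, arm))
      vals <- tryCatch(
        MASS::mvrnorm(n = n_per_cell, mu = cl$mean, Sigma = cl$cov),
        error = function(e) e
      )
      if (inherits(vals, "error") || !is.numeric(vals)) {
        stop(sprintf("covariance of cell %s is not positive semidefinite; repair with repair_psd()",
                     cell_key(genotype, age_months, arm)), call. = FALSE)
      }
      if (n_per_cell == 1) vals <- matrix(vals, nrow = 1)
      colnames(vals) <- eps
    }
    dplyr::bind_cols(meta, tibble::as_tibble(vals))
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    out <- tibble::tibble(animal_id = character(), genotype = character(),
                          age_months = numeric(), sex = character(),
                          arm = character())
    for (e in eps) out[[e]] <- numeric()
  }
  out
}

#' Estimate per-cell moments from a cohort table
#'
#' Groups the cohort by the cell-label columns and computes, per group, the
#' sample mean and the unbiased (n - 1) sample covariance of the endpoint
#' columns. With missing values, covariance is computed from
#' pairwise-complete observations and then projected back to the
#' positive-semidefinite cone by eigenvalue clipping ([repair_psd()]).
#' The number of animals in each group is recorded as `n_source`.
#'
#' @param cohort A cohort tibble (see [sample_cohort()] for the layout).
#' @param endpoints Character vector of endpoint columns; default: every
#'   column after the metadata columns.
#' @param group_by Cell-label columns to group on; defaults to genotype, age
#'   and arm (sexes pooled). Missing grouping columns are ignored with the
#'   exception of `genotype`, which is required.
#'
#' @return A [moments_set()] with one cell per observed group.
#' @export
estimate_moments <- function(cohort, endpoints = NULL,
                             group_by = c("genotype", "age_months", "arm")) {
  stopifnot(is.data.frame(cohort))
  meta_cols <- c("animal_id", "genotype", "age_months", "sex", "arm")
  if (is.null(endpoints)) {
    endpoints <- setdiff(names(cohort), meta_cols)
  }
  if (!length(endpoints)) stop("no endpoint columns found", call. = FALSE)
  if (!"genotype" %in% names(cohort)) {
    stop("cohort must have a `genotype` column", call. = FALSE)
  }
  group_by <- intersect(group_by, names(cohort))
  if (anyDuplicated(cohort$animal_id)) {
    stop("`animal_id` values must be unique", call. = FALSE)
  }

  groups <- dplyr::group_split(dplyr::group_by(
    cohort, dplyr::across(dplyr::all_of(group_by))))
  cells <- purrr::map(groups, function(g) {
    age <- if ("age_months" %in% group_by) g$age_months[1] else NA_real_
    arm <- if ("arm" %in% group_by) g$arm[1] else "baseline"
    label <- cell_key(g$genotype[1], age, arm)
    x <- as.matrix(g[endpoints])
    n_ok <- colSums(!is.na(x))
    if (any(n_ok == 0)) {
      stop(sprintf("endpoint(s) entirely missing in group %s: %s", label,
                   paste(endpoints[n_ok == 0], collapse = ", ")),
           call. = FALSE)
    }
    if (any(n_ok < 2)) {
      stop(sprintf("group %s has fewer than 2 usable rows for endpoint(s): %s",
                   label, paste(endpoints[n_ok < 2], collapse = ", ")),
           call. = FALSE)
    }
    mu <- colMeans(x, na.rm = TRUE)
    cv <- stats::cov(x, use = "pairwise.complete.obs")
    if (anyNA(cv)) {
      stop(sprintf("group %s has endpoint pairs with no joint observations",
                   label), call. = FALSE)
    }
    cell_moments(g$genotype[1], age, arm, mean = mu, cov = repair_psd(cv),
                 n_source = nrow(g))
  })
  panel <- endpoint_panel(endpoints)
  moments_set(panel, cells)
}

#' Read and write wide cohort CSV tables
#'
#' The wide cohort format has required columns `animal_id`, `genotype`,
#' `age_months`, `sex`, `arm` followed by one numeric column per endpoint.
#' Empty strings encode missing values; a header row is mandatory.
#'
#' @param path File path.
#' @param cohort A cohort tibble.
#' @return `read_cohort()` returns a cohort tibble; `write_cohort()` returns
#'   `cohort` invisibly.
#' @export
read_cohort <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE, na = c("", "NA"))
  required <- c("animal_id", "genotype", "age_months", "sex", "arm")
  miss <- setdiff(required, names(out))
  if (length(miss)) {
    stop("cohort CSV is missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  out$animal_id <- as.character(out$animal_id)
  out$sex <- as.character(out$sex)
  out
}

#' @rdname read_cohort
#' @export
write_cohort <- function(cohort, path) {
  readr::write_csv(cohort, path, na = "")
  invisible(cohort)
}
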