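#' Per-cell multivariate moments
#'
#' A `moments_set` stores, for each design cell (genotype by age by arm), the
#' mean vector and covariance matrix of a panel of endpoints. It is the
#' interface between natural-history data and the trial simulator: cells can
#' be estimated from a cohort with [estimate_moments()] or constructed
#' synthetically (e.g. via [config_moments()]), and cohorts are drawn from
#' them with [sample_cohort()].
#'
#' @param endpoints An endpoint panel tibble ([endpoint_panel()]), or a
#'   character vector of endpoint names.
#' @param cells A list of cells created with [cell_moments()].
#'
#' @return An object of class `moments_set`: list with elements `endpoints`
#'   (panel tibble) and `cells` (tibble with columns `genotype`, `age_months`,
#'   `arm`, `n_source` and list-columns `mean`, `cov`).
#' @export
moments_set <- function(endpoints, cells) {
  if (is.character(endpoints)) endpoints <- endpoint_panel(endpoints)
  stopifnot(is.data.frame(endpoints), all(c("endpoint", "direction") %in%
                                            names(endpoints)))
  eps <- endpoints$endpoint
  k <- length(eps)
  rows <- purrr::map(cells, function(cl) {
    stopifnot(inherits(cl, "cell_moments"))
    if (length(cl$mean) != k || !identical(dim(cl$cov), c(k, k))) {
      stop(sprintf("cell %s does not conform to the %d-endpoint panel",
                   cell_key(cl$genotype, cl$age_months, cl$arm), k),
           call. = FALSE)
    }
    mu <- cl$mean
    names(mu) <- eps
    cov <- cl$cov
    dimnames(cov) <- list(eps, eps)
    tibble::tibble(genotype = cl$genotype, age_months = cl$age_months,
                   arm = cl$arm, n_source = cl$n_source,
                   mean = list(mu), cov = list(cov))
  })
  cells_tbl <- dplyr::bind_rows(rows)
  if (nrow(cells_tbl) > 0 &&
      anyDuplicated(cells_tbl[c("genotype", "age_months", "arm")])) {
    stop("duplicate cells in moments set", call. = FALSE)
  }
  structure(list(endpoints = endpoints, cells = cells_tbl),
            class = "moments_set")
}

#' @describeIn moments_set Construct a single cell of a moments set. The
#'   covariance must be symmetric with eigenvalues no smaller than `-1e-10`
#'   (use [repair_psd()] for estimates that fall short).
#' @param genotype `"WT"` or `"HET"`.
#' @param age_months Age of the cell, in months.
#' @param arm `"baseline"` or `"treated"`.
#' @param mean Numeric mean vector over the panel's endpoints (assay units).
#' @param cov Covariance matrix over the panel's endpoints.
#' @param n_source Number of animals the moments were estimated from
#'   (0 for synthetic cells).
#' @export
cell_moments <- function(genotype, age_months, arm = "baseline", mean, cov,
                         n_source = 0L) {
  genotype <- match.arg(genotype, c("WT", "HET"))
  arm <- match.arg(arm, c("baseline", "treated"))
  assert_scalar_number(age_months, "age_months", lower = 0)
  cov <- as.matrix(cov)
  if (!isSymmetric(unname(cov), tol = 1e-8)) {
    stop("covariance matrix must be symmetric", call. = FALSE)
  }
  if (length(mean) != nrow(cov)) {
    stop("mean vector and covariance matrix dimensions differ", call. = FALSE)
  }
  ev <- eigen((cov + t(cov)) / 2, symmetric = TRUE, only.values = TRUE)$values
  if (length(ev) && min(ev) < -1e-10 * max(1, abs(max(ev)))) {
    stop("covariance matrix is not positive semidefinite; use repair_psd()",
         call. = FALSE)
  }
  mu <- as.numeric(mean)
  names(mu) <- names(mean) %||% rownames(cov)
  structure(list(genotype = genotype, age_months = as.numeric(age_months),
                 arm = arm, mean = mu, cov = cov,
                 n_source = as.integer(n_source)),
            class = "cell_moments")
}

cell_key <- function(genotype, age_months, arm) {
  sprintf("%s/%gmo/%s", genotype, age_months, arm)
}

#' Clip a symmetric matrix to the positive-semidefinite cone
#'
#' Eigenvalue-clipping repair: symmetrizes the input, sets negative
#' eigenvalues to zero and reconstructs. Used after pairwise-complete
#' covariance estimation, which need not produce a valid covariance matrix.
#'
#' @param x A square numeric matrix.
#' @return A symmetric positive-semidefinite matrix with the same dimnames.
#' @export
repair_psd <- function(x) {
  x <- as.matrix(x)
  stopifnot(nrow(x) == ncol(x), !anyNA(x))
  s <- (x + t(x)) / 2
  e <- eigen(s, symmetric = TRUE)
  vals <- pmax(e$values, 0)
  out <- e$vectors %*% diag(vals, nrow = length(vals)) %*% t(e$vectors)
  out <- (out + t(out)) / 2
  dimnames(out) <- dimnames(x)
  out
}

#' Look up one cell of a moments set
#'
#' @param moments A `moments_set`.
#' @inheritParams cell_moments
#' @return The matching `cell_moments` object; error naming the cell if absent.
#' @export
moments_cell <- function(moments, genotype, age_months, arm = "baseline") {
  stopifnot(inherits(moments, "moments_set"))
  i <- which(moments$cells$genotype == genotype &
               moments$cells$age_months == age_months &
               moments$cells$arm == arm)
  if (length(i) != 1) {
    stop(sprintf("cell %s not present in moments set",
                 cell_key(genotype, age_months, arm)), call. = FALSE)
  }
  row <- moments$cells[i, ]
  cell_moments(row$genotype, row$age_months, row$arm, mean = row$mean[[1]],
               cov = row$cov[[1]], n_source = row$n_source)
}

#' Restrict a moments set to a subset of endpoints
#'
#' Taking the corresponding marginal of each cell's multivariate normal:
#' means are subset, covariances are the matching submatrices.
#'
#' @param moments A `moments_set`.
#' @param endpoints Character vector of endpoint names to keep.
#' @return A `moments_set` over the requested endpoints, in the given order.
#' @export
subset_moments <- function(moments, endpoints) {
  stopifnot(inherits(moments, "moments_set"))
  missing_eps <- setdiff(endpoints, moments$endpoints$endpoint)
  if (length(missing_eps)) {
    stop("unknown endpoint(s): ", paste(missing_eps, collapse = ", "),
         call. = FALSE)
  }
  panel <- moments$endpoints[match(endpoints, moments$endpoints$endpoint), ]
  cells <- purrr::pmap(moments$cells, function(genotype, age_months, arm,
                                               n_source, mean, cov) {
    cell_moments(genotype, age_months, arm, mean = mean[endpoints],
                 cov = cov[endpoints, endpoints, drop = FALSE],
                 n_source = n_source)
  })
  moments_set(panel, cells)
}

#' @export
print.moments_set <- function(x, ...) {
  cat(sprintf("<moments_set: %d endpoints, %d cells>\n",
              nrow(x$endpoints), nrow(x$cells)))
  cat("endpoints:", paste(x$endpoints$endpoint, collapse = ", "), "\n")
  print(x$cells[c("genotype", "age_months", "arm", "n_source")])
  invisible(x)
}

#' Tidy a moments set into a long tibble
#'
#' One row per cell-by-endpoint combination with the cell mean and standard
#' deviation (square root of the diagonal of the cell covariance).
#'
#' @param x A `moments_set`.
#' @param ... Unused.
#' @return A tibble with columns `genotype`, `age_months`, `arm`, `n_source`,
#'   `endpoint`, `mean`, `sd`.
#' @export
tidy.moments_set <- function(x, ...) {
  purrr::pmap_dfr(x$cells, function(genotype, age_months, arm, n_source,
                                    mean, cov) {
    tibble::tibble(genotype = genotype, age_months = age_months, arm = arm,
                   n_source = n_source, endpoint = names(mean),
                   mean = unname(mean), sd = sqrt(pmax(diag(cov), 0)))
  })
}

#' Write and read moments sets as JSON
#'
#' The on-disk form is a single JSON object:
#' `{"endpoints": [...], "cells": [{"genotype", "age_months", "arm", "n",
#' "mean": [...], "cov": [[...]]}, ...]}`.
#'
#' @param moments A `moments_set`.
#' @param path File path.
#' @return `write_moments()` returns `moments` invisibly; `read_moments()`
#'   returns a `moments_set`.
#' @export
write_moments <- function(moments, path) {
  stopifnot(inherits(moments, "moments_set"))
  obj <- list(
    endpoints = moments$endpoints,
    cells = purrr::pmap(moments$cells, function(genotype, age_months, arm,
                                                n_source, mean, cov) {
      list(genotype = genotype, age_months = age_months, arm = arm,
           n = n_source, mean = unname(mean), cov = unname(cov))
    })
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(moments)
}

#' @rdname write_moments
#' @export
read_moments <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyMatrix = TRUE)
  panel <- endpoint_panel(obj$endpoints$endpoint,
                          obj$endpoints$assay_class %||% "transcript",
                          obj$endpoints$direction %||% 0L)
  cells_raw <- obj$cells
  if (is.data.frame(cells_raw)) {
    cells <- purrr::pmap(cells_raw, function(genotype, age_months, arm, n,
                                             mean, cov) {
      cell_moments(genotype, age_months, arm, mean = mean,
                   cov = as.matrix(cov), n_source = n)
    })
  } else {
    cells <- purrr::map(cells_raw, function(cl) {
      cell_moments(cl$genotype, cl$age_months, cl$arm, mean = unlist(cl$mean),
                   cov = as.matrix(cl$cov), n_source = cl$n)
    })
  }
  moments_set(panel, cells)
}
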