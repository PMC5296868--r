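test_that("the built-in configuration matches the emulated study design", {
  cfg <- q111_config()
  expect_setequal(cfg$panel$endpoint,
                  c("scn4b", "drd1a", "cnr1", "darpp32", "homer1",
                    "mhtt_aggregates", "mhtt_area", "darpp32_intensity",
                    "cell_count", "neuronal_ratio"))
  expect_equal(cfg$ages, c(3, 9, 12))
  expect_equal(cfg$n_per_cell, 9L)
  # aggregate-fraction genotype effects anchored at 0 / 1.6 / 6.7
  agg <- cfg$effects[cfg$effects$endpoint == "mhtt_aggregates", ]
  expect_equal(abs(agg$d[order(agg$age_months)]), c(0, 1.6, 6.7))
  # no genotype effect on any endpoint at 3 months
  expect_true(all(cfg$effects$d[cfg$effects$age_months == 3] == 0))
  # correlation: symmetric PSD, unit diagonal, 0.3 among same-direction pairs
  expect_true(isSymmetric(cfg$correlation))
  expect_equal(unname(diag(cfg$correlation)), rep(1, 10))
  expect_gte(min(eigen(cfg$correlation, symmetric = TRUE)$values), -1e-10)
  expect_equal(cfg$correlation["scn4b", "drd1a"], 0.3)
  expect_equal(cfg$correlation["scn4b", "mhtt_aggregates"], 0)
  # pure function: identical on repeated calls
  expect_identical(cfg, q111_config())
})

test_that("config_moments builds means shifted by d * sd", {
  cfg <- q111_config()
  m <- config_moments(cfg)
  wt <- moments_cell(m, "WT", 12, "baseline")
  het <- moments_cell(m, "HET", 12, "baseline")
  expect_equal(het$mean[["mhtt_aggregates"]],
               wt$mean[["mhtt_aggregates"]] + 6.7 * cfg$sd[["mhtt_aggregates"]])
  expect_equal(het$mean[["scn4b"]],
               wt$mean[["scn4b"]] - 2.6 * cfg$sd[["scn4b"]])
  expect_equal(het$cov, wt$cov)
})

test_that("sample_cohort handles empty and degenerate cases", {
  m <- toy_moments()
  empty <- sample_cohort(m, 0, seed = 1)
  expect_equal(nrow(empty), 0)
  expect_named(empty, c("animal_id", "genotype", "age_months", "sex", "arm",
                        "e1", "e2"))
  # zero covariance: every animal sits exactly on the cell mean
  mz <- moments_set(endpoint_panel(c("e1", "e2")), list(
    cell_moments("WT", 12, "baseline", mean = c(3, -1),
                 cov = matrix(0, 2, 2))))
  z <- sample_cohort(mz, 5, seed = 1)
  expect_equal(z$e1, rep(3, 5))
  expect_equal(z$e2, rep(-1, 5))
})

test_that("sample_cohort is reproducible and cell-order invariant", {
  m <- toy_moments()
  a <- sample_cohort(m, 7, seed = 11)
  b <- sample_cohort(m, 7, seed = 11)
  expect_identical(a, b)
  expect_false(identical(a, sample_cohort(m, 7, seed = 12)))
  # reversing the requested cell order permutes rows but not values
  cells_rev <- m$cells[2:1, c("genotype", "age_months", "arm")]
  c2 <- sample_cohort(m, 7, seed = 11, cells = cells_rev)
  expect_identical(dplyr::arrange(a, animal_id), dplyr::arrange(c2, animal_id))
})

test_that("sample_cohort errors name the missing cell", {
  m <- toy_moments()
  bad <- data.frame(genotype = "WT", age_months = 9, arm = "baseline")
  expect_error(sample_cohort(m, 3, seed = 1, cells = bad), "WT/9mo/baseline")
})

test_that("estimate_moments reproduces hand-computed moments", {
  cohort <- tibble::tibble(
    animal_id = c("a1", "a2"), genotype = "HET", age_months = 12,
    sex = NA_character_, arm = "baseline", e1 = c(0, 2), e2 = c(0, 2))
  m <- estimate_moments(cohort)
  cl <- moments_cell(m, "HET", 12, "baseline")
  expect_equal(unname(cl$mean), c(1, 1))
  expect_equal(unname(cl$cov), matrix(2, 2, 2))
  expect_equal(cl$n_source, 2L)
})

test_that("a constant endpoint yields zero variance and covariances", {
  cohort <- tibble::tibble(
    animal_id = sprintf("a%d", 1:6), genotype = "WT", age_months = 3,
    sex = NA_character_, arm = "baseline",
    e1 = c(1, 2, 3, 4, 5, 6), e2 = 7)
  cl <- moments_cell(estimate_moments(cohort), "WT", 3, "baseline")
  expect_equal(cl$cov["e2", "e2"], 0)
  expect_equal(cl$cov["e1", "e2"], 0)
})

test_that("estimate_moments rejects undersized or empty groups", {
  base <- tibble::tibble(
    animal_id = c("a1", "a2"), genotype = "WT", age_months = 3,
    sex = NA_character_, arm = "baseline", e1 = c(1, NA), e2 = c(1, 2))
  expect_error(estimate_moments(base), "fewer than 2 usable rows")
  base$e1 <- NA_real_
  expect_error(estimate_moments(base), "entirely missing.*e1")
})

test_that("affine closure: scaling a column scales mean, var and cov", {
  m <- toy_moments()
  cohort <- sample_cohort(m, 50, seed = 3)
  est1 <- moments_cell(estimate_moments(cohort), "WT", 12, "baseline")
  cohort$e1 <- cohort$e1 * 10
  est2 <- moments_cell(estimate_moments(cohort), "WT", 12, "baseline")
  expect_equal(est2$mean[["e1"]], 10 * est1$mean[["e1"]])
  expect_equal(est2$cov["e1", "e1"], 100 * est1$cov["e1", "e1"])
  expect_equal(est2$cov["e1", "e2"], 10 * est1$cov["e1", "e2"])
  expect_equal(est2$cov["e2", "e2"], est1$cov["e2", "e2"])
})

test_that("pairwise-complete covariance is repaired to PSD", {
  set.seed(5)
  n <- 40
  cohort <- tibble::tibble(
    animal_id = sprintf("a%d", 1:n), genotype = "WT", age_months = 3,
    sex = NA_character_, arm = "baseline",
    e1 = rnorm(n), e2 = rnorm(n), e3 = rnorm(n))
  # punch disjoint holes so pairwise covariances disagree
  cohort$e1[1:12] <- NA
  cohort$e2[13:24] <- NA
  cohort$e3[25:36] <- NA
  cl <- moments_cell(estimate_moments(cohort), "WT", 3, "baseline")
  ev <- eigen(cl$cov, symmetric = TRUE, only.values = TRUE)$values
  expect_gte(min(ev), -1e-12)
  expect_true(isSymmetric(cl$cov))
})

test_that("generate -> estimate round trip recovers the moments", {
  m <- toy_moments()
  cohort <- sample_cohort(m, 1e5, seed = 99)
  est <- estimate_moments(cohort)
  for (g in c("WT", "HET")) {
    truth <- moments_cell(m, g, 12, "baseline")
    hat <- moments_cell(est, g, 12, "baseline")
    expect_lt(max(abs(hat$mean - truth$mean) / abs(truth$mean)), 0.01)
    expect_lt(max(abs(hat$cov - truth$cov) / max(abs(truth$cov))), 0.05)
  }
})

test_that("cohort CSV and moments JSON round-trip", {
  m <- toy_moments()
  cohort <- sample_cohort(m, 5, seed = 2)
  cohort$e1[2] <- NA
  csv <- withr::local_tempfile(fileext = ".csv")
  write_cohort(cohort, csv)
  back <- read_cohort(csv)
  expect_equal(as.data.frame(back), as.data.frame(cohort))

  js <- withr::local_tempfile(fileext = ".json")
  write_moments(m, js)
  m2 <- read_moments(js)
  expect_equal(moments_cell(m2, "HET", 12, "baseline")$mean,
               moments_cell(m, "HET", 12, "baseline")$mean)
  expect_equal(moments_cell(m2, "HET", 12, "baseline")$cov,
               moments_cell(m, "HET", 12, "baseline")$cov)
})

test_that("constructors validate their invariants", {
  expect_error(endpoint_panel(c("a", "a")), "unique")
  expect_error(endpoint_panel("a", direction = 2), "-1, 0 or \\+1")
  expect_error(cell_moments("WT", 3, "baseline", mean = c(0, 0),
                            cov = matrix(c(1, 2, 3, 1), 2, 2)), "symmetric")
  expect_error(cell_moments("WT", 3, "baseline", mean = 0,
                            cov = matrix(-1, 1, 1)), "positive semidefinite")
  neg <- matrix(c(1, 2, 2, 1), 2, 2) # eigenvalues 3, -1
  fixed <- repair_psd(neg)
  expect_gte(min(eigen(fixed, symmetric = TRUE)$values), -1e-12)
})
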