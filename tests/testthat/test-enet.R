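# Common fixture: one strongly informative endpoint plus pure-noise ones.
signal_cohort <- function(n = 9, d = 6.7, noise = 9, seed = 101) {
  set.seed(seed)
  k <- noise + 1
  x <- matrix(rnorm(2 * n * k), 2 * n, k)
  x[(n + 1):(2 * n), 1] <- x[(n + 1):(2 * n), 1] + d
  colnames(x) <- c("signal", sprintf("noise%d", seq_len(noise)))
  out <- tibble::as_tibble(x)
  out$genotype <- rep(c("WT", "HET"), each = n)
  out
}

enet_eps <- function(cohort) setdiff(names(cohort), "genotype")

test_that("an overwhelming penalty zeroes all weights, keeping the log-odds", {
  coh <- signal_cohort(n = 9)
  fit <- fit_enet(coh, endpoints = enet_eps(coh), lambda = 50)
  expect_equal(fit$n_nonzero, 0)
  expect_true(all(fit$weights == 0))
  expect_equal(fit$intercept, qlogis(0.5), tolerance = 1e-8)
  # unbalanced classes: intercept is the class-balance log-odds
  coh2 <- dplyr::bind_rows(coh, coh[coh$genotype == "HET", ][1:6, ])
  coh2$animal_id <- NULL
  fit2 <- fit_enet(coh2, endpoints = enet_eps(coh), lambda = 50)
  expect_equal(fit2$intercept, qlogis(mean(coh2$genotype == "HET")),
               tolerance = 1e-8)
})

test_that("the informative endpoint takes the largest weight", {
  coh <- signal_cohort(n = 9, d = 6.7)
  fit <- fit_enet(coh, endpoints = enet_eps(coh), seed = 2)
  w <- abs(fit$weights)
  expect_equal(names(which.max(w)), "signal")
  expect_gt(fit$n_nonzero, 0)
  expect_equal(fit$positive_class, "HET")
})

test_that("ridge-leaning fits share weight across duplicated endpoints", {
  coh <- signal_cohort(n = 20, d = 3, noise = 2, seed = 7)
  lam <- 0.05
  single <- fit_enet(coh, endpoints = enet_eps(coh), alpha_mix = 0,
                     lambda = lam)
  dup <- coh
  dup$signal_copy <- dup$signal
  double <- fit_enet(dup, endpoints = c(enet_eps(coh), "signal_copy"),
                     alpha_mix = 0, lambda = lam)
  w1 <- double$weights[["signal"]]
  w2 <- double$weights[["signal_copy"]]
  expect_equal(w1, w2, tolerance = 1e-4) # grouping effect
  expect_lt(abs(w1), abs(single$weights[["signal"]]))
  # exact-duplicate ridge columns are equivalent to a single copy at half
  # the penalty: the split weights sum to that fit
  half <- fit_enet(coh, endpoints = enet_eps(coh), alpha_mix = 0,
                   lambda = lam / 2)
  expect_equal(w1 + w2, half$weights[["signal"]], tolerance = 0.01)
})

test_that("with vanishing penalty the fit matches unpenalized logistic", {
  set.seed(9)
  n <- 60
  x <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, c("e1", "e2", "e3")))
  y <- rbinom(n, 1, plogis(0.3 + 0.8 * x[, 1] - 0.5 * x[, 2]))
  dat <- tibble::as_tibble(x)
  dat$genotype <- ifelse(y == 1, "HET", "WT")
  fit <- fit_enet(dat, endpoints = c("e1", "e2", "e3"), alpha_mix = 0,
                  lambda = 1e-7)
  oracle <- stats::glm(y ~ scale(x), family = stats::binomial)
  expect_lt(max(abs(fit$weights - unname(coef(oracle)[-1]))), 1e-4)
  expect_lt(abs(fit$intercept - unname(coef(oracle)[1])), 1e-4)
})

test_that("the penalty path is weight-norm non-increasing toward large λ", {
  coh <- signal_cohort(n = 15, d = 2, noise = 3, seed = 5)
  lams <- c(0.001, 0.01, 0.1, 1, 10)
  norms <- vapply(lams, function(l) {
    sum(abs(fit_enet(coh, endpoints = enet_eps(coh), lambda = l)$weights))
  }, numeric(1))
  expect_true(all(diff(norms) <= 1e-8))
  expect_equal(norms[length(norms)], 0)
})

test_that("constant endpoints are dropped with a warning", {
  coh <- signal_cohort(n = 9)
  coh$flat <- 1
  expect_warning(
    fit <- fit_enet(coh, endpoints = c(enet_eps(coh))),
    "constant")
  expect_false("flat" %in% fit$endpoints)
  solo <- coh[c("flat", "genotype")]
  expect_error(suppressWarnings(fit_enet(solo, endpoints = "flat")),
               "usable")
  one_class <- coh[coh$genotype == "WT", ]
  expect_error(fit_enet(one_class, endpoints = enet_eps(coh)), "class")
})

test_that("composite scores follow the stated linear predictor", {
  fit <- structure(list(endpoints = c("e1", "e2"), center = c(e1 = 1, e2 = 2),
                        scale = c(e1 = 2, e2 = 4), weights = c(e1 = 3, e2 = -1),
                        intercept = 0.5, alpha_mix = 0.5, lambda = 0.1,
                        n_nonzero = 2L, positive_class = "HET", n_obs = 4L),
                   class = "enet_model")
  dat <- tibble::tibble(e1 = c(1, 3), e2 = c(2, 10))
  out <- composite_score(dat, fit)
  expect_equal(out$score, c(0.5, 0.5 + 3 * 1 - 1 * 2))
  expect_error(composite_score(dat[, "e1"], fit), "e2")
  # zero-weight model scores are constant
  fit$weights[] <- 0
  expect_equal(unique(composite_score(dat, fit)$score), 0.5)
})

test_that("scores are invariant to endpoint rescaling with refit", {
  coh <- signal_cohort(n = 12, d = 3, noise = 2, seed = 13)
  eps <- enet_eps(coh)
  f1 <- fit_enet(coh, endpoints = eps, lambda = 0.05)
  s1 <- composite_score(coh, f1)$score
  coh2 <- coh
  coh2$signal <- coh2$signal * 1000
  f2 <- fit_enet(coh2, endpoints = eps, lambda = 0.05)
  s2 <- composite_score(coh2, f2)$score
  expect_equal(s1, s2, tolerance = 1e-6)
})

test_that("cross-validated accuracy separates signal from chance", {
  # no signal: held-out accuracy near 1/2
  set.seed(15)
  null <- tibble::tibble(e1 = rnorm(20), e2 = rnorm(20),
                         genotype = rep(c("WT", "HET"), 10))
  acc0 <- cv_accuracy(null, endpoints = c("e1", "e2"), seed = 3)
  expect_lt(acc0$accuracy_cv, 0.5 + 1.96 * sqrt(0.25 / 20) + 0.05)
  # one d = 6.7 endpoint: held-out accuracy >= 0.9
  coh <- signal_cohort(n = 9, d = 6.7)
  acc <- cv_accuracy(coh, endpoints = enet_eps(coh), seed = 3)
  expect_gte(acc$accuracy_cv, 0.9)
  expect_gte(acc$accuracy_apparent, 0.9)
  # identical endpoint values across classes cannot be separated
  dup <- null
  dup$e1 <- rep(c(1, 2, 3, 4, 5), 4)
  dup$e2 <- rep(c(5, 4, 3, 2, 1), 4)
  accd <- cv_accuracy(dup, endpoints = c("e1", "e2"), seed = 3)
  expect_lte(accd$accuracy_cv, 0.5 + 0.15)
})

test_that("composite power is calibrated at the null", {
  m <- config_moments(q111_config())
  est <- estimate_power_multi(m, rescue_model(0), trial_design(10),
                              reps = 400, seed = 67)
  expect_lt(abs(est$power - 0.05),
            3 * max(est$mc_se, sqrt(0.05 * 0.95 / 400)))
})

test_that("no-signal moments give near-null power and empty models", {
  m <- config_moments(q111_config())
  est <- estimate_power_multi(m, rescue_model(0.5),
                              trial_design(10, age_months = 3),
                              reps = 300, seed = 71)
  # zero-weight fits count as non-detections, so this is conservative
  expect_lte(est$power, 0.05 + 3 * sqrt(0.05 * 0.95 / 300))
  # the trained classifier typically keeps no endpoints at 3 months
  coh3 <- sample_cohort(m, 18, seed = 73,
                        cells = data.frame(genotype = c("WT", "HET"),
                                           age_months = 3, arm = "baseline"))
  nz <- vapply(1:11, function(i) {
    fit_enet(coh3, seed = i)$n_nonzero
  }, integer(1))
  expect_equal(stats::median(nz), 0)
})

test_that("single-signal composite power tracks the univariate power", {
  d <- 2.5
  cov <- diag(c(1, 1, 1))
  dimnames(cov) <- list(c("signal", "n1", "n2"), c("signal", "n1", "n2"))
  m <- moments_set(
    endpoint_panel(c("signal", "n1", "n2"), direction = c(1L, 0L, 0L)),
    list(cell_moments("WT", 12, "baseline", mean = c(0, 0, 0), cov = cov),
         cell_moments("HET", 12, "baseline", mean = c(d, 0, 0), cov = cov)))
  uni <- estimate_power(m, "signal", rescue_model(0.5), trial_design(10),
                        reps = 500, seed = 79)
  multi <- estimate_power_multi(m, rescue_model(0.5), trial_design(10),
                                reps = 500, seed = 79)
  expect_lt(abs(multi$power - uni$power), 0.1)
})

test_that("a 1x1 power grid equals the direct call on the derived seed", {
  m <- config_moments(q111_config())
  grid <- power_grid(m, r_grid = 0.5, n_grid = 10, reps = 100, seed = 83)
  direct <- estimate_power_multi(
    m, rescue_model(0.5), trial_design(10), reps = 100,
    seed = rescuepower:::derive_seed(83, "grid", 10L))
  expect_equal(grid$power, direct$power)
  expect_error(power_grid(m, numeric(0), 10), "nonempty")
  expect_error(power_grid(m, 0.5, 10, type = "univariate"), "endpoint")
})

test_that("fixed-model power skips the refit and stays calibrated", {
  m <- toy_moments()
  coh <- sample_cohort(m, 18, seed = 87)
  fit <- fit_enet(coh, endpoints = c("e1", "e2"), seed = 1)
  est0 <- estimate_power_multi(m, rescue_model(0), trial_design(10),
                               reps = 400, seed = 89, fit = fit)
  expect_lt(abs(est0$power - 0.05),
            3 * max(est0$mc_se, sqrt(0.05 * 0.95 / 400)))
  est1 <- estimate_power_multi(m, rescue_model(1), trial_design(10),
                               reps = 200, seed = 91, fit = fit)
  expect_gt(est1$power, est0$power)
})
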