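#' Fit an elastic-net logistic genotype classifier
#'
#' Fits the penalized logistic regression
#' \deqn{\min_\beta -\ell(\beta)/N + \lambda\left[\frac{1-\alpha}{2}
#'   \|\beta\|_2^2 + \alpha \|\beta\|_1\right]}
#' of genotype on the (internally standardized) endpoint columns, via
#' [glmnet::glmnet()]. When `lambda` is not supplied, the penalty is chosen
#' by k-fold cross-validation with stratified folds derived
#' deterministically from `seed` (minimum-deviance rule by default, or the
#' one-standard-error rule). Constant endpoints are dropped with a warning;
#' single-class input is an error. The positive class is `HET` when the
#' labels are `WT`/`HET`, otherwise the second factor level.
#'
#' @param data A cohort tibble (typically the two baseline arms of a trial).
#' @param label Column holding the two-class label (tidy-eval; default
#'   `genotype`).
#' @param endpoints Character vector of endpoint columns; default: every
#'   column after the cohort metadata columns.
#' @param alpha_mix Elastic-net mixing parameter in `[0, 1]`: 0 = ridge,
#'   1 = lasso (default 0.5).
#' @param folds Number of CV folds (>= 2; must not exceed the smaller class).
#' @param lambda Optional fixed penalty (skips CV). Fitted along a warm-start
#'   path ending at the requested value.
#' @param selection CV selection rule: `"min_deviance"` or `"1se"`.
#' @param seed Integer seed for fold assignment.
#' @param nlambda,thresh Path length and convergence threshold passed to
#'   glmnet.
#'
#' @return An object of class `enet_model`: list with `endpoints`, `center`,
#'   `scale` (standardization used at fit time), `weights` (coefficients on
#'   the standardized scale), `intercept`, `alpha_mix`, `lambda`,
#'   `n_nonzero`, `positive_class`, `n_obs`, `dropped` and `seed`.
#' @examples
#' cohort <- sample_cohort(config_moments(q111_config()), 9, seed = 1)
#' fit <- fit_enet(dplyr::filter(cohort, age_months == 12), seed = 1)
#' tidy(fit)
#' @export
fit_enet <- function(data, label = genotype, endpoints = NULL,
                     alpha_mix = 0.5, folds = 5, lambda = NULL,
                     selection = c("min_deviance", "1se"), seed = 1,
                     nlambda = 50, thresh = 1e-9) {
  stopifnot(is.data.frame(data))
  selection <- match.arg(selection)
  assert_scalar_number(alpha_mix, "alpha_mix", lower = 0, upper = 1)
  folds <- assert_count(folds, "folds", lower = 2)
  meta_cols <- c("animal_id", "genotype", "age_months", "sex", "arm")
  if (is.null(endpoints)) endpoints <- setdiff(names(data), meta_cols)
  y_raw <- as.character(dplyr::pull(data, {{ label }}))
  classes <- unique(y_raw)
  if (length(classes) < 2) {
    stop("both classes must be present to fit a classifier", call. = FALSE)
  }
  if (length(classes) > 2) stop("label must be two-class", call. = FALSE)
  levels_ord <- if (setequal(classes, c("WT", "HET"))) c("WT", "HET") else
    sort(classes)
  y <- factor(y_raw, levels = levels_ord)

  x <- as.matrix(data[endpoints])
  if (anyNA(x)) stop("endpoint columns must be complete", call. = FALSE)
  fit_enet_impl(x, y, alpha_mix = alpha_mix, folds = folds, lambda = lambda,
                selection = selection, seed = seed, nlambda = nlambda,
                thresh = thresh)
}

# Matrix-level core of fit_enet(); x must be complete, y a 2-level factor.
fit_enet_impl <- function(x, y, alpha_mix, folds, lambda, selection, seed,
                          nlambda, thresh) {
  endpoints <- colnames(x)
  levels_ord <- levels(y)
  ctr <- colMeans(x)
  scl <- apply(x, 2, stats::sd)
  constant <- scl == 0
  if (any(constant)) {
    warning("dropping constant endpoint(s): ",
            paste(endpoints[constant], collapse = ", "), call. = FALSE)
    endpoints <- endpoints[!constant]
    x <- x[, !constant, drop = FALSE]
    ctr <- ctr[!constant]; scl <- scl[!constant]
  }
  if (!length(endpoints)) stop("no usable endpoints", call. = FALSE)
  xs <- scale(x, center = ctr, scale = scl)

  if (is.null(lambda)) {
    if (min(table(y)) < folds) {
      stop("each class must have at least `folds` members", call. = FALSE)
    }
    foldid <- make_foldid(y, folds, seed)
    # glmnet nags about the (deliberately) small class sizes of preclinical
    # arms; silence it, keep everything else
    cv <- tryCatch(
      suppressWarnings(
        glmnet::cv.glmnet(xs, y, family = "binomial", alpha = alpha_mix,
                          foldid = foldid, standardize = FALSE,
                          nlambda = nlambda, thresh = thresh)),
      error = function(e) NULL)
    if (is.null(cv)) {
      # degenerate data (e.g. indistinguishable classes) can abort the CV
      # path; fall back to the fully penalized null model
      fit <- suppressWarnings(
        glmnet::glmnet(xs, y, family = "binomial", alpha = alpha_mix,
                       nlambda = 3, standardize = FALSE, thresh = thresh))
      lam <- max(fit$lambda)
    } else {
      lam <- if (selection == "min_deviance") cv$lambda.min else cv$lambda.1se
      fit <- cv$glmnet.fit
    }
  } else {
    assert_scalar_number(lambda, "lambda", lower = 0)
    lam <- lambda
    # warm-start path down to the requested penalty for a stable solution
    lam_hi <- max(lam * 1000, 1)
    path <- exp(seq(log(lam_hi), log(max(lam, 1e-8)), length.out = 30))
    fit <- suppressWarnings(
      glmnet::glmnet(xs, y, family = "binomial", alpha = alpha_mix,
                     lambda = path, standardize = FALSE, thresh = thresh))
  }
  cf <- as.numeric(stats::coef(fit, s = lam))
  weights <- cf[-1]
  names(weights) <- endpoints

  structure(list(endpoints = endpoints, center = ctr, scale = scl,
                 weights = weights, intercept = cf[1], alpha_mix = alpha_mix,
                 lambda = lam, selection = selection,
                 n_nonzero = sum(weights != 0),
                 positive_class = levels_ord[2], n_obs = nrow(x),
                 dropped = names(constant)[constant] %||% character(0),
                 seed = as.integer(seed)),
            class = "enet_model")
}

# Stratified fold assignment: within each class, indices are shuffled with a
# seed-derived stream and dealt out cyclically.
make_foldid <- function(y, folds, seed) {
  foldid <- integer(length(y))
  set.seed(derive_seed(seed, "folds"))
  for (lv in levels(y)) {
    idx <- which(y == lv)
    foldid[sample(idx)] <- rep_len(seq_len(folds), length(idx))
  }
  foldid
}

#' @export
print.enet_model <- function(x, ...) {
  cat(sprintf("<enet_model: %d endpoints, %d nonzero, alpha_mix = %g, lambda = %.4g>\n",
              length(x$weights), x$n_nonzero, x$alpha_mix, x$lambda))
  print(tidy(x))
  invisible(x)
}

#' Tidy an elastic-net composite model
#'
#' @param x An `enet_model`.
#' @param ... Unused.
#' @return One row per endpoint: `endpoint`, `weight` (standardized scale),
#'   `center`, `scale`.
#' @export
tidy.enet_model <- function(x, ...) {
  tibble::tibble(endpoint = x$endpoints, weight = unname(x$weights),
                 center = unname(x$center), scale = unname(x$scale))
}

#' @export
glance.enet_model <- function(x, ...) {
  tibble::tibble(alpha_mix = x$alpha_mix, lambda = x$lambda,
                 n_nonzero = x$n_nonzero, intercept = x$intercept,
                 positive_class = x$positive_class, n_obs = x$n_obs)
}

#' Score animals with a fitted composite model
#'
#' Adds the linear predictor
#' `intercept + sum(weight_e * (x_e - center_e) / scale_e)` as a `score`
#' column: the composite endpoint of each animal (log-odds of the positive
#' class). Standardization parameters travel with the model, so scores are
#' invariant to affine rescaling of input endpoints with a matching refit.
#'
#' @param data A cohort tibble containing the model's endpoint columns.
#' @param model An `enet_model`.
#' @return `data` with an added numeric `score` column.
#' @export
composite_score <- function(data, model) {
  stopifnot(is.data.frame(data), inherits(model, "enet_model"))
  miss <- setdiff(model$endpoints, names(data))
  if (length(miss)) {
    stop("data is missing model endpoint(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  data$score <- composite_score_vec(as.matrix(data[model$endpoints]), model)
  data
}

composite_score_vec <- function(x, model) {
  xs <- sweep(sweep(x, 2, model$center, "-"), 2, model$scale, "/")
  drop(model$intercept + xs %*% model$weights)
}

#' Cross-validated accuracy of the composite classifier
#'
#' Stratified k-fold cross-validation of the elastic-net genotype classifier:
#' in each fold the model is refit (including its internal penalty selection)
#' on the training folds and held-out animals are classified at a probability
#' threshold of 0.5 (linear predictor > 0). Both the fold-averaged held-out
#' accuracy and the apparent (training-data) accuracy of the full fit are
#' reported.
#'
#' @inheritParams fit_enet
#' @return A one-row tibble: `accuracy_cv`, `accuracy_apparent`, `folds`,
#'   `n_obs`.
#' @export
cv_accuracy <- function(data, label = genotype, endpoints = NULL,
                        alpha_mix = 0.5, folds = 5,
                        selection = c("min_deviance", "1se"), seed = 1) {
  stopifnot(is.data.frame(data))
  selection <- match.arg(selection)
  y_raw <- as.character(dplyr::pull(data, {{ label }}))
  classes <- unique(y_raw)
  if (length(classes) != 2) stop("label must be two-class", call. = FALSE)
  levels_ord <- if (setequal(classes, c("WT", "HET"))) c("WT", "HET") else
    sort(classes)
  y <- factor(y_raw, levels = levels_ord)
  folds <- assert_count(folds, "folds", lower = 2)
  if (min(table(y)) < folds) {
    stop("each class must have at least `folds` members", call. = FALSE)
  }
  foldid <- make_foldid(y, folds, derive_seed(seed, "outer"))

  fold_acc <- vapply(seq_len(folds), function(k) {
    train <- data[foldid != k, , drop = FALSE]
    test <- data[foldid == k, , drop = FALSE]
    inner_folds <- min(folds, min(table(y[foldid != k])))
    fit <- fit_enet(train, label = {{ label }}, endpoints = endpoints,
                    alpha_mix = alpha_mix, folds = inner_folds,
                    selection = selection, seed = derive_seed(seed, "fold", k))
    scr <- composite_score_vec(as.matrix(test[fit$endpoints]), fit)
    pred <- ifelse(scr > 0, levels_ord[2], levels_ord[1])
    mean(pred == as.character(y[foldid == k]))
  }, numeric(1))

  full <- fit_enet(data, label = {{ label }}, endpoints = endpoints,
                   alpha_mix = alpha_mix, folds = folds,
                   selection = selection, seed = seed)
  scr <- composite_score_vec(as.matrix(data[full$endpoints]), full)
  pred <- ifelse(scr > 0, levels_ord[2], levels_ord[1])

  tibble::tibble(accuracy_cv = mean(fold_acc),
                 accuracy_apparent = mean(pred == y_raw),
                 folds = folds, n_obs = nrow(data))
}

#' Monte-Carlo power for the elastic-net composite endpoint
#'
#' Per replicate: simulate the 2x2 factorial trial, train the elastic-net
#' genotype classifier, and test the composite scores of the treated versus
#' baseline heterozygote arms with the pooled-variance t contrast at
#' `alpha`. A replicate whose fitted model has no nonzero weights (a
#' constant composite) counts as a non-detection. By default the classifier
#' is refit per replicate, so the power estimate includes model-selection
#' variability; pass a fixed `fit` for the fixed-model variant.
#'
#' Training data (`train`): the default `"independent"` draws, per
#' replicate, a separate natural-history-style baseline cohort (`n_train`
#' wild-type and `n_train` heterozygote animals) and trains on it, so the
#' detection arms are out-of-sample and the test is exactly calibrated at
#' the null. The alternative `"baseline_arms"` trains on the trial's own
#' baseline arms; because the baseline heterozygotes then appear both in
#' training and in the detection contrast, their scores are optimistically
#' shifted and the null rejection rate exceeds `alpha` — it is provided for
#' comparison, not for design use.
#'
#' @inheritParams estimate_power
#' @param alpha_mix,folds,selection Classifier settings (see [fit_enet()]).
#' @param train `"independent"` (default) or `"baseline_arms"`; see Details.
#' @param n_train Per-genotype size of the independent training cohort;
#'   default 18, the pooled-sex natural-history cell size being emulated.
#' @param fit Optional fixed `enet_model`; when supplied, the per-replicate
#'   refit is skipped and this model scores every trial.
#' @return A one-row `power_estimate` tibble (see [estimate_power()]), with
#'   `endpoint = "composite"`.
#' @export
estimate_power_multi <- function(moments, model, design, reps = 1000,
                                 seed = 1, alpha_mix = 0.5, folds = 5,
                                 selection = c("min_deviance", "1se"),
                                 train = c("independent", "baseline_arms"),
                                 n_train = 18, fit = NULL) {
  reps <- assert_count(reps, "reps", lower = 100)
  selection <- match.arg(selection)
  train <- match.arg(train)
  n_train <- assert_count(n_train, "n_train", lower = 2)
  stopifnot(inherits(design, "trial_design"))
  eps <- moments$endpoints$endpoint
  # rescue once; replicates redraw arms from per-cell streams identical to
  # those of simulate_trial() with the same derived seed
  rescued <- apply_rescue(moments, model, age_months = design$age_months)
  age <- design$age_months
  n <- design$n_per_arm
  cell_wt_b <- moments_cell(rescued, "WT", age, "baseline")
  cell_het_b <- moments_cell(rescued, "HET", age, "baseline")
  cell_het_t <- moments_cell(rescued, "HET", age, "treated")
  n_fit <- if (train == "independent") n_train else n
  y_train <- factor(rep(c("WT", "HET"), each = n_fit),
                    levels = c("WT", "HET"))

  hits <- vapply(seq_len(reps), function(i) {
    rep_seed <- derive_seed(seed, "trial", n, i)
    het_b <- draw_cell(cell_het_b, n, rep_seed)
    het_t <- draw_cell(cell_het_t, n, rep_seed)
    colnames(het_b) <- colnames(het_t) <- eps
    m <- fit
    if (is.null(m)) {
      if (train == "independent") {
        train_seed <- derive_seed(seed, "train", n, i)
        x_tr <- rbind(draw_cell(cell_wt_b, n_train, train_seed),
                      draw_cell(cell_het_b, n_train,
                                derive_seed(train_seed, "het")))
      } else {
        x_tr <- rbind(draw_cell(cell_wt_b, n, rep_seed), het_b)
      }
      colnames(x_tr) <- eps
      m <- tryCatch(
        suppressWarnings(fit_enet_impl(
          x_tr, y_train, alpha_mix = alpha_mix, folds = folds,
          lambda = NULL, selection = selection,
          seed = derive_seed(seed, "fit", i), nlambda = 50, thresh = 1e-9)),
        error = function(e) NULL)
      if (is.null(m)) return(FALSE)
    }
    if (m$n_nonzero == 0) return(FALSE)
    x <- composite_score_vec(het_t[, m$endpoints, drop = FALSE], m)
    y <- composite_score_vec(het_b[, m$endpoints, drop = FALSE], m)
    pooled_t_p(x, y) < design$alpha
  }, logical(1))

  power_estimate(mean(hits), reps, seed, endpoint = "composite",
                 age_months = design$age_months, r = model$r,
                 n_per_arm = design$n_per_arm, alpha = design$alpha,
                 method = "multivariate_enet")
}

#' Power over a rescue-fraction by sample-size grid
#'
#' Runs [estimate_power()] (univariate) or [estimate_power_multi()]
#' (composite) over the Cartesian grid of rescue fractions and per-arm sample
#' sizes. Each grid point's seed is derived from `(seed, n_per_arm)` — not
#' from `r` — so points along the rescue axis share common random numbers,
#' making power curves monotone up to Monte-Carlo noise.
#'
#' @param moments A [moments_set()].
#' @param r_grid Numeric vector of rescue fractions in `[0, 1]`.
#' @param n_grid Integer vector of per-arm sample sizes.
#' @param age_months,alpha Design settings (see [trial_design()]).
#' @param type `"multivariate"` (composite endpoint, the default) or
#'   `"univariate"`.
#' @param endpoint Endpoint name, required for `type = "univariate"`.
#' @param reps Replicates per grid point.
#' @param seed Integer seed.
#' @param ... Further arguments passed to the underlying power estimator
#'   (e.g. `alpha_mix`, `folds`, `fit`).
#' @return A `power_grid` tibble: one `power_estimate` row per grid point.
#' @export
power_grid <- function(moments, r_grid, n_grid, age_months = 12,
                       alpha = 0.05, type = c("multivariate", "univariate"),
                       endpoint = NULL, reps = 1000, seed = 1, ...) {
  type <- match.arg(type)
  if (!length(r_grid) || !length(n_grid)) {
    stop("`r_grid` and `n_grid` must be nonempty", call. = FALSE)
  }
  if (type == "univariate" && is.null(endpoint)) {
    stop("`endpoint` is required for univariate power", call. = FALSE)
  }
  grid <- tidyr::expand_grid(r = as.numeric(r_grid),
                             n_per_arm = as.integer(n_grid))
  out <- purrr::pmap_dfr(grid, function(r, n_per_arm) {
    design <- trial_design(n_per_arm = n_per_arm, alpha = alpha,
                           age_months = age_months)
    model <- rescue_model(r)
    point_seed <- derive_seed(seed, "grid", n_per_arm)
    if (type == "univariate") {
      estimate_power(moments, endpoint, model, design, reps = reps,
                     seed = point_seed)
    } else {
      estimate_power_multi(moments, model, design, reps = reps,
                           seed = point_seed, ...)
    }
  })
  class(out) <- c("power_grid", class(out))
  out
}
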