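#' Check parametric assumptions for a grouped endpoint
#'
#' Applies the natural-history decision-tree gate: Anderson-Darling normality
#' per group (case 3 statistic with the small-sample correction, via
#' [nortest::ad.test()]) and the classic mean-centered Levene test of
#' homoscedasticity across groups ([car::leveneTest()] with `center = mean`).
#' Groups smaller than 8 cannot support the Anderson-Darling test and are
#' flagged `insufficient_n`, which fails the parametric gate (the pipeline
#' then defaults to the nonparametric branch). If every within-group
#' deviation is zero, the Levene statistic is defined as `W = 0`, `p = 1` by
#' convention.
#'
#' @param data A data frame.
#' @param value,group Columns of `data` holding the numeric response and the
#'   grouping label (tidy-eval).
#' @param alpha_assume Gate level: parametric assumptions hold when every
#'   Anderson-Darling p and the Levene p exceed it (default 0.05).
#' @return An object of class `assumption_report`: list with elements
#'   `per_group` (tibble: `group`, `n`, `ad_statistic`, `ad_p`, `note`),
#'   `levene_w`, `levene_df`, `levene_p`, `alpha_assume`, `parametric_ok`
#'   and `reason`.
#' @export
check_assumptions <- function(data, value, group, alpha_assume = 0.05) {
  stopifnot(is.data.frame(data))
  assert_scalar_number(alpha_assume, "alpha_assume", lower = 0, upper = 1)
  v <- dplyr::pull(data, {{ value }})
  g <- as.factor(dplyr::pull(data, {{ group }}))
  keep <- !is.na(v) & !is.na(g)
  v <- v[keep]; g <- droplevels(g[keep])
  sizes <- table(g)
  if (any(sizes < 2)) {
    stop("every group needs at least 2 observations", call. = FALSE)
  }

  per_group <- purrr::map_dfr(levels(g), function(lv) {
    x <- v[g == lv]
    if (length(x) < 8) {
      return(tibble::tibble(group = lv, n = length(x),
                            ad_statistic = NA_real_, ad_p = NA_real_,
                            note = "insufficient_n"))
    }
    ad <- tryCatch(nortest::ad.test(x), error = function(e) NULL)
    if (is.null(ad)) {
      tibble::tibble(group = lv, n = length(x), ad_statistic = NA_real_,
                     ad_p = NA_real_, note = "ad_undefined")
    } else {
      tibble::tibble(group = lv, n = length(x),
                     ad_statistic = unname(ad$statistic),
                     ad_p = unname(ad$p.value), note = NA_character_)
    }
  })

  # classic (mean-centered) Levene
  dev <- abs(v - stats::ave(v, g, FUN = mean))
  if (all(dev == 0)) {
    lev_w <- 0; lev_p <- 1
    lev_df <- c(nlevels(g) - 1, length(v) - nlevels(g))
  } else {
    lt <- car::leveneTest(v ~ g, center = mean)
    lev_w <- lt$`F value`[1]
    lev_p <- lt$`Pr(>F)`[1]
    lev_df <- c(lt$Df[1], lt$Df[2])
  }

  normal_ok <- all(!is.na(per_group$ad_p)) && all(per_group$ad_p > alpha_assume)
  homosced_ok <- lev_p > alpha_assume
  parametric_ok <- normal_ok && homosced_ok
  reason <- if (parametric_ok) {
    "all groups pass Anderson-Darling and Levene p > alpha_assume"
  } else if (any(is.na(per_group$ad_p))) {
    "normality untestable in at least one group (n < 8 or undefined)"
  } else if (!normal_ok) {
    "Anderson-Darling rejects normality in at least one group"
  } else {
    "Levene rejects homoscedasticity"
  }
  structure(list(per_group = per_group, levene_w = lev_w, levene_df = lev_df,
                 levene_p = lev_p, alpha_assume = alpha_assume,
                 parametric_ok = parametric_ok, reason = reason),
            class = "assumption_report")
}

#' @export
print.assumption_report <- function(x, ...) {
  cat(sprintf("<assumption_report: parametric_ok = %s>\n", x$parametric_ok))
  cat(sprintf("Levene (mean-centered): W = %.4g on (%d, %d) df, p = %.4g\n",
              x$levene_w, x$levene_df[1], x$levene_df[2], x$levene_p))
  print(x$per_group)
  cat("reason:", x$reason, "\n")
  invisible(x)
}

#' @export
tidy.assumption_report <- function(x, ...) x$per_group

#' @export
glance.assumption_report <- function(x, ...) {
  tibble::tibble(levene_w = x$levene_w, levene_p = x$levene_p,
                 alpha_assume = x$alpha_assume,
                 parametric_ok = x$parametric_ok, reason = x$reason)
}

#' Two-way ANOVA with sequential (type-I) sums of squares
#'
#' Fits the linear model `response ~ a * b` (or `a + b` without interaction)
#' and returns the sequential ANOVA table, the convention used for balanced
#' natural-history designs, where term order does not matter. A constant
#' response yields `F = 0`, `p = 1` for every term (0/0 defined as 0) with a
#' warning.
#'
#' @param data A data frame.
#' @param response Response column (tidy-eval).
#' @param factor_a,factor_b Factor columns (tidy-eval); defaults `genotype`
#'   and `age_months`.
#' @param interaction Include the interaction term (default `TRUE`).
#' @return A tibble with columns `term`, `df`, `sumsq`, `meansq`,
#'   `statistic`, `p_value`, including the `Residuals` row.
#' @examples
#' cohort <- sample_cohort(config_moments(q111_config()), 9, seed = 1)
#' anova_two_way(cohort, scn4b)
#' @export
anova_two_way <- function(data, response, factor_a = genotype,
                          factor_b = age_months, interaction = TRUE) {
  stopifnot(is.data.frame(data))
  y <- dplyr::pull(data, {{ response }})
  a <- as.factor(dplyr::pull(data, {{ factor_a }}))
  b <- as.factor(dplyr::pull(data, {{ factor_b }}))
  keep <- !is.na(y) & !is.na(a) & !is.na(b)
  y <- y[keep]; a <- droplevels(a[keep]); b <- droplevels(b[keep])
  if (nlevels(a) < 2 || nlevels(b) < 2) {
    stop("each factor needs at least 2 levels", call. = FALSE)
  }
  counts <- table(a, b)
  if (any(counts == 0)) {
    empty <- which(counts == 0, arr.ind = TRUE)[1, ]
    stop(sprintf("design cell (%s, %s) is empty",
                 rownames(counts)[empty[1]], colnames(counts)[empty[2]]),
         call. = FALSE)
  }
  form <- if (interaction) y ~ a * b else y ~ a + b
  fit <- stats::aov(form, data = data.frame(y = y, a = a, b = b))
  tab <- stats::anova(fit)
  term_names <- c(a = rlang::as_name(rlang::enquo(factor_a)),
                  b = rlang::as_name(rlang::enquo(factor_b)))
  terms <- rownames(tab)
  terms <- gsub("\\ba\\b", term_names[["a"]], terms)
  terms <- gsub("\\bb\\b", term_names[["b"]], terms)
  out <- tibble::tibble(term = trimws(terms), df = tab$Df,
                        sumsq = tab$`Sum Sq`, meansq = tab$`Mean Sq`,
                        statistic = tab$`F value`, p_value = tab$`Pr(>F)`)
  if (stats::var(y) == 0) {
    warning("response is constant; F statistics defined as 0 with p = 1",
            call. = FALSE)
    effect <- out$term != "Residuals"
    out$statistic[effect] <- 0
    out$p_value[effect] <- 1
  }
  out
}

#' Kruskal-Wallis omnibus test with Dunn's post-hoc comparisons
#'
#' Runs the tie-corrected Kruskal-Wallis H test ([stats::kruskal.test()]) and
#' follows up with Dunn's rank-based z tests for the requested group pairs,
#' Bonferroni-adjusted over exactly those comparisons. Dunn's statistic for
#' groups i, j is
#' \deqn{z = \frac{\bar R_i - \bar R_j}{\sqrt{\left(\frac{N(N+1)}{12} -
#'   \frac{\sum_t (t^3 - t)}{12(N-1)}\right)\left(\frac{1}{n_i} +
#'   \frac{1}{n_j}\right)}}}
#' with mean ranks over the pooled sample and the usual tie correction.
#' If all observations are identical the omnibus statistic is defined as
#' `H = 0`, `p = 1` and all post-hoc `z = 0` (with a warning).
#'
#' @param data A data frame.
#' @param value,group Response and grouping columns (tidy-eval).
#' @param comparisons Group pairs to test: a list of length-2 vectors, or a
#'   two-column matrix/data frame of group labels. Default: all pairs.
#' @return An object of class `kruskal_dunn`: list with `omnibus` (one-row
#'   tibble: `statistic_name = "H"`, `statistic`, `df`, `p_value`) and
#'   `posthoc` (tibble: `group1`, `group2`, `z`, `p_raw`, `p_adj`).
#' @export
kruskal_dunn <- function(data, value, group, comparisons = NULL) {
  stopifnot(is.data.frame(data))
  v <- dplyr::pull(data, {{ value }})
  g <- as.factor(dplyr::pull(data, {{ group }}))
  keep <- !is.na(v) & !is.na(g)
  v <- v[keep]; g <- droplevels(g[keep])
  if (nlevels(g) < 2) stop("need at least 2 groups", call. = FALSE)
  if (length(v) < 3) stop("need at least 3 observations in total", call. = FALSE)

  if (is.null(comparisons)) {
    comparisons <- utils::combn(levels(g), 2, simplify = FALSE)
  } else if (is.matrix(comparisons) || is.data.frame(comparisons)) {
    comparisons <- purrr::map(seq_len(nrow(comparisons)),
                              function(i) as.character(unlist(comparisons[i, 1:2])))
  }
  labs <- unique(unlist(comparisons))
  unknown <- setdiff(labs, levels(g))
  if (length(unknown)) {
    stop("unknown group label(s) in comparisons: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }

  degenerate <- length(unique(v)) == 1
  if (degenerate) {
    warning("all observations identical; H defined as 0 with p = 1",
            call. = FALSE)
    omnibus <- tibble::tibble(statistic_name = "H", statistic = 0,
                              df = nlevels(g) - 1, p_value = 1)
  } else {
    kw <- stats::kruskal.test(v, g)
    omnibus <- tibble::tibble(statistic_name = "H",
                              statistic = unname(kw$statistic),
                              df = unname(kw$parameter),
                              p_value = unname(kw$p.value))
  }

  r <- rank(v)
  n_tot <- length(v)
  rbar <- tapply(r, g, mean)
  sizes <- tapply(r, g, length)
  ties <- table(v)
  tie_term <- sum(ties^3 - ties) / (12 * (n_tot - 1))
  sigma2 <- n_tot * (n_tot + 1) / 12 - tie_term
  m <- length(comparisons)
  posthoc <- purrr::map_dfr(comparisons, function(pr) {
    if (degenerate || sigma2 <= 0) {
      z <- 0; p_raw <- 1
    } else {
      z <- (rbar[[pr[1]]] - rbar[[pr[2]]]) /
        sqrt(sigma2 * (1 / sizes[[pr[1]]] + 1 / sizes[[pr[2]]]))
      p_raw <- 2 * stats::pnorm(-abs(z))
    }
    tibble::tibble(group1 = pr[1], group2 = pr[2], z = z, p_raw = p_raw,
                   p_adj = min(1, m * p_raw))
  })
  structure(list(omnibus = omnibus, posthoc = posthoc),
            class = "kruskal_dunn")
}

#' @export
print.kruskal_dunn <- function(x, ...) {
  cat(sprintf("Kruskal-Wallis: H(%g) = %.4g, p = %.4g\n", x$omnibus$df,
              x$omnibus$statistic, x$omnibus$p_value))
  cat(sprintf("Dunn post-hoc (%d comparisons, Bonferroni):\n", nrow(x$posthoc)))
  print(x$posthoc)
  invisible(x)
}

#' @export
tidy.kruskal_dunn <- function(x, ...) x$posthoc

#' @export
glance.kruskal_dunn <- function(x, ...) x$omnibus

#' Two-sample Kolmogorov-Smirnov test
#'
#' Computes `D = sup |Fx - Fy|` between the empirical distribution functions
#' of the two samples. The p-value is exact (permutation distribution over
#' all label assignments, as in [stats::psmirnov()]) when `n1 * n2 <= 400`,
#' and from the asymptotic Kolmogorov distribution otherwise.
#'
#' @param x,y Numeric samples (each nonempty).
#' @return A one-row tibble with columns `D`, `p_value`, `method`.
#' @examples
#' ks_two_sample(c(1, 2), c(3, 4)) # D = 1, exact p = 1/3
#' @export
ks_two_sample <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (!length(x) || !length(y)) stop("both samples must be nonempty",
                                     call. = FALSE)
  exact <- length(x) * length(y) <= 400
  kt <- suppressWarnings(stats::ks.test(x, y, exact = exact))
  p <- unname(kt$p.value)
  D <- unname(kt$statistic)
  if (D == 0) p <- 1
  tibble::tibble(D = D, p_value = min(1, p),
                 method = if (exact) "exact" else "asymptotic")
}

#' Run the omnibus/post-hoc decision tree on one endpoint
#'
#' The natural-history reporting procedure: test the genotype-by-age groups
#' for normality and homoscedasticity ([check_assumptions()]); if the
#' parametric gate passes, fit the two-way ANOVA ([anova_two_way()]);
#' otherwise run Kruskal-Wallis over the genotype-by-age groups followed by
#' Dunn's test restricted to the genotype contrast within each age
#' ([kruskal_dunn()]), Bonferroni-corrected over those comparisons. The
#' report records which branch fired and why.
#'
#' @param data A cohort data frame with `genotype` and `age_months` columns.
#' @param response Endpoint column (tidy-eval).
#' @param alpha_assume Level of the assumption gate (default 0.05).
#' @return An object of class `natural_history_report`: list with elements
#'   `response`, `branch` (`"anova"` or `"kruskal_dunn"`), `assumptions`,
#'   and `result` (the ANOVA tibble or the `kruskal_dunn` object).
#' @export
select_and_run <- function(data, response, alpha_assume = 0.05) {
  stopifnot(is.data.frame(data))
  if (!all(c("genotype", "age_months") %in% names(data))) {
    stop("data must have `genotype` and `age_months` columns", call. = FALSE)
  }
  resp_name <- rlang::as_name(rlang::enquo(response))
  data$.cell <- paste(data$genotype, data$age_months, sep = ".")
  assumptions <- check_assumptions(data, {{ response }}, .cell,
                                   alpha_assume = alpha_assume)
  if (assumptions$parametric_ok) {
    result <- anova_two_way(data, {{ response }})
    branch <- "anova"
  } else {
    ages <- sort(unique(data$age_months))
    comparisons <- purrr::map(ages, function(ag) {
      paste(c("WT", "HET"), ag, sep = ".")
    })
    present <- unique(data$.cell)
    comparisons <- purrr::keep(comparisons,
                               function(pr) all(pr %in% present))
    result <- kruskal_dunn(data, {{ response }}, .cell,
                           comparisons = comparisons)
    branch <- "kruskal_dunn"
  }
  structure(list(response = resp_name, branch = branch,
                 assumptions = assumptions, result = result),
            class = "natural_history_report")
}

#' @export
print.natural_history_report <- function(x, ...) {
  cat(sprintf("<natural_history_report: %s>\n", x$response))
  cat(sprintf("branch: %s (%s)\n", x$branch, x$assumptions$reason))
  print(x$result)
  invisible(x)
}
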