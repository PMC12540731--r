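#' Group summary with confidence intervals
#'
#' Mean, sample standard deviation, and 95% confidence intervals for the
#' mean (t distribution) and for the standard deviation (chi-square), the
#' dispersion summaries used throughout the per-condition figures.
#'
#' @param values Numeric vector, n >= 2.
#' @param conf Confidence level, default 0.95.
#' @return A tibble with one row: `n`, `mean`, `sd`, `ci_mean_lo`,
#'   `ci_mean_hi`, `ci_sd_lo`, `ci_sd_hi`.
#' @examples
#' summarize_group(c(1, 2, 3)) # mean 2 +/- 2.484, sd 1
#' @export
summarize_group <- function(values, conf = 0.95) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n < 2) stop("summarize_group needs at least 2 values", call. = FALSE)
  m <- mean(values)
  s <- stats::sd(values)
  a <- 1 - conf
  tq <- stats::qt(1 - a / 2, df = n - 1)
  half <- tq * s / sqrt(n)
  # chi-square interval for sigma: sqrt((n-1)s^2 / chi2_{1-a/2}), upper with chi2_{a/2}
  lo_sd <- sqrt((n - 1) * s^2 / stats::qchisq(1 - a / 2, df = n - 1))
  hi_sd <- sqrt((n - 1) * s^2 / stats::qchisq(a / 2, df = n - 1))
  tibble::tibble(
    n = n, mean = m, sd = s,
    ci_mean_lo = m - half, ci_mean_hi = m + half,
    ci_sd_lo = lo_sd, ci_sd_hi = hi_sd
  )
}

check_groups <- function(groups) {
  if (!is.list(groups) || length(groups) < 2) {
    stop("need a named list of at least 2 groups", call. = FALSE)
  }
  if (is.null(names(groups)) || any(names(groups) == "")) {
    names(groups) <- paste0("g", seq_along(groups))
  }
  groups <- lapply(groups, function(v) as.numeric(v[!is.na(v)]))
  n <- vapply(groups, length, integer(1))
  if (any(n < 2)) {
    stop("every group needs at least 2 observations", call. = FALSE)
  }
  groups
}

#' One-way analysis of variance
#'
#' Classical fixed-effects decomposition into between- and within-group
#' sums of squares, fitted through [stats::aov()].
#'
#' @param groups Named list of numeric vectors (one per condition), each
#'   with n >= 2.
#' @return A tibble with one row: `f`, `df_between`, `df_within`, `p`,
#'   `ss_between`, `ss_within`, `ms_within`.
#' @examples
#' one_way_anova(list(a = c(1, 2, 3), b = c(2, 3, 4), c = c(3, 4, 5)))
#' @export
one_way_anova <- function(groups) {
  groups <- check_groups(groups)
  df <- data.frame(
    value = unlist(groups, use.names = FALSE),
    group = factor(rep(names(groups), lengths(groups)))
  )
  ssw <- sum(vapply(groups, function(v) sum((v - mean(v))^2), numeric(1)))
  if (ssw <= 0) {
    stop("degenerate within-group variance: ANOVA is undefined when every ",
         "group is constant", call. = FALSE)
  }
  fit <- stats::aov(value ~ group, data = df)
  an <- stats::anova(fit)
  tibble::tibble(
    f = an$`F value`[1],
    df_between = an$Df[1],
    df_within = an$Df[2],
    p = an$`Pr(>F)`[1],
    ss_between = an$`Sum Sq`[1],
    ss_within = an$`Sum Sq`[2],
    ms_within = an$`Mean Sq`[2]
  )
}

#' Significance stars
#'
#' Star convention used in the figure legends: `*` p < 0.05, `**`
#' p < 0.01, `***` p < 0.001, `****` p < 0.0001, `n.s.` otherwise.
#'
#' @param p Numeric vector of p values.
#' @return Character vector of labels.
#' @export
significance_stars <- function(p) {
  dplyr::case_when(
    is.na(p) ~ NA_character_,
    p < 1e-4 ~ "****",
    p < 1e-3 ~ "***",
    p < 1e-2 ~ "**",
    p < 5e-2 ~ "*",
    TRUE ~ "n.s."
  )
}

#' Two-sided Tukey HSD pairwise comparisons
#'
#' For every pair of groups computes the mean difference, the studentized
#' range statistic `q = |mi - mj| / sqrt(MSW (1/ni + 1/nj) / 2)` and the
#' adjusted p value from the studentized range distribution with k groups
#' and the within-group degrees of freedom (Tukey-Kramer for unequal
#' group sizes, which the experimental designs here always have).
#'
#' @inheritParams one_way_anova
#' @return A tibble with one row per pair: `group_a`, `group_b`, `diff`
#'   (mean of `group_b` minus mean of `group_a`), `q`, `p_adj`, `stars`.
#' @examples
#' tukey_hsd(list(a = c(1, 2, 3), b = c(2, 3, 4), c = c(3, 4, 5)))
#' @export
tukey_hsd <- function(groups) {
  groups <- check_groups(groups)
  an <- one_way_anova(groups)
  msw <- an$ms_within
  dfw <- an$df_within
  k <- length(groups)
  means <- vapply(groups, mean, numeric(1))
  ns <- lengths(groups)
  combs <- utils::combn(names(groups), 2)
  rows <- apply(combs, 2, function(pr) {
    i <- pr[1]; j <- pr[2]
    diff <- means[[j]] - means[[i]]
    se <- sqrt(msw * (1 / ns[[i]] + 1 / ns[[j]]) / 2)
    q <- abs(diff) / se
    p <- stats::ptukey(q, nmeans = k, df = dfw, lower.tail = FALSE)
    tibble::tibble(group_a = i, group_b = j, diff = diff, q = q, p_adj = p)
  })
  out <- dplyr::bind_rows(rows)
  out$stars <- significance_stars(out$p_adj)
  out
}

#' OLS regression with a two-tailed slope t test
#'
#' Ordinary least squares of `y` on `x`, reporting the slope, intercept,
#' the two-tailed p value of the slope t test (n - 2 degrees of freedom)
#' and R-squared. An exactly collinear fit (zero residual variance) is
#' reported with p = 0 and `exact_fit = TRUE`.
#'
#' @param x,y Numeric vectors of equal length, n >= 3; `x` must vary.
#' @return A tibble with one row: `slope`, `intercept`, `p`, `r_squared`,
#'   `se_slope`, `n`, `exact_fit`.
#' @examples
#' ols_slope_test(0:3, 2 * (0:3) + 1) # slope 2, intercept 1, R^2 1
#' @export
ols_slope_test <- function(x, y) {
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3) stop("OLS slope test needs at least 3 points", call. = FALSE)
  if (stats::var(x) == 0) {
    stop("OLS slope test needs variation in x", call. = FALSE)
  }
  fit <- stats::lm(y ~ x)
  slope <- unname(stats::coef(fit)["x"])
  intercept <- unname(stats::coef(fit)["(Intercept)"])
  rss <- sum(stats::residuals(fit)^2)
  tss <- sum((y - mean(y))^2)
  if (tss == 0) {
    # y constant: slope 0, no linear signal
    return(tibble::tibble(slope = 0, intercept = mean(y), p = 1,
                          r_squared = 0, se_slope = NA_real_,
                          n = n, exact_fit = FALSE))
  }
  exact <- rss <= 1e-12 * tss
  # slope inference from the residual variance (summary.lm is unreliable
  # for numerically perfect fits)
  sxx <- sum((x - mean(x))^2)
  se <- sqrt(rss / (n - 2) / sxx)
  p <- if (exact) 0 else {
    2 * stats::pt(abs(slope / se), df = n - 2, lower.tail = FALSE)
  }
  tibble::tibble(
    slope = slope,
    intercept = intercept,
    p = p,
    r_squared = 1 - rss / tss,
    se_slope = se,
    n = n,
    exact_fit = exact
  )
}
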