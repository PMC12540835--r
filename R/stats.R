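#' One-way ANOVA with Tukey HSD post-hoc comparisons
#'
#' Classical one-way analysis of variance followed by all pairwise
#' two-sided Tukey Honest Significant Difference comparisons. Unequal
#' group sizes are handled with the Tukey-Kramer adjustment (the standard
#' behaviour of [stats::TukeyHSD()]).
#'
#' @param values Numeric observations.
#' @param group Group labels (coerced to factor), same length as `values`.
#' @return List with `F`, `df` (c(between, within)), `p` and `pairwise`, a
#'   tibble of pairwise differences with Tukey-adjusted p values.
#' @export
anova_tukey <- function(values, group) {
  group <- factor(group)
  if (nlevels(group) < 2) stop("need at least two groups", call. = FALSE)
  n_per <- table(group)
  if (any(n_per < 2))
    stop("each group needs at least two observations", call. = FALSE)
  fit <- stats::aov(values ~ group)
  tab <- summary(fit)[[1]]
  if (tab$`Sum Sq`[1] < 1e-12 && tab$`Sum Sq`[2] < 1e-12) {
    # all observations identical: no variance to partition
    lv <- levels(group)
    cmb <- utils::combn(lv, 2)
    return(list(F = 0, df = c(between = tab$Df[1], within = tab$Df[2]),
                p = 1,
                pairwise = tibble::tibble(
                  comparison = paste(cmb[2, ], cmb[1, ], sep = "-"),
                  diff = 0, lwr = 0, upr = 0, p_adj = 1)))
  }
  tk <- suppressWarnings(stats::TukeyHSD(fit)$group)
  pairs <- rownames(tk)
  list(F = tab$`F value`[1],
       df = c(between = tab$Df[1], within = tab$Df[2]),
       p = tab$`Pr(>F)`[1],
       pairwise = tibble::tibble(comparison = pairs,
                                 diff = unname(tk[, "diff"]),
                                 lwr = unname(tk[, "lwr"]),
                                 upr = unname(tk[, "upr"]),
                                 p_adj = unname(tk[, "p adj"])))
}

#' Two-proportion z-test (pooled, two-tailed)
#'
#' Pooled-variance z statistic for the difference of two proportions,
#' without continuity correction, with a two-tailed normal p value:
#' `z = (p1 - p2) / sqrt(p(1-p)(1/n1 + 1/n2))` with
#' `p = (k1 + k2)/(n1 + n2)`.
#'
#' @param k1,n1 Successes and trials in group 1.
#' @param k2,n2 Successes and trials in group 2.
#' @return List with `z` and `p`.
#' @export
two_proportion_z <- function(k1, n1, k2, n2) {
  if (n1 < 1 || n2 < 1 || k1 < 0 || k2 < 0 || k1 > n1 || k2 > n2)
    stop("need 0 <= k <= n and n >= 1 in both groups", call. = FALSE)
  pp <- (k1 + k2) / (n1 + n2)
  if (pp <= 0 || pp >= 1)
    stop("pooled proportion is 0 or 1: z undefined", call. = FALSE)
  z <- (k1 / n1 - k2 / n2) / sqrt(pp * (1 - pp) * (1 / n1 + 1 / n2))
  list(z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Chi-square test of independence
#'
#' Pearson chi-square on a contingency table, without continuity
#' correction, with `(r-1)(c-1)` degrees of freedom.
#'
#' @param counts Matrix of non-negative counts.
#' @return List with `chisq`, `df`, `p`.
#' @export
chi_square_independence <- function(counts) {
  counts <- as.matrix(counts)
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0))
    stop("zero marginal in the contingency table", call. = FALSE)
  ct <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
  list(chisq = unname(ct$statistic), df = unname(ct$parameter),
       p = ct$p.value)
}

#' Ordinary least squares fit with slope test
#'
#' Simple linear regression `y ~ x` by ordinary least squares; the slope's
#' significance is a two-tailed t test on `n - 2` degrees of freedom and
#' goodness of fit is R-squared.
#'
#' @param x,y Numeric vectors, length >= 3, `x` non-constant.
#' @return List with `slope`, `intercept`, `r_squared`, `p_slope`, `n`.
#' @export
ols_fit <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3)
    stop("need n >= 3 paired observations", call. = FALSE)
  if (stats::var(x) == 0) stop("x is constant", call. = FALSE)
  fit <- stats::lm(y ~ x)
  # an exactly collinear input is legitimate here (R^2 = 1)
  sm <- suppressWarnings(summary(fit))
  co <- sm$coefficients
  list(slope = unname(co["x", "Estimate"]),
       intercept = unname(co["(Intercept)", "Estimate"]),
       r_squared = sm$r.squared,
       p_slope = unname(co["x", "Pr(>|t|)"]),
       n = length(x))
}

#' Mean, standard deviation and their 95% confidence intervals
#'
#' t-based confidence interval for the mean and chi-square-based interval
#' for the standard deviation, the dispersion display used for
#' per-condition velocity and intensity summaries. A zero-variance sample
#' yields a degenerate sd interval, which is flagged.
#'
#' @param values Numeric vector, n >= 2.
#' @param conf Confidence level. Default 0.95.
#' @return List with `mean`, `sd`, `ci_mean`, `ci_sd`, `n`,
#'   `degenerate` (TRUE when sd is 0).
#' @export
mean_sd_ci <- function(values, conf = 0.95) {
  n <- length(values)
  if (n < 2) stop("need at least two values", call. = FALSE)
  m <- mean(values); s <- stats::sd(values)
  a <- 1 - conf
  tq <- stats::qt(1 - a / 2, df = n - 1)
  ci_mean <- c(m - tq * s / sqrt(n), m + tq * s / sqrt(n))
  if (s > 0) {
    ci_sd <- c(sqrt((n - 1) * s^2 / stats::qchisq(1 - a / 2, df = n - 1)),
               sqrt((n - 1) * s^2 / stats::qchisq(a / 2, df = n - 1)))
  } else {
    ci_sd <- c(0, 0)
  }
  list(mean = m, sd = s, ci_mean = ci_mean, ci_sd = ci_sd, n = n,
       degenerate = s == 0)
}

#' Significance stars
#'
#' Display tiers for p values (two-sided): `*` p <= 0.05, `**` p <= 0.01,
#' `***` p <= 0.001, `****` p <= 0.0001, `n.s.` otherwise. Raw p values
#' are always reported alongside.
#'
#' @param p Numeric vector of p values.
#' @return Character vector.
#' @export
significance_stars <- function(p) {
  cut(p, breaks = c(-Inf, 1e-4, 1e-3, 1e-2, 5e-2, Inf),
      labels = c("****", "***", "**", "*", "n.s.")) |> as.character()
}
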