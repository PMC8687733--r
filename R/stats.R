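#' D'Agostino-Pearson omnibus normality test
#'
#' Combines the standardized sample skewness (D'Agostino's Z1) and kurtosis
#' (Anscombe-Glynn's Z2) into K2 = Z1^2 + Z2^2, referred to a chi-squared
#' distribution with 2 degrees of freedom. Requires n >= 8 for the skewness
#' transform to be defined.
#'
#' @param x numeric sample.
#' @return a one-row tibble with `statistic` (K2), `z_skew`, `z_kurt` and
#'   `p_value`.
#' @export
dagostino_pearson <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 8) stop("D'Agostino-Pearson test requires n >= 8", call. = FALSE)
  m <- mean(x)
  m2 <- mean((x - m)^2)
  m3 <- mean((x - m)^3)
  m4 <- mean((x - m)^4)
  b1 <- m3 / m2^1.5
  b2 <- m4 / m2^2

  # skewness transform (D'Agostino 1970)
  y <- b1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  beta2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  w2 <- -1 + sqrt(2 * (beta2 - 1))
  delta <- 1 / sqrt(log(sqrt(w2)))
  alpha <- sqrt(2 / (w2 - 1))
  z1 <- delta * log(y / alpha + sqrt((y / alpha)^2 + 1))

  # kurtosis transform (Anscombe & Glynn 1983)
  eb2 <- 3 * (n - 1) / (n + 1)
  vb2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  xk <- (b2 - eb2) / sqrt(vb2)
  sb1 <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  a <- 6 + 8 / sb1 * (2 / sb1 + sqrt(1 + 4 / sb1^2))
  z2 <- ((1 - 2 / (9 * a)) -
           ((1 - 2 / a) / (1 + xk * sqrt(2 / (a - 4))))^(1 / 3)) /
    sqrt(2 / (9 * a))

  k2 <- z1^2 + z2^2
  tibble::tibble(statistic = k2, z_skew = z1, z_kurt = z2,
                 p_value = stats::pchisq(k2, df = 2, lower.tail = FALSE))
}

#' Two-group comparison with a normality gate
#'
#' The study's two-sample procedure: both samples are checked with the
#' D'Agostino-Pearson omnibus test; when both pass at alpha = 0.05 an
#' unpaired pooled-variance Student t test is used (matching the printed
#' integer degrees of freedom n1 + n2 - 2), otherwise a Mann-Whitney
#' (Wilcoxon rank-sum) test. Samples too small for the normality test
#' (n < 8) fall through to the nonparametric branch.
#'
#' @param a,b numeric samples.
#' @param alpha significance level of the normality gate.
#' @return a one-row tibble with `test_name`, `statistic`, `dof`, `p_value`,
#'   `normal_a`, `normal_b`.
#' @export
compare_groups <- function(a, b, alpha = 0.05) {
  a <- a[is.finite(a)]
  b <- b[is.finite(b)]
  if (length(a) < 3 || length(b) < 3) {
    stop("each sample needs n >= 3", call. = FALSE)
  }
  norm_p <- function(x) {
    if (length(x) < 8) return(NA_real_)
    dagostino_pearson(x)$p_value
  }
  pa <- norm_p(a)
  pb <- norm_p(b)
  normal_a <- isTRUE(pa > alpha)
  normal_b <- isTRUE(pb > alpha)

  if (normal_a && normal_b) {
    tt <- stats::t.test(a, b, var.equal = TRUE)
    tibble::tibble(
      test_name = "unpaired Student t (pooled)",
      statistic = unname(tt$statistic),
      dof = unname(tt$parameter),
      p_value = tt$p.value,
      normal_a = normal_a, normal_b = normal_b
    )
  } else {
    mw <- stats::wilcox.test(a, b, exact = FALSE, correct = TRUE)
    tibble::tibble(
      test_name = "Mann-Whitney",
      statistic = unname(mw$statistic),
      dof = NA_real_,
      p_value = mw$p.value,
      normal_a = normal_a, normal_b = normal_b
    )
  }
}

#' One-way ANOVA with Tukey HSD post hoc comparisons
#'
#' @param groups a named list of numeric samples, or a data frame with
#'   columns `value` and `group`.
#' @param alpha significance level for the post hoc flags.
#' @return a list with `anova` (one-row tibble: `f_statistic`, `dof1`,
#'   `dof2`, `p_value`) and `tukey` (tibble of pairwise comparisons:
#'   `contrast`, `diff`, `lwr`, `upr`, `p_adj`, `significant`).
#' @export
anova_tukey <- function(groups, alpha = 0.05) {
  if (is.data.frame(groups)) {
    df <- data.frame(value = groups$value, group = factor(groups$group))
  } else {
    stopifnot(length(groups) >= 2)
    if (is.null(names(groups))) {
      names(groups) <- paste0("g", seq_along(groups))
    }
    df <- data.frame(
      value = unlist(groups, use.names = FALSE),
      group = factor(rep(names(groups), lengths(groups)))
    )
  }
  if (any(table(df$group) < 2)) {
    stop("each group needs n >= 2", call. = FALSE)
  }
  fit <- stats::aov(value ~ group, data = df)
  an <- summary(fit)[[1]]
  f <- an$`F value`[1]
  p <- an$`Pr(>F)`[1]
  if (!is.finite(f) || stats::var(df$value) < 1e-20) {
    # all observations identical: no variance to apportion
    f <- 0
    p <- 1
  }
  tk <- stats::TukeyHSD(fit)$group
  tukey <- tibble::tibble(
    contrast = rownames(tk),
    diff = tk[, "diff"], lwr = tk[, "lwr"], upr = tk[, "upr"],
    p_adj = tk[, "p adj"],
    significant = tk[, "p adj"] < alpha
  )
  list(
    anova = tibble::tibble(
      f_statistic = f,
      dof1 = an$Df[1], dof2 = an$Df[2],
      p_value = p
    ),
    tukey = tukey
  )
}
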