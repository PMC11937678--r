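# t-test family with effect sizes, Bonferroni correction, Pearson
# correlation and the default JZS Bayes factor for t designs.

#' t test with Cohen's d
#'
#' One-sample, paired or two-sample Student t test (classical equal-variance
#' pooling for two samples), returning the effect size alongside: pooled-SD
#' d for two samples, mean-difference over SD-of-differences (d_z) for
#' paired data, standardized mean for one sample.
#'
#' @param a First sample.
#' @param b Second sample (`NULL` for one-sample).
#' @param paired Paired test (requires equal lengths).
#' @param mu Null value for the one-sample test.
#' @param var_equal Pool variances in the two-sample test.
#' @return List: `t`, `df`, `p`, `cohen_d`, `type`.
#' @export
ttest <- function(a, b = NULL, paired = FALSE, mu = 0, var_equal = TRUE) {
  if (is.null(b)) {
    if (stats::sd(a) == 0) stop("zero variance", call. = FALSE)
    ht <- stats::t.test(a, mu = mu)
    d <- (mean(a) - mu) / stats::sd(a)
    type <- "one-sample"
  } else if (paired) {
    if (length(a) != length(b)) stop("paired samples must match in length", call. = FALSE)
    dif <- a - b
    if (stats::sd(dif) == 0) {
      # identical samples: no evidence against the null by convention
      if (all(dif == 0)) {
        return(list(t = 0, df = length(a) - 1, p = 1, cohen_d = 0,
                    type = "paired"))
      }
      stop("zero variance of differences", call. = FALSE)
    }
    ht <- stats::t.test(a, b, paired = TRUE)
    d <- mean(dif) / stats::sd(dif)          # d_z convention
    type <- "paired"
  } else {
    if (stats::sd(a) == 0 && stats::sd(b) == 0) stop("zero variance", call. = FALSE)
    ht <- stats::t.test(a, b, var.equal = var_equal)
    sp <- sqrt(((length(a) - 1) * stats::var(a) + (length(b) - 1) * stats::var(b)) /
                 (length(a) + length(b) - 2))
    d <- (mean(a) - mean(b)) / sp
    type <- "two-sample"
  }
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value, cohen_d = d, type = type)
}

#' Bonferroni correction
#'
#' @param p_values Uncorrected p values.
#' @param m Family size (defaults to `length(p_values)`).
#' @return Corrected p values, capped at 1.
#' @export
bonferroni <- function(p_values, m = length(p_values)) {
  if (any(p_values < 0 | p_values > 1)) stop("p values must lie in [0, 1]", call. = FALSE)
  pmin(1, m * p_values)
}

#' Pearson correlation with two-sided p value
#'
#' @param x,y Equal-length numeric vectors (n >= 3).
#' @return List: `r`, `p`, `n`.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3) {
    stop("need equal-length vectors with n >= 3", call. = FALSE)
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("zero variance", call. = FALSE)
  ht <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ht$estimate), p = ht$p.value, n = length(x))
}

# JZS Bayes factor integrand machinery. Under the JZS prior the effect size
# has a Cauchy(0, rscale) prior, equivalently g ~ InverseGamma(1/2, 1/2)
# with the Cauchy scale absorbed into the effective sample size.
jzs_bf10 <- function(t, n_eff, df, rscale = 1 / sqrt(2),
                     integrator = stats::integrate) {
  null_lik <- (1 + t^2 / df)^(-(df + 1) / 2)
  integrand <- function(g) {
    k <- 1 + n_eff * rscale^2 * g
    k^(-1 / 2) * (1 + t^2 / (k * df))^(-(df + 1) / 2) *
      (2 * pi)^(-1 / 2) * g^(-3 / 2) * exp(-1 / (2 * g))
  }
  alt_lik <- integrator(integrand, 0, Inf)
  val <- if (is.list(alt_lik)) alt_lik$value else alt_lik
  if (!is.finite(val) || val <= 0) stop("Bayes factor integration failed", call. = FALSE)
  val / null_lik
}

#' JZS Bayes factor for a t design
#'
#' Default Jeffreys-Zellner-Siow Bayes factor (Cauchy prior on the
#' standardized effect, scale `1/sqrt(2)`) computed by numerical
#' integration; returned on the log scale. Positive values favor the
#' alternative.
#'
#' @param a First sample.
#' @param b Second sample (`NULL` for one-sample against `mu`).
#' @param paired Paired design.
#' @param mu One-sample null value.
#' @param rscale Cauchy prior scale.
#' @return `logBF10` (natural log).
#' @export
jzs_bayes_factor_t <- function(a, b = NULL, paired = FALSE, mu = 0,
                               rscale = 1 / sqrt(2)) {
  if (is.null(b) || paired) {
    x <- if (is.null(b)) a - mu else a - b
    t <- mean(x) / (stats::sd(x) / sqrt(length(x)))
    n_eff <- length(x); df <- length(x) - 1
  } else {
    ht <- ttest(a, b)
    t <- ht$t; df <- ht$df
    n_eff <- length(a) * length(b) / (length(a) + length(b))
  }
  log(jzs_bf10(t, n_eff, df, rscale))
}
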