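# Invert the trigamma function by Newton iteration (monotone decreasing on
# (0, Inf); used to match the variance of log sample variances).
trigamma_inverse <- function(x) {
  if (!is.finite(x) || x <= 0) return(Inf)
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (iter in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, deriv = 2L)
    y <- y + dif
    if (!is.finite(y) || y <= 0) return(Inf)
    if (abs(dif / y) < 1e-8) break
  }
  y
}

# Method-of-moments fit of the scaled inverse-chi-square prior on per-probe
# variances: matches mean and variance of log s2 using digamma/trigamma,
# giving prior df d0 and prior variance s0sq. No positive solution for the
# spread equation means the observed variances are no more dispersed than
# chi-square sampling alone explains: d0 = Inf (complete shrinkage).
estimate_variance_prior <- function(s2, df) {
  ok <- is.finite(s2) & s2 > 0
  if (!any(ok)) stop("no positive residual variances to fit the prior")
  z <- log(s2[ok])
  dfok <- if (length(df) == 1L) rep(df, sum(ok)) else df[ok]
  e <- z - digamma(dfok / 2) + log(dfok / 2)
  emean <- mean(e)
  evar <- var(e) - mean(trigamma(dfok / 2))
  if (is.na(evar) || evar <= 0) {
    list(d0 = Inf, s0sq = exp(emean))
  } else {
    d0 <- 2 * trigamma_inverse(evar)
    list(d0 = d0, s0sq = exp(emean + digamma(d0 / 2) - log(d0 / 2)))
  }
}

#' Empirical-Bayes moderated t-statistics for a two-group contrast
#'
#' Per probe, computes the log2 fold change M (nucleus minus surround group
#' mean), the pooled residual variance s2 with its degrees of freedom, then
#' shrinks every s2 toward a common prior variance s0sq estimated from all
#' probes: the posterior variance is (d0*s0sq + d*s2)/(d0 + d), the
#' moderated t is M over its posterior standard error, and p-values come
#' from a t distribution with d0 + d degrees of freedom. The prior
#' hyperparameters (d0, s0sq) are estimated by the method of moments on
#' log s2; either can be overridden, which recovers the two limits: d0 = 0
#' gives the ordinary pooled two-sample t, d0 = Inf the fixed-variance
#' z-like statistic M/(s0*SE factor).
#'
#' @param values probes-by-samples matrix (oriented log-ratios for the
#'   two-channel design, normalized log2 values for single-channel).
#' @param group character/factor of length `ncol(values)` with two levels.
#' @param contrast length-2 character: M = mean(group==contrast[1]) minus
#'   mean(group==contrast[2]). Defaults to the sorted group levels, so
#'   `c("nucleus", "surround")` gives nucleus-over-surround.
#' @param d0,s0sq optional hyperparameter overrides.
#' @return list with `table` (data.frame: probe_id, M, A, s2, t_mod,
#'   df_total, p) and `model` (d0, s0sq, df_resid).
#' @export
fit_moderated_t <- function(values, group, contrast = NULL,
                            d0 = NULL, s0sq = NULL) {
  values <- as.matrix(values)
  group <- as.character(group)
  stopifnot(length(group) == ncol(values))
  lev <- sort(unique(group))
  if (length(lev) != 2L) stop("exactly two groups required")
  if (is.null(contrast)) contrast <- lev
  stopifnot(all(contrast %in% lev), length(contrast) == 2L)
  i1 <- group == contrast[1L]
  i2 <- group == contrast[2L]
  n1 <- sum(i1); n2 <- sum(i2)
  if (n1 < 2L || n2 < 2L) stop("at least two samples per group required")
  if (is.null(rownames(values)))
    rownames(values) <- as.character(seq_len(nrow(values)))

  m1 <- rowMeans(values[, i1, drop = FALSE])
  m2 <- rowMeans(values[, i2, drop = FALSE])
  M <- m1 - m2
  A <- rowMeans(values)
  v1 <- apply(values[, i1, drop = FALSE], 1L, var)
  v2 <- apply(values[, i2, drop = FALSE], 1L, var)
  d_g <- n1 + n2 - 2L
  s2 <- ((n1 - 1L) * v1 + (n2 - 1L) * v2) / d_g

  if (is.null(d0) || is.null(s0sq)) {
    prior <- estimate_variance_prior(s2, d_g)
    if (is.null(d0)) d0 <- prior$d0
    if (is.null(s0sq)) s0sq <- prior$s0sq
  }
  stopifnot(d0 >= 0, s0sq > 0 || d0 == 0)

  s2_post <- if (is.infinite(d0)) {
    rep(s0sq, length(s2))
  } else if (d0 == 0) {
    s2
  } else {
    (d0 * s0sq + d_g * s2) / (d0 + d_g)
  }
  sef <- sqrt(1 / n1 + 1 / n2)
  t_mod <- M / (sqrt(s2_post) * sef)
  df_total <- d0 + d_g
  p <- 2 * pt(-abs(t_mod), df = df_total)

  list(
    table = data.frame(probe_id = rownames(values), M = M, A = A, s2 = s2,
                       t_mod = t_mod, df_total = df_total, p = p,
                       row.names = NULL, stringsAsFactors = FALSE),
    model = list(d0 = d0, s0sq = s0sq, df_resid = d_g,
                 n1 = n1, n2 = n2, contrast = contrast)
  )
}

#' Adjust p-values for multiple testing
#'
#' `"BH"` is the Benjamini-Hochberg step-up FDR adjustment. `"storey"`
#' rescales BH by an estimate of the null proportion pi0 obtained by the
#' median-lambda method: the median over lambda in {0.05, ..., 0.95} of
#' \#\{p > lambda\} / (m(1 - lambda)), clipped to (0, 1]. A pi0 estimate of 1
#' makes the two methods identical.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @param method `"BH"` or `"storey"`.
#' @return vector of adjusted p-values (q-values).
#' @export
adjust_pvalues <- function(p, method = c("BH", "storey")) {
  method <- match.arg(method)
  if (any(is.na(p)) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]")
  q <- p.adjust(p, method = "BH")
  if (method == "BH") return(q)
  lambda <- seq(0.05, 0.95, by = 0.05)
  pi0 <- median(vapply(lambda, function(l) mean(p > l) / (1 - l), numeric(1)))
  pi0 <- min(pi0, 1)
  if (pi0 <= 0) pi0 <- 1 / length(p)
  pmin(pi0 * q, 1)
}
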