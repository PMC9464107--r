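## The PMQL (Poisson-Modification of Quasi Lindley) law is a mixed Poisson
## distribution: the Poisson rate follows the MQL density, a two-component
## mixture of an exponential(theta) and a gamma(delta, rate theta) with mixing
## weight p = alpha^3 / (alpha^3 + 1).  Marginally the counts are a mixture of
## a geometric(theta/(1+theta)) and a negative binomial(delta, theta/(1+theta)).

alpha_cubed <- function(alpha) alpha^3

mix_weight <- function(alpha) {
  a <- alpha^3
  a / (a + 1)
}

## coefficient of mu^2/(alpha^3+delta)^2 in the variance:
## alpha^3 (alpha^3 + 2 + delta(delta-1)) + delta, derived from the
## exponential/gamma mixture moments of the rate
var_shape <- function(alpha, delta) {
  a <- alpha^3
  a * (a + 2 + delta * (delta - 1)) + delta
}

check_dispersion <- function(alpha, delta) {
  if (!is.numeric(alpha) || length(alpha) != 1L || !is.finite(alpha) ||
      alpha^3 <= -1) {
    stop("`alpha` must be a finite scalar with alpha^3 > -1", call. = FALSE)
  }
  if (!is.numeric(delta) || length(delta) != 1L || !is.finite(delta) ||
      delta <= 0) {
    stop("`delta` must be a finite positive scalar", call. = FALSE)
  }
  invisible(TRUE)
}

check_theta <- function(theta) {
  if (!is.numeric(theta) || length(theta) < 1L || any(!is.finite(theta)) ||
      any(theta <= 0)) {
    stop("`theta` must be positive and finite", call. = FALSE)
  }
  invisible(TRUE)
}

#' MQL mixing density
#'
#' Density of the Modification of Quasi Lindley (MQL) distribution, the
#' mixing law of the Poisson rate in the PMQL model.  It is the two-component
#' mixture \eqn{p\,\mathrm{Exp}(\theta) + (1-p)\,\mathrm{Gamma}(\delta,\theta)}
#' with mixing weight \eqn{p = \alpha^3/(\alpha^3+1)}.
#'
#' @param x Vector of positive evaluation points (the Poisson rate).
#' @param theta Positive scale parameter (scalar or vector recycled with `x`).
#' @param alpha Shape parameter; enters only through \eqn{\alpha^3}, which
#'   must exceed \eqn{-1}.
#' @param delta Positive shape parameter of the gamma component.
#' @param log Return the log density?
#' @return Numeric vector of (log) density values.
#' @examples
#' dmql(0.7, theta = 0.5, alpha = 1.2, delta = 2)
#' @export
dmql <- function(x, theta, alpha, delta, log = FALSE) {
  check_dispersion(alpha, delta)
  check_theta(theta)
  if (any(!is.finite(x)) || any(x <= 0)) {
    stop("`x` must be positive (support of the mixing density)", call. = FALSE)
  }
  p <- mix_weight(alpha)
  l1 <- stats::dexp(x, rate = theta, log = TRUE)
  l2 <- stats::dgamma(x, shape = delta, rate = theta, log = TRUE)
  out <- signed_mix(p, l1, l2)
  if (log) log(out) else out
}

#' PMQL probability mass function
#'
#' Probability mass function of the Poisson-Modification of Quasi Lindley
#' distribution: the two-component mixture
#' \eqn{p\,\mathrm{Geom}(q) + (1-p)\,\mathrm{NB}(\delta, q)} with
#' \eqn{q = \theta/(1+\theta)} and \eqn{p = \alpha^3/(\alpha^3+1)}.
#' All arithmetic is carried out on the log scale.
#'
#' @param x Vector of non-negative integer counts.
#' @inheritParams dmql
#' @return Numeric vector of (log) probabilities.
#' @examples
#' dpmql(0:5, theta = 1, alpha = 1, delta = 1)  # geometric(1/2) collapse
#' @export
dpmql <- function(x, theta, alpha, delta, log = FALSE) {
  check_dispersion(alpha, delta)
  check_theta(theta)
  if (any(!is.finite(x)) || any(x < 0) || any(x != floor(x))) {
    stop("`x` must contain non-negative integers", call. = FALSE)
  }
  p <- mix_weight(alpha)
  q <- theta / (1 + theta)
  l1 <- stats::dgeom(x, prob = q, log = TRUE)
  l2 <- stats::dnbinom(x, size = delta, prob = q, log = TRUE)
  out <- signed_mix(p, l1, l2)
  if (log) log(out) else out
}

## mixture p*exp(l1) + (1-p)*exp(l2) without leaving the log scale longer
## than needed; supports the signed case -1 < alpha^3 < 0 (p < 0).
signed_mix <- function(p, l1, l2) {
  if (p >= 0) {
    m <- pmax(l1, l2)
    m[!is.finite(m)] <- 0
    exp(m) * (p * exp(l1 - m) + (1 - p) * exp(l2 - m))
  } else {
    m <- pmax(l1, l2)
    m[!is.finite(m)] <- 0
    val <- exp(m) * ((1 - p) * exp(l2 - m) - abs(p) * exp(l1 - m))
    if (any(val < -1e-12)) {
      warning("negative mixture mass encountered; parameters lie outside ",
              "the valid PMQL region", call. = FALSE)
    }
    pmax(val, 0)
  }
}

#' PMQL cumulative distribution function
#'
#' @inheritParams dpmql
#' @param q Vector of quantiles.
#' @return Numeric vector of cumulative probabilities.
#' @export
ppmql <- function(q, theta, alpha, delta) {
  check_dispersion(alpha, delta)
  check_theta(theta)
  p <- mix_weight(alpha)
  s <- theta / (1 + theta)
  qf <- floor(q)
  out <- p * stats::pgeom(qf, prob = s) +
    (1 - p) * stats::pnbinom(qf, size = delta, prob = s)
  out[q < 0] <- 0
  out
}

#' Moments of the PMQL distribution
#'
#' Mean, variance, and index of dispersion (variance-to-mean ratio) of the
#' PMQL law.  The mean is \eqn{\mu = (\alpha^3+\delta)/((\alpha^3+1)\theta)}
#' and the variance is
#' \eqn{\mu + \mu^2 [\alpha^3(\alpha^3+2+\delta(\delta-1)) + \delta] /
#' (\alpha^3+\delta)^2}; the index of dispersion always exceeds one, so the
#' distribution is overdispersed.
#'
#' @inheritParams dmql
#' @return A tibble with columns `theta`, `mean`, `variance`, and
#'   `dispersion_index`, one row per element of `theta`.
#' @examples
#' pmql_moments(1, alpha = 1, delta = 1)  # mean 1, variance 2
#' @export
pmql_moments <- function(theta, alpha, delta) {
  check_dispersion(alpha, delta)
  check_theta(theta)
  a <- alpha^3
  mu <- (a + delta) / ((a + 1) * theta)
  v <- mu + mu^2 * var_shape(alpha, delta) / (a + delta)^2
  tibble::tibble(theta = theta, mean = mu, variance = v,
                 dispersion_index = v / mu)
}

#' Random generation from the PMQL distribution
#'
#' Two sampling routes are provided and agree in distribution: the
#' hierarchical route draws the Poisson rate from the MQL mixing density and
#' then a Poisson count, while the inverse-transform route inverts the
#' cumulative pmf (extending the cumulative table adaptively over the
#' unbounded support).  Sampling requires a non-negative mixing weight,
#' i.e. \eqn{\alpha \ge 0}.
#'
#' @param n Number of draws.
#' @param theta Positive scale parameter; either a scalar or a vector of
#'   length `n` (one rate per draw, as in regression simulation).
#' @inheritParams dmql
#' @param method `"hierarchical"` (default) or `"inverse"`.
#' @return Integer vector of counts.
#' @examples
#' set.seed(1)
#' y <- rpmql(1000, theta = 0.5, alpha = 1.2, delta = 2)
#' mean(y)  # close to pmql_moments(0.5, 1.2, 2)$mean
#' @export
rpmql <- function(n, theta, alpha, delta,
                  method = c("hierarchical", "inverse")) {
  method <- match.arg(method)
  check_dispersion(alpha, delta)
  check_theta(theta)
  if (n < 1) stop("`n` must be at least 1", call. = FALSE)
  if (alpha^3 < 0) {
    stop("sampling requires alpha^3 >= 0 (both mixture weights non-negative)",
         call. = FALSE)
  }
  theta <- rep_len(theta, n)
  p <- mix_weight(alpha)
  if (method == "hierarchical") {
    is_exp <- stats::runif(n) < p
    lam <- numeric(n)
    if (any(is_exp)) lam[is_exp] <- stats::rexp(sum(is_exp), rate = theta[is_exp])
    if (any(!is_exp)) {
      lam[!is_exp] <- stats::rgamma(sum(!is_exp), shape = delta,
                                    rate = theta[!is_exp])
    }
    stats::rpois(n, lam)
  } else {
    rpmql_inverse(n, theta, alpha, delta)
  }
}

## inverse-transform sampler; caches the cumulative pmf per unique theta and
## extends the table until the cumulative mass exceeds 1 - 1e-12
rpmql_inverse <- function(n, theta, alpha, delta) {
  u <- stats::runif(n)
  out <- integer(n)
  for (th in unique(theta)) {
    idx <- which(theta == th)
    size <- 64L
    repeat {
      cdf <- cumsum(dpmql(0:(size - 1L), th, alpha, delta))
      if (cdf[size] > 1 - 1e-12 || size > 2^22) break
      size <- size * 2L
    }
    out[idx] <- findInterval(u[idx], cdf)
  }
  out
}

#' Moment diagnostics of a count sample
#'
#' Sample skewness, excess kurtosis (both from the moment estimators
#' \eqn{b_1 = m_3/m_2^{3/2}} and \eqn{b_2 = m_4/m_2^2 - 3}, without
#' small-sample corrections), and the index of dispersion of a vector of
#' counts.
#'
#' @param y Vector of counts, length at least 2, non-constant.
#' @return A one-row tibble with columns `skewness`, `excess_kurtosis`, and
#'   `dispersion_index`.
#' @examples
#' sample_stats(rep(0:2, each = 10))
#' @export
sample_stats <- function(y) {
  if (length(y) < 2L) stop("`y` must have at least 2 observations", call. = FALSE)
  m <- mean(y)
  m2 <- mean((y - m)^2)
  if (m2 == 0) stop("`y` is constant; moment statistics undefined", call. = FALSE)
  m3 <- mean((y - m)^3)
  m4 <- mean((y - m)^4)
  tibble::tibble(
    skewness = m3 / m2^1.5,
    excess_kurtosis = m4 / m2^2 - 3,
    dispersion_index = stats::var(y) / m
  )
}
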