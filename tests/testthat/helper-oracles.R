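# Independent oracles used across the suite.  These deliberately avoid the
# package's own code paths: the pmf oracle transcribes the closed algebraic
# form directly (no log scale, no mixture decomposition), and the moment
# oracle integrates the Poisson mixture numerically.

# closed-form PMQL pmf (plain arithmetic)
pmf_closed <- function(y, theta, alpha, delta) {
  a <- alpha^3
  theta / (factorial(y) * (a + 1) * (1 + theta)^(y + delta) * gamma(delta)) *
    (gamma(delta) * gamma(y + 1) * a * (1 + theta)^(delta - 1) +
       theta^(delta - 1) * gamma(y + delta))
}

# closed-form MQL density (plain arithmetic)
mql_closed <- function(x, theta, alpha, delta) {
  a <- alpha^3
  theta * exp(-theta * x) / ((a + 1) * gamma(delta)) *
    (gamma(delta) * a + (theta * x)^(delta - 1))
}

# pmf by adaptive quadrature of the Poisson-MQL mixture
pmf_quadrature <- function(y, theta, alpha, delta) {
  stats::integrate(function(l) stats::dpois(y, l) * dmql(l, theta, alpha, delta),
                   0, Inf, rel.tol = 1e-12)$value
}

# central finite-difference gradient
fd_grad <- function(f, x, h = 1e-6) {
  vapply(seq_along(x), function(j) {
    e <- numeric(length(x)); e[j] <- h
    (f(x + e) - f(x - e)) / (2 * h)
  }, numeric(1))
}

# random orthogonal matrix
rand_orthogonal <- function(p) {
  qr.Q(qr(matrix(stats::rnorm(p * p), p)))
}

# synthetic converged-fit object with prescribed spectrum and coefficients;
# mirrors the fields of pmql_fit that the shrinkage layer consumes
make_synthetic_fit <- function(lambda, beta, Gamma = NULL) {
  p1 <- length(lambda)
  stopifnot(length(beta) == p1)
  if (is.null(Gamma)) Gamma <- rand_orthogonal(p1)
  S <- Gamma %*% (t(Gamma) * lambda)
  S <- (S + t(S)) / 2
  covm <- Gamma %*% (t(Gamma) / lambda)
  nms <- paste0("b", seq_len(p1))
  names(beta) <- nms
  dimnames(covm) <- list(nms, nms)
  structure(list(
    coefficients = beta,
    XtWX = S,
    eigenvalues = lambda,
    eigenvectors = Gamma,
    alpha_canon = drop(crossprod(Gamma, beta)),
    cov = covm,
    se = sqrt(diag(covm)),
    smse = sum(1 / lambda),
    converged = TRUE
  ), class = "pmql_fit")
}

rand_fit <- function(p1 = 4, lambda_min = 0.2, lambda_max = 50,
                     beta_scale = 1) {
  lambda <- sort(stats::runif(p1, lambda_min, lambda_max), decreasing = TRUE)
  make_synthetic_fit(lambda, stats::rnorm(p1, sd = beta_scale))
}

# smallest eigenvalue of the assembled MSE difference MSE(a) - MSE(b)
mse_diff_min_eigen <- function(mse_a, mse_b) {
  min(eigen((mse_a - mse_b + t(mse_a - mse_b)) / 2, symmetric = TRUE,
            only.values = TRUE)$values)
}
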