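## PMQL log-linear regression.  The mean is linked by log(mu_i) = x_i'beta and
## the distribution reparameterized through
## theta_i = (alpha^3 + delta) / ((alpha^3 + 1) exp(x_i'beta)), so that the
## conditional mean is exactly exp(x_i'beta).  Coefficients are estimated by
## iteratively weighted least squares (Fisher scoring) with the model-based
## weights W_ii = mu_i (alpha^3+delta)^2 / ((alpha^3+delta)^2 + mu_i c) where
## c = alpha^3(alpha^3+2+delta(delta-1)) + delta, and working response
## z_i = log(mu_i) + (y_i - mu_i)/mu_i.

#' Scale parameter from a linear predictor
#'
#' Inverts the mean parameterization of the PMQL regression model: given a
#' linear predictor value \eqn{\eta}, returns the scale
#' \eqn{\theta = (\alpha^3+\delta) / ((\alpha^3+1) e^{\eta})} for which the
#' PMQL mean equals \eqn{e^{\eta}}.
#'
#' @param linpred Numeric vector of linear predictor values.
#' @inheritParams dmql
#' @param clamp Absolute bound applied to `linpred` before exponentiation to
#'   avoid overflow; a warning is issued when it bites.
#' @return Numeric vector of positive scale parameters.
#' @examples
#' theta_from_linpred(0, alpha = 1, delta = 1)  # 1
#' @export
theta_from_linpred <- function(linpred, alpha, delta, clamp = 30) {
  check_dispersion(alpha, delta)
  a <- alpha^3
  if (any(abs(linpred) > clamp)) {
    warning("linear predictor clamped to [-", clamp, ", ", clamp, "]",
            call. = FALSE)
    linpred <- pmin(pmax(linpred, -clamp), clamp)
  }
  (a + delta) / ((a + 1) * exp(linpred))
}

#' Log-likelihood of the PMQL regression model
#'
#' Sum of per-observation log pmf values at
#' \eqn{\theta_i = } [theta_from_linpred()]\eqn{(x_i'\beta)}.
#'
#' @param beta Coefficient vector of length `ncol(X)`.
#' @param X Design matrix whose first column is the intercept.
#' @param y Vector of non-negative integer counts.
#' @inheritParams dmql
#' @return Scalar log-likelihood.
#' @export
pmql_loglik <- function(beta, X, y, alpha, delta) {
  eta <- drop(X %*% beta)
  th <- theta_from_linpred(eta, alpha, delta)
  sum(dpmql(y, th, alpha, delta, log = TRUE))
}

#' Score vector of the PMQL regression model
#'
#' Analytic gradient of [pmql_loglik()] with respect to the coefficients.
#' Writing \eqn{A_i = (\alpha^3+1)\mu_i + (\alpha^3+\delta)}, the i-th
#' contribution is
#' \eqn{[y_i - (y_i+\delta)(\alpha^3+1)\mu_i/A_i +
#' (\delta-1)(\alpha^3+1)(\mu_i/A_i) r_i] x_i}
#' where \eqn{r_i} is the share of the first mixture component in the pmf
#' numerator, evaluated on the log scale.
#'
#' @inheritParams pmql_loglik
#' @return Numeric gradient vector of length `ncol(X)`.
#' @export
pmql_score <- function(beta, X, y, alpha, delta) {
  check_dispersion(alpha, delta)
  a <- alpha^3
  eta <- drop(X %*% beta)
  mu <- exp(eta)
  A <- (a + 1) * mu + (a + delta)
  if (a > 0) {
    l1 <- lgamma(delta) + lgamma(y + 1) + log(a) + (delta - 1) * log(A)
    l2 <- (delta - 1) * log(a + delta) + lgamma(y + delta)
    r <- stats::plogis(l1 - l2)
  } else if (a == 0) {
    r <- rep(0, length(y))
  } else {
    b1 <- a * exp(lgamma(delta) + lgamma(y + 1) + (delta - 1) * log(A))
    b2 <- exp((delta - 1) * log(a + delta) + lgamma(y + delta))
    r <- b1 / (b1 + b2)
  }
  coefs <- y - (y + delta) * (a + 1) * mu / A +
    (delta - 1) * (a + 1) * mu / A * r
  drop(crossprod(X, coefs))
}

## model-based IWLS weights and working response at linear predictor eta
iwls_parts <- function(eta, y, alpha, delta) {
  a <- alpha^3
  s2 <- (a + delta)^2
  cc <- var_shape(alpha, delta)
  mu <- exp(eta)
  list(
    mu = mu,
    weights = mu * s2 / (s2 + mu * cc),
    working = eta + (y - mu) / mu
  )
}

#' One IWLS step
#'
#' Computes the model-based weights, the working response, and the updated
#' coefficient vector \eqn{(X'WX)^{-1} X'Wz} from a current coefficient value.
#' Exposed mainly for didactic and diagnostic use; [pmql_fit()] iterates it.
#'
#' @inheritParams pmql_loglik
#' @param clamp Absolute bound on the linear predictor inside the step.
#' @return A list with elements `weights`, `working`, `coefficients` (the
#'   updated vector), and `XtWX`.
#' @export
pmql_iwls_step <- function(beta, X, y, alpha, delta, clamp = 30) {
  eta <- pmin(pmax(drop(X %*% beta), -clamp), clamp)
  parts <- iwls_parts(eta, y, alpha, delta)
  XtWX <- crossprod(X, parts$weights * X)
  upd <- tryCatch(
    solve(XtWX, crossprod(X, parts$weights * parts$working)),
    error = function(e) {
      ev <- eigen(XtWX, symmetric = TRUE, only.values = TRUE)$values
      stop("weighted cross-product matrix is (numerically) singular; ",
           "condition number ", format(max(ev) / max(min(ev), 1e-300)),
           call. = FALSE)
    }
  )
  list(weights = parts$weights, working = parts$working,
       coefficients = drop(upd), XtWX = XtWX)
}

#' Fit the PMQL regression model
#'
#' Estimates the coefficients of the PMQL log-linear model by iteratively
#' weighted least squares (Fisher scoring) at fixed dispersion parameters
#' `(alpha, delta)`.  The converged state carries everything the shrinkage
#' estimators need: the weighted cross-product matrix \eqn{X'\hat W X}, its
#' spectral decomposition \eqn{\Gamma \Lambda \Gamma'}, the canonical
#' coefficients \eqn{\hat\alpha = \Gamma'\hat\beta}, the asymptotic
#' covariance \eqn{(X'\hat W X)^{-1}}, and the scalar mean square error
#' \eqn{\mathrm{SMSE} = \sum_j 1/\lambda_j}.
#'
#' @param data A data frame containing the response and covariates.
#' @param formula Model formula, e.g. `y ~ x1 + x2`.  An intercept is
#'   required.
#' @param alpha,delta Dispersion parameters, held fixed during fitting (the
#'   usual mode for estimator comparisons).  Use [pmql_fit_dispersion()] to
#'   estimate them by profile likelihood.
#' @param init Optional starting coefficient vector; by default ordinary
#'   least squares of `log(y + 0.5)` on the design.
#' @param tol Convergence tolerance on the max-norm coefficient change.
#' @param max_iter Maximum IWLS iterations.  Non-convergence returns a
#'   result flagged `converged = FALSE` rather than an error.
#' @param clamp Absolute bound on the linear predictor inside iterations.
#' @return An object of class `pmql_fit`.
#' @examples
#' d <- sim_fixture("well-conditioned", seed = 1)
#' fit <- pmql_fit(d, y ~ ., alpha = 0.25, delta = 0.04)
#' glance(fit)
#' @export
pmql_fit <- function(data, formula, alpha, delta, init = NULL,
                     tol = 1e-8, max_iter = 100L, clamp = 30) {
  mf <- stats::model.frame(formula, data = data)
  y <- stats::model.response(mf)
  X <- stats::model.matrix(attr(mf, "terms"), mf)
  if (!all(X[, 1] == 1)) {
    stop("the model must include an intercept", call. = FALSE)
  }
  fit <- pmql_fit_xy(X, y, alpha, delta, init = init, tol = tol,
                     max_iter = max_iter, clamp = clamp)
  fit$call <- match.call()
  fit$formula <- formula
  fit
}

#' Fit the PMQL regression model from a design matrix
#'
#' Matrix interface behind [pmql_fit()]; used directly by the simulation
#' engine.
#'
#' @inheritParams pmql_loglik
#' @inheritParams pmql_fit
#' @return An object of class `pmql_fit`.
#' @export
pmql_fit_xy <- function(X, y, alpha, delta, init = NULL,
                        tol = 1e-8, max_iter = 100L, clamp = 30) {
  check_dispersion(alpha, delta)
  X <- as.matrix(X)
  if (is.null(colnames(X))) {
    nm <- "(Intercept)"
    if (ncol(X) > 1L) nm <- c(nm, paste0("x", seq_len(ncol(X) - 1L)))
    colnames(X) <- nm
  }
  if (any(y < 0) || any(y != floor(y))) {
    stop("`y` must contain non-negative integer counts", call. = FALSE)
  }
  n <- nrow(X); p1 <- ncol(X)
  if (n <= p1) stop("need more observations than coefficients", call. = FALSE)

  beta <- if (is.null(init)) {
    drop(qr.solve(X, log(y + 0.5)))
  } else {
    stopifnot(length(init) == p1)
    as.numeric(init)
  }
  converged <- FALSE
  n_clamped <- 0L
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    eta_raw <- drop(X %*% beta)
    n_clamped <- n_clamped + sum(abs(eta_raw) > clamp)
    step <- pmql_iwls_step(beta, X, y, alpha, delta, clamp = clamp)
    delta_beta <- max(abs(step$coefficients - beta))
    beta <- step$coefficients
    if (delta_beta < tol) {
      converged <- TRUE
      break
    }
  }

  eta <- pmin(pmax(drop(X %*% beta), -clamp), clamp)
  parts <- iwls_parts(eta, y, alpha, delta)
  XtWX <- crossprod(X, parts$weights * X)
  es <- eigen(XtWX, symmetric = TRUE)
  lambda <- es$values
  Gamma <- fix_eigenvector_signs(es$vectors)
  if (min(lambda) <= 0) {
    stop("weighted cross-product matrix is singular (eigenvalues: ",
         paste(format(lambda, digits = 4), collapse = ", "), ")",
         call. = FALSE)
  }
  covm <- Gamma %*% (t(Gamma) / lambda)
  dimnames(covm) <- list(colnames(X), colnames(X))
  names(beta) <- colnames(X)

  structure(list(
    coefficients = beta,
    alpha = alpha, delta = delta,
    weights = parts$weights,
    working = parts$working,
    fitted_values = parts$mu,
    XtWX = XtWX,
    eigenvalues = lambda,
    eigenvectors = Gamma,
    alpha_canon = drop(crossprod(Gamma, beta)),
    cov = covm,
    se = sqrt(diag(covm)),
    smse = sum(1 / lambda),
    loglik = sum(dpmql(y, theta_from_linpred(eta, alpha, delta),
                       alpha, delta, log = TRUE)),
    n_iter = iter,
    converged = converged,
    n_clamped = n_clamped,
    dispersion_estimated = FALSE,
    X = X, y = y,
    nobs = n
  ), class = "pmql_fit")
}

## deterministic eigenvector orientation: largest-magnitude entry positive
fix_eigenvector_signs <- function(V) {
  for (j in seq_len(ncol(V))) {
    i <- which.max(abs(V[, j]))
    if (V[i, j] < 0) V[, j] <- -V[, j]
  }
  V
}

#' Condition number of the weighted cross-product matrix
#'
#' Ratio of the largest to smallest eigenvalue of \eqn{X'\hat W X}.  Values
#' above 1000 indicate severe multicollinearity.
#'
#' @param fit A `pmql_fit` object.
#' @return Scalar condition number.
#' @export
condition_number <- function(fit) {
  lam <- fit$eigenvalues
  if (min(lam) <= 0) stop("singular weighted cross-product matrix", call. = FALSE)
  max(lam) / min(lam)
}

#' Profile estimation of the dispersion parameters
#'
#' Maximizes the profile log-likelihood over `(alpha, delta)` with an inner
#' IWLS fit for the coefficients at each candidate pair.  The search is over
#' `alpha > 0`, `delta > 0` on the log scale by Nelder-Mead.
#'
#' @inheritParams pmql_fit
#' @param start Named vector of starting values `c(alpha = , delta = )`.
#' @param control Passed to [stats::optim()].
#' @return A list with `alpha`, `delta`, the profiled `fit` (a `pmql_fit`
#'   whose `dispersion_estimated` flag is set), and the optimizer result
#'   `opt`.
#' @export
pmql_fit_dispersion <- function(data, formula,
                                start = c(alpha = 0.5, delta = 0.5),
                                control = list(maxit = 200)) {
  mf <- stats::model.frame(formula, data = data)
  y <- stats::model.response(mf)
  X <- stats::model.matrix(attr(mf, "terms"), mf)
  if (nrow(X) <= ncol(X) + 2L) {
    stop("need n > p + 3 observations to profile the dispersion", call. = FALSE)
  }
  if (all(y == 0)) {
    stop("response is identically zero; no finite optimum", call. = FALSE)
  }
  neg_profile <- function(par) {
    al <- exp(par[1]); dl <- exp(par[2])
    f <- tryCatch(pmql_fit_xy(X, y, al, dl), error = function(e) NULL)
    if (is.null(f) || !is.finite(f$loglik)) return(1e10)
    -f$loglik
  }
  opt <- stats::optim(log(c(start[["alpha"]], start[["delta"]])),
                      neg_profile, method = "Nelder-Mead", control = control)
  if (opt$value >= 1e10) {
    stop("dispersion profiling failed to find a usable optimum", call. = FALSE)
  }
  alpha_hat <- exp(opt$par[1]); delta_hat <- exp(opt$par[2])
  fit <- pmql_fit_xy(X, y, alpha_hat, delta_hat)
  fit$dispersion_estimated <- TRUE
  list(alpha = alpha_hat, delta = delta_hat, fit = fit, opt = opt)
}

#' Chi-square goodness of fit for the marginal count distribution
#'
#' Groups the observed counts into bins `0, 1, 2, ...` (merging from the
#' right until every expected bin count reaches `min_expected`), computes the
#' expected counts from the fitted PMQL marginal (the average of the
#' per-observation pmfs), and returns the Pearson statistic with
#' `df = bins - 1 - n_params`.
#'
#' @param fit A converged `pmql_fit`.
#' @param min_expected Minimum expected count per bin (Pearson rule).
#' @return A one-row tibble with `statistic`, `df`, `p_value`, and `bins`.
#' @export
pmql_gof <- function(fit, min_expected = 5) {
  y <- fit$y
  n <- length(y)
  th <- theta_from_linpred(log(fit$fitted_values), fit$alpha, fit$delta)
  kmax <- max(y)
  ## expected count in bin k, averaged over observations; last bin is a tail
  expected <- vapply(0:kmax, function(k) {
    sum(dpmql(rep(k, n), th, fit$alpha, fit$delta))
  }, numeric(1))
  tail_mass <- n - sum(expected)
  expected <- c(expected, max(tail_mass, 0))
  observed <- c(tabulate(y + 1L, nbins = kmax + 1L), 0)
  ## merge right-to-left until all expected >= min_expected
  while (length(expected) > 2L && min(expected) < min_expected) {
    k <- length(expected)
    expected[k - 1L] <- expected[k - 1L] + expected[k]
    observed[k - 1L] <- observed[k - 1L] + observed[k]
    expected <- expected[-k]; observed <- observed[-k]
  }
  n_params <- length(fit$coefficients) + 2L * fit$dispersion_estimated
  df <- length(expected) - 1L - n_params
  if (df < 1L) {
    stop("too few bins after merging to test goodness of fit", call. = FALSE)
  }
  stat <- sum((observed - expected)^2 / expected)
  tibble::tibble(statistic = stat, df = df,
                 p_value = stats::pchisq(stat, df, lower.tail = FALSE),
                 bins = length(expected))
}

#' @export
logLik.pmql_fit <- function(object, ...) {
  structure(object$loglik,
            df = length(object$coefficients) + 2L * object$dispersion_estimated,
            nobs = object$nobs, class = "logLik")
}

#' @export
coef.pmql_fit <- function(object, ...) object$coefficients

#' @export
fitted.pmql_fit <- function(object, ...) object$fitted_values

#' @export
vcov.pmql_fit <- function(object, ...) object$cov

#' @export
residuals.pmql_fit <- function(object, type = c("pearson", "response"), ...) {
  type <- match.arg(type)
  mu <- object$fitted_values
  r <- object$y - mu
  if (type == "response") return(r)
  s2 <- (object$alpha^3 + object$delta)^2
  v <- mu + mu^2 * var_shape(object$alpha, object$delta) / s2
  r / sqrt(v)
}

#' @export
print.pmql_fit <- function(x, ...) {
  cat("PMQL regression fit (alpha =", x$alpha, ", delta =", x$delta, ")\n")
  cat("Coefficients:\n")
  print(round(x$coefficients, 4))
  cat("logLik:", format(x$loglik), "  SMSE:", format(x$smse),
      "  condition number:", format(condition_number(x)), "\n")
  if (!x$converged) cat("WARNING: IWLS did not converge\n")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @exportS3Method generics::tidy
tidy.pmql_fit <- function(x, ...) {
  est <- x$coefficients
  se <- x$se
  z <- est / se
  tibble::tibble(
    term = names(est),
    estimate = unname(est),
    std.error = unname(se),
    statistic = unname(z),
    p.value = 2 * stats::pnorm(-abs(z))
  )
}

#' @exportS3Method generics::glance
glance.pmql_fit <- function(x, ...) {
  tibble::tibble(
    logLik = x$loglik,
    AIC = stats::AIC(x),
    smse = x$smse,
    condition_number = condition_number(x),
    nobs = x$nobs,
    n_iter = x$n_iter,
    converged = x$converged
  )
}
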