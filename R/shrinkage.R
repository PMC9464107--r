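## Liu and ridge shrinkage on a converged PMQL fit.  With S = X'WX,
## the Liu estimator is beta_d = (S+I)^{-1}(S+dI) beta_hat, d in [0,1], and
## the ridge estimator is beta_k = (S+kI)^{-1} S beta_hat, k >= 0.  Both
## recover the unshrunken fit at their boundary (d = 1, k = 0).  Bias, MSE
## matrix and SMSE are evaluated at a plug-in coefficient vector (the fitted
## coefficients for data analysis; the known truth inside simulations).

#' Liu shrinkage estimate
#'
#' Applies the Liu transformation
#' \eqn{L_d = (X'\hat W X + I)^{-1}(X'\hat W X + dI)} to the fitted
#' coefficients and assembles bias, covariance, MSE matrix and SMSE.  The
#' spectral SMSE is
#' \eqn{\sum_j (\lambda_j+d)^2 / (\lambda_j(\lambda_j+1)^2) +
#' (d-1)^2 \sum_j \alpha_j^2/(\lambda_j+1)^2}.
#'
#' @param fit A converged `pmql_fit`.
#' @param d Liu parameter in `[0, 1]`; `d = 1` reproduces the unshrunken fit.
#' @param selector Label recorded for the rule that produced `d`.
#' @param beta_ref Coefficient vector at which bias and MSE are evaluated;
#'   defaults to the fitted coefficients (plug-in).
#' @return An object of class `pmql_shrinkage`.
#' @examples
#' d <- sim_fixture("well-conditioned", seed = 1)
#' fit <- pmql_fit(d, y ~ ., alpha = 0.25, delta = 0.04)
#' liu_estimate(fit, d = 0.5)
#' @export
liu_estimate <- function(fit, d, selector = "manual",
                         beta_ref = stats::coef(fit)) {
  if (!is.numeric(d) || length(d) != 1L || d < 0 || d > 1) {
    stop("`d` must be a scalar in [0, 1]", call. = FALSE)
  }
  S <- fit$XtWX
  p1 <- ncol(S)
  I <- diag(p1)
  SI_inv <- solve(S + I)
  Ld <- SI_inv %*% (S + d * I)
  beta <- drop(Ld %*% stats::coef(fit))
  bias <- drop((d - 1) * SI_inv %*% beta_ref)
  covm <- Ld %*% fit$cov %*% t(Ld)
  mse <- covm + tcrossprod(bias)
  new_shrinkage("liu", d, selector, beta, bias, covm, mse,
                names(stats::coef(fit)))
}

#' Ridge shrinkage estimate
#'
#' Applies the ridge transformation
#' \eqn{(X'\hat W X + kI)^{-1} X'\hat W X} to the fitted coefficients, with
#' bias \eqn{-k (X'\hat W X + kI)^{-1}\beta}, covariance
#' \eqn{(S+kI)^{-1} S (S+kI)^{-1}}, and spectral SMSE
#' \eqn{\sum_j \lambda_j/(\lambda_j+k)^2 +
#' k^2 \sum_j \alpha_j^2/(\lambda_j+k)^2}.
#'
#' @inheritParams liu_estimate
#' @param k Ridge parameter, non-negative; `k = 0` reproduces the fit.
#' @return An object of class `pmql_shrinkage`.
#' @export
ridge_estimate <- function(fit, k, selector = "manual",
                           beta_ref = stats::coef(fit)) {
  if (!is.numeric(k) || length(k) != 1L || k < 0) {
    stop("`k` must be a non-negative scalar", call. = FALSE)
  }
  S <- fit$XtWX
  I <- diag(ncol(S))
  A <- solve(S + k * I)
  beta <- drop(A %*% S %*% stats::coef(fit))
  bias <- drop(-k * A %*% beta_ref)
  covm <- A %*% S %*% A
  mse <- covm + tcrossprod(bias)
  new_shrinkage("ridge", k, selector, beta, bias, covm, mse,
                names(stats::coef(fit)))
}

new_shrinkage <- function(family, param, selector, beta, bias, covm, mse,
                          nms) {
  names(beta) <- nms
  dimnames(covm) <- dimnames(mse) <- list(nms, nms)
  structure(list(
    family = family, param = param, selector = selector,
    coefficients = beta, bias = bias, cov = covm, mse_matrix = mse,
    smse = sum(diag(mse)), se = sqrt(diag(covm))
  ), class = "pmql_shrinkage")
}

#' @export
print.pmql_shrinkage <- function(x, ...) {
  cat(sprintf("PMQL %s estimate (%s = %.4f, selector %s)\n",
              x$family, if (x$family == "liu") "d" else "k",
              x$param, x$selector))
  print(round(x$coefficients, 4))
  cat("SMSE:", format(x$smse), "\n")
  invisible(x)
}

#' @export
coef.pmql_shrinkage <- function(object, ...) object$coefficients

#' @exportS3Method generics::tidy
tidy.pmql_shrinkage <- function(x, ...) {
  tibble::tibble(
    term = names(x$coefficients),
    estimate = unname(x$coefficients),
    std.error = unname(x$se),
    bias = unname(x$bias)
  )
}

#' @exportS3Method generics::glance
glance.pmql_shrinkage <- function(x, ...) {
  tibble::tibble(
    family = x$family, selector = x$selector, param = x$param,
    smse = x$smse, bias_norm = sqrt(sum(x$bias^2))
  )
}

#' Coordinate-wise optimal Liu parameters
#'
#' The value \eqn{d_j = (\alpha_j^2 - 1)/(1/\lambda_j + \alpha_j^2)} that
#' zeroes the derivative of the j-th spectral SMSE contribution.  Each
#' \eqn{d_j < 1}; it is negative exactly when \eqn{\alpha_j^2 < 1}.
#'
#' @param fit A converged `pmql_fit`.
#' @return Numeric vector of per-coordinate optimal values (untruncated).
#' @export
optimal_d_components <- function(fit) {
  ac2 <- fit$alpha_canon^2
  (ac2 - 1) / (1 / fit$eigenvalues + ac2)
}

#' Liu parameter selectors
#'
#' Data-driven rules for the Liu parameter, built from the canonical
#' coefficients \eqn{\hat\alpha_j = (\Gamma'\hat\beta)_j} and eigenvalues
#' \eqn{\hat\lambda_j} of the weighted cross-product matrix.  With
#' \eqn{g_j = (\hat\alpha_j^2-1)/(1/\hat\lambda_j + \hat\alpha_j^2)}:
#' `D1` evaluates g at the pair (largest \eqn{\hat\alpha_j^2}, largest
#' \eqn{\hat\lambda_j}); `D2`, `D3`, `D4`, `D5` are the median, mean,
#' maximum and minimum of the \eqn{g_j}.  All results are truncated below
#' at 0 and capped at 1.
#'
#' @param fit A converged `pmql_fit`.
#' @param method One of `"D1"` ... `"D5"`.
#' @return Selected Liu parameter in `[0, 1]`.
#' @export
select_d <- function(fit, method = c("D1", "D2", "D3", "D4", "D5")) {
  method <- match.arg(method)
  lam <- fit$eigenvalues
  ac2 <- fit$alpha_canon^2
  g <- (ac2 - 1) / (1 / lam + ac2)
  val <- switch(method,
    D1 = (max(ac2) - 1) / (1 / max(lam) + max(ac2)),
    D2 = stats::median(g),
    D3 = mean(g),
    D4 = max(g),
    D5 = min(g)
  )
  min(max(0, val), 1)
}

#' Ridge parameter selectors
#'
#' Data-driven rules for the ridge parameter:
#' `k2` \eqn{= (p+1) / \sum_j [\hat\alpha_j^2 /
#' (1 + (1 + \hat\lambda_j\hat\alpha_j^2)^{1/2})]},
#' `k7` \eqn{= \max_j \hat\alpha_j^2}, and
#' `k12` \eqn{= \mathrm{median}_j\, 1/\hat\alpha_j^2}.
#'
#' @param fit A converged `pmql_fit`.
#' @param method One of `"k2"`, `"k7"`, `"k12"`.
#' @return Selected ridge parameter (non-negative).
#' @export
select_k <- function(fit, method = c("k2", "k7", "k12")) {
  method <- match.arg(method)
  lam <- fit$eigenvalues
  ac2 <- fit$alpha_canon^2
  switch(method,
    k2 = length(lam) / sum(ac2 / (1 + sqrt(1 + lam * ac2))),
    k7 = max(ac2),
    k12 = {
      if (any(ac2 == 0)) {
        stop("a canonical coefficient is exactly zero; k12 undefined",
             call. = FALSE)
      }
      stats::median(1 / ac2)
    }
  )
}

## spectral SMSE of the unshrunken, Liu and ridge estimators at plug-in
## canonical coefficients
smse_mle_spectral <- function(fit) sum(1 / fit$eigenvalues)

smse_liu_spectral <- function(fit, d, alpha_canon = fit$alpha_canon) {
  lam <- fit$eigenvalues
  sum((lam + d)^2 / (lam * (lam + 1)^2)) +
    (d - 1)^2 * sum(alpha_canon^2 / (lam + 1)^2)
}

smse_ridge_spectral <- function(fit, k, alpha_canon = fit$alpha_canon) {
  lam <- fit$eigenvalues
  sum(lam / (lam + k)^2) + k^2 * sum(alpha_canon^2 / (lam + k)^2)
}

#' SMSE advantage of the Liu estimator over the unshrunken fit
#'
#' \eqn{\Delta(d) = \mathrm{SMSE}_{\mathrm{MLE}} - \mathrm{SMSE}_{\mathrm{Liu}}(d)}
#' in the spectral form; \eqn{\Delta(1) = 0} exactly, and \eqn{\Delta(d) > 0}
#' means the Liu estimator is superior at that `d`.
#'
#' @inheritParams optimal_d_components
#' @param d Liu parameter in `[0, 1]`.
#' @return Scalar difference.
#' @export
smse_difference <- function(fit, d) {
  if (d < 0 || d > 1) stop("`d` must lie in [0, 1]", call. = FALSE)
  smse_mle_spectral(fit) - smse_liu_spectral(fit, d)
}

#' Variance and squared-bias terms of the Liu SMSE over a grid
#'
#' Decomposes the spectral Liu SMSE into its monotonically increasing
#' variance term \eqn{\sum_j (\lambda_j+d)^2/(\lambda_j(\lambda_j+1)^2)} and
#' monotonically decreasing squared-bias term
#' \eqn{(d-1)^2 \sum_j \alpha_j^2/(\lambda_j+1)^2}.
#'
#' @inheritParams optimal_d_components
#' @param d_grid Numeric grid of Liu parameters in `[0, 1]`.
#' @return A tibble with columns `d`, `term_variance`, `term_bias2`, `smse`.
#' @export
smse_curve_terms <- function(fit, d_grid = seq(0, 1, by = 0.01)) {
  if (any(d_grid < 0 | d_grid > 1)) {
    stop("`d_grid` must lie in [0, 1]", call. = FALSE)
  }
  lam <- fit$eigenvalues
  ac2 <- fit$alpha_canon^2
  tv <- vapply(d_grid, function(d) sum((lam + d)^2 / (lam * (lam + 1)^2)),
               numeric(1))
  tb <- vapply(d_grid, function(d) (d - 1)^2 * sum(ac2 / (lam + 1)^2),
               numeric(1))
  tibble::tibble(d = d_grid, term_variance = tv, term_bias2 = tb,
                 smse = tv + tb)
}

#' Matrix superiority of the Liu estimator over the unshrunken fit
#'
#' Checks the sufficient spectral condition
#' \eqn{\min_j [\lambda_j(\lambda_j+1)^2 - (\lambda_j+d)^2] > 0} and the
#' quadratic form \eqn{b_d' M^{-1} b_d} with
#' \eqn{M = \Gamma(\Lambda^{-1} - (\Lambda+I)^{-1}(\Lambda+dI)\Lambda^{-1}
#' (\Lambda+dI)(\Lambda+I)^{-1})\Gamma'}.  When the spectral condition holds,
#' the MSE-matrix difference (unshrunken minus Liu) is positive definite if
#' and only if the quadratic form is below one.
#'
#' @inheritParams liu_estimate
#' @return One-row tibble with `condition_a` (logical), `quadratic_form`,
#'   and `verdict` (`"superior"`, `"not-superior"`, `"boundary"` at `d = 1`,
#'   or `"not-established"` when the spectral condition fails).
#' @export
theorem1_check <- function(fit, d, beta_ref = stats::coef(fit)) {
  if (d < 0 || d > 1) stop("`d` must lie in [0, 1]", call. = FALSE)
  lam <- fit$eigenvalues
  G <- fit$eigenvectors
  cond_vals <- lam * (lam + 1)^2 - (lam + d)^2
  cond_a <- min(cond_vals) > 0
  if (d == 1) {
    return(tibble::tibble(condition_a = cond_a, quadratic_form = 0,
                          verdict = "boundary"))
  }
  S_I <- solve(fit$XtWX + diag(ncol(G)))
  b_d <- drop((d - 1) * S_I %*% beta_ref)
  diag_m <- 1 / lam - (lam + d)^2 / (lam * (lam + 1)^2)
  qf <- drop(crossprod(b_d, G %*% (crossprod(G, b_d) / diag_m)))
  verdict <- if (!cond_a) "not-established"
             else if (qf < 1) "superior" else "not-superior"
  tibble::tibble(condition_a = cond_a, quadratic_form = qf, verdict = verdict)
}

#' Matrix superiority of the Liu estimator over the ridge estimator
#'
#' Analogue of [theorem1_check()] comparing MSE matrices of the ridge
#' estimator at `k` and the Liu estimator at `d`.  The spectral condition is
#' \eqn{\min_j [\lambda_j^2(\lambda_j+1)^2 - (\lambda_j+d)^2(\lambda_j+k)^2]
#' > 0} and the quadratic form uses
#' \eqn{M = \Gamma((\Lambda+kI)^{-1}\Lambda(\Lambda+kI)^{-1} -
#' (\Lambda+I)^{-1}(\Lambda+dI)\Lambda^{-1}(\Lambda+dI)(\Lambda+I)^{-1})
#' \Gamma' + b_k b_k'}.
#'
#' @inheritParams liu_estimate
#' @param k Ridge parameter, non-negative.
#' @return One-row tibble as in [theorem1_check()].
#' @export
theorem2_check <- function(fit, d, k, beta_ref = stats::coef(fit)) {
  if (d < 0 || d > 1) stop("`d` must lie in [0, 1]", call. = FALSE)
  if (k < 0) stop("`k` must be non-negative", call. = FALSE)
  lam <- fit$eigenvalues
  G <- fit$eigenvectors
  cond_vals <- lam^2 * (lam + 1)^2 - (lam + d)^2 * (lam + k)^2
  cond_a <- min(cond_vals) > 0
  if (d == 1 && k == 0) {
    return(tibble::tibble(condition_a = cond_a, quadratic_form = 0,
                          verdict = "boundary"))
  }
  I <- diag(ncol(G))
  S_I <- solve(fit$XtWX + I)
  S_k <- solve(fit$XtWX + k * I)
  b_d <- drop((d - 1) * S_I %*% beta_ref)
  b_k <- drop(-k * S_k %*% beta_ref)
  diag_m <- lam / (lam + k)^2 - (lam + d)^2 / (lam * (lam + 1)^2)
  M <- G %*% (t(G) * diag_m) + tcrossprod(b_k)
  qf <- tryCatch(drop(crossprod(b_d, solve(M, b_d))),
                 error = function(e) {
                   stop("superiority matrix is numerically singular ",
                        "(eigenvalues: ",
                        paste(format(eigen(M, symmetric = TRUE,
                                           only.values = TRUE)$values,
                                     digits = 4), collapse = ", "), ")",
                        call. = FALSE)
                 })
  verdict <- if (!cond_a) "not-established"
             else if (qf < 1) "superior" else "not-superior"
  tibble::tibble(condition_a = cond_a, quadratic_form = qf, verdict = verdict)
}

#' All shrinkage estimates for a fit
#'
#' Convenience wrapper applying every requested Liu and ridge selector to a
#' converged fit.
#'
#' @inheritParams optimal_d_components
#' @param selectors Character vector drawn from
#'   `c("D1","D2","D3","D4","D5","k2","k7","k12")`.
#' @return A tibble with one row per selector: `selector`, `family`,
#'   `param`, `smse`, and a list-column `estimate` of `pmql_shrinkage`
#'   objects.
#' @examples
#' d <- sim_fixture("well-conditioned", seed = 1)
#' fit <- pmql_fit(d, y ~ ., alpha = 0.25, delta = 0.04)
#' pmql_shrink(fit)
#' @export
pmql_shrink <- function(fit,
                        selectors = c("D1", "D2", "D3", "D4", "D5",
                                      "k2", "k7", "k12")) {
  purrr::map_dfr(selectors, function(sel) {
    if (startsWith(sel, "D")) {
      est <- liu_estimate(fit, select_d(fit, sel), selector = sel)
    } else {
      est <- ridge_estimate(fit, select_k(fit, sel), selector = sel)
    }
    tibble::tibble(selector = sel, family = est$family, param = est$param,
                   smse = est$smse, estimate = list(est))
  })
}
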