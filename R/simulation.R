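## Monte Carlo engine comparing the unshrunken IWLS estimator with the ridge
## (k2, k7, k12) and Liu (D1-D5) estimators by estimated scalar mean square
## error: SMSE_hat = mean over replicates of (beta_hat - beta)'(beta_hat - beta).

sim_estimators <- c("MLE", "RE(k2)", "RE(k7)", "RE(k12)",
                    "LE(D1)", "LE(D2)", "LE(D3)", "LE(D4)", "LE(D5)")

#' Correlated covariate design
#'
#' Generates `p` covariate columns with controlled pairwise correlation via
#' the shared-factor construction
#' \eqn{x_{ij} = (1-\rho^2)^{1/2} m_{ij} + \rho m_{i,p+1}} with independent
#' standard normal \eqn{m}'s; distinct covariates then have expected
#' correlation \eqn{\rho^2}.  An intercept column of ones is prepended.
#'
#' @param n Number of rows.
#' @param p Number of covariates.
#' @param rho Correlation parameter in `(0, 1)`.
#' @param seed Optional integer seed for reproducibility.
#' @return An `n` by `p + 1` design matrix, first column the intercept.
#' @examples
#' X <- sim_design_matrix(100, 2, 0.99, seed = 1)
#' cor(X[, 2], X[, 3])  # about 0.98
#' @export
sim_design_matrix <- function(n, p, rho, seed = NULL) {
  if (n < 2 || p < 1 || rho <= 0 || rho >= 1) {
    stop("need n >= 2, p >= 1 and 0 < rho < 1", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  m <- matrix(stats::rnorm(n * (p + 1L)), n, p + 1L)
  x <- sqrt(1 - rho^2) * m[, seq_len(p), drop = FALSE] + rho * m[, p + 1L]
  colnames(x) <- paste0("x", seq_len(p))
  cbind(`(Intercept)` = 1, x)
}

#' Simulation coefficient vector
#'
#' Intercept `beta0` followed by `p` equal slopes \eqn{1/\sqrt{p}}, so the
#' slope vector always has unit squared norm.
#'
#' @param p Number of covariates.
#' @param beta0 Intercept value.
#' @return Numeric vector of length `p + 1`.
#' @examples
#' sim_coefficients(4, 1)  # c(1, 0.5, 0.5, 0.5, 0.5)
#' @export
sim_coefficients <- function(p, beta0) {
  c(beta0, rep(1 / sqrt(p), p))
}

#' Simulate PMQL counts for a design
#'
#' Draws one response vector from the PMQL regression model with
#' \eqn{\mu_i = e^{x_i'\beta}} and dispersion `(alpha, delta)`.
#'
#' @param X Design matrix with intercept.
#' @param beta Coefficient vector.
#' @inheritParams dmql
#' @param seed Optional integer seed.
#' @param method Sampling route passed to [rpmql()].
#' @return Integer vector of counts of length `nrow(X)`.
#' @export
sim_responses <- function(X, beta, alpha, delta, seed = NULL,
                          method = "hierarchical") {
  if (!is.null(seed)) set.seed(seed)
  eta <- pmin(pmax(drop(X %*% beta), -30), 30)
  th <- theta_from_linpred(eta, alpha, delta)
  rpmql(nrow(X), th, alpha, delta, method = method)
}

#' Run one simulation cell
#'
#' Draws the design once (or per replicate if `redraw_X = TRUE`), then for
#' each replicate simulates a response vector, fits the model by IWLS, forms
#' all nine estimators (unshrunken; ridge at k2, k7, k12; Liu at D1-D5), and
#' accumulates squared estimation errors against the generating coefficients.
#' Replicates whose fit fails or does not converge are redrawn with a fresh
#' child seed up to `max_redraw` times, then dropped and counted.
#'
#' @param n Sample size.
#' @param p Number of covariates.
#' @param rho Correlation parameter of the design.
#' @param beta0 Intercept of the generating coefficients.
#' @inheritParams dmql
#' @param reps Number of Monte Carlo replicates.
#' @param seed Master seed of the cell; child seeds for every replicate and
#'   redraw attempt are derived from it deterministically.
#' @param redraw_X Draw a fresh design every replicate instead of holding it
#'   fixed (the default conditions on one design per cell).
#' @param estimators Subset of
#'   `c("MLE","RE(k2)","RE(k7)","RE(k12)","LE(D1)",...,"LE(D5)")`.
#' @param max_redraw Redraw attempts per replicate before dropping it.
#' @param force_d Optional fixed Liu parameter overriding every Liu selector
#'   (used for estimator-identity checks).
#' @return A tibble with one row per estimator: the cell factors,
#'   `estimator`, `smse` (the Monte Carlo mean squared estimation error),
#'   `mc_se` (its standard error), `n_ok`, and `n_failed`.
#' @examples
#' sim_cell(n = 50, p = 2, rho = 0.9, beta0 = 1, alpha = 0.25, delta = 0.04,
#'          reps = 20, seed = 1)
#' @export
sim_cell <- function(n, p, rho, beta0, alpha, delta, reps = 1000L,
                     seed = 1L, redraw_X = FALSE,
                     estimators = sim_estimators, max_redraw = 5L,
                     force_d = NULL) {
  estimators <- match.arg(estimators, sim_estimators, several.ok = TRUE)
  if (reps < 1L) stop("`reps` must be at least 1", call. = FALSE)
  set.seed(seed)
  X <- sim_design_matrix(n, p, rho)
  beta <- sim_coefficients(p, beta0)
  rep_seeds <- sample.int(.Machine$integer.max - 10L, reps)
  x_seeds <- if (redraw_X) sample.int(.Machine$integer.max - 10L, reps)
  sqerr <- matrix(NA_real_, reps, length(estimators),
                  dimnames = list(NULL, estimators))
  n_failed <- 0L
  for (r in seq_len(reps)) {
    if (redraw_X) X <- sim_design_matrix(n, p, rho, seed = x_seeds[r])
    fit <- NULL
    for (attempt in 0:(max_redraw - 1L)) {
      y <- sim_responses(X, beta, alpha, delta,
                         seed = rep_seeds[r] + attempt)
      if (all(y == 0)) next
      f <- tryCatch(pmql_fit_xy(X, y, alpha, delta), error = function(e) NULL)
      if (!is.null(f) && f$converged && all(is.finite(f$coefficients))) {
        fit <- f
        break
      }
    }
    if (is.null(fit)) {
      n_failed <- n_failed + 1L
      next
    }
    for (lab in estimators) {
      bh <- switch(lab,
        "MLE" = stats::coef(fit),
        "RE(k2)" = stats::coef(ridge_estimate(fit, select_k(fit, "k2"))),
        "RE(k7)" = stats::coef(ridge_estimate(fit, select_k(fit, "k7"))),
        "RE(k12)" = stats::coef(ridge_estimate(fit, select_k(fit, "k12"))),
        {
          sel <- sub("LE\\((D[1-5])\\)", "\\1", lab)
          dd <- if (is.null(force_d)) select_d(fit, sel) else force_d
          stats::coef(liu_estimate(fit, dd, selector = sel))
        }
      )
      sqerr[r, lab] <- sum((bh - beta)^2)
    }
  }
  n_ok <- colSums(!is.na(sqerr))
  if (all(n_ok == 0)) {
    stop("every replicate of the simulation cell failed", call. = FALSE)
  }
  tibble::tibble(
    rho = rho, n = n, p = p, beta0 = beta0, alpha = alpha, delta = delta,
    reps = reps, estimator = estimators,
    smse = colMeans(sqerr, na.rm = TRUE),
    mc_se = apply(sqerr, 2, function(v) {
      stats::sd(v, na.rm = TRUE) / sqrt(sum(!is.na(v)))
    }),
    n_ok = n_ok,
    n_failed = n_failed
  )
}

#' Run a factorial simulation design
#'
#' Evaluates [sim_cell()] on every combination of the supplied factor
#' levels.  Cell failures are reported, not fatal.
#'
#' @param rho,n,p,beta0,alpha,delta Vectors of factor levels; the full cross
#'   product is run.
#' @inheritParams sim_cell
#' @return Long tibble of per-cell, per-estimator results.
#' @export
sim_factorial <- function(rho, n, p, beta0, alpha, delta,
                          reps = 1000L, seed = 1L, redraw_X = FALSE,
                          estimators = sim_estimators) {
  grid <- tidyr::expand_grid(rho = rho, n = n, p = p, beta0 = beta0,
                             alpha = alpha, delta = delta)
  set.seed(seed)
  grid$cell_seed <- sample.int(.Machine$integer.max - 10L, nrow(grid))
  purrr::pmap_dfr(grid, function(rho, n, p, beta0, alpha, delta, cell_seed) {
    tryCatch(
      sim_cell(n = n, p = p, rho = rho, beta0 = beta0, alpha = alpha,
               delta = delta, reps = reps, seed = cell_seed,
               redraw_X = redraw_X, estimators = estimators),
      error = function(e) {
        warning("cell (rho=", rho, ", n=", n, ", p=", p, ", beta0=", beta0,
                ") failed: ", conditionMessage(e), call. = FALSE)
        tibble::tibble()
      }
    )
  })
}

#' Wide table of simulation results
#'
#' Reshapes [sim_factorial()] output into the conventional layout: one row
#' per estimator, one column per sample size, blocks by intercept and
#' correlation.  The minimum of every column within a block is marked with
#' an asterisk in the formatted text rendering.
#'
#' @param results Long tibble from [sim_factorial()] or [sim_cell()].
#' @param digits Digits for the formatted values.
#' @return A tibble in wide format with character cells; column minima are
#'   suffixed with `*`.
#' @export
sim_table <- function(results, digits = 3) {
  fmt <- results |>
    dplyr::group_by(.data$rho, .data$beta0, .data$n, .data$p, .data$alpha,
                    .data$delta) |>
    dplyr::mutate(
      label = ifelse(.data$smse == min(.data$smse),
                     paste0(formatC(.data$smse, digits = digits,
                                    format = "f"), "*"),
                     formatC(.data$smse, digits = digits, format = "f"))
    ) |>
    dplyr::ungroup()
  fmt |>
    dplyr::mutate(estimator = factor(.data$estimator,
                                     levels = sim_estimators)) |>
    dplyr::arrange(.data$p, .data$alpha, .data$delta, .data$rho,
                   .data$beta0, .data$estimator) |>
    dplyr::select(dplyr::all_of(c("p", "alpha", "delta", "rho", "beta0",
                                  "estimator", "n", "label"))) |>
    tidyr::pivot_wider(names_from = "n", values_from = "label",
                       names_prefix = "n=")
}

#' Reproducible example data sets
#'
#' Generates small data sets from the PMQL regression model for examples,
#' fixtures, and hand-checking:
#' * `"multicollinear-overdispersed"`: n = 400, p = 4, rho = 0.9999,
#'   alpha = 0.25, delta = 0.04 — a severely ill-conditioned, strongly
#'   overdispersed design (condition number of the weighted cross-product
#'   far above 1000).
#' * `"well-conditioned"`: n = 200, p = 2, rho = 0.3, same dispersion.
#' * `"tiny-worked-example"`: n = 6, p = 1, small enough to verify by hand.
#'
#' @param kind One of the three kinds above.
#' @param seed Integer seed; the same seed always yields the same data.
#' @param path Optional file path; when given the tibble is also written as
#'   CSV.
#' @return A tibble with a count column `y` and covariates `x1`, ...; the
#'   generating coefficients and dispersion are attached as attributes
#'   `beta`, `alpha`, `delta`.
#' @export
sim_fixture <- function(kind = c("multicollinear-overdispersed",
                                 "well-conditioned",
                                 "tiny-worked-example"),
                        seed = 1L, path = NULL) {
  kind <- match.arg(kind)
  cfg <- switch(kind,
    "multicollinear-overdispersed" =
      list(n = 400L, p = 4L, rho = 0.9999, beta0 = 1, alpha = 0.25,
           delta = 0.04),
    "well-conditioned" =
      list(n = 200L, p = 2L, rho = 0.3, beta0 = 1, alpha = 0.25,
           delta = 0.04),
    "tiny-worked-example" =
      list(n = 6L, p = 1L, rho = 0.3, beta0 = 0.5, alpha = 1, delta = 1)
  )
  set.seed(seed)
  X <- sim_design_matrix(cfg$n, cfg$p, cfg$rho)
  beta <- sim_coefficients(cfg$p, cfg$beta0)
  y <- sim_responses(X, beta, cfg$alpha, cfg$delta)
  out <- tibble::as_tibble(as.data.frame(X[, -1, drop = FALSE]))
  out <- dplyr::bind_cols(tibble::tibble(y = y), out)
  attr(out, "beta") <- beta
  attr(out, "alpha") <- cfg$alpha
  attr(out, "delta") <- cfg$delta
  if (!is.null(path)) readr::write_csv(out, path)
  out
}
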