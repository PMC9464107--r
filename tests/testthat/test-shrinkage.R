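test_that("shrinkage boundaries reproduce the unshrunken fit exactly", {
  set.seed(14)
  fit <- rand_fit(4)
  liu1 <- liu_estimate(fit, 1)
  expect_equal(coef(liu1), coef(fit), tolerance = 1e-12)
  expect_equal(liu1$bias, rep(0, 4), tolerance = 1e-12)
  expect_equal(liu1$mse_matrix, fit$cov, tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_equal(liu1$smse, sum(1 / fit$eigenvalues), tolerance = 1e-10)
  ridge0 <- ridge_estimate(fit, 0)
  expect_equal(coef(ridge0), coef(fit), tolerance = 1e-12)
  expect_equal(ridge0$bias, rep(0, 4), tolerance = 1e-12)
  expect_equal(ridge0$mse_matrix, fit$cov, tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_error(liu_estimate(fit, 1.2), "\\[0, 1\\]")
  expect_error(ridge_estimate(fit, -0.1), "non-negative")
})

test_that("diagonal systems shrink coordinate-wise as the algebra says", {
  fit <- make_synthetic_fit(c(4, 1), c(1, 1), Gamma = diag(2))
  expect_equal(unname(coef(liu_estimate(fit, 0))), c(4 / 5, 1 / 2))
  expect_equal(unname(coef(ridge_estimate(fit, 1))), c(4 / 5, 1 / 2))
})

test_that("spectral SMSE equals the trace of the assembled MSE matrix", {
  set.seed(20)
  for (i in 1:100) {
    fit <- rand_fit(sample(3:6, 1))
    d <- runif(1)
    liu <- liu_estimate(fit, d)
    expect_equal(liu$smse,
                 pmqlreg:::smse_liu_spectral(fit, d),
                 tolerance = 1e-9)
    k <- runif(1, 0, 5)
    ridge <- ridge_estimate(fit, k)
    expect_equal(ridge$smse,
                 pmqlreg:::smse_ridge_spectral(fit, k),
                 tolerance = 1e-9)
  }
})

test_that("selectors reproduce hand arithmetic on a fixed spectrum", {
  acan <- c(0.5, 1.5, 2.0)
  lam <- c(10, 2, 0.5)
  fit <- make_synthetic_fit(lam, acan, Gamma = diag(3))  # alpha_canon = acan
  g <- (acan^2 - 1) / (1 / lam + acan^2)
  expect_equal(select_d(fit, "D1"),
               min(1, max(0, (max(acan^2) - 1) / (1 / max(lam) + max(acan^2)))))
  expect_equal(select_d(fit, "D2"), min(1, max(0, median(g))))
  expect_equal(select_d(fit, "D3"), min(1, max(0, mean(g))))
  expect_equal(select_d(fit, "D4"), min(1, max(0, max(g))))
  expect_equal(select_d(fit, "D5"), min(1, max(0, min(g))))
  expect_equal(select_k(fit, "k2"),
               3 / sum(acan^2 / (1 + sqrt(1 + lam * acan^2))))
  expect_equal(select_k(fit, "k7"), 4)
  expect_equal(select_k(fit, "k12"), median(1 / acan^2))
  # k7/k12 trivial aggregations under the declared parse
  fit2 <- make_synthetic_fit(c(3, 1), c(0.5, 2), Gamma = diag(2))
  expect_equal(select_k(fit2, "k7"), 4)
  fit3 <- make_synthetic_fit(c(3, 2, 1), c(0.5, 1, 2), Gamma = diag(3))
  expect_equal(select_k(fit3, "k12"), 1)
  # symmetric k2 case: all canonical squares 1, all eigenvalues 3
  fit4 <- make_synthetic_fit(c(3, 3, 3), c(1, -1, 1), Gamma = diag(3))
  expect_equal(select_k(fit4, "k2"), 3)
})

test_that("selector containment and ordering hold on random fits", {
  set.seed(33)
  for (i in 1:50) {
    fit <- rand_fit(sample(3:6, 1), beta_scale = runif(1, 0.2, 3))
    ds <- vapply(paste0("D", 1:5), function(m) select_d(fit, m), numeric(1))
    ks <- vapply(c("k2", "k7", "k12"), function(m) select_k(fit, m),
                 numeric(1))
    expect_true(all(ds >= 0 & ds <= 1))
    expect_true(all(ks >= 0))
    g <- optimal_d_components(fit)
    expect_true(min(g) <= median(g) && median(g) <= max(g))
    expect_true(min(g) <= mean(g) && mean(g) <= max(g))
    expect_true(all(g < 1))
    expect_equal(g < 0, fit$alpha_canon^2 < 1)
  }
})

test_that("coordinate-wise optimal d zeroes the spectral SMSE derivative", {
  set.seed(40)
  fit <- rand_fit(4, beta_scale = 2)
  dj <- optimal_d_components(fit)
  lam <- fit$eigenvalues
  ac2 <- fit$alpha_canon^2
  for (j in 1:4) {
    f_j <- function(d) {
      (lam[j] + d)^2 / (lam[j] * (lam[j] + 1)^2) +
        (d - 1)^2 * ac2[j] / (lam[j] + 1)^2
    }
    h <- 1e-6
    deriv <- (f_j(dj[j] + h) - f_j(dj[j] - h)) / (2 * h)
    expect_lt(abs(deriv), 1e-6)
  }
})

test_that("variance and bias terms are monotone with the stated boundary
           slopes", {
  set.seed(41)
  fit <- rand_fit(5, beta_scale = 1.5)
  grid <- seq(0.01, 0.99, by = 0.01)
  terms <- smse_curve_terms(fit, grid)
  expect_true(all(diff(terms$term_variance) > 0))
  expect_true(all(diff(terms$term_bias2) < 0))
  expect_equal(smse_curve_terms(fit, 1)$term_bias2, 0)
  lam <- fit$eigenvalues
  h <- 1e-7
  # variance-term slope at 0+ is 2 * sum 1/(lam+1)^2
  tv_slope0 <- (smse_curve_terms(fit, h)$term_variance -
                  smse_curve_terms(fit, 0)$term_variance) / h
  expect_equal(tv_slope0, 2 * sum(1 / (lam + 1)^2), tolerance = 1e-5)
  # variance-term slope at 1- is 2 * sum 1/(lam(lam+1))
  tv_slope1 <- (smse_curve_terms(fit, 1)$term_variance -
                  smse_curve_terms(fit, 1 - h)$term_variance) / h
  expect_equal(tv_slope1, 2 * sum(1 / (lam * (lam + 1))), tolerance = 1e-5)
})

test_that("SMSE difference vanishes at d = 1 and is positive on the stated
           window", {
  set.seed(50)
  for (i in 1:20) {
    fit <- rand_fit(4, beta_scale = runif(1, 0.3, 2))
    expect_equal(smse_difference(fit, 1), 0, tolerance = 1e-12)
    d <- runif(1)
    expect_equal(smse_difference(fit, d),
                 sum(1 / fit$eigenvalues) -
                   pmqlreg:::smse_liu_spectral(fit, d),
                 tolerance = 1e-10)
    # monotone increase of the SMSE on (d_lower, 1): difference positive there
    ac2max <- max(fit$alpha_canon^2)
    d_lower <- (ac2max - 1) / (1 / max(fit$eigenvalues) + ac2max)
    dd <- seq(max(0, d_lower) + 1e-6, 1, length.out = 25)
    smse_path <- vapply(dd, function(d) pmqlreg:::smse_liu_spectral(fit, d),
                        numeric(1))
    expect_true(all(diff(smse_path) > -1e-12))
    expect_true(all(vapply(dd, function(d) smse_difference(fit, d),
                           numeric(1)) >= -1e-12))
  }
})

test_that("superiority verdicts agree with brute-force eigen checks", {
  set.seed(60)
  n_checked <- 0
  for (i in 1:100) {
    fit <- rand_fit(4, lambda_min = 1, lambda_max = 40,
                    beta_scale = runif(1, 0.1, 4))
    d <- runif(1, 0, 0.99)
    chk <- theorem1_check(fit, d)
    if (!chk$condition_a) next
    n_checked <- n_checked + 1
    liu <- liu_estimate(fit, d)
    min_eig <- mse_diff_min_eigen(fit$cov, liu$mse_matrix)
    expect_equal(chk$verdict == "superior", min_eig > 0)
    if (chk$verdict == "superior") expect_gt(min_eig, 0)
  }
  expect_gt(n_checked, 50)
})

test_that("ridge-vs-Liu verdicts agree with brute-force eigen checks", {
  set.seed(61)
  n_checked <- 0
  for (i in 1:100) {
    fit <- rand_fit(4, lambda_min = 1.5, lambda_max = 40,
                    beta_scale = runif(1, 0.1, 3))
    d <- runif(1, 0, 0.9)
    k <- runif(1, 0, 0.5)
    chk <- theorem2_check(fit, d, k)
    if (!chk$condition_a) next
    n_checked <- n_checked + 1
    liu <- liu_estimate(fit, d)
    ridge <- ridge_estimate(fit, k)
    min_eig <- mse_diff_min_eigen(ridge$mse_matrix, liu$mse_matrix)
    expect_equal(chk$verdict == "superior", min_eig > 0)
  }
  expect_gt(n_checked, 50)
})

test_that("superiority boundary and adversarial cases behave as stated", {
  set.seed(62)
  fit <- rand_fit(3, lambda_min = 1.5, lambda_max = 20, beta_scale = 0.1)
  expect_equal(theorem1_check(fit, 1)$verdict, "boundary")
  expect_equal(theorem2_check(fit, 1, 0)$verdict, "boundary")
  # k = 0 reduces the ridge to the unshrunken estimator: same quadratic form
  d <- 0.4
  expect_equal(theorem2_check(fit, d, 0)$quadratic_form,
               theorem1_check(fit, d)$quadratic_form, tolerance = 1e-8)
  # small beta: Liu dominates; huge beta: it cannot
  small <- theorem1_check(fit, 0.3)
  expect_equal(small$verdict, "superior")
  big <- make_synthetic_fit(fit$eigenvalues, c(40, -35, 30),
                            Gamma = fit$eigenvectors)
  chk_big <- theorem1_check(big, 0.3)
  expect_equal(chk_big$verdict, "not-superior")
  expect_gte(chk_big$quadratic_form, 1)
  liu_big <- liu_estimate(big, 0.3)
  expect_lt(mse_diff_min_eigen(big$cov, liu_big$mse_matrix), 0)
})

test_that("pmql_shrink covers all selectors with canonical consistency", {
  d <- sim_fixture("well-conditioned", seed = 10)
  fit <- pmql_fit(d, y ~ ., alpha = 0.25, delta = 0.04)
  tab <- pmql_shrink(fit)
  expect_equal(nrow(tab), 8)
  expect_equal(sum(tab$family == "liu"), 5)
  expect_equal(sum(tab$family == "ridge"), 3)
  expect_equal(fit$alpha_canon, drop(crossprod(fit$eigenvectors, coef(fit))))
  # manual d = 1 row equals the fit's coefficients
  expect_equal(coef(liu_estimate(fit, 1)), coef(fit))
})
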