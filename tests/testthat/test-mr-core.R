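test_that("Wald ratio arithmetic, null case, and delta-method SE", {
  h <- make_hset(b_x = 0.5, se_x = 0.01, b_y = 0.1, se_y = 0.02)
  est <- wald_ratio(h)
  expect_equal(est$theta, 0.2)
  expect_equal(est$se, 0.04)
  expect_equal(est$ci_low, 0.2 - qnorm(0.975) * 0.04)

  h0 <- make_hset(b_x = 0.5, se_x = 0.01, b_y = 0, se_y = 0.02)
  est0 <- wald_ratio(h0)
  expect_equal(est0$theta, 0)
  expect_equal(est0$p, 1)

  hz <- make_hset(b_x = 0, se_x = 0.01, b_y = 0.1, se_y = 0.02)
  expect_error(wald_ratio(hz), class = "targetmr_input_error")
  expect_error(wald_ratio(make_hset(c(0.1, 0.2), 0.01, c(0, 0), 0.01)),
               class = "targetmr_input_error")

  # Monte-Carlo: empirical SD of the ratio within 5% of the first-order se
  set.seed(42)
  reps <- 1e5
  bx <- rnorm(reps, 0.5, 0.01)
  by <- rnorm(reps, 0.1, 0.02)
  expect_equal(sd(by / bx), 0.02 / 0.5, tolerance = 0.05)
})

test_that("correlated IVW: equal-weight mean, uncorrelated reduction, GLS oracle", {
  h <- make_hset(b_x = c(1, 1), se_x = 0.01, b_y = c(0.2, 0.4), se_y = 0.1)
  est <- ivw_correlated(h)
  expect_equal(est$theta, 0.3)
  expect_equal(est$se, 0.1 / sqrt(2))
  expect_identical(est$method, "ivw_fixed")
  expect_equal(est$phi, 1)

  # identity LD reduces to the classic uncorrelated IVW formula
  set.seed(9)
  bx <- rnorm(6, 0.2, 0.1); by <- rnorm(6, 0.02, 0.01); sey <- runif(6, 0.005, 0.02)
  h2 <- make_hset(bx, 0.01, by, sey)
  est2 <- ivw_correlated(h2, random = FALSE)
  expect_equal(est2$theta, sum(bx * by / sey^2) / sum(bx^2 / sey^2), tolerance = 1e-12)
  expect_equal(est2$se, sqrt(1 / sum(bx^2 / sey^2)), tolerance = 1e-12)

  # GLS oracle: explicit matrix inversion on AR(1) and random correlated instances
  for (seed in 1:20) {
    set.seed(seed)
    m <- sample(5:20, 1)
    rho <- if (seed %% 2 == 0) 0.7^abs(outer(1:m, 1:m, "-")) else rand_corr(m)
    sey <- runif(m, 0.005, 0.02)
    h3 <- make_hset(rnorm(m, 0.1, 0.05), 0.01, rnorm(m, 0.01, 0.01), sey, rho = rho)
    est3 <- ivw_correlated(h3)
    omega <- rho * tcrossprod(sey)
    oi <- solve(omega)
    bx <- h3$variants$b_x; by <- h3$variants$b_y
    theta_o <- drop(crossprod(bx, oi %*% by) / crossprod(bx, oi %*% bx))
    se_o <- sqrt(drop(1 / crossprod(bx, oi %*% bx)))
    if (m > 3) {
      r <- by - theta_o * bx
      se_o <- se_o * max(1, sqrt(drop(crossprod(r, oi %*% r)) / (m - 1)))
    }
    expect_equal(est3$theta, theta_o, tolerance = 1e-8)
    expect_equal(est3$se, se_o, tolerance = 1e-8)
    expect_identical(est3$method, if (m > 3) "ivw_random" else "ivw_fixed")
  }

  expect_error(ivw_correlated(make_hset(0.1, 0.01, 0, 0.01)),
               class = "targetmr_input_error")
})

test_that("near-singular LD is stabilized by shrinkage toward the identity", {
  # exact duplicates: the identity-shrinkage escalation makes Omega usable,
  # and the estimate approaches the single-variant Wald ratio
  rho <- matrix(c(1, 1, 1, 1), 2, 2)
  h <- make_hset(b_x = c(0.2, 0.2), se_x = 0.01, b_y = c(0.05, 0.05),
                 se_y = 0.01, rho = rho)
  est <- ivw_correlated(h)
  expect_true(is.finite(est$theta) && est$se > 0)
  expect_equal(est$theta, 0.25, tolerance = 1e-6)
  rho2 <- matrix(c(1, 1 - 1e-7, 1 - 1e-7, 1), 2, 2)
  h2 <- make_hset(b_x = c(0.2, 0.2), se_x = 0.01, b_y = c(0.05, 0.05),
                  se_y = 0.01, rho = rho2)
  est2 <- ivw_correlated(h2)
  expect_true(is.finite(est2$theta) && est2$se > 0)
})

test_that("MR-Egger recovers exact and affine relations and matches the whitening oracle", {
  h <- make_hset(b_x = c(0.1, 0.2, 0.3, 0.4), se_x = 0.01,
                 b_y = 0.5 * c(0.1, 0.2, 0.3, 0.4), se_y = 0.01)
  est <- egger_correlated(h)
  expect_equal(est$theta, 0.5, tolerance = 1e-10)
  expect_equal(est$intercept, 0, tolerance = 1e-10)

  h2 <- make_hset(b_x = c(0.1, 0.2, 0.3, 0.4), se_x = 0.01,
                  b_y = 0.05 + 0.2 * c(0.1, 0.2, 0.3, 0.4), se_y = 0.01)
  est2 <- egger_correlated(h2)
  expect_equal(est2$theta, 0.2, tolerance = 1e-10)
  expect_equal(est2$intercept, 0.05, tolerance = 1e-10)

  # whitening oracle on random correlated instances (Cholesky of Omega under
  # the oriented allele coding), with the estimated residual scale
  for (seed in 21:35) {
    set.seed(seed)
    m <- sample(5:15, 1)
    rho <- rand_corr(m)
    sey <- runif(m, 0.005, 0.02)
    bx <- rnorm(m, 0.05, 0.1)
    by <- 0.02 + 0.3 * bx + rnorm(m, 0, 0.01)
    h3 <- make_hset(bx, 0.01, by, sey, rho = rho)
    est3 <- egger_correlated(h3)
    f <- ifelse(bx >= 0, 1, -1)
    omega <- (rho * tcrossprod(f)) * tcrossprod(sey)
    L <- t(chol(omega))
    Xw <- solve(L, cbind(1, bx * f))
    yw <- solve(L, by * f)
    fit <- lm(yw ~ Xw - 1)
    beta_o <- unname(coef(fit))
    scale_o <- sqrt(sum(residuals(fit)^2) / (m - 2))
    se_o <- sqrt(diag(solve(crossprod(Xw)))) * scale_o
    expect_equal(est3$intercept, beta_o[1], tolerance = 1e-8)
    expect_equal(est3$theta, beta_o[2], tolerance = 1e-8)
    expect_equal(est3$intercept_se, se_o[1], tolerance = 1e-8)
    expect_equal(est3$se, se_o[2], tolerance = 1e-8)
    expect_equal(est3$p, 2 * pt(-abs(beta_o[2] / se_o[2]), m - 2), tolerance = 1e-8)
  }

  expect_error(egger_correlated(make_hset(c(0.1, 0.2), 0.01, c(0, 0), 0.01)),
               class = "targetmr_input_error")
  expect_error(egger_correlated(make_hset(c(0.1, 0.1, -0.1), 0.01, c(0, 0, 0), 0.01)),
               class = "targetmr_input_error")
})

test_that("PCA-IVW: full-rank equivalence, duplicate-collapse limit, default target", {
  expect_equal(formals(pca_ivw)$variance_target, 0.99)
  set.seed(13)
  m <- 8
  rho <- rand_corr(m)
  h <- make_hset(rnorm(m, 0.1, 0.05), 0.01, rnorm(m, 0.02, 0.01),
                 runif(m, 0.005, 0.02), rho = rho)
  full <- pca_ivw(h, variance_target = 1)
  fixed <- ivw_correlated(h, random = FALSE)
  expect_equal(full$k_components, m)
  expect_equal(full$theta, fixed$theta, tolerance = 1e-10)
  expect_equal(full$se, fixed$se, tolerance = 1e-10)

  # two near-duplicate variants collapse to one component ~ the Wald ratio
  rho2 <- matrix(c(1, 0.999, 0.999, 1), 2, 2)
  hd <- make_hset(b_x = c(0.3, 0.3), se_x = 0.01, b_y = c(0.06, 0.06),
                  se_y = c(0.01, 0.01), rho = rho2)
  est <- pca_ivw(hd)
  expect_equal(est$k_components, 1L)
  wald <- wald_ratio(hset_subset(hd, "rs001"))
  expect_equal(est$theta, wald$theta, tolerance = 1e-3)
})

test_that("Steiger filtering removes only variants explaining more outcome variance", {
  # |t_x| = 10 at n_x = 20,000 vs |t_y| = 3 at n_y = 400,000 -> retained
  h <- make_hset(b_x = 10 * 0.007, se_x = 0.007, b_y = 3 * 0.0016, se_y = 0.0016,
                 n_x = 20000, n_y = 400000)
  r2x <- 100 / (100 + 20000 - 2)
  r2y <- 9 / (9 + 400000 - 2)
  expect_equal(r2x, 4.98e-3, tolerance = 1e-3)
  expect_equal(r2y, 2.25e-5, tolerance = 1e-3)
  out <- steiger_filter(h)
  expect_identical(out$removed, character(0))

  # exact tie is retained (strict inequality rule)
  ht <- make_hset(b_x = 5 * 0.01, se_x = 0.01, b_y = 5 * 0.002, se_y = 0.002,
                  n_x = 10000, n_y = 10000)
  expect_identical(steiger_filter(ht)$removed, character(0))

  # a reverse-causal variant is removed and downstream IVW still runs
  h3 <- make_hset(b_x = c(0.15, 0.14, 0.001), se_x = 0.007,
                  b_y = c(0.01, 0.012, 0.02), se_y = 0.002,
                  n_x = 20000, n_y = 300000)
  out3 <- steiger_filter(h3)
  expect_identical(out3$removed, "rs003")
  est <- ivw_correlated(out3$retained)
  expect_true(is.finite(est$theta) && est$se > 0)

  expect_error(steiger_filter(make_hset(0.1, 0.01, 0, 0.01, n_x = 2)),
               class = "targetmr_input_error")
})

test_that("estimators are scale- and sign-equivariant; random-effects SE >= fixed", {
  set.seed(31)
  m <- 10
  rho <- rand_corr(m)
  bx <- rnorm(m, 0.1, 0.05); by <- rnorm(m, 0.02, 0.02)
  sey <- runif(m, 0.005, 0.02)
  h <- make_hset(bx, 0.01, by, sey, rho = rho)
  for (fit in list(function(x) ivw_correlated(x),
                   function(x) egger_correlated(x),
                   function(x) pca_ivw(x))) {
    base <- fit(h)
    scaled <- fit(make_hset(bx, 0.01, 3 * by, 3 * sey, rho = rho))
    expect_equal(scaled$theta, 3 * base$theta, tolerance = 1e-9)
    expect_equal(scaled$se, 3 * base$se, tolerance = 1e-9)
    neg <- fit(make_hset(bx, 0.01, -by, sey, rho = rho))
    expect_equal(neg$theta, -base$theta, tolerance = 1e-9)
  }
  # jointly negating one variant's (b_x, b_y) and recoding its LD row/column
  # leaves the IVW estimate unchanged
  flip <- c(-1, rep(1, m - 1))
  h_flip <- make_hset(bx * flip, 0.01, by * flip, sey,
                      rho = rho * tcrossprod(flip))
  expect_equal(ivw_correlated(h_flip)$theta, ivw_correlated(h)$theta,
               tolerance = 1e-9)

  fx <- ivw_correlated(h, random = FALSE)
  rd <- ivw_correlated(h, random = TRUE)
  expect_gte(rd$se, fx$se)
  expect_gte(rd$phi, 1)
})
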