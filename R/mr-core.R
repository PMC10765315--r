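#' @noRd
new_mr_estimate <- function(method, theta, se, p, n_variants, phi = 1,
                            ci = NULL, intercept = NA_real_,
                            intercept_se = NA_real_, intercept_p = NA_real_,
                            k_components = NA_integer_) {
  if (is.null(ci)) ci <- theta + c(-1, 1) * qnorm(0.975) * se
  p <- max(p, .Machine$double.xmin)  # keep p in (0, 1] under extreme z
  structure(
    list(method = method, theta = theta, se = se,
         ci_low = ci[1], ci_high = ci[2], p = p,
         n_variants = n_variants, phi = phi,
         intercept = intercept, intercept_se = intercept_se,
         intercept_p = intercept_p, k_components = k_components),
    class = "mr_estimate"
  )
}

#' @export
print.mr_estimate <- function(x, ...) {
  cat(sprintf("<mr_estimate: %s> theta = %.4f (95%% CI %.4f to %.4f), p = %.3g, %d variant(s)\n",
              x$method, x$theta, x$ci_low, x$ci_high, x$p, x$n_variants))
  if (!is.na(x$intercept)) {
    cat(sprintf("  pleiotropy intercept = %.4f (se %.4f, p = %.3g)\n",
                x$intercept, x$intercept_se, x$intercept_p))
  }
  invisible(x)
}

#' Tidy an MR estimate
#'
#' One row per estimate: method, causal effect per SD of genetically
#' predicted exposure (log-odds scale for a binary outcome), standard error,
#' 95% interval, p-value, and the odds-ratio transform `exp(theta)` with its
#' interval for binary outcomes.
#'
#' @param x An `mr_estimate`.
#' @param ... Unused.
#' @return A one-row tibble.
#' @export
tidy.mr_estimate <- function(x, ...) {
  tibble(
    method = x$method, theta = x$theta, se = x$se,
    ci_low = x$ci_low, ci_high = x$ci_high, p = x$p,
    or = exp(x$theta), or_ci_low = exp(x$ci_low), or_ci_high = exp(x$ci_high),
    n_variants = x$n_variants, phi = x$phi,
    intercept = x$intercept, intercept_se = x$intercept_se,
    intercept_p = x$intercept_p, k_components = x$k_components
  )
}

#' @export
glance.mr_estimate <- function(x, ...) {
  tibble(method = x$method, n_variants = x$n_variants, phi = x$phi,
         p = x$p)
}

#' Wald ratio estimate from a single variant
#'
#' `theta = b_y / b_x` with first-order (delta-method) standard error
#' `se_y / |b_x|`, normal confidence interval and p-value.
#'
#' @param hset An `mr_harmonized` object with exactly one variant.
#' @return An `mr_estimate` with method `"wald"`.
#' @export
wald_ratio <- function(hset) {
  if (n_variants(hset) != 1) {
    abort("wald_ratio requires exactly one variant", class = "targetmr_input_error")
  }
  v <- hset$variants
  if (v$b_x == 0) {
    abort("undefined Wald ratio: exposure effect is zero",
          class = "targetmr_input_error")
  }
  theta <- v$b_y / v$b_x
  se <- v$se_y / abs(v$b_x)
  p <- 2 * pnorm(-abs(theta / se))
  new_mr_estimate("wald", theta, se, p, 1L)
}

# Omega = D rho D with D = diag(se_y); returns a solver after conditioning.
# If cond(rho) > 1e8, rho is shrunk toward the identity as (1-l) rho + l I
# with l = 1e-6, escalating once to 1e-3 before erroring: GLS with
# correlated instruments is fragile as r^2 -> 1.
.omega_chol <- function(hset) {
  rho <- hset$rho
  se_y <- hset$variants$se_y
  for (lambda in c(0, 1e-6, 1e-3)) {
    r <- (1 - lambda) * rho + lambda * diag(nrow(rho))
    if (kappa(r, exact = TRUE) <= 1e8) {
      omega <- r * tcrossprod(se_y)
      return(chol(omega))
    }
  }
  abort("variant correlation matrix is numerically singular; re-clump at a stricter r2 threshold",
        class = "targetmr_conditioning_error")
}

# GLS building blocks on the whitened system: L' solve applied to vectors.
.whiten <- function(U, x) backsolve(U, x, transpose = TRUE)

#' Correlation-adjusted inverse-variance-weighted estimate
#'
#' Generalized-least-squares IVW with the LD-induced covariance
#' `Omega_ij = se_y_i se_y_j rho_ij`:
#' `theta = (b_x' Omega^-1 b_x)^-1 b_x' Omega^-1 b_y`. With more than three
#' variants (or `random = TRUE`) the standard error is inflated by the
#' multiplicative residual scale `phi = sqrt(resid' Omega^-1 resid / (J-1))`,
#' floored at 1; with 2-3 variants fixed effects are used. With an identity
#' correlation this reduces to the classic uncorrelated IVW formula.
#'
#' @param hset An `mr_harmonized` object with at least two variants.
#' @param random `NULL` (default) applies the ">3 variants" rule; `TRUE` or
#'   `FALSE` forces multiplicative random or fixed effects.
#' @return An `mr_estimate` with method `"ivw_fixed"` or `"ivw_random"`.
#' @export
ivw_correlated <- function(hset, random = NULL) {
  J <- n_variants(hset)
  if (J < 2) {
    abort("ivw_correlated requires at least two variants (use wald_ratio for one)",
          class = "targetmr_input_error")
  }
  if (is.null(random)) random <- J > 3
  U <- .omega_chol(hset)
  bx <- .whiten(U, hset$variants$b_x)
  by <- .whiten(U, hset$variants$b_y)
  xtx <- sum(bx^2)
  theta <- sum(bx * by) / xtx
  se <- sqrt(1 / xtx)
  phi <- 1
  if (random) {
    resid <- by - theta * bx
    phi <- sqrt(sum(resid^2) / (J - 1))
    se <- se * max(1, phi)
  }
  p <- 2 * pnorm(-abs(theta / se))
  new_mr_estimate(if (random) "ivw_random" else "ivw_fixed",
                  theta, se, p, J, phi = max(1, phi))
}

#' Correlation-adjusted MR-Egger regression
#'
#' Orients each variant so the exposure effect is non-negative (negating
#' `b_x` and `b_y` jointly, i.e. recoding the variant's effect allele, which
#' also flips that variant's row and column signs in the LD matrix), then
#' regresses `b_y` on `[1, b_x]` by generalized least squares with the
#' LD-induced covariance of [ivw_correlated()] under the oriented coding.
#' The slope is the causal estimate; the intercept absorbs directional
#' horizontal pleiotropy. Standard errors carry the estimated residual scale
#' (`J - 2` degrees of freedom, no floor) and inference uses the t
#' distribution with `J - 2` df: with an estimated scale the t statistic is
#' exactly t-distributed, so the intercept test keeps its nominal size.
#'
#' @param hset An `mr_harmonized` object with at least three variants.
#' @return An `mr_estimate` with method `"egger"` carrying the intercept
#'   fields.
#' @export
egger_correlated <- function(hset) {
  J <- n_variants(hset)
  if (J < 3) {
    abort("egger_correlated requires at least three variants",
          class = "targetmr_input_error")
  }
  flip <- sign(hset$variants$b_x)
  flip[flip == 0] <- 1
  bx_o <- hset$variants$b_x * flip
  by_o <- hset$variants$b_y * flip
  if (max(bx_o) - min(bx_o) < .Machine$double.eps^0.5 * max(abs(bx_o), 1)) {
    abort("all oriented exposure effects are equal; Egger design is collinear",
          class = "targetmr_input_error")
  }
  oriented <- hset
  oriented$rho <- hset$rho * tcrossprod(flip)
  U <- .omega_chol(oriented)
  X <- .whiten(U, cbind(intercept = 1, slope = bx_o))
  y <- .whiten(U, by_o)
  fit <- lm.fit(X, y)
  beta <- fit$coefficients
  xtx_inv <- chol2inv(chol(crossprod(X)))
  phi <- sqrt(sum(fit$residuals^2) / (J - 2))
  scale <- max(phi, 1e-12)   # guard against exactly collinear toy inputs
  ses <- sqrt(diag(xtx_inv)) * scale
  tq <- qt(0.975, df = J - 2)
  pvals <- 2 * pt(-abs(beta / ses), df = J - 2)
  new_mr_estimate(
    "egger", theta = unname(beta[2]), se = unname(ses[2]),
    p = unname(pvals[2]), n_variants = J, phi = phi,
    ci = unname(beta[2] + c(-1, 1) * tq * ses[2]),
    intercept = unname(beta[1]), intercept_se = unname(ses[1]),
    intercept_p = unname(pvals[1])
  )
}

#' Principal-components IVW
#'
#' Projects the variant-level system onto the leading eigenvectors of
#' `Phi_ij = b_x_i b_x_j rho_ij / (se_y_i se_y_j)` and runs fixed-effect
#' GLS-IVW in the projected space. The number of components `k` is the
#' smallest number whose eigenvalues account for at least `variance_target`
#' of the total (default 99% of the genetic variance), which stabilizes the
#' estimate when variants are strongly correlated.
#'
#' @param hset An `mr_harmonized` object with at least two variants.
#' @param variance_target Fraction of variance the retained components must
#'   explain (default 0.99).
#' @return An `mr_estimate` with method `"pca_ivw"` and `k_components` set.
#' @export
pca_ivw <- function(hset, variance_target = 0.99) {
  J <- n_variants(hset)
  if (J < 2) {
    abort("pca_ivw requires at least two variants", class = "targetmr_input_error")
  }
  stopifnot(variance_target > 0, variance_target <= 1)
  v <- hset$variants
  phi_mat <- tcrossprod(v$b_x) * hset$rho / tcrossprod(v$se_y)
  eg <- eigen(phi_mat, symmetric = TRUE)
  lam <- pmax(eg$values, 0)
  if (sum(lam) <= 0) {
    abort("variance matrix has no positive eigenvalues", class = "targetmr_input_error")
  }
  k <- which(cumsum(lam) / sum(lam) >= variance_target - 1e-12)[1]
  Vk <- eg$vectors[, seq_len(k), drop = FALSE]
  omega <- hset$rho * tcrossprod(v$se_y)
  bx_p <- drop(crossprod(Vk, v$b_x))
  by_p <- drop(crossprod(Vk, v$b_y))
  omega_p <- crossprod(Vk, omega %*% Vk)
  U <- chol((omega_p + t(omega_p)) / 2)
  bx <- .whiten(U, bx_p)
  by <- .whiten(U, by_p)
  xtx <- sum(bx^2)
  theta <- sum(bx * by) / xtx
  se <- sqrt(1 / xtx)
  p <- 2 * pnorm(-abs(theta / se))
  new_mr_estimate("pca_ivw", theta, se, p, J, k_components = as.integer(k))
}

#' Steiger directionality filter
#'
#' Removes variants that explain more variance in the outcome than in the
#' exposure, guarding against reverse causation. Per variant and trait,
#' variance explained is computed from the t statistic as
#' `r2 = t^2 / (t^2 + n - 2)`; a variant is removed iff `r2_y > r2_x`
#' strictly (ties retained).
#'
#' @param hset An `mr_harmonized` object with per-variant sample sizes.
#' @return A list with `retained` (the filtered `mr_harmonized`) and
#'   `removed` (character vector of removed variant IDs).
#' @export
steiger_filter <- function(hset) {
  v <- hset$variants
  if (any(v$n_x <= 2) || any(v$n_y <= 2)) {
    abort("steiger_filter requires per-variant sample sizes > 2",
          class = "targetmr_input_error")
  }
  r2_of <- function(b, se, n) {
    t2 <- (b / se)^2
    t2 / (t2 + n - 2)
  }
  r2_x <- r2_of(v$b_x, v$se_x, v$n_x)
  r2_y <- r2_of(v$b_y, v$se_y, v$n_y)
  remove <- r2_y > r2_x
  retained <- if (all(remove)) {
    abort("Steiger filtering removed every variant", class = "targetmr_input_error")
  } else if (any(remove)) {
    hset_subset(hset, v$variant_id[!remove])
  } else {
    hset
  }
  list(retained = retained, removed = v$variant_id[remove])
}

#' Fit the primary-analysis estimator for an instrument
#'
#' Applies the estimator-selection rule: Wald ratio for a single variant,
#' fixed-effect correlated IVW for 2-3 variants, multiplicative
#' random-effects correlated IVW for more than three.
#'
#' @param hset An `mr_harmonized` instrument.
#' @return An `mr_estimate`.
#' @export
mr_fit <- function(hset) {
  J <- n_variants(hset)
  if (J == 1) wald_ratio(hset) else ivw_correlated(hset)
}

#' Serialize MR estimates to a flat TSV
#'
#' @param estimates A tibble of tidied estimates (e.g. from [run_primary()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mr_estimates <- function(estimates, path) {
  readr::write_tsv(estimates, path, progress = FALSE)
  invisible(path)
}
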