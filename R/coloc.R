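#' Colocalization priors
#'
#' Per-variant prior probabilities for the enumeration-based colocalization
#' model: `p1`/`p2` for association with trait 1/2 only, `p12` for a shared
#' causal variant, plus the prior standard deviations of true effects used
#' by the approximate Bayes factors. Defaults are the standard enumeration
#' settings: `p1 = p2 = 1e-4`, `p12 = 1e-5`, prior SD 0.2 for a quantitative
#' trait and 0.15 (log-odds) for a binary trait.
#'
#' @param p1,p2,p12 Per-variant priors; each in (0,1) with sum below 1.
#' @param sd1,sd2 Prior effect standard deviations for trait 1 and trait 2.
#' @return A list of class `coloc_priors`.
#' @export
coloc_priors <- function(p1 = 1e-4, p2 = 1e-4, p12 = 1e-5,
                         sd1 = 0.2, sd2 = 0.15) {
  stopifnot(p1 > 0, p1 < 1, p2 > 0, p2 < 1, p12 > 0, p12 < 1,
            p1 + p2 + p12 < 1, sd1 > 0, sd2 > 0)
  structure(list(p1 = p1, p2 = p2, p12 = p12, sd1 = sd1, sd2 = sd2),
            class = "coloc_priors")
}

#' Wakefield log approximate Bayes factor
#'
#' For a marginal association with effect `beta`, standard error `se` and
#' prior effect variance `w`: with `V = se^2`, `z = beta/se` and
#' `r = w/(w+V)`, `log ABF = 0.5 log(1-r) + 0.5 r z^2`. At `z = 0` the log
#' ABF is negative (shrinkage toward the null); as `w -> 0` it tends to 0.
#'
#' @param beta,se Marginal effect and standard error (vectorized).
#' @param w Prior variance of the true effect.
#' @return Log approximate Bayes factor(s) favouring association.
#' @export
wakefield_log_abf <- function(beta, se, w) {
  stopifnot(all(se > 0), w > 0)
  V <- se^2
  r <- w / (w + V)
  0.5 * log(1 - r) + 0.5 * r * (beta / se)^2
}

# log(sum(exp(x))) without overflow
.logsumexp <- function(x) {
  if (length(x) == 0) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Enumeration colocalization posteriors (PP0-PP4)
#'
#' Computes per-variant Wakefield log approximate Bayes factors for both
#' traits of a harmonized region and enumerates the five hypotheses: no
#' association (H0), trait 1 only (H1), trait 2 only (H2), two distinct
#' causal variants (H3), one shared causal variant (H4). Hypothesis sums are
#' accumulated in log space (log-sum-exp); H3 sums over ordered distinct
#' pairs. A posterior probability of H4 above 0.80 is the conventional
#' evidence threshold for a shared causal variant.
#'
#' @param hset An `mr_harmonized` region: trait 1 is the exposure side
#'   (`b_x`, `se_x`), trait 2 the outcome side (`b_y`, `se_y`).
#' @param priors A [coloc_priors()] object.
#' @return A one-row tibble of class `coloc_result` with `pp_h0` ... `pp_h4`,
#'   `n_variants`, and the priors as attributes. Posteriors sum to one.
#' @export
coloc_posteriors <- function(hset, priors = coloc_priors()) {
  stopifnot(inherits(priors, "coloc_priors"))
  v <- hset$variants
  if (nrow(v) < 1) abort("coloc_posteriors needs at least one variant",
                         class = "targetmr_input_error")
  l1 <- wakefield_log_abf(v$b_x, v$se_x, priors$sd1^2)
  l2 <- wakefield_log_abf(v$b_y, v$se_y, priors$sd2^2)
  s1 <- .logsumexp(l1)
  s2 <- .logsumexp(l2)
  s12 <- .logsumexp(l1 + l2)
  # sum over ordered distinct pairs (i != j) of l1_i + l2_j:
  # exp(s1)*exp(s2) - sum_i exp(l1_i + l2_i), done in log space
  s3_all <- s1 + s2
  s3 <- if (nrow(v) > 1) {
    d <- s12 - s3_all          # fraction of the full product on the diagonal
    s3_all + log1p(-min(exp(d), 1))
  } else {
    -Inf
  }
  lh <- c(
    h0 = 0,
    h1 = log(priors$p1) + s1,
    h2 = log(priors$p2) + s2,
    h3 = log(priors$p1) + log(priors$p2) + s3,
    h4 = log(priors$p12) + s12
  )
  pp <- exp(lh - .logsumexp(lh))
  pp <- pp / sum(pp)
  out <- tibble(pp_h0 = pp[["h0"]], pp_h1 = pp[["h1"]], pp_h2 = pp[["h2"]],
                pp_h3 = pp[["h3"]], pp_h4 = pp[["h4"]], n_variants = nrow(v))
  attr(out, "priors") <- priors
  class(out) <- c("coloc_result", class(out))
  out
}

#' Write a colocalization result as one-row TSV
#'
#' @param result A `coloc_result`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_coloc_result <- function(result, path) {
  priors <- attr(result, "priors")
  out <- bind_cols(as_tibble(result),
                   tibble(p1 = priors$p1, p2 = priors$p2, p12 = priors$p12,
                          sd1 = priors$sd1, sd2 = priors$sd2))
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}
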