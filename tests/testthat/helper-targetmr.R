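# Fixture builders shared across test files. Everything is generated in
# code; no stored data.

# Harmonized set straight from effect vectors (identity LD unless given).
make_hset <- function(b_x, se_x, b_y, se_y, rho = NULL,
                      p_x = NULL, n_x = 20000, n_y = 300000,
                      pos = NULL) {
  m <- length(b_x)
  ids <- sprintf("rs%03d", seq_len(m))
  if (is.null(rho)) rho <- diag(m)
  dimnames(rho) <- list(ids, ids)
  if (is.null(p_x)) p_x <- pmax(2 * pnorm(-abs(b_x / se_x)), 1e-300)
  if (is.null(pos)) pos <- 1000L * seq_len(m)
  variants <- tibble::tibble(
    variant_id = ids, pos = pos, eaf = 0.5,
    b_x = b_x, se_x = se_x, p_x = p_x, n_x = n_x,
    b_y = b_y, se_y = se_y, p_y = pmax(2 * pnorm(-abs(b_y / se_y)), 1e-300),
    n_y = n_y
  )
  targetmr:::new_mr_harmonized(variants, rho)
}

# Random well-conditioned correlation matrix via a factor model.
rand_corr <- function(m, k = max(2L, m %/% 3L)) {
  A <- matrix(rnorm(m * k), m, k)
  S <- tcrossprod(A) + diag(runif(m, 0.5, 1.5))
  stats::cov2cor(S)
}

# Canonical sumstats tibble with arbitrary alleles for harmonization tests.
make_sumstats <- function(variant_id, pos, ea, oa, beta, se, p = NULL,
                          n = 20000, eaf = 0.3, chrom = "1") {
  if (is.null(p)) p <- pmax(2 * pnorm(-abs(beta / se)), 1e-300)
  tibble::tibble(variant_id = variant_id, chrom = chrom, pos = pos,
                 effect_allele = ea, other_allele = oa, eaf = eaf,
                 beta = beta, se = se, p = p, n = n)
}

# Independent re-implementation of greedy clumping used as the brute-force
# oracle: repeatedly pick the best remaining candidate and delete everything
# it conflicts with (structurally different from the package's keep-scan).
clump_oracle_ids <- function(variants, rho, r2_threshold) {
  pool <- variants[order(variants$p_x, variants$pos, variants$variant_id), ]
  kept <- character(0)
  while (nrow(pool) > 0) {
    top <- pool$variant_id[1]
    kept <- c(kept, top)
    r2 <- rho[top, pool$variant_id]^2
    pool <- pool[r2 <= r2_threshold & pool$variant_id != top, , drop = FALSE]
  }
  sort(kept)
}

# Brute-force BH step-up, written from the definition.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}
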