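#' Simulation configuration
#'
#' Parameters of the two-sample summary-statistics generator. Defaults
#' describe a typical cis region instrumenting a plasma protein against a
#' large binary-outcome GWAS: 50 variants at 1 kb spacing with AR(1) LD
#' (decay 0.7), 3 true pQTLs with effect SD 0.15 per SD of protein,
#' exposure GWAS of 20,000 and outcome GWAS of 300,000, no causal effect
#' and no pleiotropy unless requested.
#'
#' @param m_variants Number of variants in the region.
#' @param ld_decay AR(1) correlation decay `c` in `[0, 1)`:
#'   `rho_ij = c^|i-j|`.
#' @param n_causal Number of true causal pQTLs.
#' @param tau SD of true causal pQTL effects (per SD of protein).
#' @param theta True causal protein -> outcome effect (log-odds per SD).
#' @param pleio_sd SD of direct (pleiotropic) variant -> outcome effects on
#'   the causal positions; 0 disables pleiotropy.
#' @param n_x,n_y Exposure and outcome GWAS sample sizes.
#' @param seed Integer seed; the generator is fully reproducible given it.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(m_variants = 50, ld_decay = 0.7, n_causal = 3,
                       tau = 0.15, theta = 0, pleio_sd = 0,
                       n_x = 20000, n_y = 300000, seed = 1L) {
  stopifnot(m_variants >= n_causal, n_causal >= 0,
            ld_decay >= 0, ld_decay < 1, n_x >= 10, n_y >= 10, tau >= 0,
            pleio_sd >= 0)
  structure(list(m_variants = as.integer(m_variants), ld_decay = ld_decay,
                 n_causal = as.integer(n_causal), tau = tau, theta = theta,
                 pleio_sd = pleio_sd, n_x = n_x, n_y = n_y,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate an AR(1) LD matrix
#'
#' `rho_ij = c^|i-j|`, positive semi-definite by construction, with
#' synthetic variant IDs `sv0001...` positioned at 1 kb spacing.
#'
#' @param m Number of variants.
#' @param c Decay parameter in `[0, 1)`; 0 gives the identity.
#' @return Correlation matrix with variant IDs as dimnames and a `pos`
#'   attribute of positions.
#' @export
simulate_ld <- function(m, c = 0.7) {
  stopifnot(c >= 0, c < 1, m >= 1)
  rho <- c^abs(outer(seq_len(m), seq_len(m), "-"))
  ids <- sprintf("sv%04d", seq_len(m))
  dimnames(rho) <- list(ids, ids)
  attr(rho, "pos") <- 1000L * seq_len(m)
  rho
}

# one MVN(0, rho/n) draw via the Cholesky factor of rho
.mvn_draw <- function(chol_upper, n) {
  drop(crossprod(chol_upper, rnorm(nrow(chol_upper)))) / sqrt(n)
}

.as_sumstats <- function(ids, pos, beta, se, n) {
  tibble(
    variant_id = ids, chrom = "1", pos = pos,
    effect_allele = "A", other_allele = "G",
    eaf = 0.5,  # synthetic placeholder: standardized-genotype scale
    beta = beta, se = se,
    p = pmax(2 * pnorm(-abs(beta / se)), .Machine$double.xmin),
    n = n
  )
}

#' Simulate region-level two-sample GWAS summary statistics
#'
#' Generates marginal exposure and outcome associations for one cis region
#' under known LD and causal structure, on the standardized-genotype,
#' standardized-trait scale (`se = 1/sqrt(n)`; the emitted allele frequency
#' is a 0.5 placeholder). Sparse true pQTL effects `gamma` sit on
#' `n_causal` positions; marginal exposure means are `rho %*% gamma` with
#' `MVN(0, rho/n_x)` sampling noise. Direct (pleiotropic) outcome effects
#' `alpha` are drawn on the causal positions with SD `pleio_sd`; marginal
#' outcome means are `rho %*% (theta * gamma + alpha)` with `MVN(0, rho/n_y)`
#' noise, binary outcomes being handled on the linear log-odds
#' approximation. Outputs are byte-identical given the same seed.
#'
#' @param cfg A [sim_config()].
#' @return A list with `exposure` and `outcome` (canonical summary-stats
#'   tibbles), `ld` (the correlation matrix), and `truth` (list with
#'   `gamma`, `alpha`, `theta`, `causal_idx`, `seed`).
#' @export
simulate_region_sumstats <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  m <- cfg$m_variants
  rho <- simulate_ld(m, cfg$ld_decay)
  pos <- attr(rho, "pos")
  ids <- rownames(rho)
  U <- chol(rho + diag(1e-10, m))

  gamma <- numeric(m)
  causal_idx <- sort(sample.int(m, cfg$n_causal))
  gamma[causal_idx] <- rnorm(cfg$n_causal, 0, cfg$tau)
  alpha <- numeric(m)
  if (cfg$pleio_sd > 0) alpha[causal_idx] <- rnorm(cfg$n_causal, 0, cfg$pleio_sd)

  mu_x <- drop(rho %*% gamma)
  mu_y <- drop(rho %*% (cfg$theta * gamma + alpha))
  b_x <- mu_x + .mvn_draw(U, cfg$n_x)
  b_y <- mu_y + .mvn_draw(U, cfg$n_y)

  list(
    exposure = .as_sumstats(ids, pos, b_x, rep(1 / sqrt(cfg$n_x), m), cfg$n_x),
    outcome = .as_sumstats(ids, pos, b_y, rep(1 / sqrt(cfg$n_y), m), cfg$n_y),
    ld = rho,
    truth = list(gamma = gamma, alpha = alpha, theta = cfg$theta,
                 causal_idx = causal_idx, seed = cfg$seed)
  )
}

#' Harmonize a simulated region in one step
#'
#' Convenience wrapper: simulated exposure/outcome tables share orientation,
#' so this is [harmonize()] with palindromic dropping off (the synthetic
#' alleles are all A/G).
#'
#' @param sim Output of [simulate_region_sumstats()].
#' @return An `mr_harmonized` object.
#' @export
sim_harmonized <- function(sim) {
  harmonize(sim$exposure, sim$outcome, rho = sim$ld, drop_palindromic = FALSE)
}

#' Simulate a study-level observational review table
#'
#' Emulates a systematic-review extraction: per study, a gestational week
#' drawn uniformly on [6, 40], a total sample size drawn lognormally around
#' ~150 participants with roughly 30% HDP cases, and a log10 HDP/control
#' mean ratio `intercept + true_slope * week` plus noise with SD
#' `noise_sd / sqrt(n_total / 100)` so larger studies are tighter. Group
#' means are back-computed from the ratio with the control mean fixed at
#' 100 arbitrary units.
#'
#' @param n_studies Number of studies (>= 2).
#' @param true_slope True change in log10 ratio per gestational week.
#' @param noise_sd Noise SD on the log10 scale for a 100-participant study.
#' @param seed Integer seed.
#' @param intercept Log10 ratio at week 0; the default -0.6 with the
#'   default slope crosses zero mid-gestation (an early deficit reversing
#'   later, as described for NT-proBNP).
#' @param protein,hdp_subtype Labels stamped on every row.
#' @return A validated study-timepoint tibble (see [validate_studies()]).
#' @export
simulate_observational_studies <- function(n_studies = 30, true_slope = 0.039,
                                           noise_sd = 0.15, seed = 1L,
                                           intercept = -0.6,
                                           protein = "NT-proBNP",
                                           hdp_subtype = "preeclampsia") {
  stopifnot(n_studies >= 2)
  set.seed(seed)
  week <- runif(n_studies, 6, 40)
  n_total <- pmax(20L, as.integer(round(exp(rnorm(n_studies, log(150), 0.6)))))
  n_hdp <- pmax(5L, as.integer(round(n_total * 0.3)))
  n_ctrl <- pmax(5L, n_total - n_hdp)
  lr <- intercept + true_slope * week +
    rnorm(n_studies, 0, noise_sd / sqrt(n_total / 100))
  out <- tibble(
    study_id = sprintf("study%03d", seq_len(n_studies)),
    protein = protein, hdp_subtype = hdp_subtype,
    gest_week = week,
    mean_ctrl = 100, mean_hdp = 100 * 10^lr,
    n_hdp = n_hdp, n_ctrl = n_ctrl
  )
  validate_studies(out)
  out
}

#' Write / read a simulation truth record as JSON
#'
#' @param truth The `truth` element of [simulate_region_sumstats()] output.
#' @param path JSON path.
#' @return For the writer, `path` invisibly; for the reader, the truth list.
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$causal_idx <- as.integer(x$causal_idx)
  x$seed <- as.integer(x$seed)
  x
}
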