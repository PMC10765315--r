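#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment, monotone-enforced and capped at
#' 1, returned in the input order. Thin wrapper over
#' `stats::p.adjust(method = "BH")`.
#'
#' @param p_values Numeric vector of p-values in (0, 1].
#' @return Adjusted p-values, same length and order.
#' @export
bh_fdr <- function(p_values) {
  if (length(p_values) == 0) return(numeric(0))
  stopifnot(all(p_values > 0 & p_values <= 1))
  p.adjust(p_values, method = "BH")
}

#' Run the primary protein-outcome analyses
#'
#' For every protein-outcome pair: select an instrument (p filter then
#' greedy clumping), fit the rule-based estimator (Wald ratio for one
#' variant, fixed-effect correlated IVW for 2-3, multiplicative
#' random-effects for more than three), and control the false discovery
#' rate across tests at 5% by Benjamini-Hochberg. Proteins without a valid
#' cis-pQTL are excluded and listed in the `excluded` attribute.
#'
#' @param panel A tibble with columns `protein`, `outcome`, and `data`, a
#'   list-column of `mr_harmonized` cis regions (full region, before
#'   instrument selection).
#' @param spec An [instrument_spec()]; defaults to the primary settings
#'   `p < 1e-4`, `r^2 < 0.4`.
#' @param fdr_by `"pooled"` (default) adjusts across all protein-outcome
#'   tests jointly; `"outcome"` adjusts within each outcome.
#' @param alpha Significance level on the adjusted scale (default 0.05).
#' @return A tibble with one row per analysable pair: the tidy estimate
#'   columns plus `f_stat`, `p_fdr` and `fdr_significant`. Excluded
#'   proteins are recorded in `attr(, "excluded")`.
#' @export
run_primary <- function(panel, spec = instrument_spec(),
                        fdr_by = c("pooled", "outcome"), alpha = 0.05) {
  fdr_by <- match.arg(fdr_by)
  stopifnot(all(c("protein", "outcome", "data") %in% names(panel)))
  rows <- purrr::pmap(panel, function(protein, outcome, data, ...) {
    inst <- select_instruments(data, spec)
    if (is.null(inst)) {
      return(tibble(protein = protein, outcome = outcome, excluded = TRUE))
    }
    tidy(mr_fit(inst)) |>
      mutate(protein = protein, outcome = outcome,
             f_stat = attr(inst, "f_stat"), excluded = FALSE,
             .before = 1)
  })
  res <- bind_rows(rows)
  excluded <- res |> filter(.data$excluded) |> select("protein", "outcome")
  res <- res |> filter(!.data$excluded) |> select(-"excluded")
  if (nrow(res) > 0) {
    res <- if (fdr_by == "pooled") {
      res |> mutate(p_fdr = bh_fdr(.data$p))
    } else {
      res |> group_by(.data$outcome) |> mutate(p_fdr = bh_fdr(.data$p)) |> ungroup()
    }
    res <- res |> mutate(fdr_significant = .data$p_fdr < alpha)
  }
  attr(res, "excluded") <- excluded
  res
}

#' Sensitivity grids used in the battery
#'
#' @format Numeric vectors: six LD r-squared thresholds and two stricter
#'   instrument p-value thresholds.
#' @name sensitivity_grids
#' @keywords internal
.r2_grid <- c(0.001, 0.01, 0.1, 0.2, 0.6, 0.8)
.p_grid <- c(1e-6, 5e-8)

#' Run the sensitivity battery for one protein-outcome pair
#'
#' Re-selects instruments and re-estimates across the grid of LD thresholds
#' (`r^2` in 0.001, 0.01, 0.1, 0.2, 0.6, 0.8) and stricter instrument
#' p-value thresholds (`1e-6`, `5e-8`), and runs principal-components IVW
#' and MR-Egger on the primary instrument: up to ten sensitivity analyses.
#' Grid points where no variant survives selection (or Egger when the
#' primary instrument has fewer than three variants) are omitted and listed
#' in the profile's `omitted` field. Estimator selection at each grid point
#' follows the primary rule, so a grid point with a single surviving variant
#' is estimated by the Wald ratio.
#'
#' @param data An `mr_harmonized` cis region (full region, before
#'   selection).
#' @param spec The primary [instrument_spec()].
#' @param r2_grid,p_grid Sensitivity grids; defaults as above.
#' @param reverse_p P-value of the reverse-direction MR (outcome as
#'   exposure, instrumented by caller-supplied genome-wide significant
#'   outcome loci; see [reverse_mr()]). `NA` when not available.
#' @param steiger Apply [steiger_filter()] to each instrument before
#'   estimation? Default `FALSE` (the filter is reported separately in the
#'   primary workflow).
#' @return An object of class `sensitivity_profile`: list with `primary`
#'   (an `mr_estimate`), `grid` (tibble of labelled tidy estimates),
#'   `reverse_p`, and `omitted` (labels of grid points with no instrument).
#' @export
run_sensitivity_battery <- function(data, spec = instrument_spec(),
                                    r2_grid = .r2_grid, p_grid = .p_grid,
                                    reverse_p = NA_real_, steiger = FALSE) {
  primary_inst <- select_instruments(data, spec)
  if (is.null(primary_inst)) {
    abort("no primary instrument: no variant passes the selection thresholds",
          class = "targetmr_input_error")
  }
  if (steiger) primary_inst <- steiger_filter(primary_inst)$retained
  primary <- mr_fit(primary_inst)

  entries <- list()
  omitted <- character(0)
  add_entry <- function(label, est) {
    entries[[length(entries) + 1]] <<- tidy(est) |> mutate(label = label, .before = 1)
  }
  fit_at <- function(label, sp) {
    inst <- select_instruments(data, sp)
    if (is.null(inst)) {
      omitted <<- c(omitted, label)
      warn(sprintf("sensitivity grid point '%s': no instrument; entry omitted", label))
      return(invisible(NULL))
    }
    if (steiger) inst <- steiger_filter(inst)$retained
    add_entry(label, mr_fit(inst))
  }
  if (n_variants(primary_inst) >= 2) {
    add_entry("pca_ivw", pca_ivw(primary_inst))
  } else {
    omitted <- c(omitted, "pca_ivw")
  }
  if (n_variants(primary_inst) >= 3) {
    add_entry("egger", egger_correlated(primary_inst))
  } else {
    omitted <- c(omitted, "egger")
  }
  for (r2 in r2_grid) {
    fit_at(sprintf("ivw_r2_%g", r2), instrument_spec(spec$p_threshold, r2))
  }
  for (pthr in p_grid) {
    fit_at(sprintf("ivw_p_%g", pthr), instrument_spec(pthr, spec$r2_threshold))
  }
  structure(list(primary = primary, grid = bind_rows(entries),
                 reverse_p = reverse_p, omitted = omitted, spec = spec),
            class = "sensitivity_profile")
}

#' @export
print.sensitivity_profile <- function(x, ...) {
  cat(sprintf("<sensitivity_profile> primary %s theta = %.4f; %d sensitivity entries (%d omitted); reverse-MR p = %s\n",
              x$primary$method, x$primary$theta, nrow(x$grid), length(x$omitted),
              format(x$reverse_p)))
  invisible(x)
}

#' @export
tidy.sensitivity_profile <- function(x, ...) {
  bind_rows(tidy(x$primary) |> mutate(label = "primary", .before = 1), x$grid)
}

#' Three-criterion robustness verdict
#'
#' A protein-outcome association is graded robust iff (1) the primary
#' analysis is significant after FDR adjustment, (2) every sensitivity
#' analysis is directionally consistent with the primary estimate (point
#' estimates share one sign; significance is not required), and (3) there is
#' no evidence of reverse causation (unadjusted reverse-MR p > 0.05).
#'
#' @param profile A `sensitivity_profile`.
#' @param fdr_significant Was the primary analysis FDR-significant (from
#'   [run_primary()])?
#' @return A one-row tibble with the per-criterion flags
#'   `primary_significant`, `directionally_consistent`, `no_reverse_cause`,
#'   and the overall `robust` verdict.
#' @export
assess_robustness <- function(profile, fdr_significant) {
  stopifnot(inherits(profile, "sensitivity_profile"))
  signs <- sign(c(profile$primary$theta, profile$grid$theta))
  consistent <- length(unique(signs[signs != 0])) <= 1
  no_reverse <- !is.na(profile$reverse_p) && profile$reverse_p > 0.05
  tibble(
    primary_significant = isTRUE(fdr_significant),
    directionally_consistent = consistent,
    no_reverse_cause = no_reverse,
    robust = isTRUE(fdr_significant) && consistent && no_reverse
  )
}

#' Reverse-direction Mendelian randomization
#'
#' Tests the outcome -> protein direction using caller-supplied instruments
#' for the outcome (genome-wide significant outcome loci; the pipeline does
#' not invent them). The harmonized set must carry the outcome as the
#' exposure side (`b_x`) and the protein as the outcome side (`b_y`).
#'
#' @param hset An `mr_harmonized` object oriented outcome -> protein.
#' @return An `mr_estimate` from the rule-based estimator; its unadjusted
#'   `p` feeds criterion (3) of [assess_robustness()].
#' @export
reverse_mr <- function(hset) mr_fit(hset)

#' Phenome-wide scan of a prioritized protein
#'
#' Runs correlated IVW (Wald ratio when a single variant overlaps) of the
#' protein instrument against each phenotype panel, flags significance at
#' the Bonferroni-style threshold `alpha / n_proteins` (0.05/6 = 0.0083 for
#' six prioritized proteins), and classifies each significant association as
#' beneficial or adverse. The caller states which direction of protein
#' change lowers HDP risk; an association is beneficial iff moving the
#' protein in that HDP-protective direction also lowers the phenotype's
#' risk.
#'
#' @param phenotypes A tibble with columns `phenotype` and `data`
#'   (list-column of `mr_harmonized` sets for this protein against each
#'   phenotype), or a named list of `mr_harmonized` objects.
#' @param n_proteins Number of proteins scanned (divisor of the threshold).
#' @param hdp_protective_direction `+1` if higher protein levels lower HDP
#'   risk (e.g. NT-proBNP), `-1` if lower levels do.
#' @param protein Optional protein label carried through to the result.
#' @param alpha Family-wise alpha before division (default 0.05).
#' @return A tibble with one row per phenotype: `protein`, `phenotype`,
#'   `theta`, `se`, `p`, `or`, `significant`, and `direction_class`
#'   (`"beneficial"`/`"adverse"`, defined only when significant). Phenotypes
#'   whose harmonization failed are skipped with a warning.
#' @export
phenomewide_scan <- function(phenotypes, n_proteins,
                             hdp_protective_direction = c(1, -1),
                             protein = NA_character_, alpha = 0.05) {
  dir <- match.arg(as.character(hdp_protective_direction[1]), c("1", "-1"))
  dir <- as.numeric(dir)
  if (is.list(phenotypes) && !is.data.frame(phenotypes)) {
    phenotypes <- tibble(phenotype = names(phenotypes), data = unname(phenotypes))
  }
  stopifnot(n_proteins >= 1)
  threshold <- alpha / n_proteins
  rows <- purrr::pmap(phenotypes, function(phenotype, data, ...) {
    if (is.null(data) || n_variants(data) == 0) {
      warn(sprintf("phenotype '%s': no overlapping variants; skipped", phenotype))
      return(NULL)
    }
    est <- mr_fit(data)
    tibble(protein = protein, phenotype = phenotype,
           theta = est$theta, se = est$se, p = est$p, or = exp(est$theta),
           n_variants = est$n_variants)
  })
  out <- bind_rows(rows)
  if (nrow(out) == 0) {
    return(tibble(protein = character(), phenotype = character(),
                  theta = numeric(), se = numeric(), p = numeric(),
                  or = numeric(), n_variants = integer(),
                  significant = logical(), direction_class = character()))
  }
  out |>
    mutate(
      significant = .data$p < threshold,
      direction_class = dplyr::case_when(
        !.data$significant ~ NA_character_,
        # moving the protein in its HDP-protective direction lowers this
        # phenotype's risk iff dir * theta < 0
        dir * .data$theta < 0 ~ "beneficial",
        .default = "adverse"
      )
    )
}
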