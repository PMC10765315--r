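#' Instrument selection parameters
#'
#' The two knobs of cis-pQTL instrument construction: the region-wide
#' p-value cutoff and the squared-correlation cutoff used by greedy LD
#' clumping. Defaults are the primary-analysis settings `p < 1e-4`,
#' `r^2 < 0.4`.
#'
#' @param p_threshold Exposure p-value cutoff, in (0, 1).
#' @param r2_threshold Pairwise squared-correlation cutoff, in (0, 1].
#' @return A list of class `instrument_spec`.
#' @export
instrument_spec <- function(p_threshold = 1e-4, r2_threshold = 0.4) {
  stopifnot(p_threshold > 0, p_threshold < 1,
            r2_threshold > 0, r2_threshold <= 1)
  structure(list(p_threshold = p_threshold, r2_threshold = r2_threshold),
            class = "instrument_spec")
}

#' Greedy LD clumping of a harmonized set
#'
#' Processes variants in ascending exposure p-value (ties broken by genomic
#' position, then variant ID, for cross-platform determinism) and keeps a
#' variant iff its squared correlation with every already-kept variant is at
#' most `r2_threshold`. Output preserves genomic order. `r^2` is the square
#' of the signed LD correlation.
#'
#' @param hset An `mr_harmonized` object with exposure p-values.
#' @param r2_threshold Squared-correlation cutoff.
#' @return The clumped `mr_harmonized` object. A single-variant input is
#'   returned unchanged.
#' @export
clump_greedy <- function(hset, r2_threshold = 0.4) {
  v <- hset$variants
  if (nrow(v) <= 1) return(hset)
  ord <- order(v$p_x, v$pos, v$variant_id)
  r2 <- hset$rho^2
  kept <- integer(0)
  for (i in ord) {
    if (all(r2[i, kept] <= r2_threshold)) kept <- c(kept, i)
  }
  hset_subset(hset, v$variant_id[sort(kept)])
}

#' Select a genetic instrument from a harmonized cis region
#'
#' Applies the exposure p-value filter, then greedy LD clumping, and records
#' the selection parameters and the mean per-variant F statistic. Returns
#' `NULL` ("no instrument") when no variant passes the p filter; proteins
#' without a valid cis-pQTL are excluded from downstream analysis this way.
#'
#' @param hset An `mr_harmonized` object covering the cis region.
#' @param spec An [instrument_spec()].
#' @return An object of class `mr_instrument` (an `mr_harmonized` with
#'   attributes `spec` and `f_stat`), or `NULL` when no variant survives.
#' @export
select_instruments <- function(hset, spec = instrument_spec()) {
  stopifnot(inherits(spec, "instrument_spec"))
  pass <- hset$variants$p_x <= spec$p_threshold
  if (!any(pass)) return(NULL)
  out <- clump_greedy(hset_subset(hset, hset$variants$variant_id[pass]),
                      spec$r2_threshold)
  attr(out, "spec") <- spec
  attr(out, "f_stat") <- f_statistic(out)
  class(out) <- c("mr_instrument", class(out))
  out
}

#' Mean per-variant F statistic
#'
#' Instrument strength as the arithmetic mean of the per-variant
#' `F_j = (b_x / se_x)^2`. Values above ~10-15 indicate low risk of weak
#' instrument bias. This form needs neither allele frequencies nor an
#' aggregate r-squared.
#'
#' @param hset An `mr_harmonized` object.
#' @return The mean F across variants.
#' @export
f_statistic <- function(hset) {
  if (n_variants(hset) == 0) {
    abort("cannot compute an F statistic for an empty variant set",
          class = "targetmr_input_error")
  }
  mean((hset$variants$b_x / hset$variants$se_x)^2)
}

#' Export an instrument as TSV plus JSON sidecar
#'
#' Writes the selected variants (exposure side, canonical columns) and a
#' JSON sidecar recording the selection parameters and mean F.
#'
#' @param instrument An `mr_instrument`.
#' @param path_tsv,path_json Output paths.
#' @return `path_tsv`, invisibly.
#' @export
write_instrument <- function(instrument, path_tsv, path_json) {
  readr::write_tsv(instrument$variants, path_tsv, progress = FALSE)
  spec <- attr(instrument, "spec")
  jsonlite::write_json(
    list(p_threshold = spec$p_threshold, r2_threshold = spec$r2_threshold,
         f_stat = attr(instrument, "f_stat"),
         n_variants = n_variants(instrument)),
    path_json, auto_unbox = TRUE, digits = NA
  )
  invisible(path_tsv)
}
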