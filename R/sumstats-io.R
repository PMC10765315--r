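#' Canonical summary-statistics columns
#'
#' Summary statistics travel through the package as tibbles with one row per
#' variant and the canonical columns `variant_id`, `chrom`, `pos`,
#' `effect_allele`, `other_allele`, `eaf`, `beta`, `se`, `p`, `n`.
#' Coordinates are 1-based; `beta` is the effect per SD of a quantitative
#' trait or the log-odds for a binary trait, always reported for
#' `effect_allele`.
#'
#' @name sumstats
#' @keywords internal
NULL

.sumstats_cols <- c(
  variant_id = "SNP", chrom = "CHR", pos = "POS",
  effect_allele = "EA", other_allele = "OA", eaf = "EAF",
  beta = "BETA", se = "SE", p = "P", n = "N"
)

#' Validate a summary-statistics tibble
#'
#' Checks the per-variant invariants: positive standard errors, p-values in
#' (0, 1], distinct alleles, positions >= 1. Used by [read_sumstats()] and the
#' simulator; exported so callers can vet their own tables.
#'
#' @param stats A tibble in canonical [sumstats] form.
#' @return `stats` invisibly, if valid; otherwise an error naming the first
#'   offending row.
#' @export
validate_sumstats <- function(stats) {
  req <- names(.sumstats_cols)
  missing <- setdiff(req, names(stats))
  if (length(missing) > 0) {
    abort(paste0("missing mandatory column(s): ", paste(missing, collapse = ", ")),
          class = "targetmr_format_error")
  }
  bad_row <- function(which, what) {
    abort(sprintf("row %d: %s", which, what), class = "targetmr_validation_error")
  }
  bad <- which(!(stats$se > 0) | !is.finite(stats$se))
  if (length(bad) > 0) bad_row(bad[1], "se must be > 0")
  bad <- which(!(stats$p > 0 & stats$p <= 1) | !is.finite(stats$p))
  if (length(bad) > 0) bad_row(bad[1], "p must lie in (0, 1]")
  bad <- which(stats$effect_allele == stats$other_allele)
  if (length(bad) > 0) bad_row(bad[1], "effect_allele must differ from other_allele")
  bad <- which(stats$pos < 1)
  if (length(bad) > 0) bad_row(bad[1], "pos must be >= 1")
  invisible(stats)
}

#' Read GWAS summary statistics
#'
#' Reads a tab-separated summary-statistics file with a header row into the
#' canonical tibble form. The default dialect expects the columns `SNP`,
#' `CHR`, `POS`, `EA`, `OA`, `EAF`, `BETA`, `SE`, `P`, `N`; supply `dialect`
#' to map other header names onto the canonical ones. Missing allele
#' frequencies are encoded as `NA`. Parsing is locale-independent (decimal
#' point).
#'
#' @param path Path to a TSV file.
#' @param dialect Named character vector mapping canonical names
#'   (`variant_id`, `chrom`, ..., `n`) to the header names used in the file;
#'   defaults to the canonical `SNP`/`CHR`/... header.
#' @return A tibble of validated variant associations, one row per variant.
#' @seealso [write_sumstats()] for the inverse; [validate_sumstats()] for the
#'   row-level invariants enforced here.
#' @export
read_sumstats <- function(path, dialect = NULL) {
  map <- .sumstats_cols
  if (!is.null(dialect)) map[names(dialect)] <- dialect
  raw <- readr::read_tsv(
    path,
    col_types = readr::cols(.default = readr::col_character()),
    locale = readr::locale(decimal_mark = "."),
    progress = FALSE, show_col_types = FALSE
  )
  missing <- map[!(map %in% names(raw))]
  if (length(missing) > 0) {
    abort(paste0("missing mandatory column(s): ", paste(missing, collapse = ", ")),
          class = "targetmr_format_error")
  }
  out <- tibble(
    variant_id = raw[[map[["variant_id"]]]],
    chrom = raw[[map[["chrom"]]]],
    pos = as.integer(raw[[map[["pos"]]]]),
    effect_allele = toupper(raw[[map[["effect_allele"]]]]),
    other_allele = toupper(raw[[map[["other_allele"]]]]),
    eaf = suppressWarnings(as.numeric(raw[[map[["eaf"]]]])),
    beta = as.numeric(raw[[map[["beta"]]]]),
    se = as.numeric(raw[[map[["se"]]]]),
    p = as.numeric(raw[[map[["p"]]]]),
    n = as.numeric(raw[[map[["n"]]]])
  )
  validate_sumstats(out)
  out
}

#' Write summary statistics to TSV
#'
#' Writes the canonical header (`SNP`, `CHR`, ...) so that
#' `read_sumstats(write_sumstats(x, path))` round-trips identically.
#'
#' @param stats Canonical summary-statistics tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sumstats <- function(stats, path) {
  validate_sumstats(stats)
  out <- stats[, names(.sumstats_cols)]
  names(out) <- unname(.sumstats_cols)
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Read a linkage-disequilibrium correlation matrix
#'
#' Reads a whitespace-delimited square matrix of signed correlations plus a
#' sidecar file with one variant ID per line. Asymmetries up to `1e-8` are
#' symmetrized by averaging; anything larger is a format error, as are
#' off-unit diagonals, entries outside `[-1, 1]`, or a dimension mismatch
#' with the ID file.
#'
#' @param path_matrix Path to the square numeric matrix file.
#' @param path_ids Path to the one-ID-per-line sidecar.
#' @return A symmetric correlation matrix with the variant IDs as dimnames.
#' @export
read_ld_matrix <- function(path_matrix, path_ids) {
  ids <- readr::read_lines(path_ids, progress = FALSE)
  ids <- ids[nzchar(ids)]
  m <- as.matrix(readr::read_table(path_matrix, col_names = FALSE,
                                   col_types = readr::cols(.default = readr::col_double()),
                                   progress = FALSE))
  dimnames(m) <- NULL
  if (nrow(m) != ncol(m)) {
    abort(sprintf("LD matrix is not square (%d x %d)", nrow(m), ncol(m)),
          class = "targetmr_format_error")
  }
  if (nrow(m) != length(ids)) {
    abort(sprintf("LD matrix dimension (%d) does not match number of ids (%d)",
                  nrow(m), length(ids)),
          class = "targetmr_format_error")
  }
  dimnames(m) <- list(ids, ids)
  validate_ld_matrix(m)
}

#' Validate (and lightly symmetrize) an LD matrix
#'
#' @param r Square correlation matrix with variant IDs as dimnames.
#' @param tol Asymmetry tolerance; asymmetries within `tol` are averaged
#'   away, larger ones raise a format error.
#' @return The validated, exactly symmetric matrix.
#' @export
validate_ld_matrix <- function(r, tol = 1e-8) {
  if (!is.matrix(r) || nrow(r) != ncol(r)) {
    abort("LD matrix must be square", class = "targetmr_format_error")
  }
  asym <- max(abs(r - t(r)))
  if (asym > tol) {
    abort(sprintf("LD matrix asymmetry %.3g exceeds tolerance %.1g", asym, tol),
          class = "targetmr_format_error")
  }
  r <- (r + t(r)) / 2
  if (max(abs(diag(r) - 1)) > tol) {
    abort("LD matrix diagonal must be 1", class = "targetmr_format_error")
  }
  diag(r) <- 1
  if (max(abs(r)) > 1 + tol) {
    abort("LD correlations must lie in [-1, 1]", class = "targetmr_format_error")
  }
  r[r > 1] <- 1
  r[r < -1] <- -1
  ev_min <- min(eigen(r, symmetric = TRUE, only.values = TRUE)$values)
  if (ev_min < -1e-8) {
    abort(sprintf("LD matrix is not positive semi-definite (min eigenvalue %.3g)", ev_min),
          class = "targetmr_format_error")
  }
  r
}

#' Write an LD matrix and its ID sidecar
#'
#' @param r Correlation matrix with variant IDs as dimnames.
#' @param path_matrix,path_ids Output paths for the matrix and the sidecar.
#' @return `path_matrix`, invisibly.
#' @export
write_ld_matrix <- function(r, path_matrix, path_ids) {
  readr::write_lines(apply(r, 1, function(row) paste(format(row, digits = 17), collapse = " ")),
                     path_matrix)
  readr::write_lines(rownames(r), path_ids)
  invisible(path_matrix)
}

#' Extract a cis region around a gene
#'
#' Restricts a summary-statistics table to the variants falling in the closed
#' interval `[anchor_start - window, anchor_end + window]` around the gene
#' body (1-based, inclusive coordinates). The default +/-200 kb window is the
#' conventional cis-pQTL flank.
#'
#' @param stats Canonical summary-statistics tibble.
#' @param gene_id Gene identifier, recorded on the result.
#' @param anchor_start,anchor_end Gene-body coordinates, 1-based inclusive.
#' @param window Flank in base pairs on each side (default 200000).
#' @return The subset tibble, sorted by position, with attributes `gene_id`,
#'   `anchor_start`, `anchor_end`, `window`. An empty result is valid.
#' @export
extract_cis_region <- function(stats, gene_id, anchor_start, anchor_end,
                               window = 200000L) {
  stopifnot(window >= 0, anchor_start <= anchor_end)
  out <- stats |>
    filter(.data$pos >= anchor_start - window, .data$pos <= anchor_end + window) |>
    arrange(.data$pos, .data$variant_id)
  attr(out, "gene_id") <- gene_id
  attr(out, "anchor_start") <- anchor_start
  attr(out, "anchor_end") <- anchor_end
  attr(out, "window") <- window
  out
}

.palindromic <- function(a1, a2) {
  (a1 == "A" & a2 == "T") | (a1 == "T" & a2 == "A") |
    (a1 == "C" & a2 == "G") | (a1 == "G" & a2 == "C")
}

#' Harmonize exposure and outcome associations
#'
#' Joins exposure and outcome summary statistics by variant ID and aligns
#' both to the exposure's effect allele. Outcome records whose effect/other
#' alleles are swapped relative to the exposure have their beta negated and
#' allele frequency replaced by `1 - eaf`; variants whose allele pairs do not
#' match at all are dropped with a recorded reason, as are palindromic (A/T,
#' C/G) variants when `drop_palindromic = TRUE` (the default: strand cannot
#' be verified from summary data alone). The LD matrix is restricted and
#' reordered to the surviving variants.
#'
#' @param exposure,outcome Canonical summary-statistics tibbles.
#' @param rho LD correlation matrix covering the exposure variants (dimnames
#'   are variant IDs). `NULL` means independent variants (identity).
#' @param drop_palindromic Drop A/T and C/G variants? Default `TRUE`.
#' @return An object of class `mr_harmonized`: a list with
#'   \describe{
#'     \item{variants}{tibble with `variant_id`, `pos`, `eaf`, `b_x`, `se_x`,
#'       `p_x`, `n_x`, `b_y`, `se_y`, `p_y`, `n_y`, in genomic order}
#'     \item{rho}{the matching LD submatrix}
#'     \item{dropped}{tibble of dropped variants and reasons}
#'   }
#' @export
harmonize <- function(exposure, outcome, rho = NULL, drop_palindromic = TRUE) {
  validate_sumstats(exposure)
  validate_sumstats(outcome)
  joined <- dplyr::inner_join(
    exposure, outcome,
    by = "variant_id", suffix = c("_x", "_y")
  )
  if (nrow(joined) == 0) {
    abort("no overlapping variants between exposure and outcome",
          class = "targetmr_harmonize_error")
  }
  same <- joined$effect_allele_x == joined$effect_allele_y &
    joined$other_allele_x == joined$other_allele_y
  swapped <- joined$effect_allele_x == joined$other_allele_y &
    joined$other_allele_x == joined$effect_allele_y
  pal <- .palindromic(joined$effect_allele_x, joined$other_allele_x)

  reason <- rep(NA_character_, nrow(joined))
  reason[!same & !swapped] <- "allele mismatch"
  if (drop_palindromic) reason[is.na(reason) & pal] <- "palindromic"
  dropped <- tibble(variant_id = joined$variant_id[!is.na(reason)],
                    reason = reason[!is.na(reason)])
  keep <- is.na(reason)
  joined <- joined[keep, ]
  swapped <- swapped[keep]
  if (nrow(joined) == 0) {
    abort("no overlapping variants survive harmonization",
          class = "targetmr_harmonize_error")
  }
  joined$beta_y[swapped] <- -joined$beta_y[swapped]
  joined$eaf_y[swapped] <- 1 - joined$eaf_y[swapped]

  variants <- joined |>
    mutate(variant_id = .data$variant_id, pos = .data$pos_x, eaf = .data$eaf_x,
           b_x = .data$beta_x, se_x = .data$se_x, p_x = .data$p_x, n_x = .data$n_x,
           b_y = .data$beta_y, se_y = .data$se_y, p_y = .data$p_y, n_y = .data$n_y,
           .keep = "none") |>
    arrange(.data$pos, .data$variant_id)

  if (is.null(rho)) {
    rho <- diag(nrow(variants))
    dimnames(rho) <- list(variants$variant_id, variants$variant_id)
  } else {
    missing_ld <- setdiff(variants$variant_id, rownames(rho))
    if (length(missing_ld) > 0) {
      abort(paste0("LD matrix does not cover variant(s): ",
                   paste(head(missing_ld, 5), collapse = ", ")),
            class = "targetmr_harmonize_error")
    }
    rho <- rho[variants$variant_id, variants$variant_id, drop = FALSE]
  }
  new_mr_harmonized(variants, rho, dropped)
}

new_mr_harmonized <- function(variants, rho, dropped = tibble(variant_id = character(),
                                                              reason = character())) {
  stopifnot(nrow(variants) == nrow(rho), all(variants$se_x > 0), all(variants$se_y > 0))
  structure(list(variants = variants, rho = rho, dropped = dropped),
            class = "mr_harmonized")
}

#' Number of variants in a harmonized set
#' @param hset An `mr_harmonized` object.
#' @return Integer count.
#' @export
n_variants <- function(hset) nrow(hset$variants)

#' Subset a harmonized set by variant ID
#'
#' Restricts the variant table and the LD submatrix to `ids`, preserving
#' genomic order.
#'
#' @param hset An `mr_harmonized` object.
#' @param ids Variant IDs to keep.
#' @return A new `mr_harmonized` object.
#' @export
hset_subset <- function(hset, ids) {
  keep <- hset$variants$variant_id %in% ids
  if (!any(keep)) abort("subset removes every variant", class = "targetmr_harmonize_error")
  new_mr_harmonized(hset$variants[keep, ],
                    hset$rho[hset$variants$variant_id[keep],
                             hset$variants$variant_id[keep], drop = FALSE],
                    hset$dropped)
}

#' @export
as_tibble.mr_harmonized <- function(x, ...) x$variants

#' @export
print.mr_harmonized <- function(x, ...) {
  cat(sprintf("<mr_harmonized> %d variants (%d dropped in harmonization)\n",
              nrow(x$variants), nrow(x$dropped)))
  print(x$variants, n = 5)
  invisible(x)
}
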