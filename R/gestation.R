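#' Log10 ratio of mean protein levels, HDP vs control
#'
#' The study-level contrast: `log10(mean_hdp / mean_ctrl)`. Antisymmetric
#' under swapping the groups and invariant to rescaling both means by a
#' common factor (so units may differ between studies).
#'
#' @param mean_hdp,mean_ctrl Positive group mean concentrations (same units
#'   within a study); vectorized.
#' @return `log10(mean_hdp / mean_ctrl)`.
#' @export
log_ratio <- function(mean_hdp, mean_ctrl) {
  if (any(!is.finite(mean_hdp)) || any(!is.finite(mean_ctrl)) ||
      any(mean_hdp <= 0) || any(mean_ctrl <= 0)) {
    abort("group means must be positive", class = "targetmr_validation_error")
  }
  log10(mean_hdp / mean_ctrl)
}

#' Validate a study-timepoint table
#'
#' Expected columns: `study_id`, `protein`, `hdp_subtype` (one of
#' `"preeclampsia"`, `"gestational hypertension"`, `"mixed"`), `gest_week`,
#' `mean_hdp`, `mean_ctrl`, `n_hdp`, `n_ctrl`. Means must be positive,
#' weeks in (0, 45), group sizes at least 1. An optional logical
#' `median_reported` column flags studies whose "means" are medians
#' (accepted with a mean~median caveat).
#'
#' @param studies The study table.
#' @return `studies` invisibly.
#' @export
validate_studies <- function(studies) {
  req <- c("study_id", "protein", "hdp_subtype", "gest_week",
           "mean_hdp", "mean_ctrl", "n_hdp", "n_ctrl")
  missing <- setdiff(req, names(studies))
  if (length(missing) > 0) {
    abort(paste0("missing study column(s): ", paste(missing, collapse = ", ")),
          class = "targetmr_format_error")
  }
  if (any(studies$mean_hdp <= 0) || any(studies$mean_ctrl <= 0)) {
    abort("group means must be positive", class = "targetmr_validation_error")
  }
  if (any(studies$gest_week <= 0 | studies$gest_week >= 45)) {
    abort("gestational weeks must lie in (0, 45)", class = "targetmr_validation_error")
  }
  if (any(studies$n_hdp < 1) || any(studies$n_ctrl < 1)) {
    abort("group sizes must be >= 1", class = "targetmr_validation_error")
  }
  invisible(studies)
}

#' Sample-size-weighted gestational trend of a biomarker contrast
#'
#' Regresses the per-study `log10` mean ratio (HDP vs non-HDP) on
#' gestational age at sampling by weighted least squares, weighting each
#' study by its total sample size `n_hdp + n_ctrl` (weights matter only up
#' to proportionality). Inference is t-based with `n_points - 2` residual
#' degrees of freedom (`n_points - 3` with the optional quadratic term); a
#' p-value is only reported from three or more studies. Studies labelled
#' `"mixed"` (subtype not distinguished) are excluded by default.
#'
#' @param studies Study-timepoint table (see [validate_studies()]).
#' @param protein,hdp_subtype Optional filters; `NULL` keeps all rows.
#' @param quadratic Add a `gest_week^2` term? Reported separately as
#'   `quad_term` in [tidy()]; the linear coefficient remains the headline
#'   slope.
#' @param include_mixed Keep `"mixed"`-subtype rows? Default `FALSE`.
#' @return An object of class `trend_fit` wrapping the `lm` fit, with
#'   [tidy()]/[glance()]/[autoplot()] methods. The headline slope is the
#'   log10 fold-change per gestational week.
#' @export
fit_weighted_trend <- function(studies, protein = NULL, hdp_subtype = NULL,
                               quadratic = FALSE, include_mixed = FALSE) {
  validate_studies(studies)
  d <- studies
  if (!is.null(protein)) d <- d |> filter(.data$protein == .env$protein)
  if (!is.null(hdp_subtype)) d <- d |> filter(.data$hdp_subtype == .env$hdp_subtype)
  if (!include_mixed) d <- d |> filter(.data$hdp_subtype != "mixed")
  if (nrow(d) < 2) {
    abort("need at least two study timepoints to fit a trend",
          class = "targetmr_input_error")
  }
  if (length(unique(d$gest_week)) < 2) {
    abort("all timepoints share one gestational week; trend is collinear",
          class = "targetmr_input_error")
  }
  d <- d |> mutate(log_ratio = log_ratio(.data$mean_hdp, .data$mean_ctrl),
                   weight = .data$n_hdp + .data$n_ctrl)
  form <- if (quadratic) log_ratio ~ gest_week + I(gest_week^2) else log_ratio ~ gest_week
  fit <- lm(form, data = d, weights = weight)
  structure(list(fit = fit, data = d, quadratic = quadratic,
                 protein = protein %||% unique(d$protein),
                 hdp_subtype = hdp_subtype %||% unique(d$hdp_subtype)),
            class = "trend_fit")
}

#' @export
print.trend_fit <- function(x, ...) {
  td <- tidy(x)
  cat(sprintf("<trend_fit> %s / %s: slope %.4f log10-units per week (95%% CI %.4f to %.4f), p = %.3g, %d studies\n",
              paste(x$protein, collapse = "+"), paste(x$hdp_subtype, collapse = "+"),
              td$slope, td$ci_low, td$ci_high, td$p, td$n_points))
  invisible(x)
}

#' @export
tidy.trend_fit <- function(x, ...) {
  sm <- summary(x$fit)$coefficients
  n <- nrow(x$data)
  df <- x$fit$df.residual
  slope <- sm["gest_week", "Estimate"]
  se <- sm["gest_week", "Std. Error"]
  tq <- if (df >= 1) qt(0.975, df) else NA_real_
  tibble(
    protein = paste(x$protein, collapse = "+"),
    hdp_subtype = paste(x$hdp_subtype, collapse = "+"),
    slope = slope, se = se,
    ci_low = slope - tq * se, ci_high = slope + tq * se,
    p = if (n >= 3 && df >= 1) 2 * pt(-abs(slope / se), df) else NA_real_,
    n_points = n,
    intercept = sm["(Intercept)", "Estimate"],
    quad_term = if (x$quadratic) sm["I(gest_week^2)", "Estimate"] else NA_real_,
    quad_p = if (x$quadratic && n >= 4) sm["I(gest_week^2)", "Pr(>|t|)"] else NA_real_
  )
}

#' @export
glance.trend_fit <- function(x, ...) {
  sm <- summary(x$fit)
  tibble(r_squared = sm$r.squared, sigma = sm$sigma,
         df_residual = x$fit$df.residual, n_points = nrow(x$data))
}

#' Plot a gestational trend fit
#'
#' Week vs log10 mean ratio, point size proportional to study sample size,
#' with the weighted regression line.
#'
#' @param object A `trend_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.trend_fit <- function(object, ...) {
  d <- object$data
  ggplot(d, aes(x = .data$gest_week, y = .data$log_ratio)) +
    geom_hline(yintercept = 0, linetype = "dashed", colour = "grey60") +
    geom_point(aes(size = .data$weight), alpha = 0.6) +
    geom_smooth(aes(weight = .data$weight), method = "lm",
                formula = if (object$quadratic) y ~ x + I(x^2) else y ~ x,
                se = TRUE, colour = "#b2182b") +
    scale_size_area(name = "study n") +
    labs(x = "gestational week at sampling",
         y = expression(log[10] ~ "(mean HDP / mean control)"),
         title = paste(object$protein, collapse = "+"),
         subtitle = paste(object$hdp_subtype, collapse = "+")) +
    theme_minimal()
}

#' Write trend fits as TSV
#'
#' @param fits A `trend_fit` or list of them.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trend_fits <- function(fits, path) {
  if (inherits(fits, "trend_fit")) fits <- list(fits)
  readr::write_tsv(bind_rows(lapply(fits, tidy)), path, progress = FALSE)
  invisible(path)
}
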