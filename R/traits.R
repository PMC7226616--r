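#' Stable-isotope delta notation
#'
#' `delta = (ratio_sample / ratio_standard - 1) * 1000`, in per mil. Used
#' for carbon isotope composition (delta 13C) relative to an international
#' standard; higher (less negative) leaf or grain delta 13C indicates
#' time-integrated water stress.
#'
#' @param ratio_sample,ratio_standard Positive isotope ratios (vectorised).
#' @return Delta value(s) in per mil.
#' @examples
#' delta_notation(0.011237, 0.011237)        # 0
#' delta_notation(1.001 * 0.011237, 0.011237) # +1
#' @export
delta_notation <- function(ratio_sample, ratio_standard) {
  if (any(ratio_sample <= 0) || any(ratio_standard <= 0)) {
    abort("Isotope ratios must be > 0.")
  }
  (ratio_sample / ratio_standard - 1) * 1000
}

#' Derive standard agronomic traits per plot
#'
#' Adds grain nitrogen yield `GNY = GY * grain_pctN / 100` (same area units
#' as `GY`), harvest index `HI = GY / biomass`, and thousand-kernel weight
#' `TKW = 1000 * grain_mass / grain_count` (g). Zero biomass or grain count
#' gives `NA` for the affected trait rather than an error.
#'
#' @param plot_records A data frame with columns `GY`, `biomass`,
#'   `grain_pctN`, and optionally `grain_mass` and `grain_count` (per-plot
#'   totals for the TKW sample).
#' @return The input as a tibble with `GNY`, `HI` and (when computable)
#'   `TKW` columns appended.
#' @examples
#' derived_traits(data.frame(GY = 5, biomass = 12, grain_pctN = 2,
#'                           grain_mass = 20, grain_count = 500))
#' @export
derived_traits <- function(plot_records) {
  d <- tibble::as_tibble(plot_records)
  need <- c("GY", "biomass", "grain_pctN")
  miss <- setdiff(need, names(d))
  if (length(miss) > 0) {
    abort(sprintf("Missing column(s): %s.", paste(miss, collapse = ", ")))
  }
  d$GNY <- d$GY * d$grain_pctN / 100
  d$HI <- ifelse(d$biomass == 0, NA_real_, d$GY / d$biomass)
  if (all(c("grain_mass", "grain_count") %in% names(d))) {
    d$TKW <- ifelse(d$grain_count == 0, NA_real_,
                    1000 * d$grain_mass / d$grain_count)
  }
  d
}

#' Normalized-difference index of two reflectance bands
#'
#' `(a - b) / (a + b)`, in `[-1, 1]`; `NA` when both bands are zero.
#'
#' @param reflectance_a,reflectance_b Nonnegative reflectances (vectorised).
#' @return The index value(s).
#' @examples
#' normalized_difference(0.6, 0.3)
#' @export
normalized_difference <- function(reflectance_a, reflectance_b) {
  if (any(reflectance_a < 0, na.rm = TRUE) ||
      any(reflectance_b < 0, na.rm = TRUE)) {
    abort("Reflectances must be >= 0.")
  }
  s <- reflectance_a + reflectance_b
  ifelse(s == 0, NA_real_, (reflectance_a - reflectance_b) / s)
}

#' @rdname normalized_difference
#' @details The named wrappers bind the band pairs conventional in the
#'   literature for water-status indices, as configuration rather than
#'   constants: `ndwi()` near-infrared (857 nm) vs 1241 nm, `nwi()` 970 nm vs
#'   900 nm, `ndmi()` 819 nm vs 1649 nm. Pass reflectances already extracted
#'   at those wavelengths.
#' @param nir,swir,r970,r900 Reflectances at the respective bands.
#' @export
ndwi <- function(nir, swir) normalized_difference(nir, swir)

#' @rdname normalized_difference
#' @export
nwi <- function(r970, r900) normalized_difference(r970, r900)

#' @rdname normalized_difference
#' @export
ndmi <- function(nir, swir) normalized_difference(nir, swir)

#' Metabolite-trait correlations with FDR control
#'
#' Pearson (or Spearman) correlation of every metabolite column against every
#' trait column, with the two-sided t-approximation p-value and
#' Benjamini-Hochberg q-values computed across all pairs. Constant columns
#' yield `NA` correlations (flagged, not errors).
#'
#' @param matrix A complete [metab_matrix()] (or numeric matrix).
#' @param trait_table Data frame of numeric traits aligned with the samples
#'   (a `sample_id` column, if present, is used to align and then dropped).
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return A tibble `metabolite`, `trait`, `r`, `p`, `q`, `n`.
#' @export
metabolite_trait_correlations <- function(matrix, trait_table,
                                          method = c("pearson", "spearman")) {
  method <- match.arg(method)
  X <- if (inherits(matrix, "metab_matrix")) {
    if (any(matrix$mask)) abort("`matrix` must be complete; impute first.")
    matrix$values
  } else as.matrix(matrix)
  tt <- tibble::as_tibble(trait_table)
  if ("sample_id" %in% names(tt)) {
    if (!is.null(rownames(X)) && all(rownames(X) %in% tt$sample_id)) {
      tt <- tt[match(rownames(X), tt$sample_id), ]
    }
    tt$sample_id <- NULL
  }
  tt <- tt[vapply(tt, is.numeric, TRUE)]
  if (nrow(tt) != nrow(X)) abort("Trait table must align with the samples.")
  pairs <- tidyr::expand_grid(metabolite = colnames(X), trait = names(tt))
  res <- purrr::pmap_dfr(pairs, function(metabolite, trait) {
    x <- X[, metabolite]; y <- tt[[trait]]
    ok <- stats::complete.cases(x, y)
    n_ok <- sum(ok)
    if (n_ok < 4 || stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) {
      return(tibble::tibble(metabolite = metabolite, trait = trait,
                            r = NA_real_, p = NA_real_, n = n_ok))
    }
    ct <- stats::cor.test(x[ok], y[ok], method = method, exact = FALSE)
    tibble::tibble(metabolite = metabolite, trait = trait,
                   r = unname(ct$estimate), p = ct$p.value, n = n_ok)
  })
  res$q <- stats::p.adjust(res$p, method = "BH")
  dplyr::relocate(res, "metabolite", "trait", "r", "p", "q", "n")
}

#' Per-metabolite factorial ANOVA
#'
#' Fits, for every metabolite, a fixed-effects linear model with the
#' requested design factors and all their two-way interactions, and tests
#' each term with Type-II sums of squares (robust to mild imbalance; under a
#' balanced design Type-II equals Type-I). Factors with a single level in the
#' data are dropped with a warning. p-values are Benjamini-Hochberg adjusted
#' across metabolites within each term.
#'
#' @param matrix A complete [metab_matrix()].
#' @param design Optional design tibble (defaults to the matrix's own).
#' @param factors Design columns to use (default organ, condition, genotype,
#'   stage, intersected with what the design offers).
#' @return A tibble `metabolite`, `term`, `df`, `F`, `p`, `q`.
#' @export
factorial_anova <- function(matrix, design = NULL,
                            factors = c("organ", "condition", "genotype",
                                        "stage")) {
  stopifnot(inherits(matrix, "metab_matrix"))
  if (any(matrix$mask)) abort("`matrix` must be complete; impute first.")
  design <- tibble::as_tibble(design %||% matrix$design)
  factors <- intersect(factors, names(design))
  if (length(factors) == 0) abort("None of the requested factors are in the design.")
  n_lev <- vapply(factors, function(f) length(unique(design[[f]])), 1L)
  if (any(n_lev < 2)) {
    warn(sprintf("Dropping single-level factor(s): %s.",
                 paste(factors[n_lev < 2], collapse = ", ")))
    factors <- factors[n_lev >= 2]
  }
  if (length(factors) == 0) abort("No factor has at least two levels.")
  rhs <- if (length(factors) == 1) factors else {
    paste0("(", paste(factors, collapse = " + "), ")^2")
  }
  base <- as.data.frame(lapply(design[factors], factor))
  out <- purrr::map_dfr(colnames(matrix$values), function(met) {
    dat <- base
    dat$.y <- matrix$values[, met]
    fit <- lm(stats::as.formula(paste(".y ~", rhs)), data = dat)
    a <- car::Anova(fit, type = 2)
    terms_keep <- setdiff(rownames(a), "Residuals")
    tibble::tibble(metabolite = met, term = terms_keep,
                   df = a[terms_keep, "Df"],
                   F = a[terms_keep, "F value"],
                   p = a[terms_keep, "Pr(>F)"])
  })
  out <- dplyr::group_by(out, .data$term)
  out <- dplyr::mutate(out, q = stats::p.adjust(.data$p, method = "BH"))
  dplyr::ungroup(out)
}
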