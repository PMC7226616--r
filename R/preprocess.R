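#' Remove metabolites with too much missing data
#'
#' A metabolite is removed when its missing fraction over all samples is
#' strictly greater than `max_missing_frac` (so exactly 10 percent missing is
#' kept under the default). Sample rows are untouched.
#'
#' @param matrix A [metab_matrix()].
#' @param max_missing_frac Threshold in `[0, 1)`; default 0.10.
#' @return The filtered matrix. The accumulated preprocessing report is
#'   attached as attribute `"preprocess_report"`; see [preprocess_report()].
#' @examples
#' d <- build_design(2, 1, 2, organs = "glume", stages = "anthesis")
#' sim <- simulate_metabolome(d, n_metabolites = 6, n_blocks = 1, seed = 1,
#'                            missing_rates = c(0, 0, 0, 0, 0.5, 0.5))
#' m <- inject_missing(sim$matrix, sim$truth$missing_rates, seed = 2)
#' f <- filter_by_missingness(m)
#' preprocess_report(f)$removed_metabolites
#' @export
filter_by_missingness <- function(matrix, max_missing_frac = 0.10) {
  stopifnot(inherits(matrix, "metab_matrix"))
  if (max_missing_frac < 0 || max_missing_frac >= 1) {
    abort("`max_missing_frac` must be in [0, 1).")
  }
  if (nrow(matrix$values) == 0 || ncol(matrix$values) == 0) {
    abort("Cannot filter an empty matrix.")
  }
  frac <- colMeans(matrix$mask)
  keep <- frac <= max_missing_frac
  removed <- colnames(matrix$values)[!keep]
  out <- metab_matrix(matrix$values[, keep, drop = FALSE],
                      mask = matrix$mask[, keep, drop = FALSE],
                      design = matrix$design, scale = matrix$scale)
  add_report(out, matrix, list(removed_metabolites = removed,
                               max_missing_frac = max_missing_frac))
}

#' K-nearest-neighbour imputation of missing intensities
#'
#' For every sample with missing cells, the `k` nearest samples supply an
#' inverse-distance-weighted mean of their observed values for each missing
#' metabolite. Distances are Euclidean over the metabolites observed in both
#' samples, computed on columns standardised to unit variance (over observed
#' values) and rescaled by the number of shared observed metabolites, the
#' conventional Troyanskaya-style choice. Weights are `1/(distance + 1e-9)`.
#' Observed cells are returned bit-identical; the output mask is empty.
#'
#' If fewer than `k` candidate neighbours exist, all available ones are used
#' with a warning; a missing cell observed by none of the neighbours falls
#' back to the column median with a warning.
#'
#' @param matrix A [metab_matrix()] whose columns pass the missingness filter.
#' @param k Number of neighbours (default 10, the conventional default).
#' @return A complete matrix; report fields `k_used` and `imputed_cell_count`
#'   are added to the `"preprocess_report"` attribute.
#' @export
knn_impute <- function(matrix, k = 10) {
  stopifnot(inherits(matrix, "metab_matrix"))
  if (k < 1) abort("`k` must be >= 1.")
  v <- observed_values(matrix)
  obs <- !is.na(v)
  if (any(rowSums(obs) == 0)) {
    abort("Every sample must have at least one observed value.")
  }
  n <- nrow(v)
  out <- v

  # standardised view used only for distances
  ctr <- colMeans(v, na.rm = TRUE)
  scl <- apply(v, 2, stats::sd, na.rm = TRUE)
  scl[!is.finite(scl) | scl == 0] <- 1
  vs <- sweep(sweep(v, 2, ctr), 2, scl, "/")

  col_median <- apply(v, 2, stats::median, na.rm = TRUE)
  need <- which(rowSums(!obs) > 0)
  warned_k <- FALSE; warned_median <- FALSE
  for (i in need) {
    d <- rep(Inf, n)
    oi <- obs[i, ]
    for (ii in seq_len(n)) {
      if (ii == i) next
      shared <- oi & obs[ii, ]
      ns <- sum(shared)
      if (ns == 0) next
      d[ii] <- sqrt(sum((vs[i, shared] - vs[ii, shared])^2) / ns)
    }
    cand <- which(is.finite(d))
    if (length(cand) == 0) {
      miss_j <- which(!oi)
      out[i, miss_j] <- col_median[miss_j]
      if (!warned_median) {
        warn("Some cells had no usable neighbours; column-median fallback used.")
        warned_median <- TRUE
      }
      next
    }
    if (k > length(cand) && !warned_k) {
      warn(sprintf(
        "k = %d exceeds the %d available neighbours; using all of them.",
        k, length(cand)))
      warned_k <- TRUE
    }
    nb <- cand[order(d[cand])][seq_len(min(k, length(cand)))]
    for (j in which(!oi)) {
      nb_j <- nb[obs[nb, j]]
      if (length(nb_j) == 0) {
        out[i, j] <- col_median[j]
        if (!warned_median) {
          warn("Some cells had no neighbour observing that metabolite; column-median fallback used.")
          warned_median <- TRUE
        }
      } else {
        w <- 1 / (d[nb_j] + 1e-9)
        out[i, j] <- sum(w * v[nb_j, j]) / sum(w)
      }
    }
  }
  res <- metab_matrix(out, design = matrix$design, scale = matrix$scale)
  add_report(res, matrix,
             list(k_used = as.integer(k),
                  imputed_cell_count = sum(!obs)))
}

#' Log2-transform a raw-scale matrix
#'
#' @param matrix A raw-scale [metab_matrix()] with strictly positive values.
#' @return The matrix on the log2 scale (scale flag updated).
#' @export
log2_transform <- function(matrix) {
  stopifnot(inherits(matrix, "metab_matrix"))
  if (matrix$scale != "raw") abort("`matrix` is already on the log2 scale.")
  bad <- which(!is.na(matrix$values) & matrix$values <= 0, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    abort(sprintf("Nonpositive value at sample '%s', metabolite '%s'.",
                  rownames(matrix$values)[bad[1, 1]],
                  colnames(matrix$values)[bad[1, 2]]))
  }
  res <- metab_matrix(log2(matrix$values), mask = matrix$mask,
                      design = matrix$design, scale = "log2")
  add_report(res, matrix, list(scale_out = "log2"))
}

#' Standardise metabolite columns to mean zero, unit variance
#'
#' Uses the `n - 1` standard-deviation denominator. The returned matrix
#' carries `"center"` and `"scale"` attributes sufficient to invert the
#' transform and to de-standardise fitted coefficients
#' (`beta_raw = beta_std / scale`).
#'
#' @param matrix A complete [metab_matrix()] or plain numeric matrix.
#' @return A numeric matrix with attributes `center` and `scale`.
#' @examples
#' standardize(cbind(a = c(1, 2, 3)))
#' @export
standardize <- function(matrix) {
  v <- if (inherits(matrix, "metab_matrix")) {
    if (any(matrix$mask)) abort("`matrix` must be complete to standardise.")
    matrix$values
  } else {
    as.matrix(matrix)
  }
  ctr <- colMeans(v)
  scl <- apply(v, 2, stats::sd)
  zero <- which(scl == 0 | !is.finite(scl))
  if (length(zero) > 0) {
    abort(sprintf("Zero-variance column: %s.",
                  paste(colnames(v)[zero] %||% zero, collapse = ", ")))
  }
  out <- sweep(sweep(v, 2, ctr), 2, scl, "/")
  attr(out, "center") <- stats::setNames(ctr, colnames(v))
  attr(out, "scale") <- stats::setNames(scl, colnames(v))
  out
}

#' Retrieve the accumulated preprocessing report
#'
#' @param matrix A [metab_matrix()] that has passed through one or more
#'   preprocessing steps.
#' @return A list with any of `removed_metabolites`, `imputed_cell_count`,
#'   `k_used`, `scale_out`.
#' @export
preprocess_report <- function(matrix) {
  attr(matrix, "preprocess_report") %||% list()
}

# merge new report fields onto the report carried by `from`
add_report <- function(x, from, fields) {
  rep0 <- attr(from, "preprocess_report") %||% list()
  attr(x, "preprocess_report") <- utils::modifyList(rep0, fields)
  x
}
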