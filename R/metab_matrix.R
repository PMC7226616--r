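#' Construct a metabolome matrix
#'
#' The central container of the package: a samples-by-metabolites intensity
#' matrix with an explicit missingness mask, the sample design annotations,
#' and a scale flag. In simulated data the true values under the mask are
#' retained so imputation accuracy can be scored; code treating the matrix as
#' observed data must consult `mask`, never peek below it.
#'
#' @param values Numeric matrix, samples x metabolites. Row names are sample
#'   ids, column names metabolite ids (supplied defaults are generated).
#' @param mask Logical matrix of the same shape; `TRUE` marks an unobserved
#'   cell. Default: all observed.
#' @param design A data frame of per-sample annotations with a `sample_id`
#'   column aligned to the rows of `values`.
#' @param scale Either `"raw"` or `"log2"`; recorded, never silently changed.
#' @return An object of class `metab_matrix`.
#' @examples
#' m <- metab_matrix(matrix(2^rnorm(12, 10), 4, 3))
#' dim(m)
#' @export
metab_matrix <- function(values, mask = NULL, design = NULL, scale = "raw") {
  values <- as.matrix(values)
  if (!is.numeric(values)) abort("`values` must be a numeric matrix.")
  n <- nrow(values); p <- ncol(values)
  if (is.null(rownames(values))) rownames(values) <- sprintf("s%03d", seq_len(n))
  if (is.null(colnames(values))) colnames(values) <- sprintf("m%03d", seq_len(p))
  if (is.null(mask)) {
    mask <- matrix(FALSE, n, p, dimnames = dimnames(values))
  }
  mask <- as.matrix(mask)
  if (!is.logical(mask) || !identical(dim(mask), dim(values))) {
    abort("`mask` must be a logical matrix with the same shape as `values`.")
  }
  dimnames(mask) <- dimnames(values)
  if (is.null(design)) {
    design <- tibble::tibble(sample_id = rownames(values))
  }
  design <- tibble::as_tibble(design)
  if (!"sample_id" %in% names(design)) {
    abort("`design` must contain a `sample_id` column.")
  }
  if (nrow(design) != n || !identical(as.character(design$sample_id),
                                      rownames(values))) {
    abort("`design` rows must align with the rows of `values` (by sample_id).")
  }
  scale <- match.arg(scale, c("raw", "log2"))
  if (any(!is.finite(values[!mask]))) {
    abort("`values` must be finite wherever `mask` is FALSE.")
  }
  structure(
    list(values = values, mask = mask, design = design, scale = scale),
    class = "metab_matrix"
  )
}

#' @export
dim.metab_matrix <- function(x) dim(x$values)

#' @export
print.metab_matrix <- function(x, ...) {
  cat(sprintf(
    "<metab_matrix> %d samples x %d metabolites (%s scale), %d masked cells\n",
    nrow(x$values), ncol(x$values), x$scale, sum(x$mask)
  ))
  invisible(x)
}

#' Observed values of a metabolome matrix
#'
#' Returns the intensity matrix with masked cells set to `NA`, the view every
#' downstream computation on observed data must use.
#'
#' @param x A [metab_matrix()].
#' @return A numeric matrix with `NA` at masked cells.
#' @export
observed_values <- function(x) {
  stopifnot(inherits(x, "metab_matrix"))
  v <- x$values
  v[x$mask] <- NA_real_
  v
}

#' Long tidy view of a metabolome matrix
#'
#' @param x A [metab_matrix()].
#' @param ... Unused.
#' @return A tibble with one row per (sample, metabolite) cell: the design
#'   columns, `metabolite`, `intensity` (`NA` where masked) and `missing`.
#' @importFrom tibble as_tibble
#' @export
as_tibble.metab_matrix <- function(x, ...) {
  long <- tibble::as_tibble(observed_values(x), rownames = "sample_id") |>
    tidyr::pivot_longer(-"sample_id", names_to = "metabolite",
                        values_to = "intensity")
  miss <- tibble::as_tibble(x$mask, rownames = "sample_id") |>
    tidyr::pivot_longer(-"sample_id", names_to = "metabolite",
                        values_to = "missing")
  long$missing <- miss$missing
  dplyr::left_join(long, x$design, by = "sample_id") |>
    dplyr::relocate(dplyr::any_of(names(x$design)))
}

# replace the value matrix, keeping everything else consistent
set_values <- function(x, values, scale = x$scale, mask = x$mask) {
  metab_matrix(values, mask = mask, design = x$design, scale = scale)
}

#' Subset the samples (rows) of a metabolome matrix
#'
#' @param x A [metab_matrix()].
#' @param idx Integer or logical row index.
#' @return A [metab_matrix()] with values, mask and design subset together.
#' @examples
#' m <- metab_matrix(matrix(2^rnorm(12, 10), 4, 3))
#' dim(subset_samples(m, 1:2))
#' @export
subset_samples <- function(x, idx) {
  metab_matrix(x$values[idx, , drop = FALSE],
               mask = x$mask[idx, , drop = FALSE],
               design = x$design[idx, , drop = FALSE],
               scale = x$scale)
}
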