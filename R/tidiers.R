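#' Tidy a lasso fit
#'
#' @param x A `lasso_fit`.
#' @param ... Unused.
#' @return A tibble `term`, `estimate`, `estimate_std` (standardised scale).
#' @export
tidy.lasso_fit <- function(x, ...) {
  tibble::tibble(
    term = c("(Intercept)", names(x$beta)),
    estimate = c(x$intercept, unname(x$beta)),
    estimate_std = c(NA_real_, unname(x$beta_std))
  )
}

#' @export
glance.lasso_fit <- function(x, ...) {
  tibble::tibble(lambda = x$lambda, n_active = length(x$active_set),
                 n_iter = x$n_iter, converged = x$converged)
}

#' Tidy a stability result
#'
#' @param x A `stability_result`.
#' @param ... Unused.
#' @return The per-metabolite effects tibble (detection rate and mean
#'   effects).
#' @export
tidy.stability_result <- function(x, ...) x$effects

#' @export
glance.stability_result <- function(x, ...) x$summary

#' Tidy a refit model
#'
#' @param x A `refit_model`.
#' @param ... Unused.
#' @return A tibble `term`, `estimate`, plus each feature's variance `share`.
#' @export
tidy.refit_model <- function(x, ...) {
  est <- tibble::tibble(term = names(x$coefficients),
                        estimate = unname(x$coefficients))
  dplyr::left_join(
    est,
    dplyr::rename(x$variance_shares, term = "feature"),
    by = "term"
  )
}

#' @export
glance.refit_model <- function(x, ...) {
  tibble::tibble(subset = x$subset, n = x$n, n_features = length(x$features),
                 r2 = x$r2, adj_r2 = x$adj_r2, overall_p = x$overall_p)
}
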