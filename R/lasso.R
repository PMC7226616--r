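#' Soft-thresholding operator
#'
#' The coordinate-descent kernel: `sign(z) * max(|z| - gamma, 0)`.
#'
#' @param z Numeric vector.
#' @param gamma Nonnegative threshold.
#' @return Numeric vector of the same length.
#' @examples
#' soft_threshold(3, 1)    # 2
#' soft_threshold(-0.5, 1) # 0
#' @export
soft_threshold <- function(z, gamma) {
  if (any(gamma < 0)) abort("`gamma` must be >= 0.")
  sign(z) * pmax(abs(z) - gamma, 0)
}

#' Smallest penalty with an all-zero solution
#'
#' For the objective `(1/2n) ||y - b0 - X b||^2 + lambda ||b||_1` fitted on
#' standardised features, the null model is optimal for every
#' `lambda >= max_j |X_j . y_c| / n` (features standardised, response
#' centred); this returns that bound.
#'
#' @param X Numeric feature matrix (any scale; standardised internally).
#' @param y Numeric response.
#' @return The penalty bound (a single number, `1/(2n)` convention).
#' @export
lambda_max <- function(X, y) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n == 0) abort("`X` has no rows.")
  sx <- std_cols(X)
  yc <- y - mean(y)
  max(abs(crossprod(sx$x, yc)) / n)
}

# internal: centre/scale columns; zero-variance columns become all-zero
std_cols <- function(X) {
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  dead <- which(scl == 0 | !is.finite(scl))
  scl_safe <- scl
  scl_safe[dead] <- 1
  x <- sweep(sweep(X, 2, ctr), 2, scl_safe, "/")
  if (length(dead) > 0) x[, dead] <- 0
  list(x = x, center = ctr, scale = scl_safe, dead = dead)
}

#' Fit the lasso at a single penalty
#'
#' Minimises `(1/2n) ||y - b0 - X b||^2 + lambda ||b||_1` by cyclic
#' coordinate descent on standardised features (compiled kernel, warm-startable,
#' cyclic order for reproducibility). The intercept is never penalised:
#' `b0 = mean(y) - mean(X) . beta`. Coefficients are reported on both the
#' standardised and the original scale; zero-variance columns get coefficient
#' zero.
#'
#' @param X Numeric matrix, samples x features (complete).
#' @param y Numeric response, length `nrow(X)`.
#' @param lambda Penalty, `>= 0`, in the `1/(2n)` convention.
#' @param tol Convergence tolerance on the largest coefficient update per
#'   sweep (default 1e-8).
#' @param max_iter Sweep cap (default 1e5); non-convergence returns the fit
#'   with `converged = FALSE` and a warning.
#' @param warm_start Optional standardised-scale coefficient vector to start
#'   from.
#' @return A `lasso_fit`: `intercept`, `beta` (original scale, named),
#'   `beta_std`, `lambda`, `n_iter`, `converged`, `active_set`, and the
#'   standardisation record.
#' @examples
#' X <- matrix(rnorm(40), 20, 2, dimnames = list(NULL, c("a", "b")))
#' y <- X[, 1] + rnorm(20, 0, 0.1)
#' fit_lasso(X, y, lambda = 0.05)$active_set
#' @export
fit_lasso <- function(X, y, lambda, tol = 1e-8, max_iter = 1e5,
                      warm_start = NULL) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  if (n < 2) abort("Need at least two rows.")
  if (length(y) != n) abort("`y` must align with the rows of `X`.")
  if (lambda < 0) abort("`lambda` must be >= 0.")
  if (is.null(colnames(X))) colnames(X) <- sprintf("x%d", seq_len(p))
  sx <- std_cols(X)
  yc <- y - mean(y)
  xs <- sx$x
  res <- cd_lasso_path(xs, yc, lambda, tol, as.integer(max_iter),
                       beta_init = warm_start)
  beta_std <- drop(res$beta)
  if (!res$converged[1]) {
    warn(sprintf("Coordinate descent did not converge in %d sweeps.",
                 as.integer(max_iter)))
  }
  names(beta_std) <- colnames(X)
  beta_raw <- beta_std / sx$scale
  beta_raw[sx$dead] <- 0
  intercept <- mean(y) - sum(sx$center * beta_raw)
  structure(
    list(intercept = intercept, beta = beta_raw, beta_std = beta_std,
         lambda = lambda, n_iter = res$n_iter[1],
         converged = res$converged[1],
         active_set = colnames(X)[beta_std != 0],
         center = sx$center, scale = sx$scale, tol = tol,
         convention = "1/(2n)"),
    class = "lasso_fit"
  )
}

#' @export
print.lasso_fit <- function(x, ...) {
  cat(sprintf("<lasso_fit> lambda %.4g, %d/%d active, %sconverged (%d sweeps)\n",
              x$lambda, length(x$active_set), length(x$beta),
              if (x$converged) "" else "NOT ", x$n_iter))
  invisible(x)
}

#' @export
predict.lasso_fit <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  drop(newdata %*% object$beta) + object$intercept
}

#' @export
coef.lasso_fit <- function(object, ...) {
  c("(Intercept)" = object$intercept, object$beta)
}

# internal: whole path with warm starts; returns raw-scale coefs + intercepts.
# dev_ratio_stop < 1 truncates the path once the training fit saturates
# (glmnet-style); `n_fitted` reports how many lambdas were actually solved.
fit_lasso_path <- function(X, y, lambdas, tol = 1e-8, max_iter = 1e5,
                           dev_ratio_stop = 2) {
  sx <- std_cols(X)
  yc <- y - mean(y)
  res <- cd_lasso_path(sx$x, yc, lambdas, tol, as.integer(max_iter),
                       dev_ratio_stop = dev_ratio_stop)
  beta_raw <- res$beta / sx$scale
  if (length(sx$dead) > 0) beta_raw[sx$dead, ] <- 0
  intercepts <- mean(y) - drop(crossprod(beta_raw, sx$center))
  list(lambdas = lambdas, beta = beta_raw, beta_std = res$beta,
       intercepts = intercepts, converged = res$converged,
       n_iter = res$n_iter, n_fitted = res$n_fitted)
}

#' Karush-Kuhn-Tucker optimality certificate for a lasso fit
#'
#' On the standardised features `Xs` with centred response and residual
#' `r = y_c - Xs b`, a lasso solution satisfies
#' `Xs_j . r / n = lambda * sign(b_j)` for active `j` and
#' `|Xs_j . r / n| <= lambda` for inactive `j`. Returns the largest violation
#' of these conditions; converged fits should be within `10 * tol`.
#'
#' @param fit A [fit_lasso()] result.
#' @param X,y The data the fit was computed on.
#' @return Largest KKT violation (a single nonnegative number).
#' @export
kkt_violation <- function(fit, X, y) {
  stopifnot(inherits(fit, "lasso_fit"))
  X <- as.matrix(X)
  n <- nrow(X)
  xs <- sweep(sweep(X, 2, fit$center), 2, fit$scale, "/")
  dead <- apply(X, 2, stats::sd) == 0
  if (any(dead)) xs[, dead] <- 0
  yc <- y - mean(y)
  r <- yc - drop(xs %*% fit$beta_std)
  g <- drop(crossprod(xs, r)) / n
  active <- fit$beta_std != 0
  v_active <- if (any(active)) {
    max(abs(g[active] - fit$lambda * sign(fit$beta_std[active])))
  } else 0
  v_inactive <- if (any(!active)) max(pmax(abs(g[!active]) - fit$lambda, 0)) else 0
  max(v_active, v_inactive)
}

#' Select the lasso penalty by inner cross-validation
#'
#' Builds a log-spaced grid of `n_grid` penalties from `lambda_max(X, y)`
#' down to `eps` times it, estimates validation MSE by `inner_folds`-fold
#' cross-validation (each fold's path is fitted with standardisation inside
#' the fold's training rows, so no information leaks), and picks either the
#' MSE-minimising penalty (`rule = "min"`, ties to the largest penalty) or
#' the largest penalty within one standard error of it (`rule = "1se"`).
#' The returned fit is refit on all rows at the selected penalty.
#'
#' @param X,y Data (complete matrix and aligned response).
#' @param n_grid Grid size (default 100).
#' @param eps Grid floor as a fraction of `lambda_max` (default 1e-3).
#' @param inner_folds Folds (default 5).
#' @param rule `"min"` (default) or `"1se"`.
#' @param seed Integer seed for the fold assignment.
#' @param tol,max_iter Passed to the coordinate-descent kernel for the final
#'   fit at the selected penalty.
#' @param path_tol Coefficient-update tolerance for the inner-fold paths
#'   (selection only; default 1e-5 — far below any coefficient scale that
#'   could alter the MSE ranking, and much faster deep in the path).
#' @param dev_ratio_stop Fold paths stop early once the training fit reaches
#'   this deviance ratio (default 0.999); penalties beyond the shortest
#'   fitted fold path are excluded from selection, as in saturated-path
#'   truncation.
#' @return A list: `lambda` (selected), `fit` (a `lasso_fit` on all rows),
#'   `cv` (tibble of per-penalty mean and SE of validation MSE), `rule`.
#' @export
select_lambda_cv <- function(X, y, n_grid = 100, eps = 1e-3, inner_folds = 5,
                             rule = c("min", "1se"), seed = 1,
                             tol = 1e-8, max_iter = 1e5,
                             path_tol = 1e-5, dev_ratio_stop = 0.999) {
  rule <- match.arg(rule)
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < inner_folds) abort("Need at least `inner_folds` rows.")
  lmax <- lambda_max(X, y)
  if (lmax <= 0) {
    fit <- fit_lasso(X, y, 0, tol = tol, max_iter = max_iter)
    return(list(lambda = 0, fit = fit, cv = tibble::tibble(), rule = rule))
  }
  lambdas <- exp(seq(log(lmax), log(eps * lmax), length.out = n_grid))

  folds <- with_substream(seed, "inner_cv", sample(rep_len(seq_len(inner_folds), n)))
  if (min(table(folds)) < 2) abort("An inner fold has fewer than 2 rows.")
  mse <- matrix(NA_real_, inner_folds, n_grid)
  n_common <- n_grid
  for (f in seq_len(inner_folds)) {
    tr <- folds != f
    path <- fit_lasso_path(X[tr, , drop = FALSE], y[tr], lambdas,
                           tol = max(tol, path_tol), max_iter = max_iter,
                           dev_ratio_stop = dev_ratio_stop)
    pred <- X[!tr, , drop = FALSE] %*% path$beta +
      matrix(path$intercepts, sum(!tr), n_grid, byrow = TRUE)
    mse[f, ] <- colMeans((pred - y[!tr])^2)
    n_common <- min(n_common, path$n_fitted)
  }
  mse <- mse[, seq_len(n_common), drop = FALSE]
  lambdas <- lambdas[seq_len(n_common)]
  m <- colMeans(mse)
  se <- apply(mse, 2, stats::sd) / sqrt(inner_folds)
  i_min <- which.min(m)              # grid is decreasing: first win = largest
  i_sel <- if (rule == "1se") {
    which(m <= m[i_min] + se[i_min])[1]
  } else i_min
  lambda_star <- lambdas[i_sel]
  fit <- fit_lasso(X, y, lambda_star, tol = tol, max_iter = max_iter)
  list(lambda = lambda_star, fit = fit,
       cv = tibble::tibble(lambda = lambdas, mse = m, se = se),
       rule = rule)
}
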