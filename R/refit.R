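#' Select metabolites by detection rate
#'
#' Returns the metabolites whose detection rate meets the threshold
#' (inclusive, "at least 70 percent" under the default), ordered by
#' descending detection rate and then descending absolute mean effect.
#'
#' @param stability_result A [run_stability()] result.
#' @param threshold Detection-rate threshold in (0, 1] (default 0.70).
#' @return Character vector of metabolite labels (possibly empty, with a
#'   warning — the refit then becomes intercept-only).
#' @export
select_by_dr <- function(stability_result, threshold = 0.70) {
  stopifnot(inherits(stability_result, "stability_result"))
  if (threshold <= 0 || threshold > 1) abort("`threshold` must be in (0, 1].")
  eff <- stability_result$effects
  sel <- eff[eff$detection_rate >= threshold, ]
  sel <- sel[order(-sel$detection_rate, -abs(sel$mean_effect)), ]
  if (nrow(sel) == 0) {
    warn(sprintf("No metabolite reaches detection rate %.2f; returning an empty set.",
                 threshold))
  }
  sel$metabolite
}

#' Multiple-regression refit on detection-rate-selected metabolites
#'
#' Ordinary least squares of the response on the selected metabolites over
#' the whole dataset or a growing-condition subset (the feature set is the
#' globally selected one; coefficients are re-estimated per subset). Reports
#' the adjusted R-squared, the overall F-test p-value, the coefficients, and
#' sequential (Type-I, selection-order) variance shares.
#'
#' Rank-deficient designs drop the later-ordered collinear features with a
#' warning.
#'
#' @param matrix A complete [metab_matrix()] (or plain matrix; then only
#'   `subset = "all"` is available).
#' @param y Response aligned with the matrix rows.
#' @param features Metabolite labels, normally from [select_by_dr()] (their
#'   order defines the sequential variance decomposition).
#' @param subset `"all"` (default), `"WS"` or `"HY"`.
#' @return A `refit_model`: `features`, `coefficients` (with intercept),
#'   `r2`, `adj_r2`, `overall_p`, `n`, `subset`, `variance_shares` (tibble),
#'   and the design data used (for [partition_variance()]).
#' @export
fit_refit <- function(matrix, y, features, subset = c("all", "WS", "HY")) {
  subset <- match.arg(subset)
  if (inherits(matrix, "metab_matrix")) {
    if (any(matrix$mask)) abort("`matrix` must be complete; impute first.")
    X <- matrix$values
    cond <- if ("condition" %in% names(matrix$design)) {
      matrix$design$condition
    } else NULL
  } else {
    X <- as.matrix(matrix)
    cond <- NULL
  }
  if (length(y) != nrow(X)) abort("`y` must align with the rows of `matrix`.")
  rows <- if (subset == "all") seq_len(nrow(X)) else {
    if (is.null(cond)) abort("Condition subsets require design annotations.")
    which(cond == subset)
  }
  features <- as.character(features)
  missing_feat <- setdiff(features, colnames(X))
  if (length(missing_feat) > 0) {
    abort(sprintf("Unknown feature(s): %s.", paste(missing_feat, collapse = ", ")))
  }
  if (length(features) >= length(rows) - 1) {
    abort("Need |features| < n - 1 rows in the requested subset.")
  }
  Xs <- X[rows, features, drop = FALSE]
  ys <- y[rows]

  if (length(features) == 0) {
    fit <- lm(ys ~ 1)
    mod <- list(features = character(), coefficients = coef(fit),
                r2 = 0, adj_r2 = NA_real_, overall_p = NA_real_,
                n = length(rows), subset = subset,
                data = list(X = Xs, y = ys))
    mod$variance_shares <- tibble::tibble(feature = character(),
                                          share = numeric(),
                                          method = character())
    return(structure(mod, class = "refit_model"))
  }

  df <- data.frame(.y = ys, Xs, check.names = FALSE)
  form <- stats::as.formula(paste0(".y ~ ", paste0("`", features, "`",
                                                   collapse = " + ")))
  fit <- lm(form, data = df)
  dropped <- names(coef(fit))[is.na(coef(fit))]
  if (length(dropped) > 0) {
    dropped <- gsub("`", "", dropped)
    warn(sprintf("Dropping collinear feature(s): %s.",
                 paste(dropped, collapse = ", ")))
    features <- setdiff(features, dropped)
    return(fit_refit(matrix, y, features, subset))
  }
  sm <- summary(fit)
  overall_p <- if (!is.null(sm$fstatistic)) {
    unname(stats::pf(sm$fstatistic[1], sm$fstatistic[2], sm$fstatistic[3],
                     lower.tail = FALSE))
  } else NA_real_
  coefs <- coef(fit)
  names(coefs) <- gsub("`", "", names(coefs))
  mod <- structure(
    list(features = features, coefficients = coefs,
         r2 = sm$r.squared, adj_r2 = sm$adj.r.squared, overall_p = overall_p,
         n = length(rows), subset = subset,
         data = list(X = Xs[, features, drop = FALSE], y = ys)),
    class = "refit_model"
  )
  mod$variance_shares <- partition_variance(mod, method = "sequential_dr")
  mod
}

#' @export
print.refit_model <- function(x, ...) {
  cat(sprintf(
    "<refit_model> subset %s: %d features, n = %d, Adj-R2 %.3f, overall p %.3g\n",
    x$subset, length(x$features), x$n, x$adj_r2, x$overall_p))
  invisible(x)
}

#' Partition response variance across refit features
#'
#' `"sequential_dr"` enters the features in their selection order and assigns
#' each its incremental R-squared (Type-I); the shares telescope to the model
#' R-squared exactly. `"lmg"` averages each feature's incremental R-squared
#' over predictor orderings — exactly over all orderings for up to 10
#' features, over `n_orderings` sampled orderings for 11–20 (default 1000),
#' and refuses more than 20 features unless `n_orderings` is given.
#'
#' @param refit_model A [fit_refit()] result with at least one feature.
#' @param method `"sequential_dr"` (default) or `"lmg"`.
#' @param n_orderings Number of sampled orderings for large LMG problems.
#' @param seed Seed for ordering subsampling.
#' @return A tibble `feature`, `share`, `method`; shares sum to the model
#'   R-squared.
#' @export
partition_variance <- function(refit_model,
                               method = c("sequential_dr", "lmg"),
                               n_orderings = NULL, seed = 1) {
  stopifnot(inherits(refit_model, "refit_model"))
  method <- match.arg(method)
  X <- refit_model$data$X
  y <- refit_model$data$y
  feats <- refit_model$features
  p <- length(feats)
  if (p < 1) abort("The refit model has no features to partition.")
  X <- X[, feats, drop = FALSE]
  sst <- sum((y - mean(y))^2)
  r2_of <- function(cols) {
    if (length(cols) == 0) return(0)
    f <- stats::lm.fit(cbind(1, X[, cols, drop = FALSE]), y)
    1 - sum(f$residuals^2) / sst
  }

  shares <- if (method == "sequential_dr") {
    prev <- 0
    out <- numeric(p)
    for (j in seq_len(p)) {
      cur <- r2_of(seq_len(j))
      out[j] <- cur - prev
      prev <- cur
    }
    out
  } else {
    if (p > 20 && is.null(n_orderings)) {
      abort("LMG with more than 20 features requires `n_orderings`.")
    }
    if (p <= 10) {
      # exact: average increments over all subsets with combinatorial weights
      n_masks <- bitwShiftL(1L, p)
      r2_mask <- numeric(n_masks)
      for (m in seq_len(n_masks) - 1L) {
        cols <- which(bitwAnd(m, bitwShiftL(1L, seq_len(p) - 1L)) != 0L)
        r2_mask[m + 1L] <- r2_of(cols)
      }
      wts <- vapply(0:(p - 1), function(k) {
        factorial(k) * factorial(p - 1 - k) / factorial(p)
      }, 1)
      out <- numeric(p)
      for (j in seq_len(p)) {
        bit_j <- bitwShiftL(1L, j - 1L)
        acc <- 0
        for (m in seq_len(n_masks) - 1L) {
          if (bitwAnd(m, bit_j) == 0L) {
            k <- sum(bitwAnd(m, bitwShiftL(1L, seq_len(p) - 1L)) != 0L)
            acc <- acc + wts[k + 1] * (r2_mask[bitwOr(m, bit_j) + 1L] -
                                         r2_mask[m + 1L])
          }
        }
        out[j] <- acc
      }
      out
    } else {
      n_ord <- n_orderings %||% 1000
      out <- numeric(p)
      with_substream(seed, "lmg_orderings", {
        for (o in seq_len(n_ord)) {
          ord <- sample(p)
          prev <- 0
          for (j in seq_len(p)) {
            cur <- r2_of(ord[seq_len(j)])
            out[ord[j]] <- out[ord[j]] + (cur - prev)
            prev <- cur
          }
        }
      })
      out / n_ord
    }
  }
  tibble::tibble(feature = feats, share = shares, method = method)
}
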