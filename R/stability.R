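#' Plan repeated train/validation splits
#'
#' Default mode draws, for each of `n_runs` runs, an independent uniform
#' random training subset of `round(train_fraction * n)` samples; the
#' remainder is the validation set. With `stratify_by`, training slots are
#' allocated across the levels of a design column by largest remainder so
#' the level proportions are preserved and the total training size is exact.
#' `mode = "kfold"` instead performs `n_runs / folds` repeats of
#' `folds`-fold cross-validation (each run trains on `folds - 1` folds), the
#' literal repeated k-fold reading of the resampling scheme.
#'
#' @param n_samples Number of samples (>= 8).
#' @param n_runs Number of runs (default 100).
#' @param train_fraction Training proportion in (0, 1) (default 0.75;
#'   ignored under `mode = "kfold"`).
#' @param seed Integer seed; the plan is deterministic given it.
#' @param stratify_by Optional vector of length `n_samples` (e.g. condition)
#'   whose level proportions each training set preserves.
#' @param mode `"random"` (default) or `"kfold"`.
#' @param folds Folds for `mode = "kfold"` (default 5; `n_runs` must be a
#'   multiple).
#' @return A `split_plan`: the settings plus `assignments`, a list of
#'   training row index vectors.
#' @examples
#' plan <- make_splits(60, n_runs = 10, seed = 1)
#' lengths(plan$assignments)[1:3]   # 45 45 45
#' @export
make_splits <- function(n_samples, n_runs = 100, train_fraction = 0.75,
                        seed = 1, stratify_by = NULL,
                        mode = c("random", "kfold"), folds = 5) {
  mode <- match.arg(mode)
  if (n_samples < 8) abort("Need at least 8 samples to resample.")
  if (train_fraction <= 0 || train_fraction >= 1) {
    abort("`train_fraction` must be in (0, 1).")
  }
  if (!is.null(stratify_by) && length(stratify_by) != n_samples) {
    abort("`stratify_by` must have one entry per sample.")
  }
  assignments <- with_substream(seed, "splits", {
    if (mode == "kfold") {
      if (n_runs %% folds != 0) {
        abort("`n_runs` must be a multiple of `folds` in kfold mode.")
      }
      out <- vector("list", n_runs)
      r <- 0
      for (rep_i in seq_len(n_runs / folds)) {
        fold_of <- sample(rep_len(seq_len(folds), n_samples))
        for (f in seq_len(folds)) {
          r <- r + 1
          out[[r]] <- sort(which(fold_of != f))
        }
      }
      out
    } else {
      n_train <- round(train_fraction * n_samples)
      if (n_train < 1 || n_train >= n_samples) {
        abort("`train_fraction` leaves an empty training or validation set.")
      }
      lapply(seq_len(n_runs), function(r) {
        if (is.null(stratify_by)) {
          sort(sample(n_samples, n_train))
        } else {
          lv <- split(seq_len(n_samples), stratify_by)
          quota <- vapply(lv, length, 1L) * train_fraction
          base <- floor(quota)
          rem <- n_train - sum(base)
          extra <- rep(0L, length(lv))
          if (rem > 0) {
            ord <- order(quota - base, decreasing = TRUE)
            extra[ord[seq_len(rem)]] <- 1L
          }
          sort(unlist(Map(function(rows, k) sample(rows, k),
                          lv, base + extra), use.names = FALSE))
        }
      })
    }
  })
  structure(
    list(n_samples = n_samples, n_runs = n_runs,
         train_fraction = if (mode == "kfold") (folds - 1) / folds
                          else train_fraction,
         seed = as.integer(seed), mode = mode,
         assignments = assignments),
    class = "split_plan"
  )
}

#' @export
print.split_plan <- function(x, ...) {
  cat(sprintf("<split_plan> %d runs, %d samples, train fraction %.2f (%s), seed %d\n",
              x$n_runs, x$n_samples, x$train_fraction, x$mode, x$seed))
  invisible(x)
}

#' Adjusted coefficient of determination
#'
#' `1 - (1 - r2) (n - 1) / (n - p - 1)` with `p` the number of fitted
#' coefficients excluding the intercept. Undefined (returns `NA`) when
#' `n <= p + 1`.
#'
#' @param r2 Raw R-squared.
#' @param n Sample size.
#' @param p Number of nonzero coefficients (intercept excluded).
#' @return The adjusted R-squared (vectorised).
#' @examples
#' adjusted_r2(0.8, 100, 5)   # 0.78936...
#' @export
adjusted_r2 <- function(r2, n, p) {
  out <- 1 - (1 - r2) * (n - 1) / (n - p - 1)
  out[n <= p + 1] <- NA_real_
  out
}

#' Run the resampling stability pipeline
#'
#' For every planned split: standardisation and penalty selection happen
#' strictly inside the training rows (inner cross-validation via
#' [select_lambda_cv()]), the lasso is refit on the whole training set at the
#' selected penalty, training statistics (R-squared, adjusted R-squared with
#' `p` = selected features, RMSE) are computed, and the held-out 25 percent
#' is predicted with the de-standardised coefficients to give the predictive
#' ability (squared Pearson correlation between predicted and observed).
#' Across runs each metabolite's detection rate (fraction of runs with a
#' nonzero coefficient) and average effect (zero-inclusive, plus the
#' zero-exclusive variant) are accumulated, and all run metrics are averaged
#' as plain means.
#'
#' A metabolite with zero variance inside a training set simply gets a zero
#' coefficient for that run (counted as not selected); a warning is raised
#' the first time this happens.
#'
#' @param matrix A complete [metab_matrix()] (or plain numeric matrix).
#' @param y Numeric response aligned with the rows.
#' @param split_plan A [make_splits()] plan (default: 100 runs at 75/25 with
#'   `seed`).
#' @param lasso_config List overriding penalty-selection settings:
#'   `n_grid` (100), `eps` (1e-3), `inner_folds` (5), `rule` ("min"),
#'   `tol` (1e-8), `max_iter` (1e5).
#' @param seed Used only when `split_plan` is missing.
#' @return A `stability_result` with `per_run` (tibble of run metrics),
#'   `effects` (tibble: metabolite, detection_rate, mean_effect,
#'   mean_effect_selected), `summary` (one-row tibble of across-run means),
#'   the plan and the configuration. [tidy()] returns `effects`; [glance()]
#'   returns `summary`.
#' @export
run_stability <- function(matrix, y, split_plan = NULL, lasso_config = list(),
                          seed = 1) {
  X <- if (inherits(matrix, "metab_matrix")) {
    if (any(matrix$mask)) abort("`matrix` must be complete; impute first.")
    matrix$values
  } else as.matrix(matrix)
  n <- nrow(X)
  if (length(y) != n) abort("`y` must align with the rows of `matrix`.")
  if (is.null(split_plan)) split_plan <- make_splits(n, seed = seed)
  stopifnot(inherits(split_plan, "split_plan"))
  if (split_plan$n_samples != n) abort("`split_plan` was made for a different n.")

  cfg <- utils::modifyList(
    list(n_grid = 100, eps = 1e-3, inner_folds = 5, rule = "min",
         tol = 1e-8, max_iter = 1e5, path_tol = 1e-5,
         dev_ratio_stop = 0.999),
    lasso_config
  )
  p <- ncol(X)
  met <- colnames(X) %||% sprintf("x%d", seq_len(p))
  n_runs <- split_plan$n_runs
  betas <- matrix(0, n_runs, p, dimnames = list(NULL, met))
  per_run <- vector("list", n_runs)
  warned_dead <- FALSE

  for (r in seq_len(n_runs)) {
    tr <- split_plan$assignments[[r]]
    va <- setdiff(seq_len(n), tr)
    Xtr <- X[tr, , drop = FALSE]; ytr <- y[tr]
    if (!warned_dead && any(apply(Xtr, 2, stats::sd) == 0)) {
      warn("Zero-variance column(s) inside a training set; they are never selected in such runs.")
      warned_dead <- TRUE
    }
    sel <- select_lambda_cv(Xtr, ytr, n_grid = cfg$n_grid, eps = cfg$eps,
                            inner_folds = cfg$inner_folds, rule = cfg$rule,
                            seed = derive_seed(split_plan$seed, paste0("run", r)),
                            tol = cfg$tol, max_iter = cfg$max_iter,
                            path_tol = cfg$path_tol,
                            dev_ratio_stop = cfg$dev_ratio_stop)
    fit <- sel$fit
    betas[r, ] <- fit$beta
    pred_tr <- predict(fit, Xtr)
    sst <- sum((ytr - mean(ytr))^2)
    r2 <- if (sst > 0) 1 - sum((ytr - pred_tr)^2) / sst else 0
    n_sel <- length(fit$active_set)
    pred_va <- predict(fit, X[va, , drop = FALSE])
    pa <- if (stats::sd(pred_va) > 0 && stats::sd(y[va]) > 0) {
      stats::cor(pred_va, y[va])^2
    } else 0
    per_run[[r]] <- tibble::tibble(
      run = r, lambda = sel$lambda, n_selected = n_sel,
      r2_train = r2,
      adj_r2_train = adjusted_r2(r2, length(tr), n_sel),
      rmse_train = sqrt(mean((ytr - pred_tr)^2)),
      predictive_ability = pa
    )
  }
  per_run <- dplyr::bind_rows(per_run)
  sel_mat <- betas != 0
  dr <- colMeans(sel_mat)
  mean_eff <- colMeans(betas)
  n_sel_runs <- colSums(sel_mat)
  mean_eff_sel <- ifelse(n_sel_runs > 0, colSums(betas) / n_sel_runs, NA_real_)
  effects <- tibble::tibble(
    metabolite = met, detection_rate = dr, mean_effect = mean_eff,
    mean_effect_selected = mean_eff_sel
  )
  summary <- tibble::tibble(
    n_runs = n_runs,
    mean_r2_train = mean(per_run$r2_train),
    mean_adj_r2_train = mean(per_run$adj_r2_train, na.rm = TRUE),
    mean_rmse_train = mean(per_run$rmse_train),
    mean_predictive_ability = mean(per_run$predictive_ability),
    mean_n_selected = mean(per_run$n_selected)
  )
  structure(
    list(per_run = per_run, effects = effects, summary = summary,
         split_plan = split_plan, config = cfg,
         scale = if (inherits(matrix, "metab_matrix")) matrix$scale else NA),
    class = "stability_result"
  )
}

#' @export
print.stability_result <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "<stability_result> %d runs | mean train R2 %.3f, Adj-R2 %.3f, RMSE %.3f | mean predictive ability %.3f | %d metabolites with DR >= 0.70\n",
    s$n_runs, s$mean_r2_train, s$mean_adj_r2_train, s$mean_rmse_train,
    s$mean_predictive_ability, sum(x$effects$detection_rate >= 0.70)))
  invisible(x)
}

#' Compare raw and log2 intensity scales
#'
#' Runs [run_stability()] on the raw matrix and on its log2 transform with
#' the same split plan, and recommends the scale with the higher mean
#' predictive ability (ties go to raw, with a warning).
#'
#' @param matrix_raw A complete raw-scale, positive [metab_matrix()].
#' @param y Response aligned with the rows.
#' @param lasso_config,seed As in [run_stability()].
#' @param split_plan Optional shared [make_splits()] plan.
#' @return A `scale_comparison`: `recommended` ("raw" or "log2") plus both
#'   `stability_result`s.
#' @export
compare_scales <- function(matrix_raw, y, split_plan = NULL,
                           lasso_config = list(), seed = 1) {
  stopifnot(inherits(matrix_raw, "metab_matrix"))
  if (matrix_raw$scale != "raw") abort("`matrix_raw` must be on the raw scale.")
  if (is.null(split_plan)) {
    split_plan <- make_splits(nrow(matrix_raw$values), seed = seed)
  }
  res_raw <- run_stability(matrix_raw, y, split_plan, lasso_config)
  res_log <- run_stability(log2_transform(matrix_raw), y, split_plan,
                           lasso_config)
  pa_raw <- res_raw$summary$mean_predictive_ability
  pa_log <- res_log$summary$mean_predictive_ability
  if (pa_raw == pa_log) {
    warn("Both scales achieve identical mean predictive ability; recommending raw.")
  }
  structure(
    list(recommended = if (pa_log > pa_raw) "log2" else "raw",
         raw = res_raw, log2 = res_log),
    class = "scale_comparison"
  )
}

#' @export
print.scale_comparison <- function(x, ...) {
  cat(sprintf(
    "<scale_comparison> recommended: %s (mean predictive ability raw %.3f vs log2 %.3f)\n",
    x$recommended, x$raw$summary$mean_predictive_ability,
    x$log2$summary$mean_predictive_ability))
  invisible(x)
}
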