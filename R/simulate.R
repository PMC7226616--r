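#' Simulate a factorial-design metabolome with known ground truth
#'
#' Generates log2-scale intensities from a multivariate normal with
#' block-exchangeable correlation (`block_rho` within contiguous metabolite
#' blocks, emulating pathway co-regulation), adds additive organ / stage /
#' condition / genotype effects, and exponentiates to a strictly positive raw
#' scale. Alongside the matrix it returns the ground truth a validation needs:
#' a sparse per-metabolite yield effect vector (`n_effects` nonzero entries,
#' equal magnitude and random sign, scaled so that the metabolite signal
#' explains `target_r2` of the metabolite-plus-noise yield variance), the
#' yield intercept and water-stress penalty, per-metabolite missingness rates,
#' and the block assignment.
#'
#' @param design A design tibble from [build_design()].
#' @param n_metabolites Number of metabolite columns (default 80).
#' @param n_blocks Number of correlation blocks (default 8).
#' @param block_rho Within-block exchangeable correlation in `[0, 1)`
#'   (default 0.5, moderate pathway correlation).
#' @param effect_templates Optional named list with elements among
#'   `organ`, `stage`, `condition`, `genotype`; each a
#'   `n_metabolites x n_levels` matrix of additive log2 shifts with level
#'   column names matching the design. Missing elements are drawn with
#'   standard deviations from `effect_sds`.
#' @param seed Integer root seed; identical arguments and seed give
#'   bit-identical output.
#' @param n_effects Number of metabolites with a true yield effect
#'   (default: 10, capped at `n_metabolites`; 0 gives a pure null).
#' @param true_beta Optional explicit per-metabolite yield effect vector
#'   (log2 scale); overrides `n_effects`/`target_r2` scaling.
#' @param target_r2 Intended fraction of metabolite-plus-noise yield variance
#'   carried by the metabolite signal (default 0.7).
#' @param noise_sd Residual standard deviation of yield (default 1).
#' @param yield_intercept Baseline yield, t/ha-like scale (default 6).
#' @param condition_shift Additive yield penalty for `WS` samples
#'   (default -2, about a one-third loss at the default intercept).
#' @param missing_rates Optional per-metabolite missingness probabilities in
#'   `[0, 1)`; by default most columns get low rates and roughly one in ten
#'   exceeds the 10 percent filter threshold.
#' @param baseline_mean,baseline_sd Mean and spread of per-metabolite baseline
#'   log2 intensity (defaults 10 and 1).
#' @param residual_sd Within-cell log2 intensity standard deviation
#'   (default 1); the study design does not pin this down, so it is exposed.
#' @param effect_sds Named list of standard deviations for drawing default
#'   effect templates (`organ` 0.5, `stage` 0.3, `condition` 0.4,
#'   `genotype` 0.2 on the log2 scale).
#' @return A list with elements `matrix` (a complete raw-scale
#'   [metab_matrix()]) and `truth` (class `ground_truth`).
#' @examples
#' d <- build_design(2, 2, 2, organs = "glume", stages = "anthesis")
#' sim <- simulate_metabolome(d, n_metabolites = 10, n_blocks = 2, seed = 1)
#' sim$matrix
#' sum(sim$truth$true_beta != 0)
#' @export
simulate_metabolome <- function(design, n_metabolites = 80, n_blocks = 8,
                                block_rho = 0.5, effect_templates = NULL,
                                seed = 1, n_effects = NULL, target_r2 = 0.7,
                                true_beta = NULL,
                                noise_sd = 1, yield_intercept = 6,
                                condition_shift = -2, missing_rates = NULL,
                                baseline_mean = 10, baseline_sd = 1,
                                residual_sd = 1,
                                effect_sds = list(organ = 0.5, stage = 0.3,
                                                  condition = 0.4,
                                                  genotype = 0.2)) {
  design <- tibble::as_tibble(design)
  n <- nrow(design); p <- n_metabolites
  if (p < n_blocks || n_blocks < 1) {
    abort("Require n_metabolites >= n_blocks >= 1.")
  }
  if (block_rho < 0 || block_rho >= 1) abort("`block_rho` must be in [0, 1).")
  n_effects <- n_effects %||% min(10L, p)
  if (n_effects < 0 || n_effects > p) abort("`n_effects` must be in [0, p].")
  if (!is.null(true_beta) && length(true_beta) != p) {
    abort("`true_beta` must have one entry per metabolite.")
  }
  if (noise_sd <= 0) abort("`noise_sd` must be > 0.")
  if (!is.null(missing_rates) &&
      (length(missing_rates) != p || any(missing_rates < 0) ||
       any(missing_rates >= 1))) {
    abort("`missing_rates` must have one rate in [0, 1) per metabolite.")
  }

  met_ids <- sprintf("met%03d", seq_len(p))
  block_assignment <- stats::setNames(sort(rep_len(seq_len(n_blocks), p)),
                                      met_ids)

  factors <- c("organ", "stage", "condition", "genotype")
  with_substream(seed, "metabolome", {
    baseline <- rnorm(p, baseline_mean, baseline_sd)

    templates <- list()
    for (f in factors) {
      levels_f <- if (f %in% names(design)) unique(design[[f]]) else character()
      if (length(levels_f) == 0) next
      tmpl <- effect_templates[[f]]
      if (is.null(tmpl)) {
        tmpl <- matrix(rnorm(p * length(levels_f), 0, effect_sds[[f]] %||% 0),
                       p, length(levels_f), dimnames = list(met_ids, levels_f))
      } else {
        tmpl <- as.matrix(tmpl)
        if (nrow(tmpl) != p || ncol(tmpl) != length(levels_f)) {
          abort(sprintf(
            "effect_templates$%s must be %d x %d (metabolites x levels).",
            f, p, length(levels_f)))
        }
        if (is.null(colnames(tmpl))) colnames(tmpl) <- levels_f
        if (!all(levels_f %in% colnames(tmpl))) {
          abort(sprintf("effect_templates$%s lacks columns for all %s levels.",
                        f, f))
        }
        rownames(tmpl) <- met_ids
      }
      templates[[f]] <- tmpl
    }

    # block-exchangeable noise: z_ij = sqrt(rho) g_{i,block(j)} + sqrt(1-rho) e_ij
    g <- matrix(rnorm(n * n_blocks), n, n_blocks)
    e <- matrix(rnorm(n * p), n, p)
    z <- sqrt(block_rho) * g[, block_assignment, drop = FALSE] +
      sqrt(1 - block_rho) * e

    logv <- matrix(rep(baseline, each = n), n, p) + residual_sd * z
    for (f in names(templates)) {
      logv <- logv + t(templates[[f]][, design[[f]], drop = FALSE])
    }
    dimnames(logv) <- list(design$sample_id, met_ids)

    beta <- stats::setNames(numeric(p), met_ids)
    if (!is.null(true_beta)) {
      beta[] <- true_beta
    } else if (n_effects > 0) {
      support <- sample(p, n_effects)
      beta[support] <- sample(c(-1, 1), n_effects, replace = TRUE)
      lin <- drop(logv %*% beta)
      s_lin <- stats::sd(lin)
      if (s_lin > 0) {
        beta <- beta * noise_sd * sqrt(target_r2 / (1 - target_r2)) / s_lin
      }
    }

    if (is.null(missing_rates)) {
      u <- runif(p)
      missing_rates <- ifelse(u < 0.6, 0,
                       ifelse(u < 0.9, runif(p, 0, 0.08),
                              runif(p, 0.12, 0.3)))
    }
    missing_rates <- stats::setNames(as.numeric(missing_rates), met_ids)

    truth <- structure(
      list(true_beta = beta, intercept = yield_intercept, noise_sd = noise_sd,
           condition_shift = condition_shift, missing_rates = missing_rates,
           block_assignment = block_assignment, target_r2 = target_r2,
           seed = seed),
      class = "ground_truth"
    )
    list(matrix = metab_matrix(2^logv, design = design, scale = "raw"),
         truth = truth)
  })
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf(
    "<ground_truth> %d metabolites, %d true effects, noise_sd %.3g, WS shift %.3g\n",
    length(x$true_beta), sum(x$true_beta != 0), x$noise_sd, x$condition_shift))
  invisible(x)
}

#' Simulate agronomic traits from a metabolome and its ground truth
#'
#' Grain yield is generated from the log2 intensities:
#' `GY = intercept + log2(values) %*% true_beta + condition_shift * 1[WS] +
#' Normal(0, noise_sd)`, on a t/ha-like scale. Biomass is derived through a
#' plot-level latent harvest index, and grain nitrogen concentration is
#' mildly elevated under water stress, as is typical in the field. The
#' realised signal fraction `var(linear part) / var(GY)` is attached as
#' attribute `r2_true`.
#'
#' @param matrix A complete [metab_matrix()] (no masked cells).
#' @param truth A `ground_truth` from [simulate_metabolome()].
#' @param seed Integer root seed for the trait noise sub-stream.
#' @return A tibble with `sample_id`, `condition` (if in the design), `GY`,
#'   `biomass`, `grain_pctN`; attribute `r2_true` holds the realised signal
#'   fraction.
#' @examples
#' d <- build_design(2, 2, 2, organs = "glume", stages = "anthesis")
#' sim <- simulate_metabolome(d, n_metabolites = 10, n_blocks = 2, seed = 1)
#' tr <- simulate_traits(sim$matrix, sim$truth, seed = 1)
#' attr(tr, "r2_true")
#' @export
simulate_traits <- function(matrix, truth, seed = 1) {
  stopifnot(inherits(matrix, "metab_matrix"), inherits(truth, "ground_truth"))
  if (any(matrix$mask)) {
    abort("`matrix` must be complete (no masked cells) to simulate traits.")
  }
  logv <- if (matrix$scale == "log2") matrix$values else log2(matrix$values)
  if (length(truth$true_beta) != ncol(logv)) {
    abort("`truth$true_beta` length must match the number of metabolites.")
  }
  n <- nrow(logv)
  design <- matrix$design
  is_ws <- if ("condition" %in% names(design)) design$condition == "WS"
           else rep(FALSE, n)

  with_substream(seed, "traits", {
    lin <- drop(logv %*% truth$true_beta)
    gy <- truth$intercept + lin + truth$condition_shift * is_ws +
      rnorm(n, 0, truth$noise_sd)
    hi_lat <- pmin(pmax(rnorm(n, 0.42, 0.04), 0.2), 0.6)
    biomass <- gy / hi_lat
    pctn <- 2.2 + 0.3 * is_ws + rnorm(n, 0, 0.15)
    out <- tibble::tibble(sample_id = design$sample_id)
    if ("condition" %in% names(design)) out$condition <- design$condition
    out$GY <- gy
    out$biomass <- biomass
    out$grain_pctN <- pctn
    attr(out, "r2_true") <- if (stats::var(gy) > 0) {
      stats::var(lin) / stats::var(gy)
    } else NA_real_
    out
  })
}

#' Inject missingness into a metabolome matrix
#'
#' Masks cells of each metabolite column. Under `"mcar"` every cell of column
#' `j` is masked independently with probability `rates[j]`. Under
#' `"censored"` the lowest-intensity fraction `rates[j]` of the column is
#' masked, emulating abundance-dependent (left-censored) GC-MS missingness.
#' True values are retained internally so imputation accuracy can be scored;
#' use [observed_values()] for the observed view.
#'
#' @param matrix A [metab_matrix()].
#' @param rates Per-metabolite missingness probabilities in `[0, 1)`
#'   (recycled if length 1).
#' @param seed Integer root seed.
#' @param mechanism `"mcar"` (default) or `"censored"`.
#' @return The matrix with an updated mask.
#' @examples
#' d <- build_design(2, 1, 2, organs = "glume", stages = "anthesis")
#' sim <- simulate_metabolome(d, n_metabolites = 5, n_blocks = 1, seed = 1)
#' m <- inject_missing(sim$matrix, rates = 0.2, seed = 1)
#' sum(m$mask)
#' @export
inject_missing <- function(matrix, rates, seed = 1,
                           mechanism = c("mcar", "censored")) {
  stopifnot(inherits(matrix, "metab_matrix"))
  mechanism <- match.arg(mechanism)
  p <- ncol(matrix$values); n <- nrow(matrix$values)
  rates <- rep_len(as.numeric(rates), p)
  if (any(rates < 0) || any(rates >= 1)) {
    abort("Missingness rates must lie in [0, 1).")
  }
  mask <- with_substream(seed, "missing", {
    if (mechanism == "mcar") {
      matrix(runif(n * p), n, p) < rep(rates, each = n)
    } else {
      m <- matrix(FALSE, n, p)
      for (j in seq_len(p)) {
        if (rates[j] > 0) {
          thr <- stats::quantile(matrix$values[, j], rates[j], names = FALSE)
          m[, j] <- matrix$values[, j] <= thr
        }
      }
      m
    }
  })
  dimnames(mask) <- dimnames(matrix$values)
  metab_matrix(matrix$values, mask = mask, design = matrix$design,
               scale = matrix$scale)
}
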