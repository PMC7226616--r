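# minimal hand-built stability_result for selection tests
fake_stability <- function(dr, eff = rep(1, length(dr))) {
  structure(list(
    effects = tibble::tibble(
      metabolite = paste0("m", seq_along(dr)),
      detection_rate = dr, mean_effect = eff,
      mean_effect_selected = eff)),
    class = "stability_result")
}

test_that("detection-rate selection is inclusive at the threshold", {
  sel <- select_by_dr(fake_stability(c(0.71, 0.70, 0.69)))
  expect_identical(sel, c("m1", "m2"))
  expect_warning(empty <- select_by_dr(fake_stability(c(0, 0, 0))),
                 "empty set")
  expect_length(empty, 0)
  expect_error(select_by_dr(fake_stability(0.5), threshold = 1.2), "\\(0, 1\\]")
})

test_that("selection orders by detection rate then absolute effect", {
  st <- fake_stability(c(0.8, 0.9, 0.8), eff = c(-3, 1, 2))
  expect_identical(select_by_dr(st, 0.7), c("m2", "m1", "m3"))
})

test_that("a perfectly predictive feature yields a saturated refit", {
  set.seed(1)
  v <- matrix(2^rnorm(40, 10), 20, 2,
              dimnames = list(sprintf("s%02d", 1:20), c("a", "b")))
  m <- metab_matrix(v)
  y <- v[, 1]
  rf <- suppressWarnings(fit_refit(m, y, "a"))   # lm warns on a perfect fit
  expect_equal(rf$adj_r2, 1, tolerance = 1e-10)
  expect_equal(rf$variance_shares$share, 1, tolerance = 1e-10)
})

test_that("null features give near-zero fits and uniform overall p", {
  set.seed(2)
  ps <- replicate(200, {
    X <- matrix(rnorm(30 * 3), 30, 3,
                dimnames = list(NULL, c("a", "b", "c")))
    y <- rnorm(30)
    fit_refit(X, y, c("a", "b", "c"))$overall_p
  })
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
  expect_lt(mean(ps < 0.05), 0.1)
})

test_that("refit re-estimates per condition subset and matches lm", {
  sc <- sim_cell(seed = 91, n_effects = 3, n_metabolites = 10)
  m <- log2_transform(sc$matrix)
  feats <- sc$true_features
  for (ss in c("all", "WS", "HY")) {
    rf <- fit_refit(m, sc$y, feats, subset = ss)
    rows <- if (ss == "all") 1:60 else which(m$design$condition == ss)
    ref <- lm(sc$y[rows] ~ m$values[rows, feats])
    expect_equal(rf$adj_r2, summary(ref)$adj.r.squared, tolerance = 1e-10)
    expect_equal(unname(rf$coefficients),
                 unname(coef(ref)), tolerance = 1e-10)
  }
})

test_that("lower-noise subsets fit better", {
  # WS plots simulated with half the yield noise of HY plots
  d <- cell_design()
  sim <- simulate_metabolome(d, n_metabolites = 10, n_blocks = 1,
                             block_rho = 0, seed = 92, n_effects = 3,
                             target_r2 = 0.6, condition_shift = 0,
                             effect_sds = list(organ = 0, stage = 0,
                                               condition = 0, genotype = 0))
  ws <- sim$matrix$design$condition == "WS"
  lin <- drop(log2(sim$matrix$values) %*% sim$truth$true_beta)
  y <- withr::with_seed(92,
    sim$truth$intercept + lin + rnorm(60, 0, ifelse(ws, 0.4, 1.2)))
  feats <- names(which(sim$truth$true_beta != 0))
  m <- log2_transform(sim$matrix)
  rf_ws <- fit_refit(m, y, feats, subset = "WS")
  rf_hy <- fit_refit(m, y, feats, subset = "HY")
  expect_gt(rf_ws$adj_r2, rf_hy$adj_r2)
})

test_that("collinear features are dropped with a warning", {
  set.seed(3)
  a <- rnorm(25)
  X <- cbind(a = a, b = a, c = rnorm(25))
  y <- a + rnorm(25, 0, 0.1)
  expect_warning(rf <- fit_refit(X, y, c("a", "b", "c")), "collinear.*b")
  expect_identical(rf$features, c("a", "c"))
})

test_that("variance shares telescope to the model R2", {
  sc <- sim_cell(seed = 93, n_effects = 4, n_metabolites = 12)
  m <- log2_transform(sc$matrix)
  rf <- fit_refit(m, sc$y, sc$true_features)
  expect_equal(sum(rf$variance_shares$share), rf$r2, tolerance = 1e-10)
  lmg <- partition_variance(rf, method = "lmg")
  expect_equal(sum(lmg$share), rf$r2, tolerance = 1e-10)
  expect_true(all(lmg$share >= -1e-12))
})

test_that("orthogonal predictors make sequential and LMG shares identical", {
  n <- 32
  Q <- qr.Q(qr(cbind(1, matrix(rnorm(n * 3), n, 3))))[, -1]
  colnames(Q) <- c("a", "b", "c")
  y <- drop(Q %*% c(2, 1, 0.5)) + rnorm(n, 0, 0.3)
  rf <- fit_refit(Q, y, c("a", "b", "c"))
  seq_sh <- rf$variance_shares$share
  lmg_sh <- partition_variance(rf, method = "lmg")$share
  expect_equal(seq_sh, lmg_sh, tolerance = 1e-10)
  # order independence under orthogonality
  rf2 <- fit_refit(Q, y, c("c", "a", "b"))
  sh2 <- rf2$variance_shares
  expect_equal(sh2$share[sh2$feature == "a"],
               seq_sh[rf$variance_shares$feature == "a"], tolerance = 1e-10)
})

test_that("collinear-limit predictors leave the first with the whole share", {
  set.seed(4)
  a <- rnorm(30); y <- a + rnorm(30, 0, 0.2)
  # exact duplicate: dropped, first feature keeps the whole share
  X <- cbind(a = a, a2 = a, c = rnorm(30))
  expect_warning(rf <- fit_refit(X, y, c("a", "a2", "c")), "collinear")
  sh <- rf$variance_shares
  expect_false("a2" %in% sh$feature)
  expect_gt(sh$share[sh$feature == "a"], 0.9)
  # near-duplicate: retained, but its incremental share is at chance level
  X2 <- cbind(a = a, a2 = a + rnorm(30, 0, 1e-3), c = rnorm(30))
  rf2 <- fit_refit(X2, y, c("a", "a2", "c"))
  sh2 <- rf2$variance_shares
  expect_gt(sh2$share[sh2$feature == "a"], 0.9)
  expect_lt(abs(sh2$share[sh2$feature == "a2"]), 0.02)
})

test_that("LMG matches an exhaustive ordering average for four features", {
  set.seed(5)
  X <- matrix(rnorm(40 * 4), 40, 4, dimnames = list(NULL, letters[1:4]))
  X[, 2] <- X[, 1] * 0.6 + X[, 2] * 0.8
  y <- drop(X %*% c(1, 0.5, -0.5, 0)) + rnorm(40, 0, 0.5)
  rf <- fit_refit(X, y, letters[1:4])
  lmg <- partition_variance(rf, method = "lmg")
  # brute force: average incremental R2 over all 24 orderings
  r2_of <- function(cols) {
    if (length(cols) == 0) return(0)
    summary(lm(y ~ X[, cols, drop = FALSE]))$r.squared
  }
  perms <- as.matrix(expand.grid(1:4, 1:4, 1:4, 1:4))
  perms <- perms[apply(perms, 1, function(x) length(unique(x)) == 4), ]
  acc <- numeric(4)
  for (i in seq_len(nrow(perms))) {
    ord <- perms[i, ]
    prev <- 0
    for (j in 1:4) {
      cur <- r2_of(ord[1:j])
      acc[ord[j]] <- acc[ord[j]] + (cur - prev)
      prev <- cur
    }
  }
  brute <- acc / nrow(perms)
  expect_equal(lmg$share, unname(brute[match(lmg$feature, letters[1:4])]),
               tolerance = 1e-10)
})

test_that("large LMG problems require explicit subsampling", {
  set.seed(6)
  X <- matrix(rnorm(80 * 21), 80, 21,
              dimnames = list(NULL, paste0("f", 1:21)))
  y <- rnorm(80)
  rf <- fit_refit(X, y, paste0("f", 1:21))
  expect_error(partition_variance(rf, method = "lmg"), "n_orderings")
  sub <- partition_variance(rf, method = "lmg", n_orderings = 20)
  expect_equal(sum(sub$share), rf$r2, tolerance = 1e-8)
})
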