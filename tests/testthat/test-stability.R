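test_that("split plans have exact sizes and are reproducible", {
  plan <- make_splits(60, n_runs = 10, seed = 1)
  expect_length(plan$assignments, 10)
  expect_true(all(lengths(plan$assignments) == 45))
  for (a in plan$assignments) {
    expect_length(setdiff(seq_len(60), a), 15)
    expect_false(anyDuplicated(a) > 0)
  }
  expect_identical(make_splits(60, n_runs = 10, seed = 1), plan)
  expect_false(identical(make_splits(60, n_runs = 10, seed = 2), plan))
  expect_error(make_splits(5), "at least 8")
  expect_error(make_splits(60, train_fraction = 1.2), "\\(0, 1\\)")
})

test_that("stratified splits preserve level proportions exactly in total", {
  cond <- rep(c("WS", "HY"), each = 30)
  plan <- make_splits(60, n_runs = 20, seed = 3, stratify_by = cond)
  for (a in plan$assignments) {
    expect_length(a, 45)
    tab <- table(cond[a])
    expect_true(all(tab >= 22 & tab <= 23))
  }
})

test_that("kfold mode partitions each repeat into disjoint validation folds", {
  plan <- make_splits(40, n_runs = 10, seed = 4, mode = "kfold", folds = 5)
  expect_equal(plan$train_fraction, 0.8)
  for (rep_i in 1:2) {
    runs <- plan$assignments[(rep_i - 1) * 5 + 1:5]
    vals <- lapply(runs, function(a) setdiff(1:40, a))
    expect_equal(sort(unlist(vals)), 1:40)   # folds partition the rows
  }
  expect_error(make_splits(40, n_runs = 7, mode = "kfold"), "multiple")
})

test_that("adjusted R2 follows its closed form", {
  expect_equal(adjusted_r2(0.8, 100, 5), 0.78936, tolerance = 1e-5 / 0.78936)
  expect_identical(adjusted_r2(0.55, 30, 0), 0.55)
  set.seed(5)
  r2 <- runif(20); n <- sample(20:200, 20); p <- sample(1:10, 20, TRUE)
  expect_true(all(adjusted_r2(r2, n, p) <= r2))
  expect_true(is.na(adjusted_r2(0.5, 6, 5)))
})

test_that("stability metrics are internally consistent and reproducible", {
  sc <- sim_cell(seed = 71, n_effects = 3, n_metabolites = 15)
  m <- log2_transform(sc$matrix)
  plan <- make_splits(60, n_runs = 15, seed = 71)
  st <- run_stability(m, sc$y, plan, fast_cfg)
  expect_true(all(st$effects$detection_rate >= 0 &
                    st$effects$detection_rate <= 1))
  expect_true(all(st$per_run$predictive_ability >= 0 &
                    st$per_run$predictive_ability <= 1))
  expect_true(all(st$per_run$adj_r2_train <= st$per_run$r2_train + 1e-12,
                  na.rm = TRUE))
  # selection events tally with detection rates
  expect_equal(sum(st$per_run$n_selected),
               sum(st$effects$detection_rate) * plan$n_runs)
  # never-selected metabolites have zero-inclusive mean effect zero
  never <- st$effects$detection_rate == 0
  expect_true(all(st$effects$mean_effect[never] == 0))
  expect_true(all(is.na(st$effects$mean_effect_selected[never])))
  # determinism
  st2 <- run_stability(m, sc$y, plan, fast_cfg)
  expect_identical(st$effects, st2$effects)
  expect_identical(st$per_run, st2$per_run)
})

test_that("predictive ability equals an independently computed squared correlation", {
  sc <- sim_cell(seed = 72, n_effects = 3, n_metabolites = 12)
  m <- log2_transform(sc$matrix)
  plan <- make_splits(60, n_runs = 3, seed = 72)
  st <- run_stability(m, sc$y, plan, fast_cfg)
  # replicate run 1 from scratch
  tr <- plan$assignments[[1]]; va <- setdiff(1:60, tr)
  sel <- select_lambda_cv(m$values[tr, ], sc$y[tr],
                          n_grid = fast_cfg$n_grid, eps = fast_cfg$eps,
                          seed = derive_seed(plan$seed, "run1"))
  expect_equal(sel$lambda, st$per_run$lambda[1])
  pred <- predict(sel$fit, m$values[va, ])
  yv <- sc$y[va]
  # independent correlation: explicit sums, no cor()
  sxy <- sum((pred - mean(pred)) * (yv - mean(yv)))
  r2 <- sxy^2 / (sum((pred - mean(pred))^2) * sum((yv - mean(yv))^2))
  expect_equal(st$per_run$predictive_ability[1], r2, tolerance = 1e-12)
})

test_that("strong planted signals are detected with high stability", {
  sc <- sim_cell(seed = 73, n_effects = 2, n_metabolites = 15, target_r2 = 0.8)
  m <- log2_transform(sc$matrix)
  st <- run_stability(m, sc$y, make_splits(60, n_runs = 20, seed = 73),
                      fast_cfg)
  drs <- st$effects$detection_rate[st$effects$metabolite %in% sc$true_features]
  expect_true(all(drs >= 0.9))
  expect_gt(st$summary$mean_predictive_ability, 0.5)
})

test_that("shuffling the response destroys detection", {
  sc <- sim_cell(seed = 74, n_effects = 2, n_metabolites = 15, target_r2 = 0.8)
  m <- log2_transform(sc$matrix)
  y_perm <- sc$y[withr::with_seed(74, sample(60))]
  st <- run_stability(m, y_perm, make_splits(60, n_runs = 20, seed = 74),
                      fast_cfg)
  expect_lt(st$summary$mean_predictive_ability, 0.15)
})

test_that("predictive ability increases with the true signal fraction", {
  pa_at <- function(r2_true, seed) {
    sc <- sim_cell(seed = seed, n_effects = 3, n_metabolites = 15,
                   target_r2 = max(r2_true, 1e-6))
    if (r2_true == 0) sc <- sim_cell(seed = seed, n_effects = 0,
                                     n_metabolites = 15)
    m <- log2_transform(sc$matrix)
    run_stability(m, sc$y, make_splits(60, n_runs = 10, seed = seed),
                  fast_cfg)$summary$mean_predictive_ability
  }
  seeds <- 81:83
  pa0 <- mean(vapply(seeds, function(s) pa_at(0, s), 1))
  pa3 <- mean(vapply(seeds, function(s) pa_at(0.3, s), 1))
  pa7 <- mean(vapply(seeds, function(s) pa_at(0.7, s), 1))
  expect_lte(pa0, pa3 + 0.05)
  expect_lt(pa0, pa7)
  expect_lt(pa3, pa7)
})

test_that("scale comparison recommends the generating scale", {
  sc <- sim_cell(seed = 75, n_effects = 2, n_metabolites = 12, target_r2 = 0.8,
                 baseline_sd = 2, residual_sd = 1.5)
  plan <- make_splits(60, n_runs = 10, seed = 75)
  cmp <- compare_scales(sc$matrix, sc$y, plan, fast_cfg)
  expect_s3_class(cmp, "scale_comparison")
  expect_identical(cmp$recommended, "log2")
})

test_that("degenerate constant matrices tie and fall back to raw", {
  v <- matrix(5, 20, 3, dimnames = list(paste0("s", 1:20), paste0("m", 1:3)))
  m <- metab_matrix(v)
  plan <- make_splits(20, n_runs = 5, seed = 1)
  y <- withr::with_seed(1, rnorm(20))
  warns <- capture_warnings(cmp <- compare_scales(m, y, plan, fast_cfg))
  expect_true(any(grepl("identical mean predictive ability", warns)))
  expect_identical(cmp$recommended, "raw")
  expect_equal(cmp$raw$summary$mean_predictive_ability, 0)
})
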