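test_that("delta notation is exact, symmetric and guarded", {
  expect_identical(delta_notation(0.011237, 0.011237), 0)
  expect_equal(delta_notation(1.001 * 0.011237, 0.011237), 1)
  expect_equal(delta_notation(0.999 * 0.011237, 0.011237), -1)
  expect_error(delta_notation(-1, 0.01), "> 0")
})

test_that("derived traits follow their exact arithmetic", {
  d <- derived_traits(data.frame(GY = 5, biomass = 12, grain_pctN = 2,
                                 grain_mass = 20, grain_count = 500))
  expect_identical(d$GNY, 0.1)
  expect_identical(d$HI, 5 / 12)
  expect_identical(d$TKW, 40)
  # boundaries: GY == biomass gives HI 1; zero denominators flag missing
  d2 <- derived_traits(data.frame(GY = c(4, 4), biomass = c(4, 0),
                                  grain_pctN = c(2, 2),
                                  grain_mass = c(10, 10),
                                  grain_count = c(250, 0)))
  expect_identical(d2$HI, c(1, NA_real_))
  expect_identical(d2$TKW, c(40, NA_real_))
  expect_error(derived_traits(data.frame(GY = 1)), "Missing column")
})

test_that("normalized difference indices are bounded and antisymmetric", {
  expect_identical(normalized_difference(0.4, 0.4), 0)
  expect_identical(normalized_difference(0.7, 0), 1)
  expect_true(is.na(normalized_difference(0, 0)))
  a <- runif(20); b <- runif(20)
  expect_equal(normalized_difference(a, b), -normalized_difference(b, a))
  expect_true(all(abs(normalized_difference(a, b)) <= 1))
  expect_identical(ndwi(0.5, 0.3), normalized_difference(0.5, 0.3))
})

test_that("metabolite-trait correlations recover exact relationships", {
  set.seed(1)
  v <- matrix(2^rnorm(120, 8), 30, 4,
              dimnames = list(sprintf("s%02d", 1:30), paste0("m", 1:4)))
  m <- metab_matrix(v)
  tt <- tibble::tibble(sample_id = rownames(v), GY = v[, 1],
                       biomass = rnorm(30))
  res <- metabolite_trait_correlations(m, tt)
  r_self <- res$r[res$metabolite == "m1" & res$trait == "GY"]
  expect_equal(r_self, 1, tolerance = 1e-12)
  expect_true(all(res$q >= res$p - 1e-15, na.rm = TRUE))
})

test_that("null correlations stay small at n = 360", {
  d <- build_design()
  sim <- simulate_metabolome(d, n_metabolites = 20, n_blocks = 2,
                             block_rho = 0, seed = 2, n_effects = 0,
                             effect_sds = list(organ = 0, stage = 0,
                                               condition = 0, genotype = 0))
  tt <- simulate_traits(sim$matrix, sim$truth, seed = 2)
  res <- metabolite_trait_correlations(sim$matrix, tt["GY"] |>
                                         dplyr::mutate(sample_id = d$sample_id))
  expect_gt(mean(abs(res$r) < 0.2), 0.95)
})

test_that("BH adjustment reproduces the hand-computed step-up values", {
  # independent oracle: for p = {0.01, 0.02, 0.04}, m = 3:
  # q3 = 0.04; q2 = min(0.02 * 3/2, 0.04) = 0.03; q1 = min(0.01 * 3, 0.03) = 0.03
  expect_equal(stats::p.adjust(c(0.01, 0.02, 0.04), "BH"),
               c(0.03, 0.03, 0.04))
  # and the correlation table uses the same adjustment across all pairs
  set.seed(3)
  v <- matrix(rnorm(60), 20, 3, dimnames = list(NULL, paste0("m", 1:3)))
  tt <- tibble::tibble(t1 = rnorm(20))
  res <- metabolite_trait_correlations(metab_matrix(2^v), tt)
  expect_equal(res$q, stats::p.adjust(res$p, "BH"))
})

test_that("constant metabolites are flagged, not fatal", {
  v <- cbind(m1 = rep(4, 12), m2 = 2^rnorm(12))
  rownames(v) <- sprintf("s%02d", 1:12)
  tt <- tibble::tibble(GY = rnorm(12))
  res <- metabolite_trait_correlations(metab_matrix(v), tt)
  expect_true(is.na(res$r[res$metabolite == "m1"]))
  expect_false(is.na(res$r[res$metabolite == "m2"]))
})

test_that("planted condition effects are flagged by the factorial ANOVA", {
  d <- build_design(3, 4, 3, organs = c("flag_leaf", "glume"),
                    stages = "anthesis")
  p <- 10
  tmpl <- matrix(0, p, 2, dimnames = list(NULL, c("WS", "HY")))
  tmpl[1, "WS"] <- 1.5
  sim <- simulate_metabolome(d, n_metabolites = p, n_blocks = 1, block_rho = 0,
                             seed = 4, effect_templates = list(condition = tmpl),
                             effect_sds = list(organ = 0, stage = 0,
                                               condition = 0, genotype = 0))
  res <- factorial_anova(log2_transform(sim$matrix),
                         factors = c("organ", "condition", "genotype"))
  cond <- res[res$term == "condition", ]
  expect_lt(cond$q[cond$metabolite == "met001"], 0.05)
  expect_gt(min(cond$p[cond$metabolite != "met001"]), 1e-4)
})

test_that("Type-II equals Type-I sums of squares under balance", {
  d <- build_design(3, 2, 3, organs = c("flag_leaf", "glume"),
                    stages = "anthesis")
  sim <- simulate_metabolome(d, n_metabolites = 3, n_blocks = 1, block_rho = 0,
                             seed = 5)
  m <- log2_transform(sim$matrix)
  dat <- data.frame(y = m$values[, 1],
                    organ = factor(d$organ), genotype = factor(d$genotype))
  fit <- lm(y ~ (organ + genotype)^2, dat)
  t1 <- anova(fit)
  t2 <- car::Anova(fit, type = 2)
  for (term in c("organ", "genotype", "organ:genotype")) {
    expect_equal(t2[term, "Sum Sq"], t1[term, "Sum Sq"], tolerance = 1e-10)
  }
  res <- factorial_anova(m, factors = c("organ", "genotype"))
  expect_setequal(unique(res$term), c("organ", "genotype", "organ:genotype"))
})

test_that("single-level factors are dropped with a warning", {
  d <- build_design(2, 2, 2, organs = "glume", stages = "anthesis")
  sim <- simulate_metabolome(d, n_metabolites = 3, n_blocks = 1, seed = 6)
  expect_warning(
    res <- factorial_anova(sim$matrix, factors = c("organ", "condition")),
    "single-level")
  expect_setequal(unique(res$term), "condition")
})

test_that("permuted responses give uniform ANOVA p-values", {
  d <- build_design(3, 2, 3, organs = c("flag_leaf", "glume"),
                    stages = "anthesis")
  set.seed(7)
  ps <- replicate(100, {
    y <- rnorm(nrow(d))
    dat <- data.frame(y = y, condition = factor(d$condition),
                      genotype = factor(d$genotype))
    fit <- lm(y ~ (condition + genotype)^2, dat)
    car::Anova(fit, type = 2)["condition", "Pr(>F)"]
  })
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})
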