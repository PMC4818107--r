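test_that("discretize_bias signs and rejects zero", {
  expect_identical(discretize_bias(0.97), 1)
  expect_identical(discretize_bias(-0.4), -1)
  expect_identical(discretize_bias(c(0.2, -0.9)), c(1, -1))
  expect_error(discretize_bias(0), "no class")
})

test_that("predict_bias is the back-calculated probability difference", {
  fit <- structure(list(beta0 = 0, betas = c(x1 = 1), features = "x1"),
                   class = "logistic_fit")
  expect_equal(predict_bias(fit, c(x1 = 0)), 0)   # logit 0 -> indifferent
  # predicted bias = 1 - 2 * P_MAPK algebraically
  x <- c(-3, -1, 0, 2, 5)
  pb <- predict_bias(fit, data.frame(x1 = x))
  expect_equal(pb, 1 - 2 * plogis(x))
  expect_true(all(pb > -1 & pb < 1))
  expect_lt(predict_bias(fit, c(x1 = 50)), -0.999)  # P_MAPK -> 1 limit
  expect_error(predict_bias(fit, c(x2 = 1)), "missing features")
})

test_that("fit_logistic agrees with glm at lambda = 0 on a toy panel", {
  panel <- toy_panel()
  fit <- fit_logistic(panel, c("x1", "x2"), lambda = 0)
  ref <- oracle_logistic(panel, c("x1", "x2"))
  expect_equal(unname(c(fit$beta0, fit$betas)), unname(ref),
               tolerance = 1e-4)
})

test_that("fit_logistic: uninformative feature, prevalence intercept,
           label-flip antisymmetry, duplication invariance", {
  panel <- toy_panel(seed = 7, n = 12)
  panel$zero <- 0
  fit <- fit_logistic(panel, c("zero"), lambda = 0)
  prev_mapk <- mean(panel$class_label == -1)
  expect_equal(unname(fit$betas["zero"]), 0)
  expect_equal(fit$beta0, qlogis(prev_mapk), tolerance = 1e-6)

  f1 <- fit_logistic(panel, c("x1", "x2"), lambda = 0)
  flipped <- panel; flipped$class_label <- -panel$class_label
  f2 <- fit_logistic(flipped, c("x1", "x2"), lambda = 0)
  expect_equal(f2$beta0, -f1$beta0, tolerance = 1e-6)
  expect_equal(f2$betas, -f1$betas, tolerance = 1e-6)

  doubled <- rbind(panel, panel)
  f3 <- fit_logistic(doubled, c("x1", "x2"), lambda = 0)
  expect_equal(f3$betas, f1$betas, tolerance = 1e-6)
})

test_that("separation is tamed by the ridge default", {
  n <- 12
  panel <- data.frame(sample_id = paste0("S", 1:n),
                      sep = rep(c(1, -1), each = n / 2),
                      bias = rep(c(1, -1), each = n / 2) * 0.9,
                      class_label = rep(c(1, -1), each = n / 2))
  fit <- fit_logistic(panel, "sep")
  expect_true(all(is.finite(c(fit$beta0, fit$betas))))
  pb <- predict_bias(fit, panel)
  p_correct <- ifelse(panel$class_label == 1, (1 + pb) / 2, (1 - pb) / 2)
  expect_true(all(p_correct > 0.95))
})

test_that("normalized coefficients scale by the feature median", {
  panel <- toy_panel()
  fit <- fit_logistic(panel, c("x1", "x2"), lambda = 0)
  nc <- normalized_coefficients(fit, panel)
  expect_equal(unname(nc["x1"]),
               unname(fit$betas["x1"] * median(panel$x1)))
  # doubling a feature column and halving its beta leaves it unchanged
  panel2 <- panel; panel2$x1 <- 2 * panel$x1
  fit2 <- fit_logistic(panel2, c("x1", "x2"), lambda = 0)
  expect_equal(normalized_coefficients(fit2, panel2)[["x1"]],
               nc[["x1"]], tolerance = 1e-5)
})

test_that("feature sets resolve the documented columns", {
  expect_identical(feature_set("3BM"), c("EGFR", "ERBB3", "CDKN1B"))
  expect_identical(feature_set("GENE"),
                   c("pik3ca_mut", "pten_mut", "pik3r1_mut"))
  expect_identical(feature_set("PHEN"), c("tissue_breast", "proliferation_pd"))
  expect_identical(feature_set("PAKT_PERK"), c("pAKT", "pERK"))
  expect_identical(feature_set("3BM+HRG"),
                   c("EGFR", "ERBB3", "CDKN1B", "hrg"))
  panel <- simulate_panel(panel_recipe(seed = 1, n_lines = 4))$panel
  panel$hrg <- as.numeric(panel$hrg)
  expect_true(all(feature_set("FULL", panel) %in% names(panel)))
  expect_error(feature_set("NOPE"), "unknown feature set")
})

test_that("loocv separates a planted panel and flags degenerate folds", {
  # strongly separated: large shifts, no switch lines, low noise
  rec <- panel_recipe(seed = 31, class_mix = c(PI3K = 0.5, MAPK = 0.5,
                                               SWITCH = 0),
                      feature_effects = list(EGFR_mapk = 2, ERBB3_pi3k = 1.5,
                                             CDKN1B_pi3k = 1.2))
  panel <- simulate_panel(rec)$panel
  r <- loocv(panel, "3BM")
  expect_gte(r$accuracy, 0.9)
  expect_gt(r$pearson, 0.8)
  expect_true(r$accuracy >= 0 && r$accuracy <= 1)
  # single-class training folds are skipped with a warning and count as errors
  tiny <- toy_panel(n = 4)
  tiny$class_label <- c(1, -1, -1, -1)
  tiny$bias <- tiny$class_label * 0.5
  expect_warning(r2 <- loocv(tiny, c("x1")), "single class")
  expect_true(is.na(r2$predicted_bias[1]))
  expect_lte(r2$accuracy, 3 / 4)
})

test_that("permutation p-values are bounded, seeded, and calibrated", {
  panel <- simulate_panel(panel_recipe(seed = 17))$panel
  r1 <- permutation_test(panel, "3BM", B = 100, seed = 9)
  r2 <- permutation_test(panel, "3BM", B = 100, seed = 9)
  expect_identical(r1$p_values, r2$p_values)
  expect_true(all(r1$p_values >= 1 / 101 & r1$p_values <= 1))
  expect_identical(nrow(r1$perm_null), 100L)
  # observed never better than null -> p = 1 bound (constructed case)
  expect_error(permutation_test(panel, "3BM", B = 10), ">= 100")
})

test_that("shuffled labels drive accuracy to chance", {
  panel <- simulate_panel(panel_recipe(seed = 23))$panel
  accs <- withr::with_seed(77, replicate(30, {
    idx <- sample.int(nrow(panel))
    pp <- panel
    pp$bias <- panel$bias[idx]; pp$class_label <- panel$class_label[idx]
    suppressWarnings(loocv(pp, "3BM")$accuracy)
  }))
  expect_lt(abs(mean(accs) - 0.5), 0.1)
})
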