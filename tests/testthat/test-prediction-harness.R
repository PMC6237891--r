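test_that("the split partitions ids exactly and balances folds", {
  ids <- sprintf("p%04d", 1:1000)
  sp <- make_split(ids, split_spec(seed = 3))
  expect_equal(length(sp$test_ids), 200L)
  expect_equal(length(sp$traincv_ids), 800L)
  expect_length(intersect(sp$test_ids, sp$traincv_ids), 0)
  expect_setequal(c(sp$test_ids, sp$traincv_ids), ids)
  expect_equal(dim(sp$folds), c(800L, 10L))
  for (r in 1:10) {
    sizes <- table(sp$folds[, r])
    expect_lte(max(sizes) - min(sizes), 1)
  }
  expect_identical(sp, make_split(ids, split_spec(seed = 3)))
  expect_false(identical(sp$test_ids,
                         make_split(ids, split_spec(seed = 4))$test_ids))
  expect_error(make_split(ids[1:5], split_spec()), "too few")
})

test_that("preprocessing centres, scales and filters on the training data", {
  set.seed(8)
  x <- matrix(rnorm(200 * 10), 200, 10,
              dimnames = list(NULL, paste0("f", 1:10)))
  x <- cbind(x, dup = x[, "f1"], nzv = c(rep(0, 199), 1))
  tf <- preprocess(x, filter = TRUE)
  xt <- predict(tf, x)
  expect_true(all(abs(colMeans(xt)) < 1e-10))
  expect_equal(unname(apply(xt, 2, sd)), rep(1, ncol(xt)))
  removed <- unlist(tf$removed)
  expect_true("nzv" %in% removed)
  expect_true(any(c("dup", "f1") %in% removed))
  # transform fitted on train need not centre held-out data
  x_new <- matrix(rnorm(50 * 12, mean = 2), 50, 12,
                  dimnames = list(NULL, colnames(x)))
  expect_gt(max(abs(colMeans(predict(tf, x_new)))), 0.5)
  expect_error(preprocess(matrix(1, 5, 3)), "constant")
})

test_that("learners recover a noiseless linear signal and the null limit", {
  # dense planted signal (every tunable codon weighted): elastic net
  coh <- small_cohort(250, seed = 31, target_r2 = 1)
  fm <- assemble_feature_matrix(coh$records)
  y <- coh$responses$lifetime
  tf <- preprocess(fm)
  x <- predict(tf, fm)
  spec <- split_spec(folds = 5, repeats = 2, seed = 1)
  tuned <- tune_and_fit(x, y, spec, "elastic_linear")
  expect_lt(tuned$rmse_cv, 0.05 * sd(y))
  # sparse planted signal (two amino acids): the greedy selector's regime
  cfg_s <- synthetic_config(n_proteins = 250, length_range = c(50, 150),
                            effect_map = c(aa_A = 2, aa_D = -2),
                            target_r2 = 1, seed = 33)
  coh_s <- plant_response(generate_cds_cohort(cfg_s))
  fm_s <- assemble_feature_matrix(coh_s$records)
  ys <- coh_s$responses$lifetime
  xs <- predict(preprocess(fm_s), fm_s)
  tuned_s <- tune_and_fit(xs, ys, spec, "greedy_forward_backward")
  expect_lt(tuned_s$rmse_cv, 0.05 * sd(ys))
  # pure-noise response: CV RMSE approaches the response spread
  set.seed(9)
  y0 <- setNames(rnorm(nrow(x)), rownames(x))
  tuned0 <- tune_and_fit(x, y0, spec, "elastic_linear")
  expect_equal(tuned0$rmse_cv, sd(y0), tolerance = 0.1)
  expect_error(tune_and_fit(x, setNames(rep(1, nrow(x)), rownames(x)),
                            spec, "elastic_linear"), "degenerate")
})

test_that("the tree ensemble captures a step function better than the
           linear learners", {
  set.seed(12)
  n <- 300
  x <- matrix(rnorm(n * 10), n, 10, dimnames = list(
    sprintf("p%03d", 1:n), paste0("f", 1:10)))
  y <- setNames(ifelse(x[, 1] > 0, 5, -5) + rnorm(n, sd = 0.3), rownames(x))
  spec <- split_spec(folds = 5, repeats = 1, seed = 2)
  xt <- predict(preprocess(x, filter = FALSE), x)
  rf <- tune_and_fit(xt, y, spec, "ensemble_trees")
  lin <- tune_and_fit(xt, y, spec, "elastic_linear")
  expect_lt(rf$rmse_cv, lin$rmse_cv)
})

test_that("evaluation metrics obey their definitions", {
  obs <- c(a = 1, b = 2, c = 3, d = 5)
  # predictions identical to observations
  r <- codonlife:::evaluate_predictions(obs, obs)
  expect_equal(r$rmse_test, 0)
  expect_equal(r$r2_test, 1)
  # constant offset: rmse equals the offset, correlation unharmed
  r2 <- codonlife:::evaluate_predictions(obs, obs + 2)
  expect_equal(r2$rmse_test, 2)
  expect_equal(r2$r2_test, 1)
  expect_equal(r2$r2_test, r2$r_test^2, tolerance = 1e-12)
  # constant predictions: undefined correlation, rmse still reported
  r3 <- codonlife:::evaluate_predictions(obs, rep(2, 4))
  expect_true(is.na(r3$r_test))
  expect_false(is.na(r3$rmse_test))
})

test_that("the fitted model object supports the standard methods", {
  coh <- small_cohort(250, seed = 31, target_r2 = 1)
  fm <- assemble_feature_matrix(coh$records)
  m <- homeostasis_model(fm, coh$responses$lifetime,
                         learner = "elastic_linear",
                         spec = split_spec(folds = 5, repeats = 2, seed = 7),
                         max_expected_r2 = 0.48)
  expect_s3_class(m, "homeostasis_model")
  expect_equal(m$report$r2_test, m$report$r_test^2, tolerance = 1e-12)
  # test ids never intersect training ids
  expect_length(intersect(m$split$test_ids, m$split$traincv_ids), 0)
  # predict on the original matrix reproduces the stored test predictions
  pr <- predict(m, fm[m$split$test_ids, , drop = FALSE])
  expect_equal(unname(pr), unname(m$test_predictions))
  expect_equal(unname(residuals(m)),
               unname(m$test_observed - m$test_predictions))
  cf <- coef(m)
  expect_true("(Intercept)" %in% names(cf))
  expect_output(print(m), "elastic_linear")
  expect_output(summary(m), "test proteins")
  pom <- m$report$percent_of_max
  expect_equal(pom$percent, round(100 * m$report$r2_test / 0.48))
})

test_that("percent-of-maximum reproduces the worked arithmetic", {
  expect_equal(percent_of_max(0.17, 0.48)$percent, 35)
  expect_equal(percent_of_max(0.21, 0.48)$percent, 44)
  expect_equal(percent_of_max(0.39, 0.48)$percent, 81)
  expect_equal(percent_of_max(0.3, 0.3)$percent, 100)
  expect_equal(percent_of_max(0.17, 0.48)$raw, 100 * 0.17 / 0.48)
  expect_error(percent_of_max(0.2, 0), "positive")
})

test_that("importances are scaled to 100, grouped consistently, and find a
           planted driver", {
  # response driven solely by Ala and Asp composition
  coh <- small_cohort(300, seed = 37)
  fm <- assemble_feature_matrix(coh$records)
  set.seed(1)
  y <- setNames(2 * fm[, "aa_A"] - 2 * fm[, "aa_D"] + rnorm(nrow(fm), sd = 1),
                rownames(fm))
  spec <- split_spec(folds = 5, repeats = 2, seed = 5)
  for (lrn in c("elastic_linear", "ensemble_trees")) {
    m <- homeostasis_model(fm, y, learner = lrn, spec = spec)
    imp <- m$importances
    expect_equal(max(imp$scaled), 100)
    expect_true(all(imp$scaled >= 0 & imp$scaled <= 100))
    # scaling is invariant to positive rescaling of raw importances
    expect_equal(imp$scaled, 100 * (7.3 * imp$raw) / max(7.3 * imp$raw))
    # group sums equal member sums
    g <- imp$groups
    sh <- g[g$group == "small_hydrophobic" & g$block == "amino_acid", ]
    expect_equal(sh$importance,
                 sum(imp$scaled[paste0("aa_", c("A", "I", "L", "V"))]))
    ct <- codon_table()
    cod <- paste0("codon_", ct$codon[ct$aa %in% c("D", "E", "N", "Q")])
    np <- g[g$group == "negative_polar" & g$block == "codon", ]
    expect_equal(np$importance,
                 sum(imp$scaled[intersect(cod, names(imp$scaled))]))
    # the planted drivers top the ranking
    top2 <- names(sort(imp$scaled, decreasing = TRUE))[1:2]
    expect_setequal(top2, c("aa_A", "aa_D"))
  }
})

test_that("filtering changes the feature count but barely the error", {
  coh <- small_cohort(300, seed = 41)
  fm <- assemble_feature_matrix(coh$records)
  y <- coh$responses$lifetime
  spec <- split_spec(folds = 5, repeats = 2, seed = 3)
  m_on <- homeostasis_model(fm, y, learner = "elastic_linear", spec = spec,
                            filter = TRUE, importance = FALSE)
  m_off <- homeostasis_model(fm, y, learner = "elastic_linear", spec = spec,
                             filter = FALSE, importance = FALSE)
  expect_lt(length(m_on$transform$keep), ncol(fm))
  expect_equal(length(m_off$transform$keep), ncol(fm))
  expect_lt(abs(m_on$report$rmse_test - m_off$report$rmse_test),
            0.1 * m_off$report$rmse_test)
})

test_that("learning curves show the bias/variance signatures", {
  cfg <- synthetic_config(n_proteins = 300, length_range = c(50, 150),
                          effect_map = c(aa_A = 2, aa_D = -2),
                          target_r2 = 1, seed = 43)
  coh <- plant_response(generate_cds_cohort(cfg))
  fm <- assemble_feature_matrix(coh$records)
  y <- coh$responses$lifetime
  spec <- split_spec(folds = 5, repeats = 1, seed = 1)
  lc <- learning_curve(fm, y, spec, "greedy_forward_backward",
                       sizes = c(80, 160, 280))
  expect_equal(lc$n, c(80, 160, 280))
  # noiseless linear signal: both errors collapse toward zero at large n
  expect_lt(lc$rmse_cv[3], 0.1 * sd(y))
  # cv error never beats training error systematically
  expect_true(all(lc$rmse_cv >= lc$rmse_train - 1e-8))
  # pure noise: training error rises toward the noise sd with n
  set.seed(2)
  y0 <- setNames(rnorm(nrow(fm)), rownames(fm))
  lc0 <- learning_curve(fm, y0, spec, "elastic_linear",
                        sizes = c(80, 280))
  expect_equal(lc0$rmse_cv[2], sd(y0), tolerance = 0.15)
  expect_error(learning_curve(fm, y, spec, "elastic_linear",
                              sizes = c(100, 50)), "increasing")
})
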