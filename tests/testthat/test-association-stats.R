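test_that("pearson_r matches the closed-form oracle and flags constants", {
  expect_equal(pearson_r(1:10, 2 * (1:10) + 1), 1)
  expect_equal(pearson_r(1:10, -(1:10)), -1)
  expect_equal(pearson_r(c(1, 2, 3, 4), c(1, 3, 2, 4)), 0.8)
  set.seed(40)
  for (i in 1:10) {
    x <- rnorm(15); y <- rnorm(15)
    expect_equal(pearson_r(x, y), pearson_oracle(x, y))
    # symmetry and affine invariance
    expect_equal(pearson_r(x, y), pearson_r(y, x))
    expect_equal(pearson_r(2 * x + 3, y), pearson_r(x, y))
  }
  const <- pearson_r(rep(1, 5), rnorm(5))
  expect_true(is.na(const) && attr(const, "undefined"))
  expect_error(pearson_r(1:4, 1:5), "lengths differ")
  expect_error(pearson_r(1:2, 1:2), "at least 3")
})

test_that("correlation profiles aggregate per-dataset r values", {
  coh <- small_cohort()
  fm <- assemble_feature_matrix(coh$records)
  y <- coh$responses$lifetime

  p1 <- correlation_profile(fm, y)
  expect_true(p1$single_dataset)
  expect_equal(unname(p1$mean_r["aa_A"]),
               cor(fm[, "aa_A"], y[rownames(fm)]))
  expect_true(all(p1$sem_r == 0))

  p2 <- correlation_profile(fm, list(a = y, b = y))
  expect_equal(p2$mean_r, p1$mean_r)
  expect_true(all(p2$sem_r == 0))
  expect_true(all(abs(p2$r) <= 1, na.rm = TRUE))

  # planted wobble effect: a G/C-ending codon correlates positively, an
  # A/U-ending one negatively
  expect_gt(p1$mean_r["codon_GCC"], 0)
  expect_lt(p1$mean_r["codon_GCA"], 0)

  # datasets with too few shared proteins are skipped with a warning
  tiny <- y[1:2]
  expect_warning(p3 <- correlation_profile(fm, list(a = y, b = tiny)),
                 "fewer than 3")
  expect_equal(p3$n_datasets, 1L)
})

test_that("wobble summary reproduces a brute-force scan over the table", {
  coh <- small_cohort()
  fm <- assemble_feature_matrix(coh$records)
  resp <- list()
  c2 <- coh
  for (i in 1:4) {
    c2 <- plant_response(c2, c2$config, paste0("ds", i))
    resp[[paste0("ds", i)]] <- c2$responses[[paste0("ds", i)]]
  }
  prof <- correlation_profile(fm, resp)
  ws <- wobble_group_summary(prof)
  expect_equal(nrow(ws), 21L)
  expect_equal(sum(ws$aa %in% c("L", "R", "S")), 6L)

  # brute-force per-class means from the raw profile
  ct <- codon_table()
  for (i in sample(nrow(ws), 5)) {
    g <- ws$subgroup[i]
    gc_cod <- ct$codon[!is.na(ct$subgroup) & ct$subgroup == g &
                         ct$wobble_class == "GC_ending"]
    au_cod <- ct$codon[!is.na(ct$subgroup) & ct$subgroup == g &
                         ct$wobble_class == "AU_ending"]
    gc_ref <- mean(colMeans(prof$r[paste0("codon_", gc_cod), , drop = FALSE]))
    au_ref <- mean(colMeans(prof$r[paste0("codon_", au_cod), , drop = FALSE]))
    expect_equal(ws$gc_mean_r[i], gc_ref)
    expect_equal(ws$au_mean_r[i], au_ref)
    expect_equal(ws$difference[i], gc_ref - au_ref)
  }

  # all-equal correlations give zero differences and no significance
  prof_const <- prof
  prof_const$r[] <- 0.3
  ws0 <- wobble_group_summary(prof_const)
  expect_true(all(ws0$difference == 0))
  expect_false(any(ws0$p_value < 0.05, na.rm = TRUE))
})

test_that("null wobble effect centres the GC>AU count near 10.5", {
  # with no planted wobble contrast the per-subgroup sign is a coin flip
  counts <- vapply(1:6, function(s) {
    cfg <- synthetic_config(n_proteins = 120, length_range = c(50, 100),
                            effect_map = c(aa_A = 1), target_r2 = 0.3,
                            seed = 100 + s)
    coh <- plant_response(generate_cds_cohort(cfg))
    fm <- assemble_feature_matrix(coh$records)
    prof <- correlation_profile(fm, coh$responses["lifetime"])
    attr(wobble_group_summary(prof), "n_gc_gt_au")
  }, numeric(1))
  expect_gt(mean(counts), 21 * 0.5 - 5)
  expect_lt(mean(counts), 21 * 0.5 + 5)
})

test_that("N-end-rule association behaves at its limits", {
  coh <- small_cohort(200, seed = 19)
  recs <- coh$records
  AA <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
  rule <- setNames(seq_along(AA), AA)
  nterm <- substr(recs$protein, 2, 2)
  # response exactly equal to the mapped rule values
  y_exact <- setNames(rule[nterm], recs$id)
  expect_equal(nend_rule_association(recs, y_exact, rule)$r2, 1)
  # response independent of the N-terminus
  y_null <- coh$responses$lifetime
  expect_lt(nend_rule_association(recs, y_null, rule)$r2, 0.05)
  # shuffled map gives a different association on planted data
  set.seed(3)
  rule_shuf <- setNames(sample(rule), names(rule))
  r_a <- nend_rule_association(recs, y_exact, rule)$r2
  r_b <- nend_rule_association(recs, y_exact, rule_shuf)$r2
  expect_false(isTRUE(all.equal(r_a, r_b)))
  expect_error(nend_rule_association(recs, y_exact, rule[1:5]),
               "lacks residues")
})

test_that("motif screen finds a planted degron and flags degenerate motifs", {
  coh <- small_cohort(400, seed = 23)
  recs <- coh$records
  carriers <- grepl("DE", recs$protein)
  # ensure both classes exist in the fixture
  expect_gt(sum(carriers), 5)
  expect_gt(sum(!carriers), 5)
  set.seed(5)
  y <- setNames(rnorm(nrow(recs)) + 3 * carriers, recs$id)
  res <- motif_association(recs, y, c("DE", "WWWWWW"))
  expect_gt(res$r[1], 0)
  expect_lt(res$p_adjusted[1], 0.05)
  expect_true(res$undefined[2])   # motif absent everywhere
  res_all <- motif_association(recs, y, c("."))
  expect_true(res_all$undefined[1])  # motif present in every protein
  expect_error(motif_association(recs, y, ""), "empty motif")
})

test_that("cross-parameter matrix squares pairwise correlations", {
  st <- study_cohort()
  st <- plant_response(st, st$config, "ds1")
  st <- plant_response(st, st$config, "ds2", replicate_of = "ds1")
  cfg0 <- st$config
  cfg0$target_r2 <- 0
  st <- plant_response(st, cfg0, "indep")
  m <- cross_parameter_matrix(st$responses)
  expect_equal(diag(m), c(ds1 = 1, ds2 = 1, indep = 1))
  expect_equal(m, t(m))
  # replicate pair designed at r = 0.69 lands near r2 = 0.476
  expect_equal(m["ds1", "ds2"], 0.69^2, tolerance = 0.05 / 0.476)
  # an independently planted response shares no signal by construction
  # with the pure-noise dataset
  expect_lt(m["ds2", "indep"], 0.08)
  expect_error(cross_parameter_matrix(st$responses["ds1"]), "at least 2")
})
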