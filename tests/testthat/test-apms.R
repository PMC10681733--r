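test_that("imputation retains the valid-in-one-group rule and is seeded", {
  # feature observed once in every group is dropped under min_valid = 2
  m <- matrix(rnorm(4 * 4, 25, 2), 4, 4,
              dimnames = list(paste0("P", 1:4), paste0("s", 1:4)))
  m[1, c(2, 4)] <- NA                      # one valid per group -> dropped
  m[2, 4] <- NA                            # 2 valid in group A -> kept
  qt <- toy_table(m)
  out <- impute_missing(qt, toy_design(), imputation_params(seed = 1))
  expect_setequal(feature_ids(out), c("P2", "P3", "P4"))
  expect_false(anyNA(out$intensities))
  # identical seeds reproduce the draws exactly
  out2 <- impute_missing(qt, toy_design(), imputation_params(seed = 1))
  expect_identical(out$intensities, out2$intensities)
  # a complete table passes through unchanged
  full <- toy_table(matrix(rnorm(12, 25, 2), 3, 4))
  same <- impute_missing(full, toy_design(), imputation_params(seed = 1))
  expect_identical(same$intensities, full$intensities)
})

test_that("imputed draws sit below the observed distribution (left-censoring)", {
  set.seed(21)
  m <- matrix(rnorm(3000 * 4, 25, 2), 3000, 4,
              dimnames = list(sprintf("P%04d", 1:3000), paste0("s", 1:4)))
  m[1501:3000, 3] <- NA   # all these features stay valid via group A
  qt <- toy_table(m)
  out <- impute_missing(qt, toy_design(), imputation_params(seed = 2))
  drawn <- out$intensities[1501:3000, 3]
  obs <- m[1:1500, 3]
  mu_exp <- mean(obs) - 1.8 * sd(obs)
  expect_equal(mean(drawn), mu_exp, tolerance = 0.05)
  expect_equal(sd(drawn), 0.3 * sd(obs), tolerance = 0.05)
  # the imputed distribution sits in the left tail of the observed one
  expect_lt(mean(drawn), quantile(obs, 0.05))
  expect_gt(mean(drawn < mean(obs)), 0.999)
})

test_that("a sample with fewer than two observed values cannot be imputed", {
  m <- matrix(rnorm(12, 25, 2), 3, 4,
              dimnames = list(paste0("P", 1:3), paste0("s", 1:4)))
  m[2:3, 4] <- NA; m[1, 2] <- NA  # s4 has a single observed value
  expect_error(impute_missing(toy_table(m), toy_design(),
                              imputation_params()), "s4")
})

test_that("background detection isolates the unregulated cluster", {
  set.seed(31)
  n_bg <- 900; n_en <- 100
  base <- rnorm(n_bg + n_en, 25, 1)
  m <- matrix(base, n_bg + n_en, 6) + rnorm((n_bg + n_en) * 6, 0, 0.2)
  m[(n_bg + 1):(n_bg + n_en), 1:3] <- m[(n_bg + 1):(n_bg + n_en), 1:3] + 5
  dimnames(m) <- list(sprintf("P%04d", 1:(n_bg + n_en)), paste0("s", 1:6))
  qt <- toy_table(m)
  des <- toy_design(reps = 3, groups = c("bait", "ctrl"))
  bg <- detect_background_cluster(qt, des, "bait", "ctrl", k = 2, seed = 5)
  expect_gte(mean(feature_ids(qt)[1:n_bg] %in% bg), 0.95)
  expect_lte(mean(feature_ids(qt)[(n_bg + 1):(n_bg + n_en)] %in% bg), 0.05)
  # tri-modal case: the middle (null) cluster is returned
  m3 <- m
  m3[1:100, 1:3] <- m3[1:100, 1:3] - 5   # depleted tail
  qt3 <- toy_table(m3)
  bg3 <- detect_background_cluster(qt3, des, "bait", "ctrl", k = 3, seed = 5)
  expect_gte(mean(feature_ids(qt)[101:n_bg] %in% bg3), 0.95)
  expect_lte(mean(c(feature_ids(qt)[1:100],
                    feature_ids(qt)[(n_bg + 1):(n_bg + n_en)]) %in% bg3), 0.05)
  # identical features collapse to a single returned cluster
  flat <- toy_table(matrix(25, 10, 6,
                           dimnames = list(paste0("P", 1:10),
                                           paste0("s", 1:6))))
  expect_setequal(detect_background_cluster(flat, des, "bait", "ctrl",
                                            k = 3, seed = 1),
                  feature_ids(flat))
})

test_that("background renormalization aligns sample medians and preserves contrasts", {
  set.seed(41)
  m <- matrix(rnorm(200 * 4, 25, 1), 200, 4,
              dimnames = list(sprintf("P%03d", 1:200), paste0("s", 1:4)))
  qt <- toy_table(m)
  shifted <- qt
  shifted$intensities[, 2] <- shifted$intensities[, 2] + 2
  bg <- feature_ids(qt)[1:150]
  ren <- renormalize_to_background(shifted, bg)
  med <- apply(ren$intensities[bg, ], 2, median)
  expect_lt(max(med) - min(med), 1e-9)
  # within-sample feature differences are untouched
  d0 <- shifted$intensities[1, ] - shifted$intensities[2, ]
  d1 <- ren$intensities[1, ] - ren$intensities[2, ]
  expect_equal(d1, d0, tolerance = 1e-12)
  # already-aligned background medians: a no-op
  aligned <- renormalize_to_background(ren, bg)
  expect_equal(aligned$intensities, ren$intensities, tolerance = 1e-12)
  expect_error(renormalize_to_background(qt, character(0)), "non-empty")
  expect_error(renormalize_to_background(qt, "nope"), "absent")
})

test_that("renormalization recovers true enrichment under per-sample shifts", {
  set.seed(51)
  sim <- simulate_apms_experiment(n_features = 1000, n_interactors = 30,
                                  effect_range = c(3, 6), seed = 51)
  des <- sim$design
  lg <- log2_transform(sim$table)
  imp <- impute_missing(lg, des, imputation_params(seed = 51))
  bg <- detect_background_cluster(imp, des, "bait", "ctrl", k = 3, seed = 51)
  ren <- renormalize_to_background(imp, bg)
  fit <- moderated_ttest(ren, des, "bait", "ctrl")
  truth <- sim$truth$interactors
  est <- coef(fit)[truth$feature_id]
  # the down-shifted imputation of censored control values leaves a small
  # upward bias on strong enrichments; it must stay well under the smallest
  # simulated effect
  expect_lt(abs(mean(est - truth$effect, na.rm = TRUE)), 0.25)
  # fully-censored controls are imputed at the down-shift centre, which
  # attenuates the largest effects; typical per-feature error stays small
  expect_lt(median(abs(est - truth$effect), na.rm = TRUE), 0.5)
  expect_gt(cor(est, truth$effect, use = "complete.obs"), 0.6)
})

test_that("enrichment calls require both fold-change and FDR cutoffs", {
  res <- data.frame(feature_id = c("a", "b", "c"),
                    log2_fc = c(1.0, 0.5, -1.2),
                    adj_p = c(0.01, 0.001, 0.02))
  calls <- call_enriched(res, threshold_config(1.5, 0.05))
  expect_equal(as.character(calls$direction), c("enriched", "ns", "depleted"))
  empty <- call_enriched(res[integer(0), ], threshold_config(1.5, 0.05))
  expect_equal(nrow(empty), 0)
})

test_that("the null AP-MS workflow makes almost no calls", {
  frac <- vapply(1:10, function(s) {
    sim <- simulate_apms_experiment(n_features = 1000, n_interactors = 0,
                                    seed = 100 + s)
    run <- run_apms_workflow(sim$table, sim$design, "bait", "ctrl",
                             impute = imputation_params(seed = 100 + s))
    mean(run$calls$direction != "ns")
  }, 0)
  expect_lte(mean(frac), 0.01)
})

test_that("the workflow is reproducible and logs its parameters", {
  sim <- simulate_apms_experiment(n_features = 400, n_interactors = 10,
                                  seed = 61)
  r1 <- run_apms_workflow(sim$table, sim$design, "bait", "ctrl",
                          impute = imputation_params(seed = 61),
                          background_renorm = TRUE)
  r2 <- run_apms_workflow(sim$table, sim$design, "bait", "ctrl",
                          impute = imputation_params(seed = 61),
                          background_renorm = TRUE)
  expect_identical(r1$results$table, r2$results$table)
  expect_identical(r1$calls, r2$calls)
  expect_identical(r1$background, r2$background)
  expect_true(r1$log$background_renorm)
  expect_equal(r1$log$imputation$shift, 1.8)
  expect_equal(r1$log$imputation$width, 0.3)
  expect_false(is.null(r1$first_pass))
})
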