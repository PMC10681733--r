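# helper: two-plex design with one sample group per plex plus references
two_plex_design <- function() {
  sample_design(data.frame(
    sample_id = c("a1", "a2", "r1", "b1", "b2", "r2"),
    group = c("gA", "gA", NA, "gB", "gB", NA),
    replicate = c(1, 2, 1, 1, 2, 1),
    plex_id = rep(c("p1", "p2"), each = 3),
    channel = rep(c("126C", "127N", "131N"), 2),
    is_reference = rep(c(FALSE, FALSE, TRUE), 2),
    stringsAsFactors = FALSE))
}

test_that("impurity matrices enforce their structural invariants", {
  expect_error(impurity_matrix(matrix(1, 2, 3)), "square")
  expect_error(impurity_matrix(matrix(c(0.4, 0.6, 0.6, 0.4), 2, 2,
                                      dimnames = list(NULL, c("a", "b")))),
               "diagonal")
  expect_error(impurity_matrix(matrix(c(0.9, 0.2, 0.1, 0.9), 2, 2,
                                      dimnames = list(NULL, c("a", "b")))),
               "sum")
  expect_error(impurity_matrix(matrix(c(1, 1, 1, 1) * 0.51, 2, 2,
                                      dimnames = list(NULL, c("a", "b")))),
               "singular")
  id <- identity_impurity(c("126C", "127N"))
  expect_s3_class(id, "impurity_matrix")
  expect_equal(unclass(id), diag(2) |>
                 `dimnames<-`(list(c("126C", "127N"), c("126C", "127N"))))
})

test_that("impurity correction solves the linear mixing model", {
  M <- impurity_matrix(matrix(c(0.9, 0.1, 0.1, 0.9), 2, 2,
                              dimnames = list(NULL, c("c1", "c2"))))
  obs <- matrix(c(0.9, 0.1), 1, 2, dimnames = list("f1", c("c1", "c2")))
  corr <- correct_isotope_impurities(obs, M)
  expect_equal(unname(corr[1, ]), c(1, 0), tolerance = 1e-12)
  # mix-then-correct round trip on a random 10-channel matrix
  channels <- c("126C", "127N", "127C", "128N", "128C",
                "129N", "129C", "130N", "130C", "131N")
  imp <- ddrquant:::.make_impurity(channels)
  set.seed(13)
  true <- matrix(2^rnorm(200 * 10, 20, 2), 200, 10,
                 dimnames = list(sprintf("f%03d", 1:200), channels))
  mixed <- t(unclass(imp) %*% t(true))
  dimnames(mixed) <- dimnames(true)
  rec <- correct_isotope_impurities(mixed, imp)
  expect_lt(max(abs(rec - true) / true), 1e-8)
  # missing stays missing; over-correction yields missing, not negatives
  obs2 <- matrix(c(NA, 0.05, 1e-9, 1), 2, 2,
                 dimnames = list(c("f1", "f2"), c("c1", "c2")))
  corr2 <- correct_isotope_impurities(obs2, M)
  expect_true(is.na(corr2["f1", "c1"]))
  expect_true(all(is.na(corr2) | corr2 >= 0))
  expect_error(correct_isotope_impurities(obs[, 2:1, drop = FALSE], M),
               "order")
})

test_that("within-plex median normalization equalizes sample medians only", {
  set.seed(17)
  m <- matrix(rnorm(100 * 3, 20, 1), 100, 3,
              dimnames = list(sprintf("f%03d", 1:100), c("a1", "a2", "r1")))
  m[, 2] <- m[, 2] + 1.3
  qt <- toy_table(m, scale = "log2")
  norm <- median_normalize_within_plex(qt)
  med <- apply(norm$intensities, 2, median, na.rm = TRUE)
  expect_lt(max(med) - min(med), 1e-9)
  expect_equal(median(med), median(apply(m, 2, median)))
  # per-sample shift only: within-sample contrasts unchanged
  expect_equal(norm$intensities[1, ] - norm$intensities[2, ],
               m[1, ] - m[2, ], tolerance = 1e-12)
  expect_error(median_normalize_within_plex(toy_table(2^m, scale = "linear")),
               "log2")
})

test_that("IRS anchors each feature to the geometric mean of its references", {
  des <- two_plex_design()
  feats <- data.frame(feature_id = c("f1", "f2"),
                      razor_unique_peptides = 10L)
  p1 <- quant_table(matrix(c(10, 10, 11, 11, log2(100), 12), 2, 3,
                           dimnames = list(c("f1", "f2"),
                                           c("a1", "a2", "r1"))),
                    feats, "log2")
  p2 <- quant_table(matrix(c(14, 14, 15, 15, log2(400), NA), 2, 3,
                           dimnames = list(c("f1", "f2"),
                                           c("b1", "b2", "r2"))),
                    feats, "log2")
  out <- irs_normalize(list(p1 = p1, p2 = p2), des)
  # f2 lacks an observed reference in plex 2 and is dropped
  expect_equal(feature_ids(out), "f1")
  # anchor = mean(log2 100, log2 400) = log2 200 (geometric mean on linear)
  anchor <- mean(c(log2(100), log2(400)))
  expect_equal(out$intensities["f1", "r1"], anchor, tolerance = 1e-12)
  expect_equal(out$intensities["f1", "r2"], anchor, tolerance = 1e-12)
  shift1 <- anchor - log2(100)
  expect_equal(out$intensities["f1", c("a1", "a2")],
               c(a1 = 10, a2 = 11) + shift1, tolerance = 1e-12)
  # reference channels agree exactly across plexes after IRS
  expect_equal(out$intensities["f1", "r1"], out$intensities["f1", "r2"])
})

test_that("IRS removes a pure between-plex batch effect", {
  des <- two_plex_design()
  set.seed(19)
  base <- rnorm(300, 20, 2)
  noise <- function() rnorm(300, 0, 0.05)
  feats <- data.frame(feature_id = sprintf("f%03d", 1:300),
                      razor_unique_peptides = 10L)
  mk <- function(batch, samples) {
    m <- cbind(base + noise(), base + noise(), base + noise()) + batch
    dimnames(m) <- list(feats$feature_id, samples)
    quant_table(m, feats, "log2")
  }
  p1 <- mk(0, c("a1", "a2", "r1"))
  p2 <- mk(3, c("b1", "b2", "r2"))   # plex 2 shifted wholesale by +3
  out <- irs_normalize(list(p1 = p1, p2 = p2), des)
  diff <- rowMeans(out$intensities[, c("a1", "a2")]) -
    rowMeans(out$intensities[, c("b1", "b2")])
  expect_lt(abs(mean(diff)), 0.02)
  expect_lt(sd(diff), 0.2)
})

test_that("site-to-protein normalization cancels protein-level changes", {
  des <- two_plex_design()
  prot <- toy_table(matrix(c(20, 20, 20, 21, 21, 21), 1, 6,
                           dimnames = list("PAR1",
                                           c("a1", "a2", "r1",
                                             "b1", "b2", "r2"))),
                    scale = "log2")
  sm <- matrix(c(18, 18, 18, 19, 19, 19), 2, 6, byrow = TRUE,
               dimnames = list(NULL, colnames(prot$intensities)))
  sm[2, ] <- sm[2, ] + c(0, 0, 0, 1, 1, 1)  # extra site-level change
  st <- toy_site_table(sm, parents = c("PAR1", "PAR1"),
                       positions = c(5, 9),
                       windows = rep(toy_window(), 2), scale = "log2")
  rel <- normalize_sites_to_protein(st, prot)
  # site 1 tracks its protein exactly: flat after normalization
  expect_equal(unname(diff(range(rel$intensities["PAR1_5_1", ]))), 0)
  # site 2 keeps only its occupancy change of +1 in the b samples
  expect_equal(unname(rel$intensities["PAR1_9_1", "b1"] -
                        rel$intensities["PAR1_9_1", "a1"]), 1)
  # sites with unquantified parents are dropped
  orphan <- toy_site_table(sm, parents = c("PAR1", "NOPE"),
                           positions = c(5, 9),
                           windows = rep(toy_window(), 2), scale = "log2")
  expect_equal(feature_ids(normalize_sites_to_protein(orphan, prot)),
               "PAR1_5_1")
})

test_that("the full TMT chain recovers simulated site regulation", {
  sim <- simulate_tmt_ptm_experiment(n_proteins = 400, seed = 23)
  run <- run_tmt_workflow(sim$proteins, sim$design, sites = sim$sites,
                          impurity = sim$impurity,
                          comparisons = list(c("WT_etop", "WT_untr")))
  expect_s3_class(run, "tmt_run")
  expect_named(run$sites$fits, "WT_etop_vs_WT_untr")
  fit <- run$sites$fits[[1]]
  truth <- sim$truth$regulated_sites
  est <- coef(fit)[truth$site_key]
  bias <- mean(est - truth$effect, na.rm = TRUE)
  expect_lt(abs(bias), 0.1)
  calls <- call_regulated_sites(fit, "phospho")
  hit <- calls$feature_id[calls$direction != "ns"]
  sens <- mean(truth$site_key %in% hit)
  expect_gte(sens, 0.9)
  null_rate <- mean(setdiff(calls$feature_id, truth$site_key) %in% hit)
  expect_lte(null_rate, 0.05)
  # reference channels never appear in the testable tables
  expect_false(any(grepl("^REF", sample_ids(run$sites$table))))
  expect_false(any(grepl("^REF", sample_ids(run$proteins$table))))
})

test_that("the TMT chain warns and proceeds without an impurity matrix", {
  sim <- simulate_tmt_ptm_experiment(n_proteins = 60, seed = 29)
  expect_warning(
    run <- run_tmt_workflow(sim$proteins, sim$design,
                            comparisons = list(c("WT_etop", "WT_untr"))),
    "identity")
  expect_s3_class(run, "tmt_run")
  expect_true(is.na(run$log$n_sites))
})

test_that("mutant attenuation survives the normalization chain", {
  sim <- simulate_tmt_ptm_experiment(n_proteins = 400, seed = 31)
  run <- run_tmt_workflow(sim$proteins, sim$design, sites = sim$sites,
                          impurity = sim$impurity,
                          comparisons = list(c("WT_etop", "WT_untr"),
                                             c("KO_etop", "KO_untr")))
  truth <- sim$truth$regulated_sites
  wt <- coef(run$sites$fits[["WT_etop_vs_WT_untr"]])[truth$site_key]
  ko <- coef(run$sites$fits[["KO_etop_vs_KO_untr"]])[truth$site_key]
  keep <- is.finite(wt) & is.finite(ko)
  slope <- coef(lm(ko[keep] ~ 0 + wt[keep]))[[1]]
  expect_equal(slope, unname(sim$truth$attenuation["KO"]), tolerance = 0.1)
})
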