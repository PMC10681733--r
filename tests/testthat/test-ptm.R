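test_that("regulated-site calls use dataset-specific default cutoffs", {
  res <- data.frame(feature_id = c("s1", "s2", "s3", "s4"),
                    log2_fc = c(log2(1.6), log2(1.6), -log2(2.2), log2(2.2)),
                    adj_p = c(0.01, 0.2, 0.005, 0.02))
  ph <- call_regulated_sites(res, "phospho")
  expect_equal(as.character(ph$direction), c("up", "ns", "down", "up"))
  # acetylome cutoffs are stricter: FC 2 / FDR 0.01
  ac <- call_regulated_sites(res, "acetyl")
  expect_equal(as.character(ac$direction), c("ns", "ns", "down", "ns"))
  # explicit thresholds override the dataset defaults
  ov <- call_regulated_sites(res, "acetyl", threshold_config(1.5, 0.05))
  expect_equal(as.character(ov$direction), as.character(ph$direction))
  expect_equal(attr(ac, "dataset"), "acetyl")
})

test_that("wildtype-responsive, mutant-stable intersection behaves", {
  wt <- data.frame(feature_id = c("a", "b", "c", "d"),
                   direction = factor(c("up", "down", "ns", "up"),
                                      levels = c("up", "down", "ns")))
  mu1 <- data.frame(feature_id = c("a", "b", "c", "d"),
                    direction = factor(c("ns", "down", "ns", "ns"),
                                       levels = c("up", "down", "ns")))
  mu2 <- data.frame(feature_id = c("a", "b", "c", "d"),
                    direction = factor(c("ns", "ns", "ns", "up"),
                                       levels = c("up", "down", "ns")))
  # b responds in mutant 1, d in mutant 2; only a is WT-specific
  expect_equal(responsive_in_wt_stable_in_mutants(wt, list(mu1, mu2)), "a")
  expect_setequal(responsive_in_wt_stable_in_mutants(wt, list()),
                  c("a", "b", "d"))
  bad <- data.frame(feature_id = "zzz", direction = factor("ns"))
  expect_error(responsive_in_wt_stable_in_mutants(wt, list(bad)), "shares no")
})

test_that("SQ-motif annotation reads the window center exactly", {
  w <- c(toy_window("S", "Q"), toy_window("S", "A"), toy_window("T", "Q"),
         toy_window("S", "Q", width = 15))
  expect_equal(annotate_sq_motif(w), c(TRUE, FALSE, FALSE, TRUE))
  expect_equal(annotate_sq_motif(w, include_tq = TRUE),
               c(TRUE, FALSE, TRUE, TRUE))
  expect_error(annotate_sq_motif("SQA"), NA)   # length 3 is the minimum
  expect_error(annotate_sq_motif("SQ"), "odd")
  expect_error(annotate_sq_motif(toy_window("T", "Q"), residue = "S"),
               "center")
  # generated windows agree with their recorded truth
  gw <- generate_sequence_windows(200, 120, seed = 3)
  expect_equal(annotate_sq_motif(gw), attr(gw, "is_sq"))
  expect_equal(sum(annotate_sq_motif(gw)), 120)
})

test_that("SQ fractions are percentages rounded to one decimal", {
  flags <- c(a = TRUE, b = TRUE, c = TRUE, d = FALSE)
  expect_identical(sq_fraction(c("a", "b", "c", "d"), flags), 75.0)
  expect_identical(sq_fraction(c("a", "d"), flags), 50.0)
  expect_error(sq_fraction(character(0), flags), "empty")
  expect_error(sq_fraction(c("a", "zz"), flags), "annotated")
})

test_that("fold-change scatter comparisons join, filter and correlate", {
  set.seed(37)
  wt <- setNames(rnorm(100), paste0("s", 1:100))
  mut <- 0.5 * wt + rnorm(100, 0, 0.1)
  names(mut) <- names(wt)
  sq <- setNames(rep(c(TRUE, FALSE), 50), names(wt))
  all_r <- compare_fc_scatter(wt, mut)
  expect_gt(all_r$r_squared, 0.8)
  expect_equal(nrow(all_r$table), 100)
  sq_r <- compare_fc_scatter(wt, mut, sq_flags = sq, site_filter = "sq")
  expect_equal(sq_r$table$site_key, names(wt)[sq])
  nsq_r <- compare_fc_scatter(wt, mut, sq_flags = sq, site_filter = "non_sq")
  expect_equal(nrow(sq_r$table) + nrow(nsq_r$table), 100)
  expect_error(compare_fc_scatter(wt, mut, site_filter = "sq"), "sq_flags")
  expect_error(compare_fc_scatter(wt[1:2], mut[1:2]), "fewer than 3")
})

test_that("ortholog mapping partitions features into mapped/ambiguous/excluded", {
  orth <- data.frame(species_a = c("hA", "hB", "hB", "hB"),
                     species_b = c("mA", "mB1", "mB2", "mB1"))
  res <- map_orthologs(c("hA", "hB", "hC"), orth)
  expect_equal(res$mapping$hA, "mA")
  expect_setequal(res$mapping$hB, c("mB1", "mB2"))  # duplicate pair dropped
  expect_equal(res$ambiguous, "hB")
  expect_equal(res$excluded, "hC")
})

test_that("external SILAC ratios integrate by gene/position/window key", {
  st <- toy_site_table(matrix(20, 3, 2),
                       parents = c("P1", "P1", "P2"),
                       positions = c(10, 40, 10),
                       windows = c(toy_window("S", "Q"),
                                   toy_window("S", "A"),
                                   toy_window("S", "K")))
  st$features$gene_name <- c("GENE1", "GENE1", "GENE2")
  ext_sites <- data.frame(gene = c("Gene1", "gene2", "gene3"),
                          position = c(10, 10, 5),
                          window = c(toy_window("S", "Q"),
                                     toy_window("S", "K"),
                                     toy_window("S", "Q")),
                          ratio = c(8, 2, 4))
  ext_prot <- data.frame(gene = c("GENE1", "GENE2"), ratio = c(2, 2))
  out <- integrate_external_ratio_sites(ext_sites, ext_prot, st)
  ann <- setNames(out$features$external_log2_ratio, out$features$feature_id)
  # site ratio 8 over protein ratio 2 -> log2(4) = 2; gene match ignores case
  expect_equal(unname(ann["P1_10_1"]), 2)
  expect_equal(unname(ann["P2_10_1"]), 0)
  expect_true(is.na(ann["P1_40_1"]))  # no external counterpart
  expect_error(integrate_external_ratio_sites(
    transform(ext_sites, ratio = -1), ext_prot, st), "positive")
})

test_that("external integration drops keys matching distinct target sites", {
  w <- toy_window("S", "Q")
  st <- toy_site_table(matrix(20, 2, 2),
                       parents = c("P1", "P9"), positions = c(10, 10),
                       windows = c(w, w))
  st$features$gene_name <- c("GENE1", "GENE1")  # same gene, two accessions
  ext_sites <- data.frame(gene = "GENE1", position = 10, window = w,
                          ratio = 4)
  ext_prot <- data.frame(gene = "GENE1", ratio = 1)
  out <- integrate_external_ratio_sites(ext_sites, ext_prot, st)
  expect_true(all(is.na(out$features$external_log2_ratio)))
  # multiplicity states of one site all inherit the annotation
  st2 <- toy_site_table(matrix(20, 1, 2), parents = "P1", positions = 10,
                        windows = w)
  st2$features$gene_name <- "GENE1"
  extra <- st2$features
  extra$feature_id <- "P1_10_2"
  extra$multiplicity <- 2L
  st2$features <- rbind(st2$features, extra)
  st2$intensities <- rbind(st2$intensities,
                           P1_10_2 = st2$intensities["P1_10_1", ])
  out2 <- integrate_external_ratio_sites(ext_sites, ext_prot, st2)
  expect_equal(out2$features$external_log2_ratio, c(2, 2))
})

test_that("network filtering keeps high-confidence edges and degrees", {
  edges <- data.frame(node1 = c("A", "A", "B", "B", "D"),
                      node2 = c("B", "C", "C", "D", "E"),
                      combined_score = c(0.9, 0.7, 0.65, 0.95, 0.4))
  res <- filter_network_edges(edges)
  expect_equal(nrow(res$edges), 3)          # 0.9, 0.7 (boundary kept), 0.95
  expect_setequal(res$nodes, c("A", "B", "C", "D"))
  expect_equal(res$degrees[["A"]], 2)
  expect_equal(res$degrees[["B"]], 2)
  expect_equal(res$degrees[["C"]], 1)
  keep_all <- filter_network_edges(edges, drop_disconnected = FALSE)
  expect_setequal(keep_all$nodes, c("A", "B", "C", "D", "E"))
  expect_equal(keep_all$degrees[["E"]], 0)
  # self-loops are removed before scoring
  loop <- rbind(edges, data.frame(node1 = "A", node2 = "A",
                                  combined_score = 0.99))
  expect_equal(nrow(filter_network_edges(loop)$edges), 3)
  expect_error(filter_network_edges(edges, min_score = 1.2), "0, 1")
  bad <- transform(edges, combined_score = combined_score * 2)
  expect_error(filter_network_edges(bad), "0, 1")
})

test_that("profile clustering separates opposite response shapes", {
  set.seed(41)
  up <- matrix(rep(c(0, 0, 2, 2), each = 30), 30, 4) + rnorm(120, 0, 0.1)
  dn <- matrix(rep(c(2, 2, 0, 0), each = 30), 30, 4) + rnorm(120, 0, 0.1)
  m <- rbind(up, dn)
  rownames(m) <- sprintf("s%02d", 1:60)
  res <- cluster_site_profiles(m, k = 2, seed = 43)
  expect_equal(length(unique(res$labels[1:30])), 1)
  expect_equal(length(unique(res$labels[31:60])), 1)
  expect_false(res$labels[[1]] == res$labels[[31]])
  expect_equal(names(res$labels), rownames(m))
  expect_equal(dim(res$matrix), dim(m))
  expect_identical(res$labels, cluster_site_profiles(m, 2, seed = 43)$labels)
})
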