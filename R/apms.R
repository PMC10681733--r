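# AP-MS interactome arm: left-censored imputation, background-cluster
# renormalization, differential enrichment, interactor calls.

#' Parameters for left-censored (down-shifted normal) imputation
#'
#' Missing log2 intensities are drawn per sample from
#' \eqn{N(\mu_s, \sigma_s)} with \eqn{\mu_s = \bar x_s - shift \cdot sd_s}
#' and \eqn{\sigma_s = width \cdot sd_s}, where \eqn{\bar x_s} and
#' \eqn{sd_s} are the mean and standard deviation of the sample's observed
#' values. Defaults: shift 1.8, width 0.3, at least 2 valid values required
#' in one experimental group.
#'
#' @param shift down-shift in sample-sd units (default 1.8).
#' @param width width of the imputation distribution in sample-sd units
#'   (default 0.3).
#' @param min_valid_per_group minimum observed values a feature must have in
#'   at least one group to be retained (default 2).
#' @param seed integer seed for the random draws.
#' @return an `imputation_params` object.
#' @export
imputation_params <- function(shift = 1.8, width = 0.3,
                              min_valid_per_group = 2L, seed = 1L) {
  if (!is.numeric(shift) || shift <= 0) stop("`shift` must be > 0", call. = FALSE)
  if (!is.numeric(width) || width <= 0) stop("`width` must be > 0", call. = FALSE)
  stop_if_not_count(min_valid_per_group, "min_valid_per_group", min = 1L)
  structure(list(shift = shift, width = width,
                 min_valid_per_group = as.integer(min_valid_per_group),
                 seed = as.integer(seed)),
            class = "imputation_params")
}

#' Impute left-censored missing intensities
#'
#' Retains features with at least `min_valid_per_group` observed values in
#' one experimental group, then replaces every remaining missing entry by a
#' draw from the sample's down-shifted normal distribution (see
#' [imputation_params()]). Per-sample distribution parameters are estimated
#' from observed (never imputed) values only. Draws are seeded and
#' reproducible; a table without missing values is returned unchanged.
#'
#' @param table a log2-scale [quant_table].
#' @param design a [sample_design()] covering the table's samples.
#' @param params an [imputation_params()].
#' @return the imputed [quant_table]; attribute `"imputed_mask"` marks which
#'   entries were drawn.
#' @export
impute_missing <- function(table, design, params = imputation_params()) {
  stopifnot(inherits(table, "quant_table"), inherits(params, "imputation_params"))
  if (table$scale != "log2")
    stop("imputation operates on log2 scale", call. = FALSE)
  groups <- design_groups(design, sample_ids(table))
  m <- table$intensities
  glab <- unique(groups[!is.na(groups)])
  valid_by_group <- vapply(glab, function(g)
    rowSums(!is.na(m[, which(groups == g), drop = FALSE])), numeric(nrow(m)))
  if (is.null(dim(valid_by_group)))
    valid_by_group <- matrix(valid_by_group, nrow = nrow(m))
  keep <- apply(valid_by_group, 1L, max) >= params$min_valid_per_group
  out <- table[which(keep), ]
  m <- out$intensities
  if (!anyNA(m)) return(out)
  obs_n <- colSums(!is.na(m))
  if (any(obs_n < 2))
    stop("cannot estimate imputation distribution for sample(s) with < 2 ",
         "observed values: ",
         paste(colnames(m)[obs_n < 2], collapse = ", "), call. = FALSE)
  mu <- colMeans(m, na.rm = TRUE) - params$shift * apply(m, 2L, stats::sd, na.rm = TRUE)
  sig <- params$width * apply(m, 2L, stats::sd, na.rm = TRUE)
  mask <- is.na(m)
  m <- with_seed(params$seed, {
    for (j in seq_len(ncol(m))) {
      miss <- which(mask[, j])
      if (length(miss))
        m[miss, j] <- stats::rnorm(length(miss), mu[j], sig[j])
    }
    m
  })
  out$intensities <- m
  attr(out, "imputed_mask") <- mask
  out
}

#' Detect the background (unregulated) protein cluster
#'
#' Clusters features by their bait-minus-control mean log2 difference
#' (seeded k-means on the 1-D profile) and returns the cluster whose median
#' difference is closest to zero -- the proteins binding non-specifically,
#' usable as a normalization anchor when so many proteins are genuinely
#' enriched that global normalization assumptions fail. Ties are broken
#' toward the larger cluster.
#'
#' @param table an imputed (complete) log2 [quant_table].
#' @param design a [sample_design()].
#' @param group_a,group_b bait and control group labels; defaults to the two
#'   groups present when there are exactly two.
#' @param k number of clusters (default 3: background / enriched / depleted).
#' @param seed integer seed.
#' @return character vector of background feature ids.
#' @export
detect_background_cluster <- function(table, design, group_a = NULL,
                                      group_b = NULL, k = 3L, seed = 1L) {
  stopifnot(inherits(table, "quant_table"))
  groups <- design_groups(design, sample_ids(table))
  if (is.null(group_a) || is.null(group_b)) {
    gl <- unique(groups[!is.na(groups)])
    if (length(gl) != 2)
      stop("specify `group_a` and `group_b` (design has ", length(gl),
           " groups)", call. = FALSE)
    group_a <- gl[1]; group_b <- gl[2]
  }
  m <- table$intensities
  if (anyNA(m)) stop("background detection needs a complete (imputed) table",
                     call. = FALSE)
  if (k > nrow(m))
    stop("`k` exceeds the number of features", call. = FALSE)
  d <- rowMeans(m[, which(groups == group_a), drop = FALSE]) -
    rowMeans(m[, which(groups == group_b), drop = FALSE])
  labels <- kmeans_cluster(d, k = k, seed = seed)
  meds <- tapply(d, labels, stats::median)
  sizes <- tabulate(labels, nbins = max(labels))[as.integer(names(meds))]
  o <- order(abs(meds), -sizes)
  best <- as.integer(names(meds))[o[1]]
  feature_ids(table)[labels == best]
}

#' Renormalize a table against a background feature set
#'
#' Shifts every sample so that its median over the background features
#' equals the grand median of the background across all samples; all
#' features in a sample move by the same offset, so within-sample
#' differences are preserved exactly.
#'
#' @param table a log2 [quant_table].
#' @param background character vector of background feature ids (non-empty
#'   subset of the table's features).
#' @return the renormalized [quant_table]; attribute `"offsets"` records the
#'   per-sample shift that was subtracted.
#' @export
renormalize_to_background <- function(table, background) {
  stopifnot(inherits(table, "quant_table"))
  if (length(background) == 0)
    stop("`background` must be non-empty", call. = FALSE)
  if (!all(background %in% feature_ids(table)))
    stop("`background` contains ids absent from the table", call. = FALSE)
  bg <- table$intensities[background, , drop = FALSE]
  med_s <- apply(bg, 2L, stats::median, na.rm = TRUE)
  grand <- stats::median(as.vector(bg), na.rm = TRUE)
  offsets <- med_s - grand
  out <- table
  out$intensities <- sweep(table$intensities, 2L, offsets, "-")
  attr(out, "offsets") <- offsets
  out
}

#' Call enriched / depleted features from a differential test
#'
#' A feature is `enriched` when its log2 fold change reaches the (log2
#' equivalent of the) fold-change cutoff and its BH-adjusted p-value is at or
#' below the FDR cutoff; `depleted` symmetrically; otherwise `ns`.
#'
#' @param results a `modt` fit or data.frame with `feature_id`, `log2_fc`,
#'   `adj_p`.
#' @param thresholds a [threshold_config()].
#' @return data.frame `feature_id`, `log2_fc`, `adj_p`, `direction`
#'   (factor: enriched / depleted / ns), with the threshold snapshot stored
#'   in attribute `"thresholds"`.
#' @export
call_enriched <- function(results, thresholds = threshold_config(1.5, 0.05)) {
  tab <- if (inherits(results, "modt")) results$table else as.data.frame(results)
  stopifnot(inherits(thresholds, "threshold_config"))
  cut <- log2_fc_cutoff(thresholds)
  dir <- rep("ns", nrow(tab))
  sig <- !is.na(tab$adj_p) & tab$adj_p <= thresholds$fdr_cutoff
  dir[sig & tab$log2_fc >= cut] <- "enriched"
  dir[sig & tab$log2_fc <= -cut] <- "depleted"
  out <- data.frame(feature_id = tab$feature_id, log2_fc = tab$log2_fc,
                    adj_p = tab$adj_p,
                    direction = factor(dir, c("enriched", "depleted", "ns")),
                    stringsAsFactors = FALSE)
  attr(out, "thresholds") <- thresholds
  out
}

#' Run the AP-MS differential-enrichment workflow
#'
#' Full chain for a bait-versus-control pull-down experiment: feature
#' filtering (razor + unique peptides, contaminants, decoys), log2
#' transform, left-censored imputation, moderated t-test, optional
#' background-cluster renormalization with a second imputation/testing pass
#' (used when heavy bait enrichment breaks global normalization), and
#' enrichment calling.
#'
#' @param table a linear-scale [quant_table] (e.g. from
#'   [read_quant_table()]).
#' @param design a [sample_design()].
#' @param group_a,group_b bait and control group labels.
#' @param thresholds a [threshold_config()] (default fold change 1.5, FDR
#'   0.05).
#' @param impute an [imputation_params()]; its seed governs all random
#'   draws.
#' @param background_renorm logical; run the background-renormalization
#'   second pass.
#' @param k cluster count for background detection.
#' @param min_razor_unique peptide-evidence filter (default 2).
#' @return an object of class `apms_run`: list with `calls` (enrichment
#'   calls), `results` (the final `modt` fit), `first_pass` (the
#'   pre-renormalization fit, when a second pass ran), `background`
#'   (background feature ids or NULL), and `log` (every parameter and seed).
#' @examples
#' sim <- simulate_apms_experiment(n_features = 300, n_interactors = 10,
#'                                 seed = 7)
#' run <- run_apms_workflow(sim$table, sim$design, "bait", "ctrl",
#'                          impute = imputation_params(seed = 7))
#' table(run$calls$direction)
#' @export
run_apms_workflow <- function(table, design, group_a, group_b,
                              thresholds = threshold_config(1.5, 0.05),
                              impute = imputation_params(),
                              background_renorm = FALSE, k = 3L,
                              min_razor_unique = 2L) {
  stopifnot(inherits(table, "quant_table"))
  stop_if_not_flag(background_renorm, "background_renorm")
  filtered <- filter_features(table, min_razor_unique = min_razor_unique)
  lg <- if (filtered$scale == "linear") log2_transform(filtered) else filtered
  imp <- impute_missing(lg, design, impute)
  fit <- moderated_ttest(imp, design, group_a, group_b)
  first_pass <- NULL
  background <- NULL
  if (background_renorm) {
    first_pass <- fit
    background <- detect_background_cluster(imp, design, group_a, group_b,
                                            k = k, seed = impute$seed)
    renorm <- renormalize_to_background(lg, background)
    impute2 <- impute
    impute2$seed <- derive_seed(impute$seed)
    imp <- impute_missing(renorm, design, impute2)
    fit <- moderated_ttest(imp, design, group_a, group_b)
  }
  calls <- call_enriched(fit, thresholds)
  log <- list(group_a = group_a, group_b = group_b,
              thresholds = unclass(thresholds),
              imputation = unclass(impute),
              background_renorm = background_renorm,
              background_k = if (background_renorm) k else NA_integer_,
              background_statistic = "per-feature bait-minus-control mean log2 difference",
              reimputation_seed = if (background_renorm)
                derive_seed(impute$seed) else NA_integer_,
              min_razor_unique = min_razor_unique,
              n_features_input = nfeatures(table),
              n_features_filtered = nfeatures(filtered),
              n_features_tested = nfeatures(imp))
  structure(list(calls = calls, results = fit, first_pass = first_pass,
                 background = background, log = log),
            class = "apms_run")
}

#' @export
print.apms_run <- function(x, ...) {
  cat(sprintf("AP-MS run: %s vs %s, %d features tested\n",
              x$log$group_a, x$log$group_b, x$log$n_features_tested))
  print(table(x$calls$direction))
  if (!is.null(x$background))
    cat(sprintf("background cluster: %d features\n", length(x$background)))
  invisible(x)
}
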