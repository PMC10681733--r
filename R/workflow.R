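# Orchestration: a single entry point wiring the pipeline stages into
# runnable workflows with parameter logging and a reproducibility manifest.
# A thin command-line front-end over run_workflow() ships in
# inst/scripts/ddrquant.R.

config_error <- function(...) {
  stop(structure(class = c("ddrquant_config_error", "error", "condition"),
                 list(message = paste0(...), call = NULL)))
}

#' Read a differential-result TSV written by [write_diff_results()]
#'
#' @param path file path.
#' @return data.frame with `feature_id`, `log2_fc`, `t`, `p_value`, `adj_p`,
#'   `n_valid_a`, `n_valid_b`.
#' @export
read_diff_results <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  names(df)[names(df) == "p"] <- "p_value"
  df
}

#' Run a named workflow from a configuration
#'
#' Executes one of the pipeline workflows -- `simulate_apms`,
#' `simulate_tmt`, `apms`, `tmt`, `ptm` (downstream set/motif analyses on
#' differential results) or `net` (network-edge filtering) -- writing its
#' result tables to `out_dir` together with `manifest.json` recording every
#' parameter, the seed, and MD5 checksums of all inputs and outputs. Outputs
#' are byte-reproducible from (inputs, config, seed); the manifest carries
#' no timestamps.
#'
#' @param config a list (or path to a YAML file parsed into one) with
#'   elements `workflow`, `out_dir`, `seed`, `inputs` (named file paths) and
#'   `params` (workflow-specific parameters, see the workflow functions'
#'   documentation for meanings and defaults).
#' @return invisibly, a list with `status` (0 on success) and the manifest.
#'   Configuration problems signal a condition of class
#'   `ddrquant_config_error` (exit status 2 in the CLI); stage failures
#'   propagate as ordinary errors (exit status 1).
#' @export
run_workflow <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) config_error("config file not found: ", config)
    if (!requireNamespace("yaml", quietly = TRUE))
      config_error("reading YAML configs requires the 'yaml' package")
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) config_error("`config` must be a list or YAML path")
  wf <- config$workflow %||% config_error("config lacks `workflow`")
  known <- c("simulate_apms", "simulate_tmt", "apms", "tmt", "ptm", "net")
  if (!wf %in% known)
    config_error("unknown workflow '", wf, "'; expected one of ",
                 paste(known, collapse = ", "))
  out_dir <- config$out_dir %||% config_error("config lacks `out_dir`")
  seed <- as.integer(config$seed %||% 1L)
  inputs <- config$inputs %||% list()
  params <- config$params %||% list()
  for (p in unlist(inputs))
    if (!file.exists(p)) config_error("input file not found: ", p)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  outputs <- switch(wf,
                    simulate_apms = .wf_simulate_apms(inputs, params, seed, out_dir),
                    simulate_tmt = .wf_simulate_tmt(inputs, params, seed, out_dir),
                    apms = .wf_apms(inputs, params, seed, out_dir),
                    tmt = .wf_tmt(inputs, params, seed, out_dir),
                    ptm = .wf_ptm(inputs, params, seed, out_dir),
                    net = .wf_net(inputs, params, seed, out_dir))
  manifest <- list(
    workflow = wf, seed = seed, params = params,
    package_version = as.character(utils::packageVersion("ddrquant")),
    inputs = lapply(inputs, function(p)
      list(path = p, md5 = unname(tools::md5sum(p)))),
    outputs = lapply(outputs, function(p)
      list(path = p, md5 = unname(tools::md5sum(p)))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  invisible(list(status = 0L, manifest = manifest))
}

.num <- function(params, name, default) as.numeric(params[[name]] %||% default)

.wf_simulate_apms <- function(inputs, params, seed, out_dir) {
  sim <- simulate_apms_experiment(
    n_features = .num(params, "n_features", 2000),
    n_interactors = .num(params, "n_interactors", 50),
    reps_per_group = .num(params, "reps_per_group", 3),
    effect_range = c(.num(params, "effect_low", 2),
                     .num(params, "effect_high", 12)),
    seed = seed)
  paths <- c(table = file.path(out_dir, "proteinGroups.tsv"),
             design = file.path(out_dir, "design.tsv"),
             truth = file.path(out_dir, "truth_interactors.tsv"))
  write_quant_table(sim$table, paths["table"], "protein_groups")
  write_sample_design(sim$design, paths["design"])
  utils::write.table(sim$truth$interactors, paths["truth"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  as.list(paths)
}

.wf_simulate_tmt <- function(inputs, params, seed, out_dir) {
  sim <- simulate_tmt_ptm_experiment(
    n_proteins = .num(params, "n_proteins", 800),
    sites_per_protein = .num(params, "sites_per_protein", 2),
    frac_regulated = .num(params, "frac_regulated", 0.1),
    sq_frac = .num(params, "sq_frac", 0.536),
    seed = seed)
  paths <- c(proteins = file.path(out_dir, "proteins.tsv"),
             sites = file.path(out_dir, "sites.tsv"),
             design = file.path(out_dir, "design.tsv"),
             impurity = file.path(out_dir, "impurity.tsv"),
             truth = file.path(out_dir, "truth_sites.tsv"))
  write_quant_table(sim$proteins, paths["proteins"], "protein_groups")
  write_quant_table(sim$sites, paths["sites"], "site_table")
  write_sample_design(sim$design, paths["design"])
  imp <- as.data.frame(unclass(sim$impurity))
  utils::write.table(cbind(channel = rownames(imp), imp), paths["impurity"],
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sim$truth$regulated_sites, paths["truth"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  as.list(paths)
}

.wf_apms <- function(inputs, params, seed, out_dir) {
  if (is.null(inputs$table) || is.null(inputs$design))
    config_error("apms workflow needs inputs `table` and `design`")
  table <- read_quant_table(inputs$table, "protein_groups")
  design <- read_sample_design(inputs$design)
  groups <- unique(design$group[!design$is_reference])
  group_a <- params$group_a %||% groups[1]
  group_b <- params$group_b %||% groups[2]
  run <- run_apms_workflow(
    table, design, group_a, group_b,
    thresholds = threshold_config(.num(params, "fc", 1.5),
                                  .num(params, "fdr", 0.05)),
    impute = imputation_params(shift = .num(params, "impute_shift", 1.8),
                               width = .num(params, "impute_width", 0.3),
                               seed = seed),
    background_renorm = isTRUE(params$background_renorm),
    k = .num(params, "k", 3))
  paths <- c(results = file.path(out_dir, "results.tsv"),
             calls = file.path(out_dir, "calls.tsv"),
             log = file.path(out_dir, "run_log.json"))
  write_diff_results(run$results, paths["results"])
  utils::write.table(run$calls, paths["calls"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(run$log, paths["log"], auto_unbox = TRUE,
                       pretty = TRUE, digits = NA, null = "null",
                       force = TRUE)
  as.list(paths)
}

.wf_tmt <- function(inputs, params, seed, out_dir) {
  if (is.null(inputs$proteins) || is.null(inputs$design))
    config_error("tmt workflow needs inputs `proteins` and `design`")
  proteins <- read_quant_table(inputs$proteins, "protein_groups")
  design <- read_sample_design(inputs$design)
  sites <- if (!is.null(inputs$sites))
    read_quant_table(inputs$sites, "site_table")
  impurity <- if (!is.null(inputs$impurity))
    read_impurity_matrix(inputs$impurity)
  cmp <- params$comparisons %||%
    config_error("tmt workflow needs `comparisons` (list of 'A:B' strings)")
  comparisons <- lapply(cmp, function(s) strsplit(s, ":", fixed = TRUE)[[1]])
  run <- run_tmt_workflow(proteins, design, sites = sites,
                          impurity = impurity, comparisons = comparisons)
  paths <- list()
  for (nm in names(run$proteins$fits)) {
    p <- file.path(out_dir, paste0("proteins_", nm, ".tsv"))
    write_diff_results(run$proteins$fits[[nm]], p)
    paths[[paste0("proteins_", nm)]] <- p
  }
  if (!is.null(run$sites))
    for (nm in names(run$sites$fits)) {
      p <- file.path(out_dir, paste0("sites_", nm, ".tsv"))
      write_diff_results(run$sites$fits[[nm]], p)
      paths[[paste0("sites_", nm)]] <- p
    }
  paths
}

.wf_ptm <- function(inputs, params, seed, out_dir) {
  if (is.null(inputs$wt_results))
    config_error("ptm workflow needs input `wt_results`")
  dataset <- params$dataset %||% "phospho"
  wt <- call_regulated_sites(read_diff_results(inputs$wt_results), dataset)
  mutants <- lapply(unlist(inputs[grepl("^mutant", names(inputs))]),
                    function(p) call_regulated_sites(read_diff_results(p),
                                                    dataset))
  responsive <- responsive_in_wt_stable_in_mutants(wt, mutants)
  paths <- c(calls = file.path(out_dir, "wt_calls.tsv"),
             responsive = file.path(out_dir, "responsive_stable.tsv"))
  utils::write.table(wt, paths["calls"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  out <- data.frame(site_key = responsive, stringsAsFactors = FALSE)
  if (!is.null(inputs$windows)) {
    win <- utils::read.delim(inputs$windows, sep = "\t",
                             stringsAsFactors = FALSE)
    flags <- stats::setNames(annotate_sq_motif(win$sequence_window),
                             win$site_key)
    out$is_sq <- flags[responsive]
    sqf <- if (nrow(out)) sq_fraction(responsive, flags) else NA_real_
    jsonlite::write_json(list(n_responsive_stable = nrow(out),
                              sq_fraction_pct = sqf),
                         file.path(out_dir, "sq_summary.json"),
                         auto_unbox = TRUE, digits = NA)
    paths["sq_summary"] <- file.path(out_dir, "sq_summary.json")
  }
  utils::write.table(out, paths["responsive"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  as.list(paths)
}

.wf_net <- function(inputs, params, seed, out_dir) {
  if (is.null(inputs$edges)) config_error("net workflow needs input `edges`")
  edges <- utils::read.delim(inputs$edges, sep = "\t",
                             stringsAsFactors = FALSE)
  res <- filter_network_edges(edges,
                              min_score = .num(params, "min_score", 0.7),
                              drop_disconnected =
                                !isFALSE(params$drop_disconnected))
  paths <- c(edges = file.path(out_dir, "edges_filtered.tsv"),
             nodes = file.path(out_dir, "nodes.tsv"))
  utils::write.table(res$edges, paths["edges"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(data.frame(node = res$nodes,
                                degree = unname(res$degrees)),
                     paths["nodes"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  as.list(paths)
}
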