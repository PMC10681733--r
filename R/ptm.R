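# Downstream site-level analyses: regulated-site calls, SQ-motif
# annotation, cross-study integration, ortholog mapping, network-edge
# filtering, profile clustering.

#' Call regulated PTM sites
#'
#' Applies dataset-specific default cutoffs to a protein-normalized
#' site-level differential test: phosphorylation sites at fold change 1.5 /
#' FDR 0.05, acetylation sites at the more stringent fold change 2 /
#' FDR 0.01 (untreated acetylome replicates are noisier). Both can be
#' overridden.
#'
#' @param results a `modt` fit or data.frame with `feature_id`, `log2_fc`,
#'   `adj_p`.
#' @param dataset `"phospho"` or `"acetyl"`; picks the default thresholds.
#' @param thresholds optional [threshold_config()] override.
#' @return data.frame `feature_id`, `log2_fc`, `adj_p`, `direction`
#'   (factor: up / down / ns); attributes `"thresholds"` and `"dataset"`.
#' @export
call_regulated_sites <- function(results, dataset = c("phospho", "acetyl"),
                                 thresholds = NULL) {
  dataset <- match.arg(dataset)
  if (is.null(thresholds))
    thresholds <- switch(dataset,
                         phospho = threshold_config(1.5, 0.05),
                         acetyl = threshold_config(2, 0.01))
  calls <- call_enriched(results, thresholds)
  levels(calls$direction) <- c("up", "down", "ns")
  attr(calls, "dataset") <- dataset
  calls
}

#' Sites responsive in wildtype but stable in every mutant
#'
#' Returns the site keys called up or down in the wildtype comparison and
#' called `ns` in each of the mutant comparisons -- the set whose regulation
#' requires the intact protein under study. With no mutant collections the
#' result is simply the wildtype-regulated set.
#'
#' @param wt regulation calls (from [call_regulated_sites()]) for the
#'   wildtype contrast.
#' @param mutants list of regulation-call collections, one per mutant.
#' @return character vector of site keys.
#' @export
responsive_in_wt_stable_in_mutants <- function(wt, mutants = list()) {
  reg <- as.character(wt$feature_id[wt$direction %in% c("up", "down",
                                                        "enriched", "depleted")])
  for (mu in mutants) {
    if (!length(intersect(wt$feature_id, mu$feature_id)))
      stop("mutant call collection shares no sites with the wildtype calls",
           call. = FALSE)
    stable <- as.character(mu$feature_id[mu$direction == "ns"])
    reg <- reg[reg %in% stable]
  }
  reg
}

#' Annotate SQ motifs in phosphosite sequence windows
#'
#' A site carries an SQ motif when the central residue of its sequence
#' window is serine and the residue immediately C-terminal is glutamine --
#' the preferred substrate motif of the DNA-damage-response kinases ATM and
#' ATR. TQ motifs are only counted when `include_tq = TRUE`.
#'
#' @param windows character vector of odd-length sequence windows centered
#'   on the modified residue.
#' @param residue optional expected central residue(s); a center mismatch is
#'   a data error.
#' @param include_tq also accept threonine at the center.
#' @return logical vector.
#' @export
annotate_sq_motif <- function(windows, residue = NULL, include_tq = FALSE) {
  stop_if_not_flag(include_tq, "include_tq")
  n <- nchar(windows)
  if (any(n %% 2 == 0 | n < 3))
    stop("malformed sequence window: length must be odd and >= 3",
         call. = FALSE)
  center <- (n + 1L) %/% 2L
  cc <- substr(windows, center, center)
  if (!is.null(residue) && any(cc != residue))
    stop("sequence-window center does not match the annotated residue",
         call. = FALSE)
  nxt <- substr(windows, center + 1L, center + 1L)
  accept <- if (include_tq) c("S", "T") else "S"
  cc %in% accept & nxt == "Q"
}

#' Fraction of a site set carrying the SQ motif
#'
#' @param sites character vector of site keys (non-empty).
#' @param annotations named logical vector of SQ flags covering every site.
#' @return percentage, rounded to one decimal (e.g. `75.0`).
#' @export
sq_fraction <- function(sites, annotations) {
  if (!length(sites))
    stop("SQ fraction is undefined for an empty site set", call. = FALSE)
  flags <- annotations[sites]
  if (anyNA(flags) || length(flags) != length(sites))
    stop("every site must be annotated", call. = FALSE)
  round(100 * mean(flags), 1)
}

#' Compare fold changes between two conditions site by site
#'
#' Inner-joins two named log2 fold-change vectors on site key, optionally
#' restricts to SQ (or non-SQ) sites, and reports the squared Pearson
#' correlation together with the paired table -- the statistic behind
#' "is the mutant's damage-induced phosphorylation response a damped copy of
#' the wildtype's?".
#'
#' @param wt_fc,mutant_fc named numeric vectors of per-site log2 fold
#'   changes.
#' @param sq_flags optional named logical vector of SQ annotations, required
#'   for `site_filter != "all"`.
#' @param site_filter `"all"`, `"sq"` or `"non_sq"`.
#' @return list with `r_squared` and `table` (data.frame `site_key`,
#'   `wt_fc`, `mutant_fc`).
#' @export
compare_fc_scatter <- function(wt_fc, mutant_fc, sq_flags = NULL,
                               site_filter = c("all", "sq", "non_sq")) {
  site_filter <- match.arg(site_filter)
  common <- intersect(names(wt_fc), names(mutant_fc))
  if (site_filter != "all") {
    if (is.null(sq_flags))
      stop("`sq_flags` is required for SQ filtering", call. = FALSE)
    common <- common[common %in% names(sq_flags)]
    keep <- sq_flags[common]
    common <- if (site_filter == "sq") common[keep] else common[!keep]
  }
  if (length(common) < 3)
    stop("fewer than 3 common sites after filtering", call. = FALSE)
  tab <- data.frame(site_key = common, wt_fc = unname(wt_fc[common]),
                    mutant_fc = unname(mutant_fc[common]),
                    stringsAsFactors = FALSE)
  list(r_squared = squared_pearson(tab$wt_fc, tab$mutant_fc), table = tab)
}

#' Map features between species through an ortholog pair table
#'
#' Features with at least one ortholog pair are mapped (one-to-many
#' expanded, multi-ortholog features flagged ambiguous); features with no
#' annotated ortholog go on the excluded list and are left out of cross-
#' species analyses.
#'
#' @param features character vector of species-A feature ids.
#' @param orthologs data.frame with columns `species_a`, `species_b` (no
#'   duplicate pairs required; duplicates are dropped).
#' @return list with `mapping` (named list: A-id -> character vector of
#'   B-ids), `ambiguous` (A-ids mapping to more than one B-id) and
#'   `excluded` (A-ids without orthologs).
#' @export
map_orthologs <- function(features, orthologs) {
  stopifnot(is.data.frame(orthologs),
            all(c("species_a", "species_b") %in% names(orthologs)))
  orthologs <- unique(orthologs[, c("species_a", "species_b")])
  hits <- orthologs[orthologs$species_a %in% features, , drop = FALSE]
  mapping <- split(as.character(hits$species_b), hits$species_a)
  mapping <- mapping[intersect(features, names(mapping))]
  list(mapping = mapping,
       ambiguous = names(mapping)[lengths(mapping) > 1],
       excluded = setdiff(features, names(mapping)))
}

# center w-mer of a sequence window (default 15), for cross-dialect mapping
window_center <- function(windows, width = 15L) {
  n <- nchar(windows)
  if (any(n %% 2 == 0)) stop("malformed sequence window: even length",
                             call. = FALSE)
  c0 <- (n + 1L) %/% 2L
  half <- (width - 1L) %/% 2L
  substr(windows, pmax(c0 - half, 1L), pmin(c0 + half, n))
}

#' Integrate an external SILAC site-ratio table into a site table
#'
#' Normalizes external heavy/light site ratios to the matching protein
#' ratios (log2 site ratio minus log2 protein ratio; sites whose protein was
#' not quantified are discarded), then maps the normalized ratios onto the
#' target sites by the (gene, position, window-center-15-mer) key. Gene
#' comparison is case-insensitive. Keys matching more than one distinct
#' target site (different parent accession or position) are dropped as
#' ambiguous; multiplicity states of one site all receive the annotation.
#'
#' @param external_sites data.frame with `gene`, `position`, `window`,
#'   `ratio` (linear H/L site ratio, positive).
#' @param external_proteins data.frame with `gene`, `ratio` (linear H/L
#'   protein ratio, positive).
#' @param target_sites a site [quant_table] whose features carry
#'   `gene_name`, `position`, `sequence_window`.
#' @return `target_sites` with an `external_log2_ratio` column appended to
#'   its feature metadata (NA where no external site maps).
#' @export
integrate_external_ratio_sites <- function(external_sites, external_proteins,
                                           target_sites) {
  stopifnot(is.data.frame(external_sites), is.data.frame(external_proteins),
            inherits(target_sites, "quant_table"))
  if (any(external_sites$ratio <= 0, na.rm = TRUE) ||
      any(external_proteins$ratio <= 0, na.rm = TRUE))
    stop("H/L ratios must be positive", call. = FALSE)
  pidx <- match(tolower(external_sites$gene), tolower(external_proteins$gene))
  prot_ratio <- external_proteins$ratio[pidx]
  keep <- !is.na(prot_ratio) & !is.na(external_sites$ratio)
  ext <- external_sites[keep, , drop = FALSE]
  norm_log2 <- log2(ext$ratio) - log2(prot_ratio[keep])
  ext_key <- paste(tolower(ext$gene), ext$position,
                   window_center(ext$window), sep = "|")
  f <- target_sites$features
  tgt_key <- paste(tolower(f$gene_name), f$position,
                   window_center(f$sequence_window), sep = "|")
  # ambiguity judged on distinct sites (accession, position), not on the
  # multiplicity states of one site
  site_identity <- paste(f$protein_ids, f$position, sep = "|")
  n_distinct <- vapply(split(site_identity, tgt_key),
                       function(s) length(unique(s)), 1L)
  ambiguous_keys <- names(n_distinct)[n_distinct > 1]
  ext_ok <- !(ext_key %in% ambiguous_keys) & !duplicated(ext_key)
  ann <- stats::setNames(norm_log2[ext_ok], ext_key[ext_ok])
  out <- target_sites
  out$features$external_log2_ratio <- unname(ann[tgt_key])
  out$features$external_log2_ratio[tgt_key %in% ambiguous_keys] <- NA_real_
  out
}

#' Filter a protein-interaction network by confidence score
#'
#' Keeps edges whose combined confidence score reaches `min_score`
#' (high-confidence default 0.7), removes self-loops, optionally drops nodes
#' left without any edge, and reports node degrees (used downstream for
#' degree-proportional node rendering).
#'
#' @param edges data.frame with `node1`, `node2`, `combined_score` in
#'   \[0, 1\].
#' @param min_score minimum combined score in \[0, 1\].
#' @param drop_disconnected remove nodes of degree 0.
#' @return list with `nodes` (character), `edges` (filtered data.frame) and
#'   `degrees` (named integer vector over `nodes`).
#' @export
filter_network_edges <- function(edges, min_score = 0.7,
                                 drop_disconnected = TRUE) {
  stopifnot(is.data.frame(edges),
            all(c("node1", "node2", "combined_score") %in% names(edges)))
  if (!is.numeric(min_score) || length(min_score) != 1L ||
      min_score < 0 || min_score > 1)
    stop("`min_score` must lie in [0, 1]", call. = FALSE)
  if (any(edges$combined_score < 0 | edges$combined_score > 1, na.rm = TRUE))
    stop("combined scores must lie in [0, 1]", call. = FALSE)
  stop_if_not_flag(drop_disconnected, "drop_disconnected")
  edges <- edges[edges$node1 != edges$node2, , drop = FALSE]
  all_nodes <- unique(c(as.character(edges$node1), as.character(edges$node2)))
  kept <- edges[!is.na(edges$combined_score) &
                  edges$combined_score >= min_score, , drop = FALSE]
  rownames(kept) <- NULL
  deg_tab <- table(c(as.character(kept$node1), as.character(kept$node2)))
  degrees <- stats::setNames(rep(0L, length(all_nodes)), all_nodes)
  degrees[names(deg_tab)] <- as.integer(deg_tab)
  if (drop_disconnected) degrees <- degrees[degrees > 0]
  list(nodes = names(degrees), edges = kept, degrees = degrees)
}

#' Cluster PTM-site intensity profiles
#'
#' Log2-scale intensity rows are z-scored and clustered with seeded k-means;
#' the z-scored matrix is the heatmap input downstream.
#'
#' @param sites a complete (no missing values) log2 [quant_table] or numeric
#'   matrix.
#' @param k number of clusters.
#' @param seed integer seed.
#' @return list with `labels` (named integer vector, 1..k) and `matrix` (the
#'   z-scored matrix).
#' @export
cluster_site_profiles <- function(sites, k, seed = 1L) {
  m <- if (inherits(sites, "quant_table")) sites$intensities else sites
  z <- zscore_rows(m)
  labels <- kmeans_cluster(z, k = k, seed = seed)
  names(labels) <- rownames(m)
  list(labels = labels, matrix = z)
}
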