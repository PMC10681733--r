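# TMT isobaric-label arm: reporter-ion impurity correction, within-plex
# median normalization, between-plex IRS normalization via the shared
# reference channel, site-to-protein normalization.

#' Isotopic-impurity matrix of a TMT label lot
#'
#' Square channels-by-channels matrix; entry (i, j) is the fraction of
#' channel j's true signal that is observed in channel i. Columns must sum to
#' at most 1.02, diagonal entries must exceed 0.5, and the matrix must be
#' invertible.
#'
#' @param m numeric square matrix with channel labels as dimnames.
#' @return an `impurity_matrix`.
#' @export
impurity_matrix <- function(m) {
  stopifnot(is.matrix(m), is.numeric(m))
  if (nrow(m) != ncol(m)) stop("impurity matrix must be square", call. = FALSE)
  if (is.null(colnames(m)))
    stop("impurity matrix needs channel labels as dimnames", call. = FALSE)
  rownames(m) <- colnames(m)
  if (any(m < 0)) stop("impurity fractions must be non-negative", call. = FALSE)
  if (any(diag(m) <= 0.5))
    stop("impurity matrix diagonal entries must exceed 0.5", call. = FALSE)
  if (any(colSums(m) > 1.02))
    stop("impurity matrix columns must sum to <= 1.02", call. = FALSE)
  if (!is.finite(kappa(m)) || abs(det(m)) < .Machine$double.eps)
    stop("impurity matrix is singular", call. = FALSE)
  structure(m, class = c("impurity_matrix", "matrix"))
}

#' @rdname impurity_matrix
#' @param channels channel labels.
#' @export
identity_impurity <- function(channels) {
  impurity_matrix(diag(length(channels)) |>
                    `dimnames<-`(list(channels, channels)))
}

#' Read an impurity matrix from a channels-by-channels TSV
#'
#' First column holds the row (observed) channel labels, header the source
#' channels.
#'
#' @param path file path.
#' @return an [impurity_matrix()].
#' @export
read_impurity_matrix <- function(path) {
  df <- utils::read.delim(path, sep = "\t", check.names = FALSE,
                          row.names = 1L)
  impurity_matrix(as.matrix(df))
}

#' Correct reporter intensities for isotopic label impurities
#'
#' Reporter-ion cross-talk is linear in signal: observed = impurity %*% true
#' per feature. This solves the linear system channel-wise on linear-scale
#' intensities; negative solutions (over-corrected low signals) become
#' missing, as do channels that were missing on input.
#'
#' @param reporters features-by-channels numeric matrix, linear scale, with
#'   column names equal to the impurity matrix's channels (same order).
#' @param impurity an [impurity_matrix()].
#' @return corrected matrix of the same shape.
#' @export
correct_isotope_impurities <- function(reporters, impurity) {
  stopifnot(is.matrix(reporters), inherits(impurity, "impurity_matrix"))
  if (!identical(colnames(reporters), colnames(unclass(impurity))))
    stop("reporter channel order does not match the impurity matrix",
         call. = FALSE)
  M <- unclass(impurity)
  na_mask <- is.na(reporters)
  obs <- reporters
  obs[na_mask] <- 0
  corrected <- t(solve(M, t(obs)))
  corrected[na_mask] <- NA
  # floating-point negatives of numerically-zero magnitude are true zeros;
  # genuinely negative solutions are over-corrected low signals
  tol <- 1e-9 * max(abs(obs))
  tiny <- !is.na(corrected) & corrected < 0 & corrected >= -tol
  corrected[tiny] <- 0
  corrected[!is.na(corrected) & corrected < 0] <- NA
  dimnames(corrected) <- dimnames(reporters)
  corrected
}

#' Within-plex median normalization
#'
#' Shifts every sample of a log2-scale plex so that its median over observed
#' values equals the plex grand median (the median of the per-sample
#' medians). A pure per-sample shift: within-sample differences between
#' features are untouched, so fold changes are preserved.
#'
#' @param plex a log2 [quant_table] holding one plex's channels.
#' @return the normalized [quant_table].
#' @export
median_normalize_within_plex <- function(plex) {
  stopifnot(inherits(plex, "quant_table"))
  if (plex$scale != "log2")
    stop("median normalization operates on log2 scale", call. = FALSE)
  m <- plex$intensities
  n_obs <- colSums(!is.na(m))
  if (any(n_obs == 0))
    stop("sample(s) with no observed values: ",
         paste(colnames(m)[n_obs == 0], collapse = ", "), call. = FALSE)
  med <- apply(m, 2L, stats::median, na.rm = TRUE)
  grand <- stats::median(med)
  out <- plex
  out$intensities <- sweep(m, 2L, med - grand, "-")
  out
}

#' Between-plex IRS normalization via the shared reference channel
#'
#' Internal-reference scaling: every plex carries one channel measuring the
#' same pooled reference aliquot. Per feature, each plex is shifted (on log2
#' scale; equivalently scaled on linear scale) so its reference intensity
#' equals the cross-plex anchor -- the mean of the feature's reference log2
#' intensities, i.e. the geometric mean on linear scale. Features without an
#' observed reference value in every plex are dropped, as are features not
#' present in all plexes. After normalization each feature's reference
#' intensities agree exactly across plexes.
#'
#' @param plexes named list of log2 [quant_table]s, one per plex (e.g. from
#'   splitting a combined table by `design$plex_id`).
#' @param design a [sample_design()] declaring one reference sample per
#'   plex.
#' @return a combined log2 [quant_table] over all plexes' samples.
#' @export
irs_normalize <- function(plexes, design) {
  stopifnot(is.list(plexes), length(plexes) >= 1)
  if (!any(design$is_reference))
    stop("design declares no reference channel", call. = FALSE)
  common <- Reduce(intersect, lapply(plexes, feature_ids))
  plexes <- lapply(plexes, function(p) p[common, ])
  ref_ids <- vapply(plexes, function(p) {
    r <- intersect(sample_ids(p), design$sample_id[design$is_reference])
    if (length(r) != 1)
      stop("each plex must contain exactly one reference sample", call. = FALSE)
    r
  }, "")
  refs <- vapply(seq_along(plexes), function(i)
    plexes[[i]]$intensities[, ref_ids[i]], numeric(length(common)))
  if (is.null(dim(refs))) refs <- matrix(refs, nrow = length(common))
  keep <- rowSums(is.na(refs)) == 0
  anchor <- rowMeans(refs[keep, , drop = FALSE])
  mats <- lapply(seq_along(plexes), function(i) {
    m <- plexes[[i]]$intensities[keep, , drop = FALSE]
    m + (anchor - refs[keep, i])
  })
  combined <- do.call(cbind, mats)
  feats <- plexes[[1]]$features[keep, , drop = FALSE]
  rownames(feats) <- NULL
  quant_table(combined, feats, scale = "log2")
}

#' Normalize PTM-site intensities to parent-protein abundance
#'
#' Subtracts, per site and sample, the matched protein's log2 intensity from
#' the site's log2 intensity, so that group comparisons reflect changes in
#' site occupancy rather than protein abundance. Sites whose parent protein
#' is not quantified are dropped.
#'
#' @param sites log2 [quant_table] of PTM sites (feature metadata carries
#'   the parent accession in `protein_ids`).
#' @param proteins log2 [quant_table] of protein abundances, feature ids =
#'   accessions.
#' @return the normalized site [quant_table], restricted to the shared
#'   samples and to sites with quantified parents.
#' @export
normalize_sites_to_protein <- function(sites, proteins) {
  stopifnot(inherits(sites, "quant_table"), inherits(proteins, "quant_table"))
  if (sites$scale != "log2" || proteins$scale != "log2")
    stop("both tables must be on log2 scale", call. = FALSE)
  shared <- intersect(sample_ids(sites), sample_ids(proteins))
  if (!length(shared))
    stop("site and protein tables share no samples", call. = FALSE)
  parent <- .leading_accession(sites$features$protein_ids)
  idx <- match(parent, feature_ids(proteins))
  keep <- which(!is.na(idx))
  out <- sites[keep, shared]
  out$intensities <- out$intensities -
    proteins$intensities[idx[keep], shared, drop = FALSE]
  out
}

#' Run the TMT proteome / PTM normalization and testing chain
#'
#' Full chain for a multi-plex isobaric-label experiment: isotopic-impurity
#' correction (linear scale, per plex), log2 transform, within-plex median
#' normalization, between-plex IRS normalization through the shared
#' reference channel, optional site-to-protein normalization, and moderated
#' t-tests for the requested group comparisons.
#'
#' @param proteins linear-scale protein [quant_table].
#' @param design a [sample_design()] with `plex_id`, `channel` and one
#'   reference sample per plex.
#' @param sites optional linear-scale PTM-site [quant_table]; when given,
#'   site intensities are normalized to protein intensities before testing.
#' @param impurity optional [impurity_matrix()]; when `NULL` an identity
#'   matrix is assumed (with a warning), i.e. no cross-channel correction.
#' @param comparisons list of length-2 character vectors
#'   `c(group_a, group_b)` to test.
#' @return an object of class `tmt_run`: `proteins` and (optionally)
#'   `sites`, each a list with the normalized log2 table (reference channels
#'   removed) and one `modt` fit per comparison, plus a `log` of parameters.
#' @export
run_tmt_workflow <- function(proteins, design, sites = NULL, impurity = NULL,
                             comparisons = list()) {
  stopifnot(inherits(proteins, "quant_table"))
  if (is.null(impurity)) {
    ch <- unique(design$channel[!is.na(design$channel)])
    impurity <- identity_impurity(ch)
    warning("no impurity matrix supplied; assuming identity (no correction)",
            call. = FALSE)
  }
  norm_chain <- function(tab) {
    tab <- .apply_impurity_by_plex(tab, design, impurity)
    lg <- log2_transform(tab)
    plex_of <- design$plex_id[match(sample_ids(lg), design$sample_id)]
    plexes <- lapply(split(sample_ids(lg), plex_of),
                     function(s) median_normalize_within_plex(lg[, s]))
    combined <- irs_normalize(plexes, design)
    combined
  }
  prot_norm <- norm_chain(proteins)
  non_ref <- setdiff(sample_ids(prot_norm),
                     design$sample_id[design$is_reference])
  fit_all <- function(tab) {
    lapply(comparisons, function(cmp)
      moderated_ttest(tab[, intersect(sample_ids(tab), non_ref)], design,
                      cmp[1], cmp[2]))
  }
  out <- list(proteins = list(table = prot_norm[, non_ref],
                              fits = fit_all(prot_norm)))
  if (!is.null(sites)) {
    site_norm <- norm_chain(sites)
    site_rel <- normalize_sites_to_protein(site_norm, prot_norm)
    out$sites <- list(table = site_rel[, intersect(sample_ids(site_rel),
                                                   non_ref)],
                      fits = fit_all(site_rel))
  }
  names(out$proteins$fits) <- vapply(comparisons, paste, "", collapse = "_vs_")
  if (!is.null(out$sites))
    names(out$sites$fits) <- names(out$proteins$fits)
  out$log <- list(comparisons = comparisons,
                  impurity_channels = colnames(unclass(impurity)),
                  n_proteins = nfeatures(prot_norm),
                  n_sites = if (!is.null(out$sites))
                    nfeatures(out$sites$table) else NA_integer_)
  class(out) <- "tmt_run"
  out
}

#' @export
print.tmt_run <- function(x, ...) {
  cat(sprintf("TMT run: %d proteins", x$log$n_proteins))
  if (!is.na(x$log$n_sites)) cat(sprintf(", %d protein-normalized sites",
                                         x$log$n_sites))
  cat(sprintf(", %d comparison(s)\n", length(x$log$comparisons)))
  invisible(x)
}

# impurity correction plex by plex, columns ordered by the impurity channels
.apply_impurity_by_plex <- function(tab, design, impurity) {
  ch_order <- colnames(unclass(impurity))
  idx <- match(sample_ids(tab), design$sample_id)
  if (anyNA(idx))
    stop("samples absent from design: ",
         paste(sample_ids(tab)[is.na(idx)], collapse = ", "), call. = FALSE)
  plex_of <- design$plex_id[idx]
  chan_of <- design$channel[idx]
  m <- tab$intensities
  for (p in unique(plex_of)) {
    cols <- which(plex_of == p)
    ord <- cols[match(ch_order, chan_of[cols])]
    if (anyNA(ord))
      stop("plex ", p, " lacks channel(s): ",
           paste(ch_order[is.na(match(ch_order, chan_of[cols]))],
                 collapse = ", "), call. = FALSE)
    sub <- m[, ord, drop = FALSE]
    colnames(sub) <- ch_order
    corr <- correct_isotope_impurities(sub, impurity)
    m[, ord] <- corr
  }
  out <- tab
  out$intensities <- m
  out
}
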