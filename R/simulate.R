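# Seeded synthetic-data generators with recorded ground truth. These
# emulate the statistical structure of bait-enrichment AP-MS matrices with
# intensity-dependent missingness and of two TMT 10-plexes (3 genotypes x 3
# replicates + a pooled reference channel) with plex batch effects, so that
# every downstream stage can be exercised against known truth without any
# external download.

#' Apply intensity-dependent (MNAR) dropout to a log2 matrix
#'
#' Each entry is dropped independently with probability
#' \eqn{1 / (1 + e^{steepness (x - midpoint)})}: a logistic left-censoring
#' curve, monotone nonincreasing in intensity, equal to 0.5 at the midpoint.
#'
#' @param matrix numeric log2 matrix.
#' @param midpoint intensity at which the dropout probability is 0.5.
#' @param steepness positive slope of the logistic curve.
#' @param seed integer seed.
#' @return the matrix with dropped entries set to `NA`.
#' @export
apply_mnar_missingness <- function(matrix, midpoint, steepness, seed = 1L) {
  stopifnot(is.numeric(matrix))
  if (!is.numeric(steepness) || steepness <= 0)
    stop("`steepness` must be positive", call. = FALSE)
  p_drop <- stats::plogis(-(matrix - midpoint) * steepness)
  with_seed(seed, {
    drop <- stats::runif(length(matrix)) < p_drop
    matrix[drop] <- NA
    matrix
  })
}

#' Simulate a bait-versus-control AP-MS experiment
#'
#' Baseline log2 abundances are drawn from Normal(25, 2); a random subset of
#' features (the true interactors) receives an additive log2 enrichment
#' effect drawn uniformly from `effect_range` in the bait samples; every
#' sample gets a loading shift from U(-0.5, 0.5) and every entry independent
#' measurement noise; left-censored missingness is applied with the logistic
#' MNAR curve. The returned table is on linear scale, as a label-free
#' quantification table would be read from disk.
#'
#' @param n_features total number of protein groups.
#' @param n_interactors number of true interactors (< `n_features`).
#' @param reps_per_group replicates per group (>= 2).
#' @param effect_range log2 enrichment range `c(low, high)`.
#' @param noise_sd per-entry measurement noise sd on log2 scale.
#' @param mnar_midpoint,mnar_steepness dropout-curve parameters.
#' @param seed integer seed; the generator is a pure function of its
#'   parameters and seed.
#' @return list with `table` (linear [quant_table]), `design`
#'   ([sample_design()], groups `"bait"` and `"ctrl"`) and `truth` (list:
#'   `interactors` data.frame of feature id + log2 effect, `sample_shifts`,
#'   `missingness_params`, `seed`).
#' @export
simulate_apms_experiment <- function(n_features = 2000L, n_interactors = 50L,
                                     reps_per_group = 3L,
                                     effect_range = c(2, 12),
                                     noise_sd = 0.3,
                                     mnar_midpoint = 22, mnar_steepness = 1,
                                     seed = 1L) {
  n_features <- stop_if_not_count(n_features, "n_features", 1L)
  n_interactors <- stop_if_not_count(n_interactors, "n_interactors", 0L)
  reps_per_group <- stop_if_not_count(reps_per_group, "reps_per_group", 2L)
  if (n_interactors >= n_features)
    stop("`n_interactors` must be smaller than `n_features`", call. = FALSE)
  if (length(effect_range) != 2 || effect_range[1] > effect_range[2])
    stop("`effect_range` must be c(low, high) with low <= high", call. = FALSE)
  samples <- c(paste0("bait_", seq_len(reps_per_group)),
               paste0("ctrl_", seq_len(reps_per_group)))
  groups <- rep(c("bait", "ctrl"), each = reps_per_group)
  sim <- with_seed(seed, {
    base <- stats::rnorm(n_features, 25, 2)
    ids <- sprintf("SIMP%04d", seq_len(n_features))
    m <- matrix(base, n_features, length(samples),
                dimnames = list(ids, samples))
    inter_idx <- if (n_interactors > 0) sample.int(n_features, n_interactors)
    else integer(0)
    effects <- stats::runif(n_interactors, effect_range[1], effect_range[2])
    m[inter_idx, groups == "bait"] <- m[inter_idx, groups == "bait"] + effects
    shifts <- stats::runif(length(samples), -0.5, 0.5)
    m <- sweep(m, 2L, shifts, "+")
    m <- m + stats::rnorm(length(m), 0, noise_sd)
    razor <- 2L + stats::rpois(n_features, 10)
    list(m = m, ids = ids, inter_idx = inter_idx, effects = effects,
         shifts = shifts, razor = razor)
  })
  m <- apply_mnar_missingness(sim$m, mnar_midpoint, mnar_steepness,
                              seed = derive_seed(seed, 7L))
  features <- data.frame(feature_id = sim$ids,
                         gene_name = sim$ids,
                         protein_ids = sim$ids,
                         razor_unique_peptides = sim$razor,
                         is_contaminant = FALSE, is_reverse = FALSE,
                         stringsAsFactors = FALSE)
  table <- quant_table(2^m, features, scale = "linear")
  design <- sample_design(data.frame(
    sample_id = samples, group = groups,
    replicate = rep(seq_len(reps_per_group), 2),
    stringsAsFactors = FALSE))
  truth <- list(interactors = data.frame(feature_id = sim$ids[sim$inter_idx],
                                         effect = sim$effects,
                                         stringsAsFactors = FALSE),
                sample_shifts = stats::setNames(sim$shifts, samples),
                missingness_params = c(midpoint = mnar_midpoint,
                                       steepness = mnar_steepness),
                seed = seed)
  list(table = table, design = design, truth = truth)
}

#' Random phosphosite sequence windows with a fixed SQ count
#'
#' Uniform windows over the 20 canonical amino acids, centered on serine;
#' exactly `sq_positive` of them carry glutamine at the center+1 position,
#' the rest a non-glutamine residue. Which windows are SQ-positive is chosen
#' at random (seeded).
#'
#' @param n number of windows.
#' @param sq_positive number of SQ-positive windows (<= `n`).
#' @param width odd window width >= 3 (default 31).
#' @param seed integer seed.
#' @return character vector of windows with logical attribute `"is_sq"`.
#' @export
generate_sequence_windows <- function(n, sq_positive, width = 31L, seed = 1L) {
  n <- stop_if_not_count(n, "n", 0L)
  sq_positive <- stop_if_not_count(sq_positive, "sq_positive", 0L)
  if (sq_positive > n) stop("`sq_positive` must be <= `n`", call. = FALSE)
  if (width %% 2 == 0 || width < 3)
    stop("`width` must be odd and >= 3", call. = FALSE)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  with_seed(seed, {
    center <- (width + 1L) %/% 2L
    mat <- matrix(sample(aa, n * width, replace = TRUE), n, width)
    mat[, center] <- "S"
    is_sq <- rep(FALSE, n)
    if (sq_positive > 0) is_sq[sample.int(n, sq_positive)] <- TRUE
    mat[is_sq, center + 1L] <- "Q"
    if (any(!is_sq))
      mat[!is_sq, center + 1L] <- sample(setdiff(aa, "Q"), sum(!is_sq),
                                         replace = TRUE)
    windows <- apply(mat, 1L, paste, collapse = "")
    attr(windows, "is_sq") <- is_sq
    windows
  })
}

# neighbour-spill impurity matrix for a set of channels
.make_impurity <- function(channels, spill = 0.02) {
  n <- length(channels)
  M <- diag(1 - 2 * spill, n)
  for (i in seq_len(n)) {
    if (i > 1) M[i - 1, i] <- spill else M[i, i] <- M[i, i] + spill
    if (i < n) M[i + 1, i] <- spill else M[i, i] <- M[i, i] + spill
  }
  dimnames(M) <- list(channels, channels)
  impurity_matrix(M)
}

#' Simulate a two-plex TMT PTM experiment with ground truth
#'
#' Emulates the study design the TMT chain expects: two TMT 10-plexes (one
#' untreated, one treated), each carrying 3 genotypes x 3 replicates plus a
#' reference channel (label 131N) holding the pooled REF aliquot: a single
#' mixture of all samples from both plexes, so its per-feature value is the
#' mean of all sample signals before batch and impurity distortion,
#' identical in composition across plexes. Plex batch effects are multiplicative, \eqn{2^{U(-1, 1)}};
#' reporter signals are mixed through the impurity matrix before output.
#' A fraction of sites is treatment-regulated: the full log2 effect (drawn
#' from `effect_range`, random sign) is applied in the wildtype and scaled
#' by the per-genotype `attenuation` factor in the mutants. Site sequence
#' windows carry the SQ motif with probability `sq_frac` among regulated
#' sites and `sq_background` among unregulated ones. A fraction of parent
#' proteins also responds to treatment, which the site-to-protein
#' normalization must cancel.
#'
#' @param n_proteins number of proteins.
#' @param sites_per_protein mean number of phosphosites per protein
#'   (Poisson).
#' @param reps replicates per genotype per plex (default 3).
#' @param genotypes genotype labels; the first is the wildtype.
#' @param treatments two treatment labels, one plex each
#'   (untreated, treated).
#' @param frac_regulated fraction of sites with a treatment effect.
#' @param sq_frac SQ-motif probability among regulated sites (default 0.536,
#'   the fraction observed among damage-induced phosphosites).
#' @param sq_background SQ-motif probability among unregulated sites.
#' @param effect_range log2 magnitude range of site treatment effects.
#' @param attenuation named per-genotype multiplier on the treatment effect
#'   (wildtype 1; mutants < 1 model a damped damage response).
#' @param frac_protein_regulated fraction of proteins with a treatment
#'   effect drawn from U(-2, 2).
#' @param noise_sd per-entry measurement noise sd (log2).
#' @param ref_noise_sd measurement noise sd of the reference channel
#'   (default `noise_sd / 4`: the pooled REF aliquot is labelled with a
#'   threefold reagent amount and measured at correspondingly higher
#'   intensity, so its reporter noise is well below a single sample's).
#' @param seed integer seed.
#' @return list with `proteins` and `sites` (linear [quant_table]s),
#'   `design` ([sample_design()], groups `"<genotype>_<treatment>"`),
#'   `impurity` ([impurity_matrix()]) and `truth` (regulated sites with
#'   direction and effect, per-genotype attenuation, protein effects, plex
#'   batch log2 shifts, sample shifts, SQ flags, the pre-distortion log2
#'   matrices, seed).
#' @export
simulate_tmt_ptm_experiment <- function(n_proteins = 800L,
                                        sites_per_protein = 2,
                                        reps = 3L,
                                        genotypes = c("WT", "KO", "CI"),
                                        treatments = c("untr", "etop"),
                                        frac_regulated = 0.1,
                                        sq_frac = 0.536,
                                        sq_background = 0.1,
                                        effect_range = c(1, 3),
                                        attenuation = c(WT = 1, KO = 0.4,
                                                        CI = 0.8),
                                        frac_protein_regulated = 0.1,
                                        noise_sd = 0.2,
                                        ref_noise_sd = noise_sd / 4,
                                        seed = 1L) {
  n_proteins <- stop_if_not_count(n_proteins, "n_proteins", 1L)
  reps <- stop_if_not_count(reps, "reps", 2L)
  if (length(treatments) != 2)
    stop("exactly two treatments (one plex each) are expected", call. = FALSE)
  for (fr in c(frac_regulated, sq_frac, sq_background, frac_protein_regulated))
    if (fr < 0 || fr > 1) stop("fractions must lie in [0, 1]", call. = FALSE)
  if (!all(genotypes %in% names(attenuation)))
    stop("`attenuation` must name every genotype", call. = FALSE)
  channels <- c("126C", "127N", "127C", "128N", "128C",
                "129N", "129C", "130N", "130C", "131N")
  n_ch_needed <- length(genotypes) * reps + 1L
  if (n_ch_needed > length(channels))
    stop("design needs ", n_ch_needed, " channels; a 10-plex has 10",
         call. = FALSE)
  design <- do.call(rbind, lapply(treatments, function(trt) {
    smp <- c(as.vector(outer(seq_len(reps), genotypes,
                             function(r, g) paste0(g, "_", trt, "_", r))),
             paste0("REF_", trt))
    data.frame(sample_id = smp,
               group = c(as.vector(outer(seq_len(reps), genotypes,
                                         function(r, g) paste0(g, "_", trt))),
                         NA_character_),
               replicate = c(rep(seq_len(reps), length(genotypes)), 1L),
               plex_id = trt,
               channel = channels[c(seq_len(n_ch_needed - 1L), 10L)],
               is_reference = c(rep(FALSE, n_ch_needed - 1L), TRUE),
               stringsAsFactors = FALSE)
  }))
  design <- sample_design(design)
  impurity <- .make_impurity(channels[seq_len(10L)])
  out <- with_seed(seed, {
    prot_ids <- sprintf("SIMQ%04d", seq_len(n_proteins))
    prot_base <- stats::rnorm(n_proteins, 25, 2)
    n_prot_reg <- round(frac_protein_regulated * n_proteins)
    prot_reg <- if (n_prot_reg > 0) sample.int(n_proteins, n_prot_reg)
    else integer(0)
    prot_eff <- stats::setNames(rep(0, n_proteins), prot_ids)
    prot_eff[prot_reg] <- stats::runif(n_prot_reg, -2, 2)

    n_sites_per <- stats::rpois(n_proteins, sites_per_protein)
    parent <- rep(seq_len(n_proteins), n_sites_per)
    n_sites <- length(parent)
    site_pos <- unlist(lapply(n_sites_per, function(k)
      if (k > 0) sort(sample.int(800, k)) else integer(0)))
    if (n_sites == 0)
      stop("simulation produced no sites; increase `sites_per_protein`",
           call. = FALSE)
    site_ids <- paste(prot_ids[parent], site_pos, 1L, sep = "_")
    site_offset <- stats::rnorm(n_sites, -2, 1)

    n_reg <- round(frac_regulated * n_sites)
    reg_idx <- if (n_reg > 0) sample.int(n_sites, n_reg) else integer(0)
    reg_dir <- sample(c(-1, 1), n_reg, replace = TRUE)
    reg_eff <- stats::runif(n_reg, effect_range[1], effect_range[2])
    site_eff <- rep(0, n_sites)
    site_eff[reg_idx] <- reg_dir * reg_eff

    is_sq <- stats::runif(n_sites) < sq_background
    if (n_reg > 0) is_sq[reg_idx] <- stats::runif(n_reg) < sq_frac
    windows <- .windows_from_flags(is_sq)

    n_smp <- nrow(design)
    shifts <- stats::setNames(stats::runif(n_smp, -0.5, 0.5),
                              design$sample_id)
    batch <- stats::setNames(stats::runif(length(treatments), -1, 1),
                             treatments)

    signal_for <- function(base, eff_of) {
      m <- matrix(NA_real_, length(base), n_smp,
                  dimnames = list(names(base), design$sample_id))
      for (j in seq_len(n_smp)) {
        if (design$is_reference[j]) next
        geno <- sub("_.*$", "", design$group[j])
        trt <- design$plex_id[j]
        treated <- trt == treatments[2]
        m[, j] <- base + (if (treated) eff_of(geno) else 0) +
          shifts[j] + stats::rnorm(length(base), 0, noise_sd)
      }
      # pooled REF aliquot: one mixture of ALL samples (both plexes), split
      # and re-measured in every plex -- identical composition across
      # plexes, so IRS anchoring removes technical shifts, not biology
      pool <- rowMeans(m[, !design$is_reference, drop = FALSE])
      for (trt in treatments) {
        rcol <- which(design$plex_id == trt & design$is_reference)
        m[, rcol] <- pool + shifts[rcol] +
          stats::rnorm(length(base), 0, ref_noise_sd)
      }
      m
    }
    prot_signal <- signal_for(stats::setNames(prot_base, prot_ids),
                              function(g) prot_eff)
    site_base <- prot_base[parent] + site_offset
    names(site_base) <- site_ids
    site_signal <- signal_for(site_base, function(g) {
      prot_eff[parent] + site_eff * attenuation[[g]]
    })

    distort <- function(m) {
      md <- sweep(m, 2L, batch[design$plex_id[match(colnames(m),
                                                    design$sample_id)]], "+")
      lin <- 2^md
      for (trt in treatments) {
        cols <- which(design$plex_id == trt)
        ord <- cols[match(colnames(unclass(impurity)), design$channel[cols])]
        lin[, ord] <- t(unclass(impurity) %*% t(lin[, ord, drop = FALSE]))
      }
      lin
    }
    list(prot_signal = prot_signal, site_signal = site_signal,
         prot_lin = distort(prot_signal), site_lin = distort(site_signal),
         prot_ids = prot_ids, prot_eff = prot_eff,
         site_ids = site_ids, parent = parent, site_pos = site_pos,
         site_eff = site_eff, reg_idx = reg_idx, is_sq = is_sq,
         windows = windows, shifts = shifts, batch = batch)
  })
  prot_features <- data.frame(feature_id = out$prot_ids,
                              gene_name = out$prot_ids,
                              protein_ids = out$prot_ids,
                              razor_unique_peptides = 10L,
                              is_contaminant = FALSE, is_reverse = FALSE,
                              stringsAsFactors = FALSE)
  proteins <- quant_table(out$prot_lin, prot_features, scale = "linear")
  site_features <- data.frame(feature_id = out$site_ids,
                              gene_name = out$prot_ids[out$parent],
                              protein_ids = out$prot_ids[out$parent],
                              razor_unique_peptides = 0L,
                              is_contaminant = FALSE, is_reverse = FALSE,
                              residue = "S",
                              position = out$site_pos,
                              sequence_window = out$windows,
                              multiplicity = 1L,
                              localization_prob = NA_real_,
                              multi_acetyl_flag = FALSE,
                              stringsAsFactors = FALSE)
  sites <- quant_table(out$site_lin, site_features, scale = "linear")
  truth <- list(
    regulated_sites = data.frame(site_key = out$site_ids[out$reg_idx],
                                 effect = out$site_eff[out$reg_idx],
                                 direction = ifelse(out$site_eff[out$reg_idx] > 0,
                                                    "up", "down"),
                                 stringsAsFactors = FALSE),
    attenuation = attenuation,
    protein_effects = out$prot_eff,
    plex_batch_log2 = out$batch,
    sample_shifts = out$shifts,
    is_sq = stats::setNames(out$is_sq, out$site_ids),
    pre_distortion_proteins = out$prot_signal,
    pre_distortion_sites = out$site_signal,
    seed = seed)
  list(proteins = proteins, sites = sites, design = design,
       impurity = impurity, truth = truth)
}

# windows from SQ flags, uniform alphabet, width 31, center S
.windows_from_flags <- function(is_sq, width = 31L) {
  n <- length(is_sq)
  if (n == 0) return(character(0))
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  center <- (width + 1L) %/% 2L
  mat <- matrix(sample(aa, n * width, replace = TRUE), n, width)
  mat[, center] <- "S"
  mat[is_sq, center + 1L] <- "Q"
  if (any(!is_sq))
    mat[!is_sq, center + 1L] <- sample(setdiff(aa, "Q"), sum(!is_sq),
                                       replace = TRUE)
  apply(mat, 1L, paste, collapse = "")
}
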