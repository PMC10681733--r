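#' Quantification table
#'
#' A `quant_table` holds a features-by-samples intensity matrix together with
#' per-feature metadata and an explicit scale tag. Missing quantifications are
#' stored as `NA` (MaxQuant writes `0` for "not quantified"; zeros are
#' converted to `NA` on read so that the left-censored imputation rule is
#' meaningful). Linear-scale intensities are non-negative; log2-scale
#' intensities are unrestricted reals.
#'
#' @param intensities numeric matrix, features in rows, samples in columns.
#'   Row names are feature ids, column names sample ids.
#' @param features data.frame of per-feature metadata with at least a
#'   `feature_id` column matching the matrix row names. Conventional columns:
#'   `gene_name`, `protein_ids` (";"-joined accessions),
#'   `razor_unique_peptides`, `is_contaminant`, `is_reverse`; site tables add
#'   `residue`, `position`, `sequence_window`, `multiplicity`,
#'   `localization_prob`, `multi_acetyl_flag`.
#' @param scale `"linear"` or `"log2"`.
#' @return an object of class `quant_table`.
#' @examples
#' m <- matrix(c(100, 200, 50, NA), 2, 2,
#'             dimnames = list(c("P1", "P2"), c("s1", "s2")))
#' qt <- quant_table(m, data.frame(feature_id = c("P1", "P2")))
#' nfeatures(qt)
#' @export
quant_table <- function(intensities, features = NULL, scale = c("linear", "log2")) {
  scale <- match.arg(scale)
  if (!is.matrix(intensities) || !is.numeric(intensities))
    stop("`intensities` must be a numeric matrix", call. = FALSE)
  if (is.null(rownames(intensities)))
    stop("`intensities` must have feature ids as row names", call. = FALSE)
  if (is.null(colnames(intensities)))
    stop("`intensities` must have sample ids as column names", call. = FALSE)
  if (is.null(features))
    features <- data.frame(feature_id = rownames(intensities),
                           stringsAsFactors = FALSE)
  if (!"feature_id" %in% names(features))
    stop("`features` must contain a `feature_id` column", call. = FALSE)
  if (!"gene_name" %in% names(features)) features$gene_name <- NA_character_
  if (!"razor_unique_peptides" %in% names(features))
    features$razor_unique_peptides <- 0L
  if (!"is_contaminant" %in% names(features)) features$is_contaminant <- FALSE
  if (!"is_reverse" %in% names(features)) features$is_reverse <- FALSE
  obj <- structure(list(intensities = intensities,
                        features = features,
                        scale = scale),
                   class = "quant_table")
  validate_quant_table(obj)
}

validate_quant_table <- function(x) {
  stopifnot(inherits(x, "quant_table"))
  ids <- x$features$feature_id
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    stop("duplicate feature ids: ", paste(utils::head(dup, 10), collapse = ", "),
         call. = FALSE)
  }
  if (nrow(x$intensities) != nrow(x$features))
    stop("intensity matrix and feature metadata disagree on feature count",
         call. = FALSE)
  rn <- rownames(x$intensities)
  if (is.null(rn) && nrow(x$intensities) == 0L) rn <- character(0)
  if (!identical(rn, as.character(ids)))
    stop("intensity row names must equal features$feature_id", call. = FALSE)
  if (x$scale == "linear" && any(x$intensities < 0, na.rm = TRUE))
    stop("linear-scale intensities must be non-negative", call. = FALSE)
  x
}

#' @export
print.quant_table <- function(x, ...) {
  cat(sprintf("quant_table: %d features x %d samples [%s scale]\n",
              nrow(x$intensities), ncol(x$intensities), x$scale))
  miss <- mean(is.na(x$intensities))
  cat(sprintf("  missing: %.1f%%\n", 100 * miss))
  extra <- setdiff(names(x$features),
                   c("feature_id", "gene_name", "razor_unique_peptides",
                     "is_contaminant", "is_reverse"))
  if (length(extra))
    cat("  extra feature columns:", paste(extra, collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.quant_table <- function(x) dim(x$intensities)

#' Number of features / samples in a quant_table
#' @param x a [quant_table].
#' @return integer count.
#' @export
nfeatures <- function(x) nrow(x$intensities)

#' @rdname nfeatures
#' @export
nsamples <- function(x) ncol(x$intensities)

#' Sample ids of a quant_table
#' @param x a [quant_table].
#' @return character vector.
#' @export
sample_ids <- function(x) colnames(x$intensities)

#' Feature ids of a quant_table
#' @param x a [quant_table].
#' @return character vector.
#' @export
feature_ids <- function(x) rownames(x$intensities)

#' Subset a quant_table by features and/or samples
#'
#' @param x a [quant_table].
#' @param i feature index (logical, integer or feature-id character).
#' @param j sample index.
#' @param ... unused.
#' @return a [quant_table].
#' @export
`[.quant_table` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$intensities))
  if (missing(j)) j <- seq_len(ncol(x$intensities))
  if (is.character(i)) i <- match(i, rownames(x$intensities))
  m <- x$intensities[i, j, drop = FALSE]
  f <- x$features[i, , drop = FALSE]
  rownames(f) <- NULL
  out <- x
  out$intensities <- m
  out$features <- f
  validate_quant_table(out)
}

#' Apply the standard feature-evidence filters
#'
#' Restricts a table to features supported by at least `min_razor_unique`
#' razor + unique peptides and, optionally, drops entries flagged as
#' laboratory contaminants or reverse-database (decoy) hits. Feature order is
#' preserved and the operation is idempotent.
#'
#' @param table a [quant_table].
#' @param min_razor_unique minimum razor + unique peptide count (default 2,
#'   i.e. features with fewer than two supporting peptides are removed).
#' @param drop_contaminants drop features flagged `is_contaminant`.
#' @param drop_reverse drop features flagged `is_reverse`.
#' @return the filtered [quant_table].
#' @export
filter_features <- function(table, min_razor_unique = 2L,
                            drop_contaminants = TRUE, drop_reverse = TRUE) {
  stopifnot(inherits(table, "quant_table"))
  stop_if_not_count(min_razor_unique, "min_razor_unique")
  stop_if_not_flag(drop_contaminants, "drop_contaminants")
  stop_if_not_flag(drop_reverse, "drop_reverse")
  keep <- table$features$razor_unique_peptides >= min_razor_unique
  if (drop_contaminants) keep <- keep & !table$features$is_contaminant
  if (drop_reverse) keep <- keep & !table$features$is_reverse
  keep[is.na(keep)] <- FALSE
  table[which(keep), ]
}

#' Log2-transform a linear-scale quant_table
#'
#' Positive intensities are replaced by their base-2 logarithm; missing
#' entries stay missing. Applying the transform to an already log2-scaled
#' table is an error (double-transform guard).
#'
#' @param table a linear-scale [quant_table].
#' @return the table on log2 scale.
#' @export
log2_transform <- function(table) {
  stopifnot(inherits(table, "quant_table"))
  if (table$scale == "log2")
    stop("table is already on log2 scale", call. = FALSE)
  m <- table$intensities
  m[!is.na(m) & m == 0] <- NA  # zeros are "not quantified"
  m <- log2(m)
  out <- table
  out$intensities <- m
  out$scale <- "log2"
  out
}

#' Threshold configuration for enrichment / regulation calls
#'
#' @param fc_cutoff fold-change cutoff. On `"linear"` scale this is a fold
#'   change > 1 (e.g. 1.5 means \eqn{|log2 FC| \ge log2(1.5)}); on `"log2"`
#'   scale it is used directly as a cutoff on \eqn{|log2 FC|}.
#' @param fdr_cutoff Benjamini-Hochberg adjusted p-value cutoff in (0, 1).
#' @param fc_scale `"linear"` or `"log2"`.
#' @return an object of class `threshold_config`.
#' @examples
#' threshold_config(1.5, 0.05)           # interactome defaults
#' threshold_config(2, 0.01)             # stringent acetylome thresholds
#' @export
threshold_config <- function(fc_cutoff = 1.5, fdr_cutoff = 0.05,
                             fc_scale = c("linear", "log2")) {
  fc_scale <- match.arg(fc_scale)
  if (!is.numeric(fc_cutoff) || length(fc_cutoff) != 1L || fc_cutoff <= 0)
    stop("`fc_cutoff` must be a single positive number", call. = FALSE)
  if (fc_scale == "linear" && fc_cutoff <= 1)
    stop("linear-scale `fc_cutoff` must exceed 1", call. = FALSE)
  if (!is.numeric(fdr_cutoff) || length(fdr_cutoff) != 1L ||
      fdr_cutoff <= 0 || fdr_cutoff >= 1)
    stop("`fdr_cutoff` must lie in (0, 1)", call. = FALSE)
  structure(list(fc_cutoff = fc_cutoff, fdr_cutoff = fdr_cutoff,
                 fc_scale = fc_scale),
            class = "threshold_config")
}

# |log2 FC| cutoff implied by a threshold_config
log2_fc_cutoff <- function(config) {
  if (config$fc_scale == "linear") log2(config$fc_cutoff) else config$fc_cutoff
}
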