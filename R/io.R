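# Readers and writers for the tab-separated quantification-table dialects
# (MaxQuant-style proteinGroups and PTM-site tables) and for sample designs.

.pg_aliases <- list(
  protein_ids  = c("Majority protein IDs", "Protein IDs"),
  gene_name    = c("Gene names", "Gene Names"),
  razor_unique = c("Razor + unique peptides"),
  reverse      = c("Reverse"),
  contaminant  = c("Potential contaminant", "Contaminant")
)

.site_aliases <- list(
  protein      = c("Protein", "Proteins", "Leading proteins"),
  gene_name    = c("Gene names", "Gene Names"),
  amino_acid   = c("Amino acid"),
  position     = c("Position"),
  window       = c("Sequence window"),
  loc_prob     = c("Localization prob"),
  reverse      = c("Reverse"),
  contaminant  = c("Potential contaminant", "Contaminant")
)

.find_col <- function(header, aliases) {
  hit <- aliases[aliases %in% header]
  if (length(hit)) hit[[1]] else NA_character_
}

# Map intensity column names to sample ids. Reporter columns embed the
# channel index ("Reporter intensity corrected 3 plex1" -> sample "plex1_3").
.intensity_samples <- function(cols) {
  out <- rep(NA_character_, length(cols))
  m <- regmatches(cols, regexec("^LFQ intensity (.+)$", cols))
  has <- lengths(m) == 2
  out[has] <- vapply(m[has], `[`, "", 2)
  m <- regmatches(cols, regexec("^Reporter intensity corrected ([0-9]+) (.+)$", cols))
  has <- lengths(m) == 3
  out[has] <- vapply(m[has], function(x) paste0(x[3], "_", x[2]), "")
  m <- regmatches(cols, regexec("^Intensity (.+)$", cols))
  has <- is.na(out) & lengths(m) == 2
  out[has] <- vapply(m[which(has)], `[`, "", 2)
  out
}

.as_missing_zero <- function(m) {
  m[!is.na(m) & m == 0] <- NA
  m
}

.leading_accession <- function(x) {
  vapply(strsplit(as.character(x), ";", fixed = TRUE),
         function(p) if (length(p)) p[[1]] else NA_character_, "")
}

#' Read a quantification table in a MaxQuant-style dialect
#'
#' Parses a tab-separated `proteinGroups`-style table (`dialect =
#' "protein_groups"`) or a PTM-site table (`dialect = "site_table"`, e.g.
#' `Phospho (STY)Sites` / `Acetyl (K)Sites`) into a [quant_table]. Intensity
#' columns are recognized by their canonical prefixes (`"LFQ intensity
#' <sample>"`, `"Reporter intensity corrected <k> <sample>"`, `"Intensity
#' <sample>"`); reporter columns yield sample ids `"<sample>_<k>"`. Empty
#' cells and literal zeros become missing values. For site tables each
#' multiplicity state (`___1`, `___2`, `___3`) becomes an independent feature
#' keyed `"<accession>_<position>_<multiplicity>"`; states with no observed
#' intensity are dropped.
#'
#' @param path path to a UTF-8, tab-delimited file with a header row.
#' @param dialect `"protein_groups"` or `"site_table"`.
#' @return a linear-scale [quant_table]. For protein groups the feature id is
#'   the leading accession of the majority-protein-ids list.
#' @export
read_quant_table <- function(path, dialect = c("protein_groups", "site_table")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.delim(path, sep = "\t", check.names = FALSE, quote = "",
                           stringsAsFactors = FALSE)
  header <- names(raw)
  if (dialect == "protein_groups") {
    icols <- header[!is.na(.intensity_samples(header)) &
                      !grepl("___[0-9]+$", header)]
    if (!length(icols))
      stop("missing intensity columns: expected at least one ",
           "'LFQ intensity <sample>' column", call. = FALSE)
    samples <- .intensity_samples(icols)
    m <- as.matrix(raw[, icols, drop = FALSE])
    storage.mode(m) <- "double"
    colnames(m) <- samples
    idc <- .find_col(header, .pg_aliases$protein_ids)
    if (is.na(idc))
      stop("missing identifier column: 'Majority protein IDs'", call. = FALSE)
    protein_ids <- as.character(raw[[idc]])
    fid <- .leading_accession(protein_ids)
    if (anyDuplicated(fid))
      stop("duplicate feature ids: ",
           paste(unique(fid[duplicated(fid)]), collapse = ", "), call. = FALSE)
    gc_ <- .find_col(header, .pg_aliases$gene_name)
    rc <- .find_col(header, .pg_aliases$razor_unique)
    rev_c <- .find_col(header, .pg_aliases$reverse)
    con_c <- .find_col(header, .pg_aliases$contaminant)
    features <- data.frame(
      feature_id = fid,
      gene_name = if (!is.na(gc_)) as.character(raw[[gc_]]) else NA_character_,
      protein_ids = protein_ids,
      razor_unique_peptides = if (!is.na(rc)) as.integer(raw[[rc]]) else 0L,
      is_contaminant = if (!is.na(con_c)) raw[[con_c]] %in% "+" else FALSE,
      is_reverse = if (!is.na(rev_c)) raw[[rev_c]] %in% "+" else FALSE,
      stringsAsFactors = FALSE)
    rownames(m) <- fid
    quant_table(.as_missing_zero(m), features, scale = "linear")
  } else {
    suffixed <- grep("___[0-9]+$", header, value = TRUE)
    base <- sub("___[0-9]+$", "", suffixed)
    mult <- as.integer(sub("^.*___([0-9]+)$", "\\1", suffixed))
    ok <- !is.na(.intensity_samples(base))
    if (!any(ok))
      stop("missing intensity columns: expected multiplicity-suffixed ",
           "columns such as 'Intensity <sample>___1'", call. = FALSE)
    suffixed <- suffixed[ok]; base <- base[ok]; mult <- mult[ok]
    pc <- .find_col(header, .site_aliases$protein)
    ac <- .find_col(header, .site_aliases$amino_acid)
    poc <- .find_col(header, .site_aliases$position)
    wc <- .find_col(header, .site_aliases$window)
    req <- c("Protein" = pc, "Amino acid" = ac, "Position" = poc,
             "Sequence window" = wc)
    if (anyNA(req))
      stop("missing site-table column: '", names(req)[is.na(req)][1], "'",
           call. = FALSE)
    gc_ <- .find_col(header, .site_aliases$gene_name)
    lc <- .find_col(header, .site_aliases$loc_prob)
    rev_c <- .find_col(header, .site_aliases$reverse)
    con_c <- .find_col(header, .site_aliases$contaminant)
    acc <- .leading_accession(raw[[pc]])
    pos <- as.integer(raw[[poc]])
    mats <- list(); feats <- list()
    for (k in sort(unique(mult))) {
      cols <- suffixed[mult == k]
      samples <- .intensity_samples(base[mult == k])
      mk <- as.matrix(raw[, cols, drop = FALSE])
      storage.mode(mk) <- "double"
      colnames(mk) <- samples
      mk <- .as_missing_zero(mk)
      keep <- rowSums(!is.na(mk)) > 0
      if (!any(keep)) next
      fid <- paste(acc[keep], pos[keep], k, sep = "_")
      fk <- data.frame(
        feature_id = fid,
        gene_name = if (!is.na(gc_)) as.character(raw[[gc_]])[keep] else NA_character_,
        protein_ids = acc[keep],
        razor_unique_peptides = 0L,
        is_contaminant = if (!is.na(con_c)) raw[[con_c]][keep] %in% "+" else FALSE,
        is_reverse = if (!is.na(rev_c)) raw[[rev_c]][keep] %in% "+" else FALSE,
        residue = as.character(raw[[ac]])[keep],
        position = pos[keep],
        sequence_window = as.character(raw[[wc]])[keep],
        multiplicity = k,
        localization_prob = if (!is.na(lc)) as.numeric(raw[[lc]])[keep] else NA_real_,
        multi_acetyl_flag = FALSE,
        stringsAsFactors = FALSE)
      mk <- mk[keep, , drop = FALSE]
      rownames(mk) <- fid
      mats[[as.character(k)]] <- mk
      feats[[as.character(k)]] <- fk
    }
    if (!length(mats))
      stop("site table contains no quantified sites", call. = FALSE)
    m <- do.call(rbind, mats)
    features <- do.call(rbind, feats)
    rownames(features) <- NULL
    if (anyDuplicated(features$feature_id))
      stop("duplicate feature ids: ",
           paste(unique(features$feature_id[duplicated(features$feature_id)]),
                 collapse = ", "), call. = FALSE)
    quant_table(m, features, scale = "linear")
  }
}

#' Write a quant_table in a MaxQuant-style dialect
#'
#' Inverse of [read_quant_table()] up to the canonical column names: protein
#' tables are written with `"LFQ intensity <sample>"` columns, site tables
#' with `"Intensity <sample>___<multiplicity>"` columns (one row per
#' feature). On linear scale missing values are written as `0`, matching the
#' convention the reader inverts.
#'
#' @param table a [quant_table].
#' @param path output path.
#' @param dialect `"protein_groups"` or `"site_table"`.
#' @return `path`, invisibly.
#' @export
write_quant_table <- function(table, path,
                              dialect = c("protein_groups", "site_table")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(table, "quant_table"))
  f <- table$features
  m <- table$intensities
  mark <- function(flag) ifelse(flag, "+", "")
  if (dialect == "protein_groups") {
    out <- data.frame(
      `Majority protein IDs` = f$protein_ids %||% f$feature_id,
      `Gene names` = f$gene_name,
      `Razor + unique peptides` = f$razor_unique_peptides,
      `Reverse` = mark(f$is_reverse),
      `Potential contaminant` = mark(f$is_contaminant),
      check.names = FALSE, stringsAsFactors = FALSE)
    im <- m
    if (table$scale == "linear") im[is.na(im)] <- 0
    colnames(im) <- paste("LFQ intensity", colnames(m))
    out <- cbind(out, as.data.frame(im, check.names = FALSE))
  } else {
    mults <- sort(unique(f$multiplicity %||% 1L))
    out <- data.frame(
      `Protein` = f$protein_ids %||% f$feature_id,
      `Gene names` = f$gene_name,
      `Amino acid` = f$residue,
      `Position` = f$position,
      `Sequence window` = f$sequence_window,
      `Localization prob` = f$localization_prob %||% NA_real_,
      check.names = FALSE, stringsAsFactors = FALSE)
    for (k in mults) {
      ik <- matrix(0, nrow(m), ncol(m),
                   dimnames = list(NULL, paste0("Intensity ", colnames(m),
                                                "___", k)))
      rows <- which(f$multiplicity == k)
      ik[rows, ] <- ifelse(is.na(m[rows, , drop = FALSE]), 0,
                           m[rows, , drop = FALSE])
      out <- cbind(out, as.data.frame(ik, check.names = FALSE))
    }
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' Sample design table
#'
#' Validates a sample design: one row per sample with its experimental group,
#' replicate number and, for isobaric-label experiments, the plex and channel
#' it was measured in. When plex ids are present every plex must contain
#' exactly one reference-channel sample (the pooled aliquot shared across
#' plexes), and every non-reference sample must carry a group label.
#'
#' @param df data.frame with columns `sample_id`, `group`, `replicate` and
#'   optionally `plex_id`, `channel`, `is_reference`.
#' @return the validated design, classed `sample_design`.
#' @export
sample_design <- function(df) {
  stopifnot(is.data.frame(df))
  need <- c("sample_id", "group", "replicate")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("sample design lacks columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (!"plex_id" %in% names(df)) df$plex_id <- NA_character_
  if (!"channel" %in% names(df)) df$channel <- NA_character_
  if (!"is_reference" %in% names(df)) df$is_reference <- FALSE
  df$sample_id <- as.character(df$sample_id)
  df$group <- as.character(df$group)
  df$is_reference <- as.logical(df$is_reference)
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample ids in design", call. = FALSE)
  if (any(!is.na(df$replicate) & df$replicate < 1))
    stop("replicate numbers must be positive", call. = FALSE)
  bad <- !df$is_reference & (is.na(df$group) | df$group == "")
  if (any(bad))
    stop("non-reference samples without a group: ",
         paste(df$sample_id[bad], collapse = ", "), call. = FALSE)
  if (any(!is.na(df$plex_id))) {
    nref <- tapply(df$is_reference, df$plex_id, sum)
    off <- names(nref)[nref != 1]
    if (length(off))
      stop("each plex must contain exactly one reference sample; offending: ",
           paste(off, collapse = ", "), call. = FALSE)
  }
  class(df) <- c("sample_design", "data.frame")
  df
}

#' Read / write a sample-design TSV
#'
#' Six-column tab-separated format: `sample_id`, `group`, `replicate`,
#' `plex_id`, `channel`, `is_reference`.
#'
#' @param path file path.
#' @return [read_sample_design()] returns a validated `sample_design`.
#' @export
read_sample_design <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  sample_design(df)
}

#' @rdname read_sample_design
#' @param design a `sample_design`.
#' @export
write_sample_design <- function(design, path) {
  utils::write.table(as.data.frame(design), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

# group labels for a set of sample ids, dropping reference channels
design_groups <- function(design, samples) {
  idx <- match(samples, design$sample_id)
  if (anyNA(idx))
    stop("samples absent from design: ",
         paste(samples[is.na(idx)], collapse = ", "), call. = FALSE)
  g <- design$group[idx]
  g[design$is_reference[idx]] <- NA_character_
  names(g) <- samples
  g
}
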