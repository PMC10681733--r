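# Small in-code fixtures shared across the suite.

# quant_table from a plain matrix, defaulting metadata
toy_table <- function(m, scale = "log2", razor = 10L) {
  if (is.null(rownames(m))) rownames(m) <- paste0("P", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- paste0("s", seq_len(ncol(m)))
  quant_table(m, data.frame(feature_id = rownames(m),
                            razor_unique_peptides = razor,
                            stringsAsFactors = FALSE), scale = scale)
}

# two-group design: s1..s<r> group A, then group B
toy_design <- function(reps = 2L, groups = c("A", "B")) {
  sample_design(data.frame(
    sample_id = paste0("s", seq_len(reps * length(groups))),
    group = rep(groups, each = reps),
    replicate = rep(seq_len(reps), length(groups)),
    stringsAsFactors = FALSE))
}

# site quant_table with parent accessions, positions and windows
toy_site_table <- function(m, parents, positions, windows,
                           scale = "log2", residue = "S") {
  ids <- paste(parents, positions, 1L, sep = "_")
  rownames(m) <- ids
  if (is.null(colnames(m))) colnames(m) <- paste0("s", seq_len(ncol(m)))
  quant_table(m, data.frame(feature_id = ids, gene_name = parents,
                            protein_ids = parents,
                            razor_unique_peptides = 0L,
                            is_contaminant = FALSE, is_reverse = FALSE,
                            residue = residue, position = positions,
                            sequence_window = windows, multiplicity = 1L,
                            stringsAsFactors = FALSE), scale = scale)
}

# window string with given center pair, padded with alanines
toy_window <- function(center = "S", next_res = "Q", width = 31L) {
  half <- (width - 1L) %/% 2L
  paste0(strrep("A", half), center, next_res, strrep("A", half - 1L))
}

write_tsv_lines <- function(lines) {
  path <- tempfile(fileext = ".tsv")
  writeLines(lines, path)
  path
}
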