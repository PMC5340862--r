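#' Load a raw count matrix
#'
#' Reads a genes-by-samples TSV (first column `gene_id`), restricts it to the
#' genes present in `gene_table` (dropped genes are reported with a warning),
#' and validates samples against the design. Negative and missing counts are
#' hard errors: missing cells are never zero-imputed because the zero-count
#' condition filter depends on true zeros.
#'
#' @param path counts TSV, genes in rows, samples in columns.
#' @param gene_table a [gene_table].
#' @param design an [steady_state_design()] object.
#' @return Integer matrix (genes x samples) with dimnames.
#' @export
load_counts <- function(path, gene_table, design) {
  tab <- read_tsv(path)
  if (names(tab)[1] != "gene_id") {
    stop("first column of a counts file must be 'gene_id'", call. = FALSE)
  }
  ids <- as.character(tab$gene_id)
  m <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  keep <- ids %in% gene_table$gene_id
  if (any(!keep)) {
    warning(sum(!keep), " gene(s) absent from the gene table were dropped",
            call. = FALSE)
    m <- m[keep, , drop = FALSE]
  }
  validate_counts(m, design)
}

#' Validate a count matrix against a design
#'
#' @param counts numeric genes-by-samples matrix with dimnames.
#' @param design an [steady_state_design()] object.
#' @return The validated integer matrix.
#' @export
validate_counts <- function(counts, design) {
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("count matrix needs gene ids as rownames and sample ids as colnames",
         call. = FALSE)
  }
  unknown <- setdiff(colnames(counts), design$sample_map$sample_id)
  if (length(unknown)) {
    stop("sample(s) absent from the design: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  if (anyNA(counts)) {
    stop("count matrix contains missing cells; missing counts are an error, ",
         "not zero", call. = FALSE)
  }
  if (any(counts < 0)) {
    stop("count matrix contains negative values", call. = FALSE)
  }
  storage.mode(counts) <- "integer"
  counts
}

#' Write a count matrix to TSV
#'
#' @param counts genes-by-samples matrix.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
save_counts <- function(counts, path) {
  df <- data.frame(gene_id = rownames(counts), counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv(df, path)
}
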