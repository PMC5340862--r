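#' Two-species gene catalogs
#'
#' A gene table records, for every gene of the cyanobacterium and (optionally)
#' its heterotrophic partner, the gene length used for per-kilobase
#' normalization and the functional-category labels used for enrichment.
#'
#' @param gene_id character vector of unique gene identifiers.
#' @param species character vector; each element one of `"cyanobacterium"` or
#'   `"heterotroph"`.
#' @param length_bp positive integer gene lengths in base pairs.
#' @param categories character vector of semicolon-delimited category labels
#'   (`""` for none), or a list of character vectors.
#' @param product optional free-text product descriptions.
#' @return A `gene_table`: a data frame with columns `gene_id`, `species`,
#'   `length_bp`, `categories`, `product`.
#' @examples
#' gene_table(c("g1", "g2"), c("cyanobacterium", "heterotroph"),
#'            c(900L, 1500L), c("photosystem_II", ""))
#' @export
gene_table <- function(gene_id, species, length_bp, categories = "",
                       product = "") {
  gene_id <- as.character(gene_id)
  species <- as.character(species)
  if (is.list(categories)) {
    categories <- vapply(categories, paste, character(1), collapse = ";")
  }
  gt <- data.frame(
    gene_id = gene_id,
    species = species,
    length_bp = as.integer(length_bp),
    categories = rep_len(as.character(categories), length(gene_id)),
    product = rep_len(as.character(product), length(gene_id)),
    stringsAsFactors = FALSE
  )
  validate_gene_table(gt)
}

valid_species <- c("cyanobacterium", "heterotroph")

validate_gene_table <- function(gt) {
  required <- c("gene_id", "species", "length_bp", "categories")
  missing <- setdiff(required, names(gt))
  if (length(missing)) {
    stop("gene table is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  dup <- gt$gene_id[duplicated(gt$gene_id)]
  if (length(dup)) {
    stop("duplicate gene_id in gene table: ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  }
  bad_sp <- setdiff(unique(gt$species), valid_species)
  if (length(bad_sp)) {
    stop("unknown species label(s): ", paste(bad_sp, collapse = ", "),
         "; expected one of: ", paste(valid_species, collapse = ", "),
         call. = FALSE)
  }
  if (anyNA(gt$length_bp) || any(gt$length_bp <= 0)) {
    bad <- gt$gene_id[is.na(gt$length_bp) | gt$length_bp <= 0]
    stop("nonpositive length_bp for gene(s): ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  if (!"product" %in% names(gt)) gt$product <- ""
  gt$product <- as.character(gt$product)
  gt$product[is.na(gt$product)] <- ""
  gt$categories <- as.character(gt$categories)
  gt$categories[is.na(gt$categories)] <- ""
  class(gt) <- c("gene_table", "data.frame")
  gt
}

#' Read a gene table from TSV
#'
#' Expects columns `gene_id`, `species`, `length_bp`, `categories`
#' (semicolon-delimited; `product` optional). Duplicate ids and nonpositive
#' lengths are hard errors.
#'
#' @param path TSV file path.
#' @return A [gene_table].
#' @export
load_gene_table <- function(path) {
  validate_gene_table(read_tsv(path))
}

#' Write a gene table to TSV
#'
#' @param gt a [gene_table].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
save_gene_table <- function(gt, path) {
  gt <- validate_gene_table(gt)
  write_tsv(as.data.frame(gt), path)
}

#' Split semicolon-delimited categories into a named list
#'
#' @param gt a [gene_table].
#' @return Named list mapping `gene_id` to a character vector of categories
#'   (zero-length for unannotated genes).
#' @export
gene_categories <- function(gt) {
  out <- strsplit(gt$categories, ";", fixed = TRUE)
  out <- lapply(out, function(x) x[nzchar(x)])
  names(out) <- gt$gene_id
  out
}

#' @export
print.gene_table <- function(x, ...) {
  cat(sprintf("Gene table: %d genes (%d cyanobacterium, %d heterotroph)\n",
              nrow(x), sum(x$species == "cyanobacterium"),
              sum(x$species == "heterotroph")))
  NextMethod()
}
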