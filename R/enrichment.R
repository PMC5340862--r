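#' Functional enrichment ratio
#'
#' The fraction of a gene set annotated with a category divided by that
#' category's fraction of the reference universe:
#' `(k/n) / (K/N)`.
#'
#' @param k category hits in the set.
#' @param n set size (> 0).
#' @param K category size in the universe (> 0).
#' @param N universe size.
#' @return The enrichment ratio (>= 0).
#' @export
enrichment_ratio <- function(k, n, K, N) {
  if (n == 0 || K == 0) {
    stop("enrichment ratio is undefined for n = 0 or K = 0", call. = FALSE)
  }
  check_table(k, n, K, N)
  (k / n) / (K / N)
}

check_table <- function(k, n, K, N) {
  vals <- c(k, n, K, N)
  if (any(vals < 0) || any(vals != floor(vals))) {
    stop("k, n, K, N must be nonnegative integers", call. = FALSE)
  }
  if (K > N || n > N) stop("n and K cannot exceed N", call. = FALSE)
  if (any(k > min(n, K))) stop("k cannot exceed min(n, K)", call. = FALSE)
  if (any(k < max(0, n + K - N))) {
    stop("k is below the hypergeometric support (n + K - N)", call. = FALSE)
  }
  invisible(TRUE)
}

#' One-sided hypergeometric tail probability
#'
#' Exact tail of the hypergeometric distribution for a 2x2 category table:
#' `P(X >= k)` for over-representation (default) or `P(X <= k)` for
#' under-representation, where X counts category members in a size-`n` draw
#' without replacement from a universe of `N` genes of which `K` carry the
#' category. Equivalent to the one-sided Fisher exact test.
#'
#' @inheritParams enrichment_ratio
#' @param tail `"over"` or `"under"`.
#' @return p value(s) in `[0, 1]`; `k` may be a vector for fixed `n, K, N`.
#' @export
fisher_p <- function(k, n, K, N, tail = c("over", "under")) {
  tail <- match.arg(tail)
  check_table(k, n, K, N)
  if (tail == "over") {
    stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  } else {
    stats::phyper(k, K, N - K, n)
  }
}

#' Enrichment of every category in a gene set
#'
#' Computes the enrichment ratio and one-sided exact-test p value for each
#' functional category present in the reference universe. The universe is
#' species-restricted: all genes of the set's species (`"species-genome"`,
#' default, mirroring a whole-genome reference) or only those that survived
#' filtering (`"species-filtered"`, supply `filtered_ids`). The significance
#' flag uses the raw p value (`p < alpha`); Benjamini-Hochberg adjusted
#' values are reported alongside.
#'
#' @param set_ids character vector of gene ids (one species).
#' @param genes a [gene_table].
#' @param universe `"species-genome"` or `"species-filtered"`.
#' @param filtered_ids gene ids surviving filters; required for
#'   `"species-filtered"`.
#' @param tail `"over"` (default) or `"under"`.
#' @param alpha significance level on the raw p value (default 0.05).
#' @return Data frame sorted by p with columns `category`, `N`, `K`, `n`,
#'   `k`, `ratio`, `p`, `p_adj`, `significant`.
#' @export
enrich_all <- function(set_ids, genes,
                       universe = c("species-genome", "species-filtered"),
                       filtered_ids = NULL, tail = c("over", "under"),
                       alpha = 0.05) {
  universe <- match.arg(universe)
  tail <- match.arg(tail)
  set_ids <- unique(as.character(set_ids))
  sp <- unique(genes$species[match(set_ids, genes$gene_id)])
  if (anyNA(sp)) {
    stop("set contains gene(s) absent from the gene table", call. = FALSE)
  }
  if (length(sp) != 1) {
    stop("set must contain genes of exactly one species; got: ",
         paste(sp, collapse = ", "), call. = FALSE)
  }
  uni <- genes$gene_id[genes$species == sp]
  if (universe == "species-filtered") {
    if (is.null(filtered_ids)) {
      stop("universe = 'species-filtered' requires filtered_ids",
           call. = FALSE)
    }
    uni <- intersect(uni, filtered_ids)
  }
  if (!length(uni)) stop("empty universe", call. = FALSE)
  if (!all(set_ids %in% uni)) {
    stop("set is not a subset of the universe", call. = FALSE)
  }

  cats <- gene_categories(genes[match(uni, genes$gene_id), , drop = FALSE])
  cat_by_gene <- stack_categories(cats)
  if (!nrow(cat_by_gene)) {
    stop("no categories present in the universe", call. = FALSE)
  }
  N <- length(uni)
  n <- length(set_ids)
  per_cat <- split(cat_by_gene$gene_id, cat_by_gene$category)
  records <- lapply(names(per_cat), function(cc) {
    members <- per_cat[[cc]]
    K <- length(members)
    k <- sum(set_ids %in% members)
    data.frame(
      category = cc, N = N, K = K, n = n, k = k,
      ratio = if (n > 0 && K > 0) (k / n) / (K / N) else NA_real_,
      p = fisher_p(k, n, K, N, tail = tail),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, records)
  out$p_adj <- stats::p.adjust(out$p, method = "BH")
  out$significant <- out$p < alpha
  out[order(out$p, out$category), , drop = FALSE]
}

stack_categories <- function(cats) {
  lens <- lengths(cats)
  data.frame(
    gene_id = rep(names(cats), lens),
    category = unlist(cats, use.names = FALSE),
    stringsAsFactors = FALSE
  )
}
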