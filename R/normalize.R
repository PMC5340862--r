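#' Median-of-ratios size factors
#'
#' For each sample, the size factor is the median over reference genes of
#' `count / geometric mean across samples`, where the reference set is the
#' genes with strictly positive counts in every sample. This is the standard
#' median-of-ratios estimator used to normalize RNA-seq libraries.
#'
#' @param counts genes-by-samples count matrix (>= 2 samples).
#' @return Named numeric vector of positive per-sample factors.
#' @export
size_factors <- function(counts) {
  if (ncol(counts) < 2) stop("need >= 2 samples", call. = FALSE)
  ref <- rowSums(counts > 0) == ncol(counts)
  if (!any(ref)) {
    stop("no gene has nonzero counts in every sample; size factors are ",
         "undefined (pseudo-reference fallback is disabled)", call. = FALSE)
  }
  logc <- log(counts[ref, , drop = FALSE])
  loggeo <- rowMeans(logc)
  factors <- apply(logc, 2, function(x) exp(stats::median(x - loggeo)))
  names(factors) <- colnames(counts)
  factors
}

#' Per-kilobase normalized expression
#'
#' Counts are divided by their sample's size factor and by gene length in
#' kilobases. The `"scaled"` variant (default) further rescales each sample by
#' `1e6 / sum of its size-factor-normalized counts`, giving a classic
#' reads-per-kilobase-per-million convention; `"per-kb"` leaves the values as
#' normalized counts per kilobase. With `library = "per-species"` the
#' per-million denominator is computed within each species' genes instead of
#' the joint library, which matters when the community is strongly skewed.
#'
#' @param counts genes-by-samples count matrix.
#' @param factors size factors from [size_factors()] computed on `counts`.
#' @param genes a [gene_table] covering the rows of `counts`.
#' @param variant `"scaled"` (per-million, default) or `"per-kb"`.
#' @param library `"joint"` (default) or `"per-species"`; only used by the
#'   scaled variant.
#' @return Numeric matrix of nonnegative expression values with attribute
#'   `variant`.
#' @export
per_kb_expression <- function(counts, factors, genes,
                              variant = c("scaled", "per-kb"),
                              library = c("joint", "per-species")) {
  variant <- match.arg(variant)
  library <- match.arg(library)
  idx <- match(rownames(counts), genes$gene_id)
  if (anyNA(idx)) {
    stop("count matrix contains gene(s) absent from the gene table",
         call. = FALSE)
  }
  len_kb <- genes$length_bp[idx] / 1000
  norm <- sweep(counts, 2, factors, "/")
  expr <- norm / len_kb
  if (variant == "scaled") {
    if (library == "joint") {
      expr <- sweep(expr, 2, 1e6 / colSums(norm), "*")
    } else {
      for (sp in unique(genes$species[idx])) {
        rows <- genes$species[idx] == sp
        expr[rows, ] <- sweep(expr[rows, , drop = FALSE], 2,
                              1e6 / colSums(norm[rows, , drop = FALSE]), "*")
      }
    }
  }
  attr(expr, "variant") <- variant
  expr
}

#' Replicate means per steady-state condition
#'
#' @param expr genes-by-samples matrix (expression or counts).
#' @param design an [steady_state_design()] object covering the samples.
#' @return Genes-by-conditions matrix of arithmetic replicate means, columns
#'   in design condition order.
#' @export
condition_means <- function(expr, design) {
  labs <- design$conditions$label
  cols <- lapply(labs, function(lab) {
    s <- intersect(condition_samples(design, lab), colnames(expr))
    if (!length(s)) {
      stop("condition ", lab, " has no samples in the matrix", call. = FALSE)
    }
    rowMeans(expr[, s, drop = FALSE])
  })
  out <- matrix(unlist(cols), nrow = nrow(expr),
                dimnames = list(rownames(expr), labs))
  out
}

#' Apply the zero-count and low-abundance gene filters
#'
#' A gene is removed if its mean raw count over replicates is zero in at
#' least one condition, or if its mean expression over all samples is below
#' `min_expr` (strictly `< min_expr`; a gene at exactly the threshold is
#' kept). The zero-count rule takes precedence in the tallies.
#'
#' @param counts genes-by-samples raw count matrix.
#' @param expr matching expression matrix from [per_kb_expression()].
#' @param design an [steady_state_design()] object.
#' @param min_expr abundance threshold in expression units (default 15).
#' @return A `filter_report`: list with `n_input`,
#'   `n_removed_zero_condition`, `n_removed_low_expression`,
#'   `n_masked_low_variance` (0 until [variance_mask()] is applied) and
#'   `kept` gene ids.
#' @export
filter_genes <- function(counts, expr, design, min_expr = 15) {
  cm <- condition_means(counts, design)
  zero_cond <- apply(cm == 0, 1, any)
  low_expr <- rowMeans(expr) < min_expr
  removed_zero <- zero_cond
  removed_low <- !zero_cond & low_expr
  kept <- rownames(counts)[!zero_cond & !low_expr]
  structure(list(
    n_input = nrow(counts),
    n_removed_zero_condition = sum(removed_zero),
    n_removed_low_expression = sum(removed_low),
    n_masked_low_variance = 0L,
    kept = kept
  ), class = "filter_report")
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf(
    "Gene filters: %d in; %d removed (zero-count condition), %d removed (low expression), %d masked (low variance); %d kept\n",
    x$n_input, x$n_removed_zero_condition, x$n_removed_low_expression,
    x$n_masked_low_variance, length(x$kept) - x$n_masked_low_variance))
  invisible(x)
}

#' Mask the lowest-variance (flat) profiles
#'
#' Removes the `floor(fraction * n)` genes with the smallest sample variance
#' across their profile values. Ties are broken by lexicographic gene id so
#' the mask is deterministic. Intended to run on reference-scaled profiles
#' (see [normalize_profile()]) so that "flat" means shape, not magnitude.
#'
#' @param profiles genes-by-conditions matrix with gene ids as rownames.
#' @param fraction fraction to mask, `0 <= fraction < 1` (default 0.30).
#' @return Character vector of kept gene ids.
#' @export
variance_mask <- function(profiles, fraction = 0.30) {
  if (fraction < 0 || fraction >= 1) {
    stop("fraction must be in [0, 1)", call. = FALSE)
  }
  n <- nrow(profiles)
  n_drop <- floor(fraction * n)
  if (n_drop == 0) return(rownames(profiles))
  v <- apply(profiles, 1, stats::var)
  ord <- order(v, rownames(profiles))
  rownames(profiles)[sort(ord[-seq_len(n_drop)])]
}

#' Scale profiles to their lowest-treatment value
#'
#' Divides every profile by its first (lowest-treatment) value, so the first
#' element becomes 1 and the remaining values are fold changes relative to the
#' reference steady state.
#'
#' @param profiles genes-by-conditions matrix (axis-ordered), or a single
#'   numeric profile vector.
#' @return Matrix (or vector) of reference-scaled profiles.
#' @export
normalize_profile <- function(profiles) {
  if (is.null(dim(profiles))) {
    if (profiles[1] == 0) stop("reference value is zero", call. = FALSE)
    return(profiles / profiles[1])
  }
  ref <- profiles[, 1]
  if (any(ref == 0)) {
    bad <- rownames(profiles)[ref == 0]
    stop("reference (lowest-treatment) value is zero for gene(s): ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  profiles / ref
}

#' Log2 mean-centered profile transform
#'
#' Computes `log2(value / profile mean)`, the transform used to display
#' cluster expression patterns. All values must be positive.
#'
#' @param profiles genes-by-conditions matrix or a single profile vector.
#' @return Transformed matrix or vector. Each transformed profile sums to
#'   <= 0, with equality only for constant profiles (Jensen's inequality).
#' @export
log_mean_center <- function(profiles) {
  if (any(profiles <= 0)) {
    stop("log_mean_center requires strictly positive values", call. = FALSE)
  }
  if (is.null(dim(profiles))) {
    return(log2(profiles / mean(profiles)))
  }
  log2(profiles / rowMeans(profiles))
}
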