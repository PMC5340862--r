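#' Call treatment-responsive genes
#'
#' A gene is responsive on an axis when its condition-mean expression changes
#' at least `threshold`-fold between the lowest and highest treatment level;
#' interior conditions are ignored. A pseudocount `epsilon` (in expression
#' units) is added to both extremes before forming the ratio, so genes passing
#' the filters marginally cannot divide by zero. The threshold is inclusive
#' in both directions: `fold >= threshold` calls "up", `fold <= 1/threshold`
#' calls "down".
#'
#' @param cond_means genes-by-conditions matrix from [condition_means()].
#' @param axis_conditions data frame of axis conditions sorted ascending by
#'   treatment value (one element of [validate_design()]'s result), or a
#'   character vector of condition labels in ascending treatment order.
#' @param axis axis name stored in the result (`"irradiance"` or `"pO2"`).
#' @param threshold fold-change threshold (default 2).
#' @param epsilon pseudocount in expression units (default 0.5).
#' @return Data frame with columns `gene_id`, `axis`, `fold_change`
#'   (high extreme over low extreme), `direction` (`up`/`down`/`none`) and
#'   `responsive`.
#' @export
call_responsive <- function(cond_means, axis_conditions,
                            axis = c("irradiance", "pO2"),
                            threshold = 2, epsilon = 0.5) {
  axis <- match.arg(axis)
  labs <- if (is.data.frame(axis_conditions)) {
    axis_conditions$label
  } else {
    as.character(axis_conditions)
  }
  if (length(labs) < 2) stop("axis needs >= 2 conditions", call. = FALSE)
  missing <- setdiff(labs, colnames(cond_means))
  if (length(missing)) {
    stop("condition(s) absent from the means matrix: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  check_scalar(threshold, "threshold", lower = 1, strict_lower = TRUE)
  check_scalar(epsilon, "epsilon", lower = 0)
  lo <- cond_means[, labs[1]]
  hi <- cond_means[, labs[length(labs)]]
  if (any(lo < 0) || any(hi < 0)) {
    stop("condition means must be nonnegative", call. = FALSE)
  }
  fold <- (hi + epsilon) / (lo + epsilon)
  up <- fold >= threshold
  down <- fold <= 1 / threshold
  data.frame(
    gene_id = rownames(cond_means),
    axis = axis,
    fold_change = unname(fold),
    direction = ifelse(up, "up", ifelse(down, "down", "none")),
    responsive = up | down,
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}

#' Tally responsive calls by species, axis and direction
#'
#' @param calls data frame from [call_responsive()] (several axes may be
#'   row-bound).
#' @param genes a [gene_table] used to look up each gene's species.
#' @return Data frame with columns `species`, `axis`, `direction` (`up`,
#'   `down`, `any`) and `n`.
#' @export
count_responsive <- function(calls, genes) {
  sp <- genes$species[match(calls$gene_id, genes$gene_id)]
  if (anyNA(sp)) {
    stop("call set contains gene(s) absent from the gene table", call. = FALSE)
  }
  resp <- calls[calls$responsive, , drop = FALSE]
  sp <- sp[calls$responsive]
  if (!nrow(resp)) {
    return(data.frame(species = character(), axis = character(),
                      direction = character(), n = integer(),
                      stringsAsFactors = FALSE))
  }
  out <- as.data.frame(table(species = sp, axis = resp$axis,
                             direction = resp$direction),
                       stringsAsFactors = FALSE)
  names(out)[4] <- "n"
  any_dir <- as.data.frame(table(species = sp, axis = resp$axis),
                           stringsAsFactors = FALSE)
  any_dir$direction <- "any"
  names(any_dir)[3] <- "n"
  out <- rbind(out[, c("species", "axis", "direction", "n")],
               any_dir[, c("species", "axis", "direction", "n")])
  out$n <- as.integer(out$n)
  out[out$n > 0 | out$direction == "any", , drop = FALSE]
}

#' Differential expression between two steady states
#'
#' Per-gene test on `log2(expression + epsilon)` replicate values. The default
#' engine is the moderated t statistic (empirical-Bayes variance pooling
#' across genes), which retains power under duplicate designs where a plain
#' per-gene Welch test has ~2 degrees of freedom; `method = "welch"` selects
#' the unmoderated two-sample test. P values are Benjamini-Hochberg adjusted
#' across tested genes, and a gene is flagged significant when
#' `|log2FC| > log2(fold_threshold)` and adjusted p < `alpha`.
#'
#' @param expr genes-by-samples expression matrix.
#' @param design an [steady_state_design()] object.
#' @param condition_a,condition_b condition labels to compare (log2 fold
#'   change is `b - a`).
#' @param method `"moderated"` (default) or `"welch"`.
#' @param epsilon pseudocount before the log transform (default 0.5).
#' @param fold_threshold fold-change component of the significance rule
#'   (default 2, i.e. |log2FC| > 1).
#' @param alpha adjusted-p component of the significance rule (default 0.05).
#' @return Data frame with `gene_id`, `log2fc`, `p`, `p_adj`, `significant`.
#' @export
test_differential <- function(expr, design, condition_a, condition_b,
                              method = c("moderated", "welch"),
                              epsilon = 0.5, fold_threshold = 2,
                              alpha = 0.05) {
  method <- match.arg(method)
  sa <- intersect(condition_samples(design, condition_a), colnames(expr))
  sb <- intersect(condition_samples(design, condition_b), colnames(expr))
  if (length(sa) < 2 || length(sb) < 2) {
    stop("each condition needs >= 2 replicates", call. = FALSE)
  }
  la <- log2(expr[, sa, drop = FALSE] + epsilon)
  lb <- log2(expr[, sb, drop = FALSE] + epsilon)
  log2fc <- rowMeans(lb) - rowMeans(la)
  if (method == "moderated") {
    m <- cbind(la, lb)
    mm <- cbind(intercept = 1,
                b_vs_a = rep(c(0, 1), c(length(sa), length(sb))))
    fit <- limma::eBayes(limma::lmFit(m, mm))
    p <- fit$p.value[, "b_vs_a"]
  } else {
    p <- vapply(seq_len(nrow(la)), function(i) {
      a <- la[i, ]
      b <- lb[i, ]
      if (stats::sd(a) == 0 && stats::sd(b) == 0) {
        return(if (isTRUE(all.equal(mean(a), mean(b)))) 1 else 0)
      }
      stats::t.test(b, a)$p.value
    }, numeric(1))
  }
  p_adj <- stats::p.adjust(p, method = "BH")
  data.frame(
    gene_id = rownames(expr),
    log2fc = unname(log2fc),
    p = unname(p),
    p_adj = unname(p_adj),
    significant = abs(log2fc) > log2(fold_threshold) & p_adj < alpha,
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}
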