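#' Correlation-distance K-means with eigen-gene centroids
#'
#' Groups expression profiles that share a pattern across ordered steady
#' states. Profiles are standardized (mean 0, sd 1) so that the distance
#' `1 - Pearson correlation` is insensitive to each gene's scale and offset.
#' Lloyd iterations alternate (a) assigning every profile to the centroid it
#' correlates with best and (b) recomputing each centroid as the arithmetic
#' mean of its members' standardized profiles, re-standardized — the
#' "eigen-gene" of the cluster. An empty cluster is re-seeded with the profile
#' farthest from its current centroid. The best of `n_init` random
#' initializations (by total within-cluster distance) is returned, making the
#' procedure deterministic for fixed `(profiles, k, seed, n_init)`.
#'
#' @param profiles genes-by-conditions numeric matrix, >= 3 conditions, gene
#'   ids as rownames. Constant (zero-variance) profiles cannot be
#'   standardized and are an error; mask them first ([variance_mask()]).
#' @param k number of clusters (default 4, one per canonical pattern).
#' @param seed integer seed for the random restarts.
#' @param n_init number of random initializations (default 50).
#' @param max_iter Lloyd iteration cap per initialization (default 300).
#' @param axis optional axis name; when `k = 4` the centroids are labeled with
#'   the canonical patterns via [label_patterns()].
#' @return A `cluster_result`: list with `k`, `axis`, `assignments` (named
#'   integer vector), `centroids` (k x conditions matrix), `pattern_labels`,
#'   `seed`, `n_init`, `within_cor` (per-cluster mean member-centroid
#'   correlation), `objective` (total within-cluster `1 - r`) and
#'   `objective_trace` for the winning initialization.
#' @export
kmeans_correlation <- function(profiles, k = 4, seed = 1, n_init = 50,
                               max_iter = 300, axis = NULL) {
  if (ncol(profiles) < 3) stop("axis length must be >= 3", call. = FALSE)
  n <- nrow(profiles)
  if (is.null(rownames(profiles))) {
    stop("profiles need gene ids as rownames", call. = FALSE)
  }
  sds <- apply(profiles, 1, stats::sd)
  if (any(sds == 0)) {
    stop("zero-variance profile(s) cannot be clustered by correlation: ",
         paste(utils::head(rownames(profiles)[sds == 0], 5), collapse = ", "),
         call. = FALSE)
  }
  xs <- standardize_rows(profiles)
  if (nrow(unique(round(xs, 12))) < k) {
    stop("fewer distinct profiles than k", call. = FALSE)
  }
  m <- ncol(xs)

  run_lloyd <- function(centroids) {
    assign_old <- rep(0L, n)
    trace <- numeric(0)
    for (iter in seq_len(max_iter)) {
      r <- xs %*% t(centroids) / (m - 1)    # profile-centroid correlations
      assign_new <- max.col(r, ties.method = "first")
      # re-seed empty clusters with the profile farthest from its centroid
      for (j in which(tabulate(assign_new, k) == 0)) {
        d_own <- 1 - r[cbind(seq_len(n), assign_new)]
        far <- which.max(d_own)
        centroids[j, ] <- xs[far, ]
        assign_new[far] <- j
        r <- xs %*% t(centroids) / (m - 1)
      }
      for (j in seq_len(k)) {
        mem <- assign_new == j
        mu <- colMeans(xs[mem, , drop = FALSE])
        # members can cancel to a constant mean; keep the old centroid then
        if (stats::sd(mu) > 0) {
          centroids[j, ] <- standardize_rows(matrix(mu, 1))
        }
      }
      r <- xs %*% t(centroids) / (m - 1)
      trace <- c(trace, sum(1 - r[cbind(seq_len(n), assign_new)]))
      if (identical(assign_new, assign_old)) break
      assign_old <- assign_new
    }
    list(assignments = assign_new, centroids = centroids,
         objective = trace[length(trace)], trace = trace)
  }

  best <- with_seed(seed, {
    best <- NULL
    for (i in seq_len(n_init)) {
      init <- xs[sample.int(n, k), , drop = FALSE]
      res <- run_lloyd(init)
      if (is.null(best) || res$objective < best$objective) best <- res
    }
    best
  })

  assignments <- best$assignments
  names(assignments) <- rownames(profiles)
  centroids <- best$centroids
  rownames(centroids) <- paste0("cluster_", seq_len(k))
  colnames(centroids) <- colnames(profiles)
  r <- xs %*% t(centroids) / (m - 1)
  within_cor <- vapply(seq_len(k), function(j) {
    mean(r[assignments == j, j])
  }, numeric(1))
  labels <- if (k == 4) label_patterns(centroids) else NULL
  structure(list(
    k = k, axis = axis, assignments = assignments, centroids = centroids,
    pattern_labels = labels, seed = seed, n_init = n_init,
    within_cor = within_cor, objective = best$objective,
    objective_trace = best$trace
  ), class = "cluster_result")
}

# Row-wise standardization to mean 0, sample sd 1.
standardize_rows <- function(x) {
  mu <- rowMeans(x)
  sd <- apply(x, 1, stats::sd)
  (x - mu) / sd
}

# Canonical pattern templates over m ordered conditions, standardized.
pattern_templates <- function(m) {
  t_pos <- seq(-1, 1, length.out = m)
  templates <- rbind(
    tent = -abs(t_pos),
    inverse_tent = abs(t_pos),
    decreasing = -t_pos,
    increasing = t_pos
  )
  standardize_rows(templates)
}

#' Label eigen-gene centroids with canonical patterns
#'
#' Each centroid is matched to one of the four canonical templates (tent:
#' maximum at the midpoint; inverse-tent: minimum at the midpoint;
#' monotonically decreasing; increasing) by Pearson correlation. Labels are
#' made unique by exhaustive maximum-total-correlation matching over the 24
#' permutations; exact ties are broken by template priority order (tent,
#' inverse-tent, decreasing, increasing).
#'
#' @param centroids 4 x conditions matrix of centroids.
#' @return Character vector of pattern labels, one per centroid row.
#' @export
label_patterns <- function(centroids) {
  if (nrow(centroids) != 4) {
    stop("pattern labeling is defined for k = 4 centroids", call. = FALSE)
  }
  templates <- pattern_templates(ncol(centroids))
  r <- stats::cor(t(centroids), t(templates))   # 4 centroids x 4 templates
  perms <- all_permutations(4)
  totals <- apply(perms, 1, function(p) sum(r[cbind(1:4, p)]))
  best <- perms[which.max(totals), ]           # first max = priority order
  rownames(templates)[best]
}

all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1)
  out <- matrix(0L, 0, n)
  for (i in seq_len(n)) {
    rest <- setdiff(seq_len(n), i)
    out <- rbind(out, cbind(i, matrix(rest[sub], nrow(sub))))
  }
  unname(out)
}

#' Per-cluster species membership counts
#'
#' @param cluster a `cluster_result` from [kmeans_correlation()].
#' @param genes a [gene_table] covering the clustered genes.
#' @return Data frame with one row per (cluster, species) and the pattern
#'   label when available; counts sum to the number of clustered genes.
#' @export
cross_species_summary <- function(cluster, genes) {
  sp <- genes$species[match(names(cluster$assignments), genes$gene_id)]
  if (anyNA(sp)) {
    stop("clustered gene(s) absent from the gene table", call. = FALSE)
  }
  tab <- table(cluster = cluster$assignments,
               species = factor(sp, levels = valid_species))
  out <- as.data.frame(tab, stringsAsFactors = FALSE)
  names(out)[3] <- "n"
  out$cluster <- as.integer(out$cluster)
  out$n <- as.integer(out$n)
  if (!is.null(cluster$pattern_labels)) {
    out$pattern <- cluster$pattern_labels[out$cluster]
  }
  out[order(out$cluster, out$species), , drop = FALSE]
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("Correlation K-means: k=%d, %d profiles%s\n", x$k,
              length(x$assignments),
              if (!is.null(x$axis)) paste0(", axis ", x$axis) else ""))
  sizes <- tabulate(x$assignments, x$k)
  for (j in seq_len(x$k)) {
    cat(sprintf("  cluster %d%s: %d genes, mean within-cluster r = %.3f\n", j,
                if (!is.null(x$pattern_labels)) {
                  paste0(" (", x$pattern_labels[j], ")")
                } else "",
                sizes[j], x$within_cor[j]))
  }
  invisible(x)
}
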