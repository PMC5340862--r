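#' Configuration of the synthetic two-species transcriptome
#'
#' The generator plants, for each culture (axenic cyanobacterium or binary
#' consortium) and each treatment axis, a fixed number of responsive genes
#' whose condition means span `responsive_fold` between the axis extremes;
#' every other gene has exactly equal extreme-condition means (flat,
#' tent-shaped or inverse-tent-shaped profiles), so the planted responsive
#' sets are recoverable exactly by the two-fold caller. Default planted counts
#' reproduce the published responsive-gene tallies of the study system:
#' 354/105 (axenic, light/O2) and 339/60 (binary) cyanobacterial genes.
#' Heterotroph counts default to the same genome fractions (276/49 of 2016).
#'
#' Replicate counts follow a negative-binomial observation model
#' (variance = mu + dispersion * mu^2) with per-sample library-depth factors,
#' so the size-factor stage is exercised nontrivially. The default dispersion
#' (0.01, i.e. ~11% biological CV at depth) together with the expression-level
#' floor and the detectability floor for planted responders keeps every
#' gene's 2-fold call margin above 4.5 sigma; see the methods vignette for
#' the calibration.
#'
#' @param n_genes_cyano number of cyanobacterial genes (default 2476).
#' @param n_genes_het number of heterotroph genes (default 2016, so the joint
#'   catalog holds 4492 genes).
#' @param planted_responsive data frame with columns `culture`
#'   (`axenic`/`binary`), `species`, `axis` (`irradiance`/`pO2`) and `n`.
#' @param planted_shapes list with elements `responsive` (weights over
#'   `decreasing`, `increasing`) and `nonresponsive` (weights over `tent`,
#'   `inverse_tent`, `flat`).
#' @param responsive_fold fold span of planted responsive genes between axis
#'   extremes; must exceed 2 (default 4).
#' @param tent_fold midpoint fold of tent and inverse-tent profiles (default
#'   2, a typical saturating response); their extreme-condition ratio is
#'   exactly 1 regardless.
#' @param nonresponsive_fold_max guaranteed ceiling on the extreme-condition
#'   ratio of non-responsive genes; must be < 2 (default 1.5; planted
#'   non-responsive profiles realize a ratio of exactly 1).
#' @param dispersion negative-binomial dispersion; 0 gives a noise-free,
#'   rounded-mean dataset.
#' @param het_read_fraction expected fraction of the sequencing library
#'   originating from the heterotroph (default 0.10).
#' @param baseline_mean expected count of a length-typical, level-1 gene.
#' @param level_meanlog log-normal meanlog of per-gene expression levels.
#' @param level_sdlog log-normal sdlog of per-gene expression levels.
#' @param level_floor lower truncation of expression levels, placed well below
#'   the level mean so that only a small tail truncates while every gene —
#'   including the heterotroph's smaller library share — clears the
#'   downstream abundance filter.
#' @param depth_sdlog log-normal sd of per-sample library-depth factors.
#' @param min_responsive_mean minimum reference-condition expected count for a
#'   gene to be eligible as a planted responder (detectability floor).
#' @return A `truth_config` list.
#' @export
truth_config <- function(n_genes_cyano = 2476L,
                         n_genes_het = 2016L,
                         planted_responsive = NULL,
                         planted_shapes = list(
                           responsive = c(decreasing = 0.5, increasing = 0.5),
                           nonresponsive = c(tent = 0.1, inverse_tent = 0.1,
                                             flat = 0.8)
                         ),
                         responsive_fold = 4,
                         tent_fold = 2,
                         nonresponsive_fold_max = 1.5,
                         dispersion = 0.01,
                         het_read_fraction = 0.10,
                         baseline_mean = 200,
                         level_meanlog = 0.45,
                         level_sdlog = 0.3,
                         level_floor = 1.0,
                         depth_sdlog = 0.1,
                         min_responsive_mean = 60) {
  if (is.null(planted_responsive)) {
    # heterotroph defaults mirror the cyanobacterium's genome fractions
    het_frac <- n_genes_het / 2476
    planted_responsive <- data.frame(
      culture = c("axenic", "axenic", "binary", "binary", "binary", "binary"),
      species = c("cyanobacterium", "cyanobacterium", "cyanobacterium",
                  "cyanobacterium", "heterotroph", "heterotroph"),
      axis = c("irradiance", "pO2", "irradiance", "pO2", "irradiance", "pO2"),
      n = c(354L, 105L, 339L, 60L,
            as.integer(round(339 * het_frac)), as.integer(round(60 * het_frac))),
      stringsAsFactors = FALSE
    )
  }
  check_scalar(n_genes_cyano, "n_genes_cyano", lower = 1)
  check_scalar(n_genes_het, "n_genes_het", lower = 0)
  check_scalar(responsive_fold, "responsive_fold", lower = 2,
               strict_lower = TRUE)
  if (nonresponsive_fold_max >= 2) {
    stop("nonresponsive_fold_max must be < 2 (the responsive threshold)",
         call. = FALSE)
  }
  check_scalar(dispersion, "dispersion", lower = 0)
  check_scalar(het_read_fraction, "het_read_fraction", lower = 0, upper = 0.99)
  check_scalar(baseline_mean, "baseline_mean", lower = 0, strict_lower = TRUE)
  n_per_species <- c(cyanobacterium = as.integer(n_genes_cyano),
                     heterotroph = as.integer(n_genes_het))
  over <- planted_responsive$n > n_per_species[planted_responsive$species]
  if (any(over)) {
    stop("planted responsive counts exceed species gene totals for: ",
         paste(planted_responsive$species[over], collapse = ", "),
         call. = FALSE)
  }
  structure(list(
    n_genes_cyano = as.integer(n_genes_cyano),
    n_genes_het = as.integer(n_genes_het),
    planted_responsive = planted_responsive,
    planted_shapes = planted_shapes,
    responsive_fold = responsive_fold,
    tent_fold = tent_fold,
    nonresponsive_fold_max = nonresponsive_fold_max,
    dispersion = dispersion,
    het_read_fraction = het_read_fraction,
    baseline_mean = baseline_mean,
    level_meanlog = level_meanlog,
    level_sdlog = level_sdlog,
    level_floor = level_floor,
    depth_sdlog = depth_sdlog,
    min_responsive_mean = min_responsive_mean
  ), class = "truth_config")
}

# Fixed vocabulary of functional-category labels assigned by make_genomes().
category_vocabulary <- function() {
  c("photosystem_II", "photosystem_I", "carbon_fixation", "carboxysome",
    "nitrogen_assimilation", "amino_acid_biosynthesis", "methionine_metabolism",
    "vitamin_b12", "ros_detoxification", "fe_s_clusters", "respiration",
    "tca_cycle", "glycolysis", "transport", "translation", "transcription",
    "cell_wall", "chaperones", "cofactor_biosynthesis", "signal_transduction")
}

#' Generate a synthetic two-species gene catalog
#'
#' Gene lengths are uniform integers on 300-3000 bp; each gene carries 0-2
#' functional categories drawn from a fixed 20-label vocabulary.
#'
#' @param truth a [truth_config()].
#' @param seed integer seed; identical seeds give identical tables.
#' @return A [gene_table] with `n_genes_cyano + n_genes_het` records.
#' @export
make_genomes <- function(truth = truth_config(), seed = 1) {
  stopifnot(inherits(truth, "truth_config"))
  with_seed(seed, {
    n_cy <- truth$n_genes_cyano
    n_he <- truth$n_genes_het
    n <- n_cy + n_he
    ids <- c(sprintf("TE_%04d", seq_len(n_cy)),
             if (n_he > 0) sprintf("MR_%04d", seq_len(n_he)))
    species <- rep(c("cyanobacterium", "heterotroph"), c(n_cy, n_he))
    lengths <- sample(300:3000, n, replace = TRUE)
    vocab <- category_vocabulary()
    n_cat <- sample(0:2, n, replace = TRUE, prob = c(0.25, 0.5, 0.25))
    cats <- vapply(n_cat, function(k) {
      paste(sample(vocab, k), collapse = ";")
    }, character(1))
    gene_table(ids, species, lengths, cats,
               product = paste("hypothetical protein", ids))
  })
}

shape_names <- c("tent", "inverse_tent", "decreasing", "increasing", "flat")

# Multiplier applied to a gene's reference mean across the three ordered
# axis conditions. Every shape has minimum multiplier 1, so the reference
# expected count is the gene's minimum across conditions. Monotone shapes
# span `fold` between the extremes (geometric through the midpoint); tent
# and inverse-tent realize `tent_fold` at the midpoint with exactly equal
# extremes, so they are never extreme-ratio responsive.
shape_multipliers <- function(shape, fold, tent_fold = 2) {
  switch(shape,
    flat = c(1, 1, 1),
    increasing = c(1, sqrt(fold), fold),
    decreasing = c(fold, sqrt(fold), 1),
    tent = c(1, tent_fold, 1),
    inverse_tent = c(tent_fold, 1, tent_fold),
    stop("unknown shape: ", shape, call. = FALSE)
  )
}

# Draw per-axis shape assignments for one species under one culture.
assign_shapes <- function(ids, eligible, n_responsive, weights) {
  if (n_responsive > sum(eligible)) {
    stop("not enough detectably expressed genes to plant ", n_responsive,
         " responders", call. = FALSE)
  }
  shape <- rep(NA_character_, length(ids))
  resp_idx <- sample(which(eligible), n_responsive)
  w_r <- weights$responsive / sum(weights$responsive)
  n_dec <- round(n_responsive * w_r[["decreasing"]])
  shape[resp_idx] <- rep(c("decreasing", "increasing"),
                         c(n_dec, n_responsive - n_dec))[
                           sample.int(n_responsive)]
  rest <- which(is.na(shape))
  w_n <- weights$nonresponsive / sum(weights$nonresponsive)
  shape[rest] <- sample(names(w_n), length(rest), replace = TRUE, prob = w_n)
  shape
}

#' Simulate a steady-state transcriptome with planted ground truth
#'
#' Per-gene condition means are `reference mean x irradiance-shape multiplier
#' x pO2-shape multiplier`; the two axes factorize because both axis extremes
#' share the corner condition, so a gene's planted role on one axis never
#' perturbs its extreme-condition ratio on the other. Replicate counts are
#' negative-binomial around the condition mean scaled by a per-sample depth
#' factor. With `dispersion = 0` the generator is fully deterministic in the
#' means: depth factors are 1 and counts are rounded means.
#'
#' @param genes a [gene_table] from [make_genomes()].
#' @param design an [steady_state_design()]; must pass [validate_design()].
#' @param truth a [truth_config()].
#' @param seed integer seed.
#' @param culture `"binary"` (both species) or `"axenic"` (cyanobacterium
#'   only; heterotroph genes are excluded and no library share is reserved).
#' @return List of class `sim_expression` with elements `counts`
#'   (genes x samples integer matrix), `truth` (per-gene data frame with the
#'   planted shape, responsiveness and direction per axis), `genes` (the gene
#'   table actually simulated) and `design`.
#' @export
simulate_expression <- function(genes, design, truth = truth_config(),
                                seed = 1,
                                culture = c("binary", "axenic")) {
  culture <- match.arg(culture)
  stopifnot(inherits(truth, "truth_config"))
  axes <- validate_design(design)
  if (culture == "axenic") {
    genes <- genes[genes$species == "cyanobacterium", , drop = FALSE]
  }
  n <- nrow(genes)
  if (n == 0) stop("no genes to simulate", call. = FALSE)

  with_seed(seed, {
    # Per-gene expected count at the reference (all multipliers 1) condition:
    # proportional to length (read counts scale with gene length) times a
    # truncated log-normal expression level.
    level <- pmax(stats::rlnorm(n, truth$level_meanlog, truth$level_sdlog),
                  truth$level_floor)
    # within-species expected count before the library-share scaling; the
    # responder detectability floor is judged on this scale so the smaller
    # library share of the heterotroph does not empty its eligible set
    mu_species <- truth$baseline_mean * (genes$length_bp / 1650) * level
    mu_ref <- mu_species
    is_het <- genes$species == "heterotroph"
    if (culture == "binary" && any(is_het)) {
      h <- truth$het_read_fraction
      scale_het <- (h / (1 - h)) * sum(mu_ref[!is_het]) / sum(mu_ref[is_het])
      mu_ref[is_het] <- mu_ref[is_het] * scale_het
    }

    planted <- truth$planted_responsive
    planted <- planted[planted$culture == culture, , drop = FALSE]
    shapes <- list()
    for (ax in c("irradiance", "pO2")) {
      shape_ax <- rep(NA_character_, n)
      for (sp in unique(genes$species)) {
        sel <- genes$species == sp
        row <- planted[planted$species == sp & planted$axis == ax, , drop = FALSE]
        n_resp <- if (nrow(row)) row$n[1] else 0L
        eligible <- mu_species[sel] >= truth$min_responsive_mean
        shape_ax[sel] <- assign_shapes(genes$gene_id[sel], eligible, n_resp,
                                       truth$planted_shapes)
      }
      shapes[[ax]] <- shape_ax
    }

    # Condition means: look up each design condition's position on both axes.
    cond <- design$conditions
    mult <- matrix(1, n, nrow(cond),
                   dimnames = list(genes$gene_id, cond$label))
    irr_vals <- axes$irradiance$irradiance
    po2_vals <- axes$pO2$pO2
    m_irr <- t(vapply(shapes$irradiance, shape_multipliers,
                      numeric(length(irr_vals)), fold = truth$responsive_fold,
                      tent_fold = truth$tent_fold))
    m_po2 <- t(vapply(shapes$pO2, shape_multipliers,
                      numeric(length(po2_vals)), fold = truth$responsive_fold,
                      tent_fold = truth$tent_fold))
    for (j in seq_len(nrow(cond))) {
      i_irr <- match(cond$irradiance[j], irr_vals)
      i_po2 <- match(cond$pO2[j], po2_vals)
      if (is.na(i_irr) || is.na(i_po2)) {
        stop("condition ", cond$label[j],
             " does not lie on either treatment axis", call. = FALSE)
      }
      mult[, j] <- m_irr[, i_irr] * m_po2[, i_po2]
    }
    cond_mean <- mu_ref * mult

    samples <- design$sample_map$sample_id
    depth <- if (truth$dispersion > 0) {
      stats::rlnorm(length(samples), 0, truth$depth_sdlog)
    } else {
      rep(1, length(samples))
    }
    names(depth) <- samples
    counts <- matrix(0L, n, length(samples),
                     dimnames = list(genes$gene_id, samples))
    for (j in seq_along(samples)) {
      lab <- design$sample_map$label[j]
      mu <- cond_mean[, lab] * depth[j]
      counts[, j] <- if (truth$dispersion > 0) {
        stats::rnbinom(n, mu = mu, size = 1 / truth$dispersion)
      } else {
        as.integer(round(mu))
      }
    }

    fold <- truth$responsive_fold
    truth_df <- data.frame(
      gene_id = genes$gene_id,
      species = genes$species,
      length_bp = genes$length_bp,
      mu_ref = mu_ref,
      shape_irradiance = shapes$irradiance,
      shape_pO2 = shapes$pO2,
      responsive_irradiance = shapes$irradiance %in% c("increasing", "decreasing"),
      direction_irradiance = ifelse(shapes$irradiance == "increasing", "up",
                             ifelse(shapes$irradiance == "decreasing", "down",
                                    "none")),
      responsive_pO2 = shapes$pO2 %in% c("increasing", "decreasing"),
      direction_pO2 = ifelse(shapes$pO2 == "increasing", "up",
                      ifelse(shapes$pO2 == "decreasing", "down", "none")),
      stringsAsFactors = FALSE
    )

    structure(list(counts = counts, truth = truth_df, genes = genes,
                   design = design, culture = culture,
                   depth = depth, cond_mean = cond_mean),
              class = "sim_expression")
  })
}

#' @export
print.sim_expression <- function(x, ...) {
  cat(sprintf(
    "Synthetic %s transcriptome: %d genes x %d samples; planted responsive: %d (irradiance), %d (pO2)\n",
    x$culture, nrow(x$counts), ncol(x$counts),
    sum(x$truth$responsive_irradiance), sum(x$truth$responsive_pO2)))
  invisible(x)
}
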