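#' Default end-to-end pipeline configuration
#'
#' One configuration object drives every stage: simulation (or external
#' inputs), normalization and filtering, responsive-gene calling, clustering,
#' enrichment, turbidostat kinetics, flow cytometry and the ROS assay.
#' Stage-level parameters can be overridden by editing the returned list.
#'
#' @param seed integer master seed; stage seeds are derived from it.
#' @return A nested configuration list.
#' @export
default_config <- function(seed = 1) {
  list(
    seed = as.integer(seed),
    culture = "binary",
    inputs = NULL,   # list(gene_table=, counts=, design=) to skip simulation
    truth = truth_config(),
    design = default_design(),
    normalization = list(variant = "scaled", library = "joint",
                         min_expr = 15, mask_fraction = 0.30),
    responsive = list(threshold = 2, epsilon = 0.5),
    cluster = list(k = 4, n_init = 50),
    enrichment = list(universe = "species-genome", tail = "over",
                      alpha = 0.05),
    kinetics = list(duration_h = 16,
                    axenic = kinetics_params("axenic"),
                    binary = kinetics_params("binary")),
    facs = list(truth = facs_truth(), n_events = 50000, n_runs = 3),
    ros = list(group_means = c(`axenic-LO` = 950, `axenic-HO` = 1000,
                               `binary-LO` = 1550, `binary-HO` = 1600),
               control_mean = 200, sd = 60, n_reps = 3)
  )
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline aborted at stage '%s': %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
}

#' Run the full steady-state analysis pipeline
#'
#' Executes simulate (or load) -> normalize -> filter -> respond -> cluster
#' -> enrich -> kinetics -> facs -> ros -> report. All tables are written as
#' stamped TSV under `out_dir` together with `report.json` (the aggregated
#' results) and `manifest.json` (version, config hash, seeds, input digests,
#' per-stage row counts, timestamp). Reruns with the same config and seed
#' produce byte-identical TSV and report payloads; only the manifest
#' timestamp differs.
#'
#' @param config configuration list from [default_config()].
#' @param out_dir output directory (created if needed).
#' @param seed optional override of `config$seed`.
#' @return The report list, invisibly; written artifacts under `out_dir`.
#' @export
run_pipeline <- function(config = default_config(), out_dir, seed = NULL) {
  if (!is.null(seed)) config$seed <- as.integer(seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(tool = "consortium-coupling", version = pkg_version(),
                   seed = config$seed, stages = list())
  design <- config$design

  # --- simulate or load ----------------------------------------------------
  if (is.null(config$inputs)) {
    sim <- run_stage("simulate", {
      genes <- make_genomes(config$truth, seed = config$seed)
      simulate_expression(genes, design, config$truth, seed = config$seed,
                          culture = config$culture)
    })
    genes <- sim$genes
    counts <- sim$counts
    truth <- sim$truth
    save_gene_table(genes, file.path(out_dir, "gene_table.tsv"))
    save_counts(counts, file.path(out_dir, "counts.tsv"))
    write_tsv(truth, file.path(out_dir, "truth.tsv"))
    save_design(design, file.path(out_dir, "design.tsv"))
  } else {
    genes <- run_stage("normalize", load_gene_table(config$inputs$gene_table))
    if (!is.null(config$inputs$design)) {
      design <- run_stage("normalize", load_design(config$inputs$design))
    }
    counts <- run_stage("normalize", {
      if (is.null(config$inputs$counts) || !file.exists(config$inputs$counts)) {
        stop("counts file not found: ",
             config$inputs$counts %||% "<missing>", call. = FALSE)
      }
      load_counts(config$inputs$counts, genes, design)
    })
    truth <- NULL
  }
  manifest$stages$simulate <- list(n_genes = nrow(counts),
                                   n_samples = ncol(counts))

  # --- normalize + filter --------------------------------------------------
  nf <- config$normalization
  expr <- run_stage("normalize", {
    factors <- size_factors(counts)
    per_kb_expression(counts, factors, genes, variant = nf$variant,
                      library = nf$library)
  })
  report_filter <- run_stage("filter",
                             filter_genes(counts, expr, design,
                                          min_expr = nf$min_expr))
  expr_kept <- expr[report_filter$kept, , drop = FALSE]
  cm <- condition_means(expr_kept, design)
  write_tsv(data.frame(gene_id = rownames(expr_kept),
                       round(expr_kept, 4), check.names = FALSE),
            file.path(out_dir, "expression.tsv"))
  manifest$stages$filter <- list(
    n_input = report_filter$n_input,
    n_removed_zero_condition = report_filter$n_removed_zero_condition,
    n_removed_low_expression = report_filter$n_removed_low_expression,
    n_kept = length(report_filter$kept))

  # --- responsive calls ----------------------------------------------------
  axes <- validate_design(design)
  calls <- run_stage("respond", {
    rbind(
      call_responsive(cm, axes$irradiance, axis = "irradiance",
                      threshold = config$responsive$threshold,
                      epsilon = config$responsive$epsilon),
      call_responsive(cm, axes$pO2, axis = "pO2",
                      threshold = config$responsive$threshold,
                      epsilon = config$responsive$epsilon)
    )
  })
  counts_tab <- count_responsive(calls, genes)
  write_tsv(calls, file.path(out_dir, "responsive_calls.tsv"))
  manifest$stages$respond <- list(n_calls = sum(calls$responsive))

  # --- clustering per axis -------------------------------------------------
  clusters <- run_stage("cluster", {
    out <- list()
    for (ax in c("irradiance", "pO2")) {
      labs <- axes[[ax]]$label
      prof <- normalize_profile(cm[, labs, drop = FALSE])
      kept <- variance_mask(prof, fraction = nf$mask_fraction)
      res <- kmeans_correlation(prof[kept, , drop = FALSE],
                                k = config$cluster$k,
                                seed = config$seed,
                                n_init = config$cluster$n_init,
                                axis = ax)
      write_tsv(data.frame(gene_id = names(res$assignments),
                           cluster = unname(res$assignments),
                           pattern = if (!is.null(res$pattern_labels)) {
                             res$pattern_labels[res$assignments]
                           } else NA_character_),
                file.path(out_dir, paste0("clusters_", ax, ".tsv")))
      write_tsv(data.frame(cluster = rownames(res$centroids),
                           pattern = res$pattern_labels %||% NA_character_,
                           round(res$centroids, 6), check.names = FALSE),
                file.path(out_dir, paste0("centroids_", ax, ".tsv")))
      out[[ax]] <- res
    }
    out
  })
  cluster_species <- lapply(clusters, cross_species_summary, genes = genes)
  manifest$stages$cluster <- lapply(clusters, function(x) {
    list(k = x$k, n_profiles = length(x$assignments),
         objective = x$objective)
  })

  # --- enrichment of responsive sets ---------------------------------------
  enrichments <- run_stage("enrich", {
    out <- list()
    for (ax in c("irradiance", "pO2")) {
      for (sp in unique(genes$species)) {
        ids <- calls$gene_id[calls$axis == ax & calls$responsive &
                               genes$species[match(calls$gene_id,
                                                   genes$gene_id)] == sp]
        if (length(ids) < 1) next
        key <- paste(sp, ax, sep = ".")
        out[[key]] <- enrich_all(
          ids, genes, universe = config$enrichment$universe,
          filtered_ids = report_filter$kept,
          tail = config$enrichment$tail,
          alpha = config$enrichment$alpha)
        write_tsv(out[[key]],
                  file.path(out_dir, paste0("enrichment_", key, ".tsv")))
      }
    }
    out
  })

  # --- kinetics across cultures and steady states --------------------------
  kinetics <- run_stage("kinetics", {
    out <- list()
    for (culture in c("axenic", "binary")) {
      params <- config$kinetics[[culture]]
      rows <- list()
      for (i in seq_len(nrow(design$conditions))) {
        cnd <- design$conditions[i, ]
        duration <- max(config$kinetics$duration_h,
                        3.2 / mu_at(params, cnd$irradiance, cnd$pO2))
        tlog <- simulate_turbidostat(params, cnd, duration_h = duration,
                                     seed = config$seed + i)
        win <- detect_steady_state(tlog)
        gr <- growth_rate(tlog, win)
        q <- net_o2_rate(tlog, params$gas, win)
        rows[[cnd$label]] <- data.frame(
          culture = culture, label = cnd$label,
          irradiance = cnd$irradiance, pO2 = cnd$pO2,
          mu = gr$mu, doubling_h = gr$doubling_h,
          mu_cmol = cmol_rate(gr$mu, params$gas), q_o2 = q$q_o2,
          stringsAsFactors = FALSE)
      }
      tab <- do.call(rbind, rows)
      irr_tab <- tab[tab$label %in% axes$irradiance$label, ]
      po2_tab <- tab[tab$label %in% axes$pO2$label, ]
      sens <- o2_sensitivity(po2_tab$pO2, po2_tab$mu)
      pq <- photosynthetic_quotient(irr_tab$q_o2, irr_tab$mu_cmol)
      out[[culture]] <- list(steady_states = tab, sensitivity = sens,
                             pq = pq)
      write_tsv(tab, file.path(out_dir, paste0("kinetics_", culture, ".tsv")))
    }
    out
  })

  # --- flow cytometry ------------------------------------------------------
  facs <- run_stage("facs", {
    gates <- default_facs_gates(config$facs$truth)
    runs <- lapply(seq_len(config$facs$n_runs), function(i) {
      ev <- simulate_facs(config$facs$truth, config$facs$n_events,
                          seed = config$seed + i - 1)
      facs_composition(ev, gates)$percent
    })
    mat <- do.call(rbind, runs)
    list(per_run = mat, mean_percent = colMeans(mat))
  })

  # --- ROS -----------------------------------------------------------------
  ros <- run_stage("ros", {
    plate <- simulate_ros_plate(config$ros$group_means,
                                config$ros$control_mean,
                                sd = config$ros$sd,
                                n_reps = config$ros$n_reps,
                                seed = config$seed)
    ros_corrected(plate)
  })

  # --- report + manifest ---------------------------------------------------
  report <- list(
    responsive_counts = counts_tab,
    filter = manifest$stages$filter,
    cluster_species = cluster_species,
    cluster_patterns = lapply(clusters, function(x) x$pattern_labels),
    top_enrichments = lapply(enrichments, function(e) {
      utils::head(e[, c("category", "ratio", "p", "significant")], 5)
    }),
    kinetics = lapply(kinetics, function(k) list(
      sensitivity = k$sensitivity$sensitivity,
      sensitivity_se = k$sensitivity$se,
      pq = k$pq$slope, pq_se = k$pq$se,
      max_mu = max(k$steady_states$mu),
      min_doubling_h = min(k$steady_states$doubling_h))),
    facs_mean_percent = facs$mean_percent,
    ros = ros$groups,
    ros_significant_pairs = if (!is.null(ros$comparisons)) {
      ros$comparisons$pair[ros$comparisons$significant]
    } else character(0)
  )
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE)

  tsvs <- list.files(out_dir, pattern = "\\.tsv$", full.names = TRUE)
  digests <- tools::md5sum(sort(tsvs))
  names(digests) <- basename(names(digests))
  manifest$input_digests <- as.list(digests)
  cfg_file <- tempfile(fileext = ".json")
  jsonlite::write_json(config_fingerprint(config), cfg_file,
                       auto_unbox = TRUE, digits = 10)
  manifest$config_hash <- unname(tools::md5sum(cfg_file))
  unlink(cfg_file)
  manifest$timestamp <- format(Sys.time(), tz = "UTC")
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE)
  invisible(report)
}

# Serializable summary of a config for hashing (strips classes, drops
# anything that is not data).
config_fingerprint <- function(x) {
  if (is.list(x)) {
    x <- lapply(unclass(x), config_fingerprint)
    x[!vapply(x, is.null, logical(1))]
  } else if (is.numeric(x) || is.character(x) || is.logical(x)) {
    x
  } else {
    NULL
  }
}
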