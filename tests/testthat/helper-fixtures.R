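# Small in-code fixtures shared across tests.

toy_gene_table <- function() {
  gene_table(
    gene_id = c("cy1", "cy2", "cy3", "he1", "he2", "he3"),
    species = rep(c("cyanobacterium", "heterotroph"), each = 3),
    length_bp = c(300L, 600L, 900L, 500L, 1000L, 2000L),
    categories = c("photosystem_II;carbon_fixation", "carbon_fixation", "",
                   "transport", "transport;respiration", "")
  )
}

toy_design <- function() {
  steady_state_design(data.frame(
    label = c("A", "B", "C", "D", "E"),
    irradiance = c(100, 500, 1000, 1000, 1000),
    pO2 = c(0, 0, 0, 0.3, 0.6),
    n_replicates = 2L
  ))
}

# counts matrix matching toy_gene_table()/toy_design()
toy_counts <- function() {
  des <- toy_design()
  samples <- des$sample_map$sample_id
  set.seed(42)
  m <- matrix(rpois(6 * length(samples), 50), 6, length(samples),
              dimnames = list(toy_gene_table()$gene_id, samples))
  storage.mode(m) <- "integer"
  m
}

# deterministic profile matrix built from shape templates plus noise
template_profiles <- function(n_per_shape = 10, m = 3, noise_sd = 0,
                              seed = 1) {
  shapes <- list(
    tent = c(1, 3, 1), inverse_tent = c(3, 1, 3),
    decreasing = c(4, 2, 1), increasing = c(1, 2, 4)
  )
  set.seed(seed)
  rows <- list()
  for (s in names(shapes)) {
    base <- approx(seq_along(shapes[[s]]), shapes[[s]],
                   n = m)$y
    for (i in seq_len(n_per_shape)) {
      rows[[paste0(s, "_", i)]] <- base * runif(1, 0.5, 5) +
        rnorm(m, 0, noise_sd)
    }
  }
  out <- do.call(rbind, rows)
  colnames(out) <- paste0("c", seq_len(m))
  out
}
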