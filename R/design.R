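#' Steady-state experiment designs
#'
#' A design lists the turbidostat steady-state conditions (label, irradiance,
#' oxygen partial pressure, replicate count) and maps every sequenced sample
#' to one condition. A valid design carries two treatment axes: an irradiance
#' series at one fixed pO2 and a pO2 series at one fixed irradiance; the
#' corner condition (highest irradiance, lowest pO2) belongs to both.
#'
#' @param conditions data frame with columns `label`, `irradiance`
#'   (µmol photons m^-2 s^-1), `pO2` (atm) and `n_replicates`.
#' @param sample_map data frame with columns `sample_id`, `label`. If omitted,
#'   sample ids `<label>_r<i>` are generated from `n_replicates`.
#' @return An `ss_design` object (list with `conditions` and `sample_map`).
#' @seealso [validate_design()], [default_design()]
#' @export
steady_state_design <- function(conditions, sample_map = NULL) {
  required <- c("label", "irradiance", "pO2", "n_replicates")
  missing <- setdiff(required, names(conditions))
  if (length(missing)) {
    stop("conditions is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  conditions$label <- as.character(conditions$label)
  if (anyDuplicated(conditions$label)) {
    stop("condition labels must be unique", call. = FALSE)
  }
  if (anyDuplicated(conditions[, c("irradiance", "pO2")])) {
    stop("(irradiance, pO2) pairs must be unique across conditions",
         call. = FALSE)
  }
  if (any(conditions$irradiance < 0) || any(conditions$pO2 < 0)) {
    stop("irradiance and pO2 must be >= 0", call. = FALSE)
  }
  if (any(conditions$n_replicates < 2)) {
    stop("every condition needs n_replicates >= 2", call. = FALSE)
  }
  if (is.null(sample_map)) {
    sample_map <- do.call(rbind, lapply(seq_len(nrow(conditions)), function(i) {
      data.frame(
        sample_id = sprintf("%s_r%d", conditions$label[i],
                            seq_len(conditions$n_replicates[i])),
        label = conditions$label[i],
        stringsAsFactors = FALSE
      )
    }))
  }
  sample_map$sample_id <- as.character(sample_map$sample_id)
  sample_map$label <- as.character(sample_map$label)
  if (anyDuplicated(sample_map$sample_id)) {
    stop("sample ids must be unique", call. = FALSE)
  }
  orphan <- setdiff(sample_map$label, conditions$label)
  if (length(orphan)) {
    stop("sample(s) map to undeclared condition(s): ",
         paste(orphan, collapse = ", "), call. = FALSE)
  }
  reps <- table(factor(sample_map$label, levels = conditions$label))
  bad <- conditions$label[as.integer(reps) != conditions$n_replicates]
  if (length(bad)) {
    stop("replicate counts in sample_map do not match n_replicates for: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  structure(list(conditions = conditions, sample_map = sample_map),
            class = "ss_design")
}

#' Default five-condition turbidostat design
#'
#' Three irradiance levels (197, 1190, 1995 µmol photons m^-2 s^-1) at
#' pO2 = 0 atm and three oxygen levels (0, 0.30, 0.59 atm) at the highest
#' irradiance, sharing the corner condition HL-LO. Transcriptomic replication
#' is in duplicate except HL-LO, which is in quadruplicate.
#'
#' @return An [steady_state_design()] object.
#' @export
default_design <- function() {
  steady_state_design(data.frame(
    label = c("LL-LO", "ML-LO", "HL-LO", "HL-MO", "HL-HO"),
    irradiance = c(197, 1190, 1995, 1995, 1995),
    pO2 = c(0, 0, 0, 0.30, 0.59),
    n_replicates = c(2L, 2L, 4L, 2L, 2L),
    stringsAsFactors = FALSE
  ))
}

#' Extract the two treatment axes from a design
#'
#' The irradiance axis is the set of >= 3 conditions sharing one pO2 (the
#' lowest such pO2 if several qualify); the pO2 axis is the set of >= 3
#' conditions sharing one irradiance (the highest such irradiance). Each axis
#' is returned sorted ascending by treatment value, so axis output does not
#' depend on the input ordering of conditions.
#'
#' @param design an [steady_state_design()] object.
#' @return List with elements `irradiance` and `pO2`, each a data frame of
#'   axis conditions sorted by increasing treatment value.
#' @export
validate_design <- function(design) {
  stopifnot(inherits(design, "ss_design"))
  cond <- design$conditions

  po2_tab <- table(cond$pO2)
  po2_ok <- as.numeric(names(po2_tab))[po2_tab >= 3]
  if (!length(po2_ok)) {
    stop("no irradiance axis: need >= 3 conditions at one fixed pO2",
         call. = FALSE)
  }
  irr_axis <- cond[cond$pO2 == min(po2_ok), , drop = FALSE]
  if (length(unique(irr_axis$irradiance)) < 3) {
    stop("no irradiance axis: conditions at fixed pO2 do not span 3 distinct ",
         "irradiances", call. = FALSE)
  }
  irr_axis <- irr_axis[order(irr_axis$irradiance), , drop = FALSE]

  irr_tab <- table(cond$irradiance)
  irr_ok <- as.numeric(names(irr_tab))[irr_tab >= 3]
  if (!length(irr_ok)) {
    stop("no pO2 axis: need >= 3 conditions at one fixed irradiance",
         call. = FALSE)
  }
  po2_axis <- cond[cond$irradiance == max(irr_ok), , drop = FALSE]
  if (length(unique(po2_axis$pO2)) < 3) {
    stop("no pO2 axis: conditions at fixed irradiance do not span 3 distinct ",
         "pO2 values", call. = FALSE)
  }
  po2_axis <- po2_axis[order(po2_axis$pO2), , drop = FALSE]

  rownames(irr_axis) <- rownames(po2_axis) <- NULL
  list(irradiance = irr_axis, pO2 = po2_axis)
}

# Samples belonging to one condition label, in sample_map order.
condition_samples <- function(design, label) {
  design$sample_map$sample_id[design$sample_map$label == label]
}

#' Write a design to TSV
#'
#' One row per sample with columns `sample_id`, `label`, `irradiance`, `pO2`.
#'
#' @param design an [steady_state_design()] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
save_design <- function(design, path) {
  m <- merge(design$sample_map, design$conditions[, c("label", "irradiance", "pO2")],
             by = "label", sort = FALSE)
  m <- m[match(design$sample_map$sample_id, m$sample_id),
         c("sample_id", "label", "irradiance", "pO2")]
  write_tsv(m, path)
}

#' Read a design from TSV
#'
#' @param path TSV with columns `sample_id`, `label`, `irradiance`, `pO2`.
#' @return An [steady_state_design()] object; `n_replicates` is derived from
#'   the number of samples per condition.
#' @export
load_design <- function(path) {
  tab <- read_tsv(path)
  required <- c("sample_id", "label", "irradiance", "pO2")
  missing <- setdiff(required, names(tab))
  if (length(missing)) {
    stop("design file is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  cond <- unique(tab[, c("label", "irradiance", "pO2")])
  reps <- table(tab$label)
  cond$n_replicates <- as.integer(reps[cond$label])
  steady_state_design(cond, tab[, c("sample_id", "label")])
}

#' @export
print.ss_design <- function(x, ...) {
  cat(sprintf("Steady-state design: %d conditions, %d samples\n",
              nrow(x$conditions), nrow(x$sample_map)))
  print(x$conditions, row.names = FALSE)
  invisible(x)
}
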