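# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
pkg_version <- function() {
  as.character(utils::packageVersion("consortiumcoupling"))
}

# Header comment stamped onto every table the package writes.
format_header <- function() {
  sprintf("#consortium-coupling v%s", pkg_version())
}

#' Write a data frame as a tab-separated table
#'
#' Tables are written with a `#consortium-coupling v<version>` comment line,
#' a header row, tab delimiters, UTF-8 encoding and '.' as decimal mark.
#' This is the canonical interchange format of the package.
#'
#' @param x data frame to write.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(x, path) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(format_header(), con)
  utils::write.table(x, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a tab-separated table written by this package
#'
#' Comment lines starting with `#` (including the version stamp) are skipped.
#'
#' @param path file path.
#' @return data frame.
#' @export
read_tsv <- function(path) {
  if (!file.exists(path)) {
    stop("file not found: ", path, call. = FALSE)
  }
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                    check.names = FALSE)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG afterwards so generators never perturb user randomness.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
      stop("`seed` must be a single finite number", call. = FALSE)
    }
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Single scalar check used by constructors.
check_scalar <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop("`", name, "` must be a single finite number", call. = FALSE)
  }
  if (strict_lower && x <= lower) {
    stop("`", name, "` must be > ", lower, call. = FALSE)
  }
  if (!strict_lower && x < lower) {
    stop("`", name, "` must be >= ", lower, call. = FALSE)
  }
  if (x > upper) {
    stop("`", name, "` must be <= ", upper, call. = FALSE)
  }
  invisible(x)
}
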