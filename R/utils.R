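# internal helpers shared across modules

#' Normalize character labels
#'
#' Trims leading/trailing whitespace and collapses internal whitespace runs
#' to a single space. Case is preserved; matching elsewhere is exact after
#' this normalization.
#'
#' @param x character vector of labels.
#' @return normalized character vector.
#' @keywords internal
normalize_labels <- function(x) {
  x <- gsub("[[:space:]]+", " ", as.character(x))
  trimws(x)
}

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards. All stochastic code in the package goes
# through this so that user-level RNG state is never clobbered.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
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

# Stable derived seed for a sub-stream, kept within 32-bit integer range.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(offset)) %% 2147483587L) + 1L
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# Canonical number formatting for deterministic text outputs.
fmt_num <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) return("NA")
    if (v == as.integer(v)) sprintf("%d", as.integer(v))
    else format(v, scientific = FALSE, trim = TRUE, digits = 15)
  }, character(1))
  out
}
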