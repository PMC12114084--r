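# Internal helpers shared across modules.

#' Evaluate code under a local, explicit random seed
#'
#' Saves the caller's RNG state, seeds the generator with `seed`, evaluates
#' `code`, and restores the previous state on exit, so no function in the
#' package leaks or depends on hidden global RNG state.
#'
#' @param seed Integer seed; mandatory.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  if (is.null(seed) || length(seed) != 1L || is.na(seed)) {
    stop("an explicit integer `seed` is required", call. = FALSE)
  }
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Format a numeric for TSV output: 6 significant digits, scientific
# notation for small magnitudes (matches common GWAS export conventions).
format_num <- function(x, digits = 6L) {
  vapply(x, function(v) {
    if (is.na(v)) return("NA")
    if (v != 0 && abs(v) < 1e-3) {
      formatC(v, digits = digits, format = "e")
    } else {
      formatC(v, digits = digits, format = "g")
    }
  }, character(1))
}

# Order chromosomes numerically where possible ("1" < "2" < "10" < "X").
chrom_rank <- function(chrom) {
  num <- suppressWarnings(as.numeric(chrom))
  rank <- ifelse(is.na(num), 1e6 + as.integer(factor(chrom)), num)
  rank
}

`%||%` <- function(a, b) if (is.null(a)) b else a
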