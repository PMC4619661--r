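#' Evaluate an expression with a temporary RNG seed
#'
#' Runs `code` with the global RNG seeded to `seed`, then restores the
#' caller's RNG state, so seeded generators do not perturb the session RNG.
#'
#' @param seed Integer seed, or `NULL` to use the current RNG stream.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
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
  set.seed(seed)
  code
}

## shared argument checks ---------------------------------------------------

check_scalar <- function(x, name, lower = -Inf, upper = Inf,
                         integer = FALSE, strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("'%s' must be a finite numeric scalar", name), call. = FALSE)
  }
  if (strict_lower) {
    if (x <= lower) stop(sprintf("'%s' must be > %s", name, lower), call. = FALSE)
  } else if (x < lower) {
    stop(sprintf("'%s' must be >= %s", name, lower), call. = FALSE)
  }
  if (x > upper) stop(sprintf("'%s' must be <= %s", name, upper), call. = FALSE)
  if (integer && x != round(x)) {
    stop(sprintf("'%s' must be a whole number", name), call. = FALSE)
  }
  invisible(x)
}

check_flag <- function(x, name) {
  if (!is.logical(x) || length(x) != 1L || is.na(x)) {
    stop(sprintf("'%s' must be TRUE or FALSE", name), call. = FALSE)
  }
  invisible(x)
}

## sequence helpers ---------------------------------------------------------

as_sequence_string <- function(x, name = "sequence") {
  if (is(x, "DNAString") || is(x, "DNAStringSet")) x <- as.character(x)
  if (!is.character(x) || length(x) != 1L || nchar(x) == 0L) {
    stop(sprintf("'%s' must be a single non-empty nucleotide string", name),
         call. = FALSE)
  }
  toupper(x)
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}
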