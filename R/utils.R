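# Internal helpers shared across modules.

#' Evaluate an expression under a local RNG seed
#'
#' Runs `code` with the R RNG seeded to `seed`, restoring the caller's RNG
#' state afterwards so library functions never clobber user randomness.
#'
#' @param seed integer seed, or NULL to leave the RNG untouched.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
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
  force(code)
}

# Derive a reproducible sub-seed from a master seed and an integer salt.
# Kept strictly below 2^31 so the result is a valid R integer seed.
derive_seed <- function(seed, salt) {
  if (is.null(seed)) return(NULL)
  as.integer((as.double(seed) * 48271 + as.double(salt) * 16807) %% 2147483647)
}

# id validation shared by all artifact readers
check_unique_ids <- function(ids, what = "compound") {
  if (any(!nzchar(ids)) || anyNA(ids)) {
    stop(sprintf("empty or missing %s id", what), call. = FALSE)
  }
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0) {
    stop(sprintf("duplicate %s id(s): %s", what,
                 paste(dup, collapse = ", ")), call. = FALSE)
  }
  invisible(ids)
}

# Align a square similarity matrix to a given id order; errors on missing ids.
align_square <- function(M, ids, what = "matrix") {
  missing <- setdiff(ids, rownames(M))
  if (length(missing) > 0) {
    stop(sprintf("%s lacks compound(s): %s", what,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  M[ids, ids, drop = FALSE]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
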