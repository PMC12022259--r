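# Internal helpers shared across modules.

#' Evaluate code with a temporary RNG state
#'
#' Sets the seed, runs `code`, and restores the caller's `.Random.seed`
#' afterwards so that simulation functions are deterministic without
#' clobbering the session RNG stream.
#' @noRd
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# scalar numeric check
is_num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# row-wise Euclidean norm of an n x 3 matrix
row_norm <- function(m) sqrt(rowSums(m^2))
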