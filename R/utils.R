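#' Evaluate code with a temporary RNG seed
#'
#' Runs `code` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so generators are reproducible without clobbering the global
#' stream.
#' @param seed Integer seed, or `NULL` to run `code` unchanged.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @export
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
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
    set.seed(seed)
  }
  force(code)
}

#' Largest pairwise Euclidean distance between rows, in cm
#' @param pos_mm n x 3 matrix of positions in mm.
#' @noRd
max_pairwise_cm <- function(pos_mm) {
  if (is.null(pos_mm) || nrow(pos_mm) <= 1L) {
    return(0)
  }
  max(stats::dist(pos_mm)) / 10
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
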