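#' Derive a reproducible sub-seed from a master seed
#'
#' All randomness in the package flows from a single master seed; independent
#' components (correlation structure, exposures, noise, predictor draws, fold
#' assignments) use sub-seeds derived deterministically from it, so any
#' component can be regenerated on its own.
#'
#' @param seed Integer master seed.
#' @param ... Character or numeric tags identifying the purpose (and, e.g.,
#'   the replicate number).
#' @return A single integer in `[1, 2^31 - 1)`.
#' @export
derive_seed <- function(seed, ...) {
  tags <- paste(vapply(list(...), as.character, character(1)), collapse = "/")
  h <- 0
  if (nzchar(tags)) {
    for (ch in utf8ToInt(tags)) h <- (h * 131 + ch) %% 2147482951
  }
  as.integer((as.numeric(seed) %% 2147482951 * 48271 + h) %% 2147482951 + 1)
}

# Run code with a temporary RNG state; restores the caller's stream.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv(), inherits = FALSE)
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# abort helpers keeping error classes greppable
stop_exposelect <- function(msg, class) {
  rlang::abort(msg, class = c(class, "exposelect_error"))
}

`%||%` <- function(x, y) if (is.null(x)) y else x
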