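# Internal helpers: classed errors and reproducible local RNG streams.

rpl_stop <- function(class, msg, ...) {
  stop(errorCondition(sprintf(msg, ...), class = c(class, "rplnet_error")))
}

rpl_warn <- function(class, msg, ...) {
  warning(warningCondition(sprintf(msg, ...), class = c(class, "rplnet_warning")))
}

#' Evaluate code under a temporary RNG seed
#'
#' Sets the RNG seed for the duration of `code` and restores the previous
#' global RNG state afterwards, so seeded package functions do not perturb
#' the caller's random stream. A `NULL` seed leaves the RNG untouched.
#'
#' @param seed Integer seed or `NULL`.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
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
  force(code)
}

# Derive a per-stream seed from (master seed, stream index) so collections are
# order-independent. Kept strictly below 2^31 - 1.
derive_seed <- function(seed, index) {
  as.integer((abs(as.numeric(seed)) * 48271 + as.numeric(index) * 16807) %% 2147483629)
}

check_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    rpl_stop("rplnet_param_error", "`%s` must be a single finite number", name)
  }
  invisible(x)
}
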