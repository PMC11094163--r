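# internal argument checks and seeded evaluation

stop_invalid <- function(...) {
  stop(..., call. = FALSE)
}

check_number <- function(x, name, finite = TRUE, min = -Inf, strict = FALSE,
                         len = 1L) {
  if (!is.numeric(x) || (!is.null(len) && length(x) != len)) {
    stop_invalid("`", name, "` must be a numeric vector of length ",
                 len %||% "n")
  }
  if (finite && any(!is.finite(x))) {
    stop_invalid("`", name, "` must be finite")
  }
  if (strict) {
    if (any(x <= min)) stop_invalid("`", name, "` must be > ", min)
  } else if (any(x < min)) {
    stop_invalid("`", name, "` must be >= ", min)
  }
  invisible(x)
}

check_count <- function(x, name, min = 1L) {
  check_number(x, name, min = min)
  if (x != as.integer(x)) stop_invalid("`", name, "` must be an integer")
  invisible(as.integer(x))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
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
  expr
}
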