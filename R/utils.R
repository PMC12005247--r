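# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_domain <- function(...) stop(..., call. = FALSE)

check_prob <- function(x, name, open_left = FALSE, open_right = FALSE) {
  if (!is.numeric(x) || anyNA(x)) {
    stop_domain(name, " must be numeric and non-missing")
  }
  lo_ok <- if (open_left) all(x > 0) else all(x >= 0)
  hi_ok <- if (open_right) all(x < 1) else all(x <= 1)
  if (!lo_ok || !hi_ok) {
    stop_domain(name, " must lie in ", if (open_left) "(" else "[", "0, 1",
                if (open_right) ")" else "]")
  }
  invisible(x)
}

check_positive <- function(x, name, strict = TRUE) {
  if (!is.numeric(x) || anyNA(x) || (if (strict) any(x <= 0) else any(x < 0))) {
    stop_domain(name, " must be ", if (strict) "> 0" else ">= 0")
  }
  invisible(x)
}

# Seed handling: run `expr` under a fixed seed without disturbing the caller's
# RNG stream. `seed = NULL` uses the current stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
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
  set.seed(seed)
  expr
}

# Derive a reproducible child seed from a base seed and an index, kept within
# the 32-bit integer range R requires.
child_seed <- function(seed, index) {
  as.integer((as.double(seed) * 1000003 + index * 7919) %% 2147483647L)
}
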