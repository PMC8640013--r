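# Internal helpers shared across modules.

# Run `expr` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched. A NULL seed uses (and advances) the global stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) {
    return(expr)
  }
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

stop_contract <- function(...) {
  stop(..., call. = FALSE)
}

check_numeric <- function(x, name, finite = TRUE) {
  if (!is.numeric(x) || length(x) == 0) {
    stop_contract("`", name, "` must be a non-empty numeric vector")
  }
  if (finite && any(!is.finite(x))) {
    stop_contract("`", name, "` contains non-finite values")
  }
  invisible(x)
}

# named-vector coercion for parameter maps (lists or vectors accepted)
as_param_vector <- function(params) {
  p <- unlist(params)
  if (is.null(names(p)) || any(names(p) == "")) {
    stop_contract("parameters must be named")
  }
  p
}
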