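# internal helpers shared across modules

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# numeric matrix coercion with column names preserved; vectors become 1-column
as_num_matrix <- function(x, arg = "x") {
  if (is.null(x)) return(NULL)
  if (is.data.frame(x)) x <- as.matrix(x)
  if (!is.matrix(x)) x <- matrix(x, ncol = 1L, dimnames = list(NULL, arg))
  if (!is.numeric(x)) stop(sprintf("'%s' must be numeric", arg), call. = FALSE)
  if (is.null(colnames(x))) colnames(x) <- paste0(arg, seq_len(ncol(x)))
  x
}

stop_if_not_scalar_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0 || x >= 1)
    stop(sprintf("'%s' must be a single number in (0, 1)", name), call. = FALSE)
  invisible(x)
}
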