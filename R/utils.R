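`%||%` <- function(a, b) if (is.null(a)) b else a

## Evaluate `expr` under a temporary RNG state seeded with `seed`,
## restoring the caller's stream afterwards. `seed = NULL` uses the
## current stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

## Draw independent sub-seeds (< 2^31) from a master seed.
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max, n))
}

stopifnot_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lower || x > upper)
    stop(sprintf("`%s` must be a single finite number in [%s, %s]", name, lower, upper),
         call. = FALSE)
  invisible(x)
}

## coords helpers: k x 2 matrix <-> length-2k vector, landmark-major (x1,y1,x2,y2,...)
flatten_coords <- function(m) as.vector(t(m))

unflatten_coords <- function(v) matrix(v, ncol = 2L, byrow = TRUE)

coord_names <- function(k) {
  as.vector(rbind(paste0("x", seq_len(k)), paste0("y", seq_len(k))))
}
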