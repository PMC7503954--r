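# Internal helpers shared across modules.

# Run code with a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(code)
}

# Polynomial rolling hash of an R object's deparsed form; stable across
# sessions for the plain lists/matrices used in configs and geometry
# descriptors. Exact doubles below 2^53 keep the modular arithmetic exact.
object_hash <- function(x) {
  txt <- paste(deparse(x, control = c("keepNA", "niceNames")), collapse = "\n")
  bytes <- utf8ToInt(txt)
  h <- 5381
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", h)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# Pairwise Euclidean distances between the rows of two point matrices.
point_distances <- function(a, b) {
  sqrt(outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b))
}
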