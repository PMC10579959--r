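# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's RNG
# stream. All stochastic operations in the package route through this, so a
# user-supplied seed fully determines the output and no global state leaks.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(expr)
}

# Derive a reproducible sub-seed from a master seed and a stream label.
# Keeps results < 2^31 and decorrelates the per-structure streams.
derive_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- sum(utf8ToInt(as.character(stream)) * seq_along(utf8ToInt(as.character(stream))))
  as.integer((as.numeric(seed) * 48271 + h * 7919) %% 2147483629)
}

vec_norm <- function(v) sqrt(sum(v^2))

unit <- function(v) {
  n <- vec_norm(v)
  if (n < .Machine$double.eps) stop("cannot normalize a zero vector")
  v / n
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# grid cell size for the exact nearest-neighbour search: a cell roughly the
# scale of the typical reference spacing keeps bins small, floored at a
# fraction of the joint extent so distant/degenerate clouds still terminate
# in few ring expansions
nn_cell_size <- function(query, ref) {
  n <- nrow(ref)
  lo <- pmin(apply(ref, 2, min), apply(query, 2, min))
  hi <- pmax(apply(ref, 2, max), apply(query, 2, max))
  ext <- pmax(hi - lo, 1e-9)
  max((prod(ext) / max(n, 1))^(1 / 3), max(ext) / 64, 1e-9)
}

# exact nearest neighbour of each row of `query` among rows of `ref`
nearest_neighbor <- function(query, ref) {
  stopifnot(ncol(query) == 3L, ncol(ref) == 3L, nrow(ref) >= 1L)
  .nn_nearest(query, ref, nn_cell_size(query, ref))
}
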