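`%||%` <- function(x, y) if (is.null(x)) y else x

#' Evaluate an expression with a temporary RNG seed
#'
#' Runs `expr` with the random number generator seeded to `seed` and restores
#' the previous RNG state afterwards, so simulation helpers never clobber a
#' user's random stream.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  expr
}

# Minimal union-find used to cluster many-to-many reciprocal-overlap matches
# into connected components (transitive clustering).
uf_new <- function(n) seq_len(n)

uf_find <- function(parent, i) {
  while (parent[i] != i) i <- parent[i]
  i
}

uf_union <- function(parent, i, j) {
  ri <- uf_find(parent, i)
  rj <- uf_find(parent, j)
  if (ri != rj) parent[rj] <- ri
  parent
}

uf_components <- function(n, edges_i, edges_j) {
  parent <- uf_new(n)
  for (k in seq_along(edges_i)) {
    parent <- uf_union(parent, edges_i[k], edges_j[k])
  }
  vapply(seq_len(n), function(i) uf_find(parent, i), integer(1))
}

# Sort chromosome labels numerically where possible ("1" < "2" < "10" < "X").
chrom_order <- function(chrom) {
  num <- suppressWarnings(as.numeric(chrom))
  order(is.na(num), num, chrom)
}

is_count <- function(x) length(x) == 1 && is.numeric(x) && !is.na(x) && x == floor(x)

stop_stage <- function(stage, ...) {
  stop(sprintf("[%s] %s", stage, paste0(...)), call. = FALSE)
}
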