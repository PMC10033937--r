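# Internal helpers shared across modules. Node labels are opaque strings;
# the canonical form of an unordered pair sorts its endpoints, so (a,b) and
# (b,a) always hash to the same key.

pair_key <- function(a, b) paste(a, b, sep = "\t")

#' @keywords internal
canonicalize_pairs <- function(pairs) {
  if (is.data.frame(pairs)) pairs <- as.matrix(pairs[, 1:2])
  pairs <- as.matrix(pairs)
  if (ncol(pairs) < 2L) stop("pairs must have at least two columns")
  a <- as.character(pairs[, 1L])
  b <- as.character(pairs[, 2L])
  swap <- a > b
  if (any(swap)) {
    tmp <- a[swap]
    a[swap] <- b[swap]
    b[swap] <- tmp
  }
  cbind(node_a = a, node_b = b)
}

# Evaluate `code` under a private RNG stream; the caller's RNG state is
# untouched (reproducibility without global side effects).
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = genv)
    } else if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
      rm(".Random.seed", envir = genv)
    }
  })
  set.seed(seed)
  code
}

# Percentile rank in [0,1]: best (highest score) maps to 1, worst to 0,
# ties share the midpoint of their positions.
percentile_ranks <- function(score) {
  n <- length(score)
  if (n == 1L) return(1)
  r <- rank(-score, ties.method = "average")
  1 - (r - 1) / (n - 1)
}

node_index <- function(g, labels) {
  idx <- match(labels, g$nodes)
  if (anyNA(idx)) {
    stop("node(s) not present in graph '", g$name, "': ",
         paste(unique(labels[is.na(idx)]), collapse = ", "))
  }
  idx
}

# Resolve a `pairs` argument (matrix/data.frame of labels) into canonical
# labels plus integer endpoint indices; optionally reject self-pairs.
resolve_pairs <- function(g, pairs, allow_self = TRUE) {
  p <- canonicalize_pairs(pairs)
  if (nrow(p) == 0L) stop("empty pair list")
  ia <- node_index(g, p[, 1L])
  ib <- node_index(g, p[, 2L])
  if (!allow_self && any(ia == ib)) {
    stop("self-pairs are not scored by this method")
  }
  list(pairs = p, ia = ia, ib = ib)
}
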