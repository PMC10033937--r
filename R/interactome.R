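#' Construct an interactome
#'
#' An `interactome` is an undirected labeled graph: the universe every scorer
#' in this package operates on. Edges are stored canonically (endpoints
#' sorted lexicographically) with duplicates collapsed, so `(a,b)` and
#' `(b,a)` are the same edge. Self-loops (a protein interacting with itself)
#' are permitted when `allow_self_loops = TRUE`.
#'
#' @param edges two-column matrix or data frame of node labels (character).
#' @param nodes optional character vector of node labels; defaults to the
#'   union of edge endpoints. Extra isolated nodes may be supplied.
#' @param name graph name carried through score tables and reports.
#' @param allow_self_loops keep self-loops (`TRUE`, default) or drop them
#'   with a message.
#' @return An object of class `interactome` with components `name`, `nodes`
#'   (sorted character vector) and `edges` (canonical two-column character
#'   matrix).
#' @export
interactome <- function(edges, nodes = NULL, name = "graph",
                        allow_self_loops = TRUE) {
  if (length(edges) == 0L || nrow(as.matrix(edges)) == 0L) {
    ed <- cbind(node_a = character(0), node_b = character(0))
  } else {
    ed <- canonicalize_pairs(edges)
    keys <- pair_key(ed[, 1L], ed[, 2L])
    ed <- ed[!duplicated(keys), , drop = FALSE]
    if (!allow_self_loops) {
      self <- ed[, 1L] == ed[, 2L]
      if (any(self)) {
        message("dropped ", sum(self), " self-loop(s)")
        ed <- ed[!self, , drop = FALSE]
      }
    }
    ed <- ed[order(ed[, 1L], ed[, 2L], method = "radix"), , drop = FALSE]
  }
  nd <- sort(unique(c(nodes, as.vector(ed))), method = "radix")
  structure(
    list(name = name, nodes = nd, edges = ed,
         allow_self_loops = allow_self_loops),
    class = "interactome"
  )
}

#' @export
print.interactome <- function(x, ...) {
  cat("interactome '", x$name, "': ", length(x$nodes), " nodes, ",
      nrow(x$edges), " edges (", sum(x$edges[, 1L] == x$edges[, 2L]),
      " self-loops)\n", sep = "")
  invisible(x)
}

n_nodes <- function(g) length(g$nodes)
n_edges <- function(g) nrow(g$edges)

edge_keys <- function(g) pair_key(g$edges[, 1L], g$edges[, 2L])

#' Read an interactome from a two-column edge list
#'
#' Parses the tab/whitespace-separated edge-list format in which benchmark
#' interactomes are customarily deposited. Lines starting with `#` and blank
#' lines are skipped; columns beyond the first two are ignored; duplicate and
#' reversed-duplicate lines collapse to a single edge.
#'
#' @param path path to the edge-list file.
#' @param name graph name (defaults to the file name).
#' @param allow_self_loops keep self-loops; when `FALSE` they are dropped and
#'   their count reported in a message.
#' @return An [interactome].
#' @export
read_edge_list <- function(path, name = basename(path),
                           allow_self_loops = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  if (length(idx) == 0L) stop("no edges in ", path)
  fields <- strsplit(trimws(lines[idx]), "[ \t]+")
  bad <- which(vapply(fields, length, 1L) < 2L)
  if (length(bad) > 0L) {
    stop("malformed edge list line ", idx[bad[1L]], " in ", path,
         ": need at least two fields")
  }
  ed <- cbind(vapply(fields, `[`, "", 1L), vapply(fields, `[`, "", 2L))
  interactome(ed, name = name, allow_self_loops = allow_self_loops)
}

#' Write an interactome as a two-column edge list
#'
#' @param g an [interactome].
#' @param path output file path.
#' @export
write_edge_list <- function(g, path) {
  utils::write.table(g$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Summary statistics of an interactome
#'
#' Counts nodes, edges and self-loops and reports mean degree and density.
#' By the standard graph-theory convention a self-loop contributes 2 to its
#' node's degree; because deposited interactome statistics do not always
#' state the convention used, it is configurable via `self_loop_degree`.
#' The density denominator counts `n(n-1)/2` unordered pairs plus the `n`
#' self-pair slots when the graph admits self-loops.
#'
#' @param g an [interactome].
#' @param self_loop_degree degree contributed by a self-loop (2, the
#'   standard convention, or 1).
#' @return A list of class `graph_summary` with fields `n_nodes`, `n_edges`,
#'   `n_self_loops`, `n_edges_simple`, `mean_degree`, `density`.
#' @export
graph_summary <- function(g, self_loop_degree = 2) {
  n <- n_nodes(g)
  if (n == 0L) stop("empty graph")
  m <- n_edges(g)
  s <- sum(g$edges[, 1L] == g$edges[, 2L])
  mean_deg <- (2 * (m - s) + self_loop_degree * s) / n
  slots <- n * (n - 1) / 2 + if (g$allow_self_loops) n else 0
  structure(
    list(name = g$name, n_nodes = n, n_edges = m, n_self_loops = s,
         n_edges_simple = m - s, mean_degree = mean_deg,
         density = m / slots, self_loop_degree = self_loop_degree),
    class = "graph_summary"
  )
}

#' @export
print.graph_summary <- function(x, ...) {
  cat("graph '", x$name, "': ", x$n_nodes, " nodes, ", x$n_edges,
      " edges (", x$n_self_loops, " self-loops), mean degree ",
      signif(x$mean_degree, 4), ", density ", signif(x$density, 4), "\n",
      sep = "")
  invisible(x)
}

#' Sparse adjacency matrix of an interactome
#'
#' @param g an [interactome].
#' @param drop_self_loops remove self-loops first (most scorers operate on
#'   the simple graph).
#' @return A symmetric sparse 0/1 matrix with node labels as dimnames; a
#'   self-loop appears as a diagonal 1.
#' @export
adjacency_matrix <- function(g, drop_self_loops = TRUE) {
  n <- n_nodes(g)
  ed <- g$edges
  if (drop_self_loops) ed <- ed[ed[, 1L] != ed[, 2L], , drop = FALSE]
  if (nrow(ed) == 0L) {
    A <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                              dims = c(n, n))
  } else {
    i <- match(ed[, 1L], g$nodes)
    j <- match(ed[, 2L], g$nodes)
    self <- i == j
    A <- Matrix::sparseMatrix(i = c(i[!self], j[!self], i[self]),
                              j = c(j[!self], i[!self], j[self]),
                              x = 1, dims = c(n, n))
  }
  dimnames(A) <- list(g$nodes, g$nodes)
  A
}

# Node degrees on the simple graph (self-loops dropped); used by scorers.
simple_degrees <- function(g) {
  A <- adjacency_matrix(g, drop_self_loops = TRUE)
  Matrix::rowSums(A)
}

#' Convert an interactome to an igraph object
#'
#' @param g an [interactome].
#' @param drop_self_loops remove self-loops.
#' @return An undirected `igraph` graph over the same labeled node set.
#' @export
as_igraph <- function(g, drop_self_loops = TRUE) {
  ed <- g$edges
  if (drop_self_loops) ed <- ed[ed[, 1L] != ed[, 2L], , drop = FALSE]
  igraph::graph_from_data_frame(
    as.data.frame(ed, stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = data.frame(name = g$nodes, stringsAsFactors = FALSE)
  )
}

#' Write ranked predictions to a TSV file
#'
#' Rows are sorted by the package's deterministic ranking rule (descending
#' score, lexicographic pair order on ties) and carry an explicit rank
#' column, mirroring the "top-k predicted PPIs" deliverable of benchmark
#' studies.
#'
#' @param scores a [score_table].
#' @param path output file path.
#' @param top_k number of rows to keep; `Inf` (default) writes all. A
#'   `top_k` exceeding the table size writes all rows with a warning.
#' @return The ranked data frame that was written, invisibly.
#' @export
write_predictions <- function(scores, path, top_k = Inf) {
  if (nrow(scores) == 0L) stop("empty score table")
  ranked <- rank_candidates(scores)
  if (is.finite(top_k)) {
    if (top_k > nrow(ranked)) {
      warning("top_k (", top_k, ") exceeds table size (", nrow(ranked),
              "); writing all rows")
    } else {
      ranked <- ranked[seq_len(top_k), , drop = FALSE]
    }
  }
  utils::write.table(ranked, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(ranked)
}
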