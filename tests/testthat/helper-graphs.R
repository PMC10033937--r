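# Small graph builders used across tests. Labels are plain characters so the
# canonical (lexicographic) pair order is obvious in expectations.

path_graph <- function(n, name = paste0("path", n)) {
  lab <- as.character(seq_len(n))
  interactome(cbind(lab[-n], lab[-1]), name = name)
}

star_graph <- function(leaves = c("a", "b", "d"), hub = "c") {
  interactome(cbind(hub, leaves), name = "star")
}

complete_graph <- function(n) {
  lab <- as.character(seq_len(n))
  interactome(t(utils::combn(lab, 2)), name = paste0("K", n))
}

cycle_graph <- function(n) {
  lab <- as.character(seq_len(n))
  interactome(cbind(lab, lab[c(2:n, 1)]), name = paste0("C", n))
}

# K4 with edge (1,2) removed: the hand-enumerated CRA / L3 example graph.
k4_minus_edge <- function() {
  g <- complete_graph(4)
  interactome(g$edges[!(g$edges[, 1] == "1" & g$edges[, 2] == "2"), ],
              name = "K4me")
}

interactome_from_igraph <- function(ig, name = "atlas") {
  n <- igraph::vcount(ig)
  lab <- sprintf("n%02d", seq_len(n))
  el <- igraph::as_edgelist(ig, names = FALSE)
  interactome(cbind(lab[el[, 1]], lab[el[, 2]]), nodes = lab, name = name)
}

# All non-isomorphic connected graphs with n_min..n_max nodes and at least
# one edge, from the igraph atlas (complete up to 7 nodes).
atlas_connected <- function(n_min = 2, n_max = 7) {
  out <- list()
  for (i in 0:1252) {
    ig <- igraph::graph_from_atlas(i)
    nv <- igraph::vcount(ig)
    if (nv < n_min || nv > n_max) next
    if (igraph::ecount(ig) < 1 || !igraph::is_connected(ig)) next
    out[[length(out) + 1L]] <- interactome_from_igraph(ig, sprintf("atlas%d", i))
  }
  out
}

all_missing_pairs <- function(g) build_candidate_universe(g)

# random relabeling of a graph, returning the new graph plus the label map
relabel_graph <- function(g, seed) {
  set.seed(seed)
  new_lab <- paste0("r", sample(length(g$nodes)))
  names(new_lab) <- g$nodes
  list(graph = interactome(cbind(new_lab[g$edges[, 1]], new_lab[g$edges[, 2]]),
                           nodes = unname(new_lab), name = paste0(g$name, "_rl")),
       map = new_lab)
}
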