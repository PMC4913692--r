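#' MCODE vertex weighting
#'
#' Each vertex is weighted by its closed neighborhood: take the induced
#' subgraph on the vertex and its neighbors, find the highest k-core of
#' that subgraph, and multiply that core number k by the density of the
#' k-core. Dense, clique-like neighborhoods score high; an isolated vertex
#' weighs 0.
#'
#' @param graph an undirected simple `igraph` graph.
#' @return named numeric vector of weights.
#' @export
vertex_weights <- function(graph) {
  vs <- igraph::V(graph)
  w <- setNames(numeric(length(vs)), vs$name)
  for (v in seq_along(vs)) {
    nb <- igraph::neighbors(graph, v)
    if (!length(nb)) next
    sub <- igraph::induced_subgraph(graph, c(v, nb))
    core <- igraph::coreness(sub)
    k <- max(core)
    core_g <- igraph::induced_subgraph(sub, which(core >= k))
    w[v] <- k * .graph_density(core_g)
  }
  w
}

# edge count over n(n-1)/2, loops excluded; 0 for fewer than 2 nodes
.graph_density <- function(g) {
  n <- igraph::vcount(g)
  if (n < 2) return(0)
  igraph::ecount(igraph::simplify(g)) / (n * (n - 1) / 2)
}

#' Score a node set as a molecular complex
#'
#' Density is the number of induced edges over the theoretical maximum
#' `n(n-1)/2`; the complex score is density times the number of nodes.
#' Fewer than 2 nodes gives density and score 0.
#'
#' @param node_ids vertex names.
#' @param graph the `igraph` graph containing them.
#' @return a `complex` (list: `node_ids`, `n_nodes`, `n_edges`, `density`,
#'   `score`).
#' @export
score_complex <- function(node_ids, graph) {
  if (!all(node_ids %in% igraph::V(graph)$name))
    stop("unknown node id(s) in complex")
  sub <- igraph::induced_subgraph(graph, node_ids)
  n <- igraph::vcount(sub); e <- igraph::ecount(igraph::simplify(sub))
  dens <- if (n < 2) 0 else e / (n * (n - 1) / 2)
  structure(list(node_ids = sort(node_ids), n_nodes = as.integer(n),
                 n_edges = as.integer(e), density = dens, score = dens * n),
            class = "complex")
}

#' Detect dense complexes (MCODE-style)
#'
#' Seeds complexes at the highest-weight unvisited vertex and grows them
#' breadth-first, admitting a neighbor whose weight exceeds
#' `(1 - vwp) * seed weight`; every admitted vertex is visited at most
#' once, so complexes are disjoint. The optional haircut removes members
#' connected to the complex by a single edge. Complexes smaller than
#' `min_size` are discarded. Output is sorted by score, then size, then
#' seed id, and ranked.
#'
#' @param graph an undirected simple `igraph` graph with named vertices.
#' @param vwp vertex weight percentage in \[0, 1); larger admits more
#'   nodes. Default 0.2.
#' @param haircut remove degree-1 members of each complex (default TRUE).
#' @param min_size minimum complex size to report (default 3).
#' @return list of `complex` objects, each with a `rank` and `seed` field.
#' @export
find_complexes <- function(graph, vwp = 0.2, haircut = TRUE, min_size = 3) {
  stopifnot(vwp >= 0, vwp < 1)
  if (igraph::vcount(graph) == 0) return(list())
  if (is.null(igraph::V(graph)$name))
    graph <- igraph::set_vertex_attr(graph, "name",
                                     value = as.character(seq_len(igraph::vcount(graph))))
  w <- vertex_weights(graph)
  nm <- igraph::V(graph)$name
  visited <- setNames(logical(length(nm)), nm)
  # deterministic seed order: weight desc, then name
  order_seed <- nm[order(-w, nm)]

  complexes <- list()
  adj <- igraph::adjacent_vertices(graph, igraph::V(graph))
  names(adj) <- nm
  for (seed in order_seed) {
    if (visited[seed]) next
    thr <- (1 - vwp) * w[seed]
    members <- seed
    visited[seed] <- TRUE
    frontier <- seed
    while (length(frontier)) {
      nxt <- character(0)
      for (u in frontier) {
        for (nb in adj[[u]]$name) {
          if (!visited[nb] && w[nb] > thr) {
            visited[nb] <- TRUE
            members <- c(members, nb)
            nxt <- c(nxt, nb)
          }
        }
      }
      frontier <- nxt
    }
    if (haircut && length(members) > 1) {
      sub <- igraph::induced_subgraph(graph, members)
      deg <- igraph::degree(sub)
      members <- members[members %in% names(deg)[deg > 1]]
    }
    if (length(members) < min_size) next
    cx <- score_complex(members, graph)
    cx$seed <- seed
    complexes[[length(complexes) + 1]] <- cx
  }
  if (!length(complexes)) return(list())
  o <- order(-vapply(complexes, `[[`, 0, "score"),
             -vapply(complexes, `[[`, 0, "n_nodes"),
             vapply(complexes, `[[`, "", "seed"))
  complexes <- complexes[o]
  for (i in seq_along(complexes)) complexes[[i]]$rank <- i
  complexes
}

#' Complex list as a data.frame
#'
#' One row per complex with rank, score, node and edge counts and density —
#' the layout of an MCODE result table.
#'
#' @param complexes list from [find_complexes()].
#' @param label optional run label column.
#' @return data.frame.
#' @export
complex_table <- function(complexes, label = NA_character_) {
  if (!length(complexes))
    return(data.frame(label = character(0), rank = integer(0),
                      score = numeric(0), n_nodes = integer(0),
                      n_edges = integer(0), density = numeric(0)))
  data.frame(label = label,
             rank = vapply(complexes, `[[`, 0, "rank"),
             score = vapply(complexes, `[[`, 0, "score"),
             n_nodes = vapply(complexes, `[[`, 0L, "n_nodes"),
             n_edges = vapply(complexes, `[[`, 0L, "n_edges"),
             density = vapply(complexes, `[[`, 0, "density"))
}

#' @export
print.complex <- function(x, ...) {
  cat("complex", if (!is.null(x$rank)) paste0("#", x$rank) else "",
      ": ", x$n_nodes, " nodes, ", x$n_edges, " edges, density ",
      round(x$density, 4), ", score ", round(x$score, 2), "\n", sep = "")
  invisible(x)
}
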