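#' Cost parameters for distance-weighted homophilic choice
#'
#' The weighted friend-choice heuristic scores a candidate j for ego i as
#' `|trait_i - trait_j|^trait_exponent * d(i, j)^distance_exponent`, where
#' `d(i, j)` is the shortest-path length on the current combined network.
#' The defaults (2 and 0.5) encode that larger trait distances are disliked
#' with increasing intensity while extra network steps matter less and less
#' the further away the candidate already is.  Pairs in different components
#' have no finite path; they are scored with `unreachable_distance` instead
#' (by default the number of agents n, an upper bound on any finite
#' shortest path), which keeps cross-component friendships possible.
#'
#' @param trait_exponent Positive exponent on the absolute trait distance.
#' @param distance_exponent Positive exponent on the graph distance.
#' @param unreachable_distance Distance stand-in for disconnected pairs;
#'   `NULL` (default) means "use n at evaluation time".
#' @return An object of class `cost_params`.
#' @export
cost_params <- function(trait_exponent = 2, distance_exponent = 0.5,
                        unreachable_distance = NULL) {
  stopifnot(trait_exponent > 0, distance_exponent > 0,
            is.null(unreachable_distance) || unreachable_distance > 0)
  structure(list(trait_exponent = trait_exponent,
                 distance_exponent = distance_exponent,
                 unreachable_distance = unreachable_distance),
            class = "cost_params")
}

#' Social network: kin edges plus friendship edges under a degree target
#'
#' Wraps a kin network together with (initially zero) friendship edges and
#' the uniform degree target `nu`.  The kin subgraph is immutable: filling
#' friendships only ever adds edges, so the kin network stays a subgraph of
#' the full network.
#'
#' @param kin A `kin_network` (traits may be assigned before or after).
#' @param nu Degree target: the desired number of social contacts per agent.
#' @return An object of class `social_network` with fields `agents`,
#'   `kin_edges`, `friend_edges`, `n`, `nu` and `meta` (provenance:
#'   algorithm, seed, cost parameters once filled).
#' @export
#' @examples
#' kin <- generate_pedigree(pedigree_params(n_egos = 50, fertility = 3, seed = 1))
#' net <- social_network(assign_traits(kin, seed = 2), nu = 10)
social_network <- function(kin, nu) {
  stopifnot(inherits(kin, "kin_network"), is.numeric(nu), nu >= 1)
  structure(list(agents = kin$agents, kin_edges = kin$edges,
                 friend_edges = canonical_edges(NULL, kin$n),
                 n = kin$n, nu = as.integer(nu), meta = list()),
            class = "social_network")
}

#' @export
print.social_network <- function(x, ...) {
  cat("<social_network> ", x$n, " agents, nu = ", x$nu, ", ",
      nrow(x$kin_edges), " kin + ", nrow(x$friend_edges),
      " friend edges", sep = "")
  if (!is.null(x$meta$algorithm))
    cat(" (", x$meta$algorithm, ")", sep = "")
  cat("\n")
  invisible(x)
}

#' All edges of a social network
#'
#' @param net A `social_network`.
#' @return Edge matrix (columns `from`, `to`, 1-based, `from < to`) with an
#'   `is_kin` logical attribute column bound as a third column is *not*
#'   included; use [edge_table()] for the annotated version.
#' @export
full_edges <- function(net) {
  rbind(net$kin_edges, net$friend_edges)
}

#' Edge table with kin flag
#'
#' @param net A `social_network`.
#' @return Data frame with columns `from`, `to` (1-based ids) and `is_kin`.
#' @export
edge_table <- function(net) {
  data.frame(from = c(net$kin_edges[, 1], net$friend_edges[, 1]),
             to = c(net$kin_edges[, 2], net$friend_edges[, 2]),
             is_kin = rep(c(TRUE, FALSE),
                          c(nrow(net$kin_edges), nrow(net$friend_edges))))
}

#' Degrees in the full (kin + friend) network
#'
#' @param net A `social_network`.
#' @return Integer vector of vertex degrees.
#' @export
social_degrees <- function(net) {
  edge_degrees(full_edges(net), net$n)
}

#' Append friendship edges to a social network
#'
#' Low-level helper for building fixtures or importing externally completed
#' networks; no degree-target bookkeeping is applied.  Edges already present
#' (as kin or friend) are ignored.
#'
#' @param net A `social_network`.
#' @param edges Two-column matrix of 1-based undirected edges.
#' @return The updated network.
#' @export
add_friend_edges <- function(net, edges) {
  edges <- canonical_edges(edges, net$n)
  all_new <- canonical_edges(rbind(net$friend_edges, edges), net$n)
  # drop any that duplicate kin edges
  if (nrow(net$kin_edges) > 0 && nrow(all_new) > 0) {
    kin_key <- (as.double(net$kin_edges[, 1]) - 1) * net$n + net$kin_edges[, 2]
    new_key <- (as.double(all_new[, 1]) - 1) * net$n + all_new[, 2]
    all_new <- all_new[!(new_key %in% kin_key), , drop = FALSE]
  }
  net$friend_edges <- all_new
  net
}

#' Dense adjacency matrix of a network
#'
#' @param net A `kin_network` or `social_network`.
#' @param which For social networks, `"full"` (kin + friend, the default)
#'   or `"kin"`.
#' @return A symmetric 0/1 numeric matrix with zero diagonal.
#' @export
adjacency_matrix <- function(net, which = c("full", "kin")) {
  which <- match.arg(which)
  edges <- if (inherits(net, "social_network")) {
    if (which == "full") full_edges(net) else net$kin_edges
  } else net$edges
  A <- matrix(0, net$n, net$n)
  if (nrow(edges) > 0) {
    A[cbind(edges[, 1], edges[, 2])] <- 1
    A[cbind(edges[, 2], edges[, 1])] <- 1
  }
  A
}

# Adjacency list (list of sorted integer neighbour vectors).
adjacency_list <- function(edges, n) {
  adj <- rep.int(list(integer(0)), n)
  if (nrow(edges) > 0) {
    nb <- split(c(edges[, 2], edges[, 1]), c(edges[, 1], edges[, 2]))
    adj[as.integer(names(nb))] <- lapply(nb, function(v) sort(as.integer(v)))
  }
  adj
}

#' Convert a network to an igraph graph
#'
#' Vertices carry `trait` and `generation` attributes; edges of a social
#' network carry an `is_kin` attribute.
#'
#' @param net A `kin_network` or `social_network`.
#' @return An undirected `igraph` graph.
#' @export
as_igraph <- function(net) {
  if (inherits(net, "social_network")) {
    et <- edge_table(net)
    g <- igraph::graph_from_data_frame(
      et, directed = FALSE,
      vertices = data.frame(name = seq_len(net$n),
                            trait = net$agents$trait,
                            generation = net$agents$generation))
  } else {
    g <- igraph::graph_from_data_frame(
      data.frame(from = net$edges[, 1], to = net$edges[, 2]),
      directed = FALSE,
      vertices = data.frame(name = seq_len(net$n),
                            trait = net$agents$trait,
                            generation = net$agents$generation))
    igraph::E(g)$is_kin <- rep(TRUE, igraph::ecount(g))
  }
  g
}

#' Write a network as an undirected edge list CSV
#'
#' Ids are written 0-based, one row per edge (`from < to`), no duplicates.
#' Social networks gain an `is_kin` column.
#'
#' @param net A `kin_network` or `social_network`.
#' @param path Output file path.
#' @export
write_edgelist <- function(net, path) {
  if (inherits(net, "social_network")) {
    et <- edge_table(net)
    et$from <- et$from - 1L
    et$to <- et$to - 1L
    utils::write.csv(et, path, row.names = FALSE, quote = FALSE)
  } else {
    utils::write.csv(data.frame(from = net$edges[, 1] - 1L,
                                to = net$edges[, 2] - 1L),
                     path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Read a kin network from an edge-list CSV
#'
#' Expects the format written by [write_edgelist()]: columns `from`, `to`
#' with 0-based ids.  The number of agents defaults to the largest id + 1.
#'
#' @param path CSV path.
#' @param n Number of agents; defaults to `max(id) + 1`.
#' @return A `kin_network` (grandparent identifiers unknown).
#' @export
read_kin_edgelist <- function(path, n = NULL) {
  df <- utils::read.csv(path)
  stopifnot(all(c("from", "to") %in% names(df)))
  if (is.null(n)) n <- max(df$from, df$to) + 1L
  kin_network(n, cbind(df$from + 1L, df$to + 1L))
}

#' Write a network as GraphML
#'
#' Uses igraph's GraphML writer; vertex attributes `trait` and `generation`
#' and (for social networks) the edge attribute `is_kin` are preserved.
#' For a filled social network a JSON provenance sidecar
#' (`<path>.json`: algorithm, seed, cost parameters, nu) is written too.
#'
#' @param net A `kin_network` or `social_network`.
#' @param path Output `.graphml` path.
#' @param sidecar Write the JSON provenance sidecar (default `TRUE` when
#'   provenance is available).
#' @export
write_graphml <- function(net, path, sidecar = TRUE) {
  igraph::write_graph(as_igraph(net), path, format = "graphml")
  if (sidecar && inherits(net, "social_network") && length(net$meta) > 0) {
    meta <- net$meta
    meta$cost_params <- unclass(meta$cost_params)
    meta$n <- net$n
    meta$nu <- net$nu
    jsonlite::write_json(meta, paste0(path, ".json"),
                         auto_unbox = TRUE, null = "null", digits = NA)
  }
  invisible(path)
}

#' Read a kin network from GraphML
#'
#' @param path GraphML file written by [write_graphml()] (or any undirected
#'   GraphML graph; a `trait` vertex attribute is used when present).
#' @return A `kin_network`.
#' @export
read_kin_graphml <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  n <- igraph::vcount(g)
  el <- igraph::as_edgelist(g, names = FALSE)
  traits <- if ("trait" %in% igraph::vertex_attr_names(g))
    igraph::V(g)$trait else NULL
  kin_network(n, el, traits = traits)
}
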