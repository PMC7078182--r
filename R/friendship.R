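#' Absolute trait distance between two agents
#'
#' The type distance used by the purely homophilic friend-choice heuristic.
#'
#' @param trait_i,trait_j Finite trait values.
#' @return `|trait_i - trait_j|` (vectorised).
#' @export
#' @examples
#' type_distance(10, 30)  # 20
type_distance <- function(trait_i, trait_j) {
  stopifnot(all(is.finite(trait_i)), all(is.finite(trait_j)))
  abs(trait_i - trait_j)
}

#' Graph-distance-weighted homophily cost
#'
#' Cost of a candidate friendship under the distance-weighted heuristic:
#' `|trait_i - trait_j|^trait_exponent * graph_dist^distance_exponent`.
#' With the default exponents (2, 0.5) this is the squared trait distance
#' times the square root of the shortest-path length.
#'
#' @param trait_i,trait_j Trait values.
#' @param graph_dist Shortest-path length between the two agents on the
#'   current combined network (>= 1), or the unreachable sentinel for pairs
#'   in different components.
#' @param params A [cost_params()] object.
#' @return Non-negative cost (vectorised over candidates).
#' @export
#' @examples
#' weighted_cost(10, 13, 4)  # 9 * sqrt(4) = 18
weighted_cost <- function(trait_i, trait_j, graph_dist,
                          params = cost_params()) {
  abs(trait_i - trait_j)^params$trait_exponent *
    graph_dist^params$distance_exponent
}

#' Agents still below the degree target
#'
#' @param net A `social_network`.
#' @return Integer vector of agent ids with degree (in the full network)
#'   strictly below `nu`; empty when the network is saturated.
#' @export
eligible_set <- function(net) {
  which(social_degrees(net) < net$nu)
}

#' Pick the eligible agent with the fewest contacts
#'
#' @param X Non-empty integer vector of eligible agent ids.
#' @param net A `social_network`.
#' @param tiebreak `"random"` (uniform among tied minima, uses the current
#'   RNG stream) or `"index"` (lowest id, deterministic).
#' @return One agent id attaining the minimum degree within `X`.
#' @export
pick_min_degree <- function(X, net, tiebreak = c("random", "index")) {
  tiebreak <- match.arg(tiebreak)
  if (length(X) == 0L) stop("X must be non-empty")
  sel_min(X, social_degrees(net)[X], tiebreak)
}

# Pick the element of ids minimising score, breaking ties per policy.
sel_min <- function(ids, score, tiebreak) {
  tied <- ids[score == min(score)]
  if (tiebreak == "index" || length(tied) == 1L) return(tied[1L])
  tied[sample.int(length(tied), 1L)]
}

#' Partner choice: pure homophily
#'
#' Among eligible agents not already connected to `xi`, returns the one
#' with the smallest absolute trait distance to `xi`.
#'
#' @param xi Ego id (must be in `X`).
#' @param X Eligible set (ids with degree below the target).
#' @param net A `social_network` with traits assigned.
#' @param tiebreak See [pick_min_degree()].
#' @return A partner id, or `NA_integer_` when no unconnected eligible
#'   candidate remains (choice exhausted for this ego).
#' @export
pick_partner_homophily <- function(xi, X, net,
                                   tiebreak = c("random", "index")) {
  tiebreak <- match.arg(tiebreak)
  st <- fill_state(net)
  partner_homophily(xi, X, st$adj, st$traits, tiebreak)
}

#' Partner choice: homophily weighted by graph distance
#'
#' As [pick_partner_homophily()], but candidates are scored by
#' [weighted_cost()] with the shortest-path length from `xi` on the current
#' full network; candidates in a different component use the unreachable
#' sentinel distance (default n) and remain selectable.
#'
#' @inheritParams pick_partner_homophily
#' @param params A [cost_params()] object.
#' @return A partner id or `NA_integer_`.
#' @export
pick_partner_weighted <- function(xi, X, net, params = cost_params(),
                                  tiebreak = c("random", "index")) {
  tiebreak <- match.arg(tiebreak)
  st <- fill_state(net)
  sentinel <- params$unreachable_distance
  if (is.null(sentinel)) sentinel <- net$n
  partner_weighted(xi, X, st$adj, st$traits, params, sentinel, net$n,
                   tiebreak)
}

#' Partner choice: uniform random
#'
#' @inheritParams pick_partner_homophily
#' @return A partner id drawn uniformly among eligible unconnected
#'   candidates, or `NA_integer_`.
#' @export
pick_partner_random <- function(xi, X, net) {
  st <- fill_state(net)
  partner_random(xi, X, st$adj)
}

# ---- internal fast-path selection cores ------------------------------------

fill_state <- function(net) {
  edges <- full_edges(net)
  list(adj = adjacency_list(edges, net$n),
       deg = edge_degrees(edges, net$n),
       traits = net$agents$trait)
}

unconnected_candidates <- function(xi, X, adj) {
  cand <- X[X != xi]
  if (length(cand) == 0L) return(integer(0))
  nb <- adj[[xi]]
  if (length(nb)) cand <- cand[!(cand %in% nb)]
  cand
}

partner_homophily <- function(xi, X, adj, traits, tiebreak) {
  cand <- unconnected_candidates(xi, X, adj)
  if (length(cand) == 0L) return(NA_integer_)
  sel_min(cand, abs(traits[cand] - traits[xi]), tiebreak)
}

partner_weighted <- function(xi, X, adj, traits, params, sentinel, n,
                             tiebreak) {
  cand <- unconnected_candidates(xi, X, adj)
  if (length(cand) == 0L) return(NA_integer_)
  d <- bfs_distances(adj, xi, n)[cand]
  d[is.na(d)] <- sentinel
  cost <- abs(traits[cand] - traits[xi])^params$trait_exponent *
    d^params$distance_exponent
  sel_min(cand, cost, tiebreak)
}

partner_random <- function(xi, X, adj) {
  cand <- unconnected_candidates(xi, X, adj)
  if (length(cand) == 0L) return(NA_integer_)
  cand[sample.int(length(cand), 1L)]
}

# Single-source shortest-path lengths by breadth-first search on an
# adjacency list; NA for unreachable vertices.
bfs_distances <- function(adj, start, n) {
  dist <- rep.int(NA_integer_, n)
  dist[start] <- 0L
  frontier <- start
  d <- 0L
  while (length(frontier)) {
    d <- d + 1L
    nxt <- unlist(adj[frontier], use.names = FALSE)
    nxt <- unique(nxt[is.na(dist[nxt])])
    if (!length(nxt)) break
    dist[nxt] <- d
    frontier <- nxt
  }
  dist
}

#' Complete a social network to the degree target
#'
#' Iteratively adds friendship edges until every agent has `nu` social
#' contacts or no two eligible unconnected agents remain.  Each iteration
#' (i) forms the eligible set of agents below the degree target, (ii) picks
#' the eligible agent with the fewest contacts, (iii) picks its partner by
#' the configured heuristic, and (iv) adds the edge.  An ego for which the
#' heuristic finds no partner is set aside for the current pass but becomes
#' eligible again after any subsequent edge addition; the loop ends when a
#' full pass adds no edge.
#'
#' Kin edges are never modified.  Agents whose kin degree already meets or
#' exceeds `nu` never enter the eligible set and gain no friends, but keep
#' all their kin edges.
#'
#' @param net A `social_network`; traits must be assigned for the
#'   homophilic heuristics.
#' @param algorithm `"homophily"` (trait distance only), `"weighted"`
#'   (trait distance weighted by graph distance) or `"random"`.
#' @param params A [cost_params()] object (used by `"weighted"`).
#' @param tiebreak `"random"` or `"index"`; see [pick_min_degree()].
#' @param seed Optional integer seed; a fixed seed makes the run fully
#'   reproducible.
#' @return The completed `social_network`; `meta` records the algorithm,
#'   seed, tie-break policy and cost parameters.
#' @export
#' @examples
#' kin <- kin_network(4, traits = c(10, 12, 50, 90))
#' net <- social_network(kin, nu = 1)
#' filled <- fill_friendships(net, "homophily", tiebreak = "index")
#' filled$friend_edges
fill_friendships <- function(net, algorithm = c("homophily", "weighted",
                                                "random"),
                             params = cost_params(),
                             tiebreak = c("random", "index"),
                             seed = NULL) {
  algorithm <- match.arg(algorithm)
  tiebreak <- match.arg(tiebreak)
  stopifnot(inherits(net, "social_network"), net$nu >= 1)
  if (algorithm != "random" && anyNA(net$agents$trait))
    stop("traits must be assigned before homophilic friend choice")
  if (!is.null(seed)) set.seed(seed)

  n <- net$n
  nu <- net$nu
  st <- fill_state(net)
  adj <- st$adj
  deg <- st$deg
  traits <- st$traits
  sentinel <- params$unreachable_distance
  if (is.null(sentinel)) sentinel <- n

  new_i <- integer(0)
  new_j <- integer(0)
  iters <- 0L
  repeat {
    iters <- iters + 1L
    if (iters > n * nu)
      stop("friend-filling exceeded ", n * nu,
           " iterations: bookkeeping bug")
    X <- which(deg < nu)
    if (length(X) == 0L) break                   # every agent saturated
    active <- X
    added <- FALSE
    while (length(active) > 0L) {
      xi <- sel_min(active, deg[active], tiebreak)
      xj <- switch(algorithm,
        homophily = partner_homophily(xi, X, adj, traits, tiebreak),
        weighted  = partner_weighted(xi, X, adj, traits, params, sentinel,
                                     n, tiebreak),
        random    = partner_random(xi, X, adj))
      if (!is.na(xj)) {
        adj[[xi]] <- c(adj[[xi]], xj)
        adj[[xj]] <- c(adj[[xj]], xi)
        deg[xi] <- deg[xi] + 1L
        deg[xj] <- deg[xj] + 1L
        new_i <- c(new_i, xi)
        new_j <- c(new_j, xj)
        added <- TRUE
        break
      }
      active <- active[active != xi]
    }
    if (!added) break           # no eligible unconnected pair remains
  }

  net$friend_edges <- canonical_edges(
    rbind(net$friend_edges, cbind(new_i, new_j)), n)
  net$meta <- list(algorithm = algorithm, seed = seed, tiebreak = tiebreak,
                   cost_params = params)
  net
}
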