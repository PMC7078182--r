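# Fixture builders used across the suite. All networks are constructed in
# code; edges are 1-based two-column matrices.

# Social network with given kin and friend edges; traits default to ids.
fixture_net <- function(n, nu, kin = NULL, friends = NULL, traits = NULL) {
  if (is.null(traits)) traits <- as.numeric(seq_len(n))
  net <- social_network(kin_network(n, kin, traits = traits), nu)
  if (!is.null(friends)) net <- add_friend_edges(net, friends)
  net
}

complete_edges <- function(n) t(utils::combn(n, 2))

star_edges <- function(n) cbind(1L, 2:n)           # hub = vertex 1

path_edges <- function(n) cbind(seq_len(n - 1L), seq.int(2L, n))

# Erdos-Renyi G(n, p) edge matrix.
random_edges <- function(n, p, seed) {
  set.seed(seed)
  all_pairs <- complete_edges(n)
  all_pairs[stats::runif(nrow(all_pairs)) < p, , drop = FALSE]
}

# Vertex degrees implied by an edge matrix.
deg_of <- function(edges, n) tabulate(c(edges[, 1], edges[, 2]), nbins = n)

# Neighbour list implied by an edge matrix.
nbrs_of <- function(edges, n) {
  adj <- rep.int(list(integer(0)), n)
  for (r in seq_len(nrow(edges))) {
    i <- edges[r, 1]; j <- edges[r, 2]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  adj
}

# Two undirected edge sets are equal up to ordering and orientation.
expect_same_edges <- function(object, expected) {
  canon <- function(e) {
    e <- matrix(as.integer(as.matrix(e)), ncol = 2)
    e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
    unname(e[order(e[, 1], e[, 2]), , drop = FALSE])
  }
  expect_identical(canon(object), canon(expected))
}

# Independent local-clustering oracle: per-vertex neighbour-pair
# enumeration straight from the definition.
local_clustering_oracle <- function(edges, n) {
  A <- matrix(0L, n, n)
  if (nrow(edges)) {
    A[edges] <- 1L
    A[edges[, c(2, 1), drop = FALSE]] <- 1L
  }
  vals <- vapply(seq_len(n), function(i) {
    nb <- which(A[i, ] == 1L)
    d <- length(nb)
    if (d < 2) return(0)
    closed <- 0L
    for (u in nb) for (v in nb) {
      if (u != v && A[u, v] == 1L) closed <- closed + 1L
    }
    closed / (d * (d - 1))
  }, numeric(1))
  mean(vals)
}
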