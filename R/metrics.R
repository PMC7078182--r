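#' Friend ratio: fraction of edges that are non-kin
#'
#' The share of all social ties that are friendships rather than kin
#' relations, `1 - (kin edge count) / (total edge count)`, computed on the
#' symmetric adjacency sums.  This is the x-axis of the clustering
#' transition: it rises as fertility falls and kin become scarce.
#'
#' @param net A `social_network` with at least one edge.
#' @return A number in \[0, 1\]: 0 when every edge is kin, 1 when none is.
#' @export
friend_ratio <- function(net) {
  total <- nrow(net$kin_edges) + nrow(net$friend_edges)
  if (total == 0L)
    stop("friend ratio undefined on an edgeless network")
  1 - nrow(net$kin_edges) / total
}

#' Clustering coefficient normalised by the degree target
#'
#' The triple sum over ordered closed triples of the full adjacency matrix
#' (six times the triangle count) divided by `n^2 * nu * (nu - 1)`
#' (`denominator = "n_squared"`) or by `n * nu * (nu - 1)`
#' (`denominator = "n"`, the default).  The single-n variant is the average,
#' over agents, of the number of closed triads around an agent as a
#' proportion of all `nu * (nu - 1)` possible ordered triads at the degree
#' target; it equals the standard average local clustering coefficient when
#' every agent ends exactly at the target degree.  The n-squared variant is
#' provided for completeness; it is smaller by a factor n and cannot
#' approach 1 for large networks.
#'
#' @param net A `social_network` with `nu >= 2`.
#' @param denominator `"n"` (default) or `"n_squared"`.
#' @return Non-negative real.
#' @export
#' @examples
#' tri <- social_network(kin_network(3, rbind(c(1, 2), c(1, 3), c(2, 3))), nu = 2)
#' clustering_degree_target(tri)                # 1
#' clustering_degree_target(tri, "n_squared")   # 1/3
clustering_degree_target <- function(net, denominator = c("n", "n_squared")) {
  denominator <- match.arg(denominator)
  stopifnot(net$nu >= 2)
  trip <- ordered_closed_triples(net)
  denom <- net$n * as.double(net$nu) * (net$nu - 1)
  if (denominator == "n_squared") denom <- denom * net$n
  trip / denom
}

# Triple sum  sum_ijk b_ij b_ik b_jk  over the full adjacency matrix,
# computed via the matrix product trace; equals 6 x triangle count.
ordered_closed_triples <- function(net) {
  B <- adjacency_matrix(net, "full")
  sum((B %*% B) * B)
}

#' Average local clustering coefficient
#'
#' The standard (Watts-Strogatz) statistic: for each agent the fraction of
#' ordered pairs of its neighbours that are themselves connected,
#' averaged over all agents; agents of degree below 2 contribute 0.
#'
#' @param net A `social_network`.
#' @return A number in \[0, 1\].
#' @export
clustering_local_avg <- function(net) {
  B <- adjacency_matrix(net, "full")
  deg <- rowSums(B)
  closed <- rowSums((B %*% B) * B)   # closed ordered neighbour pairs per agent
  local <- ifelse(deg < 2, 0, closed / (deg * (deg - 1)))
  mean(local)
}

#' Exhaustive triangle count (test oracle)
#'
#' Counts unordered triangles by enumerating every vertex triple and
#' checking all three edges directly; cubic cost, guarded to `n <= 200`.
#' Intended as an independent oracle against which the matrix-product
#' triple-sum computation is verified.
#'
#' @param net A `social_network` (or `kin_network`).
#' @return Integer triangle count.
#' @export
count_triangles <- function(net) {
  if (net$n > 200L)
    stop("exhaustive triangle enumeration guarded to n <= 200")
  B <- if (inherits(net, "social_network"))
    adjacency_matrix(net, "full") else adjacency_matrix(net)
  n <- net$n
  count <- 0L
  if (n < 3L) return(0L)
  for (i in seq_len(n - 2L)) {
    for (j in seq.int(i + 1L, n - 1L)) {
      if (B[i, j] == 0) next
      for (k in seq.int(j + 1L, n)) {
        if (B[i, k] == 1 && B[j, k] == 1) count <- count + 1L
      }
    }
  }
  count
}

#' One-row summary of a completed social network
#'
#' @param net A `social_network`.
#' @return Data frame with columns `lambda` (friend ratio), `chi_nu_nsq`
#'   (triple sum over `n^2 nu (nu-1)`), `chi_nu_n` (triple sum over
#'   `n nu (nu-1)`), `chi_local` (average local clustering), `n`, `nu`.
#' @export
network_summary <- function(net) {
  data.frame(lambda = friend_ratio(net),
             chi_nu_nsq = clustering_degree_target(net, "n_squared"),
             chi_nu_n = clustering_degree_target(net, "n"),
             chi_local = clustering_local_avg(net),
             n = net$n, nu = net$nu)
}
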