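#' Parameters for the pedigree-based kin-network generator
#'
#' Bundles and validates the knobs of [generate_pedigree()].  The generator
#' builds a three-generation pedigree: founder (G0) couples, their children
#' (G1) paired into couples at random (own siblings excluded), and the G1
#' couples' children (G2), who are the egos of the kin network.  Kin edges
#' connect egos sharing at least two grandparents, i.e. siblings (all four
#' shared) and first cousins (exactly two shared).
#'
#' @param n_egos Number of egos (G2 vertices) in the returned network.
#' @param fertility Mean number of offspring per couple; drives the expected
#'   kin degree.
#' @param family_size_law Offspring-count distribution: `"binomial"`
#'   (Binomial(`binomial_max`, `fertility / binomial_max`), the default),
#'   `"poisson"`, or `"fixed"` (every couple has exactly
#'   `round(fertility)` children).
#' @param binomial_max Upper bound of the binomial offspring draw; the
#'   binomial law requires `fertility <= binomial_max`.
#' @param seed Integer seed; identical parameters (including the seed) give
#'   an identical pedigree and edge set.
#' @return An object of class `pedigree_params`.
#' @export
#' @examples
#' p <- pedigree_params(n_egos = 100, fertility = 3, seed = 1)
pedigree_params <- function(n_egos = 500, fertility,
                            family_size_law = c("binomial", "poisson", "fixed"),
                            binomial_max = 8L, seed = 1L) {
  family_size_law <- match.arg(family_size_law)
  stopifnot(is.numeric(n_egos), length(n_egos) == 1, n_egos >= 2,
            is.numeric(fertility), length(fertility) == 1, fertility > 0,
            is.numeric(binomial_max), binomial_max >= 1,
            is.numeric(seed), length(seed) == 1)
  if (family_size_law == "binomial" && fertility > binomial_max)
    stop("binomial family-size law requires fertility <= binomial_max")
  structure(list(n_egos = as.integer(n_egos), fertility = fertility,
                 family_size_law = family_size_law,
                 binomial_max = as.integer(binomial_max),
                 seed = as.integer(seed)),
            class = "pedigree_params")
}

# One offspring-count draw per couple under the configured law.
draw_offspring <- function(n_couples, params) {
  switch(params$family_size_law,
         binomial = stats::rbinom(n_couples, params$binomial_max,
                                  params$fertility / params$binomial_max),
         poisson  = stats::rpois(n_couples, params$fertility),
         fixed    = rep.int(as.integer(round(params$fertility)), n_couples))
}

#' Construct a kin network from an explicit edge list
#'
#' Used for user-supplied kin networks (e.g. read from an edge-list CSV).
#' Grandparent identifiers are unknown for such networks and left `NA`.
#'
#' @param n Number of agents.
#' @param edges Two-column integer matrix of undirected edges with 1-based
#'   vertex ids; may have zero rows.
#' @param traits Optional numeric vector of length `n` of agent traits.
#' @return An object of class `kin_network` with fields `agents` (data frame
#'   with columns `id`, `trait`, `generation`, `gp1`..`gp4`), `edges`
#'   (canonicalised: `i < j`, no duplicates) and `n`.
#' @export
kin_network <- function(n, edges = NULL, traits = NULL) {
  n <- as.integer(n)
  stopifnot(n >= 1)
  edges <- canonical_edges(edges, n)
  if (is.null(traits)) traits <- rep.int(NA_real_, n)
  stopifnot(length(traits) == n)
  agents <- data.frame(id = seq_len(n), trait = as.numeric(traits),
                       generation = rep.int(2L, n),
                       gp1 = NA_integer_, gp2 = NA_integer_,
                       gp3 = NA_integer_, gp4 = NA_integer_)
  structure(list(agents = agents, edges = edges, n = n),
            class = "kin_network")
}

# Canonicalise an undirected edge list: integer matrix, i < j, sorted,
# duplicates and self-loops removed.
canonical_edges <- function(edges, n) {
  if (is.null(edges) || NROW(edges) == 0)
    return(matrix(integer(0), ncol = 2,
                  dimnames = list(NULL, c("from", "to"))))
  edges <- matrix(as.integer(as.matrix(edges)), ncol = 2)
  if (any(edges < 1L) || any(edges > n))
    stop("edge endpoints must be in 1..n")
  i <- pmin(edges[, 1], edges[, 2])
  j <- pmax(edges[, 1], edges[, 2])
  keep <- i != j
  i <- i[keep]; j <- j[keep]
  key <- (as.double(i) - 1) * n + as.double(j)
  ord <- order(key)
  dup <- duplicated(key[ord])
  out <- cbind(from = i[ord][!dup], to = j[ord][!dup])
  storage.mode(out) <- "integer"
  out
}

#' @export
print.kin_network <- function(x, ...) {
  cat("<kin_network> ", x$n, " agents, ", nrow(x$edges), " kin edges",
      if (all(is.na(x$agents$trait))) ", traits unassigned" else "",
      "\n", sep = "")
  invisible(x)
}

#' Generate a kin network from a simulated three-generation pedigree
#'
#' Simulates founder (G0) couples, draws their offspring counts from the
#' family-size law, pairs the G1 generation into couples uniformly at random
#' excluding own siblings (unpaired leftovers remain childless), draws G2
#' offspring, and returns the G2 egos with kin edges between every pair of
#' egos sharing at least two grandparent identifiers: full siblings (same
#' parental couple, four shared grandparents) and first cousins (exactly two
#' shared grandparents).
#'
#' The founder pool is sized so that the expected number of egos is at least
#' 1.2 times `n_egos`; the realised egos are then uniformly subsampled to
#' exactly `n_egos`, keeping induced edges (a cross-section of the
#' population).  If, after a bounded number of founder-pool enlargements,
#' the pedigree still cannot supply `n_egos` egos, an error is raised (the
#' parameters are infeasible, e.g. fertility too low for any population
#' growth).
#'
#' @param params A [pedigree_params()] object.
#' @return A `kin_network` whose agents carry `gp1`..`gp4`, the G0
#'   identifiers of the ego's four grandparents.  Traits are unassigned; see
#'   [assign_traits()].
#' @export
#' @examples
#' net <- generate_pedigree(pedigree_params(n_egos = 50, fertility = 3, seed = 7))
#' net
generate_pedigree <- function(params) {
  stopifnot(inherits(params, "pedigree_params"))
  set.seed(params$seed)
  n <- params$n_egos
  f <- params$fertility
  # expected egos per founder couple ~ f^2 / 2 (G1 pairs into ~ C f / 2 couples)
  n_founder <- max(8L, ceiling(2.4 * n / max(f^2, 0.25)))
  for (attempt in seq_len(8L)) {
    ped <- build_pedigree(n_founder, params)
    if (nrow(ped$egos) >= n) {
      keep <- sort(sample.int(nrow(ped$egos), n))
      return(pedigree_to_network(ped$egos[keep, , drop = FALSE]))
    }
    n_founder <- n_founder * 2L
  }
  stop("pedigree cannot supply ", n, " egos after repeated founder-pool ",
       "enlargements; parameters look infeasible (fertility too low?)")
}

# Simulate one pedigree. Returns the G2 table: one row per ego with its
# parental-couple index and the four grandparent (G0 individual) ids.
build_pedigree <- function(n_founder, params) {
  # G0: founder couple k has members 2k-1 and 2k
  kids_g1 <- draw_offspring(n_founder, params)
  origin <- rep.int(seq_len(n_founder), kids_g1)  # founder couple of each G1
  n_g1 <- length(origin)
  couples <- pair_g1(origin)
  if (nrow(couples) == 0)
    return(list(egos = data.frame(couple = integer(0), gp1 = integer(0),
                                  gp2 = integer(0), gp3 = integer(0),
                                  gp4 = integer(0))))
  kids_g2 <- draw_offspring(nrow(couples), params)
  cpl <- rep.int(seq_len(nrow(couples)), kids_g2)
  o1 <- origin[couples[cpl, 1]]   # founder couple of parent 1
  o2 <- origin[couples[cpl, 2]]
  egos <- data.frame(couple = cpl,
                     gp1 = 2L * o1 - 1L, gp2 = 2L * o1,
                     gp3 = 2L * o2 - 1L, gp4 = 2L * o2)
  list(egos = egos)
}

# Random monogamous pairing of G1 agents excluding own siblings.  The pool
# is a random permutation; the head of the pool takes a uniform partner
# among non-siblings; agents with no feasible partner stay childless.
pair_g1 <- function(origin) {
  pool <- sample.int(length(origin))
  pairs <- matrix(integer(0), ncol = 2)
  res <- vector("list", length(origin) %/% 2L)
  np <- 0L
  while (length(pool) >= 2L) {
    x <- pool[1L]
    cand <- pool[-1L]
    cand <- cand[origin[cand] != origin[x]]
    if (length(cand) == 0L) {
      pool <- pool[-1L]
      next
    }
    y <- cand[sample.int(length(cand), 1L)]
    np <- np + 1L
    res[[np]] <- c(x, y)
    pool <- pool[pool != x & pool != y]
  }
  if (np == 0L) return(pairs)
  matrix(unlist(res[seq_len(np)]), ncol = 2, byrow = TRUE)
}

# Egos table -> kin_network: edge iff >= 2 shared grandparent ids, which for
# monogamous founders is equivalent to sharing a grandparental couple.
pedigree_to_network <- function(egos) {
  n <- nrow(egos)
  # grandparental couple ids (gp ids come in couple blocks 2k-1, 2k)
  gc1 <- (egos$gp1 + 1L) %/% 2L
  gc2 <- (egos$gp3 + 1L) %/% 2L
  groups <- split(rep(seq_len(n), 2L), c(gc1, gc2))
  edge_list <- lapply(groups, function(idx) {
    if (length(idx) < 2L) return(NULL)
    t(utils::combn(sort(idx), 2L))
  })
  edges <- do.call(rbind, edge_list)
  net <- kin_network(n, edges)
  net$agents$gp1 <- egos$gp1
  net$agents$gp2 <- egos$gp2
  net$agents$gp3 <- egos$gp3
  net$agents$gp4 <- egos$gp4
  net
}

#' Number of shared grandparent identifiers between two agents
#'
#' @param net A `kin_network` generated by [generate_pedigree()].
#' @param i,j Agent ids (1-based).
#' @return Integer count of shared grandparent identifiers (0, 2 or 4 in a
#'   monogamous pedigree).
#' @export
shared_grandparents <- function(net, i, j) {
  a <- net$agents
  gi <- c(a$gp1[i], a$gp2[i], a$gp3[i], a$gp4[i])
  gj <- c(a$gp1[j], a$gp2[j], a$gp3[j], a$gp4[j])
  if (anyNA(gi) || anyNA(gj))
    stop("grandparent identifiers unknown (user-supplied network?)")
  length(intersect(gi, gj))
}

#' Assign uniform traits to the agents of a network
#'
#' Draws one independent trait per agent from Uniform(`low`, `high`).  The
#' trait is the one-dimensional continuous type on which homophilic friend
#' choice operates.
#'
#' @param net A `kin_network` (or `social_network`).
#' @param low,high Bounds of the uniform law; defaults 0 and 100.
#' @param seed Optional integer seed; a fixed seed reproduces the trait
#'   vector exactly.
#' @return The network with `agents$trait` filled in.
#' @export
assign_traits <- function(net, low = 0, high = 100, seed = NULL) {
  stopifnot(low < high)
  if (!is.null(seed)) set.seed(seed)
  net$agents$trait <- stats::runif(net$n, low, high)
  net
}

#' Kin-degree summary of a network
#'
#' Summarises the kin-degree distribution and the fraction of agents whose
#' kin degree already meets the degree target, i.e. who would need no
#' friends at all.  Used to verify the regime in which almost all agents
#' have fewer relatives than the degree target before friend-filling.
#'
#' @param net A `kin_network`.
#' @param nu Degree target used for the `frac_at_target` column.
#' @return A one-row data frame with `mean`, `min`, `max` kin degree and
#'   `frac_at_target` (fraction of agents with kin degree >= `nu`).
#' @export
kin_degree_profile <- function(net, nu) {
  stopifnot(is.numeric(nu), nu >= 1)
  deg <- edge_degrees(net$edges, net$n)
  data.frame(mean = mean(deg), min = min(deg), max = max(deg),
             frac_at_target = mean(deg >= nu))
}

# Vertex degrees implied by a canonical edge matrix.
edge_degrees <- function(edges, n) {
  tabulate(c(edges[, 1], edges[, 2]), nbins = n)
}
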