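test_that("type distance is the absolute trait difference", {
  expect_equal(type_distance(10, 30), 20)
  expect_equal(type_distance(5, 5), 0)
  set.seed(3)
  a <- runif(1000, 0, 100); b <- runif(1000, 0, 100)
  expect_equal(type_distance(a, b), type_distance(b, a))
  expect_true(all(type_distance(a, b) >= 0))
})

test_that("weighted cost follows the exponent parameterisation", {
  expect_equal(weighted_cost(10, 13, 4), 9 * 2)       # 3^2 * 4^0.5
  expect_equal(weighted_cost(50, 50, 7), 0)
  expect_equal(weighted_cost(1, 3, 1), 4)
  p11 <- cost_params(trait_exponent = 1, distance_exponent = 1)
  expect_equal(weighted_cost(10, 13, 4, p11), 12)
  expect_error(cost_params(trait_exponent = 0), "trait_exponent")
})

test_that("eligible set is the strict below-target set", {
  net <- fixture_net(5, nu = 2)
  expect_identical(eligible_set(net), 1:5)            # empty network
  sat <- fixture_net(4, nu = 1, friends = rbind(c(1, 2), c(3, 4)))
  expect_length(eligible_set(sat), 0)                 # saturated
  # an agent whose kin degree alone meets nu is excluded
  hub <- fixture_net(5, nu = 2, kin = star_edges(5))  # hub degree 4
  expect_false(1L %in% eligible_set(hub))
  expect_true(all(2:5 %in% eligible_set(hub)))
})

test_that("minimum-degree pick honours degrees and tie policy", {
  net2 <- fixture_net(4, nu = 5, friends = rbind(c(1, 2), c(1, 3), c(1, 4),
                                                 c(2, 3), c(3, 4)))
  # degrees: 3, 2, 3, 2 -> min over X = {1,2,3} is agent 2
  expect_identical(pick_min_degree(1:3, net2), 2L)
  expect_identical(pick_min_degree(4L, net2), 4L)     # singleton
  expect_error(pick_min_degree(integer(0), net2), "non-empty")
  # uniform tie-break: all degrees equal on an empty network
  empty <- fixture_net(4, nu = 3)
  set.seed(11)
  draws <- replicate(10000, pick_min_degree(1:4, empty))
  freq <- tabulate(draws, 4) / 10000
  se <- sqrt(0.25 * 0.75 / 10000)
  expect_true(all(abs(freq - 0.25) < 3 * se))
  # index policy is deterministic
  expect_identical(pick_min_degree(1:4, empty, tiebreak = "index"), 1L)
})

test_that("homophilic partner choice minimises trait distance among unconnected", {
  net <- fixture_net(3, nu = 3, traits = c(10, 12, 50))
  expect_identical(pick_partner_homophily(1L, 1:3, net), 2L)
  # nearest candidate already connected -> next-closest unconnected
  net2 <- fixture_net(3, nu = 3, traits = c(10, 12, 50),
                      friends = rbind(c(1, 2)))
  expect_identical(pick_partner_homophily(1L, 1:3, net2), 3L)
  # exhausted ego
  expect_identical(pick_partner_homophily(1L, 1L, net), NA_integer_)
})

test_that("weighted partner choice trades similarity against graph distance", {
  # traits xi=0, a=5, b=6; dist(xi,a)=9 via a long path, dist(xi,b)=1 is
  # excluded (adjacent), so use dist(xi,b)=2: costs 25*3=75 vs 36*sqrt(2)=50.9
  # -> b despite larger trait distance
  n <- 12
  traits <- c(0, 5, 6, rep(90, n - 3))
  # path 1-4-5-6-7-8-9-10-11-2 gives dist(1,2)=9; path 1-12-3 gives dist(1,3)=2
  path_a <- cbind(c(1, 4:10, 11), c(4:10, 11, 2))
  path_b <- rbind(c(1, 12), c(12, 3))
  net <- fixture_net(n, nu = 20, traits = traits,
                     friends = rbind(path_a, path_b))
  expect_identical(pick_partner_weighted(1L, c(1L, 2L, 3L), net), 3L)
  # equidistant candidates reduce to the homophily ranking
  net_eq <- fixture_net(4, nu = 5, traits = c(10, 12, 50, 90),
                        friends = rbind(c(2, 3), c(2, 4)))
  # xi = 1 unreachable from everyone -> all candidates at the sentinel
  expect_identical(pick_partner_weighted(1L, 1:4, net_eq), 2L)
  # cross-component candidates stay selectable through the sentinel:
  # candidate 3 (other component) has tiny trait distance, candidate 2
  # (same component, distance 2) a huge one: 0.01^2*n^0.5 << 80^2*2^0.5
  net_cc <- fixture_net(6, nu = 5, traits = c(10, 90, 10.01, rep(50, 3)),
                        friends = rbind(c(1, 4), c(4, 2), c(3, 5)))
  expect_identical(pick_partner_weighted(1L, c(1L, 2L, 3L), net_cc), 3L)
})

test_that("random partner choice is uniform over unconnected candidates", {
  net <- fixture_net(3, nu = 3)
  set.seed(5)
  draws <- replicate(10000, pick_partner_random(1L, 1:3, net))
  freq <- mean(draws == 2L)
  se <- sqrt(0.5 * 0.5 / 10000)
  expect_lt(abs(freq - 0.5), 3 * se)
  expect_identical(pick_partner_random(1L, 1L, net), NA_integer_)
  net1 <- fixture_net(3, nu = 3, friends = rbind(c(1, 2)))
  expect_identical(pick_partner_random(1L, 1:3, net1), 3L)  # only 3 left
})

test_that("friend filling reproduces the four-agent worked example", {
  # traits [10, 12, 50, 90], nu = 1, empty kin, lowest-id tie-break:
  # agent 1 pairs with its nearest type (2), then 3 pairs with 4
  net <- fixture_net(4, nu = 1, traits = c(10, 12, 50, 90))
  filled <- fill_friendships(net, "homophily", tiebreak = "index")
  expect_same_edges(filled$friend_edges, rbind(c(1, 2), c(3, 4)))
  expect_identical(nrow(filled$kin_edges), 0L)
})

test_that("random filling with nu = n - 1 completes the graph", {
  n <- 9
  net <- fixture_net(n, nu = n - 1)
  filled <- fill_friendships(net, "random", seed = 8)
  expect_identical(nrow(filled$friend_edges), as.integer(n * (n - 1) / 2))
  expect_length(eligible_set(filled), 0)
})

test_that("a saturated network is returned unchanged", {
  sat <- fixture_net(4, nu = 1, friends = rbind(c(1, 2), c(3, 4)))
  out <- fill_friendships(sat, "homophily", seed = 1)
  expect_identical(out$friend_edges, sat$friend_edges)
  expect_identical(out$kin_edges, sat$kin_edges)
})

test_that("kin containment and the degree cap hold for all algorithms", {
  for (alg in c("homophily", "weighted", "random")) {
    for (s in 1:3) {
      kin <- generate_pedigree(pedigree_params(n_egos = 60, fertility = 3,
                                               seed = 100L + s))
      kin <- assign_traits(kin, seed = 200L + s)
      nu <- 8L
      net <- social_network(kin, nu)
      kin_deg <- deg_of(net$kin_edges, net$n)
      filled <- fill_friendships(net, alg, seed = 300L + s)
      # kin subgraph untouched
      expect_identical(filled$kin_edges, kin$edges)
      deg <- social_degrees(filled)
      # agents below target end at or below it; agents at/above gain nothing
      expect_true(all(deg[kin_deg < nu] <= nu))
      expect_true(all(deg[kin_deg >= nu] == kin_deg[kin_deg >= nu]))
      # friend edges only ever join agents that were below target
      expect_true(all(deg_of(filled$friend_edges, filled$n)
                      [kin_deg >= nu] == 0))
    }
  }
})

test_that("friend filling is deterministic under a fixed seed", {
  kin <- assign_traits(generate_pedigree(
    pedigree_params(n_egos = 80, fertility = 2.5, seed = 9)), seed = 10)
  net <- social_network(kin, 10)
  for (alg in c("homophily", "weighted", "random")) {
    a <- fill_friendships(net, alg, seed = 123)
    b <- fill_friendships(net, alg, seed = 123)
    expect_identical(a$friend_edges, b$friend_edges)
  }
})

test_that("homophilic friends are closer in trait than random agents", {
  # behavioural signature: on a kin-free network, almost every agent's
  # friends are nearer in type than a same-sized random sample would be
  n <- 200L
  nu <- 20L
  frac_closer <- vapply(1:10, function(s) {
    kin <- assign_traits(kin_network(n), seed = 500L + s)
    filled <- fill_friendships(social_network(kin, nu), "homophily",
                               seed = 600L + s)
    adj <- nbrs_of(full_edges(filled), n)
    tr <- filled$agents$trait
    set.seed(700L + s)
    closer <- vapply(seq_len(n), function(i) {
      friends <- adj[[i]]
      rand <- sample(setdiff(seq_len(n), i), nu)
      mean(abs(tr[friends] - tr[i])) < mean(abs(tr[rand] - tr[i]))
    }, logical(1))
    mean(closer)
  }, numeric(1))
  expect_gt(mean(frac_closer), 0.95)
})

test_that("degree-target degenerate cases terminate sensibly", {
  # nu smaller than some kin degrees: those agents keep all kin edges
  kin <- assign_traits(kin_network(5, complete_edges(5)), seed = 1)
  filled <- fill_friendships(social_network(kin, 2), "homophily", seed = 2)
  expect_same_edges(filled$kin_edges, complete_edges(5))
  expect_identical(nrow(filled$friend_edges), 0L)
})
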