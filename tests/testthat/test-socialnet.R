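test_that("co-occurrence counts tally recordings, with pup collapse counting once", {
  roster <- dplyr::bind_rows(
    make_roster(c("A", "B")),
    make_roster(c("P1", "P2"), life_stage = "juvenile")
  )
  log <- make_log(
    roster,
    make_event("R1", "2023-01-05 08:00:00", "social resting", "A",
      present = c("A", "B")
    )
  )
  s <- cooccurrence_counts(log)
  expect_equal(unname(s$n[c("A", "B")]), c(1, 1))
  expect_equal(s$x["A", "B"], 1)

  # two pups in one recording count once for the merged node
  log2 <- make_log(
    roster,
    make_event("R1", "2023-01-05 08:00:00", "social resting", "P1",
      present = c("P1", "P2")
    )
  )
  s2 <- cooccurrence_counts(log2, collapse_map = c(P1 = "Pups", P2 = "Pups"))
  expect_equal(unname(s2$n["Pups"]), 1)

  # individuals never recorded together have a zero joint count
  log3 <- make_log(
    roster,
    make_event(sprintf("A%02d", 1:10), paste0("2023-01-", 10:19, " 08:00:00"),
      "solitary resting", "A",
      present = "A"
    ),
    make_event(sprintf("B%02d", 1:10), paste0("2023-02-", 10:19, " 08:00:00"),
      "solitary resting", "B",
      present = "B"
    )
  )
  s3 <- cooccurrence_counts(log3)
  expect_equal(unname(s3$n[c("A", "B")]), c(10, 10))
  expect_equal(s3$x["A", "B"], 0)
})

test_that("unidentified occupants still count the recording for identified ones", {
  roster <- make_roster(c("A", "B"))
  log <- make_log(
    roster,
    make_event("R1", "2023-01-05 08:00:00", "scanning environment",
      "UNIDENTIFIED",
      present = c("A", "UNIDENTIFIED")
    )
  )
  s <- cooccurrence_counts(log)
  expect_equal(unname(s$n["A"]), 1)
})

test_that("simple-ratio association index matches its closed form", {
  summ <- structure(
    list(
      ids = c("A", "B"),
      n = c(A = 7, B = 7),
      x = named_square(c(7, 7, 7, 7), c("A", "B"))
    ),
    class = "sighting_summary"
  )
  expect_equal(association_matrix(summ, "sri")$weights["A", "B"], 1)

  summ$x["A", "B"] <- summ$x["B", "A"] <- 0
  expect_equal(association_matrix(summ, "sri")$weights["A", "B"], 0)

  summ$n <- c(A = 10, B = 10)
  summ$x <- named_square(c(10, 5, 5, 10), c("A", "B"))
  expect_equal(
    association_matrix(summ, "sri")$weights["A", "B"],
    5 / 15,
    tolerance = 1e-12
  )
  expect_equal(association_matrix(summ, "count")$weights["A", "B"], 5)
})

test_that("eigenvector centrality matches closed forms and errors usefully", {
  # complete graph: full symmetry, everyone at 1
  k4 <- social_network(named_square(rep(1, 16), letters[1:4]) - diag(4))
  expect_equal(eigenvector_centrality(k4)$centrality, rep(1, 4),
    tolerance = 1e-9
  )

  # star: centre 1, leaves 1/sqrt(3)
  star <- social_network(edge_weights(
    c("hub", "l1", "l2", "l3"),
    list(list("hub", "l1", 1), list("hub", "l2", 1), list("hub", "l3", 1))
  ))
  cs <- eigenvector_centrality(star)
  expect_equal(cs$centrality, c(1, rep(1 / sqrt(3), 3)), tolerance = 1e-9)

  # disconnected dyads error unless restricted
  dyads <- social_network(edge_weights(
    letters[1:4], list(list("a", "b", 1), list("c", "d", 2))
  ))
  expect_error(eigenvector_centrality(dyads), "disconnected")
  restricted <- eigenvector_centrality(dyads, largest_component = TRUE)
  expect_equal(nrow(restricted), 2)

  zero <- social_network(named_square(rep(0, 4), c("a", "b")))
  expect_error(eigenvector_centrality(zero), "zero")
})

test_that("modularity matches hand-derived values", {
  tri2 <- unit_triangles_bridged(bridge = 0)
  # all nodes in one community: Q forced to 0
  one <- setNames(rep(1, 6), letters[1:6])
  expect_equal(modularity_q(tri2, one), 0, tolerance = 1e-12)
  # true split of two disconnected triangles: Q = 0.5
  split2 <- setNames(c(1, 1, 1, 2, 2, 2), letters[1:6])
  expect_equal(modularity_q(tri2, split2), 0.5, tolerance = 1e-12)

  # single unit edge, singleton partition: Q = -0.5
  edge <- social_network(named_square(c(0, 1, 1, 0), c("a", "b")))
  expect_equal(
    modularity_q(edge, setNames(1:2, c("a", "b"))), -0.5,
    tolerance = 1e-12
  )
})

test_that("modularity agrees with the double-loop oracle on random graphs", {
  set.seed(11)
  for (i in 1:30) {
    n <- sample(3:12, 1)
    net <- random_connected_network(n)
    membership <- sample(1:3, n, replace = TRUE)
    names(membership) <- net$ids
    expect_equal(
      modularity_q(net, membership),
      oracle_modularity(net$weights, membership),
      tolerance = 1e-12
    )
  }
})

test_that("power-iteration centrality agrees with a full eigendecomposition", {
  set.seed(21)
  for (i in 1:25) {
    n <- sample(3:20, 1)
    net <- random_connected_network(n)
    got <- eigenvector_centrality(net)$centrality
    expect_lt(max(abs(got - oracle_centrality(net$weights))), 1e-8)
  }
})

test_that("centrality and communities agree with igraph on random graphs", {
  skip_if_not_installed("igraph")
  set.seed(33)
  for (i in 1:10) {
    net <- random_connected_network(sample(4:12, 1))
    g <- igraph::graph_from_adjacency_matrix(net$weights,
      mode = "undirected", weighted = TRUE
    )
    ig_cent <- igraph::eigen_centrality(g, weights = igraph::E(g)$weight)$vector
    expect_equal(
      eigenvector_centrality(net)$centrality,
      unname(ig_cent[net$ids]),
      tolerance = 1e-6
    )
    membership <- sample(1:2, length(net$ids), replace = TRUE)
    expect_equal(
      modularity_q(net, setNames(membership, net$ids)),
      igraph::modularity(g, membership, weights = igraph::E(g)$weight),
      tolerance = 1e-12
    )
  }
})

test_that("fast-greedy recovers planted structure and trivial optima", {
  # two triangles joined by a single bridge
  fg <- fast_greedy_partition(unit_triangles_bridged(bridge = 1))
  expect_equal(
    partition_groups(fg$partition$id, fg$partition$community),
    c("a,b,c", "d,e,f")
  )
  expect_equal(fg$strong_structure, fg$q_max > 0.3)

  # single edge: trace (-0.5, 0), one community at the max
  edge <- social_network(named_square(c(0, 1, 1, 0), c("a", "b")))
  fg2 <- fast_greedy_partition(edge)
  expect_equal(fg2$merges$q, c(-0.5, 0), tolerance = 1e-12)
  expect_equal(fg2$n_communities, 1)

  # complete graph K4: any split loses, single community, Q = 0
  k4 <- social_network(named_square(rep(1, 16), letters[1:4]) - diag(4))
  fg3 <- fast_greedy_partition(k4)
  expect_equal(fg3$n_communities, 1)
  expect_equal(fg3$q_max, 0, tolerance = 1e-12)

  disconnected <- social_network(edge_weights(
    letters[1:4], list(list("a", "b", 1), list("c", "d", 1))
  ))
  expect_error(fast_greedy_partition(disconnected), "disconnected")
})

test_that("fast-greedy equals the exhaustive optimum on planted two-clique graphs", {
  set.seed(55)
  for (sizes in list(c(3, 3), c(4, 3), c(4, 4))) {
    ids <- paste0("n", seq_len(sum(sizes)))
    w <- matrix(0, sum(sizes), sum(sizes), dimnames = list(ids, ids))
    g1 <- seq_len(sizes[1])
    g2 <- sizes[1] + seq_len(sizes[2])
    w[g1, g1] <- 1
    w[g2, g2] <- 1
    diag(w) <- 0
    w[sizes[1], sizes[1] + 1] <- w[sizes[1] + 1, sizes[1]] <- 0.5 # bridge
    net <- social_network(w)
    fg <- fast_greedy_partition(net)
    best <- oracle_best_partition(w)
    expect_equal(fg$q_max, best$q, tolerance = 1e-12)
    expect_equal(
      partition_groups(net$ids, fg$partition$community),
      partition_groups(net$ids, best$membership)
    )
  }
})

test_that("scaling all weights leaves centrality, Q and the partition unchanged", {
  set.seed(77)
  net <- random_connected_network(8)
  scaled <- social_network(net$weights * 13.7, weight_kind = net$weight_kind)
  expect_equal(
    eigenvector_centrality(scaled)$centrality,
    eigenvector_centrality(net)$centrality,
    tolerance = 1e-10
  )
  membership <- setNames(sample(1:2, 8, replace = TRUE), net$ids)
  expect_equal(
    modularity_q(scaled, membership),
    modularity_q(net, membership),
    tolerance = 1e-12
  )
  fg <- fast_greedy_partition(net)
  fgs <- fast_greedy_partition(scaled)
  expect_equal(fgs$partition, fg$partition)
  expect_equal(fgs$q_max, fg$q_max, tolerance = 1e-12)
})

test_that("fast-greedy Q is never below the all-in-one partition", {
  set.seed(88)
  for (i in 1:10) {
    net <- random_connected_network(sample(4:10, 1))
    fg <- fast_greedy_partition(net)
    expect_gte(fg$q_max, 0)
  }
})
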