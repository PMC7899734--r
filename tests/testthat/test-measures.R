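test_that("edge distance is the reciprocal transition count", {
  expect_equal(edge_distance(3), 1 / 3)
  expect_equal(edge_distance(1), 1)
  expect_equal(edge_distance(0), Inf)
  expect_error(edge_distance(-1), "negative")
})

test_that("shortest scanning distances on the worked network", {
  net <- worked_net()
  d <- shortest_distances(net, "B")
  expect_equal(d$distance[d$aoi == "E"], 2 / 3)  # min(direct 1, via A 1/3 + 1/3)
  expect_equal(d$distance[d$aoi == "A"], 1 / 3)
  expect_equal(d$distance[d$aoi == "C"], 5 / 6)  # B -> A -> C
  expect_equal(d$distance[d$aoi == "B"], 0)
  expect_error(shortest_distances(net, "Z"), "not a vertex")
})

test_that("shortest-path counting handles ties, intermediates, and unreachable pairs", {
  # two equal-length parallel routes K -> L: direct (weight 1) and K -> J -> L (2, 2)
  tie <- make_net(matrix(c(0, 2, 1,
                           0, 0, 2,
                           0, 0, 0), 3, 3, byrow = TRUE,
                         dimnames = list(c("K", "J", "L"), c("K", "J", "L"))))
  res <- count_shortest_paths(tie, "K", "L")
  expect_equal(res$n_paths, 2)
  expect_equal(res$through$n_paths[res$through$aoi == "J"], 1)

  net <- worked_net()
  ec <- count_shortest_paths(net, "E", "C")
  expect_equal(ec$n_paths, 1)
  expect_equal(ec$through$n_paths[ec$through$aoi == "A"], 1)

  oneway <- make_net(matrix(c(0, 1, 0, 0), 2, 2, byrow = TRUE,
                            dimnames = list(c("A", "B"), c("A", "B"))))
  expect_equal(count_shortest_paths(oneway, "B", "A")$n_paths, 0)
  expect_error(count_shortest_paths(net, "B", "B"), "distinct")
})

test_that("degree measures are matrix margins on the worked network", {
  net <- worked_net()
  expect_equal(aoi_indegree(net, "B"), 4)
  expect_equal(aoi_indegree(demo_dnet()$networks[[2]], "B"), 3)
  expect_equal(aoi_outdegree(net, "A"), 8)
  expect_equal(aoi_indegree(net, "A"), 8)  # interval 1 is a closed walk
  noin <- make_net(matrix(c(0, 1, 0, 0), 2, 2, byrow = TRUE,
                          dimnames = list(c("A", "B"), c("A", "B"))))
  expect_equal(aoi_indegree(noin, "A"), 0)
  expect_equal(aoi_outdegree(noin, "B"), 0)
})

test_that("closeness sums reciprocal shortest distances; isolation gives zero", {
  net <- worked_net()
  expect_equal(aoi_closeness(net, "A"), 8)       # 1/(1/3) + 1/(1/2) + 1/(1/3)
  expect_equal(aoi_closeness(net, "B"), 5.7)     # 3 + 1.5 + 1.2
  iso <- make_net(matrix(c(0, 1, 0, 1, 0, 0, 0, 0, 0), 3, 3, byrow = TRUE,
                         dimnames = list(c("A", "B", "Z"), c("A", "B", "Z"))))
  expect_equal(aoi_closeness(iso, "Z"), 0)
})

test_that("betweenness counts bridging shortest paths", {
  # directed star: periphery only connected through the center
  p <- 4
  labs <- c("S", LETTERS[1:p])
  star <- matrix(0, p + 1, p + 1, dimnames = list(labs, labs))
  star[1, -1] <- 1
  star[-1, 1] <- 1
  expect_equal(aoi_betweenness(make_net(star), "S"), p * (p - 1))

  net <- worked_net()
  expect_equal(aoi_betweenness(net, "A"), 6)  # A carries every other-pair shortest path
  expect_equal(aoi_betweenness(net, "B"), 0)
})

test_that("the printed worked values for B are not what the equations yield", {
  # The distance equations, evaluated independently by exhaustive path
  # enumeration, give closeness 5.7 and betweenness 0 for B in interval 1;
  # betweenness is bounded by (m-1)(m-2) = 6 on a 4-vertex network, so a
  # value of 8 is unattainable under the stated definition.
  net <- worked_net()
  oracle <- oracle_measures(net$counts)
  b <- match("B", net$states)
  expect_equal(oracle$closeness[b], 5.7)
  expect_equal(oracle$betweenness[b], 0)
  expect_equal(aoi_closeness(net, "B"), oracle$closeness[b])
  expect_equal(aoi_betweenness(net, "B"), oracle$betweenness[b])
  m <- length(net$states)
  expect_equal((m - 1) * (m - 2), 6)
})

test_that("distances, path counts, and measures agree with exhaustive enumeration", {
  withr::with_seed(123, {
    for (rep in 1:40) {
      counts <- rand_counts(sample(2:6, 1))
      net <- make_net(counts)
      m <- nrow(counts)
      D <- ifelse(counts > 0, 1 / counts, Inf)
      diag(D) <- Inf
      for (k in seq_len(m)) {
        o <- oracle_paths(D, k)
        got <- shortest_distances(net, net$states[k])
        expect_equal(got$distance, o$dist, tolerance = 1e-12)
        others <- setdiff(seq_len(m), k)
        l <- others[sample.int(length(others), 1)]
        cp <- count_shortest_paths(net, net$states[k], net$states[l])
        expect_equal(cp$n_paths, o$n_paths[l])
        expect_equal(cp$through$n_paths,
                     o$through[l, -c(k, l)], ignore_attr = TRUE)
      }
      om <- oracle_measures(counts)
      expect_equal(purrr::map_dbl(net$states, ~ aoi_closeness(net, .x)), om$closeness)
      expect_equal(purrr::map_dbl(net$states, ~ aoi_betweenness(net, .x)), om$betweenness)
    }
  })
})

test_that("distances agree with an independent graph library", {
  skip_if_not_installed("igraph")
  withr::with_seed(5, {
    for (rep in 1:15) {
      counts <- rand_counts(sample(3:6, 1))
      net <- make_net(counts)
      Dm <- ifelse(counts > 0, 1 / counts, 0)
      g <- igraph::graph_from_adjacency_matrix(Dm, mode = "directed", weighted = TRUE)
      ref <- igraph::distances(g, mode = "out")
      for (k in seq_len(nrow(counts))) {
        expect_equal(shortest_distances(net, net$states[k])$distance,
                     unname(ref[k, ]), tolerance = 1e-12)
      }
    }
  })
})

test_that("measure tables cover every interval-vertex pair deterministically", {
  dnet <- demo_dnet()
  mt <- measure_table(dnet)
  expect_equal(sort(unique(mt$interval)), 1:4)
  expect_true(all(mt$betweenness <=
                    (purrr::map_int(mt$interval, ~ length(dnet$networks[[.x]]$states)) - 1) *
                    (purrr::map_int(mt$interval, ~ length(dnet$networks[[.x]]$states)) - 2)))
  # per interval, the column sums reproduce the degree columns
  for (net in dnet$networks) {
    sub <- mt[mt$interval == net$window$index, ]
    expect_equal(sub$indegree, unname(colSums(net$counts)))
    expect_equal(sub$outdegree, unname(rowSums(net$counts)))
    expect_equal(sum(sub$indegree), sum(net$counts))
  }

  lone <- interval_network(aoi_seq("A", window = list(index = 1), collapsed = TRUE))
  mt1 <- measure_table(assemble_dnet(list(lone)))
  expect_equal(nrow(mt1), 1)
  expect_equal(mt1$indegree + mt1$outdegree + mt1$closeness + mt1$betweenness, 0)
})

test_that("an isolated extra vertex changes no existing measure", {
  counts <- worked_net()$counts
  m <- nrow(counts)
  bigger <- rbind(cbind(counts, Z = 0), Z = 0)
  colnames(bigger) <- rownames(bigger) <- c(colnames(counts), "Z")
  net0 <- make_net(counts)
  net1 <- make_net(bigger)
  for (s in colnames(counts)) {
    expect_equal(aoi_indegree(net1, s), aoi_indegree(net0, s))
    expect_equal(aoi_closeness(net1, s), aoi_closeness(net0, s))
    expect_equal(aoi_betweenness(net1, s), aoi_betweenness(net0, s))
  }
})

test_that("scaling all weights scales closeness and fixes betweenness", {
  withr::with_seed(31, {
    for (rep in 1:10) {
      counts <- rand_counts(sample(3:6, 1))
      net1 <- make_net(counts)
      net3 <- make_net(counts * 3)
      for (s in net1$states) {
        expect_equal(aoi_closeness(net3, s), 3 * aoi_closeness(net1, s))
        expect_equal(aoi_betweenness(net3, s), aoi_betweenness(net1, s))
      }
    }
  })
})
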