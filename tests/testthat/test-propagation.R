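test_that("hub_degrees ranks by degree with lexicographic ties", {
  star <- build_network(data.frame(rep("hub", 4), paste0("leaf", 1:4)))
  expect_equal(hub_degrees(star, "hub"),
               data.frame(node = "hub", degree = 4L))

  net <- gen_network("erdos_renyi", n = 80, p = 0.08, seed = 5)
  adj <- network_adjacency(net)
  seeds <- net$nodes[c(3, 10, 20, 40, 70)]
  got <- hub_degrees(net, seeds)
  expect_equal(got$degree[match(seeds, got$node)],
               unname(lengths(adj[seeds])))
  expect_true(all(diff(got$degree) <= 0))

  got <- hub_degrees(net, c("zzz", seeds))
  expect_equal(got$degree[got$node == "zzz"], 0L)
})

test_that("degree_stats reproduces hand-computed and brute-force moments", {
  star3 <- build_network(data.frame(rep("c", 3), paste0("l", 1:3)))
  st <- degree_stats(star3)  # degrees 3,1,1,1
  expect_equal(st$mean_degree, 1.5)
  expect_equal(st$second_moment, 3)
  expect_equal(st$alpha_paper, 2)
  expect_equal(st$branching, 1)
  expect_equal(st$prefactor, 2)

  # k-regular: branching is exactly k - 1
  for (k in c(3L, 4L)) {
    g <- withr::with_seed(60 + k, igraph::sample_k_regular(40, k))
    el <- igraph::as_edgelist(g)
    net <- build_network(data.frame(paste0("n", el[, 1]),
                                    paste0("n", el[, 2])))
    expect_equal(degree_stats(net)$branching, k - 1)
  }

  net <- gen_network("erdos_renyi", n = 500, p = 0.02, seed = 9)
  st <- degree_stats(net)
  deg <- as.numeric(network_degrees(net))
  m1 <- sum(deg) / length(deg)
  m2 <- sum(deg * deg) / length(deg)
  expect_equal(st$mean_degree, m1)
  expect_equal(st$second_moment, m2)
  expect_gte(st$second_moment, st$mean_degree^2)  # Jensen

  expect_error(degree_stats(build_network(NULL)), "no edges")
})

test_that("shell_decomposition matches trees and the shortest-path oracle", {
  path <- build_network(data.frame(c("A", "B"), c("B", "C")))
  sd <- shell_decomposition(path, "A")
  expect_equal(sd$shells, list("A", "B", "C"))

  tree <- gen_network("bary_tree", b = 2, depth = 5, seed = 1)
  sd <- shell_decomposition(tree, attr(tree, "root"), r_max = 8)
  expect_equal(sd$sizes, as.integer(2^(0:5)))

  net <- gen_network("erdos_renyi", n = 200, p = 0.03, seed = 13)
  seed_node <- net$nodes[5]
  sd <- shell_decomposition(net, seed_node, r_max = 30)
  d <- oracle_bfs_distances(net, seed_node)
  for (r in seq_along(sd$shells))
    expect_equal(sort(sd$shells[[r]]), sort(names(d)[d == r - 1]))
  expect_equal(sum(sd$sizes), sum(is.finite(d)))

  expect_error(shell_decomposition(net, "absent"), "not in network")
})

test_that("shells partition the reachable set on random graphs", {
  for (i in 1:20) {
    net <- gen_network("erdos_renyi", n = 30 + 10 * i, p = 2 / (30 + 10 * i),
                       seed = 200 + i)
    s <- net$nodes[1]
    sd <- shell_decomposition(net, s, r_max = 100)
    all_nodes <- unlist(sd$shells)
    expect_equal(anyDuplicated(all_nodes), 0L)
    d <- oracle_bfs_distances(net, s)
    expect_setequal(all_nodes, names(d)[is.finite(d)])
    # every node in S(r) has a neighbor in S(r-1)
    adj <- network_adjacency(net)
    for (r in seq_along(sd$shells)[-1])
      for (v in sd$shells[[r]])
        expect_true(any(adj[[v]] %in% sd$shells[[r - 1]]))
  }
})

test_that("propagation_profile normalizes shells and fits the rise", {
  fake <- structure(list(seed = "s",
                         shells = list("s", letters[1:2], letters[3:6],
                                       letters[7:14], LETTERS[1:4], "z"),
                         sizes = c(1L, 2L, 4L, 8L, 4L, 1L)),
                    class = "shell_decomposition")
  pr <- propagation_profile(fake)
  expect_equal(pr$d_of_r, c(0.05, 0.10, 0.20, 0.40, 0.20, 0.05))
  expect_equal(pr$r_s, 3L)
  expect_equal(pr$growth_rate, log(2), tolerance = 1e-12)

  # uniform path shells: first-maximum rule gives r_s = 0, slope undefined
  flat <- structure(list(seed = "a", shells = list("a", "b", "c"),
                         sizes = c(1L, 1L, 1L)),
                    class = "shell_decomposition")
  pf <- propagation_profile(flat)
  expect_equal(pf$d_of_r, rep(1 / 3, 3))
  expect_equal(pf$r_s, 0L)
  expect_true(is.na(pf$growth_rate))

  # ternary tree from the root: shell growth is exactly 3^r
  tree <- gen_network("bary_tree", b = 3, depth = 6, seed = 1)
  pr <- propagation_profile(shell_decomposition(tree, attr(tree, "root"),
                                                r_max = 8))
  expect_equal(pr$growth_rate, log(3), tolerance = 0.05)

  lone <- suppressWarnings(seed_network(build_network(data.frame("x", "y")),
                                        c("x", "zz")))
  pz <- propagation_profile(shell_decomposition(lone, "zz"))
  expect_true(pz$degenerate)
  expect_equal(pz$d_of_r, 1)
  expect_equal(pz$r_s, 0L)
})

test_that("saturation_radius is the first argmax and permutation-stable", {
  expect_equal(saturation_radius(c(0.05, 0.1, 0.2, 0.4, 0.2, 0.05)), 3L)
  expect_equal(saturation_radius(rep(0.2, 5)), 0L)
  withr::local_seed(77)
  for (i in 1:100) {
    n <- sample(3:12, 1)
    peak <- sample(n, 1)
    x <- c(sort(stats::runif(peak - 1)), 1,
           rev(sort(stats::runif(n - peak))))
    brute <- which(x == max(x))[1L] - 1L
    expect_equal(saturation_radius(x), brute)
    # moving the maximum earlier never increases r_s
    j <- sample(seq_len(peak), 1)
    y <- x
    y[c(j, peak)] <- y[c(peak, j)]
    expect_lte(saturation_radius(y), saturation_radius(x))
  }
})

test_that("model_profile follows the excess-degree branching factor", {
  st <- structure(list(mean_degree = 1.5, second_moment = 3,
                       alpha_paper = 2, branching = 1, prefactor = 2,
                       n_nodes = 4L), class = "degree_stats")
  expect_equal(model_profile(st, 0:2), c(2, 2, 2))

  # regular graph: consecutive model ratio is exactly k - 1
  g <- withr::with_seed(3, igraph::sample_k_regular(30, 4))
  el <- igraph::as_edgelist(g)
  net <- build_network(data.frame(paste0("n", el[, 1]),
                                  paste0("n", el[, 2])))
  st <- degree_stats(net)
  mp <- model_profile(st, 0:4)
  expect_equal(mp[-1] / mp[-5], rep(3, 4))

  st$branching <- 0
  expect_error(model_profile(st, 0:2), "branching")

  # sparse ER: empirical shell growth tracks the moment-based branching
  net <- gen_network("erdos_renyi", n = 2000, p = 0.005, seed = 42)
  st <- degree_stats(net)
  ratios <- vapply(net$nodes[1:5], function(s) {
    sd <- shell_decomposition(net, s, r_max = 3)
    sd$sizes[3] / sd$sizes[2]
  }, numeric(1))
  expect_equal(mean(ratios), st$branching, tolerance = 0.25)
})

test_that("analyze_seeds computes independent, normalized profiles", {
  net <- gen_network("erdos_renyi", n = 120, p = 0.05, seed = 21)
  seeds <- net$nodes[c(1, 5, 9, 9)]  # duplicated seed on purpose
  profs <- analyze_seeds(net, seeds)
  expect_length(profs, 4L)
  for (p in profs) expect_equal(sum(p$d_of_r), 1)
  expect_equal(profs[[3]]$d_of_r, profs[[4]]$d_of_r)
  single <- propagation_profile(shell_decomposition(net, seeds[2], 8))
  expect_equal(profs[[2]]$d_of_r, single$d_of_r)

  summ <- propagation_summary(profs, net)
  expect_equal(nrow(summ), 4L)
  expect_equal(summ$degree,
               unname(network_degrees(net)[summ$seed]))

  got <- analyze_seeds(net, c(seeds[1], "missing"))
  expect_true(got[[2]]$degenerate)
  expect_equal(got[[2]]$d_of_r, 1)
})
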