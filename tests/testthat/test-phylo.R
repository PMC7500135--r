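test_that("nj_tree recovers additive quartets exactly", {
  truth <- ape::read.tree(
    text = "((A:0.10,B:0.20):0.05,(C:0.15,D:0.25):0.07);")
  dm <- additive_matrix(truth)
  tr <- nj_tree(dm)
  expect_equal(phangorn::RF.dist(ape::unroot(truth), tr), 0)
  # additive input: path lengths reproduce the matrix to 1e-9
  got <- ape::cophenetic.phylo(tr)[dm$labels, dm$labels]
  expect_equal(got, dm$values, tolerance = 1e-9)
})

test_that("nj_tree on 3 taxa gives the closed-form star", {
  D <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- nj_tree(propmash:::new_phylo_dist(c("a", "b", "c"), D))
  bl <- stats::setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(bl[["a"]], (3 + 4 - 5) / 2)
  expect_equal(bl[["b"]], (3 + 5 - 4) / 2)
  expect_equal(bl[["c"]], (4 + 5 - 3) / 2)
})

test_that("nj_tree recovers random additive topologies up to 8 taxa", {
  for (ntip in 4:8) {
    truth <- random_tree(ntip, seed = 500 + ntip)
    dm <- additive_matrix(truth)
    tr <- nj_tree(dm)
    expect_equal(phangorn::RF.dist(truth, tr), 0)
    got <- ape::cophenetic.phylo(tr)[dm$labels, dm$labels]
    expect_equal(got, dm$values, tolerance = 1e-9)
  }
  D <- matrix(stats::runif(16), 4, dimnames = list(letters[1:4],
                                                   letters[1:4]))
  diag(D) <- 0
  bad <- structure(list(labels = letters[1:4], values = D),
                   class = "phylo_dist")  # bypasses constructor checks
  expect_error(nj_tree(bad), "symmetric")
})

test_that("pauplin_length matches hand expansion and the BFS oracle", {
  labs <- c("a", "b", "c")
  D <- matrix(c(0, 1, 2, 1, 0, 3, 2, 3, 0), 3,
              dimnames = list(labs, labs))
  dm <- propmash:::new_phylo_dist(labs, D)
  star <- ape::read.tree(text = "(a:1,b:1,c:1);")
  expect_equal(pauplin_length(star, dm), (1 + 2 + 3) / 2)
  zero <- propmash:::new_phylo_dist(labs, matrix(0, 3, 3,
                                                 dimnames = list(labs, labs)))
  expect_equal(pauplin_length(star, zero), 0)

  for (ntip in 4:5) {
    for (s in 1:5) {
      tr <- random_tree(ntip, seed = 900 + 10 * ntip + s)
      dm <- additive_matrix(random_tree(ntip, seed = 700 + s))
      expect_equal(pauplin_length(tr, dm), oracle_pauplin(tr, dm))
    }
  }
})

test_that("bme_refine is monotone and repairs a swapped cherry", {
  # already optimal: returned unchanged
  truth <- random_tree(6, seed = 31)
  dm <- additive_matrix(truth)
  expect_identical(bme_refine(truth, dm), truth)

  # swap two tips across cherries and ask refinement to undo it
  perturbed <- truth
  i <- which(perturbed$tip.label == "t01")
  j <- which(perturbed$tip.label == "t03")
  perturbed$tip.label[c(i, j)] <- perturbed$tip.label[c(j, i)]
  if (phangorn::RF.dist(perturbed, truth) > 0) {
    fixed <- bme_refine(perturbed, dm)
    expect_equal(phangorn::RF.dist(fixed, truth), 0)
    expect_lt(pauplin_length(fixed, dm), pauplin_length(perturbed, dm))
  }

  # balanced length never increases, random matrices
  withr::local_seed(61)
  for (rep in 1:20) {
    ntip <- sample(5:8, 1)
    pts <- matrix(stats::runif(ntip * 3), ntip)
    D <- as.matrix(stats::dist(pts))
    labs <- sprintf("t%02d", seq_len(ntip))
    dimnames(D) <- list(labs, labs)
    dm <- propmash:::new_phylo_dist(labs, D)
    start <- random_tree(ntip, seed = 1000 + rep)
    refined <- bme_refine(start, dm)
    expect_lte(pauplin_length(refined, dm),
               pauplin_length(start, dm) + 1e-12)
  }
})

test_that("req_support is 1 on additive data, 0 on all-equal distances", {
  truth <- random_tree(7, seed = 12)
  dm <- additive_matrix(truth)
  tr <- req_support(truth, dm)
  supp <- attr(tr, "req_support")
  expect_gt(nrow(supp), 0)
  expect_equal(supp$support, rep(1, nrow(supp)))

  labs <- sprintf("t%02d", 1:6)
  E <- matrix(1, 6, 6, dimnames = list(labs, labs))
  diag(E) <- 0
  dme <- propmash:::new_phylo_dist(labs, E)
  tre <- nj_tree(dme)
  se <- attr(req_support(tre, dme), "req_support")
  expect_equal(se$support, rep(0, nrow(se)))

  star <- ape::read.tree(text = "(t01:1,t02:1,t03:1);")
  s3 <- req_support(star, propmash:::new_phylo_dist(
    labs[1:3], matrix(0, 3, 3, dimnames = list(labs[1:3], labs[1:3]))))
  expect_equal(nrow(attr(s3, "req_support")), 0L)
})

test_that("sampled REQ supports track the exhaustive enumeration", {
  ntip <- 24
  truth <- random_tree(ntip, seed = 250)
  dm <- additive_matrix(truth)
  # perturb distances so supports are strictly between 0 and 1
  withr::local_seed(251)
  noise <- matrix(stats::runif(ntip^2, -0.4, 0.4), ntip)
  noisy <- dm$values * (1 + noise)
  noisy <- (noisy + t(noisy)) / 2
  diag(noisy) <- 0
  dmn <- propmash:::new_phylo_dist(dm$labels, noisy)
  exact <- attr(req_support(truth, dmn, max_quartets = 1e6), "req_support")
  expect_false(any(exact$sampled))
  sampled <- attr(req_support(truth, dmn, max_quartets = 2000, seed = 5),
                  "req_support")
  expect_true(any(sampled$sampled))
  expect_lt(max(abs(sampled$support - exact$support)), 0.05)
})

test_that("supports are invariant under leaf-label permutation", {
  truth <- random_tree(6, seed = 77)
  dm <- additive_matrix(random_tree(6, seed = 78))
  base <- attr(req_support(truth, dm), "req_support")
  perm <- sample(seq_along(dm$labels))
  dmp <- propmash:::new_phylo_dist(dm$labels[perm],
                                   dm$values[perm, perm])
  permd <- attr(req_support(truth, dmp), "req_support")
  expect_equal(permd$support, base$support)
})

test_that("support-annotated Newick output parses with labels in [0,1]", {
  truth <- random_tree(6, seed = 90)
  dm <- additive_matrix(truth)
  tr <- req_support(bme_refine(nj_tree(dm), dm), dm)
  f <- withr::local_tempfile(fileext = ".nwk")
  write_support_tree(tr, f)
  back <- ape::read.tree(f)
  vals <- suppressWarnings(as.numeric(back$node.label))
  vals <- vals[!is.na(vals)]
  expect_true(all(vals >= 0 & vals <= 1))
  expect_equal(phangorn::RF.dist(back, truth), 0)
})
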