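#' Neighbor-joining tree from a distance matrix
#'
#' Standard agglomerative NJ with the Q-criterion. Ties in Q are broken
#' deterministically by the lexicographically smallest pair of subtree
#' representative labels (the smallest leaf label inside each subtree).
#' Negative branch lengths are clamped to zero; the number clamped is
#' reported via [message()]. On an additive matrix the generating topology
#' and branch lengths are recovered exactly (up to floating point).
#'
#' @param dm a `phylo_dist` with >= 3 labels.
#' @return An unrooted [ape::read.tree()] `phylo` object with branch
#'   lengths.
#' @export
nj_tree <- function(dm) {
  stopifnot(inherits(dm, "phylo_dist"))
  labels <- dm$labels
  m <- length(labels)
  if (m < 3L) stop("need at least 3 labels")
  D <- dm$values
  if (max(abs(D - t(D))) > 1e-8) stop("distance matrix must be symmetric")
  frag <- labels          # newick fragment per active node
  rep_lab <- labels       # smallest leaf label per subtree, for tie-breaks
  clamped <- 0L
  fmt <- function(x) sprintf("%.15g", x)
  clamp <- function(x) {
    if (x < 0) { clamped <<- clamped + 1L; 0 } else x
  }
  while (m > 3L) {
    rs <- rowSums(D)
    Q <- (m - 2) * D - outer(rs, rs, "+")
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q <= qmin + 1e-12, arr.ind = TRUE)
    cand <- cand[cand[, 1L] < cand[, 2L], , drop = FALSE]
    lo <- pmin(rep_lab[cand[, 1L]], rep_lab[cand[, 2L]])
    hi <- pmax(rep_lab[cand[, 1L]], rep_lab[cand[, 2L]])
    pick <- order(lo, hi)[1L]
    i <- cand[pick, 1L]; j <- cand[pick, 2L]
    dij <- D[i, j]
    li <- clamp(dij / 2 + (rs[i] - rs[j]) / (2 * (m - 2)))
    lj <- clamp(dij - (dij / 2 + (rs[i] - rs[j]) / (2 * (m - 2))))
    newfrag <- paste0("(", frag[i], ":", fmt(li), ",",
                      frag[j], ":", fmt(lj), ")")
    dnew <- (D[i, ] + D[j, ] - dij) / 2
    keep <- setdiff(seq_len(m), c(i, j))
    D <- rbind(cbind(D[keep, keep, drop = FALSE], dnew[keep]),
               c(dnew[keep], 0))
    frag <- c(frag[keep], newfrag)
    rep_lab <- c(rep_lab[keep], min(rep_lab[c(i, j)]))
    m <- m - 1L
  }
  l1 <- clamp((D[1, 2] + D[1, 3] - D[2, 3]) / 2)
  l2 <- clamp((D[1, 2] + D[2, 3] - D[1, 3]) / 2)
  l3 <- clamp((D[1, 3] + D[2, 3] - D[1, 2]) / 2)
  newick <- paste0("(", frag[1L], ":", fmt(l1), ",",
                   frag[2L], ":", fmt(l2), ",",
                   frag[3L], ":", fmt(l3), ");")
  if (clamped > 0L)
    message("nj_tree: clamped ", clamped, " negative branch length(s) to 0")
  tr <- ape::read.tree(text = newick)
  attr(tr, "clamped") <- clamped
  tr
}

# Topological tip-to-tip edge counts of a (binary, unrooted) phylo.
topo_dist <- function(tree) {
  t2 <- tree
  t2$edge.length <- rep(1, nrow(t2$edge))
  ape::cophenetic.phylo(t2)
}

#' Balanced (Pauplin) tree length
#'
#' The balanced minimum-evolution objective for a binary unrooted topology:
#' sum over leaf pairs of d(i, j) * 2^(1 - t(i, j)), where t(i, j) is the
#' number of edges on the path between the leaves (equivalently 2^(-
#' internal nodes on the path)). For the 3-leaf star this is
#' (d12 + d13 + d23) / 2.
#'
#' @param tree a `phylo` whose tips match the matrix labels; rooted input
#'   is unrooted first.
#' @param dm a `phylo_dist`.
#' @return Non-negative balanced length.
#' @export
pauplin_length <- function(tree, dm) {
  stopifnot(inherits(dm, "phylo_dist"))
  tree <- ape::unroot(tree)
  if (!setequal(tree$tip.label, dm$labels))
    stop("tree leaves and matrix labels differ")
  ntip <- length(tree$tip.label)
  degs <- tabulate(c(tree$edge), nbins = ntip + tree$Nnode)
  if (any(degs[-seq_len(ntip)] != 3) && ntip > 3L)
    stop("pauplin_length requires a binary unrooted topology")
  Tm <- topo_dist(tree)[dm$labels, dm$labels]
  W <- 2^(1 - Tm)
  diag(W) <- 0
  sum(dm$values * W) / 2
}

# Ordinary-least-squares branch lengths for a fixed topology; negative
# estimates are clamped to zero.
ols_branch_lengths <- function(tree, dm) {
  tree <- ape::unroot(tree)
  ntip <- length(tree$tip.label)
  Dm <- dm$values[tree$tip.label, tree$tip.label]
  ned <- nrow(tree$edge)
  ekey <- new.env(parent = emptyenv())
  for (e in seq_len(ned)) {
    assign(paste(tree$edge[e, 1L], tree$edge[e, 2L]), e, envir = ekey)
    assign(paste(tree$edge[e, 2L], tree$edge[e, 1L]), e, envir = ekey)
  }
  pairs <- utils::combn(ntip, 2)
  A <- matrix(0, ncol(pairs), ned)
  y <- numeric(ncol(pairs))
  for (p in seq_len(ncol(pairs))) {
    np <- ape::nodepath(tree, pairs[1L, p], pairs[2L, p])
    for (q in seq_len(length(np) - 1L))
      A[p, get(paste(np[q], np[q + 1L]), envir = ekey)] <- 1
    y[p] <- Dm[pairs[1L, p], pairs[2L, p]]
  }
  bl <- qr.coef(qr(A), y)
  bl[is.na(bl)] <- 0
  nneg <- sum(bl < 0)
  if (nneg > 0L)
    message("ols_branch_lengths: clamped ", nneg,
            " negative branch length(s) to 0")
  tree$edge.length <- pmax(bl, 0)
  tree
}

#' Balanced minimum-evolution refinement by nearest-neighbor interchange
#'
#' Greedy hill climb: in each round all NNI neighbors of the current
#' topology are scored with [pauplin_length()] and the best strictly
#' improving neighbor is accepted; the search stops when no interchange
#' improves the balanced length or `max_rounds` is reached. If the
#' topology changed, branch lengths are re-estimated by ordinary least
#' squares (negatives clamped to zero); otherwise the input tree is
#' returned unchanged.
#'
#' @param tree starting `phylo` (typically [nj_tree()] output).
#' @param dm a `phylo_dist` over the same labels.
#' @param max_rounds maximum number of accepted interchanges (default 50).
#' @return A `phylo` whose balanced length is <= that of the input.
#' @export
bme_refine <- function(tree, dm, max_rounds = 50) {
  stopifnot(inherits(dm, "phylo_dist"))
  best <- ape::unroot(tree)
  best_len <- pauplin_length(best, dm)
  changed <- FALSE
  for (round in seq_len(max_rounds)) {
    nbrs <- phangorn::nni(best)
    lens <- vapply(nbrs, pauplin_length, numeric(1), dm = dm)
    if (min(lens) < best_len - 1e-12) {
      best <- nbrs[[which.min(lens)]]
      best_len <- min(lens)
      changed <- TRUE
    } else break
  }
  if (!changed) return(tree)
  ols_branch_lengths(best, dm)
}

# Tip index sets below each node of a phylo (postorder accumulation).
clade_tip_sets <- function(tree) {
  ntip <- length(tree$tip.label)
  res <- vector("list", ntip + tree$Nnode)
  for (i in seq_len(ntip)) res[[i]] <- i
  eo <- ape::reorder.phylo(tree, "postorder")$edge
  for (e in seq_len(nrow(eo)))
    res[[eo[e, 1L]]] <- c(res[[eo[e, 1L]]], res[[eo[e, 2L]]])
  res
}

#' Quartet-based (REQ) branch support from a distance matrix
#'
#' For each internal branch splitting the leaves into sides A | B, a
#' quartet a1, a2 | b1, b2 (a's from A, b's from B) supports the branch
#' when d(a1,a2) + d(b1,b2) is strictly smaller than both cross pairings;
#' ties count as non-supporting. Support is the supporting fraction over
#' all quartets of the branch, enumerated exhaustively when their number
#' is at most `max_quartets` and otherwise estimated from `max_quartets`
#' uniformly sampled quartets. Additive matrices give support 1 on every
#' internal branch (four-point condition); an all-equal matrix gives 0.
#'
#' @param tree a `phylo` with >= 4 leaves matching the matrix labels.
#' @param dm a `phylo_dist`.
#' @param max_quartets exhaustive-enumeration cutoff / sample size
#'   (default 10000).
#' @param seed RNG seed for quartet sampling.
#' @return The tree with `node.label` set to the support of the branch
#'   above each internal node ("" at the basal trifurcation) and an
#'   attribute `req_support`: data.frame with columns `node`, `n_quartets`,
#'   `sampled`, `support`.
#' @export
req_support <- function(tree, dm, max_quartets = 10000, seed = 1L) {
  stopifnot(inherits(dm, "phylo_dist"))
  tree <- ape::unroot(tree)
  if (!setequal(tree$tip.label, dm$labels))
    stop("tree leaves and matrix labels differ")
  ntip <- length(tree$tip.label)
  Dm <- dm$values[tree$tip.label, tree$tip.label]
  root <- setdiff(tree$edge[, 1L], tree$edge[, 2L])[1L]
  labels <- rep("", tree$Nnode)
  rows <- list()
  if (ntip >= 4L) {
    tipsets <- clade_tip_sets(tree)
    internal_children <- tree$edge[tree$edge[, 2L] > ntip, 2L]
    withr::with_seed(seed, {
      for (v in internal_children) {
        A <- tipsets[[v]]
        B <- setdiff(seq_len(ntip), A)
        nq <- choose(length(A), 2) * choose(length(B), 2)
        if (nq <= max_quartets) {
          pa <- utils::combn(A, 2)
          pb <- utils::combn(B, 2)
          ia1 <- rep(pa[1L, ], times = ncol(pb))
          ia2 <- rep(pa[2L, ], times = ncol(pb))
          ib1 <- rep(pb[1L, ], each = ncol(pa))
          ib2 <- rep(pb[2L, ], each = ncol(pa))
          sampled <- FALSE
        } else {
          pick2 <- function(set, n)
            vapply(seq_len(n), function(z) sample(set, 2L), integer(2))
          pa <- pick2(A, max_quartets)
          pb <- pick2(B, max_quartets)
          ia1 <- pa[1L, ]; ia2 <- pa[2L, ]
          ib1 <- pb[1L, ]; ib2 <- pb[2L, ]
          sampled <- TRUE
        }
        within <- Dm[cbind(ia1, ia2)] + Dm[cbind(ib1, ib2)]
        cross1 <- Dm[cbind(ia1, ib1)] + Dm[cbind(ia2, ib2)]
        cross2 <- Dm[cbind(ia1, ib2)] + Dm[cbind(ia2, ib1)]
        supp <- mean(within < pmin(cross1, cross2))
        labels[v - ntip] <- sprintf("%.2f", supp)
        rows[[length(rows) + 1L]] <-
          data.frame(node = v, n_quartets = length(within),
                     sampled = sampled, support = supp)
      }
    })
  }
  labels[root - ntip] <- ""
  tree$node.label <- labels
  attr(tree, "req_support") <- if (length(rows) > 0L)
    do.call(rbind, rows)
  else
    data.frame(node = integer(), n_quartets = integer(),
               sampled = logical(), support = numeric())
  tree
}

#' Write a support-annotated tree in Newick format
#'
#' Branch lengths are rounded to 6 decimals; REQ supports (node labels)
#' stay as 2-decimal strings in \[0, 1\].
#'
#' @param tree a `phylo` (e.g. from [req_support()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_support_tree <- function(tree, path) {
  if (!is.null(tree$edge.length))
    tree$edge.length <- round(tree$edge.length, 6)
  ape::write.tree(tree, file = path)
  invisible(path)
}
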