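#' Designated hub proteins of the aerotolerance-operon network
#'
#' The eight operon proteins with their reported interaction degrees
#' (55, 53, 39, 30, 29, 23, 22, 21), used as seed nodes throughout the
#' propagation examples. Note that this reported profile is *not*
#' realizable together with the reported 78-node / 216-edge network size
#' in any simple graph (see [bat_fixture_degrees()]), so the packaged
#' fixture reproduces it only in part.
#'
#' @return Named integer vector of hub degrees as reported.
#' @export
bat_hub_degrees <- function() {
  c(BatD = 55L, Hypo = 53L, BatE = 39L, BatB = 30L, BatA = 29L,
    BatC = 23L, MoxR = 22L, PA3071 = 21L)
}

#' Feasible hub-degree profile of the packaged network fixture
#'
#' The reported hub degrees sum to 272, but in a simple graph at most
#' 2 * choose(8, 2) = 56 of that sum can come from hub-hub edges, forcing
#' at least 216 hub-nonhub edges plus 28 hub-hub edges — at least 244
#' edges, contradicting the reported 216. The packaged fixture therefore
#' keeps the attainable headline constraints exactly (78 nodes, 216 edges,
#' top hub BatD at degree 55) and reduces the seven lower hub degrees
#' minimally, preserving the strict reported ranking, to the feasibility
#' boundary (hub degree sum 244): 55, 47, 34, 26, 25, 20, 19, 18.
#'
#' @return Named integer vector of the fixture's actual hub degrees.
#' @export
bat_fixture_degrees <- function() {
  c(BatD = 55L, Hypo = 47L, BatE = 34L, BatB = 26L, BatA = 25L,
    BatC = 20L, MoxR = 19L, PA3071 = 18L)
}

# Erdos-Gallai graphicality test for a degree sequence.
is_graphical <- function(degrees) {
  d <- sort(as.integer(degrees), decreasing = TRUE)
  n <- length(d)
  if (sum(d) %% 2L != 0L) return(FALSE)
  if (any(d < 0L) || (n > 0L && d[1L] >= n)) return(FALSE)
  for (k in seq_len(n - 1L)) {
    lhs <- sum(d[seq_len(k)])
    rhs <- k * (k - 1L) + sum(pmin(d[seq(k + 1L, n)], k))
    if (lhs > rhs) return(FALSE)
  }
  TRUE
}

# Deterministic Havel-Hakimi realization of a graphical degree sequence.
havel_hakimi <- function(degrees) {
  res <- as.integer(degrees)
  nodes <- names(degrees)
  n <- length(res)
  if (sum(res) %% 2L != 0L) stop("degree sequence sum is odd")
  if (max(res) >= n) stop("max degree must be < number of nodes")
  ef <- character(0); et <- character(0)
  repeat {
    ord <- order(-res, nodes)
    v <- ord[1L]
    d <- res[v]
    if (d == 0L) break
    targets <- ord[seq(2L, d + 1L)]
    if (any(res[targets] == 0L)) stop("degree sequence is not graphical")
    ef <- c(ef, rep(nodes[v], d))
    et <- c(et, nodes[targets])
    res[v] <- 0L
    res[targets] <- res[targets] - 1L
  }
  data.frame(from = ef, to = et, stringsAsFactors = FALSE)
}

# Degree-preserving randomization by double-edge swaps; proposals creating
# self-loops or parallel edges are rejected. Uses the current RNG stream.
edge_swap_randomize <- function(edges, n_attempts) {
  ef <- edges$from; et <- edges$to
  m <- length(ef)
  ekey <- function(x, y) paste(pmin(x, y), pmax(x, y))
  present <- new.env(hash = TRUE, parent = emptyenv())
  for (k in ekey(ef, et)) assign(k, TRUE, envir = present)
  for (s in seq_len(n_attempts)) {
    ij <- sample.int(m, 2L)
    i <- ij[1L]; j <- ij[2L]
    a <- ef[i]; b <- et[i]; cc <- ef[j]; dd <- et[j]
    if (stats::runif(1) < 0.5) {
      x1 <- a; y1 <- cc; x2 <- b; y2 <- dd
    } else {
      x1 <- a; y1 <- dd; x2 <- b; y2 <- cc
    }
    if (x1 == y1 || x2 == y2) next
    k1 <- ekey(x1, y1); k2 <- ekey(x2, y2)
    if (k1 == k2) next
    if (exists(k1, envir = present) || exists(k2, envir = present)) next
    rm(list = c(ekey(a, b), ekey(cc, dd)), envir = present)
    assign(k1, TRUE, envir = present)
    assign(k2, TRUE, envir = present)
    ef[i] <- x1; et[i] <- y1; ef[j] <- x2; et[j] <- y2
  }
  data.frame(from = ef, to = et, stringsAsFactors = FALSE)
}

#' Seeded random-network generator
#'
#' Generates simple undirected test networks. Supported models:
#' `erdos_renyi` (parameters `n`, `p`), `barabasi_albert` (`n`,
#' `attachment` edges per new node), `configuration` (a `degrees` vector;
#' stub matching with rejection of self-loops and parallel edges, bounded
#' retries), `bary_tree` (full `b`-ary tree of the given `depth`; the root
#' is recorded in the `root` attribute) and `bat_fixture`
#' (see [gen_bat_fixture()]). All models are deterministic for a fixed
#' `seed`; isolated nodes are retained.
#'
#' @param model model name.
#' @param n number of nodes (erdos_renyi, barabasi_albert).
#' @param p edge probability (erdos_renyi).
#' @param attachment edges added per node (barabasi_albert).
#' @param degrees integer degree sequence (configuration); a named vector
#'   fixes the node labels.
#' @param b,depth branching factor and depth (bary_tree).
#' @param seed RNG seed (default 42).
#' @return A `ppi_network`.
#' @export
gen_network <- function(model = c("erdos_renyi", "barabasi_albert",
                                  "configuration", "bary_tree",
                                  "bat_fixture"),
                        n = NULL, p = NULL, attachment = 2, degrees = NULL,
                        b = 2, depth = 4, seed = 42L) {
  model <- match.arg(model)
  if (model == "bat_fixture") return(gen_bat_fixture(seed))
  node_names <- function(n) sprintf("n%0*d", nchar(as.character(n)),
                                    seq_len(n))
  withr::with_seed(seed, {
    if (model == "erdos_renyi") {
      stopifnot(!is.null(n), !is.null(p))
      g <- igraph::sample_gnp(n, p)
      nm <- node_names(n)
      el <- igraph::as_edgelist(g)
      net <- new_network(nodes = nm,
                         edges = data.frame(nm[el[, 1L]], nm[el[, 2L]]))
    } else if (model == "barabasi_albert") {
      stopifnot(!is.null(n))
      g <- igraph::sample_pa(n, m = attachment, directed = FALSE)
      nm <- node_names(n)
      el <- igraph::as_edgelist(g)
      net <- new_network(nodes = nm,
                         edges = data.frame(nm[el[, 1L]], nm[el[, 2L]]))
    } else if (model == "bary_tree") {
      stopifnot(b >= 2, depth >= 1)
      nv <- sum(b^(0:depth))
      g <- igraph::make_tree(nv, children = b, mode = "undirected")
      nm <- node_names(nv)
      el <- igraph::as_edgelist(g)
      net <- new_network(nodes = nm,
                         edges = data.frame(nm[el[, 1L]], nm[el[, 2L]]))
      attr(net, "root") <- nm[1L]
    } else {  # configuration
      stopifnot(!is.null(degrees))
      degrees <- as.integer(degrees)
      nn <- length(degrees)
      if (sum(degrees) %% 2L != 0L)
        stop("infeasible degree sequence: odd sum")
      if (max(degrees) >= nn)
        stop("infeasible degree sequence: max degree >= n")
      nm <- if (!is.null(names(degrees))) names(degrees) else node_names(nn)
      stubs <- rep(nm, degrees)
      ok <- FALSE
      for (try in seq_len(200L)) {
        perm <- sample(stubs)
        a <- perm[seq(1L, length(perm), by = 2L)]
        bb <- perm[seq(2L, length(perm), by = 2L)]
        if (any(a == bb)) next
        if (anyDuplicated(paste(pmin(a, bb), pmax(a, bb)))) next
        ok <- TRUE
        break
      }
      if (!ok)
        stop("configuration-model rejection budget exhausted; ",
             "try a different seed")
      net <- new_network(nodes = nm, edges = data.frame(a, bb))
    }
    net
  })
}

#' Degree-constrained aerotolerance-operon network fixture
#'
#' A synthetic stand-in for the unpublished 78-protein interaction
#' network: exactly 78 nodes and 216 edges, with the eight designated hub
#' proteins at the feasibility-adjusted degree profile of
#' [bat_fixture_degrees()] (top hub BatD at exactly 55; the reported
#' profile itself is unrealizable in a simple graph of this size, see that
#' help page). The remaining 188 degree stubs are spread over 70 synthetic
#' partner proteins (`prot01`..`prot70`, each degree in 1..8) following a
#' truncated geometric distribution repaired to the exact stub total — a
#' heavy-tailed remainder resembling interactome degree data. The graph is
#' realized by a deterministic Havel-Hakimi construction followed by
#' seeded degree-preserving double-edge swaps; non-graphical residual
#' draws fail over to new internal seeds (bounded retries). All fixture
#' constraints are verified before returning; the generator never
#' silently relaxes one.
#'
#' @param seed RNG seed (default 42).
#' @return A `ppi_network` with attribute `hubs` (the named hub-degree
#'   vector actually realized, i.e. [bat_fixture_degrees()]).
#' @export
gen_bat_fixture <- function(seed = 42L) {
  hubs <- bat_fixture_degrees()
  n_other <- 70L
  stub_total <- 2L * 216L - sum(hubs)  # 188 residual endpoints
  net <- NULL
  for (attempt in 0:49) {
    net <- withr::with_seed(seed + attempt, {
      d <- pmin(1L + stats::rgeom(n_other, prob = 0.45), 8L)
      while (sum(d) > stub_total) {
        i <- which(d > 1L)
        i <- i[sample.int(length(i), 1L)]
        d[i] <- d[i] - 1L
      }
      while (sum(d) < stub_total) {
        i <- which(d < 8L)
        i <- i[sample.int(length(i), 1L)]
        d[i] <- d[i] + 1L
      }
      degrees <- c(hubs, stats::setNames(d, sprintf("prot%02d",
                                                    seq_len(n_other))))
      if (!is_graphical(degrees)) return(NULL)
      edges <- havel_hakimi(degrees)
      edges <- edge_swap_randomize(edges, n_attempts = 10L * nrow(edges))
      new_network(nodes = names(degrees), edges = edges)
    })
    if (!is.null(net)) break
  }
  if (is.null(net))
    stop("fixture constraint satisfaction failed after 50 internal seeds")
  deg <- network_degrees(net)
  if (n_nodes(net) != 78L || n_edges(net) != 216L ||
      !identical(as.integer(deg[names(hubs)]), as.integer(unname(hubs))))
    stop("fixture constraint satisfaction failed; try a different seed")
  attr(net, "hubs") <- hubs
  net
}

mutate_sequence <- function(bases_int, p) {
  if (p < 0 || p >= 0.75)
    stop("substitution proportion must be in [0, 0.75)")
  L <- length(bases_int)
  ns <- round(p * L)
  if (ns == 0L) return(bases_int)
  pos <- sample.int(L, ns)
  # shift each chosen site to one of the three other bases
  bases_int[pos] <- (bases_int[pos] - 1L +
                       sample.int(3L, ns, replace = TRUE)) %% 4L + 1L
  bases_int
}

#' Simulate genomes evolved along a known tree by point substitution
#'
#' The root sequence is uniform over A/C/G/T. Along each branch an exact
#' fraction `p` of positions (chosen without replacement) is substituted
#' to a uniformly chosen different base, so the parent-child Hamming
#' proportion equals `p` by construction (path sums between leaves differ
#' only by multiple hits). A star topology over `labels` is used when no
#' guide tree is given.
#'
#' @param tree optional `phylo` guide tree (traversed from its root; edge
#'   order is the `tree$edge` cladewise order).
#' @param labels leaf labels for the star topology when `tree` is `NULL`.
#' @param length sequence length in bases.
#' @param p per-branch substitution proportion in \[0, 0.75): a scalar
#'   applied to every branch, or a vector with one entry per edge of the
#'   guide tree (per leaf for a star).
#' @param seed RNG seed (default 42).
#' @return Named character vector of leaf sequences (single strings).
#' @export
simulate_genomes <- function(tree = NULL, labels = NULL, length = 10000,
                             p = 0.05, seed = 42L) {
  bases <- c("A", "C", "G", "T")
  if (any(p < 0 | p >= 0.75))
    stop("substitution proportion must be in [0, 0.75)")
  withr::with_seed(seed, {
    root_seq <- sample.int(4L, length, replace = TRUE)
    if (is.null(tree)) {
      if (is.null(labels) || length(labels) < 1L)
        stop("labels required for the star topology")
      pp <- rep_len(p, length(labels))
      leaf_seqs <- lapply(seq_along(labels),
                          function(i) mutate_sequence(root_seq, pp[i]))
      names(leaf_seqs) <- labels
    } else {
      stopifnot(inherits(tree, "phylo"))
      tree <- ape::reorder.phylo(tree, "cladewise")
      ned <- nrow(tree$edge)
      pp <- rep_len(p, ned)
      ntip <- length(tree$tip.label)
      seqs <- vector("list", ntip + tree$Nnode)
      root <- setdiff(tree$edge[, 1L], tree$edge[, 2L])[1L]
      seqs[[root]] <- root_seq
      for (e in seq_len(ned)) {
        par <- tree$edge[e, 1L]
        chl <- tree$edge[e, 2L]
        seqs[[chl]] <- mutate_sequence(seqs[[par]], pp[e])
      }
      leaf_seqs <- seqs[seq_len(ntip)]
      names(leaf_seqs) <- tree$tip.label
    }
    vapply(leaf_seqs, function(s) paste(bases[s], collapse = ""),
           character(1))
  })
}

#' Write simulated genomes as FASTA files
#'
#' One uncompressed FASTA file per genome, named `<label>.fasta`, suitable
#' as input for [cmd_phylo()].
#'
#' @param seqs named character vector of sequences.
#' @param dir output directory (created if needed).
#' @return Character vector of written paths, invisibly.
#' @export
write_genomes_fasta <- function(seqs, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(length(seqs))
  for (i in seq_along(seqs)) {
    lab <- names(seqs)[i]
    dss <- Biostrings::DNAStringSet(seqs[[i]])
    names(dss) <- lab
    paths[i] <- file.path(dir, paste0(lab, ".fasta"))
    Biostrings::writeXStringSet(dss, paths[i])
  }
  invisible(paths)
}

#' Read a genome FASTA as one sequence
#'
#' Multi-record files are concatenated with a single `N` separator so that
#' no k-mer window spans a record boundary.
#'
#' @param path FASTA file path.
#' @return A single character string.
#' @export
read_genome_fasta <- function(path) {
  dss <- Biostrings::readDNAStringSet(path)
  paste(as.character(dss), collapse = "N")
}
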