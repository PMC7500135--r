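# Shared oracles and fixture builders. Oracles deliberately avoid the code
# paths they check: shortest paths come from igraph, k-mer enumeration from
# plain string ops, Pauplin weights from an independent BFS.

# Unit-weight shortest-path distances from `seed` to all nodes (igraph).
oracle_bfs_distances <- function(net, seed) {
  g <- as_igraph(net)
  d <- igraph::distances(g, v = seed)[1L, ]
  names(d) <- igraph::V(g)$name
  d
}

# Brute-force canonical k-mer set in plain R.
oracle_canonical_kmers <- function(sequence, k) {
  s <- toupper(sequence)
  n <- nchar(s)
  if (n < k) return(character(0))
  wins <- substring(s, 1:(n - k + 1), k:n)
  ok <- !grepl("[^ACGT]", wins)
  wins <- wins[ok]
  rc <- vapply(wins, function(w)
    paste(rev(strsplit(chartr("ACGT", "TGCA", w), "")[[1L]]),
          collapse = ""), character(1), USE.NAMES = FALSE)
  unique(pmin(wins, rc))
}

# Random unrooted binary tree with positive branch lengths.
random_tree <- function(ntip, seed) {
  withr::with_seed(seed, {
    tr <- ape::rtree(ntip, rooted = FALSE,
                     tip.label = sprintf("t%02d", seq_len(ntip)))
    tr$edge.length <- stats::runif(nrow(tr$edge), 0.05, 0.5)
    tr
  })
}

# Additive distance matrix induced by a tree's path lengths.
additive_matrix <- function(tree) {
  D <- ape::cophenetic.phylo(tree)
  labs <- sort(rownames(D))
  propmash:::new_phylo_dist(labs, D[labs, labs])
}

# Independent Pauplin weights: topological tip distances by BFS over the
# tree's adjacency (no ape path utilities).
oracle_pauplin <- function(tree, dm) {
  nn <- length(tree$tip.label) + tree$Nnode
  adj <- rep(list(integer()), nn)
  for (e in seq_len(nrow(tree$edge))) {
    a <- tree$edge[e, 1L]; b <- tree$edge[e, 2L]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  ntip <- length(tree$tip.label)
  tdist <- function(from) {
    d <- rep(NA_integer_, nn)
    d[from] <- 0L
    frontier <- from
    while (length(frontier) > 0L) {
      nxt <- integer()
      for (v in frontier) for (w in adj[[v]]) if (is.na(d[w])) {
        d[w] <- d[v] + 1L
        nxt <- c(nxt, w)
      }
      frontier <- nxt
    }
    d
  }
  total <- 0
  for (i in seq_len(ntip - 1L)) {
    di <- tdist(i)
    for (j in seq(i + 1L, ntip)) {
      dij <- dm$values[tree$tip.label[i], tree$tip.label[j]]
      total <- total + dij * 2^(1 - di[j])
    }
  }
  total
}

# Hamming proportion between two equal-length sequences.
hamming_prop <- function(a, b) {
  va <- strsplit(a, "")[[1L]]
  vb <- strsplit(b, "")[[1L]]
  mean(va != vb)
}

write_links_file <- function(net, path, score = 900L) {
  lines <- c("protein1 protein2 combined_score",
             paste(net$edges$from, net$edges$to, score))
  writeLines(lines, path)
  path
}
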