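#' Hub degree ranking
#'
#' Degrees of a set of candidate hub proteins, sorted by degree descending
#' with ties broken lexicographically by node id. Seeds absent from the
#' network are reported with degree 0.
#'
#' @param network a `ppi_network`.
#' @param seeds character vector of node ids to rank.
#' @return data.frame with columns `node`, `degree`, one row per seed,
#'   ranked.
#' @export
hub_degrees <- function(network, seeds) {
  seeds <- as.character(seeds)
  deg_all <- network_degrees(network)
  deg <- integer(length(seeds))
  names(deg) <- seeds
  present <- seeds %in% names(deg_all)
  deg[present] <- deg_all[seeds[present]]
  o <- order(-deg, seeds)
  data.frame(node = seeds[o], degree = unname(deg[o]),
             stringsAsFactors = FALSE)
}

#' Degree-distribution moments and expansion statistics
#'
#' First and second moments of the degree distribution over *all* nodes
#' (degree-0 nodes included), plus the derived expansion quantities:
#' `alpha_paper` = <k^2>/<k> (the classical "rate of network expansion"),
#' `branching` = (<k^2> - <k>)/<k> (the mean excess degree, i.e. the
#' expected number of onward links when an edge is followed), and
#' `prefactor` = <k^2>/(<k^2> - <k>).
#'
#' @param network a `ppi_network` with at least one edge.
#' @return Object of class `degree_stats`: a list with fields
#'   `mean_degree`, `second_moment`, `alpha_paper`, `branching`,
#'   `prefactor` and `n_nodes`.
#' @export
degree_stats <- function(network) {
  if (n_edges(network) == 0L)
    stop("degenerate degree statistics: network has no edges")
  k <- as.numeric(network_degrees(network))
  m1 <- mean(k)
  m2 <- mean(k^2)
  structure(list(mean_degree = m1,
                 second_moment = m2,
                 alpha_paper = m2 / m1,
                 branching = (m2 - m1) / m1,
                 prefactor = m2 / (m2 - m1),
                 n_nodes = length(k)),
            class = "degree_stats")
}

#' @export
print.degree_stats <- function(x, ...) {
  cat(sprintf(paste0("degree_stats over %d nodes: <k>=%.4f  <k^2>=%.4f  ",
                     "alpha=<k^2>/<k>=%.4f  branching=%.4f\n"),
              x$n_nodes, x$mean_degree, x$second_moment, x$alpha_paper,
              x$branching))
  invisible(x)
}

#' Breadth-first shell decomposition around a seed
#'
#' Partitions the nodes reachable from `seed` into shells S(0), S(1), ...:
#' S(r) holds the nodes at shortest-path distance exactly r. A node that
#' re-appears while the network grows is kept only in the shell of its
#' first (shortest) distance. Growth is truncated at `r_max`.
#'
#' @param network a `ppi_network`.
#' @param seed a node id present in the network.
#' @param r_max maximum shell radius (default 8).
#' @return Object of class `shell_decomposition`: list with `seed`,
#'   `shells` (list of sorted character vectors, index r + 1), and
#'   `sizes` (integer vector |S(r)|).
#' @export
shell_decomposition <- function(network, seed, r_max = 8) {
  seed <- as.character(seed)
  if (!(seed %in% network$nodes))
    stop("seed '", seed, "' not in network")
  idx <- seq_along(network$nodes)
  names(idx) <- network$nodes
  ifrom <- idx[network$edges$from]
  ito <- idx[network$edges$to]
  adj <- rep(list(integer()), length(idx))
  if (length(ifrom) > 0L) {
    sp <- split(c(ito, ifrom), c(ifrom, ito))
    adj[as.integer(names(sp))] <- sp
  }
  visited <- logical(length(idx))
  s0 <- idx[[seed]]
  visited[s0] <- TRUE
  shells <- list(network$nodes[s0])
  frontier <- s0
  for (r in seq_len(r_max)) {
    nxt <- unique(unlist(adj[frontier], use.names = FALSE))
    nxt <- nxt[!visited[nxt]]
    if (length(nxt) == 0L) break
    visited[nxt] <- TRUE
    shells[[r + 1L]] <- sort(network$nodes[nxt])
    frontier <- nxt
  }
  structure(list(seed = seed, shells = shells,
                 sizes = lengths(shells)),
            class = "shell_decomposition")
}

#' Saturation radius of a propagation profile
#'
#' The smallest distance r at which |D(r)| attains its maximum — the end of
#' the rising regime in the rise-saturate-decay shape of shell growth.
#'
#' @param d_of_r non-empty numeric sequence of |D(r)| values, starting at
#'   r = 0.
#' @return Integer radius (0-based).
#' @export
saturation_radius <- function(d_of_r) {
  if (length(d_of_r) == 0L) stop("empty |D(r)| sequence")
  which.max(d_of_r) - 1L
}

#' Empirical propagation profile from a shell decomposition
#'
#' The profile |D(r)| is the probability mass of reachable nodes at
#' distance r: |S(r)| / sum of all shell sizes. It rises (approximately
#' exponentially in expanding networks), saturates at the radius `r_s`
#' where the shells stop growing, and then decays as the shells contract.
#' `growth_rate` is the least-squares slope of log |D(r)| over the rising
#' regime 1 <= r <= r_s (NA, flagged degenerate, when fewer than two points
#' are available).
#'
#' @param decomp a [shell_decomposition()] result.
#' @return Object of class `propagation_profile`: list with `seed`, `r`,
#'   `shell_sizes`, `d_of_r`, `r_s`, `growth_rate`, `peak_d` and the
#'   logical `degenerate`.
#' @export
propagation_profile <- function(decomp) {
  stopifnot(inherits(decomp, "shell_decomposition"))
  sizes <- as.numeric(decomp$sizes)
  if (length(sizes) == 0L) stop("empty shell decomposition")
  d <- sizes / sum(sizes)
  r_s <- saturation_radius(d)
  degenerate <- length(d) == 1L
  growth_rate <- NA_real_
  if (r_s >= 2L) {
    rr <- seq_len(r_s)          # r = 1 .. r_s
    y <- log(d[rr + 1L])
    growth_rate <- stats::cov(rr, y) / stats::var(rr)
  }
  structure(list(seed = decomp$seed,
                 r = seq_along(d) - 1L,
                 shell_sizes = as.integer(sizes),
                 d_of_r = d,
                 r_s = r_s,
                 growth_rate = growth_rate,
                 peak_d = max(d),
                 degenerate = degenerate),
            class = "propagation_profile")
}

#' @export
print.propagation_profile <- function(x, ...) {
  cat(sprintf("propagation_profile for seed '%s': r_s=%d  peak |D(r)|=%.4f",
              x$seed, x$r_s, x$peak_d))
  if (!is.na(x$growth_rate))
    cat(sprintf("  growth_rate=%.4f", x$growth_rate))
  if (x$degenerate) cat("  [degenerate]")
  cat("\n")
  invisible(x)
}

#' Model propagation profile from degree moments
#'
#' Exponential-growth model of the rising regime: `prefactor *
#' branching^r`, the expected shell-size growth in a locally tree-like
#' network where each followed edge leads to `branching` = (<k^2> - <k>)/<k>
#' onward neighbors on average. The classical alpha = <k^2>/<k> is carried
#' in `degree_stats` for reporting but is not the model base.
#'
#' @param stats a [degree_stats()] object with `branching > 0`.
#' @param r_values integer radii at which to evaluate the model.
#' @return Numeric vector, one value per radius.
#' @export
model_profile <- function(stats, r_values) {
  stopifnot(inherits(stats, "degree_stats"))
  if (stats$branching <= 0)
    stop("no expansion regime: branching factor <= 0")
  stats$prefactor * stats$branching^r_values
}

#' Propagation profiles for a set of seed proteins
#'
#' Computes one [propagation_profile()] per seed independently. Seeds
#' absent from the network produce a flagged degenerate profile (all mass
#' at r = 0) rather than an error.
#'
#' @param network a `ppi_network`.
#' @param seeds non-empty character vector of seed ids.
#' @param r_max maximum shell radius (default 8).
#' @return Object of class `propagation_profiles`: a named list of
#'   `propagation_profile` objects, one per seed (in input order).
#' @export
analyze_seeds <- function(network, seeds, r_max = 8) {
  seeds <- as.character(seeds)
  if (length(seeds) == 0L) stop("seeds must be non-empty")
  profiles <- lapply(seeds, function(s) {
    if (!(s %in% network$nodes)) {
      structure(list(seed = s, r = 0L, shell_sizes = 1L, d_of_r = 1,
                     r_s = 0L, growth_rate = NA_real_, peak_d = 1,
                     degenerate = TRUE),
                class = "propagation_profile")
    } else {
      propagation_profile(shell_decomposition(network, s, r_max))
    }
  })
  names(profiles) <- make.unique(seeds)
  structure(profiles, class = "propagation_profiles")
}

#' Summary table of per-seed propagation results
#'
#' @param profiles an [analyze_seeds()] result.
#' @param network the `ppi_network` the profiles were computed on (for the
#'   degree column).
#' @return data.frame with columns `seed`, `degree`, `r_s`, `growth_rate`,
#'   `peak_d`, `degenerate`.
#' @export
propagation_summary <- function(profiles, network) {
  stopifnot(inherits(profiles, "propagation_profiles"))
  deg_all <- network_degrees(network)
  rows <- lapply(profiles, function(p) {
    d <- if (p$seed %in% names(deg_all)) deg_all[[p$seed]] else 0L
    data.frame(seed = p$seed, degree = d, r_s = p$r_s,
               growth_rate = p$growth_rate, peak_d = p$peak_d,
               degenerate = p$degenerate, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Long-format profile table (seed, r, shell_size, D_of_r)
#' @param profiles an [analyze_seeds()] result.
#' @return data.frame, one row per (seed, r).
#' @export
profile_table <- function(profiles) {
  stopifnot(inherits(profiles, "propagation_profiles"))
  rows <- lapply(profiles, function(p)
    data.frame(seed = p$seed, r = p$r, shell_size = p$shell_sizes,
               D_of_r = p$d_of_r, stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
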