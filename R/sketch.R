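#' Canonical k-mer set of a nucleotide sequence
#'
#' Every window of length `kmer_size` consisting only of A/C/G/T
#' (case-insensitive) contributes the lexicographic minimum of the window
#' and its reverse complement, so both strands map to the same k-mer.
#' Windows containing any other symbol (N, gaps, IUPAC ambiguity codes)
#' are skipped.
#'
#' @param sequence a single nucleotide string.
#' @param kmer_size k-mer length in bases, >= 2.
#' @return Character vector of distinct canonical k-mers (unordered).
#' @export
canonical_kmers <- function(sequence, kmer_size) {
  stopifnot(length(sequence) == 1L, is.character(sequence))
  if (kmer_size < 2) stop("kmer_size must be >= 2")
  .canonical_kmer_set(sequence, as.integer(kmer_size))
}

#' Bottom-s MinHash sketch of a k-mer set
#'
#' Hashes each canonical k-mer with a seeded 64-bit non-cryptographic hash
#' (FNV-1a with splitmix64 finalization, truncated to 53 bits so values are
#' exact doubles) and keeps the `sketch_size` smallest distinct values.
#' Deterministic for a fixed `hash_seed` across runs and platforms.
#'
#' @param kmers character vector of k-mers (a set; duplicates collapse).
#' @param sketch_size maximum sketch size s, >= 1.
#' @param hash_seed integer seed mixed into the hash function.
#' @param kmer_size k-mer length recorded for compatibility checks; taken
#'   from the k-mers themselves when `NULL`.
#' @param label genome label carried into distance matrices.
#' @return Object of class `minhash_sketch`: list with `label`,
#'   `kmer_size`, `sketch_size`, `hash_seed` and `hashes` (sorted,
#'   strictly increasing numeric vector of at most s values).
#' @export
bottom_sketch <- function(kmers, sketch_size, hash_seed = 42L,
                          kmer_size = NULL, label = NA_character_) {
  if (sketch_size < 1) stop("sketch_size must be >= 1")
  if (length(kmers) == 0L) {
    warning("empty k-mer set: sketch is empty")
    h <- numeric(0)
    if (is.null(kmer_size)) kmer_size <- NA_integer_
  } else {
    if (is.null(kmer_size)) kmer_size <- nchar(kmers[[1L]])
    h <- sort(unique(.hash_strings(kmers, as.double(hash_seed))))
    if (length(h) > sketch_size) h <- h[seq_len(sketch_size)]
  }
  structure(list(label = label,
                 kmer_size = as.integer(kmer_size),
                 sketch_size = as.integer(sketch_size),
                 hash_seed = as.integer(hash_seed),
                 hashes = h),
            class = "minhash_sketch")
}

#' Sketch a genome sequence directly
#'
#' Convenience wrapper: [canonical_kmers()] then [bottom_sketch()].
#'
#' @param sequence nucleotide string (multi-record genomes should be
#'   concatenated by the caller; see [read_genome_fasta()]).
#' @param label genome label.
#' @param kmer_size k-mer length (default 16).
#' @param sketch_size sketch size s (default 5000).
#' @param hash_seed hash seed (default 42).
#' @return A `minhash_sketch`.
#' @export
sketch_sequence <- function(sequence, label, kmer_size = 16,
                            sketch_size = 5000, hash_seed = 42L) {
  bottom_sketch(canonical_kmers(sequence, kmer_size), sketch_size,
                hash_seed = hash_seed, kmer_size = kmer_size, label = label)
}

#' @export
print.minhash_sketch <- function(x, ...) {
  cat(sprintf("minhash_sketch '%s': k=%d  s=%d  |hashes|=%d  hash_seed=%d\n",
              x$label, x$kmer_size, x$sketch_size, length(x$hashes),
              x$hash_seed))
  invisible(x)
}

check_compatible <- function(a, b) {
  stopifnot(inherits(a, "minhash_sketch"), inherits(b, "minhash_sketch"))
  if (!identical(a$kmer_size, b$kmer_size) ||
      !identical(a$sketch_size, b$sketch_size) ||
      !identical(a$hash_seed, b$hash_seed))
    stop("incompatible sketches: kmer_size, sketch_size and hash_seed ",
         "must match")
  invisible(TRUE)
}

#' Jaccard similarity estimate from two bottom sketches
#'
#' Merged bottom-s estimator: among the s smallest distinct hash values of
#' the union of the two sketches, the fraction present in both. Equals the
#' exact set Jaccard whenever s is at least the union size.
#'
#' @param a,b `minhash_sketch` objects with matching parameters.
#' @return Estimated Jaccard index in \[0, 1\].
#' @export
jaccard <- function(a, b) {
  check_compatible(a, b)
  if (length(a$hashes) == 0L || length(b$hashes) == 0L) return(0)
  u <- sort(unique(c(a$hashes, b$hashes)))
  if (length(u) > a$sketch_size) u <- u[seq_len(a$sketch_size)]
  shared <- sum(u %in% a$hashes & u %in% b$hashes)
  shared / length(u)
}

#' Mash distance from a Jaccard estimate
#'
#' The Poisson-model inversion d = -(1/k) log(2j / (1 + j)). Identical
#' genomes (j = 1) give exactly 0; disjoint k-mer sets (j = 0) return the
#' finite `cap` so distance matrices stay usable for tree building.
#'
#' @param j Jaccard estimate in \[0, 1\].
#' @param kmer_size k-mer length used for the sketches.
#' @param cap distance returned when j = 0 (default 1.0).
#' @return Non-negative distance (substitutions per site scale).
#' @export
mash_distance <- function(j, kmer_size, cap = 1.0) {
  if (any(j < 0 | j > 1)) stop("Jaccard estimate must be in [0, 1]")
  d <- ifelse(j == 0, cap, -(1 / kmer_size) * log(2 * j / (1 + j)))
  pmax(d, 0)
}

#' p-distance from a Jaccard estimate
#'
#' Transforms the shared-k-mer fraction w = 2j/(1 + j) into the proportion
#' of substituted sites p = 1 - w^(1/k): a k-mer survives a substitution
#' proportion p with probability (1 - p)^k, so this inversion recovers p
#' directly. This is the estimate used by default for phylogenomic distance
#' matrices; [mash_distance()] is the log-scale variant.
#'
#' @inheritParams mash_distance
#' @param cap distance returned when j = 0 (default 1.0).
#' @return Estimated proportion of nucleotide differences in \[0, 1\].
#' @export
p_distance <- function(j, kmer_size, cap = 1.0) {
  if (any(j < 0 | j > 1)) stop("Jaccard estimate must be in [0, 1]")
  ifelse(j == 0, cap, 1 - (2 * j / (1 + j))^(1 / kmer_size))
}

#' Jukes-Cantor-style distance correction
#'
#' Maps a p-distance to a quantity proportional to the expected number of
#' substitution events: -(3/4) log(1 - 4p/3). Undefined at p >= 0.75. Off
#' by default in the pipeline; raw sketch distances are the primary output.
#'
#' @param p proportion of differing sites, in \[0, 0.75).
#' @return Corrected evolutionary distance (>= p).
#' @export
correct_distance <- function(p) {
  if (any(p < 0)) stop("p must be non-negative")
  if (any(p >= 0.75)) stop("correction undefined for p >= 0.75")
  -0.75 * log(1 - 4 * p / 3)
}

#' Pairwise distance matrix from MinHash sketches
#'
#' Computes all unordered pairs with the chosen distance transform;
#' symmetric with a zero diagonal by construction.
#'
#' @param sketches list of >= 2 compatible `minhash_sketch` objects with
#'   unique labels.
#' @param method `"pdistance"` (default; see [p_distance()]) or `"mash"`.
#' @param correction apply [correct_distance()] to each entry
#'   (default `FALSE`).
#' @param cap finite distance substituted when j = 0.
#' @return Object of class `phylo_dist`: list with `labels` and `values`
#'   (symmetric numeric matrix with dimnames).
#' @export
distance_matrix <- function(sketches, method = c("pdistance", "mash"),
                            correction = FALSE, cap = 1.0) {
  method <- match.arg(method)
  n <- length(sketches)
  if (n < 2L) stop("need at least 2 sketches")
  labels <- vapply(sketches, function(s) s$label, character(1))
  if (anyDuplicated(labels)) stop("duplicate genome labels")
  transform <- if (method == "mash") mash_distance else p_distance
  k <- sketches[[1L]]$kmer_size
  D <- matrix(0, n, n, dimnames = list(labels, labels))
  for (i in seq_len(n - 1L)) {
    for (jx in seq(i + 1L, n)) {
      d <- transform(jaccard(sketches[[i]], sketches[[jx]]), k, cap = cap)
      if (correction) d <- correct_distance(d)
      D[i, jx] <- D[jx, i] <- d
    }
  }
  new_phylo_dist(labels, D)
}

#' Distance matrix container
#' @param labels ordered genome names.
#' @param values symmetric non-negative matrix, zero diagonal.
#' @return A `phylo_dist` object.
#' @keywords internal
new_phylo_dist <- function(labels, values) {
  values <- as.matrix(values)
  dimnames(values) <- list(labels, labels)
  if (any(diag(values) != 0)) stop("distance matrix diagonal must be zero")
  if (max(abs(values - t(values))) > 1e-8)
    stop("distance matrix must be symmetric")
  if (any(values < 0)) stop("distances must be non-negative")
  structure(list(labels = labels, values = values), class = "phylo_dist")
}

#' @export
print.phylo_dist <- function(x, ...) {
  cat("phylo_dist over", length(x$labels), "genomes\n")
  print(round(x$values, 6))
  invisible(x)
}

#' Write a distance matrix in PHYLIP square format
#' @param dm a `phylo_dist`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_phylip <- function(dm, path) {
  stopifnot(inherits(dm, "phylo_dist"))
  n <- length(dm$labels)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%5d", n), con)
  for (i in seq_len(n)) {
    writeLines(paste0(formatC(dm$labels[i], width = -10),
                      paste(sprintf("%.6f", dm$values[i, ]),
                            collapse = "  ")), con)
  }
  invisible(path)
}

#' Read a PHYLIP square distance matrix
#' @param path input path.
#' @return A `phylo_dist`.
#' @export
read_phylip <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  n <- as.integer(trimws(lines[1L]))
  if (is.na(n) || length(lines) < n + 1L)
    stop("malformed PHYLIP matrix: bad taxon count")
  labels <- character(n)
  vals <- matrix(0, n, n)
  for (i in seq_len(n)) {
    fields <- strsplit(trimws(lines[i + 1L]), "[ \t]+")[[1L]]
    if (length(fields) != n + 1L)
      stop("malformed PHYLIP row ", i, ": expected ", n + 1L, " fields")
    labels[i] <- fields[1L]
    vals[i, ] <- as.numeric(fields[-1L])
  }
  new_phylo_dist(labels, vals)
}
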