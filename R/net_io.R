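#' Read a STRING-style protein-links table with a confidence filter
#'
#' Expects whitespace-separated rows `protein_a protein_b combined_score`.
#' Header rows beginning with `protein1` or `#` are skipped. STRING flat
#' files store the combined score as an integer on a 0--1000 scale while the
#' filter threshold is quoted on the normalized 0--1 scale; with
#' `scale = "auto"` (default) any score above 1 triggers division of all
#' scores by 1000. Self-interactions are dropped before filtering.
#'
#' @param path path to the links file.
#' @param score_threshold minimum normalized confidence retained
#'   (inclusive); default 0.4, the conventional medium-confidence cutoff.
#' @param scale `"auto"` (detect the 0--1000 dialect), `"raw"` (force
#'   division by 1000) or `"normalized"` (scores already in \[0, 1\]).
#' @return data.frame with columns `protein_a`, `protein_b`, `score`
#'   (normalized), containing only rows with `score >= score_threshold`.
#'   An empty result after filtering is returned with a warning.
#' @export
read_interactions <- function(path, score_threshold = 0.4,
                              scale = c("auto", "raw", "normalized")) {
  scale <- match.arg(scale)
  if (!file.exists(path)) stop("file not found: ", path)
  if (score_threshold < 0 || score_threshold > 1)
    stop("score_threshold must be in [0, 1]")
  lines <- readLines(path)
  a <- character(0); b <- character(0); s <- numeric(0)
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (!nzchar(ln)) next
    if (startsWith(ln, "#") || startsWith(ln, "protein1")) next
    fields <- strsplit(ln, "[ \t]+")[[1L]]
    if (length(fields) < 3L)
      stop("malformed row at line ", i, ": expected >= 3 columns")
    sc <- suppressWarnings(as.numeric(fields[3L]))
    if (is.na(sc))
      stop("malformed row at line ", i, ": non-numeric score '",
           fields[3L], "'")
    a <- c(a, fields[1L]); b <- c(b, fields[2L]); s <- c(s, sc)
  }
  if (length(s) > 0L) {
    if (scale == "raw" || (scale == "auto" && any(s > 1))) s <- s / 1000
    if (any(s < 0 | s > 1))
      stop("scores outside [0, 1] after normalization; check the scale flag")
  }
  n_self <- sum(a == b)
  if (n_self > 0L) {
    message("read_interactions: dropped ", n_self, " self-interaction(s)")
    keep <- a != b
    a <- a[keep]; b <- b[keep]; s <- s[keep]
  }
  keep <- s >= score_threshold
  out <- data.frame(protein_a = a[keep], protein_b = b[keep],
                    score = s[keep], stringsAsFactors = FALSE)
  if (nrow(out) == 0L)
    warning("no interactions pass the confidence threshold ",
            score_threshold)
  out
}

#' Read a seed-to-reference homolog mapping table
#'
#' Stand-in for a sequence-similarity search: a TSV with columns
#' `query`, `reference`, `identity`, `coverage` (identity and coverage in
#' percent). For each query the best hit is retained: highest identity,
#' ties broken by highest coverage, then by lexicographically smallest
#' reference id. A query with two fully identical candidate rows is an
#' ambiguous mapping and raises an error.
#'
#' @param path path to the TSV (an optional header row starting with
#'   `query` or `#` is skipped).
#' @return data.frame with one row per query: `query`, `reference`,
#'   `identity`, `coverage`.
#' @export
read_mapping <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  rows <- list()
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (!nzchar(ln) || startsWith(ln, "#") || startsWith(ln, "query")) next
    fields <- strsplit(ln, "\t")[[1L]]
    if (length(fields) < 4L)
      stop("malformed row at line ", i, ": expected 4 tab-separated columns")
    rows[[length(rows) + 1L]] <- fields[1:4]
  }
  if (length(rows) == 0L)
    return(data.frame(query = character(), reference = character(),
                      identity = numeric(), coverage = numeric()))
  m <- do.call(rbind, rows)
  df <- data.frame(query = m[, 1L], reference = m[, 2L],
                   identity = as.numeric(m[, 3L]),
                   coverage = as.numeric(m[, 4L]),
                   stringsAsFactors = FALSE)
  if (anyNA(df$identity) || anyNA(df$coverage))
    stop("non-numeric identity or coverage value")
  if (any(df$identity < 0 | df$identity > 100) ||
      any(df$coverage < 0 | df$coverage > 100))
    stop("identity and coverage must be in [0, 100]")
  if (anyDuplicated(df))
    stop("ambiguous mapping: duplicated query/identity/coverage/reference row")
  df <- df[order(df$query, -df$identity, -df$coverage, df$reference), ]
  best <- df[!duplicated(df$query), , drop = FALSE]
  rownames(best) <- NULL
  best
}
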