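#' Construct a co-occurrence matrix object
#'
#' The matrix is a symmetric sparse map from unordered CUI pairs to window
#' co-occurrence counts, stored as a keyed data.table of normalized pairs
#' (`cui_a < cui_b` lexicographically). Diagonal pairs are forbidden and all
#' stored counts are >= 1; an absent pair means count 0.
#'
#' @param pairs data.frame/data.table with columns `cui_a`, `cui_b`, `count`
#'   (pairs need not be normalized; duplicates after normalization are an
#'   error).
#' @param window_size window size metadata (integer >= 1).
#' @param n_documents document count metadata.
#' @return an object of class `cooc_matrix`.
#' @export
cooc_matrix <- function(pairs = data.frame(cui_a = character(),
                                           cui_b = character(),
                                           count = integer()),
                        window_size = 8L, n_documents = 0L) {
  stopifnot(window_size >= 1L, n_documents >= 0L)
  dt <- as.data.table(pairs)[, list(cui_a = as.character(cui_a),
                                    cui_b = as.character(cui_b),
                                    count = as.integer(count))]
  if (nrow(dt) > 0) {
    if (any(dt$cui_a == dt$cui_b))
      stop("diagonal pair (self co-occurrence) is not allowed")
    if (any(dt$count < 1L)) stop("all stored counts must be >= 1")
    lo <- pmin(dt$cui_a, dt$cui_b)
    hi <- pmax(dt$cui_a, dt$cui_b)
    dt[, c("cui_a", "cui_b") := list(lo, hi)]
    if (anyDuplicated(dt, by = c("cui_a", "cui_b")))
      stop("duplicate unordered pair")
  }
  setkeyv(dt, c("cui_a", "cui_b"))
  structure(list(pairs = dt,
                 window_size = as.integer(window_size),
                 n_documents = as.integer(n_documents)),
            class = "cooc_matrix")
}

#' @export
print.cooc_matrix <- function(x, ...) {
  cat(sprintf("<cooc_matrix> %d pairs | window_size=%d | n_documents=%d\n",
              nrow(x$pairs), x$window_size, x$n_documents))
  invisible(x)
}

#' Count windowed concept co-occurrences
#'
#' Two concept tokens co-occur when they lie within `window_size` positions
#' of each other in the same document; windows never cross document
#' boundaries (the unit of processing is one citation's concept stream), and
#' sentence boundaries play no role. Each unordered token-position pair
#' (i < j, j - i <= window_size) with distinct CUIs contributes exactly 1 to
#' its CUI pair, so a CUI repeated in a document contributes once per
#' qualifying position pair, and self pairs (same CUI at two positions) are
#' never counted.
#'
#' The default window of 8 follows the observation that eight concepts is
#' about the concept-length of an average sentence, balancing windowing noise
#' against missed associations.
#'
#' @param corpus a `concept_corpus`.
#' @param window_size maximum position distance counted as co-occurring.
#' @return a `cooc_matrix` with metadata recording `window_size` and the
#'   corpus document count.
#' @export
count_cooccurrences <- function(corpus, window_size = 8L) {
  stopifnot(inherits(corpus, "concept_corpus"), window_size >= 1L)
  window_size <- as.integer(window_size)
  chunks <- lapply(corpus$tokens, function(tk) {
    n <- length(tk)
    if (n < 2L) return(NULL)
    dmax <- min(window_size, n - 1L)
    a <- vector("list", dmax); b <- vector("list", dmax)
    for (d in seq_len(dmax)) {
      a[[d]] <- tk[seq_len(n - d)]
      b[[d]] <- tk[seq.int(1L + d, n)]
    }
    a <- unlist(a); b <- unlist(b)
    keep <- a != b
    if (!any(keep)) return(NULL)
    data.table(cui_a = pmin(a[keep], b[keep]), cui_b = pmax(a[keep], b[keep]))
  })
  all_pairs <- rbindlist(chunks)
  if (is.null(all_pairs) || nrow(all_pairs) == 0) {
    return(cooc_matrix(window_size = window_size,
                       n_documents = length(corpus$doc_ids)))
  }
  counted <- all_pairs[, list(count = .N), by = c("cui_a", "cui_b")]
  cooc_matrix(counted, window_size = window_size,
              n_documents = length(corpus$doc_ids))
}

#' Look up the co-occurrence count of a concept pair
#'
#' Symmetric: `pair_count(m, x, y) == pair_count(m, y, x)`. Absent pairs
#' count 0. Asking for a diagonal pair (`a == b`) is a contract violation,
#' not a zero.
#'
#' @param matrix a `cooc_matrix`.
#' @param a,b distinct concept identifiers.
#' @return integer count >= 0.
#' @export
pair_count <- function(matrix, a, b) {
  stopifnot(inherits(matrix, "cooc_matrix"), length(a) == 1L, length(b) == 1L)
  if (a == b) stop("pair_count is undefined on the diagonal (a == b)")
  row <- matrix$pairs[list(min(a, b), max(a, b)), on = c("cui_a", "cui_b")]
  if (is.na(row$count[1])) 0L else row$count[1]
}

#' Write a co-occurrence matrix as a flat file
#'
#' The on-disk analogue of a flat file of CUI-pair co-occurrence counts:
#' two header lines `#window_size=<w>` and `#n_documents=<n>`, then one line
#' per pair `cui_a<TAB>cui_b<TAB>count` with `cui_a < cui_b` and lines sorted
#' lexicographically by (cui_a, cui_b). Output is byte-deterministic.
#'
#' @param matrix a `cooc_matrix`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(matrix, path) {
  stopifnot(inherits(matrix, "cooc_matrix"))
  dt <- copy(matrix$pairs)
  setorderv(dt, c("cui_a", "cui_b"))  # radix sort: locale-independent
  lines <- c(sprintf("#window_size=%d", matrix$window_size),
             sprintf("#n_documents=%d", matrix$n_documents),
             if (nrow(dt) > 0) paste(dt$cui_a, dt$cui_b, dt$count, sep = "\t"))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read a flat co-occurrence file
#'
#' Inverse of [write_matrix()]. Pairs are normalized to unordered form on
#' read; a file carrying the same unordered pair twice (e.g. both `A B` and
#' `B A`) is an error, as are counts below 1 and missing headers.
#'
#' @param path path to a flat co-occurrence file.
#' @return a `cooc_matrix`.
#' @export
read_matrix <- function(path) {
  if (!file.exists(path)) stop("matrix file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8")
  if (length(lines) < 2L ||
      !startsWith(lines[1], "#window_size=") ||
      !startsWith(lines[2], "#n_documents="))
    stop("missing #window_size/#n_documents header in ", path)
  w <- as.integer(sub("#window_size=", "", lines[1], fixed = TRUE))
  nd <- as.integer(sub("#n_documents=", "", lines[2], fixed = TRUE))
  if (is.na(w) || is.na(nd)) stop("malformed header in ", path)
  body <- lines[-(1:2)]
  body <- body[nzchar(trimws(body))]
  if (length(body) == 0)
    return(cooc_matrix(window_size = w, n_documents = nd))
  parts <- strsplit(body, "\t", fixed = TRUE)
  if (any(lengths(parts) != 3L))
    stop("malformed pair line in ", path)
  cnt <- suppressWarnings(as.integer(vapply(parts, `[`, character(1), 3L)))
  if (anyNA(cnt) || any(cnt < 1L))
    stop("pair count missing or < 1 in ", path)
  cooc_matrix(data.table(cui_a = vapply(parts, `[`, character(1), 1L),
                         cui_b = vapply(parts, `[`, character(1), 2L),
                         count = cnt),
              window_size = w, n_documents = nd)
}

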