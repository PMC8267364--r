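# Independent brute-force oracle: O(n^2) double loop over all token-position
# pairs of every document, written without reference to the windowed counter.
brute_force_cooc <- function(corpus, window_size) {
  env <- new.env(parent = emptyenv())
  for (tk in corpus$tokens) {
    n <- length(tk)
    if (n < 2L) next
    for (i in seq_len(n - 1L)) {
      for (j in seq.int(i + 1L, n)) {
        if (j - i <= window_size && tk[i] != tk[j]) {
          key <- paste(min(tk[i], tk[j]), max(tk[i], tk[j]), sep = "|")
          prev <- if (is.null(env[[key]])) 0L else env[[key]]
          env[[key]] <- prev + 1L
        }
      }
    }
  }
  keys <- ls(env)
  if (length(keys) == 0)
    return(data.frame(cui_a = character(), cui_b = character(),
                      count = integer(), stringsAsFactors = FALSE))
  sp <- strsplit(keys, "|", fixed = TRUE)
  df <- data.frame(cui_a = vapply(sp, `[`, character(1), 1L),
                   cui_b = vapply(sp, `[`, character(1), 2L),
                   count = vapply(keys, function(k) env[[k]], integer(1)),
                   stringsAsFactors = FALSE)
  df <- df[order(df$cui_a, df$cui_b), ]
  rownames(df) <- NULL
  df
}

# cooc_matrix -> plain sorted data.frame for comparison with the oracle
matrix_as_df <- function(m) {
  df <- as.data.frame(m$pairs)
  df <- df[order(df$cui_a, df$cui_b), ]
  rownames(df) <- NULL
  df
}

# Random small corpus over a tiny CUI alphabet (repeats likely, exercising
# the duplicate-token and diagonal rules).
random_corpus <- function(n_docs, max_len, vocab_size = 10L) {
  alphabet <- sprintf("C%07d", seq_len(vocab_size))
  tokens <- lapply(seq_len(n_docs), function(i)
    sample(alphabet, sample.int(max_len, 1L), replace = TRUE))
  concept_corpus(sprintf("doc%04d", seq_len(n_docs)), tokens)
}

# LTC recount oracle: per target, count distinct B terms among surviving
# edges directly from the edge table.
brute_force_ltc <- function(filtered) {
  df <- as.data.frame(filtered)
  if (nrow(df) == 0) return(data.frame(c_term = character(), ltc = integer()))
  agg <- stats::aggregate(b_term ~ c_term, data = df,
                          FUN = function(b) length(unique(b)))
  names(agg)[2] <- "ltc"
  agg <- agg[order(-agg$ltc, agg$c_term), ]
  rownames(agg) <- NULL
  agg
}

write_tmp_lines <- function(lines) {
  f <- tempfile(fileext = ".txt")
  writeLines(lines, f, useBytes = TRUE)
  f
}
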