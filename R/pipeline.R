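#' Read a discovery query from a config file
#'
#' Plain key-value (YAML) config with keys `a_term`, `b_terms` (list),
#' `c_semantic_types` (list), `min_ab_count`, `min_bc_count`,
#' `keep_direct`. Missing optional keys take the [discovery_query()]
#' defaults.
#'
#' @param path path to a query config file.
#' @return a `discovery_query`.
#' @export
read_query_config <- function(path) {
  if (!file.exists(path)) stop("query config not found: ", path)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$a_term)) stop("query config must set a_term")
  discovery_query(
    a_term = cfg$a_term,
    b_restriction = if (!is.null(cfg$b_terms)) unlist(cfg$b_terms),
    c_semantic_types = if (!is.null(cfg$c_semantic_types))
      unlist(cfg$c_semantic_types) else "T047",
    min_ab_count = if (!is.null(cfg$min_ab_count)) cfg$min_ab_count else 1L,
    min_bc_count = if (!is.null(cfg$min_bc_count)) cfg$min_bc_count else 2L,
    keep_direct = if (!is.null(cfg$keep_direct)) cfg$keep_direct else TRUE
  )
}

#' Read a plant specification from a config file
#'
#' Same key-value format as query configs. Keys: `pair_counts` (list of
#' `[cui_a, cui_b, count]` triples), `noise_vocab_size`, `noise_documents`,
#' `noise_doc_length`, `window_size`, `seed`.
#'
#' @param path path to a plant config file.
#' @return a `plant_spec`.
#' @export
read_plant_config <- function(path) {
  if (!file.exists(path)) stop("plant config not found: ", path)
  cfg <- yaml::read_yaml(path)
  pc <- if (length(cfg$pair_counts) > 0) {
    do.call(rbind, lapply(cfg$pair_counts, function(p)
      data.frame(cui_a = as.character(p[[1]]), cui_b = as.character(p[[2]]),
                 count = as.integer(p[[3]]))))
  } else data.frame(cui_a = character(), cui_b = character(),
                    count = integer())
  plant_spec(
    pair_counts = pc,
    noise_vocab_size = if (!is.null(cfg$noise_vocab_size))
      cfg$noise_vocab_size else 0L,
    noise_documents = if (!is.null(cfg$noise_documents))
      cfg$noise_documents else 0L,
    noise_doc_length = if (!is.null(cfg$noise_doc_length))
      cfg$noise_doc_length else 10L,
    window_size = if (!is.null(cfg$window_size)) cfg$window_size else 8L,
    seed = if (!is.null(cfg$seed)) cfg$seed else 1L
  )
}

#' Build a co-occurrence matrix file from a corpus file
#'
#' Preprocessing entry point: reads a concept corpus, counts windowed
#' co-occurrences, and writes the flat matrix file. Logs document and pair
#' tallies via `message()`.
#'
#' @param corpus_path path to a corpus file.
#' @param window_size co-occurrence window (default 8).
#' @param out_path output path for the flat matrix file.
#' @return the `cooc_matrix`, invisibly.
#' @export
run_build_cooc <- function(corpus_path, window_size = 8L, out_path) {
  corpus <- read_corpus(corpus_path)
  m <- count_cooccurrences(corpus, window_size)
  write_matrix(m, out_path)
  message(sprintf("build-cooc: %d documents -> %d CUI pairs (window %d) -> %s",
                  m$n_documents, nrow(m$pairs), m$window_size, out_path))
  invisible(m)
}

#' Run discovery end to end and write its reports
#'
#' Reads the matrix and vocabulary, runs the ABC pipeline, and writes three
#' deterministic outputs under `out_dir`: `hypotheses.txt` (the ranked
#' listing with per-linking-term breakdowns), `ltc_histogram.tsv`, and
#' `threshold_listing.tsv`. An unknown start term yields empty outputs with
#' a warning rather than an error.
#'
#' @param matrix_path path to a flat co-occurrence file.
#' @param vocab_path path to a vocabulary TSV.
#' @param query a `discovery_query`, or the path of a query config file.
#' @param out_dir output directory (created if needed).
#' @param min_ltc threshold for the threshold listing (default 10).
#' @param universe_size histogram universe; default is the number of
#'   vocabulary entries carrying any queried semantic type.
#' @return the `discovery_result`, invisibly.
#' @export
run_discover <- function(matrix_path, vocab_path, query, out_dir,
                         min_ltc = 10L, universe_size = NULL) {
  matrix <- read_matrix(matrix_path)
  vocab <- load_vocabulary(vocab_path)
  if (is.character(query)) query <- read_query_config(query)
  stopifnot(inherits(query, "discovery_query"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  result <- run_discovery(query, matrix, vocab)
  if (is.null(universe_size))
    universe_size <- sum(has_semantic_type(vocab, vocab$cui,
                                           query$c_semantic_types))
  writeLines(sub("\n$", "", render_hypothesis_list(result, vocab)),
             file.path(out_dir, "hypotheses.txt"), useBytes = TRUE)
  write_report_tsv(ltc_histogram(result, universe_size),
                   file.path(out_dir, "ltc_histogram.tsv"))
  write_report_tsv(threshold_listing(result, vocab, min_ltc),
                   file.path(out_dir, "threshold_listing.tsv"))
  message(sprintf("discover: %d linked B terms, %d ranked hypotheses -> %s",
                  length(result$linked$links), length(result$hypotheses),
                  out_dir))
  invisible(result)
}

#' Generate a synthetic corpus file from a plant specification
#'
#' Writes the corpus realizing the plant and logs a recount summary
#' verifying that the planted pair counts are recovered at the plant
#' specification's window size.
#'
#' @param spec a `plant_spec`, or the path of a plant config file.
#' @param out_path output corpus path.
#' @return the generated `concept_corpus`, invisibly.
#' @export
run_simulate <- function(spec, out_path) {
  if (is.character(spec)) spec <- read_plant_config(spec)
  stopifnot(inherits(spec, "plant_spec"))
  corpus <- generate_corpus(spec)
  write_corpus(corpus, out_path)
  m <- count_cooccurrences(corpus, spec$window_size)
  pc <- spec$pair_counts
  ok <- nrow(pc) == 0 || all(vapply(seq_len(nrow(pc)), function(i)
    pair_count(m, pc$cui_a[i], pc$cui_b[i]) == pc$count[i], logical(1)))
  message(sprintf(
    "simulate: %d documents -> %s | planted pairs recovered on recount: %s",
    length(corpus$doc_ids), out_path, if (ok) "yes" else "NO"))
  invisible(corpus)
}
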