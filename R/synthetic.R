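# Noise concepts are drawn from the reserved C99xxxxx identifier range so
# they can never collide with planted CUIs.
.noise_prefix <- "C99"

noise_cui <- function(i) sprintf("C99%05d", i)

# run `expr` under a fixed RNG seed without disturbing the caller's RNG state
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Specify a synthetic corpus with planted co-occurrence counts
#'
#' A plant specification prescribes the exact pairwise co-occurrence counts
#' a generated corpus must realize under a given window size, plus optional
#' background noise documents over a reserved concept range. It is the
#' testable stand-in for a concept-mapped citation corpus: the real corpus
#' is licensed and enormous, but every pipeline property can be exercised on
#' corpora whose ground-truth counts are known by construction.
#'
#' @param pair_counts data.frame with columns `cui_a`, `cui_b`, `count`
#'   (unordered pairs, no diagonal, counts >= 1). Planted CUIs must lie
#'   outside the reserved noise range (prefix "C99").
#' @param noise_vocab_size number of distinct noise concepts available.
#' @param noise_documents number of noise documents to emit.
#' @param noise_doc_length tokens per noise document.
#' @param window_size window under which the planted counts must be
#'   recovered.
#' @param seed integer seed driving noise sampling and document shuffling.
#' @return an object of class `plant_spec`.
#' @export
plant_spec <- function(pair_counts = data.frame(cui_a = character(),
                                                cui_b = character(),
                                                count = integer()),
                       noise_vocab_size = 0L, noise_documents = 0L,
                       noise_doc_length = 10L, window_size = 8L, seed = 1L) {
  pc <- as.data.frame(pair_counts)
  stopifnot(all(c("cui_a", "cui_b", "count") %in% names(pc)) || nrow(pc) == 0,
            noise_vocab_size >= 0L, noise_documents >= 0L,
            noise_doc_length >= 1L, window_size >= 1L)
  if (nrow(pc) > 0) {
    if (any(!is_cui(pc$cui_a)) || any(!is_cui(pc$cui_b)))
      stop("malformed CUI in pair_counts")
    if (any(pc$cui_a == pc$cui_b))
      stop("diagonal pair in pair_counts")
    if (any(pc$count < 1L))
      stop("planted counts must be >= 1")
    if (any(startsWith(pc$cui_a, .noise_prefix)) ||
        any(startsWith(pc$cui_b, .noise_prefix)))
      stop("planted CUIs must not use the reserved noise range (", .noise_prefix, "...)")
    lo <- pmin(pc$cui_a, pc$cui_b); hi <- pmax(pc$cui_a, pc$cui_b)
    if (anyDuplicated(paste(lo, hi)))
      stop("duplicate unordered pair in pair_counts")
  }
  if (noise_documents > 0L && noise_vocab_size < 1L)
    stop("noise documents require noise_vocab_size >= 1")
  if (noise_vocab_size > 99999L)
    stop("noise_vocab_size exceeds the reserved identifier range")
  structure(list(pair_counts = pc,
                 noise_vocab_size = as.integer(noise_vocab_size),
                 noise_documents = as.integer(noise_documents),
                 noise_doc_length = as.integer(noise_doc_length),
                 window_size = as.integer(window_size),
                 seed = as.integer(seed)),
            class = "plant_spec")
}

#' Generate a corpus realizing a plant specification
#'
#' Each planted pair (x, y) with target count k is emitted as k minimal
#' two-token documents `[x, y]`; since windows never span documents and the
#' two tokens are adjacent, recounting at any window size >= 1 recovers
#' exactly k, and two-token documents cannot create unplanted pairs. Noise
#' documents sample uniformly (under the plant seed) from the reserved noise
#' concept range, which is disjoint from planted CUIs, so planted counts are
#' never contaminated. Document order is shuffled deterministically by the
#' seed.
#'
#' @param spec a `plant_spec`.
#' @return a `concept_corpus`.
#' @export
generate_corpus <- function(spec) {
  stopifnot(inherits(spec, "plant_spec"))
  pc <- spec$pair_counts
  planted <- if (nrow(pc) > 0) {
    idx <- rep(seq_len(nrow(pc)), pc$count)
    lapply(idx, function(i) c(pc$cui_a[i], pc$cui_b[i]))
  } else list()
  with_seed(spec$seed, {
    noise <- if (spec$noise_documents > 0L) {
      pool <- noise_cui(seq_len(spec$noise_vocab_size))
      lapply(seq_len(spec$noise_documents), function(i)
        sample(pool, spec$noise_doc_length, replace = TRUE))
    } else list()
    tokens <- c(planted, noise)
    ord <- if (length(tokens) > 1L) sample.int(length(tokens)) else
      seq_along(tokens)
    tokens <- tokens[ord]
    concept_corpus(sprintf("d%06d", seq_along(tokens)), tokens)
  })
}

#' Plant a full ABC open-discovery scenario
#'
#' Builds a corpus, query, and matching vocabulary in which a designated
#' start term A co-occurs with `n_b` linking terms, and the i-th planted
#' target term shares `bc_profile[i]` of those linking terms (each B-C edge
#' planted at count 2 so it survives the default singleton filter). A-C
#' documents are added only when `direct_ac` is TRUE, so by default every
#' planted target is a genuinely indirect discovery. The expected LTC of
#' target i is exactly `bc_profile[i]` by construction.
#'
#' @param n_b number of linking terms planted against A.
#' @param bc_profile integer vector; entry i is the number of B terms shared
#'   by the i-th planted target (each entry <= `n_b`).
#' @param direct_ac also plant a single direct A-target co-occurrence for
#'   each target?
#' @param seed shuffling/sampling seed.
#' @return list with elements `corpus` (`concept_corpus`), `query`
#'   (`discovery_query`), `vocab` (`concept_vocabulary`), and `planted`
#'   (list with `a_term`, `b_terms`, `c_terms`).
#' @export
plant_abc_scenario <- function(n_b, bc_profile = integer(), direct_ac = FALSE,
                               seed = 1L) {
  stopifnot(n_b >= 0L, all(bc_profile >= 0L))
  if (any(bc_profile > n_b))
    stop("infeasible profile: a target cannot share more than n_b linking terms")
  a <- "C0100000"
  bs <- sprintf("C02%05d", seq_len(n_b))
  cs <- sprintf("C03%05d", seq_along(bc_profile))
  rows <- list()
  if (n_b > 0)
    rows[[length(rows) + 1L]] <-
      data.frame(cui_a = a, cui_b = bs, count = 2L)
  for (j in seq_along(bc_profile)) {
    k <- bc_profile[j]
    if (k > 0)
      rows[[length(rows) + 1L]] <-
        data.frame(cui_a = bs[seq_len(k)], cui_b = cs[j], count = 2L)
    if (direct_ac)
      rows[[length(rows) + 1L]] <-
        data.frame(cui_a = a, cui_b = cs[j], count = 1L)
  }
  pc <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(cui_a = character(), cui_b = character(), count = integer())
  spec <- plant_spec(pc, window_size = 8L, seed = seed)
  corpus <- generate_corpus(spec)
  vocab_lines <- c(
    "cui\tpreferred_term\tsemantic_types\tsemantic_group",
    sprintf("%s\tStart term\tT047\tDISO", a),
    if (n_b > 0) sprintf("%s\tLinking term %d\tT109\tCHEM", bs, seq_len(n_b)),
    if (length(cs) > 0) sprintf("%s\tPlanted target %d\tT047\tDISO",
                                cs, seq_along(cs))
  )
  vf <- tempfile(fileext = ".tsv")
  writeLines(vocab_lines, vf, useBytes = TRUE)
  vocab <- load_vocabulary(vf)
  unlink(vf)
  query <- discovery_query(a_term = a,
                           b_restriction = if (n_b > 0) bs else NULL,
                           c_semantic_types = "T047",
                           min_ab_count = 1L, min_bc_count = 2L,
                           keep_direct = TRUE)
  list(corpus = corpus, query = query, vocab = vocab,
       planted = list(a_term = a, b_terms = bs, c_terms = cs))
}

# The 17 metabolites that co-occur with the cardiac-arrest start term, plus
# the two that never do. Used by the packaged fixtures and their query.
.fixture_a_term <- "C0018790"
.fixture_b_linked <- c(
  "C0368608", "C0003765", "C0007745", "C0008405", "C0556150", "C0058624",
  "C2348386", "C2348388", "C0017770", "C0019602", "C0023401", "C0024360",
  "C0028375", "C0070662", "C0031716", "C0031951", "C0037906"
)
.fixture_b_unlinked <- c("C2348307", "C0069409")

#' Packaged worked-example fixture: matrix and vocabulary
#'
#' Returns the co-occurrence fixture encoding the published worked example:
#' B-C edge lists for the two showcased disease targets (fish-eye disease
#' C0342895 and Wiskott-Aldrich syndrome C0043194) exactly as printed, A-B
#' edges for the 17 metabolites that co-occur with the cardiac-arrest start
#' term C0018790, and a mini-Metathesaurus vocabulary covering every CUI
#' involved. The two metabolites with no recorded cardiac-arrest
#' co-occurrence (C2348307, C0069409) are in the vocabulary but carry no A
#' edge.
#'
#' The source study never prints A-B co-occurrence counts, only that the 17
#' links exist; since LTC depends only on edge existence above threshold,
#' the fixture defaults them to `ab_count = 2` so the B-to-A edges also
#' clear the default singleton filter (letting the start term appear in its
#' own ranked output, as in the study).
#'
#' @param ab_count co-occurrence count assigned to each of the 17 A-B edges.
#' @return list with elements `matrix` (`cooc_matrix`), `vocab`
#'   (`concept_vocabulary`).
#' @export
fixture_matrix <- function(ab_count = 2L) {
  stopifnot(ab_count >= 1L)
  edges_path <- system.file("extdata", "tables12_bc_edges.tsv",
                            package = "ltcdiscovery", mustWork = TRUE)
  vocab_path <- system.file("extdata", "mini_metathesaurus.tsv",
                            package = "ltcdiscovery", mustWork = TRUE)
  bc <- read_matrix(edges_path)
  ab <- data.frame(cui_a = .fixture_a_term, cui_b = .fixture_b_linked,
                   count = as.integer(ab_count))
  pairs <- rbind(as.data.frame(bc$pairs), ab)
  list(matrix = cooc_matrix(pairs, window_size = bc$window_size,
                            n_documents = bc$n_documents),
       vocab = load_vocabulary(vocab_path))
}

#' The worked-example discovery query
#'
#' The open-discovery query of the source study: start term cardiac arrest
#' (C0018790), linking terms restricted to the 19 lab-identified metabolite
#' CUIs (two of which have no A co-occurrence and are excluded at linking
#' time), targets restricted to Disease or Syndrome (T047), singleton B-C
#' edges filtered, directly co-occurring targets kept.
#'
#' @return a `discovery_query`.
#' @export
fixture_query <- function() {
  discovery_query(a_term = .fixture_a_term,
                  b_restriction = c(.fixture_b_linked, .fixture_b_unlinked),
                  c_semantic_types = "T047",
                  min_ab_count = 1L, min_bc_count = 2L, keep_direct = TRUE)
}

#' Packaged LTC score distribution fixture
#'
#' The published per-score histogram of disease targets: for each LTC score
#' the number of disease terms attaining exactly that score, over a universe
#' of 55,376 disease-typed concepts. Cumulative counts are not shipped; they
#' are recomputed by [ltc_histogram_from_counts()].
#'
#' @return data.frame with columns `ltc`, `n_terms` (descending score
#'   order, including the score-0 row).
#' @export
fixture_ltc_distribution <- function() {
  path <- system.file("extdata", "ltc_score_distribution.tsv",
                      package = "ltcdiscovery", mustWork = TRUE)
  utils::read.table(path, header = TRUE, sep = "\t")
}
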