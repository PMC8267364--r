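#' Define an open-discovery ABC query
#'
#' In the ABC model a start (A) term is connected to candidate target (C)
#' terms through shared linking (B) terms; A and C need not ever co-occur
#' directly, which is what lets the pipeline surface associations absent
#' from any single publication. The query fixes A, optionally restricts the
#' B universe to a pre-identified concept set (e.g. metabolites found
#' significant in the lab), and restricts C terms by semantic type (default
#' "T047", Disease or Syndrome).
#'
#' @param a_term start-term CUI.
#' @param b_restriction optional character vector of candidate B CUIs; when
#'   NULL every concept co-occurring with `a_term` is a candidate.
#' @param c_semantic_types semantic-type codes C terms must carry.
#' @param min_ab_count minimum A-B co-occurrence count for a B term to link
#'   (default 1: any co-occurrence constitutes a relationship).
#' @param min_bc_count minimum B-C co-occurrence count for an edge to
#'   survive filtering (default 2: singleton co-occurrences are removed as
#'   uninformative).
#' @param keep_direct keep C terms that directly co-occur with A (default
#'   TRUE: direct terms are displayed rather than suppressed, both as a
#'   sanity check on the ranking and because they may still be new to the
#'   investigator).
#' @return an object of class `discovery_query`.
#' @export
discovery_query <- function(a_term,
                            b_restriction = NULL,
                            c_semantic_types = "T047",
                            min_ab_count = 1L,
                            min_bc_count = 2L,
                            keep_direct = TRUE) {
  stopifnot(length(a_term) == 1L, is_cui(a_term),
            min_ab_count >= 1L, min_bc_count >= 1L,
            length(c_semantic_types) >= 1L)
  if (!is.null(b_restriction)) {
    b_restriction <- as.character(b_restriction)
    if (any(!is_cui(b_restriction)))
      stop("malformed CUI in b_restriction")
    if (a_term %in% b_restriction)
      stop("a_term cannot be its own linking term")
  }
  structure(list(a_term = a_term,
                 b_restriction = b_restriction,
                 c_semantic_types = as.character(c_semantic_types),
                 min_ab_count = as.integer(min_ab_count),
                 min_bc_count = as.integer(min_bc_count),
                 keep_direct = isTRUE(keep_direct)),
            class = "discovery_query")
}

#' Link B terms to the start term
#'
#' A candidate B term links to A iff their co-occurrence count reaches
#' `min_ab_count`. With a B restriction, candidates below threshold are
#' reported in `excluded` — they cannot serve as linking terms because no
#' A-B link exists. Without a restriction, every concept co-occurring with
#' A at or above threshold links.
#'
#' @param query a `discovery_query`.
#' @param matrix a `cooc_matrix`.
#' @return a `linked_term_set`: list with `links` (named integer vector,
#'   CUI -> A-B count) and `excluded` (character vector of below-threshold
#'   restricted candidates).
#' @export
link_b_terms <- function(query, matrix) {
  stopifnot(inherits(query, "discovery_query"), inherits(matrix, "cooc_matrix"))
  a <- query$a_term
  dt <- matrix$pairs
  nbr <- rbind(dt[dt$cui_a == a, list(cui = cui_b, count = count)],
               dt[dt$cui_b == a, list(cui = cui_a, count = count)])
  ab <- setNames(nbr$count, nbr$cui)
  if (is.null(query$b_restriction)) {
    links <- ab[ab >= query$min_ab_count]
    excluded <- character()
  } else {
    cand <- query$b_restriction
    counts <- ifelse(cand %in% names(ab), ab[cand], 0L)
    counts <- setNames(as.integer(counts), cand)
    links <- counts[counts >= query$min_ab_count]
    excluded <- cand[counts < query$min_ab_count]
  }
  links <- links[order(names(links), method = "radix")]
  structure(list(links = links, excluded = excluded),
            class = "linked_term_set")
}

#' Expand linked B terms to candidate C terms
#'
#' Every concept co-occurring (count >= 1, pre-filter) with at least one
#' linked B term becomes a C candidate; the A term itself is retained as a
#' candidate when it co-occurs with linked B terms, so that the keep_direct
#' policy can be applied later rather than silently here.
#'
#' @param linked a `linked_term_set`.
#' @param matrix a `cooc_matrix`.
#' @return data.table with columns `c_term`, `b_term`, `bc_count`, one row
#'   per surviving B-C edge (the tabular form of the map
#'   c_term -> b_term -> count).
#' @export
generate_c_candidates <- function(linked, matrix) {
  stopifnot(inherits(linked, "linked_term_set"), inherits(matrix, "cooc_matrix"))
  bs <- names(linked$links)
  dt <- matrix$pairs
  if (length(bs) == 0 || nrow(dt) == 0)
    return(data.table(c_term = character(), b_term = character(),
                      bc_count = integer()))
  # a matrix row contributes an edge in each direction in which it touches
  # a linked B term (both directions when both endpoints are linked Bs)
  out <- rbind(
    dt[dt$cui_a %in% bs, list(c_term = cui_b, b_term = cui_a, bc_count = count)],
    dt[dt$cui_b %in% bs, list(c_term = cui_a, b_term = cui_b, bc_count = count)]
  )
  setorderv(out, c("c_term", "b_term"))
  out[]
}

#' Filter candidate C terms
#'
#' Applies, in order: (1) the co-occurrence-count filter — B-C edges with
#' count below `min_bc_count` are dropped (singleton co-occurrences are too
#' weak to constitute evidence); (2) C terms left with no edges disappear;
#' (3) the semantic-type filter — C terms whose vocabulary entry carries
#' none of the queried types are dropped, and concepts absent from the
#' vocabulary cannot pass a type-membership test so they are dropped too;
#' (4) if `keep_direct` is FALSE, C terms directly co-occurring with A are
#' dropped (this branch needs the co-occurrence `matrix` to decide
#' directness).
#'
#' @param candidates candidate edge table from [generate_c_candidates()].
#' @param query a `discovery_query`.
#' @param vocab a `concept_vocabulary`.
#' @param matrix the `cooc_matrix`, required only when
#'   `query$keep_direct` is FALSE.
#' @return filtered candidate edge table, same columns.
#' @export
apply_filters <- function(candidates, query, vocab, matrix = NULL) {
  stopifnot(inherits(query, "discovery_query"),
            inherits(vocab, "concept_vocabulary"))
  out <- as.data.table(candidates)
  out <- out[out$bc_count >= query$min_bc_count, ]
  if (nrow(out) > 0) {
    cs <- unique(out$c_term)
    ok <- cs[has_semantic_type(vocab, cs, query$c_semantic_types)]
    out <- out[out$c_term %in% ok, ]
  }
  if (!query$keep_direct && nrow(out) > 0) {
    if (is.null(matrix))
      stop("keep_direct = FALSE requires the co-occurrence matrix")
    cs <- setdiff(unique(out$c_term), query$a_term)
    direct <- cs[vapply(cs, function(cc)
      pair_count(matrix, query$a_term, cc) >= 1L, logical(1))]
    out <- out[!(out$c_term %in% c(direct, query$a_term)), ]
  }
  out[]
}

#' Rank candidate C terms by Linking Term Count
#'
#' LTC scores each target term by the number of unique linking (B) terms it
#' shares with the start term; no direct A-C co-occurrence is needed, which
#' is what makes the score usable for open discovery. Hypotheses are ordered
#' by LTC descending; within a hypothesis the B breakdown is ordered by B-C
#' count descending. Ties are broken by CUI ascending in both orderings so
#' results are fully deterministic.
#'
#' @param candidates filtered candidate edge table.
#' @param matrix optional `cooc_matrix` used to record each hypothesis's
#'   direct A-C co-occurrence count (0 when not supplied).
#' @param a_term the start term, required with `matrix`.
#' @return list of `hypothesis` objects, each with `c_term`, `ltc`,
#'   `b_breakdown` (data.table `b_term`, `bc_count`) and `direct_ac_count`.
#' @export
rank_by_ltc <- function(candidates, matrix = NULL, a_term = NULL) {
  cand <- as.data.table(candidates)
  if (nrow(cand) == 0) return(list())
  scores <- cand[, list(ltc = length(unique(b_term))), by = "c_term"]
  setorderv(scores, c("ltc", "c_term"), order = c(-1L, 1L))
  lapply(seq_len(nrow(scores)), function(k) {
    cc <- scores$c_term[k]
    br <- cand[cand$c_term == cc, list(b_term, bc_count)]
    setorderv(br, c("bc_count", "b_term"), order = c(-1L, 1L))
    direct <- if (!is.null(matrix) && !is.null(a_term) && cc != a_term)
      pair_count(matrix, a_term, cc) else 0L
    structure(list(c_term = cc, ltc = scores$ltc[k],
                   b_breakdown = br, direct_ac_count = as.integer(direct)),
              class = "hypothesis")
  })
}

#' Run the full ABC discovery pipeline
#'
#' Composes the four stages — B-term linking, C-candidate expansion,
#' count/semantic filtering, and LTC ranking — and retains each stage's
#' output in the result for reporting. Deterministic for fixed inputs. An
#' `a_term` unknown to the vocabulary is a warning (exploratory queries are
#' legitimate), not an error.
#'
#' @param query a `discovery_query`.
#' @param matrix a `cooc_matrix`.
#' @param vocab a `concept_vocabulary`.
#' @return a `discovery_result`: list with `query`, `linked`, `candidates`,
#'   `filtered`, `hypotheses`.
#' @export
run_discovery <- function(query, matrix, vocab) {
  stopifnot(inherits(query, "discovery_query"),
            inherits(matrix, "cooc_matrix"),
            inherits(vocab, "concept_vocabulary"))
  if (is.null(resolve_concept(vocab, query$a_term)))
    warning("start term ", query$a_term, " is not in the vocabulary")
  linked <- link_b_terms(query, matrix)
  candidates <- generate_c_candidates(linked, matrix)
  filtered <- apply_filters(candidates, query, vocab, matrix)
  hypotheses <- rank_by_ltc(filtered, matrix, query$a_term)
  structure(list(query = query, linked = linked, candidates = candidates,
                 filtered = filtered, hypotheses = hypotheses),
            class = "discovery_result")
}

#' @export
print.discovery_result <- function(x, ...) {
  cat(sprintf("<discovery_result> A=%s | %d linked B terms | %d hypotheses\n",
              x$query$a_term, length(x$linked$links), length(x$hypotheses)))
  if (length(x$hypotheses) > 0) {
    top <- x$hypotheses[[1]]
    cat(sprintf("  top: %s (LTC %d)\n", top$c_term, top$ltc))
  }
  invisible(x)
}

#' LTC score of one target term in a discovery result
#'
#' @param result a `discovery_result`.
#' @param c_term target CUI.
#' @return integer LTC, or `NA` if the target was not ranked.
#' @export
ltc_of <- function(result, c_term) {
  for (h in result$hypotheses) if (h$c_term == c_term) return(h$ltc)
  NA_integer_
}
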