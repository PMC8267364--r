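#' Render the ranked hypothesis listing
#'
#' The display format a researcher reads: for each hypothesis a header line
#' `<ltc> - <cui> - <preferred term>`, followed by one tab-indented line per
#' linking term, `<bc_count><TAB><cui><TAB><preferred term>`, with linking
#' terms in descending co-occurrence order. This puts "via which B terms,
#' and how strongly" one glance below each ranked disease. Unknown concepts
#' render with preferred term "UNKNOWN". Output is deterministic.
#'
#' @param result a `discovery_result`.
#' @param vocab a `concept_vocabulary`.
#' @param max_terms render at most this many hypotheses (default all).
#' @return a single character string ("" for an empty result).
#' @export
render_hypothesis_list <- function(result, vocab, max_terms = Inf) {
  stopifnot(inherits(result, "discovery_result"),
            inherits(vocab, "concept_vocabulary"))
  hyps <- result$hypotheses
  if (length(hyps) == 0) return("")
  hyps <- hyps[seq_len(min(length(hyps), max_terms))]
  blocks <- vapply(hyps, function(h) {
    header <- sprintf("%d - %s - %s", h$ltc, h$c_term,
                      preferred_term_of(vocab, h$c_term))
    body <- sprintf("\t%d\t%s\t%s", h$b_breakdown$bc_count,
                    h$b_breakdown$b_term,
                    preferred_term_of(vocab, h$b_breakdown$b_term))
    paste(c(header, body), collapse = "\n")
  }, character(1))
  paste0(paste(blocks, collapse = "\n"), "\n")
}

#' LTC histogram from per-score term counts
#'
#' Builds the full score histogram — one row per LTC value from the maximum
#' down to 0 — from a table of per-score term counts. The score-0 row is the
#' remainder of the term universe: targets eligible under the semantic
#' filter that share no linking term at all, which by construction never
#' appear in a discovery result and must therefore be supplied via
#' `universe_size`.
#'
#' @param counts data.frame with columns `ltc` (distinct scores >= 1) and
#'   `n_terms`; scores with no terms may be omitted.
#' @param universe_size total number of eligible target terms (>= the
#'   number of scored terms).
#' @return data.frame with columns `ltc`, `n_terms`, `n_at_or_above`
#'   (cumulative count of terms scoring at least `ltc`), rows in descending
#'   score order.
#' @export
ltc_histogram_from_counts <- function(counts, universe_size) {
  counts <- as.data.frame(counts)
  stopifnot(all(c("ltc", "n_terms") %in% names(counts)))
  counts <- counts[counts$ltc >= 1L, , drop = FALSE]
  if (anyDuplicated(counts$ltc)) stop("duplicate LTC score in counts")
  n_scored <- sum(counts$n_terms)
  if (universe_size < n_scored)
    stop("universe_size (", universe_size,
         ") smaller than the number of scored terms (", n_scored, ")")
  max_ltc <- if (nrow(counts) > 0) max(counts$ltc) else 0L
  ltc <- seq.int(max_ltc, 0L)
  n_terms <- integer(length(ltc))
  n_terms[match(counts$ltc, ltc)] <- as.integer(counts$n_terms)
  n_terms[ltc == 0L] <- as.integer(universe_size - n_scored)
  data.frame(ltc = ltc, n_terms = n_terms, n_at_or_above = cumsum(n_terms))
}

#' LTC histogram of a discovery result
#'
#' @param result a `discovery_result`.
#' @param universe_size number of concepts eligible as targets (in a real
#'   run, the count of vocabulary entries carrying a queried semantic type).
#' @return see [ltc_histogram_from_counts()].
#' @export
ltc_histogram <- function(result, universe_size) {
  stopifnot(inherits(result, "discovery_result"))
  scores <- vapply(result$hypotheses, function(h) h$ltc, integer(1))
  scores <- scores[scores >= 1L]
  tab <- as.data.frame(table(scores), stringsAsFactors = FALSE)
  counts <- data.frame(ltc = as.integer(tab$scores),
                       n_terms = as.integer(tab$Freq))
  ltc_histogram_from_counts(counts, universe_size)
}

#' Threshold listing of ranked hypotheses
#'
#' The concise review listing: all hypotheses scoring at least `min_ltc`, in
#' result order (rendering never re-ranks), as (ltc, cui, preferred term)
#' rows — the form handed to a domain expert for manual review.
#'
#' @param result a `discovery_result`.
#' @param vocab a `concept_vocabulary`.
#' @param min_ltc minimum LTC score to include (>= 0).
#' @return data.frame with columns `ltc`, `cui`, `preferred_term`.
#' @export
threshold_listing <- function(result, vocab, min_ltc = 10L) {
  stopifnot(inherits(result, "discovery_result"), min_ltc >= 0L)
  keep <- Filter(function(h) h$ltc >= min_ltc, result$hypotheses)
  data.frame(
    ltc = vapply(keep, function(h) h$ltc, integer(1)),
    cui = vapply(keep, function(h) h$c_term, character(1)),
    preferred_term = preferred_term_of(
      vocab, vapply(keep, function(h) h$c_term, character(1)))
  )
}

#' Write a report table as TSV
#'
#' Plain 3-column TSV writer for the histogram and threshold listings.
#'
#' @param table a data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_report_tsv <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
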