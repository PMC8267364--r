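
# CUIs are 'C' followed by exactly 7 digits, as in the UMLS Metathesaurus.
.cui_pattern <- "^C[0-9]{7}$"

is_cui <- function(x) grepl(.cui_pattern, x)

#' Construct a concept corpus
#'
#' A corpus is an ordered collection of documents, each an ordered stream of
#' concept identifiers (CUIs). This emulates concept-mapped titles+abstracts:
#' stopwords are already gone and synonyms collapsed, so a document is just
#' the CUI sequence. Token positions are implicit: the i-th CUI of a document
#' sits at 0-based position i-1, with no gaps.
#'
#' @param doc_ids character vector of unique document identifiers.
#' @param tokens list of character vectors, one per document, each a sequence
#'   of CUIs (possibly empty).
#' @return an object of class `concept_corpus`.
#' @export
concept_corpus <- function(doc_ids = character(), tokens = list()) {
  doc_ids <- as.character(doc_ids)
  stopifnot(length(doc_ids) == length(tokens))
  if (anyDuplicated(doc_ids))
    stop("duplicate doc_id: ", paste(unique(doc_ids[duplicated(doc_ids)]), collapse = ", "))
  tokens <- lapply(tokens, as.character)
  bad <- vapply(tokens, function(tk) length(tk) > 0 && !all(is_cui(tk)), logical(1))
  if (any(bad))
    stop("malformed CUI token(s) in document(s): ", paste(doc_ids[bad], collapse = ", "))
  structure(list(doc_ids = doc_ids, tokens = tokens), class = "concept_corpus")
}

#' @export
print.concept_corpus <- function(x, ...) {
  cat(sprintf("<concept_corpus> %d documents, %d tokens\n",
              length(x$doc_ids), sum(lengths(x$tokens))))
  invisible(x)
}

#' @export
length.concept_corpus <- function(x) length(x$doc_ids)

#' Read a concept corpus file
#'
#' File format: UTF-8 text, one document per line, `doc_id<TAB>cui( cui)*`.
#' Blank lines are ignored and lines starting with `#` are comments. A line
#' may carry a doc_id and no tokens (empty document).
#'
#' In strict mode (default) any token not matching the CUI pattern aborts the
#' read. In lenient mode malformed tokens are dropped and tallied in the
#' `"n_dropped_tokens"` attribute of the returned corpus, mirroring how a
#' concept-mapping pipeline tolerates unmappable phrases. Duplicate doc_ids
#' are always an error.
#'
#' @param path path to a corpus file.
#' @param strict abort on malformed tokens (default TRUE)?
#' @return a `concept_corpus`; in lenient mode with attribute
#'   `n_dropped_tokens` (integer count of dropped tokens).
#' @export
read_corpus <- function(path, strict = TRUE) {
  if (!file.exists(path)) stop("corpus file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines)) & !startsWith(lines, "#")]
  n_dropped <- 0L
  doc_ids <- character(length(lines))
  tokens <- vector("list", length(lines))
  for (k in seq_along(lines)) {
    parts <- strsplit(lines[k], "\t", fixed = TRUE)[[1]]
    if (length(parts) < 1L || !nzchar(parts[1]))
      stop("malformed corpus line (no doc_id): ", lines[k])
    doc_ids[k] <- parts[1]
    tk <- if (length(parts) >= 2L && nzchar(parts[2])) {
      strsplit(parts[2], " ", fixed = TRUE)[[1]]
    } else character()
    tk <- tk[nzchar(tk)]
    ok <- is_cui(tk)
    if (!all(ok)) {
      if (strict)
        stop("malformed CUI token(s) on line for doc '", parts[1], "': ",
             paste(tk[!ok], collapse = ", "))
      n_dropped <- n_dropped + sum(!ok)
      tk <- tk[ok]
    }
    tokens[[k]] <- tk
  }
  corp <- concept_corpus(doc_ids, tokens)
  if (!strict) attr(corp, "n_dropped_tokens") <- n_dropped
  corp
}

#' Write a concept corpus file
#'
#' Inverse of [read_corpus()]: `read_corpus(write_corpus(c))` reproduces the
#' corpus token-for-token.
#'
#' @param corpus a `concept_corpus`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_corpus <- function(corpus, path) {
  stopifnot(inherits(corpus, "concept_corpus"))
  lines <- vapply(seq_along(corpus$doc_ids), function(k) {
    paste0(corpus$doc_ids[k], "\t", paste(corpus$tokens[[k]], collapse = " "))
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Load a concept vocabulary
#'
#' The vocabulary is a miniature Metathesaurus surrogate: a UTF-8 TSV with 4
#' columns `cui`, `preferred_term`, `semantic_types` (comma-separated type
#' codes like "T047"), `semantic_group` (e.g. "DISO"). A header line is
#' optional and detected by the first cell equalling `"cui"`.
#'
#' @param path path to a vocabulary TSV.
#' @return a `concept_vocabulary`: a data.table keyed by `cui` with columns
#'   `cui`, `preferred_term`, `semantic_types` (list column of character
#'   vectors), `semantic_group`.
#' @export
load_vocabulary <- function(path) {
  if (!file.exists(path)) stop("vocabulary file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines)) & !startsWith(lines, "#")]
  if (length(lines) > 0 && startsWith(lines[1], "cui\t")) lines <- lines[-1]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ncol_ok <- lengths(parts) == 4L
  if (!all(ncol_ok))
    stop("vocabulary line(s) without 4 tab-separated columns: ",
         paste(lines[!ncol_ok], collapse = " | "))
  dt <- data.table(
    cui = vapply(parts, `[`, character(1), 1L),
    preferred_term = vapply(parts, `[`, character(1), 2L),
    types_raw = vapply(parts, `[`, character(1), 3L),
    semantic_group = vapply(parts, `[`, character(1), 4L)
  )
  if (any(!is_cui(dt$cui)))
    stop("malformed CUI in vocabulary: ", paste(dt$cui[!is_cui(dt$cui)], collapse = ", "))
  if (anyDuplicated(dt$cui))
    stop("duplicate CUI in vocabulary: ",
         paste(unique(dt$cui[duplicated(dt$cui)]), collapse = ", "))
  if (any(!nzchar(trimws(dt$types_raw))))
    stop("empty semantic-type field for: ",
         paste(dt$cui[!nzchar(trimws(dt$types_raw))], collapse = ", "))
  dt[, "semantic_types" := lapply(strsplit(types_raw, ",", fixed = TRUE), trimws)]
  dt[, "types_raw" := NULL]
  setkeyv(dt, "cui")
  structure(dt, class = c("concept_vocabulary", class(dt)))
}

#' Look up a concept, tolerating absence
#'
#' Concept streams may legitimately contain CUIs the vocabulary does not
#' cover (in the motivating study several lab-identified metabolites had no
#' UMLS mapping at all). Absence is therefore not an error: the lookup
#' returns `NULL` as the absent-marker and never raises.
#'
#' @param vocab a `concept_vocabulary`.
#' @param cui a concept identifier.
#' @return a list with fields `cui`, `preferred_term`, `semantic_types`,
#'   `semantic_group`, or `NULL` if the concept is not in the vocabulary.
#' @export
resolve_concept <- function(vocab, cui) {
  stopifnot(inherits(vocab, "concept_vocabulary"), length(cui) == 1L)
  i <- match(cui, vocab$cui)
  if (is.na(i)) return(NULL)
  list(cui = vocab$cui[i],
       preferred_term = vocab$preferred_term[i],
       semantic_types = vocab$semantic_types[[i]],
       semantic_group = vocab$semantic_group[i])
}

# Preferred term for display; unknown concepts render as "UNKNOWN".
preferred_term_of <- function(vocab, cuis) {
  i <- match(cuis, vocab$cui)
  out <- vocab$preferred_term[i]
  out[is.na(i)] <- "UNKNOWN"
  out
}

# TRUE for each cui whose vocabulary entry carries at least one of `types`;
# unknown cuis are FALSE (they cannot pass a type-membership filter).
has_semantic_type <- function(vocab, cuis, types) {
  i <- match(cuis, vocab$cui)
  vapply(seq_along(cuis), function(k) {
    if (is.na(i[k])) return(FALSE)
    any(vocab$semantic_types[[i[k]]] %in% types)
  }, logical(1))
}
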