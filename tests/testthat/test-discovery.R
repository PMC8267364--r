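fx <- fixture_matrix()
fq <- fixture_query()

test_that("B-term linking retains the 17 co-occurring metabolites and excludes the rest", {
  linked <- link_b_terms(fq, fx$matrix)
  expect_length(linked$links, 17L)
  expect_setequal(linked$excluded, c("C2348307", "C0069409"))
  expect_true(all(linked$links >= fq$min_ab_count))

  # empty candidate set -> no links
  q0 <- discovery_query("C0018790", b_restriction = character())
  expect_length(link_b_terms(q0, fx$matrix)$links, 0L)

  # threshold above every A-B count -> everything excluded
  qhi <- discovery_query("C0018790", b_restriction = fq$b_restriction,
                         min_ab_count = 10000L)
  linked_hi <- link_b_terms(qhi, fx$matrix)
  expect_length(linked_hi$links, 0L)
  expect_setequal(linked_hi$excluded, fq$b_restriction)
})

test_that("unrestricted linking takes every concept co-occurring with A", {
  m <- cooc_matrix(data.frame(cui_a = c("C0000001", "C0000001", "C0000002"),
                              cui_b = c("C0000002", "C0000003", "C0000003"),
                              count = c(5L, 1L, 9L)))
  q <- discovery_query("C0000001")
  linked <- link_b_terms(q, m)
  expect_identical(linked$links,
                   c(C0000002 = 5L, C0000003 = 1L))
})

test_that("C-candidate expansion merges edges across linked B terms", {
  linked <- structure(list(links = c(C0000010 = 1L), excluded = character()),
                      class = "linked_term_set")
  m <- cooc_matrix(data.frame(cui_a = "C0000010", cui_b = "C0000020",
                              count = 5L))
  cand <- generate_c_candidates(linked, m)
  expect_identical(as.data.frame(cand),
                   data.frame(c_term = "C0000020", b_term = "C0000010",
                              bc_count = 5L))

  linked2 <- structure(list(links = c(C0000010 = 1L, C0000011 = 1L),
                            excluded = character()),
                       class = "linked_term_set")
  m2 <- cooc_matrix(data.frame(cui_a = c("C0000010", "C0000011"),
                               cui_b = "C0000020", count = c(5L, 2L)))
  cand2 <- generate_c_candidates(linked2, m2)
  expect_identical(cand2$bc_count[order(cand2$b_term)], c(5L, 2L))
  expect_identical(unique(cand2$c_term), "C0000020")
})

test_that("C-candidate expansion equals a brute-force scan of all concepts", {
  set.seed(21)
  for (rep in 1:10) {
    corp <- random_corpus(6, 15, vocab_size = 20L)
    m <- count_cooccurrences(corp, 8)
    all_cuis <- unique(c(m$pairs$cui_a, m$pairs$cui_b))
    if (length(all_cuis) < 3) next
    bs <- sample(all_cuis, 3)
    linked <- structure(list(links = setNames(rep(1L, 3), bs),
                             excluded = character()),
                        class = "linked_term_set")
    got <- as.data.frame(generate_c_candidates(linked, m))
    got <- got[order(got$c_term, got$b_term), ]
    rownames(got) <- NULL
    rows <- list()
    for (cc in all_cuis) for (b in bs) {
      if (cc == b) next
      k <- pair_count(m, cc, b)
      if (k >= 1L) rows[[length(rows) + 1L]] <-
          data.frame(c_term = cc, b_term = b, bc_count = k)
    }
    want <- do.call(rbind, rows)
    want <- want[order(want$c_term, want$b_term), ]
    rownames(want) <- NULL
    expect_identical(got, want)
  }
})

test_that("filters drop weak edges, empty targets, and wrong semantic types", {
  vf <- write_tmp_lines(c("C0000030\tTarget\tT047\tDISO",
                          "C0000031\tDrug\tT121\tCHEM"))
  vocab <- load_vocabulary(vf)
  q <- discovery_query("C0000001", min_bc_count = 2L)
  cand <- data.frame(c_term = c("C0000030", "C0000030", "C0000031"),
                     b_term = c("C0000010", "C0000011", "C0000010"),
                     bc_count = c(1L, 3L, 7L))
  out <- as.data.frame(apply_filters(cand, q, vocab))
  # weak edge gone, T121 target gone, count-3 edge kept
  expect_identical(out,
                   data.frame(c_term = "C0000030", b_term = "C0000011",
                              bc_count = 3L))
  # unknown-vocabulary targets are removed by the semantic filter
  cand_unk <- data.frame(c_term = "C0000099", b_term = "C0000010",
                         bc_count = 5L)
  expect_identical(nrow(apply_filters(cand_unk, q, vocab)), 0L)
})

test_that("count-2 edges survive the default singleton filter", {
  res <- run_discovery(fq, fx$matrix, fx$vocab)
  wa <- Filter(function(h) h$c_term == "C0043194", res$hypotheses)[[1]]
  expect_true("C0028375" %in% wa$b_breakdown$b_term)  # Norleucine, count 2
  expect_identical(min(wa$b_breakdown$bc_count), 2L)
})

test_that("LTC ranking reproduces the worked example ordering and breakdowns", {
  res <- run_discovery(fq, fx$matrix, fx$vocab)
  expect_identical(ltc_of(res, "C0342895"), 15L)
  expect_identical(ltc_of(res, "C0043194"), 14L)
  expect_identical(ltc_of(res, "C0018790"), 17L)
  cuis <- vapply(res$hypotheses, function(h) h$c_term, character(1))
  expect_lt(match("C0342895", cuis), match("C0043194", cuis))

  fe <- res$hypotheses[[match("C0342895", cuis)]]
  expect_identical(fe$b_breakdown$b_term[1], "C0556150")
  expect_identical(fe$b_breakdown$bc_count[1], 503L)
  wa <- res$hypotheses[[match("C0043194", cuis)]]
  expect_identical(wa$b_breakdown$b_term[1], "C0019602")
  expect_identical(wa$b_breakdown$bc_count[1], 508L)
})

test_that("ranking agrees with an independent set-cardinality recount", {
  set.seed(22)
  for (rep in 1:10) {
    sc <- plant_abc_scenario(n_b = 6,
                             bc_profile = sample.int(6, 4, replace = TRUE),
                             seed = rep)
    m <- count_cooccurrences(sc$corpus, 8)
    res <- run_discovery(sc$query, m, sc$vocab)
    want <- brute_force_ltc(res$filtered)
    got <- data.frame(c_term = vapply(res$hypotheses, `[[`, character(1), "c_term"),
                      ltc = vapply(res$hypotheses, `[[`, integer(1), "ltc"))
    expect_identical(got, want)
  }
})

test_that("every LTC is bounded by the linked-set size", {
  res <- run_discovery(fq, fx$matrix, fx$vocab)
  for (h in res$hypotheses) {
    expect_gte(h$ltc, 0L)
    expect_lte(h$ltc, length(res$linked$links))
  }
})

test_that("raising thresholds never raises any LTC and never adds hypotheses", {
  sc <- plant_abc_scenario(n_b = 5, bc_profile = c(5, 3, 2), seed = 3)
  m <- count_cooccurrences(sc$corpus, 8)
  base <- run_discovery(sc$query, m, sc$vocab)
  for (bump in list(c(2L, 2L), c(1L, 3L), c(3L, 3L))) {
    q2 <- discovery_query(sc$query$a_term, sc$query$b_restriction,
                          sc$query$c_semantic_types,
                          min_ab_count = bump[1], min_bc_count = bump[2])
    res2 <- run_discovery(q2, m, sc$vocab)
    base_cuis <- vapply(base$hypotheses, `[[`, character(1), "c_term")
    for (h in res2$hypotheses) {
      expect_true(h$c_term %in% base_cuis)
      expect_lte(h$ltc, ltc_of(base, h$c_term))
    }
  }
})

test_that("ranking is invariant under document order and doc_id relabeling", {
  sc <- plant_abc_scenario(n_b = 4, bc_profile = c(4, 2), seed = 5)
  corp <- sc$corpus
  set.seed(99)
  ord <- sample.int(length(corp$doc_ids))
  shuffled <- concept_corpus(sprintf("z%05d", seq_along(ord)),
                             corp$tokens[ord])
  r1 <- run_discovery(sc$query, count_cooccurrences(corp, 8), sc$vocab)
  r2 <- run_discovery(sc$query, count_cooccurrences(shuffled, 8), sc$vocab)
  strip <- function(r) lapply(r$hypotheses, function(h)
    list(h$c_term, h$ltc, as.data.frame(h$b_breakdown)))
  expect_identical(strip(r1), strip(r2))
})

test_that("an unknown start term warns and yields an empty result", {
  expect_warning(
    res <- run_discovery(discovery_query("C8888888"), fx$matrix, fx$vocab),
    "not in the vocabulary")
  expect_length(res$hypotheses, 0L)
})

test_that("an empty matrix yields an empty result", {
  res <- run_discovery(fq, cooc_matrix(), fx$vocab)
  expect_length(res$hypotheses, 0L)
  expect_length(res$linked$links, 0L)
})
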