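test_that("planted pair counts are recovered exactly by recounting", {
  sp <- plant_spec(data.frame(cui_a = "C0556150", cui_b = "C0342895",
                              count = 503L), seed = 1L)
  m <- count_cooccurrences(generate_corpus(sp), sp$window_size)
  expect_identical(pair_count(m, "C0556150", "C0342895"), 503L)

  sp3 <- plant_spec(data.frame(cui_a = "C2348386", cui_b = "C0342895",
                               count = 3L), seed = 1L)
  m3 <- count_cooccurrences(generate_corpus(sp3), 8)
  expect_identical(pair_count(m3, "C2348386", "C0342895"), 3L)

  expect_length(generate_corpus(plant_spec()), 0L)
})

test_that("plant recovery holds for random specs across seeds, with noise", {
  set.seed(31)
  for (rep in 1:15) {
    n_pairs <- sample.int(6, 1)
    cuis <- sprintf("C%07d", sample.int(500, 2 * n_pairs))
    pc <- data.frame(cui_a = cuis[seq_len(n_pairs)],
                     cui_b = cuis[n_pairs + seq_len(n_pairs)],
                     count = sample.int(20, n_pairs, replace = TRUE))
    for (seed in c(1L, 7L, 123L)) {
      sp <- plant_spec(pc, noise_vocab_size = 20L, noise_documents = 5L,
                       noise_doc_length = 12L, seed = seed)
      m <- count_cooccurrences(generate_corpus(sp), sp$window_size)
      for (i in seq_len(n_pairs))
        expect_identical(pair_count(m, pc$cui_a[i], pc$cui_b[i]),
                         pc$count[i])
      # noise never contaminates planted CUIs
      planted <- unique(c(pc$cui_a, pc$cui_b))
      touching <- m$pairs[m$pairs$cui_a %in% planted |
                            m$pairs$cui_b %in% planted, ]
      expect_true(all(touching$cui_a %in% planted) &&
                    all(touching$cui_b %in% planted))
    }
  }
})

test_that("generation is seed-deterministic and seed-sensitive only in order", {
  pc <- data.frame(cui_a = c("C0000001", "C0000003"),
                   cui_b = c("C0000002", "C0000004"), count = c(4L, 2L))
  sp1 <- plant_spec(pc, noise_vocab_size = 5L, noise_documents = 3L, seed = 10L)
  c1 <- generate_corpus(sp1)
  c2 <- generate_corpus(sp1)
  expect_identical(c1$tokens, c2$tokens)
  expect_identical(c1$doc_ids, c2$doc_ids)

  sp2 <- plant_spec(pc, noise_vocab_size = 5L, noise_documents = 3L, seed = 11L)
  c3 <- generate_corpus(sp2)
  m1 <- count_cooccurrences(c1, 8)
  m3 <- count_cooccurrences(c3, 8)
  for (i in 1:2)
    expect_identical(pair_count(m1, pc$cui_a[i], pc$cui_b[i]),
                     pair_count(m3, pc$cui_a[i], pc$cui_b[i]))
})

test_that("spec validation rejects diagonals, bad counts, and range clashes", {
  expect_error(plant_spec(data.frame(cui_a = "C0000001", cui_b = "C0000001",
                                     count = 1L)), "diagonal")
  expect_error(plant_spec(data.frame(cui_a = "C0000001", cui_b = "C0000002",
                                     count = 0L)), ">= 1")
  expect_error(plant_spec(data.frame(cui_a = "C9900001", cui_b = "C0000002",
                                     count = 1L)), "reserved")
})

test_that("planted ABC scenarios rank targets by their designed link counts", {
  sc <- plant_abc_scenario(n_b = 5, bc_profile = c(5, 3), seed = 2)
  m <- count_cooccurrences(sc$corpus, 8)
  res <- run_discovery(sc$query, m, sc$vocab)
  c1 <- sc$planted$c_terms[1]; c2 <- sc$planted$c_terms[2]
  expect_identical(ltc_of(res, c1), 5L)
  expect_identical(ltc_of(res, c2), 3L)
  cuis <- vapply(res$hypotheses, `[[`, character(1), "c_term")
  expect_lt(match(c1, cuis), match(c2, cuis))
  # no direct A-C co-occurrence was planted
  expect_identical(pair_count(m, sc$planted$a_term, c1), 0L)

  expect_length(run_discovery(plant_abc_scenario(0)$query,
                              count_cooccurrences(plant_abc_scenario(0)$corpus, 8),
                              plant_abc_scenario(0)$vocab)$hypotheses, 0L)
})

test_that("tied planted targets resolve deterministically by CUI order", {
  sc <- plant_abc_scenario(n_b = 5, bc_profile = c(5, 5), seed = 4)
  res <- run_discovery(sc$query, count_cooccurrences(sc$corpus, 8), sc$vocab)
  cuis <- vapply(res$hypotheses, `[[`, character(1), "c_term")
  tied <- cuis[cuis %in% sc$planted$c_terms]
  expect_identical(tied, sort(sc$planted$c_terms))
})

test_that("infeasible profiles are rejected", {
  expect_error(plant_abc_scenario(2, bc_profile = c(3)), "infeasible")
})

test_that("the packaged fixture carries the printed edge structure", {
  fx <- fixture_matrix()
  expect_identical(pair_count(fx$matrix, "C0019602", "C0043194"), 508L)
  expect_identical(pair_count(fx$matrix, "C0556150", "C0342895"), 503L)
  expect_identical(pair_count(fx$matrix, "C0018790", "C2348307"), 0L)
  expect_identical(pair_count(fx$matrix, "C0018790", "C0069409"), 0L)
})
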