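# Atom mapping, RDM extraction and similarity scoring.

test_that("self-mapping covers the whole graph and unrelated elements map empty", {
  withr::with_seed(21, {
    g <- random_test_graph(7, "g")
    m <- map_atoms(reactant_pair(g, g))
    expect_equal(m$score, 7L)
    expect_equal(m$mode, "exact")
  })
  methane <- compound_graph("m", "C")
  water <- compound_graph("w", "O")
  m <- map_atoms(reactant_pair(methane, water))
  expect_equal(m$score, 0L)
})

test_that("bond orders are not a mapping constraint (ethanol vs acetaldehyde)", {
  m <- map_atoms(reactant_pair(ethanol_graph(), acetaldehyde_graph()))
  # brute-force derived: all three heavy atoms map despite the C-O / C=O change
  expect_equal(m$score, 3L)
  expect_equal(unname(m$pairs[, "product"]), c(0L, 1L, 2L))
})

test_that("exact mapping size equals the brute-force oracle on random pairs", {
  withr::with_seed(42, {
    for (rep in 1:40) {
      g1 <- random_test_graph(sample(2:8, 1), "g1")
      g2 <- random_test_graph(sample(2:8, 1), "g2")
      m <- map_atoms(reactant_pair(g1, g2), mode = "exact")
      expect_equal(m$score, oracle_mcs_size(g1, g2),
                   info = sprintf("rep %d", rep))
    }
  })
})

test_that("greedy fallback is used above the size cap and labeled", {
  withr::with_seed(5, {
    g <- random_test_graph(12, "g")
    m <- map_atoms(reactant_pair(g, g), mode = "auto", size_cap = 10L)
    expect_equal(m$mode, "greedy")
    expect_gt(m$score, 0L)
    valid <- m$pairs[, 1] >= 0 & m$pairs[, 1] < 12
    expect_true(all(valid))
  })
})

test_that("RDM extraction finds exactly the changed-bond centers", {
  pair <- reactant_pair(ethanol_graph(), acetaldehyde_graph())
  pat <- extract_rdm(pair, map_atoms(pair))
  # hand-traced: the two atoms incident to the order-changing C-O bond are
  # the only centers
  expect_equal(length(pat$triples), 2L)
  rs <- vapply(pat$triples, function(t) t$r[1], character(1))
  expect_setequal(rs, c("C.sp3.ac.h1", "O.sp3.ac.h0"))
  # identical graphs: empty pattern
  p2 <- reactant_pair(ethanol_graph(), ethanol_graph())
  expect_equal(length(extract_rdm(p2, map_atoms(p2))$triples), 0L)
})

test_that("a pendant atom unique to one side lands in its neighbor's D set", {
  propanol <- compound_graph("pol", c("C", "C", "C", "O"),
                             data.frame(a = 0:2, b = 1:3, order = "1"))
  propane <- compound_graph("pan", c("C", "C", "C"),
                            data.frame(a = 0:1, b = 1:2, order = "1"))
  pair <- reactant_pair(propanol, propane)
  pat <- extract_rdm(pair, map_atoms(pair))
  expect_equal(length(pat$triples), 1L)
  expect_equal(pat$triples[[1]]$d, "O.sp3.ac.h0")
})

test_that("extract_rdm rejects a mapping that does not fit the pair", {
  pair <- reactant_pair(ethanol_graph(), acetaldehyde_graph())
  bad <- map_atoms(pair)
  bad$pairs[1, 2] <- 2L  # carbon mapped onto oxygen
  expect_error(extract_rdm(pair, bad), class = "enzrepo_contract_error")
})

test_that("triple similarity follows the weighted R/D/M formula", {
  t1 <- enzrepo:::rdm_triple("C.sp3.ac.h0", "C.sp2.ac.h0",
                             d_set = "O.sp3.ac.h0",
                             m_set = "C.sp3.ac.h0>C.sp3.ac.h0")
  expect_equal(triple_similarity(t1, t1), 1.0)
  # same R change, disjoint non-empty D and M
  t2 <- enzrepo:::rdm_triple("C.sp3.ac.h0", "C.sp2.ac.h0",
                             d_set = "N.sp3.ac.h0",
                             m_set = "O.sp3.ac.h0>O.sp3.ac.h0")
  expect_equal(triple_similarity(t1, t2), 0.5)
  # different R change, both D and M empty: jaccard(empty, empty) = 1
  t3 <- enzrepo:::rdm_triple("C.sp3.ac.h0", "C.sp2.ac.h0", character(), character())
  t4 <- enzrepo:::rdm_triple("O.sp3.ac.h0", "O.sp2.ac.h0", character(), character())
  expect_equal(triple_similarity(t3, t4), 0.5)
  expect_error(triple_similarity(t1, t2, weights = c(1, 1, 1)),
               class = "enzrepo_config_error")
})

test_that("pattern similarity handles degenerate sizes and duplicates", {
  p <- random_pattern(3)
  expect_equal(pattern_similarity(p, p)$value, 1.0)
  empty <- pattern_obj(list())
  expect_equal(pattern_similarity(empty, empty)$value, 1.0)
  expect_equal(pattern_similarity(p, empty)$value, 0.0)
  # 2 identical triples vs 1 of them: brute-force over matchings gives
  # 1 / max(2, 1) = 0.5
  t <- enzrepo:::rdm_triple("C.sp3.ac.h0", "C.sp2.ac.h0", character(), character())
  expect_equal(pattern_similarity(pattern_obj(list(t, t)),
                                  pattern_obj(list(t)))$value, 0.5)
  mismatched <- p
  mismatched$vocabulary <- "other-vocab"
  expect_error(pattern_similarity(p, mismatched), "vocabular")
})

test_that("pattern similarity is symmetric, bounded, 1 iff equal multisets, and matches brute force", {
  withr::with_seed(77, {
    for (rep in 1:150) {
      p <- random_pattern()
      q <- if (runif(1) < 0.3) pattern_obj(sample(p$triples)) else random_pattern()
      spq <- pattern_similarity(p, q)$value
      sqp <- pattern_similarity(q, p)$value
      expect_equal(spq, sqp, tolerance = 1e-12)
      expect_gte(spq, 0); expect_lte(spq, 1)
      expect_equal(spq == 1, pattern_key(p) == pattern_key(q))
      n <- length(p$triples); m <- length(q$triples)
      if (n > 0 && m > 0) {
        W <- outer(seq_len(n), seq_len(m), Vectorize(function(i, j)
          triple_similarity(p$triples[[i]], q$triples[[j]])))
        expect_equal(spq, oracle_best_matching(W) / max(n, m),
                     tolerance = 1e-9)
      }
    }
  })
})

test_that("reaction scoring is invariant under atom-index permutation", {
  # permuting the atom indices of a real substrate/product pair must not
  # change its similarity to any other reaction
  gen <- generate_database(generator_config(seed = 62, n_plant_reactions = 6,
                                            n_planted_analogs = 6))
  withr::with_seed(9, {
    rids <- names(gen$db$reactions)
    for (rep in 1:12) {
      q <- reactant_pair_of(gen$db, sample(rids, 1))
      t <- reactant_pair_of(gen$db, sample(rids, 1))
      base <- score_reaction_pair(q, t)$value
      s2 <- permute_atoms(q$substrate, sample(nrow(q$substrate$atoms)))
      p2 <- permute_atoms(q$product, sample(nrow(q$product$atoms)))
      expect_equal(score_reaction_pair(reactant_pair(s2, p2), t)$value, base,
                   tolerance = 1e-12)
    }
  })
})

test_that("RDM patterns survive the canonical JSON round trip", {
  pair <- reactant_pair(ethanol_graph(), acetaldehyde_graph())
  pat <- extract_rdm(pair, map_atoms(pair))
  json <- rdm_pattern_to_json(pat)
  back <- rdm_pattern_from_json(json)
  expect_equal(pattern_key(back), pattern_key(pat))
  expect_equal(back$vocabulary, ATOM_TYPE_VOCABULARY)
  expect_identical(rdm_pattern_to_json(back), json)
})
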