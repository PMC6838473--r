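# The synthetic-database generator.

test_that("identical configs reproduce byte-identical outputs", {
  g1 <- generate_database(generator_config(seed = 4))
  g2 <- generate_database(generator_config(seed = 4))
  expect_identical(g1$db, g2$db)
  expect_identical(g1$manifest, g2$manifest)
  f1 <- generate_fasta(generator_config(seed = 4))
  f2 <- generate_fasta(generator_config(seed = 4))
  expect_identical(f1, f2)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_database(g1$db, d1, manifest = g1$manifest, tree = g1$tree, fasta = f1)
  write_database(g2$db, d2, manifest = g2$manifest, tree = g2$tree, fasta = f2)
  for (f in list.files(d1)) {
    expect_identical(readBin(file.path(d1, f), "raw", file.size(file.path(d1, f))),
                     readBin(file.path(d2, f), "raw", file.size(file.path(d2, f))),
                     info = f)
  }
})

test_that("per-component substreams isolate configuration changes", {
  base <- generate_database(generator_config(seed = 4))
  fewer <- generate_database(generator_config(seed = 4,
                                              n_bacterial_reactions = 2))
  for (rid in grep("^R1", names(base$db$reactions), value = TRUE)) {
    expect_identical(fewer$db$reactions[[rid]], base$db$reactions[[rid]])
    expect_identical(fewer$db$compounds[[paste0(rid, ".s")]],
                     base$db$compounds[[paste0(rid, ".s")]])
  }
})

test_that("planted pairs score exactly 1 at perturbation 0", {
  gen <- generate_database(generator_config(seed = 12))
  cfg <- score_config(cache = rdm_cache())
  for (p in gen$manifest$pairs) {
    s <- score_reaction_pair(reactant_pair_of(gen$db, p$query),
                             reactant_pair_of(gen$db, p$analog), cfg)
    expect_equal(s$value, 1.0)
  }
})

test_that("generated databases have the configured taxonomic composition", {
  cfg <- generator_config(seed = 31, n_plant_reactions = 6,
                          n_planted_analogs = 4, n_shared_reactions = 2,
                          n_orphan_plant_reactions = 3)
  gen <- generate_database(cfg)
  expect_true(validate_reaction_db(gen$db))
  status <- vapply(names(gen$db$reactions), function(rid)
    classify_reaction(rid, "plant", gen$db)$status, character(1))
  expect_equal(sum(status == "orphan-specific"), 3L)
  # every reaction with any non-plant gene is "shared" relative to plant:
  # the analogs, the bacterial background, and the mixed-taxon reactions
  expect_equal(sum(status == "shared"), 4L + 10L + 2L)
  expect_equal(sum(status == "specific"), 6L)
  expect_true(all(startsWith(names(status)[status == "specific"], "R1")))
})

test_that("infeasible configurations fail naming the violated constraint", {
  expect_error(generator_config(n_planted_analogs = 31,
                                n_plant_reactions = 40),
               "distinct site signatures")
  expect_error(generator_config(n_planted_analogs = 5, n_plant_reactions = 4),
               "exceeds n_plant_reactions")
  expect_error(generator_config(compound_size = c(1, 1)),
               "compound_size range too small")
  expect_error(generator_config(n_plant_reactions = -1), "counts must be")
})

test_that("protein generator controls pairwise identity by substitution rate", {
  cfg <- generator_config(seed = 20, n_candidate_seqs = 8,
                          substitution_rates = c(0, 0.1, 0.2, 0.7))
  fa <- generate_fasta(cfg)
  expect_equal(length(fa$candidates), 8L)
  for (i in seq_len(nrow(fa$pairs))) {
    r <- fa$pairs$rate[i]
    rep <- pairwise_identity(fa$candidates[[fa$pairs$candidate[i]]],
                             fa$known[[fa$pairs$source[i]]])
    if (r == 0) {
      expect_equal(rep$identity, 100)
    } else if (r <= 0.2) {
      # target identity 100 (1 - r), within +/- 5 points at length 300
      expect_lt(abs(rep$identity - 100 * (1 - r)), 5)
    } else {
      # near-random or not aligned
      expect_true(!rep$aligned || rep$identity < 50)
    }
  }
})

test_that("database directories round-trip through write and read", {
  gen <- generate_database(generator_config(seed = 8))
  dir <- withr::local_tempdir()
  write_database(gen$db, dir, manifest = gen$manifest, tree = gen$tree)
  back <- read_database(dir)
  expect_equal(sort(names(back$db$reactions)), sort(names(gen$db$reactions)))
  expect_identical(back$manifest, gen$manifest)
  expect_equal(sort(back$tree$tip.label), sort(gen$tree$tip.label))
  r1 <- gen$db$reactions[[1]]$reaction_id
  expect_equal(back$db$reactions[[r1]]$cluster_ids,
               gen$db$reactions[[r1]]$cluster_ids)
  expect_equal(back$db$compounds[[paste0(r1, ".s")]]$atoms$atom_type,
               gen$db$compounds[[paste0(r1, ".s")]]$atoms$atom_type)
})
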