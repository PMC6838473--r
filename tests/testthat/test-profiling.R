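# Organism profiles, tree annotation, and the sequence-independence check.

test_that("per-organism aggregation counts reactions, not genes", {
  gen <- generate_database(generator_config(seed = 55))
  res <- run_screen(gen$db, "plant", "bacteria", 0.4)
  prof <- aggregate_by_organism(res, gen$db)
  expect_true(all(prof$matrix %in% 0:1))
  expect_equal(unname(prof$marginals), unname(rowSums(prof$matrix)))
  # recompute one organism independently from the candidate table
  org <- names(prof$marginals)[which.max(prof$marginals)]
  qs <- unique(res$candidates$query_reaction_id[vapply(
    res$candidates$genes, function(g) org %in% g$organism, logical(1))])
  expect_equal(unname(prof$marginals[org]), length(qs))
  # permutation invariance of the candidate input order
  res2 <- res
  perm <- rev(seq_len(nrow(res2$candidates)))
  res2$candidates <- res2$candidates[perm, ]
  expect_identical(aggregate_by_organism(res2, gen$db)$matrix, prof$matrix)
  # empty screen: all-zero profile
  suppressWarnings(resE <- run_screen(tiny_db(), "other", "bacteria", 0.4))
  profE <- aggregate_by_organism(resE, tiny_db())
  expect_true(all(profE$matrix == 0L))
})

test_that("clade rollups conserve counts at every internal node", {
  gen <- generate_database(generator_config(seed = 55))
  res <- run_screen(gen$db, "plant", "bacteria", 0.4)
  prof <- aggregate_by_organism(res, gen$db)
  roll <- clade_rollup(prof, gen$tree)
  ntip <- length(gen$tree$tip.label)
  for (node in unique(gen$tree$edge[, 1])) {
    children <- gen$tree$edge[gen$tree$edge[, 1] == node, 2]
    expect_equal(roll$count[node], sum(roll$count[children]))
  }
  expect_equal(sum(roll$count[seq_len(ntip)]), sum(prof$marginals))
})

test_that("tree annotation export is byte-stable and zero-fills missing leaves", {
  gen <- generate_database(generator_config(seed = 55))
  res <- run_screen(gen$db, "plant", "bacteria", 0.4)
  prof <- aggregate_by_organism(res, gen$db)
  p1 <- withr::local_tempfile(fileext = ".txt")
  p2 <- withr::local_tempfile(fileext = ".txt")
  export_itol_heatmap(prof, gen$tree, p1)
  export_itol_heatmap(prof, gen$tree, p2)
  expect_identical(readBin(p1, "raw", file.size(p1)),
                   readBin(p2, "raw", file.size(p2)))
  lines <- readLines(p1)
  expect_equal(sum(seq_along(lines) > which(lines == "DATA")),
               length(gen$tree$tip.label))
  stranger <- ape::read.tree(text = "(bac01:1,zzz99:1);")
  p3 <- withr::local_tempfile(fileext = ".txt")
  expect_warning(export_itol_heatmap(prof, stranger, p3), "zzz99")
  zz <- strsplit(grep("^zzz99", readLines(p3), value = TRUE), "\t")[[1]]
  expect_true(all(zz[-1] == "0"))
})

test_that("identical sequences align at identity 100 and coverage 100", {
  r <- pairwise_identity("MKVLLTA", "MKVLLTA")
  expect_true(r$aligned)
  expect_equal(r$identity, 100)
  expect_equal(r$coverage, 100)
})

test_that("the textbook pair matches the independent DP oracle", {
  a <- "HEAGAWGHEE"; b <- "PAWHEAE"
  r <- pairwise_identity(a, b)
  o <- oracle_sw(a, b, blosum62)
  expect_equal(r$score, o$score)
  expect_equal(r$identity, o$identity)
  expect_equal(r$coverage, o$coverage)
})

test_that("alignment equals the DP oracle on random pairs and degenerates cleanly", {
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  withr::with_seed(31, {
    for (rep in 1:60) {
      a <- paste(sample(aa, sample(5:60, 1), replace = TRUE), collapse = "")
      b <- paste(sample(aa, sample(5:60, 1), replace = TRUE), collapse = "")
      r <- pairwise_identity(a, b)
      o <- oracle_sw(a, b, blosum62)
      expect_equal(r$aligned, o$aligned)
      expect_equal(r$score, o$score)
      expect_equal(r$identity, o$identity, tolerance = 1e-12)
      expect_equal(r$coverage, o$coverage, tolerance = 1e-12)
    }
  })
  # all-mismatch short peptides with no positive-scoring window
  r <- pairwise_identity("WWW", "PPP")
  expect_false(r$aligned)
  expect_equal(r$identity, 0)
  expect_equal(r$coverage, 0)
  expect_error(pairwise_identity("MK#V", "MKV"), "position 3")
})

test_that("sequence-independence reports mirror the alignment table shape", {
  fa <- generate_fasta(generator_config(seed = 9))
  path <- withr::local_tempfile(fileext = ".tsv")
  df <- sequence_independence_report(fa$candidates, fa$known, path)
  expect_equal(nrow(df), length(fa$candidates) * length(fa$known))
  # the rate-0 candidate is an exact copy of its source
  id_row <- df[df$query == "CAND01" & df$target == fa$pairs$source[1], ]
  expect_equal(id_row$identity, "100.0")
  miss <- c(fa$candidates, BROKEN = NA_character_)
  warns <- capture_warnings(df2 <- sequence_independence_report(miss, fa$known))
  expect_true(all(grepl("missing sequence for candidate BROKEN", warns)))
  expect_equal(length(warns), length(fa$known))
  expect_true(all(df2[df2$query == "BROKEN", "identity"] == "missing"))
})
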