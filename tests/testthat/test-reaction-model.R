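# Compound parsing, atom typing, and database model / I-O.

test_that("molfile parsing strips hydrogens and assigns expected types", {
  g <- parse_compound(methane_molfile(), "methane")
  expect_equal(nrow(g$atoms), 1L)
  expect_equal(nrow(g$bonds), 0L)
  expect_equal(g$atoms$atom_type, "C.sp3.ac.h0")
  expect_equal(g$atoms$n_h, 4L)

  b <- parse_compound(benzene_molfile(), "benzene")
  expect_equal(nrow(b$atoms), 6L)
  expect_equal(nrow(b$bonds), 6L)
  expect_true(all(b$atoms$ring_flag))
  expect_true(all(b$atoms$atom_type == "C.ar.rg.h0"))

  e <- parse_compound(ethanol_molfile(), "ethanol")
  expect_equal(nrow(e$atoms), 3L)
  expect_equal(nrow(e$bonds), 2L)
  expect_equal(e$atoms$n_h, c(3L, 2L, 1L))
  # hand-applied typing rules: methyl carbon has no hetero neighbor, the
  # hydroxyl carbon has one (the oxygen)
  expect_equal(e$atoms$atom_type[1], "C.sp3.ac.h0")
  expect_equal(e$atoms$atom_type[2], "C.sp3.ac.h1")
  expect_false(e$atoms$atom_type[1] == e$atoms$atom_type[2])
})

test_that("malformed molfiles fail with line-numbered diagnostics", {
  bad_counts <- methane_molfile()
  bad_counts[4] <- "  x  0  0"
  expect_error(parse_compound(bad_counts, "m"), "line 4")
  truncated <- methane_molfile()[1:6]
  expect_error(parse_compound(truncated, "m"), "count mismatch")
  bad_elem <- methane_molfile()
  bad_elem[5] <- sub(" C  ", " Qq ", bad_elem[5])
  expect_error(parse_compound(bad_elem, "m"), "unknown element.*line 5")
  bad_bond <- methane_molfile()
  bad_bond[10] <- "  1  9  1  0  0  0  0"
  expect_error(parse_compound(bad_bond, "m"), "non-existent atom at line 10")
})

test_that("atom typing is idempotent and permutation-equivariant", {
  withr::with_seed(11, {
    for (rep in 1:20) {
      g <- random_test_graph(sample(2:9, 1), "g")
      expect_identical(assign_atom_types(g), g)
      perm <- sample(nrow(g$atoms))
      h <- permute_atoms(g, perm)
      expect_identical(h$atoms$atom_type, g$atoms$atom_type[perm])
      expect_identical(h$atoms$ring_flag, g$atoms$ring_flag[perm])
    }
  })
})

test_that("SDF round-trips through write and parse", {
  withr::with_seed(3, {
    cmps <- list(random_test_graph(5, "A"), random_test_graph(7, "B"))
    names(cmps) <- c("A", "B")
    path <- withr::local_tempfile(fileext = ".sdf")
    write_sdf(cmps, path)
    back <- parse_sdf(path, is_path = TRUE)
    expect_equal(names(back), c("A", "B"))
    expect_equal(back$A$atoms$atom_type, cmps$A$atoms$atom_type)
    expect_equal(back$B$bonds, cmps$B$bonds)
  })
})

test_that("SMILES reader honors the compound-graph contract", {
  skip_if_not_installed("ChemmineOB")
  g <- parse_smiles("CCO", "eth")
  expect_s3_class(g, "compound_graph")
  expect_equal(nrow(g$atoms), 3L)
  expect_setequal(g$atoms$element, c("C", "C", "O"))
})

test_that("reaction TSV dialect maps fields and orphans directly", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("#reaction_id\tsubstrate_id\tproduct_id\tec\tcluster_ids\tpathway_taxa",
               "R001\tC001\tC002\t1.14.13.-\tOC1;OC2\t",
               "R002\tC002\tC001\t\t\tplant"), path)
  rx <- read_reaction_table(path, "tsv")
  expect_equal(length(rx), 2L)
  expect_equal(rx$R001$cluster_ids, c("OC1", "OC2"))
  expect_false(is_orphan(rx$R001))
  expect_true(is_orphan(rx$R002))
  expect_equal(rx$R002$pathway_taxa, "plant")
  dup <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("R001\tC001\tC002\t\t", "R001\tC001\tC002\t\t"), dup)
  expect_error(read_reaction_table(dup, "tsv"), "duplicate reaction_id")
})

test_that("KEGG-flat dialect takes the first compound pair as the main pair", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("ENTRY       R00001",
               "EQUATION    C001 + C003 <=> C002 + C004",
               "ENZYME      1.1.1.1",
               "ORTHOLOGY   K00001  dehydrogenase",
               "///",
               "ENTRY       R00002",
               "EQUATION    C005 <=> C006",
               "///"), path)
  rx <- read_reaction_table(path, "kegg-flat")
  expect_equal(rx$R00001$pairs[[1]],
               list(substrate_id = "C001", product_id = "C002"))
  expect_equal(rx$R00001$context$substrates, "C003")
  expect_equal(rx$R00001$cluster_ids, "K00001")
  expect_equal(rx$R00001$ec, "1.1.1.1")
  expect_true(is_orphan(rx$R00002))
})

test_that("reaction table write -> read -> write is byte-identical", {
  db <- tiny_db()
  p1 <- withr::local_tempfile(fileext = ".tsv")
  p2 <- withr::local_tempfile(fileext = ".tsv")
  write_reaction_table(db, p1)
  write_reaction_table(read_reaction_table(p1, "tsv"), p2)
  expect_identical(readBin(p1, "raw", file.size(p1)),
                   readBin(p2, "raw", file.size(p2)))
})

test_that("cluster and organism tables link records and reject bad labels", {
  cp <- withr::local_tempfile(fileext = ".tsv")
  op <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("OC1\tsco\tSCO3770\tK00001: cytochrome P450"), cp)
  writeLines(c("sco\tStreptomyces coelicolor A3(2)\tbacteria\tBacteria;Actinobacteria;Streptomycetaceae",
               "ath\tArabidopsis thaliana\tplant\tEukaryota;Viridiplantae"), op)
  cls <- read_cluster_table(cp)
  orgs <- read_organism_table(op)
  expect_equal(cls$OC1$members$gene, "SCO3770")
  expect_equal(orgs$sco$lineage[3], "Streptomycetaceae")
  expect_equal(orgs$ath$taxon_group, "plant")
  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines("xxy\tMystery organism\tarchaea\t", bad)
  expect_error(read_organism_table(bad), "plant, bacteria, other")
})

test_that("database assembly enforces referential integrity", {
  db <- tiny_db()
  expect_true(validate_reaction_db(db))
  # mutate: reaction referencing a missing cluster
  broken <- db
  broken$reactions$R01$cluster_ids <- "OC99"
  expect_error(validate_reaction_db(broken), "missing cluster OC99",
               class = "enzrepo_integrity_error")
  # cluster referencing an unknown organism
  broken2 <- db
  broken2$clusters$OC1$members$organism[1] <- "zzz"
  expect_error(validate_reaction_db(broken2), "missing organism zzz")
  # reaction referencing a missing compound
  broken3 <- db
  broken3$reactions$R01$pairs[[1]]$substrate_id <- "C99"
  expect_error(validate_reaction_db(broken3), "missing compound C99")
})

test_that("FASTA reading normalizes ids and case", {
  p <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">a some description", "mkv", ">b", "MTT"), p)
  fa <- read_fasta(p)
  expect_equal(names(fa), c("a", "b"))
  expect_equal(unname(fa["a"]), "MKV")
  dup <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">a", "M", ">a", "K"), dup)
  expect_error(read_fasta(dup), "duplicate sequence id")
})
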