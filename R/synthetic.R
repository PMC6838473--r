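# Seeded generator of complete toy reaction databases with planted
# cross-taxon analog reactions, so every pipeline stage is testable offline.
#
# Every reaction is built as a random scaffold plus a pendant transformation
# site (attach-Ca-Cb-Cc[-X]) whose RDM-relevant atom types are independent of
# the scaffold by construction: the site is an acyclic all-single-bond chain
# attached to a carbon, and no triple of the resulting RDM pattern can see
# past Ca. A planted bacterial analog applies the exact same site
# transformation to a different scaffold, hence scores exactly 1.0 against
# its plant query at perturbation 0. Planted site signatures (terminal
# element x operation x branch, 30 combinations) are unique within a
# database, and non-planted bacterial/shared (N spacer) and orphan (O
# spacer) reactions can never tie at 1.0 with a planted pattern.

SITE_X <- c("O", "N", "S")
SITE_OPS <- c("order12", "order13", "addx", "removex", "order12cb")

n_site_signatures <- function() length(SITE_X) * length(SITE_OPS) * 2L

site_signature <- function(k) {
  stopifnot(k >= 1L, k <= n_site_signatures())
  k <- k - 1L
  list(x = SITE_X[k %% 3L + 1L],
       op = SITE_OPS[(k %/% 3L) %% 5L + 1L],
       branch = (k %/% 15L) %% 2L == 1L)
}

signature_string <- function(sig)
  paste(sig$op, sig$x, if (sig$branch) "branched" else "linear", sep = "/")

#' Generator configuration
#'
#' Defaults define the study conditions of the package's test bed: 20
#' plant-specific query reactions each with a planted bacterial analog, a
#' background of 10 further bacterial reactions, 5 plant/bacteria-shared
#' reactions and 3 plant orphan reactions, over 5 plant, 8 bacterial and 2
#' other organisms, with scaffolds of 4-12 heavy atoms.
#'
#' @param seed Master seed; every component draws from its own substream, so
#'   changing one count does not perturb another component's draws.
#' @param n_plant_reactions Plant-specific reactions (the queries).
#' @param n_bacterial_reactions Non-analog bacterial background reactions.
#' @param n_shared_reactions Reactions with both plant and bacterial genes.
#' @param n_orphan_plant_reactions Orphan reactions with plant pathway
#'   evidence only.
#' @param n_planted_analogs Bacterial analogs sharing a query's exact site
#'   transformation (at most `n_plant_reactions` and at most the number of
#'   distinct site signatures).
#' @param perturbation_level Non-negative integer; cumulative edits applied
#'   to each planted analog's RDM-relevant site atoms (1: spacer carbon to
#'   N; 2: extra O on the reacting carbon; 3: terminal-element shift).
#' @param compound_size Scaffold heavy-atom size range (the pendant site
#'   adds 3-6 more).
#' @param n_plant_organisms,n_bacterial_organisms,n_other_organisms Roster
#'   sizes per taxon group.
#' @param n_known_enzymes,n_candidate_seqs,protein_length,substitution_rates
#'   Protein generator settings for [generate_fasta()].
#' @return A validated `generator_config`.
#' @export
generator_config <- function(seed = 1L,
                             n_plant_reactions = 20L,
                             n_bacterial_reactions = 10L,
                             n_shared_reactions = 5L,
                             n_orphan_plant_reactions = 3L,
                             n_planted_analogs = 20L,
                             perturbation_level = 0L,
                             compound_size = c(4L, 12L),
                             n_plant_organisms = 5L,
                             n_bacterial_organisms = 8L,
                             n_other_organisms = 2L,
                             n_known_enzymes = 3L,
                             n_candidate_seqs = 4L,
                             protein_length = 300L,
                             substitution_rates = c(0, 0.1, 0.3, 0.7)) {
  cfg <- list(seed = as.integer(seed),
              n_plant_reactions = as.integer(n_plant_reactions),
              n_bacterial_reactions = as.integer(n_bacterial_reactions),
              n_shared_reactions = as.integer(n_shared_reactions),
              n_orphan_plant_reactions = as.integer(n_orphan_plant_reactions),
              n_planted_analogs = as.integer(n_planted_analogs),
              perturbation_level = as.integer(perturbation_level),
              compound_size = as.integer(compound_size),
              n_plant_organisms = as.integer(n_plant_organisms),
              n_bacterial_organisms = as.integer(n_bacterial_organisms),
              n_other_organisms = as.integer(n_other_organisms),
              n_known_enzymes = as.integer(n_known_enzymes),
              n_candidate_seqs = as.integer(n_candidate_seqs),
              protein_length = as.integer(protein_length),
              substitution_rates = as.numeric(substitution_rates))
  counts <- cfg[grepl("^n_", names(cfg))]
  if (any(unlist(counts) < 0L))
    stop_enzrepo("generation error: all counts must be >= 0")
  if (cfg$n_planted_analogs > cfg$n_plant_reactions)
    stop_enzrepo("generation error: n_planted_analogs (",
                 cfg$n_planted_analogs, ") exceeds n_plant_reactions (",
                 cfg$n_plant_reactions, ")")
  if (cfg$n_planted_analogs > n_site_signatures())
    stop_enzrepo("generation error: n_planted_analogs (",
                 cfg$n_planted_analogs, ") exceeds the ",
                 n_site_signatures(), " distinct site signatures")
  if (length(cfg$compound_size) != 2L || cfg$compound_size[1] < 2L ||
      cfg$compound_size[2] < cfg$compound_size[1])
    stop_enzrepo("generation error: compound_size range too small for the ",
                 "site transformation (need at least 2 scaffold atoms, ",
                 "lo <= hi)")
  if (cfg$perturbation_level < 0L)
    stop_enzrepo("generation error: perturbation_level must be >= 0")
  structure(cfg, class = "generator_config")
}

# random connected scaffold: tree plus up to 2 ring-closing edges;
# atom 0 is always carbon (the site attachment point)
random_scaffold <- function(n) {
  elems <- c("C", sample(c("C", "C", "C", "N", "O", "S"), n - 1L,
                         replace = TRUE))
  a <- integer(0); b <- integer(0); ord <- character(0)
  for (k in seq_len(n - 1L)) {
    par <- if (k == 1L) 1L else sample.int(k, 1L)
    a <- c(a, par - 1L); b <- c(b, k)
    ord <- c(ord, if (stats::runif(1) < 0.15) "2" else "1")
  }
  if (n >= 4L) {
    existing <- paste(a, b)
    for (tries in seq_len(sample.int(3L, 1L) - 1L)) {
      pair <- sort(sample.int(n, 2L)) - 1L
      key <- paste(pair[1], pair[2])
      if (!key %in% existing) {
        a <- c(a, pair[1]); b <- c(b, pair[2]); ord <- c(ord, "1")
        existing <- c(existing, key)
      }
    }
  }
  list(elements = elems, bonds = data.frame(a = a, b = b, order = ord,
                                            stringsAsFactors = FALSE))
}

# Attach the transformation site to scaffold atom 0 and build the
# substrate/product pair. spacer is the Cb element ("C" for planted sites,
# "N"/"O" for background reactions); pert applies the perturbation ladder.
build_reaction_compounds <- function(scaffold, sig, spacer, pert,
                                     substrate_id, product_id) {
  x_elem <- sig$x
  if (pert >= 3L) x_elem <- SITE_X[match(sig$x, SITE_X) %% 3L + 1L]
  cb_elem <- if (pert >= 1L) (if (spacer == "N") "O" else "N") else spacer
  n0 <- length(scaffold$elements)
  elems <- c(scaffold$elements, "C", cb_elem, "C")   # Ca, Cb, Cc
  ca <- n0; cb <- n0 + 1L; cc <- n0 + 2L
  bonds <- rbind(scaffold$bonds,
                 data.frame(a = c(0L, ca, cb), b = c(ca, cb, cc),
                            order = "1", stringsAsFactors = FALSE))
  add_atom <- function(elems, bonds, elem, to, order = "1") {
    idx <- length(elems)
    list(elements = c(elems, elem),
         bonds = rbind(bonds, data.frame(a = to, b = idx, order = order,
                                         stringsAsFactors = FALSE)),
         idx = idx)
  }
  if (sig$branch) {
    g <- add_atom(elems, bonds, "C", cc); elems <- g$elements; bonds <- g$bonds
  }
  if (pert >= 2L) {
    g <- add_atom(elems, bonds, "O", cc); elems <- g$elements; bonds <- g$bonds
  }
  cx <- NA_integer_
  if (sig$op %in% c("order12", "order13", "removex", "order12cb")) {
    g <- add_atom(elems, bonds, x_elem, cc)
    elems <- g$elements; bonds <- g$bonds; cx <- g$idx
  }
  sub_elems <- elems; sub_bonds <- bonds
  prod_elems <- elems; prod_bonds <- bonds
  set_order <- function(bonds, i, j, o) {
    hit <- (bonds$a == min(i, j)) & (bonds$b == max(i, j))
    bonds$order[hit] <- o
    bonds
  }
  if (sig$op == "order12") {
    prod_bonds <- set_order(prod_bonds, cc, cx, "2")
  } else if (sig$op == "order13") {
    prod_bonds <- set_order(prod_bonds, cc, cx, "3")
  } else if (sig$op == "order12cb") {
    prod_bonds <- set_order(prod_bonds, cb, cc, "2")
  } else if (sig$op == "addx") {
    g <- add_atom(prod_elems, prod_bonds, x_elem, cc)
    prod_elems <- g$elements; prod_bonds <- g$bonds
  } else if (sig$op == "removex") {
    keep <- (prod_bonds$a != cx) & (prod_bonds$b != cx)
    prod_bonds <- prod_bonds[keep, , drop = FALSE]   # cx is the last atom
    prod_elems <- prod_elems[-(cx + 1L)]
  }
  list(substrate = compound_graph(substrate_id, sub_elems, sub_bonds),
       product = compound_graph(product_id, prod_elems, prod_bonds))
}

random_sig <- function() {
  list(x = sample(SITE_X, 1L), op = sample(SITE_OPS, 1L),
       branch = stats::runif(1) < 0.5)
}

#' Generate a synthetic reaction database with planted analogs
#'
#' Builds a complete, referentially consistent toy database: plant-specific
#' query reactions, planted bacterial analog reactions sharing the exact
#' transformation (degraded by `perturbation_level` edits when requested),
#' background bacterial reactions, plant/bacteria-shared reactions, orphan
#' plant reactions carrying pathway evidence only, organism rosters with
#' lineages, and a bacterial phylogeny. Identical configuration yields a
#' byte-identical database.
#'
#' @param config A [generator_config()].
#' @return List with `db` (a `reaction_db`), `manifest` (ground truth: one
#'   row per planted (query, analog) pair with its signature and
#'   perturbation level) and `tree` (`ape::phylo` over the bacterial
#'   organisms).
#' @export
generate_database <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  seed <- config$seed
  mk_orgs <- function(prefix, n, group, fams) {
    lapply(seq_len(n), function(i) {
      fam <- fams[(i - 1L) %% length(fams) + 1L]
      organism(sprintf("%s%02d", prefix, i),
               sprintf("Synthetic %s sp. %d", group, i), group,
               lineage = c(if (group == "bacteria") "Bacteria" else "Eukaryota",
                           fam))
    })
  }
  organisms <- c(
    mk_orgs("pln", config$n_plant_organisms, "plant",
            c("PlantFam1", "PlantFam2")),
    mk_orgs("bac", config$n_bacterial_organisms, "bacteria",
            c("BactFam1", "BactFam2", "BactFam3")),
    mk_orgs("oth", config$n_other_organisms, "other", c("OtherFam1")))
  org_codes <- function(group) {
    vapply(Filter(function(o) o$taxon_group == group, organisms),
           `[[`, character(1), "code")
  }
  compounds <- list(); reactions <- list(); clusters <- list()
  size_range <- config$compound_size
  draw_scaffold <- function() {
    n <- sample(seq(size_range[1], size_range[2]), 1L)
    random_scaffold(n)
  }
  mk_clusters <- function(rid, orgs_pool, n_genes = NULL) {
    n_cl <- sample.int(2L, 1L)
    ids <- character(n_cl)
    for (k in seq_len(n_cl)) {
      cid <- sprintf("OC.%s.%d", rid, k)
      n_mem <- min(length(orgs_pool), sample.int(3L, 1L))
      mem_orgs <- sort(sample(orgs_pool, n_mem))
      members <- data.frame(
        organism = mem_orgs,
        gene = sprintf("%s_%s_%d", mem_orgs, rid, k),
        stringsAsFactors = FALSE)
      clusters[[cid]] <<- ortholog_cluster(
        cid, members,
        ko_annotation = sprintf("K%05d: synthetic oxidoreductase %s",
                                10000L + length(clusters) + 1L, rid))
      ids[k] <- cid
    }
    ids
  }
  add_reaction <- function(rid, sig, spacer, pert, cluster_orgs,
                           pathway_taxa = character()) {
    pairres <- build_reaction_compounds(
      draw_scaffold(), sig, spacer, pert,
      substrate_id = paste0(rid, ".s"), product_id = paste0(rid, ".p"))
    compounds[[pairres$substrate$compound_id]] <<- pairres$substrate
    compounds[[pairres$product$compound_id]] <<- pairres$product
    cids <- if (is.null(cluster_orgs)) character()
            else mk_clusters(rid, cluster_orgs)
    reactions[[rid]] <<- reaction_record(
      rid, pairres$substrate$compound_id, pairres$product$compound_id,
      ec = sprintf("1.14.%d.%d", sample.int(20L, 1L), sample.int(99L, 1L)),
      cluster_ids = cids, pathway_taxa = pathway_taxa)
  }
  plant_sigs <- vector("list", config$n_plant_reactions)
  for (i in seq_len(config$n_plant_reactions)) {
    with_substream(seed, sprintf("plant/%d", i), {
      sig <- if (i <= config$n_planted_analogs) site_signature(i)
             else random_sig()
      plant_sigs[[i]] <- sig
      add_reaction(sprintf("R1%03d", i), sig, spacer = "C", pert = 0L,
                   cluster_orgs = org_codes("plant"))
    })
  }
  manifest_pairs <- list()
  for (i in seq_len(config$n_planted_analogs)) {
    with_substream(seed, sprintf("analog/%d", i), {
      rid <- sprintf("R2%03d", i)
      add_reaction(rid, plant_sigs[[i]], spacer = "C",
                   pert = config$perturbation_level,
                   cluster_orgs = org_codes("bacteria"))
      manifest_pairs[[i]] <- list(
        query = sprintf("R1%03d", i), analog = rid,
        signature = signature_string(plant_sigs[[i]]))
    })
  }
  for (i in seq_len(config$n_bacterial_reactions)) {
    with_substream(seed, sprintf("bacterial/%d", i), {
      add_reaction(sprintf("R3%03d", i), random_sig(), spacer = "N",
                   pert = 0L, cluster_orgs = org_codes("bacteria"))
    })
  }
  for (i in seq_len(config$n_shared_reactions)) {
    with_substream(seed, sprintf("shared/%d", i), {
      add_reaction(sprintf("R4%03d", i), random_sig(), spacer = "N",
                   pert = 0L,
                   cluster_orgs = c(org_codes("plant"), org_codes("bacteria")))
    })
  }
  for (i in seq_len(config$n_orphan_plant_reactions)) {
    with_substream(seed, sprintf("orphan/%d", i), {
      add_reaction(sprintf("R5%03d", i), random_sig(), spacer = "O",
                   pert = 0L, cluster_orgs = NULL, pathway_taxa = "plant")
    })
  }
  # ensure every shared reaction really has members of both groups
  for (rid in grep("^R4", names(reactions), value = TRUE)) {
    r <- reactions[[rid]]
    orgs <- unlist(lapply(r$cluster_ids,
                          function(cid) clusters[[cid]]$members$organism))
    grp <- substr(orgs, 1L, 3L)
    if (!("pln" %in% grp) || !("bac" %in% grp)) {
      cid <- r$cluster_ids[1]
      cl <- clusters[[cid]]
      extra <- c(if (!"pln" %in% grp) "pln01", if (!"bac" %in% grp) "bac01")
      cl$members <- unique(rbind(cl$members, data.frame(
        organism = extra, gene = sprintf("%s_%s_x", extra, rid),
        stringsAsFactors = FALSE)))
      clusters[[cid]] <- cl
    }
  }
  db <- reaction_db(compounds, reactions, clusters, organisms,
                    provenance = sprintf("enzrepo synthetic (seed %d)", seed))
  manifest <- list(seed = seed,
                   perturbation_level = config$perturbation_level,
                   n_planted = config$n_planted_analogs,
                   pairs = manifest_pairs)
  list(db = db, manifest = manifest, tree = bacterial_tree(db))
}

# simple family-grouped phylogeny over the bacterial organisms
bacterial_tree <- function(db) {
  bact <- Filter(function(o) o$taxon_group == "bacteria", db$organisms)
  fams <- split(names(bact), vapply(bact, function(o)
    utils::tail(o$lineage, 1), character(1)))
  parts <- character()
  for (fam in sort_c(names(fams))) {
    tips <- sort_c(fams[[fam]])
    parts <- c(parts, if (length(tips) >= 2L)
      paste0("(", paste0(tips, ":1", collapse = ","), ")", fam, ":1")
      else paste0(tips, ":1"))
  }
  ape::read.tree(text = paste0("(", paste(parts, collapse = ","), ");"))
}

#' Generate candidate and known-enzyme protein sequences
#'
#' Known enzymes are random protein sequences; candidates are mutated copies
#' at the configured substitution rates (positions chosen at random,
#' replacement uniform over the other 19 residues), cycling over the knowns,
#' so pairwise identity is controlled: at rate r and length 300 the local
#' alignment identity of a (candidate, source) pair lands near 100(1 - r).
#' Rate 0 gives identity-100 pairs; high rates give near-random or
#' not-aligned pairs. Fully determined by the config seed.
#'
#' @param config A [generator_config()].
#' @return List with `known` and `candidates` (named character vectors) and
#'   `pairs` (data frame: candidate, source known, rate).
#' @export
generate_fasta <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  known <- stats::setNames(
    vapply(seq_len(config$n_known_enzymes), function(i)
      with_substream(config$seed, sprintf("fasta/known/%d", i),
                     paste(sample(aa, config$protein_length, replace = TRUE),
                           collapse = "")), character(1)),
    sprintf("KNOWN%02d", seq_len(config$n_known_enzymes)))
  rates <- config$substitution_rates
  n_c <- config$n_candidate_seqs
  src <- names(known)[(seq_len(n_c) - 1L) %% length(known) + 1L]
  rate <- rates[(seq_len(n_c) - 1L) %% length(rates) + 1L]
  candidates <- stats::setNames(vapply(seq_len(n_c), function(i) {
    with_substream(config$seed, sprintf("fasta/cand/%d", i), {
      s <- strsplit(known[[src[i]]], "")[[1]]
      k <- round(rate[i] * length(s))
      if (k > 0L) {
        pos <- sample.int(length(s), k)
        s[pos] <- vapply(s[pos], function(old)
          sample(setdiff(aa, old), 1L), character(1))
      }
      paste(s, collapse = "")
    })
  }, character(1)), sprintf("CAND%02d", seq_len(n_c)))
  list(known = known, candidates = candidates,
       pairs = data.frame(candidate = names(candidates), source = src,
                          rate = rate, stringsAsFactors = FALSE))
}

#' Write a planted-analog manifest as canonical JSON
#' @param manifest Manifest list from [generate_database()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  json <- jsonlite::toJSON(manifest, auto_unbox = TRUE, pretty = TRUE,
                           digits = NA)
  write_lines_lf(as.character(json), path)
}

#' Read a planted-analog manifest
#' @param path JSON path written by [write_manifest()].
#' @return Manifest list with integer counts restored.
#' @export
read_manifest <- function(path) {
  m <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  list(seed = as.integer(m$seed),
       perturbation_level = as.integer(m$perturbation_level),
       n_planted = as.integer(m$n_planted),
       pairs = lapply(m$pairs, function(p)
         list(query = p$query, analog = p$analog, signature = p$signature)))
}

#' Write a generated database to a directory
#'
#' Plain-text layout: `compounds.sdf`, `reactions.tsv`, `clusters.tsv`,
#' `organisms.tsv`, plus optionally `tree.nwk`, `manifest.json` and
#' `proteins.fasta`.
#'
#' @param db A `reaction_db`.
#' @param dir Output directory (created if needed).
#' @param manifest,tree,fasta Optional extras from [generate_database()] /
#'   [generate_fasta()] (`fasta` is written as one FASTA of knowns then
#'   candidates).
#' @return The directory, invisibly.
#' @export
write_database <- function(db, dir, manifest = NULL, tree = NULL,
                           fasta = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_sdf(db$compounds[sort_c(names(db$compounds))],
            file.path(dir, "compounds.sdf"))
  write_reaction_table(db, file.path(dir, "reactions.tsv"))
  write_cluster_table(db, file.path(dir, "clusters.tsv"))
  write_organism_table(db, file.path(dir, "organisms.tsv"))
  if (!is.null(tree)) ape::write.tree(tree, file.path(dir, "tree.nwk"))
  if (!is.null(manifest)) write_manifest(manifest, file.path(dir, "manifest.json"))
  if (!is.null(fasta))
    write_fasta(c(fasta$known, fasta$candidates),
                file.path(dir, "proteins.fasta"))
  invisible(dir)
}

#' Read a database directory written by [write_database()]
#' @param dir Directory path.
#' @return List with `db` and, when present, `manifest` and `tree`.
#' @export
read_database <- function(dir) {
  compounds <- parse_sdf(file.path(dir, "compounds.sdf"), is_path = TRUE)
  reactions <- read_reaction_table(file.path(dir, "reactions.tsv"), "tsv")
  clusters <- read_cluster_table(file.path(dir, "clusters.tsv"))
  organisms <- read_organism_table(file.path(dir, "organisms.tsv"))
  db <- reaction_db(compounds, reactions, clusters, organisms,
                    provenance = paste0("dir:", dir))
  out <- list(db = db)
  if (file.exists(file.path(dir, "manifest.json")))
    out$manifest <- read_manifest(file.path(dir, "manifest.json"))
  if (file.exists(file.path(dir, "tree.nwk")))
    out$tree <- ape::read.tree(file.path(dir, "tree.nwk"))
  out
}
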