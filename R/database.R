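# Reaction database model: reactions, ortholog clusters, organisms, and the
# container tying them together, plus tabular I/O (TSV / KEGG-like flat file /
# JSON) and protein FASTA reading.

DEFAULT_TAXON_GROUPS <- c("plant", "bacteria", "other")

#' Construct an organism record
#'
#' @param code Short organism code (unique within a database).
#' @param name Organism name.
#' @param taxon_group Taxon-group label; must belong to the database's
#'   configured group vocabulary (default `plant`/`bacteria`/`other`).
#' @param lineage Character vector of clade names, outermost first.
#' @return An `organism` object.
#' @export
organism <- function(code, name, taxon_group, lineage = character()) {
  structure(list(code = code, name = name, taxon_group = taxon_group,
                 lineage = as.character(lineage)),
            class = "organism")
}

#' Construct an ortholog-cluster record
#'
#' @param cluster_id Cluster identifier.
#' @param members Data frame with columns `organism` (organism code) and
#'   `gene` (gene id); must be non-empty.
#' @param ko_annotation Optional functional label, conventionally
#'   `"K00000: description"`.
#' @return An `ortholog_cluster` object.
#' @export
ortholog_cluster <- function(cluster_id, members, ko_annotation = NA_character_) {
  members <- data.frame(organism = as.character(members$organism),
                        gene = as.character(members$gene),
                        stringsAsFactors = FALSE)
  if (nrow(members) == 0L)
    stop_enzrepo("cluster ", cluster_id, " has no members")
  structure(list(cluster_id = cluster_id, members = members,
                 ko_annotation = ko_annotation),
            class = "ortholog_cluster")
}

#' Construct a reaction record
#'
#' A reaction carries one or more substrate/product compound pairs (the main
#' pair first), an optional EC number, the ortholog clusters annotated to it
#' (empty for orphan-enzyme reactions) and optional pathway-derived taxon
#' labels used to place orphans.
#'
#' @param reaction_id Reaction identifier.
#' @param substrate_id,product_id Compound ids of the main reactant pair.
#' @param ec Optional EC number string.
#' @param cluster_ids Character vector of ortholog-cluster ids (may be empty).
#' @param pathway_taxa Character vector of taxon-group labels attached via
#'   pathway evidence (used for orphan reactions).
#' @param context Optional list with `substrates`/`products` character vectors
#'   of additional compound ids beyond the main pair.
#' @return A `reaction_record`.
#' @export
reaction_record <- function(reaction_id, substrate_id, product_id,
                            ec = NA_character_, cluster_ids = character(),
                            pathway_taxa = character(), context = list()) {
  structure(list(
    reaction_id = reaction_id,
    pairs = list(list(substrate_id = substrate_id, product_id = product_id)),
    ec = ec,
    cluster_ids = sort_c(unique(as.character(cluster_ids))),
    pathway_taxa = sort_c(unique(as.character(pathway_taxa))),
    context = context
  ), class = "reaction_record")
}

#' Is a reaction an orphan-enzyme reaction?
#'
#' A reaction is orphan when no ortholog cluster (hence no gene) is annotated
#' to it.
#'
#' @param reaction A `reaction_record`.
#' @return Logical.
#' @export
is_orphan <- function(reaction) length(reaction$cluster_ids) == 0L

#' Assemble a reaction database
#'
#' Collects compounds, reactions, clusters and organisms into one keyed
#' container and (by default) enforces referential integrity: every cluster id
#' referenced by a reaction, every organism code referenced by a cluster and
#' every compound id referenced by a reactant pair must resolve.
#'
#' @param compounds Named list of `compound_graph` objects (or a list; names
#'   are taken from `compound_id`s).
#' @param reactions List of `reaction_record`s.
#' @param clusters List of `ortholog_cluster`s.
#' @param organisms List of `organism`s.
#' @param provenance Free-text source tag.
#' @param taxon_groups Configured taxon-group vocabulary.
#' @param validate Check referential integrity (see [validate_reaction_db()]).
#' @return A `reaction_db`.
#' @export
reaction_db <- function(compounds = list(), reactions = list(),
                        clusters = list(), organisms = list(),
                        provenance = "", taxon_groups = DEFAULT_TAXON_GROUPS,
                        validate = TRUE) {
  name_by <- function(xs, field) {
    if (length(xs) == 0L) return(stats::setNames(list(), character()))
    stats::setNames(xs, vapply(xs, function(x) x[[field]], character(1)))
  }
  compounds <- name_by(compounds, "compound_id")
  reactions <- name_by(reactions, "reaction_id")
  clusters <- name_by(clusters, "cluster_id")
  organisms <- name_by(organisms, "code")
  if (anyDuplicated(names(reactions)))
    stop_enzrepo("duplicate reaction_id: ",
                 paste(unique(names(reactions)[duplicated(names(reactions))]),
                       collapse = ", "))
  db <- structure(list(compounds = compounds, reactions = reactions,
                       clusters = clusters, organisms = organisms,
                       provenance = provenance, taxon_groups = taxon_groups),
                  class = "reaction_db")
  bad_grp <- vapply(organisms, function(o) !o$taxon_group %in% taxon_groups,
                    logical(1))
  if (any(bad_grp))
    stop_enzrepo("unknown taxon_group for organism(s) ",
                 paste(names(organisms)[bad_grp], collapse = ", "),
                 "; configured vocabulary: ", paste(taxon_groups, collapse = ", "))
  if (validate) validate_reaction_db(db)
  db
}

#' @export
print.reaction_db <- function(x, ...) {
  cat(sprintf(
    "<reaction_db: %d compounds, %d reactions, %d clusters, %d organisms>%s\n",
    length(x$compounds), length(x$reactions), length(x$clusters),
    length(x$organisms),
    if (nzchar(x$provenance)) paste0(" [", x$provenance, "]") else ""))
  invisible(x)
}

#' Validate referential integrity of a reaction database
#'
#' Errors with a list of all offenders when a reaction references an unknown
#' cluster or compound, or a cluster references an unknown organism.
#'
#' @param db A `reaction_db`.
#' @return `TRUE`, invisibly, when the database is consistent.
#' @export
validate_reaction_db <- function(db) {
  offenders <- character()
  for (r in db$reactions) {
    miss <- setdiff(r$cluster_ids, names(db$clusters))
    if (length(miss) > 0L)
      offenders <- c(offenders, sprintf("reaction %s -> missing cluster %s",
                                        r$reaction_id, miss))
    for (p in r$pairs) {
      for (cid in c(p$substrate_id, p$product_id))
        if (!cid %in% names(db$compounds))
          offenders <- c(offenders, sprintf("reaction %s -> missing compound %s",
                                            r$reaction_id, cid))
    }
  }
  for (cl in db$clusters) {
    miss <- setdiff(unique(cl$members$organism), names(db$organisms))
    if (length(miss) > 0L)
      offenders <- c(offenders, sprintf("cluster %s -> missing organism %s",
                                        cl$cluster_id, miss))
  }
  if (length(offenders) > 0L)
    stop_enzrepo("referential-integrity error:\n  ",
                 paste(offenders, collapse = "\n  "),
                 class = "enzrepo_integrity_error")
  invisible(TRUE)
}

#' Resolve a reaction's main reactant pair against the database
#'
#' @param db A `reaction_db`.
#' @param reaction A `reaction_record` or a reaction id.
#' @param which Index of the reactant pair (1 = main pair).
#' @return A `reactant_pair` with resolved compound graphs.
#' @export
reactant_pair_of <- function(db, reaction, which = 1L) {
  if (is.character(reaction)) reaction <- db$reactions[[reaction]]
  p <- reaction$pairs[[which]]
  reactant_pair(db$compounds[[p$substrate_id]], db$compounds[[p$product_id]])
}

split_semi <- function(x) {
  if (is.na(x) || x == "") character() else strsplit(x, ";", fixed = TRUE)[[1]]
}

#' Read a reaction table
#'
#' Three dialects are supported.
#' \describe{
#'   \item{`tsv`}{Tab-separated with columns `reaction_id`, `substrate_id`,
#'     `product_id`, `ec`, `cluster_ids` (semicolon-joined, may be empty) and
#'     an optional sixth column `pathway_taxa` (semicolon-joined) carrying
#'     pathway-derived taxon evidence for orphan reactions. Lines starting
#'     with `#` are comments; a `#`-prefixed header is allowed.}
#'   \item{`kegg-flat`}{KEGG-REACTION-like blocks terminated by `///`, using
#'     `ENTRY`, `EQUATION`, `ENZYME` and `ORTHOLOGY` lines. The first compound
#'     on each side of the equation is the main pair; the rest are recorded as
#'     context. ORTHOLOGY identifiers populate `cluster_ids` (the model's
#'     gene-grouping key).}
#'   \item{`json`}{An array of objects with the TSV fields (`cluster_ids` and
#'     `pathway_taxa` as arrays).}
#' }
#' Compound references are not resolved here; integrity is checked when the
#' records are assembled into a database.
#'
#' @param path File path.
#' @param dialect One of `"tsv"`, `"kegg-flat"`, `"json"`.
#' @return Named list of `reaction_record`s.
#' @export
read_reaction_table <- function(path, dialect = c("tsv", "kegg-flat", "json")) {
  dialect <- match.arg(dialect)
  recs <- switch(dialect,
    "tsv" = read_reaction_tsv(path),
    "kegg-flat" = read_reaction_kegg(path),
    "json" = read_reaction_json(path))
  ids <- vapply(recs, function(r) r$reaction_id, character(1))
  if (anyDuplicated(ids))
    stop_enzrepo("duplicate reaction_id in ", path, ": ",
                 paste(unique(ids[duplicated(ids)]), collapse = ", "))
  stats::setNames(recs, ids)
}

read_reaction_tsv <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  lapply(lines, function(ln) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L)
      stop_enzrepo("reaction TSV row with fewer than 3 columns: ", sQuote(ln))
    f <- c(f, rep("", 6L - length(f)))   # trailing empty fields are implicit
    reaction_record(
      reaction_id = f[1], substrate_id = f[2], product_id = f[3],
      ec = if (f[4] == "") NA_character_ else f[4],
      cluster_ids = split_semi(f[5]),
      pathway_taxa = if (length(f) >= 6L) split_semi(f[6]) else character())
  })
}

read_reaction_kegg <- function(path) {
  lines <- readLines(path, warn = FALSE)
  blocks <- split(lines, cumsum(c(0L, head(lines, -1) == "///")))
  recs <- list()
  for (bl in blocks) {
    bl <- bl[bl != "///" & nzchar(trimws(bl))]
    if (length(bl) == 0L) next
    field <- function(key) {
      hit <- grep(paste0("^", key, "\\s"), bl, value = TRUE)
      if (length(hit) == 0L) return(NA_character_)
      trimws(sub(paste0("^", key, "\\s+"), "", hit[1]))
    }
    entry <- field("ENTRY")
    if (is.na(entry)) stop_enzrepo("KEGG-flat block without ENTRY line in ", path)
    entry <- strsplit(entry, "\\s+")[[1]][1]
    eq <- field("EQUATION")
    if (is.na(eq)) stop_enzrepo("reaction ", entry, " has no EQUATION line")
    sides <- strsplit(eq, "<=>", fixed = TRUE)[[1]]
    if (length(sides) != 2L)
      stop_enzrepo("malformed EQUATION for ", entry, ": ", sQuote(eq))
    cpds <- function(s) {
      toks <- strsplit(trimws(s), "\\s*\\+\\s*")[[1]]
      vapply(toks, function(t) utils::tail(strsplit(trimws(t), "\\s+")[[1]], 1),
             character(1), USE.NAMES = FALSE)
    }
    subs <- cpds(sides[1]); prods <- cpds(sides[2])
    orth <- grep("^ORTHOLOGY\\s", bl, value = TRUE)
    okids <- vapply(orth, function(x) strsplit(trimws(sub("^ORTHOLOGY\\s+", "", x)),
                                               "\\s+")[[1]][1],
                    character(1), USE.NAMES = FALSE)
    recs[[length(recs) + 1L]] <- reaction_record(
      reaction_id = entry, substrate_id = subs[1], product_id = prods[1],
      ec = field("ENZYME"), cluster_ids = okids,
      context = list(substrates = subs[-1], products = prods[-1]))
  }
  recs
}

read_reaction_json <- function(path) {
  arr <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  lapply(arr, function(x) reaction_record(
    reaction_id = x$reaction_id, substrate_id = x$substrate_id,
    product_id = x$product_id, ec = x$ec %||% NA_character_,
    cluster_ids = unlist(x$cluster_ids) %||% character(),
    pathway_taxa = unlist(x$pathway_taxa) %||% character()))
}

#' Write reactions as canonical TSV
#'
#' The canonical form sorts rows by `reaction_id`, joins sorted `cluster_ids`
#' and `pathway_taxa` with semicolons and always writes six columns, so
#' write-read-write round-trips are byte-identical.
#'
#' @param reactions Named list of `reaction_record`s or a `reaction_db`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_reaction_table <- function(reactions, path) {
  if (inherits(reactions, "reaction_db")) reactions <- reactions$reactions
  reactions <- reactions[order_c(vapply(reactions, `[[`, character(1),
                                        "reaction_id"))]
  rows <- vapply(reactions, function(r) paste(
    r$reaction_id, r$pairs[[1]]$substrate_id, r$pairs[[1]]$product_id,
    if (is.na(r$ec)) "" else r$ec,
    paste(r$cluster_ids, collapse = ";"),
    paste(r$pathway_taxa, collapse = ";"),
    sep = "\t"), character(1))
  write_lines_lf(
    c("#reaction_id\tsubstrate_id\tproduct_id\tec\tcluster_ids\tpathway_taxa",
      unname(rows)), path)
}

#' Read an ortholog-cluster table
#'
#' TSV with columns `cluster_id`, `organism_code`, `gene_id` and optional
#' fourth column `ko_annotation` (one member per row; annotation taken from
#' the first row of each cluster). `#` lines are comments.
#'
#' @param path File path.
#' @return Named list of `ortholog_cluster`s.
#' @export
read_cluster_table <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  f <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(f) < 3L)
  if (length(bad) > 0L)
    stop_enzrepo("cluster TSV row with fewer than 3 columns: ",
                 sQuote(lines[bad[1]]))
  df <- data.frame(cluster_id = vapply(f, `[[`, character(1), 1),
                   organism = vapply(f, `[[`, character(1), 2),
                   gene = vapply(f, `[[`, character(1), 3),
                   ko = vapply(f, function(x) if (length(x) >= 4L) x[[4]]
                                              else NA_character_, character(1)),
                   stringsAsFactors = FALSE)
  out <- lapply(split(df, df$cluster_id), function(d) {
    d <- d[order_c(d$organism, d$gene), , drop = FALSE]
    ko <- d$ko[!is.na(d$ko) & d$ko != ""]
    ortholog_cluster(d$cluster_id[1], d[, c("organism", "gene")],
                     ko_annotation = if (length(ko)) ko[1] else NA_character_)
  })
  out[sort_c(names(out))]
}

#' Write an ortholog-cluster table
#' @param clusters Named list of `ortholog_cluster`s or a `reaction_db`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_cluster_table <- function(clusters, path) {
  if (inherits(clusters, "reaction_db")) clusters <- clusters$clusters
  clusters <- clusters[order_c(vapply(clusters, `[[`, character(1), "cluster_id"))]
  rows <- unlist(lapply(clusters, function(cl) {
    m <- cl$members[order_c(cl$members$organism, cl$members$gene), , drop = FALSE]
    paste(cl$cluster_id, m$organism, m$gene,
          if (is.na(cl$ko_annotation)) "" else cl$ko_annotation, sep = "\t")
  }))
  write_lines_lf(c("#cluster_id\torganism_code\tgene_id\tko_annotation",
                   unname(rows)), path)
}

#' Read an organism table
#'
#' TSV with columns `code`, `name`, `taxon_group`, `lineage`
#' (semicolon-joined clade names). Unknown taxon-group labels error with the
#' configured vocabulary.
#'
#' @param path File path.
#' @param taxon_groups Allowed taxon-group vocabulary.
#' @return Named list of `organism`s.
#' @export
read_organism_table <- function(path, taxon_groups = DEFAULT_TAXON_GROUPS) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  out <- lapply(lines, function(ln) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L)
      stop_enzrepo("organism TSV row with fewer than 3 columns: ", sQuote(ln))
    if (!f[3] %in% taxon_groups)
      stop_enzrepo("unknown taxon_group ", sQuote(f[3]), " for organism ", f[1],
                   "; configured vocabulary: ",
                   paste(taxon_groups, collapse = ", "))
    organism(f[1], f[2], f[3],
             lineage = if (length(f) >= 4L) split_semi(f[4]) else character())
  })
  stats::setNames(out, vapply(out, `[[`, character(1), "code"))
}

#' Write an organism table
#' @param organisms Named list of `organism`s or a `reaction_db`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_organism_table <- function(organisms, path) {
  if (inherits(organisms, "reaction_db")) organisms <- organisms$organisms
  organisms <- organisms[order_c(vapply(organisms, `[[`, character(1), "code"))]
  rows <- vapply(organisms, function(o) paste(
    o$code, o$name, o$taxon_group, paste(o$lineage, collapse = ";"),
    sep = "\t"), character(1))
  write_lines_lf(c("#code\tname\ttaxon_group\tlineage", unname(rows)), path)
}

#' Read a protein FASTA file
#'
#' Sequence ids are the first whitespace token of each header; residues are
#' uppercased. Errors on an empty file or duplicate ids.
#'
#' @param path FASTA file path.
#' @return Named character vector of protein sequences, in input order.
#' @export
read_fasta <- function(path) {
  aas <- Biostrings::readBStringSet(path)
  if (length(aas) == 0L) stop_enzrepo("empty FASTA file: ", path)
  ids <- sub("\\s.*$", "", names(aas))
  if (anyDuplicated(ids))
    stop_enzrepo("duplicate sequence id in ", path, ": ",
                 paste(unique(ids[duplicated(ids)]), collapse = ", "))
  stats::setNames(toupper(as.character(aas)), ids)
}

#' Write a protein FASTA file
#' @param sequences Named character vector of sequences.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_fasta <- function(sequences, path) {
  lines <- unlist(lapply(names(sequences), function(id) {
    s <- sequences[[id]]
    c(paste0(">", id),
      substring(s, seq(1, nchar(s), 60), pmin(seq(60, nchar(s) + 59, 60), nchar(s))))
  }))
  write_lines_lf(lines, path)
}
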