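# Taxon-specificity of reactions from ortholog-cluster membership and
# pathway evidence.
#
# A reaction with genes is "specific" to a taxon group when every annotated
# gene belongs to an organism of that group (the strictest reading of
# "only occurs in" that group), and "shared" otherwise. Orphan reactions
# (no genes) are "orphan-specific" only on explicit pathway evidence naming
# exactly that group; taxon is never inferred from absence of data.

#' Organisms annotated to a reaction
#'
#' Union of member organisms over the reaction's ortholog clusters; empty
#' for orphan reactions.
#'
#' @param reaction A `reaction_record` or reaction id.
#' @param db A `reaction_db`.
#' @return Sorted character vector of organism codes.
#' @export
organisms_of <- function(reaction, db) {
  if (is.character(reaction)) reaction <- db$reactions[[reaction]]
  orgs <- unlist(lapply(reaction$cluster_ids, function(cid)
    db$clusters[[cid]]$members$organism))
  sort_c(unique(orgs %||% character()))
}

#' Classify a reaction's taxon specificity
#'
#' Status is a pure function of the database and the query taxon group:
#' \describe{
#'   \item{`specific`}{has genes and every annotated organism is in the group;}
#'   \item{`shared`}{has genes and at least one organism outside the group;}
#'   \item{`orphan-specific`}{no genes, and pathway evidence names exactly
#'     this group;}
#'   \item{`unassigned`}{no genes and no (or ambiguous) pathway evidence.}
#' }
#'
#' @param reaction A `reaction_record` or reaction id.
#' @param taxon_group A label from the database's taxon-group vocabulary.
#' @param db A `reaction_db`.
#' @return A `taxon_assignment`: list with `reaction_id`, `status` and
#'   `evidence` (per-cluster organism lists, or the pathway tag).
#' @export
classify_reaction <- function(reaction, taxon_group, db) {
  if (is.character(reaction)) reaction <- db$reactions[[reaction]]
  if (!taxon_group %in% db$taxon_groups)
    stop_enzrepo("unknown taxon_group ", sQuote(taxon_group),
                 "; configured vocabulary: ",
                 paste(db$taxon_groups, collapse = ", "))
  if (!is_orphan(reaction)) {
    evidence <- lapply(reaction$cluster_ids, function(cid)
      list(source = cid,
           organisms = sort_c(unique(db$clusters[[cid]]$members$organism))))
    orgs <- organisms_of(reaction, db)
    groups <- vapply(orgs, function(o) db$organisms[[o]]$taxon_group, character(1))
    status <- if (all(groups == taxon_group)) "specific" else "shared"
  } else if (identical(reaction$pathway_taxa, taxon_group)) {
    status <- "orphan-specific"
    evidence <- list(list(source = "pathway",
                          organisms = character(),
                          taxa = reaction$pathway_taxa))
  } else {
    status <- "unassigned"
    evidence <- if (length(reaction$pathway_taxa) > 0L)
      list(list(source = "pathway", organisms = character(),
                taxa = reaction$pathway_taxa)) else list()
  }
  structure(list(reaction_id = reaction$reaction_id, status = status,
                 evidence = evidence),
            class = "taxon_assignment")
}

#' Find taxon-specific reactions
#'
#' All reactions classified `specific` for the group, optionally extended
#' with `orphan-specific` reactions (orphan-enzyme reactions placed in the
#' group by pathway evidence, so that targets without a known gene can still
#' be queried).
#'
#' @param db A `reaction_db`.
#' @param taxon_group Taxon-group label.
#' @param include_orphans Include `orphan-specific` reactions.
#' @return List of `taxon_assignment`s, sorted by reaction id.
#' @export
find_taxon_specific <- function(db, taxon_group, include_orphans = TRUE) {
  ids <- sort_c(names(db$reactions))
  keep <- c("specific", if (include_orphans) "orphan-specific")
  out <- list()
  for (id in ids) {
    a <- classify_reaction(db$reactions[[id]], taxon_group, db)
    if (a$status %in% keep) out[[length(out) + 1L]] <- a
  }
  out
}

#' Write a taxon-assignment table
#'
#' TSV with columns `reaction_id`, `status`, `evidence` (semicolon-joined
#' `source:organisms` items).
#'
#' @param assignments List of `taxon_assignment`s.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_assignment_table <- function(assignments, path) {
  rows <- vapply(assignments, function(a) {
    ev <- vapply(a$evidence, function(e) paste0(
      e$source, ":",
      paste(if (length(e$organisms)) e$organisms else e$taxa %||% character(),
            collapse = ",")), character(1))
    paste(a$reaction_id, a$status, paste(ev, collapse = ";"), sep = "\t")
  }, character(1))
  write_lines_lf(c("#reaction_id\tstatus\tevidence", unname(rows)), path)
}
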