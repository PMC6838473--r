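# Candidate profiling: per-organism aggregation of screen results, clade
# rollups over a phylogeny, and tree-annotation (iTOL-dataset-style) export.

#' Aggregate screen candidates per organism
#'
#' Builds the binary organism x query matrix (1 when the organism carries at
#' least one candidate gene for that query reaction — reactions are counted,
#' not genes) plus per-organism marginal counts. Rows cover every organism of
#' the screen's target taxon group so strains with zero candidates appear
#' explicitly.
#'
#' @param result A `screen_result`.
#' @param db The `reaction_db` the screen ran on.
#' @return A `taxon_profile`: list with `matrix` (integer 0/1), `marginals`
#'   (row sums) and the target group label.
#' @export
aggregate_by_organism <- function(result, db) {
  group <- result$config$target_taxon
  orgs <- sort_c(names(Filter(function(o) o$taxon_group == group, db$organisms)))
  qids <- sort_c(unique(result$query_ids))
  m <- matrix(0L, length(orgs), length(qids),
              dimnames = list(orgs, qids))
  for (r in seq_len(nrow(result$candidates))) {
    cand <- result$candidates[r, ]
    hit_orgs <- unique(cand$genes[[1]]$organism)
    m[hit_orgs, cand$query_reaction_id] <- 1L
  }
  structure(list(matrix = m, marginals = rowSums(m), taxon_group = group),
            class = "taxon_profile")
}

#' @export
print.taxon_profile <- function(x, ...) {
  cat(sprintf("<taxon_profile (%s): %d organisms x %d query reactions, %d cell(s) set>\n",
              x$taxon_group, nrow(x$matrix), ncol(x$matrix), sum(x$matrix)))
  invisible(x)
}

#' Roll candidate counts up the clades of a tree
#'
#' For every node of the tree, the sum of leaf marginals over its leaf
#' descendants (leaves absent from the profile count 0). Children therefore
#' sum exactly to their parent.
#'
#' @param profile A `taxon_profile`.
#' @param tree An `ape::phylo` tree whose tip labels are organism codes.
#' @return Data frame with columns `node` (ape node number), `label` (tip or
#'   node label, possibly empty), `n_tips`, `count`.
#' @export
clade_rollup <- function(profile, tree) {
  stopifnot(inherits(tree, "phylo"))
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  counts <- numeric(nnode)
  leaf_val <- function(lab) if (lab %in% names(profile$marginals))
    profile$marginals[[lab]] else 0
  counts[seq_len(ntip)] <- vapply(tree$tip.label, leaf_val, numeric(1))
  ntips_below <- c(rep(1, ntip), rep(0, ntip + tree$Nnode - ntip))
  # postorder accumulation over edges
  eo <- rev(seq_len(nrow(tree$edge)))
  for (e in eo) {
    par <- tree$edge[e, 1L]; child <- tree$edge[e, 2L]
    counts[par] <- counts[par] + counts[child]
    ntips_below[par] <- ntips_below[par] + ntips_below[child]
  }
  labels <- c(tree$tip.label,
              tree$node.label %||% rep("", tree$Nnode))
  if (length(labels) < nnode) labels <- c(labels, rep("", nnode - length(labels)))
  data.frame(node = seq_len(nnode), label = labels, n_tips = ntips_below,
             count = counts, stringsAsFactors = FALSE)
}

#' Export a tree-annotation heatmap (iTOL dataset style)
#'
#' Writes a plain-text dataset annotation consumable by tree viewers: a
#' `DATASET_HEATMAP` header with tab separator and field labels (the query
#' reaction ids), then one `leaf label + per-field 0/1 values` line per tree
#' leaf, in tree order. Leaves absent from the profile get zero-filled lines;
#' all leaf/profile mismatches are reported as a warning list. Output is
#' byte-stable for fixed input.
#'
#' @param profile A `taxon_profile`.
#' @param tree An `ape::phylo` tree (leaf names should be organism codes).
#' @param path Output path.
#' @return Invisibly, the character vector of mismatched leaf names.
#' @export
export_itol_heatmap <- function(profile, tree, path) {
  stopifnot(inherits(tree, "phylo"))
  leaves <- tree$tip.label
  missing <- setdiff(leaves, rownames(profile$matrix))
  if (length(missing) > 0L)
    warning("tree leaves absent from profile (zero-filled): ",
            paste(missing, collapse = ", "))
  lines <- c(
    "DATASET_HEATMAP",
    "SEPARATOR TAB",
    paste0("DATASET_LABEL\tcandidate reactions (", profile$taxon_group, ")"),
    "COLOR\t#084594",
    paste(c("FIELD_LABELS", colnames(profile$matrix)), collapse = "\t"),
    "DATA")
  for (leaf in leaves) {
    vals <- if (leaf %in% rownames(profile$matrix))
      profile$matrix[leaf, ] else rep(0L, ncol(profile$matrix))
    lines <- c(lines, paste(c(leaf, vals), collapse = "\t"))
  }
  write_lines_lf(lines, path)
  invisible(missing)
}

#' Read a tree-annotation heatmap written by [export_itol_heatmap()]
#' @param path Annotation file path.
#' @return Integer matrix (leaves x fields).
#' @export
read_itol_heatmap <- function(path) {
  lines <- readLines(path, warn = FALSE)
  fl <- grep("^FIELD_LABELS\t", lines, value = TRUE)
  fields <- strsplit(fl, "\t", fixed = TRUE)[[1]][-1]
  start <- which(lines == "DATA")
  rows <- lines[seq(start + 1L, length(lines))]
  rows <- rows[nzchar(rows)]
  f <- strsplit(rows, "\t", fixed = TRUE)
  m <- t(vapply(f, function(x) as.integer(x[-1]), integer(length(fields))))
  if (length(fields) == 1L) m <- matrix(as.integer(unlist(lapply(f, `[`, -1))),
                                        ncol = 1L)
  dimnames(m) <- list(vapply(f, `[[`, character(1), 1), fields)
  m
}
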