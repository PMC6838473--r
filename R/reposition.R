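# The re-positioning screen: score every taxon-specific query reaction of
# one taxon group against all reactions with genes in a target group,
# threshold, rank, and report candidate genes.

#' Screen configuration
#'
#' @param weights Triple-similarity weights (see [triple_similarity()]).
#' @param tiers Ascending similarity tiers for the summary counts.
#' @param include_orphans Include orphan-specific reactions among queries.
#' @param mode,size_cap Atom-mapping options (see [map_atoms()]).
#' @param prefilter Skip scoring pairs whose reaction-center element
#'   multisets are disjoint. A coarse speed knob, off by default; its
#'   conservativeness at the run threshold is checked empirically in the
#'   test suite, not guaranteed analytically.
#' @param seed Recorded in the result for provenance symmetry with the
#'   generator (the screen itself is deterministic).
#' @param verbose Emit per-query progress messages.
#' @return A `screen_config` list.
#' @export
screen_config <- function(weights = DEFAULT_RDM_WEIGHTS,
                          tiers = seq(0.4, 0.9, by = 0.1),
                          include_orphans = TRUE,
                          mode = "auto", size_cap = 30L,
                          prefilter = FALSE, seed = NA_integer_,
                          verbose = FALSE) {
  check_weights(weights)
  list(weights = weights, tiers = tiers, include_orphans = include_orphans,
       mode = mode, size_cap = size_cap, prefilter = prefilter, seed = seed,
       verbose = verbose)
}

#' Read a screen configuration from YAML
#' @param path YAML file with any subset of the [screen_config()] fields.
#' @return A `screen_config` list.
#' @export
read_screen_config <- function(path) {
  y <- yaml::read_yaml(path)
  cfg <- screen_config()
  for (k in intersect(names(y), names(cfg))) cfg[[k]] <- y[[k]]
  if (!is.null(y$weights)) cfg$weights <- as.numeric(unlist(y$weights))
  check_weights(cfg$weights)
  cfg
}

center_elements <- function(pattern) {
  vapply(pattern$triples, function(t) strsplit(t$r[1], ".", fixed = TRUE)[[1]][1],
         character(1))
}

# genes of a reaction's clusters restricted to organisms of a taxon group
genes_in_group <- function(reaction, db, taxon_group) {
  rows <- lapply(reaction$cluster_ids, function(cid) {
    m <- db$clusters[[cid]]$members
    grp <- vapply(m$organism, function(o) db$organisms[[o]]$taxon_group,
                  character(1))
    m <- m[grp == taxon_group, , drop = FALSE]
    if (nrow(m) == 0L) return(NULL)
    data.frame(organism = m$organism, gene = m$gene, cluster = cid,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(organism = character(), gene = character(),
                      cluster = character(), stringsAsFactors = FALSE)
  out <- unique(out)
  out[order_c(out$organism, out$gene, out$cluster), , drop = FALSE]
}

#' Run the enzyme re-positioning screen
#'
#' Queries are the `query_taxon`-specific reactions (optionally including
#' orphan-specific ones); the target pool is every reaction with at least one
#' gene in `target_taxon`, excluding the query itself. Every (query, target)
#' pair is scored with [score_reaction_pair()] on the main reactant pairs;
#' hits with score at or above `threshold` are retained with the hit
#' reaction's genes restricted to target-taxon organisms. Candidates are
#' sorted by (query id, descending score, hit id); ranking ties are broken by
#' hit reaction id for reproducibility. An empty query set or target pool
#' yields an empty result with a warning status rather than an error.
#'
#' @param db A `reaction_db`.
#' @param query_taxon,target_taxon Taxon-group labels.
#' @param threshold Minimum similarity score in `[0, 1]` (default 0.4).
#' @param config A [screen_config()].
#' @return A `screen_result`: run configuration, the candidate table
#'   (`candidates`: one row per (query, hit) with a `genes` list-column),
#'   per-tier summary counts, and a `status` flag.
#' @export
run_screen <- function(db, query_taxon, target_taxon, threshold = 0.4,
                       config = screen_config()) {
  stopifnot(threshold >= 0, threshold <= 1)
  run_cfg <- list(threshold = threshold, weights = config$weights,
                  query_taxon = query_taxon, target_taxon = target_taxon,
                  vocabulary = ATOM_TYPE_VOCABULARY, seed = config$seed,
                  tiers = config$tiers, main_pair_convention = "first-pair")
  queries <- find_taxon_specific(db, query_taxon, config$include_orphans)
  query_ids <- vapply(queries, `[[`, character(1), "reaction_id")
  target_ids <- sort_c(names(Filter(
    function(r) nrow(genes_in_group(r, db, target_taxon)) > 0L, db$reactions)))
  empty <- data.frame(query_reaction_id = character(),
                      hit_reaction_id = character(), score = numeric(),
                      ec_of_hit = character(), stringsAsFactors = FALSE)
  empty$genes <- list()
  mk_result <- function(cands, status) {
    res <- structure(list(config = run_cfg, candidates = cands,
                          query_ids = query_ids, target_ids = target_ids,
                          status = status, tier_counts = NULL),
                     class = "screen_result")
    res$tier_counts <- tier_counts(res, config$tiers)
    res
  }
  if (length(query_ids) == 0L) {
    warning("run_screen: empty query set for taxon group ", sQuote(query_taxon))
    return(mk_result(empty, "empty-queries"))
  }
  if (length(target_ids) == 0L) {
    warning("run_screen: empty target pool for taxon group ", sQuote(target_taxon))
    return(mk_result(empty, "empty-targets"))
  }
  cache <- rdm_cache()
  sc_cfg <- score_config(weights = config$weights, mode = config$mode,
                         size_cap = config$size_cap, cache = cache)
  pat_of <- function(id) get_rdm_pattern(reactant_pair_of(db, id), sc_cfg)
  rows <- list()
  for (qid in query_ids) {
    qpat <- pat_of(qid)
    qelem <- center_elements(qpat)
    if (config$verbose)
      message("query ", qid, ": scoring ", length(target_ids), " targets")
    for (tid in setdiff(target_ids, qid)) {
      tpat <- pat_of(tid)
      if (config$prefilter &&
          length(intersect(qelem, center_elements(tpat))) == 0L &&
          (length(qelem) > 0L || length(center_elements(tpat)) > 0L)) next
      sc <- pattern_similarity(qpat, tpat, weights = config$weights)
      if (sc$value >= threshold) {
        hit <- db$reactions[[tid]]
        rows[[length(rows) + 1L]] <- list(
          query_reaction_id = qid, hit_reaction_id = tid, score = sc$value,
          ec_of_hit = hit$ec, genes = genes_in_group(hit, db, target_taxon))
      }
    }
  }
  if (length(rows) == 0L) return(mk_result(empty, "ok"))
  cands <- data.frame(
    query_reaction_id = vapply(rows, `[[`, character(1), "query_reaction_id"),
    hit_reaction_id = vapply(rows, `[[`, character(1), "hit_reaction_id"),
    score = vapply(rows, `[[`, numeric(1), "score"),
    ec_of_hit = vapply(rows, `[[`, character(1), "ec_of_hit"),
    stringsAsFactors = FALSE)
  cands$genes <- lapply(rows, `[[`, "genes")
  ord <- order_c(cands$query_reaction_id, -cands$score, cands$hit_reaction_id)
  cands <- cands[ord, , drop = FALSE]
  rownames(cands) <- NULL
  mk_result(cands, "ok")
}

#' @export
print.screen_result <- function(x, ...) {
  cat(sprintf(
    "<screen_result [%s]: %d queries (%s) x %d targets (%s), threshold %.2f, %d candidate hit(s)>\n",
    x$status, length(x$query_ids), x$config$query_taxon, length(x$target_ids),
    x$config$target_taxon, x$config$threshold, nrow(x$candidates)))
  if (!is.null(x$tier_counts)) {
    cat("  queries with a candidate at score >= tier:\n")
    for (t in names(x$tier_counts))
      cat(sprintf("    %s: %d\n", t, x$tier_counts[[t]]))
  }
  invisible(x)
}

#' Count queries with a candidate per similarity tier
#'
#' For each tier, the number of distinct query reactions having at least one
#' candidate with score at or above the tier. Counts are necessarily
#' non-increasing along ascending tiers (nested sets).
#'
#' @param result A `screen_result`.
#' @param tiers Ascending numeric tiers in `[0, 1]`.
#' @return Named integer vector, one count per tier.
#' @export
tier_counts <- function(result, tiers = seq(0.4, 0.9, by = 0.1)) {
  if (any(tiers < 0 | tiers > 1))
    stop_enzrepo("tiers must lie in [0, 1]")
  if (is.unsorted(tiers, strictly = TRUE))
    stop_enzrepo("tiers must be strictly ascending")
  cands <- result$candidates
  counts <- vapply(tiers, function(t)
    length(unique(cands$query_reaction_id[cands$score >= t])), integer(1))
  stats::setNames(counts, format(tiers, trim = TRUE))
}

#' Write the candidate gene table
#'
#' One row per candidate gene, mirroring a published candidate report:
#' columns `query_reaction_id`, `hit_reaction_id`, `organism`, `gene`,
#' `score` (3 decimals), `cluster`, `definition`, `ko` (definition and KO
#' split from the cluster's `ko_annotation`, `"K00000: text"` convention),
#' and `ec_of_hit`.
#'
#' @param result A `screen_result`.
#' @param db The `reaction_db` the screen ran on (for cluster annotations).
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_candidate_table <- function(result, db, path) {
  header <- paste("#query_reaction_id", "hit_reaction_id", "organism", "gene",
                  "score", "cluster", "definition", "ko", "ec_of_hit",
                  sep = "\t")
  rows <- character()
  for (r in seq_len(nrow(result$candidates))) {
    cand <- result$candidates[r, ]
    genes <- cand$genes[[1]]
    for (g in seq_len(nrow(genes))) {
      anno <- db$clusters[[genes$cluster[g]]]$ko_annotation
      ko <- ""; def <- ""
      if (!is.na(anno)) {
        parts <- strsplit(anno, ": ", fixed = TRUE)[[1]]
        if (length(parts) >= 2L && grepl("^K\\d{5}$", parts[1])) {
          ko <- parts[1]; def <- paste(parts[-1], collapse = ": ")
        } else def <- anno
      }
      rows <- c(rows, paste(
        cand$query_reaction_id, cand$hit_reaction_id, genes$organism[g],
        genes$gene[g], sprintf("%.3f", cand$score), genes$cluster[g],
        def, ko, if (is.na(cand$ec_of_hit)) "" else cand$ec_of_hit,
        sep = "\t"))
    }
  }
  write_lines_lf(c(header, rows), path)
}

#' Read a candidate gene table
#' @param path A TSV written by [write_candidate_table()].
#' @return Data frame with one row per candidate gene.
#' @export
read_candidate_table <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  cols <- c("query_reaction_id", "hit_reaction_id", "organism", "gene",
            "score", "cluster", "definition", "ko", "ec_of_hit")
  if (length(lines) == 0L) {
    df <- as.data.frame(stats::setNames(rep(list(character()), length(cols)),
                                        cols), stringsAsFactors = FALSE)
    df$score <- numeric()
    return(df)
  }
  f <- strsplit(lines, "\t", fixed = TRUE)
  df <- as.data.frame(stats::setNames(lapply(seq_along(cols), function(i)
    vapply(f, function(x) if (length(x) >= i) x[[i]] else "", character(1))),
    cols), stringsAsFactors = FALSE)
  df$score <- as.numeric(df$score)
  df
}
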