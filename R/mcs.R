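# Maximum common connected-subgraph atom mapping between substrate and
# product.
#
# Compatibility: elements must match; bond ORDERS deliberately need not
# (order changes are exactly what RDM extraction detects), but bond
# EXISTENCE must agree within the mapped set (induced common subgraph), and
# the mapped subgraph must be connected through common bonds. Exact search
# is a backtracking enumeration over connected extensions with a
# reachability bound; beyond the size cap a documented greedy extension
# heuristic is used and the mapping is labeled with its mode.

#' Construct a reactant pair
#'
#' One substrate -> product transformation; the atom mapping is attached
#' after [map_atoms()].
#'
#' @param substrate,product `compound_graph` objects.
#' @return A `reactant_pair`.
#' @export
reactant_pair <- function(substrate, product) {
  stopifnot(inherits(substrate, "compound_graph"),
            inherits(product, "compound_graph"))
  structure(list(substrate = substrate, product = product, mapping = NULL),
            class = "reactant_pair")
}

#' Compute a maximum common connected-subgraph atom mapping
#'
#' Finds the largest atom correspondence between substrate and product such
#' that mapped atoms have identical elements, bond existence is preserved in
#' both directions within the mapped set, and the mapped subgraph is
#' connected through bonds present on both sides. Bond orders are not a
#' compatibility constraint. Among equal-size maximum mappings the
#' lexicographically smallest sequence of (substrate index, product index)
#' pairs is returned, making the result bit-reproducible.
#'
#' @param pair A `reactant_pair`.
#' @param mode `"exact"` (optimal, guaranteed up to `size_cap` atoms per
#'   graph), `"greedy"` (fast heuristic), or `"auto"` (exact when both graphs
#'   are within the cap).
#' @param size_cap Heavy-atom count above which `"auto"` falls back to the
#'   greedy heuristic.
#' @return An `atom_mapping`: list with `pairs` (two-column integer matrix of
#'   0-based substrate/product indices, sorted by substrate index), `score`
#'   (number of mapped atoms) and `mode` actually used.
#' @export
map_atoms <- function(pair, mode = c("auto", "exact", "greedy"), size_cap = 30L) {
  mode <- match.arg(mode)
  s <- pair$substrate; p <- pair$product
  ns <- nrow(s$atoms); np <- nrow(p$atoms)
  use_exact <- switch(mode,
    exact = TRUE, greedy = FALSE,
    auto = ns <= size_cap && np <= size_cap)
  adj_s <- cg_order_matrix(s) != ""
  adj_p <- cg_order_matrix(p) != ""
  compat <- outer(s$atoms$element, p$atoms$element, "==")
  res <- if (use_exact)
    mcs_exact_cpp(matrix(as.integer(adj_s), nrow(adj_s)),
                  matrix(as.integer(adj_p), nrow(adj_p)),
                  matrix(as.integer(compat), nrow(compat)))
  else mcs_greedy(adj_s, adj_p, compat, s$atoms$atom_type, p$atoms$atom_type)
  pairs <- res
  if (nrow(pairs) > 0L) {
    pairs <- pairs[order(pairs[, 1L]), , drop = FALSE]
    pairs <- pairs - 1L                       # back to 0-based
  }
  colnames(pairs) <- c("substrate", "product")
  structure(list(pairs = pairs, score = nrow(pairs),
                 mode = if (use_exact) "exact" else "greedy"),
            class = "atom_mapping")
}

#' @export
print.atom_mapping <- function(x, ...) {
  cat(sprintf("<atom_mapping: %d atoms mapped (%s mode)>\n", x$score, x$mode))
  invisible(x)
}

# enumerate frontier candidates for a partial mapping; 1-based indices
mcs_candidates <- function(adj_s, adj_p, compat, ms, mp, banned) {
  mapped_s <- which(ms > 0L)
  free_s <- which(ms == 0L)
  free_p <- which(mp == 0L)
  out <- NULL
  for (i in free_s) {
    for (j in free_p) {
      if (!compat[i, j] || banned[i, j]) next
      ok <- TRUE; touch <- FALSE
      for (k in mapped_s) {
        bs <- adj_s[i, k]; bp <- adj_p[j, ms[k]]
        if (bs != bp) { ok <- FALSE; break }
        if (bs) touch <- TRUE
      }
      if (ok && (length(mapped_s) == 0L || touch))
        out <- rbind(out, c(i, j))
    }
  }
  out
}

mcs_greedy <- function(adj_s, adj_p, compat, type_s, type_p) {
  ns <- nrow(adj_s); np <- nrow(adj_p)
  ms <- integer(ns); mp <- integer(np)
  pick <- function(cands) {
    if (is.null(cands) || nrow(cands) == 0L) return(NULL)
    same_type <- type_s[cands[, 1L]] == type_p[cands[, 2L]]
    pool <- if (any(same_type)) cands[same_type, , drop = FALSE] else cands
    pool[order(pool[, 1L], pool[, 2L])[1L], ]
  }
  banned <- matrix(FALSE, ns, np)
  size <- 0L
  repeat {
    cand <- pick(mcs_candidates(adj_s, adj_p, compat, ms, mp, banned))
    if (is.null(cand)) break
    ms[cand[1L]] <- cand[2L]; mp[cand[2L]] <- cand[1L]
    size <- size + 1L
  }
  idx <- which(ms > 0L)
  cbind(idx, ms[idx])
}
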