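# RDM reaction-center patterns and similarity between reactions.
#
# A mapped atom is a reaction center iff its atom-type code changes across
# the mapping, OR it is adjacent to an unmapped atom on either side, OR an
# incident bond within the mapped set changes order. Each center yields one
# triple: the R change (type before/after at the center), the D set (types
# of unmapped atoms adjacent to the center, on either side), and the M set
# (type-before/after pairs of mapped atoms adjacent to the center).

DEFAULT_RDM_WEIGHTS <- c(r = 0.5, d = 0.25, m = 0.25)

rdm_triple <- function(r_before, r_after, d_set, m_set) {
  structure(list(r = c(r_before, r_after),
                 d = sort_c(d_set),
                 m = sort_c(m_set)),
            class = "rdm_triple")
}

triple_key <- function(t) {
  paste(t$r[1], t$r[2], paste(t$d, collapse = ","), paste(t$m, collapse = ","),
        sep = "|")
}

#' Extract the RDM pattern of a reactant pair
#'
#' Walks the atom mapping and builds one RDM triple per reaction-center
#' atom. The pattern is empty exactly when the mapping is a full atom-type-
#' preserving isomorphism between the two connected graphs.
#'
#' @param pair A `reactant_pair` with typed compound graphs.
#' @param mapping An `atom_mapping` valid for the pair (defaults to
#'   computing one with [map_atoms()]).
#' @return An `rdm_pattern`: list of `rdm_triple`s plus provenance
#'   (`pair_id`) and the atom-type vocabulary version.
#' @export
extract_rdm <- function(pair, mapping = NULL) {
  s <- pair$substrate; p <- pair$product
  if (is.null(mapping)) mapping <- map_atoms(pair)
  mp <- mapping$pairs
  ns <- nrow(s$atoms); np <- nrow(p$atoms)
  if (nrow(mp) > 0L) {
    if (any(mp[, 1L] < 0L | mp[, 1L] >= ns | mp[, 2L] < 0L | mp[, 2L] >= np) ||
        anyDuplicated(mp[, 1L]) || anyDuplicated(mp[, 2L]) ||
        any(s$atoms$element[mp[, 1L] + 1L] != p$atoms$element[mp[, 2L] + 1L]))
      stop_enzrepo("mapping does not fit this reactant pair",
                   class = "enzrepo_contract_error")
  }
  type_s <- s$atoms$atom_type; type_p <- p$atoms$atom_type
  ord_s <- cg_order_matrix(s); ord_p <- cg_order_matrix(p)
  s2p <- rep(NA_integer_, ns); p2s <- rep(NA_integer_, np)
  if (nrow(mp) > 0L) {
    s2p[mp[, 1L] + 1L] <- mp[, 2L] + 1L
    p2s[mp[, 2L] + 1L] <- mp[, 1L] + 1L
  }
  nb_s <- cg_neighbors(s); nb_p <- cg_neighbors(p)
  triples <- list()
  for (r in seq_len(nrow(mp))) {
    i <- mp[r, 1L] + 1L; j <- mp[r, 2L] + 1L
    un_s <- nb_s[[i]][is.na(s2p[nb_s[[i]]])]
    un_p <- nb_p[[j]][is.na(p2s[nb_p[[j]]])]
    mapped_nb <- nb_s[[i]][!is.na(s2p[nb_s[[i]]])]
    # bond present on both sides iff induced-consistent; order may differ
    order_change <- any(vapply(mapped_nb, function(k) {
      jj <- s2p[k]
      ord_s[i, k] != "" && ord_p[j, jj] != "" && ord_s[i, k] != ord_p[j, jj]
    }, logical(1)))
    is_center <- type_s[i] != type_p[j] ||
      length(un_s) > 0L || length(un_p) > 0L || order_change
    if (!is_center) next
    m_nb <- mapped_nb[vapply(mapped_nb, function(k) ord_p[j, s2p[k]] != "",
                             logical(1))]
    triples[[length(triples) + 1L]] <- rdm_triple(
      r_before = type_s[i], r_after = type_p[j],
      d_set = c(type_s[un_s], type_p[un_p]),
      m_set = paste0(type_s[m_nb], ">", type_p[s2p[m_nb]]))
  }
  if (length(triples) > 0L)
    triples <- triples[order_c(vapply(triples, triple_key, character(1)))]
  structure(list(triples = triples,
                 pair_id = paste0(s$compound_id, ">", p$compound_id),
                 vocabulary = ATOM_TYPE_VOCABULARY),
            class = "rdm_pattern")
}

#' @export
print.rdm_pattern <- function(x, ...) {
  cat(sprintf("<rdm_pattern %s: %d reaction-center triple(s)>\n",
              x$pair_id, length(x$triples)))
  for (t in x$triples)
    cat(sprintf("  R %s -> %s | D {%s} | M {%s}\n", t$r[1], t$r[2],
                paste(t$d, collapse = ", "), paste(t$m, collapse = ", ")))
  invisible(x)
}

check_weights <- function(weights) {
  if (length(weights) != 3L || any(weights < 0) ||
      abs(sum(weights) - 1) > 1e-9)
    stop_enzrepo("weights must be 3 nonnegative numbers summing to 1",
                 class = "enzrepo_config_error")
  invisible(weights)
}

#' Similarity between two RDM triples
#'
#' `w_R * [equal R change] + w_D * jaccard(D sets) + w_M * jaccard(M sets)`,
#' with multiset Jaccard and `jaccard(empty, empty) = 1` (two pure
#' bond-order-change centers with no difference region can score 1).
#'
#' @param a,b `rdm_triple`s.
#' @param weights Numeric vector `(w_R, w_D, w_M)`, nonnegative, summing
#'   to 1; default `(0.5, 0.25, 0.25)` — the reaction-center change
#'   dominates.
#' @return A number in `[0, 1]`.
#' @export
triple_similarity <- function(a, b, weights = DEFAULT_RDM_WEIGHTS) {
  check_weights(weights)
  weights[[1L]] * as.numeric(identical(a$r, b$r)) +
    weights[[2L]] * multiset_jaccard(a$d, b$d) +
    weights[[3L]] * multiset_jaccard(a$m, b$m)
}

#' Similarity between two RDM patterns
#'
#' Maximum-weight bipartite matching between the two triple multisets under
#' [triple_similarity()], normalized by the larger pattern size:
#' `sum(matched weights) / max(|p|, |q|)`. Two empty patterns score 1;
#' exactly one empty scores 0. Symmetric, bounded in `[0, 1]`, and equal to
#' 1 exactly when the two triple multisets are equal.
#'
#' @param p,q `rdm_pattern`s extracted under the same atom-type vocabulary.
#' @param weights Triple-similarity weights.
#' @return A `similarity_score`: list with `value` and `components` (matched
#'   triple indices and weights, for explainability).
#' @export
pattern_similarity <- function(p, q, weights = DEFAULT_RDM_WEIGHTS) {
  if (!identical(p$vocabulary, q$vocabulary))
    stop_enzrepo("RDM patterns use different atom-type vocabularies (",
                 p$vocabulary, " vs ", q$vocabulary, ")")
  check_weights(weights)
  n <- length(p$triples); m <- length(q$triples)
  empty_components <- data.frame(p_triple = integer(), q_triple = integer(),
                                 weight = numeric())
  if (n == 0L && m == 0L)
    return(structure(list(value = 1, components = empty_components),
                     class = "similarity_score"))
  if (n == 0L || m == 0L)
    return(structure(list(value = 0, components = empty_components),
                     class = "similarity_score"))
  w <- matrix(0, n, m)
  for (i in seq_len(n)) for (j in seq_len(m))
    w[i, j] <- triple_similarity(p$triples[[i]], q$triples[[j]], weights)
  pos <- which(w > 0, arr.ind = TRUE)
  if (nrow(pos) == 0L)
    return(structure(list(value = 0, components = empty_components),
                     class = "similarity_score"))
  g <- igraph::make_bipartite_graph(
    types = c(rep(FALSE, n), rep(TRUE, m)),
    edges = as.vector(t(cbind(pos[, 1L], n + pos[, 2L]))))
  match <- igraph::max_bipartite_match(g, weights = w[pos], eps = 1e-10)
  mi <- match$matching[seq_len(n)]
  matched <- which(!is.na(mi))
  comp <- data.frame(p_triple = matched, q_triple = mi[matched] - n,
                     weight = w[cbind(matched, mi[matched] - n)])
  structure(list(value = sum(comp$weight) / max(n, m), components = comp),
            class = "similarity_score")
}

#' @export
print.similarity_score <- function(x, ...) {
  cat(sprintf("<similarity_score: %.3f (%d matched triple(s))>\n",
              x$value, nrow(x$components)))
  invisible(x)
}

#' Scoring configuration for reaction comparison
#'
#' @param weights Triple-similarity weights `(w_R, w_D, w_M)`.
#' @param mode Atom-mapping mode passed to [map_atoms()].
#' @param size_cap Exact-MCS size cap.
#' @param cache Optional environment used to memoize RDM patterns, keyed by
#'   (substrate id, product id, vocabulary version). Create one per database
#'   with [new.env()] or [rdm_cache()].
#' @return A `score_config` list.
#' @export
score_config <- function(weights = DEFAULT_RDM_WEIGHTS, mode = "auto",
                         size_cap = 30L, cache = NULL) {
  check_weights(weights)
  list(weights = weights, mode = mode, size_cap = size_cap, cache = cache)
}

#' Create an RDM pattern cache
#' @return An empty environment.
#' @export
rdm_cache <- function() new.env(parent = emptyenv())

get_rdm_pattern <- function(pair, config = score_config()) {
  key <- paste(pair$substrate$compound_id, pair$product$compound_id,
               ATOM_TYPE_VOCABULARY, sep = "\r")
  if (!is.null(config$cache) && !is.null(config$cache[[key]]))
    return(config$cache[[key]])
  pat <- extract_rdm(pair, map_atoms(pair, mode = config$mode,
                                     size_cap = config$size_cap))
  if (!is.null(config$cache)) config$cache[[key]] <- pat
  pat
}

#' Score the similarity of two reactions
#'
#' Composes atom mapping and RDM extraction on both reactant pairs, then
#' compares the patterns with [pattern_similarity()]. Patterns are memoized
#' in `config$cache` when provided.
#'
#' @param query,target `reactant_pair`s.
#' @param config A [score_config()].
#' @return A `similarity_score`.
#' @export
score_reaction_pair <- function(query, target, config = score_config()) {
  pattern_similarity(get_rdm_pattern(query, config),
                     get_rdm_pattern(target, config),
                     weights = config$weights)
}

#' Serialize an RDM pattern to JSON
#'
#' Triples are written as sorted lists so serialization is canonical; the
#' vocabulary version is embedded and checked on read.
#'
#' @param pattern An `rdm_pattern`.
#' @return A JSON string.
#' @export
rdm_pattern_to_json <- function(pattern) {
  obj <- list(
    pair_id = pattern$pair_id,
    vocabulary = pattern$vocabulary,
    triples = lapply(pattern$triples, function(t)
      list(r = as.list(t$r), d = as.list(t$d), m = as.list(t$m))))
  as.character(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA))
}

#' Deserialize an RDM pattern from JSON
#' @param json A JSON string produced by [rdm_pattern_to_json()].
#' @return An `rdm_pattern`.
#' @export
rdm_pattern_from_json <- function(json) {
  obj <- jsonlite::fromJSON(json, simplifyVector = FALSE)
  triples <- lapply(obj$triples, function(t)
    rdm_triple(t$r[[1]], t$r[[2]], unlist(t$d) %||% character(),
               unlist(t$m) %||% character()))
  structure(list(triples = triples, pair_id = obj$pair_id,
                 vocabulary = obj$vocabulary),
            class = "rdm_pattern")
}
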