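# CompoundGraph: heavy-atom molecular graph with deterministic atom-type codes.
#
# Atoms are stored 0-based (index column) in a data frame; bonds reference
# atom indices with order one of "1", "2", "3", "ar". Hydrogens are implicit:
# explicit H atoms are stripped at parse time and remembered per heavy atom in
# the n_h column.

ELEMENT_SET <- c(
  "C", "N", "O", "S", "P", "F", "Cl", "Br", "I", "B", "Si", "Se", "As",
  "Na", "K", "Mg", "Ca", "Fe", "Zn", "Cu", "Mn", "Co", "Ni", "Mo", "H"
)

BOND_ORDERS <- c("1", "2", "3", "ar")

#' Current atom-type vocabulary version
#'
#' RDM patterns are only comparable when extracted under the same atom-type
#' vocabulary; this string is embedded in every pattern.
#' @export
ATOM_TYPE_VOCABULARY <- "enzrepo-atomtypes-1"

#' Construct a compound graph
#'
#' Builds a heavy-atom molecular graph from element symbols and a bond list,
#' validates its structural invariants, and assigns atom-type codes (see
#' [assign_atom_types()]).
#'
#' @param compound_id Identifier for the compound.
#' @param elements Character vector of element symbols, one per atom; atom
#'   `i` (0-based) is `elements[i + 1]`.
#' @param bonds Data frame with columns `a`, `b` (0-based atom indices) and
#'   `order` (one of `"1"`, `"2"`, `"3"`, `"ar"`); `NULL` means no bonds.
#' @param n_h Optional integer vector of stripped explicit-hydrogen counts.
#' @return An object of class `compound_graph`.
#' @export
compound_graph <- function(compound_id, elements, bonds = NULL, n_h = NULL) {
  n <- length(elements)
  bad <- setdiff(unique(elements), ELEMENT_SET)
  if (length(bad) > 0L)
    stop_enzrepo("unknown element symbol(s): ", paste(bad, collapse = ", "))
  if (is.null(bonds) || nrow(bonds) == 0L) {
    bonds <- data.frame(a = integer(), b = integer(), order = character(),
                        stringsAsFactors = FALSE)
  } else {
    bonds <- data.frame(a = as.integer(bonds$a), b = as.integer(bonds$b),
                        order = as.character(bonds$order),
                        stringsAsFactors = FALSE)
    if (any(bonds$a < 0L | bonds$a >= n | bonds$b < 0L | bonds$b >= n))
      stop_enzrepo("bond references a non-existent atom in compound ", compound_id)
    if (any(bonds$a == bonds$b))
      stop_enzrepo("self-bond in compound ", compound_id)
    swap <- bonds$a > bonds$b
    tmp <- bonds$a[swap]; bonds$a[swap] <- bonds$b[swap]; bonds$b[swap] <- tmp
    if (anyDuplicated(bonds[, c("a", "b")]))
      stop_enzrepo("duplicate bond in compound ", compound_id)
    if (!all(bonds$order %in% BOND_ORDERS))
      stop_enzrepo("invalid bond order in compound ", compound_id,
                   " (allowed: ", paste(BOND_ORDERS, collapse = ", "), ")")
    bonds <- bonds[order_c(bonds$a, bonds$b), , drop = FALSE]
    rownames(bonds) <- NULL
  }
  g <- structure(
    list(
      compound_id = compound_id,
      atoms = data.frame(
        index = seq_len(n) - 1L,
        element = as.character(elements),
        atom_type = NA_character_,
        ring_flag = NA,
        n_h = as.integer(n_h %||% rep(0L, n)),
        stringsAsFactors = FALSE
      ),
      bonds = bonds
    ),
    class = "compound_graph"
  )
  assign_atom_types(g)
}

#' @export
print.compound_graph <- function(x, ...) {
  cat(sprintf("<compound_graph %s: %d atoms, %d bonds>\n",
              x$compound_id, nrow(x$atoms), nrow(x$bonds)))
  invisible(x)
}

# neighbor list, 1-based internal indexing
cg_neighbors <- function(graph) {
  n <- nrow(graph$atoms)
  nb <- vector("list", n)
  for (k in seq_len(nrow(graph$bonds))) {
    a <- graph$bonds$a[k] + 1L
    b <- graph$bonds$b[k] + 1L
    nb[[a]] <- c(nb[[a]], b)
    nb[[b]] <- c(nb[[b]], a)
  }
  lapply(nb, function(v) sort(unique(v %||% integer())))
}

# n x n character matrix of bond orders ("" = no bond), 1-based
cg_order_matrix <- function(graph) {
  n <- nrow(graph$atoms)
  m <- matrix("", n, n)
  if (nrow(graph$bonds) > 0L) {
    a <- graph$bonds$a + 1L
    b <- graph$bonds$b + 1L
    m[cbind(a, b)] <- graph$bonds$order
    m[cbind(b, a)] <- graph$bonds$order
  }
  m
}

# Ring membership: an atom is in a ring iff it is incident to a cycle edge,
# i.e. to an edge that is not a bridge. Equivalent to membership in some
# smallest-set-of-smallest-rings ring for flag purposes.
cg_ring_flags <- function(graph) {
  n <- nrow(graph$atoms)
  flags <- rep(FALSE, n)
  if (nrow(graph$bonds) == 0L) return(flags)
  ig <- igraph::make_graph(edges = rbind(graph$bonds$a + 1L, graph$bonds$b + 1L),
                           n = n, directed = FALSE)
  br <- igraph::bridges(ig)
  cyc <- setdiff(seq_len(nrow(graph$bonds)), as.integer(br))
  for (k in cyc) flags[c(graph$bonds$a[k], graph$bonds$b[k]) + 1L] <- TRUE
  flags
}

#' Assign deterministic atom-type codes
#'
#' Every heavy atom receives a code `ELEMENT.hyb.ring.het` where
#' `hyb` is a hybridization class derived from incident bond orders
#' (`ar` if any aromatic bond; `sp` if any triple or two or more double bonds;
#' `sp2` if exactly one double bond; `sp3` otherwise — the `sp3` class doubles
#' as the catch-all for unusual environments), `ring` is `rg`/`ac` for
#' ring/acyclic membership, and `het` classifies the number of non-carbon
#' heavy-atom neighbors as `h0`, `h1` or `h2` (two or more). Examples:
#' a methane carbon is `C.sp3.ac.h0`, a benzene carbon `C.ar.rg.h0`.
#'
#' The assignment is a pure function of elements and bonds, hence idempotent
#' and equivariant under atom relabeling.
#'
#' @param graph A `compound_graph`.
#' @return The graph with `atom_type` and `ring_flag` columns filled in.
#' @export
assign_atom_types <- function(graph) {
  stopifnot(inherits(graph, "compound_graph"))
  n <- nrow(graph$atoms)
  if (n == 0L) return(graph)
  ring <- cg_ring_flags(graph)
  nb <- cg_neighbors(graph)
  ords <- vector("list", n)
  for (k in seq_len(nrow(graph$bonds))) {
    a <- graph$bonds$a[k] + 1L
    b <- graph$bonds$b[k] + 1L
    o <- graph$bonds$order[k]
    ords[[a]] <- c(ords[[a]], o)
    ords[[b]] <- c(ords[[b]], o)
  }
  hyb <- vapply(seq_len(n), function(i) {
    o <- ords[[i]] %||% character()
    if (any(o == "ar")) "ar"
    else if (any(o == "3") || sum(o == "2") >= 2L) "sp"
    else if (sum(o == "2") == 1L) "sp2"
    else "sp3"
  }, character(1))
  het <- vapply(seq_len(n), function(i) {
    k <- sum(graph$atoms$element[nb[[i]]] != "C")
    if (k == 0L) "h0" else if (k == 1L) "h1" else "h2"
  }, character(1))
  graph$atoms$ring_flag <- ring
  graph$atoms$atom_type <- paste(graph$atoms$element, hyb,
                                 ifelse(ring, "rg", "ac"), het, sep = ".")
  graph
}

#' Permute atom indices of a compound graph
#'
#' Relabels atoms by a permutation; useful for checking that typing, mapping
#' and scoring are invariant under atom-index relabeling.
#'
#' @param graph A `compound_graph`.
#' @param perm Integer permutation of `1..n`: new atom `i` (0-based
#'   `i - 1`) is old atom `perm[i] - 1`.
#' @return A relabeled `compound_graph` (types reassigned).
#' @export
permute_atoms <- function(graph, perm) {
  n <- nrow(graph$atoms)
  stopifnot(length(perm) == n, all(sort(perm) == seq_len(n)))
  inv <- integer(n)
  inv[perm] <- seq_len(n)
  bonds <- graph$bonds
  if (nrow(bonds) > 0L) {
    bonds$a <- inv[bonds$a + 1L] - 1L
    bonds$b <- inv[bonds$b + 1L] - 1L
  }
  compound_graph(graph$compound_id, graph$atoms$element[perm], bonds,
                 n_h = graph$atoms$n_h[perm])
}
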