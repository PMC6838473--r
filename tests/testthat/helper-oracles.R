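# Independent brute-force oracles. These deliberately reimplement the
# quantities under test by enumeration / plain dynamic programming and stay
# independent of the package's algorithmic code paths.

# ---- maximum common connected induced subgraph size, by exhaustive
# enumeration of all partial mappings (memoized on the mapping set) --------
oracle_mcs_size <- function(g1, g2) {
  n1 <- nrow(g1$atoms); n2 <- nrow(g2$atoms)
  el1 <- g1$atoms$element; el2 <- g2$atoms$element
  A1 <- matrix(FALSE, n1, n1); A2 <- matrix(FALSE, n2, n2)
  for (k in seq_len(nrow(g1$bonds)))
    A1[g1$bonds$a[k] + 1, g1$bonds$b[k] + 1] <- A1[g1$bonds$b[k] + 1, g1$bonds$a[k] + 1] <- TRUE
  for (k in seq_len(nrow(g2$bonds)))
    A2[g2$bonds$a[k] + 1, g2$bonds$b[k] + 1] <- A2[g2$bonds$b[k] + 1, g2$bonds$a[k] + 1] <- TRUE
  best <- 0L
  seen <- new.env(hash = TRUE, parent = emptyenv())
  rec <- function(pairs) {
    key <- paste0("k", paste(sort(paste(pairs[, 1], pairs[, 2])), collapse = ";"))
    if (!is.null(seen[[key]])) return(invisible())
    seen[[key]] <- TRUE
    best <<- max(best, nrow(pairs))
    used1 <- pairs[, 1]; used2 <- pairs[, 2]
    for (i in setdiff(seq_len(n1), used1)) {
      for (j in setdiff(seq_len(n2), used2)) {
        if (el1[i] != el2[j]) next
        ok <- TRUE; touch <- FALSE
        if (nrow(pairs) > 0) {
          for (r in seq_len(nrow(pairs))) {
            b1 <- A1[i, pairs[r, 1]]; b2 <- A2[j, pairs[r, 2]]
            if (b1 != b2) { ok <- FALSE; break }
            if (b1) touch <- TRUE
          }
          if (!touch) ok <- FALSE
        }
        if (ok) rec(rbind(pairs, c(i, j)))
      }
    }
  }
  rec(matrix(integer(), 0, 2))
  best
}

# ---- maximum-weight assignment by brute force over all matchings ---------
oracle_best_matching <- function(W) {
  n <- nrow(W); m <- ncol(W)
  if (n == 0 || m == 0) return(0)
  if (n > m) return(oracle_best_matching(t(W)))
  best <- 0
  rec <- function(i, used, acc) {
    if (i > n) { best <<- max(best, acc); return(invisible()) }
    rec(i + 1L, used, acc)                      # row i unmatched
    for (j in setdiff(seq_len(m), used))
      rec(i + 1L, c(used, j), acc + W[i, j])
  }
  rec(1L, integer(), 0)
  best
}

# ---- Smith-Waterman affine-gap DP mirroring the documented conventions ---
# gap of length k costs open + k * ext; start cell = max score with smallest
# query index then target index; preference diagonal > gap-in-target
# (consume query) > gap-in-query.
oracle_sw <- function(a, b, sub, open = 11, ext = 1) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  H <- matrix(0, n + 1, m + 1)
  E <- matrix(-Inf, n + 1, m + 1); F <- matrix(-Inf, n + 1, m + 1)
  pH <- matrix(0L, n + 1, m + 1); pE <- matrix(0L, n + 1, m + 1)
  pF <- matrix(0L, n + 1, m + 1)
  for (i in seq_len(n) + 1) {
    for (j in seq_len(m) + 1) {
      eH <- H[i, j - 1] - open - ext; eE <- E[i, j - 1] - ext
      if (eH >= eE) { E[i, j] <- eH; pE[i, j] <- 1L } else { E[i, j] <- eE; pE[i, j] <- 2L }
      fH <- H[i - 1, j] - open - ext; fF <- F[i - 1, j] - ext
      if (fH >= fF) { F[i, j] <- fH; pF[i, j] <- 1L } else { F[i, j] <- fF; pF[i, j] <- 2L }
      d <- H[i - 1, j - 1] + sub[A[i - 1], B[j - 1]]
      h <- 0; p <- 0L
      if (d > h) { h <- d; p <- 1L }
      if (F[i, j] > h) { h <- F[i, j]; p <- 2L }
      if (E[i, j] > h) { h <- E[i, j]; p <- 3L }
      H[i, j] <- h; pH[i, j] <- p
    }
  }
  best <- 0; bi <- 0L; bj <- 0L
  for (i in seq_len(n) + 1) for (j in seq_len(m) + 1)
    if (H[i, j] > best) { best <- H[i, j]; bi <- i; bj <- j }
  if (best <= 0)
    return(list(aligned = FALSE, score = 0, identity = 0, coverage = 0))
  i <- bi; j <- bj; state <- 0L
  n_match <- 0L; len <- 0L
  repeat {
    if (state == 0L) {
      p <- pH[i, j]
      if (p == 0L) break
      if (p == 1L) {
        len <- len + 1L
        if (A[i - 1] == B[j - 1]) n_match <- n_match + 1L
        i <- i - 1L; j <- j - 1L
      } else if (p == 2L) state <- 1L else state <- 2L
    } else if (state == 1L) {
      len <- len + 1L
      if (pF[i, j] == 1L) state <- 0L
      i <- i - 1L
    } else {
      len <- len + 1L
      if (pE[i, j] == 1L) state <- 0L
      j <- j - 1L
    }
  }
  list(aligned = TRUE, score = best,
       identity = 100 * n_match / len,
       coverage = 100 * ((bi - 1) - (i - 1 + 1) + 1) / n,
       q_start = i, q_end = bi - 1)
}

blosum62 <- local({
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
})

# ---- independent set-logic taxonomy oracle -------------------------------
oracle_classify <- function(reaction, group, db) {
  orgs <- character()
  for (cid in reaction$cluster_ids)
    orgs <- c(orgs, db$clusters[[cid]]$members$organism)
  orgs <- unique(orgs)
  if (length(orgs) > 0) {
    in_group <- vapply(orgs, function(o)
      db$organisms[[o]]$taxon_group == group, logical(1))
    if (all(in_group)) "specific" else "shared"
  } else if (length(reaction$pathway_taxa) == 1 &&
             reaction$pathway_taxa == group) {
    "orphan-specific"
  } else "unassigned"
}

# random database (no chemistry needed beyond two shared dummy compounds)
random_taxonomy_db <- function(n_reactions = 8) {
  cmp <- list(compound_graph("CX", "C"), compound_graph("CY", "O"))
  orgs <- list()
  for (g in c("plant", "bacteria", "other"))
    for (i in 1:3)
      orgs[[paste0(g, i)]] <- organism(paste0(substr(g, 1, 2), i), g, g)
  codes <- vapply(orgs, `[[`, character(1), "code")
  cls <- list()
  for (k in 1:6) {
    mem <- sample(codes, sample(1:3, 1))
    cls[[k]] <- ortholog_cluster(paste0("OC", k),
                                 data.frame(organism = mem,
                                            gene = paste0(mem, "_g", k)))
  }
  rx <- list()
  for (r in seq_len(n_reactions)) {
    kind <- sample(c("clustered", "orphan"), 1)
    if (kind == "clustered") {
      rx[[r]] <- reaction_record(sprintf("R%02d", r), "CX", "CY",
                                 cluster_ids = sample(paste0("OC", 1:6),
                                                      sample(1:2, 1)))
    } else {
      pt <- sample(list(character(), "plant", "bacteria",
                        c("plant", "bacteria")), 1)[[1]]
      rx[[r]] <- reaction_record(sprintf("R%02d", r), "CX", "CY",
                                 pathway_taxa = pt)
    }
  }
  reaction_db(cmp, rx, cls, orgs)
}

# ---- random RDM patterns -------------------------------------------------
type_vocab <- c("C.sp3.ac.h0", "C.sp3.ac.h1", "C.sp2.ac.h0", "C.ar.rg.h0",
                "O.sp3.ac.h0", "O.sp2.ac.h0", "N.sp3.ac.h0", "S.sp3.ac.h0")

random_triple <- function() {
  enzrepo:::rdm_triple(
    sample(type_vocab, 1), sample(type_vocab, 1),
    d_set = sample(type_vocab, sample(0:3, 1), replace = TRUE),
    m_set = if ((k <- sample(0:3, 1)) > 0)
      paste0(sample(type_vocab, k, replace = TRUE), ">",
             sample(type_vocab, k, replace = TRUE)) else character())
}

random_pattern <- function(k = sample(0:5, 1)) {
  pattern_obj(lapply(seq_len(k), function(i) random_triple()))
}

pattern_obj <- function(triples) {
  structure(list(triples = triples, pair_id = "test",
                 vocabulary = ATOM_TYPE_VOCABULARY),
            class = "rdm_pattern")
}

pattern_key <- function(p)
  paste(sort(vapply(p$triples, enzrepo:::triple_key, character(1))),
        collapse = "||")
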