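# Sequence-independence check: local protein alignment of candidate enzymes
# against known enzymes, BLAST-convention identity and coverage, no E-value
# statistics.

#' Optimal local protein alignment with identity and coverage
#'
#' Smith-Waterman local alignment under a substitution matrix (default
#' BLOSUM62 from Biostrings) with affine gap costs in BLAST-default style
#' (open 11, extend 1; a gap of length k costs `11 + k`). Identity is
#' matches over aligned columns including gap columns (the BLAST
#' convention, not over full sequence length); coverage is the aligned query
#' span over the query length. When no local alignment with positive score
#' exists the report is flagged unaligned with identity 0 and coverage 0.
#' No E-value is computed (`evalue_free` is always `TRUE`).
#'
#' @param a Query protein sequence (characters must be rows of the
#'   substitution matrix; `X` is allowed and scored per the matrix).
#' @param b Target protein sequence.
#' @param params List with `matrix` (a scoring matrix or the name of one
#'   shipped with Biostrings), `gap_open`, `gap_ext`.
#' @param query_id,target_id Optional ids carried into the report.
#' @return An `alignment_report`: `score`, `identity`, `coverage` (percent),
#'   `aligned` flag, `n_match`, `aln_length`, 1-based query/target spans,
#'   and `evalue_free = TRUE`.
#' @export
pairwise_identity <- function(a, b,
                              params = list(matrix = "BLOSUM62",
                                            gap_open = 11, gap_ext = 1),
                              query_id = NA_character_,
                              target_id = NA_character_) {
  if (!nzchar(a) || !nzchar(b))
    stop_enzrepo("sequences must be non-empty")
  sub <- params$matrix %||% "BLOSUM62"
  if (is.character(sub)) {
    e <- new.env()
    utils::data(list = sub, package = "Biostrings", envir = e)
    sub <- e[[params$matrix]]
  }
  enc <- function(s, who) {
    ch <- strsplit(toupper(s), "", fixed = TRUE)[[1]]
    idx <- match(ch, rownames(sub))
    if (anyNA(idx))
      stop_enzrepo("illegal character ", sQuote(ch[which(is.na(idx))[1]]),
                   " at position ", which(is.na(idx))[1], " of ", who,
                   " sequence")
    idx - 1L
  }
  res <- sw_align_cpp(enc(a, "query"), enc(b, "target"), sub,
                      params$gap_open %||% 11, params$gap_ext %||% 1)
  structure(list(
    query_id = query_id, target_id = target_id,
    score = res$score,
    identity = if (res$aligned) 100 * res$n_match / res$aln_length else 0,
    coverage = if (res$aligned)
      100 * (res$q_end - res$q_start + 1) / nchar(a) else 0,
    aligned = res$aligned,
    n_match = res$n_match, aln_length = res$aln_length,
    q_start = res$q_start, q_end = res$q_end,
    t_start = res$t_start, t_end = res$t_end,
    evalue_free = TRUE
  ), class = "alignment_report")
}

#' @export
print.alignment_report <- function(x, ...) {
  if (!x$aligned) {
    cat("<alignment_report: not aligned (no positive-scoring local alignment)>\n")
  } else {
    cat(sprintf(
      "<alignment_report: score %.1f, identity %.1f%%, coverage %.1f%% (query %d-%d)>\n",
      x$score, x$identity, x$coverage, x$q_start, x$q_end))
  }
  invisible(x)
}

#' Sequence-independence report for candidate enzymes
#'
#' Aligns every candidate against every known enzyme and writes one TSV row
#' per (candidate, known) pair with columns `query`, `target`, `score`,
#' `coverage`, `identity`. Pairs with no positive-scoring local alignment
#' are written as `N.A.` (mirroring BLAST's no-hit behavior at a
#' deterministic, tool-free criterion); candidates whose sequence is missing
#' get a `missing` marker row and a warning.
#'
#' @param candidates Named character vector of candidate protein sequences
#'   (`NA` entries mark candidates without a sequence).
#' @param known_enzymes Named character vector of known enzyme sequences
#'   (e.g. from [read_fasta()]).
#' @param path Optional output TSV path.
#' @param params Alignment parameters, see [pairwise_identity()].
#' @return Data frame of the report rows (scores and percents as strings,
#'   `N.A.`/`missing` markers included), invisibly written to `path`.
#' @export
sequence_independence_report <- function(candidates, known_enzymes,
                                         path = NULL,
                                         params = list(matrix = "BLOSUM62",
                                                       gap_open = 11,
                                                       gap_ext = 1)) {
  rows <- list()
  for (q in names(candidates)) {
    for (t in names(known_enzymes)) {
      if (is.na(candidates[[q]])) {
        warning("missing sequence for candidate ", q)
        rows[[length(rows) + 1L]] <- c(q, t, "missing", "missing", "missing")
        next
      }
      rep <- pairwise_identity(candidates[[q]], known_enzymes[[t]],
                               params = params, query_id = q, target_id = t)
      rows[[length(rows) + 1L]] <- if (!rep$aligned) c(q, t, "N.A.", "N.A.", "N.A.")
        else c(q, t, sprintf("%.1f", rep$score), sprintf("%.1f", rep$coverage),
               sprintf("%.1f", rep$identity))
    }
  }
  df <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  names(df) <- c("query", "target", "score", "coverage", "identity")
  if (!is.null(path))
    write_lines_lf(c("#query\ttarget\tscore\tcoverage\tidentity",
                     apply(df, 1L, paste, collapse = "\t")), path)
  df
}
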