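# MDL molfile (V2000) and SDF I/O for compound graphs.
#
# Only connectivity, elements and bond orders are used: coordinates,
# charges, isotopes and stereo flags are ignored. Explicit hydrogens are
# stripped into the per-atom n_h count.

#' Parse a V2000 molfile into a compound graph
#'
#' Reads the counts line, atom block and bond block of an MDL molfile
#' (V2000). Explicit hydrogen atoms are removed from the graph and counted
#' into their heavy neighbor's `n_h`; coordinates and stereo/charge fields
#' are ignored. Bond type 4 is read as aromatic; no aromaticity perception is
#' performed beyond that annotation. Atom types are assigned on return.
#'
#' @param text Molfile content: a single string or a character vector of lines.
#' @param compound_id Identifier to attach to the compound.
#' @return A `compound_graph`.
#' @export
parse_compound <- function(text, compound_id) {
  lines <- if (length(text) == 1L) strsplit(text, "\n", fixed = TRUE)[[1]] else text
  if (length(lines) < 4L)
    stop_enzrepo("molfile too short for ", compound_id,
                 ": counts line (line 4) missing")
  counts <- lines[4]
  n_atoms <- suppressWarnings(as.integer(trimws(substr(counts, 1L, 3L))))
  n_bonds <- suppressWarnings(as.integer(trimws(substr(counts, 4L, 6L))))
  if (is.na(n_atoms) || is.na(n_bonds) || n_atoms < 0L || n_bonds < 0L)
    stop_enzrepo("malformed counts line at line 4 for ", compound_id,
                 ": ", sQuote(counts))
  if (length(lines) < 4L + n_atoms + n_bonds)
    stop_enzrepo("atom/bond count mismatch for ", compound_id,
                 ": counts line declares ", n_atoms, " atoms and ", n_bonds,
                 " bonds but file ends at line ", length(lines))
  elements <- character(n_atoms)
  for (i in seq_len(n_atoms)) {
    ln <- 4L + i
    tok <- strsplit(trimws(lines[ln]), "\\s+")[[1]]
    if (length(tok) < 4L)
      stop_enzrepo("malformed atom line at line ", ln, " for ", compound_id)
    el <- tok[4]
    if (!el %in% ELEMENT_SET)
      stop_enzrepo("unknown element symbol ", sQuote(el), " at line ", ln,
                   " for ", compound_id)
    elements[i] <- el
  }
  a <- integer(n_bonds); b <- integer(n_bonds); ord <- character(n_bonds)
  for (i in seq_len(n_bonds)) {
    ln <- 4L + n_atoms + i
    line <- lines[ln]
    # bond block is column-based: atoms in cols 1-3 and 4-6, type in 7-9
    ai <- suppressWarnings(as.integer(trimws(substr(line, 1L, 3L))))
    bi <- suppressWarnings(as.integer(trimws(substr(line, 4L, 6L))))
    ti <- suppressWarnings(as.integer(trimws(substr(line, 7L, 9L))))
    if (is.na(ai) || is.na(bi) || is.na(ti))
      stop_enzrepo("malformed bond line at line ", ln, " for ", compound_id)
    if (ai < 1L || ai > n_atoms || bi < 1L || bi > n_atoms)
      stop_enzrepo("bond references non-existent atom at line ", ln,
                   " for ", compound_id)
    if (!ti %in% c(1L, 2L, 3L, 4L))
      stop_enzrepo("unsupported bond type ", ti, " at line ", ln,
                   " for ", compound_id)
    a[i] <- ai - 1L; b[i] <- bi - 1L
    ord[i] <- if (ti == 4L) "ar" else as.character(ti)
  }
  heavy <- which(elements != "H")
  n_h <- integer(length(heavy))
  remap <- rep(NA_integer_, n_atoms)
  remap[heavy] <- seq_along(heavy) - 1L
  keep <- logical(n_bonds)
  for (i in seq_len(n_bonds)) {
    ha <- elements[a[i] + 1L] != "H"
    hb <- elements[b[i] + 1L] != "H"
    keep[i] <- ha && hb
    if (ha && !hb) n_h[remap[a[i] + 1L] + 1L] <- n_h[remap[a[i] + 1L] + 1L] + 1L
    if (hb && !ha) n_h[remap[b[i] + 1L] + 1L] <- n_h[remap[b[i] + 1L] + 1L] + 1L
  }
  bonds <- data.frame(a = remap[a[keep] + 1L], b = remap[b[keep] + 1L],
                      order = ord[keep], stringsAsFactors = FALSE)
  compound_graph(compound_id, elements[heavy], bonds, n_h = n_h)
}

#' Parse a multi-record SDF
#'
#' Splits an SD file on `$$$$` record separators and parses each record's
#' molfile part. The compound identifier is the first header line of each
#' record (falling back to `CMPD<n>` when blank).
#'
#' @param text SDF content (single string or lines), or a file path if
#'   `is_path = TRUE`.
#' @param is_path Read `text` as a file path.
#' @return Named list of `compound_graph` objects.
#' @export
parse_sdf <- function(text, is_path = FALSE) {
  lines <- if (is_path) readLines(text, warn = FALSE)
           else if (length(text) == 1L) strsplit(text, "\n", fixed = TRUE)[[1]]
           else text
  recs <- split(lines, cumsum(c(0L, head(lines, -1) == "$$$$")))
  out <- list()
  k <- 0L
  for (rec in recs) {
    rec <- rec[rec != "$$$$"]
    # drop the data block (everything from the line after "M  END")
    end <- which(trimws(rec) == "M  END")
    if (length(end) > 0L) rec <- rec[seq_len(end[1] - 1L)]
    if (all(trimws(rec) == "")) next
    k <- k + 1L
    id <- trimws(rec[1])
    if (id == "") id <- sprintf("CMPD%d", k)
    out[[id]] <- parse_compound(rec, id)
  }
  out
}

#' Parse a SMILES string (optional reader)
#'
#' Converts a SMILES string to a molfile via ChemmineOB (OpenBabel) and
#' parses it behind the same `compound_graph` contract as [parse_compound()].
#' Requires the ChemmineOB package.
#'
#' @param smiles A SMILES string.
#' @param compound_id Identifier to attach.
#' @return A `compound_graph`.
#' @export
parse_smiles <- function(smiles, compound_id) {
  if (!requireNamespace("ChemmineOB", quietly = TRUE))
    stop_enzrepo("parse_smiles requires the ChemmineOB package")
  sdf <- ChemmineOB::convertFormat("SMI", "SDF", smiles)
  parse_compound(sdf, compound_id)
}

#' Write a compound graph as a V2000 molfile
#'
#' Coordinates are written as zeros (the package ignores geometry);
#' aromatic bonds are written as bond type 4.
#'
#' @param graph A `compound_graph`.
#' @return Character vector of molfile lines.
#' @export
write_molfile <- function(graph) {
  n <- nrow(graph$atoms)
  nb <- nrow(graph$bonds)
  lines <- c(
    graph$compound_id, "  enzrepo", "",
    sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n, nb)
  )
  for (i in seq_len(n)) {
    lines <- c(lines, sprintf(
      "%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
      0, 0, 0, graph$atoms$element[i]))
  }
  for (k in seq_len(nb)) {
    t <- if (graph$bonds$order[k] == "ar") 4L else as.integer(graph$bonds$order[k])
    lines <- c(lines, sprintf("%3d%3d%3d  0  0  0  0",
                              graph$bonds$a[k] + 1L, graph$bonds$b[k] + 1L, t))
  }
  c(lines, "M  END")
}

#' Write compounds as a multi-record SDF
#'
#' @param compounds List of `compound_graph` objects.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_sdf <- function(compounds, path) {
  lines <- unlist(lapply(compounds, function(g) c(write_molfile(g), "$$$$")))
  write_lines_lf(lines, path)
}
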