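#' @useDynLib enzrepo, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Multiset Jaccard index
#'
#' Jaccard index between two multisets of strings, computed on element
#' multiplicities: sum of per-element minimum counts over sum of per-element
#' maximum counts. The empty-vs-empty case is defined as 1 (absence matching
#' absence counts as agreement).
#'
#' @param x,y Character vectors interpreted as multisets.
#' @return A number in `[0, 1]`.
#' @export
multiset_jaccard <- function(x, y) {
  if (length(x) == 0L && length(y) == 0L) return(1)
  if (length(x) == 0L || length(y) == 0L) return(0)
  keys <- union(x, y)
  cx <- table(factor(x, levels = keys))
  cy <- table(factor(y, levels = keys))
  sum(pmin(cx, cy)) / sum(pmax(cx, cy))
}

# Deterministic 31-bit seed for a named substream of a master seed.
# Changing one component's draws must not perturb another's, so every
# generator component derives its own seed from (seed, label).
substream_seed <- function(seed, label) {
  h <- 0
  for (ch in utf8ToInt(label)) h <- (h * 131 + ch) %% 1977326743
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483629 + 1)
}

with_substream <- function(seed, label, code) {
  withr::with_seed(substream_seed(seed, label), code)
}

stop_enzrepo <- function(..., class = "enzrepo_error") {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

# stable sort helper (C locale, byte order) so reports are bit-stable
sort_c <- function(x) {
  old <- Sys.getlocale("LC_COLLATE")
  on.exit(Sys.setlocale("LC_COLLATE", old), add = TRUE)
  Sys.setlocale("LC_COLLATE", "C")
  sort(x, method = "radix")
}

order_c <- function(...) order(..., method = "radix")

write_lines_lf <- function(lines, path) {
  con <- file(path, open = "wb")
  on.exit(close(con), add = TRUE)
  writeLines(lines, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}
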