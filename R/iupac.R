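# IUPAC degenerate-base machinery shared by masking, enzyme scanning and
# motif canonicalization. The degeneracy table itself comes from Biostrings.

.iupac_sets <- function() {
  map <- Biostrings::IUPAC_CODE_MAP
  lapply(map, function(s) strsplit(s, "")[[1]])
}

# cached at load time
.pkg_env <- new.env(parent = emptyenv())

.iupac_table <- function() {
  if (is.null(.pkg_env$iupac)) .pkg_env$iupac <- .iupac_sets()
  .pkg_env$iupac
}

#' Expand an IUPAC letter to its set of concrete bases
#'
#' @param letter single IUPAC nucleotide letter (e.g. "R").
#' @return Character vector of the bases in the letter's degeneracy set
#'   (e.g. \code{c("A","G")} for R; all four bases for N).
#' @export
#' @examples
#' iupac_expand("R")
#' iupac_expand("N")
iupac_expand <- function(letter) {
  stopifnot(is.character(letter), length(letter) == 1L, nchar(letter) == 1L)
  tab <- .iupac_table()
  set <- tab[[toupper(letter)]]
  if (is.null(set)) stop("not an IUPAC nucleotide letter: '", letter, "'")
  set
}

#' Does a concrete base match an IUPAC pattern letter?
#'
#' @param pattern_base IUPAC letter from a recognition pattern.
#' @param base concrete base, one of A, C, G or T.
#' @return TRUE iff \code{base} lies in the degeneracy set of
#'   \code{pattern_base}.
#' @export
iupac_match <- function(pattern_base, base) {
  base <- toupper(base)
  if (!base %in% c("A", "C", "G", "T"))
    stop("base must be one of A, C, G, T; got '", base, "'")
  base %in% iupac_expand(pattern_base)
}

#' IUPAC code for a set of bases
#'
#' Inverse of \code{\link{iupac_expand}}: the single letter whose degeneracy
#' set equals the given base set.
#'
#' @param bases character vector of concrete bases (order and duplicates
#'   ignored).
#' @return Single IUPAC letter.
#' @export
#' @examples
#' iupac_code(c("A", "G"))  # "R"
iupac_code <- function(bases) {
  bases <- sort(unique(toupper(bases)))
  if (!all(bases %in% c("A", "C", "G", "T")))
    stop("bases must be drawn from A, C, G, T")
  if (length(bases) == 0L) stop("empty base set")
  tab <- .iupac_table()
  key <- vapply(tab, function(s) identical(sort(s), bases), logical(1))
  names(tab)[which(key)[1]]
}

#' Reverse complement of a (possibly degenerate) DNA string
#'
#' Handles the full IUPAC alphabet, so recognition patterns such as GTYRAC
#' reverse-complement correctly.
#'
#' @param x character vector of DNA strings.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  comp <- chartr("ACGTRYSWKMBDHVN", "TGCAYRSWMKVHDBN", toupper(x))
  vapply(comp, function(s) {
    paste(rev(strsplit(s, "")[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# Scan a subject sequence for all (overlapping) forward-strand matches of an
# IUPAC pattern. Subject N never matches a pattern letter other than N, so
# masked regions cannot produce phantom recognition sites.
scan_iupac <- function(seq, pattern) {
  seq <- toupper(seq)
  pattern <- toupper(pattern)
  x <- strsplit(seq, "")[[1]]
  m <- nchar(pattern)
  L <- length(x)
  if (L < m || m == 0L) return(integer(0))
  p <- strsplit(pattern, "")[[1]]
  ok <- rep(TRUE, L - m + 1L)
  for (j in seq_len(m)) {
    allowed <- iupac_expand(p[j])
    if (p[j] == "N") allowed <- c(allowed, "N")
    ok <- ok & (x[j:(L - m + j)] %in% allowed)
  }
  which(ok)
}
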