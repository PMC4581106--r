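# Transcript container and readers for the plain-text inputs the pipeline
# consumes: FASTA transcriptome, ORF table, exon-boundary table.
#
# A transcriptome is a data.frame with one row per unigene:
#   id          character, unique
#   sequence    upper-case DNA over {A,C,G,T,N}
#   length      nchar(sequence)
#   orf_start   1-based inclusive CDS start, NA when no ORF annotation
#   orf_end     1-based inclusive CDS end, NA when no ORF annotation
#   boundaries  list column of strictly increasing 1-based exon-exon
#               junction positions (integer(0) when none)

#' Build a transcriptome table
#'
#' @param id character vector of unique transcript ids.
#' @param sequence DNA strings over A,C,G,T,N (case-folded to upper).
#' @param orf_start,orf_end optional 1-based inclusive CDS coordinates
#'   (NA where unannotated).
#' @param boundaries optional list of integer vectors of exon-exon junction
#'   positions in transcript coordinates.
#' @return A \code{transcriptome} data.frame (see file header for columns).
#' @export
transcriptome <- function(id, sequence, orf_start = NA_integer_,
                          orf_end = NA_integer_, boundaries = NULL) {
  id <- as.character(id)
  if (anyDuplicated(id))
    stop("duplicate id ", id[duplicated(id)][1])
  sequence <- toupper(as.character(sequence))
  if (any(!nzchar(sequence))) stop("empty sequence")
  bad <- regexpr("[^ACGTN]", sequence)
  if (any(bad > 0)) {
    i <- which(bad > 0)[1]
    stop("non-IUPAC character in '", id[i], "' at position ", bad[i])
  }
  len <- nchar(sequence)
  orf_start <- as.integer(rep_len(orf_start, length(id)))
  orf_end <- as.integer(rep_len(orf_end, length(id)))
  has_orf <- !is.na(orf_start) & !is.na(orf_end)
  if (any(has_orf & (orf_start < 1L | orf_start > orf_end | orf_end > len)))
    stop("invalid ORF coordinates (need 1 <= orf_start <= orf_end <= length)")
  if (is.null(boundaries)) boundaries <- rep(list(integer(0)), length(id))
  boundaries <- lapply(seq_along(id), function(i) {
    b <- as.integer(boundaries[[i]])
    if (length(b)) {
      if (is.unsorted(b, strictly = TRUE))
        stop("boundary positions of '", id[i], "' must be strictly increasing")
      if (any(b < 1L | b > len[i]))
        stop("boundary position outside '", id[i], "'")
    }
    b
  })
  out <- data.frame(id = id, sequence = sequence, length = len,
                    orf_start = orf_start, orf_end = orf_end,
                    stringsAsFactors = FALSE)
  out$boundaries <- boundaries
  class(out) <- c("transcriptome", "data.frame")
  out
}

#' Read a transcriptome FASTA
#'
#' Sequences are upper-cased; record order is preserved; duplicate ids and
#' characters outside the \{A,C,G,T,N\} alphabet are hard errors.
#'
#' @param path FASTA file, one record per unigene.
#' @return A \code{\link{transcriptome}} data.frame.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) == 0L) stop("empty FASTA file: ", path)
  ids <- sub("\\s.*$", "", names(ss))
  transcriptome(id = ids, sequence = as.character(ss))
}

#' Write a transcriptome FASTA
#'
#' @param tx a \code{\link{transcriptome}}.
#' @param path output file.
#' @param width line-wrap width.
#' @export
write_fasta <- function(tx, path, width = 70L) {
  ss <- Biostrings::DNAStringSet(tx$sequence)
  names(ss) <- tx$id
  Biostrings::writeXStringSet(ss, filepath = path, width = width)
  invisible(path)
}

#' Read an ORF annotation table
#'
#' Tab-separated columns: transcript_id, orf_start, orf_end (1-based
#' inclusive CDS coordinates).
#'
#' @param path TSV file.
#' @return data.frame with those three columns.
#' @export
read_orf_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("transcript_id", "orf_start", "orf_end")
  if (!all(need %in% names(df)))
    stop("ORF table must have columns: ", paste(need, collapse = ", "))
  df$orf_start <- as.integer(df$orf_start)
  df$orf_end <- as.integer(df$orf_end)
  df
}

#' Read an exon-boundary table
#'
#' Tab-separated columns: transcript_id, boundary_pos, one row per exon-exon
#' junction in transcript coordinates.
#'
#' @param path TSV file.
#' @return data.frame with columns transcript_id, boundary_pos.
#' @export
read_boundary_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("transcript_id", "boundary_pos")
  if (!all(need %in% names(df)))
    stop("boundary table must have columns: ", paste(need, collapse = ", "))
  df$boundary_pos <- as.integer(df$boundary_pos)
  df
}

#' Attach ORF and boundary annotations to a transcriptome
#'
#' @param tx a \code{\link{transcriptome}}.
#' @param orf optional data.frame from \code{\link{read_orf_table}}.
#' @param boundaries optional data.frame from
#'   \code{\link{read_boundary_table}}.
#' @return The annotated transcriptome.
#' @export
annotate_transcriptome <- function(tx, orf = NULL, boundaries = NULL) {
  if (!is.null(orf)) {
    unknown <- setdiff(orf$transcript_id, tx$id)
    if (length(unknown)) stop("unknown transcript id: ", unknown[1])
    i <- match(orf$transcript_id, tx$id)
    tx$orf_start[i] <- orf$orf_start
    tx$orf_end[i] <- orf$orf_end
  }
  if (!is.null(boundaries)) {
    unknown <- setdiff(boundaries$transcript_id, tx$id)
    if (length(unknown)) stop("unknown transcript id: ", unknown[1])
    bl <- split(boundaries$boundary_pos, boundaries$transcript_id)
    for (id in names(bl)) {
      tx$boundaries[[match(id, tx$id)]] <- sort(as.integer(bl[[id]]))
    }
  }
  transcriptome(tx$id, tx$sequence, tx$orf_start, tx$orf_end, tx$boundaries)
}

# fetch one transcript row, erroring with the offending id
.tx_row <- function(tx, transcript_id) {
  i <- match(transcript_id, tx$id)
  if (is.na(i)) stop("unknown transcript id: ", transcript_id)
  i
}

#' @export
print.transcriptome <- function(x, ...) {
  cat("transcriptome: ", nrow(x), " transcripts, ",
      format(sum(x$length), big.mark = ","), " bp total\n", sep = "")
  invisible(x)
}
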