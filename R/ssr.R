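# MISA-style microsatellite detection. Perfect tandem repeats of 2-6 bp
# units are reported when they meet the published repeat-count thresholds
# (6 for di-, 5 for tri- through hexanucleotides); mononucleotide runs are
# excluded. A repeat region is reported exactly once, at its smallest
# primitive unit.

.default_ssr_thresholds <- c(`2` = 6L, `3` = 5L, `4` = 5L, `5` = 5L, `6` = 5L)

# is the motif not itself a whole-number repetition of a shorter unit?
.is_primitive <- function(motif) {
  k <- nchar(motif)
  for (d in seq_len(k - 1L)) {
    if (k %% d == 0L &&
        motif == strrep(substr(motif, 1L, d), k / d)) return(FALSE)
  }
  TRUE
}

#' Detect SSR loci in one sequence
#'
#' Finds all maximal perfect tandem repeats with primitive units of 2-6 bp
#' meeting the per-unit-length repeat thresholds. Detection runs one pass
#' per unit length over the lag-k self-match profile of the sequence, so a
#' run of period k appears as a run of matches at lag k; only whole repeat
#' units count. Repeats containing N are not reported. A locus whose span
#' lies wholly inside a reported locus of smaller unit length is
#' suppressed (non-redundant reporting).
#'
#' @param seq DNA string.
#' @param thresholds named integer vector: minimal repeat count per unit
#'   length "2".."6".
#' @return data.frame sorted by start: start, end (1-based inclusive),
#'   motif (as it appears), unit, n_repeats, canonical_class.
#' @export
#' @examples
#' detect_ssrs(paste0("TT", strrep("AG", 6), "TT"))
detect_ssrs <- function(seq, thresholds = .default_ssr_thresholds) {
  x <- strsplit(toupper(seq), "")[[1]]
  L <- length(x)
  found <- list()
  for (k in 2:6) {
    thr <- thresholds[[as.character(k)]]
    if (is.null(thr) || L < k * thr) next
    eq <- x[seq_len(L - k)] == x[(k + 1L):L]
    r <- rle(eq)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (ri in which(r$values & r$lengths >= (thr - 1L) * k)) {
      i <- starts[ri]
      m <- r$lengths[ri]
      n_rep <- (m + k) %/% k
      if (n_rep < thr) next
      motif <- paste(x[i:(i + k - 1L)], collapse = "")
      if (grepl("N", motif, fixed = TRUE)) next
      if (!.is_primitive(motif)) next
      found[[length(found) + 1L]] <- data.frame(
        start = i, end = i + n_rep * k - 1L, motif = motif,
        unit = k, n_repeats = n_rep, stringsAsFactors = FALSE)
    }
  }
  if (!length(found))
    return(data.frame(start = integer(0), end = integer(0),
                      motif = character(0), unit = integer(0),
                      n_repeats = integer(0),
                      canonical_class = character(0),
                      stringsAsFactors = FALSE))
  df <- do.call(rbind, found)
  # suppress longer-unit loci wholly contained in a smaller-unit locus
  keep <- rep(TRUE, nrow(df))
  for (i in seq_len(nrow(df))) {
    contained <- df$unit < df$unit[i] &
      df$start <= df$start[i] & df$end >= df$end[i]
    if (any(contained)) keep[i] <- FALSE
  }
  df <- df[keep, , drop = FALSE]
  df <- df[order(df$start, df$unit), , drop = FALSE]
  rownames(df) <- NULL
  df$canonical_class <- vapply(df$motif, canonical_class, character(1),
                               USE.NAMES = FALSE)
  df
}

#' Detect SSRs across a transcriptome
#'
#' @param tx a \code{\link{transcriptome}}.
#' @param thresholds as in \code{\link{detect_ssrs}}.
#' @param max_gap interruption distance for compound grouping, bp.
#' @return data.frame: transcript_id, start, end, motif, unit, n_repeats,
#'   canonical_class, compound_group (NA for singletons). Output is
#'   independent of transcript order (sorted by transcript_id, start).
#' @export
detect_ssrs_transcriptome <- function(tx, thresholds = .default_ssr_thresholds,
                                      max_gap = 100L) {
  per <- lapply(order(tx$id), function(i) {
    d <- detect_ssrs(tx$sequence[i], thresholds)
    if (nrow(d))
      cbind(data.frame(transcript_id = tx$id[i], stringsAsFactors = FALSE), d)
    else NULL
  })
  per <- per[!vapply(per, is.null, logical(1))]
  if (!length(per))
    return(data.frame(transcript_id = character(0), start = integer(0),
                      end = integer(0), motif = character(0),
                      unit = integer(0), n_repeats = integer(0),
                      canonical_class = character(0),
                      compound_group = integer(0), stringsAsFactors = FALSE))
  loci <- do.call(rbind, per)
  rownames(loci) <- NULL
  group_compound(loci, max_gap)
}

.rotations <- function(s) {
  k <- nchar(s)
  vapply(seq_len(k), function(i)
    paste0(substr(s, i, k), substr(s, 1L, i - 1L)), character(1))
}

#' Canonical motif class
#'
#' The canonical representative of a repeat unit is the lexicographic
#' minimum over all rotations of the motif and all rotations of its
#' reverse complement, so e.g. GA, AG, TC and CT all canonicalize to AG.
#' The class label pairs the representative with the minimal distinct
#' rotation of its reverse complement ("AG/CT", "AAG/CTT", "AT/TA").
#'
#' @param motif primitive repeat unit of 2-6 bp.
#' @return Class label string.
#' @export
#' @examples
#' canonical_class("GA")   # "AG/CT"
#' canonical_class("TTC")  # "AAG/CTT"
canonical_class <- function(motif) {
  motif <- toupper(motif)
  if (!.is_primitive(motif))
    stop("motif '", motif, "' is not primitive")
  cands <- c(.rotations(motif), .rotations(revcomp(motif)))
  canon <- min(cands)
  rc_rot <- .rotations(revcomp(canon))
  other <- setdiff(rc_rot, canon)
  second <- if (length(other)) min(other) else canon
  paste(canon, second, sep = "/")
}

#' Group SSRs into compound formations
#'
#' Consecutive loci on one transcript separated by at most \code{max_gap}
#' interrupting bases share a compound group id; isolated loci get NA.
#'
#' @param loci data.frame with transcript_id, start, end (sorted within
#'   transcript by start).
#' @param max_gap maximal interruption, bp (MISA's default interruption
#'   distance is 100).
#' @return The loci with a compound_group integer column.
#' @export
group_compound <- function(loci, max_gap = 100L) {
  loci <- loci[order(loci$transcript_id, loci$start), , drop = FALSE]
  rownames(loci) <- NULL
  n <- nrow(loci)
  grp <- rep(NA_integer_, n)
  gid <- 0L
  if (n > 1L) {
    for (i in 2:n) {
      same <- loci$transcript_id[i] == loci$transcript_id[i - 1L]
      gap <- loci$start[i] - loci$end[i - 1L] - 1L
      if (same && gap <= max_gap) {
        if (is.na(grp[i - 1L])) {
          gid <- gid + 1L
          grp[i - 1L] <- gid
        }
        grp[i] <- grp[i - 1L]
      }
    }
  }
  loci$compound_group <- grp
  loci
}

#' Summarise SSR content of a transcriptome
#'
#' @param loci data.frame from \code{\link{detect_ssrs_transcriptome}}.
#' @param tx the \code{\link{transcriptome}} that was scanned.
#' @return List: n_sequences, total_bp, n_ssrs, n_containing (SSR-bearing
#'   transcripts), n_multi (transcripts with > 1 SSR), n_compound (loci in
#'   compound formation), by_unit (counts for unit lengths 2-6),
#'   freq_kb_per_ssr, and motif_matrix (canonical class x repeat count,
#'   di- and trinucleotide classes).
#' @export
summarize_ssrs <- function(loci, tx) {
  per_tx <- table(loci$transcript_id)
  by_unit <- table(factor(loci$unit, levels = 2:6))
  names(by_unit) <- c("di", "tri", "tetra", "penta", "hexa")
  mm <- NULL
  small <- loci[loci$unit %in% c(2L, 3L), , drop = FALSE]
  if (nrow(small)) {
    mm <- table(small$canonical_class, small$n_repeats)
  }
  list(n_sequences = nrow(tx),
       total_bp = sum(tx$length),
       n_ssrs = nrow(loci),
       n_containing = length(per_tx),
       n_multi = sum(per_tx > 1L),
       n_compound = sum(!is.na(loci$compound_group)),
       by_unit = by_unit,
       freq_kb_per_ssr = if (nrow(loci))
         ssr_frequency(sum(tx$length), nrow(loci)) else NA_real_,
       motif_matrix = mm)
}

#' Design primers for SSR loci
#'
#' Runs \code{\link{design_primers}} for each locus with the published SSR
#' constraints (amplicon 100-280 bp, Tm 55-65, length 18-28, GC 45-55).
#'
#' @param loci data.frame from \code{\link{detect_ssrs_transcriptome}}.
#' @param tx the \code{\link{transcriptome}}.
#' @param params a \code{\link{primer_params}}.
#' @return The loci data.frame extended with forward, reverse,
#'   product_start, product_end, product_size and status ("OK" or the
#'   rejection reason).
#' @export
ssr_primers <- function(loci, tx, params = primer_params()) {
  n <- nrow(loci)
  out <- loci
  out$forward <- out$reverse <- NA_character_
  out$product_start <- out$product_end <- out$product_size <- NA_integer_
  out$status <- NA_character_
  for (i in seq_len(n)) {
    t_i <- .tx_row(tx, loci$transcript_id[i])
    pr <- design_primers(tx$sequence[t_i], loci$start[i], loci$end[i], params)
    if (!is.null(pr$rejected)) {
      out$status[i] <- pr$rejected
    } else {
      out$status[i] <- "OK"
      out$forward[i] <- pr$forward
      out$reverse[i] <- pr$reverse
      out$product_start[i] <- pr$product_start
      out$product_end[i] <- pr$product_end
      out$product_size[i] <- pr$product_size
    }
  }
  out
}
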