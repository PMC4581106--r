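# CAPS (cleaved amplified polymorphic sequence) marker prediction. A SNP is
# a CAPS candidate when some restriction enzyme has a recognition match
# covering the SNP position in exactly one of the two alleles, so digestion
# of the PCR product distinguishes the alleles. The predictor additionally
# computes the digestion fragment ladder for each allele (the scorability
# check that pure recognition-difference pipelines omit) and places a
# single 200-400 bp amplicon with one constrained primer pair.

#' Scan a sequence for recognition-site matches
#'
#' Reports every (possibly overlapping) forward-strand start position where
#' the enzyme's IUPAC recognition pattern matches. N in the subject matches
#' only N in the pattern. The bundled enzymes are all palindromic, so
#' forward-strand scanning is exhaustive.
#'
#' @param seq DNA string over A,C,G,T,N.
#' @param enzyme one row of an enzyme table (list/data.frame row with
#'   \code{recognition}).
#' @return Integer vector of 1-based match start positions.
#' @export
#' @examples
#' enz <- load_enzyme_table()
#' scan_sites("TTGAATTCAA", enz[enz$name == "EcoRI", ])
scan_sites <- function(seq, enzyme) {
  scan_iupac(seq, enzyme$recognition)
}

# allele windows of +/- flank around the SNP; truncated at transcript ends
.allele_windows <- function(sequence, pos, ref, alt, flank) {
  L <- nchar(sequence)
  lo <- max(1L, pos - flank)
  hi <- min(L, pos + flank)
  win <- strsplit(substr(sequence, lo, hi), "")[[1]]
  centre <- pos - lo + 1L
  if (win[centre] != ref)
    stop("reference allele mismatch at position ", pos)
  alt_win <- win
  alt_win[centre] <- alt
  list(ref = paste(win, collapse = ""),
       alt = paste(alt_win, collapse = ""),
       centre = centre)
}

#' Enzymes that cut exactly one allele of a SNP
#'
#' Builds the two allele windows around a biallelic SNP and reports every
#' enzyme with a recognition match covering the SNP position in exactly one
#' window, together with which allele is cut.
#'
#' @param panel a \code{\link{snp_panel}}.
#' @param i site index into the panel (must be biallelic).
#' @param tx a \code{\link{transcriptome}}.
#' @param enzymes enzyme table from \code{\link{load_enzyme_table}}.
#' @param flank half-window in bp (default 10, longer than any bundled
#'   recognition site); truncated at transcript ends.
#' @return data.frame with columns enzyme, allele_cut ("REF" or "ALT");
#'   zero rows when no enzyme is diagnostic.
#' @export
differential_enzymes <- function(panel, i, tx, enzymes, flank = 10L) {
  s <- panel$sites[i, ]
  if (grepl(",", s$alt, fixed = TRUE))
    stop("differential digestion is defined for biallelic sites")
  t_i <- .tx_row(tx, s$transcript_id)
  w <- .allele_windows(tx$sequence[t_i], s$pos, s$ref, s$alt, flank)
  covering <- function(window, rec_len) {
    hits <- scan_iupac(window, rec_len$recognition)
    m <- nchar(rec_len$recognition)
    any(hits <= w$centre & w$centre <= hits + m - 1L)
  }
  hit_ref <- vapply(seq_len(nrow(enzymes)), function(k)
    covering(w$ref, enzymes[k, ]), logical(1))
  hit_alt <- vapply(seq_len(nrow(enzymes)), function(k)
    covering(w$alt, enzymes[k, ]), logical(1))
  diag <- xor(hit_ref, hit_alt)
  data.frame(enzyme = enzymes$name[diag],
             allele_cut = ifelse(hit_ref[diag], "REF", "ALT"),
             stringsAsFactors = FALSE)
}

#' Predict restriction fragments of an amplicon
#'
#' Cut positions are match_start - 1 + cut_offset in amplicon coordinates;
#' the fragments partition the amplicon (cuts falling on the amplicon
#' boundaries produce no fragment). With no match the single full-length
#' fragment is returned.
#'
#' @param amplicon_seq amplicon sequence.
#' @param enzyme one enzyme-table row.
#' @return Sorted integer fragment lengths summing to the amplicon length.
#' @export
digest_fragments <- function(amplicon_seq, enzyme) {
  L <- nchar(amplicon_seq)
  hits <- scan_iupac(amplicon_seq, enzyme$recognition)
  cuts <- hits - 1L + enzyme$cut_offset
  cuts <- sort(unique(cuts[cuts > 0L & cuts < L]))
  sort(diff(c(0L, cuts, L)))
}

# directed-Hausdorff style ladder separation: the largest distance from a
# fragment in one ladder to its nearest fragment in the other
.ladder_separation <- function(a, b) {
  d <- function(x, y) max(vapply(x, function(f) min(abs(f - y)), numeric(1)))
  max(d(a, b), d(b, a))
}

#' Design a CAPS marker for one SNP
#'
#' Finds the diagnostic enzymes, places a single amplicon of 200-400 bp
#' with the SNP as centered as primer feasibility allows (ties toward the
#' smaller amplicon), designs one primer pair on the amplicon flanks, and
#' predicts the digestion fragment ladder of each allele for each
#' diagnostic enzyme.
#'
#' @param panel a \code{\link{snp_panel}}.
#' @param i biallelic site index.
#' @param tx a \code{\link{transcriptome}}.
#' @param enzymes enzyme table.
#' @param params primer constraints from \code{\link{primer_params}};
#'   defaults to the CAPS amplicon range 200-400 bp with the standard
#'   primer windows.
#' @param scorability_min_diff minimum required separation (bp) between the
#'   two allele ladders of at least one diagnostic enzyme; 0 disables the
#'   screen (recognition-difference-only behaviour).
#' @param flank half-window for the differential-digestion scan.
#' @return A list of class \code{caps_marker} (site, enzymes, amplicon,
#'   primer pair, per-enzyme per-allele fragment ladders), or a rejection
#'   list with \code{rejected} in \{NO_ENZYME, NO_AMPLICON, NOT_SCORABLE\}.
#' @export
design_caps_marker <- function(panel, i, tx, enzymes,
                               params = primer_params(amp_min = 200L,
                                                      amp_max = 400L),
                               scorability_min_diff = 0L, flank = 10L) {
  diag <- differential_enzymes(panel, i, tx, enzymes, flank)
  if (nrow(diag) == 0L) return(list(rejected = "NO_ENZYME"))
  s <- panel$sites[i, ]
  t_i <- .tx_row(tx, s$transcript_id)
  seq <- tx$sequence[t_i]
  idx <- .primer_index(seq, params)
  amp <- .place_caps_amplicon(idx, s$pos, params)
  if (is.null(amp)) return(list(rejected = "NO_AMPLICON",
                                diagnostic = diag))
  amp_ref <- substr(seq, amp$product_start, amp$product_end)
  alt_chars <- strsplit(amp_ref, "")[[1]]
  alt_chars[s$pos - amp$product_start + 1L] <- s$alt
  amp_alt <- paste(alt_chars, collapse = "")
  ladders <- lapply(seq_len(nrow(diag)), function(k) {
    e <- enzymes[enzymes$name == diag$enzyme[k], ]
    list(enzyme = diag$enzyme[k],
         ref = digest_fragments(amp_ref, e),
         alt = digest_fragments(amp_alt, e))
  })
  if (scorability_min_diff > 0L) {
    sep <- vapply(ladders, function(l)
      .ladder_separation(l$ref, l$alt), numeric(1))
    keep <- sep >= scorability_min_diff
    if (!any(keep)) return(list(rejected = "NOT_SCORABLE",
                                diagnostic = diag))
    diag <- diag[keep, , drop = FALSE]
    ladders <- ladders[keep]
  }
  structure(list(transcript_id = s$transcript_id, pos = s$pos,
                 ref = s$ref, alt = s$alt,
                 diagnostic = diag,
                 amplicon = c(start = amp$product_start,
                              end = amp$product_end),
                 primer_pair = amp,
                 ladders = ladders),
            class = "caps_marker")
}

# Amplicon placement for a point target: among all (start, end) pairs with
# feasible primers and 200-400 bp product covering the SNP, pick the one
# whose centre is nearest the SNP; ties toward the smaller product, then
# leftmost. Candidate ends are resolved per start by bisection into the
# sorted feasible reverse-end set.
.place_caps_amplicon <- function(idx, pos, params) {
  fc <- .flank_candidates(idx, pos, pos, params)
  if (!length(fc$Fs) || !length(fc$Re)) return(NULL)
  Re <- fc$Re
  best <- NULL
  for (s in fc$Fs) {
    e_lo <- s + params$amp_min - 1L
    e_hi <- s + params$amp_max - 1L
    e_star <- 2L * pos - s       # end that centres the SNP exactly
    lo_i <- findInterval(e_lo - 1L, Re) + 1L
    hi_i <- findInterval(e_hi, Re)
    if (lo_i > hi_i) next
    near <- findInterval(e_star, Re)
    cand_i <- unique(pmin(pmax(c(near, near + 1L), lo_i), hi_i))
    for (ci in cand_i) {
      e <- Re[ci]
      off <- abs((s + e) / 2 - pos)
      P <- e - s + 1L
      if (is.null(best) || off < best$off ||
          (off == best$off && (P < best$P ||
                               (P == best$P && s < best$s)))) {
        best <- list(s = s, e = e, off = off, P = P)
      }
    }
  }
  if (is.null(best)) return(NULL)
  .pair_record(idx, best$s, best$e, idx$fwd_min[best$s], idx$rev_min[best$e])
}

#' Batch CAPS prediction over a panel
#'
#' Runs \code{\link{design_caps_marker}} on every biallelic site and
#' returns one row per (site, diagnostic enzyme), plus a per-site rollup.
#'
#' @inheritParams design_caps_marker
#' @param blocks optional alignment-block table for
#'   \code{\link{project_to_genome}}; adds scaffold/genome_pos columns.
#' @return List with \code{markers} (data.frame: transcript_id, pos, ref,
#'   alt, enzyme, allele_cut, amplicon_start, amplicon_end, forward,
#'   reverse, ladder_ref, ladder_alt, and genome projection when
#'   available), \code{per_site} (site rollup with n_enzymes or the
#'   rejection reason), and \code{objects} (the caps_marker objects).
#' @export
caps_markers <- function(panel, tx, enzymes = load_enzyme_table(),
                         params = primer_params(amp_min = 200L,
                                                amp_max = 400L),
                         scorability_min_diff = 0L, flank = 10L,
                         blocks = NULL) {
  rows <- list()
  site_rows <- list()
  objects <- list()
  bi <- which(is_biallelic(panel))
  for (i in bi) {
    mk <- design_caps_marker(panel, i, tx, enzymes, params,
                             scorability_min_diff, flank)
    s <- panel$sites[i, ]
    if (!is.null(mk$rejected)) {
      site_rows[[length(site_rows) + 1L]] <-
        data.frame(transcript_id = s$transcript_id, pos = s$pos,
                   n_enzymes = 0L, status = mk$rejected,
                   stringsAsFactors = FALSE)
      next
    }
    objects[[length(objects) + 1L]] <- mk
    proj <- list(scaffold = NA_character_, genome_pos = NA_integer_,
                 strand = NA_character_)
    if (!is.null(blocks)) {
      proj_try <- try(project_to_genome(s$transcript_id, s$pos, blocks),
                      silent = TRUE)
      if (!inherits(proj_try, "try-error")) proj <- proj_try
    }
    for (k in seq_len(nrow(mk$diagnostic))) {
      l <- mk$ladders[[k]]
      rows[[length(rows) + 1L]] <- data.frame(
        transcript_id = s$transcript_id, pos = s$pos,
        ref = s$ref, alt = s$alt,
        enzyme = mk$diagnostic$enzyme[k],
        allele_cut = mk$diagnostic$allele_cut[k],
        amplicon_start = mk$amplicon[["start"]],
        amplicon_end = mk$amplicon[["end"]],
        forward = mk$primer_pair$forward,
        reverse = mk$primer_pair$reverse,
        ladder_ref = paste(l$ref, collapse = ","),
        ladder_alt = paste(l$alt, collapse = ","),
        scaffold = proj$scaffold, genome_pos = proj$genome_pos,
        strand = proj$strand,
        stringsAsFactors = FALSE)
    }
    site_rows[[length(site_rows) + 1L]] <-
      data.frame(transcript_id = s$transcript_id, pos = s$pos,
                 n_enzymes = nrow(mk$diagnostic), status = "MARKER",
                 stringsAsFactors = FALSE)
  }
  bind <- function(l, proto) if (length(l)) do.call(rbind, l) else proto
  list(markers = bind(rows, data.frame()),
       per_site = bind(site_rows, data.frame()),
       objects = objects)
}

#' Project a transcript position onto genome scaffolds
#'
#' Affine within-block mapping of transcript coordinates through an
#' alignment-block table; on the minus strand positions count down from the
#' block's genomic end.
#'
#' @param transcript_id transcript name.
#' @param pos 1-based transcript position.
#' @param blocks data.frame with columns transcript_id, t_start, t_end,
#'   scaffold, g_start, g_end, strand ("+" or "-").
#' @return List with scaffold, genome_pos, strand.
#' @export
project_to_genome <- function(transcript_id, pos, blocks) {
  b <- blocks[blocks$transcript_id == transcript_id &
                blocks$t_start <= pos & pos <= blocks$t_end, , drop = FALSE]
  if (nrow(b) == 0L)
    stop("UNMAPPED: position ", pos, " of ", transcript_id,
         " falls outside all alignment blocks")
  b <- b[1, ]
  off <- pos - b$t_start
  gpos <- if (b$strand == "-") b$g_end - off else b$g_start + off
  list(scaffold = b$scaffold, genome_pos = as.integer(gpos),
       strand = b$strand)
}
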