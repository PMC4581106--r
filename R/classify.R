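# Per-site SNP classification: transcript region relative to the predicted
# ORF, substitution class and transition/transversion status, per-sample
# zygosity, pairwise polymorphism between accessions, pooled minor-allele
# read-count frequency, and IUPAC masking of variant positions.

#' Classify SNP positions into 5'UTR / CDS / 3'UTR
#'
#' Region is UNKNOWN exactly when the transcript carries no ORF annotation.
#' Coordinates are 1-based inclusive; the ORF endpoints belong to the CDS.
#'
#' @param panel a \code{\link{snp_panel}}.
#' @param tx a \code{\link{transcriptome}}.
#' @return Character vector over \{FIVE_UTR, CDS, THREE_UTR, UNKNOWN\}.
#' @export
classify_region <- function(panel, tx) {
  s <- panel$sites
  ti <- match(s$transcript_id, tx$id)
  if (anyNA(ti))
    stop("unknown transcript id: ", s$transcript_id[is.na(ti)][1])
  if (any(s$pos < 1L | s$pos > tx$length[ti])) {
    i <- which(s$pos < 1L | s$pos > tx$length[ti])[1]
    stop("position ", s$pos[i], " outside transcript ", s$transcript_id[i])
  }
  os <- tx$orf_start[ti]
  oe <- tx$orf_end[ti]
  out <- rep("UNKNOWN", nrow(s))
  has <- !is.na(os) & !is.na(oe)
  out[has & s$pos < os] <- "FIVE_UTR"
  out[has & s$pos >= os & s$pos <= oe] <- "CDS"
  out[has & s$pos > oe] <- "THREE_UTR"
  out
}

#' Substitution class of a biallelic change
#'
#' The class is the unordered allele pair, written in the conventional
#' order (A/G, C/T, A/C, A/T, C/G, G/T). Transitions are the
#' purine-purine and pyrimidine-pyrimidine pairs A/G and C/T.
#'
#' @param ref,alt single bases; vectors recycle.
#' @return data.frame with columns \code{class} and \code{is_transition}.
#' @export
classify_substitution <- function(ref, alt) {
  ref <- toupper(ref); alt <- toupper(alt)
  n <- max(length(ref), length(alt))
  ref <- rep_len(ref, n); alt <- rep_len(alt, n)
  if (any(!ref %in% c("A", "C", "G", "T") | !alt %in% c("A", "C", "G", "T")))
    stop("alleles must be single bases in A, C, G, T")
  if (any(ref == alt)) stop("ref and alt must differ")
  ordered_classes <- c("A/G", "C/T", "A/C", "A/T", "C/G", "G/T")
  cls <- paste(pmin(ref, alt), pmax(ref, alt), sep = "/")
  stopifnot(all(cls %in% ordered_classes))
  data.frame(class = cls, is_transition = cls %in% c("A/G", "C/T"),
             stringsAsFactors = FALSE)
}

#' Zygosity of genotype calls
#'
#' @param gt character vector of diploid genotype strings ("0/0", "0/1",
#'   "1/1", "./." or NA).
#' @param n_alleles optional number of alleles at the site (1 + number of
#'   alternates); when given, out-of-range allele indices are an error.
#' @return Character vector over \{HOM_REF, HOM_ALT, HET, MISSING\}.
#' @export
zygosity_of <- function(gt, n_alleles = NULL) {
  vapply(seq_along(gt), function(i) {
    a <- .gt_alleles(gt[i])
    if (anyNA(a)) return("MISSING")
    if (!is.null(n_alleles)) {
      na <- rep_len(n_alleles, length(gt))[i]
      if (any(a >= na | a < 0L))
        stop("allele index out of range in genotype '", gt[i], "'")
    }
    if (a[1] != a[2]) "HET" else if (a[1] == 0L) "HOM_REF" else "HOM_ALT"
  }, character(1))
}

#' Pairwise polymorphism status between two accessions
#'
#' A comparison is only attempted when both genotypes are called and both
#' per-sample depths are strictly greater than \code{min_dp} (the published
#' rule is "greater than 10", so depth exactly 10 is insufficient).
#'
#' @param panel a \code{\link{snp_panel}}.
#' @param a,b sample names.
#' @param min_dp depth threshold (strict).
#' @return Character vector over \{MONOMORPHIC, POLY_HOM, POLY_OTHER,
#'   INSUFFICIENT_DEPTH\}: POLY_HOM = both homozygous for different
#'   alleles; POLY_OTHER = any other polymorphic comparison (involving a
#'   heterozygote).
#' @export
pair_status <- function(panel, a, b, min_dp = 10L) {
  for (smp in c(a, b))
    if (!smp %in% panel$samples) stop("unknown sample name: ", smp)
  n <- n_sites(panel)
  ga <- panel$gt[, a]; gb <- panel$gt[, b]
  da <- panel$dp[, a]; db <- panel$dp[, b]
  vapply(seq_len(n), function(i) {
    aa <- .gt_alleles(ga[i]); ab <- .gt_alleles(gb[i])
    if (anyNA(aa) || anyNA(ab) ||
        is.na(da[i]) || is.na(db[i]) || da[i] <= min_dp || db[i] <= min_dp)
      return("INSUFFICIENT_DEPTH")
    if (identical(sort(aa), sort(ab))) return("MONOMORPHIC")
    hom_a <- aa[1] == aa[2]; hom_b <- ab[1] == ab[2]
    if (hom_a && hom_b) "POLY_HOM" else "POLY_OTHER"
  }, character(1))
}

#' Pooled minor-allele read-count frequency
#'
#' Allele-depth (AD) counts are pooled over all samples; the frequency is
#' the pooled count of the least common observed allele divided by the
#' total pooled count. Alleles with zero pooled count are ignored (a pool
#' where only one allele was ever read has frequency 1 for that allele).
#'
#' @param panel a \code{\link{snp_panel}}.
#' @param strict error when a site has no allele-count evidence (default);
#'   with \code{strict = FALSE} such sites return NA.
#' @return Numeric vector of frequencies in [0, 0.5] for biallelic sites.
#' @export
minor_allele_rc_freq <- function(panel, strict = TRUE) {
  n <- n_sites(panel)
  n_all <- 1L + lengths(strsplit(panel$sites$alt, ",", fixed = TRUE))
  out <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    pooled <- numeric(n_all[i])
    for (j in seq_along(panel$samples)) {
      adv <- panel$ad[i, j]
      if (is.na(adv)) next
      cnt <- suppressWarnings(as.numeric(strsplit(adv, ",", fixed = TRUE)[[1]]))
      cnt[is.na(cnt)] <- 0
      k <- min(length(cnt), n_all[i])
      pooled[seq_len(k)] <- pooled[seq_len(k)] + cnt[seq_len(k)]
    }
    tot <- sum(pooled)
    if (tot == 0) {
      if (strict)
        stop("no allele-count evidence at ", panel$sites$transcript_id[i],
             ":", panel$sites$pos[i])
      next
    }
    observed <- pooled[pooled > 0]
    out[i] <- min(observed) / tot
  }
  out
}

#' Mask variant positions with IUPAC codes
#'
#' Each variant position is replaced by the degenerate code for the union
#' of reference and alternate alleles (used when designing primers across
#' loci that must amplify in every accession). Length is preserved.
#'
#' @param tx a \code{\link{transcriptome}}.
#' @param transcript_id the transcript to mask.
#' @param panel a \code{\link{snp_panel}}; only sites on
#'   \code{transcript_id} are applied.
#' @return The masked sequence as a single string.
#' @export
mask_variants <- function(tx, transcript_id, panel) {
  i <- .tx_row(tx, transcript_id)
  x <- strsplit(tx$sequence[i], "")[[1]]
  sel <- which(panel$sites$transcript_id == transcript_id)
  for (k in sel) {
    pos <- panel$sites$pos[k]
    ref <- panel$sites$ref[k]
    alts <- strsplit(panel$sites$alt[k], ",", fixed = TRUE)[[1]]
    if (pos < 1L || pos > length(x))
      stop("position ", pos, " outside transcript ", transcript_id)
    if (x[pos] != ref)
      stop("reference allele mismatch at position ", pos, " of ",
           transcript_id, " (sequence has ", x[pos], ", site says ", ref, ")")
    x[pos] <- iupac_code(c(ref, alts))
  }
  paste(x, collapse = "")
}

#' Full classification table for a panel
#'
#' One row per site: region, substitution class (biallelic sites),
#' transition flag, per-sample zygosity, and pooled minor-allele read-count
#' frequency.
#'
#' @param panel a \code{\link{snp_panel}}.
#' @param tx a \code{\link{transcriptome}}.
#' @return data.frame with columns transcript_id, pos, ref, alt, biallelic,
#'   region, class, is_transition, zygosity_<sample>..., marcf.
#' @export
classify_panel <- function(panel, tx) {
  s <- panel$sites
  bi <- is_biallelic(panel)
  cls <- rep(NA_character_, nrow(s))
  tr <- rep(NA, nrow(s))
  if (any(bi)) {
    sub <- classify_substitution(s$ref[bi], s$alt[bi])
    cls[bi] <- sub$class
    tr[bi] <- sub$is_transition
  }
  out <- data.frame(transcript_id = s$transcript_id, pos = s$pos,
                    ref = s$ref, alt = s$alt, biallelic = bi,
                    region = classify_region(panel, tx),
                    class = cls, is_transition = tr,
                    stringsAsFactors = FALSE)
  n_all <- 1L + lengths(strsplit(s$alt, ",", fixed = TRUE))
  for (smp in panel$samples)
    out[[paste0("zygosity_", smp)]] <- zygosity_of(panel$gt[, smp], n_all)
  out$marcf <- minor_allele_rc_freq(panel, strict = FALSE)
  out
}
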