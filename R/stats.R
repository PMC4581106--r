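# Summary-statistics layer: SNP/SSR frequencies, transition/transversion
# tables stratified by transcript region, per-unigene SNP distributions,
# three-way Venn partitions of pairwise polymorphisms, and assembly metrics.

# half-up rounding to match how the published tables were formatted
round_half_up <- function(x, digits = 0L) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

#' SNP frequency as bp per SNP
#'
#' Total reference length divided by the SNP count, to the nearest integer
#' (reported as "1 SNP / n bp").
#'
#' @param total_bp total transcriptome length in bp.
#' @param n_snps number of SNPs (> 0).
#' @return Integer bp-per-SNP.
#' @export
snp_frequency <- function(total_bp, n_snps) {
  if (n_snps == 0) stop("n_snps must be positive")
  as.integer(round_half_up(total_bp / n_snps))
}

#' SSR frequency as kb per SSR
#'
#' @param total_bp total transcriptome length in bp.
#' @param n_ssrs number of SSR loci (> 0).
#' @return kb-per-SSR, one decimal.
#' @export
ssr_frequency <- function(total_bp, n_ssrs) {
  if (n_ssrs == 0) stop("n_ssrs must be positive")
  round_half_up(total_bp / n_ssrs / 1000, 1L)
}

.sub_classes <- c("A/G", "C/T", "G/T", "A/C", "A/T", "C/G")

#' Transition/transversion summary table
#'
#' Counts and percentages of the six substitution classes, stratified over
#' ALL sites and the three transcript regions, computed over biallelic
#' sites only. The Ts/Tv ratio is the A/G + C/T count over the remaining
#' four classes; with zero transversions the ratio is NA (undefined), never
#' infinite.
#'
#' @param classifications data.frame from \code{\link{classify_panel}}
#'   (needs columns class, region, biallelic).
#' @return List of class \code{tstv_table}: \code{counts} and \code{pct}
#'   (strata x classes), \code{n} per stratum, \code{tstv} per stratum
#'   (one decimal).
#' @export
tstv_summary <- function(classifications) {
  if (nrow(classifications) == 0L) stop("no classifications supplied")
  cl <- classifications[classifications$biallelic &
                          !is.na(classifications$class), , drop = FALSE]
  strata <- list(ALL = rep(TRUE, nrow(cl)),
                 CDS = cl$region == "CDS",
                 FIVE_UTR = cl$region == "FIVE_UTR",
                 THREE_UTR = cl$region == "THREE_UTR")
  counts <- t(vapply(strata, function(keep) {
    tab <- table(factor(cl$class[keep], levels = .sub_classes))
    as.integer(tab)
  }, integer(length(.sub_classes))))
  colnames(counts) <- .sub_classes
  n <- rowSums(counts)
  pct <- counts / ifelse(n > 0, n, NA_real_) * 100
  pct <- round_half_up(pct, 1L)
  ts <- counts[, "A/G"] + counts[, "C/T"]
  tv <- n - ts
  tstv <- ifelse(tv > 0, round_half_up(ts / tv, 1L), NA_real_)
  structure(list(counts = counts, pct = pct, n = n, tstv = tstv),
            class = "tstv_table")
}

#' Ts/Tv ratio from class percentages
#'
#' Recomputes the ratio from a printed six-class percentage row (transition
#' percentages over transversion percentages), one decimal.
#'
#' @param pct named numeric vector over the six substitution classes.
#' @return Ts/Tv ratio, one decimal; NA when transversions are zero.
#' @export
tstv_from_percentages <- function(pct) {
  ts <- sum(pct[c("A/G", "C/T")])
  tv <- sum(pct[setdiff(.sub_classes, c("A/G", "C/T"))])
  if (tv == 0) return(NA_real_)
  round_half_up(ts / tv, 1L)
}

#' Per-unigene SNP distribution
#'
#' @param panel a \code{\link{snp_panel}} (typically the passing set).
#' @param tx a \code{\link{transcriptome}}.
#' @return List of class \code{unigene_distribution}: \code{per_transcript}
#'   (named counts over all transcripts), \code{histogram} (bins "1".."9",
#'   ">=10" over SNP-containing transcripts), \code{n_containing},
#'   \code{mean_per_transcript} (denominator = ALL transcripts),
#'   \code{pct_ge10} (share of SNP-containing transcripts with >= 10 SNPs,
#'   one decimal).
#' @export
unigene_distribution <- function(panel, tx) {
  counts <- table(factor(panel$sites$transcript_id, levels = tx$id))
  counts <- as.integer(counts)
  names(counts) <- tx$id
  containing <- counts[counts > 0L]
  bins <- c(as.character(1:9), ">=10")
  histogram <- integer(length(bins))
  names(histogram) <- bins
  if (length(containing)) {
    binned <- ifelse(containing >= 10L, ">=10", as.character(containing))
    tab <- table(factor(binned, levels = bins))
    histogram <- as.integer(tab)
    names(histogram) <- bins
  }
  structure(list(
    per_transcript = counts,
    histogram = histogram,
    n_containing = length(containing),
    mean_per_transcript = round_half_up(sum(counts) / length(counts), 1L),
    pct_ge10 = if (length(containing))
      round_half_up(100 * sum(containing >= 10L) / length(containing), 1L)
    else NA_real_),
    class = "unigene_distribution")
}

#' Three-way Venn partition of pairwise polymorphisms
#'
#' Each site polymorphic in at least one pairwise comparison contributes to
#' exactly one of the 7 Venn regions; computed twice, once counting any
#' polymorphism (POLY_HOM or POLY_OTHER) and once counting homozygous
#' polymorphisms (POLY_HOM) only.
#'
#' @param status_ab,status_ac,status_bc character vectors from
#'   \code{\link{pair_status}} for the three sample pairs, site-aligned.
#' @return List with \code{all} and \code{hom}: named integer vectors over
#'   regions ab_only, ac_only, bc_only, ab_ac, ab_bc, ac_bc, all_three.
#' @export
venn_counts <- function(status_ab, status_ac, status_bc) {
  stopifnot(length(status_ab) == length(status_ac),
            length(status_ab) == length(status_bc))
  region_of <- function(p1, p2, p3) {
    key <- paste0(as.integer(p1), as.integer(p2), as.integer(p3))
    map <- c("100" = "ab_only", "010" = "ac_only", "001" = "bc_only",
             "110" = "ab_ac", "101" = "ab_bc", "011" = "ac_bc",
             "111" = "all_three", "000" = NA_character_)
    map[key]
  }
  regions <- c("ab_only", "ac_only", "bc_only", "ab_ac", "ab_bc", "ac_bc",
               "all_three")
  count <- function(poly_set) {
    r <- region_of(status_ab %in% poly_set, status_ac %in% poly_set,
                   status_bc %in% poly_set)
    tab <- table(factor(r, levels = regions))
    out <- as.integer(tab)
    names(out) <- regions
    out
  }
  list(all = count(c("POLY_HOM", "POLY_OTHER")),
       hom = count("POLY_HOM"))
}

#' Assembly metrics: N50, mean length, size-bin histogram
#'
#' N50 is the largest observed length L such that transcripts of length
#' >= L jointly cover at least half the assembly (descending cumulative
#' rule). Size bins follow the conventional 500 bp histogram
#' (<=500, 501-1000, 1001-1500, ...).
#'
#' @param tx a \code{\link{transcriptome}} (or any data.frame with a
#'   \code{length} column); must be non-empty.
#' @return List: n50, mean_length (one decimal), total_bp, size_bins.
#' @export
assembly_metrics <- function(tx) {
  len <- tx$length
  if (length(len) == 0L) stop("empty transcript set")
  dec <- sort(len, decreasing = TRUE)
  csum <- cumsum(dec)
  n50 <- dec[which(csum >= sum(dec) / 2)[1]]
  top <- max(len)
  breaks <- seq(0L, (top %/% 500L + 1L) * 500L, by = 500L)
  labs <- paste(breaks[-length(breaks)] + 1L, breaks[-1L], sep = "-")
  bins <- table(cut(len, breaks = breaks, labels = labs))
  list(n50 = n50,
       mean_length = round_half_up(mean(len), 1L),
       total_bp = sum(len),
       size_bins = bins)
}
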