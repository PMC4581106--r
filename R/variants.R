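# Multi-sample SNP panel. Sites are stored column-wise (one data.frame row
# per site plus per-sample genotype/depth/allele-count matrices), mirroring
# how VCF tools lay the data out and keeping the filter layer vectorised.
#
# snp_panel structure:
#   sites   data.frame: transcript_id, pos, ref, alt (comma-joined for
#           multiallelic sites), qual, fs, qd, mq0f, dp  (NA = annotation
#           absent, never zero)
#   gt      character matrix sites x samples ("0/0", "0/1", ...; NA missing)
#   dp      integer matrix sites x samples
#   ad      character matrix sites x samples (comma-joined per-allele read
#           counts, ref first)
#   samples character vector (VCF order preserved)

#' Construct a SNP panel
#'
#' @param sites data.frame with columns transcript_id, pos, ref, alt and
#'   optionally qual, fs, qd, mq0f, dp (missing annotations as NA).
#' @param gt,dp,ad per-sample matrices (sites x samples); see file header.
#' @param samples sample names, in order.
#' @return An object of class \code{snp_panel}.
#' @export
snp_panel <- function(sites, gt, dp, ad, samples) {
  for (col in c("qual", "fs", "qd", "mq0f", "dp"))
    if (is.null(sites[[col]])) sites[[col]] <- NA_real_
  sites$pos <- as.integer(sites$pos)
  sites$transcript_id <- as.character(sites$transcript_id)
  sites$ref <- toupper(as.character(sites$ref))
  sites$alt <- toupper(as.character(sites$alt))
  alts <- strsplit(sites$alt, ",", fixed = TRUE)
  bad <- vapply(seq_len(nrow(sites)), function(i) {
    a <- alts[[i]]
    any(nchar(c(sites$ref[i], a)) != 1L) ||
      sites$ref[i] %in% a ||
      !all(c(sites$ref[i], a) %in% c("A", "C", "G", "T"))
  }, logical(1))
  if (any(bad))
    stop("invalid alleles at ", sites$transcript_id[bad][1], ":",
         sites$pos[bad][1],
         " (single-base A/C/G/T alleles required, ref not in alts)")
  as_mat <- function(m, mode) {
    m <- as.matrix(m)
    storage.mode(m) <- mode
    dimnames(m) <- list(NULL, samples)
    m
  }
  obj <- list(sites = sites,
              gt = as_mat(gt, "character"),
              dp = as_mat(dp, "integer"),
              ad = as_mat(ad, "character"),
              samples = as.character(samples))
  stopifnot(nrow(obj$gt) == nrow(sites), ncol(obj$gt) == length(samples))
  class(obj) <- "snp_panel"
  obj
}

#' Number of sites in a panel
#' @param panel a \code{\link{snp_panel}}.
#' @export
n_sites <- function(panel) nrow(panel$sites)

#' Subset a SNP panel by site index
#' @param x a \code{\link{snp_panel}}.
#' @param i integer or logical site index.
#' @param ... ignored.
#' @export
`[.snp_panel` <- function(x, i, ...) {
  snp_panel(x$sites[i, , drop = FALSE],
            x$gt[i, , drop = FALSE],
            x$dp[i, , drop = FALSE],
            x$ad[i, , drop = FALSE],
            x$samples)
}

#' @export
print.snp_panel <- function(x, ...) {
  cat("snp_panel: ", n_sites(x), " sites, ", length(x$samples),
      " samples (", paste(x$samples, collapse = ", "), ")\n", sep = "")
  invisible(x)
}

#' Is a site biallelic?
#' @param panel a \code{\link{snp_panel}}.
#' @return Logical vector, TRUE where the site has exactly one alternate
#'   allele.
#' @export
is_biallelic <- function(panel) !grepl(",", panel$sites$alt, fixed = TRUE)

#' Read multi-sample SNP calls from a VCF
#'
#' Wraps \code{vcfR::read.vcfR}. Site annotations FS, QD and the zero-
#' mapping-quality fraction (INFO key MQ0F if present, else MQ0/DP when both
#' are present) are carried along; absent annotations are stored as NA, not
#' zero. With \code{snps_only}, records with any allele longer than one base
#' (indels) are dropped and counted.
#'
#' @param path VCF 4.x file with GT, DP, AD FORMAT fields.
#' @param snps_only drop non-SNP records (default TRUE).
#' @return A \code{\link{snp_panel}}; the number of skipped records is in
#'   attribute \code{"skipped"}.
#' @export
read_snp_vcf <- function(path, snps_only = TRUE) {
  if (!file.exists(path)) stop("no such file: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  n <- nrow(fix)
  info_num <- function(key) {
    x <- suppressWarnings(vcfR::extract.info(v, element = key,
                                             as.numeric = TRUE))
    if (is.null(x) || length(x) == 0L) rep(NA_real_, n) else as.numeric(x)
  }
  fs <- info_num("FS")
  qd <- info_num("QD")
  dp_site <- info_num("DP")
  mq0f <- info_num("MQ0F")
  mq0 <- info_num("MQ0")
  use_ratio <- is.na(mq0f) & !is.na(mq0) & !is.na(dp_site) & dp_site > 0
  mq0f[use_ratio] <- mq0[use_ratio] / dp_site[use_ratio]

  gt <- vcfR::extract.gt(v, element = "GT")
  dp <- suppressWarnings(vcfR::extract.gt(v, element = "DP",
                                          as.numeric = TRUE))
  ad <- vcfR::extract.gt(v, element = "AD")
  gt[gt %in% c(".", "./.", ".|.")] <- NA_character_
  gt <- gsub("|", "/", gt, fixed = TRUE)

  sites <- data.frame(transcript_id = fix$CHROM,
                      pos = as.integer(fix$POS),
                      ref = fix$REF,
                      alt = fix$ALT,
                      qual = suppressWarnings(as.numeric(fix$QUAL)),
                      fs = fs, qd = qd, mq0f = mq0f, dp = dp_site,
                      stringsAsFactors = FALSE)
  keep <- rep(TRUE, n)
  if (snps_only) {
    alt_ok <- vapply(strsplit(sites$alt, ",", fixed = TRUE),
                     function(a) all(nchar(a) == 1L) && !any(a %in% c(".", "*")),
                     logical(1))
    keep <- nchar(sites$ref) == 1L & alt_ok
  }
  skipped <- sum(!keep)
  panel <- snp_panel(sites[keep, , drop = FALSE],
                     gt[keep, , drop = FALSE],
                     dp[keep, , drop = FALSE],
                     ad[keep, , drop = FALSE],
                     colnames(v@gt)[-1])
  attr(panel, "skipped") <- skipped
  panel
}

#' Write a SNP panel as VCF
#'
#' Emits a minimal VCF 4.2 with GT:DP:AD genotype columns and the site
#' annotations the filter layer consumes. When verdicts are supplied the
#' FILTER column carries PASS or the semicolon-joined failure reason codes.
#'
#' @param panel a \code{\link{snp_panel}}.
#' @param path output file.
#' @param verdicts optional verdict data.frame from
#'   \code{\link{run_filter_pipeline}} (row-aligned with the panel).
#' @export
write_snp_vcf <- function(panel, path, verdicts = NULL) {
  s <- panel$sites
  n <- nrow(s)
  fmt_num <- function(x) ifelse(is.na(x), NA_character_,
                                formatC(x, format = "g", digits = 10))
  info <- vapply(seq_len(n), function(i) {
    kv <- c(DP = fmt_num(s$dp[i]), FS = fmt_num(s$fs[i]),
            QD = fmt_num(s$qd[i]), MQ0F = fmt_num(s$mq0f[i]))
    kv <- kv[!is.na(kv)]
    if (!length(kv)) "." else paste(names(kv), kv, sep = "=", collapse = ";")
  }, character(1))
  filter <- rep(".", n)
  if (!is.null(verdicts)) {
    stopifnot(nrow(verdicts) == n)
    filter <- ifelse(verdicts$passed, "PASS",
                     gsub(",", ";", verdicts$reasons, fixed = TRUE))
  }
  gt_col <- function(i, j) {
    g <- panel$gt[i, j]
    d <- panel$dp[i, j]
    a <- panel$ad[i, j]
    paste(ifelse(is.na(g), "./.", g),
          ifelse(is.na(d), ".", d),
          ifelse(is.na(a), ".", a), sep = ":")
  }
  body <- vapply(seq_len(n), function(i) {
    paste(c(s$transcript_id[i], s$pos[i], ".", s$ref[i], s$alt[i],
            ifelse(is.na(s$qual[i]), ".", fmt_num(s$qual[i])),
            filter[i], info[i], "GT:DP:AD",
            vapply(seq_along(panel$samples), function(j) gt_col(i, j),
                   character(1))),
          collapse = "\t")
  }, character(1))
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=transmark",
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Total read depth\">",
    "##INFO=<ID=FS,Number=1,Type=Float,Description=\"Phred-scaled strand-bias p-value\">",
    "##INFO=<ID=QD,Number=1,Type=Float,Description=\"Quality by depth\">",
    "##INFO=<ID=MQ0F,Number=1,Type=Float,Description=\"Fraction of zero mapping quality reads\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Per-allele read counts\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", panel$samples), collapse = "\t"))
  writeLines(c(header, body), path)
  invisible(path)
}

# split genotype string into integer allele indices (NA for missing)
.gt_alleles <- function(g) {
  if (is.na(g)) return(c(NA_integer_, NA_integer_))
  a <- suppressWarnings(as.integer(strsplit(g, "/", fixed = TRUE)[[1]]))
  if (length(a) != 2L) return(c(NA_integer_, NA_integer_))
  a
}
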