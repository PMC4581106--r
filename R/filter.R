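# Two-round hard filtering of transcriptome SNP calls.
#
# Round 1 mirrors the variant-caller-side filters: SNP clusters (>= 3 sites
# in a 100 bp span on one transcript), excessive zero-mapping-quality reads,
# strand bias (FS), pooled minor-allele read-count frequency, quality by
# depth, site quality and total depth. Round 2 applies the transcript-aware
# filters: 30 bp transcript edges, 30 bp exon-boundary windows, at least two
# deeply covered genotypes, and exclusion of sites where the reference
# accession itself is called heterozygous.
#
# Missing annotations always pass (a filter on an absent value is a no-op),
# and reasons from both rounds are accumulated so reports are complete.

.reason_codes <- c("CLUSTER", "MQ0", "STRAND_BIAS", "LOW_MAF", "LOW_QD",
                   "LOW_QUAL", "LOW_DEPTH", "EDGE", "BOUNDARY",
                   "INSUFFICIENT_DEEP_GENOTYPES", "REF_HET")

#' Filter thresholds
#'
#' Defaults reproduce the published pipeline: remove any three SNPs within
#' 100 bp, MQ0 fraction > 0.10, FS > 60, pooled minor-allele read-count
#' frequency < 0.01, QD < 2, QUAL < 11, total depth < 11, 30 bp edge and
#' exon-boundary exclusion, at least 2 genotypes with depth > 10, and no
#' heterozygous call in the reference accession.
#'
#' @param cluster_size,cluster_window_bp cluster rule: any
#'   \code{cluster_size} sites spanning <= \code{cluster_window_bp} fail.
#' @param max_mq0_fraction maximum tolerated fraction of zero-mapping-quality
#'   reads.
#' @param max_fs maximum Phred-scaled strand-bias p-value.
#' @param min_maf minimum pooled minor-allele read-count frequency.
#' @param min_qual minimum site QUAL.
#' @param min_total_depth minimum site read depth.
#' @param min_qd minimum quality-by-depth.
#' @param edge_exclusion_bp excluded window at each transcript end.
#' @param boundary_exclusion_bp excluded window around each exon boundary.
#' @param min_deep_genotypes,deep_genotype_dp require at least this many
#'   samples with per-sample depth strictly greater than
#'   \code{deep_genotype_dp}.
#' @param reference_sample name of the sample mapped against its own
#'   transcriptome (heterozygous calls there are discarded).
#' @return A list of class \code{filter_config}.
#' @export
filter_config <- function(cluster_size = 3L, cluster_window_bp = 100L,
                          max_mq0_fraction = 0.10, max_fs = 60,
                          min_maf = 0.01, min_qual = 11,
                          min_total_depth = 11, min_qd = 2.0,
                          edge_exclusion_bp = 30L, boundary_exclusion_bp = 30L,
                          min_deep_genotypes = 2L, deep_genotype_dp = 10L,
                          reference_sample = NULL) {
  cfg <- list(cluster_size = as.integer(cluster_size),
              cluster_window_bp = as.integer(cluster_window_bp),
              max_mq0_fraction = max_mq0_fraction, max_fs = max_fs,
              min_maf = min_maf, min_qual = min_qual,
              min_total_depth = min_total_depth, min_qd = min_qd,
              edge_exclusion_bp = as.integer(edge_exclusion_bp),
              boundary_exclusion_bp = as.integer(boundary_exclusion_bp),
              min_deep_genotypes = as.integer(min_deep_genotypes),
              deep_genotype_dp = as.integer(deep_genotype_dp),
              reference_sample = reference_sample)
  num <- unlist(cfg[vapply(cfg, is.numeric, logical(1))])
  if (any(num < 0)) stop("all thresholds must be non-negative")
  class(cfg) <- "filter_config"
  cfg
}

.check_sorted <- function(sites) {
  o <- order(sites$transcript_id, sites$pos)
  if (!identical(o, seq_len(nrow(sites))))
    stop("sites must be sorted by (transcript_id, pos)")
}

#' Flag clustered SNPs
#'
#' A site fails iff it belongs to at least one run of \code{size} sites on
#' the same transcript whose inclusive span (max - min + 1) is at most
#' \code{window_bp}. Evaluated by sliding over consecutive site k-tuples,
#' which is equivalent to checking all k-subsets (any qualifying subset
#' contains a qualifying consecutive run).
#'
#' @param panel a \code{\link{snp_panel}} sorted by (transcript_id, pos).
#' @param size cluster size (default 3).
#' @param window_bp window span in bp (default 100, inclusive).
#' @return Logical vector: TRUE where the site fails the cluster rule.
#' @export
remove_clusters <- function(panel, size = 3L, window_bp = 100L) {
  s <- panel$sites
  .check_sorted(s)
  fail <- rep(FALSE, nrow(s))
  for (idx in split(seq_len(nrow(s)), s$transcript_id)) {
    p <- s$pos[idx]
    n <- length(p)
    if (n < size) next
    for (i in seq_len(n - size + 1L)) {
      j <- i + size - 1L
      if (p[j] - p[i] + 1L <= window_bp) fail[idx[i:j]] <- TRUE
    }
  }
  fail
}

# reason matrix -> verdict data.frame
.verdicts <- function(sites, reason_mat) {
  passed <- rowSums(reason_mat) == 0L
  reasons <- if (nrow(reason_mat))
    apply(reason_mat, 1L, function(r)
      paste(colnames(reason_mat)[r], collapse = ","))
  else character(0)
  data.frame(transcript_id = sites$transcript_id, pos = sites$pos,
             passed = passed, reasons = reasons,
             stringsAsFactors = FALSE)
}

#' Round-1 site-quality filters
#'
#' @param panel a \code{\link{snp_panel}} sorted by (transcript_id, pos).
#' @param cfg a \code{\link{filter_config}}.
#' @return List with \code{verdicts} (data.frame: transcript_id, pos,
#'   passed, reasons) and \code{reason_matrix} (logical sites x reasons).
#' @export
filter_round1 <- function(panel, cfg = filter_config()) {
  s <- panel$sites
  .check_sorted(s)
  n <- nrow(s)
  m <- matrix(FALSE, n, 7L,
              dimnames = list(NULL, c("CLUSTER", "MQ0", "STRAND_BIAS",
                                      "LOW_MAF", "LOW_QD", "LOW_QUAL",
                                      "LOW_DEPTH")))
  m[, "MQ0"] <- !is.na(s$mq0f) & s$mq0f > cfg$max_mq0_fraction
  m[, "STRAND_BIAS"] <- !is.na(s$fs) & s$fs > cfg$max_fs
  marcf <- minor_allele_rc_freq(panel, strict = FALSE)
  m[, "LOW_MAF"] <- !is.na(marcf) & marcf < cfg$min_maf
  m[, "LOW_QD"] <- !is.na(s$qd) & s$qd < cfg$min_qd
  m[, "LOW_QUAL"] <- !is.na(s$qual) & s$qual < cfg$min_qual
  depth <- s$dp
  no_info <- is.na(depth)
  if (any(no_info) && n > 0) {
    samp_sum <- rowSums(panel$dp, na.rm = TRUE)
    all_na <- rowSums(!is.na(panel$dp)) == 0L
    depth[no_info & !all_na] <- samp_sum[no_info & !all_na]
  }
  m[, "LOW_DEPTH"] <- !is.na(depth) & depth < cfg$min_total_depth
  # the cluster rule sees only the survivors of the other round-1 filters
  survivors <- which(rowSums(m) == 0L)
  if (length(survivors)) {
    cl <- remove_clusters(panel[survivors], cfg$cluster_size,
                          cfg$cluster_window_bp)
    m[survivors[cl], "CLUSTER"] <- TRUE
  }
  list(verdicts = .verdicts(s, m), reason_matrix = m)
}

#' Round-2 transcript-aware filters
#'
#' @param panel a \code{\link{snp_panel}}.
#' @param tx a \code{\link{transcriptome}} resolving every site's
#'   transcript_id.
#' @param cfg a \code{\link{filter_config}}; \code{reference_sample} must be
#'   set (defaults to the panel's first sample).
#' @return List with \code{verdicts} and \code{reason_matrix} as in
#'   \code{\link{filter_round1}}.
#' @export
filter_round2 <- function(panel, tx, cfg = filter_config()) {
  s <- panel$sites
  n <- nrow(s)
  ref_sample <- cfg$reference_sample
  if (is.null(ref_sample)) ref_sample <- panel$samples[1]
  if (!ref_sample %in% panel$samples)
    stop("reference sample '", ref_sample, "' not among panel samples")
  ti <- match(s$transcript_id, tx$id)
  if (anyNA(ti))
    stop("unknown transcript id: ", s$transcript_id[is.na(ti)][1])
  m <- matrix(FALSE, n, 4L,
              dimnames = list(NULL, c("EDGE", "BOUNDARY",
                                      "INSUFFICIENT_DEEP_GENOTYPES",
                                      "REF_HET")))
  len <- tx$length[ti]
  e <- cfg$edge_exclusion_bp
  m[, "EDGE"] <- s$pos <= e | s$pos > len - e
  b <- cfg$boundary_exclusion_bp
  m[, "BOUNDARY"] <- vapply(seq_len(n), function(i) {
    bp <- tx$boundaries[[ti[i]]]
    length(bp) > 0L && any(abs(s$pos[i] - bp) <= b)
  }, logical(1))
  deep <- rowSums(panel$dp > cfg$deep_genotype_dp, na.rm = TRUE)
  m[, "INSUFFICIENT_DEEP_GENOTYPES"] <- deep < cfg$min_deep_genotypes
  ref_gt <- panel$gt[, ref_sample]
  m[, "REF_HET"] <- vapply(ref_gt, function(g) {
    a <- .gt_alleles(g)
    !anyNA(a) && a[1] != a[2]
  }, logical(1), USE.NAMES = FALSE)
  list(verdicts = .verdicts(s, m), reason_matrix = m)
}

#' Run the full two-round filter pipeline
#'
#' Applies both rounds, accumulates failure reasons, and reports per-reason
#' site counts. Idempotent: re-running on the passing set removes nothing.
#'
#' @param panel a \code{\link{snp_panel}} sorted by (transcript_id, pos).
#' @param tx a \code{\link{transcriptome}}.
#' @param cfg a \code{\link{filter_config}}.
#' @return List with \code{passing} (the passing \code{snp_panel}),
#'   \code{verdicts} (one row per input site, columns transcript_id, pos,
#'   passed, reasons), \code{reason_matrix}, and \code{report} (named
#'   per-reason failing-site counts plus n_input / n_pass).
#' @export
run_filter_pipeline <- function(panel, tx, cfg = filter_config()) {
  r1 <- filter_round1(panel, cfg)
  r2 <- filter_round2(panel, tx, cfg)
  m <- cbind(r1$reason_matrix, r2$reason_matrix)
  m <- m[, .reason_codes, drop = FALSE]
  verdicts <- .verdicts(panel$sites, m)
  report <- c(colSums(m), n_input = nrow(m), n_pass = sum(verdicts$passed))
  list(passing = panel[verdicts$passed], verdicts = verdicts,
       reason_matrix = m, report = report)
}
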