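# End-to-end orchestration: filter -> classify -> stats -> CAPS -> SSR,
# plus the configuration plumbing and run manifest used by the thin
# command-line wrapper in inst/cli/transmark.R.

#' Run the marker-discovery pipeline on loaded objects
#'
#' @param tx a \code{\link{transcriptome}}.
#' @param panel a \code{\link{snp_panel}}.
#' @param cfg a \code{\link{filter_config}}.
#' @param enzymes enzyme table.
#' @param caps_params primer constraints for CAPS amplicons.
#' @param ssr_params primer constraints for SSR amplicons.
#' @param scorability_min_diff CAPS ladder-separation screen (0 = off).
#' @param design_ssr_primers,design_caps run the (slower) design stages.
#' @param blocks optional genome alignment blocks for CAPS projection.
#' @return List: filter (verdicts/report/passing), classifications, stats
#'   (tstv, unigene distribution, venn, assembly, snp_frequency), caps,
#'   ssr (loci, primers, summary).
#' @export
run_marker_pipeline <- function(tx, panel, cfg = filter_config(),
                                enzymes = load_enzyme_table(),
                                caps_params = primer_params(amp_min = 200L,
                                                            amp_max = 400L),
                                ssr_params = primer_params(),
                                scorability_min_diff = 0L,
                                design_ssr_primers = TRUE,
                                design_caps = TRUE,
                                blocks = NULL) {
  flt <- run_filter_pipeline(panel, tx, cfg)
  cls <- classify_panel(flt$passing, tx)
  smp <- panel$samples
  stats <- list(
    tstv = tstv_summary(cls),
    unigenes = unigene_distribution(flt$passing, tx),
    assembly = assembly_metrics(tx),
    snp_frequency = snp_frequency(sum(tx$length),
                                  max(1L, n_sites(flt$passing))))
  if (length(smp) == 3L) {
    st_ab <- pair_status(flt$passing, smp[1], smp[2])
    st_ac <- pair_status(flt$passing, smp[1], smp[3])
    st_bc <- pair_status(flt$passing, smp[2], smp[3])
    stats$venn <- venn_counts(st_ab, st_ac, st_bc)
  }
  caps <- NULL
  if (design_caps)
    caps <- caps_markers(flt$passing, tx, enzymes, caps_params,
                         scorability_min_diff, blocks = blocks)
  loci <- detect_ssrs_transcriptome(tx)
  ssr <- list(loci = loci, summary = summarize_ssrs(loci, tx))
  if (design_ssr_primers) ssr$primers <- ssr_primers(loci, tx, ssr_params)
  list(filter = flt, classifications = cls, stats = stats,
       caps = caps, ssr = ssr)
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Run a pipeline stage from a configuration list
#'
#' Commands: \code{simulate} (generate a synthetic study into the output
#' directory), \code{filter-snps}, \code{classify}, \code{stats},
#' \code{caps}, \code{ssr}, or \code{all}. Inputs are read from the paths
#' in \code{config}; outputs and a machine-readable run manifest are
#' written to \code{config$out_dir}.
#'
#' @param command one of simulate, filter-snps, classify, stats, caps,
#'   ssr, all.
#' @param config named list: fasta, vcf, orf, boundaries, enzymes
#'   (optional), out_dir, seed (simulate), reference_sample, and any
#'   \code{\link{filter_config}} threshold overrides under \code{filter}.
#' @return Invisibly, the list of result objects; files are written as a
#'   side effect.
#' @export
tm_run <- function(command = c("all", "simulate", "filter-snps", "classify",
                               "stats", "caps", "ssr"),
                   config) {
  command <- match.arg(command)
  out_dir <- config$out_dir
  if (is.null(out_dir)) stop("config$out_dir is required")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  if (command == "simulate" || (command == "all" && is.null(config$fasta))) {
    seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
    sim <- generate(sim_spec(seed = seed), dir = out_dir)
    config$fasta <- file.path(out_dir, "transcripts.fasta")
    config$vcf <- file.path(out_dir, "variants.vcf")
    config$orf <- file.path(out_dir, "orf.tsv")
    config$boundaries <- file.path(out_dir, "boundaries.tsv")
    if (command == "simulate") {
      .write_manifest(command, config, out_dir)
      return(invisible(list(sim = sim)))
    }
  }

  tx <- read_fasta(config$fasta)
  if (!is.null(config$orf))
    tx <- annotate_transcriptome(tx, orf = read_orf_table(config$orf))
  if (!is.null(config$boundaries))
    tx <- annotate_transcriptome(
      tx, boundaries = read_boundary_table(config$boundaries))
  panel <- read_snp_vcf(config$vcf)
  fc_args <- if (is.null(config$filter)) list() else config$filter
  if (!is.null(config$reference_sample))
    fc_args$reference_sample <- config$reference_sample
  cfg <- do.call(filter_config, fc_args)
  enzymes <- if (is.null(config$enzymes)) load_enzyme_table()
  else load_enzyme_table(config$enzymes)

  res <- run_marker_pipeline(
    tx, panel, cfg, enzymes,
    design_caps = command %in% c("all", "caps"),
    design_ssr_primers = command %in% c("all", "ssr"))

  if (command %in% c("all", "filter-snps")) {
    .write_tsv(res$filter$verdicts, file.path(out_dir, "verdicts.tsv"))
    write_snp_vcf(panel, file.path(out_dir, "filtered.vcf"),
                  verdicts = res$filter$verdicts)
  }
  if (command %in% c("all", "classify"))
    .write_tsv(res$classifications, file.path(out_dir, "classifications.tsv"))
  if (command %in% c("all", "stats")) {
    jsonlite::write_json(
      list(report = as.list(res$filter$report),
           tstv = res$stats$tstv$tstv,
           snp_frequency = res$stats$snp_frequency,
           n50 = res$stats$assembly$n50,
           mean_length = res$stats$assembly$mean_length),
      file.path(out_dir, "stats.json"), auto_unbox = TRUE, pretty = TRUE)
  }
  if (command %in% c("all", "caps") && !is.null(res$caps) &&
      nrow(res$caps$markers))
    .write_tsv(res$caps$markers, file.path(out_dir, "caps_markers.tsv"))
  if (command %in% c("all", "ssr")) {
    tab <- if (!is.null(res$ssr$primers)) res$ssr$primers else res$ssr$loci
    .write_tsv(tab, file.path(out_dir, "ssr_loci.tsv"))
  }
  .write_manifest(command, config, out_dir)
  invisible(res)
}

# reproducibility record: package version, command, full config echo and
# input checksums
.write_manifest <- function(command, config, out_dir) {
  inputs <- config[names(config) %in%
                     c("fasta", "vcf", "orf", "boundaries", "enzymes")]
  sums <- lapply(inputs, function(p)
    if (!is.null(p) && file.exists(p)) unname(tools::md5sum(p))
    else NA_character_)
  manifest <- list(
    tool = "transmark",
    version = as.character(utils::packageVersion("transmark")),
    command = command,
    config = config[!vapply(config, is.null, logical(1))],
    input_md5 = sums,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
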