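# Deterministic synthetic transcriptome + variant-panel generator. Every
# feature the pipeline is supposed to recover is planted with known
# coordinates and recorded in a truth table, so end-to-end tests can assert
# exact recovery without any external data. One pseudo-random stream per
# feature family (sequence, SSR, CAPS, SNP placement, alleles, genotypes,
# depths), each seeded from the master seed, so adding one family never
# perturbs the draws of another.

#' Specification of a synthetic study
#'
#' Defaults emulate a three-accession transcriptome variant panel: 200
#' unigenes of 1.5-3.5 kb, ~5000 SNPs placed outside the filtered zones,
#' an ORF covering the middle of most transcripts (13% 5'UTR, 60% CDS),
#' target transition/transversion ratio 1.7, a reference accession that is
#' never heterozygous, one highly heterozygous accession, read depths
#' around 100x, 50 planted microsatellites, 20 planted CAPS-diagnostic
#' contexts, and one planted violation per filter reason.
#'
#' @param seed master seed (integer).
#' @param n_transcripts number of unigenes.
#' @param length_range uniform min/max transcript length, bp.
#' @param utr5_frac,cds_frac fractions of transcript length for the 5'UTR
#'   and CDS of annotated transcripts (remainder is 3'UTR).
#' @param orf_annotated_frac fraction of transcripts with an ORF
#'   annotation; the rest classify as region UNKNOWN.
#' @param n_snps target number of clean (filter-passing) SNPs.
#' @param target_tstv transition/transversion ratio the substitution
#'   sampler aims for in expectation.
#' @param zygosity_mix per-sample genotype proportions
#'   (hom_ref/hom_alt/het); the reference sample must have het = 0.
#' @param mean_depth mean per-sample read depth.
#' @param allele_noise fraction of reads supporting the unexpected allele
#'   in homozygous calls (sequencing error / misalignment).
#' @param n_ssr number of planted SSR loci.
#' @param ssr_units unit lengths cycled through when planting SSRs.
#' @param n_caps number of planted CAPS-diagnostic SNP contexts.
#' @param caps_enzymes enzyme names cycled through when planting.
#' @param boundary_frac fraction of transcripts given exon boundaries.
#' @param plant_violations plant one filter violation per reason code.
#' @param samples sample names; first is the reference accession.
#' @return List of class \code{sim_spec}.
#' @export
sim_spec <- function(seed = 1L,
                     n_transcripts = 200L,
                     length_range = c(1500L, 3500L),
                     utr5_frac = 0.13, cds_frac = 0.60,
                     orf_annotated_frac = 0.97,
                     n_snps = 5000L,
                     target_tstv = 1.7,
                     zygosity_mix = list(
                       c(hom_ref = 0.95, hom_alt = 0.05, het = 0),
                       c(hom_ref = 0.35, hom_alt = 0.55, het = 0.10),
                       c(hom_ref = 0.20, hom_alt = 0.20, het = 0.60)),
                     mean_depth = 100,
                     allele_noise = 0.02,
                     n_ssr = 50L,
                     ssr_units = c(2L, 3L, 4L, 5L, 6L),
                     n_caps = 20L,
                     caps_enzymes = c("EcoRI", "SacI", "BamHI", "DraI",
                                      "HpaI"),
                     boundary_frac = 0.3,
                     plant_violations = TRUE,
                     samples = c("A", "B", "C")) {
  stopifnot(length(samples) == length(zygosity_mix))
  for (m in zygosity_mix)
    if (abs(sum(m) - 1) > 1e-8) stop("zygosity proportions must sum to 1")
  if (zygosity_mix[[1]][["het"]] != 0)
    stop("the reference sample cannot have heterozygous calls")
  if (length_range[1] < 1300L && plant_violations)
    stop("transcripts shorter than 1300 bp cannot host the violation set")
  spec <- list(seed = as.integer(seed), n_transcripts = as.integer(n_transcripts),
               length_range = as.integer(length_range),
               utr5_frac = utr5_frac, cds_frac = cds_frac,
               orf_annotated_frac = orf_annotated_frac,
               n_snps = as.integer(n_snps), target_tstv = target_tstv,
               zygosity_mix = zygosity_mix, mean_depth = mean_depth,
               allele_noise = allele_noise, n_ssr = as.integer(n_ssr),
               ssr_units = as.integer(ssr_units), n_caps = as.integer(n_caps),
               caps_enzymes = caps_enzymes,
               boundary_frac = boundary_frac,
               plant_violations = isTRUE(plant_violations),
               samples = samples)
  class(spec) <- "sim_spec"
  spec
}

.stream <- function(seed, offset) {
  set.seed((as.numeric(seed) * 131 + offset * 9973 + 7) %% 2147483629)
}

.rand_seq <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# replace [from, to] with random bases, leaving protected positions alone
.randomize_span <- function(x, from, to, protected = NULL) {
  span <- from:to
  if (!is.null(protected)) span <- setdiff(span, protected)
  if (!length(span)) stop("cannot scrub: whole span is protected")
  x[span] <- sample(c("A", "C", "G", "T"), length(span), replace = TRUE)
  x
}

# remove every accidental SSR from a sequence (used before planting)
.scrub_ssrs <- function(seq, thresholds = .default_ssr_thresholds,
                        protected = NULL, max_iter = 25L) {
  x <- strsplit(seq, "")[[1]]
  for (iter in seq_len(max_iter)) {
    d <- detect_ssrs(paste(x, collapse = ""), thresholds)
    if (!is.null(protected) && nrow(d)) {
      inside <- vapply(seq_len(nrow(d)), function(i)
        all(d$start[i]:d$end[i] %in% protected), logical(1))
      d <- d[!inside, , drop = FALSE]
    }
    if (nrow(d) == 0L) return(paste(x, collapse = ""))
    for (i in seq_len(nrow(d)))
      x <- .randomize_span(x, d$start[i], d$end[i], protected)
  }
  stop("flank scrub did not converge")
}

#' Plant a microsatellite into a sequence
#'
#' Substitutes \code{n_repeats} copies of \code{motif} at position
#' \code{at} (length preserved) and verifies by round-trip through
#' \code{\link{detect_ssrs}} that the planted locus — and only the planted
#' locus — is detected at exactly the planted coordinates; flanks are
#' re-randomised when they accidentally extend or merge the repeat.
#'
#' @param sequence DNA string.
#' @param motif primitive repeat unit (2-6 bp).
#' @param n_repeats number of copies.
#' @param at 1-based start position of the planted locus.
#' @param thresholds detection thresholds (to assert detectability).
#' @param max_tries flank re-randomisation attempts.
#' @return List: sequence (modified), start, end.
#' @export
plant_ssr <- function(sequence, motif, n_repeats, at,
                      thresholds = .default_ssr_thresholds,
                      max_tries = 10L) {
  motif <- toupper(motif)
  k <- nchar(motif)
  if (!k %in% 2:6) stop("motif unit length must be 2-6")
  if (!.is_primitive(motif)) stop("motif must be primitive")
  thr <- thresholds[[as.character(k)]]
  if (n_repeats < thr)
    stop("planted repeat count ", n_repeats,
         " is below the detection threshold ", thr)
  ins <- strrep(motif, n_repeats)
  end <- at + nchar(ins) - 1L
  if (at < 1L || end > nchar(sequence)) stop("planted SSR does not fit")
  x <- strsplit(sequence, "")[[1]]
  x[at:end] <- strsplit(ins, "")[[1]]
  pad <- 6L * max(thr, 6L)     # widest window another repeat could span
  protected <- at:end
  for (try in seq_len(max_tries)) {
    lo <- max(1L, at - pad)
    hi <- min(length(x), end + pad)
    local <- detect_ssrs(paste(x[lo:hi], collapse = ""), thresholds)
    local$start <- local$start + lo - 1L
    local$end <- local$end + lo - 1L
    exact <- nrow(local) == 1L && local$start == at && local$end == end &&
      local$n_repeats == n_repeats
    if (exact) return(list(sequence = paste(x, collapse = ""),
                           start = at, end = end))
    # scrub the flanks (never the planted bases) and re-verify
    if (at > 1L)
      x <- .randomize_span(x, max(1L, at - pad), at - 1L, protected)
    if (end < length(x))
      x <- .randomize_span(x, end + 1L, min(length(x), end + pad), protected)
  }
  stop("flank scrub impossible around planted SSR at ", at)
}

# Substitute a restriction site so the SNP at snp_pos is diagnostic for
# `enzyme`: the cut allele carries the intact recognition site, the other
# allele carries a base outside the degeneracy set at one position.
.plant_caps_context <- function(x, enzyme, at, allele_cut, max_tries = 10L) {
  rec <- strsplit(enzyme$recognition, "")[[1]]
  m <- length(rec)
  concrete <- vapply(rec, function(p) iupac_expand(p)[1], character(1))
  fixed_pos <- which(vapply(rec, function(p)
    length(iupac_expand(p)) == 1L, logical(1)))
  j <- fixed_pos[ceiling(length(fixed_pos) / 2)]
  site_base <- concrete[j]
  broken <- setdiff(c("A", "C", "G", "T"), iupac_expand(rec[j]))[1]
  snp_pos <- at + j - 1L
  x[at:(at + m - 1L)] <- concrete
  if (allele_cut == "ALT") x[snp_pos] <- broken
  ref <- x[snp_pos]
  alt <- if (allele_cut == "ALT") site_base else broken
  flank <- 10L
  for (try in seq_len(max_tries)) {
    lo <- max(1L, snp_pos - flank)
    hi <- min(length(x), snp_pos + flank)
    centre <- snp_pos - lo + 1L
    win_ref <- paste(x[lo:hi], collapse = "")
    wa <- x[lo:hi]; wa[centre] <- alt
    win_alt <- paste(wa, collapse = "")
    covers <- function(win) {
      hits <- scan_iupac(win, enzyme$recognition)
      any(hits <= centre & centre <= hits + m - 1L)
    }
    ok <- if (allele_cut == "REF") covers(win_ref) && !covers(win_alt)
    else !covers(win_ref) && covers(win_alt)
    if (ok) return(list(x = x, snp_pos = snp_pos, ref = ref, alt = alt))
    x <- .randomize_span(x, max(1L, at - flank), min(length(x), at + m - 1L + flank),
                         protected = at:(at + m - 1L))
  }
  stop("could not plant a clean diagnostic context at ", at)
}

# pick `count` positions from `pool`, keeping every picked pair (including
# pre-seeded positions) more than `min_gap` bp apart
.pick_spaced <- function(pool, count, seeded = integer(0), min_gap = 50L) {
  picked <- integer(0)
  anchors <- seeded
  while (length(picked) < count && length(pool)) {
    i <- if (length(pool) == 1L) 1L else sample.int(length(pool), 1L)
    p <- pool[i]
    pool <- pool[-i]
    if (!length(anchors) || min(abs(anchors - p)) > min_gap) {
      picked <- c(picked, p)
      anchors <- c(anchors, p)
    }
  }
  sort(picked)
}

# draw alt allele given ref so transitions occur with probability
# tstv/(1+tstv)
.draw_alt <- function(ref, target_tstv) {
  partner <- c(A = "G", G = "A", C = "T", T = "C")
  p_ts <- target_tstv / (1 + target_tstv)
  vapply(ref, function(r) {
    if (stats::runif(1) < p_ts) partner[[r]]
    else sample(setdiff(c("A", "C", "G", "T"), c(r, partner[[r]])), 1L)
  }, character(1), USE.NAMES = FALSE)
}

.region_of_pos <- function(pos, orf_start, orf_end) {
  if (is.na(orf_start)) return("UNKNOWN")
  if (pos < orf_start) "FIVE_UTR"
  else if (pos <= orf_end) "CDS"
  else "THREE_UTR"
}

#' Generate a synthetic transcriptome study with planted truth
#'
#' Produces a transcriptome, ORF and boundary annotations, a multi-sample
#' SNP panel, and truth tables for every planted feature: clean SNPs (with
#' region and substitution class), CAPS-diagnostic contexts, SSR loci, and
#' filter violations (one event per reason code). Runs are byte-identical
#' for a fixed spec.
#'
#' @param spec a \code{\link{sim_spec}}.
#' @param dir optional directory; when given, writes transcripts.fasta,
#'   orf.tsv, boundaries.tsv, variants.vcf and truth_*.tsv files there.
#' @return List: \code{tx} (transcriptome), \code{panel}
#'   (\code{\link{snp_panel}}), \code{truth} (list of data.frames: snps,
#'   ssr, caps, violations), \code{spec}.
#' @export
generate <- function(spec, dir = NULL) {
  stopifnot(inherits(spec, "sim_spec"))
  n <- spec$n_transcripts
  ids <- sprintf("TX%04d", seq_len(n))
  reserved <- if (spec$plant_violations) 1:2 else integer(0)

  ## sequences -------------------------------------------------------------
  .stream(spec$seed, 1L)
  lens <- sample(spec$length_range[1]:spec$length_range[2], n, replace = TRUE)
  seqs <- vapply(lens, .rand_seq, character(1))
  seqs <- vapply(seqs, .scrub_ssrs, character(1), USE.NAMES = FALSE)

  ## ORFs and boundaries ---------------------------------------------------
  .stream(spec$seed, 2L)
  annotated <- rep(TRUE, n)
  n_unk <- round((1 - spec$orf_annotated_frac) * n)
  if (n_unk > 0)
    annotated[sample(setdiff(seq_len(n), reserved), n_unk)] <- FALSE
  orf_start <- ifelse(annotated, pmax(2L, floor(lens * spec$utr5_frac) + 1L),
                      NA_integer_)
  orf_end <- ifelse(annotated,
                    pmin(lens - 1L,
                         orf_start + floor(lens * spec$cds_frac) - 1L),
                    NA_integer_)
  boundaries <- rep(list(integer(0)), n)
  n_bnd <- round(spec$boundary_frac * n)
  bnd_tx <- sample(setdiff(seq_len(n), reserved),
                   min(n_bnd, n - length(reserved)))
  for (i in bnd_tx) {
    k <- sample(1:2, 1L)
    b <- sort(sample(seq(200L, lens[i] - 200L), k))
    if (k == 2L && diff(b) < 80L) b <- b[1]
    boundaries[[i]] <- as.integer(b)
  }
  if (spec$plant_violations) boundaries[[2]] <- 500L

  ## planted SSRs ----------------------------------------------------------
  .stream(spec$seed, 3L)
  occupied <- rep(list(integer(0)), n)   # protected positions per transcript
  truth_ssr <- NULL
  plantable <- setdiff(seq_len(n), reserved)
  if (spec$n_ssr > 0L) {
    rows <- vector("list", spec$n_ssr)
    for (j in seq_len(spec$n_ssr)) {
      unit <- spec$ssr_units[(j - 1L) %% length(spec$ssr_units) + 1L]
      thr <- .default_ssr_thresholds[[as.character(unit)]]
      n_rep <- thr + (j %% 4L)
      repeat {
        motif <- .rand_seq(unit)
        if (.is_primitive(motif)) break
      }
      placed <- FALSE
      for (try in seq_len(50L)) {
        i <- sample(plantable, 1L)
        span <- unit * n_rep
        lo <- 120L
        hi <- lens[i] - span - 120L
        if (hi <= lo) next
        at <- sample(lo:hi, 1L)
        guard <- max(1L, at - 60L):min(lens[i], at + span + 59L)
        if (any(guard %in% occupied[[i]])) next
        pl <- plant_ssr(seqs[i], motif, n_rep, at)
        seqs[i] <- pl$sequence
        occupied[[i]] <- c(occupied[[i]], guard)
        rows[[j]] <- data.frame(transcript_id = ids[i], start = pl$start,
                                end = pl$end, motif = motif, unit = unit,
                                n_repeats = n_rep, stringsAsFactors = FALSE)
        placed <- TRUE
        break
      }
      if (!placed) stop("could not place planted SSR ", j)
    }
    truth_ssr <- do.call(rbind, rows)
  }

  ## planted CAPS contexts -------------------------------------------------
  .stream(spec$seed, 4L)
  enzymes <- load_enzyme_table()
  truth_caps <- NULL
  caps_by_tx <- rep(list(integer(0)), n)   # planted SNP positions
  if (spec$n_caps > 0L) {
    rows <- vector("list", spec$n_caps)
    for (j in seq_len(spec$n_caps)) {
      ename <- spec$caps_enzymes[(j - 1L) %% length(spec$caps_enzymes) + 1L]
      e <- enzymes[enzymes$name == ename, ]
      if (nrow(e) != 1L) stop("unknown CAPS enzyme: ", ename)
      allele_cut <- if (j %% 2L == 0L) "ALT" else "REF"
      placed <- FALSE
      for (try in seq_len(50L)) {
        i <- sample(plantable, 1L)
        m <- nchar(e$recognition)
        lo <- 220L
        hi <- lens[i] - m - 220L
        if (hi <= lo) next
        at <- sample(lo:hi, 1L)
        guard <- max(1L, at - 60L):min(lens[i], at + m - 1L + 60L)
        if (any(guard %in% occupied[[i]])) next
        bnd <- boundaries[[i]]
        if (length(bnd) && any(abs(at - bnd) <= 40L)) next
        x <- strsplit(seqs[i], "")[[1]]
        pc <- .plant_caps_context(x, e, at, allele_cut)
        seqs[i] <- paste(pc$x, collapse = "")
        occupied[[i]] <- c(occupied[[i]], guard)
        caps_by_tx[[i]] <- c(caps_by_tx[[i]], pc$snp_pos)
        rows[[j]] <- data.frame(transcript_id = ids[i], pos = pc$snp_pos,
                                ref = pc$ref, alt = pc$alt, enzyme = ename,
                                allele_cut = allele_cut,
                                stringsAsFactors = FALSE)
        placed <- TRUE
        break
      }
      if (!placed) stop("could not place planted CAPS context ", j)
    }
    truth_caps <- do.call(rbind, rows)
  }
  # CAPS planting may have disturbed scrubbed flanks; remove any repeat it
  # created while protecting planted loci
  if (!is.null(truth_ssr)) {
    for (i in plantable) {
      prot <- occupied[[i]]
      seqs[i] <- .scrub_ssrs(seqs[i], protected = prot)
    }
    # final exactness check: the detector must see exactly the planted set
    det <- do.call(rbind, lapply(plantable, function(i) {
      d <- detect_ssrs(seqs[i])
      if (nrow(d)) cbind(data.frame(transcript_id = ids[i]), d) else NULL
    }))
    det_key <- if (is.null(det)) character(0)
    else paste(det$transcript_id, det$start, det$end, det$motif)
    tru_key <- paste(truth_ssr$transcript_id, truth_ssr$start,
                     truth_ssr$end, truth_ssr$motif)
    if (!setequal(det_key, tru_key))
      stop("internal: planted SSR set does not round-trip")
  }

  ## clean SNP positions ---------------------------------------------------
  .stream(spec$seed, 5L)
  budget <- spec$n_snps
  weights <- lens
  weights[reserved] <- 0L
  per_tx <- as.integer(round(budget * weights / sum(weights)))
  snp_pos <- vector("list", n)
  for (i in seq_len(n)) {
    if (per_tx[i] == 0L) { snp_pos[[i]] <- integer(0); next }
    pool <- 31:(lens[i] - 30L)
    bnd <- boundaries[[i]]
    if (length(bnd))
      pool <- pool[vapply(pool, function(p) all(abs(p - bnd) > 30L),
                          logical(1))]
    snp_pos[[i]] <- .pick_spaced(pool, per_tx[i],
                                 seeded = caps_by_tx[[i]], min_gap = 50L)
  }

  ## allele draw -----------------------------------------------------------
  .stream(spec$seed, 6L)
  clean <- do.call(rbind, lapply(seq_len(n), function(i) {
    p <- snp_pos[[i]]
    if (!length(p)) return(NULL)
    data.frame(tx_i = i, pos = p, stringsAsFactors = FALSE)
  }))
  clean$ref <- vapply(seq_len(nrow(clean)), function(r)
    substr(seqs[clean$tx_i[r]], clean$pos[r], clean$pos[r]), character(1))
  clean$alt <- .draw_alt(clean$ref, spec$target_tstv)
  clean$kind <- "clean"

  if (!is.null(truth_caps)) {
    caps_rows <- data.frame(tx_i = match(truth_caps$transcript_id, ids),
                            pos = truth_caps$pos, ref = truth_caps$ref,
                            alt = truth_caps$alt, kind = "caps",
                            stringsAsFactors = FALSE)
    clean <- rbind(clean, caps_rows)
  }

  ## genotypes, depths, annotations ----------------------------------------
  .stream(spec$seed, 7L)
  ns <- nrow(clean)
  n_smp <- length(spec$samples)
  gt <- matrix(NA_character_, ns, n_smp)
  for (j in seq_len(n_smp)) {
    mix <- spec$zygosity_mix[[j]]
    z <- sample(c("0/0", "1/1", "0/1"), ns, replace = TRUE, prob = mix)
    gt[, j] <- z
  }
  is_caps <- clean$kind == "caps"
  gt[is_caps, 1L] <- "0/0"          # reference accession carries ref
  gt[is_caps, 2L] <- "1/1"          # a homozygous-diagnostic partner
  allref <- rowSums(gt != "0/0") == 0L
  gt[allref, 2L] <- "1/1"           # every site must segregate somewhere
  # at an all-hom-alt site the reference allele would be supported only by
  # error reads and could not survive the allele-frequency filter; the
  # reference accession keeps its own assembly allele instead
  allalt <- rowSums(gt != "1/1") == 0L
  gt[allalt, 1L] <- "0/0"

  .stream(spec$seed, 8L)
  dp <- matrix(pmax(stats::rpois(ns * n_smp, spec$mean_depth), 12L), ns, n_smp)
  ad <- matrix(NA_character_, ns, n_smp)
  for (j in seq_len(n_smp)) {
    err <- stats::rbinom(ns, dp[, j], spec$allele_noise)
    altn <- ifelse(gt[, j] == "0/0", err,
                   ifelse(gt[, j] == "1/1", dp[, j] - err,
                          stats::rbinom(ns, dp[, j], 0.5)))
    ad[, j] <- paste(dp[, j] - altn, altn, sep = ",")
  }
  site_dp <- rowSums(dp)
  qd <- stats::runif(ns, 5, 30)
  qual <- pmin(3000, qd * site_dp)
  fs <- stats::runif(ns, 0, 20)
  mq0f <- stats::runif(ns, 0, 0.05)

  sites <- data.frame(transcript_id = ids[clean$tx_i], pos = clean$pos,
                      ref = clean$ref, alt = clean$alt,
                      qual = qual, fs = fs, qd = qd, mq0f = mq0f,
                      dp = site_dp, stringsAsFactors = FALSE)

  truth_snps <- data.frame(transcript_id = sites$transcript_id,
                           pos = sites$pos, ref = sites$ref,
                           alt = sites$alt, kind = clean$kind,
                           reason = NA_character_,
                           stringsAsFactors = FALSE)
  truth_snps$region <- vapply(seq_len(ns), function(r)
    .region_of_pos(sites$pos[r], orf_start[clean$tx_i[r]],
                   orf_end[clean$tx_i[r]]), character(1))
  sub <- classify_substitution(sites$ref, sites$alt)
  truth_snps$class <- sub$class
  truth_snps$is_transition <- sub$is_transition

  ## planted filter violations ---------------------------------------------
  truth_viol <- NULL
  if (spec$plant_violations) {
    .stream(spec$seed, 9L)
    v <- .plant_violations(ids, seqs, lens, spec)
    sites <- rbind(sites, v$sites)
    gt <- rbind(gt, v$gt)
    dp <- rbind(dp, v$dp)
    ad <- rbind(ad, v$ad)
    truth_viol <- v$truth
    extra <- data.frame(transcript_id = v$sites$transcript_id,
                        pos = v$sites$pos, ref = v$sites$ref,
                        alt = v$sites$alt, kind = "violation",
                        reason = v$truth$reason,
                        stringsAsFactors = FALSE)
    vi <- match(extra$transcript_id, ids)
    extra$region <- vapply(seq_len(nrow(extra)), function(r)
      .region_of_pos(extra$pos[r], orf_start[vi[r]], orf_end[vi[r]]),
      character(1))
    esub <- classify_substitution(extra$ref, extra$alt)
    extra$class <- esub$class
    extra$is_transition <- esub$is_transition
    truth_snps <- rbind(truth_snps, extra[, names(truth_snps)])
  }

  ## assemble, sorted by (transcript, pos) ----------------------------------
  o <- order(sites$transcript_id, sites$pos)
  panel <- snp_panel(sites[o, ], gt[o, , drop = FALSE],
                     dp[o, , drop = FALSE], ad[o, , drop = FALSE],
                     spec$samples)
  truth_snps <- truth_snps[o, ]
  rownames(truth_snps) <- NULL
  tx <- transcriptome(ids, seqs, orf_start, orf_end, boundaries)
  out <- list(tx = tx, panel = panel,
              truth = list(snps = truth_snps, ssr = truth_ssr,
                           caps = truth_caps, violations = truth_viol),
              spec = spec)
  if (!is.null(dir)) .write_sim(out, dir)
  out
}

# One clean-but-for-one-reason site per reason code, on two reserved
# transcripts (the second carries the exon boundary at 500). Positions are
# fixed so no planted site interacts with another rule.
.plant_violations <- function(ids, seqs, lens, spec) {
  n_smp <- length(spec$samples)
  base_site <- function(tx_i, pos) {
    ref <- substr(seqs[tx_i], pos, pos)
    alt <- setdiff(c("A", "G", "C", "T"), ref)[1]
    list(site = data.frame(transcript_id = ids[tx_i], pos = pos, ref = ref,
                           alt = alt, qual = 900, fs = 2, qd = 20,
                           mq0f = 0.01, dp = 300, stringsAsFactors = FALSE),
         gt = c("0/0", "1/1", rep("0/0", n_smp - 2L)),
         dp = rep(100L, n_smp),
         ad = c("98,2", "2,98", rep("98,2", n_smp - 2L)))
  }
  plan <- list(
    list(reason = "EDGE", tx = 1L, pos = 15L),
    list(reason = "CLUSTER", tx = 1L, pos = 200L),
    list(reason = "CLUSTER", tx = 1L, pos = 240L),
    list(reason = "CLUSTER", tx = 1L, pos = 280L),
    list(reason = "MQ0", tx = 1L, pos = 420L),
    list(reason = "STRAND_BIAS", tx = 1L, pos = 540L),
    list(reason = "LOW_MAF", tx = 1L, pos = 660L),
    list(reason = "LOW_QD", tx = 1L, pos = 780L),
    list(reason = "LOW_QUAL", tx = 1L, pos = 900L),
    list(reason = "LOW_DEPTH", tx = 1L, pos = 1020L),
    list(reason = "INSUFFICIENT_DEEP_GENOTYPES", tx = 1L, pos = 1140L),
    list(reason = "REF_HET", tx = 1L, pos = 1260L),
    list(reason = "BOUNDARY", tx = 2L, pos = 510L))
  sites <- NULL; gt <- NULL; dpm <- NULL; adm <- NULL; truth <- NULL
  for (p in plan) {
    b <- base_site(p$tx, p$pos)
    s <- b$site
    g <- b$gt; d <- b$dp; a <- b$ad
    switch(p$reason,
           MQ0 = { s$mq0f <- 0.25 },
           STRAND_BIAS = { s$fs <- 75 },
           LOW_MAF = {
             g <- rep("0/0", n_smp)
             d <- rep(200L, n_smp)
             a <- rep("199,1", n_smp)
             s$dp <- 600
           },
           LOW_QD = { s$qd <- 1.5 },
           LOW_QUAL = { s$qual <- 8 },
           LOW_DEPTH = { s$dp <- 9 },
           INSUFFICIENT_DEEP_GENOTYPES = {
             d <- c(50L, 9L, rep(8L, n_smp - 2L))
             a <- c("49,1", "1,8", rep("7,1", n_smp - 2L))
             s$dp <- sum(d)
           },
           REF_HET = {
             g[1] <- "0/1"
             a[1] <- "50,50"
           },
           NULL)
    sites <- rbind(sites, s)
    gt <- rbind(gt, g)
    dpm <- rbind(dpm, d)
    adm <- rbind(adm, a)
    truth <- rbind(truth, data.frame(reason = p$reason,
                                     transcript_id = ids[p$tx], pos = p$pos,
                                     stringsAsFactors = FALSE))
  }
  list(sites = sites, gt = gt, dp = dpm, ad = adm, truth = truth)
}

.write_sim <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(sim$tx, file.path(dir, "transcripts.fasta"))
  orf <- sim$tx[!is.na(sim$tx$orf_start),
                c("id", "orf_start", "orf_end")]
  names(orf)[1] <- "transcript_id"
  utils::write.table(orf, file.path(dir, "orf.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  bl <- do.call(rbind, lapply(seq_len(nrow(sim$tx)), function(i) {
    b <- sim$tx$boundaries[[i]]
    if (!length(b)) return(NULL)
    data.frame(transcript_id = sim$tx$id[i], boundary_pos = b)
  }))
  if (is.null(bl))
    bl <- data.frame(transcript_id = character(0), boundary_pos = integer(0))
  utils::write.table(bl, file.path(dir, "boundaries.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_snp_vcf(sim$panel, file.path(dir, "variants.vcf"))
  for (nm in names(sim$truth)) {
    if (is.null(sim$truth[[nm]])) next
    utils::write.table(sim$truth[[nm]],
                       file.path(dir, paste0("truth_", nm, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}
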