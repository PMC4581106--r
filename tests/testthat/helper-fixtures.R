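# Fixtures built in code plus the independent oracles the property tests
# compare against. Oracles deliberately re-derive everything from first
# principles (brute force / regex / exhaustive enumeration) instead of
# calling the implementation under test.

# --- tiny panel construction -------------------------------------------

make_panel <- function(transcript_id, pos, ref, alt,
                       gt = NULL, dp = NULL, ad = NULL,
                       samples = c("A", "B", "C"),
                       qual = 1000, fs = 1, qd = 25, mq0f = 0.01,
                       dp_site = 300) {
  n <- length(pos)
  sites <- data.frame(transcript_id = transcript_id, pos = pos,
                      ref = ref, alt = alt,
                      qual = rep_len(qual, n), fs = rep_len(fs, n),
                      qd = rep_len(qd, n), mq0f = rep_len(mq0f, n),
                      dp = rep_len(dp_site, n), stringsAsFactors = FALSE)
  if (is.null(gt))   # reference accession homozygous by default
    gt <- matrix(rep_len(c("0/0", "1/1", "0/1"), length(samples)),
                 n, length(samples), byrow = TRUE)
  if (is.null(dp)) dp <- matrix(100L, n, length(samples))
  if (is.null(ad)) ad <- matrix("50,50", n, length(samples))
  snp_panel(sites, gt, dp, ad, samples)
}

make_tx <- function(n = 1, len = 500, seed = 42) {
  set.seed(seed)
  seqs <- vapply(rep_len(len, n), function(L)
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = ""),
    character(1))
  transcriptome(sprintf("T%02d", seq_len(n)), seqs)
}

# one shared medium-sized synthetic study, generated once per test run
.sim_cache <- new.env(parent = emptyenv())
small_sim <- function() {
  if (is.null(.sim_cache$sim))
    .sim_cache$sim <- generate(sim_spec(seed = 7, n_transcripts = 40,
                                        n_snps = 600, n_ssr = 15,
                                        n_caps = 10))
  .sim_cache$sim
}

# --- oracle: cluster filter by exhaustive triples ----------------------

cluster_oracle <- function(tids, pos, size = 3L, window = 100L) {
  fail <- rep(FALSE, length(pos))
  for (t in unique(tids)) {
    idx <- which(tids == t)
    if (length(idx) < size) next
    stopifnot(!is.unsorted(pos[idx]))
    cmb <- utils::combn(idx, size)   # every size-subset, exhaustively
    spans <- pos[cmb[size, ]] - pos[cmb[1L, ]] + 1L
    hit <- cmb[, spans <= window, drop = FALSE]
    fail[unique(as.vector(hit))] <- TRUE
  }
  fail
}

# --- oracle: SSR detection via regex + containment filter ---------------

oracle_primitive <- function(motif) {
  k <- nchar(motif)
  for (d in seq_len(k - 1L)) {
    if (k %% d != 0L) next
    unit <- substr(motif, 1L, d)
    if (paste(rep(unit, k / d), collapse = "") == motif) return(FALSE)
  }
  TRUE
}

ssr_regex_oracle <- function(seq, thresholds = c(`2` = 6L, `3` = 5L,
                                                 `4` = 5L, `5` = 5L,
                                                 `6` = 5L)) {
  rows <- list()
  for (k in 2:6) {
    thr <- thresholds[[as.character(k)]]
    pat <- sprintf("([ACGT]{%d})\\1{%d,}", k, thr - 1L)
    m <- gregexpr(pat, seq, perl = TRUE)[[1]]
    if (m[1] == -1L) next
    for (i in seq_along(m)) {
      start <- m[i]
      mlen <- attr(m, "match.length")[i]
      motif <- substr(seq, start, start + k - 1L)
      if (!oracle_primitive(motif)) next
      n <- mlen %/% k
      rows[[length(rows) + 1L]] <- data.frame(
        start = start, end = start + n * k - 1L, motif = motif,
        unit = k, n_repeats = n, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(start = integer(0), end = integer(0),
                      motif = character(0), unit = integer(0),
                      n_repeats = integer(0)))
  df <- do.call(rbind, rows)
  keep <- rep(TRUE, nrow(df))
  for (i in seq_len(nrow(df))) {
    if (any(df$unit < df$unit[i] & df$start <= df$start[i] &
              df$end >= df$end[i])) keep[i] <- FALSE
  }
  df <- df[keep, , drop = FALSE]
  df[order(df$start, df$unit), , drop = FALSE]
}

# a random sequence with random repeat bursts (above and below threshold)
repeat_rich_seq <- function(len = 10000L, n_bursts = 8L) {
  base <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
  s <- paste(base, collapse = "")
  for (b in seq_len(n_bursts)) {
    k <- sample(2:6, 1L)
    reps <- sample(3:9, 1L)
    motif <- paste(sample(c("A", "C", "G", "T"), k, replace = TRUE),
                   collapse = "")
    burst <- strrep(motif, reps)
    at <- sample.int(nchar(s) - nchar(burst), 1L)
    substr(s, at, at + nchar(burst) - 1L) <- burst
  }
  s
}

# --- oracle: differential enzymes by exhaustive concrete-pattern scan ----

ORACLE_IUPAC <- list(A = "A", C = "C", G = "G", T = "T",
                     R = c("A", "G"), Y = c("C", "T"),
                     N = c("A", "C", "G", "T"))

oracle_expand_pattern <- function(rec) {
  sets <- ORACLE_IUPAC[strsplit(rec, "")[[1]]]
  grid <- do.call(expand.grid, c(sets, stringsAsFactors = FALSE))
  apply(grid, 1L, paste, collapse = "")
}

caps_oracle <- function(sequence, pos, ref, alt, enzymes, flank = 10L) {
  L <- nchar(sequence)
  allele_seq <- function(base) {
    x <- sequence
    substr(x, pos, pos) <- base
    x
  }
  covering_hit <- function(seqstr, rec) {
    m <- nchar(rec)
    pats <- oracle_expand_pattern(rec)
    for (start in max(1L, pos - m + 1L):pos) {
      if (start + m - 1L > L) next
      if (start < pos - flank || start + m - 1L > pos + flank) next
      win <- substr(seqstr, start, start + m - 1L)
      if (win %in% pats) return(TRUE)
    }
    FALSE
  }
  rows <- list()
  for (k in seq_len(nrow(enzymes))) {
    hr <- covering_hit(allele_seq(ref), enzymes$recognition[k])
    ha <- covering_hit(allele_seq(alt), enzymes$recognition[k])
    if (xor(hr, ha))
      rows[[length(rows) + 1L]] <- data.frame(
        enzyme = enzymes$name[k],
        allele_cut = if (hr) "REF" else "ALT",
        stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(enzyme = character(0), allele_cut = character(0)))
  do.call(rbind, rows)
}

# --- oracle: N50 by scanning all candidate lengths ----------------------

n50_oracle <- function(len) {
  cand <- sort(unique(len))
  ok <- cand[vapply(cand, function(L)
    sum(len[len >= L]) >= sum(len) / 2, logical(1))]
  max(ok)
}
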