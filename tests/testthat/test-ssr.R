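test_that("detection applies the per-unit thresholds and primitivity", {
  d <- detect_ssrs(paste0("TT", strrep("AG", 6), "TT"))
  expect_equal(nrow(d), 1L)
  expect_equal(d$motif, "AG")
  expect_equal(d$n_repeats, 6L)
  expect_equal(d$start, 3L)
  expect_equal(d$end, 14L)

  # five dinucleotide repeats are below the threshold of six
  expect_equal(nrow(detect_ssrs(paste0("TT", strrep("AG", 5), "TT"))), 0L)
  # five trinucleotide repeats meet the threshold of five
  expect_equal(nrow(detect_ssrs(paste0("TT", strrep("AAG", 5), "TT"))), 1L)

  # a 12-mer AT run is reported at the primitive unit, never as ATAT x 3
  d2 <- detect_ssrs("ATATATATATAT")
  expect_equal(nrow(d2), 1L)
  expect_equal(d2$motif, "AT")
  expect_equal(d2$n_repeats, 6L)

  # mononucleotide runs are not SSRs here, and AA is not primitive
  expect_equal(nrow(detect_ssrs(strrep("A", 30))), 0L)
  # runs containing N are not reported
  expect_equal(nrow(detect_ssrs(paste0(strrep("AN", 8), "CC"))), 0L)
})

test_that("locus arithmetic invariant: span = unit x repeats", {
  set.seed(9)
  for (r in 1:20) {
    d <- detect_ssrs(repeat_rich_seq(3000L, 5L))
    if (!nrow(d)) next
    expect_equal(d$end - d$start + 1L, d$unit * d$n_repeats)
    expect_true(all(vapply(d$motif, .is_primitive, logical(1))))
  }
})

test_that("detector agrees with the regex oracle on repeat-rich sequences", {
  set.seed(13)
  for (r in 1:40) {
    s <- repeat_rich_seq(10000L, sample(0:8, 1))
    d <- detect_ssrs(s)
    o <- ssr_regex_oracle(s)
    expect_identical(paste(d$start, d$end, d$motif, d$n_repeats),
                     paste(o$start, o$end, o$motif, o$n_repeats))
  }
})

test_that("canonicalization is rotation and revcomp invariant", {
  expect_equal(canonical_class("GA"), "AG/CT")
  expect_equal(canonical_class("AG"), "AG/CT")
  expect_equal(canonical_class("TC"), "AG/CT")
  expect_equal(canonical_class("CT"), "AG/CT")
  expect_equal(canonical_class("TTC"), "AAG/CTT")
  expect_equal(canonical_class("AT"), "AT/TA")
  expect_error(canonical_class("ATAT"), "primitive")
  set.seed(17)
  for (r in 1:50) {
    k <- sample(2:6, 1)
    repeat {
      m <- paste(sample(c("A", "C", "G", "T"), k, replace = TRUE),
                 collapse = "")
      if (.is_primitive(m)) break
    }
    cls <- canonical_class(m)
    rot <- .rotations(m)[sample.int(k, 1)]
    expect_equal(canonical_class(rot), cls)
    expect_equal(canonical_class(revcomp(m)), cls)
  }
})

test_that("exactly 4 dinucleotide and 10 trinucleotide classes exist", {
  all_motifs <- function(k) {
    g <- do.call(expand.grid, rep(list(c("A", "C", "G", "T")), k))
    m <- apply(g, 1, paste, collapse = "")
    m[vapply(m, .is_primitive, logical(1))]
  }
  expect_equal(length(unique(vapply(all_motifs(2), canonical_class,
                                    character(1)))), 4L)
  expect_equal(length(unique(vapply(all_motifs(3), canonical_class,
                                    character(1)))), 10L)
})

test_that("compound grouping follows the interruption distance", {
  loci <- data.frame(transcript_id = "t1",
                     start = c(10L, 25L, 300L),
                     end = c(21L, 39L, 320L))
  g <- group_compound(loci, max_gap = 100L)
  expect_equal(g$compound_group, c(1L, 1L, NA))
  g2 <- group_compound(data.frame(transcript_id = "t1", start = c(10L, 172L),
                                  end = c(21L, 190L)), max_gap = 100L)
  expect_equal(g2$compound_group, c(NA_integer_, NA_integer_))
  g3 <- group_compound(data.frame(transcript_id = "t1", start = 10L,
                                  end = 21L))
  expect_true(is.na(g3$compound_group))
  # a gap of exactly max_gap still groups; loci on different transcripts do not
  g4 <- group_compound(data.frame(transcript_id = c("t1", "t2"),
                                  start = c(10L, 30L), end = c(21L, 44L)))
  expect_true(all(is.na(g4$compound_group)))
})

test_that("planted loci are recovered exactly across the transcriptome", {
  sim <- small_sim()
  loci <- detect_ssrs_transcriptome(sim$tx)
  tr <- sim$truth$ssr
  expect_setequal(paste(loci$transcript_id, loci$start, loci$end, loci$motif),
                  paste(tr$transcript_id, tr$start, tr$end, tr$motif))
  # order independence
  perm <- sample(nrow(sim$tx))
  tx_shuffled <- sim$tx[perm, ]
  loci2 <- detect_ssrs_transcriptome(tx_shuffled)
  expect_identical(loci, loci2)
})

test_that("summary counts totals, multi-SSR transcripts and compounds", {
  sim <- small_sim()
  loci <- detect_ssrs_transcriptome(sim$tx)
  sm <- summarize_ssrs(loci, sim$tx)
  expect_equal(sm$n_ssrs, nrow(sim$truth$ssr))
  expect_equal(sum(sm$by_unit), sm$n_ssrs)
  per_tx <- table(sim$truth$ssr$transcript_id)
  expect_equal(sm$n_containing, length(per_tx))
  expect_equal(sm$n_multi, sum(per_tx > 1))
  expect_equal(sm$n_compound, sum(!is.na(loci$compound_group)))
  expect_equal(sm$freq_kb_per_ssr,
               round(sum(sim$tx$length) / sm$n_ssrs / 1000, 1))
  # empty input
  sm0 <- summarize_ssrs(detect_ssrs_transcriptome(make_tx(2, 60)), make_tx(2, 60))
  expect_equal(sm0$n_ssrs, 0L)
  expect_equal(sm0$n_containing, 0L)
})

test_that("planting asserts detectability and exact round-trip", {
  set.seed(31)
  base <- paste(sample(c("A", "C", "G", "T"), 400, replace = TRUE),
                collapse = "")
  base <- .scrub_ssrs(base)
  pl <- plant_ssr(base, "AG", 6L, at = 100L)
  expect_equal(pl$start, 100L)
  expect_equal(pl$end, 111L)
  d <- detect_ssrs(pl$sequence)
  expect_equal(nrow(d), 1L)
  expect_equal(c(d$start, d$end, d$motif), c("100", "111", "AG"))
  pl3 <- plant_ssr(base, "AAG", 5L, at = 150L)
  d3 <- detect_ssrs(pl3$sequence)
  expect_equal(d3$motif, "AAG")
  expect_equal(d3$n_repeats, 5L)
  expect_error(plant_ssr(base, "AG", 5L, at = 100L), "below the detection")
  expect_error(plant_ssr(base, "ATAT", 5L, at = 100L), "primitive")
})
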