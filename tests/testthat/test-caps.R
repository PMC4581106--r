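enz <- load_enzyme_table()
enz_row <- function(name) enz[enz$name == name, ]

test_that("recognition-site scanning finds literal and nested sites", {
  expect_equal(scan_sites("TTGAATTCAA", enz_row("EcoRI")), 3L)
  expect_equal(scan_sites("GAGCTC", enz_row("SacI")), 1L)
  # every SacI site contains an AluI site one base in
  expect_equal(scan_sites("GAGCTC", enz_row("AluI")), 2L)
  expect_equal(scan_sites("AAAA", enz_row("EcoRI")), integer(0))
  # overlapping matches are all reported
  expect_equal(scan_sites("GATCGATC", enz_row("DpnII")), c(1L, 5L))
  # degenerate recognition (HincII GTYRAC)
  expect_equal(scan_sites("AGTCAACA", enz_row("HincII")), 2L)
  expect_equal(scan_sites("AGTTGACA", enz_row("HincII")), 2L)
})

test_that("differential enzymes require a match covering the SNP", {
  # ...TTGAATTCTT... with the SNP at the EcoRI A2: ref window has the
  # site, alt destroys it
  seq <- paste0(strrep("TC", 20), "TTGAATTCTT", strrep("CA", 20))
  pos <- 40L + 5L                       # the first A of GAATTC is pos 43
  tx <- transcriptome("t1", seq)
  expect_equal(substr(seq, pos, pos), "A")
  p <- make_panel("t1", pos, "A", "G")
  d <- differential_enzymes(p, 1L, tx, enz)
  expect_true(any(d$enzyme == "EcoRI" & d$allele_cut == "REF"))

  # GAGCT[C/A]: SacI diagnostic, AluI not reported because its AGCT match
  # does not cover the SNP
  seq2 <- paste0(strrep("TT", 15), "GAGCTC", strrep("TT", 15))
  pos2 <- 36L
  tx2 <- transcriptome("t2", seq2)
  expect_equal(substr(seq2, pos2, pos2), "C")
  p2 <- make_panel("t2", pos2, "C", "A")
  d2 <- differential_enzymes(p2, 1L, tx2, enz)
  expect_true(any(d2$enzyme == "SacI" & d2$allele_cut == "REF"))
  expect_false("AluI" %in% d2$enzyme)

  # a context matching no enzyme in either allele
  seq3 <- strrep("AC", 40)
  tx3 <- transcriptome("t3", seq3)
  p3 <- make_panel("t3", 41L, "A", "T")
  expect_equal(nrow(differential_enzymes(p3, 1L, tx3, enz)), 0L)
})

test_that("swapping ref and alt swaps every allele_cut label", {
  sim <- small_sim()
  pass <- run_filter_pipeline(sim$panel, sim$tx,
                              filter_config(reference_sample = "A"))$passing
  idx <- which(is_biallelic(pass))[1:40]
  for (i in idx) {
    d <- differential_enzymes(pass, i, sim$tx, enz)
    if (!nrow(d)) next
    swapped <- pass
    r <- swapped$sites$ref[i]
    swapped$sites$ref[i] <- swapped$sites$alt[i]
    swapped$sites$alt[i] <- r
    # the sequence carries the original ref, so patch a transcriptome copy
    tx2 <- sim$tx
    t_i <- match(swapped$sites$transcript_id[i], tx2$id)
    substr(tx2$sequence[t_i], swapped$sites$pos[i],
           swapped$sites$pos[i]) <- swapped$sites$ref[i]
    d2 <- differential_enzymes(swapped, i, tx2, enz)
    expect_setequal(paste(d$enzyme, ifelse(d$allele_cut == "REF", "ALT",
                                           "REF")),
                    paste(d2$enzyme, d2$allele_cut))
  }
})

test_that("differential caller agrees with the exhaustive oracle", {
  sim <- small_sim()
  pass <- run_filter_pipeline(sim$panel, sim$tx,
                              filter_config(reference_sample = "A"))$passing
  set.seed(21)
  idx <- sample(which(is_biallelic(pass)), 120L)
  n_diag <- 0L
  for (i in idx) {
    s <- pass$sites[i, ]
    t_i <- match(s$transcript_id, sim$tx$id)
    d <- differential_enzymes(pass, i, sim$tx, enz)
    o <- caps_oracle(sim$tx$sequence[t_i], s$pos, s$ref, s$alt, enz)
    expect_setequal(paste(d$enzyme, d$allele_cut),
                    paste(o$enzyme, o$allele_cut))
    n_diag <- n_diag + nrow(d)
  }
  expect_gt(n_diag, 0L)  # the comparison actually exercised diagnostics
})

test_that("digestion fragments partition the amplicon", {
  # one EcoRI site starting at position 100 in a 300 bp amplicon:
  # cut at 99 + 1 = 100 -> fragments 100 and 200
  amp <- paste0(strrep("C", 99), "GAATTC", strrep("C", 195))
  expect_equal(nchar(amp), 300L)
  expect_equal(digest_fragments(amp, enz_row("EcoRI")), c(100L, 200L))
  expect_equal(digest_fragments(strrep("C", 300), enz_row("EcoRI")), 300L)
  amp2 <- paste0(strrep("C", 50), "AGCT", strrep("C", 60), "AGCT",
                 strrep("C", 40))
  fr <- digest_fragments(amp2, enz_row("AluI"))
  expect_equal(length(fr), 3L)
  expect_equal(sum(fr), nchar(amp2))
  # a cut offset of 0 on a site at position 1 cuts nothing off
  expect_equal(digest_fragments(paste0("GATC", strrep("A", 20)),
                                enz_row("DpnII")), 24L)
})

test_that("marker design centres the SNP, sizes the amplicon, rejects edges", {
  sim <- small_sim()
  tc <- sim$truth$caps
  found <- 0L
  for (r in seq_len(nrow(tc))) {
    i <- which(sim$panel$sites$transcript_id == tc$transcript_id[r] &
                 sim$panel$sites$pos == tc$pos[r])
    mk <- design_caps_marker(sim$panel, i, sim$tx, enz)
    if (!is.null(mk$rejected)) next
    found <- found + 1L
    width <- mk$amplicon[["end"]] - mk$amplicon[["start"]] + 1L
    expect_gte(width, 200L)
    expect_lte(width, 400L)
    expect_gte(tc$pos[r], mk$amplicon[["start"]])
    expect_lte(tc$pos[r], mk$amplicon[["end"]])
    expect_true(any(mk$diagnostic$enzyme == tc$enzyme[r] &
                      mk$diagnostic$allele_cut == tc$allele_cut[r]))
    # fragment conservation for every ladder
    for (l in mk$ladders) {
      expect_equal(sum(l$ref), width)
      expect_equal(sum(l$alt), width)
      expect_false(identical(sort(l$ref), sort(l$alt)))
    }
  }
  expect_gt(found, 0L)

  # a SNP 50 bp from the transcript end cannot host a 200 bp amplicon
  seq <- paste0(strrep("GC", 20), strrep("AT", 20),
                "GAATTC", strrep("TA", 22))
  tx <- transcriptome("t1", seq)
  p <- make_panel("t1", 83L, substr(seq, 83, 83), "C")
  mk <- design_caps_marker(p, 1L, tx, enz)
  expect_equal(mk$rejected, "NO_AMPLICON")
})

test_that("scorability screen keeps well-separated ladders", {
  expect_gte(.ladder_separation(c(100, 200), 300), 20)
  expect_equal(.ladder_separation(c(150, 150), c(150, 150)), 0)
  expect_equal(.ladder_separation(c(100, 200), c(110, 190)), 10)
})

test_that("genome projection is affine and strand-aware", {
  blocks <- data.frame(transcript_id = "t1", t_start = 101L, t_end = 200L,
                       scaffold = "scf5", g_start = 5001L, g_end = 5100L,
                       strand = "+")
  pr <- project_to_genome("t1", 150L, blocks)
  expect_equal(pr$genome_pos, 5050L)
  expect_equal(pr$scaffold, "scf5")
  blocks$strand <- "-"
  expect_equal(project_to_genome("t1", 150L, blocks)$genome_pos, 5051L)
  expect_error(project_to_genome("t1", 250L, blocks), "UNMAPPED")
})
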