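test_that("region classification partitions the transcript by the ORF", {
  tx <- transcriptome("t1", strrep("ACGT", 125), orf_start = 101L,
                      orf_end = 400L)
  region_at <- function(pos)
    classify_region(make_panel("t1", pos, "A", "G"), tx)
  expect_equal(region_at(50L), "FIVE_UTR")
  expect_equal(region_at(100L), "FIVE_UTR")
  expect_equal(region_at(101L), "CDS")       # inclusive endpoints
  expect_equal(region_at(400L), "CDS")
  expect_equal(region_at(401L), "THREE_UTR")
  tx_no_orf <- transcriptome("t1", strrep("ACGT", 125))
  expect_equal(classify_region(make_panel("t1", 50L, "A", "G"), tx_no_orf),
               "UNKNOWN")
  expect_error(region_at(501L), "outside")

  # partition property: FIVE_UTR + CDS + THREE_UTR counts cover all sites
  pos <- seq(5L, 500L, by = 7L)
  r <- classify_region(make_panel("t1", pos, "A", "G"), tx)
  expect_equal(sum(r %in% c("FIVE_UTR", "CDS", "THREE_UTR")), length(pos))
})

test_that("substitution classes are symmetric with 2 of 6 transitions", {
  expect_equal(classify_substitution("A", "G"),
               data.frame(class = "A/G", is_transition = TRUE))
  expect_equal(classify_substitution("G", "A")$class, "A/G")
  expect_false(classify_substitution("A", "C")$is_transition)
  expect_error(classify_substitution("A", "A"), "differ")
  bases <- c("A", "C", "G", "T")
  pairs <- expand.grid(ref = bases, alt = bases,
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$ref != pairs$alt, ]
  cls <- classify_substitution(pairs$ref, pairs$alt)
  swapped <- classify_substitution(pairs$alt, pairs$ref)
  expect_identical(cls$class, swapped$class)
  expect_equal(length(unique(cls$class)), 6L)
  expect_equal(sum(unique(cls[cls$is_transition, "class"]) %in%
                     c("A/G", "C/T")), 2L)
})

test_that("zygosity maps genotype strings and validates allele indices", {
  expect_equal(zygosity_of(c("0/0", "0/1", "1/1", "./.", NA, "1/2")),
               c("HOM_REF", "HET", "HOM_ALT", "MISSING", "MISSING", "HET"))
  expect_error(zygosity_of("0/2", n_alleles = 2L), "out of range")
  expect_equal(zygosity_of("0/2", n_alleles = 3L), "HET")
})

test_that("pairwise status obeys the strict depth rule and is symmetric", {
  p <- make_panel("t1", c(10L, 20L, 30L, 40L), "A", "G",
                  gt = rbind(c("0/0", "1/1", "0/0"),
                             c("0/0", "0/0", "0/0"),
                             c("0/0", "1/1", "0/0"),
                             c("0/0", "0/1", "0/0")),
                  dp = rbind(c(20L, 15L, 20L),
                             c(20L, 40L, 20L),
                             c(20L, 10L, 20L),
                             c(20L, 30L, 20L)))
  st <- pair_status(p, "A", "B")
  expect_equal(st, c("POLY_HOM", "MONOMORPHIC", "INSUFFICIENT_DEPTH",
                     "POLY_OTHER"))
  expect_identical(pair_status(p, "B", "A"), st)
  expect_error(pair_status(p, "A", "nope"), "unknown sample")
})

test_that("minor-allele read-count frequency pools AD across samples", {
  p <- make_panel("t1", 10L, "A", "G",
                  ad = matrix(c("25,25", "15,15", "10,10"), 1))
  expect_equal(minor_allele_rc_freq(p), 0.5)
  p <- make_panel("t1", 10L, "A", "G",
                  ad = matrix(c("40,10", "20,10", "10,10"), 1))
  expect_equal(minor_allele_rc_freq(p), 0.3)
  # triallelic: the single least common observed allele
  sites <- data.frame(transcript_id = "t1", pos = 10L, ref = "A",
                      alt = "G,T")
  p3 <- snp_panel(sites, matrix(c("0/1", "1/2", "0/0"), 1),
                  matrix(100L, 1, 3),
                  matrix(c("30,20,0", "20,10,10", "10,0,0"), 1),
                  c("A", "B", "C"))
  expect_equal(minor_allele_rc_freq(p3), 0.1)
  # zero-count alleles are ignored; no evidence at all errors
  p0 <- make_panel("t1", 10L, "A", "G", ad = matrix(NA_character_, 1, 3))
  expect_error(minor_allele_rc_freq(p0), "no allele-count evidence")
  expect_true(is.na(minor_allele_rc_freq(p0, strict = FALSE)))
})

test_that("IUPAC masking replaces exactly the variant positions", {
  tx <- transcriptome("t1", "AAAAAAAAAAAA")
  p <- make_panel("t1", c(3L, 7L), "A", c("G", "C"))
  expect_equal(mask_variants(tx, "t1", p), "AARAAAMAAAAA")
  sites <- data.frame(transcript_id = "t1", pos = 5L, ref = "A", alt = "C,T")
  p2 <- snp_panel(sites, matrix("0/1", 1, 3), matrix(100L, 1, 3),
                  matrix("50,25,25", 1, 3), c("A", "B", "C"))
  expect_equal(mask_variants(tx, "t1", p2), "AAAAHAAAAAAA")
  expect_equal(mask_variants(tx, "t1", p[integer(0)]), tx$sequence)
  p_bad <- make_panel("t1", 3L, "G", "C")
  expect_error(mask_variants(tx, "t1", p_bad), "position 3")

  # masking then expanding each code recovers ref and alts
  masked <- mask_variants(tx, "t1", p)
  for (i in 1:2) {
    set <- iupac_expand(substr(masked, p$sites$pos[i], p$sites$pos[i]))
    expect_setequal(set, c(p$sites$ref[i], p$sites$alt[i]))
  }
})

test_that("classification recovers planted regions and classes exactly", {
  sim <- small_sim()
  flt <- run_filter_pipeline(sim$panel, sim$tx,
                             filter_config(reference_sample = "A"))
  cls <- classify_panel(flt$passing, sim$tx)
  tr <- sim$truth$snps[sim$truth$snps$kind != "violation", ]
  key <- function(d) paste(d$transcript_id, d$pos)
  m <- match(key(cls), key(tr))
  expect_false(anyNA(m))
  expect_identical(cls$region, tr$region[m])
  expect_identical(cls$class, tr$class[m])
  expect_identical(cls$is_transition, tr$is_transition[m])
})
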