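test_that("round-1 thresholds act on the published boundaries", {
  clean <- list(qual = 100, fs = 0, qd = 20, mq0f = 0, dp_site = 50)
  one_site <- function(...) {
    args <- utils::modifyList(clean, list(...))
    make_panel("t1", 100L, "A", "G", qual = args$qual, fs = args$fs,
               qd = args$qd, mq0f = args$mq0f, dp_site = args$dp_site)
  }
  verdict <- function(panel) filter_round1(panel)$verdicts
  expect_true(verdict(one_site())$passed)
  expect_equal(verdict(one_site(fs = 75))$reasons, "STRAND_BIAS")
  expect_true(verdict(one_site(fs = 60))$passed)          # > 60, not >=
  expect_equal(verdict(one_site(qual = 10.5))$reasons, "LOW_QUAL")
  expect_true(verdict(one_site(qual = 11))$passed)
  expect_equal(verdict(one_site(qd = 1.9))$reasons, "LOW_QD")
  expect_equal(verdict(one_site(mq0f = 0.11))$reasons, "MQ0")
  expect_true(verdict(one_site(mq0f = 0.10))$passed)
  expect_equal(verdict(one_site(dp_site = 10))$reasons, "LOW_DEPTH")
  expect_true(verdict(one_site(dp_site = 11))$passed)
})

test_that("absent annotations pass instead of failing", {
  p <- make_panel("t1", 100L, "A", "G", qual = NA, fs = NA, qd = NA,
                  mq0f = NA, dp_site = NA)
  expect_true(filter_round1(p)$verdicts$passed)
})

test_that("pooled minor-allele read-count frequency drives LOW_MAF", {
  ad <- matrix(c("199,1", "199,1", "199,1"), 1)
  p <- make_panel("t1", 100L, "A", "G", gt = matrix("0/0", 1, 3),
                  ad = ad, dp_site = 600)
  expect_equal(filter_round1(p)$verdicts$reasons, "LOW_MAF")
  ad2 <- matrix(c("190,10", "190,10", "190,10"), 1)
  p2 <- make_panel("t1", 100L, "A", "G", gt = matrix("0/0", 1, 3),
                   ad = ad2, dp_site = 600)
  expect_true(filter_round1(p2)$verdicts$passed)
})

test_that("cluster rule: worked spans and brute-force equivalence", {
  p <- make_panel("t1", c(100L, 150L, 199L), "A", "G")
  expect_equal(remove_clusters(p), c(TRUE, TRUE, TRUE))     # span 100
  p <- make_panel("t1", c(100L, 150L, 201L), "A", "G")
  expect_equal(remove_clusters(p), c(FALSE, FALSE, FALSE))  # span 102
  p <- make_panel("t1", c(100L, 150L), "A", "G")
  expect_equal(remove_clusters(p), c(FALSE, FALSE))         # below size

  # property: agreement with the exhaustive all-triples oracle
  set.seed(5)
  for (r in 1:20) {
    n <- sample(20:120, 1)
    tids <- sort(sample(paste0("t", 1:4), n, replace = TRUE))
    pos <- unlist(lapply(split(seq_len(n), tids), function(idx)
      sort(sample.int(1500, length(idx)))), use.names = FALSE)
    p <- make_panel(tids, pos, "A", "G")
    expect_equal(remove_clusters(p), cluster_oracle(tids, pos))
  }
})

test_that("unsorted input is rejected", {
  sites <- data.frame(transcript_id = "t1", pos = c(200L, 100L),
                      ref = "A", alt = "G")
  p <- snp_panel(sites, matrix("0/1", 2, 3), matrix(100L, 2, 3),
                 matrix("50,50", 2, 3), c("A", "B", "C"))
  expect_error(filter_round1(p), "sorted")
})

test_that("round-2 edge, boundary, depth and reference-het rules", {
  tx <- transcriptome("t1", strrep("ACGT", 125), orf_start = 101L,
                      orf_end = 400L, boundaries = list(250L))
  cfg <- filter_config(reference_sample = "A")
  run1 <- function(pos, ...) {
    p <- make_panel("t1", pos, "A", "G", ...)
    filter_round2(p, tx, cfg)$verdicts
  }
  expect_equal(run1(30L)$reasons, "EDGE")
  expect_true(!grepl("EDGE", run1(31L)$reasons))
  expect_equal(run1(471L)$reasons, "EDGE")      # pos > 500 - 30
  expect_equal(run1(220L)$reasons, "BOUNDARY")  # |220 - 250| <= 30
  expect_equal(run1(280L)$reasons, "BOUNDARY")
  expect_true(run1(281L)$passed)
  expect_equal(run1(100L, dp = matrix(c(50L, 9L, 8L), 1))$reasons,
               "INSUFFICIENT_DEEP_GENOTYPES")
  # depth exactly 10 does not count as deep (strictly greater than 10)
  expect_equal(run1(100L, dp = matrix(c(50L, 10L, 10L), 1))$reasons,
               "INSUFFICIENT_DEEP_GENOTYPES")
  expect_equal(run1(100L, gt = matrix(c("0/1", "0/0", "1/1"), 1))$reasons,
               "REF_HET")
  expect_error(filter_round2(make_panel("nope", 100L, "A", "G"), tx, cfg),
               "unknown transcript id: nope")
})

test_that("pipeline composes rounds, reports counts, and is idempotent", {
  sim <- small_sim()
  cfg <- filter_config(reference_sample = "A")
  res <- run_filter_pipeline(sim$panel, sim$tx, cfg)
  expect_equal(nrow(res$verdicts), n_sites(sim$panel))
  expect_equal(res$report[["n_pass"]], sum(res$verdicts$passed))
  # every planted violation fails with exactly its planted reason
  tr <- sim$truth$snps
  viol <- tr$kind == "violation"
  expect_true(all(!res$verdicts$passed[viol]))
  expect_identical(res$verdicts$reasons[viol], tr$reason[viol])
  expect_true(all(res$verdicts$passed[!viol]))
  # per-reason counts equal the planted truth table exactly
  exp_counts <- table(sim$truth$violations$reason)
  expect_equal(as.integer(res$report[names(exp_counts)]),
               as.integer(exp_counts))
  # idempotence
  res2 <- run_filter_pipeline(res$passing, sim$tx, cfg)
  expect_equal(n_sites(res2$passing), n_sites(res$passing))
  expect_true(all(res2$verdicts$passed))
})

test_that("empty input yields an empty pass set and zero-count report", {
  sim <- small_sim()
  empty <- sim$panel[integer(0)]
  res <- run_filter_pipeline(empty, sim$tx,
                             filter_config(reference_sample = "A"))
  expect_equal(n_sites(res$passing), 0L)
  expect_equal(res$report[["n_input"]], 0L)
  expect_true(all(res$report == 0L))
})

test_that("relaxing any single threshold never shrinks the passing set", {
  sim <- small_sim()
  base_cfg <- filter_config(reference_sample = "A")
  base <- run_filter_pipeline(sim$panel, sim$tx, base_cfg)
  key <- function(res) paste(res$passing$sites$transcript_id,
                             res$passing$sites$pos)
  relaxed <- list(
    filter_config(reference_sample = "A", max_fs = 120),
    filter_config(reference_sample = "A", max_mq0_fraction = 0.5),
    filter_config(reference_sample = "A", min_maf = 0),
    filter_config(reference_sample = "A", min_qual = 1),
    filter_config(reference_sample = "A", min_total_depth = 1),
    filter_config(reference_sample = "A", min_qd = 0),
    filter_config(reference_sample = "A", edge_exclusion_bp = 5),
    filter_config(reference_sample = "A", boundary_exclusion_bp = 5),
    filter_config(reference_sample = "A", min_deep_genotypes = 1),
    filter_config(reference_sample = "A", cluster_window_bp = 10))
  for (cfg in relaxed) {
    res <- run_filter_pipeline(sim$panel, sim$tx, cfg)
    expect_true(all(key(base) %in% key(res)))
  }
})
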