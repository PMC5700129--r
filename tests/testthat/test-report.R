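test_that("summary arithmetic matches the defined ratios and percentages", {
  calls <- data.frame(label = c("HDR", "NHEJ", "WT"),
                      count = c(40L, 10L, 950L), stringsAsFactors = FALSE)
  s <- summarize_sample(calls)
  expect_equal(s$pct_hdr, 4.0)
  expect_equal(s$hdr_indel_ratio, 4.0)
  expect_identical(s$n_target, 1000L)

  # all-WT sample: zero HDR, undefined ratio
  s2 <- summarize_sample(data.frame(label = "WT", count = 500L))
  expect_equal(s2$pct_hdr, 0)
  expect_false(s2$ratio_defined)
  expect_true(is.na(s2$hdr_indel_ratio))

  # pseudocount mode keeps the ratio finite
  s3 <- summarize_sample(data.frame(label = "HDR", count = 3L),
                         pseudocount = TRUE)
  expect_equal(s3$hdr_indel_ratio, 3.5 / 0.5)

  # no target reads at all: flagged, percentages undefined
  s4 <- summarize_sample(data.frame(label = character(), count = integer()))
  expect_true(is.na(s4$pct_hdr))
  expect_false(s4$ratio_defined)
})

test_that("ambiguous reads dilute the denominator but join no numerator", {
  calls <- data.frame(label = c("HDR", "NHEJ", "WT", "AMBIGUOUS"),
                      count = c(10L, 10L, 70L, 10L), stringsAsFactors = FALSE)
  s <- summarize_sample(calls)
  expect_equal(s$pct_hdr, 10)
  expect_equal(s$pct_nhej, 10)
  expect_identical(s$reads_wt + s$reads_hdr + s$reads_nhej +
                     s$reads_ambiguous, s$n_target)
})

test_that("clone-mode genotype labels flow through the same statistic", {
  cl <- clone_calls(c(rep("HDR", 8), rep("NHEJ", 8), rep("WT", 18)))
  s <- summarize_sample(cl, sample_id = "sorted_clones")
  expect_identical(s$n_target, 34L)
  expect_equal(s$hdr_indel_ratio, 1.0)
  expect_error(clone_calls(c("HDR", "INDEL")))
})

test_that("fold enrichment is the ratio of ratios with flag propagation", {
  mk <- function(h, n, w = 100L, id = "s")
    summarize_sample(data.frame(label = c("HDR", "NHEJ", "WT"),
                                count = c(h, n, w)), sample_id = id)
  expect_equal(compare_conditions(mk(10L, 10L), mk(2L, 20L))$fold_enrichment,
               10)
  same <- mk(7L, 13L)
  expect_equal(compare_conditions(same, same)$fold_enrichment, 1.0)
  undef <- summarize_sample(data.frame(label = "WT", count = 100L))
  cc <- compare_conditions(mk(10L, 10L), undef)
  expect_false(cc$defined)
  expect_true(is.na(cc$fold_enrichment))
  # control ratio of zero is flagged, not infinite
  cc2 <- compare_conditions(mk(10L, 10L), mk(0L, 20L))
  expect_false(cc2$defined)
})

test_that("summaries are invariant under permutation of input reads", {
  cfg <- simulation_config(fix_switch3$locus, fix_switch3$donor,
                           n_reads = 1200, p_hdr = 0.1, p_nhej = 0.2,
                           subst_error_rate = 0.002, seed = 47)
  sim <- simulate_sample(cfg)
  run_once <- function(seqs) {
    targets <- identify_targets(
      filter_low_frequency(collapse_reads(seqs), 2), fix_switch3$locus)
    calls <- classify_sample(targets, fix_switch3$locus, fix_switch3$donor)
    summarize_sample(calls)
  }
  s1 <- run_once(sim$sequences)
  set.seed(1)
  s2 <- run_once(sample(sim$sequences))
  expect_equal(s1$pct_hdr, s2$pct_hdr)
  expect_equal(s1$pct_nhej, s2$pct_nhej)
  expect_identical(s1$reads_wt, s2$reads_wt)
})

test_that("run_pipeline writes consistent reports and handles empty input", {
  dir <- withr::local_tempdir()
  loc <- fix_switch3$locus; don <- fix_switch3$donor
  fq_a <- file.path(dir, "cond.fastq")
  fq_b <- file.path(dir, "ctrl.fastq")
  simulate_sample(simulation_config(loc, don, n_reads = 1500, p_hdr = 0.10,
                                    p_nhej = 0.10, subst_error_rate = 0,
                                    seed = 51), fastq_path = fq_a)
  simulate_sample(simulation_config(loc, don, n_reads = 1500, p_hdr = 0.02,
                                    p_nhej = 0.20, subst_error_rate = 0,
                                    seed = 52), fastq_path = fq_b)
  res <- run_pipeline(c(cond = fq_a, ctrl = fq_b),
                      list(locus = loc, donor = don),
                      min_count = 1L, out_dir = dir, control = "ctrl")
  expect_named(res$summaries, c("cond", "ctrl"))
  expect_true(file.exists(file.path(dir, "cond_alleles.tsv")))
  expect_true(file.exists(file.path(dir, "cond_summary.json")))
  expect_true(file.exists(file.path(dir, "comparison.tsv")))
  js <- jsonlite::read_json(file.path(dir, "cond_summary.json"))
  expect_identical(js$n_target, res$summaries$cond$n_target)
  expect_identical(nrow(res$comparisons), 1L)
  expect_true(res$comparisons$fold_enrichment > 1)

  # empty FASTQ: valid all-zero summary with undefined ratios
  fq_e <- file.path(dir, "empty.fastq")
  file.create(fq_e)
  res_e <- run_pipeline(c(empty = fq_e), list(locus = loc, donor = don))
  expect_identical(res_e$summaries$empty$n_target, 0L)
  expect_false(res_e$summaries$empty$ratio_defined)

  # missing files and missing donor are named errors
  expect_error(run_pipeline(c(x = file.path(dir, "nope.fastq")),
                            list(locus = loc, donor = don)), "not found")
  expect_error(run_pipeline(c(cond = fq_a), list(locus = loc, donor = NULL)),
               class = "locus_error")
})

test_that("repeated pipeline runs produce byte-identical reports", {
  dir1 <- withr::local_tempdir(); dir2 <- withr::local_tempdir()
  loc <- fix_switch3$locus; don <- fix_switch3$donor
  fq <- file.path(dir1, "s.fastq")
  simulate_sample(simulation_config(loc, don, n_reads = 1000,
                                    subst_error_rate = 0.002, seed = 53),
                  fastq_path = fq)
  run_pipeline(c(s = fq), list(locus = loc, donor = don),
               out_dir = file.path(dir1, "out"))
  run_pipeline(c(s = fq), list(locus = loc, donor = don),
               out_dir = file.path(dir2, "out"))
  for (f in c("s_alleles.tsv", "s_summary.json")) {
    expect_identical(unname(tools::md5sum(file.path(dir1, "out", f))),
                     unname(tools::md5sum(file.path(dir2, "out", f))))
  }
})
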