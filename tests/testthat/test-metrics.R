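test_that("indel_size is the allele length difference", {
  df <- data.frame(ref = c("TATC", "A", "A", "AC"),
                   alt = c("T", "ATTC", "G", "GT"))
  expect_equal(indel_size(df), c(3L, 3L, 0L, 0L))
})

test_that("sizes map to the printed report bins", {
  b <- size_binning()
  expect_equal(b$labels, c("1-10", "11-20", "21-50", ">50"))
  expect_equal(assign_bin(c(1, 10, 11, 20, 21, 50, 51, 200), b),
               c("1-10", "1-10", "11-20", "11-20", "21-50", "21-50",
                 ">50", ">50"))
  expect_error(assign_bin(0, b), "size")
})

test_that("compute_metrics reproduces published-style rows exactly", {
  r1 <- compute_metrics(data.frame(tp_query = 7781, fp = 4, fn = 22,
                                   total_bases = 13728555))
  expect_equal(floor(r1$precision * 100 + 0.5) / 100, 99.95)
  expect_equal(floor(r1$recall * 100 + 0.5) / 100, 99.72)
  expect_equal(r1$tn, 13720748)
  r2 <- compute_metrics(data.frame(tp_query = 148, fp = 12, fn = 9,
                                   total_bases = 12626866))
  expect_equal(floor(r2$precision * 100 + 0.5) / 100, 92.50)
  expect_equal(floor(r2$recall * 100 + 0.5) / 100, 94.27)
  expect_equal(r2$tn, 12626697)
})

test_that("undefined ratios are NA, never zero or one hundred", {
  r <- compute_metrics(data.frame(tp_query = 0, fp = 0, fn = 0,
                                  total_bases = 100))
  expect_true(is.na(r$precision))
  expect_true(is.na(r$recall))
  expect_equal(r$tn, 100)
  expect_equal(r$npa, 100)
})

test_that("counts exceeding the region size raise an inconsistency error", {
  expect_error(compute_metrics(data.frame(tp_query = 80, fp = 30, fn = 0,
                                          total_bases = 100)),
               "negative")
})

test_that("metrics match an independent one-line oracle at full precision", {
  set.seed(51)
  for (rep in 1:50) {
    tp <- sample(0:500, 1); fp <- sample(0:50, 1); fn <- sample(0:50, 1)
    tb <- sample(10000:100000, 1)
    r <- compute_metrics(data.frame(tp_query = tp, fp = fp, fn = fn,
                                    total_bases = tb))
    if (tp + fp > 0) expect_identical(r$precision, 100 * tp / (tp + fp))
    if (tp + fn > 0) expect_identical(r$recall, 100 * tp / (tp + fn))
    expect_identical(r$tn, tb - (tp + fp + fn))
    expect_identical(r$npa, 100 * r$tn / (r$tn + fp))
  }
})

test_that("metrics are scale-free and NPA is monotone in FP", {
  base <- data.frame(tp_query = 40, fp = 10, fn = 5, total_bases = 1e6)
  r1 <- compute_metrics(base)
  r2 <- compute_metrics(transform(base, tp_query = tp_query * 7, fp = fp * 7,
                                  fn = fn * 7))
  expect_equal(r1$precision, r2$precision)
  expect_equal(r1$recall, r2$recall)
  npa <- vapply(c(0, 5, 50, 500), function(fp)
    compute_metrics(data.frame(tp_query = 40, fp = fp, fn = 5,
                               total_bases = 1e6))$npa, 0)
  expect_true(all(diff(npa) <= 0))
})

test_that("merged bins sum counts and recompute (never average) percentages", {
  per_bin <- data.frame(size_bin = c("1-10", "11-20"),
                        tp_truth = c(136, 9), tp_query = c(136, 9),
                        fp = c(12, 0), fn = c(9, 0),
                        truth_total = c(145, 9),
                        total_bases = 12626866)
  m <- merge_bins(per_bin, list("1-20" = c("1-10", "11-20")))
  expect_equal(c(m$tp_query, m$fp, m$fn), c(145, 12, 9))
  expect_equal(floor(m$precision * 100 + 0.5) / 100, 92.36)  # 145/157
  expect_false(isTRUE(all.equal(m$precision, mean(c(100 * 136 / 148, 100)))))
  # single-bin merge is the identity on counts
  one <- merge_bins(per_bin, list("1-10" = "1-10"))
  expect_equal(one$tp_query, 136)
  expect_error(merge_bins(per_bin, list(x = "21-50")),
               class = "varbench_config_error")
})

test_that("per-bin tallies sum to the all-InDels stratum", {
  fx <- generate_fixture(fixture_config(seed = 13), tempfile())
  ref <- ref_accessor(fx$paths$reference)
  cl <- classify(read_vcf(fx$paths$truth), read_vcf(fx$paths$query),
                 read_bed(fx$paths$roi), ref,
                 confident = read_bed(fx$paths$confident))
  ind <- cl$counts[cl$counts$variant_type == "INDEL", ]
  bins <- ind[ind$size_bin != "ALL", ]
  all_row <- ind[ind$size_bin == "ALL", ]
  for (col in c("tp_truth", "tp_query", "fp", "fn"))
    expect_equal(sum(bins[[col]]), all_row[[col]])
})

test_that("the spectrum histogram equals the per-bin confusion tallies", {
  fx <- generate_fixture(fixture_config(seed = 14), tempfile())
  ref <- ref_accessor(fx$paths$reference)
  cl <- classify(read_vcf(fx$paths$truth), read_vcf(fx$paths$query),
                 read_bed(fx$paths$roi), ref,
                 confident = read_bed(fx$paths$confident))
  h <- spectrum_histogram(cl$classified)
  ind <- cl$counts[cl$counts$variant_type == "INDEL" &
                     cl$counts$size_bin != "ALL", ]
  expect_equal(h$TP, ind$tp_query, ignore_attr = TRUE)
  expect_equal(h$FP, ind$fp, ignore_attr = TRUE)
  expect_equal(h$FN, ind$fn, ignore_attr = TRUE)
  # a planted 25 bp insertion lands in the 21-50 bin
  cfg <- fixture_config(seed = 15, n_snp_tp = 2L,
                        n_indel_tp = c("21-50" = 1L), n_snp_fp = 0L,
                        n_indel_fp = 0L, n_snp_fn = 0L, n_indel_fn = 0L)
  fx2 <- generate_fixture(cfg, tempfile())
  cl2 <- classify(read_vcf(fx2$paths$truth), read_vcf(fx2$paths$query),
                  read_bed(fx2$paths$roi), ref_accessor(fx2$paths$reference),
                  confident = read_bed(fx2$paths$confident))
  h2 <- spectrum_histogram(cl2$classified)
  expect_equal(h2$TP[h2$size_bin == "21-50"], 1L)
  # TSV and plot files are written when requested
  tsv <- tempfile(fileext = ".tsv"); pdf <- tempfile(fileext = ".pdf")
  spectrum_histogram(cl$classified, tsv = tsv, plot = pdf)
  expect_true(file.exists(tsv) && file.exists(pdf))
})
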