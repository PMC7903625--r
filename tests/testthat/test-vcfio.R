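test_that("read_vcf maps fields, sorts, and drops missing genotypes with a count", {
  p <- write_vcf_lines(c(vline("chr1", 200, "C", "T", "0/1"),
                         vline("chr1", 100, "A", "G", "0/1"),
                         vline("chr1", 150, "G", "C", "./.")))
  v <- suppressMessages(read_vcf(p, sample_id = "S1"))
  expect_equal(nrow(v), 2L)
  expect_equal(attr(v, "n_dropped"), 1L)
  expect_equal(v$pos, c(100L, 200L))  # (chrom, pos) sorted
  expect_equal(v[1, c("chrom", "ref", "alt", "gt1", "gt2")],
               data.frame(chrom = "chr1", ref = "A", alt = "G",
                          gt1 = 0L, gt2 = 1L),
               ignore_attr = TRUE)
})

test_that("a clinical deletion row parses to the expected record", {
  p <- write_vcf_lines(vline("15", 91310152, "TATC", "T", "0/1"))
  v <- read_vcf(p)
  expect_equal(v$pos, 91310152L)
  expect_equal(v$ref, "TATC")
  expect_equal(v$alt, "T")
})

test_that("multi-allelic records pass through intact for later decomposition", {
  p <- write_vcf_lines(vline("chr1", 100, "A", "G,T", "1/2"))
  v <- read_vcf(p)
  expect_equal(v$alt, "G,T")
  expect_equal(c(v$gt1, v$gt2), c(1L, 2L))
})

test_that("read_vcf errors name malformed lines and absent samples", {
  bad <- tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.1", "#CHROM\tPOS", "chr1\tnotanumber\t.\tA"),
             bad)
  expect_error(read_vcf(bad), "line 3")
  p <- write_vcf_lines(paste(vline("chr1", 100, "A", "G", "0/1"), "0/1",
                             sep = "\t"),
                       samples = c("S1", "S2"))
  expect_error(read_vcf(p, sample_id = "S3"), "absent",
               class = "varbench_config_error")
  expect_error(read_vcf(p), "2 samples")
})

test_that("pass_only drops non-passing records", {
  p <- write_vcf_lines(c(vline("chr1", 100, "A", "G", "0/1"),
                         vline("chr1", 200, "C", "T", "0/1", filter = "LowQual")))
  expect_equal(nrow(read_vcf(p)), 2L)
  expect_equal(nrow(read_vcf(p, pass_only = TRUE)), 1L)
})

test_that("read_bed parses, merges and counts bases; errors carry line numbers", {
  b <- tempfile(fileext = ".bed")
  writeLines("chr1\t0\t10", b)
  expect_equal(total_bases(read_bed(b)), 10)
  writeLines(c("chr1\t0\t10", "chr1\t5\t20"), b)
  rs <- read_bed(b)
  expect_equal(as.data.frame(rs),
               data.frame(chrom = "chr1", start = 0L, end = 20L))
  writeLines(character(0), b)
  expect_equal(total_bases(read_bed(b)), 0)
  writeLines("chr1\t10\t5", b)
  expect_error(read_bed(b), "line 1")
  writeLines("chr1\tx\t5", b)
  expect_error(read_bed(b), "non-integer")
})

test_that("BED round-trip reproduces the merged interval set", {
  rs <- region_set(c("chr2", "chr1", "chr1"), c(100, 0, 5), c(200, 10, 30))
  p <- tempfile(fileext = ".bed")
  write_bed(rs, p)
  expect_equal(as.data.frame(read_bed(p)), as.data.frame(rs))
})

test_that("annotated VCF writes hap.py-style BD/BVT fields and round-trips", {
  cl <- data.frame(
    role = c("truth", "query", "truth"),
    chrom = "chr1", pos = c(100L, 100L, 300L),
    ref = c("A", "A", "CT"), alt = c("G", "G", "C"),
    gt1 = 0L, gt2 = 1L, phased = FALSE,
    label = c("TP", "TP", "FN"),
    variant_type = c("SNP", "SNP", "INDEL"),
    stringsAsFactors = FALSE)
  p <- tempfile(fileext = ".vcf")
  write_annotated_vcf(cl, p)
  lines <- readLines(p)
  expect_true(any(grepl("##FORMAT=<ID=BD", lines)))
  expect_true(any(grepl("##FORMAT=<ID=BVT", lines)))
  rec <- grep("^chr1\t100", lines, value = TRUE)
  expect_match(rec, "GT:BD:BVT\t0/1:TP:SNP\t0/1:TP:SNP")
  # FN-only truth record: query side has missing genotype and "." annotations
  rec2 <- grep("^chr1\t300", lines, value = TRUE)
  expect_match(rec2, "0/1:FN:INDEL\t\\./\\.:\\.:\\.$")
  back <- read_annotated_vcf(p)
  expect_equal(back[, c("role", "chrom", "pos", "ref", "alt", "label")],
               cl[order(cl$role, cl$pos), c("role", "chrom", "pos", "ref",
                                            "alt", "label")],
               ignore_attr = TRUE)
  # conformance: sorted records, declared FORMAT keys only
  body <- lines[!startsWith(lines, "#")]
  pos <- as.integer(vapply(strsplit(body, "\t"), `[`, "", 2))
  expect_equal(pos, sort(pos))
})

test_that("metrics table renders a clinical SNP row with expected counts", {
  rows <- compute_metrics(data.frame(
    tp_truth = 7436, tp_query = 7436, fp = 0, fn = 16,
    truth_total = 7452, total_bases = 12626866))
  rows$sample <- "NA24385"; rows$region <- "clinical"
  rows$variant_type <- "SNP"; rows$size_bin <- "ALL"
  p <- tempfile(fileext = ".tsv")
  write_metrics_table(rows, p)
  tab <- read.delim(p)
  expect_equal(tab$TP, 7436)
  expect_equal(tab$FN, 16)
  expect_equal(nrow(tab), 1L)  # header + one row
  expect_error(write_metrics_table(rows[0, ], p), "empty")
})

test_that("assertion tables parse and validate", {
  p <- tempfile(fileext = ".tsv")
  writeLines(c("sample\tchrom\tpos\tref\talt",
               "NA04408\t15\t91,310,152\tTATC\tT"), p)
  a <- read_assertions(p)
  expect_equal(a$pos, 91310152L)
  writeLines(c("sample\tchrom\tpos\tref\talt", "X\t1\t10\tQQ\tT"), p)
  expect_error(read_assertions(p), "row 1")
})
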