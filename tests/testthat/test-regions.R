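test_that("construction merges book-ended, contained and disjoint intervals", {
  expect_equal(total_bases(region_set("c", c(0, 10), c(10, 20))), 20)
  expect_equal(as.data.frame(region_set("c", c(0, 10), c(10, 20)))$end, 20L)
  expect_equal(total_bases(region_set("c", c(0, 5), c(10, 8))), 10)
  rs <- region_set("c", c(0, 10), c(5, 15))
  expect_equal(nrow(as.data.frame(rs)), 2L)
  expect_equal(total_bases(rs), 10)
})

test_that("region_pad extends, clamps at zero, and flank 0 is identity", {
  rs <- region_set("c", 100, 200)
  expect_equal(as.data.frame(region_pad(rs, 20)),
               data.frame(chrom = "c", start = 80L, end = 220L))
  expect_equal(as.data.frame(region_pad(region_set("c", 5, 10), 20)),
               data.frame(chrom = "c", start = 0L, end = 30L))
  expect_equal(as.data.frame(region_pad(rs, 0)), as.data.frame(rs))
  # clamp at contig length when known
  expect_equal(as.data.frame(region_pad(rs, 20, c(c = 210)))$end, 210L)
})

test_that("region_intersect is commutative, idempotent and bounded", {
  a <- region_set("c", 0, 10); b <- region_set("c", 5, 20)
  expect_equal(as.data.frame(region_intersect(a, b)),
               data.frame(chrom = "c", start = 5L, end = 10L))
  expect_equal(as.data.frame(region_intersect(b, a)),
               as.data.frame(region_intersect(a, b)))
  expect_equal(total_bases(region_intersect(region_set("c", 0, 5),
                                            region_set("c", 10, 15))), 0)
  expect_equal(as.data.frame(region_intersect(a, a)), as.data.frame(a))
})

test_that("total_bases is invariant under input permutation and re-merging", {
  set.seed(11)
  for (rep in 1:20) {
    n <- sample(1:12, 1)
    start <- sample(0:400, n)
    end <- start + sample(1:80, n, replace = TRUE)
    chrom <- sample(c("c1", "c2"), n, replace = TRUE)
    rs1 <- region_set(chrom, start, end)
    perm <- sample(n)
    rs2 <- region_set(chrom[perm], start[perm], end[perm])
    expect_equal(total_bases(rs1), total_bases(rs2))
    expect_equal(total_bases(region_merge(rs1, rs1)), total_bases(rs1))
  }
})

test_that("inclusion-exclusion holds on random region sets", {
  set.seed(12)
  for (rep in 1:25) {
    mk <- function() {
      n <- sample(1:8, 1)
      s <- sample(0:300, n)
      region_set(rep("c", n), s, s + sample(1:60, n, replace = TRUE))
    }
    a <- mk(); b <- mk()
    # independent per-base membership oracle
    base_set <- function(r) {
      df <- as.data.frame(r)
      out <- unlist(mapply(function(s, e) seq(s, e - 1L), df$start, df$end,
                           SIMPLIFY = FALSE))
      if (is.null(out)) integer(0) else as.integer(out)
    }
    expect_equal(total_bases(a), length(base_set(a)))
    expect_equal(total_bases(region_merge(a, b)) +
                   total_bases(region_intersect(a, b)),
                 total_bases(a) + total_bases(b))
    expect_equal(sort(base_set(region_intersect(a, b))),
                 sort(intersect(base_set(a), base_set(b))))
  }
})

test_that("padding then intersecting with a superset does not clip", {
  rs <- region_set("c", c(100, 300), c(200, 350))
  sup <- region_set("c", 0, 10000)
  padded <- region_pad(rs, 20)
  expect_equal(as.data.frame(region_intersect(padded, sup)),
               as.data.frame(padded))
})

test_that("build_clinical_roi selects exons containing pathogenic sites", {
  exons <- region_set(c("c", "c"), c(100, 300), c(200, 400))
  sites <- data.frame(chrom = "c", pos = 150)  # 1-based site
  roi <- build_clinical_roi(sites, exons, flank = 20)
  expect_equal(as.data.frame(roi),
               data.frame(chrom = "c", start = 80L, end = 220L))
  # boundary: 1-based site 101 is the first base of exon (100, 200)
  expect_equal(total_bases(build_clinical_roi(
    data.frame(chrom = "c", pos = 101), exons, flank = 0)), 100)
  # 1-based site 100 is *before* the exon starting at 0-based 100
  expect_warning(
    empty <- build_clinical_roi(data.frame(chrom = "c", pos = 100),
                                region_set("c", 100, 200), flank = 0),
    "empty")
  expect_equal(total_bases(empty), 0)
  # no sites: deep-intronic only
  deep <- region_set("c", 1000, 1100)
  expect_equal(as.data.frame(build_clinical_roi(
    data.frame(chrom = character(), pos = integer()), exons,
    deep_intronic = deep)), as.data.frame(deep))
  # site in two overlapping exons: one merged padded interval
  ov <- region_set(c("c", "c"), c(100, 150), c(200, 260))
  expect_equal(nrow(as.data.frame(build_clinical_roi(
    data.frame(chrom = "c", pos = 160), ov, flank = 20))), 1L)
})
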