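mk <- function(pos, ref, alt, gt1 = 0L, gt2 = 1L, phased = FALSE) {
  data.frame(chrom = "chr1", pos = as.integer(pos), ref = ref, alt = alt,
             gt1 = as.integer(gt1), gt2 = as.integer(gt2), phased = phased,
             stringsAsFactors = FALSE)
}

test_that("clustering pairs nearby variants and separates distant ones", {
  vt <- function(df) variant_table(df$chrom, df$pos, df$ref, df$alt,
                                   df$gt1, df$gt2)
  cl <- cluster_variants(vt(mk(100, "A", "G")), vt(mk(100, "A", "G")))
  expect_length(cl, 1L)
  expect_equal(c(nrow(cl[[1]]$truth), nrow(cl[[1]]$query)), c(1L, 1L))
  # MNP at 5-6 and SNPs at 5 and 6 share footprints
  truth <- vt(mk(5, "AC", "GT"))
  query <- vt(rbind(mk(5, "A", "G"), mk(6, "C", "T")))
  cl <- cluster_variants(truth, query, window = 10L)
  expect_length(cl, 1L)
  expect_equal(nrow(cl[[1]]$query), 2L)
  # gap beyond the window splits
  both <- vt(rbind(mk(100, "A", "G"), mk(200, "C", "T")))
  expect_length(cluster_variants(both, both[0, ], window = 50L), 2L)
})

test_that("oversized clusters split at the largest gap deterministically", {
  pos <- c(seq(100, 106, by = 2), seq(140, 146, by = 2), 120)
  df <- mk(sort(pos), "A", "G")
  df$ref <- "A"; df$alt <- "G"
  vt <- variant_table(df$chrom, df$pos, df$ref, df$alt, df$gt1, df$gt2)
  cl <- cluster_variants(vt, vt[0, ], window = 30L, max_cluster_size = 4L)
  expect_true(length(cl) >= 2L)
  expect_true(all(vapply(cl, function(c) nrow(c$truth) <= 4L, TRUE)))
  expect_true(any(vapply(cl, `[[`, TRUE, "flagged")))
})

test_that("haplotype spellings enumerate phase assignments", {
  ref <- toy_ref("ATTG")
  # hom deletion TT->T: no phase freedom, one pair
  s <- haplotype_spellings(mk(2, "TT", "T", 1L, 1L), "chr1", 1L, 4L, ref)
  expect_equal(s$pairs, "ATG|ATG")
  # two unphased het SNPs: cis and trans give two distinct pairs
  ref2 <- toy_ref("ACAC")
  mem <- rbind(mk(1, "A", "G"), mk(3, "A", "T"))
  s2 <- haplotype_spellings(mem, "chr1", 1L, 4L, ref2)
  expect_length(s2$pairs, 2L)
  expect_setequal(s2$pairs, c(paste(sort(c("GCTC", "ACAC")), collapse = "|"),
                              paste(sort(c("GCAC", "ACTC")), collapse = "|")))
  # hom MNP equals two hom SNPs over the same span
  ref3 <- toy_ref("GACT")
  s_mnp <- haplotype_spellings(mk(2, "AC", "GT", 1L, 1L), "chr1", 1L, 4L, ref3)
  s_snp <- haplotype_spellings(rbind(mk(2, "A", "G", 1L, 1L),
                                     mk(3, "C", "T", 1L, 1L)),
                               "chr1", 1L, 4L, ref3)
  expect_equal(s_mnp$pairs, s_snp$pairs)
})

test_that("overlapping same-haplotype alleles mark the cluster inconsistent", {
  ref <- toy_ref("GACTG")
  mem <- rbind(mk(2, "ACT", "A", 1L, 1L), mk(3, "C", "G", 1L, 1L))
  s <- haplotype_spellings(mem, "chr1", 1L, 5L, ref)
  expect_true(s$inconsistent)
})

test_that("match_clusters applies haplotype equivalence then exact fallback", {
  ref <- toy_ref("GACTG")
  # truth hom MNP vs query two hom SNPs: all TP by spelling
  m <- match_clusters(mk(2, "AC", "GT", 1L, 1L),
                      rbind(mk(2, "A", "G", 1L, 1L), mk(3, "C", "T", 1L, 1L)),
                      ref)
  expect_equal(m$truth_labels, "TP")
  expect_equal(m$query_labels, c("TP", "TP"))
  # genotype mismatch: truth FN, query FP
  m2 <- match_clusters(mk(2, "A", "G", 1L, 1L), mk(2, "A", "G", 0L, 1L), ref)
  expect_equal(m2$truth_labels, "FN")
  expect_equal(m2$query_labels, "FP")
  # empty truth side: query FP
  m3 <- match_clusters(mk(2, "A", "G")[0, ], mk(2, "A", "G"), ref)
  expect_equal(m3$query_labels, "FP")
  m4 <- match_clusters(mk(2, "A", "G"), mk(2, "A", "G")[0, ], ref)
  expect_equal(m4$truth_labels, "FN")
})

test_that("matcher agrees with exhaustive phasing enumeration on small clusters", {
  set.seed(31)
  refstr <- paste(sample(c("A", "C", "G", "T"), 60, replace = TRUE),
                  collapse = "")
  ref <- toy_ref(refstr)
  chars <- strsplit(refstr, "")[[1]]
  n_checked <- 0L
  for (rep in 1:120) {
    truth <- random_cluster(40L, 4L, chars)
    query <- random_cluster(40L, 4L, chars)
    if (nrow(truth) == 0 || nrow(query) == 0) next
    span <- c(1L, 50L)
    m <- match_clusters(truth, query, ref, span = span)
    refspan <- substr(refstr, span[1], span[2])
    ot <- oracle_pair_set(truth, refspan, span[1])
    oq <- oracle_pair_set(query, refspan, span[1])
    equivalent <- length(intersect(ot, oq)) > 0
    all_tp <- all(m$truth_labels == "TP") && all(m$query_labels == "TP")
    expect_equal(all_tp, equivalent)
    n_checked <- n_checked + 1L
  }
  expect_gt(n_checked, 60L)
})

test_that("labels partition records and swapping roles swaps FP and FN", {
  set.seed(32)
  refstr <- paste(sample(c("A", "C", "G", "T"), 60, replace = TRUE),
                  collapse = "")
  ref <- toy_ref(refstr)
  chars <- strsplit(refstr, "")[[1]]
  for (rep in 1:40) {
    truth <- random_cluster(40L, 3L, chars)
    query <- random_cluster(40L, 3L, chars)
    m <- match_clusters(truth, query, ref, span = c(1L, 50L))
    expect_true(all(m$truth_labels %in% c("TP", "FN")))
    expect_true(all(m$query_labels %in% c("TP", "FP")))
    sw <- match_clusters(query, truth, ref, span = c(1L, 50L))
    expect_equal(sum(sw$truth_labels == "FN"), sum(m$query_labels == "FP"))
    expect_equal(sum(sw$query_labels == "FP"), sum(m$truth_labels == "FN"))
  }
})
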