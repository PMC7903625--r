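# shared helpers: tiny in-code fixtures and independent oracles

toy_ref <- function(seq, name = "chr1") {
  ref_accessor(setNames(toupper(seq), name))
}

# write a VCF from raw body lines (tab-joined), bypassing the package writer
write_vcf_lines <- function(body, samples = "S1", path = tempfile(fileext = ".vcf")) {
  header <- c("##fileformat=VCFv4.1",
              '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", samples), collapse = "\t"))
  writeLines(c(header, body), path)
  path
}

vline <- function(chrom, pos, ref, alt, gt, filter = "PASS") {
  paste(chrom, pos, ".", ref, alt, ".", filter, ".", "GT", gt, sep = "\t")
}

# independent haplotype spelling: per-base cell substitution, unlike the
# cursor-based splicing inside the package
oracle_apply <- function(refstr, span_start, mems) {
  cells <- strsplit(refstr, "")[[1]]
  if (nrow(mems)) {
    for (i in seq_len(nrow(mems))) {
      idx <- mems$pos[i] - span_start + 1L
      cells[idx] <- mems$alt[i]
      w <- nchar(mems$ref[i])
      if (w > 1L) cells[(idx + 1L):(idx + w - 1L)] <- ""
    }
  }
  paste(cells, collapse = "")
}

# exhaustive phasing enumeration of one side's unordered haplotype pairs
# (members assumed unphased with non-overlapping footprints)
oracle_pair_set <- function(mems, refstr, span_start) {
  hom <- mems$gt1 == 1L & mems$gt2 == 1L
  het <- which(!hom)
  if (length(het) == 0) {
    s <- oracle_apply(refstr, span_start, mems[hom, , drop = FALSE])
    return(paste(sort(c(s, s))[1], sort(c(s, s))[2], sep = "|"))
  }
  grids <- expand.grid(rep(list(c(1L, 2L)), length(het)))
  pairs <- character(0)
  for (g in seq_len(nrow(grids))) {
    asg <- unlist(grids[g, ])
    onA <- c(which(hom), het[asg == 1L])
    onB <- c(which(hom), het[asg == 2L])
    sA <- oracle_apply(refstr, span_start,
                       mems[sort(onA), , drop = FALSE])
    sB <- oracle_apply(refstr, span_start,
                       mems[sort(onB), , drop = FALSE])
    pairs <- c(pairs, paste(sort(c(sA, sB)), collapse = "|"))
  }
  sort(unique(pairs))
}

# random cluster of <= n_max variants with disjoint footprints on [1, len]
random_cluster <- function(len, n_max, ref_chars) {
  n <- sample(0:n_max, 1L)
  if (n == 0) {
    return(data.frame(chrom = character(), pos = integer(), ref = character(),
                      alt = character(), gt1 = integer(), gt2 = integer(),
                      phased = logical(), stringsAsFactors = FALSE))
  }
  rows <- list()
  taken_end <- 0L
  for (i in seq_len(n)) {
    p <- taken_end + sample(2:5, 1L)
    kind <- sample(c("snp", "del", "ins"), 1L)
    if (kind == "snp") {
      r <- ref_chars[p]; a <- sample(setdiff(c("A", "C", "G", "T"), r), 1L)
    } else if (kind == "del") {
      w <- sample(1:3, 1L)
      r <- paste(ref_chars[p:(p + w)], collapse = ""); a <- ref_chars[p]
    } else {
      r <- ref_chars[p]
      a <- paste(c(r, sample(c("A", "C", "G", "T"), sample(1:3, 1L),
                             replace = TRUE)), collapse = "")
    }
    if (p + nchar(r) - 1L > len - 2L) break
    hom <- sample(c(TRUE, FALSE), 1L)
    rows[[length(rows) + 1L]] <- data.frame(
      chrom = "chr1", pos = p, ref = r, alt = a,
      gt1 = if (hom) 1L else 0L, gt2 = 1L, phased = FALSE,
      stringsAsFactors = FALSE)
    taken_end <- p + nchar(r) - 1L
  }
  if (length(rows) == 0) return(random_cluster(len, 0L, ref_chars))
  do.call(rbind, rows)
}
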