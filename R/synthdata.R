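#' Configuration for a synthetic benchmarking fixture
#'
#' Describes a toy truth/query dataset with planted classification
#' structure: a random reference contig, a truth callset, and a query
#' callset equal to the truth minus designated false negatives, plus
#' planted false positives, with designated true positives optionally
#' re-represented (prefix padding, InDel shifts inside forced homopolymer
#' runs, MNP/SNP splits). Identical configuration and seed produce
#' byte-identical output files.
#'
#' Defaults are desk-scale: one 12 kb contig, 20 SNP and 8 InDel true
#' positives spread over the four reporting size bins, a handful of planted
#' errors, 30% homozygous calls. Planted variants are spaced at least
#' \code{spacing} bases apart (default 160: larger than the widest planted
#' footprint plus the 30 bp cluster window) so each planted unit is its own
#' cluster.
#'
#' @param seed integer RNG seed.
#' @param contig_length bases in the single toy contig.
#' @param n_snp_tp,n_snp_fp,n_snp_fn SNP counts per label.
#' @param n_indel_tp named counts per size bin (default bins of
#'   [size_binning()]).
#' @param n_indel_fp,n_indel_fn InDel counts (sizes drawn from 1-10).
#' @param n_unk query-only records planted outside the region of interest.
#' @param p_hom proportion of homozygous-alt genotypes.
#' @param perturb named fractions of TP units re-represented in the query:
#'   \code{pad} (reference-base prefix padding), \code{shift} (right-shifted
#'   InDel inside a forced homopolymer), \code{mnp_split} (truth holds two
#'   adjacent SNPs, query one MNP).
#' @param spacing minimum distance between planted units, bases.
#' @return A list of class \code{fixture_config}.
#' @export
fixture_config <- function(seed = 1L, contig_length = 12000L,
                           n_snp_tp = 20L,
                           n_indel_tp = c("1-10" = 4L, "11-20" = 2L,
                                          "21-50" = 1L, ">50" = 1L),
                           n_snp_fp = 2L, n_indel_fp = 1L,
                           n_snp_fn = 2L, n_indel_fn = 1L,
                           n_unk = 0L, p_hom = 0.3,
                           perturb = c(pad = 0, shift = 0, mnp_split = 0),
                           spacing = 160L) {
  stopifnot(seed == floor(seed), contig_length > 500,
            all(c(n_snp_tp, n_indel_tp, n_snp_fp, n_indel_fp,
                  n_snp_fn, n_indel_fn, n_unk) >= 0),
            p_hom >= 0, p_hom <= 1, spacing >= 120)
  p <- c(pad = 0, shift = 0, mnp_split = 0)
  p[names(perturb)] <- perturb
  structure(list(seed = as.integer(seed), contig_length = as.integer(contig_length),
                 n_snp_tp = as.integer(n_snp_tp), n_indel_tp = n_indel_tp,
                 n_snp_fp = as.integer(n_snp_fp), n_indel_fp = as.integer(n_indel_fp),
                 n_snp_fn = as.integer(n_snp_fn), n_indel_fn = as.integer(n_indel_fn),
                 n_unk = as.integer(n_unk), p_hom = p_hom, perturb = p,
                 spacing = as.integer(spacing)),
            class = "fixture_config")
}

#' Generate a synthetic benchmarking fixture
#'
#' Writes a toy reference FASTA, truth and query VCFs with planted
#' TP/FP/FN structure, confidence and ROI BED files, a truth-assertion
#' table, and a planted-truth ledger recording each unit's intended label,
#' type and size bin. The ledger is the oracle for recovery tests: running
#' [classify()] on the files must reproduce its expected tallies exactly.
#'
#' @param cfg a [fixture_config()].
#' @param outdir output directory (created if needed).
#' @return Manifest list: file \code{paths}, the planted \code{ledger}
#'   data frame, and \code{expected} tallies (tp_truth, tp_query, fp, fn,
#'   n_unk, and per-bin InDel TP counts).
#' @export
generate_fixture <- function(cfg, outdir) {
  stopifnot(inherits(cfg, "fixture_config"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  L <- cfg$contig_length
  contig <- "ctg1"

  n_units <- cfg$n_snp_tp + sum(cfg$n_indel_tp) + cfg$n_snp_fp +
    cfg$n_indel_fp + cfg$n_snp_fn + cfg$n_indel_fn
  zone_lo <- 61L; zone_hi <- L - 160L
  slots_all <- seq(zone_lo, zone_hi, by = cfg$spacing)
  if (n_units > length(slots_all))
    vb_stop("contig too small for %d planted units at spacing %d",
            n_units, cfg$spacing, class = "varbench_config_error")

  set.seed(cfg$seed)
  bases <- sample(c("A", "C", "G", "T"), L, replace = TRUE)

  set.seed(cfg$seed + 1000L)
  slots <- sort(sample(slots_all, n_units))
  units <- data.frame(pos = sample(slots), stringsAsFactors = FALSE)
  units$label <- rep(c("TP", "FP", "FN"),
                     c(cfg$n_snp_tp + sum(cfg$n_indel_tp),
                       cfg$n_snp_fp + cfg$n_indel_fp,
                       cfg$n_snp_fn + cfg$n_indel_fn))
  units$type <- c(rep("SNP", cfg$n_snp_tp),
                  rep("INDEL", sum(cfg$n_indel_tp)),
                  rep("SNP", cfg$n_snp_fp), rep("INDEL", cfg$n_indel_fp),
                  rep("SNP", cfg$n_snp_fn), rep("INDEL", cfg$n_indel_fn))
  units$bin <- NA_character_
  units$size <- 0L

  set.seed(cfg$seed + 2000L)
  bn <- size_binning()
  tp_bins <- rep(names(cfg$n_indel_tp), cfg$n_indel_tp)
  units$bin[units$label == "TP" & units$type == "INDEL"] <- tp_bins
  units$bin[units$label != "TP" & units$type == "INDEL"] <- "1-10"
  is_ind <- units$type == "INDEL"
  units$size[is_ind] <- vapply(units$bin[is_ind], function(b) {
    i <- match(b, bn$labels)
    lo <- bn$lower[i]; hi <- if (is.na(bn$upper[i])) bn$lower[i] + 9L else bn$upper[i]
    sample(lo:hi, 1L)
  }, 0L)

  # perturbation assignment: deterministic counts from fractions, applied to
  # the first eligible TP units in position order
  tp_snp_idx <- which(units$label == "TP" & units$type == "SNP")
  tp_ind_idx <- which(units$label == "TP" & units$type == "INDEL")
  n_split <- floor(cfg$perturb[["mnp_split"]] * length(tp_snp_idx))
  n_pad <- floor(cfg$perturb[["pad"]] * length(tp_snp_idx))
  n_shift <- floor(cfg$perturb[["shift"]] * length(tp_ind_idx))
  units$perturb <- "none"
  units$perturb[tp_snp_idx[seq_len(n_split)]] <- "mnp_split"
  rem_snp <- setdiff(tp_snp_idx, tp_snp_idx[seq_len(n_split)])
  units$perturb[rem_snp[seq_len(min(n_pad, length(rem_snp)))]] <- "pad"
  units$perturb[tp_ind_idx[seq_len(n_shift)]] <- "shift"

  # force homopolymer context for shift-perturbed InDels before spelling
  set.seed(cfg$seed + 3000L)
  units$ins <- FALSE
  units$ins[is_ind] <- sample(c(TRUE, FALSE), sum(is_ind), replace = TRUE)
  for (i in which(units$perturb == "shift")) {
    p <- units$pos[i]; sz <- units$size[i]
    run <- if (units$ins[i]) 4L else sz + 4L
    b <- bases[p]
    prev <- setdiff(c("A", "C", "G", "T"), b)[1]
    bases[p - 1L] <- prev
    bases[p:(p + run - 1L)] <- b
    bases[p + run] <- setdiff(c("A", "C", "G", "T"), b)[1]
  }
  seqs <- setNames(paste(bases, collapse = ""), contig)
  ref <- ref_accessor(seqs)

  set.seed(cfg$seed + 4000L)
  units$hom <- sample(c(TRUE, FALSE), n_units, replace = TRUE,
                      prob = c(cfg$p_hom, 1 - cfg$p_hom))

  other_base <- function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1L)
  truth_rows <- list(); query_rows <- list(); ledger <- list()
  set.seed(cfg$seed + 5000L)
  for (i in seq_len(n_units)) {
    u <- units[i, ]
    g1 <- if (u$hom) 1L else 0L
    rec <- function(pos, refa, alta) {
      data.frame(chrom = contig, pos = pos, ref = refa, alt = alta,
                 gt1 = g1, gt2 = 1L, phased = FALSE, filter = "PASS",
                 sample_id = "s", stringsAsFactors = FALSE)
    }
    if (u$type == "SNP" && u$perturb == "mnp_split") {
      r1 <- bases[u$pos]; r2 <- bases[u$pos + 1L]
      a1 <- other_base(r1); a2 <- other_base(r2)
      tr <- rbind(rec(u$pos, r1, a1), rec(u$pos + 1L, r2, a2))
      qr <- rec(u$pos, paste0(r1, r2), paste0(a1, a2))
    } else if (u$type == "SNP") {
      r1 <- bases[u$pos]; a1 <- other_base(r1)
      tr <- rec(u$pos, r1, a1)
      qr <- tr
    } else if (u$ins) {
      b <- bases[u$pos]
      insert <- if (u$perturb == "shift") strrep(b, u$size) else
        paste(sample(c("A", "C", "G", "T"), u$size, replace = TRUE), collapse = "")
      tr <- rec(u$pos, b, paste0(b, insert))
      qr <- tr
      if (u$perturb == "shift") qr$pos <- u$pos + 2L
      if (u$perturb == "shift") { qr$ref <- bases[qr$pos]; qr$alt <- paste0(qr$ref, insert) }
    } else {
      delref <- ref(contig, u$pos, u$pos + u$size)
      tr <- rec(u$pos, delref, substr(delref, 1L, 1L))
      qr <- tr
      if (u$perturb == "shift") {
        qr$pos <- u$pos + 2L
        qr$ref <- ref(contig, qr$pos, qr$pos + u$size)
        qr$alt <- substr(qr$ref, 1L, 1L)
      }
    }
    if (u$perturb == "pad") {
      qr$ref <- paste0(bases[qr$pos - 1L], qr$ref)
      qr$alt <- paste0(bases[qr$pos - 1L], qr$alt)
      qr$pos <- qr$pos - 1L
    }
    if (u$label %in% c("TP", "FN")) truth_rows[[length(truth_rows) + 1L]] <- tr
    if (u$label %in% c("TP", "FP")) query_rows[[length(query_rows) + 1L]] <- qr
    ledger[[length(ledger) + 1L]] <- data.frame(
      unit = i, pos = u$pos, label = u$label, type = u$type,
      size = u$size, bin = u$bin, perturb = u$perturb,
      n_truth = if (u$label == "FP") 0L else nrow(tr),
      n_query = if (u$label == "FN") 0L else nrow(qr),
      stringsAsFactors = FALSE)
  }

  # query-only records outside the region of interest (reported UNK)
  set.seed(cfg$seed + 6000L)
  if (cfg$n_unk > 0) {
    upos <- seq(8L, 8L + (cfg$n_unk - 1L) * 4L, by = 4L)
    for (p in upos) {
      r1 <- bases[p]
      query_rows[[length(query_rows) + 1L]] <- data.frame(
        chrom = contig, pos = p, ref = r1, alt = other_base(r1),
        gt1 = 0L, gt2 = 1L, phased = FALSE, filter = "PASS",
        sample_id = "s", stringsAsFactors = FALSE)
    }
  }

  truth <- do.call(rbind, truth_rows) %||%
    data.frame(chrom = character(), pos = integer(), ref = character(),
               alt = character(), gt1 = integer(), gt2 = integer(),
               phased = logical(), filter = character(),
               sample_id = character())
  query <- do.call(rbind, query_rows) %||% truth[0, ]
  truth <- truth[order(truth$pos), , drop = FALSE]
  query <- query[order(query$pos), , drop = FALSE]

  lens <- setNames(L, contig)
  paths <- list(
    reference = file.path(outdir, "reference.fa"),
    truth = file.path(outdir, "truth.vcf"),
    query = file.path(outdir, "query.vcf"),
    confident = file.path(outdir, "confident.bed"),
    roi = file.path(outdir, "roi.bed"),
    assertions = file.path(outdir, "assertions.tsv"),
    ledger = file.path(outdir, "ledger.tsv")
  )
  write_fasta(seqs, paths$reference)
  write_vcf(truth, paths$truth, "TRUTH", lens)
  write_vcf(query, paths$query, "QUERY", lens)
  confident <- region_set(contig, 50L, L - 50L)
  write_bed(confident, paths$confident)
  write_bed(confident, paths$roi)

  led <- do.call(rbind, ledger)
  write.table(led, paths$ledger, sep = "\t", quote = FALSE, row.names = FALSE)

  # assertions: up to three planted TP truth variants expected present, plus
  # one FN unit (absent from the query) expected absent
  tp_led <- led[led$label == "TP" & led$perturb != "mnp_split", , drop = FALSE]
  fn_led <- led[led$label == "FN", , drop = FALSE]
  apick <- utils::head(tp_led$unit, 3L)
  fpick <- utils::head(fn_led$unit, 1L)
  arow <- function(unit, expected) {
    tr <- truth[truth$pos == led$pos[led$unit == unit][1], , drop = FALSE][1, ]
    data.frame(sample = "s", chrom = tr$chrom, pos = tr$pos, ref = tr$ref,
               alt = tr$alt, expected = expected, stringsAsFactors = FALSE)
  }
  adf <- do.call(rbind, c(lapply(apick, arow, expected = TRUE),
                          lapply(fpick, arow, expected = FALSE)))
  if (is.null(adf))
    adf <- data.frame(sample = character(), chrom = character(),
                      pos = integer(), ref = character(), alt = character(),
                      expected = logical())
  write.table(adf, paths$assertions, sep = "\t", quote = FALSE, row.names = FALSE)

  per_bin <- vapply(bn$labels, function(b)
    sum(led$label == "TP" & led$type == "INDEL" & led$bin == b), 0L)
  expected <- list(
    tp_truth = sum(led$n_truth[led$label == "TP"]),
    tp_query = sum(led$n_query[led$label == "TP"]),
    fp = sum(led$label == "FP"),
    fn = sum(led$label == "FN"),
    n_unk = cfg$n_unk,
    indel_tp_per_bin = per_bin
  )
  list(paths = paths, ledger = led, expected = expected, config = cfg,
       contig_lengths = lens)
}

#' Toy fixture of the six GeT-RM clinical truth variants
#'
#' Builds a toy reference spanning the six published GeT-RM clinically
#' relevant variant loci, remapped from GRCh37 onto short contigs (the
#' offsets are recorded in the manifest), a query VCF containing all six
#' variants, and the matching truth-assertion table. Three of the variants
#' sit within seven bases of each other on chromosome 15, which exercises
#' independent verification of adjacent clinical calls.
#'
#' @param outdir output directory.
#' @return Manifest list with \code{paths}, the assertion data frame
#'   (\code{assertions}), contig lengths and a \code{coordinates} table
#'   mapping toy to GRCh37 positions.
#' @export
plant_getrm_fixture <- function(outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  clen <- 220L
  offset <- c("15" = 91310051L, "17" = 41275943L, "13" = 32914336L,
              "10" = 43609002L)
  set.seed(20210224L)
  bases <- lapply(offset, function(o)
    sample(c("A", "C", "G", "T"), clen, replace = TRUE))
  # toy pos = GRCh37 pos - offset
  plant <- data.frame(
    sample = c("NA04408", "NA04408", "NA04408", "NA14090", "NA14170", "NA16658"),
    chrom = c("15", "15", "15", "17", "13", "10"),
    grch37_pos = c(91310152L, 91310156L, 91310158L, 41276044L, 32914437L,
                   43609103L),
    ref = c("TATC", "T", "A", "ACT", "GT", "G"),
    alt = c("T", "TA", "ATTC", "A", "G", "T"),
    stringsAsFactors = FALSE
  )
  plant$pos <- plant$grch37_pos - offset[plant$chrom]
  for (i in seq_len(nrow(plant))) {
    b <- strsplit(plant$ref[i], "")[[1]]
    bases[[plant$chrom[i]]][plant$pos[i] + seq_along(b) - 1L] <- b
  }
  # guard the run boundaries so planted alleles normalize in place
  bases[["15"]][100] <- "G"; bases[["15"]][106] <- "G"
  seqs <- vapply(bases, paste, "", collapse = "")
  paths <- list(reference = file.path(outdir, "reference.fa"),
                query = file.path(outdir, "query.vcf"),
                assertions = file.path(outdir, "assertions.tsv"))
  write_fasta(seqs, paths$reference)
  q <- data.frame(chrom = plant$chrom, pos = plant$pos, ref = plant$ref,
                  alt = plant$alt, gt1 = 0L, gt2 = 1L, phased = FALSE,
                  filter = "PASS", sample_id = "GeT-RM",
                  stringsAsFactors = FALSE)
  lens <- setNames(rep(clen, length(offset)), names(offset))
  write_vcf(q, paths$query, "QUERY", lens)
  adf <- data.frame(sample = plant$sample, chrom = plant$chrom,
                    pos = plant$pos, ref = plant$ref, alt = plant$alt,
                    expected = TRUE, stringsAsFactors = FALSE)
  write.table(adf, paths$assertions, sep = "\t", quote = FALSE,
              row.names = FALSE)
  list(paths = paths, assertions = adf, contig_lengths = lens,
       coordinates = plant[, c("sample", "chrom", "grch37_pos", "pos",
                               "ref", "alt")])
}
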