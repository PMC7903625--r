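#' Read a germline VCF into a record table
#'
#' Parses a single-sample (or named-sample) VCF v4.1+ through \pkg{vcfR}
#' after a structural pre-validation pass that reports malformed lines by
#' line number. Multi-allelic sites are passed through intact (comma-joined
#' ALT, raw genotype indices) for later decomposition by
#' [decompose_multiallelic()]. Records with a missing genotype (\code{./.})
#' are dropped; the drop count is messaged and attached as
#' \code{attr(, "n_dropped")}.
#'
#' @param path VCF file.
#' @param sample_id sample column to read; may be omitted for a
#'   single-sample file. The returned records carry this label.
#' @param pass_only drop records whose FILTER is neither "PASS" nor "."
#'   (clinical assays report only passing calls; truth sets are usually read
#'   with the default \code{FALSE} and restricted by confidence regions
#'   instead).
#' @param chr_harmonize strip a leading "chr" from contig names.
#' @return A data frame of raw records (class \code{vcf_records}) sorted by
#'   (chrom, pos), with columns chrom, pos, ref, alt, gt1, gt2, phased,
#'   filter, sample_id. Genotype indices may exceed 1 until decomposition.
#' @export
read_vcf <- function(path, sample_id = NULL, pass_only = FALSE,
                     chr_harmonize = FALSE) {
  if (!file.exists(path)) vb_stop("VCF file not found: %s", path)
  prevalidate_vcf(path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  gt <- v@gt
  if (is.null(gt) || ncol(gt) < 2)
    vb_stop("VCF has no genotype columns: %s", path)
  samples <- colnames(gt)[-1]
  if (is.null(sample_id)) {
    if (length(samples) != 1)
      vb_stop("VCF %s has %d samples; specify sample_id", path, length(samples))
    sample_col <- samples[1]
    label <- samples[1]
  } else if (sample_id %in% samples) {
    sample_col <- sample_id
    label <- sample_id
  } else if (length(samples) == 1) {
    # single-sample file; accept under the requested label
    sample_col <- samples[1]
    label <- sample_id
  } else {
    vb_stop("sample '%s' absent from VCF %s (has: %s)", sample_id, path,
            paste(samples, collapse = ", "), class = "varbench_config_error")
  }
  chrom <- as.character(fix[, "CHROM"])
  if (chr_harmonize) chrom <- sub("^chr", "", chrom)
  filter <- as.character(fix[, "FILTER"])
  filter[is.na(filter)] <- "."
  gt_str <- sub(":.*$", "", as.character(gt[, sample_col]))
  df <- data.frame(
    chrom = chrom,
    pos = as.integer(fix[, "POS"]),
    ref = toupper(as.character(fix[, "REF"])),
    alt = toupper(as.character(fix[, "ALT"])),
    filter = filter,
    gt_str = gt_str,
    stringsAsFactors = FALSE
  )
  missing_gt <- is.na(df$gt_str) | df$gt_str %in% c(".", "./.", ".|.")
  n_dropped <- sum(missing_gt)
  if (n_dropped > 0)
    message(sprintf("read_vcf: dropped %d record(s) with missing genotype from %s",
                    n_dropped, basename(path)))
  df <- df[!missing_gt, , drop = FALSE]
  if (pass_only) df <- df[df$filter %in% c("PASS", "."), , drop = FALSE]
  al <- parse_gt(df$gt_str)
  out <- data.frame(
    chrom = df$chrom, pos = df$pos, ref = df$ref, alt = df$alt,
    gt1 = al$gt1, gt2 = al$gt2, phased = al$phased,
    filter = df$filter, sample_id = rep_len(label, nrow(df)),
    stringsAsFactors = FALSE
  )
  out <- out[order(out$chrom, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("vcf_records", "data.frame")
  attr(out, "n_dropped") <- n_dropped
  out
}

parse_gt <- function(gt_str) {
  phased <- grepl("|", gt_str, fixed = TRUE)
  parts <- strsplit(gt_str, "[/|]")
  gt1 <- integer(length(parts)); gt2 <- integer(length(parts))
  for (i in seq_along(parts)) {
    p <- suppressWarnings(as.integer(parts[[i]]))
    if (length(p) == 1L) p <- c(p, p)  # haploid call treated as homozygous
    if (length(p) != 2L || any(is.na(p)))
      vb_stop("cannot parse genotype '%s'", gt_str[i])
    gt1[i] <- p[1]; gt2[i] <- p[2]
  }
  list(gt1 = gt1, gt2 = gt2, phased = phased)
}

prevalidate_vcf <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0 || !grepl("^##fileformat=VCF", lines[1]))
    vb_stop("not a VCF file (missing ##fileformat header): %s", path)
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (!nzchar(ln) || startsWith(ln, "#")) next
    p <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(p) < 8)
      vb_stop("VCF parse error at line %d: fewer than 8 columns", i)
    if (is.na(suppressWarnings(as.integer(p[2]))))
      vb_stop("VCF parse error at line %d: POS is not an integer", i)
    if (!nzchar(p[4]) || p[4] == ".")
      vb_stop("VCF parse error at line %d: empty REF allele", i)
  }
  invisible(TRUE)
}

vcf_header <- function(sample_cols, contig_lengths = NULL, annotated = FALSE) {
  h <- c("##fileformat=VCFv4.2",
         "##source=varbench")
  if (!is.null(contig_lengths))
    h <- c(h, sprintf("##contig=<ID=%s,length=%d>",
                      names(contig_lengths), as.integer(contig_lengths)))
  h <- c(h, '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">')
  if (annotated) {
    h <- c(h,
      '##FORMAT=<ID=BD,Number=1,Type=String,Description="Benchmarking decision (TP/FP/FN/UNK)">',
      '##FORMAT=<ID=BVT,Number=1,Type=String,Description="Benchmarking variant type (SNP/MNP/INDEL)">')
  }
  c(h, paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
               "FORMAT", sample_cols), collapse = "\t"))
}

gt_field <- function(gt1, gt2, phased) {
  sep <- ifelse(phased, "|", "/")
  paste0(gt1, sep, gt2)
}

#' Write a variant table as a single-sample VCF
#'
#' @param df a \code{variant_table} or compatible data frame.
#' @param path output file.
#' @param sample_id sample column name (defaults to the records' label).
#' @param contig_lengths optional named vector for ##contig header lines.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(df, path, sample_id = NULL, contig_lengths = NULL) {
  sample_id <- sample_id %||% (if (nrow(df)) df$sample_id[1] else "sample")
  df <- df[order(df$chrom, df$pos, df$ref, df$alt), , drop = FALSE]
  body <- sprintf("%s\t%d\t.\t%s\t%s\t.\t%s\t.\tGT\t%s",
                  df$chrom, df$pos, df$ref, df$alt,
                  ifelse(nzchar(df$filter), df$filter, "."),
                  gt_field(df$gt1, df$gt2, df$phased))
  writeLines(c(vcf_header(sample_id, contig_lengths), body), path)
  invisible(path)
}

#' Write the classified comparison as a two-sample annotated VCF
#'
#' Emits one record per distinct (chrom, pos, ref, alt) with TRUTH and QUERY
#' sample columns and per-sample annotation fields \code{BD} (benchmarking
#' decision: TP/FP/FN/UNK) and \code{BVT} (variant type), the output
#' convention of the GA4GH benchmarking tools. A side with no record at the
#' site carries a missing genotype and "." annotations. The file round-trips
#' through [read_annotated_vcf()].
#'
#' @param classified data frame of classified records as produced by
#'   [classify()] (columns role, chrom, pos, ref, alt, gt1, gt2, phased,
#'   label, variant_type).
#' @param path output file.
#' @param contig_lengths optional named vector for ##contig header lines.
#' @return `path`, invisibly.
#' @export
write_annotated_vcf <- function(classified, path, contig_lengths = NULL) {
  stopifnot(all(classified$label %in% c("TP", "FP", "FN", "UNK")))
  key <- paste(classified$chrom, classified$pos, classified$ref,
               classified$alt, sep = "\r")
  sites <- !duplicated(key)
  sdf <- classified[sites, c("chrom", "pos", "ref", "alt"), drop = FALSE]
  skey <- key[sites]
  ord <- order(sdf$chrom, sdf$pos, sdf$ref, sdf$alt)
  sdf <- sdf[ord, , drop = FALSE]; skey <- skey[ord]
  col_for <- function(role) {
    idx <- match(skey, key[classified$role == role])
    sub <- classified[classified$role == role, , drop = FALSE]
    out <- rep("./.:.:.", nrow(sdf))
    hit <- !is.na(idx)
    out[hit] <- sprintf("%s:%s:%s",
                        gt_field(sub$gt1[idx[hit]], sub$gt2[idx[hit]],
                                 sub$phased[idx[hit]]),
                        sub$label[idx[hit]], sub$variant_type[idx[hit]])
    out
  }
  body <- sprintf("%s\t%d\t.\t%s\t%s\t.\t.\t.\tGT:BD:BVT\t%s\t%s",
                  sdf$chrom, sdf$pos, sdf$ref, sdf$alt,
                  col_for("truth"), col_for("query"))
  writeLines(c(vcf_header(c("TRUTH", "QUERY"), contig_lengths,
                          annotated = TRUE), body), path)
  invisible(path)
}

#' Read an annotated comparison VCF back into a classified table
#'
#' @param path file written by [write_annotated_vcf()].
#' @return Data frame with columns role, chrom, pos, ref, alt, gt1, gt2,
#'   phased, label, variant_type.
#' @export
read_annotated_vcf <- function(path) {
  prevalidate_vcf(path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  gt <- v@gt
  one_side <- function(role, col) {
    cells <- strsplit(as.character(gt[, col]), ":", fixed = TRUE)
    gt_str <- vapply(cells, `[`, "", 1L)
    keep <- !(gt_str %in% c(".", "./.", ".|."))
    if (!any(keep)) return(NULL)
    al <- parse_gt(gt_str[keep])
    data.frame(role = role,
               chrom = as.character(fix[keep, "CHROM"]),
               pos = as.integer(fix[keep, "POS"]),
               ref = toupper(as.character(fix[keep, "REF"])),
               alt = toupper(as.character(fix[keep, "ALT"])),
               gt1 = al$gt1, gt2 = al$gt2, phased = al$phased,
               label = vapply(cells[keep], `[`, "", 2L),
               variant_type = vapply(cells[keep], `[`, "", 3L),
               stringsAsFactors = FALSE)
  }
  out <- rbind(one_side("truth", "TRUTH"), one_side("query", "QUERY"))
  out <- out[order(out$role, out$chrom, out$pos, out$ref, out$alt), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a metrics table as TSV
#'
#' One row per stratum (sample x region x variant type x size bin) with the
#' confusion tallies and derived metrics. Precision/recall are rendered at
#' \code{digits} decimals (half-up); NPA likewise, or as a nearest integer
#' when \code{npa_integer} is set, matching the convention of printed
#' validation tables.
#'
#' @param rows data frame as produced by [compute_metrics()] with stratum
#'   columns sample, region, variant_type, size_bin.
#' @param path output file.
#' @param digits decimals for precision/recall (default 2).
#' @param npa_integer render NPA as a nearest integer.
#' @return `path`, invisibly.
#' @export
write_metrics_table <- function(rows, path, digits = 2, npa_integer = FALSE) {
  if (NROW(rows) == 0) vb_stop("empty metrics report")
  fmt <- function(x, d) ifelse(is.na(x), "NA",
                               formatC(round_half_up(x, d), format = "f", digits = d))
  out <- data.frame(
    sample = rows$sample, region = rows$region,
    variant_type = rows$variant_type, size_bin = rows$size_bin,
    total_bases = format(rows$total_bases, scientific = FALSE, trim = TRUE),
    truth_total = rows$truth_total,
    TP = rows$tp_query, FP = rows$fp, FN = rows$fn,
    TN = format(rows$tn, scientific = FALSE, trim = TRUE),
    NPA = if (npa_integer) fmt(rows$npa, 0) else fmt(rows$npa, digits),
    precision = fmt(rows$precision, digits),
    recall = fmt(rows$recall, digits),
    stringsAsFactors = FALSE
  )
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a truth-assertion table
#'
#' Headered TSV describing clinically relevant variants whose presence (or
#' absence) the assay must confirm: columns \code{sample}, \code{chrom},
#' \code{pos}, \code{ref}, \code{alt}, optionally \code{genotype}
#' ("het"/"hom") and \code{expected} (TRUE/FALSE, default TRUE).
#'
#' @param path TSV file.
#' @return Data frame of assertions.
#' @export
read_assertions <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                   colClasses = "character")
  need <- c("sample", "chrom", "pos", "ref", "alt")
  if (!all(need %in% names(df)))
    vb_stop("assertion table must have columns: %s", paste(need, collapse = ", "))
  df$pos <- suppressWarnings(as.integer(gsub(",", "", df$pos)))
  df$ref <- toupper(df$ref); df$alt <- toupper(df$alt)
  bad <- is.na(df$pos) | df$pos < 1 | grepl("[^ACGTN]", df$ref) |
    grepl("[^ACGTN]", df$alt) | !nzchar(df$ref) | !nzchar(df$alt)
  if (any(bad))
    vb_stop("assertion row %d does not parse as a VCF-style variant", which(bad)[1])
  if (is.null(df$genotype)) df$genotype <- NA_character_
  df$expected <- if (is.null(df$expected)) TRUE else as.logical(df$expected)
  df
}
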