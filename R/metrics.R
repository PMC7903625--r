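#' InDel size of each record
#'
#' The absolute length difference between the alleles of a normalized
#' record; 0 identifies non-length-changing records (SNPs/MNPs), which are
#' excluded from InDel binning.
#'
#' @param df a \code{variant_table} or compatible data frame.
#' @return Integer vector of sizes.
#' @examples
#' indel_size(data.frame(ref = c("TATC", "A", "A"), alt = c("T", "ATTC", "G")))
#' @export
indel_size <- function(df) abs(nchar(df$alt) - nchar(df$ref))

#' InDel size binning
#'
#' Defines the inclusive size ranges used to stratify InDel metrics. The
#' default bins are 1-10, 11-20, 21-50 and >50 base pairs; the last bin is
#' open-ended so the ranges cover every size >= 1.
#'
#' @param breaks upper edges of the closed bins (default c(10, 20, 50)).
#' @return An object of class \code{size_binning} with elements
#'   \code{breaks}, \code{labels}, \code{lower}, \code{upper}.
#' @export
size_binning <- function(breaks = c(10L, 20L, 50L)) {
  breaks <- sort(unique(as.integer(breaks)))
  stopifnot(all(breaks >= 1))
  lower <- c(1L, breaks + 1L)
  upper <- c(breaks, NA_integer_)
  labels <- c(paste0(lower[-length(lower)], "-", breaks), paste0(">", max(breaks)))
  structure(list(breaks = breaks, labels = labels, lower = lower, upper = upper),
            class = "size_binning")
}

#' Assign InDel sizes to bins
#'
#' @param size integer vector of InDel sizes (>= 1; size 0 records are not
#'   InDels and are a contract violation here).
#' @param binning a [size_binning()].
#' @return Character vector of bin labels.
#' @examples
#' assign_bin(c(10, 11, 51), size_binning()) # "1-10" "11-20" ">50"
#' @export
assign_bin <- function(size, binning = size_binning()) {
  out <- rep(NA_character_, length(size))
  ok <- !is.na(size)
  if (any(size[ok] < 1))
    vb_stop("InDel size must be >= 1 (got %d)", min(size[ok]))
  idx <- findInterval(size[ok], c(binning$lower, Inf))
  out[ok] <- binning$labels[idx]
  out
}

#' Compute precision, recall, TN and NPA from confusion tallies
#'
#' Applies the benchmarking formulae: precision = TP/(TP+FP) on the query
#' side, recall = TP/(TP+FN) on the truth side,
#' TN = region bases - (TP+FP+FN), Total Negatives = TN + FP and
#' NPA (negative percent agreement, the specificity surrogate used in
#' clinical assay validation) = TN/Total Negatives. Percentages are on the
#' 0-100 scale at full precision; rendering is the writer's concern.
#' Undefined ratios (0/0) are reported as NA, never as 0 or 100, so empty
#' strata cannot bias a report.
#'
#' @param counts data frame with columns tp_query, fp, fn, total_bases and
#'   (optionally) tp_truth; when tp_truth is absent, tp_query is used for
#'   the recall numerator too (the usual case without representation
#'   splits). Additional columns pass through.
#' @return The input with columns precision, recall, tn, total_negatives,
#'   npa appended. A negative derived TN (counts exceeding the region size)
#'   raises an inconsistency error.
#' @examples
#' compute_metrics(data.frame(tp_query = 7781, fp = 4, fn = 22,
#'                            total_bases = 13728555))
#' @export
compute_metrics <- function(counts) {
  counts <- as.data.frame(counts)
  tpq <- counts$tp_query
  tpt <- if (!is.null(counts$tp_truth)) counts$tp_truth else tpq
  fp <- counts$fp; fn <- counts$fn; tb <- counts$total_bases
  rat <- function(num, den) ifelse(den > 0, 100 * num / den, NA_real_)
  counts$precision <- rat(tpq, tpq + fp)
  counts$recall <- rat(tpt, tpt + fn)
  counts$tn <- tb - (tpq + fp + fn)
  if (any(counts$tn < 0))
    vb_stop("derived TN is negative: confusion counts exceed the region size")
  counts$total_negatives <- counts$tn + fp
  counts$npa <- rat(counts$tn, counts$total_negatives)
  counts
}

#' Merge InDel size bins and recompute metrics
#'
#' Coarsens per-bin confusion tallies into user-preferred merged ranges
#' (e.g. 1-20 from 1-10 and 11-20). Counts are summed across constituent
#' bins and metrics recomputed from the sums — percentages are never
#' averaged.
#'
#' @param per_bin data frame of per-bin counts (columns size_bin, tp_truth,
#'   tp_query, fp, fn, truth_total, total_bases).
#' @param target named list mapping each merged label to the base-bin
#'   labels it unions, e.g. \code{list("1-20" = c("1-10", "11-20"))}.
#' @return Data frame of merged-bin counts with metrics columns.
#' @export
merge_bins <- function(per_bin, target) {
  rows <- lapply(names(target), function(lab) {
    parts <- target[[lab]]
    missing <- setdiff(parts, per_bin$size_bin)
    if (length(missing))
      vb_stop("merged bin '%s' references unknown base bin(s): %s",
              lab, paste(missing, collapse = ", "),
              class = "varbench_config_error")
    sub <- per_bin[per_bin$size_bin %in% parts, , drop = FALSE]
    data.frame(size_bin = lab,
               tp_truth = sum(sub$tp_truth), tp_query = sum(sub$tp_query),
               fp = sum(sub$fp), fn = sum(sub$fn),
               truth_total = sum(sub$truth_total),
               total_bases = sub$total_bases[1],
               stringsAsFactors = FALSE)
  })
  compute_metrics(do.call(rbind, rows))
}

#' InDel size-spectrum histogram
#'
#' Counts TP/FP/FN InDels per size bin from a classified record set, writes
#' the counts as TSV and optionally draws a grouped bar chart (PDF). The
#' counts equal the per-bin confusion tallies used for metrics.
#'
#' @param classified classified record data frame from [classify()].
#' @param binning a [size_binning()].
#' @param tsv optional TSV output path.
#' @param plot optional PDF output path.
#' @return Data frame of per-bin, per-label counts, invisibly when writing.
#' @export
spectrum_histogram <- function(classified, binning = size_binning(),
                               tsv = NULL, plot = NULL) {
  ind <- classified[classified$variant_type == "INDEL" &
                      classified$label != "UNK", , drop = FALSE]
  counts <- data.frame(size_bin = binning$labels, stringsAsFactors = FALSE)
  counts$TP <- vapply(binning$labels, function(b)
    sum(ind$size_bin == b & ind$role == "query" & ind$label == "TP"), 0L)
  counts$FP <- vapply(binning$labels, function(b)
    sum(ind$size_bin == b & ind$label == "FP"), 0L)
  counts$FN <- vapply(binning$labels, function(b)
    sum(ind$size_bin == b & ind$label == "FN"), 0L)
  if (!is.null(tsv))
    write.table(counts, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(plot)) {
    grDevices::pdf(plot, width = 6, height = 4)
    on.exit(grDevices::dev.off(), add = TRUE)
    m <- t(as.matrix(counts[, c("TP", "FP", "FN")]))
    colnames(m) <- counts$size_bin
    graphics::barplot(m, beside = TRUE, legend.text = rownames(m),
                      xlab = "InDel size (bp)", ylab = "count",
                      main = "InDel size spectrum",
                      col = c("#2c7fb8", "#d95f0e", "#756bb1"))
  }
  if (is.null(tsv) && is.null(plot)) counts else invisible(counts)
}

#' Consolidate per-sample metrics into a validation report
#'
#' Produces the single deterministic text report of a validation run: a
#' provenance header (tool version, configuration, MD5 checksum per input
#' file), one metrics block per sample x region x variant type x size bin,
#' an optional merged-bin section, and the clinical-variant verification
#' table. Identical inputs yield a byte-identical report body.
#'
#' @param metrics data frame of stratified metric rows (as written by
#'   [write_metrics_table()], with stratum columns sample/region).
#' @param path output file.
#' @param verification optional verdict table from [verify_variants()].
#' @param merged optional merged-bin metrics data frame.
#' @param input_files character vector of input paths to checksum.
#' @param config_lines character vector describing the run configuration.
#' @param npa_integer render NPA as nearest integer.
#' @return `path`, invisibly.
#' @export
consolidate <- function(metrics, path, verification = NULL, merged = NULL,
                        input_files = character(0),
                        config_lines = character(0), npa_integer = FALSE) {
  if (NROW(metrics) == 0) vb_stop("empty metrics report")
  con <- textConnection("rpt", "w", local = TRUE)
  w <- function(...) writeLines(sprintf(...), con)
  w("varbench analytical validation report")
  w("tool: varbench %s (R package)",
    as.character(utils::packageVersion("varbench")))
  if (length(config_lines)) {
    w("configuration:")
    for (l in sort(config_lines)) w("  %s", l)
  }
  if (length(input_files)) {
    w("input checksums (md5):")
    for (f in sort(input_files)) w("  %s", checksum_line(f))
  }
  w("")
  w("== benchmarking metrics ==")
  tmp <- tempfile(); on.exit(unlink(tmp), add = TRUE)
  ord <- order(metrics$sample, metrics$region, metrics$variant_type,
               metrics$size_bin)
  write_metrics_table(metrics[ord, , drop = FALSE], tmp,
                      npa_integer = npa_integer)
  writeLines(readLines(tmp), con)
  if (!is.null(merged) && NROW(merged)) {
    w("")
    w("== merged InDel size bins ==")
    write_metrics_table(merged, tmp, npa_integer = npa_integer)
    writeLines(readLines(tmp), con)
  }
  if (!is.null(verification) && NROW(verification)) {
    w("")
    w("== truth-variant verification ==")
    vv <- verification[order(verification$sample, verification$chrom,
                             verification$pos), , drop = FALSE]
    w("sample\tchrom\tpos\tref\talt\tdetected")
    for (i in seq_len(nrow(vv)))
      w("%s\t%s\t%d\t%s\t%s\t%s", vv$sample[i], vv$chrom[i], vv$pos[i],
        vv$ref[i], vv$alt[i], vv$verdict[i])
  }
  close(con)
  writeLines(rpt, path)
  invisible(path)
}
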