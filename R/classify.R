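#' Classify query variants against a truth set within an evaluation region
#'
#' The full comparison for one sample and one region of interest. Both
#' callsets are decomposed to biallelic records and normalized; the
#' evaluation region is the intersection of the high-confidence region with
#' the region of interest (or the ROI alone when no confidence region is
#' supplied); records whose normalized footprint does not overlap the
#' evaluation region are labeled UNK and excluded from all counts; the
#' remaining records are clustered and matched haplotype-aware, yielding
#' TP/FP/FN labels; and confusion tallies are accumulated per variant type
#' and InDel size bin together with the region base count, from which
#' [compute_metrics()] derives precision, recall, TN and NPA.
#'
#' True-positive tallies are kept separately for the truth side (recall
#' numerator) and the query side (precision numerator): the two differ when
#' representation splits let, say, one query MNP match two truth SNPs.
#'
#' @param truth,query raw records from [read_vcf()] or ready
#'   \code{variant_table}s.
#' @param roi \code{RegionSet} of the region of interest.
#' @param ref_seq reference accessor from [ref_accessor()].
#' @param confident optional \code{RegionSet} of high-confidence truth
#'   regions; only calls inside it are scored.
#' @param window,max_cluster_size clustering parameters, see
#'   [cluster_variants()].
#' @param pass_only drop non-passing query records before comparison
#'   (default TRUE; clinical assays report only passing calls).
#' @param binning InDel size binning, see [size_binning()].
#' @return List of class \code{varbench_classification}:
#'   \describe{
#'     \item{classified}{data frame of all records with role, label,
#'       variant_type, indel_size, size_bin.}
#'     \item{counts}{per-stratum confusion tallies (variant_type x
#'       size_bin) with tp_truth, tp_query, fp, fn, truth_total,
#'       total_bases.}
#'     \item{region}{the evaluation \code{RegionSet}.}
#'   }
#' @export
classify <- function(truth, query, roi, ref_seq, confident = NULL,
                     window = 30L, max_cluster_size = 8L, pass_only = TRUE,
                     binning = size_binning()) {
  region <- if (!is.null(confident)) region_intersect(confident, roi) else roi
  if (total_bases(region) == 0)
    vb_stop("evaluation region is empty (confidence regions do not overlap the region of interest)",
            class = "varbench_config_error")
  if (is.data.frame(query) && "filter" %in% names(query) && pass_only)
    query <- query[query$filter %in% c("PASS", "."), , drop = FALSE]
  check_contig_namespaces(truth, query)
  tnorm <- normalize_variants(decompose_if_needed(truth), ref_seq)
  qnorm <- normalize_variants(decompose_if_needed(query), ref_seq)

  label_side <- function(df) {
    lab <- rep(NA_character_, nrow(df))
    if (nrow(df) == 0) return(lab)
    hits <- GenomicRanges::findOverlaps(variants_to_granges(df),
                                        regions_granges(region))
    inside <- seq_len(nrow(df)) %in% S4Vectors::queryHits(hits)
    lab[!inside] <- "UNK"
    lab
  }
  tlab <- label_side(tnorm); qlab <- label_side(qnorm)

  tin <- tnorm[is.na(tlab), , drop = FALSE]
  qin <- qnorm[is.na(qlab), , drop = FALSE]
  clusters <- cluster_variants(tin, qin, window = window,
                               max_cluster_size = max_cluster_size)
  res_t <- list(); res_q <- list()
  for (cl in clusters) {
    m <- match_clusters(cl$truth, cl$query, ref_seq)
    if (nrow(cl$truth)) {
      ct <- cl$truth; ct$label <- m$truth_labels; res_t[[length(res_t) + 1L]] <- ct
    }
    if (nrow(cl$query)) {
      cq <- cl$query; cq$label <- m$query_labels; res_q[[length(res_q) + 1L]] <- cq
    }
  }
  bind_side <- function(norm, lab, res, role) {
    unk <- as.data.frame(norm)[which(lab == "UNK"), , drop = FALSE]
    if (nrow(unk)) unk$label <- "UNK"
    inner <- if (length(res)) do.call(rbind, res) else NULL
    keep <- c("chrom", "pos", "ref", "alt", "gt1", "gt2", "phased", "label")
    out <- rbind(if (nrow(unk)) unk[, keep, drop = FALSE] else NULL,
                 if (!is.null(inner)) inner[, keep, drop = FALSE] else NULL)
    if (is.null(out))
      out <- data.frame(chrom = character(), pos = integer(), ref = character(),
                        alt = character(), gt1 = integer(), gt2 = integer(),
                        phased = logical(), label = character(),
                        stringsAsFactors = FALSE)
    out$role <- rep_len(role, nrow(out))
    out
  }
  classified <- rbind(bind_side(tnorm, tlab, res_t, "truth"),
                      bind_side(qnorm, qlab, res_q, "query"))
  classified <- classified[order(classified$chrom, classified$pos,
                                 classified$ref, classified$alt,
                                 classified$role), , drop = FALSE]
  rownames(classified) <- NULL
  classified$variant_type <- variant_type(classified)
  classified$indel_size <- indel_size(classified)
  classified$size_bin <- rep(NA_character_, nrow(classified))
  is_ind <- classified$variant_type == "INDEL"
  classified$size_bin[is_ind] <- assign_bin(classified$indel_size[is_ind],
                                            binning)
  counts <- confusion_counts(classified, total_bases(region), binning)
  structure(list(classified = classified, counts = counts, region = region),
            class = "varbench_classification")
}

decompose_if_needed <- function(x) {
  if (inherits(x, "variant_table")) return(x)
  decompose_multiallelic(x)
}

check_contig_namespaces <- function(truth, query) {
  tc <- unique(truth$chrom); qc <- unique(query$chrom)
  if (length(tc) && length(qc) && length(intersect(tc, qc)) == 0)
    vb_stop(paste0("truth and query use disjoint contig namespaces (%s vs %s); ",
                   "consider chr_harmonize = TRUE when reading"),
            paste(head(tc, 3), collapse = ","), paste(head(qc, 3), collapse = ","),
            class = "varbench_config_error")
  invisible(TRUE)
}

#' Tally confusion counts per variant type and InDel size bin
#'
#' @param classified classified record data frame from [classify()].
#' @param region_bases total bases of the evaluation region.
#' @param binning a [size_binning()].
#' @return Data frame with one row per stratum plus per-type "ALL" rows;
#'   columns variant_type, size_bin, tp_truth, tp_query, fp, fn,
#'   truth_total, total_bases.
#' @export
confusion_counts <- function(classified, region_bases, binning = size_binning()) {
  cc <- classified[classified$label != "UNK", , drop = FALSE]
  tally <- function(sub) {
    data.frame(
      tp_truth = sum(sub$role == "truth" & sub$label == "TP"),
      tp_query = sum(sub$role == "query" & sub$label == "TP"),
      fp = sum(sub$label == "FP"),
      fn = sum(sub$label == "FN"),
      stringsAsFactors = FALSE
    )
  }
  rows <- list()
  for (vt in c("SNP", "MNP", "INDEL")) {
    sub <- cc[cc$variant_type == vt, , drop = FALSE]
    if (vt == "INDEL") {
      for (b in binning$labels) {
        r <- tally(sub[!is.na(sub$size_bin) & sub$size_bin == b, , drop = FALSE])
        rows[[length(rows) + 1L]] <- cbind(variant_type = vt, size_bin = b, r)
      }
      r <- tally(sub)
      rows[[length(rows) + 1L]] <- cbind(variant_type = vt, size_bin = "ALL", r)
    } else {
      r <- tally(sub)
      rows[[length(rows) + 1L]] <- cbind(variant_type = vt, size_bin = "ALL", r)
    }
  }
  out <- do.call(rbind, rows)
  out$truth_total <- out$tp_truth + out$fn
  out$total_bases <- region_bases
  out
}

#' @export
print.varbench_classification <- function(x, ...) {
  cc <- x$counts[x$counts$size_bin == "ALL", , drop = FALSE]
  cat("varbench classification\n")
  cat(sprintf("  evaluation region: %s bases\n",
              format(total_bases(x$region), big.mark = ",")))
  for (i in seq_len(nrow(cc))) {
    cat(sprintf("  %-6s TP(truth)=%d TP(query)=%d FP=%d FN=%d\n",
                cc$variant_type[i], cc$tp_truth[i], cc$tp_query[i],
                cc$fp[i], cc$fn[i]))
  }
  invisible(x)
}
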