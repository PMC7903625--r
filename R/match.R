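#' Cluster truth and query variants by proximity
#'
#' Groups variants from both callsets by transitive closure of footprint
#' proximity: any two records (either role) whose reference footprints lie
#' within \code{window} bases fall in the same paired cluster. Ambiguity in
#' allelic representation is local — adjacent SNPs, MNPs and shifted InDels
#' spell the same haplotype only within a bounded neighbourhood — so
#' matching is performed per cluster. Clusters whose per-role member count
#' exceeds \code{max_cluster_size} are split at their largest internal gap
#' (left-most on ties, keeping the output deterministic) and flagged.
#'
#' @param truth,query normalized \code{variant_table}s.
#' @param window clustering window in bases (default 30).
#' @param max_cluster_size maximum members per role per cluster (default 8,
#'   bounding phase enumeration at 2^7 per side).
#' @return List of clusters; each has elements \code{chrom}, \code{truth},
#'   \code{query} (row subsets) and \code{flagged}.
#' @export
cluster_variants <- function(truth, query, window = 30L, max_cluster_size = 8L) {
  t2 <- as.data.frame(truth); q2 <- as.data.frame(query)
  t2$role <- rep_len("truth", nrow(t2)); q2$role <- rep_len("query", nrow(q2))
  cols <- c("chrom", "pos", "ref", "alt", "gt1", "gt2", "phased", "role")
  comb <- rbind(t2[, cols, drop = FALSE], q2[, cols, drop = FALSE])
  if (nrow(comb) == 0) return(list())
  comb$fstart <- comb$pos
  comb$fend <- comb$pos + nchar(comb$ref) - 1L
  comb <- comb[order(comb$chrom, comb$fstart, comb$fend), , drop = FALSE]
  # sweep: new cluster when the gap to everything seen so far exceeds window
  cid <- integer(nrow(comb)); cur <- 0L; cur_end <- -Inf; cur_chrom <- ""
  for (i in seq_len(nrow(comb))) {
    if (comb$chrom[i] != cur_chrom || comb$fstart[i] - cur_end > window) {
      cur <- cur + 1L
      cur_chrom <- comb$chrom[i]
      cur_end <- comb$fend[i]
    } else {
      cur_end <- max(cur_end, comb$fend[i])
    }
    cid[i] <- cur
  }
  out <- list()
  for (k in unique(cid)) {
    sub <- comb[cid == k, , drop = FALSE]
    out <- c(out, split_oversized(sub, max_cluster_size))
  }
  out
}

# recursively split a cluster whose truth or query side exceeds the bound,
# cutting at the largest internal gap (left-most on ties)
split_oversized <- function(sub, max_cluster_size, flagged = FALSE) {
  n_t <- sum(sub$role == "truth"); n_q <- sum(sub$role == "query")
  if ((n_t <= max_cluster_size && n_q <= max_cluster_size) || nrow(sub) < 2) {
    return(list(make_cluster(sub, flagged)))
  }
  gaps <- sub$fstart[-1] - cummax(sub$fend)[-nrow(sub)]
  cut <- which.max(gaps)  # which.max takes the left-most maximum
  c(split_oversized(sub[seq_len(cut), , drop = FALSE], max_cluster_size, TRUE),
    split_oversized(sub[-seq_len(cut), , drop = FALSE], max_cluster_size, TRUE))
}

make_cluster <- function(sub, flagged) {
  list(chrom = sub$chrom[1],
       truth = sub[sub$role == "truth", , drop = FALSE],
       query = sub[sub$role == "query", , drop = FALSE],
       flagged = flagged)
}

# apply non-overlapping alleles (sorted by pos) to the reference span;
# returns NULL when two alleles on the same haplotype overlap
apply_alleles <- function(members, chrom, span_start, span_end, ref_seq) {
  if (nrow(members) == 0) return(ref_seq(chrom, span_start, span_end))
  members <- members[order(members$pos), , drop = FALSE]
  cursor <- span_start
  out <- character(0)
  for (i in seq_len(nrow(members))) {
    p <- members$pos[i]
    if (p < cursor) return(NULL)
    out <- c(out, ref_seq(chrom, cursor, p - 1L), members$alt[i])
    cursor <- p + nchar(members$ref[i])
  }
  if (cursor > span_end + 1L) return(NULL)
  paste0(paste(out, collapse = ""), ref_seq(chrom, cursor, span_end))
}

#' Enumerate the haplotype spellings of a variant cluster
#'
#' For one role's cluster members, enumerates every phase assignment
#' consistent with the genotypes — homozygous members sit on both
#' haplotypes, phased heterozygotes keep their phase, unphased
#' heterozygotes are free — applies each assignment's alleles to the
#' reference span, and returns the distinct unordered pairs of spelled
#' sequences. Assignments that would place overlapping alleles on one
#' haplotype are discarded; if no assignment is internally consistent the
#' cluster is marked inconsistent (callers fall back to exact-representation
#' matching with a warning).
#'
#' @param members data frame of cluster members (pos, ref, alt, gt1, gt2,
#'   phased) on one chromosome.
#' @param chrom chromosome name.
#' @param span_start,span_end 1-based inclusive reference span to spell.
#' @param ref_seq reference accessor.
#' @return List with \code{pairs} (character vector of canonical
#'   "seq1|seq2" keys, sorted within pair) and \code{inconsistent}.
#' @export
haplotype_spellings <- function(members, chrom, span_start, span_end, ref_seq) {
  if (nrow(members) == 0) {
    r <- ref_seq(chrom, span_start, span_end)
    return(list(pairs = paste(r, r, sep = "|"), inconsistent = FALSE))
  }
  hom <- members$gt1 == 1L & members$gt2 == 1L
  het <- !hom
  phased_het <- het & members$phased
  free <- which(het & !members$phased)
  pairs <- character(0)
  for (mask in 0:(2^length(free) - 1L)) {
    onA <- hom | (phased_het & members$gt1 == 1L)
    onB <- hom | (phased_het & members$gt2 == 1L)
    if (length(free)) {
      toA <- bitwAnd(mask, bitwShiftL(1L, seq_along(free) - 1L)) > 0L
      onA[free[toA]] <- TRUE
      onB[free[!toA]] <- TRUE
    }
    sA <- apply_alleles(members[onA, , drop = FALSE], chrom, span_start,
                        span_end, ref_seq)
    sB <- apply_alleles(members[onB, , drop = FALSE], chrom, span_start,
                        span_end, ref_seq)
    if (is.null(sA) || is.null(sB)) next
    key <- paste(sort(c(sA, sB)), collapse = "|")
    pairs <- c(pairs, key)
  }
  if (length(pairs) == 0) return(list(pairs = character(0), inconsistent = TRUE))
  list(pairs = sort(unique(pairs)), inconsistent = FALSE)
}

#' Match one paired truth/query cluster
#'
#' Declares the clusters concordant when some phasing of each side spells
#' the same unordered pair of local haplotype sequences, in which case every
#' member on both sides is a true positive. An empty truth side makes the
#' query members false positives (and vice versa false negatives). When
#' both sides are non-empty but no spelling matches, matching falls back to
#' exact representation: records agreeing on (chrom, pos, ref, alt) with
#' equal genotype are TP; with unequal genotype the truth record counts FN
#' and the query record FP (genotype mismatch, no partial credit);
#' remaining truth records are FN and query records FP.
#'
#' @param truth,query data frames of normalized members of one paired
#'   cluster (single chromosome).
#' @param ref_seq reference accessor.
#' @param span optional c(start, end) reference span; derived from the
#'   members' footprints when omitted.
#' @return List with \code{truth_labels} and \code{query_labels}
#'   (character vectors aligned to the input rows) and \code{fallback}.
#' @export
match_clusters <- function(truth, query, ref_seq, span = NULL) {
  n_t <- nrow(truth); n_q <- nrow(query)
  if (n_t == 0 && n_q == 0)
    return(list(truth_labels = character(0), query_labels = character(0),
                fallback = FALSE))
  if (n_t == 0)
    return(list(truth_labels = character(0),
                query_labels = rep("FP", n_q), fallback = FALSE))
  if (n_q == 0)
    return(list(truth_labels = rep("FN", n_t),
                query_labels = character(0), fallback = FALSE))
  chrom <- c(truth$chrom, query$chrom)[1]
  if (is.null(span)) {
    all_pos <- c(truth$pos, query$pos)
    all_end <- c(truth$pos + nchar(truth$ref) - 1L,
                 query$pos + nchar(query$ref) - 1L)
    span <- c(min(all_pos), max(all_end))
  }
  ts <- haplotype_spellings(truth, chrom, span[1], span[2], ref_seq)
  qs <- haplotype_spellings(query, chrom, span[1], span[2], ref_seq)
  if (ts$inconsistent || qs$inconsistent) {
    vb_warn("inconsistent cluster at %s:%d (overlapping same-haplotype alleles); falling back to exact matching",
            chrom, span[1])
    return(c(exact_match(truth, query), list(fallback = TRUE)))
  }
  if (length(intersect(ts$pairs, qs$pairs)) > 0) {
    return(list(truth_labels = rep("TP", n_t),
                query_labels = rep("TP", n_q), fallback = FALSE))
  }
  c(exact_match(truth, query), list(fallback = FALSE))
}

exact_match <- function(truth, query) {
  tkey <- paste(truth$chrom, truth$pos, truth$ref, truth$alt, sep = "\r")
  qkey <- paste(query$chrom, query$pos, query$ref, query$alt, sep = "\r")
  tl <- rep("FN", nrow(truth)); ql <- rep("FP", nrow(query))
  used_q <- rep(FALSE, nrow(query))
  gt_key <- function(df) paste(pmin(df$gt1, df$gt2), pmax(df$gt1, df$gt2))
  tg <- gt_key(truth); qg <- gt_key(query)
  for (i in seq_along(tkey)) {
    j <- which(qkey == tkey[i] & !used_q)
    if (length(j) == 0) next
    j <- j[1]
    used_q[j] <- TRUE
    if (tg[i] == qg[j]) {
      tl[i] <- "TP"; ql[j] <- "TP"
    }
    # unequal genotype: truth stays FN, query stays FP
  }
  list(truth_labels = tl, query_labels = ql)
}
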