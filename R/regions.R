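#' Region sets: merged genomic intervals with a base count
#'
#' A \code{RegionSet} holds sorted, non-overlapping genomic intervals in BED
#' convention (0-based start, exclusive end). All interval algebra (merging,
#' padding, intersection, overlap queries) is delegated to
#' \pkg{GenomicRanges}/\pkg{IRanges}; this class fixes the coordinate
#' convention at the boundary and carries the total base count that the
#' negative-agreement metrics depend on.
#'
#' Construction always merges: overlapping and book-ended (end == start)
#' intervals are coalesced, so \code{total_bases()} is well defined and
#' invariant under input order and re-merging.
#'
#' @param chrom character vector of chromosome names, or a data frame with
#'   columns chrom/start/end.
#' @param start,end integer vectors; 0-based half-open intervals.
#' @return An object of class \code{RegionSet}.
#' @examples
#' rs <- region_set("chr1", c(0, 5), c(10, 20))
#' total_bases(rs) # 20: the two intervals merge
#' @export
region_set <- function(chrom = character(), start = integer(), end = integer()) {
  if (is.data.frame(chrom)) {
    df <- chrom
    chrom <- df$chrom; start <- df$start; end <- df$end
  }
  start <- as.numeric(start); end <- as.numeric(end)
  if (any(is.na(start)) || any(is.na(end)) || any(start != floor(start)) ||
      any(end != floor(end)))
    vb_stop("interval coordinates must be integers")
  if (any(start < 0)) vb_stop("interval start must be >= 0")
  if (any(start >= end)) vb_stop("interval start must be < end")
  gr <- GenomicRanges::GRanges(as.character(chrom),
                               IRanges::IRanges(start + 1, end))
  new_region_set(GenomicRanges::reduce(GenomicRanges::sort(gr)))
}

new_region_set <- function(gr) {
  structure(list(gr = gr), class = "RegionSet")
}

regions_granges <- function(rs) rs$gr

#' @rdname region_set
#' @param x a \code{RegionSet}.
#' @export
total_bases <- function(x) {
  sum(as.numeric(GenomicRanges::width(x$gr)))
}

#' @export
print.RegionSet <- function(x, ...) {
  cat(sprintf("RegionSet: %d interval(s), %s bases\n",
              length(x$gr), format(total_bases(x), big.mark = ",")))
  invisible(x)
}

#' @export
as.data.frame.RegionSet <- function(x, ...) {
  gr <- x$gr
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr),
             stringsAsFactors = FALSE)
}

#' Union of region sets
#'
#' @param ... \code{RegionSet} objects (or interval data frames).
#' @return A merged \code{RegionSet}.
#' @export
region_merge <- function(...) {
  parts <- lapply(list(...), function(r) {
    if (inherits(r, "RegionSet")) r$gr else region_set(r)$gr
  })
  gr <- do.call(c, c(parts, list(ignore.mcols = TRUE)))
  new_region_set(GenomicRanges::reduce(GenomicRanges::sort(gr)))
}

#' Pad every interval by a flank
#'
#' Extends each interval by \code{flank} bases on either end — the
#' convention used to pull canonical and non-canonical splice sites into an
#' exon-based reportable range — clamping at position 0 (and at the contig
#' length when \code{contig_lengths} is given), then re-merges.
#'
#' @param x a \code{RegionSet}.
#' @param flank non-negative integer, bases added on each side (default 20,
#'   the usual splice-site margin).
#' @param contig_lengths optional named vector bounding each contig.
#' @return A padded, merged \code{RegionSet}.
#' @export
region_pad <- function(x, flank = 20L, contig_lengths = NULL) {
  stopifnot(flank >= 0)
  if (flank == 0L) return(x)
  df <- as.data.frame(x)
  if (nrow(df) == 0) return(x)
  df$start <- pmax(0L, df$start - flank)
  df$end <- df$end + flank
  if (!is.null(contig_lengths)) {
    has <- df$chrom %in% names(contig_lengths)
    df$end[has] <- pmin(df$end[has], as.integer(contig_lengths[df$chrom[has]]))
  }
  region_set(df)
}

#' Intersection of two region sets
#'
#' @param a,b \code{RegionSet} objects.
#' @return Their intersection as a \code{RegionSet}; commutative, and
#'   \code{total_bases()} of the result never exceeds either input.
#' @export
region_intersect <- function(a, b) {
  ga <- a$gr; gb <- b$gr
  lv <- union(GenomeInfoDb::seqlevels(ga), GenomeInfoDb::seqlevels(gb))
  GenomeInfoDb::seqlevels(ga) <- lv
  GenomeInfoDb::seqlevels(gb) <- lv
  new_region_set(GenomicRanges::intersect(ga, gb))
}

empty_region_set <- function() {
  new_region_set(GenomicRanges::GRanges())
}

#' Build a clinically relevant region of interest
#'
#' Selects the exon intervals that contain at least one known pathogenic
#' site, pads them by \code{flank} bases on either end to capture splice
#' sites, and unions the result with any deep-intronic regions that carry
#' pathogenic variants. Deterministic in its inputs.
#'
#' @param sites data frame with columns \code{chrom} and \code{pos}
#'   (1-based positions of known pathogenic variants).
#' @param exons a \code{RegionSet} of exon intervals (coding and
#'   non-coding).
#' @param flank padding in bases (default 20).
#' @param deep_intronic optional \code{RegionSet} of deep-intronic regions,
#'   unioned unpadded.
#' @param contig_lengths optional named vector bounding the padding.
#' @return The clinical \code{RegionSet}; warns (not errors) when empty.
#' @export
build_clinical_roi <- function(sites, exons, flank = 20L,
                               deep_intronic = NULL, contig_lengths = NULL) {
  exdf <- as.data.frame(exons)
  keep <- rep(FALSE, nrow(exdf))
  if (nrow(exdf) && NROW(sites)) {
    site0 <- pos1_to_pos0(sites$pos)  # audited 1-based -> 0-based conversion
    for (i in seq_len(nrow(exdf))) {
      keep[i] <- any(sites$chrom == exdf$chrom[i] &
                       site0 >= exdf$start[i] & site0 < exdf$end[i])
    }
  }
  sel <- if (any(keep)) {
    region_pad(region_set(exdf[keep, , drop = FALSE]), flank, contig_lengths)
  } else {
    empty_region_set()
  }
  out <- if (!is.null(deep_intronic)) region_merge(sel, deep_intronic) else sel
  if (total_bases(out) == 0)
    vb_warn("clinical region of interest is empty")
  out
}

# The single place a 1-based site becomes a 0-based coordinate for
# containment tests; off-by-one here is the classic failure mode.
pos1_to_pos0 <- function(pos) as.integer(pos) - 1L

#' Read a BED file as a RegionSet
#'
#' Intervals are interpreted as 0-based half-open (BED standard); the result
#' is merged and sorted. Lines failing basic structural checks raise a parse
#' error naming the offending line.
#'
#' @param path BED file (>= 3 tab-separated columns per line).
#' @param chr_harmonize if TRUE, a leading "chr" prefix is stripped from
#'   contig names so "chr1" and "1" dialects can be mixed.
#' @return A \code{RegionSet}.
#' @export
read_bed <- function(path, chr_harmonize = FALSE) {
  if (!file.exists(path)) vb_stop("BED file not found: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  lines <- lines[!grepl("^(track|browser|#)", lines)]
  if (length(lines) == 0) return(empty_region_set())
  parts <- strsplit(lines, "\t", fixed = TRUE)
  for (i in seq_along(parts)) {
    p <- parts[[i]]
    if (length(p) < 3)
      vb_stop("BED parse error at line %d: fewer than 3 columns", i)
    s <- suppressWarnings(as.integer(p[2])); e <- suppressWarnings(as.integer(p[3]))
    if (is.na(s) || is.na(e))
      vb_stop("BED parse error at line %d: non-integer coordinates", i)
    if (s >= e)
      vb_stop("BED parse error at line %d: start >= end", i)
  }
  chrom <- vapply(parts, `[[`, "", 1L)
  if (chr_harmonize) chrom <- sub("^chr", "", chrom)
  region_set(chrom,
             vapply(parts, function(p) as.integer(p[2]), 0L),
             vapply(parts, function(p) as.integer(p[3]), 0L))
}

#' Write a RegionSet to BED3
#'
#' @param x a \code{RegionSet}.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  df <- as.data.frame(x)
  writeLines(sprintf("%s\t%d\t%d", df$chrom, df$start, df$end), path)
  invisible(path)
}
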