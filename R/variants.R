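#' Construct a table of biallelic variant records
#'
#' The atom of comparison throughout the package is a normalized, biallelic
#' variant call with a genotype. Records are held in an ordinary data frame
#' (class \code{"variant_table"}) with one row per record and columns
#' \code{chrom}, \code{pos} (1-based, VCF convention), \code{ref},
#' \code{alt}, \code{gt1}, \code{gt2} (allele indices in \{0, 1\}),
#' \code{phased}, \code{filter} and \code{sample_id}.
#'
#' @param chrom character vector of chromosome names.
#' @param pos integer vector of 1-based reference positions.
#' @param ref,alt character vectors of reference / alternate alleles
#'   (A/C/G/T/N; uppercased on construction).
#' @param gt1,gt2 integer allele indices, each 0 (ref) or 1 (alt). A
#'   homozygous-reference genotype (0/0) is not a variant record and is
#'   rejected.
#' @param phased logical; whether gt1/gt2 carry haplotype identity
#'   (\code{|} in VCF).
#' @param filter character; VCF FILTER field ("." and "PASS" both mean
#'   passing).
#' @param sample_id character label attached to every record.
#' @return A \code{variant_table} data frame sorted by (chrom, pos).
#' @examples
#' variant_table("chr1", 100L, "A", "G", 0L, 1L)
#' @export
variant_table <- function(chrom = character(), pos = integer(),
                          ref = character(), alt = character(),
                          gt1 = integer(), gt2 = integer(),
                          phased = FALSE, filter = "PASS",
                          sample_id = "sample") {
  n <- length(chrom)
  df <- data.frame(
    chrom = as.character(chrom),
    pos = as.integer(pos),
    ref = toupper(as.character(ref)),
    alt = toupper(as.character(alt)),
    gt1 = as.integer(rep_len(gt1, n)),
    gt2 = as.integer(rep_len(gt2, n)),
    phased = rep_len(as.logical(phased), n),
    filter = rep_len(as.character(filter), n),
    sample_id = rep_len(as.character(sample_id), n),
    stringsAsFactors = FALSE
  )
  validate_variant_table(as_variant_table(df))
}

as_variant_table <- function(df) {
  class(df) <- c("variant_table", "data.frame")
  df
}

validate_variant_table <- function(df) {
  if (nrow(df) == 0) return(sort_variants(df))
  if (any(df$pos < 1L)) vb_stop("variant positions must be >= 1")
  if (any(!nzchar(df$ref)) || any(!nzchar(df$alt)))
    vb_stop("ref and alt alleles must be non-empty")
  bad <- grepl("[^ACGTN]", df$ref) | grepl("[^ACGTN]", df$alt)
  if (any(bad))
    vb_stop("non-nucleotide allele at %s:%d", df$chrom[which(bad)[1]],
            df$pos[which(bad)[1]])
  if (any(!(df$gt1 %in% 0:1)) || any(!(df$gt2 %in% 0:1)))
    vb_stop("genotype indices must be 0 or 1 after decomposition")
  if (any(df$gt1 == 0L & df$gt2 == 0L))
    vb_stop("homozygous-reference (0/0) records are not variant calls")
  sort_variants(df)
}

sort_variants <- function(df) {
  df <- df[order(df$chrom, df$pos, df$ref, df$alt), , drop = FALSE]
  rownames(df) <- NULL
  as_variant_table(df)
}

# 1-based inclusive reference footprint; an insertion occupies its anchor base
variant_end <- function(df) df$pos + nchar(df$ref) - 1L

#' Variant type of each record
#'
#' SNP: single-base substitution; MNP: equal-length multi-base substitution;
#' INDEL: length-changing allele pair.
#'
#' @param df a \code{variant_table}.
#' @return character vector in \{"SNP", "MNP", "INDEL"\}.
#' @export
variant_type <- function(df) {
  nr <- nchar(df$ref); na <- nchar(df$alt)
  ifelse(nr != na, "INDEL", ifelse(nr == 1L, "SNP", "MNP"))
}

#' @export
print.variant_table <- function(x, ...) {
  cat(sprintf("variant_table: %d record(s)\n", nrow(x)))
  if (nrow(x)) print.data.frame(utils::head(as.data.frame(x), 20), ...)
  if (nrow(x) > 20) cat(sprintf("... and %d more\n", nrow(x) - 20L))
  invisible(x)
}

variants_to_granges <- function(df) {
  GenomicRanges::GRanges(df$chrom, IRanges::IRanges(df$pos, variant_end(df)))
}
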