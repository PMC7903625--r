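#' Decompose multi-allelic records into biallelic variant records
#'
#' Splits each raw VCF record into one biallelic record per alternate
#' allele actually carried by the genotype, recoding the genotype against
#' alleles \{0 (ref), 1 (alt)\}. A het-alt genotype such as 1/2 yields two
#' heterozygous records; alleles not carried by the genotype are dropped,
#' and homozygous-reference records are never emitted.
#'
#' @param df raw records from [read_vcf()] (ALT may be comma-joined,
#'   genotype indices unrestricted).
#' @return A validated \code{variant_table}.
#' @export
decompose_multiallelic <- function(df) {
  if (nrow(df) == 0)
    return(variant_table())
  rows <- vector("list", nrow(df))
  for (i in seq_len(nrow(df))) {
    alts <- strsplit(df$alt[i], ",", fixed = TRUE)[[1]]
    g <- c(df$gt1[i], df$gt2[i])
    if (any(g > length(alts)))
      vb_stop("genotype at %s:%d references allele %d but record has %d ALT allele(s)",
              df$chrom[i], df$pos[i], max(g), length(alts))
    carried <- sort(unique(g[g > 0L]))
    if (length(carried) == 0) next  # 0/0: not a variant call
    sub <- lapply(carried, function(a) {
      data.frame(chrom = df$chrom[i], pos = df$pos[i], ref = df$ref[i],
                 alt = alts[a],
                 gt1 = as.integer(g[1] == a), gt2 = as.integer(g[2] == a),
                 phased = df$phased[i], filter = df$filter[i],
                 sample_id = df$sample_id[i], stringsAsFactors = FALSE)
    })
    rows[[i]] <- do.call(rbind, sub)
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  if (is.null(out)) return(variant_table())
  out <- out[out$alt != "*", , drop = FALSE]  # spanning-deletion placeholder
  validate_variant_table(as_variant_table(out))
}

#' Normalize variants to a parsimonious, left-most representation
#'
#' Each record is trimmed of its shared allele suffix and then prefix
#' (always retaining at least one base on each side for length-changing
#' records, per VCF anchoring), and InDels are then left-shifted one base at
#' a time while the identical allele strings still match the reference at
#' the shifted position and spell the same alternate haplotype. The result
#' is parsimonious, left-most under this shift rule, and the operation is
#' idempotent.
#'
#' @param df a \code{variant_table} (or compatible data frame).
#' @param ref_seq a reference accessor from [ref_accessor()].
#' @return The normalized \code{variant_table}, re-sorted.
#' @examples
#' ref <- ref_accessor(c(chr1 = "CATTTTG"))
#' v <- variant_table("chr1", 4L, "TT", "T", 0L, 1L)
#' normalize_variants(v, ref)$pos # 3: start of the homopolymer run
#' @export
normalize_variants <- function(df, ref_seq) {
  if (nrow(df) == 0) return(as_variant_table(df))
  check_ref_alleles(df, ref_seq)
  for (i in seq_len(nrow(df))) {
    nv <- normalize_one(df$chrom[i], df$pos[i], df$ref[i], df$alt[i], ref_seq)
    df$pos[i] <- nv$pos; df$ref[i] <- nv$ref; df$alt[i] <- nv$alt
  }
  validate_variant_table(as_variant_table(df))
}

normalize_one <- function(chrom, pos, ref, alt, ref_seq) {
  if (identical(ref, alt))
    vb_stop("ref and alt identical at %s:%d", chrom, pos)
  # trim shared suffix, retaining >= 1 base on each side
  while (nchar(ref) > 1L && nchar(alt) > 1L &&
         substr(ref, nchar(ref), nchar(ref)) == substr(alt, nchar(alt), nchar(alt))) {
    ref <- substr(ref, 1L, nchar(ref) - 1L)
    alt <- substr(alt, 1L, nchar(alt) - 1L)
  }
  # trim shared prefix, advancing pos
  while (nchar(ref) > 1L && nchar(alt) > 1L &&
         substr(ref, 1L, 1L) == substr(alt, 1L, 1L)) {
    ref <- substr(ref, 2L, nchar(ref))
    alt <- substr(alt, 2L, nchar(alt))
    pos <- pos + 1L
  }
  if (nchar(ref) != nchar(alt)) {
    # left-shift the identical allele strings while they still match the
    # reference and spell the same alternate haplotype
    while (pos > 1L && can_shift_left(chrom, pos, ref, alt, ref_seq)) {
      pos <- pos - 1L
    }
  }
  list(pos = pos, ref = ref, alt = alt)
}

can_shift_left <- function(chrom, pos, ref, alt, ref_seq) {
  newpos <- pos - 1L
  rl <- nchar(ref)
  if (!identical(ref_seq(chrom, newpos, newpos + rl - 1L), ref)) return(FALSE)
  # compare spelled alternate sequence over the combined window
  win_start <- newpos
  win_end <- pos + rl - 1L
  spell <- function(p) {
    paste0(ref_seq(chrom, win_start, p - 1L), alt,
           ref_seq(chrom, p + rl, win_end))
  }
  identical(spell(newpos), spell(pos))
}
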