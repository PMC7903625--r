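#' Verify the presence of named clinical variants in a query callset
#'
#' For each asserted variant (chrom, pos, ref, alt) the query VCF is
#' searched for a haplotype-equivalent call, robust to representation
#' differences: the assertion is normalized, the query records near it are
#' gathered, and the verdict is Yes when some subset of those records —
#' applied together to one haplotype — spells the same local sequence as
#' the assertion's own alternate haplotype. Subset search (rather than
#' whole-cluster comparison) lets several adjacent clinical variants be
#' verified independently, as required when a sample carries a run of
#' nearby pathogenic calls.
#'
#' Genotype is not required to match unless the assertion specifies one
#' ("hom" requires every matching record homozygous; "het" at least one
#' heterozygous).
#'
#' @param assertions data frame from [read_assertions()] (columns sample,
#'   chrom, pos, ref, alt, optional genotype, expected).
#' @param query raw records from [read_vcf()] or a \code{variant_table}.
#' @param ref_seq reference accessor from [ref_accessor()].
#' @param window bases of context searched around the assertion footprint
#'   (default 30).
#' @param max_members cap on nearby query records enumerated (default 8).
#' @return The assertion table with logical \code{detected} and character
#'   \code{verdict} ("Yes"/"No") columns appended.
#' @export
verify_variants <- function(assertions, query, ref_seq, window = 30L,
                            max_members = 8L) {
  qn <- split_mnps(normalize_variants(decompose_if_needed(query), ref_seq))
  if (is.null(assertions$genotype)) assertions$genotype <- NA_character_
  assertions$detected <- FALSE
  for (i in seq_len(nrow(assertions))) {
    a <- assertions[i, ]
    av <- variant_table(a$chrom, a$pos, a$ref, a$alt, 0L, 1L)
    # reference-mismatch here is an input error, not a "No"
    check_ref_alleles(av, ref_seq)
    av <- normalize_variants(av, ref_seq)
    assertions$detected[i] <- assertion_detected(av, a$genotype, qn, ref_seq,
                                                 window, max_members)
  }
  assertions$verdict <- ifelse(assertions$detected, "Yes", "No")
  assertions
}

# query MNPs are split into their per-base SNP primitives so that an
# assertion for a constituent substitution can still verify
split_mnps <- function(df) {
  is_mnp <- nchar(df$ref) == nchar(df$alt) & nchar(df$ref) > 1L
  if (!any(is_mnp)) return(df)
  keep <- df[!is_mnp, , drop = FALSE]
  parts <- lapply(which(is_mnp), function(i) {
    r <- strsplit(df$ref[i], "")[[1]]; a <- strsplit(df$alt[i], "")[[1]]
    k <- which(r != a)
    out <- df[rep(i, length(k)), , drop = FALSE]
    out$pos <- df$pos[i] + k - 1L
    out$ref <- r[k]; out$alt <- a[k]
    out
  })
  out <- rbind(keep, do.call(rbind, parts))
  sort_variants(as_variant_table(out))
}

assertion_detected <- function(av, genotype, qn, ref_seq, window, max_members) {
  chrom <- av$chrom[1]
  a_start <- av$pos[1]; a_end <- a_start + nchar(av$ref[1]) - 1L
  lens <- attr(ref_seq, "lengths")
  if (!chrom %in% names(lens)) return(FALSE)
  win_start <- max(1L, a_start - window)
  win_end <- min(as.integer(lens[[chrom]]), a_end + window)
  near <- qn[qn$chrom == chrom & qn$pos <= win_end &
               variant_end(qn) >= win_start, , drop = FALSE]
  if (nrow(near) == 0) return(FALSE)
  if (nrow(near) > max_members) {
    d <- abs(near$pos - a_start)
    near <- near[order(d)[seq_len(max_members)], , drop = FALSE]
  }
  # widen the spelling window to cover every candidate footprint
  win_start <- min(win_start, min(near$pos))
  win_end <- max(win_end, max(variant_end(near)))
  target <- apply_alleles(as.data.frame(av), chrom, win_start, win_end, ref_seq)
  refspell <- ref_seq(chrom, win_start, win_end)
  if (identical(target, refspell)) return(FALSE)  # degenerate assertion
  n <- nrow(near)
  for (mask in 1:(2^n - 1L)) {
    on <- bitwAnd(mask, bitwShiftL(1L, seq_len(n) - 1L)) > 0L
    sub <- near[on, , drop = FALSE]
    spelled <- apply_alleles(sub, chrom, win_start, win_end, ref_seq)
    if (is.null(spelled) || !identical(spelled, target)) next
    if (is.na(genotype) || !nzchar(genotype)) return(TRUE)
    hom <- sub$gt1 == 1L & sub$gt2 == 1L
    if (identical(tolower(genotype), "hom") && all(hom)) return(TRUE)
    if (identical(tolower(genotype), "het") && any(!hom)) return(TRUE)
  }
  FALSE
}
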