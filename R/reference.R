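#' Reference-sequence accessor
#'
#' Wraps a reference genome as a simple lookup function
#' \code{f(chrom, start, end)} returning the uppercase sequence on the
#' 1-based inclusive interval. Soft-masked (lowercase) bases are uppercased,
#' so comparisons never distinguish masking state.
#'
#' @param x a FASTA file path, a named character vector of contig
#'   sequences, or a [Biostrings::DNAStringSet].
#' @return A function \code{(chrom, start, end)}; its
#'   \code{attr(, "lengths")} gives the named contig lengths.
#' @examples
#' ref <- ref_accessor(c(chr1 = "ACGTACGT"))
#' ref("chr1", 2, 4) # "CGT"
#' @export
ref_accessor <- function(x) {
  if (is.character(x) && length(x) == 1L && is.null(names(x)) && file.exists(x)) {
    ss <- Biostrings::readDNAStringSet(x)
    seqs <- toupper(as.character(ss))
    names(seqs) <- sub("\\s.*$", "", names(seqs))
  } else if (methods::is(x, "DNAStringSet")) {
    seqs <- toupper(as.character(x))
    names(seqs) <- sub("\\s.*$", "", names(x))
  } else if (is.character(x) && !is.null(names(x))) {
    seqs <- toupper(x)
  } else {
    vb_stop("cannot interpret reference input (need FASTA path, named character vector or DNAStringSet)")
  }
  lens <- setNames(nchar(seqs), names(seqs))
  f <- function(chrom, start, end) {
    if (!chrom %in% names(seqs))
      vb_stop("contig '%s' absent from reference", chrom)
    n <- lens[[chrom]]
    if (start < 1L || end > n || start > end + 1L)
      vb_stop("reference window %s:%d-%d out of bounds (contig length %d)",
              chrom, start, end, n)
    if (start > end) return("")  # empty window (insertion edge case)
    substr(seqs[[chrom]], start, end)
  }
  attr(f, "lengths") <- lens
  f
}

#' Write contig sequences to FASTA
#'
#' @param seqs named character vector of sequences.
#' @param path output file.
#' @param width line wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  ss <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(ss, path, width = width)
  invisible(path)
}

# check that every record's ref allele agrees with the reference sequence
check_ref_alleles <- function(df, ref_seq) {
  if (nrow(df) == 0) return(invisible(TRUE))
  for (i in seq_len(nrow(df))) {
    obs <- ref_seq(df$chrom[i], df$pos[i], df$pos[i] + nchar(df$ref[i]) - 1L)
    if (!identical(obs, df$ref[i]))
      vb_stop("reference mismatch at %s:%d: record says '%s', reference has '%s'",
              df$chrom[i], df$pos[i], df$ref[i], obs,
              class = "varbench_ref_mismatch")
  }
  invisible(TRUE)
}
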