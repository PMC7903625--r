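# internal helpers shared across modules

# half-up rounding at d decimals; base round() rounds half-to-even, which
# disagrees with the rendering used in clinical validation tables
round_half_up <- function(x, d = 2) {
  out <- floor(x * 10^d + 0.5) / 10^d
  out[is.na(x)] <- NA_real_
  out
}

vb_stop <- function(fmt, ..., class = "varbench_error") {
  stop(errorCondition(sprintf(fmt, ...), class = c(class, "error", "condition")))
}

vb_warn <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# file checksum line used by the consolidated report; md5 keeps provenance
# stable across platforms
checksum_line <- function(path) {
  sprintf("%s  %s", unname(tools::md5sum(path)), basename(path))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
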