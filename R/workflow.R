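#' Read and validate a benchmark run configuration
#'
#' The configuration is a YAML file describing a multi-sample validation
#' run:
#' \preformatted{
#' reference: ref.fa
#' samples:
#'   - sample_id: NA12878
#'     query: q.vcf
#'     truth: t.vcf
#'     confident: conf.bed     # optional
#' rois:
#'   clinical: clinical.bed
#'   exome: exome.bed
#' assertions: assertions.tsv  # optional
#' options:                    # all optional
#'   window: 30
#'   max_cluster_size: 8
#'   pass_only: true
#'   chr_harmonize: false
#'   npa_integer: false
#'   bins: [10, 20, 50]
#'   merge_bins: {"1-20": ["1-10", "11-20"]}
#' }
#' Relative paths are resolved against the configuration file's directory.
#' Every referenced file must exist; sample ids and ROI names must be
#' unique.
#'
#' @param path YAML configuration file.
#' @return A validated list of class \code{run_config}.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) vb_stop("config file not found: %s", path)
  cfg <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  resolve <- function(p) {
    if (is.null(p)) return(NULL)
    if (!grepl("^(/|[A-Za-z]:)", p)) p <- file.path(base, p)
    p
  }
  cfg$reference <- resolve(cfg$reference)
  cfg$assertions <- resolve(cfg$assertions)
  for (i in seq_along(cfg$samples)) {
    for (f in c("query", "truth", "confident"))
      cfg$samples[[i]][[f]] <- resolve(cfg$samples[[i]][[f]])
  }
  cfg$rois <- lapply(cfg$rois, resolve)
  validate_run_config(cfg)
}

validate_run_config <- function(cfg) {
  if (is.null(cfg$reference)) vb_stop("config: 'reference' is required",
                                      class = "varbench_config_error")
  if (length(cfg$samples) == 0) vb_stop("config: at least one sample required",
                                        class = "varbench_config_error")
  if (length(cfg$rois) == 0) vb_stop("config: at least one ROI required",
                                     class = "varbench_config_error")
  ids <- vapply(cfg$samples, function(s) s$sample_id %||% "", "")
  if (any(!nzchar(ids)) || anyDuplicated(ids))
    vb_stop("config: sample_id must be present and unique",
            class = "varbench_config_error")
  if (is.null(names(cfg$rois)) || anyDuplicated(names(cfg$rois)))
    vb_stop("config: ROI names must be present and unique",
            class = "varbench_config_error")
  files <- c(cfg$reference, cfg$assertions, unlist(cfg$rois),
             unlist(lapply(cfg$samples, function(s)
               c(s$query, s$truth, s$confident))))
  missing <- files[!file.exists(files)]
  if (length(missing))
    vb_stop("config references missing file(s): %s",
            paste(missing, collapse = ", "), class = "varbench_config_error")
  opts <- cfg$options %||% list()
  cfg$options <- list(
    window = as.integer(opts$window %||% 30L),
    max_cluster_size = as.integer(opts$max_cluster_size %||% 8L),
    pass_only = isTRUE(opts$pass_only %||% TRUE),
    chr_harmonize = isTRUE(opts$chr_harmonize %||% FALSE),
    npa_integer = isTRUE(opts$npa_integer %||% FALSE),
    bins = as.integer(unlist(opts$bins %||% c(10L, 20L, 50L))),
    merge_bins = opts$merge_bins
  )
  class(cfg) <- "run_config"
  cfg
}

#' Run the end-to-end benchmark
#'
#' For each sample and region of interest: classify the query against the
#' truth inside the confidence/ROI intersection, write the annotated
#' comparison VCF and per-type/per-label splits, the InDel size spectrum
#' (TSV and PDF) and the stratified metrics table; then consolidate all
#' strata — plus the clinical-variant verification table, when an
#' assertion file is configured — into one deterministic validation report
#' with input checksums. A failure in one sample-ROI stratum is logged and
#' skipped; the remaining strata still run, and the returned status
#' reflects the partial failure.
#'
#' @param cfg a \code{run_config} from [read_run_config()], or a path to
#'   the YAML file.
#' @param outdir output directory.
#' @return Invisibly, a list of class \code{varbench_run}: per-stratum
#'   \code{results}, combined \code{metrics}, \code{verification},
#'   \code{failures} and the \code{report} path. Status is "ok" when every
#'   stratum succeeded, "partial" otherwise.
#' @export
run_benchmark <- function(cfg, outdir) {
  if (is.character(cfg)) cfg <- read_run_config(cfg)
  stopifnot(inherits(cfg, "run_config"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  op <- cfg$options
  ref <- ref_accessor(cfg$reference)
  binning <- size_binning(op$bins)
  results <- list(); failures <- list(); metrics_rows <- list()
  merged_rows <- list()
  # deterministic iteration order regardless of config listing order
  sample_order <- order(vapply(cfg$samples, `[[`, "", "sample_id"))
  for (s in cfg$samples[sample_order]) {
    truth <- read_vcf(s$truth, sample_id = s$sample_id,
                      chr_harmonize = op$chr_harmonize)
    query <- read_vcf(s$query, sample_id = s$sample_id,
                      chr_harmonize = op$chr_harmonize)
    confident <- if (!is.null(s$confident))
      read_bed(s$confident, chr_harmonize = op$chr_harmonize) else NULL
    for (rn in sort(names(cfg$rois))) {
      tag <- sprintf("%s.%s", s$sample_id, rn)
      res <- tryCatch({
        roi <- read_bed(cfg$rois[[rn]], chr_harmonize = op$chr_harmonize)
        cl <- classify(truth, query, roi, ref, confident = confident,
                       window = op$window,
                       max_cluster_size = op$max_cluster_size,
                       pass_only = op$pass_only, binning = binning)
        sdir <- file.path(outdir, tag)
        dir.create(sdir, recursive = TRUE, showWarnings = FALSE)
        write_annotated_vcf(cl$classified, file.path(sdir, "comparison.vcf"))
        write_stratum_splits(cl$classified, sdir)
        spectrum_histogram(cl$classified, binning,
                           tsv = file.path(sdir, "indel_spectrum.tsv"),
                           plot = file.path(sdir, "indel_spectrum.pdf"))
        mr <- compute_metrics(cl$counts)
        mr$sample <- s$sample_id; mr$region <- rn
        write_metrics_table(mr, file.path(sdir, "metrics.tsv"),
                            npa_integer = op$npa_integer)
        if (!is.null(op$merge_bins)) {
          per_bin <- cl$counts[cl$counts$variant_type == "INDEL" &
                                 cl$counts$size_bin != "ALL", , drop = FALSE]
          mb <- merge_bins(per_bin, op$merge_bins)
          mb$variant_type <- "INDEL"
          mb$sample <- s$sample_id; mb$region <- rn
          merged_rows[[tag]] <- mb
        }
        metrics_rows[[tag]] <- mr
        cl
      }, error = function(e) e)
      if (inherits(res, "error")) {
        vb_warn("stratum %s failed: %s", tag, conditionMessage(res))
        failures[[tag]] <- conditionMessage(res)
      } else {
        results[[tag]] <- res
      }
    }
  }
  verification <- NULL
  if (!is.null(cfg$assertions)) {
    assertions <- read_assertions(cfg$assertions)
    vparts <- list()
    for (s in cfg$samples[sample_order]) {
      sub <- assertions[assertions$sample == s$sample_id, , drop = FALSE]
      if (nrow(sub) == 0) next
      query <- read_vcf(s$query, sample_id = s$sample_id,
                        chr_harmonize = op$chr_harmonize)
      vparts[[s$sample_id]] <- verify_variants(sub, query, ref,
                                               window = op$window)
    }
    if (length(vparts)) verification <- do.call(rbind, vparts)
  }
  metrics <- do.call(rbind, metrics_rows)
  merged <- if (length(merged_rows)) do.call(rbind, merged_rows) else NULL
  report <- file.path(outdir, "final_benchmarking_metrics.txt")
  if (!is.null(metrics)) {
    inputs <- unique(c(cfg$reference, cfg$assertions, unlist(cfg$rois),
                       unlist(lapply(cfg$samples, function(s)
                         c(s$query, s$truth, s$confident)))))
    consolidate(metrics, report, verification = verification, merged = merged,
                input_files = inputs,
                config_lines = sprintf("%s=%s", names(op)[order(names(op))],
                                       vapply(op[order(names(op))], function(x)
                                         paste(format(unlist(x) %||% ""),
                                               collapse = ","), "")),
                npa_integer = op$npa_integer)
  }
  out <- structure(list(results = results, metrics = metrics,
                        verification = verification, failures = failures,
                        report = report,
                        status = if (length(failures)) "partial" else "ok"),
                   class = "varbench_run")
  invisible(out)
}

# per-type, per-label VCF splits of the annotated comparison (one file per
# non-empty stratum), mirroring the split stage of the benchmark
write_stratum_splits <- function(classified, dir) {
  for (vt in unique(classified$variant_type)) {
    for (lb in unique(classified$label)) {
      sub <- classified[classified$variant_type == vt &
                          classified$label == lb, , drop = FALSE]
      if (nrow(sub) == 0) next
      write_annotated_vcf(sub, file.path(dir, sprintf("%s_%s.vcf", vt, lb)))
    }
  }
  invisible(NULL)
}

#' @export
print.varbench_run <- function(x, ...) {
  cat(sprintf("varbench run: %d stratum result(s), status %s\n",
              length(x$results), x$status))
  cat(sprintf("report: %s\n", x$report))
  if (length(x$failures))
    cat(sprintf("failed: %s\n", paste(names(x$failures), collapse = ", ")))
  invisible(x)
}
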