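# Read quality control for long-read 16S amplicon FASTQ files.

#' Filter reads by length and mean quality
#'
#' Retains reads with length >= `min_length` *and* arithmetic mean
#' per-base PHRED score >= `min_mean_q`; the defaults (400 bp, Q7) are
#' the usual gate for full-length 16S nanopore amplicons.  Thresholds
#' are inclusive: the filter removes reads strictly shorter / strictly
#' below the quality bound.  Removal reasons are tallied with length
#' taking precedence over quality.
#'
#' Requires the `Biostrings` package (PHRED+33 FASTQ).
#'
#' @param input path to a FASTQ file, or a
#'   `Biostrings::QualityScaledDNAStringSet`.
#' @param output optional path; when given, retained reads are written
#'   there as FASTQ.
#' @param min_length minimum read length in bp.
#' @param min_mean_q minimum mean PHRED quality.
#' @return List of class `read_qc`: `reads` (the retained set),
#'   `total`, `retained`, `removed_length`, `removed_quality`, and the
#'   logical vector `keep`.
#' @export
filter_reads <- function(input, output = NULL, min_length = 400,
                         min_mean_q = 7) {
  if (!requireNamespace("Biostrings", quietly = TRUE)) {
    abort("the 'Biostrings' package is required for FASTQ filtering",
          "digestor_dependency_error")
  }
  reads <- if (is.character(input)) {
    tryCatch(
      # Biostrings warns about dropped metadata columns on every read
      suppressWarnings(Biostrings::readQualityScaledDNAStringSet(input)),
      error = function(e) abort(
        sprintf("malformed FASTQ '%s': %s", input, conditionMessage(e)),
        "digestor_parse_error"))
  } else input
  len <- Biostrings::width(reads)
  quals <- tryCatch({
    qwidth <- Biostrings::width(Biostrings::quality(reads))
    if (any(qwidth != len)) {
      stop(sprintf("sequence/quality length mismatch at record(s) %s",
                   paste(utils::head(which(qwidth != len), 5),
                         collapse = ", ")))
    }
    methods::as(Biostrings::quality(reads), "IntegerList")
  }, error = function(e) abort(
    paste0("malformed FASTQ qualities: ", conditionMessage(e)),
    "digestor_parse_error"))
  mean_q <- vapply(quals, function(q) {
    if (length(q)) mean(q) else 0
  }, numeric(1))
  short <- len < min_length
  lowq <- !short & mean_q < min_mean_q
  keep <- !short & !lowq
  kept <- reads[keep]
  if (!is.null(output)) {
    Biostrings::writeQualityScaledXStringSet(kept, output)
  }
  structure(
    list(reads = kept, total = length(reads), retained = sum(keep),
         removed_length = sum(short), removed_quality = sum(lowq),
         keep = keep, min_length = min_length, min_mean_q = min_mean_q),
    class = "read_qc")
}

#' @export
print.read_qc <- function(x, ...) {
  cat(sprintf(
    "<read_qc> %d reads: %d retained, %d removed (length < %g), %d removed (mean Q < %g)\n",
    x$total, x$retained, x$removed_length, x$min_length,
    x$removed_quality, x$min_mean_q))
  invisible(x)
}
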