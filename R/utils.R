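# Shared internal helpers: validation, interval conversion, logging.

TIMEPOINTS_H <- c(0, 0.5, 1, 2, 6)
CHIP_TIMEPOINTS_H <- c(0, 0.5, 1, 2)
GENOTYPES <- c("WT", "Nfkb1", "Nfkbiz", "Bcl3", "Nfkbid")
STIMULI <- c("lipidA", "TNF")

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Ratio with a pseudocount on both terms
#'
#' Computes `(num + eps) / (den + eps)`; used for binding-preference and
#' binding-dependence ratios where either term may be zero.
#' @param num,den nonnegative numerics.
#' @param eps pseudocount (RPKM units).
#' @return numeric ratio vector.
#' @keywords internal
pseudo_ratio <- function(num, den, eps = 0.1) {
  stopifnot(eps > 0)
  (num + eps) / (den + eps)
}

# Validate a peak data.frame (chrom/start/end/peak_id/score + rpkm columns).
validate_peaks <- function(peaks, context = "peak table") {
  need <- c("chrom", "start", "end", "peak_id", "score")
  miss <- setdiff(need, names(peaks))
  if (length(miss)) {
    stop(context, " is missing columns: ", paste(miss, collapse = ", "))
  }
  bad <- which(peaks$start >= peaks$end)
  if (length(bad)) {
    stop(context, ": start >= end at row(s) ", paste(head(bad, 5), collapse = ", "))
  }
  if (any(peaks$score < 0)) stop(context, ": negative peak score")
  rk <- rpkm_columns(peaks)
  if (length(rk) && any(as.matrix(peaks[rk]) < 0)) {
    stop(context, ": negative RPKM")
  }
  if (anyDuplicated(peaks$peak_id)) stop(context, ": duplicate peak_id")
  invisible(peaks)
}

rpkm_columns <- function(peaks) {
  setdiff(names(peaks), c("chrom", "start", "end", "peak_id", "score"))
}

# 0-based half-open peak rows -> GRanges (1-based closed, as IRanges expects).
peaks_to_granges <- function(peaks) {
  GenomicRanges::GRanges(
    seqnames = peaks$chrom,
    ranges = IRanges::IRanges(start = peaks$start + 1L, end = peaks$end),
    peak_id = peaks$peak_id
  )
}

granges_to_peaks <- function(gr, peak_id = NULL) {
  data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    peak_id = peak_id %||% sprintf("loc_%05d", seq_along(gr)),
    stringsAsFactors = FALSE
  )
}

# One structured log line per pipeline stage.
stage_log <- function(stage, ..., verbose = getOption("nfkbcodep.verbose", FALSE)) {
  if (!isTRUE(verbose)) return(invisible(NULL))
  kv <- list(...)
  msg <- paste(sprintf("%s=%s", names(kv), vapply(kv, function(v)
    paste(format(v), collapse = ","), character(1))), collapse = " ")
  message(sprintf("[nfkbcodep] stage=%s %s", stage, msg))
  invisible(NULL)
}

# Float serialization convention for all TSV writers: 6 significant digits.
format_num <- function(x) {
  ifelse(is.na(x), "NA", formatC(x, digits = 6, format = "g"))
}

write_tsv_file <- function(df, path) {
  num <- vapply(df, is.double, logical(1))
  out <- df
  out[num] <- lapply(df[num], format_num)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

read_tsv_file <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, check.names = FALSE)
}
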