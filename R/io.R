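#' Read a BED-like peak table
#'
#' Peak files are headerless tab-separated tables in the BED dialect used
#' throughout the pipeline: `chrom`, `start`, `end` (0-based half-open),
#' `peak_id`, peak score in column 5, then one RPKM column per sample.
#' Sample labels come either from `sample_labels` or from a sidecar file
#' `<path>.samples` (one label per line) written by [write_peak_table()].
#'
#' @param path path to the peak table.
#' @param sample_labels character vector naming the RPKM columns in order;
#'   if `NULL` the sidecar file is consulted.
#' @return A data.frame with columns `chrom`, `start`, `end`, `peak_id`,
#'   `score`, and one numeric column per sample.
#' @export
read_peak_table <- function(path, sample_labels = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (is.null(sample_labels)) {
    sidecar <- paste0(path, ".samples")
    if (file.exists(sidecar)) sample_labels <- readLines(sidecar)
  }
  if (!length(lines)) {
    cols <- c("chrom", "start", "end", "peak_id", "score", sample_labels)
    out <- as.data.frame(matrix(nrow = 0, ncol = length(cols)))
    names(out) <- cols
    out$chrom <- character(0); out$peak_id <- character(0)
    for (nm in setdiff(cols, c("chrom", "peak_id"))) out[[nm]] <- numeric(0)
    out$start <- integer(0); out$end <- integer(0)
    return(out)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 4)) {
    stop("parse error at line ", which(nf < 4)[1], ": fewer than 4 columns")
  }
  if (length(unique(nf)) != 1) {
    stop("parse error at line ", which(nf != nf[1])[1],
         ": inconsistent column count")
  }
  m <- do.call(rbind, fields)
  n_rpkm <- ncol(m) - 5L
  if (n_rpkm < 0) n_rpkm <- 0L
  if (is.null(sample_labels)) {
    sample_labels <- if (n_rpkm > 0) sprintf("s%d", seq_len(n_rpkm)) else character(0)
  }
  if (length(sample_labels) != n_rpkm) {
    stop("expected ", length(sample_labels), " RPKM columns, found ", n_rpkm)
  }
  suppress_na <- function(x, what) {
    y <- suppressWarnings(as.numeric(x))
    if (anyNA(y)) stop("parse error at line ", which(is.na(y))[1],
                       ": non-numeric ", what)
    y
  }
  peaks <- data.frame(
    chrom = m[, 1],
    start = as.integer(suppress_na(m[, 2], "start")),
    end = as.integer(suppress_na(m[, 3], "end")),
    peak_id = m[, 4],
    score = if (ncol(m) >= 5) suppress_na(m[, 5], "score") else 0,
    stringsAsFactors = FALSE
  )
  for (j in seq_len(n_rpkm)) {
    peaks[[sample_labels[j]]] <- suppress_na(m[, 5L + j], "RPKM")
  }
  validate_peaks(peaks, context = path)
  stage_log("read_peak_table", path = path, n = nrow(peaks))
  peaks
}

#' Write a BED-like peak table with its sample sidecar
#'
#' @param peaks peak data.frame as returned by [read_peak_table()].
#' @param path output path; sample labels go to `<path>.samples`.
#' @return `path`, invisibly.
#' @export
write_peak_table <- function(peaks, path) {
  validate_peaks(peaks)
  rk <- rpkm_columns(peaks)
  cols <- c("chrom", "start", "end", "peak_id", "score", rk)
  m <- peaks[cols]
  m$score <- format_num(m$score)
  for (nm in rk) m[[nm]] <- format_num(m[[nm]])
  utils::write.table(m, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  writeLines(rk, paste0(path, ".samples"))
  invisible(path)
}

#' Construct an expression table
#'
#' The container for genotype x stimulus x timepoint x replicate expression
#' data. `genes` holds per-gene metadata (TSS, length, primary/secondary
#' response class); `values` holds one row per gene and sample with both the
#' raw read count and the RPKM.
#'
#' @param genes data.frame with columns `gene_id`, `length_kb`, `chrom`,
#'   `tss`, `strand`, `response_class`.
#' @param values data.frame with columns `gene_id`, `genotype`, `stimulus`,
#'   `timepoint`, `replicate`, `count`, `rpkm`.
#' @return An object of class `"expr_table"`.
#' @export
expr_table <- function(genes, values) {
  need_g <- c("gene_id", "length_kb", "chrom", "tss", "strand", "response_class")
  need_v <- c("gene_id", "genotype", "stimulus", "timepoint", "replicate",
              "count", "rpkm")
  if (!all(need_g %in% names(genes))) stop("genes table missing columns")
  if (!all(need_v %in% names(values))) stop("values table missing columns")
  if (anyDuplicated(genes$gene_id)) stop("duplicate gene_id in annotation")
  if (any(genes$length_kb <= 0)) stop("gene length_kb must be positive")
  if (!all(values$timepoint %in% TIMEPOINTS_H)) {
    bad <- setdiff(unique(values$timepoint), TIMEPOINTS_H)
    stop("unknown timepoint(s): ", paste(bad, collapse = ", "))
  }
  if (any(values$count < 0) || any(values$rpkm < 0)) {
    stop("counts and RPKM must be nonnegative")
  }
  key <- with(values, paste(gene_id, genotype, stimulus, timepoint, replicate))
  if (anyDuplicated(key)) stop("duplicate (gene, sample) cell in values")
  if (!all(values$gene_id %in% genes$gene_id)) {
    stop("values reference genes absent from the annotation")
  }
  structure(list(genes = genes[order(genes$gene_id), , drop = FALSE],
                 values = values),
            class = "expr_table")
}

#' @export
print.expr_table <- function(x, ...) {
  cat(sprintf("expr_table: %d genes, %d cells (%s genotypes, %s stimuli)\n",
              nrow(x$genes), nrow(x$values),
              length(unique(x$values$genotype)),
              length(unique(x$values$stimulus))))
  invisible(x)
}

#' Write an expression table to a single long-format TSV
#'
#' Gene metadata is repeated on each row so the file round-trips through
#' [read_expression_table()] unchanged.
#' @param table an `expr_table`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_expression_table <- function(table, path) {
  stopifnot(inherits(table, "expr_table"))
  df <- merge(table$values, table$genes, by = "gene_id", sort = FALSE)
  df <- df[order(df$gene_id, df$genotype, df$stimulus,
                 df$timepoint, df$replicate), ]
  write_tsv_file(df, path)
}

#' Read an expression table written by [write_expression_table()]
#'
#' @param path TSV path.
#' @return An `expr_table`.
#' @export
read_expression_table <- function(path) {
  df <- read_tsv_file(path)
  need <- c("gene_id", "genotype", "stimulus", "timepoint", "replicate",
            "count", "rpkm", "length_kb", "chrom", "tss", "strand",
            "response_class")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("expression table missing columns: ",
                         paste(miss, collapse = ", "))
  genes <- unique(df[c("gene_id", "length_kb", "chrom", "tss", "strand",
                       "response_class")])
  if (anyDuplicated(genes$gene_id)) {
    stop("inconsistent metadata for duplicated gene_id")
  }
  tab <- expr_table(genes, df[c("gene_id", "genotype", "stimulus",
                                "timepoint", "replicate", "count", "rpkm")])
  stage_log("read_expression_table", path = path, n_genes = nrow(tab$genes))
  tab
}

#' Read a position frequency matrix in the simple text format
#'
#' Format: a header line `>name`, then one line per position with four
#' whitespace-separated counts or frequencies in A C G T order.
#'
#' @param path PWM text file; may contain several matrices.
#' @return A list of PWM objects as built by [make_pwm()].
#' @export
read_pwm <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  idx <- grep("^>", lines)
  if (!length(idx)) stop("no PWM header ('>name') found in ", path)
  bounds <- c(idx, length(lines) + 1L)
  out <- list()
  for (i in seq_along(idx)) {
    name <- sub("^>\\s*", "", lines[idx[i]])
    block <- lines[(bounds[i] + 1L):(bounds[i + 1L] - 1L)]
    rows <- lapply(strsplit(block, "\\s+"), as.numeric)
    if (any(lengths(rows) != 4)) stop("PWM '", name, "': rows must have 4 values")
    freq <- do.call(rbind, rows)
    out[[name]] <- make_pwm(name, freq)
  }
  out
}

#' Build a PWM object from a position frequency matrix
#'
#' Frequencies are converted to probabilities with a 0.5 pseudocount per
#' cell, then to log2 odds against a uniform background. The default hit
#' threshold is 80% of the maximal attainable score.
#'
#' @param name motif name.
#' @param freq positions x 4 matrix of counts/frequencies (A, C, G, T).
#' @param threshold absolute score threshold; default `0.8 * max score`.
#' @return A list with elements `name`, `logodds`, `threshold`, `consensus`.
#' @export
make_pwm <- function(name, freq, threshold = NULL) {
  stopifnot(is.matrix(freq), ncol(freq) == 4)
  if (any(freq < 0)) stop("PWM frequencies must be nonnegative")
  p <- (freq + 0.5) / rowSums(freq + 0.5)
  lo <- log2(p / 0.25)
  colnames(lo) <- c("A", "C", "G", "T")
  max_score <- sum(apply(lo, 1, max))
  list(name = name, logodds = lo,
       threshold = threshold %||% 0.8 * max_score,
       max_score = max_score,
       consensus = paste(colnames(lo)[apply(lo, 1, which.max)], collapse = ""))
}

#' Write peak-window sequences to FASTA
#' @param seqs named character vector of sequences (names = peak ids).
#' @param path output FASTA path.
#' @return `path`, invisibly.
#' @export
write_window_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read peak-window sequences from FASTA
#' @param path FASTA path.
#' @return named character vector of uppercase sequences.
#' @export
read_window_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(toupper(as.character(x)), names(x))
}
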