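# The p50 homodimer kappaB element: each p50 subunit contacts three G:C
# base pairs in its half-site, and the half-sites flank a 5 bp spacer. On
# the plus strand this reads GGGNNNNNCCC (11 bp); the pattern class is its
# own reverse complement, so every plus-strand match has a minus-strand
# match over the same window.
HOMODIMER_LEN <- 11L
HOMODIMER_REGEX <- "(?=GGG[ACGTN]{5}CCC)"

#' Scan a sequence for the p50 homodimer motif
#'
#' Reports every position matching `GGGNNNNNCCC` (GGG, any 5 bases, CCC) on
#' both strands, including overlapping occurrences. An ambiguous base (`N`)
#' in the subject never matches a constrained (G/C) position but is allowed
#' in the unconstrained spacer. Because the pattern class equals its own
#' reverse complement, each matching window yields one hit per strand at the
#' same window start.
#'
#' @param sequence a single A/C/G/T/N string (a peak window).
#' @param peak_id optional id recorded in the output.
#' @return data.frame `peak_id`, `offset` (0-based window start), `strand`,
#'   `match` (the 11-mer); zero rows if the sequence is shorter than the
#'   motif or has no match.
#' @export
scan_homodimer <- function(sequence, peak_id = NA_character_) {
  empty <- data.frame(peak_id = character(0), offset = integer(0),
                      strand = character(0), match = character(0))
  sequence <- toupper(sequence)
  if (nchar(sequence) < HOMODIMER_LEN) return(empty)
  if (grepl("[^ACGTN]", sequence)) stop("sequence must be over A/C/G/T/N")
  m <- gregexpr(HOMODIMER_REGEX, sequence, perl = TRUE)[[1]]
  if (m[1] == -1) return(empty)
  offsets <- as.integer(m) - 1L
  # spacer N check: regex already permits N only in the spacer
  matches <- substring(sequence, offsets + 1L, offsets + HOMODIMER_LEN)
  data.frame(
    peak_id = peak_id,
    offset = rep(offsets, each = 2L),
    strand = rep(c("+", "-"), times = length(offsets)),
    match = rep(matches, each = 2L),
    stringsAsFactors = FALSE
  )
}

#' Does a window contain a p50 homodimer motif?
#'
#' Vectorized convenience wrapper over [scan_homodimer()].
#' @param sequences character vector of windows.
#' @return logical vector.
#' @export
has_homodimer <- function(sequences) {
  vapply(sequences, function(s) nrow(scan_homodimer(s)) > 0, logical(1),
         USE.NAMES = FALSE)
}

revcomp <- function(x) {
  chartr("ACGTN", "TGCAN", vapply(x, function(s)
    paste(rev(strsplit(s, "")[[1]]), collapse = ""), character(1),
    USE.NAMES = FALSE))
}

#' Scan a sequence with a position weight matrix
#'
#' Slides the log-odds matrix over both strands; ambiguous bases contribute
#' `-Inf` so windows containing `N` never score as hits. Returns the best
#' score over all positions and strands plus every above-threshold hit.
#'
#' @param sequence a single A/C/G/T/N string.
#' @param pwm a PWM object from [make_pwm()] / [read_pwm()].
#' @return list with `best_score`, `hits` (data.frame `offset`, `strand`,
#'   `score`), `n_hits`.
#' @export
pwm_scan <- function(sequence, pwm) {
  sequence <- toupper(sequence)
  lo <- pwm$logodds
  w <- nrow(lo)
  L <- nchar(sequence)
  if (w > L) return(list(best_score = -Inf,
                         hits = data.frame(offset = integer(0),
                                           strand = character(0),
                                           score = numeric(0)),
                         n_hits = 0L))
  score_strand <- function(s) {
    chars <- strsplit(s, "")[[1]]
    idx <- match(chars, c("A", "C", "G", "T"))
    n_pos <- L - w + 1L
    vapply(seq_len(n_pos), function(start) {
      ii <- idx[start:(start + w - 1L)]
      if (anyNA(ii)) return(-Inf)
      sum(lo[cbind(seq_len(w), ii)])
    }, numeric(1))
  }
  plus <- score_strand(sequence)
  minus <- score_strand(revcomp(sequence))
  # minus-strand window starting at i (on revcomp) covers plus window
  # starting at L - w - i (0-based)
  ip <- which(plus >= pwm$threshold)
  im <- which(minus >= pwm$threshold)
  hits <- rbind(
    data.frame(offset = ip - 1L, strand = rep("+", length(ip)),
               score = plus[ip]),
    data.frame(offset = L - w - (im - 1L), strand = rep("-", length(im)),
               score = minus[im])
  )
  hits <- hits[order(hits$offset, hits$strand), , drop = FALSE]
  rownames(hits) <- NULL
  list(best_score = max(plus, minus), hits = hits, n_hits = nrow(hits))
}

#' Hypergeometric motif enrichment of a foreground window set
#'
#' Tests whether motif-containing windows are over-represented in the
#' foreground (one bin) relative to foreground + background (all other
#' bins) with a one-sided hypergeometric tail, as used for the bin x motif
#' enrichment heat map.
#'
#' @param foreground_has logical vector: motif presence per foreground window.
#' @param background_has logical vector: motif presence per background window.
#' @return list with `p_value`, `neg_log10_p`, counts.
#' @export
motif_enrichment <- function(foreground_has, background_has) {
  if (!length(foreground_has)) stop("empty foreground")
  k <- sum(foreground_has)
  n_fg <- length(foreground_has)
  K <- k + sum(background_has)
  N <- n_fg + length(background_has)
  p <- stats::phyper(k - 1, K, N - K, n_fg, lower.tail = FALSE)
  list(p_value = p, neg_log10_p = -log10(p),
       n_foreground = n_fg, n_foreground_hits = k,
       n_total = N, n_total_hits = K)
}

#' Bin-by-motif enrichment matrix
#'
#' For each bin, the foreground is that bin's windows and the background is
#' every other bin; repeated for each motif presence vector.
#'
#' @param bins integer bin index per window.
#' @param motif_presence named list of logical vectors (one per motif),
#'   aligned with `bins`.
#' @return matrix of -log10 p, bins x motifs.
#' @export
motif_enrichment_matrix <- function(bins, motif_presence) {
  n_bins <- max(bins)
  out <- sapply(motif_presence, function(has) {
    vapply(seq_len(n_bins), function(b) {
      motif_enrichment(has[bins == b], has[bins != b])$neg_log10_p
    }, numeric(1))
  })
  out <- matrix(out, nrow = n_bins,
                dimnames = list(seq_len(n_bins), names(motif_presence)))
  out
}
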