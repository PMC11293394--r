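# Independent brute-force oracles and fixture builders shared across tests.

# Character-by-character homodimer scan: GGG, any 5 of ACGTN, CCC; counts a
# plus and a minus hit per matching window (the pattern class is its own
# reverse complement). Deliberately avoids regex to stay independent of the
# implementation.
oracle_homodimer_offsets <- function(seq) {
  chars <- strsplit(toupper(seq), "")[[1]]
  L <- length(chars)
  if (L < 11) return(integer(0))
  hits <- integer(0)
  for (i in seq_len(L - 10)) {
    win <- chars[i:(i + 10)]
    if (all(win[1:3] == "G") && all(win[9:11] == "C") &&
        all(win[4:8] %in% c("A", "C", "G", "T", "N"))) {
      hits <- c(hits, i - 1L)
    }
  }
  hits
}

# O(n^2) interval merge on 0-based half-open intervals within one chromosome
# table; returns merged intervals sorted by start.
oracle_merge_intervals <- function(df) {
  if (!nrow(df)) return(df[0, c("chrom", "start", "end")])
  out <- list()
  for (ch in unique(df$chrom)) {
    iv <- df[df$chrom == ch, c("start", "end")]
    merged <- list()
    used <- rep(FALSE, nrow(iv))
    for (i in seq_len(nrow(iv))) {
      if (used[i]) next
      cur <- c(iv$start[i], iv$end[i])
      used[i] <- TRUE
      repeat {
        grew <- FALSE
        for (j in seq_len(nrow(iv))) {
          if (used[j]) next
          if (iv$start[j] < cur[2] && iv$end[j] > cur[1]) {
            cur <- c(min(cur[1], iv$start[j]), max(cur[2], iv$end[j]))
            used[j] <- TRUE
            grew <- TRUE
          }
        }
        if (!grew) break
      }
      merged[[length(merged) + 1]] <- data.frame(chrom = ch, start = cur[1],
                                                 end = cur[2])
    }
    out <- c(out, merged)
  }
  res <- do.call(rbind, out)
  res[order(res$chrom, res$start), , drop = FALSE]
}

# all-pairs overlap test (0-based half-open)
oracle_overlaps_any <- function(peaks, others) {
  vapply(seq_len(nrow(peaks)), function(i) {
    any(others$chrom == peaks$chrom[i] &
          others$start < peaks$end[i] & others$end > peaks$start[i])
  }, logical(1))
}

random_interval_set <- function(n, seed, chroms = c("chr1", "chr2"),
                                span = 10000) {
  set.seed(seed)
  chrom <- sample(chroms, n, replace = TRUE)
  start <- sample.int(span, n, replace = TRUE)
  width <- sample(10:300, n, replace = TRUE)
  data.frame(chrom = chrom, start = start, end = start + width,
             peak_id = sprintf("r%03d", seq_len(n)),
             stringsAsFactors = FALSE)
}

random_seq <- function(w) {
  paste(sample(c("A", "C", "G", "T"), w, replace = TRUE), collapse = "")
}

# rejection-sample a window with no homodimer match (for exact-count fixtures)
motif_free_seq <- function(w = 200) {
  repeat {
    s <- random_seq(w)
    if (length(oracle_homodimer_offsets(s)) == 0) return(s)
  }
}

plant_motif <- function(seq, offset = NULL) {
  w <- nchar(seq)
  if (is.null(offset)) offset <- sample.int(w - 10, 1) - 1L
  spacer <- paste(sample(c("A", "C", "G", "T"), 5, replace = TRUE),
                  collapse = "")
  paste0(substr(seq, 1, offset), "GGG", spacer, "CCC",
         substr(seq, offset + 12, w))
}

# Deterministic two-genotype expression fixture. `spec_df` has one row per
# gene: gene_id, wt (list-col of per-timepoint WT RPKM), ratio_ko (KO/WT at
# post-0 timepoints), response_class. Counts are exact (no sampling);
# replicates are jittered by +/- jitter counts so variance is tiny.
make_expr_fixture <- function(spec_df, regulators = "Nfkb1",
                              length_kb = 1, lib = 1, jitter = 0) {
  genes <- data.frame(
    gene_id = spec_df$gene_id,
    length_kb = length_kb,
    chrom = "chr1",
    tss = seq_len(nrow(spec_df)) * 10000,
    strand = "+",
    response_class = spec_df$response_class %||% "secondary",
    stringsAsFactors = FALSE
  )
  tps <- c(0, 0.5, 1, 2, 6)
  rows <- list()
  for (i in seq_len(nrow(spec_df))) {
    wt <- spec_df$wt[[i]]
    for (tj in seq_along(tps)) {
      for (genotype in c("WT", regulators)) {
        rcol <- paste0("ratio_", genotype)
        ratio <- if (!is.null(spec_df[[rcol]])) spec_df[[rcol]][i] else spec_df$ratio_ko[i]
        mult <- if (genotype == "WT" || tps[tj] == 0) 1 else ratio
        mean_rpkm <- wt[tj] * mult
        for (r in 1:2) {
          cnt <- round(mean_rpkm * length_kb * lib) + (r - 1) * jitter
          rows[[length(rows) + 1]] <- data.frame(
            gene_id = spec_df$gene_id[i], genotype = genotype,
            stimulus = "lipidA", timepoint = tps[tj], replicate = r,
            count = cnt, rpkm = cnt / (length_kb * lib),
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  expr_table(genes, do.call(rbind, rows))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Deterministic expression fixture encoding the reported dependence-category
# counts: 67 p50-dependent genes (11 with KO/WT ratio < 0.1), 28 of them
# IkBzeta-codependent (7 among the strongest 11), 20 of them secondary
# response (12 codependent), plus null filler genes.
codependence_count_fixture <- function() {
  dep_ids <- sprintf("d%02d", 1:67)
  null_ids <- sprintf("n%02d", 1:80)
  fix <- data.frame(gene_id = c(dep_ids, null_ids),
                    stringsAsFactors = FALSE)
  fix$wt <- replicate(nrow(fix), c(2, 3, 100, 100, 100), simplify = FALSE)
  r_nfkb1 <- c(rep(0.05, 11), rep(0.2, 56), rep(1, 80))
  codep <- c(sprintf("d%02d", 1:7), sprintf("d%02d", 12:32))
  r_nfkbiz <- ifelse(fix$gene_id %in% codep, 0.1, 1)
  fix$ratio_Nfkb1 <- r_nfkb1
  fix$ratio_Nfkbiz <- r_nfkbiz
  secondary <- c(sprintf("d%02d", 1:7), sprintf("d%02d", 12:16),
                 sprintf("d%02d", 40:47))
  fix$response_class <- ifelse(fix$gene_id %in% secondary, "secondary",
                               "primary")
  make_expr_fixture(fix, regulators = c("Nfkb1", "Nfkbiz"))
}

# Binding-dependence fixture with planted band counts 1976 (independent),
# 1570 (mild) and 187 (strong).
banded_dependence_fixture <- function() {
  n <- c(independent = 1976, mild = 1570, strong = 187)
  ko_level <- c(independent = 12, mild = 7, strong = 2)
  ids <- sprintf("pk%04d", seq_len(sum(n)))
  wt <- stats::setNames(rep(10, sum(n)), ids)
  ko <- stats::setNames(rep(ko_level, n), ids)
  binding_dependence(wt, ko, "IkBzeta", run_config())
}
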