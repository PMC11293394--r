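#' p50:RelA binding-preference scores
#'
#' Combines the full reproducible p50 peak set with the equal-size top-N
#' RelA set (N = number of p50 peaks, ranked by RelA RPKM), then scores each
#' location in the combined set by the 1 h replicate-averaged
#' p50 RPKM : RelA RPKM ratio with a pseudocount on both terms. Peaks are
#' returned sorted in descending ratio order (strongest p50 preference
#' first), ties broken by peak id.
#'
#' @param peaks data.frame with columns `peak_id`, `p50_rpkm_1h`,
#'   `rela_rpkm_1h`, and logical membership columns `is_p50`, `is_rela`
#'   (reproducible-set membership per factor).
#' @param config a [run_config()].
#' @return data.frame `peak_id`, `p50_rpkm_1h`, `rela_rpkm_1h`, `ratio`,
#'   sorted by descending ratio.
#' @export
preference_ratio <- function(peaks, config = run_config()) {
  need <- c("peak_id", "p50_rpkm_1h", "rela_rpkm_1h", "is_p50", "is_rela")
  miss <- setdiff(need, names(peaks))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  if (anyNA(peaks$p50_rpkm_1h) || anyNA(peaks$rela_rpkm_1h)) {
    stop("missing 1 h RPKM values")
  }
  p50_set <- peaks[peaks$is_p50, ]
  n <- nrow(p50_set)
  if (n == 0) stop("empty p50 set")
  rela_pool <- peaks[peaks$is_rela, ]
  rela_pool <- rela_pool[order(-rela_pool$rela_rpkm_1h, rela_pool$peak_id), ]
  rela_top <- utils::head(rela_pool, n)
  sel <- peaks[peaks$peak_id %in% union(p50_set$peak_id, rela_top$peak_id), ]
  eps <- config$ratio_pseudocount
  sel$ratio <- pseudo_ratio(sel$p50_rpkm_1h, sel$rela_rpkm_1h, eps)
  sel <- sel[order(-sel$ratio, sel$peak_id), ]
  rownames(sel) <- NULL
  stage_log("preference_ratio", n_p50 = n, n_combined = nrow(sel))
  sel[c("peak_id", "p50_rpkm_1h", "rela_rpkm_1h", "ratio")]
}

#' Partition pre-sorted items into equal-size contiguous bins
#'
#' With `n` items and `b` bins and remainder `r = n %% b`, the first `r`
#' bins receive one extra item, so bin sizes differ by at most one and every
#' item is binned exactly once.
#'
#' @param n_items number of items (already sorted by the relevant score).
#' @param n_bins number of bins.
#' @return integer vector of bin indices (1..n_bins), one per item in order.
#' @export
partition_bins <- function(n_items, n_bins) {
  if (n_bins > n_items) stop("more bins than items")
  if (n_bins < 1) stop("need >= 1 bin")
  base <- n_items %/% n_bins
  extra <- n_items %% n_bins
  sizes <- rep(base, n_bins) + c(rep(1L, extra), rep(0L, n_bins - extra))
  rep(seq_len(n_bins), times = sizes)
}

#' Annotate peaks to their nearest TSS within a window
#'
#' Each peak is linked to the gene with the TSS nearest to the peak center,
#' provided the distance does not exceed the window; equidistant TSSs are
#' resolved toward the lexicographically smaller gene id. Optionally the
#' candidate genes are restricted to an expressed set first.
#'
#' @param peaks peak data.frame (`chrom`, `start`, `end`, `peak_id`).
#' @param annotation gene data.frame (`gene_id`, `chrom`, `tss`).
#' @param window_kb maximum center-to-TSS distance in kb.
#' @param expressed_genes optional character vector; when supplied only these
#'   genes are annotation candidates.
#' @return data.frame `peak_id`, `gene_id`, `distance_bp`, `window_kb` with
#'   one row per linked peak (unlinked peaks are dropped).
#' @export
annotate_peaks <- function(peaks, annotation, window_kb = 5,
                           expressed_genes = NULL) {
  ann <- annotation
  if (!is.null(expressed_genes)) {
    ann <- ann[ann$gene_id %in% expressed_genes, , drop = FALSE]
  }
  if (!nrow(ann) || !nrow(peaks)) {
    return(data.frame(peak_id = character(0), gene_id = character(0),
                      distance_bp = numeric(0), window_kb = numeric(0)))
  }
  center <- (peaks$start + peaks$end) / 2
  links <- lapply(seq_len(nrow(peaks)), function(i) {
    cand <- ann[ann$chrom == peaks$chrom[i], , drop = FALSE]
    if (!nrow(cand)) return(NULL)
    d <- abs(cand$tss - center[i])
    dmin <- min(d)
    if (dmin > window_kb * 1000) return(NULL)
    hit <- cand$gene_id[d == dmin]
    data.frame(peak_id = peaks$peak_id[i], gene_id = min(hit),
               distance_bp = dmin, window_kb = window_kb,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, links)
  if (is.null(out)) {
    out <- data.frame(peak_id = character(0), gene_id = character(0),
                      distance_bp = numeric(0), window_kb = numeric(0))
  }
  stage_log("annotate_peaks", n_peaks = nrow(peaks), n_linked = nrow(out),
            window_kb = window_kb)
  out
}

#' Per-bin fraction of peaks satisfying a predicate
#'
#' @param bins integer vector of bin indices (1..n_bins), one per peak.
#' @param predicate logical vector aligned with `bins`.
#' @return data.frame `bin`, `n`, `n_positive`, `fraction`.
#' @export
bin_fraction <- function(bins, predicate) {
  if (length(bins) != length(predicate)) stop("bins/predicate length mismatch")
  if (anyNA(predicate)) stop("predicate must be defined for every peak")
  n_bins <- max(bins)
  n <- tabulate(bins, nbins = n_bins)
  pos <- tabulate(bins[predicate], nbins = n_bins)
  data.frame(bin = seq_len(n_bins), n = n, n_positive = pos,
             fraction = pos / n)
}

#' Genotype dependence of factor binding, with banded classification
#'
#' For each peak the knockout/wild-type RPKM ratio (pseudocount on both
#' terms) is computed and banded: strong dependence below 0.33 (strict),
#' mild dependence from 0.33 to 1.0 inclusive, independent above 1.0.
#'
#' @param wt_rpkm,ko_rpkm named numeric vectors over the same peak universe
#'   (names = peak ids).
#' @param factor_name label stored in the output (e.g. `"IkBzeta"`).
#' @param config a [run_config()].
#' @return data.frame `peak_id`, `factor`, `wt_rpkm`, `ko_rpkm`, `ratio`,
#'   `band`.
#' @export
binding_dependence <- function(wt_rpkm, ko_rpkm, factor_name = "IkBzeta",
                               config = run_config()) {
  if (is.null(names(wt_rpkm)) || is.null(names(ko_rpkm))) {
    stop("wt_rpkm and ko_rpkm must be named by peak id")
  }
  if (!setequal(names(wt_rpkm), names(ko_rpkm))) {
    stop("peak universes differ between genotypes")
  }
  ko_rpkm <- ko_rpkm[names(wt_rpkm)]
  r <- pseudo_ratio(ko_rpkm, wt_rpkm, config$ratio_pseudocount)
  band <- ifelse(r < config$dependence_ratio, "strong",
          ifelse(r <= 1.0, "mild", "independent"))
  out <- data.frame(peak_id = names(wt_rpkm), factor = factor_name,
                    wt_rpkm = as.numeric(wt_rpkm),
                    ko_rpkm = as.numeric(ko_rpkm),
                    ratio = as.numeric(r), band = band,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  stage_log("binding_dependence", factor = factor_name, n = nrow(out),
            n_strong = sum(band == "strong"))
  out
}

#' Keep one peak per gene: the most genotype-dependent
#'
#' Among a gene's linked peaks, retains the peak with the minimum KO/WT
#' ratio (the maximum change in binding); ties go to the smallest peak id.
#'
#' @param links output of [annotate_peaks()].
#' @param dependence output of [binding_dependence()] over the same peaks.
#' @return the filtered `links` rows, augmented with `ratio`.
#' @export
one_peak_per_gene <- function(links, dependence) {
  m <- merge(links, dependence[c("peak_id", "ratio")], by = "peak_id")
  m <- m[order(m$gene_id, m$ratio, m$peak_id), ]
  m[!duplicated(m$gene_id), , drop = FALSE]
}

#' Per-bin gene-class enrichment of binned peaks
#'
#' For peaks binned by binding dependence, computes the percentage of peaks
#' in each bin whose linked gene carries each dependence class (and the sum
#' across classes). Peaks without a link count toward the bin size.
#'
#' @param peak_ids peak ids in bin order.
#' @param bins integer bin index per peak.
#' @param links [annotate_peaks()] output (possibly filtered by
#'   [one_peak_per_gene()]).
#' @param gene_classes named character vector gene_id -> class label.
#' @param classes class labels to tabulate (default: all observed).
#' @return data.frame: `bin`, `n`, one percentage column per class, `total_pct`.
#' @export
dependence_enrichment <- function(peak_ids, bins, links, gene_classes,
                                  classes = NULL) {
  stopifnot(length(peak_ids) == length(bins))
  cls_of_peak <- rep(NA_character_, length(peak_ids))
  i <- match(peak_ids, links$peak_id)
  linked_gene <- links$gene_id[i]
  cls_of_peak[!is.na(i)] <- gene_classes[linked_gene[!is.na(i)]]
  classes <- classes %||% sort(unique(stats::na.omit(cls_of_peak)))
  n_bins <- max(bins)
  out <- data.frame(bin = seq_len(n_bins),
                    n = tabulate(bins, nbins = n_bins))
  for (cl in classes) {
    hit <- !is.na(cls_of_peak) & cls_of_peak == cl
    out[[paste0("pct_", cl)]] <-
      100 * tabulate(bins[hit], nbins = n_bins) / out$n
  }
  pct_cols <- paste0("pct_", classes)
  out$total_pct <- if (length(pct_cols)) {
    rowSums(out[, pct_cols, drop = FALSE])
  } else {
    rep(0, n_bins)
  }
  out
}
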