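#' Filter peaks to reproducible locations
#'
#' A genomic location is reproducible when a peak with score above `ps_cut`
#' and RPKM above `expressed_rpkm` (both strict) is present in at least
#' `k`-of-`n` replicates at one or more timepoints. Input is a nested list:
#' one element per timepoint, each a list of replicate peak tables whose RPKM
#' column holds that replicate's signal. Kept locations are the
#' replicate-merged intervals (minimum start, maximum end of contributors).
#'
#' @param peak_replicates list (timepoints) of lists (replicates) of peak
#'   data.frames; each replicate table needs exactly one RPKM column.
#' @param config a [run_config()].
#' @param k minimum number of qualifying replicates (default 2).
#' @return data.frame of merged reproducible locations (`chrom`, `start`,
#'   `end`, `peak_id`).
#' @export
filter_reproducible <- function(peak_replicates, config = run_config(), k = 2) {
  if (!length(peak_replicates)) stop("no peak tables supplied")
  if (!is.list(peak_replicates[[1]])) peak_replicates <- list(peak_replicates)
  all_tabs <- unlist(peak_replicates, recursive = FALSE)
  if (length(all_tabs) < 2) stop("need >= 2 replicate peak tables")
  chrom_sets <- lapply(all_tabs, function(p) sort(unique(p$chrom)))
  nonempty <- chrom_sets[lengths(chrom_sets) > 0]
  if (length(nonempty) > 1) {
    universe <- sort(unique(unlist(nonempty)))
    for (cs in nonempty) {
      if (!all(cs %in% universe) || !all(universe %in% union(universe, cs))) {
        stop("replicate tables disagree on chromosome set")
      }
    }
    # require each table's chroms to be a subset of the union; a fully
    # disjoint chromosome set indicates mismatched assemblies
    pair_overlap <- outer(seq_along(nonempty), seq_along(nonempty),
                          Vectorize(function(i, j)
                            i == j || length(intersect(nonempty[[i]],
                                                       nonempty[[j]])) > 0))
    if (!all(pair_overlap)) stop("replicate tables disagree on chromosome set")
  }
  lapply(all_tabs, validate_peaks)
  combined <- do.call(rbind, lapply(all_tabs, function(p)
    p[c("chrom", "start", "end")]))
  if (!nrow(combined)) {
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), peak_id = character(0)))
  }
  gr_all <- GenomicRanges::GRanges(combined$chrom,
                                   IRanges::IRanges(combined$start + 1L,
                                                    combined$end))
  locs <- GenomicRanges::reduce(gr_all, min.gapwidth = 0L)
  locs <- GenomicRanges::sort(GenomeInfoDb::sortSeqlevels(locs))
  keep <- rep(FALSE, length(locs))
  for (tp in seq_along(peak_replicates)) {
    reps <- peak_replicates[[tp]]
    qual <- matrix(FALSE, length(locs), length(reps))
    for (r in seq_along(reps)) {
      p <- reps[[r]]
      rk <- rpkm_columns(p)
      if (length(rk) != 1) stop("replicate table must have exactly 1 RPKM column")
      ok <- p$score > config$ps_cut & p[[rk]] > config$expressed_rpkm
      if (!any(ok)) next
      gr <- GenomicRanges::GRanges(p$chrom[ok],
                                   IRanges::IRanges(p$start[ok] + 1L, p$end[ok]))
      qual[, r] <- IRanges::overlapsAny(locs, gr)
    }
    keep <- keep | rowSums(qual) >= k
  }
  out <- granges_to_peaks(locs[keep])
  stage_log("filter_reproducible", n_locations = length(locs),
            n_kept = nrow(out), k = k, ps_cut = config$ps_cut)
  out
}

#' Union of peak sets with provenance flags
#'
#' Merges all intervals overlapping by at least 1 bp into single locations
#' and records, per location, which input sets contributed.
#'
#' @param peaksets named list of peak data.frames.
#' @return data.frame of merged locations plus one logical column
#'   `in_<setname>` per input set.
#' @export
union_peaksets <- function(peaksets) {
  if (!length(peaksets)) stop("need >= 1 peak set")
  if (is.null(names(peaksets)) || any(!nzchar(names(peaksets)))) {
    names(peaksets) <- sprintf("set%d", seq_along(peaksets))
  }
  grl <- lapply(peaksets, function(p) {
    if (!nrow(p)) return(GenomicRanges::GRanges())
    GenomicRanges::GRanges(p$chrom, IRanges::IRanges(p$start + 1L, p$end))
  })
  all_gr <- suppressWarnings(do.call(c, unname(grl)))
  if (!length(all_gr)) {
    out <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), peak_id = character(0))
    for (nm in names(peaksets)) out[[paste0("in_", nm)]] <- logical(0)
    return(out)
  }
  merged <- GenomicRanges::reduce(all_gr, min.gapwidth = 0L)
  merged <- GenomicRanges::sort(GenomeInfoDb::sortSeqlevels(merged))
  out <- granges_to_peaks(merged)
  for (nm in names(peaksets)) {
    out[[paste0("in_", nm)]] <- IRanges::overlapsAny(merged, grl[[nm]])
  }
  stage_log("union_peaksets", n_inputs = length(peaksets),
            n_locations = nrow(out))
  out
}

#' Quantify peak signal as RPKM
#'
#' @param peaks data.frame of locations (0-based half-open).
#' @param counts matrix of read counts, rows = peaks (in `peaks` order),
#'   columns = samples.
#' @param library_size_millions per-sample depths in millions, recycled or
#'   named by column.
#' @return numeric matrix of RPKM with peak ids as rownames.
#' @export
quantify <- function(peaks, counts, library_size_millions) {
  counts <- as.matrix(counts)
  if (nrow(counts) != nrow(peaks)) stop("counts rows must match peaks")
  width_kb <- (peaks$end - peaks$start) / 1000
  if (any(width_kb <= 0)) stop("zero-width location")
  lib <- rep(library_size_millions, length.out = ncol(counts))
  rpkm <- sweep(counts / width_kb, 2, lib, "/")
  rownames(rpkm) <- peaks$peak_id
  rpkm
}

# Archetype-ordering convention: clusters are numbered by the timepoint at
# which their centroid peaks (earliest first); ties go to the cluster with
# the higher mean pre-peak level (the 0 h level when the peak is early), so
# cluster 1 is high at 0 h and cluster 6 stays low until 2 h.
relabel_clusters <- function(centers) {
  argmax_t <- apply(centers, 1, which.max)
  premean <- vapply(seq_len(nrow(centers)), function(i) {
    mean(centers[i, seq_len(max(1L, argmax_t[i] - 1L))])
  }, numeric(1))
  ord <- order(argmax_t, -premean)
  # returns the new label for original cluster i at position i
  stats::setNames(seq_len(nrow(centers)), ord)[as.character(seq_len(nrow(centers)))]
}

#' Kinetic k-means clustering of peak binding profiles
#'
#' Each peak's profile over the four ChIP timepoints (0, 0.5, 1, 2 h;
#' replicate-averaged, factor-pooled) is scaled to its own maximum so that
#' clusters encode temporal shape rather than amplitude, then clustered with
#' `stats::kmeans` (50 restarts under a fixed seed). Cluster labels are
#' normalized to the archetype order described in [relabel_clusters()]
#' (cluster 1 peaks at 0 h; cluster 6 is low until 2 h).
#'
#' @param profile_matrix peaks x 4 numeric matrix with peak ids as rownames.
#' @param k number of clusters (default 6).
#' @param seed RNG seed for the restarts.
#' @param nstart number of k-means restarts.
#' @return list with `cluster` (named integer vector), `centers` (k x 4,
#'   rows in relabeled order), `sizes`.
#' @export
kinetic_kmeans <- function(profile_matrix, k = 6, seed = 1L, nstart = 50) {
  profile_matrix <- as.matrix(profile_matrix)
  if (k > nrow(profile_matrix)) stop("k exceeds number of peaks")
  if (ncol(profile_matrix) != 4) stop("expected 4 timepoint columns")
  mx <- apply(profile_matrix, 1, max)
  if (any(mx <= 0)) stop("peak profile with nonpositive maximum")
  scaled <- profile_matrix / mx
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  if (k == nrow(scaled)) {
    # degenerate case: every profile is its own cluster
    km <- list(cluster = seq_len(k), centers = scaled)
    dimnames(km$centers) <- list(seq_len(k), colnames(scaled))
  } else {
    km <- stats::kmeans(scaled, centers = k, nstart = nstart, iter.max = 100)
  }
  new_label <- relabel_clusters(km$centers)
  cluster <- as.integer(new_label[as.character(km$cluster)])
  names(cluster) <- rownames(profile_matrix)
  centers <- km$centers[order(new_label), , drop = FALSE]
  rownames(centers) <- seq_len(k)
  stage_log("kinetic_kmeans", n_peaks = nrow(scaled), k = k,
            sizes = as.vector(table(cluster)))
  list(cluster = cluster, centers = centers,
       sizes = as.vector(table(factor(cluster, levels = seq_len(k)))))
}

#' Per-factor cluster composition
#'
#' @param clustering named integer vector of cluster assignments (output of
#'   [kinetic_kmeans()]`$cluster`).
#' @param per_factor_membership named list mapping factor name to the peak
#'   ids bound by that factor.
#' @param k number of clusters.
#' @return data.frame: one row per factor, percentage per cluster (rows sum
#'   to 100), plus `n_peaks`; factors with zero peaks get an all-NA row and a
#'   `flagged` mark.
#' @export
cluster_composition <- function(clustering, per_factor_membership,
                                k = max(clustering)) {
  out <- lapply(names(per_factor_membership), function(f) {
    ids <- intersect(per_factor_membership[[f]], names(clustering))
    n <- length(ids)
    if (n == 0) {
      pct <- rep(NA_real_, k)
    } else {
      pct <- 100 * tabulate(clustering[ids], nbins = k) / n
    }
    row <- as.data.frame(as.list(stats::setNames(pct, paste0("cluster", seq_len(k)))))
    row$n_peaks <- n
    row$factor <- f
    row$flagged <- n == 0
    row
  })
  res <- do.call(rbind, out)
  res[c("factor", paste0("cluster", seq_len(k)), "n_peaks", "flagged")]
}

#' Flag peaks accessible in unstimulated chromatin
#'
#' A peak is accessible at 0 h iff it overlaps (>= 1 bp, half-open
#' coordinates) a called ATAC peak from unstimulated cells.
#'
#' @param peaks peak data.frame.
#' @param atac_0h_peaks ATAC peak data.frame at 0 h (called peaks only).
#' @return logical vector named by `peaks$peak_id`.
#' @export
accessibility_overlay <- function(peaks, atac_0h_peaks) {
  if (!nrow(peaks)) return(stats::setNames(logical(0), character(0)))
  gr <- GenomicRanges::GRanges(peaks$chrom,
                               IRanges::IRanges(peaks$start + 1L, peaks$end))
  if (!nrow(atac_0h_peaks)) {
    return(stats::setNames(rep(FALSE, nrow(peaks)), peaks$peak_id))
  }
  atac <- GenomicRanges::GRanges(atac_0h_peaks$chrom,
                                 IRanges::IRanges(atac_0h_peaks$start + 1L,
                                                  atac_0h_peaks$end))
  stats::setNames(IRanges::overlapsAny(gr, atac), peaks$peak_id)
}

#' Rank-order a signal matrix by a reference column
#'
#' Rows are sorted in descending order of the reference column; ties are
#' broken by lexicographic row name. Used for binding-strength heat maps and
#' sequential-ChIP signal displays.
#'
#' @param matrix numeric matrix with peak ids as rownames.
#' @param reference_column column name or index to rank by.
#' @return the row-permuted matrix.
#' @export
rank_order_matrix <- function(matrix, reference_column) {
  if (is.character(reference_column) &&
      !reference_column %in% colnames(matrix)) {
    stop("reference column not found: ", reference_column)
  }
  ref <- matrix[, reference_column]
  matrix[order(-ref, rownames(matrix), method = "radix"), , drop = FALSE]
}
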