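#' Pipeline configuration
#'
#' Collects every tunable threshold used by the pipeline in a single
#' validated list. The defaults are the working thresholds of the analysis:
#' a knockout/wild-type ratio below 0.33 with an adjusted p below 0.01 calls
#' dependence; genes and peaks are considered expressed/bound above 3 RPKM;
#' peak reproducibility additionally requires a peak score above 19; genes
#' are "induced" above 5-fold (the stimulus-differential module uses its own
#' 3-fold induction filter); stimulus-differential tiers sit at TNF:lipid A
#' ratios of 1/3 and 1/60.
#'
#' @param dependence_ratio KO/WT RPKM ratio below which a gene or peak is
#'   dependent (strict `<`).
#' @param p_cut significance cutoff on the BH-adjusted p-value (strict `<`).
#' @param expressed_rpkm expression/binding floor in RPKM (strict `>`).
#' @param ps_cut peak-score floor for reproducible peaks (strict `>`).
#' @param induced_fc fold-change above which a gene is induced (strict `>`).
#' @param weak_fc_range fold-change interval labelled weakly induced.
#' @param tss_window_kb peak-to-gene annotation windows in kb; the first
#'   element is the default window.
#' @param diff_ratios stimulus-differential tier cutoffs (TNF : lipid A).
#' @param n_clusters number of kinetic k-means clusters.
#' @param bin_counts supported equal-size bin counts; first is the default.
#' @param preference_bin_size size of the top/middle/bottom preference slices.
#' @param motif_window_bp width of the sequence window centred on each peak.
#' @param ratio_pseudocount RPKM pseudocount added to both terms of the
#'   preference and binding-dependence ratios.
#' @param rpkm_guard replicate-averaged WT RPKM floor used as the denominator
#'   guard in expression dependence ratios.
#' @param dispersion_floor lower bound on the pooled NB dispersion estimate.
#' @param rng_seed integer seed recorded for downstream generators.
#'
#' @return A named list with class `"run_config"`.
#' @export
run_config <- function(dependence_ratio = 0.33,
                       p_cut = 0.01,
                       expressed_rpkm = 3,
                       ps_cut = 19,
                       induced_fc = 5,
                       weak_fc_range = c(1, 5),
                       tss_window_kb = c(5, 30),
                       diff_ratios = c(1 / 3, 1 / 60),
                       n_clusters = 6,
                       bin_counts = c(15, 20),
                       preference_bin_size = 300,
                       motif_window_bp = 200,
                       ratio_pseudocount = 0.1,
                       rpkm_guard = 0.5,
                       dispersion_floor = 0.01,
                       rng_seed = 1L) {
  cfg <- list(
    dependence_ratio = dependence_ratio, p_cut = p_cut,
    expressed_rpkm = expressed_rpkm, ps_cut = ps_cut,
    induced_fc = induced_fc, weak_fc_range = weak_fc_range,
    tss_window_kb = tss_window_kb, diff_ratios = diff_ratios,
    n_clusters = n_clusters, bin_counts = bin_counts,
    preference_bin_size = preference_bin_size,
    motif_window_bp = motif_window_bp,
    ratio_pseudocount = ratio_pseudocount,
    rpkm_guard = rpkm_guard,
    dispersion_floor = dispersion_floor,
    rng_seed = as.integer(rng_seed)
  )
  scalar <- c("dependence_ratio", "p_cut", "expressed_rpkm", "ps_cut",
              "induced_fc", "preference_bin_size", "motif_window_bp",
              "ratio_pseudocount", "rpkm_guard", "dispersion_floor")
  for (nm in scalar) {
    v <- cfg[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      stop("config field '", nm, "' must be a single positive number")
    }
  }
  if (any(cfg$bin_counts < 2)) stop("bin counts must be >= 2")
  if (cfg$n_clusters < 2) stop("n_clusters must be >= 2")
  if (any(cfg$diff_ratios <= 0)) stop("diff_ratios must be positive")
  class(cfg) <- "run_config"
  cfg
}

#' @export
print.run_config <- function(x, ...) {
  cat("nfkbcodep run configuration\n")
  for (nm in names(x)) {
    cat(sprintf("  %-20s %s\n", nm, paste(format(x[[nm]]), collapse = ", ")))
  }
  invisible(x)
}
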