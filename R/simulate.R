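#' Parameters for the synthetic macrophage dataset
#'
#' The generator emulates the statistical structure of a stimulated-BMDM
#' study: nascent-transcript time courses across five genotypes (WT and four
#' knockouts), two stimuli, five timepoints and two replicates, plus
#' multi-factor ChIP-seq peak kinetics with knockout tracks, ATAC
#' accessibility and peak-window sequences -- all with planted ground truth.
#'
#' Class mixture (sums to 1): a few percent of genes are planted as
#' codependent (induction collapses in both Nfkb1-/- and Nfkbiz-/- cells),
#' p50-only or IkBzeta-only dependent, a larger induced-but-independent
#' group, a repressed group, and a weakly/not induced majority -- tens of
#' dependent genes among thousands.
#'
#' @param n_genes,n_peaks numbers of genes and ChIP peak locations.
#' @param chrom_sizes named vector of chromosome lengths (bp).
#' @param class_mixture named gene-class proportions.
#' @param effect_ratio KO/WT mean ratio at affected timepoints for dependent
#'   genes (default 0.15).
#' @param nb_dispersion NB dispersion for expression counts.
#' @param peak_lognorm_sigma lognormal sigma for replicate peak RPKM.
#' @param induced_fold WT fold induction of induced genes.
#' @param motif_prob_dependent,motif_prob_background homodimer-motif planting
#'   probabilities for p50-dependent vs other peaks.
#' @param tnf_factor_codependent,tnf_factor_ikbz planted TNF:lipidA
#'   expression factors for codependent and IkBzeta-only genes (others 1).
#' @param library_size_millions sequencing depth per expression sample.
#' @param peak_library_size_millions depth per ChIP sample.
#' @param frac_ikbz_dependent_extra extra IkBzeta peaks (beyond those planted
#'   at codependent genes) given p50-dependent binding.
#' @param window_bp sequence window width around peak centers.
#' @param rng_seed integer seed; every generated object is a deterministic
#'   function of it.
#' @return list of class `"generator_params"`.
#' @export
generator_params <- function(n_genes = 2000,
                             n_peaks = 3000,
                             chrom_sizes = c(chr1 = 60e6, chr2 = 50e6,
                                             chr3 = 40e6),
                             class_mixture = c(codependent = 0.02,
                                               p50_only = 0.02,
                                               ikbz_only = 0.03,
                                               independent = 0.08,
                                               repressed = 0.05,
                                               weak = 0.80),
                             effect_ratio = 0.15,
                             nb_dispersion = 0.05,
                             peak_lognorm_sigma = 0.25,
                             induced_fold = 20,
                             motif_prob_dependent = 0.8,
                             motif_prob_background = 0.1,
                             tnf_factor_codependent = 1 / 200,
                             tnf_factor_ikbz = 1 / 20,
                             library_size_millions = 20,
                             peak_library_size_millions = 15,
                             frac_ikbz_dependent_extra = 0.02,
                             window_bp = 200,
                             rng_seed = 1L) {
  if (abs(sum(class_mixture) - 1) > 1e-8) stop("mixture proportions must sum to 1")
  if (any(class_mixture < 0)) stop("mixture proportions must be nonnegative")
  if (nb_dispersion <= 0 || peak_lognorm_sigma <= 0) stop("dispersion must be > 0")
  if (!length(chrom_sizes)) stop("chrom_sizes must be nonempty")
  if (n_genes < 1) stop("n_genes must be >= 1")
  if (window_bp %% 2 != 0) stop("window_bp must be even")
  p <- as.list(environment())
  p$rng_seed <- as.integer(rng_seed)
  class(p) <- "generator_params"
  p
}

# expression kinetic shapes (multiplier of baseline at 0/0.5/1/2/6 h)
expr_shape <- function(kind, fold) {
  switch(kind,
    primary = c(1, fold, fold, 0.8 * fold, 0.5 * fold),
    primary_late = c(1, fold, fold, fold, 0.9 * fold),
    secondary = c(1, 1.2, 0.25 * fold, fold, fold),
    repressed = c(1, 0.8, 0.5, 0.3, 0.25),
    flat = rep(1, 5)
  )
}

# ChIP archetype shapes over 0/0.5/1/2 h: constitutive-then-declining (1),
# sustained and transient binding first seen at 0.5 h (2, 3), transient
# binding at 1 h (4), late-sustained binding (5), low until 2 h (6).
# Row order matches the relabel_clusters() convention (argmax time, then
# 0 h level) so planted archetype ids align with recovered cluster ids.
ARCHETYPE_SHAPES <- rbind(
  c(1.00, 0.60, 0.20, 0.05),
  c(0.10, 1.00, 1.00, 0.95),
  c(0.05, 1.00, 0.30, 0.10),
  c(0.05, 0.10, 1.00, 0.20),
  c(0.05, 0.10, 0.80, 1.00),
  c(0.03, 0.05, 0.10, 1.00)
)

#' The six planted kinetic archetype shapes
#'
#' Mean binding profiles over 0/0.5/1/2 h used by [generate_peaks()], as a
#' fraction of each archetype's own maximum. Rows are ordered by the
#' [kinetic_kmeans()] relabeling convention.
#'
#' @return 6 x 4 numeric matrix (archetypes x timepoints).
#' @export
archetype_shapes <- function() {
  m <- ARCHETYPE_SHAPES
  dimnames(m) <- list(archetype = 1:6, timepoint_h = CHIP_TIMEPOINTS_H)
  m
}

#' Generate the synthetic gene annotation
#'
#' Places TSSs uniformly on the declared chromosomes, draws lognormal gene
#' lengths, and plants the gene-class and kinetic-subtype truth labels that
#' the expression generator consumes. Deterministic under the seed.
#'
#' @param params a [generator_params()].
#' @return data.frame: `gene_id`, `chrom`, `tss`, `strand`, `length_kb`,
#'   `response_class` (primary/secondary/unclassified), and planted labels
#'   `true_class`, `true_kinetics`.
#' @export
generate_genome <- function(params = generator_params()) {
  set.seed(params$rng_seed + 101L)
  n <- params$n_genes
  chroms <- names(params$chrom_sizes)
  chrom <- sample(chroms, n, replace = TRUE,
                  prob = params$chrom_sizes / sum(params$chrom_sizes))
  tss <- floor(stats::runif(n, 1e5, params$chrom_sizes[chrom] - 1e5))
  length_kb <- pmax(0.3, stats::rlnorm(n, meanlog = log(2), sdlog = 0.6))
  cls <- sample(names(params$class_mixture), n, replace = TRUE,
                prob = params$class_mixture)
  kin <- vapply(cls, function(cl) {
    switch(cl,
      codependent = sample(c("secondary", "primary_late"), 1,
                           prob = c(0.7, 0.3)),
      p50_only = sample(c("primary", "secondary"), 1, prob = c(0.5, 0.5)),
      ikbz_only = sample(c("primary_late", "secondary"), 1,
                         prob = c(0.3, 0.7)),
      independent = sample(c("primary", "secondary"), 1, prob = c(0.5, 0.5)),
      repressed = "repressed",
      weak = "flat")
  }, character(1))
  response <- ifelse(kin %in% c("primary", "primary_late"), "primary",
              ifelse(kin == "secondary", "secondary", "unclassified"))
  ann <- data.frame(
    gene_id = sprintf("g%04d", seq_len(n)),
    chrom = chrom, tss = as.numeric(tss),
    strand = sample(c("+", "-"), n, replace = TRUE),
    length_kb = length_kb,
    response_class = response,
    true_class = cls,
    true_kinetics = kin,
    stringsAsFactors = FALSE
  )
  stage_log("generate_genome", n_genes = n,
            n_codependent = sum(cls == "codependent"))
  ann
}

# KO mean multiplier for gene class x genotype x timepoint
ko_factor <- function(cls, kin, genotype, tp, effect) {
  if (genotype %in% c("WT", "Bcl3", "Nfkbid")) return(1)
  affected <- switch(cls,
    codependent = genotype %in% c("Nfkb1", "Nfkbiz"),
    p50_only = genotype == "Nfkb1",
    ikbz_only = genotype == "Nfkbiz",
    FALSE)
  if (!affected) return(1)
  late_from <- if (kin == "primary_late") 2 else 1
  if (tp >= late_from) effect else 1
}

#' Generate the synthetic expression table
#'
#' Builds per-gene mean trajectories from the planted class and kinetic
#' subtype (induced genes rise above `induced_fold`; dependent genes' KO
#' means are the WT means times `effect_ratio` at the affected timepoints;
#' codependent secondary genes rise late and collapse in both knockouts;
#' primary-late genes keep their initial induction and lose only the
#' sustained phase), draws NB counts around the means at equal sequencing
#' depth, and stores RPKM recomputed from the realized counts.
#'
#' @param params a [generator_params()].
#' @param annotation output of [generate_genome()].
#' @return an [expr_table()].
#' @export
generate_expression <- function(params = generator_params(),
                                annotation = generate_genome(params)) {
  set.seed(params$rng_seed + 202L)
  n <- nrow(annotation)
  baseline <- ifelse(annotation$true_class == "weak",
                     stats::rlnorm(n, log(5), 1.0),
                     stats::rlnorm(n, log(2), 0.5))
  fold <- params$induced_fold * stats::rlnorm(n, 0, 0.15)
  weak_fold <- stats::runif(n, 1, 3)
  tnf_fac <- ifelse(annotation$true_class == "codependent",
                    params$tnf_factor_codependent,
             ifelse(annotation$true_class == "ikbz_only",
                    params$tnf_factor_ikbz, 1))
  grid <- expand.grid(genotype = GENOTYPES, stimulus = STIMULI,
                      timepoint = TIMEPOINTS_H, replicate = 1:2,
                      stringsAsFactors = FALSE)
  lib <- params$library_size_millions
  rows <- vector("list", nrow(grid))
  for (j in seq_len(nrow(grid))) {
    g <- grid[j, ]
    tp_idx <- match(g$timepoint, TIMEPOINTS_H)
    shape_val <- vapply(seq_len(n), function(i) {
      kin <- annotation$true_kinetics[i]
      f <- if (kin == "flat") weak_fold[i] else fold[i]
      s <- expr_shape(kin, f)[tp_idx]
      if (kin == "flat" && g$timepoint > 0) {
        # weak genes drift mildly up to their (small) fold by 2 h
        s <- 1 + (weak_fold[i] - 1) * min(1, g$timepoint / 2)
      }
      s
    }, numeric(1))
    kof <- vapply(seq_len(n), function(i) {
      ko_factor(annotation$true_class[i], annotation$true_kinetics[i],
                g$genotype, g$timepoint, params$effect_ratio)
    }, numeric(1))
    tf <- if (g$stimulus == "TNF" && g$timepoint > 0) tnf_fac else rep(1, n)
    mu_rpkm <- baseline * shape_val * kof * tf
    mu_count <- mu_rpkm * annotation$length_kb * lib
    counts <- stats::rnbinom(n, mu = mu_count, size = 1 / params$nb_dispersion)
    rows[[j]] <- data.frame(
      gene_id = annotation$gene_id,
      genotype = g$genotype, stimulus = g$stimulus,
      timepoint = g$timepoint, replicate = g$replicate,
      count = counts,
      rpkm = compute_rpkm(counts, annotation$length_kb, lib),
      stringsAsFactors = FALSE
    )
  }
  values <- do.call(rbind, rows)
  tab <- expr_table(annotation[c("gene_id", "length_kb", "chrom", "tss",
                                 "strand", "response_class")], values)
  stage_log("generate_expression", n_cells = nrow(values))
  tab
}

#' Generate synthetic ChIP/ATAC peaks with planted kinetics and dependence
#'
#' Each peak gets a kinetic archetype (IkBzeta-bound peaks sit almost
#' exclusively in the late archetype 6), factor memberships for p50, RelA,
#' IkBzeta, ATAC and H3K27ac, replicate RPKMs lognormal around the archetype
#' mean with peak scores correlated with signal, and knockout (Nfkb1-/-)
#' tracks for IkBzeta and RelA in which planted p50-dependent peaks carry
#' `effect_ratio` of the WT signal. One IkBzeta peak is planted near the TSS
#' of every codependent gene and labelled p50-dependent for both IkBzeta and
#' RelA binding.
#'
#' @param params a [generator_params()].
#' @param annotation output of [generate_genome()].
#' @return list: `peaks` (locations + planted labels), `tables` (factor ->
#'   timepoint -> replicate peak data.frames for the reproducibility filter),
#'   `signal` (factor -> peaks x timepoint replicate-averaged RPKM matrix),
#'   `binding` (WT/KO 2 h replicate-averaged vectors for IkBzeta and RelA),
#'   `atac_0h` (called 0 h ATAC peak table).
#' @export
generate_peaks <- function(params = generator_params(),
                           annotation = generate_genome(params)) {
  set.seed(params$rng_seed + 303L)
  n <- params$n_peaks
  codep <- annotation[annotation$true_class == "codependent", ]
  n_codep <- nrow(codep)
  if (n < n_codep + 10) stop("n_peaks too small for planted peaks")
  chroms <- names(params$chrom_sizes)
  chrom <- sample(chroms, n, replace = TRUE,
                  prob = params$chrom_sizes / sum(params$chrom_sizes))
  center <- floor(stats::runif(n, 2e4, params$chrom_sizes[chrom] - 2e4))
  # plant one peak near each codependent gene's TSS (within 30 kb)
  if (n_codep > 0) {
    planted <- seq_len(n_codep)
    chrom[planted] <- codep$chrom
    center[planted] <- pmax(2e4, floor(codep$tss +
                                         stats::runif(n_codep, -2e4, 2e4)))
  }
  half_width <- floor(stats::runif(n, 150, 300))
  peaks <- data.frame(
    peak_id = sprintf("pk%05d", seq_len(n)),
    chrom = chrom,
    start = as.integer(center - half_width),
    end = as.integer(center + half_width),
    stringsAsFactors = FALSE
  )

  archetype <- sample(1:6, n, replace = TRUE,
                      prob = c(0.10, 0.15, 0.20, 0.20, 0.15, 0.20))
  is_p50 <- stats::runif(n) < ifelse(archetype < 6, 0.5, 0.1)
  is_rela <- stats::runif(n) < ifelse(archetype < 6, 0.8, 0.3)
  is_ikbz <- stats::runif(n) < ifelse(archetype == 6, 0.9, 0.001)
  if (n_codep > 0) {
    pl <- seq_len(n_codep)
    archetype[pl] <- 6L
    is_ikbz[pl] <- TRUE
    is_rela[pl] <- TRUE
    is_p50[pl] <- TRUE
  }
  # p50-dependence of IkBzeta / RelA binding
  ikbz_dep <- rep(FALSE, n)
  rela_dep <- rep(FALSE, n)
  if (n_codep > 0) {
    ikbz_dep[seq_len(n_codep)] <- TRUE
    rela_dep[seq_len(n_codep)] <- TRUE
  }
  extra_pool <- which(is_ikbz & !ikbz_dep)
  n_extra <- round(params$frac_ikbz_dependent_extra * length(extra_pool))
  if (n_extra > 0) {
    extra <- sample(extra_pool, n_extra)
    ikbz_dep[extra] <- TRUE
    rela_dep[extra] <- stats::runif(n_extra) < 0.5
  }
  dep_label <- ifelse(ikbz_dep, "ikbz_p50_dependent",
               ifelse(rela_dep, "rela_p50_dependent", "independent"))
  # accessibility at 0 h: early archetypes poised; IkBzeta sites open
  acc_prob <- ifelse(archetype <= 4, 0.9, ifelse(is_ikbz, 0.7, 0.15))
  accessible <- stats::runif(n) < acc_prob
  motif_p <- ifelse(ikbz_dep, params$motif_prob_dependent,
                    params$motif_prob_background)
  motif_planted <- stats::runif(n) < motif_p

  amp <- stats::rlnorm(n, log(10), 0.6)
  sig <- params$peak_lognorm_sigma
  factors <- c("p50", "RelA", "IkBzeta", "ATAC", "H3K27ac")
  member <- list(p50 = is_p50, RelA = is_rela, IkBzeta = is_ikbz,
                 ATAC = rep(TRUE, n), H3K27ac = rep(TRUE, n))
  tables <- list(); signal <- list()
  lib <- params$peak_library_size_millions
  for (f in factors) {
    famp <- amp * stats::rlnorm(n, 0, 0.3)
    tabs_tp <- list(); avg <- matrix(0, n, length(CHIP_TIMEPOINTS_H),
                                     dimnames = list(peaks$peak_id,
                                                     CHIP_TIMEPOINTS_H))
    for (ti in seq_along(CHIP_TIMEPOINTS_H)) {
      shape_t <- ARCHETYPE_SHAPES[archetype, ti]
      if (f == "ATAC") {
        # accessibility: open sites flat-high from 0 h, closed sites follow
        # their archetype (opening with binding)
        shape_t <- ifelse(accessible, 1, ARCHETYPE_SHAPES[archetype, ti])
      }
      if (f == "H3K27ac") shape_t <- pmin(1, ARCHETYPE_SHAPES[archetype, ti] * 1.2)
      reps <- list()
      for (r in 1:2) {
        rpkm <- famp * shape_t * stats::rlnorm(n, 0, sig)
        rpkm[!member[[f]]] <- stats::rlnorm(n, log(0.3), 0.5)[!member[[f]]]
        score <- rpkm * 6 * stats::rlnorm(n, 0, 0.3)
        tab <- cbind(peaks[c("chrom", "start", "end", "peak_id")],
                     score = score, rpkm = rpkm)
        reps[[paste0("rep", r)]] <- tab
        avg[, ti] <- avg[, ti] + rpkm / 2
      }
      tabs_tp[[as.character(CHIP_TIMEPOINTS_H[ti])]] <- reps
    }
    tables[[f]] <- tabs_tp
    signal[[f]] <- avg
  }
  # knockout (Nfkb1-/-) 2 h tracks for IkBzeta and RelA
  binding <- list()
  for (f in c("IkBzeta", "RelA")) {
    wt <- signal[[f]][, "2"]
    depn <- if (f == "IkBzeta") ikbz_dep else rela_dep
    kfac <- ifelse(depn, params$effect_ratio * stats::rlnorm(n, 0, sig),
                   stats::rlnorm(n, 0, 0.35))
    ko <- wt * kfac * stats::rlnorm(n, 0, sig)
    binding[[f]] <- list(wt = stats::setNames(wt, peaks$peak_id),
                         ko = stats::setNames(ko, peaks$peak_id))
  }
  atac_0h <- cbind(peaks[accessible, c("chrom", "start", "end", "peak_id")],
                   score = 20 + stats::rlnorm(sum(accessible), log(10), 0.5))
  atac_0h$peak_id <- paste0("atac_", atac_0h$peak_id)

  peaks$archetype <- archetype
  peaks$is_p50 <- is_p50; peaks$is_rela <- is_rela; peaks$is_ikbz <- is_ikbz
  peaks$peak_dependence <- dep_label
  peaks$motif_planted <- motif_planted
  peaks$accessible_0h <- accessible
  stage_log("generate_peaks", n_peaks = n,
            n_ikbz = sum(is_ikbz), n_ikbz_dep = sum(ikbz_dep))
  list(peaks = peaks, tables = tables, signal = signal, binding = binding,
       atac_0h = atac_0h, library_size_millions = lib)
}

#' Generate peak-window sequences with planted homodimer motifs
#'
#' Draws i.i.d. uniform A/C/G/T backgrounds of `window_bp` and inserts one
#' `GGGNNNNNCCC` instance (random spacer) at a random offset into each peak
#' whose `motif_planted` flag is set.
#'
#' @param peaks the `peaks` data.frame from [generate_peaks()] (needs
#'   `peak_id` and `motif_planted`).
#' @param params a [generator_params()].
#' @return named character vector of sequences.
#' @export
generate_sequences <- function(peaks, params = generator_params()) {
  if (params$window_bp < HOMODIMER_LEN) stop("window smaller than motif")
  set.seed(params$rng_seed + 404L)
  w <- params$window_bp
  n <- nrow(peaks)
  seqs <- vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), w, replace = TRUE), collapse = "")
  }, character(1))
  plant <- which(peaks$motif_planted)
  for (i in plant) {
    off <- sample.int(w - HOMODIMER_LEN + 1L, 1L) - 1L
    spacer <- paste(sample(c("A", "C", "G", "T"), 5, replace = TRUE),
                    collapse = "")
    motif <- paste0("GGG", spacer, "CCC")
    seqs[i] <- paste0(substr(seqs[i], 1, off), motif,
                      substr(seqs[i], off + HOMODIMER_LEN + 1L, w))
  }
  stats::setNames(seqs, peaks$peak_id)
}

#' Generate the full synthetic dataset with ground truth
#'
#' Convenience wrapper running [generate_genome()], [generate_expression()],
#' [generate_peaks()] and [generate_sequences()] under one seed and
#' assembling the truth tables used to score the classifiers.
#'
#' @param params a [generator_params()].
#' @return list: `annotation`, `expression`, `peaks` (from
#'   [generate_peaks()]), `sequences`, `truth` (list of `gene_class`,
#'   `gene_kinetics`, `peak_archetype`, `peak_dependence`, `motif_planted`,
#'   `accessible_0h`), `params`.
#' @export
simulate_dataset <- function(params = generator_params()) {
  annotation <- generate_genome(params)
  expression <- generate_expression(params, annotation)
  pk <- generate_peaks(params, annotation)
  sequences <- generate_sequences(pk$peaks, params)
  truth <- list(
    gene_class = stats::setNames(annotation$true_class, annotation$gene_id),
    gene_kinetics = stats::setNames(annotation$true_kinetics,
                                    annotation$gene_id),
    peak_archetype = stats::setNames(pk$peaks$archetype, pk$peaks$peak_id),
    peak_dependence = stats::setNames(pk$peaks$peak_dependence,
                                      pk$peaks$peak_id),
    motif_planted = stats::setNames(pk$peaks$motif_planted, pk$peaks$peak_id),
    accessible_0h = stats::setNames(pk$peaks$accessible_0h, pk$peaks$peak_id)
  )
  list(annotation = annotation, expression = expression, peaks = pk,
       sequences = sequences, truth = truth, params = params)
}
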