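#' Reads-per-kilobase-per-million normalization
#'
#' @param counts numeric vector/matrix of raw read counts.
#' @param gene_length_kb feature length(s) in kilobases.
#' @param library_size_millions sequencing depth(s) in millions of reads.
#' @return RPKM values with the shape of `counts`.
#' @export
compute_rpkm <- function(counts, gene_length_kb, library_size_millions) {
  if (any(gene_length_kb <= 0)) stop("gene length must be positive")
  if (any(library_size_millions <= 0)) stop("library size must be positive")
  counts / (gene_length_kb * library_size_millions)
}

#' Pooled method-of-moments NB dispersion estimate
#'
#' Estimates a single dispersion (variance = mu + phi * mu^2) shared across
#' genes from replicate groups. Uses the ratio-of-sums estimator
#' `sum(s2 - m) / sum(m^2 - s2/n)`, which is robust to the per-group noise of
#' two-replicate designs, floored at `floor`.
#'
#' @param count_groups list of numeric replicate-count vectors (one per
#'   gene x condition group), or a matrix with replicates in columns.
#' @param floor minimum returned dispersion.
#' @return single dispersion estimate.
#' @export
estimate_dispersion <- function(count_groups, floor = 0.01) {
  if (is.matrix(count_groups)) {
    count_groups <- split(count_groups, row(count_groups))
  }
  m <- vapply(count_groups, mean, numeric(1))
  s2 <- vapply(count_groups, stats::var, numeric(1))
  n <- lengths(count_groups)
  keep <- n >= 2 & m > 0 & is.finite(s2)
  if (!any(keep)) return(floor)
  num <- sum(s2[keep] - m[keep])
  den <- sum(m[keep]^2 - s2[keep] / n[keep])
  if (den <= 0) return(floor)
  max(floor, num / den)
}

#' Negative-binomial exact contrast test
#'
#' Two-sided exact test for a difference in mean counts between two small
#' replicate groups, conditioning on the total count (the sum of independent
#' NB(mu, 1/phi) variables is NB(n*mu, n/phi)). All splits of the total whose
#' conditional probability does not exceed that of the observed split
#' contribute to the p-value. With `dispersion = 0` the test reduces to the
#' Poisson (binomial-conditional) exact test.
#'
#' @param counts_ko,counts_wt replicate count vectors (>= 2 each).
#' @param dispersion NB dispersion phi (variance = mu + phi mu^2).
#' @return list with `p_value` and `degenerate` (TRUE when both arms are
#'   all-zero, in which case p = 1).
#' @export
test_contrast <- function(counts_ko, counts_wt, dispersion = 0.05) {
  if (length(counts_ko) < 2 || length(counts_wt) < 2) {
    stop("need >= 2 replicates per arm")
  }
  if (dispersion < 0) stop("dispersion must be nonnegative")
  s_ko <- sum(counts_ko); s_wt <- sum(counts_wt)
  total <- s_ko + s_wt
  if (total == 0) return(list(p_value = 1, degenerate = TRUE))
  n_ko <- length(counts_ko); n_wt <- length(counts_wt)
  mu0 <- total / (n_ko + n_wt)
  a <- 0:total
  dens <- function(x, n) {
    if (dispersion < 1e-12) {
      stats::dpois(x, lambda = n * mu0, log = TRUE)
    } else {
      stats::dnbinom(x, mu = n * mu0, size = n / dispersion, log = TRUE)
    }
  }
  logp <- dens(a, n_ko) + dens(total - a, n_wt)
  logp <- logp - max(logp)
  p_all <- exp(logp)
  p_obs <- p_all[s_ko + 1L]
  p <- sum(p_all[p_all <= p_obs * (1 + 1e-10)]) / sum(p_all)
  list(p_value = min(1, p), degenerate = FALSE)
}

# Replicate-averaged RPKM per gene x timepoint for one genotype/stimulus.
avg_rpkm_by_timepoint <- function(values, genotype, stimulus) {
  v <- values[values$genotype == genotype & values$stimulus == stimulus, ]
  if (!nrow(v)) return(NULL)
  ag <- stats::aggregate(rpkm ~ gene_id + timepoint, data = v, FUN = mean)
  ag
}

#' Classify genes as dependent on a regulator
#'
#' For each gene, the knockout/wild-type replicate-averaged RPKM ratio is
#' evaluated at every post-stimulation timepoint at which the WT RPKM exceeds
#' the expression floor. The timepoint with the minimum ratio is selected and
#' a NB exact contrast p-value is computed there; dependence requires both
#' `min_ratio < dependence_ratio` and BH-adjusted p `< p_cut` (strict
#' inequalities). The 0.5 h timepoint is screened separately (early
#' dependence) from the pooled 1/2/6 h screen (late dependence), with BH
#' adjustment within each screen; a gene is dependent if either screen calls
#' it. Genes with no eligible timepoint are excluded as `not_expressed`.
#'
#' @param table an [expr_table()].
#' @param regulator knockout genotype to contrast against WT (e.g. `"Nfkb1"`).
#' @param config a [run_config()].
#' @param stimulus stimulus whose time course is used (default `"lipidA"`).
#' @param dispersion optional NB dispersion; estimated from the table's WT
#'   and KO replicate groups when `NULL`.
#' @return data.frame with one row per gene: ratio, selected timepoint,
#'   p-values, per-screen and combined dependence calls, induction class.
#' @export
classify_dependence <- function(table, regulator, config = run_config(),
                                stimulus = "lipidA", dispersion = NULL) {
  stopifnot(inherits(table, "expr_table"))
  v <- table$values
  if (!regulator %in% v$genotype) stop("genotype not in table: ", regulator)
  wt <- avg_rpkm_by_timepoint(v, "WT", stimulus)
  ko <- avg_rpkm_by_timepoint(v, regulator, stimulus)
  if (is.null(wt) || is.null(ko)) stop("missing genotype/stimulus samples")
  if (is.null(dispersion)) {
    sub <- v[v$genotype %in% c("WT", regulator) & v$stimulus == stimulus, ]
    groups <- split(sub$count,
                    paste(sub$gene_id, sub$genotype, sub$timepoint))
    dispersion <- estimate_dispersion(groups, floor = config$dispersion_floor)
  }
  vs <- v[v$stimulus == stimulus & v$genotype %in% c("WT", regulator), ]
  cnt_split <- split(vs$count, paste(vs$gene_id, vs$genotype, vs$timepoint))
  counts_of <- function(gene, genotype, tp) {
    cnt_split[[paste(gene, genotype, tp)]]
  }
  # fast lookup matrices gene x timepoint
  tps <- sort(unique(v$timepoint))
  to_mat <- function(ag) {
    m <- matrix(NA_real_, nrow(table$genes), length(tps),
                dimnames = list(table$genes$gene_id, tps))
    m[cbind(ag$gene_id, as.character(ag$timepoint))] <- ag$rpkm
    m
  }
  wt_m <- to_mat(wt); ko_m <- to_mat(ko)
  post <- tps[tps > 0]
  genes <- table$genes$gene_id

  screen_of <- function(tp) if (tp == 0.5) "early" else "late"
  res <- data.frame(gene_id = genes, regulator = regulator,
                    stringsAsFactors = FALSE)
  res$min_ratio <- NA_real_; res$selected_timepoint <- NA_real_
  res$p_value <- NA_real_; res$adjusted_p <- NA_real_
  res$screen <- NA_character_; res$status <- "ok"
  per_screen <- list(early = res[0, ], late = res[0, ])
  sel <- vector("list", length(genes)); names(sel) <- genes

  ratios <- array(NA_real_, c(length(genes), length(post)),
                  dimnames = list(genes, post))
  for (j in seq_along(post)) {
    tp <- as.character(post[j])
    wt_t <- wt_m[, tp]; ko_t <- ko_m[, tp]
    eligible <- !is.na(wt_t) & wt_t > config$expressed_rpkm & !is.na(ko_t)
    r <- ko_t / pmax(wt_t, config$rpkm_guard)
    r[!eligible] <- NA_real_
    ratios[, j] <- r
  }

  # per-screen selection and testing
  screen_calls <- list()
  for (sc in c("early", "late")) {
    sc_tps <- post[vapply(post, screen_of, "") == sc]
    if (!length(sc_tps)) next
    sub <- ratios[, as.character(sc_tps), drop = FALSE]
    has <- rowSums(!is.na(sub)) > 0
    idx <- which(has)
    if (!length(idx)) next
    df <- data.frame(gene_id = genes[idx], stringsAsFactors = FALSE)
    df$min_ratio <- apply(sub[idx, , drop = FALSE], 1, min, na.rm = TRUE)
    df$selected_timepoint <- vapply(idx, function(i) {
      r <- sub[i, ]
      sc_tps[which(r == min(r, na.rm = TRUE) & !is.na(r))[1]]
    }, numeric(1))
    df$p_value <- vapply(seq_len(nrow(df)), function(k) {
      g <- df$gene_id[k]; tp <- df$selected_timepoint[k]
      test_contrast(counts_of(g, regulator, tp), counts_of(g, "WT", tp),
                    dispersion = dispersion)$p_value
    }, numeric(1))
    df$adjusted_p <- stats::p.adjust(df$p_value, method = "BH")
    df$dependent <- df$min_ratio < config$dependence_ratio &
      df$adjusted_p < config$p_cut
    df$screen <- sc
    screen_calls[[sc]] <- df
  }

  early <- screen_calls[["early"]]; late <- screen_calls[["late"]]
  res$dependent_early <- res$gene_id %in% early$gene_id[early$dependent]
  res$dependent_late <- res$gene_id %in% late$gene_id[late$dependent]
  res$dependent <- res$dependent_early | res$dependent_late
  all_calls <- do.call(rbind, screen_calls)
  if (!is.null(all_calls) && nrow(all_calls)) {
    best <- all_calls[order(all_calls$gene_id, all_calls$min_ratio,
                            all_calls$selected_timepoint), ]
    best <- best[!duplicated(best$gene_id), ]
    i <- match(best$gene_id, res$gene_id)
    res$min_ratio[i] <- best$min_ratio
    res$selected_timepoint[i] <- best$selected_timepoint
    res$p_value[i] <- best$p_value
    res$adjusted_p[i] <- best$adjusted_p
    res$screen[i] <- best$screen
  }
  res$status[is.na(res$min_ratio)] <- "not_expressed"
  ind <- classify_induction(table, config, stimulus = stimulus)
  res$induction_class <- ind$induction_class[match(res$gene_id, ind$gene_id)]
  res$dispersion_used <- dispersion
  stage_log("classify_dependence", regulator = regulator,
            n_genes = nrow(res), n_dependent = sum(res$dependent),
            dispersion = signif(dispersion, 3))
  res
}

#' Classify wild-type induction strength
#'
#' The maximum WT fold-change over the unstimulated baseline decides the
#' class: strictly above `induced_fc` the gene carries its annotated primary
#' or secondary response label; at or below `induced_fc` (including
#' repression) it is `weak_or_repressed`; genes whose WT RPKM never exceeds
#' the expression floor are `not_induced`. A zero baseline is replaced by a
#' 0.5 RPKM pseudocount and flagged.
#'
#' @inheritParams classify_dependence
#' @return data.frame with `gene_id`, `max_fold_change`, `induction_class`,
#'   `zero_baseline` flag.
#' @export
classify_induction <- function(table, config = run_config(),
                               stimulus = "lipidA") {
  stopifnot(inherits(table, "expr_table"))
  wt <- avg_rpkm_by_timepoint(table$values, "WT", stimulus)
  if (is.null(wt)) stop("no WT samples for stimulus ", stimulus)
  genes <- table$genes
  out <- data.frame(gene_id = genes$gene_id, stringsAsFactors = FALSE)
  base <- wt$rpkm[wt$timepoint == 0][match(out$gene_id,
                                           wt$gene_id[wt$timepoint == 0])]
  post <- wt[wt$timepoint > 0, ]
  peak_by_gene <- tapply(post$rpkm, post$gene_id, max)
  peak <- as.numeric(peak_by_gene[out$gene_id])
  max_by_gene <- tapply(wt$rpkm, wt$gene_id, max)
  expressed <- !is.na(max_by_gene[out$gene_id]) &
    as.numeric(max_by_gene[out$gene_id]) > config$expressed_rpkm
  out$zero_baseline <- !is.na(base) & base == 0
  denom <- ifelse(out$zero_baseline, 0.5, base)
  out$max_fold_change <- peak / denom
  cls <- ifelse(!expressed, "not_induced",
         ifelse(out$max_fold_change > config$induced_fc,
                genes$response_class[match(out$gene_id, genes$gene_id)],
                "weak_or_repressed"))
  cls[cls %in% c("unclassified", NA)] <- "not_induced"
  out$induction_class <- cls
  out
}

#' Join two dependence-call sets into codependence labels
#'
#' A gene is codependent only when it independently meets both the ratio and
#' significance thresholds under each regulator; a low ratio without
#' significance under one regulator leaves the gene in the other regulator's
#' single-dependence class.
#'
#' @param calls_a,calls_b outputs of [classify_dependence()] for two
#'   regulators over the same gene universe.
#' @return data.frame with `gene_id`, both per-regulator calls and ratios,
#'   and `label` in `codependent`, `<A>_only`, `<B>_only`, `neither`.
#' @export
codependence_join <- function(calls_a, calls_b) {
  reg_a <- unique(calls_a$regulator); reg_b <- unique(calls_b$regulator)
  stopifnot(length(reg_a) == 1, length(reg_b) == 1)
  m <- merge(calls_a[c("gene_id", "dependent", "min_ratio")],
             calls_b[c("gene_id", "dependent", "min_ratio")],
             by = "gene_id", all = TRUE, suffixes = c("_a", "_b"))
  only_one <- is.na(m$dependent_a) | is.na(m$dependent_b)
  dep_a <- !is.na(m$dependent_a) & m$dependent_a
  dep_b <- !is.na(m$dependent_b) & m$dependent_b
  m$label <- ifelse(dep_a & dep_b, "codependent",
             ifelse(dep_a, paste0(reg_a, "_only"),
             ifelse(dep_b, paste0(reg_b, "_only"), "neither")))
  m$label[only_one] <- "neither"
  m$flagged_partial <- only_one
  names(m)[match(c("dependent_a", "min_ratio_a"), names(m))] <-
    paste0(c("dependent_", "min_ratio_"), reg_a)
  names(m)[match(c("dependent_b", "min_ratio_b"), names(m))] <-
    paste0(c("dependent_", "min_ratio_"), reg_b)
  stage_log("codependence_join", n = nrow(m),
            n_codependent = sum(m$label == "codependent"))
  m
}
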