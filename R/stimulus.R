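#' Per-gene TNF : lipid A expression ratios
#'
#' For genes passing the induced/expressed filter (lipid A WT fold induction
#' strictly above `induced_fc_filter` and WT RPKM above the expression floor
#' at some timepoint), computes the replicate-averaged TNF/lipid A RPKM
#' ratio at every shared post-stimulation timepoint (pseudocount on both
#' terms) and its minimum.
#'
#' @param table an [expr_table()] holding both stimuli (typically mRNA).
#' @param config a [run_config()].
#' @param induced_fc_filter induction filter for this analysis (default 3,
#'   the stimulus-differential convention; the induction-class analysis uses
#'   5).
#' @param genotype genotype whose samples are compared (default `"WT"`).
#' @param filter_table optional second [expr_table()] used only for the
#'   induced/expressed filter (e.g. nascent transcripts) when the ratio
#'   table should not silently stand in for it.
#' @return data.frame: `gene_id`, one `ratio_<t>` column per timepoint,
#'   `min_ratio`, `min_timepoint`, `included` flag (excluded genes keep a
#'   row, flagged, with NA ratios).
#' @export
stimulus_ratio <- function(table, config = run_config(),
                           induced_fc_filter = 3, genotype = "WT",
                           filter_table = NULL) {
  stopifnot(inherits(table, "expr_table"))
  ft <- filter_table %||% table
  la <- avg_rpkm_by_timepoint(table$values, genotype, "lipidA")
  tnf <- avg_rpkm_by_timepoint(table$values, genotype, "TNF")
  if (is.null(la) || is.null(tnf)) stop("both stimuli must be present")
  fla <- avg_rpkm_by_timepoint(ft$values, genotype, "lipidA")
  genes <- sort(unique(table$genes$gene_id))
  tps <- sort(intersect(unique(la$timepoint), unique(tnf$timepoint)))
  tps <- tps[tps > 0]
  base <- fla$rpkm[fla$timepoint == 0][match(genes,
                                             fla$gene_id[fla$timepoint == 0])]
  peak_la <- tapply(fla$rpkm[fla$timepoint > 0],
                    fla$gene_id[fla$timepoint > 0], max)[genes]
  max_la <- tapply(fla$rpkm, fla$gene_id, max)[genes]
  denom <- ifelse(!is.na(base) & base > 0, base, 0.5)
  induced <- !is.na(peak_la) & (peak_la / denom) > induced_fc_filter
  expressed <- !is.na(max_la) & max_la > config$expressed_rpkm
  included <- induced & expressed

  out <- data.frame(gene_id = genes, included = included,
                    stringsAsFactors = FALSE)
  eps <- config$ratio_pseudocount
  rmat <- matrix(NA_real_, length(genes), length(tps),
                 dimnames = list(genes, paste0("ratio_", tps)))
  for (tp in tps) {
    la_t <- la$rpkm[la$timepoint == tp][match(genes,
                                              la$gene_id[la$timepoint == tp])]
    tnf_t <- tnf$rpkm[tnf$timepoint == tp][match(genes,
                                                 tnf$gene_id[tnf$timepoint == tp])]
    rmat[, paste0("ratio_", tp)] <- pseudo_ratio(tnf_t, la_t, eps)
  }
  rmat[!included, ] <- NA_real_
  out <- cbind(out, as.data.frame(rmat))
  out$min_ratio <- suppressWarnings(apply(rmat, 1, min, na.rm = TRUE))
  out$min_ratio[!is.finite(out$min_ratio)] <- NA_real_
  out$min_timepoint <- vapply(seq_along(genes), function(i) {
    r <- rmat[i, ]
    if (all(is.na(r))) NA_real_ else tps[which.min(r)]
  }, numeric(1))
  rownames(out) <- NULL
  stage_log("stimulus_ratio", n_genes = length(genes),
            n_included = sum(included))
  out
}

#' Tier the stimulus-differential calls
#'
#' Tiers by the minimum TNF/lipid A ratio against the 1/3 and 1/60 cutoffs
#' (inclusive `<=`): `strong` at or below 1/60, `differential` at or below
#' 1/3, otherwise `not_differential`. Tiers are nested: every strong gene is
#' also differential by construction of the cutoffs.
#'
#' @param ratios output of [stimulus_ratio()].
#' @param config a [run_config()] (`diff_ratios` holds the two cutoffs).
#' @return the input with a `tier` column (`NA` for excluded genes).
#' @export
classify_differential <- function(ratios, config = run_config()) {
  cuts <- sort(config$diff_ratios) # c(1/60, 1/3)
  tier <- ifelse(is.na(ratios$min_ratio), NA_character_,
          ifelse(ratios$min_ratio <= cuts[1], "strong",
          ifelse(ratios$min_ratio <= cuts[2], "differential",
                 "not_differential")))
  ratios$tier <- tier
  ratios
}

#' Cross-tabulate differential tiers against dependence classes
#'
#' Counts genes per (tier x dependence class) with tier-conditional
#' percentages. Dependence labels come in as a per-gene annotation (e.g.
#' IkBzeta dependence from nascent transcripts, IRF3 dependence from
#' separate knockout data); genes without a label are tallied as
#' `unlabeled`.
#'
#' @param differential_calls output of [classify_differential()].
#' @param dependence_labels named character vector gene_id -> class.
#' @return data.frame `tier`, `class`, `n`, `pct_of_tier`.
#' @export
crosstab_dependence <- function(differential_calls, dependence_labels) {
  dc <- differential_calls[!is.na(differential_calls$tier), ]
  lab <- dependence_labels[dc$gene_id]
  lab[is.na(lab)] <- "unlabeled"
  tiers <- c("not_differential", "differential", "strong")
  classes <- sort(unique(lab))
  tab <- table(factor(dc$tier, levels = tiers), factor(lab, levels = classes))
  out <- as.data.frame(tab, stringsAsFactors = FALSE)
  names(out) <- c("tier", "class", "n")
  tier_totals <- rowSums(tab)[out$tier]
  out$pct_of_tier <- ifelse(tier_totals > 0, 100 * out$n / tier_totals, 0)
  out
}
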