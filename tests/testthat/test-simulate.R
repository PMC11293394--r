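test_that("genome generation is seed-deterministic and respects bounds", {
  p <- generator_params(n_genes = 120, n_peaks = 60, rng_seed = 5)
  a1 <- generate_genome(p)
  a2 <- generate_genome(p)
  expect_identical(a1, a2)
  # every TSS inside its declared chromosome
  expect_true(all(a1$tss > 0 & a1$tss < p$chrom_sizes[a1$chrom]))
  expect_true(all(a1$length_kb > 0))
  expect_error(generator_params(n_genes = 0), "n_genes")
  expect_error(generator_params(chrom_sizes = numeric(0)), "chrom_sizes")
  expect_error(generator_params(class_mixture = c(a = 0.5, b = 0.6)),
               "sum to 1")
})

test_that("null effect ratio gives KO/WT near 1; default effect collapses it", {
  p_null <- generator_params(n_genes = 300, n_peaks = 60, effect_ratio = 1,
                             rng_seed = 7)
  ds <- simulate_dataset(p_null)
  # fixed-timepoint KO/WT ratio (the min over timepoints is biased below 1)
  v <- ds$expression$values
  v2 <- v[v$stimulus == "lipidA" & v$timepoint == 2, ]
  mu <- tapply(v2$rpkm, list(v2$gene_id, v2$genotype), mean)
  ratio2h <- mu[, "Nfkb1"] / pmax(mu[, "WT"], 0.5)
  expressed <- mu[, "WT"] > 3
  expect_lt(abs(stats::median(ratio2h[expressed]) - 1), 0.1)
  calls <- classify_dependence(ds$expression, "Nfkb1", run_config())
  ok <- calls$status == "ok"
  expect_lt(mean(calls$dependent[ok]), 0.01)

  # default effect 0.15: planted codependent genes realize ratio < 0.33
  # at >= 1 timepoint in >= 95% of cases
  p_eff <- generator_params(n_genes = 600, n_peaks = 80, rng_seed = 8)
  ds2 <- simulate_dataset(p_eff)
  calls2 <- classify_dependence(ds2$expression, "Nfkbiz", run_config())
  planted <- ds2$annotation$gene_id[ds2$annotation$true_class == "codependent"]
  realized <- calls2$min_ratio[match(planted, calls2$gene_id)]
  expect_gte(mean(realized < 0.33, na.rm = TRUE), 0.95)
})

test_that("planted TNF differential is a construction-level scaling", {
  ds <- simulate_dataset(generator_params(n_genes = 500, n_peaks = 60,
                                          rng_seed = 9))
  v <- ds$expression$values
  codep <- ds$annotation$gene_id[ds$annotation$true_class == "codependent"]
  fac <- ds$params$tnf_factor_codependent
  expect_gt(length(codep), 0)
  for (g in codep) {
    la <- v[v$gene_id == g & v$genotype == "WT" & v$stimulus == "lipidA" &
              v$timepoint == 2, "rpkm"]
    tnf <- v[v$gene_id == g & v$genotype == "WT" & v$stimulus == "TNF" &
               v$timepoint == 2, "rpkm"]
    # TNF mean is the lipid A mean times the planted factor; with NB noise
    # the realized ratio should be within a few-fold of the factor
    expect_lt(mean(tnf), mean(la) * fac * 5 + 0.5)
  }
})

test_that("counts and RPKM stay consistent to 6 significant digits", {
  ds <- simulate_dataset(generator_params(n_genes = 80, n_peaks = 40,
                                          rng_seed = 10))
  v <- ds$expression$values
  len <- ds$annotation$length_kb[match(v$gene_id, ds$annotation$gene_id)]
  recomputed <- compute_rpkm(v$count, len, ds$params$library_size_millions)
  expect_equal(signif(recomputed, 6), signif(v$rpkm, 6))
})

test_that("peak generation plants archetypes, dependence and accessibility", {
  p <- generator_params(n_genes = 300, n_peaks = 500, rng_seed = 11)
  ann <- generate_genome(p)
  pk <- generate_peaks(p, ann)
  peaks <- pk$peaks

  # IkBzeta binding is essentially confined to the late archetype
  expect_gte(mean(peaks$archetype[peaks$is_ikbz] == 6), 0.95)

  # archetype-6 IkBzeta signal: 0/0.5/1 h means are <= 10% of the 2 h mean
  sig <- pk$signal$IkBzeta
  late <- peaks$peak_id[peaks$is_ikbz & peaks$archetype == 6]
  m <- colMeans(sig[late, , drop = FALSE])
  expect_true(all(m[c("0", "0.5", "1")] <= 0.12 * m["2"]))

  # planted dependent peaks have low KO/WT ratio in expectation
  b <- pk$binding$IkBzeta
  dep_ids <- peaks$peak_id[peaks$peak_dependence == "ikbz_p50_dependent"]
  indep_ids <- peaks$peak_id[peaks$peak_dependence == "independent" &
                               peaks$is_ikbz]
  r_dep <- mean(b$ko[dep_ids] / pmax(b$wt[dep_ids], 0.1))
  r_indep <- stats::median(b$ko[indep_ids] / pmax(b$wt[indep_ids], 0.1))
  expect_lt(r_dep, 0.33)
  expect_gt(r_indep, 0.7)

  # every codependent gene has a planted IkBzeta peak within 30 kb of TSS
  codep <- ann[ann$true_class == "codependent", ]
  links <- annotate_peaks(peaks[peaks$is_ikbz, ], codep, window_kb = 30)
  expect_true(all(codep$gene_id %in% links$gene_id))

  # ATAC table matches the accessibility truth flags
  acc <- accessibility_overlay(peaks, pk$atac_0h)
  expect_equal(unname(acc), peaks$accessible_0h)
})

test_that("two seeds give distinct but distribution-matched peak signal", {
  p1 <- generator_params(n_genes = 100, n_peaks = 1000, rng_seed = 13)
  p2 <- generator_params(n_genes = 100, n_peaks = 1000, rng_seed = 14)
  s1 <- generate_peaks(p1, generate_genome(p1))$signal$RelA[, "1"]
  s2 <- generate_peaks(p2, generate_genome(p2))$signal$RelA[, "1"]
  expect_false(identical(s1, s2))
  ks <- suppressWarnings(stats::ks.test(s1, s2))
  expect_gt(ks$p.value, 0.01)
})

test_that("sequence windows have exact width and plant exactly where flagged", {
  p <- generator_params(n_genes = 60, n_peaks = 150, rng_seed = 15)
  ann <- generate_genome(p)
  pk <- generate_peaks(p, ann)
  seqs <- generate_sequences(pk$peaks, p)
  expect_true(all(nchar(seqs) == p$window_bp))
  planted <- pk$peaks$motif_planted
  # every planted window contains a scanner hit
  expect_true(all(has_homodimer(seqs[planted])))
  expect_error(generate_sequences(pk$peaks,
                                  generator_params(window_bp = 10,
                                                   rng_seed = 1)),
               "window")
})

test_that("unplanted windows hit at the analytic background rate", {
  p <- generator_params(n_genes = 50, n_peaks = 3000,
                        motif_prob_background = 0, motif_prob_dependent = 0,
                        rng_seed = 16)
  fake <- data.frame(peak_id = sprintf("s%04d", 1:3000),
                     motif_planted = FALSE)
  seqs <- generate_sequences(fake, p)
  counts <- vapply(seqs, function(s) nrow(scan_homodimer(s)), numeric(1))
  w <- p$window_bp
  expected <- 2 * (w - 10) * (1 / 4)^6 # both strands collapse to one pattern
  # windows are independent; per-window counts are near-Poisson
  se <- sqrt(expected / length(seqs))
  expect_lt(abs(mean(counts) - expected), 4 * se)
})

test_that("full dataset is deterministic under the seed", {
  p <- generator_params(n_genes = 60, n_peaks = 80, rng_seed = 17)
  d1 <- simulate_dataset(p)
  d2 <- simulate_dataset(p)
  expect_identical(d1$annotation, d2$annotation)
  expect_identical(d1$expression$values, d2$expression$values)
  expect_identical(d1$peaks$peaks, d2$peaks$peaks)
  expect_identical(d1$sequences, d2$sequences)
})
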