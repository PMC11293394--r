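test_that("compute_rpkm matches its unit definition and an element-wise oracle", {
  expect_equal(compute_rpkm(1000, 1, 1), 1000)
  expect_equal(compute_rpkm(0, 2, 5), 0)
  expect_error(compute_rpkm(10, 0, 1), "length")
  expect_error(compute_rpkm(10, 1, 0), "library")

  set.seed(91)
  counts <- matrix(rpois(400, 50), 50, 8)
  len <- runif(50, 0.5, 10)
  lib <- runif(8, 5, 40)
  # brute-force element-wise recomputation with per-column libraries
  rpkm <- sweep(compute_rpkm(counts, len, 1), 2, lib, "/")
  oracle <- matrix(0, 50, 8)
  for (i in 1:50) for (j in 1:8) oracle[i, j] <- counts[i, j] / (len[i] * lib[j])
  expect_equal(rpkm, oracle)
})

test_that("NB exact contrast test handles null, extreme and degenerate inputs", {
  expect_equal(test_contrast(c(10, 12), c(10, 12), 0.05)$p_value, 1)
  expect_lt(test_contrast(c(0, 0), c(500, 520), 0)$p_value, 1e-6)
  deg <- test_contrast(c(0, 0), c(0, 0), 0.05)
  expect_equal(deg$p_value, 1)
  expect_true(deg$degenerate)
  expect_error(test_contrast(5, c(1, 2)), "replicates")
  # p-values live in (0, 1]
  set.seed(5)
  for (i in 1:20) {
    p <- test_contrast(rpois(2, 30), rpois(2, 60), 0.05)$p_value
    expect_gt(p, 0)
    expect_lte(p, 1)
  }
})

test_that("pooled MoM dispersion estimator recovers the simulated dispersion", {
  set.seed(31)
  phi <- 0.08
  mu <- rlnorm(4000, log(80), 0.7)
  groups <- lapply(mu, function(m) rnbinom(2, mu = m, size = 1 / phi))
  est <- estimate_dispersion(groups)
  expect_gt(est, phi * 0.7)
  expect_lt(est, phi * 1.4)
  # floor applies for underdispersed data
  pois <- lapply(mu[1:500], function(m) rpois(2, m))
  expect_gte(estimate_dispersion(pois, floor = 0.01), 0.01)
})

test_that("dependence thresholds force calls on deterministic fixtures", {
  fix <- data.frame(gene_id = c("dep", "edge", "indep", "silent"))
  fix$wt <- list(c(2, 3, 12, 12, 12), c(2, 3, 100, 100, 100),
                 c(2, 3, 12, 12, 12), c(0.5, 0.6, 0.7, 0.6, 0.5))
  fix$ratio_ko <- c(0.25, 0.33, 1.0, 1.0)
  fix$response_class <- "secondary"
  tab <- make_expr_fixture(fix, length_kb = 1, lib = 1)
  calls <- classify_dependence(tab, "Nfkb1", run_config())

  dep <- calls[calls$gene_id == "dep", ]
  expect_true(dep$dependent)
  expect_equal(dep$min_ratio, 0.25, tolerance = 1e-6)
  expect_lt(dep$adjusted_p, 0.01)

  # ratio exactly at the threshold is NOT dependent (strict inequality)
  edge <- calls[calls$gene_id == "edge", ]
  expect_equal(edge$min_ratio, 0.33, tolerance = 1e-9)
  expect_false(edge$dependent)

  expect_false(calls$dependent[calls$gene_id == "indep"])
  expect_equal(calls$status[calls$gene_id == "silent"], "not_expressed")
})

test_that("a strong early-response defect is caught by the 0.5 h screen", {
  # a gene induced ~129-fold in WT but only ~8-fold in the knockout at 0.5 h
  fix <- data.frame(gene_id = c("egr1_like", sprintf("null%02d", 1:9)))
  fix$wt <- c(list(c(2, 258, 3, 2, 2)),
              replicate(9, c(5, 30, 30, 30, 30), simplify = FALSE))
  fix$ratio_ko <- c(8 / 129, rep(1, 9))
  fix$response_class <- "primary"
  tab <- make_expr_fixture(fix)
  calls <- classify_dependence(tab, "Nfkb1", run_config())
  g <- calls[calls$gene_id == "egr1_like", ]
  expect_true(g$dependent_early)
  expect_equal(g$selected_timepoint, 0.5)
  expect_lt(g$min_ratio, 0.1)
  expect_false(any(calls$dependent[calls$gene_id != "egr1_like"]))
})

test_that("induction classes follow the fold-change rules", {
  fix <- data.frame(gene_id = c("ind", "weak", "edge47", "down"))
  fix$wt <- list(c(2, 3, 20, 30, 25), c(10, 10, 9.5, 9, 8),
                 c(3, 4, 12, 14, 13), c(10, 9, 8, 5, 4))
  fix$ratio_ko <- 1
  fix$response_class <- c("primary", "unclassified", "unclassified",
                          "unclassified")
  tab <- make_expr_fixture(fix)
  ind <- classify_induction(tab, run_config())
  expect_equal(ind$induction_class[ind$gene_id == "ind"], "primary")
  expect_equal(ind$max_fold_change[ind$gene_id == "ind"], 15, tolerance = 1e-6)
  expect_equal(ind$induction_class[ind$gene_id == "weak"], "weak_or_repressed")
  # max fold 14/3 = 4.67 stays below the strict > 5 rule
  expect_equal(ind$induction_class[ind$gene_id == "edge47"],
               "weak_or_repressed")
  expect_equal(ind$induction_class[ind$gene_id == "down"], "weak_or_repressed")
})

test_that("codependence requires both regulators to meet ratio AND significance", {
  fix <- data.frame(gene_id = c("both", "a_only", "ratio_no_p", "none"))
  fix$wt <- replicate(4, c(2, 4, 30, 30, 30), simplify = FALSE)
  fix$ratio_Nfkb1 <- c(0.1, 0.1, 1.0, 1.0)
  fix$ratio_Nfkbiz <- c(0.1, 1.0, 0.1, 1.0)
  fix$response_class <- "secondary"
  tab <- make_expr_fixture(fix, regulators = c("Nfkb1", "Nfkbiz"))
  ca <- classify_dependence(tab, "Nfkb1", run_config())
  cb <- classify_dependence(tab, "Nfkbiz", run_config())
  co <- codependence_join(ca, cb)
  lab <- setNames(co$label, co$gene_id)
  expect_equal(lab[["both"]], "codependent")
  expect_equal(lab[["a_only"]], "Nfkb1_only")
  expect_equal(lab[["ratio_no_p"]], "Nfkbiz_only")
  expect_equal(lab[["none"]], "neither")

  # a low ratio whose p-value misses the cutoff does not count: force a
  # non-significant low ratio by making the KO counts noisy but overlapping
  ca2 <- ca
  ca2$adjusted_p[ca2$gene_id == "both"] <- 0.02
  ca2$dependent[ca2$gene_id == "both"] <- FALSE
  co2 <- codependence_join(ca2, cb)
  expect_equal(co2$label[co2$gene_id == "both"], "Nfkbiz_only")

  # gene in one universe only -> neither, flagged
  co3 <- codependence_join(ca[ca$gene_id != "both", ], cb)
  expect_equal(co3$label[co3$gene_id == "both"], "neither")
  expect_true(co3$flagged_partial[co3$gene_id == "both"])
})

test_that("loosening the ratio threshold never removes a dependent call", {
  ds <- simulate_dataset(generator_params(n_genes = 250, n_peaks = 60,
                                          rng_seed = 17))
  tight <- classify_dependence(ds$expression, "Nfkb1",
                               run_config(dependence_ratio = 0.25))
  loose <- classify_dependence(ds$expression, "Nfkb1",
                               run_config(dependence_ratio = 0.40))
  expect_true(all(tight$gene_id[tight$dependent] %in%
                    loose$gene_id[loose$dependent]))
})

test_that("early and late screens partition the dependent set", {
  ds <- simulate_dataset(generator_params(n_genes = 250, n_peaks = 60,
                                          rng_seed = 19))
  calls <- classify_dependence(ds$expression, "Nfkbiz", run_config())
  expect_equal(calls$dependent, calls$dependent_early | calls$dependent_late)
})
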