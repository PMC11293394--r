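mk_rep <- function(df, score, rpkm) {
  out <- df
  out$score <- score
  out$rpkm <- rpkm
  out
}

test_that("reproducibility filter enforces strict thresholds and k-of-n", {
  base <- data.frame(chrom = "chr1", start = c(100L, 1000L, 5000L),
                     end = c(400L, 1400L, 5300L),
                     peak_id = c("a", "b", "c"), stringsAsFactors = FALSE)
  cfg <- run_config()
  # peak a: qualifies in both reps; peak b: PS exactly 19 (excluded, strict >);
  # peak c: qualifies in one replicate only
  r1 <- mk_rep(base, score = c(25, 19, 30), rpkm = c(4, 10, 8))
  r2 <- mk_rep(base, score = c(25, 19, 10), rpkm = c(4, 10, 1))
  kept <- filter_reproducible(list(t1 = list(r1, r2)), cfg, k = 2)
  hit <- oracle_overlaps_any(base, kept)
  expect_equal(hit, c(TRUE, FALSE, FALSE))

  # 2-of-3: present in 1 of 3 replicates only -> excluded
  r3 <- mk_rep(base, score = c(2, 2, 2), rpkm = c(0.5, 0.5, 0.5))
  kept3 <- filter_reproducible(list(t1 = list(r1, r3, r3)), cfg, k = 2)
  expect_equal(nrow(kept3), 0L)
  kept3b <- filter_reproducible(list(t1 = list(r1, r2, r3)), cfg, k = 2)
  expect_equal(oracle_overlaps_any(base, kept3b), c(TRUE, FALSE, FALSE))

  # mismatched chromosome sets -> error
  r_alt <- r2
  r_alt$chrom <- "chrX"
  expect_error(filter_reproducible(list(t1 = list(r1, r_alt))),
               "chromosome set")
})

test_that("reproducible-peak count is monotone nonincreasing in ps_cut", {
  set.seed(23)
  base <- random_interval_set(40, seed = 23)
  r1 <- mk_rep(base, score = runif(40, 0, 60), rpkm = runif(40, 0, 10))
  r2 <- mk_rep(base, score = runif(40, 0, 60), rpkm = runif(40, 0, 10))
  n_kept <- vapply(c(5, 19, 30, 50), function(ps) {
    nrow(filter_reproducible(list(list(r1, r2)), run_config(ps_cut = ps)))
  }, numeric(1))
  expect_true(all(diff(n_kept) <= 0))
})

test_that("union_peaksets merges exactly like the all-pairs oracle", {
  # disjoint sets simply concatenate
  s1 <- data.frame(chrom = "chr1", start = c(0L, 100L, 200L),
                   end = c(50L, 150L, 250L), peak_id = paste0("a", 1:3))
  s2 <- data.frame(chrom = "chr2", start = c(0L, 100L, 200L, 300L),
                   end = c(50L, 150L, 250L, 350L), peak_id = paste0("b", 1:4))
  u <- union_peaksets(list(x = s1, y = s2))
  expect_equal(nrow(u), 7L)
  expect_true(all(u$in_x == (u$chrom == "chr1")))

  # idempotence on identical sets
  u2 <- union_peaksets(list(x = s1, y = s1))
  expect_equal(nrow(u2), nrow(s1))

  # randomized fixtures against the O(n^2) oracle
  for (seed in 1:10) {
    sets <- list(a = random_interval_set(40, seed * 3 + 1),
                 b = random_interval_set(30, seed * 3 + 2),
                 c = random_interval_set(20, seed * 3 + 3))
    got <- union_peaksets(sets)
    oracle <- oracle_merge_intervals(do.call(rbind, sets))
    expect_equal(got[c("chrom", "start", "end")], oracle,
                 ignore_attr = TRUE)
    # provenance flags match the oracle overlap test
    for (nm in names(sets)) {
      expect_equal(got[[paste0("in_", nm)]],
                   oracle_overlaps_any(got, sets[[nm]]))
    }
  }
})

test_that("signal quantification is RPKM unit arithmetic", {
  peaks <- data.frame(chrom = "chr1", start = 0L, end = 200L, peak_id = "p1")
  expect_equal(as.numeric(quantify(peaks, matrix(40), 10)), 20)
  expect_equal(as.numeric(quantify(peaks, matrix(0), 10)), 0)
  bad <- peaks; bad$end <- 0L
  expect_error(quantify(bad, matrix(1), 10), "zero-width")

  set.seed(7)
  pk <- random_interval_set(25, 7)
  cnt <- matrix(rpois(100, 80), 25, 4)
  lib <- c(5, 10, 20, 40)
  got <- quantify(pk, cnt, lib)
  oracle <- matrix(0, 25, 4)
  for (i in 1:25) for (j in 1:4) {
    oracle[i, j] <- cnt[i, j] / (((pk$end[i] - pk$start[i]) / 1000) * lib[j])
  }
  expect_equal(unname(got), oracle)
})

test_that("kinetic k-means separates noiseless archetypes and respects the label convention", {
  shapes <- nfkbcodep:::ARCHETYPE_SHAPES
  rownames(shapes) <- paste0("arch", 1:6)
  km <- kinetic_kmeans(shapes * 50, k = 6, seed = 4)
  expect_equal(as.integer(km$cluster), 1:6) # one singleton per archetype
  expect_equal(unname(km$sizes), rep(1L, 6))

  # a profile rising only at the last timepoint joins the late cluster
  prof <- rbind(shapes * 50, late = c(1, 1, 1, 10))
  km2 <- kinetic_kmeans(prof, k = 6, seed = 4)
  expect_equal(unname(km2$cluster["late"]), 6L)

  expect_error(kinetic_kmeans(shapes, k = 10, seed = 1), "exceeds")
})

test_that("kinetic k-means is deterministic under a fixed seed", {
  set.seed(55)
  prof <- nfkbcodep:::ARCHETYPE_SHAPES[sample(1:6, 300, TRUE), ] *
    rlnorm(300, log(10), 0.5) * matrix(rlnorm(1200, 0, 0.25), 300, 4)
  rownames(prof) <- sprintf("p%03d", 1:300)
  a <- kinetic_kmeans(prof, seed = 9)
  b <- kinetic_kmeans(prof, seed = 9)
  expect_identical(a$cluster, b$cluster)
  expect_equal(a$centers, b$centers)
})

test_that("cluster composition percentages are well-formed", {
  cl <- setNames(c(1L, 1L, 6L, 6L, 6L, 3L), paste0("p", 1:6))
  comp <- cluster_composition(cl, list(all6 = paste0("p", 3:5),
                                       mixed = paste0("p", 1:6),
                                       none = character(0)), k = 6)
  a6 <- comp[comp$factor == "all6", paste0("cluster", 1:6)]
  expect_equal(as.numeric(a6), c(0, 0, 0, 0, 0, 100))
  mx <- comp[comp$factor == "mixed", paste0("cluster", 1:6)]
  expect_equal(sum(mx), 100, tolerance = 1e-9)
  expect_true(comp$flagged[comp$factor == "none"])
})

test_that("accessibility overlay honors half-open coordinates and the oracle", {
  peaks <- data.frame(chrom = "chr1", start = c(100L, 300L), end = c(200L, 400L),
                      peak_id = c("in", "out"))
  atac <- data.frame(chrom = "chr1", start = 50L, end = 300L,
                     peak_id = "atac1")
  acc <- accessibility_overlay(peaks, atac)
  expect_true(acc[["in"]])
  expect_false(acc[["out"]]) # starts exactly at the ATAC end (half-open)

  for (seed in 1:10) {
    pk <- random_interval_set(50, seed + 100)
    at <- random_interval_set(30, seed + 200)
    expect_equal(unname(accessibility_overlay(pk, at)),
                 oracle_overlaps_any(pk, at))
  }
})

test_that("rank ordering sorts by reference with lexicographic tie-break", {
  m <- matrix(c(3, 9, 1, 5, 6, 7), ncol = 2,
              dimnames = list(c("pA", "pB", "pC"), c("ref", "other")))
  r <- rank_order_matrix(m, "ref")
  expect_equal(rownames(r), c("pB", "pA", "pC"))

  m2 <- matrix(c(2, 2, 2, 1, 5, 3), ncol = 2,
               dimnames = list(c("pC", "pA", "pB"), c("ref", "other")))
  expect_equal(rownames(rank_order_matrix(m2, "ref")), c("pA", "pB", "pC"))

  # sorting permutes rows without altering their contents
  set.seed(3)
  m3 <- matrix(runif(40), 10, 4,
               dimnames = list(sprintf("p%02d", 1:10), paste0("c", 1:4)))
  r3 <- rank_order_matrix(m3, "c2")
  expect_equal(r3[rownames(m3), ], m3)
})
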