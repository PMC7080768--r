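# LD pruning, PCA, Weir-Cockerham Fst, runs of homozygosity, inbreeding.

test_that("LD pruning removes the later site of correlated pairs", {
  set.seed(42)
  g <- matrix(sample(0:2, 200, replace = TRUE), nrow = 10)
  g[2, ] <- g[1, ]                 # identical pair -> one survives
  ds <- toy_dataset(g)
  kept <- ld_prune(ds, window_sites = 10, step_sites = 5, maf_min = 0)
  expect_true(1 %in% kept)
  expect_false(2 %in% kept)
  # brute-force oracle on a toy with a correlated triple
  set.seed(7)
  h <- matrix(sample(0:2, 120, replace = TRUE), nrow = 10)
  h[4, ] <- h[3, ]; h[8, ] <- 2L - h[3, ]
  ds2 <- toy_dataset(h)
  kept2 <- ld_prune(ds2, window_sites = 5, step_sites = 2, maf_min = 0)
  expect_identical(kept2, oracle_ld_prune(h, 5, 2, 0.4, 0))
  # independent sites with adequate frequency all survive
  set.seed(1)
  ind <- matrix(rbinom(40 * 400, 2, 0.5), nrow = 40)
  keptI <- ld_prune(toy_dataset(ind), window_sites = 10, step_sites = 5)
  expect_equal(length(keptI), 40L)
  # invariant to sample order
  perm <- sample(ncol(h))
  expect_identical(ld_prune(toy_dataset(h[, perm]), 5, 2, maf_min = 0), kept2)
})

test_that("PCA separates duplicated groups and reports a valid spectrum", {
  a <- c(0L, 0L, 2L, 2L, 1L, 0L, 2L, 1L)
  b <- c(2L, 2L, 0L, 0L, 1L, 2L, 0L, 1L)
  g <- cbind(a, a, a, b, b, b)
  res <- pca_genotypes(toy_dataset(g), k = 3)
  pc1 <- res$scores[, 1]
  expect_lt(max(abs(pc1[1:3] - pc1[1])), 1e-9)   # zero within-group spread
  expect_lt(max(abs(pc1[4:6] - pc1[4])), 1e-9)
  expect_gt(abs(pc1[1] - pc1[4]), 1)             # groups separate on PC1
  expect_lte(sum(res$varexp), 1 + 1e-12)
  expect_gt(res$scores[which.max(abs(res$scores[, 1])), 1], 0)  # sign rule
  expect_error(pca_genotypes(toy_dataset(matrix(1L, 3, 4))), "variable site")
})

test_that("Weir-Cockerham Fst matches the hand oracle and its limits", {
  # printed toy, one locus: value frozen from an independent
  # textbook-formula computation
  p1 <- matrix(c(0L, 1L, 2L, 0L), 1, 4)
  p2 <- matrix(c(2L, 2L, 1L, 2L), 1, 4)
  f <- pairwise_fst(list(x = p1, y = p2))
  expect_equal(f$fst["x", "y"], 0.29824561403508776, tolerance = 1e-12)
  expect_equal(f$fst["x", "x"], 0)
  expect_equal(f$fst, t(f$fst))
  # fixed difference -> Fst 1
  ff <- pairwise_fst(list(x = matrix(c(0L, 0L), 1), y = matrix(c(2L, 2L), 1)))
  expect_equal(ff$fst["x", "y"], 1)
  # identical populations -> near zero (estimator noise only)
  set.seed(3)
  gg <- matrix(rbinom(50 * 8, 2, 0.4), nrow = 50)
  fi <- pairwise_fst(list(x = gg, y = gg))
  # identical data cannot look differentiated; the estimator sits at or
  # slightly below zero (small negatives are part of its construction)
  expect_lte(fi$fst["x", "y"], 0)
  expect_gte(fi$fst["x", "y"], -0.1)
  expect_error(pairwise_fst(list(x = gg)), ">= 2")
})

test_that("runs of homozygosity recover planted tracts and obey filters", {
  set.seed(11)
  L <- 600
  pos <- sort(sample.int(3e6, L))
  # heterozygous background with a planted homozygous tract
  g <- matrix(1L, nrow = L, ncol = 2)
  g[, 2] <- sample(c(0L, 1L, 2L), L, replace = TRUE, prob = c(.3, .4, .3))
  tract <- which(pos >= 1e6 & pos <= 2e6)
  g[tract, 1] <- sample(c(0L, 2L), length(tract), replace = TRUE)
  g[-tract, 1] <- 1L
  ds <- cohort_dataset(
    keys = data.frame(chrom = "1", pos = pos, ref = "A", alt = "G"),
    geno = g, sample_ids = c("planted", "hetero"))
  roh <- detect_roh(ds, window_sites = 20, max_het_per_window = 1,
                    min_sites = 50, min_length_bp = 5e5, max_gap_bp = 5e5)
  seg <- roh$segments[roh$segments$sample_id == "planted", ]
  expect_equal(nrow(seg), 1L)
  overlap <- (min(seg$end, 2e6) - max(seg$start, 1e6)) / 1e6
  expect_gte(overlap, 0.95)
  # a fully heterozygous sample has no segment
  expect_equal(roh$per_sample$n_segments[roh$per_sample$sample_id == "hetero"], 0L)
  # doubling the length filter never adds segments
  roh2 <- detect_roh(ds, window_sites = 20, max_het_per_window = 1,
                     min_sites = 50, min_length_bp = 1e6, max_gap_bp = 5e5)
  expect_lte(nrow(roh2$segments), nrow(roh$segments))
  bad <- ds; bad$keys$pos <- rev(bad$keys$pos)
  expect_error(detect_roh(bad), "sorted")
})

test_that("inbreeding F matches its closed form at the limits and on a toy", {
  p <- c(0.5, 0.2, 0.1)
  # (het, hom, hom): observed homozygosity exactly matches expectation
  f0 <- inbreeding_f(toy_dataset(matrix(c(1L, 0L, 2L), 3, 1)), freqs = p)
  expect_equal(f0$F, 0, tolerance = 1e-12)
  # all homozygous -> F = 1
  f1 <- inbreeding_f(toy_dataset(matrix(c(0L, 0L, 2L), 3, 1)), freqs = p)
  expect_equal(f1$F, 1, tolerance = 1e-12)
  # (het, het, hom): O=1, E=2, L-E=1 -> F = -1
  f2 <- inbreeding_f(toy_dataset(matrix(c(1L, 1L, 2L), 3, 1)), freqs = p)
  expect_equal(f2$F, -1, tolerance = 1e-12)
  # degenerate: all sites fixed (p=1) -> E_hom = L -> undefined
  f3 <- inbreeding_f(toy_dataset(matrix(c(2L, 2L), 2, 1)), freqs = c(1, 1))
  expect_true(is.na(f3$F))
})

test_that("isolates show more homozygosity than their source population", {
  hits <- sapply(1:8, function(s) {
    cfg <- sim_config(seed = s, n_sites = 1200, n_haplotypes_base = 60,
                      chrom_length_bp = 6e6)
    base <- simulate_founders(cfg)
    iso <- derive_isolate(base, 8, 10, 60, seed = s + 50)
    roh_args <- list(window_sites = 20, max_het_per_window = 1,
                     min_sites = 25, min_length_bp = 2e5, max_gap_bp = 1e6)
    tb <- do.call(detect_roh, c(list(panel_to_dataset(base)), roh_args))
    ti <- do.call(detect_roh, c(list(panel_to_dataset(iso)), roh_args))
    c(gt = mean(ti$per_sample$total_bp) > mean(tb$per_sample$total_bp),
      some = mean(ti$per_sample$total_bp) > 0)
  })
  expect_gt(mean(hits["gt", ]), 0.7)
  expect_gt(mean(hits["some", ]), 0.7)
})
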