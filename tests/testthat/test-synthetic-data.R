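# Synthetic cohort generator: determinism, degenerate limits, and the
# statistical structure downstream analyses rely on.

test_that("simulation is a pure function of the seed", {
  cfg <- sim_config(seed = 1, n_sites = 300, n_haplotypes_base = 40)
  a <- simulate_founders(cfg)
  b <- simulate_founders(cfg)
  expect_identical(a$haplotypes, b$haplotypes)
  expect_identical(a$positions, b$positions)
  iso1 <- derive_isolate(a, 10, 5, 40, seed = 9)
  iso2 <- derive_isolate(a, 10, 5, 40, seed = 9)
  expect_identical(iso1$haplotypes, iso2$haplotypes)
})

test_that("a single founder without mutation yields identical haplotypes", {
  cfg <- sim_config(seed = 2, n_founders = 1, mutation_rate_per_copy = 0,
                    n_sites = 100, n_haplotypes_base = 20)
  p <- simulate_founders(cfg)
  expect_equal(nrow(unique(p$haplotypes)), 1L)
})

test_that("base panels show a rare-heavy folded site frequency spectrum", {
  rhos <- sapply(1:10, function(s) {
    cfg <- sim_config(seed = s, n_haplotypes_base = 200, n_sites = 5000)
    p <- simulate_founders(cfg)
    dac <- colSums(p$haplotypes)
    mac <- pmin(dac, nrow(p$haplotypes) - dac)
    counts <- table(cut(mac, seq(0, 100, by = 10)))  # equal-width bins
    suppressWarnings(cor(seq_along(counts), as.numeric(counts),
                         method = "spearman"))
  })
  expect_lt(mean(rhos), 0)
  expect_gt(mean(rhos < 0), 0.7)
})

test_that("a full-width zero-generation bottleneck permutes the base panel", {
  cfg <- sim_config(seed = 3, n_sites = 200, n_haplotypes_base = 30)
  base <- simulate_founders(cfg)
  iso <- derive_isolate(base, nrow(base$haplotypes), 0,
                        nrow(base$haplotypes), seed = 4)
  key <- function(m) sort(apply(m, 1, paste, collapse = ""))
  expect_identical(key(iso$haplotypes), key(base$haplotypes))
})

test_that("bottleneck size larger than the base panel is rejected", {
  cfg <- sim_config(seed = 3, n_sites = 50, n_haplotypes_base = 20)
  base <- simulate_founders(cfg)
  expect_error(derive_isolate(base, 100, 1, 20), "larger than")
})

test_that("stronger bottlenecks drift further from the base population", {
  diffs <- sapply(1:20, function(s) {
    cfg <- sim_config(seed = s, n_sites = 400, n_haplotypes_base = 100)
    base <- simulate_founders(cfg)
    small <- derive_isolate(base, 10, 10, 100, seed = s + 500)
    large <- derive_isolate(base, 100, 10, 100, seed = s + 900)
    g <- list(BASE = panel_to_dataset(base), S = panel_to_dataset(small),
              L = panel_to_dataset(large))
    f <- pairwise_fst(g)$fst
    f["BASE", "S"] - f["BASE", "L"]
  })
  expect_gt(mean(diffs > 0), 0.7)
  expect_gt(mean(diffs), 0)
})

test_that("planted sweeps homogenise carriers and leave the rest untouched", {
  cfg <- sim_config(seed = 5, n_sites = 500, n_haplotypes_base = 60,
                    chrom_length_bp = 1e6)
  base <- simulate_founders(cfg)
  # degenerate flank: only the focal column changes
  sw0 <- plant_sweep(base, 5e5, 0.4, 0, seed = 6)
  fi <- attr(sw0, "focal_index")
  expect_identical(sw0$haplotypes[, -fi], base$haplotypes[, -fi])
  expect_setequal(unique(sw0$haplotypes[, fi]), c(0L, 1L))
  # carriers are near-identical over the flank
  sw <- plant_sweep(base, 5e5, 0.5, 2e5, seed = 6, private_mut_rate = 1e-3)
  fi <- attr(sw, "focal_index")
  carriers <- which(sw$haplotypes[, fi] == 1L)
  flank <- which(sw$positions >= sw$positions[fi] - 2e5 &
                   sw$positions <= sw$positions[fi] + 2e5)
  flank <- setdiff(flank, fi)
  block <- sw$haplotypes[carriers, flank]
  mism <- apply(block, 1, function(r) mean(r != block[1, ]))
  expect_lt(max(mism), 0.02)
  # non-carriers untouched outside the focal column
  outsiders <- setdiff(seq_len(nrow(sw$haplotypes)), carriers)
  expect_identical(sw$haplotypes[outsiders, -fi], base$haplotypes[outsiders, -fi])
  expect_error(plant_sweep(base, 5e9, 0.5, 1e5), "outside")
})

test_that("annotations respect the requested consequence-class probabilities", {
  cfg <- sim_config(seed = 7, n_sites = 200, n_haplotypes_base = 40)
  p <- simulate_founders(cfg)
  # no high-impact class -> nothing passes the knockout consequence filter
  ann0 <- annotate_sites(p, list(p_high_impact = 0), seed = 8)
  expect_false(any(classify_lof(ann0)))
  expect_true(all(ann0$affected_transcripts <= ann0$n_transcripts))
  expect_true(all(ann0$affected_transcripts >= 1))
  # binomial count check at p = 0.01 over 10^4 sites
  cfg2 <- sim_config(seed = 9, n_sites = 12000, n_haplotypes_base = 40)
  p2 <- simulate_founders(cfg2)
  ann <- annotate_sites(p2, list(p_high_impact = 0.01), seed = 10)
  n_high <- sum(ann$consequence %in% hko_high_impact_terms())
  bounds <- qbinom(c(0.005, 0.995), nrow(ann), 0.01)
  expect_gte(n_high, bounds[1])
  expect_lte(n_high, bounds[2])
  # all four deleteriousness bins populated under defaults
  expect_setequal(unique(as.character(cut(ann$cadd_phred, c(0, 5, 15, 20, Inf),
                                          right = FALSE))),
                  c("[0,5)", "[5,15)", "[15,20)", "[20,Inf)"))
})

test_that("posterior corruption is normalised, noise-monotone and exact at zero", {
  cfg <- sim_config(seed = 11, n_sites = 400, n_haplotypes_base = 80)
  g <- panel_to_dataset(simulate_founders(cfg))$geno
  clean <- corrupt_to_posteriors(g, list(e_min = 0, e_max = 0, maf_decay = 0.05),
                                 seed = 1)
  expect_true(all(abs(clean$p0 + clean$p1 + clean$p2 - 1) < 1e-9))
  cc <- concordance_r2_by_maf(g, clean)
  expect_true(all(cc$by_bin$mean_r2[cc$by_bin$n > cc$by_bin$n_excluded] == 1))
  expect_equal(mean(info_scores(clean)), 1)
  means <- sapply(1:10, function(s) {
    lo <- corrupt_to_posteriors(g, list(e_min = 0.02, e_max = 0.02,
                                        maf_decay = 0.05), seed = s)
    hi <- corrupt_to_posteriors(g, list(e_min = 0.25, e_max = 0.25,
                                        maf_decay = 0.05), seed = s)
    r2m <- function(p) mean(concordance_r2_by_maf(g, p)$per_site$r2, na.rm = TRUE)
    c(lo = r2m(lo), hi = r2m(hi))
  })
  expect_true(all(means["hi", ] <= means["lo", ]))
  expect_error(corrupt_to_posteriors(g, list(e_min = -1, e_max = 0,
                                             maf_decay = 1)), ">= 0")
})

test_that("the cohort bundle is complete, deterministic and self-consistent", {
  cfg <- sim_config(seed = 12, n_sites = 150, n_haplotypes_base = 20,
                    bottleneck_founders = c(P1 = 6L, P2 = 10L, P3 = 14L))
  d1 <- file.path(tempdir(), "bundle1"); d2 <- file.path(tempdir(), "bundle2")
  generate_cohort_set(cfg, d1)
  generate_cohort_set(cfg, d2)
  files <- list.files(d1)
  expect_length(grep("\\.vcf$", files), 3L)
  expect_length(grep("_annotation\\.tsv$", files), 3L)
  expect_true(all(c("external_sites.tsv", "rvis.tsv", "manifest.json") %in% files))
  for (f in grep("\\.vcf$", files, value = TRUE)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
  ext <- read_site_list(file.path(d1, "external_sites.tsv"))
  union_keys <- unique(unlist(lapply(grep("\\.vcf$", files, value = TRUE),
    function(f) variant_key(read_vcf(file.path(d1, f))$keys))))
  expect_true(all(variant_key(ext) %in% union_keys))
  unlink(c(d1, d2), recursive = TRUE)
})
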