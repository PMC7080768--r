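# EHH curves, iHS scan against a brute-force integration oracle,
# standardisation, gene-level candidate calling and overlaps.

test_that("EHH matches hand combinatorics and is monotone non-increasing", {
  # 4 carriers split into two identical pairs: EHH = 2 / C(4,2) = 1/3
  hap <- rbind(c(1, 0, 1), c(1, 0, 1), c(1, 1, 0), c(1, 1, 0),
               c(0, 0, 0), c(0, 1, 1))
  e <- ehh_curve(hap, core = 1, allele = 1)
  expect_equal(e$ehh[e$side == "core"], 1)
  expect_equal(e$ehh[e$side == "right"], c(1 / 3, 1 / 3))
  # identical carriers keep EHH at 1
  same <- rbind(c(1, 1, 0, 1), c(1, 1, 0, 1), c(0, 0, 0, 0), c(0, 1, 1, 1))
  es <- ehh_curve(same, core = 1, allele = 1)
  expect_true(all(es$ehh == 1))
  # non-increasing on random panels, both sides, checked against the oracle
  set.seed(5)
  for (rep in 1:5) {
    h <- matrix(rbinom(12 * 15, 1, 0.5), nrow = 12)
    core <- 8
    ec <- ehh_curve(h, core, 1)
    if (is.null(ec)) next
    for (side in c("left", "right")) {
      v <- ec$ehh[ec$side == side]
      expect_true(all(diff(v) <= 1e-12))
    }
    rc <- ec[ec$side == "right", ]
    for (k in seq_len(nrow(rc))) {
      expect_equal(rc$ehh[k], oracle_ehh(h, core, 1, core:(rc$site[k])))
    }
  }
  expect_warning(ehh_curve(rbind(c(1, 0), c(0, 0), c(0, 1)), 1, 1), "carriers")
})

test_that("iHS integration agrees with the brute-force trapezoid oracle", {
  set.seed(9)
  for (rep in 1:4) {
    n_hap <- 10; L <- 40
    h <- matrix(rbinom(n_hap * L, 1, 0.5), nrow = n_hap)
    pos <- sort(sample.int(50000, L))
    panel <- toy_panel(h, pos)
    scan <- ihs_scan(panel, maf_min = 0.2, ehh_cutoff = 0.05,
                     max_gap_bp = Inf)
    for (s in which(scan$valid)) {
      oa <- oracle_ihh(h, pos, s, 0, 0.05)
      od <- oracle_ihh(h, pos, s, 1, 0.05)
      expect_true(oa$ok && od$ok)
      expect_equal(scan$ihh_a[s], oa$ihh, tolerance = 1e-9)
      expect_equal(scan$ihh_d[s], od$ihh, tolerance = 1e-9)
      expect_equal(scan$ihs_unstd[s], log(oa$ihh / od$ihh), tolerance = 1e-9)
    }
    # every site the oracle can finish, the scan validates, and vice versa
    for (s in which(!scan$valid & scan$reason == "edge")) {
      oa <- oracle_ihh(h, pos, s, 0, 0.05)
      od <- oracle_ihh(h, pos, s, 1, 0.05)
      expect_false(oa$ok && od$ok)
    }
  }
})

test_that("iHS is antisymmetric in the ancestral labelling and zero on mirrors", {
  set.seed(21)
  h <- matrix(rbinom(16 * 30, 1, 0.5), nrow = 16)
  pos <- sort(sample.int(40000, 30))
  panel <- toy_panel(h, pos)
  s1 <- ihs_scan(panel, ancestral = rep(0L, 30), maf_min = 0.2, max_gap_bp = Inf)
  s2 <- ihs_scan(panel, ancestral = rep(1L, 30), maf_min = 0.2, max_gap_bp = Inf)
  both <- which(s1$valid & s2$valid)
  expect_gt(length(both), 0)
  expect_equal(s1$ihs_unstd[both], -s2$ihs_unstd[both], tolerance = 1e-9)
  # mirror construction: derived carriers are a relabelled copy of the
  # ancestral carriers -> identical haplotype structure, iHS exactly 0
  block <- matrix(rbinom(8 * 21, 1, 0.5), nrow = 8)
  core <- 11
  mirror <- rbind(`[<-`(block, , core, 0L), `[<-`(block, , core, 1L))
  pm <- toy_panel(mirror, sort(sample.int(30000, 21)))
  sm <- ihs_scan(pm, maf_min = 0.2, max_gap_bp = Inf)
  if (sm$valid[core]) expect_equal(sm$ihs_unstd[core], 0, tolerance = 1e-12)
  expect_equal(sm$derived_freq[core], 0.5)
})

test_that("standardisation gives per-bin mean 0 and SD 1 and is order-invariant", {
  cfg <- sim_config(seed = 31, n_sites = 3000, n_haplotypes_base = 100,
                    chrom_length_bp = 3e6)
  scan <- ihs_scan(simulate_founders(cfg))
  std <- standardize_ihs(scan, n_freq_bins = 20)
  for (b in unique(std$freq_bin[std$standardizable])) {
    v <- std$ihs_std[std$standardizable & std$freq_bin == b]
    expect_equal(mean(v), 0, tolerance = 1e-9)
    expect_equal(sd(v), 1, tolerance = 1e-9)
  }
  perm <- sample(nrow(scan))
  std_p <- standardize_ihs(scan[perm, ], n_freq_bins = 20)
  expect_equal(std_p$ihs_std, std$ihs_std[perm], tolerance = 1e-12)
  # bins with fewer than two sites are flagged unstandardisable
  tiny <- scan[1:1, ]
  expect_true(all(is.na(standardize_ihs(tiny, 5)$ihs_std)))
})

test_that("gene candidate calling applies the marker-count rule with nesting", {
  genes <- data.frame(gene = c("g1", "g2"), chrom = "1",
                      start = c(1, 1001), end = c(1000, 2000))
  mk <- function(n_hits_g1, n_hits_g2) {
    data.frame(chrom = "1",
               pos = c(seq_len(n_hits_g1), 1000 + seq_len(n_hits_g2)),
               ihs_std = 2.2)
  }
  r1 <- gene_selection_candidates(mk(25, 19), genes, ihs_threshold = 2,
                                  min_markers = 20)
  expect_true(r1$candidate[r1$gene == "g1"])
  expect_false(r1$candidate[r1$gene == "g2"])
  # stricter threshold candidates nest within the looser ones
  set.seed(2)
  res <- data.frame(chrom = "1", pos = sample.int(2000, 500, replace = TRUE),
                    ihs_std = rnorm(500, sd = 2))
  c20 <- gene_selection_candidates(res, genes, 2, min_markers = 5)
  c25 <- gene_selection_candidates(res, genes, 2.5, min_markers = 5)
  expect_true(all(c25$gene[c25$candidate] %in% c20$gene[c20$candidate]))
})

test_that("selection overlap partitions shared and private candidates", {
  sets <- list(P1 = c("A", "B", "C"), P2 = c("B", "C"), P3 = "C")
  ov <- selection_overlap(sets)
  expect_identical(ov$intersection, "C")
  expect_equal(ov$per_population$private_fraction[
    ov$per_population$population == "P1"], 1 / 3)
  ident <- selection_overlap(list(a = c("x", "y"), b = c("x", "y")))
  expect_equal(ident$per_population$private_fraction, c(0, 0))
  expect_setequal(ident$intersection, c("x", "y"))
  disj <- selection_overlap(list(a = "x", b = "y"))
  expect_equal(disj$per_population$private_fraction, c(1, 1))
  expect_length(disj$intersection, 0)
  ref <- selection_overlap(sets, reference = "P3")
  expect_equal(ref$per_population$absent_from_reference[
    ref$per_population$population == "P1"], 2 / 3)
})
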