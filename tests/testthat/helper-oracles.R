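# Independent brute-force oracles and small fixture builders. Oracles are
# deliberately naive (string grouping, exhaustive loops) so they share no
# code path with the implementation they check.

# toy cohort_dataset from a genotype matrix (sites x samples)
toy_dataset <- function(geno, dp = NULL, pos = seq_len(nrow(as.matrix(geno))),
                        pop = "toy") {
  geno <- as.matrix(geno)
  cohort_dataset(
    keys = data.frame(chrom = "1", pos = pos,
                      ref = rep("A", nrow(geno)), alt = rep("G", nrow(geno)),
                      stringsAsFactors = FALSE),
    geno = geno, dp = dp,
    sample_ids = paste0("s", seq_len(ncol(geno))), population_id = pop)
}

toy_panel <- function(hap, pos = seq_len(ncol(as.matrix(hap)))) {
  hap <- as.matrix(hap)
  haplotype_panel(hap, pos, rep("A", ncol(hap)), rep("G", ncol(hap)),
                  sample_ids = paste0("s", seq_len(nrow(hap) / 2)))
}

# site-stats row set from named AC/AF vectors keyed by variant key
toy_stats <- function(keys, AC, AF, mean_DP = rep(10, length(keys))) {
  data.frame(key = keys, AC = AC, AN = round(2 * AC / pmax(AF, 1e-9)),
             AF = AF, mean_DP = mean_DP, stringsAsFactors = FALSE)
}

# EHH by exhaustive haplotype-string comparison among core-allele carriers
oracle_ehh <- function(hap, core, allele, cols) {
  carriers <- which(hap[, core] == allele)
  n <- length(carriers)
  strings <- apply(hap[carriers, cols, drop = FALSE], 1, paste, collapse = "")
  pairs_same <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) if (strings[i] == strings[j]) pairs_same <- pairs_same + 1
  }
  pairs_same / choose(n, 2)
}

# one-side iHH by explicit trapezoid over oracle EHH values, truncating at
# the first marker whose EHH falls below the cutoff (that trapezoid kept)
oracle_ihh_side <- function(hap, pos, core, allele, dir, cutoff) {
  L <- ncol(hap)
  cols <- core
  ehh_prev <- 1
  prev <- core
  ihh <- 0
  j <- core + dir
  while (j >= 1 && j <= L) {
    cols <- c(cols, j)
    e <- oracle_ehh(hap, core, allele, cols)
    ihh <- ihh + 0.5 * (ehh_prev + e) * abs(pos[j] - pos[prev])
    if (e < cutoff) return(list(ihh = ihh, ok = TRUE))
    ehh_prev <- e
    prev <- j
    j <- j + dir
  }
  list(ihh = ihh, ok = FALSE)  # hit the edge before the cutoff
}

oracle_ihh <- function(hap, pos, core, allele, cutoff = 0.05) {
  l <- oracle_ihh_side(hap, pos, core, allele, -1, cutoff)
  r <- oracle_ihh_side(hap, pos, core, allele, +1, cutoff)
  list(ihh = l$ihh + r$ihh, ok = l$ok && r$ok)
}

# LD pruning by literal re-statement of the windowed rule
oracle_ld_prune <- function(geno, window, step, r2_max, maf_min) {
  af <- rowMeans(geno) / 2
  idx <- which(pmin(af, 1 - af) >= maf_min)
  alive <- rep(TRUE, length(idx))
  start <- 1
  repeat {
    win <- start:min(start + window - 1, length(idx))
    for (a in win) for (b in win) {
      if (a < b && alive[a] && alive[b]) {
        r <- suppressWarnings(cor(geno[idx[a], ], geno[idx[b], ]))
        if (!is.na(r) && r^2 > r2_max) alive[b] <- FALSE
      }
    }
    if (start + window - 1 >= length(idx)) break
    start <- start + step
  }
  idx[alive]
}

# minimal annotation table for a vector of variant keys
toy_ann <- function(keys, cadd) {
  parts <- do.call(rbind, strsplit(keys, ":"))
  data.frame(chrom = parts[, 1], pos = as.numeric(parts[, 2]),
             ref = parts[, 3], alt = parts[, 4], gene = "g",
             n_transcripts = 1, affected_transcripts = 1,
             consequence = "missense_variant", cadd_phred = cadd,
             stringsAsFactors = FALSE)
}

# drifted-set enumeration on a toy table of per-population AC/AF
oracle_drifted <- function(x, y, ac_lo, ac_hi, thr) {
  out <- character()
  for (k in x$key) {
    acx <- x$AC[x$key == k]
    afy <- if (k %in% y$key) y$AF[y$key == k] else 0
    if (acx >= ac_lo && acx <= ac_hi && afy < thr) out <- c(out, k)
  }
  out
}
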