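# Haplotype-based selection scans: EHH curves, integrated haplotype
# homozygosity, the iHS statistic with frequency-bin standardisation,
# gene-level candidate calling and cross-population sharing.

#' Extended haplotype homozygosity around a core site
#'
#' Among the carriers of `allele` at the core site, EHH after extending k
#' markers in one direction is the probability that two random carriers
#' are identical over the extended interval:
#' sum over distinct extended haplotypes h of C(n_h, 2) / C(n, 2).
#' EHH at the core itself is 1 and the sequence is non-increasing.
#'
#' @param haplotypes 2N x L phased 0/1 matrix.
#' @param core core site column index.
#' @param allele core allele (0 or 1).
#' @param positions optional physical positions for the `distance` column.
#' @return data frame (side, site, distance_bp, ehh) including the core
#'   row (side "core", ehh 1); `NULL` with a warning when fewer than two
#'   carriers exist.
#' @export
ehh_curve <- function(haplotypes, core, allele, positions = NULL) {
  h <- as.matrix(haplotypes)
  carriers <- which(h[, core] == allele)
  n <- length(carriers)
  if (n < 2L) {
    warning("fewer than two carriers of the core allele; EHH undefined")
    return(NULL)
  }
  positions <- positions %||% seq_len(ncol(h))
  denom <- choose(n, 2)
  one_side <- function(cols, side) {
    if (!length(cols)) return(NULL)
    ids <- rep("", n)
    ehh <- numeric(length(cols))
    for (k in seq_along(cols)) {
      ids <- paste0(ids, h[carriers, cols[k]])
      cnt <- table(ids)
      ehh[k] <- sum(choose(cnt, 2)) / denom
    }
    data.frame(side = side, site = cols,
               distance_bp = abs(positions[cols] - positions[core]),
               ehh = ehh, stringsAsFactors = FALSE)
  }
  rbind(
    data.frame(side = "core", site = core, distance_bp = 0, ehh = 1,
               stringsAsFactors = FALSE),
    one_side(rev(seq_len(core - 1L)), "left"),
    one_side(seq(core + 1L, ncol(h), length.out = max(ncol(h) - core, 0L)),
             "right")
  )
}

#' Genome-wide iHS scan
#'
#' For every site passing the MAF filter, the EHH curve of the ancestral
#' and of the derived allele is integrated over physical distance
#' (trapezoid rule) away from the core until EHH drops below
#' `ehh_cutoff`, in both directions; the integrals are summed per allele
#' into iHH_A and iHH_D and the unstandardised score is
#' ln(iHH_A / iHH_D). Sites whose curve hits the chromosome edge, an
#' inter-marker gap larger than `max_gap_bp`, or `max_extend_bp` before
#' reaching the cutoff are flagged invalid rather than penalised.
#'
#' @param panel a phased [haplotype_panel()].
#' @param ancestral per-site ancestral allele (0/1); default 0 treats the
#'   reference allele as ancestral.
#' @param maf_min sites with MAF not exceeding this are skipped.
#' @param ehh_cutoff EHH truncation level.
#' @param max_gap_bp per-side maximum tolerated inter-marker gap.
#' @param max_extend_bp maximum one-side extension.
#' @return data frame (chrom, pos, ref, alt, derived_freq, ihh_a, ihh_d,
#'   ihs_unstd, valid, reason).
#' @export
ihs_scan <- function(panel, ancestral = NULL, maf_min = 0.05,
                     ehh_cutoff = 0.05, max_gap_bp = 2e5,
                     max_extend_bp = Inf) {
  stopifnot(inherits(panel, "haplotype_panel"))
  L <- ncol(panel$haplotypes)
  ancestral <- ancestral %||% rep(0L, L)
  if (length(ancestral) != L || !all(ancestral %in% c(0L, 1L))) {
    stop_config("ancestral must be a 0/1 vector with one entry per site")
  }
  res <- ihs_scan_cpp(panel$haplotypes, panel$positions,
                      as.integer(ancestral), maf_min, ehh_cutoff,
                      max_gap_bp, max_extend_bp)
  reasons <- c("ok", "low_maf", "edge", "gap")
  data.frame(
    chrom = panel$chrom, pos = panel$positions,
    ref = panel$ref, alt = panel$alt,
    derived_freq = res$derived_freq,
    ihh_a = res$ihh_a, ihh_d = res$ihh_d,
    ihs_unstd = ifelse(res$reason == 0L, log(res$ihh_a / res$ihh_d), NA_real_),
    valid = res$reason == 0L,
    reason = reasons[res$reason + 1L],
    stringsAsFactors = FALSE
  )
}

#' Standardise iHS within derived-allele-frequency bins
#'
#' Valid scores are binned by derived-allele frequency into `n_freq_bins`
#' equal-width bins; within each bin the mean is subtracted and the
#' standard deviation divided out, so each occupied bin has mean 0 and SD
#' 1. Bins with fewer than two valid sites, or zero spread, are flagged
#' unstandardisable (`ihs_std` NA).
#'
#' @param results output of [ihs_scan()].
#' @param n_freq_bins number of equal-width frequency bins.
#' @return `results` with columns `freq_bin`, `ihs_std`,
#'   `standardizable` added.
#' @export
standardize_ihs <- function(results, n_freq_bins = 50L) {
  edges <- seq(0, 1, length.out = n_freq_bins + 1L)
  bin <- cut(results$derived_freq, edges, include.lowest = TRUE)
  std <- rep(NA_real_, nrow(results))
  ok_bin <- rep(FALSE, nrow(results))
  for (b in levels(bin)) {
    in_bin <- which(bin == b & results$valid & !is.na(results$ihs_unstd))
    if (length(in_bin) < 2L) next
    m <- mean(results$ihs_unstd[in_bin])
    s <- stats::sd(results$ihs_unstd[in_bin])
    if (s == 0) next
    std[in_bin] <- (results$ihs_unstd[in_bin] - m) / s
    ok_bin[in_bin] <- TRUE
  }
  results$freq_bin <- bin
  results$ihs_std <- std
  results$standardizable <- ok_bin
  results
}

#' Gene-level selection candidates
#'
#' Counts, per gene interval, markers with |standardised iHS| at or above
#' `ihs_threshold`; a gene is a candidate when at least `min_markers`
#' qualify. Overlapping genes are allowed: a marker may count for several.
#'
#' @param results standardised scan results (needs `ihs_std`, `pos`,
#'   `chrom`).
#' @param genes data frame (gene, chrom, start, end), 1-based inclusive.
#' @param ihs_threshold |iHS| cutoff (conventionally 2 or 2.5).
#' @param min_markers markers required to call a candidate.
#' @param population optional label carried into the output.
#' @return data frame (gene, population, n_markers_over_threshold,
#'   threshold, candidate).
#' @export
gene_selection_candidates <- function(results, genes, ihs_threshold = 2,
                                      min_markers = 20L, population = NA) {
  hits <- results[!is.na(results$ihs_std) &
                    abs(results$ihs_std) >= ihs_threshold, , drop = FALSE]
  n_hit <- vapply(seq_len(nrow(genes)), function(i) {
    sum(hits$chrom == genes$chrom[i] &
          hits$pos >= genes$start[i] & hits$pos <= genes$end[i])
  }, integer(1))
  data.frame(gene = genes$gene, population = population,
             n_markers_over_threshold = n_hit, threshold = ihs_threshold,
             candidate = n_hit >= min_markers, stringsAsFactors = FALSE)
}

#' Sharing of selection candidates across populations
#'
#' For each population, the private fraction is the share of its candidate
#' genes found in no other population; when a `reference` population is
#' named, the fraction of candidates absent from that reference is also
#' reported. The all-population intersection is returned alongside.
#'
#' @param sets named list of candidate gene vectors.
#' @param reference optional name of a reference population in `sets`.
#' @return list `per_population` (population, n_candidates,
#'   private_fraction, absent_from_reference) and `intersection`.
#' @export
selection_overlap <- function(sets, reference = NULL) {
  if (length(sets) < 2L) stop_config("need >= 2 populations")
  pops <- names(sets)
  per <- lapply(pops, function(nm) {
    s <- sets[[nm]]
    others <- unique(unlist(sets[setdiff(pops, nm)]))
    data.frame(
      population = nm, n_candidates = length(s),
      private_fraction = if (length(s)) mean(!(s %in% others)) else NA_real_,
      absent_from_reference = if (!is.null(reference) && nm != reference) {
        if (length(s)) mean(!(s %in% sets[[reference]])) else NA_real_
      } else NA_real_,
      stringsAsFactors = FALSE)
  })
  list(per_population = do.call(rbind, per),
       intersection = Reduce(intersect, sets))
}
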