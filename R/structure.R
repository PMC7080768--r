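# Population structure: LD pruning, PCA, pairwise Weir-Cockerham Fst,
# runs of homozygosity, and method-of-moments inbreeding coefficients.

#' Sliding-window LD pruning
#'
#' PLINK-style `--indep-pairwise` rule: sites with MAF below `maf_min` are
#' removed first; within each window of `window_sites` remaining sites the
#' ordered pairs (i < j) are scanned and the later site of any pair whose
#' genotype correlation r2 exceeds `r2_max` is removed; the window then
#' advances by `step_sites`. Output is independent of sample order.
#'
#' @param dataset a [cohort_dataset()] (or any object with `geno`, `keys`).
#' @param window_sites,step_sites window geometry in site counts.
#' @param r2_max prune when pairwise r2 exceeds this.
#' @param maf_min minimum minor allele frequency.
#' @return integer vector of retained site indices (into `dataset$keys`).
#' @export
ld_prune <- function(dataset, window_sites = 200L, step_sites = 50L,
                     r2_max = 0.4, maf_min = 0.02) {
  g <- dataset$geno
  if (nrow(g) < 1L) stop_config("need at least one site")
  af <- rowMeans(g, na.rm = TRUE) / 2
  idx <- which(maf_of(af) >= maf_min & !is.nan(af))
  alive <- rep(TRUE, length(idx))
  start <- 1L
  while (start <= length(idx)) {
    win <- start:min(start + window_sites - 1L, length(idx))
    live <- win[alive[win]]
    if (length(live) > 1L) {
      cm <- suppressWarnings(
        stats::cor(t(g[idx[live], , drop = FALSE]),
                   use = "pairwise.complete.obs"))
      r2 <- cm^2
      for (a in seq_along(live)) {
        if (!alive[live[a]]) next
        for (b in seq_along(live)) {
          if (b <= a || !alive[live[b]]) next
          if (!is.na(r2[a, b]) && r2[a, b] > r2_max) alive[live[b]] <- FALSE
        }
      }
    }
    if (start + window_sites - 1L >= length(idx)) break
    start <- start + step_sites
  }
  idx[alive]
}

#' PCA of a genotype matrix
#'
#' Sites are centred at twice the alternative allele frequency and scaled
#' by sqrt(2 p (1 - p)); missing genotypes are mean-imputed per site.
#' Sample coordinates come from the singular value decomposition of the
#' standardised matrix; each axis is oriented so its largest-magnitude
#' coordinate is positive.
#'
#' @param dataset a [cohort_dataset()] or sites x samples matrix.
#' @param k number of axes to return.
#' @return list `scores` (samples x k), `varexp` (fraction of variance
#'   per axis), `sdev`.
#' @export
pca_genotypes <- function(dataset, k = 10L) {
  g <- if (inherits(dataset, "cohort_dataset")) dataset$geno else as.matrix(dataset)
  if (nrow(g) < 2L || ncol(g) < 2L) stop_config("need >= 2 samples and >= 2 sites")
  p <- rowMeans(g, na.rm = TRUE) / 2
  v <- rowMeans(g^2, na.rm = TRUE) - (2 * p)^2
  keep <- !is.nan(p) & p > 0 & p < 1 & v > 0
  if (!any(keep)) stop_config("genotype matrix has no variable site")
  g <- g[keep, , drop = FALSE]; p <- p[keep]
  x <- (g - 2 * p) / sqrt(2 * p * (1 - p))
  x[is.na(x)] <- 0  # mean imputation after centring
  sv <- svd(t(x))
  k <- min(k, length(sv$d))
  scores <- sv$u[, seq_len(k), drop = FALSE] %*% diag(sv$d[seq_len(k)], k, k)
  for (j in seq_len(k)) {
    if (scores[which.max(abs(scores[, j])), j] < 0) scores[, j] <- -scores[, j]
  }
  rownames(scores) <- if (inherits(dataset, "cohort_dataset")) dataset$sample_ids
  list(scores = scores, varexp = (sv$d^2 / sum(sv$d^2))[seq_len(k)],
       sdev = sv$d[seq_len(k)])
}

# Weir & Cockerham (1984) variance components for one pair of
# populations, vectorised over loci. Returns per-locus a, b, c.
wc_components <- function(g1, g2) {
  n1 <- rowSums(!is.na(g1)); n2 <- rowSums(!is.na(g2))
  p1 <- rowSums(g1, na.rm = TRUE) / (2 * n1)
  p2 <- rowSums(g2, na.rm = TRUE) / (2 * n2)
  h1 <- rowSums(g1 == 1L, na.rm = TRUE) / n1
  h2 <- rowSums(g2 == 1L, na.rm = TRUE) / n2
  r <- 2
  nbar <- (n1 + n2) / 2
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - s2 * (r - 1) / r - (2 * nbar - 1) / (4 * nbar) * hbar)
  c <- hbar / 2
  usable <- n1 > 0 & n2 > 0 & nbar > 1 & pbar > 0 & pbar < 1
  list(a = a, b = b, c = c, usable = usable)
}

#' Pairwise Weir-Cockerham Fst
#'
#' Two-population Weir & Cockerham (1984) estimator per locus, aggregated
#' genome-wide as the ratio of summed variance components
#' (ratio of averages). Loci monomorphic across both populations are
#' skipped. Small negative values are possible by construction of the
#' estimator.
#'
#' @param genos named list of aligned sites x samples dosage matrices (or
#'   [cohort_dataset()]s), one per population.
#' @return list `fst` (symmetric matrix, diagonal 0) and `n_loci`
#'   (loci used per pair).
#' @export
pairwise_fst <- function(genos) {
  if (length(genos) < 2L) stop_config("need >= 2 populations")
  genos <- lapply(genos, function(x) {
    if (inherits(x, "cohort_dataset")) x$geno else as.matrix(x)
  })
  if (is.null(names(genos))) names(genos) <- paste0("pop", seq_along(genos))
  L <- unique(vapply(genos, nrow, integer(1)))
  if (length(L) != 1L) stop_config("populations must share one key list")
  pops <- names(genos)
  np <- length(pops)
  fst <- matrix(0, np, np, dimnames = list(pops, pops))
  n_loci <- matrix(0L, np, np, dimnames = list(pops, pops))
  for (i in seq_len(np - 1L)) {
    for (j in (i + 1L):np) {
      w <- wc_components(genos[[i]], genos[[j]])
      u <- w$usable
      denom <- sum((w$a + w$b + w$c)[u])
      fst[i, j] <- fst[j, i] <- if (denom == 0) NA_real_ else sum(w$a[u]) / denom
      n_loci[i, j] <- n_loci[j, i] <- sum(u)
    }
  }
  list(fst = fst, n_loci = n_loci)
}

#' Detect runs of homozygosity
#'
#' PLINK-style scan: per sample, sliding windows of `window_sites` sites
#' are scored homozygosity-compatible when they contain at most
#' `max_het_per_window` heterozygous calls (missing calls are compatible
#' but never anchor a run); a homozygous site lying in at least one
#' compatible window is flagged. Maximal stretches of flagged sites -- in
#' which missing sites may be interspersed but never a het, and where
#' consecutive used sites are at most `max_gap_bp` apart -- become
#' segments if they span at least `min_sites` flagged sites and
#' `min_length_bp`.
#'
#' @param dataset a [cohort_dataset()]; positions must be sorted.
#' @param window_sites,max_het_per_window window geometry.
#' @param min_sites,min_length_bp,max_gap_bp segment filters.
#' @return list `segments` (sample_id, chrom, start, end, n_sites,
#'   length_bp) and `per_sample` (sample_id, n_segments, total_bp).
#' @export
detect_roh <- function(dataset, window_sites = 50L, max_het_per_window = 1L,
                       min_sites = 100L, min_length_bp = 1e6,
                       max_gap_bp = 1e6) {
  pos <- dataset$keys$pos
  if (is.unsorted(pos, strictly = TRUE)) stop_config("positions must be sorted")
  g <- dataset$geno
  L <- nrow(g)
  segs <- list()
  for (s in seq_len(ncol(g))) {
    gv <- g[, s]
    het <- !is.na(gv) & gv == 1L
    hom <- !is.na(gv) & gv != 1L
    w <- min(window_sites, L)
    het_run <- c(0, cumsum(het))
    win_het <- het_run[(w + 1):(L + 1)] - het_run[1:(L - w + 1)]  # per window start
    good_start <- win_het <= max_het_per_window
    # site i is covered by window starts max(1, i-w+1) .. min(i, L-w+1)
    gs <- c(0, cumsum(good_start))
    lo <- pmax(1L, seq_len(L) - w + 1L)
    hi <- pmin(seq_len(L), L - w + 1L)
    covered_good <- hi >= lo & (gs[pmin(hi, length(good_start)) + 1L] - gs[lo]) > 0
    flagged <- hom & covered_good
    # walk sites, building runs of flagged sites tolerant of missing calls
    run_start <- NA_integer_; last_flag <- NA_integer_; n_run <- 0L
    close_run <- function(a, b, n) {
      len <- pos[b] - pos[a] + 1
      if (n >= min_sites && len >= min_length_bp) {
        segs[[length(segs) + 1L]] <<- data.frame(
          sample_id = dataset$sample_ids[s], chrom = dataset$keys$chrom[a],
          start = pos[a], end = pos[b], n_sites = n, length_bp = len,
          stringsAsFactors = FALSE)
      }
    }
    for (i in seq_len(L)) {
      if (flagged[i]) {
        if (is.na(run_start)) {
          run_start <- i; last_flag <- i; n_run <- 1L
        } else if (pos[i] - pos[last_flag] > max_gap_bp) {
          close_run(run_start, last_flag, n_run)
          run_start <- i; last_flag <- i; n_run <- 1L
        } else {
          last_flag <- i; n_run <- n_run + 1L
        }
      } else if (is.na(gv[i])) {
        next  # missing call: neither extends nor breaks
      } else if (!is.na(run_start)) {
        close_run(run_start, last_flag, n_run)
        run_start <- NA_integer_; n_run <- 0L
      }
    }
    if (!is.na(run_start)) close_run(run_start, last_flag, n_run)
  }
  segments <- if (length(segs)) do.call(rbind, segs) else
    data.frame(sample_id = character(), chrom = character(), start = numeric(),
               end = numeric(), n_sites = integer(), length_bp = numeric())
  per_sample <- data.frame(
    sample_id = dataset$sample_ids,
    n_segments = vapply(dataset$sample_ids,
                        function(id) sum(segments$sample_id == id), integer(1)),
    total_bp = vapply(dataset$sample_ids,
                      function(id) sum(segments$length_bp[segments$sample_id == id]),
                      numeric(1)),
    row.names = NULL)
  list(segments = segments, per_sample = per_sample)
}

#' Method-of-moments inbreeding coefficient
#'
#' Per sample, F = (O_hom - E_hom) / (L - E_hom), with O_hom the observed
#' homozygous calls, L the called sites, and
#' E_hom = sum over called sites of (1 - 2 p (1 - p)) the Hardy-Weinberg
#' expectation at the supplied (or pooled-sample) allele frequencies.
#'
#' @param dataset a [cohort_dataset()] or dosage matrix.
#' @param freqs per-site alternative allele frequencies; defaults to the
#'   pooled sample frequencies of `dataset`.
#' @return data frame (sample_id, n_sites, F); F is NA when L equals
#'   E_hom (no information).
#' @export
inbreeding_f <- function(dataset, freqs = NULL) {
  g <- if (inherits(dataset, "cohort_dataset")) dataset$geno else as.matrix(dataset)
  ids <- if (inherits(dataset, "cohort_dataset")) dataset$sample_ids
         else colnames(g) %||% paste0("s", seq_len(ncol(g)))
  p <- freqs %||% (rowMeans(g, na.rm = TRUE) / 2)
  if (length(p) != nrow(g)) stop_config("freqs must have one entry per site")
  e_site <- 1 - 2 * p * (1 - p)
  out <- lapply(seq_len(ncol(g)), function(s) {
    called <- !is.na(g[, s])
    L <- sum(called)
    O <- sum(g[called, s] != 1L)
    E <- sum(e_site[called])
    data.frame(sample_id = ids[s], n_sites = L,
               F = if (abs(L - E) < 1e-12) NA_real_ else (O - E) / (L - E),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
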