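# Imputation-quality metrics (IMPUTE-type info score, dosage concordance
# r2 by MAF), well-imputed tabulation, association-study variant QC and
# direction-consistent sample-size-weighted meta-analysis.

#' IMPUTE-type info score for one site
#'
#' With per-sample posterior triples (p0, p1, p2), expected dosage
#' e_i = p1 + 2 p2 and second moment f_i = p1 + 4 p2, the estimated allele
#' frequency is theta = sum(e_i) / 2N and
#' info = 1 - sum(f_i - e_i^2) / (2N * theta * (1 - theta)).
#' The score is clamped to `[0, 1]`; when theta is 0 or 1 (monomorphic
#' certainty) the score is defined as 1.
#'
#' @param p N x 3 matrix of posterior probabilities, rows summing to 1.
#' @return a single number in `[0, 1]`.
#' @export
info_score <- function(p) {
  p <- as.matrix(p)
  if (ncol(p) != 3L || nrow(p) < 1L) stop_config("need an N x 3 matrix")
  if (any(p < 0) || any(abs(rowSums(p) - 1) > 1e-6)) {
    stop_config("posterior triples must be non-negative and sum to 1")
  }
  e <- p[, 2L] + 2 * p[, 3L]
  f <- p[, 2L] + 4 * p[, 3L]
  n <- nrow(p)
  theta <- sum(e) / (2 * n)
  if (theta <= 0 || theta >= 1) return(1)
  raw <- 1 - sum(f - e^2) / (2 * n * theta * (1 - theta))
  min(max(raw, 0), 1)
}

#' Info scores for every site of a posterior set
#' @param post a `posterior_genotypes` object.
#' @return numeric vector of per-site scores.
#' @export
info_scores <- function(post) {
  e <- post$p1 + 2 * post$p2
  f <- post$p1 + 4 * post$p2
  n <- ncol(e)
  theta <- rowSums(e) / (2 * n)
  raw <- 1 - rowSums(f - e^2) / (2 * n * theta * (1 - theta))
  out <- pmin(pmax(raw, 0), 1)
  out[theta <= 0 | theta >= 1] <- 1
  out
}

#' Genotype concordance r2 stratified by MAF
#'
#' Per site, r2 is the squared Pearson correlation between the true dosage
#' and the posterior expected dosage across samples (sign-blind by
#' construction: anti-correlated dosages also give r2 = 1). Sites where
#' either vector has zero variance are excluded and counted. Bins are
#' assigned by truth-panel MAF.
#'
#' @param truth sites x samples dosage matrix.
#' @param post aligned `posterior_genotypes`.
#' @param maf_bins bin edges.
#' @return list `per_site` (maf, r2) and `by_bin`
#'   (maf_bin, n, n_excluded, mean_r2).
#' @export
concordance_r2_by_maf <- function(truth, post, maf_bins = default_maf_bins()) {
  truth <- as.matrix(truth)
  if (!all(dim(truth) == dim(post$p0))) {
    stop_config("truth and posteriors are misaligned")
  }
  dos <- posterior_dosage(post)
  ok <- !is.na(truth)
  n_called <- rowSums(ok)
  tm <- rowSums(truth * ok, na.rm = TRUE) / n_called
  dm <- rowSums(dos * ok) / n_called
  tc <- (truth - tm) * ok; tc[is.na(tc)] <- 0
  dc <- (dos - dm) * ok
  vt <- rowSums(tc^2); vd <- rowSums(dc^2)
  r2 <- rowSums(tc * dc)^2 / (vt * vd)
  degenerate <- vt == 0 | vd == 0 | n_called < 2L
  r2[degenerate] <- NA_real_
  af <- rowSums(truth, na.rm = TRUE) / (2 * n_called)
  maf <- maf_of(af)
  bin <- assign_maf_bin(maf, maf_bins)
  per_site <- data.frame(maf = maf, maf_bin = bin, r2 = r2)
  agg <- split(per_site, bin)
  by_bin <- do.call(rbind, lapply(names(agg), function(b) {
    x <- agg[[b]]
    data.frame(maf_bin = b, n = nrow(x), n_excluded = sum(is.na(x$r2)),
               mean_r2 = if (all(is.na(x$r2))) NA_real_
                         else mean(x$r2, na.rm = TRUE))
  }))
  list(per_site = per_site, by_bin = by_bin)
}

#' Tabulate well-imputed sites by MAF bin
#'
#' Counts and proportions of sites whose info score reaches `threshold`
#' (default 0.4, the conventional usable-for-GWAS cutoff), per MAF bin.
#'
#' @param info per-site info scores.
#' @param maf per-site minor allele frequencies.
#' @param maf_bins bin edges.
#' @param threshold info-score cutoff.
#' @return data frame (maf_bin, n, n_well_imputed, proportion).
#' @export
well_imputed_table <- function(info, maf, maf_bins = default_maf_bins(),
                               threshold = 0.4) {
  stopifnot(length(info) == length(maf))
  bin <- assign_maf_bin(maf, maf_bins)
  well <- info >= threshold
  n <- tapply(well, bin, length)
  k <- tapply(well, bin, sum)
  n[is.na(n)] <- 0L; k[is.na(k)] <- 0L
  data.frame(maf_bin = names(n), n = as.integer(n),
             n_well_imputed = as.integer(k),
             proportion = ifelse(n > 0, k / n, NA_real_),
             row.names = NULL)
}

#' Association-study variant QC filter
#'
#' Keeps a variant iff (MAF >= 1% and info > 0.4) or
#' (0.1% <= MAF < 1% and info >= 0.8); variants with MAF below 0.1% are
#' dropped. The common band excludes info <= 0.4 (strict), the rare band
#' requires info >= 0.8 (inclusive).
#'
#' @param variants data frame with columns `maf` and `info`.
#' @return the data frame with logical column `kept` and a `reason` code
#'   (`"pass"`, `"low_info_common"`, `"low_info_rare"`, `"below_maf"`).
#' @export
gwas_qc_filter <- function(variants) {
  stopifnot(all(c("maf", "info") %in% names(variants)))
  maf <- variants$maf; info <- variants$info
  common <- maf >= 0.01
  rare <- maf >= 0.001 & maf < 0.01
  kept <- (common & info > 0.4) | (rare & info >= 0.8)
  reason <- rep("pass", length(maf))
  reason[common & info <= 0.4] <- "low_info_common"
  reason[rare & info < 0.8] <- "low_info_rare"
  reason[maf < 0.001] <- "below_maf"
  variants$kept <- kept
  variants$reason <- reason
  variants
}

#' Sample-size-weighted meta-analysis with direction-consistency filter
#'
#' Combines per-cohort z-scores by the Stouffer method with sqrt(n)
#' weights: z_meta = sum(sqrt(n_i) z_i) / sqrt(sum(n_i)). A variant is
#' flagged excluded unless it is present with the same effect sign in at
#' least two cohorts. Significance is Bonferroni: p < 0.05 / n_tests.
#'
#' @param results data frame with columns `variant`, `cohort`, `z`, `n`.
#' @param n_tests number of tests for the Bonferroni divisor; defaults to
#'   the number of distinct variants.
#' @return data frame (variant, n_cohorts, z_meta, p, excluded, reason,
#'   significant).
#' @export
meta_analyze <- function(results, n_tests = NULL) {
  stopifnot(all(c("variant", "cohort", "z", "n") %in% names(results)))
  variants <- unique(results$variant)
  n_tests <- n_tests %||% length(variants)
  out <- lapply(variants, function(v) {
    x <- results[results$variant == v, , drop = FALSE]
    k <- nrow(x)
    z_meta <- sum(sqrt(x$n) * x$z) / sqrt(sum(x$n))
    p <- 2 * stats::pnorm(-abs(z_meta))
    signs <- sign(x$z)
    concordant <- any(table(signs[signs != 0]) >= 2L)
    reason <- if (k < 2L) "single_cohort"
              else if (!concordant) "direction_discordant" else "pass"
    data.frame(variant = v, n_cohorts = k, z_meta = z_meta, p = p,
               excluded = reason != "pass", reason = reason,
               significant = reason == "pass" & p < 0.05 / n_tests,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
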