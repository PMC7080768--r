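# Reference-imputation-panel site selection: per-cohort allele-count and
# depth statistics, the inclusion rules (AC >= 2 & depth, singleton
# rescue via cross-cohort or external sharing), and sharing spectra.

#' Per-site allele-count and depth statistics
#'
#' AC counts alternative alleles over non-missing genotypes, AN the called
#' alleles; AF = AC/AN (NA when no genotype is called). `mean_DP` averages
#' depth over samples with a called genotype, NA when the dataset carries
#' no depths.
#'
#' @param dataset a [cohort_dataset()].
#' @return data frame (chrom, pos, ref, alt, key, AC, AN, AF, mean_DP).
#' @export
compute_site_stats <- function(dataset) {
  stopifnot(inherits(dataset, "cohort_dataset"))
  g <- dataset$geno
  called <- !is.na(g)
  AC <- as.integer(rowSums(g, na.rm = TRUE))
  AN <- as.integer(2L * rowSums(called))
  AF <- ifelse(AN > 0L, AC / AN, NA_real_)
  if (!is.null(dataset$dp)) {
    dp <- dataset$dp
    dp[!called] <- NA
    mean_DP <- rowMeans(dp, na.rm = TRUE)
    mean_DP[rowSums(called) == 0L] <- NA_real_
  } else {
    mean_DP <- rep(NA_real_, nrow(g))
  }
  cbind(dataset$keys,
        data.frame(key = dataset_keys(dataset), AC = AC, AN = AN, AF = AF,
                   mean_DP = mean_DP, stringsAsFactors = FALSE))
}

#' Select reference-panel sites per cohort
#'
#' A site enters a cohort's panel contribution iff
#' (a) its AC is at least 2 and its mean depth at least `min_dp`, or
#' (b) it is a singleton (AC = 1) shared with at least one other cohort
#'     (any AC) or present in at least one external resource.
#' The rule is evaluated independently per cohort; matching is by exact
#' (chrom, pos, ref, alt). Sites with no called genotypes are excluded.
#' When a cohort carries no depth information the depth clause is treated
#' as satisfied.
#'
#' @param cohorts named list of site-stats data frames
#'   (from [compute_site_stats()]).
#' @param externals list of external site-list data frames or key vectors.
#' @param min_ac,min_dp rule (a) thresholds.
#' @return list `retained` (named list of key vectors) and `report`
#'   (per-cohort site totals and retention proportion).
#' @export
select_panel_sites <- function(cohorts, externals = list(),
                               min_ac = 2L, min_dp = 5) {
  if (length(cohorts) < 1L) stop_config("need at least one cohort")
  if (is.null(names(cohorts))) names(cohorts) <- paste0("pop", seq_along(cohorts))
  ext_keys <- unique(unlist(lapply(externals, function(e) {
    if (is.character(e)) e else variant_key(e)
  })))
  # a site counts as present in a cohort only when polymorphic there
  all_keys <- lapply(cohorts, function(s) s$key[s$AC > 0L])
  retained <- list()
  report <- data.frame(population = character(), n_sites = integer(),
                       n_retained = integer(), retention = numeric(),
                       stringsAsFactors = FALSE)
  for (nm in names(cohorts)) {
    s <- cohorts[[nm]]
    if (nrow(s) == 0L) {
      warning(sprintf("cohort %s has no sites", nm))
      retained[[nm]] <- character(0)
      report <- rbind(report, data.frame(population = nm, n_sites = 0L,
                                         n_retained = 0L, retention = NA_real_))
      next
    }
    other <- unique(unlist(all_keys[setdiff(names(cohorts), nm)]))
    dp_ok <- is.na(s$mean_DP) | s$mean_DP >= min_dp
    rule_a <- s$AC >= min_ac & dp_ok
    rule_b <- s$AC == 1L & (s$key %in% other | s$key %in% ext_keys)
    keep <- (rule_a | rule_b) & s$AN > 0L
    retained[[nm]] <- s$key[keep]
    report <- rbind(report, data.frame(
      population = nm, n_sites = sum(s$AC > 0L), n_retained = sum(keep),
      retention = sum(keep) / max(sum(s$AC > 0L), 1L)))
  }
  list(retained = retained, report = report)
}

#' Cross-resource sharing spectrum
#'
#' Classifies each cohort's polymorphic sites as present-in-external,
#' shared-with-another-cohort-only, or private-to-cohort, cross-tabulated
#' by minor-allele-frequency bin. Categories partition each cohort's
#' sites.
#'
#' @param cohorts named list of site-stats data frames.
#' @param externals list of external site lists (data frames or keys).
#' @param maf_bins bin edges, strictly increasing.
#' @return data frame (population, maf_bin, category, n).
#' @export
sharing_spectrum <- function(cohorts, externals = list(),
                             maf_bins = default_maf_bins()) {
  if (any(diff(maf_bins) <= 0)) stop_config("maf bin edges must be increasing")
  if (is.null(names(cohorts))) names(cohorts) <- paste0("pop", seq_along(cohorts))
  ext_keys <- unique(unlist(lapply(externals, function(e) {
    if (is.character(e)) e else variant_key(e)
  })))
  all_keys <- lapply(cohorts, function(s) s$key[s$AC > 0L])
  out <- list()
  for (nm in names(cohorts)) {
    s <- cohorts[[nm]]
    s <- s[!is.na(s$AF) & s$AC > 0L, , drop = FALSE]
    other <- unique(unlist(all_keys[setdiff(names(cohorts), nm)]))
    category <- ifelse(s$key %in% ext_keys, "external",
                       ifelse(s$key %in% other, "ingi_shared", "private"))
    bin <- assign_maf_bin(maf_of(s$AF), maf_bins)
    tab <- as.data.frame(table(maf_bin = bin, category =
                                 factor(category, c("private", "ingi_shared",
                                                    "external"))))
    tab$population <- nm
    out[[nm]] <- tab[, c("population", "maf_bin", "category", "Freq")]
  }
  res <- do.call(rbind, out)
  names(res)[4L] <- "n"
  rownames(res) <- NULL
  res
}
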