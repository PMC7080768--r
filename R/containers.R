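# Core data containers: phased haplotype panels and diploid cohort datasets.

#' Phased haplotype panel
#'
#' Holds a phased 0/1 haplotype matrix for one population: two rows per
#' sample (maternal/paternal copy), one column per biallelic site. Allele 0
#' is the reference allele and, in synthetic panels, also the ancestral
#' state unless an ancestral vector says otherwise.
#'
#' @param haplotypes integer matrix of 0/1 with `2 * length(sample_ids)`
#'   rows and `length(positions)` columns.
#' @param positions strictly increasing 1-based physical positions (bp).
#' @param ref,alt character vectors of alleles per site; `ref != alt`.
#' @param sample_ids sample labels; haplotype rows `2i - 1` and `2i` belong
#'   to sample `i`.
#' @param population_id label for the population.
#' @param chrom chromosome label (single value).
#' @param mut_rate,recomb_rate per-site mutation probability per copied
#'   haplotype and per-bp recombination switch rate; carried so that
#'   isolates derived from this panel inherit the simulation regime.
#' @return an object of class `haplotype_panel`.
#' @export
haplotype_panel <- function(haplotypes, positions, ref, alt, sample_ids,
                            population_id = "pop", chrom = "1",
                            mut_rate = 0, recomb_rate = 0) {
  haplotypes <- as.matrix(haplotypes)
  storage.mode(haplotypes) <- "integer"
  if (nrow(haplotypes) %% 2L != 0L) stop_config("haplotype row count must be even")
  if (nrow(haplotypes) != 2L * length(sample_ids)) {
    stop_config("need exactly two haplotype rows per sample")
  }
  if (ncol(haplotypes) != length(positions)) {
    stop_config("positions length must equal haplotype column count")
  }
  if (length(positions) > 1L && any(diff(positions) <= 0)) {
    stop_config("positions must be strictly increasing")
  }
  if (length(ref) != length(positions) || length(alt) != length(positions)) {
    stop_config("ref/alt must have one entry per site")
  }
  if (any(!nzchar(ref)) || any(!nzchar(alt)) || any(ref == alt)) {
    stop_config("alleles must be non-empty and ref != alt")
  }
  if (length(positions) && !all(haplotypes %in% c(0L, 1L))) {
    stop_config("haplotypes must contain only 0/1")
  }
  structure(list(
    population_id = population_id, chrom = chrom,
    sample_ids = sample_ids, haplotypes = haplotypes,
    positions = as.numeric(positions), ref = as.character(ref),
    alt = as.character(alt), mut_rate = mut_rate, recomb_rate = recomb_rate
  ), class = "haplotype_panel")
}

#' @export
print.haplotype_panel <- function(x, ...) {
  cat(sprintf("<haplotype_panel> %s: %d haplotypes (%d samples) x %d sites on chr%s\n",
              x$population_id, nrow(x$haplotypes), length(x$sample_ids),
              ncol(x$haplotypes), x$chrom))
  invisible(x)
}

panel_keys <- function(panel) {
  variant_key(panel$chrom, panel$positions, panel$ref, panel$alt)
}

#' Diploid cohort dataset
#'
#' Genotype dosages (0/1/2 alternative-allele copies, NA for missing) for
#' one cohort, aligned to a variant-key table; optionally carries
#' per-genotype depths and the phased haplotypes the genotypes came from.
#'
#' @param keys data frame with columns `chrom`, `pos`, `ref`, `alt`.
#' @param geno sites x samples integer matrix of dosages.
#' @param sample_ids sample labels (columns of `geno`).
#' @param dp optional sites x samples depth matrix.
#' @param haplotypes optional phased 0/1 matrix, `2 * n_samples` rows.
#' @param population_id label.
#' @return an object of class `cohort_dataset`.
#' @export
cohort_dataset <- function(keys, geno, sample_ids, dp = NULL,
                           haplotypes = NULL, population_id = "pop") {
  geno <- as.matrix(geno)
  if (nrow(geno) != nrow(keys)) stop_config("geno rows must match key rows")
  if (ncol(geno) != length(sample_ids)) stop_config("geno columns must match samples")
  if (!all(is.na(geno) | geno %in% 0:2)) stop_config("genotypes must be 0/1/2 or NA")
  if (!is.null(dp)) {
    dp <- as.matrix(dp)
    if (!all(dim(dp) == dim(geno))) stop_config("dp must have geno dimensions")
  }
  if (!is.null(haplotypes)) {
    haplotypes <- as.matrix(haplotypes)
    if (nrow(haplotypes) != 2L * ncol(geno) || ncol(haplotypes) != nrow(geno)) {
      stop_config("haplotypes must be 2*n_samples rows x n_sites columns")
    }
  }
  structure(list(
    population_id = population_id,
    keys = as.data.frame(keys)[, c("chrom", "pos", "ref", "alt")],
    geno = geno, dp = dp, haplotypes = haplotypes, sample_ids = sample_ids
  ), class = "cohort_dataset")
}

#' @export
print.cohort_dataset <- function(x, ...) {
  cat(sprintf("<cohort_dataset> %s: %d sites x %d samples%s%s\n",
              x$population_id, nrow(x$geno), ncol(x$geno),
              if (!is.null(x$dp)) " +DP" else "",
              if (!is.null(x$haplotypes)) " (phased)" else ""))
  invisible(x)
}

#' Convert a phased panel to a diploid cohort dataset
#'
#' Consecutive haplotype row pairs become one diploid sample; dosage is the
#' sum of the two haplotype alleles.
#'
#' @param panel a [haplotype_panel()].
#' @param dp optional depth matrix or single mean depth used as a constant.
#' @return a [cohort_dataset()] with haplotypes retained.
#' @export
panel_to_dataset <- function(panel, dp = NULL) {
  h <- panel$haplotypes
  n <- nrow(h) / 2L
  geno <- t(h[seq(1L, 2L * n, by = 2L), , drop = FALSE] +
              h[seq(2L, 2L * n, by = 2L), , drop = FALSE])
  if (!is.null(dp) && length(dp) == 1L) {
    dp <- matrix(as.numeric(dp), nrow = nrow(geno), ncol = ncol(geno))
  }
  cohort_dataset(
    keys = data.frame(chrom = panel$chrom, pos = panel$positions,
                      ref = panel$ref, alt = panel$alt,
                      stringsAsFactors = FALSE),
    geno = geno, sample_ids = panel$sample_ids, dp = dp,
    haplotypes = h, population_id = panel$population_id
  )
}

dataset_keys <- function(dataset) variant_key(dataset$keys)
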