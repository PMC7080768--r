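# Human-knockout detection: loss-of-function classification, homozygote
# screening across cohorts, TOTAL/PARTIAL classification, cross-population
# gene overlaps restricted to an external catalogue, and comparison of
# gene-intolerance (RVIS) distributions.

#' High-impact consequence terms
#'
#' The eight standard loss-of-function consequence terms: frameshift,
#' splice acceptor, splice donor, stop gained, stop lost, start lost,
#' transcript ablation, transcript amplification.
#' @return character vector of VEP-style terms.
#' @export
hko_high_impact_terms <- function() {
  c("frameshift_variant", "splice_acceptor_variant", "splice_donor_variant",
    "stop_gained", "stop_lost", "start_lost", "transcript_ablation",
    "transcript_amplification")
}

known_consequence_terms <- function() {
  c(hko_high_impact_terms(),
    "missense_variant", "synonymous_variant", "intron_variant",
    "intergenic_variant", "3_prime_UTR_variant", "5_prime_UTR_variant",
    "upstream_gene_variant", "downstream_gene_variant",
    "non_coding_transcript_variant", "splice_region_variant")
}

#' Classify variants as putative loss-of-function
#'
#' TRUE iff the consequence term belongs to the eight-term high-impact set
#' and the deleteriousness score is at least `cadd_min` (default 20).
#' Unknown consequence terms yield FALSE with a warning.
#'
#' @param annotations annotation data frame (`consequence`, `cadd_phred`).
#' @param cadd_min minimum phred-like score.
#' @return logical vector, one per annotation row.
#' @export
classify_lof <- function(annotations, cadd_min = 20) {
  cons <- annotations$consequence
  unknown <- !(cons %in% known_consequence_terms())
  if (any(unknown)) {
    warning(sprintf("%d unknown consequence term(s) treated as non-LoF (e.g. %s)",
                    sum(unknown), cons[which(unknown)[1L]]))
  }
  cons %in% hko_high_impact_terms() & annotations$cadd_phred >= cadd_min
}

#' Detect putative human knockouts
#'
#' A loss-of-function variant is a putative knockout when at least one
#' individual in at least one cohort is homozygous for the alternative
#' allele (dosage 2; missing genotypes are ignored). The record is TOTAL
#' when the variant affects all of its gene's transcripts, PARTIAL
#' otherwise. Per-individual counts of TOTAL knockouts are reported
#' alongside.
#'
#' @param datasets named list of [cohort_dataset()]s (one per population).
#' @param annotations shared annotation table.
#' @param cadd_min score threshold passed to [classify_lof()].
#' @param external_sites optional site list (data frame or key vector)
#'   standing in for a public catalogue; fills `in_external_list`.
#' @return list `records` (key, gene, classification, populations,
#'   hom_counts per population, in_external_list) and `per_individual`
#'   (population, sample_id, n_total_hko).
#' @export
detect_hko <- function(datasets, annotations, cadd_min = 20,
                       external_sites = NULL) {
  if (is.null(names(datasets))) names(datasets) <- paste0("pop", seq_along(datasets))
  lof <- classify_lof(annotations, cadd_min)
  ann <- annotations[lof, , drop = FALSE]
  ann_keys <- variant_key(ann)
  ext_keys <- if (is.null(external_sites)) NULL
              else if (is.character(external_sites)) external_sites
              else variant_key(external_sites)
  pops <- names(datasets)
  hom <- matrix(0L, nrow = length(ann_keys), ncol = length(pops),
                dimnames = list(NULL, pops))
  for (p in pops) {
    ds <- datasets[[p]]
    idx <- match(ann_keys, dataset_keys(ds))
    present <- !is.na(idx)
    if (any(present)) {
      hom[present, p] <- rowSums(
        ds$geno[idx[present], , drop = FALSE] == 2L, na.rm = TRUE)
    }
  }
  has_hom <- rowSums(hom) > 0L
  records <- data.frame(
    key = ann_keys[has_hom], gene = ann$gene[has_hom],
    classification = ifelse(
      ann$affected_transcripts[has_hom] == ann$n_transcripts[has_hom],
      "TOTAL", "PARTIAL"),
    populations = vapply(which(has_hom), function(i) {
      paste(pops[hom[i, ] > 0L], collapse = ",")
    }, character(1)),
    stringsAsFactors = FALSE)
  records <- cbind(records, as.data.frame(hom[has_hom, , drop = FALSE]))
  records$in_external_list <- if (is.null(ext_keys)) NA else
    records$key %in% ext_keys
  total_keys <- records$key[records$classification == "TOTAL"]
  per_individual <- do.call(rbind, lapply(pops, function(p) {
    ds <- datasets[[p]]
    idx <- match(total_keys, dataset_keys(ds))
    idx <- idx[!is.na(idx)]
    counts <- if (length(idx)) {
      colSums(ds$geno[idx, , drop = FALSE] == 2L, na.rm = TRUE)
    } else rep(0L, length(ds$sample_ids))
    data.frame(population = p, sample_id = ds$sample_ids,
               n_total_hko = as.integer(counts), stringsAsFactors = FALSE)
  }))
  rownames(per_individual) <- NULL
  list(records = records, per_individual = per_individual)
}

#' Cross-population knockout gene overlap
#'
#' Restricts records to variants present in the external catalogue (a
#' false-positive guard), collapses variants to genes per population, and
#' reports per-population private gene counts together with the
#' all-population intersection.
#'
#' @param records the `records` frame from [detect_hko()].
#' @param external_sites site list (data frame or key vector); when NULL
#'   the stored `in_external_list` flag is used.
#' @return list `gene_sets` (per population), `private_counts`,
#'   `shared_all` (genes present in every population),
#'   `n_genes_total`.
#' @export
hko_overlap <- function(records, external_sites = NULL) {
  keep <- if (!is.null(external_sites)) {
    ext <- if (is.character(external_sites)) external_sites
           else variant_key(external_sites)
    records$key %in% ext
  } else if (!all(is.na(records$in_external_list))) {
    records$in_external_list %in% TRUE
  } else rep(TRUE, nrow(records))
  records <- records[keep, , drop = FALSE]
  if (nrow(records) == 0L) {
    warning("no knockout record left after external-list restriction")
    return(list(gene_sets = list(), private_counts = integer(),
                shared_all = character(), n_genes_total = 0L))
  }
  pops <- unique(unlist(strsplit(records$populations, ",")))
  gene_sets <- lapply(pops, function(p) {
    unique(records$gene[vapply(strsplit(records$populations, ","),
                               function(x) p %in% x, logical(1))])
  })
  names(gene_sets) <- pops
  private <- vapply(pops, function(p) {
    others <- unique(unlist(gene_sets[setdiff(pops, p)]))
    sum(!(gene_sets[[p]] %in% others))
  }, integer(1))
  list(gene_sets = gene_sets, private_counts = private,
       shared_all = Reduce(intersect, gene_sets),
       n_genes_total = length(unique(records$gene)))
}

#' Compare gene-intolerance scores of knockout genes to the background
#'
#' Wilcoxon rank-sum test (normal approximation with tie correction)
#' comparing the RVIS scores of knockout genes against all scored genes;
#' medians of both groups are reported. When the rank variance is zero
#' (all values tied) the statistic sits at its null midpoint and p = 1.
#'
#' @param hko_genes gene ids with a detected knockout.
#' @param all_genes background gene ids.
#' @param rvis named RVIS vector from [read_rvis_table()].
#' @return list (median_hko, median_all, n_hko, n_all, statistic, p).
#' @export
rvis_test <- function(hko_genes, all_genes, rvis) {
  x <- rvis[intersect(unique(hko_genes), names(rvis))]
  y <- rvis[intersect(unique(all_genes), names(rvis))]
  if (length(x) == 0L || length(y) == 0L) {
    stop_config("need at least one scored gene on each side")
  }
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  r <- rank(c(x, y))
  W <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  ties <- table(r)
  sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  if (sigma2 <= 0) {
    z <- 0; p <- 1
  } else {
    z <- (W - mu) / sqrt(sigma2)
    p <- 2 * stats::pnorm(-abs(z))
  }
  list(median_hko = stats::median(x), median_all = stats::median(y),
       n_hko = n1, n_all = n2, statistic = W, z = z, p = p)
}
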