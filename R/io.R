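# Readers and writers for the formats the pipeline touches: VCF 4.2 with
# GT (+DP), annotation/site-list/RVIS TSVs, and posterior tables.

#' Read a multi-sample VCF into a cohort dataset
#'
#' Loads genotypes (and FORMAT/DP when present) from a biallelic VCF.
#' Multiallelic records are skipped with a warning or rejected, per
#' `multiallelic`. Phase is retained when every genotype is phased.
#'
#' @param path VCF file (plain or gzipped).
#' @param require_phase error unless all genotypes are phased (`|`).
#' @param multiallelic `"skip"` (drop rows, warn) or `"error"`.
#' @param population_id label; defaults to the file name.
#' @return a [cohort_dataset()].
#' @export
read_vcf <- function(path, require_phase = FALSE,
                     multiallelic = c("skip", "error"),
                     population_id = NULL) {
  multiallelic <- match.arg(multiallelic)
  if (!file.exists(path)) stop_config("VCF not found: %s", path)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  multi <- grepl(",", fix$ALT, fixed = TRUE)
  if (any(multi)) {
    if (multiallelic == "error") {
      stop_config("%d multiallelic record(s) present", sum(multi))
    }
    warning(sprintf("skipping %d multiallelic record(s)", sum(multi)))
  }
  keep <- !multi
  gt <- vcfR::extract.gt(vcf, element = "GT")
  gt <- gt[keep, , drop = FALSE]
  fix <- fix[keep, , drop = FALSE]
  alleles <- gt
  alleles[alleles %in% c(".", "./.", ".|.")] <- NA
  phased <- grepl("|", alleles, fixed = TRUE)
  unphased <- grepl("/", alleles, fixed = TRUE)
  if (require_phase && any(unphased & !is.na(alleles))) {
    stop_config("unphased genotypes present but phase is required")
  }
  a1 <- suppressWarnings(as.integer(substr(alleles, 1L, 1L)))
  a2 <- suppressWarnings(as.integer(substr(alleles, 3L, 3L)))
  geno <- matrix(a1 + a2, nrow = nrow(gt), dimnames = dimnames(gt))
  dp <- NULL
  fmt <- vcf@gt[, 1L]
  if (length(fmt) && any(grepl("DP", fmt))) {
    dp <- vcfR::extract.gt(vcf, element = "DP", as.numeric = TRUE)
    dp <- dp[keep, , drop = FALSE]
  }
  haps <- NULL
  all_phased <- nrow(gt) > 0 && all(phased | is.na(alleles))
  if (all_phased && !anyNA(alleles)) {
    haps <- matrix(0L, nrow = 2L * ncol(gt), ncol = nrow(gt))
    haps[seq(1L, nrow(haps), by = 2L), ] <- t(matrix(a1, nrow = nrow(gt)))
    haps[seq(2L, nrow(haps), by = 2L), ] <- t(matrix(a2, nrow = nrow(gt)))
  }
  cohort_dataset(
    keys = data.frame(chrom = fix$CHROM, pos = as.numeric(fix$POS),
                      ref = fix$REF, alt = fix$ALT, stringsAsFactors = FALSE),
    geno = geno, sample_ids = colnames(gt), dp = dp, haplotypes = haps,
    population_id = population_id %||% sub("\\.vcf(\\.gz)?$", "", basename(path))
  )
}

#' Write a cohort dataset as VCF 4.2
#'
#' Emits GT (phased `|` when haplotypes are present, otherwise unphased
#' `/`) plus DP when depths are present. Records are sorted by
#' (chrom, pos); unsorted input is sorted with a message.
#'
#' @param dataset a [cohort_dataset()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(dataset, path) {
  stopifnot(inherits(dataset, "cohort_dataset"))
  keys <- dataset$keys
  ord <- order(keys$chrom, keys$pos)
  if (is.unsorted(ord)) message("sorting records by (chrom, pos) on write")
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=isopop",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">'
  )
  has_dp <- !is.null(dataset$dp)
  if (has_dp) {
    header <- c(header,
      '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">')
  }
  header <- c(header, paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                              "FILTER", "INFO", "FORMAT", dataset$sample_ids),
                            collapse = "\t"))
  L <- nrow(keys)
  if (L == 0L) {
    writeLines(header, path)
    return(invisible(path))
  }
  phased <- !is.null(dataset$haplotypes)
  if (phased) {
    h <- dataset$haplotypes
    n <- ncol(dataset$geno)
    gt <- matrix(paste(t(h[seq(1L, 2L * n, 2L), , drop = FALSE]),
                       t(h[seq(2L, 2L * n, 2L), , drop = FALSE]), sep = "|"),
                 nrow = L)
  } else {
    g <- dataset$geno
    gt <- matrix(c("0/0", "0/1", "1/1")[g + 1L], nrow = L)
    gt[is.na(g)] <- "./."
  }
  if (has_dp) {
    dp <- dataset$dp
    dpc <- matrix(as.character(dp), nrow = L)
    dpc[is.na(dp)] <- "."
    gt <- matrix(paste(gt, dpc, sep = ":"), nrow = L)
  }
  body <- data.table::data.table(
    CHROM = keys$chrom, POS = keys$pos, ID = ".",
    REF = keys$ref, ALT = keys$alt, QUAL = ".", FILTER = "PASS", INFO = ".",
    FORMAT = if (has_dp) "GT:DP" else "GT"
  )
  body <- cbind(body, data.table::as.data.table(gt))
  body <- body[ord, ]
  writeLines(header, path)
  data.table::fwrite(body, path, sep = "\t", append = TRUE, col.names = FALSE)
  invisible(path)
}

read_tsv_checked <- function(path, required, what) {
  if (!file.exists(path)) stop_config("%s table not found: %s", what, path)
  dt <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE)
  missing <- setdiff(required, names(dt))
  if (length(missing)) {
    stop_config("%s table %s lacks required column(s): %s", what, path,
                paste(missing, collapse = ", "))
  }
  dt
}

#' Read a per-variant annotation table
#'
#' TSV with header chrom, pos, ref, alt, gene, n_transcripts,
#' affected_transcripts, consequence, cadd_phred. Duplicate variant keys
#' keep the last row, with a warning.
#'
#' @param path file path.
#' @return data frame keyed by variant.
#' @export
read_annotation_table <- function(path) {
  dt <- read_tsv_checked(path, c("chrom", "pos", "ref", "alt", "gene",
                                 "n_transcripts", "affected_transcripts",
                                 "consequence", "cadd_phred"), "annotation")
  key <- variant_key(dt)
  if (anyDuplicated(key)) {
    warning(sprintf("%d duplicate annotation key(s); keeping last",
                    sum(duplicated(key))))
    dt <- dt[!duplicated(key, fromLast = TRUE), , drop = FALSE]
  }
  dt
}

#' Read an external-resource site list
#'
#' Four-column TSV (chrom, pos, ref, alt) standing in for membership in a
#' public panel. Duplicates are dropped.
#'
#' @param path file path.
#' @return data frame of unique variant keys.
#' @export
read_site_list <- function(path) {
  dt <- read_tsv_checked(path, c("chrom", "pos", "ref", "alt"), "site list")
  dt[!duplicated(variant_key(dt)), , drop = FALSE]
}

#' Read a gene-to-RVIS table
#'
#' Two-column TSV (gene, rvis). Duplicate genes keep the last row with a
#' warning. Lookups of absent genes must yield `NA`, not 0: use
#' [rvis_lookup()].
#'
#' @param path file path.
#' @return named numeric vector of RVIS scores.
#' @export
read_rvis_table <- function(path) {
  dt <- read_tsv_checked(path, c("gene", "rvis"), "RVIS")
  if (anyDuplicated(dt$gene)) {
    warning(sprintf("%d duplicate gene(s) in RVIS table; keeping last",
                    sum(duplicated(dt$gene))))
    dt <- dt[!duplicated(dt$gene, fromLast = TRUE), , drop = FALSE]
  }
  stats::setNames(as.numeric(dt$rvis), dt$gene)
}

#' Look up RVIS scores with an explicit absent marker
#' @param rvis named vector from [read_rvis_table()].
#' @param genes gene ids.
#' @return numeric vector, `NA` where a gene is unscored.
#' @export
rvis_lookup <- function(rvis, genes) {
  out <- rvis[genes]
  names(out) <- genes
  out
}

#' Read annotation, site-list and RVIS tables together
#' @param annotation_path,site_list_path,rvis_path file paths.
#' @return list(annotation, sites, rvis).
#' @export
read_tables <- function(annotation_path, site_list_path, rvis_path) {
  list(annotation = read_annotation_table(annotation_path),
       sites = read_site_list(site_list_path),
       rvis = read_rvis_table(rvis_path))
}

#' Write imputation-style posteriors as TSV
#'
#' One row per site: key columns then three probability columns per sample
#' (`<id>.p0`, `<id>.p1`, `<id>.p2`), Oxford GEN-style.
#'
#' @param post a `posterior_genotypes` object.
#' @param keys variant key data frame.
#' @param sample_ids sample labels.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_posteriors <- function(post, keys, sample_ids, path) {
  L <- nrow(post$p0); N <- ncol(post$p0)
  stopifnot(nrow(keys) == L, length(sample_ids) == N)
  probs <- matrix(0, nrow = L, ncol = 3L * N)
  probs[, seq(1L, 3L * N, 3L)] <- post$p0
  probs[, seq(2L, 3L * N, 3L)] <- post$p1
  probs[, seq(3L, 3L * N, 3L)] <- post$p2
  colnames(probs) <- paste0(rep(sample_ids, each = 3L), c(".p0", ".p1", ".p2"))
  data.table::fwrite(cbind(keys, as.data.frame(signif(probs, 7))), path, sep = "\t")
  invisible(path)
}

#' Read posteriors written by [write_posteriors()]
#' @param path file path.
#' @return list(post = `posterior_genotypes`, keys, sample_ids).
#' @export
read_posteriors <- function(path) {
  dt <- read_tsv_checked(path, c("chrom", "pos", "ref", "alt"), "posterior")
  prob_cols <- grep("\\.p[012]$", names(dt), value = TRUE)
  sample_ids <- unique(sub("\\.p[012]$", "", prob_cols))
  p0 <- as.matrix(dt[, paste0(sample_ids, ".p0"), drop = FALSE])
  p1 <- as.matrix(dt[, paste0(sample_ids, ".p1"), drop = FALSE])
  p2 <- as.matrix(dt[, paste0(sample_ids, ".p2"), drop = FALSE])
  dimnames(p0) <- dimnames(p1) <- dimnames(p2) <- NULL
  list(post = structure(list(p0 = p0, p1 = p1, p2 = p2),
                        class = "posterior_genotypes"),
       keys = dt[, c("chrom", "pos", "ref", "alt")],
       sample_ids = sample_ids)
}
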