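# Synthetic cohort simulator: founder-mosaic haplotypes, isolate
# bottlenecks, planted sweeps, annotations and imputation posteriors.
# The copying model is Li-Stephens-like: each haplotype is a mosaic of
# founder templates with geometric (per-bp exponential) switch distances,
# plus new point mutations. This reproduces the features the downstream
# statistics rely on (LD decay, rare-heavy SFS, drift under bottlenecks)
# without a full coalescent machinery.

#' Simulation configuration
#'
#' Bundles and validates all parameters of the synthetic cohort generator.
#' Defaults define a small multi-isolate study: a common founder pool from
#' which three isolates of differing severity are drawn.
#'
#' @param seed master RNG seed; equal configs give bit-identical output.
#' @param n_founders founder templates in the base pool.
#' @param n_haplotypes_base haplotypes drawn for the base panel (even).
#' @param n_sites polymorphic sites requested (monomorphic draws are
#'   dropped, so the realised count can be slightly lower).
#' @param chrom_length_bp chromosome length in bp.
#' @param mutation_rate_per_copy per-site flip probability applied each
#'   time a haplotype is copied.
#' @param recombination_switch_rate_per_bp template switch rate; switch
#'   probability across a gap of g bp is `1 - exp(-rate * g)`.
#' @param bottleneck_founders named integer vector: haplotypes drawn
#'   (without replacement) to found each isolate; smaller = more drift.
#' @param n_isolate_generations scales mutation/recombination opportunity
#'   during isolate copying.
#' @param sweep_spec optional list(`focal_pos`, `carrier_fraction`,
#'   `flank_bp`, optional `population`) describing a planted sweep.
#' @param annotation_spec list of annotation parameters, see
#'   [annotate_sites()].
#' @param posterior_noise list(`e_min`, `e_max`, `maf_decay`): genotype
#'   error rate `e_min + (e_max - e_min) * exp(-maf / maf_decay)`, so rare
#'   sites are imputed worse, mirroring real panels.
#' @param dp_mean mean simulated per-genotype read depth.
#' @param missing_rate probability a genotype is set missing in emitted
#'   datasets.
#' @return a validated `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       n_founders = 25L,
                       n_haplotypes_base = 200L,
                       n_sites = 5000L,
                       chrom_length_bp = 5e6,
                       mutation_rate_per_copy = 5e-5,
                       recombination_switch_rate_per_bp = 5e-6,
                       bottleneck_founders = c(ISO1 = 12L, ISO2 = 30L, ISO3 = 60L),
                       n_isolate_generations = 10L,
                       sweep_spec = NULL,
                       annotation_spec = list(),
                       posterior_noise = list(e_min = 0.01, e_max = 0.2,
                                              maf_decay = 0.05),
                       dp_mean = 20,
                       missing_rate = 0) {
  check_positive(n_founders, "n_founders")
  check_positive(n_haplotypes_base, "n_haplotypes_base")
  check_positive(n_sites, "n_sites")
  check_positive(chrom_length_bp, "chrom_length_bp")
  check_positive(dp_mean, "dp_mean")
  if (n_haplotypes_base %% 2 != 0) stop_config("n_haplotypes_base must be even")
  if (mutation_rate_per_copy < 0 || recombination_switch_rate_per_bp < 0) {
    stop_config("rates must be non-negative")
  }
  check_positive(bottleneck_founders, "bottleneck_founders")
  if (is.null(names(bottleneck_founders))) {
    names(bottleneck_founders) <- paste0("ISO", seq_along(bottleneck_founders))
  }
  if (n_isolate_generations < 0) stop_config("n_isolate_generations must be >= 0")
  check_fraction(missing_rate, "missing_rate")
  if (!is.null(sweep_spec)) {
    check_positive(sweep_spec$focal_pos, "sweep_spec$focal_pos")
    check_fraction(sweep_spec$carrier_fraction, "sweep_spec$carrier_fraction",
                   open = TRUE)
    if (sweep_spec$flank_bp < 0) stop_config("sweep flank must be >= 0")
  }
  annotation_spec <- do.call(annotation_spec_defaults, annotation_spec)
  if (posterior_noise$e_min < 0 || posterior_noise$e_max < 0) {
    stop_config("posterior noise rates must be non-negative")
  }
  structure(list(
    seed = as.integer(seed), n_founders = as.integer(n_founders),
    n_haplotypes_base = as.integer(n_haplotypes_base),
    n_sites = as.integer(n_sites), chrom_length_bp = chrom_length_bp,
    mutation_rate_per_copy = mutation_rate_per_copy,
    recombination_switch_rate_per_bp = recombination_switch_rate_per_bp,
    bottleneck_founders = bottleneck_founders,
    n_isolate_generations = as.integer(n_isolate_generations),
    sweep_spec = sweep_spec, annotation_spec = annotation_spec,
    posterior_noise = posterior_noise, dp_mean = dp_mean,
    missing_rate = missing_rate
  ), class = "sim_config")
}

annotation_spec_defaults <- function(p_high_impact = 0.01,
                                     low_terms = c("missense_variant",
                                                   "synonymous_variant",
                                                   "intron_variant",
                                                   "intergenic_variant",
                                                   "3_prime_UTR_variant"),
                                     low_term_probs = NULL,
                                     cadd_tail_prob = 0.08,
                                     genes_per_chrom = 50L,
                                     transcripts_per_gene = 3) {
  check_fraction(p_high_impact, "p_high_impact")
  check_fraction(cadd_tail_prob, "cadd_tail_prob")
  check_positive(genes_per_chrom, "genes_per_chrom")
  check_positive(transcripts_per_gene, "transcripts_per_gene")
  if (is.null(low_term_probs)) {
    low_term_probs <- rep(1 / length(low_terms), length(low_terms))
  }
  if (abs(sum(low_term_probs) - 1) > 1e-9 || any(low_term_probs < 0)) {
    stop_config("low_term_probs must be a probability vector summing to 1")
  }
  list(p_high_impact = p_high_impact, low_terms = low_terms,
       low_term_probs = low_term_probs, cadd_tail_prob = cadd_tail_prob,
       genes_per_chrom = as.integer(genes_per_chrom),
       transcripts_per_gene = transcripts_per_gene)
}

# mosaic copy of `n_out` haplotypes from a founder matrix; switch
# probability per inter-site gap and per-site flip probability given.
mosaic_copy <- function(founders, positions, n_out, switch_rate, mut_rate) {
  L <- ncol(founders)
  nf <- nrow(founders)
  out <- matrix(0L, nrow = n_out, ncol = L)
  p_switch <- if (L > 1L) 1 - exp(-switch_rate * diff(positions)) else numeric(0)
  for (i in seq_len(n_out)) {
    if (nf == 1L) {
      path <- rep(1L, L)
    } else {
      sw <- c(0L, as.integer(stats::runif(L - 1L) < p_switch))
      seg <- cumsum(sw) + 1L
      templ <- sample.int(nf, max(seg), replace = TRUE)
      path <- templ[seg]
    }
    hap <- founders[cbind(path, seq_len(L))]
    if (mut_rate > 0) {
      flip <- stats::runif(L) < mut_rate
      hap[flip] <- 1L - hap[flip]
    }
    out[i, ] <- hap
  }
  out
}

#' Simulate a base haplotype panel
#'
#' Builds founder templates whose site frequencies follow the neutral
#' 1/k spectrum, then draws the panel as recombinant founder mosaics with
#' new mutations. Sites monomorphic in the realised panel are dropped.
#'
#' @param config a [sim_config()].
#' @return a [haplotype_panel()]; deterministic given `config$seed`.
#' @export
simulate_founders <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed, {
    L <- config$n_sites
    positions <- sort(sample.int(config$chrom_length_bp, L))
    nf <- config$n_founders
    founders <- matrix(0L, nrow = nf, ncol = L)
    if (nf > 1L) {
      kmax <- nf - 1L
      k <- sample.int(kmax, L, replace = TRUE, prob = 1 / seq_len(kmax))
      for (j in seq_len(L)) {
        founders[sample.int(nf, k[j]), j] <- 1L
      }
    }
    hap <- mosaic_copy(founders, positions, config$n_haplotypes_base,
                       config$recombination_switch_rate_per_bp,
                       config$mutation_rate_per_copy)
    cs <- colSums(hap)
    poly <- cs > 0L & cs < nrow(hap)
    if (config$n_founders == 1L && config$mutation_rate_per_copy == 0) {
      poly <- rep(TRUE, L)  # degenerate single-founder panel kept intact
    }
    alle <- replicate(sum(poly), sample(c("A", "C", "G", "T"), 2L))
    haplotype_panel(
      haplotypes = hap[, poly, drop = FALSE],
      positions = positions[poly],
      ref = alle[1L, ], alt = alle[2L, ],
      sample_ids = sprintf("%s_s%03d", "BASE", seq_len(config$n_haplotypes_base / 2L)),
      population_id = "BASE", chrom = "1",
      mut_rate = config$mutation_rate_per_copy,
      recomb_rate = config$recombination_switch_rate_per_bp
    )
  })
}

#' Derive an isolate panel through a founder bottleneck
#'
#' Samples `n_bottleneck_founders` haplotypes from the base without
#' replacement, then copies `n_out` haplotypes as mosaics of the founders.
#' `n_generations` scales the mutation and recombination opportunity; with
#' zero generations the output is a resampling of the founders themselves.
#' The isolate keeps the base panel's site list so cohorts stay key-aligned.
#'
#' Recombination inside the isolate uses `recomb_per_generation_bp`, a
#' per-meiosis rate, not the base panel's mosaic rate: the base mosaic
#' compresses many generations of ancestral recombination into one copying
#' pass, whereas isolate haplotypes are separated from their founders by
#' only `n_generations` meioses. Keeping the per-meiosis rate low is what
#' gives isolates their hallmark long identical-by-descent tracts (and
#' hence runs of homozygosity).
#'
#' @param base a [haplotype_panel()].
#' @param n_bottleneck_founders bottleneck size (haplotypes).
#' @param n_generations non-negative integer.
#' @param n_out haplotypes to emit (even).
#' @param seed RNG seed.
#' @param population_id label for the derived panel.
#' @param recomb_per_generation_bp per-bp, per-generation template switch
#'   rate within the isolate (human-scale default 1e-8).
#' @return a [haplotype_panel()].
#' @export
derive_isolate <- function(base, n_bottleneck_founders, n_generations,
                           n_out = nrow(base$haplotypes), seed = 1L,
                           population_id = "ISO",
                           recomb_per_generation_bp = 1e-8) {
  stopifnot(inherits(base, "haplotype_panel"))
  nb <- nrow(base$haplotypes)
  if (n_bottleneck_founders > nb) {
    stop_config("bottleneck (%d) larger than base panel (%d)",
                n_bottleneck_founders, nb)
  }
  if (n_out %% 2 != 0) stop_config("n_out must be even")
  withr::with_seed(seed, {
    founders <- base$haplotypes[sample.int(nb, n_bottleneck_founders), ,
                                drop = FALSE]
    if (n_generations == 0L) {
      rows <- if (n_out <= n_bottleneck_founders) {
        sample.int(n_bottleneck_founders, n_out)
      } else {
        sample.int(n_bottleneck_founders, n_out, replace = TRUE)
      }
      hap <- founders[rows, , drop = FALSE]
    } else {
      hap <- mosaic_copy(founders, base$positions, n_out,
                         recomb_per_generation_bp * n_generations,
                         min(1, base$mut_rate * n_generations))
    }
    haplotype_panel(
      haplotypes = hap, positions = base$positions,
      ref = base$ref, alt = base$alt,
      sample_ids = sprintf("%s_s%03d", population_id, seq_len(n_out / 2L)),
      population_id = population_id, chrom = base$chrom,
      mut_rate = base$mut_rate, recomb_rate = base$recomb_rate
    )
  })
}

#' Plant a selective sweep into a panel
#'
#' Marks the site nearest `focal_pos` as the sweep locus: a chosen carrier
#' set receives the derived allele there and has its flanking region
#' (`focal_pos +/- flank_bp`) replaced by one shared carrier haplotype,
#' with a few private mutations injected. Non-carriers are untouched, so
#' the derived-allele haplotype homozygosity is artificially extended --
#' the truth signal an iHS scan should recover.
#'
#' @param panel a [haplotype_panel()].
#' @param focal_pos target position (bp); must fall within the panel range.
#' @param carrier_fraction fraction of haplotypes carrying the sweep, in (0,1).
#' @param flank_bp half-width of the homogenised region.
#' @param seed RNG seed.
#' @param private_mut_rate per-site flip probability applied to each
#'   carrier's homogenised flank.
#' @return the modified panel; the focal site index is attached as
#'   attribute `focal_index`.
#' @export
plant_sweep <- function(panel, focal_pos, carrier_fraction, flank_bp,
                        seed = 1L, private_mut_rate = 2e-4) {
  stopifnot(inherits(panel, "haplotype_panel"))
  check_fraction(carrier_fraction, "carrier_fraction", open = TRUE)
  pos <- panel$positions
  if (focal_pos < min(pos) || focal_pos > max(pos)) {
    stop_config("focal position %s outside panel coordinates [%s, %s]",
                focal_pos, min(pos), max(pos))
  }
  focal <- which.min(abs(pos - focal_pos))
  withr::with_seed(seed, {
    h <- panel$haplotypes
    n <- nrow(h)
    carriers <- sample.int(n, ceiling(carrier_fraction * n))
    flank_cols <- which(pos >= pos[focal] - flank_bp & pos <= pos[focal] + flank_bp)
    flank_cols <- setdiff(flank_cols, focal)
    if (length(flank_cols)) {
      template <- h[carriers[1L], flank_cols]
      for (i in carriers) {
        row <- template
        flip <- stats::runif(length(row)) < private_mut_rate
        row[flip] <- 1L - row[flip]
        h[i, flank_cols] <- row
      }
    }
    h[, focal] <- 0L
    h[carriers, focal] <- 1L
    out <- panel
    out$haplotypes <- h
    attr(out, "focal_index") <- focal
    out
  })
}

#' Tile a chromosome into gene intervals
#'
#' @param chrom_length_bp chromosome length.
#' @param genes_per_chrom number of equal-width gene intervals.
#' @param chrom chromosome label.
#' @return data frame (gene, chrom, start, end), 1-based inclusive.
#' @export
gene_map <- function(chrom_length_bp, genes_per_chrom, chrom = "1") {
  width <- ceiling(chrom_length_bp / genes_per_chrom)
  start <- (seq_len(genes_per_chrom) - 1L) * width + 1
  data.frame(
    gene = sprintf("GENE%04d", seq_len(genes_per_chrom)),
    chrom = chrom, start = start,
    end = pmin(start + width - 1, chrom_length_bp),
    stringsAsFactors = FALSE
  )
}

#' Annotate panel sites with genes, consequences and CADD-like scores
#'
#' Emulates the per-variant annotation a functional-effect predictor would
#' supply. Genes tile the chromosome; each site draws one consequence term
#' (a high-impact loss-of-function term with probability `p_high_impact`)
#' and a phred-like deleteriousness score from a two-component mixture (a
#' low-score bulk plus a heavy right tail) so that all standard score bins
#' are populated. Scores are synthetic stand-ins, never real CADD values.
#'
#' @param panel a [haplotype_panel()].
#' @param spec list as produced inside [sim_config()]; see
#'   `annotation_spec` there.
#' @param seed RNG seed.
#' @param chrom_length_bp chromosome length used for gene tiling.
#' @return data frame (chrom, pos, ref, alt, gene, n_transcripts,
#'   affected_transcripts, consequence, cadd_phred).
#' @export
annotate_sites <- function(panel, spec = list(), seed = 1L,
                           chrom_length_bp = max(panel$positions)) {
  spec <- do.call(annotation_spec_defaults, spec)
  withr::with_seed(seed, {
    L <- length(panel$positions)
    genes <- gene_map(chrom_length_bp, spec$genes_per_chrom, panel$chrom)
    gene_idx <- pmin(findInterval(panel$positions, genes$start), nrow(genes))
    n_tx_gene <- 1L + stats::rpois(nrow(genes),
                                   max(spec$transcripts_per_gene - 1, 0))
    n_tx <- n_tx_gene[gene_idx]
    affected <- vapply(n_tx, function(k) sample.int(k, 1L), integer(1))
    high <- stats::runif(L) < spec$p_high_impact
    consequence <- character(L)
    consequence[high] <- sample(hko_high_impact_terms(), sum(high), replace = TRUE)
    consequence[!high] <- sample(spec$low_terms, sum(!high), replace = TRUE,
                                 prob = spec$low_term_probs)
    tail <- stats::runif(L) < spec$cadd_tail_prob
    cadd <- numeric(L)
    cadd[!tail] <- stats::rgamma(sum(!tail), shape = 2, scale = 2)
    cadd[tail] <- 15 + stats::rgamma(sum(tail), shape = 2, scale = 4)
    data.frame(
      chrom = panel$chrom, pos = panel$positions,
      ref = panel$ref, alt = panel$alt,
      gene = genes$gene[gene_idx], n_transcripts = n_tx,
      affected_transcripts = affected, consequence = consequence,
      cadd_phred = cadd, stringsAsFactors = FALSE
    )
  })
}

#' Corrupt true genotypes into imputation-style posteriors
#'
#' With MAF-dependent error rate eps, each genotype is replaced with
#' probability eps by a draw from the site's Hardy-Weinberg distribution;
#' the posterior then puts mass `1 - eps/2` on the (possibly corrupted)
#' call and spreads `eps/2` over genotypes in Hardy-Weinberg proportion.
#' With zero noise the posterior is degenerate at the truth. Missing
#' genotypes receive the plain Hardy-Weinberg prior.
#'
#' @param geno sites x samples dosage matrix (0/1/2/NA).
#' @param noise list(`e_min`, `e_max`, `maf_decay`); see [sim_config()].
#' @param seed RNG seed.
#' @return a `posterior_genotypes` object: matrices `p0`, `p1`, `p2`
#'   (sites x samples) with rows summing to one per entry.
#' @export
corrupt_to_posteriors <- function(geno, noise = list(e_min = 0.01, e_max = 0.2,
                                                     maf_decay = 0.05),
                                  seed = 1L) {
  if (noise$e_min < 0 || noise$e_max < 0) stop_config("noise rates must be >= 0")
  geno <- as.matrix(geno)
  withr::with_seed(seed, {
    L <- nrow(geno); N <- ncol(geno)
    af <- rowMeans(geno, na.rm = TRUE) / 2
    af[is.nan(af)] <- 0
    eps <- noise$e_min + (noise$e_max - noise$e_min) *
      exp(-maf_of(af) / noise$maf_decay)
    hwe <- cbind((1 - af)^2, 2 * af * (1 - af), af^2)
    hwe[hwe == 0] <- 1e-12
    hwe <- hwe / rowSums(hwe)
    p0 <- p1 <- p2 <- matrix(0, L, N)
    for (j in seq_len(N)) {
      g <- geno[, j]
      corrupt <- stats::runif(L) < eps
      called <- g
      resample <- corrupt & !is.na(g)
      if (any(resample)) {
        u <- stats::runif(sum(resample))
        cum <- t(apply(hwe[resample, , drop = FALSE], 1, cumsum))
        called[resample] <- (u > cum[, 1]) + (u > cum[, 2])
      }
      w <- ifelse(is.na(g), 1, eps / 2)
      pj <- hwe * w
      idx <- which(!is.na(called))
      pj[cbind(idx, called[idx] + 1L)] <-
        pj[cbind(idx, called[idx] + 1L)] + (1 - w[idx])
      pj <- pj / rowSums(pj)
      p0[, j] <- pj[, 1]; p1[, j] <- pj[, 2]; p2[, j] <- pj[, 3]
    }
    structure(list(p0 = p0, p1 = p1, p2 = p2), class = "posterior_genotypes")
  })
}

#' Expected alternative-allele dosage from posteriors
#' @param post a `posterior_genotypes` object.
#' @return sites x samples matrix `p1 + 2 * p2`.
#' @export
posterior_dosage <- function(post) post$p1 + 2 * post$p2

#' Generate a complete synthetic cohort bundle on disk
#'
#' Simulates the base population, derives one isolate per entry of
#' `bottleneck_founders`, optionally plants a sweep, and writes per
#' population a phased VCF, an annotation table and a posterior table,
#' plus one external-resource site list (a random subset of the union
#' sites, standing in for public-panel membership), a gene-to-RVIS table,
#' and a JSON manifest recording seeds and paths.
#'
#' @param config a [sim_config()].
#' @param out_dir output directory (created if needed).
#' @return the manifest, invisibly.
#' @export
generate_cohort_set <- function(config, out_dir) {
  stopifnot(inherits(config, "sim_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop_config("cannot create output directory %s", out_dir)
  base <- simulate_founders(config)
  pops <- names(config$bottleneck_founders)
  panels <- list()
  for (i in seq_along(pops)) {
    panels[[pops[i]]] <- derive_isolate(
      base, config$bottleneck_founders[[i]], config$n_isolate_generations,
      n_out = config$n_haplotypes_base, seed = config$seed + i,
      population_id = pops[i]
    )
  }
  if (!is.null(config$sweep_spec)) {
    sp <- config$sweep_spec
    target <- sp$population %||% pops[1L]
    panels[[target]] <- plant_sweep(panels[[target]], sp$focal_pos,
                                    sp$carrier_fraction, sp$flank_bp,
                                    seed = config$seed + 1000L)
  }
  manifest <- list(seed = config$seed, populations = pops, files = list())
  for (i in seq_along(pops)) {
    pop <- pops[i]
    ds <- panel_to_dataset(panels[[pop]])
    withr::with_seed(config$seed + 100L + i, {
      ds$dp <- matrix(stats::rpois(length(ds$geno), config$dp_mean),
                      nrow = nrow(ds$geno))
      if (config$missing_rate > 0) {
        drop <- matrix(stats::runif(length(ds$geno)) < config$missing_rate,
                       nrow = nrow(ds$geno))
        ds$geno[drop] <- NA_integer_
        ds$haplotypes <- NULL  # phase no longer complete
      }
    })
    vcf_path <- file.path(out_dir, paste0(pop, ".vcf"))
    write_vcf(ds, vcf_path)
    ann <- annotate_sites(panels[[pop]], config$annotation_spec,
                          seed = config$seed + 200L,
                          chrom_length_bp = config$chrom_length_bp)
    ann_path <- file.path(out_dir, paste0(pop, "_annotation.tsv"))
    data.table::fwrite(ann, ann_path, sep = "\t")
    post <- corrupt_to_posteriors(ds$geno, config$posterior_noise,
                                  seed = config$seed + 300L + i)
    post_path <- file.path(out_dir, paste0(pop, "_posteriors.tsv"))
    write_posteriors(post, ds$keys, ds$sample_ids, post_path)
    manifest$files[[pop]] <- list(vcf = vcf_path, annotation = ann_path,
                                  posteriors = post_path)
  }
  union_keys <- data.frame(chrom = base$chrom, pos = base$positions,
                           ref = base$ref, alt = base$alt,
                           stringsAsFactors = FALSE)
  withr::with_seed(config$seed + 400L, {
    ext <- union_keys[sort(sample.int(nrow(union_keys),
                                      ceiling(nrow(union_keys) / 2))), ]
    genes <- gene_map(config$chrom_length_bp,
                      config$annotation_spec$genes_per_chrom, base$chrom)
    rvis <- data.frame(gene = genes$gene,
                       rvis = round(stats::rnorm(nrow(genes)), 4))
  })
  ext_path <- file.path(out_dir, "external_sites.tsv")
  data.table::fwrite(ext, ext_path, sep = "\t")
  rvis_path <- file.path(out_dir, "rvis.tsv")
  data.table::fwrite(rvis, rvis_path, sep = "\t")
  manifest$files$external_sites <- ext_path
  manifest$files$rvis <- rvis_path
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, pretty = TRUE)
  manifest$path <- manifest_path
  invisible(manifest)
}
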