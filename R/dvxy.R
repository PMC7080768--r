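# Drifted deleterious-variant enrichment: AC-class x deleteriousness-bin
# partition, drifted-variant sets against a reference population, the
# directional DVxy count ratio with bootstrap uncertainty, and the
# private/shared DV ratio.

ac_class_levels <- function() c("1-2", "3-5", "5-10", ">10")
cadd_bin_levels <- function() c("0-5", "5-15", "15-20", ">20")

#' Bin variants by allele-count class and deleteriousness score
#'
#' AC classes are 1-2, 3-5, 5-10 and >10, read as the disjoint intervals
#' `1..2`, `3..5`, `6..10`, `11..`; phred-score bins are `[0,5)`,
#' `[5,15)`, `[15,20)`, `[20,Inf)`. Every annotated polymorphic
#' biallelic variant maps to exactly one cell; AC = 0 sites get NA class.
#'
#' @param stats site-stats data frame from [compute_site_stats()].
#' @param annotations annotation data frame with `cadd_phred`, keyed by
#'   (chrom, pos, ref, alt).
#' @return `stats` with factor columns `ac_class` and `cadd_bin`.
#' @export
bin_variants <- function(stats, annotations) {
  ann_key <- variant_key(annotations)
  cadd <- annotations$cadd_phred[match(stats$key, ann_key)]
  if (any(cadd < 0, na.rm = TRUE)) stop_config("negative deleteriousness score")
  stats$ac_class <- factor(ac_class_of(stats$AC), levels = ac_class_levels())
  stats$cadd_bin <- factor(cadd_bin_of(cadd), levels = cadd_bin_levels())
  stats
}

ac_class_of <- function(ac) {
  out <- rep(NA_character_, length(ac))
  out[ac >= 1 & ac <= 2] <- "1-2"
  out[ac >= 3 & ac <= 5] <- "3-5"
  out[ac > 5 & ac <= 10] <- "5-10"
  out[ac > 10] <- ">10"
  out
}

cadd_bin_of <- function(cadd) {
  out <- rep(NA_character_, length(cadd))
  out[cadd >= 0 & cadd < 5] <- "0-5"
  out[cadd >= 5 & cadd < 15] <- "5-15"
  out[cadd >= 15 & cadd < 20] <- "15-20"
  out[cadd >= 20] <- ">20"
  out
}

#' Drifted variants of one population against a reference
#'
#' A variant is drifted in X relative to Y when its allele count in X
#' falls in `ac_class` while it is rare in Y: AF_Y below
#' `rare_af_threshold` (a variant absent from Y counts as AF_Y = 0).
#'
#' @param x_stats,y_stats site-stats data frames (X = study population,
#'   Y = reference).
#' @param ac_class one of `"1-2"`, `"3-5"`, `"5-10"`, `">10"`.
#' @param rare_af_threshold reference-frequency cutoff (default 0.5%).
#' @return character vector of drifted variant keys.
#' @export
drifted_variants <- function(x_stats, y_stats, ac_class = "3-5",
                             rare_af_threshold = 0.005) {
  ac_class <- match.arg(ac_class, ac_class_levels())
  af_y <- y_stats$AF[match(x_stats$key, y_stats$key)]
  af_y[is.na(af_y)] <- 0
  in_class <- !is.na(ac_class_of(x_stats$AC)) &
    ac_class_of(x_stats$AC) == ac_class
  x_stats$key[in_class & af_y < rare_af_threshold]
}

#' DVxy: directional drifted-variant enrichment
#'
#' Counts variants drifted in X relative to Y and vice versa, restricted
#' to one allele-count class and one deleteriousness bin, and reports
#' their ratio dvxy = D_x / D_y. The bootstrap SD resamples the combined
#' drifted-variant list with replacement `n_boot` times and recomputes
#' the ratio. The enrichment call follows the dvxy - sd > 1 decision
#' rule: X carries an excess only when the ratio exceeds one by more
#' than one bootstrap SD.
#'
#' @param x_stats,y_stats site-stats data frames.
#' @param annotations shared annotation table (for the score bin).
#' @param ac_class,cadd_bin cell to analyse.
#' @param rare_af_threshold drift rarity cutoff in the opposite population.
#' @param n_boot bootstrap resamples.
#' @param seed RNG seed for the bootstrap.
#' @return one-row data frame (ac_class, cadd_bin, d_x, d_y, dvxy, sd,
#'   n_boot, enriched); `dvxy` is NA-flagged when D_y = 0.
#' @export
dvxy <- function(x_stats, y_stats, annotations, ac_class = "3-5",
                 cadd_bin = ">20", rare_af_threshold = 0.005,
                 n_boot = 1000L, seed = 1L) {
  cadd_bin <- match.arg(cadd_bin, cadd_bin_levels())
  ann_key <- variant_key(annotations)
  bin_of <- function(keys) {
    cadd_bin_of(annotations$cadd_phred[match(keys, ann_key)])
  }
  dx_keys <- drifted_variants(x_stats, y_stats, ac_class, rare_af_threshold)
  dy_keys <- drifted_variants(y_stats, x_stats, ac_class, rare_af_threshold)
  dx_keys <- dx_keys[!is.na(bin_of(dx_keys)) & bin_of(dx_keys) == cadd_bin]
  dy_keys <- dy_keys[!is.na(bin_of(dy_keys)) & bin_of(dy_keys) == cadd_bin]
  d_x <- length(dx_keys); d_y <- length(dy_keys)
  est <- if (d_y > 0L) d_x / d_y else NA_real_
  sd_boot <- NA_real_
  if (d_x + d_y > 0L) {
    lab <- c(rep(1L, d_x), rep(0L, d_y))
    ratios <- withr::with_seed(seed, vapply(seq_len(n_boot), function(b) {
      rs <- lab[sample.int(length(lab), replace = TRUE)]
      nx <- sum(rs); ny <- length(rs) - nx
      if (ny == 0L) NA_real_ else nx / ny
    }, numeric(1)))
    sd_boot <- stats::sd(ratios[is.finite(ratios)])
  }
  data.frame(ac_class = ac_class, cadd_bin = cadd_bin, d_x = d_x, d_y = d_y,
             dvxy = est, sd = sd_boot, n_boot = n_boot,
             enriched = !is.na(est) && !is.na(sd_boot) && est - sd_boot > 1,
             stringsAsFactors = FALSE)
}

#' Private/shared drifted-variant ratio
#'
#' Given the drifted-variant key sets of two populations (each computed
#' against the same reference), returns
#' |drifted in X only| / |drifted in both|. Highly positive values mean
#' the drifted burden is population-specific.
#'
#' @param drifted_x,drifted_y key vectors from [drifted_variants()].
#' @return list (n_only_x, n_both, ratio); ratio is `Inf` when the shared
#'   set is empty but the private one is not, and NA when both are empty.
#' @export
dv_ratio <- function(drifted_x, drifted_y) {
  both <- intersect(drifted_x, drifted_y)
  only_x <- setdiff(drifted_x, drifted_y)
  ratio <- if (length(both) > 0L) length(only_x) / length(both)
           else if (length(only_x) > 0L) Inf else NA_real_
  list(n_only_x = length(only_x), n_both = length(both), ratio = ratio)
}
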