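# Shared helpers: argument checking and variant-key strings.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_config <- function(...) stop(sprintf(...), call. = FALSE)

check_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) < 1L || any(!is.finite(x)) || any(x <= 0)) {
    stop_config("`%s` must be positive and finite", name)
  }
  invisible(x)
}

check_fraction <- function(x, name, open = FALSE) {
  ok <- is.numeric(x) && all(is.finite(x)) &&
    (if (open) all(x > 0 & x < 1) else all(x >= 0 & x <= 1))
  if (!ok) stop_config("`%s` must lie in %s", name, if (open) "(0, 1)" else "[0, 1]")
  invisible(x)
}

#' Build exact-match variant keys
#'
#' A variant is identified by chromosome, 1-based position, reference and
#' alternative allele; two records match only when all four fields agree.
#'
#' @param chrom,pos,ref,alt vectors of equal length (or a data frame with
#'   those columns passed as `chrom`).
#' @return character vector of `chrom:pos:ref:alt` keys.
#' @export
variant_key <- function(chrom, pos = NULL, ref = NULL, alt = NULL) {
  if (is.data.frame(chrom)) {
    df <- chrom
    return(paste(df$chrom, df$pos, df$ref, df$alt, sep = ":"))
  }
  paste(chrom, pos, ref, alt, sep = ":")
}

# minor allele frequency from an alternative-allele frequency
maf_of <- function(af) pmin(af, 1 - af)

# cut MAF values into labelled bins; bins are (lo, hi] with the first
# bin closed at 0 so monomorphic sites fall in the rarest class.
maf_bin_labels <- function(edges) {
  paste0("(", format(edges[-length(edges)], trim = TRUE), ",",
         format(edges[-1L], trim = TRUE), "]")
}

assign_maf_bin <- function(maf, edges) {
  if (any(diff(edges) <= 0)) stop_config("maf bin edges must be strictly increasing")
  cut(maf, breaks = edges, labels = maf_bin_labels(edges), include.lowest = TRUE)
}

#' Default minor-allele-frequency bins
#'
#' Edges 0, 0.5%, 1%, 5%, 50%: the rare bin (MAF <= 0.5%) is kept separate
#' because imputation quality is reported for it specifically.
#' @return numeric vector of bin edges.
#' @export
default_maf_bins <- function() c(0, 0.005, 0.01, 0.05, 0.5)
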