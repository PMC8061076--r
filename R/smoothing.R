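# Coverage-weighted local-polynomial smoothing of methylation fractions,
# in the BSmooth family: tricube kernel over a window constrained by both a
# minimum width and a minimum locus count, weights proportional to coverage.

#' Smoothing configuration
#'
#' A window at a locus is the smallest symmetric extension satisfying both
#' `width >= min_width_bp` and `locus count >= min_loci`.
#'
#' @param min_width_bp minimum window width in bp (>= 1).
#' @param min_loci minimum number of loci in a window (must be at least
#'   `degree + 2`).
#' @param kernel kernel name; only `"tricube"` is implemented.
#' @param degree local polynomial degree (default 2, the BSmooth choice).
#' @return Object of class `SmoothingConfig`.
#' @export
smoothing_config <- function(min_width_bp, min_loci, kernel = "tricube",
                             degree = 2L) {
  stopifnot(min_width_bp >= 1, kernel == "tricube",
            min_loci >= degree + 2)
  structure(list(min_width_bp = as.numeric(min_width_bp),
                 min_loci = as.integer(min_loci),
                 kernel = kernel, degree = as.integer(degree)),
            class = "SmoothingConfig")
}

#' Named smoothing presets
#'
#' `cg_small`: windows of at least 1 kb containing at least 70 CpGs, for
#' ordinary CG-DMRs. `cg_block`: at least 20 kb and 500 CpGs, for large
#' blocks of differential methylation. `ch`: at least 3 kb and 200 CpAs or
#' CpTs, for the strand-specific non-CpG analysis.
#'
#' @param name `"cg_small"`, `"cg_block"`, or `"ch"`.
#' @return A [smoothing_config()].
#' @export
smoothing_preset <- function(name = c("cg_small", "cg_block", "ch")) {
  name <- match.arg(name)
  cfg <- switch(name,
                cg_small = smoothing_config(1000, 70),
                cg_block = smoothing_config(20000, 500),
                ch = smoothing_config(3000, 200))
  cfg$preset <- name
  cfg
}

#' Smooth methylation fractions
#'
#' Fits, per sample and locus, a local weighted polynomial of raw fractions
#' `M/Cov` against position over the window given by `cfg`, with tricube
#' distance weights multiplied by read coverage (zero-coverage loci carry no
#' weight but still receive the neighborhood fit). Fitted values are clamped
#' to `[0, 1]`. A window holding no covered locus for a sample yields `NA`
#' there. Chromosomes with fewer than `min_loci` loci are smoothed with the
#' whole-chromosome window.
#'
#' @param d a `MethDataset`.
#' @param cfg a `SmoothingConfig` or preset name.
#' @return Object of class `SmoothedDataset`: the loci of `d`, a
#'   `beta` matrix (loci x samples) of smoothed fractions, the
#'   configuration, and a fingerprint of the source counts.
#' @export
smooth_methylation <- function(d, cfg = smoothing_preset("cg_small")) {
  stopifnot(inherits(d, "MethDataset"))
  if (is.character(cfg)) cfg <- smoothing_preset(cfg)
  stopifnot(inherits(cfg, "SmoothingConfig"))
  beta <- matrix(NA_real_, length(d$pos), ncol(d$M),
                 dimnames = list(NULL, colnames(d$M)))
  for (ch in unique(d$chrom)) {
    idx <- which(d$chrom == ch)
    beta[idx, ] <- smooth_chr_cpp(as.numeric(d$pos[idx]),
                                  d$M[idx, , drop = FALSE],
                                  d$Cov[idx, , drop = FALSE],
                                  cfg$min_width_bp, cfg$min_loci, cfg$degree)
  }
  structure(list(chrom = d$chrom, pos = d$pos, strand = d$strand,
                 context = d$context, beta = beta, config = cfg,
                 samples = d$samples,
                 fingerprint = c(n_loci = length(d$pos), n_samples = ncol(d$M),
                                 sum_M = sum(as.numeric(d$M)),
                                 sum_Cov = sum(as.numeric(d$Cov)))),
            class = "SmoothedDataset")
}

#' @export
print.SmoothedDataset <- function(x, ...) {
  cat(sprintf(
    "SmoothedDataset: %d loci x %d samples | window >= %g bp, >= %d loci, degree %d\n",
    length(x$pos), ncol(x$beta), x$config$min_width_bp, x$config$min_loci,
    x$config$degree))
  invisible(x)
}
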