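# Variably methylated regions: within-tissue across-sample standard
# deviation of smoothed methylation, a single SD cutoff taken as the minimum
# over per-tissue 99th percentiles, run segmentation, CpG-count and
# Cook's-distance filtering, effect sizes, and cross-tissue sharing classes.

#' Coverage-based locus filter
#'
#' A locus is kept when strictly more than `min_samples` samples have
#' coverage strictly greater than `min_cov` (both inequalities strict,
#' mirroring the "> 5 reads in > 100 samples" style of rule). The default
#' `min_samples` scales with the design as `floor(0.55 * n_samples)`.
#'
#' @param d a `MethDataset` (raw counts).
#' @param min_cov coverage threshold (kept loci need `Cov > min_cov`).
#' @param min_samples sample-count threshold (strictly exceeded).
#' @return Logical mask over loci.
#' @export
coverage_filter <- function(d, min_cov = 5L,
                            min_samples = floor(0.55 * ncol(d$Cov))) {
  stopifnot(inherits(d, "MethDataset"), min_cov >= 0,
            min_samples <= ncol(d$Cov))
  rowSums(d$Cov > min_cov) > min_samples
}

#' Per-locus standard deviation within one tissue
#'
#' Sample standard deviation (n-1 denominator) of smoothed methylation
#' across the tissue's samples at each locus; missing values are excluded
#' locus-wise and loci with fewer than two non-missing samples get `NA`.
#'
#' @param s a `SmoothedDataset` with a sample table.
#' @param tissue tissue name (needs >= 3 samples).
#' @param samples optional `SampleTable` overriding `s$samples`.
#' @return Numeric vector of per-locus SDs.
#' @export
per_tissue_sd <- function(s, tissue, samples = s$samples) {
  stopifnot(inherits(s, "SmoothedDataset"), !is.null(samples))
  cols <- which(samples$tissue == tissue)
  if (length(cols) < 3) stop("tissue '", tissue, "' has < 3 samples")
  x <- s$beta[, cols, drop = FALSE]
  if (!anyNA(x)) {
    n <- ncol(x)
    m <- rowMeans(x)
    v <- (rowSums(x^2) - n * m^2) / (n - 1)
    return(sqrt(pmax(v, 0)))
  }
  apply(x, 1, function(y) {
    y <- y[!is.na(y)]
    if (length(y) < 2) NA_real_ else stats::sd(y)
  })
}

#' Single SD cutoff from per-tissue quantiles
#'
#' The cutoff is the minimum over tissues of the `q`-th quantile (type-7
#' linear interpolation) of that tissue's per-locus SD distribution. Using
#' one shared cutoff lets different tissues yield different numbers of VMRs
#' rather than taking a fixed top fraction per tissue.
#'
#' @param per_tissue_sds named list `tissue -> numeric SD vector`.
#' @param q quantile (default 0.99).
#' @return The cutoff (scalar).
#' @export
select_cutoff <- function(per_tissue_sds, q = 0.99) {
  stopifnot(length(per_tissue_sds) >= 1)
  qs <- vapply(per_tissue_sds, function(v) {
    v <- v[!is.na(v)]
    if (!length(v)) stop("empty SD vector")
    stats::quantile(v, q, names = FALSE, type = 7)
  }, numeric(1))
  min(qs)
}

#' Call variably methylated regions from a per-locus SD track
#'
#' Maximal runs of loci with `SD > cutoff` (strict), split at inter-locus
#' gaps larger than `max_gap_bp`; runs with fewer than `min_cpgs` loci are
#' dropped (the default keeps regions with more than 10 CpGs). Loci with
#' missing SD (e.g. removed by [coverage_filter()]) never qualify.
#'
#' @param sd_vec per-locus SD (NA allowed).
#' @param s the `SmoothedDataset` carrying locus coordinates.
#' @param cutoff positive SD cutoff (see [select_cutoff()]).
#' @param max_gap_bp maximum within-region gap (default 300 bp).
#' @param min_cpgs minimum loci per VMR (default 11, i.e. > 10 CpGs).
#' @return data.frame of pre-filter VMRs: `chrom`, `start`, `end`,
#'   `n_cpgs`, `max_sd`, `mean_sd`, `idx_start`, `idx_end`.
#' @export
call_vmrs <- function(sd_vec, s, cutoff, max_gap_bp = 300, min_cpgs = 11L) {
  stopifnot(inherits(s, "SmoothedDataset"), cutoff > 0,
            length(sd_vec) == length(s$pos))
  runs <- .find_runs(sd_vec > cutoff, s$chrom, s$pos, max_gap_bp, min_cpgs)
  n <- nrow(runs)
  out <- data.frame(chrom = character(n), start = integer(n), end = integer(n),
                    n_cpgs = integer(n), max_sd = numeric(n),
                    mean_sd = numeric(n), stringsAsFactors = FALSE)
  for (r in seq_len(n)) {
    sl <- runs$idx_start[r]:runs$idx_end[r]
    out$chrom[r] <- s$chrom[sl[1]]
    out$start[r] <- s$pos[sl[1]]
    out$end[r] <- s$pos[sl[length(sl)]]
    out$n_cpgs[r] <- length(sl)
    out$max_sd[r] <- max(sd_vec[sl])
    out$mean_sd[r] <- mean(sd_vec[sl])
  }
  out$idx_start <- runs$idx_start
  out$idx_end <- runs$idx_end
  out
}

#' Cook's-distance outlier filter for VMRs
#'
#' For each VMR, the per-sample region-mean methylation within the tissue is
#' fit by an intercept-only model (the tissue mean); Cook's distance of
#' sample i is `D_i = e_i^2 h / (p s^2 (1 - h)^2)` with leverage `h = 1/n`,
#' `p = 1` parameter, and `s^2` the residual mean square. A VMR whose
#' maximum Cook's distance exceeds `threshold` is removed as driven by a
#' sample outlier rather than population variability. Degenerate inputs:
#' all region means equal gives `D = 0` (retained); fewer than 3 samples is
#' rejected with a diagnostic.
#'
#' @param vmrs data.frame from [call_vmrs()].
#' @param s a `SmoothedDataset`.
#' @param tissue tissue whose samples are assessed.
#' @param samples optional `SampleTable` overriding `s$samples`.
#' @param threshold Cook's distance threshold (default 0.7).
#' @return `vmrs` with columns `cooks_max`, `retained`, and `diagnostic`.
#' @export
cooks_filter <- function(vmrs, s, tissue, samples = s$samples,
                         threshold = 0.7) {
  stopifnot(inherits(s, "SmoothedDataset"), !is.null(samples))
  cols <- which(samples$tissue == tissue)
  n <- nrow(vmrs)
  vmrs$cooks_max <- rep(NA_real_, n)
  vmrs$retained <- rep(FALSE, n)
  vmrs$diagnostic <- rep(NA_character_, n)
  if (length(cols) < 3) {
    vmrs$diagnostic <- rep("insufficient samples (< 3)", n)
    return(vmrs)
  }
  if (n == 0) return(vmrs)
  rmat <- region_methylation_matrix(vmrs, s)[, cols, drop = FALSE]
  for (r in seq_len(n)) {
    y <- rmat[r, ]
    y <- y[!is.na(y)]
    nn <- length(y)
    if (nn < 3) {
      vmrs$diagnostic[r] <- "insufficient samples (< 3)"
      next
    }
    e <- y - mean(y)
    s2 <- sum(e^2) / (nn - 1)
    if (s2 == 0) {
      vmrs$cooks_max[r] <- 0
      vmrs$retained[r] <- TRUE
      next
    }
    h <- 1 / nn
    D <- e^2 * h / (1 * s2 * (1 - h)^2)
    vmrs$cooks_max[r] <- max(D)
    vmrs$retained[r] <- max(D) <= threshold
    if (!vmrs$retained[r]) vmrs$diagnostic[r] <- "outlier-driven (Cook's D)"
  }
  vmrs
}

#' VMR effect size
#'
#' The range (max minus min) of the per-sample, across-region average
#' methylation within the tissue.
#'
#' @param vmrs data.frame of VMRs.
#' @param s a `SmoothedDataset`.
#' @param tissue tissue name.
#' @param samples optional `SampleTable` overriding `s$samples`.
#' @return `vmrs` with an `effect_size` column.
#' @export
effect_size <- function(vmrs, s, tissue, samples = s$samples) {
  cols <- which(samples$tissue == tissue)
  if (nrow(vmrs) == 0) {
    vmrs$effect_size <- numeric(0)
    return(vmrs)
  }
  rmat <- region_methylation_matrix(vmrs, s)[, cols, drop = FALSE]
  vmrs$effect_size <- apply(rmat, 1, function(y)
    diff(range(y, na.rm = TRUE)))
  vmrs
}

#' Full per-tissue VMR pipeline
#'
#' Coverage filter, per-tissue SD, shared cutoff from per-tissue quantiles,
#' run calling, Cook's-distance filtering and effect sizes for every tissue.
#'
#' @param d raw `MethDataset` (for the coverage filter).
#' @param s matching `SmoothedDataset`.
#' @param tissues tissues to analyze (default: all tissues having at least
#'   3 samples in the sample table).
#' @param samples optional `SampleTable` overriding `s$samples`.
#' @param min_cov,min_samples see [coverage_filter()].
#' @param q cutoff quantile (default 0.99).
#' @param max_gap_bp,min_cpgs see [call_vmrs()].
#' @param cooks_threshold see [cooks_filter()].
#' @return List: `vmrs` (named list tissue -> VMR data.frame with filter
#'   columns), `cutoff`, `mask`, `per_tissue_q` (the per-tissue quantiles).
#' @export
find_vmrs <- function(d, s, tissues = NULL, samples = s$samples,
                      min_cov = 5L, min_samples = floor(0.55 * ncol(d$Cov)),
                      q = 0.99, max_gap_bp = 300, min_cpgs = 11L,
                      cooks_threshold = 0.7) {
  stopifnot(!is.null(samples))
  if (is.null(tissues)) {
    tab <- table(samples$tissue)
    tissues <- names(tab)[tab >= 3]
  }
  mask <- coverage_filter(d, min_cov, min_samples)
  sds <- lapply(tissues, function(tt) {
    v <- per_tissue_sd(s, tt, samples)
    v[!mask] <- NA_real_
    v
  })
  names(sds) <- tissues
  per_q <- vapply(sds, function(v)
    stats::quantile(v, q, na.rm = TRUE, names = FALSE, type = 7), numeric(1))
  cutoff <- min(per_q)
  vmrs <- lapply(tissues, function(tt) {
    v <- call_vmrs(sds[[tt]], s, cutoff, max_gap_bp, min_cpgs)
    v <- cooks_filter(v, s, tt, samples, cooks_threshold)
    v <- effect_size(v, s, tt, samples)
    v$tissue <- rep(tt, nrow(v))
    v
  })
  names(vmrs) <- tissues
  list(vmrs = vmrs, cutoff = cutoff, mask = mask, per_tissue_q = per_q)
}

#' Classify cross-tissue sharing of VMRs
#'
#' All retained VMR intervals are union-merged across tissues (two intervals
#' belong to the same merged unit when they share at least one bp, closed
#' transitively). Each merged interval's member tissues are the tissues
#' contributing at least one overlapping VMR; the class is
#' `tissue_specific` (exactly one member), `ubiquitous` (every configured
#' tissue), else `shared`. The number of merged intervals is the number of
#' unique VMRs.
#'
#' @param per_tissue_vmrs named list `tissue -> data.frame` of retained VMRs
#'   (rows with `retained == FALSE` are dropped if the column is present).
#' @param all_tissues the configured tissue universe (default: names of
#'   `per_tissue_vmrs`).
#' @return data.frame of merged intervals: `chrom`, `start`, `end` (1-based
#'   inclusive), `n_tissues`, `tissues` (comma-joined), `class`; per-class
#'   counts in attribute `"counts"`.
#' @export
classify_sharing <- function(per_tissue_vmrs,
                             all_tissues = names(per_tissue_vmrs)) {
  dfs <- lapply(names(per_tissue_vmrs), function(tt) {
    v <- per_tissue_vmrs[[tt]]
    if (!is.null(v$retained)) v <- v[v$retained, , drop = FALSE]
    if (nrow(v) == 0) return(NULL)
    data.frame(chrom = v$chrom, start = v$start, end = v$end, tissue = tt,
               stringsAsFactors = FALSE)
  })
  dfs <- dfs[!vapply(dfs, is.null, logical(1))]
  if (!length(dfs)) {
    out <- data.frame(chrom = character(), start = integer(),
                      end = integer(), n_tissues = integer(),
                      tissues = character(), class = character())
    attr(out, "counts") <- c(tissue_specific = 0L, shared = 0L,
                             ubiquitous = 0L)
    return(out)
  }
  all_df <- do.call(rbind, dfs)
  gr <- .granges1(all_df$chrom, all_df$start, all_df$end)
  # min.gapwidth = 0: merge only on >= 1 shared bp, not mere adjacency
  merged <- GenomicRanges::reduce(gr, min.gapwidth = 0L)
  hits <- GenomicRanges::findOverlaps(merged, gr)
  member <- split(all_df$tissue[S4Vectors::subjectHits(hits)],
                  S4Vectors::queryHits(hits))
  tis <- lapply(member, function(x) sort(unique(x)))
  n_t <- lengths(tis)
  cls <- ifelse(n_t == 1L, "tissue_specific",
                ifelse(n_t == length(all_tissues), "ubiquitous", "shared"))
  out <- data.frame(chrom = as.character(GenomicRanges::seqnames(merged)),
                    start = GenomicRanges::start(merged),
                    end = GenomicRanges::end(merged),
                    n_tissues = as.integer(n_t),
                    tissues = vapply(tis, paste, character(1), collapse = ","),
                    class = cls, stringsAsFactors = FALSE)
  attr(out, "counts") <- c(
    tissue_specific = sum(cls == "tissue_specific"),
    shared = sum(cls == "shared"),
    ubiquitous = sum(cls == "ubiquitous"))
  out
}
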