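# CpX-resolution enrichment of region sets in genomic features: 2x2 counts
# of cytosines by region membership and feature membership, closed-form
# log2 odds ratio with standard error and +/- 2 SE confidence interval, and
# Fisher's exact test of independence.

#' Build the CpX 2x2 contingency table
#'
#' Every locus is classified by membership in the region set and in the
#' feature set (point-in-interval on the cytosine coordinate). Counting
#' cytosines rather than regions or bases accounts for their non-uniform
#' genomic distribution:
#' `n11` in-regions/in-feature, `n12` in-regions/out-feature,
#' `n21` out-regions/in-feature, `n22` out-regions/out-feature.
#'
#' @param loci data.frame with `chrom` and `pos` (1-based cytosine
#'   positions) restricted to the relevant context, or a `MethDataset` /
#'   `SmoothedDataset`.
#' @param regions a `RegionSet` or region data.frame (1-based inclusive).
#' @param feature a `FeatureSet` (0-based half-open).
#' @return Object of class `ContingencyTable`: named integer vector
#'   `n11`, `n12`, `n21`, `n22`.
#' @export
build_contingency <- function(loci, regions, feature) {
  if (inherits(loci, c("MethDataset", "SmoothedDataset")))
    loci <- data.frame(chrom = loci$chrom, pos = loci$pos)
  stopifnot(all(c("chrom", "pos") %in% names(loci)),
            inherits(feature, "FeatureSet"))
  pts <- .granges1(loci$chrom, loci$pos, loci$pos)
  rdf <- if (inherits(regions, "RegionSet")) regions$regions else regions
  in_reg <- if (nrow(rdf) == 0) rep(FALSE, length(pts)) else
    GenomicRanges::countOverlaps(pts, .granges1(rdf$chrom, rdf$start,
                                                rdf$end)) > 0
  fi <- feature$intervals
  in_feat <- if (nrow(fi) == 0) rep(FALSE, length(pts)) else
    GenomicRanges::countOverlaps(pts, .granges0(fi$chrom, fi$start,
                                                fi$end)) > 0
  structure(c(n11 = sum(in_reg & in_feat), n12 = sum(in_reg & !in_feat),
              n21 = sum(!in_reg & in_feat), n22 = sum(!in_reg & !in_feat)),
            class = "ContingencyTable")
}

#' Log2 odds ratio of a 2x2 table with SE and 95% CI
#'
#' Applies the closed forms
#' `log2(OR) = log2(n11) + log2(n22) - log2(n12) - log2(n21)` and
#' `se = sqrt(1/n11 + 1/n12 + 1/n21 + 1/n22)` (on the log2 scale), with the
#' approximate 95% interval `log2(OR) -/+ 2 se`. A table with any zero cell
#' is flagged undefined rather than patched; set `haldane = TRUE` to apply
#' the Haldane-Anscombe +0.5 correction explicitly instead.
#'
#' @param tab a `ContingencyTable` or numeric vector `(n11, n12, n21, n22)`.
#' @param haldane add 0.5 to every cell before the formulas (default FALSE).
#' @return List of class `EnrichmentResult`: `log2_or`, `se`, `ci95`
#'   (length-2), `undefined` flag, and the four cells.
#' @export
log2_odds_ratio <- function(tab, haldane = FALSE) {
  x <- as.numeric(tab)
  stopifnot(length(x) == 4, all(x >= 0))
  names(x) <- c("n11", "n12", "n21", "n22")
  undefined <- any(x == 0) && !haldane
  if (undefined) {
    res <- list(log2_or = NA_real_, se = NA_real_,
                ci95 = c(NA_real_, NA_real_), undefined = TRUE, cells = x)
  } else {
    y <- if (haldane) x + 0.5 else x
    lor <- log2(y["n11"]) + log2(y["n22"]) - log2(y["n12"]) - log2(y["n21"])
    # the reciprocal-cell SE is used verbatim with the log2 estimate
    # (the conventional delta-method SE is for ln OR; kept as published)
    se <- sqrt(sum(1 / y))
    res <- list(log2_or = unname(lor), se = unname(se),
                ci95 = unname(c(lor - 2 * se, lor + 2 * se)),
                undefined = FALSE, cells = x)
  }
  class(res) <- "EnrichmentResult"
  res
}

#' Fisher's exact test on a 2x2 table
#'
#' Two-sided exact p-value for the null of independence of rows and columns
#' (no enrichment or depletion), summing hypergeometric probabilities no
#' larger than the observed table's.
#'
#' @param tab a `ContingencyTable` or numeric vector `(n11, n12, n21, n22)`.
#' @return The p-value in (0, 1].
#' @export
fisher_exact <- function(tab) {
  x <- as.numeric(tab)
  stopifnot(length(x) == 4, all(x >= 0))
  stats::fisher.test(matrix(x, 2, 2, byrow = TRUE))$p.value
}

#' Batch enrichment of one region set over many feature sets
#'
#' One enrichment per feature set, with Benjamini-Hochberg adjustment of the
#' Fisher p-values across features and a significance flag at `sig_alpha`
#' (figure-style masking keeps only significant enrichments or depletions).
#' When `averaging_groups` maps feature names to group labels, the
#' arithmetic mean of the defined `log2_or` values within each group is also
#' reported (significance is never averaged).
#'
#' @param loci locus table (see [build_contingency()]).
#' @param regions a `RegionSet` or region data.frame.
#' @param features list of `FeatureSet` objects.
#' @param averaging_groups optional named character vector
#'   `feature name -> group label`.
#' @param sig_alpha significance level on the adjusted p (default 0.05).
#' @param p_adjust_method multiplicity correction (default `"BH"`).
#' @param haldane passed to [log2_odds_ratio()].
#' @return data.frame with one row per feature: cells, `log2_or`, `se`,
#'   `ci_lo`, `ci_hi`, `fisher_p`, `p_adj`, `significant`, `undefined`.
#'   When averaging is requested, attribute `"group_means"` holds a
#'   data.frame `group`, `mean_log2_or`, `n_features`.
#' @export
enrich_batch <- function(loci, regions, features, averaging_groups = NULL,
                         sig_alpha = 0.05, p_adjust_method = "BH",
                         haldane = FALSE) {
  stopifnot(length(features) >= 1)
  rows <- lapply(features, function(f) {
    ct <- build_contingency(loci, regions, f)
    er <- log2_odds_ratio(ct, haldane = haldane)
    data.frame(feature = f$name, n11 = ct[["n11"]], n12 = ct[["n12"]],
               n21 = ct[["n21"]], n22 = ct[["n22"]],
               log2_or = er$log2_or, se = er$se,
               ci_lo = er$ci95[1], ci_hi = er$ci95[2],
               fisher_p = fisher_exact(ct), undefined = er$undefined,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$p_adj <- stats::p.adjust(out$fisher_p, method = p_adjust_method)
  out$significant <- out$p_adj < sig_alpha & !out$undefined
  if (!is.null(averaging_groups)) {
    grp <- averaging_groups[out$feature]
    keep <- !is.na(grp) & !out$undefined
    gm <- tapply(out$log2_or[keep], grp[keep], mean)
    attr(out, "group_means") <- data.frame(
      group = names(gm), mean_log2_or = as.numeric(gm),
      n_features = as.integer(table(grp[keep])[names(gm)]),
      stringsAsFactors = FALSE)
  }
  out
}
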