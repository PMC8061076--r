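# DMR calling on smoothed methylation: per-locus one-way ANOVA F statistics
# (signed t for two groups), segmentation of above-cutoff runs into candidate
# regions scored by areaStat/maxStat, permutation-based family-wise error
# control on the maximum |areaStat|, pairwise group annotation, and selection
# of group-discriminatory regions.

#' Per-locus F statistics across sample groups
#'
#' One-way ANOVA on smoothed methylation values at every locus:
#' `F = [SSB/(k-1)] / [SSW/(n-k)]`. With exactly two groups the signed
#' pooled-variance t statistic is also returned (`F = t^2`). Missing smoothed
#' values are excluded locus-wise; a locus where any group retains fewer than
#' two non-missing samples gets a missing statistic. Degenerate loci follow
#' the convention `SSW = 0, SSB = 0 -> F = 0` and `SSW = 0, SSB > 0 ->
#' F = Inf` (capped later, at segmentation).
#'
#' @param s a `SmoothedDataset`.
#' @param group factor (or coercible) of length `ncol(s$beta)` assigning each
#'   sample to a group; at least 2 groups with at least 2 samples each.
#' @return A list of class `LocusStat`: `stat` (F, or signed t when
#'   `signed = TRUE` and k = 2), `F`, `t` (or `NULL`), `group_means`
#'   (loci x groups), `df` (k - 1, n - k), `groups` (levels).
#' @param signed when TRUE and there are exactly 2 groups, `stat` is the
#'   signed t statistic instead of F (used for two-group segmentation).
#' @export
locus_fstat <- function(s, group, signed = FALSE) {
  stopifnot(inherits(s, "SmoothedDataset"))
  group <- droplevels(as.factor(group))
  beta <- s$beta
  stopifnot(length(group) == ncol(beta))
  k <- nlevels(group)
  if (k < 2) stop("need >= 2 groups")
  if (any(table(group) < 2)) stop("every group needs >= 2 samples")
  n <- ncol(beta)
  G <- stats::model.matrix(~ 0 + group)
  colnames(G) <- levels(group)

  if (!anyNA(beta)) {
    ng <- colSums(G)
    gs <- beta %*% G
    m_g <- sweep(gs, 2, ng, "/")
    tot <- rowSums(gs)
    mbar <- tot / n
    SSB <- rowSums(sweep(m_g^2, 2, ng, "*")) - n * mbar^2
    TSS <- rowSums(beta^2) - n * mbar^2
    SSW <- TSS - SSB
    # guard tiny negatives from cancellation
    SSB <- pmax(SSB, 0)
    SSW <- pmax(SSW, 0)
    scale <- pmax(TSS, 1e-300)
    Fstat <- ifelse(SSW / scale < 1e-12,
                    ifelse(SSB / scale < 1e-12 | TSS < 1e-18, 0, Inf),
                    (SSB / (k - 1)) / (SSW / (n - k)))
  } else {
    L <- nrow(beta)
    m_g <- matrix(NA_real_, L, k, dimnames = list(NULL, levels(group)))
    Fstat <- rep(NA_real_, L)
    SSW <- SSB <- rep(NA_real_, L)
    for (i in seq_len(L)) {
      y <- beta[i, ]
      ok <- !is.na(y)
      ni <- tapply(ok, group, sum)
      if (any(ni < 2)) next
      mg <- tapply(y[ok], group[ok], mean)
      m_g[i, ] <- mg
      nn <- sum(ok)
      mb <- mean(y[ok])
      ssb <- sum(ni * (mg - mb)^2)
      tss <- sum((y[ok] - mb)^2)
      ssw <- max(tss - ssb, 0)
      SSB[i] <- ssb; SSW[i] <- ssw
      Fstat[i] <- if (ssw / max(tss, 1e-300) < 1e-12)
        (if (ssb / max(tss, 1e-300) < 1e-12 || tss < 1e-18) 0 else Inf)
      else (ssb / (k - 1)) / (ssw / (nn - k))
    }
  }

  tstat <- NULL
  if (k == 2) {
    # signed pooled-variance t; F = t^2 identically
    sgn <- sign(m_g[, 1] - m_g[, 2])
    tstat <- sgn * sqrt(Fstat)
  }
  structure(list(stat = if (signed && k == 2) tstat else Fstat,
                 F = Fstat, t = tstat, group_means = m_g,
                 df = c(k - 1, n - k), groups = levels(group),
                 signed = signed && k == 2),
            class = "LocusStat")
}

# Maximal runs of TRUE in `keep`, split at chromosome changes, at inter-locus
# gaps > max_gap_bp, and wherever `split_on` changes value; runs shorter than
# min_loci are dropped. Returns a data.frame of index ranges.
.find_runs <- function(keep, chrom, pos, max_gap_bp, min_loci,
                       split_on = NULL) {
  keep[is.na(keep)] <- FALSE
  if (!any(keep)) {
    return(data.frame(idx_start = integer(), idx_end = integer()))
  }
  idx <- which(keep)
  new_run <- c(TRUE,
               chrom[idx[-1]] != chrom[idx[-length(idx)]] |
                 idx[-1] != idx[-length(idx)] + 1L |
                 pos[idx[-1]] - pos[idx[-length(idx)]] > max_gap_bp)
  if (!is.null(split_on)) {
    new_run <- new_run |
      c(TRUE, split_on[idx[-1]] != split_on[idx[-length(idx)]])
  }
  run_id <- cumsum(new_run)
  starts <- idx[!duplicated(run_id)]
  ends <- idx[rev(!duplicated(rev(run_id)))]
  len <- ends - starts + 1L
  ok <- len >= min_loci
  data.frame(idx_start = starts[ok], idx_end = ends[ok])
}

# Note: runs are split where consecutive qualifying loci are non-adjacent in
# the locus index (an intervening below-cutoff locus breaks a run).

#' Segment locus statistics into candidate regions
#'
#' Candidate DMRs are maximal runs of consecutive loci whose statistic meets
#' the cutoff (`stat >= cutoff`; in signed two-group mode `|t| >= cutoff`
#' with constant sign), split where the distance between neighboring loci
#' exceeds `max_gap_bp`. Runs with fewer than `min_loci` loci are discarded.
#' Infinite locus statistics (zero within-group variance) are capped at the
#' largest finite value before segmentation so that areaStat stays finite.
#'
#' @param stats a `LocusStat` from [locus_fstat()].
#' @param s the `SmoothedDataset` the statistics were computed on.
#' @param cutoff positive entry cutoff on the locus statistic.
#' @param max_gap_bp maximum within-region gap between neighboring loci (bp).
#' @param min_loci minimum number of loci per region.
#' @return data.frame of regions: `chrom`, `start`, `end` (1-based inclusive
#'   span of member loci), `n_loci`, `areaStat`, `maxStat`, per-group mean
#'   smoothed methylation (`mean_<group>`), `max_group_diff`, and member
#'   index range `idx_start`, `idx_end`.
#' @export
call_candidates <- function(stats, s, cutoff, max_gap_bp = 300,
                            min_loci = 5L) {
  stopifnot(inherits(stats, "LocusStat"), inherits(s, "SmoothedDataset"),
            cutoff > 0)
  x <- stats$stat
  finite_max <- suppressWarnings(max(x[is.finite(x)], na.rm = TRUE))
  if (!is.finite(finite_max)) finite_max <- 0
  x[is.infinite(x)] <- finite_max
  score <- if (stats$signed) abs(x) else x
  keep <- score >= cutoff
  runs <- .find_runs(keep, s$chrom, s$pos, max_gap_bp, min_loci,
                     split_on = if (stats$signed) sign(x) else NULL)
  .score_regions(runs, x, stats$group_means, s)
}

.score_regions <- function(runs, stat_vec, group_means, s) {
  n <- nrow(runs)
  k <- ncol(group_means)
  gm <- matrix(NA_real_, n, k,
               dimnames = list(NULL, paste0("mean_", colnames(group_means))))
  out <- data.frame(chrom = character(n), start = integer(n), end = integer(n),
                    n_loci = integer(n), areaStat = numeric(n),
                    maxStat = numeric(n), stringsAsFactors = FALSE)
  for (r in seq_len(n)) {
    i1 <- runs$idx_start[r]; i2 <- runs$idx_end[r]
    sl <- i1:i2
    out$chrom[r] <- s$chrom[i1]
    out$start[r] <- s$pos[i1]
    out$end[r] <- s$pos[i2]
    out$n_loci[r] <- length(sl)
    out$areaStat[r] <- sum(stat_vec[sl])
    out$maxStat[r] <- max(abs(stat_vec[sl]))
    gm[r, ] <- colMeans(group_means[sl, , drop = FALSE])
  }
  out <- cbind(out, as.data.frame(gm))
  out$max_group_diff <- if (n) {
    apply(gm, 1, function(v) if (all(is.na(v))) NA_real_ else
      diff(range(v, na.rm = TRUE)))
  } else numeric(0)
  out$idx_start <- runs$idx_start
  out$idx_end <- runs$idx_end
  out
}

#' Permutation-based FWER control for DMR calling
#'
#' Runs the full locus-statistic and segmentation pipeline on the observed
#' grouping, then on `B` random permutations of the group labels. Each
#' permutation records the maximum `|areaStat|` over its candidate regions
#' (0 when none). An observed region's family-wise error rate p-value is the
#' add-one estimator `(1 + #[permutation maxima >= |areaStat|]) / (B + 1)`;
#' regions with `fwer_p <= alpha` are flagged significant.
#'
#' The entry cutoff defaults to the genome-wide `cutoff_quantile` of the
#' finite locus statistics and is recomputed inside every permutation, so
#' the permuted pipeline is exchangeable with the observed one. Supplying a
#' numeric `cutoff` fixes it across all runs instead.
#'
#' @param s a `SmoothedDataset`.
#' @param group sample grouping factor (>= 2 groups, >= 2 samples each).
#' @param cutoff optional fixed entry cutoff; overrides `cutoff_quantile`.
#' @param cutoff_quantile quantile of the finite locus statistic used as the
#'   entry cutoff (default 0.99).
#' @param max_gap_bp,min_loci segmentation parameters, see
#'   [call_candidates()].
#' @param B number of permutations (>= 1); ignored when `exhaustive`.
#' @param seed integer seed for the permutation draw (required).
#' @param alpha significance level for flagging (default 0.05).
#' @param kind region-set kind recorded in the output.
#' @param signed use signed two-group t segmentation when there are exactly
#'   two groups (default TRUE in that case).
#' @param exhaustive for two-group designs, enumerate every distinct label
#'   assignment instead of drawing randomly (exact permutation null for
#'   small n; the observed assignment is part of the enumeration).
#' @return A `RegionSet` whose regions carry `fwer_p` and `significant`;
#'   provenance records parameters, the observed cutoff, the permutation
#'   maxima, and the seed.
#' @export
permutation_fwer <- function(s, group, cutoff = NULL, cutoff_quantile = 0.99,
                             max_gap_bp = 300, min_loci = 5L, B = 100L,
                             seed, alpha = 0.05, kind = "cg_dmr",
                             signed = NULL, exhaustive = FALSE) {
  group <- droplevels(as.factor(group))
  if (nlevels(group) < 2) stop("degenerate design: need >= 2 groups")
  if (missing(seed) || is.null(seed)) stop("a seed is required")
  stopifnot(B >= 1)
  if (is.null(signed)) signed <- nlevels(group) == 2

  pick_cutoff <- function(st) {
    if (!is.null(cutoff)) return(cutoff)
    v <- abs(st$stat)
    v <- v[is.finite(v)]
    cf <- stats::quantile(v, cutoff_quantile, names = FALSE, type = 7)
    if (!is.finite(cf) || cf <= 0) cf <- .Machine$double.eps
    cf
  }

  obs_stat <- locus_fstat(s, group, signed = signed)
  obs_cutoff <- pick_cutoff(obs_stat)
  regions <- call_candidates(obs_stat, s, obs_cutoff, max_gap_bp, min_loci)

  perm_groups <- NULL
  if (exhaustive) {
    if (nlevels(group) != 2)
      stop("exhaustive enumeration is implemented for 2-group designs")
    n1 <- sum(group == levels(group)[1])
    combs <- utils::combn(length(group), n1)
    perm_groups <- lapply(seq_len(ncol(combs)), function(j) {
      g <- rep(levels(group)[2], length(group))
      g[combs[, j]] <- levels(group)[1]
      factor(g, levels = levels(group))
    })
    B <- length(perm_groups)
  }
  perm_max <- numeric(B)
  with_seed(seed, {
    for (b in seq_len(B)) {
      pg <- if (exhaustive) perm_groups[[b]] else sample(group)
      pst <- locus_fstat(s, pg, signed = signed)
      pcf <- pick_cutoff(pst)
      pr <- call_candidates(pst, s, pcf, max_gap_bp, min_loci)
      perm_max[b] <- if (nrow(pr)) max(abs(pr$areaStat)) else 0
    }
  })

  if (nrow(regions)) {
    regions$fwer_p <- vapply(abs(regions$areaStat), function(a)
      (1 + sum(perm_max >= a)) / (B + 1), numeric(1))
    regions$significant <- regions$fwer_p <= alpha
  } else {
    regions$fwer_p <- numeric(0)
    regions$significant <- logical(0)
  }
  region_set(regions, kind = kind,
             provenance = list(cutoff = obs_cutoff,
                               cutoff_quantile = if (is.null(cutoff))
                                 cutoff_quantile else NA_real_,
                               max_gap_bp = max_gap_bp, min_loci = min_loci,
                               B = B, seed = seed, alpha = alpha,
                               groups = levels(group),
                               smoothing = s$config, perm_max = perm_max))
}

#' Annotate regions with pairwise group differences
#'
#' A group pair `(g1, g2)` is attached to a region when the absolute
#' difference of its region-mean smoothed methylation between the two groups
#' is at least `delta_min`.
#'
#' @param rs a `RegionSet` from [permutation_fwer()] (or a compatible
#'   region data.frame inside one).
#' @param s the `SmoothedDataset` used for calling.
#' @param group sample grouping factor.
#' @param delta_min minimum absolute methylation difference (default 0.1).
#' @return The `RegionSet` with an `annotation` list-column of `"g1|g2"`
#'   pair strings (alphabetical within a pair).
#' @export
annotate_pairwise <- function(rs, s, group, delta_min = 0.1) {
  stopifnot(inherits(rs, "RegionSet"))
  group <- droplevels(as.factor(group))
  rmat <- region_methylation_matrix(rs, s)
  lv <- levels(group)
  ann <- vector("list", nrow(rs$regions))
  if (nrow(rs$regions)) {
    gm <- t(apply(rmat, 1, function(y) tapply(y, group, mean, na.rm = TRUE)))
    if (length(lv) == 1) gm <- matrix(gm, ncol = 1, dimnames = list(NULL, lv))
    pairs <- utils::combn(lv, 2)
    for (r in seq_len(nrow(rs$regions))) {
      hit <- abs(gm[r, pairs[1, ]] - gm[r, pairs[2, ]]) >= delta_min
      hit[is.na(hit)] <- FALSE
      ann[[r]] <- paste(pairs[1, hit], pairs[2, hit], sep = "|")
    }
  }
  rs$regions$annotation <- ann
  rs
}

#' Select group-discriminatory regions
#'
#' A region is discriminatory for group `g` when every one of its annotated
#' pairs contains `g` (so the region separates `g` from other groups and
#' makes no distinction among the rest). Per-group results are sorted by
#' `maxStat` descending and truncated to `caps[[g]]` when a cap is given.
#'
#' @param rs an annotated `RegionSet` (see [annotate_pairwise()]).
#' @param caps optional named list/vector `group -> integer` cap.
#' @return Named list `group -> data.frame` of discriminatory regions; the
#'   total count across groups is attached as attribute `"total"`.
#' @export
select_discriminatory <- function(rs, caps = NULL) {
  stopifnot(inherits(rs, "RegionSet"),
            !is.null(rs$regions$annotation))
  df <- rs$regions
  groups <- sort(unique(unlist(strsplit(unlist(df$annotation), "|",
                                        fixed = TRUE))))
  out <- list()
  for (g in groups) {
    in_all <- vapply(df$annotation, function(pp) {
      length(pp) > 0 && all(vapply(strsplit(pp, "|", fixed = TRUE),
                                   function(p) g %in% p, logical(1)))
    }, logical(1))
    sel <- df[in_all, , drop = FALSE]
    sel <- sel[order(-sel$maxStat), , drop = FALSE]
    if (!is.null(caps) && !is.null(caps[[g]]))
      sel <- utils::head(sel, caps[[g]])
    rownames(sel) <- NULL
    out[[g]] <- sel
  }
  attr(out, "total") <- sum(vapply(out, nrow, integer(1)))
  out
}

#' Combine per-stratum region sets into one reported table
#'
#' The non-CpG analysis runs the identical pipeline once per
#' strand/dinucleotide stratum (e.g. CA+, CA-, CT+, CT-) and reports the
#' union of the resulting region sets. This concatenates the region tables
#' with a `stratum` column, sorted by coordinate; regions from different
#' strata may overlap and are deliberately not merged.
#'
#' @param rs_list named list of `RegionSet` objects (names = strata).
#' @return data.frame of all regions with a `stratum` column.
#' @export
combine_region_sets <- function(rs_list) {
  stopifnot(length(rs_list) >= 1, !is.null(names(rs_list)))
  tabs <- lapply(names(rs_list), function(nm) {
    df <- rs_list[[nm]]$regions
    if (nrow(df)) df$stratum <- nm else df$stratum <- character(0)
    df
  })
  out <- do.call(rbind, tabs)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Region-by-sample mean methylation matrix
#'
#' Per region and sample, the mean smoothed methylation over member loci
#' (missing values excluded). Member loci are found by coordinate: loci of
#' the region's chromosome with `start <= pos <= end`.
#'
#' @param rs a `RegionSet` or region data.frame (1-based inclusive).
#' @param s a `SmoothedDataset`.
#' @return Matrix regions x samples.
#' @export
region_methylation_matrix <- function(rs, s) {
  df <- if (inherits(rs, "RegionSet")) rs$regions else rs
  stopifnot(inherits(s, "SmoothedDataset"))
  out <- matrix(NA_real_, nrow(df), ncol(s$beta),
                dimnames = list(NULL, colnames(s$beta)))
  for (r in seq_len(nrow(df))) {
    sl <- which(s$chrom == df$chrom[r] & s$pos >= df$start[r] &
                  s$pos <= df$end[r])
    if (!length(sl))
      stop(sprintf("region %s:%d-%d contains no loci", df$chrom[r],
                   df$start[r], df$end[r]))
    out[r, ] <- colMeans(s$beta[sl, , drop = FALSE], na.rm = TRUE)
  }
  out
}

#' Evaluate RNG-dependent code under a temporary seed
#'
#' Saves and restores the global RNG state so that no stage consumes global
#' randomness.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return The value of `code`.
#' @export
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  code
}
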