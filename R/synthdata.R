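# Seeded generator of multi-tissue, multi-donor WGBS count data: clustered
# CpG placement (island / open-sea mixture), bimodal baseline methylation,
# Poisson coverage, beta-binomial emission, planted DMRs, blocks, VMRs
# (Gaussian per-sample level shifts, optionally genotype-driven trimodal),
# designated outlier samples, and a sparse non-CpG (CpA, forward strand)
# track -- together with a machine-readable truth set.

#' Simulation configuration
#'
#' Defaults emulate a multi-tissue, multi-donor WGBS study design at desk
#' scale: 5 tissue groups sampled from 12 shared donors, two 2-Mb
#' chromosomes carrying ~40,000 CpGs in an island / open-sea mixture,
#' Poisson coverage around 12x, beta-binomial counts with ambient
#' dispersion 0.02, and planted region classes sized so the full pipeline
#' runs in minutes. Planted VMRs span 40-60 CpGs -- about the small
#' smoothing window, the resolution scale of smoothing-based callers
#' (narrower variability is attenuated by the smoother) -- and occupy just
#' under 1% of CpGs per tissue, so that the 99th-percentile SD rule lands
#' in the gap between ambient noise and genuine variability, as it does on
#' real methylomes where the top percentile of across-sample SD is
#' dominated by true VMRs. Per-sample VMR shifts have SD 0.12, on the
#' scale of published VMR cutoffs and effect sizes.
#'
#' @param tissues tissue names.
#' @param samples_per_tissue donors sampled per tissue (donors are shared
#'   across tissues).
#' @param chrom_lengths named vector of chromosome lengths (bp).
#' @param islands_per_mb CpG islands per Mb.
#' @param island_width_bp island width (bp).
#' @param island_spacing_bp mean CpG spacing inside islands (bp).
#' @param opensea_spacing_bp mean CpG spacing in open sea (bp).
#' @param baseline_island,baseline_opensea baseline methylation levels.
#' @param baseline_jitter_sd per-locus jitter SD on the baseline.
#' @param coverage_lambda Poisson mean read coverage.
#' @param dispersion beta-binomial dispersion rho (ambient).
#' @param n_dmrs,dmr_delta,dmr_n_loci planted DMRs: count, group mean shift,
#'   range of member-locus counts.
#' @param n_blocks,block_delta,block_width_bp planted blocks: long intervals
#'   with small shifts.
#' @param vmrs_per_tissue,vmr_sd,vmr_n_loci planted VMRs per tissue:
#'   count, per-sample level-shift SD, range of member-locus counts.
#' @param n_ubiquitous_vmrs VMRs planted at the same location in every
#'   tissue (each tissue's samples get independent shifts).
#' @param n_genotype_vmrs,genotype_maf,genotype_effect VMRs driven by a
#'   biallelic SNP: donor genotypes drawn at the given minor-allele
#'   frequency; methylation shifts by `genotype_effect/2` per minor allele
#'   (trimodal across genotypes, shared across tissues of a donor).
#' @param n_outlier_regions,outlier_shift,n_outlier_samples regions where
#'   designated outlier samples alone are shifted.
#' @param ch_enabled simulate the CpA forward-strand track.
#' @param ch_spacing_bp mean CpA spacing (bp; sparser than reality to keep
#'   fixtures small).
#' @param ch_baseline baseline mCA level.
#' @param n_ch_dmrs,ch_delta,ch_width_bp planted mCA-elevated DMRs.
#' @param group_map optional named vector mapping tissues to analysis
#'   groups (default identity).
#' @return List of class `SimulationConfig`.
#' @export
sim_config <- function(tissues = c("cortical", "basal_ganglia", "hippocampus",
                                   "hypothalamus", "amygdala"),
                       samples_per_tissue = 12L,
                       chrom_lengths = c(chr1 = 2e6, chr2 = 2e6),
                       islands_per_mb = 10, island_width_bp = 1000,
                       island_spacing_bp = 10, opensea_spacing_bp = 110,
                       baseline_island = 0.10, baseline_opensea = 0.85,
                       baseline_jitter_sd = 0.03,
                       coverage_lambda = 12, dispersion = 0.02,
                       n_dmrs = 10L, dmr_delta = 0.3,
                       dmr_n_loci = c(15L, 35L),
                       n_blocks = 2L, block_delta = 0.08,
                       block_width_bp = 30000,
                       vmrs_per_tissue = 4L, vmr_sd = 0.12,
                       vmr_n_loci = c(40L, 60L),
                       n_ubiquitous_vmrs = 1L,
                       n_genotype_vmrs = 1L, genotype_maf = 0.3,
                       genotype_effect = 0.3,
                       n_outlier_regions = 3L, outlier_shift = 0.5,
                       n_outlier_samples = 1L,
                       ch_enabled = FALSE, ch_spacing_bp = 150,
                       ch_baseline = 0.03, n_ch_dmrs = 6L, ch_delta = 0.06,
                       ch_width_bp = 30000,
                       group_map = NULL) {
  stopifnot(length(tissues) >= 1, samples_per_tissue >= 3,
            all(chrom_lengths > 0), dispersion >= 0, dispersion < 1,
            coverage_lambda > 0)
  cfg <- as.list(environment())
  if (is.null(cfg$group_map))
    cfg$group_map <- setNames(tissues, tissues)
  class(cfg) <- "SimulationConfig"
  cfg
}

# clustered CpG positions for one chromosome: sparse open-sea background
# (exponential gaps) overlaid with dense CpG islands (geometric gaps);
# returns sorted unique positions with an island membership flag
.sim_positions <- function(len, islands_per_mb, island_width, island_gap_mean,
                           sea_gap_mean) {
  n_isl <- max(0L, round(islands_per_mb * len / 1e6))
  isl_starts <- if (n_isl > 0)
    sort(sample.int(max(1L, len - island_width), n_isl)) else integer()
  n_sea <- ceiling(len / sea_gap_mean * 1.4)
  pos <- floor(cumsum(stats::rexp(n_sea, 1 / sea_gap_mean) + 2))
  for (st in isl_starts) {
    n_i <- ceiling(island_width / island_gap_mean)
    p <- st + cumsum(stats::rgeom(n_i, 1 / island_gap_mean) + 2L)
    pos <- c(pos, p[p < st + island_width])
  }
  pos <- sort(unique(pos))
  pos <- pos[pos >= 1 & pos <= len - 1]
  island <- rep(FALSE, length(pos))
  for (st in isl_starts)
    island[pos >= st & pos < st + island_width] <- TRUE
  list(pos = as.integer(pos), island = island)
}

# choose non-overlapping runs of consecutive loci (never spanning a
# chromosome boundary); returns list of index vectors
.plant_runs <- function(chrom, n_regions, len_range, taken) {
  n_loci_total <- length(chrom)
  out <- list()
  tries <- 0
  while (length(out) < n_regions && tries < 2000) {
    tries <- tries + 1
    k <- sample(seq(len_range[1], len_range[2]), 1)
    if (n_loci_total - k < 1L) next
    st <- sample.int(n_loci_total - k, 1)
    sl <- st:(st + k - 1L)
    if (!any(taken[sl]) && chrom[sl[1]] == chrom[sl[k]]) {
      taken[sl] <- TRUE
      out[[length(out) + 1L]] <- sl
    }
  }
  if (length(out) < n_regions)
    stop("could not place all planted regions; genome too small/crowded")
  list(runs = out, taken = taken)
}

.truth_row <- function(class, chrom, pos, sl, target, effect, context = "CG") {
  data.frame(class = class, chrom = chrom[sl[1]], start = pos[sl[1]],
             end = pos[sl[length(sl)]], n_loci = length(sl),
             target = target, effect = effect, context = context,
             stringsAsFactors = FALSE)
}

#' Simulate a multi-tissue WGBS study
#'
#' Per locus l and sample s the true methylation is
#' `pi = clamp(baseline(l) + delta * [s's group affected] + b_s * [l in a
#' planted VMR] + genotype effect + outlier shift, 0, 1)`, with `b_s ~
#' N(0, vmr_sd^2)` drawn once per (sample, region). Coverage is
#' `Cov ~ Poisson(lambda)` and counts `M ~ BetaBinomial(Cov, pi, rho)`.
#' Fully reproducible under the seed; the RNG state of the session is left
#' untouched.
#'
#' @param cfg a [sim_config()].
#' @param seed integer seed (required).
#' @return List of class `Simulation`: `datasets` (named list of
#'   `MethDataset`, one per context stratum: `CG` strand-collapsed and,
#'   when enabled, `CA_plus`), `samples` (a `SampleTable`), `truth`
#'   (data.frame of planted regions: class `dmr`, `block`, `vmr`,
#'   `ch_dmr`, or `outlier`; 1-based inclusive intervals; affected
#'   target; effect parameter), and `config`.
#' @export
simulate_wgbs <- function(cfg, seed) {
  stopifnot(inherits(cfg, "SimulationConfig"))
  if (missing(seed) || is.null(seed)) stop("a seed is required")
  with_seed(seed, .simulate_impl(cfg))
}

#' Simulate a null study with no planted regions
#'
#' Identical generative process to [simulate_wgbs()] with empty planting:
#' group labels are exchangeable by construction and the truth set is
#' empty. Used for family-wise error calibration.
#'
#' @inheritParams simulate_wgbs
#' @return As [simulate_wgbs()], with zero truth rows.
#' @export
simulate_null <- function(cfg, seed) {
  stopifnot(inherits(cfg, "SimulationConfig"))
  cfg$n_dmrs <- 0L; cfg$n_blocks <- 0L
  cfg$vmrs_per_tissue <- 0L; cfg$n_ubiquitous_vmrs <- 0L
  cfg$n_genotype_vmrs <- 0L; cfg$n_outlier_regions <- 0L
  cfg$n_ch_dmrs <- 0L
  simulate_wgbs(cfg, seed)
}

.simulate_impl <- function(cfg) {
  # -- samples ---------------------------------------------------------------
  donors <- sprintf("D%02d", seq_len(cfg$samples_per_tissue))
  samples <- sample_table(
    sample_id = as.vector(t(outer(cfg$tissues, donors, paste, sep = "."))),
    donor_id = rep(donors, times = length(cfg$tissues)),
    tissue = rep(cfg$tissues, each = length(donors)),
    group_map = cfg$group_map,
    tissue_class = ifelse(rep(cfg$tissues, each = length(donors)) %in%
                            c("lung", "thyroid"), "non_brain", "brain"))
  ns <- nrow(samples)

  # -- CpG landscape ---------------------------------------------------------
  chrom <- character(); pos <- integer(); island <- logical()
  for (cn in names(cfg$chrom_lengths)) {
    p <- .sim_positions(cfg$chrom_lengths[[cn]], cfg$islands_per_mb,
                        cfg$island_width_bp, cfg$island_spacing_bp,
                        cfg$opensea_spacing_bp)
    chrom <- c(chrom, rep(cn, length(p$pos)))
    pos <- c(pos, p$pos)
    island <- c(island, p$island)
  }
  L <- length(pos)
  baseline <- ifelse(island, cfg$baseline_island, cfg$baseline_opensea) +
    stats::rnorm(L, 0, cfg$baseline_jitter_sd)
  baseline <- pmin(pmax(baseline, 0.02), 0.98)

  # -- planting --------------------------------------------------------------
  pi_mat <- matrix(baseline, L, ns)
  taken <- logical(L)
  truth <- list()
  grp <- samples$group
  tis <- samples$tissue

  if (cfg$n_dmrs > 0) {
    pr <- .plant_runs(chrom, cfg$n_dmrs, cfg$dmr_n_loci, taken); taken <- pr$taken
    affected <- rep(unique(grp), length.out = cfg$n_dmrs)
    for (i in seq_len(cfg$n_dmrs)) {
      sl <- pr$runs[[i]]
      # shift toward the far side of the unit interval so the full effect
      # survives clamping
      d <- ifelse(mean(baseline[sl]) > 0.5, -cfg$dmr_delta, cfg$dmr_delta)
      cols <- which(grp == affected[i])
      pi_mat[sl, cols] <- pi_mat[sl, cols] + d
      truth[[length(truth) + 1L]] <-
        .truth_row("dmr", chrom, pos, sl, affected[i], d)
    }
  }

  if (cfg$n_blocks > 0) {
    # blocks planted by width: convert to locus runs covering block_width_bp
    mean_gap <- mean(diff(pos[chrom == chrom[1]]))
    k <- max(50L, round(cfg$block_width_bp / mean_gap))
    pr <- .plant_runs(chrom, cfg$n_blocks, c(k, k), taken); taken <- pr$taken
    affected <- rep(rev(unique(grp)), length.out = cfg$n_blocks)
    for (i in seq_len(cfg$n_blocks)) {
      sl <- pr$runs[[i]]
      d <- ifelse(mean(baseline[sl]) > 0.5, -cfg$block_delta, cfg$block_delta)
      cols <- which(grp == affected[i])
      pi_mat[sl, cols] <- pi_mat[sl, cols] + d
      truth[[length(truth) + 1L]] <-
        .truth_row("block", chrom, pos, sl, affected[i], d)
    }
  }

  if (cfg$vmrs_per_tissue > 0 || cfg$n_ubiquitous_vmrs > 0) {
    for (tt in cfg$tissues) {
      n_t <- cfg$vmrs_per_tissue
      if (n_t == 0) next
      pr <- .plant_runs(chrom, n_t, cfg$vmr_n_loci, taken); taken <- pr$taken
      cols <- which(tis == tt)
      for (i in seq_len(n_t)) {
        sl <- pr$runs[[i]]
        b <- stats::rnorm(length(cols), 0, cfg$vmr_sd)
        pi_mat[sl, cols] <- pi_mat[sl, cols] + rep(b, each = length(sl))
        truth[[length(truth) + 1L]] <-
          .truth_row("vmr", chrom, pos, sl, tt, cfg$vmr_sd)
      }
    }
    if (cfg$n_ubiquitous_vmrs > 0) {
      pr <- .plant_runs(chrom, cfg$n_ubiquitous_vmrs,
                        cfg$vmr_n_loci, taken); taken <- pr$taken
      for (i in seq_len(cfg$n_ubiquitous_vmrs)) {
        sl <- pr$runs[[i]]
        b <- stats::rnorm(ns, 0, cfg$vmr_sd)  # every sample, every tissue
        pi_mat[sl, ] <- pi_mat[sl, ] + rep(b, each = length(sl))
        for (tt in cfg$tissues)
          truth[[length(truth) + 1L]] <-
            .truth_row("vmr", chrom, pos, sl, tt, cfg$vmr_sd)
      }
    }
  }

  genotypes <- NULL
  if (cfg$n_genotype_vmrs > 0) {
    pr <- .plant_runs(chrom, cfg$n_genotype_vmrs, cfg$vmr_n_loci, taken)
    taken <- pr$taken
    genotypes <- matrix(stats::rbinom(length(donors) * cfg$n_genotype_vmrs,
                                      2, cfg$genotype_maf),
                        nrow = cfg$n_genotype_vmrs,
                        dimnames = list(NULL, donors))
    for (i in seq_len(cfg$n_genotype_vmrs)) {
      sl <- pr$runs[[i]]
      g <- genotypes[i, samples$donor_id]
      # keep the trimodal spread inside [0,1]: push down from high baselines
      dirn <- ifelse(mean(baseline[sl]) > 0.5, -1, 1)
      shift <- dirn * g * cfg$genotype_effect / 2
      pi_mat[sl, ] <- pi_mat[sl, ] + rep(shift, each = length(sl))
      for (tt in cfg$tissues)
        truth[[length(truth) + 1L]] <-
          .truth_row("vmr", chrom, pos, sl, tt, cfg$genotype_effect)
    }
  }

  if (cfg$n_outlier_regions > 0 && cfg$n_outlier_samples > 0) {
    out_samp <- samples$sample_id[seq_len(cfg$n_outlier_samples)]
    pr <- .plant_runs(chrom, cfg$n_outlier_regions, cfg$vmr_n_loci, taken)
    taken <- pr$taken
    for (i in seq_len(cfg$n_outlier_regions)) {
      sl <- pr$runs[[i]]
      cols <- match(out_samp, samples$sample_id)
      dirn <- ifelse(mean(baseline[sl]) > 0.5, -1, 1)
      pi_mat[sl, cols] <- pi_mat[sl, cols] + dirn * cfg$outlier_shift
      truth[[length(truth) + 1L]] <-
        .truth_row("outlier", chrom, pos, sl,
                   paste(out_samp, collapse = ","), dirn * cfg$outlier_shift)
    }
  }

  pi_mat <- pmin(pmax(pi_mat, 0), 1)

  # -- emission: Poisson coverage, beta-binomial counts ----------------------
  cg <- .emit_counts(chrom, pos, pi_mat, cfg$coverage_lambda, cfg$dispersion,
                     samples, strand = "both", context = "CG")

  datasets <- list(CG = cg)

  if (isTRUE(cfg$ch_enabled)) {
    ch <- .simulate_ch(cfg, samples)
    datasets$CA_plus <- ch$dataset
    truth <- c(truth, ch$truth)
  }

  truth_df <- if (length(truth)) do.call(rbind, truth) else
    data.frame(class = character(), chrom = character(), start = integer(),
               end = integer(), n_loci = integer(), target = character(),
               effect = numeric(), context = character(),
               stringsAsFactors = FALSE)
  rownames(truth_df) <- NULL

  structure(list(datasets = datasets, samples = samples, truth = truth_df,
                 genotypes = genotypes, config = cfg),
            class = "Simulation")
}

.emit_counts <- function(chrom, pos, pi_mat, lambda, rho, samples,
                         strand, context) {
  L <- nrow(pi_mat); ns <- ncol(pi_mat)
  Cov <- matrix(stats::rpois(L * ns, lambda), L, ns)
  pvec <- as.vector(pi_mat)
  if (rho > 0) {
    a <- pvec * (1 / rho - 1)
    b <- (1 - pvec) * (1 / rho - 1)
    inner <- ifelse(a <= 0, 0, ifelse(b <= 0, 1,
                                      stats::rbeta(L * ns, pmax(a, 1e-12),
                                                   pmax(b, 1e-12))))
  } else inner <- pvec
  M <- matrix(stats::rbinom(L * ns, as.vector(Cov), inner), L, ns)
  dimnames(M) <- dimnames(Cov) <- list(NULL, samples$sample_id)
  meth_dataset(chrom, pos, strand, context, M, Cov, samples)
}

.simulate_ch <- function(cfg, samples) {
  chrom <- character(); pos <- integer()
  for (cn in names(cfg$chrom_lengths)) {
    len <- cfg$chrom_lengths[[cn]]
    gaps <- stats::rexp(ceiling(len / cfg$ch_spacing_bp * 1.3),
                        1 / cfg$ch_spacing_bp) + 2
    p <- floor(cumsum(gaps))
    p <- p[p <= len - 1]
    chrom <- c(chrom, rep(cn, length(p)))
    pos <- c(pos, as.integer(p))
  }
  L <- length(pos)
  ns <- nrow(samples)
  baseline <- pmin(pmax(cfg$ch_baseline +
                          stats::rnorm(L, 0, cfg$ch_baseline / 3), 0.002), 0.2)
  pi_mat <- matrix(baseline, L, ns)
  truth <- list()
  if (cfg$n_ch_dmrs > 0) {
    mean_gap <- cfg$ch_spacing_bp
    k <- max(30L, round(cfg$ch_width_bp / mean_gap))
    pr <- .plant_runs(chrom, cfg$n_ch_dmrs, c(k, k), logical(L))
    affected <- rep(unique(samples$group), length.out = cfg$n_ch_dmrs)
    for (i in seq_len(cfg$n_ch_dmrs)) {
      sl <- pr$runs[[i]]
      cols <- which(samples$group == affected[i])
      pi_mat[sl, cols] <- pi_mat[sl, cols] + cfg$ch_delta
      truth[[length(truth) + 1L]] <-
        .truth_row("ch_dmr", chrom, pos, sl, affected[i], cfg$ch_delta,
                   context = "CA")
    }
  }
  pi_mat <- pmin(pmax(pi_mat, 0), 1)
  list(dataset = .emit_counts(chrom, pos, pi_mat, cfg$coverage_lambda,
                              cfg$dispersion, samples,
                              strand = "+", context = "CA"),
       truth = truth)
}

#' Write simulation outputs as an on-disk fixture
#'
#' Emits one Bismark-style cytosine report per sample (CpG counts split
#' deterministically across the two strands so that strand collapsing
#' restores them exactly; CpA loci written on the forward strand), a
#' tab-separated sample sheet, and the truth set as a BED-style table
#' (0-based half-open intervals with class/target/effect attributes).
#'
#' @param sim a `Simulation` from [simulate_wgbs()].
#' @param dir output directory (created if needed).
#' @param gzip write gzip-compressed reports (default FALSE).
#' @return Invisibly, the named list of written paths.
#' @export
write_fixture <- function(sim, dir, gzip = FALSE) {
  stopifnot(inherits(sim, "Simulation"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cg <- sim$datasets$CG
  ca <- sim$datasets$CA_plus
  paths <- list()
  for (j in seq_len(nrow(sim$samples))) {
    sid <- sim$samples$sample_id[j]
    M <- cg$M[, j]; Cov <- cg$Cov[, j]
    # deterministic strand split conserving the pair totals
    cov_p <- Cov %/% 2L + Cov %% 2L
    m_p <- pmin(M, cov_p)
    dt <- data.table::data.table(
      chrom = rep(cg$chrom, 2L),
      pos = c(cg$pos, cg$pos + 1L),
      strand = rep(c("+", "-"), each = length(cg$pos)),
      m = c(m_p, M - m_p),
      u = c(cov_p - m_p, (Cov - cov_p) - (M - m_p)),
      context = "CG", tri = "CGN")
    if (!is.null(ca)) {
      dt <- rbind(dt, data.table::data.table(
        chrom = ca$chrom, pos = ca$pos, strand = "+",
        m = ca$M[, j], u = ca$Cov[, j] - ca$M[, j],
        context = "CA", tri = "CAN"))
    }
    data.table::setorder(dt, chrom, pos, strand)
    f <- file.path(dir, paste0(sid, ".CX_report.txt", if (gzip) ".gz" else ""))
    data.table::fwrite(dt, f, sep = "\t", col.names = FALSE,
                       compress = if (gzip) "gzip" else "none")
    paths[[sid]] <- f
  }
  sheet <- file.path(dir, "sample_sheet.tsv")
  write_sample_sheet(sim$samples, sheet)
  truth_path <- file.path(dir, "truth.bed")
  tr <- sim$truth
  con <- file(truth_path, "w")
  writeLines("# chrom\tstart\tend\tclass\ttarget\teffect\tn_loci\tcontext", con)
  if (nrow(tr)) {
    utils::write.table(
      data.frame(tr$chrom, tr$start - 1L, tr$end, tr$class, tr$target,
                 tr$effect, tr$n_loci, tr$context),
      con, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  }
  close(con)
  invisible(c(paths, list(sample_sheet = sheet, truth = truth_path)))
}

#' Read a written fixture back into datasets
#'
#' Round-trip companion to [write_fixture()]: reads every per-sample report
#' named in the sample sheet, collapses CpG strands, and reassembles the
#' multi-sample dataset(s).
#'
#' @param dir fixture directory.
#' @param contexts contexts to load (default CG).
#' @return List: `datasets` (named as in the simulation), `samples`.
#' @export
read_fixture <- function(dir, contexts = "CG") {
  samples <- read_sample_sheet(file.path(dir, "sample_sheet.tsv"))
  datasets <- list()
  for (ctx in contexts) {
    dsets <- lapply(samples$sample_id, function(sid) {
      f <- file.path(dir, paste0(sid, ".CX_report.txt"))
      if (!file.exists(f)) f <- paste0(f, ".gz")
      d <- read_cytosine_report(f, contexts = ctx, sample_id = sid)
      if (ctx == "CG") collapse_cpg_strands(d) else d
    })
    nm <- if (ctx == "CG") "CG" else paste0(ctx, "_plus")
    datasets[[nm]] <- combine_samples(dsets, samples)
  }
  list(datasets = datasets, samples = samples)
}
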