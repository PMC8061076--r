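# Orchestration: a single structured run configuration (R list or YAML file)
# drives simulate/read -> smooth -> DMR -> VMR -> enrichment, with logging,
# deterministic seeding per stage, and a machine-readable provenance
# manifest. Exit discipline for scripted use: configuration problems raise
# condition class "methscape_config_error" before any compute starts.

.config_error <- function(msg) {
  stop(structure(class = c("methscape_config_error", "error", "condition"),
                 list(message = msg, call = NULL)))
}

#' Build and validate a run configuration
#'
#' @param x a named list, or the path of a YAML file holding one. Top-level
#'   fields:
#'   \describe{
#'     \item{analysis}{run name (used in output file names).}
#'     \item{seed}{integer; master seed for every stochastic stage.}
#'     \item{simulate}{optional list of [sim_config()] arguments; when
#'       present the input is simulated.}
#'     \item{input}{alternative to `simulate`: list with `dir` (fixture
#'       directory of per-sample cytosine reports plus sample sheet).}
#'     \item{grouping}{optional named mapping tissue -> group; every named
#'       tissue must exist in the sample table.}
#'     \item{smoothing}{preset name (default `"cg_small"`).}
#'     \item{dmr}{list: `cutoff_quantile` (0.99), `max_gap_bp` (300),
#'       `min_loci` (5), `B` (100), `alpha` (0.05).}
#'     \item{vmr}{list: `min_cov` (5), `min_samples`, `q` (0.99),
#'       `max_gap_bp` (300), `min_cpgs` (11), `cooks_threshold` (0.7).}
#'     \item{enrich}{optional list: `features` = named vector of BED paths.}
#'   }
#' @return Validated list of class `RunConfig`.
#' @export
run_config <- function(x) {
  if (is.character(x) && length(x) == 1) x <- yaml::read_yaml(x)
  if (!is.list(x)) .config_error("run configuration must be a list or YAML file")
  if (is.null(x$analysis)) x$analysis <- "run"
  if (is.null(x$seed)) .config_error("a 'seed' is required")
  if (is.null(x$simulate) && is.null(x$input))
    .config_error("either 'simulate' or 'input' must be given")
  x$smoothing <- if (is.null(x$smoothing)) "cg_small" else x$smoothing
  if (!x$smoothing %in% c("cg_small", "cg_block", "ch"))
    .config_error(paste0("unknown smoothing preset '", x$smoothing, "'"))
  dmr_def <- list(cutoff_quantile = 0.99, max_gap_bp = 300, min_loci = 5L,
                  B = 100L, alpha = 0.05)
  x$dmr <- utils::modifyList(dmr_def, if (is.null(x$dmr)) list() else x$dmr)
  vmr_def <- list(min_cov = 5L, min_samples = NULL, q = 0.99,
                  max_gap_bp = 300, min_cpgs = 11L, cooks_threshold = 0.7)
  x$vmr <- utils::modifyList(vmr_def, if (is.null(x$vmr)) list() else x$vmr,
                             keep.null = TRUE)
  class(x) <- "RunConfig"
  x
}

#' Run the full analysis pipeline
#'
#' Stages: obtain input (simulate or read a fixture), validate the grouping
#' against the sample sheet (pre-flight; a bad grouping fails before any
#' compute), smooth, call DMRs with permutation FWER control, call and
#' filter per-tissue VMRs with sharing classification, optionally compute
#' feature enrichments, and write region tables, BED files, a log, and a
#' provenance manifest. Outputs are deterministic given the seed:
#' re-running an identical configuration reproduces identical tables.
#'
#' @param config a `RunConfig`, list, or YAML path (see [run_config()]).
#' @param out_dir output directory (created).
#' @param quiet suppress progress messages (default FALSE).
#' @return Invisibly, a named list of output paths plus the in-memory
#'   results (`dmrs`, `vmrs`, `sharing`, `enrichment`).
#' @export
run_pipeline <- function(config, out_dir, quiet = FALSE) {
  cfg <- run_config(config)
  t0 <- proc.time()[["elapsed"]]
  timings <- list()
  say <- function(...) if (!quiet) message(sprintf(...))
  tick <- function(stage) {
    timings[[stage]] <<- round(proc.time()[["elapsed"]] - t0, 2)
  }

  # -- input (pre-flight validation before compute) --------------------------
  if (!is.null(cfg$simulate)) {
    sc <- do.call(sim_config, cfg$simulate)
    tissues_avail <- sc$tissues
  } else {
    sheet <- file.path(cfg$input$dir, "sample_sheet.tsv")
    if (!file.exists(sheet))
      .config_error(paste0("missing sample sheet: ", sheet))
    tissues_avail <- unique(read_sample_sheet(sheet)$tissue)
  }
  if (!is.null(cfg$grouping)) {
    unknown <- setdiff(names(cfg$grouping), tissues_avail)
    if (length(unknown))
      .config_error(paste0("grouping names tissues absent from the sample ",
                           "sheet: ", paste(unknown, collapse = ", ")))
  }

  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, paste0(cfg$analysis, ".log"))
  log_con <- file(log_path, "w")
  on.exit(close(log_con), add = TRUE)
  log_line <- function(...) {
    msg <- sprintf(...)
    writeLines(msg, log_con)
    say("%s", msg)
  }

  log_line("analysis=%s seed=%d", cfg$analysis, cfg$seed)
  if (!is.null(cfg$simulate)) {
    sim <- simulate_wgbs(sc, seed = cfg$seed)
    d <- sim$datasets$CG
    samples <- sim$samples
    truth <- sim$truth
  } else {
    fx <- read_fixture(cfg$input$dir)
    d <- fx$datasets$CG
    samples <- fx$samples
    truth <- NULL
  }
  if (!is.null(cfg$grouping)) {
    map <- setNames(tissues_avail, tissues_avail)
    map[names(cfg$grouping)] <- unlist(cfg$grouping)
    samples$group <- unname(map[samples$tissue])
    d$samples <- samples
  }
  log_line("input: %d loci x %d samples, %d tissues", length(d$pos),
           ncol(d$M), length(unique(samples$tissue)))
  tick("input")

  # -- smoothing -------------------------------------------------------------
  sm <- smooth_methylation(d, smoothing_preset(cfg$smoothing))
  sm$samples <- samples
  log_line("smoothed with preset %s", cfg$smoothing)
  tick("smoothing")

  # -- DMRs ------------------------------------------------------------------
  dmr_seed <- cfg$seed + 1L
  dmrs <- permutation_fwer(sm, samples$group,
                           cutoff_quantile = cfg$dmr$cutoff_quantile,
                           max_gap_bp = cfg$dmr$max_gap_bp,
                           min_loci = cfg$dmr$min_loci, B = cfg$dmr$B,
                           seed = dmr_seed, alpha = cfg$dmr$alpha,
                           kind = if (cfg$smoothing == "cg_block")
                             "cg_block" else "cg_dmr")
  dmrs <- annotate_pairwise(dmrs, sm, samples$group)
  dmr_tab <- dmrs$regions
  dmr_tab$annotation <- vapply(dmr_tab$annotation, paste, character(1),
                               collapse = ";")
  dmr_path <- file.path(out_dir, paste0(cfg$analysis, "_dmrs.tsv"))
  utils::write.table(dmr_tab, dmr_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  write_regions_bed(dmrs, file.path(out_dir,
                                    paste0(cfg$analysis, "_dmrs.bed")))
  log_line("DMRs: %d candidates, %d significant at alpha=%.2f",
           nrow(dmr_tab), sum(dmr_tab$significant), cfg$dmr$alpha)
  tick("dmr")

  # -- VMRs ------------------------------------------------------------------
  vmr_args <- cfg$vmr
  if (is.null(vmr_args$min_samples))
    vmr_args$min_samples <- floor(0.55 * ncol(d$Cov))
  vres <- find_vmrs(d, sm, samples = samples,
                    min_cov = vmr_args$min_cov,
                    min_samples = vmr_args$min_samples, q = vmr_args$q,
                    max_gap_bp = vmr_args$max_gap_bp,
                    min_cpgs = vmr_args$min_cpgs,
                    cooks_threshold = vmr_args$cooks_threshold)
  vmr_tab <- do.call(rbind, vres$vmrs)
  vmr_path <- file.path(out_dir, paste0(cfg$analysis, "_vmrs.tsv"))
  utils::write.table(vmr_tab, vmr_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  sharing <- classify_sharing(vres$vmrs)
  sharing_path <- file.path(out_dir, paste0(cfg$analysis, "_vmr_sharing.tsv"))
  utils::write.table(sharing, sharing_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  retained <- if (is.null(vmr_tab)) 0L else sum(vmr_tab$retained)
  log_line("VMRs: cutoff=%.4f, %d called, %d retained, %d merged intervals",
           vres$cutoff, if (is.null(vmr_tab)) 0L else nrow(vmr_tab),
           retained, nrow(sharing))
  tick("vmr")

  # -- enrichment ------------------------------------------------------------
  enr <- NULL
  if (!is.null(cfg$enrich) && length(cfg$enrich$features)) {
    feats <- lapply(names(cfg$enrich$features), function(nm)
      read_bed(cfg$enrich$features[[nm]], name = nm))
    sig <- dmrs$regions[dmrs$regions$significant, , drop = FALSE]
    enr <- enrich_batch(data.frame(chrom = d$chrom, pos = d$pos), sig, feats)
    enr_path <- file.path(out_dir, paste0(cfg$analysis, "_enrichment.tsv"))
    utils::write.table(enr, enr_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    log_line("enrichment: %d features, %d significant", nrow(enr),
             sum(enr$significant))
  }
  tick("enrich")

  # -- provenance ------------------------------------------------------------
  manifest <- list(
    analysis = cfg$analysis,
    seed = cfg$seed,
    stage_seeds = list(simulate = cfg$seed, dmr = dmr_seed),
    smoothing = cfg$smoothing,
    dmr = cfg$dmr[c("cutoff_quantile", "max_gap_bp", "min_loci", "B",
                    "alpha")],
    dmr_cutoff_observed = dmrs$provenance$cutoff,
    vmr = vmr_args,
    vmr_cutoff = vres$cutoff,
    n_truth = if (is.null(truth)) NA_integer_ else nrow(truth),
    package_version = as.character(utils::packageVersion("methscape")),
    timings_s = timings)
  jsonlite::write_json(manifest, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  if (!is.null(truth)) {
    utils::write.table(truth, file.path(out_dir, "truth.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  log_line("done")

  invisible(list(out_dir = out_dir, dmr_table = dmr_path,
                 vmr_table = vmr_path, sharing_table = sharing_path,
                 log = log_path, dmrs = dmrs, vmrs = vres, sharing = sharing,
                 enrichment = enr, truth = truth, samples = samples))
}

#' Sensitivity and FDR of region recovery against a truth set
#'
#' A truth region is recovered when it shares at least one bp with a called
#' region; a called region is a false discovery when it overlaps no truth
#' region. Used to score simulated analyses.
#'
#' @param called data.frame of called regions (`chrom`, `start`, `end`,
#'   1-based inclusive).
#' @param truth data.frame of truth regions (same convention).
#' @return List: `sensitivity`, `fdr`, `n_called`, `n_truth`,
#'   `recovered` (logical per truth row), `false_call` (logical per call).
#' @export
recovery_stats <- function(called, truth) {
  if (nrow(truth) == 0)
    return(list(sensitivity = NA_real_, fdr = if (nrow(called)) 1 else NA_real_,
                n_called = nrow(called), n_truth = 0L,
                recovered = logical(0), false_call = rep(TRUE, nrow(called))))
  if (nrow(called) == 0)
    return(list(sensitivity = 0, fdr = NA_real_, n_called = 0L,
                n_truth = nrow(truth), recovered = rep(FALSE, nrow(truth)),
                false_call = logical(0)))
  gt <- .granges1(truth$chrom, truth$start, truth$end)
  gc <- .granges1(called$chrom, called$start, called$end)
  recovered <- GenomicRanges::countOverlaps(gt, gc) > 0
  false_call <- GenomicRanges::countOverlaps(gc, gt) == 0
  list(sensitivity = mean(recovered), fdr = mean(false_call),
       n_called = nrow(called), n_truth = nrow(truth),
       recovered = recovered, false_call = false_call)
}
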