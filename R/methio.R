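# I/O and interval primitives: cytosine reports, sample sheets, BED features,
# strand collapsing, binning, promoter construction, interval overlap.
#
# Coordinate conventions (kept native at each boundary):
#   * cytosine-report loci and region tables: 1-based, inclusive
#   * feature sets and BED files: 0-based, half-open

VALID_CONTEXTS <- c("CG", "CA", "CT", "CC")

#' Construct a methylation count dataset
#'
#' The raw substrate of all downstream stages: per-locus methylated and total
#' read counts across samples, for one cytosine context/strand stratum.
#'
#' @param chrom character vector of chromosome names.
#' @param pos integer vector of 1-based cytosine positions.
#' @param strand single strand for the stratum: `"+"`, `"-"`, or `"both"`
#'   (strand-collapsed CpG), or a per-locus vector.
#' @param context single context for the stratum (`"CG"`, `"CA"`, `"CT"`,
#'   `"CC"`), or a per-locus vector.
#' @param M,Cov integer matrices (loci x samples) of methylated and total read
#'   counts, `0 <= M <= Cov`. Zero-coverage loci are retained; coverage
#'   filters belong to the individual analyses.
#' @param samples optional sample table (see [sample_table()]); its
#'   `sample_id` must match `colnames(M)`.
#'
#' @return An object of class `MethDataset` with loci sorted by
#'   chromosome and position.
#' @export
meth_dataset <- function(chrom, pos, strand, context, M, Cov, samples = NULL) {
  M <- as.matrix(M)
  Cov <- as.matrix(Cov)
  n <- length(pos)
  stopifnot(length(chrom) == n, nrow(M) == n, nrow(Cov) == n,
            ncol(M) == ncol(Cov))
  if (length(strand) == 1L) strand <- rep(strand, n)
  if (length(context) == 1L) context <- rep(context, n)
  pos <- as.integer(pos)
  if (n > 0L) {
    if (any(pos < 1L)) stop("locus positions must be >= 1")
    if (!all(context %in% VALID_CONTEXTS)) stop("unknown context symbol")
    if (!all(strand %in% c("+", "-", "both"))) stop("invalid strand")
    if (any(strand == "both" & context != "CG"))
      stop("strand 'both' is only permitted for CG loci (post strand-collapse)")
    if (any(M < 0) || any(Cov < 0) || any(M > Cov))
      stop("counts must satisfy 0 <= M <= Cov")
    o <- order(chrom, pos)
    chrom <- chrom[o]; pos <- pos[o]; strand <- strand[o]; context <- context[o]
    M <- M[o, , drop = FALSE]; Cov <- Cov[o, , drop = FALSE]
    dup <- duplicated(data.frame(chrom, pos, strand))
    if (any(dup)) stop("duplicated loci (same chrom/pos/strand)")
  }
  if (!is.null(samples)) {
    if (is.null(colnames(M))) colnames(M) <- colnames(Cov) <- samples$sample_id
    stopifnot(identical(colnames(M), samples$sample_id))
  }
  structure(list(chrom = chrom, pos = pos, strand = strand, context = context,
                 M = M, Cov = Cov, samples = samples),
            class = "MethDataset")
}

#' @export
print.MethDataset <- function(x, ...) {
  cat(sprintf("MethDataset: %d loci x %d samples | context %s | strand %s\n",
              length(x$pos), ncol(x$M),
              paste(unique(x$context), collapse = ","),
              paste(unique(x$strand), collapse = ",")))
  invisible(x)
}

#' Construct and validate a sample table
#'
#' @param sample_id unique sample identifiers.
#' @param donor_id donor each sample came from.
#' @param tissue tissue of origin (non-empty).
#' @param group analysis grouping label; when omitted, derived from `tissue`
#'   via `group_map` (a named character vector `tissue -> group`), defaulting
#'   to the identity mapping.
#' @param tissue_class `"brain"` or `"non_brain"` per sample.
#' @param group_map optional named character vector mapping tissues to groups.
#' @return A `data.frame` with class `SampleTable`.
#' @export
sample_table <- function(sample_id, donor_id, tissue, group = NULL,
                         tissue_class = "brain", group_map = NULL) {
  sample_id <- as.character(sample_id)
  if (anyDuplicated(sample_id)) stop("sample_id must be unique")
  tissue <- as.character(tissue)
  if (any(!nzchar(tissue))) stop("every sample needs a non-empty tissue")
  if (is.null(group)) {
    if (is.null(group_map)) group_map <- setNames(unique(tissue), unique(tissue))
    missing_t <- setdiff(tissue, names(group_map))
    if (length(missing_t))
      stop("tissues absent from group mapping: ", paste(missing_t, collapse = ", "))
    group <- unname(group_map[tissue])
  }
  if (any(!nzchar(group))) stop("every sample needs a non-empty group")
  if (length(tissue_class) == 1L) tissue_class <- rep(tissue_class, length(sample_id))
  stopifnot(all(tissue_class %in% c("brain", "non_brain")))
  out <- data.frame(sample_id = sample_id, donor_id = as.character(donor_id),
                    tissue = tissue, group = group, tissue_class = tissue_class,
                    stringsAsFactors = FALSE)
  class(out) <- c("SampleTable", "data.frame")
  out
}

#' Read a sample sheet
#'
#' Delimited text with header columns `sample_id`, `donor_id`, `tissue`,
#' `group`, `tissue_class`.
#'
#' @param path file path.
#' @param sep field separator (default tab).
#' @return A `SampleTable`.
#' @export
read_sample_sheet <- function(path, sep = "\t") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  need <- c("sample_id", "donor_id", "tissue", "group", "tissue_class")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("sample sheet lacks columns: ", paste(miss, collapse = ", "))
  sample_table(df$sample_id, df$donor_id, df$tissue, df$group, df$tissue_class)
}

#' Write a sample sheet
#' @param samples a `SampleTable`.
#' @param path output path.
#' @export
write_sample_sheet <- function(samples, path) {
  utils::write.table(samples, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a Bismark-style per-cytosine report
#'
#' Tab-separated, one cytosine per row: chrom, 1-based position, strand,
#' methylated count, unmethylated count, context (an optional seventh
#' trinucleotide column is ignored). Returns a single-sample dataset;
#' zero-coverage loci are retained.
#'
#' @param path report file (may be gzip-compressed).
#' @param contexts contexts to keep (default `"CG"`).
#' @param strand optional strand filter (`"+"` or `"-"`).
#' @param sample_id column name for the sample (default: file base name).
#' @return A single-sample [meth_dataset()].
#' @export
read_cytosine_report <- function(path, contexts = "CG", strand = NULL,
                                 sample_id = NULL) {
  if (is.null(sample_id))
    sample_id <- sub("\\.(txt|tsv|CX_report\\.txt)(\\.gz)?$", "", basename(path))
  dt <- suppressWarnings(
    data.table::fread(path, header = FALSE, sep = "\t", fill = TRUE,
                      colClasses = list(character = 1),
                      showProgress = FALSE))
  if (nrow(dt) == 0L) {
    return(meth_dataset(character(), integer(), "both",
                        contexts[1], matrix(integer(), 0, 1,
                                            dimnames = list(NULL, sample_id)),
                        matrix(integer(), 0, 1,
                               dimnames = list(NULL, sample_id))))
  }
  if (ncol(dt) < 6L)
    stop("cytosine report needs >= 6 tab-separated columns, found ", ncol(dt))
  chrom <- as.character(dt[[1]])
  pos <- suppressWarnings(as.integer(dt[[2]]))
  strand_col <- as.character(dt[[3]])
  m <- suppressWarnings(as.integer(dt[[4]]))
  u <- suppressWarnings(as.integer(dt[[5]]))
  ctx <- as.character(dt[[6]])
  bad <- which(is.na(pos) | pos < 1L | is.na(m) | m < 0L | is.na(u) | u < 0L |
                 !strand_col %in% c("+", "-", "both"))
  if (length(bad))
    stop(sprintf("malformed cytosine-report line %d in %s", bad[1], path))
  bad_ctx <- which(!ctx %in% VALID_CONTEXTS)
  if (length(bad_ctx))
    stop(sprintf("unknown context symbol '%s' at line %d in %s",
                 ctx[bad_ctx[1]], bad_ctx[1], path))
  keep <- ctx %in% contexts
  if (!is.null(strand)) keep <- keep & strand_col == strand
  M <- matrix(m[keep], ncol = 1, dimnames = list(NULL, sample_id))
  Cov <- matrix((m + u)[keep], ncol = 1, dimnames = list(NULL, sample_id))
  meth_dataset(chrom[keep], pos[keep], strand_col[keep], ctx[keep], M, Cov)
}

#' Write a single-sample per-cytosine report
#'
#' Inverse of [read_cytosine_report()] up to column normalization: emits
#' chrom, position, strand, methylated count, unmethylated count, context.
#'
#' @param d single-sample `MethDataset`.
#' @param path output path (`.gz` suffix writes gzip).
#' @export
write_cytosine_report <- function(d, path) {
  stopifnot(inherits(d, "MethDataset"), ncol(d$M) == 1L)
  dt <- data.table::data.table(chrom = d$chrom, pos = d$pos, strand = d$strand,
                               m = d$M[, 1], u = d$Cov[, 1] - d$M[, 1],
                               context = d$context)
  data.table::fwrite(dt, path, sep = "\t", col.names = FALSE,
                     compress = if (grepl("\\.gz$", path)) "gzip" else "none")
  invisible(path)
}

#' Combine single-sample datasets into one multi-sample dataset
#'
#' Loci are merged by union across samples; a sample without a row at a locus
#' gets zero coverage there. All inputs must share one context/strand stratum.
#'
#' @param dsets list of single-sample `MethDataset` objects.
#' @param samples optional `SampleTable` ordering/annotating the columns.
#' @return A multi-sample `MethDataset`.
#' @export
combine_samples <- function(dsets, samples = NULL) {
  stopifnot(length(dsets) >= 1L)
  ids <- vapply(dsets, function(d) colnames(d$M)[1], character(1))
  if (!is.null(samples)) {
    stopifnot(setequal(ids, samples$sample_id))
    dsets <- dsets[match(samples$sample_id, ids)]
    ids <- samples$sample_id
  }
  key_list <- lapply(dsets, function(d)
    data.table::data.table(chrom = d$chrom, pos = d$pos, strand = d$strand,
                           context = d$context))
  all_keys <- unique(data.table::rbindlist(key_list))
  data.table::setorder(all_keys, chrom, pos)
  n <- nrow(all_keys)
  M <- matrix(0L, n, length(dsets), dimnames = list(NULL, ids))
  Cov <- M
  key_str <- paste(all_keys$chrom, all_keys$pos, all_keys$strand)
  for (j in seq_along(dsets)) {
    d <- dsets[[j]]
    idx <- match(paste(d$chrom, d$pos, d$strand), key_str)
    M[idx, j] <- d$M[, 1]
    Cov[idx, j] <- d$Cov[, 1]
  }
  meth_dataset(all_keys$chrom, all_keys$pos, all_keys$strand, all_keys$context,
               M, Cov, samples)
}

#' Collapse CpG counts across strands
#'
#' CpG dinucleotides are palindromic: the cytosine at position p on the
#' forward strand pairs with the cytosine at p+1 on the reverse strand.
#' Counts of a pair are summed into one locus at the forward-strand C
#' position with strand `"both"`. Unpaired loci pass through with their own
#' counts (an unpaired reverse-strand C is assigned its pair coordinate,
#' p-1, so that collapsed coordinates are comparable across samples).
#' Total M and Cov are conserved.
#'
#' @param d `MethDataset` of context CG with per-strand loci.
#' @return A strand-collapsed `MethDataset`.
#' @export
collapse_cpg_strands <- function(d) {
  stopifnot(inherits(d, "MethDataset"), all(d$context == "CG"))
  if (length(d$pos) == 0L) {
    return(meth_dataset(character(), integer(), "both", "CG",
                        d$M, d$Cov, d$samples))
  }
  if (all(d$strand == "both")) return(d)
  # anchor every locus at the forward-strand C position of its CpG
  anchor <- ifelse(d$strand == "-", d$pos - 1L, d$pos)
  key <- paste(d$chrom, anchor)
  grp <- match(key, unique(key))
  ng <- max(grp)
  M <- rowsum(d$M, grp, reorder = FALSE)
  Cov <- rowsum(d$Cov, grp, reorder = FALSE)
  first <- !duplicated(grp)
  meth_dataset(d$chrom[first], anchor[first], "both", "CG",
               matrix(as.integer(M), ng, ncol(d$M), dimnames = dimnames(d$M)),
               matrix(as.integer(Cov), ng, ncol(d$Cov), dimnames = dimnames(d$Cov)),
               d$samples)
}

#' Average smoothed methylation in fixed-width genomic bins
#'
#' Bin b covers the 0-based half-open interval `[b*bin_bp, (b+1)*bin_bp)`.
#' Values are unweighted means of smoothed methylation over member loci;
#' bins with no loci are dropped.
#'
#' @param s a `SmoothedDataset` (see [smooth_methylation()]).
#' @param bin_bp bin width in bp (>= 1).
#' @return A list: `bins` (data.frame chrom/start/end/n_loci, 0-based
#'   half-open) and `beta` (matrix bins x samples).
#' @export
bin_methylation <- function(s, bin_bp) {
  stopifnot(inherits(s, "SmoothedDataset"), bin_bp >= 1)
  bin <- (s$pos - 1L) %/% as.integer(bin_bp)
  key <- paste(s$chrom, bin)
  grp <- match(key, unique(key))
  first <- !duplicated(grp)
  n_loci <- as.integer(table(grp)[as.character(seq_len(max(grp)))])
  sums <- rowsum(ifelse(is.na(s$beta), 0, s$beta), grp, reorder = FALSE)
  cnts <- rowsum((!is.na(s$beta)) * 1, grp, reorder = FALSE)
  beta <- sums / cnts  # NaN where a bin/sample has no non-missing locus
  beta[cnts == 0] <- NA_real_
  colnames(beta) <- colnames(s$beta)
  bins <- data.frame(chrom = s$chrom[first],
                     start = bin[first] * as.integer(bin_bp),
                     end = (bin[first] + 1L) * as.integer(bin_bp),
                     n_loci = n_loci, stringsAsFactors = FALSE)
  list(bins = bins, beta = beta)
}

#' Construct a genomic feature set
#'
#' Intervals are 0-based half-open; overlapping intervals within one set are
#' legal (multi-state annotations are represented as one set per state).
#'
#' @param name feature-set name.
#' @param chrom,start,end interval vectors (0-based half-open, `start < end`).
#' @param label optional per-interval label.
#' @return Object of class `FeatureSet`.
#' @export
feature_set <- function(name, chrom, start, end, label = NULL) {
  start <- as.integer(start); end <- as.integer(end)
  if (length(chrom) == 1L && length(start) > 1L)
    chrom <- rep(chrom, length(start))
  stopifnot(length(chrom) == length(start), length(start) == length(end))
  if (length(start) && (any(start < 0) || any(start >= end)))
    stop("feature intervals need 0 <= start < end")
  if (is.null(label)) label <- rep(NA_character_, length(start))
  intervals <- data.frame(chrom = as.character(chrom), start = start, end = end,
                          label = as.character(label),
                          stringsAsFactors = FALSE)
  structure(list(name = name, intervals = intervals), class = "FeatureSet")
}

#' @export
print.FeatureSet <- function(x, ...) {
  cat(sprintf("FeatureSet '%s': %d intervals\n", x$name, nrow(x$intervals)))
  invisible(x)
}

#' Build promoter windows centered on transcription start sites
#'
#' Each promoter is the window `[tss - flank_bp, tss + flank_bp)` in 0-based
#' half-open coordinates (TSS given 1-based), clipped at zero. The window is
#' centered, so strand does not alter it; a flank of 2000 bp yields the
#' common 4-kb promoter definition.
#'
#' @param tss_table data.frame with columns `chrom`, `tss_pos` (1-based),
#'   `strand`, `gene`.
#' @param flank_bp half-width in bp (>= 1).
#' @return A `FeatureSet` named `"promoters"` labeled by gene.
#' @export
make_promoters <- function(tss_table, flank_bp) {
  stopifnot(flank_bp >= 1,
            all(c("chrom", "tss_pos", "gene") %in% names(tss_table)))
  tss0 <- as.integer(tss_table$tss_pos) - 1L
  start <- pmax(0L, tss0 - as.integer(flank_bp))
  end <- tss0 + as.integer(flank_bp)
  feature_set("promoters", tss_table$chrom, start, end, tss_table$gene)
}

# --- interval helpers -------------------------------------------------------

# GRanges from 1-based inclusive intervals
.granges1 <- function(chrom, start, end) {
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start = start, end = end))
}

# GRanges from 0-based half-open intervals
.granges0 <- function(chrom, start, end) {
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start = start + 1L, end = end))
}

.region_granges <- function(x) {
  df <- if (inherits(x, "RegionSet")) x$regions else x
  .granges1(df$chrom, df$start, df$end)
}

#' Overlap regions with a genomic feature set
#'
#' Region tables are 1-based inclusive, feature sets 0-based half-open; both
#' are normalized internally before comparison. `any_bp` flags regions that
#' share at least one bp with any feature; `contained` flags regions lying
#' entirely inside a single feature interval.
#'
#' @param a a `RegionSet` or a data.frame with `chrom`, `start`, `end`
#'   (1-based inclusive).
#' @param b a `FeatureSet`.
#' @param mode `"any_bp"` or `"contained"`.
#' @return A list: `flag` (logical per region), `pairs` (data.frame of
#'   region/feature index pairs), `n_overlapping` (count of flagged regions).
#' @export
overlap_regions <- function(a, b, mode = c("any_bp", "contained")) {
  mode <- match.arg(mode)
  stopifnot(inherits(b, "FeatureSet"))
  gr_a <- .region_granges(a)
  gr_b <- .granges0(b$intervals$chrom, b$intervals$start, b$intervals$end)
  hits <- GenomicRanges::findOverlaps(
    gr_a, gr_b, type = if (mode == "contained") "within" else "any")
  flag <- logical(length(gr_a))
  flag[S4Vectors::queryHits(hits)] <- TRUE
  list(flag = flag,
       pairs = data.frame(region = S4Vectors::queryHits(hits),
                          feature = S4Vectors::subjectHits(hits)),
       n_overlapping = sum(flag))
}

#' Write a region set as BED
#'
#' Emits 0-based half-open intervals with a name column (`kind_i`) and a
#' score column carrying `maxStat` for DMR-family regions or `max_sd` for
#' VMRs. An empty set yields a file holding only the header comment.
#'
#' @param r a `RegionSet` (see [region_set()]).
#' @param path output path.
#' @export
write_regions_bed <- function(r, path) {
  stopifnot(inherits(r, "RegionSet"))
  df <- r$regions
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# methscape regions: kind=%s n=%d", r$kind, nrow(df)), con)
  if (nrow(df)) {
    score <- if (r$kind == "vmr") df$max_sd else df$maxStat
    bed <- data.frame(chrom = df$chrom, start = df$start - 1L, end = df$end,
                      name = sprintf("%s_%d", r$kind, seq_len(nrow(df))),
                      score = signif(score, 8))
    utils::write.table(bed, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Read a BED3/BED4 file into a feature set
#'
#' @param path BED file (0-based half-open); `#` comment and `track` lines
#'   are skipped.
#' @param name feature-set name (default: file base name).
#' @return A `FeatureSet`.
#' @export
read_bed <- function(path, name = NULL) {
  if (is.null(name)) name <- sub("\\.bed(\\.gz)?$", "", basename(path))
  lines <- readLines(path)
  lines <- lines[!grepl("^(#|track|browser)", lines) & nzchar(lines)]
  if (!length(lines)) return(feature_set(name, character(), integer(), integer()))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ncols <- lengths(parts)
  if (any(ncols < 3L)) stop("BED line with fewer than 3 columns in ", path)
  chrom <- vapply(parts, `[[`, character(1), 1L)
  start <- as.integer(vapply(parts, `[[`, character(1), 2L))
  end <- as.integer(vapply(parts, `[[`, character(1), 3L))
  label <- ifelse(ncols >= 4L, vapply(parts, function(p)
    if (length(p) >= 4L) p[[4L]] else NA_character_, character(1)), NA_character_)
  feature_set(name, chrom, start, end, label)
}

#' Construct a region set
#'
#' A scored, sorted, non-overlapping collection of genomic regions (DMRs,
#' blocks, or VMRs) with its configuration snapshot.
#'
#' @param regions data.frame with at least `chrom`, `start`, `end`
#'   (1-based inclusive) and `n_loci`.
#' @param kind one of `"cg_dmr"`, `"cg_block"`, `"ch_dmr"`, `"vmr"`.
#' @param provenance list recording the configuration that produced the set
#'   (smoothing preset, cutoffs, seed, ...).
#' @return Object of class `RegionSet`.
#' @export
region_set <- function(regions, kind = c("cg_dmr", "cg_block", "ch_dmr", "vmr"),
                       provenance = list()) {
  kind <- match.arg(kind)
  stopifnot(all(c("chrom", "start", "end", "n_loci") %in% names(regions)))
  if (nrow(regions)) {
    o <- order(regions$chrom, regions$start)
    regions <- regions[o, , drop = FALSE]
    rownames(regions) <- NULL
    same <- regions$chrom[-1] == regions$chrom[-nrow(regions)]
    if (nrow(regions) > 1 && any(same &
        regions$start[-1] <= regions$end[-nrow(regions)]))
      stop("regions within one set must be non-overlapping")
  }
  structure(list(regions = regions, kind = kind, provenance = provenance),
            class = "RegionSet")
}

#' @export
print.RegionSet <- function(x, ...) {
  cat(sprintf("RegionSet (%s): %d regions\n", x$kind, nrow(x$regions)))
  invisible(x)
}
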