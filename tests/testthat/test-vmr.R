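# VMR procedure: coverage filter, per-tissue SD, cutoff, calling, Cook's
# filter, effect size, sharing classification.

three_tissue_samples <- function(n_per = 4L) {
  tis <- rep(c("t1", "t2", "t3"), each = n_per)
  sample_table(paste0(tis, "_", seq_along(tis)),
               rep(paste0("d", seq_len(n_per)), 3), tis)
}

test_that("coverage filter applies strict double thresholds", {
  Cov <- rbind(rep(5L, 6),                 # Cov == min_cov everywhere -> out
               c(rep(6L, 4), 5L, 5L),      # Cov > 5 in 4 samples
               rep(6L, 6))                 # Cov > 5 in all
  d <- meth_dataset(rep("chr1", 3), c(100L, 200L, 300L), "both", "CG",
                    matrix(0L, 3, 6), Cov)
  expect_equal(coverage_filter(d, min_cov = 5L, min_samples = 3L),
               c(FALSE, TRUE, TRUE))
  expect_equal(coverage_filter(d, min_cov = 5L, min_samples = 4L),
               c(FALSE, FALSE, TRUE))
  # random mask equals the brute-force count oracle
  with_seed(61, {
    Cov <- matrix(rpois(50 * 8, 6), 50, 8)
    d2 <- meth_dataset(rep("chr1", 50), seq(100L, by = 10L, length.out = 50L),
                       "both", "CG", matrix(0L, 50, 8), Cov)
    got <- coverage_filter(d2, 5L, 4L)
    want <- apply(Cov, 1, function(r) sum(r > 5) > 4)
    expect_equal(got, want)
  })
})

test_that("per-tissue SD matches the textbook formula", {
  st <- three_tissue_samples(4L)
  with_seed(67, {
    beta <- matrix(runif(30 * 12), 30, 12,
                   dimnames = list(NULL, st$sample_id))
    sm <- as_smoothed(beta, pos = seq(100L, by = 25L, length.out = 30L),
                      samples = st)
    v <- per_tissue_sd(sm, "t2")
    want <- apply(beta[, st$tissue == "t2"], 1, sd)
    expect_equal(v, want, tolerance = 1e-12)
  })
  # closed forms
  sm2 <- as_smoothed(cbind(c(0, 0.5), c(1, 0.5), c(0.5, 0.5), 0.5, 0.5,
                           0.5, 0.5, 0.5, 0.5, 0.5, 0.5, 0.5)[, 1:12],
                     pos = c(100L, 200L), samples = st)
  v2 <- per_tissue_sd(sm2, "t1")
  expect_equal(v2[2], 0)                       # identical values
  expect_error(per_tissue_sd(sm2, "absent"), "< 3 samples")
})

test_that("SD of an n=2 pair follows the closed form", {
  # sd({0,1}) = 1/sqrt(2); exercised through the missing-value path
  st <- three_tissue_samples(4L)
  beta <- matrix(0.5, 2, 12, dimnames = list(NULL, st$sample_id))
  beta[1, st$tissue == "t1"] <- c(0, 1, NA, NA)
  sm <- as_smoothed(beta, pos = c(100L, 200L), samples = st)
  v <- per_tissue_sd(sm, "t1")
  expect_equal(v[1], sqrt(0.5), tolerance = 1e-12)
  beta[2, st$tissue == "t1"] <- c(0.3, NA, NA, NA)
  sm2 <- as_smoothed(beta, pos = c(100L, 200L), samples = st)
  expect_true(is.na(per_tissue_sd(sm2, "t1")[2]))  # < 2 non-missing
})

test_that("the shared cutoff is the minimum per-tissue quantile", {
  expect_equal(select_cutoff(list(a = rep(c(0.01, 0.12), c(99, 1)),
                                  b = rep(c(0.01, 0.095), c(99, 1)),
                                  c = rep(c(0.01, 0.11), c(99, 1))),
                             q = 0.99),
               min(quantile(rep(c(0.01, 0.12), c(99, 1)), 0.99),
                   quantile(rep(c(0.01, 0.095), c(99, 1)), 0.99),
                   quantile(rep(c(0.01, 0.11), c(99, 1)), 0.99)))
  # single tissue: its own quantile (type-7)
  with_seed(71, {
    v <- runif(500)
    expect_equal(select_cutoff(list(only = v), q = 0.99),
                 quantile(v, 0.99, names = FALSE, type = 7))
  })
  expect_error(select_cutoff(list(a = numeric(0))), "empty")
})

test_that("VMR run calling matches a run-length oracle", {
  pos <- c(seq(100L, by = 50L, length.out = 15L), 5000L)
  sdv <- c(rep(0.2, 11), 0.01, rep(0.2, 3), 0.2)
  sm <- as_smoothed(matrix(0.5, 16, 3), pos = pos)
  v <- call_vmrs(sdv, sm, cutoff = 0.1, max_gap_bp = 300, min_cpgs = 11L)
  # run 1: loci 1..11 (11 CpGs, kept); run 2: loci 13..15 (3, dropped);
  # locus 16 isolated
  expect_equal(nrow(v), 1L)
  expect_equal(v$n_cpgs, 11L)
  expect_equal(v$start, 100L)
  expect_equal(v$end, 600L)
  expect_equal(v$max_sd, 0.2)
  # no locus above cutoff -> empty
  expect_equal(nrow(call_vmrs(sdv, sm, cutoff = 0.5)), 0L)
  # strictly greater: loci at the cutoff never qualify
  expect_equal(nrow(call_vmrs(rep(0.1, 16), sm, cutoff = 0.1,
                              min_cpgs = 2L)), 0L)
})

test_that("raising the SD cutoff shrinks VMRs monotonically", {
  # qualifying loci shrink as the cutoff rises, so total VMR-covered loci
  # never grow and every higher-cutoff VMR nests inside a lower-cutoff one
  # (run counts themselves can transiently rise when a long run splits)
  with_seed(73, {
    pos <- sort(sample.int(20000L, 300))
    sdv <- runif(300, 0, 0.3)
    sm <- as_smoothed(matrix(0.5, 300, 3), pos = pos)
    cuts <- seq(0.02, 0.28, by = 0.02)
    calls <- lapply(cuts, function(cf)
      call_vmrs(sdv, sm, cf, max_gap_bp = 500, min_cpgs = 3L))
    covered <- vapply(calls, function(v) sum(v$n_cpgs), integer(1))
    expect_true(all(diff(covered) <= 0L))
    for (i in seq_along(cuts)[-1]) {
      hi <- calls[[i]]; lo <- calls[[i - 1]]
      if (nrow(hi) == 0) next
      nested <- vapply(seq_len(nrow(hi)), function(r)
        any(lo$start <= hi$start[r] & lo$end >= hi$end[r]), logical(1))
      expect_true(all(nested))
    }
  })
})

test_that("Cook's distance matches the closed-form oracle and flags outliers", {
  st <- sample_table(paste0("s", 1:10), paste0("d", 1:10), rep("t1", 10))
  y <- c(rep(0.2, 9), 0.9)
  beta <- matrix(rep(y, each = 12), nrow = 12)
  colnames(beta) <- st$sample_id
  sm <- as_smoothed(beta, pos = seq(100L, by = 20L, length.out = 12L),
                    samples = st)
  vmrs <- data.frame(chrom = "chr1", start = 100L, end = 320L, n_cpgs = 12L,
                     max_sd = 0.3, mean_sd = 0.25)
  out <- cooks_filter(vmrs, sm, "t1", threshold = 0.7)
  expect_equal(out$cooks_max, max(cooks_oracle(y)), tolerance = 1e-12)
  expect_true(out$cooks_max > 0.7)
  expect_false(out$retained)
  expect_match(out$diagnostic, "outlier")

  # all equal -> D = 0, retained
  beta0 <- matrix(0.4, 12, 10, dimnames = list(NULL, st$sample_id))
  sm0 <- as_smoothed(beta0, pos = seq(100L, by = 20L, length.out = 12L),
                     samples = st)
  out0 <- cooks_filter(vmrs, sm0, "t1", threshold = 0.7)
  expect_equal(out0$cooks_max, 0)
  expect_true(out0$retained)

  # n = 2 is a declared degenerate input: rejected with a diagnostic
  st2 <- sample_table(c("a", "b"), c("d1", "d2"), rep("t2", 2))
  sm2 <- as_smoothed(matrix(0.5, 12, 2, dimnames = list(NULL, c("a", "b"))),
                     pos = seq(100L, by = 20L, length.out = 12L),
                     samples = st2)
  out2 <- cooks_filter(vmrs, sm2, "t2", threshold = 0.7)
  expect_false(out2$retained)
  expect_match(out2$diagnostic, "insufficient")
})

test_that("effect size is the range of per-sample region means", {
  st <- sample_table(paste0("s", 1:3), paste0("d", 1:3), rep("t1", 3))
  beta <- matrix(rep(c(0.2, 0.5, 0.7), each = 4), nrow = 4)
  colnames(beta) <- st$sample_id
  sm <- as_smoothed(beta, pos = seq(100L, by = 10L, length.out = 4L),
                    samples = st)
  v <- data.frame(chrom = "chr1", start = 100L, end = 130L, n_cpgs = 4L,
                  max_sd = 0.3, mean_sd = 0.2)
  expect_equal(effect_size(v, sm, "t1")$effect_size, 0.5)
  sm0 <- as_smoothed(matrix(0.4, 4, 3, dimnames = list(NULL, st$sample_id)),
                     pos = seq(100L, by = 10L, length.out = 4L), samples = st)
  expect_equal(effect_size(v, sm0, "t1")$effect_size, 0)
})

test_that("sharing classification merges transitively and partitions", {
  mk <- function(start, end) data.frame(chrom = "chr1", start = start,
                                        end = end, n_cpgs = 12L,
                                        retained = TRUE)
  # chained overlaps: t1 [100,200], t2 [150,300], t3 [250,400] merge into one
  per <- list(t1 = mk(100L, 200L), t2 = mk(150L, 300L), t3 = mk(250L, 400L))
  sh <- classify_sharing(per, all_tissues = c("t1", "t2", "t3"))
  expect_equal(nrow(sh), 1L)
  expect_equal(sh$class, "ubiquitous")
  expect_equal(sh$start, 100L)
  expect_equal(sh$end, 400L)

  # isolated VMR in one tissue -> tissue_specific; two tissues -> shared
  per2 <- list(t1 = mk(c(100L, 1000L), c(200L, 1100L)),
               t2 = mk(1050L, 1200L), t3 = mk(5000L, 5100L))
  sh2 <- classify_sharing(per2, all_tissues = c("t1", "t2", "t3"))
  sh2 <- sh2[order(sh2$start), ]
  expect_equal(sh2$class, c("tissue_specific", "shared", "tissue_specific"))
  cnt <- attr(classify_sharing(per2, c("t1", "t2", "t3")), "counts")
  expect_equal(sum(cnt), nrow(sh2))  # classes partition merged intervals
  # adjacency without a shared bp does not merge
  per3 <- list(t1 = mk(100L, 200L), t2 = mk(201L, 300L))
  expect_equal(nrow(classify_sharing(per3, c("t1", "t2"))), 2L)
  # retained == FALSE rows are ignored
  per4 <- list(t1 = rbind(mk(100L, 200L),
                          transform(mk(900L, 990L), retained = FALSE)))
  expect_equal(nrow(classify_sharing(per4, "t1")), 1L)
})
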