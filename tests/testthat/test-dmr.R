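# Locus statistics, segmentation, permutation FWER, annotation, selection.

test_that("locus F agrees with a hand-coded ANOVA oracle", {
  # 3-group toy from first principles
  beta <- rbind(c(0.1, 0.2, 0.5, 0.6, 0.9, 1.0))
  sm <- as_smoothed(beta)
  grp <- factor(c("a", "a", "b", "b", "c", "c"))
  st <- locus_fstat(sm, grp)
  expect_equal(st$F[1], anova_oracle(beta[1, ], grp), tolerance = 1e-12)
  expect_equal(unname(st$group_means[1, ]), c(0.15, 0.55, 0.95))

  # random matrix against the oracle
  with_seed(41, {
    beta <- matrix(runif(20 * 9), 20, 9)
    grp <- factor(rep(c("x", "y", "z"), each = 3))
    st <- locus_fstat(as_smoothed(beta), grp)
    for (i in c(1, 5, 20))
      expect_equal(st$F[i], anova_oracle(beta[i, ], grp), tolerance = 1e-10)
  })
})

test_that("degenerate loci follow the F conventions", {
  sm <- as_smoothed(rbind(rep(0.4, 6),      # all identical -> 0
                          c(0.2, 0.2, 0.2, 0.8, 0.8, 0.8)))  # SSW=0, SSB>0
  grp <- factor(rep(c("a", "b"), each = 3))
  st <- locus_fstat(sm, grp)
  expect_equal(st$F[1], 0)
  expect_true(is.infinite(st$F[2]))
})

test_that("two-group F equals the squared pooled t identically", {
  with_seed(43, {
    beta <- matrix(runif(30 * 8), 30, 8)
    grp <- factor(rep(c("g1", "g2"), each = 4))
    st <- locus_fstat(as_smoothed(beta), grp, signed = TRUE)
    expect_equal(st$t^2, st$F, tolerance = 1e-9)
    # signed t follows the direction of the group-1 excess
    expect_equal(sign(st$t),
                 sign(st$group_means[, 1] - st$group_means[, 2]))
    # cross-check one t against the textbook pooled formula
    y <- beta[7, ]
    v1 <- y[1:4]; v2 <- y[5:8]
    sp2 <- (3 * var(v1) + 3 * var(v2)) / 6
    t_ref <- (mean(v1) - mean(v2)) / sqrt(sp2 * (1 / 4 + 1 / 4))
    expect_equal(st$t[7], t_ref, tolerance = 1e-10)
  })
})

test_that("missing values are excluded locus-wise", {
  beta <- rbind(c(0.1, 0.2, NA, 0.8, 0.9, 0.7),
                c(0.1, NA, NA, 0.8, 0.9, 0.7))
  grp <- factor(rep(c("a", "b"), each = 3))
  st <- locus_fstat(as_smoothed(beta), grp)
  expect_equal(st$F[1], anova_oracle(c(0.1, 0.2, 0.8, 0.9, 0.7),
                                     c("a", "a", "b", "b", "b")),
               tolerance = 1e-10)
  expect_true(is.na(st$F[2]))  # group a has < 2 non-missing samples
})

test_that("segmentation matches a run-length oracle", {
  pos <- c(100L, 150L, 200L, 600L, 650L, 700L, 750L, 2000L)
  stat <- c(5, 6, 7, 8, 1, 9, 9, 9)
  sm <- as_smoothed(matrix(0.5, 8, 4), pos = pos)
  grp <- factor(c("a", "a", "b", "b"))
  fake <- structure(list(stat = stat, F = stat, t = NULL,
                         group_means = matrix(0.5, 8, 2,
                                              dimnames = list(NULL, c("a", "b"))),
                         df = c(1, 6), groups = c("a", "b"), signed = FALSE),
                    class = "LocusStat")
  # cutoff 4, max gap 300: run {100,150,200}; 600 isolated by the 400-bp
  # gap (dropped, 1 locus); 650 below cutoff breaks; {700,750}; 2000 far
  r <- call_candidates(fake, sm, cutoff = 4, max_gap_bp = 300, min_loci = 2L)
  expect_equal(nrow(r), 2L)
  expect_equal(r$start, c(100L, 700L))
  expect_equal(r$end, c(200L, 750L))
  expect_equal(r$areaStat, c(18, 18))
  expect_equal(r$maxStat, c(7, 9))
  # no locus above the cutoff -> empty
  expect_equal(nrow(call_candidates(fake, sm, cutoff = 100,
                                    max_gap_bp = 300, min_loci = 1L)), 0L)
  # all loci above, small gaps -> one region per gap-block
  r2 <- call_candidates(fake, sm, cutoff = 0.5, max_gap_bp = 1e6,
                        min_loci = 1L)
  expect_equal(nrow(r2), 1L)
  expect_equal(r2$n_loci, 8L)
})

test_that("infinite locus stats are capped before areaStat", {
  pos <- seq(100L, by = 50L, length.out = 4L)
  sm <- as_smoothed(matrix(0.5, 4, 4), pos = pos)
  fake <- structure(list(stat = c(10, Inf, 12, 1), F = c(10, Inf, 12, 1),
                         t = NULL,
                         group_means = matrix(0.5, 4, 2,
                                              dimnames = list(NULL, c("a", "b"))),
                         df = c(1, 2), groups = c("a", "b"), signed = FALSE),
                    class = "LocusStat")
  r <- call_candidates(fake, sm, cutoff = 5, max_gap_bp = 100, min_loci = 3L)
  expect_equal(r$areaStat, 10 + 12 + 12)  # Inf replaced by max finite
  expect_equal(r$maxStat, 12)
})

test_that("permutation p equals exhaustive enumeration for n = 4", {
  # 2 groups of 2: the C(4,2) = 6 label assignments are enumerable, so the
  # package's exhaustive mode must reproduce a hand-rolled enumeration
  # oracle exactly
  with_seed(47, {
    beta <- matrix(runif(40 * 4, 0.4, 0.5), 40, 4)
    # strong two-group difference on loci 10..20, low ambient noise
    beta[10:20, 1:2] <- beta[10:20, 1:2] + 0.4
    sm <- as_smoothed(beta, pos = seq(100L, by = 50L, length.out = 40L))
    grp <- factor(c("A", "A", "B", "B"))

    run_max <- function(lab) {
      st <- locus_fstat(sm, factor(lab), signed = TRUE)
      cf <- quantile(abs(st$stat[is.finite(st$stat)]), 0.75, names = FALSE)
      rr <- call_candidates(st, sm, cf, max_gap_bp = 300, min_loci = 3L)
      if (nrow(rr)) max(abs(rr$areaStat)) else 0
    }
    st <- locus_fstat(sm, grp, signed = TRUE)
    cf <- quantile(abs(st$stat[is.finite(st$stat)]), 0.75, names = FALSE)
    obs <- call_candidates(st, sm, cf, max_gap_bp = 300, min_loci = 3L)
    obs_max <- max(abs(obs$areaStat))

    # exhaustive oracle over all C(4,2) = 6 assignments
    enum_max <- apply(combn(4, 2), 2, function(ix) {
      lab <- rep("B", 4); lab[ix] <- "A"
      run_max(lab)
    })
    p_oracle <- (1 + sum(enum_max >= obs_max)) / (6 + 1)

    rs <- permutation_fwer(sm, grp, cutoff_quantile = 0.75, max_gap_bp = 300,
                           min_loci = 3L, seed = 99, exhaustive = TRUE)
    top <- which.max(abs(rs$regions$areaStat))
    expect_equal(rs$regions$fwer_p[top], p_oracle, tolerance = 1e-12)
    # the strong planted region beats every non-identity assignment
    expect_equal(obs_max, max(enum_max))
  })
})

test_that("fwer_p follows the add-one estimator", {
  with_seed(53, {
    beta <- matrix(runif(60 * 6, 0.45, 0.55), 60, 6)
    beta[25:40, 1:3] <- beta[25:40, 1:3] + 0.4
    sm <- as_smoothed(beta, pos = seq(100L, by = 40L, length.out = 60L))
    grp <- factor(rep(c("A", "B"), each = 3))

    # random draws: every region's p obeys (1 + #[max >= |area|]) / (B + 1)
    rs <- permutation_fwer(sm, grp, cutoff = 3, B = 24, seed = 3)
    pm <- rs$provenance$perm_max
    for (r in seq_len(nrow(rs$regions)))
      expect_equal(rs$regions$fwer_p[r],
                   (1 + sum(pm >= abs(rs$regions$areaStat[r]))) / 25)

    # exhaustive C(6,3) = 20 assignments: only the observed labeling and its
    # mirror reach the planted region's areaStat, so p = (1 + 2) / 21
    re <- permutation_fwer(sm, grp, cutoff = 3, seed = 3, exhaustive = TRUE)
    top <- which.max(abs(re$regions$areaStat))
    expect_equal(re$regions$fwer_p[top], 3 / 21)

    # identical seed reproduces identical results
    rs2 <- permutation_fwer(sm, grp, cutoff = 3, B = 24, seed = 3)
    expect_identical(rs$regions, rs2$regions)
    expect_error(permutation_fwer(sm, factor(rep("A", 6)), B = 2, seed = 1),
                 "degenerate")
  })
})

test_that("pairwise annotation equals the all-pairs threshold oracle", {
  beta <- rbind(rep(c(0.2, 0.2, 0.8), each = 2),
                rep(c(0.5, 0.5, 0.5), each = 2))
  sm <- as_smoothed(beta, pos = c(100L, 200L))
  grp <- factor(rep(c("A", "B", "C"), each = 2))
  regions <- data.frame(chrom = "chr1", start = c(100L, 200L),
                        end = c(100L, 200L), n_loci = 1L,
                        areaStat = c(5, 5), maxStat = c(5, 5))
  rs <- region_set(regions, "cg_dmr")
  ann <- annotate_pairwise(rs, sm, grp, delta_min = 0.1)
  expect_setequal(ann$regions$annotation[[1]], c("A|C", "B|C"))
  expect_equal(length(ann$regions$annotation[[2]]), 0L)

  with_seed(59, {
    means <- runif(6)
    beta_r <- matrix(rep(means, each = 1), nrow = 1)
    smr <- as_smoothed(beta_r, pos = 150L)
    grp6 <- factor(letters[1:6])
    # single-sample groups: annotate via region means oracle
    regions1 <- data.frame(chrom = "chr1", start = 150L, end = 150L,
                           n_loci = 1L, areaStat = 1, maxStat = 1)
    skip_if(any(table(grp6) < 1))
    ann1 <- annotate_pairwise(region_set(regions1, "cg_dmr"), smr, grp6,
                              delta_min = 0.25)
    want <- combn(letters[1:6], 2)
    keep <- abs(means[match(want[1, ], letters)] -
                  means[match(want[2, ], letters)]) >= 0.25
    expect_setequal(ann1$regions$annotation[[1]],
                    paste(want[1, keep], want[2, keep], sep = "|"))
  })
})

test_that("discriminatory selection requires the group in every pair", {
  regions <- data.frame(chrom = "chr1",
                        start = c(100L, 300L, 500L, 700L, 900L),
                        end = c(200L, 400L, 600L, 800L, 1000L),
                        n_loci = 5L, areaStat = 1,
                        maxStat = c(9, 7, 5, 3, 1))
  regions$annotation <- list(
    c("A|B", "A|C", "A|D", "A|E"),  # discriminatory for A
    c("A|B", "B|C"),                # discriminatory for B
    c("A|B", "C|D"),                # no common group
    c("A|B"),                       # both A and B qualify
    character(0))                   # unannotated
  rs <- region_set(regions, "cg_dmr")
  sel <- select_discriminatory(rs)
  expect_equal(sel$A$start, c(100L, 700L))
  expect_equal(sel$B$start, c(300L, 700L))
  expect_false(500L %in% unlist(lapply(sel, `[[`, "start")))
  # caps truncate by maxStat descending
  sel2 <- select_discriminatory(rs, caps = list(A = 1L))
  expect_equal(sel2$A$maxStat, 9)
  expect_equal(attr(sel, "total"), sum(vapply(sel, nrow, integer(1))))
})

test_that("region methylation matrix averages member loci", {
  beta <- cbind(c(0.2, 0.4, 0.9), c(0.6, 0.8, 0.1))
  sm <- as_smoothed(beta, pos = c(100L, 150L, 400L))
  regions <- data.frame(chrom = "chr1", start = c(100L, 400L),
                        end = c(150L, 400L), n_loci = c(2L, 1L))
  m <- region_methylation_matrix(regions, sm)
  expect_equal(unname(m[1, ]), c(0.3, 0.7))
  expect_equal(unname(m[2, ]), c(0.9, 0.1))  # single-locus row
  bad <- data.frame(chrom = "chr1", start = 200L, end = 300L, n_loci = 0L)
  expect_error(region_methylation_matrix(bad, sm), "no loci")
})
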