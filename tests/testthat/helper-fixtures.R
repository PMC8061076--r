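# Small in-code fixtures shared across test files.

# a tiny multi-sample dataset with hand-set counts
tiny_dataset <- function(pos = c(100L, 150L, 220L, 300L, 410L),
                         chrom = "chr1", n_samples = 4L, seed = 11) {
  with_seed(seed, {
    L <- length(pos)
    Cov <- matrix(rpois(L * n_samples, 10) + 1L, L, n_samples)
    M <- matrix(rbinom(L * n_samples, as.vector(Cov), 0.5), L, n_samples)
    colnames(M) <- colnames(Cov) <- paste0("s", seq_len(n_samples))
    meth_dataset(rep(chrom, L), pos, "both", "CG", M, Cov)
  })
}

# evenly spaced loci with constant coverage and given fractions
uniform_dataset <- function(frac, cov = 10L, spacing = 50L, n_samples = 1L,
                            chrom = "chr1") {
  L <- length(frac)
  Cov <- matrix(cov, L, n_samples)
  M <- matrix(as.integer(round(frac * cov)), L, n_samples)
  colnames(M) <- colnames(Cov) <- paste0("s", seq_len(n_samples))
  meth_dataset(rep(chrom, L), seq(100L, by = spacing, length.out = L),
               "both", "CG", M, Cov)
}

# wrap a plain beta matrix as a SmoothedDataset on given coordinates
as_smoothed <- function(beta, pos = seq(100L, by = 50L,
                                        length.out = nrow(beta)),
                        chrom = "chr1", samples = NULL) {
  beta <- as.matrix(beta)
  if (is.null(colnames(beta))) colnames(beta) <- paste0("s", seq_len(ncol(beta)))
  structure(list(chrom = rep(chrom, nrow(beta)), pos = as.integer(pos),
                 strand = rep("both", nrow(beta)),
                 context = rep("CG", nrow(beta)), beta = beta,
                 config = smoothing_config(1000, 4, degree = 2),
                 samples = samples,
                 fingerprint = c(n_loci = nrow(beta), n_samples = ncol(beta),
                                 sum_M = NA, sum_Cov = NA)),
            class = "SmoothedDataset")
}

# independent brute-force one-way ANOVA oracle (plain sums of squares)
anova_oracle <- function(values, group) {
  group <- as.factor(group)
  k <- nlevels(group)
  n <- length(values)
  mbar <- mean(values)
  mg <- tapply(values, group, mean)
  ng <- tapply(values, group, length)
  ssb <- sum(ng * (mg - mbar)^2)
  ssw <- sum((values - mg[group])^2)
  (ssb / (k - 1)) / (ssw / (n - k))
}

# independent weighted-least-squares polynomial oracle: fit value at x0
wls_oracle <- function(x, y, w, degree, x0 = 0) {
  X <- outer(x - x0, 0:degree, "^")
  W <- diag(w)
  beta <- solve(t(X) %*% W %*% X, t(X) %*% W %*% y)
  beta[1]
}

# closed-form Cook's distance oracle for an intercept-only fit
cooks_oracle <- function(y) {
  n <- length(y)
  e <- y - mean(y)
  s2 <- sum(e^2) / (n - 1)
  h <- 1 / n
  e^2 * h / (s2 * (1 - h)^2)
}

# two-sided Fisher exact p by full hypergeometric enumeration
fisher_oracle <- function(n11, n12, n21, n22) {
  r1 <- n11 + n12
  c1 <- n11 + n21
  n <- n11 + n12 + n21 + n22
  ks <- max(0, r1 + c1 - n):min(r1, c1)
  probs <- dhyper(ks, c1, n - c1, r1)
  p_obs <- dhyper(n11, c1, n - c1, r1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}
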