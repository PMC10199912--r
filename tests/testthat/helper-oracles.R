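# Independent oracle implementations used to cross-check the package's
# statistics, written as direct transcriptions of the defining formulas.

# Weir & Cockerham (1984) two-population variance components, one site at a
# time, straight from the per-population sample sizes, allele frequencies and
# heterozygote proportions.
fst_oracle_site <- function(gA, gB) {
  gA <- gA[!is.na(gA)]; gB <- gB[!is.na(gB)]
  n1 <- length(gA); n2 <- length(gB)
  if (n1 < 2 || n2 < 2) return(c(a = NA, b = NA, c = NA, fst = NA))
  p1 <- sum(gA) / (2 * n1); p2 <- sum(gB) / (2 * n2)
  h1 <- mean(gA == 1); h2 <- mean(gB == 1)
  r <- 2
  nbar <- (n1 + n2) / r
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  if (pbar <= 0 || pbar >= 1) return(c(a = NA, b = NA, c = NA, fst = NA))
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- (nbar / nc) * (s2 - 1 / (nbar - 1) *
                        (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4))
  b <- nbar / (nbar - 1) * (pbar * (1 - pbar) - (r - 1) / r * s2 -
                              (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  c(a = a, b = b, c = cc, fst = a / (a + b + cc))
}

# EHH by direct pair enumeration: fraction of carrier pairs identical over
# the site interval from the core out to column j (inclusive), among
# carriers with complete data over that interval.
ehh_oracle <- function(alleles, core, carriers, j) {
  rng <- if (j >= core) core:j else j:core
  seg <- alleles[carriers, rng, drop = FALSE]
  ok <- rowSums(is.na(seg)) == 0
  seg <- seg[ok, , drop = FALSE]
  n <- nrow(seg)
  if (n < 2) return(NA_real_)
  same <- 0L
  for (x in seq_len(n - 1))
    for (y in (x + 1):n)
      if (all(seg[x, ] == seg[y, ])) same <- same + 1L
  same / choose(n, 2)
}

# Exact HWE test by full enumeration with factorial arithmetic.
hwe_oracle <- function(nAA, nAa, naa) {
  n <- nAA + nAa + naa
  nA <- 2 * nAA + nAa
  na <- 2 * n - nA
  hs <- seq(nA %% 2, min(nA, na), by = 2)
  pr <- vapply(hs, function(h) {
    2^h * factorial(n) / (factorial((nA - h) / 2) * factorial(h) *
                            factorial((na - h) / 2))
  }, numeric(1))
  pr <- pr / sum(pr)
  obs <- pr[match(nAa, hs)]
  sum(pr[pr <= obs * (1 + 1e-12)])
}

# Small random phased matrix with optional missingness.
rand_hm <- function(n_hap, L, seed, miss = 0, chrom = "1") {
  set.seed(seed)
  p <- runif(L, 0.1, 0.9)
  a <- matrix(rbinom(n_hap * L, 1L, rep(p, each = n_hap)), n_hap, L)
  if (miss > 0) a[runif(length(a)) < miss] <- NA_integer_
  hap_matrix(a, sort(sample.int(1e6, L)), chrom,
             sprintf("S%03d", seq_len(n_hap / 2)))
}

small_vt <- function(hm, aa = "A") {
  variant_table(hm$chrom, hm$positions,
                sprintf("v%03d", seq_len(n_sites(hm))), "A", "G", aa)
}

# study-condition simulator config used across tests
test_sim_config <- function(seed, ...) sim_config(seed = seed, ...)
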