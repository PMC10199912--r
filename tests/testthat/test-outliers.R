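test_that("rank-based p-values follow rank/(N+1) with average ties", {
  p <- rank_to_pvalues(c(5, 1, 3), key = "signed")
  expect_equal(p, c(1, 3, 2) / 4)
  # maximum |score| among N = 99 -> p = 0.01
  set.seed(1)
  x <- c(100, runif(98, -1, 1))
  expect_equal(rank_to_pvalues(x, "abs")[1], 1 / 100)
  # tied top pair among N = 3 -> both 1.5/4
  expect_equal(rank_to_pvalues(c(7, 7, 1), "signed")[1:2], c(1.5, 1.5) / 4)
  # monotone transform: order of p equals reverse order of |score|
  y <- rnorm(50)
  expect_equal(order(rank_to_pvalues(y, "abs")), order(-abs(y)))
  # NA handling
  pna <- rank_to_pvalues(c(2, NA, 1), "signed")
  expect_true(is.na(pna[2]))
  expect_equal(pna[c(1, 3)], c(1, 2) / 3)
})

test_that("Fisher's combined score matches the closed form and the chi-square tail", {
  fc <- fisher_combined_score(1, 1)
  expect_equal(fc$fcs, 0)
  expect_equal(fc$p, 1)
  expect_equal(fisher_combined_score(0.01, 0.01)$fcs, -4 * log(0.01))
  expect_equal(fisher_combined_score(0.01, 0.01)$fcs, 18.42068, tolerance = 1e-6)
  expect_error(fisher_combined_score(0, 0.5), "> 0")
  # upper tail of chi-square(4) against a quadrature oracle
  set.seed(42)
  p1 <- runif(30, 1e-4, 1); p2 <- runif(30, 1e-4, 1)
  fc2 <- fisher_combined_score(p1, p2)
  dens <- function(x) x * exp(-x / 2) / 4     # chi-square(4) density
  for (i in seq_len(30)) {
    oracle <- stats::integrate(dens, fc2$fcs[i], Inf, rel.tol = 1e-12)$value
    expect_lt(abs(fc2$p[i] - oracle), 1e-10)
  }
  # FCS ordering is the p1*p2 ordering
  expect_equal(order(-fc2$fcs), order(p1 * p2))
})

test_that("top-fraction outlier sets have the stated size and invariances", {
  sc <- data.frame(chrom = "1", pos = 1:1000 * 100,
                   id = sprintf("v%04d", 1:1000), std = rnorm(1000))
  expect_equal(nrow(top_fraction_outliers(sc, "std", 0.001, "abs")), 1)
  expect_equal(nrow(top_fraction_outliers(sc, "std", 0.5, "abs")), 500)
  expect_error(top_fraction_outliers(sc, "std", 0.7, "abs"), "q must be")
  # invariance to positive rescaling
  sc2 <- sc; sc2$std <- sc$std * 37
  expect_equal(top_fraction_outliers(sc, "std", 0.01, "abs")$id,
               top_fraction_outliers(sc2, "std", 0.01, "abs")$id)
})

test_that("combining scans intersects the two top fractions and ranks by FCS", {
  set.seed(7)
  n <- 500
  fst <- structure(data.frame(chrom = "1", pos = 1:n * 1000,
                              id = sprintf("s%03d", 1:n),
                              fst = runif(n, 0, 0.2)),
                   statistic = "FST", class = c("scan_scores", "data.frame"))
  xp <- structure(data.frame(chrom = "1", pos = 1:n * 1000,
                             id = sprintf("s%03d", 1:n), std = rnorm(n)),
                  statistic = "XPEHH", class = c("scan_scores", "data.frame"))
  # plant a joint outlier
  fst$fst[100] <- 0.9
  xp$std[100] <- 8
  cb <- combine_differentiation_scans(fst, xp, q = 0.01)
  expect_true("s100" %in% cb$id)
  # members must be top-q in both scans
  top_f <- top_fraction_outliers(fst, "fst", 0.01, "signed")$id
  top_x <- top_fraction_outliers(xp, "std", 0.01, "abs")$id
  expect_true(all(cb$id %in% intersect(top_f, top_x)))
  # FCS order equals order by p1 * p2
  expect_equal(order(-cb$fcs), order(cb$p_fst * cb$p_xpehh))
  # a site extreme in one scan only is excluded
  fst2 <- fst; fst2$fst[200] <- 0.95; xp2 <- xp; xp2$std[200] <- 0
  cb2 <- combine_differentiation_scans(fst2, xp2, q = 0.01)
  expect_false("s200" %in% cb2$id)
})

test_that("region merging is single-linkage with padding and idempotent", {
  sites <- data.frame(chrom = "1", pos = c(1e6, 1.01e6, 1.31e6))
  r1 <- merge_outliers_into_regions(sites, gap_bp = 2e5, test = "t")
  expect_equal(nrow(r1), 2)        # 10 kb apart merge, 300 kb apart split
  expect_equal(r1$start[1], 1e6 - 1e5)
  expect_equal(r1$end[1], 1.01e6 + 1e5)
  sites2 <- data.frame(chrom = "1", pos = c(5e5, 5.1e5))
  expect_equal(nrow(merge_outliers_into_regions(sites2, 2e5)), 1)
  # idempotence: merging region midpoints reproduces one region per region
  mid <- data.frame(chrom = r1$chrom, pos = (r1$pos_min + r1$pos_max) / 2)
  expect_equal(nrow(merge_outliers_into_regions(mid, 2e5)), nrow(r1))
})

test_that("gene annotation uses half-open overlap", {
  regions <- merge_outliers_into_regions(
    data.frame(chrom = "1", pos = c(1e6)), gap_bp = 2e5, test = "t")
  genes <- data.frame(chrom = "1",
                      start = c(1.0e6, regions$end[1], 0),
                      end = c(1.02e6, regions$end[1] + 5e4, 1e5),
                      name = c("inside", "abutting", "far"))
  ann <- annotate_regions_with_genes(regions, genes)
  expect_equal(ann$genes, "inside")
  expect_equal(annotate_regions_with_genes(regions, genes[0, ])$genes, "")
})

test_that("pairwise LD matches hand-counted haplotype tables", {
  mk <- function(haps) {
    a <- do.call(rbind, lapply(haps, function(h)
      as.integer(strsplit(h, "")[[1]])))
    hap_matrix(a, c(100, 200), "1", sprintf("S%d", seq_len(nrow(a) / 2)))
  }
  r <- ld_pair_stats(mk(c("11", "11", "00", "00")), 1, 2)
  expect_equal(r$r2, 1); expect_equal(r$Dprime, 1)
  r2 <- ld_pair_stats(mk(c("11", "10", "01", "00")), 1, 2)
  expect_equal(r2$D, 0); expect_equal(r2$r2, 0)
  r3 <- ld_pair_stats(mk(c("11", "11", "10", "00")), 1, 2)
  expect_equal(r3$r2, 1 / 3, tolerance = 1e-12)
  expect_equal(r3$Dprime, 1)
  expect_error(ld_pair_stats(mk(c("10", "10", "10", "10")), 1, 2), "monomorphic")
  # random fixtures against a direct 2x2 count oracle
  for (rr in 1:50) {
    hm <- rand_hm(20, 2, seed = 5000 + rr)
    x <- hm$alleles[, 1]; y <- hm$alleles[, 2]
    if (length(unique(x)) < 2 || length(unique(y)) < 2) next
    res <- ld_pair_stats(hm, 1, 2)
    p11 <- mean(x == 1 & y == 1); pA <- mean(x); pB <- mean(y)
    D <- p11 - pA * pB
    expect_lt(abs(res$D - D), 1e-12)
    expect_lt(abs(res$r2 - D^2 / (pA * (1 - pA) * pB * (1 - pB))), 1e-12)
    expect_lte(abs(res$Dprime), 1 + 1e-12)
  }
})

test_that("classification depends only on overlaps and is order-invariant", {
  reg <- function(s, e) {
    r <- data.frame(chrom = "1", start = s, end = e, n_sites = 1L,
                    pos_min = s, pos_max = e, tests = "t")
    class(r) <- c("candidate_regions", "data.frame")
    r
  }
  targets <- rbind(reg(1e6, 2e6), reg(5e6, 6e6), reg(9e6, 10e6))
  class(targets) <- c("candidate_regions", "data.frame")
  srcs <- list(EUR = reg(1.9e6, 3e6), WEA = reg(20e6, 21e6))
  lad <- reg(9.5e6, 9.6e6)
  cls <- classify_candidate_signals(targets, srcs, lad)
  expect_equal(cls$classification,
               c("shared_with_EUR", "private_target", "post_admixture"))
  # permuting rows and source order changes nothing but row order
  cls2 <- classify_candidate_signals(targets[c(3, 1, 2), ],
                                     srcs[c("WEA", "EUR")], lad)
  expect_equal(cls2$classification,
               c("post_admixture", "shared_with_EUR", "private_target"))
  # abutting (zero-overlap) source region does not mark shared
  srcs2 <- list(EUR = reg(2e6, 3e6))
  expect_equal(classify_candidate_signals(targets[1, ], srcs2,
                                          NULL)$classification,
               "private_target")
  # multi-label ordering: post_admixture before shared
  cls3 <- classify_candidate_signals(targets[3, ],
                                     list(EUR = reg(9.8e6, 11e6)), lad)
  expect_equal(cls3$classification, "post_admixture;shared_with_EUR")
})

test_that("external ancestry-scan ingestion applies the LLRT cutoff", {
  f <- withr::local_tempfile(fileext = ".tsv")
  write.table(data.frame(chrom = "1", pos = c(100, 200, 300),
                         llrt = c(20, 15, 3)),
              f, sep = "\t", quote = FALSE, row.names = FALSE)
  kept <- ingest_llrt_table(f, threshold = 15)
  expect_equal(kept$pos, 100)   # strictly greater than 15
})
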