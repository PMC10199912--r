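test_that("VCF round trip preserves alleles, phase, positions and AA", {
  hm <- rand_hm(8, 12, seed = 1, miss = 0.1)
  vt <- small_vt(hm, aa = rep(c("A", "G"), 6))
  # make missingness diploid-consistent: both haplotypes of a sample missing
  a <- hm$alleles
  for (j in seq_len(ncol(a))) {
    bad <- which(is.na(a[, j]))
    mates <- ifelse(bad %% 2 == 1, bad + 1L, bad - 1L)
    a[mates, j] <- NA_integer_
  }
  hm <- hap_matrix(a, hm$positions, hm$chrom, hm$samples)
  f <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(hm, vt, f)
  back <- read_vcf(f)
  expect_identical(back$hap$alleles, hm$alleles)
  expect_equal(back$hap$positions, hm$positions)
  expect_identical(back$hap$samples, hm$samples)
  expect_identical(back$variants$aa, vt$aa)
})

test_that("unphased and half-missing genotypes are read as missing, odd records skipped", {
  f <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2",
               "##contig=<ID=1>",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"g\">",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1\tS2\tS3",
               "1\t100\ta\tA\tG\t.\tPASS\t.\tGT\t0|1\t0/1\t1|1",
               "1\t200\tb\tA\tG\t.\tPASS\t.\tGT\t.|1\t1|0\t.\t",
               "1\t300\tc\tA\tGT\t.\tPASS\t.\tGT\t0|0\t0|0\t0|0",
               "1\t400\td\tA\tG,C\t.\tPASS\t.\tGT\t0|0\t0|0\t0|0"), f)
  suppressMessages(r <- read_vcf(f))
  expect_equal(dim(r$hap$alleles), c(6L, 2L))  # indel + multiallelic skipped
  # S2 at site 100 unphased -> both haplotypes missing
  expect_true(all(is.na(r$hap$alleles[3:4, 1])))
  expect_equal(unname(r$hap$alleles[5:6, 1]), c(1L, 1L))
  # half-missing and fully missing calls
  expect_true(all(is.na(r$hap$alleles[1:2, 2])))
  expect_true(all(is.na(r$hap$alleles[5:6, 2])))
})

test_that("HWE exact test matches hand-derived and enumerated values", {
  expect_equal(hwe_exact_test(1, 0, 1), 1 / 3)
  expect_equal(hwe_exact_test(5, 0, 0), 1)     # monomorphic
  expect_error(hwe_exact_test(0, 0, 0), "all-zero")
  # probabilities over all heterozygote counts sum to 1 (n <= 25)
  for (n in c(2, 7, 25)) {
    for (nA in seq(0, 2 * n, by = 3)) {
      hs <- seq(nA %% 2, min(nA, 2 * n - nA), by = 2)
      lp <- hs * log(2) - lfactorial((nA - hs) / 2) - lfactorial(hs) -
        lfactorial((2 * n - nA - hs) / 2)
      expect_equal(sum(exp(lp - max(lp)) / sum(exp(lp - max(lp)))), 1,
                   tolerance = 1e-12)
    }
  }
})

test_that("HWE exact test equals full-enumeration oracle for all configurations n <= 25", {
  worst <- 0
  for (n in 1:25) {
    for (nA in 0:(2 * n)) {
      hmax <- min(nA, 2 * n - nA)
      for (h in seq(nA %% 2, hmax, by = 2)) {
        nAA <- (nA - h) / 2
        naa <- n - nAA - h
        worst <- max(worst, abs(hwe_exact_test(nAA, h, naa) -
                                  hwe_oracle(nAA, h, naa)))
      }
    }
  }
  expect_lt(worst, 1e-9)
})

test_that("QC filters apply in order with correct per-filter accounting", {
  # 10 sites x 40 diploids, engineered failures
  set.seed(5)
  n <- 40
  a <- matrix(rbinom(2 * n * 10, 1L, 0.5), 2 * n, 10)
  # sites 1-2 fail MAF: one minor-allele copy among 80 haplotypes
  a[, 1] <- c(1L, rep(0L, 2 * n - 1))
  a[, 2] <- c(rep(1L, 2 * n - 1), 0L)
  # site 3 fails missingness (25% of samples missing)
  a[1:20, 3] <- NA_integer_
  # site 4 fails HWE: every individual heterozygous (p ~ 1e-11 at n = 40)
  a[, 4] <- rep(c(0L, 1L), n)
  # remaining sites: balanced random genotypes, HWE-compatible
  for (j in 5:10) a[, j] <- rbinom(2 * n, 1L, 0.5)
  hm <- hap_matrix(a, seq(1000, by = 1000, length.out = 10), "1",
                   sprintf("S%02d", 1:n))
  vt <- small_vt(hm)
  spec <- pop_spec(setNames(rep("pop1", n), hm$samples))
  qc <- apply_qc_filters(hm, vt, spec,
                         list(missingness = 0.10, hwe_p = 1e-8, maf = 0.05))
  rep <- setNames(qc$report$n, qc$report$filter)
  expect_equal(rep[["missingness"]], 1)
  expect_equal(rep[["maf"]], 2)
  expect_equal(rep[["hwe"]], 1)
  expect_equal(rep[["kept"]], 6)
  expect_equal(n_sites(qc$hap), 6)

  # site failing both missingness and MAF counts under missingness only
  a2 <- a
  a2[, 1][!is.na(a2[, 1])] <- 0L
  a2[1:20, 1] <- NA_integer_
  hm2 <- hap_matrix(a2, hm$positions, "1", hm$samples)
  qc2 <- apply_qc_filters(hm2, vt, spec,
                          list(missingness = 0.10, hwe_p = 1e-8, maf = 0.05))
  rep2 <- setNames(qc2$report$n, qc2$report$filter)
  expect_equal(rep2[["missingness"]], 2)

  # no-op thresholds -> identity
  qc3 <- apply_qc_filters(hm, vt, spec,
                          list(missingness = 1.0, hwe_p = 0, maf = 0))
  expect_equal(n_sites(qc3$hap), 10)
  # idempotence
  qc4 <- apply_qc_filters(qc$hap, qc$variants, spec,
                          list(missingness = 0.10, hwe_p = 1e-8, maf = 0.05))
  expect_equal(n_sites(qc4$hap), n_sites(qc$hap))
})

test_that("LD pruning respects the r2 bound inside windows and keeps independent sites", {
  hm <- rand_hm(40, 30, seed = 9)
  kept <- ld_prune(hm, window_bp = 50000, step_snps = 5, r2_max = 0.5)
  dos <- genotype_dosage(hm)[, kept, drop = FALSE]
  pos <- hm$positions[kept]
  r2 <- suppressWarnings(cor(dos, use = "pairwise.complete.obs"))^2
  for (i in seq_along(kept))
    for (j in seq_along(kept))
      if (j > i && pos[j] - pos[i] <= 50000)
        expect_lte(r2[i, j], 0.5 + 1e-12)

  # duplicated column -> exactly one of the pair survives
  a <- hm$alleles
  a[, 2] <- a[, 1]
  pos2 <- hm$positions
  pos2[2] <- pos2[1] + 1
  hm2 <- hap_matrix(a[, order(pos2)], sort(pos2), "1", hm$samples)
  kept2 <- ld_prune(hm2)
  expect_equal(sum(kept2 %in% c(1L, 2L)), 1L)

  # pruning is idempotent
  expect_equal(ld_prune(subset_sites(hm, kept)), seq_along(kept))
})

test_that("polarization flips alt-ancestral columns and drops unknowns", {
  hm <- rand_hm(6, 9, seed = 3, miss = 0.1)
  aa <- rep(c("A", "G", "N"), each = 3)
  vt <- small_vt(hm, aa = aa)
  pol <- polarize_to_ancestral(hm, vt)
  expect_equal(pol$dropped, 7:9)
  expect_equal(n_sites(pol$hap), 6)
  expect_identical(pol$hap$alleles[, 1:3], hm$alleles[, 1:3])
  expect_identical(pol$hap$alleles[, 4:6], 1L - hm$alleles[, 4:6])
  expect_true(all(is.na(pol$hap$alleles[, 4:6]) == is.na(hm$alleles[, 4:6])))
  # AA = ref everywhere -> identity
  pol2 <- polarize_to_ancestral(hm, small_vt(hm, aa = "A"))
  expect_identical(pol2$hap$alleles, hm$alleles)
  expect_equal(length(pol2$dropped), 0)
})
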