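#' Read phased genotypes from VCF
#'
#' Parses a VCF (v4.2) with phased GT fields into a \code{\link{hap_matrix}}
#' and a \code{\link{variant_table}}. Multiallelic records and indels are
#' skipped (counted in a message). Unphased or half-missing genotypes are
#' recorded as missing on both haplotypes, as downstream haplotype statistics
#' cannot use them. The ancestral allele is taken from the \code{AA} INFO tag
#' when present.
#'
#' @param path VCF file (plain or gzipped).
#' @param samples optional character vector restricting (and ordering) the
#'   samples read.
#' @return list with elements \code{hap} (\code{hap_matrix}) and
#'   \code{variants} (\code{variant_table}).
#' @export
read_vcf <- function(path, samples = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  gt <- v@gt
  have <- colnames(gt)[-1L]
  if (is.null(samples)) samples <- have
  if (!length(intersect(samples, have)))
    stop("none of the requested samples present in ", path)
  miss <- setdiff(samples, have)
  if (length(miss)) stop("samples absent from VCF: ", paste(miss, collapse = ", "))

  snp <- nchar(fix$REF) == 1L & !is.na(fix$ALT) & nchar(fix$ALT) == 1L &
    !grepl(",", fix$ALT, fixed = TRUE)
  n_skip <- sum(!snp)
  if (n_skip > 0)
    message("read_vcf: skipped ", n_skip, " multiallelic/indel record(s)")
  fix <- fix[snp, , drop = FALSE]
  gt <- gt[snp, , drop = FALSE]

  fmt <- strsplit(gt[, 1L], ":", fixed = TRUE)
  gti <- vapply(fmt, function(f) match("GT", f), integer(1L))
  if (anyNA(gti)) stop("records without GT field")

  L <- nrow(fix)
  n <- length(samples)
  a1 <- matrix(NA_integer_, L, n)
  a2 <- matrix(NA_integer_, L, n)
  for (j in seq_len(n)) {
    cell <- gt[, samples[j]]
    g <- vapply(strsplit(cell, ":", fixed = TRUE),
                function(x, i) x[[1L]][i][1L], character(1L), i = 1L)
    # only fully phased, fully called genotypes are usable as haplotypes
    ok <- grepl("^[01]\\|[01]$", g)
    a1[ok, j] <- as.integer(substr(g[ok], 1L, 1L))
    a2[ok, j] <- as.integer(substr(g[ok], 3L, 3L))
  }
  alleles <- matrix(NA_integer_, 2L * n, L)
  alleles[seq(1L, 2L * n, by = 2L), ] <- t(a1)
  alleles[seq(2L, 2L * n, by = 2L), ] <- t(a2)

  aa <- rep(NA_character_, L)
  info <- fix$INFO
  hit <- regmatches(info, regexpr("(?<=^AA=|;AA=)[^;]+", info, perl = TRUE))
  has <- grepl("(^|;)AA=", info)
  aa[has] <- hit
  ord <- order(as.numeric(fix$POS))
  vt <- variant_table(fix$CHROM[ord], as.numeric(fix$POS)[ord],
                      ifelse(is.na(fix$ID[ord]) | fix$ID[ord] == ".",
                             paste0(fix$CHROM[ord], ":", fix$POS[ord]), fix$ID[ord]),
                      fix$REF[ord], fix$ALT[ord], aa[ord])
  hm <- hap_matrix(alleles[, ord, drop = FALSE], vt$pos, vt$chrom[1L], samples)
  list(hap = hm, variants = vt)
}

#' Write phased genotypes to VCF v4.2
#'
#' Inverse of \code{\link{read_vcf}} for in-memory data: allele code 1 is
#' written as ALT, missing genotypes as \code{.|.}, and the ancestral allele
#' (when known) as the \code{AA} INFO tag.
#'
#' @param hm a \code{hap_matrix}
#' @param vt matching \code{variant_table}
#' @param path output path
#' @export
write_vcf <- function(hm, vt, path) {
  stopifnot(n_sites(hm) == nrow(vt))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               sprintf("##contig=<ID=%s>", hm$chrom),
               "##INFO=<ID=AA,Number=1,Type=String,Description=\"Ancestral allele\">",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", hm$samples), collapse = "\t")), con)
  if (n_sites(hm) == 0L) return(invisible(path))
  a1 <- hm$alleles[seq(1L, n_hap(hm), by = 2L), , drop = FALSE]
  a2 <- hm$alleles[seq(2L, n_hap(hm), by = 2L), , drop = FALSE]
  info <- ifelse(is.na(vt$aa), ".", paste0("AA=", vt$aa))
  lines <- character(nrow(vt))
  for (s in seq_len(nrow(vt))) {
    g <- paste0(a1[, s], "|", a2[, s])
    g[is.na(a1[, s]) | is.na(a2[, s])] <- ".|."
    lines[s] <- paste(c(vt$chrom[s], format(vt$pos[s], scientific = FALSE),
                        vt$id[s], vt$ref[s], vt$alt[s], ".", "PASS",
                        info[s], "GT", g), collapse = "\t")
  }
  writeLines(lines, con)
  invisible(path)
}

#' Exact test of Hardy-Weinberg equilibrium
#'
#' Two-sided exact test conditioning on the observed allele counts: the
#' p-value is the sum of probabilities of all heterozygote counts (of the
#' same parity as the observed one) whose conditional probability does not
#' exceed that of the observed count. The conditional distribution is
#' \eqn{P(h) \propto 2^h n! / (n_{AA}! h! n_{aa}!)} scaled by the allele-count
#' multinomial constant.
#'
#' @param n_AA,n_Aa,n_aa genotype counts (vectors recycled to equal length).
#' @return numeric vector of p-values in (0, 1].
#' @export
hwe_exact_test <- function(n_AA, n_Aa, n_aa) {
  m <- max(length(n_AA), length(n_Aa), length(n_aa))
  n_AA <- rep_len(as.integer(n_AA), m)
  n_Aa <- rep_len(as.integer(n_Aa), m)
  n_aa <- rep_len(as.integer(n_aa), m)
  if (any(n_AA < 0 | n_Aa < 0 | n_aa < 0)) stop("negative genotype count")
  vapply(seq_len(m), function(i) {
    n <- n_AA[i] + n_Aa[i] + n_aa[i]
    if (n < 1L) stop("all-zero genotype counts")
    nA <- 2L * n_AA[i] + n_Aa[i]
    na <- 2L * n - nA
    h <- seq.int(nA %% 2L, min(nA, na), by = 2L)
    # log conditional probability up to a constant shared by all h
    lp <- h * log(2) - lfactorial((nA - h) / 2) - lfactorial(h) -
      lfactorial((na - h) / 2)
    p <- exp(lp - max(lp))
    p <- p / sum(p)
    obs <- p[match(n_Aa[i], h)]
    sum(p[p <= obs * (1 + 1e-12)])
  }, numeric(1L))
}

# internal: per-site fraction of missing haplotype calls
site_missingness <- function(hm) colMeans(is.na(hm$alleles))

# internal: derived/alt allele frequency over a set of haplotype rows,
# missing excluded from numerator and denominator
hap_freq <- function(alleles, rows = seq_len(nrow(alleles))) {
  a <- alleles[rows, , drop = FALSE]
  colSums(a, na.rm = TRUE) / colSums(!is.na(a))
}

#' Apply the standard site-QC filters
#'
#' Filters are applied in order: site missingness, per-population exact HWE,
#' minor-allele frequency, biallelic check. A site failing several filters is
#' counted only under the first in this order. MAF and missingness are
#' computed on the analysis sample set (all samples assigned in \code{spec}
#' and present in \code{hm}); HWE is computed per population and a site fails
#' if any population falls below the p-value floor.
#'
#' @param hm a \code{hap_matrix}
#' @param vt matching \code{variant_table}
#' @param spec a \code{pop_spec}
#' @param thresholds list with elements \code{missingness} (max fraction,
#'   default 0.10), \code{hwe_p} (min p, default 1e-8), \code{maf} (min minor
#'   allele frequency, default 0.05).
#' @return list: \code{hap}, \code{variants} (filtered), \code{kept} (site
#'   index), \code{report} (data.frame of removal counts per filter).
#' @export
apply_qc_filters <- function(hm, vt, spec,
                             thresholds = list(missingness = 0.10,
                                               hwe_p = 1e-8, maf = 0.05)) {
  th <- utils::modifyList(list(missingness = 0.10, hwe_p = 1e-8, maf = 0.05),
                          thresholds)
  ana <- intersect(names(spec$assignments), hm$samples)
  if (!length(ana)) stop("no assigned samples present in the haplotype matrix")
  sub <- subset_samples(hm, ana)
  L <- n_sites(hm)

  fail_miss <- site_missingness(sub) > th$missingness

  dos <- genotype_dosage(sub)
  pops <- spec$assignments[ana]
  fail_hwe <- rep(FALSE, L)
  if (th$hwe_p > 0) {
    for (p in unique(pops)) {
      dp <- dos[pops == p, , drop = FALSE]
      nAA <- colSums(dp == 2L, na.rm = TRUE)
      nAa <- colSums(dp == 1L, na.rm = TRUE)
      naa <- colSums(dp == 0L, na.rm = TRUE)
      ok <- (nAA + nAa + naa) >= 1L
      pv <- rep(1, L)
      pv[ok] <- hwe_exact_test(nAA[ok], nAa[ok], naa[ok])
      fail_hwe <- fail_hwe | pv < th$hwe_p
    }
  }

  p <- hap_freq(sub$alleles)
  maf <- pmin(p, 1 - p)
  fail_maf <- is.na(maf) | maf < th$maf
  if (th$maf <= 0) fail_maf <- rep(FALSE, L)

  fail_biallelic <- nchar(vt$ref) != 1L | nchar(vt$alt) != 1L

  first <- rep(0L, L)
  first[fail_biallelic] <- 4L
  first[fail_maf] <- 3L
  first[fail_hwe] <- 2L
  first[fail_miss] <- 1L
  keep <- first == 0L

  report <- data.frame(
    filter = c("input", "missingness", "hwe", "maf", "not_biallelic", "kept"),
    n = c(L, sum(first == 1L), sum(first == 2L), sum(first == 3L),
          sum(first == 4L), sum(keep)))
  if (!any(keep)) message("apply_qc_filters: no sites survive QC")
  list(hap = subset_sites(hm, keep), variants = vt[keep, , drop = FALSE],
       kept = which(keep), report = report)
}

#' Greedy LD pruning in sliding windows
#'
#' Mirrors the common pruning convention: within each window of
#' \code{window_bp}, the later site of any pair with squared genotype-dosage
#' correlation above \code{r2_max} is dropped; the window start advances by
#' \code{step_snps} sites. r-squared is computed on diploid dosages with
#' pairwise-complete observations.
#'
#' @param hm a \code{hap_matrix}
#' @param window_bp window width in bp (default 50000).
#' @param step_snps window step in SNPs (default 5).
#' @param r2_max maximum allowed r-squared (default 0.5).
#' @return integer vector of kept site indices.
#' @export
ld_prune <- function(hm, window_bp = 50000, step_snps = 5, r2_max = 0.5) {
  L <- n_sites(hm)
  if (L < 1L) stop("ld_prune: empty matrix")
  dos <- genotype_dosage(hm)
  removed <- logical(L)
  pos <- hm$positions
  i <- 1L
  while (i <= L) {
    jmax <- max(which(pos <= pos[i] + window_bp))
    win <- i:jmax
    win <- win[!removed[win]]
    if (length(win) > 1L) {
      r2 <- suppressWarnings(stats::cor(dos[, win, drop = FALSE],
                                        use = "pairwise.complete.obs"))^2
      for (a in seq_along(win)) {
        if (removed[win[a]]) next
        for (b in seq_along(win)) {
          if (b <= a || removed[win[b]]) next
          if (!is.na(r2[a, b]) && r2[a, b] > r2_max) removed[win[b]] <- TRUE
        }
      }
    }
    i <- i + as.integer(step_snps)
  }
  which(!removed)
}

#' Polarize allele codes to the ancestral state
#'
#' After polarization allele code 1 means the derived allele. Sites where the
#' ancestral allele equals ALT are complemented (missing preserved); sites
#' with an unknown ancestral state, or one matching neither REF nor ALT, are
#' dropped.
#'
#' @param hm a \code{hap_matrix}
#' @param vt matching \code{variant_table} with the \code{aa} column filled
#'   where known.
#' @return list: \code{hap}, \code{variants} (kept sites, with a
#'   \code{flipped} logical column), \code{dropped} (indices of removed sites).
#' @export
polarize_to_ancestral <- function(hm, vt) {
  stopifnot(n_sites(hm) == nrow(vt))
  is_ref <- !is.na(vt$aa) & vt$aa == vt$ref
  is_alt <- !is.na(vt$aa) & vt$aa == vt$alt
  drop <- which(!(is_ref | is_alt))
  keep <- which(is_ref | is_alt)
  a <- hm$alleles[, keep, drop = FALSE]
  flip <- is_alt[keep]
  if (any(flip)) a[, flip] <- 1L - a[, flip]
  vt2 <- vt[keep, , drop = FALSE]
  vt2$flipped <- flip
  hm2 <- hap_matrix(a, hm$positions[keep], hm$chrom, hm$samples)
  list(hap = hm2, variants = vt2, dropped = drop)
}

#' Read a BED file of gene (or other) intervals
#'
#' BED is 0-based half-open; the 4th column (name) is kept when present.
#' @param path BED3/BED4 file.
#' @return data.frame with columns chrom, start, end, name.
#' @export
read_bed <- function(path) {
  df <- utils::read.table(path, header = FALSE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (ncol(df) < 3L) stop("BED needs at least 3 columns")
  out <- data.frame(chrom = as.character(df[[1L]]), start = as.numeric(df[[2L]]),
                    end = as.numeric(df[[3L]]),
                    name = if (ncol(df) >= 4L) as.character(df[[4L]])
                           else paste0("feature_", seq_len(nrow(df))),
                    stringsAsFactors = FALSE)
  out
}
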