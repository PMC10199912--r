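#' Derived-allele frequencies for a sample group
#'
#' Missing haplotype calls are excluded from both numerator and denominator.
#'
#' @param hm a \code{hap_matrix} (allele code 1 = derived after polarization,
#'   otherwise 1 = ALT).
#' @param spec optional \code{pop_spec}; with \code{group}, restricts to that
#'   group's samples.
#' @param group group or population name.
#' @return numeric vector of per-site frequencies (NaN where no calls).
#' @export
allele_frequencies <- function(hm, spec = NULL, group = NULL) {
  rows <- seq_len(n_hap(hm))
  if (!is.null(group)) {
    if (is.null(spec)) stop("group given without a pop_spec")
    sam <- intersect(group_samples(spec, group), hm$samples)
    if (!length(sam)) stop("group '", group, "' has no samples in the matrix")
    rows <- hap_rows(hm, sam)
  }
  hap_freq(hm$alleles, rows)
}

#' Per-SNP Weir-Cockerham FST between two groups
#'
#' Computes the 1984 variance components for two populations of diploids:
#' \code{a} (among populations), \code{b} (among individuals within
#' populations) and \code{c} (within individuals), from per-population sample
#' sizes, allele frequencies and observed heterozygosity; the estimator is
#' \code{a / (a + b + c)}. Sites monomorphic across both groups (or with no
#' data in a group) are returned as \code{NA} and flagged undefined.
#' Individuals with a missing haplotype at a site are excluded at that site.
#'
#' @param hm a \code{hap_matrix}
#' @param spec a \code{pop_spec}
#' @param groupA,groupB disjoint groups with at least 2 diploids each.
#' @param vt optional \code{variant_table} supplying chrom/pos/id columns.
#' @return \code{scan_scores} data.frame: chrom, pos, id, a, b, c, fst,
#'   undefined.
#' @export
weir_cockerham_fst <- function(hm, spec, groupA, groupB, vt = NULL) {
  sA <- intersect(group_samples(spec, groupA), hm$samples)
  sB <- intersect(group_samples(spec, groupB), hm$samples)
  if (length(intersect(sA, sB))) stop("groups overlap")
  if (length(sA) < 2L || length(sB) < 2L) stop("each group needs >= 2 diploids")
  dos <- genotype_dosage(hm)
  comp <- function(sam) {
    d <- dos[sam, , drop = FALSE]
    n <- colSums(!is.na(d))
    list(n = n, p = colSums(d, na.rm = TRUE) / (2 * n),
         h = colSums(d == 1L, na.rm = TRUE) / n)
  }
  A <- comp(sA); B <- comp(sB)
  r <- 2
  nbar <- (A$n + B$n) / r
  nc <- (r * nbar - (A$n^2 + B$n^2) / (r * nbar)) / (r - 1)
  pbar <- (A$n * A$p + B$n * B$p) / (r * nbar)
  s2 <- (A$n * (A$p - pbar)^2 + B$n * (B$p - pbar)^2) / ((r - 1) * nbar)
  hbar <- (A$n * A$h + B$n * B$h) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar * (2 * nbar - 1) / (4 * nbar))
  cc <- hbar / 2
  undef <- A$n < 2L | B$n < 2L | pbar <= 0 | pbar >= 1
  fst <- a / (a + b + cc)
  fst[undef] <- NA_real_
  a[undef] <- b[undef] <- cc[undef] <- NA_real_
  df <- data.frame(
    chrom = if (is.null(vt)) hm$chrom else vt$chrom,
    pos = hm$positions,
    id = if (is.null(vt)) paste0(hm$chrom, ":", hm$positions) else vt$id,
    a = a, b = b, c = cc, fst = fst, undefined = undef)
  new_scan_scores(df, "FST",
                  list(groupA = groupA, groupB = groupB,
                       nA = length(sA), nB = length(sB)))
}

# internal EHH walk over one direction from a core site.
#
# rows: haplotype row indices carrying the core allele (no NA at core);
# grp0: initial partition of those rows (all 1s for an allele class, the core
# allele itself for pooled mode). Haplotypes hitting a missing call are
# dropped from that distance onward and the pair denominator follows the
# retained carriers. Stops at the chromosome end, at a gap > maxgap_bp, when
# fewer than 2 carriers remain, once EHH < stop_below (that point is kept),
# or after max_steps extension points.
ehh_walk <- function(alleles, positions, core, rows, grp0, step,
                     maxgap_bp = 2e5, stop_below = 0, max_steps = Inf) {
  dist <- 0
  ehh <- 1
  ended <- "edge"
  grp <- grp0
  j <- core
  L <- length(positions)
  taken <- 0L
  while (taken < max_steps) {
    jn <- j + step
    if (jn < 1L || jn > L) { ended <- "edge"; break }
    if (abs(positions[jn] - positions[j]) > maxgap_bp) { ended <- "gap"; break }
    a <- alleles[rows, jn]
    ok <- !is.na(a)
    if (sum(ok) < 2L) { ended <- "carriers"; break }
    rows <- rows[ok]
    grp <- grp[ok]
    key <- grp * 2L + a[ok]
    grp <- match(key, unique(key))
    n <- length(grp)
    cnt <- tabulate(grp)
    e <- sum(cnt * (cnt - 1)) / (n * (n - 1))
    dist <- c(dist, abs(positions[jn] - positions[core]))
    ehh <- c(ehh, e)
    j <- jn
    taken <- taken + 1L
    if (e < stop_below) { ended <- "cutoff"; break }
  }
  if (taken >= max_steps && ended == "edge") ended <- "maxsteps"
  list(distance = dist, ehh = ehh, ended = ended)
}

#' Extended haplotype homozygosity decay curve
#'
#' EHH at a distance is the probability that two random haplotypes carrying
#' the core allele are identical over the interval from the core site out to
#' that distance: \eqn{\sum_i \binom{n_i}{2} / \binom{n_c}{2}} over the
#' partition of carriers into identical extended haplotypes. EHH at distance
#' 0 is 1 by definition. \code{allele_mode = "pooled"} uses all haplotypes
#' (the core allele itself is part of the extended haplotype identity).
#'
#' @param hm a \code{hap_matrix}
#' @param core site index of the core SNP.
#' @param allele_mode one of \code{"derived"}, \code{"ancestral"},
#'   \code{"pooled"}.
#' @param direction \code{"downstream"} (increasing position) or
#'   \code{"upstream"}.
#' @param maxgap_bp truncate the curve at an inter-site gap larger than this.
#' @param stop_below stop extending once EHH falls below this value (the
#'   first sub-threshold point is retained); 0 walks to the chromosome end.
#' @return object of class \code{ehh_curve}: core, allele, direction,
#'   distance, ehh, n_core, ended, valid.
#' @export
ehh_curve <- function(hm, core, allele_mode = c("derived", "ancestral", "pooled"),
                      direction = c("downstream", "upstream"),
                      maxgap_bp = 2e5, stop_below = 0) {
  allele_mode <- match.arg(allele_mode)
  direction <- match.arg(direction)
  a0 <- hm$alleles[, core]
  rows <- switch(allele_mode,
                 derived = which(!is.na(a0) & a0 == 1L),
                 ancestral = which(!is.na(a0) & a0 == 0L),
                 pooled = which(!is.na(a0)))
  out <- list(core = core, allele = allele_mode, direction = direction,
              n_core = length(rows), distance = 0, ehh = 1,
              ended = "none", valid = length(rows) >= 2L)
  class(out) <- "ehh_curve"
  if (!out$valid) return(out)
  grp0 <- if (allele_mode == "pooled") as.integer(a0[rows]) + 1L
          else rep(1L, length(rows))
  w <- ehh_walk(hm$alleles, hm$positions, core, rows, grp0,
                if (direction == "downstream") 1L else -1L,
                maxgap_bp, stop_below)
  out$distance <- w$distance
  out$ehh <- w$ehh
  out$ended <- w$ended
  out
}

#' Integrate an EHH curve into iHH
#'
#' Trapezoidal integral of EHH over physical distance, outward from the core,
#' over the consecutive points with EHH at or above \code{cutoff}. A curve
#' that never falls below the cutoff before it ends (chromosome edge, gap, or
#' carrier exhaustion) is flagged censored; censored sites are excluded from
#' the scans to avoid edge-truncated, downward-biased iHH.
#'
#' @param curve an \code{ehh_curve}.
#' @param cutoff EHH truncation level (default 0.05).
#' @return list with \code{ihh} (bp x EHH units) and \code{censored}.
#' @export
integrate_ehh <- function(curve, cutoff = 0.05) {
  if (!isTRUE(curve$valid)) return(list(ihh = NA_real_, censored = NA))
  e <- curve$ehh
  d <- curve$distance
  if (!length(e)) stop("empty curve")
  below <- which(e < cutoff)
  k <- if (length(below)) below[1L] - 1L else length(e)
  ihh <- if (k >= 2L) sum(diff(d[1:k]) * (e[1:(k - 1L)] + e[2:k]) / 2) else 0
  list(ihh = ihh, censored = !length(below))
}

# internal: both-direction iHH for one allele class at one core site
ihh_both <- function(hm, core, allele_mode, cutoff, maxgap_bp) {
  tot <- 0
  for (dir in c("downstream", "upstream")) {
    cv <- ehh_curve(hm, core, allele_mode, dir, maxgap_bp, stop_below = cutoff)
    if (!isTRUE(cv$valid)) return(NA_real_)
    ii <- integrate_ehh(cv, cutoff)
    if (isTRUE(ii$censored)) return(NA_real_)
    tot <- tot + ii$ihh
  }
  tot
}

#' Integrated haplotype score (iHS) scan
#'
#' Per qualifying site the raw score is \eqn{\ln(iHH_A / iHH_D)}, the log
#' ratio of ancestral to derived integrated EHH (both directions summed per
#' allele). Raw scores are standardized to mean 0 / SD 1 within equal-width
#' derived-allele-frequency bins spanning \code{[maf_min, 1 - maf_min]}; bins
#' holding fewer than 2 scored sites are merged with a neighbour (messaged).
#' Sites with a censored or zero iHH, or with fewer than 2 carriers of either
#' allele, are excluded. Requires polarized data (allele code 1 = derived).
#'
#' @param hm a \code{hap_matrix} (optionally already subset to the scanned
#'   group via \code{spec}/\code{group}).
#' @param vt matching \code{variant_table}.
#' @param spec,group optional group restriction.
#' @param maf_min minimum minor (derived or ancestral) frequency, default 0.05.
#' @param n_bins number of frequency bins for standardization, default 20.
#' @param cutoff EHH integration cutoff, default 0.05.
#' @param maxgap_bp maximum tolerated inter-site gap, default 200 kb.
#' @return \code{scan_scores}: chrom, pos, id, freq_derived, ihh_a, ihh_d,
#'   raw, bin, std (NA rows = excluded sites), with per-bin normalization
#'   statistics in the \code{normalization} attribute.
#' @export
ihs_scan <- function(hm, vt, spec = NULL, group = NULL, maf_min = 0.05,
                     n_bins = 20, cutoff = 0.05, maxgap_bp = 2e5) {
  if (!is.null(group)) hm <- subset_samples(hm, intersect(group_samples(spec, group),
                                                          hm$samples))
  L <- n_sites(hm)
  p <- hap_freq(hm$alleles)
  raw <- rep(NA_real_, L)
  ihh_a <- rep(NA_real_, L)
  ihh_d <- rep(NA_real_, L)
  scored <- !is.na(p) & p >= maf_min & p <= 1 - maf_min
  for (i in which(scored)) {
    iA <- ihh_both(hm, i, "ancestral", cutoff, maxgap_bp)
    iD <- ihh_both(hm, i, "derived", cutoff, maxgap_bp)
    if (is.na(iA) || is.na(iD) || iA <= 0 || iD <= 0) next
    ihh_a[i] <- iA
    ihh_d[i] <- iD
    raw[i] <- log(iA / iD)
  }
  ok <- !is.na(raw)
  breaks <- seq(maf_min, 1 - maf_min, length.out = n_bins + 1L)
  bin <- rep(NA_integer_, L)
  bin[ok] <- pmin(pmax(findInterval(p[ok], breaks, rightmost.closed = TRUE), 1L),
                  n_bins)
  # merge underfilled bins into their nearest lower (else upper) occupied bin
  repeat {
    cnt <- table(factor(bin[ok], levels = seq_len(n_bins)))
    small <- which(cnt > 0 & cnt < 2)
    if (!length(small)) break
    b <- small[1L]
    occupied <- setdiff(which(cnt > 0), b)
    if (!length(occupied)) break
    tgt <- occupied[which.min(abs(occupied - b))]
    message("ihs_scan: merging frequency bin ", b, " (n=", cnt[b],
            ") into bin ", tgt)
    bin[!is.na(bin) & bin == b] <- as.integer(tgt)
  }
  std <- rep(NA_real_, L)
  stats_list <- list()
  for (b in sort(unique(bin[ok]))) {
    sel <- ok & bin == b
    m <- mean(raw[sel]); s <- stats::sd(raw[sel])
    stats_list[[as.character(b)]] <- c(bin = b, mean = m, sd = s, n = sum(sel))
    std[sel] <- if (!is.na(s) && s > 0) (raw[sel] - m) / s else NA_real_
  }
  df <- data.frame(chrom = vt$chrom, pos = vt$pos, id = vt$id,
                   freq_derived = p, ihh_a = ihh_a, ihh_d = ihh_d,
                   raw = raw, bin = bin, std = std)
  new_scan_scores(df, "iHS",
                  list(maf_min = maf_min, n_bins = n_bins, cutoff = cutoff,
                       bins = do.call(rbind, stats_list)))
}

# internal: one direction of the cross-population walk. Both panels are
# extended over the same site sequence; integration runs to the further of
# the two cutoff crossings (the joint-extent convention), so the faster-
# decaying panel contributes its sub-cutoff tail over that shared interval.
xp_walk <- function(hmA, hmB, core, step, cutoff, maxgap_bp) {
  a0 <- hmA$alleles[, core]; b0 <- hmB$alleles[, core]
  rowsA <- which(!is.na(a0)); rowsB <- which(!is.na(b0))
  if (length(rowsA) < 2L || length(rowsB) < 2L)
    return(list(censored = TRUE))
  walk <- function(hm, rows, g0, stop_below, max_steps = Inf)
    ehh_walk(hm$alleles, hm$positions, core, rows, g0, step, maxgap_bp,
             stop_below, max_steps)
  wA <- walk(hmA, rowsA, as.integer(a0[rowsA]) + 1L, cutoff)
  wB <- walk(hmB, rowsB, as.integer(b0[rowsB]) + 1L, cutoff)
  crossA <- which(wA$ehh < cutoff)[1L]
  crossB <- which(wB$ehh < cutoff)[1L]
  if (is.na(crossA) || is.na(crossB)) return(list(censored = TRUE))
  k <- max(crossA, crossB) - 1L   # last point of the later-decaying panel at/above cutoff
  if (k < 1L) return(list(censored = FALSE, ihhA = 0, ihhB = 0))
  # extend the earlier-decaying panel past its own cutoff, out to the joint
  # extent, so both integrals cover the same interval
  if (length(wA$ehh) < k)
    wA <- walk(hmA, rowsA, as.integer(a0[rowsA]) + 1L, 0, max_steps = k - 1L)
  if (length(wB$ehh) < k)
    wB <- walk(hmB, rowsB, as.integer(b0[rowsB]) + 1L, 0, max_steps = k - 1L)
  if (length(wA$ehh) < k || length(wB$ehh) < k) return(list(censored = TRUE))
  trapz <- function(d, e, k)
    if (k < 2L) 0 else sum(diff(d[1:k]) * (e[1:(k - 1L)] + e[2:k]) / 2)
  list(censored = FALSE,
       ihhA = trapz(wA$distance, wA$ehh, k),
       ihhB = trapz(wB$distance, wB$ehh, k))
}

#' Cross-population EHH (XP-EHH) scan
#'
#' Per site, pooled-allele iHH is computed in each panel over the same
#' truncation extent (the further of the two panels' cutoff crossings, per
#' direction); the raw score is \eqn{\ln(iHH_A / iHH_B)} summed over both
#' directions, positive when haplotype homozygosity extends further in panel
#' A. Scores are standardized genome-wide to mean 0 / SD 1. Sites censored or
#' undefined in either panel are excluded.
#'
#' @param hmA,hmB \code{hap_matrix} panels sharing the site map.
#' @param vt matching \code{variant_table}.
#' @param cutoff EHH truncation level, default 0.05.
#' @param maxgap_bp maximum tolerated inter-site gap, default 200 kb.
#' @return \code{scan_scores}: chrom, pos, id, ihh_a, ihh_b, raw, std.
#' @export
xpehh_scan <- function(hmA, hmB, vt, cutoff = 0.05, maxgap_bp = 2e5) {
  if (!isTRUE(all.equal(hmA$positions, hmB$positions)))
    stop("panels must share the site map")
  L <- n_sites(hmA)
  raw <- ihh_a <- ihh_b <- rep(NA_real_, L)
  for (i in seq_len(L)) {
    tA <- 0; tB <- 0; bad <- FALSE
    for (step in c(1L, -1L)) {
      w <- xp_walk(hmA, hmB, i, step, cutoff, maxgap_bp)
      if (w$censored) { bad <- TRUE; break }
      tA <- tA + w$ihhA; tB <- tB + w$ihhB
    }
    if (bad || tA <= 0 || tB <= 0) next
    ihh_a[i] <- tA; ihh_b[i] <- tB
    raw[i] <- log(tA / tB)
  }
  ok <- !is.na(raw)
  m <- mean(raw[ok]); s <- stats::sd(raw[ok])
  std <- rep(NA_real_, L)
  if (!is.na(s) && s > 0) std[ok] <- (raw[ok] - m) / s
  df <- data.frame(chrom = vt$chrom, pos = vt$pos, id = vt$id,
                   ihh_a = ihh_a, ihh_b = ihh_b, raw = raw, std = std)
  new_scan_scores(df, "XPEHH",
                  list(mean = m, sd = s, n = sum(ok), cutoff = cutoff))
}
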