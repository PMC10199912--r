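#' Rank-based p-values for a score vector
#'
#' p = rank / (N + 1), rank 1 being the most extreme score under the ranking
#' key; tied scores receive their average rank. The (N + 1) denominator keeps
#' every p strictly positive so that Fisher's combined score stays finite.
#' Non-finite scores get \code{NA} and do not count towards N.
#'
#' @param scores numeric vector.
#' @param key \code{"abs"} ranks by |score| (haplotype statistics),
#'   \code{"signed"} ranks by the score itself, high = extreme (FST).
#' @return numeric vector of p-values in (0, 1], \code{NA} where the score is
#'   not finite.
#' @export
rank_to_pvalues <- function(scores, key = c("abs", "signed")) {
  key <- match.arg(key)
  v <- if (key == "abs") abs(scores) else scores
  ok <- is.finite(v)
  if (!any(ok)) stop("no finite scores")
  p <- rep(NA_real_, length(scores))
  r <- rank(-v[ok], ties.method = "average")
  p[ok] <- r / (sum(ok) + 1)
  p
}

#' Fisher's combined score for two p-values
#'
#' \eqn{F_{CS} = -2(\ln p_1 + \ln p_2)}; under independence the score is
#' chi-square distributed with 4 degrees of freedom, giving the combined
#' p-value as the upper tail at the score.
#'
#' @param p1,p2 p-values in (0, 1] (vectors recycled).
#' @return data.frame with columns \code{fcs} and \code{p}.
#' @export
fisher_combined_score <- function(p1, p2) {
  if (any(p1 <= 0 | p2 <= 0, na.rm = TRUE)) stop("p-values must be > 0")
  if (any(p1 > 1 | p2 > 1, na.rm = TRUE)) stop("p-values must be <= 1")
  fcs <- -2 * (log(p1) + log(p2))
  data.frame(fcs = fcs, p = stats::pchisq(fcs, df = 4, lower.tail = FALSE))
}

#' Extract the top fraction of a score table
#'
#' Keeps the \code{ceiling(q * N)} most extreme sites under the ranking key,
#' N counting sites with a finite score, and attaches their rank-based
#' p-values.
#'
#' @param scores a \code{scan_scores} data.frame (or any data.frame with
#'   chrom/pos/id columns).
#' @param value name of the score column to rank (e.g. \code{"std"},
#'   \code{"fst"}).
#' @param q fraction in (0, 0.5].
#' @param key ranking key, see \code{\link{rank_to_pvalues}}.
#' @return data.frame of member sites (chrom, pos, id, score, rank, p),
#'   ordered most extreme first; class \code{outlier_set} with attributes
#'   statistic, q, key, n_scored.
#' @export
top_fraction_outliers <- function(scores, value, q, key = c("abs", "signed")) {
  key <- match.arg(key)
  if (!is.numeric(q) || q <= 0 || q > 0.5) stop("q must be in (0, 0.5]")
  v <- scores[[value]]
  p <- rank_to_pvalues(v, key)
  ok <- which(!is.na(p))
  n <- length(ok)
  k <- ceiling(q * n)
  kv <- if (key == "abs") abs(v) else v
  sel <- ok[order(-kv[ok])][seq_len(k)]
  out <- data.frame(chrom = scores$chrom[sel], pos = scores$pos[sel],
                    id = scores$id[sel], score = v[sel],
                    rank = rank(-kv[ok], ties.method = "average")[match(sel, ok)],
                    p = p[sel])
  structure(out, statistic = attr(scores, "statistic"), q = q, key = key,
            n_scored = n, class = c("outlier_set", "data.frame"))
}

#' Combine FST and XP-EHH outliers with Fisher's score
#'
#' Takes the top-\code{q} sites of FST (signed) and of |standardized XP-EHH|
#' independently, intersects them, and scores the intersection with Fisher's
#' combined score on the two rank-based p-values (ranks taken over all scored
#' sites of each statistic). An empty intersection is returned as an empty
#' set, with a message.
#'
#' @param fst \code{scan_scores} from \code{\link{weir_cockerham_fst}}.
#' @param xpehh \code{scan_scores} from \code{\link{xpehh_scan}}.
#' @param q outlier fraction for each statistic (default 0.01).
#' @return data.frame (class \code{combined_outliers}): chrom, pos, id, fst,
#'   xpehh_std, p_fst, p_xpehh, fcs, p_combined, ordered by decreasing fcs.
#' @export
combine_differentiation_scans <- function(fst, xpehh, q = 0.01) {
  key <- paste(fst$chrom, fst$pos)
  keyx <- paste(xpehh$chrom, xpehh$pos)
  common <- intersect(key, keyx)
  if (!length(common)) stop("scans share no sites")
  empty <- function() {
    message("combine_differentiation_scans: empty intersection")
    out <- data.frame(chrom = character(), pos = numeric(), id = character(),
                      fst = numeric(), xpehh_std = numeric(),
                      p_fst = numeric(), p_xpehh = numeric(),
                      fcs = numeric(), p_combined = numeric())
    structure(out, q = q, class = c("combined_outliers", "data.frame"))
  }
  if (!any(is.finite(fst$fst)) || !any(is.finite(xpehh$std))) return(empty())
  p_fst <- rank_to_pvalues(fst$fst, "signed")
  p_xp <- rank_to_pvalues(xpehh$std, "abs")
  top_f <- top_fraction_outliers(fst, "fst", q, "signed")
  top_x <- top_fraction_outliers(xpehh, "std", q, "abs")
  both <- intersect(paste(top_f$chrom, top_f$pos), paste(top_x$chrom, top_x$pos))
  if (!length(both)) return(empty())
  i_f <- match(both, key)
  i_x <- match(both, keyx)
  fc <- fisher_combined_score(p_fst[i_f], p_xp[i_x])
  out <- data.frame(chrom = fst$chrom[i_f], pos = fst$pos[i_f],
                    id = fst$id[i_f], fst = fst$fst[i_f],
                    xpehh_std = xpehh$std[i_x],
                    p_fst = p_fst[i_f], p_xpehh = p_xp[i_x],
                    fcs = fc$fcs, p_combined = fc$p)
  out <- out[order(-out$fcs), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, q = q, class = c("combined_outliers", "data.frame"))
}

#' Merge outlier sites into candidate regions
#'
#' Single-linkage merge per chromosome: sites closer than \code{gap_bp} join
#' one region; region bounds are the extreme member positions padded by
#' \code{gap_bp / 2} on each side (floored at 0). Merging is idempotent.
#'
#' @param sites data.frame with chrom and pos columns (e.g. an
#'   \code{outlier_set}).
#' @param gap_bp merge distance in bp (default 200 kb).
#' @param test label recorded in the \code{tests} column (defaults to the
#'   statistic attribute when present).
#' @return data.frame (class \code{candidate_regions}): chrom, start, end,
#'   n_sites, pos_min, pos_max, tests.
#' @export
merge_outliers_into_regions <- function(sites, gap_bp = 2e5, test = NULL) {
  if (is.null(test)) test <- attr(sites, "statistic")
  if (is.null(test)) test <- "unknown"
  if (!nrow(sites)) {
    out <- data.frame(chrom = character(), start = numeric(), end = numeric(),
                      n_sites = integer(), pos_min = numeric(),
                      pos_max = numeric(), tests = character())
    return(structure(out, gap_bp = gap_bp,
                     class = c("candidate_regions", "data.frame")))
  }
  res <- list()
  for (ch in unique(sites$chrom)) {
    pos <- sort(unique(sites$pos[sites$chrom == ch]))
    grp <- cumsum(c(1, diff(pos) > gap_bp))
    for (g in unique(grp)) {
      pg <- pos[grp == g]
      res[[length(res) + 1L]] <- data.frame(
        chrom = ch, start = max(0, min(pg) - gap_bp / 2),
        end = max(pg) + gap_bp / 2, n_sites = length(pg),
        pos_min = min(pg), pos_max = max(pg), tests = test)
    }
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  structure(out, gap_bp = gap_bp, class = c("candidate_regions", "data.frame"))
}

#' Attach overlapping genes to candidate regions
#'
#' Overlap is half-open interval intersection: a gene abutting a region end
#' (zero-width overlap) is not attached.
#'
#' @param regions a \code{candidate_regions} data.frame.
#' @param genes data.frame from \code{\link{read_bed}} (chrom, start, end,
#'   name).
#' @return \code{regions} with a \code{genes} column (comma-separated names,
#'   "" when none).
#' @export
annotate_regions_with_genes <- function(regions, genes) {
  if (any(genes$start >= genes$end)) stop("invalid gene interval")
  regions$genes <- vapply(seq_len(nrow(regions)), function(i) {
    hit <- genes$chrom == regions$chrom[i] &
      genes$start < regions$end[i] & genes$end > regions$start[i]
    paste(genes$name[hit], collapse = ",")
  }, character(1L))
  regions
}

#' Two-locus linkage disequilibrium from phased haplotypes
#'
#' Haplotype frequencies are counted on pairwise-complete haplotypes;
#' \eqn{D = p_{11} - p_A p_B}, \eqn{D' = D / D_{max}}, and
#' \eqn{r^2 = D^2 / (p_A q_A p_B q_B)}, where allele 1 at each site defines
#' the counted haplotype.
#'
#' @param hm a \code{hap_matrix}
#' @param site_i,site_j site indices.
#' @param spec,group optional group restriction.
#' @return object of class \code{ld_result}: counts (2x2 haplotype table),
#'   pA, pB, D, Dprime, r2, n.
#' @export
ld_pair_stats <- function(hm, site_i, site_j, spec = NULL, group = NULL) {
  rows <- seq_len(n_hap(hm))
  if (!is.null(group)) rows <- hap_rows(hm, intersect(group_samples(spec, group),
                                                      hm$samples))
  x <- hm$alleles[rows, site_i]
  y <- hm$alleles[rows, site_j]
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 2L) stop("fewer than 2 complete haplotypes")
  pA <- mean(x); pB <- mean(y)
  if (pA %in% c(0, 1) || pB %in% c(0, 1)) stop("monomorphic site in group")
  p11 <- mean(x == 1L & y == 1L)
  D <- p11 - pA * pB
  dmax <- if (D >= 0) min(pA * (1 - pB), (1 - pA) * pB)
          else min(pA * pB, (1 - pA) * (1 - pB))
  counts <- matrix(c(sum(x == 0 & y == 0), sum(x == 0 & y == 1),
                     sum(x == 1 & y == 0), sum(x == 1 & y == 1)),
                   2L, 2L, byrow = TRUE,
                   dimnames = list(c("i0", "i1"), c("j0", "j1")))
  structure(list(counts = counts, pA = pA, pB = pB, D = D,
                 Dprime = if (dmax > 0) D / dmax else 0,
                 r2 = D^2 / (pA * (1 - pA) * pB * (1 - pB)), n = n),
            class = "ld_result")
}

#' @export
print.ld_result <- function(x, ...) {
  cat(sprintf("LD pair: D = %.4f, D' = %.4f, r2 = %.4f (n = %d haplotypes)\n",
              x$D, x$Dprime, x$r2, x$n))
  invisible(x)
}

# internal: any >= 1 bp half-open overlap between one region and a region table
overlaps_any <- function(chrom, start, end, tab) {
  if (is.null(tab) || !nrow(tab)) return(FALSE)
  any(tab$chrom == chrom & tab$start < end & tab$end > start)
}

#' Classify target candidate regions as private, shared, or post-admixture
#'
#' A target region overlapping (by at least 1 bp) a candidate region of any
#' source-group scan is labelled \code{shared_with_<source>} (whether this
#' reflects adaptive admixture or a residual shared sweep is not determined
#' by the overlap itself); a region overlapping a significant LAD region is
#' labelled \code{post_admixture}; a region overlapping neither is
#' \code{private_target}. Multiple labels are allowed and reported in the
#' fixed order post_admixture, shared, private. Classification depends only
#' on the overlap structure: input row order never changes the labels.
#'
#' @param target_regions \code{candidate_regions} found in the target group.
#' @param source_regions named list of \code{candidate_regions}, one per
#'   source group.
#' @param lad_regions optional \code{candidate_regions} from the LAD scan.
#' @return \code{target_regions} with a \code{classification} column
#'   (";"-separated labels).
#' @export
classify_candidate_signals <- function(target_regions, source_regions = list(),
                                       lad_regions = NULL) {
  labs <- character(nrow(target_regions))
  src_names <- sort(names(source_regions))
  for (i in seq_len(nrow(target_regions))) {
    ch <- target_regions$chrom[i]
    s <- target_regions$start[i]; e <- target_regions$end[i]
    l <- character()
    if (overlaps_any(ch, s, e, lad_regions)) l <- c(l, "post_admixture")
    for (src in src_names)
      if (overlaps_any(ch, s, e, source_regions[[src]]))
        l <- c(l, paste0("shared_with_", src))
    if (!length(l)) l <- "private_target"
    labs[i] <- paste(l, collapse = ";")
  }
  target_regions$classification <- labs
  target_regions
}

#' Ingest an external ancestry-component selection scan
#'
#' Reads a table of per-site log-likelihood ratios from an ancestry-aware
#' selection method and keeps the sites above the threshold (default
#' LLRT > 15).
#'
#' @param path TSV with columns chrom, pos, llrt (header required).
#' @param threshold minimum LLRT (exclusive), default 15.
#' @return data.frame of retained sites (chrom, pos, llrt).
#' @export
ingest_llrt_table <- function(path, threshold = 15) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (!all(c("chrom", "pos", "llrt") %in% names(df)))
    stop("LLRT table needs columns chrom, pos, llrt")
  df[df$llrt > threshold, , drop = FALSE]
}
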