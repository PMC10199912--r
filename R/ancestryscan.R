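#' Per-site ancestry dosage from haplotype tracts
#'
#' For each site and ancestry k the dosage \eqn{\alpha_k(s)} is the fraction
#' of haplotypes whose covering tract at that position carries label k;
#' genome-wide mean and empirical SD per ancestry are recorded for the LAD
#' standardization. Every position must be covered by a tract on every
#' haplotype.
#'
#' @param tracts a \code{tract_set}.
#' @param positions bp positions to evaluate.
#' @param labels ancestry label set (defaults to the tract set's labels).
#' @return object of class \code{ancestry_profile}: alpha (L x K matrix),
#'   positions, labels, mean, sd, n_hap.
#' @export
tracts_to_locus_dosage <- function(tracts, positions, labels = NULL) {
  if (is.null(labels)) labels <- attr(tracts, "labels")
  labels <- as.character(labels)
  haps <- unique(tracts$haplotype_id)
  L <- length(positions)
  K <- length(labels)
  counts <- matrix(0L, L, K, dimnames = list(NULL, labels))
  for (h in haps) {
    tr <- tracts[tracts$haplotype_id == h, , drop = FALSE]
    o <- order(tr$start)
    tr <- tr[o, , drop = FALSE]
    idx <- findInterval(positions, tr$start)
    if (any(idx < 1L) || any(positions >= tr$end[pmax(idx, 1L)]))
      stop("position not covered by tracts of haplotype ", h)
    lab <- tr$ancestry[idx]
    ji <- match(lab, labels)
    if (anyNA(ji)) stop("tract label outside declared ancestry set")
    counts[cbind(seq_len(L), ji)] <- counts[cbind(seq_len(L), ji)] + 1L
  }
  alpha <- counts / length(haps)
  structure(list(alpha = alpha, positions = as.numeric(positions),
                 labels = labels,
                 mean = colMeans(alpha), sd = apply(alpha, 2L, stats::sd),
                 n_hap = length(haps)),
            class = "ancestry_profile")
}

#' @export
print.ancestry_profile <- function(x, ...) {
  cat(sprintf("ancestry_profile: %d sites x %d ancestries, %d haplotypes\n",
              nrow(x$alpha), length(x$labels), x$n_hap))
  print(round(rbind(mean = x$mean, sd = x$sd), 4))
  invisible(x)
}

#' Local ancestry deviation (LAD) scan
#'
#' Standardized deviation of the local ancestry dosage from its genome-wide
#' mean, \eqn{LAD_k(s) = (\alpha_k(s) - \bar\alpha_k) / \sigma_k}, per site
#' and ancestry, with \eqn{\sigma_k} the empirical genome-wide SD of the
#' dosage. Ancestries with zero SD are skipped (messaged); fewer than 100
#' sites triggers a warning because the SD estimate is then unstable.
#'
#' @param profile an \code{ancestry_profile}.
#' @param chrom chromosome label for the output table.
#' @param method \code{"binomial"} (default) standardizes with the median
#'   dosage as center and the binomial sampling SE
#'   \eqn{\sqrt{c_k(1-c_k)/n_{hap}}} as scale: under the pulse model,
#'   haplotypes are independent, so this is the exact null SD of a per-site
#'   dosage, and it cannot be inflated by a true selected region the way an
#'   empirical SD can when one region covers a sizeable share of the scanned
#'   sites. \code{"moments"} uses the genome-wide mean and empirical SD, the
#'   construction of choice when the input spans a whole genome and any
#'   selected region is a negligible fraction of it.
#' @return \code{scan_scores} in long format: chrom, pos, ancestry, dosage,
#'   lad; the per-ancestry center/scale are kept in the \code{normalization}
#'   attribute.
#' @export
lad_scan <- function(profile, chrom = "1", method = c("binomial", "moments")) {
  method <- match.arg(method)
  L <- nrow(profile$alpha)
  if (L < 100L)
    warning("lad_scan: fewer than 100 sites; the dosage scale estimate is unstable")
  keep <- profile$sd > 0
  skipped <- profile$labels[!keep]
  if (length(skipped))
    message("lad_scan: skipping constant-dosage ancestry(ies): ",
            paste(skipped, collapse = ", "))
  if (!any(keep)) stop("no ancestry with positive dosage SD")
  if (method == "binomial") {
    center <- apply(profile$alpha, 2L, stats::median)
    scale <- sqrt(center * (1 - center) / profile$n_hap)
    deg <- keep & scale == 0
    scale[deg] <- profile$sd[deg]   # median at 0 or 1 but dosage not constant
  } else {
    center <- profile$mean
    scale <- profile$sd
  }
  out <- do.call(rbind, lapply(profile$labels[keep], function(k) {
    data.frame(chrom = chrom, pos = profile$positions, ancestry = k,
               dosage = profile$alpha[, k],
               lad = (profile$alpha[, k] - center[k]) / scale[k])
  }))
  rownames(out) <- NULL
  new_scan_scores(out, "LAD",
                  list(center = center[keep], scale = scale[keep],
                       method = method, n_hap = profile$n_hap,
                       skipped = skipped))
}

#' Extract significant LAD regions
#'
#' Contiguous runs of sites with |LAD| above the threshold are merged within
#' the standard region gap rule, separately per ancestry, and tagged with the
#' deviated ancestry, the peak |LAD| and the dosage at the peak site.
#'
#' @param lad \code{scan_scores} from \code{\link{lad_scan}}.
#' @param threshold |LAD| significance threshold (default 4.42).
#' @param gap_bp merge distance passed to
#'   \code{\link{merge_outliers_into_regions}}.
#' @return \code{candidate_regions} with extra columns ancestry, peak_lad,
#'   peak_dosage.
#' @export
extract_lad_regions <- function(lad, threshold = 4.42, gap_bp = 2e5) {
  res <- list()
  for (k in unique(lad$ancestry)) {
    sub <- lad[lad$ancestry == k & abs(lad$lad) > threshold, , drop = FALSE]
    if (!nrow(sub)) next
    reg <- merge_outliers_into_regions(sub, gap_bp = gap_bp, test = "LAD")
    reg$ancestry <- k
    reg$peak_lad <- NA_real_
    reg$peak_dosage <- NA_real_
    for (i in seq_len(nrow(reg))) {
      m <- sub[sub$chrom == reg$chrom[i] & sub$pos >= reg$pos_min[i] &
                 sub$pos <= reg$pos_max[i], , drop = FALSE]
      top <- which.max(abs(m$lad))
      reg$peak_lad[i] <- m$lad[top]
      reg$peak_dosage[i] <- m$dosage[top]
    }
    res[[k]] <- reg
  }
  if (!length(res)) {
    out <- merge_outliers_into_regions(
      data.frame(chrom = character(), pos = numeric()), gap_bp, test = "LAD")
    out$ancestry <- character()
    out$peak_lad <- numeric()
    out$peak_dosage <- numeric()
    return(out)
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  structure(out, gap_bp = gap_bp, threshold = threshold,
            class = c("candidate_regions", "data.frame"))
}

#' Write LAD regions as BED4 (0-based half-open; ancestry in the name field)
#' @param regions \code{candidate_regions} from \code{\link{extract_lad_regions}}.
#' @param path output BED path.
#' @export
write_lad_regions_bed <- function(regions, path) {
  df <- data.frame(chrom = regions$chrom,
                   start = format(regions$start, scientific = FALSE, trim = TRUE),
                   end = format(regions$end, scientific = FALSE, trim = TRUE),
                   name = if (nrow(regions)) regions$ancestry else character())
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Rank variants inside a LAD region by source-frequency contrast
#'
#' Sites within the region are ranked by the absolute derived-allele
#' frequency difference between two source groups, descending. When a
#' functional-score table is supplied (e.g. deleteriousness scores), sites
#' scoring at or below \code{score_min} are removed before ranking; sites
#' absent from the table are kept.
#'
#' @param region single-row region (chrom, start, end).
#' @param source_freqs data.frame with columns id, pos, and one frequency
#'   column per source group.
#' @param sources length-2 character vector naming the two source columns.
#' @param score_table optional data.frame (id, score).
#' @param score_min exclusive lower bound on the functional score (default 10).
#' @return data.frame of ranked sites: id, pos, freq columns, delta_freq.
#' @export
prioritize_lad_variants <- function(region, source_freqs, sources,
                                    score_table = NULL, score_min = 10) {
  if (length(sources) != 2L) stop("exactly two source groups required")
  miss <- setdiff(sources, names(source_freqs))
  if (length(miss)) stop("unknown source group(s): ", paste(miss, collapse = ", "))
  sel <- source_freqs$pos >= region$start & source_freqs$pos < region$end
  df <- source_freqs[sel, , drop = FALSE]
  if (!is.null(score_table)) {
    sc <- score_table$score[match(df$id, score_table$id)]
    df <- df[is.na(sc) | sc > score_min, , drop = FALSE]
  }
  df$delta_freq <- abs(df[[sources[1L]]] - df[[sources[2L]]])
  df <- df[order(-df$delta_freq), , drop = FALSE]
  rownames(df) <- NULL
  df
}
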