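#' Phased haplotype matrix
#'
#' Container for phased biallelic data: a 2N x L integer matrix of allele
#' codes (0/1, \code{NA} = missing), ascending physical positions, and a
#' fixed haplotype-to-sample convention (rows 2j-1 and 2j are the two
#' haplotypes of sample j).
#'
#' @param alleles integer matrix, 2N rows (haplotypes) x L columns (sites),
#'   entries in \{0, 1, NA\}.
#' @param positions numeric vector of length L, strictly increasing base-pair
#'   positions.
#' @param chrom single chromosome label.
#' @param samples character vector of N sample ids; haplotype ids are derived
#'   as \code{<sample>_1} / \code{<sample>_2}.
#' @return An object of class \code{hap_matrix}.
#' @export
hap_matrix <- function(alleles, positions, chrom, samples) {
  alleles <- as.matrix(alleles)
  storage.mode(alleles) <- "integer"
  if (nrow(alleles) != 2L * length(samples))
    stop("hap_matrix: need exactly 2 haplotypes per sample")
  if (ncol(alleles) != length(positions))
    stop("hap_matrix: positions/column mismatch")
  positions <- as.numeric(positions)
  if (length(positions) > 1L && any(diff(positions) <= 0))
    stop("hap_matrix: positions must be strictly increasing")
  bad <- !(alleles %in% c(0L, 1L, NA_integer_))
  if (any(bad)) stop("hap_matrix: allele codes must be 0, 1 or NA")
  rownames(alleles) <- paste0(rep(samples, each = 2L), "_", c(1L, 2L))
  structure(list(alleles = alleles, positions = positions,
                 chrom = as.character(chrom)[1L], samples = as.character(samples)),
            class = "hap_matrix")
}

#' @export
print.hap_matrix <- function(x, ...) {
  cat(sprintf("hap_matrix: %d haplotypes (%d samples) x %d sites, chrom %s [%s-%s bp]\n",
              n_hap(x), length(x$samples), n_sites(x), x$chrom,
              format(min(x$positions), big.mark = ","),
              format(max(x$positions), big.mark = ",")))
  invisible(x)
}

#' Number of haplotypes / sites
#' @param hm a \code{hap_matrix}
#' @return integer count.
#' @export
n_hap <- function(hm) nrow(hm$alleles)

#' @rdname n_hap
#' @export
n_sites <- function(hm) ncol(hm$alleles)

#' Subset a haplotype matrix by site index or by sample id
#' @param hm a \code{hap_matrix}
#' @param sites integer or logical index over sites.
#' @return a \code{hap_matrix}.
#' @export
subset_sites <- function(hm, sites) {
  hap_matrix(hm$alleles[, sites, drop = FALSE], hm$positions[sites],
             hm$chrom, hm$samples)
}

#' @rdname subset_sites
#' @param samples character vector of sample ids to keep (order preserved).
#' @export
subset_samples <- function(hm, samples) {
  miss <- setdiff(samples, hm$samples)
  if (length(miss)) stop("samples not present: ", paste(miss, collapse = ", "))
  rows <- hap_rows(hm, samples)
  hap_matrix(hm$alleles[rows, , drop = FALSE], hm$positions, hm$chrom, samples)
}

#' Haplotype row indices for a set of samples
#' @inheritParams subset_samples
#' @return integer vector of row indices into \code{hm$alleles}.
#' @export
hap_rows <- function(hm, samples) {
  j <- match(samples, hm$samples)
  if (anyNA(j)) stop("unknown sample(s): ", paste(samples[is.na(j)], collapse = ", "))
  as.vector(rbind(2L * j - 1L, 2L * j))
}

#' Diploid genotype dosages (0/1/2 copies of the coded-1 allele)
#'
#' A genotype is missing (\code{NA}) if either haplotype is missing.
#' @param hm a \code{hap_matrix}
#' @return N x L integer matrix with sample rownames.
#' @export
genotype_dosage <- function(hm) {
  a <- hm$alleles
  d <- a[seq(1L, nrow(a), by = 2L), , drop = FALSE] +
       a[seq(2L, nrow(a), by = 2L), , drop = FALSE]
  rownames(d) <- hm$samples
  d
}

#' Per-site variant metadata table
#'
#' @param chrom,pos,id,ref,alt,aa vectors of equal length: chromosome,
#'   position, identifier, reference allele, alternate allele, ancestral
#'   allele (\code{NA} when unknown).
#' @return data.frame of class \code{variant_table}.
#' @export
variant_table <- function(chrom, pos, id, ref, alt, aa = NA_character_) {
  vt <- data.frame(chrom = as.character(chrom), pos = as.numeric(pos),
                   id = as.character(id), ref = as.character(ref),
                   alt = as.character(alt), aa = as.character(aa),
                   stringsAsFactors = FALSE)
  class(vt) <- c("variant_table", "data.frame")
  vt
}

#' Sample-to-population assignments with named population groups
#'
#' Groups are named unions of populations (e.g. \code{target},
#' \code{source_EUR}); a bare population name is always usable as a group.
#'
#' @param assignments named character vector: names are sample ids, values
#'   population labels.
#' @param groups named list of character vectors of population labels.
#' @return object of class \code{pop_spec}.
#' @export
pop_spec <- function(assignments, groups = list()) {
  stopifnot(is.character(assignments), !is.null(names(assignments)))
  pops <- unique(unname(assignments))
  for (g in names(groups)) {
    bad <- setdiff(groups[[g]], pops)
    if (length(bad)) stop("group '", g, "' references unknown population(s): ",
                          paste(bad, collapse = ", "))
  }
  structure(list(assignments = assignments, groups = groups), class = "pop_spec")
}

#' Samples belonging to a group (or a single population)
#' @param spec a \code{pop_spec}
#' @param group group name defined in \code{spec$groups}, or a population label.
#' @return character vector of sample ids.
#' @export
group_samples <- function(spec, group) {
  pops <- if (group %in% names(spec$groups)) spec$groups[[group]] else group
  bad <- setdiff(pops, unique(unname(spec$assignments)))
  if (length(bad)) stop("unknown group or population: ", group)
  names(spec$assignments)[spec$assignments %in% pops]
}

#' Read a two-column sample/population table and optional YAML group file
#' @param path TSV with columns sample, population (no header required if two
#'   columns; a header line \code{sample\tpopulation} is accepted).
#' @param groups_yaml optional YAML file mapping group names to population lists.
#' @return a \code{pop_spec}.
#' @export
read_pop_spec <- function(path, groups_yaml = NULL) {
  tab <- utils::read.table(path, header = FALSE, sep = "\t",
                           stringsAsFactors = FALSE, col.names = c("sample", "population"))
  if (identical(tolower(tab$sample[1]), "sample")) tab <- tab[-1L, , drop = FALSE]
  asg <- stats::setNames(tab$population, tab$sample)
  groups <- if (!is.null(groups_yaml)) yaml::read_yaml(groups_yaml) else list()
  groups <- lapply(groups, as.character)
  pop_spec(asg, groups)
}

#' @export
write_pop_spec <- function(spec, path, groups_yaml = NULL) {
  utils::write.table(data.frame(sample = names(spec$assignments),
                                population = unname(spec$assignments)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  if (!is.null(groups_yaml)) yaml::write_yaml(spec$groups, groups_yaml)
  invisible(path)
}

# internal: tag a score data.frame with its statistic + normalisation metadata
new_scan_scores <- function(df, statistic, norm = list()) {
  attr(df, "statistic") <- statistic
  attr(df, "normalization") <- norm
  class(df) <- c("scan_scores", "data.frame")
  df
}

#' Write a scan score table as TSV
#' @param scores a \code{scan_scores} data.frame
#' @param path output file
#' @export
write_scores <- function(scores, path) {
  utils::write.table(as.data.frame(scores), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Per-haplotype ancestry tracts
#'
#' Half-open \code{[start, end)} intervals in bp that tile each haplotype.
#'
#' @param df data.frame with columns haplotype_id, chrom, start, end, ancestry.
#' @param chrom_length chromosome length in bp (tracts must tile \code{[0, chrom_length)}).
#' @param labels declared ancestry label set.
#' @return data.frame of class \code{tract_set}.
#' @export
tract_set <- function(df, chrom_length, labels = sort(unique(df$ancestry))) {
  need <- c("haplotype_id", "chrom", "start", "end", "ancestry")
  if (!all(need %in% names(df))) stop("tract_set: missing columns")
  if (any(df$start >= df$end)) stop("tract_set: empty or inverted interval")
  bad <- setdiff(unique(df$ancestry), labels)
  if (length(bad)) stop("tract_set: undeclared ancestry label(s): ",
                        paste(bad, collapse = ", "))
  df <- df[order(df$haplotype_id, df$start), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, chrom_length = as.numeric(chrom_length), labels = labels,
            class = c("tract_set", "data.frame"))
}

#' Read / write tract files (TSV: haplotype_id, chrom, start, end, ancestry)
#' @param path file path
#' @param chrom_length chromosome length in bp
#' @param labels optional declared label set
#' @export
read_tracts <- function(path, chrom_length, labels = NULL) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                          colClasses = c(haplotype_id = "character",
                                         chrom = "character",
                                         start = "numeric", end = "numeric",
                                         ancestry = "character"))
  if (is.null(labels)) labels <- sort(unique(df$ancestry))
  tract_set(df, chrom_length, labels)
}

#' @rdname read_tracts
#' @param tracts a \code{tract_set}
#' @export
write_tracts <- function(tracts, path) {
  utils::write.table(as.data.frame(tracts), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
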