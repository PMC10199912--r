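run_config_defaults <- function() {
  list(q_fst_xpehh = 0.01, q_ihs = 0.001, lad = 4.42, llrt = 15,
       missingness = 0.10, hwe_p = 1e-8, maf = 0.05,
       ehh_cutoff = 0.05, maxgap_bp = 2e5, gap_bp = 2e5)
}

#' Load and validate a full-scan run configuration
#'
#' YAML keys: \code{inputs} (target_vcf, source_vcfs as a label-to-path map,
#' populations TSV, tracts TSV; optional genes BED, llrt_table TSV),
#' \code{groups} (target group name, optional target_subgroups, sources),
#' \code{ancestries}, \code{chrom_length_bp}, \code{thresholds} (missing
#' entries filled with the standard defaults: outlier fractions 0.01 for
#' FST/XP-EHH and 0.001 for iHS, |LAD| 4.42, LLRT 15, missingness 0.10,
#' HWE p 1e-8, MAF 0.05), \code{seed}, \code{out_dir}. Unknown keys are
#' rejected.
#'
#' @param path YAML file.
#' @return list of class \code{run_config}.
#' @export
load_config <- function(path) {
  raw <- yaml::read_yaml(path)
  validate_run_config(raw)
}

#' @rdname load_config
#' @param cfg a raw configuration list.
#' @export
validate_run_config <- function(cfg) {
  known <- c("inputs", "groups", "ancestries", "chrom_length_bp",
             "thresholds", "seed", "out_dir")
  extra <- setdiff(names(cfg), known)
  if (length(extra)) stop("unknown config key(s): ", paste(extra, collapse = ", "))
  th <- utils::modifyList(run_config_defaults(),
                          if (is.null(cfg$thresholds)) list() else cfg$thresholds)
  extra_th <- setdiff(names(th), names(run_config_defaults()))
  if (length(extra_th)) stop("unknown threshold(s): ", paste(extra_th, collapse = ", "))
  for (qk in c("q_fst_xpehh", "q_ihs"))
    if (th[[qk]] <= 0 || th[[qk]] > 0.5) stop(qk, " must be in (0, 0.5]")
  for (pk in c("missingness", "maf"))
    if (th[[pk]] < 0 || th[[pk]] > 1) stop(pk, " must be in [0, 1]")
  if (th$hwe_p < 0 || th$hwe_p > 1) stop("hwe_p must be in [0, 1]")
  if (th$lad <= 0) stop("lad threshold must be positive")
  cfg$thresholds <- th
  if (is.null(cfg$groups$target)) cfg$groups$target <- "target"
  if (is.null(cfg$groups$target_subgroups))
    cfg$groups$target_subgroups <- cfg$groups$target
  if (is.null(cfg$seed)) cfg$seed <- 1L
  structure(cfg, class = "run_config")
}

#' @rdname load_config
#' @param file output YAML path.
#' @export
write_config <- function(cfg, file) {
  yaml::write_yaml(unclass(cfg), file)
  invisible(file)
}

#' Build a run configuration for a written scenario bundle
#'
#' Convenience constructor pointing a \code{\link{run_full_scan}} at the
#' files emitted by \code{\link{write_bundle}}: the target VCF, the non-
#' autochthonous pools as sources, the ground-truth tracts and the bundled
#' population table.
#'
#' @param dir bundle directory.
#' @param out_dir run output directory.
#' @param sources source group labels (default: every ancestry but the first).
#' @param thresholds optional threshold overrides.
#' @param genes optional gene BED path.
#' @param llrt_table optional external ancestry-scan table path.
#' @return a \code{run_config}.
#' @export
bundle_run_config <- function(dir, out_dir, sources = NULL, thresholds = list(),
                              genes = NULL, llrt_table = NULL) {
  meta <- jsonlite::read_json(file.path(dir, "truth.json"), simplifyVector = TRUE)
  anc <- meta$config$ancestries
  if (is.null(sources)) sources <- anc[-1L]
  src_vcfs <- stats::setNames(file.path(dir, paste0("source_", sources, ".vcf")),
                              sources)
  validate_run_config(list(
    inputs = list(target_vcf = file.path(dir, "target.vcf"),
                  source_vcfs = as.list(src_vcfs),
                  populations = file.path(dir, "populations.tsv"),
                  tracts = file.path(dir, "tracts.tsv"),
                  genes = genes, llrt_table = llrt_table),
    groups = list(target = "target", sources = sources),
    ancestries = anc,
    chrom_length_bp = meta$config$chrom_length_bp,
    thresholds = thresholds,
    seed = meta$config$seed,
    out_dir = out_dir))
}

# internal: stack haplotype matrices sharing a site map (distinct samples)
stack_hap_matrices <- function(hms) {
  pos <- hms[[1L]]$positions
  for (h in hms[-1L])
    if (!isTRUE(all.equal(h$positions, pos))) stop("site maps differ")
  hap_matrix(do.call(rbind, lapply(hms, function(h) h$alleles)), pos,
             hms[[1L]]$chrom, unlist(lapply(hms, function(h) h$samples)))
}

log_stage <- function(run_log, stage, detail) {
  line <- sprintf("[%s] %s", stage, detail)
  message(line)
  cat(line, "\n", file = run_log, append = TRUE)
}

#' Run the full selection scan end to end
#'
#' Orchestrates QC, polarization, the per-comparison FST and XP-EHH scans
#' with their Fisher-combined intersection, iHS per target subgroup and per
#' source, the LAD scan from ancestry tracts, and the private / shared /
#' post-admixture classification. Every intermediate table is written to the
#' output directory as TSV, together with a machine-readable JSON manifest
#' (config, package version, seed, per-stage row counts). The run is a
#' deterministic function of inputs + seed: rerunning with the same config
#' yields bit-identical files.
#'
#' @param cfg a \code{run_config} (see \code{\link{load_config}}).
#' @return invisibly, a list with the main in-memory results and the output
#'   directory.
#' @export
run_full_scan <- function(cfg) {
  cfg <- validate_run_config(unclass(cfg))
  th <- cfg$thresholds
  out <- cfg$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  run_log <- file.path(out, "run.log")
  cat("", file = run_log)
  set.seed(cfg$seed)
  counts <- list()

  stage <- "read"
  res <- tryCatch({
    tgt <- read_vcf(cfg$inputs$target_vcf)
    srcs <- lapply(cfg$inputs$source_vcfs, function(p) read_vcf(p)$hap)
    spec <- read_pop_spec(cfg$inputs$populations)
    hm <- stack_hap_matrices(c(list(tgt$hap), srcs))
    vt <- tgt$variants
    log_stage(run_log, stage, sprintf("%d samples x %d sites",
                                      length(hm$samples), n_sites(hm)))
    counts$sites_input <- n_sites(hm)

    stage <- "qc"
    qc <- apply_qc_filters(hm, vt, spec,
                           list(missingness = th$missingness,
                                hwe_p = th$hwe_p, maf = th$maf))
    utils::write.table(qc$report, file.path(out, "qc_report.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    counts$sites_after_qc <- n_sites(qc$hap)
    log_stage(run_log, stage, sprintf("%d sites kept", counts$sites_after_qc))

    stage <- "polarize"
    pol <- polarize_to_ancestral(qc$hap, qc$variants)
    hm <- pol$hap; vt <- pol$variants
    counts$sites_polarized <- n_sites(hm)
    log_stage(run_log, stage,
              sprintf("%d sites polarized, %d dropped", n_sites(hm),
                      length(pol$dropped)))

    target_grp <- cfg$groups$target
    tgt_panel <- subset_samples(hm, intersect(group_samples(spec, target_grp),
                                              hm$samples))
    target_regions <- list()
    source_regions <- list()

    stage <- "fst_xpehh"
    for (src in cfg$groups$sources) {
      fst <- weir_cockerham_fst(hm, spec, target_grp, src, vt)
      src_panel <- subset_samples(hm, intersect(group_samples(spec, src),
                                                hm$samples))
      xp <- xpehh_scan(tgt_panel, src_panel, vt, cutoff = th$ehh_cutoff,
                       maxgap_bp = th$maxgap_bp)
      write_scores(fst, file.path(out, paste0("fst_vs_", src, ".tsv")))
      write_scores(xp, file.path(out, paste0("xpehh_vs_", src, ".tsv")))
      comb <- combine_differentiation_scans(fst, xp, q = th$q_fst_xpehh)
      utils::write.table(comb, file.path(out, paste0("combined_vs_", src, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      counts[[paste0("combined_vs_", src)]] <- nrow(comb)
      if (nrow(comb))
        target_regions[[paste0("fst_xpehh_vs_", src)]] <-
          merge_outliers_into_regions(comb, th$gap_bp,
                                      test = paste0("FST_XPEHH_vs_", src))
      log_stage(run_log, stage,
                sprintf("vs %s: %d combined outliers", src, nrow(comb)))
    }

    stage <- "fst_xpehh_sources"
    srcs_all <- cfg$groups$sources
    if (length(srcs_all) > 1L) {
      for (i1 in seq_len(length(srcs_all) - 1L)) {
        for (i2 in (i1 + 1L):length(srcs_all)) {
          sA <- srcs_all[i1]; sB <- srcs_all[i2]
          fst <- weir_cockerham_fst(hm, spec, sA, sB, vt)
          pA <- subset_samples(hm, intersect(group_samples(spec, sA), hm$samples))
          pB <- subset_samples(hm, intersect(group_samples(spec, sB), hm$samples))
          xp <- xpehh_scan(pA, pB, vt, cutoff = th$ehh_cutoff,
                           maxgap_bp = th$maxgap_bp)
          comb <- combine_differentiation_scans(fst, xp, q = th$q_fst_xpehh)
          utils::write.table(comb,
                             file.path(out, paste0("combined_", sA, "_vs_", sB, ".tsv")),
                             sep = "\t", quote = FALSE, row.names = FALSE)
          if (nrow(comb)) {
            # positive XP-EHH: longer homozygosity in the first panel
            for (side in list(list(grp = sA, rows = comb$xpehh_std > 0),
                              list(grp = sB, rows = comb$xpehh_std < 0))) {
              sub <- comb[side$rows, , drop = FALSE]
              if (!nrow(sub)) next
              reg <- merge_outliers_into_regions(
                sub, th$gap_bp, test = paste0("FST_XPEHH_", sA, "_vs_", sB))
              source_regions[[side$grp]] <-
                if (is.null(source_regions[[side$grp]])) reg
                else rbind(source_regions[[side$grp]], reg)
            }
          }
          log_stage(run_log, stage,
                    sprintf("%s vs %s: %d combined outliers", sA, sB, nrow(comb)))
        }
      }
    }

    stage <- "ihs"
    for (grp in unique(c(cfg$groups$target_subgroups, cfg$groups$sources))) {
      is_src <- grp %in% cfg$groups$sources
      ihs <- ihs_scan(hm, vt, spec, grp, maf_min = th$maf,
                      cutoff = th$ehh_cutoff, maxgap_bp = th$maxgap_bp)
      write_scores(ihs, file.path(out, paste0("ihs_", grp, ".tsv")))
      if (!any(is.finite(ihs$std))) {
        log_stage(run_log, stage, sprintf("%s: no scored sites", grp))
        next
      }
      topi <- top_fraction_outliers(ihs, "std", th$q_ihs, "abs")
      reg <- merge_outliers_into_regions(topi, th$gap_bp,
                                         test = paste0("iHS_", grp))
      counts[[paste0("ihs_", grp, "_scored")]] <- sum(!is.na(ihs$std))
      if (is_src) {
        source_regions[[grp]] <- if (is.null(source_regions[[grp]])) reg
                                 else rbind(source_regions[[grp]], reg)
      } else {
        target_regions[[paste0("ihs_", grp)]] <- reg
      }
      log_stage(run_log, stage, sprintf("%s: %d outlier sites -> %d regions",
                                        grp, nrow(topi), nrow(reg)))
    }

    stage <- "llrt"
    if (!is.null(cfg$inputs$llrt_table)) {
      hits <- ingest_llrt_table(cfg$inputs$llrt_table, th$llrt)
      if (nrow(hits))
        target_regions$ancestry_llrt <-
          merge_outliers_into_regions(hits, th$gap_bp, test = "ancestry_LLRT")
      log_stage(run_log, stage, sprintf("%d sites above LLRT threshold", nrow(hits)))
    }

    stage <- "lad"
    tracts <- read_tracts(cfg$inputs$tracts, cfg$chrom_length_bp,
                          labels = cfg$ancestries)
    prof <- tracts_to_locus_dosage(tracts, hm$positions, cfg$ancestries)
    lad <- lad_scan(prof, chrom = hm$chrom)
    write_scores(lad, file.path(out, "lad.tsv"))
    lad_regions <- extract_lad_regions(lad, th$lad, th$gap_bp)
    utils::write.table(as.data.frame(lad_regions),
                       file.path(out, "lad_regions.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    write_lad_regions_bed(lad_regions, file.path(out, "lad_regions.bed"))
    counts$lad_regions <- nrow(lad_regions)
    log_stage(run_log, stage, sprintf("%d significant LAD region(s)",
                                      nrow(lad_regions)))

    stage <- "classify"
    tr <- if (length(target_regions)) do.call(rbind, lapply(target_regions,
                                                            as.data.frame))
          else data.frame(chrom = character(), start = numeric(),
                          end = numeric(), n_sites = integer(),
                          pos_min = numeric(), pos_max = numeric(),
                          tests = character())
    rownames(tr) <- NULL
    class(tr) <- c("candidate_regions", "data.frame")
    if (!is.null(cfg$inputs$genes))
      tr <- annotate_regions_with_genes(tr, read_bed(cfg$inputs$genes))
    cls <- classify_candidate_signals(tr, source_regions, lad_regions)
    utils::write.table(as.data.frame(cls), file.path(out, "classification.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    counts$target_regions <- nrow(cls)
    log_stage(run_log, stage, sprintf("%d target region(s) classified", nrow(cls)))

    manifest <- list(package = "admixscan",
                     version = as.character(utils::packageVersion("admixscan")),
                     seed = cfg$seed, config = unclass(cfg), counts = counts)
    jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    list(classification = cls, lad = lad, lad_regions = lad_regions,
         source_regions = source_regions, counts = counts, out_dir = out)
  }, error = function(e) {
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(res)
}
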