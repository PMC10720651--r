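#' Build the four-statistic window table
#'
#' Runs the per-chromosome selection statistics on phased haplotypes and
#' aggregates them on the common sliding-window grid: Tajima's D per
#' window; per-site pi, frequency-standardized iHS and nSL averaged per
#' window; then each statistic's window column z-standardized
#' genome-wide over the included windows. Windows with fewer than
#' `min_snps` SNPs, or with no usable iHS/nSL score, are excluded before
#' standardization.
#'
#' @param haps named list of [haplotype_matrix()], one per chromosome.
#' @param window_size,step grid geometry in bp (defaults 100 kb / 25 kb).
#' @param min_snps minimum SNPs per included window (default 10).
#' @param ihs_args,nsl_args optional argument lists for [ihs()]/[nsl()].
#' @param n_bins frequency bins for [standardize_by_freq()].
#' @return List with `windows` (included windows: `chrom`, `start`,
#'   `end`, `n_snps`, raw columns `tajima_d`, `pi`, `ihs`, `nsl` and
#'   z-columns `pi_z`, `ihs_z`, `nsl_z`), `excluded` (count),
#'   `per_snp` (iHS/nSL per-SNP tables).
#' @export
selection_scan <- function(haps, window_size = 1e5, step = 2.5e4,
                           min_snps = 10, ihs_args = list(),
                           nsl_args = list(), n_bins = 50) {
  stopifnot(length(haps) >= 1)
  lens <- vapply(haps, function(h) h$chrom_length, 0)
  names(lens) <- vapply(haps, function(h) h$chrom, "")
  grid <- window_grid(lens, window_size, step)
  if (is.null(grid) || !nrow(grid))
    stop("no window fits on any chromosome")

  ihs_all <- do.call(rbind, lapply(haps, function(h)
    do.call(ihs, c(list(h), ihs_args))))
  nsl_all <- do.call(rbind, lapply(haps, function(h)
    do.call(nsl, c(list(h), nsl_args))))
  ihs_all$z <- standardize_by_freq(ihs_all$score, ihs_all$freq, n_bins)
  nsl_all$z <- standardize_by_freq(nsl_all$score, nsl_all$freq, n_bins)

  taj <- do.call(rbind, lapply(haps, function(h)
    tajimas_d(h, grid[grid$chrom == h$chrom, , drop = FALSE])))
  site_chrom <- unlist(lapply(haps, function(h)
    rep(h$chrom, length(h$pos))))
  site_pos <- unlist(lapply(haps, function(h) h$pos))
  pi_site <- unlist(lapply(haps, per_site_pi))

  pi_w <- window_aggregate(pi_site, site_chrom, site_pos, grid)
  ihs_w <- window_aggregate(ihs_all$z, ihs_all$chrom, ihs_all$pos, grid)
  nsl_w <- window_aggregate(nsl_all$z, nsl_all$chrom, nsl_all$pos, grid)

  wt <- data.frame(chrom = grid$chrom, start = grid$start,
                   end = grid$end, n_snps = pi_w$n_snps,
                   tajima_d = taj$tajima_d, pi = pi_w$mean_value,
                   ihs = ihs_w$mean_value, nsl = nsl_w$mean_value)
  ok <- wt$n_snps >= min_snps & !is.na(wt$tajima_d) & !is.na(wt$pi) &
    !is.na(wt$ihs) & !is.na(wt$nsl)
  excluded <- sum(!ok)
  wt <- wt[ok, , drop = FALSE]
  rownames(wt) <- NULL
  wt$pi_z <- zstd(wt$pi)
  wt$ihs_z <- zstd(wt$ihs)
  wt$nsl_z <- zstd(wt$nsl)
  list(windows = wt, excluded = excluded,
       per_snp = list(ihs = ihs_all, nsl = nsl_all))
}

#' DCMS scoring of a window table
#'
#' Converts the four window statistics to fractional-rank p-values
#' (Tajima's D and pi left-tailed, iHS and nSL two-tailed), estimates
#' their robust correlation by MCD, combines them into DCMS, fits a
#' normal for per-window p-values and calls/merges candidate regions.
#'
#' @param wt window table from [selection_scan()].
#' @param alpha,nsamp MCD parameters (defaults 0.75 / 50000).
#' @param seed RNG seed for the MCD subset draw.
#' @param robust_fit fit the DCMS null with median/MAD instead of
#'   mean/SD.
#' @param threshold_logp candidate threshold on `-log10(p)` (default 4).
#' @return List with `windows` (wt plus p columns, `dcms`, `p`,
#'   `neg_log10_p`, `candidate`), `correlation`, `fit` (mu, sigma) and
#'   `regions`.
#' @export
dcms_scan <- function(wt, alpha = 0.75, nsamp = 50000, seed = NULL,
                      robust_fit = FALSE, threshold_logp = 4) {
  stat_cols <- c("tajima_d", "pi_z", "ihs_z", "nsl_z")
  x <- as.matrix(wt[, stat_cols])
  colnames(x) <- c("tajima_d", "pi", "ihs", "nsl")
  pmat <- cbind(tajima_d = stat_to_pvalue(x[, 1], "left"),
                pi = stat_to_pvalue(x[, 2], "left"),
                ihs = stat_to_pvalue(x[, 3], "two"),
                nsl = stat_to_pvalue(x[, 4], "two"))
  corr <- mcd_correlation(x, alpha = alpha, nsamp = nsamp, seed = seed)
  scores <- dcms(pmat, corr$correlation)
  fit <- dcms_pvalues(scores, robust = robust_fit)
  out <- cbind(wt,
               p_tajima_d = pmat[, 1], p_pi = pmat[, 2],
               p_ihs = pmat[, 3], p_nsl = pmat[, 4],
               dcms = scores, p = fit$p, neg_log10_p = -log10(fit$p))
  out$candidate <- out$neg_log10_p >= threshold_logp
  regions <- call_and_merge(out[, c("chrom", "start", "end")], fit$p,
                            threshold_logp)
  list(windows = out, correlation = corr$correlation,
       fit = list(mu = fit$mu, sigma = fit$sigma), regions = regions)
}

default_pipeline_config <- function() {
  list(window_size = 1e5, step = 2.5e4, min_snps = 10,
       alpha = 0.75, nsamp = 50000, robust_fit = TRUE,
       threshold_logp = 4, hwe_p = 1e-6, maf_max = 0.05,
       ld_window = 50, ld_step = 10, ld_r2 = 0.5, ibs_max = 0.95)
}

write_tsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Run the full selection-scan pipeline
#'
#' Executes, in order: optional simulation (phased sweep/neutral VCF and
#' gene track), VCF reading, two-track QC, diversity summaries, the
#' four-statistic scan, DCMS scoring with candidate-region calling, and
#' gene overlap. Every intermediate table is written to `out_dir` as
#' TSV/BED, together with a JSON run log (seeds, thresholds, counts)
#' and a summary.
#'
#' @param config a configuration list or path to a JSON file. Keys:
#'   either `simulate` (arguments for [sim_config()], plus optional
#'   `sweep` = arguments for [sweep_spec()] and `n_genes`) or `vcf_path`
#'   (phased VCF) with optional `genes_path`; optional `chrom_lengths`
#'   (named list); any of the threshold parameters
#'   (`window_size`, `step`, `min_snps`, `alpha`, `nsamp`,
#'   `robust_fit`, `threshold_logp`, `hwe_p`, `maf_max`, `ld_window`,
#'   `ld_step`, `ld_r2`, `ibs_max`); `groups` for diversity means.
#' @param out_dir artifact directory (created if needed).
#' @param seed global seed; also reused for simulation and MCD unless
#'   the config pins its own.
#' @return Invisibly, a list with `summary`, `qc`, `diversity`, `scan`,
#'   `dcms`, `genes` and the artifact paths.
#' @export
run_pipeline <- function(config, out_dir = tempfile("dcmscan_run_"),
                         seed = 1) {
  if (is.character(config)) config <- jsonlite::read_json(config,
                                                          simplifyVector = TRUE)
  prm <- utils::modifyList(default_pipeline_config(), config,
                           keep.null = TRUE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log <- list(seed = seed, params = prm[names(default_pipeline_config())])

  # --- stage: simulate (optional) -----------------------------------
  genes <- NULL
  chrom_lengths <- NULL
  if (!is.null(config$simulate)) {
    simargs <- config$simulate
    swp <- NULL
    if (!is.null(simargs$sweep)) swp <- do.call(sweep_spec, simargs$sweep)
    n_genes <- simargs$n_genes %||% 0
    n_chrom <- simargs$n_chromosomes %||% 1
    simargs[c("sweep", "n_genes", "n_chromosomes")] <- NULL
    if (is.null(simargs$seed)) simargs$seed <- seed
    cfg <- do.call(sim_config, c(simargs, list(sweep = swp)))
    haps_sim <- simulate_genome(cfg, n_chrom)
    vcf_path <- file.path(out_dir, "simulated.vcf")
    write_simulated_vcf(haps_sim, cfg, vcf_path)
    chrom_lengths <- setNames(rep(cfg$chrom_length_bp, n_chrom),
                              names(haps_sim))
    if (n_genes > 0)
      genes <- make_gene_annotation(cfg$chrom_length_bp, n_genes,
                                    seed = cfg$seed + 3L,
                                    path = file.path(out_dir, "genes.gff3"),
                                    chrom = cfg$chrom)
    log$simulate <- list(config = unclass(cfg)[setdiff(names(cfg), "sweep")],
                         sweep = if (!is.null(swp)) unclass(swp))
  } else {
    vcf_path <- config$vcf_path
    if (is.null(vcf_path)) stop("stage input: need `simulate` or `vcf_path`")
    if (!is.null(config$genes_path))
      genes <- read_gene_annotation(config$genes_path)
    if (!is.null(config$chrom_lengths))
      chrom_lengths <- unlist(config$chrom_lengths)
  }

  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  # --- stage: read + QC ---------------------------------------------
  v <- run_stage("read_vcf", read_vcf(vcf_path, require_phased = TRUE))
  qc_div <- run_stage("qc", qc_track(v, "diversity",
                                     window_snps = prm$ld_window,
                                     step_snps = prm$ld_step,
                                     r2_max = prm$ld_r2))
  qc_sel <- run_stage("qc", qc_track(v, "selection"))
  ibs <- run_stage("qc", ibs_sample_filter(qc_div$genotypes, prm$ibs_max))
  write_tsv(cbind(track = "diversity", qc_div$report),
            file.path(out_dir, "qc_report_diversity.tsv"))
  write_tsv(cbind(track = "selection", qc_sel$report),
            file.path(out_dir, "qc_report_selection.tsv"))
  writeLines(paste(v$genotypes$chrom[qc_sel$keep],
                   v$genotypes$pos[qc_sel$keep], sep = ":"),
             file.path(out_dir, "selection_track.snplist"))

  # --- stage: diversity ---------------------------------------------
  div <- run_stage("diversity", {
    gdiv <- qc_div$genotypes
    hom <- observed_homozygosity(gdiv, config$groups)
    fis <- inbreeding_f(gdiv)
    pc <- if (ncol(gdiv$dosages) >= 2) pca_genotypes(gdiv) else NULL
    list(homozygosity = hom, fis = fis, pca = pc)
  })
  write_tsv(data.frame(sample = names(div$fis),
                       homozygosity = div$homozygosity$individual,
                       fis = div$fis),
            file.path(out_dir, "diversity_individual.tsv"))
  if (!is.null(div$pca))
    write_tsv(data.frame(sample = rownames(div$pca$scores),
                         div$pca$scores[, seq_len(min(5, ncol(div$pca$scores)))],
                         check.names = FALSE),
              file.path(out_dir, "pca_scores.tsv"))

  # --- stage: selection statistics ----------------------------------
  haps <- run_stage("sel_stats",
                    haplotypes_from_vcf(v, qc_sel$keep, chrom_lengths))
  scan <- run_stage("sel_stats",
                    selection_scan(haps, prm$window_size, prm$step,
                                   prm$min_snps))
  write_tsv(scan$windows, file.path(out_dir, "window_stats.tsv"))

  # --- stage: DCMS ---------------------------------------------------
  dc <- run_stage("dcms",
                  dcms_scan(scan$windows, alpha = prm$alpha,
                            nsamp = prm$nsamp, seed = seed + 7L,
                            robust_fit = isTRUE(prm$robust_fit),
                            threshold_logp = prm$threshold_logp))
  write_tsv(dc$windows, file.path(out_dir, "dcms_windows.tsv"))
  write_tsv(dc$regions, file.path(out_dir, "candidate_regions.tsv"))
  write.table(dc$regions[, c("chrom", "start", "end")],
              file.path(out_dir, "candidate_regions.bed"), sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)

  # --- stage: annotate -----------------------------------------------
  gene_overlap <- NULL
  if (!is.null(genes)) {
    gene_overlap <- run_stage("annotate", overlap_genes(dc$regions, genes))
    write_tsv(gene_overlap$table, file.path(out_dir, "region_genes.tsv"))
  }
  nvar <- run_stage("annotate",
                    count_region_variants(v$genotypes$chrom[qc_sel$keep],
                                          v$genotypes$pos[qc_sel$keep],
                                          dc$regions))

  summary <- list(
    n_samples = length(v$genotypes$sample_ids),
    n_samples_kept = length(ibs$keep),
    n_sites_selection = length(qc_sel$keep),
    n_sites_diversity = length(qc_div$keep),
    n_windows = nrow(dc$windows),
    n_windows_excluded = scan$excluded,
    n_candidate_windows = sum(dc$windows$candidate),
    n_regions = nrow(dc$regions),
    region_size_mean = if (nrow(dc$regions)) mean(dc$regions$size_bp) else NA,
    region_size_sd = if (nrow(dc$regions)) sd(dc$regions$size_bp) else NA,
    n_region_variants = sum(nvar),
    n_distinct_genes = if (!is.null(gene_overlap))
      gene_overlap$n_distinct_genes else NA,
    dcms_range = range(dc$windows$dcms),
    fit = dc$fit)
  log$summary <- summary
  log$correlation <- dc$correlation
  jsonlite::write_json(log, file.path(out_dir, "run_log.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE,
                       force = TRUE)

  invisible(list(summary = summary, qc = list(diversity = qc_div,
                                              selection = qc_sel,
                                              ibs = ibs),
                 diversity = div, scan = scan, dcms = dc,
                 genes = gene_overlap, region_variants = nvar,
                 out_dir = out_dir))
}
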