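#' Simulation configuration
#'
#' Describes one simulated chromosome of phased diploid haplotypes. The
#' defaults describe the scale used throughout the test-bed: a 2 Mb
#' chromosome, 20 diploids (40 haplotypes, matching a small livestock
#' resequencing panel rounded to an even haplotype count), ~4000 SNPs
#' (2 SNPs/kb, the density of a several-million-SNP panel on a ~2.2 Gb
#' genome), and an LD scale of 20 kb, the order of magnitude over which
#' r-squared decays in livestock populations.
#'
#' @param n_individuals number of diploid individuals (>= 2).
#' @param chrom_length_bp chromosome length in bp.
#' @param target_snp_count number of segregating sites to simulate. If
#'   `NULL`, derived from `theta` via Watterson's expectation
#'   `theta * sum(1/(1:(2N-1)))` per kb scaled to the chromosome.
#' @param theta scaled mutation intensity per kb; only used when
#'   `target_snp_count` is `NULL`.
#' @param ld_block_bp characteristic LD length: the distance at which the
#'   probability that a haplotype keeps copying the same founder has
#'   decayed by `1/e`. `0` gives unlinked sites.
#' @param missing_rate per-genotype missingness fraction in `[0, 1)`
#'   applied when writing a VCF.
#' @param bad_site_fraction fraction of sites in `[0, 1)` given at least
#'   one GATK-style annotation violating the hard filters when writing a
#'   VCF.
#' @param mean_dp mean per-sample read depth for simulated DP fields.
#' @param sweep optional [sweep_spec()].
#' @param chrom chromosome label.
#' @param seed RNG seed; identical configs give byte-identical output.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_individuals = 20, chrom_length_bp = 2e6,
                       target_snp_count = 4000, theta = 10,
                       ld_block_bp = 2e4, missing_rate = 0,
                       bad_site_fraction = 0, mean_dp = 11.4,
                       sweep = NULL, chrom = "1", seed = 1) {
  stopifnot(n_individuals >= 2, chrom_length_bp > 0,
            missing_rate >= 0, missing_rate < 1,
            bad_site_fraction >= 0, bad_site_fraction < 1,
            ld_block_bp >= 0)
  if (is.null(target_snp_count)) {
    a1 <- sum(1 / seq_len(2 * n_individuals - 1))
    target_snp_count <- round(theta * a1 * chrom_length_bp / 1e3)
  }
  if (target_snp_count > chrom_length_bp)
    stop("target_snp_count exceeds chrom_length_bp")
  if (!is.null(sweep)) stopifnot(inherits(sweep, "sweep_spec"))
  structure(list(n_individuals = as.integer(n_individuals),
                 chrom_length_bp = as.numeric(chrom_length_bp),
                 target_snp_count = as.integer(target_snp_count),
                 theta = theta, ld_block_bp = ld_block_bp,
                 missing_rate = missing_rate,
                 bad_site_fraction = bad_site_fraction,
                 mean_dp = mean_dp, sweep = sweep,
                 chrom = as.character(chrom), seed = as.integer(seed)),
            class = "sim_config")
}

#' Hard-sweep specification
#'
#' A hard selective sweep is caricatured by haplotype copying: a randomly
#' chosen set of carrier haplotypes has its alleles replaced by one donor
#' haplotype over a core interval around the focal site, producing the
#' extended shared haplotype at high frequency and the depressed local
#' diversity that iHS/nSL/pi/Tajima's D detect.
#'
#' @param focal_pos focal position in bp.
#' @param carrier_fraction fraction of haplotypes carrying the swept core,
#'   in (0, 1]; `carrier_fraction * 2N` must be at least 2.
#' @param core_halfwidth_bp half-width of the shared core on each side of
#'   the focal site.
#' @return A `sweep_spec` list.
#' @export
sweep_spec <- function(focal_pos, carrier_fraction = 0.6,
                       core_halfwidth_bp = 1.5e5) {
  stopifnot(focal_pos > 0, carrier_fraction > 0, carrier_fraction <= 1,
            core_halfwidth_bp > 0)
  structure(list(focal_pos = as.numeric(focal_pos),
                 carrier_fraction = carrier_fraction,
                 core_halfwidth_bp = as.numeric(core_halfwidth_bp)),
            class = "sweep_spec")
}

#' Simulate neutral phased haplotypes
#'
#' Founder-mosaic model: each haplotype copies a founder label along the
#' chromosome, switching to a random founder between adjacent sites with
#' probability `1 - exp(-gap / ld_block_bp)`, so stretches of identical
#' haplotypes have characteristic length `ld_block_bp`. The derived-allele
#' count of each site is drawn from the neutral frequency spectrum
#' (P(count = k) proportional to 1/k), and the carriers are the haplotypes
#' whose founder score -- a per-founder process with the same correlation
#' length -- is smallest at that site, which ties allele sharing to
#' founder sharing and yields LD that decays on the `ld_block_bp` scale.
#'
#' @param config a [sim_config()]; any sweep component is ignored here
#'   (see [apply_sweep()]).
#' @param n_founders size of the founder pool.
#' @return A [haplotype_matrix()].
#' @export
simulate_neutral_haplotypes <- function(config, n_founders = 16) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n2 <- 2L * config$n_individuals
  S <- config$target_snp_count
  L <- config$chrom_length_bp
  Fk <- as.integer(n_founders)

  pos <- sort(sample.int(L, S))
  gaps <- c(0, diff(pos))
  rho <- if (config$ld_block_bp > 0) exp(-gaps / config$ld_block_bp)
         else as.numeric(gaps == 0)

  # neutral SFS: derived count k with probability 1/k
  kfreq <- 1 / seq_len(n2 - 1)
  k <- sample.int(n2 - 1, S, replace = TRUE, prob = kfreq)

  alleles <- matrix(0L, n2, S)
  lab <- sample.int(Fk, n2, replace = TRUE)
  score <- rnorm(Fk)
  tie <- 1e-6
  for (s in seq_len(S)) {
    if (s > 1) {
      switch_mask <- runif(n2) > rho[s]
      nsw <- sum(switch_mask)
      if (nsw) lab[switch_mask] <- sample.int(Fk, nsw, replace = TRUE)
      score <- rho[s] * score + sqrt(1 - rho[s]^2) * rnorm(Fk)
    }
    hs <- score[lab] + tie * runif(n2)
    alleles[order(hs)[seq_len(k[s])], s] <- 1L
  }
  haplotype_matrix(alleles, pos, config$chrom, L)
}

#' Plant a hard sweep into a haplotype matrix
#'
#' Replaces the alleles of `ceiling(carrier_fraction * 2N)` randomly
#' chosen haplotypes with one donor haplotype over
#' `[focal_pos - halfwidth, focal_pos + halfwidth]`. Sites outside the
#' core are untouched and dimensions are unchanged.
#'
#' @param hap a [haplotype_matrix()].
#' @param spec a [sweep_spec()].
#' @param seed RNG seed for the carrier/donor draw.
#' @return The modified [haplotype_matrix()].
#' @export
apply_sweep <- function(hap, spec, seed = 1) {
  stopifnot(inherits(hap, "haplotype_matrix"), inherits(spec, "sweep_spec"))
  if (spec$focal_pos > hap$chrom_length)
    stop("focal_pos outside the chromosome")
  if (2 * spec$core_halfwidth_bp >= hap$chrom_length)
    stop("sweep core spans the whole chromosome")
  n2 <- nrow(hap$alleles)
  ncar <- ceiling(spec$carrier_fraction * n2)
  if (ncar < 2) stop("carrier_fraction * 2N must be >= 2")

  set.seed(seed)
  focal_idx <- which.min(abs(hap$pos - spec$focal_pos))
  core <- which(hap$pos >= spec$focal_pos - spec$core_halfwidth_bp &
                  hap$pos <= spec$focal_pos + spec$core_halfwidth_bp)
  stopifnot(focal_idx %in% core)
  donor <- sample.int(n2, 1)
  carriers <- sample.int(n2, ncar)
  hap$alleles[carriers, core] <-
    matrix(hap$alleles[donor, core], ncar, length(core), byrow = TRUE)
  hap
}

# GATK-style hard-filter thresholds; a site fails when FS > 60, QD < 2,
# MQ < 40, QUAL < 30, MQRankSum < -12.5 or ReadPosRankSum < -8.
hard_filter_thresholds <- list(FS = 60, QD = 2, MQ = 40, QUAL = 30,
                               MQRankSum = -12.5, ReadPosRankSum = -8)

# draw per-site annotation fields; rows flagged in `bad` get >= 1 violation
simulate_annotations <- function(S, bad) {
  ann <- data.frame(
    QUAL = runif(S, 100, 1000),
    FS = runif(S, 0, 30),
    QD = runif(S, 5, 30),
    MQ = runif(S, 50, 60),
    MQRankSum = runif(S, -2, 2),
    ReadPosRankSum = runif(S, -2, 2)
  )
  violated <- character(S)
  rules <- c("FS", "QD", "MQ", "QUAL", "MQRankSum", "ReadPosRankSum")
  for (i in which(bad)) {
    picked <- rules[runif(6) < 0.4]
    if (!length(picked)) picked <- sample(rules, 1)
    for (r in picked) {
      ann[[r]][i] <- switch(r,
        FS = runif(1, 60.5, 200),
        QD = runif(1, 0, 1.9),
        MQ = runif(1, 10, 39.5),
        QUAL = runif(1, 1, 29.5),
        MQRankSum = runif(1, -20, -12.6),
        ReadPosRankSum = runif(1, -15, -8.1))
    }
    violated[i] <- paste(picked, collapse = ",")
  }
  list(ann = ann, violated = violated)
}

#' Simulate a multi-chromosome phased genome
#'
#' Convenience wrapper around [simulate_neutral_haplotypes()] /
#' [apply_sweep()]: simulates `n_chromosomes` independent chromosomes of
#' identical geometry (labels `1..k`, per-chromosome seeds derived from
#' `config$seed`), planting the configured sweep on chromosome `1`.
#'
#' @param config a [sim_config()] (its `chrom`/`sweep` fields describe
#'   chromosome 1).
#' @param n_chromosomes number of independent chromosomes.
#' @return Named list of [haplotype_matrix()].
#' @export
simulate_genome <- function(config, n_chromosomes = 1) {
  stopifnot(inherits(config, "sim_config"), n_chromosomes >= 1)
  haps <- lapply(seq_len(n_chromosomes), function(i) {
    ci <- config
    ci$chrom <- as.character(i)
    ci$seed <- config$seed + (i - 1L) * 1009L
    h <- simulate_neutral_haplotypes(ci)
    if (i == 1 && !is.null(config$sweep))
      h <- apply_sweep(h, config$sweep, seed = ci$seed + 2L)
    h
  })
  names(haps) <- as.character(seq_len(n_chromosomes))
  haps
}

#' Write a simulated phased VCF with planted filter violations
#'
#' Emits a VCF 4.2 file with phased GT, per-site INFO annotations
#' (FS, QD, MQ, MQRankSum, ReadPosRankSum), QUAL and per-sample DP.
#' A fraction `bad_site_fraction` of sites receives at least one
#' annotation violating the GATK-style hard-filter thresholds; the rest
#' pass all of them. A fraction `missing_rate` of genotypes is set to
#' `./.` (those sites then fail the 100% call-rate rule). The truth table
#' of planted violations is written next to the VCF as
#' `<path>.truth.tsv` with columns `pos`, `violated_filters`
#' (comma-separated, empty = clean) and `n_missing`.
#'
#' @param hap a [haplotype_matrix()], or a named list of them (one per
#'   chromosome, e.g. from [simulate_genome()]).
#' @param config the [sim_config()] that produced it (supplies
#'   `bad_site_fraction`, `missing_rate`, `mean_dp` and the annotation
#'   seed, derived from `config$seed`).
#' @param path output VCF path.
#' @return Invisibly, the total number of sites written.
#' @export
write_simulated_vcf <- function(hap, config, path) {
  haps <- if (inherits(hap, "haplotype_matrix")) list(hap) else hap
  stopifnot(length(haps) >= 1,
            all(vapply(haps, inherits, TRUE, "haplotype_matrix")),
            inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  N <- nrow(haps[[1]]$alleles) / 2
  samples <- sprintf("S%02d", seq_len(N))

  body <- character(0)
  truth <- NULL
  for (hp in haps) {
    a <- hp$alleles
    n2 <- nrow(a)
    S <- ncol(a)
    bad <- runif(S) < config$bad_site_fraction
    sa <- simulate_annotations(S, bad)

    # REF/ALT drawn per site; transition-biased for cosmetic realism
    ref <- sample(c("A", "C", "G", "T"), S, replace = TRUE)
    ti <- c(A = "G", G = "A", C = "T", T = "C")
    alt <- ifelse(runif(S) < 0.7, ti[ref],
                  vapply(ref, function(r)
                    sample(setdiff(c("A", "C", "G", "T"), r), 1), ""))

    h1 <- a[seq(1, n2, by = 2), , drop = FALSE]
    h2 <- a[seq(2, n2, by = 2), , drop = FALSE]
    gt <- matrix(paste0(h1, "|", h2), N, S)
    miss <- matrix(runif(N * S) < config$missing_rate, N, S)
    gt[miss] <- "./."
    dp <- matrix(pmax(0L, rpois(N * S, config$mean_dp)), N, S)
    field <- matrix(paste0(gt, ":", dp), N, S)

    info <- sprintf(
      "FS=%.3f;QD=%.3f;MQ=%.3f;MQRankSum=%.3f;ReadPosRankSum=%.3f",
      sa$ann$FS, sa$ann$QD, sa$ann$MQ, sa$ann$MQRankSum,
      sa$ann$ReadPosRankSum)
    body <- c(body,
              paste(hp$chrom, as.integer(hp$pos), ".", ref, alt,
                    sprintf("%.2f", sa$ann$QUAL), ".", info, "GT:DP",
                    apply(field, 2, paste, collapse = "\t"), sep = "\t"))
    truth <- rbind(truth,
                   data.frame(chrom = hp$chrom, pos = as.integer(hp$pos),
                              violated_filters = sa$violated,
                              n_missing = colSums(miss)))
  }

  hdr <- c("##fileformat=VCFv4.2",
           "##source=dcmscan-simulator",
           vapply(haps, function(hp)
             sprintf("##contig=<ID=%s,length=%d>", hp$chrom,
                     as.integer(hp$chrom_length)), ""),
           "##INFO=<ID=FS,Number=1,Type=Float,Description=\"Phred-scaled strand bias\">",
           "##INFO=<ID=QD,Number=1,Type=Float,Description=\"Quality by depth\">",
           "##INFO=<ID=MQ,Number=1,Type=Float,Description=\"RMS mapping quality\">",
           "##INFO=<ID=MQRankSum,Number=1,Type=Float,Description=\"Mapping quality rank sum\">",
           "##INFO=<ID=ReadPosRankSum,Number=1,Type=Float,Description=\"Read position rank sum\">",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", samples), collapse = "\t"))
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(c(hdr, body), con)
  write.table(truth, paste0(path, ".truth.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(nrow(truth))
}

#' Simulate a gene annotation track
#'
#' Random non-degenerate gene intervals with stable IDs, written as GFF3
#' (1-based inclusive) or BED (0-based half-open). Intervals are sorted
#' by start and may overlap.
#'
#' @param chrom_length chromosome length in bp.
#' @param n_genes number of genes (>= 0).
#' @param seed RNG seed.
#' @param path optional output path; format from extension (`.gff3`/
#'   `.gff` or `.bed`).
#' @param chrom chromosome label.
#' @param mean_len mean gene length in bp.
#' @return Data frame with columns `chrom`, `start`, `end` (0-based
#'   half-open), `gene_id`, `name`; written to `path` if given.
#' @export
make_gene_annotation <- function(chrom_length, n_genes, seed = 1,
                                 path = NULL, chrom = "1",
                                 mean_len = 2e4) {
  stopifnot(n_genes >= 0, chrom_length > 1)
  set.seed(seed)
  if (n_genes == 0) {
    genes <- data.frame(chrom = character(), start = numeric(),
                        end = numeric(), gene_id = character(),
                        name = character())
  } else {
    len <- pmax(200, pmin(round(rexp(n_genes, 1 / mean_len)),
                          chrom_length - 1))
    start0 <- vapply(len, function(l)
      sample.int(chrom_length - l, 1) - 1, 0)
    o <- order(start0, start0 + len)
    genes <- data.frame(chrom = chrom, start = start0[o],
                        end = (start0 + len)[o],
                        gene_id = sprintf("GENE%04d", seq_len(n_genes)),
                        name = sprintf("gene-%04d", seq_len(n_genes)))
  }
  if (!is.null(path)) {
    if (grepl("\\.bed$", path, ignore.case = TRUE)) {
      write.table(genes[, c("chrom", "start", "end", "gene_id")], path,
                  sep = "\t", quote = FALSE, row.names = FALSE,
                  col.names = FALSE)
    } else {
      lines <- c("##gff-version 3")
      if (nrow(genes))
        lines <- c(lines, paste(genes$chrom, "dcmscan", "gene",
                                genes$start + 1, genes$end, ".", "+", ".",
                                sprintf("ID=%s;Name=%s", genes$gene_id,
                                        genes$name), sep = "\t"))
      writeLines(lines, path)
    }
  }
  genes
}
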