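test_that("neutral simulation is deterministic and respects the config", {
  cfg <- sim_config(n_individuals = 20, chrom_length_bp = 2e6,
                    target_snp_count = 4000, seed = 7)
  h1 <- simulate_neutral_haplotypes(cfg)
  h2 <- simulate_neutral_haplotypes(cfg)
  expect_identical(h1$alleles, h2$alleles)
  expect_identical(h1$pos, h2$pos)
  expect_equal(dim(h1), c(40L, 4000L))
  expect_true(all(diff(h1$pos) > 0))
  expect_error(sim_config(target_snp_count = 100, chrom_length_bp = 50),
               "exceeds")
})

test_that("neutral SFS matches the 1/k spectrum (singleton fraction)", {
  cfg <- sim_config(seed = 19)
  h <- simulate_neutral_haplotypes(cfg)
  n2 <- nrow(h$alleles)
  k <- colSums(h$alleles)
  expect_true(all(k > 0 & k < n2))
  p1 <- 1 / sum(1 / seq_len(n2 - 1))
  tol <- 3 * sqrt(p1 * (1 - p1) / ncol(h$alleles))
  expect_lt(abs(mean(k == 1) - p1), tol)
})

test_that("ld_block_bp -> 0 gives statistically unlinked adjacent sites", {
  cfg <- sim_config(n_individuals = 20, chrom_length_bp = 1e6,
                    target_snp_count = 1000, ld_block_bp = 0, seed = 5)
  h <- simulate_neutral_haplotypes(cfg)
  a <- h$alleles
  adj <- vapply(seq_len(ncol(a) - 1), function(i)
    suppressWarnings(pairwise_r2(a[, i], a[, i + 1])), 0)
  set.seed(1)
  perm <- vapply(seq_len(ncol(a) - 1), function(i)
    suppressWarnings(pairwise_r2(a[, i], sample(a[, i + 1]))), 0)
  # same location up to Monte-Carlo noise of the permuted-null mean
  se <- sd(perm) / sqrt(length(perm))
  expect_lt(abs(mean(adj) - mean(perm)), 4 * se)
  # and a linked simulation is clearly above that null
  cfg2 <- sim_config(n_individuals = 20, chrom_length_bp = 1e6,
                     target_snp_count = 1000, ld_block_bp = 2e4, seed = 5)
  h2 <- simulate_neutral_haplotypes(cfg2)
  adj2 <- vapply(seq_len(ncol(a) - 1), function(i)
    suppressWarnings(pairwise_r2(h2$alleles[, i], h2$alleles[, i + 1])), 0)
  expect_gt(mean(adj2), mean(perm) + 10 * se)
})

test_that("apply_sweep edits only the core and fixes diversity at 2N carriers", {
  sc <- neutral_scene(23)
  spec <- sweep_spec(2.5e5, carrier_fraction = 1, core_halfwidth_bp = 5e4)
  hs <- apply_sweep(sc$hap, spec, seed = 3)
  core <- sc$hap$pos >= 2e5 & sc$hap$pos <= 3e5
  expect_identical(hs$alleles[, !core], sc$hap$alleles[, !core])
  expect_true(all(per_site_pi(hs)[core] == 0))
  expect_equal(dim(hs), dim(sc$hap))

  # partial sweep: swept-allele EHH dominates at 100 kb
  spec2 <- sweep_spec(1e6, 0.6, 1.5e5)
  cfg <- sim_config(seed = 31)
  h <- apply_sweep(simulate_neutral_haplotypes(cfg), spec2, seed = 4)
  # nearest core site where both alleles still have >= 2 carriers
  cand <- order(abs(h$pos - 1e6))
  foc <- cand[which(vapply(cand, function(s) {
    k <- sum(h$alleles[, s])
    k >= 2 && nrow(h$alleles) - k >= 2
  }, TRUE))[1]]
  swept <- as.integer(names(which.max(table(h$alleles[, foc]))))
  e_s <- ehh(h, foc, swept)
  e_o <- ehh(h, foc, 1 - swept)
  at <- function(e) e$ehh[which.min(abs(e$distance_bp - 1e5))]
  expect_gte(at(e_s), at(e_o))
  expect_error(apply_sweep(h, sweep_spec(1e6, 0.6, 2e6), 1), "whole")
})

test_that("simulated VCF round-trips and its truth table is honest", {
  cfg <- sim_config(n_individuals = 10, chrom_length_bp = 4e5,
                    target_snp_count = 600, bad_site_fraction = 0.1,
                    missing_rate = 0.01, seed = 13)
  h <- simulate_neutral_haplotypes(cfg)
  vp <- file.path(tempdir(), "sim13.vcf")
  n <- write_simulated_vcf(h, cfg, vp)
  expect_equal(n, 600)

  v <- read_vcf(vp, require_phased = TRUE)
  expect_equal(v$genotypes$pos, h$pos)
  truth <- read.table(paste0(vp, ".truth.tsv"), header = TRUE, sep = "\t")
  full <- truth$n_missing == 0
  expect_identical(v$hap_alleles[, full], h$alleles[, full])

  # hard filter retains exactly the sites with no planted violation
  hf <- hard_filter_sites(v$annotations)
  expect_identical(hf$keep, truth$violated_filters == "")
  expect_equal(sum(hf$keep), sum(is.na(truth$violated_filters) |
                                   truth$violated_filters == ""))

  # clean config keeps everything
  cfg0 <- sim_config(n_individuals = 10, chrom_length_bp = 4e5,
                     target_snp_count = 600, seed = 13)
  vp0 <- file.path(tempdir(), "sim13c.vcf")
  write_simulated_vcf(h, cfg0, vp0)
  v0 <- read_vcf(vp0)
  expect_true(all(hard_filter_sites(v0$annotations)$keep))
})

test_that("neutral genomes do not inflate the candidate-window rate", {
  # scaled-down calibration: 10 x 2 Mb neutral chromosomes = 770 windows
  # (the full-scale version of this invariant would use >= 3000); at
  # p <= 1e-4 with ~4x overlapping windows the expected flag count is
  # ~0.3, so more than 4 flags would signal order-of-magnitude inflation
  cfg <- sim_config(seed = 808)
  haps <- simulate_genome(cfg, n_chromosomes = 10)
  scan <- selection_scan(haps)
  dc <- dcms_scan(scan$windows, nsamp = 5000, seed = 808,
                  robust_fit = TRUE)
  expect_gte(nrow(dc$windows), 700)
  expect_lte(sum(dc$windows$candidate), 4)
})

test_that("gene annotation simulation is sorted, bounded and deterministic", {
  g1 <- make_gene_annotation(1e6, 50, seed = 9)
  g2 <- make_gene_annotation(1e6, 50, seed = 9)
  expect_identical(g1, g2)
  expect_true(all(g1$start >= 0 & g1$start < g1$end & g1$end <= 1e6))
  expect_true(!is.unsorted(g1$start))

  gff <- file.path(tempdir(), "genes9.gff3")
  make_gene_annotation(1e6, 50, seed = 9, path = gff)
  rt <- read_gene_annotation(gff)
  expect_equal(rt$start, g1$start)
  expect_equal(rt$end, g1$end)

  g0 <- make_gene_annotation(1e6, 0, seed = 1)
  expect_equal(nrow(g0), 0)
  ov <- overlap_genes(data.frame(chrom = "1", start = 0, end = 1e5), g0)
  expect_equal(ov$n_distinct_genes, 0)
})
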