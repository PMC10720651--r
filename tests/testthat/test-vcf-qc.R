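make_vcf_lines <- function(records, samples = c("A", "B")) {
  c("##fileformat=VCFv4.2",
    "##INFO=<ID=FS,Number=1,Type=Float,Description=\"x\">",
    "##INFO=<ID=QD,Number=1,Type=Float,Description=\"x\">",
    "##INFO=<ID=MQ,Number=1,Type=Float,Description=\"x\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"x\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
            "INFO", "FORMAT", samples), collapse = "\t"),
    records)
}

test_that("read_vcf decodes dosages, drops non-biallelic, enforces phasing", {
  p <- file.path(tempdir(), "toy.vcf")
  writeLines(make_vcf_lines(c(
    "1\t100\t.\tA\tG\t50\t.\tFS=1;QD=10;MQ=55\tGT\t0|1\t1|1",
    "1\t200\t.\tC\tT\t50\t.\tFS=1;QD=10;MQ=55\tGT\t./.\t0|0",
    "1\t300\t.\tG\tA,T\t50\t.\tFS=1;QD=10;MQ=55\tGT\t0|1\t0|2",
    "1\t400\t.\tT\tTA\t50\t.\tFS=1;QD=10;MQ=55\tGT\t0|1\t0|0")), p)
  expect_message(v <- read_vcf(p), "2 non-biallelic")
  expect_equal(v$n_dropped, 2)
  expect_equal(v$genotypes$pos, c(100, 200))
  expect_equal(unname(v$genotypes$dosages[, 1]), c(1L, 2L))
  expect_equal(unname(v$genotypes$dosages[, 2]), c(NA_integer_, 0L))
  # missing GT is tolerated under require_phased, unphased is not
  vp <- read_vcf(p, require_phased = TRUE)
  expect_equal(vp$hap_alleles[, 1], c(0L, 1L, 1L, 1L))
  p2 <- file.path(tempdir(), "toy2.vcf")
  writeLines(make_vcf_lines(
    "1\t100\t.\tA\tG\t50\t.\tFS=1;QD=10;MQ=55\tGT\t0/1\t1|1"), p2)
  expect_error(read_vcf(p2, require_phased = TRUE), "unphased")
})

test_that("hard_filter_sites applies strict thresholds with per-rule counts", {
  base <- data.frame(qual = 50, fs = 1, qd = 10, mq = 55, mq_rank = 0,
                     readpos_rank = 0)
  ann <- base[rep(1, 8), ]
  ann$fs[2] <- 61          # fails FS > 60
  ann$fs[3] <- 60          # boundary: retained
  ann$qd[4] <- 1.9
  ann$mq[5] <- 39
  ann$qual[6] <- 29
  ann$mq_rank[7] <- -13
  ann$readpos_rank[8] <- -8.5
  hf <- hard_filter_sites(ann)
  expect_equal(which(!hf$keep), c(2L, 4L, 5L, 6L, 7L, 8L))
  expect_equal(unname(hf$counts[c("FS", "QD", "MQ", "QUAL", "MQRankSum",
                                  "ReadPosRankSum")]),
               c(1, 1, 1, 1, 1, 1))
  # absent rank-sum annotations pass; absent unconditional ones fail
  ann2 <- base
  ann2$mq_rank <- NA
  ann2$readpos_rank <- NA
  expect_true(hard_filter_sites(ann2)$keep)
  ann3 <- base
  ann3$mq <- NA
  expect_false(hard_filter_sites(ann3)$keep)
})

test_that("depth_filter brackets mean depth in [2, mu + 3 sd]", {
  dp <- matrix(10, 4, 1000)
  expect_true(all(depth_filter(dp)))          # sigma = 0 degenerate case
  dp[, 1] <- 1.5                              # below lower bound
  set.seed(2)
  dp[, 2:999] <- 10 + matrix(rnorm(4 * 998), 4)
  mu <- mean(colMeans(dp))
  sg <- sd(colMeans(dp))
  dp[, 1000] <- mu + 5 * sg                   # spiked outlier
  keep <- depth_filter(dp)
  expect_false(keep[1])
  expect_false(keep[1000])
  expect_true(all(keep[2:999]))
  expect_warning(depth_filter(NULL), "skipped")
})

test_that("hwe_exact_test equals full enumeration for n <= 20", {
  expect_equal(hwe_exact_test(1, 0, 1), 1 / 3, tolerance = 1e-12)
  expect_equal(hwe_exact_test(0, 2, 0), 1)
  expect_equal(hwe_exact_test(7, 0, 0), 1)
  for (n in c(2, 5, 11, 20)) {
    for (nAA in 0:n) {
      for (nAa in 0:(n - nAA)) {
        naa <- n - nAA - nAa
        expect_equal(hwe_exact_test(nAA, nAa, naa),
                     hwe_brute(nAA, nAa, naa), tolerance = 1e-12)
      }
    }
  }
})

test_that("site_qc removes call-rate, MAF and HWE failures in order", {
  # 29 diploids as in a small resequencing panel
  set.seed(4)
  n <- 29
  d <- cbind(
    rbinom(n, 2, 0.5),                 # clean
    c(NA, rbinom(n - 1, 2, 0.5)),      # call-rate failure
    c(rep(0, n - 3), 1, 1, 1),         # minor count 3: MAF 3/58 > 0.05
    c(rep(0, n - 1), 1),               # minor count 1: MAF 1/58 <= 0.05
    c(rep(0, 14), rep(2, 15))          # extreme het deficit: HWE failure
  )
  g <- genotype_matrix(d, "1", c(10, 20, 30, 40, 50))
  sq <- site_qc(g)
  expect_equal(sq$keep, c(TRUE, FALSE, TRUE, FALSE, FALSE))
  rep_ <- setNames(sq$report$n_snps, sq$report$criterion)
  expect_equal(unname(rep_[c("call_rate_lt_100", "maf_le_0.05",
                             "hwe_p_lt_1e-6", "remaining")]),
               c(1, 1, 1, 2))
  # additivity: input = exclusions + remaining
  expect_equal(rep_[["input"]],
               sum(rep_[c("call_rate_lt_100", "maf_le_0.05",
                          "hwe_p_lt_1e-6", "remaining")]))
  # every survivor re-passes all thresholds
  ds <- d[, sq$keep, drop = FALSE]
  expect_true(all(colSums(is.na(ds)) == 0))
  af <- colMeans(ds) / 2
  expect_true(all(pmin(af, 1 - af) > 0.05))
  for (s in seq_len(ncol(ds)))
    expect_gte(hwe_exact_test(sum(ds[, s] == 0), sum(ds[, s] == 1),
                              sum(ds[, s] == 2)), 1e-6)
})

test_that("pairwise_r2 is symmetric under allele flips and near 0 when unlinked", {
  set.seed(8)
  x <- rbinom(1000, 2, 0.4)
  expect_equal(pairwise_r2(x, x), 1)
  expect_equal(pairwise_r2(x, 2 - x), 1)
  y <- rbinom(1000, 2, 0.4)
  expect_lt(pairwise_r2(x, y), 0.01)
  expect_warning(r <- pairwise_r2(c(1, NA), c(NA, 1)), "undefined")
  expect_equal(r, 0)
})

test_that("ld_prune removes duplicates, keeps independents, self-checks clean", {
  set.seed(15)
  d <- matrix(rbinom(40 * 60, 2, 0.5), 40, 60)
  d[, 31] <- d[, 30]                       # duplicated site
  g <- genotype_matrix(d, "1", seq_len(60) * 100)
  kept <- ld_prune(g)
  expect_true(xor(30 %in% kept, 31 %in% kept))
  # pruning is invariant to allele-label flips
  d2 <- d
  d2[, 30] <- 2 - d2[, 30]
  d2[, 31] <- 2 - d2[, 31]
  expect_equal(ld_prune(genotype_matrix(d2, "1", g$pos)), kept)
  # final set has no violating pair within any window (self-check oracle)
  for (start in seq(1, 60, by = 10)) {
    win <- intersect(start:(start + 49), kept)
    if (length(win) < 2) next
    r2 <- cor(d[, win])^2
    diag(r2) <- 0
    expect_lt(max(r2), 0.5 + 1e-12)
  }
})

test_that("ibs_sample_filter removes duplicated samples, keeps unrelated ones", {
  sc <- neutral_scene(77)
  g <- hap_to_dosages_for_test(sc$hap)
  expect_equal(ibs_sample_filter(g)$keep, seq_len(nrow(g$dosages)))
  # duplicate sample 1 into sample 2
  d <- g$dosages
  d[2, ] <- d[1, ]
  g2 <- genotype_matrix(d, g$chrom, g$pos)
  kept <- ibs_sample_filter(g2)$keep
  expect_equal(length(kept), nrow(d) - 1)
  expect_false(all(c(1, 2) %in% kept))
  # homozygous-opposite pair has IBS 0
  g3 <- genotype_matrix(rbind(rep(0L, 10), rep(2L, 10)), "1",
                        seq_len(10) * 10)
  out <- ibs_sample_filter(g3)
  expect_equal(out$ibs[1, 2], 0)
  expect_equal(out$keep, c(1L, 2L))
})
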