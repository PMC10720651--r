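# Independent oracles and small fixture builders shared across the suite.
# These deliberately use different computational routes than the package.

# random segregating haplotype matrix
rand_hap <- function(n_hap, n_site, seed, spacing = 500) {
  set.seed(seed)
  repeat {
    a <- matrix(rbinom(n_hap * n_site, 1, runif(1, 0.2, 0.8)),
                n_hap, n_site)
    d <- colSums(a)
    a <- a[, d > 0 & d < n_hap, drop = FALSE]
    if (ncol(a) >= 2) break
  }
  haplotype_matrix(a, seq_len(ncol(a)) * spacing, "1",
                   (ncol(a) + 1) * spacing)
}

# Tajima's D by explicit pairwise-difference loops
taj_brute <- function(a) {
  n <- nrow(a)
  pidiff <- 0
  for (i in 1:(n - 1))
    for (j in (i + 1):n)
      pidiff <- pidiff + sum(a[i, ] != a[j, ])
  pihat <- pidiff / choose(n, 2)
  d <- colSums(a)
  S <- sum(d > 0 & d < n)
  i <- 1:(n - 1)
  a1 <- sum(1 / i); a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1)); b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1; c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  (pihat - S / a1) / sqrt(c1 / a1 * S + c2 / (a1^2 + a2) * S * (S - 1))
}

# per-site pi by enumerating all haplotype pairs
pi_brute <- function(a) {
  n <- nrow(a)
  pairs <- utils::combn(n, 2)
  vapply(seq_len(ncol(a)), function(s)
    mean(a[pairs[1, ], s] != a[pairs[2, ], s]), 0)
}

# HWE exact test via Levene's absolute probabilities (no normalization):
# P(het = h | n, nA) = n! 2^h nA! na! / (homA! h! homa! (2n)!)
hwe_brute <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  nA <- 2 * n_AA + n_Aa
  na <- 2 * n - nA
  m <- min(nA, na)
  if (m == 0) return(1)
  hets <- seq(m %% 2, m, by = 2)
  pr <- vapply(hets, function(h) {
    homA <- (nA - h) / 2
    homa <- (na - h) / 2
    exp(lfactorial(n) + h * log(2) + lfactorial(nA) + lfactorial(na) -
          lfactorial(homA) - lfactorial(h) - lfactorial(homa) -
          lfactorial(2 * n))
  }, 0)
  obs <- pr[match(n_Aa, hets)]
  min(1, sum(pr[pr <= obs * (1 + 1e-9)]))
}

# exhaustive-subset MCD correlation (R route: combn + cov + det)
mcd_brute_corr <- function(x, alpha = 0.75) {
  n <- nrow(x)
  h <- ceiling(alpha * n)
  subsets <- utils::combn(n, h)
  dets <- apply(subsets, 2, function(i) det(cov(x[i, , drop = FALSE])))
  best <- subsets[, which.min(dets)]
  stats::cov2cor(cov(x[best, , drop = FALSE]))
}

# brute-force interval overlap (0-based half-open, >= 1 bp shared)
overlap_brute <- function(regions, genes) {
  lapply(seq_len(nrow(regions)), function(i) {
    hit <- genes$chrom == regions$chrom[i] &
      genes$start < regions$end[i] & genes$end > regions$start[i]
    genes$gene_id[hit]
  })
}

gm_subset_for_test <- function(g, idx) {
  genotype_matrix(g$dosages[, idx, drop = FALSE], g$chrom[idx], g$pos[idx])
}

# pair haplotype rows (2i-1, 2i) into diploid dosages
hap_to_dosages_for_test <- function(hap) {
  a <- hap$alleles
  n2 <- nrow(a)
  genotype_matrix(a[seq(1, n2, 2), ] + a[seq(2, n2, 2), ],
                  hap$chrom, hap$pos)
}

# small neutral simulated scene used by several files
neutral_scene <- function(seed = 11, ...) {
  cfg <- sim_config(n_individuals = 12, chrom_length_bp = 5e5,
                    target_snp_count = 800, seed = seed, ...)
  list(cfg = cfg, hap = simulate_neutral_haplotypes(cfg))
}
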