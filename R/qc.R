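#' GATK-style hard filtering of sites
#'
#' A site is removed iff any rule fires: `FS > 60`, `QD < 2`, `MQ < 40`,
#' `QUAL < 30`, `MQRankSum < -12.5` or `ReadPosRankSum < -8`. A site may
#' count toward several rules. The two rank-sum annotations are often
#' absent in real callsets (no heterozygous reference reads), so an
#' absent value passes those two rules; QUAL/FS/QD/MQ are unconditional
#' and an absent value fails.
#'
#' @param ann annotation data frame from [read_vcf()] (columns `qual`,
#'   `fs`, `qd`, `mq`, `mq_rank`, `readpos_rank`).
#' @return List with `keep` (logical mask) and `counts` (named per-rule
#'   exclusion counts plus `excluded`/`retained`).
#' @export
hard_filter_sites <- function(ann) {
  fail_na <- function(x, bad) ifelse(is.na(x), TRUE, bad(x))
  pass_na <- function(x, bad) ifelse(is.na(x), FALSE, bad(x))
  fails <- cbind(
    FS = fail_na(ann$fs, function(x) x > 60),
    QD = fail_na(ann$qd, function(x) x < 2),
    MQ = fail_na(ann$mq, function(x) x < 40),
    QUAL = fail_na(ann$qual, function(x) x < 30),
    MQRankSum = pass_na(ann$mq_rank, function(x) x < -12.5),
    ReadPosRankSum = pass_na(ann$readpos_rank, function(x) x < -8)
  )
  keep <- rowSums(fails) == 0
  counts <- c(colSums(fails), excluded = sum(!keep), retained = sum(keep))
  list(keep = keep, counts = counts)
}

#' Depth-of-coverage filter
#'
#' Retains sites whose mean per-sample depth lies in `[2, mu + 3*sigma]`,
#' where `mu` and `sigma` are the mean and SD of per-site mean depth
#' across all sites.
#'
#' @param dp samples x sites depth matrix (or `NULL`).
#' @return Logical keep mask (all `TRUE`, with a warning, when depth is
#'   absent).
#' @export
depth_filter <- function(dp) {
  if (is.null(dp) || all(is.na(dp))) {
    warning("no DP values; depth filter skipped")
    return(rep(TRUE, if (is.null(dp)) 0 else ncol(dp)))
  }
  site_mean <- colMeans(dp, na.rm = TRUE)
  mu <- mean(site_mean)
  sigma <- sd(site_mean)
  if (is.na(sigma)) sigma <- 0
  site_mean >= 2 & site_mean <= mu + 3 * sigma
}

#' Hardy-Weinberg exact test
#'
#' Two-sided conditional exact test: with the minor-allele count fixed,
#' all heterozygote counts of matching parity are enumerated, weighted by
#' the exact conditional distribution, and the probabilities of
#' configurations no more likely than the observed one are summed.
#'
#' @param n_AA,n_Aa,n_aa genotype counts.
#' @return p-value in (0, 1]; monomorphic samples give 1.
#' @export
hwe_exact_test <- function(n_AA, n_Aa, n_aa) {
  stopifnot(n_AA >= 0, n_Aa >= 0, n_aa >= 0)
  n <- n_AA + n_Aa + n_aa
  if (n < 1) stop("empty sample")
  n_minor <- min(2 * n_AA + n_Aa, 2 * n_aa + n_Aa)
  if (n_minor == 0) return(1)

  hets <- seq(n_minor %% 2, n_minor, by = 2)
  # conditional log-probability up to a constant:
  #   P(het = h | n, n_minor) propto n! 2^h / (n_hommin! h! n_hommaj!)
  logp <- lfactorial(n) + hets * log(2) -
    lfactorial((n_minor - hets) / 2) - lfactorial(hets) -
    lfactorial(n - (n_minor + hets) / 2)
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  obs <- p[match(n_Aa, hets)]
  min(1, sum(p[p <= obs * (1 + 1e-12)]))
}

#' Site-level quality control
#'
#' The three-criterion QC applied identically to both analysis tracks:
#' sites are removed, in order and with exclusive attribution, when
#' (1) any genotype is missing (call rate < 100%), (2) minor-allele
#' frequency is \eqn{\le} 0.05, or (3) the Hardy-Weinberg exact p-value is
#' < 1e-6.
#'
#' @param g a [genotype_matrix()].
#' @param hwe_p HWE p-value threshold.
#' @param maf_max MAF threshold (exclusive: sites with MAF strictly
#'   greater survive).
#' @return List with `keep` (logical mask) and `report` (data frame of
#'   exclusive per-criterion exclusions plus input/remaining; the
#'   Table-1-style layout).
#' @export
site_qc <- function(g, hwe_p = 1e-6, maf_max = 0.05) {
  d <- g$dosages
  S <- ncol(d)
  callrate_fail <- colSums(is.na(d)) > 0
  maf_fail <- !callrate_fail & gm_maf(g) <= maf_max
  active <- !callrate_fail & !maf_fail
  hwe_fail <- rep(FALSE, S)
  for (s in which(active)) {
    x <- d[, s]
    hwe_fail[s] <-
      hwe_exact_test(sum(x == 0), sum(x == 1), sum(x == 2)) < hwe_p
  }
  keep <- active & !hwe_fail
  report <- data.frame(
    criterion = c("input", "call_rate_lt_100", "maf_le_0.05",
                  "hwe_p_lt_1e-6", "remaining"),
    n_snps = c(S, sum(callrate_fail), sum(maf_fail), sum(hwe_fail),
               sum(keep)))
  list(keep = keep, report = report)
}

#' Squared genotype correlation between two sites
#'
#' Squared Pearson correlation of dosage vectors over jointly non-missing
#' samples; 0 when either vector is constant, 0 with a warning when fewer
#' than two joint observations exist.
#'
#' @param g_i,g_j dosage vectors.
#' @return r-squared in `[0, 1]`.
#' @export
pairwise_r2 <- function(g_i, g_j) {
  ok <- !is.na(g_i) & !is.na(g_j)
  if (sum(ok) < 2) {
    warning("fewer than 2 joint observations; r2 undefined, using 0")
    return(0)
  }
  x <- g_i[ok]
  y <- g_j[ok]
  if (sd(x) == 0 || sd(y) == 0) return(0)
  cor(x, y)^2
}

# r2 matrix over the columns of a complete dosage matrix; constant
# columns give 0 rather than NA
r2_matrix <- function(d) {
  sds <- apply(d, 2, sd)
  r <- suppressWarnings(cor(d))
  r[is.na(r)] <- 0
  r[, sds == 0] <- 0
  r[sds == 0, ] <- 0
  diag(r) <- 1
  r^2
}

#' Windowed LD pruning
#'
#' PLINK-style greedy pruning (`--indep-pairwise`): within each window of
#' `window_snps` sites, while any retained pair has r-squared above
#' `r2_max`, the member of the worst offending pair with the lower MAF
#' is removed (ties remove the later site); the window then slides by
#' `step_snps`. The final kept set has no violating pair inside any
#' window.
#'
#' @param g a [genotype_matrix()] (complete, post call-rate filter).
#' @param window_snps,step_snps,r2_max pruning parameters.
#' @return Integer vector of kept site indices (relative to `g`).
#' @export
ld_prune <- function(g, window_snps = 50, step_snps = 10, r2_max = 0.5) {
  maf <- gm_maf(g)
  keep <- rep(TRUE, ncol(g$dosages))
  for (ch in unique(g$chrom)) {
    sites <- which(g$chrom == ch)
    start <- 1
    repeat {
      win <- sites[seq(start, min(start + window_snps - 1, length(sites)))]
      act <- win[keep[win]]
      if (length(act) > 1) {
        r2 <- r2_matrix(g$dosages[, act, drop = FALSE])
        diag(r2) <- 0
        while (TRUE) {
          w <- which(r2 > r2_max, arr.ind = TRUE)
          if (!nrow(w)) break
          top <- w[which.max(r2[w]), ]
          pair <- act[c(top[1], top[2])]
          victim <- if (maf[pair[1]] < maf[pair[2]]) pair[1]
                    else if (maf[pair[2]] < maf[pair[1]]) pair[2]
                    else max(pair)
          keep[victim] <- FALSE
          vi <- match(victim, act)
          r2[vi, ] <- 0
          r2[, vi] <- 0
        }
      }
      if (start + window_snps - 1 >= length(sites)) break
      start <- start + step_snps
    }
  }
  which(keep)
}

#' Identity-by-state sample filter
#'
#' Pairwise IBS similarity is the mean, over jointly called sites, of
#' `(2 - |d_i - d_j|) / 2`. While any pair reaches `ibs_max`, the member
#' with the lower call rate is removed (ties remove the later sample).
#'
#' @param g a [genotype_matrix()].
#' @param ibs_max removal threshold (default 0.95).
#' @return List with `keep` (indices of retained samples) and `ibs`
#'   (the initial similarity matrix).
#' @export
ibs_sample_filter <- function(g, ibs_max = 0.95) {
  d <- g$dosages
  n <- nrow(d)
  stopifnot(n >= 2)
  ibs <- matrix(1, n, n, dimnames = list(g$sample_ids, g$sample_ids))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      ok <- !is.na(d[i, ]) & !is.na(d[j, ])
      ibs[i, j] <- ibs[j, i] <-
        if (any(ok)) mean((2 - abs(d[i, ok] - d[j, ok])) / 2) else 0
    }
  }
  callrate <- rowMeans(!is.na(d))
  alive <- rep(TRUE, n)
  repeat {
    m <- ibs
    m[!alive, ] <- 0
    m[, !alive] <- 0
    diag(m) <- 0
    if (max(m) < ibs_max) break
    top <- which(m == max(m), arr.ind = TRUE)[1, ]
    pair <- sort(c(top[1], top[2]))
    victim <- if (callrate[pair[1]] < callrate[pair[2]]) pair[1]
              else if (callrate[pair[2]] < callrate[pair[1]]) pair[2]
              else pair[2]
    alive[victim] <- FALSE
  }
  list(keep = which(alive), ibs = ibs)
}

#' Two-track SNP quality control
#'
#' Applies the full QC cascade to a read VCF: hard filters, depth filter,
#' then per-track site QC (call rate, MAF, HWE) with LD pruning only in
#' the diversity track.
#'
#' @param v result of [read_vcf()].
#' @param track `"diversity"` (with LD pruning) or `"selection"`
#'   (without).
#' @param ... passed to [ld_prune()].
#' @return List with `keep` (site indices into the VCF read), `report`
#'   (Table-1-style data frame including hard-filter and depth stages)
#'   and `genotypes` (the QC'd [genotype_matrix()]).
#' @export
qc_track <- function(v, track = c("selection", "diversity"), ...) {
  track <- match.arg(track)
  hf <- hard_filter_sites(v$annotations)
  dpk <- if (is.null(v$dp)) rep(TRUE, length(hf$keep)) else depth_filter(v$dp)
  idx <- which(hf$keep & dpk)
  g <- gm_subset_sites(v$genotypes, idx)
  sq <- site_qc(g)
  idx2 <- idx[sq$keep]
  g2 <- gm_subset_sites(v$genotypes, idx2)
  ld_removed <- 0L
  if (track == "diversity" && ncol(g2$dosages) > 1) {
    kept <- ld_prune(g2, ...)
    ld_removed <- ncol(g2$dosages) - length(kept)
    idx2 <- idx2[kept]
    g2 <- gm_subset_sites(v$genotypes, idx2)
  }
  report <- data.frame(
    criterion = c("input", "hard_filter", "depth",
                  sq$report$criterion[2:4],
                  "ld_r2_gt_0.5", "remaining"),
    n_snps = c(length(hf$keep), sum(!hf$keep), sum(hf$keep & !dpk),
               sq$report$n_snps[2:4], ld_removed, length(idx2)))
  list(keep = idx2, report = report, genotypes = g2)
}
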