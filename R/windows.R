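#' Sliding-window grid
#'
#' 0-based half-open windows `[start, start + size)` anchored at
#' coordinate 0 of each chromosome, advancing by `step` (which must
#' divide `size`). Every window whose start lies within the chromosome
#' and whose end does not overrun it is emitted.
#'
#' @param chrom_lengths named numeric vector of chromosome lengths (bp).
#' @param size window size in bp (default 100 kb).
#' @param step step in bp (default 25 kb).
#' @return Data frame with `chrom`, `start`, `end` (0-based half-open).
#' @export
window_grid <- function(chrom_lengths, size = 1e5, step = 2.5e4) {
  stopifnot(size %% step == 0, size > 0)
  out <- lapply(names(chrom_lengths), function(ch) {
    L <- chrom_lengths[[ch]]
    if (L < size) return(NULL)
    starts <- seq(0, L - size, by = step)
    data.frame(chrom = ch, start = starts, end = starts + size)
  })
  do.call(rbind, out)
}

# indices of sites (chrom/pos, 1-based pos) inside each half-open window
sites_in_windows <- function(grid, chrom, pos) {
  lapply(seq_len(nrow(grid)), function(i) {
    which(chrom == grid$chrom[i] & pos > grid$start[i] &
            pos <= grid$end[i])
  })
}

# Tajima constants for n haplotypes
tajima_constants <- function(n) {
  i <- seq_len(n - 1)
  a1 <- sum(1 / i)
  a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  list(a1 = a1, a2 = a2, b1 = b1, b2 = b2, c1 = c1, c2 = c2,
       e1 = c1 / a1, e2 = c2 / (a1^2 + a2))
}

#' Per-site nucleotide diversity
#'
#' For derived count `d` among `n` haplotypes, the probability that two
#' haplotypes drawn without replacement differ:
#' `pi_s = 2 d (n - d) / (n (n - 1))`.
#'
#' @param hap a [haplotype_matrix()].
#' @return Numeric vector, one value per site.
#' @export
per_site_pi <- function(hap) {
  n <- nrow(hap$alleles)
  d <- colSums(hap$alleles)
  2 * d * (n - d) / (n * (n - 1))
}

#' Sliding-window Tajima's D
#'
#' Per window: `S` segregating sites, mean pairwise difference
#' `pi = sum_s 2 d (n - d) / (n (n - 1))`, and
#' `D = (pi - S/a1) / sqrt(e1 S + e2 S (S - 1))` with the usual constants
#' `a1, a2, b1, b2, c1, c2, e1, e2` for `n` haplotypes. Windows with no
#' segregating site are `NA`.
#'
#' @param hap a [haplotype_matrix()].
#' @param grid window grid for this chromosome (see [window_grid()]).
#' @return Data frame: grid columns plus `n_snps`, `S_seg`, `pi_sum`,
#'   `tajima_d`.
#' @export
tajimas_d <- function(hap, grid) {
  n <- nrow(hap$alleles)
  if (n < 4) stop("need at least 4 haplotypes")
  k <- tajima_constants(n)
  d <- colSums(hap$alleles)
  seg <- d > 0 & d < n
  pi_site <- per_site_pi(hap)
  idx <- sites_in_windows(grid, rep(hap$chrom, length(hap$pos)), hap$pos)
  S <- vapply(idx, function(i) sum(seg[i]), 0)
  pi_sum <- vapply(idx, function(i) sum(pi_site[i]), 0)
  D <- ifelse(S > 0,
              (pi_sum - S / k$a1) / sqrt(k$e1 * S + k$e2 * S * (S - 1)),
              NA_real_)
  cbind(grid, n_snps = lengths(idx), S_seg = S, pi_sum = pi_sum,
        tajima_d = D)
}

#' Aggregate per-site values onto a window grid
#'
#' Mean of the constituent per-site values in each (overlapping) window;
#' a site contributes to every window covering it.
#'
#' @param values numeric vector of per-site values (`NA` allowed; the
#'   mean is over non-missing values).
#' @param chrom,pos site coordinates (1-based positions).
#' @param grid window grid.
#' @return Data frame: grid plus `n_snps` (sites in window), `n_used`
#'   (non-missing values) and `mean_value`.
#' @export
window_aggregate <- function(values, chrom, pos, grid) {
  if (!nrow(grid)) stop("empty window grid")
  idx <- sites_in_windows(grid, chrom, pos)
  mv <- vapply(idx, function(i) {
    v <- values[i]
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  }, 0)
  cbind(grid, n_snps = lengths(idx),
        n_used = vapply(idx, function(i) sum(!is.na(values[i])), 0),
        mean_value = mv)
}

# genome-wide z-standardization of a vector (NA-tolerant)
zstd <- function(x) {
  mu <- mean(x, na.rm = TRUE)
  s <- sd(x, na.rm = TRUE)
  if (is.na(s) || s == 0) return(rep(0, length(x)))
  (x - mu) / s
}
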