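#' Extended haplotype homozygosity from a core site
#'
#' Among the carriers of `core_allele` at `core_site`, EHH at site `x` is
#' the probability that two randomly drawn carriers are identical over
#' the interval from the core to `x`:
#' `sum_g C(m_g, 2) / C(n_carriers, 2)` over groups `g` of identical
#' extended haplotypes. EHH is 1 at the core and non-increasing outward.
#'
#' This is the reference (plain R) implementation used for curves and
#' verification; the genome scans ([ihs()], [nsl()]) use a compiled
#' walker.
#'
#' @param hap a [haplotype_matrix()].
#' @param core_site site index (column).
#' @param core_allele 0 or 1.
#' @param max_extend_bp stop once this physical distance is exceeded.
#' @return Data frame with `site`, `pos`, `distance_bp` and `ehh`,
#'   ordered from the left end to the right end of the evaluated span
#'   (the core row included with `ehh = 1`).
#' @export
ehh <- function(hap, core_site, core_allele, max_extend_bp = 1e6) {
  a <- hap$alleles
  carriers <- which(a[, core_site] == core_allele)
  if (length(carriers) < 2)
    stop("core allele carried by fewer than 2 haplotypes")
  nc <- length(carriers)
  denom <- choose(nc, 2)

  one_side <- function(dir) {
    sites <- integer(0)
    vals <- numeric(0)
    j <- core_site + dir
    key <- rep("", nc)
    while (j >= 1 && j <= ncol(a) &&
           abs(hap$pos[j] - hap$pos[core_site]) <= max_extend_bp) {
      key <- paste0(key, a[carriers, j])
      grp <- table(key)
      sites <- c(sites, j)
      vals <- c(vals, sum(choose(grp, 2)) / denom)
      j <- j + dir
    }
    data.frame(site = sites, ehh = vals)
  }
  left <- one_side(-1L)
  right <- one_side(1L)
  out <- rbind(left[rev(seq_len(nrow(left))), , drop = FALSE],
               data.frame(site = core_site, ehh = 1),
               right)
  out$pos <- hap$pos[out$site]
  out$distance_bp <- out$pos - hap$pos[core_site]
  rownames(out) <- NULL
  out[, c("site", "pos", "distance_bp", "ehh")]
}

# shared driver for ihs()/nsl(); site_scale switches distance units
scan_haplotype_score <- function(hap, cutoff, maxgap, maxextend,
                                 site_scale) {
  res <- cpp_scan_ihh(hap$alleles, hap$pos, cutoff, maxgap, maxextend,
                      site_scale)
  score <- log(res$ihh_a / res$ihh_d)
  data.frame(chrom = hap$chrom, pos = hap$pos, freq = res$freq,
             ihh_a = res$ihh_a, ihh_d = res$ihh_d, score = score,
             status = factor(res$status, levels = 0:4,
                             labels = c("ok", "gap", "edge", "mono",
                                        "zero_integral")))
}

#' Per-SNP unstandardized iHS
#'
#' For every site, the EHH curve of each allele is integrated
#' (trapezoidal rule against physical distance, both directions from the
#' core) until EHH drops below `cutoff`; `iHS = ln(iHH_A / iHH_D)` with
#' A the ancestral (reference) and D the derived (alternate) allele.
#' Sites are skipped (NA score, with a reason code) when an inter-site
#' gap exceeds `maxgap_bp` or the chromosome edge is reached before the
#' cutoff, when an allele has fewer than two carriers, or when an
#' integral is zero; truncation at `max_extend_bp` keeps the site.
#'
#' No outgroup polarization is attempted: the reference allele is
#' treated as ancestral. Mispolarized sites flip the sign of iHS, which
#' the two-tailed treatment downstream absorbs.
#'
#' @param hap a [haplotype_matrix()].
#' @param cutoff EHH truncation level (selscan default 0.05).
#' @param maxgap_bp maximum tolerated inter-site gap (default 200 kb).
#' @param max_extend_bp maximum extension from the core (default 1 Mb).
#' @return Data frame with `chrom`, `pos`, `freq` (derived allele),
#'   `ihh_a`, `ihh_d`, `score` and `status`.
#' @export
ihs <- function(hap, cutoff = 0.05, maxgap_bp = 2e5, max_extend_bp = 1e6) {
  scan_haplotype_score(hap, cutoff, maxgap_bp, max_extend_bp,
                       site_scale = FALSE)
}

#' Per-SNP unstandardized nSL
#'
#' Identical machinery to [ihs()] but haplotype-homozygosity lengths are
#' measured in numbers of sites (each inter-site step has length 1),
#' with no gap rule: `nSL = ln(SL_A / SL_D)`. Invariant under any
#' strictly monotone redefinition of physical positions.
#'
#' @param hap a [haplotype_matrix()].
#' @param cutoff EHH truncation level.
#' @param max_extend_sites maximum extension in sites (default 200).
#' @return As [ihs()].
#' @export
nsl <- function(hap, cutoff = 0.05, max_extend_sites = 200) {
  scan_haplotype_score(hap, cutoff, Inf, max_extend_sites,
                       site_scale = TRUE)
}

#' Frequency-bin standardization of haplotype scores
#'
#' Standardizes scores within equal-width derived-allele-frequency bins
#' (z-score against the bin mean and SD), the usual normalization for
#' iHS/nSL whose raw values trend with allele frequency. Bins with fewer
#' than two non-missing scores are merged with their nearest lower
#' neighbor (the first bin merges upward). A bin with zero SD yields
#' z = 0.
#'
#' @param scores numeric vector (NA allowed).
#' @param freqs derived-allele frequencies in `[0, 1]`.
#' @param n_bins number of equal-width bins (default 50).
#' @return Numeric vector of standardized scores (NA preserved).
#' @export
standardize_by_freq <- function(scores, freqs, n_bins = 50) {
  stopifnot(length(scores) == length(freqs))
  bin <- pmin(pmax(ceiling(freqs * n_bins), 1L), n_bins)
  ok <- !is.na(scores)
  # merge sparse bins leftward so every effective bin has >= 2 scores
  counts <- tabulate(bin[ok], n_bins)
  eff <- integer(n_bins)
  cur <- 1L
  acc <- 0L
  for (b in seq_len(n_bins)) {
    eff[b] <- cur
    acc <- acc + counts[b]
    if (acc >= 2 && b < n_bins) {
      cur <- cur + 1L
      acc <- 0L
    }
  }
  # a trailing sparse group merges back into the previous one
  if (acc < 2 && cur > 1L) eff[eff == cur] <- cur - 1L
  z <- rep(NA_real_, length(scores))
  for (e in unique(eff)) {
    sel <- ok & eff[bin] == e
    if (!any(sel)) next
    mu <- mean(scores[sel])
    s <- sd(scores[sel])
    z[sel] <- if (is.na(s) || s == 0) 0 else (scores[sel] - mu) / s
  }
  z
}
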