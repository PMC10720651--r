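#' Fractional-rank p-values for a statistic
#'
#' Converts per-window statistic values to p-values `rank / (n + 1)`
#' (ties share their mean rank), so p never reaches 0 or 1. Left tail:
#' the most negative value gets the smallest p (used for Tajima's D and
#' pi, where selection depresses the statistic). Two-tailed: values are
#' ranked by descending magnitude, so the largest `|value|` gets the
#' smallest p (used for iHS and nSL).
#'
#' @param values finite numeric vector, length >= 2.
#' @param tail `"left"` or `"two"`.
#' @return Numeric vector of p-values in (0, 1).
#' @export
stat_to_pvalue <- function(values, tail = c("left", "two")) {
  tail <- match.arg(tail)
  stopifnot(length(values) >= 2, all(is.finite(values)))
  n <- length(values)
  if (all(values == values[1])) return(rep(0.5, n))
  r <- switch(tail,
              left = rank(values, ties.method = "average"),
              two = rank(-abs(values), ties.method = "average"))
  r / (n + 1)
}

#' Robust correlation via the minimum covariance determinant
#'
#' FAST-MCD estimate of the correlation between statistics across
#' windows: the `h = ceiling(alpha * n)`-point subset with the smallest
#' covariance determinant is located (exhaustively when `choose(n, h)`
#' is small, otherwise by `nsamp` random `(d+1)`-element starts with
#' concentration steps), the covariance is rescaled by the standard
#' consistency factor and converted to a correlation matrix.
#'
#' @param x numeric matrix, windows x statistics (no missing values).
#' @param alpha MCD support fraction (default 0.75).
#' @param nsamp number of random starting subsets (default 50000).
#' @param seed optional RNG seed (restores the RNG state on exit).
#' @param exhaustive_limit use exact enumeration when `choose(n, h)` is
#'   at most this.
#' @return List with `correlation` (d x d), `covariance` (consistency-
#'   corrected), `center`, `subset` (row indices of the optimal
#'   h-subset) and `h`.
#' @export
mcd_correlation <- function(x, alpha = 0.75, nsamp = 50000, seed = NULL,
                            exhaustive_limit = 50000) {
  x <- as.matrix(x)
  stopifnot(!anyNA(x), alpha > 0.5, alpha <= 1)
  n <- nrow(x)
  d <- ncol(x)
  if (n < 4 * (d + 1)) stop("too few windows for a stable MCD fit")
  if (any(apply(x, 2, sd) == 0))
    stop("constant column: covariance is singular")
  h <- as.integer(ceiling(alpha * n))

  # exact-fit degeneracy: collinear columns make every subset singular
  cv <- stats::cov(x)
  ev <- eigen(cv, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < max(ev) * 1e-12) {
    warning("exact fit: columns are collinear; ",
            "returning the classical covariance of all rows")
    return(list(correlation = stats::cov2cor(cv), covariance = cv,
                center = colMeans(x), subset = seq_len(n), h = h))
  }

  if (!is.null(seed)) {
    if (exists(".Random.seed", globalenv())) {
      old <- get(".Random.seed", globalenv())
      on.exit(assign(".Random.seed", old, globalenv()))
    }
    set.seed(seed)
  }
  exhaustive <- choose(n, h) <= exhaustive_limit
  fit <- cpp_mcd(x, h, as.integer(nsamp), exhaustive)

  # consistency factor for the h/n-trimmed normal covariance
  q <- qchisq(h / n, d)
  cf <- (h / n) / pchisq(q, d + 2)
  covc <- fit$cov * cf
  corr <- stats::cov2cor(covc)
  dimnames(corr) <- list(colnames(x), colnames(x))
  list(correlation = corr, covariance = covc,
       center = as.numeric(fit$center), subset = as.integer(fit$subset),
       h = h)
}

#' De-correlated composite of multiple signals
#'
#' Combines per-window rank p-values of d statistics into one score:
#' `DCMS_j = sum_i logit(1 - p_ij) / w_i` with `w_i = sum_k |r_ik|`, the
#' total absolute correlation of statistic i with all statistics
#' (including itself). Correlated statistics therefore share their
#' weight: d duplicated statistics contribute exactly one statistic's
#' worth of signal. Larger DCMS means more selection-like.
#'
#' @param pmat windows x statistics matrix of p-values in (0, 1).
#' @param corr d x d correlation matrix, columns aligned with `pmat`.
#' @return Numeric vector of DCMS scores per window.
#' @export
dcms <- function(pmat, corr) {
  pmat <- as.matrix(pmat)
  corr <- as.matrix(corr)
  stopifnot(ncol(pmat) == ncol(corr), nrow(corr) == ncol(corr))
  if (any(pmat <= 0 | pmat >= 1)) stop("p-values must lie in (0, 1)")
  w <- rowSums(abs(corr))
  logits <- log((1 - pmat) / pmat)
  as.numeric(logits %*% (1 / w))
}

#' Normal-fit p-values for DCMS scores
#'
#' Fits a normal to the genome-wide DCMS distribution and reports the
#' upper-tail probability of each score. Location and scale come either
#' from the mean/SD (default) or from the median and the scaled MAD
#' (`robust = TRUE`), the latter being less influenced by the right
#' skew selection itself induces.
#'
#' @param scores numeric vector of DCMS scores (>= 30 windows).
#' @param robust use median/MAD instead of mean/SD.
#' @return List with `p` (upper-tail p-values), `mu`, `sigma`.
#' @export
dcms_pvalues <- function(scores, robust = FALSE) {
  stopifnot(length(scores) >= 30, all(is.finite(scores)))
  if (robust) {
    mu <- median(scores)
    sigma <- mad(scores)  # 1.4826 * MAD, consistent for the normal
  } else {
    mu <- mean(scores)
    sigma <- sd(scores)
  }
  if (sigma == 0) stop("zero scale: all DCMS scores identical")
  list(p = pnorm(scores, mu, sigma, lower.tail = FALSE), mu = mu,
       sigma = sigma)
}

#' Call candidate windows and merge them into regions
#'
#' Windows with `-log10(p) >= threshold_logp` are flagged and
#' transitively overlapping flagged windows on the same chromosome are
#' merged into maximal candidate regions.
#'
#' @param windows data frame with `chrom`, `start`, `end` (0-based
#'   half-open).
#' @param p per-window p-values.
#' @param threshold_logp significance threshold on `-log10(p)`
#'   (default 4).
#' @return Data frame of regions: `chrom`, `start`, `end`, `size_bp`,
#'   `n_windows`, `peak_neg_log10_p` (empty when nothing is flagged).
#' @export
call_and_merge <- function(windows, p, threshold_logp = 4) {
  stopifnot(nrow(windows) == length(p))
  neglog <- -log10(p)
  flag <- neglog >= threshold_logp
  empty <- data.frame(chrom = character(), start = numeric(),
                      end = numeric(), size_bp = numeric(),
                      n_windows = integer(), peak_neg_log10_p = numeric())
  if (!any(flag)) return(empty)
  w <- windows[flag, , drop = FALSE]
  nl <- neglog[flag]
  gr <- GenomicRanges::GRanges(w$chrom,
                               IRanges::IRanges(w$start + 1, w$end))
  # min.gapwidth = 0: strict overlap only, abutting windows stay apart
  red <- GenomicRanges::reduce(gr, min.gapwidth = 0)
  hits <- GenomicRanges::findOverlaps(gr, red)
  reg_of <- S4Vectors::subjectHits(hits)[order(S4Vectors::queryHits(hits))]
  data.frame(
    chrom = as.character(GenomicRanges::seqnames(red)),
    start = GenomicRanges::start(red) - 1,
    end = GenomicRanges::end(red),
    size_bp = GenomicRanges::width(red),
    n_windows = as.integer(table(factor(reg_of, seq_along(red)))),
    peak_neg_log10_p = as.numeric(tapply(nl, factor(reg_of, seq_along(red)),
                                         max))
  )
}
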