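#' Observed homozygosity per individual
#'
#' Fraction of sites at which an individual is homozygous (dosage 0 or
#' 2), with optional group means.
#'
#' @param g a [genotype_matrix()] with no missing genotypes.
#' @param groups optional factor/character vector of population labels,
#'   one per sample.
#' @return List with `individual` (named numeric vector) and
#'   `group_means` (or `NULL`).
#' @export
observed_homozygosity <- function(g, groups = NULL) {
  d <- g$dosages
  stopifnot(!anyNA(d))
  hom <- rowMeans(d != 1L)
  names(hom) <- g$sample_ids
  gm <- NULL
  if (!is.null(groups)) {
    groups <- as.factor(groups)
    if (any(table(groups) == 0)) stop("empty group")
    gm <- tapply(hom, groups, mean)
  }
  list(individual = hom, group_means = gm)
}

#' Per-individual inbreeding coefficient
#'
#' `F_i = (O_i - E) / (L - E)` where `O_i` is the observed homozygous
#' site count of individual i, `E = sum_s (1 - 2 p_s q_s)` the expected
#' homozygous count under Hardy-Weinberg at the sample allele
#' frequencies, and `L` the number of sites. No small-sample correction
#' is applied to `E`, so with `N` diploids the estimator carries a
#' negative bias of order `1/(2N)` (documented, and well inside the
#' between-individual spread at panel scale).
#'
#' @param g a [genotype_matrix()] with no missing genotypes.
#' @return Named numeric vector of F per individual.
#' @export
inbreeding_f <- function(g) {
  d <- g$dosages
  stopifnot(!anyNA(d))
  L <- ncol(d)
  p <- colMeans(d) / 2
  E <- sum(1 - 2 * p * (1 - p))
  if (abs(L - E) < .Machine$double.eps * L)
    stop("all sites monomorphic: F undefined")
  O <- rowSums(d != 1L)
  setNames((O - E) / (L - E), g$sample_ids)
}

#' Nonparametric rank tests
#'
#' Two-sample Mann-Whitney U test, or (with `y = NULL`) the one-sample
#' Wilcoxon signed-rank test of `x` against `mu0`. Exact distributions
#' are used for sample sizes up to 25 without ties; otherwise the normal
#' approximation with tie and continuity correction. Two-sided.
#'
#' @param x,y numeric samples (`y = NULL` for the one-sample mode).
#' @param mu0 null location for the one-sample mode.
#' @return List with `statistic` and `p_value`.
#' @export
rank_tests <- function(x, y = NULL, mu0 = 0) {
  if (is.null(y)) {
    dif <- x - mu0
    if (all(dif == 0)) return(list(statistic = 0, p_value = 1))
    exact <- length(dif[dif != 0]) <= 25 &&
      !any(duplicated(abs(dif[dif != 0]))) && !any(dif == 0)
    ht <- suppressWarnings(wilcox.test(x, mu = mu0, exact = exact,
                                       correct = TRUE))
  } else {
    exact <- max(length(x), length(y)) <= 25 &&
      !any(duplicated(c(x, y)))
    ht <- suppressWarnings(wilcox.test(x, y, exact = exact,
                                       correct = TRUE))
  }
  list(statistic = unname(ht$statistic), p_value = ht$p.value)
}

#' Principal component analysis of genotypes
#'
#' PCA on the column-centered (unscaled) dosage matrix via singular value
#' decomposition, with a fixed sign convention: for each component the
#' loading with the largest magnitude is made positive.
#'
#' @param g a [genotype_matrix()], ideally post-QC and LD-pruned.
#' @return List with `scores` (samples x components),
#'   `variance_explained` (fractions summing to 1) and `loadings`.
#' @export
pca_genotypes <- function(g) {
  d <- g$dosages
  if (ncol(d) < 2) stop("need at least 2 sites")
  pr <- prcomp(d, center = TRUE, scale. = FALSE)
  flip <- apply(pr$rotation, 2, function(v) sign(v[which.max(abs(v))]))
  flip[flip == 0] <- 1
  scores <- sweep(pr$x, 2, flip, `*`)
  rownames(scores) <- g$sample_ids
  list(scores = scores,
       variance_explained = pr$sdev^2 / sum(pr$sdev^2),
       loadings = sweep(pr$rotation, 2, flip, `*`))
}
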