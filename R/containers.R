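#' Haplotype matrix
#'
#' Phased binary haplotypes for one chromosome: `2N` haplotype rows by `S`
#' site columns, alleles coded 0 (reference/ancestral) and 1
#' (alternate/derived), with strictly increasing physical positions.
#' This is the substrate for EHH, iHS and nSL.
#'
#' @param alleles integer matrix, haplotypes x sites, values in \{0, 1\}.
#' @param pos numeric vector of 1-based physical positions (bp), strictly
#'   increasing, one per site.
#' @param chrom single chromosome label.
#' @param chrom_length chromosome length in bp (defaults to the last
#'   position); used to anchor the sliding-window grid.
#' @return An object of class `haplotype_matrix`.
#' @export
haplotype_matrix <- function(alleles, pos, chrom = "1",
                             chrom_length = NULL) {
  alleles <- as.matrix(alleles)
  storage.mode(alleles) <- "integer"
  pos <- as.numeric(pos)
  stopifnot(ncol(alleles) == length(pos), all(alleles %in% c(0L, 1L)))
  if (length(pos) > 1 && any(diff(pos) <= 0))
    stop("positions must be strictly increasing")
  if (is.null(chrom_length)) chrom_length <- if (length(pos)) max(pos) else 0
  structure(list(alleles = alleles, pos = pos,
                 chrom = as.character(chrom)[1],
                 chrom_length = as.numeric(chrom_length)),
            class = "haplotype_matrix")
}

#' @export
print.haplotype_matrix <- function(x, ...) {
  cat(sprintf("<haplotype_matrix> %d haplotypes x %d sites, chrom %s (%.3g Mb)\n",
              nrow(x$alleles), ncol(x$alleles), x$chrom,
              x$chrom_length / 1e6))
  invisible(x)
}

#' @export
dim.haplotype_matrix <- function(x) dim(x$alleles)

#' Genotype matrix
#'
#' Per-sample diploid allele dosages (0/1/2, `NA` = missing) with per-site
#' metadata. The substrate for quality control, diversity summaries,
#' Tajima's D and pi.
#'
#' @param dosages integer matrix, samples x sites, values 0/1/2/`NA`.
#' @param chrom chromosome label per site.
#' @param pos 1-based position per site (strictly increasing within each
#'   chromosome).
#' @param ref,alt reference / alternate alleles per site.
#' @param sample_ids sample names (defaults to rownames or S1..Sn).
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(dosages, chrom, pos, ref = NULL, alt = NULL,
                            sample_ids = NULL) {
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "integer"
  S <- ncol(dosages)
  chrom <- rep_len(as.character(chrom), S)
  pos <- as.numeric(pos)
  stopifnot(length(pos) == S, all(dosages %in% c(0L, 1L, 2L, NA)))
  for (ch in unique(chrom)) {
    p <- pos[chrom == ch]
    if (length(p) > 1 && any(diff(p) <= 0))
      stop("positions must be strictly increasing within chromosome ", ch)
  }
  if (is.null(sample_ids))
    sample_ids <- rownames(dosages) %||% paste0("S", seq_len(nrow(dosages)))
  rownames(dosages) <- sample_ids
  structure(list(dosages = dosages, chrom = chrom, pos = pos,
                 ref = ref %||% rep("A", S), alt = alt %||% rep("T", S),
                 sample_ids = sample_ids),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("<genotype_matrix> %d samples x %d sites on %d chromosome(s)\n",
              nrow(x$dosages), ncol(x$dosages), length(unique(x$chrom))))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosages)

`%||%` <- function(a, b) if (is.null(a)) b else a

# subset sites of a genotype_matrix (logical or integer index)
gm_subset_sites <- function(g, idx) {
  genotype_matrix(g$dosages[, idx, drop = FALSE], g$chrom[idx], g$pos[idx],
                  g$ref[idx], g$alt[idx], g$sample_ids)
}

gm_subset_samples <- function(g, idx) {
  genotype_matrix(g$dosages[idx, , drop = FALSE], g$chrom, g$pos,
                  g$ref, g$alt, g$sample_ids[idx])
}

# minor allele frequency per site from dosages (missing ignored)
gm_maf <- function(g) {
  af <- colMeans(g$dosages, na.rm = TRUE) / 2
  pmin(af, 1 - af)
}

# pair haplotype rows (2i-1, 2i) into diploid dosages
hap_to_genotypes <- function(hap) {
  a <- hap$alleles
  n2 <- nrow(a)
  stopifnot(n2 %% 2 == 0)
  d <- a[seq(1, n2, by = 2), , drop = FALSE] +
    a[seq(2, n2, by = 2), , drop = FALSE]
  genotype_matrix(d, hap$chrom, hap$pos)
}
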