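#' Read a multi-sample SNP VCF
#'
#' Parses a VCF 4.2 file (via `VariantAnnotation::readVcf`), keeping only
#' biallelic SNP records (others are dropped and counted). Dosage is the
#' ALT-allele count per genotype; missing genotypes are preserved as `NA`.
#' INFO annotations used by the hard filters (FS, QD, MQ, MQRankSum,
#' ReadPosRankSum), QUAL and per-sample DP are returned site-aligned with
#' the genotypes.
#'
#' @param path VCF path (plain text or bgzipped).
#' @param require_phased if `TRUE`, every non-missing GT must be phased
#'   (`|` separator) and a [haplotype_matrix()] per chromosome is
#'   returned; the first unphased record is named in the error. Missing
#'   genotypes (`./.` or `.|.`) carry no phase and are accepted.
#' @return List with elements `genotypes` ([genotype_matrix()]),
#'   `annotations` (data frame: `qual`, `fs`, `qd`, `mq`, `mq_rank`,
#'   `readpos_rank`), `dp` (samples x sites matrix or `NULL`),
#'   `haplotypes` (named list of [haplotype_matrix()], one per
#'   chromosome, or `NULL`), and `n_dropped` (non-biallelic-SNP records
#'   removed).
#' @export
read_vcf <- function(path, require_phased = FALSE) {
  vcf <- VariantAnnotation::readVcf(path)
  snv <- VariantAnnotation::isSNV(vcf, singleAltOnly = TRUE)
  n_dropped <- sum(!snv)
  if (n_dropped)
    message(n_dropped, " non-biallelic-SNP record(s) dropped")
  vcf <- vcf[snv, ]

  rr <- SummarizedExperiment::rowRanges(vcf)
  chrom <- as.character(GenomicRanges::seqnames(rr))
  pos <- GenomicRanges::start(rr)
  ref <- as.character(rr$REF)
  alt <- as.character(unlist(rr$ALT))

  gt <- t(VariantAnnotation::geno(vcf)$GT)  # samples x sites
  a1 <- substr(gt, 1, 1)
  sep <- substr(gt, 2, 2)
  a2 <- substr(gt, 3, 3)
  miss <- a1 == "." | a2 == "." | gt == "."

  if (require_phased) {
    unphased <- !miss & sep != "|"
    if (any(unphased)) {
      j <- which(unphased, arr.ind = TRUE)[1, ]
      stop(sprintf("unphased genotype '%s' at %s:%d (sample %s)",
                   gt[j[1], j[2]], chrom[j[2]], pos[j[2]],
                   rownames(gt)[j[1]]))
    }
  }

  d1 <- suppressWarnings(as.integer(a1))
  d2 <- suppressWarnings(as.integer(a2))
  dos <- matrix(d1 + d2, nrow(gt), ncol(gt))
  dos[miss] <- NA_integer_
  g <- genotype_matrix(dos, chrom, pos, ref, alt, rownames(gt))

  info <- VariantAnnotation::info(vcf)
  grab <- function(key) {
    if (key %in% colnames(info)) as.numeric(info[[key]])
    else rep(NA_real_, length(pos))
  }
  ann <- data.frame(qual = as.numeric(VariantAnnotation::qual(vcf)),
                    fs = grab("FS"), qd = grab("QD"), mq = grab("MQ"),
                    mq_rank = grab("MQRankSum"),
                    readpos_rank = grab("ReadPosRankSum"))

  dp <- VariantAnnotation::geno(vcf)$DP
  dp <- if (is.null(dp)) NULL else t(dp)

  hap_alleles <- NULL
  if (require_phased) {
    n2 <- 2L * nrow(gt)
    hap_alleles <- matrix(NA_integer_, n2, ncol(gt))
    hap_alleles[seq(1, n2, 2), ] <- d1
    hap_alleles[seq(2, n2, 2), ] <- d2
  }

  list(genotypes = g, annotations = ann, dp = dp,
       hap_alleles = hap_alleles, n_dropped = n_dropped)
}

#' Build per-chromosome haplotype matrices from a phased VCF read
#'
#' Companion to [read_vcf()]: subsets the phased allele matrix to the
#' kept sites (which must be fully called, as guaranteed by the 100%
#' call-rate rule) and splits it per chromosome.
#'
#' @param v result of `read_vcf(path, require_phased = TRUE)`.
#' @param keep integer site indices to retain (default all).
#' @param chrom_lengths optional named vector of chromosome lengths.
#' @return Named list of [haplotype_matrix()] per chromosome.
#' @export
haplotypes_from_vcf <- function(v, keep = NULL, chrom_lengths = NULL) {
  if (is.null(v$hap_alleles))
    stop("VCF was not read with require_phased = TRUE")
  g <- v$genotypes
  idx <- sort(keep %||% seq_along(g$pos))
  ha <- v$hap_alleles[, idx, drop = FALSE]
  if (anyNA(ha)) stop("missing genotypes among kept sites")
  chs <- g$chrom[idx]
  out <- lapply(unique(chs), function(ch) {
    sel <- chs == ch
    cl <- if (!is.null(chrom_lengths) && !is.na(chrom_lengths[ch]))
      chrom_lengths[[ch]] else NULL
    haplotype_matrix(ha[, sel, drop = FALSE], g$pos[idx][sel], ch, cl)
  })
  names(out) <- unique(chs)
  out
}
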