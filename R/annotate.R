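#' Intersect candidate regions with gene annotations
#'
#' A gene overlaps a region iff their 0-based half-open intervals share
#' at least one base. Distinct genes are counted once genome-wide.
#'
#' @param regions data frame with `chrom`, `start`, `end` (0-based
#'   half-open), e.g. from [call_and_merge()].
#' @param genes data frame with `chrom`, `start`, `end` (0-based
#'   half-open), `gene_id`, optionally `name`, e.g. from
#'   [make_gene_annotation()] or [read_gene_annotation()].
#' @return List with `per_region` (list of gene-id vectors, one per
#'   region), `table` (long data frame region x gene) and
#'   `n_distinct_genes`.
#' @export
overlap_genes <- function(regions, genes) {
  nR <- nrow(regions)
  if (nR == 0 || nrow(genes) == 0)
    return(list(per_region = rep(list(character(0)), nR),
                table = data.frame(region = integer(), chrom = character(),
                                   start = numeric(), end = numeric(),
                                   gene_id = character()),
                n_distinct_genes = 0L))
  shared <- intersect(unique(regions$chrom), unique(genes$chrom))
  if (!length(shared)) {
    warning("no shared chromosome names between regions (",
            paste(unique(regions$chrom), collapse = ","), ") and genes (",
            paste(unique(genes$chrom), collapse = ","), ")")
  }
  gr_r <- GenomicRanges::GRanges(regions$chrom,
                                 IRanges::IRanges(regions$start + 1,
                                                  regions$end))
  gr_g <- GenomicRanges::GRanges(genes$chrom,
                                 IRanges::IRanges(genes$start + 1,
                                                  genes$end))
  hits <- suppressWarnings(GenomicRanges::findOverlaps(gr_r, gr_g))
  qh <- S4Vectors::queryHits(hits)
  sh <- S4Vectors::subjectHits(hits)
  per_region <- lapply(seq_len(nR), function(i) genes$gene_id[sh[qh == i]])
  tab <- data.frame(region = qh, chrom = regions$chrom[qh],
                    start = regions$start[qh], end = regions$end[qh],
                    gene_id = genes$gene_id[sh])
  list(per_region = per_region, table = tab,
       n_distinct_genes = length(unique(genes$gene_id[sh])))
}

#' Count variants per candidate region
#'
#' Number of sites whose (1-based VCF) position falls inside each
#' 0-based half-open region.
#'
#' @param chrom,pos site coordinates (1-based positions).
#' @param regions region data frame (`chrom`, `start`, `end`).
#' @return Integer vector, one count per region.
#' @export
count_region_variants <- function(chrom, pos, regions) {
  vapply(seq_len(nrow(regions)), function(i)
    sum(chrom == regions$chrom[i] & pos > regions$start[i] &
          pos <= regions$end[i]),
    integer(1))
}

#' Read a gene annotation file
#'
#' Accepts GFF3 (1-based inclusive; `gene` features, ID/Name parsed from
#' the attributes) or BED (0-based half-open). Coordinates are stored
#' 0-based half-open internally.
#'
#' @param path annotation path; dialect from the extension
#'   (`.bed` = BED, anything else = GFF3).
#' @return Data frame with `chrom`, `start`, `end`, `gene_id`, `name`.
#' @export
read_gene_annotation <- function(path) {
  if (grepl("\\.bed$", path, ignore.case = TRUE)) {
    bed <- read.table(path, sep = "\t", header = FALSE,
                      stringsAsFactors = FALSE)
    data.frame(chrom = as.character(bed[[1]]), start = bed[[2]],
               end = bed[[3]],
               gene_id = if (ncol(bed) >= 4) bed[[4]]
                         else sprintf("GENE%04d", seq_len(nrow(bed))),
               name = if (ncol(bed) >= 4) bed[[4]] else NA_character_)
  } else {
    gff <- read.table(path, sep = "\t", header = FALSE, comment.char = "#",
                      stringsAsFactors = FALSE, quote = "")
    gff <- gff[gff[[3]] == "gene", , drop = FALSE]
    attr_get <- function(attrs, key) {
      m <- regmatches(attrs, regexec(paste0(key, "=([^;]+)"), attrs))
      vapply(m, function(x) if (length(x) == 2) x[2] else NA_character_, "")
    }
    data.frame(chrom = as.character(gff[[1]]), start = gff[[4]] - 1,
               end = gff[[5]], gene_id = attr_get(gff[[9]], "ID"),
               name = attr_get(gff[[9]], "Name"))
  }
}
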