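#' Marker editing: MAF filter and complete-LD pruning
#'
#' Standard pre-analysis editing of a phased marker set: (a) remove markers
#' with minor allele frequency below `maf_min`; (b) optionally prune
#' markers in complete LD with an adjacent retained marker. Pruning scans
#' each chromosome left to right over the MAF-retained markers: within any
#' maximal run of consecutive markers whose successive pairs have r2 = 1,
#' only the first marker is kept. The operation is idempotent.
#'
#' @param geno a [phased_genotypes()] object.
#' @param maf_min minimum minor allele frequency, in `[0, 0.5)`.
#' @param prune_complete_ld logical; prune adjacent markers with r2 = 1.
#' @param samples optional sample ids over which frequencies and LD are
#'   computed (defaults to all samples).
#' @return a `phased_genotypes` object with the surviving markers, in the
#'   original order; the integer indices of the kept markers are attached
#'   as attribute `kept_markers`.
#' @export
edit_markers <- function(geno, maf_min = 0.01, prune_complete_ld = TRUE,
                         samples = NULL) {
  stopifnot(maf_min >= 0, maf_min < 0.5)
  h <- geno$haplotypes
  if (!is.null(samples)) h <- h[haplotype_rows(geno, samples), , drop = FALSE]
  f <- colMeans(h)
  keep <- which(pmin(f, 1 - f) >= maf_min & f > 0 & f < 1)
  if (length(keep) == 0L) stop("all markers removed by the MAF filter")

  if (prune_complete_ld) {
    pruned <- integer(0)
    for (chr in unique(geno$map$chrom)) {
      idx <- keep[geno$map$chrom[keep] == chr]
      if (length(idx) < 2L) next
      for (t in seq_len(length(idx) - 1L)) {
        a <- idx[t]
        b <- idx[t + 1L]
        # consecutive-pair r2 = 1 <=> identical or complementary columns
        if (all(h[, a] == h[, b]) || all(h[, a] == 1L - h[, b])) {
          pruned <- c(pruned, b)
          idx[t + 1L] <- a   # chain: compare next marker against run head
        }
      }
    }
    keep <- setdiff(keep, pruned)
  }
  if (length(keep) == 0L) stop("all markers removed by editing")
  out <- subset_markers(geno, keep)
  attr(out, "kept_markers") <- keep
  out
}
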