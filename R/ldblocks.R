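#' Pairwise linkage disequilibrium between two markers
#'
#' Computes the classical haplotype-frequency LD measures from two binary
#' haplotype vectors: `D = pAB - pA pB`, the normalized
#' `D' = D / Dmax` (with `Dmax = min(pA(1-pB), (1-pA)pB)` when `D > 0`
#' and `min(pA pB, (1-pA)(1-pB))` when `D < 0`; `D' = 0` when `D = 0`),
#' and `r2 = D^2 / (pA(1-pA) pB(1-pB))`. Allele "1" is the reference
#' allele for both markers; `|D'|` and `r2` are invariant to that choice.
#'
#' @param hapA,hapB binary vectors over the same haplotypes.
#' @return list with elements `D`, `Dprime`, `r2`.
#' @export
pairwise_dprime <- function(hapA, hapB) {
  if (length(hapA) != length(hapB)) stop("haplotype vectors differ in length")
  pA <- mean(hapA)
  pB <- mean(hapB)
  if (pA <= 0 || pA >= 1 || pB <= 0 || pB >= 1) {
    stop("monomorphic marker: LD is undefined; filter markers first")
  }
  pAB <- mean(hapA == 1L & hapB == 1L)
  D <- pAB - pA * pB
  if (D > 0) {
    dmax <- min(pA * (1 - pB), (1 - pA) * pB)
  } else if (D < 0) {
    dmax <- min(pA * pB, (1 - pA) * (1 - pB))
  } else {
    dmax <- 1
  }
  list(D = D,
       Dprime = if (D == 0) 0 else D / dmax,
       r2 = D^2 / (pA * (1 - pA) * pB * (1 - pB)))
}

# |D'| for one anchor column against several columns of a 0/1 matrix,
# vectorized over pairs; columns must be polymorphic.
abs_dprime_vec <- function(anchor, hmat) {
  pA <- mean(anchor)
  pB <- colMeans(hmat)
  pAB <- as.vector(crossprod(anchor, hmat)) / length(anchor)
  D <- pAB - pA * pB
  dmax <- ifelse(D >= 0,
                 pmin(pA * (1 - pB), (1 - pA) * pB),
                 pmin(pA * pB, (1 - pA) * (1 - pB)))
  out <- abs(D) / dmax
  out[D == 0] <- 0
  out
}

#' Build haploblocks by the all-pairs |D'| criterion
#'
#' A haploblock is a maximal run of adjacent SNPs on one chromosome such
#' that every pair of SNPs in the run has `|D'| >= threshold` on the
#' reference (training) haplotypes. Blocks are grown greedily left to
#' right: a block is extended by the next marker iff its `|D'|` with every
#' marker already in the block meets the threshold, otherwise the block is
#' closed and a new one started. Every marker belongs to exactly one
#' block; single-marker blocks are allowed. Markers monomorphic in the
#' reference haplotypes (possible when the reference is a subset of the
#' samples used for MAF filtering) cannot enter an LD comparison and are
#' emitted as singleton blocks.
#'
#' @param geno an edited [phased_genotypes()] object.
#' @param threshold minimum pairwise `|D'|` within a block (default 0.45).
#' @param reference_samples sample ids whose haplotypes define LD
#'   (defaults to all samples); test animals must be excluded here to
#'   avoid leakage.
#' @param measure `"dprime"` (default) or `"r2"`: the pairwise statistic
#'   compared against `threshold`.
#' @return list of `haploblock` objects, each a list with `block_id`,
#'   `chrom`, `markers` (integer indices into `geno$map`), `start_bp`,
#'   `end_bp`; variant catalogues are added by [catalogue_variants()].
#' @export
build_blocks <- function(geno, threshold = 0.45, reference_samples = NULL,
                         measure = c("dprime", "r2")) {
  measure <- match.arg(measure)
  h <- geno$haplotypes
  if (!is.null(reference_samples)) {
    if (length(reference_samples) == 0L) stop("reference_samples must be nonempty")
    h <- h[haplotype_rows(geno, reference_samples), , drop = FALSE]
  }
  storage.mode(h) <- "double"
  f <- colMeans(h)
  poly <- f > 0 & f < 1

  blocks <- list()
  bid <- 0L
  for (chr in unique(geno$map$chrom)) {
    idx <- which(geno$map$chrom == chr)
    i <- 1L
    while (i <= length(idx)) {
      members <- idx[i]
      j <- i + 1L
      if (poly[idx[i]]) {
        while (j <= length(idx) && poly[idx[j]]) {
          ld <- if (measure == "dprime") {
            abs_dprime_vec(h[, idx[j]], h[, members, drop = FALSE])
          } else {
            as.vector(stats::cor(h[, idx[j]], h[, members, drop = FALSE]))^2
          }
          if (all(ld >= threshold)) {
            members <- c(members, idx[j])
            j <- j + 1L
          } else break
        }
      }
      bid <- bid + 1L
      blocks[[bid]] <- structure(
        list(block_id = sprintf("HB%05d", bid),
             chrom = chr,
             markers = members,
             start_bp = geno$map$pos[members[1L]],
             end_bp = geno$map$pos[members[length(members)]]),
        class = "haploblock"
      )
      i <- i + length(members)
    }
  }
  blocks
}

#' Catalogue the haplotype variants of a haploblock
#'
#' The variants ("alleles") of a block are the distinct haplotype strings
#' observed over the block's markers among the reference haplotypes,
#' ordered by descending frequency then lexicographically. Blocks with a
#' single variant carry no contrast and are flagged `excluded`.
#'
#' @param block a `haploblock` from [build_blocks()].
#' @param geno the same [phased_genotypes()] the block was built on.
#' @param reference_samples sample ids defining the catalogue (defaults to
#'   all samples); must match the set used in [build_blocks()].
#' @return the block with `variants` (character vector), `variant_freq`
#'   (numeric, sums to 1) and `excluded` (logical) filled in.
#' @export
catalogue_variants <- function(block, geno, reference_samples = NULL) {
  h <- geno$haplotypes
  if (!is.null(reference_samples)) {
    h <- h[haplotype_rows(geno, reference_samples), , drop = FALSE]
  }
  strings <- apply(h[, block$markers, drop = FALSE], 1L, paste, collapse = "")
  tab <- table(strings)
  ord <- order(-as.vector(tab), names(tab), method = "radix")
  block$variants <- names(tab)[ord]
  block$variant_freq <- as.vector(tab)[ord] / length(strings)
  block$excluded <- length(block$variants) == 1L
  block
}

#' @rdname catalogue_variants
#' @param blocks list of haploblocks.
#' @return for `catalogue_all_variants`, the list with catalogues filled.
#' @export
catalogue_all_variants <- function(blocks, geno, reference_samples = NULL) {
  lapply(blocks, catalogue_variants, geno = geno,
         reference_samples = reference_samples)
}

#' Haploblock design matrix
#'
#' Builds the n x q variant-dosage matrix M used as the genomic design
#' matrix: one column per (block, catalogued variant), with entry equal to
#' the number of the sample's two haplotypes matching that variant over
#' the block's markers. For reference samples the dosages of a block's
#' columns sum to 2; a test haplotype absent from the training catalogue
#' contributes no dosage (novel variants carry no estimated effect).
#'
#' @param blocks list of catalogued, non-excluded haploblocks.
#' @param geno a [phased_genotypes()] object.
#' @param samples sample ids to encode (rows of M).
#' @return list of class `haploblock_design` with `M` (integer matrix,
#'   rownames = sample ids), `columns` (data.frame: `block_id`,
#'   `variant_index`, `variant`, `chrom`), and `blocks`.
#' @export
design_matrix <- function(blocks, geno, samples = NULL) {
  if (is.null(samples)) samples <- geno$sample_ids
  if (any(vapply(blocks, function(b) is.null(b$variants), logical(1L)))) {
    stop("blocks must be catalogued first (see catalogue_variants)")
  }
  if (any(vapply(blocks, `[[`, logical(1L), "excluded"))) {
    stop("excluded (single-variant) blocks must not enter the design matrix")
  }
  rows <- haplotype_rows(geno, samples)
  h <- geno$haplotypes[rows, , drop = FALSE]
  n <- length(samples)
  q <- sum(vapply(blocks, function(b) length(b$variants), integer(1L)))
  M <- matrix(0L, nrow = n, ncol = q)
  col_meta <- vector("list", length(blocks))
  col0 <- 0L
  for (bi in seq_along(blocks)) {
    b <- blocks[[bi]]
    strings <- apply(h[, b$markers, drop = FALSE], 1L, paste, collapse = "")
    hit <- match(strings, b$variants)           # NA = novel variant
    hap1 <- hit[seq(1L, 2L * n, 2L)]
    hap2 <- hit[seq(2L, 2L * n, 2L)]
    for (v in seq_along(b$variants)) {
      M[, col0 + v] <- (!is.na(hap1) & hap1 == v) + (!is.na(hap2) & hap2 == v)
    }
    col_meta[[bi]] <- data.frame(
      block_id = b$block_id, variant_index = seq_along(b$variants),
      variant = b$variants, chrom = b$chrom, stringsAsFactors = FALSE
    )
    col0 <- col0 + length(b$variants)
  }
  rownames(M) <- samples
  structure(
    list(M = M, columns = do.call(rbind, col_meta), blocks = blocks),
    class = "haploblock_design"
  )
}

#' Summary statistics of a haploblock partition
#'
#' @param blocks list of catalogued haploblocks.
#' @return list with `n_blocks`, `n_excluded`, `n_markers`,
#'   `snps_per_block` (table-ready integer vector), `variants_per_block`,
#'   `mean_snps`, `mean_variants`, and `q` (total variant columns over
#'   included blocks).
#' @export
block_stats <- function(blocks) {
  if (any(vapply(blocks, function(b) is.null(b$variants), logical(1L)))) {
    stop("blocks must be catalogued first")
  }
  snps <- vapply(blocks, function(b) length(b$markers), integer(1L))
  vars <- vapply(blocks, function(b) length(b$variants), integer(1L))
  excl <- vapply(blocks, `[[`, logical(1L), "excluded")
  list(
    n_blocks = length(blocks),
    n_excluded = sum(excl),
    n_markers = sum(snps),
    snps_per_block = snps,
    variants_per_block = vars,
    mean_snps = mean(snps),
    mean_variants = mean(vars),
    q = sum(vars[!excl])
  )
}

#' Export haploblocks as a BED-like TSV
#'
#' Columns: chrom, start_bp, end_bp, block_id, n_snps, n_variants,
#' excluded.
#'
#' @param blocks list of catalogued haploblocks.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_blocks_tsv <- function(blocks, path) {
  df <- data.frame(
    chrom = vapply(blocks, `[[`, character(1L), "chrom"),
    start_bp = vapply(blocks, `[[`, numeric(1L), "start_bp"),
    end_bp = vapply(blocks, `[[`, numeric(1L), "end_bp"),
    block_id = vapply(blocks, `[[`, character(1L), "block_id"),
    n_snps = vapply(blocks, function(b) length(b$markers), integer(1L)),
    n_variants = vapply(blocks, function(b)
      if (is.null(b$variants)) NA_integer_ else length(b$variants), integer(1L)),
    excluded = vapply(blocks, function(b)
      isTRUE(b$excluded), logical(1L)),
    stringsAsFactors = FALSE
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Map every marker to its containing block
#'
#' @param blocks list of haploblocks partitioning the markers.
#' @param m total number of markers.
#' @return integer vector of length `m`: block list index per marker.
#' @export
marker_block_index <- function(blocks, m) {
  out <- integer(m)
  for (bi in seq_along(blocks)) out[blocks[[bi]]$markers] <- bi
  if (any(out == 0L)) stop("blocks do not cover every marker")
  out
}
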