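#' Construct a phased-genotype object
#'
#' Container for phased biallelic SNP data: a haplotype matrix with two rows
#' per sample (rows `2i - 1` and `2i` are the two haplotypes of sample `i`)
#' and an ordered marker map. Alleles are coded 0/1; allele dosage of a
#' sample at a marker is the sum over its two haplotype rows.
#'
#' @param haplotypes integer matrix of shape `2n x m` with entries in
#'   \{0, 1\}; no missing values (data must be phased and complete).
#' @param map data.frame with columns `marker_id`, `chrom`, `pos`,
#'   `allele0`, `allele1`; one row per marker, grouped by chromosome with
#'   strictly increasing positions within each chromosome.
#' @param sample_ids character vector of `n` unique sample identifiers.
#'
#' @return An object of class `phased_genotypes` with elements
#'   `haplotypes`, `map` and `sample_ids`.
#' @export
phased_genotypes <- function(haplotypes, map, sample_ids) {
  haplotypes <- as.matrix(haplotypes)
  storage.mode(haplotypes) <- "integer"
  map <- as.data.frame(map, stringsAsFactors = FALSE)
  needed <- c("marker_id", "chrom", "pos", "allele0", "allele1")
  missing_cols <- setdiff(needed, names(map))
  if (length(missing_cols) > 0L) {
    stop("marker map lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  map$chrom <- as.character(map$chrom)
  map$pos <- as.integer(map$pos)
  sample_ids <- as.character(sample_ids)
  obj <- structure(
    list(haplotypes = haplotypes, map = map[, needed], sample_ids = sample_ids),
    class = "phased_genotypes"
  )
  validate_phased_genotypes(obj)
}

validate_phased_genotypes <- function(x) {
  h <- x$haplotypes
  m <- nrow(x$map)
  n <- length(x$sample_ids)
  if (n < 1L || m < 1L) stop("need at least one sample and one marker")
  if (nrow(h) != 2L * n) {
    stop("haplotype matrix has ", nrow(h), " rows; expected 2 x ", n, " samples")
  }
  if (ncol(h) != m) {
    stop("haplotype matrix has ", ncol(h), " columns; map describes ", m, " markers")
  }
  if (anyNA(h)) stop("missing haplotype entries; phased, complete data required")
  if (!all(h == 0L | h == 1L)) stop("haplotype entries must be 0 or 1")
  if (anyDuplicated(x$sample_ids)) stop("sample ids must be unique")
  key <- paste(x$map$chrom, x$map$pos)
  if (anyDuplicated(key)) stop("duplicate (chromosome, position) in marker map")
  for (chr in unique(x$map$chrom)) {
    idx <- which(x$map$chrom == chr)
    if (any(diff(idx) != 1L)) stop("markers of chromosome ", chr, " are not contiguous")
    if (is.unsorted(x$map$pos[idx], strictly = TRUE)) {
      stop("positions not strictly increasing on chromosome ", chr)
    }
  }
  x
}

#' @export
print.phased_genotypes <- function(x, ...) {
  cat(sprintf(
    "phased_genotypes: %d samples, %d markers on %d chromosome(s)\n",
    n_samples(x), n_markers(x), length(unique(x$map$chrom))
  ))
  invisible(x)
}

#' Numbers of samples and markers
#' @param geno a `phased_genotypes` object.
#' @return integer count.
#' @export
n_samples <- function(geno) length(geno$sample_ids)

#' @rdname n_samples
#' @export
n_markers <- function(geno) nrow(geno$map)

#' Allele-1 frequencies and minor allele frequencies
#'
#' Frequencies are computed over all haplotypes, or over the haplotypes of
#' a subset of samples.
#'
#' @param geno a `phased_genotypes` object.
#' @param samples optional character vector of sample ids restricting the
#'   haplotypes used.
#' @return numeric vector of length `n_markers(geno)`.
#' @export
allele_freq <- function(geno, samples = NULL) {
  h <- geno$haplotypes
  if (!is.null(samples)) h <- h[haplotype_rows(geno, samples), , drop = FALSE]
  colMeans(h)
}

#' @rdname allele_freq
#' @export
maf <- function(geno, samples = NULL) {
  p <- allele_freq(geno, samples)
  pmin(p, 1 - p)
}

#' Row indices of the haplotypes belonging to a set of samples
#' @inheritParams allele_freq
#' @return integer vector of row indices into `geno$haplotypes`.
#' @export
haplotype_rows <- function(geno, samples) {
  i <- match(samples, geno$sample_ids)
  if (anyNA(i)) stop("unknown sample id(s): ", paste(samples[is.na(i)], collapse = ", "))
  as.vector(rbind(2L * i - 1L, 2L * i))
}

#' Allele-dosage matrix
#'
#' Sums the two haplotypes of each sample, giving the usual n x m dosage
#' matrix with entries in \{0, 1, 2\} used for individual-SNP models.
#'
#' @inheritParams allele_freq
#' @return integer matrix (samples x markers) with sample ids as rownames.
#' @export
dosage_matrix <- function(geno, samples = NULL) {
  if (is.null(samples)) samples <- geno$sample_ids
  rows <- haplotype_rows(geno, samples)
  h <- geno$haplotypes[rows, , drop = FALSE]
  d <- h[seq(1L, nrow(h), 2L), , drop = FALSE] + h[seq(2L, nrow(h), 2L), , drop = FALSE]
  rownames(d) <- samples
  colnames(d) <- geno$map$marker_id
  d
}

#' Subset markers of a phased-genotype object
#' @param geno a `phased_genotypes` object.
#' @param keep integer or logical index over markers (map order preserved).
#' @return a `phased_genotypes` object.
#' @export
subset_markers <- function(geno, keep) {
  phased_genotypes(
    geno$haplotypes[, keep, drop = FALSE],
    geno$map[keep, , drop = FALSE],
    geno$sample_ids
  )
}
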