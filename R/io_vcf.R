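#' Read phased genotypes from a VCF file
#'
#' Loads a VCF with phased, diploid GT fields into a [phased_genotypes()]
#' object. Only biallelic SNP records are kept; multi-allelic or non-SNP
#' records are skipped and counted. Unphased ("/" separated) or missing GT
#' values are hard errors: phasing and imputation are out of scope, so the
#' input must already be complete.
#'
#' @param path path to a VCF 4.x file (uncompressed or bgzipped).
#' @param region optional `"chrom"` or `"chrom:start-end"` string; records
#'   outside the region are dropped after parsing.
#' @return a `phased_genotypes` object; the number of skipped non-biallelic
#'   records is attached as attribute `skipped_records`.
#' @export
read_phased_vcf <- function(path, region = NULL) {
  if (!file.exists(path)) stop("VCF not found: ", path)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  gt <- vcf@gt
  sample_ids <- colnames(gt)[-1L]

  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]
  biallelic_snp <- !is.na(alt) & nchar(ref) == 1L & nchar(alt) == 1L &
    ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
  skipped <- sum(!biallelic_snp)
  if (!any(biallelic_snp)) stop("no biallelic SNP records in ", path)

  keep <- which(biallelic_snp)
  if (!is.null(region)) {
    reg <- parse_region(region)
    pos <- as.integer(fix[keep, "POS"])
    in_reg <- fix[keep, "CHROM"] == reg$chrom &
      pos >= reg$start & pos <= reg$end
    keep <- keep[in_reg]
    if (length(keep) == 0L) stop("no biallelic SNP records in region ", region)
  }

  # GT is the first colon-separated subfield of each genotype string
  # (sub() drops dim attributes, so restore the records x samples shape)
  gt_only <- matrix(sub(":.*$", "", gt[keep, -1L, drop = FALSE]),
                    nrow = length(keep))
  bad_missing <- matrix(grepl(".", gt_only, fixed = TRUE), nrow = nrow(gt_only))
  if (any(bad_missing)) {
    i <- which(bad_missing, arr.ind = TRUE)[1L, ]
    stop(sprintf(
      "missing GT at record %s:%s sample %s; complete data required",
      fix[keep[i[1L]], "CHROM"], fix[keep[i[1L]], "POS"], sample_ids[i[2L]]
    ))
  }
  unphased <- matrix(grepl("/", gt_only, fixed = TRUE), nrow = nrow(gt_only))
  if (any(unphased)) {
    i <- which(unphased, arr.ind = TRUE)[1L, ]
    stop(sprintf(
      "unphased GT at record %s:%s sample %s; phased ('|') genotypes required",
      fix[keep[i[1L]], "CHROM"], fix[keep[i[1L]], "POS"], sample_ids[i[2L]]
    ))
  }

  a1 <- substr(gt_only, 1L, 1L)
  a2 <- substr(gt_only, 3L, 3L)
  if (!all(c(a1, a2) %in% c("0", "1"))) stop("GT alleles outside {0,1} in ", path)
  m <- length(keep)
  n <- length(sample_ids)
  hap <- matrix(0L, nrow = 2L * n, ncol = m)
  hap[seq(1L, 2L * n, 2L), ] <- t(matrix(as.integer(a1), nrow = m))
  hap[seq(2L, 2L * n, 2L), ] <- t(matrix(as.integer(a2), nrow = m))

  id <- fix[keep, "ID"]
  id[is.na(id) | id == "."] <- paste0(fix[keep, "CHROM"], "_", fix[keep, "POS"])[is.na(id) | id == "."]
  map <- data.frame(
    marker_id = id,
    chrom = fix[keep, "CHROM"],
    pos = as.integer(fix[keep, "POS"]),
    allele0 = ref[keep],
    allele1 = alt[keep],
    stringsAsFactors = FALSE
  )
  geno <- phased_genotypes(hap, map, sample_ids)
  attr(geno, "skipped_records") <- skipped
  geno
}

parse_region <- function(region) {
  if (!grepl(":", region, fixed = TRUE)) {
    return(list(chrom = region, start = 0L, end = .Machine$integer.max))
  }
  parts <- strsplit(region, "[:-]")[[1L]]
  if (length(parts) != 3L) stop("region must be 'chrom' or 'chrom:start-end'")
  list(chrom = parts[1L], start = as.integer(parts[2L]), end = as.integer(parts[3L]))
}

#' Write phased genotypes as VCF
#'
#' Emits a minimal VCF 4.2 file with phased GT fields that round-trips
#' through [read_phased_vcf()].
#'
#' @param geno a `phased_genotypes` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_phased_vcf <- function(geno, path) {
  n <- n_samples(geno)
  h <- geno$haplotypes
  gt <- matrix(
    paste0(h[seq(1L, 2L * n, 2L), , drop = FALSE], "|", h[seq(2L, 2L * n, 2L), , drop = FALSE]),
    nrow = n
  )
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=hapblockr",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO", "FORMAT",
            geno$sample_ids), collapse = "\t")
  )
  body <- paste(
    geno$map$chrom, geno$map$pos, geno$map$marker_id,
    geno$map$allele0, geno$map$allele1, ".", "PASS", ".", "GT",
    apply(gt, 2L, paste, collapse = "\t"),
    sep = "\t"
  )
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read/write a plain haplotype-matrix text format
#'
#' Whitespace-separated fixture format: a map table (`marker_id chrom pos
#' allele0 allele1`) in `<path>.map`, and one row per haplotype in `path`,
#' the first column being the sample id (repeated twice per sample).
#'
#' @param path path of the haplotype matrix file.
#' @return a `phased_genotypes` object.
#' @export
read_hapmat <- function(path) {
  tab <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE)
  ids <- tab[[1L]]
  if (nrow(tab) %% 2L != 0L) stop("haplotype matrix must have an even number of rows")
  odd <- seq(1L, nrow(tab), 2L)
  if (!identical(ids[odd], ids[odd + 1L])) {
    stop("haplotype rows must come in consecutive pairs per sample")
  }
  map <- utils::read.table(paste0(path, ".map"), header = TRUE, stringsAsFactors = FALSE)
  phased_genotypes(as.matrix(tab[, -1L, drop = FALSE]), map, ids[odd])
}

#' @rdname read_hapmat
#' @param geno a `phased_genotypes` object to write.
#' @export
write_hapmat <- function(geno, path) {
  ids <- rep(geno$sample_ids, each = 2L)
  utils::write.table(
    data.frame(id = ids, geno$haplotypes),
    path, quote = FALSE, row.names = FALSE, col.names = FALSE
  )
  utils::write.table(geno$map, paste0(path, ".map"), quote = FALSE, row.names = FALSE)
  invisible(path)
}
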