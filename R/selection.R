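#' Select QTL-haploblocks from ranked SNP effects
#'
#' A "QTL-haploblock" is a haploblock containing at least one of the
#' top-`k` markers ranked by absolute estimated SNP effect. Selection is
#' deterministic given the ranked table: the top-`k` markers are mapped to
#' their containing blocks, excluded (single-variant) blocks are dropped
#' without topping `k` up, and the result is deduplicated in genome order.
#' Selection is model-matched downstream: blocks selected from a model's
#' SNP effects are fitted with that same model.
#'
#' @param ranked_effects data.frame from [snp_effect_table()] (must cover
#'   all markers the blocks were built on).
#' @param blocks catalogued haploblock list partitioning those markers.
#' @param k number of top-ranked markers used for selection (`1 <= k <= m`).
#' @return list with `blocks` (the selected non-excluded blocks, genome
#'   order), `block_index` (indices into `blocks` argument), `n_blocks`,
#'   `q` (total variant columns), `k`, and `trigger_markers` (the top-k
#'   marker indices).
#' @export
select_qtl_haploblocks <- function(ranked_effects, blocks, k) {
  m <- sum(vapply(blocks, function(b) length(b$markers), integer(1L)))
  stopifnot(k >= 1L, k <= m)
  if (nrow(ranked_effects) < m) {
    stop("ranked table covers ", nrow(ranked_effects), " markers; blocks cover ", m)
  }
  top <- ranked_effects$marker[seq_len(k)]
  map_idx <- marker_block_index(blocks, m)
  sel <- sort(unique(map_idx[top]))
  excl <- vapply(blocks, function(b) isTRUE(b$excluded), logical(1L))
  sel <- sel[!excl[sel]]
  picked <- blocks[sel]
  list(
    blocks = picked,
    block_index = sel,
    n_blocks = length(picked),
    q = sum(vapply(picked, function(b) length(b$variants), integer(1L))),
    k = as.integer(k),
    trigger_markers = top
  )
}

#' Random-haploblock selection baseline
#'
#' Mirrors the QTL-haploblock procedure with random marker choice: per
#' replicate, `k` markers are sampled uniformly without replacement and
#' mapped to their containing non-excluded blocks. Used as the baseline
#' the QTL-guided selection is compared against.
#'
#' @param blocks catalogued haploblock list.
#' @param k number of markers sampled per replicate.
#' @param replicates number of independent replicates (the reference
#'   protocol uses 10).
#' @param seed integer seed; selections are reproducible.
#' @return list of `replicates` selection lists, each shaped like the
#'   result of [select_qtl_haploblocks()] (without `trigger_markers`
#'   ranking semantics: markers are the sampled ones).
#' @export
select_random_haploblocks <- function(blocks, k, replicates = 10L, seed = 1L) {
  m <- sum(vapply(blocks, function(b) length(b$markers), integer(1L)))
  stopifnot(k >= 1L, k <= m, replicates >= 1L)
  map_idx <- marker_block_index(blocks, m)
  excl <- vapply(blocks, function(b) isTRUE(b$excluded), logical(1L))
  set.seed(seed)
  lapply(seq_len(replicates), function(rep) {
    picked_markers <- sample.int(m, k)
    sel <- sort(unique(map_idx[picked_markers]))
    sel <- sel[!excl[sel]]
    picked <- blocks[sel]
    list(
      blocks = picked,
      block_index = sel,
      n_blocks = length(picked),
      q = sum(vapply(picked, function(b) length(b$variants), integer(1L))),
      k = as.integer(k),
      trigger_markers = picked_markers,
      replicate = rep
    )
  })
}

#' Write a selection manifest as TSV
#'
#' @param selection result of [select_qtl_haploblocks()] (or one element
#'   of [select_random_haploblocks()]).
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_selection_tsv <- function(selection, path) {
  df <- data.frame(
    block_id = vapply(selection$blocks, `[[`, character(1L), "block_id"),
    chrom = vapply(selection$blocks, `[[`, character(1L), "chrom"),
    n_snps = vapply(selection$blocks, function(b) length(b$markers), integer(1L)),
    n_variants = vapply(selection$blocks, function(b) length(b$variants), integer(1L)),
    stringsAsFactors = FALSE
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
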