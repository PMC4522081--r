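test_that("pairwise LD matches hand-computed values in canonical configurations", {
  # complete LD: only AB and ab haplotypes
  hapA <- c(rep(1, 5), rep(0, 5))
  res <- pairwise_dprime(hapA, hapA)
  expect_equal(abs(res$Dprime), 1)
  expect_equal(res$r2, 1)

  # independence: all four haplotypes equally frequent
  hA <- c(1, 1, 0, 0)
  hB <- c(1, 0, 1, 0)
  res <- pairwise_dprime(hA, hB)
  expect_equal(res$D, 0)
  expect_equal(res$Dprime, 0)
  expect_equal(res$r2, 0)

  # AB=4, Ab=1, aB=1, ab=4 against the direct-count oracle
  hA <- c(rep(1, 5), rep(0, 5))
  hB <- c(rep(1, 4), 0, 1, rep(0, 4))
  res <- pairwise_dprime(hA, hB)
  oracle <- brute_ld(hA, hB)
  expect_equal(res$Dprime, oracle$Dprime)
  expect_equal(res$r2, oracle$r2)
})

test_that("pairwise LD equals the brute-force count-table oracle on random pairs", {
  set.seed(101)
  pop <- small_pop()
  h <- pop$geno$haplotypes
  f <- colMeans(h)
  poly <- which(f > 0 & f < 1)
  for (rep in 1:1000) {
    jk <- sample(poly, 2)
    res <- pairwise_dprime(h[, jk[1]], h[, jk[2]])
    oracle <- brute_ld(h[, jk[1]], h[, jk[2]])
    expect_equal(res$D, oracle$D, tolerance = 1e-12)
    expect_equal(res$Dprime, oracle$Dprime, tolerance = 1e-12)
    expect_equal(res$r2, oracle$r2, tolerance = 1e-12)
    expect_lte(abs(res$Dprime), 1 + 1e-12)
    expect_true(res$r2 >= 0 && res$r2 <= 1 + 1e-12)
  }
})

test_that("monomorphic markers are rejected by pairwise LD", {
  expect_error(pairwise_dprime(rep(1, 10), rbinom(10, 1, 0.5)), "monomorphic")
})

test_that("block construction handles the degenerate extremes", {
  # duplicated columns: every pair in complete LD -> one block per chromosome
  col <- c(1, 0, 1, 0, 1, 0, 1, 0)
  hap <- matrix(col, nrow = 8, ncol = 6)
  geno <- make_geno(hap, chrom = rep(c("1", "2"), each = 3))
  blocks <- build_blocks(geno, 0.45)
  expect_equal(length(blocks), 2L)
  expect_equal(lengths(lapply(blocks, `[[`, "markers")), c(3L, 3L))

  # independent markers: all |D'| = 0 -> singleton blocks
  hA <- c(1, 1, 0, 0)
  hB <- c(1, 0, 1, 0)
  geno2 <- make_geno(cbind(hA, hB, hA, hB))
  blocks2 <- build_blocks(geno2, 0.45)
  expect_equal(length(blocks2), 4L)
})

test_that("emitted blocks satisfy the all-pairs rule, are greedy-maximal, and partition markers", {
  pop <- small_pop()
  split <- pop_split(pop)
  ed <- edit_markers(pop$geno)
  threshold <- 0.45
  blocks <- build_blocks(ed, threshold, reference_samples = split$train)

  # partition
  all_markers <- sort(unlist(lapply(blocks, `[[`, "markers")))
  expect_equal(all_markers, seq_len(n_markers(ed)))
  expect_true(all(vapply(blocks, function(b) all(diff(b$markers) == 1), logical(1))))

  h <- ed$haplotypes[haplotype_rows(ed, split$train), ]
  pairwise_ok <- function(markers) {
    if (length(markers) < 2) return(TRUE)
    for (i in seq_along(markers)[-length(markers)]) {
      for (j in (i + 1):length(markers)) {
        ld <- brute_ld(h[, markers[i]], h[, markers[j]])
        if (abs(ld$Dprime) < threshold) return(FALSE)
      }
    }
    TRUE
  }
  # every multi-marker block passes an independent all-pairs check
  expect_true(all(vapply(blocks, function(b) pairwise_ok(b$markers), logical(1))))

  # greedy maximality: the marker after each block must violate the rule
  # against at least one block member (unless a chromosome ends there or a
  # boundary marker is monomorphic in the reference set)
  f <- colMeans(h)
  chrom <- ed$map$chrom
  for (b in blocks) {
    nxt <- max(b$markers) + 1L
    if (nxt > n_markers(ed) || chrom[nxt] != b$chrom) next
    if (f[nxt] <= 0 || f[nxt] >= 1) next
    if (any(f[b$markers] <= 0 | f[b$markers] >= 1)) next
    viol <- any(vapply(b$markers, function(m)
      abs(brute_ld(h[, m], h[, nxt])$Dprime) < threshold, logical(1)))
    expect_true(viol)
  }
})

test_that("raising the threshold shrinks leading blocks and never merges more markers", {
  pop <- small_pop()
  split <- pop_split(pop)
  ed <- edit_markers(pop$geno)
  thresholds <- c(0.30, 0.45, 0.60, 0.80)
  runs <- lapply(thresholds, build_blocks, geno = ed,
                 reference_samples = split$train)
  # the first block of each chromosome can only shrink as the threshold
  # rises (greedy extension passes a strict subset of candidates); later
  # block boundaries shift, so only the leading block is comparable
  first_sizes <- sapply(runs, function(blocks) {
    sapply(unique(ed$map$chrom), function(chr) {
      length(Filter(function(b) b$chrom == chr, blocks)[[1]]$markers)
    })
  })
  expect_true(all(apply(first_sizes, 1, function(s) all(diff(s) <= 0))))
  # and the partition can only fragment overall
  n_blocks <- sapply(runs, length)
  expect_true(all(diff(n_blocks) >= 0))
})

test_that("variant catalogues equal the distinct rows of the block submatrix", {
  pop <- small_pop()
  split <- pop_split(pop)
  ed <- edit_markers(pop$geno)
  blocks <- build_blocks(ed, 0.45, reference_samples = split$train)
  blocks <- catalogue_all_variants(blocks, ed, reference_samples = split$train)
  h <- ed$haplotypes[haplotype_rows(ed, split$train), ]
  multi <- Filter(function(b) length(b$markers) >= 2, blocks)
  for (b in multi[seq_len(min(10, length(multi)))]) {
    rows <- apply(h[, b$markers, drop = FALSE], 1, paste, collapse = "")
    expect_setequal(b$variants, unique(rows))
    expect_equal(sum(b$variant_freq), 1)
    expect_true(all(diff(b$variant_freq) <= 0))
  }
  # single-SNP polymorphic block: exactly the two alleles
  singles <- Filter(function(b) length(b$markers) == 1 && !b$excluded, blocks)
  if (length(singles) > 0) expect_setequal(singles[[1]]$variants, c("0", "1"))
})

test_that("blocks monomorphic in the reference are excluded", {
  hap <- cbind(rep(1, 8), c(1, 0, 1, 0, 1, 0, 1, 0))
  geno <- make_geno(hap)
  blocks <- build_blocks(geno, 0.45)
  blocks <- catalogue_all_variants(blocks, geno)
  expect_true(blocks[[1]]$excluded)
  expect_equal(length(blocks[[1]]$variants), 1L)
  expect_false(blocks[[2]]$excluded)
})

test_that("design matrix dosages split each sample's two haplotypes over variants", {
  pop <- small_pop()
  split <- pop_split(pop)
  ed <- edit_markers(pop$geno)
  blocks <- build_blocks(ed, 0.45, reference_samples = split$train)
  blocks <- catalogue_all_variants(blocks, ed, reference_samples = split$train)
  included <- Filter(function(b) !b$excluded, blocks)
  dm <- design_matrix(included, ed, c(split$train, split$test))
  expect_true(all(dm$M %in% 0:2))
  # reference samples: block-wise dosage sums are exactly 2
  bid <- dm$columns$block_id
  Mtrain <- dm$M[split$train, , drop = FALSE]
  for (b in unique(bid)[1:20]) {
    expect_true(all(rowSums(Mtrain[, bid == b, drop = FALSE]) == 2))
  }
  # test samples: sums are 2 minus the number of novel haplotypes (<= 2)
  Mtest <- dm$M[split$test, , drop = FALSE]
  sums <- sapply(unique(bid), function(b) rowSums(Mtest[, bid == b, drop = FALSE]))
  expect_true(all(sums %in% 0:2))
})

test_that("a test haplotype absent from the catalogue contributes no dosage", {
  # train on 4 samples; sample 5 carries a novel haplotype in the block
  hap <- rbind(
    c(1, 1), c(1, 1), c(0, 0), c(0, 0),
    c(1, 1), c(0, 0), c(1, 1), c(0, 0),
    c(1, 0), c(0, 0)   # sample 5: "10" is novel, "00" is catalogued
  )
  geno <- make_geno(hap)
  train <- paste0("S", 1:4)
  blocks <- build_blocks(geno, 0.45, reference_samples = train)
  expect_equal(length(blocks), 1L)
  blocks <- catalogue_all_variants(blocks, geno, reference_samples = train)
  dm <- design_matrix(blocks, geno, "S5")
  expect_equal(sum(dm$M), 1L)   # only the catalogued copy counts
})

test_that("block statistics recount the block list", {
  pop <- small_pop()
  split <- pop_split(pop)
  ed <- edit_markers(pop$geno)
  blocks <- build_blocks(ed, 0.45, reference_samples = split$train)
  blocks <- catalogue_all_variants(blocks, ed, reference_samples = split$train)
  s <- block_stats(blocks)
  expect_equal(s$n_blocks, length(blocks))
  expect_equal(s$n_markers, n_markers(ed))
  expect_equal(s$mean_snps, mean(lengths(lapply(blocks, `[[`, "markers"))))
  q_oracle <- sum(vapply(blocks, function(b)
    if (b$excluded) 0L else length(b$variants), integer(1)))
  expect_equal(s$q, q_oracle)

  dir <- tempfile(fileext = ".tsv")
  write_blocks_tsv(blocks, dir)
  tab <- read.delim(dir)
  expect_equal(nrow(tab), s$n_blocks)
  expect_equal(sum(tab$n_snps), s$n_markers)
})
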