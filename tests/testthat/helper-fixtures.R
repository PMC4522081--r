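# Shared fixtures, built in code. Heavier objects are memoised per test run.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, force(expr), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

# Tiny hand-made phased genotype object: n samples, markers on one or two
# chromosomes, haplotypes supplied as a 2n x m matrix.
make_geno <- function(hap, chrom = NULL, pos = NULL) {
  hap <- as.matrix(hap)
  m <- ncol(hap)
  n <- nrow(hap) / 2
  if (is.null(chrom)) chrom <- rep("1", m)
  if (is.null(pos)) {
    pos <- stats::ave(seq_len(m), chrom, FUN = seq_along) * 1000L
  }
  phased_genotypes(
    hap,
    data.frame(marker_id = paste0("snp", seq_len(m)), chrom = as.character(chrom),
               pos = pos, allele0 = "A", allele1 = "C", stringsAsFactors = FALSE),
    paste0("S", seq_len(n))
  )
}

# Random polymorphic haplotype matrix (independent markers).
random_geno <- function(n_samples, m, seed = 1) {
  set.seed(seed)
  repeat {
    hap <- matrix(rbinom(2 * n_samples * m, 1, runif(m, 0.15, 0.85)[
      rep(seq_len(m), each = 2 * n_samples)]), nrow = 2 * n_samples)
    f <- colMeans(hap)
    if (all(f > 0 & f < 1)) return(make_geno(hap))
  }
}

# Small simulated population shared across test files.
small_pop <- function() {
  memo("small_pop", simulate_population(sim_config(
    n_founders = 60, n_generations = 2, generation_size = 60,
    markers_per_chrom = 150, n_chromosomes = 2, n_qtl = 12, seed = 42
  )))
}

pop_split <- function(pop) {
  gen <- pop$generation
  test_ids <- pop$geno$sample_ids[gen == max(gen)]
  list(train = setdiff(pop$geno$sample_ids, test_ids), test = test_ids)
}

pop_ainv <- function(pop) {
  build_A_inverse(pedigree_table(as.data.frame(pop$pedigree)[, c("id", "sire", "dam")]))
}

# Brute-force LD from the 2x2 haplotype count table, kept deliberately
# independent of pairwise_dprime().
brute_ld <- function(hapA, hapB) {
  n <- length(hapA)
  n11 <- sum(hapA == 1 & hapB == 1)
  n10 <- sum(hapA == 1 & hapB == 0)
  n01 <- sum(hapA == 0 & hapB == 1)
  n00 <- sum(hapA == 0 & hapB == 0)
  pA <- (n11 + n10) / n
  pB <- (n11 + n01) / n
  D <- n11 / n - pA * pB
  dmax <- if (D > 0) min(pA * (1 - pB), (1 - pA) * pB)
          else if (D < 0) min(pA * pB, (1 - pA) * (1 - pB)) else 1
  list(D = D, Dprime = if (D == 0) 0 else D / dmax,
       r2 = D^2 / (pA * (1 - pA) * pB * (1 - pB)))
}
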