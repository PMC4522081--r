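#' Configuration for the pedigreed-population simulator
#'
#' Defines a forward-in-time simulation: founders are drawn by a
#' copying-with-switching process from a small ancestral haplotype pool
#' (which creates block-structured LD), then random mating over discrete
#' generations drops haplotypes through a recorded pedigree under a
#' Haldane crossover model. A quantitative trait with a four-component
#' mixture architecture and deregressed-proof (DRP) phenotypes with
#' per-animal reliabilities is layered on top.
#'
#' Defaults describe a desk-scale dairy-cattle-like population: 3
#' chromosomes of 1000 markers and 1 Morgan each, 200 founders plus 4
#' discrete generations of 200 (1000 animals in total, the last generation
#' serving as a natural validation set), heritability 0.3 with 40 QTL, and
#' DRP reliabilities uniform on (0.6, 0.95).
#'
#' @param n_founders number of founder animals.
#' @param n_generations number of discrete non-founder generations.
#' @param generation_size animals born per generation.
#' @param offspring_per_mating litter size; `generation_size /
#'   offspring_per_mating` matings are formed per generation.
#' @param n_chromosomes,markers_per_chrom marker map dimensions.
#' @param chrom_length_morgans genetic length of each chromosome; expected
#'   crossovers per gamete per chromosome (Haldane, no interference).
#' @param chrom_length_bp physical length used to place markers.
#' @param pool_size number of ancestral pool haplotypes founders copy from.
#' @param switch_rate per-marker probability that a founder haplotype
#'   switches to a different pool template; small values give long shared
#'   segments and strong local LD.
#' @param mutation_rate per-marker probability of flipping the copied
#'   allele; keeps markers polymorphic.
#' @param n_qtl number of causal markers.
#' @param mixture_props,mixture_vars four-class mixture over QTL effects:
#'   class proportions (summing to 1) and the ordered class variances the
#'   raw effects are drawn from (effects are subsequently rescaled to the
#'   target heritability, so only variance ratios matter).
#' @param h2 narrow-sense heritability of the trait, in (0, 1).
#' @param drp_reliability_range range of per-animal DRP reliabilities,
#'   drawn uniformly.
#' @param seed integer seed; every simulation function is deterministic
#'   given the config.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_founders = 200L,
                       n_generations = 4L,
                       generation_size = n_founders,
                       offspring_per_mating = 2L,
                       n_chromosomes = 3L,
                       markers_per_chrom = 1000L,
                       chrom_length_morgans = 1.0,
                       chrom_length_bp = 1e8,
                       pool_size = 4L,
                       switch_rate = 0.06,
                       mutation_rate = 0.01,
                       n_qtl = 40L,
                       mixture_props = c(0.889, 0.1, 0.01, 0.001),
                       mixture_vars = c(0.0001, 0.001, 0.01, 0.1),
                       h2 = 0.3,
                       drp_reliability_range = c(0.6, 0.95),
                       seed = 1L) {
  cfg <- list(
    n_founders = as.integer(n_founders),
    n_generations = as.integer(n_generations),
    generation_size = as.integer(generation_size),
    offspring_per_mating = as.integer(offspring_per_mating),
    n_chromosomes = as.integer(n_chromosomes),
    markers_per_chrom = as.integer(markers_per_chrom),
    chrom_length_morgans = chrom_length_morgans,
    chrom_length_bp = chrom_length_bp,
    pool_size = as.integer(pool_size),
    switch_rate = switch_rate,
    mutation_rate = mutation_rate,
    n_qtl = as.integer(n_qtl),
    mixture_props = mixture_props,
    mixture_vars = mixture_vars,
    h2 = h2,
    drp_reliability_range = drp_reliability_range,
    seed = as.integer(seed)
  )
  stopifnot(
    cfg$n_founders >= 2L, cfg$pool_size >= 2L,
    cfg$h2 > 0, cfg$h2 < 1,
    abs(sum(cfg$mixture_props) - 1) < 1e-8,
    all(cfg$mixture_vars >= 0),
    cfg$n_qtl <= cfg$n_chromosomes * cfg$markers_per_chrom,
    cfg$generation_size %% cfg$offspring_per_mating == 0L,
    cfg$drp_reliability_range[1] > 0, cfg$drp_reliability_range[2] < 1
  )
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate founder haplotypes with block-structured LD
#'
#' Each founder haplotype is built by copying alleles from an ancestral
#' pool of `pool_size` haplotypes, switching to a randomly chosen other
#' template with probability `switch_rate` per marker and flipping the
#' copied allele with probability `mutation_rate`. Long shared segments
#' between founders generate strong local LD with approximately
#' exponential decay. Markers that end up with MAF < 0.01 among founders
#' are redrawn (new pool column, same copying paths) a bounded number of
#' times; failure to produce a polymorphic marker is an error.
#'
#' @param config a [sim_config()].
#' @param max_retries retries of the MAF guard per marker batch.
#' @return a [phased_genotypes()] for the founders (sample ids `F1..Fn`).
#' @export
simulate_founder_haplotypes <- function(config, max_retries = 30L) {
  set.seed(config$seed)
  m_per <- config$markers_per_chrom
  m <- config$n_chromosomes * m_per
  n_hap <- 2L * config$n_founders
  P <- config$pool_size

  # ancestral pool allele frequencies biased away from the boundaries
  pool_freq <- stats::runif(m, 0.1, 0.9)
  pool <- matrix(stats::rbinom(P * m, 1L, rep(pool_freq, each = P)), nrow = P)

  # template paths: switch templates within chromosomes only
  templates <- matrix(0L, nrow = n_hap, ncol = m)
  for (chr in seq_len(config$n_chromosomes)) {
    cols <- ((chr - 1L) * m_per + 1L):(chr * m_per)
    cur <- sample.int(P, n_hap, replace = TRUE)
    for (j in cols) {
      sw <- stats::runif(n_hap) < config$switch_rate
      if (any(sw)) {
        cur[sw] <- 1L + (cur[sw] - 1L + sample.int(P - 1L, sum(sw), replace = TRUE)) %% P
      }
      templates[, j] <- cur
    }
  }
  flip <- matrix(stats::runif(n_hap * m) < config$mutation_rate, nrow = n_hap)

  hap <- matrix(pool[cbind(as.vector(templates), rep(seq_len(m), each = n_hap))],
                nrow = n_hap)
  hap[flip] <- 1L - hap[flip]

  for (retry in seq_len(max_retries)) {
    f <- colMeans(hap)
    bad <- which(pmin(f, 1 - f) < 0.01)
    if (length(bad) == 0L) break
    if (retry == max_retries) {
      stop(length(bad), " marker(s) failed the MAF guard after ", max_retries, " retries")
    }
    pool[, bad] <- stats::rbinom(P * length(bad), 1L, stats::runif(length(bad), 0.2, 0.8))
    redraw <- pool[cbind(as.vector(templates[, bad, drop = FALSE]),
                         rep(bad, each = n_hap))]
    flip_bad <- stats::runif(n_hap * length(bad)) < config$mutation_rate
    redraw[flip_bad] <- 1L - redraw[flip_bad]
    hap[, bad] <- redraw
  }

  pos_per <- round(seq(1, config$chrom_length_bp, length.out = m_per))
  map <- data.frame(
    marker_id = sprintf("chr%d_%d", rep(seq_len(config$n_chromosomes), each = m_per),
                        rep(pos_per, config$n_chromosomes)),
    chrom = as.character(rep(seq_len(config$n_chromosomes), each = m_per)),
    pos = rep(pos_per, config$n_chromosomes),
    allele0 = "A", allele1 = "C",
    stringsAsFactors = FALSE
  )
  phased_genotypes(hap, map, sprintf("F%d", seq_len(config$n_founders)))
}

# One gamete from a parent's two haplotypes (rows of a 2 x m matrix).
# Crossovers per chromosome ~ Poisson(length in Morgans), uniform positions,
# random starting haplotype: the Haldane model without interference.
make_gamete <- function(parent_haps, map_chrom, map_pos, chrom_lengths_m) {
  m <- ncol(parent_haps)
  gamete <- integer(m)
  for (chr in names(chrom_lengths_m)) {
    idx <- which(map_chrom == chr)
    pos <- map_pos[idx]
    n_co <- stats::rpois(1L, chrom_lengths_m[[chr]])
    cur <- sample.int(2L, 1L)
    if (n_co == 0L) {
      gamete[idx] <- parent_haps[cur, idx]
      next
    }
    span <- range(pos)
    co_pos <- sort(stats::runif(n_co, span[1], span[2]))
    phase <- (cur - 1L + findInterval(pos, co_pos)) %% 2L + 1L
    gamete[idx] <- parent_haps[cbind(phase, idx)]
  }
  gamete
}

#' Drop founder haplotypes through a random-mating pedigree
#'
#' Simulates `n_generations` discrete generations: each generation, the
#' previous generation is split at random into sires and dams,
#' `generation_size / offspring_per_mating` disjoint pairs are mated, and
#' each mating produces `offspring_per_mating` offspring. Gametes follow
#' the Haldane model (Poisson crossover counts, uniform positions, no
#' interference). Founders have unknown parents.
#'
#' @param founders founder [phased_genotypes()] from
#'   [simulate_founder_haplotypes()].
#' @param config a [sim_config()].
#' @return list with `geno` (all animals, founders first, generation order)
#'   and `pedigree` (a [pedigree_table()] with a `generation` column kept
#'   as attribute `generation` on the geno object as well).
#' @export
drop_through_pedigree <- function(founders, config) {
  set.seed(config$seed + 1L)
  stopifnot(config$n_generations >= 1L)
  m <- n_markers(founders)
  map_chrom <- founders$map$chrom
  map_pos <- founders$map$pos
  chrom_lengths <- stats::setNames(
    rep(config$chrom_length_morgans, config$n_chromosomes),
    unique(map_chrom)
  )

  total <- config$n_founders + config$n_generations * config$generation_size
  hap <- matrix(0L, nrow = 2L * total, ncol = m)
  hap[seq_len(2L * config$n_founders), ] <- founders$haplotypes
  ids <- c(founders$sample_ids,
           sprintf("G%d_%d", rep(seq_len(config$n_generations), each = config$generation_size),
                   rep(seq_len(config$generation_size), config$n_generations)))
  sire <- rep(NA_character_, total)
  dam <- rep(NA_character_, total)
  generation <- c(rep(0L, config$n_founders),
                  rep(seq_len(config$n_generations), each = config$generation_size))

  prev <- seq_len(config$n_founders)
  next_row <- config$n_founders + 1L
  n_matings <- config$generation_size %/% config$offspring_per_mating
  for (g in seq_len(config$n_generations)) {
    if (2L * n_matings > length(prev)) {
      stop("generation ", g, " needs ", 2L * n_matings,
           " distinct parents but only ", length(prev), " are available")
    }
    shuffled <- sample(prev)
    sires <- shuffled[seq_len(n_matings)]
    dams <- shuffled[n_matings + seq_len(n_matings)]
    for (k in seq_len(n_matings)) {
      s <- sires[k]; d <- dams[k]
      for (o in seq_len(config$offspring_per_mating)) {
        i <- next_row
        hap[2L * i - 1L, ] <- make_gamete(hap[c(2L * s - 1L, 2L * s), , drop = FALSE],
                                          map_chrom, map_pos, chrom_lengths)
        hap[2L * i, ] <- make_gamete(hap[c(2L * d - 1L, 2L * d), , drop = FALSE],
                                     map_chrom, map_pos, chrom_lengths)
        sire[i] <- ids[s]
        dam[i] <- ids[d]
        next_row <- next_row + 1L
      }
    }
    prev <- (next_row - config$generation_size):(next_row - 1L)
  }

  geno <- phased_genotypes(hap, founders$map, ids)
  attr(geno, "generation") <- generation
  ped <- pedigree_table(data.frame(id = ids, sire = sire, dam = dam,
                                   stringsAsFactors = FALSE))
  ped$generation <- generation[match(ped$id, ids)]
  list(geno = geno, pedigree = ped)
}

#' Simulate a quantitative trait and DRP phenotypes
#'
#' QTL positions are sampled uniformly over the markers; raw additive
#' effects come from the four-class normal mixture in `config`. True
#' breeding values are `TBV = X beta` on allele dosages, with effects
#' rescaled so that the realized genetic variance equals `h2` on a unit
#' phenotypic scale. Each animal receives a DRP reliability drawn
#' uniformly from `drp_reliability_range`, and
#' `DRP = TBV + e` with `Var(e) = Var(TBV) (1 - r2) / r2`, so that the
#' expected squared correlation of DRP with TBV equals its reliability.
#'
#' @param geno all-animal [phased_genotypes()].
#' @param pedigree matching [pedigree_table()] (used for id checks only;
#'   transmission already shaped the genotypes).
#' @param config a [sim_config()].
#' @return list with `drp` (a [drp_table()]) and `truth` (list: `tbv`
#'   named vector, `effects` length-m vector, `qtl_idx`, `qtl_class`,
#'   `var_tbv`).
#' @export
simulate_trait <- function(geno, pedigree, config) {
  set.seed(config$seed + 2L)
  stopifnot(config$n_qtl <= n_markers(geno))
  X <- dosage_matrix(geno)
  for (attempt in 1:20) {
    qtl_idx <- sort(sample.int(n_markers(geno), config$n_qtl))
    qtl_class <- sample.int(4L, config$n_qtl, replace = TRUE,
                            prob = config$mixture_props)
    beta_qtl <- stats::rnorm(config$n_qtl, 0,
                             sqrt(config$mixture_vars[qtl_class]))
    tbv <- as.vector(X[, qtl_idx, drop = FALSE] %*% beta_qtl)
    if (stats::var(tbv) > 0) break
    if (attempt == 20L) stop("degenerate trait: Var(TBV) = 0 after 20 QTL resamples")
  }
  scale <- sqrt(config$h2 / stats::var(tbv))
  beta_qtl <- beta_qtl * scale
  tbv <- tbv * scale
  tbv <- tbv - mean(tbv)
  var_tbv <- stats::var(tbv)

  n <- length(tbv)
  r2 <- stats::runif(n, config$drp_reliability_range[1], config$drp_reliability_range[2])
  err <- stats::rnorm(n, 0, sqrt(var_tbv * (1 - r2) / r2))
  effects <- numeric(n_markers(geno))
  effects[qtl_idx] <- beta_qtl
  names(tbv) <- geno$sample_ids
  drp <- drp_table(data.frame(
    id = geno$sample_ids, trait = "sim",
    drp = tbv + err, reliability = r2, stringsAsFactors = FALSE
  ))
  list(drp = drp,
       truth = list(tbv = tbv, effects = effects, qtl_idx = qtl_idx,
                    qtl_class = qtl_class, var_tbv = var_tbv))
}

#' Simulate a complete pedigreed population with trait and DRP
#'
#' Convenience wrapper chaining [simulate_founder_haplotypes()],
#' [drop_through_pedigree()] and [simulate_trait()].
#'
#' @param config a [sim_config()].
#' @return list with `geno`, `pedigree`, `drp`, `truth`, `generation`
#'   (integer vector, 0 = founder) and `config`.
#' @export
simulate_population <- function(config = sim_config()) {
  founders <- simulate_founder_haplotypes(config)
  dropped <- drop_through_pedigree(founders, config)
  trait <- simulate_trait(dropped$geno, dropped$pedigree, config)
  list(geno = dropped$geno,
       pedigree = dropped$pedigree,
       drp = trait$drp,
       truth = trait$truth,
       generation = attr(dropped$geno, "generation"),
       config = config)
}

#' Write a simulated population to standard formats
#'
#' Emits phased VCF, pedigree CSV, DRP CSV, and a truth CSV of marker
#' effects plus a TBV CSV.
#'
#' @param pop result of [simulate_population()].
#' @param dir output directory (created if needed).
#' @return named character vector of file paths, invisibly.
#' @export
write_population <- function(pop, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    vcf = file.path(dir, "genotypes.vcf"),
    pedigree = file.path(dir, "pedigree.csv"),
    drp = file.path(dir, "drp.csv"),
    effects = file.path(dir, "true_effects.csv"),
    tbv = file.path(dir, "true_bv.csv")
  )
  write_phased_vcf(pop$geno, paths[["vcf"]])
  ped_out <- pop$pedigree
  write_pedigree(pedigree_table(ped_out[, c("id", "sire", "dam")]), paths[["pedigree"]])
  write_drp(pop$drp, paths[["drp"]])
  utils::write.csv(
    data.frame(marker_id = pop$geno$map$marker_id, effect = pop$truth$effects),
    paths[["effects"]], row.names = FALSE, quote = FALSE
  )
  utils::write.csv(
    data.frame(id = names(pop$truth$tbv), tbv = as.numeric(pop$truth$tbv),
               generation = pop$generation),
    paths[["tbv"]], row.names = FALSE, quote = FALSE
  )
  invisible(paths)
}
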