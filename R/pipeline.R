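#' Configuration of a full prediction experiment
#'
#' Describes an end-to-end run: simulate (or load) data, edit markers, fit
#' the individual-SNP model, rank effects, build haploblocks on the
#' training animals, select QTL-haploblocks over a k-grid (optionally with
#' random-selection baselines), fit the haploblock models, and evaluate on
#' the held-out animals. Selection is model-matched: blocks selected from
#' a model's SNP effects are only ever fitted with that same model.
#'
#' @param sim a [sim_config()], or `NULL` to load data from `paths`.
#' @param paths named list (`vcf`, `pedigree`, `drp`, and either
#'   `train_ids`/`test_ids` character vectors or files of ids, one per
#'   line); ignored when `sim` is given — simulated data are split by
#'   generation (the last generation is the test set).
#' @param models character vector, subset of `c("blup", "mixture4")`.
#' @param threshold `|D'|` threshold for block construction.
#' @param maf_min,prune_complete_ld marker-editing parameters.
#' @param k_grid integer vector of main-SNP counts for QTL-haploblock
#'   selection.
#' @param random_replicates random-selection baselines per k for the first
#'   model (0 disables the baseline arm).
#' @param selection_source model whose ranked SNP effects drive the
#'   selection; must equal the prediction model (the default `NULL` keeps
#'   the pairing automatic), so a cross-model request is rejected up
#'   front.
#' @param chain_length,burn_in,thinning MCMC protocol for every fit.
#' @param out_dir run directory (created; existing files overwritten).
#' @param seed master seed; stage seeds are derived deterministically.
#' @return a `run_config` list, validated up front.
#' @export
run_config <- function(sim = sim_config(),
                       paths = NULL,
                       models = "blup",
                       threshold = 0.45,
                       maf_min = 0.01,
                       prune_complete_ld = TRUE,
                       k_grid = c(50L, 100L, 250L, 500L, 1000L, 2000L),
                       random_replicates = 0L,
                       selection_source = NULL,
                       chain_length = 5000L,
                       burn_in = 2000L,
                       thinning = 1L,
                       out_dir = tempfile("hapblockr_run_"),
                       seed = 1L) {
  models <- match.arg(models, c("blup", "mixture4"), several.ok = TRUE)
  if (is.null(sim) && is.null(paths)) stop("either sim or paths must be given")
  if (is.null(sim)) {
    needed <- c("vcf", "pedigree", "drp", "train_ids", "test_ids")
    missing <- setdiff(needed, names(paths))
    if (length(missing) > 0L) stop("paths lacks: ", paste(missing, collapse = ", "))
    for (p in c("vcf", "pedigree", "drp")) {
      if (!file.exists(paths[[p]])) stop("input not found: ", paths[[p]])
    }
  }
  if (!is.null(selection_source) && !setequal(selection_source, models)) {
    stop("selection_source must match the prediction model(s): blocks selected ",
         "by one model's SNP effects are only fitted with that same model")
  }
  cfg <- list(
    sim = sim, paths = paths, models = models, threshold = threshold,
    maf_min = maf_min, prune_complete_ld = isTRUE(prune_complete_ld),
    k_grid = sort(unique(as.integer(k_grid))),
    random_replicates = as.integer(random_replicates),
    chain_length = as.integer(chain_length), burn_in = as.integer(burn_in),
    thinning = as.integer(thinning),
    out_dir = out_dir, seed = as.integer(seed)
  )
  stopifnot(cfg$burn_in < cfg$chain_length, all(cfg$k_grid >= 1L),
            cfg$threshold > 0, cfg$threshold <= 1)
  class(cfg) <- "run_config"
  cfg
}

#' Run the full haploblock genomic-prediction pipeline
#'
#' Executes the stages in dependency order and records every emitted file
#' with its MD5 hash in `manifest.json`, so that a rerun with the same
#' configuration and seed reproduces the run bit for bit. Test-set
#' phenotypes are only touched by the evaluation stage.
#'
#' @param config a [run_config()].
#' @return invisible list with the run directory, the comparison tables
#'   per model, the block statistics, and the manifest.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(
    package_version = as.character(utils::packageVersion("hapblockr")),
    seed = config$seed,
    chain_length = config$chain_length,
    burn_in = config$burn_in,
    stages = list()
  )
  note <- function(stage, files, extra = NULL) {
    manifest$stages[[stage]] <<- c(
      list(files = as.list(tools::md5sum(unname(files)))), extra
    )
  }

  # --- data ---
  if (!is.null(config$sim)) {
    pop <- simulate_population(config$sim)
    files <- write_population(pop, file.path(config$out_dir, "data"))
    geno <- pop$geno; ped <- pop$pedigree; drp <- pop$drp
    gen <- pop$generation
    test_ids <- geno$sample_ids[gen == max(gen)]
    train_ids <- setdiff(geno$sample_ids, test_ids)
    truth <- pop$truth
  } else {
    geno <- read_phased_vcf(config$paths$vcf)
    ped <- read_pedigree(config$paths$pedigree)
    drp <- read_drp(config$paths$drp)
    train_ids <- read_id_arg(config$paths$train_ids)
    test_ids <- read_id_arg(config$paths$test_ids)
    files <- unlist(config$paths[c("vcf", "pedigree", "drp")])
    truth <- NULL
  }
  if (length(intersect(train_ids, test_ids)) > 0L) {
    stop("training and test sets overlap")
  }
  note("data", files, list(n_train = length(train_ids), n_test = length(test_ids)))

  # --- marker editing ---
  edited <- edit_markers(geno, config$maf_min, config$prune_complete_ld)
  note("edit", character(0), list(m_before = n_markers(geno), m_after = n_markers(edited)))

  # --- pedigree relationship ---
  Ainv <- build_A_inverse(pedigree_table(as.data.frame(ped)[, c("id", "sire", "dam")]))

  # --- haploblocks (training haplotypes only) ---
  blocks <- build_blocks(edited, config$threshold, reference_samples = train_ids)
  blocks <- catalogue_all_variants(blocks, edited, reference_samples = train_ids)
  blocks_tsv <- file.path(config$out_dir, "blocks.tsv")
  write_blocks_tsv(blocks, blocks_tsv)
  stats <- block_stats(blocks)
  note("blocks", blocks_tsv,
       list(n_blocks = stats$n_blocks, n_excluded = stats$n_excluded, q = stats$q))

  included <- blocks[!vapply(blocks, `[[`, logical(1L), "excluded")]
  design_all <- design_matrix(included, edited, c(train_ids, test_ids))
  M_full <- design_all$M
  drp_train <- drp[match(train_ids, drp$id), ]
  drp_test <- drp[match(test_ids, drp$id), ]

  X_snp <- dosage_matrix(edited, c(train_ids, test_ids))
  storage.mode(X_snp) <- "double"

  tables <- list()
  for (model in config$models) {
    model_seed <- config$seed + 1000L * match(model, c("blup", "mixture4"))
    spec <- function(s) model_spec(
      model, chain_length = config$chain_length, burn_in = config$burn_in,
      thinning = config$thinning, seed = s
    )

    # --- individual-SNP fit and ranking ---
    fit_snp <- fit_gibbs(drp_train, X_snp[train_ids, , drop = FALSE], Ainv,
                         spec(model_seed + 1L))
    ranked <- snp_effect_table(fit_snp, edited$map)
    eff_tsv <- file.path(config$out_dir, paste0("snp_effects_", model, ".tsv"))
    utils::write.table(ranked, eff_tsv, sep = "\t", quote = FALSE, row.names = FALSE)
    gebv_snp <- predict_gebv(fit_snp, X_snp[test_ids, , drop = FALSE])
    note(paste0("fit_snp_", model), eff_tsv, list(seed = model_seed + 1L))

    # --- full-haploblock fit ---
    fit_full <- fit_gibbs(drp_train, M_full[train_ids, , drop = FALSE], Ainv,
                          spec(model_seed + 2L))
    gebv_full <- predict_gebv(fit_full, M_full[test_ids, , drop = FALSE])

    # --- QTL-haploblock grid, model-matched ---
    gebv_grid <- list()
    sel_meta <- list()
    for (k in config$k_grid) {
      sel <- select_qtl_haploblocks(ranked, blocks, k)
      cols <- design_all$columns$block_id %in%
        vapply(sel$blocks, `[[`, character(1L), "block_id")
      fit_k <- fit_gibbs(drp_train, M_full[train_ids, cols, drop = FALSE], Ainv,
                         spec(model_seed + 10L + match(k, config$k_grid)))
      gebv_grid[[as.character(k)]] <- predict_gebv(
        fit_k, M_full[test_ids, cols, drop = FALSE])
      sel_meta[[as.character(k)]] <- list(n_blocks = sel$n_blocks, q = sel$q)
    }

    # --- random-selection baseline (first model only, when requested) ---
    if (config$random_replicates > 0L && model == config$models[[1L]]) {
      rnd_rows <- list()
      for (k in config$k_grid) {
        sels <- select_random_haploblocks(blocks, k, config$random_replicates,
                                          seed = config$seed + 77L + k)
        rel <- vapply(seq_along(sels), function(r) {
          cols <- design_all$columns$block_id %in%
            vapply(sels[[r]]$blocks, `[[`, character(1L), "block_id")
          fit_r <- fit_gibbs(drp_train, M_full[train_ids, cols, drop = FALSE],
                             Ainv, spec(model_seed + 500L + 100L * r +
                                          match(k, config$k_grid)))
          gebv_r <- predict_gebv(fit_r, M_full[test_ids, cols, drop = FALSE])
          reliability(drp_test$drp, gebv_r, mean(drp_test$reliability))$reliability
        }, numeric(1L))
        rnd_rows[[as.character(k)]] <- data.frame(
          k = k, replicates = config$random_replicates,
          mean_reliability = mean(rel), min_reliability = min(rel),
          max_reliability = max(rel)
        )
      }
      rnd_tsv <- file.path(config$out_dir, paste0("random_baseline_", model, ".tsv"))
      utils::write.table(do.call(rbind, rnd_rows), rnd_tsv, sep = "\t",
                         quote = FALSE, row.names = FALSE)
      note(paste0("random_baseline_", model), rnd_tsv)
    }

    tab <- evaluate_grid(
      stats::setNames(drp_test$drp, drp_test$id), mean(drp_test$reliability),
      gebv_grid, gebv_full, gebv_snp
    )
    tab$n_blocks <- c(vapply(sel_meta, function(x) x$n_blocks, integer(1L)),
                      stats$n_blocks - stats$n_excluded, NA_integer_)
    tab$q <- c(vapply(sel_meta, function(x) x$q, integer(1L)),
               stats$q, ncol(X_snp))
    tab_tsv <- file.path(config$out_dir, paste0("comparison_", model, ".tsv"))
    utils::write.table(tab, tab_tsv, sep = "\t", quote = FALSE, row.names = FALSE)
    gebv_tsv <- file.path(config$out_dir, paste0("gebv_", model, ".tsv"))
    gebv_out <- data.frame(
      id = test_ids,
      do.call(cbind, c(gebv_grid, list(full = gebv_full, snp = gebv_snp))),
      check.names = FALSE, stringsAsFactors = FALSE
    )
    names(gebv_out) <- c("id", paste0("k", names(gebv_grid)), "full", "snp")
    utils::write.table(gebv_out, gebv_tsv, sep = "\t", quote = FALSE, row.names = FALSE)
    note(paste0("evaluate_", model), c(tab_tsv, gebv_tsv))
    tables[[model]] <- tab
  }

  manifest_path <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, pretty = TRUE)
  invisible(list(out_dir = config$out_dir, tables = tables,
                 block_stats = stats, manifest = manifest,
                 truth = truth, train_ids = train_ids, test_ids = test_ids))
}

read_id_arg <- function(x) {
  if (length(x) == 1L && file.exists(x)) readLines(x) else as.character(x)
}

#' Load a run configuration from YAML
#'
#' YAML keys mirror the arguments of [run_config()]; a `sim:` mapping is
#' passed to [sim_config()]. Used by the `hapblock` command-line script.
#'
#' @param path YAML file.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$sim)) y$sim <- do.call(sim_config, y$sim)
  do.call(run_config, y)
}
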