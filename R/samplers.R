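#' Specification of a Bayesian whole-genome regression model
#'
#' Two models are available, differing only in the prior on the genomic
#' effects `g` in `y = 1 mu + M g + Z a + e`:
#' * `"blup"` — Bayesian BLUP: `g ~ N(0, I sigma2_g)`, one common variance.
#' * `"mixture4"` — four-component normal mixture with fixed mixing
#'   proportions `pi = (0.889, 0.1, 0.01, 0.001)` and class variances
#'   estimated under the ordering constraint
#'   `sigma2_1 < sigma2_2 < sigma2_3 < sigma2_4`.
#'
#' Both carry an optional pedigree polygenic effect `a ~ N(0, A sigma2_a)`
#' and heterogeneous residual variances `e ~ N(0, D sigma2_e)` with
#' `d_ii = 1/w_i`, the DRP reliability weights. Variances get improper
#' uniform priors; their conditionals are scaled inverse-chi-square.
#'
#' @param model `"blup"` or `"mixture4"`.
#' @param chain_length total MCMC cycles (default 5000; the reference
#'   protocol of 50000 is available by configuration).
#' @param burn_in cycles discarded before accumulating posterior means.
#' @param thinning keep every `thinning`-th post-burn-in cycle.
#' @param mixture_props fixed mixing proportions (mixture model only).
#' @param include_polygenic include the pedigree polygenic effect.
#' @param update_variances sample variance components; set `FALSE` to run
#'   at fixed variances (used by the mixed-model-equation cross-checks).
#' @param seed integer seed for the chain.
#' @param keep_samples store retained samples of all location parameters
#'   (memory-heavy; for small problems and diagnostics only).
#' @return a `model_spec` list.
#' @export
model_spec <- function(model = c("blup", "mixture4"),
                       chain_length = 5000L,
                       burn_in = 2000L,
                       thinning = 1L,
                       mixture_props = c(0.889, 0.1, 0.01, 0.001),
                       include_polygenic = TRUE,
                       update_variances = TRUE,
                       seed = 1L,
                       keep_samples = FALSE) {
  model <- match.arg(model)
  spec <- list(
    model = model,
    chain_length = as.integer(chain_length),
    burn_in = as.integer(burn_in),
    thinning = as.integer(thinning),
    mixture_props = mixture_props,
    include_polygenic = isTRUE(include_polygenic),
    update_variances = isTRUE(update_variances),
    seed = as.integer(seed),
    keep_samples = isTRUE(keep_samples)
  )
  if (spec$burn_in >= spec$chain_length) {
    stop("burn_in must be smaller than chain_length")
  }
  stopifnot(spec$thinning >= 1L, abs(sum(mixture_props) - 1) < 1e-8,
            all(mixture_props > 0))
  class(spec) <- "model_spec"
  spec
}

#' Fit a Bayesian BLUP or mixture model by Gibbs sampling
#'
#' Runs a single-chain Gibbs sampler for
#' `y = 1 mu + M g + Z a + e` with reliability weights: phenotypes are the
#' DRP of the training animals, `M` is any genomic design matrix (SNP
#' dosages or haploblock variant dosages), and the polygenic vector `a`
#' spans *all* animals in the pedigree — unphenotyped (e.g. validation)
#' animals are carried in the chain through the pedigree prior, so their
#' posterior-mean polygenic values are available for prediction.
#'
#' @param drp a [drp_table()]; only animals present in `rownames(M)` are
#'   used as phenotype records.
#' @param M numeric design matrix with training animal ids as rownames.
#' @param A_inverse sparse inverse numerator relationship matrix from
#'   [build_A_inverse()], covering at least all animals in `M`; its
#'   dimnames define the animal ordering of `a`. `NULL` drops the
#'   polygenic effect regardless of `spec$include_polygenic`.
#' @param spec a [model_spec()].
#' @param init_var optional list overriding initial values `var_g`
#'   (length 1 or 4), `var_a`, `var_e`; with
#'   `spec$update_variances = FALSE` these are the fixed values.
#' @return object of class `posterior_summary`: posterior means `mu`, `g`
#'   (named by columns of `M`), `a` (named by animal), variances, `gebv`
#'   for the training animals, the retained-sample variance trace, mixture
#'   class-membership probabilities (mixture only), and the model
#'   specification used.
#' @export
fit_gibbs <- function(drp, M, A_inverse = NULL, spec = model_spec(),
                      init_var = NULL) {
  if (is.null(rownames(M))) stop("M must carry animal ids as rownames")
  ids <- rownames(M)
  rec <- match(ids, drp$id)
  if (anyNA(rec)) stop("animals missing from the DRP table: ",
                       paste(ids[is.na(rec)], collapse = ", "))
  y <- drp$drp[rec]
  w <- drp$weight[rec]
  n <- length(y)

  include_poly <- spec$include_polygenic && !is.null(A_inverse)
  if (include_poly) {
    Ainv <- methods::as(methods::as(A_inverse, "generalMatrix"), "CsparseMatrix")
    all_ids <- rownames(Ainv)
    if (is.null(all_ids)) stop("A_inverse must carry animal ids as dimnames")
    train_animal <- match(ids, all_ids)
    if (anyNA(train_animal)) {
      stop("animals absent from A_inverse: ",
           paste(ids[is.na(train_animal)], collapse = ", "))
    }
    Ai <- Ainv@i; Ap <- Ainv@p; Ax <- Ainv@x
    n_all <- nrow(Ainv)
  } else {
    all_ids <- ids
    train_animal <- rep(NA_integer_, n)
    Ai <- integer(0); Ap <- integer(n + 1L); Ax <- numeric(0)
    n_all <- n
  }

  K <- if (spec$model == "mixture4") 4L else 1L
  vy <- stats::var(y)
  var_g0 <- if (K == 1L) vy / (2 * max(ncol(M), 1L)) else
    vy / (2 * max(ncol(M), 1L)) * c(0.01, 0.1, 1, 10)
  var_a0 <- vy / 4
  var_e0 <- vy / 2
  if (!is.null(init_var)) {
    if (!is.null(init_var$var_g)) var_g0 <- init_var$var_g
    if (!is.null(init_var$var_a)) var_a0 <- init_var$var_a
    if (!is.null(init_var$var_e)) var_e0 <- init_var$var_e
  }
  if (length(var_g0) != K) stop("init var_g must have length ", K)

  storage.mode(M) <- "double"
  set.seed(spec$seed)
  res <- gibbs_core(
    y, M, w, Ai, Ap, Ax, n_all,
    ifelse(is.na(train_animal), -1L, train_animal - 1L),
    if (spec$model == "mixture4") 1L else 0L,
    spec$mixture_props,
    spec$chain_length, spec$burn_in, spec$thinning,
    spec$update_variances, include_poly,
    as.numeric(var_g0), var_a0, var_e0,
    spec$keep_samples
  )

  g <- stats::setNames(res$g, colnames(M))
  a <- stats::setNames(res$a, all_ids)
  gebv_train <- as.vector(M %*% g) + if (include_poly) a[ids] else rep(0, n)
  colnames(res$var_trace) <- c(
    if (K == 1L) "var_g" else paste0("var_pi", 1:4), "var_a", "var_e"
  )
  out <- list(
    mu = res$mu, g = g, a = a,
    var_g = res$var_g, var_a = res$var_a, var_e = res$var_e,
    gebv_train = stats::setNames(as.vector(gebv_train), ids),
    n_retained = res$n_retained,
    var_trace = res$var_trace,
    label_prob = if (K == 4L) res$label_prob else NULL,
    samples = if (spec$keep_samples) res$samples else NULL,
    train_ids = ids,
    columns = colnames(M),
    include_polygenic = include_poly,
    spec = spec
  )
  class(out) <- "posterior_summary"
  out
}

#' @export
print.posterior_summary <- function(x, ...) {
  cat(sprintf(
    "posterior_summary: %s model, %d effects, %d training animals, %d retained cycles\n",
    x$spec$model, length(x$g), length(x$train_ids), x$n_retained
  ))
  cat(sprintf("  var_g = %s; var_a = %.4g; var_e = %.4g\n",
              paste(signif(x$var_g, 4), collapse = ", "), x$var_a, x$var_e))
  invisible(x)
}

#' Genomic estimated breeding values for new animals
#'
#' `GEBV_i = sum_j m_ij ghat_j + ahat_i`: the linear combination of the
#' posterior-mean effects with the animal's design row, plus its
#' posterior-mean polygenic value (sampled in-chain through the pedigree).
#'
#' @param summary a `posterior_summary` from [fit_gibbs()].
#' @param M_new design matrix for the animals to predict; its columns must
#'   match the training design columns exactly.
#' @return named numeric vector of GEBV.
#' @export
predict_gebv <- function(summary, M_new) {
  if (is.null(rownames(M_new))) stop("M_new must carry animal ids as rownames")
  if (ncol(M_new) != length(summary$g) ||
      !identical(colnames(M_new), summary$columns)) {
    stop("columns of M_new do not match the training design matrix")
  }
  ids <- rownames(M_new)
  gebv <- as.vector(M_new %*% summary$g)
  if (summary$include_polygenic) {
    miss <- setdiff(ids, names(summary$a))
    if (length(miss) > 0L) {
      stop("animals absent from the fitted polygenic vector: ",
           paste(miss, collapse = ", "))
    }
    gebv <- gebv + summary$a[ids]
  }
  stats::setNames(as.vector(gebv), ids)
}

#' Ranked table of estimated SNP effects
#'
#' Ranks the posterior-mean effects of an individual-SNP fit by descending
#' absolute value; ties are broken by genome order (map order), so the
#' ranking is deterministic.
#'
#' @param summary a `posterior_summary` from a fit where `M` was the SNP
#'   dosage matrix (one column per marker, in map order).
#' @param map optional marker map carried into the output.
#' @return data.frame with columns `marker` (map index), `marker_id`,
#'   `effect`, `abs_effect`, `rank`, sorted by rank.
#' @export
snp_effect_table <- function(summary, map = NULL) {
  eff <- summary$g
  m <- length(eff)
  ord <- order(-abs(eff), seq_len(m), method = "radix")
  out <- data.frame(
    marker = ord,
    marker_id = if (!is.null(map)) map$marker_id[ord] else
      if (!is.null(names(eff))) names(eff)[ord] else as.character(ord),
    effect = as.numeric(eff[ord]),
    abs_effect = abs(as.numeric(eff[ord])),
    rank = seq_len(m),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Direct solution of the weighted mixed-model equations
#'
#' Solves for the posterior mode/mean of `(mu, g, a)` at *fixed* variance
#' components: the coefficient matrix is
#' `t(W) %*% W`-weighted least squares augmented with the ridge penalty
#' `I/var_g` on `g` and the pedigree penalty `A^{-1}/var_a` on `a`. With
#' Gaussian priors and fixed variances the Gibbs posterior mean converges
#' to this solution, which makes it an independent oracle for the sampler.
#'
#' @param drp a [drp_table()].
#' @param M design matrix with animal ids as rownames.
#' @param A_inverse sparse A-inverse (or `NULL` for no polygenic effect).
#' @param var_g,var_a,var_e fixed variance components.
#' @return list with `mu`, `g`, `a` (named; over all animals in
#'   `A_inverse`).
#' @export
solve_mme <- function(drp, M, A_inverse, var_g, var_a, var_e) {
  ids <- rownames(M)
  rec <- match(ids, drp$id)
  y <- drp$drp[rec]
  w <- drp$weight[rec]
  n <- length(y)
  q <- ncol(M)
  include_poly <- !is.null(A_inverse)
  if (include_poly) {
    all_ids <- rownames(A_inverse)
    n_all <- length(all_ids)
    Z <- Matrix::sparseMatrix(i = seq_len(n), j = match(ids, all_ids),
                              x = 1, dims = c(n, n_all))
  } else {
    n_all <- 0L
    Z <- NULL
  }
  X <- cbind(1, M)
  if (include_poly) X <- cbind(X, as.matrix(Z))
  W <- Matrix::Diagonal(x = w)
  C <- as.matrix(Matrix::t(X) %*% W %*% X) / var_e
  pen <- c(0, rep(1 / var_g, q),
           if (include_poly) rep(0, n_all) else numeric(0))
  C <- C + diag(pen)
  if (include_poly) {
    idx <- 1L + q + seq_len(n_all)
    C[idx, idx] <- C[idx, idx] + as.matrix(A_inverse) / var_a
  }
  rhs <- as.vector(Matrix::t(X) %*% (w * y)) / var_e
  sol <- solve(C, rhs)
  list(
    mu = sol[1L],
    g = stats::setNames(sol[1L + seq_len(q)], colnames(M)),
    a = if (include_poly) stats::setNames(sol[1L + q + seq_len(n_all)], all_ids)
        else NULL
  )
}
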