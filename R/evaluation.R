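#' Reliability and bias of genomic predictions
#'
#' Reliability of GEBV in a validation set is the squared Pearson
#' correlation between DRP and GEBV corrected for the average DRP
#' reliability of the test animals:
#' `r2 = Cor^2(DRP, GEBV) / mean_r2_drp`. Bias is reported as `b - 1`,
#' where `b` is the ordinary least-squares regression coefficient of DRP
#' on GEBV (`b = 1` means unbiased dispersion of the predictions).
#'
#' @param drp numeric vector of test-animal DRP.
#' @param gebv numeric vector of matching GEBV.
#' @param mean_r2_drp average DRP reliability of the test animals, in
#'   `(0, 1]`.
#' @return list of class `evaluation_result`: `reliability`, `correlation`,
#'   `slope`, `bias` (`slope - 1`), `n_test`, `mean_r2_drp`.
#' @export
reliability <- function(drp, gebv, mean_r2_drp) {
  if (length(drp) != length(gebv)) stop("drp and gebv differ in length")
  if (length(drp) < 3L) stop("need at least 3 test animals")
  stopifnot(mean_r2_drp > 0, mean_r2_drp <= 1)
  if (stats::var(gebv) == 0) stop("zero-variance GEBV: nothing to evaluate")
  r <- stats::cor(drp, gebv)
  b <- stats::cov(drp, gebv) / stats::var(gebv)
  structure(
    list(reliability = r^2 / mean_r2_drp,
         correlation = r,
         slope = b,
         bias = b - 1,
         n_test = length(drp),
         mean_r2_drp = mean_r2_drp),
    class = "evaluation_result"
  )
}

#' @export
print.evaluation_result <- function(x, ...) {
  cat(sprintf("reliability %.4f (cor %.4f), bias %.4f, n = %d\n",
              x$reliability, x$correlation, x$bias, x$n_test))
  invisible(x)
}

#' Hotelling-Williams test for two dependent correlations
#'
#' Tests whether two prediction models are equally correlated with the
#' same DRP vector: `H0: cor(DRP, GEBV_i) = cor(DRP, GEBV_j)`. The
#' statistic is
#' \deqn{T = \frac{(r_{di} - r_{dj}) \sqrt{(n-3)(1+r_{ij})/(2|R|)}}{
#'   \sqrt{1 + (n-3)(r_{di}+r_{dj})^2 (1-r_{ij})^3 / (8 (n-1) |R|)}}}{
#'   T = (r_di - r_dj) sqrt((n-3)(1+r_ij)/(2|R|)) /
#'   sqrt(1 + (n-3)(r_di+r_dj)^2 (1-r_ij)^3 / (8(n-1)|R|))}
#' where `|R|` is the determinant of the 3x3 correlation matrix of
#' `(DRP, GEBV_i, GEBV_j)`. Under H0, `T ~ t(n-3)`; the p-value is
#' two-tailed.
#'
#' @param drp,gebv_i,gebv_j numeric vectors of equal length `n >= 4`.
#' @return list of class `hw_test`: `r_drp_i`, `r_drp_j`, `r_ij`, `detR`,
#'   `n`, `T`, `df`, `p_value`.
#' @export
hotelling_williams <- function(drp, gebv_i, gebv_j) {
  n <- length(drp)
  if (length(gebv_i) != n || length(gebv_j) != n) stop("vectors differ in length")
  if (n < 4L) stop("need at least 4 observations")
  if (stats::var(drp) == 0 || stats::var(gebv_i) == 0 || stats::var(gebv_j) == 0) {
    stop("zero-variance input vector")
  }
  r_di <- stats::cor(drp, gebv_i)
  r_dj <- stats::cor(drp, gebv_j)
  r_ij <- stats::cor(gebv_i, gebv_j)
  R <- matrix(c(1, r_di, r_dj,
                r_di, 1, r_ij,
                r_dj, r_ij, 1), 3L, 3L)
  detR <- det(R)
  if (r_di == r_dj) {
    # identical correlations: T = 0 regardless of |R| (which may be 0
    # when the two predictions are numerically identical)
    Tstat <- 0
  } else {
    if (detR <= 0) {
      stop("degenerate correlation matrix (|R| <= 0): predictions are collinear")
    }
    num <- (r_di - r_dj) * sqrt((n - 3) * (1 + r_ij) / (2 * detR))
    den <- sqrt(1 + (n - 3) * (r_di + r_dj)^2 * (1 - r_ij)^3 / (8 * (n - 1) * detR))
    Tstat <- num / den
  }
  structure(
    list(r_drp_i = r_di, r_drp_j = r_dj, r_ij = r_ij, detR = detR,
         n = n, T = Tstat, df = n - 3L,
         p_value = 2 * stats::pt(abs(Tstat), df = n - 3L, lower.tail = FALSE)),
    class = "hw_test"
  )
}

#' @export
print.hw_test <- function(x, ...) {
  cat(sprintf("Hotelling-Williams: r_di = %.4f, r_dj = %.4f, T = %.3f (df %d), p = %.4f\n",
              x$r_drp_i, x$r_drp_j, x$T, x$df, x$p_value))
  invisible(x)
}

#' Comparison table over a k-grid of selections
#'
#' Assembles the standard results layout: one row per `k` with the
#' reliability and bias of the corresponding QTL-haploblock model plus the
#' Hotelling-Williams p-value against the full-haploblock model, followed
#' by one row for the full-haploblock model and one for the
#' individual-SNP model. All GEBV vectors must be for the same test
#' animals in the same order.
#'
#' @param drp_test numeric vector of test-animal DRP.
#' @param mean_r2_drp average test-set DRP reliability.
#' @param gebv_grid named list of GEBV vectors, one per `k` (names are the
#'   `k` values).
#' @param gebv_full GEBV vector of the full-haploblock model.
#' @param gebv_snp GEBV vector of the individual-SNP model.
#' @return data.frame with columns `model`, `k`, `reliability`, `bias`,
#'   `hw_p_vs_full`.
#' @export
evaluate_grid <- function(drp_test, mean_r2_drp, gebv_grid, gebv_full, gebv_snp) {
  n <- length(drp_test)
  vecs <- c(gebv_grid, list(full = gebv_full, snp = gebv_snp))
  for (nm in names(vecs)) {
    v <- vecs[[nm]]
    if (length(v) != n) stop("GEBV '", nm, "' does not match the test set")
    if (!is.null(names(v)) && !is.null(names(drp_test)) &&
        !identical(names(v), names(drp_test))) {
      stop("GEBV '", nm, "' is ordered differently from the test DRP")
    }
  }
  row_for <- function(model, k, gebv, compare_full) {
    ev <- reliability(drp_test, gebv, mean_r2_drp)
    p <- if (compare_full) {
      if (isTRUE(all.equal(as.numeric(gebv), as.numeric(gebv_full)))) 1
      else hotelling_williams(drp_test, gebv, gebv_full)$p_value
    } else NA_real_
    data.frame(model = model, k = k, reliability = ev$reliability,
               bias = ev$bias, hw_p_vs_full = p, stringsAsFactors = FALSE)
  }
  rows <- lapply(names(gebv_grid), function(kname) {
    row_for("qtl_haploblocks", as.integer(kname), gebv_grid[[kname]], TRUE)
  })
  rows <- c(rows, list(
    row_for("all_haploblocks", NA_integer_, gebv_full, TRUE),
    row_for("individual_snp", NA_integer_, gebv_snp, FALSE)
  ))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
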