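#' Pedigree numerator relationship matrix A
#'
#' Tabular (recursive) method on a topologically sorted pedigree:
#' `A[j,j] = 1 + A[s,d]/2` and `A[i,j] = (A[i,s] + A[i,d])/2` for `i < j`,
#' with unknown parents contributing zero. The diagonal is `1 + F` with
#' `F` the inbreeding coefficient, so inbreeding is carried exactly.
#'
#' @param pedigree a [pedigree_table()] (already sorted: parents precede
#'   offspring).
#' @return list of class `pedigree_relationship` with `ids`, `A` (dense
#'   symmetric matrix with ids as dimnames) and `F` (inbreeding
#'   coefficients).
#' @export
build_A <- function(pedigree) {
  check_sorted_pedigree(pedigree)
  n <- nrow(pedigree)
  ids <- pedigree$id
  s <- match(pedigree$sire, ids)
  d <- match(pedigree$dam, ids)
  A <- matrix(0, n, n, dimnames = list(ids, ids))
  for (j in seq_len(n)) {
    sj <- s[j]; dj <- d[j]
    if (j > 1L) {
      i <- seq_len(j - 1L)
      row <- numeric(j - 1L)
      if (!is.na(sj)) row <- row + A[i, sj]
      if (!is.na(dj)) row <- row + A[i, dj]
      row <- row / 2
      A[i, j] <- row
      A[j, i] <- row
    }
    A[j, j] <- 1 + if (!is.na(sj) && !is.na(dj)) 0.5 * A[sj, dj] else 0
  }
  structure(list(ids = ids, A = A, F = diag(A) - 1),
            class = "pedigree_relationship")
}

#' Inverse of the numerator relationship matrix by Henderson's rules
#'
#' Assembles A-inverse directly from the pedigree, accounting for
#' inbreeding: the Mendelian-sampling variance of individual `j` is
#' `0.5 - 0.25 (F_s + F_d)` (both parents known),
#' `0.75 - 0.25 F_p` (one parent known) or `1` (founder), and its
#' reciprocal is scattered over the (individual, parents) sub-block.
#' Inbreeding coefficients come from [build_A()] (dense; intended for
#' pedigrees up to a few thousand individuals).
#'
#' @param pedigree a [pedigree_table()].
#' @return sparse symmetric matrix (class `dsCMatrix`) with ids as
#'   dimnames.
#' @export
build_A_inverse <- function(pedigree) {
  check_sorted_pedigree(pedigree)
  n <- nrow(pedigree)
  ids <- pedigree$id
  Fi <- build_A(pedigree)$F
  s <- match(pedigree$sire, ids)
  d <- match(pedigree$dam, ids)

  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  add <- function(i, j, x) {
    ii <<- c(ii, i); jj <<- c(jj, j); xx <<- c(xx, x)
  }
  for (j in seq_len(n)) {
    sj <- s[j]; dj <- d[j]
    msv <- if (!is.na(sj) && !is.na(dj)) {
      0.5 - 0.25 * (Fi[sj] + Fi[dj])
    } else if (!is.na(sj)) {
      0.75 - 0.25 * Fi[sj]
    } else if (!is.na(dj)) {
      0.75 - 0.25 * Fi[dj]
    } else 1
    alpha <- 1 / msv
    add(j, j, alpha)
    for (p in c(sj, dj)) {
      if (!is.na(p)) {
        add(p, j, -alpha / 2)
        add(j, p, -alpha / 2)
        add(p, p, alpha / 4)
      }
    }
    if (!is.na(sj) && !is.na(dj)) {
      add(sj, dj, alpha / 4)
      add(dj, sj, alpha / 4)
    }
  }
  Ainv <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n),
                               dimnames = list(ids, ids))
  Matrix::forceSymmetric(Ainv)
}

check_sorted_pedigree <- function(pedigree) {
  if (!inherits(pedigree, "pedigree_table")) {
    stop("expected a pedigree_table (see pedigree_table())")
  }
  ids <- pedigree$id
  if (anyDuplicated(ids)) stop("duplicate individuals in pedigree")
  pos <- seq_along(ids)
  names(pos) <- ids
  for (col in c("sire", "dam")) {
    p <- pedigree[[col]]
    known <- !is.na(p)
    if (any(pos[p[known]] >= pos[known])) {
      stop("pedigree not sorted: a ", col, " appears after its offspring")
    }
  }
  invisible(pedigree)
}

#' Export nonzero relationship coefficients as TSV
#'
#' @param rel a `pedigree_relationship` from [build_A()].
#' @param path output path.
#' @param tol entries with `|A_ij| <= tol` are omitted.
#' @return `path`, invisibly.
#' @export
write_relationship_tsv <- function(rel, path, tol = 0) {
  idx <- which(upper.tri(rel$A, diag = TRUE) & abs(rel$A) > tol, arr.ind = TRUE)
  df <- data.frame(id_i = rel$ids[idx[, 1L]], id_j = rel$ids[idx[, 2L]],
                   a = rel$A[idx], stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
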