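#' Construct and validate a pedigree table
#'
#' A pedigree is a data.frame with columns `id`, `sire`, `dam`; unknown
#' parents are `NA`. Records are topologically sorted (parents before
#' offspring) on construction; a cycle (an individual among its own
#' ancestors) is a hard error.
#'
#' @param df data.frame with columns `id`, `sire`, `dam`; unknown parents
#'   coded `NA`, `0`, or `""`.
#' @return a `pedigree_table`: the sorted, validated data.frame.
#' @export
pedigree_table <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  needed <- c("id", "sire", "dam")
  if (!all(needed %in% names(df))) stop("pedigree needs columns id, sire, dam")
  df <- df[, needed]
  for (col in needed) {
    v <- as.character(df[[col]])
    v[v %in% c("0", "")] <- NA_character_
    df[[col]] <- v
  }
  if (anyNA(df$id)) stop("pedigree ids may not be missing")
  if (anyDuplicated(df$id)) {
    stop("duplicate pedigree id(s): ", paste(unique(df$id[duplicated(df$id)]), collapse = ", "))
  }
  for (col in c("sire", "dam")) {
    unknown <- !is.na(df[[col]]) & !(df[[col]] %in% df$id)
    if (any(unknown)) {
      stop("parent(s) absent from pedigree: ", paste(df[[col]][unknown], collapse = ", "))
    }
  }
  ord <- pedigree_toposort(df)
  df <- df[ord, , drop = FALSE]
  rownames(df) <- NULL
  structure(df, class = c("pedigree_table", "data.frame"))
}

# Kahn's algorithm over the parent -> offspring DAG; detects cycles.
pedigree_toposort <- function(df) {
  n <- nrow(df)
  idx <- seq_len(n)
  names(idx) <- df$id
  sire_i <- unname(idx[df$sire])
  dam_i <- unname(idx[df$dam])
  indeg <- (!is.na(sire_i)) + (!is.na(dam_i))
  children <- vector("list", n)
  for (j in seq_len(n)) {
    for (p in c(sire_i[j], dam_i[j])) {
      if (!is.na(p)) children[[p]] <- c(children[[p]], j)
    }
  }
  queue <- which(indeg == 0L)
  out <- integer(0)
  while (length(queue) > 0L) {
    # stable order keeps the sort deterministic
    queue <- sort(queue)
    v <- queue[1L]
    queue <- queue[-1L]
    out <- c(out, v)
    for (ch in children[[v]]) {
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) queue <- c(queue, ch)
    }
  }
  if (length(out) != n) {
    stop("pedigree contains a cycle involving: ",
         paste(df$id[setdiff(idx, out)], collapse = ", "))
  }
  out
}

#' Read a pedigree from a CSV/TSV file
#'
#' @param path file with header columns `id`, `sire`, `dam` (comma- or
#'   tab-separated; unknown parents `0` or empty).
#' @return a sorted [pedigree_table()].
#' @export
read_pedigree <- function(path) {
  pedigree_table(read_delim_auto(path))
}

#' @rdname read_pedigree
#' @param ped a `pedigree_table` to write.
#' @export
write_pedigree <- function(ped, path) {
  out <- as.data.frame(ped)
  out$sire[is.na(out$sire)] <- "0"
  out$dam[is.na(out$dam)] <- "0"
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Construct a table of deregressed proofs (DRP)
#'
#' Each record carries a pseudo-phenotype (the DRP) and its reliability
#' r2 in (0, 1). The residual weight `w = r2 / (1 - r2)` is derived on
#' construction; the weighted models use residual variances proportional
#' to `1/w`. Reliabilities outside `[0.01, 0.99]` are capped (with a
#' warning) so weights stay finite and positive.
#'
#' @param df data.frame with columns `id`, `drp`, `reliability` (an
#'   optional `trait` column is carried through).
#' @return a `drp_table` data.frame with the derived `weight` column.
#' @export
drp_table <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  if (!all(c("id", "drp", "reliability") %in% names(df))) {
    stop("DRP table needs columns id, drp, reliability")
  }
  df$id <- as.character(df$id)
  if (anyDuplicated(df$id)) stop("duplicate animal id(s) in DRP table")
  r2 <- as.numeric(df$reliability)
  if (anyNA(r2) || anyNA(df$drp)) stop("missing DRP or reliability values")
  needs_cap <- r2 < 0.01 | r2 > 0.99
  if (any(needs_cap)) {
    warning(sum(needs_cap), " reliability value(s) capped to [0.01, 0.99]",
            if (any(r2 <= 0 | r2 >= 1)) {
              paste0("; outside (0,1) for id(s): ",
                     paste(df$id[r2 <= 0 | r2 >= 1], collapse = ", "))
            } else "")
  }
  r2 <- pmin(pmax(r2, 0.01), 0.99)
  df$reliability <- r2
  df$weight <- r2 / (1 - r2)
  structure(df, class = c("drp_table", "data.frame"))
}

#' Read a DRP table from a CSV/TSV file
#'
#' @param path file with header columns `id`, `drp`, `reliability`
#'   (optionally `trait`).
#' @return a [drp_table()] with derived weights.
#' @export
read_drp <- function(path) {
  drp_table(read_delim_auto(path))
}

#' @rdname read_drp
#' @param drp a `drp_table` to write (the derived weight column is not
#'   written; it is recomputed on read).
#' @export
write_drp <- function(drp, path) {
  out <- as.data.frame(drp)
  out$weight <- NULL
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

read_delim_auto <- function(path) {
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  utils::read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
                    colClasses = NA, comment.char = "")
}
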