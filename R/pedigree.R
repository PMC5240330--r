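## Pedigree container, numerator relationship matrix (tabular method),
## inbreeding coefficients and the block partition used by single-step methods.

#' Construct and validate a pedigree
#'
#' A pedigree is a data frame with integer columns `id`, `sire`, `dam`
#' (0 denotes an unknown parent) and optional `generation` and `sex` columns,
#' sorted so that every known parent appears before its offspring.
#'
#' @param records data frame with at least `id`, `sire`, `dam`.
#' @return the validated records with class `"pedigree"` prepended.
#' @examples
#' ped <- as_pedigree(data.frame(id = 1:3, sire = c(0, 0, 1), dam = c(0, 0, 2)))
#' @export
as_pedigree <- function(records) {
  req <- c("id", "sire", "dam")
  if (!all(req %in% names(records))) {
    stop("pedigree records need columns 'id', 'sire', 'dam'")
  }
  records$id <- as.integer(records$id)
  records$sire <- as.integer(records$sire)
  records$dam <- as.integer(records$dam)
  if (anyDuplicated(records$id)) stop("pedigree IDs must be unique")
  if (any(records$id == 0L)) stop("0 is reserved for unknown parents")
  pos <- match(records$id, records$id)  # identity, used via lookup below
  idx_of <- function(x) match(x, records$id)
  n <- nrow(records)
  for (col in c("sire", "dam")) {
    p <- records[[col]]
    known <- p != 0L
    at <- idx_of(p[known])
    if (anyNA(at)) {
      stop(sprintf("unknown %s ID(s): %s", col,
                   paste(utils::head(p[known][is.na(at)], 5L), collapse = ", ")))
    }
    if (any(at >= seq_len(n)[known])) {
      stop("pedigree is not sorted parents-first (refusing to re-sort)")
    }
  }
  both <- records$sire != 0L & records$sire == records$dam
  if (any(both)) stop("an animal cannot be both sire and dam of the same offspring")
  class(records) <- unique(c("pedigree", class(records)))
  records
}

#' @export
print.pedigree <- function(x, ...) {
  cat(sprintf("pedigree: %d animals, %d founders\n",
              nrow(x), sum(x$sire == 0L & x$dam == 0L)))
  NextMethod()
}

#' Numerator relationship matrix by the tabular method
#'
#' Builds the additive (numerator) relationship matrix A over all pedigree
#' animals with the recursive tabular rules: `a_ii = 1 + 0.5 a_{s(i),d(i)}`
#' and `a_ij = 0.5 (a_{j,s(i)} + a_{j,d(i)})` for `j` preceding `i`; unknown
#' parents contribute 0 (founders are taken as unrelated and non-inbred).
#'
#' @param pedigree a [as_pedigree()] object.
#' @return symmetric matrix with animal IDs as dimnames and attribute
#'   `kind = "NRM"`. Diagonal elements equal one plus the inbreeding
#'   coefficient.
#' @seealso [inbreeding()], [partition_nrm()]
#' @export
build_nrm <- function(pedigree) {
  pedigree <- as_pedigree(pedigree)
  n <- nrow(pedigree)
  ids <- pedigree$id
  si <- match(pedigree$sire, ids)  # NA for unknown
  di <- match(pedigree$dam, ids)
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    s <- si[i]; d <- di[i]
    asd <- if (!is.na(s) && !is.na(d)) A[s, d] else 0
    if (i > 1L) {
      j <- seq_len(i - 1L)
      v <- 0.5 * ((if (!is.na(s)) A[j, s] else 0) + (if (!is.na(d)) A[j, d] else 0))
      A[j, i] <- v
      A[i, j] <- v
    }
    A[i, i] <- 1 + 0.5 * asd
  }
  dimnames(A) <- list(ids, ids)
  attr(A, "kind") <- "NRM"
  A
}

#' Inbreeding coefficients
#'
#' `F_i = a_ii - 1` from the numerator relationship matrix; founders have 0.
#'
#' @inheritParams build_nrm
#' @return named numeric vector of inbreeding coefficients.
#' @export
inbreeding <- function(pedigree) {
  A <- build_nrm(pedigree)
  diag(A) - 1
}

#' Partition the relationship matrix into genotyped/non-genotyped blocks
#'
#' Extracts the blocks `A_gg`, `A_ng`, `A_gn`, `A_nn` needed by single-step
#' methods. Genotyped IDs keep the supplied order; non-genotyped IDs keep the
#' order of `A`.
#'
#' @param A relationship matrix with ID dimnames (from [build_nrm()]).
#' @param genotyped_ids vector of IDs present in `A`; must be non-empty.
#' @return an object of class `"nrm_partition"`: a list with the four blocks
#'   and the two ordered ID vectors.
#' @export
partition_nrm <- function(A, genotyped_ids) {
  ids <- rownames(A)
  if (is.null(ids)) stop("A must carry animal IDs as dimnames")
  genotyped_ids <- as.character(genotyped_ids)
  if (length(genotyped_ids) == 0L) {
    stop("single-step partitions require at least one genotyped animal")
  }
  at <- match(genotyped_ids, ids)
  if (anyNA(at)) {
    stop(sprintf("genotyped ID(s) not in A: %s",
                 paste(utils::head(genotyped_ids[is.na(at)], 5L), collapse = ", ")))
  }
  if (anyDuplicated(genotyped_ids)) stop("duplicated genotyped IDs")
  non <- ids[!(ids %in% genotyped_ids)]
  out <- list(
    A_gg = A[genotyped_ids, genotyped_ids, drop = FALSE],
    A_ng = A[non, genotyped_ids, drop = FALSE],
    A_gn = A[genotyped_ids, non, drop = FALSE],
    A_nn = A[non, non, drop = FALSE],
    genotyped_ids = genotyped_ids,
    nongenotyped_ids = non
  )
  class(out) <- "nrm_partition"
  out
}

#' @export
print.nrm_partition <- function(x, ...) {
  cat(sprintf("NRM partition: %d genotyped, %d non-genotyped animals\n",
              length(x$genotyped_ids), length(x$nongenotyped_ids)))
  invisible(x)
}

#' Read/write a pedigree CSV
#'
#' Columns `id,sire,dam[,generation][,sex]`, 0 meaning unknown parent; the
#' format written by [simulate_pedigree()].
#'
#' @param path file path.
#' @return `read_pedigree()` returns a [as_pedigree()] object.
#' @export
read_pedigree <- function(path) {
  as_pedigree(read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname read_pedigree
#' @param pedigree pedigree to write.
#' @export
write_pedigree <- function(pedigree, path) {
  write.csv(as.data.frame(pedigree), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
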