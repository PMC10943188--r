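# Uncorrected p-distances with pairwise deletion.
#
# For each pair of aligned sequences, only columns where *both* members carry
# an unambiguous base (A/C/G/T) are compared; the distance is the mismatch
# proportion over those columns. IUPAC partial ambiguities (R, Y, ...) are
# treated as missing, like N/-/?, consistent with the package-wide missing
# set. A pair with zero comparable columns has distance NA (flagged, not an
# error) and is excluded from downstream summaries.

#' p-distance between two aligned sequences
#'
#' @param a,b Aligned sequence strings of equal length.
#' @return A one-row tibble (`distance`, `n_compared`). `distance` is NA when
#'   no column is comparable.
#' @examples
#' p_distance("ACGT", "ACGA")  # 0.25 over 4 sites
#' p_distance("ACGN", "TCGA")  # 1/3 over 3 sites; column 4 deleted pairwise
#' @export
p_distance <- function(a, b) {
  if (nchar(a) != nchar(b)) abort("sequences have unequal lengths")
  x <- strsplit(toupper(a), "", fixed = TRUE)[[1]]
  y <- strsplit(toupper(b), "", fixed = TRUE)[[1]]
  ok <- x %in% BASES & y %in% BASES
  n <- sum(ok)
  tibble(distance = if (n == 0L) NA_real_ else sum(x[ok] != y[ok]) / n,
         n_compared = n)
}

#' Pairwise p-distance matrix with pairwise deletion
#'
#' Computes all pairwise uncorrected p-distances of a reference set, keeping
#' the per-pair compared-site counts. Internally the alignment is expanded
#' into per-base indicator matrices so the whole matrix is a handful of
#' matrix products.
#'
#' @param ref Reference-set tibble.
#' @return An object of class `p_dist`: list with `ids`, `d` (symmetric
#'   distance matrix, zero diagonal, NA where no sites are comparable) and
#'   `n_compared` (symmetric integer matrix of compared-site counts).
#'   `tidy()` gives the lower triangle in long form; `as.matrix()` and
#'   `as.dist()` extract `d`.
#' @export
distance_matrix <- function(ref) {
  check_ref(ref)
  m <- seq_char_matrix(ref)
  valid <- matrix(as.numeric(m %in% BASES), nrow = nrow(m))
  n_compared <- valid %*% t(valid)
  matches <- matrix(0, nrow(m), nrow(m))
  for (b in BASES) {
    ind <- matrix(as.numeric(m == b), nrow = nrow(m))
    matches <- matches + ind %*% t(ind)
  }
  d <- (n_compared - matches) / n_compared  # NaN where n_compared == 0
  d[n_compared == 0] <- NA_real_
  diag(d) <- 0
  storage.mode(n_compared) <- "integer"
  ids <- ref$specimen_id
  dimnames(d) <- dimnames(n_compared) <- list(ids, ids)
  structure(list(ids = ids, d = d, n_compared = n_compared), class = "p_dist")
}

#' @export
print.p_dist <- function(x, ...) {
  rng <- range(x$d[upper.tri(x$d)], na.rm = TRUE)
  cat("<p_dist> ", length(x$ids), " sequences; distance range ",
      sprintf("%.4f-%.4f", rng[1], rng[2]), "\n", sep = "")
  invisible(x)
}

#' @export
as.matrix.p_dist <- function(x, ...) x$d

#' @export
as.dist.p_dist <- function(m, ...) stats::as.dist(m$d)

#' @rdname distance_matrix
#' @param x A `p_dist` object.
#' @param ... Unused.
#' @return For `tidy()`: a tibble (`id1`, `id2`, `distance`, `n_compared`)
#'   over unordered pairs, `id1` before `id2` in input order.
#' @export
tidy.p_dist <- function(x, ...) {
  idx <- which(upper.tri(x$d), arr.ind = TRUE)
  tibble(
    id1 = x$ids[idx[, 1]],
    id2 = x$ids[idx[, 2]],
    distance = x$d[idx],
    n_compared = x$n_compared[idx]
  ) %>% dplyr::arrange(match(.data$id1, x$ids), match(.data$id2, x$ids))
}

#' Write a distance matrix as TSV
#'
#' @param dm A `p_dist` object.
#' @param matrix_path Optional path for the square matrix (ids as header
#'   row and first column).
#' @param long_path Optional path for the long format
#'   (`id1`, `id2`, `distance`, `n_compared`).
#' @return `dm`, invisibly.
#' @export
write_distance_matrix <- function(dm, matrix_path = NULL, long_path = NULL) {
  stopifnot(inherits(dm, "p_dist"))
  if (!is.null(matrix_path)) {
    sq <- as_tibble(dm$d, rownames = "specimen_id")
    readr::write_tsv(sq, matrix_path, progress = FALSE)
  }
  if (!is.null(long_path)) {
    readr::write_tsv(tidy(dm), long_path, progress = FALSE)
  }
  invisible(dm)
}
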