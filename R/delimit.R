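# Distance-threshold MOTU delimitation.
#
# Single-linkage clustering at every informative threshold in a prior range,
# scored by the width of the local barcoding gap: gap_score(t) is the
# minimum over resulting clusters of (NN distance - max intra distance),
# singletons contributing intra_max = 0. Single linkage mirrors
# threshold-based barcode clustering and guarantees that the number of
# groups is non-increasing in the threshold, so the scan is monotone and
# each partition refines all coarser ones. This is a deliberate
# simplification of recursive-partitioning delimiters such as ASAP/ABGD:
# their composite score is replaced by the directly testable gap width.

#' Candidate thresholds for a delimitation scan
#'
#' Midpoints between consecutive distinct pairwise distance values,
#' restricted to `[lo, hi]`, plus `lo` and `hi` themselves; deduplicated,
#' ascending. Undefined distances are ignored.
#'
#' @param dm A `p_dist` object.
#' @param lo,hi Prior threshold range as proportions (defaults 0.005, 0.05).
#' @return Ascending numeric vector of thresholds.
#' @export
candidate_thresholds <- function(dm, lo = 0.005, hi = 0.05) {
  stopifnot(inherits(dm, "p_dist"))
  if (!(lo < hi)) abort("lo must be < hi")
  if (length(dm$ids) == 0L) return(numeric(0))
  v <- sort(unique(dm$d[upper.tri(dm$d)]))
  v <- v[!is.na(v)]
  mids <- if (length(v) > 1L) (v[-1] + v[-length(v)]) / 2 else numeric(0)
  sort(unique(c(lo, hi, mids[mids >= lo & mids <= hi])))
}

#' Delimit MOTUs by a single-linkage threshold scan
#'
#' For each candidate threshold `t`, sequences are clustered by single
#' linkage (i and j linked whenever some chain of pairwise distances
#' `<= t` connects them) and the partition is scored by its narrowest local
#' barcoding gap. The selected partition maximises the gap score; ties are
#' broken toward fewer groups, then toward the smaller threshold. Pairs
#' with undefined distance are treated as farther than `hi` (never linked).
#' Partitions with a single group have no between-cluster distance and
#' score `-Inf`.
#'
#' @inheritParams candidate_thresholds
#' @return An object of class `threshold_scan`: list with `scan` (tibble
#'   `threshold`, `n_groups`, `gap_score`), `selected_threshold`,
#'   `partition` (tibble `specimen_id`, `motu`) and `n_motus`. `tidy()`
#'   returns the scan table, `glance()` a one-row summary, `autoplot()` the
#'   scan profile.
#' @export
delimit_motus <- function(dm, lo = 0.005, hi = 0.05) {
  stopifnot(inherits(dm, "p_dist"))
  thresholds <- candidate_thresholds(dm, lo, hi)
  if (length(thresholds) == 0L) abort("no candidate thresholds")
  n <- length(dm$ids)

  d <- dm$d
  big <- hi + 1  # undefined pairs: never linked within the scan range
  d[is.na(d)] <- big

  if (n == 1L) {
    memb <- matrix(1L, nrow = 1L, dimnames = list(dm$ids, NULL))
    memb <- memb[, rep(1L, length(thresholds)), drop = FALSE]
  } else {
    tree <- stats::hclust(stats::as.dist(d), method = "single")
    memb <- stats::cutree(tree, h = thresholds)
    if (is.null(dim(memb))) memb <- matrix(memb, ncol = 1L,
                                           dimnames = list(dm$ids, NULL))
  }

  score_partition <- function(labels) {
    if (length(unique(labels)) < 2L) return(-Inf)
    min(vapply(unique(labels), function(cl) {
      inside <- labels == cl
      di <- d[inside, inside, drop = FALSE]
      intra_max <- if (sum(inside) > 1L) max(di[upper.tri(di)]) else 0
      nn <- min(d[inside, !inside, drop = FALSE])
      nn - intra_max
    }, numeric(1)))
  }

  scan <- tibble(
    threshold = thresholds,
    n_groups = unname(apply(memb, 2, function(v) length(unique(v)))),
    gap_score = unname(apply(memb, 2, score_partition))
  )

  best <- which(
    scan$gap_score == max(scan$gap_score) &
      scan$n_groups == min(scan$n_groups[scan$gap_score == max(scan$gap_score)])
  )[1]
  labels <- memb[, best]
  # stable MOTU names: number groups by first appearance in input order
  first_seen <- unique(labels)
  motu <- sprintf("MOTU_%03d", match(labels, first_seen))
  structure(
    list(scan = scan,
         selected_threshold = scan$threshold[best],
         partition = tibble(specimen_id = dm$ids, motu = motu),
         n_motus = scan$n_groups[best]),
    class = "threshold_scan"
  )
}

#' @export
print.threshold_scan <- function(x, ...) {
  cat("<threshold_scan> ", nrow(x$scan), " thresholds in [",
      min(x$scan$threshold), ", ", max(x$scan$threshold), "]; selected t = ",
      x$selected_threshold, " -> ", x$n_motus, " MOTUs\n", sep = "")
  invisible(x)
}

#' @rdname delimit_motus
#' @param x A `threshold_scan` object.
#' @param ... Unused.
#' @export
tidy.threshold_scan <- function(x, ...) x$scan

#' @rdname delimit_motus
#' @export
glance.threshold_scan <- function(x, ...) {
  tibble(selected_threshold = x$selected_threshold,
         n_motus = x$n_motus,
         gap_score = x$scan$gap_score[x$scan$threshold == x$selected_threshold][1],
         n_thresholds = nrow(x$scan))
}

#' @rdname delimit_motus
#' @param object A `threshold_scan` object.
#' @export
autoplot.threshold_scan <- function(object, ...) {
  df <- object$scan %>%
    tidyr::pivot_longer(c("n_groups", "gap_score"),
                        names_to = "metric", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$threshold, y = .data$value)) +
    ggplot2::geom_step() +
    ggplot2::geom_vline(xintercept = object$selected_threshold,
                        linetype = "dashed", colour = "firebrick") +
    ggplot2::facet_wrap(~metric, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "distance threshold", y = NULL) +
    ggplot2::theme_minimal()
}

#' Compare two partitions of the same specimens
#'
#' Thin adapter over [classify_congruence()]: `q`'s groups play the role of
#' barcode clusters and `p`'s groups the role of species names.
#'
#' @param p Reference partition (e.g. morphological species).
#' @param q Partition under evaluation (e.g. MOTUs).
#' @param p_col,q_col Label columns when `p`/`q` are data frames.
#' @return A `congruence` object (see [classify_congruence()]).
#' @export
compare_partitions <- function(p, q, p_col = "species", q_col = "motu") {
  classify_congruence(as_partition(p, p_col), as_partition(q, q_col))
}
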