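# Per-cluster divergence audit: intra-cluster distance summaries, nearest
# neighbour (NN) identification, and the local barcoding-gap test
# (intra_max < distance to NN).

#' Audit clusters against a distance matrix
#'
#' For every cluster: the number of sequences, min/mean/max intra-cluster
#' p-distance (NA for singletons), the nearest-neighbour cluster (the other
#' cluster holding the closest sequence; ties broken by cluster name), its
#' distance, and the local barcoding-gap flag. The gap test uses strict
#' inequality `intra_max < nn_distance`; singletons are evaluated with
#' `intra_max` taken as 0, so they show a gap whenever their NN distance is
#' positive. Pairs with undefined distance (no comparable sites) are dropped
#' from every min/mean/max with a warning stating how many were dropped.
#'
#' @param dm A `p_dist` object from [distance_matrix()].
#' @param partition Cluster assignment: a data frame with columns
#'   `specimen_id` and a label column (default name `cluster`), or a vector
#'   named by specimen_id. Every id in `dm` must be assigned.
#' @param cluster_col Name of the label column when `partition` is a data
#'   frame.
#' @param ref Optional reference-set tibble; when given, per-cluster
#'   haplotype counts (ambiguity-tolerant policy) are added.
#' @return A tibble with one row per cluster, ordered by cluster label:
#'   `cluster`, `n_sequences`, (`n_haplotypes`,) `intra_min`, `intra_mean`,
#'   `intra_max`, `nn_cluster`, `nn_distance`, `has_gap`.
#' @export
audit_clusters <- function(dm, partition, cluster_col = "cluster", ref = NULL) {
  stopifnot(inherits(dm, "p_dist"))
  grp <- as_partition(partition, label_col = cluster_col)
  missing_ids <- setdiff(dm$ids, grp$specimen_id)
  if (length(missing_ids)) {
    abort(paste0("ids without a cluster assignment: ",
                 paste(missing_ids, collapse = ", ")))
  }
  labels <- setNames(grp$label, grp$specimen_id)[dm$ids]
  clusters <- sort(unique(labels))
  d <- dm$d

  n_undef <- sum(is.na(d[upper.tri(d)]))
  if (n_undef > 0) {
    warn(paste0(n_undef, " sequence pair(s) with no comparable sites ",
                "excluded from distance summaries"))
  }

  rows <- purrr::map(clusters, function(cl) {
    inside <- labels == cl
    di <- d[inside, inside, drop = FALSE]
    intra <- di[upper.tri(di)]
    intra <- intra[!is.na(intra)]
    has_intra <- length(intra) > 0L
    dx <- d[inside, !inside, drop = FALSE]
    out_labels <- labels[!inside]
    if (length(out_labels)) {
      # min distance to each other cluster, then the NN among them
      per_cluster_min <- vapply(split(seq_along(out_labels), out_labels),
                                function(j) {
                                  v <- dx[, j, drop = FALSE]
                                  if (all(is.na(v))) NA_real_ else min(v, na.rm = TRUE)
                                }, numeric(1))
      if (all(is.na(per_cluster_min))) {
        nn_cluster <- NA_character_; nn_distance <- NA_real_
      } else {
        nn_distance <- min(per_cluster_min, na.rm = TRUE)
        # ties broken by lexicographic cluster name (names are sorted by split)
        nn_cluster <- names(per_cluster_min)[which(per_cluster_min == nn_distance)[1]]
      }
    } else {
      nn_cluster <- NA_character_; nn_distance <- NA_real_
    }
    intra_max <- if (has_intra) max(intra) else NA_real_
    tibble(
      cluster = cl,
      n_sequences = sum(inside),
      intra_min = if (has_intra) min(intra) else NA_real_,
      intra_mean = if (has_intra) mean(intra) else NA_real_,
      intra_max = intra_max,
      nn_cluster = nn_cluster,
      nn_distance = nn_distance,
      # singleton / undefined intra treated as 0 so singletons are evaluable
      has_gap = if (is.na(nn_distance)) NA else
        (if (is.na(intra_max)) 0 else intra_max) < nn_distance
    )
  })
  out <- dplyr::bind_rows(rows)

  if (!is.null(ref)) {
    check_ref(ref)
    hap <- collapse_haplotypes(ref) %>%
      dplyr::left_join(grp, by = "specimen_id") %>%
      dplyr::group_by(cluster = .data$label) %>%
      dplyr::summarise(n_haplotypes = dplyr::n_distinct(.data$haplotype_id),
                       .groups = "drop")
    out <- dplyr::left_join(out, hap, by = "cluster") %>%
      dplyr::relocate("n_haplotypes", .after = "n_sequences")
  }
  out
}

#' Summarise an audit: pooled divergence means and per-group breakdown
#'
#' Overall means pool all pairwise distances (not means of per-cluster
#' means): `overall_mean_intra` over every defined within-cluster pair and
#' `overall_mean_inter` over every defined between-cluster pair. The
#' "mean range" reported for between-cluster divergence is the range of
#' per-cluster-pair mean distances. When a grouping (e.g. family) is given,
#' the same statistics are computed within each group, over pairs whose two
#' members both belong to the group.
#'
#' @param audits Output of [audit_clusters()].
#' @param dm The `p_dist` object the audit was computed from.
#' @param partition The cluster assignment used for the audit.
#' @param cluster_col Label column name, as in [audit_clusters()].
#' @param groups Optional grouping: data frame (`specimen_id`, group label)
#'   or named vector, e.g. family membership.
#' @param group_col Label column name when `groups` is a data frame.
#' @return An object of class `audit_summary`: list with `overall` (one-row
#'   tibble), `by_group` (tibble or NULL), `pair_means` (per cluster-pair
#'   mean distances) and `clusters` (the audit rows). `tidy()` returns the
#'   audit rows, `glance()` the overall row.
#' @export
summarize_audit <- function(audits, dm, partition, cluster_col = "cluster",
                            groups = NULL, group_col = "family") {
  stopifnot(inherits(dm, "p_dist"))
  grp <- as_partition(partition, label_col = cluster_col)
  labels <- setNames(grp$label, grp$specimen_id)[dm$ids]

  long <- tidy(dm) %>%
    dplyr::mutate(cluster1 = unname(labels[.data$id1]),
                  cluster2 = unname(labels[.data$id2]),
                  intra = .data$cluster1 == .data$cluster2) %>%
    dplyr::filter(!is.na(.data$distance))

  inter <- dplyr::filter(long, !.data$intra)
  pair_means <- inter %>%
    dplyr::mutate(ca = pmin(.data$cluster1, .data$cluster2),
                  cb = pmax(.data$cluster1, .data$cluster2)) %>%
    dplyr::group_by(.data$ca, .data$cb) %>%
    dplyr::summarise(mean_distance = mean(.data$distance), .groups = "drop") %>%
    dplyr::rename(cluster_a = "ca", cluster_b = "cb") %>%
    dplyr::arrange(.data$cluster_a, .data$cluster_b)

  summarise_block <- function(long_block, audit_block) {
    intra_d <- long_block$distance[long_block$intra]
    inter_d <- long_block$distance[!long_block$intra]
    pm <- long_block %>%
      dplyr::filter(!.data$intra) %>%
      dplyr::mutate(ca = pmin(.data$cluster1, .data$cluster2),
                    cb = pmax(.data$cluster1, .data$cluster2)) %>%
      dplyr::group_by(.data$ca, .data$cb) %>%
      dplyr::summarise(m = mean(.data$distance), .groups = "drop")
    tibble(
      n_clusters = nrow(audit_block),
      n_gap = sum(audit_block$has_gap, na.rm = TRUE),
      pct_gap = 100 * sum(audit_block$has_gap, na.rm = TRUE) / nrow(audit_block),
      mean_intra = if (length(intra_d)) mean(intra_d) else NA_real_,
      max_intra = if (length(intra_d)) max(intra_d) else NA_real_,
      mean_inter = if (length(inter_d)) mean(inter_d) else NA_real_,
      inter_pair_mean_min = if (nrow(pm)) min(pm$m) else NA_real_,
      inter_pair_mean_max = if (nrow(pm)) max(pm$m) else NA_real_
    )
  }

  overall <- summarise_block(long, audits)

  by_group <- NULL
  if (!is.null(groups)) {
    gmap <- as_partition(groups, label_col = group_col)
    gl <- setNames(gmap$label, gmap$specimen_id)
    cluster_group <- grp %>%
      dplyr::mutate(group = unname(gl[.data$specimen_id])) %>%
      dplyr::distinct(.data$label, .data$group)
    dup <- cluster_group$label[duplicated(cluster_group$label)]
    if (length(dup)) {
      warn(paste0("cluster(s) spanning multiple groups: ",
                  paste(unique(dup), collapse = ", ")))
    }
    by_group <- purrr::map(sort(unique(gmap$label)), function(g) {
      in_g <- names(gl)[gl == g]
      lb <- dplyr::filter(long, .data$id1 %in% in_g, .data$id2 %in% in_g)
      ab <- dplyr::filter(audits, .data$cluster %in%
                            cluster_group$label[cluster_group$group == g])
      dplyr::bind_cols(tibble(group = g), summarise_block(lb, ab))
    }) %>% dplyr::bind_rows()
  }

  structure(list(overall = overall, by_group = by_group,
                 pair_means = pair_means, clusters = audits),
            class = "audit_summary")
}

#' @export
print.audit_summary <- function(x, ...) {
  o <- x$overall
  cat("<audit_summary> ", o$n_clusters, " clusters; gap in ", o$n_gap,
      sprintf(" (%.1f%%); mean intra %.1f%%, mean inter %.1f%%\n",
              o$pct_gap, 100 * o$mean_intra, 100 * o$mean_inter), sep = "")
  invisible(x)
}

#' @rdname summarize_audit
#' @param x An `audit_summary` object.
#' @param ... Unused.
#' @export
tidy.audit_summary <- function(x, ...) x$clusters

#' @rdname summarize_audit
#' @export
glance.audit_summary <- function(x, ...) x$overall

#' Barcoding-gap scatter plot
#'
#' Maximum intra-cluster distance against the distance to the nearest
#' neighbour, one point per cluster. Points above the identity line show a
#' local barcoding gap; points on or below it overlap.
#'
#' @param audits Output of [audit_clusters()] (or an `audit_summary`).
#' @return A ggplot object.
#' @export
plot_barcoding_gap <- function(audits) {
  if (inherits(audits, "audit_summary")) audits <- audits$clusters
  df <- audits %>%
    dplyr::mutate(intra_max_eval = dplyr::coalesce(.data$intra_max, 0)) %>%
    dplyr::filter(!is.na(.data$nn_distance))
  ggplot2::ggplot(df, ggplot2::aes(x = 100 * .data$intra_max_eval,
                                   y = 100 * .data$nn_distance,
                                   colour = .data$has_gap)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey50") +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::labs(x = "max intra-cluster distance (%)",
                  y = "distance to nearest neighbour (%)",
                  colour = "barcoding gap") +
    ggplot2::theme_minimal()
}
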