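# Morphology-vs-cluster congruence: classify each barcode cluster by the
# species names of its members.
#
# Let S(c) be the species names inside cluster c, and call a species "split"
# when its (analysed) members occupy two or more clusters. Then:
#   match: |S(c)| = 1 and that species is not split
#   lump:  |S(c)| >= 2 and none of them is split
#   split: |S(c)| = 1 and that species is split
#   both:  |S(c)| >= 2 and at least one of them is split
# The categories are mutually exclusive and exhaustive. Exclusions (e.g.
# morphologically ambiguous larvae or females) are removed before anything
# is computed, so a species' split status is judged on the analysed ids
# only; a cluster whose members are all excluded is reported as "excluded".

#' Classify congruence between species names and barcode clusters
#'
#' @param species Partition giving each specimen its (morphological) species
#'   name: data frame (`specimen_id` + label column) or named vector.
#' @param clusters Partition giving each specimen its barcode-cluster label.
#'   Must cover the same specimen ids as `species`.
#' @param exclude_ids Optional character vector of specimen ids to drop
#'   before classification. Specimens with an empty or missing species name
#'   are dropped automatically with a warning.
#' @param species_col,cluster_col Label column names for data-frame input.
#' @return An object of class `congruence`: list with `per_cluster` (tibble
#'   `cluster`, `n_sequences`, `n_species`, `species` (names, comma-joined),
#'   `category`), `counts` (tibble `category`, `n`, `pct`), and
#'   `n_excluded`. `tidy()` returns `per_cluster`, `glance()` the counts in
#'   one row.
#' @examples
#' sp <- c(a = "s1", b = "s1", c = "s2")
#' cl <- c(a = "K1", b = "K1", c = "K2")
#' classify_congruence(sp, cl)  # both clusters match
#' @export
classify_congruence <- function(species, clusters, exclude_ids = NULL,
                                species_col = "species",
                                cluster_col = "cluster") {
  sp <- as_partition2(species, species_col, allow_empty = TRUE)
  cl <- as_partition(clusters, cluster_col)
  if (!setequal(sp$specimen_id, cl$specimen_id)) {
    off <- c(setdiff(sp$specimen_id, cl$specimen_id),
             setdiff(cl$specimen_id, sp$specimen_id))
    abort(paste0("species and cluster partitions cover different ids: ",
                 paste(head(off, 10), collapse = ", ")))
  }
  df <- dplyr::inner_join(
    dplyr::rename(sp, species = "label"),
    dplyr::rename(cl, cluster = "label"),
    by = "specimen_id"
  )

  unnamed <- is.na(df$species) | !nzchar(df$species)
  if (any(unnamed)) {
    warn(paste0(sum(unnamed), " specimen(s) without a species name ",
                "excluded from the congruence assessment"))
  }
  drop <- unnamed | df$specimen_id %in% exclude_ids
  all_clusters <- sort(unique(df$cluster))
  n_excluded <- sum(drop)
  kept <- df[!drop, , drop = FALSE]

  split_species <- kept %>%
    dplyr::distinct(.data$species, .data$cluster) %>%
    dplyr::count(.data$species) %>%
    dplyr::filter(.data$n >= 2L) %>%
    dplyr::pull(.data$species)

  per_cluster <- kept %>%
    dplyr::group_by(.data$cluster) %>%
    dplyr::summarise(
      n_sequences = dplyr::n(),
      n_species = dplyr::n_distinct(.data$species),
      any_split = any(.data$species %in% split_species),
      species = paste(sort(unique(.data$species)), collapse = ","),
      .groups = "drop"
    ) %>%
    dplyr::mutate(category = dplyr::case_when(
      .data$n_species == 1L & !.data$any_split ~ "match",
      .data$n_species >= 2L & !.data$any_split ~ "lump",
      .data$n_species == 1L & .data$any_split ~ "split",
      TRUE ~ "both"
    )) %>%
    dplyr::select(-"any_split")

  emptied <- setdiff(all_clusters, per_cluster$cluster)
  if (length(emptied)) {
    per_cluster <- dplyr::bind_rows(
      per_cluster,
      tibble(cluster = emptied, n_sequences = 0L, n_species = 0L,
             species = "", category = "excluded")
    )
  }
  per_cluster <- dplyr::arrange(per_cluster, .data$cluster)

  cats <- c("match", "lump", "split", "both", "excluded")
  counts <- per_cluster %>%
    dplyr::count(category = factor(.data$category, levels = cats),
                 .drop = FALSE, name = "n") %>%
    dplyr::mutate(category = as.character(.data$category),
                  pct = 100 * .data$n / nrow(per_cluster))

  structure(list(per_cluster = per_cluster, counts = counts,
                 n_excluded = n_excluded),
            class = "congruence")
}

# as_partition but optionally tolerating empty/NA labels (species side).
as_partition2 <- function(x, label_col, allow_empty = FALSE) {
  if (!allow_empty) return(as_partition(x, label_col))
  if (is.data.frame(x)) {
    if (!"specimen_id" %in% names(x)) {
      abort("partition data frame needs a 'specimen_id' column")
    }
    if (!label_col %in% names(x)) {
      other <- setdiff(names(x), "specimen_id")
      if (length(other) == 1L) label_col <- other
      else abort(paste0("no column '", label_col, "' in partition"))
    }
    out <- tibble(specimen_id = as.character(x$specimen_id),
                  label = as.character(x[[label_col]]))
  } else {
    if (is.null(names(x))) abort("partition vector must be named by specimen_id")
    out <- tibble(specimen_id = names(x), label = as.character(unname(x)))
  }
  if (anyDuplicated(out$specimen_id)) {
    abort("partition assigns some specimen_id more than once")
  }
  out
}

#' @export
print.congruence <- function(x, ...) {
  n <- sum(x$counts$n)
  cat("<congruence> ", n, " clusters: ",
      paste(sprintf("%s %d", x$counts$category, x$counts$n), collapse = ", "),
      "; ", x$n_excluded, " specimen(s) excluded\n", sep = "")
  invisible(x)
}

#' @rdname classify_congruence
#' @param x A `congruence` object.
#' @param ... Unused.
#' @export
tidy.congruence <- function(x, ...) x$per_cluster

#' @rdname classify_congruence
#' @export
glance.congruence <- function(x, ...) {
  wide <- x$counts %>%
    dplyr::select("category", "n") %>%
    tidyr::pivot_wider(names_from = "category", values_from = "n",
                       names_prefix = "n_")
  dplyr::bind_cols(tibble(n_clusters = sum(x$counts$n)), wide,
                   tibble(n_excluded_specimens = x$n_excluded))
}

#' Congruence counts table
#'
#' Counts and percentages (computed on the classified clusters) per
#' category; optionally broken down by a grouping of specimens (e.g.
#' family).
#'
#' @param result A `congruence` object.
#' @param groups Optional specimen grouping (data frame or named vector);
#'   each cluster is attributed to the group of its members (warned if
#'   mixed, majority wins, ties by name).
#' @param group_col Label column when `groups` is a data frame.
#' @param clusters Required with `groups`: the cluster partition used for
#'   classification.
#' @param cluster_col Label column when `clusters` is a data frame.
#' @return A tibble of counts: one row per category (and group).
#' @export
congruence_table <- function(result, groups = NULL, group_col = "family",
                             clusters = NULL, cluster_col = "cluster") {
  stopifnot(inherits(result, "congruence"))
  if (is.null(groups)) {
    return(dplyr::mutate(result$counts, pct = round(.data$pct, 1)))
  }
  if (is.null(clusters)) abort("groups requires the cluster partition too")
  gmap <- as_partition(groups, group_col)
  cl <- as_partition(clusters, cluster_col)
  cluster_group <- dplyr::inner_join(cl, gmap, by = "specimen_id",
                                     suffix = c(".cl", ".g")) %>%
    dplyr::count(cluster = .data$label.cl, group = .data$label.g) %>%
    dplyr::group_by(.data$cluster) %>%
    dplyr::arrange(dplyr::desc(.data$n), .data$group, .by_group = TRUE) %>%
    dplyr::slice(1) %>%
    dplyr::ungroup() %>%
    dplyr::select("cluster", "group")
  result$per_cluster %>%
    dplyr::left_join(cluster_group, by = "cluster") %>%
    dplyr::count(.data$group, .data$category, name = "n") %>%
    dplyr::group_by(.data$group) %>%
    dplyr::mutate(pct = round(100 * .data$n / sum(.data$n), 1)) %>%
    dplyr::ungroup() %>%
    dplyr::arrange(.data$group, .data$category)
}

#' Congruence category bar chart
#'
#' @param result A `congruence` object.
#' @return A ggplot object.
#' @export
plot_congruence <- function(result) {
  stopifnot(inherits(result, "congruence"))
  df <- dplyr::filter(result$counts, .data$n > 0)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$category, y = .data$n)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%d (%.1f%%)", .data$n,
                                                    .data$pct)),
                       vjust = -0.4, size = 3) +
    ggplot2::labs(x = NULL, y = "clusters") +
    ggplot2::theme_minimal()
}
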