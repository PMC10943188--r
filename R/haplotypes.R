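# Collapsing a library to unique haplotypes.

#' Collapse a reference set to unique haplotypes
#'
#' Groups records whose aligned sequences are identical under the chosen
#' policy. `"strict"` requires equality at every column. The default,
#' `"ambiguity_tolerant"`, treats missing/ambiguous symbols (anything outside
#' A/C/G/T) as matching anything: two sequences are compatible when no column
#' holds two *different* unambiguous bases. Compatibility is not transitive
#' ("ANG" is compatible with both "AAG" and "ACG", which conflict), so
#' grouping is greedy in record order: each record joins the first existing
#' haplotype whose *every* member it is compatible with, else founds a new
#' one. This keeps members pairwise identical under the policy and makes the
#' result deterministic. The haplotype id is the representative's
#' `specimen_id` (its first member in record order).
#'
#' @param ref Reference-set tibble.
#' @param policy `"ambiguity_tolerant"` (default) or `"strict"`.
#' @return A tibble (`specimen_id`, `haplotype_id`) with one row per input
#'   record, in input order.
#' @examples
#' ref <- tibble::tibble(specimen_id = c("a", "b"), sequence = c("ACGT", "ACGN"))
#' collapse_haplotypes(ref)                    # 1 haplotype
#' collapse_haplotypes(ref, policy = "strict") # 2 haplotypes
#' @export
collapse_haplotypes <- function(ref, policy = c("ambiguity_tolerant", "strict")) {
  check_ref(ref)
  policy <- match.arg(policy)
  n <- nrow(ref)

  if (policy == "strict") {
    first <- match(ref$sequence, ref$sequence)
    return(tibble(specimen_id = ref$specimen_id,
                  haplotype_id = ref$specimen_id[first]))
  }

  m <- seq_char_matrix(ref)
  known <- m %in% BASES
  dim(known) <- dim(m)

  compatible <- function(i, j) {
    both <- known[i, ] & known[j, ]
    !any(m[i, both] != m[j, both])
  }

  # haplotypes: list of integer member vectors, in founding order
  haps <- list()
  assignment <- integer(n)
  for (i in seq_len(n)) {
    placed <- FALSE
    for (h in seq_along(haps)) {
      if (all(vapply(haps[[h]], function(j) compatible(i, j), logical(1)))) {
        haps[[h]] <- c(haps[[h]], i)
        assignment[i] <- h
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      haps[[length(haps) + 1L]] <- i
      assignment[i] <- length(haps)
    }
  }
  reps <- ref$specimen_id[vapply(haps, `[`, integer(1), 1L)]
  tibble(specimen_id = ref$specimen_id, haplotype_id = reps[assignment])
}

#' Count haplotypes per group
#'
#' Applies [collapse_haplotypes()] independently within each level of a
#' metadata column (e.g. `family`).
#'
#' @param ref Reference-set tibble.
#' @param group_column Name of the grouping column.
#' @inheritParams collapse_haplotypes
#' @return A tibble (`group`, `n_sequences`, `n_haplotypes`), ordered by
#'   group name.
#' @export
haplotypes_by_group <- function(ref, group_column,
                                policy = c("ambiguity_tolerant", "strict")) {
  check_ref(ref)
  policy <- match.arg(policy)
  if (!group_column %in% names(ref)) {
    abort(paste0("no column '", group_column, "' in reference set"))
  }
  ref %>%
    dplyr::group_by(group = .data[[group_column]]) %>%
    dplyr::group_modify(function(d, key) {
      h <- collapse_haplotypes(dplyr::mutate(d, specimen_id = .data$specimen_id),
                               policy = policy)
      tibble(n_sequences = nrow(d),
             n_haplotypes = dplyr::n_distinct(h$haplotype_id))
    }) %>%
    dplyr::ungroup() %>%
    dplyr::arrange(.data$group)
}
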