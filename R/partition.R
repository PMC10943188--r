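# Partitions: labellings of specimens into named groups (morphological
# species, a-priori barcode clusters, or MOTUs). Internally normalised to a
# two-column tibble (specimen_id, label).

#' Coerce to a partition tibble
#'
#' Accepts a data frame holding `specimen_id` plus a label column, or a
#' vector named by specimen id, and returns a tibble
#' (`specimen_id`, `label`).
#'
#' @param x Data frame or named vector.
#' @param label_col Which column carries the label when `x` is a data frame.
#'   Ignored for vectors. If `label_col` is missing from `x` but `x` has
#'   exactly two columns, the non-id column is used.
#' @return A tibble (`specimen_id`, `label`), labels as character.
#' @export
as_partition <- function(x, label_col = "cluster") {
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
  if (any(is.na(out$label) | !nzchar(out$label))) {
    abort("partition labels must be non-empty")
  }
  out
}
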