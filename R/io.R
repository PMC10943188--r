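# Reading, joining, validating and trimming the aligned barcode library.
#
# A reference set is an ordinary tibble with one row per specimen:
#   specimen_id (chr, unique), sequence (chr, aligned, uppercase), species
#   (chr), and optional metadata columns (cluster, family, sex, stage, ...).
# Every downstream function takes this tibble first, so calls chain with the
# pipe. Validation happens on entry to each consumer via check_ref().

# The unambiguous states. Everything else (IUPAC ambiguity codes, N, -, ?)
# counts as missing for site statistics, distances and haplotype collapsing:
# one convention shared by all stages.
BASES <- c("A", "C", "G", "T")

#' Read an aligned barcode library and its specimen metadata
#'
#' Joins an aligned FASTA to a tab-separated metadata table on `specimen_id`
#' and returns one tibble with the sequence attached to each specimen row.
#' Row order follows the metadata table.
#'
#' @param fasta_path Path to an aligned FASTA (wrapped or unwrapped). All
#'   sequences must have equal length. Symbols are uppercased on read;
#'   IUPAC ambiguity codes, `N`, `-` and `?` are allowed.
#' @param metadata_path Path to a TSV with a header row. Required columns:
#'   `specimen_id`, `species`. Recognised optional columns (`cluster`,
#'   `family`, `sex`, `stage`, ...) and any unknown columns are carried
#'   through untouched.
#' @param policy `"strict"` (default) requires the FASTA ids and metadata ids
#'   to match exactly; `"intersect"` keeps the common ids and drops the rest.
#'   Under both policies the FASTA may not contain duplicate ids.
#' @return A tibble with columns `specimen_id`, `sequence`, then the metadata
#'   columns in their original order.
#' @examples
#' fa <- system.file("extdata", "toy_barcodes.fasta", package = "refaudit")
#' tsv <- system.file("extdata", "toy_metadata.tsv", package = "refaudit")
#' read_reference_set(fa, tsv)
#' @export
read_reference_set <- function(fasta_path, metadata_path,
                               policy = c("strict", "intersect")) {
  policy <- match.arg(policy)
  if (!file.exists(fasta_path)) abort(paste0("FASTA not found: ", fasta_path))
  if (!file.exists(metadata_path)) abort(paste0("metadata not found: ", metadata_path))

  # BStringSet, not DNAStringSet: input may carry '?' which the DNA alphabet
  # rejects.
  seqs <- Biostrings::readBStringSet(fasta_path)
  if (length(seqs) == 0L) abort("empty FASTA: no sequences read")
  ids <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(ids)) {
    abort(paste0("duplicate FASTA ids: ",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  seq_chr <- toupper(as.character(seqs))
  names(seq_chr) <- ids

  meta <- readr::read_tsv(metadata_path, col_types = readr::cols(
    .default = readr::col_character()
  ), progress = FALSE)
  if (nrow(meta) == 0L) abort("empty metadata table")
  for (col in c("specimen_id", "species")) {
    if (!col %in% names(meta)) abort(paste0("metadata lacks required column '", col, "'"))
  }
  if (anyDuplicated(meta$specimen_id)) {
    abort(paste0("duplicate metadata specimen_ids: ",
                 paste(unique(meta$specimen_id[duplicated(meta$specimen_id)]),
                       collapse = ", ")))
  }

  missing_in_fasta <- setdiff(meta$specimen_id, ids)
  missing_in_meta <- setdiff(ids, meta$specimen_id)
  if (policy == "strict") {
    if (length(missing_in_fasta)) {
      abort(paste0("metadata ids absent from FASTA: ",
                   paste(missing_in_fasta, collapse = ", ")))
    }
    if (length(missing_in_meta)) {
      abort(paste0("FASTA ids absent from metadata: ",
                   paste(missing_in_meta, collapse = ", ")))
    }
  } else {
    meta <- dplyr::filter(meta, .data$specimen_id %in% ids)
    if (nrow(meta) == 0L) abort("no ids shared between FASTA and metadata")
  }

  ref <- meta %>%
    dplyr::mutate(sequence = unname(seq_chr[.data$specimen_id])) %>%
    dplyr::relocate("specimen_id", "sequence")
  check_ref(ref)
  ref
}

#' Write a reference set back to FASTA + TSV
#'
#' Inverse of [read_reference_set()]: `read_reference_set()` on the written
#' files reproduces the input tibble.
#'
#' @param ref Reference-set tibble.
#' @param fasta_path,metadata_path Output paths.
#' @param width Line width for FASTA wrapping (default 70).
#' @return `ref`, invisibly.
#' @export
write_reference_set <- function(ref, fasta_path, metadata_path, width = 70L) {
  check_ref(ref)
  x <- Biostrings::BStringSet(setNames(ref$sequence, ref$specimen_id))
  Biostrings::writeXStringSet(x, fasta_path, width = width)
  readr::write_tsv(dplyr::select(ref, -"sequence"), metadata_path, progress = FALSE)
  invisible(ref)
}

#' Trim an alignment to the barcode window
#'
#' Keeps alignment columns `[offset, offset + target_length)` (0-based,
#' half-open), the standard 658-bp Folmer window by default.
#'
#' @param ref Reference-set tibble.
#' @param target_length Window length in alignment columns (default 658).
#' @param offset 0-based start column of the window (default 0).
#' @return The reference set with all sequences exactly `target_length` long.
#' @export
trim_to_barcode <- function(ref, target_length = 658L, offset = 0L) {
  check_ref(ref)
  len <- nchar(ref$sequence[1])
  if (offset < 0L) abort("offset must be >= 0")
  if (len < offset + target_length) {
    abort(paste0("alignment has ", len, " columns; cannot take window [",
                 offset, ", ", offset + target_length, ")"))
  }
  dplyr::mutate(ref, sequence = substr(.data$sequence, offset + 1L,
                                       offset + target_length))
}

#' Alignment site statistics
#'
#' Counts variable and parsimony-informative columns and the overall missing
#' fraction. A column is variable when at least two distinct unambiguous
#' bases (A/C/G/T) occur in it, and parsimony-informative when at least two
#' such bases each occur in at least two sequences. Ambiguity codes, `N`,
#' `-` and `?` never count as states but do count toward `missing_fraction`
#' (missing cells over all cells).
#'
#' @param ref Reference-set tibble.
#' @return A one-row tibble: `n_sites`, `n_variable`,
#'   `n_parsimony_informative`, `missing_fraction`.
#' @export
site_statistics <- function(ref) {
  check_ref(ref)
  m <- seq_char_matrix(ref)
  base_counts <- vapply(BASES, function(b) colSums(m == b), numeric(ncol(m)))
  if (ncol(m) == 1L) base_counts <- matrix(base_counts, nrow = 1L)
  n_states <- rowSums(base_counts > 0L)
  n_states2 <- rowSums(base_counts >= 2L)
  tibble(
    n_sites = ncol(m),
    n_variable = sum(n_states >= 2L),
    n_parsimony_informative = sum(n_states2 >= 2L),
    missing_fraction = sum(!(m %in% BASES)) / length(m)
  )
}

#' Screen a reading frame for stop codons
#'
#' Translates each sequence in the given frame under the named genetic code
#' and counts stop codons. Under the invertebrate mitochondrial code the
#' stops are TAA and TAG (TGA codes for tryptophan, AGA/AGG for serine);
#' under the standard code TAA, TAG and TGA. Codons containing any
#' non-A/C/G/T symbol are skipped.
#'
#' @param ref Reference-set tibble (trimmed).
#' @param frame Frame offset 0, 1 or 2, or `"auto"` (default) to pick the
#'   frame minimising the total stop-codon count (ties: lowest frame).
#' @param genetic_code `"invertebrate_mitochondrial"` (default) or
#'   `"standard"`.
#' @return An object of class `frame_check`: a list with `frame`,
#'   `n_stop_codons`, and `offending`, a tibble of (`specimen_id`,
#'   `codon_index`) with 0-based codon indices. `tidy()` returns `offending`;
#'   `glance()` a one-row summary.
#' @export
check_stop_codons <- function(ref, frame = "auto",
                              genetic_code = c("invertebrate_mitochondrial",
                                               "standard")) {
  check_ref(ref)
  genetic_code <- match.arg(genetic_code)
  stops <- switch(genetic_code,
                  invertebrate_mitochondrial = c("TAA", "TAG"),
                  standard = c("TAA", "TAG", "TGA"))

  scan_frame <- function(f) {
    purrr::map(ref$specimen_id, function(id) {
      s <- ref$sequence[ref$specimen_id == id]
      n_codons <- (nchar(s) - f) %/% 3L
      if (n_codons <= 0L) return(integer(0))
      starts <- f + 3L * (seq_len(n_codons) - 1L) + 1L
      codons <- substring(s, starts, starts + 2L)
      which(codons %in% stops) - 1L
    }) %>% setNames(ref$specimen_id)
  }

  if (identical(frame, "auto")) {
    per_frame <- purrr::map(0:2, scan_frame)
    totals <- purrr::map_int(per_frame, ~ sum(lengths(.x)))
    frame <- which.min(totals) - 1L  # which.min takes the first minimum
    hits <- per_frame[[frame + 1L]]
  } else {
    frame <- as.integer(frame)
    if (!frame %in% 0:2) abort("frame must be 0, 1, 2 or \"auto\"")
    hits <- scan_frame(frame)
  }

  offending <- tibble(
    specimen_id = rep(names(hits), lengths(hits)),
    codon_index = as.integer(unlist(hits, use.names = FALSE))
  )
  structure(
    list(frame = frame, n_stop_codons = nrow(offending),
         offending = offending, genetic_code = genetic_code),
    class = "frame_check"
  )
}

#' @export
print.frame_check <- function(x, ...) {
  cat("<frame_check> frame ", x$frame, " (", x$genetic_code, "): ",
      x$n_stop_codons, " stop codon(s)\n", sep = "")
  invisible(x)
}

#' @rdname check_stop_codons
#' @param x A `frame_check` object.
#' @param ... Unused.
#' @export
tidy.frame_check <- function(x, ...) x$offending

#' @rdname check_stop_codons
#' @export
glance.frame_check <- function(x, ...) {
  tibble(frame = x$frame, n_stop_codons = x$n_stop_codons,
         n_offending_records = dplyr::n_distinct(x$offending$specimen_id),
         genetic_code = x$genetic_code)
}

# ---- internal helpers -------------------------------------------------------

# Assert the reference-set contract; returns invisibly.
check_ref <- function(ref, require_species = FALSE) {
  if (!is.data.frame(ref) || nrow(ref) == 0L) {
    abort("reference set must be a non-empty data frame")
  }
  for (col in c("specimen_id", "sequence")) {
    if (!col %in% names(ref)) abort(paste0("reference set lacks column '", col, "'"))
  }
  if (any(is.na(ref$specimen_id)) || any(!nzchar(ref$specimen_id))) {
    abort("specimen_id must be non-empty")
  }
  if (anyDuplicated(ref$specimen_id)) {
    abort(paste0("duplicate specimen_id: ",
                 paste(unique(ref$specimen_id[duplicated(ref$specimen_id)]),
                       collapse = ", ")))
  }
  lens <- nchar(ref$sequence)
  if (length(unique(lens)) != 1L) {
    abort("sequences are not aligned: unequal lengths")
  }
  if ("cluster" %in% names(ref) && "species" %in% names(ref)) {
    bad <- !is.na(ref$cluster) & (is.na(ref$species) | !nzchar(ref$species))
    if (any(bad)) {
      abort(paste0("records with a cluster label but no species label: ",
                   paste(ref$specimen_id[bad], collapse = ", ")))
    }
  }
  invisible(ref)
}

# Character matrix (n_records x n_sites), rownames = specimen_id.
seq_char_matrix <- function(ref) {
  m <- matrix(unlist(strsplit(ref$sequence, "", fixed = TRUE), use.names = FALSE),
              nrow = nrow(ref), byrow = TRUE)
  rownames(m) <- ref$specimen_id
  m
}
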