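# End-to-end audit: validate -> site stats / frame check -> collapse ->
# distances -> per-cluster audit -> MOTU delimitation -> congruence, bundled
# into one machine-readable report.

#' Run the full reference-library audit
#'
#' Executes every stage in fixed order on a reference set (either an
#' in-memory tibble or FASTA + TSV paths) and returns a single report. Any
#' stage failure aborts with the failing stage named.
#'
#' @param ref Reference-set tibble; or `NULL` to read from files.
#' @param fasta,metadata Input paths, used when `ref` is `NULL`.
#' @param cluster_col Metadata column with the a-priori cluster labels
#'   (default `"cluster"`). If absent, cluster-dependent stages are skipped.
#' @param species_col Metadata column with species names (default
#'   `"species"`).
#' @param group_col Optional metadata column for grouped summaries (default
#'   `"family"`, used only if present).
#' @param trim_length,trim_offset If `trim_length` is not `NULL`, the
#'   alignment is trimmed to `[trim_offset, trim_offset + trim_length)`
#'   first.
#' @param frame Reading frame for the stop-codon screen (default `"auto"`).
#' @param lo,hi Threshold range for MOTU delimitation (defaults 0.005,
#'   0.05).
#' @param exclude_ids Specimen ids excluded from the congruence assessment.
#' @param haplotype_policy Policy for [collapse_haplotypes()].
#' @param quiet Suppress stage progress messages (default TRUE).
#' @return An object of class `audit_report`: a list of blocks `dataset`,
#'   `distance`, `cluster`, `delimitation`, `congruence`, `provenance`.
#'   `glance()` gives a one-row overview; [write_audit_report()] writes the
#'   JSON + TSV bundle; [render_tables()] the human-readable tables.
#' @export
run_pipeline <- function(ref = NULL, fasta = NULL, metadata = NULL,
                         cluster_col = "cluster", species_col = "species",
                         group_col = "family",
                         trim_length = NULL, trim_offset = 0L,
                         frame = "auto", lo = 0.005, hi = 0.05,
                         exclude_ids = NULL,
                         haplotype_policy = "ambiguity_tolerant",
                         quiet = TRUE) {
  say <- function(...) if (!quiet) message("[refaudit] ", ...)
  stage <- function(name, expr) {
    t0 <- Sys.time()
    out <- tryCatch(expr, error = function(e) {
      abort(paste0("stage '", name, "' failed: ", conditionMessage(e)))
    })
    say(name, " done in ",
        sprintf("%.2fs", as.numeric(Sys.time() - t0, units = "secs")))
    out
  }

  input_hashes <- NULL
  if (is.null(ref)) {
    if (is.null(fasta) || is.null(metadata)) {
      abort("provide either `ref` or both `fasta` and `metadata`")
    }
    input_hashes <- list(fasta = unname(tools::md5sum(fasta)),
                         metadata = unname(tools::md5sum(metadata)))
    ref <- stage("read", read_reference_set(fasta, metadata))
  } else {
    check_ref(ref)
  }
  if (!is.null(trim_length)) {
    ref <- stage("trim", trim_to_barcode(ref, trim_length, trim_offset))
  }

  has_cluster <- cluster_col %in% names(ref)
  has_species <- species_col %in% names(ref)
  has_group <- group_col %in% names(ref)

  sites <- stage("site_statistics", site_statistics(ref))
  fcheck <- stage("frame_check", check_stop_codons(ref, frame = frame))
  haps <- stage("haplotypes", collapse_haplotypes(ref, policy = haplotype_policy))

  dataset <- list(
    n_sequences = nrow(ref),
    n_haplotypes = dplyr::n_distinct(haps$haplotype_id),
    alignment_length = nchar(ref$sequence[1]),
    site_stats = sites,
    frame_check = glance(fcheck),
    by_group = if (has_group) haplotypes_by_group(ref, group_col,
                                                  policy = haplotype_policy)
               else NULL
  )

  dm <- stage("distances", distance_matrix(ref))
  pair_d <- tidy(dm)$distance
  distance <- list(
    min = min(pair_d, na.rm = TRUE),
    max = max(pair_d, na.rm = TRUE),
    n_undefined_pairs = sum(is.na(pair_d))
  )

  cluster_block <- NULL; congruence_block <- NULL; summary_obj <- NULL
  if (has_cluster) {
    part <- ref[, c("specimen_id", cluster_col)]
    audits <- stage("audit", audit_clusters(dm, part, cluster_col = cluster_col,
                                            ref = ref))
    summary_obj <- stage("summary", summarize_audit(
      audits, dm, part, cluster_col = cluster_col,
      groups = if (has_group) ref[, c("specimen_id", group_col)] else NULL,
      group_col = group_col
    ))
    cluster_block <- list(audits = audits, summary = summary_obj)
    distance$overall_mean_intra <- summary_obj$overall$mean_intra
    distance$overall_mean_inter <- summary_obj$overall$mean_inter

    if (has_species) {
      cong <- stage("congruence", classify_congruence(
        ref[, c("specimen_id", species_col)], part,
        exclude_ids = exclude_ids,
        species_col = species_col, cluster_col = cluster_col
      ))
      congruence_block <- cong
    }
  }

  scan <- stage("delimitation", delimit_motus(dm, lo = lo, hi = hi))
  motu_vs_species <- NULL
  if (has_species) {
    sp <- ref[!ref$specimen_id %in% exclude_ids, c("specimen_id", species_col)]
    keep <- dplyr::filter(scan$partition, .data$specimen_id %in% sp$specimen_id)
    motu_vs_species <- stage("motu_congruence",
                             compare_partitions(sp, keep, p_col = species_col))
  }
  delimitation <- list(scan = scan, motu_vs_species = motu_vs_species)

  report <- structure(list(
    dataset = dataset,
    distance = distance,
    cluster = cluster_block,
    delimitation = delimitation,
    congruence = congruence_block,
    provenance = list(
      package_version = as.character(utils::packageVersion("refaudit")),
      input_hashes = input_hashes,
      config = list(cluster_col = cluster_col, species_col = species_col,
                    group_col = group_col, trim_length = trim_length,
                    trim_offset = trim_offset, frame = frame, lo = lo,
                    hi = hi, haplotype_policy = haplotype_policy,
                    exclude_ids = exclude_ids),
      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
    )
  ), class = "audit_report")
  check_report_consistency(report)
  report
}

#' @export
print.audit_report <- function(x, ...) {
  cat("<audit_report>\n")
  cat("  sequences:  ", x$dataset$n_sequences, " (",
      x$dataset$n_haplotypes, " haplotypes)\n", sep = "")
  cat("  distances:  ", sprintf("%.1f-%.1f%%", 100 * x$distance$min,
                                100 * x$distance$max), "\n", sep = "")
  if (!is.null(x$cluster)) {
    o <- x$cluster$summary$overall
    cat("  clusters:   ", o$n_clusters, "; gap in ", o$n_gap,
        sprintf(" (%.1f%%)", o$pct_gap), "\n", sep = "")
  }
  cat("  MOTUs:      ", x$delimitation$scan$n_motus, " at t = ",
      x$delimitation$scan$selected_threshold, "\n", sep = "")
  if (!is.null(x$congruence)) {
    cts <- x$congruence$counts
    cat("  congruence: ",
        paste(sprintf("%s %d", cts$category, cts$n), collapse = ", "),
        "\n", sep = "")
  }
  invisible(x)
}

#' @rdname run_pipeline
#' @param x An `audit_report`.
#' @param ... Unused.
#' @export
glance.audit_report <- function(x, ...) {
  dplyr::bind_cols(
    tibble(n_sequences = x$dataset$n_sequences,
           n_haplotypes = x$dataset$n_haplotypes,
           distance_min = x$distance$min,
           distance_max = x$distance$max),
    if (!is.null(x$cluster)) x$cluster$summary$overall else NULL,
    tibble(n_motus = x$delimitation$scan$n_motus,
           selected_threshold = x$delimitation$scan$selected_threshold)
  )
}

#' Render an audit report as deterministic tables
#'
#' Returns the report's tabular surface: clusters ordered by label,
#' groups by name, percentages to one decimal place.
#'
#' @param report An `audit_report`.
#' @return Named list of tibbles (`summary`, `clusters`, `scan`, `motus`,
#'   `congruence`, `congruence_counts`, and `by_group` when available);
#'   blocks absent from the report are omitted.
#' @export
render_tables <- function(report) {
  stopifnot(inherits(report, "audit_report"))
  pct <- function(x) round(100 * x, 1)
  out <- list()

  out$summary <- glance(report) %>%
    dplyr::mutate(dplyr::across(dplyr::any_of(c(
      "distance_min", "distance_max", "mean_intra", "max_intra",
      "mean_inter", "inter_pair_mean_min", "inter_pair_mean_max"
    )), pct)) %>%
    dplyr::mutate(dplyr::across(dplyr::any_of("pct_gap"), ~ round(.x, 1)))

  if (!is.null(report$cluster)) {
    out$clusters <- report$cluster$audits %>%
      dplyr::arrange(.data$cluster) %>%
      dplyr::mutate(dplyr::across(c("intra_min", "intra_mean", "intra_max",
                                    "nn_distance"), pct))
    if (!is.null(report$cluster$summary$by_group)) {
      out$by_group <- report$cluster$summary$by_group %>%
        dplyr::arrange(.data$group) %>%
        dplyr::mutate(dplyr::across(c("mean_intra", "max_intra", "mean_inter",
                                      "inter_pair_mean_min",
                                      "inter_pair_mean_max"), pct),
                      pct_gap = round(.data$pct_gap, 1))
    }
  }

  out$scan <- tidy(report$delimitation$scan)
  out$motus <- report$delimitation$scan$partition

  if (!is.null(report$congruence)) {
    out$congruence <- tidy(report$congruence) %>% dplyr::arrange(.data$cluster)
    out$congruence_counts <- report$congruence$counts %>%
      dplyr::mutate(pct = round(.data$pct, 1))
  }
  out
}

#' Write an audit report as a JSON + TSV bundle
#'
#' Writes `report.json` plus one TSV per table from [render_tables()] into
#' a directory.
#'
#' @param report An `audit_report`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_audit_report <- function(report, dir) {
  stopifnot(inherits(report, "audit_report"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tables <- render_tables(report)
  paths <- character(0)
  for (nm in names(tables)) {
    p <- file.path(dir, paste0(nm, ".tsv"))
    tab <- tables[[nm]]
    tab <- dplyr::mutate(tab, dplyr::across(tidyselect::where(is.list),
                                            ~ purrr::map_chr(.x, paste, collapse = ",")))
    readr::write_tsv(tab, p, progress = FALSE)
    paths <- c(paths, p)
  }
  json <- list(
    dataset = list(
      n_sequences = report$dataset$n_sequences,
      n_haplotypes = report$dataset$n_haplotypes,
      alignment_length = report$dataset$alignment_length,
      site_stats = as.list(report$dataset$site_stats),
      frame_check = as.list(report$dataset$frame_check)
    ),
    distance = report$distance,
    cluster = if (!is.null(report$cluster)) {
      as.list(report$cluster$summary$overall)
    },
    delimitation = as.list(glance(report$delimitation$scan)),
    congruence = if (!is.null(report$congruence)) {
      list(counts = report$congruence$counts,
           n_excluded = report$congruence$n_excluded)
    },
    provenance = report$provenance
  )
  jp <- file.path(dir, "report.json")
  jsonlite::write_json(json, jp, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(c(paths, jp))
}

# Every derived percentage in the report must be recomputable from its own
# counts; called on construction.
check_report_consistency <- function(report) {
  if (!is.null(report$cluster)) {
    o <- report$cluster$summary$overall
    stopifnot(isTRUE(all.equal(o$pct_gap, 100 * o$n_gap / o$n_clusters)))
  }
  if (!is.null(report$congruence)) {
    cts <- report$congruence$counts
    stopifnot(isTRUE(all.equal(cts$pct, 100 * cts$n / sum(cts$n))))
  }
  invisible(report)
}
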