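# Synthetic barcode libraries with known ground truth.
#
# Star genealogy within species: a single root sequence, one ancestor per
# species mutated from the root at per-site probability between/2, and each
# specimen mutated from its ancestor at per-site probability within/2
# (mutations go to a uniformly chosen alternative base). With these
# per-site probabilities the expected pairwise p-distance is close to the
# nominal divergence: two conspecifics at per-site rate p mismatch with
# probability 2p - (4/3)p^2 per site (see expected_pairwise_divergence()).
# Stop codons in frame 0 are removed by resampling the offending codon's
# third position; missing data is injected as 'N' per cell; optional lump
# and split label events then perturb the written species names while the
# truth is retained.

#' Simulate a barcode reference library
#'
#' The defaults emulate the divergence structure of a curated CO1 reference
#' library: ~0.8% mean within-cluster and ~18.6% mean between-cluster
#' p-distance, ~3.6% missing data, 5 sequences per species, 658-bp
#' alignment.
#'
#' @param n_species Number of true species.
#' @param seqs_per_species Sequences per species: a single count (default 5)
#'   or a length-`n_species` vector.
#' @param seq_length Alignment length (default 658).
#' @param within_divergence Nominal conspecific pairwise divergence
#'   (default 0.008); per-site mutation probability is half of it.
#' @param between_divergence Nominal heterospecific pairwise divergence
#'   (default 0.186); each species ancestor is mutated from the root at half
#'   of it per site.
#' @param missing_fraction Per-cell probability of replacing the base by
#'   `N` (default 0.036).
#' @param n_lump_events,n_split_events Number of label perturbations (see
#'   [apply_label_events()]).
#' @param seed Integer seed; the output is deterministic given the seed.
#' @return A list with `ref` (reference-set tibble: `specimen_id`,
#'   `sequence`, `species` = written (possibly perturbed) name, `cluster` =
#'   true species label) and `truth` (list: `params`, `true_species` tibble,
#'   `events` tibble).
#' @examples
#' sim <- simulate_reference_set(n_species = 3, seqs_per_species = 4, seed = 1)
#' dplyr::count(sim$ref, cluster)
#' @export
simulate_reference_set <- function(n_species = 20, seqs_per_species = 5,
                                   seq_length = 658,
                                   within_divergence = 0.008,
                                   between_divergence = 0.186,
                                   missing_fraction = 0.036,
                                   n_lump_events = 0, n_split_events = 0,
                                   seed = 1) {
  if (!(within_divergence < between_divergence)) {
    abort("within_divergence must be < between_divergence")
  }
  for (p in c(within_divergence, between_divergence, missing_fraction)) {
    if (p < 0 || p > 1) abort("divergence and missing parameters must be in [0, 1]")
  }
  n_per <- if (length(seqs_per_species) == 1L) {
    rep(as.integer(seqs_per_species), n_species)
  } else {
    if (length(seqs_per_species) != n_species) {
      abort("seqs_per_species must have length 1 or n_species")
    }
    as.integer(seqs_per_species)
  }
  if (any(n_per < 1L)) abort("seqs_per_species must be >= 1")

  set.seed(seed)
  p_within <- within_divergence / 2
  p_between <- between_divergence / 2

  root <- fix_stop_codons(sample(BASES, seq_length, replace = TRUE))
  species_names <- sprintf("sp%02d", seq_len(n_species))
  ancestors <- purrr::map(seq_len(n_species), function(i) {
    fix_stop_codons(mutate_sites(root, p_between))
  })

  records <- purrr::map2(seq_len(n_species), n_per, function(i, k) {
    seqs <- purrr::map_chr(seq_len(k), function(j) {
      s <- fix_stop_codons(mutate_sites(ancestors[[i]], p_within))
      if (missing_fraction > 0) {
        s[runif(seq_length) < missing_fraction] <- "N"
      }
      paste(s, collapse = "")
    })
    tibble(specimen_id = sprintf("%s_%02d", species_names[i], seq_len(k)),
           sequence = seqs, species = species_names[i])
  }) %>% dplyr::bind_rows()

  true_species <- dplyr::select(records, "specimen_id", "species")
  ev <- apply_label_events(true_species, n_lump = n_lump_events,
                           n_split = n_split_events)
  ref <- records %>%
    dplyr::mutate(species = ev$labels$species[match(.data$specimen_id,
                                                    ev$labels$specimen_id)],
                  cluster = true_species$species)
  list(
    ref = ref,
    truth = list(
      params = list(n_species = n_species, seqs_per_species = n_per,
                    seq_length = seq_length,
                    within_divergence = within_divergence,
                    between_divergence = between_divergence,
                    missing_fraction = missing_fraction,
                    n_lump_events = n_lump_events,
                    n_split_events = n_split_events, seed = seed),
      true_species = true_species,
      events = ev$events
    )
  )
}

#' Perturb species labels with lump and split events
#'
#' A *lump* event relabels every member of one species with another
#' species' name (so the written name spans two true species). A *split*
#' event renames `floor(n/2)` members of one species to a new name (so the
#' true species is written under two names). Affected species are drawn
#' uniformly without replacement among eligible species; split events
#' require species with at least two members. The event log is sufficient
#' to reconstruct the written labels from the true ones.
#'
#' @param labels Tibble (`specimen_id`, `species`) of true labels.
#' @param n_lump,n_split Event counts.
#' @param seed Optional seed; by default the current RNG state is used (as
#'   when called from [simulate_reference_set()]).
#' @return List with `labels` (perturbed tibble, same row order) and
#'   `events` (tibble `type`, `source_species`, `target_species`,
#'   `affected_ids` list-column).
#' @export
apply_label_events <- function(labels, n_lump = 0, n_split = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(is.data.frame(labels),
            all(c("specimen_id", "species") %in% names(labels)))
  species <- unique(labels$species)
  sizes <- table(labels$species)
  n_events <- n_lump + n_split
  if (n_lump > 0 && length(species) < 2L) {
    abort("lump events need at least two species")
  }
  if (n_events > length(species)) {
    abort("more label events than species")
  }
  splittable <- names(sizes)[sizes >= 2L]

  out <- labels
  events <- list()
  affected <- character(0)

  if (n_split > 0) {
    eligible <- setdiff(splittable, affected)
    if (length(eligible) < n_split) {
      abort("not enough species with >= 2 members for the requested split events")
    }
    chosen <- sample(eligible, n_split)
    for (s in chosen) {
      members <- labels$specimen_id[labels$species == s]
      moved <- members[seq_len(length(members) %/% 2L)]
      new_name <- paste0(s, "_split")
      out$species[out$specimen_id %in% moved] <- new_name
      events[[length(events) + 1L]] <- tibble(
        type = "split", source_species = s, target_species = new_name,
        affected_ids = list(moved)
      )
    }
    affected <- c(affected, chosen)
  }

  if (n_lump > 0) {
    eligible <- setdiff(species, affected)
    if (length(eligible) < n_lump + 1L) {
      abort("not enough unaffected species for the requested lump events")
    }
    chosen <- sample(eligible, n_lump)
    for (s in chosen) {
      targets <- setdiff(species, c(affected, chosen))
      if (length(targets) == 0L) abort("no target species left for lump event")
      target <- if (length(targets) == 1L) targets else sample(targets, 1)
      members <- labels$specimen_id[labels$species == s]
      out$species[out$specimen_id %in% members] <- target
      events[[length(events) + 1L]] <- tibble(
        type = "lump", source_species = s, target_species = target,
        affected_ids = list(members)
      )
    }
    affected <- c(affected, chosen)
  }

  list(labels = out,
       events = if (length(events)) dplyr::bind_rows(events) else
         tibble(type = character(), source_species = character(),
                target_species = character(), affected_ids = list()))
}

#' Exact expected pairwise p-distance under the simulation model
#'
#' Per-site mutation at probability `r` to a uniformly chosen alternative
#' base is a Jukes-Cantor step, so steps compose exactly:
#' `M(a) M(b) = M(c)` with `(1 - 4c/3) = (1 - 4a/3)(1 - 4b/3)`. The
#' expectation is computed from the explicit 4x4 transition matrices, not
#' the closed form, so tests can check the closed form against it.
#'
#' @param within_divergence Nominal conspecific divergence; the per-site
#'   tip rate is half of it.
#' @param between_divergence If `NULL` (default), the expectation for two
#'   conspecific sequences; otherwise for two sequences from species whose
#'   ancestors each diverged from the root at half this value per site.
#' @return Expected pairwise mismatch proportion.
#' @export
expected_pairwise_divergence <- function(within_divergence,
                                         between_divergence = NULL) {
  step <- function(r) {
    m <- matrix(r / 3, 4, 4)
    diag(m) <- 1 - r
    m
  }
  tip <- step(within_divergence / 2)
  n <- if (is.null(between_divergence)) tip else
    step(between_divergence / 2) %*% tip
  # both tips evolve independently from a common base; root base is uniform
  # but by symmetry any row gives the same collision probability
  1 - sum(n[1, ]^2)
}

# ---- internal ---------------------------------------------------------------

# Mutate each site independently with probability r to a uniform alternative.
mutate_sites <- function(seq_chars, r) {
  hit <- which(runif(length(seq_chars)) < r)
  if (length(hit)) {
    seq_chars[hit] <- vapply(seq_chars[hit], function(b) {
      sample(setdiff(BASES, b), 1)
    }, character(1), USE.NAMES = FALSE)
  }
  seq_chars
}

# Resample the third position of frame-0 TAA/TAG codons until none remain.
fix_stop_codons <- function(seq_chars) {
  n_codons <- length(seq_chars) %/% 3L
  if (n_codons == 0L) return(seq_chars)
  repeat {
    starts <- 3L * (seq_len(n_codons) - 1L) + 1L
    c1 <- seq_chars[starts]; c2 <- seq_chars[starts + 1L]
    c3 <- seq_chars[starts + 2L]
    bad <- which(c1 == "T" & c2 == "A" & c3 %in% c("A", "G"))
    if (length(bad) == 0L) return(seq_chars)
    seq_chars[starts[bad] + 2L] <- sample(BASES, length(bad), replace = TRUE)
  }
}
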