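# Independent oracles and fixture builders. Everything here is deliberately
# naive (per-column loops, raw contingency tables) so it shares no code with
# the implementation it checks.

BASES4 <- c("A", "C", "G", "T")

# Naive per-column p-distance with pairwise deletion.
brute_p_distance <- function(a, b) {
  x <- strsplit(a, "")[[1]]
  y <- strsplit(b, "")[[1]]
  n <- 0L; mism <- 0L
  for (k in seq_along(x)) {
    if (x[k] %in% BASES4 && y[k] %in% BASES4) {
      n <- n + 1L
      if (x[k] != y[k]) mism <- mism + 1L
    }
  }
  list(distance = if (n == 0L) NA_real_ else mism / n, n_compared = n)
}

brute_distance_matrix <- function(seqs) {
  n <- length(seqs)
  d <- matrix(0, n, n)
  nc <- matrix(0L, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      r <- brute_p_distance(seqs[i], seqs[j])
      d[i, j] <- if (i == j) 0 else r$distance
      nc[i, j] <- r$n_compared
    }
  }
  list(d = d, n_compared = nc)
}

# Random aligned sequences with a given missing ('N') fraction.
random_seqs <- function(n, len, missing = 0.1) {
  vapply(seq_len(n), function(i) {
    s <- sample(BASES4, len, replace = TRUE)
    s[runif(len) < missing] <- "N"
    paste(s, collapse = "")
  }, character(1))
}

random_ref <- function(n, len, missing = 0.1, ids = sprintf("r%02d", seq_len(n))) {
  tibble::tibble(specimen_id = ids, sequence = random_seqs(n, len, missing))
}

# Wrap an arbitrary symmetric distance matrix as a p_dist object so audit
# and delimitation can be checked against hand-built matrices.
fake_p_dist <- function(d, ids = NULL) {
  if (is.null(ids)) ids <- sprintf("q%02d", seq_len(nrow(d)))
  dimnames(d) <- list(ids, ids)
  nc <- matrix(1L, nrow(d), ncol(d), dimnames = dimnames(d))
  structure(list(ids = ids, d = d, n_compared = nc), class = "p_dist")
}

# Random symmetric distance matrix with zero diagonal.
random_dist_matrix <- function(n, max_d = 0.1) {
  d <- matrix(0, n, n)
  v <- runif(n * (n - 1) / 2, 0, max_d)
  d[upper.tri(d)] <- v
  d <- d + t(d)
  d
}

# Congruence categories recomputed from the raw species x cluster
# contingency table.
oracle_congruence <- function(species, clusters) {
  tab <- table(species, clusters)
  split_sp <- rownames(tab)[rowSums(tab > 0) >= 2]
  cats <- character(ncol(tab))
  names(cats) <- colnames(tab)
  for (cl in colnames(tab)) {
    sp_in <- rownames(tab)[tab[, cl] > 0]
    n_sp <- length(sp_in)
    any_split <- any(sp_in %in% split_sp)
    cats[cl] <-
      if (n_sp == 1 && !any_split) "match"
      else if (n_sp >= 2 && !any_split) "lump"
      else if (n_sp == 1 && any_split) "split"
      else "both"
  }
  cats
}

# Naive per-cluster audit by pair enumeration.
brute_audit <- function(d, labels) {
  clusters <- sort(unique(labels))
  out <- list()
  for (cl in clusters) {
    inside <- which(labels == cl)
    intra <- c()
    if (length(inside) > 1) {
      for (i in inside) for (j in inside) if (i < j && !is.na(d[i, j])) {
        intra <- c(intra, d[i, j])
      }
    }
    nn_cl <- NA_character_; nn_d <- Inf
    for (other in setdiff(clusters, cl)) {
      outside <- which(labels == other)
      m <- Inf
      for (i in inside) for (j in outside) {
        if (!is.na(d[i, j]) && d[i, j] < m) m <- d[i, j]
      }
      if (m < nn_d) { nn_d <- m; nn_cl <- other }
      # ties: keep the lexicographically first (clusters scanned in order)
    }
    out[[cl]] <- list(
      n = length(inside),
      intra_min = if (length(intra)) min(intra) else NA_real_,
      intra_mean = if (length(intra)) mean(intra) else NA_real_,
      intra_max = if (length(intra)) max(intra) else NA_real_,
      nn_cluster = nn_cl,
      nn_distance = if (is.finite(nn_d)) nn_d else NA_real_,
      has_gap = (if (length(intra)) max(intra) else 0) <
        (if (is.finite(nn_d)) nn_d else NA_real_)
    )
  }
  out
}

# Two tight groups with a wide gap; the scan range holds thresholds both
# inside and above the intra-group distances.
two_gap_matrix <- function() {
  d <- matrix(0.2, 6, 6)
  d[1:3, 1:3] <- matrix(c(0, .01, .02, .01, 0, .015, .02, .015, 0), 3, 3)
  d[4:6, 4:6] <- matrix(c(0, .012, .03, .012, 0, .025, .03, .025, 0), 3, 3)
  diag(d) <- 0
  fake_p_dist(d)
}

toy_fasta <- function() system.file("extdata", "toy_barcodes.fasta",
                                    package = "refaudit")
toy_tsv <- function() system.file("extdata", "toy_metadata.tsv",
                                  package = "refaudit")
toy_ref <- function() read_reference_set(toy_fasta(), toy_tsv())

# Tibble reference set from bare sequences.
ref_from <- function(...) {
  seqs <- c(...)
  ids <- if (is.null(names(seqs))) letters[seq_along(seqs)] else names(seqs)
  tibble::tibble(specimen_id = ids, sequence = unname(seqs))
}
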