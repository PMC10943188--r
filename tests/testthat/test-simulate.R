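test_that("the generator honours counts and writes truth without events", {
  sim <- simulate_reference_set(n_species = 3, seqs_per_species = 4, seed = 2)
  expect_equal(nrow(sim$ref), 12)
  expect_equal(dplyr::n_distinct(sim$ref$cluster), 3)
  expect_equal(sim$ref$species, sim$truth$true_species$species)
  expect_equal(nrow(sim$truth$events), 0)
  expect_equal(unique(nchar(sim$ref$sequence)), 658)
})

test_that("zero within-divergence makes conspecifics identical", {
  sim <- simulate_reference_set(n_species = 4, seqs_per_species = 3,
                                seq_length = 120, within_divergence = 0,
                                between_divergence = 0.2,
                                missing_fraction = 0, seed = 3)
  h <- collapse_haplotypes(sim$ref, policy = "strict")
  expect_equal(dplyr::n_distinct(h$haplotype_id), 4)
})

test_that("identical params and seed reproduce the library byte for byte", {
  a <- simulate_reference_set(n_species = 5, seqs_per_species = 3,
                              seq_length = 90, seed = 11,
                              n_lump_events = 1, n_split_events = 1)
  b <- simulate_reference_set(n_species = 5, seqs_per_species = 3,
                              seq_length = 90, seed = 11,
                              n_lump_events = 1, n_split_events = 1)
  expect_identical(a$ref, b$ref)
  expect_identical(a$truth$events, b$truth$events)
})

test_that("simulated sequences are stop-free in frame 0", {
  sim <- simulate_reference_set(n_species = 6, seqs_per_species = 4,
                                seq_length = 300, seed = 13)
  fc <- check_stop_codons(sim$ref, frame = 0)
  expect_equal(fc$n_stop_codons, 0)
  # and frame=auto therefore finds a stop-free frame
  expect_equal(check_stop_codons(sim$ref)$n_stop_codons, 0)
})

test_that("the exact pairwise expectation matches the closed form", {
  # one mutation step at rate r is Jukes-Cantor; two tips at composite
  # per-site rate c mismatch with probability 2c - (4/3)c^2
  for (w in c(0.008, 0.05, 0.2)) {
    p <- w / 2
    expect_equal(expected_pairwise_divergence(w), 2 * p - (4 / 3) * p^2)
  }
  # heterospecific: compose the root->ancestor and ancestor->tip steps
  q <- 0.186 / 2; p <- 0.008 / 2
  cc <- (1 - (1 - 4 * q / 3) * (1 - 4 * p / 3)) * 3 / 4
  expect_equal(expected_pairwise_divergence(0.008, 0.186),
               2 * cc - (4 / 3) * cc^2)
})

test_that("realised divergence matches the exact expectation at long lengths", {
  sim <- simulate_reference_set(n_species = 4, seqs_per_species = 4,
                                seq_length = 20000, within_divergence = 0.05,
                                between_divergence = 0.3,
                                missing_fraction = 0.05, seed = 17)
  dm <- distance_matrix(sim$ref)
  long <- tidy(dm)
  cl <- setNames(sim$ref$cluster, sim$ref$specimen_id)
  intra <- long$distance[cl[long$id1] == cl[long$id2]]
  inter <- long$distance[cl[long$id1] != cl[long$id2]]
  expect_equal(mean(intra), expected_pairwise_divergence(0.05),
               tolerance = 0.05)
  expect_equal(mean(inter), expected_pairwise_divergence(0.05, 0.3),
               tolerance = 0.05)
})

test_that("label events perturb the written names and log their inverse", {
  sim <- simulate_reference_set(n_species = 5, seqs_per_species = 4,
                                seq_length = 90, seed = 19,
                                n_lump_events = 1, n_split_events = 1)
  ev <- sim$truth$events
  expect_equal(sort(ev$type), c("lump", "split"))
  # replaying the log on the truth reproduces the written labels
  replay <- sim$truth$true_species
  for (k in seq_len(nrow(ev))) {
    ids <- ev$affected_ids[[k]]
    replay$species[replay$specimen_id %in% ids] <- ev$target_species[k]
  }
  expect_equal(replay$species, sim$ref$species)
})

test_that("injected events are recovered as congruence categories", {
  # clusters := written-label groups, species := truth; a lump event then
  # shows as one lump-category cluster, a split event as two split clusters
  sim <- simulate_reference_set(n_species = 6, seqs_per_species = 4,
                                seq_length = 90, seed = 23,
                                n_lump_events = 1, n_split_events = 1)
  written <- sim$ref[, c("specimen_id", "species")]
  r <- classify_congruence(sim$truth$true_species,
                           setNames(written$species, written$specimen_id))
  counts <- setNames(r$counts$n, r$counts$category)
  expect_equal(unname(counts["lump"]), 1)
  expect_equal(unname(counts["split"]), 2)
  expect_equal(unname(counts["both"]), 0)

  # no events: 100% match
  sim0 <- simulate_reference_set(n_species = 4, seqs_per_species = 3,
                                 seq_length = 90, seed = 29)
  r0 <- classify_congruence(sim0$truth$true_species,
                            setNames(sim0$ref$species, sim0$ref$specimen_id))
  expect_true(all(r0$per_cluster$category == "match"))
})

test_that("infeasible event counts and parameters abort", {
  expect_error(simulate_reference_set(n_species = 2, n_lump_events = 3,
                                      seed = 1),
               "more label events than species")
  expect_error(simulate_reference_set(n_species = 3, seqs_per_species = 1,
                                      n_split_events = 1, seed = 1),
               "split")
  expect_error(simulate_reference_set(within_divergence = 0.5,
                                      between_divergence = 0.1, seed = 1),
               "within_divergence")
})
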