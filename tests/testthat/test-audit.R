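two_cluster_dm <- function() {
  # K1 = {q01,q02} intra 0.01; K2 = {q03,q04} intra 0.00; cross 0.02
  d <- matrix(0.02, 4, 4)
  d[1, 2] <- d[2, 1] <- 0.01
  d[3, 4] <- d[4, 3] <- 0
  diag(d) <- 0
  fake_p_dist(d)
}

two_cluster_part <- function() {
  tibble::tibble(specimen_id = sprintf("q%02d", 1:4),
                 cluster = c("K1", "K1", "K2", "K2"))
}

test_that("a clear gap is flagged for every cluster", {
  audits <- audit_clusters(two_cluster_dm(), two_cluster_part())
  expect_equal(audits$cluster, c("K1", "K2"))
  expect_equal(audits$intra_max, c(0.01, 0))
  expect_equal(audits$nn_distance, c(0.02, 0.02))
  expect_equal(audits$nn_cluster, c("K2", "K1"))
  expect_true(all(audits$has_gap))
})

test_that("equality of intra_max and NN distance counts as overlap", {
  d <- two_cluster_dm()$d
  d[1, 2] <- d[2, 1] <- 0.02  # intra_max == nn_distance for K1
  audits <- audit_clusters(fake_p_dist(d), two_cluster_part())
  expect_false(audits$has_gap[audits$cluster == "K1"])
  expect_true(audits$has_gap[audits$cluster == "K2"])
})

test_that("singletons are audited with undefined intra stats and gap from NN", {
  d <- matrix(c(0, 0.05, 0.05, 0), 2, 2)
  part <- tibble::tibble(specimen_id = c("q01", "q02"), cluster = c("A", "B"))
  audits <- audit_clusters(fake_p_dist(d), part)
  expect_true(all(is.na(audits$intra_max)))
  expect_true(all(audits$has_gap))  # nn_distance > 0
})

test_that("audit rows equal a brute-force enumeration on random matrices", {
  set.seed(31)
  for (i in 1:8) {
    n <- sample(6:12, 1)
    d <- random_dist_matrix(n)
    labels <- sample(paste0("C", 1:4), n, replace = TRUE)
    dm <- fake_p_dist(d)
    part <- tibble::tibble(specimen_id = dm$ids, cluster = labels)
    audits <- audit_clusters(dm, part)
    bf <- brute_audit(d, labels)
    for (k in seq_len(nrow(audits))) {
      row <- audits[k, ]
      ref <- bf[[row$cluster]]
      expect_equal(row$n_sequences, ref$n)
      expect_equal(row$intra_min, ref$intra_min)
      expect_equal(row$intra_mean, ref$intra_mean)
      expect_equal(row$intra_max, ref$intra_max)
      expect_equal(row$nn_distance, ref$nn_distance)
      expect_equal(row$has_gap, ref$has_gap)
    }
  }
})

test_that("nearest-neighbour ties break to the lexicographically first cluster", {
  d <- matrix(0.03, 3, 3); diag(d) <- 0
  part <- tibble::tibble(specimen_id = sprintf("q%02d", 1:3),
                         cluster = c("B", "A", "C"))
  audits <- audit_clusters(fake_p_dist(d), part)
  expect_equal(audits$nn_cluster[audits$cluster == "B"], "A")
  expect_equal(audits$nn_cluster[audits$cluster == "A"], "B")
})

test_that("unassigned ids abort with their name", {
  dm <- two_cluster_dm()
  part <- two_cluster_part()[1:3, ]
  expect_error(audit_clusters(dm, part), "q04")
})

test_that("pooled summary means equal brute-force pair averages", {
  set.seed(37)
  d <- random_dist_matrix(10)
  labels <- sample(c("C1", "C2", "C3"), 10, replace = TRUE)
  dm <- fake_p_dist(d)
  part <- tibble::tibble(specimen_id = dm$ids, cluster = labels)
  audits <- audit_clusters(dm, part)
  s <- summarize_audit(audits, dm, part)

  intra <- c(); inter <- c()
  for (i in 1:9) for (j in (i + 1):10) {
    if (labels[i] == labels[j]) intra <- c(intra, d[i, j])
    else inter <- c(inter, d[i, j])
  }
  expect_equal(s$overall$mean_intra, mean(intra))
  expect_equal(s$overall$mean_inter, mean(inter))
  # intra pairs + inter pairs account for every pair
  expect_equal(length(intra) + length(inter), choose(10, 2))
  # mean range over per-cluster-pair means
  expect_equal(s$overall$inter_pair_mean_min, min(s$pair_means$mean_distance))
  expect_equal(s$overall$inter_pair_mean_max, max(s$pair_means$mean_distance))
})

test_that("identical sequences in two clusters give zero pooled means", {
  ref <- ref_from(a = "ACGT", b = "ACGT", c = "ACGT", d = "ACGT")
  part <- tibble::tibble(specimen_id = letters[1:4],
                         cluster = c("K1", "K1", "K2", "K2"))
  dm <- distance_matrix(ref)
  audits <- audit_clusters(dm, part)
  s <- summarize_audit(audits, dm, part)
  expect_equal(s$overall$mean_intra, 0)
  expect_equal(s$overall$mean_inter, 0)
  expect_false(any(audits$has_gap))  # zero NN distance is no gap
})

test_that("merging two clusters never shrinks intra_max or nn_distance", {
  set.seed(43)
  for (i in 1:8) {
    n <- 12
    d <- random_dist_matrix(n)
    labels <- sample(c("C1", "C2", "C3", "C4"), n, replace = TRUE)
    if (dplyr::n_distinct(labels) < 3) next
    dm <- fake_p_dist(d)
    part <- tibble::tibble(specimen_id = dm$ids, cluster = labels)
    a0 <- audit_clusters(dm, part)
    pair <- sample(unique(labels), 2)
    merged <- ifelse(labels %in% pair, "MERGED", labels)
    a1 <- audit_clusters(dm, tibble::tibble(specimen_id = dm$ids,
                                            cluster = merged))
    m <- a1[a1$cluster == "MERGED", ]
    olds <- a0[a0$cluster %in% pair, ]
    expect_gte(m$intra_max, max(olds$intra_max, na.rm = TRUE))
    expect_gte(m$nn_distance, min(olds$nn_distance))
  }
})

test_that("per-group summaries restrict to within-group pairs", {
  set.seed(47)
  d <- random_dist_matrix(8)
  dm <- fake_p_dist(d)
  labels <- c("C1", "C1", "C2", "C2", "C3", "C3", "C4", "C4")
  fams <- c(rep("F1", 4), rep("F2", 4))
  part <- tibble::tibble(specimen_id = dm$ids, cluster = labels)
  audits <- audit_clusters(dm, part)
  s <- summarize_audit(audits, dm, part,
                       groups = tibble::tibble(specimen_id = dm$ids,
                                               family = fams))
  f1 <- s$by_group[s$by_group$group == "F1", ]
  expect_equal(f1$n_clusters, 2)
  expect_equal(f1$mean_intra, mean(c(d[1, 2], d[3, 4])))
  inter_f1 <- c(d[1, 3], d[1, 4], d[2, 3], d[2, 4])
  expect_equal(f1$mean_inter, mean(inter_f1))
})

test_that("undefined pairs are dropped from summaries with a warning", {
  d <- two_cluster_dm()$d
  d[1, 3] <- d[3, 1] <- NA
  expect_warning(audits <- audit_clusters(fake_p_dist(d), two_cluster_part()),
                 "no comparable sites")
  expect_equal(audits$nn_distance, c(0.02, 0.02))
})
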