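test_that("the four categories follow their definitions on hand-built cases", {
  # perfect 1:1
  r <- classify_congruence(c(a = "s1", b = "s1", c = "s2"),
                           c(a = "K1", b = "K1", c = "K2"))
  expect_equal(r$per_cluster$category, c("match", "match"))

  # two names in one cluster, neither split: lump
  r2 <- classify_congruence(c(a = "s1", b = "s2"), c(a = "K1", b = "K1"))
  expect_equal(r2$per_cluster$category, "lump")

  # one name over two clusters: both clusters split
  r3 <- classify_congruence(c(a = "s1", b = "s1"), c(a = "K1", b = "K2"))
  expect_equal(r3$per_cluster$category, c("split", "split"))

  # 6-id scenario: x = {a,b,c}, y = {d}; K1 = {a,b,d}, K2 = {c}
  # K1 holds two names with x split -> both; K2 holds split x alone -> split
  sp <- c(a = "x", b = "x", c = "x", d = "y")
  cl <- c(a = "K1", b = "K1", c = "K2", d = "K1")
  r4 <- classify_congruence(sp, cl)
  expect_equal(r4$per_cluster$category[r4$per_cluster$cluster == "K1"], "both")
  expect_equal(r4$per_cluster$category[r4$per_cluster$cluster == "K2"], "split")
  expect_equal(unname(oracle_congruence(sp, cl)[c("K1", "K2")]),
               c("both", "split"))
})

test_that("identical partitions give all-match and exhaustive counts", {
  set.seed(61)
  ids <- sprintf("i%02d", 1:20)
  labels <- sample(paste0("g", 1:6), 20, replace = TRUE)
  r <- classify_congruence(setNames(labels, ids),
                           setNames(paste0("cl_", labels), ids))
  expect_true(all(r$per_cluster$category == "match"))
  expect_equal(sum(r$counts$n), nrow(r$per_cluster))
  expect_equal(r$counts$n[r$counts$category == "match"],
               dplyr::n_distinct(labels))
})

test_that("bijective relabeling never changes categories", {
  set.seed(67)
  ids <- sprintf("i%02d", 1:15)
  sp <- setNames(sample(paste0("s", 1:5), 15, replace = TRUE), ids)
  cl <- setNames(sample(paste0("K", 1:5), 15, replace = TRUE), ids)
  r <- classify_congruence(sp, cl)
  sp2 <- setNames(paste0("renamed_", sp), ids)
  cl2 <- setNames(chartr("K", "Q", cl), ids)
  r2 <- classify_congruence(sp2, cl2)
  expect_equal(r2$per_cluster$category, r$per_cluster$category)
  expect_equal(r2$counts$n, r$counts$n)
})

test_that("categories match the contingency-table oracle on random partitions", {
  set.seed(71)
  for (i in 1:50) {
    n <- sample(5:25, 1)
    ids <- sprintf("i%02d", seq_len(n))
    sp <- setNames(sample(paste0("s", 1:5), n, replace = TRUE), ids)
    cl <- setNames(sample(paste0("K", 1:5), n, replace = TRUE), ids)
    got <- classify_congruence(sp, cl)$per_cluster
    want <- oracle_congruence(sp, cl)
    expect_equal(setNames(got$category, got$cluster), want[got$cluster])
  }
})

test_that("exclusions are applied before split status is evaluated", {
  # species s1 occupies K1 and K2 only through specimen c; excluding c
  # turns K1 from split into match and empties K2
  sp <- c(a = "s1", b = "s1", c = "s1")
  cl <- c(a = "K1", b = "K1", c = "K2")
  r_all <- classify_congruence(sp, cl)
  expect_equal(r_all$per_cluster$category, c("split", "split"))
  r_excl <- classify_congruence(sp, cl, exclude_ids = "c")
  expect_equal(r_excl$per_cluster$category[r_excl$per_cluster$cluster == "K1"],
               "match")
  expect_equal(r_excl$per_cluster$category[r_excl$per_cluster$cluster == "K2"],
               "excluded")
  expect_equal(r_excl$n_excluded, 1)
})

test_that("specimens without a species name are dropped with a warning", {
  sp <- c(a = "s1", b = "", c = "s2")
  cl <- c(a = "K1", b = "K1", c = "K2")
  expect_warning(r <- classify_congruence(sp, cl), "without a species name")
  expect_equal(r$n_excluded, 1)
  expect_equal(r$per_cluster$category, c("match", "match"))
})

test_that("mismatched id universes abort", {
  expect_error(classify_congruence(c(a = "s1"), c(b = "K1")), "different ids")
})

test_that("count tables report percentages over classified clusters", {
  # 10 clusters: 8 match, 1 lump, 1 split... build 1 lump + 2 split clusters
  ids <- sprintf("i%02d", 1:22)
  sp <- setNames(c(paste0("s", rep(1:8, each = 2)),   # 8 matched pairs
                   "s9", "s10",                       # lumped into one cluster
                   "s11", "s11", "s11", "s11"), ids)  # split over two clusters
  cl <- setNames(c(paste0("K", rep(1:8, each = 2)),
                   "K9", "K9",
                   "K10", "K10", "K11", "K11"), ids)
  r <- classify_congruence(sp, cl)
  tab <- congruence_table(r)
  expect_equal(tab$n[tab$category == "match"], 8)
  expect_equal(tab$n[tab$category == "lump"], 1)
  expect_equal(tab$n[tab$category == "split"], 2)
  expect_equal(tab$pct[tab$category == "lump"], round(100 / 11, 1))
  expect_equal(sum(tab$n), 11)
})

test_that("grouped count tables attribute each cluster to its family", {
  ids <- letters[1:6]
  sp <- setNames(c("s1", "s1", "s2", "s3", "s4", "s4"), ids)
  cl <- setNames(c("K1", "K1", "K2", "K2", "K3", "K3"), ids)
  fam <- setNames(c(rep("F1", 4), rep("F2", 2)), ids)
  r <- classify_congruence(sp, cl)
  tab <- congruence_table(r, groups = fam, clusters = cl)
  expect_equal(tab$n[tab$group == "F1" & tab$category == "lump"], 1)
  expect_equal(tab$n[tab$group == "F2" & tab$category == "match"], 1)
})
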