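test_that("single-linkage cut matches the connected-components oracle", {
  set.seed(7)
  # two tight groups far apart, raw scale (no standardization so the cutoff
  # is interpretable against the brute-force oracle)
  g1 <- matrix(rnorm(8 * 3, 0, 0.05), 8, 3)
  g2 <- matrix(rnorm(8 * 3, 5, 0.05), 8, 3)
  mat <- rbind(g1, g2)
  ca <- hierarchical_clusters(mat, cutoff = 1, standardize = FALSE)
  oracle <- components_at_cutoff(mat, 1)
  expect_equal(ca$n_clusters, 2L)
  expect_equal(adjusted_rand(ca$assignment$cluster, oracle), 1)
  expect_equal(adjusted_rand(ca$assignment$cluster, rep(1:2, each = 8)), 1)
})

test_that("degenerate cutoffs give one cluster / all singletons", {
  same <- matrix(1, 5, 4)
  ca <- hierarchical_clusters(same, cutoff = 0.5, standardize = FALSE)
  expect_equal(ca$n_clusters, 1L)

  set.seed(1)
  spread <- matrix(rnorm(12, sd = 10), 6, 2)
  tiny <- hierarchical_clusters(spread, cutoff = 1e-9, standardize = FALSE)
  expect_equal(tiny$n_clusters, 6L)

  expect_error(hierarchical_clusters(matrix(1, 1, 3)), "at least 2")
  expect_error(hierarchical_clusters(matrix(1, 5, 3), cutoff = 0), "positive")
})

test_that("clustering is invariant to isolate row order", {
  pan <- simulate_phenotype_panel(n_clusters = 3, separation = 10,
                                  noise_sd = 0.5, seed = 5)
  ca1 <- hierarchical_clusters(pan)
  perm <- sample(nrow(pan))
  ca2 <- hierarchical_clusters(pan[perm, ])
  m <- match(ca2$assignment$isolate, ca1$assignment$isolate)
  expect_equal(adjusted_rand(ca2$assignment$cluster, ca1$assignment$cluster[m]), 1)
})

test_that("planted partitions are recovered when separation dominates noise", {
  pan <- simulate_phenotype_panel(n_clusters = 6, separation = 10,
                                  noise_sd = 0.5, seed = 31)
  ca <- hierarchical_clusters(pan)
  expect_equal(adjusted_rand(ca$assignment$cluster, pan$true_cluster), 1)
})

test_that("diversity score implements (clusters represented / n) x 100", {
  mk <- function(clusters) data.frame(isolate = sprintf("i%d", seq_along(clusters)),
                                      population = 1, cluster = clusters)
  expect_equal(diversity_score(mk(rep(1, 8)))$score, 12.5)   # single cluster
  expect_equal(diversity_score(mk(1:8))$score, 100)          # all distinct
  expect_equal(diversity_score(mk(rep(1:4, 2)))$score, 50)   # 4 of 8

  # scores for 8-isolate populations are always multiples of 12.5
  set.seed(2)
  for (i in 1:20) {
    sc <- diversity_score(mk(sample(1:8, 8, replace = TRUE)))$score
    expect_true(sc %in% seq(12.5, 100, by = 12.5))
  }

  odd <- diversity_score(mk(c(1, 1, 2, 2, 3)))
  expect_equal(odd$score, 60)
  expect_true(odd$nonstandard_n)
})

test_that("diversity score validates its population mapping", {
  df <- data.frame(isolate = c("a", "b"), cluster = c(1, 2))
  expect_error(diversity_score(df), "no population mapping")
  expect_error(diversity_score(df, populations = c(a = 1)), "without a population")
  ok <- diversity_score(df, populations = c(a = 1, b = 1))
  expect_equal(ok$n_clusters, 2L)
  expect_equal(ok$score, 100)  # 2 clusters among 2 isolates
})

test_that("end-to-end panel -> clusters -> per-population scores", {
  pan <- simulate_phenotype_panel(n_clusters = 6, separation = 10,
                                  noise_sd = 0.5, seed = 12)
  ca <- hierarchical_clusters(pan)
  rep_ <- diversity_score(ca)
  expect_equal(nrow(rep_), 6L)
  expect_true(all(rep_$n_isolates == 8))
  expect_true(all(rep_$score >= 12.5 & rep_$score <= 100))
  # isolates are spread over clusters round-robin: every population holds
  # several planted clusters, so no population should sit at the minimum
  expect_true(all(rep_$score > 12.5))
})

test_that("dendrograms serialize to Newick and survive a round-trip", {
  pan <- simulate_phenotype_panel(n_clusters = 3, separation = 10,
                                  noise_sd = 0.5, seed = 8)
  ca <- hierarchical_clusters(pan)
  nwk <- dendrogram_newick(ca)
  tree <- ape::read.tree(text = nwk)
  expect_equal(sort(tree$tip.label), sort(pan$isolate))
})

test_that("phenotype CSVs round-trip through the reader", {
  pan <- simulate_phenotype_panel(n_clusters = 6, separation = 10,
                                  noise_sd = 0.5, seed = 4)
  f <- tempfile(fileext = ".csv")
  write.csv(pan[setdiff(names(pan), "true_cluster")], f, row.names = FALSE)
  back <- read_phenotype_csv(f)
  ca <- hierarchical_clusters(back)
  expect_equal(adjusted_rand(ca$assignment$cluster, pan$true_cluster), 1)
  unlink(f)
})
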