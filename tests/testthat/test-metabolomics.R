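groups_2x2 <- function(log_scales) {
  data.frame(strain = rep(c("WT", "MUT"), each = 2),
             batch = rep(c("b1", "b2"), 2),
             log_scale = log_scales, stringsAsFactors = FALSE)
}

test_that("balanced noise-free offsets equal mean log differences (both dialects)", {
  # one group scaled x2: its offset must be ln 2, everything else 0
  tab <- make_balanced_table(groups = groups_2x2(c(0, 0, 0, log(2))))
  for (d in c("ols", "glm")) {
    m <- fit_scaling_model(tab, dialect = d, reference_strain = "WT")
    off <- coef(m)
    expect_equal(unname(off["WT:b1"]), 0)
    expect_equal(unname(off["MUT:b2"]), log(2), tolerance = 1e-6)
    expect_lt(max(abs(off[c("WT:b2", "MUT:b1")])), 1e-6)
    # oracle: difference of group means of log peak area
    logmean <- tapply(log(tab$peak_area),
                      paste(tab$mutant_id, tab$experiment_id, sep = ":"), mean)
    expect_equal(unname(off[names(logmean)]),
                 as.numeric(logmean - logmean[["WT:b1"]]), tolerance = 1e-6)
  }
})

test_that("identical samples give all-zero offsets; absent groups are named", {
  tab <- make_balanced_table(groups = groups_2x2(c(0, 0, 0, 0)))
  m <- fit_scaling_model(tab)
  expect_lt(max(abs(coef(m))), 1e-9)

  missing <- tab[!(tab$mutant_id == "MUT" & tab$experiment_id == "b2"), ]
  expect_error(fit_scaling_model(missing), "MUT:b2")
})

test_that("normalization divides by the fitted scale and is idempotent", {
  tab <- make_balanced_table(groups = groups_2x2(c(0, log(2), 0, -0.7)))
  m <- fit_scaling_model(tab, reference_strain = "WT")
  norm <- normalize_peak_areas(tab, m)
  grp <- norm$mutant_id == "WT" & norm$experiment_id == "b2"
  expect_equal(norm$peak_area[grp], tab$peak_area[grp] / 2, tolerance = 1e-9)
  # group means of log area equalize after normalization
  logmean <- tapply(log(norm$peak_area),
                    paste(norm$mutant_id, norm$experiment_id), mean)
  expect_lt(diff(range(logmean)), 1e-6)
  # refitting on normalized data finds nothing left to correct
  expect_lt(max(abs(coef(fit_scaling_model(norm)))), 1e-6)

  zero <- m
  zero$group_log_offsets[] <- 0
  expect_equal(normalize_peak_areas(tab, zero)$peak_area, tab$peak_area)
})

test_that("changed metabolites leak into one-pass offsets; exclusion removes the bias", {
  effects <- matrix(0, 12, 2, dimnames = list(sprintf("m%02d", 1:12), c("WT", "MUT")))
  effects["m01", "MUT"] <- 2  # one strongly changed metabolite, no noise
  tab <- make_balanced_table(groups = groups_2x2(c(0, 0, 0, 0)),
                             effects = effects, reps = 3)
  naive <- fit_scaling_model(tab, reference_strain = "WT")
  # the planted effect leaks into both MUT group offsets by 2/12
  expect_equal(unname(coef(naive)[c("MUT:b1", "MUT:b2")]), rep(2 / 12, 2),
               tolerance = 1e-6)
  clean <- fit_scaling_model(tab, reference_strain = "WT",
                             exclude_metabolites = "m01")
  expect_lt(max(abs(coef(clean))), 1e-9)
})

test_that("the two-stage robust fit recovers true offsets at study scale", {
  tr <- metabolome_truth(seed = 7)
  sim <- simulate_metabolome(tr)
  true_off <- log(tr$scale_factor_per_group) -
    log(tr$scale_factor_per_group[[paste0(tr$reference_strain, ":batch1")]])
  naive <- fit_scaling_model(sim$table, reference_strain = "WT")
  robust <- fit_scaling_model_robust(sim$table, reference_strain = "WT")
  expect_setequal(robust$excluded_metabolites, tr$changed_metabolites)
  err_naive <- max(abs(coef(naive)[names(true_off)] - true_off))
  err_robust <- max(abs(coef(robust)[names(true_off)] - true_off))
  expect_lt(err_robust, err_naive)
  expect_lt(err_robust, 0.05)
})

test_that("ANOVA selection controls its threshold and reports differences", {
  tr <- metabolome_truth(seed = 7)
  sim <- simulate_metabolome(tr)
  m <- fit_scaling_model(sim$table, reference_strain = "WT")
  norm <- normalize_peak_areas(sim$table, m)
  sel <- select_changed_metabolites(norm, alpha = 0.01, reference_strain = "WT")
  expect_equal(attr(sel, "n_tests"), 142L)
  expect_equal(sel$corrected_alpha, rep(0.01 / 142, 142))
  expect_setequal(sel$metabolite_id[sel$significant], tr$changed_metabolites)

  # alpha 0 -> nothing; Bonferroni monotone in alpha
  none <- select_changed_metabolites(norm, alpha = 0)
  expect_equal(sum(none$significant), 0L)
  loose <- select_changed_metabolites(norm, alpha = 0.05)
  strict <- select_changed_metabolites(norm, alpha = 0.001)
  expect_true(all(strict$metabolite_id[strict$significant] %in%
                    loose$metabolite_id[loose$significant]))

  # Holm is at least as powerful as Bonferroni at the same alpha
  holm <- select_changed_metabolites(norm, alpha = 0.01, correction = "holm")
  expect_true(all(sel$significant <= holm$significant))

  # reported per-strain differences recover the planted log fold change
  changed <- tr$changed_metabolites[1]
  hit_strain <- colnames(tr$effect_log_fold)[tr$effect_log_fold[changed, ] != 0]
  d <- sel[sel$metabolite_id == changed, paste0("diff_", hit_strain)]
  expect_equal(d, log(4), tolerance = 0.4)
})

test_that("ANOVA guards: single strain, constant metabolite", {
  tab <- make_balanced_table(groups = groups_2x2(c(0, 0, 0, 0)))
  one <- tab[tab$mutant_id == "WT", ]
  expect_error(select_changed_metabolites(one), "at least 2 strains")
  # a constant metabolite is flagged with p = 1, never significant
  sel <- select_changed_metabolites(tab, alpha = 0.5)
  expect_true(all(sel$constant))
  expect_true(all(sel$p_value == 1))
  expect_false(any(sel$significant))
})

test_that("row standardization follows the sample-sd convention", {
  expect_equal(as.numeric(row_standardize(rbind(c(1, 2, 3)))), c(-1, 0, 1))
  const <- row_standardize(rbind(c(5, 5, 5), c(1, 2, 3)))
  expect_equal(const[1, ], c(0, 0, 0))
  expect_equal(attr(const, "constant_rows"), c(TRUE, FALSE))
  # idempotence
  set.seed(3)
  m <- matrix(rnorm(40), 5, 8)
  z <- row_standardize(m)
  expect_equal(unname(row_standardize(z)), unname(z), tolerance = 1e-12)
  expect_true(all(abs(rowMeans(z)) < 1e-12))
  expect_equal(apply(z, 1, sd), rep(1, 5), tolerance = 1e-12)
  expect_error(row_standardize(matrix(1, 3, 1)), "at least 2 columns")
})

test_that("clustergram separates strain groups with opposite planted effects", {
  # two strain blocks with opposite-signed effects on half the metabolites
  set.seed(11)
  samples <- paste0(rep(c("up", "dn"), each = 3), 1:3)
  m <- matrix(rnorm(20 * 6, sd = 0.1), 20, 6,
              dimnames = list(sprintf("m%02d", 1:20), samples))
  m[1:10, 1:3] <- m[1:10, 1:3] + 2
  m[1:10, 4:6] <- m[1:10, 4:6] - 2
  cg <- clustergram(row_standardize(m))
  top_split <- cutree(cg$col_tree, k = 2)
  expect_equal(adjusted_rand(top_split, rep(1:2, each = 3)), 1)

  # column permutation relabels leaves but preserves the tree geometry
  perm <- c(4, 1, 6, 2, 5, 3)
  cg2 <- clustergram(row_standardize(m)[, perm])
  d1 <- as.matrix(cophenetic(cg$col_tree))
  d2 <- as.matrix(cophenetic(cg2$col_tree))
  expect_equal(d2[colnames(d1), colnames(d1)], d1, tolerance = 1e-12)

  small <- clustergram(matrix(c(0, 1, 10, 11), 2, 2))
  expect_equal(nrow(small$row_tree$merge), 1L)
  expect_equal(nrow(small$col_tree$merge), 1L)
  expect_error(clustergram(matrix(1:3, 3, 1)), "at least 2")
})

test_that("strain difference panels report mean log differences vs the reference", {
  tr <- metabolome_truth(seed = 13, noise_sd_log = 0, scale_range = c(1, 1))
  sim <- simulate_metabolome(tr)
  sel <- select_changed_metabolites(sim$table, reference_strain = "WT")
  panel <- strain_difference_panel(sim$table, sel, reference_strain = "WT")
  expect_setequal(unique(panel$metabolite_id), tr$changed_metabolites)
  for (i in seq_len(nrow(panel))) {
    expect_equal(panel$log_difference[i],
                 tr$effect_log_fold[panel$metabolite_id[i], panel$strain[i]],
                 tolerance = 1e-9)
  }
  # a strain identical to the reference (noise-free) has all-zero differences
  wt_like <- panel[panel$strain == "dRhlA" &
                     !panel$metabolite_id %in%
                       rownames(tr$effect_log_fold)[tr$effect_log_fold[, "dRhlA"] != 0], ]
  expect_true(all(abs(wt_like$log_difference) < 1e-9))

  empty <- sel
  empty$significant <- FALSE
  expect_equal(nrow(strain_difference_panel(sim$table, empty, "WT")), 0L)
  expect_error(strain_difference_panel(sim$table, sel, "nope"), "absent")
})

test_that("long tables pivot to matrices and read back from CSV", {
  tr <- metabolome_truth(n_metabolites = 8, n_changed = 2, seed = 2)
  sim <- simulate_metabolome(tr)
  m <- metabolite_matrix(sim$table)
  expect_equal(dim(m), c(8L, 30L))

  f <- tempfile(fileext = ".csv")
  tab <- sim$table
  tab$peak_area[1] <- -5  # corrupt one record
  write.csv(tab, f, row.names = FALSE)
  expect_message(back <- read_peak_areas(f), "dropped")
  expect_equal(nrow(back), nrow(tab) - 1L)
  unlink(f)
})
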