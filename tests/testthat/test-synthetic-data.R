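test_that("growth-curve generator covers the degenerate and exponential limits", {
  flat <- simulate_growth_curve(0, od0 = 0.05, noise_sd = 0, duration_h = 2)
  expect_true(all(flat$od == 0.05))

  r <- 0.85
  gc <- simulate_growth_curve(r, od0 = 0.001, carrying_capacity = 1e12,
                              noise_sd = 0, duration_h = 5)
  expect_equal(gc$od, 0.001 * exp(r * gc$times / 60), tolerance = 1e-9)

  a <- simulate_growth_curve(0.7, 0.002, noise_sd = 0.01, seed = 42)
  b <- simulate_growth_curve(0.7, 0.002, noise_sd = 0.01, seed = 42)
  expect_identical(a$od, b$od)
  expect_true(all(is.finite(a$od)) && all(a$od >= 0))

  expect_error(simulate_growth_curve(0.5, od0 = 0), "positive")
  expect_error(simulate_growth_curve(0.5, od0 = 2, carrying_capacity = 1), "below")
})

test_that("competition frequency update follows the logistic form", {
  expect_equal(expected_final_fraction(0.3, 0, 10), 0.3)   # neutral
  expect_equal(expected_final_fraction(0.3, 0.5, 0), 0.3)  # no generations
  expect_equal(expected_final_fraction(0.5, log(4), 1), 0.8)
  # s and g enter only through their product
  expect_equal(expected_final_fraction(0.7, 0.2, 5),
               expected_final_fraction(0.7, 1, 1))
})

test_that("competition observations are reproducible and carry the expectation", {
  tr <- competition_truth(selection_coefficient = 0.1, generations = 8,
                          sampling_depth = 500, seed = 11)
  a <- simulate_competition(tr)
  b <- simulate_competition(tr)
  expect_identical(a, b)
  expect_equal(attr(a, "expected_final_fraction"),
               expected_final_fraction(25 / 26, 0.1, 8))
  expect_setequal(a$stage, c("start", "end"))
  expect_equal(sum(a$cfu_per_ml[a$stage == "start"]), 500)
  expect_error(competition_truth(start_fraction_actor = 1), "\\(0, 1\\)")
  expect_error(competition_truth(sampling_depth = 0), ">= 1")
})

test_that("metabolome generator reproduces its stated construction", {
  # null model: no changes, no noise, all scale factors 1
  tr0 <- metabolome_truth(n_metabolites = 20, n_changed = 0,
                          scale_range = c(1, 1), noise_sd_log = 0, seed = 3)
  tab0 <- simulate_metabolome(tr0)$table
  by_strain <- tapply(tab0$peak_area, list(tab0$metabolite_id, tab0$mutant_id), mean)
  expect_true(all(abs(by_strain - by_strain[, 1]) < 1e-12))
  expect_true(all(tab0$peak_area > 0))

  # doubling one group's scale factor doubles exactly that group's areas
  tr2 <- tr0
  tr2$scale_factor_per_group[["dCbrA:batch2"]] <- 2
  tab2 <- simulate_metabolome(tr2)$table
  grp <- tab2$mutant_id == "dCbrA" & tab2$experiment_id == "batch2"
  expect_equal(tab2$peak_area[grp], 2 * tab0$peak_area[grp], tolerance = 1e-12)
  expect_equal(tab2$peak_area[!grp], tab0$peak_area[!grp])

  # fixed seed -> bitwise identical table
  tr <- metabolome_truth(seed = 5)
  expect_identical(simulate_metabolome(tr)$table, simulate_metabolome(tr)$table)

  # defaults mirror the study design: 142 metabolites, 5 strains, 2 batches,
  # 3 replicates per cell = 6 per strain
  tab <- simulate_metabolome(tr)$table
  expect_equal(length(unique(tab$metabolite_id)), 142L)
  expect_equal(length(unique(tab$mutant_id)), 5L)
  expect_equal(nrow(tab), 142L * 5L * 2L * 3L)

  expect_error(metabolome_truth(strains = character()), "non-empty")
  expect_error(metabolome_truth(reference_strain = "nope"), "must be one of")
  # reference strain carries no planted effects
  expect_true(all(tr$effect_log_fold[, tr$reference_strain] == 0))
  expect_true(all(tr$scale_factor_per_group > 0))
})

test_that("phenotype panel plants the promised cluster structure", {
  one <- simulate_phenotype_panel(n_clusters = 1, separation = 5,
                                  noise_sd = 0, seed = 2)
  chan <- c("A600", "A690", "A310", "GFP", "PVD", "F340")
  expect_true(all(apply(one[chan], 2, function(x) length(unique(x))) == 1))
  expect_equal(nrow(one), 48L)

  a <- simulate_phenotype_panel(n_clusters = 4, separation = 8, noise_sd = 1, seed = 9)
  b <- simulate_phenotype_panel(n_clusters = 4, separation = 8, noise_sd = 1, seed = 9)
  expect_identical(a, b)

  expect_error(simulate_phenotype_panel(n_clusters = 0, separation = 1, noise_sd = 1),
               ">= 1")
  expect_error(simulate_phenotype_panel(n_clusters = 49, separation = 1, noise_sd = 1),
               "exceeds")
})

test_that("generators leave the caller's RNG stream untouched", {
  set.seed(123)
  before <- .Random.seed
  invisible(simulate_metabolome(metabolome_truth(seed = 8)))
  invisible(simulate_growth_curve(0.5, 0.002, noise_sd = 0.01, seed = 8))
  expect_identical(.Random.seed, before)
})

test_that("truth parameters round-trip to a JSON sidecar", {
  f <- tempfile(fileext = ".json")
  tr <- metabolome_truth(n_metabolites = 10, n_changed = 2, seed = 4)
  write_truth_json(tr, f)
  back <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_equal(sort(back$changed_metabolites), sort(tr$changed_metabolites))
  expect_equal(back$noise_sd_log, tr$noise_sd_log)
  unlink(f)
})
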