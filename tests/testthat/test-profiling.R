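make_consensus <- function(rt, rdt, series, group_id, form,
                           n_rep = length(series[[1]])) {
  occ <- vapply(series, function(s) sum(!is.na(s)), integer(1))
  data.frame(retention_time_s = rt, drift_time_ms = rdt * 4.889,
             relative_drift_time = rdt,
             intensity_V = vapply(series, mean, 0, na.rm = TRUE),
             is_rip = FALSE, occurrence = occ, n_replicates = n_rep,
             intensity_series = I(series),
             group_id = group_id, form = form)
}

test_that("relative score follows the zero-centred signed convention", {
  expect_equal(relative_score(2, 2), list(fold = 1, score = 0))
  expect_equal(relative_score(8, 2), list(fold = 4, score = 3))
  expect_equal(relative_score(1, 4), list(fold = 0.25, score = -3))
  expect_error(relative_score(0, 1), "indoor_mean_V")
  expect_error(relative_score(1, -2), "outdoor_mean_V")
})

test_that("score is odd under fold inversion", {
  set.seed(7)
  f <- exp(stats::runif(100, -3, 3))
  s1 <- relative_score(f, 1)$score
  s2 <- relative_score(1, f)$score  # fold 1/f
  expect_equal(s1, -s2)
  expect_true(all((s1 == 0) == (f == 1)))
})

test_that("form aggregation sums scores and pools folds", {
  a <- aggregate_forms(data.frame(group_id = 1,
                                  form = c("monomer", "dimer"),
                                  fold = c(2.2, 1.8),
                                  score = c(1.2, 0.8)))
  expect_equal(a$score, 2.0)
  b <- aggregate_forms(data.frame(group_id = 2, form = "monomer",
                                  fold = 3, score = 2))
  expect_equal(b$score, 2)  # monomer-only group unchanged
  expect_equal(b$fold, 3)
  # intensity-weighted group fold when means are available
  d <- aggregate_forms(data.frame(group_id = 1,
                                  form = c("monomer", "dimer"),
                                  indoor_mean_V = c(10, 5),
                                  outdoor_mean_V = c(2, 1),
                                  fold = c(5, 5),
                                  score = c(4, 4)))
  expect_equal(d$fold, 5)
  expect_equal(d$score, 8)
})

test_that("mean group intensity averages replicate series", {
  cons <- make_consensus(rt = 73, rdt = 1.056,
                         series = list(c(2, 2, 2)),
                         group_id = 1L, form = "monomer")
  m <- mean_group_intensity(cons)
  expect_equal(m$mean_intensity_V, 2)
  # lognormal replicate scatter: mean of 31 draws at CV 0.2 stays within
  # 3 sigma of 1 (sigma = 0.2 / sqrt(31))
  set.seed(5)
  sdlog <- sqrt(log1p(0.2^2))
  s <- stats::rlnorm(31, -sdlog^2 / 2, sdlog)
  cons2 <- make_consensus(73, 1.056, list(s), 1L, "monomer")
  expect_lt(abs(mean_group_intensity(cons2)$mean_intensity_V - 1), 0.11)
})

test_that("profiles are flat when indoor equals outdoor", {
  d <- study_design(location_names = c("canteen", "outdoor"),
                    replicates_per_location = 2, replicate_cv = 0,
                    seed = 9)
  tabs <- run_small_study(d, base_amplitudes = c(`1` = 1, `7` = 1),
                          noise_sd = 0, grid = tiny_grid())
  prof <- build_profiles(tabs, lib_fix)
  expect_identical(nrow(prof), 20L)  # one indoor location x 20 groups
  expect_equal(prof$fold, rep(1, 20))
  expect_equal(prof$score, rep(0, 20))
})

test_that("materials-lab folds 5/10/15 are recovered exactly at CV 0", {
  folds <- c(`7` = 5, `17` = 10, `15` = 15)
  d <- study_design(location_names = c("materials_engineering_lab",
                                       "outdoor"),
                    replicates_per_location = 2,
                    fold_map = list(materials_engineering_lab = folds),
                    replicate_cv = 0, seed = 1)
  tabs <- run_small_study(d, base_amplitudes = c(`7` = 1, `17` = 1,
                                                 `15` = 1),
                          noise_sd = 0, grid = fast_grid())
  prof <- build_profiles(tabs, lib_fix)
  got <- prof$fold[match(c(7L, 17L, 15L), prof$group_id)]
  expect_equal(got, c(5, 10, 15), tolerance = 1e-6)
  # butanal has two forms at fold 5: group score = 2 x (5 - 1)
  expect_equal(prof$score[prof$group_id == 7L], 8, tolerance = 1e-6)
})

test_that("a three-fold enrichment is recovered from noisy replicates", {
  d <- study_design(location_names = c("electronic_engineering_building",
                                       "outdoor"),
                    replicates_per_location = 31,
                    fold_map = list(electronic_engineering_building =
                                      c(`15` = 3)),
                    replicate_cv = 0.2, seed = 7)
  tabs <- run_small_study(d, base_amplitudes = c(`15` = 1),
                          grid = fast_grid(), min_occurrence = 16L)
  prof <- build_profiles(tabs, lib_fix)
  expect_gt(prof$fold[prof$group_id == 15L], 2.7)
  expect_lt(prof$fold[prof$group_id == 15L], 3.3)
})

test_that("build_profiles validates the outdoor baseline and censors", {
  tabs <- list(indoor = make_consensus(262, 1.219, list(c(1, 1)), 20L,
                                       "monomer"))
  expect_error(build_profiles(tabs, lib_fix), "outdoor")
  # indoor-only group: normalized against the floor and flagged
  tabs$outdoor <- make_consensus(73, 1.056, list(c(1, 1)), 1L, "monomer")
  prof <- build_profiles(tabs, lib_fix, outdoor_floor = 0.01)
  row <- prof[prof$group_id == 20L, ]
  expect_true(row$censored)
  expect_equal(row$fold, 100)
  # groups absent everywhere stay at fold 1 / score 0, uncensored
  expect_equal(prof$fold[prof$group_id == 5L], 1)
  expect_false(prof$censored[prof$group_id == 5L])
})

test_that("stability report ranks locations by replicate CV", {
  # location A: CV 0.05; location B: CV 0.4 (constructed series)
  set.seed(31)
  mk <- function(cv) {
    sdlog <- sqrt(log1p(cv^2))
    make_consensus(73, 1.056,
                   list(stats::rlnorm(31, -sdlog^2 / 2, sdlog)),
                   1L, "monomer")
  }
  tabs <- list(workshop = mk(0.4), electronics_lab = mk(0.05))
  rep_ <- stability_report(tabs, lib_fix)
  expect_identical(rep_$most_stable, "electronics_lab")
  expect_identical(rep_$least_stable, "workshop")
  expect_equal(rep_$per_series$n, c(31L, 31L))
  # CV-0 series tie; ranking falls back to location name order
  tabs0 <- list(b_site = make_consensus(73, 1.056, list(rep(2, 5)), 1L,
                                        "monomer"),
                a_site = make_consensus(73, 1.056, list(rep(2, 5)), 1L,
                                        "monomer"))
  rep0 <- stability_report(tabs0, lib_fix)
  expect_equal(rep0$per_series$cv, c(0, 0))
  expect_identical(rep0$location_ranking$location, c("a_site", "b_site"))
})

test_that("stability report refuses single-replicate tables", {
  tabs <- list(a = make_consensus(73, 1.056, list(2), 1L, "monomer"))
  expect_error(stability_report(tabs, lib_fix), ">= 2 replicates")
})
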