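test_that("config validation rejects malformed probability inputs", {
  expect_error(identity_config(10, prevalence = c(cervicitis = 0.6, CIN1 = 0.3,
                                                  CIN2 = 0.2, CIN3 = 0.1,
                                                  cancer = 0.05)),
               "sum to < 1")
  cfg_args <- identity_config(10)
  bad_dist <- stats::setNames(c(0.5, 0.5, 0.1, 0, 0), age_group_labels())
  expect_error(simulation_config(
    n_women = 10, age_distribution = bad_dist,
    prevalence = cfg_args$prevalence,
    ai_reader = identity_reader(), manual_reader = identity_reader()),
    "sum to 1")
  bad <- matrix(1 / 5, 6, 5)
  bad[1, 1] <- 0.5
  expect_error(reader_model(bad), "sum to 1")
})

test_that("identical seeds give identical cohorts; different seeds differ", {
  cfg <- default_screening_config(n_women = 3000)
  a <- simulate_cohort(cfg, seed = 11)
  b <- simulate_cohort(cfg, seed = 11)
  expect_identical(a$records, b$records)
  c_ <- simulate_cohort(cfg, seed = 12)
  expect_false(identical(a$records, c_$records))
})

test_that("simulation does not disturb the caller's RNG stream", {
  set.seed(99)
  before <- .Random.seed
  invisible(simulate_cohort(default_screening_config(n_women = 100), seed = 5))
  expect_identical(.Random.seed, before)
})

test_that("perfect correlation with identical readers forces identical grades", {
  cfg <- identity_config(2000, reader_correlation = 1)
  # non-degenerate readers: blend identity with noise, same for both arms
  blur <- 0.7 * unclass(identity_reader()) + 0.3 * matrix(1 / 5, 6, 5)
  cfg$ai_reader <- cfg$manual_reader <- reader_model(blur)
  rec <- simulate_cohort(cfg, seed = 3)$records
  expect_identical(rec$ai_grade, rec$manual_grade)
})

test_that("identity readers with no unsatisfactory slides reproduce latent states", {
  cfg <- identity_config(3000, unsatisfactory_rate = 0)
  rec <- simulate_cohort(cfg, seed = 4)$records
  expected <- c(healthy = "NILM", cervicitis = "ASC-US", CIN1 = "LSIL",
                CIN2 = "ASC-H", CIN3 = "HSIL", cancer = "HSIL")
  expect_identical(rec$ai_grade, unname(expected[rec$latent_state]))
  expect_identical(rec$manual_grade, unname(expected[rec$latent_state]))
  expect_true(all(rec$adequacy == "satisfactory"))
})

test_that("default configuration encodes the programme's marginal anchors", {
  cfg <- default_screening_config()
  prof <- expected_profile(cfg)
  expect_equal(unname(prof$ai_margins["ASC-US"]), 0.034, tolerance = 0.01)
  expect_equal(prof$abnormal_fraction, 0.049, tolerance = 0.02)
  expect_equal(cfg$unsatisfactory_rate, 0.033)
  expect_equal(cfg$negative_review_fraction, 0.10)
  expect_equal(cfg$n_clusters, 83L)
  # expected CIN2+ yield close to 155 per 100,000 screened
  expect_equal(prof$cin2plus_yield_per_100k, 155, tolerance = 0.10)
  # age trend in latent disease is monotone increasing
  expect_true(all(diff(cfg$age_multipliers) > 0))
})

test_that("simulated grade margins converge to the configured expectations", {
  cfg <- default_screening_config(n_women = 200000)
  rec <- simulate_cohort(cfg, seed = 1)$records
  prof <- expected_profile(cfg)
  graded <- rec$ai_grade[!is.na(rec$ai_grade)]
  n <- length(graded)
  for (g in cytology_grades()) {
    p_hat <- mean(graded == g)
    p_exp <- unname(prof$ai_margins[g])
    se <- sqrt(p_exp * (1 - p_exp) / n)
    expect_lt(abs(p_hat - p_exp), 3 * se + 1e-12, label = g)
  }
  # abnormal fraction within 3 SE of the 4.9% anchor
  p_abn <- mean(graded != "NILM")
  expect_lt(abs(p_abn - 0.049), 3 * sqrt(0.049 * 0.951 / n) + 0.002)
  # unsatisfactory rate
  p_unsat <- mean(rec$adequacy != "satisfactory")
  expect_lt(abs(p_unsat - 0.033),
            3 * sqrt(0.033 * 0.967 / nrow(rec)))
})

test_that("abnormal cytology prevalence rises monotonically with age group", {
  rec <- simulate_cohort(default_screening_config(n_women = 200000),
                         seed = 2)$records
  rec <- rec[!is.na(rec$ai_grade), ]
  by_age <- tapply(rec$ai_grade != "NILM", rec$age_group, mean)
  by_age <- by_age[age_group_labels()]
  expect_true(all(diff(by_age) > 0))
})

test_that("cell-based AI arm agrees with the latent abnormal state", {
  cfg <- default_screening_config(n_women = 500)
  cfg$ai_mode <- "cells"
  co <- simulate_cohort(cfg, seed = 6)
  rec <- co$records
  expect_length(co$cell_scores, 500)
  sat <- rec$adequacy == "satisfactory"
  agree <- mean((rec$latent_state[sat] != "healthy") ==
                  (rec$ai_grade[sat] != "NILM"))
  expect_gte(agree, 0.99)
  # adequacy is derived from the generated cell counts (healthy slides have
  # no appended abnormal cells, so their score count is the raw cell count)
  n_cells <- lengths(co$cell_scores)
  healthy <- rec$latent_state == "healthy"
  too_few <- rec$adequacy == "too-few-cells"
  expect_true(all(n_cells[too_few & healthy] < 5000))
  expect_true(all(n_cells[sat] >= 5000))
})
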