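ref <- load_reference_tables()

test_that("per-grade detection rates match the published counts and rates", {
  hsil <- detection_rate(ref$histology, "ai", "HSIL", "CIN2+")
  expect_equal(hsil$numerator, 236)
  expect_equal(hsil$denominator, 432)
  expect_equal(round(100 * hsil$rate, 1), 54.6)
  ascus <- detection_rate(ref$histology, "ai", "ASC-US", "CIN2+")
  expect_equal(c(ascus$numerator, ascus$denominator), c(107, 2100))
  expect_equal(round(100 * ascus$rate, 1), 5.1)
  # zero numerator: rate 0 with CI lower bound 0 (Clopper-Pearson)
  long <- data.frame(histology = rep("cervicitis", 2), arm = c("ai", "manual"),
                     grade = "HSIL", count = 10)
  z <- detection_rate(histology_grade_table(long), "ai", "HSIL", "CIN2+")
  expect_equal(z$rate, 0)
  expect_equal(z$ci[1], 0)
  expect_error(detection_rate(histology_grade_table(long), "ai", "NILM"),
               "no biopsied women")
})

test_that("detection-rate intervals are exact binomial intervals", {
  dr <- detection_rate(ref$histology, "manual", "LSIL", "CIN3+")
  oracle <- stats::binom.test(dr$numerator, dr$denominator)$conf.int
  expect_equal(dr$ci, as.vector(oracle), tolerance = 1e-12)
})

test_that("trend in detection rates across grades behaves as expected", {
  dr <- detection_rates(ref$histology, "ai", "CIN2+")
  trend <- detection_trend(dr$numerator, dr$denominator)
  expect_lt(trend$p_value, 0.001)
  # flat series: no trend
  flat <- detection_trend(rep(10, 4), rep(100, 4))
  expect_equal(flat$p_value, 1)
  # strictly increasing series at n = 10^4 per grade
  inc <- detection_trend(c(100, 200, 400, 800), rep(1e4, 4))
  expect_lt(inc$p_value, 1e-6)
  # large-sample normal oracle for the chi-squared trend statistic
  num <- dr$numerator; den <- dr$denominator
  sc <- seq_along(num)
  p_bar <- sum(num) / sum(den)
  num_stat <- sum(num * sc) - sum(den * sc) * p_bar
  var_stat <- p_bar * (1 - p_bar) *
    (sum(den * sc^2) - sum(den * sc)^2 / sum(den))
  expect_equal(trend$statistic, num_stat^2 / var_stat, tolerance = 1e-8)
})

test_that("sensitivity/specificity construction matches the published accuracy table", {
  a <- sens_spec(ref$histology, "CIN2+",
                 concordant_normal = ref$components$concordant_normal)
  expect_equal(a$n_cases, 1088)
  expect_equal(a$n_negatives, 68818)
  expect_equal(round(100 * a$sens[["ai"]], 1), 90.1)
  expect_equal(round(100 * a$sens[["manual"]], 1), 84.3)
  expect_equal(round(100 * a$spec[["ai"]], 1), 94.8)
  expect_equal(round(100 * a$spec[["manual"]], 1), 95.2)
  expect_equal(round(100 * a$sens_diff_ci, 1), c(3.0, 8.6))
})

test_that("table-based and record-based accuracy agree on a synthetic cohort", {
  cfg <- default_screening_config(n_women = 30000)
  pr <- apply_protocol(simulate_cohort(cfg, seed = 10), seed = 11)
  acc <- assemble_accuracy_set(pr)
  from_records <- sens_spec(acc, "CIN2+")
  # rebuild the histology table from the biopsied records
  b <- pr$biopsied
  long <- rbind(
    data.frame(histology = b$histology, arm = "ai", grade = b$ai_grade,
               count = 1),
    data.frame(histology = b$histology, arm = "manual", grade = b$manual_grade,
               count = 1))
  ht <- histology_grade_table(stats::aggregate(count ~ ., long, sum))
  from_tables <- sens_spec(ht, "CIN2+",
                           concordant_normal = sum(acc$group == "concordant_normal"))
  expect_equal(from_records$sens, from_tables$sens, tolerance = 1e-12)
  expect_equal(from_records$spec, from_tables$spec, tolerance = 1e-12)
})

test_that("sensitivity and miss rate are complementary; concordant normals only move specificity", {
  a1 <- sens_spec(ref$histology, "CIN2+", concordant_normal = 63209)
  a2 <- sens_spec(ref$histology, "CIN2+", concordant_normal = 0)
  for (arm in c("ai", "manual")) {
    miss <- 1 - a1$sens[[arm]]
    expect_equal(a1$sens[[arm]] + miss, 1)
    expect_equal(a1$sens[[arm]], a2$sens[[arm]], tolerance = 1e-12)
    expect_false(isTRUE(all.equal(a1$spec[[arm]], a2$spec[[arm]])))
  }
})

test_that("paired OR is 1 for identical arms and recovers a known log-OR", {
  # identical arms: every biopsied woman graded the same by both, with a
  # mix of disease outcomes inside the grade
  rec <- make_records(ai_grade = rep("HSIL", 40),
                      manual_grade = rep("HSIL", 40),
                      latent_state = rep(c("CIN3", "cervicitis"), each = 20))
  rec$histology <- rec$latent_state
  fit <- paired_detection_or(rec, "HSIL", "CIN2+")
  expect_equal(fit$or, 1, tolerance = 1e-8)
})

test_that("GEE equals ordinary logistic under independence with one record per woman", {
  set.seed(41)
  n <- 2000
  x <- cbind(`(Intercept)` = 1, arm = rbinom(n, 1, 0.5))
  y <- rbinom(n, 1, stats::plogis(-1 + 0.4 * x[, "arm"]))
  gee <- gee_logit(y, x, id = seq_len(n), corstr = "independence")
  ml <- stats::glm(y ~ x[, "arm"], family = stats::binomial())
  expect_equal(unname(gee$coefficients), unname(stats::coef(ml)),
               tolerance = 1e-6)
  # and the vectorised pair path equals the general cluster loop
  id <- rep(seq_len(n / 2), each = 2)
  fast <- gee_logit(y, x, id, corstr = "exchangeable")
  slow <- cervscreen:::gee_logit_general(y, x, id, "exchangeable", 1e-10, 50)
  expect_equal(fast$coefficients, slow$coefficients, tolerance = 1e-10)
  expect_equal(fast$vcov, slow$vcov, tolerance = 1e-10)
})

test_that("paired GEE recovers a generative between-arm log-OR of 0.35", {
  set.seed(50)
  n <- 50000
  rho <- 0.5
  z1 <- rnorm(n)
  z2 <- rho * z1 + sqrt(1 - rho^2) * rnorm(n)
  y_manual <- as.numeric(stats::pnorm(z1) < stats::plogis(-1))
  y_ai <- as.numeric(stats::pnorm(z2) < stats::plogis(-1 + 0.35))
  fit <- gee_logit(c(y_ai, y_manual), cbind(1, arm = rep(1:0, each = n)),
                   id = rep(seq_len(n), 2), corstr = "exchangeable")
  se <- sqrt(fit$vcov["arm", "arm"])
  expect_lt(abs(fit$coefficients[["arm"]] - 0.35), 3 * se)
  expect_gt(fit$alpha, 0.1)  # the copula correlation is picked up
})

test_that("conditional discordant-pair odds ratio matches the b/c construction", {
  rec <- make_records(
    ai_grade = c(rep("HSIL", 23), rep("NILM", 1), rep("HSIL", 10)),
    manual_grade = c(rep("NILM", 23), rep("HSIL", 1), rep("HSIL", 10)),
    latent_state = "CIN3")
  rec$histology <- "CIN3"
  fit <- paired_detection_or(rec, "HSIL", "CIN2+", method = "conditional")
  expect_equal(fit$or, 23)
  expect_equal(fit$se, sqrt(1 / 23 + 1))
})

test_that("cluster-robust prevalence widens under real site heterogeneity only", {
  set.seed(61)
  n <- 20000
  # no cluster structure: design effect near 1
  rec <- make_records(sample(c("NILM", "ASC-US"), n, TRUE, prob = c(0.95, 0.05)),
                      rep(NA_character_, n))
  rec$cluster_id <- sample(50, n, replace = TRUE)
  flat <- cluster_prevalence(rec, "ASC-US", arm = "ai")
  expect_gt(flat$design_effect, 0.5)
  expect_lt(flat$design_effect, 1.5)
  # strong site random intercept: wider than binomial
  cfg <- default_screening_config(n_women = 50000)
  rec2 <- simulate_cohort(cfg, seed = 62)$records
  rec2 <- rec2[!is.na(rec2$ai_grade), ]
  clus <- cluster_prevalence(rec2, lsil_plus_grades(), arm = "ai")
  p <- clus$estimate
  binom_se <- sqrt(p * (1 - p) / clus$n)
  expect_gt(clus$se, binom_se)
  # single cluster falls back to binomial with a warning
  rec3 <- rec[rec$cluster_id == 1, ]
  expect_warning(single <- cluster_prevalence(rec3, "ASC-US", arm = "ai"),
                 "single cluster")
  expect_equal(single$design_effect, 1)
})
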