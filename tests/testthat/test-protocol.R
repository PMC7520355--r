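test_that("with no negative sampling the paired set is exactly the AI-abnormal set", {
  cfg <- default_screening_config(n_women = 5000)
  co <- simulate_cohort(cfg, seed = 1)
  pr <- apply_protocol(co, negative_review_fraction = 0, seed = 2)
  abn <- co$records$woman_id[!is.na(co$records$ai_grade) &
                               co$records$ai_grade != "NILM"]
  expect_setequal(pr$paired$woman_id, abn)
  expect_true(all(pr$paired$manual_read_reason == "ai-positive"))
})

test_that("referral follows the either-arm LSIL+ rule", {
  # AI-normal woman whose manual reading is ASC-H must be referred once read
  rec <- make_records(ai_grade = c("NILM", "NILM", "ASC-US", "LSIL"),
                      manual_grade = c("ASC-H", "NILM", "NILM", "LSIL"),
                      latent_state = "cervicitis")
  pr <- apply_protocol(rec, negative_review_fraction = 1, seed = 1)
  expect_equal(pr$records$referred, c(TRUE, FALSE, FALSE, TRUE))
  # ASC-US in either arm without referral means interim rescreen
  expect_equal(pr$records$follow_up,
               c("colposcopy", "routine-24m", "interim-6-12m", "colposcopy"))
  # histology only for attenders, and biopsy-negative healthy/cervicitis
  # women get the verified-negative label
  expect_equal(pr$records$histology,
               c("cervicitis", "no-biopsy", "no-biopsy", "cervicitis"))
})

test_that("fixed-seed review sampling is reproducible (golden membership)", {
  cfg <- default_screening_config(n_women = 100, seed = 7)
  co <- simulate_cohort(cfg)
  pr <- apply_protocol(co, negative_review_fraction = 0.1, seed = 42)
  expect_equal(sort(pr$paired$woman_id),
               c(10, 19, 25, 26, 47, 49, 51, 56, 69, 70, 77, 80, 90, 100))
  expect_equal(unname(pr$flow[c("unsatisfactory", "ai_abnormal",
                                "ai_normal_sampled")]),
               c(2, 5, 9))
})

test_that("flow counts are conserved at every node", {
  cfg <- default_screening_config(n_women = 20000)
  pr <- apply_protocol(simulate_cohort(cfg, seed = 3), seed = 4)
  f <- as.list(pr$flow)
  expect_equal(f$satisfactory + f$unsatisfactory, f$total)
  expect_equal(f$ai_abnormal + f$ai_normal, f$satisfactory)
  expect_equal(f$paired, f$ai_abnormal + f$ai_normal_sampled)
  expect_lte(f$referred, f$paired)
  expect_lte(f$attended, f$referred)
  expect_equal(f$biopsied, f$attended)
  # unsatisfactory records appear in no analysis set
  expect_true(all(pr$paired$adequacy == "satisfactory"))
  expect_true(all(pr$biopsied$adequacy == "satisfactory"))
})

test_that("no woman below the referral threshold in both arms is ever biopsied", {
  for (seed in 1:3) {
    cfg <- default_screening_config(n_women = 10000)
    pr <- apply_protocol(simulate_cohort(cfg, seed = seed), seed = seed + 100)
    neg <- c("NILM", "ASC-US")
    both_neg <- pr$biopsied$ai_grade %in% neg &
      (is.na(pr$biopsied$manual_grade) | pr$biopsied$manual_grade %in% neg)
    expect_equal(sum(both_neg), 0)
  }
})

test_that("each AI-normal record enters the paired set with frequency ~ f", {
  rec <- make_records(ai_grade = rep("NILM", 200),
                      manual_grade = rep("NILM", 200))
  f <- 0.3
  n_rep <- 200
  hits <- numeric(200)
  for (s in seq_len(n_rep)) {
    pr <- apply_protocol(rec, negative_review_fraction = f, seed = s)
    hits[pr$paired$woman_id] <- hits[pr$paired$woman_id] + 1
  }
  freq <- hits / n_rep
  se <- sqrt(f * (1 - f) / n_rep)
  expect_true(all(abs(freq - f) < 3 * se))
  # and the overall sampled fraction is exact for a fixed-size sample
  expect_equal(unname(pr$flow[["ai_normal_sampled"]]), round(f * 200))
})

test_that("accuracy set combines biopsied women and concordant normals", {
  cfg <- default_screening_config(n_women = 10000)
  pr <- apply_protocol(simulate_cohort(cfg, seed = 5), seed = 6)
  acc <- assemble_accuracy_set(pr)
  comp <- attr(acc, "components")
  expect_equal(nrow(acc), sum(comp))
  expect_equal(unname(comp["concordant_normal"]),
               sum(pr$paired$ai_grade == "NILM" &
                     pr$paired$manual_grade == "NILM" &
                     pr$paired$histology == "no-biopsy", na.rm = TRUE))
  # concordant normals carry NILM in both arms
  cn <- acc[acc$group == "concordant_normal", ]
  expect_true(all(cn$ai_grade == "NILM" & cn$manual_grade == "NILM"))
  # empty biopsy set: accuracy set reduces to concordant normals
  rec <- make_records(rep("NILM", 50), rep("NILM", 50))
  pr0 <- apply_protocol(rec, negative_review_fraction = 1, seed = 1)
  acc0 <- assemble_accuracy_set(pr0)
  expect_true(all(acc0$group == "concordant_normal"))
  expect_equal(nrow(acc0), 50)
})

test_that("full verification classifies every satisfactory woman", {
  cfg <- default_screening_config(n_women = 500)
  co <- simulate_cohort(cfg, seed = 8)
  pr <- apply_protocol(co, negative_review_fraction = 1,
                       attendance_rate = 1, seed = 9, verify_all = TRUE)
  acc <- assemble_accuracy_set(pr)
  n_sat <- sum(co$records$adequacy == "satisfactory")
  expect_equal(nrow(acc), n_sat)
  expect_true(all(acc$group == "biopsied"))
})

test_that("protocol rejects invalid configuration", {
  rec <- make_records("NILM", "NILM")
  expect_error(apply_protocol(rec, negative_review_fraction = 1.2),
               "config-error")
  expect_error(apply_protocol(rec, attendance_rate = -0.1), "config-error")
})
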