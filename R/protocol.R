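#' Apply the dual-arm partial-verification screening protocol
#'
#' Applies the study flow to a cohort: (1) unsatisfactory slides are
#' excluded from every analysis set; (2) all AI-abnormal slides receive a
#' manual reading, plus a simple random sample (fraction
#' `negative_review_fraction`) of AI-normal slides — manual grades of
#' unsampled AI-normal slides are masked; (3) a woman is referred iff either
#' available grade is in the LSIL+ set \{ASC-H, LSIL, HSIL\}; (4) referred
#' women attend colposcopy with probability `attendance_rate`; (5) histology
#' is revealed only for attenders (with `verify_all = TRUE` every
#' satisfactory woman is verified — the full-verification contrast);
#' non-referred women with an ASC-US reading are flagged for interim
#' rescreening in 6-12 months, the rest for routine screening in 24 months.
#'
#' @param cohort A `screening_cohort` from [simulate_cohort()], or a
#'   screening-record data frame carrying `ai_grade`, `manual_grade` (the
#'   reading the manual arm would give when asked), `adequacy`, and — for
#'   histology revelation — `latent_state` or `histology`.
#' @param negative_review_fraction Fraction of AI-normal slides manually
#'   reviewed (default from the cohort config, else 0.10).
#' @param attendance_rate Colposcopy attendance probability given referral
#'   (default from the cohort config, else 1).
#' @param seed Seed for the review sample and attendance draws.
#' @param verify_all Reveal histology for all satisfactory women regardless
#'   of referral (full verification)? Default `FALSE`.
#' @return Object of class `protocol_result`: list with `records` (all
#'   input records with protocol fields filled in), `paired` (records with
#'   both grades), `referred`, `biopsied` (histology-verified), `flow`
#'   (named counts at each node of the protocol flowchart), and the
#'   parameters used.
#' @export
apply_protocol <- function(cohort,
                           negative_review_fraction = NULL,
                           attendance_rate = NULL,
                           seed = 1L,
                           verify_all = FALSE) {
  if (inherits(cohort, "screening_cohort")) {
    records <- cohort$records
    if (is.null(negative_review_fraction)) {
      negative_review_fraction <- cohort$config$negative_review_fraction
    }
    if (is.null(attendance_rate)) {
      attendance_rate <- cohort$config$attendance_rate
    }
  } else {
    records <- cohort
    if (is.null(negative_review_fraction)) negative_review_fraction <- 0.10
    if (is.null(attendance_rate)) attendance_rate <- 1.0
  }
  if (negative_review_fraction < 0 || negative_review_fraction > 1) {
    stop("config-error: 'negative_review_fraction' must lie in [0, 1]")
  }
  if (attendance_rate < 0 || attendance_rate > 1) {
    stop("config-error: 'attendance_rate' must lie in [0, 1]")
  }
  with_sim_seed(seed, {
    n <- nrow(records)
    sat <- records$adequacy == "satisfactory" & !is.na(records$ai_grade)
    ai_abnormal <- sat & records$ai_grade != "NILM"
    ai_normal <- sat & records$ai_grade == "NILM"
    # simple random sample of AI-normal slides for manual review
    normal_idx <- which(ai_normal)
    n_sample <- round(negative_review_fraction * length(normal_idx))
    sampled <- if (n_sample > 0) sample(normal_idx, n_sample) else integer()
    read_manual <- ai_abnormal
    read_manual[sampled] <- TRUE
    records$manual_read_reason <- ifelse(
      ai_abnormal, "ai-positive",
      ifelse(seq_len(n) %in% sampled, "random-negative-sample", "none"))
    records$manual_grade[!read_manual] <- NA_character_
    # referral: either available grade in the LSIL+ set
    pos <- lsil_plus_grades()
    ai_pos <- sat & records$ai_grade %in% pos
    man_pos <- read_manual & !is.na(records$manual_grade) &
      records$manual_grade %in% pos
    records$referred <- ai_pos | man_pos
    # attendance and histology revelation
    records$attended <- records$referred &
      stats::runif(n) < attendance_rate
    reveal <- if (verify_all) sat else records$attended
    records$histology <- ifelse(
      reveal,
      ifelse(records$latent_state == "healthy", "cervicitis",
             records$latent_state),
      "no-biopsy")
    # follow-up recommendation for non-referred women
    ascus_any <- sat & !records$referred &
      ((records$ai_grade == "ASC-US") |
         (!is.na(records$manual_grade) & records$manual_grade == "ASC-US"))
    records$follow_up <- ifelse(records$referred, "colposcopy",
                                ifelse(ascus_any, "interim-6-12m",
                                       ifelse(sat, "routine-24m", "none")))
    flow <- c(total = n,
              unsatisfactory = sum(!sat),
              satisfactory = sum(sat),
              ai_abnormal = sum(ai_abnormal),
              ai_normal = sum(ai_normal),
              ai_normal_sampled = length(sampled),
              paired = sum(read_manual),
              referred = sum(records$referred),
              attended = sum(records$attended),
              biopsied = sum(records$histology != "no-biopsy"))
    structure(list(records = records,
                   paired = records[read_manual, , drop = FALSE],
                   referred = records[records$referred, , drop = FALSE],
                   biopsied = records[records$histology != "no-biopsy", ,
                                      drop = FALSE],
                   flow = flow,
                   negative_review_fraction = negative_review_fraction,
                   attendance_rate = attendance_rate,
                   verify_all = verify_all,
                   seed = seed),
              class = "protocol_result")
  })
}

#' @export
print.protocol_result <- function(x, ...) {
  cat("Screening protocol flow:\n")
  print(x$flow)
  invisible(x)
}

#' Assemble the accuracy analysis set
#'
#' The dataset behind the sensitivity/specificity construction: all
#' histology-verified women, plus the concordant-normal block — paired-read
#' women graded NILM by both arms, who enter as disease-negative without
#' verification. The three component counts (verified CIN1+, verified
#' biopsy-negative, concordant normals) are attached as attribute
#' `components`.
#'
#' @param result A `protocol_result` from [apply_protocol()].
#' @return Data frame with columns `woman_id`, `ai_grade`, `manual_grade`,
#'   `histology`, `group` (`"biopsied"` or `"concordant_normal"`), ready for
#'   [sens_spec()]; attribute `components` holds the counts.
#' @export
assemble_accuracy_set <- function(result) {
  stopifnot(inherits(result, "protocol_result"))
  biopsied <- result$biopsied
  paired <- result$paired
  conc_normal <- paired[paired$ai_grade == "NILM" &
                          !is.na(paired$manual_grade) &
                          paired$manual_grade == "NILM" &
                          paired$histology == "no-biopsy", , drop = FALSE]
  cols <- c("woman_id", "ai_grade", "manual_grade", "histology")
  b <- biopsied[, cols, drop = FALSE]
  b$group <- rep("biopsied", nrow(b))
  cn <- conc_normal[, cols, drop = FALSE]
  cn$group <- rep("concordant_normal", nrow(cn))
  out <- rbind(b, cn)
  rownames(out) <- NULL
  attr(out, "components") <- c(
    cin = sum(biopsied$histology %in% endpoint_strata("CIN1+")),
    negative = sum(biopsied$histology == "cervicitis"),
    concordant_normal = nrow(conc_normal))
  out
}
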