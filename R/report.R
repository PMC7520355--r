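#' Recompute the reference study's headline statistics from the fixture
#'
#' Runs the whole fixture-based analysis in one call: agreement statistics
#' on the paired 5x5 table (overall and per grade, unweighted and
#' linear-weighted kappa), binary collapses at the ASC-US and LSIL
#' thresholds with McNemar tests, per-grade CIN2+/CIN3+ detection rates
#' with Cochran-Armitage trend for both arms, the missed-CIN2+ discordance
#' test, sensitivity/specificity for the three endpoints under the
#' concordant-normal augmentation, and the counting identities. All values
#' are computed from the embedded fixture at call time; full precision is
#' kept, and `summary_table` additionally renders the conventional rounding
#' (one decimal for percentages, two for kappa).
#'
#' @return Object of class `reference_evaluation`: nested list with
#'   elements `agreement`, `per_grade`, `thresholds`, `detection`,
#'   `missed_cin2`, `accuracy`, `counts`, and `summary_table` (data frame
#'   of quantity, value, rounded rendering).
#' @examples
#' ev <- evaluate_reference_study()
#' ev$summary_table[1:8, ]
#' @export
evaluate_reference_study <- function() {
  ref <- load_reference_tables()
  t1 <- ref$pair_counts
  t2 <- ref$histology
  comp <- ref$components
  totals <- ref$totals

  agreement <- list(
    overall = agreement_rate(t1),
    kappa_linear = cohen_kappa(t1, weights = "linear"),
    kappa_unweighted = cohen_kappa(t1, weights = "unweighted"))
  per_grade <- lapply(stats::setNames(nm = cytology_grades()), function(g) {
    list(agreement = agreement_rate(collapse_binary(t1, g)),
         kappa = per_grade_kappa(t1, g))
  })
  thresholds <- lapply(c("ASC-US" = "ASC-US", "LSIL" = "LSIL"), function(th) {
    tab <- collapse_threshold(t1, th)
    list(table = tab,
         ai_positive = sum(tab[1, ]), manual_positive = sum(tab[, 1]),
         mcnemar = mcnemar_test(tab[1, 2], tab[2, 1]))
  })
  detection <- list()
  for (arm in c("ai", "manual")) {
    for (ep in c("CIN2+", "CIN3+")) {
      dr <- detection_rates(t2, arm, ep)
      trend <- detection_trend(dr$numerator, dr$denominator)
      detection[[paste(arm, ep)]] <- list(rates = dr, trend = trend)
    }
  }
  # CIN2+ cases graded NILM: discordant misses of the two arms
  cin2_strata <- endpoint_strata("CIN2+")
  missed_manual <- sum(t2[cin2_strata, "NILM", "manual"])
  missed_ai <- sum(t2[cin2_strata, "NILM", "ai"])
  missed_cin2 <- list(manual = missed_manual, ai = missed_ai,
                      mcnemar = mcnemar_test(missed_manual, missed_ai))
  accuracy <- lapply(c("CIN1+" = "CIN1+", "CIN2+" = "CIN2+",
                       "CIN3+" = "CIN3+"), function(ep) {
    sens_spec(t2, endpoint = ep,
              concordant_normal = comp$concordant_normal)
  })
  nilm_cell <- unclass(t1)["NILM", "NILM"]
  counts <- list(
    ai_normal_confirmation = nilm_cell / totals$ai_normal_sampled,
    accuracy_set_size = comp$cin + comp$negative + comp$concordant_normal,
    ascus_prevalence = sum(unclass(t1)["ASC-US", ]) / totals$enrolled,
    concordant_normal_gap = nilm_cell - comp$concordant_normal)

  pct <- function(x) sprintf("%.1f", 100 * x)
  rows <- list(
    c("overall agreement (%)", agreement$overall$estimate,
      pct(agreement$overall$estimate)),
    c("linear-weighted kappa", agreement$kappa_linear$kappa,
      sprintf("%.2f", agreement$kappa_linear$kappa)),
    c("unweighted kappa", agreement$kappa_unweighted$kappa,
      sprintf("%.2f", agreement$kappa_unweighted$kappa)))
  for (g in cytology_grades()) {
    rows <- c(rows, list(
      c(paste0("agreement ", g, " (%)"), per_grade[[g]]$agreement$estimate,
        pct(per_grade[[g]]$agreement$estimate)),
      c(paste0("kappa ", g), per_grade[[g]]$kappa$kappa,
        sprintf("%.2f", per_grade[[g]]$kappa$kappa))))
  }
  for (ep in names(accuracy)) {
    a <- accuracy[[ep]]
    rows <- c(rows, list(
      c(paste0("sensitivity AI ", ep, " (%)"), a$sens[["ai"]], pct(a$sens[["ai"]])),
      c(paste0("sensitivity manual ", ep, " (%)"), a$sens[["manual"]],
        pct(a$sens[["manual"]])),
      c(paste0("specificity AI ", ep, " (%)"), a$spec[["ai"]], pct(a$spec[["ai"]])),
      c(paste0("specificity manual ", ep, " (%)"), a$spec[["manual"]],
        pct(a$spec[["manual"]]))))
  }
  dr <- detection[["ai CIN2+"]]$rates
  for (i in seq_len(nrow(dr))) {
    rows <- c(rows, list(c(paste0("CIN2+ detection AI ", dr$grade[i], " (%)"),
                           dr$rate[i], pct(dr$rate[i]))))
  }
  rows <- c(rows, list(
    c("AI-normal confirmation (%)", counts$ai_normal_confirmation,
      pct(counts$ai_normal_confirmation)),
    c("accuracy-set size", counts$accuracy_set_size,
      format(counts$accuracy_set_size)),
    c("AI ASC-US prevalence (%)", counts$ascus_prevalence,
      pct(counts$ascus_prevalence))))
  summary_table <- data.frame(
    quantity = vapply(rows, `[[`, "", 1),
    value = as.numeric(vapply(rows, `[[`, "", 2)),
    rounded = vapply(rows, `[[`, "", 3),
    stringsAsFactors = FALSE)

  structure(list(agreement = agreement, per_grade = per_grade,
                 thresholds = thresholds, detection = detection,
                 missed_cin2 = missed_cin2, accuracy = accuracy,
                 counts = counts, summary_table = summary_table),
            class = "reference_evaluation")
}

#' @export
print.reference_evaluation <- function(x, ...) {
  cat("Reference-study evaluation (recomputed from the embedded fixture)\n\n")
  df <- x$summary_table
  cat(sprintf("  %-36s %s\n", df$quantity, df$rounded), sep = "")
  invisible(x)
}
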