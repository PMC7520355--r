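#' Per-grade detection rate (positive predictive value) with exact CI
#'
#' Proportion of biopsied women in one cytology grade (one arm) whose
#' histology reached the endpoint, with a Clopper-Pearson exact binomial
#' 95% interval. This is the per-grade PPV of the screening arm among
#' verified women.
#'
#' @param histo_table A [histology_grade_table()].
#' @param arm `"ai"` or `"manual"`.
#' @param grade Cytology grade label.
#' @param endpoint `"CIN1+"`, `"CIN2+"` (default) or `"CIN3+"`.
#' @param conf_level Confidence level for the exact interval.
#' @return Object of class `detection_rate`: list with `grade`, `arm`,
#'   `endpoint`, `numerator`, `denominator`, `rate`, `ci`.
#' @examples
#' t2 <- load_reference_tables()$histology
#' detection_rate(t2, "ai", "HSIL", "CIN2+")  # 236/432 = 54.6%
#' @export
detection_rate <- function(histo_table, arm = c("ai", "manual"), grade,
                           endpoint = c("CIN2+", "CIN3+", "CIN1+"),
                           conf_level = 0.95) {
  stopifnot(inherits(histo_table, "histology_grade_table"))
  arm <- match.arg(arm)
  endpoint <- match.arg(endpoint)
  match_grade(grade)
  strata <- endpoint_strata(endpoint)
  num <- sum(histo_table[strata, grade, arm])
  den <- sum(histo_table[, grade, arm])
  if (den == 0) stop("no biopsied women in grade ", grade, " (", arm, " arm)")
  ci <- stats::binom.test(num, den, conf.level = conf_level)$conf.int
  structure(list(grade = grade, arm = arm, endpoint = endpoint,
                 numerator = num, denominator = den, rate = num / den,
                 ci = as.vector(ci)),
            class = "detection_rate")
}

#' @export
print.detection_rate <- function(x, ...) {
  cat(sprintf("%s detection in %s grade (%s arm): %d/%d = %.1f%% (95%% CI %.1f-%.1f)\n",
              x$endpoint, x$grade, x$arm, as.integer(x$numerator),
              as.integer(x$denominator), 100 * x$rate,
              100 * x$ci[1], 100 * x$ci[2]))
  invisible(x)
}

#' Detection rates across the abnormal grades of one arm
#'
#' @inheritParams detection_rate
#' @param grades Grades to tabulate, in severity order (default the four
#'   abnormal grades ASC-US, LSIL, ASC-H, HSIL).
#' @return Data frame with one row per grade: numerator, denominator, rate
#'   and exact CI bounds.
#' @export
detection_rates <- function(histo_table, arm = c("ai", "manual"),
                            endpoint = c("CIN2+", "CIN3+", "CIN1+"),
                            grades = c("ASC-US", "LSIL", "ASC-H", "HSIL")) {
  arm <- match.arg(arm)
  endpoint <- match.arg(endpoint)
  rows <- lapply(grades, function(g)
    detection_rate(histo_table, arm, g, endpoint))
  data.frame(grade = grades,
             arm = arm,
             endpoint = endpoint,
             numerator = vapply(rows, `[[`, 0, "numerator"),
             denominator = vapply(rows, `[[`, 0, "denominator"),
             rate = vapply(rows, `[[`, 0, "rate"),
             ci_low = vapply(rows, function(r) r$ci[1], 0),
             ci_high = vapply(rows, function(r) r$ci[2], 0))
}

#' Cochran-Armitage trend test over ordered detection rates
#'
#' Tests for a monotone trend in the endpoint proportion across cytology
#' grades ordered by severity, with equally spaced scores
#' (chi-squared trend test on proportions, two-sided).
#'
#' @param numerators,denominators Integer vectors of endpoint-positive and
#'   total biopsied counts per grade, in severity order (at least 3 grades).
#' @return List with `statistic` (1-df chi-squared), `p_value`, `scores`.
#' @export
detection_trend <- function(numerators, denominators) {
  stopifnot(length(numerators) == length(denominators),
            length(numerators) >= 3)
  if (length(unique(numerators / denominators)) == 1L) {
    return(list(statistic = 0, p_value = 1,
                scores = seq_along(numerators)))
  }
  tt <- stats::prop.trend.test(numerators, denominators)
  list(statistic = unname(tt$statistic), p_value = tt$p.value,
       scores = seq_along(numerators))
}

#' Sensitivity and specificity under the partial-verification design
#'
#' Computes, per arm, sensitivity and specificity at the LSIL+ referral
#' threshold under the study's construction: cases are histology-verified
#' endpoint-positive women; the negative group is histology-verified
#' endpoint-negative women plus the concordant-normal block (women graded
#' NILM by both arms, counted disease-negative without verification, and
#' counted screen-negative in both arms). Sensitivity counts cases graded
#' in \{ASC-H, LSIL, HSIL\}; specificity counts negatives graded in
#' \{NILM, ASC-US\} (below the referral threshold). Wald intervals per arm;
#' the arm difference uses an independent-samples Wald interval.
#'
#' @param x A [histology_grade_table()] (with `concordant_normal` supplied),
#'   or an accuracy-set data frame from [assemble_accuracy_set()].
#' @param endpoint `"CIN1+"`, `"CIN2+"` (default) or `"CIN3+"`.
#' @param ... Passed to methods.
#' @return Object of class `accuracy_result`: list with `endpoint`,
#'   per-arm `sens`/`spec` estimates and CIs, `sens_diff`/`spec_diff`
#'   (AI minus manual) with CIs, and the group sizes.
#' @examples
#' ref <- load_reference_tables()
#' sens_spec(ref$histology, endpoint = "CIN2+",
#'           concordant_normal = ref$components$concordant_normal)
#' @export
sens_spec <- function(x, endpoint = c("CIN2+", "CIN3+", "CIN1+"), ...) {
  UseMethod("sens_spec")
}

#' @rdname sens_spec
#' @param concordant_normal Count of women graded NILM by both arms,
#'   appended unverified to the negative group.
#' @param conf_level Confidence level.
#' @export
sens_spec.histology_grade_table <- function(x,
                                            endpoint = c("CIN2+", "CIN3+", "CIN1+"),
                                            concordant_normal,
                                            conf_level = 0.95, ...) {
  endpoint <- match.arg(endpoint)
  stopifnot(is.numeric(concordant_normal), concordant_normal >= 0)
  case_strata <- endpoint_strata(endpoint)
  neg_strata <- setdiff(dimnames(x)$histology, case_strata)
  pos_grades <- lsil_plus_grades()
  neg_grades <- setdiff(cytology_grades(), pos_grades)
  n_cases <- sum(x[case_strata, , "ai"])
  n_neg <- sum(x[neg_strata, , "ai"]) + concordant_normal
  per_arm <- lapply(c(ai = "ai", manual = "manual"), function(arm) {
    tp <- sum(x[case_strata, pos_grades, arm])
    tn <- sum(x[neg_strata, neg_grades, arm]) + concordant_normal
    list(tp = tp, tn = tn)
  })
  build_accuracy_result(endpoint, per_arm, n_cases, n_neg,
                        concordant_normal, conf_level)
}

#' @rdname sens_spec
#' @export
sens_spec.data.frame <- function(x, endpoint = c("CIN2+", "CIN3+", "CIN1+"),
                                 conf_level = 0.95, ...) {
  endpoint <- match.arg(endpoint)
  stopifnot(all(c("ai_grade", "manual_grade", "histology", "group") %in% names(x)))
  case_strata <- endpoint_strata(endpoint)
  is_case <- x$group == "biopsied" & x$histology %in% case_strata
  pos_grades <- lsil_plus_grades()
  n_cases <- sum(is_case)
  n_neg <- sum(!is_case)
  if (n_cases == 0 || n_neg == 0) {
    stop("empty case or negative group for endpoint ", endpoint)
  }
  per_arm <- lapply(c(ai = "ai", manual = "manual"), function(arm) {
    g <- if (arm == "ai") x$ai_grade else x$manual_grade
    # concordant normals carry NILM in both arms by construction
    list(tp = sum(is_case & g %in% pos_grades, na.rm = TRUE),
         tn = sum(!is_case & !(g %in% pos_grades), na.rm = TRUE))
  })
  build_accuracy_result(endpoint, per_arm, n_cases, n_neg,
                        sum(x$group == "concordant_normal"), conf_level)
}

build_accuracy_result <- function(endpoint, per_arm, n_cases, n_neg,
                                  concordant_normal, conf_level) {
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  wald <- function(p, n) pmin(pmax(p + c(-1, 1) * z * sqrt(p * (1 - p) / n), 0), 1)
  sens <- vapply(per_arm, function(a) a$tp / n_cases, 0)
  spec <- vapply(per_arm, function(a) a$tn / n_neg, 0)
  diff_ci <- function(p1, p2, n) {
    se <- sqrt(p1 * (1 - p1) / n + p2 * (1 - p2) / n)
    (p1 - p2) + c(-1, 1) * z * se
  }
  structure(list(
    endpoint = endpoint,
    n_cases = n_cases, n_negatives = n_neg,
    concordant_normal = concordant_normal,
    sens = sens,
    sens_ci = list(ai = wald(sens[["ai"]], n_cases),
                   manual = wald(sens[["manual"]], n_cases)),
    spec = spec,
    spec_ci = list(ai = wald(spec[["ai"]], n_neg),
                   manual = wald(spec[["manual"]], n_neg)),
    sens_diff = sens[["ai"]] - sens[["manual"]],
    sens_diff_ci = diff_ci(sens[["ai"]], sens[["manual"]], n_cases),
    spec_diff = spec[["ai"]] - spec[["manual"]],
    spec_diff_ci = diff_ci(spec[["ai"]], spec[["manual"]], n_neg)),
    class = "accuracy_result")
}

#' @export
print.accuracy_result <- function(x, ...) {
  cat(sprintf("%s accuracy at the LSIL+ threshold (%d cases, %d negatives incl. %d concordant normals)\n",
              x$endpoint, as.integer(x$n_cases), as.integer(x$n_negatives),
              as.integer(x$concordant_normal)))
  for (arm in c("ai", "manual")) {
    cat(sprintf("  %-6s sensitivity %.1f%% (%.1f-%.1f)  specificity %.1f%% (%.1f-%.1f)\n",
                arm, 100 * x$sens[[arm]], 100 * x$sens_ci[[arm]][1],
                100 * x$sens_ci[[arm]][2], 100 * x$spec[[arm]],
                100 * x$spec_ci[[arm]][1], 100 * x$spec_ci[[arm]][2]))
  }
  cat(sprintf("  difference (AI - manual): sensitivity %.1f (%.1f-%.1f), specificity %.1f (%.1f-%.1f)\n",
              100 * x$sens_diff, 100 * x$sens_diff_ci[1], 100 * x$sens_diff_ci[2],
              100 * x$spec_diff, 100 * x$spec_diff_ci[1], 100 * x$spec_diff_ci[2]))
  invisible(x)
}

#' Paired-arm odds ratio of detection within a cytology grade
#'
#' Compares, for one cytology grade, the odds of the histology endpoint
#' among biopsied women placed in that grade by the AI arm versus by the
#' manual arm. Each woman contributes one observation per arm that assigned
#' her the grade, and the two observations share her histology, so women
#' are the clusters: the default method is a logistic GEE with exchangeable
#' working correlation and robust sandwich variance ([gee_logit()]),
#' optionally adjusted for age group. The `"conditional"` method uses only
#' discordant endpoint-positive women (in the grade under exactly one arm):
#' OR = b/c with a log-scale Wald interval.
#'
#' @param records Screening-record data frame with both grades, histology,
#'   and (for `age_adjust`) `age_group`.
#' @param grade Cytology grade label.
#' @param endpoint Histology endpoint.
#' @param age_adjust Add age-group indicator covariates? Default `FALSE`.
#' @param method `"gee-exchangeable"` or `"conditional"`.
#' @param conf_level Confidence level.
#' @return Object of class `paired_effect`: list with `or`, `ci`,
#'   `log_or`, `se`, `method`, `n_obs`, `n_women`.
#' @export
paired_detection_or <- function(records, grade,
                                endpoint = c("CIN2+", "CIN3+", "CIN1+"),
                                age_adjust = FALSE,
                                method = c("gee-exchangeable", "conditional"),
                                conf_level = 0.95) {
  endpoint <- match.arg(endpoint)
  method <- match.arg(method)
  match_grade(grade)
  strata <- endpoint_strata(endpoint)
  biopsied <- records[!is.na(records$histology) &
                        records$histology != "no-biopsy", , drop = FALSE]
  in_ai <- !is.na(biopsied$ai_grade) & biopsied$ai_grade == grade
  in_manual <- !is.na(biopsied$manual_grade) & biopsied$manual_grade == grade
  y_disease <- biopsied$histology %in% strata
  if (method == "conditional") {
    b <- sum(y_disease & in_ai & !in_manual)
    cc <- sum(y_disease & !in_ai & in_manual)
    if (b == 0 || cc == 0) {
      stop("no discordant information: cannot estimate a conditional odds ratio")
    }
    log_or <- log(b / cc)
    se <- sqrt(1 / b + 1 / cc)
    z <- stats::qnorm(1 - (1 - conf_level) / 2)
    return(structure(list(or = b / cc, ci = exp(log_or + c(-1, 1) * z * se),
                          log_or = log_or, se = se, method = method,
                          n_obs = b + cc, n_women = b + cc),
                     class = "paired_effect"))
  }
  rows <- rbind(
    data.frame(id = biopsied$woman_id[in_ai], arm = 1,
               y = as.numeric(y_disease[in_ai]),
               age_group = biopsied$age_group[in_ai]),
    data.frame(id = biopsied$woman_id[in_manual], arm = 0,
               y = as.numeric(y_disease[in_manual]),
               age_group = biopsied$age_group[in_manual]))
  if (nrow(rows) == 0) stop("no biopsied women in grade ", grade)
  x <- cbind(`(Intercept)` = 1, arm = rows$arm)
  if (age_adjust) {
    ag <- factor(rows$age_group)
    if (nlevels(ag) > 1) {
      x <- cbind(x, stats::model.matrix(~ ag)[, -1, drop = FALSE])
    }
  }
  fit <- gee_logit(rows$y, x, rows$id, corstr = "exchangeable")
  log_or <- fit$coefficients[["arm"]]
  # fully concordant arms leave a robust variance of exactly zero, which can
  # land a hair below zero in floating point
  se <- sqrt(max(fit$vcov["arm", "arm"], 0))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  structure(list(or = exp(log_or), ci = exp(log_or + c(-1, 1) * z * se),
                 log_or = log_or, se = se, method = method,
                 n_obs = nrow(rows), n_women = fit$n_clusters,
                 fit = fit),
            class = "paired_effect")
}

#' @export
print.paired_effect <- function(x, ...) {
  cat(sprintf("Paired detection OR (AI vs manual, %s): %.2f (95%% CI %.2f-%.2f)\n",
              x$method, x$or, x$ci[1], x$ci[2]))
  invisible(x)
}

#' Cluster-aware prevalence of a cytology grade set
#'
#' Prevalence of a grade set in one arm among satisfactorily screened women,
#' with a cluster-robust (between-site) variance: screening sites are
#' primary sampling units, so the variance uses between-cluster variation
#' of cluster totals. The design effect is the ratio of the cluster-robust
#' variance to the simple binomial variance.
#'
#' @param records Screening-record data frame with `cluster_id` and the
#'   arm's grade column.
#' @param grades Character vector of grades counted as positive.
#' @param arm `"ai"` or `"manual"`.
#' @param conf_level Confidence level.
#' @return Object of class `prevalence_result`: list with `estimate`, `se`,
#'   `ci`, `design_effect`, `n`, `n_clusters`.
#' @export
cluster_prevalence <- function(records, grades, arm = c("ai", "manual"),
                               conf_level = 0.95) {
  arm <- match.arg(arm)
  g <- if (arm == "ai") records$ai_grade else records$manual_grade
  keep <- !is.na(g)
  g <- g[keep]
  cl <- records$cluster_id[keep]
  n <- length(g)
  if (n == 0) stop("no graded records for arm ", arm)
  pos <- as.numeric(g %in% grades)
  p <- mean(pos)
  y_k <- tapply(pos, cl, sum)
  n_k <- tapply(pos, cl, length)
  k <- length(y_k)
  var_bin <- p * (1 - p) / n
  if (k < 2) {
    warning("single cluster: falling back to binomial variance")
    v <- var_bin
    deff <- 1
  } else {
    v <- k / (k - 1) * sum((y_k - p * n_k)^2) / n^2
    deff <- if (var_bin > 0) v / var_bin else 1
  }
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  structure(list(estimate = p, se = sqrt(v),
                 ci = pmin(pmax(p + c(-1, 1) * z * sqrt(v), 0), 1),
                 design_effect = deff, n = n, n_clusters = k),
            class = "prevalence_result")
}

#' @export
print.prevalence_result <- function(x, ...) {
  cat(sprintf("Prevalence %.2f%% (95%% CI %.2f-%.2f), design effect %.2f, %d clusters, n = %d\n",
              100 * x$estimate, 100 * x$ci[1], 100 * x$ci[2],
              x$design_effect, as.integer(x$n_clusters), as.integer(x$n)))
  invisible(x)
}
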