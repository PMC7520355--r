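#' Cytology grade levels (The Bethesda System)
#'
#' The five TBS reporting categories used throughout the package, in the
#' display order of the paired classification table: NILM, ASC-US, ASC-H,
#' LSIL, HSIL. Clinical severity does not coincide with display order
#' (ASC-H sits between LSIL and HSIL in severity); severity-based operations
#' use [grade_severity()] instead of position.
#'
#' @return Character vector of the five grade labels.
#' @seealso [grade_severity()], [lsil_plus_grades()]
#' @export
cytology_grades <- function() {
  c("NILM", "ASC-US", "ASC-H", "LSIL", "HSIL")
}

#' Histology outcome levels
#'
#' Biopsy outcomes ordered by severity. `"no-biopsy"` marks women without
#' histological verification and is never treated as disease-negative;
#' `"cervicitis"` is the biopsy-confirmed negative class (only verified women
#' can receive it).
#'
#' @return Character vector of the six histology labels.
#' @export
histology_grades <- function() {
  c("no-biopsy", "cervicitis", "CIN1", "CIN2", "CIN3", "cancer")
}

#' Clinical severity rank of cytology grades
#'
#' NILM < ASC-US < LSIL = ASC-H < HSIL. ASC-H ("cannot exclude HSIL") and
#' LSIL share the referral tier: both trigger immediate colposcopy.
#'
#' @param grade Character vector of grade labels.
#' @return Integer severity ranks (0 = NILM ... 3 = HSIL).
#' @export
grade_severity <- function(grade) {
  sev <- c("NILM" = 0L, "ASC-US" = 1L, "LSIL" = 2L, "ASC-H" = 2L, "HSIL" = 3L)
  out <- unname(sev[match(grade, names(sev))])
  if (anyNA(out) && !anyNA(grade)) {
    stop("unknown cytology grade: ",
         paste(setdiff(grade, names(sev)), collapse = ", "))
  }
  out
}

#' Referral-positive (LSIL+) grade set
#'
#' Grades that trigger immediate colposcopy referral: ASC-H, LSIL and HSIL.
#' ASC-US is managed by interim rescreening, not referral.
#'
#' @return Character vector of the three referral-positive labels.
#' @export
lsil_plus_grades <- function() {
  c("ASC-H", "LSIL", "HSIL")
}

match_grade <- function(grade) {
  i <- match(grade, cytology_grades())
  if (is.na(i)) stop("unknown cytology grade: ", grade)
  i
}

#' Paired 5x5 cytology grade table
#'
#' Container for the joint classification of the same slides by the AI arm
#' (rows) and the manual arm (columns) on the five TBS grades.
#'
#' @param counts 5x5 matrix of non-negative integer counts; dimnames, if
#'   present, must match [cytology_grades()] in order.
#' @return An object of class `paired_grade_table`: the count matrix with
#'   canonical dimnames and attribute `n` (total count).
#' @examples
#' tab <- paired_grade_table(diag(5) * 100)
#' agreement_rate(tab)
#' @export
paired_grade_table <- function(counts) {
  counts <- as.matrix(counts)
  if (!all(dim(counts) == c(5L, 5L))) {
    stop("'counts' must be a 5x5 matrix")
  }
  if (anyNA(counts) || any(counts < 0) || any(counts != round(counts))) {
    stop("'counts' must be non-negative integers")
  }
  g <- cytology_grades()
  if (!is.null(dimnames(counts))) {
    if (!identical(unname(rownames(counts)), g) ||
        !identical(unname(colnames(counts)), g)) {
      stop("dimnames must match cytology_grades() in order")
    }
  }
  storage.mode(counts) <- "double"
  dimnames(counts) <- list(ai = g, manual = g)
  structure(counts, n = sum(counts), class = c("paired_grade_table", "matrix"))
}

#' @export
print.paired_grade_table <- function(x, ...) {
  cat("Paired cytology grade table (AI rows x manual columns), n =",
      format(attr(x, "n"), big.mark = ","), "\n")
  print(unclass(x)[, ], ...)
  invisible(x)
}

#' Tabulate paired grades from record-level data
#'
#' Builds the paired 5x5 table from screening records, using only records
#' where both arms' grades are present (the double-read set).
#'
#' @param records Screening-record data frame (see [read_screening_records()]
#'   for the schema); needs columns `ai_grade` and `manual_grade`.
#' @return A [paired_grade_table()].
#' @export
tabulate_paired_grades <- function(records) {
  keep <- !is.na(records$ai_grade) & !is.na(records$manual_grade)
  g <- cytology_grades()
  tab <- table(factor(records$ai_grade[keep], levels = g),
               factor(records$manual_grade[keep], levels = g))
  paired_grade_table(unclass(tab))
}

#' Collapse a paired table to one-vs-rest for a single grade
#'
#' Dichotomises both arms as `grade` versus any other grade, giving the 2x2
#' table behind the per-grade agreement rates and one-vs-rest kappas.
#'
#' @param table A [paired_grade_table()].
#' @param grade Grade label to single out.
#' @return 2x2 matrix; rows = AI (`grade`, `other`), columns = manual.
#' @examples
#' t1 <- load_reference_tables()$pair_counts
#' collapse_binary(t1, "NILM")
#' @export
collapse_binary <- function(table, grade) {
  stopifnot(inherits(table, "paired_grade_table"))
  i <- match_grade(grade)
  m <- unclass(table)
  both <- m[i, i]
  ai_only <- sum(m[i, ]) - both
  manual_only <- sum(m[, i]) - both
  neither <- sum(m) - both - ai_only - manual_only
  matrix(c(both, ai_only, manual_only, neither), nrow = 2, byrow = TRUE,
         dimnames = list(ai = c(grade, "other"), manual = c(grade, "other")))
}

#' Collapse a paired table at a severity threshold
#'
#' Dichotomises both arms as at/above versus below a severity threshold.
#' Thresholding uses clinical severity, not display order: at the LSIL
#' threshold the positive set is \{ASC-H, LSIL, HSIL\} (the referral set), at
#' the ASC-US threshold it is all abnormal grades.
#'
#' @param table A [paired_grade_table()].
#' @param threshold Grade label; must be abnormal (not NILM).
#' @return 2x2 matrix; rows = AI (`positive`, `negative`), columns = manual.
#' @export
collapse_threshold <- function(table, threshold) {
  stopifnot(inherits(table, "paired_grade_table"))
  match_grade(threshold)
  if (threshold == "NILM") {
    stop("threshold must be an abnormal grade (ASC-US or worse)")
  }
  pos <- grade_severity(cytology_grades()) >= grade_severity(threshold)
  m <- unclass(table)
  out <- matrix(c(sum(m[pos, pos]), sum(m[pos, !pos]),
                  sum(m[!pos, pos]), sum(m[!pos, !pos])),
                nrow = 2, byrow = TRUE,
                dimnames = list(ai = c("positive", "negative"),
                                manual = c("positive", "negative")))
  out
}

#' Histology-by-grade count table for both arms
#'
#' Counts of biopsied women cross-classified by histology outcome
#' (cervicitis through cancer), cytology grade, and reading arm. Both arms
#' grade the same biopsied women, so within each histology stratum the two
#' arm totals must be equal.
#'
#' @param long Data frame with columns `histology`, `arm` (`"ai"`/`"manual"`),
#'   `grade`, `count`.
#' @return Object of class `histology_grade_table`: a 5 x 5 x 2 array
#'   (histology x grade x arm).
#' @export
histology_grade_table <- function(long) {
  need <- c("histology", "arm", "grade", "count")
  if (!all(need %in% names(long))) {
    stop("'long' must have columns ", paste(need, collapse = ", "))
  }
  hist_levels <- setdiff(histology_grades(), "no-biopsy")
  if (!all(long$histology %in% hist_levels)) {
    stop("unknown histology label(s): ",
         paste(setdiff(long$histology, hist_levels), collapse = ", "))
  }
  if (!all(long$arm %in% c("ai", "manual"))) stop("arm must be 'ai' or 'manual'")
  if (!all(long$grade %in% cytology_grades())) {
    stop("unknown grade label(s): ",
         paste(setdiff(long$grade, cytology_grades()), collapse = ", "))
  }
  if (any(long$count < 0) || any(long$count != round(long$count))) {
    stop("counts must be non-negative integers")
  }
  arr <- array(0, dim = c(5, 5, 2),
               dimnames = list(histology = hist_levels,
                               grade = cytology_grades(),
                               arm = c("ai", "manual")))
  idx <- cbind(match(long$histology, hist_levels),
               match(long$grade, cytology_grades()),
               match(long$arm, c("ai", "manual")))
  arr[idx] <- arr[idx] + long$count
  ai_tot <- apply(arr[, , "ai"], 1, sum)
  man_tot <- apply(arr[, , "manual"], 1, sum)
  if (!isTRUE(all.equal(ai_tot, man_tot))) {
    stop("AI and manual totals differ within a histology stratum; ",
         "both arms must grade the same biopsied women")
  }
  structure(arr, class = c("histology_grade_table", "array"))
}

#' @export
print.histology_grade_table <- function(x, ...) {
  cat("Histology x cytology-grade counts, ",
      format(sum(x) / 2, big.mark = ","), " biopsied women per arm\n", sep = "")
  print(unclass(x)[, , ], ...)
  invisible(x)
}

#' Histology strata at or above an endpoint
#'
#' @param endpoint One of `"CIN1+"`, `"CIN2+"`, `"CIN3+"`.
#' @return Character vector of histology labels counted as cases.
#' @export
endpoint_strata <- function(endpoint = c("CIN2+", "CIN3+", "CIN1+")) {
  endpoint <- match.arg(endpoint)
  switch(endpoint,
         "CIN1+" = c("CIN1", "CIN2", "CIN3", "cancer"),
         "CIN2+" = c("CIN2", "CIN3", "cancer"),
         "CIN3+" = c("CIN3", "cancer"))
}
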