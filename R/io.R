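#' Read or write record-level screening data
#'
#' CSV schema: `woman_id, age_group, cluster_id, adequacy, ai_grade,
#' manual_grade, manual_read_reason, referred, attended, histology` (grade
#' labels as text, empty string = absent); any extra columns (such as
#' `latent_state` or `follow_up`) round-trip unchanged.
#'
#' @param path File path.
#' @return `read_screening_records()` returns the validated data frame with
#'   `NA` for absent grades.
#' @export
read_screening_records <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  need <- c("woman_id", "age_group", "cluster_id", "adequacy", "ai_grade",
            "manual_grade", "manual_read_reason", "referred", "attended",
            "histology")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop("schema error: missing column(s) ",
         paste(missing_cols, collapse = ", "))
  }
  df$woman_id <- as.integer(df$woman_id)
  df$cluster_id <- as.integer(df$cluster_id)
  df$ai_grade[df$ai_grade == ""] <- NA_character_
  df$manual_grade[df$manual_grade == ""] <- NA_character_
  df$referred <- as.logical(df$referred)
  df$attended <- as.logical(df$attended)
  for (col in c("ai_grade", "manual_grade")) {
    bad <- setdiff(stats::na.omit(unique(df[[col]])), cytology_grades())
    if (length(bad)) {
      stop("schema error in column '", col, "': unknown grade label(s) ",
           paste(bad, collapse = ", "))
    }
  }
  bad <- setdiff(unique(df$histology), histology_grades())
  if (length(bad)) {
    stop("schema error in column 'histology': unknown label(s) ",
         paste(bad, collapse = ", "))
  }
  df
}

#' @rdname read_screening_records
#' @param records Screening-record data frame.
#' @return `write_screening_records()` invisibly returns `path`.
#' @export
write_screening_records <- function(records, path) {
  out <- records
  out$ai_grade[is.na(out$ai_grade)] <- ""
  out$manual_grade[is.na(out$manual_grade)] <- ""
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read or write a paired 5x5 grade table as CSV
#'
#' Format: a header row of manual-arm grade labels, one row per AI-arm
#' grade with the label in the first column (`grade`).
#'
#' @param path File path.
#' @return `read_grade_table()` returns a [paired_grade_table()].
#' @export
read_grade_table <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(df)[1] != "grade" ||
      !identical(df$grade, cytology_grades()) ||
      !identical(names(df)[-1], cytology_grades())) {
    stop("schema error: expected a 'grade' label column and columns ",
         paste(cytology_grades(), collapse = ", "))
  }
  m <- as.matrix(df[, -1])
  rownames(m) <- df$grade
  paired_grade_table(m)
}

#' @rdname read_grade_table
#' @param table A [paired_grade_table()].
#' @export
write_grade_table <- function(table, path) {
  stopifnot(inherits(table, "paired_grade_table"))
  df <- data.frame(grade = cytology_grades(), unclass(table)[, ],
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Load the embedded reference-study fixture
#'
#' The package ships the published aggregate data of the reference
#' screening programme as plain-text fixtures: the paired 5x5 cytology
#' table, the histology-by-grade-by-arm counts for biopsied women, the
#' three accuracy-set component counts, and the programme totals (the
#' source alternates between three enrollment totals; all are shipped with
#' provenance notes rather than reconciled). Every fixture invariant is
#' re-checked on load; any violation aborts with a data-integrity error.
#'
#' @return List with `pair_counts` ([paired_grade_table()]), `histology`
#'   ([histology_grade_table()]), `components` (named list: `cin`,
#'   `negative`, `concordant_normal`), and `totals` (named list).
#' @examples
#' ref <- load_reference_tables()
#' ref$pair_counts
#' @export
load_reference_tables <- function() {
  pkg_file <- function(f) {
    p <- system.file("extdata", f, package = "cervscreen")
    if (p == "") stop("fixture-corrupt: missing extdata file ", f)
    p
  }
  t1 <- read_grade_table(pkg_file("cytology_pair_counts.csv"))
  long <- utils::read.csv(pkg_file("histology_by_grade.csv"),
                          stringsAsFactors = FALSE)
  t2 <- histology_grade_table(long)
  components <- jsonlite::read_json(pkg_file("accuracy_components.json"),
                                    simplifyVector = TRUE)
  totals <- jsonlite::read_json(pkg_file("study_totals.json"),
                                simplifyVector = TRUE)
  fail <- function(msg) stop("fixture-corrupt: ", msg)
  if (attr(t1, "n") != totals$paired_total) {
    fail("paired table total does not match the recorded total")
  }
  if (!identical(unname(rowSums(unclass(t1))),
                 as.numeric(totals$pair_row_totals)) ||
      !identical(unname(colSums(unclass(t1))),
                 as.numeric(totals$pair_col_totals))) {
    fail("paired table margins do not match the recorded margins")
  }
  per_hist <- apply(t2, c(1, 3), sum)
  if (!isTRUE(all.equal(unname(per_hist[, "ai"]), unname(per_hist[, "manual"])))) {
    fail("AI and manual totals differ within a histology stratum")
  }
  if (!identical(unname(per_hist[, "ai"]),
                 as.numeric(totals$histology_totals))) {
    fail("histology stratum totals do not match the recorded totals")
  }
  if (components$cin + components$negative + components$concordant_normal !=
      totals$accuracy_set_total) {
    fail("accuracy-set components do not sum to the recorded total")
  }
  list(pair_counts = t1, histology = t2,
       components = as.list(components), totals = as.list(totals))
}
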