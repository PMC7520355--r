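#' Aggregate per-cell prediction scores into a slide score
#'
#' The slide-level score is an exponentially rank-weighted mean of the top
#' `M` per-cell prediction scores:
#' \deqn{S = \frac{\sum_{m=1}^{M'} e^{-m} S_m}{\sum_{m=1}^{M'} e^{-m}},}
#' where \eqn{S_1 \ge S_2 \ge \dots} are the cell scores in descending order,
#' \eqn{M' = \min(M, \#\mathrm{cells})}, and ties keep input order. The fast
#' decay of \eqn{e^{-m}} makes the most abnormal-looking cells dominate, so
#' \eqn{S} behaves like a softened maximum: a handful of high-scoring cells
#' pushes the slide score up regardless of the thousands of normal cells.
#'
#' @param scores Numeric vector of per-cell prediction scores in \[0, 1\].
#' @param M Number of top-ranked cells to aggregate (default 20, the number
#'   of image patches of interest the scanner displays).
#' @return Object of class `slide_score`: list with elements `S` (the
#'   aggregated score), `M` (cells actually used), `used_scores` (descending),
#'   and `weights` (normalised, summing to 1).
#' @examples
#' aggregate_slide_score(c(0.9, 0.6, 0.3), M = 3)$S  # 0.7726
#' @export
aggregate_slide_score <- function(scores, M = 20) {
  if (length(scores) == 0) stop("'scores' must contain at least one score")
  if (anyNA(scores) || any(scores < 0) || any(scores > 1)) {
    stop("all scores must lie in [0, 1]")
  }
  if (length(M) != 1 || is.na(M) || M < 1 || M != round(M)) {
    stop("'M' must be a positive integer")
  }
  m_used <- min(M, length(scores))
  # stable descending sort: ties keep input order
  ord <- order(-scores)
  used <- scores[ord][seq_len(m_used)]
  w <- exp(-seq_len(m_used))
  w <- w / sum(w)
  structure(list(S = sum(w * used), M = m_used, used_scores = used,
                 weights = w),
            class = "slide_score")
}

#' @export
print.slide_score <- function(x, ...) {
  cat(sprintf("Slide score S = %.4f (top %d cells, exponential rank weights)\n",
              x$S, x$M))
  invisible(x)
}

#' Classify a slide score as normal or abnormal
#'
#' A slide score below 0.5 is equivalent to normal cytology; scores at or
#' above 0.5 are abnormal (only "less than 0.5" is defined as normal, so the
#' boundary falls on the abnormal side).
#'
#' @param score A `slide_score` or a bare numeric score in \[0, 1\].
#' @param threshold Normality threshold (default 0.5).
#' @return `"normal"` or `"abnormal"` (vectorised over numeric input).
#' @export
classify_slide <- function(score, threshold = 0.5) {
  s <- if (inherits(score, "slide_score")) score$S else score
  if (anyNA(s) || any(s < 0) || any(s > 1)) stop("score must lie in [0, 1]")
  ifelse(s < threshold, "normal", "abnormal")
}

#' Slide adequacy check
#'
#' A slide is unsatisfactory when it carries fewer than 5000 epithelial
#' cells (the dominant reason in practice) or when any quality flag is set
#' (stacked cells, obscured background, scant cellularity). The cell-count
#' rule takes precedence when reporting a reason.
#'
#' @param n_epithelial_cells Integer count of epithelial cells on the slide.
#' @param flags Character vector among `"stacked-cells"`,
#'   `"obscured-background"`, `"scant-cellularity"` (empty = no flags).
#' @param min_cells Adequacy threshold (default 5000).
#' @return Object of class `adequacy_status`: list with `satisfactory`
#'   (logical) and `reason` (one of the flag reasons, `"too-few-cells"`, or
#'   `"none"`).
#' @export
check_adequacy <- function(n_epithelial_cells, flags = character(),
                           min_cells = 5000) {
  allowed <- c("stacked-cells", "obscured-background", "scant-cellularity")
  if (length(flags) && !all(flags %in% allowed)) {
    stop("unknown quality flag(s): ",
         paste(setdiff(flags, allowed), collapse = ", "))
  }
  if (n_epithelial_cells < min_cells) {
    status <- list(satisfactory = FALSE, reason = "too-few-cells")
  } else if (length(flags)) {
    status <- list(satisfactory = FALSE, reason = flags[[1L]])
  } else {
    status <- list(satisfactory = TRUE, reason = "none")
  }
  structure(status, class = "adequacy_status")
}

#' @export
print.adequacy_status <- function(x, ...) {
  cat(if (x$satisfactory) "satisfactory\n"
      else paste0("unsatisfactory (", x$reason, ")\n"))
  invisible(x)
}
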