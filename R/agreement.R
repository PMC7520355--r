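#' Overall agreement rate with confidence interval
#'
#' Proportion of slides given the same grade by both arms (diagonal of the
#' paired table), with a Wald or Wilson 95% interval.
#'
#' @param table A [paired_grade_table()] or any square count matrix.
#' @param method Interval method: `"wald"` (default) or `"wilson"`.
#' @param conf_level Confidence level (default 0.95).
#' @return List with `estimate`, `ci` (length-2 vector clipped to \[0, 1\]),
#'   `n`, `method`.
#' @examples
#' agreement_rate(load_reference_tables()$pair_counts)  # 94.7% (94.5-94.8)
#' @export
agreement_rate <- function(table, method = c("wald", "wilson"),
                           conf_level = 0.95) {
  method <- match.arg(method)
  m <- unclass(as.matrix(table))
  stopifnot(nrow(m) == ncol(m))
  n <- sum(m)
  if (n == 0) stop("empty table: no paired observations")
  p <- sum(diag(m)) / n
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  ci <- if (method == "wald") {
    half <- z * sqrt(p * (1 - p) / n)
    c(p - half, p + half)
  } else {
    centre <- (p + z^2 / (2 * n)) / (1 + z^2 / n)
    half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / (1 + z^2 / n)
    c(centre - half, centre + half)
  }
  list(estimate = p, ci = pmin(pmax(ci, 0), 1), n = n, method = method)
}

#' Cohen's kappa (unweighted or linear-weighted) on a square table
#'
#' Chance-corrected agreement \eqn{\kappa = (P_o - P_e)/(1 - P_e)} with
#' agreement weights \eqn{w_{ij}}: identity weights (`"unweighted"`) or
#' linear weights \eqn{w_{ij} = 1 - |i-j|/(k-1)} on the stored category
#' order (`"linear"`), which credit near-miss ordinal disagreements. The
#' standard error is the asymptotic (Fleiss-Cohen-Everitt) non-null SE.
#'
#' @param table Square count matrix (e.g. a [paired_grade_table()] or a 2x2
#'   collapse).
#' @param weights `"unweighted"` or `"linear"`.
#' @param conf_level Confidence level for the Wald interval on kappa.
#' @return Object of class `kappa_result`: list with `kappa`, `po`, `pe`,
#'   `weights` (the w matrix), `se`, `ci`, `n`.
#' @examples
#' cohen_kappa(load_reference_tables()$pair_counts, weights = "linear")
#' @export
cohen_kappa <- function(table, weights = c("unweighted", "linear"),
                        conf_level = 0.95) {
  weights <- match.arg(weights)
  m <- unclass(as.matrix(table))
  k <- nrow(m)
  stopifnot(k == ncol(m), k >= 2)
  n <- sum(m)
  if (n == 0) stop("empty table: no paired observations")
  w <- if (weights == "unweighted") diag(k)
       else 1 - abs(outer(seq_len(k), seq_len(k), "-")) / (k - 1)
  p <- m / n
  r <- rowSums(p)
  cc <- colSums(p)
  po <- sum(w * p)
  pe <- sum(w * outer(r, cc))
  if (1 - pe <= .Machine$double.eps^0.5) {
    stop("degenerate margins: expected agreement is 1, kappa undefined")
  }
  kap <- (po - pe) / (1 - pe)
  # Fleiss, Cohen & Everitt asymptotic variance of weighted kappa
  wbar_row <- as.vector(w %*% cc)   # average weight of row i against col margin
  wbar_col <- as.vector(r %*% w)    # average weight of col j against row margin
  cross <- outer(wbar_row, wbar_col, "+")
  var_num <- sum(p * (w - cross * (1 - kap))^2) - (kap - pe * (1 - kap))^2
  se <- sqrt(max(var_num, 0) / (n * (1 - pe)^2))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  structure(list(kappa = kap, po = po, pe = pe, weights = w, se = se,
                 ci = c(kap - z * se, kap + z * se), n = n,
                 scheme = weights),
            class = "kappa_result")
}

#' @export
print.kappa_result <- function(x, ...) {
  cat(sprintf("%s kappa = %.3f (95%% CI %.3f-%.3f), Po = %.4f, Pe = %.4f, n = %d\n",
              x$scheme, x$kappa, x$ci[1], x$ci[2], x$po, x$pe, as.integer(x$n)))
  invisible(x)
}

#' One-vs-rest kappa for a single cytology grade
#'
#' Unweighted Cohen's kappa on the [collapse_binary()] 2x2 table for one
#' grade — the per-grade kappa column of the paired comparison table.
#'
#' @param table A [paired_grade_table()].
#' @param grade Grade label.
#' @inheritParams cohen_kappa
#' @return A `kappa_result` (see [cohen_kappa()]).
#' @export
per_grade_kappa <- function(table, grade, conf_level = 0.95) {
  cohen_kappa(collapse_binary(table, grade), weights = "unweighted",
              conf_level = conf_level)
}

#' McNemar's test from discordant-pair counts
#'
#' Paired comparison of the two arms at a binary cut via the discordant
#' counts: `b` = arm-1 positive / arm-2 negative, `c` = the reverse.
#' Uncorrected statistic \eqn{(b-c)^2/(b+c)}; with continuity correction
#' \eqn{(|b-c|-1)^2/(b+c)}. With no discordant pairs the p-value is 1.
#'
#' @param b,c Discordant counts.
#' @param correct Apply the continuity correction? Default `FALSE`.
#' @return Object of class `mcnemar_result`: list with `b`, `c`,
#'   `statistic`, `p_value`, `correct`.
#' @examples
#' mcnemar_test(23, 1)   # chi2 = 20.17, p = 7.1e-06
#' @export
mcnemar_test <- function(b, c, correct = FALSE) {
  if (b < 0 || c < 0 || b != round(b) || c != round(c)) {
    stop("'b' and 'c' must be non-negative integer counts")
  }
  if (b + c == 0) {
    stat <- 0
    p <- 1
  } else {
    num <- if (correct) max(abs(b - c) - 1, 0)^2 else (b - c)^2
    stat <- num / (b + c)
    p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
  }
  structure(list(b = b, c = c, statistic = stat, p_value = p,
                 correct = correct),
            class = "mcnemar_result")
}

#' @export
print.mcnemar_result <- function(x, ...) {
  cat(sprintf("McNemar%s: b = %d, c = %d, chi2 = %.3f, p = %.3g\n",
              if (x$correct) " (continuity-corrected)" else "",
              as.integer(x$b), as.integer(x$c), x$statistic, x$p_value))
  invisible(x)
}
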