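#' Latent histology states of the simulator
#'
#' The generative disease states: `healthy` women whose biopsy (if taken)
#' would be negative is split from `cervicitis`, the biopsy-confirmed
#' negative class, because only verified women can receive the latter label.
#'
#' @return Character vector of the six latent state labels.
#' @export
latent_states <- function() {
  c("healthy", "cervicitis", "CIN1", "CIN2", "CIN3", "cancer")
}

#' Reader model: grade confusion given latent state
#'
#' A row-stochastic 6x5 matrix giving P(reported TBS grade | latent state)
#' for one reading arm. An identity-like confusion (each state mapped to a
#' single grade with probability 1) reproduces latent states
#' deterministically.
#'
#' @param confusion 6x5 numeric matrix; rows = [latent_states()], columns =
#'   [cytology_grades()]; each row must sum to 1 (within 1e-8; rows are then
#'   renormalised exactly).
#' @return Object of class `reader_model`.
#' @export
reader_model <- function(confusion) {
  confusion <- as.matrix(confusion)
  if (!all(dim(confusion) == c(6, 5))) stop("'confusion' must be 6x5")
  if (anyNA(confusion) || any(confusion < 0)) {
    stop("confusion probabilities must be non-negative")
  }
  rs <- rowSums(confusion)
  if (any(abs(rs - 1) > 1e-8)) stop("confusion rows must sum to 1")
  confusion <- confusion / rs
  dimnames(confusion) <- list(state = latent_states(),
                              grade = cytology_grades())
  structure(confusion, class = c("reader_model", "matrix"))
}

#' Simulation configuration for a synthetic screening cohort
#'
#' Bundles and validates every parameter of the cohort generator. All
#' probability vectors must sum to 1 within 1e-12 (after the documented
#' renormalisations); together with `seed` the configuration fully
#' determines the simulated cohort.
#'
#' @param n_women Cohort size.
#' @param seed Integer seed; fully determines the output of
#'   [simulate_cohort()].
#' @param age_distribution Named probabilities over the five age groups
#'   `20-29 ... 60+`.
#' @param n_clusters Number of screening sites (default 83).
#' @param cluster_sd SD of the site-level random intercept on the log-odds
#'   of each latent disease state (0 disables cluster effects).
#' @param prevalence Named marginal probabilities of the five non-healthy
#'   latent states (`cervicitis`, `CIN1`, `CIN2`, `CIN3`, `cancer`);
#'   `healthy` is the remainder.
#' @param age_multipliers Positive multipliers on disease prevalence per age
#'   group; internally normalised so the population marginal equals
#'   `prevalence` (monotone increase mirrors the age-prevalence trend).
#' @param ai_reader,manual_reader [reader_model()] objects for the two arms.
#' @param reader_correlation Gaussian-copula correlation between the two
#'   arms' grade draws for the same woman, in \[0, 1\].
#' @param unsatisfactory_rate Probability a slide is unsatisfactory.
#' @param unsat_reason_probs Named probabilities over the unsatisfactory
#'   reasons (must sum to 1).
#' @param negative_review_fraction Fraction of AI-normal slides sampled for
#'   manual review (default 0.10); consumed by [apply_protocol()].
#' @param attendance_rate Probability of colposcopy attendance given
#'   referral; consumed by [apply_protocol()].
#' @param ai_mode `"reader"` draws the AI grade directly from `ai_reader`;
#'   `"cells"` generates per-cell scores from `cell_model`, aggregates them
#'   with [aggregate_slide_score()], classifies with [classify_slide()], and
#'   assigns abnormal grades from the `ai_reader` row restricted to abnormal
#'   grades.
#' @param cell_model Parameters of the per-cell score generator (see
#'   [default_cell_model()]).
#' @return Object of class `simulation_config` (a validated list).
#' @export
simulation_config <- function(n_women,
                              seed = 1L,
                              age_distribution,
                              n_clusters = 83L,
                              cluster_sd = 0.3,
                              prevalence,
                              age_multipliers = c(1, 1, 1, 1, 1),
                              ai_reader,
                              manual_reader,
                              reader_correlation = 0.9,
                              unsatisfactory_rate = 0.033,
                              unsat_reason_probs = c("too-few-cells" = 0.947,
                                                     "stacked-cells" = 0.018,
                                                     "obscured-background" = 0.018,
                                                     "scant-cellularity" = 0.017),
                              negative_review_fraction = 0.10,
                              attendance_rate = 1.0,
                              ai_mode = c("reader", "cells"),
                              cell_model = default_cell_model()) {
  ai_mode <- match.arg(ai_mode)
  stopifnot(n_women >= 1, n_clusters >= 1, cluster_sd >= 0,
            reader_correlation >= 0, reader_correlation <= 1,
            unsatisfactory_rate >= 0, unsatisfactory_rate < 1,
            negative_review_fraction >= 0, negative_review_fraction <= 1,
            attendance_rate >= 0, attendance_rate <= 1)
  groups <- age_group_labels()
  if (!identical(names(age_distribution), groups)) {
    stop("'age_distribution' must be named over ",
         paste(groups, collapse = ", "))
  }
  check_probs <- function(p, what) {
    if (any(p < 0) || abs(sum(p) - 1) > 1e-12) {
      stop("'", what, "' must be non-negative and sum to 1 (within 1e-12)")
    }
  }
  check_probs(age_distribution, "age_distribution")
  check_probs(unsat_reason_probs, "unsat_reason_probs")
  disease <- setdiff(latent_states(), "healthy")
  if (!identical(names(prevalence), disease)) {
    stop("'prevalence' must be named over ", paste(disease, collapse = ", "))
  }
  if (any(prevalence < 0) || sum(prevalence) >= 1) {
    stop("disease prevalences must be non-negative and sum to < 1")
  }
  if (length(age_multipliers) != length(groups) || any(age_multipliers <= 0)) {
    stop("'age_multipliers' must be ", length(groups), " positive values")
  }
  if (!inherits(ai_reader, "reader_model") ||
      !inherits(manual_reader, "reader_model")) {
    stop("'ai_reader' and 'manual_reader' must be reader_model objects")
  }
  # normalise so that sum_a w_a m_a = 1: population marginal == prevalence
  age_multipliers <- age_multipliers /
    sum(age_distribution * age_multipliers)
  structure(list(n_women = as.integer(n_women), seed = as.integer(seed),
                 age_distribution = age_distribution,
                 n_clusters = as.integer(n_clusters), cluster_sd = cluster_sd,
                 prevalence = prevalence, age_multipliers = age_multipliers,
                 ai_reader = ai_reader, manual_reader = manual_reader,
                 reader_correlation = reader_correlation,
                 unsatisfactory_rate = unsatisfactory_rate,
                 unsat_reason_probs = unsat_reason_probs,
                 negative_review_fraction = negative_review_fraction,
                 attendance_rate = attendance_rate,
                 ai_mode = ai_mode, cell_model = cell_model),
            class = "simulation_config")
}

#' Age group labels
#' @return The five age-group labels used throughout.
#' @export
age_group_labels <- function() {
  c("20-29", "30-39", "40-49", "50-59", "60+")
}

#' Default per-cell score model
#'
#' Cells on normal slides draw scores from a low Beta distribution; abnormal
#' slides add a Poisson number of high-scoring abnormal cells. The cell
#' count per slide is log-normal, placing about 3.1% of slides below the
#' 5000-cell adequacy threshold; rare quality flags bring the total
#' unsatisfactory fraction to about 3.3%.
#'
#' @return List of cell-model parameters.
#' @export
default_cell_model <- function() {
  list(mean_log_cells = log(9000), sd_log_cells = 0.3155,
       normal_shape = c(2, 50), abnormal_shape = c(8, 2),
       abnormal_cells_lambda = 25, flag_prob = 6e-4)
}

# run expr with a private, restored RNG state
with_sim_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Default configuration anchored to the reference screening programme
#'
#' Returns a [simulation_config()] whose marginal expectations match the
#' programme's headline figures: AI-arm abnormal cytology about 4.9%
#' (ASC-US 3.4%, LSIL 1.2%, ASC-H/HSIL 0.3%), unsatisfactory slides 3.3%
#' (94.7% of them for too few cells), 83 screening sites, 10% review of
#' AI-normal slides, and an expected CIN2+ yield of about 155 per 100,000
#' screened. Reader confusion rows for the disease states follow the
#' empirical grade distributions of verified lesions; the healthy rows are
#' solved from the target marginal grade distribution, so the expected
#' AI-arm margins equal the targets exactly. Latent disease prevalences are
#' illustrative defaults consistent with those anchors, not published
#' values.
#'
#' @param n_women Cohort size (default 200,000).
#' @param seed Seed stored in the config (default 1).
#' @return A [simulation_config()].
#' @export
default_screening_config <- function(n_women = 200000, seed = 1L) {
  eligible <- 701301
  age_counts <- c("20-29" = 30035, "30-39" = 113970, "40-49" = 253474,
                  "50-59" = 235684, "60+" = 69940)
  age_dist <- age_counts / sum(age_counts)
  # AI-arm target grade margins among eligible women (display order)
  t_ai <- c(NILM = NA, "ASC-US" = 23933, "ASC-H" = 1431, LSIL = 8438,
            HSIL = 936) / eligible
  t_ai["NILM"] <- 1 - sum(t_ai[-1])
  # manual-arm targets: AI targets scaled by the paired-table column/row
  # ratios (the two arms' relative grade frequencies on the same slides)
  t_man <- t_ai * c(NILM = NA, "ASC-US" = 22281 / 23933,
                    "ASC-H" = 1799 / 1431, LSIL = 7433 / 8438,
                    HSIL = 1234 / 936)
  t_man["NILM"] <- 1 - sum(t_man[-1])
  prevalence <- c(cervicitis = 0.012, CIN1 = 0.0025, CIN2 = 0.0005,
                  CIN3 = 0.00115, cancer = 0.00014)
  # verified-lesion grade distributions per arm (counts per histology row)
  disease_ai <- rbind(
    cervicitis = c(23, 1889, 330, 2407, 141),
    CIN1       = c(0, 104, 62, 598, 55),
    CIN2       = c(0, 34, 43, 171, 31),
    CIN3       = c(1, 65, 144, 337, 180),
    cancer     = c(0, 8, 20, 29, 25))
  disease_man <- rbind(
    cervicitis = c(217, 1900, 387, 2068, 218),
    CIN1       = c(14, 156, 73, 503, 73),
    CIN2       = c(7, 54, 43, 141, 34),
    CIN3       = c(13, 85, 139, 303, 187),
    cancer     = c(3, 9, 18, 25, 27))
  build_reader <- function(target, disease_rows) {
    disease_rows <- disease_rows / rowSums(disease_rows)
    healthy_row <- (target - colSums(prevalence * disease_rows)) /
      (1 - sum(prevalence))
    if (any(healthy_row < 0)) stop("infeasible healthy confusion row")
    reader_model(rbind(healthy = healthy_row, disease_rows))
  }
  simulation_config(
    n_women = n_women, seed = seed,
    age_distribution = age_dist,
    n_clusters = 83L, cluster_sd = 0.3,
    prevalence = prevalence,
    age_multipliers = c(0.45, 0.7, 1.0, 1.25, 1.45),
    ai_reader = build_reader(t_ai, disease_ai),
    manual_reader = build_reader(t_man, disease_man),
    reader_correlation = 0.9,
    unsatisfactory_rate = 0.033,
    negative_review_fraction = 0.10,
    attendance_rate = 1.0)
}

# bivariate standard normal CDF P(Z1 <= a, Z2 <= b) with correlation rho
pbinorm <- function(a, b, rho) {
  if (rho >= 1 - 1e-12) return(stats::pnorm(min(a, b)))
  if (abs(rho) < 1e-12) return(stats::pnorm(a) * stats::pnorm(b))
  f <- function(z) {
    stats::dnorm(z) * stats::pnorm((b - rho * z) / sqrt(1 - rho^2))
  }
  stats::integrate(f, -Inf, a, rel.tol = 1e-10)$value
}

#' Exact expected profile of a simulation configuration
#'
#' Closed-form expectations implied by a configuration (ignoring the
#' site-level random intercept, whose effect on these marginals is
#' negligible at the default variance): the AI-arm marginal grade
#' distribution, the abnormal fraction, the unsatisfactory rate, the
#' generative per-arm sensitivity for each endpoint (probability a case is
#' graded LSIL+), and the expected CIN2+ yield per 100,000 screened women
#' under either-arm referral (bivariate-normal orthant probability under
#' the reader copula) and the configured attendance rate.
#'
#' @param config A [simulation_config()].
#' @return List with `ai_margins`, `manual_margins`, `abnormal_fraction`,
#'   `unsatisfactory_rate`, `true_sens` (arm x endpoint matrix),
#'   `cin2plus_yield_per_100k`.
#' @export
expected_profile <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  p_state <- c(healthy = 1 - sum(config$prevalence), config$prevalence)
  ai_margins <- drop(p_state %*% unclass(config$ai_reader))
  manual_margins <- drop(p_state %*% unclass(config$manual_reader))
  pos <- cytology_grades() %in% lsil_plus_grades()
  sens_arm <- function(reader, endpoint) {
    strata <- endpoint_strata(endpoint)
    w <- config$prevalence[strata]
    sum(w * rowSums(unclass(reader)[strata, pos, drop = FALSE])) / sum(w)
  }
  true_sens <- sapply(c("CIN1+", "CIN2+", "CIN3+"), function(ep)
    c(ai = sens_arm(config$ai_reader, ep),
      manual = sens_arm(config$manual_reader, ep)))
  # either-arm referral probability per CIN2+ state via the grade copula
  rho <- config$reader_correlation
  either_pos <- vapply(endpoint_strata("CIN2+"), function(s) {
    p_neg_ai <- sum(unclass(config$ai_reader)[s, !pos])
    p_neg_man <- sum(unclass(config$manual_reader)[s, !pos])
    1 - pbinorm(stats::qnorm(p_neg_ai), stats::qnorm(p_neg_man), rho)
  }, 0)
  yield <- (1 - config$unsatisfactory_rate) * config$attendance_rate *
    sum(config$prevalence[endpoint_strata("CIN2+")] * either_pos)
  list(ai_margins = ai_margins, manual_margins = manual_margins,
       abnormal_fraction = unname(1 - ai_margins["NILM"]),
       unsatisfactory_rate = config$unsatisfactory_rate,
       true_sens = true_sens,
       cin2plus_yield_per_100k = 1e5 * yield)
}

# draw one grade per row of u, given latent state indices and a confusion
# matrix: inverse-CDF on the state's row cumulative probabilities
draw_grades <- function(u, state_idx, confusion) {
  cum <- t(apply(unclass(confusion), 1, cumsum))
  out <- integer(length(u))
  for (s in seq_len(nrow(cum))) {
    in_s <- state_idx == s
    if (any(in_s)) {
      out[in_s] <- findInterval(u[in_s], cum[s, -ncol(cum)]) + 1L
    }
  }
  cytology_grades()[out]
}

#' Simulate a synthetic screening cohort
#'
#' Generates `n_women` screening records: age group, screening site, latent
#' histology state (age- and site-modulated), slide adequacy, and the two
#' arms' cytology grades, correlated within woman through a shared
#' Gaussian-copula draw. In `"cells"` mode the AI arm instead generates
#' per-cell prediction scores, aggregates them with
#' [aggregate_slide_score()], classifies the slide, and assigns abnormal
#' grades from the AI reader's abnormal-grade profile. Records carry only
#' generated fields; the verification protocol is applied separately by
#' [apply_protocol()].
#'
#' @param config A [simulation_config()].
#' @param seed Seed (default `config$seed`); identical seeds give identical
#'   cohorts.
#' @return Object of class `screening_cohort`: list with `records` (one row
#'   per woman; unsatisfactory slides carry no grades), `cell_scores`
#'   (per-slide score vectors in `"cells"` mode, else `NULL`), and `config`.
#' @examples
#' cfg <- default_screening_config(n_women = 2000)
#' cohort <- simulate_cohort(cfg)
#' table(cohort$records$ai_grade)
#' @export
simulate_cohort <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "simulation_config"))
  with_sim_seed(seed, {
    n <- config$n_women
    groups <- age_group_labels()
    age_idx <- sample.int(length(groups), n, replace = TRUE,
                          prob = config$age_distribution)
    cluster_id <- sample.int(config$n_clusters, n, replace = TRUE)
    u_site <- stats::rnorm(config$n_clusters, 0, config$cluster_sd)
    # latent state: disease probabilities scaled by age, shifted on the
    # log-odds scale by the site intercept; healthy is the remainder
    mult <- config$age_multipliers[age_idx]
    q <- sapply(config$prevalence, function(pv) {
      stats::plogis(stats::qlogis(pv * mult) + u_site[cluster_id])
    })
    healthy <- 1 - rowSums(q)
    if (any(healthy <= 0)) {
      stop("config-error: disease probabilities exceed 1 for some women")
    }
    probs <- cbind(healthy, q)
    cumprob <- probs
    for (j in 2:ncol(cumprob)) cumprob[, j] <- cumprob[, j - 1] + cumprob[, j]
    r <- stats::runif(n)
    state_idx <- rowSums(r > cumprob[, -ncol(cumprob), drop = FALSE]) + 1L
    # adequacy
    reasons <- names(config$unsat_reason_probs)
    cell_scores <- NULL
    if (config$ai_mode == "reader") {
      unsat <- stats::runif(n) < config$unsatisfactory_rate
      adequacy <- rep("satisfactory", n)
      if (any(unsat)) {
        adequacy[unsat] <- sample(reasons, sum(unsat), replace = TRUE,
                                  prob = config$unsat_reason_probs)
      }
    }
    # correlated grade draws
    z1 <- stats::rnorm(n)
    rho <- config$reader_correlation
    z2 <- rho * z1 + sqrt(1 - rho^2) * stats::rnorm(n)
    u_ai <- stats::pnorm(z1)
    u_man <- stats::pnorm(z2)
    manual_grade <- draw_grades(u_man, state_idx, config$manual_reader)
    if (config$ai_mode == "reader") {
      ai_grade <- draw_grades(u_ai, state_idx, config$ai_reader)
    } else {
      cm <- config$cell_model
      n_cells <- pmax(round(stats::rlnorm(n, cm$mean_log_cells,
                                          cm$sd_log_cells)), 1)
      flagged <- stats::runif(n) < 3 * cm$flag_prob
      adequacy <- ifelse(n_cells < 5000, "too-few-cells",
                         ifelse(flagged, "stacked-cells", "satisfactory"))
      is_abnormal_state <- state_idx > 1L
      n_abn <- ifelse(is_abnormal_state,
                      1 + stats::rpois(n, cm$abnormal_cells_lambda), 0)
      cell_scores <- lapply(seq_len(n), function(i) {
        s <- stats::rbeta(n_cells[i], cm$normal_shape[1], cm$normal_shape[2])
        if (n_abn[i] > 0) {
          s <- c(stats::rbeta(n_abn[i], cm$abnormal_shape[1],
                              cm$abnormal_shape[2]), s)
        }
        s
      })
      slide_s <- vapply(cell_scores,
                        function(s) aggregate_slide_score(s, M = 20)$S, 0)
      abnormal <- classify_slide(slide_s) == "abnormal"
      # abnormal slides draw a TBS grade from the AI reader's profile
      # restricted to abnormal grades (renormalised), keeping the copula draw
      conf_abn <- unclass(config$ai_reader)[, -1, drop = FALSE]
      conf_abn <- conf_abn / rowSums(conf_abn)
      ai_grade <- rep("NILM", n)
      if (any(abnormal)) {
        cumg <- t(apply(conf_abn, 1, cumsum))
        idx <- integer(sum(abnormal))
        st <- state_idx[abnormal]
        ua <- u_ai[abnormal]
        for (s in seq_len(nrow(cumg))) {
          in_s <- st == s
          if (any(in_s)) {
            idx[in_s] <- findInterval(ua[in_s], cumg[s, -ncol(cumg)]) + 1L
          }
        }
        ai_grade[abnormal] <- cytology_grades()[-1][idx]
      }
      names(cell_scores) <- as.character(seq_len(n))
    }
    sat <- adequacy == "satisfactory"
    records <- data.frame(
      woman_id = seq_len(n),
      age_group = groups[age_idx],
      cluster_id = cluster_id,
      adequacy = adequacy,
      ai_grade = ifelse(sat, ai_grade, NA_character_),
      manual_grade = ifelse(sat, manual_grade, NA_character_),
      manual_read_reason = "none",
      referred = FALSE,
      attended = FALSE,
      histology = "no-biopsy",
      latent_state = latent_states()[state_idx],
      stringsAsFactors = FALSE)
    structure(list(records = records, cell_scores = cell_scores,
                   config = config, seed = seed),
              class = "screening_cohort")
  })
}

#' @export
print.screening_cohort <- function(x, ...) {
  cat(sprintf("Synthetic screening cohort: %d women, %d sites, seed %d (%s mode)\n",
              nrow(x$records), x$config$n_clusters, x$seed, x$config$ai_mode))
  invisible(x)
}
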