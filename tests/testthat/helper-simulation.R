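# shared builders for simulator- and protocol-level tests

# reader that maps each latent state to a single grade with certainty
identity_reader <- function() {
  m <- matrix(0, 6, 5)
  # healthy -> NILM, cervicitis -> ASC-US, CIN1 -> LSIL,
  # CIN2 -> ASC-H, CIN3 -> HSIL, cancer -> HSIL
  m[cbind(1:6, c(1, 2, 4, 3, 5, 5))] <- 1
  reader_model(m)
}

identity_config <- function(n_women, seed = 1L, unsatisfactory_rate = 0,
                            cluster_sd = 0, reader_correlation = 1,
                            prevalence = c(cervicitis = 0.05, CIN1 = 0.03,
                                           CIN2 = 0.02, CIN3 = 0.01,
                                           cancer = 0.005)) {
  simulation_config(
    n_women = n_women, seed = seed,
    age_distribution = stats::setNames(rep(0.2, 5), age_group_labels()),
    n_clusters = 5L, cluster_sd = cluster_sd,
    prevalence = prevalence,
    ai_reader = identity_reader(), manual_reader = identity_reader(),
    reader_correlation = reader_correlation,
    unsatisfactory_rate = unsatisfactory_rate)
}

# minimal hand-built screening records (pre-protocol: manual_grade holds the
# reading the manual arm would give when asked)
make_records <- function(ai_grade, manual_grade, latent_state = "healthy",
                         adequacy = "satisfactory") {
  n <- length(ai_grade)
  data.frame(
    woman_id = seq_len(n),
    age_group = rep(age_group_labels()[1], n),
    cluster_id = rep(1L, n),
    adequacy = rep_len(adequacy, n),
    ai_grade = ai_grade,
    manual_grade = manual_grade,
    manual_read_reason = "none",
    referred = FALSE,
    attended = FALSE,
    histology = "no-biopsy",
    latent_state = rep_len(latent_state, n),
    stringsAsFactors = FALSE)
}
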