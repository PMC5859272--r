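# shared builders for small test cohorts

tiny_neutral_design <- function(n_stem = 16, rate = 0.1,
                                timepoints = c(4, 7, 10, 14, 21),
                                mice = 2L, crypts = 200L,
                                labelling_mean = 1.2) {
  cohort_design(
    arms = list(truth = cohort_arm(drift_params(n_stem, rate),
                                   make_niche(n_stem, 0), "none")),
    timepoints = timepoints, mice_per_arm = mice,
    crypts_per_mouse = crypts, labelling_mean = labelling_mean,
    clones_scored_min = min(crypts, 200L))
}

two_arm_design <- function(timepoints = c(4, 21), mice = 1L, crypts = 60L,
                           labelling_mean = 1.2) {
  s <- default_drift_settings()
  base <- drift_params(s$n_stem, s$replacement_rate)
  ly <- make_niche(s$n_centre, s$n_border)
  cohort_design(
    arms = list(vehicle = cohort_arm(base, ly, "none"),
                inhibitor = cohort_arm(base, ly, "remove_border",
                                       strength = 1)),
    timepoints = timepoints, mice_per_arm = mice, crypts_per_mouse = crypts,
    labelling_mean = labelling_mean, clones_scored_min = min(crypts, 200L))
}

# independent uniformization oracle for the clone-size chain: evolves the
# distribution through the embedded jump chain with Poisson-weighted event
# counts (never calls the package's matrix-exponential or eigen paths)
uniformization_dist <- function(n_stem, lambda, bias, n0, t,
                                tol = 1e-14) {
  N <- n_stem
  rate <- 2 * lambda            # total stepping rate in transient states
  P <- diag(N + 1)
  for (n in seq_len(N - 1)) {
    P[n + 1, ] <- 0
    P[n + 1, n + 2] <- bias
    P[n + 1, n] <- 1 - bias
  }
  v <- numeric(N + 1)
  v[n0 + 1] <- 1
  out <- numeric(N + 1)
  m <- 0
  repeat {
    wm <- stats::dpois(m, rate * t)
    out <- out + wm * v
    if (m > rate * t && wm < tol) break
    v <- as.vector(v %*% P)
    m <- m + 1
  }
  out / sum(out)
}
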