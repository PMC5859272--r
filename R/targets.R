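#' Recompute the headline fixation kinetics
#'
#' Runs the documented default model (see [default_drift_settings()]) from
#' scratch and measures the four headline readouts of the Wnt-inhibition
#' clonal-fate experiment:
#' \describe{
#'   \item{t1}{percent of surviving labelled crypts fully fixed (8/8
#'     eighths) at day 21 in the inhibitor arm (border pool removed at the
#'     day-1 treatment switch).}
#'   \item{t2}{the same fraction in the vehicle arm.}
#'   \item{t3}{median time to monoclonal conversion, in 30-day months,
#'     among vehicle-arm clones that eventually fix.}
#'   \item{t4}{the day the inhibitor arm's surviving-clones-per-field count
#'     reaches its plateau (first day within 5 percent of the day-60
#'     value).}
#' }
#'
#' Labelling, treatment switch and scoring follow the default cohort
#' conventions: zero-truncated Poisson induction (mean 1.2 cells/crypt),
#' treatment from day 1, eighths scored over the competing positions,
#' fixation fractions among surviving clones.
#'
#' @param seed integer master seed.
#' @param n_crypts crypts per arm for the day-21/plateau readouts.
#' @param n_absorb vehicle crypts simulated to absorption for the fixation
#'   time.
#' @param horizon last day of the plateau scan (default 60).
#' @return named list `t1`..`t4`, each `list(value, n)`.
#' @examples
#' \donttest{reproduce_targets(seed = 1, n_crypts = 500, n_absorb = 200)}
#' @export
reproduce_targets <- function(seed = 1L, n_crypts = 10000L,
                              n_absorb = 5000L, horizon = 60) {
  s <- default_drift_settings()
  base <- drift_params(s$n_stem, s$replacement_rate)
  ly <- make_niche(s$n_centre, s$n_border)
  inhibitor <- cohort_arm(base, ly, "remove_border", strength = 1)
  vehicle <- cohort_arm(base, ly, "none")
  days <- seq(1, horizon)

  # inhibitor arm: daily survival to the horizon + day-21 eighths
  surv_count <- integer(length(days))
  fixed21 <- 0L
  surv21 <- 0L
  for (i in seq_len(n_crypts)) {
    set.seed(crypt_seed(seed, i))
    init <- make_init(s$n_stem, ly, s$labelling_mean_low)
    st <- run_crypt_states(inhibitor, init, t_grid = days,
                           treatment_day = s$treatment_day)
    sizes <- colSums(st$labels == 1L, na.rm = TRUE)
    surv_count <- surv_count + (sizes >= 1L)
    n_comp <- sum(!is.na(st$labels[, days == 21]))
    e21 <- score_eighths(sizes[days == 21], n_comp)
    if (e21 > 0L) {
      surv21 <- surv21 + 1L
      if (e21 == 8L) fixed21 <- fixed21 + 1L
    }
  }
  t1 <- 100 * fixed21 / surv21
  plateau <- days[which(surv_count <= 1.05 * surv_count[length(days)])[1]]

  # vehicle arm at day 21
  vfixed <- 0L
  vsurv <- 0L
  for (i in seq_len(n_crypts)) {
    set.seed(crypt_seed(seed, n_crypts + i))
    init <- make_init(s$n_stem, ly, s$labelling_mean_low)
    st <- run_crypt_states(vehicle, init, t_grid = 21,
                           treatment_day = s$treatment_day)
    size <- sum(st$labels[, 1] == 1L, na.rm = TRUE)
    if (size >= 1L) {
      vsurv <- vsurv + 1L
      if (size == s$n_stem) vfixed <- vfixed + 1L
    }
  }
  t2 <- 100 * vfixed / vsurv

  # vehicle arm to absorption: median fixation day among eventual fixers
  fix_times <- numeric(0)
  for (i in seq_len(n_absorb)) {
    set.seed(crypt_seed(seed, 2L * n_crypts + i))
    init <- make_init(s$n_stem, ly, s$labelling_mean_low)
    ab <- simulate_to_absorption(base, init$labels, layout = ly,
                                 t_max = 3000)
    if (identical(ab$outcome, "fixed")) fix_times <- c(fix_times, ab$time)
  }
  t3 <- median(fix_times) / 30

  list(t1 = list(value = t1, n = n_crypts),
       t2 = list(value = t2, n = n_crypts),
       t3 = list(value = t3, n = length(fix_times)),
       t4 = list(value = as.numeric(plateau), n = n_crypts))
}

#' Reproduce-and-check report
#'
#' Runs [reproduce_targets()] and checks each readout against the
#' published headline values: inhibitor-arm fixation at day 21 above 80
#' percent, vehicle below 20 percent, vehicle median fixation time of at
#' least 2 months, and an inhibitor clones-per-field plateau by day 10.
#'
#' @param seed integer master seed.
#' @param out optional path of a JSON file to write
#'   (`{"t1": {"value": ..., "n": ...}, ...}`).
#' @inheritParams reproduce_targets
#' @return tibble report (target, value, n, reference, cmp, pass) with the
#'   provenance hash as attribute.
#' @export
run_reproduce <- function(seed = 1L, out = NULL, n_crypts = 10000L,
                          n_absorb = 5000L, horizon = 60) {
  tg <- reproduce_targets(seed = seed, n_crypts = n_crypts,
                          n_absorb = n_absorb, horizon = horizon)
  ref <- c(t1 = 80, t2 = 20, t3 = 2, t4 = 10)
  cmp <- c(t1 = ">=", t2 = "<=", t3 = ">=", t4 = "<=")
  vals <- vapply(tg, `[[`, numeric(1), "value")
  pass <- ifelse(cmp == ">=", vals >= ref, vals <= ref)
  report <- tibble::tibble(
    target = names(tg), value = unname(vals),
    n = vapply(tg, `[[`, numeric(1), "n"),
    reference = unname(ref), cmp = unname(cmp), pass = unname(pass))
  attr(report, "provenance") <- new_provenance(seed, list(n_crypts,
                                                          n_absorb, horizon))
  if (!is.null(out)) {
    jsonlite::write_json(tg, out, auto_unbox = TRUE, digits = NA)
  }
  report
}
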