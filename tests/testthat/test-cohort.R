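test_that("labelling draws zero-truncated counts placed on the ring", {
  d <- tiny_neutral_design(crypts = 50L)
  inits <- generate_labelling(d, 2000, seed = 3)
  # determinism
  inits2 <- generate_labelling(d, 2000, seed = 3)
  expect_identical(inits, inits2)
  ks <- vapply(inits, `[[`, integer(1), "n_induced")
  expect_true(all(ks >= 1L))
  m_true <- ztpois_mean(1.2)
  expect_lt(abs(mean(ks) - m_true), 3 * sd(ks) / sqrt(length(ks)))
  # label count matches the induced count
  expect_equal(vapply(inits, function(x) sum(x$labels), integer(1)), ks)
  # vanishing labelling mean leaves exactly one induced cell
  d1 <- tiny_neutral_design(crypts = 50L, labelling_mean = 1e-9)
  one <- generate_labelling(d1, 300, seed = 4)
  expect_true(all(vapply(one, `[[`, integer(1), "n_induced") == 1L))
  expect_error(cohort_design(
    arms = list(a = cohort_arm(drift_params(4, 0.1), make_niche(4, 0))),
    timepoints = 4, labelling_mean = 0), "labelling_mean")
})

test_that("neutral cohorts are reproducible and structurally valid", {
  d <- two_arm_design(timepoints = c(4, 21), crypts = 60L)
  ds <- run_neutral_cohort(d, seed = 11)
  expect_s3_class(ds, "clonal_dataset")
  # every (arm, day) cell has the designed number of records
  tab <- table(ds$arm, ds$day)
  expect_true(all(tab == 60L))
  expect_false(is.null(attr(ds, "provenance")$parameter_hash))
  # flags are consistent
  expect_true(all(ds$fixed == (ds$eighths == 8L)))
  expect_true(all(ds$surviving == (ds$clone_size_cells >= 1L)))
  expect_true(all((ds$eighths == 0L) == (!ds$surviving)))
  # inhibitor records at day 21 compete over the centre pool only
  expect_true(all(ds$n_competing[ds$arm == "inhibitor" & ds$day == 21] ==
                    default_drift_settings()$n_centre))
  # byte-identical CSV on rerun
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_clonal_dataset(ds, f1)
  write_clonal_dataset(run_neutral_cohort(d, seed = 11), f2)
  expect_identical(readLines(f1), readLines(f2))
  rt <- read_clonal_dataset(f1)
  expect_equal(nrow(rt), nrow(ds))
  expect_equal(attr(rt, "provenance")$seed, "11")
})

test_that("scoring before treatment reflects the initial labelling only", {
  d <- two_arm_design(timepoints = c(1, 21), crypts = 80L)
  # replace day-1 with day-0 scoring: timepoint at induction itself
  d$timepoints <- c(0, 21)
  ds <- run_neutral_cohort(d, seed = 8)
  d0 <- ds[ds$day == 0, ]
  expect_equal(d0$clone_size_cells, d0$n_induced)
  # both arms were induced identically before treatment: same crypt counts
  expect_equal(sum(d0$arm == "vehicle"), sum(d0$arm == "inhibitor"))
})

test_that("exchangeable arms give matching summaries within noise", {
  s <- default_drift_settings()
  base <- drift_params(s$n_stem, s$replacement_rate)
  ly <- make_niche(s$n_centre, s$n_border)
  d <- cohort_design(
    arms = list(a1 = cohort_arm(base, ly, "none"),
                a2 = cohort_arm(base, ly, "none")),
    timepoints = 10, mice_per_arm = 1L, crypts_per_mouse = 1500L,
    labelling_mean = 1.2, clones_scored_min = 200L)
  ds <- run_neutral_cohort(d, seed = 13)
  s1 <- summarize_timepoint(ds[ds$arm == "a1", ])
  s2 <- summarize_timepoint(ds[ds$arm == "a2", ])
  p1 <- s1$n_surviving / s1$n_clones
  p2 <- s2$n_surviving / s2$n_clones
  se <- sqrt(p1 * (1 - p1) / 1500 + p2 * (1 - p2) / 1500)
  expect_lt(abs(p1 - p2), 3 * se)
})

test_that("vehicle clones-per-field declines progressively over the course", {
  d <- two_arm_design(timepoints = c(4, 10, 21), crypts = 800L)
  ds <- run_neutral_cohort(d, seed = 19)
  veh <- ds[ds$arm == "vehicle", ]
  cpf <- vapply(c(4, 10, 21), function(dd)
    summarize_timepoint(veh[veh$day == dd, ])$clones_per_field, numeric(1))
  expect_true(all(diff(cpf) < 0))
})

test_that("imaging cohorts condition on day-1 presence and track growth", {
  im <- run_imaging_cohort(default_imaging_design(),
                           clones_per_compartment = 400, seed = 21)
  ps <- im$persistence
  expect_true(all(ps$fraction_surviving[ps$day == 1] == 1))
  expect_true(all(tapply(ps$fraction_surviving,
                         paste(ps$arm, ps$start_compartment),
                         function(x) all(diff(x) <= 0))))
  # surviving control clones grow on average over imaging days 1-4
  ctrl <- c(im$trajectories$control$centre, im$trajectories$control$border)
  mean_surv_size <- vapply(1:4, function(day) {
    sz <- vapply(ctrl, function(tr)
      sum(tr$labels[, day] == 1L, na.rm = TRUE), numeric(1))
    mean(sz[sz > 0])
  }, numeric(1))
  expect_true(all(diff(mean_surv_size) > 0))
  # fewer border-start inhibitor clones remain at day 4 than in control
  n_at_day4 <- function(arm) {
    trs <- im$trajectories[[arm]]$border
    sum(vapply(trs, function(tr)
      sum(tr$labels[, 4] == 1L, na.rm = TRUE) >= 1L, logical(1)))
  }
  expect_lt(n_at_day4("inhibitor") / 400, n_at_day4("control") / 400)
})

test_that("Apc cohorts resolve partial crypts and respond to pool size", {
  s <- default_drift_settings()
  base <- drift_params(s$n_stem, s$replacement_rate)
  ly <- make_niche(s$n_centre, s$n_border)
  d <- cohort_design(
    arms = list(vehicle = cohort_arm(base, ly, "none"),
                inhibitor = cohort_arm(base, ly, "remove_border", 1)),
    timepoints = c(7, 21), mice_per_arm = 1L, crypts_per_mouse = 1200L,
    labelling_mean = s$labelling_mean_high, induction = "high",
    clones_scored_min = 200L)
  res <- run_apc_cohort(d, seed = 23)
  ds <- res$dataset
  n_partial <- function(arm, day)
    sum(ds$category == "partial" & ds$arm == arm & ds$day == day)
  # partial crypts resolve between day 7 and day 21
  expect_lt(n_partial("inhibitor", 21), n_partial("inhibitor", 7))
  expect_lt(n_partial("vehicle", 21), n_partial("vehicle", 7))
  # full-crypt ratio is non-decreasing in time in both arms
  for (arm in c("vehicle", "inhibitor")) {
    r7 <- full_crypt_ratio(ds$category[ds$arm == arm & ds$day == 7])
    r21 <- full_crypt_ratio(ds$category[ds$arm == arm & ds$day == 21])
    expect_gte(r21, r7)
  }
  # the reduced pool fixes more Apc-null crypts by day 21
  full21 <- function(arm)
    sum(ds$category == "full" & ds$arm == arm & ds$day == 21)
  expect_gt(full21("inhibitor"), full21("vehicle"))
  # adenoma counts come from the final timepoint
  expect_equal(sort(unique(res$adenoma_counts$arm)),
               c("inhibitor", "vehicle"))
})

test_that("without Apc recombination no adenomas initiate", {
  s <- default_drift_settings()
  base <- drift_params(s$n_stem, s$replacement_rate)
  ly <- make_niche(s$n_centre, s$n_border)
  d <- cohort_design(
    arms = list(vehicle = cohort_arm(base, ly, "none")),
    timepoints = 14, mice_per_arm = 1L, crypts_per_mouse = 300L,
    labelling_mean = s$labelling_mean_high, clones_scored_min = 200L)
  cfg <- list(proximal = list(p_reporter = 0.95, q = 0))
  res <- run_apc_cohort(d, recombination = cfg, seed = 29)
  expect_true(all(res$dataset$category == "none"))
  expect_true(all(res$adenoma_counts$count == 0L))
})
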