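test_that("binned likelihood matches brute-force enumeration on a toy chain", {
  # one timepoint, N = 4: bin probabilities assembled by hand from the
  # uniformization oracle, marginalised over the truncated induced-cell mix
  N <- 4; lam <- 0.3; t <- 3; m <- 1.2
  w <- dpois(1:N, m); w <- w / sum(w)
  p1 <- uniformization_dist(N, lam, 0.5, 1, t)
  # independent-fragment convolution capped at N
  conv_cap <- function(a, b) {
    out <- numeric(N + 1)
    for (s in 0:N) for (r in 0:N) {
      i <- min(s + r, N)
      out[i + 1] <- out[i + 1] + a[s + 1] * b[r + 1]
    }
    out
  }
  pk <- c(1, numeric(N)); p <- numeric(N + 1)
  for (k in 1:N) { pk <- conv_cap(pk, p1); p <- p + w[k] * pk }
  bins <- score_eighths(0:N, N)
  ds <- tibble::tibble(day = t, eighths = c(0L, 2L, 8L, 2L))
  ll_hand <- sum(log(vapply(ds$eighths, function(e)
    sum(p[bins == e]), numeric(1))))
  expect_equal(binned_loglik(ds, N, lam, init_mean = m), ll_hand,
               tolerance = 1e-10)
  # survivors-only conditioning drops the lost record
  ll_cond <- sum(log(vapply(c(2L, 8L, 2L), function(e)
    sum(p[-1][bins[-1] == e]) / (1 - p[1]), numeric(1))))
  expect_equal(binned_loglik(ds, N, lam, init_mean = m,
                             condition_on_survival = TRUE),
               ll_cond, tolerance = 1e-10)
  # contiguous initial condition instead of fragments
  pc <- as.vector(w %*% t(vapply(1:N, function(k)
    uniformization_dist(N, lam, 0.5, k, t), numeric(N + 1))))
  ll_cont <- sum(log(vapply(ds$eighths, function(e)
    sum(pc[bins == e]), numeric(1))))
  expect_equal(binned_loglik(ds, N, lam, init_mean = m,
                             init_model = "contiguous"), ll_cont,
               tolerance = 1e-10)
})

test_that("binned likelihood honours its boundary contracts", {
  expect_equal(binned_loglik(tibble::tibble(day = numeric(0),
                                            eighths = integer(0)),
                             8, 0.2), 0)
  # a day-0 record whose bin matches the (near) point-mass initial state
  ds0 <- tibble::tibble(day = 0, eighths = score_eighths(1, 16))
  expect_equal(binned_loglik(ds0, 16, 0.1, init_mean = 1e-9), 0,
               tolerance = 1e-6)
  expect_error(binned_loglik(tibble::tibble(day = -1, eighths = 1L), 8, 0.2),
               "day")
})

test_that("parameters are recovered from a synthetic cohort", {
  truth_N <- 16; truth_l <- 0.1
  ds <- run_neutral_cohort(tiny_neutral_design(truth_N, truth_l), seed = 101)
  fit <- suppressWarnings(fit_drift(ds))
  expect_s3_class(fit, "drift_fit")
  expect_lte(abs(fit$n_stem_hat - truth_N), 2)
  expect_lt(abs(fit$replacement_rate_hat - truth_l) / truth_l, 0.25)
  expect_true(fit$rate_ci[1] <= fit$replacement_rate_hat &&
                fit$replacement_rate_hat <= fit$rate_ci[2])
  expect_true(fit$n_stem_hat %in% fit$n_support)
  # likelihood at the truth beats the doubled-N/halved-rate ridge point
  ll_true <- binned_loglik(ds, truth_N, truth_l)
  ll_ridge <- binned_loglik(ds, 2 * truth_N, truth_l / 2)
  expect_gt(ll_true, ll_ridge)
})

test_that("weak designs trigger identifiability warnings but still fit", {
  d1 <- tiny_neutral_design(timepoints = 10, crypts = 150L, mice = 1L)
  ds1 <- run_neutral_cohort(d1, seed = 7)
  expect_warning(fit_drift(ds1, n_grid = seq(4, 32, by = 2)),
                 "single timepoint")
  # degenerate data: every clone fixed at every day
  flat <- tibble::tibble(day = rep(c(4, 21), each = 20),
                         eighths = 8L, mouse_id = "m1", arm = "a")
  fit <- suppressWarnings(fit_drift(flat, n_grid = 4:12))
  expect_true(4L %in% fit$n_support)     # small-N / fast-rate corner
  expect_gt(fit$replacement_rate_hat, 1)
})

test_that("arm comparison recovers a pool-size contrast", {
  mk <- function(N, rate, arm) {
    d <- cohort_design(
      arms = setNames(list(cohort_arm(drift_params(N, rate),
                                      make_niche(N, 0), "none")), arm),
      timepoints = c(4, 10, 21), mice_per_arm = 3L, crypts_per_mouse = 120L,
      labelling_mean = 1.2, clones_scored_min = 120L)
    run_neutral_cohort(d, seed = 300 + N)
  }
  ds <- rbind(mk(16, 0.1, "wide"), mk(8, 0.1, "narrow"))
  ctr <- suppressWarnings(compare_arms(ds, n_boot = 25L, n_grid = 4:24))
  expect_equal(names(ctr$fits), c("wide", "narrow"))
  expect_gt(ctr$contrast["delta_n"], 0)
  # bootstrap interval for delta N excludes zero
  expect_gt(ctr$ci[1, "delta_n"], 0)
  # the estimated rate difference is small (same lambda in both arms)
  expect_lt(abs(ctr$contrast["delta_rate"]), 0.025)
  expect_error(compare_arms(ds[ds$arm == "wide", ]), "at least 2 arms")
  # an arm with a single timepoint is flagged and excluded
  ds1 <- rbind(mk(16, 0.1, "a"), mk(8, 0.1, "b"))
  ds1 <- ds1[!(ds1$arm == "b" & ds1$day > 4), ]
  expect_error(suppressWarnings(compare_arms(ds1)), "fewer than 2 arms")
})
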