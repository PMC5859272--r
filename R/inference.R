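#' Log-likelihood of eighths-binned clone records
#'
#' Observation model for cross-sectional clone-size data: each record is a
#' crypt scored once, at its mouse's timepoint, with the clone size binned
#' in eighths.  The probability of a record's bin is the exact birth-death
#' clone-size distribution at its day, summed over the cell counts that map
#' to that bin under [score_eighths()], marginalised over the unknown
#' number of induced cells (zero-truncated Poisson with mean `init_mean`,
#' truncated at N).  Records are treated as independent across crypts.
#'
#' Synthetic cohorts record lost clones (eighths 0), so the default
#' likelihood is unconditional and uses the loss kinetics, which sharply
#' separate N from lambda.  For real fixed-tissue data, where lost clones
#' are unobservable, set `condition_on_survival = TRUE` to drop eighths-0
#' records and condition each bin probability on survival at its day —
#' the same survivors convention the fixation readouts use.
#'
#' Two initial-condition models are available.  `"fragments"` (default)
#' treats the k induced cells as independently drifting single-cell clones
#' and convolves k single-cell size distributions (total capped at N):
#' sparsely placed induced cells start as separate fragments, so this
#' matches the generator closely at low labelling intensity.
#' `"contiguous"` starts the chain at size k directly.
#'
#' @param dataset a `clonal_dataset` (or any data frame with `day` and
#'   `eighths` columns).
#' @param n_stem candidate stem-cell number N.
#' @param replacement_rate candidate replacement rate lambda (/cell/day).
#' @param init_mean labelling intensity (mean induced cells per labelled
#'   crypt).
#' @param init_model `"fragments"` or `"contiguous"`.
#' @param condition_on_survival condition each record's bin probability on
#'   survival at its day and drop lost records (default `FALSE`; see
#'   Details).
#' @param propagator optional pre-built unit-rate propagator from
#'   `chain_propagator(n_stem)` (reused across calls for speed).
#' @return the log-likelihood (0 for an empty dataset).
#' @examples
#' ds <- tibble::tibble(day = c(4, 7), eighths = c(2L, 8L))
#' binned_loglik(ds, n_stem = 8, replacement_rate = 0.2)
#' @export
binned_loglik <- function(dataset, n_stem, replacement_rate,
                          init_mean = 1.2,
                          init_model = c("fragments", "contiguous"),
                          condition_on_survival = FALSE, propagator = NULL) {
  init_model <- match.arg(init_model)
  N <- check_count(n_stem, "n_stem", min = 2L)
  lam <- check_positive(replacement_rate, "replacement_rate")
  if (is.null(dataset) || nrow(dataset) == 0L) return(0)
  if (any(dataset$day < 0)) stop("record day < 0", call. = FALSE)
  if (condition_on_survival) dataset <- dataset[dataset$eighths > 0L, ]
  if (nrow(dataset) == 0L) return(0)
  prop <- propagator %||% chain_propagator(N)
  bin_map <- eighths_bin_map(N)   # eighths of sizes 0..N
  ll <- 0
  for (day in unique(dataset$day)) {
    p <- marginal_size_dist(prop, N, lam * day, init_mean, init_model)
    if (condition_on_survival) {
      p_bin <- vapply(1:8, function(e)
        sum(p[-1][bin_map[-1] == e]), numeric(1)) / (1 - p[1])
      names(p_bin) <- 1:8
      e_obs <- dataset$eighths[dataset$day == day]
      ll <- ll + sum(log(p_bin[e_obs]))
    } else {
      p_bin <- vapply(0:8, function(e)
        sum(p[bin_map == e]), numeric(1))
      names(p_bin) <- 0:8
      e_obs <- dataset$eighths[dataset$day == day]
      ll <- ll + sum(log(p_bin[as.character(e_obs)]))
    }
  }
  as.numeric(ll)
}

# marginal clone-size distribution over 0..N at scaled time s = lambda * t,
# mixing over the zero-truncated Poisson induced-cell count
marginal_size_dist <- function(prop, N, s, init_mean, init_model) {
  w <- ztpois_weights(init_mean, N)
  if (s == 0) {
    p <- c(0, w)
    return(p)
  }
  Pt <- prop(s)
  if (init_model == "contiguous") {
    p <- as.vector(w %*% Pt[-1, , drop = FALSE])
  } else {
    p1 <- Pt[2, ]                       # single-cell clone distribution
    M <- frag_operator(p1, N)           # one capped convolution with p1
    p <- numeric(N + 1)
    pk <- c(1, numeric(N))              # conv of k copies, capped at N
    K <- max(which(w > 1e-12))          # negligible tail of the count mix
    for (k in seq_len(K)) {
      pk <- as.vector(M %*% pk)
      p <- p + w[k] * pk
    }
  }
  p[p < 0] <- 0
  p / sum(p)
}

# linear operator adding one independent single-cell fragment (law p1) to a
# clone-size distribution, with the total capped at N
frag_operator <- function(p1, N) {
  M <- matrix(0, N + 1, N + 1)
  for (s in 0:N) {
    hi <- N - s
    M[(s:N) + 1L, s + 1L] <- p1[1:(hi + 1L)]
    if (hi < N)
      M[N + 1L, s + 1L] <- M[N + 1L, s + 1L] + sum(p1[(hi + 2L):(N + 1L)])
  }
  M
}

#' Fit stem-cell number and replacement rate
#'
#' Profile maximum likelihood over the two drift parameters: for each
#' integer N on `n_grid` the replacement rate is maximised by bounded 1-D
#' optimisation of [binned_loglik()]; the reported estimate is the overall
#' argmax, with a likelihood-ratio support set for N (all N whose profile
#' log-likelihood is within `qchisq(level, 1)/2` of the maximum) and a
#' profile-likelihood confidence interval for lambda at the selected N.
#'
#' @param dataset a `clonal_dataset` with `day` and `eighths` columns.
#' @param n_grid integer candidate N values (default 4..32).
#' @param rate_bounds search interval for lambda (/cell/day).
#' @param level confidence/support level (default 0.95).
#' @inheritParams binned_loglik
#' @return an object of class `drift_fit`: `n_stem_hat`,
#'   `replacement_rate_hat`, `rate_ci`, `n_support`, `loglik`, `surface`
#'   (tibble of N, lambda-hat, profile log-likelihood), `warnings`.
#' @examples
#' \donttest{
#' d <- default_fixation_design(timepoints = c(4, 10, 21), mice_per_arm = 1,
#'                              crypts_per_mouse = 150,
#'                              clones_scored_min = 100)
#' ds <- run_neutral_cohort(d, seed = 2)
#' fit <- fit_drift(ds[ds$arm == "vehicle", ], n_grid = 10:30)
#' fit$n_stem_hat
#' }
#' @export
fit_drift <- function(dataset, n_grid = 4:32, rate_bounds = c(0.02, 3),
                      init_mean = 1.2,
                      init_model = c("fragments", "contiguous"),
                      condition_on_survival = FALSE, level = 0.95) {
  init_model <- match.arg(init_model)
  if (is.null(dataset) || nrow(dataset) == 0L)
    stop("dataset is empty", call. = FALSE)
  msgs <- character()
  n_days <- length(unique(dataset$day))
  if (n_days < 2L) {
    msgs <- c(msgs, "single timepoint: (N, lambda) only weakly identifiable")
    warning(msgs[length(msgs)], call. = FALSE)
  }
  n_grid <- sort(unique(as.integer(n_grid)))
  prof <- lapply(n_grid, function(N) {
    prop <- chain_propagator(N)
    obj <- function(l) {
      v <- -binned_loglik(dataset, N, l, init_mean = init_mean,
                          init_model = init_model,
                          condition_on_survival = condition_on_survival,
                          propagator = prop)
      # an observed bin can be unreachable under this N (exact mapping);
      # keep the optimizer on finite ground, the profile stays -Inf there
      if (!is.finite(v)) v <- .Machine$double.xmax / 2
      v
    }
    op <- optimize(obj, rate_bounds, tol = 1e-4)
    list(N = N, rate = op$minimum, loglik = -op$objective, prop = prop)
  })
  ll <- vapply(prof, `[[`, numeric(1), "loglik")
  best <- which.max(ll)
  crit <- qchisq(level, df = 1) / 2
  support <- n_grid[ll >= ll[best] - crit]
  if (length(support) > length(n_grid) / 2 && length(n_grid) > 4L) {
    msgs <- c(msgs, paste(
      "flat likelihood ridge: the data constrain (N, lambda) only weakly;",
      "early fixation kinetics depend mainly on lambda/N^2"))
    warning(msgs[length(msgs)], call. = FALSE)
  }
  N_hat <- n_grid[best]
  rate_hat <- prof[[best]]$rate
  # profile CI for lambda at N_hat
  prop <- prof[[best]]$prop
  llfun <- function(l) binned_loglik(dataset, N_hat, l,
                                     init_mean = init_mean,
                                     init_model = init_model,
                                     condition_on_survival =
                                       condition_on_survival,
                                     propagator = prop)
  target <- ll[best] - crit
  g <- function(l) llfun(l) - target
  lo <- if (g(rate_bounds[1]) < 0)
    uniroot(g, c(rate_bounds[1], rate_hat), tol = 1e-5)$root
  else rate_bounds[1]
  hi <- if (g(rate_bounds[2]) < 0)
    uniroot(g, c(rate_hat, rate_bounds[2]), tol = 1e-5)$root
  else rate_bounds[2]
  structure(list(
    n_stem_hat = N_hat,
    replacement_rate_hat = rate_hat,
    rate_ci = c(lower = lo, upper = hi),
    n_support = support,
    loglik = ll[best],
    surface = tibble::tibble(
      n_stem = n_grid,
      replacement_rate_hat = vapply(prof, `[[`, numeric(1), "rate"),
      loglik = ll),
    level = level,
    n_records = nrow(dataset),
    warnings = msgs), class = "drift_fit")
}

#' @export
print.drift_fit <- function(x, ...) {
  cat("Drift-parameter fit (profile maximum likelihood)\n")
  cat(sprintf("  N hat:      %d (%.0f%% support set: %s)\n", x$n_stem_hat,
              100 * x$level, paste(range(x$n_support), collapse = "-")))
  cat(sprintf("  lambda hat: %.4g /cell/day (%.0f%% CI %.4g-%.4g)\n",
              x$replacement_rate_hat, 100 * x$level, x$rate_ci[1],
              x$rate_ci[2]))
  cat(sprintf("  log-likelihood %.2f over %d records\n", x$loglik,
              x$n_records))
  for (w in x$warnings) cat("  note:", w, "\n")
  invisible(x)
}

#' Compare drift parameters between arms
#'
#' Fits (N, lambda) independently per arm and reports the contrast
#' (Delta N, Delta lambda) between the first two arms with a cluster
#' bootstrap over mice (mice resampled with replacement within arm,
#' percentile intervals).
#'
#' @param dataset a `clonal_dataset` with `arm`, `mouse_id`, `day`,
#'   `eighths` columns and at least two arms.
#' @param n_boot bootstrap replicates (default 100).
#' @inheritParams fit_drift
#' @return an object of class `arm_contrast`: per-arm `fits`, `contrast`
#'   (point estimates), `ci` (percentile bootstrap), `excluded_arms`.
#' @export
compare_arms <- function(dataset, n_boot = 100L, n_grid = 4:32,
                         rate_bounds = c(0.02, 3), init_mean = 1.2,
                         init_model = c("fragments", "contiguous"),
                         condition_on_survival = FALSE, level = 0.95) {
  init_model <- match.arg(init_model)
  arms <- unique(dataset$arm)
  if (length(arms) < 2L)
    stop("compare_arms needs at least 2 arms", call. = FALSE)
  excluded <- character()
  for (a in arms) {
    if (length(unique(dataset$day[dataset$arm == a])) < 2L) {
      excluded <- c(excluded, a)
      warning(sprintf("arm '%s' has < 2 timepoints; excluded from contrast",
                      a), call. = FALSE)
    }
  }
  use <- setdiff(arms, excluded)
  if (length(use) < 2L)
    stop("fewer than 2 arms with >= 2 timepoints", call. = FALSE)
  use <- use[1:2]
  fit1 <- function(d) fit_drift(d, n_grid = n_grid,
                                rate_bounds = rate_bounds,
                                init_mean = init_mean,
                                init_model = init_model,
                                condition_on_survival = condition_on_survival,
                                level = level)
  fits <- lapply(setNames(use, use),
                 function(a) fit1(dataset[dataset$arm == a, ]))
  d_n <- fits[[1]]$n_stem_hat - fits[[2]]$n_stem_hat
  d_rate <- fits[[1]]$replacement_rate_hat - fits[[2]]$replacement_rate_hat
  boot <- matrix(NA_real_, n_boot, 2,
                 dimnames = list(NULL, c("delta_n", "delta_rate")))
  for (b in seq_len(n_boot)) {
    est <- lapply(use, function(a) {
      da <- dataset[dataset$arm == a, ]
      mice <- unique(da$mouse_id)
      take <- sample(mice, length(mice), replace = TRUE)
      db <- do.call(rbind, lapply(take, function(mm) da[da$mouse_id == mm, ]))
      f <- suppressWarnings(fit1(db))
      c(f$n_stem_hat, f$replacement_rate_hat)
    })
    boot[b, ] <- c(est[[1]][1] - est[[2]][1], est[[1]][2] - est[[2]][2])
  }
  alpha <- 1 - level
  ci <- apply(boot, 2, quantile, probs = c(alpha / 2, 1 - alpha / 2))
  structure(list(fits = fits,
                 contrast = c(delta_n = d_n, delta_rate = d_rate),
                 ci = ci, boot = boot, excluded_arms = excluded,
                 level = level), class = "arm_contrast")
}

#' @export
print.arm_contrast <- function(x, ...) {
  cat("Arm contrast (cluster bootstrap over mice)\n")
  a <- names(x$fits)
  cat(sprintf("  arms: %s vs %s\n", a[1], a[2]))
  cat(sprintf("  Delta N:      %d (CI %.1f to %.1f)\n", x$contrast[1],
              x$ci[1, "delta_n"], x$ci[2, "delta_n"]))
  cat(sprintf("  Delta lambda: %.3g (CI %.3g to %.3g)\n", x$contrast[2],
              x$ci[1, "delta_rate"], x$ci[2, "delta_rate"]))
  if (length(x$excluded_arms))
    cat("  excluded arms:", paste(x$excluded_arms, collapse = ", "), "\n")
  invisible(x)
}
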