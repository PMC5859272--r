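test_that("clonal chain has absorbing boundaries and a proper jump matrix", {
  for (pars in list(c(2, 0.5, 0.5), c(5, 0.1, 0.5), c(8, 0.3, 0.7),
                    c(16, 0.6, 0.2))) {
    ch <- build_clonal_chain(drift_params(pars[1], pars[2], bias = pars[3]))
    expect_equal(unname(rowSums(ch$jump)), rep(1, pars[1] + 1))
    expect_equal(unname(rowSums(ch$Q)), rep(0, pars[1] + 1),
                 tolerance = 1e-12)
    expect_equal(unname(ch$Q[1, ]), rep(0, pars[1] + 1))   # size 0 absorbing
    expect_equal(unname(ch$Q[pars[1] + 1, ]), rep(0, pars[1] + 1)) # size N
    # only nearest-neighbour moves in the interior
    for (n in seq_len(pars[1] - 1)) {
      nz <- which(ch$jump[n + 1, ] > 0) - 1
      expect_true(all(abs(nz - n) == 1))
    }
  }
  expect_error(drift_params(1, 0.1), "n_stem")
  expect_error(drift_params(8, -1), "replacement_rate")
  expect_error(drift_params(8, 0.1, bias = 1.5), "bias")
})

test_that("N=2 single cell resolves to loss or fixation with equal chance", {
  ch <- build_clonal_chain(drift_params(2, 0.2))
  expect_equal(unname(ch$jump[2, ]), c(0.5, 0, 0.5))
})

test_that("clone_size_distribution matches an independent uniformization oracle", {
  cases <- list(list(N = 4, lam = 0.25, b = 0.5, n0 = 2, t = 2),
                list(N = 5, lam = 0.1, b = 0.5, n0 = 1, t = 10),
                list(N = 8, lam = 0.3, b = 0.7, n0 = 3, t = 7))
  for (cs in cases) {
    ch <- build_clonal_chain(drift_params(cs$N, cs$lam, bias = cs$b))
    got <- clone_size_distribution(ch, cs$n0, cs$t)
    ora <- uniformization_dist(cs$N, cs$lam, cs$b, cs$n0, cs$t)
    expect_equal(unname(got), ora, tolerance = 1e-10)
    expect_equal(sum(got), 1, tolerance = 1e-10)
  }
  # t = 0 is a point mass; long-time mass at N equals n0/N (martingale)
  ch <- build_clonal_chain(drift_params(5, 0.5))
  expect_equal(unname(clone_size_distribution(ch, 3, 0)),
               c(0, 0, 0, 1, 0, 0))
  p_inf <- clone_size_distribution(ch, 1, 2000)
  expect_equal(unname(p_inf[6]), 0.2, tolerance = 1e-8)
  expect_error(clone_size_distribution(ch, 6, 1), "n0")
})

test_that("spectral propagator agrees with the matrix exponential", {
  for (N in c(4, 16, 32)) {
    prop <- cryptdrift:::chain_propagator(N, bias = 0.5)
    ch <- build_clonal_chain(drift_params(N, 1))
    for (s in c(0.3, 2, 12)) {
      Pe <- as.matrix(Matrix::expm(Matrix::Matrix(ch$Q * s)))
      expect_equal(prop(s), Pe, tolerance = 1e-8, ignore_attr = TRUE)
    }
  }
})

test_that("fixation probability: closed forms, limits and monotonicity", {
  expect_equal(fixation_probability(8, 8, 0.5), 1)
  expect_equal(fixation_probability(8, 0, 0.9), 0)
  expect_equal(fixation_probability(8, 1, 0.5), 0.125)
  expect_equal(fixation_probability(5, 1, 2 / 3), (1 - 0.5) / (1 - 0.5^5),
               tolerance = 1e-12)
  # continuity at the neutral limit
  expect_equal(fixation_probability(12, 3, 0.5 + 1e-10), 3 / 12,
               tolerance = 1e-6)
  # against brute-force absorption of the chain
  for (b in c(0.3, 0.6, 0.8)) {
    ch <- build_clonal_chain(drift_params(6, 0.4, bias = b))
    p_num <- clone_size_distribution(ch, 2, 5000)[7]
    expect_equal(unname(p_num), fixation_probability(6, 2, b),
                 tolerance = 1e-8)
  }
  # strictly increasing in bias
  bs <- seq(0.05, 0.95, by = 0.05)
  fp <- vapply(bs, function(b) fixation_probability(10, 2, b), numeric(1))
  expect_true(all(diff(fp) > 0))
  expect_error(fixation_probability(8, 9, 0.5), "n0")
})

test_that("simulate_crypt is seed-deterministic and conserves the ring", {
  p <- drift_params(10, 0.4)
  init <- c(1L, 1L, rep(0L, 8))
  t1 <- simulate_crypt(p, init, c(2, 5, 9), seed = 42)
  t2 <- simulate_crypt(p, init, c(2, 5, 9), seed = 42)
  expect_identical(t1$labels, t2$labels)
  expect_identical(t1$events, t2$events)
  # ring length constant; no label creation
  expect_equal(dim(t1$labels), c(10L, 3L))
  expect_true(all(unique(as.vector(t1$labels)) %in% unique(init)))
  # monoclonal start stays monoclonal
  t3 <- simulate_crypt(p, rep(7L, 10), c(1, 4), seed = 1)
  expect_true(all(t3$labels == 7L))
  expect_error(simulate_crypt(p, c(1, 0), 5), "length")
  expect_error(simulate_crypt(p, init, numeric(0)), "t_grid")
})

test_that("neutral simulation fixes single clones at rate n0/N", {
  p <- drift_params(8, 0.5)
  n <- 4000
  fixed <- 0L
  for (i in seq_len(n)) {
    ab <- simulate_to_absorption(p, c(1L, rep(0L, 7)),
                                 seed = 9000 + i)
    expect_true(ab$outcome %in% c("fixed", "lost"))
    if (ab$outcome == "fixed") fixed <- fixed + 1L
  }
  phat <- fixed / n
  se <- sqrt(0.125 * 0.875 / n)
  expect_lt(abs(phat - 0.125), 3 * se)
})

test_that("biased simulation reproduces the gambler's-ruin fixation rate", {
  b <- 2 / 3
  p <- drift_params(5, 0.5, bias = b)
  init <- c(0L, rep(0L, 3), 1L)
  geno <- c(0L, rep(0L, 3), 2L)
  n <- 4000
  fixed <- 0L
  for (i in seq_len(n)) {
    ab <- simulate_to_absorption(p, init, init_genotypes = geno,
                                 seed = 17000 + i)
    if (ab$outcome == "fixed") fixed <- fixed + 1L
  }
  p_true <- fixation_probability(5, 1, b)
  se <- sqrt(p_true * (1 - p_true) / n)
  expect_lt(abs(fixed / n - p_true), 3 * se)
})

test_that("unconditional mean clone size is a martingale", {
  p <- drift_params(12, 0.4)
  n0 <- 3L
  init <- c(rep(1L, n0), rep(0L, 9))
  n <- 10000
  sizes <- matrix(0L, n, 3)
  set.seed(31)
  for (i in seq_len(n))
    sizes[i, ] <- clone_sizes(simulate_crypt(p, init, c(2, 6, 15)))
  for (j in 1:3) {
    se <- sd(sizes[, j]) / sqrt(n)
    expect_lt(abs(mean(sizes[, j]) - n0), 3 * se)
  }
})

test_that("simulated clone sizes match the exact chain (total variation)", {
  # single-clone dynamics on small rings against the birth-death oracle
  for (cs in list(list(N = 6, b = 0.5, t = 4), list(N = 8, b = 0.65, t = 6))) {
    p <- drift_params(cs$N, 0.4, bias = cs$b)
    ch <- build_clonal_chain(p)
    init <- c(1L, rep(0L, cs$N - 1))
    geno <- if (cs$b == 0.5) NULL else c(2L, rep(0L, cs$N - 1))
    n <- 8000
    counts <- numeric(cs$N + 1)
    set.seed(77)
    for (i in seq_len(n)) {
      sz <- clone_sizes(simulate_crypt(p, init, cs$t,
                                       init_genotypes = geno))
      counts[sz + 1] <- counts[sz + 1] + 1
    }
    tv <- 0.5 * sum(abs(counts / n -
                          clone_size_distribution(ch, 1, cs$t)))
    expect_lt(tv, 0.03)
  }
})

test_that("fixation by a fixed day is monotone non-increasing in N", {
  # common random numbers: same per-replicate seed across ring sizes
  frac_fixed <- function(N, nrep = 1500) {
    p <- drift_params(N, 0.5)
    f <- 0L
    for (i in seq_len(nrep)) {
      sz <- clone_sizes(simulate_crypt(p, c(1L, rep(0L, N - 1)), 15,
                                       seed = 400000 + i))
      if (sz == N) f <- f + 1L
    }
    f / nrep
  }
  fr <- vapply(c(4, 8, 16), frac_fixed, numeric(1))
  expect_true(all(diff(fr) < 0))
})

test_that("trajectory export is tidy and drops removed positions", {
  p <- drift_params(6, 0.3)
  tr <- simulate_crypt(p, c(1L, rep(0L, 5)), c(1, 3), seed = 5)
  tab <- trajectory_table(tr, "cA")
  expect_equal(nrow(tab), 12)
  expect_named(tab, c("crypt_id", "day", "position", "clone_label",
                      "genotype"))
  expect_true(all(tab$genotype == "wt"))
})
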