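#' Exact birth-death chain for a contiguous clone
#'
#' A contiguous clone on a ring of N competing stem cells always has exactly
#' two boundaries with the surrounding cells.  Under the replacement-rate
#' convention used throughout the package (each (cell, side) pair divides
#' outward at rate lambda/2, i.e. lambda replacement events per cell per
#' day), each boundary is resolved at rate lambda per day, independent of the
#' clone size.  The clone size n therefore performs a continuous-time random
#' walk on 0..N with constant total stepping rate 2*lambda for 0 < n < N,
#' stepping up with probability `bias` and down with probability `1 - bias`;
#' 0 (clone lost) and N (monoclonal conversion, "fixation") are absorbing.
#'
#' @param params a [drift_params()] object; `border_loss_rate` is ignored
#'   (the chain describes the core competition only).
#' @return an object of class `clonal_chain` with elements `n_stem`, `bias`,
#'   `replacement_rate`, `boundary_rate` (= `replacement_rate`), the
#'   generator matrix `Q` over sizes 0..N and the embedded jump matrix
#'   `jump`.
#' @examples
#' ch <- build_clonal_chain(drift_params(5, 0.1))
#' rowSums(ch$jump)  # all 1
#' @export
build_clonal_chain <- function(params) {
  if (!is_drift_params(params)) params <- do.call(drift_params, params)
  N <- params$n_stem
  lam <- params$replacement_rate
  b <- params$bias
  up <- 2 * lam * b
  dn <- 2 * lam * (1 - b)
  Q <- matrix(0, N + 1, N + 1,
              dimnames = list(size = 0:N, size = 0:N))
  for (n in seq_len(N - 1)) {
    Q[n + 1, n + 2] <- up
    Q[n + 1, n]     <- dn
    Q[n + 1, n + 1] <- -(up + dn)
  }
  P <- diag(N + 1)
  dimnames(P) <- dimnames(Q)
  for (n in seq_len(N - 1)) {
    P[n + 1, n + 1] <- 0
    P[n + 1, n + 2] <- b
    P[n + 1, n]     <- 1 - b
  }
  structure(list(n_stem = N, bias = b, replacement_rate = lam,
                 boundary_rate = lam, Q = Q, jump = P),
            class = "clonal_chain")
}

#' @export
print.clonal_chain <- function(x, ...) {
  cat(sprintf(
    "Birth-death clone-size chain: N = %d, boundary rate = %.3g/day, bias = %.3g\n",
    x$n_stem, x$boundary_rate, x$bias))
  invisible(x)
}

#' Clone-size distribution at a given time
#'
#' Exact distribution of the size of a contiguous clone after `t` days,
#' starting from `n0` cells, via the matrix exponential of the chain
#' generator.
#'
#' @param chain a [build_clonal_chain()] object.
#' @param n0 initial clone size, 0..N.
#' @param t time in days, >= 0.
#' @return named probability vector over sizes 0..N (sums to 1 within 1e-10).
#' @examples
#' ch <- build_clonal_chain(drift_params(4, 0.1))
#' clone_size_distribution(ch, n0 = 2, t = 0)   # point mass at 2
#' sum(clone_size_distribution(ch, 1, 30))      # 1
#' @export
clone_size_distribution <- function(chain, n0, t) {
  stopifnot(inherits(chain, "clonal_chain"))
  N <- chain$n_stem
  n0 <- check_count(n0, "n0")
  if (n0 > N) stop("n0 must lie in 0..N", call. = FALSE)
  if (!is.numeric(t) || length(t) != 1L || t < 0)
    stop("t must be a single day >= 0", call. = FALSE)
  if (t == 0) {
    p <- numeric(N + 1)
    p[n0 + 1] <- 1
  } else {
    Pt <- as.matrix(Matrix::expm(Matrix::Matrix(chain$Q * t)))
    p <- Pt[n0 + 1, ]
    p[p < 0] <- 0
    p <- p / sum(p)
  }
  setNames(p, 0:N)
}

# Fast spectral propagator for the unit-rate chain.  Because Q is linear in
# lambda, exp(Q t) = exp(Q1 * (lambda * t)) where Q1 is the generator at
# lambda = 1; one eigendecomposition per (N, bias) serves every (lambda, t).
# Returns function(s) -> (N+1)x(N+1) transition matrix over sizes 0..N.
chain_propagator <- function(n_stem, bias = 0.5) {
  ch1 <- build_clonal_chain(drift_params(n_stem, 1, bias = bias))
  eg <- eigen(ch1$Q)
  V <- eg$vectors
  Vi <- solve(V)
  ev <- eg$values
  function(s) {
    M <- Re(V %*% (exp(ev * s) * Vi))
    M[M < 0] <- 0
    M / rowSums(M)
  }
}

#' Fixation probability of a clone
#'
#' Probability that a clone of `n0` of `n_stem` competing stem cells
#' ultimately takes over the whole niche.  Neutral competition
#' (`bias = 0.5`) gives the label-symmetry result `n0 / n_stem`; biased
#' competition gives the gambler's-ruin closed form
#' \deqn{P = (1 - \rho^{n_0}) / (1 - \rho^{N}), \quad \rho = (1-b)/b,}
#' continuous in the limit b -> 0.5.  `bias = 0` and `bias = 1` are handled
#' as limits (a fully disadvantaged clone never fixes unless it already
#' occupies the crypt; a fully advantaged one always does once present).
#'
#' @param n_stem ring size N (>= 2).
#' @param n0 initial clone size, 0..N.
#' @param bias boundary win probability in \[0, 1\].
#' @return fixation probability.
#' @examples
#' fixation_probability(8, 1, 0.5)            # 0.125
#' fixation_probability(5, 1, 2 / 3)          # (1 - 0.5) / (1 - 0.5^5)
#' @export
fixation_probability <- function(n_stem, n0, bias = 0.5) {
  N <- check_count(n_stem, "n_stem", min = 2L)
  n0 <- check_count(n0, "n0")
  if (n0 > N) stop("n0 must lie in 0..N", call. = FALSE)
  bias <- check_prob(bias, "bias")
  if (n0 == 0) return(0)
  if (n0 == N) return(1)
  if (bias == 0) return(0)
  if (bias == 1) return(1)
  lr <- log1p(-bias) - log(bias)  # log rho
  if (abs(lr) < 1e-12) return(n0 / N)
  expm1(n0 * lr) / expm1(N * lr)
}
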