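`%||%` <- function(x, y) if (is.null(x)) y else x

check_count <- function(x, name, min = 0L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != round(x) || x < min)
    stop(sprintf("%s must be a single integer >= %d", name, min), call. = FALSE)
  as.integer(x)
}

check_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    stop(sprintf("%s must lie in [0, 1]", name), call. = FALSE)
  as.numeric(x)
}

check_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0)
    stop(sprintf("%s must be a single number > 0", name), call. = FALSE)
  as.numeric(x)
}

check_nonneg <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0)
    stop(sprintf("%s must be a single number >= 0", name), call. = FALSE)
  as.numeric(x)
}

#' Zero-truncated Poisson draws
#'
#' Number of tamoxifen-induced cells per labelled crypt: Poisson sampling of
#' independent recombination events, conditioned on the crypt being labelled
#' at all (at least one event).
#'
#' @param n number of draws.
#' @param mean the mean of the untruncated Poisson.
#' @return integer vector of positive counts.
#' @examples
#' set.seed(1)
#' mean(rztpois(1000, 1.2)) # close to 1.2 / (1 - exp(-1.2))
#' @export
rztpois <- function(n, mean) {
  mean <- check_positive(mean, "mean")
  # inverse-CDF conditioned on k >= 1 (stable for tiny means)
  u <- runif(n, exp(-mean), 1)
  as.integer(qpois(u, mean))
}

#' @rdname rztpois
#' @export
ztpois_mean <- function(mean) mean / (1 - exp(-mean))

# pmf of the induced-cell count truncated at n_max and renormalised
ztpois_weights <- function(mean, n_max) {
  k <- seq_len(n_max)
  w <- dpois(k, mean)
  w / sum(w)
}

# deterministic per-crypt seed stream derived from one master seed
crypt_seed <- function(seed, index) {
  s <- (as.double(seed) * 48271 + as.double(index) * 16807) %% 2147483647
  as.integer(s) + 1L
}

new_provenance <- function(seed, pars) {
  list(seed = seed, parameter_hash = rlang::hash(pars),
       package = "cryptdrift",
       version = as.character(utils::packageVersion("cryptdrift")))
}
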