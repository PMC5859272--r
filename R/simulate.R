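#' Simulate stem-cell replacement on the crypt ring
#'
#' Event-driven (Gillespie) simulation of the Moran-type replacement process
#' on a ring of `params$n_stem` positions.  At each replacement event a
#' uniformly chosen cell divides and its progeny displaces one of its two
#' ring neighbours (uniform side choice); at a boundary between an Apc-null
#' cell and a wild-type/heterozygous cell the contested position goes to the
#' mutant with probability `params$bias`.  If `params$border_loss_rate > 0`
#' and the layout has border positions, each border position additionally
#' loses its occupant to the transit-amplifying zone at that rate and is
#' refilled by the progeny of a uniformly chosen centre cell.
#'
#' The trajectory is sampled at the requested days.  With the same seed and
#' inputs the trajectory is reproducible bit for bit.
#'
#' @param params a [drift_params()] object.
#' @param init_labels integer vector of length `n_stem`: clone label per
#'   position (0 = unlabelled).
#' @param t_grid strictly increasing vector of sampling days (>= `t_start`).
#' @param init_genotypes optional integer vector of per-position genotypes:
#'   0 wild type, 1 Apc heterozygous, 2 Apc null.  Defaults to all wild type.
#' @param layout optional [make_niche()] layout (needed for border loss);
#'   defaults to an all-centre niche.
#' @param het_bias boundary win probability of heterozygous vs wild-type
#'   cells (default 0.5, neutral).
#' @param seed optional integer seed (`set.seed` is called if supplied).
#' @param t_start simulation start day (default 0); sampling times must not
#'   precede it.
#' @return an object of class `crypt_trajectory`: list with `times`,
#'   `labels` (positions x times matrix), `genotypes`, `events`, `params`,
#'   `layout`.
#' @examples
#' p <- drift_params(8, 0.2)
#' tr <- simulate_crypt(p, init_labels = c(1, rep(0, 7)), t_grid = c(7, 14),
#'                      seed = 1)
#' clone_sizes(tr)
#' @export
simulate_crypt <- function(params, init_labels, t_grid, init_genotypes = NULL,
                           layout = NULL, het_bias = 0.5, seed = NULL,
                           t_start = 0) {
  stopifnot(is_drift_params(params))
  N <- params$n_stem
  if (length(init_labels) != N)
    stop(sprintf("init_labels has length %d but n_stem is %d",
                 length(init_labels), N), call. = FALSE)
  if (length(t_grid) == 0L) stop("t_grid must not be empty", call. = FALSE)
  if (is.unsorted(t_grid, strictly = TRUE))
    stop("t_grid must be strictly increasing", call. = FALSE)
  if (any(t_grid < t_start))
    stop("t_grid must not precede t_start", call. = FALSE)
  init_genotypes <- init_genotypes %||% integer(N)
  if (length(init_genotypes) != N)
    stop("init_genotypes must match n_stem", call. = FALSE)
  if (!all(init_genotypes %in% 0:2))
    stop("unknown genotype code; use 0 (wt), 1 (het), 2 (null)", call. = FALSE)
  layout <- layout %||% make_niche(N, 0)
  if (layout$n_stem != N) stop("layout must match n_stem", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  res <- ring_gillespie_cpp(as.integer(init_labels),
                            as.integer(init_genotypes),
                            border_indices(layout) - 1L,
                            centre_indices(layout) - 1L,
                            params$replacement_rate, params$bias,
                            check_prob(het_bias, "het_bias"),
                            params$border_loss_rate,
                            as.numeric(t_grid), as.numeric(t_start))
  structure(list(times = as.numeric(t_grid), labels = res$labels,
                 genotypes = res$genotypes, events = res$events,
                 params = params, layout = layout),
            class = "crypt_trajectory")
}

#' @export
print.crypt_trajectory <- function(x, ...) {
  cat(sprintf(
    "Crypt trajectory: %d positions, %d sampled days (%.3g-%.3g), %g events\n",
    nrow(x$labels), length(x$times), min(x$times), max(x$times), x$events))
  invisible(x)
}

#' Clone sizes along a trajectory
#'
#' @param trajectory a [simulate_crypt()] trajectory.
#' @param label clone label to count (default 1).
#' @return integer vector of clone sizes per sampled day.
#' @export
clone_sizes <- function(trajectory, label = 1L) {
  stopifnot(inherits(trajectory, "crypt_trajectory"))
  setNames(colSums(trajectory$labels == label, na.rm = TRUE),
           trajectory$times)
}

#' Simulate a crypt to clonal absorption
#'
#' Runs the ring until the focal clone is either lost or has taken over
#' every competing position (monoclonal conversion), and reports the
#' absorption day.
#'
#' @inheritParams simulate_crypt
#' @param focal_label label of the tracked clone (default 1).
#' @param t_max censoring horizon in days (default `Inf`).
#' @return list with `time` (day), `outcome` (`"fixed"`, `"lost"` or
#'   `"censored"`), and `events`.
#' @export
simulate_to_absorption <- function(params, init_labels, init_genotypes = NULL,
                                   layout = NULL, het_bias = 0.5,
                                   focal_label = 1L, t_max = Inf,
                                   seed = NULL) {
  stopifnot(is_drift_params(params))
  N <- params$n_stem
  if (length(init_labels) != N)
    stop("init_labels must match n_stem", call. = FALSE)
  init_genotypes <- init_genotypes %||% integer(N)
  layout <- layout %||% make_niche(N, 0)
  if (!is.null(seed)) set.seed(seed)
  res <- ring_absorb_cpp(as.integer(init_labels), as.integer(init_genotypes),
                         border_indices(layout) - 1L,
                         centre_indices(layout) - 1L,
                         params$replacement_rate, params$bias,
                         check_prob(het_bias, "het_bias"),
                         params$border_loss_rate,
                         as.integer(focal_label), as.numeric(t_max))
  outcome <- c("lost", "fixed", "censored")[match(res$outcome, c(0, 1, -1))]
  list(time = res$time, outcome = outcome, events = res$events,
       size = res$size)
}

#' Tidy per-position export of a trajectory
#'
#' @param trajectory a [simulate_crypt()] trajectory.
#' @param crypt_id identifier recorded in the output.
#' @return tibble with columns `crypt_id`, `day`, `position`, `clone_label`,
#'   `genotype` (removed positions are dropped).
#' @export
trajectory_table <- function(trajectory, crypt_id = "crypt1") {
  stopifnot(inherits(trajectory, "crypt_trajectory"))
  N <- nrow(trajectory$labels)
  TT <- length(trajectory$times)
  out <- tibble::tibble(
    crypt_id = crypt_id,
    day = rep(trajectory$times, each = N),
    position = rep(seq_len(N), times = TT),
    clone_label = as.vector(trajectory$labels),
    genotype = c("wt", "het", "null")[as.vector(trajectory$genotypes) + 1L])
  out[!is.na(out$clone_label), ]
}
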