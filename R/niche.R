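#' Centre/border layout of the stem-cell niche
#'
#' Intravital imaging distinguishes "centre" stem cells at the crypt base
#' from "border" stem cells at the upper edge of the niche, adjacent to the
#' transit-amplifying (TA) zone.  On the model's ring the compartments are
#' two contiguous arcs: positions `1..n_centre` are the centre, positions
#' `(n_centre+1)..(n_centre+n_border)` are the border arc leading to the TA
#' exit.
#'
#' @param n_centre number of centre positions (>= 1).
#' @param n_border number of border positions (>= 0).
#' @return an object of class `niche_layout` with fields `n_centre`,
#'   `n_border`, `n_stem` and the per-position `assignment`
#'   (`"centre"`/`"border"`).
#' @examples
#' make_niche(8, 8)
#' make_niche(4, 0)  # inhibitor-collapsed, all-centre pool
#' @export
make_niche <- function(n_centre, n_border) {
  n_centre <- check_count(n_centre, "n_centre", min = 1L)
  n_border <- check_count(n_border, "n_border", min = 0L)
  assignment <- c(rep("centre", n_centre), rep("border", n_border))
  structure(list(n_centre = n_centre, n_border = n_border,
                 n_stem = n_centre + n_border, assignment = assignment),
            class = "niche_layout")
}

#' @export
print.niche_layout <- function(x, ...) {
  cat(sprintf("Niche layout: %d positions (%d centre + %d border)\n",
              x$n_stem, x$n_centre, x$n_border))
  invisible(x)
}

is_niche_layout <- function(x) inherits(x, "niche_layout")

border_indices <- function(layout) which(layout$assignment == "border")
centre_indices <- function(layout) which(layout$assignment == "centre")

#' Map Wnt-ligand inhibition onto the niche
#'
#' Porcupine inhibition removes stem-cell activity specifically from the
#' upper (border) part of the niche while leaving centre kinetics unchanged.
#' Two representations are provided:
#' \describe{
#'   \item{`remove_border`}{a fraction `strength` of the border positions
#'     stops competing immediately, shrinking the effective pool; with
#'     `strength = 1` only the centre arc competes.  Positions are removed
#'     from the middle of the border arc outward (farthest from the centre
#'     first).}
#'   \item{`border_loss`}{border positions keep competing but each loses its
#'     occupant to the TA zone at rate `strength` per day; the emptied slot
#'     is refilled by the progeny of a uniformly chosen centre cell.
#'     Expelled cells do not re-enter.}
#' }
#'
#' @param params a [drift_params()] object.
#' @param layout a [make_niche()] layout.
#' @param mode `"remove_border"` or `"border_loss"`.
#' @param strength fraction of border positions removed (`remove_border`,
#'   in \[0,1\]) or expulsion rate per border position per day
#'   (`border_loss`, >= 0).
#' @return list with modified `params` and `layout`.
#' @examples
#' p <- drift_params(16, 0.2)
#' ly <- make_niche(8, 8)
#' apply_wnt_inhibition(p, ly, "remove_border", 1)$params$n_stem  # 8
#' @export
apply_wnt_inhibition <- function(params, layout,
                                 mode = c("remove_border", "border_loss"),
                                 strength) {
  stopifnot(is_drift_params(params), is_niche_layout(layout))
  mode <- match.arg(mode)
  strength <- check_nonneg(strength, "strength")
  if (params$n_stem != layout$n_stem)
    stop("params$n_stem must match the layout", call. = FALSE)
  if (mode == "remove_border") {
    strength <- check_prob(strength, "strength")
    n_remove <- as.integer(round(strength * layout$n_border))
    if (n_remove == 0L) return(list(params = params, layout = layout))
    new_layout <- make_niche(layout$n_centre, layout$n_border - n_remove)
    new_params <- drift_params(new_layout$n_stem, params$replacement_rate,
                               bias = params$bias, border_loss_rate = 0)
    list(params = new_params, layout = new_layout)
  } else {
    new_params <- drift_params(params$n_stem, params$replacement_rate,
                               bias = params$bias,
                               border_loss_rate = strength)
    list(params = new_params, layout = layout)
  }
}

# which original ring positions remain after remove_border: the kept border
# positions are those nearest the centre arc ends; removal starts at the
# middle of the border arc (farthest from the centre).
kept_positions <- function(layout, n_keep_border) {
  nc <- layout$n_centre
  nb <- layout$n_border
  keep <- seq_len(nc)
  if (n_keep_border > 0L) {
    b <- nc + seq_len(nb)              # border arc positions in ring order
    take_low <- ceiling(n_keep_border / 2)   # adjacent to centre position nc
    take_high <- n_keep_border - take_low    # adjacent to centre position 1
    keep_b <- c(if (take_low > 0) b[seq_len(take_low)],
                if (take_high > 0) b[nb - seq_len(take_high) + 1L])
    keep <- c(keep, sort(keep_b))
  }
  keep
}

#' Clone persistence curve from imaging-style trajectories
#'
#' Fraction of clones that still have at least one cell in the niche (centre
#' or border position) on each imaging day, stratified by the compartment
#' the clone started in.  Cells pushed into the transit-amplifying region
#' are, by construction of the model, no longer on the ring and are not
#' counted.  The first imaging day is the conditioning day: every clone in
#' the input is present then, so the curve starts at 1.
#'
#' @param trajectories list of [simulate_crypt()] trajectories, each with a
#'   `start_compartment` attribute and the focal clone labelled `1`.
#' @param start_compartment `"centre"` or `"border"`; trajectories must
#'   match.
#' @return a tibble with columns `day`, `n_clones`, `fraction_surviving`,
#'   `start_compartment`.
#' @export
persistence_curve <- function(trajectories,
                              start_compartment = c("centre", "border")) {
  start_compartment <- match.arg(start_compartment)
  if (length(trajectories) == 0L)
    stop("no trajectories supplied", call. = FALSE)
  for (i in seq_along(trajectories)) {
    sc <- attr(trajectories[[i]], "start_compartment")
    if (!identical(sc, start_compartment))
      stop(sprintf("trajectory %d started in compartment '%s', not '%s'",
                   i, sc %||% "<unset>", start_compartment), call. = FALSE)
  }
  days <- trajectories[[1]]$times
  alive <- vapply(trajectories, function(tr) {
    colSums(tr$labels == 1L, na.rm = TRUE) >= 1L
  }, logical(length(days)))
  if (length(days) == 1L) alive <- matrix(alive, nrow = 1L)
  frac <- rowMeans(alive)
  tibble::tibble(day = days, n_clones = length(trajectories),
                 fraction_surviving = frac,
                 start_compartment = start_compartment)
}
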