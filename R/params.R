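#' Drift model parameters
#'
#' The neutral-drift dynamics of intestinal stem cells are defined by two
#' parameters: the number of competing stem cells `n_stem` (N) and the
#' per-cell replacement rate `replacement_rate` (lambda, replacement events
#' per stem cell per day).  Two further parameters extend the neutral model:
#' `bias`, the probability that at a clone boundary between an Apc-null cell
#' and a wild-type (or heterozygous) cell the mutant's progeny takes the
#' contested position (0.5 = neutral competition), and `border_loss_rate`,
#' the per-day rate at which each border niche position loses its occupant to
#' the transit-amplifying zone under Wnt-ligand (Porcupine) inhibition
#' (0 = untreated).
#'
#' @param n_stem integer number of competing niche positions, at least 2.
#' @param replacement_rate expected replacement events per stem cell per day
#'   (> 0).  Under this convention each boundary of a contiguous clone is
#'   resolved at rate `replacement_rate` per day (see
#'   [build_clonal_chain()]).
#' @param bias probability in \[0, 1\] that the mutant wins a mutant/wild-type
#'   boundary contest; 0.5 is neutral.
#' @param border_loss_rate expected expulsions per border position per day
#'   (>= 0).
#' @return an object of class `drift_params`.
#' @examples
#' drift_params(n_stem = 16, replacement_rate = 0.2)
#' @seealso [make_niche()], [simulate_crypt()], [build_clonal_chain()]
#' @export
drift_params <- function(n_stem, replacement_rate, bias = 0.5,
                         border_loss_rate = 0) {
  out <- structure(
    list(n_stem = check_count(n_stem, "n_stem", min = 2L),
         replacement_rate = check_positive(replacement_rate, "replacement_rate"),
         bias = check_prob(bias, "bias"),
         border_loss_rate = check_nonneg(border_loss_rate, "border_loss_rate")),
    class = "drift_params")
  out
}

#' @export
print.drift_params <- function(x, ...) {
  cat("Drift parameters\n")
  cat(sprintf("  stem cells (N):        %d\n", x$n_stem))
  cat(sprintf("  replacement rate:      %.3g /cell/day\n", x$replacement_rate))
  cat(sprintf("  mutant bias:           %.3g%s\n", x$bias,
              if (x$bias == 0.5) " (neutral)" else ""))
  cat(sprintf("  border loss rate:      %.3g /position/day\n",
              x$border_loss_rate))
  invisible(x)
}

is_drift_params <- function(x) inherits(x, "drift_params")

#' Documented default model settings
#'
#' The single jointly-calibrated default parameter set used throughout the
#' package: baseline crypt of `n_stem` positions split into a centre and a
#' border compartment, a common replacement rate, the Apc-null displacement
#' bias, the border-expulsion rate used for intravital-imaging emulation,
#' labelling intensities for low (0.15 mg tamoxifen style) and high (3 mg)
#' induction, per-region Cre-lox recombination efficiencies, and the standard
#' fixed-tissue timepoints.  These values were chosen once, by calibrating
#' the model against the published fixation kinetics (see the methods
#' vignette); they are deliberately not tunable per readout.
#'
#' @return a named list of defaults.
#' @examples
#' default_drift_settings()$n_stem
#' @export
default_drift_settings <- function() {
  list(
    n_stem = 20L,            # competing positions in the untreated crypt
    n_centre = 3L,           # crypt-base positions retained under inhibition
    n_border = 17L,
    replacement_rate = 0.6,  # events per stem cell per day
    apc_bias = 0.7,          # Apc-null vs wild-type boundary win probability
    het_bias = 0.5,          # Apc heterozygous cells compete neutrally
    border_loss_rate = 1.0,  # expulsions per border position per day (treated)
    treatment_day = 1,       # inhibitor dosing starts 24 h post induction
    labelling_mean_low = 1.2,   # induced cells per labelled crypt, 0.15 mg
    labelling_mean_high = 6,    # induced cells per labelled crypt, 3 mg
    p_reporter = 0.95,       # reporter-allele recombination per induced cell
    q_proximal = 0.30,       # per-Apc-allele efficiency, proximal SI
    q_distal = 0.60,         # per-Apc-allele efficiency, distal SI
    discordance_day = 7,     # scoring day for reporter/Apc discordance
    crypts_per_field = 50,   # crypts per microscope field for clones/field
    timepoints = c(4, 7, 10, 14, 21)
  )
}
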