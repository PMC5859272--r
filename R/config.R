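default_run_config <- function() {
  s <- default_drift_settings()
  list(
    seed = 1L,
    drift = list(n_stem = s$n_stem, n_centre = s$n_centre,
                 n_border = s$n_border,
                 replacement_rate = s$replacement_rate,
                 apc_bias = s$apc_bias, het_bias = s$het_bias,
                 border_loss_rate = s$border_loss_rate,
                 treatment_day = s$treatment_day),
    cohort = list(timepoints = s$timepoints, mice_per_arm = 3L,
                  crypts_per_mouse = 200L, labelling_mean = NULL,
                  induction = "low", clones_scored_min = 200L,
                  crypts_per_field = s$crypts_per_field,
                  inhibition_mode = "remove_border",
                  inhibition_strength = 1),
    recombination = default_recombination_config(),
    inference = list(n_min = 4L, n_max = 32L, rate_min = 0.02,
                     rate_max = 3, init_model = "fragments",
                     condition_on_survival = FALSE))
}

#' Read and validate a run configuration
#'
#' YAML configuration for reproducible runs.  Only the documented blocks
#' (`seed`, `drift`, `cohort`, `recombination`, `inference`) and keys are
#' accepted; unknown keys raise an error naming their YAML path.  Supplied
#' values overlay the documented defaults and are validated by the same
#' constructors the package uses everywhere
#' ([drift_params()], [make_niche()], [cohort_design()], ...).
#'
#' @param path path to a YAML file, or `NULL` for pure defaults.
#' @return a validated `run_config` list.
#' @export
read_run_config <- function(path = NULL) {
  cfg <- default_run_config()
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    check_keys <- function(u, d, where) {
      bad <- setdiff(names(u), names(d))
      if (length(bad))
        stop(sprintf("unknown configuration key%s at %s: %s",
                     if (length(bad) > 1) "s" else "", where,
                     paste(bad, collapse = ", ")), call. = FALSE)
    }
    check_keys(user, cfg, "top level")
    for (blk in intersect(names(user), c("drift", "cohort", "inference")))
      check_keys(user[[blk]], cfg[[blk]], blk)
    cfg <- modifyList(cfg, user)
  }
  # validate through the constructors
  drift_params(cfg$drift$n_stem, cfg$drift$replacement_rate,
               border_loss_rate = cfg$drift$border_loss_rate)
  make_niche(cfg$drift$n_centre, cfg$drift$n_border)
  if (cfg$drift$n_centre + cfg$drift$n_border != cfg$drift$n_stem)
    stop("drift: n_centre + n_border must equal n_stem", call. = FALSE)
  check_prob(cfg$drift$apc_bias, "drift$apc_bias")
  structure(cfg, class = "run_config")
}

config_design <- function(cfg) {
  base <- drift_params(cfg$drift$n_stem, cfg$drift$replacement_rate)
  ly <- make_niche(cfg$drift$n_centre, cfg$drift$n_border)
  strength <- if (cfg$cohort$inhibition_mode == "border_loss")
    cfg$drift$border_loss_rate else cfg$cohort$inhibition_strength
  cohort_design(
    arms = list(
      vehicle = cohort_arm(base, ly, "none"),
      inhibitor = cohort_arm(base, ly, cfg$cohort$inhibition_mode,
                             strength = strength)),
    timepoints = cfg$cohort$timepoints,
    mice_per_arm = cfg$cohort$mice_per_arm,
    crypts_per_mouse = cfg$cohort$crypts_per_mouse,
    labelling_mean = cfg$cohort$labelling_mean,
    induction = cfg$cohort$induction,
    treatment_day = cfg$drift$treatment_day,
    clones_scored_min = cfg$cohort$clones_scored_min,
    crypts_per_field = cfg$cohort$crypts_per_field,
    het_bias = cfg$drift$het_bias)
}

#' Run a configured cohort simulation to files
#'
#' Builds the two-arm cohort design from a [read_run_config()]
#' configuration, simulates it, and writes the clonal dataset plus per
#' (arm, day) fixation summaries as CSV with provenance headers.
#'
#' @param config a `run_config` (or path to a YAML file).
#' @param out_dir output directory (created if missing).
#' @param seed overrides `config$seed` when given.
#' @return named paths of the files written, invisibly.
#' @export
run_simulate <- function(config = NULL, out_dir = ".", seed = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  if (is.null(config)) config <- read_run_config(NULL)
  seed <- seed %||% config$seed
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  design <- config_design(config)
  ds <- run_neutral_cohort(design, seed = seed)
  ds_path <- file.path(out_dir, "clonal_dataset.csv")
  write_clonal_dataset(ds, ds_path)
  groups <- split(ds, list(ds$arm, ds$day), drop = TRUE)
  summ <- do.call(rbind, lapply(groups, function(g) {
    out <- summarize_timepoint(g, crypts_per_field = design$crypts_per_field)
    out$arm <- g$arm[1]
    out[, c("arm", setdiff(names(out), "arm"))]
  }))
  summ <- summ[order(summ$arm, summ$day), ]
  sm_path <- file.path(out_dir, "fixation_summary.csv")
  utils::write.csv(summ, sm_path, row.names = FALSE)
  invisible(c(dataset = ds_path, summary = sm_path))
}

#' Fit drift parameters from a dataset file
#'
#' Reads a clonal-dataset CSV (see [write_clonal_dataset()]), fits
#' (N, lambda) per arm by profile maximum likelihood, and writes the
#' estimates as JSON plus the profile surfaces as CSV.
#'
#' @param dataset_path path to a clonal-dataset CSV.
#' @param config a `run_config` (or path to YAML, or `NULL` for defaults).
#' @param out_dir output directory.
#' @return the list of per-arm [fit_drift()] objects, invisibly.
#' @export
run_fit <- function(dataset_path, config = NULL, out_dir = ".") {
  if (is.character(config)) config <- read_run_config(config)
  if (is.null(config)) config <- read_run_config(NULL)
  ds <- read_clonal_dataset(dataset_path)
  required <- c("arm", "mouse_id", "day", "eighths")
  missing <- setdiff(required, names(ds))
  if (length(missing))
    stop(sprintf("dataset is missing column%s: %s",
                 if (length(missing) > 1) "s" else "",
                 paste(missing, collapse = ", ")), call. = FALSE)
  if (nrow(ds) == 0L) stop("dataset is empty", call. = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  inf <- config$inference
  fits <- lapply(split(ds, ds$arm), function(d)
    fit_drift(d, n_grid = inf$n_min:inf$n_max,
              rate_bounds = c(inf$rate_min, inf$rate_max),
              init_mean = config$cohort$labelling_mean %||%
                default_drift_settings()$labelling_mean_low,
              init_model = inf$init_model,
              condition_on_survival = inf$condition_on_survival))
  res <- lapply(fits, function(f) list(
    n_stem_hat = f$n_stem_hat,
    replacement_rate_hat = f$replacement_rate_hat,
    rate_ci = as.list(f$rate_ci),
    n_support = f$n_support,
    loglik = f$loglik, n_records = f$n_records,
    warnings = f$warnings))
  jsonlite::write_json(res, file.path(out_dir, "drift_fit.json"),
                       auto_unbox = TRUE, digits = NA)
  surface <- do.call(rbind, lapply(names(fits), function(a) {
    s <- fits[[a]]$surface
    s$arm <- a
    s
  }))
  utils::write.csv(surface, file.path(out_dir, "drift_fit_surface.csv"),
                   row.names = FALSE)
  invisible(fits)
}
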