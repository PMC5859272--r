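#' Define one arm of a cohort
#'
#' @param params a [drift_params()] object (untreated baseline).
#' @param layout a [make_niche()] layout matching `params$n_stem`.
#' @param inhibition_mode `"none"`, `"remove_border"` or `"border_loss"`;
#'   applied from the design's `treatment_day` onward.
#' @param strength inhibition strength (see [apply_wnt_inhibition()]).
#' @return a `cohort_arm` list.
#' @export
cohort_arm <- function(params, layout,
                       inhibition_mode = c("none", "remove_border",
                                           "border_loss"),
                       strength = 0) {
  inhibition_mode <- match.arg(inhibition_mode)
  stopifnot(is_drift_params(params), is_niche_layout(layout))
  if (params$n_stem != layout$n_stem)
    stop("params$n_stem must match the layout", call. = FALSE)
  structure(list(params = params, layout = layout,
                 inhibition_mode = inhibition_mode,
                 strength = check_nonneg(strength, "strength")),
            class = "cohort_arm")
}

#' Cohort design for synthetic lineage-tracing experiments
#'
#' Describes a fixed-tissue clonal-fate experiment: sparse tamoxifen
#' labelling of single stem cells, treatment from `treatment_day` (24 h post
#' induction), and cross-sectional scoring — each mouse is sampled at one
#' timepoint and contributes `crypts_per_mouse` labelled crypts.
#'
#' @param arms named list of [cohort_arm()] objects (e.g. `vehicle`,
#'   `inhibitor`).
#' @param timepoints ascending scoring days.
#' @param mice_per_arm mice per arm per timepoint.
#' @param crypts_per_mouse labelled crypts scored per mouse.
#' @param labelling_mean mean of the zero-truncated Poisson number of
#'   induced cells per labelled crypt (default 1.2, low-dose induction).
#' @param induction `"low"` or `"high"`; a convenience switch selecting the
#'   documented low/high labelling means when `labelling_mean` is `NULL`.
#' @param treatment_day day treatment starts (default 1).
#' @param clones_scored_min minimum clones per (arm, day) cell the design
#'   must yield (default 200).
#' @param crypts_per_field crypts per imaging field for the
#'   clones-per-field readout.
#' @param het_bias heterozygous-vs-wild-type boundary win probability.
#' @return an object of class `cohort_design`.
#' @examples
#' s <- default_drift_settings()
#' d <- default_fixation_design(mice_per_arm = 1, crypts_per_mouse = 50,
#'                              clones_scored_min = 50)
#' names(d$arms)
#' @export
cohort_design <- function(arms, timepoints, mice_per_arm = 3L,
                          crypts_per_mouse = 200L, labelling_mean = NULL,
                          induction = c("low", "high"), treatment_day = 1,
                          clones_scored_min = 200L, crypts_per_field = 50,
                          het_bias = 0.5) {
  induction <- match.arg(induction)
  if (is.null(labelling_mean)) {
    s <- default_drift_settings()
    labelling_mean <- if (induction == "low") s$labelling_mean_low
                      else s$labelling_mean_high
  }
  if (length(arms) == 0L || is.null(names(arms)) || any(names(arms) == ""))
    stop("arms must be a non-empty named list", call. = FALSE)
  for (a in arms) if (!inherits(a, "cohort_arm"))
    stop("every arm must be built with cohort_arm()", call. = FALSE)
  if (length(timepoints) == 0L || is.unsorted(timepoints, strictly = TRUE) ||
      any(timepoints < 0))
    stop("timepoints must be ascending non-negative days", call. = FALSE)
  mice_per_arm <- check_count(mice_per_arm, "mice_per_arm", min = 1L)
  crypts_per_mouse <- check_count(crypts_per_mouse, "crypts_per_mouse",
                                  min = 1L)
  clones_scored_min <- check_count(clones_scored_min, "clones_scored_min",
                                   min = 1L)
  if (mice_per_arm * crypts_per_mouse < clones_scored_min)
    stop("design yields fewer than clones_scored_min clones per (arm, day)",
         call. = FALSE)
  structure(list(arms = arms, timepoints = as.numeric(timepoints),
                 mice_per_arm = mice_per_arm,
                 crypts_per_mouse = crypts_per_mouse,
                 labelling_mean = check_positive(labelling_mean,
                                                 "labelling_mean"),
                 induction = induction,
                 treatment_day = check_nonneg(treatment_day, "treatment_day"),
                 clones_scored_min = clones_scored_min,
                 crypts_per_field = check_positive(crypts_per_field,
                                                   "crypts_per_field"),
                 het_bias = check_prob(het_bias, "het_bias")),
            class = "cohort_design")
}

#' @export
print.cohort_design <- function(x, ...) {
  cat(sprintf(
    "Cohort design: arms [%s]; days %s; %d mice/arm/day x %d crypts; labelling mean %.3g (%s)\n",
    paste(names(x$arms), collapse = ", "),
    paste(x$timepoints, collapse = ", "), x$mice_per_arm,
    x$crypts_per_mouse, x$labelling_mean, x$induction))
  invisible(x)
}

#' Documented default cohort designs
#'
#' `default_fixation_design()` is the two-arm (vehicle vs Porcupine
#' inhibitor) fixed-tissue clonal-fate design; the inhibitor arm removes
#' the border compartment from the competition at the treatment switch.
#' `default_imaging_design()` is the intravital-imaging design, where the
#' treated arm instead loses border occupants stochastically at the
#' documented border-loss rate.
#'
#' @param timepoints scoring days.
#' @param mice_per_arm,crypts_per_mouse,clones_scored_min,labelling_mean
#'   passed to [cohort_design()].
#' @return a [cohort_design()] object.
#' @export
default_fixation_design <- function(timepoints = default_drift_settings()$timepoints,
                                    mice_per_arm = 3L,
                                    crypts_per_mouse = 200L,
                                    clones_scored_min = 200L,
                                    labelling_mean = NULL) {
  s <- default_drift_settings()
  base <- drift_params(s$n_stem, s$replacement_rate)
  ly <- make_niche(s$n_centre, s$n_border)
  cohort_design(
    arms = list(
      vehicle = cohort_arm(base, ly, "none"),
      inhibitor = cohort_arm(base, ly, "remove_border", strength = 1)),
    timepoints = timepoints, mice_per_arm = mice_per_arm,
    crypts_per_mouse = crypts_per_mouse,
    labelling_mean = labelling_mean %||% s$labelling_mean_low,
    treatment_day = s$treatment_day,
    clones_scored_min = clones_scored_min,
    crypts_per_field = s$crypts_per_field)
}

#' @rdname default_fixation_design
#' @param imaging_days days of imaging relative to the start of treatment.
#' @export
default_imaging_design <- function(crypts_per_mouse = 30L,
                                   imaging_days = 1:4) {
  s <- default_drift_settings()
  base <- drift_params(s$n_stem, s$replacement_rate)
  ly <- make_niche(s$n_centre, s$n_border)
  d <- cohort_design(
    arms = list(
      control = cohort_arm(base, ly, "none"),
      inhibitor = cohort_arm(base, ly, "border_loss",
                             strength = s$border_loss_rate)),
    timepoints = s$treatment_day + imaging_days,
    mice_per_arm = 1L, crypts_per_mouse = crypts_per_mouse,
    labelling_mean = 1e-6, clones_scored_min = 1L,
    treatment_day = s$treatment_day)
  d$imaging_days <- imaging_days
  d
}

# --- labelling ---------------------------------------------------------

# initial state of one labelled crypt (runs under the caller's RNG state)
make_init <- function(n_stem, layout, labelling_mean, recombination = NULL) {
  k <- min(rztpois(1L, labelling_mean), n_stem)
  pos <- sample.int(n_stem, k)
  labels <- integer(n_stem)
  genotypes <- integer(n_stem)
  if (is.null(recombination)) {
    labels[pos] <- 1L
  } else {
    g <- sample_cell_genotype(recombination, k)
    labels[pos] <- as.integer(g$reporter_on)
    genotypes[pos] <- g$apc_alleles
  }
  list(labels = labels, genotypes = genotypes, positions = pos,
       n_induced = k,
       start_compartment = layout$assignment[pos[1]])
}

#' Generate initial labelled-crypt states
#'
#' Sparse tamoxifen induction: the number of induced cells per labelled
#' crypt is zero-truncated Poisson with mean `design$labelling_mean`
#' (few cells per crypt at low dose), induced cells are placed uniformly
#' over the niche positions, and — for Apc cohorts — each induced cell's
#' reporter/Apc genotype is drawn from the supplied recombination model.
#'
#' @param design a [cohort_design()] object.
#' @param n_crypts number of crypts to initialise.
#' @param arm arm name whose layout to use (default first arm).
#' @param recombination optional [recombination_params()] for Apc cohorts.
#' @param seed integer master seed; crypt `i` uses a seed derived from
#'   `(seed, i)`, so initial states are reproducible and order-independent.
#' @return list of per-crypt initial states (`labels`, `genotypes`,
#'   `positions`, `n_induced`, `start_compartment`).
#' @export
generate_labelling <- function(design, n_crypts, arm = NULL,
                               recombination = NULL, seed = 1L) {
  stopifnot(inherits(design, "cohort_design"))
  n_crypts <- check_count(n_crypts, "n_crypts", min = 1L)
  arm <- arm %||% names(design$arms)[1]
  a <- design$arms[[arm]]
  if (is.null(a)) stop(sprintf("unknown arm '%s'", arm), call. = FALSE)
  lapply(seq_len(n_crypts), function(i) {
    set.seed(crypt_seed(seed, i))
    make_init(a$params$n_stem, a$layout, design$labelling_mean, recombination)
  })
}

# --- single-crypt engine with treatment switch -------------------------

# simulate one crypt on [0, max(t_grid)] with inhibition applied from
# treatment_day; returns labels/genotypes (original ring size x length(t_grid),
# NA rows after removal) sampled at t_grid
run_crypt_states <- function(arm, init, t_grid, treatment_day,
                             het_bias = 0.5) {
  p0 <- arm$params
  ly0 <- arm$layout
  N <- p0$n_stem
  td <- treatment_day
  no_switch <- arm$inhibition_mode == "none" || arm$strength == 0 ||
    max(t_grid) <= td
  if (no_switch) {
    tr <- simulate_crypt(p0, init$labels, t_grid,
                         init_genotypes = init$genotypes, layout = ly0,
                         het_bias = het_bias)
    return(list(times = t_grid, labels = tr$labels,
                genotypes = tr$genotypes))
  }
  pre <- t_grid[t_grid <= td]
  post <- t_grid[t_grid > td]
  grid1 <- unique(c(pre, td))
  tr1 <- simulate_crypt(p0, init$labels, grid1,
                        init_genotypes = init$genotypes, layout = ly0,
                        het_bias = het_bias)
  at_td <- length(grid1)
  lab_td <- tr1$labels[, at_td]
  gen_td <- tr1$genotypes[, at_td]
  inh <- apply_wnt_inhibition(p0, ly0, arm$inhibition_mode, arm$strength)
  if (arm$inhibition_mode == "remove_border") {
    keep <- kept_positions(ly0, inh$layout$n_border)
    tr2 <- simulate_crypt(inh$params, lab_td[keep], post,
                          init_genotypes = gen_td[keep],
                          layout = inh$layout, het_bias = het_bias,
                          t_start = td)
    lab2 <- matrix(NA_integer_, N, length(post))
    gen2 <- matrix(NA_integer_, N, length(post))
    lab2[keep, ] <- tr2$labels
    gen2[keep, ] <- tr2$genotypes
  } else {
    tr2 <- simulate_crypt(inh$params, lab_td, post, init_genotypes = gen_td,
                          layout = inh$layout, het_bias = het_bias,
                          t_start = td)
    lab2 <- tr2$labels
    gen2 <- tr2$genotypes
  }
  labs <- cbind(tr1$labels[, match(pre, grid1), drop = FALSE], lab2)
  gens <- cbind(tr1$genotypes[, match(pre, grid1), drop = FALSE], gen2)
  list(times = t_grid, labels = labs, genotypes = gens)
}

# --- cohort runners ----------------------------------------------------

new_clonal_dataset <- function(df, seed, pars) {
  attr(df, "provenance") <- new_provenance(seed, pars)
  class(df) <- c("clonal_dataset", class(df))
  df
}

#' @export
print.clonal_dataset <- function(x, ...) {
  pv <- attr(x, "provenance")
  cat(sprintf("Clonal dataset: %d records, arms [%s], days %s (seed %s)\n",
              nrow(x), paste(unique(x$arm), collapse = ", "),
              paste(sort(unique(x$day)), collapse = ", "),
              format(pv$seed)))
  NextMethod()
}

#' Run a neutral-drift clonal-fate cohort
#'
#' Simulates every labelled crypt of the design with the ring model,
#' switching each arm to its inhibition mode at `design$treatment_day`
#' (treatment starts 24 h post induction), and scores clone records at each
#' mouse's timepoint: clone size in cells, eighths bin, fixed and surviving
#' flags.  Mice are cross-sectional — each mouse is scored at exactly one
#' day.
#'
#' @param design a [cohort_design()] object.
#' @param seed integer master seed; per-crypt seeds are derived from it, so
#'   identical (design, seed) gives identical datasets.
#' @return a `clonal_dataset` tibble with provenance attribute.
#' @examples
#' d <- default_fixation_design(timepoints = c(4, 21), mice_per_arm = 1,
#'                              crypts_per_mouse = 40, clones_scored_min = 40)
#' ds <- run_neutral_cohort(d, seed = 1)
#' summarize_timepoint(ds[ds$arm == "vehicle" & ds$day == 21, ])
#' @export
run_neutral_cohort <- function(design, seed = 1L) {
  stopifnot(inherits(design, "cohort_design"))
  arms <- names(design$arms)
  n_total <- length(arms) * length(design$timepoints) *
    design$mice_per_arm * design$crypts_per_mouse
  arm_v <- character(n_total); mouse_v <- character(n_total)
  day_v <- numeric(n_total); comp_v <- character(n_total)
  ind_v <- integer(n_total); size_v <- integer(n_total)
  ncomp_v <- integer(n_total)
  idx <- 0L
  for (arm_name in arms) {
    a <- design$arms[[arm_name]]
    for (day in design$timepoints) {
      for (m in seq_len(design$mice_per_arm)) {
        mouse_id <- sprintf("%s_d%g_m%d", arm_name, day, m)
        for (cc in seq_len(design$crypts_per_mouse)) {
          idx <- idx + 1L
          set.seed(crypt_seed(seed, idx))
          init <- make_init(a$params$n_stem, a$layout,
                            design$labelling_mean)
          st <- run_crypt_states(a, init, t_grid = day,
                                 treatment_day = design$treatment_day,
                                 het_bias = design$het_bias)
          lab <- st$labels[, 1]
          arm_v[idx] <- arm_name; mouse_v[idx] <- mouse_id
          day_v[idx] <- day; comp_v[idx] <- init$start_compartment
          ind_v[idx] <- init$n_induced
          ncomp_v[idx] <- sum(!is.na(lab))
          size_v[idx] <- sum(lab == 1L, na.rm = TRUE)
        }
      }
    }
  }
  eighths <- integer(n_total)
  for (n in unique(ncomp_v)) {
    sel <- ncomp_v == n
    eighths[sel] <- score_eighths(size_v[sel], n)
  }
  df <- tibble::tibble(
    arm = arm_v, mouse_id = mouse_v, day = day_v,
    crypt_id = sprintf("c%06d", seq_len(n_total)),
    n_induced = ind_v, start_compartment = comp_v,
    clone_size_cells = size_v, n_competing = ncomp_v, eighths = eighths,
    fixed = eighths == 8L, surviving = size_v >= 1L)
  new_clonal_dataset(df, seed, design)
}

#' Run an intravital-imaging cohort
#'
#' Emulates daily intravital tracking of single labelled stem cells over
#' the first days of treatment: every clone starts as exactly one induced
#' cell (placed in a prescribed compartment), treatment starts at
#' `design$treatment_day`, and the ring is sampled once per day from one
#' day after the first treatment.  Days in the output are counted as
#' imaging days (day 1 = first imaging session); clones are conditioned on
#' being present at day 1.
#'
#' @param design an imaging [cohort_design()] (see
#'   [default_imaging_design()]); arm inhibition `"border_loss"` reproduces
#'   the treated group.
#' @param clones_per_compartment clones started per (arm, compartment).
#' @param seed integer master seed.
#' @return list with `trajectories` (nested by arm then compartment) and
#'   `persistence`, the combined [persistence_curve()] tibble with an `arm`
#'   column.
#' @export
run_imaging_cohort <- function(design, clones_per_compartment = 30L,
                               seed = 1L) {
  stopifnot(inherits(design, "cohort_design"))
  clones_per_compartment <- check_count(clones_per_compartment,
                                        "clones_per_compartment", min = 1L)
  days_abs <- design$timepoints   # absolute days post induction
  td <- design$treatment_day
  trajectories <- list()
  curves <- list()
  idx <- 0L
  for (arm_name in names(design$arms)) {
    a <- design$arms[[arm_name]]
    trajectories[[arm_name]] <- list()
    for (comp in c("centre", "border")) {
      pool <- which(a$layout$assignment == comp)
      if (length(pool) == 0L) next
      trs <- vector("list", clones_per_compartment)
      for (i in seq_len(clones_per_compartment)) {
        idx <- idx + 1L
        set.seed(crypt_seed(seed, idx))
        pos <- pool[sample.int(length(pool), 1L)]
        labels <- integer(a$params$n_stem)
        labels[pos] <- 1L
        init <- list(labels = labels, genotypes = integer(a$params$n_stem),
                     positions = pos, n_induced = 1L,
                     start_compartment = comp)
        st <- run_crypt_states(a, init, t_grid = days_abs,
                               treatment_day = td,
                               het_bias = design$het_bias)
        tr <- structure(list(times = days_abs - td, labels = st$labels,
                             genotypes = st$genotypes,
                             events = NA, params = a$params,
                             layout = a$layout),
                        class = "crypt_trajectory")
        attr(tr, "start_compartment") <- comp
        trs[[i]] <- tr
      }
      # condition on presence at the first imaging day
      present <- vapply(trs, function(tr)
        sum(tr$labels[, 1] == 1L, na.rm = TRUE) >= 1L, logical(1))
      trs <- trs[present]
      trajectories[[arm_name]][[comp]] <- trs
      if (length(trs) > 0L) {
        cv <- persistence_curve(trs, comp)
        cv$arm <- arm_name
        curves[[paste(arm_name, comp)]] <- cv
      }
    }
  }
  persistence <- do.call(rbind, curves)
  rownames(persistence) <- NULL
  list(trajectories = trajectories, persistence = persistence,
       provenance = new_provenance(seed, design))
}

#' Run an Apc tumour-initiation cohort
#'
#' Simulates crypt-level competition of Apc-mutant clones: induced cells
#' draw a reporter state and 0-2 recombined Apc alleles from the
#' region-specific Cre-lox model, Apc-null cells displace non-null
#' neighbours with probability `bias` (heterozygous cells compete neutrally
#' by default), and crypts are scored for the reporter clone, the Apc-null
#' clone (none/partial/full, and whether the null clone holds the majority
#' of positions), at each timepoint.  The adenoma-initiation count of a
#' mouse is its number of crypts fully fixed for the Apc-null clone at
#' scoring; clonal expansion beyond the crypt is not modelled.
#'
#' @param design a [cohort_design()] (typically high induction).
#' @param bias Apc-null boundary win probability (>= 0.5 expected).
#' @param recombination per-region configuration, see
#'   [default_recombination_config()].
#' @param region_mix named proportions of crypts per region (e.g.
#'   `c(proximal = 0.5, distal = 0.5)`).
#' @param seed integer master seed.
#' @return list with `dataset` (per-crypt tibble incl. genotype scores) and
#'   `adenoma_counts` (per mouse at the final timepoint).
#' @export
run_apc_cohort <- function(design,
                           bias = default_drift_settings()$apc_bias,
                           recombination = default_recombination_config(),
                           region_mix = c(proximal = 1), seed = 1L) {
  stopifnot(inherits(design, "cohort_design"))
  bias <- check_prob(bias, "bias")
  if (is.null(names(region_mix)) || any(!names(region_mix) %in%
                                        names(recombination)))
    stop("region_mix names must match the recombination config",
         call. = FALSE)
  region_mix <- region_mix / sum(region_mix)
  rp <- lapply(setNames(names(region_mix), names(region_mix)),
               regional_params, config = recombination)
  arms <- names(design$arms)
  n_total <- length(arms) * length(design$timepoints) *
    design$mice_per_arm * design$crypts_per_mouse
  arm_v <- character(n_total); mouse_v <- character(n_total)
  day_v <- numeric(n_total); reg_v <- character(n_total)
  ind_v <- integer(n_total); tom_v <- integer(n_total)
  null_v <- integer(n_total); ncomp_v <- integer(n_total)
  cat_v <- character(n_total)
  idx <- 0L
  for (arm_name in arms) {
    a <- design$arms[[arm_name]]
    ab <- a
    ab$params$bias <- bias
    for (day in design$timepoints) {
      for (m in seq_len(design$mice_per_arm)) {
        mouse_id <- sprintf("%s_d%g_m%d", arm_name, day, m)
        for (cc in seq_len(design$crypts_per_mouse)) {
          idx <- idx + 1L
          set.seed(crypt_seed(seed, idx))
          region <- names(region_mix)[
            sample.int(length(region_mix), 1L, prob = region_mix)]
          init <- make_init(a$params$n_stem, a$layout,
                            design$labelling_mean,
                            recombination = rp[[region]])
          st <- run_crypt_states(ab, init, t_grid = day,
                                 treatment_day = design$treatment_day,
                                 het_bias = design$het_bias)
          lab <- st$labels[, 1]
          gen <- st$genotypes[, 1]
          keep <- !is.na(lab)
          arm_v[idx] <- arm_name; mouse_v[idx] <- mouse_id
          day_v[idx] <- day; reg_v[idx] <- region
          ind_v[idx] <- init$n_induced
          ncomp_v[idx] <- sum(keep)
          tom_v[idx] <- sum(lab[keep] == 1L)
          null_v[idx] <- sum(gen[keep] == 2L)
          cat_v[idx] <- score_crypt_genotype(gen[keep])
        }
      }
    }
  }
  eighths <- integer(n_total)
  for (n in unique(ncomp_v)) {
    sel <- ncomp_v == n
    eighths[sel] <- score_eighths(tom_v[sel], n)
  }
  df <- tibble::tibble(
    arm = arm_v, mouse_id = mouse_v, day = day_v,
    crypt_id = sprintf("c%06d", seq_len(n_total)), region = reg_v,
    n_induced = ind_v, tdtom_cells = tom_v, apc_null_cells = null_v,
    n_competing = ncomp_v, eighths = eighths, category = cat_v,
    majority_loss = null_v >= ncomp_v / 2,
    surviving = tom_v >= 1L, fixed = eighths == 8L)
  final_day <- max(design$timepoints)
  fin <- df[df$day == final_day, ]
  counts <- tapply(fin$category == "full", fin$mouse_id, sum)
  adenoma <- tibble::tibble(
    mouse_id = names(counts),
    arm = sub("_d.*$", "", names(counts)),
    count = as.integer(counts))
  list(dataset = new_clonal_dataset(df, seed, list(design, bias,
                                                   recombination,
                                                   region_mix)),
       adenoma_counts = adenoma)
}

#' Summarise reporter/Apc discordance at crypt level
#'
#' Among reporter-positive crypts (>= 1 tdTom+ cell at scoring): the
#' fraction with no Apc-null cell ("still expresses Apc"), and the fraction
#' in which the Apc-null clone holds at least half of the competing
#' positions ("lost Apc in the majority of cells"), per region.
#'
#' @param dataset the `dataset` tibble of [run_apc_cohort()].
#' @param day scoring day (default: earliest timepoint present).
#' @return tibble per region: `n_tdtom`, `fraction_apc_retained`,
#'   `fraction_majority_loss`.
#' @export
summarize_discordance <- function(dataset, day = NULL) {
  day <- day %||% min(dataset$day)
  d <- dataset[dataset$day == day & dataset$tdtom_cells >= 1L, ]
  if (nrow(d) == 0L) stop("no reporter-positive crypts at that day",
                          call. = FALSE)
  out <- lapply(split(d, d$region), function(x) tibble::tibble(
    region = x$region[1], day = day, n_tdtom = nrow(x),
    fraction_apc_retained = mean(x$apc_null_cells == 0L),
    fraction_majority_loss = mean(x$majority_loss)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
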