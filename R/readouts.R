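#' Score a clone size in eighths
#'
#' Whole-mount clone scoring discretises the labelled fraction of the crypt
#' circumference into eighths, 0-8.  The binning rule: size 0 scores 0, a
#' fully clonal crypt (size N) scores 8, and any surviving non-fixed clone
#' scores `round(8 * size / N)` clamped to 1..7, so survival and fixation
#' are read off the bin exactly.
#'
#' @param clone_size_cells integer clone size(s), 0..`n_stem`.
#' @param n_stem number of competing positions.
#' @return integer eighths score(s) in 0..8.
#' @examples
#' score_eighths(c(0, 6, 16), 16)  # 0, 3, 8
#' @export
score_eighths <- function(clone_size_cells, n_stem) {
  n_stem <- check_count(n_stem, "n_stem", min = 2L)
  s <- clone_size_cells
  if (any(is.na(s)) || any(s != round(s)) || any(s < 0))
    stop("clone_size_cells must be non-negative integers", call. = FALSE)
  if (any(s > n_stem))
    stop("clone_size_cells exceeds n_stem", call. = FALSE)
  e <- as.integer(pmin(7, pmax(1, round(8 * s / n_stem))))
  e[s == 0] <- 0L
  e[s == n_stem] <- 8L
  e
}

# size values (0..N) falling in each eighths bin; used by the likelihood
eighths_bin_map <- function(n_stem) score_eighths(0:n_stem, n_stem)

#' Summarise one timepoint of clonal records
#'
#' The standard fixed-tissue readouts for one day: mean clone size in
#' eighths among surviving clones, fraction of fully fixed crypts, and the
#' number of surviving labelled crypts per microscope field.
#'
#' The fixation denominator is, by default, the surviving clones at that
#' timepoint (`denominator = "surviving"`); clone loss is accounted
#' separately by the clones-per-field readout.  Set
#' `denominator = "induced"` to divide by all induced clones instead.
#' Fields are taken to contain `crypts_per_field` scored crypts, so
#' `clones_per_field = crypts_per_field * n_surviving / n_records`.
#'
#' @param records tibble/data.frame of clone records sharing one `day`, with
#'   columns `day`, `eighths`, `surviving`, `fixed`.
#' @param crypts_per_field crypts per field (> 0), default 50.
#' @param denominator `"surviving"` (default) or `"induced"`.
#' @return one-row tibble: `day`, `n_clones`, `n_surviving`,
#'   `mean_clone_size_eighths`, `fraction_fixed`, `clones_per_field`.
#' @examples
#' rec <- tibble::tibble(day = 14, eighths = c(8L, 4L, 0L, 4L),
#'                       surviving = c(TRUE, TRUE, FALSE, TRUE),
#'                       fixed = c(TRUE, FALSE, FALSE, FALSE))
#' summarize_timepoint(rec)  # mean 16/3, fraction fixed 1/3
#' @export
summarize_timepoint <- function(records, crypts_per_field = 50,
                                denominator = c("surviving", "induced")) {
  denominator <- match.arg(denominator)
  if (is.null(records) || nrow(records) == 0L)
    stop("records must contain at least one clone", call. = FALSE)
  if (length(unique(records$day)) != 1L)
    stop("all records must share one day; split by day first", call. = FALSE)
  crypts_per_field <- check_positive(crypts_per_field, "crypts_per_field")
  surv <- records$surviving
  n <- nrow(records)
  ns <- sum(surv)
  denom <- if (denominator == "surviving") ns else n
  tibble::tibble(
    day = records$day[1],
    n_clones = n,
    n_surviving = ns,
    mean_clone_size_eighths = if (ns > 0) mean(records$eighths[surv]) else NA_real_,
    fraction_fixed = if (denom > 0) sum(records$fixed) / denom else NA_real_,
    clones_per_field = crypts_per_field * ns / n)
}

#' Score a crypt's mutant genotype category
#'
#' Mirrors partial/full crypt scoring by nuclear beta-catenin: a crypt is
#' `"full"` when every competing position carries the Apc-null genotype
#' (both alleles recombined), `"partial"` when some but not all do, and
#' `"none"` otherwise.
#'
#' @param genotypes integer vector of per-position genotypes at scoring time
#'   (0 wt, 1 het, 2 null); `NA` entries (removed positions) are ignored.
#' @return `"none"`, `"partial"` or `"full"`.
#' @examples
#' score_crypt_genotype(c(2, 2, 0, 0))  # "partial"
#' @export
score_crypt_genotype <- function(genotypes) {
  g <- genotypes[!is.na(genotypes)]
  if (length(g) == 0L) stop("no competing positions", call. = FALSE)
  if (!all(g %in% 0:2))
    stop("unknown genotype code; use 0 (wt), 1 (het), 2 (null)", call. = FALSE)
  n_null <- sum(g == 2L)
  if (n_null == 0L) "none" else if (n_null == length(g)) "full" else "partial"
}

#' Ratio of full to recombined crypts
#'
#' `#full / (#full + #partial)`; crypts scoring `"none"` are excluded, so
#' the ratio tracks how partially recombined crypts resolve into fully
#' clonal ones over time.
#'
#' @param scores character vector of `"none"`/`"partial"`/`"full"` scores.
#' @return the ratio.
#' @examples
#' full_crypt_ratio(c("full", "partial", "partial", "none"))  # 1/3
#' @export
full_crypt_ratio <- function(scores) {
  if (!all(scores %in% c("none", "partial", "full")))
    stop("scores must be none/partial/full", call. = FALSE)
  nf <- sum(scores == "full")
  np <- sum(scores == "partial")
  if (nf + np == 0L)
    stop("no recombined crypts: denominator is zero", call. = FALSE)
  nf / (nf + np)
}
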