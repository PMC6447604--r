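#' Average extraction-replicate copy numbers
#'
#' Template-containing samples are extracted in duplicate and each extract
#' run once on ddPCR; their per-reaction copy numbers are averaged to give
#' the sample ACN (and NTC wells are averaged across their four technical
#' replicates the same way). The range (max - min) is retained for error
#' bars, and runs with fewer than the expected number of replicates are
#' flagged (e.g. a buffer that yielded material for only one extraction).
#'
#' @param values Numeric vector of copies per reaction, length >= 1.
#' @param expected_n Expected replicate count (default 2).
#'
#' @return List with `mean`, `range`, `n` and `single_replicate` flag
#'   (`TRUE` when `n < expected_n`).
#' @examples
#' average_replicates(c(100, 120))  # mean 110, range 20
#' @export
average_replicates <- function(values, expected_n = 2) {
  if (length(values) < 1) stop("need at least one replicate value", call. = FALSE)
  stopifnot(is.numeric(values), all(is.finite(values)))
  list(mean = mean(values), range = max(values) - min(values),
       n = length(values), single_replicate = length(values) < expected_n)
}

#' Background- and dilution-adjust a sample ACN
#'
#' Applies the adjustment `(ACN_sample - ACN_ntc) * dilution_factor`, which
#' yields copies per microlitre of DNA extract because each 20 ul reaction
#' receives exactly 1 ul of diluted extract. A negative adjusted value
#' (background exceeding signal) is clipped to 0 and flagged rather than
#' reported as a negative concentration.
#'
#' @param acn_sample Replicate-averaged sample copies per reaction.
#' @param acn_ntc NTC-averaged background copies per reaction.
#' @param dilution_factor Fold dilution of the extract; must be >= 1.
#'
#' @return List with `copies_per_ul_extract` and `clipped_flag`.
#' @examples
#' adjust_acn(100, 4, 50)$copies_per_ul_extract  # 4800
#' @export
adjust_acn <- function(acn_sample, acn_ntc, dilution_factor) {
  stopifnot(is.numeric(acn_sample), acn_sample >= 0,
            is.numeric(acn_ntc), acn_ntc >= 0)
  if (!is.numeric(dilution_factor) || dilution_factor < 1)
    stop("dilution_factor must be >= 1", call. = FALSE)
  adj <- (acn_sample - acn_ntc) * dilution_factor
  clipped <- adj < 0
  list(copies_per_ul_extract = max(adj, 0), clipped_flag = clipped)
}

#' Normalise extract concentration to stool mass
#'
#' The default `"literal"` mode divides copies per microlitre of extract by
#' the mass of stool (mg) contained in the ~200 ul homogenate aliquot that
#' went into the extraction, exactly as the pipeline reports copies per mg
#' stool. The opt-in `"total"` mode first multiplies by the elution volume,
#' giving total recovered copies per mg.
#'
#' @param copies_per_ul_extract Copies per microlitre of extract; >= 0.
#' @param stool_mass_mg Stool mass in the homogenate aliquot, mg; > 0.
#' @param mode `"literal"` (default) or `"total"`.
#' @param elution_volume_ul Elution volume, microlitres (default 100); used
#'   only in `"total"` mode.
#'
#' @return Copies per mg stool (numeric scalar).
#' @examples
#' normalize_per_mg(4950, 49.5)  # 100
#' @export
normalize_per_mg <- function(copies_per_ul_extract, stool_mass_mg,
                             mode = c("literal", "total"),
                             elution_volume_ul = 100) {
  mode <- match.arg(mode)
  stopifnot(is.numeric(copies_per_ul_extract), copies_per_ul_extract >= 0)
  if (!is.numeric(stool_mass_mg) || !is.finite(stool_mass_mg) || stool_mass_mg <= 0)
    stop("stool_mass_mg must be > 0", call. = FALSE)
  if (mode == "literal") copies_per_ul_extract / stool_mass_mg
  else copies_per_ul_extract * elution_volume_ul / stool_mass_mg
}

#' Percent spike-in recovery
#'
#' R = 100 x (ACN(purified lysate with gDNA spike) - ACN(purified lysate
#' with buffer)) / ACN(unpurified gDNA spike alone). Values above 100% or
#' below 0% are reported and flagged, not clipped: they indicate measurement
#' noise, not impossible recoveries.
#'
#' @param acn_spike ACN of purified faecal lysate with gDNA spike.
#' @param acn_buffer ACN of purified faecal lysate with buffer only.
#' @param acn_alone ACN of the unpurified gDNA spike alone; must be > 0.
#'
#' @return List with `recovery_pct` and `out_of_range` flag.
#' @examples
#' spike_recovery(1000, 200, 1600)$recovery_pct  # 50
#' @export
spike_recovery <- function(acn_spike, acn_buffer, acn_alone) {
  if (!is.numeric(acn_alone) || acn_alone <= 0)
    stop("acn_alone must be > 0", call. = FALSE)
  r <- 100 * (acn_spike - acn_buffer) / acn_alone
  list(recovery_pct = r, out_of_range = r < 0 || r > 100)
}

#' Assay specificity as a signal-to-noise ratio
#'
#' ACN per pg of input DNA from the intended (host) source divided by ACN
#' per pg from a non-target genome. A zero-noise measurement is reported as
#' a censored lower bound (">x") computed against `epsilon`, one
#' background-subtracted copy per assay input, matching the ">1000"-style
#' reporting convention.
#'
#' @param acn_per_pg_signal Copies per pg input DNA, target genome; >= 0.
#' @param acn_per_pg_noise Copies per pg input DNA, non-target genome; >= 0.
#' @param epsilon Detection floor used for censoring (default 1/80, one copy
#'   in an 80 pg input).
#'
#' @return List with `ratio`, `censored` flag and `label` (e.g. `"125"` or
#'   `">40000"`).
#' @examples
#' signal_to_noise(500, 4)$ratio  # 125
#' @export
signal_to_noise <- function(acn_per_pg_signal, acn_per_pg_noise,
                            epsilon = 1 / 80) {
  if (!is.numeric(acn_per_pg_signal) || acn_per_pg_signal < 0 ||
      !is.numeric(acn_per_pg_noise) || acn_per_pg_noise < 0)
    stop("signal and noise must be non-negative", call. = FALSE)
  if (acn_per_pg_noise == 0) {
    bound <- acn_per_pg_signal / epsilon
    list(ratio = bound, censored = TRUE, label = sprintf(">%g", bound))
  } else {
    r <- acn_per_pg_signal / acn_per_pg_noise
    list(ratio = r, censored = FALSE, label = sprintf("%g", r))
  }
}

#' Percent yield of a standard
#'
#' 100 x measured copies / expected copies; may exceed 100 (digested gDNA
#' standards scored against in silico predicted copies yielded a median of
#' 395%, indicating the prediction underestimates true copy number).
#'
#' @param measured Measured copies; >= 0.
#' @param expected Expected (theoretical) copies; > 0.
#' @return Percent yield (numeric scalar).
#' @examples
#' percent_yield(22910, 5800)  # 395
#' @export
percent_yield <- function(measured, expected) {
  if (!is.numeric(expected) || expected <= 0)
    stop("expected copies must be > 0", call. = FALSE)
  stopifnot(is.numeric(measured), measured >= 0)
  100 * measured / expected
}

#' Percent coefficient of variation
#'
#' 100 x sample standard deviation (n - 1 denominator) / mean, the
#' day-to-day reproducibility metric for triplicate standard curves.
#'
#' @param replicate_values Numeric vector, length >= 2, with positive mean.
#' @return Percent CV (numeric scalar).
#' @examples
#' percent_cv(c(8, 10, 12))  # 20
#' @export
percent_cv <- function(replicate_values) {
  if (length(replicate_values) < 2)
    stop("need at least two replicate values", call. = FALSE)
  m <- mean(replicate_values)
  if (!is.finite(m) || m <= 0) stop("mean must be > 0", call. = FALSE)
  100 * stats::sd(replicate_values) / m
}

#' Fit and validate a standard curve
#'
#' Ordinary least squares of measured on theoretical copies (linear scale),
#' with per-point percent yield, per-level percent CV across replicates and
#' the median percent yield, the three validation statistics reported for
#' the dilution-series experiments.
#'
#' @param points Data.frame with numeric columns `theoretical` and
#'   `measured`; at least two distinct theoretical values.
#'
#' @return An object of class `standard_curve_fit`: list with `points`,
#'   `slope`, `intercept`, `r_squared`, `percent_yield_per_point`,
#'   `median_percent_yield` and `percent_cv_per_level` (named by theoretical
#'   level; `NA` for singleton levels).
#' @examples
#' fit_standard_curve(data.frame(theoretical = c(100, 200, 400),
#'                               measured = c(100, 200, 400)))$slope
#' @export
fit_standard_curve <- function(points) {
  stopifnot(is.data.frame(points),
            all(c("theoretical", "measured") %in% names(points)))
  th <- points$theoretical; me <- points$measured
  if (length(unique(th)) < 2)
    stop("need at least two distinct theoretical values", call. = FALSE)
  if (any(th <= 0)) stop("theoretical copies must be > 0", call. = FALSE)
  fit <- stats::lm(me ~ th)
  yields <- 100 * me / th
  cvs <- vapply(split(me, th), function(v)
    if (length(v) >= 2 && mean(v) > 0) percent_cv(v) else NA_real_, numeric(1))
  structure(
    list(points = points,
         slope = unname(stats::coef(fit)[2]),
         intercept = unname(stats::coef(fit)[1]),
         r_squared = summary(fit)$r.squared,
         percent_yield_per_point = yields,
         median_percent_yield = stats::median(yields),
         percent_cv_per_level = cvs),
    class = "standard_curve_fit"
  )
}

#' @export
print.standard_curve_fit <- function(x, ...) {
  cat(sprintf("<standard_curve_fit> slope %.4g, intercept %.4g, R^2 %.4f, median yield %.1f%%\n",
              x$slope, x$intercept, x$r_squared, x$median_percent_yield))
  invisible(x)
}

#' Conversion constants for genome-equivalent and cell-count estimates
#'
#' `ge_per_ng` converts a mass of human genomic DNA to haploid genome
#' equivalents; 290 GE/ng reproduces all three reference conversions
#' (800 ng = 232,000 GE, 80 ng = 23,200 GE, 8 ng = 2,320 GE).
#' `insilico_copies_per_genome` is the predicted LINE-1 target copies per
#' haploid genome (~5,800) and `median_yield_fraction` the empirical
#' measured/predicted ratio for digested gDNA (3.95, i.e. a 395% median
#' yield); their product is the empirical copies per genome equivalent used
#' for cell-count estimation.
#'
#' @param ge_per_ng Genome equivalents per ng gDNA (default 290).
#' @param insilico_copies_per_genome Predicted target copies per haploid
#'   genome (default 5800).
#' @param median_yield_fraction Empirical measured/predicted yield fraction
#'   (default 3.95).
#'
#' @return An object of class `conversion_constants` (a validated list).
#' @export
conversion_constants <- function(ge_per_ng = 290,
                                 insilico_copies_per_genome = 5800,
                                 median_yield_fraction = 3.95) {
  stopifnot(ge_per_ng > 0, insilico_copies_per_genome > 0,
            median_yield_fraction > 0)
  structure(list(ge_per_ng = ge_per_ng,
                 insilico_copies_per_genome = insilico_copies_per_genome,
                 median_yield_fraction = median_yield_fraction),
            class = "conversion_constants")
}

#' Convert a DNA mass to genome equivalents
#'
#' @param mass_ng Mass of genomic DNA in ng; >= 0.
#' @param constants A [conversion_constants()].
#' @param signif_digits Significant digits for reporting (default 3).
#' @return Genome equivalents (numeric scalar).
#' @examples
#' mass_to_ge(800)  # 232000
#' @export
mass_to_ge <- function(mass_ng, constants = conversion_constants(),
                       signif_digits = 3) {
  if (!is.numeric(mass_ng) || mass_ng < 0)
    stop("mass_ng must be >= 0", call. = FALSE)
  stopifnot(inherits(constants, "conversion_constants"))
  signif(mass_ng * constants$ge_per_ng, signif_digits)
}

#' Empirical target copies per genome equivalent
#'
#' The in silico predicted copies per genome scaled by the empirical median
#' yield fraction; with the defaults, 5,800 x 3.95 = 22,910 LINE-1 copies
#' per genome equivalent.
#'
#' @param constants A [conversion_constants()].
#' @return Copies per genome equivalent (numeric scalar).
#' @examples
#' empirical_copies_per_ge()  # 22910
#' @export
empirical_copies_per_ge <- function(constants = conversion_constants()) {
  stopifnot(inherits(constants, "conversion_constants"))
  constants$insilico_copies_per_genome * constants$median_yield_fraction
}

#' Estimate host cells per mg stool
#'
#' Copies per mg divided by empirical copies per genome equivalent, floored
#' to whole cells. This is an estimate: target copies per genome are
#' polymorphic across individuals, so the conversion constant calibrated on
#' a reference genomic DNA need not transfer exactly.
#'
#' @param copies_per_mg Target copies per mg stool; >= 0.
#' @param copies_per_ge Copies per genome equivalent; > 0 (default
#'   [empirical_copies_per_ge()]).
#' @return Integer cell-count estimate.
#' @examples
#' cells_per_mg(4050000)  # 176
#' @export
cells_per_mg <- function(copies_per_mg, copies_per_ge = empirical_copies_per_ge()) {
  if (!is.numeric(copies_per_ge) || copies_per_ge <= 0)
    stop("copies_per_ge must be > 0", call. = FALSE)
  stopifnot(is.numeric(copies_per_mg), copies_per_mg >= 0)
  floor(copies_per_mg / copies_per_ge)
}

#' Change from baseline for a stability time course
#'
#' Subtracts the time-0 value from each time point. For duplicate
#' extractions the per-point standard error is (range/2)/sqrt(2); the SE of
#' a delta is propagated in quadrature with the baseline SE (the baseline's
#' own delta is exactly 0 with SE 0).
#'
#' @param series Data.frame with numeric columns `time`, `value` and
#'   optionally `se`; must contain time 0.
#' @return Data.frame with columns `time`, `delta` and `se`.
#' @examples
#' change_from_baseline(data.frame(time = c(0, 24), value = c(10, 14)))
#' @export
change_from_baseline <- function(series) {
  stopifnot(is.data.frame(series), all(c("time", "value") %in% names(series)))
  if (!0 %in% series$time)
    stop("series must contain the baseline time 0", call. = FALSE)
  se <- if ("se" %in% names(series)) series$se else rep(0, nrow(series))
  base_i <- which(series$time == 0)[1]
  delta <- series$value - series$value[base_i]
  se_out <- sqrt(se^2 + se[base_i]^2)
  se_out[series$time == 0] <- 0
  data.frame(time = series$time, delta = delta, se = se_out)
}

#' Standard error of duplicate extractions
#'
#' (range/2)/sqrt(2): half-range as the per-replicate deviation, scaled to
#' the SE of the mean of two replicates.
#'
#' @param values Numeric vector of replicate values, length >= 2.
#' @return Numeric standard error.
#' @export
duplicate_se <- function(values) {
  if (length(values) < 2) stop("need >= 2 replicates", call. = FALSE)
  ((max(values) - min(values)) / 2) / sqrt(2)
}
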