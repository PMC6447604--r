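#' Quality-control filter on accepted droplet counts
#'
#' Wells are only quantified if the droplet reader accepted at least
#' `min_accepted` droplets (default 10,000); wells below the minimum are
#' set aside with their observed count as the rejection reason.
#'
#' @param wells A `droplet_well` or list of them.
#' @param min_accepted Minimum accepted droplet count (inclusive).
#'
#' @return A list with elements `accepted` (list of wells) and `rejected`
#'   (data.frame with columns `well_id`, `sample_id`, `assay_id`,
#'   `accepted_count`, `reason`).
#' @examples
#' w <- droplet_well("A01", "S1", "LINE1_60", rep(1800, 9999))
#' qc_filter(list(w))$rejected$reason
#' @export
qc_filter <- function(wells, min_accepted = 10000) {
  stopifnot(is.numeric(min_accepted), min_accepted > 0)
  if (length(wells) == 0)
    return(list(accepted = list(),
                rejected = data.frame(well_id = character(), sample_id = character(),
                                      assay_id = character(), accepted_count = integer(),
                                      reason = character(), stringsAsFactors = FALSE)))
  wells <- as_well_list(wells)
  counts <- vapply(wells, `[[`, integer(1), "accepted_count")
  ok <- counts >= min_accepted
  rej <- wells[!ok]
  rejected <- data.frame(
    well_id = vapply(rej, `[[`, character(1), "well_id"),
    sample_id = vapply(rej, `[[`, character(1), "sample_id"),
    assay_id = vapply(rej, `[[`, character(1), "assay_id"),
    accepted_count = vapply(rej, `[[`, integer(1), "accepted_count"),
    reason = sprintf("accepted droplets %d < minimum %d",
                     vapply(rej, `[[`, integer(1), "accepted_count"),
                     as.integer(min_accepted)),
    stringsAsFactors = FALSE
  )
  list(accepted = wells[ok], rejected = rejected)
}

#' Call droplets positive or negative at an amplitude threshold
#'
#' A droplet is positive when its amplitude is strictly greater than the
#' threshold; a droplet sitting exactly at a threshold chosen to delimit
#' negative droplets is counted negative.
#'
#' @param well A `droplet_well`.
#' @param threshold Positive amplitude threshold.
#'
#' @return An object of class `droplet_counts`: list with `positives`,
#'   `negatives`, `total` and `threshold_used`.
#' @examples
#' w <- droplet_well("A01", "S1", "LINE1_60", c(2000, 3400, 5000))
#' call_droplets(w, 3400)$positives
#' @export
call_droplets <- function(well, threshold) {
  stopifnot(is_droplet_well(well), is.numeric(threshold),
            length(threshold) == 1L, threshold > 0)
  if (well$accepted_count == 0L)
    stop("well '", well$well_id, "' has no droplets; cannot call", call. = FALSE)
  pos <- sum(well$amplitudes > threshold)
  structure(
    list(positives = pos, negatives = well$accepted_count - pos,
         total = well$accepted_count, threshold_used = threshold),
    class = "droplet_counts"
  )
}

#' Derive an amplitude threshold from no-template controls
#'
#' Pools the droplet amplitudes of all supplied NTC wells and returns
#' `multiplier` times their 99.9th percentile, floored at the pooled median.
#' This is the opt-in alternative to the fixed per-assay thresholds in
#' [default_thresholds()].
#'
#' @param ntc_wells A `droplet_well` or list of NTC wells.
#' @param multiplier Safety factor above the NTC percentile (default 1.2).
#'
#' @return Numeric amplitude threshold.
#' @examples
#' ntc <- droplet_well("H01", "NTC", "LINE1_60", rep(1800, 100))
#' threshold_from_ntc(ntc)  # 2160
#' @export
threshold_from_ntc <- function(ntc_wells, multiplier = 1.2) {
  wells <- as_well_list(ntc_wells)
  amps <- unlist(lapply(wells, `[[`, "amplitudes"), use.names = FALSE)
  if (length(amps) == 0)
    stop("no NTC droplets available; use the fixed assay thresholds instead ",
         "(see default_thresholds())", call. = FALSE)
  max(multiplier * stats::quantile(amps, 0.999, names = FALSE, type = 7),
      stats::median(amps))
}

#' Poisson absolute copy-number estimate for one well
#'
#' Under Poisson loading of target molecules into droplets of volume
#' `droplet_volume_nl`, the mean copies per droplet is
#' `lambda = -ln(negatives / total)`, and the target concentration in the
#' reaction is `lambda` divided by the droplet volume in microlitres. The
#' confidence interval is a normal-approximation interval on the negative
#' fraction transformed through `-ln`; with at least 10,000 droplets this is
#' indistinguishable from exact methods. A well with zero negative droplets
#' is saturated: the point estimate is undefined and `saturated_flag` is set
#' rather than raising an error, so batch runs complete.
#'
#' @param counts A `droplet_counts` object from [call_droplets()].
#' @param droplet_volume_nl Droplet volume in nanolitres (default 0.85).
#' @param reaction_volume_ul Reaction volume in microlitres (default 20).
#' @param conf_level Confidence level for the interval (default 0.95).
#'
#' @return An object of class `concentration`: list with `lambda_`,
#'   `copies_per_ul_reaction`, `copies_per_reaction`, `ci_low`, `ci_high`
#'   (copies per microlitre of reaction) and `saturated_flag`.
#' @examples
#' cts <- structure(list(positives = 1813, negatives = 8187, total = 10000,
#'                       threshold_used = 3400), class = "droplet_counts")
#' poisson_concentration(cts)$copies_per_ul_reaction  # ~235.4
#' @export
poisson_concentration <- function(counts, droplet_volume_nl = 0.85,
                                  reaction_volume_ul = 20, conf_level = 0.95) {
  stopifnot(inherits(counts, "droplet_counts"),
            is.numeric(droplet_volume_nl), droplet_volume_nl > 0,
            conf_level > 0, conf_level < 1)
  n <- counts$total
  if (n <= 0) stop("total droplet count must be positive", call. = FALSE)
  vol_ul <- droplet_volume_nl / 1000
  if (counts$negatives == 0) {
    return(structure(
      list(lambda_ = NA_real_, copies_per_ul_reaction = NA_real_,
           copies_per_reaction = NA_real_, ci_low = NA_real_, ci_high = Inf,
           saturated_flag = TRUE),
      class = "concentration"))
  }
  p <- counts$negatives / n
  lambda <- -log(p)
  conc <- lambda / vol_ul
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  se <- sqrt(p * (1 - p) / n)
  p_hi <- min(p + z * se, 1)
  p_lo <- p - z * se
  ci_low <- -log(p_hi) / vol_ul               # high negative fraction -> low conc
  ci_high <- if (p_lo <= 0) Inf else -log(p_lo) / vol_ul
  structure(
    list(lambda_ = lambda, copies_per_ul_reaction = conc,
         copies_per_reaction = conc * reaction_volume_ul,
         ci_low = ci_low, ci_high = ci_high, saturated_flag = FALSE),
    class = "concentration"
  )
}

#' @export
print.concentration <- function(x, ...) {
  if (isTRUE(x$saturated_flag)) {
    cat("<concentration> saturated (no negative droplets)\n")
  } else {
    cat(sprintf("<concentration> %.4g copies/ul reaction (lambda %.4g; 95%% CI %.4g-%.4g)\n",
                x$copies_per_ul_reaction, x$lambda_, x$ci_low, x$ci_high))
  }
  invisible(x)
}

#' Quantify one well end to end
#'
#' Convenience wrapper: [call_droplets()] followed by
#' [poisson_concentration()].
#'
#' @inheritParams call_droplets
#' @inheritParams poisson_concentration
#' @return A `concentration` object.
#' @export
quantify_well <- function(well, threshold, droplet_volume_nl = 0.85,
                          reaction_volume_ul = 20, conf_level = 0.95) {
  poisson_concentration(call_droplets(well, threshold),
                        droplet_volume_nl = droplet_volume_nl,
                        reaction_volume_ul = reaction_volume_ul,
                        conf_level = conf_level)
}
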