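#' Simulation configuration for synthetic droplet data
#'
#' Forward model for a ddPCR well: ~20,000 droplets of 0.85 nl are generated
#' per 20 ul reaction, of which a fixed fraction is accepted by the reader.
#' Target molecules load droplets as independent Poisson counts with mean
#' `lambda = concentration x droplet volume`. Occupied droplets emit
#' positive-cluster amplitudes (a small fraction re-drawn uniformly between
#' the cluster means, modelling "rain"); empty droplets emit
#' negative-cluster amplitudes except for rare false positives. Cluster and
#' rain parameters are synthetic defaults chosen so that the fixed human
#' threshold (3400) cleanly separates the clusters while rain exercises
#' threshold sensitivity; they are not instrument estimates.
#'
#' @param droplet_volume_nl Droplet volume, nanolitres (default 0.85).
#' @param n_droplets_generated Droplets generated per well (default 20000).
#' @param accepted_fraction Fraction of generated droplets accepted by the
#'   reader, in (0, 1] (default 0.9).
#' @param neg_mean,neg_sd Negative-cluster amplitude mean and sd
#'   (defaults 1800, 200).
#' @param pos_mean,pos_sd Positive-cluster amplitude mean and sd
#'   (defaults 6500, 400).
#' @param rain_fraction Fraction of positive droplets re-drawn uniformly
#'   between the cluster means (default 0.02).
#' @param false_positive_rate Per-droplet probability that an empty droplet
#'   emits a positive-cluster amplitude (default 5e-5).
#' @param seed Optional default integer seed carried with the config.
#'
#' @return An object of class `sim_config` (a validated list).
#' @examples
#' cfg <- sim_config()
#' cfg$droplet_volume_nl
#' @export
sim_config <- function(droplet_volume_nl = 0.85, n_droplets_generated = 20000,
                       accepted_fraction = 0.9, neg_mean = 1800, neg_sd = 200,
                       pos_mean = 6500, pos_sd = 400, rain_fraction = 0.02,
                       false_positive_rate = 5e-5, seed = NULL) {
  stopifnot(droplet_volume_nl > 0, n_droplets_generated >= 1,
            accepted_fraction > 0, accepted_fraction <= 1,
            neg_mean < pos_mean, neg_sd > 0, pos_sd > 0,
            rain_fraction >= 0, rain_fraction <= 1,
            false_positive_rate >= 0, false_positive_rate <= 1)
  structure(
    list(droplet_volume_nl = droplet_volume_nl,
         n_droplets_generated = n_droplets_generated,
         accepted_fraction = accepted_fraction,
         neg_mean = neg_mean, neg_sd = neg_sd,
         pos_mean = pos_mean, pos_sd = pos_sd,
         rain_fraction = rain_fraction,
         false_positive_rate = false_positive_rate,
         seed = seed),
    class = "sim_config"
  )
}

#' Longitudinal stool study design
#'
#' Parameters of a simulated serial stool collection study: subjects,
#' collection days, the log-scale day-to-day biological variation of the
#' true host DNA level, the baseline copies per mg stool, the stool mass
#' per ~200 ul homogenate aliquot, the extract dilution before ddPCR, the
#' technical CV between duplicate extractions and the elution volume.
#' Defaults emulate the healthy-donor arm: three subjects, baseline inside
#' the observed 52,000-4,050,000 copies/mg range, masses around the 49.5 mg
#' median, a 500-fold dilution (human extracts were diluted 5-500-fold;
#' mouse extracts 3600-fold), and "several-fold" day-to-day variation.
#'
#' @param subjects Character vector of subject labels.
#' @param timepoints Numeric vector of collection days.
#' @param log_variation_sd SD on the natural-log scale of day-to-day true
#'   host DNA level (default 0.8).
#' @param baseline_copies_per_mg Baseline true copies per mg stool
#'   (default 2e5).
#' @param stool_mass_range Length-2 numeric, min and max stool mass (mg) per
#'   aliquot (default c(20, 80)).
#' @param dilution_factor Fold dilution of extract before ddPCR (default 500).
#' @param extraction_cv Technical CV between duplicate extractions
#'   (default 0.1).
#' @param elution_volume_ul Extract elution volume, microlitres (default 100).
#'
#' @return An object of class `study_design` (a validated list).
#' @export
study_design <- function(subjects = c("D-145x", "D-165x", "D-166x"),
                         timepoints = 1:10, log_variation_sd = 0.8,
                         baseline_copies_per_mg = 2e5,
                         stool_mass_range = c(20, 80), dilution_factor = 500,
                         extraction_cv = 0.1, elution_volume_ul = 100) {
  stopifnot(length(subjects) >= 1, length(timepoints) >= 1,
            log_variation_sd >= 0, baseline_copies_per_mg > 0,
            length(stool_mass_range) == 2, stool_mass_range[1] > 0,
            stool_mass_range[2] >= stool_mass_range[1],
            dilution_factor >= 1, extraction_cv >= 0, elution_volume_ul > 0)
  structure(
    list(subjects = as.character(subjects), timepoints = timepoints,
         log_variation_sd = log_variation_sd,
         baseline_copies_per_mg = baseline_copies_per_mg,
         stool_mass_range = stool_mass_range,
         dilution_factor = dilution_factor, extraction_cv = extraction_cv,
         elution_volume_ul = elution_volume_ul),
    class = "study_design"
  )
}

# Evaluate expr with a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministic sub-seed for the k-th well under a base seed.
sub_seed <- function(seed, k) (as.integer(seed) + 7919L * as.integer(k)) %% 2147483647L

#' Simulate one ddPCR well
#'
#' Draws the accepted droplets of a single well at a given true target
#' concentration under the amplitude model described in [sim_config()].
#' Identical `(inputs, seed)` give bit-identical wells.
#'
#' @param true_copies_per_ul_reaction True target concentration in the
#'   reaction, copies per microlitre; must be >= 0.
#' @param cfg A [sim_config()].
#' @param seed Integer seed (falls back to `cfg$seed`).
#' @param well_id,sample_id,assay_id Identity labels for the well.
#'
#' @return A [droplet_well()].
#' @examples
#' w <- simulate_well(235.4, sim_config(), seed = 1)
#' mean(w$amplitudes > 3400)  # ~ 1 - exp(-235.4 * 0.00085)
#' @export
simulate_well <- function(true_copies_per_ul_reaction, cfg = sim_config(),
                          seed = cfg$seed, well_id = "W01",
                          sample_id = "S01", assay_id = "LINE1_60") {
  stopifnot(inherits(cfg, "sim_config"))
  if (!is.numeric(true_copies_per_ul_reaction) ||
      length(true_copies_per_ul_reaction) != 1L ||
      !is.finite(true_copies_per_ul_reaction) ||
      true_copies_per_ul_reaction < 0)
    stop("true_copies_per_ul_reaction must be a single non-negative number",
         call. = FALSE)
  if (is.null(seed)) stop("a seed is required for reproducible simulation",
                          call. = FALSE)
  n <- round(cfg$n_droplets_generated * cfg$accepted_fraction)
  lambda <- true_copies_per_ul_reaction * cfg$droplet_volume_nl / 1000
  amps <- with_seed(seed, {
    occupied <- stats::rpois(n, lambda) > 0
    a <- numeric(n)
    n_pos <- sum(occupied)
    n_neg <- n - n_pos
    if (n_pos > 0) {
      pos_amp <- stats::rnorm(n_pos, cfg$pos_mean, cfg$pos_sd)
      if (cfg$rain_fraction > 0) {
        rain <- stats::runif(n_pos) < cfg$rain_fraction
        if (any(rain))
          pos_amp[rain] <- stats::runif(sum(rain), cfg$neg_mean, cfg$pos_mean)
      }
      a[occupied] <- pos_amp
    }
    if (n_neg > 0) {
      neg_amp <- stats::rnorm(n_neg, cfg$neg_mean, cfg$neg_sd)
      if (cfg$false_positive_rate > 0) {
        fp <- stats::runif(n_neg) < cfg$false_positive_rate
        if (any(fp))
          neg_amp[fp] <- stats::rnorm(sum(fp), cfg$pos_mean, cfg$pos_sd)
      }
      a[!occupied] <- neg_amp
    }
    pmax(a, 0)
  })
  droplet_well(well_id, sample_id, assay_id, amps)
}

#' Simulate a dilution series of wells
#'
#' Builds the standard-curve fixture: a stock of known copy number diluted
#' by the given factors, each level run in replicate wells. The default
#' arguments span ~193 to 120,440 copies per reaction over five levels in
#' triplicate, the validated linear range. An optional `yield` scales the
#' concentration actually simulated (measured copies) while the truth table
#' keeps the theoretical copies, emulating sub-unity percent yield of
#' dilute synthetic standards.
#'
#' @param stock_copies Copies per reaction at dilution factor 1; > 0.
#' @param dilution_factors Numeric vector of fold dilutions, all >= 1.
#' @param replicates_per_level Wells per dilution level (default 3).
#' @param cfg A [sim_config()].
#' @param seed Integer seed.
#' @param yield Fraction of theoretical copies actually measurable
#'   (default 1).
#' @param reaction_volume_ul Reaction volume, microlitres (default 20).
#'
#' @return List with `wells` (list of [droplet_well()]) and `truth`
#'   (data.frame: `well_id`, `sample_id`, `dilution_factor`,
#'   `true_copies_per_reaction`, `true_copies_per_ul_reaction`).
#' @examples
#' ds <- simulate_dilution_series(seed = 1)
#' range(ds$truth$true_copies_per_reaction)
#' @export
simulate_dilution_series <- function(stock_copies = 120440,
                                     dilution_factors = c(1, 5.5, 30.6, 170, 624),
                                     replicates_per_level = 3,
                                     cfg = sim_config(), seed = cfg$seed,
                                     yield = 1, reaction_volume_ul = 20) {
  stopifnot(stock_copies > 0, replicates_per_level >= 1, yield >= 0)
  if (length(dilution_factors) == 0)
    stop("dilution_factors must be non-empty", call. = FALSE)
  if (any(dilution_factors < 1))
    stop("all dilution factors must be >= 1", call. = FALSE)
  if (is.null(seed)) stop("a seed is required", call. = FALSE)
  wells <- list(); truth <- list(); k <- 0L
  for (i in seq_along(dilution_factors)) {
    true_rxn <- stock_copies / dilution_factors[i]
    for (r in seq_len(replicates_per_level)) {
      k <- k + 1L
      wid <- sprintf("L%02dR%d", i, r)
      sid <- sprintf("dil_%02d", i)
      wells[[k]] <- simulate_well(yield * true_rxn / reaction_volume_ul, cfg,
                                  seed = sub_seed(seed, k), well_id = wid,
                                  sample_id = sid)
      truth[[k]] <- data.frame(
        well_id = wid, sample_id = sid, dilution_factor = dilution_factors[i],
        true_copies_per_reaction = true_rxn,
        true_copies_per_ul_reaction = true_rxn / reaction_volume_ul,
        stringsAsFactors = FALSE)
    }
  }
  list(wells = wells, truth = do.call(rbind, truth))
}

#' Simulate a gDNA spike-in recovery experiment
#'
#' Emulates the DNA isolation efficiency experiment: pooled stool lysate
#' aliquots receive a genomic DNA spike (or buffer) and are carried through
#' purification, while the spike alone is measured without purification.
#' Truth per reaction: with-spike = background + spike x copies_per_ge x
#' true_recovery x reaction_fraction; buffer-only = background; spike-alone
#' = spike x copies_per_ge x reaction_fraction (no purification loss).
#' `reaction_fraction` maps total spiked copies to copies per reaction; the
#' default 1/50000 corresponds to a 100 ul elution, 500-fold dilution and
#' 1 ul loaded per reaction.
#'
#' @param spike_ge_levels Genome equivalents spiked, one value per level
#'   (default c(232000, 23200, 2320), i.e. 800/80/8 ng of human gDNA).
#' @param copies_per_ge Target copies per genome equivalent (default 5800,
#'   the in silico LINE-1 copy estimate).
#' @param true_recovery Generative recovery fraction in [0, 1].
#' @param background_acn Endogenous background, copies per reaction
#'   (default 500).
#' @param replicates Wells per arm and level (default 3).
#' @param cfg A [sim_config()].
#' @param seed Integer seed.
#' @param reaction_fraction Fraction of total spiked copies ending up in one
#'   reaction (default 1/50000).
#' @param reaction_volume_ul Reaction volume, microlitres (default 20).
#'
#' @return List with `wells` (all three arms; `sample_id` encodes arm and
#'   level) and `truth` (data.frame: `well_id`, `sample_id`, `arm`,
#'   `spike_ge`, `true_copies_per_reaction`).
#' @export
simulate_spikein_experiment <- function(spike_ge_levels = c(232000, 23200, 2320),
                                        copies_per_ge = 5800,
                                        true_recovery = 0.62,
                                        background_acn = 500, replicates = 3,
                                        cfg = sim_config(), seed = cfg$seed,
                                        reaction_fraction = 1 / 50000,
                                        reaction_volume_ul = 20) {
  stopifnot(true_recovery >= 0, true_recovery <= 1, background_acn >= 0,
            copies_per_ge > 0, replicates >= 1, reaction_fraction > 0)
  if (is.null(seed)) stop("a seed is required", call. = FALSE)
  wells <- list(); truth <- list(); k <- 0L
  add_well <- function(arm, level, spike_ge, true_rxn, r) {
    k <<- k + 1L
    wid <- sprintf("%s_L%d_R%d", arm, level, r)
    sid <- sprintf("%s_ge%g", arm, spike_ge)
    wells[[k]] <<- simulate_well(true_rxn / reaction_volume_ul, cfg,
                                 seed = sub_seed(seed, k), well_id = wid,
                                 sample_id = sid)
    truth[[k]] <<- data.frame(well_id = wid, sample_id = sid, arm = arm,
                              spike_ge = spike_ge,
                              true_copies_per_reaction = true_rxn,
                              stringsAsFactors = FALSE)
  }
  for (i in seq_along(spike_ge_levels)) {
    spike_rxn <- spike_ge_levels[i] * copies_per_ge * reaction_fraction
    for (r in seq_len(replicates)) {
      add_well("spike", i, spike_ge_levels[i],
               background_acn + spike_rxn * true_recovery, r)
      add_well("buffer", i, spike_ge_levels[i], background_acn, r)
      add_well("alone", i, spike_ge_levels[i], spike_rxn, r)
    }
  }
  list(wells = wells, truth = do.call(rbind, truth))
}

#' Simulate a longitudinal stool collection study
#'
#' Per subject and collection day: a stool mass is drawn uniformly from the
#' design range, the true copies per mg is drawn log-normally around the
#' design baseline, and two extraction replicates (each perturbed
#' multiplicatively by the extraction CV) are run as one well each, plus
#' shared NTC wells (four technical replicates per study, emulating the
#' plate layout). Copies per ul extract follow the literal normalisation
#' identity (copies/mg x stool mass), and each reaction receives 1 ul of
#' extract diluted by the design dilution factor.
#'
#' @param design A [study_design()].
#' @param cfg A [sim_config()].
#' @param seed Integer seed.
#' @param n_ntc Number of NTC technical replicate wells (default 4).
#' @param reaction_volume_ul Reaction volume, microlitres (default 20).
#'
#' @return List with `wells`, `sample_sheet` (the [read_sample_sheet()]
#'   dialect as a data.frame) and `truth` (data.frame: `sample_id`,
#'   `true_copies_per_ul_reaction` per replicate well averaged,
#'   `true_copies_per_ul_extract`, `true_copies_per_mg`).
#' @export
simulate_longitudinal_study <- function(design = study_design(),
                                        cfg = sim_config(), seed = cfg$seed,
                                        n_ntc = 4, reaction_volume_ul = 20) {
  stopifnot(inherits(design, "study_design"))
  if (is.null(seed)) stop("a seed is required", call. = FALSE)
  cv <- design$extraction_cv
  sdlog_tech <- if (cv > 0) sqrt(log(1 + cv^2)) else 0
  wells <- list(); sheet <- list(); truth <- list(); k <- 0L
  draws <- with_seed(seed, {
    ns <- length(design$subjects) * length(design$timepoints)
    list(mass = stats::runif(ns, design$stool_mass_range[1],
                             design$stool_mass_range[2]),
         biolog = stats::rnorm(ns, 0, design$log_variation_sd),
         tech = if (sdlog_tech > 0)
           matrix(stats::rlnorm(2 * ns, -sdlog_tech^2 / 2, sdlog_tech), ncol = 2)
         else matrix(1, ns, 2))
  })
  s_idx <- 0L
  for (subj in design$subjects) {
    for (day in design$timepoints) {
      s_idx <- s_idx + 1L
      sid <- sprintf("%s_d%03d", subj, day)
      mass <- draws$mass[s_idx]
      cpm_true <- design$baseline_copies_per_mg * exp(draws$biolog[s_idx])
      cpul_extract <- cpm_true * mass
      for (rep_i in 1:2) {
        k <- k + 1L
        cpul_rep <- cpul_extract * draws$tech[s_idx, rep_i]
        conc_rxn <- (cpul_rep / design$dilution_factor) / reaction_volume_ul
        wid <- sprintf("%s_e%d", sid, rep_i)
        wells[[k]] <- simulate_well(conc_rxn, cfg, seed = sub_seed(seed, k),
                                    well_id = wid, sample_id = sid)
        sheet[[k]] <- data.frame(
          sample_id = sid, subject_id = subj, collection_day = day,
          stool_mass_mg = mass, dilution_factor = design$dilution_factor,
          extraction_replicate = rep_i, is_ntc = FALSE, buffer = "EDTA",
          bristol = NA_integer_, elution_volume_ul = design$elution_volume_ul,
          stringsAsFactors = FALSE)
      }
      truth[[s_idx]] <- data.frame(
        sample_id = sid, subject_id = subj, collection_day = day,
        true_copies_per_ul_extract = cpul_extract,
        true_copies_per_mg = cpm_true,
        true_copies_per_ul_reaction =
          (cpul_extract / design$dilution_factor) / reaction_volume_ul,
        stringsAsFactors = FALSE)
    }
  }
  for (j in seq_len(n_ntc)) {
    k <- k + 1L
    sid <- sprintf("NTC_%d", j)
    wells[[k]] <- simulate_well(0, cfg, seed = sub_seed(seed, k),
                                well_id = sprintf("NTC%02d", j),
                                sample_id = sid)
    sheet[[k]] <- data.frame(
      sample_id = sid, subject_id = "NTC", collection_day = 0,
      stool_mass_mg = NA_real_, dilution_factor = 1,
      extraction_replicate = j, is_ntc = TRUE, buffer = "none",
      bristol = NA_integer_, elution_volume_ul = design$elution_volume_ul,
      stringsAsFactors = FALSE)
  }
  list(wells = wells, sample_sheet = do.call(rbind, sheet),
       truth = do.call(rbind, truth))
}

#' Simulate a preservative-buffer stability time course
#'
#' Emulates the room-temperature stool stability experiment: per buffer, the
#' true copies per ul extract decays (or grows, for negative rates such as
#' bacterial 16S in EDTA) exponentially over the incubation times; each time
#' point is extracted in duplicate except buffers flagged single-extraction
#' (the OMNI case).
#'
#' @param buffers Character vector of buffer labels
#'   (default c("EDTA", "TEN2", "OMNI")).
#' @param decay_rate_per_hour Named numeric vector, per-buffer exponential
#'   decay rate per hour (negative = growth). Default 0 for all buffers.
#' @param timepoints_hours Incubation times in hours; must include 0
#'   (default c(0, 4, 24, 72, 96)).
#' @param baseline_copies_per_ul_extract True level at time 0 (default 1e5).
#' @param single_extraction Buffers with only one extraction per time point
#'   (default "OMNI").
#' @param dilution_factor Extract fold-dilution before ddPCR (default 100).
#' @param cfg A [sim_config()].
#' @param seed Integer seed.
#' @param reaction_volume_ul Reaction volume, microlitres (default 20).
#'
#' @return List with `wells` and `truth` (data.frame: `sample_id`, `buffer`,
#'   `time_h`, `true_copies_per_ul_extract`).
#' @export
simulate_preservation_timecourse <- function(buffers = c("EDTA", "TEN2", "OMNI"),
                                             decay_rate_per_hour =
                                               stats::setNames(rep(0, length(buffers)), buffers),
                                             timepoints_hours = c(0, 4, 24, 72, 96),
                                             baseline_copies_per_ul_extract = 1e5,
                                             single_extraction = "OMNI",
                                             dilution_factor = 100,
                                             cfg = sim_config(), seed = cfg$seed,
                                             reaction_volume_ul = 20) {
  if (!0 %in% timepoints_hours)
    stop("timepoints_hours must include the baseline time 0", call. = FALSE)
  if (is.null(seed)) stop("a seed is required", call. = FALSE)
  stopifnot(baseline_copies_per_ul_extract > 0, dilution_factor >= 1)
  rates <- decay_rate_per_hour
  if (is.null(names(rates))) names(rates) <- buffers
  wells <- list(); truth <- list(); k <- 0L; t_idx <- 0L
  for (buf in buffers) {
    rate <- if (buf %in% names(rates)) rates[[buf]] else 0
    n_rep <- if (buf %in% single_extraction) 1L else 2L
    for (t in timepoints_hours) {
      t_idx <- t_idx + 1L
      cpul <- baseline_copies_per_ul_extract * exp(-rate * t)
      sid <- sprintf("%s_t%03d", buf, t)
      for (r in seq_len(n_rep)) {
        k <- k + 1L
        wells[[k]] <- simulate_well(
          (cpul / dilution_factor) / reaction_volume_ul, cfg,
          seed = sub_seed(seed, k),
          well_id = sprintf("%s_e%d", sid, r), sample_id = sid)
      }
      truth[[t_idx]] <- data.frame(sample_id = sid, buffer = buf, time_h = t,
                                   true_copies_per_ul_extract = cpul,
                                   stringsAsFactors = FALSE)
    }
  }
  list(wells = wells, truth = do.call(rbind, truth))
}
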