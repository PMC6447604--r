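#' Pipeline run configuration
#'
#' Bundles every tunable of the quantification pipeline: droplet and
#' reaction volumes, the accepted-droplet QC minimum, the per-assay
#' amplitude thresholds, conversion constants and the per-mg normalisation
#' mode. `acn_ntc_override` permits running assays without NTC wells by
#' supplying an explicit background (usually 0).
#'
#' @param droplet_volume_nl Droplet volume, nanolitres (default 0.85).
#' @param reaction_volume_ul Reaction volume, microlitres (default 20).
#' @param min_accepted_droplets QC minimum accepted droplets (default 10000).
#' @param thresholds Named numeric vector of per-assay amplitude thresholds
#'   (default [default_thresholds()]).
#' @param constants A [conversion_constants()].
#' @param normalisation_mode `"literal"` or `"total"` (see
#'   [normalize_per_mg()]).
#' @param acn_ntc_override Optional explicit NTC background (copies per
#'   reaction) used when an assay has no NTC wells; default `NULL` (error
#'   in that case).
#' @param conf_level Confidence level for Poisson intervals (default 0.95).
#' @param seed Optional integer seed recorded in run manifests.
#'
#' @return An object of class `run_config` (a validated list).
#' @export
run_config <- function(droplet_volume_nl = 0.85, reaction_volume_ul = 20,
                       min_accepted_droplets = 10000,
                       thresholds = default_thresholds(),
                       constants = conversion_constants(),
                       normalisation_mode = c("literal", "total"),
                       acn_ntc_override = NULL, conf_level = 0.95,
                       seed = NULL) {
  normalisation_mode <- match.arg(normalisation_mode)
  stopifnot(droplet_volume_nl > 0, reaction_volume_ul > 0,
            min_accepted_droplets > 0, is.numeric(thresholds),
            !is.null(names(thresholds)), all(thresholds > 0),
            inherits(constants, "conversion_constants"))
  structure(
    list(droplet_volume_nl = droplet_volume_nl,
         reaction_volume_ul = reaction_volume_ul,
         min_accepted_droplets = min_accepted_droplets,
         thresholds = thresholds, constants = constants,
         normalisation_mode = normalisation_mode,
         acn_ntc_override = acn_ntc_override,
         conf_level = conf_level, seed = seed),
    class = "run_config"
  )
}

droplet_csv_header <- c("well_id", "sample_id", "assay_id", "amplitude")
sample_sheet_header <- c("sample_id", "subject_id", "collection_day",
                         "stool_mass_mg", "dilution_factor",
                         "extraction_replicate", "is_ntc", "buffer",
                         "bristol", "elution_volume_ul")

#' Read a droplet-level amplitude CSV
#'
#' One row per droplet, header exactly
#' `well_id,sample_id,assay_id,amplitude`. Rows are grouped into wells by
#' `(well_id, sample_id, assay_id)`; the accepted droplet count of a well is
#' its row count, and the result is independent of row order. A well_id
#' carrying more than one assay, a missing column or a non-numeric amplitude
#' is a parse error reporting the offending line.
#'
#' @param path Path to the CSV file.
#' @return A list of [droplet_well()] objects, ordered by
#'   `(sample_id, assay_id, well_id)`.
#' @export
read_droplet_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c("character", "character", "character",
                                       "character"))
  if (!identical(names(df), droplet_csv_header))
    stop("droplet CSV header must be exactly '",
         paste(droplet_csv_header, collapse = ","), "' but found '",
         paste(names(df), collapse = ","), "'", call. = FALSE)
  amp <- suppressWarnings(as.numeric(df$amplitude))
  bad <- which(!is.finite(amp))
  if (length(bad) > 0)
    stop(sprintf("non-numeric or non-finite amplitude '%s' at line %d",
                 df$amplitude[bad[1]], bad[1] + 1L), call. = FALSE)
  mixed <- tapply(df$assay_id, df$well_id, function(a) length(unique(a)) > 1)
  if (any(mixed))
    stop("well_id '", names(mixed)[which(mixed)[1]],
         "' carries more than one assay_id", call. = FALSE)
  key <- paste(df$sample_id, df$assay_id, df$well_id, sep = "\r")
  idx <- split(seq_len(nrow(df)), key)
  idx <- idx[order(names(idx))]
  lapply(idx, function(i)
    droplet_well(df$well_id[i[1]], df$sample_id[i[1]], df$assay_id[i[1]],
                 amp[i]))
}

#' Write wells to the droplet CSV dialect
#'
#' @param wells A `droplet_well` or list of them.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_droplet_csv <- function(wells, path) {
  wells <- as_well_list(wells)
  df <- do.call(rbind, lapply(wells, function(w)
    data.frame(well_id = w$well_id, sample_id = w$sample_id,
               assay_id = w$assay_id, amplitude = w$amplitudes,
               stringsAsFactors = FALSE)))
  if (is.null(df)) df <- stats::setNames(
    data.frame(character(), character(), character(), numeric()),
    droplet_csv_header)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and validate a sample sheet CSV
#'
#' Header: `sample_id,subject_id,collection_day,stool_mass_mg,`
#' `dilution_factor,extraction_replicate,is_ntc,buffer,bristol,`
#' `elution_volume_ul`. Optional fields (`stool_mass_mg` for NTCs,
#' `bristol`) may be empty. All validation violations (Bristol score outside
#' 1-7, dilution below 1, duplicated `(sample_id, extraction_replicate)`,
#' missing stool mass on a non-NTC sample) are collected and reported
#' together.
#'
#' @param path Path to the CSV file.
#' @return A validated data.frame of sample records.
#' @export
read_sample_sheet <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!identical(names(df), sample_sheet_header))
    stop("sample sheet header must be exactly '",
         paste(sample_sheet_header, collapse = ","), "'", call. = FALSE)
  df$is_ntc <- as.logical(df$is_ntc)
  problems <- character()
  bad_bristol <- which(!is.na(df$bristol) & (df$bristol < 1 | df$bristol > 7))
  for (i in bad_bristol)
    problems <- c(problems, sprintf("row %d: bristol %s outside 1-7", i,
                                    df$bristol[i]))
  bad_dil <- which(!is.na(df$dilution_factor) & df$dilution_factor < 1)
  for (i in bad_dil)
    problems <- c(problems, sprintf("row %d: dilution_factor %s < 1", i,
                                    df$dilution_factor[i]))
  key <- paste(df$sample_id, df$extraction_replicate)
  dup <- which(duplicated(key))
  for (i in dup)
    problems <- c(problems,
                  sprintf("row %d: duplicate (sample_id, extraction_replicate) (%s, %s)",
                          i, df$sample_id[i], df$extraction_replicate[i]))
  bad_mass <- which(!df$is_ntc & (is.na(df$stool_mass_mg) | df$stool_mass_mg <= 0))
  for (i in bad_mass)
    problems <- c(problems, sprintf("row %d: non-NTC sample '%s' lacks a positive stool_mass_mg",
                                    i, df$sample_id[i]))
  if (length(problems) > 0)
    stop("sample sheet validation failed:\n  ",
         paste(problems, collapse = "\n  "), call. = FALSE)
  df
}

#' Write a sample sheet to its CSV dialect
#'
#' @param sheet Data.frame with the [read_sample_sheet()] columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sample_sheet <- function(sheet, path) {
  stopifnot(identical(names(sheet), sample_sheet_header))
  utils::write.csv(sheet, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Run the full quantification pipeline
#'
#' Assembles the analysis sequence: accepted-droplet QC, threshold calling,
#' Poisson concentration per well, replicate averaging to the sample ACN,
#' NTC background averaging and subtraction, dilution adjustment to copies
#' per ul extract, and normalisation to copies per mg stool. One result row
#' per (sample, assay); wells failing QC are listed in the `rejected`
#' attribute. Confidence bounds for a sample are computed from the pooled
#' positive/negative counts of its replicate wells and carried through the
#' same linear adjustment and normalisation as the point estimate.
#'
#' @param droplets Path to a droplet CSV or a list of [droplet_well()]s.
#' @param sheet Path to a sample sheet CSV or an equivalent data.frame.
#' @param config A [run_config()].
#'
#' @return A data.frame with one row per (sample_id, assay_id):
#'   `positives`, `total_droplets`, `lambda`, `copies_per_ul_reaction`,
#'   `acn_per_reaction`, `acn_range`, `acn_ntc`, `copies_per_ul_extract`,
#'   `copies_per_mg`, `ci_low_per_mg`, `ci_high_per_mg` and the flags
#'   `clipped`, `single_replicate`, `saturated`. Attribute `rejected` holds
#'   the QC rejection report.
#' @export
run_pipeline <- function(droplets, sheet, config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  wells <- if (is.character(droplets)) read_droplet_csv(droplets)
           else as_well_list(droplets)
  records <- if (is.character(sheet)) read_sample_sheet(sheet) else sheet
  stopifnot(is.data.frame(records))
  if (!all(vapply(wells, `[[`, character(1), "sample_id") %in% records$sample_id))
    stop("droplet file contains sample_ids absent from the sample sheet",
         call. = FALSE)

  qc <- qc_filter(wells, config$min_accepted_droplets)
  wells <- qc$accepted

  assay_of <- vapply(wells, `[[`, character(1), "assay_id")
  missing_thr <- setdiff(unique(assay_of), names(config$thresholds))
  if (length(missing_thr) > 0)
    stop("no threshold configured for assay(s): ",
         paste(missing_thr, collapse = ", "), call. = FALSE)

  per_well <- lapply(wells, function(w) {
    cts <- call_droplets(w, config$thresholds[[w$assay_id]])
    conc <- poisson_concentration(cts, config$droplet_volume_nl,
                                  config$reaction_volume_ul, config$conf_level)
    list(well = w, counts = cts, conc = conc)
  })

  sample_of <- vapply(per_well, function(x) x$well$sample_id, character(1))
  ntc_ids <- records$sample_id[records$is_ntc]
  is_ntc_well <- sample_of %in% ntc_ids

  # NTC-averaged background per assay (copies per reaction)
  acn_ntc <- list()
  for (a in unique(assay_of)) {
    ntc_concs <- Filter(function(x) x$well$assay_id == a,
                        per_well[is_ntc_well])
    vals <- vapply(ntc_concs, function(x)
      if (x$conc$saturated_flag) NA_real_ else x$conc$copies_per_reaction,
      numeric(1))
    vals <- vals[!is.na(vals)]
    if (length(vals) == 0) {
      if (is.null(config$acn_ntc_override))
        stop("no NTC wells for assay '", a,
             "'; supply acn_ntc_override in run_config() to proceed",
             call. = FALSE)
      acn_ntc[[a]] <- config$acn_ntc_override
    } else {
      acn_ntc[[a]] <- average_replicates(vals, expected_n = 4)$mean
    }
  }

  meta <- records[!records$is_ntc, , drop = FALSE]
  out <- list(); k <- 0L
  for (sid in unique(meta$sample_id)) {
    srec <- meta[meta$sample_id == sid, , drop = FALSE]
    if (length(unique(srec$dilution_factor)) > 1)
      stop("sample '", sid, "': replicates must share a dilution factor",
           call. = FALSE)
    sw <- per_well[sample_of == sid & !is_ntc_well]
    if (length(sw) == 0) next
    for (a in unique(vapply(sw, function(x) x$well$assay_id, character(1)))) {
      aw <- Filter(function(x) x$well$assay_id == a, sw)
      saturated <- any(vapply(aw, function(x) x$conc$saturated_flag, logical(1)))
      usable <- Filter(function(x) !x$conc$saturated_flag, aw)
      k <- k + 1L
      if (length(usable) == 0) {
        out[[k]] <- data.frame(
          sample_id = sid, assay_id = a, n_wells = length(aw),
          positives = sum(vapply(aw, function(x) x$counts$positives, numeric(1))),
          total_droplets = sum(vapply(aw, function(x) x$counts$total, numeric(1))),
          lambda = NA_real_, copies_per_ul_reaction = NA_real_,
          acn_per_reaction = NA_real_, acn_range = NA_real_,
          acn_ntc = acn_ntc[[a]], copies_per_ul_extract = NA_real_,
          copies_per_mg = NA_real_, ci_low_per_mg = NA_real_,
          ci_high_per_mg = NA_real_, clipped = FALSE,
          single_replicate = TRUE, saturated = TRUE,
          stringsAsFactors = FALSE)
        next
      }
      acns <- vapply(usable, function(x) x$conc$copies_per_reaction, numeric(1))
      avg <- average_replicates(acns, expected_n = 2)
      adj <- adjust_acn(avg$mean, acn_ntc[[a]], srec$dilution_factor[1])
      mass <- srec$stool_mass_mg[1]
      cpm <- normalize_per_mg(adj$copies_per_ul_extract, mass,
                              mode = config$normalisation_mode,
                              elution_volume_ul = srec$elution_volume_ul[1])
      # pooled-count CI, transformed through the same linear pipeline
      pooled <- structure(
        list(positives = sum(vapply(usable, function(x) x$counts$positives, numeric(1))),
             negatives = sum(vapply(usable, function(x) x$counts$negatives, numeric(1))),
             total = sum(vapply(usable, function(x) x$counts$total, numeric(1))),
             threshold_used = config$thresholds[[a]]),
        class = "droplet_counts")
      pc <- poisson_concentration(pooled, config$droplet_volume_nl,
                                  config$reaction_volume_ul, config$conf_level)
      to_per_mg <- function(acn_rxn) {
        v <- max((acn_rxn - acn_ntc[[a]]) * srec$dilution_factor[1], 0)
        normalize_per_mg(v, mass, mode = config$normalisation_mode,
                         elution_volume_ul = srec$elution_volume_ul[1])
      }
      out[[k]] <- data.frame(
        sample_id = sid, assay_id = a, n_wells = length(aw),
        positives = pooled$positives, total_droplets = pooled$total,
        lambda = pc$lambda_,
        copies_per_ul_reaction = avg$mean / config$reaction_volume_ul,
        acn_per_reaction = avg$mean, acn_range = avg$range,
        acn_ntc = acn_ntc[[a]],
        copies_per_ul_extract = adj$copies_per_ul_extract,
        copies_per_mg = cpm,
        ci_low_per_mg = to_per_mg(pc$ci_low * config$reaction_volume_ul),
        ci_high_per_mg = to_per_mg(pc$ci_high * config$reaction_volume_ul),
        clipped = adj$clipped_flag,
        single_replicate = avg$single_replicate || length(usable) < length(aw),
        saturated = saturated,
        stringsAsFactors = FALSE)
    }
  }
  res <- if (k == 0L) data.frame() else do.call(rbind, out)
  attr(res, "rejected") <- qc$rejected
  res
}

#' Write pipeline results as TSV with a run manifest
#'
#' Writes the results table to `path` and a sidecar `<path>.manifest.txt`
#' echoing the configuration, seed and input checksums, so a run can be
#' reproduced byte for byte.
#'
#' @param results Data.frame from [run_pipeline()].
#' @param path Output TSV path.
#' @param config The [run_config()] used.
#' @param inputs Optional character vector of input file paths to checksum.
#' @return `path`, invisibly.
#' @export
write_results_tsv <- function(results, path, config = NULL, inputs = character()) {
  utils::write.table(results, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  manifest <- c(sprintf("written: %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")))
  if (!is.null(config)) {
    manifest <- c(manifest,
                  sprintf("droplet_volume_nl: %g", config$droplet_volume_nl),
                  sprintf("reaction_volume_ul: %g", config$reaction_volume_ul),
                  sprintf("min_accepted_droplets: %g", config$min_accepted_droplets),
                  sprintf("normalisation_mode: %s", config$normalisation_mode),
                  sprintf("seed: %s", if (is.null(config$seed)) "NA" else config$seed),
                  sprintf("thresholds: %s",
                          paste(sprintf("%s=%g", names(config$thresholds),
                                        config$thresholds), collapse = " ")))
  }
  for (f in inputs)
    if (file.exists(f))
      manifest <- c(manifest, sprintf("input %s md5 %s", f, unname(tools::md5sum(f))))
  writeLines(manifest, paste0(path, ".manifest.txt"))
  invisible(path)
}
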