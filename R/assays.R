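#' Catalog of ddPCR assays for faecal host DNA quantification
#'
#' The primer sets used by the pipeline: two human LINE-1 assays (55 and
#' 60 bp amplicons), two human mitochondrial assays (ND5 83 bp, CO2 77 bp),
#' two mouse LINE-1 assays (58 and 62 bp) and a pan-bacterial 16S assay.
#' Amplitude thresholds separating positive from negative droplets are the
#' fixed per-assay values used throughout: 3400 for the four human assays,
#' 6300 for the 16S assay and 3000 for the two mouse assays. All reactions
#' use a 60 degC annealing/extension step for human targets and 59 degC for
#' mouse targets.
#'
#' The 16S amplicon length is recorded twice in the source material (173 bp
#' in the primer table, 172 bp alongside its threshold); both values are kept
#' (`amplicon_length`, `amplicon_length_alt`) rather than silently resolved.
#'
#' @return A data.frame with one row per assay and columns `assay_id`,
#'   `species`, `forward_primer`, `reverse_primer`, `amplicon_length`,
#'   `amplicon_length_alt`, `threshold` and `anneal_temp`.
#' @examples
#' assay_catalog()[, c("assay_id", "threshold")]
#' @export
assay_catalog <- function() {
  cat <- data.frame(
    assay_id = c("LINE1_55", "LINE1_60", "ND5_83", "CO2_77",
                 "mLINE1_58", "mLINE1_62", "16S_173"),
    species = c("human", "human", "human", "human", "mouse", "mouse", "bacteria"),
    forward_primer = c("CTCCACCCCAAATCAACAGAAT", "AAGACAGTGTGGCGATTCCT",
                       "AAAACCTGCCCCTACTCCTC", "CATCCTAGTCCTCATCGCCC",
                       "AGGCAACGCTGGAGATAGAA", "GGAGCTAAAGGGAACTGCAA",
                       "CGGTGAATACGTTCYCGG"),
    reverse_primer = c("AATAGGTGTGGTGTGGTGCT", "GATGGCTGGGTCAAATGGTAT",
                       "GGTGGAGATTTGGTGCTGTG", "TGGTAAGGGAGGGATCGTTG",
                       "ATGCTCGCATCTATGGTTCC", "CCGGGGTACTGCTTAGTTCA",
                       "AAGGAGGTGATCCRGCCGCA"),
    amplicon_length = c(55L, 60L, 83L, 77L, 58L, 62L, 173L),
    amplicon_length_alt = c(NA, NA, NA, NA, NA, NA, 172L),
    threshold = c(3400, 3400, 3400, 3400, 3000, 3000, 6300),
    anneal_temp = c(60, 60, 60, 60, 59, 59, 60),
    stringsAsFactors = FALSE
  )
  bad <- !grepl("^[ACGTRYSWKMBDHVN]+$", c(cat$forward_primer, cat$reverse_primer))
  stopifnot(!any(bad))
  cat
}

#' Default per-assay amplitude thresholds
#'
#' Named numeric vector mapping each catalogued assay to its fixed positive
#' calling threshold.
#'
#' @return Named numeric vector of amplitude thresholds.
#' @export
default_thresholds <- function() {
  cat <- assay_catalog()
  stats::setNames(cat$threshold, cat$assay_id)
}
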