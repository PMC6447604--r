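#' Construct a droplet well
#'
#' A `droplet_well` holds the raw per-droplet fluorescence amplitudes read
#' from a single ddPCR well, together with its identity (well, sample and
#' assay labels). The accepted droplet count is, by definition, the length of
#' the amplitude vector.
#'
#' @param well_id Character scalar; plate-well label (e.g. `"A01"`).
#' @param sample_id Character scalar; sample the well was loaded with.
#' @param assay_id Character scalar; assay (primer set) run in the well.
#' @param amplitudes Numeric vector of droplet fluorescence amplitudes
#'   (arbitrary units). Must be finite and non-negative.
#'
#' @return An object of class `droplet_well`: a list with elements
#'   `well_id`, `sample_id`, `assay_id`, `amplitudes` and `accepted_count`.
#' @examples
#' w <- droplet_well("A01", "S1", "LINE1_60", c(1800, 1750, 6400))
#' w$accepted_count
#' @export
droplet_well <- function(well_id, sample_id, assay_id, amplitudes) {
  stopifnot(is.character(well_id), length(well_id) == 1L,
            is.character(sample_id), length(sample_id) == 1L,
            is.character(assay_id), length(assay_id) == 1L)
  amplitudes <- as.numeric(amplitudes)
  if (length(amplitudes) > 0 && (any(!is.finite(amplitudes)) || any(amplitudes < 0)))
    stop("amplitudes must be finite and >= 0", call. = FALSE)
  structure(
    list(well_id = well_id, sample_id = sample_id, assay_id = assay_id,
         amplitudes = amplitudes, accepted_count = length(amplitudes)),
    class = "droplet_well"
  )
}

#' @export
print.droplet_well <- function(x, ...) {
  cat(sprintf("<droplet_well> %s | sample %s | assay %s | %d accepted droplets\n",
              x$well_id, x$sample_id, x$assay_id, x$accepted_count))
  invisible(x)
}

is_droplet_well <- function(x) inherits(x, "droplet_well")

as_well_list <- function(wells) {
  if (is_droplet_well(wells)) return(list(wells))
  if (!is.list(wells) || !all(vapply(wells, is_droplet_well, logical(1))))
    stop("expected a droplet_well or a list of droplet_well objects", call. = FALSE)
  wells
}
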