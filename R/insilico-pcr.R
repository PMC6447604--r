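IUPAC_CHARS <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M",
                 "B", "D", "H", "V", "N")

check_iupac <- function(x, what) {
  chars <- unique(strsplit(toupper(x), "")[[1]])
  bad <- setdiff(chars, IUPAC_CHARS)
  if (length(bad) > 0)
    stop(sprintf("non-IUPAC character '%s' in %s", bad[1], what), call. = FALSE)
  invisible(TRUE)
}

# Accept a character vector (optionally named), DNAString(Set), or a FASTA
# file path, and return a named DNAStringSet.
as_template_set <- function(templates) {
  if (inherits(templates, "DNAStringSet")) {
    set <- templates
  } else if (inherits(templates, "DNAString")) {
    set <- Biostrings::DNAStringSet(templates)
  } else if (is.character(templates)) {
    if (length(templates) == 1 && !grepl("^[ACGTRYSWKMBDHVNacgtryswkmbdhvn]+$", templates) &&
        file.exists(templates)) {
      set <- Biostrings::readDNAStringSet(templates)
    } else {
      for (i in seq_along(templates))
        check_iupac(templates[i], sprintf("template %d", i))
      set <- Biostrings::DNAStringSet(toupper(templates))
      if (!is.null(names(templates))) names(set) <- names(templates)
    }
  } else {
    stop("templates must be character, DNAString(Set) or a FASTA path",
         call. = FALSE)
  }
  if (length(set) > 0) {
    if (is.null(names(set)) || any(names(set) == ""))
      names(set) <- paste0("template_", seq_along(set))
    names(set) <- sub("\\s.*$", "", names(set))
  }
  set
}

empty_amplicons <- function() {
  data.frame(template_id = character(), start = integer(), end = integer(),
             strand = character(), length = integer(), sequence = character(),
             stringsAsFactors = FALSE)
}

# Plus-strand products of (fwd, rev) on one subject sequence; 1-based coords.
plus_strand_products <- function(subject, fwd, rev, max_product_bp, max_mismatch) {
  f_hits <- Biostrings::matchPattern(fwd, subject, max.mismatch = max_mismatch,
                                     fixed = "subject")
  if (length(f_hits) == 0) return(NULL)
  rc_rev <- Biostrings::reverseComplement(Biostrings::DNAString(rev))
  r_hits <- Biostrings::matchPattern(rc_rev, subject, max.mismatch = max_mismatch,
                                     fixed = "subject")
  if (length(r_hits) == 0) return(NULL)
  out <- list(); k <- 0L
  for (i in seq_along(f_hits)) {
    fs <- IRanges::start(f_hits)[i]; fe <- IRanges::end(f_hits)[i]
    for (j in seq_along(r_hits)) {
      rs <- IRanges::start(r_hits)[j]; re <- IRanges::end(r_hits)[j]
      if (rs > fe && (re - fs + 1) <= max_product_bp) {
        k <- k + 1L
        out[[k]] <- c(start = fs, end = re)
      }
    }
  }
  if (k == 0L) return(NULL)
  do.call(rbind, out)
}

#' Enumerate in silico PCR products of a primer pair
#'
#' Reports every site where the forward primer matches one strand of a
#' template and the reverse complement of the reverse primer matches
#' downstream on the same strand within `max_product_bp`, allowing up to
#' `max_mismatch` mismatches per primer. Degenerate IUPAC codes in the
#' primers match their base set at zero mismatch cost (a Y matches C or T);
#' template letters are taken literally. Both strands are searched and all
#' overlapping products are reported, sorted by template and start.
#'
#' Coordinates are 0-based half-open on the forward strand of the template;
#' see [amplicons_onebased()] for 1-based inclusive display coordinates.
#' The reported `sequence` is primer-oriented: it begins with the forward
#' primer match, so minus-strand products carry the reverse complement of
#' the template slice.
#'
#' @param templates Templates to scan: character vector of sequences
#'   (IUPAC), a `DNAStringSet`, or a FASTA file path.
#' @param fwd,rev Primer sequences (IUPAC DNA strings).
#' @param max_product_bp Maximum product length (default 4000).
#' @param max_mismatch Maximum mismatches allowed per primer (default 0).
#'
#' @return Data.frame with columns `template_id`, `start`, `end`, `strand`,
#'   `length` and `sequence`.
#' @examples
#' find_amplicons("TTTAAGACAGTGTGGCGATTCCTGGGATACCATTTGACCCAGCCATCTTT",
#'                "AAGACAGTGTGGCGATTCCT", "GATGGCTGGGTCAAATGGTAT")
#' @export
find_amplicons <- function(templates, fwd, rev, max_product_bp = 4000,
                           max_mismatch = 0) {
  if (!is.character(fwd) || nchar(fwd) == 0 || !is.character(rev) || nchar(rev) == 0)
    stop("primers must be non-empty strings", call. = FALSE)
  fwd <- toupper(fwd); rev <- toupper(rev)
  check_iupac(fwd, "forward primer")
  check_iupac(rev, "reverse primer")
  if (max_product_bp < nchar(fwd) + nchar(rev))
    stop("max_product_bp must be >= combined primer length", call. = FALSE)
  stopifnot(max_mismatch >= 0)
  set <- as_template_set(templates)
  rows <- list(); k <- 0L
  for (i in seq_along(set)) {
    subj <- set[[i]]
    tid <- names(set)[i]
    len <- length(subj)
    plus <- plus_strand_products(subj, fwd, rev, max_product_bp, max_mismatch)
    if (!is.null(plus)) {
      for (r in seq_len(nrow(plus))) {
        s1 <- plus[r, "start"]; e1 <- plus[r, "end"]
        k <- k + 1L
        rows[[k]] <- data.frame(
          template_id = tid, start = s1 - 1L, end = e1, strand = "+",
          length = e1 - s1 + 1L,
          sequence = as.character(Biostrings::subseq(subj, s1, e1)),
          stringsAsFactors = FALSE)
      }
    }
    rc_subj <- Biostrings::reverseComplement(subj)
    minus <- plus_strand_products(rc_subj, fwd, rev, max_product_bp, max_mismatch)
    if (!is.null(minus)) {
      for (r in seq_len(nrow(minus))) {
        s1 <- minus[r, "start"]; e1 <- minus[r, "end"]
        k <- k + 1L
        rows[[k]] <- data.frame(
          template_id = tid, start = len - e1, end = len - s1 + 1L, strand = "-",
          length = e1 - s1 + 1L,
          sequence = as.character(Biostrings::subseq(rc_subj, s1, e1)),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (k == 0L) return(empty_amplicons())
  out <- do.call(rbind, rows)
  out$start <- as.integer(out$start); out$end <- as.integer(out$end)
  out <- out[order(out$template_id, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Convert amplicon coordinates to 1-based inclusive display form
#'
#' @param amplicons Data.frame from [find_amplicons()].
#' @return Same data.frame with added `start1` and `end1` columns.
#' @export
amplicons_onebased <- function(amplicons) {
  amplicons$start1 <- amplicons$start + 1L
  amplicons$end1 <- amplicons$end
  amplicons
}

#' Count predicted PCR products across a template collection
#'
#' Total in silico product count of a primer pair over all records of a
#' FASTA collection; on a genome assembly this estimates the target copies
#' per genome for repeat-element assays.
#'
#' @inheritParams find_amplicons
#' @return Integer product count.
#' @examples
#' copies_per_genome(c(a = "TTAAGACAGTGTGGCGATTCCTGGATACCATTTGACCCAGCCATCTT"),
#'                   "AAGACAGTGTGGCGATTCCT", "GATGGCTGGGTCAAATGGTAT")
#' @export
copies_per_genome <- function(templates, fwd, rev, max_product_bp = 4000,
                              max_mismatch = 0) {
  set <- as_template_set(templates)
  if (length(set) == 0) stop("template collection is empty", call. = FALSE)
  nrow(find_amplicons(set, fwd, rev, max_product_bp, max_mismatch))
}

#' Count restriction sites and expected fragment length
#'
#' Non-overlapping, left-to-right occurrences of a non-degenerate
#' recognition site on the forward strand (mirroring enzymatic digestion),
#' with the expected mean fragment length `len(template) / (count + 1)`.
#' HaeIII (GGCC) digestion of the human genome gives a theoretical mean
#' fragment of ~347 bp by this arithmetic.
#'
#' @param template A single DNA sequence (character or `DNAString`).
#' @param site Recognition site, non-degenerate (default `"GGCC"`, HaeIII;
#'   EcoRI is `"GAATTC"`).
#' @return List with `count` and `mean_fragment_length`.
#' @examples
#' restriction_site_count("AAGGCCAA")$count  # 1
#' @export
restriction_site_count <- function(template, site = "GGCC") {
  if (inherits(template, "DNAString")) template <- as.character(template)
  stopifnot(is.character(template), length(template) == 1)
  if (!is.character(site) || nchar(site) == 0)
    stop("site must be a non-empty string", call. = FALSE)
  site <- toupper(site); template <- toupper(template)
  if (!grepl("^[ACGT]+$", site))
    stop("site must be non-degenerate (A/C/G/T only)", call. = FALSE)
  check_iupac(template, "template")
  m <- gregexpr(site, template, fixed = TRUE)[[1]]
  count <- if (m[1] == -1) 0L else length(m)
  list(count = count,
       mean_fragment_length = nchar(template) / (count + 1))
}

#' Bundled synthetic quantification standard (gBlock) sequences
#'
#' Returns the two double-stranded synthetic DNA standards used for assay
#' validation as a `DNAStringSet`: a gBlock carrying the 60-bp LINE-1
#' amplicon and a 196-bp gBlock carrying the 83-bp ND5 amplicon, each with
#' two substituted nucleotides creating an internal EcoRI site.
#'
#' @return A `Biostrings::DNAStringSet` with records `gblock_LINE1_60` and
#'   `gblock_ND5_83`.
#' @examples
#' gblock_templates()
#' @export
gblock_templates <- function() {
  path <- system.file("extdata", "gblocks.fasta", package = "stoolddpcr",
                      mustWork = TRUE)
  set <- Biostrings::readDNAStringSet(path)
  names(set) <- sub("\\s.*$", "", names(set))
  set
}
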