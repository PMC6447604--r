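# Pure-R oracles and fixture builders, independent of the package internals.

IUPAC_SET <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

# Hand-rolled reverse complement over plain characters (IUPAC-aware).
rc_chr <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R", S = "S",
            W = "W", K = "M", M = "K", B = "V", D = "H", H = "D", V = "B",
            N = "N")
  paste(rev(comp[strsplit(x, "")[[1]]]), collapse = "")
}

# Naive O(n*m) scan: 1-based start positions where every primer letter's
# IUPAC set contains the template letter, allowing <= max_mm mismatches.
naive_scan <- function(template, primer, max_mm = 0) {
  tc <- strsplit(template, "")[[1]]
  pc <- strsplit(primer, "")[[1]]
  n <- length(tc); m <- length(pc)
  if (n < m) return(integer())
  np <- n - m + 1
  mm <- integer(np)
  for (j in seq_len(m)) {
    hit <- tc[j:(j + np - 1)] %in% IUPAC_SET[[pc[j]]]
    mm <- mm + !hit
  }
  which(mm <= max_mm)
}

# Naive product enumeration on both strands; 0-based half-open coordinates
# on the forward strand, mirroring the documented output contract.
naive_products <- function(template, fwd, rev, max_product = 4000, max_mm = 0) {
  L <- nchar(template)
  one_strand <- function(t) {
    fs <- naive_scan(t, fwd, max_mm)
    rs <- naive_scan(t, rc_chr(rev), max_mm)
    out <- list(); k <- 0
    for (f in fs) for (r in rs) {
      prod_len <- (r + nchar(rev) - 1) - f + 1
      if (r > f + nchar(fwd) - 1 && prod_len <= max_product) {
        k <- k + 1
        out[[k]] <- c(start1 = f, end1 = r + nchar(rev) - 1)
      }
    }
    if (k == 0) NULL else do.call(rbind, out)
  }
  rows <- list(); k <- 0
  p <- one_strand(template)
  if (!is.null(p)) for (i in seq_len(nrow(p))) {
    k <- k + 1
    rows[[k]] <- data.frame(start = p[i, 1] - 1L, end = p[i, 2], strand = "+")
  }
  m <- one_strand(rc_chr(template))
  if (!is.null(m)) for (i in seq_len(nrow(m))) {
    k <- k + 1
    rows[[k]] <- data.frame(start = L - m[i, 2], end = L - m[i, 1] + 1L,
                            strand = "-")
  }
  if (k == 0) return(data.frame(start = integer(), end = integer(),
                                strand = character()))
  out <- do.call(rbind, rows)
  out[order(out$start, out$end, out$strand), , drop = FALSE]
}

random_template <- function(n, seed) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Random template with the primer pair planted at a random position/strand
# so that equivalence tests exercise non-empty product sets.
planted_template <- function(n, fwd, rev, seed, gap = 40) {
  set.seed(seed)
  insert <- paste0(fwd,
                   paste(sample(c("A", "C", "G", "T"), gap, replace = TRUE),
                         collapse = ""),
                   rc_chr(rev))
  if (runif(1) < 0.5) insert <- rc_chr(insert)
  base <- paste(sample(c("A", "C", "G", "T"), n - nchar(insert), replace = TRUE),
                collapse = "")
  at <- sample.int(nchar(base), 1)
  paste0(substr(base, 1, at), insert, substr(base, at + 1, nchar(base)))
}

make_counts <- function(positives, negatives, threshold = 3400) {
  structure(list(positives = positives, negatives = negatives,
                 total = positives + negatives, threshold_used = threshold),
            class = "droplet_counts")
}

constant_well <- function(amp, n, well_id = "W1", sample_id = "S1",
                          assay_id = "LINE1_60") {
  droplet_well(well_id, sample_id, assay_id, rep(amp, n))
}

# 99% binomial interval half-width for a proportion.
binom99_halfwidth <- function(p, n) qnorm(0.995) * sqrt(p * (1 - p) / n)
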