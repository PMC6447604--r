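l1_fwd <- "AAGACAGTGTGGCGATTCCT"
l1_rev <- "GATGGCTGGGTCAAATGGTAT"
nd5_fwd <- "AAAACCTGCCCCTACTCCTC"
nd5_rev <- "GGTGGAGATTTGGTGCTGTG"

test_that("bundled quantification standards carry their printed amplicons", {
  gb <- gblock_templates()
  l1 <- find_amplicons(gb, l1_fwd, l1_rev)
  expect_equal(nrow(l1), 1)
  expect_equal(l1$length, 60)
  expect_equal(l1$template_id, "gblock_LINE1_60")
  nd5 <- find_amplicons(gb, nd5_fwd, nd5_rev)
  expect_equal(nrow(nd5), 1)
  expect_equal(nd5$length, 83)
  expect_equal(nd5$template_id, "gblock_ND5_83")
  # length labels: ND5 record is 196 nt as labelled; the LINE-1 transcript
  # is 125 nt (its label says 126); advisory only, the amplicons above bind.
  expect_equal(Biostrings::width(gb)[[2]], 196)
})

test_that("each gBlock contains exactly one engineered EcoRI site", {
  gb <- gblock_templates()
  for (i in 1:2)
    expect_equal(restriction_site_count(as.character(gb[[i]]), "GAATTC")$count, 1)
})

test_that("primer pairs absent from a template yield no products", {
  t <- random_template(500, seed = 1)
  expect_equal(nrow(find_amplicons(t, l1_fwd, l1_rev)), 0)
})

test_that("reverse-complementing the template preserves product lengths", {
  for (s in 1:5) {
    t <- planted_template(800, l1_fwd, l1_rev, seed = 200 + s)
    fwd_hits <- find_amplicons(t, l1_fwd, l1_rev)
    rc_hits <- find_amplicons(rc_chr(t), l1_fwd, l1_rev)
    expect_equal(sort(fwd_hits$length), sort(rc_hits$length))
    expect_equal(nrow(fwd_hits), nrow(rc_hits))
  }
})

test_that("product sequences are primer-oriented and match the template slice", {
  t <- planted_template(600, nd5_fwd, nd5_rev, seed = 31)
  amp <- find_amplicons(t, nd5_fwd, nd5_rev)
  expect_gte(nrow(amp), 1)
  for (i in seq_len(nrow(amp))) {
    expect_true(startsWith(amp$sequence[i], nd5_fwd))
    expect_true(endsWith(amp$sequence[i], rc_chr(nd5_rev)))
    expect_equal(amp$end[i] - amp$start[i], amp$length[i])
    slice <- substr(t, amp$start[i] + 1, amp$end[i])
    if (amp$strand[i] == "+") expect_equal(amp$sequence[i], slice)
    else expect_equal(amp$sequence[i], rc_chr(slice))
  }
})

test_that("degenerate primer codes match their base set at zero mismatches", {
  # 16S forward primer carries a Y (C or T)
  fwd16 <- "CGGTGAATACGTTCYCGG"
  rev16 <- "AAGGAGGTGATCCRGCCGCA"
  for (y in c("C", "T")) {
    for (r in c("A", "G")) {
      core <- paste0(sub("Y", y, fwd16), strrep("A", 30),
                     rc_chr(sub("R", r, rev16)))
      t <- paste0("GGGG", core, "TTTT")
      amp <- find_amplicons(t, fwd16, rev16, max_mismatch = 0)
      expect_equal(nrow(amp), 1)
      expect_equal(amp$length, nchar(core))
    }
  }
})

test_that("raising max_mismatch never decreases the product count", {
  for (s in 1:5) {
    t <- planted_template(700, l1_fwd, l1_rev, seed = 300 + s)
    counts <- vapply(0:2, function(mm)
      nrow(find_amplicons(t, l1_fwd, l1_rev, max_mismatch = mm)), numeric(1))
    expect_true(all(diff(counts) >= 0))
  }
})

test_that("non-IUPAC symbols are rejected by name", {
  expect_error(find_amplicons("ACGTXACGT", l1_fwd, l1_rev), "X")
  expect_error(find_amplicons("ACGT", "ACEG", l1_rev), "E")
})

test_that("product enumeration agrees with the naive quadratic oracle", {
  for (s in 1:40) {
    t <- if (s %% 2 == 0) planted_template(1000, l1_fwd, l1_rev, seed = 400 + s)
         else random_template(1000, seed = 400 + s)
    got <- find_amplicons(t, l1_fwd, l1_rev)
    want <- naive_products(t, l1_fwd, l1_rev)
    expect_equal(nrow(got), nrow(want))
    if (nrow(got) > 0) {
      expect_equal(got$start, want$start)
      expect_equal(got$end, want$end)
      expect_equal(got$strand, want$strand)
    }
  }
})

test_that("copy counting is additive over repeated records", {
  gb <- gblock_templates()
  expect_equal(copies_per_genome(gb, l1_fwd, l1_rev), 1)
  l1_seq <- as.character(gb[[1]])
  three <- c(a = l1_seq, b = l1_seq, c = l1_seq)
  expect_equal(copies_per_genome(three, l1_fwd, l1_rev), 3)
  expect_error(copies_per_genome(Biostrings::DNAStringSet(), l1_fwd, l1_rev),
               "empty")
})

test_that("restriction site counting is non-overlapping and left to right", {
  expect_equal(restriction_site_count("ACGTACGT", "GGCC")$count, 0)
  expect_equal(restriction_site_count("ACGTACGT", "GGCC")$mean_fragment_length, 8)
  n <- 6
  poly <- strrep("GGCC", n)
  expect_equal(restriction_site_count(poly, "GGCC")$count, n)
  expect_error(restriction_site_count("ACGT", ""), "non-empty")
  expect_error(restriction_site_count("ACGT", "GGYC"), "non-degenerate")
})

test_that("FASTA input and one-based display coordinates work", {
  path <- system.file("extdata", "gblocks.fasta", package = "stoolddpcr")
  amp <- find_amplicons(path, l1_fwd, l1_rev)
  expect_equal(amp$length, 60)
  disp <- amplicons_onebased(amp)
  expect_equal(disp$start1, amp$start + 1)
  expect_equal(disp$end1 - disp$start1 + 1, amp$length)
})
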