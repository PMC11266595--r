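test_that("find_orfs reports the longest ORF per stop codon", {
  o <- find_orfs("ATGAAATGA", min_len = 9)
  expect_equal(nrow(o), 1)
  expect_equal(o$length_nt, 9)
  expect_equal(o$start, 0L)
  expect_equal(o$end, 9L)
  expect_equal(o$sequence, "ATGAAATGA")

  # inner ATG is not reported: longest per stop only
  o2 <- find_orfs("ATGATGAAATGA", min_len = 9)
  expect_equal(nrow(o2), 1)
  expect_equal(o2$start, 0L)
  expect_equal(o2$length_nt, 12)

  # min_len counts the stop codon: a 27-nt ORF is dropped at the default 30
  s27 <- paste0("ATG", strrep("AAA", 7), "TGA")
  expect_equal(nrow(find_orfs(s27)), 0)
  s30 <- paste0("ATG", strrep("AAA", 8), "TGA")
  expect_equal(nrow(find_orfs(s30)), 1)
})

test_that("reported ORFs always satisfy the record invariants", {
  set.seed(61)
  for (i in 1:20) {
    s <- paste(sample(NT, 400, replace = TRUE), collapse = "")
    o <- find_orfs(s, min_len = 30)
    if (nrow(o) == 0) next
    expect_true(all(o$length_nt %% 3 == 0))
    expect_true(all(o$length_nt >= 30))
    expect_true(all(substr(o$sequence, 1, 3) == "ATG"))
    expect_true(all(substring(o$sequence, o$length_nt - 2) %in% STOPS))
    interior_has_stop <- vapply(o$sequence, function(x) {
      n <- nchar(x) / 3
      cods <- substring(x, 3 * (1:(n - 1)) - 2, 3 * (1:(n - 1)))
      any(cods %in% STOPS)
    }, TRUE)
    expect_false(any(interior_has_stop))
    expect_true(all(o$sequence == substring(s, o$start + 1, o$end)))
  }
})

test_that("reverse-complement scanning mirrors onto minus-strand intervals", {
  set.seed(62)
  s <- paste(sample(NT, 600, replace = TRUE), collapse = "")
  n <- nchar(s)
  rev <- find_orfs(oracle_revcomp(s), min_len = 30)
  expect_gt(nrow(rev), 0)
  for (r in seq_len(nrow(rev))) {
    a <- n - rev$end[r]
    b <- n - rev$start[r]
    expect_true(a >= 0 && b <= n)
    # the mirrored forward-strand substring, reverse complemented, is the ORF
    expect_equal(oracle_revcomp(substr(s, a + 1, b)), rev$sequence[r])
  }
})

test_that("sub_orfs enumerates internal in-frame ATGs by brute force", {
  o <- find_orfs(paste0("ATGATG", strrep("AAA", 10), "TGA"), min_len = 30)
  subs <- sub_orfs(o, min_len = 30)
  expect_equal(nrow(subs), 1)
  expect_equal(subs$length_nt, o$length_nt - 3)
  expect_equal(subs$stop_anchor, o$stop_anchor)
  expect_true(all(subs$is_sub_orf))

  # no internal ATG -> none
  o2 <- find_orfs(paste0("ATG", strrep("AAA", 9), "TGA"), min_len = 30)
  expect_equal(nrow(sub_orfs(o2)), 0)

  # brute-force oracle: parent + sub-ORFs per stop = number of in-frame ATGs
  # with >= 30 nt remaining to the shared stop
  set.seed(63)
  for (i in 1:10) {
    s <- paste(sample(NT, 500, replace = TRUE, prob = c(.35, .15, .15, .35)),
               collapse = "")
    parents <- find_orfs(s, min_len = 30)
    if (nrow(parents) == 0) next
    all_orfs <- dplyr::bind_rows(parents, sub_orfs(parents, min_len = 30))
    for (r in seq_len(nrow(parents))) {
      x <- parents$sequence[r]
      ncod <- nchar(x) / 3
      cods <- substring(x, 3 * seq_len(ncod) - 2, 3 * seq_len(ncod))
      expected_n <- sum(cods == "ATG" & 3 * (ncod - seq_len(ncod) + 1) >= 30)
      got <- sum(all_orfs$stop_anchor == parents$stop_anchor[r] &
                   all_orfs$frame_offset == parents$frame_offset[r])
      expect_equal(got, expected_n)
    }
  }
})

test_that("classify_frame implements the register arithmetic", {
  # sense CDS on +, asORF on -: exact antiparallel codon overlap is frame 0
  cf <- classify_frame(6, 15, "-", 0, 30, "+")
  expect_equal(cf$frame, "as0")
  # shifted one nt toward the sense 5' end (left): frame 1
  cf1 <- classify_frame(5, 14, "-", 0, 30, "+")
  expect_equal(cf1$frame, "as1")
  cf2 <- classify_frame(4, 13, "-", 0, 30, "+")
  expect_equal(cf2$frame, "as2")
  # anchor invariance: any sense codon start gives the same register
  expect_equal(classify_frame(5, 14, "-", 3, 30, "+")$frame, "as1")
  expect_equal(classify_frame(5, 14, "-", 9, 33, "+")$frame, "as1")
  # overlap fraction
  expect_equal(classify_frame(5, 14, "-", 0, 30, "+")$overlap_fraction, 1)
  expect_equal(classify_frame(27, 36, "-", 0, 30, "+")$overlap_fraction, 1 / 3)
  # mirrored geometry: sense on minus strand
  expect_equal(classify_frame(0, 9, "+", 0, 30, "-")$frame, "as0")
  expect_equal(classify_frame(1, 10, "+", 0, 30, "-")$frame, "as1")
  expect_error(classify_frame(0, 9, "+", 0, 30, "+"), "opposite")
  expect_error(classify_frame(50, 60, "-", 0, 30, "+"), "overlap")
})

test_that("planted asORFs are recovered with exact frames and coordinates", {
  spec <- synthetic_genome_spec(seed = 7, g = 0.4, n_cds = 8,
                                cds_codons = c(60, 90),
                                planted = c(as0 = 2, as1 = 2, as2 = 2),
                                planted_k = 14)
  gen <- generate_genome(spec)
  scan <- scan_antisense_transcripts(gen$genome, gen$cds, gen$transcripts,
                                     min_len = 30, min_overlap = 1.0)
  found <- scan$orfs[!scan$orfs$is_sub_orf, ]
  for (r in seq_len(nrow(gen$truth))) {
    hit <- found[found$gstart == gen$truth$gstart[r] &
                   found$gend == gen$truth$gend[r], ]
    expect_equal(nrow(hit), 1)
    expect_equal(hit$frame, gen$truth$frame[r])
    expect_equal(hit$strand, "-")
  }
})

test_that("scan handles empty input and missing contigs", {
  spec <- synthetic_genome_spec(seed = 8, n_cds = 2, cds_codons = c(40, 50))
  gen <- generate_genome(spec)
  empty_tx <- GenomicRanges::GRanges()
  scan <- scan_antisense_transcripts(gen$genome, gen$cds, empty_tx)
  expect_equal(sum(scan$summary$n), 0)
  bad_tx <- GenomicRanges::GRanges("chrMissing",
                                   IRanges::IRanges(1, 50), strand = "-")
  expect_error(
    scan_antisense_transcripts(gen$genome, gen$cds, bad_tx),
    "chrMissing"
  )
})

test_that("exon GC comparison recovers a planted composition difference", {
  set.seed(64)
  draw_exons <- function(g, n, len) {
    vapply(seq_len(n), function(i) {
      paste(sample(NT, len, replace = TRUE,
                   prob = c((1 - g) / 2, g / 2, g / 2, (1 - g) / 2)),
            collapse = "")
    }, "")
  }
  ov <- draw_exons(0.36, 60, 400)
  al <- draw_exons(0.40, 60, 400)
  res <- exon_gc_comparison(ov, al)
  expect_lt(res$median_overlap, res$median_all)
  expect_lt(res$p, 0.01)
  expect_equal(res$median_overlap, 0.36, tolerance = 0.02)
  # identical sets: medians equal, no significance
  same <- exon_gc_comparison(ov, ov)
  expect_equal(same$median_overlap, same$median_all)
  expect_gt(same$p, 0.4)
  expect_error(exon_gc_comparison(character(0), al), "nonempty")
})
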