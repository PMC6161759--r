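test_that("exact substring aligns as a single block without gaps", {
  set.seed(1)
  locus <- randomSeq(400)
  amp <- substr(locus, 51, 350)
  aln <- splicedAlign(amp, locus)
  expect_identical(nrow(aln@blocks), 1L)
  expect_length(aln@gaps, 0L)
  expect_identical(aln@mismatches, 0L)
  expect_identical(aln@blocks$gStart, 51L)
  expect_identical(aln@blocks$gEnd, 350L)
})

test_that("a constructed two-block splice is recovered exactly", {
  set.seed(2)
  locus <- randomSeq(400)
  amp <- paste0(substr(locus, 1, 200), substr(locus, 261, 400))
  aln <- splicedAlign(amp, locus)
  expect_identical(nrow(aln@blocks), 2L)
  expect_length(aln@gaps, 1L)
  # leftmost normal form of the planted [201,260] gap
  ref <- bruteSingleGap(amp, locus)
  expect_identical(start(aln@gaps), ref[1])
  expect_identical(end(aln@gaps), ref[2])
  expect_identical(width(aln@gaps), 60L)
})

test_that("no-alignment input raises NO_ALIGNMENT", {
  set.seed(3)
  expect_error(splicedAlign(randomSeq(100), randomSeq(400)), "NO_ALIGNMENT")
})

test_that("random single-gap cases match the brute-force oracle", {
  set.seed(101)
  for (i in 1:100) {
    b1 <- sample(25:180, 1); b2 <- sample(25:180, 1); gl <- sample(20:120, 1)
    locus <- randomSeq(b1 + gl + b2)
    amp <- paste0(substr(locus, 1, b1),
                  substr(locus, b1 + gl + 1, nchar(locus)))
    # up to 1% substitutions
    nMut <- rbinom(1, nchar(amp), 0.01)
    if (nMut > 0) {
      at <- sample(nchar(amp), nMut)
      v <- strsplit(amp, "")[[1]]
      for (j in at) v[j] <- sample(setdiff(c("A", "C", "G", "T"), v[j]), 1)
      amp <- paste(v, collapse = "")
    }
    aln <- splicedAlign(amp, locus, minSpliceGap = 8L)
    ref <- bruteSingleGap(amp, locus)
    expect_identical(length(aln@gaps), 1L)
    expect_identical(c(start(aln@gaps), end(aln@gaps)), ref,
                     info = sprintf("case %d (b1=%d gl=%d b2=%d)", i, b1, gl, b2))
  }
})

test_that("block reconstruction reproduces the amplicon up to reported noise", {
  set.seed(55)
  locus <- randomSeq(600)
  amp <- paste0(substr(locus, 1, 220), substr(locus, 301, 450),
                substr(locus, 521, 600))
  aln <- splicedAlign(amp, locus)
  expect_identical(nrow(aln@blocks), 3L)
  recon <- paste(vapply(seq_len(nrow(aln@blocks)), function(i)
    substr(locus, aln@blocks$gStart[i], aln@blocks$gEnd[i]), character(1)),
    collapse = "")
  expect_identical(recon, amp)
})

test_that("sub-splice-gap deletions are absorbed as indels, not gaps", {
  set.seed(56)
  locus <- randomSeq(400)
  amp <- paste0(substr(locus, 1, 200), substr(locus, 206, 400))  # 5 bp deletion
  aln <- splicedAlign(amp, locus, minSpliceGap = 8L)
  expect_length(aln@gaps, 0L)
  expect_identical(nrow(aln@blocks), 1L)
  expect_identical(aln@smallIndels, 5L)
  # the same deletion counts as a splice once minSpliceGap drops below it
  aln2 <- splicedAlign(amp, locus, minSpliceGap = 5L)
  expect_length(aln2@gaps, 1L)
  expect_identical(width(aln2@gaps), 5L)
})

test_that("lowering minSpliceGap never loses splicing evidence", {
  set.seed(57)
  for (i in 1:10) {
    locus <- randomSeq(500)
    cut <- sample(100:300, 1); gl <- sample(8:60, 1)
    amp <- paste0(substr(locus, 1, cut), substr(locus, cut + gl + 1, 500))
    gaps8 <- length(splicedAlign(amp, locus, minSpliceGap = 8L)@gaps)
    gaps5 <- length(splicedAlign(amp, locus, minSpliceGap = 5L)@gaps)
    expect_true(gaps5 >= gaps8)
  }
})

test_that("boundary refinement picks the canonical placement among shifts", {
  # unique placement already GT..AG: unchanged, canonical
  set.seed(70)
  e1 <- randomSeq(60); e2 <- randomSeq(60)
  intron <- paste0("GT", randomSeq(30), "AG")
  locus <- paste0(e1, intron, e2)
  amp <- paste0(e1, e2)
  aln <- refineBoundaries(splicedAlign(amp, locus), locus)
  expect_identical(start(aln@gaps), 61L)
  expect_identical(end(aln@gaps), 94L)
  expect_true(S4Vectors::mcols(aln@gaps)$canonical)

  # shiftable by repeated edge bases: exactly one shift is GT..AG
  # locus: e1 + "GT" + core + "AG" + e2, where e2 begins with the same two
  # bases as the intron start, so the gap can slide but only one placement
  # is canonical
  core <- randomSeq(26)
  intr2 <- paste0("GT", core, "AG")
  e2b <- paste0("GT", randomSeq(58))          # repeat of the donor bases
  locus2 <- paste0(e1, intr2, e2b)
  amp2 <- paste0(e1, e2b)
  aln2 <- refineBoundaries(splicedAlign(amp2, locus2), locus2)
  ref2 <- bruteRefine(locus2, 61, 90, 60, 60)
  expect_true(S4Vectors::mcols(aln2@gaps)$canonical)
  expect_identical(start(aln2@gaps), 61L + ref2$shift)

  # no canonical placement: leftmost kept, canonical FALSE
  intr3 <- paste0("CC", randomSeq(26), "CC")
  locus3 <- paste0(e1, intr3, e2)
  amp3 <- paste0(e1, e2)
  aln3 <- refineBoundaries(splicedAlign(amp3, locus3), locus3)
  expect_false(S4Vectors::mcols(aln3@gaps)$canonical)
  ref3 <- bruteRefine(locus3, 61, 90, 60, 60)
  expect_identical(start(aln3@gaps), 61L + ref3$shift)
})

test_that("refinement agrees with brute-force shift enumeration", {
  set.seed(71)
  for (i in 1:60) {
    e1 <- randomSeq(50); e2 <- randomSeq(50)
    gl <- sample(10:40, 1)
    intron <- if (i %% 2 == 0) paste0("GT", randomSeq(gl - 4), "AG")
              else randomSeq(gl)
    # force shiftability in a third of cases by repeating edges
    if (i %% 3 == 0) {
      sh <- randomSeq(sample(1:4, 1))
      e2 <- paste0(sh, e2)
      intron <- paste0(sh, substr(intron, nchar(sh) + 1, gl))
    }
    locus <- paste0(e1, intron, e2)
    amp <- paste0(e1, e2)
    aln <- refineBoundaries(splicedAlign(amp, locus), locus)
    ref <- bruteRefine(locus, nchar(e1) + 1, nchar(e1) + nchar(intron),
                       nchar(e1), nchar(e2))
    expect_identical(length(aln@gaps), 1L, info = paste("case", i))
    expect_identical(start(aln@gaps), nchar(e1) + 1L + ref$shift,
                     info = paste("case", i))
    expect_identical(S4Vectors::mcols(aln@gaps)$canonical, ref$canonical,
                     info = paste("case", i))
  }
})

test_that("minus-strand refinement seeks CT..AC on the forward strand", {
  set.seed(72)
  e1 <- randomSeq(60); e2 <- randomSeq(60)
  intron <- paste0("CT", randomSeq(26), "AC")  # GT..AG in transcript sense
  locus <- paste0(e1, intron, e2)
  amp <- paste0(e1, e2)
  aln <- refineBoundaries(splicedAlign(amp, locus), locus, strand = "-")
  expect_true(S4Vectors::mcols(aln@gaps)$canonical)
})
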