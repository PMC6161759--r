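test_that("readGenome normalizes case, keeps first header token, validates", {
  fa <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">chr1 some description", "acgt", ">chr2", "NNACGT"), fa)
  g <- readGenome(fa)
  expect_identical(names(g), c("chr1", "chr2"))
  expect_identical(as.character(g[["chr1"]]), "ACGT")
  expect_identical(width(g), c(4L, 6L))

  dup <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">chr1", "ACGT", ">chr1", "GGCC"), dup)
  expect_error(readGenome(dup), "duplicate")

  empty <- withr::local_tempfile(fileext = ".fa")
  writeLines(character(0), empty)
  expect_error(readGenome(empty))
})

test_that("readAnnotation links gene/mRNA/exon and orders exons by strand", {
  fa <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">chr1", strrep("ACGT", 100)), fa)
  g <- readGenome(fa)
  gff <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\tx\tgene\t1\t250\t.\t+\t.\tID=gA",
    "chr1\tx\tmRNA\t1\t250\t.\t+\t.\tID=gA.1;Parent=gA",
    "chr1\tx\texon\t1\t100\t.\t+\t.\tParent=gA.1",
    "chr1\tx\texon\t151\t250\t.\t+\t.\tParent=gA.1",
    "chr1\tx\tgene\t261\t390\t.\t-\t.\tID=gB",
    "chr1\tx\tmRNA\t261\t390\t.\t-\t.\tID=gB.1;Parent=gB",
    "chr1\tx\texon\t261\t300\t.\t-\t.\tParent=gB.1",
    "chr1\tx\texon\t351\t390\t.\t-\t.\tParent=gB.1"), gff)
  gm <- readAnnotation(gff, g)
  expect_setequal(isoformIds(gm), c("gA.1", "gB.1"))
  eA <- exonsByIsoform(gm)[["gA.1"]]
  expect_identical(start(eA), c(1L, 151L))
  expect_identical(end(eA), c(100L, 250L))
  # minus strand: exon with larger coordinates first in transcription order
  eB <- exonsByIsoform(gm)[["gB.1"]]
  expect_identical(start(eB), c(351L, 261L))
  expect_identical(unname(txToGene(gm)["gB.1"]), "gB")
})

test_that("readAnnotation rejects orphan exons and out-of-bounds exons", {
  fa <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">chr1", strrep("ACGT", 25)), fa)
  g <- readGenome(fa)
  orphan <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "chr1\tx\tgene\t1\t50\t.\t+\t.\tID=g",
               "chr1\tx\tmRNA\t1\t50\t.\t+\t.\tID=g.1;Parent=g",
               "chr1\tx\texon\t1\t50\t.\t+\t.\tParent=ghost.1"), orphan)
  expect_error(readAnnotation(orphan, g), "unknown parent")
  oob <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "chr1\tx\tgene\t1\t500\t.\t+\t.\tID=g",
               "chr1\tx\tmRNA\t1\t500\t.\t+\t.\tID=g.1;Parent=g",
               "chr1\tx\texon\t1\t500\t.\t+\t.\tParent=g.1"), oob)
  expect_error(readAnnotation(oob, g), "bounds")
})

test_that("GFF3 round-trip preserves internal intervals", {
  gm <- twoGeneModels()
  fa <- withr::local_tempfile(fileext = ".fa")
  writeXStringSet(genomeSeq(gm), fa)
  gff <- withr::local_tempfile(fileext = ".gff3")
  writeAnnotation(gm, gff)
  gm2 <- readAnnotation(gff, readGenome(fa))
  expect_setequal(isoformIds(gm2), isoformIds(gm))
  for (iso in isoformIds(gm)) {
    a <- exonsByIsoform(gm)[[iso]]; b <- exonsByIsoform(gm2)[[iso]]
    expect_identical(start(a), start(b))
    expect_identical(end(a), end(b))
    expect_identical(as.character(strand(a)), as.character(strand(b)))
  }
})

test_that("deriveIntrons gets intervals, IDs and splice dinucleotides right", {
  gm <- twoGeneModels()
  intr <- deriveIntrons(gm)
  expect_length(intr, 2L)
  m <- S4Vectors::mcols(intr)
  plus <- intr[m$isoform_id == "gPlus.1"]
  expect_identical(start(plus), 101L)
  expect_identical(end(plus), 150L)
  expect_identical(width(plus), 50L)
  expect_identical(S4Vectors::mcols(plus)$intron_id, "gPlus.1-1")
  expect_identical(S4Vectors::mcols(plus)$donor, "GT")
  expect_identical(S4Vectors::mcols(plus)$acceptor, "AG")
  # minus strand: interval forward-strand, dinucleotides in transcript
  # orientation (sense intron was built GT..AG before reverse complementing)
  minus <- intr[m$isoform_id == "gMinus.1"]
  expect_identical(start(minus), 401L)
  expect_identical(end(minus), 450L)
  expect_identical(S4Vectors::mcols(minus)$donor, "GT")
  expect_identical(S4Vectors::mcols(minus)$acceptor, "AG")
  expect_true(all(S4Vectors::mcols(intr)$canonical))
})

test_that("single-exon isoforms yield no introns", {
  genome <- DNAStringSet(setNames(strrep("ACGT", 30), "chr1"))
  exons <- GRangesList(s.1 = GRanges("chr1", IRanges(1, 100), strand = "+"))
  gm <- GeneModels(genome, exons, c(s.1 = "s"))
  expect_length(deriveIntrons(gm), 0L)
})

test_that("exons plus introns tile the transcript span contiguously", {
  sim <- simulateGenome(nGenes = 8, seed = 5)
  intr <- deriveIntrons(sim$models)
  for (iso in isoformIds(sim$models)) {
    e <- exonsByIsoform(sim$models)[[iso]]
    i <- intr[S4Vectors::mcols(intr)$isoform_id == iso]
    u <- reduce(c(granges(e), granges(i)))
    expect_length(u, 1L)
    expect_identical(start(u), min(start(e)))
    expect_identical(end(u), max(end(e)))
  }
})

test_that("deriveIntrons recovers the generator's annotated intron truth", {
  sim <- simulateGenome(nGenes = 10, seed = 9)
  intr <- deriveIntrons(sim$models)
  key <- paste(S4Vectors::mcols(intr)$isoform_id, start(intr), end(intr))
  expect_true(all(paste(sim$truth$isoform_id, sim$truth$ann_start,
                        sim$truth$ann_end) %in% key))
})

test_that("census tallies lengths into lower-edge bins", {
  gr <- GRanges("chr1", IRanges(1, width = c(95, 85, 75, 65, 55, 30)))
  cen <- intronCensus(gr)
  expect_identical(cen$count, c(0L, 1L, 0L, 0L, 1L, 1L, 1L, 1L, 1L))
  expect_identical(attr(cen, "total_in_range"), 6L)
  expect_identical(sum(cen$count), attr(cen, "total_in_range"))

  empty <- intronCensus(GRanges())
  expect_true(all(empty$count == 0L))
  expect_identical(attr(empty, "total_all"), 0L)
})

test_that("census totals over sub-bins equal the under-L count", {
  sim <- simulateGenome(nGenes = 30, seed = 21)
  intr <- deriveIntrons(sim$models)
  cen <- intronCensus(intr, maxLen = 99L)
  expect_identical(sum(cen$count), sum(width(intr) <= 99L & width(intr) >= 1L))
})

test_that("uniqueLoci collapses introns shared between isoforms", {
  genome <- DNAStringSet(setNames(strrep("ACGT", 100), "chr1"))
  exons <- GRangesList(
    g.1 = GRanges("chr1", IRanges(c(1, 61), c(40, 100)), strand = "+"),
    g.2 = GRanges("chr1", IRanges(c(1, 61), c(40, 120)), strand = "+"))
  gm <- GeneModels(genome, exons, c(g.1 = "g", g.2 = "g"))
  intr <- deriveIntrons(gm)
  expect_length(intr, 2L)
  expect_identical(sum(intronCensus(intr, maxLen = 99)$count), 2L)
  expect_identical(sum(intronCensus(intr, maxLen = 99, uniqueLoci = TRUE)$count), 1L)
})
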