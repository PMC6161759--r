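mkIntrons <- function(lens) {
  gr <- GRanges("chr1", IRanges(1, width = lens))
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    intron_id = sprintf("g%d.1-1", seq_along(lens)),
    isoform_id = sprintf("g%d.1", seq_along(lens)),
    gene_id = sprintf("g%d", seq_along(lens)),
    ordinal = 1L, donor = "GT", acceptor = "AG", canonical = TRUE)
  gr
}

test_that("selectCandidates applies an inclusive threshold", {
  intr <- mkIntrons(c(8, 30, 31, 59))
  expect_identical(nrow(selectCandidates(intr, 30)), 2L)
  expect_identical(nrow(selectCandidates(intr, 59)), 4L)
  expect_identical(sort(selectCandidates(intr, 30)$length), c(8L, 30L))
})

test_that("selectCandidates is threshold-monotone and idempotent", {
  set.seed(4)
  intr <- mkIntrons(sample(5:120, 60, replace = TRUE))
  for (pair in list(c(10, 30), c(30, 59), c(59, 100))) {
    a <- selectCandidates(intr, pair[1])$candidate_id
    b <- selectCandidates(intr, pair[2])$candidate_id
    expect_true(all(a %in% b))
  }
  once <- selectCandidates(intr, 30)
  expect_identical(once[order(once$gene_id, once$candidate_id), ], once)
})

test_that("exclusion rules partition candidates exhaustively", {
  panel <- simulateScreeningPanel(nRetained = 5, nSoleIntron = 3,
                                  nNoPrimerSite = 2, seed = 2)
  cands <- panel$candidates
  expect_identical(nrow(cands), 10L)
  tab <- table(cands$exclusion)
  expect_identical(unname(tab["NONE"]), 5L)
  expect_identical(unname(tab["NO_CONTROL_INTRON"]), 3L)
  expect_identical(unname(tab["NO_PRIMER_SITE"]), 2L)
  # partition is total: exactly one label each
  expect_true(all(cands$exclusion %in%
    c("NONE", "NO_CONTROL_INTRON", "NO_PRIMER_SITE", "AMBIGUOUS_PRODUCT")))
})

test_that("a second isoform with more introns rescues a sole-intron candidate", {
  genome <- DNAStringSet(setNames(paste0(
    randomSeq(100), "GT", randomSeq(16), "AG",   # 20 bp candidate 101-120
    randomSeq(100), "GT", randomSeq(76), "AG",   # 80 bp control  221-300
    randomSeq(100)), "chr1"))
  exons <- GRangesList(
    g.1 = GRanges("chr1", IRanges(c(1, 121), c(100, 220)), strand = "+"),
    g.2 = GRanges("chr1", IRanges(c(1, 121, 301), c(100, 220, 400)),
                  strand = "+"))
  gm <- GeneModels(genome, exons, c(g.1 = "g", g.2 = "g"))
  cands <- selectCandidates(deriveIntrons(gm), 30)
  cands <- applyExclusions(cands, gm)
  expect_true(all(cands$exclusion == "NONE"))
})

test_that("applyExclusions reports a missing gene and AMBIGUOUS_PRODUCT", {
  panel <- simulateScreeningPanel(nRetained = 2, nSoleIntron = 0,
                                  nNoPrimerSite = 0, seed = 3)
  cands <- panel$candidates
  orphan <- cands
  orphan$gene_id[1] <- "NOT_A_GENE"
  expect_error(applyExclusions(orphan, panel$models), "missing")
  amb <- applyExclusions(cands, panel$models,
                         ambiguous = cands$candidate_id[1])
  expect_identical(amb$exclusion[1], "AMBIGUOUS_PRODUCT")
})

test_that("repeat flagging finds the planted hexamer tract", {
  tract <- strrep("CAACAG", 4)
  genome <- DNAStringSet(setNames(
    paste0(randomSeq(60), tract, randomSeq(60)), "chr1"))
  cand <- data.frame(seq_id = "chr1", start = 75, end = 90)
  rr <- flagRepeatContext(cand, genome, flank = 30)
  expect_true(rr$flagged)
  expect_identical(rr$period, 6L)
  expect_identical(rr$copies, 4L)
  expect_identical(substr(strrep(rr$motif, 2), 1, 6), rr$motif)
})

test_that("homopolymers flag at period 1; non-repetitive context does not flag", {
  genome <- DNAStringSet(setNames(paste0("ACGTACTG", "AAAAAA", "CTGCA"), "chr1"))
  cand <- data.frame(seq_id = "chr1", start = 9, end = 14)
  rr <- flagRepeatContext(cand, genome, flank = 4)
  expect_true(rr$flagged)
  expect_identical(rr$motif, "A")
  expect_identical(rr$copies, 6L)

  set.seed(99)
  quiet <- DNAStringSet(setNames("ACGTACTGACTGCA", "chr1"))
  rq <- flagRepeatContext(data.frame(seq_id = "chr1", start = 5, end = 10),
                          quiet, flank = 4, minCopies = 3)
  expect_false(rq$flagged)
})

test_that("repeat scanner agrees with the exhaustive oracle on random sequence", {
  set.seed(123)
  for (i in 1:40) {
    s <- randomSeq(200)
    if (i %% 4 == 0) {  # plant a tract in some cases
      motif <- randomSeq(sample(1:8, 1))
      at <- sample(1:150, 1)
      s <- paste0(substr(s, 1, at - 1), strrep(motif, sample(3:5, 1)),
                  substr(s, at, 200))
    }
    genome <- DNAStringSet(setNames(s, "chr1"))
    mine <- flagRepeatContext(
      data.frame(seq_id = "chr1", start = 1, end = nchar(s)), genome,
      flank = 0, minPeriod = 1, maxPeriod = 10, minCopies = 3)
    ref <- bruteBestRepeat(s, 1, 10)
    if (is.null(ref)) {
      expect_identical(mine$copies, 0L)
    } else {
      expect_identical(mine$copies, ref$copies)
      expect_identical(mine$period, ref$period)
      expect_identical(mine$motif, ref$motif)
    }
  }
})

test_that("diffAnnotations splits retained from removed", {
  d <- diffAnnotations(c("a", "b", "c"), c("a", "c"))
  expect_identical(d$retained, c("a", "c"))
  expect_identical(d$removed, "b")
  same <- diffAnnotations(c("a", "b"), c("b", "a"))
  expect_length(same$removed, 0L)
})

test_that("candidate sets from two annotation versions diff by planted removals", {
  sim <- simulateGenome(nGenes = 20, seed = 31)
  cands <- selectCandidates(deriveIntrons(sim$models), 59)
  drop <- sort(sample(cands$candidate_id, 6))
  newCands <- cands[!cands$candidate_id %in% drop, ]
  d <- diffAnnotations(cands, newCands)
  expect_identical(d$removed, drop)
  expect_identical(length(d$retained) + length(d$removed),
                   length(unique(cands$candidate_id)))
})

test_that("candidateReport ranks by descending expression and carries metadata", {
  sim <- simulateGenome(nGenes = 10, seed = 13)
  cands <- selectCandidates(deriveIntrons(sim$models), 59)
  cands <- cands[cands$candidate_id %in% sim$truth$candidate_id, ]
  cands <- applyExclusions(cands, sim$models)
  repo <- candidateReport(cands, sim$models)
  expect_identical(repo$no, seq_len(nrow(repo)))
  ex <- repo$expression
  expect_true(all(diff(ex[!is.na(ex)]) <= 0))
  ri <- sim$truth$candidate_id[sim$truth$kind == "REPEAT_INDUCED"]
  if (length(ri))
    expect_true(all(repo$repeat_flag[repo$candidate_id %in% ri]))
})
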