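test_that("Wallace rule melting temperature", {
  expect_identical(meltingTemperature("ACGT"), 12)
  expect_identical(meltingTemperature(strrep("A", 18)), 36)
  expect_identical(meltingTemperature(strrep("GC", 9)), 72)
  expect_error(meltingTemperature(""), "empty")
  expect_error(meltingTemperature("ACGN"), "ACGT")
})

test_that("designPrimers spans candidate plus control intron", {
  gene <- plusGene(c(300, 200, 300), c(25, 90), seed = 7)
  gm <- gene$models
  cands <- selectCandidates(deriveIntrons(gm), 30)
  expect_identical(nrow(cands), 1L)
  pp <- designPrimers(gm, cands[1, ])
  expect_s4_class(pp, "PrimerPair")
  expect_identical(pp@controlIntrons, "g1.1-2")
  # amplicon contains both introns
  expect_true(pp@ampliconStart <= gene$introns[1, 1] &&
              pp@ampliconEnd >= gene$introns[2, 2])
  # cDNA length = genomic span minus spanned intron lengths
  genomicLen <- pp@ampliconEnd - pp@ampliconStart + 1L
  expect_identical(pp@cdnaLength, genomicLen - 25L - 90L)
  # both primers within annotated exons
  expect_true(pp@forwardStart >= 1 && pp@forwardStart + nchar(pp@forwardSeq) - 1 <= 300)
  expect_true(pp@reverseStart >= gene$exons[3, 1])
  # constraints respected
  cons <- primerConstraints()
  for (tm in c(pp@tmForward, pp@tmReverse))
    expect_true(tm >= cons$tmRange[1] && tm <= cons$tmRange[2])
  expect_true(abs(pp@tmForward - pp@tmReverse) <= cons$maxTmDiff)
})

test_that("design is deterministic and fails informatively", {
  gene <- plusGene(c(300, 200, 300), c(25, 90), seed = 7)
  cands <- selectCandidates(deriveIntrons(gene$models), 30)
  a <- designPrimers(gene$models, cands[1, ])
  b <- designPrimers(gene$models, cands[1, ])
  expect_identical(a@forwardSeq, b@forwardSeq)
  expect_identical(a@reverseSeq, b@reverseSeq)

  solo <- plusGene(c(300, 300), 25, seed = 8, geneId = "solo")
  soloCands <- selectCandidates(deriveIntrons(solo$models), 30)
  expect_identical(designPrimers(solo$models, soloCands[1, ]),
                   "NO_CONTROL_INTRON")

  tiny <- plusGene(c(10, 10, 10), c(25, 90), seed = 9, geneId = "tiny")
  tinyCands <- selectCandidates(deriveIntrons(tiny$models), 30)
  expect_identical(designPrimers(tiny$models, tinyCands[1, ]),
                   "NO_PRIMER_SITE")
})

test_that("a last-intron candidate takes its control upstream", {
  gene <- plusGene(c(300, 200, 300), c(90, 25), seed = 17)
  cands <- selectCandidates(deriveIntrons(gene$models), 30)
  expect_identical(cands$ordinal, 2L)
  pp <- designPrimers(gene$models, cands[1, ])
  expect_s4_class(pp, "PrimerPair")
  expect_identical(pp@controlIntrons, "g1.1-1")
})

test_that("in-silico PCR discriminates genomic from spliced template", {
  gene <- plusGene(c(300, 200, 300), c(25, 90), seed = 7)
  gm <- gene$models
  cands <- selectCandidates(deriveIntrons(gm), 30)
  pp <- designPrimers(gm, cands[1, ])
  locus <- as.character(genomeSeq(gm)[["chr1"]])
  gHits <- inSilicoPcr(locus, pp)
  expect_identical(nrow(gHits), 1L)
  expect_identical(gHits$length, pp@ampliconEnd - pp@ampliconStart + 1L)
  # spliced template: product shorter by the summed intron lengths
  ex <- exonsByIsoform(gm)[["g1.1"]]
  cdna <- transcribe(ex, genomeSeq(gm))
  cHits <- inSilicoPcr(cdna, pp)
  expect_identical(nrow(cHits), 1L)
  expect_identical(gHits$length - cHits$length, 25L + 90L)
  expect_identical(cHits$length, pp@cdnaLength)
  # product starts with the forward primer on either template
  expect_identical(substr(gHits$product, 1, nchar(pp@forwardSeq)),
                   pp@forwardSeq)
})

test_that("in-silico PCR finds reverse-orientation products", {
  gene <- plusGene(c(300, 200, 300), c(25, 90), seed = 7)
  gm <- gene$models
  pp <- designPrimers(gm, selectCandidates(deriveIntrons(gm), 30)[1, ])
  locus <- as.character(genomeSeq(gm)[["chr1"]])
  hits <- inSilicoPcr(rc(locus), pp)
  expect_identical(nrow(hits), 1L)
  expect_identical(hits$orientation, "-")
  expect_identical(substr(hits$product, 1, nchar(pp@forwardSeq)),
                   pp@forwardSeq)
})

test_that("mismatch tolerance follows maxMismatch and matches a direct scan", {
  set.seed(42)
  template <- randomSeq(400)
  fwd <- substr(template, 51, 70)
  rev <- rc(substr(template, 301, 320))
  pair <- list(forwardSeq = fwd, reverseSeq = rev)
  exact <- inSilicoPcr(template, pair)
  expect_identical(exact$start, 51L)
  expect_identical(exact$end, 320L)
  # inject one internal mismatch into the forward primer
  fwdMut <- fwd
  substr(fwdMut, 10, 10) <- setdiff(c("A", "C", "G", "T"),
                                    substr(fwd, 10, 10))[1]
  pairMut <- list(forwardSeq = fwdMut, reverseSeq = rev)
  expect_identical(nrow(inSilicoPcr(template, pairMut, maxMismatch = 0)), 0L)
  one <- inSilicoPcr(template, pairMut, maxMismatch = 1)
  expect_identical(one$start, 51L)
  # brute-force check of the binding-site scan
  w <- nchar(fwdMut)
  ref <- which(vapply(1:(nchar(template) - w + 1), function(i)
    sum(utf8ToInt(substr(template, i, i + w - 1)) != utf8ToInt(fwdMut)) <= 1,
    logical(1)))
  expect_identical(intronAudit:::mismatchScan(template, fwdMut, 1L), ref)
})

test_that("minus-strand design places primers on exons and products verify", {
  sim <- simulateGenome(nGenes = 6, seed = 77)
  minus <- sim$truth[sim$truth$strand == "-", ][1, ]
  expect_false(is.na(minus$gene_id))
  cands <- selectCandidates(deriveIntrons(sim$models), 59)
  cand <- cands[cands$candidate_id == minus$candidate_id, ]
  pp <- designPrimers(sim$models, cand)
  expect_s4_class(pp, "PrimerPair")
  locus <- as.character(genomeSeq(sim$models)[["chr1"]])
  hits <- inSilicoPcr(locus, pp)
  expect_identical(nrow(hits), 1L)
  expect_identical(hits$start, pp@ampliconStart)
  expect_identical(hits$end, pp@ampliconEnd)
})
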