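## Hand-built fixtures and independent brute-force oracles shared by the
## suite.  Everything is generated in code; no binary data.

suppressPackageStartupMessages({
  library(Biostrings)
  library(GenomicRanges)
  library(IRanges)
})

randomSeq <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                               collapse = "")

rc <- function(x) as.character(reverseComplement(DNAStringSet(x)))

## Tiny two-gene model on one chromosome, built from explicit exon/intron
## pieces so every coordinate is hand-checkable.
##   gPlus  (+): exon 1-100, intron 101-150 (GT..AG), exon 151-250
##   gMinus (-): exon 301-400, intron 401-450, exon 451-550
##               (transcription order: exon 451-550 first)
twoGeneModels <- function(seed = 11) {
  set.seed(seed)
  e1 <- randomSeq(100); i1 <- paste0("GT", randomSeq(46), "AG")
  e2 <- randomSeq(100)
  spacer <- randomSeq(50)
  e3 <- randomSeq(100); i2 <- paste0("GT", randomSeq(46), "AG")
  e4 <- randomSeq(100)
  # minus-strand gene: the sense sequence is e3-i2-e4, placed revcomp'd
  minusBlock <- rc(paste0(e3, i2, e4))
  chrom <- paste0(e1, i1, e2, spacer, minusBlock)
  genome <- DNAStringSet(setNames(chrom, "chr1"))
  exons <- GRangesList(
    "gPlus.1" = GRanges("chr1", IRanges(c(1, 151), c(100, 250)), strand = "+"),
    "gMinus.1" = GRanges("chr1", IRanges(c(451, 301), c(550, 400)),
                         strand = "-"))
  GeneModels(genome, exons, c("gPlus.1" = "gPlus", "gMinus.1" = "gMinus"))
}

## Single-isoform plus-strand gene with explicit exon/intron lengths,
## returning the models plus the intron intervals.
plusGene <- function(exonLens, intronLens, seed = 3, geneId = "g1") {
  set.seed(seed)
  stopifnot(length(exonLens) == length(intronLens) + 1L)
  exSeq <- vapply(exonLens, randomSeq, character(1))
  inSeq <- vapply(intronLens, function(l) paste0("GT", randomSeq(l - 4), "AG"),
                  character(1))
  parts <- character(0); exIv <- NULL; inIv <- NULL; pos <- 0L
  for (i in seq_along(exonLens)) {
    exIv <- rbind(exIv, c(pos + 1L, pos + exonLens[i]))
    parts <- c(parts, exSeq[i]); pos <- pos + exonLens[i]
    if (i <= length(intronLens)) {
      inIv <- rbind(inIv, c(pos + 1L, pos + intronLens[i]))
      parts <- c(parts, inSeq[i]); pos <- pos + intronLens[i]
    }
  }
  genome <- DNAStringSet(setNames(paste(parts, collapse = ""), "chr1"))
  iso <- paste0(geneId, ".1")
  exons <- GRangesList(GRanges("chr1", IRanges(exIv[, 1], exIv[, 2]),
                               strand = "+"))
  names(exons) <- iso
  list(models = GeneModels(genome, exons, setNames(geneId, iso)),
       exons = exIv, introns = inIv)
}

## ---- independent oracles -------------------------------------------------

## Brute-force single-gap spliced aligner: enumerates every split point p
## (amplicon prefix length) for the fixed gap length L - m, scores each
## reconstruction by Hamming distance, picks the minimum (leftmost on
## ties).  Returns the locus gap interval.
bruteSingleGap <- function(amplicon, locus) {
  m <- nchar(amplicon); L <- nchar(locus)
  gl <- L - m
  stopifnot(gl > 0)
  best <- NULL
  for (p in 0:m) {
    recon <- paste0(substr(locus, 1, p), substr(locus, p + gl + 1, L))
    d <- sum(utf8ToInt(recon) != utf8ToInt(amplicon))
    if (is.null(best) || d < best$d) best <- list(d = d, p = p)
  }
  c(best$p + 1L, best$p + gl)
}

## Brute-force boundary refinement: enumerate every shift of a gap that
## preserves the reconstructed amplicon exactly, return the leftmost
## canonical (GT..AG) placement, or the leftmost placement if none.
bruteRefine <- function(locus, gs, ge, lw, rw, strand = "+") {
  L <- nchar(locus)
  recon <- function(s) paste0(substr(locus, gs - lw, gs + s - 1),
                              substr(locus, ge + s + 1, ge + rw))
  ref <- paste0(substr(locus, gs - lw, gs - 1), substr(locus, ge + 1, ge + rw))
  shifts <- integer(0)
  for (s in -(lw - 1):(rw - 1)) {
    if (gs + s < 1 || ge + s > L) next
    ok <- if (s >= 0)
      substr(locus, gs, gs + s - 1) == substr(locus, ge + 1, ge + s)
    else
      substr(locus, gs + s, gs - 1) == substr(locus, ge + s + 1, ge)
    if (ok) shifts <- c(shifts, s)
  }
  canon <- function(s) {
    d <- substr(locus, gs + s, gs + s + 1)
    a <- substr(locus, ge + s - 1, ge + s)
    if (strand == "-") d == "CT" && a == "AC" else d == "GT" && a == "AG"
  }
  ok <- Filter(canon, shifts)
  s <- if (length(ok)) min(unlist(ok)) else min(shifts)
  list(shift = s, canonical = length(ok) > 0)
}

## Exhaustive tandem-repeat scanner: every period x every phase, direct
## copy counting.
bruteBestRepeat <- function(s, minPeriod, maxPeriod) {
  n <- nchar(s)
  best <- NULL
  for (p in minPeriod:maxPeriod) {
    for (i in 1:max(1, n - 2 * p + 1)) {
      if (i + 2 * p - 1 > n) break
      motif <- substr(s, i, i + p - 1)
      copies <- 1L
      while (i + (copies + 1) * p - 1 <= n &&
             substr(s, i + copies * p, i + (copies + 1) * p - 1) == motif)
        copies <- copies + 1L
      if (copies >= 2L &&
          (is.null(best) || copies > best$copies ||
           (copies == best$copies && p < best$period)))
        best <- list(motif = motif, copies = copies, period = p)
    }
  }
  best
}
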