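#' Default true-intron length law
#'
#' Discrete distribution over 59-500 bp peaked in the low 80s: a normal
#' bump (mean 85, sd 10) mixed with a uniform tail, mimicking the strongly
#' modal size distribution of small plant introns while keeping a long
#' tail.  59 bp is the smallest length a true intron is given -- the
#' smallest size experimentally verified introns reach.
#'
#' @param lengths integer support (default 59:500).
#' @param peakMean,peakSd,peakWeight mixture parameters.
#' @return list with \code{lengths} and \code{prob} (sums to 1).
#' @export
intronLengthLaw <- function(lengths = 59:500, peakMean = 85, peakSd = 10,
                            peakWeight = 0.8) {
  p <- peakWeight * stats::dnorm(lengths, peakMean, peakSd) +
    (1 - peakWeight) / length(lengths)
  list(lengths = as.integer(lengths), prob = p / sum(p))
}

sampleIntronLength <- function(n, law) {
  sample(law$lengths, n, replace = TRUE, prob = law$prob)
}

.SCENARIOS <- c("TRUE_SMALL_INTRON", "FALSE_MICROINTRON", "BOUNDARY_SHIFT",
                "EXTRA_INTRON", "PSEUDOGENE", "REPEAT_INDUCED")

.EXPECTED_CALL <- c(TRUE_SMALL_INTRON = "CDNA_CONFIRMED",
                    FALSE_MICROINTRON = "CDNA_NOT_AN_INTRON",
                    BOUNDARY_SHIFT = "CDNA_LARGER",
                    EXTRA_INTRON = "CDNA_CONFIRMED",
                    PSEUDOGENE = "GDNA_UNABLE_TO_JUDGE",
                    REPEAT_INDUCED = "CDNA_NOT_AN_INTRON")

#' Generate a synthetic genome with planted annotation errors
#'
#' Builds a toy chromosome of multi-exon genes whose annotation deviates
#' from the (known) truth according to a scenario mix:
#' \describe{
#'   \item{TRUE_SMALL_INTRON}{a genuine GT..AG intron of
#'     \code{candidateLength} bp; annotation correct (expected verdict:
#'     confirmed).}
#'   \item{FALSE_MICROINTRON}{an 8-30 bp interval inside a real exon is
#'     annotated as an intron; the transcript retains it (expected: not an
#'     intron).}
#'   \item{REPEAT_INDUCED}{as above, but the false microintron sits inside
#'     at least three copies of a short tandem motif (default CAACAG), the
#'     classic misprediction context (expected: not an intron, repeat
#'     flag).}
#'   \item{BOUNDARY_SHIFT}{the annotated interval lies strictly inside a
#'     larger true GT..AG intron (expected: larger than predicted, actual
#'     size = the true intron).}
#'   \item{EXTRA_INTRON}{the candidate is real but a second, unannotated
#'     intron is also spliced within the amplicon (expected: confirmed plus
#'     extra splicing).}
#'   \item{PSEUDOGENE}{expression 0; the only obtainable product is
#'     genomic (expected: unable to judge).}
#' }
#' True introns always start GT and end AG.  Background sequence is
#' i.i.d. uniform ACGT.  A single integer seed governs all randomness;
#' regenerating with the same seed and configuration reproduces identical
#' output.
#'
#' @param nGenes number of genes (>= 1).
#' @param scenarioMix named proportions over the scenario kinds (must sum
#'   to 1); genes are assigned round-robin by cumulative proportion so the
#'   realised mix is deterministic.
#' @param law true-intron length law (\code{\link{intronLengthLaw}}).
#' @param candidateLength length of planted true small introns (default
#'   59 bp).
#' @param nExons exons per gene (>= 3; first intron slot carries the
#'   candidate, remaining slots draw from \code{law}).
#' @param exonLenRange,spacerRange integer ranges for exon and intergenic
#'   spacer lengths.
#' @param repeatMotif motif used by REPEAT_INDUCED (default "CAACAG").
#' @param secondIsoformProb probability a gene gets a second isoform
#'   (first isoform minus its last exon), giving multi-isoform models.
#' @param seed integer seed.
#' @return list with \code{genome} (\code{DNAStringSet}), \code{models}
#'   (\code{\linkS4class{GeneModels}}, annotated structure, expression
#'   attached), \code{truth} (\code{data.frame}: one row per gene with
#'   kind, candidate id/intervals, true intervals, expected call,
#'   expression), \code{truthExons} (\code{GRangesList} of TRUE exon
#'   structures per primary isoform, transcription order), \code{config}.
#' @export
simulateGenome <- function(nGenes = 50,
                           scenarioMix = c(TRUE_SMALL_INTRON = 0.3,
                                           FALSE_MICROINTRON = 0.25,
                                           BOUNDARY_SHIFT = 0.15,
                                           EXTRA_INTRON = 0.1,
                                           PSEUDOGENE = 0.1,
                                           REPEAT_INDUCED = 0.1),
                           law = intronLengthLaw(),
                           candidateLength = 59L,
                           nExons = 3L,
                           exonLenRange = c(120L, 300L),
                           spacerRange = c(200L, 400L),
                           repeatMotif = "CAACAG",
                           secondIsoformProb = 0.25,
                           seed = 1L) {
  stopifnot(nGenes >= 1L, nExons >= 3L,
            all(names(scenarioMix) %in% .SCENARIOS),
            abs(sum(scenarioMix) - 1) < 1e-8,
            candidateLength >= 8L, nchar(repeatMotif) <= 10L)
  set.seed(seed)
  # deterministic scenario assignment by cumulative proportion
  kinds <- rep(names(scenarioMix),
               diff(round(cumsum(c(0, scenarioMix)) * nGenes)))
  if (length(kinds) < nGenes)
    kinds <- c(kinds, rep(names(scenarioMix)[1L], nGenes - length(kinds)))
  kinds <- kinds[seq_len(nGenes)]

  chromParts <- character(0)
  offset <- 0L
  annExons <- list(); truthExonsL <- list()
  txGene <- character(0)
  truthRows <- vector("list", nGenes)
  for (gi in seq_len(nGenes)) {
    gid <- sprintf("SYNG%04d", gi)
    iso <- paste0(gid, ".1")
    strand <- sample(c("+", "-"), 1L)
    spacer <- randomDna(sample(spacerRange[1L]:spacerRange[2L], 1L))
    g <- .buildGene(kinds[gi], law, candidateLength, nExons, exonLenRange,
                    repeatMotif)
    Lg <- nchar(g$seq)
    geneSeq <- if (strand == "-") revComp(g$seq) else g$seq
    geneOffset <- offset + nchar(spacer)
    toGenomic <- function(iv) {
      # iv: matrix/list of local sense intervals (1-based closed)
      if (strand == "+") cbind(geneOffset + iv[, 1L], geneOffset + iv[, 2L])
      else cbind(geneOffset + Lg - iv[, 2L] + 1L, geneOffset + Lg - iv[, 1L] + 1L)
    }
    annG <- toGenomic(g$annExons)
    truG <- toGenomic(g$truthExons)
    mkGr <- function(m) {
      gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(m[, 1L], m[, 2L]),
                                   strand = strand)
      gr[order(GenomicRanges::start(gr), decreasing = (strand == "-"))]
    }
    annExons[[iso]] <- mkGr(annG)
    truthExonsL[[iso]] <- mkGr(truG)
    txGene[iso] <- gid
    if (stats::runif(1) < secondIsoformProb && nrow(g$annExons) >= 4L) {
      iso2 <- paste0(gid, ".2")
      e2 <- annExons[[iso]]
      annExons[[iso2]] <- e2[-length(e2)]   # drop last exon (transcription order)
      txGene[iso2] <- gid
    }
    candG <- toGenomic(rbind(g$candAnn))
    trueG <- if (is.null(g$candTrue)) c(NA_integer_, NA_integer_)
             else toGenomic(rbind(g$candTrue))[1L, ]
    extraG <- if (is.null(g$extraIntron)) c(NA_integer_, NA_integer_)
              else toGenomic(rbind(g$extraIntron))[1L, ]
    expression <- if (kinds[gi] == "PSEUDOGENE") 0
                  else round(stats::rlnorm(1, meanlog = 3, sdlog = 0.6), 2)
    truthRows[[gi]] <- data.frame(
      gene_id = gid, isoform_id = iso, kind = kinds[gi], seq_id = "chr1",
      strand = strand,
      ann_start = candG[1L, 1L], ann_end = candG[1L, 2L],
      true_start = trueG[1L], true_end = trueG[2L],
      extra_start = extraG[1L], extra_end = extraG[2L],
      expected_call = unname(.EXPECTED_CALL[kinds[gi]]),
      expect_extra = kinds[gi] == "EXTRA_INTRON",
      expression = expression,
      stringsAsFactors = FALSE)
    chromParts <- c(chromParts, spacer, geneSeq)
    offset <- geneOffset + Lg
  }
  chromParts <- c(chromParts, randomDna(sample(spacerRange[1L]:spacerRange[2L], 1L)))
  genome <- Biostrings::DNAStringSet(paste(chromParts, collapse = ""))
  names(genome) <- "chr1"
  truth <- do.call(rbind, truthRows)
  models <- GeneModels(genome,
                       GenomicRanges::GRangesList(annExons),
                       txGene,
                       expression = setNames(truth$expression, truth$gene_id))
  # candidate intron IDs: match annotated candidate interval on isoform 1
  introns <- deriveIntrons(models)
  m <- S4Vectors::mcols(introns)
  key <- paste(m$isoform_id, GenomicRanges::start(introns),
               GenomicRanges::end(introns))
  truth$candidate_id <- m$intron_id[match(
    paste(truth$isoform_id, truth$ann_start, truth$ann_end), key)]
  structure(list(genome = genome, models = models, truth = truth,
                 truthExons = GenomicRanges::GRangesList(truthExonsL),
                 config = list(nGenes = nGenes, scenarioMix = scenarioMix,
                               candidateLength = candidateLength,
                               nExons = nExons, exonLenRange = exonLenRange,
                               seed = seed)),
            class = "syntheticAudit")
}

## Build one gene in local sense coordinates.  Returns the gene sequence,
## truth/annotated exon interval matrices (sense, 1-based closed), the
## annotated candidate interval, the true candidate interval (or NULL) and
## any unannotated extra intron interval.
.buildGene <- function(kind, law, candidateLength, nExons, exonLenRange,
                       repeatMotif) {
  exLens <- sample(exonLenRange[1L]:exonLenRange[2L], nExons, replace = TRUE)
  nInt <- nExons - 1L
  intLens <- sampleIntronLength(nInt, law)
  mkIntron <- function(len) paste0("GT", randomDna(len - 4L), "AG")
  exSeq <- vapply(exLens, randomDna, character(1))
  if (kind %in% c("TRUE_SMALL_INTRON", "PSEUDOGENE", "EXTRA_INTRON"))
    intLens[1L] <- as.integer(candidateLength)
  intSeq <- vapply(intLens, mkIntron, character(1))

  microLen <- sample(8:30, 1L)
  if (kind %in% c("FALSE_MICROINTRON", "REPEAT_INDUCED")) {
    # plant the fake microintron inside exon 2
    e2 <- exSeq[2L]
    if (kind == "REPEAT_INDUCED") {
      tract <- strrep(repeatMotif, 4L)
      microLen <- 2L * nchar(repeatMotif)      # two motif copies annotated
      at <- sample(40:(nchar(e2) - 40L - nchar(tract)), 1L)
      e2 <- paste0(substr(e2, 1L, at - 1L), tract,
                   substr(e2, at + nchar(tract), nchar(e2)))
      microAt <- at + nchar(repeatMotif)       # second copy onward
    } else {
      microAt <- sample(40:(nchar(e2) - 40L - microLen), 1L)
      # make the fake intron look splice-like: GT..AG written into the exon
      substr(e2, microAt, microAt + 1L) <- "GT"
      substr(e2, microAt + microLen - 2L, microAt + microLen - 1L) <- "AG"
    }
    exSeq[2L] <- e2
    microIv <- c(microAt, microAt + microLen - 1L)   # local to exon 2
  }
  if (kind == "BOUNDARY_SHIFT") {
    # annotated interval strictly inside true intron 1
    intLens[1L] <- max(intLens[1L], microLen + 10L)
    intSeq[1L] <- mkIntron(intLens[1L])
    off <- sample(2:(intLens[1L] - microLen), 1L)    # 1 < off, end < |I1|
    microIv <- c(off, off + microLen - 1L)           # local to intron 1
  }
  extraIv <- NULL
  if (kind == "EXTRA_INTRON") {
    exLen <- min(sampleIntronLength(1L, law), 150L)
    exIntron <- mkIntron(exLen)
    e2 <- exSeq[2L]
    at <- sample(40:(nchar(e2) - 40L), 1L)
    exSeq[2L] <- paste0(substr(e2, 1L, at - 1L), exIntron,
                        substr(e2, at, nchar(e2)))
    extraLocal <- c(at, at + exLen - 1L)             # local to (new) exon 2
  }

  # assemble truth sequence: E1 I1 E2 I2 ... En
  parts <- character(0)
  truthEx <- matrix(0L, nExons, 2L)
  truthInt <- matrix(0L, nInt, 2L)
  pos <- 0L
  for (i in seq_len(nExons)) {
    truthEx[i, ] <- c(pos + 1L, pos + nchar(exSeq[i]))
    parts <- c(parts, exSeq[i]); pos <- pos + nchar(exSeq[i])
    if (i <= nInt) {
      truthInt[i, ] <- c(pos + 1L, pos + nchar(intSeq[i]))
      parts <- c(parts, intSeq[i]); pos <- pos + nchar(intSeq[i])
    }
  }
  seq <- paste(parts, collapse = "")

  annEx <- truthEx; candTrue <- NULL
  if (kind %in% c("TRUE_SMALL_INTRON", "PSEUDOGENE")) {
    candAnn <- truthInt[1L, ]
    candTrue <- if (kind == "TRUE_SMALL_INTRON") truthInt[1L, ] else NULL
  } else if (kind == "EXTRA_INTRON") {
    candAnn <- truthInt[1L, ]
    candTrue <- truthInt[1L, ]
    # truth exon 2 is split by the extra intron; annotation keeps it whole
    e2s <- truthEx[2L, 1L]
    extraIv <- c(e2s + extraLocal[1L] - 1L, e2s + extraLocal[2L] - 1L)
    truthEx <- rbind(truthEx[1L, ],
                     c(e2s, extraIv[1L] - 1L),
                     c(extraIv[2L] + 1L, truthEx[2L, 2L]),
                     truthEx[-(1:2), , drop = FALSE])
  } else if (kind %in% c("FALSE_MICROINTRON", "REPEAT_INDUCED")) {
    e2s <- truthEx[2L, 1L]
    candAnn <- c(e2s + microIv[1L] - 1L, e2s + microIv[2L] - 1L)
    # annotation splits exon 2 around the fake microintron
    annEx <- rbind(annEx[1L, ],
                   c(e2s, candAnn[1L] - 1L),
                   c(candAnn[2L] + 1L, annEx[2L, 2L]),
                   annEx[-(1:2), , drop = FALSE])
  } else if (kind == "BOUNDARY_SHIFT") {
    i1 <- truthInt[1L, ]
    candAnn <- c(i1[1L] + microIv[1L] - 1L, i1[1L] + microIv[2L] - 1L)
    candTrue <- i1
    # annotation absorbs the flanks of the true intron into the exons
    annEx[1L, 2L] <- candAnn[1L] - 1L
    annEx[2L, 1L] <- candAnn[2L] + 1L
  }
  list(seq = seq, truthExons = truthEx, annExons = annEx,
       candAnn = candAnn, candTrue = candTrue, extraIntron = extraIv)
}

#' Mature transcript (cDNA) sequence from a truth exon structure
#'
#' Concatenates the exon sequences in transcription order,
#' reverse-complementing minus-strand exons: the spliced product with all
#' true introns removed.
#'
#' @param exons \code{GRanges} in transcription order (one isoform).
#' @param genome \code{DNAStringSet}.
#' @return character scalar cDNA sequence (5' to 3' of the transcript).
#' @export
transcribe <- function(exons, genome) {
  sq <- as.character(GenomicRanges::seqnames(exons))[1L]
  strand <- as.character(GenomicRanges::strand(exons))[1L]
  pieces <- vapply(seq_along(exons), function(i) {
    s <- genomeSub(genome, sq, GenomicRanges::start(exons)[i],
                   GenomicRanges::end(exons)[i])
    if (strand == "-") revComp(s) else s
  }, character(1))
  paste(pieces, collapse = "")
}

#' Simulate sequenced amplicons for a primer panel
#'
#' Expressed genes yield the in-silico PCR product of the true (spliced)
#' cDNA; expression-0 genes (pseudogenes) yield the genomic product.
#' Substitution errors are injected per base at \code{errorRate}.  FASTA
#' names follow \code{<candidateID>|<replicate> kind=<scenario>} so tests
#' can assert against the hidden truth.
#'
#' @param report primer report (\code{\link{primerReport}}).
#' @param sim result of \code{\link{simulateGenome}}.
#' @param errorRate per-base substitution probability (default 0).
#' @param seed integer seed.
#' @return \code{DNAStringSet} of amplicons; rows for which neither
#'   template yields a product are recorded in the \code{"no_product"}
#'   attribute (a character vector of candidate IDs), not errors.
#' @export
simulateAmplicons <- function(report, sim, errorRate = 0, seed = 1L) {
  set.seed(seed)
  ok <- report[report$status == "OK", , drop = FALSE]
  seqs <- character(0); noProduct <- character(0)
  for (i in seq_len(nrow(ok))) {
    row <- ok[i, , drop = FALSE]
    tr <- sim$truth[sim$truth$gene_id == row$gene_id, , drop = FALSE][1L, ]
    template <- if (tr$expression > 0)
      transcribe(sim$truthExons[[tr$isoform_id]], sim$genome)
    else {
      seqLen <- Biostrings::width(sim$genome)[match(row$seq_id, names(sim$genome))]
      genomeSub(sim$genome, row$seq_id,
                max(1L, row$amplicon_start - 50L),
                min(seqLen, row$amplicon_end + 50L))
    }
    prod <- inSilicoPcr(template,
                        list(forwardSeq = row$forward_seq,
                             reverseSeq = row$reverse_seq))
    if (nrow(prod) == 0L) { noProduct <- c(noProduct, row$candidate_id); next }
    s <- prod$product[1L]
    if (errorRate > 0) s <- .injectSubstitutions(s, errorRate)
    seqs[sprintf("%s|1 kind=%s", row$candidate_id, tr$kind)] <- s
  }
  out <- Biostrings::DNAStringSet(seqs)
  attr(out, "no_product") <- noProduct
  out
}

.injectSubstitutions <- function(s, rate) {
  v <- strsplit(s, "")[[1L]]
  hit <- which(stats::runif(length(v)) < rate)
  for (i in hit) {
    v[i] <- sample(setdiff(c("A", "C", "G", "T"), v[i]), 1L)
  }
  paste(v, collapse = "")
}

#' Write synthetic data to standard files
#'
#' @param sim result of \code{\link{simulateGenome}}.
#' @param dir output directory (created if needed); writes
#'   \code{genome.fa}, \code{annotation.gff3}, \code{truth.tsv} and
#'   \code{expression.tsv}.
#' @return \code{dir}, invisibly.
#' @export
writeSyntheticData <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Biostrings::writeXStringSet(sim$genome, file.path(dir, "genome.fa"))
  writeAnnotation(sim$models, file.path(dir, "annotation.gff3"))
  write.table(sim$truth, file.path(dir, "truth.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(data.frame(gene_id = sim$truth$gene_id,
                         score = sim$truth$expression),
              file.path(dir, "expression.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(dir)
}

#' Synthetic screening panel with known exclusion structure
#'
#' Builds gene models for a screening-arithmetic exercise: \code{nRetained}
#' genes whose microintron candidate is screenable, \code{nSoleIntron}
#' genes where the candidate is the gene's only intron (no co-amplifiable
#' control: excluded), and \code{nNoPrimerSite} genes whose exons are too
#' short to host primers (excluded).
#'
#' @param nRetained,nSoleIntron,nNoPrimerSite panel composition (defaults
#'   48/16/7, i.e. a 71-candidate panel).
#' @param seed integer seed.
#' @return list with \code{models} (\code{GeneModels}) and
#'   \code{candidates} (screened candidate data.frame, exclusions applied).
#' @export
simulateScreeningPanel <- function(nRetained = 48L, nSoleIntron = 16L,
                                   nNoPrimerSite = 7L, seed = 1L) {
  set.seed(seed)
  parts <- character(0); offset <- 0L
  exons <- list(); txGene <- character(0)
  addGene <- function(gid, exLens, intLens) {
    exSeq <- vapply(exLens, randomDna, character(1))
    intSeq <- vapply(intLens, function(l) paste0("GT", randomDna(l - 4L), "AG"),
                     character(1))
    seq <- exSeq[1L]
    iv <- matrix(c(1L, exLens[1L]), 1L)
    pos <- exLens[1L]
    for (i in seq_along(intLens)) {
      seq <- paste0(seq, intSeq[i], exSeq[i + 1L])
      iv <- rbind(iv, c(pos + intLens[i] + 1L, pos + intLens[i] + exLens[i + 1L]))
      pos <- pos + intLens[i] + exLens[i + 1L]
    }
    spacer <- randomDna(50L)
    iso <- paste0(gid, ".1")
    exons[[iso]] <<- GenomicRanges::GRanges("chr1",
      IRanges::IRanges(offset + nchar(spacer) + iv[, 1L],
                       offset + nchar(spacer) + iv[, 2L]), strand = "+")
    txGene[iso] <<- gid
    parts <<- c(parts, spacer, seq)
    offset <<- offset + nchar(spacer) + nchar(seq)
  }
  for (i in seq_len(nRetained))
    addGene(sprintf("RET%03d", i), c(200L, 200L, 200L), c(20L, 80L))
  for (i in seq_len(nSoleIntron))
    addGene(sprintf("SOLE%03d", i), c(200L, 200L), 20L)
  for (i in seq_len(nNoPrimerSite))
    addGene(sprintf("NOPR%03d", i), c(10L, 10L, 10L), c(20L, 80L))
  genome <- Biostrings::DNAStringSet(setNames(paste(parts, collapse = ""), "chr1"))
  models <- GeneModels(genome, GenomicRanges::GRangesList(exons), txGene)
  cands <- selectCandidates(deriveIntrons(models), maxLen = 30L)
  cands <- applyExclusions(cands, models)
  list(models = models, candidates = cands)
}
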