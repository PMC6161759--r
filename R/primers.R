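#' Wallace-rule melting temperature
#'
#' Tm = 2(A+T) + 4(G+C) in degrees C; the classic rule of thumb for short
#' oligos.
#'
#' @param seq character vector of ACGT primer sequences.
#' @return numeric vector of melting temperatures.
#' @examples
#' meltingTemperature("ACGT")  # 12
#' @export
meltingTemperature <- function(seq) {
  if (any(nchar(seq) == 0L)) stop("empty primer sequence")
  if (any(grepl("[^ACGT]", seq))) stop("primer sequence must be ACGT only")
  vapply(seq, function(s) {
    v <- strsplit(s, "")[[1L]]
    2 * sum(v %in% c("A", "T")) + 4 * sum(v %in% c("G", "C"))
  }, numeric(1), USE.NAMES = FALSE)
}

gcPercent <- function(seq) {
  vapply(seq, function(s) {
    v <- strsplit(s, "")[[1L]]
    100 * sum(v %in% c("G", "C")) / length(v)
  }, numeric(1), USE.NAMES = FALSE)
}

#' Primer design constraints
#'
#' Conventional Sanger-friendly defaults: primer length 18-25 nt, Wallace
#' Tm 50-65 degrees C, GC 40-60 percent, pair Tm difference at most 5, and
#' a spliced (cDNA) product of 120-1000 bp.
#'
#' @param primerLen integer length-2, min/max primer length.
#' @param tmRange numeric length-2, acceptable Tm window (degrees C).
#' @param gcRange numeric length-2, acceptable GC percentage window.
#' @param maxTmDiff max |Tm(F) - Tm(R)|.
#' @param cdnaLenRange integer length-2, acceptable spliced product length.
#' @return named list of constraints.
#' @export
primerConstraints <- function(primerLen = c(18L, 25L),
                              tmRange = c(50, 65),
                              gcRange = c(40, 60),
                              maxTmDiff = 5,
                              cdnaLenRange = c(120L, 1000L)) {
  list(primerLen = as.integer(primerLen), tmRange = tmRange,
       gcRange = gcRange, maxTmDiff = maxTmDiff,
       cdnaLenRange = as.integer(cdnaLenRange))
}

## >=4 bp perfect 3' dimer between (or within) primers -> reject.
has3primeDimer <- function(a, b, k = 4L) {
  tail4 <- function(s) substr(s, nchar(s) - k + 1L, nchar(s))
  pairs <- list(c(a, a), c(a, b), c(b, b))
  any(vapply(pairs, function(p) tail4(p[1L]) == revComp(tail4(p[2L])),
             logical(1)))
}

windowOk <- function(seq, cons) {
  !grepl("[^ACGT]", seq) &&
    meltingTemperature(seq) >= cons$tmRange[1L] &&
    meltingTemperature(seq) <= cons$tmRange[2L] &&
    gcPercent(seq) >= cons$gcRange[1L] &&
    gcPercent(seq) <= cons$gcRange[2L]
}

#' Design an RT-PCR primer pair spanning candidate plus control intron
#'
#' Implements the two-intron amplicon principle: the product must contain
#' the candidate intron and at least one other (control) intron of the same
#' isoform, so that a spliced control proves cDNA origin while the
#' candidate's own presence/absence is read out.  The control intron is the
#' annotated intron adjacent to the candidate, downstream in transcript
#' orientation when one exists, otherwise upstream (so a first intron gets
#' a downstream control and a last intron an upstream one).
#'
#' The scan is deterministic: forward windows 5' to 3' through the exon
#' upstream of the earliest spanned intron, reverse windows 3' to 5'
#' through the exon downstream of the last spanned intron, longer primers
#' tried only after shorter ones fail at a given position; the first pair
#' meeting all constraints wins.
#'
#' @param models \code{\linkS4class{GeneModels}}.
#' @param candidate one-row candidate data.frame
#'   (\code{\link{selectCandidates}} row) or a candidate ID present in
#'   \code{deriveIntrons(models)}.
#' @param constraints see \code{\link{primerConstraints}}.
#' @return A \code{\linkS4class{PrimerPair}} on success; otherwise the
#'   character failure reason \code{"NO_CONTROL_INTRON"} or
#'   \code{"NO_PRIMER_SITE"}.
#' @export
designPrimers <- function(models, candidate,
                          constraints = primerConstraints()) {
  if (is.character(candidate)) {
    all <- selectCandidates(deriveIntrons(models), maxLen = .Machine$integer.max)
    row <- all[all$candidate_id == candidate, , drop = FALSE]
    if (nrow(row) == 0L) stop("unknown candidate: ", candidate)
    candidate <- row
  }
  iso <- candidate$isoform_id
  ex <- exonsByIsoform(models)
  if (!iso %in% names(ex)) stop("candidate isoform not in models: ", iso)
  # isoforms of the gene that carry the candidate interval as an intron and
  # offer at least one other intron; the candidate's own isoform first
  gene <- candidate$gene_id
  geneIsos <- names(ex)[unname(txToGene(models))[match(names(ex), isoformIds(models))] == gene]
  geneIsos <- unique(c(iso, geneIsos))
  anyControl <- FALSE
  for (curIso in geneIsos) {
    introns <- deriveIntrons(models, curIso)
    hit <- which(GenomicRanges::start(introns) == candidate$start &
                 GenomicRanges::end(introns) == candidate$end)
    if (length(hit) != 1L || length(introns) < 2L) next
    anyControl <- TRUE
    ord <- S4Vectors::mcols(introns)$ordinal[hit]
    n <- length(ex[[curIso]])
    ctrlChoices <- c(if (ord + 1L <= n - 1L) ord + 1L,
                     if (ord - 1L >= 1L) ord - 1L)
    candHere <- candidate
    candHere$isoform_id <- curIso
    candHere$ordinal <- ord
    candHere$candidate_id <- candidate$candidate_id
    for (ctrl in ctrlChoices) {
      res <- .designForSpan(models, curIso, candHere, sort(c(ord, ctrl)),
                            constraints)
      if (methods::is(res, "PrimerPair")) return(res)
    }
  }
  if (!anyControl) "NO_CONTROL_INTRON" else "NO_PRIMER_SITE"
}

## Scan primer windows for a span of intron ordinals (transcription order).
.designForSpan <- function(models, iso, candidate, span, cons) {
  ex <- exonsByIsoform(models)[[iso]]
  n <- length(ex)
  strand <- as.character(GenomicRanges::strand(ex))[1L]
  sq <- as.character(GenomicRanges::seqnames(ex))[1L]
  gen <- genomeSeq(models)
  # oriented exon sequences (transcript 5'->3') + their genomic intervals
  exSeq <- vapply(seq_len(n), function(i) {
    s <- genomeSub(gen, sq, GenomicRanges::start(ex)[i],
                   GenomicRanges::end(ex)[i])
    if (strand == "-") revComp(s) else s
  }, character(1))
  introns <- deriveIntrons(models, iso)
  intronW <- GenomicRanges::width(introns)
  fwdExon <- span[1L]            # exon upstream of earliest spanned intron
  revExon <- span[length(span)] + 1L  # exon downstream of last spanned intron
  fseq <- exSeq[fwdExon]; rseq <- exSeq[revExon]
  lens <- cons$primerLen[1L]:cons$primerLen[2L]
  # cDNA distance from a forward-primer start (offset in fwd exon, 1-based)
  # to a reverse-primer end (offset from the 3' end of rev exon)
  innerExonLen <- if (revExon - fwdExon > 1L)
    sum(nchar(exSeq[(fwdExon + 1L):(revExon - 1L)])) else 0L
  for (fs in seq_len(max(0L, nchar(fseq) - cons$primerLen[1L] + 1L))) {
    fhit <- NULL
    for (w in lens) {
      if (fs + w - 1L > nchar(fseq)) break
      cand <- substr(fseq, fs, fs + w - 1L)
      if (windowOk(cand, cons)) { fhit <- cand; break }
    }
    if (is.null(fhit)) next
    fTm <- meltingTemperature(fhit)
    # product-length constraint bounds the reverse-primer end position
    upstreamLen <- (nchar(fseq) - fs + 1L) + innerExonLen
    reLo <- max(cons$primerLen[1L], cons$cdnaLenRange[1L] - upstreamLen)
    reHi <- min(nchar(rseq), cons$cdnaLenRange[2L] - upstreamLen)
    if (reLo > nchar(rseq)) break   # product can only shrink as fs advances
    if (reHi < reLo) next
    for (re in seq(reHi, reLo)) {   # 3'->5': latest end first
      rhit <- NULL
      for (w in lens) {
        if (re - w + 1L < 1L) break
        win <- substr(rseq, re - w + 1L, re)
        if (windowOk(win, cons)) { rhit <- win; break }
      }
      if (is.null(rhit)) next
      rTm <- meltingTemperature(rhit)
      if (abs(fTm - rTm) > cons$maxTmDiff) next
      cdnaLen <- (nchar(fseq) - fs + 1L) + innerExonLen + re
      if (cdnaLen < cons$cdnaLenRange[1L] || cdnaLen > cons$cdnaLenRange[2L])
        next
      rprimer <- revComp(rhit)
      if (has3primeDimer(fhit, rprimer)) next
      return(.makePrimerPair(models, iso, candidate, span, fwdExon, revExon,
                             fs, nchar(fhit), re, nchar(rhit),
                             fhit, rprimer, fTm, rTm, cdnaLen, introns))
    }
  }
  "NO_PRIMER_SITE"
}

.makePrimerPair <- function(models, iso, candidate, span, fwdExon, revExon,
                            fs, fw, re, rw, fseqP, rseqP, fTm, rTm,
                            cdnaLen, introns) {
  ex <- exonsByIsoform(models)[[iso]]
  strand <- as.character(GenomicRanges::strand(ex))[1L]
  sq <- as.character(GenomicRanges::seqnames(ex))[1L]
  fEx <- ex[fwdExon]; rEx <- ex[revExon]
  if (strand == "+") {
    fGstart <- GenomicRanges::start(fEx) + fs - 1L
    rGend <- GenomicRanges::start(rEx) + re - 1L
    rGstart <- rGend - rw + 1L
    ampStart <- fGstart; ampEnd <- rGend
  } else {
    # oriented offset fs from the exon's 3'-most genomic end
    fGend <- GenomicRanges::end(fEx) - fs + 1L
    fGstart <- fGend - fw + 1L
    rGstart <- GenomicRanges::end(rEx) - re + 1L
    ampStart <- rGstart; ampEnd <- fGend
  }
  spannedIds <- S4Vectors::mcols(introns)$intron_id[span]
  ctrl <- setdiff(spannedIds, candidate$candidate_id)
  new("PrimerPair",
      candidateId = candidate$candidate_id, isoformId = iso,
      seqId = sq, strand = strand,
      forwardSeq = fseqP, reverseSeq = rseqP,
      forwardStart = as.integer(fGstart), reverseStart = as.integer(rGstart),
      tmForward = fTm, tmReverse = rTm,
      ampliconStart = as.integer(ampStart), ampliconEnd = as.integer(ampEnd),
      cdnaLength = as.integer(cdnaLen),
      controlIntrons = ctrl)
}

#' In-silico PCR
#'
#' Finds every product where the two primers bind the template in
#' convergent orientation with at most \code{maxMismatch} substitutions
#' each.  Both primer-to-strand assignments are scanned (forward primer on
#' the given strand with the reverse primer downstream, and the
#' mirror-image arrangement); duplicates are removed.
#'
#' @param template character or \code{DNAString}, the template sequence.
#' @param pair \code{\linkS4class{PrimerPair}} (or list with
#'   \code{forwardSeq}/\code{reverseSeq}).
#' @param maxMismatch substitutions tolerated per primer (default 0).
#' @param maxProductLen longest product reported (default 5000).
#' @return \code{data.frame} with \code{start}, \code{end} (template
#'   coordinates, 1-based closed), \code{length}, \code{orientation}
#'   (\code{"+"} if the forward primer lies on the given strand), and
#'   \code{product} (sequence written 5'->3' starting with the forward
#'   primer).
#' @export
inSilicoPcr <- function(template, pair, maxMismatch = 0L,
                        maxProductLen = 5000L) {
  template <- toupper(as.character(template))
  if (nchar(template) == 0L) stop("empty template")
  fwd <- if (methods::is(pair, "PrimerPair")) pair@forwardSeq else pair$forwardSeq
  rev <- if (methods::is(pair, "PrimerPair")) pair@reverseSeq else pair$reverseSeq
  hits <- list()
  scan <- function(p1, p2, orientation) {
    # p1 binds the + strand of `template`; p2 binds - strand downstream
    s1 <- mismatchScan(template, p1, maxMismatch)
    s2 <- mismatchScan(template, revComp(p2), maxMismatch)
    for (a in s1) for (b in s2) {
      end <- b + nchar(p2) - 1L
      if (b >= a && end - a + 1L <= maxProductLen &&
          end - a + 1L >= nchar(p1) + nchar(p2) - 1L) {
        prod <- substr(template, a, end)
        if (orientation == "-") prod <- revComp(prod)
        hits[[length(hits) + 1L]] <<- data.frame(
          start = a, end = end, length = end - a + 1L,
          orientation = orientation, product = prod,
          stringsAsFactors = FALSE)
      }
    }
  }
  scan(fwd, rev, "+")
  scan(rev, fwd, "-")
  if (!length(hits))
    return(data.frame(start = integer(0), end = integer(0),
                      length = integer(0), orientation = character(0),
                      product = character(0)))
  res <- do.call(rbind, hits)
  res <- res[!duplicated(res[, c("start", "end")]), , drop = FALSE]
  res[order(res$start, res$end), , drop = FALSE] |> `rownames<-`(NULL)
}

#' Build / write a primer report table
#'
#' One row per candidate: design outcome, primer sequences, Tm values,
#' genomic and cDNA product sizes and the control intron IDs.  Both
#' product sizes are the discrimination signal: their difference equals
#' the summed spanned intron lengths.
#'
#' @param models \code{GeneModels}.
#' @param candidates screened candidate data.frame; rows with exclusion
#'   other than \code{NONE} are reported with empty primer fields.
#' @param constraints see \code{\link{primerConstraints}}.
#' @return \code{data.frame} primer report.
#' @export
primerReport <- function(models, candidates,
                         constraints = primerConstraints()) {
  rows <- vector("list", nrow(candidates))
  for (i in seq_len(nrow(candidates))) {
    cand <- candidates[i, , drop = FALSE]
    base <- data.frame(candidate_id = cand$candidate_id,
                       gene_id = cand$gene_id, isoform_id = cand$isoform_id,
                       seq_id = cand$seq_id, strand = cand$strand,
                       predicted_size = cand$length,
                       candidate_start = cand$start, candidate_end = cand$end,
                       stringsAsFactors = FALSE)
    if (cand$exclusion != "NONE") {
      rows[[i]] <- cbind(base, .emptyPrimerCols(cand$exclusion))
      next
    }
    res <- designPrimers(models, cand, constraints)
    if (!methods::is(res, "PrimerPair")) {
      rows[[i]] <- cbind(base, .emptyPrimerCols(res))
      next
    }
    rows[[i]] <- cbind(base, data.frame(
      status = "OK", forward_seq = res@forwardSeq, reverse_seq = res@reverseSeq,
      tm_forward = res@tmForward, tm_reverse = res@tmReverse,
      amplicon_start = res@ampliconStart, amplicon_end = res@ampliconEnd,
      genomic_len = res@ampliconEnd - res@ampliconStart + 1L,
      cdna_len = res@cdnaLength,
      control_introns = paste(res@controlIntrons, collapse = ","),
      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

.emptyPrimerCols <- function(status) {
  data.frame(status = status, forward_seq = "", reverse_seq = "",
             tm_forward = NA_real_, tm_reverse = NA_real_,
             amplicon_start = NA_integer_, amplicon_end = NA_integer_,
             genomic_len = NA_integer_, cdna_len = NA_integer_,
             control_introns = "", stringsAsFactors = FALSE)
}

#' @rdname primerReport
#' @param report a primer report.
#' @param path output TSV.
#' @export
writePrimerReport <- function(report, path) {
  write.table(report, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname primerReport
#' @export
readPrimerReport <- function(path) {
  read.delim(path, stringsAsFactors = FALSE,
             colClasses = c(control_introns = "character",
                            forward_seq = "character",
                            reverse_seq = "character"))
}
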