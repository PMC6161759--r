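#' Classify an amplicon as cDNA or genomic and re-annotate the candidate
#'
#' Decision tree over the spliced alignment (boundary-refined first, so the
#' result is invariant to sequence-preserving gap shifts):
#' \enumerate{
#'   \item no splice gap at all: the product is indistinguishable from
#'     genomic DNA -- \code{GDNA_UNABLE_TO_JUDGE};
#'   \item splice gaps present but none overlapping the candidate interval:
#'     the candidate is retained in the mature transcript --
#'     \code{CDNA_NOT_AN_INTRON};
#'   \item a gap overlapping the candidate: equal to the predicted interval
#'     gives \code{CDNA_CONFIRMED}; a larger (or smaller) gap gives
#'     \code{CDNA_LARGER} (\code{CDNA_SMALLER}) with the gap as the
#'     re-annotated intron;
#'   \item gaps matching no annotated intron and not overlapping the
#'     candidate are reported as extra splicing.
#' }
#'
#' @param alignment \code{\linkS4class{SplicedAlignment}} of the amplicon
#'   against the locus containing the candidate.
#' @param locus the locus sequence (needed for boundary refinement).
#' @param candidate one-row candidate data.frame with \code{candidate_id},
#'   \code{start}, \code{end}, \code{length}, \code{strand} (genomic,
#'   forward-strand coordinates).
#' @param introns \code{GRanges} of the isoform's annotated introns
#'   (genomic coordinates), used to recognise annotated splicing.
#' @param locusStart genomic coordinate of locus position 1.
#' @param amplicon optional amplicon sequence (the orientation the
#'   alignment used), passed to \code{\link{refineBoundaries}}.
#' @return An \code{\linkS4class{AmpliconVerdict}}.
#' @export
classifyAmplicon <- function(alignment, locus, candidate, introns,
                             locusStart = 1L, amplicon = NULL) {
  strand <- if ("strand" %in% names(candidate)) candidate$strand else "+"
  alignment <- refineBoundaries(alignment, locus, strand, amplicon = amplicon)
  blocks <- alignment@blocks
  span <- c(locusStart + min(blocks$gStart) - 1L,
            locusStart + max(blocks$gEnd) - 1L)
  if (span[1L] > candidate$start || span[2L] < candidate$end)
    stop("COVERAGE: amplicon alignment does not span the candidate interval")
  gaps <- alignment@gaps
  canon <- S4Vectors::mcols(gaps)$canonical
  gapsG <- IRanges::shift(gaps, locusStart - 1L)  # genomic coordinates
  candR <- IRanges::IRanges(candidate$start, candidate$end)
  mkVerdict <- function(call, actual = NULL, canonical = NA, extraIdx = integer(0)) {
    new("AmpliconVerdict",
        candidateId = candidate$candidate_id,
        call = call,
        predictedLength = as.integer(candidate$length),
        actualStart = if (is.null(actual)) NA_integer_ else IRanges::start(actual),
        actualEnd = if (is.null(actual)) NA_integer_ else IRanges::end(actual),
        actualLength = if (is.null(actual)) NA_integer_ else IRanges::width(actual),
        canonical = as.logical(canonical),
        extraSplicing = if (length(extraIdx)) gapsG[extraIdx]
          else IRanges::IRanges(),
        mismatches = alignment@mismatches)
  }
  if (!length(gaps)) return(mkVerdict("GDNA_UNABLE_TO_JUDGE"))
  ov <- IRanges::overlapsAny(gapsG, candR)
  annotated <- if (length(introns))
    paste(GenomicRanges::start(introns), GenomicRanges::end(introns))
  else character(0)
  isAnnot <- paste(IRanges::start(gapsG), IRanges::end(gapsG)) %in% annotated
  extraIdx <- which(!ov & !isAnnot)
  if (!any(ov)) return(mkVerdict("CDNA_NOT_AN_INTRON", extraIdx = extraIdx))
  ci <- which(ov)
  if (length(ci) > 1L)   # widest overlap wins (multiple gaps touching: rare)
    ci <- ci[which.max(IRanges::width(IRanges::pintersect(
      gapsG[ci], rep(candR, length(ci)))))]
  gap <- gapsG[ci]
  call <- if (IRanges::start(gap) == candidate$start &&
              IRanges::end(gap) == candidate$end) "CDNA_CONFIRMED"
          else if (IRanges::width(gap) > candidate$length) "CDNA_LARGER"
          else if (IRanges::width(gap) < candidate$length) "CDNA_SMALLER"
          else "CDNA_LARGER"   # equal length, shifted interval: re-annotated
  mkVerdict(call, actual = gap, canonical = canon[ci], extraIdx = extraIdx)
}

#' Verify a panel of sequenced amplicons
#'
#' Batch driver: aligns every amplicon to its candidate's locus (both
#' orientations tried; the alignment with more matched bases wins, exact
#' ties keep the forward strand), classifies it, and returns one verdict
#' row per amplicon.
#'
#' @param amplicons \code{DNAStringSet} or FASTA path; names follow
#'   \code{<candidateID>|<replicate>} (anything after whitespace ignored).
#' @param report primer report (\code{\link{primerReport}}) covering every
#'   candidate named in \code{amplicons}.
#' @param models \code{\linkS4class{GeneModels}}.
#' @param minSpliceGap,edgeTrim,k passed to \code{\link{splicedAlign}}.
#' @param locusMargin extra genomic bases taken on each side of the
#'   amplicon interval when extracting the locus (default 25).
#' @return \code{data.frame} with one row per amplicon: candidate ID,
#'   replicate, call, predicted and actual sizes, canonical flag, extra
#'   splicing (\code{"start-end"} strings, \code{;}-separated) and
#'   mismatch count.  The \code{AmpliconVerdict} objects are attached as
#'   the \code{"verdicts"} attribute.
#' @export
verifyPanel <- function(amplicons, report, models,
                        minSpliceGap = 8L, edgeTrim = 5L, k = 15L,
                        locusMargin = 25L) {
  if (is.character(amplicons) && length(amplicons) == 1L &&
      file.exists(amplicons))
    amplicons <- Biostrings::readDNAStringSet(amplicons)
  empty <- data.frame(candidate_id = character(0), replicate = character(0),
                      call = character(0), predicted_size = integer(0),
                      actual_size = integer(0), actual_start = integer(0),
                      actual_end = integer(0), canonical = logical(0),
                      extra_splicing = character(0), mismatches = integer(0))
  if (length(amplicons) == 0L) return(empty)
  hdr <- vapply(strsplit(names(amplicons), "\\s+"), `[`, character(1), 1L)
  parts <- strsplit(hdr, "|", fixed = TRUE)
  candIds <- vapply(parts, `[`, character(1), 1L)
  reps <- vapply(parts, function(p) if (length(p) >= 2L) p[2L] else "1",
                 character(1))
  unknown <- setdiff(candIds, report$candidate_id)
  if (length(unknown))
    stop("amplicon names unknown candidate(s): ",
         paste(unique(unknown), collapse = ", "))
  gen <- genomeSeq(models)
  rows <- vector("list", length(amplicons))
  verdicts <- vector("list", length(amplicons))
  for (i in seq_along(amplicons)) {
    row <- report[report$candidate_id == candIds[i], , drop = FALSE][1L, ]
    if (is.na(row$amplicon_start))
      stop("no primer design for candidate ", candIds[i])
    seqLen <- Biostrings::width(gen)[match(row$seq_id, names(gen))]
    ls <- max(1L, row$amplicon_start - locusMargin)
    le <- min(seqLen, row$amplicon_end + locusMargin)
    locus <- genomeSub(gen, row$seq_id, ls, le)
    aSeq <- as.character(amplicons[[i]])
    oriented <- .alignBothStrands(aSeq, locus, minSpliceGap, edgeTrim, k)
    aln <- oriented$alignment
    cand <- data.frame(candidate_id = candIds[i],
                       start = row$candidate_start, end = row$candidate_end,
                       length = row$predicted_size, strand = row$strand,
                       stringsAsFactors = FALSE)
    introns <- deriveIntrons(models, row$isoform_id)
    v <- classifyAmplicon(aln, locus, cand, introns, locusStart = ls,
                          amplicon = oriented$amplicon)
    verdicts[[i]] <- v
    extra <- if (length(v@extraSplicing))
      paste(sprintf("%d-%d", IRanges::start(v@extraSplicing),
                    IRanges::end(v@extraSplicing)), collapse = ";")
    else ""
    rows[[i]] <- data.frame(
      candidate_id = candIds[i], replicate = reps[i], call = v@call,
      predicted_size = v@predictedLength, actual_size = v@actualLength,
      actual_start = v@actualStart, actual_end = v@actualEnd,
      canonical = v@canonical, extra_splicing = extra,
      mismatches = v@mismatches, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  attr(res, "verdicts") <- verdicts
  res
}

## Try both orientations; more matched bases wins, tie -> forward.
.alignBothStrands <- function(aSeq, locus, minSpliceGap, edgeTrim, k) {
  score <- function(aln) {
    if (is.null(aln)) return(-Inf)
    sum(aln@blocks$aEnd - aln@blocks$aStart + 1L) - aln@mismatches -
      aln@smallIndels
  }
  fwd <- tryCatch(splicedAlign(aSeq, locus, minSpliceGap = minSpliceGap,
                               edgeTrim = edgeTrim, k = k),
                  error = function(e) NULL)
  rev <- tryCatch(splicedAlign(revComp(aSeq), locus,
                               minSpliceGap = minSpliceGap,
                               edgeTrim = edgeTrim, k = k),
                  error = function(e) NULL)
  if (is.null(fwd) && is.null(rev))
    stop("NO_ALIGNMENT: amplicon aligns to its locus on neither strand")
  if (score(fwd) >= score(rev)) list(alignment = fwd, amplicon = aSeq)
  else list(alignment = rev, amplicon = revComp(aSeq))
}

#' Write a verdict table to TSV
#'
#' @param verdictTable result of \code{\link{verifyPanel}}.
#' @param path output TSV.
#' @return \code{path}, invisibly.
#' @export
writeVerdictTable <- function(verdictTable, path) {
  write.table(verdictTable, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
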