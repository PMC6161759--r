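#' GeneModels: genome plus per-isoform exon structures
#'
#' Container tying a genome (\code{DNAStringSet}) to gene models parsed from
#' GFF3: a \code{GRangesList} of exons per isoform (elements ordered in
#' transcription order, i.e. 5' to 3' of the transcript), the isoform-to-gene
#' map, and optional per-gene expression scores and homolog counts used for
#' candidate screening and panel assembly.
#'
#' @slot genome \code{DNAStringSet} of chromosome/scaffold sequences
#'   (uppercase, alphabet ACGTN).
#' @slot exons \code{GRangesList}, one element per isoform, named by isoform
#'   ID; each element's ranges are the isoform's exons sorted in
#'   transcription order (ascending start on \code{+}, descending on
#'   \code{-}).
#' @slot txToGene named \code{character}, isoform ID to gene ID.
#' @slot expression named \code{numeric}, per-gene expression score
#'   (non-negative; may be empty).
#' @slot homologCount named \code{integer}, per-gene number of homologous
#'   genes (may be empty).
#'
#' @seealso \code{\link{readAnnotation}}, \code{\link{deriveIntrons}}
#' @export
setClass("GeneModels",
  representation(
    genome       = "DNAStringSet",
    exons        = "CompressedGRangesList",
    txToGene     = "character",
    expression   = "numeric",
    homologCount = "integer"
  )
)

setValidity("GeneModels", function(object) {
  msgs <- character(0)
  ex <- object@exons
  if (is.null(names(ex)) || anyDuplicated(names(ex)))
    msgs <- c(msgs, "exons must be named by unique isoform IDs")
  if (!all(names(ex) %in% names(object@txToGene)))
    msgs <- c(msgs, "every isoform needs a txToGene entry")
  if (any(lengths(ex) == 0L))
    msgs <- c(msgs, "every isoform needs at least one exon")
  u <- unlist(ex, use.names = FALSE)
  if (length(u)) {
    sq <- as.character(GenomicRanges::seqnames(u))
    if (!all(sq %in% names(object@genome)))
      msgs <- c(msgs, "exon on a sequence absent from the genome")
    else {
      lens <- Biostrings::width(object@genome)[match(sq, names(object@genome))]
      if (any(GenomicRanges::start(u) < 1L) || any(GenomicRanges::end(u) > lens))
        msgs <- c(msgs, "exon outside sequence bounds")
    }
  }
  if (length(object@expression) && any(object@expression < 0))
    msgs <- c(msgs, "expression scores must be non-negative")
  if (length(msgs)) msgs else TRUE
})

#' PrimerPair: an RT-PCR primer pair spanning candidate plus control intron
#'
#' Result of \code{\link{designPrimers}}.  Both primers lie in annotated
#' exons of the chosen isoform; the genomic amplicon contains the candidate
#' intron and at least one control intron, so the cDNA product is shorter
#' than the genomic product by the summed spanned intron lengths -- the
#' discrimination signal the design exists for.
#'
#' @slot candidateId character, candidate intron ID.
#' @slot isoformId character, isoform the design used.
#' @slot seqId,strand character, locus sequence and gene strand.
#' @slot forwardSeq,reverseSeq character, primer sequences 5'->3' (the
#'   reverse primer is in reverse-complement orientation relative to the
#'   transcript).
#' @slot forwardStart,reverseStart integer, genomic (forward-strand) start
#'   coordinates of the primer binding sites.
#' @slot tmForward,tmReverse numeric, Wallace-rule melting temperatures
#'   (degrees C).
#' @slot ampliconStart,ampliconEnd integer, genomic interval of the product.
#' @slot cdnaLength integer, expected spliced product length (bp).
#' @slot controlIntrons character, IDs of spanned introns other than the
#'   candidate.
#' @export
setClass("PrimerPair",
  representation(
    candidateId   = "character",
    isoformId     = "character",
    seqId         = "character",
    strand        = "character",
    forwardSeq    = "character",
    reverseSeq    = "character",
    forwardStart  = "integer",
    reverseStart  = "integer",
    tmForward     = "numeric",
    tmReverse     = "numeric",
    ampliconStart = "integer",
    ampliconEnd   = "integer",
    cdnaLength    = "integer",
    controlIntrons = "character"
  )
)

#' SplicedAlignment: block/gap decomposition of an amplicon against a locus
#'
#' Produced by \code{\link{splicedAlign}}.  Blocks are collinear aligned
#' segments (amplicon interval mapped to a locus interval); gaps are the
#' locus intervals between consecutive blocks, i.e. sequence present in the
#' locus but absent from the amplicon -- the splicing signal.  Coordinates
#' are 1-based closed and local to the supplied locus string.
#'
#' @slot blocks \code{data.frame} with columns \code{aStart}, \code{aEnd}
#'   (amplicon) and \code{gStart}, \code{gEnd} (locus).
#' @slot gaps \code{IRanges} of locus intervals between consecutive blocks
#'   (every gap at least \code{minSpliceGap} wide).
#' @slot mismatches integer, substitutions within blocks.
#' @slot smallIndels integer, bases absorbed as small (sub-splice-gap)
#'   insertions or deletions.
#' @slot ampliconLength,locusLength integer.
#' @export
setClass("SplicedAlignment",
  representation(
    blocks        = "data.frame",
    gaps          = "IRanges",
    mismatches    = "integer",
    smallIndels   = "integer",
    ampliconLength = "integer",
    locusLength   = "integer"
  )
)

setValidity("SplicedAlignment", function(object) {
  b <- object@blocks
  need <- c("aStart", "aEnd", "gStart", "gEnd")
  if (!all(need %in% names(b))) return("blocks need aStart/aEnd/gStart/gEnd")
  if (nrow(b) >= 2L) {
    if (any(diff(b$aStart) <= 0) || any(diff(b$gStart) <= 0))
      return("blocks must be collinear on both sequences")
    if (any(b$aStart[-1L] <= b$aEnd[-nrow(b)]) ||
        any(b$gStart[-1L] <= b$gEnd[-nrow(b)]))
      return("blocks must not overlap")
  }
  TRUE
})

#' AmpliconVerdict: cDNA/gDNA call and candidate re-annotation
#'
#' Produced by \code{\link{classifyAmplicon}}.  \code{call} follows the
#' verification vocabulary: \code{GDNA_UNABLE_TO_JUDGE} (no splicing
#' evidence, product indistinguishable from genomic DNA),
#' \code{CDNA_NOT_AN_INTRON} (spliced product retains the candidate
#' interval), \code{CDNA_CONFIRMED} (gap equals the predicted interval),
#' \code{CDNA_LARGER} / \code{CDNA_SMALLER} (gap overlaps the candidate but
#' differs in extent; the re-annotated interval is reported).
#'
#' @slot candidateId character.
#' @slot call character, one of the vocabulary above.
#' @slot predictedLength integer, annotated candidate length (bp).
#' @slot actualStart,actualEnd integer, re-annotated genomic interval
#'   (\code{NA} unless the call carries one).
#' @slot actualLength integer, \code{NA} unless the call carries one.
#' @slot canonical logical, GT..AG (transcript orientation) at the
#'   re-annotated boundaries; \code{NA} when there is no candidate gap.
#' @slot extraSplicing \code{IRanges} (genomic, forward strand) of spliced
#'   gaps matching no annotated intron and not overlapping the candidate.
#' @slot mismatches integer, from the underlying alignment.
#' @export
setClass("AmpliconVerdict",
  representation(
    candidateId    = "character",
    call           = "character",
    predictedLength = "integer",
    actualStart    = "integer",
    actualEnd      = "integer",
    actualLength   = "integer",
    canonical      = "logical",
    extraSplicing  = "IRanges",
    mismatches     = "integer"
  )
)

.VERDICT_CALLS <- c("GDNA_UNABLE_TO_JUDGE", "CDNA_NOT_AN_INTRON",
                    "CDNA_CONFIRMED", "CDNA_LARGER", "CDNA_SMALLER")

setValidity("AmpliconVerdict", function(object) {
  if (!object@call %in% .VERDICT_CALLS)
    return(paste("call must be one of:", paste(.VERDICT_CALLS, collapse = ", ")))
  hasActual <- object@call %in% c("CDNA_CONFIRMED", "CDNA_LARGER", "CDNA_SMALLER")
  if (hasActual && is.na(object@actualLength))
    return("calls that re-annotate the intron need actualLength")
  if (!hasActual && !is.na(object@actualLength))
    return("actualLength only valid for confirmed/larger/smaller calls")
  TRUE
})
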