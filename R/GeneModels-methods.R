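#' Construct a GeneModels object
#'
#' Usually made by \code{\link{readAnnotation}}; exposed for building models
#' programmatically (tests, simulations).
#'
#' @param genome \code{DNAStringSet}.
#' @param exons \code{GRangesList} named by isoform ID, each element's exons
#'   in transcription order.
#' @param txToGene named character vector mapping isoform IDs to gene IDs.
#' @param expression optional named numeric, per-gene expression score.
#' @param homologCount optional named integer, per-gene homolog count.
#' @return A \code{\linkS4class{GeneModels}} object.
#' @export
GeneModels <- function(genome, exons, txToGene,
                       expression = numeric(0), homologCount = integer(0)) {
  new("GeneModels", genome = genome, exons = as(exons, "CompressedGRangesList"),
      txToGene = txToGene, expression = expression,
      homologCount = as.integer(homologCount) |> setNames(names(homologCount)))
}

#' @describeIn GeneModels genome sequences (\code{DNAStringSet}).
#' @param x,object a \code{GeneModels} object.
#' @export
genomeSeq <- function(x) x@genome

#' @describeIn GeneModels exon \code{GRangesList} (transcription order).
#' @export
exonsByIsoform <- function(x) x@exons

#' @describeIn GeneModels isoform IDs.
#' @export
isoformIds <- function(x) names(x@exons)

#' @describeIn GeneModels gene IDs (unique).
#' @export
geneIds <- function(x) unique(unname(x@txToGene))

#' @describeIn GeneModels isoform-to-gene map (named character).
#' @export
txToGene <- function(x) x@txToGene

#' @describeIn GeneModels per-gene expression scores (named numeric).
#' @export
geneExpression <- function(x) x@expression

#' @describeIn GeneModels per-gene homolog counts (named integer).
#' @export
homologCounts <- function(x) x@homologCount

#' Attach expression scores / homolog counts to gene models
#'
#' Pass-through annotations consumed from TSV inputs (expression:
#' \code{gene_id <tab> score}; homologs: \code{gene_id <tab>
#' comma-separated homolog IDs}).  Unknown gene IDs are ignored with a
#' warning.
#'
#' @param x a \code{GeneModels} object.
#' @param path TSV file path.
#' @return The updated \code{GeneModels}.
#' @export
addExpression <- function(x, path) {
  tab <- read.delim(path, header = FALSE, col.names = c("gene_id", "score"),
                    colClasses = c("character", "numeric"))
  unknown <- setdiff(tab$gene_id, geneIds(x))
  if (length(unknown))
    warning("expression for unknown genes ignored: ",
            paste(unknown, collapse = ", "))
  keep <- tab$gene_id %in% geneIds(x)
  x@expression <- setNames(tab$score[keep], tab$gene_id[keep])
  validObject(x)
  x
}

#' @rdname addExpression
#' @export
addHomologs <- function(x, path) {
  tab <- read.delim(path, header = FALSE, col.names = c("gene_id", "homologs"),
                    colClasses = "character")
  keep <- tab$gene_id %in% geneIds(x)
  n <- ifelse(tab$homologs == "" | is.na(tab$homologs), 0L,
              lengths(strsplit(tab$homologs, ",", fixed = TRUE)))
  x@homologCount <- setNames(as.integer(n[keep]), tab$gene_id[keep])
  validObject(x)
  x
}

setMethod("show", "GeneModels", function(object) {
  ng <- length(geneIds(object))
  ni <- length(object@exons)
  cat(sprintf("GeneModels: %d gene%s, %d isoform%s on %d sequence%s\n",
              ng, if (ng == 1) "" else "s",
              ni, if (ni == 1) "" else "s",
              length(object@genome),
              if (length(object@genome) == 1) "" else "s"))
  if (length(object@expression))
    cat(sprintf("  expression scores for %d genes\n", length(object@expression)))
  if (length(object@homologCount))
    cat(sprintf("  homolog counts for %d genes\n", length(object@homologCount)))
})

setMethod("show", "PrimerPair", function(object) {
  cat(sprintf("PrimerPair for %s (%s, %s strand)\n", object@candidateId,
              object@isoformId, object@strand))
  cat(sprintf("  F 5'-%s-3' (Tm %.0f)\n  R 5'-%s-3' (Tm %.0f)\n",
              object@forwardSeq, object@tmForward,
              object@reverseSeq, object@tmReverse))
  cat(sprintf("  amplicon %s:%d-%d  genomic %d bp, cDNA %d bp\n",
              object@seqId, object@ampliconStart, object@ampliconEnd,
              object@ampliconEnd - object@ampliconStart + 1L,
              object@cdnaLength))
  cat(sprintf("  control introns: %s\n",
              paste(object@controlIntrons, collapse = ", ")))
})

setMethod("show", "SplicedAlignment", function(object) {
  cat(sprintf("SplicedAlignment: %d block(s), %d splice gap(s), %d mismatch(es), %d indel base(s)\n",
              nrow(object@blocks), length(object@gaps),
              object@mismatches, object@smallIndels))
  if (length(object@gaps)) {
    g <- object@gaps
    cat(sprintf("  gaps: %s\n",
        paste(sprintf("[%d,%d] (%d bp)", IRanges::start(g), IRanges::end(g),
                      IRanges::width(g)), collapse = ", ")))
  }
})

setMethod("show", "AmpliconVerdict", function(object) {
  cat(sprintf("AmpliconVerdict %s: %s", object@candidateId, object@call))
  if (!is.na(object@actualLength))
    cat(sprintf(" (actual %d bp, canonical=%s)", object@actualLength,
                object@canonical))
  cat("\n")
  if (length(object@extraSplicing))
    cat(sprintf("  extra splicing: %d unannotated gap(s)\n",
                length(object@extraSplicing)))
})

#' @describeIn classifyAmplicon verdict call accessor.
#' @param x an \code{AmpliconVerdict}.
#' @export
verdictCall <- function(x) x@call

#' @describeIn classifyAmplicon re-annotated intron length accessor
#'   (\code{NA} when the call carries none).
#' @export
actualIntronLength <- function(x) x@actualLength

#' @describeIn classifyAmplicon extra (unannotated) spliced gaps accessor.
#' @export
extraSplicing <- function(x) x@extraSplicing
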