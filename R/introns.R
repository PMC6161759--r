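#' Derive per-isoform introns from gene models
#'
#' One intron per adjacent exon pair, numbered 1..n-1 in transcription
#' order; intron IDs follow the \code{<isoform>-<ordinal>} convention.
#' Genomic intervals are always on the forward strand; donor and acceptor
#' dinucleotides are read in transcript orientation (reverse-complemented
#' for minus-strand isoforms).  Canonical introns start GT and end AG;
#' donors/acceptors containing N (or too short to read) are flagged
#' non-canonical rather than erroring.
#'
#' @param x a \code{\linkS4class{GeneModels}} object.
#' @param isoforms optional character vector restricting to these isoform
#'   IDs (default: all).
#' @return \code{GRanges} (forward-strand intervals, strand column carries
#'   the gene strand) with metadata columns \code{intron_id},
#'   \code{isoform_id}, \code{gene_id}, \code{ordinal}, \code{donor},
#'   \code{acceptor}, \code{canonical}.  Single-exon isoforms contribute no
#'   rows.
#' @examples
#' gm <- simulateGenome(nGenes = 2, seed = 1)$models
#' deriveIntrons(gm)
#' @export
deriveIntrons <- function(x, isoforms = NULL) {
  ex <- exonsByIsoform(x)
  if (!is.null(isoforms)) {
    missing <- setdiff(isoforms, names(ex))
    if (length(missing)) stop("unknown isoform(s): ", paste(missing, collapse = ", "))
    ex <- ex[isoforms]
  }
  gen <- genomeSeq(x)
  tg <- txToGene(x)
  out <- vector("list", length(ex))
  for (i in seq_along(ex)) {
    e <- ex[[i]]
    iso <- names(ex)[i]
    n <- length(e)
    if (n < 2L) { out[[i]] <- GenomicRanges::GRanges(); next }
    strand <- as.character(GenomicRanges::strand(e))[1L]
    sq <- as.character(GenomicRanges::seqnames(e))[1L]
    s <- GenomicRanges::start(e); en <- GenomicRanges::end(e)
    if (strand == "-") {
      # transcription order is descending start: intron k lies between
      # exon k's start and exon k+1's end
      istart <- en[-1L] + 1L
      iend <- s[-n] - 1L
    } else {
      istart <- en[-n] + 1L
      iend <- s[-1L] - 1L
    }
    if (any(iend < istart))
      stop("overlapping or abutting exons in isoform ", iso)
    ord <- seq_len(n - 1L)
    gr <- GenomicRanges::GRanges(sq, IRanges::IRanges(istart, iend),
                                 strand = strand)
    chrom <- as.character(gen[[sq]])
    don <- acc <- character(n - 1L)
    for (k in ord) {
      ilen <- iend[k] - istart[k] + 1L
      d2 <- substr(chrom, istart[k], min(istart[k] + 1L, iend[k]))
      a2 <- substr(chrom, max(iend[k] - 1L, istart[k]), iend[k])
      if (strand == "-") {
        don[k] <- revComp(a2)
        acc[k] <- revComp(d2)
      } else {
        don[k] <- d2
        acc[k] <- a2
      }
    }
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
      intron_id = sprintf("%s-%d", iso, ord),
      isoform_id = iso,
      gene_id = unname(tg[iso]),
      ordinal = ord,
      donor = don,
      acceptor = acc,
      canonical = don == "GT" & acc == "AG")
    out[[i]] <- gr
  }
  out <- out[lengths(out) > 0L]
  if (!length(out)) return(GenomicRanges::GRanges())
  res <- suppressWarnings(do.call(c, unname(out)))
  res
}

#' Intron-size census
#'
#' Tallies intron lengths into the irregular decade bins used for
#' sub-100 bp intron surveys: below 30, exactly 30, 31-39, 40-49, 50-59,
#' 60-70, 71-80, 81-89 and 90-99 bp by default.  Bins are defined by their
#' inclusive lower edges; each bin ends where the next begins.  Introns are
#' counted per isoform occurrence by default (matching per-isoform intron
#' IDs); \code{uniqueLoci = TRUE} collapses identical genomic intervals
#' first.
#'
#' @param introns \code{GRanges} from \code{\link{deriveIntrons}}.
#' @param binLows integer vector of inclusive lower bin edges (ascending).
#' @param maxLen censused range is \code{[min(binLows), maxLen]} inclusive.
#' @param uniqueLoci collapse introns sharing seqname/start/end before
#'   counting.
#' @return \code{data.frame} with columns \code{bin_low}, \code{bin_high},
#'   \code{count}, \code{percent_of_range}, \code{percent_of_all};
#'   attributes \code{total_in_range} and \code{total_all}.
#' @export
intronCensus <- function(introns,
                         binLows = c(1L, 30L, 31L, 40L, 50L, 60L, 71L, 81L, 90L),
                         maxLen = 99L,
                         uniqueLoci = FALSE) {
  stopifnot(length(binLows) >= 1L, !is.unsorted(binLows, strictly = TRUE),
            maxLen >= max(binLows))
  if (uniqueLoci && length(introns)) {
    key <- paste(GenomicRanges::seqnames(introns),
                 GenomicRanges::start(introns),
                 GenomicRanges::end(introns))
    introns <- introns[!duplicated(key)]
  }
  lens <- if (length(introns)) GenomicRanges::width(introns) else integer(0)
  totalAll <- length(lens)
  inRange <- lens[lens >= binLows[1L] & lens <= maxLen]
  binHigh <- c(binLows[-1L] - 1L, maxLen)
  counts <- vapply(seq_along(binLows), function(i)
    sum(inRange >= binLows[i] & inRange <= binHigh[i]), integer(1))
  res <- data.frame(
    bin_low = binLows, bin_high = binHigh, count = counts,
    percent_of_range = if (length(inRange))
      roundHalfUp(100 * counts / length(inRange), 2) else rep(0, length(counts)),
    percent_of_all = if (totalAll)
      roundHalfUp(100 * counts / totalAll, 2) else rep(0, length(counts)))
  attr(res, "total_in_range") <- length(inRange)
  attr(res, "total_all") <- totalAll
  res
}

#' Write a census table to TSV
#'
#' @param census result of \code{\link{intronCensus}}.
#' @param path output TSV.
#' @return \code{path}, invisibly.
#' @export
writeCensus <- function(census, path) {
  write.table(census, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
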