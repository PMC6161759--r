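#' Select ultra-small intron candidates
#'
#' All and only introns whose length is at most \code{maxLen} (inclusive;
#' the conventional microintron screen uses 30 bp), wrapped as candidate
#' rows with exclusion pending, ordered deterministically by gene then
#' intron ID.
#'
#' @param introns \code{GRanges} from \code{\link{deriveIntrons}}.
#' @param maxLen inclusive length threshold in bp (>= 1).
#' @return \code{data.frame} with columns \code{candidate_id} (= intron ID),
#'   \code{gene_id}, \code{isoform_id}, \code{ordinal}, \code{seq_id},
#'   \code{start}, \code{end}, \code{length}, \code{strand}, \code{donor},
#'   \code{acceptor}, \code{canonical}, \code{exclusion} (\code{"NONE"}).
#' @export
selectCandidates <- function(introns, maxLen = 30L) {
  stopifnot(maxLen >= 1L)
  keep <- introns[GenomicRanges::width(introns) <= maxLen]
  m <- S4Vectors::mcols(keep)
  res <- data.frame(
    candidate_id = m$intron_id,
    gene_id = m$gene_id,
    isoform_id = m$isoform_id,
    ordinal = m$ordinal,
    seq_id = as.character(GenomicRanges::seqnames(keep)),
    start = GenomicRanges::start(keep),
    end = GenomicRanges::end(keep),
    length = GenomicRanges::width(keep),
    strand = as.character(GenomicRanges::strand(keep)),
    donor = m$donor,
    acceptor = m$acceptor,
    canonical = m$canonical,
    exclusion = rep("NONE", length(keep)),
    stringsAsFactors = FALSE)
  res[order(res$gene_id, res$candidate_id), , drop = FALSE] |>
    `rownames<-`(NULL)
}

#' Apply candidate exclusion rules
#'
#' Labels every candidate with exactly one of \code{NONE},
#' \code{NO_CONTROL_INTRON} (no isoform of the gene offers a second intron,
#' so no co-amplifiable control exists and a cDNA product could never be
#' told apart from genomic DNA), \code{NO_PRIMER_SITE} (the neighbouring
#' exons cannot host an acceptable primer pair), or
#' \code{AMBIGUOUS_PRODUCT} (reserved label for candidates whose product
#' could not be discriminated downstream; assigned via \code{ambiguous}).
#'
#' @param candidates \code{data.frame} from \code{\link{selectCandidates}}.
#' @param models \code{\linkS4class{GeneModels}} containing every candidate
#'   gene.
#' @param primerFeasibility function(candidateRow, models) returning
#'   \code{TRUE} if a primer pair is designable; default runs
#'   \code{\link{designPrimers}} with default constraints.
#' @param ambiguous character vector of candidate IDs to label
#'   \code{AMBIGUOUS_PRODUCT} (post-hoc knowledge from verification).
#' @return The candidates with \code{exclusion} filled in.
#' @export
applyExclusions <- function(candidates, models,
                            primerFeasibility = NULL,
                            ambiguous = character(0)) {
  if (nrow(candidates) == 0L) return(candidates)
  missing <- setdiff(candidates$gene_id, geneIds(models))
  if (length(missing))
    stop("candidate gene(s) missing from models: ",
         paste(missing, collapse = ", "))
  if (is.null(primerFeasibility)) {
    primerFeasibility <- function(cand, models) {
      res <- designPrimers(models, cand)
      methods::is(res, "PrimerPair")
    }
  }
  nIntrons <- lengths(exonsByIsoform(models)) - 1L
  geneMax <- tapply(nIntrons, unname(txToGene(models))[match(
    names(exonsByIsoform(models)), isoformIds(models))], max)
  excl <- character(nrow(candidates))
  for (i in seq_len(nrow(candidates))) {
    cand <- candidates[i, , drop = FALSE]
    if (cand$candidate_id %in% ambiguous) {
      excl[i] <- "AMBIGUOUS_PRODUCT"
    } else if (geneMax[[cand$gene_id]] < 2L) {
      excl[i] <- "NO_CONTROL_INTRON"
    } else if (!isTRUE(primerFeasibility(cand, models))) {
      excl[i] <- "NO_PRIMER_SITE"
    } else {
      excl[i] <- "NONE"
    }
  }
  candidates$exclusion <- excl
  candidates
}

#' Flag tandem-repeat context around a candidate intron
#'
#' Scans the candidate interval extended by \code{flank} on each side for a
#' perfect tandem repeat with period between \code{minPeriod} and
#' \code{maxPeriod} and at least \code{minCopies} exact consecutive copies.
#' Repetitive context (for example runs of a CAACAG hexamer) can induce
#' spurious microintron predictions, so flagged candidates carry the best
#' motif found: most copies first, smallest period on ties, leftmost start
#' on remaining ties.
#'
#' @param candidate one-row data.frame from \code{\link{selectCandidates}}
#'   (needs \code{seq_id}, \code{start}, \code{end}).
#' @param genome \code{DNAStringSet}.
#' @param flank bp added on each side of the intron (default 30).
#' @param minPeriod,maxPeriod motif length range scanned (defaults 1 and 10).
#' @param minCopies copies required to raise the flag (default 3).
#' @return list with \code{flagged} (logical), \code{motif}, \code{copies},
#'   \code{period}, \code{start} (window-relative 1-based start of the
#'   repeat tract; \code{NA} when nothing repeats).
#' @export
flagRepeatContext <- function(candidate, genome, flank = 30L,
                              minPeriod = 1L, maxPeriod = 10L,
                              minCopies = 3L) {
  stopifnot(flank >= 0L, minPeriod >= 1L, maxPeriod >= minPeriod,
            minCopies >= 2L)
  len <- Biostrings::width(genome)[match(candidate$seq_id, names(genome))]
  ws <- max(1L, candidate$start - flank)
  we <- min(len, candidate$end + flank)
  window <- genomeSub(genome, candidate$seq_id, ws, we)
  best <- bestTandemRepeat(window, minPeriod, maxPeriod)
  if (is.null(best))
    return(list(flagged = FALSE, motif = NA_character_, copies = 0L,
                period = NA_integer_, start = NA_integer_))
  list(flagged = best$copies >= minCopies,
       motif = best$motif, copies = best$copies,
       period = best$period, start = best$start)
}

## Best perfect tandem repeat in `s`: maximise copy count, then minimise
## period, then leftmost.  Uses the self-comparison-at-lag trick: positions
## where s[i] == s[i+p]; a run of r consecutive matches at lag p starting at
## i means floor(r/p)+1 copies of s[i..i+p-1].
bestTandemRepeat <- function(s, minPeriod, maxPeriod) {
  n <- nchar(s)
  v <- utf8ToInt(s)
  best <- NULL
  for (p in minPeriod:maxPeriod) {
    if (n < 2L * p) break
    eq <- v[seq_len(n - p)] == v[(p + 1L):n]
    r <- rle(eq)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    hit <- which(r$values & r$lengths >= p)
    for (h in hit) {
      copies <- r$lengths[h] %/% p + 1L
      cand <- list(motif = substr(s, starts[h], starts[h] + p - 1L),
                   copies = copies, period = p, start = starts[h])
      if (is.null(best) ||
          copies > best$copies ||
          (copies == best$copies && p < best$period) ||
          (copies == best$copies && p == best$period && cand$start < best$start))
        best <- cand
    }
  }
  best
}

#' Diff candidate sets across annotation versions
#'
#' @param oldCandidates,newCandidates candidate data.frames (or character
#'   vectors of candidate IDs) sharing the same ID convention.
#' @return list with \code{retained} (IDs in both) and \code{removed} (IDs
#'   only in the old set), each sorted.
#' @export
diffAnnotations <- function(oldCandidates, newCandidates) {
  ids <- function(x) if (is.data.frame(x)) x$candidate_id else as.character(x)
  old <- unique(ids(oldCandidates)); new <- unique(ids(newCandidates))
  list(retained = sort(intersect(old, new)),
       removed = sort(setdiff(old, new)))
}

#' Assemble and write a candidate report
#'
#' One row per candidate, mirroring a verification-table layout: running
#' number, intron ID, size, exclusion label, repeat flag, splice-variant
#' count and homolog count, ordered by descending gene expression (genes
#' without a score sort last) for panel assembly -- high-expression genes
#' are amplified first.
#'
#' @param candidates screened candidates (after
#'   \code{\link{applyExclusions}}).
#' @param models \code{GeneModels} supplying expression, homolog counts and
#'   splice-variant counts.
#' @param genome \code{DNAStringSet} for repeat-context scanning.
#' @param ... passed to \code{\link{flagRepeatContext}}.
#' @return \code{data.frame} report.
#' @export
candidateReport <- function(candidates, models, genome = genomeSeq(models),
                            ...) {
  if (nrow(candidates) == 0L) {
    return(data.frame(no = integer(0), candidate_id = character(0),
                      size = integer(0), exclusion = character(0),
                      repeat_flag = logical(0), repeat_motif = character(0),
                      splice_variants = integer(0), homologs = integer(0),
                      expression = numeric(0)))
  }
  tg <- txToGene(models)
  nIso <- table(unname(tg))
  expr <- geneExpression(models)
  hom <- homologCounts(models)
  rep_flag <- logical(nrow(candidates)); rep_motif <- character(nrow(candidates))
  for (i in seq_len(nrow(candidates))) {
    rr <- flagRepeatContext(candidates[i, , drop = FALSE], genome, ...)
    rep_flag[i] <- rr$flagged
    rep_motif[i] <- if (rr$flagged) rr$motif else ""
  }
  ex <- unname(expr[candidates$gene_id])
  res <- data.frame(
    candidate_id = candidates$candidate_id,
    size = candidates$length,
    exclusion = candidates$exclusion,
    repeat_flag = rep_flag,
    repeat_motif = rep_motif,
    splice_variants = as.integer(nIso[candidates$gene_id]),
    homologs = ifelse(candidates$gene_id %in% names(hom),
                      unname(hom[candidates$gene_id]), NA_integer_),
    expression = ex,
    stringsAsFactors = FALSE)
  o <- order(-ifelse(is.na(res$expression), -Inf, res$expression),
             res$candidate_id)
  res <- res[o, , drop = FALSE]
  res <- cbind(no = seq_len(nrow(res)), res)
  rownames(res) <- NULL
  res
}

#' @rdname candidateReport
#' @param report result of \code{candidateReport}.
#' @param path output TSV.
#' @export
writeCandidateReport <- function(report, path) {
  write.table(report, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
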