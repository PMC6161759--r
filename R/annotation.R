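#' Read a genome FASTA
#'
#' Loads all records, uppercases the sequence, and validates the alphabet
#' (ACGTN after normalisation).  Record IDs are the first
#' whitespace-delimited token of each header and must be unique.
#'
#' @param path FASTA file.
#' @return \code{DNAStringSet} named by record ID.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">chr1 demo", "acgtACGT"), fa)
#' readGenome(fa)
#' @export
readGenome <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  dna <- Biostrings::readDNAStringSet(path)
  if (length(dna) == 0L) stop("empty FASTA: ", path)
  names(dna) <- vapply(strsplit(names(dna), "\\s+"), `[`, character(1), 1L)
  dup <- names(dna)[duplicated(names(dna))]
  if (length(dup)) stop("duplicate sequence ID(s): ", paste(unique(dup), collapse = ", "))
  if (any(Biostrings::width(dna) == 0L)) stop("empty sequence record in ", path)
  dna <- Biostrings::DNAStringSet(toupper(as.character(dna)))
  bad <- Biostrings::alphabetFrequency(dna, baseOnly = TRUE)[, "other", drop = TRUE] -
    Biostrings::letterFrequency(dna, "N")[, 1L]
  if (any(bad > 0))
    stop("characters outside ACGTN in: ",
         paste(names(dna)[bad > 0], collapse = ", "))
  dna
}

#' Read a GFF3 gene annotation into GeneModels
#'
#' Parses gene / mRNA (or transcript) / exon features linked by ID and
#' Parent attributes.  Exon intervals are taken over from GFF3 (1-based
#' inclusive, the convention kept internally via \code{GRanges}) and sorted
#' into transcription order per isoform: ascending start on \code{+},
#' descending on \code{-}.
#'
#' @param path GFF3 file.
#' @param genome \code{DNAStringSet} from \code{\link{readGenome}}; exon
#'   bounds are validated against it.
#' @return A \code{\linkS4class{GeneModels}} object.
#' @export
readAnnotation <- function(path, genome) {
  gff <- rtracklayer::import(path, format = "gff3")
  type <- as.character(gff$type)
  mrna <- gff[type %in% c("mRNA", "transcript")]
  if (length(mrna) == 0L) stop("no mRNA/transcript features in ", path)
  if (any(is.na(mrna$ID))) stop("mRNA feature without ID in ", path)
  txGene <- setNames(
    vapply(mrna$Parent, function(p) if (length(p)) p[[1L]] else NA_character_,
           character(1)),
    mrna$ID)
  if (anyNA(txGene)) stop("mRNA feature without gene Parent in ", path)

  ex <- gff[type == "exon"]
  if (length(ex) == 0L) stop("no exon features in ", path)
  parents <- ex$Parent
  if (any(lengths(parents) == 0L)) stop("exon without Parent in ", path)
  # exons may belong to several isoforms: expand per parent
  idx <- rep(seq_along(ex), lengths(parents))
  ex <- ex[idx]
  par <- unlist(parents, use.names = FALSE)
  unknown <- setdiff(unique(par), names(txGene))
  if (length(unknown))
    stop("exon references unknown parent isoform(s): ",
         paste(unknown, collapse = ", "))

  sq <- as.character(GenomicRanges::seqnames(ex))
  if (!all(sq %in% names(genome)))
    stop("exon on sequence absent from genome: ",
         paste(setdiff(unique(sq), names(genome)), collapse = ", "))
  lens <- Biostrings::width(genome)[match(sq, names(genome))]
  if (any(GenomicRanges::start(ex) < 1L) || any(GenomicRanges::end(ex) > lens))
    stop("exon outside sequence bounds in ", path)

  ex <- GenomicRanges::granges(ex)  # drop metadata
  grl <- GenomicRanges::split(ex, factor(par, levels = unique(names(txGene))[
    unique(names(txGene)) %in% unique(par)]))
  grl <- sortExonsTranscription(grl)
  GeneModels(genome = genome, exons = grl,
             txToGene = txGene[names(grl)])
}

## Sort each isoform's exons into transcription order.
sortExonsTranscription <- function(grl) {
  as(S4Vectors::endoapply(grl, function(g) {
    o <- order(GenomicRanges::start(g),
               decreasing = all(as.character(GenomicRanges::strand(g)) == "-"))
    g[o]
  }), "CompressedGRangesList")
}

#' Write GeneModels back to GFF3
#'
#' Emits gene, mRNA and exon features with ID/Parent linkage; coordinates
#' follow the GFF3 1-based inclusive convention.  Round-trips through
#' \code{\link{readAnnotation}}.
#'
#' @param x a \code{GeneModels} object.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeAnnotation <- function(x, path) {
  ex <- exonsByIsoform(x)
  tg <- txToGene(x)
  lines <- c("##gff-version 3")
  byGene <- split(names(ex), unname(tg[names(ex)]))
  for (g in names(byGene)) {
    isos <- byGene[[g]]
    u <- unlist(ex[isos], use.names = FALSE)
    sq <- as.character(GenomicRanges::seqnames(u))[1L]
    st <- as.character(GenomicRanges::strand(u))[1L]
    lines <- c(lines, sprintf("%s\tintronAudit\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
      sq, min(GenomicRanges::start(u)), max(GenomicRanges::end(u)), st, g))
    for (iso in isos) {
      e <- ex[[iso]]
      lines <- c(lines,
        sprintf("%s\tintronAudit\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s",
                sq, min(GenomicRanges::start(e)), max(GenomicRanges::end(e)),
                st, iso, g),
        sprintf("%s\tintronAudit\texon\t%d\t%d\t.\t%s\t.\tParent=%s",
                sq, sort(GenomicRanges::start(e)),
                sort(GenomicRanges::end(e)), st, iso))
    }
  }
  writeLines(lines, path)
  invisible(path)
}
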