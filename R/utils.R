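#' @import methods
#' @import S4Vectors
#' @import IRanges
#' @import GenomicRanges
#' @import Biostrings
#' @importFrom stats setNames
#' @importFrom utils read.delim write.table
NULL

## Round half away from zero to `digits` decimals (printed-table convention;
## base round() is round-half-even).
roundHalfUp <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

## Reverse complement for plain character vectors (ACGTN).
revComp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

## Extract genome subsequence as an uppercase character scalar.
## `genome` is a DNAStringSet; coordinates 1-based closed.
genomeSub <- function(genome, seqId, start, end) {
  if (!seqId %in% names(genome))
    stop("unknown sequence ID: ", seqId)
  len <- Biostrings::width(genome)[match(seqId, names(genome))]
  if (start < 1L || end > len || end < start)
    stop(sprintf("coordinates [%d,%d] out of bounds for %s (length %d)",
                 start, end, seqId, len))
  as.character(Biostrings::subseq(genome[[seqId]], start, end))
}

## Positions (1-based) on `template` where `pattern` matches with at most
## `maxMismatch` substitutions.  Vectorised over offsets; O(w * n).
mismatchScan <- function(template, pattern, maxMismatch = 0L) {
  n <- nchar(template); w <- nchar(pattern)
  if (w > n || w == 0L) return(integer(0))
  tv <- utf8ToInt(template)
  pv <- utf8ToInt(pattern)
  counts <- integer(n - w + 1L)
  for (j in seq_len(w)) {
    counts <- counts + (tv[j:(n - w + j)] != pv[j])
  }
  which(counts <= maxMismatch)
}

## Number of mismatching characters between two equal-length strings.
hammingDist <- function(a, b) {
  stopifnot(nchar(a) == nchar(b))
  if (nchar(a) == 0L) return(0L)
  sum(utf8ToInt(a) != utf8ToInt(b))
}

randomDna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
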