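#' Spliced alignment of an amplicon against its genomic locus
#'
#' Decomposes a (Sanger-scale) amplicon into collinear blocks on the locus
#' separated by locus-only gaps -- the splicing signal.  Exact k-mer
#' anchors are collected, merged into maximal exact diagonal segments,
#' chained collinearly by dynamic programming to maximise matched amplicon
#' bases, and the inter-segment regions are resolved: unaligned amplicon
#' bases are attached to the flanking blocks at the split maximising
#' matches (leftmost on ties), locus-only gaps shorter than
#' \code{minSpliceGap} are absorbed as small deletions (blocks merged), and
#' amplicon-only bases as small insertions.  If the amplicon is a
#' concatenation of locus blocks (each at least \code{k} bp) separated by
#' gaps of at least \code{minSpliceGap}, with per-block mismatch rate at
#' most \code{maxMismatchRate}, the exact block structure is recovered.
#'
#' @param amplicon,locus character or \code{DNAString}; the caller handles
#'   orientation (both presumed on the same strand).
#' @param minSpliceGap smallest locus gap treated as splicing evidence
#'   (default 8 bp -- small enough that even the tiniest tested candidate
#'   intron still counts as a splice, large enough to absorb alignment
#'   indels).
#' @param maxMismatchRate tolerated per-block substitution rate (contract
#'   parameter; default 0.05).
#' @param edgeTrim bases at each amplicon end allowed to stay uncovered
#'   (Sanger end noise; default 5).
#' @param k anchor k-mer size (default 15).
#' @return A \code{\linkS4class{SplicedAlignment}}.  Coordinates are
#'   1-based closed and local to \code{locus}.
#' @examples
#' locus <- paste(rep(c("ACGT"), 100), collapse = "")
#' @export
splicedAlign <- function(amplicon, locus, minSpliceGap = 8L,
                         maxMismatchRate = 0.05, edgeTrim = 5L, k = 15L) {
  a <- toupper(as.character(amplicon))
  g <- toupper(as.character(locus))
  m <- nchar(a); L <- nchar(g)
  if (m == 0L || L == 0L) stop("empty amplicon or locus")
  # anchor-size ladder: a short edge block carrying a substitution can lack
  # any exact k-mer, in which case its splice gap would be missed; retry
  # with shorter anchors while the alignment looks noisier than the
  # tolerated substitution rate
  ladder <- unique(pmin(c(k, 11L, 8L), m))
  best <- NULL; lastErr <- NULL
  for (kk in ladder) {
    aln <- tryCatch(.alignOnce(a, g, kk, minSpliceGap, edgeTrim),
                    error = function(e) e)
    if (inherits(aln, "error")) { lastErr <- aln; next }
    if (is.null(best) || aln@mismatches < best@mismatches) best <- aln
    if (best@mismatches <= maxMismatchRate * m) break
  }
  if (is.null(best)) stop(lastErr)
  best
}

.alignOnce <- function(a, g, k, minSpliceGap, edgeTrim) {
  m <- nchar(a)
  segs <- .anchorSegments(a, g, k)
  if (nrow(segs) == 0L)
    stop("NO_ALIGNMENT: no anchor match between amplicon and locus")
  chain <- .chainSegments(segs)
  covered <- sum(chain$aEnd - chain$aStart + 1L)
  if (covered < 0.5 * m)
    stop("NO_ALIGNMENT: anchor chain covers less than half of the amplicon")
  .resolveChain(a, g, chain, minSpliceGap, edgeTrim)
}

## Maximal exact diagonal segments from shared k-mers.
.anchorSegments <- function(a, g, k) {
  m <- nchar(a); L <- nchar(g)
  if (L < k) return(data.frame(aStart = integer(0), aEnd = integer(0),
                               gStart = integer(0), gEnd = integer(0)))
  gk <- substring(g, 1:(L - k + 1L), k:L)
  ak <- substring(a, 1:(m - k + 1L), k:m)
  pos <- split(seq_along(gk), gk)
  hits <- pos[ak]
  ni <- lengths(hits)
  ni[is.na(names(hits))] <- 0L
  keep <- which(ni > 0L & ni <= 100L)   # skip hyper-repetitive k-mers
  if (!length(keep)) return(data.frame(aStart = integer(0), aEnd = integer(0),
                                       gStart = integer(0), gEnd = integer(0)))
  i <- rep(keep, ni[keep])
  j <- unlist(hits[keep], use.names = FALSE)
  d <- j - i
  o <- order(d, i)
  i <- i[o]; j <- j[o]; d <- d[o]
  newseg <- c(TRUE, diff(d) != 0L | diff(i) != 1L)
  segId <- cumsum(newseg)
  aStart <- tapply(i, segId, min)
  aEnd <- tapply(i, segId, max) + k - 1L
  gStart <- tapply(j, segId, min)
  data.frame(aStart = as.integer(aStart), aEnd = as.integer(aEnd),
             gStart = as.integer(gStart),
             gEnd = as.integer(gStart + (aEnd - aStart)))
}

## Collinear chaining maximising covered amplicon bases (overlap-trimmed);
## ties broken toward fewer junctions, then leftmost locus placement.
.chainSegments <- function(segs) {
  segs <- segs[order(segs$aStart, segs$gStart), , drop = FALSE]
  n <- nrow(segs)
  len <- segs$aEnd - segs$aStart + 1L
  score <- as.numeric(len)
  prev <- rep(NA_integer_, n)
  for (s in seq_len(n)) {
    for (p in seq_len(s - 1L)) {
      if (segs$aStart[p] >= segs$aStart[s] || segs$gStart[p] >= segs$gStart[s] ||
          segs$aEnd[p] >= segs$aEnd[s] || segs$gEnd[p] >= segs$gEnd[s]) next
      ovA <- max(0L, segs$aEnd[p] - segs$aStart[s] + 1L)
      ovG <- max(0L, segs$gEnd[p] - segs$gStart[s] + 1L)
      cand <- score[p] + len[s] - max(ovA, ovG) - 0.01  # junction penalty
      if (cand > score[s] + 1e-9) { score[s] <- cand; prev[s] <- p }
    }
  }
  best <- which.max(score)
  path <- integer(0)
  while (!is.na(best)) { path <- c(best, path); best <- prev[best] }
  chain <- segs[path, , drop = FALSE]
  rownames(chain) <- NULL
  # trim overlaps between consecutive chained segments
  if (nrow(chain) >= 2L) {
    for (s in 2:nrow(chain)) {
      cutA <- chain$aEnd[s - 1L] - chain$aStart[s] + 1L
      cutG <- chain$gEnd[s - 1L] - chain$gStart[s] + 1L
      cut <- max(0L, cutA, cutG)
      chain$aStart[s] <- chain$aStart[s] + cut
      chain$gStart[s] <- chain$gStart[s] + cut
    }
    chain <- chain[chain$aStart <= chain$aEnd, , drop = FALSE]
  }
  chain
}

## Resolve inter-segment regions, absorb small indels, extend the ends.
.resolveChain <- function(a, g, chain, minSpliceGap, edgeTrim) {
  m <- nchar(a); L <- nchar(g)
  mismatches <- 0L; smallIndels <- 0L
  blocks <- chain[1L, , drop = FALSE]
  if (nrow(chain) >= 2L) {
    for (s in 2:nrow(chain)) {
      p <- nrow(blocks)
      da <- chain$aStart[s] - blocks$aEnd[p] - 1L      # unplaced amplicon bases
      dg <- chain$gStart[s] - blocks$gEnd[p] - 1L      # unplaced locus bases
      att <- min(da, dg)                                # bases we can attach
      if (att > 0L) {
        sp <- .bestSplit(a, g, blocks$aEnd[p], blocks$gEnd[p],
                         chain$aStart[s], chain$gStart[s], att)
        mismatches <- mismatches + sp$mism
        blocks$aEnd[p] <- blocks$aEnd[p] + sp$t
        blocks$gEnd[p] <- blocks$gEnd[p] + sp$t
        chain$aStart[s] <- chain$aStart[s] - (att - sp$t)
        chain$gStart[s] <- chain$gStart[s] - (att - sp$t)
        da <- da - att; dg <- dg - att
      }
      if (da > 0L) {          # amplicon insertion: absorb, merge blocks
        smallIndels <- smallIndels + da
        blocks$aEnd[p] <- chain$aEnd[s]
        blocks$gEnd[p] <- chain$gEnd[s]
      } else if (dg == 0L) {  # contiguous: merge
        blocks$aEnd[p] <- chain$aEnd[s]
        blocks$gEnd[p] <- chain$gEnd[s]
      } else if (dg < minSpliceGap) {  # small deletion: absorb, merge
        smallIndels <- smallIndels + dg
        blocks$aEnd[p] <- chain$aEnd[s]
        blocks$gEnd[p] <- chain$gEnd[s]
      } else {                # splice gap
        blocks <- rbind(blocks, chain[s, , drop = FALSE])
      }
    }
  }
  # extend ends over the uncovered amplicon margins where the locus allows
  left <- min(blocks$aStart[1L] - 1L, blocks$gStart[1L] - 1L)
  if (left > 0L) {
    mismatches <- mismatches +
      hammingDist(substr(a, blocks$aStart[1L] - left, blocks$aStart[1L] - 1L),
                  substr(g, blocks$gStart[1L] - left, blocks$gStart[1L] - 1L))
    blocks$aStart[1L] <- blocks$aStart[1L] - left
    blocks$gStart[1L] <- blocks$gStart[1L] - left
  }
  nb <- nrow(blocks)
  right <- min(m - blocks$aEnd[nb], L - blocks$gEnd[nb])
  if (right > 0L) {
    mismatches <- mismatches +
      hammingDist(substr(a, blocks$aEnd[nb] + 1L, blocks$aEnd[nb] + right),
                  substr(g, blocks$gEnd[nb] + 1L, blocks$gEnd[nb] + right))
    blocks$aEnd[nb] <- blocks$aEnd[nb] + right
    blocks$gEnd[nb] <- blocks$gEnd[nb] + right
  }
  rownames(blocks) <- NULL
  blocks <- .normalizeGapsLeft(g, blocks)
  gaps <- if (nrow(blocks) >= 2L)
    IRanges::IRanges(blocks$gEnd[-nrow(blocks)] + 1L,
                     blocks$gStart[-1L] - 1L)
  else IRanges::IRanges()
  new("SplicedAlignment", blocks = blocks, gaps = gaps,
      mismatches = as.integer(mismatches),
      smallIndels = as.integer(smallIndels),
      ampliconLength = m, locusLength = L)
}

## Deterministic normal form: shift every gap to its leftmost
## sequence-preserving placement (possible when block ends repeat the gap
## edges).  refineBoundaries() later moves gaps toward canonical GT..AG.
.normalizeGapsLeft <- function(g, blocks) {
  if (nrow(blocks) < 2L) return(blocks)
  for (i in seq_len(nrow(blocks) - 1L)) {
    gs <- blocks$gEnd[i] + 1L
    ge <- blocks$gStart[i + 1L] - 1L
    lw <- blocks$aEnd[i] - blocks$aStart[i] + 1L
    s <- 0L
    while (s < lw - 1L && gs - s - 1L >= 1L &&
           substr(g, gs - s - 1L, gs - s - 1L) ==
           substr(g, ge - s, ge - s))
      s <- s + 1L
    if (s > 0L) {
      blocks$aEnd[i] <- blocks$aEnd[i] - s
      blocks$gEnd[i] <- blocks$gEnd[i] - s
      blocks$aStart[i + 1L] <- blocks$aStart[i + 1L] - s
      blocks$gStart[i + 1L] <- blocks$gStart[i + 1L] - s
    }
  }
  blocks
}

## Attach `att` amplicon bases between two blocks: t to the left block,
## att - t to the right; maximise matches, tie -> smallest t (leftmost gap).
.bestSplit <- function(a, g, paEnd, pgEnd, saStart, sgStart, att) {
  bestT <- 0L; bestMatch <- -1L; bestMism <- 0L
  mid <- substr(a, paEnd + 1L, saStart - 1L)
  leftG <- substr(g, pgEnd + 1L, pgEnd + att)
  rightG <- substr(g, sgStart - att, sgStart - 1L)
  midLen <- nchar(mid)
  for (t in 0:att) {
    lm <- if (t > 0L) hammingDist(substr(mid, 1L, t), substr(leftG, 1L, t)) else 0L
    rn <- att - t
    rm <- if (rn > 0L)
      hammingDist(substr(mid, midLen - rn + 1L, midLen),
                  substr(rightG, att - rn + 1L, att)) else 0L
    match <- att - lm - rm
    if (match > bestMatch) { bestMatch <- match; bestT <- t; bestMism <- lm + rm }
  }
  list(t = bestT, mism = bestMism)
}

#' Refine splice-gap boundaries toward canonical GT..AG
#'
#' For each gap, enumerates every shift that preserves the reconstructed
#' amplicon sequence exactly (possible when block ends repeat the gap
#' edges) and keeps the placement whose gap starts with the canonical
#' donor and ends with the canonical acceptor in transcript orientation
#' (GT..AG; on a minus-strand gene the forward-strand gap must read
#' CT..AC).  When several canonical placements exist the leftmost is kept;
#' when none exists the gap is shifted fully left and flagged
#' non-canonical.
#'
#' @param alignment a \code{\linkS4class{SplicedAlignment}}.
#' @param locus the locus sequence the alignment was computed against.
#' @param strand \code{"+"} or \code{"-"}: transcript orientation of the
#'   locus.
#' @param amplicon optional: the amplicon the alignment was computed from
#'   (same orientation).  When supplied, placements are compared by the
#'   mismatch cost of shifting the gap -- for a mismatch-free alignment
#'   zero-cost shifts reduce to exact sequence preservation -- and a
#'   canonical placement costing at most \code{maxShiftCost} extra
#'   mismatch is preferred over a non-canonical one.  This applies the
#'   GT..AG prior when a substitution right at a splice junction makes
#'   the raw gap position ambiguous.
#' @param maxShiftCost extra mismatches tolerated to reach a canonical
#'   placement (only used when \code{amplicon} is given; default 1).
#' @return The alignment with shifted gaps; \code{gaps} carry a
#'   \code{canonical} metadata column.
#' @export
refineBoundaries <- function(alignment, locus, strand = "+",
                             amplicon = NULL, maxShiftCost = 1L) {
  g <- toupper(as.character(locus))
  a <- if (!is.null(amplicon)) toupper(as.character(amplicon))
  blocks <- alignment@blocks
  gaps <- alignment@gaps
  if (!length(gaps)) {
    S4Vectors::mcols(gaps)$canonical <- logical(0)
    alignment@gaps <- gaps
    return(alignment)
  }
  canon <- logical(length(gaps))
  mism <- alignment@mismatches
  for (i in seq_along(gaps)) {
    gs <- IRanges::start(gaps)[i]; ge <- IRanges::end(gaps)[i]
    lw <- blocks$aEnd[i] - blocks$aStart[i] + 1L
    rw <- blocks$aEnd[i + 1L] - blocks$aStart[i + 1L] + 1L
    chr <- function(s, p) substr(s, p, p)
    if (is.null(a)) {
      # exact mode: enumerate sequence-preserving shifts
      maxR <- 0L
      while (maxR < rw - 1L && ge + maxR + 1L <= nchar(g) &&
             chr(g, gs + maxR) == chr(g, ge + maxR + 1L))
        maxR <- maxR + 1L
      maxL <- 0L
      while (maxL < lw - 1L && gs - maxL - 1L >= 1L &&
             chr(g, gs - maxL - 1L) == chr(g, ge - maxL))
        maxL <- maxL + 1L
      shifts <- seq(-maxL, maxR)
      cost <- rep(0L, length(shifts))
    } else {
      # scored mode: mismatch cost of each shift, bounded window
      lo <- -min(lw - 1L, gs - 1L, 30L)
      hi <- min(rw - 1L, nchar(g) - ge, 30L)
      shifts <- seq(lo, hi)
      cost <- integer(length(shifts))
      cum <- 0L
      for (t in seq_len(hi)) {  # right shifts
        ab <- chr(a, blocks$aEnd[i] + t)
        cum <- cum + (ab != chr(g, gs + t - 1L)) - (ab != chr(g, ge + t))
        cost[shifts == t] <- cum
      }
      cum <- 0L
      for (t in seq_len(-lo)) { # left shifts
        ab <- chr(a, blocks$aStart[i + 1L] - t)
        cum <- cum + (ab != chr(g, ge + 1L - t)) - (ab != chr(g, gs - t))
        cost[shifts == -t] <- cum
      }
    }
    isCanon <- vapply(shifts, function(s)
      .gapCanonical(g, gs + s, ge + s, strand), logical(1))
    cmin <- min(cost)
    best <- shifts[cost == cmin]
    bestCanon <- shifts[isCanon & cost == cmin]
    nearCanon <- shifts[isCanon & cost <= cmin + maxShiftCost]
    pick <- if (length(bestCanon)) bestCanon[1L]
            else if (length(nearCanon)) nearCanon[1L]
            else best[1L]
    canon[i] <- isCanon[shifts == pick]
    mism <- mism + cost[shifts == pick]
    if (pick != 0L) {
      blocks$aEnd[i] <- blocks$aEnd[i] + pick
      blocks$gEnd[i] <- blocks$gEnd[i] + pick
      blocks$aStart[i + 1L] <- blocks$aStart[i + 1L] + pick
      blocks$gStart[i + 1L] <- blocks$gStart[i + 1L] + pick
      gaps[i] <- IRanges::shift(gaps[i], pick)
    }
  }
  S4Vectors::mcols(gaps)$canonical <- canon
  alignment@blocks <- blocks
  alignment@gaps <- gaps
  alignment@mismatches <- as.integer(max(0L, mism))
  validObject(alignment)
  alignment
}

.gapCanonical <- function(g, gs, ge, strand) {
  if (ge - gs + 1L < 4L) return(FALSE)
  d <- substr(g, gs, gs + 1L)
  a <- substr(g, ge - 1L, ge)
  if (strand == "-") d == "CT" && a == "AC" else d == "GT" && a == "AG"
}
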