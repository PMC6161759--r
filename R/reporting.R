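#' Summarise a verification panel
#'
#' Tallies verdict calls into the verification-panel vocabulary: cDNA
#' products (any \code{CDNA_*} call) versus genomic/unable-to-judge
#' products, and within the cDNA products how many candidates were
#' retained in the transcript (not an intron), confirmed exactly, or
#' re-annotated larger than predicted.  The minimum confirmed intron
#' length -- the smallest intron the panel actually verified -- is reported
#' when any candidate was confirmed.
#'
#' @param verdicts \code{data.frame} with at least a \code{call} column and,
#'   for confirmed/larger calls, \code{actual_size}
#'   (\code{\link{verifyPanel}} output or \code{\link{readTable1}} rows).
#' @return list with \code{n_total}, \code{n_cdna}, \code{n_gdna_uj},
#'   \code{n_not_intron}, \code{n_confirmed}, \code{n_larger},
#'   \code{n_smaller}, \code{min_confirmed_len} (\code{NA} when nothing was
#'   confirmed) and the per-candidate \code{rows}.
#' @export
summarizePanel <- function(verdicts) {
  calls <- if (nrow(verdicts)) verdicts$call else character(0)
  nConf <- sum(calls == "CDNA_CONFIRMED")
  minConf <- if (nConf)
    min(verdicts$actual_size[calls == "CDNA_CONFIRMED"], na.rm = TRUE)
  else NA_integer_
  list(
    n_total = length(calls),
    n_cdna = sum(startsWith(calls, "CDNA_")),
    n_gdna_uj = sum(calls == "GDNA_UNABLE_TO_JUDGE"),
    n_not_intron = sum(calls == "CDNA_NOT_AN_INTRON"),
    n_confirmed = nConf,
    n_larger = sum(calls == "CDNA_LARGER"),
    n_smaller = sum(calls == "CDNA_SMALLER"),
    min_confirmed_len = minConf,
    rows = verdicts)
}

#' Arithmetic consistency report over printed survey counts
#'
#' Recomputes every derived share from the primitive bin counts of a
#' sub-100 bp intron survey and compares each against its printed value at
#' the printed rounding (half-up, 1 or 2 decimals).  The genome-wide
#' intron total is not a primitive: it is derived from the
#' sub-100 bp-count/percentage anchor (count divided by share) and
#' labelled as derived.
#'
#' @param counts named numeric vector or list; required primitives:
#'   \code{n_90_99}, \code{n_81_89}, \code{n_71_80}, \code{n_50_59},
#'   \code{n_40_49}, \code{n_30_39}, \code{n_len30} (exactly 30 bp),
#'   \code{n_lt30}, \code{n_lt100} (all introns under 100 bp) and
#'   \code{pct_lt100_of_all} (the anchor percentage).  Optional printed
#'   values \code{printed_*} (same names as the derived quantities below)
#'   are compared when present.
#' @return \code{data.frame} with columns \code{name}, \code{derived},
#'   \code{printed}, \code{match} (\code{NA} when no printed value was
#'   supplied).  Derived quantities: \code{pct_70_99_of_lt100},
#'   \code{n_le30}, \code{pct_le30_of_lt100}, \code{n_31_59},
#'   \code{total_all_derived}, \code{pct_50_59_of_all},
#'   \code{pct_40_49_of_all}, \code{pct_30_39_of_all},
#'   \code{pct_le30_of_all}.
#' @export
consistencyReport <- function(counts) {
  cn <- as.list(counts)
  need <- c("n_90_99", "n_81_89", "n_71_80", "n_50_59", "n_40_49",
            "n_30_39", "n_len30", "n_lt30", "n_lt100", "pct_lt100_of_all")
  missing <- setdiff(need, names(cn))
  if (length(missing))
    stop("missing primitive count(s): ", paste(missing, collapse = ", "))
  if (any(unlist(cn[need]) < 0)) stop("counts must be non-negative")
  if (cn$n_lt100 == 0 || cn$pct_lt100_of_all == 0)
    stop("zero anchor: cannot derive totals")
  totalAll <- cn$n_lt100 / (cn$pct_lt100_of_all / 100)
  derived <- c(
    pct_70_99_of_lt100 =
      roundHalfUp(100 * (cn$n_90_99 + cn$n_81_89 + cn$n_71_80) / cn$n_lt100, 1),
    n_le30 = cn$n_len30 + cn$n_lt30,
    pct_le30_of_lt100 =
      roundHalfUp(100 * (cn$n_len30 + cn$n_lt30) / cn$n_lt100, 2),
    n_31_59 = (cn$n_30_39 - cn$n_len30) + cn$n_40_49 + cn$n_50_59,
    total_all_derived = roundHalfUp(totalAll, 0),
    pct_50_59_of_all = roundHalfUp(100 * cn$n_50_59 / totalAll, 2),
    pct_40_49_of_all = roundHalfUp(100 * cn$n_40_49 / totalAll, 2),
    pct_30_39_of_all = roundHalfUp(100 * cn$n_30_39 / totalAll, 2),
    pct_le30_of_all =
      roundHalfUp(100 * (cn$n_len30 + cn$n_lt30) / totalAll, 2))
  printed <- vapply(names(derived), function(nm) {
    key <- paste0("printed_", nm)
    if (key %in% names(cn)) as.numeric(cn[[key]]) else NA_real_
  }, numeric(1))
  data.frame(name = names(derived),
             derived = unname(derived),
             printed = unname(printed),
             match = ifelse(is.na(printed), NA, unname(derived) == printed),
             stringsAsFactors = FALSE)
}

#' Read the bundled printed survey counts
#'
#' @param path TSV of \code{name <tab> value} pairs; defaults to the
#'   bundled sub-100 bp intron survey counts.
#' @return named numeric vector.
#' @export
readPrintedCounts <- function(path = system.file("extdata",
                                                 "printed_counts.tsv",
                                                 package = "intronAudit")) {
  tab <- read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  setNames(tab$value, tab$name)
}

#' Read a verification table fixture
#'
#' Parses a table in the verification-panel layout (columns \code{no},
#' \code{intron_id}, \code{size_bp}, \code{sequencing_result}
#' (cDNA/gDNA), \code{existence} (\code{No} / \code{Yes} / \code{UJ} /
#' \code{"<n> bp"}), \code{splice_variants}, \code{homologs},
#' \code{panel}) and derives the verdict vocabulary: gDNA rows become
#' \code{GDNA_UNABLE_TO_JUDGE}; cDNA rows become
#' \code{CDNA_NOT_AN_INTRON} (\code{No}), \code{CDNA_CONFIRMED}
#' (\code{Yes}; actual = predicted) or \code{CDNA_LARGER}
#' (\code{"<n> bp"}; actual = n).
#'
#' @param path TSV path; defaults to the bundled table.
#' @return \code{data.frame} with the original columns plus \code{call}
#'   and \code{actual_size}.
#' @export
readTable1 <- function(path = system.file("extdata", "table1.tsv",
                                          package = "intronAudit")) {
  tab <- read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                    colClasses = c(no = "character"))
  sized <- grepl("^[0-9]+ bp$", tab$existence)
  call <- ifelse(tab$sequencing_result == "gDNA", "GDNA_UNABLE_TO_JUDGE",
          ifelse(tab$existence == "No", "CDNA_NOT_AN_INTRON",
          ifelse(tab$existence == "Yes", "CDNA_CONFIRMED",
          ifelse(sized, "CDNA_LARGER", NA_character_))))
  if (anyNA(call)) stop("unparseable existence value in ", path)
  actual <- rep(NA_integer_, nrow(tab))
  actual[tab$existence == "Yes"] <- tab$size_bp[tab$existence == "Yes"]
  actual[sized] <- as.integer(sub(" bp$", "", tab$existence[sized]))
  tab$call <- call
  tab$actual_size <- actual
  tab
}

#' Write a verification-style table
#'
#' Columns \code{no}, \code{intron_id}, \code{size_bp},
#' \code{sequencing_result}, \code{existence}, \code{splice_variants},
#' \code{homologs}; rows kept in the given (stable) order.  Round-trips
#' through \code{read.delim}.
#'
#' @param rows \code{data.frame} with those columns.
#' @param path output TSV.
#' @return \code{path}, invisibly.
#' @export
writeTable1Like <- function(rows, path) {
  cols <- c("no", "intron_id", "size_bp", "sequencing_result", "existence",
            "splice_variants", "homologs")
  missing <- setdiff(cols, names(rows))
  if (length(missing))
    stop("missing column(s): ", paste(missing, collapse = ", "))
  write.table(rows[, cols, drop = FALSE], path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Human-readable panel summary
#'
#' @param summary result of \code{\link{summarizePanel}}.
#' @return character vector of report lines.
#' @export
formatPanelSummary <- function(summary) {
  c(sprintf("candidates verified: %d", summary$n_total),
    sprintf("  cDNA products:     %d", summary$n_cdna),
    sprintf("  gDNA (unable to judge): %d", summary$n_gdna_uj),
    sprintf("  not an intron:     %d", summary$n_not_intron),
    sprintf("  confirmed:         %d", summary$n_confirmed),
    sprintf("  larger than predicted: %d", summary$n_larger),
    if (summary$n_smaller > 0)
      sprintf("  smaller than predicted: %d", summary$n_smaller),
    if (!is.na(summary$min_confirmed_len))
      sprintf("  smallest confirmed intron: %d bp", summary$min_confirmed_len))
}
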