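#' Canonical recombination-signal-sequence elements
#'
#' Consensus heptamer and nonamer recognized by the RAG1/RAG2 recombinase
#' during V(D)J recombination, separated by a spacer of 12 or 23 bp.
#' Supplied as configurable defaults to the scanner.
#' @format Character scalars.
#' @export
RSS_HEPTAMER <- "CACAGTG"

#' @rdname RSS_HEPTAMER
#' @export
RSS_NONAMER <- "ACAAAAACC"

#' Extract a flank of a breakpoint from a reference sequence
#'
#' Returns the `length` bases on one side of a 1-based breakpoint position:
#' downstream starts at `pos + 1`, upstream ends at `pos - 1`, so
#' upstream + base-at-pos + downstream reconstructs the window.  A flank
#' running past a contig end is truncated and flagged.
#'
#' @param sequence a [Biostrings::DNAString-class] or character scalar.
#' @param pos 1-based breakpoint position.
#' @param side `"upstream"` or `"downstream"`.
#' @param length flank length in bp (0 gives an empty sequence).
#' @param revcomp reverse-complement the flank (for breakpoints whose
#'   retained side is on the minus strand of the derivative).
#' @return list with `seq` (character), `truncated` flag.
#' @examples
#' extractFlank("AAAACGTTTT", 5, "downstream", 3)$seq # "GTT"
#' @export
extractFlank <- function(sequence, pos, side = c("upstream", "downstream"),
                         length, revcomp = FALSE) {
  side <- match.arg(side)
  seq <- if (is.character(sequence)) DNAString(sequence) else sequence
  L <- base::length(seq)
  if (pos < 1L || pos > L) stop("breakpoint position ", pos, " outside sequence")
  if (length < 0L) stop("'length' must be >= 0")
  if (side == "downstream") {
    from <- pos + 1L
    to <- min(pos + length, L)
    truncated <- (pos + length) > L
  } else {
    from <- max(pos - length, 1L)
    to <- pos - 1L
    truncated <- (pos - length) < 1L
  }
  out <- if (from > to) "" else as.character(subseq(seq, from, to))
  if (revcomp && nzchar(out)) {
    out <- as.character(reverseComplement(DNAString(out)))
  }
  list(seq = out, truncated = truncated)
}

#' Scan a sequence for recombination signal sequences
#'
#' Finds every heptamer occurrence on both strands (within a mismatch
#' budget) and, for each, searches for the nonamer at offsets consistent
#' with a 12- or 23-bp spacer (plus/minus `slack`) on the same strand.
#' Occurrences with a nonamer partner are classified `full-RSS`, the rest
#' `heptamer-only`.
#'
#' @param sequence a [Biostrings::DNAString-class] or character scalar;
#'   bases outside A/C/G/T/N are an error.
#' @param heptamer,nonamer consensus elements (defaults [RSS_HEPTAMER],
#'   [RSS_NONAMER]).
#' @param spacers candidate spacer classes in bp (default `c(12, 23)`).
#' @param slack spacer tolerance in bp (default 1).
#' @param maxMismatchHeptamer,maxMismatchNonamer Hamming budgets (defaults
#'   0 and 1; heptamer conservation is functionally strict).
#' @return data.frame with one row per heptamer occurrence: `start`
#'   (1-based position of the heptamer's first base in `sequence`
#'   coordinates), `strand`, `heptMismatches`, `spacerClass` (12/23 or NA),
#'   `spacerLen` (actual, or NA), `nonaMismatches`, `classification`.
#' @export
rssScan <- function(sequence, heptamer = RSS_HEPTAMER, nonamer = RSS_NONAMER,
                    spacers = c(12L, 23L), slack = 1L,
                    maxMismatchHeptamer = 0L, maxMismatchNonamer = 1L) {
  seqChar <- toupper(if (is.character(sequence)) sequence else as.character(sequence))
  bad <- setdiff(unique(strsplit(seqChar, "")[[1]]), c("A", "C", "G", "T", "N"))
  if (length(bad)) {
    stop("invalid base(s) in sequence: ", paste(bad, collapse = ", "))
  }
  seq <- DNAString(seqChar)
  L <- length(seq)
  hep <- DNAString(toupper(heptamer))
  non <- DNAString(toupper(nonamer))
  if (L < length(hep)) stop("sequence shorter than the heptamer")
  scanStrand <- function(subject) {
    # returns hits in *subject* coordinates
    hh <- matchPattern(hep, subject, max.mismatch = maxMismatchHeptamer)
    if (length(hh) == 0L) return(NULL)
    res <- lapply(start(hh), function(s) {
      hm <- neditStartingAt(hep, subject, starting.at = s)
      best <- list(class = NA_integer_, len = NA_integer_, mm = NA_integer_)
      for (sp in spacers) {
        for (d in (sp - slack):(sp + slack)) {
          ns <- s + length(hep) + d
          if (ns < 1L || ns + length(non) - 1L > length(subject)) next
          mm <- neditStartingAt(non, subject, starting.at = ns)
          if (mm <= maxMismatchNonamer &&
              (is.na(best$mm) || mm < best$mm ||
                (mm == best$mm && abs(d - sp) < abs(best$len - best$class)))) {
            best <- list(class = as.integer(sp), len = as.integer(d), mm = as.integer(mm))
          }
        }
      }
      data.frame(start = s, heptMismatches = hm, spacerClass = best$class,
        spacerLen = best$len, nonaMismatches = best$mm,
        classification = if (!is.na(best$class)) "full-RSS" else "heptamer-only")
    })
    do.call(rbind, res)
  }
  fwd <- scanStrand(seq)
  if (!is.null(fwd)) fwd$strand <- "+"
  rcHits <- scanStrand(reverseComplement(seq))
  if (!is.null(rcHits)) {
    # map a hit at s' on the reverse complement back to plus-strand coords:
    # the heptamer occupies L - s' - 6 .. L - s' + 1 - 1 + 7? -> first base
    rcHits$start <- L - (rcHits$start + length(hep) - 1L) + 1L
    rcHits$strand <- "-"
  }
  out <- rbind(fwd, rcHits)
  if (is.null(out)) {
    out <- data.frame(start = integer(0), heptMismatches = integer(0),
      spacerClass = integer(0), spacerLen = integer(0),
      nonaMismatches = integer(0), classification = character(0),
      strand = character(0))
  }
  out <- out[order(out$start), c("start", "strand", "heptMismatches",
    "spacerClass", "spacerLen", "nonaMismatches", "classification")]
  rownames(out) <- NULL
  out
}

#' Classify a breakpoint by proximal recombination signals
#'
#' Looks for RSS hits near a breakpoint and classifies it as
#' `full-RSS-proximal`, `heptamer-only-proximal`, or `no-RSS`.  Distance is
#' from the breakpoint position to the nearest base of the heptamer.
#'
#' @param hits result of [rssScan()] in the same coordinate frame as `pos`.
#' @param pos 1-based breakpoint position.
#' @param window maximum distance in bp for a hit to count (default 50).
#' @param heptamerLength length of the heptamer used in the scan.
#' @return list with `category`, `nearestDistance` (NA when no hit in
#'   window), and the qualifying `hits`.
#' @export
classifyBreakpoint <- function(hits, pos, window = 50,
                               heptamerLength = nchar(RSS_HEPTAMER)) {
  if (nrow(hits) == 0L) {
    return(list(category = "no-RSS", nearestDistance = NA_real_,
      hits = hits))
  }
  s <- hits$start
  e <- hits$start + heptamerLength - 1L
  d <- ifelse(pos < s, s - pos, ifelse(pos > e, pos - e, 0))
  keep <- d <= window
  if (!any(keep)) {
    return(list(category = "no-RSS", nearestDistance = NA_real_,
      hits = hits[0, , drop = FALSE]))
  }
  near <- hits[keep, , drop = FALSE]
  cat <- if (any(near$classification == "full-RSS")) {
    "full-RSS-proximal"
  } else {
    "heptamer-only-proximal"
  }
  list(category = cat, nearestDistance = min(d[keep]), hits = near)
}
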