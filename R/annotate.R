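#' Assign ChIP peaks to nearby transcription start sites
#'
#' A gene is assigned to a peak when the distance from its TSS position to
#' the nearest edge of the peak interval (0 when the TSS lies inside) is at
#' most `window` base pairs, inclusive.  All qualifying peak-gene pairs are
#' reported; TSS strand is ignored for the distance.
#'
#' @param peaks a [GenomicRanges::GRanges-class] of peak intervals (1-based
#'   closed, as usual in R; BED input is converted on import).
#' @param tss data.frame with columns `gene`, `chrom`, `pos` (1-based TSS
#'   position) and optionally `strand`.
#' @param window maximum TSS-to-peak-edge distance in bp (default 1000).
#' @return data.frame with columns `gene`, `peak` (name or index),
#'   `distance`; zero rows when inputs are empty or nothing qualifies.
#' @export
assignPeaksToTss <- function(peaks, tss, window = 1000) {
  if (length(peaks) == 0L || nrow(tss) == 0L) {
    return(data.frame(gene = character(0), peak = character(0),
      distance = numeric(0)))
  }
  stopifnot(all(c("gene", "chrom", "pos") %in% names(tss)))
  tssGr <- GRanges(tss$chrom, IRanges(tss$pos, width = 1))
  peakNames <- if (!is.null(names(peaks))) names(peaks) else as.character(seq_along(peaks))
  # candidates within gap <= window cover every pair with edge distance <= window
  hits <- findOverlaps(tssGr, peaks, maxgap = window)
  if (length(hits) == 0L) {
    return(data.frame(gene = character(0), peak = character(0),
      distance = numeric(0)))
  }
  p <- tss$pos[queryHits(hits)]
  s <- start(peaks)[subjectHits(hits)]
  e <- end(peaks)[subjectHits(hits)]
  d <- ifelse(p < s, s - p, ifelse(p > e, p - e, 0))
  keep <- d <= window
  out <- data.frame(gene = tss$gene[queryHits(hits)][keep],
    peak = peakNames[subjectHits(hits)][keep], distance = d[keep])
  out[order(out$gene, out$peak), , drop = FALSE]
}

#' Link two intervals through Hi-C contacts
#'
#' Determines whether two genomic intervals are in 3D contact: each
#' interval is mapped to the fixed-size bins it overlaps (0-based
#' `floor(position / resolution)`), and the pair is linked when the maximum
#' normalized contact value over the bin cross-product reaches `threshold`.
#' Intervals falling in the same bin are linked by convention (distance 0,
#' below the map's resolution).
#'
#' @param map a [ContactMap-class].
#' @param a,b [GenomicRanges::GRanges-class] intervals (length 1) on the
#'   map's chromosome.
#' @param threshold minimum contact value declaring a link (no default in
#'   the pipeline configuration; required here).
#' @return list with `linked`, `value` (max contact over the bin pairs),
#'   `binsA`, `binsB`, and `flag` (`"no-data"` when an interval lies beyond
#'   the map's extent, `"same-bin"` for the sub-resolution convention).
#' @export
hicLink <- function(map, a, b, threshold) {
  stopifnot(is(map, "ContactMap"), length(a) == 1L, length(b) == 1L)
  res <- map@resolution
  binsOf <- function(gr) {
    seq.int(floor((start(gr) - 1) / res), floor((end(gr) - 1) / res))
  }
  binsA <- binsOf(a)
  binsB <- binsOf(b)
  if (min(binsA) > map@maxBin || min(binsB) > map@maxBin) {
    return(list(linked = NA, value = NA_real_, binsA = binsA, binsB = binsB,
      flag = "no-data"))
  }
  if (length(intersect(binsA, binsB))) {
    vals <- vapply(binsA, function(i) {
      max(vapply(binsB, function(j) contactValue(map, i, j), numeric(1)), na.rm = TRUE)
    }, numeric(1))
    return(list(linked = TRUE, value = suppressWarnings(max(vals, na.rm = TRUE)),
      binsA = binsA, binsB = binsB, flag = "same-bin"))
  }
  vals <- outer(binsA, binsB, Vectorize(function(i, j) contactValue(map, i, j)))
  mx <- suppressWarnings(max(vals, na.rm = TRUE))
  if (!is.finite(mx)) mx <- NA_real_
  list(linked = !is.na(mx) && mx >= threshold, value = mx,
    binsA = binsA, binsB = binsB, flag = character(0))
}

#' Scan a sequence for a consensus motif
#'
#' Reports every occurrence of an IUPAC consensus within a Hamming-distance
#' budget, on the forward strand and (optionally) the reverse complement.
#' Palindromic hits found on both strands at the same position are
#' collapsed to one record with strand `"both"`.  Matching is delegated to
#' [Biostrings::matchPattern()] with an ambiguity-aware pattern.
#'
#' @param sequence a [Biostrings::DNAString-class] or character scalar.
#' @param consensus consensus motif, IUPAC codes allowed.
#' @param maxMismatch maximum mismatches tolerated (default 0).
#' @param bothStrands also scan the reverse complement (default TRUE).
#' @return data.frame with `start` (1-based), `end`, `strand` (`"+"`,
#'   `"-"`, `"both"`), ordered by position.
#' @examples
#' motifScan("GGTTGCGCAAGG", "TTGCGCAA") # palindrome: strand "both"
#' @export
motifScan <- function(sequence, consensus, maxMismatch = 0, bothStrands = TRUE) {
  seq <- if (is.character(sequence)) DNAString(sequence) else sequence
  bad <- setdiff(strsplit(toupper(as.character(consensus)), "")[[1]],
    names(IUPAC_CODE_MAP))
  if (length(bad)) {
    stop("invalid IUPAC character(s) in consensus: ",
      paste(unique(bad), collapse = ", "))
  }
  pat <- DNAString(toupper(as.character(consensus)))
  if (length(pat) > length(seq)) stop("consensus longer than sequence")
  fwd <- matchPattern(pat, seq, max.mismatch = maxMismatch, fixed = "subject")
  hits <- data.frame(start = start(fwd), end = end(fwd),
    strand = rep("+", length(fwd)))
  if (bothStrands) {
    rev <- matchPattern(reverseComplement(pat), seq,
      max.mismatch = maxMismatch, fixed = "subject")
    hits <- rbind(hits, data.frame(start = start(rev), end = end(rev),
      strand = rep("-", length(rev))))
  }
  if (nrow(hits) == 0L) {
    return(data.frame(start = integer(0), end = integer(0), strand = character(0)))
  }
  dup <- duplicated(hits$start) | duplicated(hits$start, fromLast = TRUE)
  if (any(dup)) {
    both <- unique(hits$start[dup])
    hits <- hits[!duplicated(hits$start), , drop = FALSE]
    hits$strand[hits$start %in% both] <- "both"
  }
  hits <- hits[order(hits$start), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}
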