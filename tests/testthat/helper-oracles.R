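# Independent oracles used across the suite: direct enumerations and
# brute-force loops, deliberately written without reference to the package
# implementations they check.

# exact minimum-likelihood two-sided binomial p by full pmf enumeration
minlikeEnum <- function(k, n, p0) {
  d <- choose(n, 0:n) * p0^(0:n) * (1 - p0)^(n - (0:n))
  sum(d[d <= d[k + 1] * (1 + 1e-7)])
}

# exact upper-tail P(X >= x), X ~ Binomial(size, prob), by term summation
upperTailEnum <- function(x, size, prob) {
  if (x <= 0) return(1)
  ks <- x:size
  sum(choose(size, ks) * prob^ks * (1 - prob)^(size - ks))
}

# all-pairs peak/TSS assignment by explicit loops
bruteAssign <- function(peaks, tss, window) {
  pChrom <- as.character(GenomicRanges::seqnames(peaks))
  pStart <- GenomicRanges::start(peaks)
  pEnd <- GenomicRanges::end(peaks)
  rows <- list()
  for (i in seq_along(peaks)) {
    for (j in seq_len(nrow(tss))) {
      if (pChrom[i] != tss$chrom[j]) next
      p <- tss$pos[j]
      s <- pStart[i]
      e <- pEnd[i]
      d <- if (p < s) s - p else if (p > e) p - e else 0
      if (d <= window) {
        rows[[length(rows) + 1L]] <- data.frame(gene = tss$gene[j],
          peak = names(peaks)[i], distance = d)
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(gene = character(0), peak = character(0),
      distance = numeric(0)))
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$gene, out$peak), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# all-pairs LD block by explicit per-variant filtering
bruteBlock <- function(dos, lead, r2min, mafmin) {
  ids <- colnames(dos)
  out <- character(0)
  for (v in setdiff(ids, lead)) {
    af <- mean(dos[, v]) / 2
    maf <- min(af, 1 - af)
    r2 <- if (sd(dos[, v]) == 0 || sd(dos[, lead]) == 0) NA else
      cor(dos[, lead], dos[, v])^2
    if (maf > mafmin && !is.na(r2) && r2 >= r2min) out <- c(out, v)
  }
  out
}

# random DNA of length n from a given RNG state
randomDna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
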