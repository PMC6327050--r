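#' Sample-by-variant genotype container
#'
#' Holds hard genotype calls (0/1/2 copies of the alternate/risk allele),
#' continuous dosages, and optionally per-sample posterior genotype
#' probability triples for imputed variants.  Rows are samples, columns are
#' variants.
#'
#' @slot calls integer matrix of hard calls in \{0,1,2\} (NA allowed).
#' @slot dosage numeric matrix of expected alternate-allele dosages in [0,2].
#' @slot gp numeric array `samples x variants x 3` of genotype posterior
#'   probabilities (p0, p1, p2), or an empty array when absent.
#'
#' @seealso [GenotypeTable()] for construction, [dosages()], [hardCalls()],
#'   [posteriorProbs()].
#' @exportClass GenotypeTable
setClass("GenotypeTable",
  slots = c(calls = "matrix", dosage = "matrix", gp = "array"),
  prototype = list(gp = array(numeric(0), dim = c(0, 0, 3)))
)

setValidity("GenotypeTable", function(object) {
  msg <- character()
  if (!identical(dim(object@calls), dim(object@dosage))) {
    msg <- c(msg, "'calls' and 'dosage' must have identical dimensions")
  }
  cl <- object@calls[!is.na(object@calls)]
  if (length(cl) && !all(cl %in% 0:2)) {
    msg <- c(msg, "hard calls must be 0, 1 or 2")
  }
  dv <- object@dosage[!is.na(object@dosage)]
  if (length(dv) && (min(dv) < 0 || max(dv) > 2)) {
    msg <- c(msg, "dosages must lie in [0, 2]")
  }
  if (is.null(rownames(object@calls)) || is.null(colnames(object@calls))) {
    msg <- c(msg, "'calls' must carry sample rownames and variant colnames")
  }
  if (length(object@gp)) {
    d <- dim(object@gp)
    if (length(d) != 3L || d[3] != 3L || d[1] != nrow(object@calls) ||
        d[2] != ncol(object@calls)) {
      msg <- c(msg, "'gp' must be a samples x variants x 3 array")
    } else {
      sums <- apply(object@gp, c(1, 2), sum)
      if (any(abs(sums - 1) > 1e-6)) {
        msg <- c(msg, "posterior triples must sum to 1 (tolerance 1e-6)")
      }
    }
  }
  if (length(msg)) msg else TRUE
})

#' Construct a GenotypeTable
#'
#' @param calls matrix of hard calls (samples x variants); dimnames are kept,
#'   or generated as `S1..`/`V1..` when missing.
#' @param dosage optional dosage matrix; defaults to the hard calls.
#' @param gp optional `samples x variants x 3` posterior array.
#' @return A [GenotypeTable-class] object.
#' @examples
#' gt <- GenotypeTable(matrix(c(0, 1, 2, 1), 2, 2))
#' dosages(gt)
#' @export
GenotypeTable <- function(calls, dosage = NULL, gp = NULL) {
  calls <- as.matrix(calls)
  if (is.null(rownames(calls))) rownames(calls) <- paste0("S", seq_len(nrow(calls)))
  if (is.null(colnames(calls))) colnames(calls) <- paste0("V", seq_len(ncol(calls)))
  storage.mode(calls) <- "integer"
  if (is.null(dosage)) {
    dosage <- calls
    storage.mode(dosage) <- "double"
  } else {
    dosage <- as.matrix(dosage)
    storage.mode(dosage) <- "double"
    dimnames(dosage) <- dimnames(calls)
  }
  if (is.null(gp)) gp <- array(numeric(0), dim = c(0, 0, 3))
  new("GenotypeTable", calls = calls, dosage = dosage, gp = gp)
}

#' Expression matrix in TPM with sample metadata
#'
#' A thin [SummarizedExperiment::SummarizedExperiment-class] subclass whose
#' `"tpm"` assay holds non-negative transcripts-per-million values (genes x
#' samples).  Sample metadata columns used by the pipeline, when present:
#' `copy_number` (copies of the chromosome of interest), `translocated`
#' (logical driver-translocation flag), `group` (e.g. case/control).
#'
#' @seealso [TpmExperiment()], [tpm()]
#' @exportClass TpmExperiment
setClass("TpmExperiment", contains = "SummarizedExperiment")

setValidity("TpmExperiment", function(object) {
  if (!"tpm" %in% assayNames(object)) {
    return("assay 'tpm' is required")
  }
  a <- assay(object, "tpm")
  if (any(!is.finite(a)) || any(a < 0)) {
    return("TPM values must be finite and non-negative")
  }
  TRUE
})

#' Construct a TpmExperiment
#'
#' @param tpm genes x samples matrix of TPM values.
#' @param sampleData optional data.frame/DataFrame of per-sample metadata.
#' @return A [TpmExperiment-class] object.
#' @examples
#' te <- TpmExperiment(matrix(1:6, 2, 3,
#'   dimnames = list(c("G1", "G2"), c("a", "b", "c"))))
#' tpm(te)[1, ]
#' @export
TpmExperiment <- function(tpm, sampleData = NULL) {
  tpm <- as.matrix(tpm)
  if (is.null(rownames(tpm))) rownames(tpm) <- paste0("G", seq_len(nrow(tpm)))
  if (is.null(colnames(tpm))) colnames(tpm) <- paste0("S", seq_len(ncol(tpm)))
  if (is.null(sampleData)) {
    cd <- S4Vectors::DataFrame(row.names = colnames(tpm))
  } else {
    cd <- S4Vectors::DataFrame(sampleData, row.names = colnames(tpm))
  }
  se <- SummarizedExperiment(assays = list(tpm = tpm), colData = cd)
  new("TpmExperiment", se)
}

#' Allelic read tallies at one heterozygous site
#'
#' Reference/alternate/other read counts for one assay at one biallelic
#' site.  `kOther` counts reads whose base is neither allele or fell below
#' the base-quality threshold.
#'
#' @slot site character site identifier.
#' @slot chrom character chromosome name.
#' @slot pos integer 1-based position.
#' @slot ref,alt single-character alleles.
#' @slot kRef,kAlt,kOther integer read tallies (all >= 0).
#' @slot assay character assay label (e.g. "H3K27ac", "input").
#' @slot flag character vector of quality flags (e.g. "uncovered").
#' @exportClass AllelicCount
setClass("AllelicCount",
  slots = c(
    site = "character", chrom = "character", pos = "integer",
    ref = "character", alt = "character",
    kRef = "integer", kAlt = "integer", kOther = "integer",
    assay = "character", flag = "character"
  ),
  prototype = list(flag = character(0))
)

setValidity("AllelicCount", function(object) {
  msg <- character()
  if (any(c(object@kRef, object@kAlt, object@kOther) < 0)) {
    msg <- c(msg, "read tallies must be non-negative")
  }
  if (nchar(object@ref) != 1L || nchar(object@alt) != 1L) {
    msg <- c(msg, "'ref' and 'alt' must be single bases")
  }
  if (identical(toupper(object@ref), toupper(object@alt))) {
    msg <- c(msg, "'ref' and 'alt' must differ")
  }
  if (length(msg)) msg else TRUE
})

#' Construct an AllelicCount
#'
#' @param site site identifier.
#' @param kRef,kAlt,kOther read tallies.
#' @param chrom,pos,ref,alt site description (1-based position, single-base
#'   alleles).
#' @param assay assay label.
#' @param flag optional character flags.
#' @return An [AllelicCount-class] object.
#' @examples
#' AllelicCount("rs1", kRef = 35, kAlt = 65, assay = "H3K27ac")
#' @export
AllelicCount <- function(site, kRef, kAlt, kOther = 0L, chrom = "chr14",
                         pos = 1L, ref = "G", alt = "A", assay = "assay",
                         flag = character(0)) {
  new("AllelicCount",
    site = as.character(site), chrom = as.character(chrom),
    pos = as.integer(pos), ref = as.character(ref), alt = as.character(alt),
    kRef = as.integer(kRef), kAlt = as.integer(kAlt),
    kOther = as.integer(kOther), assay = as.character(assay), flag = flag
  )
}

#' Binned Hi-C contact map for one chromosome
#'
#' Sparse upper-triangle storage of normalized contact values between
#' fixed-size genomic bins.  The matrix is symmetrized on construction;
#' conflicting duplicate entries are an error.
#'
#' @slot chrom chromosome name.
#' @slot resolution bin width in base pairs.
#' @slot contacts data.frame with columns `bin_i`, `bin_j` (0-based bin
#'   indices, `bin_i <= bin_j`) and `value` (>= 0).
#' @slot maxBin largest bin index covered by the map (its extent).
#' @seealso [ContactMap()], [contactValue()], [hicLink()]
#' @exportClass ContactMap
setClass("ContactMap",
  slots = c(
    chrom = "character", resolution = "numeric",
    contacts = "data.frame", maxBin = "integer"
  )
)

setValidity("ContactMap", function(object) {
  msg <- character()
  cc <- object@contacts
  if (!all(c("bin_i", "bin_j", "value") %in% names(cc))) {
    msg <- c(msg, "'contacts' needs columns bin_i, bin_j, value")
  } else {
    if (any(cc$value < 0)) msg <- c(msg, "contact values must be >= 0")
    if (any(cc$bin_i > cc$bin_j)) msg <- c(msg, "contacts must be stored with bin_i <= bin_j")
    if (any(cc$bin_i < 0)) msg <- c(msg, "bin indices must be >= 0")
  }
  if (object@resolution <= 0) msg <- c(msg, "'resolution' must be positive")
  if (length(msg)) msg else TRUE
})

#' Construct a ContactMap from contact triples
#'
#' @param contacts data.frame of `bin_i`, `bin_j`, `value` triples in any
#'   bin order; symmetrized on ingest.  A pair given in both orientations
#'   with different values is an error.
#' @param chrom chromosome the map describes.
#' @param resolution bin width in base pairs (> 0).
#' @param maxBin optional map extent; defaults to the largest bin seen.
#' @return A [ContactMap-class] object.
#' @examples
#' cm <- ContactMap(data.frame(bin_i = 2, bin_j = 5, value = 10), "chr14", 5000)
#' contactValue(cm, 5, 2)
#' @export
ContactMap <- function(contacts, chrom, resolution, maxBin = NULL) {
  contacts <- as.data.frame(contacts)
  stopifnot(all(c("bin_i", "bin_j", "value") %in% names(contacts)))
  i <- pmin(contacts$bin_i, contacts$bin_j)
  j <- pmax(contacts$bin_i, contacts$bin_j)
  canon <- data.frame(bin_i = i, bin_j = j, value = contacts$value)
  key <- paste(canon$bin_i, canon$bin_j)
  if (anyDuplicated(key)) {
    agg <- tapply(canon$value, key, function(v) diff(range(v)))
    if (any(agg > 1e-9)) {
      stop("asymmetric duplicate contact entries for bin pair(s): ",
        paste(names(agg)[agg > 1e-9], collapse = ", "))
    }
    canon <- canon[!duplicated(key), , drop = FALSE]
  }
  if (is.null(maxBin)) {
    maxBin <- if (nrow(canon)) max(canon$bin_j) else -1L
  }
  new("ContactMap",
    chrom = as.character(chrom), resolution = as.numeric(resolution),
    contacts = canon, maxBin = as.integer(maxBin)
  )
}
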