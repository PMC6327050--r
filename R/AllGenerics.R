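#' @name regfine-accessors
#' @title Accessors for regfine data classes
#' @description Slot accessors for [GenotypeTable-class],
#'   [TpmExperiment-class], [AllelicCount-class] and [ContactMap-class].
#' @param x a regfine data object.
#' @param ... unused.
#' @return The requested component (matrix, array, character vector or
#'   numeric value).
NULL

#' @rdname regfine-accessors
#' @export
setGeneric("dosages", function(x, ...) standardGeneric("dosages"))

#' @rdname regfine-accessors
#' @export
setGeneric("hardCalls", function(x, ...) standardGeneric("hardCalls"))

#' @rdname regfine-accessors
#' @export
setGeneric("posteriorProbs", function(x, ...) standardGeneric("posteriorProbs"))

#' @rdname regfine-accessors
#' @export
setGeneric("hasPosteriors", function(x, ...) standardGeneric("hasPosteriors"))

#' @rdname regfine-accessors
#' @export
setGeneric("sampleIds", function(x, ...) standardGeneric("sampleIds"))

#' @rdname regfine-accessors
#' @export
setGeneric("variantIds", function(x, ...) standardGeneric("variantIds"))

#' @rdname regfine-accessors
#' @export
setGeneric("tpm", function(x, ...) standardGeneric("tpm"))

#' @rdname regfine-accessors
#' @param i,j bin indices (0-based) for [ContactMap-class] lookup.
#' @export
setGeneric("contactValue", function(x, i, j, ...) standardGeneric("contactValue"))

#' @rdname regfine-accessors
#' @export
setMethod("dosages", "GenotypeTable", function(x, ...) x@dosage)

#' @rdname regfine-accessors
#' @export
setMethod("hardCalls", "GenotypeTable", function(x, ...) x@calls)

#' @rdname regfine-accessors
#' @export
setMethod("posteriorProbs", "GenotypeTable", function(x, ...) {
  if (!length(x@gp)) {
    stop("this GenotypeTable carries no posterior probabilities")
  }
  x@gp
})

#' @rdname regfine-accessors
#' @export
setMethod("hasPosteriors", "GenotypeTable", function(x, ...) length(x@gp) > 0L)

#' @rdname regfine-accessors
#' @export
setMethod("sampleIds", "GenotypeTable", function(x, ...) rownames(x@calls))

#' @rdname regfine-accessors
#' @export
setMethod("variantIds", "GenotypeTable", function(x, ...) colnames(x@calls))

#' @rdname regfine-accessors
#' @export
setMethod("tpm", "TpmExperiment", function(x, ...) assay(x, "tpm"))

#' @rdname regfine-accessors
#' @export
setMethod("contactValue", "ContactMap", function(x, i, j, ...) {
  bi <- pmin(i, j)
  bj <- pmax(i, j)
  if (bi < 0 || bj > x@maxBin) {
    return(NA_real_)
  }
  hit <- x@contacts$bin_i == bi & x@contacts$bin_j == bj
  if (any(hit)) x@contacts$value[which(hit)[1]] else 0
})

setMethod("show", "GenotypeTable", function(object) {
  cat("GenotypeTable:", nrow(object@calls), "samples x",
    ncol(object@calls), "variants",
    if (hasPosteriors(object)) "(with posteriors)" else "", "\n")
})

setMethod("show", "AllelicCount", function(object) {
  n <- object@kRef + object@kAlt
  cat(sprintf(
    "AllelicCount %s [%s:%d %s/%s, %s] ref=%d alt=%d other=%d (alt fraction %.3f)%s\n",
    object@site, object@chrom, object@pos, object@ref, object@alt,
    object@assay, object@kRef, object@kAlt, object@kOther,
    if (n > 0) object@kAlt / n else NA_real_,
    if (length(object@flag)) paste0(" [", paste(object@flag, collapse = ","), "]") else ""
  ))
})

setMethod("show", "ContactMap", function(object) {
  cat("ContactMap:", object@chrom, "at", object@resolution, "bp;",
    nrow(object@contacts), "stored pairs; extent bin", object@maxBin, "\n")
})
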