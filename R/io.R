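#' Read and write pipeline file formats
#'
#' Plain-text interchange: long-format genotype TSV (`sample`, `variant`,
#' `call`, `dosage`, optional `p0`/`p1`/`p2`), gene x sample expression TSV
#' (TPM), BED peaks (0-based half-open, via rtracklayer), TSS TSV (`gene`,
#' `chrom`, `pos`, `strand`), contact triples TSV with a `# chrom=...
#' resolution=...` header, and FASTA sequences (via Biostrings).
#'
#' @param gt,te,map,peaks objects to serialize.
#' @param path file path.
#' @name regfine-io
NULL

#' @rdname regfine-io
#' @export
writeGenotypeTsv <- function(gt, path) {
  stopifnot(is(gt, "GenotypeTable"))
  calls <- hardCalls(gt)
  long <- data.frame(
    sample = rep(rownames(calls), times = ncol(calls)),
    variant = rep(colnames(calls), each = nrow(calls)),
    call = as.vector(calls),
    dosage = as.vector(dosages(gt)))
  if (hasPosteriors(gt)) {
    gp <- posteriorProbs(gt)
    long$p0 <- as.vector(gp[, , 1])
    long$p1 <- as.vector(gp[, , 2])
    long$p2 <- as.vector(gp[, , 3])
  }
  write.table(long, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname regfine-io
#' @export
readGenotypeTsv <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample", "variant", "call", "dosage")
  if (!all(need %in% names(d))) {
    stop("genotype TSV lacks column(s): ", paste(setdiff(need, names(d)), collapse = ", "))
  }
  badCall <- !is.na(d$call) & !d$call %in% 0:2
  if (any(badCall)) {
    stop("invalid hard call at line ", which(badCall)[1] + 1L, " of ", path)
  }
  samples <- unique(d$sample)
  variants <- unique(d$variant)
  shape <- function(col) {
    m <- matrix(NA_real_, length(samples), length(variants),
      dimnames = list(samples, variants))
    m[cbind(match(d$sample, samples), match(d$variant, variants))] <- d[[col]]
    m
  }
  gp <- NULL
  if (all(c("p0", "p1", "p2") %in% names(d))) {
    gp <- array(c(shape("p0"), shape("p1"), shape("p2")),
      dim = c(length(samples), length(variants), 3))
  }
  GenotypeTable(shape("call"), dosage = shape("dosage"), gp = gp)
}

#' @rdname regfine-io
#' @param sampleCols colData columns to serialize alongside the matrix.
#' @export
writeExpressionTsv <- function(te, path, sampleCols = TRUE) {
  stopifnot(is(te, "TpmExperiment"))
  mat <- tpm(te)
  d <- data.frame(gene = rownames(mat), mat, check.names = FALSE)
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (isTRUE(sampleCols) && ncol(colData(te))) {
    meta <- data.frame(sample = colnames(mat),
      as.data.frame(colData(te)), check.names = FALSE)
    write.table(meta, paste0(path, ".samples"), sep = "\t", quote = FALSE,
      row.names = FALSE)
  }
  invisible(path)
}

#' @rdname regfine-io
#' @export
readExpressionTsv <- function(path) {
  d <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(d)[1] != "gene") stop("expression TSV must start with a 'gene' column")
  if (anyDuplicated(d$gene)) {
    stop("duplicated gene id(s) in ", path, ": ",
      paste(unique(d$gene[duplicated(d$gene)]), collapse = ", "))
  }
  mat <- as.matrix(d[, -1, drop = FALSE])
  rownames(mat) <- d$gene
  metaPath <- paste0(path, ".samples")
  sampleData <- NULL
  if (file.exists(metaPath)) {
    meta <- read.delim(metaPath, stringsAsFactors = FALSE)
    sampleData <- meta[match(colnames(mat), meta$sample), -1, drop = FALSE]
  }
  TpmExperiment(mat, sampleData)
}

#' @rdname regfine-io
#' @export
writePeaksBed <- function(peaks, path) {
  rtracklayer::export(peaks, path, format = "BED")
  invisible(path)
}

#' @rdname regfine-io
#' @export
readPeaksBed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  if (!is.null(gr$name)) names(gr) <- gr$name
  gr
}

#' @rdname regfine-io
#' @param tss TSS data.frame (`gene`, `chrom`, `pos`, `strand`).
#' @export
writeTssTsv <- function(tss, path) {
  write.table(tss, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname regfine-io
#' @export
readTssTsv <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene", "chrom", "pos")
  if (!all(need %in% names(d))) {
    stop("TSS TSV lacks column(s): ", paste(setdiff(need, names(d)), collapse = ", "))
  }
  if (any(d$pos < 1)) stop("TSS positions must be >= 1 (1-based)")
  d
}

#' @rdname regfine-io
#' @export
writeContactsTsv <- function(map, path) {
  stopifnot(is(map, "ContactMap"))
  con <- file(path, "w")
  writeLines(sprintf("# chrom=%s resolution=%d", map@chrom,
    as.integer(map@resolution)), con)
  write.table(map@contacts, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  invisible(path)
}

#' @rdname regfine-io
#' @export
readContactsTsv <- function(path) {
  header <- readLines(path, n = 1)
  m <- regmatches(header, regexec("# chrom=(\\S+) resolution=(\\d+)", header))[[1]]
  if (length(m) != 3L) {
    stop("contacts TSV must begin with '# chrom=<name> resolution=<bp>'")
  }
  d <- read.delim(path, skip = 1, stringsAsFactors = FALSE)
  ContactMap(d, chrom = m[2], resolution = as.numeric(m[3]))
}

#' Validate pipeline input files
#'
#' Per-file format checks, distinguishing fatal errors from warnings; the
#' function itself never throws for content problems, it reports them.
#'
#' @param paths named character vector or list of file paths; recognized
#'   names: `genotypes`, `expression`, `peaks`, `tss`, `contacts`, `fasta`.
#' @return data.frame with columns `file`, `level` (`"error"`/`"warning"`),
#'   `message`; zero rows when everything is well-formed.
#' @export
validateInputs <- function(paths) {
  paths <- as.list(paths)
  out <- data.frame(file = character(0), level = character(0),
    message = character(0))
  note <- function(file, level, message) {
    rbind(out, data.frame(file = file, level = level, message = message))
  }
  for (kind in names(paths)) {
    p <- paths[[kind]]
    if (!file.exists(p)) {
      out <- note(p, "error", "file does not exist")
      next
    }
    res <- tryCatch({
      switch(kind,
        genotypes = {
          readGenotypeTsv(p)
          NULL
        },
        expression = {
          readExpressionTsv(p)
          NULL
        },
        peaks = {
          raw <- read.delim(p, header = FALSE, stringsAsFactors = FALSE)
          if (any(raw[[2]] >= raw[[3]])) {
            stop("BED intervals must satisfy start < end")
          }
          NULL
        },
        tss = {
          readTssTsv(p)
          NULL
        },
        contacts = {
          readContactsTsv(p)
          NULL
        },
        fasta = {
          readDNAStringSet(p)
          NULL
        },
        sprintf("unrecognized input kind '%s'", kind)
      )
    }, error = function(e) conditionMessage(e))
    if (is.character(res)) {
      lvl <- if (startsWith(res, "unrecognized")) "warning" else "error"
      out <- note(p, lvl, res)
    }
  }
  out
}
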