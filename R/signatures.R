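#' Read gene signatures from a GMT file
#'
#' GMT is tab-separated: signature name, description, then one gene
#' identifier per field.  Duplicate genes within a line are removed with
#' a warning; an empty gene list or a duplicated signature name is an
#' error.
#'
#' @param path path to a `.gmt` file.
#' @return A [SignatureSet-class].
#' @export
readGMT <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("GMT file '", path, "' contains no signatures")
  sigs <- list()
  for (ln in lines) {
    fields <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3L)
      stop("GMT line for signature '", fields[1],
           "' has an empty gene list")
    nm <- fields[1]
    genes <- fields[-(1:2)]
    genes <- genes[nzchar(genes)]
    if (length(genes) == 0L)
      stop("GMT line for signature '", nm, "' has an empty gene list")
    if (anyDuplicated(genes)) {
      warning(sprintf("signature '%s': %d duplicate gene(s) removed",
                      nm, sum(duplicated(genes))))
      genes <- unique(genes)
    }
    if (nm %in% names(sigs))
      stop("duplicate signature name '", nm, "' in GMT file")
    sigs[[nm]] <- genes
  }
  new("SignatureSet", signatures = sigs)
}

#' Write a SignatureSet to GMT
#'
#' @param x a [SignatureSet-class].
#' @param path output path.
#' @param descriptions optional character vector of per-signature
#'   descriptions (recycled; default "na").
#' @return `path`, invisibly.
#' @export
writeGMT <- function(x, path, descriptions = "na") {
  stopifnot(is(x, "SignatureSet"))
  descriptions <- rep_len(descriptions, length(x))
  lines <- vapply(seq_along(x@signatures), function(i) {
    paste(c(names(x)[i], descriptions[i], x@signatures[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

# Restrict a signature to the genes present in the matrix.  Missing genes
# are dropped with a warning; fewer than minGenes survivors is an error.
.matchSignature <- function(genes, universe, name = "signature",
                            minGenes = 2L) {
  present <- genes[genes %in% universe]
  dropped <- length(genes) - length(present)
  if (dropped > 0L)
    warning(sprintf("%s: %d gene(s) absent from the matrix dropped, %d kept",
                    name, dropped, length(present)))
  if (length(present) < minGenes)
    stop(sprintf("%s: only %d gene(s) present in the matrix (need >= %d)",
                 name, length(present), minGenes))
  present
}
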