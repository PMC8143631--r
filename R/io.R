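#' Read and write the tabular formats used by the screen
#'
#' Plain TSV dialects: the PSM table (candidate proteins
#' semicolon-separated), per-residue disorder tracks, localization tables,
#' per-nucleus measurements, known-substrate lists (one identifier per
#' line), and the protein relative-abundance matrix.
#'
#' @param psm,file,path,x,se,truth objects/paths as appropriate.
#' @return readers return data.frames (or a `SummarizedExperiment` for
#'   [readProteinRA()]); writers return the path invisibly.
#' @name screen-io
NULL

#' @rdname screen-io
#' @export
writePsmTable <- function(psm, file) {
  write.table(psm, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname screen-io
#' @export
readPsmTable <- function(file) {
  psm <- read.delim(file, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("psm_id", "peptide", "proteins", "is_decoy", "posterior")
  miss <- setdiff(need, names(psm))
  if (length(miss))
    stop("PSM table is missing columns: ", paste(miss, collapse = ", "))
  psm$is_decoy <- as.logical(psm$is_decoy)
  psm
}

#' @rdname screen-io
#' @export
writeDisorderTrack <- function(x, file) {
  write.table(x, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname screen-io
#' @export
readDisorderTrack <- function(file)
  read.delim(file, stringsAsFactors = FALSE)

#' @rdname screen-io
#' @export
writeLocalization <- function(x, file) {
  write.table(x, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname screen-io
#' @export
readLocalization <- function(file) {
  x <- read.delim(file, stringsAsFactors = FALSE)
  x$intracellular <- as.logical(x$intracellular)
  x$secreted <- as.logical(x$secreted)
  x
}

#' @rdname screen-io
#' @export
writeNucleusTable <- function(x, file) {
  write.table(x, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname screen-io
#' @export
readNucleusTable <- function(file)
  read.delim(file, stringsAsFactors = FALSE)

#' @rdname screen-io
#' @export
readKnownSubstrates <- function(file) {
  x <- readLines(file)
  x <- trimws(x)
  x[nzchar(x) & !startsWith(x, "#")]
}

#' @rdname screen-io
#' @export
writeProteinRA <- function(se, file) {
  ra <- SummarizedExperiment::assay(se, "ra")
  rd <- SummarizedExperiment::rowData(se)
  out <- data.frame(protein = rownames(se),
                    n_peptides = rd$n_peptides,
                    q_value = rd$q_value,
                    stringsAsFactors = FALSE)
  raDf <- as.data.frame(ra)
  names(raDf) <- paste0("ra_", colnames(ra))
  write.table(cbind(out, raDf), file, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(file)
}

#' @rdname screen-io
#' @export
readProteinRA <- function(file) {
  x <- read.delim(file, stringsAsFactors = FALSE, check.names = FALSE)
  raCols <- grep("^ra_", names(x), value = TRUE)
  ra <- as.matrix(x[, raCols, drop = FALSE])
  colnames(ra) <- sub("^ra_", "", raCols)
  rownames(ra) <- x$protein
  SummarizedExperiment::SummarizedExperiment(
    assays = list(ra = ra),
    rowData = S4Vectors::DataFrame(n_peptides = x$n_peptides,
                                   q_value = x$q_value,
                                   row.names = x$protein))
}

#' @rdname screen-io
#' @export
writeGroundTruth <- function(truth, file) {
  truth$config <- NULL
  jsonlite::write_json(truth, file, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(file)
}
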