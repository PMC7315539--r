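#' Read and write the pipeline's interchange files
#'
#' Tab-separated tables with a header row carry all tabular data; FASTA
#' carries sequence. Expression tables have a \code{gene_id} column followed
#' by the 24 time-point columns \code{t000..t069}.
#'
#' @param file path.
#' @param mat gene x 24 numeric matrix with gene ids as rownames.
#' @return \code{readExpressionMatrix}: a numeric matrix;
#'   \code{readOrthogroups}: a data.frame; \code{readPromoters}: a
#'   \code{DNAStringSet} (names truncated at the first whitespace).
#' @name io
NULL

#' @rdname io
#' @export
writeExpressionMatrix <- function(mat, file) {
  df <- data.frame(gene_id = rownames(mat), mat, check.names = FALSE)
  write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname io
#' @export
readExpressionMatrix <- function(file) {
  df <- read.delim(file, check.names = FALSE)
  stopifnot("gene_id" %in% names(df))
  m <- as.matrix(df[setdiff(names(df), "gene_id")])
  rownames(m) <- df$gene_id
  storage.mode(m) <- "double"
  m
}

#' @rdname io
#' @export
readOrthogroups <- function(file) {
  df <- read.delim(file, check.names = FALSE)
  stopifnot("group_id" %in% names(df))
  df
}

#' @rdname io
#' @export
readPromoters <- function(file) {
  x <- Biostrings::readDNAStringSet(file)
  names(x) <- sub("\\s.*$", "", names(x))
  x
}

#' Bundle an expression matrix as a SummarizedExperiment
#'
#' Convenience container: assay \code{fpkm}, colData with \code{time_h}
#' (hours since lights-on) and \code{day}, species label in metadata.
#'
#' @param mat gene x 24 matrix.
#' @param species species label.
#' @return a \code{\link[SummarizedExperiment]{SummarizedExperiment}}.
#' @export
makeTimeCourse <- function(mat, species = NA_character_) {
  t <- sampleTimes()
  stopifnot(ncol(mat) == length(t))
  SummarizedExperiment::SummarizedExperiment(
    assays = list(fpkm = mat),
    colData = S4Vectors::DataFrame(time_h = t, day = (t %/% 24) + 1L),
    metadata = list(species = species))
}

.assayMatrix <- function(x) {
  if (is(x, "SummarizedExperiment"))
    SummarizedExperiment::assay(x)
  else as.matrix(x)
}

#' Read a simulation configuration from a YAML file
#'
#' Every constructor argument of \code{\link{DielSimConfig}} is accepted as
#' a key; \code{backgroundComposition} may be a per-species list of 4
#' probabilities and \code{plantedMotifs} a list of maps.
#'
#' @param file YAML path.
#' @return a \linkS4class{DielSimConfig}.
#' @export
readSimConfig <- function(file) {
  y <- yaml::read_yaml(file)
  if (!is.null(y$backgroundComposition))
    y$backgroundComposition <- do.call(rbind, lapply(y$backgroundComposition,
                                                     unlist))
  if (!is.null(y$plantedMotifs))
    y$plantedMotifs <- lapply(y$plantedMotifs, function(pm) {
      pm$phaseInterval <- as.numeric(unlist(pm$phaseInterval))
      pm
    })
  known <- names(formals(DielSimConfig))
  bad <- setdiff(names(y), known)
  if (length(bad))
    stop("unknown config keys: ", paste(bad, collapse = ", "))
  do.call(DielSimConfig, y)
}
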