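## On-disk format: delimited text (TSV by default), header row
## Z1..ZJ X1..XK Y GROUP, literal "NA" for missing cells, UTF-8.

#' Write an MR dataset to a delimited text file
#'
#' @param data an [MRData-class].
#' @param path output file path.
#' @param sep field separator (default tab).
#' @return `path`, invisibly.
#' @seealso [readMRData()]
#' @export
writeMRData <- function(data, path, sep = "\t") {
  validObject(data)
  df <- data.frame(data@Z, data@X, Y = data@Y, GROUP = data@group,
    check.names = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE,
    na = "NA", fileEncoding = "UTF-8")
  invisible(path)
}

#' Read an MR dataset from a delimited text file
#'
#' Columns named `Z*` are instruments, `X*` exposures, `Y` the outcome and
#' `GROUP` the group label ("A"/"B"/"C"; reconstructed from the missingness
#' pattern when absent). The missingness pattern is validated against the
#' group labels; a complete-data (group A) row with a missing exposure, for
#' instance, is an error naming the offending row.
#'
#' @param path input file path.
#' @param sep field separator (default tab).
#' @return An [MRData-class].
#' @export
readMRData <- function(path, sep = "\t") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
    na.strings = "NA", check.names = FALSE, fileEncoding = "UTF-8")
  zCols <- grep("^Z", names(df), value = TRUE)
  xCols <- grep("^X", names(df), value = TRUE)
  if (length(zCols) == 0L || length(xCols) == 0L || !"Y" %in% names(df))
    stop("file must have Z*, X* and Y columns: ", path)
  badZ <- which(rowSums(is.na(df[zCols])) > 0L)
  if (length(badZ))
    stop(sprintf("missing instrument value at data row %d of '%s'", badZ[1L], path))
  group <- if ("GROUP" %in% names(df)) as.character(df$GROUP) else NULL
  if (!is.null(group)) {
    xMiss <- rowSums(is.na(df[xCols]))
    partial <- which(xMiss > 0L & xMiss < length(xCols))
    if (length(partial))
      stop(sprintf("partially missing exposures at data row %d of '%s'",
        partial[1L], path))
    bad <- which((group == "A" & (xMiss > 0L | is.na(df$Y))) |
                 (group == "B" & (xMiss > 0L | !is.na(df$Y))) |
                 (group == "C" & (xMiss == 0L | is.na(df$Y))))
    if (length(bad))
      stop(sprintf(
        "group-%s row at data row %d of '%s' violates its missingness pattern",
        group[bad[1L]], bad[1L], path))
  }
  mrData(as.matrix(df[zCols]), as.matrix(df[xCols]), df$Y, group = group)
}
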