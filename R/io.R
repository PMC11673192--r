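#' Read a delimited expression matrix
#'
#' Reads a TSV/CSV expression matrix in either orientation and returns it as
#' an [OmicsMatrix-class] in samples-by-features orientation. TCGA-style
#' RNASeq / miRNA-Seq layouts (features in rows, one identifier column)
#' are covered by `orientation = "features_in_rows"`.
#'
#' Missing tokens (`NA`, empty string) become missing entries; any other
#' non-numeric cell is an error reporting its location.
#'
#' @param path path to a delimited text file with one header row and one
#'   identifier column.
#' @param orientation `"samples_in_rows"` or `"features_in_rows"`.
#' @param omicsName label for the omics layer.
#' @param sep field separator; guessed from the file extension by default
#'   (`.csv` = comma, otherwise tab).
#' @return An [OmicsMatrix-class], samples in rows.
#' @export
readExpressionMatrix <- function(path,
                                 orientation = c("samples_in_rows",
                                                 "features_in_rows"),
                                 omicsName = "omics",
                                 sep = NULL) {
  orientation <- match.arg(orientation)
  if (is.null(sep))
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- read.delim(path, sep = sep, header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE, na.strings = c("NA", ""))
  ids <- as.character(df[[1]])
  df <- df[, -1, drop = FALSE]
  if (anyDuplicated(ids))
    stop("duplicated row identifiers in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (anyDuplicated(colnames(df)))
    stop("duplicated column identifiers in ", path, ": ",
         paste(unique(colnames(df)[duplicated(colnames(df))]), collapse = ", "))
  m <- matrix(NA_real_, nrow(df), ncol(df),
              dimnames = list(ids, colnames(df)))
  for (j in seq_len(ncol(df))) {
    col <- df[[j]]
    if (is.numeric(col)) { m[, j] <- col; next }
    num <- suppressWarnings(as.numeric(col))
    bad <- which(is.na(num) & !is.na(col))
    if (length(bad))
      stop("non-numeric value '", col[bad[1]], "' at row ", bad[1],
           ", column '", colnames(df)[j], "' of ", path)
    m[, j] <- num
  }
  if (orientation == "features_in_rows") m <- t(m)
  omicsMatrix(m, omicsName)
}

#' Write an expression matrix to TSV
#'
#' Inverse of [readExpressionMatrix()] (samples-in-rows orientation, first
#' column `sample_id`).
#'
#' @param x an [OmicsMatrix-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeExpressionMatrix <- function(x, path) {
  v <- omicsValues(x)
  df <- data.frame(sample_id = rownames(v), v, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a survival outcome table
#'
#' Expects columns `sample_id`, `time`, `event`. Rows with non-positive
#' time or an event indicator outside \{0, 1\} are rejected with their row
#' numbers.
#'
#' @param path path to a TSV/CSV file.
#' @param sep field separator; guessed from the extension by default.
#' @return A data.frame with columns `sample_id` (character), `time`
#'   (numeric), `event` (integer).
#' @export
readSurvivalTable <- function(path, sep = NULL) {
  if (is.null(sep))
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- read.delim(path, sep = sep, header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE)
  req <- c("sample_id", "time", "event")
  miss <- setdiff(req, colnames(df))
  if (length(miss))
    stop("survival table ", path, " is missing column(s): ",
         paste(miss, collapse = ", "))
  df <- df[req]
  df$sample_id <- as.character(df$sample_id)
  df$time <- as.numeric(df$time)
  bad <- which(!is.finite(df$time) | df$time <= 0)
  if (length(bad))
    stop("non-positive or missing time at row(s): ",
         paste(bad, collapse = ", "))
  ev <- df$event
  bad <- which(!(ev %in% c(0, 1)))
  if (length(bad))
    stop("event indicator outside {0,1} at row(s): ",
         paste(bad, collapse = ", "))
  if (anyDuplicated(df$sample_id))
    stop("duplicated sample ids in survival table: ",
         paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "))
  df$event <- as.integer(ev)
  df
}

#' Write a survival outcome table to TSV
#'
#' @param survival data.frame with columns `sample_id`, `time`, `event`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeSurvivalTable <- function(survival, path) {
  write.table(survival[c("sample_id", "time", "event")], path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}
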