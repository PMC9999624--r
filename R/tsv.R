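## Tabular results are TSV with a commented ("#"-prefixed) header line.
## Numeric columns are formatted with a fixed rule so that identical inputs
## produce byte-identical files (the determinism contract of run_all()).

#' Write a results table as TSV with a commented header
#'
#' @param df data.frame to write.
#' @param path output file path.
#' @param digits significant digits used for numeric (double) columns.
#' @return `path`, invisibly.
#' @export
write_tsv_c <- function(df, path, digits = 10) {
  df <- as.data.frame(df)
  out <- df
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) out[[j]] <- formatC(out[[j]], digits = digits,
                                                 format = "g")
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#", paste(names(df), collapse = "\t")), con)
  if (nrow(out) > 0)
    writeLines(do.call(paste, c(lapply(out, as.character), sep = "\t")), con)
  invisible(path)
}

#' Read a TSV written by [write_tsv_c()]
#'
#' @param path file path.
#' @return data.frame with the column names from the commented header.
#' @export
read_tsv_c <- function(path) {
  header <- readLines(path, n = 1L)
  if (!startsWith(header, "#"))
    stop("expected a commented header line in ", path)
  cols <- strsplit(sub("^#", "", header), "\t", fixed = TRUE)[[1]]
  df <- read.table(path, sep = "\t", skip = 1L, header = FALSE,
                   col.names = cols, stringsAsFactors = FALSE,
                   comment.char = "", quote = "")
  df
}
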