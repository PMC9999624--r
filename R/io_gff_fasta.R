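## GFF3 annotation and FASTA sequence I/O. Coordinates are 1-based
## inclusive throughout, matching both formats.

#' Read gene-level annotation from a GFF3 file
#'
#' Returns one record per `gene` or `transposable_element` feature, with
#' 1-based inclusive coordinates as in the file.
#'
#' @param path GFF3 file path.
#' @param feature_classes feature types to keep.
#' @return data.frame with columns `gene_id`, `chrom`, `start`, `end`,
#'   `strand`, `feature_class`.
#' @export
read_gff <- function(path, feature_classes = c("gene", "transposable_element")) {
  lines <- readLines(path)
  data_lines <- which(!grepl("^#", lines) & nzchar(trimws(lines)))
  for (i in data_lines) {
    if (length(strsplit(lines[i], "\t", fixed = TRUE)[[1]]) < 9)
      stop(sprintf("read_gff: malformed GFF3 line %d in %s", i, path))
  }
  if (length(data_lines) == 0L)
    return(data.frame(gene_id = character(), chrom = character(),
                      start = integer(), end = integer(),
                      strand = character(), feature_class = character()))
  g <- as.data.frame(rtracklayer::readGFF(path))
  g <- g[g$type %in% feature_classes, , drop = FALSE]
  if (nrow(g) == 0L)
    return(data.frame(gene_id = character(), chrom = character(),
                      start = integer(), end = integer(),
                      strand = character(), feature_class = character()))
  id <- if ("ID" %in% names(g)) as.character(g$ID) else NA_character_
  ann <- data.frame(gene_id = id,
                    chrom = as.character(g$seqid),
                    start = as.integer(g$start),
                    end = as.integer(g$end),
                    strand = as.character(g$strand),
                    feature_class = as.character(g$type),
                    stringsAsFactors = FALSE)
  if (anyDuplicated(ann$gene_id))
    stop("read_gff: duplicate feature IDs")
  if (any(ann$start > ann$end))
    stop("read_gff: feature with start > end")
  ann
}

#' Write gene-level annotation as GFF3
#'
#' @param ann data.frame as returned by [read_gff()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gff <- function(ann, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  if (nrow(ann) > 0)
    writeLines(paste(ann$chrom, "pseudohet", ann$feature_class, ann$start,
                     ann$end, ".", ann$strand, ".",
                     paste0("ID=", ann$gene_id), sep = "\t"), con)
  invisible(path)
}

#' Read / write FASTA sequences
#'
#' Sequences are handled as a named character vector (uppercase ACGTN).
#' `read_fasta(write_fasta(x))` is the identity up to line wrapping.
#'
#' @param path FASTA file path.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  ids <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(ids)) stop("read_fasta: duplicate sequence ids")
  setNames(toupper(as.character(ss)), ids)
}

#' @rdname read_fasta
#' @param seqs named character vector of nucleotide sequences.
#' @export
write_fasta <- function(seqs, path) {
  if (anyDuplicated(names(seqs))) stop("write_fasta: duplicate sequence ids")
  ss <- Biostrings::DNAStringSet(toupper(unname(seqs)))
  names(ss) <- names(seqs)
  Biostrings::writeXStringSet(ss, path, width = 70L)
  invisible(path)
}
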