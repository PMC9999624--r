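## VCF input/output. Parsing is delegated to vcfR; writing emits plain
## sorted VCF 4.2 text. Only biallelic SNPs are kept; heterozygosity is
## defined purely from the GT field (phased "0|1" treated as unphased).

#' Read a VCF into a genotype matrix
#'
#' Loads all biallelic SNP rows of a VCF 4.x file with diploid GT fields.
#' Genotypes are recoded `0/0 -> 0`, `0/1` or `1/0 -> 1`, `1/1 -> 2`,
#' `./. -> -1`; phased separators (`|`) are accepted and treated as
#' unphased. Multi-allelic rows are skipped and counted (attribute
#' `n_skipped`, also reported via `message()`).
#'
#' @param path path to a VCF file.
#' @return a [genotype_matrix()] with attribute `n_skipped` (count of
#'   skipped multi-allelic rows).
#' @export
read_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  n <- nrow(fix)
  accessions <- colnames(v@gt)[-1]
  if (n == 0L) {
    gm <- genotype_matrix(
      map = data.frame(chrom = character(), pos = integer(),
                       id = character(), ref = character(),
                       alt = character()),
      calls = matrix(integer(), 0, length(accessions)),
      accessions = as.character(accessions))
    attr(gm, "n_skipped") <- 0L
    return(gm)
  }
  alt <- fix[, "ALT"]
  ref <- fix[, "REF"]
  biallelic <- !grepl(",", alt, fixed = TRUE) &
    nchar(ref) == 1L & nchar(alt) == 1L & !is.na(alt)
  n_skipped <- sum(!biallelic)
  if (n_skipped > 0)
    message(sprintf("read_vcf: skipped %d non-biallelic-SNP row(s)",
                    n_skipped))
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = n)
  gt <- gt[biallelic, , drop = FALSE]
  fix <- fix[biallelic, , drop = FALSE]
  gt_clean <- gsub("|", "/", gt, fixed = TRUE)
  codes <- c("0/0" = 0L, "0/1" = 1L, "1/0" = 1L, "1/1" = 2L, "./." = -1L)
  calls <- codes[gt_clean]
  calls[is.na(gt_clean)] <- -1L
  unknown <- is.na(calls)
  if (any(unknown)) {
    bad <- gt_clean[unknown][1]
    if (!grepl("^[0-9.]+/[0-9.]+$", bad) || grepl("/.+/", gt[unknown][1]))
      stop("read_vcf: non-diploid or malformed GT field: ", gt[unknown][1])
    stop("read_vcf: unsupported GT field: ", gt[unknown][1])
  }
  calls <- matrix(calls, nrow = nrow(gt), ncol = ncol(gt))
  id <- fix[, "ID"]
  no_id <- is.na(id) | id == "."
  id[no_id] <- snp_id(fix[no_id, "CHROM"], fix[no_id, "POS"])
  map <- data.frame(chrom = fix[, "CHROM"], pos = as.integer(fix[, "POS"]),
                    id = id, ref = fix[, "REF"], alt = fix[, "ALT"],
                    stringsAsFactors = FALSE)
  gm <- genotype_matrix(map, calls, as.character(accessions))
  attr(gm, "n_skipped") <- n_skipped
  gm
}

#' Write a genotype matrix as VCF
#'
#' Emits a sorted VCF 4.2 file readable by [read_vcf()]; `read_vcf(write_vcf(gm))`
#' reproduces `gm` field by field.
#'
#' @param gm a [genotype_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(gm, path) {
  validate_genotype_matrix(gm)
  con <- tryCatch(file(path, "w"), error = function(e)
    stop("write_vcf: cannot open ", path, ": ", conditionMessage(e)))
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=pseudohet",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">'),
             con)
  writeLines(paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", gm$accessions), collapse = "\t"), con)
  if (nrow(gm$map) > 0) {
    gt_code <- c("./.", "0/0", "0/1", "1/1")
    gt <- matrix(gt_code[gm$calls + 2L], nrow = nrow(gm$calls))
    body <- do.call(paste, c(list(gm$map$chrom, gm$map$pos, gm$map$id,
                                  gm$map$ref, gm$map$alt, ".", ".", ".",
                                  "GT"),
                             as.data.frame(gt), list(sep = "\t")))
    writeLines(body, con)
  }
  invisible(path)
}
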