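## Core container: accessions x biallelic SNPs with calls coded
## 0 = hom-ref, 1 = het, 2 = hom-alt, -1 = missing.

#' Construct a genotype matrix
#'
#' The central container of the package: an ordered set of biallelic SNPs
#' (rows) by accessions (columns), with integer calls `0` (homozygous
#' reference), `1` (heterozygous), `2` (homozygous alternate) and `-1`
#' (missing). In a selfing species the expectation is that no call is `1`;
#' heterozygous calls are the pseudo-SNP signal the rest of the package
#' works on.
#'
#' @param map data.frame with columns `chrom`, `pos` (1-based), `id`,
#'   `ref`, `alt`; one row per SNP, sorted by (`chrom`, `pos`).
#' @param calls integer matrix, `nrow(map)` x `length(accessions)`, values
#'   in `{-1, 0, 1, 2}`.
#' @param accessions character vector of unique accession ids.
#' @return An object of class `genotype_matrix`: a list with elements
#'   `map`, `calls`, `accessions`.
#' @examples
#' gm <- genotype_matrix(
#'   map = data.frame(chrom = "chr1", pos = 100L, id = "chr1_100",
#'                    ref = "A", alt = "G"),
#'   calls = matrix(c(0L, 1L, 2L), 1, 3),
#'   accessions = c("acc1", "acc2", "acc3"))
#' gm
#' @export
genotype_matrix <- function(map, calls, accessions) {
  stopifnot(is.data.frame(map), is.matrix(calls))
  map <- as.data.frame(map)
  required <- c("chrom", "pos", "id", "ref", "alt")
  if (!all(required %in% names(map)))
    stop("map must have columns: ", paste(required, collapse = ", "))
  if (!is.character(accessions) || anyDuplicated(accessions))
    stop("accession ids must be unique character strings")
  storage.mode(calls) <- "integer"
  if (nrow(calls) != nrow(map) || ncol(calls) != length(accessions))
    stop("calls must be nrow(map) x length(accessions)")
  bad <- !(calls %in% c(-1L, 0L, 1L, 2L))
  if (any(bad)) stop("calls must be in {-1, 0, 1, 2}")
  map$pos <- as.integer(map$pos)
  map$chrom <- as.character(map$chrom)
  if (any(map$pos < 1L)) stop("positions must be >= 1")
  if (any(map$ref == map$alt)) stop("ref and alt alleles must differ")
  gm <- structure(list(map = map, calls = calls,
                       accessions = as.character(accessions)),
                  class = "genotype_matrix")
  validate_genotype_matrix(gm)
  gm
}

#' Validate genotype-matrix invariants
#'
#' Checks sortedness (strictly increasing positions within chromosome),
#' uniqueness of (chrom, pos) and accession ids, and call coding.
#'
#' @param gm a `genotype_matrix`.
#' @return `gm`, invisibly; errors on violation.
#' @export
validate_genotype_matrix <- function(gm) {
  stopifnot(inherits(gm, "genotype_matrix"))
  map <- gm$map
  if (nrow(map) > 0L) {
    by_chr <- split(seq_len(nrow(map)), factor(map$chrom, unique(map$chrom)))
    for (idx in by_chr) {
      p <- map$pos[idx]
      if (is.unsorted(p, strictly = TRUE)) {
        bad <- idx[which(diff(p) <= 0)[1] + 1L]
        stop(sprintf(
          "SNPs not strictly sorted: record %d (%s:%d) out of order",
          bad, map$chrom[bad], map$pos[bad]))
      }
    }
  }
  invisible(gm)
}

#' @export
print.genotype_matrix <- function(x, ...) {
  n_het <- sum(x$calls == 1L)
  cat(sprintf(
    "genotype_matrix: %d SNPs x %d accessions (%d chromosome%s), %d het call%s\n",
    nrow(x$map), length(x$accessions), length(unique(x$map$chrom)),
    if (length(unique(x$map$chrom)) == 1) "" else "s",
    n_het, if (n_het == 1) "" else "s"))
  invisible(x)
}

#' Number of SNPs / accessions
#' @param gm a `genotype_matrix`.
#' @return integer count.
#' @export
n_snps <- function(gm) nrow(gm$map)

#' @rdname n_snps
#' @export
n_accessions <- function(gm) length(gm$accessions)

#' Subset a genotype matrix by SNP index
#' @param gm a `genotype_matrix`.
#' @param i integer or logical index over SNPs.
#' @return a `genotype_matrix` with the selected rows.
#' @export
subset_snps <- function(gm, i) {
  genotype_matrix(gm$map[i, , drop = FALSE],
                  gm$calls[i, , drop = FALSE],
                  gm$accessions)
}

## internal: default SNP id
snp_id <- function(chrom, pos) paste(chrom, pos, sep = "_")
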