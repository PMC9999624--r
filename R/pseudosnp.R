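## Pseudo-SNP filtering: from all heterozygous calls to the core set of
## common, genic pseudo-SNPs; binary phenotypes for the association scan;
## rare-variant enrichment in already-identified duplicated genes.

#' Filter the core pseudo-SNP set
#'
#' Applies the two filtering steps that define the core pseudo-SNP set:
#' keep heterozygous SNPs whose heterozygote frequency is at least
#' `freq_threshold` of the population, and that lie within an annotated
#' gene feature. The per-stage counts (total SNPs, het SNPs, frequency
#' pass, genic pass) are recorded as attribute `funnel`.
#'
#' @param gm a [genotype_matrix()].
#' @param annotation data.frame from [read_gff()].
#' @param freq_threshold minimum het frequency (inclusive; "at least 5%
#'   of the population" by default).
#' @param denominator `"all"` (default; frequency out of all accessions)
#'   or `"nonmissing"`.
#' @param feature_classes annotation feature classes that count as genic.
#' @return data.frame with columns `id`, `chrom`, `pos`, `het_count`,
#'   `het_frequency`, `gene_id`; attribute `funnel` holds the stage
#'   counts.
#' @export
filter_pseudo_snps <- function(gm, annotation, freq_threshold = 0.05,
                               denominator = c("all", "nonmissing"),
                               feature_classes = "gene") {
  denominator <- match.arg(denominator)
  hs <- summarize_het(gm, denominator = denominator)
  is_het <- hs$het_count > 0
  freq_ok <- is_het & !is.na(hs$het_frequency) &
    hs$het_frequency >= freq_threshold
  ann <- annotation[annotation$feature_class %in% feature_classes, ,
                    drop = FALSE]
  gene_id <- rep(NA_character_, nrow(hs))
  if (nrow(ann) > 0 && nrow(hs) > 0) {
    ov <- IRanges::findOverlaps(
      IRanges::IRanges(hs$pos, hs$pos),
      IRanges::IRanges(ann$start, ann$end))
    qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
    same_chr <- hs$chrom[qh] == ann$chrom[sh]
    gene_id[qh[same_chr]] <- ann$gene_id[sh[same_chr]]
  }
  keep <- freq_ok & !is.na(gene_id)
  out <- data.frame(id = hs$id, chrom = hs$chrom, pos = hs$pos,
                    het_count = hs$het_count,
                    het_frequency = hs$het_frequency,
                    gene_id = gene_id,
                    stringsAsFactors = FALSE)[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "funnel") <- data.frame(
    stage = c("total_snps", "het_snps", "freq_pass", "genic_pass"),
    count = c(nrow(hs), sum(is_het), sum(freq_ok), sum(keep)))
  out
}

#' Binary heterozygosity phenotype for one SNP
#'
#' Heterozygosity at the focal SNP coded 1 (present) / 0 (absent), the
#' phenotype fed to the mixed-model scan.
#'
#' @param gm a [genotype_matrix()].
#' @param snp_id focal SNP id.
#' @param missing_as how missing calls are coded: `"zero"` (default) or
#'   `"na"` (excluded from the model fit).
#' @return named numeric vector over accessions with attribute `snp_id`.
#' @export
make_phenotype <- function(gm, snp_id, missing_as = c("zero", "na")) {
  missing_as <- match.arg(missing_as)
  s <- match(snp_id, gm$map$id)
  if (is.na(s)) stop("make_phenotype: unknown SNP id: ", snp_id)
  v <- gm$calls[s, ]
  y <- as.numeric(v == 1L)
  if (missing_as == "na") y[v == -1L] <- NA_real_
  names(y) <- gm$accessions
  attr(y, "snp_id") <- snp_id
  y
}

#' Enrichment of rare pseudo-SNPs in duplicated genes
#'
#' Tests whether singleton (het in exactly 1 accession) or doubleton
#' (exactly 2) heterozygous SNPs fall inside an already-identified set of
#' duplicated genes more often than expected from the fraction of genic
#' SNP positions those genes contain. One-sided exact binomial test.
#'
#' @param gm a [genotype_matrix()].
#' @param duplicated_genes character vector of gene ids.
#' @param annotation data.frame from [read_gff()].
#' @param multiplicity `"singleton"` or `"doubleton"`.
#' @return list with `observed` (fraction of rare het SNPs in duplicated
#'   genes), `expected` (fraction of genic SNP positions in duplicated
#'   genes), `p_value`, `n_rare`, and `undefined` (no rare SNPs).
#' @export
rare_enrichment <- function(gm, duplicated_genes, annotation,
                            multiplicity = c("singleton", "doubleton")) {
  multiplicity <- match.arg(multiplicity)
  target_count <- if (multiplicity == "singleton") 1L else 2L
  hs <- summarize_het(gm)
  ann <- annotation[annotation$feature_class == "gene", , drop = FALSE]
  gene_of <- rep(NA_character_, nrow(hs))
  if (nrow(ann) > 0 && nrow(hs) > 0) {
    ov <- IRanges::findOverlaps(IRanges::IRanges(hs$pos, hs$pos),
                                IRanges::IRanges(ann$start, ann$end))
    qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
    same_chr <- hs$chrom[qh] == ann$chrom[sh]
    gene_of[qh[same_chr]] <- ann$gene_id[sh[same_chr]]
  }
  genic <- !is.na(gene_of)
  expected <- sum(genic & gene_of %in% duplicated_genes) / sum(genic)
  rare <- hs$het_count == target_count & genic
  n_rare <- sum(rare)
  if (n_rare == 0)
    return(list(observed = NA_real_, expected = expected, p_value = NA_real_,
                n_rare = 0L, undefined = TRUE))
  x <- sum(rare & gene_of %in% duplicated_genes)
  list(observed = x / n_rare, expected = expected,
       p_value = binom.test(x, n_rare, p = expected,
                            alternative = "greater")$p.value,
       n_rare = n_rare, undefined = FALSE)
}
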