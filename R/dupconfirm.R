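## Confirmation of predicted duplications in assembled genomes:
## peak-position anchoring, the within-20-kb confirmation rule,
## copy-number estimation (alignment match count and coverage ratio),
## flank-gene synteny, and read-pair insertion-presence calls.

#' Map a reference position into an assembled genome
#'
#' Anchors the `2 * halfwidth` reference segment centered on `pos` in the
#' target genome by local alignment and returns the implied position of
#' `pos` in the target's coordinates (center of the best anchor match).
#'
#' @param reference named character vector (reference genome).
#' @param chrom,pos reference location.
#' @param genome named character vector (assembled genome).
#' @param halfwidth anchor segment half-width (bp).
#' @param params an [align_params()].
#' @return list `target`, `pos`, or `NULL` when the segment cannot be
#'   anchored.
#' @export
anchor_position <- function(reference, chrom, pos, genome,
                            halfwidth = 2500L, params = align_params()) {
  seqlen <- nchar(reference[[chrom]])
  s <- max(1L, pos - halfwidth); e <- min(seqlen, pos + halfwidth)
  segment <- substr(reference[[chrom]], s, e)
  hits <- align_search(segment, genome, min_identity = 70, min_cov = 0.5,
                       params = params)
  if (nrow(hits) == 0) return(NULL)
  best <- hits[1, ]
  ## place `pos` proportionally inside the matched query interval
  offset <- (pos - s + 1L) - best$qstart
  list(target = best$target,
       pos = as.integer(best$tstart + max(0L, min(offset,
                                                  best$tend - best$tstart))))
}

#' Confirm a predicted duplication in an assembled genome
#'
#' Maps the predicted peak position into the accession genome by segment
#' anchoring, searches for the gene sequence, and calls the prediction
#' confirmed when a match center lies within `radius` of the mapped peak
#' position. When the source locus is supplied, a second call excluding
#' matches at the mapped source position is reported (the meaningful
#' criterion for trans duplications, where the syntenic ortholog itself
#' is not evidence of a duplicate).
#'
#' @param gene_seq nucleotide sequence of the gene (reference allele).
#' @param peak_chrom,peak_pos predicted duplicate location (reference
#'   coordinates).
#' @param genome assembled genome (named character vector).
#' @param reference reference genome (named character vector).
#' @param radius confirmation radius (bp).
#' @param source_chrom,source_pos optional source-locus location used for
#'   the syntenic-exclusion call.
#' @param min_identity,min_cov alignment thresholds.
#' @param anchor_halfwidth half-width (bp) of the reference segments used
#'   to map positions into the assembly.
#' @param params an [align_params()].
#' @return list: `confirmed`, `confirmed_excluding_source`, `mapped_pos`,
#'   `mapped_target`, `n_matches`, `matches`.
#' @export
confirm_prediction <- function(gene_seq, peak_chrom, peak_pos, genome,
                               reference, radius = 20000L,
                               source_chrom = NULL, source_pos = NULL,
                               min_identity = 70, min_cov = 0.70,
                               anchor_halfwidth = 2500L,
                               params = align_params()) {
  anchor <- anchor_position(reference, peak_chrom, peak_pos, genome,
                            halfwidth = anchor_halfwidth, params = params)
  matches <- align_search(gene_seq, genome, min_identity, min_cov, params)
  if (is.null(anchor))
    return(list(confirmed = FALSE, confirmed_excluding_source = FALSE,
                mapped_pos = NA_integer_, mapped_target = NA_character_,
                n_matches = nrow(matches), matches = matches))
  centers <- (matches$tstart + matches$tend) / 2
  near_peak <- matches$target == anchor$target &
    abs(centers - anchor$pos) <= radius
  excl <- rep(FALSE, nrow(matches))
  if (!is.null(source_chrom)) {
    src_anchor <- anchor_position(reference, source_chrom, source_pos,
                                  genome, halfwidth = anchor_halfwidth,
                                  params = params)
    if (!is.null(src_anchor))
      excl <- matches$target == src_anchor$target &
        abs(centers - src_anchor$pos) <= radius
  }
  list(confirmed = any(near_peak),
       confirmed_excluding_source = any(near_peak & !excl),
       mapped_pos = anchor$pos, mapped_target = anchor$target,
       n_matches = nrow(matches), matches = matches)
}

#' Copy-number estimate for a gene in an assembled genome
#'
#' Combines the alignment match count (category `0`, `1` or `>1`) with a
#' read-depth ratio: mean depth over the gene's coverage windows divided
#' by the genome-wide median window depth (about 2 for a collapsed
#' two-copy gene).
#'
#' @param gene_seq gene nucleotide sequence.
#' @param genome assembled genome (named character vector).
#' @param depth_table optional data.frame of window depths (`accession`
#'   optional; `chrom`, `start`, `end`, `depth`) from collapsed mapping.
#' @param gene_chrom,gene_start,gene_end gene interval in the depth
#'   table's coordinates.
#' @param min_identity,min_cov alignment thresholds.
#' @param params an [align_params()].
#' @return list: `n_matches`, `category`, `coverage_ratio` (NA without a
#'   depth table), `matches`.
#' @export
copy_number <- function(gene_seq, genome, depth_table = NULL,
                        gene_chrom = NULL, gene_start = NULL,
                        gene_end = NULL, min_identity = 70, min_cov = 0.70,
                        params = align_params()) {
  matches <- align_search(gene_seq, genome, min_identity, min_cov, params)
  n <- nrow(matches)
  ratio <- NA_real_
  if (!is.null(depth_table)) {
    stopifnot(!is.null(gene_chrom), !is.null(gene_start), !is.null(gene_end))
    over <- depth_table$chrom == gene_chrom &
      depth_table$start <= gene_end & depth_table$end >= gene_start
    if (any(over))
      ratio <- mean(depth_table$depth[over]) / median(depth_table$depth)
  }
  list(n_matches = n,
       category = if (n == 0) "0" else if (n == 1) "1" else ">1",
       coverage_ratio = ratio, matches = matches)
}

#' Flank-gene synteny table
#'
#' Aligns the `n_flank` annotated genes upstream and downstream of a
#' focal gene into an assembled genome, keeping matches covering at least
#' `min_frac` of the input sequence, to expose the local structure around
#' a duplication (collinear single matches for an unrearranged region;
#' extra focal-gene copies between single-match flanks for a tandem
#' array).
#'
#' @param gene_id focal gene.
#' @param annotation data.frame from [read_gff()].
#' @param reference reference genome providing flank sequences.
#' @param genome assembled genome searched.
#' @param n_flank flank genes on each side.
#' @param min_identity minimum percent identity.
#' @param min_frac minimum aligned fraction of the input sequence.
#' @param params an [align_params()].
#' @return data.frame with one row per flank-gene match (plus `n_matches
#'   = 0` rows for unmatched flanks): `flank_gene`, `side`, `rank`,
#'   `n_matches`, `target`, `tstart`, `tend`, `strand`,
#'   `percent_identity`, `query_coverage`.
#' @export
flank_synteny <- function(gene_id, annotation, reference, genome,
                          n_flank = 3L, min_identity = 70, min_frac = 0.5,
                          params = align_params()) {
  ann <- annotation[annotation$feature_class == "gene", , drop = FALSE]
  focal <- ann[ann$gene_id == gene_id, ]
  if (nrow(focal) != 1) stop("flank_synteny: unknown gene ", gene_id)
  same <- ann[ann$chrom == focal$chrom, ]
  up <- same[same$end < focal$start, ]
  up <- up[order(-up$end), ][seq_len(min(n_flank, sum(same$end < focal$start))), ,
                             drop = FALSE]
  down <- same[same$start > focal$end, ]
  down <- down[order(down$start), ][seq_len(min(n_flank,
                                                sum(same$start > focal$end))), ,
                                    drop = FALSE]
  tag_side <- function(df, side) {
    if (nrow(df) == 0) return(NULL)
    cbind(df, side = side, rank = seq_len(nrow(df)))
  }
  probe <- rbind(tag_side(up, "upstream"), tag_side(down, "downstream"))
  if (is.null(probe))
    return(data.frame(flank_gene = character(), side = character(),
                      rank = integer(), n_matches = integer(),
                      target = character(), tstart = integer(),
                      tend = integer(), strand = character(),
                      percent_identity = numeric(),
                      query_coverage = numeric()))
  rows <- list(); k <- 0L
  for (i in seq_len(nrow(probe))) {
    g <- probe[i, ]
    seq_i <- substr(reference[[g$chrom]], g$start, g$end)
    hits <- align_search(seq_i, genome, min_identity = min_identity,
                         min_cov = min_frac, params = params)
    k <- k + 1L
    if (nrow(hits) == 0) {
      rows[[k]] <- data.frame(flank_gene = g$gene_id, side = g$side,
                              rank = g$rank, n_matches = 0L,
                              target = NA_character_, tstart = NA_integer_,
                              tend = NA_integer_, strand = NA_character_,
                              percent_identity = NA_real_,
                              query_coverage = NA_real_,
                              stringsAsFactors = FALSE)
    } else {
      rows[[k]] <- data.frame(flank_gene = g$gene_id, side = g$side,
                              rank = g$rank, n_matches = nrow(hits),
                              target = hits$target, tstart = hits$tstart,
                              tend = hits$tend, strand = hits$strand,
                              percent_identity = hits$percent_identity,
                              query_coverage = hits$query_coverage,
                              stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Insertion presence from junction-spanning read pairs
#'
#' A pair spans the insertion border when mate 1 ends before the junction
#' and mate 2 starts after it; the insertion is called present with at
#' least `min_pairs` spanning pairs.
#'
#' @param pairs data.frame with columns `m1_start`, `m1_end`, `m2_start`,
#'   `m2_end` (one accession's pairs; see [emit_read_pairs()]).
#' @param junction junction position on the pair coordinate system.
#' @param min_pairs minimum spanning pairs.
#' @return list: `present` (`"present"`/`"absent"`), `spanning` count.
#' @export
insertion_present <- function(pairs, junction, min_pairs = 3L) {
  spanning <- sum(pairs$m1_end < junction & pairs$m2_start > junction)
  list(present = if (spanning >= min_pairs) "present" else "absent",
       spanning = as.integer(spanning))
}
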