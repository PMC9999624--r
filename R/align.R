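## Seed-and-extend local alignment search: exact k-mer seeds located with
## Biostrings::matchPDict, seeds clustered by diagonal, each candidate
## window extended with an affine-gap Smith-Waterman (src/align.cpp), and
## fragmentary hits on the same target chained before coverage
## computation. Percent identity is computed over alignment columns,
## including gaps (BLAST-style).

#' Alignment scoring parameters
#'
#' @param match,mismatch,gap_open,gap_ext alignment scores; a gap of
#'   length k costs `gap_open + k * gap_ext`.
#' @param k exact seed length.
#' @param chain_gap maximum target-interval gap (bp) across which two
#'   same-strand fragmentary hits of one copy are chained.
#' @param window_margin bp added on each side of a seeded candidate
#'   window before extension.
#' @return list of class `align_params`.
#' @export
align_params <- function(match = 1, mismatch = -2, gap_open = 5,
                         gap_ext = 2, k = 15L, chain_gap = 1000L,
                         window_margin = 100L) {
  structure(list(match = match, mismatch = mismatch, gap_open = gap_open,
                 gap_ext = gap_ext, k = as.integer(k),
                 chain_gap = as.integer(chain_gap),
                 window_margin = as.integer(window_margin)),
            class = "align_params")
}

## internal: exact numeric hash of every k-mer (2 bits/base, k <= 26 fits
## a double exactly); NA for k-mers containing non-ACGT letters
kmer_hashes <- function(s, k) {
  code <- rep(NA_real_, 256)
  code[utf8ToInt("A")] <- 0; code[utf8ToInt("C")] <- 1
  code[utf8ToInt("G")] <- 2; code[utf8ToInt("T")] <- 3
  v <- code[utf8ToInt(s)]
  if (length(v) < k) return(numeric(0))
  h <- stats::filter(v, 4^(0:(k - 1)), method = "convolution", sides = 1)
  as.numeric(h[k:length(v)])
}

#' Precompute a genome k-mer index for repeated searches
#'
#' Hashing the target genome dominates [align_search()] runtime when many
#' queries probe the same genome; an index computes it once. Any function
#' taking a `genome` argument also accepts a `genome_index`.
#'
#' @param genome named character vector of target sequences.
#' @param k seed length (must match the [align_params()] used later).
#' @return an object of class `genome_index`.
#' @export
genome_index <- function(genome, k = 15L) {
  seqs <- vapply(genome, toupper, character(1))
  structure(list(seqs = seqs,
                 hash = lapply(seqs, kmer_hashes, k = k),
                 k = as.integer(k)),
            class = "genome_index")
}

## internal: seed hits of `query` k-mers in a target (exact matches via
## hash lookup; duplicated query k-mers resolve to their first position,
## which is enough to build candidate windows)
seed_hits <- function(query_hash, target_hash) {
  m <- match(target_hash, query_hash)
  t_pos <- which(!is.na(m))
  q_pos <- m[t_pos]
  data.frame(q = q_pos, t = t_pos, d = t_pos - q_pos + 1L)
}

## internal: cluster seed hits into candidate windows
cluster_seeds <- function(hits, qlen, band = 50L, margin = 100L) {
  if (nrow(hits) == 0) return(list())
  hits <- hits[order(hits$d, hits$t), ]
  grp <- cumsum(c(1L, diff(hits$d) > band))
  out <- list()
  for (g in split(hits, grp)) {
    ## split a diagonal group at large target jumps (distinct copies)
    g <- g[order(g$t), ]
    sub <- cumsum(c(1L, diff(g$t) > qlen + 2L * margin))
    for (h in split(g, sub)) {
      out[[length(out) + 1L]] <- c(
        start = min(h$d) - margin,
        end = max(h$t) + (qlen - min(h$q)) + margin)
    }
  }
  out
}

#' Local alignment search of a query in a genome
#'
#' Finds all occurrences of `query` in `genome` (both strands) passing
#' the identity and query-coverage thresholds; the defaults implement the
#' 70% identity / 70% length confirmation rule. Fragmentary same-strand
#' hits closer than `chain_gap` on the target whose query intervals are
#' essentially disjoint are chained into one match before coverage is
#' computed.
#'
#' @param query nucleotide string (length at least the seed size `k`).
#' @param genome named character vector of target sequences (see
#'   [read_fasta()]), or a [genome_index()] when many queries probe the
#'   same genome.
#' @param min_identity minimum percent identity (matched bases /
#'   alignment columns x 100).
#' @param min_cov minimum query coverage (aligned query length / query
#'   length).
#' @param params an [align_params()].
#' @return data.frame sorted by decreasing score: `target`, `tstart`,
#'   `tend`, `strand`, `percent_identity`, `query_coverage`, `score`,
#'   `qstart`, `qend`, `n_fragments`.
#' @export
align_search <- function(query, genome, min_identity = 70, min_cov = 0.70,
                         params = align_params()) {
  query <- toupper(query)
  qlen <- nchar(query)
  if (qlen < params$k)
    stop("align_search: query shorter than seed length k = ", params$k)
  if (inherits(genome, "genome_index")) {
    if (genome$k != params$k)
      stop("align_search: genome_index built with a different seed length")
    index <- genome
  } else {
    index <- genome_index(genome, params$k)
  }
  queries <- c("+" = query,
               "-" = as.character(
                 Biostrings::reverseComplement(Biostrings::DNAString(query))))
  q_hash <- lapply(queries, kmer_hashes, k = params$k)
  rows <- list(); kk <- 0L
  for (tg in names(index$seqs)) {
    tseq <- index$seqs[[tg]]
    tlen <- nchar(tseq)
    t_hash <- index$hash[[tg]]
    for (strand in c("+", "-")) {
      q <- queries[[strand]]
      hits <- seed_hits(q_hash[[strand]], t_hash)
      windows <- cluster_seeds(hits, qlen, margin = params$window_margin)
      for (w in windows) {
        ws <- max(1L, as.integer(w["start"]))
        we <- min(tlen, as.integer(w["end"]))
        aln <- .sw_align(q, substr(tseq, ws, we), params$match,
                         params$mismatch, params$gap_open, params$gap_ext)
        if (aln$score <= 0) next
        kk <- kk + 1L
        rows[[kk]] <- data.frame(
          target = tg, tstart = ws + aln$tstart - 1L,
          tend = ws + aln$tend - 1L, strand = strand,
          matches = aln$matches, columns = aln$columns,
          score = aln$score, qstart = aln$qstart, qend = aln$qend,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (kk == 0) return(empty_matches())
  m <- do.call(rbind, rows)
  ## map minus-strand query coords back to the original query orientation
  minus <- m$strand == "-"
  if (any(minus)) {
    qs <- qlen - m$qend[minus] + 1L
    qe <- qlen - m$qstart[minus] + 1L
    m$qstart[minus] <- qs; m$qend[minus] <- qe
  }
  m <- dedupe_matches(m)
  m <- chain_matches(m, qlen, params$chain_gap)
  m$percent_identity <- 100 * m$matches / m$columns
  m$query_coverage <- m$q_span / qlen
  m <- m[m$percent_identity >= min_identity & m$query_coverage >= min_cov, ,
         drop = FALSE]
  m <- m[order(-m$score, m$target, m$tstart), , drop = FALSE]
  rownames(m) <- NULL
  m[, c("target", "tstart", "tend", "strand", "percent_identity",
        "query_coverage", "score", "qstart", "qend", "n_fragments")]
}

empty_matches <- function() {
  data.frame(target = character(), tstart = integer(), tend = integer(),
             strand = character(), percent_identity = numeric(),
             query_coverage = numeric(), score = numeric(),
             qstart = integer(), qend = integer(), n_fragments = integer())
}

## internal: drop duplicate / heavily target-overlapping hits of one copy
dedupe_matches <- function(m) {
  keep <- rep(TRUE, nrow(m))
  ord <- order(-m$score)
  for (a in ord) {
    if (!keep[a]) next
    same <- which(keep & m$target == m$target[a] & m$strand == m$strand[a] &
                  seq_len(nrow(m)) != a)
    for (b in same) {
      ov <- min(m$tend[a], m$tend[b]) - max(m$tstart[a], m$tstart[b]) + 1L
      la <- m$tend[a] - m$tstart[a] + 1L
      lb <- m$tend[b] - m$tstart[b] + 1L
      if (ov > 0 && ov >= 0.5 * min(la, lb) && m$score[b] <= m$score[a])
        keep[b] <- FALSE
    }
  }
  m[keep, , drop = FALSE]
}

## internal: chain fragmentary same-copy hits (disjoint query intervals,
## nearby on the target) into one match
chain_matches <- function(m, qlen, chain_gap) {
  m$q_span <- m$qend - m$qstart + 1L
  m$n_fragments <- 1L
  if (nrow(m) <= 1) return(m)
  repeat {
    merged <- FALSE
    m <- m[order(m$target, m$strand, m$tstart), , drop = FALSE]
    i <- 1L
    while (i < nrow(m)) {
      a <- i; b <- i + 1L
      gap <- m$tstart[b] - m$tend[a]
      q_ov <- min(m$qend[a], m$qend[b]) - max(m$qstart[a], m$qstart[b]) + 1L
      if (m$target[a] == m$target[b] && m$strand[a] == m$strand[b] &&
          gap <= chain_gap &&
          q_ov <= 0.25 * min(m$q_span[a], m$q_span[b])) {
        m$tend[a] <- max(m$tend[a], m$tend[b])
        m$qstart[a] <- min(m$qstart[a], m$qstart[b])
        m$qend[a] <- max(m$qend[a], m$qend[b])
        m$matches[a] <- m$matches[a] + m$matches[b]
        m$columns[a] <- m$columns[a] + m$columns[b]
        m$score[a] <- m$score[a] + m$score[b]
        m$q_span[a] <- m$q_span[a] + m$q_span[b] - max(0L, q_ov)
        m$n_fragments[a] <- m$n_fragments[a] + m$n_fragments[b]
        m <- m[-b, , drop = FALSE]
        merged <- TRUE
      } else i <- i + 1L
    }
    if (!merged) break
  }
  m
}
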