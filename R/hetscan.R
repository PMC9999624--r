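## Heterozygosity characterization: per-SNP sharing statistics, genomic
## density of shared heterozygosity, and per-accession runs (tracts) of
## heterozygosity detected with a sliding window over consecutive SNPs.

#' Per-SNP heterozygosity summary
#'
#' For each SNP: how many accessions are called heterozygous, the
#' heterozygote frequency, and whether both alleles are also present as
#' homozygotes somewhere in the population (for genuine pre-existing
#' allelic variation captured by a duplication this is expected; the study
#' observed it for 97% of putatively heterozygous SNPs).
#'
#' @param gm a [genotype_matrix()].
#' @param denominator `"nonmissing"` (default) divides the het count by
#'   the number of non-missing calls; `"all"` divides by the accession
#'   count.
#' @return data.frame with one row per SNP: `id`, `chrom`, `pos`,
#'   `het_count`, `het_frequency`, `both_alleles_homozygous`,
#'   `undefined` (no non-missing calls).
#' @export
summarize_het <- function(gm, denominator = c("nonmissing", "all")) {
  denominator <- match.arg(denominator)
  if (n_snps(gm) == 0)
    return(data.frame(id = character(), chrom = character(), pos = integer(),
                      het_count = integer(), het_frequency = numeric(),
                      both_alleles_homozygous = logical(),
                      undefined = logical()))
  het <- rowSums(gm$calls == 1L)
  nonmiss <- rowSums(gm$calls != -1L)
  denom <- if (denominator == "nonmissing") nonmiss
           else rep(n_accessions(gm), n_snps(gm))
  freq <- ifelse(denom > 0, het / denom, NA_real_)
  data.frame(id = gm$map$id, chrom = gm$map$chrom, pos = gm$map$pos,
             het_count = as.integer(het), het_frequency = freq,
             both_alleles_homozygous = rowSums(gm$calls == 0L) > 0 &
               rowSums(gm$calls == 2L) > 0,
             undefined = nonmiss == 0L,
             stringsAsFactors = FALSE)
}

#' Genomic density of shared heterozygous SNPs
#'
#' Bins SNPs that are heterozygous in at least `min_share` accessions into
#' fixed-width windows per chromosome. Bin counts sum to the total number
#' of shared-het SNPs.
#'
#' @param gm a [genotype_matrix()].
#' @param window_bp bin width in bp.
#' @param min_share minimum het count for a SNP to be "shared".
#' @return data.frame with columns `chrom`, `bin`, `start`, `end`, `count`.
#' @export
het_density <- function(gm, window_bp, min_share = 2L) {
  hs <- summarize_het(gm)
  out <- list(); k <- 0L
  for (ch in unique(gm$map$chrom)) {
    rows <- hs[hs$chrom == ch, ]
    n_bins <- max((max(gm$map$pos[gm$map$chrom == ch]) - 1L) %/% window_bp + 1L, 1L)
    bin <- (rows$pos - 1L) %/% window_bp + 1L
    count <- tabulate(bin[rows$het_count >= min_share], nbins = n_bins)
    k <- k + 1L
    out[[k]] <- data.frame(chrom = ch, bin = seq_len(n_bins),
                           start = (seq_len(n_bins) - 1L) * window_bp + 1L,
                           end = seq_len(n_bins) * window_bp,
                           count = count, stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Parameters for run-of-heterozygosity detection
#'
#' Defaults replicate the sliding-window run detection of the detectRUNS
#' package as parameterized for heterozygosity runs: `window_size = 10`
#' SNPs, window-vote `threshold = 0.05`, `min_density` of 1 SNP per 100 kb
#' (expressed in SNPs per kb), and the package's documented defaults for
#' the remaining knobs.
#'
#' @param window_size SNPs per sliding window.
#' @param threshold minimum fraction (strict) of overlapping windows
#'   called heterozygous for a SNP to be in-run.
#' @param min_density minimum SNPs per kb of tract length.
#' @param min_snp minimum SNPs in a tract.
#' @param max_gap maximum gap (bp) between consecutive SNPs in a tract.
#' @param min_length minimum tract length (bp).
#' @param max_opp_window maximum homozygous calls tolerated per window.
#' @param max_miss_window maximum missing calls tolerated per window.
#' @return a list of class `tract_params`.
#' @export
tract_params <- function(window_size = 10L, threshold = 0.05,
                         min_density = 1 / 100, min_snp = 3L,
                         max_gap = 1e6, min_length = 1000L,
                         max_opp_window = 1L, max_miss_window = 1L) {
  stopifnot(window_size >= 1, threshold > 0, threshold <= 1)
  structure(list(window_size = as.integer(window_size),
                 threshold = threshold, min_density = min_density,
                 min_snp = as.integer(min_snp), max_gap = max_gap,
                 min_length = as.integer(min_length),
                 max_opp_window = as.integer(max_opp_window),
                 max_miss_window = as.integer(max_miss_window)),
            class = "tract_params")
}

#' Detect runs (tracts) of heterozygosity
#'
#' Per accession and chromosome, a window of `window_size` consecutive
#' SNPs is called heterozygous when it contains at most `max_opp_window`
#' homozygous and at most `max_miss_window` missing calls. A SNP is
#' in-run when the fraction of windows overlapping it that are
#' heterozygous strictly exceeds `threshold`. Maximal stretches of in-run
#' SNPs are split at gaps larger than `max_gap` and reported as tracts if
#' they satisfy `min_snp`, `min_length` and `min_density`.
#'
#' @param gm a [genotype_matrix()].
#' @param params a [tract_params()].
#' @return data.frame with columns `accession`, `chrom`, `start`, `end`,
#'   `n_snps`, `length_bp`.
#' @export
detect_het_tracts <- function(gm, params = tract_params()) {
  out <- list(); k <- 0L
  for (ch in unique(gm$map$chrom)) {
    rows <- which(gm$map$chrom == ch)
    pos <- gm$map$pos[rows]
    m <- length(rows)
    if (m < params$window_size) {
      message(sprintf(
        "detect_het_tracts: %s has %d SNPs (< window_size %d); skipped",
        ch, m, params$window_size))
      next
    }
    for (i in seq_len(n_accessions(gm))) {
      v <- gm$calls[rows, i]
      segs <- het_run_segments(v, pos, params)
      if (nrow(segs) > 0) {
        k <- k + 1L
        segs$accession <- gm$accessions[i]
        segs$chrom <- ch
        out[[k]] <- segs[, c("accession", "chrom", "start", "end",
                             "n_snps", "length_bp")]
      }
    }
  }
  if (k == 0)
    return(data.frame(accession = character(), chrom = character(),
                      start = integer(), end = integer(),
                      n_snps = integer(), length_bp = integer()))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

## internal: run detection on one accession x chromosome call vector
het_run_segments <- function(v, pos, params) {
  m <- length(v)
  w <- params$window_size
  hom <- as.integer(v == 0L | v == 2L)
  mis <- as.integer(v == -1L)
  n_win <- m - w + 1L
  cs_hom <- c(0L, cumsum(hom)); cs_mis <- c(0L, cumsum(mis))
  win_het <- (cs_hom[(w + 1L):(m + 1L)] - cs_hom[1:n_win]) <= params$max_opp_window &
             (cs_mis[(w + 1L):(m + 1L)] - cs_mis[1:n_win]) <= params$max_miss_window
  ## windows overlapping SNP j: max(1, j-w+1) .. min(j, n_win)
  cs_win <- c(0L, cumsum(as.integer(win_het)))
  j <- seq_len(m)
  lo <- pmax(1L, j - w + 1L); hi <- pmin(j, n_win)
  n_overlap <- hi - lo + 1L
  n_het_win <- cs_win[hi + 1L] - cs_win[lo]
  in_run <- n_het_win / n_overlap > params$threshold
  segs <- list(); k <- 0L
  r <- rle(in_run)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  for (s in which(r$values)) {
    idx <- starts[s]:ends[s]
    ## split on large gaps
    gap_break <- which(diff(pos[idx]) > params$max_gap)
    bounds <- cbind(c(1L, gap_break + 1L), c(gap_break, length(idx)))
    for (b in seq_len(nrow(bounds))) {
      sub <- idx[bounds[b, 1]:bounds[b, 2]]
      n <- length(sub)
      len <- pos[sub[n]] - pos[sub[1]] + 1L
      if (n >= params$min_snp && len >= params$min_length &&
          n / (len / 1000) >= params$min_density) {
        k <- k + 1L
        segs[[k]] <- data.frame(start = pos[sub[1]], end = pos[sub[n]],
                                n_snps = n, length_bp = len)
      }
    }
  }
  if (k == 0)
    return(data.frame(start = integer(), end = integer(),
                      n_snps = integer(), length_bp = integer()))
  do.call(rbind, segs)
}

#' Tract length distribution and cross-accession sharing
#'
#' Tracts from different accessions are considered shared when their
#' reciprocal overlap is at least `min_overlap` of each tract's length.
#'
#' @param tracts data.frame from [detect_het_tracts()].
#' @param min_overlap reciprocal-overlap fraction defining sharing.
#' @return list with `length_summary` (quantiles of tract length) and
#'   `sharing` (the input tracts with a `share_count` column counting the
#'   accessions sharing each tract, including its owner).
#' @export
tract_sharing <- function(tracts, min_overlap = 0.5) {
  if (nrow(tracts) == 0)
    return(list(length_summary = data.frame(quantile = numeric(),
                                            length_bp = numeric()),
                sharing = cbind(tracts, share_count = integer())))
  qs <- c(0, 0.25, 0.5, 0.75, 1)
  length_summary <- data.frame(quantile = qs,
                               length_bp = as.numeric(
                                 quantile(tracts$length_bp, qs)))
  share <- integer(nrow(tracts))
  for (i in seq_len(nrow(tracts))) {
    same <- tracts$chrom == tracts$chrom[i]
    ov <- pmin(tracts$end[same], tracts$end[i]) -
          pmax(tracts$start[same], tracts$start[i]) + 1L
    frac_ok <- ov >= min_overlap * tracts$length_bp[same] &
               ov >= min_overlap * tracts$length_bp[i]
    share[i] <- length(unique(tracts$accession[same][frac_ok & ov > 0]))
  }
  list(length_summary = length_summary,
       sharing = cbind(tracts, share_count = share))
}
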