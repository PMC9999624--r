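## Peak calling on association scans: grid the per-SNP -log10 p signal
## onto fixed bins, smooth by keeping only the lowest-frequency Fourier
## components, detect local maxima, pick the top SNP within +/-10 kb of
## each peak center, classify cis/trans at 50 kb, and summarize per gene.

#' Peak-calling parameters
#'
#' @param pc_keep_comp fraction of low-frequency Fourier components kept
#'   by the smoother.
#' @param bin_bp width of the signal grid (bp).
#' @param peak_floor minimum smoothed height for a local maximum to be
#'   called (on the smoothed -log10 p scale, matching the raw-output
#'   filter).
#' @param search_halfwidth half-width (bp) of the top-SNP search window
#'   around a peak center.
#' @param logp_final,maf_final final thresholds applied to the top SNP
#'   when summarizing genes.
#' @param cis_radius distance (bp) separating cis from trans
#'   associations.
#' @return a list of class `peak_params`.
#' @export
peak_params <- function(pc_keep_comp = 0.05, bin_bp = 1000L,
                        peak_floor = 4, search_halfwidth = 10000L,
                        logp_final = 20, maf_final = 0.1,
                        cis_radius = 50000L) {
  stopifnot(pc_keep_comp > 0, pc_keep_comp <= 1, bin_bp >= 1,
            search_halfwidth > 0, cis_radius > 0)
  structure(list(pc_keep_comp = pc_keep_comp, bin_bp = as.integer(bin_bp),
                 peak_floor = peak_floor,
                 search_halfwidth = as.integer(search_halfwidth),
                 logp_final = logp_final, maf_final = maf_final,
                 cis_radius = as.integer(cis_radius)),
            class = "peak_params")
}

#' FFT low-pass smoothing of a binned signal
#'
#' Discrete Fourier transform of the signal; all components above the
#' `ceiling(pc_keep_comp * length)` lowest frequencies are zeroed
#' (conjugate symmetry preserved) and the signal inverse-transformed.
#' With `pc_keep_comp = 1` the signal is returned unchanged (to within
#' round-off). Negative ringing is clipped at zero unless `clip = FALSE`
#' (the unclipped smoother is exactly linear).
#'
#' @param signal numeric vector of per-bin values for one chromosome.
#' @param pc_keep_comp fraction of low-frequency components kept.
#' @param clip clip negative output at zero.
#' @return smoothed numeric vector, same length.
#' @export
fft_smooth <- function(signal, pc_keep_comp = 0.05, clip = TRUE) {
  n <- length(signal)
  if (n < 4) stop("fft_smooth: signal length must be >= 4")
  if (all(signal == 0)) return(signal)
  k <- ceiling(pc_keep_comp * n)
  f <- fft(signal)
  ## component i (1-based) has frequency index i-1; mirror is n-i+2
  freq <- c(0:(n %/% 2), rev(seq_len(n - n %/% 2 - 1L)))
  f[freq >= k] <- 0                     # k >= 1, so DC is always kept
  out <- Re(fft(f, inverse = TRUE)) / n
  if (clip) out[out < 0] <- 0
  out
}

#' Detect local maxima in a smoothed signal
#'
#' Strict local maxima (greater than both neighbors) with height at least
#' `peak_floor`; a plateau of equal values higher than its flanks reports
#' its central bin. Monotone signals have no interior peaks.
#'
#' @param smoothed numeric vector.
#' @param peak_floor minimum height.
#' @return integer vector of peak center bins.
#' @export
detect_peaks <- function(smoothed, peak_floor = 4) {
  n <- length(smoothed)
  if (n < 3) return(integer())
  r <- rle(smoothed)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  nruns <- length(r$values)
  peaks <- integer()
  for (i in seq_len(nruns)) {
    if (i == 1L || i == nruns) next          # boundary runs are not interior maxima
    if (r$values[i] > r$values[i - 1L] && r$values[i] > r$values[i + 1L] &&
        r$values[i] >= peak_floor) {
      peaks <- c(peaks, (starts[i] + ends[i]) %/% 2L)
    }
  }
  peaks
}

#' Top SNP within a window around a peak center
#'
#' The SNP with maximal -log10 p inside `[center - halfwidth,
#' center + halfwidth]` on the peak's chromosome; ties are broken by
#' smaller position. Returns `NULL` when the window holds no SNP (the
#' peak is discarded).
#'
#' @param scan an `association_scan`.
#' @param chrom peak chromosome.
#' @param center_bp peak center (bp).
#' @param halfwidth window half-width (bp).
#' @return one-row data.frame or `NULL`.
#' @export
top_snp_in_window <- function(scan, chrom, center_bp, halfwidth = 10000L) {
  w <- scan[scan$chrom == chrom &
            scan$pos >= center_bp - halfwidth &
            scan$pos <= center_bp + halfwidth, , drop = FALSE]
  if (nrow(w) == 0) return(NULL)
  w <- w[order(-w$minus_log10_p, w$pos), , drop = FALSE]
  w[1, , drop = FALSE]
}

#' Classify an association peak as cis or trans
#'
#' Cis: same chromosome as the focal pseudo-SNP and within `cis_radius`
#' (50 kb by default, the usual extent of association peaks in a selfing
#' plant); otherwise trans.
#'
#' @param pseudo_chrom,pseudo_pos focal pseudo-SNP location.
#' @param top_chrom,top_pos top-SNP location of the peak.
#' @param cis_radius distance threshold (bp).
#' @return `"cis"` or `"trans"`.
#' @export
classify_peak <- function(pseudo_chrom, pseudo_pos, top_chrom, top_pos,
                          cis_radius = 50000L) {
  if (identical(pseudo_chrom, top_chrom) &&
      abs(top_pos - pseudo_pos) <= cis_radius) "cis" else "trans"
}

#' Call peaks for one pseudo-SNP's association scan
#'
#' Grids the scan's -log10 p values onto `bin_bp` bins per chromosome
#' (maximum per bin, empty bins 0), smooths each chromosome with
#' [fft_smooth()], detects local maxima, attaches the top SNP within
#' `search_halfwidth` of each peak center and classifies each peak
#' cis/trans relative to the focal pseudo-SNP.
#'
#' @param scan an `association_scan` (typically after [filter_scan()]).
#' @param pseudo_chrom,pseudo_pos focal pseudo-SNP location.
#' @param params a [peak_params()].
#' @param chrom_lengths optional named lengths used to size the grid
#'   (defaults to max SNP position per chromosome).
#' @return data.frame with one row per called peak: `peak_chrom`,
#'   `center_bp`, `top_id`, `top_pos`, `minus_log10_p`, `maf`, `label`.
#' @export
call_peaks <- function(scan, pseudo_chrom, pseudo_pos,
                       params = peak_params(), chrom_lengths = NULL) {
  out <- list(); k <- 0L
  for (ch in unique(scan$chrom)) {
    rows <- scan[scan$chrom == ch, , drop = FALSE]
    len <- if (!is.null(chrom_lengths) && ch %in% names(chrom_lengths))
      chrom_lengths[[ch]] else max(rows$pos)
    n_bins <- max(4L, as.integer((len - 1L) %/% params$bin_bp + 1L))
    bin <- (rows$pos - 1L) %/% params$bin_bp + 1L
    signal <- numeric(n_bins)
    agg <- tapply(rows$minus_log10_p, bin, max)
    signal[as.integer(names(agg))] <- agg
    sm <- fft_smooth(signal, params$pc_keep_comp)
    centers <- detect_peaks(sm, params$peak_floor)
    for (cb in centers) {
      center_bp <- as.integer((cb - 0.5) * params$bin_bp)
      top <- top_snp_in_window(scan, ch, center_bp, params$search_halfwidth)
      if (is.null(top)) next
      k <- k + 1L
      out[[k]] <- data.frame(
        peak_chrom = ch, center_bp = center_bp, top_id = top$id,
        top_pos = top$pos, minus_log10_p = top$minus_log10_p,
        maf = top$maf,
        label = classify_peak(pseudo_chrom, pseudo_pos, ch, top$pos,
                              params$cis_radius),
        stringsAsFactors = FALSE)
    }
  }
  if (k == 0)
    return(data.frame(peak_chrom = character(), center_bp = integer(),
                      top_id = character(), top_pos = integer(),
                      minus_log10_p = numeric(), maf = numeric(),
                      label = character()))
  do.call(rbind, out)
}

#' Summarize duplication evidence for one gene
#'
#' Pools the peaks called for all of a gene's pseudo-SNP phenotypes,
#' keeps those whose top SNP passes the final thresholds, and assigns the
#' gene to `cis_only`, `trans_only`, `both` or `none` from the surviving
#' label set. Categories partition the gene set by construction.
#'
#' @param peaks data.frame of peaks for one gene (rows from
#'   [call_peaks()], possibly over several pseudo-SNPs).
#' @param logp_final,maf_final final thresholds.
#' @return list with `category` and `peaks` (the surviving rows).
#' @export
summarize_gene <- function(peaks, logp_final = 20, maf_final = 0.1) {
  if (nrow(peaks) == 0)
    return(list(category = "none", peaks = peaks))
  keep <- peaks$minus_log10_p >= logp_final & peaks$maf >= maf_final
  surv <- peaks[keep, , drop = FALSE]
  labels <- unique(surv$label)
  category <- if (length(labels) == 0) "none"
  else if (setequal(labels, "cis")) "cis_only"
  else if (setequal(labels, "trans")) "trans_only"
  else "both"
  list(category = category, peaks = surv)
}
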