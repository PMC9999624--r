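# Independent oracles used to check the package implementations.
# Deliberately naive: direct enumeration / dense solves / the Biostrings
# aligner, never sharing code with the functions under test.

# Brute-force run-of-heterozygosity caller: enumerate every window
# explicitly, vote per SNP, then walk segments one by one.
oracle_het_tracts <- function(calls, pos, params) {
  m <- length(calls)
  w <- params$window_size
  if (m < w) return(data.frame(start = integer(), end = integer(),
                               n_snps = integer(), length_bp = integer()))
  win_het <- logical(m - w + 1)
  for (i in seq_len(m - w + 1)) {
    v <- calls[i:(i + w - 1)]
    win_het[i] <- sum(v == 0 | v == 2) <= params$max_opp_window &&
      sum(v == -1) <= params$max_miss_window
  }
  in_run <- logical(m)
  for (j in seq_len(m)) {
    overlapping <- intersect(seq_len(m - w + 1), (j - w + 1):j)
    in_run[j] <- mean(win_het[overlapping]) > params$threshold
  }
  segs <- list()
  j <- 1
  while (j <= m) {
    if (!in_run[j]) { j <- j + 1; next }
    k <- j
    while (k + 1 <= m && in_run[k + 1] &&
           pos[k + 1] - pos[k] <= params$max_gap) k <- k + 1
    n <- k - j + 1
    len <- pos[k] - pos[j] + 1
    if (n >= params$min_snp && len >= params$min_length &&
        n / (len / 1000) >= params$min_density)
      segs[[length(segs) + 1]] <- data.frame(start = pos[j], end = pos[k],
                                             n_snps = n, length_bp = len)
    j <- k + 1
  }
  if (length(segs) == 0)
    return(data.frame(start = integer(), end = integer(),
                      n_snps = integer(), length_bp = integer()))
  do.call(rbind, segs)
}

# Dense GLS oracle: per-SNP generalized least squares with the full
# covariance K + delta * I solved directly.
oracle_gls_scan <- function(y, G, K, delta) {
  n <- length(y)
  C <- K + delta * diag(n)
  Ci <- solve(C)
  vapply(seq_len(nrow(G)), function(s) {
    g <- G[s, ]
    X <- cbind(1, g)
    XtCi <- t(X) %*% Ci
    b <- solve(XtCi %*% X, XtCi %*% y)
    r <- y - X %*% b
    s2 <- as.numeric(t(r) %*% Ci %*% r) / (n - 2)
    vb <- s2 * solve(XtCi %*% X)
    tt <- b[2] / sqrt(vb[2, 2])
    2 * pt(abs(tt), n - 2, lower.tail = FALSE)
  }, numeric(1))
}

# Pairwise kinship by an explicit double loop.
oracle_kinship <- function(calls) {
  n <- ncol(calls)
  K <- matrix(NA_real_, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    ok <- calls[, i] %in% c(0, 2) & calls[, j] %in% c(0, 2)
    K[i, j] <- mean(calls[ok, i] == calls[ok, j])
  }
  K
}

# Smith-Waterman oracle via Biostrings (same scoring convention:
# a length-k gap costs gap_open + k * gap_ext).
oracle_sw <- function(query, target, match = 1, mismatch = -2,
                      gap_open = 5, gap_ext = 2) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = match,
                                                  mismatch = mismatch,
                                                  baseOnly = TRUE)
  al <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(query), Biostrings::DNAString(target),
    type = "local", substitutionMatrix = mat,
    gapOpening = gap_open, gapExtension = gap_ext)
  list(score = Biostrings::score(al),
       tstart = BiocGenerics::start(Biostrings::subject(al)),
       tend = BiocGenerics::end(Biostrings::subject(al)),
       matches = Biostrings::nmatch(al),
       columns = Biostrings::nchar(al))
}

# Direct DFT low-pass smoother used against fft_smooth.
oracle_fft_lowpass <- function(x, pc) {
  n <- length(x)
  k <- ceiling(pc * n)
  f <- fft(x)
  keep <- logical(n)
  for (i in seq_len(n)) {
    freq <- min(i - 1, n - (i - 1))
    keep[i] <- freq < k
  }
  f[!keep] <- 0
  Re(fft(f, inverse = TRUE)) / n
}

# Random mutated copy of a sequence with an exact substitution count.
mutate_seq <- function(seq, n_sub) {
  v <- strsplit(seq, "")[[1]]
  at <- sample(length(v), n_sub)
  for (i in at) v[i] <- sample(setdiff(c("A", "C", "G", "T"), v[i]), 1)
  paste(v, collapse = "")
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")
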