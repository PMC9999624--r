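## Accelerated linear mixed-model association scan (EMMAX approximation):
## identity-by-state kinship on homozygous calls, one REML fit of the
## variance-component ratio under the null by eigendecomposition, then a
## per-SNP generalized-least-squares t-test on the rotated, reweighted
## system. Binary heterozygosity phenotypes are treated as Gaussian.

#' Identity-by-state kinship matrix
#'
#' K[i, j] is the fraction of shared alleles over SNPs where both
#' accessions have a non-missing homozygous call (1 for identical
#' homozygotes, 0 otherwise); heterozygous calls are excluded, as the
#' genotype matrix used for the scan has them filtered out. A centered
#' cross-product (VanRaden) kinship is available via `method`.
#'
#' @param gm a [genotype_matrix()].
#' @param method `"ibs"` (default) or `"vanraden"`.
#' @return symmetric accession x accession matrix with unit diagonal
#'   (class `matrix`), attribute `method`.
#' @export
compute_kinship <- function(gm, method = c("ibs", "vanraden")) {
  method <- match.arg(method)
  if (n_accessions(gm) < 2) stop("compute_kinship: need >= 2 accessions")
  ## signed hom coding: 0 -> +1, 2 -> -1, het/missing -> 0
  A <- matrix(0, nrow = n_snps(gm), ncol = n_accessions(gm))
  A[gm$calls == 0L] <- 1
  A[gm$calls == 2L] <- -1
  if (method == "ibs") {
    S <- crossprod(A)            # sum of a_i * a_j over co-typed sites
    N <- crossprod(abs(A))       # co-typed (both hom, non-missing) count
    if (any(N == 0))
      stop("compute_kinship: accession pair with no co-typed SNPs")
    K <- (S + N) / (2 * N)
  } else {
    X <- (1 - A) / 2             # dosage 0/1, het/missing -> 0.5 midpoint
    X[A == 0] <- NA
    mu <- rowMeans(X, na.rm = TRUE)
    Xc <- X - mu
    Xc[is.na(Xc)] <- 0
    K <- crossprod(Xc) / nrow(Xc)
    d <- sqrt(diag(K))
    if (any(d == 0)) stop("compute_kinship: degenerate accession")
    K <- K / tcrossprod(d)
  }
  dimnames(K) <- list(gm$accessions, gm$accessions)
  attr(K, "method") <- method
  K
}

#' REML fit of the null mixed model
#'
#' Fits y = mu + g + e with g ~ N(0, sigma_g^2 K), e ~ N(0, sigma_e^2 I)
#' by restricted maximum likelihood, profiling the criterion over
#' delta = sigma_e^2 / sigma_g^2 on log-delta in \[-10, 10\] (64-point
#' grid pre-scan followed by Brent refinement). If the restricted
#' likelihood is flat in delta (e.g. K = I, where only total variance is
#' identifiable), the convention delta = exp(10), heritability 0 is
#' returned and flagged.
#'
#' @param y numeric phenotype vector (non-constant).
#' @param K kinship matrix from [compute_kinship()].
#' @return list of class `variance_components`: `delta`, `sigma_g2`,
#'   `sigma_e2`, `heritability`, `eigenvalues`, `rotation` (eigenvectors
#'   of K, cached for the scan), `flat` (non-identifiable flag),
#'   `reml_loglik`.
#' @export
fit_null <- function(y, K) {
  y <- as.numeric(y)
  n <- length(y)
  stopifnot(nrow(K) == n)
  if (stats::var(y) == 0) stop("fit_null: phenotype invariant")
  eK <- eigen(K, symmetric = TRUE)
  ## REML: project out the intercept, eigendecompose S K S
  J <- diag(n) - matrix(1 / n, n, n)
  eS <- eigen(J %*% K %*% J, symmetric = TRUE)
  xi <- eS$values[seq_len(n - 1L)]
  xi[xi < 1e-10] <- 1e-10
  eta <- crossprod(eS$vectors[, seq_len(n - 1L)], y)[, 1]
  nq <- n - 1L
  rll <- function(logd) {
    d <- exp(logd)
    ss <- sum(eta^2 / (xi + d))
    0.5 * (nq * (log(nq / (2 * pi)) - 1 - log(ss)) - sum(log(xi + d)))
  }
  grid <- seq(-10, 10, length.out = 64)
  vals <- vapply(grid, rll, numeric(1))
  flat <- diff(range(vals)) < 1e-8
  if (flat) {
    logd <- 10
  } else {
    i <- which.max(vals)
    lo <- grid[max(1, i - 1)]; hi <- grid[min(length(grid), i + 1)]
    opt <- optimize(rll, c(lo, hi), maximum = TRUE, tol = 1e-6)
    logd <- if (opt$objective >= vals[i]) opt$maximum else grid[i]
  }
  delta <- exp(logd)
  sigma_g2 <- sum(eta^2 / (xi + delta)) / nq
  sigma_e2 <- delta * sigma_g2
  structure(list(delta = delta, sigma_g2 = sigma_g2, sigma_e2 = sigma_e2,
                 heritability = if (flat) 0 else 1 / (1 + delta),
                 eigenvalues = eK$values, rotation = eK$vectors,
                 flat = flat, reml_loglik = rll(logd)),
            class = "variance_components")
}

#' Mixed-model association scan (EMMAX-style GLS)
#'
#' Tests every SNP against a phenotype with the variance components held
#' fixed from the null fit. Heterozygous calls are excluded from the
#' genotype coding (dosage 0 for hom-ref, 1 for hom-alt, missing
#' otherwise; missing dosages mean-imputed per SNP). The phenotype and
#' design are rotated by the eigenvectors of K and weighted by
#' (lambda_i + delta)^(-1/2); ordinary least squares on the transformed
#' system gives the GLS effect estimate and a two-sided t-test with n - 2
#' degrees of freedom. P-values below 1e-300 are floored at
#' -log10 p = 300.
#'
#' @param y phenotype vector (see [make_phenotype()]); missing values are
#'   mean-imputed.
#' @param gm a [genotype_matrix()].
#' @param K kinship matrix.
#' @param vc a `variance_components` object from [fit_null()].
#' @return data.frame of class `association_scan`: `id`, `chrom`, `pos`,
#'   `maf`, `beta`, `minus_log10_p` (zero-variance SNPs are skipped; the
#'   skip count is attribute `n_skipped`).
#' @export
scan_assoc <- function(y, gm, K, vc) {
  stopifnot(inherits(vc, "variance_components"))
  y <- as.numeric(y)
  y[is.na(y)] <- mean(y, na.rm = TRUE)
  n <- length(y)
  m <- n_snps(gm)
  ## dosage coding with het excluded
  G <- matrix(NA_real_, m, n)
  G[gm$calls == 0L] <- 0
  G[gm$calls == 2L] <- 1
  p_alt <- rowMeans(G, na.rm = TRUE)
  maf <- pmin(p_alt, 1 - p_alt)
  na_idx <- which(is.na(G))
  if (length(na_idx) > 0)
    G[na_idx] <- p_alt[(na_idx - 1L) %% m + 1L]
  U <- vc$rotation
  w <- 1 / (vc$eigenvalues + vc$delta)     # GLS weights
  sw <- sqrt(w)
  yt <- crossprod(U, y)[, 1] * sw
  ones <- crossprod(U, rep(1, n))[, 1] * sw
  Gt <- tcrossprod(G, t(U))                # m x n rotated dosages
  Gt <- sweep(Gt, 2, sw, "*")
  ## per-SNP weighted 2-parameter regression, vectorized over SNPs
  S11 <- sum(ones^2)
  S1y <- sum(ones * yt)
  Syy <- sum(yt^2)
  S1g <- as.vector(Gt %*% ones)
  Sgy <- as.vector(Gt %*% yt)
  Sgg <- rowSums(Gt^2)
  det <- S11 * Sgg - S1g^2
  var_ok <- is.finite(det) & det > 1e-12 * S11 * pmax(Sgg, 1e-300)
  var_ok[is.na(var_ok)] <- FALSE
  beta <- (S11 * Sgy - S1g * S1y) / det
  alpha <- (Sgg * S1y - S1g * Sgy) / det
  rss <- Syy - alpha * S1y - beta * Sgy
  rss <- pmax(rss, 0)
  df <- n - 2L
  se2 <- rss / df * S11 / det
  tstat <- beta / sqrt(se2)
  logp <- -(pt(abs(tstat), df, lower.tail = FALSE, log.p = TRUE) +
              log(2)) / log(10)
  logp[logp > 300] <- 300
  res <- data.frame(id = gm$map$id, chrom = gm$map$chrom, pos = gm$map$pos,
                    maf = maf, beta = beta, minus_log10_p = logp,
                    stringsAsFactors = FALSE)[var_ok, , drop = FALSE]
  rownames(res) <- NULL
  n_skipped <- sum(!var_ok)
  if (n_skipped > 0)
    message(sprintf("scan_assoc: skipped %d zero-variance SNP(s)", n_skipped))
  attr(res, "n_skipped") <- n_skipped
  class(res) <- c("association_scan", "data.frame")
  res
}

#' Filter a raw association scan
#'
#' Retains SNPs with minor allele frequency at least `maf_min` and
#' -log10 p at least `logp_min` (both inclusive), the raw-output filter
#' applied before peak calling.
#'
#' @param scan an `association_scan` from [scan_assoc()].
#' @param maf_min minimum minor allele frequency.
#' @param logp_min minimum -log10 p-value.
#' @return the filtered scan.
#' @export
filter_scan <- function(scan, maf_min = 0.05, logp_min = 4) {
  out <- scan[!is.na(scan$maf) & scan$maf >= maf_min &
              scan$minus_log10_p >= logp_min, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("association_scan", "data.frame")
  out
}

#' Genomic-control lambda of a scan
#'
#' Median chi-square statistic implied by the scan's p-values divided by
#' the null median; values near 1 indicate a calibrated test.
#'
#' @param logp vector of -log10 p-values.
#' @return numeric lambda.
#' @export
gc_lambda <- function(logp) {
  chisq <- qchisq(-logp * log(10), df = 1, lower.tail = FALSE, log.p = TRUE)
  median(chisq) / qchisq(0.5, df = 1)
}
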