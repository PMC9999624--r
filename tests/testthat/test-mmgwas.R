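random_gm <- function(n, m, seed, p_miss = 0, p_het = 0) {
  set.seed(seed)
  calls <- matrix(sample(c(0L, 2L), n * m, replace = TRUE), m, n)
  if (p_het > 0) calls[runif(n * m) < p_het] <- 1L
  if (p_miss > 0) calls[runif(n * m) < p_miss] <- -1L
  ## keep polymorphic-in-homozygotes rows
  keep <- apply(calls, 1, function(v) length(unique(v[v %in% c(0L, 2L)])) == 2)
  calls <- calls[keep, , drop = FALSE]
  genotype_matrix(
    map = data.frame(chrom = "chr1",
                     pos = seq(1000L, by = 100L, length.out = nrow(calls)),
                     id = paste0("s", seq_len(nrow(calls))), ref = "A",
                     alt = "G"),
    calls = calls, accessions = sprintf("a%02d", seq_len(n)))
}

test_that("IBS kinship hits its extremes and matches the pairwise oracle", {
  gm <- random_gm(8, 60, seed = 21)
  gm$calls[, 2] <- gm$calls[, 1]            # identical pair
  gm$calls[, 3] <- 2L - gm$calls[, 1]       # fully opposite pair
  K <- compute_kinship(gm)
  expect_equal(K[1, 2], 1)
  expect_equal(K[1, 3], 0)
  expect_true(isSymmetric(K))
  expect_equal(unname(diag(K)), rep(1, 8))
  expect_equal(unname(K), oracle_kinship(gm$calls), ignore_attr = TRUE)
  expect_true(min(eigen(K, symmetric = TRUE,
                        only.values = TRUE)$values) > -1e-8)
})

test_that("kinship handles het/missing exclusion and degenerate pairs", {
  gm <- random_gm(6, 80, seed = 22, p_miss = 0.1, p_het = 0.1)
  expect_equal(unname(compute_kinship(gm)), oracle_kinship(gm$calls),
               ignore_attr = TRUE)
  gm2 <- random_gm(3, 20, seed = 23)
  gm2$calls[, 1] <- -1L
  expect_error(compute_kinship(gm2), "co-typed")
})

test_that("null REML recovers the heritability regime", {
  ## structured relatedness from a founder mosaic gives an identifiable K
  gm <- simulate_population(small_cfg())
  n <- n_accessions(gm)
  K <- compute_kinship(gm)
  ## pure-noise phenotypes: near-zero heritability on average
  h2_noise <- vapply(1:20, function(r) {
    set.seed(100 + r)
    fit_null(rnorm(n), K)$heritability
  }, numeric(1))
  expect_lt(mean(h2_noise), 0.25)
  ## phenotype drawn from the kinship: heritability near 1
  L <- chol(K + 1e-8 * diag(n))
  h2_gen <- vapply(1:20, function(r) {
    set.seed(200 + r)
    g <- as.numeric(t(L) %*% rnorm(n))
    fit_null(g + rnorm(n, sd = 0.02 * sd(g)), K)$heritability
  }, numeric(1))
  expect_gt(mean(h2_gen), 0.9)
  expect_error(fit_null(rep(1, n), K), "invariant")
})

test_that("with identity kinship the model degenerates to plain regression", {
  n <- 40
  gm <- random_gm(n, 60, seed = 25)
  K <- diag(n); dimnames(K) <- list(gm$accessions, gm$accessions)
  set.seed(26)
  y <- rnorm(n)
  vc <- fit_null(y, K)
  expect_true(vc$flat)
  expect_equal(vc$heritability, 0)
  sc <- suppressMessages(scan_assoc(y, gm, K, vc))
  for (i in seq_len(nrow(sc))) {
    g <- as.numeric(gm$calls[match(sc$id[i], gm$map$id), ] == 2L)
    p_lm <- summary(stats::lm(y ~ g))$coefficients[2, 4]
    expect_equal(10^(-sc$minus_log10_p[i]), p_lm, tolerance = 1e-6)
  }
})

test_that("scan p-values match the dense GLS oracle to 1e-8", {
  for (r in 1:20) {
    n <- sample(15:30, 1)
    m <- sample(20:50, 1)
    gm <- random_gm(n, m, seed = 300 + r)
    K <- compute_kinship(gm)
    set.seed(400 + r)
    y <- rnorm(n) + as.numeric(gm$calls[1, ] == 2L)
    vc <- fit_null(y, K)
    sc <- suppressMessages(scan_assoc(y, gm, K, vc))
    G <- matrix(as.numeric(gm$calls == 2L), nrow(gm$calls))
    G <- G[match(sc$id, gm$map$id), , drop = FALSE]
    p_oracle <- oracle_gls_scan(y, G, K, vc$delta)
    p_scan <- 10^(-sc$minus_log10_p)
    expect_equal(p_scan, p_oracle, tolerance = 1e-8)
  }
})

test_that("p-values are invariant under accession relabeling", {
  gm <- random_gm(30, 80, seed = 27)
  K <- compute_kinship(gm)
  set.seed(28)
  y <- rnorm(30)
  sc1 <- suppressMessages(scan_assoc(y, gm, K, fit_null(y, K)))
  perm <- sample(30)
  gm2 <- gm
  gm2$calls <- gm2$calls[, perm]
  gm2$accessions <- gm2$accessions[perm]
  y2 <- y[perm]
  K2 <- compute_kinship(gm2)
  sc2 <- suppressMessages(scan_assoc(y2, gm2, K2, fit_null(y2, K2)))
  expect_equal(sc2$minus_log10_p, sc1$minus_log10_p, tolerance = 1e-6)
})

test_that("a dosage-defined phenotype maps back to its SNP", {
  sim <- small_sim()
  gm <- sim$gm
  K <- compute_kinship(gm)
  s <- which(!gm$map$injected)[100]
  y <- as.numeric(gm$calls[s, ] == 2L)
  vc <- fit_null(y, K)
  sc <- suppressMessages(scan_assoc(y, gm, K, vc))
  top <- sc[which.max(sc$minus_log10_p), ]
  ## the top hit is the causal SNP or a perfect-LD proxy
  g_top <- as.numeric(gm$calls[match(top$id, gm$map$id), ] == 2L)
  expect_equal(abs(stats::cor(g_top, y)), 1)
})

test_that("the raw-output filter applies both thresholds inclusively", {
  sc <- structure(data.frame(
    id = paste0("s", 1:3), chrom = "chr1", pos = 1:3,
    maf = c(0.04, 0.2, 0.2), beta = 0,
    minus_log10_p = c(10, 3.9, 4.0)),
    class = c("association_scan", "data.frame"))
  out <- filter_scan(sc, maf_min = 0.05, logp_min = 4)
  expect_equal(out$id, "s3")
})
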