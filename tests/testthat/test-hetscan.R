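test_that("per-SNP het summary counts and the homozygote-allele flag", {
  gm <- genotype_matrix(
    map = data.frame(chrom = "chr1", pos = c(100L, 200L, 300L),
                     id = paste0("s", 1:3), ref = "A", alt = "G"),
    calls = rbind(c(1L, 1L, 0L, 2L),
                  c(0L, 0L, 0L, 0L),
                  c(1L, -1L, -1L, -1L)),
    accessions = paste0("a", 1:4))
  hs <- summarize_het(gm)
  expect_equal(hs$het_count, c(2L, 0L, 1L))
  expect_equal(hs$het_frequency, c(0.5, 0, 1))
  expect_equal(hs$both_alleles_homozygous, c(TRUE, FALSE, FALSE))
  hs_all <- summarize_het(gm, denominator = "all")
  expect_equal(hs_all$het_frequency[3], 0.25)
  expect_equal(nrow(summarize_het(subset_snps(gm, integer()))), 0L)
})

test_that("het frequency is invariant under accession permutation", {
  sim <- small_sim()
  hs1 <- summarize_het(sim$gm)
  perm <- sample(n_accessions(sim$gm))
  gm2 <- sim$gm
  gm2$calls <- gm2$calls[, perm]
  gm2$accessions <- gm2$accessions[perm]
  expect_equal(summarize_het(gm2)$het_frequency, hs1$het_frequency)
})

test_that("shared-het SNPs land in the right density bins and are conserved", {
  gm <- genotype_matrix(
    map = data.frame(chrom = "chr1", pos = c(500L, 1500L, 2500L),
                     id = paste0("s", 1:3), ref = "A", alt = "G"),
    calls = rbind(c(0L, 0L), c(1L, 1L), c(1L, 0L)),
    accessions = c("a1", "a2"))
  d <- het_density(gm, window_bp = 1000L)
  expect_equal(d$count[d$bin == 2], 1L)    # the shared het at 1500
  expect_equal(sum(d$count), 1L)
  sim <- small_sim()
  ds <- het_density(sim$gm, window_bp = 10000L)
  hs <- summarize_het(sim$gm)
  expect_equal(sum(ds$count), sum(hs$het_count >= 2))
})

test_that("a run of 20 het calls over 2 kb yields one tract with all SNPs", {
  pos <- seq(1000L, by = 100L, length.out = 20L)
  gm <- genotype_matrix(
    map = data.frame(chrom = "chr1", pos = pos,
                     id = paste0("s", seq_along(pos)), ref = "A", alt = "G"),
    calls = matrix(1L, 20, 1), accessions = "a1")
  tr <- detect_het_tracts(gm)
  expect_equal(nrow(tr), 1L)
  expect_equal(tr$n_snps, 20L)
  expect_equal(c(tr$start, tr$end), c(1000L, 2900L))
})

test_that("all-homozygous accessions and 2-SNP runs give no tracts", {
  pos <- seq(1000L, by = 100L, length.out = 20L)
  gm_hom <- genotype_matrix(
    map = data.frame(chrom = "chr1", pos = pos,
                     id = paste0("s", seq_along(pos)), ref = "A", alt = "G"),
    calls = matrix(rep(c(0L, 2L), 10), 20, 1), accessions = "a1")
  expect_equal(nrow(detect_het_tracts(gm_hom)), 0L)
  calls <- matrix(0L, 20, 1); calls[10:11] <- 1L
  gm_2 <- genotype_matrix(gm_hom$map, calls, "a1")
  tr <- detect_het_tracts(gm_2, tract_params(min_snp = 3L))
  expect_true(all(tr$n_snps >= 3L))
})

test_that("tract caller equals the brute-force window oracle", {
  params <- tract_params()   # window 10, threshold 0.05, density 1/100
  set.seed(11)
  for (rep in 1:25) {
    m <- 200L
    pos <- sort(sample.int(3e5, m))
    v <- sample(c(0L, 2L), m, replace = TRUE)
    ## plant 1-3 het stretches of random length
    for (s in seq_len(sample(1:3, 1))) {
      a <- sample.int(m - 30L, 1)
      v[a:(a + sample(5:30, 1))] <- 1L
    }
    v[sample.int(m, 5)] <- -1L
    gm <- genotype_matrix(
      map = data.frame(chrom = "chr1", pos = pos,
                       id = paste0("s", seq_len(m)), ref = "A", alt = "G"),
      calls = matrix(v, m, 1), accessions = "a1")
    got <- detect_het_tracts(gm, params)
    want <- oracle_het_tracts(v, pos, params)
    expect_equal(nrow(got), nrow(want))
    if (nrow(want) > 0) {
      expect_equal(got$start, want$start)
      expect_equal(got$end, want$end)
      expect_equal(got$n_snps, want$n_snps)
    }
  }
})

test_that("lowering the vote threshold never removes a tract", {
  set.seed(12)
  m <- 200L
  pos <- sort(sample.int(2e5, m))
  v <- sample(c(0L, 1L, 2L), m, replace = TRUE, prob = c(0.4, 0.3, 0.3))
  gm <- genotype_matrix(
    map = data.frame(chrom = "chr1", pos = pos,
                     id = paste0("s", seq_len(m)), ref = "A", alt = "G"),
    calls = matrix(v, m, 1), accessions = "a1")
  hi <- detect_het_tracts(gm, tract_params(threshold = 0.5))
  lo <- detect_het_tracts(gm, tract_params(threshold = 0.05))
  expect_gte(nrow(lo), nrow(hi))
  ## every SNP inside a high-threshold tract is inside a low-threshold one
  for (i in seq_len(nrow(hi))) {
    covered <- any(lo$start <= hi$start[i] & lo$end >= hi$end[i])
    expect_true(covered)
  }
})

test_that("tracts at planted source intervals are shared by carriers", {
  sim <- tract_sim()
  ev <- sim$truth[[1]]
  tr <- detect_het_tracts(sim$gm)
  expect_gt(nrow(tr), 0)
  expect_true(all(tr$accession %in% ev$carriers))
  ov <- tr$start <= ev$source_end & tr$end >= ev$source_start
  expect_true(all(ov))
  sh <- tract_sharing(tr)
  expect_true(all(sh$sharing$share_count >= 2))
  expect_equal(nrow(sh$length_summary), 5L)
})

test_that("identical and disjoint tracts share as expected", {
  tracts <- data.frame(
    accession = c("a1", "a2", "a3"), chrom = "chr1",
    start = c(1000L, 1000L, 50000L), end = c(2000L, 2000L, 51000L),
    n_snps = 10L, length_bp = c(1001L, 1001L, 1001L))
  sh <- tract_sharing(tracts)$sharing$share_count
  expect_equal(sh, c(2L, 2L, 1L))
})
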