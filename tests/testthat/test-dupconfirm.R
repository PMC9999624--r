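test_that("verbatim planted queries are found with full identity", {
  set.seed(41)
  q <- random_dna(300)
  genome <- c(chrA = paste0(random_dna(2000), q, random_dna(2000)))
  hits <- align_search(q, genome)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$percent_identity, 100)
  expect_equal(hits$query_coverage, 1)
  expect_equal(c(hits$tstart, hits$tend), c(2001L, 2300L))
  expect_error(align_search("ACGT", genome), "shorter")
})

test_that("the reverse-complement copy is found on the minus strand", {
  set.seed(42)
  q <- random_dna(200)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(q)))
  genome <- c(chrA = paste0(random_dna(1000), rc, random_dna(1000)))
  hits <- align_search(q, genome)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$strand, "-")
  expect_equal(c(hits$tstart, hits$tend), c(1001L, 1200L))
})

test_that("35%-substituted copies are rejected by the 70%/70% rule", {
  set.seed(43)
  for (r in 1:5) {
    q <- random_dna(300)
    mut <- mutate_seq(q, 105)   # exactly 35% of bases substituted
    genome <- c(chrA = paste0(random_dna(1500), mut, random_dna(1500)))
    expect_equal(nrow(align_search(q, genome)), 0L)
  }
})

test_that("a verbatim plus a diverged copy are both located", {
  set.seed(44)
  q <- random_dna(400)
  div <- mutate_seq(q, 40)      # 10% divergence
  genome <- c(chrA = paste0(random_dna(1000), q, random_dna(3000), div,
                            random_dna(1000)))
  hits <- align_search(q, genome)
  expect_equal(nrow(hits), 2L)
  hits <- hits[order(hits$tstart), ]
  expect_equal(c(hits$tstart[1], hits$tend[1]), c(1001L, 1400L))
  ## the diverged copy sits at 4401..4800; local trimming may shave ends
  expect_lt(abs(hits$tstart[2] - 4401L), 30L)
  expect_lt(abs(hits$tend[2] - 4800L), 30L)
  expect_lt(hits$percent_identity[2], 95)
})

test_that("windowed extension equals the Smith-Waterman oracle", {
  set.seed(45)
  for (r in 1:12) {
    qlen <- sample(150:300, 1)
    q <- random_dna(qlen)
    n_sub <- round(qlen * runif(1, 0, 0.1))
    copy <- mutate_seq(q, n_sub)
    target <- paste0(random_dna(sample(500:1500, 1)), copy,
                     random_dna(sample(500:1200, 1)))
    got <- align_search(q, c(t = target), min_identity = 0, min_cov = 0)
    want <- oracle_sw(q, target)
    expect_gte(nrow(got), 1L)
    best <- got[1, ]
    expect_lte(abs(best$tstart - want$tstart), 1L)
    expect_lte(abs(best$tend - want$tend), 1L)
    id_oracle <- 100 * want$matches / want$columns
    expect_lte(abs(best$percent_identity - id_oracle),
               100 / want$columns)   # within one column
    expect_equal(best$score, want$score)
  }
})

confirm_sim <- function() cached("confirm_sim", {
  cfg <- sim_config(n_accessions = 20, chrom_lengths = c(chr1 = 60000,
                                                         chr2 = 60000),
                    snp_density = 2e-3, n_founders = 4, recomb_rate = 2e-5,
                    seed = 46)
  simulate_study(cfg, n_genes = 6, gene_length = 800, events = 1,
                 divergence = 0.05, min_trans_distance = 30000)
})

test_that("confirmation succeeds within 20 kb for carriers only", {
  sim <- confirm_sim()
  ev <- sim$truth[[1]]
  asm <- emit_assemblies(sim, c(ev$carriers[1:2],
                                setdiff(sim$gm$accessions, ev$carriers)[1]))
  row <- sim$annotation[sim$annotation$gene_id == ev$source_gene, ]
  gene_seq <- substr(sim$reference[[row$chrom]], row$start, row$end)
  for (acc in names(asm)) {
    res <- confirm_prediction(gene_seq, ev$insertion_chrom,
                              ev$tag_pos, asm[[acc]], sim$reference,
                              source_chrom = row$chrom,
                              source_pos = as.integer((row$start + row$end) / 2))
    expect_equal(res$confirmed, acc %in% ev$carriers)
    if (acc %in% ev$carriers)
      expect_true(res$confirmed_excluding_source)
  }
})

test_that("matches beyond the 20 kb radius do not confirm", {
  set.seed(47)
  ref <- c(chr1 = random_dna(60000))
  gene <- substr(ref[["chr1"]], 30001, 30800)
  ## genome = reference with an extra copy 30 kb from the probed position
  genome <- c(chr1 = paste0(substr(ref[["chr1"]], 1, 55000), gene,
                            substr(ref[["chr1"]], 55001, 60000)))
  near <- confirm_prediction(gene, "chr1", 50000, genome, ref,
                             radius = 20000)
  far <- confirm_prediction(gene, "chr1", 10000, genome, ref,
                            radius = 20000)
  expect_true(near$confirmed)     # copy at ~55 kb, peak at 50 kb
  expect_false(far$confirmed)     # nothing within 20 kb of 10 kb
})

test_that("confirmation rate never increases with divergence", {
  rates <- vapply(c(0, 0.1, 0.35), function(d) {
    cfg <- sim_config(n_accessions = 10, chrom_lengths = c(chr1 = 40000,
                                                           chr2 = 40000),
                      snp_density = 2e-3, n_founders = 3,
                      recomb_rate = 2e-5, seed = 48)
    sim <- simulate_study(cfg, n_genes = 4, gene_length = 600, events = 1,
                          divergence = d, min_trans_distance = 20000)
    ev <- sim$truth[[1]]
    carriers <- ev$carriers[seq_len(min(3, length(ev$carriers)))]
    asm <- emit_assemblies(sim, carriers)
    row <- sim$annotation[sim$annotation$gene_id == ev$source_gene, ]
    gene_seq <- substr(sim$reference[[row$chrom]], row$start, row$end)
    mean(vapply(carriers, function(acc)
      confirm_prediction(gene_seq, ev$insertion_chrom, ev$tag_pos,
                         asm[[acc]], sim$reference)$confirmed, logical(1)))
  }, numeric(1))
  expect_true(all(diff(rates) <= 0))
  expect_equal(rates[1], 1)
})

test_that("copy number combines match counts with the coverage ratio", {
  sim <- confirm_sim()
  ev <- sim$truth[[1]]
  carrier <- ev$carriers[1]
  non_carrier <- setdiff(sim$gm$accessions, ev$carriers)[1]
  asm <- emit_assemblies(sim, c(carrier, non_carrier))
  cov <- emit_coverage(sim, accessions = c(carrier, non_carrier),
                       mean_depth = 30)
  row <- sim$annotation[sim$annotation$gene_id == ev$source_gene, ]
  gene_seq <- substr(sim$reference[[row$chrom]], row$start, row$end)
  est_c <- copy_number(gene_seq, asm[[carrier]],
                       depth_table = cov[cov$accession == carrier, ],
                       gene_chrom = row$chrom, gene_start = row$start,
                       gene_end = row$end)
  expect_equal(est_c$category, ">1")
  expect_equal(est_c$n_matches, 2L)
  expect_equal(est_c$coverage_ratio, 2, tolerance = 0.2)
  est_n <- copy_number(gene_seq, asm[[non_carrier]],
                       depth_table = cov[cov$accession == non_carrier, ],
                       gene_chrom = row$chrom, gene_start = row$start,
                       gene_end = row$end)
  expect_equal(est_n$category, "1")
  expect_equal(est_n$coverage_ratio, 1, tolerance = 0.2)
  ## absent gene
  est_0 <- copy_number(random_dna(600), asm[[non_carrier]])
  expect_equal(est_0$category, "0")
})

test_that("flank synteny is collinear around an unrearranged region and
           spots tandem arrays", {
  set.seed(49)
  ref <- c(chr1 = random_dna(40000))
  ann <- data.frame(gene_id = paste0("g", 1:7), chrom = "chr1",
                    start = seq(2000L, by = 5000L, length.out = 7),
                    end = seq(2800L, by = 5000L, length.out = 7),
                    strand = "+", feature_class = "gene")
  fs <- flank_synteny("g4", ann, ref, ref)
  expect_equal(nrow(fs), 6L)
  expect_true(all(fs$n_matches == 1L))
  up <- fs[fs$side == "upstream", ]
  expect_equal(up$flank_gene[order(up$rank)], c("g3", "g2", "g1"))
  expect_true(!is.unsorted(fs$tstart[order(fs$flank_gene)]))
  ## tandem simulant: extra focal copy between the flanks
  focal <- substr(ref[["chr1"]], 17000, 17800)
  genome2 <- c(chr1 = paste0(substr(ref[["chr1"]], 1, 18500), focal,
                             substr(ref[["chr1"]], 18501, 40000)))
  fs2 <- flank_synteny("g4", ann, ref, genome2)
  expect_true(all(fs2$n_matches == 1L))
  expect_equal(copy_number(focal, genome2)$n_matches, 2L)
})

test_that("short flank fragments are excluded by the 50% length rule", {
  set.seed(50)
  ref <- c(chr1 = random_dna(30000))
  ann <- data.frame(gene_id = c("up1", "focal"), chrom = "chr1",
                    start = c(5000L, 15000L), end = c(5999L, 15999L),
                    strand = "+", feature_class = "gene")
  ## genome containing only 45% of the flank gene
  frag <- substr(ref[["chr1"]], 5000, 5449)
  genome <- c(chrX = paste0(random_dna(5000), frag, random_dna(5000)))
  fs <- flank_synteny("focal", ann, ref, genome, n_flank = 1)
  expect_equal(fs$n_matches[fs$flank_gene == "up1"], 0L)
})

test_that("insertion presence applies the 3-spanning-pair rule exactly", {
  pair <- function(m1s, m2s, rl = 50)
    data.frame(m1_start = m1s, m1_end = m1s + rl - 1,
               m2_start = m2s, m2_end = m2s + rl - 1)
  J <- 1000
  three <- do.call(rbind, lapply(1:3, function(i) pair(900 + i, 1010 + i)))
  expect_equal(insertion_present(three, J)$present, "present")
  two <- three[1:2, ]
  expect_equal(insertion_present(two, J)$present, "absent")
  none <- pair(100, 200)
  expect_equal(insertion_present(none, J)$spanning, 0L)
})
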