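test_that("single-founder populations are monomorphic and filtered empty", {
  cfg <- sim_config(n_accessions = 10, chrom_lengths = c(chr1 = 20000),
                    snp_density = 2e-3, n_founders = 1, recomb_rate = 1e-4,
                    seed = 1)
  gm <- simulate_population(cfg)
  expect_equal(n_snps(gm), 0L)
})

test_that("without recombination every accession equals one founder", {
  cfg <- sim_config(n_accessions = 12, chrom_lengths = c(chr1 = 50000),
                    snp_density = 2e-3, n_founders = 4, recomb_rate = 0,
                    seed = 2)
  gm <- simulate_population(cfg)
  mosaic <- attr(gm, "mosaic")
  expect_true(all(apply(mosaic, 2, function(x) length(unique(x)) == 1)))
  founders <- attr(gm, "founders")
  for (i in seq_len(n_accessions(gm)))
    expect_identical(gm$calls[, i], unname(founders[mosaic[1, i], ]))
})

test_that("the population is homozygous and polymorphic, deterministically", {
  cfg <- small_cfg()
  gm1 <- simulate_population(cfg)
  gm2 <- simulate_population(cfg)
  expect_identical(gm1$calls, gm2$calls)
  expect_identical(gm1$map, gm2$map)
  expect_true(all(gm1$calls %in% c(0L, 2L)))
  p <- rowMeans(gm1$calls == 2L)
  expect_true(all(p > 0 & p < 1))
})

test_that("trans injection equals the per-site template/carrier comparison", {
  cfg <- sim_config(n_accessions = 30, chrom_lengths = c(chr1 = 60000),
                    snp_density = 5e-3, n_founders = 4, recomb_rate = 5e-5,
                    seed = 3)
  gm <- simulate_population(cfg)
  src <- c(10000L, 20000L)    # interval with many SNPs
  ev <- duplication_event("chr1", src[1], src[2], "chr1", 50000L,
                          mode = "trans", carrier_founder = 2,
                          divergence = 0, template_founder = 1)
  out <- plant_duplication(gm, ev, cfg)
  ev_done <- attr(out, "events")[[1]]
  expect_gt(length(ev_done$carriers), 0)
  founders <- attr(gm, "founders"); mosaic <- attr(gm, "mosaic")
  in_src <- which(gm$map$chrom == "chr1" & gm$map$pos >= src[1] &
                  gm$map$pos <= src[2])
  for (acc in ev_done$carriers) {
    i <- match(acc, gm$accessions)
    expected_het <- sum(founders[1, in_src] !=
                        founders[cbind(mosaic[in_src, i], in_src)])
    expect_equal(sum(out$calls[, i] == 1L), expected_het)
  }
  ## non-carriers untouched
  for (acc in setdiff(gm$accessions, ev_done$carriers)) {
    i <- match(acc, gm$accessions)
    expect_true(all(out$calls[, i] != 1L))
  }
})

test_that("tandem duplications with zero divergence inject nothing", {
  cfg <- sim_config(n_accessions = 20, chrom_lengths = c(chr1 = 60000),
                    snp_density = 5e-3, n_founders = 4, recomb_rate = 5e-5,
                    seed = 4)
  gm <- simulate_population(cfg)
  ev <- duplication_event("chr1", 10000L, 15000L, "chr1", 16000L,
                          mode = "tandem", carrier_founder = 1,
                          divergence = 0)
  out <- plant_duplication(gm, ev, cfg)
  expect_equal(sum(out$calls == 1L), 0L)
  expect_error(duplication_event("chr1", 1000L, 2000L, "chr1", 50000L,
                                 mode = "tandem", carrier_founder = 1,
                                 divergence = 0), "20 kb")
})

test_that("injected het calls stay inside planted source intervals", {
  sim <- small_sim()
  ev <- sim$truth[[1]]
  het_rows <- which(rowSums(sim$gm$calls == 1L) > 0)
  expect_true(all(sim$gm$map$chrom[het_rows] == ev$source_chrom &
                  sim$gm$map$pos[het_rows] >= ev$source_start &
                  sim$gm$map$pos[het_rows] <= ev$source_end))
  ## only carriers are het
  het_cols <- which(colSums(sim$gm$calls == 1L) > 0)
  expect_true(all(sim$gm$accessions[het_cols] %in% ev$carriers))
})

test_that("the carrier set has a perfect-LD tag SNP", {
  sim <- small_sim()
  ev <- sim$truth[[1]]
  tag <- match(ev$tag_snp, sim$gm$map$id)
  carrier <- as.numeric(sim$gm$accessions %in% ev$carriers)
  dosage <- as.numeric(sim$gm$calls[tag, ] == 2L)
  expect_equal(stats::cor(carrier, dosage)^2, 1)
})

test_that("divergence injects about m * d new pseudo-SNPs per event", {
  cfg <- sim_config(n_accessions = 10, chrom_lengths = c(chr1 = 40000),
                    snp_density = 1e-3, n_founders = 3, recomb_rate = 0,
                    seed = 5)
  gm <- simulate_population(cfg)
  src <- c(5000L, 6999L)
  in_src <- sum(gm$map$pos >= src[1] & gm$map$pos <= src[2])
  m <- (src[2] - src[1] + 1) - in_src   # SNP-free template bases
  d <- 0.02
  n_new <- vapply(seq_len(50), function(r) {
    ev <- duplication_event("chr1", src[1], src[2], "chr1", 30000L,
                            mode = "trans", carrier_founder = 1,
                            divergence = d, id = paste0("e", r))
    out <- plant_duplication(gm, ev, cfg, seed = 1000 + r)
    sum(out$map$injected)
  }, numeric(1))
  se_mean <- sqrt(m * d * (1 - d) / 50)
  expect_lt(abs(mean(n_new) - m * d), 3 * se_mean)
})

test_that("assemblies carry the insertion in carriers only", {
  cfg <- sim_config(n_accessions = 8, chrom_lengths = c(chr1 = 30000,
                                                        chr2 = 30000),
                    snp_density = 2e-3, n_founders = 3, recomb_rate = 2e-5,
                    seed = 6)
  sim <- simulate_study(cfg, n_genes = 4, gene_length = 600, events = 1,
                        divergence = 0, min_trans_distance = 5000)
  ev <- sim$truth[[1]]
  asm <- emit_assemblies(sim)
  copy_len <- ev$source_end - ev$source_start + 1L
  for (acc in sim$gm$accessions) {
    g <- asm[[acc]]
    if (acc %in% ev$carriers) {
      expect_equal(nchar(g[[ev$insertion_chrom]]),
                   nchar(sim$reference[[ev$insertion_chrom]]) + copy_len)
      ## divergence 0, trans: inserted copy is the template haplotype and
      ## occurs verbatim at the insertion point
      ins <- substr(g[[ev$insertion_chrom]], ev$insertion_pos + 1L,
                    ev$insertion_pos + copy_len)
      i <- match(acc, sim$gm$accessions)
      expect_identical(ins, pseudohet:::copy_sequence(sim, ev, i))
    } else {
      for (ch in names(g))
        expect_equal(nchar(g[[ch]]), nchar(sim$reference[[ch]]))
    }
  }
})

test_that("collapsed methylation counts pool copies; own-genome keeps them apart", {
  cfg <- sim_config(n_accessions = 6, chrom_lengths = c(chr1 = 30000),
                    snp_density = 2e-3, n_founders = 2, recomb_rate = 2e-5,
                    seed = 8, founder_probs = c(0.5, 0.5))
  sim <- simulate_study(cfg, n_genes = 3, gene_length = 500, events = 1,
                        divergence = 0.05, min_trans_distance = 5000)
  ev <- sim$truth[[1]]
  ## copies at levels 0 and 1: collapsed expectation 0.5 at equal depth
  dup <- sim$meth_truth$gene_id == ev$source_gene
  sim$meth_truth$level_source[dup] <- 0
  sim$meth_truth$level_copy[dup] <- 1
  expect_error(emit_methylation(sim, depth = 0), "depth")
  meth <- emit_methylation(sim, depth = 10000, n_cyt = 5)
  lv <- methylation_levels(meth)
  carrier <- ev$carriers[1]
  lv_dup <- lv[lv$gene_id == ev$source_gene & lv$accession == carrier &
               lv$context == "CG", ]
  expect_equal(lv_dup$level[lv_dup$target == "reference"], 0.5,
               tolerance = 0.02)
  expect_equal(lv_dup$level[lv_dup$target == "own_genome"], 0,
               tolerance = 0.02)
  ## single-copy gene: identical reads under both targets
  single <- setdiff(sim$annotation$gene_id, ev$source_gene)[1]
  lv_s <- lv[lv$gene_id == single & lv$accession == carrier &
             lv$context == "CG", ]
  expect_equal(lv_s$level[lv_s$target == "reference"],
               lv_s$level[lv_s$target == "own_genome"])
  ## binomial sampling converges to truth at high depth
  truth <- sim$meth_truth[sim$meth_truth$gene_id == single &
                          sim$meth_truth$context == "CG", ]
  expect_equal(lv_s$level[lv_s$target == "own_genome"],
               truth$level_source, tolerance = 0.02)
})

test_that("read pairs span the junction for carriers only", {
  sim <- small_sim()
  ev <- sim$truth[[1]]
  rp <- emit_read_pairs(sim, ev, n_pairs = 10)
  J <- attr(rp, "junction")
  for (acc in sim$gm$accessions) {
    res <- insertion_present(rp[rp$accession == acc, ], J)
    expected <- if (acc %in% ev$carriers) "present" else "absent"
    expect_equal(res$present, expected)
  }
  rp2 <- emit_read_pairs(sim, ev, n_pairs = 2)
  res2 <- insertion_present(rp2[rp2$accession == ev$carriers[1], ],
                            attr(rp2, "junction"))
  expect_equal(res2$present, "absent")   # below the 3-pair threshold
  expect_equal(res2$spanning, 2L)
})
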