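# Shared simulation fixtures, built once per test run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, .fixture_cache)) assign(key, force(expr), .fixture_cache)
  get(key, .fixture_cache)
}

# Small population: 60 accessions, 2 x 150 kb, ~600 SNPs.
small_cfg <- function(seed = 7, ...) {
  sim_config(n_accessions = 60, chrom_lengths = c(chr1 = 150000,
                                                  chr2 = 150000),
             snp_density = 2e-3, n_founders = 6, recomb_rate = 2e-5,
             seed = seed, ...)
}

small_sim <- function() cached("small_sim", {
  simulate_study(small_cfg(founder_probs = c(0.3, rep(0.7 / 5, 5))),
                 n_genes = 10, gene_length = 800, events = 1,
                 divergence = 0.05, min_trans_distance = 1e5)
})

# Longer genes so injected het runs exceed the 1 kb tract minimum.
tract_sim <- function() cached("tract_sim", {
  simulate_study(small_cfg(seed = 9, founder_probs = c(0.3, rep(0.7 / 5, 5))),
                 n_genes = 6, gene_length = 2500, events = 1,
                 divergence = 0.05, min_trans_distance = 1e5)
})

# The study-scale conditions: 300 accessions, 2 x 1 Mb, ~5000 SNPs,
# carrier frequency 0.3.
study_cfg <- function(seed, n_events = 1) {
  run_config(seed = seed, n_accessions = 300, n_chrom = 2,
             chrom_length = 1e6, snp_density = 2.5e-3, n_founders = 10,
             recomb_rate = 1e-5, carrier_freq = 0.3, n_events = n_events,
             divergence = 0.05, n_genes = 20, gene_length = 1000)
}

study_sim <- function(seed, n_events = 1) {
  cfg <- study_cfg(seed, n_events)
  simulate_study(sim_config(n_accessions = cfg$n_accessions,
                            chrom_lengths = c(chr1 = 1e6, chr2 = 1e6),
                            snp_density = cfg$snp_density,
                            n_founders = cfg$n_founders,
                            recomb_rate = cfg$recomb_rate,
                            seed = cfg$seed,
                            founder_probs = cfg$founder_probs),
                 n_genes = cfg$n_genes, gene_length = cfg$gene_length,
                 events = cfg$n_events, divergence = cfg$divergence)
}

# Run the discovery arm (filter -> phenotype -> mixed model -> peaks) for
# the highest-frequency pseudo-SNP of each gene; returns peaks per gene.
discovery_arm <- function(sim, logp_min = 4, maf_min = 0.05) {
  ps <- filter_pseudo_snps(sim$gm, sim$annotation)
  if (nrow(ps) == 0) return(list(pseudo = ps, peaks = NULL))
  K <- compute_kinship(sim$gm)
  chrom_lengths <- sim$cfg$chrom_lengths
  peaks <- list()
  for (g in unique(ps$gene_id)) {
    sub <- ps[ps$gene_id == g, ]
    sub <- sub[order(-sub$het_frequency, sub$pos), ]
    focal <- sub[1, ]
    y <- make_phenotype(sim$gm, focal$id)
    vc <- fit_null(y, K)
    sc <- suppressMessages(scan_assoc(y, sim$gm, K, vc))
    sc <- filter_scan(sc, maf_min = maf_min, logp_min = logp_min)
    pk <- call_peaks(sc, focal$chrom, focal$pos, peak_params(),
                     chrom_lengths)
    if (nrow(pk) > 0) {
      pk$gene_id <- g
      pk$pseudo_snp <- focal$id
      peaks[[g]] <- pk
    }
  }
  list(pseudo = ps,
       peaks = if (length(peaks)) do.call(rbind, peaks) else NULL)
}
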