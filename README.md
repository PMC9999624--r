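# pseudohet

Mapping cryptic gene duplications in inbred (selfing) lines from the
spurious heterozygous SNP calls they leave behind.

## The problem

Lines of a highly selfing species are homozygous essentially genome-wide,
so a heterozygous genotype call is almost always an artifact. The most
common cause is a duplication that is present in the sequenced line but
absent from the reference genome: short reads from the diverged extra
copy mis-map onto the original locus and produce "pseudo-SNPs" —
heterozygous calls shared by exactly the carriers of the duplication.
`pseudohet` turns this artifact into a mapping signal:

1. **Scan** genotype matrices for shared heterozygosity and runs
   (tracts) of heterozygous calls (`summarize_het()`,
   `detect_het_tracts()`).
2. **Filter** a core pseudo-SNP set: heterozygous in ≥ 5% of the
   population and inside annotated genes (`filter_pseudo_snps()`).
3. **Map** the duplicate copy by GWAS, using heterozygosity at each
   focal SNP as a binary phenotype (1 = het) in an accelerated linear
   mixed model: identity-by-state kinship K, one REML fit of
   y = μ + g + e with g ~ N(0, σ²g K), e ~ N(0, σ²e I) under the null,
   then per-SNP generalized-least-squares t-tests with the variance
   ratio δ = σ²e/σ²g held fixed (`compute_kinship()`, `fit_null()`,
   `scan_assoc()`).
4. **Call peaks** on the FFT-smoothed −log10 p signal (lowest 5% of
   Fourier components kept), take the top SNP within ±10 kb of each
   peak, and classify peaks **cis** (≤ 50 kb from the focal pseudo-SNP,
   same chromosome — the source locus) or **trans** (the duplicate's
   location) at final thresholds −log10 p ≥ 20, MAF ≥ 0.1
   (`call_peaks()`, `summarize_gene()`).
5. **Confirm** predictions in assembled genomes with a seed-and-extend
   local aligner at the 70% identity / 70% length rule, a match within
   20 kb of the mapped peak counting as confirmation; estimate copy
   number from match counts and 50 bp coverage windows; call insertion
   presence from ≥ 3 junction-spanning read pairs
   (`align_search()`, `confirm_prediction()`, `copy_number()`,
   `insertion_present()`).
6. **Quantify** the downstream bisulfite artifact: weighted methylation
   levels Σc/Σt (cytosine depth ≥ 3), differential calls at strict
   0.05 (CG) / 0.03 (CHG) thresholds, and discordance between
   reference-collapsed and own-genome mapping stratified by copy number
   (`weighted_level()`, `discordance_table()`).

A forward simulator of selfed founder-mosaic populations with planted
trans/tandem duplications (`simulate_study()`) provides ground truth for
every stage, and `run_all()` executes the whole pipeline into a
directory of TSVs with a per-event recovery report.

## Worked example

Simulate the packaged study conditions — 300 accessions, 2 chromosomes
× 1 Mb (~5,000 SNPs), one trans duplication of a 1 kb gene at carrier
frequency 0.3 and 5% copy divergence — and map the duplicate:

```r
library(pseudohet)

cfg <- sim_config(n_accessions = 300,
                  chrom_lengths = c(chr1 = 1e6, chr2 = 1e6),
                  snp_density = 2.5e-3, n_founders = 10,
                  recomb_rate = 1e-5, seed = 42,
                  founder_probs = c(0.3, rep(0.7 / 9, 9)))
sim <- simulate_study(cfg, n_genes = 20, gene_length = 1000,
                      events = 1, divergence = 0.05)
sim
#> pseudohet_sim: 300 accessions, 5044 SNPs, 20 genes, 1 planted event(s)

ps <- filter_pseudo_snps(sim$gm, sim$annotation)
attr(ps, "funnel")
#>        stage count
#> 1 total_snps  5044
#> 2   het_snps    51
#> 3  freq_pass    51
#> 4 genic_pass    51

y  <- make_phenotype(sim$gm, ps$id[1])   # 1 = het at the focal SNP
K  <- compute_kinship(sim$gm)
vc <- fit_null(y, K)
sc <- filter_scan(scan_assoc(y, sim$gm, K, vc))
pk <- call_peaks(sc, ps$chrom[1], ps$pos[1], peak_params(),
                 c(chr1 = 1e6, chr2 = 1e6))
pk
#>   peak_chrom center_bp      top_id top_pos minus_log10_p  maf label
#> 1       chr1    791500 chr1_791196  791196    300.000000 0.32 trans
#> 2       chr1    816500 chr1_809164  809164      4.335568 0.45 trans

sim$truth[[1]]$insertion_pos
#> [1] 791297
```

The 51 pseudo-SNPs are the heterozygous calls injected into the planted
source gene; every one passes the 5%-frequency and genic filters. The
strongest trans peak (−log10 p floored at 300, MAF 0.32 ≈ the carrier
frequency) identifies the duplicate's insertion point to within ~100 bp
(top SNP at 791,196 vs true insertion at 791,297 on chr1; the source
gene is on chr2). The second, weaker peak is smoothing ringing below the
final −log10 p ≥ 20 threshold and is discarded by `summarize_gene()`.

The same experiment as one command, including confirmation in simulated
assemblies and the methylation comparison:

```r
cfg <- run_config(seed = 42)          # the defaults are the study conditions
report <- run_all(cfg, "run42")
read_tsv_c("run42/recovery_report.tsv")
```

A thin CLI over the same functions is installed at
`inst/cli/pseudohet.R` (subcommands `simulate`, `hetscan`, `filter`,
`gwas`, `peaks`, `confirm`, `insertion-freq`, `methyl`, `run-all`).

## Layout

| path | contents |
| --- | --- |
| `R/` | io (VCF/GFF3/FASTA/TSV), simulator, het scanning, pseudo-SNP filter, mixed model, peak calling, aligner + confirmation, methylation, pipeline |
| `src/` | affine-gap Smith–Waterman extension (Rcpp) |
| `tests/testthat/` | unit + property tests with independent oracles; `test-acceptance.R` holds the end-to-end checks |
| `vignettes/duplication-mapping.Rmd` | the model, its assumptions, parameter defaults and design choices |
| `scripts/acceptance.R` | recomputes the headline numbers (above) |
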