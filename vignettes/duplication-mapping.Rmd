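---
title: "Mapping cryptic duplications from pseudo-heterozygosity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping cryptic duplications from pseudo-heterozygosity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pseudohet)
```

## The problem

In a highly selfing species, every line in a sequenced collection is
expected to be homozygous essentially genome-wide. Yet SNP calling from
short reads routinely reports heterozygous genotypes in such lines. When
a gene is duplicated in an accession but the duplication is absent from
the reference genome, reads from the extra copy have nowhere to go: they
mis-map onto the original locus, and any sequence difference between the
two copies appears as a well-supported heterozygous call — a
*pseudo-SNP*. Two properties make this artifact exploitable rather than
merely annoying:

* the same positions are "heterozygous" in the same subset of lines —
  exactly the carriers of the duplication — so pseudo-heterozygosity
  segregates like a genetic marker;
* the duplicate copy sits somewhere specific in carrier genomes, so SNPs
  in linkage disequilibrium (LD) with its insertion site tag it, exactly
  as they would tag a causal allele in an association study.

`pseudohet` implements the resulting workflow end to end: characterize
shared heterozygosity, distill a core pseudo-SNP set, run a linear
mixed-model association scan with heterozygosity at each focal SNP as a
binary phenotype, call smoothed association peaks, classify them *cis*
(tagging the source locus) or *trans* (tagging the duplicate), confirm
predicted copies in assembled genomes by local alignment, and quantify
the methylation-calling artifacts the same mis-mapping causes in
bisulfite data.

## The synthetic population

Every stage is exercised against a forward simulator
(`simulate_study()`), which is first-class, tested code rather than a
fixture. It emulates:

* **A selfed population with controlled LD.** Each of `n_accessions`
  lines is a homozygous recombinant mosaic of `n_founders` ancestral
  haplotypes; the founder index switches between adjacent SNPs with
  probability $1 - e^{-r \cdot \mathrm{gap}}$. A founder-mosaic model was
  chosen over a coalescent simulator deliberately: the method needs
  tag-SNP LD and a controlled carrier frequency, not realistic
  genealogies, and the mosaic gives both exactly.
* **Segregating duplications.** A `duplication_event()` copies a source
  gene to an insertion point. Carriers are the accessions whose mosaic
  at the insertion point equals a designated founder, so carrier status
  behaves like any founder allele; its population frequency is set by
  `founder_probs` (0.3 in the default study conditions). In `trans` mode
  the copy descends from one founder haplotype, so pre-existing allelic
  differences between that template and a carrier's own allele produce
  instant pseudo-heterozygosity; in `tandem` mode the copy templates the
  carrier's own haplotype and only post-duplication divergence
  (`divergence`, substitutions per bp) creates pseudo-SNPs — which is
  why dispersed duplications are intrinsically easier to detect.
* **Pseudo-SNP injection.** At pre-existing SNPs inside the source
  interval, a carrier's call becomes heterozygous when the copy allele
  differs from its own. Divergence mutations at SNP-free template bases
  create *new* SNP records, heterozygous in every carrier (about
  $m \cdot d$ of them for $m$ template bases at divergence $d$).
  Injection is deterministic given the copy sequence; an optional
  per-site false-negative rate (default 0) models reads that fail to
  mis-map. The SNP nearest the insertion point is recoded into a
  founder-indicator allele, so a perfect-LD tag for the carrier set
  always exists — this encodes the assumption that the insertion site is
  taggable at all, which in real data fails when duplications insert
  into regions with no well-genotyped SNPs nearby.
* **Matching emissions.** Per-accession genome assemblies (reference
  plus own alleles, plus the inserted copy in carriers), per-cytosine
  bisulfite counts under own-genome vs reference-collapsed mapping,
  junction read pairs, and 50 bp coverage windows with doubled expected
  depth over collapsed duplicated genes.

What the simulator does **not** model: read-level noise and mapping
quality, indels and rearrangements beyond a clean insertion, repetitive
sequence (the reference is i.i.d. random DNA), and genuine residual
heterozygosity from recent outcrossing. Passing tests therefore
demonstrate the statistical machinery and its thresholds, not robustness
to alignment pathologies in real genomes.

## Heterozygosity scanning

`summarize_het()` reports per-SNP heterozygote counts and whether both
alleles also occur as homozygotes (expected when copies descend from a
segregating allele). `detect_het_tracts()` finds runs of heterozygosity
per accession with a sliding window over consecutive SNPs — window size
10, vote threshold 0.05, at most one homozygous and one missing call per
window, minimum 3 SNPs, 1 kb, and one SNP per 100 kb of tract length,
with a 1 Mb gap limit. These defaults replicate the documented behavior
of the detectRUNS package as parameterized for heterozygosity runs; all
of them are explicit `tract_params()` fields so any divergence from that
tool is testable. The caller is verified against a brute-force window
enumeration oracle. Sharing between tracts uses 50% reciprocal overlap —
one concrete formalization of "shared tracts", which the underlying
analysis never pins down; per-SNP sharing is available from
`summarize_het()` alongside.

## The pseudo-SNP funnel and phenotypes

`filter_pseudo_snps()` keeps heterozygous SNPs seen in at least 5% of
the population (inclusive; the frequency denominator is all accessions,
with a non-missing-denominator flag) that lie inside annotated gene
bodies. Gene bodies rather than CDS intervals operationalize "coding
regions"; CDS-only filtering is a flag away but is not the default
because the simulator annotates whole genes. `make_phenotype()` codes
heterozygosity at one focal SNP as 1/0; missing calls default to 0
(not-heterozygous) rather than NA because absence of a het call is the
phenotype's definition, not missing data — exclusion is available by
flag. `rare_enrichment()` tests whether singleton or doubleton het SNPs
concentrate in genes already identified as duplicated, with a one-sided
exact binomial test against the fraction of genic SNP positions those
genes contain (the underlying analysis reports p-values without naming a
test; the exact binomial is the conservative elementary choice).

## The mixed-model scan

The scan is an EMMAX-style accelerated mixed model, written in-house:

1. **Kinship.** `compute_kinship()` builds identity-by-state similarity
   over homozygous, non-missing calls (heterozygous calls are excluded
   throughout the genotype side, matching a scan whose genotype matrix
   has het calls filtered out). A VanRaden centered kinship is available
   behind a flag.
2. **One REML fit under the null.** `fit_null()` profiles the restricted
   likelihood of $y = \mu + g + e$, $g \sim N(0, \sigma_g^2 K)$,
   $e \sim N(0, \sigma_e^2 I)$ over $\delta = \sigma_e^2/\sigma_g^2$
   via the eigendecomposition of $K$: a 64-point grid on
   $\log\delta \in [-10, 10]$ followed by Brent refinement to $10^{-6}$.
   REML rather than ML is standard practice for variance components and
   keeps the intercept from biasing $\delta$. When the criterion is flat
   in $\delta$ (e.g. $K = I$, where only total variance is identifiable)
   the convention heritability = 0 is returned and flagged.
3. **Per-SNP GLS.** `scan_assoc()` rotates the phenotype and the
   (intercept, dosage) design by the eigenvectors of $K$, weights by
   $(\lambda_i + \delta)^{-1/2}$, and solves ordinary least squares on
   the transformed system — algebraically the generalized-least-squares
   test with variance components fixed from the null, which is what
   "accelerated" denotes. The dosage codes hom-ref 0 / hom-alt 1, het
   and missing are mean-imputed per SNP, and the two-sided t-test uses
   $n - 2$ degrees of freedom. The binary phenotype is treated as
   Gaussian, as the upstream toolchain implicitly does; no logistic
   mixed model is attempted. P-values below $10^{-300}$ are floored at
   $-\log_{10} p = 300$.

`filter_scan()` applies the raw-output filter (MAF $\ge$ 0.05,
$-\log_{10} p \ge 4$); filtering happens after testing, not before. The
tests pin the scan to a dense GLS oracle at $10^{-8}$ relative error, to
plain-regression t-tests when $K = I$, and to a calibrated permutation
null (fraction of $p < 0.05$ within $0.05 \pm 0.01$ over $10^4$ tests;
genomic-control $\lambda \in [0.9, 1.1]$).

## Peak calling and cis/trans classification

SNP-indexed $-\log_{10} p$ values are gridded onto 1 kb bins per
chromosome (maximum per bin, empty bins 0) — the source analysis never
states how an irregular scan becomes a smoothable signal, so the bin
width is an exposed `peak_params()` field. `fft_smooth()` keeps the
`ceiling(0.05 * length)` lowest-frequency Fourier components (the
`pcKeepComp = 0.05` convention) and clips negative ringing at zero;
because clipping breaks linearity, `clip = FALSE` exposes the exactly
linear smoother that the linearity property test uses.
`detect_peaks()` reports strict local maxima above a floor of 4 on the
smoothed scale (consistent with the raw filter; plateaus report their
central bin), `top_snp_in_window()` takes the strongest SNP within
±10 kb of each peak center (ties to the smaller position), and
`classify_peak()` labels a peak *cis* when its top SNP is on the focal
pseudo-SNP's chromosome within 50 kb, else *trans*. `summarize_gene()`
pools peaks over a gene's pseudo-SNP phenotypes — the union of peaks
surviving the final thresholds ($-\log_{10} p \ge 20$, MAF $\ge 0.1$) —
and assigns `cis_only` / `trans_only` / `both` / `none`; the final MAF
threshold (0.1) intentionally differs from the raw filter (0.05), as the
two are distinct knobs in the upstream procedure. The pipeline scans up
to `max_phenotypes_per_gene = 2` pseudo-SNPs per gene (highest het
frequency first): at simulator scale the phenotypes of one gene are
near-duplicates and scanning all of them only repeats the same peak.

## Confirmation in assembled genomes

`align_search()` is a seed-and-extend local aligner: exact 15-mer seeds
(located by exact numeric k-mer hashing; `genome_index()` precomputes
the genome side when many queries probe one assembly), seeds clustered
by diagonal, each candidate window extended with an affine-gap
Smith–Waterman (Gotoh) DP in C++ at match +1 / mismatch −2 / gap open −5
/ gap extend −2, a length-$k$ gap costing $\mathrm{open} + k \cdot
\mathrm{ext}$. Percent identity is computed over alignment columns
including gaps, since the 70% rule alone does not fix a convention.
Fragmentary same-strand hits within 1 kb on the target whose query
intervals are essentially disjoint (≤ 25% overlap of the shorter) are
chained before coverage computation, so a split hit counts as one copy
while two full-length copies stay separate. Matches need ≥ 70% identity
and ≥ 70% query coverage.

`confirm_prediction()` maps a predicted peak position into an assembly
by aligning the reference segment centered on it (5 kb by default —
at simulator scale a 5 kb anchor is unambiguous and keeps the
$O(nm)$ DP small; the half-width is a parameter) and calls the
prediction confirmed when a gene-sequence match lies within 20 kb of the
mapped position. Because the syntenic ortholog itself is not evidence of
a duplicate, a second call excluding matches at the mapped source locus
is always reported; for trans predictions that is the meaningful one.
`copy_number()` combines the match count (categories 0 / 1 / >1) with
mean 50 bp-window depth over the gene divided by the genome-wide median
(≈ 2 for a collapsed two-copy gene). `flank_synteny()` aligns the three
annotated genes on each side of a focal gene, keeping matches covering
at least 50% of the input, to expose local structure.
`insertion_present()` calls an insertion present when at least 3 read
pairs span the junction (mate 1 ending before it, mate 2 starting after
it).

## Methylation artifacts

`weighted_level()` computes $\sum c_i / \sum t_i$ over a unit's
cytosines with depth ≥ 3 (undefined when none qualify);
`differential_call()` uses strict thresholds of 0.05 (CG) and 0.03
(CHG), with a $10^{-9}$ guard so floating-point representation of a
boundary difference never flips a call. `discordance_table()`
stratifies reference-vs-own-genome differential calls by copy-number
category, with an all-accession intersection row; genes undefined in
either target are excluded from denominators, and genes absent from the
copy-number table count as 0 copies. Gene-body levels are compared (the
upstream analysis computes both gene-body and 200 bp-window levels;
windows remain available through `methylation_levels()` input). In the
simulator, single-copy genes reuse the same simulated reads under both
mapping targets — mapping the same reads to two equivalent targets —
so their discordance reflects only threshold crossings and is ~0; real
single-copy disagreement (a few percent) additionally contains mapping
noise that is out of scope here. For carriers the reference target pools
source and copy reads, which is the artifact mechanism itself.

## Pipeline, determinism and problem sizes

`run_all()` chains the stages into one run directory of TSVs (commented
header lines; fixed numeric formatting), each stage re-runnable from the
previous stage's files. All randomness derives from the single config
seed through fixed per-stage offsets, so a repeated run is
byte-identical — asserted by test. The recovery report lists, per
planted event, whether it was detected, whether the label was right, the
distance from the top trans peak to the true insertion point, and
whether an assembly confirmed it.

The packaged study conditions are 300 accessions, 2 chromosomes × 1 Mb,
~5,000 SNPs, 10 founders, carrier frequency 0.3, 1 kb genes and 5%
copy divergence; the test suite runs 20 seeds of the discovery arm at
those conditions (plus 20 null seeds) in a few minutes, and smaller
populations (e.g. 60 accessions × 2 × 150 kb) everywhere a full-scale
run adds nothing. These sizes are the package's own choice of a
desk-scale experiment that keeps every stage's behavior observable.

## Known limitations

* Binary phenotypes in a Gaussian mixed model are slightly conservative
  at low carrier frequency; the calibration tests bound, but do not
  remove, this.
* Allelic heterogeneity (multiple independent duplications of one gene)
  produces composite peaks that the single-phenotype scan does not
  deconvolve; no conditional analysis is attempted.
* The aligner is a desk-scale tool: exact 15-mer seeding loses
  sensitivity beyond ~25% divergence (by design, given the 70% identity
  rule) and the windowed DP is quadratic in the anchor size.
* Rare duplications (carrier frequency below the 5% filter) are
  invisible to the scan by construction; `rare_enrichment()` only tests
  their association with commonly duplicated genes.
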