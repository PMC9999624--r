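## End-to-end orchestration: a single config drives simulation,
## heterozygosity scanning, pseudo-SNP filtering, the mixed-model scan,
## peak calling, confirmation in assembled genomes, insertion-presence
## calls and the methylation comparison, with one seed and per-stage TSV
## outputs. Each stage reads only prior stage files, so stages can be
## re-run independently.

#' Pipeline run configuration
#'
#' All stage parameters with their standard defaults. `carrier_freq`
#' sets the population frequency of the duplication-carrying founder.
#'
#' @param seed master seed; every stage derives its randomness from it.
#' @param n_accessions,n_chrom,chrom_length,snp_density,n_founders,recomb_rate
#'   population parameters (see [sim_config()]).
#' @param carrier_freq carrier frequency of planted duplications.
#' @param n_events number of trans duplications planted (0 for a null
#'   run).
#' @param divergence per-bp copy divergence.
#' @param n_genes,gene_length annotation parameters.
#' @param n_assembled accessions for which assemblies, coverage,
#'   methylation and read pairs are emitted (carriers are preferentially
#'   included, as assembled lines were chosen to segregate the events).
#' @param freq_threshold pseudo-SNP frequency filter.
#' @param maf_min,logp_min raw scan filters.
#' @param max_phenotypes_per_gene pseudo-SNP phenotypes scanned per gene
#'   (highest het frequency first).
#' @param tract,peaks,align [tract_params()], [peak_params()],
#'   [align_params()] blocks.
#' @param meth_depth,meth_cytosines methylation simulation parameters.
#' @param pairs_per_carrier junction-spanning pairs per carrier.
#' @param coverage_depth,coverage_window coverage simulation parameters.
#' @param anchor_halfwidth half-width (bp) of the reference anchor
#'   segment used to map peak positions into assemblies.
#' @return list of class `run_config`.
#' @export
run_config <- function(seed = 1L, n_accessions = 300L, n_chrom = 2L,
                       chrom_length = 1e6, snp_density = 2.5e-3,
                       n_founders = 10L, recomb_rate = 1e-5,
                       carrier_freq = 0.3, n_events = 1L,
                       divergence = 0.05, n_genes = 20L,
                       gene_length = 1000L, n_assembled = 6L,
                       freq_threshold = 0.05, maf_min = 0.05,
                       logp_min = 4, max_phenotypes_per_gene = 2L,
                       tract = tract_params(), peaks = peak_params(),
                       align = align_params(), meth_depth = 30,
                       meth_cytosines = 20L, pairs_per_carrier = 10L,
                       coverage_depth = 30, coverage_window = 50L,
                       anchor_halfwidth = 2500L) {
  fp <- c(carrier_freq,
          rep((1 - carrier_freq) / (n_founders - 1), n_founders - 1))
  structure(list(seed = as.integer(seed),
                 n_accessions = as.integer(n_accessions),
                 n_chrom = as.integer(n_chrom),
                 chrom_length = chrom_length, snp_density = snp_density,
                 n_founders = as.integer(n_founders),
                 recomb_rate = recomb_rate, carrier_freq = carrier_freq,
                 founder_probs = fp, n_events = as.integer(n_events),
                 divergence = divergence, n_genes = as.integer(n_genes),
                 gene_length = as.integer(gene_length),
                 n_assembled = as.integer(n_assembled),
                 freq_threshold = freq_threshold, maf_min = maf_min,
                 logp_min = logp_min,
                 max_phenotypes_per_gene = as.integer(max_phenotypes_per_gene),
                 tract = tract, peaks = peaks, align = align,
                 meth_depth = meth_depth,
                 meth_cytosines = as.integer(meth_cytosines),
                 pairs_per_carrier = as.integer(pairs_per_carrier),
                 coverage_depth = coverage_depth,
                 coverage_window = as.integer(coverage_window),
                 anchor_halfwidth = as.integer(anchor_halfwidth)),
            class = "run_config")
}

#' Parse a plain-text run configuration
#'
#' Reads `key = value` lines (# comments allowed); keys are the scalar
#' arguments of [run_config()]. `seed` is required.
#'
#' @param path config file path.
#' @return a [run_config()].
#' @export
parse_run_config <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- lines[grepl("=", lines, fixed = TRUE)]
  kv <- do.call(rbind, strsplit(lines, "=", fixed = TRUE))
  keys <- trimws(kv[, 1]); vals <- trimws(kv[, 2])
  args <- lapply(seq_along(keys), function(i) {
    v <- suppressWarnings(as.numeric(vals[i]))
    if (is.na(v)) vals[i] else v
  })
  names(args) <- keys
  if (!"seed" %in% keys) stop("parse_run_config: seed is required")
  allowed <- setdiff(names(formals(run_config)),
                     c("tract", "peaks", "align"))
  bad <- setdiff(keys, allowed)
  if (length(bad) > 0)
    stop("parse_run_config: unknown key(s): ", paste(bad, collapse = ", "))
  do.call(run_config, args)
}

## internal: the sim_config implied by a run_config
sim_config_of <- function(config) {
  sim_config(n_accessions = config$n_accessions,
             chrom_lengths = setNames(rep(config$chrom_length,
                                          config$n_chrom),
                                      paste0("chr", seq_len(config$n_chrom))),
             snp_density = config$snp_density,
             n_founders = config$n_founders,
             recomb_rate = config$recomb_rate,
             seed = config$seed,
             founder_probs = config$founder_probs)
}

#' Run the simulation stage
#'
#' Simulates the study and writes `sim.vcf`, `genes.gff3`,
#' `reference.fa`, `truth_events.tsv`, per-assembled-accession
#' `accession_<id>.fa`, `methylation.tsv`, `read_pairs.tsv` and
#' `coverage.tsv` into `dir`.
#'
#' @param config a [run_config()].
#' @param dir output directory (created if missing).
#' @return the `pseudohet_sim`, invisibly.
#' @export
stage_simulate <- function(config, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_study(sim_config_of(config), n_genes = config$n_genes,
                        gene_length = config$gene_length,
                        events = config$n_events,
                        divergence = config$divergence)
  write_vcf(sim$gm, file.path(dir, "sim.vcf"))
  write_gff(sim$annotation, file.path(dir, "genes.gff3"))
  write_fasta(sim$reference, file.path(dir, "reference.fa"))
  ev_df <- if (length(sim$truth) == 0)
    data.frame(id = character(), source_gene = character(),
               source_chrom = character(), source_start = integer(),
               source_end = integer(), insertion_chrom = character(),
               insertion_pos = integer(), mode = character(),
               carrier_founder = integer(), divergence = numeric(),
               n_carriers = integer(), carriers = character())
  else do.call(rbind, lapply(sim$truth, function(e) data.frame(
    id = e$id, source_gene = if (is.null(e$source_gene)) NA else e$source_gene,
    source_chrom = e$source_chrom, source_start = e$source_start,
    source_end = e$source_end, insertion_chrom = e$insertion_chrom,
    insertion_pos = e$insertion_pos, mode = e$mode,
    carrier_founder = e$carrier_founder, divergence = e$divergence,
    n_carriers = length(e$carriers),
    carriers = paste(e$carriers, collapse = ","),
    stringsAsFactors = FALSE)))
  write_tsv_c(ev_df, file.path(dir, "truth_events.tsv"))

  ## assembled subset: carriers of each event first, then non-carriers
  carriers <- unique(unlist(lapply(sim$truth, `[[`, "carriers")))
  pool <- c(intersect(sim$gm$accessions, carriers),
            setdiff(sim$gm$accessions, carriers))
  assembled <- head(pool, config$n_assembled)
  assembled <- assembled[order(match(assembled, sim$gm$accessions))]
  asm <- emit_assemblies(sim, assembled)
  for (acc in assembled)
    write_fasta(asm[[acc]], file.path(dir, paste0("accession_", acc, ".fa")))
  write_tsv_c(data.frame(accession = assembled),
              file.path(dir, "assembled.tsv"))
  meth <- emit_methylation(sim, depth = config$meth_depth,
                           n_cyt = config$meth_cytosines,
                           accessions = assembled)
  write_tsv_c(meth, file.path(dir, "methylation.tsv"))
  if (length(sim$truth) > 0) {
    rp <- do.call(rbind, lapply(seq_along(sim$truth), function(i) {
      p <- emit_read_pairs(sim, sim$truth[[i]],
                           n_pairs = config$pairs_per_carrier,
                           seed = sim$cfg$seed + 211L + i)
      p$event <- sim$truth[[i]]$id
      p$junction <- attr(p, "junction")
      p
    }))
    write_tsv_c(rp, file.path(dir, "read_pairs.tsv"))
  } else {
    write_tsv_c(data.frame(accession = character(), m1_start = integer(),
                           m1_end = integer(), m2_start = integer(),
                           m2_end = integer(), event = character(),
                           junction = integer()),
                file.path(dir, "read_pairs.tsv"))
  }
  cov <- emit_coverage(sim, accessions = assembled,
                       mean_depth = config$coverage_depth,
                       window = config$coverage_window)
  write_tsv_c(cov, file.path(dir, "coverage.tsv"))
  invisible(sim)
}

#' Run the heterozygosity-scan stage
#'
#' Reads `sim.vcf` and writes `het_summary.tsv`, `tracts.tsv`,
#' `density.tsv`.
#'
#' @param config a [run_config()].
#' @param dir run directory.
#' @return invisibly, the het summary.
#' @export
stage_hetscan <- function(config, dir) {
  gm <- read_vcf(file.path(dir, "sim.vcf"))
  hs <- summarize_het(gm)
  write_tsv_c(hs, file.path(dir, "het_summary.tsv"))
  tracts <- detect_het_tracts(gm, config$tract)
  write_tsv_c(tracts, file.path(dir, "tracts.tsv"))
  write_tsv_c(het_density(gm, window_bp = 100000L),
              file.path(dir, "density.tsv"))
  invisible(hs)
}

#' Run the pseudo-SNP filtering stage
#'
#' Reads `sim.vcf` and `genes.gff3`; writes `pseudo_snps.tsv` and
#' `funnel_counts.tsv`.
#'
#' @param config a [run_config()].
#' @param dir run directory.
#' @return invisibly, the pseudo-SNP table.
#' @export
stage_filter <- function(config, dir) {
  gm <- read_vcf(file.path(dir, "sim.vcf"))
  ann <- read_gff(file.path(dir, "genes.gff3"))
  ps <- filter_pseudo_snps(gm, ann, freq_threshold = config$freq_threshold)
  write_tsv_c(ps, file.path(dir, "pseudo_snps.tsv"))
  write_tsv_c(attr(ps, "funnel"), file.path(dir, "funnel_counts.tsv"))
  invisible(ps)
}

## internal: pick the phenotype SNPs scanned per gene
select_phenotype_snps <- function(ps, max_per_gene) {
  ps <- ps[order(ps$gene_id, -ps$het_frequency, ps$pos), , drop = FALSE]
  keep <- unlist(lapply(split(seq_len(nrow(ps)), ps$gene_id),
                        head, max_per_gene), use.names = FALSE)
  ps[sort(keep), , drop = FALSE]
}

#' Run the mixed-model GWAS stage
#'
#' Reads `sim.vcf` and `pseudo_snps.tsv`; for up to
#' `max_phenotypes_per_gene` pseudo-SNPs per gene, builds the binary
#' heterozygosity phenotype, fits the null mixed model and scans all
#' SNPs, writing the filtered scan as `scan_<snp>.tsv` and an index
#' `phenotypes.tsv`.
#'
#' @param config a [run_config()].
#' @param dir run directory.
#' @return invisibly, the phenotype index.
#' @export
stage_gwas <- function(config, dir) {
  gm <- read_vcf(file.path(dir, "sim.vcf"))
  ps <- read_tsv_c(file.path(dir, "pseudo_snps.tsv"))
  idx <- data.frame(snp_id = character(), gene_id = character(),
                    chrom = character(), pos = integer(),
                    scan_file = character())
  if (nrow(ps) > 0) {
    sel <- select_phenotype_snps(ps, config$max_phenotypes_per_gene)
    K <- compute_kinship(gm)
    for (i in seq_len(nrow(sel))) {
      y <- make_phenotype(gm, sel$id[i])
      vc <- fit_null(y, K)
      sc <- scan_assoc(y, gm, K, vc)
      sc <- filter_scan(sc, maf_min = config$maf_min,
                        logp_min = config$logp_min)
      f <- paste0("scan_", gsub("[^A-Za-z0-9_]", "_", sel$id[i]), ".tsv")
      write_tsv_c(sc, file.path(dir, f))
      idx <- rbind(idx, data.frame(snp_id = sel$id[i],
                                   gene_id = sel$gene_id[i],
                                   chrom = sel$chrom[i], pos = sel$pos[i],
                                   scan_file = f, stringsAsFactors = FALSE))
    }
  }
  write_tsv_c(idx, file.path(dir, "phenotypes.tsv"))
  invisible(idx)
}

#' Run the peak-calling stage
#'
#' Reads the per-phenotype scans; writes `peaks.tsv` (one row per called
#' peak) and `gene_summary.tsv` (cis/trans/both/none category per gene).
#'
#' @param config a [run_config()].
#' @param dir run directory.
#' @return invisibly, the gene summary.
#' @export
stage_peaks <- function(config, dir) {
  idx <- read_tsv_c(file.path(dir, "phenotypes.tsv"))
  chrom_lengths <- setNames(rep(config$chrom_length, config$n_chrom),
                            paste0("chr", seq_len(config$n_chrom)))
  all_peaks <- list(); k <- 0L
  for (i in seq_len(nrow(idx))) {
    sc <- read_tsv_c(file.path(dir, idx$scan_file[i]))
    if (nrow(sc) == 0) next
    pk <- call_peaks(sc, idx$chrom[i], idx$pos[i], config$peaks,
                     chrom_lengths)
    if (nrow(pk) == 0) next
    k <- k + 1L
    pk$pseudo_snp <- idx$snp_id[i]
    pk$gene_id <- idx$gene_id[i]
    all_peaks[[k]] <- pk
  }
  peaks <- if (k > 0) do.call(rbind, all_peaks) else
    data.frame(peak_chrom = character(), center_bp = integer(),
               top_id = character(), top_pos = integer(),
               minus_log10_p = numeric(), maf = numeric(),
               label = character(), pseudo_snp = character(),
               gene_id = character())
  write_tsv_c(peaks, file.path(dir, "peaks.tsv"))
  genes <- unique(read_tsv_c(file.path(dir, "pseudo_snps.tsv"))$gene_id)
  summ <- do.call(rbind, c(list(
    data.frame(gene_id = character(), category = character())),
    lapply(genes, function(g) {
      sg <- summarize_gene(peaks[peaks$gene_id == g, , drop = FALSE],
                           logp_final = config$peaks$logp_final,
                           maf_final = config$peaks$maf_final)
      data.frame(gene_id = g, category = sg$category,
                 stringsAsFactors = FALSE)
    })))
  write_tsv_c(summ, file.path(dir, "gene_summary.tsv"))
  invisible(summ)
}

#' Run the assembly-confirmation stage
#'
#' For every significant peak of every gene and every assembled
#' accession, maps the peak into the assembly, searches for the gene
#' sequence and applies the within-20-kb rule; also estimates copy
#' number per gene and accession. Writes `confirmations.tsv` and
#' `copy_number.tsv`.
#'
#' @param config a [run_config()].
#' @param dir run directory.
#' @return invisibly, the confirmation table.
#' @export
stage_confirm <- function(config, dir) {
  peaks <- read_tsv_c(file.path(dir, "peaks.tsv"))
  ann <- read_gff(file.path(dir, "genes.gff3"))
  reference <- read_fasta(file.path(dir, "reference.fa"))
  assembled <- read_tsv_c(file.path(dir, "assembled.tsv"))$accession
  coverage <- read_tsv_c(file.path(dir, "coverage.tsv"))
  ap <- config$align
  sig <- peaks[peaks$minus_log10_p >= config$peaks$logp_final &
               peaks$maf >= config$peaks$maf_final, , drop = FALSE]
  conf <- list(); cn <- list(); k <- 0L; k2 <- 0L
  for (acc in assembled) {
    genome <- read_fasta(file.path(dir, paste0("accession_", acc, ".fa")))
    idx <- genome_index(genome, ap$k)
    depth <- coverage[coverage$accession == acc, , drop = FALSE]
    ## copy number for the whole gene universe (the Table-1 analog)
    for (g in ann$gene_id[ann$feature_class == "gene"]) {
      row <- ann[ann$gene_id == g, ]
      gene_seq <- substr(reference[[row$chrom]], row$start, row$end)
      est <- copy_number(gene_seq, idx, depth_table = depth,
                         gene_chrom = row$chrom, gene_start = row$start,
                         gene_end = row$end, params = ap)
      k2 <- k2 + 1L
      cn[[k2]] <- data.frame(gene_id = g, accession = acc,
                             n_matches = est$n_matches,
                             category = est$category,
                             coverage_ratio = est$coverage_ratio,
                             stringsAsFactors = FALSE)
    }
    for (g in unique(sig$gene_id)) {
      row <- ann[ann$gene_id == g, ]
      gene_seq <- substr(reference[[row$chrom]], row$start, row$end)
      gp <- sig[sig$gene_id == g, , drop = FALSE]
      for (i in seq_len(nrow(gp))) {
        res <- confirm_prediction(
          gene_seq, gp$peak_chrom[i], gp$top_pos[i], idx, reference,
          source_chrom = row$chrom,
          source_pos = as.integer((row$start + row$end) / 2),
          anchor_halfwidth = config$anchor_halfwidth,
          params = align_params(
            match = ap$match, mismatch = ap$mismatch,
            gap_open = ap$gap_open, gap_ext = ap$gap_ext, k = ap$k,
            chain_gap = ap$chain_gap, window_margin = ap$window_margin))
        k <- k + 1L
        conf[[k]] <- data.frame(
          gene_id = g, accession = acc, pseudo_snp = gp$pseudo_snp[i],
          peak_chrom = gp$peak_chrom[i], top_pos = gp$top_pos[i],
          label = gp$label[i], confirmed = res$confirmed,
          confirmed_excluding_source = res$confirmed_excluding_source,
          mapped_pos = res$mapped_pos, n_matches = res$n_matches,
          stringsAsFactors = FALSE)
      }
    }
  }
  conf_df <- if (k > 0) do.call(rbind, conf) else
    data.frame(gene_id = character(), accession = character(),
               pseudo_snp = character(), peak_chrom = character(),
               top_pos = integer(), label = character(),
               confirmed = logical(), confirmed_excluding_source = logical(),
               mapped_pos = integer(), n_matches = integer())
  cn_df <- if (k2 > 0) do.call(rbind, cn) else
    data.frame(gene_id = character(), accession = character(),
               n_matches = integer(), category = character(),
               coverage_ratio = numeric())
  write_tsv_c(conf_df, file.path(dir, "confirmations.tsv"))
  write_tsv_c(cn_df, file.path(dir, "copy_number.tsv"))
  invisible(conf_df)
}

#' Run the insertion-presence stage
#'
#' Reads `read_pairs.tsv` and calls presence per accession and event
#' from junction-spanning pairs; writes `presence.tsv`.
#'
#' @param config a [run_config()].
#' @param dir run directory.
#' @return invisibly, the presence table.
#' @export
stage_insertion_freq <- function(config, dir) {
  rp <- read_tsv_c(file.path(dir, "read_pairs.tsv"))
  out <- list(); k <- 0L
  if (nrow(rp) > 0) {
    for (ev in unique(rp$event)) {
      sub <- rp[rp$event == ev, , drop = FALSE]
      J <- sub$junction[1]
      for (acc in unique(sub$accession)) {
        res <- insertion_present(sub[sub$accession == acc, , drop = FALSE], J)
        k <- k + 1L
        out[[k]] <- data.frame(event = ev, accession = acc,
                               spanning = res$spanning,
                               present = res$present,
                               stringsAsFactors = FALSE)
      }
    }
  }
  pres <- if (k > 0) do.call(rbind, out) else
    data.frame(event = character(), accession = character(),
               spanning = integer(), present = character())
  write_tsv_c(pres, file.path(dir, "presence.tsv"))
  invisible(pres)
}

#' Run the methylation-comparison stage
#'
#' Reads `methylation.tsv` and `copy_number.tsv`; writes `levels.tsv`,
#' `differential.tsv` and `discordance_summary.tsv`.
#'
#' @param config a [run_config()].
#' @param dir run directory.
#' @return invisibly, the discordance summary.
#' @export
stage_methyl <- function(config, dir) {
  meth <- read_tsv_c(file.path(dir, "methylation.tsv"))
  cn <- read_tsv_c(file.path(dir, "copy_number.tsv"))
  lv <- methylation_levels(meth)
  write_tsv_c(lv, file.path(dir, "levels.tsv"))
  wide <- merge(lv[lv$target == "reference",
                   c("gene_id", "accession", "context", "level")],
                lv[lv$target == "own_genome",
                   c("gene_id", "accession", "context", "level")],
                by = c("gene_id", "accession", "context"),
                suffixes = c("_ref", "_own"))
  wide$call <- vapply(seq_len(nrow(wide)), function(i)
    differential_call(wide$level_ref[i], wide$level_own[i],
                      wide$context[i]), character(1))
  wide <- wide[order(wide$gene_id, wide$accession, wide$context), ]
  write_tsv_c(wide, file.path(dir, "differential.tsv"))
  if (nrow(cn) == 0)
    cn <- data.frame(gene_id = character(), accession = character(),
                     n_matches = integer(), category = character(),
                     coverage_ratio = numeric())
  disc <- discordance_table(lv, cn)
  write_tsv_c(disc$discordance, file.path(dir, "discordance_summary.tsv"))
  write_tsv_c(disc$copy_counts, file.path(dir, "copy_counts.tsv"))
  invisible(disc)
}

#' Recovery report against simulation truth
#'
#' Per planted event: was a significant association of the right label
#' found for the source gene, how far is the top trans peak from the
#' true insertion point, and was the duplicate confirmed in at least one
#' carrier assembly. Writes `recovery_report.tsv`.
#'
#' @param config a [run_config()].
#' @param dir run directory.
#' @return the report data.frame, invisibly.
#' @export
stage_recovery <- function(config, dir) {
  truth <- read_tsv_c(file.path(dir, "truth_events.tsv"))
  peaks <- read_tsv_c(file.path(dir, "peaks.tsv"))
  conf <- read_tsv_c(file.path(dir, "confirmations.tsv"))
  rows <- list()
  for (i in seq_len(nrow(truth))) {
    ev <- truth[i, ]
    sig <- peaks[peaks$gene_id == ev$source_gene &
                 peaks$minus_log10_p >= config$peaks$logp_final &
                 peaks$maf >= config$peaks$maf_final, , drop = FALSE]
    tr <- sig[sig$label == "trans", , drop = FALSE]
    detected <- nrow(sig) > 0
    label_ok <- if (ev$mode == "trans") nrow(tr) > 0 else
      any(sig$label == "cis")
    dist <- NA_real_
    if (nrow(tr) > 0) {
      top <- tr[order(-tr$minus_log10_p, tr$top_pos), ][1, ]
      dist <- if (top$peak_chrom == ev$insertion_chrom)
        abs(top$top_pos - ev$insertion_pos) else Inf
    }
    carriers <- strsplit(ev$carriers, ",", fixed = TRUE)[[1]]
    cf <- conf[conf$gene_id == ev$source_gene &
               conf$accession %in% carriers, , drop = FALSE]
    rows[[i]] <- data.frame(
      event = ev$id, source_gene = ev$source_gene, mode = ev$mode,
      detected = detected, label_correct = label_ok,
      top_trans_distance_bp = dist,
      confirmed = nrow(cf) > 0 && any(cf$confirmed),
      stringsAsFactors = FALSE)
  }
  rep <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(event = character(), source_gene = character(),
               mode = character(), detected = logical(),
               label_correct = logical(), top_trans_distance_bp = numeric(),
               confirmed = logical())
  write_tsv_c(rep, file.path(dir, "recovery_report.tsv"))
  invisible(rep)
}

#' Run the complete pipeline
#'
#' Executes every stage in order into `dir`; deterministic given the
#' configuration seed (two runs produce byte-identical TSVs). A stage
#' failure aborts with the stage name and the input fingerprint.
#'
#' @param config a [run_config()].
#' @param dir output directory.
#' @return the recovery report, invisibly.
#' @export
run_all <- function(config, dir) {
  stages <- list(simulate = stage_simulate, hetscan = stage_hetscan,
                 filter = stage_filter, gwas = stage_gwas,
                 peaks = stage_peaks, confirm = stage_confirm,
                 insertion_freq = stage_insertion_freq,
                 methyl = stage_methyl, recovery = stage_recovery)
  for (nm in names(stages)) {
    tryCatch(stages[[nm]](config, dir),
             error = function(e) stop(sprintf(
               "pipeline stage '%s' failed (seed %d, dir %s): %s",
               nm, config$seed, dir, conditionMessage(e)), call. = FALSE))
  }
  invisible(read_tsv_c(file.path(dir, "recovery_report.tsv")))
}
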