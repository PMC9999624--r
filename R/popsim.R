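## Forward simulator of a fully selfed population with founder-mosaic
## linkage disequilibrium and planted duplications whose diverged copies
## generate pseudo-heterozygous calls at the source locus in carriers only.

#' Evaluate an expression under a fixed RNG seed
#'
#' Saves and restores the global RNG state so package simulations do not
#' perturb the caller's random stream.
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

BASES <- c("A", "C", "G", "T")

#' Simulation configuration
#'
#' Describes the selfing population to simulate: every accession is a
#' homozygous recombinant mosaic of `n_founders` ancestral haplotypes, so
#' linkage disequilibrium is fully controlled and heterozygosity is zero
#' until duplications are planted.
#'
#' @param n_accessions number of accessions (inbred lines).
#' @param chrom_lengths named integer vector of chromosome lengths (bp);
#'   unnamed vectors get names `chr1`, `chr2`, ...
#' @param snp_density SNPs per bp (e.g. `2.5e-3` gives ~2500 SNPs/Mb).
#' @param n_founders number of ancestral founder haplotypes.
#' @param recomb_rate crossover probability per bp per mosaic draw; the
#'   founder index switches between adjacent SNPs with probability
#'   `1 - exp(-recomb_rate * gap)`.
#' @param seed integer seed; all simulator output is deterministic given it.
#' @param founder_probs founder sampling probabilities (default uniform).
#'   The population frequency of founder `k` - hence the carrier frequency
#'   of a duplication assigned to founder `k` - is approximately
#'   `founder_probs[k]`.
#' @param fn_rate per-site probability that a pseudo-het injection is
#'   missed (models imperfect mis-mapping; default 0).
#' @param origin_founder founder haplotype providing the default copy
#'   template of trans duplications.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_accessions, chrom_lengths, snp_density,
                       n_founders, recomb_rate, seed,
                       founder_probs = NULL, fn_rate = 0,
                       origin_founder = 1L) {
  stopifnot(n_accessions >= 1, n_founders >= 1, snp_density > 0,
            recomb_rate >= 0, fn_rate >= 0, fn_rate <= 1,
            all(chrom_lengths >= 1))
  if (any(snp_density * chrom_lengths < 10))
    stop("sim_config: need snp_density * length >= 10 per chromosome")
  if (is.null(names(chrom_lengths)))
    names(chrom_lengths) <- paste0("chr", seq_along(chrom_lengths))
  if (is.null(founder_probs)) founder_probs <- rep(1 / n_founders, n_founders)
  stopifnot(length(founder_probs) == n_founders,
            abs(sum(founder_probs) - 1) < 1e-8,
            origin_founder >= 1, origin_founder <= n_founders)
  structure(list(n_accessions = as.integer(n_accessions),
                 chrom_lengths = chrom_lengths,
                 snp_density = snp_density,
                 n_founders = as.integer(n_founders),
                 recomb_rate = recomb_rate,
                 seed = as.integer(seed),
                 founder_probs = founder_probs,
                 fn_rate = fn_rate,
                 origin_founder = as.integer(origin_founder)),
            class = "sim_config")
}

#' Simulate a fully selfed founder-mosaic population
#'
#' Each accession is a recombinant mosaic of the founder haplotypes and is
#' homozygous at every site (zero heterozygous calls). Monomorphic sites
#' are removed, so remaining allele frequencies lie strictly in (0, 1).
#' The result carries the internal state needed by the other simulator
#' stages as attributes: `founders` (founder allele matrix), `mosaic`
#' (per-SNP founder index per accession), `reference` (reference genome as
#' a named character vector) and `cfg`.
#'
#' @param cfg a [sim_config()].
#' @return a [genotype_matrix()] with simulator attributes.
#' @export
simulate_population <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(cfg$seed, {
    chroms <- names(cfg$chrom_lengths)
    ref <- setNames(vapply(cfg$chrom_lengths, function(len)
      paste(sample(BASES, len, replace = TRUE), collapse = ""),
      character(1)), chroms)
    map_list <- list(); mos_list <- list(); fnd_list <- list()
    for (ch in chroms) {
      len <- cfg$chrom_lengths[[ch]]
      m <- max(10L, as.integer(round(cfg$snp_density * len)))
      pos <- sort(sample.int(len, m))
      refal <- strsplit(ref[[ch]], "")[[1]][pos]
      alt_tab <- t(vapply(BASES, function(b) BASES[BASES != b], character(3)))
      alt <- alt_tab[cbind(match(refal, BASES), sample.int(3L, m, TRUE))]
      founders <- matrix(rbinom(cfg$n_founders * m, 1L, 0.5) * 2L,
                         nrow = cfg$n_founders)
      mosaic <- matrix(0L, nrow = m, ncol = cfg$n_accessions)
      gaps <- diff(pos)
      p_switch <- 1 - exp(-cfg$recomb_rate * gaps)
      for (i in seq_len(cfg$n_accessions)) {
        sw <- runif(m - 1L) < p_switch
        seg <- cumsum(c(1L, sw))
        fnd <- sample.int(cfg$n_founders, max(seg), replace = TRUE,
                          prob = cfg$founder_probs)
        mosaic[, i] <- fnd[seg]
      }
      map_list[[ch]] <- data.frame(chrom = ch, pos = as.integer(pos),
                                   id = snp_id(ch, pos), ref = refal,
                                   alt = alt, stringsAsFactors = FALSE)
      mos_list[[ch]] <- mosaic
      fnd_list[[ch]] <- founders
    }
    map <- do.call(rbind, map_list)
    mosaic <- do.call(rbind, mos_list)
    founders <- do.call(cbind, fnd_list)
    m_all <- nrow(map)
    calls <- matrix(founders[cbind(as.vector(mosaic),
                                   rep(seq_len(m_all), cfg$n_accessions))],
                    nrow = m_all)
    poly <- rowSums(calls != calls[, 1]) > 0
    map <- map[poly, , drop = FALSE]
    rownames(map) <- NULL
    calls <- calls[poly, , drop = FALSE]
    mosaic <- mosaic[poly, , drop = FALSE]
    founders <- founders[, poly, drop = FALSE]
    map$injected <- logical(nrow(map))
    map$source_event <- rep(NA_character_, nrow(map))
    gm <- genotype_matrix(map[, c("chrom", "pos", "id", "ref", "alt")],
                          calls, sprintf("acc%03d", seq_len(cfg$n_accessions)))
    gm$map$injected <- map$injected
    gm$map$source_event <- map$source_event
    attr(gm, "founders") <- founders
    attr(gm, "mosaic") <- mosaic
    attr(gm, "reference") <- ref
    attr(gm, "cfg") <- cfg
    attr(gm, "events") <- list()
    gm
  })
}

#' Describe a duplication event to plant
#'
#' A duplication copies the `source` interval (the gene that will show
#' pseudo-heterozygosity) into `insertion_pos`. Carriers are the
#' accessions whose founder mosaic at the insertion point equals
#' `carrier_founder`, so carrier status segregates like any founder
#' allele and is taggable by nearby SNPs. In `trans` mode the copy
#' template is the haplotype of `template_founder` (pre-existing allelic
#' differences between template and carrier generate instant pseudo-hets);
#' in `tandem` mode the copy templates the carrier's own local haplotype,
#' so only divergence mutations inject pseudo-hets.
#'
#' @param source_chrom,source_start,source_end source interval (1-based
#'   inclusive).
#' @param insertion_chrom,insertion_pos location of the extra copy.
#' @param mode `"trans"` or `"tandem"`; tandem insertions must lie within
#'   20 kb of the source interval.
#' @param carrier_founder founder index defining the carrier set.
#' @param divergence per-bp substitution probability between copy and its
#'   template.
#' @param source_gene optional gene id of the source interval.
#' @param template_founder copy template founder for trans events
#'   (default: the configuration's `origin_founder`).
#' @param id event id.
#' @return a list of class `duplication_event`.
#' @export
duplication_event <- function(source_chrom, source_start, source_end,
                              insertion_chrom, insertion_pos,
                              mode = c("trans", "tandem"),
                              carrier_founder, divergence,
                              source_gene = NULL, template_founder = NULL,
                              id = NULL) {
  mode <- match.arg(mode)
  stopifnot(source_start <= source_end, insertion_pos >= 1, divergence >= 0,
            divergence <= 1)
  if (mode == "tandem") {
    if (insertion_chrom != source_chrom ||
        min(abs(insertion_pos - c(source_start, source_end))) > 20000)
      stop("duplication_event: tandem insertion must be within 20 kb of source")
  }
  structure(list(id = if (is.null(id)) sprintf("ev_%s_%d", source_chrom,
                                               source_start) else id,
                 source_chrom = source_chrom,
                 source_start = as.integer(source_start),
                 source_end = as.integer(source_end),
                 insertion_chrom = insertion_chrom,
                 insertion_pos = as.integer(insertion_pos),
                 mode = mode,
                 carrier_founder = as.integer(carrier_founder),
                 divergence = divergence,
                 source_gene = source_gene,
                 template_founder = template_founder),
            class = "duplication_event")
}

#' Plant a duplication into a simulated population
#'
#' Injects the pseudo-heterozygous calls that reference-collapsed read
#' mapping would produce. For each carrier and each SNP of the source
#' interval, the call becomes heterozygous when the copy allele (template
#' allele, mutated at rate `divergence`) differs from the carrier's own
#' allele. Divergence mutations at SNP-free template bases create new
#' pseudo-SNP rows that are heterozygous in every carrier. The SNP nearest
#' the insertion point is recoded into a founder-indicator (alternate
#' allele carried only by `carrier_founder`), guaranteeing a perfect-LD
#' tag for the carrier set.
#'
#' @param gm a [genotype_matrix()] from [simulate_population()].
#' @param event a [duplication_event()].
#' @param cfg the [sim_config()] used (defaults to the one stored in `gm`).
#' @param seed RNG seed for mutation draws (default derived from the
#'   configuration seed and the number of already-planted events).
#' @return `gm` with injected calls; the completed event (carriers,
#'   mutated offsets, copy alleles, tag SNP) is appended to
#'   `attr(gm, "events")`.
#' @export
plant_duplication <- function(gm, event, cfg = attr(gm, "cfg"), seed = NULL) {
  stopifnot(inherits(event, "duplication_event"), !is.null(cfg))
  founders <- attr(gm, "founders"); mosaic <- attr(gm, "mosaic")
  if (is.null(founders) || is.null(mosaic))
    stop("plant_duplication: gm must come from simulate_population()")
  if (is.null(seed))
    seed <- cfg$seed + 1000L * (length(attr(gm, "events")) + 1L)
  if (is.null(event$template_founder))
    event$template_founder <- cfg$origin_founder
  map <- gm$map; calls <- gm$calls
  reference <- attr(gm, "reference")

  ## tag SNP: founder indicator at the SNP nearest the insertion point
  on_ins <- which(map$chrom == event$insertion_chrom & !map$injected)
  if (length(on_ins) == 0) stop("plant_duplication: no SNPs on insertion chromosome")
  tag <- on_ins[which.min(abs(map$pos[on_ins] - event$insertion_pos))]
  founders[, tag] <- 0L
  founders[event$carrier_founder, tag] <- 2L
  calls[tag, ] <- ifelse(mosaic[tag, ] == event$carrier_founder, 2L, 0L)
  event$tag_snp <- map$id[tag]
  event$tag_pos <- map$pos[tag]

  carriers <- which(mosaic[tag, ] == event$carrier_founder)
  event$carriers <- gm$accessions[carriers]
  if (length(carriers) == 0) {
    warning("plant_duplication: event has no carriers; matrix unchanged")
    gm$calls <- calls
    attr(gm, "founders") <- founders
    attr(gm, "events") <- c(attr(gm, "events"), list(event))
    return(gm)
  }

  with_seed(seed, {
    src_len <- event$source_end - event$source_start + 1L
    mut_off <- which(runif(src_len) < event$divergence)
    mut_pos <- event$source_start + mut_off - 1L
    in_src <- which(map$chrom == event$source_chrom &
                    map$pos >= event$source_start &
                    map$pos <= event$source_end & !map$injected)
    src_pos <- map$pos[in_src]
    is_at_snp <- mut_pos %in% src_pos

    ## copy alleles at pre-existing SNPs of the source interval
    n_inj <- 0L
    for (s in in_src) {
      mutated_here <- map$pos[s] %in% mut_pos
      if (event$mode == "trans") {
        copy_al <- founders[event$template_founder, s]
        differs <- mutated_here | (calls[s, carriers] != copy_al)
      } else {
        differs <- rep(mutated_here, length(carriers))
      }
      if (cfg$fn_rate > 0)
        differs <- differs & (runif(length(carriers)) >= cfg$fn_rate)
      calls[s, carriers[differs]] <- 1L
      n_inj <- n_inj + sum(differs)
    }

    ## mutated SNP-free template bases become new pseudo-SNP rows
    new_pos <- mut_pos[!is_at_snp]
    mut_bases <- character(length(mut_pos))
    ref_chr_seq <- reference[[event$source_chrom]]
    for (k in seq_along(mut_pos)) {
      refb <- substr(ref_chr_seq, mut_pos[k], mut_pos[k])
      pool <- BASES[BASES != refb]
      if (is_at_snp[k]) {
        s <- in_src[match(mut_pos[k], src_pos)]
        pool <- setdiff(pool, map$alt[s])   # third allele: differs from both
      }
      mut_bases[k] <- sample(pool, 1L)
    }
    event$mut_pos <- mut_pos
    event$mut_bases <- mut_bases
    if (length(new_pos) > 0) {
      new_ref <- vapply(new_pos, function(p)
        substr(ref_chr_seq, p, p), character(1))
      new_alt <- mut_bases[!is_at_snp]
      new_calls <- matrix(0L, nrow = length(new_pos), ncol = ncol(calls))
      if (cfg$fn_rate > 0) {
        keep <- matrix(runif(length(new_pos) * length(carriers)) >= cfg$fn_rate,
                       nrow = length(new_pos))
        for (j in seq_along(carriers))
          new_calls[keep[, j], carriers[j]] <- 1L
      } else new_calls[, carriers] <- 1L
      n_inj <- n_inj + sum(new_calls == 1L)
      new_map <- data.frame(chrom = event$source_chrom,
                            pos = as.integer(new_pos),
                            id = snp_id(event$source_chrom, new_pos),
                            ref = new_ref, alt = new_alt,
                            injected = TRUE, source_event = event$id,
                            stringsAsFactors = FALSE)
      map <- rbind(map, new_map)
      calls <- rbind(calls, new_calls)
      nearest <- vapply(new_pos, function(p) {
        cand <- which(map$chrom == event$source_chrom & !map$injected)
        cand[which.min(abs(map$pos[cand] - p))]
      }, integer(1))
      mosaic <- rbind(mosaic, mosaic[nearest, , drop = FALSE])
      founders <- cbind(founders,
                        matrix(0L, nrow = nrow(founders),
                               ncol = length(new_pos)))
      ord <- order(match(map$chrom, names(reference)), map$pos)
      map <- map[ord, , drop = FALSE]; rownames(map) <- NULL
      calls <- calls[ord, , drop = FALSE]
      mosaic <- mosaic[ord, , drop = FALSE]
      founders <- founders[, ord, drop = FALSE]
    }
    event$n_injected <- n_inj
  })

  out <- genotype_matrix(map[, c("chrom", "pos", "id", "ref", "alt")],
                         calls, gm$accessions)
  out$map$injected <- map$injected
  out$map$source_event <- map$source_event
  attr(out, "founders") <- founders
  attr(out, "mosaic") <- mosaic
  attr(out, "reference") <- reference
  attr(out, "cfg") <- cfg
  attr(out, "events") <- c(attr(gm, "events"), list(event))
  out
}

#' Simulate a complete study: population, annotation and duplications
#'
#' Generates a selfed population, places non-overlapping gene annotations,
#' plants the requested duplication events in randomly chosen source genes
#' and draws per-copy methylation truth levels (CG and CHG contexts).
#'
#' @param cfg a [sim_config()].
#' @param n_genes number of genes to annotate.
#' @param gene_length gene length in bp.
#' @param events either an integer (number of trans events to auto-place,
#'   divergence `divergence`, carrier founder 1) or a list of
#'   [duplication_event()] templates with `source_gene` naming a gene id
#'   (coordinates are filled in from the annotation).
#' @param divergence per-bp copy divergence for auto-placed events.
#' @param min_trans_distance minimum distance between source gene and
#'   auto-placed trans insertion point (bp).
#' @return an object of class `pseudohet_sim`: list with `gm`, `truth`
#'   (completed events), `annotation`, `reference`, `meth_truth`, `cfg`.
#' @export
simulate_study <- function(cfg, n_genes = 20, gene_length = 1000,
                           events = 1L, divergence = 0.05,
                           min_trans_distance = 2e5) {
  gm <- simulate_population(cfg)
  chroms <- names(cfg$chrom_lengths)
  ann <- with_seed(cfg$seed + 7L, {
    per_chrom <- table(factor(sample(chroms, n_genes, replace = TRUE,
                                     prob = cfg$chrom_lengths /
                                       sum(cfg$chrom_lengths)), chroms))
    rows <- list()
    k <- 0L
    for (ch in chroms) {
      ng <- per_chrom[[ch]]
      if (ng == 0) next
      len <- cfg$chrom_lengths[[ch]]
      ## lay genes on a jittered grid so they never overlap
      slot <- floor(len / (ng + 1))
      if (slot <= gene_length + 100)
        stop("simulate_study: chromosome too short for n_genes")
      starts <- vapply(seq_len(ng), function(i)
        as.integer((i - 1) * slot + sample.int(slot - gene_length - 1L, 1L)),
        integer(1))
      for (s in sort(starts)) {
        k <- k + 1L
        rows[[k]] <- data.frame(gene_id = sprintf("gene%03d", k), chrom = ch,
                                start = as.integer(s),
                                end = as.integer(s + gene_length - 1L),
                                strand = sample(c("+", "-"), 1L),
                                feature_class = "gene",
                                stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, rows)
  })

  if (is.numeric(events)) {
    n_ev <- as.integer(events)
    events <- with_seed(cfg$seed + 13L, {
      if (n_ev > nrow(ann)) stop("more events than genes")
      src <- sample(ann$gene_id, n_ev)
      lapply(src, function(g) {
        row <- ann[ann$gene_id == g, ]
        repeat {
          ins_chrom <- sample(chroms, 1L)
          ins_pos <- sample.int(cfg$chrom_lengths[[ins_chrom]] - 1000L, 1L)
          if (ins_chrom != row$chrom ||
              abs(ins_pos - row$start) >= min_trans_distance) break
        }
        duplication_event(row$chrom, row$start, row$end, ins_chrom, ins_pos,
                          mode = "trans", carrier_founder = 1L,
                          divergence = divergence, source_gene = g,
                          id = paste0("ev_", g))
      })
    })
  } else {
    events <- lapply(events, function(ev) {
      if (!is.null(ev$source_gene) && is.na(ev$source_start)) {
        row <- ann[ann$gene_id == ev$source_gene, ]
        ev$source_chrom <- row$chrom
        ev$source_start <- row$start
        ev$source_end <- row$end
      }
      ev
    })
  }
  for (ev in events) gm <- plant_duplication(gm, ev, cfg)

  meth_truth <- with_seed(cfg$seed + 23L, {
    grid <- expand.grid(gene_id = ann$gene_id, context = c("CG", "CHG"),
                        stringsAsFactors = FALSE)
    grid$level_source <- runif(nrow(grid))
    grid$level_copy <- runif(nrow(grid))   # used only for duplicated genes
    grid
  })

  structure(list(gm = gm, truth = attr(gm, "events"), annotation = ann,
                 reference = attr(gm, "reference"),
                 meth_truth = meth_truth, cfg = cfg),
            class = "pseudohet_sim")
}

#' @export
print.pseudohet_sim <- function(x, ...) {
  cat(sprintf("pseudohet_sim: %d accessions, %d SNPs, %d genes, %d planted event(s)\n",
              n_accessions(x$gm), n_snps(x$gm), nrow(x$annotation),
              length(x$truth)))
  invisible(x)
}
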