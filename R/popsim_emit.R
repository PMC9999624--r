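## Simulator emissions: per-accession genome assemblies, per-cytosine
## methylation count tables under reference-collapsed vs own-genome
## mapping, read-pair placements around insertion junctions, and
## coverage-window depth tables.

## internal: underlying (pre-injection) homozygous allele of one accession
## at the original SNP rows of a chromosome
own_alt_positions <- function(gm, acc_idx, chrom) {
  founders <- attr(gm, "founders"); mosaic <- attr(gm, "mosaic")
  rows <- which(gm$map$chrom == chrom & !gm$map$injected)
  own <- founders[cbind(mosaic[rows, acc_idx], rows)]
  list(pos = gm$map$pos[rows][own == 2L],
       alt = gm$map$alt[rows][own == 2L])
}

## internal: the diverged copy sequence of one event for one accession
copy_sequence <- function(sim, event, acc_idx) {
  gm <- sim$gm
  ref <- sim$reference[[event$source_chrom]]
  base <- strsplit(substr(ref, event$source_start, event$source_end), "")[[1]]
  rows <- which(gm$map$chrom == event$source_chrom & !gm$map$injected &
                gm$map$pos >= event$source_start &
                gm$map$pos <= event$source_end)
  if (length(rows) > 0) {
    tmpl <- if (event$mode == "trans") {
      attr(gm, "founders")[event$template_founder, rows]
    } else {
      attr(gm, "founders")[cbind(attr(gm, "mosaic")[rows, acc_idx], rows)]
    }
    sub <- tmpl == 2L
    base[gm$map$pos[rows][sub] - event$source_start + 1L] <-
      gm$map$alt[rows][sub]
  }
  if (length(event$mut_pos) > 0)
    base[event$mut_pos - event$source_start + 1L] <- event$mut_bases
  paste(base, collapse = "")
}

#' Emit per-accession genome assemblies
#'
#' Each accession genome is the reference with the accession's own SNP
#' alleles substituted; carriers additionally contain the diverged copy
#' sequence inserted after the insertion point, so their chromosome grows
#' by the copy length.
#'
#' @param sim a `pseudohet_sim` from [simulate_study()].
#' @param accessions accession ids to assemble (default: all).
#' @return named list (per accession) of named character vectors
#'   (per chromosome).
#' @export
emit_assemblies <- function(sim, accessions = sim$gm$accessions) {
  gm <- sim$gm
  out <- list()
  for (acc in accessions) {
    i <- match(acc, gm$accessions)
    if (is.na(i)) stop("unknown accession: ", acc)
    genome <- sim$reference
    for (ch in names(genome)) {
      sub <- own_alt_positions(gm, i, ch)
      if (length(sub$pos) > 0) {
        s <- Biostrings::DNAString(genome[[ch]])
        s <- Biostrings::replaceLetterAt(s, sub$pos, sub$alt)
        genome[[ch]] <- as.character(s)
      }
    }
    ## insertions, rightmost first so earlier coordinates stay valid
    evs <- Filter(function(e) acc %in% e$carriers, sim$truth)
    if (length(evs) > 0) {
      ord <- order(vapply(evs, function(e) e$insertion_pos, integer(1)),
                   decreasing = TRUE)
      for (e in evs[ord]) {
        cp <- copy_sequence(sim, e, i)
        ch <- e$insertion_chrom
        g <- genome[[ch]]
        genome[[ch]] <- paste0(substr(g, 1L, e$insertion_pos), cp,
                               substr(g, e$insertion_pos + 1L, nchar(g)))
      }
    }
    out[[acc]] <- genome
  }
  out
}

#' Emit per-cytosine methylation count tables
#'
#' Simulates bisulfite read counts for each gene under two mapping
#' targets. Under `own_genome` mapping every copy of a gene gets its own
#' binomial counts at that copy's true methylation level. Under
#' `reference` (collapsed) mapping, reads from all copies of a carrier
#' pile onto the single reference locus, so depths and methylated counts
#' are pooled across copies; for single-copy genes the reference counts
#' are the same reads as the own-genome counts.
#'
#' @param sim a `pseudohet_sim`.
#' @param depth mean per-cytosine read depth (Poisson).
#' @param n_cyt cytosines simulated per gene and context.
#' @param accessions accessions to emit (default: all).
#' @param seed RNG seed (default derived from the simulation seed).
#' @return data.frame with columns `gene_id`, `accession`, `context`,
#'   `cyt`, `target` (`reference`/`own_genome`), `copy`, `t`, `c`.
#' @export
emit_methylation <- function(sim, depth = 30, n_cyt = 20,
                             accessions = sim$gm$accessions,
                             seed = sim$cfg$seed + 101L) {
  if (depth < 1) stop("emit_methylation: depth must be >= 1")
  gene_events <- split(sim$truth,
                       vapply(sim$truth, function(e)
                         if (is.null(e$source_gene)) "" else e$source_gene,
                         character(1)))
  with_seed(seed, {
    rows <- list(); k <- 0L
    for (g in sim$annotation$gene_id) {
      for (ctx in c("CG", "CHG")) {
        tr <- sim$meth_truth[sim$meth_truth$gene_id == g &
                             sim$meth_truth$context == ctx, ]
        evs <- gene_events[[g]]
        for (acc in accessions) {
          t1 <- rpois(n_cyt, depth)
          c1 <- rbinom(n_cyt, t1, tr$level_source)
          k <- k + 1L
          rows[[k]] <- data.frame(gene_id = g, accession = acc,
                                  context = ctx, cyt = seq_len(n_cyt),
                                  target = "own_genome", copy = "copy1",
                                  t = t1, c = c1, stringsAsFactors = FALSE)
          t_ref <- t1; c_ref <- c1
          if (!is.null(evs)) {
            for (e in evs) {
              if (!(acc %in% e$carriers)) next
              t2 <- rpois(n_cyt, depth)
              c2 <- rbinom(n_cyt, t2, tr$level_copy)
              k <- k + 1L
              rows[[k]] <- data.frame(gene_id = g, accession = acc,
                                      context = ctx, cyt = seq_len(n_cyt),
                                      target = "own_genome", copy = "copy2",
                                      t = t2, c = c2,
                                      stringsAsFactors = FALSE)
              t_ref <- t_ref + t2; c_ref <- c_ref + c2
            }
          }
          k <- k + 1L
          rows[[k]] <- data.frame(gene_id = g, accession = acc,
                                  context = ctx, cyt = seq_len(n_cyt),
                                  target = "reference", copy = NA_character_,
                                  t = t_ref, c = c_ref,
                                  stringsAsFactors = FALSE)
        }
      }
    }
    do.call(rbind, rows)
  })
}

#' Emit paired-read placements around an insertion junction
#'
#' Coordinates are on the insertion-flank system: a region of
#' `2 * region_flank` bp with the insertion border (junction) at position
#' `region_flank`. Carriers receive `n_pairs` junction-spanning pairs plus
#' flank-only pairs; non-carriers receive flank-only pairs that never span
#' the border.
#'
#' @param sim a `pseudohet_sim`.
#' @param event the [duplication_event()] whose insertion is probed.
#' @param n_pairs number of spanning pairs generated per carrier.
#' @param insert_size,read_len fragment and read lengths (bp).
#' @param region_flank flank length on each side of the junction (bp).
#' @param seed RNG seed.
#' @return data.frame with columns `accession`, `m1_start`, `m1_end`,
#'   `m2_start`, `m2_end`, plus attribute `junction`.
#' @export
emit_read_pairs <- function(sim, event, n_pairs = 10, insert_size = 500,
                            read_len = 100, region_flank = 2000,
                            seed = sim$cfg$seed + 211L) {
  stopifnot(insert_size > 2 * read_len, region_flank > insert_size)
  J <- region_flank
  with_seed(seed, {
    rows <- list(); k <- 0L
    for (acc in sim$gm$accessions) {
      carrier <- acc %in% event$carriers
      if (carrier) {
        ## spanning: mate1 ends before J, mate2 starts after J
        lo <- J + 1L - insert_size + read_len
        hi <- J - read_len
        s <- sample(seq.int(lo, hi), n_pairs, replace = TRUE)
        k <- k + 1L
        rows[[k]] <- data.frame(accession = acc, m1_start = s,
                                m1_end = s + read_len - 1L,
                                m2_start = s + insert_size - read_len,
                                m2_end = s + insert_size - 1L,
                                stringsAsFactors = FALSE)
      }
      ## flank-only pairs on both sides (never span)
      n_fl <- max(2L, n_pairs %/% 2L)
      sL <- sample(seq.int(1L, J - insert_size), n_fl, replace = TRUE)
      sR <- sample(seq.int(J + 1L, 2L * region_flank - insert_size), n_fl,
                   replace = TRUE)
      s <- c(sL, sR)
      k <- k + 1L
      rows[[k]] <- data.frame(accession = acc, m1_start = s,
                              m1_end = s + read_len - 1L,
                              m2_start = s + insert_size - read_len,
                              m2_end = s + insert_size - 1L,
                              stringsAsFactors = FALSE)
    }
    out <- do.call(rbind, rows)
    attr(out, "junction") <- J
    out
  })
}

#' Emit a coverage-window depth table
#'
#' Simulates reference-collapsed short-read coverage in fixed windows:
#' carriers of a duplication receive doubled expected depth over the
#' source gene (reads from both copies map to the one reference locus).
#'
#' @param sim a `pseudohet_sim`.
#' @param accessions accessions to emit.
#' @param mean_depth genome-wide mean read depth.
#' @param window window size (bp).
#' @param seed RNG seed.
#' @return data.frame with columns `accession`, `chrom`, `start`, `end`,
#'   `depth`.
#' @export
emit_coverage <- function(sim, accessions = sim$gm$accessions,
                          mean_depth = 30, window = 50,
                          seed = sim$cfg$seed + 307L) {
  with_seed(seed, {
    rows <- list(); k <- 0L
    for (acc in accessions) {
      for (ch in names(sim$reference)) {
        len <- nchar(sim$reference[[ch]])
        starts <- seq.int(1L, len, by = window)
        ends <- pmin(starts + window - 1L, len)
        lambda <- rep(mean_depth, length(starts))
        for (e in sim$truth) {
          if (!(acc %in% e$carriers) || e$source_chrom != ch) next
          dup <- starts <= e$source_end & ends >= e$source_start
          lambda[dup] <- lambda[dup] * 2
        }
        depth <- rpois(length(starts), lambda * (ends - starts + 1L)) /
          (ends - starts + 1L)
        k <- k + 1L
        rows[[k]] <- data.frame(accession = acc, chrom = ch, start = starts,
                                end = ends, depth = depth,
                                stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, rows)
  })
}
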