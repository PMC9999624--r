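## Methylation artifact quantification: weighted methylation levels,
## differential calls between mapping targets, and the copy-number
## stratified discordance summary.

#' Weighted methylation level
#'
#' Total methylated reads divided by total reads over the unit's
#' cytosines with depth at least `min_depth`: sum(c_i) / sum(t_i).
#' Undefined (NA) when no cytosine qualifies.
#'
#' @param t_i,c_i vectors of per-cytosine total and methylated read
#'   counts for one unit (gene body or window) and context.
#' @param min_depth minimum per-cytosine depth.
#' @return list: `level` (NA when undefined), `n_cytosines` used,
#'   `undefined`.
#' @export
weighted_level <- function(t_i, c_i, min_depth = 3L) {
  stopifnot(length(t_i) == length(c_i), all(c_i <= t_i), all(c_i >= 0))
  keep <- t_i >= min_depth
  if (!any(keep))
    return(list(level = NA_real_, n_cytosines = 0L, undefined = TRUE))
  list(level = sum(c_i[keep]) / sum(t_i[keep]),
       n_cytosines = as.integer(sum(keep)), undefined = FALSE)
}

#' Differential-methylation call between mapping targets
#'
#' Differential when the absolute difference in weighted level strictly
#' exceeds 0.05 (CG) or 0.03 (CHG).
#'
#' @param level_ref,level_own weighted levels under reference-collapsed
#'   and own-genome mapping.
#' @param context `"CG"` or `"CHG"`.
#' @param thresholds named thresholds per context.
#' @return `"differential"` or `"concordant"` (NA if either level is NA).
#' @export
differential_call <- function(level_ref, level_own, context,
                              thresholds = c(CG = 0.05, CHG = 0.03)) {
  if (is.na(level_ref) || is.na(level_own)) return(NA_character_)
  thr <- thresholds[[context]]
  ## strict boundary, guarded against floating-point ties
  if (abs(level_ref - level_own) - thr > 1e-9) "differential" else "concordant"
}

#' Per-gene weighted levels from a cytosine record table
#'
#' Aggregates per-cytosine counts (see [emit_methylation()]) to gene-body
#' weighted levels per accession, context and mapping target. Under
#' own-genome mapping the level of the copy syntenic to the reference
#' position (`copy1`) is used for comparison, as the reference locus
#' corresponds to that copy.
#'
#' @param records data.frame with columns `gene_id`, `accession`,
#'   `context`, `target`, `copy`, `t`, `c`.
#' @param min_depth minimum per-cytosine depth.
#' @param syntenic_copy which own-genome copy is compared to the
#'   reference locus.
#' @return data.frame: `gene_id`, `accession`, `context`, `target`,
#'   `level`, `n_cytosines`.
#' @export
methylation_levels <- function(records, min_depth = 3L,
                               syntenic_copy = "copy1") {
  own <- records$target == "own_genome"
  records <- records[!own | records$copy %in% syntenic_copy, , drop = FALSE]
  key <- interaction(records$gene_id, records$accession, records$context,
                     records$target, drop = TRUE)
  parts <- split(records, key)
  rows <- lapply(parts, function(p) {
    wl <- weighted_level(p$t, p$c, min_depth)
    data.frame(gene_id = p$gene_id[1], accession = p$accession[1],
               context = p$context[1], target = p$target[1],
               level = wl$level, n_cytosines = wl$n_cytosines,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Copy-number stratified methylation discordance summary
#'
#' Per accession: counts of genes with 0 / 1 / >1 copies (with an
#' all-accession intersection row), and within the single-copy and
#' multi-copy strata the fraction of genes called differentially
#' methylated between reference-collapsed and own-genome mapping, per
#' context. Genes with an undefined level in either target are excluded
#' from the fraction denominators; genes missing from the copy-number
#' table count in the 0-copies column and are excluded from fractions.
#'
#' @param levels data.frame from [methylation_levels()].
#' @param copy_numbers data.frame with columns `gene_id`, `accession`,
#'   `category` (`"0"`, `"1"`, `">1"`).
#' @param thresholds differential thresholds per context.
#' @return list: `copy_counts` (per accession + intersection),
#'   `discordance` (per accession x context x stratum: `n_compared`,
#'   `n_differential`, `fraction`).
#' @export
discordance_table <- function(levels, copy_numbers,
                              thresholds = c(CG = 0.05, CHG = 0.03)) {
  genes <- unique(levels$gene_id)
  accs <- unique(levels$accession)
  cat_of <- function(acc, g) {
    row <- copy_numbers[copy_numbers$accession == acc &
                        copy_numbers$gene_id == g, ]
    if (nrow(row) == 0) "0" else row$category[1]
  }
  cats <- matrix("0", nrow = length(genes), ncol = length(accs),
                 dimnames = list(genes, accs))
  for (a in accs) for (g in genes) cats[g, a] <- cat_of(a, g)
  copy_counts <- do.call(rbind, lapply(accs, function(a)
    data.frame(accession = a,
               n0 = sum(cats[, a] == "0"), n1 = sum(cats[, a] == "1"),
               n_multi = sum(cats[, a] == ">1"), stringsAsFactors = FALSE)))
  copy_counts <- rbind(copy_counts, data.frame(
    accession = "intersection",
    n0 = sum(apply(cats == "0", 1, all)),
    n1 = sum(apply(cats == "1", 1, all)),
    n_multi = sum(apply(cats == ">1", 1, all))))
  rows <- list(); k <- 0L
  for (a in accs) for (ctx in unique(levels$context)) {
    for (stratum in c("1", ">1")) {
      in_str <- genes[cats[, a] == stratum]
      n_cmp <- 0L; n_diff <- 0L
      for (g in in_str) {
        lr <- levels$level[levels$gene_id == g & levels$accession == a &
                           levels$context == ctx &
                           levels$target == "reference"]
        lo <- levels$level[levels$gene_id == g & levels$accession == a &
                           levels$context == ctx &
                           levels$target == "own_genome"]
        if (length(lr) == 0 || length(lo) == 0 ||
            is.na(lr[1]) || is.na(lo[1])) next
        call <- differential_call(lr[1], lo[1], ctx, thresholds)
        n_cmp <- n_cmp + 1L
        if (identical(call, "differential")) n_diff <- n_diff + 1L
      }
      k <- k + 1L
      rows[[k]] <- data.frame(accession = a, context = ctx,
                              stratum = stratum, n_compared = n_cmp,
                              n_differential = n_diff,
                              fraction = if (n_cmp > 0) n_diff / n_cmp
                                         else NA_real_,
                              stringsAsFactors = FALSE)
    }
  }
  list(copy_counts = copy_counts, discordance = do.call(rbind, rows))
}
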