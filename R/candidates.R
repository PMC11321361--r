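#' Per-position phenotype rank test
#'
#' For every position, a two-sided Wilcoxon rank-sum test comparing the
#' phenotype ranks of species carrying the human reference allele against
#' those carrying the alternate allele (missing calls excluded). Records
#' which allele's carriers rank higher. Positions where either carrier
#' group is empty are skipped.
#'
#' @param m allele_matrix (subset to GWAS-significant positions).
#' @param trait_ranks named phenotype ranks over the matrix species (or a
#'   superset).
#' @return data.frame (PositionTest table): rsid, chrom, pos, p,
#'   higher_rank_code ("ref"/"alt"), n_ref, n_alt.
#' @export
per_position_test <- function(m, trait_ranks) {
  units <- intersect(m$species, names(trait_ranks))
  calls <- m$calls[, units, drop = FALSE]
  r <- trait_ranks[units]
  rows <- lapply(seq_len(nrow(m$positions)), function(i) {
    ref_r <- r[calls[i, ] == "ref"]
    alt_r <- r[calls[i, ] == "alt"]
    if (length(ref_r) == 0L || length(alt_r) == 0L) return(NULL)
    wt <- stats::wilcox.test(ref_r, alt_r, alternative = "two.sided")
    data.frame(rsid = m$positions$rsid[i], chrom = m$positions$chrom[i],
               pos = m$positions$pos[i], p = wt$p.value,
               higher_rank_code = if (mean(ref_r) >= mean(alt_r)) "ref"
               else "alt",
               n_ref = length(ref_r), n_alt = length(alt_r))
  })
  skipped <- vapply(rows, is.null, logical(1L))
  if (any(skipped))
    message(sum(skipped),
            " position(s) with an empty carrier group skipped")
  rows <- rows[!skipped]
  if (length(rows) == 0L) return(NULL)
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Select putatively causative positions
#'
#' Positions with a per-position rank-test p-value below `alpha` are
#' split by whether the allele whose carriers rank higher equals the
#' trait-increasing allele predicted by human GWAS. The concordant set is
#' the candidate set carried forward; the discordant set (significant but
#' opposite to the human direction) is always returned alongside and
#' never silently dropped.
#'
#' @param tests PositionTest table from [per_position_test()].
#' @param gwas GWAS table covering the tested positions.
#' @param alpha selection threshold (default 0.05).
#' @return list: `concordant` and `discordant` PositionTest subsets, each
#'   with a `concordant` logical column added.
#' @export
select_causative <- function(tests, gwas, alpha = 0.05) {
  idx <- match(paste(tests$chrom, tests$pos),
               paste(gwas$chrom, gwas$pos))
  if (anyNA(idx)) stop("GWAS record missing for tested position")
  inc <- trait_increasing_code(gwas$effect_sign[idx])
  tests$concordant <- tests$higher_rank_code == inc
  sig <- tests[tests$p < alpha, , drop = FALSE]
  list(concordant = sig[sig$concordant, , drop = FALSE],
       discordant = sig[!sig$concordant, , drop = FALSE])
}

#' Position overlap with an interval set
#'
#' @param positions data.frame with chrom and 1-based pos.
#' @param intervals data.frame chrom, start, end (0-based half-open),
#'   e.g. a conserved-cCRE set.
#' @return logical per position.
#' @export
interval_overlap <- function(positions, intervals)
  position_in_intervals(positions, intervals)

#' Mean conservation score over a window around a position
#'
#' The mean per-base score over the `2 * pad + 1` bases centred on the
#' position (default the 21-base window pos +/- 10). Bases not covered by
#' the track are dropped from the mean with a warning; a fully uncovered
#' window gives NA.
#'
#' @param chrom,pos position (1-based).
#' @param track data.frame chrom, start, end, score (0-based half-open
#'   runs of constant score).
#' @param pad bases of padding on either side.
#' @return mean score (NA if no base of the window is covered).
#' @export
phylop_window <- function(chrom, pos, track, pad = 10L) {
  bases <- (pos - pad):(pos + pad)
  tr <- track[track$chrom == chrom, , drop = FALSE]
  vals <- vapply(bases, function(b) {
    hit <- which(tr$start <= b - 1L & b - 1L < tr$end)
    if (length(hit) == 0L) NA_real_ else tr$score[hit[1L]]
  }, numeric(1L))
  if (all(is.na(vals))) {
    warning("window fully outside conservation track")
    return(NA_real_)
  }
  if (anyNA(vals))
    warning("partial track coverage: mean over ", sum(!is.na(vals)),
            " of ", length(vals), " bases")
  mean(vals, na.rm = TRUE)
}

#' Distance to the nearest transcription start site
#'
#' @param chrom,pos position (1-based).
#' @param tss data.frame with chrom and 1-based pos of TSS points.
#' @return minimum absolute distance in bases (NA with a warning if the
#'   chromosome has no TSS).
#' @export
tss_distance <- function(chrom, pos, tss) {
  cand <- tss$pos[tss$chrom == chrom]
  if (length(cand) == 0L) {
    warning("no TSS on chromosome ", chrom)
    return(NA_real_)
  }
  min(abs(pos - cand))
}

#' One-sided group comparison for annotation summaries
#'
#' Wilcoxon rank-sum test that cCRE-overlapping positions have smaller
#' TSS distances (`side = "less"`) or larger conservation scores
#' (`side = "greater"`) than non-overlapping ones.
#'
#' @param values_overlap,values_nonoverlap numeric vectors (non-empty).
#' @param side alternative for the overlap group: "less" or "greater".
#' @return one-sided p-value.
#' @export
compare_groups <- function(values_overlap, values_nonoverlap,
                           side = c("less", "greater")) {
  side <- match.arg(side)
  if (length(values_overlap) == 0L || length(values_nonoverlap) == 0L) {
    warning("empty comparison group; test undefined")
    return(NA_real_)
  }
  stats::wilcox.test(values_overlap, values_nonoverlap,
                     alternative = side)$p.value
}

#' Genes in synteny with a position across species
#'
#' Expands the position's mapped coordinate in each species by the
#' window on both sides and intersects the per-species lists of
#' overlapping genes. A position unmapped in any species is unmappable:
#' it returns NULL (reported, never silently dropped by callers).
#'
#' @param rsid position identifier.
#' @param maps named list (per species) of data.frames `rsid`, `chrom`,
#'   `pos` giving the position's coordinate in that species.
#' @param genes named list (per species, same names) of gene models:
#'   data.frames `chrom`, `start`, `end` (0-based half-open), `gene`.
#' @param window bases on either side (default 500 kb).
#' @return character vector of gene names present in the window in every
#'   species; NULL if the position is unmappable in at least one species.
#' @export
synteny_genes <- function(rsid, maps, genes, window = 500000L) {
  if (!setequal(names(maps), names(genes)))
    stop("maps and genes must cover the same species")
  sets <- vector("list", length(maps))
  for (i in seq_along(maps)) {
    sp <- names(maps)[i]
    row <- maps[[sp]][maps[[sp]]$rsid == rsid, , drop = FALSE]
    if (nrow(row) == 0L) return(NULL)          # unmappable
    g <- genes[[sp]]
    lo <- row$pos[1L] - window; hi <- row$pos[1L] + window
    # gene interval [start+1, end] (1-based) intersects [lo, hi]
    hit <- g$chrom == row$chrom[1L] & g$start + 1L <= hi & g$end >= lo
    sets[[i]] <- unique(g$gene[hit])
  }
  Reduce(intersect, sets)
}

#' Genes linked to a position by cis-eQTL evidence
#'
#' @param rsid position identifier.
#' @param eqtl data.frame with columns `rsid` and `gene`.
#' @return de-duplicated character vector of genes (empty when absent).
#' @export
eqtl_annotate <- function(rsid, eqtl)
  unique(eqtl$gene[eqtl$rsid == rsid])

#' Annotate candidate positions
#'
#' Applies the full annotation cascade to a candidate PositionTest table:
#' conserved-cCRE overlap, mean conservation over the 21-base window,
#' nearest-TSS distance, cross-species syntenic genes, cis-eQTL genes,
#' and (when sequence windows and PWMs are supplied) transcription-factor
#' motifs shared between the two genomic backgrounds.
#'
#' @param candidates PositionTest table (e.g. the concordant set).
#' @param bundle annotation bundle: list with elements `ccre`, `tss`,
#'   `conservation`, `maps`, `genes`, `eqtl`, and optionally `pwms` and
#'   `windows` (list of per-background data.frames rsid, ref_window,
#'   alt_window). See [generate_annotations()].
#' @param window synteny window in bases.
#' @return data.frame: rsid, chrom, pos, p, ccre_overlap, phylop,
#'   tss_distance, syntenic_genes, eqtl_genes, shared_tf_motifs, mappable
#'   (gene/motif sets comma-collapsed; unmappable positions keep an empty
#'   gene set and `mappable = FALSE`).
#' @export
annotate_candidates <- function(candidates, bundle, window = 500000L) {
  n <- nrow(candidates)
  out <- candidates[, c("rsid", "chrom", "pos", "p")]
  out$ccre_overlap <- interval_overlap(candidates, bundle$ccre)
  out$phylop <- vapply(seq_len(n), function(i)
    phylop_window(candidates$chrom[i], candidates$pos[i],
                  bundle$conservation), numeric(1L))
  out$tss_distance <- vapply(seq_len(n), function(i)
    tss_distance(candidates$chrom[i], candidates$pos[i], bundle$tss),
    numeric(1L))
  syn <- lapply(candidates$rsid, synteny_genes, maps = bundle$maps,
                genes = bundle$genes, window = window)
  out$mappable <- !vapply(syn, is.null, logical(1L))
  out$syntenic_genes <- vapply(syn, function(g)
    paste(sort(g), collapse = ","), character(1L))
  out$eqtl_genes <- vapply(candidates$rsid, function(id)
    paste(sort(eqtl_annotate(id, bundle$eqtl)), collapse = ","),
    character(1L))
  if (!is.null(bundle$pwms) && !is.null(bundle$windows)) {
    out$shared_tf_motifs <- vapply(candidates$rsid, function(id) {
      res <- lapply(bundle$windows, function(w) {
        row <- w[w$rsid == id, , drop = FALSE]
        if (nrow(row) == 0L) return(NULL)
        motif_disruption(row$ref_window[1L], row$alt_window[1L],
                         bundle$pwms)
      })
      res <- res[!vapply(res, is.null, logical(1L))]
      if (length(res) < 2L) return("")
      paste(sort(shared_motifs(res[[1L]], res[[2L]])), collapse = ",")
    }, character(1L))
  }
  out
}
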