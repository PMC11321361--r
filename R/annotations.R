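#' Generate a synthetic annotation bundle
#'
#' Emulates the annotation inputs of the real analysis around a simulated
#' matrix: a blacklist, a conserved-cCRE interval set enriched over causal
#' positions, TSS points placed nearer to causal positions, per-species
#' gene models and coordinate maps such that a configurable subset of
#' causal positions keeps a gene within the synteny window in every
#' species, a per-base conservation track elevated around cCRE-overlapping
#' positions, a cis-eQTL table, and two PWMs with known consensus together
#' with per-position ref/alt sequence windows (two genomic backgrounds)
#' in which a fraction of causal positions carries an embedded motif.
#'
#' @param m allele_matrix from [simulate_matrix()].
#' @param causal character vector of causal rsids.
#' @param seed integer seed.
#' @param ccre_causal_cover,ccre_other_cover fraction of causal /
#'   non-causal positions covered by a cCRE interval.
#' @param tss_near,tss_far TSS distance ranges (min, max) for causal and
#'   non-causal positions.
#' @param synteny_fraction fraction of causal positions given a gene
#'   within the synteny window in all species.
#' @param unmappable_fraction fraction of non-causal positions dropped
#'   from one species' coordinate map (unmappable downstream).
#' @param eqtl_fraction fraction of syntenic causal positions given
#'   cis-eQTL rows for their gene.
#' @param motif_fraction fraction of causal positions with a PWM
#'   consensus embedded across the variant in both backgrounds.
#' @param blacklist_fraction fraction of non-causal positions covered by
#'   a blacklist interval.
#' @param conservation_background,conservation_elevated track scores
#'   outside / inside the +/-10 bp windows around cCRE positions.
#' @param species names of the synthetic genomes for synteny.
#' @return list (annotation bundle): blacklist, ccre, tss, genes, maps,
#'   conservation, eqtl, pwms, windows (list of two backgrounds).
#' @export
generate_annotations <- function(m, causal, seed = 1L,
                                 ccre_causal_cover = 0.9,
                                 ccre_other_cover = 0.1,
                                 tss_near = c(200L, 2000L),
                                 tss_far = c(5000L, 50000L),
                                 synteny_fraction = 0.7,
                                 unmappable_fraction = 0.05,
                                 eqtl_fraction = 0.8,
                                 motif_fraction = 0.5,
                                 blacklist_fraction = 0.02,
                                 conservation_background = 0,
                                 conservation_elevated = 2,
                                 species = c("genomeA", "genomeB",
                                             "genomeC", "genomeD",
                                             "genomeE")) {
  if (nrow(m$positions) == 0L) stop("matrix is empty")
  set.seed(seed)
  pos <- m$positions
  n <- nrow(pos)
  is_causal <- pos$rsid %in% causal

  covered <- ifelse(is_causal,
                    stats::runif(n) < ccre_causal_cover,
                    stats::runif(n) < ccre_other_cover)
  ccre <- data.frame(chrom = pos$chrom[covered],
                     start = pos$pos[covered] - 1L -
                       sample(0:3, sum(covered), replace = TRUE),
                     end = pos$pos[covered] +
                       sample(1:4, sum(covered), replace = TRUE),
                     label = paste0("ccre_", pos$rsid[covered]))

  dist <- integer(n)
  dist[is_causal] <- sample(tss_near[1L]:tss_near[2L], sum(is_causal),
                            replace = TRUE)
  dist[!is_causal] <- sample(tss_far[1L]:tss_far[2L], sum(!is_causal),
                             replace = TRUE)
  tss <- data.frame(chrom = pos$chrom, pos = pos$pos + dist)

  # per-species maps: same chromosome, species-specific coordinate shift
  shifts <- stats::setNames(seq_along(species) * 37L, species)
  maps <- lapply(shifts, function(s)
    data.frame(rsid = pos$rsid, chrom = pos$chrom, pos = pos$pos + s))
  unmappable <- !is_causal & stats::runif(n) < unmappable_fraction
  if (any(unmappable))
    maps[[2L]] <- maps[[2L]][!unmappable, , drop = FALSE]

  syntenic <- is_causal & stats::runif(n) < synteny_fraction
  genes <- lapply(species, function(sp) {
    s <- shifts[[sp]]
    g <- data.frame(chrom = pos$chrom[syntenic],
                    start = pos$pos[syntenic] + s + 1000L,
                    end = pos$pos[syntenic] + s + 5000L,
                    gene = paste0("gene_", pos$rsid[syntenic]))
    # decoy genes far outside every window
    rbind(g, data.frame(chrom = pos$chrom[syntenic],
                        start = pos$pos[syntenic] + s + 2000000L,
                        end = pos$pos[syntenic] + s + 2005000L,
                        gene = paste0("far_", pos$rsid[syntenic])))
  })
  names(genes) <- species

  elev <- position_in_intervals(pos, ccre)
  conservation <- data.frame(
    chrom = pos$chrom,
    start = pos$pos - 1L - ifelse(elev, 10L, 15L),
    end = pos$pos + ifelse(elev, 10L, 15L),
    score = ifelse(elev, conservation_elevated,
                   conservation_background))
  # background runs so non-elevated queries see the background value
  conservation <- rbind(conservation[elev, , drop = FALSE],
                        conservation[!elev, , drop = FALSE])

  with_eqtl <- syntenic & stats::runif(n) < eqtl_fraction
  eqtl <- data.frame(rsid = pos$rsid[with_eqtl],
                     gene = paste0("gene_", pos$rsid[with_eqtl]))

  pwms <- synthetic_pwms()
  with_motif <- is_causal & stats::runif(n) < motif_fraction
  windows <- .make_windows(pos, with_motif, pwms[[1L]])

  bl <- !is_causal & stats::runif(n) < blacklist_fraction
  blacklist <- data.frame(chrom = pos$chrom[bl],
                          start = pos$pos[bl] - 1L,
                          end = pos$pos[bl] + 1L,
                          label = "blacklist")

  list(blacklist = blacklist, ccre = ccre, tss = tss, genes = genes,
       maps = maps, conservation = conservation, eqtl = eqtl,
       pwms = pwms, windows = windows)
}

#' Built-in synthetic PWMs
#'
#' Two count matrices with unambiguous consensus sequences (`TGACTCA`
#' and `CACGTG`): 97 counts on the consensus base, 1 elsewhere.
#'
#' @return named list of 4 x L count matrices.
#' @export
synthetic_pwms <- function() {
  from_consensus <- function(consensus) {
    bases <- strsplit(consensus, "")[[1L]]
    m <- matrix(1, 4L, length(bases),
                dimnames = list(c("A", "C", "G", "T"), NULL))
    for (j in seq_along(bases)) m[bases[j], j] <- 97
    m
  }
  list(TF_alpha = from_consensus("TGACTCA"),
       TF_beta = from_consensus("CACGTG"))
}

# ref/alt 21-base windows in two genomic backgrounds; positions flagged
# in `with_motif` get the PWM consensus embedded across the centre (the
# variant base replaces the consensus base at its offset)
.make_windows <- function(pos, with_motif, pwm_counts) {
  consensus <- rownames(pwm_counts)[apply(pwm_counts, 2L, which.max)]
  L <- length(consensus)
  make_bg <- function(mutate) {
    n <- nrow(pos)
    refw <- character(n); altw <- character(n)
    for (i in seq_len(n)) {
      chars <- sample(c("A", "C", "G", "T"), 21L, replace = TRUE)
      if (with_motif[i]) {
        off <- 11L - ((L + 1L) %/% 2L) + 1L   # motif centred on variant
        chars[off:(off + L - 1L)] <- consensus
      }
      if (mutate) {   # second background: tweak a flank base
        j <- sample(c(1:3, 19:21), 1L)
        chars[j] <- sample(setdiff(c("A", "C", "G", "T"), chars[j]), 1L)
      }
      rc <- chars; rc[11L] <- pos$ref[i]
      ac <- chars; ac[11L] <- pos$alt[i]
      refw[i] <- paste(rc, collapse = "")
      altw[i] <- paste(ac, collapse = "")
    }
    data.frame(rsid = pos$rsid, ref_window = refw, alt_window = altw)
  }
  list(backgroundA = make_bg(FALSE), backgroundB = make_bg(TRUE))
}

#' Write an annotation bundle to a directory
#'
#' BED for blacklist/cCRE/TSS/genes, bedGraph for conservation, TSV for
#' maps/eQTL/windows, JASPAR-style counts for PWMs.
#'
#' @param bundle list from [generate_annotations()].
#' @param dir output directory (created if needed).
#' @return dir, invisibly.
#' @export
write_annotations <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(...) file.path(dir, ...)
  write_bed(bundle$blacklist, fp("blacklist.bed"))
  write_bed(bundle$ccre, fp("ccre.bed"))
  write_bed(data.frame(chrom = bundle$tss$chrom,
                       start = bundle$tss$pos - 1L,
                       end = bundle$tss$pos, label = "tss"),
            fp("tss.bed"))
  for (sp in names(bundle$genes)) {
    write_bed(cbind(bundle$genes[[sp]][, c("chrom", "start", "end")],
                    label = bundle$genes[[sp]]$gene),
              fp(paste0("genes_", sp, ".bed")))
    utils::write.table(bundle$maps[[sp]], fp(paste0("map_", sp, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  write_track(bundle$conservation, fp("conservation.bedgraph"))
  utils::write.table(bundle$eqtl, fp("eqtl.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_pwms(bundle$pwms, fp("pwms.txt"))
  for (bg in names(bundle$windows))
    utils::write.table(bundle$windows[[bg]],
                       fp(paste0("windows_", bg, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
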