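#' @title Matrix filter cascade
#'
#' @description
#' Filtering rules applied to the raw SNP-by-species matrix before scoring:
#' blacklist removal, autosome restriction, masking of calls matching
#' neither human allele, removal of invariant positions, splitting off of
#' monophyletic positions (single clade-defining substitutions), and an
#' alignment-coverage threshold. Each filter returns the filtered matrix
#' together with a one-row audit record (`stage`, `positions_in`,
#' `positions_out`).
#'
#' @name filters
NULL

.report <- function(stage, n_in, n_out)
  data.frame(stage = stage, positions_in = n_in, positions_out = n_out)

#' Remove positions inside blacklist regions
#'
#' Positions whose 1-based coordinate falls inside any 0-based half-open
#' blacklist interval on the same chromosome are removed (a position `p`
#' is inside `[start, end)` iff `start <= p - 1 < end`). An empty
#' blacklist is the identity.
#'
#' @param m allele_matrix.
#' @param blacklist data.frame chrom, start, end (0-based half-open).
#' @return list(matrix = filtered allele_matrix, report = FilterReport row).
#' @export
filter_blacklist <- function(m, blacklist) {
  hit <- position_in_intervals(m$positions, blacklist)
  list(matrix = subset_positions(m, !hit),
       report = .report("blacklist", nrow(m$positions), sum(!hit)))
}

#' Flag positions covered by an interval set
#'
#' @param positions data.frame with chrom and 1-based pos.
#' @param intervals data.frame chrom, start, end (0-based half-open).
#' @return logical per position: inside any interval.
#' @export
position_in_intervals <- function(positions, intervals) {
  if (is.null(intervals) || nrow(intervals) == 0L)
    return(rep(FALSE, nrow(positions)))
  vapply(seq_len(nrow(positions)), function(i) {
    on_chrom <- intervals$chrom == positions$chrom[i]
    p0 <- positions$pos[i] - 1L  # 0-based base index
    any(on_chrom & intervals$start <= p0 & p0 < intervals$end)
  }, logical(1L))
}

#' Keep autosomal positions only
#'
#' @param m allele_matrix.
#' @param autosomes chromosome names to keep (default chr1-chr22).
#' @return list(matrix, report).
#' @export
filter_autosomes <- function(m, autosomes = paste0("chr", 1:22)) {
  keep <- m$positions$chrom %in% autosomes
  list(matrix = subset_positions(m, keep),
       report = .report("autosomes", nrow(m$positions), sum(keep)))
}

#' Mask calls matching neither human allele
#'
#' Bases that match neither the human reference nor alternate allele carry
#' no information interpretable through human GWAS summary statistics;
#' every "other" call becomes "missing". Idempotent.
#'
#' @param m allele_matrix.
#' @return allele_matrix with no "other" calls.
#' @export
mask_nonhuman <- function(m) {
  m$calls[m$calls == "other"] <- "missing"
  m
}

#' Remove invariant positions
#'
#' A perfectly conserved position cannot have evolved in parallel:
#' positions whose non-missing calls all share one code, and positions
#' with no non-missing call at all, are removed. Expects [mask_nonhuman()]
#' to have been applied (asserted), since unmasked "other" calls would
#' make conservation ambiguous.
#'
#' @param m allele_matrix.
#' @return list(matrix, report).
#' @export
remove_invariant <- function(m) {
  if (any(m$calls == "other"))
    stop("remove_invariant requires mask_nonhuman to be applied first")
  n_ref <- rowSums(m$calls == "ref")
  n_alt <- rowSums(m$calls == "alt")
  keep <- n_ref > 0L & n_alt > 0L
  list(matrix = subset_positions(m, keep),
       report = .report("invariant", nrow(m$positions), sum(keep)))
}

#' Split off monophyletic positions
#'
#' A position is monophyletic when, among species with non-missing calls,
#' the carriers of one of the two allele codes are exactly the non-missing
#' tips descending from a single node of the tree (both codes present).
#' Such a pattern is parsimoniously explained by one fixation on the
#' clade's stem branch, so these positions are set aside for the
#' internal-branch analysis rather than the parallel-evolution score.
#' Either allele may define the clade, and a clade may be a single tip
#' (a lineage-specific fixation). Missing species are excluded from both
#' the carrier set and the clade's tip set.
#'
#' @param m allele_matrix (masked; species must all be tree tips).
#' @param tree rooted `phylo` tree containing every matrix species as tip.
#' @return list(non_mono = allele_matrix, mono = allele_matrix with extra
#'   position columns `mono_node` (ape node id of the defining clade) and
#'   `clade_code` ("ref"/"alt": the allele fixed in the clade),
#'   report = FilterReport for the non-monophyletic branch).
#' @export
split_monophyletic <- function(m, tree) {
  if (!all(m$species %in% tree$tip.label))
    stop("matrix species missing from tree: ",
         paste(setdiff(m$species, tree$tip.label), collapse = ", "))
  clades <- .node_tip_sets(tree)         # node id -> tip label set
  npos <- nrow(m$positions)
  mono_node <- rep(NA_integer_, npos)
  clade_code <- rep(NA_character_, npos)
  for (i in seq_len(npos)) {
    row <- m$calls[i, ]
    called <- m$species[row != "missing"]
    ref_set <- m$species[row == "ref"]
    alt_set <- m$species[row == "alt"]
    if (length(ref_set) == 0L || length(alt_set) == 0L) next
    for (code in c("ref", "alt")) {
      carriers <- if (code == "ref") ref_set else alt_set
      hit <- .find_defining_node(carriers, called, clades)
      if (!is.na(hit)) {
        mono_node[i] <- hit
        clade_code[i] <- code
        break
      }
    }
  }
  is_mono <- !is.na(mono_node)
  mono <- subset_positions(m, is_mono)
  mono$positions$mono_node <- mono_node[is_mono]
  mono$positions$clade_code <- clade_code[is_mono]
  list(non_mono = subset_positions(m, !is_mono), mono = mono,
       report = .report("monophyletic", npos, sum(!is_mono)))
}

# tip label sets under every node (tips included as singleton clades)
.node_tip_sets <- function(tree) {
  ntip <- length(tree$tip.label)
  sets <- vector("list", ntip + tree$Nnode)
  for (i in seq_len(ntip)) sets[[i]] <- tree$tip.label[i]
  edges <- ape::reorder.phylo(tree, "postorder")$edge
  for (k in seq_len(nrow(edges))) {
    par <- edges[k, 1L]; child <- edges[k, 2L]
    sets[[par]] <- c(sets[[par]], sets[[child]])
  }
  sets
}

# node whose tips, restricted to `called`, equal `carriers`; NA if none
.find_defining_node <- function(carriers, called, clades) {
  for (node in seq_along(clades)) {
    induced <- intersect(clades[[node]], called)
    if (length(induced) == length(carriers) &&
        setequal(induced, carriers))
      return(node)
  }
  NA_integer_
}

#' Alignment-coverage filter over a species subset
#'
#' Restricts the matrix to `species_subset` and keeps positions where the
#' fraction of non-missing calls among the subset meets the threshold
#' (e.g. 0.75 across all mammals, 0.85 across primates).
#'
#' @param m allele_matrix.
#' @param species_subset species to retain as columns.
#' @param threshold minimum called fraction, in (0, 1].
#' @return list(matrix, report).
#' @export
filter_coverage <- function(m, species_subset = m$species, threshold) {
  if (length(species_subset) == 0L) stop("empty species subset")
  stopifnot(threshold > 0, threshold <= 1)
  m <- subset_species(m, species_subset)
  frac <- rowMeans(m$calls != "missing")
  keep <- frac >= threshold
  list(matrix = subset_positions(m, keep),
       report = .report("coverage", nrow(m$positions), sum(keep)))
}

#' Subset to genome-wide significant positions
#'
#' Keeps positions with a GWAS record whose p-value is strictly below
#' `alpha` (default the genome-wide significance threshold 5e-8).
#' Positions without a GWAS record are dropped with a message.
#'
#' @param m allele_matrix.
#' @param gwas GWAS table (see [read_gwas()]).
#' @param alpha significance threshold; strict inequality.
#' @return allele_matrix of significant positions.
#' @export
subset_significant <- function(m, gwas, alpha = 5e-8) {
  key <- paste(m$positions$chrom, m$positions$pos)
  gkey <- paste(gwas$chrom, gwas$pos)
  idx <- match(key, gkey)
  if (anyNA(idx))
    message(sum(is.na(idx)), " position(s) without a GWAS record dropped")
  keep <- !is.na(idx) & gwas$pvalue[idx] < alpha
  subset_positions(m, keep)
}

#' Run the full filter cascade
#'
#' Applies blacklist, autosome, masking, invariant, monophyletic-split and
#' coverage filters in the canonical order and collects the audit trail.
#' Order matters only where mathematically required: invariant removal
#' must follow masking, and the monophyly split must follow invariant
#' removal (both allele codes present is a precondition of the clade test).
#'
#' @param m raw allele_matrix (as produced by [read_matrix()]).
#' @param tree rooted `phylo` tree.
#' @param blacklist blacklist intervals or NULL.
#' @param autosomes chromosomes to keep.
#' @param species_subset coverage subset (default all species).
#' @param coverage called-fraction threshold.
#' @return list(matrix = analysis-ready matrix, mono = monophyletic
#'   matrix, report = data.frame of per-stage FilterReports).
#' @export
filter_cascade <- function(m, tree, blacklist = NULL,
                           autosomes = paste0("chr", 1:22),
                           species_subset = m$species, coverage = 0.75) {
  s1 <- filter_blacklist(m, blacklist)
  s2 <- filter_autosomes(s1$matrix, autosomes)
  masked <- mask_nonhuman(s2$matrix)
  s3 <- remove_invariant(masked)
  s4 <- split_monophyletic(s3$matrix, tree)
  s5 <- filter_coverage(s4$non_mono, species_subset, coverage)
  list(matrix = s5$matrix, mono = s4$mono,
       report = rbind(s1$report, s2$report, s3$report, s4$report,
                      s5$report))
}
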