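#' Brownian maximum-likelihood ancestral states
#'
#' Maximum-likelihood ancestral estimates of a continuous trait at every
#' internal node under Brownian motion (the re-rooted GLS estimator
#' computed by phytools' fast two-pass algorithm). Here the trait is a
#' ranked phenotype, following the rank scale used throughout the
#' pipeline. Returns a complete node map: tips carry their observed
#' values, internal nodes their estimates, named by ape node id.
#'
#' @param tree rooted `phylo` with branch lengths.
#' @param tip_values named vector covering every tip.
#' @param zero_branch_epsilon length added to zero-length internal
#'   branches (with a warning) so the estimator is defined.
#' @return named numeric vector over all node ids (1..Ntip are tips).
#' @export
ancestral_states <- function(tree, tip_values,
                             zero_branch_epsilon = 1e-8) {
  if (!setequal(names(tip_values), tree$tip.label))
    stop("tip_values must cover exactly the tree tips")
  if (any(tree$edge.length == 0)) {
    warning("zero-length branches padded by ", zero_branch_epsilon)
    tree$edge.length[tree$edge.length == 0] <- zero_branch_epsilon
  }
  ntip <- length(tree$tip.label)
  x <- tip_values[tree$tip.label]
  anc <- phytools::fastAnc(tree, x)
  out <- c(stats::setNames(as.numeric(x), seq_len(ntip)),
           stats::setNames(as.numeric(anc), names(anc)))
  out
}

#' Per-branch trait change
#'
#' For every internal, non-root node: the descendant's estimated value
#' minus its direct ancestor's. Tip branches are excluded (the analysis
#' concerns internal branches only).
#'
#' @param tree rooted `phylo`.
#' @param states node-id-named vector from [ancestral_states()].
#' @return named numeric vector of deltas keyed by child node id.
#' @export
branch_deltas <- function(tree, states) {
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  child <- tree$edge[, 2L]
  internal <- child > ntip & child != root
  parent <- tree$edge[internal, 1L]
  child <- child[internal]
  stats::setNames(states[as.character(child)] -
                    states[as.character(parent)],
                  child)
}

#' Count direction matches and mismatches per internal branch
#'
#' For each internal branch, over the GWAS-significant monophyletic
#' positions whose defining clade is the branch's child node: the
#' clade-fixed allele is a match when the trait direction implied by its
#' GWAS sign (trait-increasing allele is positive) equals the sign of the
#' branch's inferred trait change, a mismatch when opposite. Branches
#' with zero trait change count their positions as neither.
#'
#' @param mono allele_matrix from [split_monophyletic()] (positions carry
#'   `mono_node` and `clade_code`), subset to GWAS-significant positions.
#' @param gwas GWAS table covering the mono positions.
#' @param tree rooted `phylo` (for node bookkeeping).
#' @param deltas branch deltas from [branch_deltas()].
#' @return data.frame (BranchRecord table): node, delta, matches,
#'   mismatches — one row per internal branch in `deltas`.
#' @export
count_matches <- function(mono, gwas, tree, deltas) {
  if (!all(c("mono_node", "clade_code") %in% names(mono$positions)))
    stop("mono matrix must carry mono_node and clade_code columns")
  idx <- match(paste(mono$positions$chrom, mono$positions$pos),
               paste(gwas$chrom, gwas$pos))
  if (anyNA(idx)) stop("GWAS record missing for monophyletic position")
  inc <- trait_increasing_code(gwas$effect_sign[idx])
  # trait direction of the allele fixed in the clade
  allele_dir <- ifelse(mono$positions$clade_code == inc, 1L, -1L)
  nodes <- as.integer(names(deltas))
  rec <- data.frame(node = nodes, delta = as.numeric(deltas),
                    matches = 0L, mismatches = 0L)
  dsign <- sign(rec$delta)
  at <- match(mono$positions$mono_node, rec$node)
  for (i in seq_along(at)) {
    j <- at[i]
    if (is.na(j) || dsign[j] == 0) next   # tip/root clades or flat branch
    if (allele_dir[i] == dsign[j]) rec$matches[j] <- rec$matches[j] + 1L
    else rec$mismatches[j] <- rec$mismatches[j] + 1L
  }
  rec
}

#' Residualize matches on mismatches
#'
#' Longer branches accumulate more clade fixations of either direction,
#' so raw match counts track branch length; the residual of matches
#' after removing the trend shared with mismatches is the excess of
#' direction-concordant fixations on a branch. Three residual methods:
#'
#' * `"difference"` (default): residual = matches - mismatches, i.e.
#'   residuals about the unit-slope line through the origin. Because both
#'   counts carry the same per-branch sampling noise, any fitted line is
#'   attenuated by errors in the predictor and leaks a branch-length
#'   loading into its residuals; the fixed unit-slope line is immune and
#'   keeps the downstream one-sided test calibrated.
#' * `"ols"`: ordinary least-squares of matches on mismatches (observed
#'   minus fitted matches). If all mismatch counts are identical the line
#'   is undefined and the residual falls back to matches minus their
#'   mean, with a warning.
#' * `"major_axis"`: the symmetric (major-axis) line, treating both
#'   counts as noisy.
#'
#' @param records BranchRecord table from [count_matches()].
#' @param method residual method (see above).
#' @return the table with a `residual` column added.
#' @export
residual_split <- function(records,
                           method = c("difference", "ols",
                                      "major_axis")) {
  method <- match.arg(method)
  if (nrow(records) < 3L) stop("need at least 3 branches")
  m <- records$matches; mm <- records$mismatches
  if (method == "difference") {
    records$residual <- m - mm
  } else if (method == "ols") {
    if (length(unique(mm)) == 1L) {
      warning("mismatch counts constant; residual = matches - mean")
      records$residual <- m - mean(m)
      return(records)
    }
    fit <- stats::lm(m ~ mm)
    records$residual <- m - stats::fitted(fit)
  } else {
    cm <- stats::cov(cbind(mm, m))
    e <- eigen(cm)$vectors[, 1L]
    if (abs(e[1L]) < 1e-12) {
      warning("mismatch counts constant; residual = matches - mean")
      records$residual <- m - mean(m)
      return(records)
    }
    b <- e[2L] / e[1L]
    records$residual <- m - (mean(m) + b * (mm - mean(mm)))
  }
  records
}

#' Branch-enrichment test
#'
#' One-sided Wilcoxon rank-sum test of whether branches with a positive
#' residual of matches over mismatches show larger absolute trait change
#' than branches with a negative residual. Residual-zero branches carry
#' no directional information and are dropped by default; assigning them
#' to the negative group (`zero_residual = "negative"`) biases the test
#' anti-conservatively, because zero-residual branches are mostly short
#' branches with little trait change.
#'
#' @param records BranchRecord table with `residual` filled.
#' @param zero_residual "drop" (default) or "negative".
#' @return list: p (one-sided), n_positive, n_negative, statistic.
#' @export
enrichment_test <- function(records,
                            zero_residual = c("drop", "negative")) {
  zero_residual <- match.arg(zero_residual)
  if (is.null(records$residual)) stop("run residual_split first")
  pos <- abs(records$delta[records$residual > 0])
  neg <- if (zero_residual == "drop")
    abs(records$delta[records$residual < 0]) else
    abs(records$delta[records$residual <= 0])
  if (length(pos) == 0L || length(neg) == 0L) {
    warning("a residual-sign group is empty; test undefined")
    return(list(p = NA_real_, n_positive = length(pos),
                n_negative = length(neg), statistic = NA_real_))
  }
  wt <- stats::wilcox.test(pos, neg, alternative = "greater")
  list(p = wt$p.value, n_positive = length(pos),
       n_negative = length(neg), statistic = unname(wt$statistic))
}

#' Internal-branch enrichment analysis, end to end
#'
#' Reconstructs ancestral trait ranks, computes per-branch changes,
#' counts direction matches and mismatches of clade-fixed substitutions,
#' residualizes, and tests for enrichment of matches on high-change
#' branches.
#'
#' @param mono monophyletic allele_matrix (GWAS-significant subset is
#'   taken internally).
#' @param gwas GWAS table.
#' @param tree rooted `phylo`.
#' @param trait named phenotype vector over the tree tips.
#' @param alpha genome-wide significance threshold.
#' @param method residual method, see [residual_split()].
#' @return list: records (BranchRecord table with residuals), test
#'   (from [enrichment_test()]), states, deltas.
#' @export
branch_enrichment <- function(mono, gwas, tree, trait, alpha = 5e-8,
                              method = "difference") {
  units <- intersect(names(trait)[!is.na(trait)], tree$tip.label)
  pruned <- length(units) < length(tree$tip.label) ||
    !setequal(mono$species, units)
  tree <- ape::keep.tip(tree, units)
  if (pruned) {
    # defining nodes are keyed to tree node ids: re-derive them on the
    # pruned tree (positions losing clade structure drop out)
    mono <- split_monophyletic(
      subset_species(mask_nonhuman(mono), units), tree)$mono
  }
  sig <- subset_significant(mono, gwas, alpha)
  states <- ancestral_states(tree, to_ranks(trait[units]))
  deltas <- branch_deltas(tree, states)
  records <- residual_split(count_matches(sig, gwas, tree, deltas),
                            method = method)
  list(records = records, test = enrichment_test(records),
       states = states, deltas = deltas)
}
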