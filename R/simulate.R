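#' Simulation configuration
#'
#' Houses the knobs of the synthetic-data generator. Defaults describe a
#' desk-scale study: a 32-species ultrametric tree of depth 100 time
#' units, 300 GWAS positions of which 10% are causal with a one
#' trait-unit allele effect, a Brownian rate making the neutral
#' phylogenetic component comparable to the causal genetic component, a
#' per-unit-time allele flip rate giving a handful of substitutions per
#' position across the tree, and mild missingness/corruption.
#'
#' @param n_species number of tips (>= 3).
#' @param n_positions number of SNP positions (>= 1).
#' @param causal_fraction fraction of positions coupled to the phenotype.
#' @param effect_size phenotype units added per causal trait-increasing
#'   allele carried.
#' @param bm_sigma2 Brownian rate of the phenotype's neutral component
#'   (trait-units^2 per unit branch length).
#' @param flip_rate allele substitutions per unit branch length; the
#'   per-branch flip probability is `1 - exp(-flip_rate * length)`.
#' @param missing_rate fraction of matrix cells set to missing.
#' @param other_rate fraction of matrix cells corrupted to a non-human
#'   base ("other" calls).
#' @param causal_pvalue GWAS p-value assigned to causal positions
#'   (default 1e-9, genome-wide significant).
#' @param noncausal_pvalue GWAS p-value assigned to non-causal positions
#'   (default 0.5, non-significant).
#' @param seed integer seed; identical seed and config give
#'   byte-identical outputs.
#' @return validated list of class `sim_config`.
#' @export
sim_config <- function(n_species = 32L, n_positions = 300L,
                       causal_fraction = 0.1, effect_size = 1,
                       bm_sigma2 = 0.2, flip_rate = 0.005,
                       missing_rate = 0.05, other_rate = 0.02,
                       causal_pvalue = 1e-9, noncausal_pvalue = 0.5,
                       seed = 1L) {
  cfg <- list(n_species = as.integer(n_species),
              n_positions = as.integer(n_positions),
              causal_fraction = causal_fraction,
              effect_size = effect_size, bm_sigma2 = bm_sigma2,
              flip_rate = flip_rate, missing_rate = missing_rate,
              other_rate = other_rate, causal_pvalue = causal_pvalue,
              noncausal_pvalue = noncausal_pvalue, seed = as.integer(seed))
  props <- c("causal_fraction", "missing_rate", "other_rate")
  for (p in props)
    if (cfg[[p]] < 0 || cfg[[p]] > 1)
      stop(p, " must lie in [0, 1]")
  if (cfg$n_species < 3L) stop("n_species must be at least 3")
  if (cfg$n_positions < 1L) stop("n_positions must be positive")
  if (cfg$flip_rate < 0 || cfg$bm_sigma2 < 0)
    stop("rates must be non-negative")
  structure(cfg, class = "sim_config")
}

#' Generate a random ultrametric species tree
#'
#' Pure-birth (Yule) topology rescaled to depth 100 arbitrary time units,
#' emulating the ultrametric character of time-calibrated trees. Tips are
#' labelled `sp01`, `sp02`, ...
#'
#' @param n_species number of tips (>= 3).
#' @param seed integer seed.
#' @param depth root-to-tip depth after rescaling.
#' @return rooted binary ultrametric `phylo`.
#' @export
generate_tree <- function(n_species, seed = 1L, depth = 100) {
  if (n_species < 3L) stop("n_species must be at least 3")
  set.seed(seed)
  tree <- ape::rphylo(n_species, birth = 1, death = 0)
  d <- max(ape::node.depth.edgelength(tree))
  tree$edge.length <- tree$edge.length / d * depth
  tree$tip.label <- sprintf("sp%02d", seq_len(n_species))
  tree
}

#' Simulate a SNP-by-species matrix with controllable parallel signal
#'
#' Each position carries a binary allele state evolved along the tree by
#' symmetric per-branch flips (probability `1 - exp(-flip_rate * len)`);
#' the root state is ref or alt with equal probability. A fraction
#' `causal_fraction` of positions is causal: each gets a signed direction
#' and contributes `effect_size * direction` to the phenotype of every
#' species carrying its alternate allele. The phenotype is that causal
#' sum plus a Brownian component (drawn first from the seed, so with
#' `causal_fraction = 0` the phenotype equals [simulate_bm()] at the same
#' seed). The GWAS table gives causal positions an effect sign equal to
#' their simulated direction and p-value `causal_pvalue`; non-causal
#' positions get random signs and `noncausal_pvalue`. Missing and "other"
#' corruption are injected after the phenotype is computed, so phenotypes
#' always reflect the true underlying states.
#'
#' @param tree rooted `phylo` whose tips are the species (typically from
#'   [generate_tree()]).
#' @param config [sim_config()].
#' @return list: `matrix` (allele_matrix), `gwas` (GWAS table), `trait`
#'   (named phenotype vector), `causal` (character vector of causal
#'   rsids), `directions` (named +1/-1 per causal rsid).
#' @export
simulate_matrix <- function(tree, config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  ntip <- length(tree$tip.label)
  npos <- config$n_positions

  # Brownian component first: shares the seed stream with simulate_bm()
  bm <- drop(.bm_draw(tree, 1L, config$bm_sigma2, 0))

  # binary allele states (TRUE = alt) evolved by per-branch flips
  ord <- ape::reorder.phylo(tree, "postorder")
  pre <- rev(seq_len(nrow(ord$edge)))
  edges <- ord$edge[pre, , drop = FALSE]
  plens <- ord$edge.length[pre]
  nnode <- ntip + tree$Nnode
  states <- matrix(FALSE, nnode, npos)
  states[ntip + 1L, ] <- stats::runif(npos) < 0.5
  pflip <- 1 - exp(-config$flip_rate * plens)
  for (k in seq_len(nrow(edges))) {
    flip <- stats::runif(npos) < pflip[k]
    states[edges[k, 2L], ] <- xor(states[edges[k, 1L], ], flip)
  }
  tip_alt <- t(states[seq_len(ntip), , drop = FALSE])   # npos x ntip

  # positions: unique coordinates on autosomes, distinct ref/alt bases
  chrom <- paste0("chr", sample(1:22, npos, replace = TRUE))
  pos <- integer(npos)
  for (ch in unique(chrom)) {
    i <- chrom == ch
    # random gaps of 100..20099 bases: unique, sorted, spaced coordinates
    pos[i] <- cumsum(sample.int(20000L, sum(i), replace = TRUE) + 99L)
  }
  ref <- sample(c("A", "C", "G", "T"), npos, replace = TRUE)
  alt <- vapply(ref, function(r)
    sample(setdiff(c("A", "C", "G", "T"), r), 1L), character(1L))
  positions <- data.frame(rsid = sprintf("rs%05d", seq_len(npos)),
                          chrom = chrom, pos = pos, ref = ref, alt = alt)

  n_causal <- round(config$causal_fraction * npos)
  causal_idx <- if (n_causal > 0L) sort(sample.int(npos, n_causal)) else
    integer(0)
  directions <- stats::setNames(
    sample(c(-1L, 1L), n_causal, replace = TRUE),
    positions$rsid[causal_idx])

  trait <- bm
  if (n_causal > 0L) {
    contrib <- t(tip_alt[causal_idx, , drop = FALSE]) %*%
      as.numeric(directions)
    trait <- bm + config$effect_size * drop(contrib)
  }
  names(trait) <- tree$tip.label

  signs <- sample(c(-1L, 1L), npos, replace = TRUE)
  signs[causal_idx] <- directions
  pvals <- rep(config$noncausal_pvalue, npos)
  pvals[causal_idx] <- config$causal_pvalue
  gwas <- data.frame(rsid = positions$rsid, chrom = positions$chrom,
                     pos = positions$pos, ref = positions$ref,
                     alt = positions$alt, effect_sign = signs,
                     pvalue = pvals)

  calls <- matrix(ifelse(tip_alt, "alt", "ref"), npos, ntip)
  ncell <- length(calls)
  corrupt <- stats::runif(ncell)
  calls[corrupt < config$other_rate] <- "other"
  calls[corrupt >= config$other_rate &
        corrupt < config$other_rate + config$missing_rate] <- "missing"
  m <- allele_matrix(positions, tree$tip.label, calls)
  list(matrix = m, gwas = gwas, trait = trait,
       causal = positions$rsid[causal_idx], directions = directions)
}

#' Simulate an inbred strain panel
#'
#' Strains carry unlinked genotypes at a random subset of the matrix
#' positions (the same two alleles per position, each strain alt with
#' probability 1/2). The strain phenotype is the causal allele
#' contribution plus independent noise, emitted as two sex-labelled
#' replicates (each base value plus its own noise draw) whose mean is the
#' analysis value.
#'
#' @param m parent allele_matrix.
#' @param gwas parent GWAS table.
#' @param n_strains number of strains (>= 5).
#' @param config [sim_config()] (supplies effect sizes and the seed; the
#'   strain stream is offset from the species stream).
#' @param directions named +1/-1 vector over causal rsids (from
#'   [simulate_matrix()]); positions absent from it are non-causal.
#' @param shared_fraction fraction of matrix positions present in the
#'   panel.
#' @param noise standard deviation of the per-replicate noise.
#' @return list: `genotypes` (strain allele_matrix), `phenotypes`
#'   (data.frame strain, sex, value), `trait` (named per-strain mean).
#' @export
generate_strain_panel <- function(m, gwas, n_strains = 18L,
                                  config = sim_config(),
                                  directions = NULL,
                                  shared_fraction = 0.8, noise = 2) {
  if (n_strains < 5L) stop("n_strains must be at least 5")
  set.seed(config$seed + 1000003L)
  npos <- nrow(m$positions)
  keep <- sort(sample.int(npos, max(1L, round(shared_fraction * npos))))
  positions <- m$positions[keep, , drop = FALSE]
  strains <- sprintf("CC%03d", seq_len(n_strains))
  alt <- matrix(stats::runif(nrow(positions) * n_strains) < 0.5,
                nrow(positions), n_strains)
  calls <- matrix(ifelse(alt, "alt", "ref"), nrow(positions), n_strains)
  geno <- allele_matrix(positions, strains, calls)
  base <- rep(0, n_strains)
  if (!is.null(directions) && length(directions) > 0L) {
    idx <- match(names(directions), positions$rsid)
    has <- !is.na(idx)
    if (any(has))
      base <- drop(t(alt[idx[has], , drop = FALSE]) %*%
                     as.numeric(directions[has])) * config$effect_size
  }
  reps <- data.frame(
    strain = rep(strains, times = 2L),
    sex = rep(c("f", "m"), each = n_strains),
    value = rep(base, 2L) + stats::rnorm(2L * n_strains, sd = noise))
  list(genotypes = geno, phenotypes = reps,
       trait = average_sexes(reps))
}

#' Plant clade-fixed substitutions with branch-concordant directions
#'
#' Builds a monophyletic-position matrix for the internal-branch
#' enrichment analysis. Positions fall on internal branches with
#' probability proportional to branch length (longer branches accumulate
#' more clade fixations); the clade's members carry the alternate
#' allele, everyone else the reference. On the `top_fraction` of
#' internal branches with the largest inferred trait change, each
#' position's GWAS effect sign matches the branch's direction of change
#' with probability `concordance` (0.5 gives a null dataset with no
#' planted signal); elsewhere signs are fair coin flips.
#'
#' @param tree rooted `phylo`.
#' @param trait named tip phenotype vector (ranks are taken internally
#'   for the ancestral reconstruction that guides planting).
#' @param n_positions number of clade fixations to place.
#' @param concordance probability that a position on a high-change
#'   branch gets a GWAS sign matching the branch's trait change.
#' @param top_fraction fraction of internal branches (by absolute trait
#'   change) carrying the sign bias.
#' @param seed integer seed.
#' @return list: `mono` (allele_matrix with `mono_node`, `clade_code`),
#'   `gwas` (GWAS table, all genome-wide significant).
#' @export
simulate_clade_signal <- function(tree, trait, n_positions = 2000L,
                                  concordance = 0.5,
                                  top_fraction = 0.4, seed = 1L) {
  set.seed(seed)
  ntip <- length(tree$tip.label)
  states <- ancestral_states(tree, to_ranks(trait))
  deltas <- branch_deltas(tree, states)
  nodes <- as.integer(names(deltas))
  node_len <- tree$edge.length[match(nodes, tree$edge[, 2L])]
  pos_nodes <- sample(nodes, n_positions, replace = TRUE,
                      prob = node_len / sum(node_len))
  n_top <- max(1L, ceiling(top_fraction * length(nodes)))
  top_nodes <- nodes[order(-abs(deltas))][seq_len(n_top)]

  clades <- .node_tip_sets(tree)
  calls <- matrix("ref", n_positions, ntip)
  colnames(calls) <- tree$tip.label
  for (i in seq_len(n_positions))
    calls[i, clades[[pos_nodes[i]]]] <- "alt"

  # the alt allele is clade-fixed, so a GWAS sign equal to the branch's
  # delta sign makes the fixation a direction match
  dsign <- as.integer(sign(deltas[as.character(pos_nodes)]))
  p_match <- ifelse(pos_nodes %in% top_nodes, concordance, 0.5)
  is_match <- stats::runif(n_positions) < p_match
  signs <- ifelse(is_match, dsign, -dsign)
  flat <- signs == 0L                     # branches with no trait change
  signs[flat] <- sample(c(-1L, 1L), sum(flat), replace = TRUE)
  positions <- data.frame(rsid = sprintf("mono%05d",
                                         seq_len(n_positions)),
                          chrom = "chr1",
                          pos = seq_len(n_positions) * 1000L,
                          ref = "A", alt = "G",
                          mono_node = pos_nodes,
                          clade_code = "alt")
  gwas <- data.frame(rsid = positions$rsid, chrom = positions$chrom,
                     pos = positions$pos, ref = "A", alt = "G",
                     effect_sign = signs, pvalue = 1e-9)
  list(mono = allele_matrix(positions, tree$tip.label, calls),
       gwas = gwas)
}
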