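# Independent brute-force oracles and random fixture builders. Every
# oracle recomputes its quantity by naive enumeration, never through the
# package's own code path.

rand_tree <- function(n, seed) {
  set.seed(seed)
  tree <- ape::rcoal(n)
  tree$tip.label <- sprintf("t%02d", seq_len(n))
  tree
}

rand_calls_matrix <- function(n_pos, n_sp, seed,
                              codes = c("ref", "alt", "other",
                                        "missing"),
                              probs = c(0.4, 0.3, 0.1, 0.2),
                              species = sprintf("t%02d", seq_len(n_sp))) {
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n_pos, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L),
                character(1L))
  positions <- data.frame(rsid = sprintf("rs%04d", seq_len(n_pos)),
                          chrom = sample(paste0("chr", 1:3), n_pos,
                                         replace = TRUE),
                          pos = sample.int(1e6L, n_pos),
                          ref = ref, alt = alt)
  # resample any duplicate (chrom, pos)
  while (anyDuplicated(paste(positions$chrom, positions$pos)))
    positions$pos <- sample.int(1e6L, n_pos)
  calls <- matrix(sample(codes, n_pos * n_sp, replace = TRUE,
                         prob = probs), n_pos, n_sp)
  allele_matrix(positions, species, calls)
}

rand_gwas_for <- function(m, seed) {
  set.seed(seed)
  n <- nrow(m$positions)
  data.frame(rsid = m$positions$rsid, chrom = m$positions$chrom,
             pos = m$positions$pos, ref = m$positions$ref,
             alt = m$positions$alt,
             effect_sign = sample(c(-1L, 1L), n, replace = TRUE),
             pvalue = stats::runif(n, 1e-12, 1))
}

# per-species score by explicit double loop
oracle_score <- function(m, gwas) {
  out <- data.frame(unit = m$species, score = NA_real_,
                    n_increasing = 0L, n_total = 0L)
  for (j in seq_along(m$species)) {
    n_tot <- 0L; n_inc <- 0L
    for (i in seq_len(nrow(m$positions))) {
      g <- gwas[gwas$chrom == m$positions$chrom[i] &
                  gwas$pos == m$positions$pos[i], ]
      inc <- if (g$effect_sign[1] > 0) "alt" else "ref"
      cell <- m$calls[i, j]
      if (cell %in% c("ref", "alt")) {
        n_tot <- n_tot + 1L
        if (cell == inc) n_inc <- n_inc + 1L
      }
    }
    out$n_total[j] <- n_tot; out$n_increasing[j] <- n_inc
    out$score[j] <- if (n_tot > 0L) n_inc / n_tot else NA_real_
  }
  out
}

# BM covariance by explicit root-to-MRCA path summation
oracle_vcv <- function(tree, tips = tree$tip.label) {
  depth <- ape::node.depth.edgelength(tree)
  n <- length(tips)
  V <- matrix(0, n, n, dimnames = list(tips, tips))
  idx <- match(tips, tree$tip.label)
  mrca_tab <- ape::mrca(tree)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    a <- if (i == j) idx[i] else
      mrca_tab[tree$tip.label[idx[i]], tree$tip.label[idx[j]]]
    V[i, j] <- if (i == j) depth[idx[i]] else depth[a]
  }
  V
}

# membership scan over every (position, interval) pair
oracle_overlap <- function(positions, intervals) {
  out <- logical(nrow(positions))
  for (i in seq_len(nrow(positions))) {
    for (k in seq_len(nrow(intervals))) {
      if (intervals$chrom[k] == positions$chrom[i] &&
          positions$pos[i] - 1L >= intervals$start[k] &&
          positions$pos[i] - 1L < intervals$end[k]) {
        out[i] <- TRUE
        break
      }
    }
  }
  out
}

oracle_tss <- function(chrom, pos, tss) {
  best <- Inf
  for (k in seq_len(nrow(tss)))
    if (tss$chrom[k] == chrom) best <- min(best, abs(pos - tss$pos[k]))
  if (is.infinite(best)) NA_real_ else best
}

oracle_synteny <- function(rsid, maps, genes, window) {
  sets <- list()
  for (sp in names(maps)) {
    row <- maps[[sp]][maps[[sp]]$rsid == rsid, ]
    if (nrow(row) == 0L) return(NULL)
    found <- character(0)
    g <- genes[[sp]]
    for (k in seq_len(nrow(g))) {
      if (g$chrom[k] != row$chrom[1]) next
      lo <- row$pos[1] - window; hi <- row$pos[1] + window
      if (g$start[k] + 1L <= hi && g$end[k] >= lo)
        found <- union(found, g$gene[k])
    }
    sets[[sp]] <- found
  }
  Reduce(intersect, sets)
}

# monophyly by enumeration of every node's descendant tip set
oracle_mono <- function(m, tree) {
  tip_sets <- lapply(seq_len(length(tree$tip.label) + tree$Nnode),
                     function(node) {
                       if (node <= length(tree$tip.label))
                         return(tree$tip.label[node])
                       tree$tip.label[
                         phangorn::Descendants(tree, node,
                                               "tips")[[1L]]]
                     })
  vapply(seq_len(nrow(m$positions)), function(i) {
    row <- m$calls[i, ]
    called <- m$species[row != "missing"]
    for (code in c("ref", "alt")) {
      carriers <- m$species[row == code]
      others <- m$species[row != "missing" & row != code]
      if (length(carriers) == 0L || length(others) == 0L) next
      for (s in tip_sets)
        if (setequal(intersect(s, called), carriers)) return(TRUE)
    }
    FALSE
  }, logical(1L))
}

oracle_empirical_p <- function(observed, nulls) {
  cnt <- 0L
  for (v in nulls) if (v >= observed) cnt <- cnt + 1L
  (1 + cnt) / (1 + length(nulls))
}

# exact Wilcoxon rank-sum p by enumeration of all group assignments
oracle_wilcox_exact <- function(x, y,
                                alternative = c("two.sided", "greater",
                                                "less")) {
  alternative <- match.arg(alternative)
  n1 <- length(x); n <- n1 + length(y)
  r <- rank(c(x, y))
  w_obs <- sum(r[seq_len(n1)])
  combos <- utils::combn(n, n1)
  w_all <- apply(combos, 2L, function(id) sum(r[id]))
  p_ge <- mean(w_all >= w_obs - 1e-9)
  p_le <- mean(w_all <= w_obs + 1e-9)
  switch(alternative,
         greater = p_ge, less = p_le,
         two.sided = min(1, 2 * min(p_ge, p_le)))
}
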