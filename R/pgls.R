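#' Brownian-motion covariance of a phylogeny
#'
#' Under Brownian trait evolution the covariance of two tips equals the
#' shared path length from the root to their most recent common ancestor;
#' the diagonal holds root-to-tip depths. This is the error covariance
#' kernel of the PGLS regression.
#'
#' @param tree rooted `phylo` with branch lengths.
#' @param tips ordered tip names to use (subset of `tree$tip.label`).
#' @return symmetric positive-semidefinite matrix with dimnames `tips`.
#' @export
bm_covariance <- function(tree, tips = tree$tip.label) {
  if (!all(tips %in% tree$tip.label))
    stop("unknown tips: ", paste(setdiff(tips, tree$tip.label),
                                 collapse = ", "))
  V <- ape::vcv.phylo(tree)
  V[tips, tips, drop = FALSE]
}

#' Rank PGLS fit
#'
#' Generalized least squares of `y` on `[1, x]` with error covariance `V`:
#' coefficients `(X' V^-1 X)^-1 X' V^-1 y`, residual variance on n - 2
#' degrees of freedom, t test on the slope. In this pipeline both `y`
#' (phenotype) and `x` (genomic score) are average-tie ranks, but the fit
#' itself is generic.
#'
#' @param y named response vector.
#' @param x named predictor vector over the same units.
#' @param V covariance matrix with matching dimnames.
#' @return list of class `pgls_fit`: slope, intercept, slope_se, t_stat,
#'   p_two_sided, p_one_sided_positive, sign (+1/-1), n, df.
#' @export
pgls_fit <- function(y, x, V) {
  units <- names(y)
  if (is.null(units) || !setequal(units, names(x)) ||
      !setequal(units, rownames(V)))
    stop("y, x and V must cover the same named units")
  n <- length(units)
  if (n < 3L) stop("PGLS needs at least 3 units")
  x <- x[units]; V <- V[units, units]
  L <- tryCatch(chol(V), error = function(e)
    stop("singular or non-positive-definite covariance: ",
         conditionMessage(e)))
  X <- cbind(intercept = 1, slope = x)
  Xw <- backsolve(L, X, transpose = TRUE)   # L' \ X whitens the model
  yw <- backsolve(L, y, transpose = TRUE)
  XtX <- crossprod(Xw)
  XtXi <- solve(XtX)
  beta <- drop(XtXi %*% crossprod(Xw, yw))
  resid <- yw - Xw %*% beta
  df <- n - 2L
  sigma2 <- sum(resid^2) / df
  se <- sqrt(sigma2 * XtXi[2L, 2L])
  t_stat <- if (se > 0) beta[2L] / se else sign(beta[2L]) * Inf
  p2 <- 2 * stats::pt(abs(t_stat), df, lower.tail = FALSE)
  structure(list(slope = unname(beta[2L]), intercept = unname(beta[1L]),
                 slope_se = se, t_stat = t_stat, p_two_sided = p2,
                 p_one_sided_positive = if (beta[2L] > 0) p2 / 2 else
                   1 - p2 / 2,
                 sign = if (beta[2L] >= 0) 1L else -1L,
                 n = n, df = df),
            class = "pgls_fit")
}

#' @export
print.pgls_fit <- function(x, ...) {
  cat(sprintf(
    "PGLS fit (n = %d): slope %.4g (se %.4g), t = %.4g, p = %.4g (%s)\n",
    x$n, x$slope, x$slope_se, x$t_stat, x$p_two_sided,
    if (x$sign > 0) "+" else "-"))
  invisible(x)
}

# one BM draw per tip; internal, consumes the current RNG stream.
# Returns tips x n matrix of independent realizations.
.bm_draw <- function(tree, n = 1L, sigma2 = 1, root_value = 0) {
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  ord <- ape::reorder.phylo(tree, "postorder")
  edges <- ord$edge[rev(seq_len(nrow(ord$edge))), , drop = FALSE]  # preorder
  lens <- ord$edge.length[rev(seq_len(nrow(ord$edge)))]
  vals <- matrix(0, nnode, n)
  vals[ntip + 1L, ] <- root_value               # root
  incr <- matrix(stats::rnorm(nrow(edges) * n), nrow(edges), n) *
    sqrt(sigma2 * lens)
  for (k in seq_len(nrow(edges)))
    vals[edges[k, 2L], ] <- vals[edges[k, 1L], ] + incr[k, ]
  out <- vals[seq_len(ntip), , drop = FALSE]
  rownames(out) <- tree$tip.label
  out
}

#' Simulate Brownian trait evolution on a tree
#'
#' Each branch increment is an independent normal draw with variance
#' `sigma2` times the branch length, accumulated from `root_value` down
#' to the tips.
#'
#' @param tree rooted `phylo` with branch lengths.
#' @param sigma2 Brownian rate (trait-units squared per unit branch
#'   length), non-negative.
#' @param root_value trait value at the root.
#' @param seed integer seed; identical seed and tree give identical tips.
#' @return named numeric vector of tip values.
#' @export
simulate_bm <- function(tree, sigma2 = 1, root_value = 0, seed = NULL) {
  if (sigma2 < 0) stop("sigma2 must be non-negative")
  if (!is.null(seed)) set.seed(seed)
  drop(.bm_draw(tree, 1L, sigma2, root_value))
}

#' Permulate a trait along a phylogeny
#'
#' A phylogeny-aware permutation: simulate one Brownian realization on
#' the tree, then reassign the observed values so that the observed value
#' of rank k lands on the tip holding the k-th ranked simulated value.
#' The output is a permutation of the observed multiset that preserves
#' tree-induced clustering. The Brownian rate is irrelevant to
#' rank-matching and fixed at 1.
#'
#' @param tree rooted `phylo`.
#' @param observed named trait vector covering tips to permute.
#' @param seed integer seed (optional).
#' @return named vector: permuted values on the same units.
#' @export
permulate <- function(tree, observed, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (!all(names(observed) %in% tree$tip.label))
    stop("observed units must be tree tips")
  tree <- ape::keep.tip(tree, names(observed))
  sim <- drop(.bm_draw(tree, 1L))[names(observed)]
  out <- observed
  out[order(sim)] <- sort(observed)
  out
}

#' Add-one empirical p-value
#'
#' `(1 + #{null >= observed}) / (1 + n_null)`: ties count against the
#' observed statistic and the estimator never returns zero.
#'
#' @param observed observed statistic.
#' @param nulls numeric vector of null statistics (non-empty).
#' @return probability in `[1/(n+1), 1]`.
#' @export
empirical_p <- function(observed, nulls) {
  if (length(nulls) == 0L) stop("nulls must be non-empty")
  (1 + sum(nulls >= observed)) / (1 + length(nulls))
}

#' Genomic-score / phenotype association with permulation calibration
#'
#' The pipeline's central test. Subsets the matrix to genome-wide
#' significant positions, computes genomic scores, converts scores and
#' phenotype to average-tie ranks over the units with both defined,
#' fits the rank PGLS under the Brownian covariance, then repeats the fit
#' on `n_perm` permulated trait rankings and reports the empirical
#' p-value of the slope t-statistic (one-sided toward a positive slope by
#' default, matching the directional hypothesis that species matching
#' more trait-increasing alleles rank higher for the trait).
#'
#' @param m allele_matrix (filtered, analysis-ready).
#' @param gwas GWAS table.
#' @param tree rooted `phylo` containing the matrix species.
#' @param trait named phenotype vector (species lacking values are
#'   dropped pairwise with a message).
#' @param n_perm number of permulations (default 1000).
#' @param seed integer seed for the permulation stream.
#' @param alpha genome-wide significance threshold for the subset step.
#' @param alternative "greater" (default, one-sided positive) or
#'   "two.sided" for the permulation comparison.
#' @return list: `pgls` ([pgls_fit()] result), `perm` (list
#'   observed_stat, null_stats, p_empirical, n_perm), `scores`
#'   (score_table), `n_species`, `n_positions`.
#' @export
run_association <- function(m, gwas, tree, trait, n_perm = 1000L,
                            seed = NULL, alpha = 5e-8,
                            alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  if (n_perm < 1L) stop("n_perm must be at least 1")
  if (!is.null(seed)) set.seed(seed)
  sig <- subset_significant(m, gwas, alpha)
  if (nrow(sig$positions) == 0L)
    stop("no genome-wide significant positions in matrix")
  scores <- suppressWarnings(genomic_score(sig, gwas))
  units <- scores$unit[!is.na(scores$score)]
  dropped <- setdiff(units, names(trait)[!is.na(trait)])
  if (length(dropped) > 0L)
    message(length(dropped), " species without phenotype dropped")
  units <- intersect(units, names(trait)[!is.na(trait)])
  if (length(units) < 3L) stop("fewer than 3 species with score and trait")
  x <- to_ranks(stats::setNames(
    scores$score[match(units, scores$unit)], units))
  y <- to_ranks(trait[units])
  V <- bm_covariance(ape::keep.tip(tree, units), units)
  fit <- pgls_fit(y, x, V)

  # vectorized permulation refit: whiten once, then every permuted
  # response is an ordinary least-squares problem on the same design
  sub <- ape::keep.tip(tree, units)
  sims <- .bm_draw(sub, n_perm)[units, , drop = FALSE]
  ys <- apply(sims, 2L, function(s) {
    out <- y; out[order(s)] <- sort(y); out
  })
  L <- chol(V[units, units])
  X <- cbind(1, x)
  Xw <- backsolve(L, X, transpose = TRUE)
  Yw <- backsolve(L, ys, transpose = TRUE)
  XtXi <- solve(crossprod(Xw))
  B <- XtXi %*% crossprod(Xw, Yw)               # 2 x n_perm
  RSS <- colSums((Yw - Xw %*% B)^2)
  df <- length(units) - 2L
  se <- sqrt(RSS / df * XtXi[2L, 2L])
  null_t <- ifelse(se > 0, B[2L, ] / se, sign(B[2L, ]) * Inf)
  obs <- if (alternative == "greater") fit$t_stat else abs(fit$t_stat)
  nulls <- if (alternative == "greater") null_t else abs(null_t)
  list(pgls = fit,
       perm = list(observed_stat = obs, null_stats = nulls,
                   p_empirical = empirical_p(obs, nulls),
                   n_perm = n_perm),
       scores = scores, n_species = length(units),
       n_positions = nrow(sig$positions))
}
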