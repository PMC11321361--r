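test_that("two-tip root estimate is the inverse-length weighted mean", {
  tree <- ape::read.tree(text = "(A:2,B:3);")
  a <- 1; b <- 11
  st <- ancestral_states(tree, c(A = a, B = b))
  expect_equal(unname(st["3"]),
               (a / 2 + b / 3) / (1 / 2 + 1 / 3), tolerance = 1e-8)
})

test_that("constant tip values reconstruct constant ancestors", {
  tree <- rand_tree(9, seed = 2)
  st <- ancestral_states(tree, stats::setNames(rep(4.2, 9),
                                               tree$tip.label))
  expect_equal(unname(st), rep(4.2, length(st)), tolerance = 1e-8)
})

test_that("ancestral states equal the explicit re-rooted GLS estimator", {
  for (s in 1:6) {
    tree <- rand_tree(6, seed = s + 40)
    y <- stats::setNames(stats::rnorm(6), tree$tip.label)
    st <- ancestral_states(tree, y)
    for (node in 8:11) {   # non-root internal nodes
      rerooted <- phytools::reroot(tree, node)
      Sigma <- oracle_vcv(rerooted)[names(y), names(y)]
      Si <- solve(Sigma)
      one <- rep(1, 6)
      chat <- drop(solve(t(one) %*% Si %*% one) %*% t(one) %*% Si %*% y)
      expect_equal(unname(st[as.character(node)]), chat,
                   tolerance = 1e-8)
    }
    # root estimate: GLS mean under the original covariance
    Si <- solve(oracle_vcv(tree)[names(y), names(y)])
    one <- rep(1, 6)
    expect_equal(unname(st["7"]),
                 drop(solve(t(one) %*% Si %*% one) %*% t(one) %*%
                        Si %*% y), tolerance = 1e-8)
  }
})

test_that("branch deltas subtract parent from child over internal branches", {
  tree <- ape::read.tree(text = "(((A:1,B:1):1,C:2):1,D:3);")
  ntip <- 4L
  states <- stats::setNames(rep(0, 7), as.character(1:7))
  # ape node ids: tips A..D = 1..4, root = 5, then internal nodes 6
  # ({A,B,C}) and 7 ({A,B}); parent of 7 is 6
  states["5"] <- 1; states["6"] <- 3; states["7"] <- 4
  d <- branch_deltas(tree, states)
  expect_setequal(names(d), c("6", "7"))
  expect_equal(unname(d["6"]), states[["6"]] - states[["5"]])
  expect_equal(unname(d["7"]), states[["7"]] - states[["6"]])
  # constant states give zero deltas
  d0 <- branch_deltas(tree, stats::setNames(rep(2, 7), 1:7))
  expect_equal(unname(d0), c(0, 0))
})

test_that("match and mismatch counts equal hand enumeration", {
  tree <- ape::read.tree(
    text = "(((A:1,B:1):1,(C:1,D:1):1):1,(E:1,F:1):2);")
  # tips A..F = 1..6, root = 7; internal nodes 8 ({A,B,C,D}), 9 ({A,B}),
  # 10 ({C,D}), 11 ({E,F})
  deltas <- c("8" = 2, "9" = -1, "10" = 0, "11" = 3)
  clade_tips <- list("9" = c("A", "B"), "10" = c("C", "D"),
                     "11" = c("E", "F"), "8" = c("A", "B", "C", "D"))
  nodes <- c(9, 9, 10, 11, 11, 8)
  signs <- c(1L, -1L, 1L, -1L, 1L, 1L)
  calls <- matrix("ref", 6, 6,
                  dimnames = list(NULL, c("A", "B", "C", "D", "E",
                                          "F")))
  for (i in 1:6) calls[i, clade_tips[[as.character(nodes[i])]]] <- "alt"
  positions <- data.frame(rsid = sprintf("m%d", 1:6), chrom = "chr1",
                          pos = 1:6 * 100L, ref = "A", alt = "G",
                          mono_node = nodes, clade_code = "alt")
  mono <- allele_matrix(positions, colnames(calls), calls)
  gwas <- data.frame(rsid = positions$rsid, chrom = "chr1",
                     pos = positions$pos, ref = "A", alt = "G",
                     effect_sign = signs, pvalue = 1e-9)
  rec <- count_matches(mono, gwas, tree, deltas)
  got <- rec[order(rec$node), ]
  # node 8 (delta +2): one alt-fixation with sign +1 -> match
  # node 9 (delta -1): signs +1 (mismatch) and -1 (match)
  # node 10 (delta 0): neither; node 11 (delta +3): -1 mism, +1 match
  expect_equal(got$matches[got$node == 8], 1L)
  expect_equal(got$matches[got$node == 9], 1L)
  expect_equal(got$mismatches[got$node == 9], 1L)
  expect_equal(got$matches[got$node == 10], 0L)
  expect_equal(got$mismatches[got$node == 10], 0L)
  expect_equal(got$matches[got$node == 11], 1L)
  expect_equal(got$mismatches[got$node == 11], 1L)
  # totals: matched + mismatched + neither = all positions
  expect_equal(sum(got$matches) + sum(got$mismatches) + 1L, 6L)
})

test_that("residual methods behave on aligned and random counts", {
  rec <- data.frame(node = 1:5, delta = stats::rnorm(5),
                    matches = c(2L, 4L, 6L, 8L, 10L),
                    mismatches = c(2L, 4L, 6L, 8L, 10L))
  for (mth in c("difference", "ols", "major_axis"))
    expect_equal(residual_split(rec, method = mth)$residual,
                 rep(0, 5), tolerance = 1e-9)
  set.seed(3)
  rnd <- data.frame(node = 1:8, delta = stats::rnorm(8),
                    matches = rpois(8, 6), mismatches = rpois(8, 6))
  fit <- stats::lm(matches ~ mismatches, data = rnd)
  expect_equal(residual_split(rnd, method = "ols")$residual,
               unname(stats::residuals(fit)), tolerance = 1e-9)
  expect_equal(residual_split(rnd, method = "difference")$residual,
               rnd$matches - rnd$mismatches)
  const <- transform(rnd, mismatches = 3L)
  expect_warning(r <- residual_split(const, method = "ols"),
                 "constant")
  expect_equal(r$residual, const$matches - mean(const$matches))
})

test_that("enrichment test gives exact extreme tails", {
  # positive-residual branches all larger: minimal one-sided tail
  rec <- data.frame(node = 1:6, delta = c(5, 6, 7, 1, 2, 3),
                    matches = 0L, mismatches = 0L,
                    residual = c(1, 1, 1, -1, -1, -1))
  expect_equal(enrichment_test(rec)$p, 1 / choose(6, 3))
  # identical |delta| distributions: no enrichment
  rec2 <- transform(rec, delta = c(1, 2, 3, 1, 2, 3))
  expect_gte(suppressWarnings(enrichment_test(rec2)$p), 0.5)
  # a single-sign residual vector leaves the test undefined
  rec3 <- transform(rec, residual = 1)
  expect_warning(out <- enrichment_test(rec3), "empty")
  expect_true(is.na(out$p))
})

test_that("enrichment p matches exact rank-sum enumeration on small cases", {
  for (s in 1:12) {
    set.seed(s)
    n <- sample(5:8, 1)
    rec <- data.frame(node = seq_len(n), delta = stats::rnorm(n),
                      matches = 0L, mismatches = 0L,
                      residual = sample(c(-1, 1), n, replace = TRUE))
    if (all(rec$residual > 0) || all(rec$residual < 0)) next
    got <- enrichment_test(rec)$p
    expect_equal(got,
                 oracle_wilcox_exact(abs(rec$delta[rec$residual > 0]),
                                     abs(rec$delta[rec$residual < 0]),
                                     "greater"))
  }
})

test_that("planted concordant fixations drive the p-value down", {
  tree <- generate_tree(48, seed = 77)
  trait <- simulate_bm(tree, sigma2 = 1, seed = 78)
  p_at <- function(conc) {
    sig <- simulate_clade_signal(tree, trait, n_positions = 2000,
                                 concordance = conc, seed = 79)
    branch_enrichment(sig$mono, sig$gwas, tree, trait)$test$p
  }
  ps <- vapply(c(0.5, 0.7, 0.95), p_at, numeric(1L))
  expect_true(all(diff(ps) < 0))   # monotone power in planting strength
  expect_lt(ps[3], 0.05)
})
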