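ranked_matrix <- function(calls_by_pos, species) {
  n <- length(calls_by_pos)
  allele_matrix(data.frame(rsid = sprintf("rs%d", seq_len(n)),
                           chrom = "chr1", pos = seq_len(n) * 100L,
                           ref = "A", alt = "G"),
                species,
                do.call(rbind, calls_by_pos))
}

test_that("per-position rank test recovers the exact two-sided p", {
  sp <- paste0("s", 1:6)
  m <- ranked_matrix(list(c("ref", "ref", "ref", "alt", "alt", "alt")),
                     sp)
  ranks <- stats::setNames(c(4, 5, 6, 1, 2, 3), sp)
  tests <- per_position_test(m, ranks)
  expect_equal(tests$p, 0.1)   # exact enumeration for groups of 3 and 3
  expect_equal(tests$higher_rank_code, "ref")
  # identical rank distributions in the two groups: p = 1
  m2 <- ranked_matrix(list(c("ref", "alt", "ref", "alt")),
                      paste0("s", 1:4))
  tied <- stats::setNames(c(1.5, 1.5, 3.5, 3.5), paste0("s", 1:4))
  expect_equal(suppressWarnings(per_position_test(m2, tied))$p, 1)
  # invariant positions are skipped with a message
  m3 <- ranked_matrix(list(rep("ref", 4)), paste0("s", 1:4))
  expect_message(out <- per_position_test(
    m3, stats::setNames(1:4, paste0("s", 1:4))), "skipped")
  expect_null(out)
})

test_that("per-position p equals exact rank-sum enumeration", {
  for (s in 1:20) {
    set.seed(s)
    n <- sample(5:8, 1)
    sp <- paste0("s", seq_len(n))
    calls <- sample(c("ref", "alt"), n, replace = TRUE)
    if (length(unique(calls)) < 2L) calls[1:2] <- c("ref", "alt")
    m <- ranked_matrix(list(calls), sp)
    ranks <- stats::setNames(sample(n), sp)
    got <- per_position_test(m, ranks)
    expect_equal(got$p,
                 oracle_wilcox_exact(ranks[calls == "ref"],
                                     ranks[calls == "alt"],
                                     "two.sided"))
  }
})

test_that("causative selection splits by GWAS concordance", {
  tests <- data.frame(rsid = c("a", "b", "c"), chrom = "chr1",
                      pos = c(10L, 20L, 30L),
                      p = c(0.04, 0.04, 0.2),
                      higher_rank_code = c("alt", "ref", "alt"),
                      n_ref = 3L, n_alt = 3L)
  gwas <- data.frame(rsid = c("a", "b", "c"), chrom = "chr1",
                     pos = c(10L, 20L, 30L), ref = "A", alt = "G",
                     effect_sign = 1L, pvalue = 1e-9)
  sel <- select_causative(tests, gwas, alpha = 0.05)
  expect_equal(sel$concordant$rsid, "a")   # alt carriers higher, alt increasing
  expect_equal(sel$discordant$rsid, "b")
  # p = 0.2 sits in neither set
  expect_false("c" %in% c(sel$concordant$rsid, sel$discordant$rsid))
})

test_that("interval overlap respects the half-open convention", {
  # BED [100, 200) covers 0-based bases 100..199, i.e. 1-based
  # positions 101..200 — the same mapping the blacklist filter uses
  iv <- data.frame(chrom = "chr1", start = 100L, end = 200L)
  pos <- data.frame(chrom = "chr1", pos = c(150L, 200L, 100L, 201L))
  expect_equal(interval_overlap(pos, iv), c(TRUE, TRUE, FALSE, FALSE))
  for (s in 1:20) {
    set.seed(s)
    p <- data.frame(chrom = sample(c("chr1", "chr2"), 30,
                                   replace = TRUE),
                    pos = sample.int(1000L, 30))
    iv <- data.frame(chrom = sample(c("chr1", "chr2"), 10,
                                    replace = TRUE),
                     start = sample.int(900L, 10))
    iv$end <- iv$start + sample.int(100L, 10)
    expect_equal(interval_overlap(p, iv), oracle_overlap(p, iv))
  }
})

test_that("conservation windows average 21 bases around the position", {
  const <- data.frame(chrom = "chr1", start = 0L, end = 1000L,
                      score = 2.0)
  expect_equal(phylop_window("chr1", 500L, const), 2.0)
  # per-base track equal to the coordinate: mean is the centre
  ramp <- data.frame(chrom = "chr1", start = 89:110, end = 90:111,
                     score = 90:111)
  expect_equal(phylop_window("chr1", 100L, ramp), 100)
  set.seed(4)
  rnd <- data.frame(chrom = "chr1", start = 0:120, end = 1:121,
                    score = stats::rnorm(121))
  expect_equal(phylop_window("chr1", 60L, rnd),
               mean(rnd$score[rnd$start %in% 49:69]))
  expect_warning(partial <- phylop_window("chr1", 1005L, const),
                 "partial")
  expect_equal(partial, 2.0)
  expect_warning(none <- phylop_window("chr2", 500L, const),
                 "outside")
  expect_true(is.na(none))
})

test_that("TSS distance is the same-chromosome minimum", {
  tss <- data.frame(chrom = c("chr1", "chr1", "chr2"),
                    pos = c(400L, 1500L, 999L))
  expect_equal(tss_distance("chr1", 1000L, tss), 500)
  expect_equal(tss_distance("chr1", 1500L, tss), 0)
  expect_warning(na <- tss_distance("chr3", 5L, tss), "no TSS")
  expect_true(is.na(na))
  for (s in 1:20) {
    set.seed(s)
    t2 <- data.frame(chrom = "chr1", pos = sample.int(1e5L, 12))
    p <- sample.int(1e5L, 1)
    expect_equal(tss_distance("chr1", p, t2),
                 oracle_tss("chr1", p, t2))
  }
})

test_that("group comparisons give exact extreme and null tails", {
  expect_equal(compare_groups(c(1, 2, 3), c(10, 20, 30), "less"),
               1 / choose(6, 3))
  expect_gte(suppressWarnings(
    compare_groups(c(1, 2, 3), c(1, 2, 3), "less")), 0.5)
  expect_warning(na <- compare_groups(numeric(0), 1:3, "less"),
                 "empty")
  expect_true(is.na(na))
  for (s in 1:10) {
    set.seed(s)
    a <- stats::rnorm(4); b <- stats::rnorm(5)
    expect_equal(compare_groups(a, b, "greater"),
                 oracle_wilcox_exact(a, b, "greater"))
  }
})

test_that("synteny requires the gene in every species' window", {
  maps <- lapply(stats::setNames(c(0L, 100L, 200L, 300L, 400L),
                                 paste0("sp", 1:5)),
                 function(s) data.frame(rsid = "rs1", chrom = "chr1",
                                        pos = 1000000L + s))
  in_all <- lapply(maps, function(mp)
    data.frame(chrom = "chr1", start = mp$pos + 399999L,
               end = mp$pos + 405000L, gene = "NEAR"))
  expect_equal(synteny_genes("rs1", maps, in_all), "NEAR")
  # gene inside the window in only 4 of 5 species is excluded
  four <- in_all
  four[[5]]$start <- four[[5]]$start + 2000000L
  four[[5]]$end <- four[[5]]$end + 2000000L
  expect_length(synteny_genes("rs1", maps, four), 0L)
  # unmappable position: NULL
  broken <- maps
  broken[[3]] <- broken[[3]][0, ]
  expect_null(synteny_genes("rs1", broken, in_all))
  for (s in 1:10) {
    set.seed(s)
    mp <- lapply(stats::setNames(1:3, paste0("g", 1:3)), function(i)
      data.frame(rsid = "rs1", chrom = "chr1",
                 pos = sample.int(5e6L, 1)))
    gn <- lapply(mp, function(x)
      data.frame(chrom = "chr1",
                 start = sample.int(5e6L, 6),
                 end = integer(6), gene = paste0("G", 1:6)))
    gn <- lapply(gn, function(g) {
      g$end <- g$start + sample.int(1e4L, 6); g
    })
    expect_setequal(synteny_genes("rs1", mp, gn, window = 5e5L),
                    oracle_synteny("rs1", mp, gn, window = 5e5L))
  }
})

test_that("eQTL annotation de-duplicates and handles absence", {
  eqtl <- data.frame(rsid = c("a", "a", "a", "b"),
                     gene = c("G1", "G2", "G1", "G3"))
  expect_setequal(eqtl_annotate("a", eqtl), c("G1", "G2"))
  expect_length(eqtl_annotate("zzz", eqtl), 0L)
})

test_that("a consensus match scores above its broken variant", {
  # non-palindromic consensus ATGCTTA so the broken allele cannot be
  # rescued by a minus-strand match
  from_consensus <- function(cons) {
    b <- strsplit(cons, "")[[1]]
    m <- matrix(1, 4, length(b),
                dimnames = list(c("A", "C", "G", "T"), NULL))
    for (j in seq_along(b)) m[b[j], j] <- 97
    m
  }
  pwms <- list(TF_test = from_consensus("ATGCTTA"))
  flank <- "CGATCGA"
  ref <- paste0(flank, "ATGCTTA", flank)          # 21 bases, centre = C
  alt <- paste0(flank, "ATGGTTA", flank)          # break max-info column
  res <- motif_disruption(ref, alt, pwms)
  expect_true(res$ref_hit)
  expect_gt(res$score_delta, 0)
  expect_gt(res$best_ref, res$best_alt)
  # identical windows are the degenerate neutral case
  deg <- motif_disruption(ref, ref, pwms)
  expect_equal(deg$score_delta, 0)
  expect_equal(deg$class, "neutral")
  expect_error(motif_disruption(ref, paste0("A", substr(alt, 2, 21)),
                                pwms), "centre")
})

test_that("motif scan finds the consensus on the reverse strand", {
  pwms <- synthetic_pwms()["TF_beta"]   # CACGTG, palindrome-free check
  pwms2 <- list(TF = matrix(c(97, 1, 1, 1,   # consensus ATGC
                              1, 1, 1, 97,
                              1, 1, 97, 1,
                              1, 97, 1, 1), 4, 4,
                            dimnames = list(c("A", "C", "G", "T"),
                                            NULL)))
  fw <- paste0("AAAAAAAAA", "ATGC", "AAAAAAAA")      # 21, centre in motif
  rc <- paste(rev(strsplit(chartr("ACGT", "TGCA", fw), "")[[1]]),
              collapse = "")
  sub <- function(w, b) {
    s <- strsplit(w, "")[[1]]; s[11] <- b; paste(s, collapse = "")
  }
  r1 <- motif_disruption(fw, sub(fw, "G"), pwms2)
  r2 <- motif_disruption(rc, sub(rc, "G"), pwms2)
  expect_equal(r1$best_ref, r2$best_ref, tolerance = 1e-12)
})

test_that("null tail probabilities equal exhaustive enumeration", {
  for (L in c(4L, 6L)) {
    set.seed(L)
    counts <- matrix(stats::rpois(4 * L, 5) + 1, 4, L,
                     dimnames = list(c("A", "C", "G", "T"), NULL))
    probs <- sweep(counts + 0.25, 2, colSums(counts) + 1, "/")
    ic <- 2 + colSums(probs * log2(probs))
    contribs <- sweep(probs, 2, ic, "*")
    tail_fn <- parevo:::.pwm_null_tail(contribs)
    # enumerate all 4^L sequences
    grid <- as.matrix(expand.grid(rep(list(1:4), L)))
    scores <- apply(grid, 1, function(b)
      sum(contribs[cbind(b, seq_len(L))]))
    for (q in stats::quantile(scores, c(0.01, 0.5, 0.9, 0.999)))
      expect_equal(tail_fn(q), mean(scores >= q - 1e-9),
                   tolerance = 1e-12)
  }
})

test_that("shared motifs intersect hits across backgrounds", {
  a <- data.frame(tf = c("X", "Y"), ref_hit = c(TRUE, TRUE),
                  alt_hit = c(FALSE, FALSE))
  b <- data.frame(tf = c("X", "Y"), ref_hit = c(TRUE, FALSE),
                  alt_hit = c(FALSE, FALSE))
  expect_equal(shared_motifs(a, b), "X")
  expect_length(shared_motifs(a[0, ], b), 0L)
})

test_that("PWM files round-trip through the JASPAR-style format", {
  pwms <- synthetic_pwms()
  path <- withr::local_tempfile(fileext = ".txt")
  write_pwms(pwms, path)
  got <- read_pwms(path)
  expect_equal(got, lapply(pwms, function(m) {
    dimnames(m) <- list(c("A", "C", "G", "T"), NULL); m
  }))
})
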