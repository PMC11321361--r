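#' Read / write position weight matrices (JASPAR-style plain counts)
#'
#' Format: a `>name` header line followed by four rows
#' `A [ 4 19 0 ... ]` (base letter, counts per motif column in brackets),
#' one block per motif.
#'
#' @param path file path.
#' @return `read_pwms`: named list of 4 x L count matrices with rownames
#'   A, C, G, T.
#' @export
read_pwms <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  heads <- grep("^>", lines)
  if (length(heads) == 0L) stop("no PWM headers in ", path)
  out <- list()
  for (h in seq_along(heads)) {
    name <- sub("^>\\s*", "", lines[heads[h]])
    block <- lines[(heads[h] + 1L):(heads[h] + 4L)]
    mat <- t(vapply(block, function(l) {
      nums <- regmatches(l, gregexpr("[0-9.]+", l))[[1L]]
      as.numeric(nums)
    }, numeric(length(
      regmatches(block[1L], gregexpr("[0-9.]+", block[1L]))[[1L]]))))
    rownames(mat) <- toupper(substr(trimws(block), 1L, 1L))
    out[[name]] <- mat[c("A", "C", "G", "T"), , drop = FALSE]
  }
  out
}

#' @rdname read_pwms
#' @param pwms named list of 4 x L count matrices.
#' @export
write_pwms <- function(pwms, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (name in names(pwms)) {
    writeLines(paste0(">", name), con)
    m <- pwms[[name]]
    for (b in c("A", "C", "G", "T"))
      writeLines(sprintf("%s [ %s ]", b,
                         paste(m[b, ], collapse = " ")), con)
  }
  invisible(path)
}

# counts -> probabilities with a background-weighted pseudocount
.pwm_probs <- function(counts, pseudocount = 1,
                       bkg = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)) {
  counts <- counts[c("A", "C", "G", "T"), , drop = FALSE]
  sweep(counts + pseudocount * bkg, 2L,
        colSums(counts) + pseudocount, "/")
}

# information-content-weighted per-column contributions: column IC times
# base probability; the motif match score of a sequence is the sum of one
# contribution per column
.pwm_contribs <- function(probs) {
  ic <- 2 + colSums(probs * log2(probs))
  sweep(probs, 2L, ic, "*")
}

# exact null tail of the match score under a uniform-base background:
# full enumeration of the 4^L per-column contribution sums for L <= 10,
# fine-grid dynamic programming beyond. Returns function(raw_score) ->
# P(S >= raw_score).
.pwm_null_tail <- function(contribs) {
  L <- ncol(contribs)
  if (L <= 10L) {
    sums <- 0
    for (j in seq_len(L))
      sums <- as.vector(outer(sums, contribs[, j], "+"))
    function(s) mean(sums >= s - 1e-9)
  } else {
    grid <- 1e-5
    probs <- 1
    offset <- 0
    for (j in seq_len(L)) {
      ki <- round(contribs[, j] / grid)
      width <- length(probs) + max(ki) - min(ki)
      acc <- numeric(width)
      for (b in 1:4) {
        sh <- ki[b] - min(ki)
        acc[(1L + sh):(length(probs) + sh)] <-
          acc[(1L + sh):(length(probs) + sh)] + probs * 0.25
      }
      probs <- acc
      offset <- offset + min(ki)
    }
    function(s) {
      k <- ceiling((s - 1e-9) / grid) - offset
      if (k <= 0) 1 else if (k > length(probs)) 0 else
        sum(probs[k:length(probs)])
    }
  }
}

.revcomp <- function(seq)
  paste(rev(strsplit(chartr("ACGTacgt", "TGCAtgca", seq), "")[[1L]]),
        collapse = "")

# best normalized match score of a PWM over all offsets covering the
# window's centre base, both strands
.pwm_best_score <- function(window, contribs) {
  L <- ncol(contribs)
  W <- nchar(window)
  centre <- (W + 1L) %/% 2L
  smin <- sum(apply(contribs, 2L, min))
  smax <- sum(apply(contribs, 2L, max))
  best <- -Inf
  for (strand_seq in c(window, .revcomp(window))) {
    chars <- strsplit(toupper(strand_seq), "")[[1L]]
    idx <- match(chars, c("A", "C", "G", "T"))
    for (o in max(1L, centre - L + 1L):min(W - L + 1L, centre)) {
      b <- idx[o:(o + L - 1L)]
      if (anyNA(b)) next
      s <- sum(contribs[cbind(b, seq_len(L))])
      best <- max(best, (s - smin) / (smax - smin))
    }
  }
  best
}

#' Motif disruption scores for a variant
#'
#' Scans both alleles' sequence windows against each PWM over both
#' strands and every offset covering the variant base. The match score is
#' the information-content-weighted probability sum, min-max normalized
#' to [0, 1]; an allele "hits" a motif when the exact tail probability of
#' its best score under the uniform-background null (computed by
#' enumerating or convolving the per-column score distribution) is below
#' `p_threshold`. The score difference between alleles classifies the
#' variant's effect on each motif as strong / weak / neutral.
#'
#' @param ref_window,alt_window equal-length odd-width sequences
#'   differing at most at the centre base (default width 21: the variant
#'   plus 10 flanking bases on either side; identical windows are a
#'   degenerate case scoring delta 0).
#' @param pwms named list of 4 x L count matrices (see [read_pwms()]).
#' @param p_threshold null tail probability below which an allele's best
#'   score counts as a motif hit.
#' @param strong_cut,weak_cut |score_delta| thresholds for the
#'   strong / weak / neutral classification.
#' @param pseudocount,bkg PWM normalization parameters.
#' @return data.frame: tf, ref_hit, alt_hit, best_ref, best_alt,
#'   score_delta (best_ref - best_alt), class. PWMs longer than the
#'   window are skipped with a warning.
#' @export
motif_disruption <- function(ref_window, alt_window, pwms,
                             p_threshold = 1e-4, strong_cut = 0.7,
                             weak_cut = 0.4, pseudocount = 1,
                             bkg = c(A = 0.25, C = 0.25, G = 0.25,
                                     T = 0.25)) {
  W <- nchar(ref_window)
  if (nchar(alt_window) != W || W %% 2L == 0L)
    stop("windows must be equal odd lengths")
  centre <- (W + 1L) %/% 2L
  rc <- strsplit(toupper(ref_window), "")[[1L]]
  ac <- strsplit(toupper(alt_window), "")[[1L]]
  # identical windows are allowed as a degenerate case (delta 0, neutral)
  if (any(rc[-centre] != ac[-centre]))
    stop("windows may differ only at the centre base")
  rows <- lapply(names(pwms), function(tf) {
    counts <- pwms[[tf]]
    if (ncol(counts) > W) {
      warning("PWM ", tf, " longer than window; skipped")
      return(NULL)
    }
    contribs <- .pwm_contribs(.pwm_probs(counts, pseudocount, bkg))
    tail_p <- .pwm_null_tail(contribs)
    smin <- sum(apply(contribs, 2L, min))
    smax <- sum(apply(contribs, 2L, max))
    denorm <- function(s) s * (smax - smin) + smin
    best_ref <- .pwm_best_score(ref_window, contribs)
    best_alt <- .pwm_best_score(alt_window, contribs)
    delta <- best_ref - best_alt
    data.frame(tf = tf,
               ref_hit = tail_p(denorm(best_ref)) < p_threshold,
               alt_hit = tail_p(denorm(best_alt)) < p_threshold,
               best_ref = best_ref, best_alt = best_alt,
               score_delta = delta,
               class = if (abs(delta) >= strong_cut) "strong"
               else if (abs(delta) >= weak_cut) "weak" else "neutral")
  })
  rows <- rows[!vapply(rows, is.null, logical(1L))]
  if (length(rows) == 0L) return(NULL)
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Motifs shared between two genomic backgrounds
#'
#' Transcription factors whose motif is hit by either allele (neutral
#' classes included) in both backgrounds — candidates for conserved
#' regulatory function.
#'
#' @param results_a,results_b [motif_disruption()] tables from the two
#'   backgrounds (e.g. human and mouse sequence contexts).
#' @return character vector of shared TF names.
#' @export
shared_motifs <- function(results_a, results_b) {
  hit <- function(res) {
    if (is.null(res) || nrow(res) == 0L) return(character(0))
    res$tf[res$ref_hit | res$alt_hit]
  }
  intersect(hit(results_a), hit(results_b))
}
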