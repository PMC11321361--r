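#' Trait-increasing allele code for a GWAS record
#'
#' The effect sign applies to the alternate allele: a positive sign means
#' the alternate allele increases the trait, so the trait-increasing call
#' code is `"alt"`; a negative sign makes it `"ref"`.
#'
#' @param effect_sign integer vector of +1 / -1.
#' @return character vector of `"alt"` / `"ref"`.
#' @export
trait_increasing_code <- function(effect_sign) {
  effect_sign <- as.integer(effect_sign)
  if (!all(effect_sign %in% c(-1L, 1L)))
    stop("effect_sign must be +1 or -1")
  ifelse(effect_sign > 0L, "alt", "ref")
}

#' Per-unit genomic score
#'
#' For each species (or strain), the proportion of trait-increasing allele
#' matches among all matches to either human allele across the positions
#' of the matrix: `score = n_increasing / n_total`, where `n_total`
#' counts ref- plus alt-matching calls and `n_increasing` counts calls
#' equal to the trait-increasing code of the position's GWAS record.
#' Missing (and masked) calls contribute to neither count. The matrix is
#' expected to be pre-subset to genome-wide significant positions
#' ([subset_significant()]); every position must have a GWAS record.
#'
#' @param m allele_matrix.
#' @param gwas GWAS table covering every matrix position.
#' @param min_calls minimum `n_total` for a defined score (default 1);
#'   units below it get score NA and are excluded from ranking downstream.
#' @return data.frame (class `score_table`) with columns `unit`, `score`,
#'   `n_increasing`, `n_total`; score is NA (flagged) when
#'   `n_total < min_calls`.
#' @export
genomic_score <- function(m, gwas, min_calls = 1L) {
  key <- paste(m$positions$chrom, m$positions$pos)
  idx <- match(key, paste(gwas$chrom, gwas$pos))
  if (anyNA(idx))
    stop("every matrix position needs a GWAS record; missing: ",
         paste(m$positions$rsid[is.na(idx)], collapse = ", "))
  inc_code <- trait_increasing_code(gwas$effect_sign[idx])
  called <- m$calls == "ref" | m$calls == "alt"
  increasing <- m$calls == inc_code   # row-wise recycling over columns
  n_total <- colSums(called)
  n_inc <- colSums(increasing & called)
  score <- ifelse(n_total >= min_calls, n_inc / n_total, NA_real_)
  if (anyNA(score))
    warning(sum(is.na(score)), " unit(s) with fewer than ", min_calls,
            " called position(s); score undefined")
  structure(data.frame(unit = m$species, score = score,
                       n_increasing = n_inc, n_total = n_total,
                       row.names = NULL),
            class = c("score_table", "data.frame"))
}

#' Average-tie ranks
#'
#' Ascending ranks with ties averaged, so the rank sum is always
#' n(n+1)/2. Used to put genomic scores and phenotypes on a common,
#' outlier-robust scale before regression.
#'
#' @param values named numeric vector, all values defined.
#' @return named numeric vector of ranks.
#' @export
to_ranks <- function(values) {
  if (anyNA(values)) stop("to_ranks requires all values defined")
  rank(values, ties.method = "average")
}
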