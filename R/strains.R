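#' Subset a matrix to positions shared with a strain panel
#'
#' Keeps positions whose unordered human allele set {ref, alt} equals the
#' panel's allele set at the lifted position. Matching is orientation
#' -aware set equality; strand complementing is out of scope (a
#' complement-aware mode would be speculative without strand metadata).
#'
#' @param m allele_matrix.
#' @param panel_positions data.frame `chrom`, `pos` (human coordinates),
#'   `allele1`, `allele2` (the panel's two alleles at that position).
#' @return allele_matrix restricted to shared positions.
#' @export
subset_shared <- function(m, panel_positions) {
  key <- paste(m$positions$chrom, m$positions$pos)
  idx <- match(key, paste(panel_positions$chrom, panel_positions$pos))
  keep <- !is.na(idx)
  same <- logical(nrow(m$positions))
  for (i in which(keep)) {
    j <- idx[i]
    same[i] <- setequal(
      toupper(c(m$positions$ref[i], m$positions$alt[i])),
      toupper(c(panel_positions$allele1[j], panel_positions$allele2[j])))
  }
  subset_positions(m, same)
}

#' Average phenotypes between the sexes
#'
#' The per-strain analysis value is the arithmetic mean of the two
#' sex-labelled replicates; strains with a single sex use that value with
#' a warning.
#'
#' @param phenotypes data.frame `strain`, `sex`, `value`.
#' @return named numeric vector of per-strain means.
#' @export
average_sexes <- function(phenotypes) {
  sp <- split(phenotypes$value, phenotypes$strain)
  single <- names(sp)[vapply(sp, length, integer(1L)) < 2L]
  if (length(single) > 0L)
    warning("single-sex strain(s) use the available value: ",
            paste(single, collapse = ", "))
  vapply(sp, mean, numeric(1L))
}

#' Genomic-score / phenotype association in a strain panel
#'
#' The within-species validation: no phylogeny relates the strains (a
#' multiparental cross has no tree), so the score and phenotype ranks are
#' compared by ordinary least squares (reported with R-squared) and a
#' one-tailed Spearman correlation test toward positive association.
#'
#' @param genotypes strain allele_matrix (positions already subset to
#'   those shared with the parent matrix and GWAS-significant).
#' @param gwas GWAS table.
#' @param trait named per-strain phenotype (means over sexes).
#' @param exact use the exact Spearman null (errors with ties); default
#'   FALSE uses the t approximation.
#' @return list: slope, intercept, r_squared, rho, p_one_tailed, n.
#' @export
strain_association <- function(genotypes, gwas, trait, exact = FALSE) {
  scores <- suppressWarnings(genomic_score(genotypes, gwas))
  units <- intersect(scores$unit[!is.na(scores$score)],
                     names(trait)[!is.na(trait)])
  dropped <- setdiff(genotypes$species, units)
  if (length(dropped) > 0L)
    message(length(dropped), " strain(s) without score or phenotype ",
            "dropped")
  if (length(units) < 5L) stop("need at least 5 strains with scores")
  x <- to_ranks(stats::setNames(
    scores$score[match(units, scores$unit)], units))
  y <- to_ranks(trait[units])
  fit <- stats::lm(y ~ x)
  ct <- suppressWarnings(
    stats::cor.test(x, y, method = "spearman",
                    alternative = "greater", exact = exact))
  list(slope = unname(stats::coef(fit)[2L]),
       intercept = unname(stats::coef(fit)[1L]),
       r_squared = summary(fit)$r.squared,
       rho = unname(ct$estimate), p_one_tailed = ct$p.value,
       n = length(units))
}

#' Per-position rank tests within a strain panel
#'
#' The per-position Wilcoxon rank-sum test of [per_position_test()],
#' applied with strains as units; positions invariant in the panel are
#' skipped.
#'
#' @param genotypes strain allele_matrix.
#' @param trait named per-strain phenotype.
#' @return PositionTest table.
#' @export
strain_position_tests <- function(genotypes, trait) {
  units <- intersect(genotypes$species, names(trait)[!is.na(trait)])
  per_position_test(subset_species(genotypes, units),
                    to_ranks(trait[units]))
}
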