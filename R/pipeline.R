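#' Run the full synthetic pipeline end to end
#'
#' Generates a tree, matrix, GWAS table, phenotype, annotation bundle and
#' strain panel from one configuration, then runs the complete analysis:
#' filter cascade, genomic scoring, rank PGLS with permulations,
#' internal-branch enrichment, candidate-position selection and
#' annotation, and strain-panel validation. When `outdir` is given, all
#' inputs and result tables are written as plain-text files (TSV / BED /
#' newick), so two runs from one seed can be compared byte for byte.
#'
#' @param config [sim_config()].
#' @param outdir optional output directory.
#' @param n_perm permulations for the association test.
#' @param n_strains strains in the validation panel.
#' @param coverage called-fraction threshold of the cascade.
#' @param candidate_alpha per-position selection threshold.
#' @return list: tree, sim (generator outputs), cascade, association,
#'   branches, candidates (selection + annotated table), strains.
#' @export
run_pipeline <- function(config = sim_config(), outdir = NULL,
                         n_perm = 200L, n_strains = 18L,
                         coverage = 0.75, candidate_alpha = 0.05) {
  tree <- generate_tree(config$n_species, seed = config$seed)
  sim <- simulate_matrix(tree, config)
  bundle <- generate_annotations(sim$matrix, sim$causal,
                                 seed = config$seed)
  cascade <- filter_cascade(sim$matrix, tree,
                            blacklist = bundle$blacklist,
                            coverage = coverage)
  assoc <- run_association(cascade$matrix, sim$gwas, tree, sim$trait,
                           n_perm = n_perm, seed = config$seed)
  branches <- branch_enrichment(cascade$mono, sim$gwas, tree, sim$trait)

  units <- names(sim$trait)
  sig <- subset_significant(cascade$matrix, sim$gwas)
  tests <- per_position_test(sig, to_ranks(sim$trait[units]))
  sel <- select_causative(tests, sim$gwas, alpha = candidate_alpha)
  annotated <- if (nrow(sel$concordant) > 0L)
    annotate_candidates(sel$concordant, bundle) else NULL

  panel <- generate_strain_panel(sim$matrix, sim$gwas,
                                 n_strains = n_strains, config = config,
                                 directions = sim$directions)
  shared <- subset_shared(
    subset_significant(panel$genotypes, sim$gwas),
    data.frame(chrom = sim$matrix$positions$chrom,
               pos = sim$matrix$positions$pos,
               allele1 = sim$matrix$positions$ref,
               allele2 = sim$matrix$positions$alt))
  strains <- strain_association(shared, sim$gwas, panel$trait)

  result <- list(tree = tree, sim = sim, cascade = cascade,
                 association = assoc, branches = branches,
                 candidates = list(selection = sel,
                                   annotated = annotated),
                 strains = strains)
  if (!is.null(outdir)) .write_pipeline(result, bundle, panel, outdir)
  result
}

.write_pipeline <- function(result, bundle, panel, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(...) file.path(outdir, ...)
  ape::write.tree(result$tree, fp("tree.nwk"))
  write_matrix(result$sim$matrix, fp("matrix.tsv"))
  write_gwas(result$sim$gwas, fp("gwas.tsv"))
  write_trait(result$sim$trait, fp("trait.tsv"))
  write_annotations(bundle, fp("annotations"))
  write_matrix(result$cascade$matrix, fp("matrix_filtered.tsv"))
  write_matrix(result$cascade$mono, fp("matrix_monophyletic.tsv"))
  utils::write.table(result$cascade$report, fp("filter_report.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(result$association$scores, fp("scores.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  a <- result$association
  assoc_row <- data.frame(
    n_species = a$n_species, n_positions = a$n_positions,
    sign = if (a$pgls$sign > 0) "+" else "-",
    pgls_p = a$pgls$p_one_sided_positive,
    permulation_p = a$perm$p_empirical)
  utils::write.table(assoc_row, fp("association.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(result$branches$records, fp("branches.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(result$candidates$selection$concordant,
                     fp("candidates_concordant.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(result$candidates$selection$discordant,
                     fp("candidates_discordant.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(result$candidates$annotated))
    utils::write.table(result$candidates$annotated,
                       fp("candidates_annotated.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  write_matrix(panel$genotypes, fp("strain_genotypes.tsv"))
  utils::write.table(panel$phenotypes, fp("strain_phenotypes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  s <- result$strains
  utils::write.table(
    data.frame(n = s$n, rho = s$rho, p_one_tailed = s$p_one_tailed,
               r_squared = s$r_squared),
    fp("strain_association.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  invisible(outdir)
}
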