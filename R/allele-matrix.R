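#' @title SNP-by-species allele matrix
#'
#' @description
#' The central container of the pipeline: a grid of classified allele calls
#' with one row per human SNP position and one column per species (or
#' strain). Cells never hold raw bases; each call is classified against the
#' two human alleles of its position into one of four codes:
#' `"ref"` (matches the human reference allele), `"alt"` (matches the human
#' alternate allele), `"other"` (an unambiguous base matching neither human
#' allele) and `"missing"` (unaligned or ambiguous).
#'
#' Positions are 1-based single-nucleotide coordinates (VCF-like); all
#' interval inputs elsewhere in the package are 0-based half-open (BED).
#'
#' @param positions data.frame with columns `rsid`, `chrom`, `pos` (1-based
#'   integer), `ref`, `alt` (single distinct bases). Extra columns (for
#'   example the defining clade of a monophyletic position) are carried
#'   along untouched.
#' @param species character vector of unique species (or strain) names.
#' @param calls character matrix, `nrow(positions)` x `length(species)`,
#'   with entries from [call_codes()].
#' @return An object of class `allele_matrix`: a list with elements
#'   `positions`, `species` and `calls` (rownames = rsid, colnames =
#'   species).
#' @examples
#' pos <- data.frame(rsid = "rs1", chrom = "chr1", pos = 100L,
#'                   ref = "A", alt = "G")
#' m <- allele_matrix(pos, c("sp1", "sp2"),
#'                    matrix(c("ref", "alt"), 1, 2))
#' @export
allele_matrix <- function(positions, species, calls) {
  stopifnot(is.data.frame(positions), is.character(species))
  required <- c("rsid", "chrom", "pos", "ref", "alt")
  if (!all(required %in% names(positions)))
    stop("positions must have columns: ", paste(required, collapse = ", "))
  if (!is.matrix(calls))
    calls <- matrix(calls, nrow = nrow(positions), ncol = length(species))
  if (nrow(calls) != nrow(positions) || ncol(calls) != length(species))
    stop("calls grid dimensions do not match positions x species")
  if (anyDuplicated(species))
    stop("species names must be unique")
  key <- paste(positions$chrom, positions$pos)
  if (anyDuplicated(key))
    stop("duplicate (chrom, pos) in positions")
  if (any(positions$ref == positions$alt))
    stop("ref and alt alleles must differ (biallelic positions only)")
  bad <- !(calls %in% call_codes())
  if (any(bad))
    stop("invalid call codes: ", paste(unique(calls[bad]), collapse = ", "))
  rownames(calls) <- positions$rsid
  colnames(calls) <- species
  structure(list(positions = positions, species = species, calls = calls),
            class = "allele_matrix")
}

#' Allele-call codes
#'
#' @return The four classified call codes, in the order ref-match,
#'   alt-match, other, missing.
#' @export
call_codes <- function() c("ref", "alt", "other", "missing")

#' @export
print.allele_matrix <- function(x, ...) {
  cat(sprintf("allele_matrix: %d positions x %d species\n",
              nrow(x$positions), length(x$species)))
  tab <- table(factor(x$calls, levels = call_codes()))
  cat("  calls:", paste(names(tab), tab, sep = "=", collapse = " "), "\n")
  invisible(x)
}

#' @export
dim.allele_matrix <- function(x) dim(x$calls)

#' Subset an allele matrix by position index
#'
#' Row filters used by the cascade; keeps species columns untouched.
#'
#' @param m allele_matrix.
#' @param keep logical or integer index over positions.
#' @return allele_matrix restricted to the kept positions.
#' @export
subset_positions <- function(m, keep) {
  allele_matrix(m$positions[keep, , drop = FALSE], m$species,
                m$calls[keep, , drop = FALSE])
}

#' Subset an allele matrix by species
#'
#' @param m allele_matrix.
#' @param species character vector, subset of `m$species`.
#' @return allele_matrix restricted to those columns.
#' @export
subset_species <- function(m, species) {
  if (!all(species %in% m$species))
    stop("unknown species: ",
         paste(setdiff(species, m$species), collapse = ", "))
  allele_matrix(m$positions, species,
                m$calls[, species, drop = FALSE])
}

# classify raw single-character base calls against ref/alt alleles
# (case-insensitive; '-' and 'N' mean missing)
.classify_calls <- function(bases, ref, alt) {
  b <- toupper(bases)
  out <- rep("other", length(b))
  out[b == toupper(ref)] <- "ref"
  out[b == toupper(alt)] <- "alt"
  out[b %in% c("-", "N", "")] <- "missing"
  out
}

#' Read / write the SNP-by-species matrix TSV
#'
#' @description
#' The matrix dialect is a TSV with header
#' `rsid chrom pos ref alt <species...>`; data cells hold single raw base
#' characters which are classified against that row's ref/alt at read time
#' (case-insensitively): base equal to ref gives a ref-match, equal to alt
#' an alt-match, `-`/`N` missing, anything else "other". Non-biallelic
#' records (ref equal to alt, or alleles that are not single A/C/G/T bases)
#' are dropped at read time with a message, so they never enter the matrix.
#'
#' `write_matrix` emits raw bases again: ref/alt matches print the
#' corresponding human allele, missing prints `-`, and "other" prints the
#' alphabetically first base that matches neither human allele, so that
#' read-write-read round-trips are the identity on the classified matrix.
#'
#' @param path file path.
#' @return `read_matrix`: an [allele_matrix()].
#' @export
read_matrix <- function(path) {
  nf <- utils::count.fields(path, sep = "\t", quote = "")
  if (length(unique(nf)) != 1L)
    stop("ragged rows in matrix TSV: ", path)
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          colClasses = "character", check.names = FALSE)
  fixed <- c("rsid", "chrom", "pos", "ref", "alt")
  if (!all(fixed %in% names(df)[seq_along(fixed)]))
    stop("matrix TSV must start with columns: ",
         paste(fixed, collapse = ", "))
  species <- names(df)[-seq_along(fixed)]
  if (length(species) == 0L) stop("matrix TSV has no species columns")
  ok <- toupper(df$ref) %in% c("A", "C", "G", "T") &
        toupper(df$alt) %in% c("A", "C", "G", "T") &
        toupper(df$ref) != toupper(df$alt)
  if (any(!ok))
    message(sum(!ok), " non-biallelic record(s) dropped at read time")
  df <- df[ok, , drop = FALSE]
  key <- paste(df$chrom, df$pos)
  if (anyDuplicated(key))
    stop("duplicate (chrom, pos) in matrix TSV")
  positions <- data.frame(rsid = df$rsid, chrom = df$chrom,
                          pos = as.integer(df$pos),
                          ref = toupper(df$ref), alt = toupper(df$alt))
  calls <- matrix("missing", nrow(df), length(species))
  for (i in seq_len(nrow(df)))
    calls[i, ] <- .classify_calls(unlist(df[i, species], use.names = FALSE),
                                  positions$ref[i], positions$alt[i])
  allele_matrix(positions, species, calls)
}

#' @rdname read_matrix
#' @param m allele_matrix to write.
#' @return `write_matrix`: the path, invisibly.
#' @export
write_matrix <- function(m, path) {
  bases <- c(A = "A", C = "C", G = "G", T = "T")
  other_base <- function(ref, alt) setdiff(names(bases), c(ref, alt))[1L]
  out <- m$calls
  for (i in seq_len(nrow(out))) {
    p <- m$positions[i, ]
    out[i, ] <- c(ref = p$ref, alt = p$alt,
                  other = other_base(p$ref, p$alt),
                  missing = "-")[m$calls[i, ]]
  }
  df <- cbind(m$positions[, c("rsid", "chrom", "pos", "ref", "alt")],
              as.data.frame(out))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a GWAS summary table
#'
#' TSV with columns `rsid chrom pos ref alt effect_sign pvalue`, where
#' `effect_sign` is +1 or -1 (sign of the alternate allele's effect on the
#' trait: +1 means the alternate allele is trait-increasing) and `pvalue`
#' the association probability in (0, 1]. Effect sizes (betas) are never
#' carried: only the sign is portable across species.
#'
#' @param path file path.
#' @return `read_gwas`: data.frame with those columns, `effect_sign`
#'   integer, `pvalue` numeric.
#' @export
read_gwas <- function(path) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          colClasses = c(rsid = "character",
                                         chrom = "character"))
  validate_gwas(df)
}

#' @rdname read_gwas
#' @param gwas GWAS table to write.
#' @export
write_gwas <- function(gwas, path) {
  utils::write.table(gwas, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Validate a GWAS table
#'
#' @param gwas data.frame with columns rsid, chrom, pos, ref, alt,
#'   effect_sign, pvalue.
#' @return The table, with effect_sign coerced to integer.
#' @export
validate_gwas <- function(gwas) {
  required <- c("rsid", "chrom", "pos", "ref", "alt", "effect_sign",
                "pvalue")
  if (!all(required %in% names(gwas)))
    stop("GWAS table must have columns: ", paste(required, collapse = ", "))
  gwas$effect_sign <- as.integer(gwas$effect_sign)
  if (!all(gwas$effect_sign %in% c(-1L, 1L)))
    stop("effect_sign must be +1 or -1")
  if (!all(gwas$pvalue > 0 & gwas$pvalue <= 1))
    stop("pvalue must lie in (0, 1]")
  gwas
}

#' Read / write BED interval files
#'
#' Plain 3+ column BED: `chrom start end [label]`, 0-based half-open.
#' Used for blacklist regions, cCRE sets, TSS points (as width-1
#' intervals) and per-species gene models.
#'
#' @param path file path.
#' @return `read_bed`: data.frame with columns chrom, start, end, label.
#' @export
read_bed <- function(path) {
  df <- utils::read.delim(path, sep = "\t", header = FALSE,
                          colClasses = "character")
  if (ncol(df) < 3L) stop("BED file needs at least 3 columns: ", path)
  out <- data.frame(chrom = df[[1L]], start = as.integer(df[[2L]]),
                    end = as.integer(df[[3L]]),
                    label = if (ncol(df) >= 4L) df[[4L]] else
                      paste0("iv", seq_len(nrow(df))))
  if (any(out$start < 0L | out$start >= out$end))
    stop("invalid BED intervals (need 0 <= start < end): ", path)
  out
}

#' @rdname read_bed
#' @param intervals data.frame with chrom, start, end and optionally label.
#' @export
write_bed <- function(intervals, path) {
  cols <- intersect(c("chrom", "start", "end", "label"), names(intervals))
  utils::write.table(intervals[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read / write a per-base conservation track (bedGraph)
#'
#' `chrom start end score` with 0-based half-open intervals of constant
#' score; bases not covered by any interval are gaps.
#'
#' @param path file path.
#' @return `read_track`: data.frame chrom, start, end, score.
#' @export
read_track <- function(path) {
  df <- utils::read.delim(path, sep = "\t", header = FALSE,
                          colClasses = "character")
  data.frame(chrom = df[[1L]], start = as.integer(df[[2L]]),
             end = as.integer(df[[3L]]), score = as.numeric(df[[4L]]))
}

#' @rdname read_track
#' @param track data.frame chrom, start, end, score.
#' @export
write_track <- function(track, path) {
  utils::write.table(track[, c("chrom", "start", "end", "score")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Read / write a per-species phenotype table
#'
#' TSV with columns `unit value` (species or strain name, trait value).
#'
#' @param path file path.
#' @return `read_trait`: named numeric vector of trait values.
#' @export
read_trait <- function(path) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          colClasses = c(unit = "character"))
  stats::setNames(as.numeric(df$value), df$unit)
}

#' @rdname read_trait
#' @param trait named numeric vector.
#' @export
write_trait <- function(trait, path) {
  utils::write.table(data.frame(unit = names(trait), value = unname(trait)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
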