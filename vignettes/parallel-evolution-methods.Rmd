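---
title: "Detecting parallel evolution at GWAS positions: models and methods"
author: "parevo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting parallel evolution at GWAS positions: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(parevo)
```

## The question and the model

Highly polygenic traits are controlled by thousands of small-effect
variants, most of them regulatory. If a nucleotide position tunes a trait
in humans, the same substitution at the orthologous position may have been
fixed independently in other lineages under selection toward a similar
phenotype — parallel evolution at single-base resolution. `parevo` tests
this hypothesis with a cross-species design:

1. **Allele matrix.** Species genomes are read at human GWAS SNP
   positions, each call classified against the two human alleles
   (`ref` / `alt` / `other` / `missing`). Within-species polymorphism is
   ignored: each call is treated as fixed in that species.
2. **Genomic score.** For a trait, each species gets the proportion of
   trait-increasing allele matches among all matches to either human
   allele, over the genome-wide significant positions (GWAS
   p < 5e-8). Effect sizes are deliberately discarded — only the sign of
   each allele's effect is assumed portable across species.
3. **Rank PGLS.** Score and phenotype are converted to average-tie ranks
   (a scale robust to outliers and to cross-species measurement error)
   and regressed by generalized least squares with the Brownian-motion
   covariance `V[i, j] =` shared root-to-MRCA path length. The
   directional hypothesis is a positive slope.
4. **Permulations.** Because both score and phenotype are phylogenetically
   structured, the parametric PGLS p-value is calibrated against a
   phylogeny-aware permutation null: simulate a Brownian trait on the
   tree, then reassign the *observed* values by rank-matching the
   simulated ones. Each permuted ranking is refit and the slope
   t-statistic collected; the reported p-value is the add-one empirical
   tail `(1 + #{t_null >= t_obs}) / (1 + n_perm)`.

Two follow-up analyses localize and dissect a detected signal: an
internal-branch enrichment test (did direction-concordant clade fixations
accumulate on branches with large inferred trait change?) and a
candidate-position cascade (which individual positions drive the
association, and do they look regulatory?). A strain-panel analysis
replays the scoring inside one species, where no phylogeny applies.

## Filter cascade

The raw matrix passes through the filters in a fixed order; each stage
emits an audit row (`positions_in`, `positions_out`):

* blacklist regions (BED, 0-based half-open) — positions with known
  alignment pathologies;
* autosomes only — sex chromosomes have asymmetric inheritance;
* masking: calls matching neither human allele are uninterpretable under
  human summary statistics and become `missing`;
* invariant positions — a perfectly conserved base cannot have evolved in
  parallel (this stage must follow masking, which the code asserts);
* monophyletic split — positions where all carriers of one allele form a
  single clade are parsimoniously one fixation event, not parallel
  evolution; they are set aside (with their defining node) for the
  branch analysis. A single species counts as a (singleton) clade, and
  missing species are excluded from both the carrier set and the clade's
  induced tip set;
* coverage — keep positions called in at least a fraction (e.g. 0.75
  across mammals, 0.85 across primates) of the species subset.

Coordinates are 1-based for SNP positions (VCF-like) and 0-based
half-open for every interval file (BED); a 1-based position `p` overlaps
`[start, end)` iff `start <= p - 1 < end`. This single rule is used by
the blacklist, cCRE, and every other interval query.

## Branch enrichment: why not raw residuals from a fitted line

Ancestral trait ranks are reconstructed at internal nodes by
maximum-likelihood Brownian estimation (`phytools::fastAnc`), and each
internal branch gets a trait change `delta` (child minus parent) plus
counts of clade-fixed substitutions whose GWAS sign matches (`matches`)
or opposes (`mismatches`) the sign of `delta`. Longer branches carry more
fixations of either kind, and also larger `|delta|`, so raw match counts
confound signal with branch length.

The obvious correction — residuals of matches regressed on mismatches —
turns out to be biased: both counts carry binomial sampling noise, so any
*fitted* line is attenuated (errors-in-variables), leaving a positive
branch-length loading in the residuals; branches with large `|delta|`
then drift into the positive-residual group even under the null. The
default here is therefore the fixed unit-slope line through the origin,
i.e. `residual = matches - mismatches`, whose sign is symmetric per
branch under the null regardless of branch length. Zero-residual branches
carry no directional information and are dropped from the group
comparison (assigning them to the negative group looks conservative but
is not: they are mostly short branches with small `|delta|`, and placing
them in the negative group inflates the one-sided test). The fitted-line
variants remain available (`method = "ols"`, `"major_axis"`) for
comparison with the classical procedure. The test itself is the one-sided
Wilcoxon rank-sum of `|delta|`, positive- versus negative-residual
branches.

## Candidate positions

Within the significant set, each position is tested by a two-sided
Wilcoxon rank-sum comparison of phenotype ranks between ref- and
alt-carriers. Positions with p below 0.05 (configurable; no multiple
-testing correction by default, mirroring raw-threshold practice, with
Benjamini-Hochberg available upstream via `p.adjust` if wanted) are split
into a **concordant** set — the allele whose carriers rank higher is the
GWAS trait-increasing allele — and a **discordant** set. The concordant
set is the candidate set; the discordant set is always emitted too, since
its size is the natural empirical yardstick for how many concordant
positions chance alone would produce.

Annotation steps are independent and commute: conserved-cCRE overlap;
mean conservation over the 21-base window centred on the variant
(position ± 10, gaps dropped from the mean with a warning); distance to
the nearest TSS; genes within ± 500 kb of the position's mapped
coordinate in every species, intersected across species (positions
unmapped in any species are reported with an empty gene set and a
`mappable = FALSE` flag, never silently dropped); cis-eQTL gene joins;
and motif disruption.

### Motif scoring

PWM counts are normalized to probabilities with a background-weighted
pseudocount; each column is weighted by its information content
(`2 + sum p log2 p`); a sequence's match score is the sum of one weighted
probability per column, min-max normalized to [0, 1]. Both strands and
every offset covering the variant base are scanned and the best score
kept per allele. An allele *hits* a motif when the exact tail probability
of its best score under the uniform-background null is below 1e-4; the
null distribution is computed exactly — full enumeration of the 4^L
per-column contribution sums for motifs up to 10 columns, a fine-grid
(1e-5) convolution beyond. The allele score difference classifies the
variant's effect (|delta| ≥ 0.7 strong, ≥ 0.4 weak, else neutral;
configurable). TFs hit in both genomic backgrounds (e.g. human and mouse
sequence contexts) are intersected to nominate conserved binding.

## Strain panel

Inbred panels descended from a multiparental cross have no meaningful
phylogeny, so the within-species validation uses ordinary least squares
on the score and phenotype ranks (reported with R²) plus a one-tailed
Spearman test toward positive correlation (t-approximation by default —
score ranks usually carry ties, which break the exact null; an exact
option exists). Panel phenotypes arrive as two sex-labelled replicates
and are averaged; panel positions must carry the same unordered allele
pair as the parent matrix (no strand complementing — adding it without
strand metadata would be guesswork).

## The synthetic-data generator

The generator emulates the statistical structure of the real inputs so
the whole pipeline is testable offline; it is first-class, tested code.

* **Tree**: pure-birth topology rescaled to an ultrametric depth of 100
  arbitrary time units, matching the character of time-calibrated trees.
* **Alleles**: a symmetric two-state process per position with per-branch
  flip probability `1 - exp(-flip_rate * length)`; the analysis only ever
  sees match/other/missing classes, so two states suffice. `other` calls
  and missingness are injected as separate corruption knobs after the
  phenotype is computed.
* **Phenotype**: a Brownian component plus `effect_size * direction` per
  causal alternate allele, additive on the raw scale before rank
  conversion (mirroring GWAS additivity; the rank transform downstream is
  part of what is under test). The Brownian component is drawn first from
  the seed, so `causal_fraction = 0` reproduces `simulate_bm` exactly.
* **GWAS**: causal positions get their true direction and p = 1e-9;
  non-causal positions get random signs and p = 0.5 by default (the
  pipeline only thresholds p-values). Null-calibration experiments set
  the non-causal p-value to 1e-9 as well, so the significant set is full
  size while the phenotype carries no genetic signal.
* **Defaults** (chosen once, on design grounds): 32 species, 300
  positions, 10% causal, effect 1, Brownian rate 0.2 (making the
  phylogenetic and causal components of comparable magnitude — the
  regime where permulation calibration actually matters), flip rate
  0.005 per unit time (a handful of substitutions per position across
  the tree), 5% missing, 2% `other`.
* **Clade-fixation generator** for the branch analysis: positions land on
  internal branches with probability proportional to branch length (the
  empirically observed pattern) and their GWAS signs match the branch's
  trait-change direction with probability `concordance` on the
  top-`top_fraction` branches by `|delta|`; `concordance = 0.5` is an
  exact null. Study conditions for the acceptance experiments: 48 tips,
  2000 positions, top fraction 0.4, concordance 0.9.
* **Strain panel**: strains draw alleles independently (fair coin) at a
  subset of matrix positions; phenotype = causal contribution + per-sex
  replicate noise (default sd 2, putting strain "heritability" near one
  half). **Annotations**: cCRE intervals cover a configurable fraction of
  causal (0.9) versus non-causal (0.1) positions, TSSs sit nearer causal
  positions, a subset of causal positions keeps a gene inside the synteny
  window in all species, conservation is elevated in ± 10 bp windows
  around cCRE positions, and two PWMs with known consensus sequences are
  emitted together with per-position ref/alt sequence windows in two
  genomic backgrounds.

What the generator does **not** model: linkage disequilibrium between
positions (positions are treated as independent, as the scoring method
itself assumes), sequence-level alignment artifacts, clade-structured
missingness (a uniform rate only — the real missingness structure across
clades is uncharacterized), ascertainment of GWAS hits, or realistic
genome geometry. Passing tests therefore demonstrate the statistical
machinery is correct and calibrated under these idealized conditions, not
that real alignments are free of confounders.

## Numerical choices and degenerate inputs

* PGLS is solved by Cholesky whitening; a singular covariance raises an
  error naming the cause. Permulation refits reuse the factorization and
  run as one vectorized least-squares pass over all permuted responses.
* Zero-length internal branches are padded by 1e-8 (with a warning)
  before ancestral reconstruction.
* `wilcox.test` handles all rank-sum tests: exact for small untied
  samples, normal approximation with continuity correction otherwise.
* Empirical p-values use the add-one estimator, so the minimum attainable
  value with 1000 permulations is 1/1001 and ties count against the
  observed statistic.
* Species with no called position (undefined score) or no phenotype are
  dropped pairwise per trait, with a message.
* Ranks are ascending for both variables; only consistency matters for
  the slope sign, which a symmetry test asserts.

## Problem sizes used by the test-suite experiments

Monte-Carlo checks run at desk scale, chosen as the smallest sizes at
which the asserted properties are stable: null calibration uses 1000
datasets of 32 species x 300 positions with 200 permulations each;
power and precision use 30 seeds per effect size at 64 species x 500
positions; branch-enrichment calibration uses 150 null and 20 planted
datasets at 48 tips x 2000 fixations. The acceptance script reruns the
same experiments at 100-200 null seeds.

## Known limitations

* The branch-enrichment default deviates from the classical
  fitted-residual procedure for the calibration reasons given above; use
  `method = "ols"` to reproduce the classical behavior.
* The per-position Wilcoxon tests are reported without multiplicity
  correction by design; their role is ranking candidates, not inference.
* Monophyly is assessed on the induced (non-missing) tip set; with heavy
  missingness a truly scattered pattern can look clade-like.
* The strain analysis assumes panel genotypes are exactly biallelic at
  shared positions and ignores kinship among strains.
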