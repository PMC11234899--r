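---
title: "Inferring oligotrophic and copiotrophic soil bacteria: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring oligotrophic and copiotrophic soil bacteria: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oligotraits)
```

## The inference problem

Oligotrophic soil bacteria — taxa adapted to chronically low organic
carbon availability — are operationally defined here by contrast:
within a paired design (carbon-limited vs carbon-rich soils from the
same system), the taxa significantly enriched on the carbon-limited
side are treated as putative oligotrophs and those enriched on the
carbon-rich side as putative copiotrophs. The package chains five
stages: per-dataset filtering, per-ASV differential relative
abundance, ASV-to-reference-genome matching, genomic trait contrasts,
and functional (COG) contrasts with a cross-dataset consistency
screen. Each stage is an exported function; `run_pipeline()` composes
them and `demo_run_config()` packages a three-contrast synthetic
demonstration.

The central statistical assumptions are deliberately minimal:

* Counts are compositional; only relative abundances within a sample
  carry signal, and the per-sample denominator is the post-filtering
  total.
* Group comparisons use the two-sided Mann–Whitney test — a rank test
  that needs no distributional model for relative abundances — with
  Bonferroni control of the family-wise error rate.
* Genome-level inference assumes the reference catalogue is informative
  for the classified ASVs at ≥97% 16S identity; everything downstream
  conditions on that mapping.

## Filtering policies

`filter_policy()` captures the per-dataset thresholds; three presets
ship with the package:

| preset | sample floor (reads) | ASV floor (reads) | prevalence floor | prevalence unit |
|---|---|---|---|---|
| `soil_profile` | 10 000 | 50 | 5 | profile |
| `rhizosphere` | 1 000 | 50 | 5 | sample |
| `microcosm` | 0 | 50 | 3 | sample |

Boundary conventions are fixed and tested: samples are *retained* iff
total reads are strictly greater than the floor; ASVs are *removed*
iff totals or prevalence are strictly below theirs (an ASV with
exactly 50 reads, or seen in exactly 5 profiles, survives). Removal
order is taxonomy exclusions → unassigned phylum → low total reads →
low prevalence, and the per-step removal counts are reported so a
run's bookkeeping can be audited line by line. Taxonomy assignments
with classifier confidence below 0.5 are treated as unassigned at all
ranks, mirroring the common 50% bootstrap convention of naive-Bayes
16S classifiers.

## Classification

Per ASV the test statistic is the Mann–Whitney U computed from
midranks. The p-value is exact (from the null distribution of U) when
both groups have fewer than 50 observations and the pooled values are
tie-free, and otherwise uses the tie-corrected normal approximation
with continuity correction — the same switching rule R's
`wilcox.test()` applies, which keeps results interpretable against the
field's default tooling. A dedicated test compares the implementation
against exhaustive enumeration of all group assignments up to 8 vs 8.

Two genuinely open choices were resolved as follows:

* **Bonferroni family size** is the number of ASVs tested within one
  dataset after filtering. Datasets are analysed independently
  throughout, so the dataset is the natural inferential unit; families
  never pool across datasets.
* **Group sizes are data-driven.** Nothing in the package hard-codes
  how many carbon-limited vs carbon-rich samples a dataset has; labels
  come from the metadata.

A consequence worth stating explicitly: with very small designs the
Bonferroni bound can be unattainable. At 5 vs 4 samples the smallest
two-sided exact p is 2/C(9,4) ≈ 0.016, so no ASV can clear a
several-hundred-fold correction. The packaged microcosm-style demo
therefore uses 15 samples per group — the smallest size at which the
full chain (classification → matching → genome contrasts) remains
estimable — rather than a literal 5 vs 4 microcosm design.

## Genome matching

The matcher re-creates reference-based amplicon matching semantics at
desk scale: global alignment of the (shorter) query within the
reference, both strands, identity defined as matching columns over
alignment columns with internal gaps counted and terminal gaps on the
longer sequence free; `N` never counts as a match. Alignment uses
match +1 / mismatch −1 with small gap penalties (opening 2, extension
1), which maximises matching columns for near-identical sequences —
the only regime that matters above a 0.97 identity threshold. All
references are scanned exhaustively; no acceptance/rejection
heuristics or k-mer prefilters are reproduced, which at synthetic
scale is strictly more sensitive. A genome with multiple 16S copies is
represented by its best-scoring copy. Exact identity ties break by
higher completeness, then lower contamination, then accession order,
making `match_asvs()` deterministic and independent of catalogue
ordering. Genomes matched by both life-history groups are removed from
both before any genomic comparison.

## The codon-usage growth proxy

Maximum potential growth rate correlates with codon-usage bias in
highly expressed genes (HEGs, canonically ribosomal proteins). The
package quantifies bias with Wright's effective number of codons:
per amino-acid family, homozygosity `F = (n·Σp² − 1)/(n − 1)`;
degeneracy-class means over families with at least two codons
observed; `Nc = 2 + 9/F̄₂ + 1/F̄₃ + 5/F̄₄ + 3/F̄₆`. Conventions, all
tested:

* Six-fold amino acids (Leu, Ser, Arg) are single families (Wright's
  original treatment), giving 9/1/5/3 families of degeneracy 2/3/4/6
  over 59 codons.
* A degeneracy class with no usable family falls back to its neutral
  value `F̄ = 1/k`, keeping Nc defined on short inputs; non-positive
  family F values (possible at tiny counts) are excluded as undefined.
* Nc is clamped to its theoretical range [20, 61] to absorb sampling
  noise.
* Because F carries a finite-sample bias correction in `n`, Nc is
  scale-invariant only asymptotically; the test suite checks exact
  permutation invariance and monotone decrease along a bias path, and
  scale invariance at large counts.

The growth proxy is `ΔENC = (Nc_background − Nc_HEG)/Nc_background`:
zero when HEGs look like the background, approaching (61−20)/61 ≈ 0.67
when HEGs collapse onto single preferred codons against an unbiased
background. No absolute doubling-time calibration is attempted — only
the ordering of ΔENC between groups is interpreted. HEG membership
comes from the input annotation (`heg=` flags or an explicit id list);
ribosomal-protein detection is out of scope.

## Functional profiles

COG abundances are genome-size-normalised (`copies per Mbp`), category
proportions divide per-category gene counts by the *total* COG-assigned
gene count — a COG in several categories counts in each, so
proportions may exceed 1 in sum — and hypothesis scores sum member-COG
normalised abundances, with category members expanding to their COG
sets. Three separate Bonferroni families are used: the 25 category
proportions, the hypothesis battery, and the full per-COG screen; the
three answer different questions and pooling them would trade power
across unlike hypotheses.

The shipped hypothesis map (`inst/extdata/hypothesis_map.tsv`) encodes
the classic oligotroph trait expectations (more amino-acid/lipid
transport, storage-polymer synthesis, CO and H₂ oxidation, stress
sigma factors; less motility, defense, transcription, signal
transduction, replication machinery, thiamine biosynthesis). The
individual-gene rows carry representative COG identifiers as an
editable starting point, not a curated annotation; users with a real
annotation should supply their own map via
`default_hypothesis_map(path = ...)`.

The consistency screen labels a COG oligotroph- (or copiotroph-)
consistent only when it is Bonferroni-significant with that direction
in *every* dataset — per-dataset significance being the literal
reading of "consistently more abundant across all datasets" — and the
three summary counts partition the COG universe by construction.

## What the synthetic data do and do not emulate

`simulate_counts()` draws a shared lognormal community profile,
applies planted multiplicative effects to the Dirichlet weights of one
group, then samples per-sample compositions from a Dirichlet with
total concentration `base_concentration` (default 500 — moderate
community-level overdispersion of the kind soil 16S data show) and
counts from a multinomial at a negative-binomial library size
(default mean 30 000, dispersion 5, so a realistic minority of samples
falls below the 10 000-read floor and the sample filter has work to
do). Nuisance ASVs carry organelle/eukaryote labels or a missing
phylum at configurable fractions. `simulate_genomes()` plants the
trait contrasts the analysis is designed to detect — smaller genomes,
more MAGs, fewer rRNA operons, weaker HEG codon bias, and a small set
of enriched COGs on the oligotroph side — and emits 800-nt synthetic
16S references from which 250-nt V4-style ASV fragments are cut with
0–2 substitutions (both strands).

What this validates: the statistical machinery (error control,
sensitivity, direction calls), the bookkeeping contracts, and the
determinism of the full chain. What it cannot show: robustness to
phylogenetically structured sequence similarity (synthetic 16S are
mutually random, so matching is easier than against a real reference
database), to taxonomic misannotation, to compositional effects of a
few dominant taxa, or to the ecological validity of the
carbon-contrast design itself.

## Problem sizes and numerical details

The packaged demonstration runs three datasets of 250–300 ASVs with
15–30 samples per group against a 40-genome catalogue with 60 CDS per
genome — sizes chosen so a complete run, including the acceptance
script, finishes in well under a minute while every stage still has
non-trivial work. The test suite additionally runs 200 null
simulations (20 samples/group, 500 ASVs) for the family-wise error
check and 50 seeded simulations (40 samples/group, planted log
fold-change 2) for the sensitivity check.

Numerical conventions not already covered: relative-abundance columns
are checked to sum to 1 within 1e-12; completely tied Mann–Whitney
inputs return p = 1 (zero variance guard); Bonferroni p-values cap at
1; the classifier's direction is the sign of the carbon-rich minus
carbon-limited mean; and every generator is deterministic under its
seed, with `run_pipeline()` deriving independent per-stage seeds from
the run seed.

## Known limitations

* ΔENC is a proxy ordering, not a doubling-time estimate; no
  GC-correction (Nc′) is applied, so strong compositional bias could
  masquerade as translational selection in real genomes.
* The matcher's exhaustive scan is quadratic in practice and meant for
  catalogue sizes in the hundreds, not for a full reference database.
* The per-COG screen uses normalised abundances by default; a
  presence/absence variant is available
  (`compare_profiles(..., presence_absence = TRUE)`) but no fidelity
  claim is made for either choice with respect to annotation
  pipelines.
* Archaea receive no special handling; taxonomy filters only remove
  organelle and eukaryote signal and unassigned phyla.
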