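---
title: "Methods and design choices in landqtl"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design choices in landqtl}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`landqtl` turns a genotyped, multi-season-phenotyped panel of inbred
landraces into marker–trait associations (MTAs), LD-based MTA-QTL
intervals, high-density multi-trait regions screened for days-to-heading
(DH) confounding, and expression-filtered candidate genes. This vignette
explains the statistical model behind each stage, the tunable parameters
and their defaults, what the synthetic-data generator does and does not
emulate, and the numerical conventions that a reader of the outputs should
know about.

## Genotype coding and the panel container

The package targets selfing crops genotyped with biallelic
reduced-representation markers. Accessions are treated as fully inbred, so
a marker call is 0, 1 or missing — there is no heterozygote class. Readers
of VCF or HapMap-style TSV map `0/0` to 0, `1/1` to 1 and `./.` to
missing; heterozygous calls are set missing with one warning per site
(configurable to a hard reject). Internally all coordinates are 1-based
inclusive; BED output converts to 0-based half-open at exactly one place,
the writer. Markers without a genomic position are kept on a
pseudo-chromosome `U`, spaced 1 Mb apart in file order, so they can still
be scanned; because that spacing is synthetic, their LD blocks are
effectively single-marker unless r² links immediate neighbours.

## Marker quality control

Three filters run in a fixed order: duplicate allelic profiles (identical
call vectors including the missing pattern; the first marker in map order
is kept), missing fraction strictly above 10 %, and minor allele frequency
strictly below 0.05 computed on non-missing calls. Boundary markers (10 %
missing exactly, MAF exactly 0.05) are retained. The order only affects
which filter a doubly-bad marker is attributed to; the retained set is
order-invariant, and a test verifies this on random panels.

## Linkage disequilibrium

For every same-chromosome pair with at least `min_overlap = 20` jointly
non-missing accessions, r² is the squared Pearson correlation of the 0/1
call vectors. For inbred haploid coding this equals the classical
D²/(p_A q_A p_B q_B). Significance uses the large-sample approximation
n·r² ~ χ²₁; the reported per-chromosome summaries count pairs significant
at p < 0.001. Pairs under the overlap floor are emitted with r²
undefined and excluded from summaries.

The decay curve is a LOESS fit (degree 1, default span 0.5) of r² on
physical distance over all valid pairs, subsampled to at most 200,000
pairs under a fixed seed. "Half decay" is operationalised as half of the
fitted value at the minimum observed distance; the half-decay distance is
the first grid crossing below that level, by linear interpolation on a
512-point grid, and is undefined (NA) when the fitted curve never
crosses — e.g. flat LD. Two numerical caveats are deliberate: fitted
values are clamped to [0, 1], and the benchmark against a known
exponential (`decay_benchmark`) uses a tighter span of 0.2, because a
locally-linear smoother with a wide window systematically flattens the
short-range end of a strongly curved decay and biases the crossing point
(we measured ~8 % relative error at span 0.2 versus ~16 % at span 0.3 and
~27 % at span 0.4 on 0.4·exp(−d/1 Mb) data).

## Effective number of tests and the Bonferroni threshold

Markers that carry identical information should not each count as a test.
Within each chromosome, markers are grouped by the transitive closure of
pairwise r² = 1 (tolerance 1 − 10⁻⁹ to absorb floating-point noise; r²
computed on pairwise-complete accessions, so classes beyond exact
duplicates can arise through missing-pattern differences). The effective
number of tests N_eff is the total class count; the genome-wide threshold
is α/N_eff with α = 0.05 by default, shared across all trait–environment
scans. Dividing only by the marker-based N_eff (not additionally by the
number of traits) is liberal family-wise but is the convention this
analysis follows; the per-trait family-wise error is what the calibration
suite checks.

## Phenotype preparation

Normality is checked per trait with Shapiro–Wilk within each season and
the p-values combined as their minimum — conservative toward
transforming, since any one clearly non-normal season triggers the
transform path. If the combined p < 0.01, all raw values are positive,
and the log-transformed values pass at 0.01, the trait is replaced by its
natural log and flagged; otherwise the reason (raw passes / non-positive
values / log does not restore) is recorded. Season and subpopulation
effects use Kruskal–Wallis with pairwise Wilcoxon post-hoc tests under
Holm adjustment (the adjustment is our choice; the underlying tests are
standard for non-normal agronomic traits), and homoscedasticity is
checked with Levene's test on season groups.

Between-season Spearman correlations decide the scanning mode per trait:
if every pairwise season correlation strictly exceeds 0.5 the trait gets
one BLUE per accession, otherwise it is scanned season by season. The
BLUE comes from the fixed-effects model `value ~ accession + season` by
ordinary least squares with sum-to-zero season contrasts, i.e. the
accession estimate at the average season; in balanced data this equals
the accession mean plus a constant. A mixed model with random blocks or
spatial terms would be preferable when the field design is known, but the
package models only what its inputs carry — accession, season, value —
and documents this as a simplification. Trait-by-trait correlations are
computed on per-accession means across seasons.

## Association scan

Each marker is tested by ordinary least squares of the phenotype on an
intercept, the structure covariates Q, and the marker coding, over the
accessions with non-missing genotype and phenotype (listwise deletion;
`min_n = 30` guards against tiny subsets). One Q column is dropped
automatically when collinear with the intercept (one-hot membership). The
marker p-value is the partial F-test with one numerator degree of
freedom; the allele effect is the marker coefficient; PVE is the
incremental R² of the full model over the covariates-only model fitted on
the same accessions. Markers monomorphic on the tested subset are skipped
with a reason rather than reported at p = 1. A perfect fit reports the
smallest positive double rather than zero.

## From MTAs to MTA-QTLs, stable QTLs and regions

The LD block around a significant seed marker is walked outward in map
order, upstream and downstream separately: a neighbour is included while
its r² **with the seed** (not chained neighbour-to-neighbour) is strictly
greater than 0.3; the first neighbour at or below 0.3 — or with
undefined r² — terminates the walk and is excluded. Blocks therefore need
not decay monotonically: a dip to 0.35 followed by 0.4 keeps walking.
MTAs whose blocks share at least one base pair merge transitively into
MTA-QTLs; adjacency without a shared bp does not merge. Serial ids
(`<chrom>.<serial>`, regions `R<chrom>.<serial>`) follow positional
order. For trait counting, season suffixes collapse: TKW detected in
three seasons is one base trait, annotated with one star per environment
in report tables. A QTL associated with the same trait in two or more
environments is flagged stable (threshold configurable).

High-density regions are maximal sets of transitively overlapping
MTA-QTLs whose union of base traits has at least four members. Four is
the adopted reading of an ambiguous source convention ("more than 4"
versus "at least four"); tables of published regions list exactly four
traits, so ≥ 4 is used and the parameter is exposed as `min_traits`.

The DH re-test asks whether a region's associations are real or merely
ride on phenology: for every member MTA whose trait is not DH or DM, the
model `y = intercept + ω·DH + M·marker` is fitted and the MTA is retained
when the marker term stays significant at a nominal 0.05 (nominal because
the re-test is confirmatory on pre-selected associations; a Bonferroni
mode is a parameter away). The DH covariate is the DH BLUE — DH
correlates strongly across seasons, so a single adjusted value per
accession is its natural summary — and the same covariate is used against
per-season traits. Phenology associations themselves (DH, DM) are
excluded from the retained set, so a region that owed its trait count to
DH loses it. Regions are then recomputed from the retained MTAs' blocks:
`dropped` below `min_traits`, `shrunk` if the interval contracted,
`retained` otherwise; the re-test can never enlarge a region or add
traits. Regions with DH missing for more than half the accessions are
left `untested`.

## Candidate genes

Gene models come from GFF3 (`gene` features only, 1-based inclusive);
overlap queries use GenomicRanges. A gene belongs to a region when the
intervals share at least one bp. The closest gene to a region's most
significant marker (smallest raw p, then largest |effect|, then smallest
position) is reported with its interval distance, 0 when the marker lies
inside; ties break by smaller gene start, then lexicographic id. The
expression filter keeps a gene when its **maximum** TPM over the
configured target tissues is ≥ 0.5 — the any-tissue reading of an
ambiguous "did not reach 0.5 TPM in target stages and tissues" rule; the
all-tissue reading would be far stricter and is not what expression
atlases of developmental time courses support. Genes absent from the
expression matrix are dropped and counted separately rather than treated
as silent.

## The synthetic-data generator

The generator exists so that every stage above can be tested against a
known truth. It emulates, at desk scale, the statistical structure of a
landrace panel:

* **Structure** — accessions split evenly into `n_subpops` hard clusters
  (default 4). Per marker, an ancestral frequency p₀ ~ Uniform(0.1, 0.9)
  and Balding–Nichols subpopulation frequencies
  Beta(p₀(1−F)/F, (1−p₀)(1−F)/F) at FST = F (default 0.2). A
  Hudson-estimator check recovers F within ±0.05 at 400 accessions and
  500 markers.
* **LD** — along each chromosome an accession copies its previous
  marker's allele with probability `ld_rho` (default 0.5), else draws
  from its subpopulation frequency: a first-order Markov chain, the
  simplest mechanism giving monotone distance decay. `ld_rho = 1` is
  rejected as degenerate. Marker positions are sorted uniform draws over
  desk-scale chromosomes (default 4 × 50 Mb; realistic wheat chromosome
  sizes are a non-goal).
* **Phenotypes** — for trait t, season s, accession i:
  y = μ + m_s + Σ β_k x_ik + u_pop + g_i δ_s + γ DH_i + ε, with season
  offsets m_s ~ N(0, season_effect_sd²), planted marker effects β in
  phenotype-SD units on the 0/1 coding, a subpopulation effect
  (SD 0.25), a latent polygenic g_i whose variance tops up total genetic
  variance to the configured broad-sense h², season loadings
  δ_s = 1 + N(0, gxe_sd) normalised to unit mean square (so G×E
  decorrelates seasons without inflating variance), and residual variance
  1 − h². DH is generated first; a configured γ feeds its standardised
  accession value into a target trait, creating the confounding path the
  DH re-test must detect. With gxe_sd = 0 and h² = 0.9 the between-season
  correlation is 0.9 by the repeatability formula, which simulation
  confirms.
* **Annotation** — non-overlapping gene intervals at a Poisson density
  per Mb, and a TPM matrix from an expressed/silent mixture in which
  expressed genes exceed 0.5 TPM in at least one target tissue; truth
  labels make the expression filter exactly checkable.

All randomness flows through one seeded generator per call: identical
configs give byte-identical outputs. What the generator does **not**
emulate: coalescent genealogies, allele-frequency spectra of real
genotyping platforms, linked selection, admixed (non-hard) structure,
spatial field trends, and trait distributions needing transformation
beyond the log. Passing recovery tests therefore demonstrate the
pipeline's correctness and calibration under its own modelling
assumptions, not performance on any particular real panel.

### Preset conditions and problem sizes

`synth_config_paper_like()` fixes the study conditions used throughout
the examples: 200 accessions, 4 subpopulations at FST 0.2, 1,000 markers,
3 seasons, grain traits with season correlations above 0.5 (scanned on
BLUEs), a kernel-weight trait with strong G×E (h² 0.45, gxe_sd 2.5;
scanned per season), a DH → kernel-weight confounding path (γ = 0.4), and
six planted loci. `synth_config_recovery()` is the same design with
effects sized so the expected per-cell PVE lies in 0.10–0.15, the band
the recovery suite targets. The validation suites use 50 replicates for
recovery, 2,000 null markers for type-I calibration, 200 paired
replicates for the DH re-test, and 5,000 synthetic pairs for decay
recovery — sizes at which the binomial error of the reported rates is
small relative to the margins they are compared against.

## Known limitations

* The BLUE model ignores field-design terms (blocks, checks, spatial
  trends) that a richer input format could support.
* The χ² approximation for r² significance is anti-conservative for very
  small joint sample sizes; the `min_overlap` floor bounds the damage.
* The half-decay definition is one of several in use; it is exposed as a
  fitted-curve property rather than a model parameter, and comparisons
  across datasets should hold the span fixed.
* The DH re-test conditions on a single covariate; genuinely pleiotropic
  loci with direct and DH-mediated effects will be attenuated, not
  cleanly separated.
* One shared Bonferroni threshold across trait–environment scans controls
  the per-scan, not the experiment-wise, error rate.
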