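---
title: "Methods and design of the speltpop pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design of the speltpop pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette explains the models and procedures behind each stage of the
pipeline, the parameters that matter and their defaults, what the
synthetic-data generator does and does not emulate, and the numerical and
design choices made where more than one convention was defensible.

## Genotype data model and filters

Genotypes are diploid alt-allele counts (0/1/2, `NA` for missing) over
biallelic SNPs. Coordinates are 1-based inclusive throughout (the VCF and
GFF convention); no half-open representation is used internally, avoiding
double conversions. Heterozygote phase is ignored (`0/1` and `1/0` are the
same state): genotyping-by-sequencing data are unphased. The chromosome →
subgenome rule takes the trailing alphabetic character of the chromosome
name among {A, B, D}; every other name maps to "unanchored". The mapping
is total by construction.

Filters read the "more than 20% discarded" convention literally: a site or
accession with missing fraction *strictly greater* than the threshold is
removed, so a missing rate of exactly 20% is retained. Minor allele
frequency is computed over non-missing *alleles* (not samples), and the
MAF filter exposes both strict (`gt`, used for the 0.05 association
filter) and inclusive (`ge`, used in 1%/5% summary tables) comparators,
because both conventions appear in diversity-panel reporting. Singletons
are sites whose minor allele is observed exactly once — one heterozygote;
a single homozygote carrier counts two alleles and stays. Site classes
follow the precedence exonic > intronic > proximal > intergenic, with
"intronic" meaning inside a gene's CDS envelope but outside CDS intervals
(toy annotations have no UTR concept) and "proximal" meaning within 2 kb
of the envelope. Distance thinning is a greedy ascending scan per
chromosome keeping a site iff it lies at least 20 kb beyond the last kept
site; greedy ascending order is the deterministic common convention for
this step.

## Population structure

PCA mean-imputes missing codes per site, mean-centers columns, and
eigen-decomposes the sample covariance matrix; variance explained is
eigenvalue over total variance. Columns are *not* scaled to unit variance —
the simplest convention, and the qualitative contrast the pipeline
reports (lower variance explained on the D subgenome than A and B)
survives either choice. Component signs are fixed by making the
largest-magnitude loading positive, so results are invariant to sample
and site order.

The stratification covariates for the GWAS come from classical metric MDS
on the distance `1 − IBS`, where IBS between two samples is the mean over
sites non-missing in both of `(2 − |g_i − g_j|)/2`. This mirrors the
common association-toolkit construction; since more than one MDS distance
is in circulation, the choice is declared here. Coordinates
are the top-2 eigenvectors of the double-centered squared-distance matrix
scaled by the square roots of their eigenvalues, hence centered per axis.

## Folded joint site-frequency spectra

Because the ancestral allele is unknown, spectra are folded; because
samples have missing calls, each population's counts at a site are
projected down to a fixed haploid target by hypergeometric sampling
without replacement, so partially observed sites contribute fractional
mass rather than being dropped. Sites observed below the target in either
population are dropped for that pair. The pairwise grid is the outer
product of the two projection vectors accumulated over sites; folding
reflects mass at `(i, j)` with `i + j > (n_a + n_b)/2` onto
`(n_a − i, n_b − j)`. Mass exactly on the fold line stays in the cell with
the smaller first index (ties: smaller second index) — conventions differ
across tools, so this one is fixed and tested. The monomorphic corners are
zeroed after folding and the removed mass recorded; cells that cannot
carry mass after folding (beyond the line, the reflected half of the line,
and the corners) are masked, so observed and model spectra agree
cell-for-cell on which entries are structural zeros.

## Coalescent simulator and demographic models

The simulator is a backwards-in-time Kingman coalescent over three demes:
within a deme of diploid size `N`, each lineage pair coalesces at rate
`1/(2N)` per generation; a split event moves all lineages of the derived
deme into its source; one optional admixture pulse moves each sink lineage
with probability `m`. An unsampled "ghost" ancestor is represented by
re-labelling an emptied deme slot with the ghost size. For expected
spectra the engine accumulates, for each genealogy, the branch length
subtending every joint descendant configuration; under infinite sites the
expected unfolded SFS is proportional to this branch profile, which has
much lower Monte-Carlo variance than throwing mutations. A lineage's
configuration is fixed over its lifetime, so its whole contribution is
accrued at coalescence — this makes the engine O(events) per genealogy and
fast enough to sit inside an optimizer.

When genotypes (not expectations) are needed, one segregating site is
drawn per genealogy. Genealogies are *resampled proportional to their
total branch length* before mutation placement: a genealogy's mutation
count is proportional to its length, so the site-frequency distribution
is `E[l_i]/E[T]`, not `E[l_i/T]` — sampling one mutation per unweighted
genealogy visibly inflates singletons (the error is >10 standard errors
at n = 10 with 50,000 genealogies, which is how the test suite would
catch a regression).

The six models cross three scenarios — single introduction (Iberia splits
from Central Europe, which earlier split from the ancestor), independent
origins (both European pools split independently from the ancestor), and
a hybrid with one recent Asia→Iberia pulse — with the ancestor being
either the sampled Asian pool or a ghost. Sizes (`N_asia`, `N_ce`,
`N_ib`, diploids) are always free; ghost variants add the ghost size and
the time at which Asia itself joins the ghost. Under this
parameterisation the two non-hybrid scenarios happen to have equal
free-parameter counts (5; hybrid 7; ghost +2), since ancestral sizes are
tied to the continuing lineage rather than estimated separately.
The default mutation rate is 1.3 × 10⁻⁸ per site per generation; times
are reported in generations with no year conversion.

## Composite likelihood, optimization, model selection

The objective is a multinomial composite log-likelihood over the unmasked
cells of the three pairwise folded spectra (summed pairwise 2D, not one
joint 3D spectrum — with three populations the pairwise decomposition
keeps cells well-populated at these sample sizes), plus an optional
Poisson term on the total observed segregating mass with expectation
`μ · n_loci · Σ(expected unmasked branch mass)`. The anchor matters: a
pure multinomial is invariant to rescaling all sizes and times by a
common factor, leaving absolute scale unidentified. Both sides of the
anchor are defined on the same projected sample configuration, so dropped
sites and corner-removed mass affect observation and expectation
identically. Expected cells with zero simulated mass are floored at
`ε = 1/(10 · n_genealogies)` and renormalized, preventing −∞ objectives.

In place of an ECM-style optimizer the fit uses multi-start
bounded direct search: each run draws a start uniformly in the (log-
scaled) box, optionally after a cheap screening pass that scores a few
dozen uniform draws and keeps the best as starts, then runs Nelder–Mead
on the internal scale with out-of-box and topology-violating proposals
penalized. Each run fixes one simulation seed (common random numbers), so
its objective is deterministic and the optimizer chases structure rather
than noise. Sizes and times are searched on the log scale over
[50, 50 000] diploids and [50, 20 000] generations; the pulse proportion
linearly on (0.01, 0.9). AIC = 2k − 2·loglik ranks models, ties broken by
fewer parameters then model id. Percentile bootstrap CIs use inverse-ECDF
quantiles, so with two replicates the interval is exactly their range;
replicate refits that fail are excluded with a warning and more than 20%
failures is an error.

Scaled problem sizes used by the tests and the acceptance script — 24/40/24
haploid samples projected to 18/30/18, ~1000 segregating sites, 5 (or 3)
runs × 5000 genealogies per objective evaluation, 10 replicates — are the
package's own desk-scale study conditions; full-scale settings
(20 runs, 100 000 simulations per evaluation, 100 bootstraps) remain
plain function arguments.

## GWAS

The scan fits, per SNP passing the MAF filter, a maximum-likelihood
logistic regression of red/white on the additive genotype code plus two
MDS covariates, on the samples non-missing at that site (no imputation in
the scan). Convergence is IRLS with log-likelihood tolerance 1e-8 within
25 iterations, and the reported test is the Wald test of the genotype
coefficient — the common association-tool default. A fully penetrant
dominant locus, however, separates cases from controls perfectly; the ML
estimate diverges and the Wald statistic collapses (Hauck–Donner), which
is precisely the regime the glume-color locus occupies. Separated or
non-converged fits are therefore flagged and fall back to the
likelihood-ratio test of the genotype term, mirroring the fallback
strategy modern association tools use for the same reason; each result
row records which test produced its p. Significance is `p < α` with
α = 1e-5. Significant sites are grouped per chromosome into maximal runs
with consecutive gaps under 5 Mb; the gap rule is this pipeline's own
convention for delimiting a peak's physical confidence interval. The QQ diagnostic reports λ as the median observed χ²
divided by the null median 0.4549.

## Haplotype classification, trees, in-silico PCR

CDS identity is global Needleman–Wunsch (match +2, mismatch −1, gap open
−5, gap extend −1; the scoring is fixed and documented because identity
values depend on it), with identity = identical columns /
alignment columns. Membership in the candidate-allele set requires
identity to the reference strictly above 93%. Structural features are
detected by aligning each intron against an insertion-free baseline (the
reference with its annotated insertions excised — the reference itself
carries the group-1 MULE): insertions ≥50 bp are reported and classed
large (≥1 kb, MULE-like) or small (<1 kb, SINE-like) — a size convention
of this pipeline; real TE calls would come from element annotation —
and deletions ≥20 bp are reported to capture the 47-bp intron-1 InDel
that defines group 3 (G3 also requires the deletion in the 40–60 bp
window). G1/G2 split on an intact ORF vs a premature stop; G4 is the
no-insertion, no-deletion residual; conflicting insertion classes leave
an allele unassigned with a reason.

Neighbor joining runs on `100 − identity` distances; bootstrap support
resamples CDS alignment columns (the fixture CDS are equal-length and
substitution-only, so column resampling needs no realignment) and counts
the fraction of replicate trees containing each internal bipartition. NJ
is exact on additive matrices, which the tests exploit: up to 7 taxa the
oracle is a brute-force least-squares topology search over all unrooted
topologies; at 8 taxa (10 395 topologies) the generating tree itself is
the oracle, being the unique zero-error additive fit. In-silico PCR is
exact string matching of the forward primer and the reverse complement of
the reverse primer within 5 kb; amplicon lengths include both primer
sites.

## Relative expression

ΔCt = Ct_target − Ct_reference per sample and biological replicate;
ΔΔCt subtracts the calibrator group's mean ΔCt per gene; fold change is
2^−ΔΔCt. Group summaries average on the ΔΔCt (log2) scale and report
2^−mean with the standard error on the log2 scale, so the calibrator's
own summary fold change is exactly 1 and a constant shift of one sample's
Ct values cancels identically. Biological replicates are the unit of
error; no hypothesis test is attached; group means with standard errors over
biological replicates are the reported quantity. Technical replicates, if present as duplicate
rows, are rejected at construction rather than silently averaged.

## The synthetic-data generator

The generator emulates: three diverged gene pools with the package's own
coalescent (one genealogy engine, used by simulation and inference alike,
so it is doubly tested — its closed-form behavior in tests, and its
round-trip consistency through parameter recovery); rare-variant-heavy
site-frequency spectra (a property of the neutral coalescent, matching
the predominance of low-MAF variants in GBS panels); ~15% missing calls
(missing completely at random — the real missingness mechanism is
unknown, and MCAR keeps the projection arithmetic unbiased); positions
≥20 kb apart on chromosomes 1A–7D so thinning and subgenome operations
are exercised; a dominant glume-color locus with configurable penetrance
(default 1.0) and phenocopy rate (default 0.0 — the real penetrance is
unknown; these are fixture choices, not inferences). The default truth
model is independent origins with sizes 2000/1500/800 diploids and split
times 1023 and 1218 generations, adopted once as the emulated truth for
a late-Holocene crop divergence. The GWAS
calibration cohort uses 40 diploids per pool with stratified prevalences
0.7/0.4/0.15, chosen once as a moderate-stratification regime: strong
enough that the unadjusted scan inflates severely, mild enough that the
adjusted scan's asymptotics hold at this sample size.

It does **not** emulate: linkage disequilibrium within loci (sites are
unlinked by construction, so LD-pruning behavior is untested),
sequencing-error or genotype-likelihood models, informative missingness,
admixed individuals or passport errors, or selection. Passing tests
therefore demonstrate correctness of the estimators under the stated
model, not robustness to those real-data complications.

## Known limitations

- Composite-likelihood AICs ignore linkage-induced dependence; with truly
  linked data the likelihood differences would be overstated.
- The Poisson scale anchor presumes the mutational-target count
  (`n_loci`) is known; for real GBS data it must be estimated from the
  assay footprint, and scale estimates inherit its error.
- Ghost-ancestor variants are structurally near-degenerate with their
  Asian-ancestor counterparts at desk-scale sample sizes; scenario
  recovery is assessed among the three Asian-ancestor models.
- The Wald→LRT fallback changes the test statistic exactly at separated
  sites; mixed-statistic scans are standard practice but p-values at
  those sites are not comparable to Wald p-values at the same α in small
  samples.
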