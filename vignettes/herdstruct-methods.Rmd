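---
title: "Models and methods behind herdstruct"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind herdstruct}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`herdstruct` analyses the fine-scale structure of closed livestock
populations from dense autosomal SNP genotypes.  This vignette explains
the statistical machinery stage by stage: the models and their
assumptions, the tunable parameters and their defaults, the numerical
choices, what the synthetic-data generator does and does not emulate,
and the known limitations.

## Genotype data and filtering

The central container (`geno_dataset`) holds individuals with
population labels, a marker map sorted by chromosome and 1-based
inclusive bp position (strictly increasing within a chromosome), and an
n × m matrix of B-allele dosages {0, 1, 2, NA}.  PLINK text
`.ped`/`.map` and VCF 4.x are read and written; in PLINK text the
B allele is defined as the lexicographically larger observed allele so
that write–read round-trips preserve the dosage matrix.  Markers with
position 0 or chromosome "0" are excluded on read, mirroring the usual
treatment of probes without a confirmed genomic placement.

`maf_filter()` computes the minor allele frequency over non-missing
calls across the pooled sample and removes markers *strictly below*
the threshold (default 0.05): a marker at exactly 0.05 is retained,
because the exclusion rule is "less than".  Frequencies are always
computed on observed calls; imputation is out of scope.  Whether MAF
should be pooled or per breed is a genuine choice — pooled is used, as
the filtered panel feeds cross-breed clustering and admixture, where a
pooled spectrum is the relevant one.

## Relationships, PCA, F_ST

The relationship matrix *G* stores pairwise identity by state: per SNP
the score is 1 for identical genotypes, 0.5 for one shared allele, 0
for opposite homozygotes, averaged over the markers where both
individuals are called (pairwise-complete, as PLINK does).  A pair with
no shared markers is an error rather than a silent NA.

PCA is not well defined on a raw similarity matrix, so `pca_grm()`
double-centers *G* (J G J with J = I − 11′/n) before the symmetric
eigendecomposition.  Variance fractions divide by the sum of the
*positive* eigenvalues only — double-centered similarity matrices are
routinely indefinite — and each eigenvector is sign-fixed so its
largest-magnitude loading is positive, a deterministic convention for
reproducible output.

`pairwise_fst()` implements the Weir–Cockerham (1984) estimator for
each pair of populations: per-SNP variance components a (among
populations), b (among individuals within), c (within individuals) are
computed from sample sizes, allele frequencies and observed
heterozygosity, and combined across SNPs as a ratio of sums
Σa / Σ(a+b+c).  Negative per-SNP components are retained in the sums
(they are part of the estimator's unbiasedness); only the final
estimate is floored at zero.  This is the estimator behind the
"Wright's F_ST" option of PLINK 1.9, which is why it is the default; a
Hudson-type estimator (Bhatia et al. 2013 formulation) is available as
`method = "hudson"` for sensitivity checks.  A NEXUS TAXA/DISTANCES
export allows the F_ST matrix to be drawn as a phylogenetic network by
SplitsTree-class software; network layout itself is out of scope.

## Admixture by EM

Both admixture modes maximise the independent-SNP binomial
log-likelihood

L(Q, F) = Σ_{ij} [ g_ij log p_ij + (2 − g_ij) log(1 − p_ij) ],
p = Q F′,

with Q rows on the simplex and ancestral frequencies F clamped to
[ε, 1−ε], ε = 1e-6, to keep the likelihood finite at the boundary.
The optimizer is the classic multiplicative EM (FRAPPE-style): it is
monotone in the log-likelihood, simple to verify, and fully adequate at
the problem sizes the package targets; the default tolerance is 1e-4
log-likelihood units with at most 2000 iterations and, for the
unsupervised mode, 3 random restarts keeping the best run.  SNPs are
treated as independent — no LD pruning is applied, consistent with
running on a MAF-filtered array panel.

In supervised mode F is fixed to the observed reference-panel
frequencies (each ancestral population needs at least two reference
individuals) and only the targets' Q rows are estimated; targets must
be disjoint from the references.  In unsupervised mode Q and F are
alternated from a seeded random start; cluster labels are arbitrary, so
`align_q_columns()` provides greedy best-permutation matching on column
correlations for comparing runs or matching truth.  A_GEN, the genomic
foreign-ancestry percentage, is 100 × (1 − q_reference) from a
supervised fit.

Cross-validation (`admix_cv_error()`) partitions the observed genotype
entries into disjoint random folds, refits with each fold's entries
masked out of the likelihood (weight zero — the masking is exact, not
approximate), and scores the held-out entries by their mean binomial
deviance under the fitted dosage expectation 2QF′.  On single-population
data the CV error does not improve past K = 1; on well-separated
two-breed data it is minimised at K = 2 in most replicates.  CV on real
admixed data can still be inconclusive — that is a property of the
data, not a defect of the procedure.

## Significant PCs and contribution scores

Horn's parallel analysis compares the observed eigenvalues of the
double-centered *G* with the (1 − P) quantile of eigenvalues obtained
under a null.  The primary null permutes every marker's genotype column
independently and recomputes the IBS matrix — this preserves the
allele-frequency spectrum while destroying individual-level structure,
which is the right null for relationship matrices.  A matrix-only
fallback permutes the off-diagonal entries of *G* instead, for when
genotypes are unavailable.  k_significant counts leading observed
eigenvalues exceeding their rank-matched null quantile, stopping at the
first failure.  Defaults are P = 0.01 with 1000 iterations; desk-scale
analyses in this package use a few hundred iterations, which is ample
for the 0.99 quantile at the matrix sizes involved.

The genetic contribution score of individual j is
gc_j = Σ_{i=1..k} w_i |cor(G_{·j}, u_i)|, where u_i are the left
singular vectors of *G*, w_i = λ_i / Σ_{1..k} λ_i the normalised
singular values, and k the retained component count.  The exact
weighting is a design choice of this package — variance-weighted
absolute correlations match the verbal definition of the score
(correlation between an individual's relationship profile and the
leading standardized eigenvectors, limited to the significant PCs) and
reduce to mean |correlation| at equal weights; the weighting is
isolated in one function so alternates (unweighted, squared) can be
swapped.  Columns with zero variance have no defined correlation and
score 0 with a warning.  Ranking is dense (ties share a rank).

## Population networks

`knn_network()` connects each individual to its k smallest-distance
neighbours (default k = 10, the NetView default).  The union rule —
keep an edge if either endpoint selects it — is the default because it
guarantees minimum degree k and preserves hubs; mutual-only selection
is available as a flag.  Ties at equal distance break deterministically
by ascending individual id.  Edge thickness for rendering is the
min-max normalised (1 − distance), so ordering of thickness is exactly
the reverse of distance.  Layout is delegated to standard force-directed
rendering and deliberately kept outside the tested surface; all tests
and exports operate on topology and attributes (GraphML).

## Runs of homozygosity

Detection follows the PLINK `--homozyg` two-level semantics.  A window
of 50 SNPs passes when it has at most 1 heterozygous and at most 5
missing calls; each SNP's hit-rate is the fraction of passing windows
among windows containing it, and SNPs with hit-rate strictly above
0.05 are ROH-eligible.  Maximal runs of eligible SNPs are then split at
gaps over 100 kb and trimmed into segments that satisfy the per-segment
constraints: at most 1 heterozygote, at least 80 SNPs, at least 500 kb,
and at least one SNP per 50 kb on average.  Only the five segment-level
values are typically reported in array studies; the three window
parameters are PLINK defaults, recorded in output headers.  Three
further choices are pinned down explicitly:

* "more than 80 SNPs" is implemented as n ≥ 80 (PLINK's
  `--homozyg-snp` is an inclusive minimum); a strict-inequality switch
  exists.
* Segment length is end − start + 1 bp, 1-based inclusive.
* Segments must start and end on homozygous non-missing SNPs, and when
  a run admits several valid sub-segments the leftmost-maximal one is
  emitted and scanning continues after it (greedy).  This makes the
  output a deterministic function of the input, and it is the rule the
  test suite's brute-force enumerator implements independently.

Chromosomes with fewer SNPs than one window are treated as a single
window spanning all their SNPs.  A practical consequence of the
hit-rate rule worth knowing: the outermost few SNPs of a homozygous
stretch are covered by only a handful of passing windows, so called
segments sit a few SNPs inside the true stretch.

F_ROH = 100 × S_ROH / L_AUTO.  L_AUTO defaults to 2280.92 Mb (the
equine autosome) and is configurable; simulated datasets pass their own
autosome length.  Length-class profiles use the classes 0.5–1, >1–2,
>2–4, >4–6, >6–8, >8–10, >10 Mb (lower-exclusive, upper-inclusive,
first class closed at 0.5).

ROH islands are maximal runs of consecutive markers whose
per-SNP incidence (fraction of the breed's individuals in a ROH
covering the marker) is *strictly* greater than 0.5 — exactly half the
breed does not make an island.  The denominator is the breed's
genotyped individuals.  Island bounds are the first/last member SNP
positions (no extension to inter-marker midpoints).  Two islands
overlap when they share at least 2 common markers — shared marker
indices, not bp intersection, which matters at island edges — and an
island is private when it overlaps no island of any other breed.
Multi-breed overlaps are reported per contiguous run of markers covered
by the same set of two or more breeds.

## Pedigree statistics

F_PED is the kinship of an individual's parents, computed by the
Meuwissen–Luo tabular algorithm (tracing the A = L D L′ factorisation
ancestor by ancestor), which scales as O(n · ancestors) rather than
O(n²) for the full relationship matrix.  Unknown parents are treated as
unrelated, non-inbred founders — the standard convention.  Wright's
path-counting formula is retained in the test suite as an independent
oracle; the two agree to machine precision on random five-generation
pedigrees and reproduce the classic closed forms (full-sib 0.25,
half-sib 0.125, parent–offspring 0.25) exactly.

A_PED generalises the usual studbook convention: founders labelled with
the home breed, or born before a configurable cutoff year (default
1950), count as 0 % foreign; all other founders count 100 % (or an
explicit per-founder percentage); every non-founder is the parental
mean, with unknown parents counting as purebred.  An F1 of a foreign
sire and a purebred dam is therefore exactly 50.00 %.  Under the
gene-dropping simulator A_PED equals the founder-fraction expectation
of the true ancestry, since both are parental means.

`compare_genomic_pedigree()` reports Pearson r and OLS
slope/intercept/R² for F_ROH vs F_PED and A_GEN vs A_PED, solving the
normal equations on an explicit design matrix (QR); adding sire and dam
as categorical factors gives the augmented model's R².  Genomic
inbreeding generally exceeds pedigree inbreeding when pedigrees are
shallow or erroneous; the factor-augmented model captures the
family-level structure of that discrepancy.

## The synthetic-data generator

The generator emulates the study design the analyses are built for:
several breeds diverged from one ancestral gene pool, bred forward in
discrete generations with occasional close-relative matings, plus
cross-breeding events producing admixed individuals.

* **Founder frequencies** follow the Balding–Nichols model: for
  divergence F, breed frequencies are Beta with mean p (the ancestral
  frequency, uniform in (0.1, 0.9) by default) and variance p(1−p)F.
  Per-breed F defaults to 0.1, which yields pairwise Weir–Cockerham
  estimates near 0.1–0.2 — the range typical of related horse breeds.
* **Pedigree**: 4 breeds × 30 founders and 6 generations by default,
  with a 0.2 fraction of matings between full/half sibs and one
  cross-breeding event; all of these are configuration, not code.
  The historical mating system of any real breed is far more
  structured; the defaults are chosen to produce the features the
  estimators must recover (divergence, admixture, autozygosity), not to
  calibrate to a particular breed's history.
* **Gene dropping**: founder haplotypes draw SNP alleles independently
  from their breed's frequencies; descendants inherit recombinant
  gametes with crossovers as a Poisson process at 1 per 100 cM, uniform
  in cM and mapped linearly to bp, without interference.  20,000 SNPs
  on five 50 Mb / 50 cM chromosomes is the default desk-scale genome
  (≈12.5 kb spacing, comfortably above the one-SNP-per-50 kb ROH
  density floor).
* **Ground truth**: the founder-haplotype origin of every genome
  segment is tracked exactly, giving per-individual ancestry fractions
  (true_q, summing to 1) and autozygous tracts (both haplotypes from
  the same founder haplotype), whose union length over the autosome is
  the true autozygosity.

What the generator does *not* emulate — and what passing tests
therefore do not certify about real data: background linkage
disequilibrium within founder haplotypes (founder SNPs are
independent), mutation, genotyping error, array ascertainment bias, sex
chromosomes, and overlapping generations.  Because true autozygosity
counts tracts of any length while ROH detection has a 500 kb / 80 SNP
floor, F_ROH is expected to *underestimate* true autozygosity slightly;
validation therefore asserts high correlation and a one-sided bias, not
equality.  A genuinely subtle point surfaced by the simulator: the
classic expectation of 25 % autozygosity for offspring of an F1 × F1
full-sib mating holds when averaged over parental meioses; hundreds of
offspring of a *single* F1 pair share their parents' realized mosaics
and can average far from 25 %, so replicate families are needed to see
the textbook number.

## Pipeline, determinism and problem sizes

`run_pipeline()` chains the stages with one config (R list or YAML) and
one master seed from which per-stage seeds are derived, writing every
stage's artifacts as TSV/GraphML/NEXUS plus a JSON manifest of
parameters, seeds and output hashes; reruns with the same config are
identical.  Stage toggles omit exactly the toggled stage's outputs.
The package's interface is R functions plus this orchestrator; the
acceptance script under `scripts/` is a thin Rscript over the same
functions.

The test suite runs everything at desk scale, chosen so the whole suite
completes in minutes on one core while still giving the estimators
enough signal: ROH oracle equivalence on 200 random 1000-SNP
chromosomes; supervised-admixture recovery at 10,000 SNPs and
divergence 0.15; F_ST recovery at 2 × 100 individuals and 5,000 SNPs;
F_ROH-vs-truth on a 30-founder, 5-generation, 20,000-SNP gene drop;
parallel analysis at 80–100 individuals, 1,500–2,000 SNPs and a few
hundred iterations.  Real array panels are 1–2 orders of magnitude
larger in markers; every algorithm here is linear in markers except the
IBS matrix (n² m) and parallel analysis (iterations × n² m), which are
the places to spend cores first if scaling up.
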