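---
title: "Genomic relationships from low-depth pool sequencing: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genomic relationships from low-depth pool sequencing: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Forage-grass breeding programmes evaluate three kinds of material side by
side: diploid single plants (SPs), bi-parental F2 family pools, and
multi-parent synthetic varieties (SYNs). Genotyping-by-sequencing (GBS) of a
pooled DNA sample yields, at each SNP, a reference and an alternative read
count; their ratio estimates the pool allele frequency. Run cheaply — at low
coverage depth — these estimates are noisy and patchy, and a genomic
relationship matrix (GRM) built from them is biased: the diagonal elements
are inflated by read-sampling noise, mimicking inbreeding that is not there.
`poolgrm` implements an allele-frequency GRM that treats a pool as a
polyploid genotype, a closed-form correction of the depth-induced diagonal
inflation, missing-frequency imputation, and GBLUP with the cross-validation
schemes used in breeding evaluation, plus the simulator used to validate all
of it.

# The GRM for frequencies

With sample-by-marker frequencies $F_{ij}$, the matrix is centred by marker
means, $M_{ij} = F_{ij} - \bar F_j$, and

$$G = \frac{M M'}{\sigma^2_G}, \qquad
  \sigma^2_G = \frac{1}{n}\sum_j \bar F_j (1 - \bar F_j),$$

where $n$ is the assumed ploidy of the reference material. A pool is treated
as one genotype of ploidy equal to the summed ploidy of its parents: 2 for an
SP, 4 for an F2 pool, $2 k$ for a $k$-parent SYN. Under own-ploidy scaling
the expected diagonal is $1 + F$; scaled at a reference ploidy $n_{ref}$ it
becomes $(n_{ref}/n_i)(1 + F)$ (`expected_grm_diagonal()`). When materials
are mixed in one GRM the F2 ploidy ($n_{ref} = 4$) is the conventional
reference, so SPs (with $F = 0.25$ from full-sib F1 mating) sit near 2.5 and
an 8-parent SYN near 0.25.

# The depth bias and its correction

An observed frequency is $\hat p = S_A / S_T$ with
$S_A \sim \mathrm{Binomial}(S_T, p)$, so each squared, centred entry carries
an extra $p(1-p)/S_T$ of sampling variance. Accumulated over markers this
inflates only the diagonal (read noise is independent between samples).
The fraction of a sample's apparent marker variance that is noise has the
closed form

$$\omega_i = \frac{n_i - 1}{\bar S_{T,i} + n_i - 1},$$

with $\bar S_{T,i}$ the sample's mean depth over covered markers; it does not
depend on the allele frequencies. `correct_diagonal()` rescales
$D_{c,i} = D_{b,i} (1 - \omega_i)$ and leaves off-diagonals untouched. The
exact per-SNP sums behind this (`binomial_variance_components()`) reduce to
the closed form algebraically under constant depth — one of the package's
oracle tests asserts this at $10^{-12}$.

Two practical notes, both verified by the test suite:

* The $1/(1-\omega)$ inflation law describes the *Hardy–Weinberg* (no-drift)
  expectation. When family pools carry drift inflation $\delta$ from small
  family sizes, the uncorrected diagonal at depth $d$ is
  $1 + \delta + (n - 1 - \delta)/d$ rather than $(1+\delta)(1 + (n-1)/d)$;
  the mismatch is $\approx 4\delta/d$ for F2 pools. The depth-sweep
  validation therefore simulates family size 400 (drift $< 1\%$), where the
  law holds within three standard errors of the mean at every depth from 1 to
  100; at size 50 it would be confounded at low depth.
* Deflating diagonals can make a GRM non-positive-definite. GBLUP adds a
  ridge to push the smallest eigenvalue to at least $10^{-8}$ (default extra
  ridge $10^{-6}$) and records the amount in the fit object.

# The simulator

`simulate_breeding_population()` follows the breeding funnel: founder allele
frequencies are Beta(2, 8) (mean 0.2, the low-frequency-dominated spectrum
typical of GBS panels); 300 unrelated founder pairs each produce an F1
family; F2 individuals come from crossing two random F1 members of the same
family; the F2 pool frequency is the mean member dosage; SPs are F2 members;
SYNs polycross 8 SPs from distinct F2 families with 50 progeny per parent
slot. Transmission uses exact Bernoulli/Binomial draws — a gamete from a
parent with dosage $g$ carries the alternative allele with probability $g$,
which for unlinked markers is distributionally identical to picking one of
the parent's two alleles. Read-depth degradation (`degrade_matrix()`) uses
exact binomial sampling rather than its normal approximation, which fails
exactly where the method matters (depth 1–5).

Two deliberate design positions deserve emphasis because they determine the
numbers the acceptance checks produce:

* **SYN parents are genuinely inbred SPs.** SPs carry $F = 0.25$, so the
  variance of the SYN pool mean is $(1+F)\,p(1-p)/16$ and the expected
  own-ploidy SYN diagonal is $\approx 1.25$, not 1.0. The idealised
  "16 independent gametes" model that yields 1.0 would require non-inbred
  parents, contradicting the breeding design being emulated. We keep the
  pedigree-faithful construction; the package documents, rather than hides,
  the gap to the idealised value.
* **Finite pools drift.** With family size $s$ in both generations the F2
  pool diagonal is inflated by $\approx 2.5/s$ (about $1/s$ from F1-stage
  drift and $1.5/s$ from pool-level gamete sampling). `drift_sweep()`
  measures this; the inflation decays monotonically but reaches the 1% level
  only near $s \approx 250$, not at 50. Both effects were confirmed against
  independent one-marker brute-force Monte-Carlo before being frozen into
  tests.

`simulate_linked_scaffolds()` exists because the unlinked generator carries
no between-marker signal, and k-nearest-neighbour (kNN) and random-forest
(RF) imputation live off linkage disequilibrium (LD). Founder haplotypes are
mosaics of a small pool of ancestral haplotypes; ancestry switches with
probability $2r$ per adjacent marker pair (so $r = 0.5$ makes ancestry
marker-independent) and meiosis flips between parental haplotypes with
probability $r$. The ancestral-pool size bounds attainable marker–marker
$r^2$ at roughly $1/(A-1)$; the default $A = 3$ was calibrated so that
masking-based imputation accuracies on the default dataset land in the
regime reported for dense real GBS panels (mean imputation $\approx$ 0.5–0.65,
kNN $\approx$ 0.75, RF $\approx$ 0.85). What the generator does *not*
emulate: allele-frequency spectra shaped by selection, scaffold-length
variation, mapping and calling artefacts, and non-random missingness — so a
passing imputation ordering here shows the methods exploit LD correctly, not
that they will reach any particular accuracy on real data.

`simulate_phenotypes()` draws breeding values with covariance proportional
to a (PSD-repaired) GRM, adds trial fixed effects and residuals; `h2` is the
single-record heritability, with unit total variance.

# Imputation

* **Mean (MNi)**: missing $x_{ij}$ becomes marker $j$'s observed mean — the
  imputation implicit in the standard GRM construction (a mean-imputed entry
  contributes zero after centring).
* **kNN (kNNi)**: per scaffold, each missing entry is the $1/d^2$-weighted
  average of the sample's values at the $k = 6$ nearest markers, where every
  other marker enters the candidate set in original and flipped ($1-x$)
  form so strong negative LD is usable. Distances are Euclidean over
  pairwise-complete samples, rescaled by the completeness ratio; candidates
  overlapping in fewer than 10 samples are dropped; distance-zero duplicates
  take full weight exclusively; ties break by (distance, marker index,
  original-before-flipped). A marker never predicts itself in either state.
* **RF (RFi)**: initialise with MNi; per iteration regress each incomplete
  marker on its scaffold neighbours with a 100-tree regression forest
  (bootstrap of observed samples, $\lceil m/3 \rceil$ predictors per split,
  unlimited depth — the regression-forest conventions), update the missing
  entries, and stop after 10 iterations or as soon as the sum of squared
  changes between successive imputed matrices rises, returning the
  pre-divergence state. Markers are processed most-observed-first by
  default (`order = "column"` reproduces plain column order). Per-scaffold
  seeds derive from the global seed and the scaffold name, making results
  invariant to scaffold processing order.

Accuracy is estimated by `masking_accuracy()`: mask a fraction of observed
entries on a random subset of scaffolds, re-impute, and score
$R^2 = 1 - \sum (x_{true} - x_{imp})^2 / \sum (x_{true} - \bar x)^2$ over
the masked entries ($R^2$ can be negative; a constant-mean imputer scores
near zero). The protocol leaves the input untouched. The stated masking
convention ("a fraction of observed values per marker") is implemented as a
joint draw over the selected scaffolds' observed entries, which is
equivalent in expectation and well-defined for sparsely observed markers.

# GBLUP and cross-validation

The mixed model is
$y = 1\mu + X t + Z_1 i + Z_2 l + e$ with trial fixed effects nested in
location–year, genomic values $i \sim N(0, G\sigma^2_i)$, an optional
genotype-by-location-year interaction $l \sim N(0, I\sigma^2_{ily})$
(included only when at least two location–years exist), and residuals.
Variance components are estimated by average-information REML on the
$V$-matrix parameterisation with step-halving and an EM fallback, so the
restricted log-likelihood never decreases along the trace; convergence is a
log-likelihood change below $10^{-8}$, and the final score norm is stored.
GEBVs are returned for all GRM samples, including unphenotyped ones,
through their genomic relationships. Two fixed-variance solver routes —
Henderson's mixed-model equations with $G^{-1}$, and the eigen-rotated
diagonal solve — are both exposed (`solve_gblup()`) and must agree to
$10^{-8}$; this is the internal algebra oracle.

Cross-validation follows the two-stage convention: fixed effects are
estimated once on the full data, phenotypes are corrected and averaged per
sample, and prediction operates on the corrected means. Leave-one-out holds
the variance components at their full-data estimates (refitting hundreds of
REMLs per GRM is disproportionate; `refit_each_fold = TRUE` does the exact
refit for small data) and uses rank-one downdating of $V^{-1}$, which the
tests verify against explicit per-fold solves. The across-set scheme masks
one material entirely and predicts it from the others through the combined
($n_{ref} = 4$) GRM. Predictive ability is the Pearson correlation between
cross-validated GEBVs and corrected phenotype means, unweighted by
replicate count. The two-stage correction leaks a little information
through $\hat\mu$; with hundreds of samples the effect on predictive
ability is below Monte-Carlo noise (the null-trait calibration test bounds
it).

One empirical caution, measured here and worth stating plainly: in clean
simulations with near-homogeneous depths the diagonal correction leaves
predictive ability essentially unchanged (paired differences are within
Monte-Carlo error of zero). The correction's demonstrable value in
simulation is calibration — unbiased diagonals and hence interpretable
inbreeding and variance components — not a prediction gain; gains reported
on real multi-assay data plausibly involve depth heterogeneity and
missing-data structure that the clean simulation lacks.

# Problem sizes used in the validation suite

The acceptance checks simulate the study design at full scale: 300 families
by 5,000 markers for the diagonal expectations; a 300-family, 1,000-marker,
family-size-400 population for the depth sweep over
$S_T \in \{1,2,5,10,20,50,100\}$; family sizes $\{5,10,25,50,100\}$ at 2,000
markers for the drift sweep; a 150-pool, 240-marker linked dataset with 10%
missingness for the imputation ordering (10 paired masking replicates); and
300 single plants across 20 seeds for heritability recovery. These sizes
are the package's validation choices: large enough for three-standard-error
discrimination of the effects under test, small enough to run routinely.

# Known limitations

* Filtering (missingness, then folded-mean MAF) uses the folded column mean
  as the MAF analogue for continuous frequencies; other pool-level MAF
  definitions exist.
* kNN distances use pairwise-complete rescaling; under extreme, structured
  missingness the rescaling can distort neighbourhoods.
* The LOO fast path folds the interaction variance into a per-sample
  residual term ($\sigma^2_{ily}/L_i + \sigma^2_e/r_i$); with strongly
  unbalanced location–year structures the exact refit path is preferable.
* The simulator draws unlinked markers for everything except the dedicated
  linked-scaffold generator; real panels mix both regimes.
* VCF ingestion reads biallelic SNPs with AD fields only; other variant
  classes are skipped and counted.
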