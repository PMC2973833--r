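---
title: "Methods: quantitative genetics of a plant metabolome panel"
author: "metaboGWA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantitative genetics of a plant metabolome panel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

metaboGWA analyzes replicated, untargeted metabolite profiles (GC-TOF-MS ion
counts) measured on a panel of homozygous inbred *Arabidopsis thaliana*
accessions, together with a dense genome-wide SNP matrix.  The pipeline has
seven analysis layers — preprocessing, heritability and genetic coefficients
of variation, genetic metabolite–metabolite networks, kinship-corrected
single-SNP association scans, gene-level candidate calling with hotspot
detection, gene-level linkage disequilibrium, and metabolite class
statistics — plus a synthetic-data generator that emulates the study design
so every layer can be validated end to end without the original data.  This
vignette records the statistical models, the parameter conventions, and the
design decisions that were genuinely open.

# Data model

A `MetabolitePanel` (a `SummarizedExperiment`) holds a compounds × samples
ion-count matrix with per-sample metadata: accession, experiment, flat,
replicate, and GC-TOF-MS run date.  "Detected" always means a non-missing,
positive ion count; absences in GC-TOF-MS data appear as missing entries.
A `GenotypeSet` holds the accessions × SNPs matrix coded 0/1 — the
accessions are fully homozygous inbred lines, so a haploid coding suffices
and no heterozygote state exists — plus SNP coordinates and gene models as
`GRanges`.  Accession means, association tables, candidate links, hotspot
intervals and edge lists are plain data frames.

# Preprocessing

Three steps, applied independently within each experiment and in this fixed
order:

1. **Compound presence filter.**  A compound is retained iff at least one
   accession detects it in *strictly more than* 50% of that accession's
   samples.  The strict inequality is deliberate and unit-tested at the
   boundary (2 of 4 samples = exactly 0.5 → removed).
2. **Sample coverage filter.**  The *predominant* set is the compounds
   detected in ≥ 70% of all samples; samples detecting ≥ 50% of that set
   are retained.  Both thresholds here are inclusive.  The predominant set
   is computed after the compound filter; `filterSamplesByCoverage()` can
   be called on an unfiltered panel to flip that order.  If the predominant
   set is empty the step warns and retains all samples.
3. **Normalization.**  Values are log2-transformed and, within each
   run-date batch, shifted by (9 − batch median), so every batch's median
   is exactly 9 log2 units.  This removes day-to-day drifts in MS
   sensitivity; multiplying all counts of one batch by a constant leaves
   its normalized values unchanged (unit-tested equivariance).
   Non-positive counts are a data error and abort with the offending
   sample and compound named.

# Heritability, accession means, genetic CV

Per compound, on the normalized log2 values, the fixed-effects model

$$y_{safr} = \mu + S_s + F_f + A_{a(s)} + R_{r(f)} + \varepsilon,\qquad
\varepsilon \sim N(0, \sigma^2_\varepsilon)$$

is fitted with accession $A$ nested in structure group $S$ and replicate
$R$ nested in flat $F$.  Broad-sense heritability is the type-II sum of
squares of $A(S)$ — computed by model comparison (full model versus the
model dropping $A(S)$), which remains valid for unbalanced data — divided
by the total corrected sum of squares.  A raw sum of squares is not a
heritability, so the ratio to the total SS is the reported $H^2$; the raw
SS and the full sequential SS table are also returned, and on balanced
designs the type-II and sequential accession SS coincide (asserted by a
test).  Structure groups are an input mapping; when absent,
`deriveStructureGroups()` cuts an average-linkage clustering of
$1 - K$ (kinship) into eight groups.

Two properties of this estimator are worth recording.  First, it has a
design floor: under a pure-noise null its expectation is
$(a - s)/(N - 1)$ — about 0.23 with 96 accessions, 8 groups and 4
replicates, falling towards 0 as replication grows.  Second, because $S$
precedes $A(S)$, genetic variance aligned with population structure is
credited to $S$, not to $A(S)$: the estimand is heritability *net of
structure*.  The synthetic generator is calibrated to exactly this
estimand (below), which is what makes parameter-recovery experiments
well-posed.

Adjusted accession means use the same model without $S$
($y = \mu + F + A + R(F) + \varepsilon$); the mean for accession $a$ is
the model prediction averaged over the flat × replicate grid, which places
all accessions on a common, nuisance-adjusted scale.  Structure is left in
the means deliberately: the association scan corrects for it through the
kinship random effect.

The genetic coefficient of variation is $\sigma/\mu$ over the accession
means, reported as a fraction; compounds with non-positive mean get `NA`
with a warning.  Whether to compute it on the log2 scale or after
back-transforming to counts is not determined by the method itself, so the
scale of the input table is used by default and `backTransform = TRUE`
exponentiates first.  `compareCVDistributions()` reports, on the shared
compounds of two populations, the fraction with the higher CV in the
second population and the fraction exceeding the first population's
maximum.

# Genetic metabolite–metabolite networks

Zero-order association is Spearman's $\rho$ on pairwise-complete accession
means with the standard $t$ approximation
$t = \rho\sqrt{(n-2)/(1-\rho^2)}$ on $n - 2$ df.  (The algebraically
inconsistent variant of this formula sometimes quoted — without the square
on $\rho$ — is not implemented.)

First-order structure uses the analytic-shrinkage partial-correlation
estimator: the sample correlation matrix $R$ is shrunk towards the
identity, $R^\ast = (1-\lambda^\ast) R + \lambda^\ast I$, with

$$\lambda^\ast = \frac{\sum_{i<j}\widehat{\mathrm{Var}}(r_{ij})}
{\sum_{i<j} r_{ij}^2}$$

clipped to $[0,1]$, and partial correlations are the negative scaled
inverse of $R^\ast$.  With $\lambda = 0$ this reduces exactly to the plain
inverse-correlation partial correlation (an oracle test asserts agreement
to $10^{-10}$), and for $\lambda > 0$ the shrunk matrix is positive
definite.  Missing cells are handled by pairwise-complete estimation of
both $r_{ij}$ and its variance; compounds with under 50% accession
coverage or zero variance are excluded from network inference.  The full
shrinkage estimator conditions on *all* remaining compounds; this is what
the standard network-inference procedure computes even where the
literature loosely says "first-order".

Edge significance uses a density-based local false discovery rate with the
two-component model $f(x) = \eta_0 f_0(x;\kappa) + (1-\eta_0) f_A(x)$,
where $f_0$ is the null density of a sample correlation with $\kappa$
degrees of freedom.  $\kappa$ is fitted by censored maximum likelihood on
the statistics below the 0.75 quantile of $|x|$ (the central,
predominantly null region), $\eta_0$ follows from the censored fraction
divided by the null mass below the censoring point (clipped at 1), the
mixture density is a Grenander (monotone, least-concave-majorant)
estimate on $|x|$, and $\mathrm{fdr}(x) = \eta_0 f_0(x)/f(|x|)$ is clipped
to $[0,1]$ and made monotone non-increasing in $|x|$ by a running minimum.
Degenerate inputs (all statistics equal) give fdr = 1 everywhere with a
warning.  Networks threshold at local FDR 5% (strict) or the more lenient
20%; summaries (average degree $k = 2E/V$ over incident nodes, per-degree
clustering $C(k)$, degree distribution $P(k)$) are computed with igraph.

Cross-experiment comparison reports shared unordered edges with per-edge
sign agreement, and tests connectivity differences by two-sample
permutation of node-level quantities (degree for average connectivity,
local clustering for triad closure; ≥ 1000 rounds) plus a two-sample
Kolmogorov–Smirnov test on the degree sequences.  The permutation design
is this package's choice — the original analysis does not specify its
test — and identical networks yield p ≈ 1 by construction.

# Kinship-corrected association scans

Per SNP $s$ and trait $y$ (accession means):

$$y = \mu + x_s\beta + u + \varepsilon,\qquad u \sim N(0, \sigma^2_g K),
\quad \varepsilon \sim N(0, \sigma^2_e I)$$

with $K$ the identity-by-state allele-sharing kinship matrix (symmetric,
unit diagonal, PSD by construction).  The variance ratio
$\delta = \sigma^2_e/\sigma^2_g$ is estimated by maximum likelihood — not
REML, matching the cited reference implementation — under the null
(no-SNP) model via one spectral decomposition of $K$ per trait, a
100-point grid on $\log\delta \in [-10, 10]$ refined by Brent
optimization (the refinement is guarded to never fall below the best grid
point).  Each SNP is then tested by a generalized-least-squares F test on
$(1, N-2)$ df under the null-model variance components.  Reusing the null
variance components for all SNPs is the standard
population-parameters-previously-determined approximation; it is what
makes 206k SNPs × hundreds of metabolites feasible, and with $K = I$ the
scan collapses exactly to ordinary least squares (asserted to $10^{-8}$).
Missing genotypes are mean-imputed per SNP; monomorphic SNPs report
$\beta = 0,\ p = 1$.  SNPs at minor allele frequency ≤ 5% are removed
beforehand (strict inequality).

Multiplicity control uses Storey q-values per metabolite — each
metabolite's scan is its own family, since downstream counts are reported
per metabolite.  $\pi_0$ comes from the usual smoother (a cubic spline
through $\pi_0(\lambda)$ on $\lambda = 0.05,\dots,0.95$, evaluated at the
right end, clipped to $(0,1]$); families under 20 p-values fall back to
Benjamini–Hochberg with a warning.  Significance is $q < 0.20$ by
default; the stricter 0.05 used in parts of the original presentation is
a config value, and both are exposed.

# Candidate genes and hotspots

SNPs map to genes within a 1 kb flank, 1-based inclusive on both ends; a
SNP may serve several (overlapping or adjacent) genes.  A gene–metabolite
link is a candidate iff ≥ 2 distinct mapped SNPs have $q$ below the cutoff
for that metabolite — the two-SNP rule is what suppresses singleton
false positives.  Candidate links are monotone in both thresholds
(property-tested).

Hotspots: per-gene counts of linked metabolites → sliding averages over
windows of `windowGenes` consecutive genes (step 1).  Windows never span
chromosome boundaries — a hotspot is a physical genomic region — and are
truncated with a warning on short chromosomes.  A gene passes if *any*
window covering it exceeds the permutation threshold (strictly); genes
with no passing immediate neighbor are pruned; maximal runs of survivors
form intervals; an interval is kept iff its mean metabolites per gene
exceeds 2, or it has at least 8 genes with a mean above 1 (both strict).
The threshold is the "maximum average number of false compounds per
gene": accession labels are re-sampled without replacement independently
within each compound, the entire scan → candidates → sliding-average path
is recomputed, and the maximum sliding average over permutations is taken.
The identity permutation reproduces the observed statistics exactly, and
the permutation round count is a config value (the original count is
unstated; the full-scale default is 10, and the scaled validation study
uses 8).

# Gene-level linkage disequilibrium

For gene-level LD every gene is collapsed to a biallelic locus: the
empirically observed haplotype strings over the gene's SNPs are tallied;
the most frequent becomes the major allele (0) and all others minor (1).
Frequency ties break to the lexicographically smallest string, for
determinism; accessions with any missing genotype in the gene are dropped
from that gene's collapse rather than fabricating haplotypes.  $r^2$ is
the squared Pearson correlation of the binary vectors — identical to
$(p_{ab} - p_a p_b)^2 / (p_a(1-p_a)p_b(1-p_b))$ — invariant to allele
relabeling and accession order.

The trans-LD screen takes gene pairs that are candidates for the same
compound and lie on different chromosomes and reports those with collapsed
$r^2 > 0.4$ (a deliberately conservative cut), alongside the 99th
percentile and maximum of *all* non-syntenic collapsed $r^2$ as the
empirical background.

The hotspot-versus-genome profile uses the average maximum SNP–SNP $r^2$:
all SNP-pair $r^2$ between two genes; per-SNP maxima taken separately
from each gene's side; the two side-wise means averaged.  The statistic is
symmetric, bounded in $[0,1]$, equals plain $r^2$ for single-SNP genes,
is 1 for a gene against itself, and dominates the plain mean SNP–SNP
$r^2$ (all property-tested; a 2 × 3 toy pair is checked against
brute-force enumeration of the 6 SNP pairs).  The per-SNP maxima bias the
statistic upward; no correction is applied, matching the source
procedure's own caveat.  The significance threshold is the mean statistic
over all different-chromosome gene pairs in the profile, always recomputed
from the data at hand, never hard-coded.

# Class statistics

Differential abundance between experiments is a paired t test per shared
compound across the shared accessions (the accession is the only shared
pairing unit), Bonferroni-corrected over the shared compounds; the
differential flag additionally requires a greater-than-two-fold
difference, with fold defined as the ratio of geometric means,
$2^{|\overline{\Delta \log_2}|}$ — the source does not define its fold, so
this choice is recorded here.  Means-level and replicate-level testing are
both possible (pass accession means or a panel's values).  Class
over-representation is a per-class 2 × 2 Pearson $\chi^2$ (1 df, no
continuity correction) of membership against association with ≥ 1 gene;
classes with an expected cell below 1 are flagged unreliable but still
reported.  Gene sharing within a class counts genes linked to ≥ 2 group
compounds and compares binned gene-association-count distributions by
$\chi^2$.

# The synthetic-data generator

The generator emulates the study design: ~96 inbred accessions in 8
structure groups; LD-blocked biallelic SNPs; gene models tiled every 2 kb
(1.6 kb wide, SNPs every 200 bp, so a gene ± 1 kb covers ~18 SNPs);
metabolites with planted causal genes, an optional pleiotropic hotspot
gene, and a latent precision-matrix network; two flats × two replicates
per accession (four plants); run-date batches with log2 median shifts;
log-normal ion counts with an optional detection limit that records low
counts as missing, to exercise the presence filters.

**LD blocks.**  Each block carries two base haplotypes whose ancestral
frequency is diverged across structure groups by a Balding–Nichols model
(default $F_{st}$ 0.1 — the simplest generator of the confounding a
kinship correction must absorb); each accession copies one base haplotype
per block at its group's frequency and accumulates 2% per-SNP flips.
Within-block $r^2$ is therefore strong (≈ 0.9 between typical block
mates) and decays to the structure-induced background between blocks —
the regime in which the ≥ 2-SNP candidate rule is meaningful.  SNPs that
end up at MAF ≤ the floor are removed.

**Heritability calibration.**  `targetH2` is expressed on the scale of
the estimator the pipeline uses: the expected share of a metabolite's
total sum of squares attributable to accession-within-group.  The
accession-level component (causal + network latent) is centered within
structure groups and scaled so that
$\mathbb{E}[\mathrm{SS}_A]/\mathbb{E}[\mathrm{SS}_{tot}]$ equals the
target, with the design floor $(a-s)/(N-1)$ respected (targets below the
floor yield a zero genetic component).  This makes the generator's dial
and the estimator's output commensurable, which is the precondition for
recovery experiments; it also means `targetH2` should be read as
"heritability net of structure", matching the estimand.

**What it does not emulate:** realistic recombination maps or demography,
selective sweeps, compound annotation chemistry, retention-index
artifacts, or the heavy-tailed contamination of real ion counts.  Passing
recovery tests therefore demonstrates the statistical machinery is
correct and calibrated under the assumed data-generating structure — not
that real data meet those assumptions.

# Validation studies and problem sizes

The packaged studies (also recomputed by `scripts/acceptance.R`) run at
these sizes, chosen to finish in minutes on one CPU while keeping each
comparison well-powered:

* **Mixed-model calibration** — 96 accessions, 2000 SNPs, $F_{st}$ 0.2,
  50 traits of pure polygenic background ($h^2$ 0.5): pooled genomic
  inflation of the mixed scan stays near 1 while naive OLS inflates.
* **Heritability recovery** — targets {0.2, 0.45, 0.8}, 100 metabolites
  each; mean estimates land within ±0.10 of target (the 0.2 target sits
  just below the 4-replicate design floor and is recovered at ≈ 0.23).
* **Hotspot recovery and calibration** — 25 runs of a scaled experiment
  (2000 SNPs over 5 chromosomes, 30 metabolites, a planted pleiotropic
  gene affecting 12 of them at effect 3 sd, window 10 genes, 8
  permutations): the planted gene is recovered inside a reported hotspot
  in ≥ 80% of runs, and an independent within-compound shuffle pushed
  through the identical path yields ≈ 0 hotspots per run.  The 3 sd
  planted effect is a deliberate strong-signal regime: a recovery study
  asks whether the machinery finds what is there, not whether weak
  signals are detectable at n = 96.
* **Edge recovery** — 20 compounds, 10 planted edges at |pcor| 0.45 on a
  degree-≤ 2 random graph (so chains exist and indirect marginal
  correlations penalize zero-order ranking), n = 96, 10 replicates:
  local-FDR ranking beats |ρ| ranking on PR-AUC.  0.45 is the largest
  magnitude for which degree-2 nodes keep the precision matrix safely
  positive definite; at 0.5 only a perfect matching is possible and the
  two rankings tie trivially.

# Numerical conventions

Correlations are clipped to $[-1, 1]$ and $|x| \le 1 - 10^{-10}$ inside
the null density; p-values are floored at $10^{-300}$; GLS residual sums
of squares are floored at 0; kinship eigenvalues are clipped at 0 after a
PSD check at relative tolerance $10^{-6}$; the SS decomposition is tested
at relative $10^{-8}$.  All stochastic components are driven by explicit
integer seeds, and identical config + seed reproduces byte-identical
genotype matrices, panels, and pipeline output hashes (manifest-checked).

# Known limitations

The heritability model treats accession and structure as fixed effects
(no REML variance components, no narrow-sense heritability).  The
mixed-model scan's P3D approximation slightly misstates per-SNP variance
components when a SNP explains a large variance share.  The local-FDR
null fit assumes the central 75% of statistics is predominantly null;
under pervasive dependence (e.g. a strong pleiotropic hotspot coupling
many metabolites) $\eta_0$ is underestimated and networks become liberal.
The class $\chi^2$ tests are asymptotic and flagged, not corrected, at
small expected counts.  Hotspot interval boundaries inherit the window
resolution (one gene).
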