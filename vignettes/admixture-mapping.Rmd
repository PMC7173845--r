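---
title: "Admixture mapping of blood pressure: models, thresholds and design choices"
author: "admixscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Admixture mapping of blood pressure: models, thresholds and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(admixscan)
```

## The problem

Hypertension is markedly more prevalent in African Americans than in
European Americans. If part of that difference is genetic, causal variants
should sit more often on chromosome segments inherited from the ancestral
population with the higher risk. In a recently admixed population each
individual's genome is a mosaic of African- and European-derived tracts, so
one can test, locus by locus, whether carrying extra African ancestry at
that locus shifts blood pressure. This *admixture mapping* scan needs far
fewer tests than a SNP association study — ancestry tracts are megabases
long — and therefore works at cohort sizes (a few hundred individuals)
where a GWAS would be hopeless.

`admixscan` implements that analysis end to end: cohort simulation, marker
QC, phenotype construction, the local-ancestry scan, multiple-testing
thresholds, significant-region extraction, regional fine-mapping with
ancestry-differentiated SNPs, conditional mediation scans, and
local-ancestry-stratified meta-analysis.

## The scan model

For individual $i$ with global (exome-averaged) African ancestry $G_i \in
[0,1]$ and diploid local African ancestry $L_{im} \in \{0, \tfrac12, 1\}$
at marker $m$, the scan fits, by ordinary least squares,

$$
y_i \;=\; \beta_0 + \beta_1 G_i + \beta_2 (G_i - L_{im})
      + \beta_3\,\mathrm{age}_i + \beta_4\,\mathrm{age}_i^2
      + \beta_5\,\mathrm{sex}_i + \beta_6\,\mathrm{BMI}_i + \varepsilon_i .
$$

Local and global ancestry are strongly correlated, so the local term enters
as the difference $G - L$: $\beta_2$ is the *local response accounting for
the global ancestral effect that every locus carries*. Note the sign
convention: $\beta_2$ multiplies $G - L$, so a positive $\beta_2$ means BP
rises where local African ancestry falls **below** the individual's
genome-wide average. `fitAdmixtureModel()` fits one locus;
`admixtureScan()` fits every marker, sharing one residualization of the
common covariates (Frisch–Waugh–Lovell, algebraically identical to
refitting the full model per marker — a test asserts equality with a
normal-equations oracle to 1e-10).

Phenotypes ($y$): diastolic BP and mean arterial pressure untransformed,
systolic BP as $\log_{10}$ — the scales on which a Shapiro–Wilk check
treats each as acceptably normal. Measured pressures in medicated
individuals are first corrected by the standard fixed offsets (+5 mmHg
DBP, +10 mmHg SBP), and MAP is built from the corrected values:
$\mathrm{MAP} = \tfrac13\,\mathrm{SBP} + \tfrac23\,\mathrm{DBP}$.

## Multiple testing: effective number of tests

Neighbouring markers share ancestry tracts, so the scan performs far fewer
independent tests than it has markers. Following the spectral-density
approach, for each individual and chromosome an AR($p$) model is fitted by
Yule–Walker to the local-ancestry series along the marker grid, with $p
\le \lfloor 10\log_{10} n\rfloor$ chosen by AIC
($n\log\hat\sigma^2_p + 2p$, ties to the smaller order), and the effective
sample size is

$$
\mathrm{ESS} = \frac{n\,\widehat{\mathrm{var}}(x)}{\hat s(0)},
\qquad
\hat s(0) = \frac{\hat\sigma^2}{(1 - \sum_j \hat\phi_j)^2},
$$

clamped to $[1, n]$; a chromosome with constant ancestry contributes one
test. Per-individual chromosome ESS values are summed and averaged across
individuals to give $M_\mathrm{eff}$, and the family-wise threshold is
$\alpha = \mathrm{FWER}/M_\mathrm{eff}$ (e.g.
`significanceThreshold(66.84)` gives $\alpha$ = 7.48e-4, $-\log_{10}\alpha$
= 3.13). The implementation reproduces the standard `coda` estimator on
identical series (a cross-check test asserts agreement); ESS is invariant
to the $\{0,\tfrac12,1\}$ versus $\{0,1,2\}$ ancestry coding because it is
scale-free.

Significant regions are contiguous runs of markers within a one-unit drop
of the peak score — LOD $=(\beta_2/\mathrm{SE})^2 / (2\ln 10)$ by default,
optionally $-\log_{10} p$ — which approximates a 95% support interval.
Region bounds are the first and last qualifying marker positions; nothing
is interpolated, because exome markers are sparse.

## Fine-mapping, conditioning, stratified meta-analysis

SNPs that drive an ancestry association must differ in frequency between
the ancestral populations, so inside each significant region only SNPs
with $\delta = |f_\mathrm{AFR} - f_\mathrm{EUR}| > 0.4$ are tested:
OLS of the phenotype on allele dosage with age, age², sex, BMI and the
first 10 genotype principal components, Bonferroni-corrected at the
phenotype-level count of $\delta$-selected SNPs (e.g. 0.05/21 = 2.38e-3).
The PCs come from the cohort's own standardized dosage matrix
(mean-imputed missing calls) — a reference-based projection would need
external panels the package deliberately does not fetch.

Whether the SNPs *explain* the ancestry signal is tested two ways:

* **Conditional scans** (`conditionalScan()`): re-run the ancestry scan
  with candidate SNP dosages as covariates and compare the prior peak's
  p-value before/after. Verdicts follow the usual reading: conditional
  $p \ge 0.05$, fully explained; $\alpha \le p < 0.05$, partially
  explained; $p < \alpha$, unexplained.
* **Stratified meta-analysis** (`stratifiedMeta()`): within each
  local-ancestry stratum at the SNP ($L = 0, \tfrac12, 1$) the genotype
  test cannot be confounded by local ancestry, so per-stratum effects
  (covariate-adjusted by default; stratification replaces PC adjustment)
  are pooled by DerSimonian–Laird random effects
  ($Q$, $\tau^2 = \max\{0, (Q - k + 1)/(\sum w - \sum w^2/\sum w)\}$,
  inverse-variance weights $1/(\mathrm{SE}^2+\tau^2)$). Strata under 30
  individuals are excluded and reported; fewer than two usable strata
  makes the SNP not assessable — at a few hundred individuals this is
  common, which is exactly the small-stratum caveat the design inherits.

## The cohort simulator

Nothing downloadable reproduces a protected clinical cohort, so the
package ships a generative simulator whose defaults emulate an African
American exome cohort and are the conditions under which every calibration
suite runs:

* **Ancestry tracts.** Individual African proportion $q \sim$ Beta with
  mean 0.767, SD 0.128. Each haplotype follows a two-state Markov chain
  along the genetic map with stationary distribution $(q, 1-q)$ and
  $P(\text{copy previous state}) = e^{-g d}$ over $d$ Morgans — the
  hybrid-isolation (single admixture pulse) tract model with $g = 6$
  generations, the simplest model consistent with a single-pulse history;
  continuous gene flow is not modelled. The default map is 22 autosomes
  totalling ~35.6 Morgans with markers every 0.5 cM (1 cM/Mb), an
  exome-sparse grid: at these settings an individual shows ~127 observed
  diploid ancestry switch points, matching what a whole-exome design
  sees (denser maps would see more). How map length and marker sparsity
  combine is exposed (`g`, `chromosomes`, `markerSpacingCM`) rather than
  hard-coded.
* **Genotypes.** Given the haplotype's ancestry at a marker, each allele
  is Bernoulli($f_\mathrm{AFR}$) or Bernoulli($f_\mathrm{EUR}$); a
  configurable fraction (default 10%) of markers is strongly
  ancestry-differentiated ($\delta \sim U(0.45, 0.9)$), the rest nearly
  shared. Markers are independent given ancestry — there is no
  within-population LD, so the admixture LD the scan exploits is present
  but fine-scale haplotype structure is not. This is the main gap between
  simulated and real data: passing tests show the *scan machinery* is
  correct and calibrated, not that real exomes carry no LD complications.
* **Phenotypes.** True diastolic BP follows the scan equation itself
  (defaults: intercept 62.3, global-ancestry effect +8 mmHg — giving the
  observed ancestry–DBP correlation of ~0.12 — age 0.05/yr, male +1,
  BMI 0.05 per kg/m², residual SD 8.8, total SD ≈ 9 around a mean of 73);
  systolic BP adds a truncated-normal pulse pressure (mean 52, SD 10.7,
  floor 10), so SBP averages ~125 with SD ~14 and always exceeds DBP.
  Medication (target rate 45%) is a logistic function of true SBP with
  its intercept calibrated to the target rate; stored raw pressures have
  the treatment offsets subtracted so that `preparePhenotypes()` recovers
  the generative scale exactly. Covariates: age $\sim U(45, 65)$, 74%
  female, BMI $\sim N(32, 10)$ truncated at 15.
* **Determinism.** One run seed; each stage (ancestry, genotypes,
  covariates, phenotypes) draws from a deterministically derived
  sub-stream, so any stage can be re-run bit-identically.

## Numerical and design choices

* **QC boundaries are strict**: call rate < 0.98, MAF < 0.005 and HWE
  exact p < 5.7e-7 remove a marker; a marker at a boundary is retained.
  All flags are recorded even when one marker fails several rules. The
  HWE test is the exact conditional test (sum of configurations no more
  probable than the observed one, no mid-p); probabilities are compared
  with a 1e-9 relative tolerance so floating-point ties count as ties.
  Read-level GQ/DP filters need read data and are documented as upstream
  steps, as is sample-level QC (sex checks, relatedness, PC outliers).
* **LD pruning** works on 200-marker windows stepping by 20 at
  $r^2 > 0.1$ (pairwise-complete Pearson on dosages), keeping the
  higher-depth member of an offending pair; depth ties keep the
  lower-position marker so output is deterministic. Pruning serves
  ancestry inference (all-MAF marker set); association runs on the
  MAF-filtered set — both paths are exposed.
* **Degenerate loci**: a marker where $G - L$ has zero variance gets NA
  statistics and a warning, never silent removal; a cohort with constant
  global ancestry drops $G$ (it is the intercept) with a warning.
* **Missingness**: dosages may be missing (listwise deletion per model);
  local ancestry may not — the scan needs a call at every locus, and the
  upstream caller is expected to be complete.
* **Conditioning SNP collinear with a covariate** is an error naming the
  columns, not a silent drop.

## Problem sizes used by the test suites

The calibration suites run at the cohort scale the analysis targets
(n = 484) but on compact marker panels chosen to keep the regime right
(marker spacing well below the tract scale $1/g$, several chromosomes):
type-I error uses 2000 locus-tests on effectively independent loci (100
single-marker chromosomes × 20 cohorts); effect recovery and localization
use a 1.6-Morgan chromosome with 4-cM spacing and 200 replicates at the
effect sizes the scan is meant to detect (|β₂| = 5.28 and 7.94 mmHg);
mediation uses a strongly differentiated causal SNP
($f_\mathrm{EUR} = 0.05$, $f_\mathrm{AFR} = 0.95$, +6 mmHg/allele) so that
"fully mediated" is unambiguous — with a weak mediator the argmax peak's
winner's curse contaminates the conditional p-value and the test would
measure the fixture rather than the method. The threshold-calibration
suite uses six 1.5-Morgan chromosomes at 1-cM spacing, n = 100, with a
500-permutation min-p threshold as oracle and 500 independent null genome
scans for the family-wise error rate.

## Known limitations

* **The effective-tests threshold is anticonservative.** Measured against
  the permutation oracle, the AR-spectral $M_\mathrm{eff}$ undercounts the
  effective tests of the scan *maximum*: ancestry autocorrelation measures
  how fast the predictor decorrelates, not how many near-independent
  chances the scan maximum gets, and the Yule–Walker AR coefficient is
  biased away from 1 when a chromosome holds only a handful of ancestry
  switches ($g \cdot T_\mathrm{chrom}$ of order 10). In our null
  experiments the $M_\mathrm{eff}$ threshold exceeds the permutation
  threshold several-fold and the realized family-wise error rate is
  ~0.2 rather than 0.05, across marker densities and map scales. This
  reproduces the published behaviour of the method; users who need strict
  FWER control should calibrate by permutation (the acceptance suite
  shows exactly how) and read $M_\mathrm{eff}$-based regions as a
  screening threshold.
* The simulator has no within-population LD, no X chromosome, and no
  coalescent-accurate haplotypes.
* Mixed-model association, case-control admixture mapping and
  more-than-two-way ancestry models are out of scope.
* Reported Shapiro–Wilk statistics on any real cohort depend on that
  cohort's data; the package only recomputes them on whatever data it is
  given.

## A worked example

```{r example, eval = FALSE}
library(admixscan)

params <- simParams(nIndividuals = 484, causalLocus = 2000,
                    effects = list(beta2 = 5.28), seed = 1)
x <- simulateAdmixedCohort(params)
x <- preparePhenotypes(qcFilter(x, admixConfig())$experiment)

mres <- effectiveTests(x)                   # Meff and alpha
scan <- admixtureScan(x, "dbp_adj", alpha = sigThreshold(mres))
regions <- peakRegions(scan, sigThreshold(mres))
reg <- regionalAssociation(x, regions, "dbp_adj")
hits <- scanStats(scan)$id[which.min(scanStats(scan)$p)]
cond <- conditionalScan(x, "dbp_adj", snps = hits, regions = regions,
                        alpha = sigThreshold(mres))
mediation(cond)
```

Or in one call: `runPipeline(admixConfig(sim = params), outDir = "run/")`,
which writes every stage's output (VCF, ancestry and phenotype TSVs, scan
tables, `meff.json`, `report.json`) with provenance headers carrying the
package version, seed and config hash.
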