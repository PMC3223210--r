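---
title: "Methods: simulating and benchmarking chemosensory phenotyping for GWAS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and benchmarking chemosensory phenotyping for GWAS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(propbench)
```

`propbench` simulates a bitter-taste cohort dominated by one strong receptor
locus, measures it with the two standard sensory instruments (adaptive
staircase thresholds and gLMS intensity ratings), and evaluates analysis
designs with a from-scratch GWAS engine and analytic power theory. This
vignette is the package's account of the underlying models, every default
that matters, the numerical conventions, and what the simulation does and
does not capture.

## 1. The latent threshold model

Subject $i$'s true detection threshold on the log10-mM scale is

$$\theta_i = m_{D_i} + \beta_{\text{age}}(\text{age}_i - \bar a) + e_i,
\qquad e_i \sim N(0, V_e),$$

where $D_i \in \{0,1,2\}$ counts copies of the sensitive allele at the causal
SNP and $m_d = \log_{10}$ of the genotype-class geometric means (defaults
0.37, 0.113, 0.047 mM — the class means are encoded exactly as configured,
including their slight dominance deviation). On each phenotyping session a
day effect $u_{ij} \sim N(0, \sigma_{\text{day}}^2)$ shifts the threshold:
the staircase measures $\theta_i + u_{ij}$.

**The variance budget.** The additive genetic variance
$V_A = \mathrm{Cov}(m_D, D)^2/\mathrm{Var}(D)$ is fixed once the class means
and the allele frequency (default 0.46, Hardy–Weinberg class weights) are
set. The calibration solves, in closed form, for the residual variance $V_e$
and age slope $\beta_{\text{age}}$ such that the causal SNP explains
`target_causal_r2` (default 0.49) and age explains `age_effect_r2` (default
0.038) of the *reference phenotype variance* $V_P = V_A / r^2_{\text{causal}}$.

Two calibration conventions are supported, and the choice matters:

* `calibration = "measured"` (default): $V_P$ is the variance of the
  *observed* phenotype — the log-average of `n_measurement_repeats = 2`
  sessions — so the latent total is $V_T = V_P - \sigma_{\text{day}}^2/2$.
  With the defaults this yields $V_P \approx 0.208$, $V_e \approx 0.057$,
  and three consequences at once: the measured duplicate-average phenotype
  carries an additive causal $r^2 \approx 0.49$, measurement error accounts
  for $\tfrac{\sigma_{\text{day}}^2/2}{V_P} \approx 0.19$–$0.20$ of observed
  variance, and the age share is 3.8% of the same observed variance. These
  three quantities form a single coherent decomposition of one phenotype,
  which is why measured calibration is the default.
* `calibration = "latent"`: the target $r^2$ is imposed on the noiseless
  $\theta$ itself; the observed phenotype then carries $r^2 \approx 0.41$
  and an error share of ~0.16. Useful when the latent trait is the object of
  interest.

The budget is infeasible (a calibration error) when the class-mean variance
plus the age and measurement-noise shares exceed $V_P$ — e.g. when a very
large $r^2$ is requested of class means that already embed dominance.

$\sigma_{\text{day}} = 0.2836$ is derived from the Gaussian identity
$E|u_{i1}-u_{i2}| = 2\sigma/\sqrt{\pi} = 0.32$: the generator matches the
stated first moment of day-to-day variability with the minimal (Gaussian)
model. A Gaussian day effect puts ~12% of subjects beyond 0.62 log10 units
between sessions; real panels can show a heavier tail (~17%), which this
model deliberately does not reproduce — tests that pass under Gaussian day
effects say nothing about heavy-tailed session drift.

**Covariates.** Age is uniform on [18, 47] (only the range and mean of the
emulated panel are known; uniform is the simplest model matching both), sex
is Bernoulli(0.5), BMI is normal(25.5, 4.5²) truncated to [16.6, 46.1].

**Genotypes.** Null SNPs follow the Balding–Nichols model: ancestral
frequencies uniform on [0.05, 0.95], per-population frequencies
Beta-distributed with divergence `fst` (default 0.1 across 2 populations),
subject frequencies mixed by uniform-Dirichlet admixture proportions — a
caricature of a continuously admixed urban cohort. The causal SNP's
frequency is pinned to 0.46 in every population, so its signal carries no
stratification confound by construction; LD partners copy each causal
haplotype with probability `ld_copy_prob` (default 0.9, giving dosage
correlation ≈ 0.9). Only pairwise LD with the causal SNP is modelled — enough
for conditional-analysis experiments, nothing like a realistic LD map.

The default panel is 5000 SNPs (4997 null + causal + 2 partners). This is
not cosmetic: ancestry PCs are estimated from the panel, and with only a few
hundred SNPs the correlated causal trio becomes a *supercritical spike* of
the dosage covariance at $n = 225$ (the detection threshold is
$1+\sqrt{m/n}$), so one estimated PC partially aligns with the causal
dosage and covariate residualisation destroys real signal. At 5000 SNPs the
trio is far below the detection edge and the PCs behave like chip-density
ancestry axes.

## 2. The staircase instrument

The dilution ladder has 25 rungs from 3.2 mM down to 0.32 µM in 1/6-log10
steps (1.468-fold); protocol constants (4-down/1-up, 5 reversals, estimate
from the last 4, starts at 0.047/0.689 mM selected by a noiseless pre-test
against 0.2 mM, 60-trial budget) are all exposed in `staircase_config()`.
Conventions the protocol description leaves open, and how they are resolved:

* **Reversal average.** "Average of the last four reversal concentrations"
  is computed as the *geometric* mean (arithmetic mean of log10 values),
  consistent with the logarithmic ladder and log-scale analysis; the
  arithmetic option is one flag away.
* **Reversal bookkeeping.** A reversal is logged at the concentration where
  the direction of movement flips; the run stops the moment the fifth
  reversal is logged. Step size is one rung throughout (no step-halving).
* **Boundaries.** Moves are clamped at the ladder ends; clamped moves count
  neither as moves nor as reversals. A run pinned at an end (day threshold
  outside the tested range) never converges; the per-run object reports
  `converged = FALSE` with no estimate.
* **Censoring at cohort level.** `measure_thresholds()` records pinned runs
  at the boundary concentration by default (`censor = "bounds"`), as a lab
  would record "threshold ≥ highest concentration". Dropping those subjects
  instead (`censor = "drop"`) truncates the upper tail of the insensitive
  class and biases its geometric mean ~3–5% low; censoring keeps the class
  means nearly unbiased (~1–3% low, from the residual tail mass). Runs that
  merely exhaust the trial budget mid-ladder are always treated as missing.
* **Psychometric function.** The default per-trial model is the noiseless
  step (detect iff concentration ≥ day threshold). A graded probit model
  (slope `sigma_p`, guess rate) is available, but note the 4-down/1-up rule
  converges to the ~84% point of a graded psychometric, which would bias
  threshold recovery upward; the step default keeps the estimator centred on
  $\theta$, which is what the calibration assumes. With the step model the
  staircase deterministically ends up oscillating between the two rungs
  straddling the day threshold, so the estimate is their log-midpoint:
  quantisation error is bounded by half a rung (1/12 log10) and averages out
  across subjects.

`measure_thresholds()` uses a lean inner loop without trial logging,
protocol-identical to `run_staircase()` (the equivalence is itself under
test), so 20,000 runs take well under a second.

## 3. The gLMS instrument

Session ratings follow a hinge on the log-concentration axis with a mildly
convex rise:

$$\text{rating}(c) = \mathrm{clip}_{[0,100]}\!\big(b_i + s_i \,
\max(0,\ \log_{10} c - \theta_i - u_{ij})^{\gamma} + \varepsilon \big),$$

water contributing no concentration term. Per-subject baselines
$b_i \sim N(5, 2^2)$ and slopes $s_i \sim N(20, 3^2)$ (both truncated at 0),
trial noise $\varepsilon \sim N(0, 12^2)$, exponent $\gamma = 1.5$. None of
these response parameters are externally given; they were fixed once so the
simulated instrument reproduces the benchmark's qualitative fingerprint —
insensitive homozygotes rate sub-threshold solutions like water, GWAS on
ratings at concentrations below the panel's mean threshold (~0.12–0.13 mM)
finds no genome-wide signal, while 0.32/1/3.2 mM give clean hits with
$r^2 \approx 0.3$ at 1 mM. The exponent is the one place the response model
is deliberately non-linear: with a linear hinge ($\gamma = 1$) no
slope/noise combination keeps near-threshold class separation below the
noise floor while preserving strong supra-threshold signal, because the
linear rise is too steep just above threshold. $\gamma = 1.5$ leaves the
one-decade-above-threshold rating at exactly $b_i + s_i$ (the exponent is
invisible there) and $\gamma = 1$ remains available. Presentation order is a
seeded random permutation per subject per session, as in the protocol.

## 4. The GWAS engine

QC retains SNPs with MAF > 0.05, call rate > 0.95 and 1-df chi-square
Hardy–Weinberg p > 1e-5 (strict inequalities; monomorphic SNPs get HWE p = 1
by convention and fall to the MAF filter). Ancestry PCs come from the
QC-passing panel *including* the causal region — the emulated pipeline
computed PCs on its entire dataset — with dosages centred by $2\hat p$,
scaled by $\sqrt{2\hat p(1-\hat p)}$, missing values mean-imputed for the
PCA only; the top-$k$ left singular vectors are obtained from the small
$n \times n$ Gram matrix.

Continuous phenotypes are residualised on an intercept, age, sex, BMI and
the first 10 PCs (collinear columns dropped with a warning), then each SNP
is fit by simple OLS of residual on dosage with a two-sided t-test;
`r2_snp` is the squared correlation. This two-step residualisation is the
emulated pipeline's own procedure; at finite $n$ it costs the causal SNP
the fraction of its dosage variance lying in the covariate span (~6% at
$n = 225$ with 13 regressors), so engine $r^2$ estimates sit slightly below
the generative target. Missing dosages are dropped pairwise per SNP. The
stacked-repeats representation simply duplicates subject rows — the point of
that representation is precisely that it violates the independence
assumption, which the engine must *not* silently repair.

Binary (taster/non-taster) phenotypes go through per-SNP logistic IRLS with
the same covariates inside the model — residualising a binary outcome is
ill-defined, so the covariate handling is asymmetric by design. Separation
and non-convergence (|linear predictor| > 25) are flagged and excluded from
p-value output rather than reported as spuriously tiny p-values. The taster
definition is geometric-mean threshold strictly below the cutoff (default
0.2 mM); a tie at the cutoff is a non-taster.

Genomic control converts two-sided p-values to 1-df chi-squares through the
quantile function (making it representation-agnostic), estimates
$\lambda = \text{median}(\chi^2)/0.4549$, and corrects only when
$\lambda > 1$; the correction is idempotent. QQ coordinates use the
$(i-0.5)/m$ plotting positions.

## 5. Power theory

$\text{power} = \Phi(\sqrt{s\,r^2/(1-r^2)} - z_{\text{crit}})$ with the
two-sided $z_{\text{crit}} = \Phi^{-1}(1-\alpha/2)$ by default
($\alpha = 5\times10^{-8}$). The one-sided convention is exposed because the
~11.5% detectability bound at $s = 225$, 50% power is convention-sensitive
(0.112 one-sided vs 0.117 two-sided); both are documented rather than
silently chosen. `min_subjects()` returns the exact integer crossing (seeded
by the closed form $s = \frac{1-r^2}{r^2}(z_{\text{crit}} + z_{\text{power}})^2$);
`min_r2()` bisects to 1e-6. At the defaults the solver gives 48 subjects for
90% power at $r^2 = 0.49$ and 53.5% power at $s = 225$, $r^2 = 0.12$ —
values the test suite recomputes, and which the simulation experiment
(below) confirms within Monte-Carlo error.

## 6. Experiments, problem sizes, and what passing means

The scripted experiments fix QC, covariates and genomic control across
conditions, and every report is reproducible from (config, seed). Choices
the protocol text leaves open: sub-panels are drawn without replacement,
independently across draws; "averaging" sub-panel results means averaging
$-\log_{10} p_{\min}$ across draws; conditional analysis residualises the
phenotype on the top SNP's dosage linearly (additive, matching the engine).

Problem sizes used by the test suite and `scripts/acceptance.R` are the
package's chosen working points: 500 replicate cohorts of $n = 100$ with
2000 null SNPs for the simulation–analytic power comparison (2000 keeps the
PCs free of the small-panel spike artefact at $n = 100$ while staying fast);
10,000 subjects for staircase class-mean recovery; 100 seeded cohorts of
$n = 120$ with 250 null SNPs for the representation-ordering properties;
1000 half-panel draws on a 225-subject cohort for the panel-size trade-off.
These sizes give Monte-Carlo standard errors comfortably inside the asserted
tolerances (e.g. the class-0 geometric mean is recovered within ~±3.5% at
$n = 10^4$, against a ±5% assertion).

What passing does *not* show: the generator has Gaussian day effects,
independent sessions, no learning or adaptation, no kinship, no realistic
LD, uniform age structure, and an idealised pre-test. Conclusions about
representation orderings and design trade-offs transfer to real data only
insofar as those ingredients are second-order for the comparisons made —
which is the benchmark's working hypothesis, not a theorem.

## 7. Known limitations

* Staircase censoring at the ladder top makes the insensitive-class
  geometric mean ~1–3% conservative; widening the ladder (not part of the
  emulated protocol) would remove it.
* The logistic scan refits the full IRLS per SNP; at chip scale one would
  use score tests. At the package's panel sizes this costs seconds.
* `stacked_repeats` genomic control corrects the *global* inflation
  ($\lambda \approx 1+\rho$, intraclass correlation $\rho \approx 0.7$ at
  the defaults); with Gaussian phenotypes the corrected causal signal is
  then close to the log-averaged one, so the stacked representation's
  post-correction penalty is milder here than in heavy-tailed real data.
* No X chromosome, no imputation dosages, no relatedness, no multi-allelic
  sites; the VCF interface is a minimal GT-only dialect.
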