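---
title: "Methods: genome-level dN/dS dynamics in tumor evolution"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: genome-level dN/dS dynamics in tumor evolution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dndshift)
```

## The problem

A tumor genome accumulates somatic point mutations under selection. The
ratio of nonsynonymous to synonymous substitution rates, dN/dS, summarizes
the regime: values near 1 indicate effectively neutral evolution, values
above 1 positive selection, values below 1 purifying selection. Multi-sample
designs -- pre/post treatment, primary/metastasis, serial primaries -- let
one ask how the regime *moves*: whether therapy pushes resistant tumors
toward neutrality, whether clonal (trunk) and subclonal (branch) mutations
sit in different regimes, and whether the distance from neutrality carries
prognostic information. `dndshift` implements that analysis end to end for
MAF-style somatic mutation tables plus coding reference sequences, and
ships a fully seeded synthetic-cohort generator so every stage is testable
without patient data.

## The estimator

The exome is treated as one concatenated coding sequence. From the
reference CDS we count, per codon, the number of nonsynonymous (nN) and
synonymous (nS) sites: at each codon position the synonymous fraction is
the number of the three possible substitutions that preserve the amino
acid, divided by three, so nN + nS = 3 per codon exactly. Substitutions
that create a stop count as nonsynonymous (nonsense mutations are
protein-changing); codons that *are* stops are excluded. Substitutions are
weighted equally -- no transition/transversion bias -- because the estimate
normalizes by raw site counts only; the counting is isolated in
`codon_site_counts()`/`build_site_table()` so a weighted scheme could be
swapped in.

With N nonsilent and S silent mutations observed in a sample,

$$ dN/dS = \frac{N / nN}{S / nS}. $$

The assumptions are that synonymous mutations are neutral and unsaturated
(no site mutated twice). Genes absent from the site table are dropped and
counted; indels, splice and UTR records (class `other`) never enter N or S
because per-site substitution theory does not cover them. Whether nonsense
mutations belong in N differs between published cohorts; the default class
map includes them, and `default_class_map(include_nonsense = FALSE)` or a
YAML override switches the convention.

### Validity gating

Sparse samples give wildly unstable ratios, so a sample is only
*quantifiable* when N + S >= 10 and S > 0. No pseudocounts are added: a
sample with S = 0 is excluded, not smoothed, because any smoothing constant
would dominate exactly where the data are weakest. The threshold of 10 is
not arbitrary: `min_mutation_threshold()` re-derives it by simulating
neutral samples (mutation type multinomial in the site masses) at growing
burden m and returning the first m where at least 95% of estimates are
finite and the median sits within 0.2 of 1. On the default synthetic
reference (nN/nS about 3) the finite-fraction clause alone forces
m around 11, since P(S = 0) = (nN/(nN+nS))^m; the derived value
lands at the same order as the operating threshold of 10. The criterion
(tolerance, confidence) is exposed because the exact rule behind any given
threshold choice is a judgment call; what matters is that the result is
insensitive to it within a factor of ~2.

### Regional estimates and background attribution

Somatic mutations are extremely sparse, so a regional estimate (a gene set,
typically >100 genes) augments its silent count with *background* silent
mutations -- those in genes harboring only silent mutations anywhere in the
genome -- attributed proportionally to the region's size. Size is measured
in synonymous-site mass (nS), the quantity that actually scales expected
silent yield; nucleotide length is available via `size_measure = "length"`.
Background genes are excluded from the region's direct counts first, so a
background mutation is never counted twice; with the whole genome as the
region the formula collapses to the plain sample estimate.

### Replicate error

`replicate_error()` pools the within-group standard deviation of dN/dS over
groups of same-patient, same-timepoint samples. The matching simulator
(`simulate_replicates()`) draws one underlying tumor mutation set per group
and lets each replicate detect each mutation with probability 0.8 (a
typical WES cross-replicate concordance): replicates share the tumor's
mutations, so their disagreement reflects detection dropout, not full
independent resampling, which would roughly double the apparent error. At
an underlying burden of 125 (about 100 detected) the pooled SD comes out
near 0.12.

## Paired regressions and the shift-to-neutrality test

For each patient the earlier and later sample (timepoint order; missing
timepoints fall back to ascending mutation count, then sample id) give an
ordered pair (dN/dS_1, dN/dS_2). `lms_fit()` is ordinary least squares of
the later on the earlier value; `bisquare_fit()` is the Tukey bisquare
IRLS fit (tuning constant 4.685, 50 iterations, tolerance 1e-6, via
`MASS::rlm`) for cohorts with hypermutator outliers. Two cohorts'
regressions are compared by the nested extra-sum-of-squares F test
(`compare_regressions_anova()`): pooled single line versus separate lines,
F on (2, nA + nB - 4) df.

The question "does this cohort deviate from a strict identity
relationship?" is answered by `reference_model_test()`. The construction
builds an artificial reference cohort on the same predictors whose response
is x + e, with e the residuals of the observed fit, and compares the two
regressions. A subtlety decides the default: OLS residuals are orthogonal
to the predictor and sum to zero, so the reference regression is *exactly*
the identity line and its residual sum of squares duplicates the observed
one. Feeding both groups to the two-group ANOVA therefore halves F and
doubles the error df, and simulation confirms the naive construction
rejects a true identity relationship at rate ~0.005 instead of 0.05.
Algebraically, the construction is equivalent to the classical test of
H0: (intercept, slope) = (0, 1),

$$ F = \frac{\left(\sum_i (y_i - x_i)^2 - RSS\right)/2}{RSS/(n-2)}
     \sim F_{2,\,n-2}, $$

which is exact under normal errors; that is what the default
(`reference = "exact"`) reports. The literal two-group construction
(`"paired-anova"`) and a variant that decouples residuals from their own x
by a deterministic cyclic shift (`"permuted"`) are kept for sensitivity
analysis. At the cohort sizes of interest (n = 30 pairs, response noise
0.1) the calibrated test holds its 5% level and has essentially full power
against a contraction with slope 0.5.

Regression direction is later-on-earlier throughout (the natural reading of
the paired design); the intercept p-value tests b = 0 in y = ax + b.
Errors-in-variables regression (both axes carry estimation noise) is
deliberately out of scope -- at mutation burdens of ~1000 the attenuation
of the slope is below 2%, smaller than the biases the tests are meant to
detect.

## Survival scans

Two derived quantities drive the clinical analyses: DIS = |1 - dN/dS_2|,
the distance from neutrality after the second sample, and
DELTA = dN/dS_2 - dN/dS_1, the change across the pair.

* `range_scan()` sweeps a (mu, sigma) grid; patients with dN/dS inside
  [mu - sigma, mu + sigma] are compared to those outside with a log-rank
  test.
* `paired_scan()` sweeps (DIS, DELTA) thresholds; a patient is classified
  `escape` when DIS >= its threshold, or when |DELTA| >= its threshold
  *and* dN/dS_2 ends outside the strict neutral band [0.9, 1.1] -- the
  guard keeps patients who wobble but land neutral in the neutral class.
  |DELTA| covers both exit directions; a signed option exists.

The prognosis direction of a cell is read from the difference in restricted
mean survival time up to the last observed event (the median can be
undefined under heavy censoring). Cells where either group is smaller than
5 are masked. Scan p-values are reported raw, as heatmaps of unadjusted
log-rank tests; a Benjamini-Hochberg column is available behind
`adjust = TRUE` and is labeled an extension, not part of the core readout.

`cox_drug_effects()` renders the drug analysis literally: each drug is an
independent 0/1 covariate in a proportional-hazards fit whose *duration*
variable is DIS itself, every record an event (DIS is fully observed, not
censored). HR > 1 then means exposure is associated with arriving closer
to neutrality. Because this duration reading is unusual, the conventional
construction -- survival time as duration, DIS and drugs as covariates --
is available as `variant = "time_as_duration"`. Zero distances are floored
at 1e-8 since Cox durations must be positive.

## Allele-frequency-resolved dynamics

Allele frequency acts as an approximate time axis: high-AF mutations are
enriched for early, clonal events. For each threshold t,
`af_correlation()` computes per sample the pair (N, dN/dS) restricted to
the early window AF > t and the late window AF < t, then correlates N with
dN/dS across the samples of one patient (Pearson). Patients need at least
5 AF-bearing samples; a cell needs at least 3 samples surviving the
mutation gate. Windows are half-open (low, high] so a grid partitions
(0, 1] exactly; "AF < t" windows use an open upper bound. Correlations are
computed within patients only -- pooling patients would mix baselines and
manufacture spurious correlation. No CCF correction for purity/ploidy is
attempted; AF is used as-is, which is the main caveat when reading the
panels as time.

Trunk/branch analysis uses exact mutation identity where the input provides
positions (`gene:position:class`), falling back to `gene:class:AF-bin`;
the key builder `mutation_key()` is exported so cross-cohort inputs behave
predictably. Trunk = mutations in every sample of the patient; branch =
each sample's remainder, pooled with each distinct mutation counted once.

## The synthetic cohort generator

`sim_config()` fixes the study conditions the package is tested under:

| knob | default | why |
|---|---|---|
| omega_1 law | log-uniform on [0.3, 3] | spans purifying to positive selection symmetrically around 1 on the log scale |
| contraction kappa | 0.5 | a visible but not degenerate shift toward neutrality |
| pair noise sd | 0.1 | matches the estimator's replicate error scale |
| burden law | log-uniform 50-2000 | sparse-to-hypermutated WES range |
| trunk / branch omega | 1.5 / 0.7 | positive clonal, purifying subclonal selection |
| trunk AF | Beta(8,8) on (0.3, 0.6) | clonal frequencies, above the 0.25 early anchor |
| branch AF | Beta(2,8) on (0, 0.35) | subclonal tail, below the 0.33 late anchor |
| survival | h0 = 0.05/month, beta = 2, center 0.5 | near-neutral patients (small DIS) die faster |
| censor rate | 0.2 | probability a patient is censored, at a uniform fraction of its event time |
| invalid rate | 0.05 | forces sub-threshold samples so validity branches are exercised |

Mutations are placed multinomially: nonsilent with probability
omega * nN / (omega * nN + nS), gene proportional to site mass. The
generator records ground truth (true omegas, compartments, hazard
parameters) in a sidecar that the pipeline under test never reads. A
(config, seed) pair reproduces every output byte for byte.

What the generator does *not* emulate -- per-gene mutation-rate
heterogeneity (a gamma-rate option exists for stress-testing background
attribution), trinucleotide signatures, copy-number structure, purity
effects, forward-time clonal dynamics. Passing tests therefore demonstrate
that the estimators and tests recover the parameters of this generative
model at realistic sizes; they do not certify robustness to every bias of
real sequencing data, which is why the robustness comparisons
(`compare_dnds_distributions()` across CNA/MSI/purity strata) exist as a
separate tool.

## Numerical choices and degenerate inputs

* nN + nS = 3 per codon holds exactly in floating point (nN is computed as
  3 - nS and (3 - k/3) + k/3 == 3 for k = 0..3).
* Genes with internal stops, ambiguous bases or length not divisible by 3
  are skipped with a warning, never repaired; a terminal stop is trimmed.
* Exact-fit degeneracies return F = 0, p = 1 (identical regressions) or
  F = Inf, p = 0 (separate lines fit perfectly, pooled does not).
* `MASS::rlm` cannot iterate from a zero residual scale; on exact-line
  input the bisquare fit returns the OLS solution, which is the IRLS fixed
  point with all weights 1.
* The MSI score boundary is strict: exactly 3.5 classifies as MSS.
* Sample ordering is a total order (timepoint, then burden, then id), so
  every pairing is reproducible across row permutations.

## Problem sizes used in the checks

The shipped tests run the estimator recovery at 10^4 mutations x 200
replicates per omega; the calibration of the shift test at 2000 simulated
cohorts of 30 pairs; trunk/branch recovery at 200 patients with 500
mutations per compartment; scan power at cohorts of 200 patients; Cox
recovery at 200 cohorts of 500 patients. These sizes keep every
distributional claim at a few percent of Monte-Carlo error while the whole
suite completes in about a minute.

## Limitations

Gene-level selection inference across patients (dNdScv-style), codon-model
maximum-likelihood omega, and synonymous-saturation corrections are out of
scope. The Cox duration reading of DIS is a literal rendering of the
analysis it mirrors and should be interpreted as an association statement
about distance from neutrality, not a causal treatment effect. AF windows
approximate time only as well as AF approximates cellular fraction.
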