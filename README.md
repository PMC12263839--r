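# dndshift

Genome-level dN/dS dynamics and selection regimes in tumor evolution.

Somatic point mutations accumulate in tumor genomes under selection, and
the ratio of nonsynonymous to synonymous substitution *rates* summarizes
the regime: dN/dS ≈ 1 is effectively neutral evolution, > 1 positive
selection, < 1 purifying selection. `dndshift` is for researchers with
multi-sample somatic cohorts (pre/post therapy, primary/metastasis, serial
biopsies) who want to quantify not just the regime of each sample but its
*movement* — in particular, a shift toward neutrality under treatment and
what that shift means for prognosis.

The core estimator treats the exome as one concatenated coding sequence.
With nN and nS the nonsynonymous and synonymous site counts of the
reference (per codon, the synonymous fraction of each position is the
number of amino-acid-preserving substitutions out of three, so
nN + nS = 3 per codon), and N and S the observed nonsilent and silent
mutation counts of a sample,

```
dN/dS = (N / nN) / (S / nS)
```

Samples with N + S < 10 or S = 0 are flagged non-quantifiable rather than
smoothed. Around this estimator the package provides:

* **IO** — MAF-like mutation TSVs, clinical tables with drug indicators,
  sample metadata, CDS FASTA (`read_maf`, `read_clinical`,
  `build_site_table`), with a configurable variant-class map and an
  MSI score classifier (unstable iff score > 3.5);
* **estimation** — per-sample profiles (`sample_dnds`,
  `cohort_profiles`), regional estimates with background
  silent-mutation attribution (`region_dnds`), trunk/branch
  (clonal/subclonal) partitions (`partition_clonal`,
  `trunk_branch_dnds`), allele-frequency windows (`af_window_dnds`),
  replicate error (`replicate_error`) and a simulation-based derivation
  of the minimal quantifiable burden (`min_mutation_threshold`);
* **paired regressions** — least-squares and Tukey-bisquare fits of
  later on earlier dN/dS (`lms_fit`, `bisquare_fit`), the two-cohort
  extra-sum-of-squares ANOVA (`compare_regressions_anova`) and a
  calibrated test of deviation from the identity relationship built on
  an artificial linear reference at matched noise
  (`reference_model_test`);
* **survival** — Kaplan-Meier and log-rank (`km_estimate`, `logrank`),
  systematic (µ ± σ) range scans and paired (DIS, Δ) neutral/escape
  scans with prognosis direction (`range_scan`, `paired_scan`,
  `classify_neutral_escape`), and Cox analysis of per-drug effects on
  the distance from neutrality (`cox_drug_effects`);
* **AF dynamics** — per-patient Pearson correlation of dN/dS with N in
  early/late allele-frequency windows (`af_correlation`);
* **simulation** — a fully seeded synthetic cohort generator
  (`sim_config`, `simulate_paired_cohort`, `simulate_patient_history`,
  `simulate_survival`, `simulate_drug_exposures`) emitting the exact
  file formats the pipeline reads, with ground truth in a sidecar.

Key derived quantities: **DIS** = |1 − dN/dS₂|, the distance from
neutrality after the later sample, and **Δ** = dN/dS₂ − dN/dS₁, the change
across the pair.

## Worked example

Simulate a 40-patient paired cohort whose second samples contract halfway
toward neutrality (κ = 0.5), estimate profiles, fit the paired regression,
and test the deviation from the identity line:

```r
library(dndshift)

ref <- generate_reference(n_genes = 50, codons_per_gene = 100, seed = 7)
ref$site_table
#> Site table: 50 genes, 15000 coding nt
#>   nN = 11324.00, nS = 3676.00 (nN/nS = 3.081)

cfg <- sim_config(seed = 7, n_patients = 40, kappa = 0.5)
cohort <- simulate_paired_cohort(cfg)
head(cohort$profiles[c("patient_id", "sample_id", "N", "S", "dnds", "valid")], 4)
#>   patient_id sample_id   N   S      dnds valid
#> 1       P001   P001_S1 324  30 3.5058990  TRUE
#> 2       P001   P001_S2 446  72 2.0108423  TRUE
#> 3       P002   P002_S1 200  86 0.7549309  TRUE
#> 4       P002   P002_S2 833 300 0.9013623  TRUE

lms_fit(cohort$pairs)
#> LMS fit (n = 38): dnds_2 = 0.4192 * dnds_1 + 0.6709
#>   R^2 = 0.6573; p(slope) = 6.84e-10; p(intercept) = 4.21e-10

reference_model_test(cohort$pairs)
#> ANOVA F(2, 36) = 66.6, p = 7.988e-13
```

Reading the output: patient P001 starts under positive selection
(dN/dS = 3.51) and moves toward 1 after the second sample (2.01); two of
the 80 samples fell below the validity gate, leaving 38 quantifiable
pairs. The fitted slope 0.42 (true contraction 0.5, plus estimation noise
on the x axis) with intercept 0.67 pulls the cohort toward the neutral
point, and the reference-model test rejects a strict identity
relationship decisively.

Linking the pairs to survival with a hazard that increases near
neutrality, the paired scan classifies patients neutral vs escape at each
threshold cell and attaches a log-rank p-value and direction:

```r
clin <- simulate_survival(cohort$pairs, h0 = 0.05, beta = 2, center = 0.5,
                          censor_rate = 0.2, seed = 8)
sc <- paired_scan(cohort$pairs, clin, dis_grid = c(0.2, 0.3, 0.4),
                  delta_grid = c(0.2, 0.3))
head(as.data.frame(sc), 3)
#>   dis_thr delta_thr         p     direction n_in n_out masked
#> 1     0.2       0.2 0.4411940 neutral_worse    7    31  FALSE
#> 2     0.3       0.2 0.2372095 neutral_worse   13    25  FALSE
#> 3     0.4       0.2 0.2372095 neutral_worse   13    25  FALSE
```

At 40 patients the cells point in the expected direction
(`neutral_worse`) but are not individually significant — the scan reaches
its nominal power around 200 patients (see the methods vignette for the
study sizes at which each property is verified).

A thin command-line front end over the same functions is installed at
`inst/cli/dndshift.R` (`estimate | pairs | scan | af | simulate | all`).

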