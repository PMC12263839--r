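test_that("synthetic reference is stop-free, conservative and reproducible", {
  ref <- generate_reference(10, 100, seed = 42)
  expect_length(ref$sequences, 10)
  expect_equal(ref$site_table$per_gene$nN + ref$site_table$per_gene$nS,
               rep(300, 10))
  expect_length(ref$site_table$skipped, 0)  # no internal stops by design
  ref2 <- generate_reference(10, 100, seed = 42)
  expect_identical(ref$sequences, ref2$sequences)
  expect_error(generate_reference(0, 10), ">= 1")
})

test_that("simulate_sample follows the binomial mutation-type law", {
  st <- test_site_table()
  nN <- st$totals$nN_total; nS <- st$totals$nS_total
  m <- simulate_sample(1, 1e4, st, seed = 43)
  p <- nN / (nN + nS)
  n_obs <- sum(m$variant_class == "nonsilent")
  expect_lt(abs(n_obs - 1e4 * p), 3 * sqrt(1e4 * p * (1 - p)))
  # omega >> 1 limit: essentially all nonsilent
  m2 <- simulate_sample(1e6, 1000, st, seed = 44)
  expect_gt(mean(m2$variant_class == "nonsilent"), 0.99)
  expect_equal(nrow(simulate_sample(1, 0, st)), 0)
  # AF law respected and positions unique
  expect_true(all(m$allele_frequency >= 0 & m$allele_frequency <= 1))
  expect_false(anyDuplicated(m$position) > 0)
})

test_that("paired cohort honors kappa limits and records ground truth", {
  cfg1 <- sim_config(seed = 45, kappa = 1, pair_noise_sd = 0,
                     n_patients = 20)
  c1 <- simulate_paired_cohort(cfg1, mutation_level = FALSE)
  expect_equal(c1$truth$omega_2, c1$truth$omega_1)
  cfg0 <- sim_config(seed = 46, kappa = 0, pair_noise_sd = 0,
                     n_patients = 20)
  c0 <- simulate_paired_cohort(cfg0, mutation_level = FALSE)
  expect_equal(c0$truth$omega_2, rep(1, 20))
  # determinism at the mutation level
  cfg <- sim_config(seed = 47, n_patients = 6)
  a <- simulate_paired_cohort(cfg)
  b <- simulate_paired_cohort(cfg)
  expect_identical(a$mutations, b$mutations)
  expect_identical(a$profiles, b$profiles)
  # truth sidecar aligns with the generated patients
  expect_setequal(a$truth$patient_id, unique(a$mutations$patient_id))
})

test_that("estimated pairs recover the contraction slope at mutation level", {
  cfg <- sim_config(seed = 48, n_patients = 200, kappa = 0.5,
                    pair_noise_sd = 0.1,
                    mutations_per_sample_law = function(n) rep(1000L, n),
                    invalid_rate = 0)
  cohort <- simulate_paired_cohort(cfg)
  fit <- lms_fit(cohort$pairs)
  expect_gt(fit$slope, 0.4)
  expect_lt(fit$slope, 0.6)
})

test_that("invalid-burden samples appear at the configured rate", {
  cfg <- sim_config(seed = 49, n_patients = 100, invalid_rate = 0.2)
  cohort <- simulate_paired_cohort(cfg)
  frac_invalid <- mean(!cohort$profiles$valid)
  expect_gt(frac_invalid, 0.05)
  expect_lt(frac_invalid, 0.4)
  # pipeline remains runnable: pairs derived from the valid remainder
  expect_gt(nrow(cohort$pairs), 10)
})

test_that("patient history separates compartments and is seed-stable", {
  st <- test_site_table()
  cfg <- sim_config()
  m <- simulate_patient_history(cfg, st, n_samples = 3, m_trunk = 50,
                                m_branch = 30, patient_id = "PX",
                                seed = 50)
  p <- partition_clonal(m)
  expect_length(p$trunk, 50)
  expect_true(all(lengths(p$branch_per_sample) == 30))
  # trunk fraction 1: everything clonal
  m2 <- simulate_patient_history(cfg, st, n_samples = 2, m_trunk = 40,
                                 m_branch = 0, seed = 51)
  expect_length(partition_clonal(m2)$trunk, 40)
  expect_identical(m, simulate_patient_history(cfg, st, n_samples = 3,
                                               m_trunk = 50, m_branch = 30,
                                               patient_id = "PX",
                                               seed = 50))
  # AF laws straddle the clonal/subclonal anchors
  trunk_af <- m$allele_frequency[mutation_key(m) %in% p$trunk]
  expect_true(all(trunk_af > 0.25))
})

test_that("survival generator links hazard to DIS and censors as asked", {
  pairs <- data.frame(patient_id = sprintf("P%02d", 1:500),
                      dis = rep(c(0.05, 0.95), 250))
  cl <- simulate_survival(pairs, h0 = 0.05, beta = 2, center = 0.5,
                          censor_rate = 0, seed = 52)
  expect_true(all(cl$event == 1))
  # beta > 0: near-neutral (small DIS) die faster
  near <- cl$survival_time[pairs$dis < 0.5]
  far <- cl$survival_time[pairs$dis > 0.5]
  expect_lt(median(near), median(far))
  all_cens <- simulate_survival(pairs, censor_rate = 1, seed = 53)
  expect_true(all(all_cens$event == 0))
})

test_that("written cohort files are read back consistently", {
  cfg <- sim_config(seed = 54, n_patients = 8)
  cohort <- simulate_paired_cohort(cfg)
  clin <- simulate_survival(cohort$pairs, seed = 55)
  dir <- tempfile("cohort")
  paths <- write_cohort(cohort, dir, clinical = clin)
  expect_true(all(file.exists(paths)))
  m <- read_maf(paths[["maf"]])
  expect_equal(nrow(m), nrow(cohort$mutations))
  expect_equal(sort(unique(m$sample_id)),
               sort(unique(cohort$mutations$sample_id)))
  st <- read_site_table(paths[["sites"]])
  expect_equal(st$totals$nN_total, cohort$site_table$totals$nN_total,
               tolerance = 1e-9)
  st_fa <- build_site_table(paths[["fasta"]])
  expect_equal(st_fa$totals$nS_total, cohort$site_table$totals$nS_total)
  cl2 <- read_clinical(paths[["clinical"]])
  expect_equal(nrow(cl2), nrow(clin))
})
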