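test_that("estimate_dnds implements (N/nN)/(S/nS) with validity gates", {
  expect_equal(estimate_dnds(30, 10, 3000, 1000)$dnds, 1)
  expect_equal(estimate_dnds(40, 5, 2000, 1000)$dnds, 4)
  below <- estimate_dnds(5, 4, 3000, 1000)
  expect_false(below$valid)
  expect_equal(below$reason, "below_threshold")
  nosil <- estimate_dnds(20, 0, 3000, 1000)
  expect_false(nosil$valid)
  expect_equal(nosil$reason, "no_silent")
  expect_error(estimate_dnds(1, 1, 0, 10), "positive")
  # scale invariance
  a <- estimate_dnds(12, 8, 3e7, 1e7)
  b <- estimate_dnds(12 * 5, 8 * 5, 3e7 * 5, 1e7 * 5)
  expect_equal(a$dnds, b$dnds)
  expect_equal(a$dnds, 0.5)
})

test_that("sample_dnds equals an independent brute-force recount", {
  st <- test_site_table()
  genes <- st$per_gene$gene
  set.seed(11)
  for (i in 1:100) {
    n <- sample(0:40, 1)
    m <- make_mutations(sample(genes, n, replace = TRUE),
                        sample(c("nonsilent", "silent", "other"), n,
                               replace = TRUE))
    prof <- sample_dnds(m, st)
    # brute force: direct tallies over the record list
    N <- 0; S <- 0
    for (j in seq_len(nrow(m))) {
      if (m$variant_class[j] == "nonsilent") N <- N + 1
      if (m$variant_class[j] == "silent") S <- S + 1
    }
    expect_equal(prof$N, N)
    expect_equal(prof$S, S)
    if (N + S >= 10 && S > 0)
      expect_equal(prof$dnds, (N / st$totals$nN_total) /
                     (S / st$totals$nS_total))
    else expect_false(prof$valid)
  }
})

test_that("mutations in unknown genes are dropped and counted", {
  st <- test_site_table()
  m <- make_mutations(c(st$per_gene$gene[1:12], "NOT_A_GENE"),
                      c(rep("nonsilent", 6), rep("silent", 7)))
  prof <- sample_dnds(m, st)
  expect_equal(prof$n_dropped_genes, 1)
  expect_equal(prof$N + prof$S, 12)
  empty <- sample_dnds(m[0, ], st)
  expect_equal(empty$N + empty$S, 0)
  expect_false(empty$valid)
})

test_that("region_dnds attributes background silent mutations by site mass", {
  st <- toy_site_table()
  m <- make_mutations(c("A", "A", "A", "A", "B", "B"),
                      c("nonsilent", "nonsilent", "nonsilent", "silent",
                        "silent", "silent"))
  r <- region_dnds(m, "A", st, allow_small = TRUE, min_mutations = 1)
  expect_equal(r$B, 2)
  expect_equal(r$S_eff, 1 + 2 * (200 / 400))
  expect_equal(r$dnds, (3 / 600) / (2 / 200))
  # B = 0 reduces to the plain region formula
  m2 <- make_mutations(c("A", "A", "A", "A"),
                       c("nonsilent", "nonsilent", "nonsilent", "silent"))
  r2 <- region_dnds(m2, "A", st, allow_small = TRUE, min_mutations = 1)
  expect_equal(r2$dnds, (3 / 600) / (1 / 200))
  # whole-genome region equals sample_dnds
  st2 <- test_site_table()
  set.seed(3)
  big <- simulate_sample(0.8, 500, st2, seed = 5)
  r3 <- region_dnds(big, st2$per_gene$gene, st2, allow_small = TRUE)
  expect_equal(r3$dnds, sample_dnds(big, st2)$dnds)
  # gates
  expect_error(region_dnds(m, character(0), st), "non-empty")
  expect_false(region_dnds(m, "A", st)$valid)  # below min_genes
})

test_that("clonal partition separates trunk from branches exhaustively", {
  m <- rbind(
    make_mutations(c("A", "B", "C"), "nonsilent", sample = "s1",
                   position = 1:3),
    make_mutations(c("A", "B", "D"), "nonsilent", sample = "s2",
                   position = c(1, 2, 4)))
  p <- partition_clonal(m)
  expect_setequal(p$trunk, c("A:1:nonsilent", "B:2:nonsilent"))
  expect_equal(unname(p$branch_per_sample[["s1"]]), "C:3:nonsilent")
  expect_equal(unname(p$branch_per_sample[["s2"]]), "D:4:nonsilent")
  # disjoint and jointly exhaustive
  for (s in names(p$branch_per_sample)) {
    expect_length(intersect(p$trunk, p$branch_per_sample[[s]]), 0)
    expect_setequal(union(p$trunk, p$branch_per_sample[[s]]),
                    p$leaf_per_sample[[s]])
  }
  # identical samples -> all trunk; disjoint -> empty trunk
  m2 <- rbind(make_mutations("A", "silent", sample = "s1", position = 1),
              make_mutations("A", "silent", sample = "s2", position = 1))
  expect_length(partition_clonal(m2)$branch_per_sample[["s1"]], 0)
  m3 <- rbind(make_mutations("A", "silent", sample = "s1", position = 1),
              make_mutations("B", "silent", sample = "s2", position = 2))
  expect_length(partition_clonal(m3)$trunk, 0)
  expect_error(partition_clonal(make_mutations("A", "silent")), ">= 2")
})

test_that("trunk/branch estimates recover simulated compartment selection", {
  st <- test_site_table()
  cfg <- sim_config(trunk_omega = 1.5, branch_omega = 0.7)
  m <- simulate_patient_history(cfg, st, n_samples = 3, m_trunk = 2000,
                                m_branch = 2000, seed = 8)
  p <- partition_clonal(m)
  tb <- trunk_branch_dnds(m, p, st)
  expect_gt(tb$trunk$dnds, 1)
  expect_lt(tb$branch$dnds, 1)
  # each leaf mixes the compartments, so lies between branch and trunk
  for (lf in tb$leaves) {
    expect_gt(lf$dnds, tb$branch$dnds)
    expect_lt(lf$dnds, tb$trunk$dnds)
  }
  # all-trunk patient: branch estimate invalid on zero mutations
  m_all <- simulate_patient_history(cfg, st, n_samples = 2, m_trunk = 100,
                                    m_branch = 0, seed = 9)
  tb2 <- trunk_branch_dnds(m_all, partition_clonal(m_all), st)
  expect_false(tb2$branch$valid)
  expect_true(tb2$trunk$valid)
})

test_that("AF windows select half-open intervals and partition the sample", {
  st <- test_site_table()
  g <- st$per_gene$gene[1]
  m <- make_mutations(rep(g, 4), rep("silent", 4),
                      af = c(0.1, 0.2, 0.3, 0.6))
  w_early <- af_window_dnds(m, st, 0.25, 1, min_mutations = 1)
  expect_equal(w_early$n_window, 2)  # AF > 0.25
  w_late <- af_window_dnds(m, st, -1e-9, 0.33, min_mutations = 1,
                           include_upper = FALSE)
  expect_equal(w_late$n_window, 3)   # AF < 0.33
  expect_error(af_window_dnds(m, st, 0.5, 0.2), "af_low < af_high")
  # windows over a partition of (0,1] sum to the non-missing total
  m2 <- make_mutations(rep(g, 50), rep("silent", 50),
                       af = c(runif(45), rep(NA, 5)))
  cuts <- seq(0, 1, 0.25)
  tot <- sum(vapply(seq_len(4), function(i)
    af_window_dnds(m2, st, cuts[i], cuts[i + 1], 1)$n_window, numeric(1)))
  expect_equal(tot, 45)
  expect_equal(af_window_dnds(m2, st, 0, 1, 1)$n_missing_af, 5)
})

test_that("replicate error pools within-group standard deviations", {
  prof <- data.frame(patient_id = c("p1", "p1", "p2", "p2"),
                     status = "rep", timepoint = 1,
                     dnds = c(0.9, 1.1, 1.0, 1.0),
                     valid = TRUE)
  re <- replicate_error(prof)
  expect_equal(re$sd, sqrt((0.02 + 0) / 2))  # two-point SD 0.1414 pooled with 0
  expect_equal(re$n_groups, 2)
  one <- prof[c(1, 3), ]
  expect_error(replicate_error(one), "no replicate group")
  ident <- data.frame(patient_id = "p", status = "rep", timepoint = 1,
                      dnds = c(1.2, 1.2), valid = TRUE)
  expect_equal(replicate_error(ident)$sd, 0)
})

test_that("mutation threshold derivation is deterministic and monotone", {
  st <- test_site_table()
  # vacuous criterion
  expect_equal(min_mutation_threshold(st, tolerance = Inf, conf = 0,
                                      reps = 50, seed = 1), 1)
  t_tight <- min_mutation_threshold(st, tolerance = 0.2, reps = 500,
                                    seed = 4)
  t_loose <- min_mutation_threshold(st, tolerance = 1, reps = 500, seed = 4)
  expect_lte(t_loose, t_tight)
  expect_equal(min_mutation_threshold(st, reps = 500, seed = 4),
               min_mutation_threshold(st, reps = 500, seed = 4))
})

test_that("distribution comparison is calibrated and detects shifts", {
  set.seed(5)
  a <- rlnorm(100, 0, 0.3)
  expect_equal(compare_dnds_distributions(a, a)$p, 1)
  expect_lt(compare_dnds_distributions(a, a + 0.5)$p, 0.01)
  expect_error(compare_dnds_distributions(a, a[1:2]), ">= 3")
  # type-I calibration of the rank test on equal laws
  ps <- replicate(200, compare_dnds_distributions(rlnorm(30, 0, 0.3),
                                                  rlnorm(30, 0, 0.3))$p)
  expect_gt(mean(ps < 0.05), 0.005)
  expect_lt(mean(ps < 0.05), 0.12)
})
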