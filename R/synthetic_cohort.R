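with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  code
}

#' Simulation configuration for synthetic tumor cohorts
#'
#' Bundles every knob of the generator with defaults emulating the
#' multi-sample whole-exome cohorts the pipeline targets: patients with two
#' or more samples, per-sample point-mutation burdens log-uniform over
#' 50-2000 (spanning the sparse-to-hypermutated range), starting selection
#' strength omega_1 log-uniform over [0.3, 3], a controllable contraction
#' toward neutrality omega_2 = 1 + kappa (omega_1 - 1) + noise, clonal
#' (trunk) mutations at high allele frequency under positive selection and
#' subclonal (branch) mutations at low frequency under purifying selection,
#' and censored survival whose hazard decreases with the distance from
#' neutrality.
#'
#' @param seed integer master seed; fully determines every output.
#' @param n_genes,codons_per_gene size of the synthetic coding reference.
#' @param n_patients cohort size.
#' @param omega1_law function(n) drawing true initial omega values.
#' @param kappa contraction of omega_2 toward 1 (1 = identity, 0 = full
#'   collapse to neutrality).
#' @param pair_noise_sd Gaussian noise on omega_2.
#' @param mutations_per_sample_law function(n) drawing per-sample burdens.
#' @param trunk_omega,branch_omega selection strength of clonal / subclonal
#'   compartments.
#' @param trunk_af_law,branch_af_law functions(n) drawing allele
#'   frequencies; defaults Beta(8,8) scaled to (0.3, 0.6) and Beta(2,8)
#'   scaled to (0, 0.35), straddling the printed AF > 0.25 / AF < 0.33
#'   window anchors.
#' @param survival list `h0` (baseline hazard per month), `beta` (log-hazard
#'   slope on centered DIS), `center`, `censor_rate` (probability a patient
#'   is censored).
#' @param drugs named numeric vector: multiplicative effect of each drug on
#'   the DIS scale (0.5 halves the expected distance from neutrality).
#' @param invalid_rate fraction of samples whose burden is forced below the
#'   validity threshold (default 0.05), so cohorts exercise the
#'   non-quantifiable branches downstream.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(seed = 1, n_genes = 50, codons_per_gene = 100,
                       n_patients = 30,
                       omega1_law = function(n)
                         exp(stats::runif(n, log(0.3), log(3))),
                       kappa = 0.5, pair_noise_sd = 0.1,
                       mutations_per_sample_law = function(n)
                         round(10^stats::runif(n, log10(50), log10(2000))),
                       trunk_omega = 1.5, branch_omega = 0.7,
                       trunk_af_law = function(n)
                         0.3 + 0.3 * stats::rbeta(n, 8, 8),
                       branch_af_law = function(n)
                         0.35 * stats::rbeta(n, 2, 8),
                       survival = list(h0 = 0.05, beta = 2, center = 0.5,
                                       censor_rate = 0.2),
                       drugs = c(drug_A = 0.5, drug_B = 1.0),
                       invalid_rate = 0.05) {
  stopifnot(n_genes >= 1, codons_per_gene >= 1, kappa >= 0, kappa <= 1,
            pair_noise_sd >= 0, trunk_omega > 0, branch_omega > 0)
  cfg <- list(seed = seed, n_genes = n_genes,
              codons_per_gene = codons_per_gene, n_patients = n_patients,
              omega1_law = omega1_law, kappa = kappa,
              pair_noise_sd = pair_noise_sd,
              mutations_per_sample_law = mutations_per_sample_law,
              trunk_omega = trunk_omega, branch_omega = branch_omega,
              trunk_af_law = trunk_af_law, branch_af_law = branch_af_law,
              survival = survival, drugs = drugs,
              invalid_rate = invalid_rate)
  class(cfg) <- "sim_config"
  cfg
}

#' Generate a synthetic coding reference and its site table
#'
#' Draws stop-free random codon sequences (uniform over the 61 sense
#' codons) for `n_genes` genes and builds the site table.
#'
#' @param n_genes,codons_per_gene reference dimensions.
#' @param seed RNG seed (NULL = use current RNG state).
#' @return list `sequences` (named character vector) and `site_table`.
#' @export
generate_reference <- function(n_genes, codons_per_gene, seed = NULL) {
  if (n_genes < 1) stop("n_genes must be >= 1")
  with_seed(seed, {
    sense <- codon_site_lookup()$codon
    seqs <- vapply(seq_len(n_genes), function(i)
      paste(sample(sense, codons_per_gene, replace = TRUE), collapse = ""),
      character(1))
    names(seqs) <- sprintf("gene%04d", seq_len(n_genes))
    list(sequences = seqs, site_table = build_site_table(seqs))
  })
}

#' Write a synthetic reference to FASTA
#'
#' @param sequences named character vector of coding sequences.
#' @param path output path.
#' @export
write_reference_fasta <- function(sequences, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(sequences), path)
  invisible(path)
}

#' Simulate the mutation records of one sample
#'
#' Each of `m_total` point mutations is nonsilent with probability
#' `omega * nN / (omega * nN + nS)` (genome totals) and silent otherwise;
#' the gene is drawn proportionally to the corresponding site mass, and the
#' allele frequency from `af_law`. Positions are unique integers (offset by
#' `position_base`) so mutation identity is exact.
#'
#' @param omega true selection strength (> 0).
#' @param m_total number of mutations.
#' @param site_table a `site_table`.
#' @param af_law function(n) drawing allele frequencies.
#' @param sample_id,patient_id identifiers.
#' @param position_base offset for the synthetic position column.
#' @param seed RNG seed (NULL = current state).
#' @return mutation-record data.frame.
#' @export
simulate_sample <- function(omega, m_total, site_table,
                            af_law = function(n) stats::rbeta(n, 2, 5),
                            sample_id = "S1", patient_id = "P1",
                            position_base = 0L, seed = NULL) {
  stopifnot(omega > 0, m_total >= 0)
  with_seed(seed, {
    pg <- site_table$per_gene
    nN <- site_table$totals$nN_total
    nS <- site_table$totals$nS_total
    if (m_total == 0)
      return(data.frame(patient_id = character(0), sample_id = character(0),
                        gene = character(0),
                        variant_class = factor(character(0),
                          levels = c("nonsilent", "silent", "other")),
                        allele_frequency = numeric(0),
                        raw_class = character(0), position = integer(0),
                        stringsAsFactors = FALSE))
    p_ns <- omega * nN / (omega * nN + nS)
    nonsil <- stats::runif(m_total) < p_ns
    gene <- character(m_total)
    if (any(nonsil))
      gene[nonsil] <- sample(pg$gene, sum(nonsil), replace = TRUE,
                             prob = pg$nN)
    if (any(!nonsil))
      gene[!nonsil] <- sample(pg$gene, sum(!nonsil), replace = TRUE,
                              prob = pg$nS)
    data.frame(
      patient_id = patient_id, sample_id = sample_id, gene = gene,
      variant_class = factor(ifelse(nonsil, "nonsilent", "silent"),
                             levels = c("nonsilent", "silent", "other")),
      allele_frequency = af_law(m_total),
      raw_class = ifelse(nonsil, "Missense_Mutation", "Silent"),
      position = position_base + seq_len(m_total),
      stringsAsFactors = FALSE)
  })
}

#' Simulate replicate samples of the same tumors
#'
#' Replicate samples taken from one tumor at the same time share the
#' tumor's mutation set; what differs between them is which mutations each
#' sequencing run detects. Each group therefore draws one underlying sample
#' of `m_total` mutations, and every replicate keeps each mutation
#' independently with probability `detection_rate`. The pooled within-group
#' standard deviation of the resulting dN/dS estimates is the replicate
#' error of the estimator; full independent resampling would overstate it.
#'
#' @param omega true selection strength shared by all groups.
#' @param m_total underlying mutation burden per tumor.
#' @param site_table a `site_table`.
#' @param n_groups number of tumors.
#' @param n_replicates replicates per tumor (default 2).
#' @param detection_rate per-mutation detection probability (default 0.8).
#' @param min_mutations validity threshold for the profiles.
#' @param seed RNG seed (NULL = current state).
#' @return profile data.frame (one row per replicate) with `patient_id`
#'   identifying the group, ready for [replicate_error()].
#' @export
simulate_replicates <- function(omega, m_total, site_table, n_groups,
                                n_replicates = 2, detection_rate = 0.8,
                                min_mutations = 10, seed = NULL) {
  stopifnot(detection_rate > 0, detection_rate <= 1, n_replicates >= 2)
  with_seed(seed, {
    rows <- list()
    for (g in seq_len(n_groups)) {
      pid <- sprintf("G%03d", g)
      truth <- simulate_sample(omega, m_total, site_table,
                               patient_id = pid, sample_id = "T")
      for (r in seq_len(n_replicates)) {
        keep <- stats::runif(nrow(truth)) < detection_rate
        rep_m <- truth[keep, , drop = FALSE]
        rep_m$sample_id <- sprintf("%s_R%d", pid, r)
        prof <- sample_dnds(rep_m, site_table, min_mutations)
        prof$patient_id <- pid
        prof$status <- "replicate"
        prof$timepoint <- 1
        rows[[length(rows) + 1L]] <- prof
      }
    }
    do.call(rbind, rows)
  })
}

#' Simulate a paired two-sample cohort with contraction toward neutrality
#'
#' Per patient: omega_1 from `omega1_law`, then
#' `omega_2 = 1 + kappa (omega_1 - 1) + Normal(0, pair_noise_sd)` (draws
#' <= 0.01 are redrawn and counted). With `mutation_level = TRUE` the two
#' samples are generated mutation by mutation and pushed through the
#' estimator; otherwise the pairs carry the true omegas directly (useful
#' for studying the regression tests free of estimation noise).
#'
#' @param config a [sim_config()].
#' @param mutation_level simulate individual mutations (default TRUE).
#' @return list `truth` (patient, omega_1, omega_2, m_1, m_2, n_redrawn),
#'   `pairs` (data.frame compatible with the regression tests), and -- at
#'   mutation level -- `mutations`, `profiles`, `site_table`, `sequences`.
#' @export
simulate_paired_cohort <- function(config, mutation_level = TRUE) {
  with_seed(config$seed, {
    n <- config$n_patients
    omega1 <- config$omega1_law(n)
    omega2 <- numeric(n)
    redrawn <- 0L
    for (i in seq_len(n)) {
      repeat {
        o2 <- 1 + config$kappa * (omega1[i] - 1) +
          stats::rnorm(1, 0, config$pair_noise_sd)
        if (o2 > 0.01) break
        redrawn <- redrawn + 1L
      }
      omega2[i] <- o2
    }
    pid <- sprintf("P%03d", seq_len(n))
    m1 <- config$mutations_per_sample_law(n)
    m2 <- config$mutations_per_sample_law(n)
    if (config$invalid_rate > 0) {
      force1 <- stats::runif(n) < config$invalid_rate
      force2 <- stats::runif(n) < config$invalid_rate
      m1[force1] <- sample(0:9, sum(force1), replace = TRUE)
      m2[force2] <- sample(0:9, sum(force2), replace = TRUE)
    }
    truth <- data.frame(patient_id = pid, omega_1 = omega1,
                        omega_2 = omega2, m_1 = m1, m_2 = m2,
                        stringsAsFactors = FALSE)
    if (!mutation_level) {
      pairs <- data.frame(patient_id = pid,
                          sample_1 = paste0(pid, "_S1"),
                          sample_2 = paste0(pid, "_S2"),
                          dnds_1 = omega1, dnds_2 = omega2,
                          N_1 = m1, N_2 = m2, stringsAsFactors = FALSE)
      pairs$dis <- abs(1 - pairs$dnds_2)
      pairs$delta <- pairs$dnds_2 - pairs$dnds_1
      return(list(truth = truth, pairs = pairs, n_redrawn = redrawn))
    }
    ref <- generate_reference(config$n_genes, config$codons_per_gene)
    muts <- vector("list", 2 * n)
    pos <- 0L
    for (i in seq_len(n)) {
      for (k in 1:2) {
        m <- if (k == 1) m1[i] else m2[i]
        om <- if (k == 1) omega1[i] else omega2[i]
        rec <- simulate_sample(om, m, ref$site_table,
                               af_law = config$branch_af_law,
                               sample_id = paste0(pid[i], "_S", k),
                               patient_id = pid[i], position_base = pos)
        rec$timepoint <- rep(k, nrow(rec))
        pos <- pos + m
        muts[[2 * (i - 1) + k]] <- rec
      }
    }
    mutations <- do.call(rbind, muts)
    profiles <- cohort_profiles(mutations, ref$site_table)
    tp <- unique(mutations[c("sample_id", "timepoint")])
    profiles <- merge(profiles, tp, by = "sample_id", sort = FALSE)
    pairs <- derive_pairs(profiles, context = "first_last")
    list(truth = truth, pairs = pairs, mutations = mutations,
         profiles = profiles, site_table = ref$site_table,
         sequences = ref$sequences, n_redrawn = redrawn)
  })
}

#' Simulate a multi-sample patient with trunk and branch compartments
#'
#' Trunk mutations (shared by every sample) are generated once under
#' `trunk_omega` with the high-AF law; each sample adds private branch
#' mutations under `branch_omega` with the low-AF law.
#'
#' @param config a [sim_config()].
#' @param site_table a `site_table`.
#' @param n_samples number of samples (>= 2).
#' @param m_trunk,m_branch mutations in the trunk and per-sample branch.
#' @param patient_id identifier.
#' @param seed RNG seed (NULL = current state).
#' @return mutation-record data.frame over all samples.
#' @export
simulate_patient_history <- function(config, site_table, n_samples = 3,
                                     m_trunk = 200, m_branch = 200,
                                     patient_id = "P1", seed = NULL) {
  if (n_samples < 2) stop("n_samples must be >= 2")
  with_seed(seed, {
    trunk <- simulate_sample(config$trunk_omega, m_trunk, site_table,
                             af_law = config$trunk_af_law,
                             sample_id = "TRUNK", patient_id = patient_id,
                             position_base = 0L)
    out <- vector("list", n_samples)
    pos <- m_trunk
    for (s in seq_len(n_samples)) {
      sid <- sprintf("%s_S%d", patient_id, s)
      tr <- trunk
      tr$sample_id <- sid
      priv <- simulate_sample(config$branch_omega, m_branch, site_table,
                              af_law = config$branch_af_law,
                              sample_id = sid, patient_id = patient_id,
                              position_base = pos)
      pos <- pos + m_branch
      out[[s]] <- rbind(tr, priv)
    }
    do.call(rbind, out)
  })
}

#' Simulate censored survival linked to the distance from neutrality
#'
#' Event times are exponential with hazard
#' `h0 * exp(beta * (center - DIS))`: with `beta > 0`, patients near the
#' neutral regime (small DIS) die faster, the direction the survival scans
#' are designed to detect. A patient is censored with probability
#' `censor_rate`, at a uniform fraction of its event time.
#'
#' @param pairs data.frame with `patient_id` and `dis`.
#' @param h0,beta,center,censor_rate hazard model (see [sim_config()]).
#' @param seed RNG seed (NULL = current state).
#' @return clinical data.frame `patient_id`, `survival_time`, `event`.
#' @export
simulate_survival <- function(pairs, h0 = 0.05, beta = 2, center = 0.5,
                              censor_rate = 0.2, seed = NULL) {
  with_seed(seed, {
    n <- nrow(pairs)
    rate <- h0 * exp(beta * (center - pairs$dis))
    t_event <- stats::rexp(n, rate)
    censored <- stats::runif(n) < censor_rate
    time <- ifelse(censored, t_event * stats::runif(n), t_event)
    data.frame(patient_id = pairs$patient_id,
               survival_time = pmax(time, 1e-6),
               event = as.integer(!censored), stringsAsFactors = FALSE)
  })
}

#' Simulate drug exposures and their effect on the distance from neutrality
#'
#' Each drug is a Bernoulli(`p_exposed`) indicator per patient; a patient's
#' DIS is exponential with scale `base_scale` multiplied by the effects of
#' every drug received (an effect of 0.5 halves the expected distance,
#' i.e. pushes patients toward the neutral regime -- hazard ratio 2 in the
#' duration reading).
#'
#' @param config a [sim_config()] (supplies `drugs` and `n_patients`).
#' @param base_scale baseline expected DIS (default 0.5).
#' @param p_exposed exposure probability per drug (default 0.5).
#' @param seed RNG seed (NULL = `config$seed`).
#' @return data.frame `patient_id`, one 0/1 column per drug, `dis`.
#' @export
simulate_drug_exposures <- function(config, base_scale = 0.5,
                                    p_exposed = 0.5, seed = config$seed) {
  with_seed(seed, {
    n <- config$n_patients
    drugs <- config$drugs
    out <- data.frame(patient_id = sprintf("P%03d", seq_len(n)),
                      stringsAsFactors = FALSE)
    scale <- rep(base_scale, n)
    for (d in names(drugs)) {
      exposed <- stats::rbinom(n, 1, p_exposed)
      out[[d]] <- exposed
      scale <- scale * ifelse(exposed == 1, drugs[[d]], 1)
    }
    out$dis <- stats::rexp(n, rate = 1 / scale)
    out
  })
}

#' Write a synthetic cohort to the on-disk formats the pipeline reads
#'
#' Emits the MAF-like mutation TSV, clinical TSV (when survival data is
#' present), reference FASTA, site-table TSV and the ground-truth sidecar.
#'
#' @param cohort result of [simulate_paired_cohort()] at mutation level.
#' @param dir output directory (created if needed).
#' @param clinical optional clinical data.frame from [simulate_survival()].
#' @return invisibly, the named vector of paths written.
#' @export
write_cohort <- function(cohort, dir, clinical = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(maf = file.path(dir, "mutations.maf.tsv"),
             fasta = file.path(dir, "reference.fasta"),
             sites = file.path(dir, "site_table.tsv"),
             truth = file.path(dir, "truth.tsv"))
  write_maf(cohort$mutations, paths[["maf"]])
  write_reference_fasta(cohort$sequences, paths[["fasta"]])
  write_site_table(cohort$site_table, paths[["sites"]])
  if ("timepoint" %in% names(cohort$mutations)) {
    paths[["meta"]] <- file.path(dir, "sample_meta.tsv")
    meta <- unique(cohort$mutations[c("patient_id", "sample_id",
                                      "timepoint")])
    utils::write.table(meta, paths[["meta"]], sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  utils::write.table(cohort$truth, paths[["truth"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(clinical)) {
    paths[["clinical"]] <- file.path(dir, "clinical.tsv")
    utils::write.table(clinical, paths[["clinical"]], sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(paths)
}
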