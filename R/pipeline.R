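#' Assemble a pipeline run configuration
#'
#' Collects the paths and parameters shared by the `run_*` orchestration
#' functions. The configuration is serialized verbatim (YAML) into the
#' output directory of every run for reproducibility.
#'
#' @param maf path to the MAF-like mutation TSV.
#' @param out output directory.
#' @param cds_fasta path to the coding FASTA (exclusive with `site_table`).
#' @param site_table path to a serialized site table.
#' @param clinical optional clinical TSV.
#' @param sample_meta optional sample-meta TSV.
#' @param min_mutations dN/dS validity threshold (default 10).
#' @param context pairing context for [derive_pairs()].
#' @param mu_grid,sigma_grid,dis_grid,delta_grid scan grids.
#' @param seed integer seed used by any stochastic step.
#' @return list of class `run_config`.
#' @export
run_config <- function(maf, out, cds_fasta = NULL, site_table = NULL,
                       clinical = NULL, sample_meta = NULL,
                       min_mutations = 10, context = "consecutive",
                       mu_grid = seq(0.4, 1.6, 0.1),
                       sigma_grid = seq(0.05, 0.5, 0.05),
                       dis_grid = seq(0.1, 0.6, 0.05),
                       delta_grid = seq(0.1, 0.6, 0.05), seed = 1) {
  if (is.null(cds_fasta) && is.null(site_table))
    stop("one of cds_fasta or site_table is required")
  for (p in c(maf, cds_fasta, site_table, clinical, sample_meta))
    if (!is.null(p) && !file.exists(p)) stop("input does not exist: ", p)
  cfg <- list(maf = maf, out = out, cds_fasta = cds_fasta,
              site_table = site_table, clinical = clinical,
              sample_meta = sample_meta, min_mutations = min_mutations,
              context = context, mu_grid = mu_grid, sigma_grid = sigma_grid,
              dis_grid = dis_grid, delta_grid = delta_grid, seed = seed)
  class(cfg) <- "run_config"
  cfg
}

init_run <- function(config, step) {
  dir.create(config$out, showWarnings = FALSE, recursive = TRUE)
  plain <- config
  class(plain) <- NULL
  plain <- plain[!vapply(plain, is.null, logical(1))]
  yaml::write_yaml(plain, file.path(config$out, "run_config.yaml"))
  logf <- file.path(config$out, paste0(step, ".log"))
  cat(sprintf("step=%s seed=%d min_mutations=%d\n", step, config$seed,
              config$min_mutations), file = logf)
  logf
}

log_line <- function(logf, ...) cat(sprintf(...), "\n", sep = "", file = logf,
                                    append = TRUE)

load_site_table <- function(config) {
  if (!is.null(config$site_table)) read_site_table(config$site_table)
  else build_site_table(config$cds_fasta)
}

load_profiles <- function(config, site_table) {
  mutations <- read_maf(config$maf)
  meta <- if (!is.null(config$sample_meta))
    read_sample_meta(config$sample_meta) else NULL
  cohort_profiles(mutations, site_table, meta = meta,
                  min_mutations = config$min_mutations)
}

#' Estimate per-sample dN/dS profiles (pipeline step)
#'
#' Reads the mutation table and reference, estimates every sample's profile
#' and writes `profiles.tsv` (invalid samples are flagged, not dropped).
#'
#' @param config a [run_config()].
#' @return the profile data.frame, invisibly.
#' @export
run_estimate <- function(config) {
  logf <- init_run(config, "estimate")
  st <- load_site_table(config)
  prof <- load_profiles(config, st)
  utils::write.table(prof, file.path(config$out, "profiles.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  log_line(logf, "samples=%d valid=%d", nrow(prof), sum(prof$valid))
  invisible(prof)
}

#' Paired regression analysis (pipeline step)
#'
#' Derives ordered pairs, fits the least-squares and bisquare regressions,
#' runs the identity-reference deviation test, and writes `pairs.tsv` plus
#' a `fit_report.json`.
#'
#' @param config a [run_config()].
#' @return list `pairs`, `lms`, `bisquare`, `reference_test`, invisibly.
#' @export
run_pair_analysis <- function(config) {
  logf <- init_run(config, "pairs")
  st <- load_site_table(config)
  prof <- load_profiles(config, st)
  pairs <- derive_pairs(prof, context = config$context)
  if (nrow(pairs) < 3)
    stop("insufficient data: fewer than 3 quantifiable pairs")
  utils::write.table(pairs, file.path(config$out, "pairs.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  lms <- lms_fit(pairs)
  bis <- if (nrow(pairs) >= 5)
    tryCatch(bisquare_fit(pairs), error = function(e) {
      log_line(logf, "bisquare fit skipped: %s", conditionMessage(e))
      NULL
    }) else NULL
  ref <- if (nrow(pairs) >= 5) reference_model_test(pairs) else NULL
  report <- list(
    n_pairs = nrow(pairs),
    quantifiability = attr(pairs, "report"),
    lms = lms[c("slope", "intercept", "r_squared", "p_slope",
                "p_intercept", "n")],
    bisquare = if (!is.null(bis))
      bis[c("slope", "intercept", "r_squared", "p_slope", "p_intercept")],
    reference_test = if (!is.null(ref)) unclass(ref))
  jsonlite::write_json(report, file.path(config$out, "fit_report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  log_line(logf, "pairs=%d slope=%.4f", nrow(pairs), lms$slope)
  invisible(list(pairs = pairs, lms = lms, bisquare = bis,
                 reference_test = ref))
}

#' Survival scans (pipeline step)
#'
#' Runs the (mu, sigma) range scan on per-patient dN/dS and, when pairs are
#' derivable, the paired (DIS, DELTA) scan; writes long-format TSVs and a
#' JSON summary with masked-cell accounting.
#'
#' @param config a [run_config()]; `clinical` is required.
#' @return list `range`, `paired`, invisibly.
#' @export
run_survival_scan <- function(config) {
  if (is.null(config$clinical)) stop("clinical table required for scans")
  logf <- init_run(config, "scan")
  st <- load_site_table(config)
  prof <- load_profiles(config, st)
  clin <- read_clinical(config$clinical)
  ok <- prof[prof$valid, , drop = FALSE]
  # one dN/dS per patient for the range scan: the last ordered sample
  ok$n_mutations <- ok$N + ok$S
  last <- do.call(rbind, lapply(split(ok, ok$patient_id), function(p)
    utils::tail(order_samples(p), 1)))
  m <- merge(last, clin[c("patient_id", "survival_time", "event")],
             by = "patient_id")
  rng <- range_scan(m$dnds, m$survival_time, m$event, config$mu_grid,
                    config$sigma_grid)
  utils::write.table(rng, file.path(config$out, "range_scan.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  pairs <- derive_pairs(prof, context = config$context)
  prd <- if (nrow(merge(pairs, clin, by = "patient_id")) >= 2)
    paired_scan(pairs, clin, config$dis_grid, config$delta_grid) else NULL
  if (!is.null(prd))
    utils::write.table(prd, file.path(config$out, "paired_scan.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  summarize <- function(s) if (is.null(s)) NULL else
    list(cells = nrow(s), masked = sum(s$masked),
         significant = sum(s$p < 0.05, na.rm = TRUE))
  jsonlite::write_json(list(range = summarize(rng), paired = summarize(prd)),
                       file.path(config$out, "scan_summary.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  log_line(logf, "range cells=%d masked=%d", nrow(rng), sum(rng$masked))
  invisible(list(range = rng, paired = prd))
}

#' Allele-frequency heatmap (pipeline step)
#'
#' Writes the long-format per-patient AF-threshold correlation table.
#'
#' @param config a [run_config()].
#' @return the correlation data.frame, invisibly.
#' @export
run_af_heatmap <- function(config) {
  logf <- init_run(config, "af")
  st <- load_site_table(config)
  mutations <- read_maf(config$maf)
  res <- af_correlation_cohort(mutations, st,
                               min_mutations = config$min_mutations)
  if (is.null(res)) stop("insufficient data: no patient with >= 5 AF samples")
  utils::write.table(res, file.path(config$out, "af_correlation.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  log_line(logf, "patients=%d skipped=%d",
           length(unique(res$patient_id)), length(attr(res, "skipped")))
  invisible(res)
}

#' Simulate a cohort to disk (pipeline step)
#'
#' Generates a seeded synthetic paired cohort with linked survival and
#' writes the exact file formats the other steps consume.
#'
#' @param sim a [sim_config()].
#' @param out output directory.
#' @return named vector of written paths, invisibly.
#' @export
run_simulate <- function(sim, out) {
  cohort <- simulate_paired_cohort(sim)
  clin <- simulate_survival(cohort$pairs, h0 = sim$survival$h0,
                            beta = sim$survival$beta,
                            center = sim$survival$center,
                            censor_rate = sim$survival$censor_rate,
                            seed = sim$seed + 1)
  paths <- write_cohort(cohort, out, clinical = clin)
  invisible(paths)
}
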