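#' Genome-level dN/dS point estimate with validity gating
#'
#' Computes `dN/dS = (N/nN) / (S/nS)`: observed nonsilent and silent mutation
#' counts, each normalized by the corresponding number of available sites.
#' The estimate assumes synonymous mutations are neutral and unsaturated.
#' Samples with fewer than `min_mutations` total point mutations are flagged
#' invalid (sampling error dominates below that burden), as are samples with
#' no silent mutations (the ratio is undefined; no pseudocounts are added --
#' such cases are excluded, not smoothed).
#'
#' @param N nonsilent mutation count.
#' @param S silent mutation count.
#' @param nN,nS nonsynonymous / synonymous site counts (positive).
#' @param min_mutations validity threshold on `N + S` (default 10).
#' @return list with `dnds` (numeric, `NA` when invalid), `valid` (logical),
#'   `reason` (`"ok"`, `"below_threshold"` or `"no_silent"`).
#' @examples
#' estimate_dnds(30, 10, 3000, 1000)  # dnds = 1
#' @export
estimate_dnds <- function(N, S, nN, nS, min_mutations = 10) {
  if (nN <= 0 || nS <= 0) stop("site counts nN and nS must be positive")
  if (N < 0 || S < 0) stop("mutation counts must be non-negative")
  if (N + S < min_mutations)
    return(list(dnds = NA_real_, valid = FALSE, reason = "below_threshold"))
  if (S == 0)
    return(list(dnds = NA_real_, valid = FALSE, reason = "no_silent"))
  list(dnds = (N / nN) / (S / nS), valid = TRUE, reason = "ok")
}

count_ns <- function(mutations) {
  c(N = sum(mutations$variant_class == "nonsilent"),
    S = sum(mutations$variant_class == "silent"))
}

#' Per-sample dN/dS profile
#'
#' Tallies nonsilent and silent mutations of one sample against genome-total
#' site counts and applies [estimate_dnds()]. Mutations in genes absent from
#' the site table are dropped (their number is reported in the
#' `n_dropped_genes` column); `other`-class records never enter the counts.
#'
#' @param mutations mutation-record data.frame of a single sample.
#' @param site_table a `site_table`.
#' @param min_mutations validity threshold (default 10).
#' @return one-row data.frame: `patient_id`, `sample_id`, `N`, `S`, `dnds`,
#'   `valid`, `reason`, `n_dropped_genes`.
#' @export
sample_dnds <- function(mutations, site_table, min_mutations = 10) {
  stopifnot(length(unique(mutations$sample_id)) <= 1)
  known <- mutations$gene %in% site_table$per_gene$gene
  dropped <- sum(!known)
  m <- mutations[known, , drop = FALSE]
  ns <- count_ns(m)
  est <- estimate_dnds(ns[["N"]], ns[["S"]],
                       site_table$totals$nN_total, site_table$totals$nS_total,
                       min_mutations)
  data.frame(
    patient_id = if (nrow(mutations)) mutations$patient_id[1] else NA_character_,
    sample_id = if (nrow(mutations)) mutations$sample_id[1] else NA_character_,
    N = ns[["N"]], S = ns[["S"]], dnds = est$dnds, valid = est$valid,
    reason = est$reason, n_dropped_genes = dropped,
    stringsAsFactors = FALSE)
}

#' dN/dS profiles for every sample of a cohort
#'
#' Applies [sample_dnds()] per sample and merges per-sample metadata when
#' given.
#'
#' @param mutations mutation-record data.frame (many samples).
#' @param site_table a `site_table`.
#' @param meta optional sample-meta data.frame to merge on
#'   `(patient_id, sample_id)`.
#' @param min_mutations validity threshold.
#' @return data.frame with one row per sample.
#' @export
cohort_profiles <- function(mutations, site_table, meta = NULL,
                            min_mutations = 10) {
  parts <- split(mutations, mutations$sample_id)
  prof <- do.call(rbind, lapply(parts, sample_dnds, site_table = site_table,
                                min_mutations = min_mutations))
  rownames(prof) <- NULL
  if (!is.null(meta))
    prof <- merge(prof, meta, by = c("patient_id", "sample_id"),
                  all.x = TRUE, sort = FALSE)
  prof[order(prof$patient_id, prof$sample_id), , drop = FALSE]
}

#' Regional dN/dS with background silent-mutation attribution
#'
#' Because somatic mutations are extremely sparse, a region's silent count is
#' augmented by background silent mutations -- those in genes harboring only
#' silent mutations anywhere in the genome -- attributed proportionally to
#' the size of the region. Size is measured in synonymous-site mass by
#' default (the quantity that scales expected silent counts); nucleotide
#' length is available via `size_measure = "length"`. Background genes are
#' excluded from the region's own direct counts to avoid double counting.
#'
#' @param mutations mutation-record data.frame of one sample.
#' @param gene_subset character vector of region genes (subset of the site
#'   table).
#' @param site_table a `site_table`.
#' @param min_genes minimum region size in genes for a reliable estimate
#'   (default 100); smaller regions return invalid unless
#'   `allow_small = TRUE`.
#' @param min_mutations validity threshold on region `N + S_eff`.
#' @param allow_small bypass the region-size gate (for small worked
#'   examples).
#' @param size_measure `"sites"` (synonymous-site mass, default) or
#'   `"length"`.
#' @return list `dnds`, `valid`, `reason`, plus the intermediate counts
#'   `N`, `S`, `B`, `S_eff`.
#' @export
region_dnds <- function(mutations, gene_subset, site_table, min_genes = 100,
                        min_mutations = 10, allow_small = FALSE,
                        size_measure = c("sites", "length")) {
  size_measure <- match.arg(size_measure)
  if (length(gene_subset) == 0) stop("gene_subset must be non-empty")
  if (!all(gene_subset %in% site_table$per_gene$gene))
    stop("gene_subset contains genes absent from the site table")
  pg <- site_table$per_gene
  nN_region <- sum(pg[gene_subset, "nN"])
  nS_region <- sum(pg[gene_subset, "nS"])
  if (length(gene_subset) < min_genes && !allow_small)
    return(list(dnds = NA_real_, valid = FALSE, reason = "region_too_small",
                N = NA, S = NA, B = NA, S_eff = NA))
  byg <- split(mutations$variant_class, mutations$gene)
  bg_genes <- names(byg)[vapply(byg, function(v)
    any(v == "silent") && !any(v == "nonsilent"), logical(1))]
  bg_genes <- intersect(bg_genes, pg$gene)
  B <- sum(mutations$variant_class == "silent" & mutations$gene %in% bg_genes)
  region_direct <- setdiff(gene_subset, bg_genes)
  in_region <- mutations$gene %in% region_direct
  N <- sum(mutations$variant_class == "nonsilent" & in_region)
  S <- sum(mutations$variant_class == "silent" & in_region)
  frac <- if (size_measure == "sites")
    nS_region / site_table$totals$nS_total
  else sum(pg[gene_subset, "length_nt"]) / site_table$totals$length_total
  S_eff <- S + B * frac
  if (N + S_eff < min_mutations)
    return(list(dnds = NA_real_, valid = FALSE, reason = "below_threshold",
                N = N, S = S, B = B, S_eff = S_eff))
  if (S_eff == 0)
    return(list(dnds = NA_real_, valid = FALSE, reason = "no_silent",
                N = N, S = S, B = B, S_eff = S_eff))
  list(dnds = (N / nN_region) / (S_eff / nS_region), valid = TRUE,
       reason = "ok", N = N, S = S, B = B, S_eff = S_eff)
}

#' Mutation identity keys for trunk/branch partitioning
#'
#' Builds the most specific identity available: with a `position` column the
#' key is `gene:position:class`; otherwise `gene:class:AF` with AF rounded
#' to one decimal. The builder is exported so cross-cohort inputs behave
#' predictably.
#'
#' @param mutations mutation-record data.frame.
#' @return character vector of keys, one per record.
#' @export
mutation_key <- function(mutations) {
  if (!is.null(mutations$position) && !all(is.na(mutations$position))) {
    paste(mutations$gene, mutations$position, mutations$variant_class,
          sep = ":")
  } else {
    af_bin <- ifelse(is.na(mutations$allele_frequency), "NA",
                     sprintf("%.1f", mutations$allele_frequency))
    paste(mutations$gene, mutations$variant_class, af_bin, sep = ":")
  }
}

#' Partition a patient's mutations into trunk and branches
#'
#' Mutations present in every sample of the patient form the trunk of the
#' patient's phylogeny (clonal); the remainder of each sample is its branch
#' (subclonal/private). Mutation identity uses the most specific key the
#' input offers (see the `key` element of the result for the keys used).
#'
#' @param mutations mutation-record data.frame of one patient with >= 2
#'   samples.
#' @return object of class `clonal_partition`: list `trunk` (keys),
#'   `branch_per_sample`, `leaf_per_sample` (named lists of key vectors).
#' @export
partition_clonal <- function(mutations) {
  samples <- unique(mutations$sample_id)
  if (length(samples) < 2)
    stop("trunk/branch partition requires >= 2 samples")
  keys <- mutation_key(mutations)
  per_sample <- lapply(split(keys, mutations$sample_id), unique)
  trunk <- Reduce(intersect, per_sample)
  out <- list(trunk = trunk,
              branch_per_sample = lapply(per_sample, setdiff, y = trunk),
              leaf_per_sample = per_sample)
  class(out) <- "clonal_partition"
  out
}

#' @export
print.clonal_partition <- function(x, ...) {
  cat("Clonal partition:", length(x$trunk), "trunk mutations;",
      length(x$branch_per_sample), "samples, branch sizes:",
      paste(vapply(x$branch_per_sample, length, integer(1)), collapse = ", "),
      "\n")
  invisible(x)
}

dnds_of_keys <- function(mutations, keys, site_table, min_mutations) {
  all_keys <- mutation_key(mutations)
  sel <- mutations[!duplicated(all_keys) & all_keys %in% keys, , drop = FALSE]
  ns <- count_ns(sel)
  estimate_dnds(ns[["N"]], ns[["S"]], site_table$totals$nN_total,
                site_table$totals$nS_total, min_mutations)
}

#' Trunk, branch and leaf dN/dS of one patient
#'
#' Estimates dN/dS on the trunk (shared, clonal) mutation set, on the pooled
#' branch (private, subclonal) sets -- each distinct non-trunk mutation
#' counted once -- and on each leaf (every mutation of one sample).
#'
#' @param mutations mutation-record data.frame of one patient.
#' @param partition result of [partition_clonal()] on the same mutations.
#' @param site_table a `site_table`.
#' @param min_mutations validity threshold.
#' @return list `trunk`, `branch`, `leaves` (named list per sample), each an
#'   [estimate_dnds()] result.
#' @export
trunk_branch_dnds <- function(mutations, partition, site_table,
                              min_mutations = 10) {
  branch_keys <- unique(unlist(partition$branch_per_sample))
  leaves <- lapply(names(partition$leaf_per_sample), function(s)
    dnds_of_keys(mutations[mutations$sample_id == s, , drop = FALSE],
                 partition$leaf_per_sample[[s]], site_table, min_mutations))
  names(leaves) <- names(partition$leaf_per_sample)
  list(trunk = dnds_of_keys(mutations, partition$trunk, site_table,
                            min_mutations),
       branch = dnds_of_keys(mutations, branch_keys, site_table,
                             min_mutations),
       leaves = leaves)
}

#' dN/dS within an allele-frequency window
#'
#' Restricts a sample to mutations whose allele frequency lies in the
#' half-open window `(af_low, af_high]` (bounds configurable) and estimates
#' dN/dS there; high-AF windows enrich for early (clonal) mutations, low-AF
#' windows for late (subclonal) ones. Records with missing AF are skipped and
#' their count reported.
#'
#' @param mutations mutation-record data.frame of one sample.
#' @param site_table a `site_table`.
#' @param af_low,af_high window bounds, `0 <= af_low < af_high <= 1`.
#' @param min_mutations validity threshold inside the window.
#' @param include_lower,include_upper whether each bound is closed
#'   (defaults: lower open, upper closed, so windows over a grid partition
#'   `(0, 1]` exactly).
#' @return list as [estimate_dnds()] plus `n_window` (mutations retained) and
#'   `n_missing_af` (skipped for missing AF).
#' @export
af_window_dnds <- function(mutations, site_table, af_low, af_high,
                           min_mutations = 10, include_lower = FALSE,
                           include_upper = TRUE) {
  if (af_low >= af_high) stop("need af_low < af_high")
  af <- mutations$allele_frequency
  n_missing <- sum(is.na(af))
  lo <- if (include_lower) af >= af_low else af > af_low
  hi <- if (include_upper) af <= af_high else af < af_high
  keep <- !is.na(af) & lo & hi
  ns <- count_ns(mutations[keep, , drop = FALSE])
  est <- estimate_dnds(ns[["N"]], ns[["S"]], site_table$totals$nN_total,
                       site_table$totals$nS_total, min_mutations)
  c(est, list(N = ns[["N"]], S = ns[["S"]], n_window = sum(keep),
              n_missing_af = n_missing))
}

#' Pooled replicate error of dN/dS estimates
#'
#' Pooled within-group standard deviation of dN/dS over groups of replicate
#' samples (same patient, same status/timepoint, sequenced separately):
#' `sqrt(sum((n_g - 1) * sd_g^2) / sum(n_g - 1))`. Groups with fewer than
#' two valid estimates are ignored.
#'
#' @param profiles profile data.frame with `dnds` and `valid` columns.
#' @param group_cols columns defining a replicate group (default patient,
#'   status, timepoint -- whichever are present).
#' @return list `sd` (pooled SD), `n_groups`, `df` (pooled degrees of
#'   freedom).
#' @export
replicate_error <- function(profiles,
                            group_cols = c("patient_id", "status",
                                           "timepoint")) {
  group_cols <- intersect(group_cols, names(profiles))
  ok <- profiles[profiles$valid, , drop = FALSE]
  groups <- split(ok$dnds, ok[group_cols], drop = TRUE)
  groups <- groups[vapply(groups, length, integer(1)) >= 2]
  if (length(groups) == 0) stop("no replicate group with >= 2 valid estimates")
  ss <- vapply(groups, function(g) sum((g - mean(g))^2), numeric(1))
  df <- vapply(groups, function(g) length(g) - 1, numeric(1))
  list(sd = sqrt(sum(ss) / sum(df)), n_groups = length(groups),
       df = sum(df))
}

#' Derive the minimal mutation burden for reliable dN/dS
#'
#' Simulates neutral samples (mutation type multinomial with probabilities
#' proportional to nN and nS) at increasing burden m and returns the smallest
#' m at which the estimator behaves: the fraction of finite estimates (S > 0)
#' reaches `conf` and the median of the finite estimates lies within
#' `tolerance` of 1. Deterministic given `seed`.
#'
#' @param site_table a `site_table` (supplies the nN/nS ratio).
#' @param tolerance allowed deviation of the median from 1 (default 0.2).
#' @param conf required finite-estimate fraction (default 0.95).
#' @param reps neutral samples simulated per burden (default 2000).
#' @param seed RNG seed.
#' @param max_m search limit (default 1000).
#' @return integer threshold.
#' @export
min_mutation_threshold <- function(site_table, tolerance = 0.2, conf = 0.95,
                                   reps = 2000, seed = 1, max_m = 1000) {
  nN <- site_table$totals$nN_total
  nS <- site_table$totals$nS_total
  ratio <- nN / nS
  p_n <- nN / (nN + nS)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  for (m in seq_len(max_m)) {
    N <- stats::rbinom(reps, m, p_n)
    S <- m - N
    finite <- S > 0
    if (mean(finite) < conf) next
    est <- (N[finite] / S[finite]) / ratio
    if (abs(stats::median(est) - 1) <= tolerance) return(m)
  }
  stop("criterion not reachable within m <= ", max_m)
}

#' Compare two dN/dS distributions
#'
#' Rank-based (Wilcoxon/Mann-Whitney) two-sided test, used for robustness
#' checks such as comparing estimates across CNA, MSI or purity strata.
#'
#' @param group_a,group_b numeric vectors of valid dN/dS values (n >= 3
#'   each).
#' @return list `p`, `statistic`, `n_a`, `n_b`.
#' @export
compare_dnds_distributions <- function(group_a, group_b) {
  group_a <- group_a[is.finite(group_a)]
  group_b <- group_b[is.finite(group_b)]
  if (length(group_a) < 3 || length(group_b) < 3)
    stop("each group needs >= 3 valid values")
  wt <- stats::wilcox.test(group_a, group_b, exact = FALSE)
  list(p = wt$p.value, statistic = unname(wt$statistic),
       n_a = length(group_a), n_b = length(group_b))
}
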