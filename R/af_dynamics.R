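#' Pearson correlation with two-sided p-value
#'
#' Thin wrapper used by the allele-frequency heatmap: returns `NA` with a
#' validity flag instead of erroring when a vector is constant.
#'
#' @param xs,ys numeric vectors (n >= 3).
#' @return list `r`, `p`, `n`, `valid`.
#' @export
pearson <- function(xs, ys) {
  ok <- is.finite(xs) & is.finite(ys)
  xs <- xs[ok]; ys <- ys[ok]
  n <- length(xs)
  if (n < 3 || stats::var(xs) == 0 || stats::var(ys) == 0)
    return(list(r = NA_real_, p = NA_real_, n = n, valid = FALSE))
  ct <- stats::cor.test(xs, ys, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = n, valid = TRUE)
}

#' Allele-frequency-resolved dN/dS vs N correlation for one patient
#'
#' Allele frequency is an approximate time axis: high-AF mutations are
#' enriched for early (clonal) events, low-AF for late (subclonal) ones.
#' For each threshold t, every sample of the patient is restricted to its
#' early window (AF > t) and late window (AF < t); within each window the
#' sample contributes its `(N_window, dN/dS_window)` point, samples failing
#' the mutation-count gate are dropped, and the Pearson correlation between
#' N and dN/dS is computed across the remaining samples. A cell needs at
#' least `min_samples` contributing samples to be valid; the patient needs
#' at least `min_total_samples` samples with AF data to be analyzed at all.
#'
#' @param mutations mutation-record data.frame of one patient.
#' @param site_table a `site_table`.
#' @param thresholds AF threshold grid (default `seq(0.05, 0.95, 0.05)`).
#' @param min_mutations per-window validity gate (default 10).
#' @param min_samples minimum samples per valid cell (default 3).
#' @param min_total_samples patient eligibility (default 5).
#' @return object of class `af_correlation`: data.frame `patient_id`,
#'   `panel` (`early`/`late`), `threshold`, `r`, `p`, `n_used`, `valid`.
#' @export
af_correlation <- function(mutations, site_table,
                           thresholds = seq(0.05, 0.95, 0.05),
                           min_mutations = 10, min_samples = 3,
                           min_total_samples = 5) {
  has_af <- !is.na(mutations$allele_frequency)
  samples <- unique(mutations$sample_id[has_af])
  if (length(samples) < min_total_samples)
    stop("patient has fewer than ", min_total_samples,
         " samples with allele-frequency data")
  by_sample <- split(mutations, mutations$sample_id)
  pid <- mutations$patient_id[1]
  rows <- list()
  for (t in thresholds) {
    for (panel in c("early", "late")) {
      pts <- lapply(by_sample, function(m) {
        w <- if (panel == "early") {
          if (t >= 1) NULL  # empty window
          else af_window_dnds(m, site_table, t, 1, min_mutations)
        } else {
          if (t <= 0) NULL
          else af_window_dnds(m, site_table, -1e-9, t, min_mutations,
                              include_upper = FALSE)
        }
        if (!is.null(w) && w$valid) c(N = w$N, dnds = w$dnds) else NULL
      })
      pts <- do.call(rbind, pts[!vapply(pts, is.null, logical(1))])
      cell <- if (is.null(pts) || nrow(pts) < min_samples)
        list(r = NA_real_, p = NA_real_,
             n = if (is.null(pts)) 0L else nrow(pts), valid = FALSE)
      else pearson(pts[, "N"], pts[, "dnds"])
      rows[[length(rows) + 1L]] <- data.frame(
        patient_id = pid, panel = panel, threshold = t, r = cell$r,
        p = cell$p, n_used = cell$n, valid = cell$valid,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("af_correlation", "data.frame")
  out
}

#' @export
print.af_correlation <- function(x, ...) {
  cat(sprintf(
    "AF-resolved correlation, patient %s: %d cells, %d valid (r in [%.2f, %.2f])\n",
    x$patient_id[1], nrow(x), sum(x$valid),
    suppressWarnings(min(x$r, na.rm = TRUE)),
    suppressWarnings(max(x$r, na.rm = TRUE))))
  invisible(x)
}

#' AF-resolved correlations for all eligible patients of a cohort
#'
#' Runs [af_correlation()] per patient, skipping (with a message) patients
#' with too few AF-bearing samples.
#'
#' @inheritParams af_correlation
#' @return data.frame of stacked per-patient results; skipped patients in
#'   attribute `"skipped"`.
#' @export
af_correlation_cohort <- function(mutations, site_table,
                                  thresholds = seq(0.05, 0.95, 0.05),
                                  min_mutations = 10, min_samples = 3,
                                  min_total_samples = 5) {
  parts <- split(mutations, mutations$patient_id)
  skipped <- character(0)
  rows <- list()
  for (pid in names(parts)) {
    res <- tryCatch(
      af_correlation(parts[[pid]], site_table, thresholds, min_mutations,
                     min_samples, min_total_samples),
      error = function(e) NULL)
    if (is.null(res)) skipped <- c(skipped, pid) else rows[[pid]] <- res
  }
  if (length(skipped))
    message(length(skipped), " patient(s) skipped (too few samples with AF)")
  if (length(rows) == 0) return(NULL)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  out
}
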