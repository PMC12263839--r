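#' Kaplan-Meier survival curve
#'
#' Product-limit estimator for right-censored time-to-event data.
#'
#' @param time positive event/censoring times.
#' @param event 1 = event, 0 = censored.
#' @return object of class `km_curve`: data.frame `time`, `n_risk`,
#'   `n_event`, `n_censor`, `surv`, with the underlying
#'   [survival::survfit()] object as attribute `"survfit"`.
#' @export
km_estimate <- function(time, event) {
  if (length(time) == 0) stop("empty input")
  if (any(time <= 0)) stop("times must be positive")
  fit <- survival::survfit(survival::Surv(time, event) ~ 1)
  out <- data.frame(time = fit$time, n_risk = fit$n.risk,
                    n_event = fit$n.event, n_censor = fit$n.censor,
                    surv = fit$surv)
  attr(out, "survfit") <- fit
  class(out) <- c("km_curve", "data.frame")
  out
}

#' Two-group log-rank test
#'
#' Standard 1-df log-rank statistic for the difference between two survival
#' curves. A group with zero events yields a warning but the statistic is
#' still computed.
#'
#' @param time,event pooled survival data.
#' @param group two-level grouping vector.
#' @return list `chi2`, `p`, `n` (per-group sizes), `obs`, `exp`.
#' @export
logrank <- function(time, event, group) {
  group <- as.factor(group)
  if (nlevels(droplevels(group)) != 2) stop("need exactly two groups")
  ev <- tapply(event, group, sum)
  if (any(ev == 0)) warning("a group has zero events")
  sd <- survival::survdiff(survival::Surv(time, event) ~ group)
  list(chi2 = unname(sd$chisq),
       p = stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE),
       n = as.vector(sd$n), obs = as.vector(sd$obs),
       exp = as.vector(sd$exp))
}

# Restricted mean survival time (area under KM) per group, up to the last
# observed event time overall; used as the direction statistic because the
# median can be undefined at high censoring.
rmst_by_group <- function(time, event, group) {
  tau <- max(time[event == 1], max(time))
  fit <- survival::survfit(survival::Surv(time, event) ~ group)
  tbl <- summary(fit, rmean = tau)$table
  stats::setNames(tbl[, "rmean"], sub("^group=", "", rownames(tbl)))
}

scan_cell <- function(time, event, in_group, min_group,
                      labels = c("in_group", "out_group"),
                      directions = c("in_group_worse", "in_group_better")) {
  n_in <- sum(in_group)
  n_out <- sum(!in_group)
  if (min(n_in, n_out) < min_group)
    return(list(p = NA_real_, direction = NA_character_, n_in = n_in,
                n_out = n_out, masked = TRUE))
  grp <- factor(ifelse(in_group, labels[1], labels[2]), levels = labels)
  lr <- suppressWarnings(logrank(time, event, grp))
  rm <- rmst_by_group(time, event, grp)
  dir <- if (rm[labels[1]] < rm[labels[2]]) directions[1] else directions[2]
  list(p = lr$p, direction = dir, n_in = n_in, n_out = n_out, masked = FALSE)
}

new_dnds_scan <- function(df, type) {
  attr(df, "scan_type") <- type
  class(df) <- c("dnds_scan", "data.frame")
  df
}

#' Systematic survival scan over dN/dS ranges
#'
#' For every cell of a (mu, sigma) grid, patients with dN/dS inside
#' `[mu - sigma, mu + sigma]` are compared against those outside by log-rank
#' test; the prognosis direction is read from the restricted-mean-survival
#' difference. Cells where either group is smaller than `min_group` are
#' masked. p-values are reported raw (no multiple-testing correction); an
#' optional Benjamini-Hochberg column can be added with `adjust = TRUE` as a
#' labeled extension.
#'
#' @param dnds valid per-patient dN/dS values.
#' @param time,event survival data aligned with `dnds`.
#' @param mu_grid,sigma_grid numeric grids.
#' @param min_group minimum per-group size (default 5).
#' @param adjust add a `p_bh` column (default FALSE).
#' @return `dnds_scan` data.frame: `mu`, `sigma`, `p`, `direction`
#'   (`in_group_worse`/`in_group_better`), `n_in`, `n_out`, `masked`.
#' @export
range_scan <- function(dnds, time, event, mu_grid = seq(0.4, 1.6, 0.1),
                       sigma_grid = seq(0.05, 0.5, 0.05), min_group = 5,
                       adjust = FALSE) {
  stopifnot(length(dnds) == length(time), length(time) == length(event))
  cells <- expand.grid(mu = mu_grid, sigma = sigma_grid,
                       KEEP.OUT.ATTRS = FALSE)
  res <- lapply(seq_len(nrow(cells)), function(i) {
    inside <- dnds >= cells$mu[i] - cells$sigma[i] &
      dnds <= cells$mu[i] + cells$sigma[i]
    scan_cell(time, event, inside, min_group)
  })
  out <- cbind(cells, do.call(rbind, lapply(res, as.data.frame)))
  if (adjust) out$p_bh <- stats::p.adjust(out$p, method = "BH")
  if (all(out$masked)) warning("all scan cells masked")
  new_dnds_scan(out, "range")
}

#' Classify a paired observation as neutral or escape
#'
#' A patient escapes the neutral regime when the post-treatment distance
#' from neutrality is high (`DIS >= dis_thr`), or when the change in dN/dS
#' is high (`|DELTA| >= delta_thr`) AND the second estimate ends outside the
#' strict neutral regime (`dN/dS_2 < 0.9` or `> 1.1`); otherwise the patient
#' is in the neutral regime or approaching it. `signed_delta = TRUE`
#' replaces `|DELTA|` with `DELTA` (one-directional escape).
#'
#' @param dnds_1,dnds_2 earlier / later dN/dS (vectorized).
#' @param dis_thr,delta_thr classification thresholds.
#' @param signed_delta use signed DELTA (default FALSE).
#' @return character vector of `"neutral"` / `"escape"`.
#' @export
classify_neutral_escape <- function(dnds_1, dnds_2, dis_thr, delta_thr,
                                    signed_delta = FALSE) {
  dis <- abs(1 - dnds_2)
  delta <- dnds_2 - dnds_1
  dd <- if (signed_delta) delta else abs(delta)
  escape <- dis >= dis_thr |
    (dd >= delta_thr & (dnds_2 < 0.9 | dnds_2 > 1.1))
  ifelse(escape, "escape", "neutral")
}

#' Paired (DIS, DELTA) survival scan
#'
#' For every threshold cell, patients are classified neutral vs escape by
#' [classify_neutral_escape()] and the two classes compared by log-rank
#' test; the direction says whether the neutral class fares worse
#' (`neutral_worse`) or better (`neutral_better`) by restricted mean
#' survival. Masking as in [range_scan()] (`n_in` counts the neutral class).
#'
#' @param pairs pair data.frame with `patient_id`, `dnds_1`, `dnds_2`.
#' @param clinical data.frame with `patient_id`, `survival_time`, `event`.
#' @param dis_grid,delta_grid threshold grids.
#' @param min_group minimum class size (default 5).
#' @param signed_delta passed to [classify_neutral_escape()].
#' @return `dnds_scan` data.frame: `dis_thr`, `delta_thr`, `p`, `direction`,
#'   `n_in`, `n_out`, `masked`.
#' @export
paired_scan <- function(pairs, clinical, dis_grid = seq(0.1, 0.6, 0.05),
                        delta_grid = seq(0.1, 0.6, 0.05), min_group = 5,
                        signed_delta = FALSE) {
  m <- merge(pairs, clinical[c("patient_id", "survival_time", "event")],
             by = "patient_id")
  if (nrow(m) == 0) stop("no pairs with linked survival data")
  cells <- expand.grid(dis_thr = dis_grid, delta_thr = delta_grid,
                       KEEP.OUT.ATTRS = FALSE)
  res <- lapply(seq_len(nrow(cells)), function(i) {
    cls <- classify_neutral_escape(m$dnds_1, m$dnds_2, cells$dis_thr[i],
                                   cells$delta_thr[i], signed_delta)
    scan_cell(m$survival_time, m$event, cls == "neutral", min_group,
              labels = c("neutral", "escape"),
              directions = c("neutral_worse", "neutral_better"))
  })
  out <- cbind(cells, do.call(rbind, lapply(res, as.data.frame)))
  if (all(out$masked)) warning("all scan cells masked")
  new_dnds_scan(out, "paired")
}

#' @export
print.dnds_scan <- function(x, ...) {
  unmasked <- sum(!x$masked)
  cat(sprintf("%s survival scan: %d cells (%d unmasked), %d with p < 0.05\n",
              attr(x, "scan_type"), nrow(x), unmasked,
              sum(x$p < 0.05, na.rm = TRUE)))
  invisible(x)
}

#' @export
plot.dnds_scan <- function(x, ...) {
  ax <- names(x)[1:2]
  g1 <- sort(unique(x[[1]])); g2 <- sort(unique(x[[2]]))
  z <- matrix(NA_real_, length(g1), length(g2))
  z[cbind(match(x[[1]], g1), match(x[[2]], g2))] <- -log10(x$p)
  graphics::image(g1, g2, z, xlab = ax[1], ylab = ax[2],
                  main = "-log10 p", ...)
  invisible(x)
}

#' Cox analysis of drug effects on the distance from neutrality
#'
#' Proportional-hazards fit in which each drug is an independent binary
#' covariate. The default, literal construction takes DIS (distance of
#' dN/dS from 1) as the duration variable with every record an event -- DIS
#' is fully observed, not censored -- so HR > 1 means the drug is associated
#' with smaller DIS, i.e. arrival closer to the neutral regime. The
#' conventional alternative (`variant = "time_as_duration"`) models survival
#' time with DIS and drugs as covariates.
#'
#' @param data data.frame with a `dis` column and 0/1 drug indicator
#'   columns; for the alternative variant also `survival_time` and `event`.
#' @param drugs character vector of drug column names (default: columns
#'   starting with `drug`).
#' @param variant `"dis_as_duration"` (default) or `"time_as_duration"`.
#' @return data.frame `drug`, `hr`, `lo95`, `hi95`, `p`, `n_exposed`, with
#'   the `coxph` fit as attribute `"fit"`. Drugs never or always given are
#'   dropped with a warning.
#' @export
cox_drug_effects <- function(data, drugs = NULL,
                             variant = c("dis_as_duration",
                                         "time_as_duration")) {
  variant <- match.arg(variant)
  if (is.null(drugs))
    drugs <- grep("^drug", names(data), ignore.case = TRUE, value = TRUE)
  keep <- vapply(drugs, function(d) length(unique(data[[d]])) == 2,
                 logical(1))
  if (any(!keep))
    warning("dropping drug(s) without both exposure states: ",
            paste(drugs[!keep], collapse = ", "))
  drugs <- drugs[keep]
  if (length(drugs) < 1) stop("no drug with both exposure states")
  if (variant == "dis_as_duration") {
    y <- survival::Surv(pmax(data$dis, 1e-8), rep(1, nrow(data)))
  } else {
    y <- survival::Surv(data$survival_time, data$event)
    drugs <- c(drugs, "dis")
  }
  fml <- stats::reformulate(drugs, response = "y")
  fit <- survival::coxph(fml, data = data)
  sm <- summary(fit)
  out <- data.frame(drug = rownames(sm$coefficients),
                    hr = sm$conf.int[, "exp(coef)"],
                    lo95 = sm$conf.int[, "lower .95"],
                    hi95 = sm$conf.int[, "upper .95"],
                    p = sm$coefficients[, "Pr(>|z|)"],
                    n_exposed = vapply(rownames(sm$coefficients), function(d)
                      if (d %in% names(data)) sum(data[[d]] == 1) else
                        NA_integer_, numeric(1)),
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "fit") <- fit
  out
}
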