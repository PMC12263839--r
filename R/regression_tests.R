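#' Derive ordered dN/dS pairs from cohort profiles
#'
#' For each patient with at least two valid profiles, emits ordered
#' `(dN/dS_1, dN/dS_2)` observations -- the first member the earlier sample
#' -- together with the derived distance from neutrality after the second
#' sample, `DIS = |1 - dN/dS_2|`, and the change `DELTA = dN/dS_2 -
#' dN/dS_1`. Sample order follows [order_samples()] (timepoint, then total
#' mutation count, then id). Patients without two valid estimates are not
#' quantifiable and are counted in the report attached as attribute
#' `"report"`.
#'
#' @param profiles profile data.frame from [cohort_profiles()]; may carry
#'   `status` and `timepoint` columns.
#' @param context pairing rule: `"consecutive"` (all adjacent ordered
#'   pairs), `"first_last"`, or `"pre_post"` (first `pre_treatment` vs first
#'   `post_treatment`/`relapse` status).
#' @return data.frame `patient_id`, `sample_1`, `sample_2`, `dnds_1`,
#'   `dnds_2`, `N_1`, `N_2`, `dis`, `delta`, `context`.
#' @export
derive_pairs <- function(profiles,
                         context = c("consecutive", "first_last",
                                     "pre_post")) {
  context <- match.arg(context)
  profiles$n_mutations <- profiles$N + profiles$S
  by_pat <- split(profiles, profiles$patient_id)
  n_skipped <- 0L
  rows <- list()
  for (pat in names(by_pat)) {
    p <- order_samples(by_pat[[pat]])
    v <- p[p$valid, , drop = FALSE]
    idx <- NULL
    if (context == "pre_post") {
      pre <- which(v$status == "pre_treatment")
      post <- which(v$status %in% c("post_treatment", "relapse"))
      if (length(pre) && length(post))
        idx <- cbind(pre[1], post[1])
    } else if (nrow(v) >= 2) {
      idx <- if (context == "first_last") cbind(1, nrow(v))
      else cbind(seq_len(nrow(v) - 1), seq(2, nrow(v)))
    }
    if (is.null(idx)) {
      n_skipped <- n_skipped + 1L
      next
    }
    rows[[pat]] <- data.frame(
      patient_id = pat,
      sample_1 = v$sample_id[idx[, 1]], sample_2 = v$sample_id[idx[, 2]],
      dnds_1 = v$dnds[idx[, 1]], dnds_2 = v$dnds[idx[, 2]],
      N_1 = v$N[idx[, 1]], N_2 = v$N[idx[, 2]],
      stringsAsFactors = FALSE)
  }
  pairs <- do.call(rbind, rows)
  if (is.null(pairs))
    pairs <- data.frame(patient_id = character(0), sample_1 = character(0),
                        sample_2 = character(0), dnds_1 = numeric(0),
                        dnds_2 = numeric(0), N_1 = integer(0),
                        N_2 = integer(0), stringsAsFactors = FALSE)
  rownames(pairs) <- NULL
  pairs$dis <- abs(1 - pairs$dnds_2)
  pairs$delta <- pairs$dnds_2 - pairs$dnds_1
  pairs$context <- context
  attr(pairs, "report") <- list(n_patients = length(by_pat),
                                n_quantifiable = length(by_pat) - n_skipped,
                                n_pairs = nrow(pairs))
  pairs
}

new_dnds_regression <- function(fit, pairs, method, converged = TRUE) {
  cf <- stats::coef(fit)
  sm <- summary(fit)
  n <- nrow(pairs)
  if (inherits(fit, "rlm")) {
    se <- sm$coefficients[, "Std. Error"]
    tval <- cf / se
    pvals <- 2 * stats::pt(-abs(tval), df = n - 2)
    r2 <- stats::cor(stats::fitted(fit), pairs$dnds_2)^2
  } else {
    pvals <- sm$coefficients[, 4]
    r2 <- sm$r.squared
  }
  out <- list(slope = unname(cf[2]), intercept = unname(cf[1]),
              r_squared = unname(r2), p_slope = unname(pvals[2]),
              p_intercept = unname(pvals[1]), n = n, method = method,
              fit = fit, pairs = pairs)
  class(out) <- "dnds_regression"
  out
}

#' Least-squares fit of later on earlier dN/dS
#'
#' Ordinary least-squares regression `dnds_2 ~ dnds_1` (the figure convention
#' `y = a x + b`), with two-sided p-values for slope = 0 and intercept = 0.
#' A slope below 1 with intercept pulling toward 1 indicates contraction of
#' the cohort toward the neutral regime.
#'
#' @param pairs data.frame with `dnds_1`, `dnds_2` (>= 3 rows).
#' @return object of class `dnds_regression` with `slope`, `intercept`,
#'   `r_squared`, `p_slope`, `p_intercept`, `n`, `method`, underlying `fit`.
#' @export
lms_fit <- function(pairs) {
  if (nrow(pairs) < 3) stop("need >= 3 pairs")
  if (stats::var(pairs$dnds_1) == 0) stop("zero variance in dnds_1")
  new_dnds_regression(stats::lm(dnds_2 ~ dnds_1, data = pairs), pairs, "LMS")
}

#' Robust bisquare fit of later on earlier dN/dS
#'
#' Iteratively reweighted least squares with Tukey bisquare weights (tuning
#' constant 4.685, up to 50 iterations, convergence 1e-6), for cohorts with
#' gross outliers such as hypermutators. p-values use the t approximation on
#' n - 2 df; `r_squared` is the squared correlation between fitted and
#' observed responses.
#'
#' @param pairs data.frame with `dnds_1`, `dnds_2` (>= 5 rows).
#' @return object of class `dnds_regression`.
#' @export
bisquare_fit <- function(pairs) {
  if (nrow(pairs) < 5) stop("need >= 5 pairs")
  if (stats::var(pairs$dnds_1) == 0) stop("zero variance in dnds_1")
  ols <- stats::lm(dnds_2 ~ dnds_1, data = pairs)
  if (stats::sd(stats::resid(ols)) < 1e-10) {
    # exact line: zero scale degenerates the reweighting; all weights are 1
    return(new_dnds_regression(ols, pairs, "bisquare"))
  }
  fit <- MASS::rlm(dnds_2 ~ dnds_1, data = pairs, psi = MASS::psi.bisquare,
                   c = 4.685, maxit = 50, acc = 1e-6)
  if (!fit$converged)
    stop("bisquare fit did not converge in 50 iterations")
  new_dnds_regression(fit, pairs, "bisquare")
}

#' @export
print.dnds_regression <- function(x, digits = 4, ...) {
  cat(sprintf("%s fit (n = %d): dnds_2 = %.*f * dnds_1 + %.*f\n",
              x$method, x$n, digits, x$slope, digits, x$intercept))
  cat(sprintf("  R^2 = %.*f; p(slope) = %.3g; p(intercept) = %.3g\n",
              digits, x$r_squared, x$p_slope, x$p_intercept))
  invisible(x)
}

#' 95% confidence band of a fitted regression
#'
#' @param x a `dnds_regression`.
#' @param grid x-values at which to evaluate the band (default 50 points
#'   over the observed range).
#' @return data.frame `dnds_1`, `fit`, `lwr`, `upr`.
#' @export
confidence_band <- function(x, grid = NULL) {
  if (is.null(grid))
    grid <- seq(min(x$pairs$dnds_1), max(x$pairs$dnds_1), length.out = 50)
  nd <- data.frame(dnds_1 = grid)
  pr <- stats::predict(x$fit, newdata = nd, interval = "confidence",
                       level = 0.95)
  if (is.null(dim(pr))) {  # rlm: build band from t quantiles
    se <- stats::predict(x$fit, newdata = nd, se.fit = TRUE)
    tq <- stats::qt(0.975, df = x$n - 2)
    pr <- cbind(fit = se$fit, lwr = se$fit - tq * se$se.fit,
                upr = se$fit + tq * se$se.fit)
  }
  data.frame(dnds_1 = grid, fit = pr[, "fit"], lwr = pr[, "lwr"],
             upr = pr[, "upr"])
}

#' @export
plot.dnds_regression <- function(x, ...) {
  plot(x$pairs$dnds_1, x$pairs$dnds_2, xlab = "dN/dS (earlier)",
       ylab = "dN/dS (later)", ...)
  graphics::abline(x$intercept, x$slope, col = "red")
  graphics::abline(0, 1, lty = 2, col = "grey")
  bd <- confidence_band(x)
  graphics::lines(bd$dnds_1, bd$lwr, lty = 3, col = "red")
  graphics::lines(bd$dnds_1, bd$upr, lty = 3, col = "red")
  invisible(x)
}

new_dnds_anova <- function(F, df_num, df_den, p) {
  out <- list(F = F, df_num = df_num, df_den = df_den, p = p)
  class(out) <- "dnds_anova"
  out
}

#' @export
print.dnds_anova <- function(x, ...) {
  cat(sprintf("ANOVA F(%d, %d) = %.4g, p = %.4g\n",
              x$df_num, x$df_den, x$F, x$p))
  invisible(x)
}

#' One-way ANOVA comparison of two paired regressions
#'
#' Nested extra-sum-of-squares F test: a pooled single line (2 parameters)
#' over both cohorts against separate lines per cohort (4 parameters),
#' F on (2, nA + nB - 4) df. Symmetric in its arguments.
#'
#' @param pairs_a,pairs_b pair data.frames (>= 3 rows each).
#' @return object of class `dnds_anova` (`F`, `df_num`, `df_den`, `p`).
#' @export
compare_regressions_anova <- function(pairs_a, pairs_b) {
  if (nrow(pairs_a) < 3 || nrow(pairs_b) < 3)
    stop("each pair set needs >= 3 rows")
  n <- nrow(pairs_a) + nrow(pairs_b)
  if (n - 4 <= 0) stop("insufficient degrees of freedom")
  rss <- function(p) sum(stats::resid(stats::lm(dnds_2 ~ dnds_1,
                                                data = p))^2)
  pooled <- rbind(pairs_a[c("dnds_1", "dnds_2")],
                  pairs_b[c("dnds_1", "dnds_2")])
  rss_pooled <- rss(pooled)
  rss_sep <- rss(pairs_a) + rss(pairs_b)
  if (rss_sep <= .Machine$double.eps * n) {
    if (rss_pooled - rss_sep <= .Machine$double.eps * n)
      return(new_dnds_anova(0, 2L, n - 4L, 1))
    return(new_dnds_anova(Inf, 2L, n - 4L, 0))
  }
  F <- ((rss_pooled - rss_sep) / 2) / (rss_sep / (n - 4))
  F <- max(F, 0)
  new_dnds_anova(F, 2L, n - 4L,
                 stats::pf(F, 2, n - 4, lower.tail = FALSE))
}

#' Test deviation of a paired cohort from the identity-line relationship
#'
#' Asks whether the observed `(dN/dS_1, dN/dS_2)` relation deviates from a
#' strict linear identity (slope 1, intercept 0) at the noise level of the
#' data, by comparing the observed regression against an artificial linear
#' reference whose response is `x + e`, with `e` the residuals of the
#' observed LMS fit.
#'
#' Because OLS residuals are orthogonal to the predictor, the paired
#' reference fit is exactly the identity line and its residual sum of
#' squares duplicates the observed one; a naive two-group ANOVA on the two
#' sets is therefore conservative by a factor of two in F. The default
#' (`reference = "exact"`) reports the algebraically equivalent, exactly
#' calibrated F test of H0: (intercept, slope) = (0, 1):
#' `F = (sum((y - x)^2) - RSS) / 2 / (RSS / (n - 2))` on (2, n - 2) df.
#' `"paired-anova"` gives the literal two-group construction;
#' `"permuted"` pairs the residuals to a deterministic cyclic shift of the
#' x-order before the two-group ANOVA (sensitivity analysis).
#'
#' @param pairs data.frame with `dnds_1`, `dnds_2` (>= 5 rows).
#' @param reference `"exact"` (default), `"paired-anova"` or `"permuted"`.
#' @return object of class `dnds_anova`.
#' @export
reference_model_test <- function(pairs,
                                 reference = c("exact", "paired-anova",
                                               "permuted")) {
  reference <- match.arg(reference)
  if (nrow(pairs) < 5) stop("need >= 5 pairs")
  n <- nrow(pairs)
  fit <- stats::lm(dnds_2 ~ dnds_1, data = pairs)
  e <- stats::resid(fit)
  if (reference == "exact") {
    rss <- sum(e^2)
    rss0 <- sum((pairs$dnds_2 - pairs$dnds_1)^2)
    if (rss <= .Machine$double.eps * n) {
      if (rss0 - rss <= .Machine$double.eps * n)
        return(new_dnds_anova(0, 2L, n - 2L, 1))
      return(new_dnds_anova(Inf, 2L, n - 2L, 0))
    }
    F <- max((rss0 - rss) / 2 / (rss / (n - 2)), 0)
    return(new_dnds_anova(F, 2L, n - 2L,
                          stats::pf(F, 2, n - 2, lower.tail = FALSE)))
  }
  e_ref <- if (reference == "permuted") {
    ord <- order(pairs$dnds_1, pairs$dnds_2)
    shifted <- ord[c(seq_along(ord)[-1], 1)]
    out <- numeric(n)
    out[shifted] <- e[ord]
    out
  } else e
  ref <- data.frame(dnds_1 = pairs$dnds_1,
                    dnds_2 = pairs$dnds_1 + e_ref)
  compare_regressions_anova(pairs[c("dnds_1", "dnds_2")], ref)
}
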