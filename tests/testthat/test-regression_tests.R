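pairs_df <- function(x, y) data.frame(dnds_1 = x, dnds_2 = y)

test_that("least-squares fit recovers exact and degenerate lines", {
  f <- suppressWarnings(lms_fit(pairs_df(0:2, 0:2)))
  expect_equal(f$slope, 1)
  expect_equal(f$intercept, 0, tolerance = 1e-12)
  expect_equal(f$r_squared, 1)
  flat <- suppressWarnings(lms_fit(pairs_df(0:2, c(1, 1, 1))))
  expect_equal(flat$slope, 0, tolerance = 1e-12)
  expect_equal(flat$r_squared, 0)
  expect_error(lms_fit(pairs_df(0:1, 0:1)), ">= 3")
  expect_error(lms_fit(pairs_df(c(1, 1, 1), 0:2)), "zero variance")
})

test_that("least-squares confidence interval covers a simulated slope", {
  set.seed(7)
  cover <- replicate(300, {
    x <- runif(50, 0.3, 3)
    y <- 1 + 0.5 * (x - 1) + rnorm(50, 0, 0.2)
    f <- lms_fit(pairs_df(x, y))
    ci <- confint(f$fit)["dnds_1", ]
    ci[1] <= 0.5 && 0.5 <= ci[2]
  })
  expect_gt(mean(cover), 0.91)
  expect_lt(mean(cover), 0.99)
})

test_that("bisquare fit matches LMS on clean data and resists outliers", {
  set.seed(8)
  x <- seq(0.3, 3, length.out = 20)
  y <- 0.6 * x + 0.2
  clean <- suppressWarnings(bisquare_fit(pairs_df(x, y)))
  expect_equal(clean$slope, 0.6, tolerance = 1e-6)
  expect_equal(clean$intercept, 0.2, tolerance = 1e-6)
  # one gross outlier (a hypermutator-like point)
  wins <- replicate(50, {
    yy <- 0.6 * x + 0.2 + rnorm(20, 0, 0.05)
    yy[20] <- 8
    bis <- bisquare_fit(pairs_df(x, yy))
    lms <- lms_fit(pairs_df(x, yy))
    abs(bis$slope - 0.6) < abs(lms$slope - 0.6)
  })
  expect_gt(mean(wins), 0.9)
  expect_error(bisquare_fit(pairs_df(rep(1, 5), 1:5)), "zero variance")
  expect_error(bisquare_fit(pairs_df(1:4, 1:4)), ">= 5")
})

test_that("two-regression ANOVA is symmetric with known limiting cases", {
  set.seed(9)
  a <- pairs_df(runif(20, 0.3, 3), NA)
  a$dnds_2 <- 0.7 * a$dnds_1 + 0.3 + rnorm(20, 0, 0.1)
  same <- compare_regressions_anova(a, a)
  expect_equal(same$F, 0)
  expect_equal(same$p, 1)
  # parallel offset lines with zero noise: separate RSS = 0, pooled > 0
  b <- a
  b$dnds_2 <- a$dnds_1 * 0.5
  c_ <- a
  c_$dnds_2 <- a$dnds_1 * 0.5 + 1
  par <- compare_regressions_anova(b, c_)
  expect_lt(par$p, 1e-10)
  # symmetry
  d <- pairs_df(runif(15, 0.3, 3), NA)
  d$dnds_2 <- 1 + 0.4 * (d$dnds_1 - 1) + rnorm(15, 0, 0.1)
  expect_equal(compare_regressions_anova(a, d)$F,
               compare_regressions_anova(d, a)$F)
  expect_equal(same$df_num, 2L)
  expect_equal(compare_regressions_anova(a, d)$df_den, 20L + 15L - 4L)
})

test_that("two-regression ANOVA holds its nominal level on a shared line", {
  set.seed(10)
  ps <- replicate(400, {
    x1 <- runif(25, 0.3, 3); x2 <- runif(25, 0.3, 3)
    compare_regressions_anova(
      pairs_df(x1, 0.8 * x1 + 0.1 + rnorm(25, 0, 0.1)),
      pairs_df(x2, 0.8 * x2 + 0.1 + rnorm(25, 0, 0.1)))$p
  })
  expect_gt(mean(ps < 0.05), 0.02)
  expect_lt(mean(ps < 0.05), 0.09)
})

test_that("reference-model test: exact on y = x, powerful under contraction", {
  x <- seq(0.3, 3, length.out = 10)
  perfect <- reference_model_test(pairs_df(x, x))
  expect_equal(perfect$F, 0)
  expect_equal(perfect$p, 1)
  # relabeling patients leaves the p-value unchanged
  set.seed(12)
  p1 <- make_profile_pairs(30, 0.5, 0.1)
  shuffled <- p1[sample(nrow(p1)), ]
  expect_equal(reference_model_test(p1)$p, reference_model_test(shuffled)$p)
  # all three reference constructions exist and agree on direction
  for (kind in c("exact", "paired-anova", "permuted"))
    expect_lt(reference_model_test(p1, reference = kind)$p, 0.05)
  expect_error(reference_model_test(p1[1:4, ]), ">= 5")
})

test_that("derive_pairs orders samples, drops invalid members, chains consecutive", {
  prof <- data.frame(
    patient_id = c("p1", "p1", "p2", "p2", "p3", "p3", "p3"),
    sample_id = c("a", "b", "a", "b", "a", "b", "c"),
    timepoint = c(2, 1, NA, NA, 1, 2, 3),
    N = c(50, 20, 90, 30, 10, 20, 30), S = c(10, 10, 10, 10, 5, 5, 5),
    dnds = c(1.2, 0.8, 1.1, NA, 0.5, 0.9, 1.4),
    valid = c(TRUE, TRUE, TRUE, FALSE, TRUE, TRUE, TRUE),
    stringsAsFactors = FALSE)
  pairs <- derive_pairs(prof, context = "consecutive")
  # p1 ordered by timepoint: b then a
  r1 <- pairs[pairs$patient_id == "p1", ]
  expect_equal(c(r1$dnds_1, r1$dnds_2), c(0.8, 1.2))
  # p2 has one invalid member: not quantifiable
  expect_false("p2" %in% pairs$patient_id)
  expect_equal(attr(pairs, "report")$n_quantifiable, 2)
  # p3: three consecutive samples give pairs (1,2) and (2,3)
  r3 <- pairs[pairs$patient_id == "p3", ]
  expect_equal(nrow(r3), 2)
  expect_equal(r3$dnds_1, c(0.5, 0.9))
  expect_equal(r3$dnds_2, c(0.9, 1.4))
  # derived quantities
  expect_equal(pairs$dis, abs(1 - pairs$dnds_2))
  expect_equal(pairs$delta, pairs$dnds_2 - pairs$dnds_1)
  # pre/post context
  prof$status <- c("pre_treatment", "post_treatment")[c(1, 2, 1, 2, 1, 2, 2)]
  pp <- derive_pairs(prof, context = "pre_post")
  expect_equal(sort(unique(pp$patient_id)), c("p1", "p3"))
})

test_that("fitted slope recovers the contraction factor without bias", {
  set.seed(13)
  for (kappa in c(0.25, 0.5, 0.75, 1)) {
    slopes <- replicate(40, lms_fit(make_profile_pairs(200, kappa,
                                                       0.05))$slope)
    expect_lt(abs(mean(slopes) - kappa), 0.05)
  }
})
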