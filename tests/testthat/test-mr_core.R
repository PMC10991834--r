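harm_df <- function(be, bo, se_o, se_e = 0.003) {
  data.frame(variant_id = sprintf("rs%d", seq_along(be)),
             effect_allele = "A", other_allele = "G",
             beta_exposure = be, se_exposure = se_e, eaf_exposure = 0.3,
             beta_outcome = bo, se_outcome = se_o, eaf_outcome = 0.3,
             action = "none", palindromic = FALSE,
             stringsAsFactors = FALSE)
}

test_that("Wald ratios follow the delta method and are sign-invariant", {
  w <- wald_estimates(harm_df(0.05, 0.1, 0.2), "s1")
  expect_equal(w$theta, 2)
  expect_equal(w$se, 4)
  expect_equal(w$ci_low, 2 - 1.96 * 4)
  expect_equal(wald_estimates(harm_df(0.05, 0, 0.2), "s1")$theta, 0)
  # flipping the effect allele flips both betas and leaves theta unchanged
  w2 <- wald_estimates(harm_df(-0.05, -0.1, 0.2), "s1")
  expect_equal(w2$theta, w$theta)
  expect_equal(w2$se, w$se)
  expect_error(wald_estimates(harm_df(0, 0.1, 0.2), "s1"), "invalid instrument")
})

test_that("the second-order Wald SE adds the exposure uncertainty term", {
  h <- harm_df(0.05, 0.1, 0.2, se_e = 0.01)
  w1 <- wald_estimates(h, "s1", se_method = "delta1")
  w2 <- wald_estimates(h, "s1", se_method = "delta2")
  expect_equal(w2$se, sqrt(0.2^2 / 0.05^2 + 0.1^2 * 0.01^2 / 0.05^4))
  expect_gt(w2$se, w1$se)
})

test_that("IVW pools symmetrically, gives Q = 0 for identical estimates, and scales ORs", {
  e <- ivw(data.frame(theta = c(1, 3), se = c(0.5, 0.5)))
  expect_equal(e$theta, 2)
  same <- ivw(data.frame(theta = rep(1.2, 4), se = c(0.2, 0.3, 0.4, 0.5)))
  expect_equal(same$theta, 1.2)
  expect_equal(same$q, 0)
  expect_equal(same$q_df, 3)
  expect_equal(e$or, exp(e$theta))
  expect_equal(e$or_ci_low, exp(e$ci_low))
  one <- ivw(data.frame(theta = 1, se = 0.1))
  expect_true(is.na(one$q))
  expect_error(ivw(data.frame(theta = numeric(), se = numeric())), "no estimates")
})

test_that("IVW equals the weighted-least-squares-through-origin oracle", {
  set.seed(1)
  for (case in 1:30) {
    k <- sample(2:12, 1)
    theta <- rnorm(k, 0.1, 1)
    se <- runif(k, 0.05, 2)
    e <- ivw(data.frame(theta = theta, se = se))
    o <- ivw_wls_oracle(theta, se)
    expect_equal(e$theta, o$theta, tolerance = 1e-10)
    expect_equal(e$se, o$se, tolerance = 1e-10)
    expect_equal(e$q, o$q, tolerance = 1e-10)
    expect_equal(e$q_pvalue, pchisq(o$q, k - 1, lower.tail = FALSE),
                 tolerance = 1e-10)
  }
})

test_that("IVW agrees with an established fixed-effect meta-analysis routine", {
  skip_if_not_installed("metafor")
  set.seed(2)
  theta <- rnorm(6); se <- runif(6, 0.1, 1)
  e <- ivw(data.frame(theta = theta, se = se))
  m <- metafor::rma(yi = theta, sei = se, method = "FE")
  expect_equal(e$theta, as.numeric(m$beta), tolerance = 1e-8)
  expect_equal(e$se, m$se, tolerance = 1e-8)
  expect_equal(e$q, m$QE, tolerance = 1e-8)
})

test_that("the fixed-effect SE decreases monotonically as estimates accrue", {
  set.seed(3)
  theta <- rnorm(8); se <- runif(8, 0.2, 1)
  ses <- vapply(2:8, function(k)
    ivw(data.frame(theta = theta[1:k], se = se[1:k]))$se, numeric(1))
  expect_true(all(diff(ses) < 0))
})

test_that("multiplicative random effects never deflate the fixed-effect SE", {
  df <- data.frame(theta = c(0, 2, -1), se = c(0.2, 0.2, 0.2))
  fe <- ivw(df); re <- ivw(df, random_effects = TRUE)
  expect_equal(re$se, fe$se * sqrt(fe$q / fe$q_df))
  hom <- data.frame(theta = rep(1, 3), se = 0.2)
  expect_equal(ivw(hom, random_effects = TRUE)$se, ivw(hom)$se)
})

test_that("pooling across studies matches flat pooling of variant estimates", {
  set.seed(4)
  # three identical studies leave the estimate unchanged with Q = 0
  e1 <- ivw(data.frame(theta = c(0.1, 0.3), se = c(0.2, 0.4)), label = "a")
  p_same <- pool_studies(list(e1, e1, e1))
  expect_equal(p_same$theta, e1$theta)
  expect_equal(p_same$q, 0)
  # a study with a vastly smaller SE dominates the pool
  tiny <- ivw(data.frame(theta = 5, se = 1e-5))
  p_dom <- pool_studies(list(e1, tiny))
  expect_equal(p_dom$theta, 5, tolerance = 1e-4)
  # algebraic identity: fixed-effect pooling of per-study IVW estimates
  # equals one-stage IVW over all variant-level estimates
  wald <- lapply(1:3, function(s)
    data.frame(theta = rnorm(4), se = runif(4, 0.1, 1)))
  per_study <- lapply(wald, ivw)
  pooled2 <- pool_studies(per_study)
  pooled1 <- ivw(do.call(rbind, wald))
  expect_equal(pooled2$theta, pooled1$theta, tolerance = 1e-12)
  expect_equal(pooled2$se, pooled1$se, tolerance = 1e-12)
  # fewer than two studies passes through with a warning
  expect_warning(p1 <- pool_studies(list(e1)), "fewer than 2")
  expect_equal(p1$theta, e1$theta)
  expect_identical(p1$level, "pooled_across_studies")
})

test_that("the forest table has one row per variant x study plus pooled rows", {
  set.seed(5)
  studies <- c("meta2019", "ukb", "finngen")
  wald <- lapply(studies, function(s)
    wald_estimates(harm_df(runif(12, 0.02, 0.05), rnorm(12, 0, 0.05),
                           runif(12, 0.1, 0.4)), s))
  names(wald) <- studies
  est <- lapply(wald, function(w) ivw(w, label = w$study[1]))
  pooled <- pool_studies(est)
  ft <- forest_table(wald, est, pooled)
  expect_equal(nrow(ft), 12 * 3 + 3 + 1)
  expect_equal(sum(ft$level == "variant"), 36)
  expect_equal(sum(ft$level == "study"), 3)
  expect_equal(sum(ft$level == "pooled"), 1)
  expect_equal(ft$OR, exp(ft$logOR))
  expect_equal(ft$ci_low, exp(ft$logOR - 1.96 * ft$se))
  # empty input gives a header-only report
  empty <- forest_table(list(), list(), NULL)
  expect_equal(nrow(empty), 0)
  expect_identical(names(empty),
                   c("level", "study", "variant_id", "logOR", "se", "OR",
                     "ci_low", "ci_high", "Q", "Q_df", "Q_p"))
})
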