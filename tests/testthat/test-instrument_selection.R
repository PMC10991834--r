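test_that("region filtering is inclusive at the window boundaries and idempotent", {
  reg <- region_spec("1", 154377669, 154441926, flank = 100000)
  df <- make_assoc_df(5, seed = 1)
  df$pos <- c(154277669,   # start - flank: kept
              154277668,   # one below: removed
              154541926,   # end + flank: kept
              154541927,   # one above: removed
              154400000)   # inside the gene body: kept
  x <- sumstats(df, validate = FALSE)
  f <- filter_region(x, reg)
  expect_identical(f$data$pos, df$pos[c(1, 3, 5)])
  expect_identical(filter_region(f, reg)$data, f$data)
  # different chromosome never passes
  x$data$chrom <- "2"
  expect_equal(n_variants(filter_region(x, reg)), 0)
})

test_that("significance filter is strict and the Bonferroni constructor is alpha/m", {
  expect_equal(bonferroni_threshold(0.05, 1000), 5e-5)
  df <- make_assoc_df(3, seed = 2)
  df$beta <- c(0.05, 0.06, 0.07)
  df$se <- abs(df$beta) / qnorm(c(5e-5, 1e-6, 0.5) / 2, lower.tail = FALSE)
  df$pvalue <- c(5e-5, 1e-6, 0.5)
  x <- sumstats(df, validate = FALSE)
  kept <- filter_pvalue(x, 5e-5)
  expect_identical(kept$data$variant_id, df$variant_id[2])  # p == threshold removed
  all1 <- x; all1$data$pvalue <- rep(1, 3)
  expect_equal(n_variants(filter_pvalue(all1, 0.5)), 0)
  expect_error(filter_pvalue(x, 0), "threshold")
})

test_that("clumping keeps the most significant variant of a correlated pair", {
  df <- make_assoc_df(2, seed = 3)
  df$variant_id <- c("rsA", "rsB")
  df$pvalue <- c(1e-8, 1e-6)
  x <- sumstats(df, validate = FALSE)
  ld <- make_ld(c("rsA", "rsB"), r = sqrt(0.5))
  cl <- clump(x, ld, r2_max = 0.1)
  expect_identical(cl$exposure$data$variant_id, "rsA")
  log <- cl$selection_log
  expect_identical(log$status[log$variant_id == "rsB"], "removed-by-clump")
  expect_identical(log$index_variant[log$variant_id == "rsB"], "rsA")
  # mutually uncorrelated variants are all kept
  cl0 <- clump(x, make_ld(c("rsA", "rsB"), 0), r2_max = 0.1)
  expect_equal(n_variants(cl0$exposure), 2)
})

test_that("clumping reproduces a hand-traced greedy run on a 5-variant fixture", {
  # greedy trace at r2_max = 0.1, p order a < c < b < d < e:
  #   keep a; drop b (r^2 = 0.25 with a); keep c (r^2 = 0.04 with a);
  #   drop d (r^2 = 0.16 with c); keep e (r^2 0.01 with a, 0.0625 with c)
  ids <- c("a", "b", "c", "d", "e")
  r <- make_ld(ids, 0)
  r["a", "b"] <- r["b", "a"] <- 0.5
  r["a", "c"] <- r["c", "a"] <- 0.2
  r["c", "d"] <- r["d", "c"] <- -0.4
  r["a", "e"] <- r["e", "a"] <- 0.1
  r["c", "e"] <- r["e", "c"] <- 0.25
  df <- make_assoc_df(5, seed = 4)
  df$variant_id <- ids
  df$pvalue <- c(1e-8, 1e-6, 1e-7, 1e-5, 1e-4)
  x <- sumstats(df, validate = FALSE)
  cl <- clump(x, r, r2_max = 0.1)
  expect_identical(cl$exposure$data$variant_id, c("a", "c", "e"))
  log <- cl$selection_log
  expect_identical(log$index_variant[log$variant_id == "b"], "a")
  expect_identical(log$index_variant[log$variant_id == "d"], "c")
})

test_that("clumping is invariant to input row order and enforces its postcondition", {
  set.seed(5)
  for (case in 1:10) {
    n <- 12
    df <- make_assoc_df(n, seed = 100 + case)
    ids <- df$variant_id
    a <- matrix(rnorm(n * n), n)
    r <- cov2cor(crossprod(a) + diag(n))
    dimnames(r) <- list(ids, ids)
    x <- sumstats(df, validate = FALSE)
    ref <- clump(x, r, r2_max = 0.1)
    perm <- sample(n)
    shuf <- sumstats(df[perm, ], validate = FALSE)
    out <- clump(shuf, r, r2_max = 0.1)
    expect_setequal(out$exposure$data$variant_id,
                    ref$exposure$data$variant_id)
    kept <- ref$exposure$data$variant_id
    if (length(kept) > 1) {
      sub <- r[kept, kept]^2; diag(sub) <- 0
      expect_lte(max(sub), 0.1)
    }
  }
})

test_that("a variant missing from the LD matrix is a hard error naming it", {
  x <- make_sumstats(3, seed = 6)
  ld <- make_ld(x$data$variant_id[1:2], 0)
  expect_error(clump(x, ld), x$data$variant_id[3], fixed = TRUE)
})

test_that("F-statistics, variance explained and sample-size inflation follow their formulas", {
  df <- make_assoc_df(3, seed = 7)
  df$beta <- c(0.03, 0, 0.02)
  df$se <- c(0.003, 0.005, 0.002)
  df$pvalue <- 2 * pnorm(-abs(df$beta / df$se))
  df$eaf <- c(0.5, 0.2, 0.3)
  x <- sumstats(df, validate = FALSE)
  f <- f_statistics(x)
  expect_equal(unname(f$per_variant_f), c(100, 0, 100))
  expect_equal(f$mean_f, 200 / 3)
  one <- sumstats(df[1, ], validate = FALSE)
  expect_equal(f_statistics(one)$mean_f, 100)

  expect_equal(variance_explained(one), 2 * 0.5 * 0.5 * 0.03^2)  # 0.00045
  single <- df[1, ]; single$beta <- 0.1
  single$pvalue <- 2 * pnorm(-abs(single$beta / single$se))
  expect_equal(variance_explained(sumstats(single, validate = FALSE)), 0.005)
  two <- sumstats(rbind(single, transform(single, variant_id = "rsX")),
                  validate = FALSE)
  expect_equal(variance_explained(two), 0.01)  # additivity
  zero <- x; zero$data$beta <- 0
  expect_equal(variance_explained(zero), 0)
  na_eaf <- x; na_eaf$data$eaf[2] <- NA
  expect_error(variance_explained(na_eaf), "missing")

  expect_equal(sample_size_inflation(0.01), 100)
  expect_equal(sample_size_inflation(1), 1)
  expect_equal(sample_size_inflation(0.5), 2)
  expect_error(sample_size_inflation(0), "domain")
  expect_error(sample_size_inflation(-0.1), "domain")
})
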