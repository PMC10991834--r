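# Small exposure/outcome pairs built in code; each fixture isolates one
# alignment rule.

h_pair <- function(e_alleles, o_alleles, e_eaf = 0.3, o_eaf = 0.3,
                   o_beta = 0.2, band = c(0.42, 0.58)) {
  df <- make_assoc_df(1, seed = 1)
  df$variant_id <- "rs1"
  e <- df
  e$effect_allele <- e_alleles[1]; e$other_allele <- e_alleles[2]
  e$eaf <- e_eaf
  o <- df
  o$effect_allele <- o_alleles[1]; o$other_allele <- o_alleles[2]
  o$eaf <- o_eaf; o$beta <- o_beta
  o$pvalue <- 2 * pnorm(-abs(o$beta / o$se))
  harmonise(sumstats(e, validate = FALSE),
            sumstats(o, trait_scale = "log_odds", validate = FALSE),
            ambiguity_band = band)
}

test_that("swapped alleles flip the outcome sign and frequency", {
  h <- h_pair(c("A", "G"), c("G", "A"), o_eaf = 0.3, o_beta = 0.2)
  expect_equal(h$harmonised$beta_outcome, -0.2)
  expect_equal(h$harmonised$eaf_outcome, 0.7)
  expect_identical(h$harmonised$action, "sign_flip")
})

test_that("reverse-complement alleles are strand-flipped without sign change", {
  h <- h_pair(c("A", "G"), c("T", "C"), o_beta = 0.2)
  expect_equal(h$harmonised$beta_outcome, 0.2)
  expect_identical(h$harmonised$action, "strand_flip")
  # complement of the swapped pair: both flips
  h2 <- h_pair(c("A", "G"), c("C", "T"), o_beta = 0.2)
  expect_equal(h2$harmonised$beta_outcome, -0.2)
  expect_identical(h2$harmonised$action, "strand_flip_and_sign_flip")
})

test_that("palindromic variants resolve by frequency or are excluded", {
  # maximal ambiguity: eaf = 0.5 falls in the band
  h <- h_pair(c("A", "T"), c("A", "T"), e_eaf = 0.5, o_eaf = 0.5)
  expect_equal(nrow(h$harmonised), 0)
  expect_identical(h$exclusions$reason, "palindromic-ambiguous")
  # concordant frequencies outside the band align directly
  h2 <- h_pair(c("A", "T"), c("A", "T"), e_eaf = 0.2, o_eaf = 0.25,
               o_beta = 0.2)
  expect_equal(h2$harmonised$beta_outcome, 0.2)
  expect_identical(h2$harmonised$action, "none")
  # discordant frequencies imply the opposite strand: sign flip
  h3 <- h_pair(c("A", "T"), c("A", "T"), e_eaf = 0.2, o_eaf = 0.8,
               o_beta = 0.2)
  expect_equal(h3$harmonised$beta_outcome, -0.2)
  expect_equal(h3$harmonised$eaf_outcome, 0.2)
  # band edges are excluded (inclusive band)
  h4 <- h_pair(c("C", "G"), c("C", "G"), e_eaf = 0.42, o_eaf = 0.2)
  expect_identical(h4$exclusions$reason, "palindromic-ambiguous")
})

test_that("irreconcilable, non-SNP and absent variants are excluded with reasons", {
  h <- h_pair(c("A", "G"), c("A", "C"))
  expect_identical(h$exclusions$reason, "allele-mismatch")
  h2 <- h_pair(c("AT", "G"), c("AT", "G"))
  expect_identical(h2$exclusions$reason, "non-SNP")
  e <- make_sumstats(3, seed = 2)
  o <- make_sumstats(3, seed = 2)
  o$data <- o$data[-2, ]
  h3 <- harmonise(e, o)
  expect_identical(h3$exclusions$variant_id, e$data$variant_id[2])
  expect_identical(h3$exclusions$reason, "missing-in-outcome")
  expect_equal(nrow(h3$harmonised), 2)
})

test_that("harmonising a table against itself is the identity for non-palindromic variants", {
  x <- make_sumstats(20, seed = 3)
  h <- harmonise(x, x)
  expect_equal(nrow(h$harmonised), 20)
  expect_true(all(h$harmonised$action == "none"))
  expect_identical(h$harmonised$beta_outcome, x$data$beta)
})

test_that("harmonisation is idempotent", {
  e <- make_sumstats(10, seed = 4)
  o <- make_sumstats(10, seed = 4)
  set.seed(5)
  flip <- sample(c(TRUE, FALSE), 10, replace = TRUE)
  d <- o$data
  tmp <- d$effect_allele[flip]
  d$effect_allele[flip] <- d$other_allele[flip]
  d$other_allele[flip] <- tmp
  d$beta[flip] <- -d$beta[flip]
  d$eaf[flip] <- 1 - d$eaf[flip]
  o$data <- d
  h1 <- harmonise(e, o)
  # rebuild the outcome from the harmonised result and harmonise again
  o2 <- o
  o2$data$effect_allele <- h1$harmonised$effect_allele
  o2$data$other_allele <- h1$harmonised$other_allele
  o2$data$beta <- h1$harmonised$beta_outcome
  o2$data$eaf <- h1$harmonised$eaf_outcome
  h2 <- harmonise(e, o2)
  expect_true(all(h2$harmonised$action == "none"))
  expect_equal(h2$harmonised$beta_outcome, h1$harmonised$beta_outcome)
})

test_that("the exposure-outcome effect product is invariant to re-polarisation", {
  set.seed(6)
  e <- make_sumstats(15, seed = 6)
  o <- make_sumstats(15, seed = 6)
  o$data$beta <- rnorm(15, 0, 0.1)
  o$data$pvalue <- 2 * pnorm(-abs(o$data$beta / o$data$se))
  ref <- harmonise(e, o)$harmonised
  ref_prod <- ref$beta_exposure * ref$beta_outcome
  for (case in 1:5) {
    repol <- function(x) {
      d <- x$data
      flip <- sample(c(TRUE, FALSE), nrow(d), replace = TRUE)
      tmp <- d$effect_allele[flip]
      d$effect_allele[flip] <- d$other_allele[flip]
      d$other_allele[flip] <- tmp
      d$beta[flip] <- -d$beta[flip]
      d$eaf[flip] <- 1 - d$eaf[flip]
      x$data <- d
      x
    }
    h <- harmonise(repol(e), repol(o))$harmonised
    expect_equal(h$beta_exposure * h$beta_outcome, ref_prod)
  }
})
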