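# Fixture builders and independent oracles shared across the test files.
# Oracles deliberately use a different computational route than the package
# (lm() for IVW, hand-coded step-up BH for FIQT).

# A valid summary-statistics data frame with p-values consistent with
# beta/se under the two-sided normal.
make_assoc_df <- function(n = 10, seed = 1, chrom = "1",
                          pos_start = 154300000) {
  set.seed(seed)
  pairs <- list(c("A", "G"), c("C", "T"), c("G", "A"), c("T", "C"),
                c("A", "C"), c("G", "T"))
  idx <- sample(length(pairs), n, replace = TRUE)
  beta <- rnorm(n, 0, 0.05)
  se <- runif(n, 0.002, 0.02)
  data.frame(
    variant_id = sprintf("rs%05d", sample.int(90000, n)),
    chrom = chrom,
    pos = as.numeric(pos_start + sort(sample.int(2e5, n))),
    effect_allele = vapply(idx, function(i) pairs[[i]][1], character(1)),
    other_allele = vapply(idx, function(i) pairs[[i]][2], character(1)),
    eaf = runif(n, 0.05, 0.95),
    beta = beta, se = se,
    pvalue = 2 * pnorm(-abs(beta / se)),
    n = 10000,
    stringsAsFactors = FALSE)
}

make_sumstats <- function(n = 10, seed = 1, scale = "quantitative", ...) {
  sumstats(make_assoc_df(n, seed, ...), trait_label = "test",
           trait_scale = scale, validate = FALSE)
}

# Compound-symmetric LD matrix over given IDs.
make_ld <- function(ids, r = 0) {
  m <- matrix(r, length(ids), length(ids), dimnames = list(ids, ids))
  diag(m) <- 1
  m
}

# Independent IVW oracle: weighted least squares of theta on a constant.
# Fixed-effect SE strips the residual scale from lm's vcov; Q is the
# weighted residual sum of squares.
ivw_wls_oracle <- function(theta, se) {
  w <- 1 / se^2
  fit <- lm(theta ~ 1, weights = w)
  s2 <- summary(fit)$sigma^2
  list(theta = unname(coef(fit)[1]),
       se = sqrt(unname(vcov(fit)[1, 1]) / s2),
       q = sum(w * resid(fit)^2))
}

# Literal step-up Benjamini-Hochberg over a declared number of tests m:
# adjusted p at ascending rank r is p_(r) * m / r, then a running minimum
# from the largest rank down, capped at 1.
bh_oracle <- function(p, m) {
  k <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(k)
  if (k > 1) for (i in (k - 1):1) adj[i] <- min(adj[i], adj[i + 1])
  pmin(adj, 1)[order(o)]
}

# Literal FIQT recipe: z -> two-sided p -> BH over m tests -> inverse
# normal quantile with the original sign.
fiqt_oracle <- function(beta, se, m) {
  z <- beta / se
  p <- 2 * pnorm(-abs(z))
  p_bh <- bh_oracle(p, m)
  sign(z) * qnorm(p_bh / 2, lower.tail = FALSE)
}
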