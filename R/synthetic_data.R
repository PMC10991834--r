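# Synthetic GWAS summary statistics with the statistical structure the
# cis-MR analysis assumes: one LD-structured gene region, a quantitative
# exposure GWAS, and several case-control outcome GWASs on the log-odds
# scale with small case fractions.

#' Case-control designs of the three PAH GWAS sources
#'
#' The outcome study sizes emulated by the default generator configuration:
#' the 2019 international PAH case-control meta-analysis (2085 cases, 9659
#' controls), the UK Biobank PAH GWAS (493 cases, 24 650 matched controls),
#' and FinnGen round 9 (234 cases among 377 277 participants).
#'
#' @return Data frame with columns `study`, `n_cases`, `n_controls`.
#' @export
pah_study_designs <- function() {
  data.frame(study = c("intl_meta_2019", "uk_biobank", "finngen_r9"),
             n_cases = c(2085, 493, 234),
             n_controls = c(9659, 24650, 377043),
             stringsAsFactors = FALSE)
}

#' Reference settings and comparators of the IL6R/PAH analysis
#'
#' The published analysis design this package re-implements: the IL6R cis
#' region and selection thresholds, the exposure GWAS size (UK Biobank CRP,
#' n = 361 194), the three outcome study designs, the number of instruments
#' retained after clumping (12), and the earlier single-biobank analysis it
#' is compared against (FinnGen round 5: 125 cases among n = 162 959, 6
#' instruments).
#'
#' @return Named list: `region`, `p_threshold`, `r2_max`, `n_region_tests`,
#'   `n_exposure`, `studies`, `n_instruments`, `prior` (list with `study`,
#'   `n`, `n_cases`, `n_instruments`).
#' @export
il6r_pah_reference <- function() {
  list(region = il6r_region(),
       p_threshold = bonferroni_threshold(0.05, 1000),
       r2_max = 0.1,
       n_region_tests = 1000,
       n_exposure = 361194,
       studies = pah_study_designs(),
       n_instruments = 12,
       prior = list(study = "finngen_r5", n = 162959, n_cases = 125,
                    n_instruments = 6))
}

#' Generator configuration
#'
#' Defines the synthetic study conditions. Defaults emulate the reference
#' analysis: ~1000 variants in the IL6R cis window, a standardised
#' quantitative exposure measured in 361 194 individuals, and three
#' case-control outcome GWASs with the designs of [pah_study_designs()].
#'
#' @param n_variants number of variants in the region (default 1000).
#' @param n_causal number of variants with a nonzero per-allele exposure
#'   effect (default 12).
#' @param causal_beta_sd SD of the nonzero per-allele effects, in exposure
#'   SD units (default 0.03).
#' @param ld_block_size variants per LD block (default 20; a final short
#'   block absorbs any remainder).
#' @param ld_within_block_r signed correlation between any two variants of
#'   the same block, in `[0, 1)` (default 0.5); blocks are independent.
#' @param maf_range minor-allele-frequency range, within (0, 0.5].
#' @param n_exposure exposure GWAS sample size.
#' @param study_designs data frame with `study`, `n_cases`, `n_controls`.
#' @param true_theta causal effect of the exposure on the outcome, in
#'   log-odds per exposure unit (default 0).
#' @param pleiotropy_sd SD of direct (non-mediated) variant effects on the
#'   outcome log-odds, shared across studies (default 0).
#' @param palindromic_fraction fraction of variants with A/T or C/G allele
#'   pairs (default 0.15).
#' @param region [region_spec] positions are drawn from (default
#'   [il6r_region()]).
#' @param seed default seed for [generate_region()].
#' @return Object of class `synth_config`.
#' @export
synth_config <- function(n_variants = 1000, n_causal = 12,
                         causal_beta_sd = 0.03, ld_block_size = 20,
                         ld_within_block_r = 0.5, maf_range = c(0.05, 0.5),
                         n_exposure = 361194,
                         study_designs = pah_study_designs(),
                         true_theta = 0, pleiotropy_sd = 0,
                         palindromic_fraction = 0.15,
                         region = il6r_region(), seed = 1L) {
  if (n_variants < 1 || n_causal < 0 || ld_block_size < 1 || n_exposure < 1)
    stop("configuration error: counts must be positive")
  if (n_causal > n_variants)
    stop("configuration error: n_causal exceeds n_variants")
  if (ld_within_block_r < 0 || ld_within_block_r >= 1)
    stop("configuration error: ld_within_block_r must lie in [0, 1)")
  if (length(maf_range) != 2 || maf_range[1] <= 0 || maf_range[2] > 0.5 ||
      maf_range[1] > maf_range[2])
    stop("configuration error: maf_range must lie within (0, 0.5]")
  if (palindromic_fraction < 0 || palindromic_fraction > 1)
    stop("configuration error: palindromic_fraction must lie in [0, 1]")
  if (pleiotropy_sd < 0 || causal_beta_sd < 0)
    stop("configuration error: standard deviations must be >= 0")
  stopifnot(is.data.frame(study_designs),
            all(c("study", "n_cases", "n_controls") %in% names(study_designs)),
            all(study_designs$n_cases > 0), all(study_designs$n_controls > 0))
  structure(list(n_variants = as.integer(n_variants),
                 n_causal = as.integer(n_causal),
                 causal_beta_sd = causal_beta_sd,
                 ld_block_size = as.integer(ld_block_size),
                 ld_within_block_r = ld_within_block_r,
                 maf_range = maf_range, n_exposure = n_exposure,
                 study_designs = study_designs, true_theta = true_theta,
                 pleiotropy_sd = pleiotropy_sd,
                 palindromic_fraction = palindromic_fraction,
                 region = region, seed = as.integer(seed)),
            class = "synth_config")
}

# Block sizes: full blocks plus a final short block for any remainder.
block_sizes <- function(n_variants, block_size) {
  sizes <- rep(block_size, n_variants %/% block_size)
  if (n_variants %% block_size) sizes <- c(sizes, n_variants %% block_size)
  sizes
}

#' Block-diagonal LD matrix of a generator configuration
#'
#' Compound-symmetric blocks: correlation `ld_within_block_r` within a
#' block, 0 between blocks. Deterministic given the configuration (variant
#' IDs are positional).
#'
#' @param config a [synth_config].
#' @return Validated LD matrix.
#' @export
synth_ld_matrix <- function(config) {
  n <- config$n_variants
  ids <- sprintf("rs%07d", seq_len(n))
  r <- matrix(0, n, n, dimnames = list(ids, ids))
  off <- 0L
  for (m in block_sizes(n, config$ld_block_size)) {
    idx <- off + seq_len(m)
    r[idx, idx] <- config$ld_within_block_r
    off <- off + m
  }
  diag(r) <- 1
  r
}

# Correlated standard-normal noise per trait column, block by block.
# Cholesky factors are cached per block size (blocks share one compound-
# symmetric correlation matrix).
block_noise <- function(config, n_traits) {
  n <- config$n_variants
  sizes <- block_sizes(n, config$ld_block_size)
  chol_for <- list()
  for (m in unique(sizes)) {
    rb <- matrix(config$ld_within_block_r, m, m)
    diag(rb) <- 1
    chol_for[[as.character(m)]] <- chol(rb)  # upper triangular
  }
  z <- matrix(stats::rnorm(n * n_traits), n, n_traits)
  eps <- matrix(0, n, n_traits)
  off <- 0L
  for (m in sizes) {
    idx <- off + seq_len(m)
    eps[idx, ] <- crossprod(chol_for[[as.character(m)]], z[idx, , drop = FALSE])
    off <- off + m
  }
  eps
}

.pal_pairs <- list(c("A", "T"), c("T", "A"), c("C", "G"), c("G", "C"))
.nonpal_pairs <- list(c("A", "C"), c("A", "G"), c("C", "A"), c("C", "T"),
                      c("G", "A"), c("G", "T"), c("T", "C"), c("T", "G"))

#' Effective sample size of a case-control GWAS
#'
#' `4 / (1/n_cases + 1/n_controls)`: the size of a balanced design with the
#' same power, used to approximate log-odds standard errors in the
#' generator. With very small case fractions (e.g. 234 cases among 377 277)
#' the effective size is close to `4 * n_cases`, which is why the smallest
#' case counts dominate power.
#'
#' @param n_cases,n_controls case and control counts.
#' @return Effective sample size.
#' @export
effective_sample_size <- function(n_cases, n_controls) {
  4 / (1 / n_cases + 1 / n_controls)
}

#' Generate a synthetic cis region with exposure and outcome GWASs
#'
#' Simulates, fully reproducibly from `seed`:
#' 1. minor-allele frequencies uniform on `maf_range`, effect alleles
#'    polarised at random, allele pairs palindromic with probability
#'    `palindromic_fraction`, positions within the region window;
#' 2. block-diagonal LD with within-block correlation `ld_within_block_r`;
#' 3. `n_causal` variants with per-allele (joint) exposure effects drawn
#'    `N(0, causal_beta_sd^2)`, propagated through LD to marginal effects
#'    (`marginal = R %*% joint`);
#' 4. exposure estimates multivariate normal around the marginal effects
#'    with covariance `r_ij se_i se_j`, where
#'    `se_j = (2 maf_j (1-maf_j) n_exposure)^(-1/2)` (unit-variance trait);
#' 5. outcome marginal log-odds `true_theta * marginal + pleiotropy`, with
#'    standard errors from the [effective_sample_size()] of each design and
#'    the same LD-structured estimate noise;
#' 6. two-sided normal p-values throughout.
#'
#' @param config a [synth_config].
#' @param seed integer seed (defaults to `config$seed`).
#' @param ld optional precomputed [synth_ld_matrix()] for this
#'   configuration, to avoid rebuilding it across many replicates.
#' @return Object of class `synth_region`: list with `exposure`
#'   ([sumstats], quantitative), `outcomes` (named list of case-control
#'   [sumstats]), `ld` (validated LD matrix), `truth` (data frame of true
#'   joint and marginal effects, causal flags, and per-study true outcome
#'   log-odds effects) and `config`.
#' @export
generate_region <- function(config, seed = config$seed, ld = NULL) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(seed)
  n <- config$n_variants
  reg <- config$region
  ids <- sprintf("rs%07d", seq_len(n))
  window <- c(reg$start - reg$flank, reg$end + reg$flank)
  pos <- as.numeric(sort(sample(seq(window[1], window[2]), n)))
  maf <- stats::runif(n, config$maf_range[1], config$maf_range[2])
  eaf <- ifelse(stats::runif(n) < 0.5, maf, 1 - maf)
  pal <- stats::runif(n) < config$palindromic_fraction
  pair_idx <- ifelse(pal, sample.int(4L, n, replace = TRUE),
                     sample.int(8L, n, replace = TRUE))
  ea <- character(n); oa <- character(n)
  for (i in seq_len(n)) {
    p <- if (pal[i]) .pal_pairs[[pair_idx[i]]] else .nonpal_pairs[[pair_idx[i]]]
    ea[i] <- p[1]; oa[i] <- p[2]
  }
  if (is.null(ld)) ld <- synth_ld_matrix(config)

  joint <- numeric(n)
  causal <- sort(sample.int(n, config$n_causal))
  joint[causal] <- stats::rnorm(config$n_causal, 0, config$causal_beta_sd)
  marginal <- as.vector(ld %*% joint)

  pleio <- if (config$pleiotropy_sd > 0)
    stats::rnorm(n, 0, config$pleiotropy_sd) else numeric(n)

  designs <- config$study_designs
  n_studies <- nrow(designs)
  eps <- block_noise(config, 1L + n_studies)

  se_exp <- 1 / sqrt(2 * maf * (1 - maf) * config$n_exposure)
  beta_exp <- marginal + se_exp * eps[, 1]
  make_table <- function(beta, se, n_tot, n_cases, label, scale) {
    d <- data.frame(variant_id = ids, chrom = reg$chrom, pos = pos,
                    effect_allele = ea, other_allele = oa, eaf = eaf,
                    beta = beta, se = se,
                    pvalue = 2 * stats::pnorm(-abs(beta / se)),
                    n = n_tot, stringsAsFactors = FALSE)
    if (!is.null(n_cases)) d$n_cases <- n_cases
    sumstats(d, trait_label = label, trait_scale = scale, validate = FALSE)
  }
  exposure <- make_table(beta_exp, se_exp, config$n_exposure, NULL,
                         "exposure", "quantitative")
  marginal_out <- config$true_theta * marginal + pleio
  outcomes <- list()
  for (s in seq_len(n_studies)) {
    n_eff <- effective_sample_size(designs$n_cases[s], designs$n_controls[s])
    se_out <- 1 / sqrt(2 * maf * (1 - maf) * n_eff)
    beta_out <- marginal_out + se_out * eps[, 1L + s]
    outcomes[[designs$study[s]]] <-
      make_table(beta_out, se_out, designs$n_cases[s] + designs$n_controls[s],
                 designs$n_cases[s], designs$study[s], "log_odds")
  }
  truth <- data.frame(variant_id = ids, causal = joint != 0,
                      beta_joint = joint, beta_marginal = marginal,
                      beta_outcome_marginal = marginal_out,
                      maf = maf, stringsAsFactors = FALSE)
  attr(truth, "true_theta") <- config$true_theta
  structure(list(exposure = exposure, outcomes = outcomes, ld = ld,
                 truth = truth, config = config, seed = seed),
            class = "synth_region")
}

#' @export
print.synth_region <- function(x, ...) {
  cat("Synthetic cis region:", x$config$n_variants, "variants,",
      x$config$n_causal, "causal; true theta =", x$config$true_theta, "\n")
  cat("  exposure n =", x$config$n_exposure, "; outcome studies:",
      paste(names(x$outcomes), collapse = ", "), "\n")
  invisible(x)
}

#' Write a synthetic study bundle to disk
#'
#' Emits the complete set of plain-text inputs for a pipeline run through
#' the package's own I/O path: one exposure file, one file per outcome
#' study, the LD matrix, the truth table, and a `config.yaml` echoing the
#' generator parameters.
#'
#' @param sim a [generate_region()] result.
#' @param dir output directory (created if needed).
#' @return Named list of written paths, invisibly.
#' @export
write_study_bundle <- function(sim, dir) {
  stopifnot(inherits(sim, "synth_region"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(exposure = file.path(dir, "exposure.tsv"),
                ld = file.path(dir, "ld_matrix.tsv"),
                truth = file.path(dir, "truth.tsv"))
  write_sumstats(sim$exposure, paths$exposure)
  write_ld_matrix(sim$ld, paths$ld)
  tr <- sim$truth
  for (col in c("beta_joint", "beta_marginal", "beta_outcome_marginal", "maf"))
    tr[[col]] <- fmt_num(tr[[col]])
  data.table::fwrite(tr, paths$truth, sep = "\t", quote = FALSE)
  paths$outcomes <- character(0)
  for (s in names(sim$outcomes)) {
    p <- file.path(dir, paste0("outcome_", s, ".tsv"))
    write_sumstats(sim$outcomes[[s]], p)
    paths$outcomes[s] <- p
  }
  cfg <- sim$config
  yaml::write_yaml(list(
    n_variants = cfg$n_variants, n_causal = cfg$n_causal,
    causal_beta_sd = cfg$causal_beta_sd, ld_block_size = cfg$ld_block_size,
    ld_within_block_r = cfg$ld_within_block_r, maf_range = cfg$maf_range,
    n_exposure = cfg$n_exposure, true_theta = cfg$true_theta,
    pleiotropy_sd = cfg$pleiotropy_sd,
    palindromic_fraction = cfg$palindromic_fraction, seed = sim$seed,
    region = list(chrom = cfg$region$chrom, start = cfg$region$start,
                  end = cfg$region$end, flank_bp = cfg$region$flank),
    study_designs = cfg$study_designs),
    file.path(dir, "config.yaml"))
  paths$config <- file.path(dir, "config.yaml")
  invisible(paths)
}
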