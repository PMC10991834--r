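# The MR estimator: per-variant Wald ratios, fixed-effect inverse-variance
# weighted pooling within and across studies, Cochran's Q heterogeneity, and
# odds-ratio scaling.

Z95 <- 1.96  # normal quantile used for all 95% intervals

#' Per-variant Wald ratio estimates
#'
#' The causal effect proxied by one variant is the ratio of its outcome
#' association to its exposure association,
#' `theta = beta_outcome / beta_exposure` (log-odds of the outcome per unit
#' exposure). The default standard error is the first-order delta-method
#' approximation `se_outcome / |beta_exposure|`, which ignores exposure-side
#' uncertainty and is standard for strong instruments; `"delta2"` adds the
#' second-order exposure term
#' `sqrt(se_o^2/b_e^2 + b_o^2 se_e^2 / b_e^4)`.
#'
#' @param h a [harmonise()] result (or its `harmonised` data frame).
#' @param study_label label of the outcome study.
#' @param se_method `"delta1"` (default) or `"delta2"`.
#' @return Data frame of class `wald_estimates`: `variant_id`, `study`,
#'   `theta`, `se`, `ci_low`, `ci_high`.
#' @export
wald_estimates <- function(h, study_label,
                           se_method = c("delta1", "delta2")) {
  se_method <- match.arg(se_method)
  d <- if (inherits(h, "harmonisation")) h$harmonised else h
  if (!nrow(d)) stop("no harmonised instruments to estimate from")
  if (any(d$beta_exposure == 0))
    stop("invalid instrument: beta_exposure is 0 for ",
         paste(d$variant_id[d$beta_exposure == 0], collapse = ", "))
  theta <- d$beta_outcome / d$beta_exposure
  se <- switch(se_method,
    delta1 = d$se_outcome / abs(d$beta_exposure),
    delta2 = sqrt(d$se_outcome^2 / d$beta_exposure^2 +
                  d$beta_outcome^2 * d$se_exposure^2 / d$beta_exposure^4))
  out <- data.frame(variant_id = d$variant_id, study = study_label,
                    theta = theta, se = se,
                    ci_low = theta - Z95 * se, ci_high = theta + Z95 * se,
                    stringsAsFactors = FALSE)
  class(out) <- c("wald_estimates", "data.frame")
  out
}

new_mr_estimate <- function(theta, se, level, label, k, q, q_df, q_p) {
  structure(list(level = level, label = label, k = k,
                 theta = theta, se = se,
                 ci_low = theta - Z95 * se, ci_high = theta + Z95 * se,
                 or = exp(theta),
                 or_ci_low = exp(theta - Z95 * se),
                 or_ci_high = exp(theta + Z95 * se),
                 q = q, q_df = q_df, q_pvalue = q_p),
            class = "mr_estimate")
}

#' Fixed-effect inverse-variance-weighted meta-analysis
#'
#' Pools component estimates with weights `w_j = 1/se_j^2`:
#' `theta = sum(w theta_j) / sum(w)`, `se = 1/sqrt(sum(w))` (fixed effect).
#' Cochran's Q, `sum(w (theta_j - theta)^2)` on `k - 1` degrees of freedom
#' with a chi-square upper-tail p-value, measures heterogeneity among the
#' components; with a single component Q is reported as absent (`NA`).
#' Correlation between components is deliberately ignored (instruments are
#' clumped to near-independence beforehand). With
#' `random_effects = TRUE` the standard error is inflated by the
#' multiplicative heterogeneity factor `sqrt(max(1, Q/(k-1)))`.
#'
#' @param estimates data frame with columns `theta` and `se` (e.g.
#'   [wald_estimates()] output), at least one row, all `se > 0`.
#' @param level provenance of the pooled value: `"per_study"` when pooling
#'   variant-specific ratios within one study, `"pooled_across_studies"`
#'   when pooling study-level estimates.
#' @param label name attached to the estimate (study name or `"pooled"`).
#' @param random_effects use multiplicative random-effects scaling of the
#'   standard error (default fixed effect).
#' @return Object of class `mr_estimate`: `theta`, `se`, `ci_low`,
#'   `ci_high`, odds-ratio scale (`or`, `or_ci_low`, `or_ci_high`), `q`,
#'   `q_df`, `q_pvalue`, `k`, `level`, `label`.
#' @export
ivw <- function(estimates, level = "per_study", label = NA_character_,
                random_effects = FALSE) {
  theta <- estimates$theta
  se <- estimates$se
  k <- length(theta)
  if (k == 0) stop("ivw: no estimates to pool")
  if (any(!is.finite(se) | se <= 0)) stop("ivw: all se must be positive")
  w <- 1 / se^2
  th <- sum(w * theta) / sum(w)
  se_fe <- sqrt(1 / sum(w))
  if (k >= 2) {
    q <- sum(w * (theta - th)^2)
    q_df <- k - 1
    q_p <- stats::pchisq(q, df = q_df, lower.tail = FALSE)
  } else {
    q <- NA_real_; q_df <- NA_integer_; q_p <- NA_real_
  }
  se_out <- if (random_effects && k >= 2) se_fe * sqrt(max(1, q / q_df))
            else se_fe
  new_mr_estimate(th, se_out, level, label, k, q, q_df, q_p)
}

#' Pool study-level MR estimates across GWAS sources
#'
#' Fixed-effect IVW meta-analysis of the study-specific estimates, exactly
#' as [ivw()]; here Cochran's Q measures between-dataset heterogeneity.
#' With fewer than two studies the single estimate is passed through with a
#' warning.
#'
#' @param per_study list of `mr_estimate` objects (one per study).
#' @param random_effects as in [ivw()].
#' @return An `mr_estimate` with `level = "pooled_across_studies"`.
#' @export
pool_studies <- function(per_study, random_effects = FALSE) {
  if (inherits(per_study, "mr_estimate")) per_study <- list(per_study)
  stopifnot(all(vapply(per_study, inherits, logical(1), "mr_estimate")))
  if (length(per_study) < 2) {
    warning("fewer than 2 study estimates; passing the single estimate through",
            call. = FALSE)
    est <- per_study[[1]]
    est$level <- "pooled_across_studies"
    return(est)
  }
  df <- data.frame(theta = vapply(per_study, `[[`, numeric(1), "theta"),
                   se = vapply(per_study, `[[`, numeric(1), "se"))
  ivw(df, level = "pooled_across_studies", label = "pooled",
      random_effects = random_effects)
}

#' @export
print.mr_estimate <- function(x, digits = 3, ...) {
  cat(sprintf("MR estimate [%s%s], k = %d\n", x$level,
              if (!is.na(x$label)) paste0(": ", x$label) else "", x$k))
  cat(sprintf("  logOR % .4f (SE %.4f), 95%% CI % .4f to % .4f\n",
              x$theta, x$se, x$ci_low, x$ci_high))
  cat(sprintf("  OR %.*f, 95%% CI %.*f to %.*f\n", digits, x$or,
              digits, x$or_ci_low, digits, x$or_ci_high))
  if (!is.na(x$q))
    cat(sprintf("  Cochran's Q = %.3f on %d df, p = %.3f\n",
                x$q, x$q_df, x$q_pvalue))
  invisible(x)
}

forest_row <- function(level, study, variant_id, theta, se,
                       q = NA_real_, q_df = NA_integer_, q_p = NA_real_) {
  data.frame(level = level, study = study, variant_id = variant_id,
             logOR = theta, se = se, OR = exp(theta),
             ci_low = exp(theta - Z95 * se), ci_high = exp(theta + Z95 * se),
             Q = q, Q_df = q_df, Q_p = q_p, stringsAsFactors = FALSE)
}

#' Tabular forest report of all estimation levels
#'
#' One row per variant x study (the variant-specific Wald ratios), one row
#' per study (the within-study IVW pool), and one overall row (the
#' across-study IVW pool), each with the odds ratio and 95% CI on the odds
#' scale per unit exposure; heterogeneity columns are filled for the pooled
#' rows.
#'
#' @param wald_by_study named list of [wald_estimates()] data frames.
#' @param study_estimates named list of per-study `mr_estimate` objects.
#' @param pooled the across-study `mr_estimate` (or `NULL` to omit).
#' @return Data frame with columns `level`, `study`, `variant_id`, `logOR`,
#'   `se`, `OR`, `ci_low`, `ci_high`, `Q`, `Q_df`, `Q_p`.
#' @export
forest_table <- function(wald_by_study, study_estimates, pooled = NULL) {
  rows <- list()
  for (s in names(wald_by_study)) {
    w <- wald_by_study[[s]]
    if (nrow(w))
      rows[[length(rows) + 1L]] <-
        forest_row("variant", s, w$variant_id, w$theta, w$se)
  }
  for (s in names(study_estimates)) {
    e <- study_estimates[[s]]
    rows[[length(rows) + 1L]] <-
      forest_row("study", s, NA_character_, e$theta, e$se,
                 e$q, e$q_df, e$q_pvalue)
  }
  if (!is.null(pooled))
    rows[[length(rows) + 1L]] <-
      forest_row("pooled", "all", NA_character_, pooled$theta, pooled$se,
                 pooled$q, pooled$q_df, pooled$q_pvalue)
  out <- if (length(rows)) do.call(rbind, rows) else data.frame(
    level = character(), study = character(), variant_id = character(),
    logOR = numeric(), se = numeric(), OR = numeric(), ci_low = numeric(),
    ci_high = numeric(), Q = numeric(), Q_df = integer(), Q_p = numeric(),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Write a forest table as tab-delimited text
#' @param x a [forest_table()] data frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_forest_table <- function(x, path) {
  out <- x
  for (col in c("logOR", "se", "OR", "ci_low", "ci_high", "Q", "Q_p"))
    out[[col]] <- fmt_num(out[[col]])
  data.table::fwrite(out, path, sep = "\t", quote = FALSE, na = "NA")
  invisible(path)
}
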