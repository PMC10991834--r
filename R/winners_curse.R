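# Winner's curse correction by the FDR inverse quantile transformation
# (FIQT): Benjamini-Hochberg adjust the two-sided p-values over the declared
# selection context, then back-transform to shrunken z-scores.

#' FIQT winner's curse adjustment
#'
#' Effect estimates of variants selected for passing a significance
#' threshold are biased away from zero (winner's curse). FIQT shrinks each
#' z-score `z = beta/se` by Benjamini-Hochberg-adjusting its two-sided
#' normal p-value over the set of tests that selection was performed on,
#' then mapping the adjusted p-value back through the normal quantile:
#' `z_adj = sign(z) * qnorm(1 - p_BH/2)`, `beta_adj = z_adj * se`.
#' Standard errors are not modified. Because BH-adjusted p-values are never
#' smaller than raw ones, `|z_adj| <= |z|` elementwise and the ranking by
#' `|z|` is preserved.
#'
#' The adjustment context matters: winner's curse arises from region-wide
#' selection, so by default the full pre-selection region table should be
#' adjusted (see `fiqt_context` in [mr_analyse()]) and the instruments'
#' adjusted effects read off from it. `context_size` declares the number of
#' tests the FDR correction is computed over and must be at least the number
#' of records supplied.
#'
#' @param x a [sumstats] object (typically variant-exposure associations;
#'   selection was on exposure p-values, so outcome associations are never
#'   adjusted).
#' @param context_size number of tests in the selection context; defaults to
#'   the number of records.
#' @return Object of class `fiqt_result`: list with `variant_id`,
#'   `original_z`, `adjusted_z`, `adjusted_beta`, `bh_adjusted_p`,
#'   `context_size`.
#' @references Bigdeli et al. (2016) Bioinformatics 32:2598-2603 (FIQT).
#' @export
fiqt_adjust <- function(x, context_size = NULL) {
  stopifnot(inherits(x, "sumstats"))
  d <- x$data
  k <- nrow(d)
  if (is.null(context_size)) context_size <- k
  if (context_size < k)
    stop("configuration error: context_size (", context_size,
         ") is smaller than the number of records (", k, ")")
  z <- d$beta / d$se
  p <- 2 * stats::pnorm(-abs(z))
  p_bh <- stats::p.adjust(p, method = "BH", n = context_size)
  # |adj_z| <= |z| holds analytically (BH never lowers a p-value); enforcing
  # it also guards the back-transform where p underflows to 0 in the far tail
  adj_z <- sign(z) * pmin(stats::qnorm(p_bh / 2, lower.tail = FALSE), abs(z))
  if (any(p_bh >= 1))
    message("cismr: ", sum(p_bh >= 1),
            " variant(s) with BH-adjusted p = 1 shrunk to z = 0")
  structure(list(variant_id = d$variant_id, original_z = z,
                 adjusted_z = adj_z, adjusted_beta = adj_z * d$se,
                 bh_adjusted_p = p_bh, context_size = context_size),
            class = "fiqt_result")
}

#' @export
print.fiqt_result <- function(x, ...) {
  cat("FIQT winner's curse adjustment over", x$context_size, "tests,",
      length(x$original_z), "record(s)\n")
  cat(sprintf("  mean |z| %.2f -> %.2f\n", mean(abs(x$original_z)),
              mean(abs(x$adjusted_z))))
  invisible(x)
}

#' Apply the FIQT adjustment to a summary-statistics table
#'
#' Returns the table with `beta` replaced by the adjusted effect and
#' `pvalue` recomputed from the adjusted z (so the table stays internally
#' consistent); the unadjusted effect is retained in `beta_unadjusted` and
#' the flag column `fiqt_adjusted` marks the rows.
#'
#' @inheritParams fiqt_adjust
#' @return The adjusted [sumstats] object, with attribute `"fiqt"` holding
#'   the [fiqt_adjust()] result.
#' @export
fiqt_apply <- function(x, context_size = NULL) {
  fr <- fiqt_adjust(x, context_size)
  x$data$beta_unadjusted <- x$data$beta
  x$data$beta <- fr$adjusted_beta
  x$data$pvalue <- 2 * stats::pnorm(-abs(fr$adjusted_z))
  x$data$fiqt_adjusted <- TRUE
  attr(x, "fiqt") <- fr
  x
}
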