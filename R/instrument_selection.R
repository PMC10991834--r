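# Cis-instrument selection: gene-window filter, significance threshold,
# greedy LD clumping, and instrument-strength diagnostics.

#' Define a gene region with flanking window
#'
#' Coordinates are 1-based and inclusive; `flank` base pairs are added to
#' each side when filtering, so the cis window is
#' `[start - flank, end + flank]`.
#'
#' @param chrom chromosome label (compared as a string).
#' @param start,end gene body coordinates in base pairs, `start <= end`.
#' @param flank window added to each side, in base pairs (`>= 0`).
#' @return An object of class `region_spec`.
#' @examples
#' il6r_region()  # IL6R gene body with the default 100-kb flank
#' @export
region_spec <- function(chrom, start, end, flank = 0) {
  start <- as.numeric(start); end <- as.numeric(end); flank <- as.numeric(flank)
  if (is.na(start) || is.na(end) || start > end)
    stop("region_spec: need start <= end")
  if (is.na(flank) || flank < 0) stop("region_spec: flank must be >= 0")
  structure(list(chrom = as.character(chrom), start = start, end = end,
                 flank = flank), class = "region_spec")
}

#' @export
print.region_spec <- function(x, ...) {
  cat(sprintf("Region chr%s:%d-%d, flank %d bp (window %d-%d)\n",
              x$chrom, x$start, x$end, x$flank,
              x$start - x$flank, x$end + x$flank))
  invisible(x)
}

#' The IL6R gene region used in the reference analysis
#'
#' Gene body Chr1:154377669-154441926 with a 100-kb flank on each side, the
#' cis window from which CRP-associated instruments proxying IL-6 signalling
#' are drawn.
#'
#' @param flank flanking window in bp (default 100 000).
#' @return A [region_spec].
#' @export
il6r_region <- function(flank = 100000) {
  region_spec("1", 154377669, 154441926, flank = flank)
}

#' Restrict a table to a gene region
#'
#' Keeps variants with matching chromosome and position inside
#' `[start - flank, end + flank]`, boundaries inclusive. Idempotent; an
#' empty result is allowed.
#'
#' @param x a [sumstats] object.
#' @param region a [region_spec].
#' @return Filtered `sumstats`.
#' @export
filter_region <- function(x, region) {
  stopifnot(inherits(x, "sumstats"), inherits(region, "region_spec"))
  d <- x$data
  keep <- !is.na(d$chrom) & d$chrom == region$chrom &
    !is.na(d$pos) &
    d$pos >= region$start - region$flank &
    d$pos <= region$end + region$flank
  subset_sumstats(x, keep)
}

#' Significance filter
#'
#' Keeps variants with `pvalue < threshold` (strict inequality).
#'
#' @param x a [sumstats] object.
#' @param threshold p-value threshold in (0, 1); see
#'   [bonferroni_threshold()] for the region-wide default.
#' @return Filtered `sumstats`.
#' @export
filter_pvalue <- function(x, threshold) {
  stopifnot(inherits(x, "sumstats"))
  if (!is.numeric(threshold) || threshold <= 0 || threshold >= 1)
    stop("p-value threshold must lie in (0, 1)")
  subset_sumstats(x, x$data$pvalue < threshold)
}

#' Bonferroni significance threshold
#'
#' `alpha / n_tests`; with the default family-wise level 0.05 over the
#' roughly 1000 variants of a cis region this gives the region-wide
#' threshold 5e-5.
#'
#' @param alpha family-wise error rate.
#' @param n_tests number of tests corrected over.
#' @return The per-test threshold.
#' @examples
#' bonferroni_threshold(0.05, 1000)
#' @export
bonferroni_threshold <- function(alpha = 0.05, n_tests = 1000) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  if (n_tests < 1) stop("n_tests must be >= 1")
  alpha / n_tests
}

#' Greedy LD clumping
#'
#' Sorts variants by ascending p-value (ties broken by ascending
#' `variant_id`, so runs are reproducible), repeatedly keeps the best
#' remaining variant and discards all remaining variants with squared
#' correlation `r^2 > r2_max` against it. The postcondition that all
#' pairwise `r^2` among kept variants is at most `r2_max` is asserted on
#' every run. The result is invariant to input row order.
#'
#' @param x a [sumstats] object; every variant must be present in `ld`.
#' @param ld signed LD correlation matrix (see [read_ld_matrix()]).
#' @param r2_max maximum pairwise squared correlation among kept variants.
#' @return An object of class `instrument_set`: list with `exposure` (the
#'   kept variants as `sumstats`, in selection order) and `selection_log`
#'   (one row per input variant: `variant_id`, `status`, `index_variant`).
#' @export
clump <- function(x, ld, r2_max = 0.1) {
  stopifnot(inherits(x, "sumstats"))
  if (!is.numeric(r2_max) || r2_max < 0 || r2_max > 1)
    stop("r2_max must lie in [0, 1]")
  d <- x$data
  missing <- setdiff(d$variant_id, rownames(ld))
  if (length(missing))
    stop("variant(s) missing from LD matrix: ",
         paste(missing, collapse = ", "))
  ord <- order(d$pvalue, d$variant_id)
  ids <- d$variant_id[ord]
  status <- stats::setNames(rep(NA_character_, length(ids)), ids)
  index_of <- stats::setNames(rep(NA_character_, length(ids)), ids)
  remaining <- ids
  kept <- character(0)
  while (length(remaining)) {
    top <- remaining[1]
    kept <- c(kept, top)
    status[top] <- "kept"
    remaining <- remaining[-1]
    if (length(remaining)) {
      r2 <- ld[top, remaining]^2
      drop <- remaining[r2 > r2_max]
      status[drop] <- "removed-by-clump"
      index_of[drop] <- top
      remaining <- setdiff(remaining, drop)
    }
  }
  if (length(kept) > 1) {
    sub <- ld[kept, kept]^2
    diag(sub) <- 0
    stopifnot(max(sub) <= r2_max + 1e-12)
  }
  log <- data.frame(variant_id = ids, status = unname(status[ids]),
                    index_variant = unname(index_of[ids]),
                    stringsAsFactors = FALSE)
  kept_x <- subset_sumstats(x, match(kept, d$variant_id))
  structure(list(exposure = kept_x, selection_log = log),
            class = "instrument_set")
}

#' @export
print.instrument_set <- function(x, ...) {
  cat("Instrument set:", n_variants(x$exposure), "variant(s) kept of",
      nrow(x$selection_log), "\n")
  print(x$exposure, ...)
  invisible(x)
}

#' Per-variant and mean instrument F-statistics
#'
#' For a variant-exposure association, `F = (beta/se)^2`; a mean F well
#' above 10 indicates weak-instrument bias is negligible.
#'
#' @param x a [sumstats] object with `se > 0`.
#' @return List with `per_variant_f` (named by variant) and `mean_f`.
#' @export
f_statistics <- function(x) {
  stopifnot(inherits(x, "sumstats"))
  f <- (x$data$beta / x$data$se)^2
  names(f) <- x$data$variant_id
  list(per_variant_f = f, mean_f = mean(f))
}

#' Exposure variance explained by a set of independent variants
#'
#' `sum(2 * eaf * (1 - eaf) * beta^2) / trait_variance`, valid for
#' (approximately) independent variants and a standardised exposure; for an
#' unstandardised exposure supply its variance.
#'
#' @param x a [sumstats] object; `eaf` must be present for every variant.
#' @param trait_variance variance of the exposure trait (default 1,
#'   standardised scale).
#' @return Proportion of variance explained.
#' @export
variance_explained <- function(x, trait_variance = 1) {
  stopifnot(inherits(x, "sumstats"))
  d <- x$data
  if (any(is.na(d$eaf)))
    stop("variance_explained: effect-allele frequency missing for ",
         paste(d$variant_id[is.na(d$eaf)], collapse = ", "))
  sum(2 * d$eaf * (1 - d$eaf) * d$beta^2) / trait_variance
}

#' Required sample-size inflation of an MR study
#'
#' An MR study needs roughly `1 / r2` times the sample size of an
#' observational study for the same power, where `r2` is the proportion of
#' exposure variance explained by the instruments.
#'
#' @param r2_total proportion of variance explained, in (0, 1].
#' @return The fold inflation `1 / r2_total`.
#' @examples
#' sample_size_inflation(0.01)  # instruments explaining 1% -> 100-fold
#' @export
sample_size_inflation <- function(r2_total) {
  if (!is.numeric(r2_total) || is.na(r2_total) || r2_total <= 0 ||
      r2_total > 1)
    stop("domain error: r2_total must lie in (0, 1]")
  1 / r2_total
}

#' Instrument-strength diagnostics
#'
#' Bundles [f_statistics()], [variance_explained()] and
#' [sample_size_inflation()] for a selected instrument set.
#'
#' @param x a [sumstats] object of selected instruments.
#' @param trait_variance exposure trait variance (default 1).
#' @return Object of class `strength_diagnostics`: list with
#'   `per_variant_f`, `mean_f`, `r2_total`, `sample_size_inflation`.
#' @export
strength_diagnostics <- function(x, trait_variance = 1) {
  f <- f_statistics(x)
  r2 <- variance_explained(x, trait_variance)
  structure(list(per_variant_f = f$per_variant_f, mean_f = f$mean_f,
                 r2_total = r2,
                 sample_size_inflation = sample_size_inflation(r2)),
            class = "strength_diagnostics")
}

#' @export
print.strength_diagnostics <- function(x, ...) {
  cat(sprintf(paste0("Instrument strength: %d variant(s), mean F = %.1f, ",
                     "variance explained = %.3g%%\n"),
              length(x$per_variant_f), x$mean_f, 100 * x$r2_total))
  cat(sprintf("Equivalent-power MR sample-size inflation: %.3g-fold\n",
              x$sample_size_inflation))
  invisible(x)
}
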