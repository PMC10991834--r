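# End-to-end orchestration: region filter -> significance filter -> LD
# clumping -> winner's curse adjustment -> per-study harmonisation -> Wald
# ratios -> within-study IVW -> across-study IVW, with a machine-readable
# run manifest. The analysis path contains no randomness and all
# tie-breaking is deterministic, so reruns on identical inputs are
# byte-identical.

empty_stage_error <- function(stage) {
  stop(structure(class = c("cismr_empty", "error", "condition"),
                 list(message = paste0("no variants remain after stage: ",
                                       stage),
                      call = NULL, stage = stage)))
}

#' Run the cis-MR analysis on in-memory tables
#'
#' Executes the full estimator: optional gene-window filter, significance
#' filter, greedy LD clumping, FIQT winner's curse adjustment of the
#' exposure effects, per-study harmonisation, Wald ratios, within-study IVW
#' and the across-study IVW pool, plus instrument-strength diagnostics and
#' a forest table. Stage counts are recorded and are non-increasing by
#' construction; if any stage empties the variant set the run terminates
#' with a condition of class `cismr_empty` naming the stage.
#'
#' @param exposure [sumstats] of variant-exposure associations
#'   (quantitative scale).
#' @param outcomes named list of [sumstats] objects of variant-outcome
#'   associations (log-odds scale), one per study; a single `sumstats` is
#'   accepted.
#' @param ld signed LD correlation matrix covering the selected variants.
#' @param region optional [region_spec]; `NULL` if the input is already
#'   region-restricted.
#' @param p_threshold significance threshold (strict), default the
#'   region-wide Bonferroni threshold 5e-5.
#' @param r2_max clumping threshold on squared correlation (default 0.1).
#' @param fiqt apply the FIQT winner's curse correction (default TRUE;
#'   disable for sensitivity analysis).
#' @param fiqt_context `"region"` (default) adjusts over the full
#'   pre-selection region table, matching the selection process that causes
#'   the bias; `"instruments"` adjusts over the selected set only.
#' @param ambiguity_band palindromic frequency ambiguity band, see
#'   [harmonise()].
#' @param se_method Wald-ratio SE method, see [wald_estimates()].
#' @param random_effects multiplicative random-effects SE scaling in the
#'   IVW pools (default fixed-effect).
#' @param trait_variance exposure trait variance for
#'   [variance_explained()].
#' @return Object of class `mr_analysis`: list with `estimates`
#'   (`$per_study`, `$pooled`), `wald`, `forest`, `diagnostics`, `fiqt`,
#'   `harmonisation`, `selection_log`, `counts`, `params`.
#' @export
mr_analyse <- function(exposure, outcomes, ld, region = NULL,
                       p_threshold = bonferroni_threshold(0.05, 1000),
                       r2_max = 0.1, fiqt = TRUE,
                       fiqt_context = c("region", "instruments"),
                       ambiguity_band = c(0.42, 0.58),
                       se_method = c("delta1", "delta2"),
                       random_effects = FALSE, trait_variance = 1) {
  fiqt_context <- match.arg(fiqt_context)
  se_method <- match.arg(se_method)
  if (inherits(outcomes, "sumstats")) {
    outcomes <- stats::setNames(list(outcomes), outcomes$trait_label)
  }
  stopifnot(length(outcomes) >= 1, !is.null(names(outcomes)))

  counts <- list(input = n_variants(exposure))
  tbl <- exposure
  if (!is.null(region)) tbl <- filter_region(tbl, region)
  counts$region <- n_variants(tbl)
  if (!counts$region) empty_stage_error("region filter")

  sig <- filter_pvalue(tbl, p_threshold)
  counts$significant <- n_variants(sig)
  if (!counts$significant) empty_stage_error("p-value filter")

  inst <- clump(sig, ld, r2_max)
  counts$clumped <- n_variants(inst$exposure)

  sel_log <- inst$selection_log
  removed_p <- setdiff(tbl$data$variant_id, sig$data$variant_id)
  if (length(removed_p))
    sel_log <- rbind(sel_log,
                     data.frame(variant_id = removed_p,
                                status = "removed-by-p",
                                index_variant = NA_character_,
                                stringsAsFactors = FALSE))
  if (!is.null(region)) {
    removed_w <- setdiff(exposure$data$variant_id, tbl$data$variant_id)
    if (length(removed_w))
      sel_log <- rbind(sel_log,
                       data.frame(variant_id = removed_w,
                                  status = "removed-by-window",
                                  index_variant = NA_character_,
                                  stringsAsFactors = FALSE))
  }

  diagnostics <- strength_diagnostics(inst$exposure, trait_variance)

  fr <- NULL
  instr_exp <- inst$exposure
  if (fiqt) {
    if (fiqt_context == "region") {
      # adjust the whole pre-selection region, then read the instruments'
      # adjusted effects off it
      adj <- fiqt_apply(tbl, context_size = n_variants(tbl))
      fr <- attr(adj, "fiqt")
      idx <- match(instr_exp$data$variant_id, adj$data$variant_id)
      instr_exp$data$beta_unadjusted <- instr_exp$data$beta
      instr_exp$data$beta <- adj$data$beta[idx]
      instr_exp$data$pvalue <- adj$data$pvalue[idx]
      instr_exp$data$fiqt_adjusted <- TRUE
    } else {
      instr_exp <- fiqt_apply(instr_exp,
                              context_size = n_variants(instr_exp))
      fr <- attr(instr_exp, "fiqt")
    }
  }

  wald_list <- list()
  harm_list <- list()
  est_list <- list()
  counts$harmonised <- integer(0)
  for (s in names(outcomes)) {
    h <- harmonise(instr_exp, outcomes[[s]], ambiguity_band)
    harm_list[[s]] <- h
    counts$harmonised[s] <- nrow(h$harmonised)
    if (!nrow(h$harmonised))
      empty_stage_error(paste0("harmonisation (", s, ")"))
    w <- wald_estimates(h, s, se_method)
    wald_list[[s]] <- w
    est_list[[s]] <- ivw(w, level = "per_study", label = s,
                         random_effects = random_effects)
  }
  pooled <- if (length(est_list) >= 2) {
    pool_studies(est_list, random_effects = random_effects)
  } else {
    est_list[[1]]
  }
  forest <- forest_table(wald_list, est_list,
                         if (length(est_list) >= 2) pooled else NULL)
  structure(list(
    estimates = list(per_study = est_list, pooled = pooled),
    wald = wald_list, forest = forest, diagnostics = diagnostics,
    fiqt = fr, harmonisation = harm_list, selection_log = sel_log,
    counts = counts,
    params = list(p_threshold = p_threshold, r2_max = r2_max,
                  fiqt = fiqt, fiqt_context = fiqt_context,
                  ambiguity_band = ambiguity_band, se_method = se_method,
                  random_effects = random_effects,
                  region = region)),
    class = "mr_analysis")
}

#' @export
print.mr_analysis <- function(x, ...) {
  cat("cis-MR analysis:", x$counts$clumped, "instrument(s) from",
      x$counts$region, "region variants;",
      length(x$estimates$per_study), "outcome study(ies)\n\n")
  print(x$estimates$pooled)
  invisible(x)
}

#' Build a pipeline run configuration
#'
#' Validates input paths and bundles all thresholds for [run_pipeline()].
#'
#' @param exposure path to the exposure summary-statistics file.
#' @param outcomes named character vector of outcome summary-statistics
#'   paths (names are study labels).
#' @param ld path to the LD matrix file.
#' @param out_dir output directory.
#' @param region a [region_spec] or `NULL`.
#' @inheritParams mr_analyse
#' @param column_map column mapping for the input files.
#' @param seed seed recorded in the manifest (the analysis itself is
#'   deterministic).
#' @return Object of class `run_config`.
#' @export
run_config <- function(exposure, outcomes, ld, out_dir,
                       region = NULL,
                       p_threshold = bonferroni_threshold(0.05, 1000),
                       r2_max = 0.1, fiqt = TRUE, fiqt_context = "region",
                       ambiguity_band = c(0.42, 0.58),
                       se_method = "delta1", random_effects = FALSE,
                       trait_variance = 1,
                       column_map = default_column_map(), seed = NULL) {
  paths <- c(exposure, unname(outcomes), ld)
  missing <- paths[!file.exists(paths)]
  if (length(missing))
    stop("configuration error: input file(s) not found: ",
         paste(missing, collapse = ", "))
  if (is.null(names(outcomes)) || any(names(outcomes) == ""))
    stop("configuration error: outcome paths must be named by study")
  structure(list(exposure = exposure, outcomes = outcomes, ld = ld,
                 out_dir = out_dir, region = region,
                 p_threshold = p_threshold, r2_max = r2_max, fiqt = fiqt,
                 fiqt_context = fiqt_context,
                 ambiguity_band = ambiguity_band, se_method = se_method,
                 random_effects = random_effects,
                 trait_variance = trait_variance, column_map = column_map,
                 seed = seed),
            class = "run_config")
}

#' Read a pipeline run configuration from YAML
#'
#' Recognised keys: `exposure`, `outcomes` (map of study label to path),
#' `ld`, `out_dir`, `chrom`/`start`/`end`/`flank_bp` (optional region),
#' `p_threshold`, `r2_max`, `fiqt`, `fiqt_context`, `ambiguity_band`,
#' `se_method`, `random_effects`, `trait_variance`, `seed`. Relative paths
#' are resolved against the configuration file's directory.
#'
#' @param path YAML file path.
#' @return A [run_config].
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  resolve <- function(p)
    ifelse(grepl("^/", p), p, file.path(base, p))
  region <- NULL
  if (!is.null(y$chrom))
    region <- region_spec(y$chrom, y$start, y$end,
                          flank = if (is.null(y$flank_bp)) 0 else y$flank_bp)
  args <- list(exposure = resolve(y$exposure),
               outcomes = vapply(y$outcomes, resolve, character(1)),
               ld = resolve(y$ld),
               out_dir = resolve(y$out_dir),
               region = region)
  for (key in c("p_threshold", "r2_max", "fiqt", "fiqt_context",
                "ambiguity_band", "se_method", "random_effects",
                "trait_variance", "seed"))
    if (!is.null(y[[key]])) args[[key]] <- y[[key]]
  do.call(run_config, args)
}

manifest_lines <- function(config, counts = NULL, status = "ok",
                           stage = NA_character_) {
  lines <- c(
    paste0("cismr_version: ",
           as.character(utils::packageVersion("cismr"))),
    paste0("status: ", status))
  if (!is.na(stage)) lines <- c(lines, paste0("failed_stage: ", stage))
  reg <- config$region
  lines <- c(lines,
    paste0("region: ", if (is.null(reg)) "none" else
      sprintf("chr%s:%d-%d flank %d", reg$chrom, reg$start, reg$end,
              reg$flank)),
    paste0("p_threshold: ", format(config$p_threshold, digits = 15)),
    paste0("r2_max: ", format(config$r2_max, digits = 15)),
    paste0("fiqt: ", config$fiqt),
    paste0("fiqt_context: ", config$fiqt_context),
    paste0("ambiguity_band: ",
           paste(config$ambiguity_band, collapse = "-")),
    paste0("se_method: ", config$se_method),
    paste0("random_effects: ", config$random_effects),
    paste0("seed: ", if (is.null(config$seed)) "none" else config$seed))
  if (!is.null(counts)) {
    lines <- c(lines,
      paste0("n_input: ", counts$input),
      paste0("n_region: ", counts$region),
      paste0("n_significant: ", counts$significant),
      paste0("n_clumped: ", counts$clumped))
    for (s in names(counts$harmonised))
      lines <- c(lines, paste0("n_harmonised_", s, ": ",
                               counts$harmonised[[s]]))
  }
  lines
}

#' Run the full cis-MR pipeline from files
#'
#' Reads the exposure, outcome and LD inputs named in `config`, runs
#' [mr_analyse()], and writes to `config$out_dir`: `forest.tsv` (the forest
#' table), `selection_log.tsv`, `exclusions.tsv` (harmonisation exclusions,
#' all studies), `diagnostics.txt`, and a machine-readable `manifest.txt`
#' echoing every parameter and the per-stage variant counts. If a stage
#' empties the variant set, the run terminates gracefully: the manifest
#' records the failing stage and the returned object has
#' `status = "empty"`.
#'
#' The manifest contains no timestamps; the analysis path is deterministic,
#' so rerunning on identical inputs produces byte-identical outputs.
#'
#' @param config a [run_config] (or path to a YAML file, passed through
#'   [read_run_config()]).
#' @return Invisibly, a list with `status` (`"ok"` or `"empty"`), `result`
#'   (the `mr_analysis`, or the failing stage), and `paths` of written
#'   files.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  exposure <- read_sumstats(config$exposure, column_map = config$column_map,
                            trait_scale = "quantitative")
  outcomes <- lapply(config$outcomes, read_sumstats,
                     column_map = config$column_map,
                     trait_scale = "log_odds")
  names(outcomes) <- names(config$outcomes)
  ld <- read_ld_matrix(config$ld)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest_path <- file.path(config$out_dir, "manifest.txt")

  res <- tryCatch(
    mr_analyse(exposure, outcomes, ld, region = config$region,
               p_threshold = config$p_threshold, r2_max = config$r2_max,
               fiqt = config$fiqt, fiqt_context = config$fiqt_context,
               ambiguity_band = config$ambiguity_band,
               se_method = config$se_method,
               random_effects = config$random_effects,
               trait_variance = config$trait_variance),
    cismr_empty = function(e) e)

  if (inherits(res, "cismr_empty")) {
    writeLines(manifest_lines(config, status = "empty", stage = res$stage),
               manifest_path)
    message("pipeline terminated: ", conditionMessage(res))
    return(invisible(list(status = "empty", stage = res$stage,
                          paths = list(manifest = manifest_path))))
  }

  paths <- list(
    forest = file.path(config$out_dir, "forest.tsv"),
    selection_log = file.path(config$out_dir, "selection_log.tsv"),
    exclusions = file.path(config$out_dir, "exclusions.tsv"),
    diagnostics = file.path(config$out_dir, "diagnostics.txt"),
    manifest = manifest_path)
  write_forest_table(res$forest, paths$forest)
  data.table::fwrite(res$selection_log, paths$selection_log, sep = "\t",
                     quote = FALSE, na = "NA")
  excl <- do.call(rbind, lapply(names(res$harmonisation), function(s) {
    e <- res$harmonisation[[s]]$exclusions
    if (nrow(e)) cbind(study = s, e) else NULL
  }))
  if (is.null(excl))
    excl <- data.frame(study = character(), variant_id = character(),
                       reason = character(), rule = character())
  data.table::fwrite(excl, paths$exclusions, sep = "\t", quote = FALSE)
  d <- res$diagnostics
  writeLines(c(sprintf("mean_f: %.10g", d$mean_f),
               sprintf("r2_total: %.10g", d$r2_total),
               sprintf("sample_size_inflation: %.10g",
                       d$sample_size_inflation),
               sprintf("per_variant_f_%s: %.10g",
                       names(d$per_variant_f), d$per_variant_f)),
             paths$diagnostics)
  writeLines(manifest_lines(config, counts = res$counts), manifest_path)
  invisible(list(status = "ok", result = res, paths = paths))
}

#' Replicate the pipeline on freshly simulated regions
#'
#' Simulation driver for calibration and power studies: for each replicate,
#' generates a region with [generate_region()] (seeds `seed`, `seed + 1`,
#' ...) and runs [mr_analyse()] on it (no region filter; the generated
#' table is already region-restricted, and the FIQT context is the full
#' generated region). Replicates where selection leaves no instrument are
#' recorded as `NA` rows.
#'
#' @param config a [synth_config].
#' @param n_reps number of replicates.
#' @param seed base seed; replicate `i` uses `seed + i - 1`.
#' @param ... further arguments to [mr_analyse()] (e.g. `fiqt = FALSE`,
#'   `p_threshold`).
#' @return Data frame with one row per replicate: `rep`, `theta`, `se`,
#'   `ci_low`, `ci_high`, `n_instruments`, `excludes_zero` (whether the
#'   pooled 95% CI excludes a zero log-odds effect).
#' @export
simulate_mr <- function(config, n_reps, seed = 1L, ...) {
  stopifnot(inherits(config, "synth_config"), n_reps >= 1)
  ld <- synth_ld_matrix(config)
  out <- data.frame(rep = seq_len(n_reps), theta = NA_real_, se = NA_real_,
                    ci_low = NA_real_, ci_high = NA_real_,
                    n_instruments = NA_integer_, excludes_zero = NA)
  for (i in seq_len(n_reps)) {
    sim <- generate_region(config, seed = seed + i - 1L, ld = ld)
    res <- tryCatch(
      suppressMessages(suppressWarnings(
        mr_analyse(sim$exposure, sim$outcomes, sim$ld, region = NULL, ...))),
      cismr_empty = function(e) NULL)
    if (is.null(res)) next
    p <- res$estimates$pooled
    out$theta[i] <- p$theta
    out$se[i] <- p$se
    out$ci_low[i] <- p$ci_low
    out$ci_high[i] <- p$ci_high
    out$n_instruments[i] <- res$counts$clumped
    out$excludes_zero[i] <- p$ci_low > 0 || p$ci_high < 0
  }
  out
}
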