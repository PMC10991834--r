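# Reading, validating and writing GWAS summary statistics and LD matrices.
# All formats are delimited text with a header; coordinates are 1-based
# inclusive base pairs throughout the package.

.mandatory_fields <- c("variant_id", "chrom", "pos", "effect_allele",
                       "other_allele", "eaf", "beta", "se", "pvalue", "n")
.optional_fields <- "n_cases"

#' Default column mapping for GWAS summary-statistics files
#'
#' Maps the package's canonical field names to the column headers commonly
#' found in GWAS summary-statistics files, so typical files load without
#' renaming columns. Override individual entries to read other dialects,
#' e.g. `default_column_map()` with `beta = "b"`.
#'
#' @param ... named overrides, one per canonical field (e.g.
#'   `variant_id = "rsid"`).
#' @return Named character vector mapping canonical field names
#'   (`variant_id`, `chrom`, `pos`, `effect_allele`, `other_allele`, `eaf`,
#'   `beta`, `se`, `pvalue`, `n`, `n_cases`) to file column headers.
#' @examples
#' default_column_map()
#' default_column_map(pvalue = "p_value", n = "sample_size")
#' @export
default_column_map <- function(...) {
  map <- c(variant_id = "SNP", chrom = "CHR", pos = "BP",
           effect_allele = "EA", other_allele = "OA", eaf = "EAF",
           beta = "BETA", se = "SE", pvalue = "P", n = "N",
           n_cases = "N_CASES")
  over <- c(...)
  if (length(over)) {
    bad <- setdiff(names(over), names(map))
    if (length(bad))
      stop("unknown column-map field(s): ", paste(bad, collapse = ", "))
    map[names(over)] <- over
  }
  map
}

empty_rejection_report <- function() {
  data.frame(row = integer(), variant_id = character(),
             reason = character(), original = character(),
             stringsAsFactors = FALSE)
}

# Row-level validation. Never mutates values beyond the two documented
# normalisations (alleles uppercased, p = 0 replaced by the smallest positive
# double); rejected rows are returned verbatim in the report.
validate_sumstats_rows <- function(df, z_tolerance = 0.1) {
  n <- nrow(df)
  reasons <- vector("list", n)
  add <- function(idx, why) {
    for (i in which(idx)) reasons[[i]] <<- c(reasons[[i]], why)
  }
  original <- if (n) apply(df, 1L, paste, collapse = "\t") else character()

  df$variant_id <- as.character(df$variant_id)
  df$chrom <- as.character(df$chrom)
  for (col in c("pos", "eaf", "beta", "se", "pvalue", "n"))
    if (!is.double(df[[col]])) df[[col]] <- suppressWarnings(as.numeric(df[[col]]))
  if ("n_cases" %in% names(df) && !is.double(df$n_cases))
    df$n_cases <- suppressWarnings(as.numeric(df$n_cases))

  ea <- toupper(as.character(df$effect_allele))
  oa <- toupper(as.character(df$other_allele))
  if (n && (any(ea != df$effect_allele, na.rm = TRUE) ||
            any(oa != df$other_allele, na.rm = TRUE)))
    message("cismr: lowercase alleles normalised to uppercase")
  df$effect_allele <- ea
  df$other_allele <- oa

  add(is.na(df$variant_id) | df$variant_id == "", "missing variant ID")
  add(duplicated(df$variant_id) & !is.na(df$variant_id) & df$variant_id != "",
      "duplicate variant ID")
  ok_allele <- function(a) !is.na(a) & grepl("^[ACGT]+$", a)
  add(!ok_allele(df$effect_allele) | !ok_allele(df$other_allele),
      "unparseable allele")
  add(ok_allele(df$effect_allele) & ok_allele(df$other_allele) &
        df$effect_allele == df$other_allele, "identical alleles")
  add(!is.finite(df$beta), "non-numeric beta")
  add(!is.finite(df$se) | df$se <= 0, "non-positive SE")
  add(!is.na(df$pos) & df$pos < 1, "non-positive position")
  add(!is.na(df$eaf) & (df$eaf < 0 | df$eaf > 1),
      "allele frequency out of [0,1]")
  add(!is.na(df$n) & df$n <= 0, "non-positive sample size")

  p_bad <- is.na(df$pvalue) | df$pvalue < 0 | df$pvalue > 1
  add(p_bad, "p-value outside (0,1]")
  p_zero <- !p_bad & df$pvalue == 0
  if (any(p_zero)) {
    warning(sum(p_zero), " p-value(s) of exactly 0 replaced by the smallest ",
            "positive double (needed for quantile back-transformation)",
            call. = FALSE)
    df$pvalue[p_zero] <- .Machine$double.xmin
  }

  # reported p must round-trip with |beta/se| under the two-sided normal
  chk <- !p_bad & !p_zero & is.finite(df$beta) & is.finite(df$se) & df$se > 0
  if (any(chk)) {
    z_imp <- abs(df$beta[chk]) / df$se[chk]
    z_rep <- stats::qnorm(df$pvalue[chk] / 2, lower.tail = FALSE)
    bad <- abs(z_rep - z_imp) > pmax(z_tolerance, 0.05 * z_imp)
    idx <- logical(n); idx[which(chk)[bad]] <- TRUE
    add(idx, "p-value inconsistent with beta/se")
  }

  rej <- !vapply(reasons, is.null, logical(1))
  report <- data.frame(
    row = which(rej),
    variant_id = df$variant_id[rej],
    reason = vapply(reasons[rej], paste, character(1), collapse = "; "),
    original = original[rej],
    stringsAsFactors = FALSE)
  list(data = df[!rej, , drop = FALSE], rejected = report)
}

#' Construct a summary-statistics table
#'
#' Wraps a data frame of per-variant associations for one trait in a
#' validated container. Fields: `variant_id`, `chrom`, `pos` (1-based bp),
#' `effect_allele`, `other_allele`, `eaf`, `beta`, `se`, `pvalue`, `n` and
#' optionally `n_cases`. The exposure trait is on the standardised
#' quantitative scale; case-control outcomes are on the log-odds scale.
#'
#' Validation rejects (never silently drops) rows with missing or duplicate
#' IDs, unparseable alleles, non-positive SEs, out-of-range frequencies or
#' p-values, or a p-value inconsistent with `2*pnorm(-|beta/se|)`. Rejected
#' rows are reported via [rejected_rows()]. p-values of exactly 0 are
#' replaced by the smallest positive double with a warning.
#'
#' @param data data frame with the fields above.
#' @param trait_label short trait name (e.g. `"CRP"`).
#' @param trait_scale `"quantitative"` (SD units) or `"log_odds"`.
#' @param validate run row validation (disable only for internally
#'   constructed, already-validated tables).
#' @return An object of class `sumstats`: a list with elements `trait_label`,
#'   `trait_scale`, `data` (the validated rows) and `rejected` (the report).
#' @seealso [read_sumstats()], [write_sumstats()]
#' @export
sumstats <- function(data, trait_label = "trait",
                     trait_scale = c("quantitative", "log_odds"),
                     validate = TRUE) {
  trait_scale <- match.arg(trait_scale)
  data <- as.data.frame(data, stringsAsFactors = FALSE)
  miss <- setdiff(.mandatory_fields, names(data))
  if (length(miss))
    stop("configuration error: missing mandatory column(s): ",
         paste(miss, collapse = ", "))
  rejected <- empty_rejection_report()
  if (validate) {
    v <- validate_sumstats_rows(data)
    data <- v$data
    rejected <- v$rejected
    if (nrow(rejected))
      message("cismr: rejected ", nrow(rejected), " row(s); see rejected_rows()")
  }
  rownames(data) <- NULL
  structure(list(trait_label = trait_label, trait_scale = trait_scale,
                 data = data, rejected = rejected),
            class = "sumstats")
}

#' @export
print.sumstats <- function(x, ...) {
  cat("GWAS summary statistics: ", x$trait_label,
      " (", x$trait_scale, " scale), ", nrow(x$data), " variants\n", sep = "")
  if (nrow(x$rejected))
    cat("  ", nrow(x$rejected), "row(s) rejected at validation\n")
  if (nrow(x$data)) print(utils::head(x$data, 6), ...)
  invisible(x)
}

#' @export
as.data.frame.sumstats <- function(x, ...) x$data

#' Number of variants in a summary-statistics table
#' @param x a `sumstats` object.
#' @return Integer count of validated rows.
#' @export
n_variants <- function(x) nrow(x$data)

#' Rows rejected during validation
#' @param x a `sumstats` object.
#' @return Data frame with columns `row`, `variant_id`, `reason`, `original`
#'   (the rejected row's original text).
#' @export
rejected_rows <- function(x) x$rejected

# internal: subset preserving metadata, no re-validation
subset_sumstats <- function(x, idx) {
  x$data <- x$data[idx, , drop = FALSE]
  rownames(x$data) <- NULL
  x
}

#' Read GWAS summary statistics from delimited text
#'
#' Reads a tab- or comma-delimited file with a header row, maps its columns
#' to the canonical fields via `column_map`, and validates every row.
#' Rows failing validation are rejected with a per-row reason, available
#' through [rejected_rows()]; a missing mandatory column is a configuration
#' error.
#'
#' @param path file path.
#' @param column_map named mapping from canonical fields to file headers;
#'   see [default_column_map()].
#' @param trait_scale `"quantitative"` or `"log_odds"`.
#' @param trait_label trait name; defaults to the file name.
#' @return A [sumstats] object.
#' @export
read_sumstats <- function(path, column_map = default_column_map(),
                          trait_scale = c("quantitative", "log_odds"),
                          trait_label = NULL) {
  trait_scale <- match.arg(trait_scale)
  if (is.null(trait_label))
    trait_label <- sub("\\.[^.]*$", "", basename(path))
  raw <- data.table::fread(path, data.table = FALSE, showProgress = FALSE)
  need <- column_map[.mandatory_fields]
  miss <- .mandatory_fields[!(need %in% names(raw))]
  if (length(miss))
    stop("configuration error: file ", path, " lacks column(s) ",
         paste(column_map[miss], collapse = ", "),
         " (mapped fields: ", paste(miss, collapse = ", "), ")")
  df <- stats::setNames(raw[, need, drop = FALSE], .mandatory_fields)
  nc <- column_map[["n_cases"]]
  if (!is.na(nc) && nc %in% names(raw)) df$n_cases <- raw[[nc]]
  sumstats(df, trait_label = trait_label, trait_scale = trait_scale)
}

fmt_num <- function(v) {
  out <- sprintf("%.17g", v)
  out[is.na(v)] <- "NA"
  out
}

#' Write summary statistics as tab-delimited text
#'
#' Writes with the canonical headers of [default_column_map()] and 17
#' significant digits, so `read_sumstats(write_sumstats(x))` reproduces every
#' field exactly.
#'
#' @param x a `sumstats` object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_sumstats <- function(x, path) {
  stopifnot(inherits(x, "sumstats"))
  map <- default_column_map()
  df <- x$data
  fields <- intersect(c(.mandatory_fields, .optional_fields), names(df))
  out <- df[, fields, drop = FALSE]
  for (col in c("pos", "eaf", "beta", "se", "pvalue", "n", "n_cases"))
    if (col %in% names(out)) out[[col]] <- fmt_num(out[[col]])
  names(out) <- map[fields]
  data.table::fwrite(out, path, sep = "\t", quote = FALSE, na = "NA")
  invisible(path)
}

#' Validate an LD correlation matrix
#'
#' Checks that `r` is square with variant IDs as dimnames, symmetric within
#' `tol`, has a unit diagonal, and all entries in `[-1, 1]`. Entries are
#' signed correlations; clumping squares them.
#'
#' @param r numeric matrix with identical row and column names.
#' @param tol symmetry / diagonal tolerance (default `1e-8`).
#' @return `r`, invisibly, if valid; otherwise an error.
#' @export
validate_ld_matrix <- function(r, tol = 1e-8) {
  if (!is.matrix(r) || !is.numeric(r) || nrow(r) != ncol(r))
    stop("LD matrix format error: not a square numeric matrix")
  ids <- rownames(r)
  if (is.null(ids) || is.null(colnames(r)) || !identical(ids, colnames(r)))
    stop("LD matrix format error: row and column variant IDs must match")
  if (anyDuplicated(ids))
    stop("LD matrix format error: duplicated variant IDs")
  if (any(!is.finite(r)))
    stop("LD matrix format error: non-finite entries")
  if (max(abs(r - t(r))) > tol)
    stop("LD matrix format error: asymmetric beyond tolerance ",
         format(tol))
  if (max(abs(diag(r) - 1)) > tol)
    stop("LD matrix format error: diagonal entries must be 1")
  if (max(abs(r)) > 1 + tol)
    stop("LD matrix format error: entries outside [-1, 1]")
  invisible(r)
}

#' Read a precomputed LD correlation matrix
#'
#' Expects delimited text with a header row of variant IDs and an ID column
#' first: the square matrix of signed pairwise correlations (e.g. estimated
#' from a reference panel such as 1000 Genomes). The matrix is validated
#' with [validate_ld_matrix()].
#'
#' @param path file path.
#' @param tol symmetry tolerance passed to the validator.
#' @return Numeric matrix with variant-ID dimnames.
#' @export
read_ld_matrix <- function(path, tol = 1e-8) {
  raw <- data.table::fread(path, data.table = FALSE, showProgress = FALSE)
  ids <- as.character(raw[[1]])
  m <- as.matrix(raw[, -1, drop = FALSE])
  if (!is.numeric(m))
    stop("LD matrix format error: non-numeric entries in ", path)
  storage.mode(m) <- "double"
  rownames(m) <- ids
  if (!identical(colnames(m), ids))
    stop("LD matrix format error: header IDs do not match ID column in ",
         path)
  validate_ld_matrix(m, tol = tol)
  m
}

#' Write an LD correlation matrix as delimited text
#' @param r validated LD matrix (variant-ID dimnames).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_ld_matrix <- function(r, path) {
  validate_ld_matrix(r)
  out <- data.frame(ID = rownames(r),
                    matrix(sprintf("%.17g", r), nrow = nrow(r),
                           dimnames = list(NULL, colnames(r))),
                    check.names = FALSE, stringsAsFactors = FALSE)
  data.table::fwrite(out, path, sep = "\t", quote = FALSE)
  invisible(path)
}
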