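# Allele harmonisation: align exposure and outcome associations to a shared
# effect allele, resolving strand flips and excluding palindromic variants
# whose orientation cannot be settled by allele frequency.

.complement <- c(A = "T", C = "G", G = "C", T = "A")

is_palindromic <- function(effect_allele, other_allele) {
  nchar(effect_allele) == 1 & nchar(other_allele) == 1 &
    unname(.complement[effect_allele]) == other_allele
}

#' Harmonise exposure and outcome summary statistics
#'
#' For every exposure variant found in the outcome table, aligns the outcome
#' association to the exposure's effect allele:
#' * alleles match directly: no action;
#' * alleles swapped: outcome beta sign-flipped, `eaf_outcome <- 1 - eaf`;
#' * alleles match under reverse complement: strand flip, then as above;
#' * palindromic pair (A/T or C/G): strand orientation is ambiguous, so the
#'   effect-allele frequencies decide. If either study's frequency lies
#'   inside the ambiguity band the variant is excluded
#'   (`"palindromic-ambiguous"`); otherwise concordant sides of 0.5 keep the
#'   label alignment and discordant sides imply the opposite strand, i.e. an
#'   additional sign flip;
#' * irreconcilable alleles: excluded (`"allele-mismatch"`).
#'
#' Variants absent from the outcome are excluded (`"missing-in-outcome"`),
#' indels / multi-base alleles are excluded (`"non-SNP"`), and palindromic
#' variants lacking a frequency in either study are excluded. Non-palindromic
#' variants with missing frequency are kept with a warning. Every exclusion
#' is reported, never silent.
#'
#' @param exposure,outcome [sumstats] objects sharing variant IDs.
#' @param ambiguity_band frequency interval within which a palindromic
#'   variant cannot be aligned; default `c(0.42, 0.58)`.
#' @return Object of class `harmonisation`: list with `harmonised` (data
#'   frame: `variant_id`, `effect_allele`, `other_allele`, `beta_exposure`,
#'   `se_exposure`, `eaf_exposure`, `beta_outcome`, `se_outcome`,
#'   `eaf_outcome`, `action`, `palindromic`) and `exclusions` (data frame:
#'   `variant_id`, `reason`, `rule`).
#' @export
harmonise <- function(exposure, outcome, ambiguity_band = c(0.42, 0.58)) {
  stopifnot(inherits(exposure, "sumstats"), inherits(outcome, "sumstats"))
  if (length(ambiguity_band) != 2 || ambiguity_band[1] > ambiguity_band[2])
    stop("ambiguity_band must be c(low, high) with low <= high")
  ed <- exposure$data
  od <- outcome$data
  oi <- match(ed$variant_id, od$variant_id)

  n <- nrow(ed)
  rows <- vector("list", n)
  excl <- vector("list", n)
  n_missing_eaf <- 0L
  in_band <- function(f) f >= ambiguity_band[1] & f <= ambiguity_band[2]

  for (i in seq_len(n)) {
    id <- ed$variant_id[i]
    j <- oi[i]
    if (is.na(j)) {
      excl[[i]] <- c(id, "missing-in-outcome", "presence")
      next
    }
    ea <- ed$effect_allele[i]; oa <- ed$other_allele[i]
    oea <- od$effect_allele[j]; ooa <- od$other_allele[j]
    if (any(nchar(c(ea, oa, oea, ooa)) > 1)) {
      excl[[i]] <- c(id, "non-SNP", "allele-pair")
      next
    }
    bo <- od$beta[j]; eo <- od$eaf[j]
    pal <- unname(.complement[ea]) == oa
    action <- "none"
    if (!pal) {
      if (oea == ea && ooa == oa) {
        action <- "none"
      } else if (oea == oa && ooa == ea) {
        bo <- -bo; eo <- 1 - eo; action <- "sign_flip"
      } else {
        cea <- unname(.complement[oea]); coa <- unname(.complement[ooa])
        if (cea == ea && coa == oa) {
          action <- "strand_flip"
        } else if (cea == oa && coa == ea) {
          bo <- -bo; eo <- 1 - eo; action <- "strand_flip_and_sign_flip"
        } else {
          excl[[i]] <- c(id, "allele-mismatch", "allele-pair")
          next
        }
      }
      if (is.na(ed$eaf[i]) || is.na(eo)) n_missing_eaf <- n_missing_eaf + 1L
    } else {
      # palindromic: the complement pair equals the swapped pair, so only
      # label orientation plus frequency concordance can align it
      if (!setequal(c(oea, ooa), c(ea, oa))) {
        excl[[i]] <- c(id, "allele-mismatch", "allele-pair")
        next
      }
      if (is.na(ed$eaf[i]) || is.na(eo)) {
        excl[[i]] <- c(id, "palindromic-ambiguous", "palindromic-frequency")
        next
      }
      if (oea == oa) {
        bo <- -bo; eo <- 1 - eo; action <- "sign_flip"
      }
      if (in_band(ed$eaf[i]) || in_band(eo)) {
        excl[[i]] <- c(id, "palindromic-ambiguous", "palindromic-frequency")
        next
      }
      if ((ed$eaf[i] > 0.5) != (eo > 0.5)) {
        # discordant frequencies: outcome reported on the opposite strand
        bo <- -bo; eo <- 1 - eo
        action <- if (action == "none") "strand_flip_and_sign_flip"
                  else "strand_flip"
      }
    }
    rows[[i]] <- data.frame(
      variant_id = id, effect_allele = ea, other_allele = oa,
      beta_exposure = ed$beta[i], se_exposure = ed$se[i],
      eaf_exposure = ed$eaf[i],
      beta_outcome = bo, se_outcome = od$se[j], eaf_outcome = eo,
      action = action, palindromic = pal, stringsAsFactors = FALSE)
  }
  if (n_missing_eaf)
    warning(n_missing_eaf, " non-palindromic variant(s) kept despite a ",
            "missing allele frequency", call. = FALSE)
  harm <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(harm))
    harm <- data.frame(variant_id = character(), effect_allele = character(),
                       other_allele = character(), beta_exposure = numeric(),
                       se_exposure = numeric(), eaf_exposure = numeric(),
                       beta_outcome = numeric(), se_outcome = numeric(),
                       eaf_outcome = numeric(), action = character(),
                       palindromic = logical(), stringsAsFactors = FALSE)
  rownames(harm) <- NULL
  ex <- excl[!vapply(excl, is.null, logical(1))]
  exclusions <- if (length(ex)) {
    m <- do.call(rbind, ex)
    data.frame(variant_id = m[, 1], reason = m[, 2], rule = m[, 3],
               stringsAsFactors = FALSE)
  } else {
    data.frame(variant_id = character(), reason = character(),
               rule = character(), stringsAsFactors = FALSE)
  }
  structure(list(harmonised = harm, exclusions = exclusions,
                 exposure_trait = exposure$trait_label,
                 outcome_trait = outcome$trait_label),
            class = "harmonisation")
}

#' @export
print.harmonisation <- function(x, ...) {
  cat("Harmonisation ", x$exposure_trait, " -> ", x$outcome_trait, ": ",
      nrow(x$harmonised), " aligned, ", nrow(x$exclusions), " excluded\n",
      sep = "")
  if (nrow(x$exclusions))
    print(table(x$exclusions$reason))
  invisible(x)
}

#' Write a harmonisation exclusion report
#' @param x a `harmonisation` object.
#' @param path output path for the delimited report
#'   (`variant_id`, `reason`, `rule`).
#' @return `path`, invisibly.
#' @export
write_exclusion_report <- function(x, path) {
  stopifnot(inherits(x, "harmonisation"))
  data.table::fwrite(x$exclusions, path, sep = "\t", quote = FALSE)
  invisible(path)
}
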