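# GWAS summary-statistics container, delimited-text I/O, allele harmonization.

SUMSTATS_COLS <- c("variant_id", "chrom", "pos", "effect_allele", "other_allele",
                   "eaf", "beta", "se", "pval", "n")

VALID_ALLELES <- c("A", "C", "G", "T")

#' Construct a GWAS summary-statistics table
#'
#' A `sumstats_table` holds one GWAS: one row per biallelic SNP with its
#' association estimate for a single trait. Rows violating the per-variant
#' invariants (positive `se`, `eaf` in \[0, 1\], `pval` in (0, 1\], single-base
#' distinct alleles, `pos >= 1`) are removed and recorded with a reason; the
#' table is never rejected wholesale because of a bad row.
#'
#' @param records data.frame with columns `variant_id`, `chrom`, `pos`,
#'   `effect_allele`, `other_allele`, `eaf`, `beta`, `se`, `pval`, `n`.
#'   `eaf` and `n` may be `NA`.
#' @param trait_id short machine identifier for the trait.
#' @param trait_label human-readable trait name (defaults to `trait_id`).
#' @return Object of class `sumstats_table`: a list with `trait_id`,
#'   `trait_label`, `records` (validated data.frame) and `rejected`
#'   (data.frame of `variant_id`, `reason`).
#' @export
sumstats_table <- function(records, trait_id = "trait", trait_label = trait_id) {
  stopifnot(is.data.frame(records))
  missing_cols <- setdiff(SUMSTATS_COLS, names(records))
  if (length(missing_cols) > 0L) {
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  records <- records[, SUMSTATS_COLS, drop = FALSE]
  records$variant_id <- as.character(records$variant_id)
  records$chrom <- as.character(records$chrom)
  records$effect_allele <- toupper(as.character(records$effect_allele))
  records$other_allele <- toupper(as.character(records$other_allele))
  for (col in c("pos", "eaf", "beta", "se", "pval", "n")) {
    records[[col]] <- suppressWarnings(as.numeric(records[[col]]))
  }

  reason <- rep(NA_character_, nrow(records))
  flag <- function(bad, why) {
    bad[is.na(bad)] <- FALSE
    reason[is.na(reason) & bad] <<- why
  }
  flag(is.na(records$variant_id) | records$variant_id == "", "missing variant_id")
  flag(duplicated(records$variant_id), "duplicate variant_id")
  flag(is.na(records$beta), "unparseable beta")
  flag(is.na(records$se), "unparseable se")
  flag(is.na(records$pval), "unparseable pval")
  flag(is.na(records$pos), "unparseable pos")
  flag(records$se <= 0, "nonpositive se")
  flag(records$pval <= 0 | records$pval > 1, "pval outside (0,1]")
  flag(records$pos < 1, "pos < 1")
  flag(!is.na(records$eaf) & (records$eaf < 0 | records$eaf > 1), "eaf outside [0,1]")
  flag(!is.na(records$n) & records$n <= 0, "nonpositive n")
  flag(!(records$effect_allele %in% VALID_ALLELES) |
         !(records$other_allele %in% VALID_ALLELES), "non-SNP allele")
  flag(records$effect_allele == records$other_allele, "identical alleles")

  keep <- is.na(reason)
  rejected <- data.frame(variant_id = records$variant_id[!keep],
                         reason = reason[!keep], stringsAsFactors = FALSE)
  out <- list(trait_id = as.character(trait_id),
              trait_label = as.character(trait_label),
              records = records[keep, , drop = FALSE],
              rejected = rejected)
  rownames(out$records) <- NULL
  class(out) <- "sumstats_table"
  out
}

#' @export
print.sumstats_table <- function(x, ...) {
  cat(sprintf("<sumstats_table> trait '%s' (%s): %d variants, %d rejected\n",
              x$trait_id, x$trait_label, nrow(x$records), nrow(x$rejected)))
  invisible(x)
}

#' Number of variants in a summary-statistics table
#' @param table a `sumstats_table`.
#' @return integer count of retained variants.
#' @export
n_variants <- function(table) nrow(table$records)

#' Read GWAS summary statistics from delimited text
#'
#' Canonical dialect: tab-separated with header
#' `variant_id chrom pos effect_allele other_allele eaf beta se pval n` and
#' missing values coded `NA`. Files with foreign headers are mapped through
#' `column_map`. Rows failing invariant checks are dropped row-by-row and
#' reported in the returned table's `rejected` slot; only a missing mandatory
#' column is a hard error.
#'
#' @param path path to a delimited text file with a header row.
#' @param column_map optional named character vector mapping file column names
#'   to canonical field names, e.g. `c(b = "beta", SNP = "variant_id")`.
#' @param trait_id,trait_label trait identifiers stored on the table.
#' @param sep field separator (default tab).
#' @param missing_token string representing missing values (default `"NA"`).
#' @return a [sumstats_table].
#' @export
read_sumstats <- function(path, column_map = NULL, trait_id = "trait",
                          trait_label = trait_id, sep = "\t",
                          missing_token = "NA") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          na.strings = missing_token,
                          colClasses = "character",
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (!is.null(column_map)) {
    stopifnot(!is.null(names(column_map)))
    hit <- names(df) %in% names(column_map)
    names(df)[hit] <- unname(column_map[names(df)[hit]])
  }
  sumstats_table(ensure_sumstats_cols(df), trait_id = trait_id,
                 trait_label = trait_label)
}

# Promote a character data.frame to the canonical column set; error on a
# missing mandatory column (eaf and n are optional and default to NA).
ensure_sumstats_cols <- function(df) {
  for (opt in c("eaf", "n")) if (!opt %in% names(df)) df[[opt]] <- NA
  missing_cols <- setdiff(SUMSTATS_COLS, names(df))
  if (length(missing_cols) > 0L) {
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  df[, SUMSTATS_COLS, drop = FALSE]
}

#' Write a summary-statistics table in the canonical dialect
#'
#' Tab-separated, canonical header, missing values as `missing_token`.
#' `read_sumstats()` on the written file reproduces the table field-for-field.
#'
#' @param table a [sumstats_table].
#' @param path output path.
#' @param missing_token token used for missing values (default `"NA"`).
#' @return invisibly, `path`.
#' @export
write_sumstats <- function(table, path, missing_token = "NA") {
  stopifnot(inherits(table, "sumstats_table"))
  utils::write.table(table$records, file = path, sep = "\t", na = missing_token,
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

DNA_COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

is_palindromic <- function(a1, a2) DNA_COMPLEMENT[a1] == a2

#' Harmonize exposure and outcome summary statistics
#'
#' Aligns the outcome GWAS to the exposure GWAS effect alleles so that per-SNP
#' effect pairs refer to the same allele, the prerequisite for any two-sample
#' MR estimator. Variants present in only one table are ignored. When the
#' outcome reports the swapped allele pair, its beta is negated and its
#' effect-allele frequency replaced by `1 - eaf`; alleles reported on the
#' opposite strand are complemented before matching. Strand-ambiguous
#' (palindromic A/T or C/G) variants are dropped under `"drop_all"`, or
#' resolved by comparing allele frequencies to 0.5 under `"infer_by_eaf"`
#' and dropped when either frequency lies within `palindrome_threshold` of
#' 0.5 (or is missing). Irreconcilable allele sets are dropped with a reason.
#'
#' @param exposure,outcome [sumstats_table] objects for the two traits.
#' @param palindrome_policy `"infer_by_eaf"` (default) or `"drop_all"`.
#' @param palindrome_threshold drop a palindromic variant when either eaf is
#'   within this distance of 0.5 (default 0.08, i.e. eaf in \[0.42, 0.58\]).
#' @return Object of class `harmonized_set`: list with `exposure_id`,
#'   `outcome_id`, `rows` (data.frame `variant_id`, `beta_exp`, `se_exp`,
#'   `beta_out`, `se_out`, `eaf_exp`, `eaf_out`) and `dropped`
#'   (data.frame `variant_id`, `reason`).
#' @export
harmonize <- function(exposure, outcome,
                      palindrome_policy = c("infer_by_eaf", "drop_all"),
                      palindrome_threshold = 0.08) {
  stopifnot(inherits(exposure, "sumstats_table"),
            inherits(outcome, "sumstats_table"))
  palindrome_policy <- match.arg(palindrome_policy)

  ex <- exposure$records
  ou <- outcome$records
  shared <- intersect(ex$variant_id, ou$variant_id)
  if (length(shared) == 0L) {
    stop(no_shared_instruments_error(exposure$trait_id, outcome$trait_id))
  }
  ex <- ex[match(shared, ex$variant_id), ]
  ou <- ou[match(shared, ou$variant_id), ]

  e1 <- ex$effect_allele; e2 <- ex$other_allele
  o1 <- ou$effect_allele; o2 <- ou$other_allele
  pal <- is_palindromic(e1, e2)

  # Orientation of outcome alleles relative to exposure. For palindromic
  # variants "match" and "complement swap" are indistinguishable from alleles
  # alone, so orientation is provisional until checked against eaf.
  same     <- o1 == e1 & o2 == e2
  swapped  <- o1 == e2 & o2 == e1
  csame    <- DNA_COMPLEMENT[o1] == e1 & DNA_COMPLEMENT[o2] == e2
  cswapped <- DNA_COMPLEMENT[o1] == e2 & DNA_COMPLEMENT[o2] == e1

  flip <- rep(NA, length(shared))        # NA => irreconcilable
  flip[same | csame] <- FALSE
  flip[swapped | cswapped] <- TRUE
  flip[same & pal] <- FALSE              # provisional; resolved below

  reason <- rep(NA_character_, length(shared))
  reason[is.na(flip)] <- "allele mismatch"

  if (palindrome_policy == "drop_all") {
    reason[pal & is.na(reason)] <- "palindromic"
  } else {
    ambiguous <- pal & (is.na(ex$eaf) | is.na(ou$eaf) |
                          abs(ex$eaf - 0.5) < palindrome_threshold |
                          abs(ou$eaf - 0.5) < palindrome_threshold)
    reason[ambiguous & is.na(reason)] <- "ambiguous palindrome"
    # Resolvable palindrome: trust eaf concordance over nominal allele match.
    resolvable <- pal & is.na(reason)
    if (any(resolvable)) {
      eaf_out_nominal <- ifelse(flip[resolvable], 1 - ou$eaf[resolvable],
                                ou$eaf[resolvable])
      discordant <- (ex$eaf[resolvable] < 0.5) != (eaf_out_nominal < 0.5)
      flip[resolvable][discordant] <- !flip[resolvable][discordant]
    }
  }

  keep <- is.na(reason)
  rows <- data.frame(
    variant_id = shared[keep],
    beta_exp = ex$beta[keep],
    se_exp = ex$se[keep],
    beta_out = ifelse(flip[keep], -ou$beta[keep], ou$beta[keep]),
    se_out = ou$se[keep],
    eaf_exp = ex$eaf[keep],
    eaf_out = ifelse(flip[keep], 1 - ou$eaf[keep], ou$eaf[keep]),
    stringsAsFactors = FALSE
  )
  rownames(rows) <- NULL
  out <- list(exposure_id = exposure$trait_id,
              outcome_id = outcome$trait_id,
              rows = rows,
              dropped = data.frame(variant_id = shared[!keep],
                                   reason = reason[!keep],
                                   stringsAsFactors = FALSE))
  class(out) <- "harmonized_set"
  out
}

#' @export
print.harmonized_set <- function(x, ...) {
  cat(sprintf("<harmonized_set> %s -> %s: %d instruments, %d dropped\n",
              x$exposure_id, x$outcome_id, nrow(x$rows), nrow(x$dropped)))
  invisible(x)
}

#' Build a harmonized set directly from aligned effect vectors
#'
#' Convenience constructor for simulation studies and tests where allele
#' alignment has already been done (or is not modeled).
#'
#' @param beta_exp,se_exp,beta_out,se_out numeric vectors of equal length.
#' @param variant_id optional variant identifiers.
#' @param eaf_exp,eaf_out optional effect-allele frequencies.
#' @param exposure_id,outcome_id trait identifiers.
#' @return a `harmonized_set`.
#' @export
harmonized_set <- function(beta_exp, se_exp, beta_out, se_out,
                           variant_id = paste0("snp", seq_along(beta_exp)),
                           eaf_exp = NA_real_, eaf_out = NA_real_,
                           exposure_id = "exposure", outcome_id = "outcome") {
  stopifnot(length(beta_exp) == length(se_exp),
            length(beta_exp) == length(beta_out),
            length(beta_exp) == length(se_out),
            all(se_exp > 0), all(se_out > 0))
  out <- list(exposure_id = exposure_id, outcome_id = outcome_id,
              rows = data.frame(variant_id = as.character(variant_id),
                                beta_exp = beta_exp, se_exp = se_exp,
                                beta_out = beta_out, se_out = se_out,
                                eaf_exp = eaf_exp, eaf_out = eaf_out,
                                stringsAsFactors = FALSE),
              dropped = data.frame(variant_id = character(),
                                   reason = character(),
                                   stringsAsFactors = FALSE))
  class(out) <- "harmonized_set"
  out
}

no_shared_instruments_error <- function(exposure_id, outcome_id) {
  structure(class = c("mrpath_no_shared_instruments", "error", "condition"),
            list(message = sprintf("no shared instruments between '%s' and '%s'",
                                   exposure_id, outcome_id),
                 call = NULL))
}
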