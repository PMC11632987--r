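# Instrument selection: p-value filter, greedy LD clumping, F-statistic filter.

#' Pairwise linkage-disequilibrium table
#'
#' Symmetric lookup of r-squared between variant pairs. Pairs absent from the
#' table are treated as independent (r2 = 0), the conventional model for
#' post-clumping GWAS instruments; `ld_r2(ld, a, a)` is 1 by convention.
#'
#' @param pairs data.frame with columns `variant_a`, `variant_b`, `r2`
#'   (values in \[0, 1\]). May have zero rows.
#' @return object of class `ld_pair_table`.
#' @export
ld_pair_table <- function(pairs = data.frame(variant_a = character(),
                                             variant_b = character(),
                                             r2 = numeric())) {
  stopifnot(is.data.frame(pairs),
            all(c("variant_a", "variant_b", "r2") %in% names(pairs)))
  pairs$variant_a <- as.character(pairs$variant_a)
  pairs$variant_b <- as.character(pairs$variant_b)
  pairs$r2 <- as.numeric(pairs$r2)
  if (any(is.na(pairs$r2)) || any(pairs$r2 < 0 | pairs$r2 > 1)) {
    stop("r2 must lie in [0, 1]", call. = FALSE)
  }
  env <- new.env(parent = emptyenv(), size = max(16L, 2L * nrow(pairs)))
  key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")
  if (nrow(pairs) > 0L) {
    k <- key(pairs$variant_a, pairs$variant_b)
    for (i in seq_along(k)) assign(k[i], pairs$r2[i], envir = env)
  }
  structure(list(pairs = pairs, env = env, key = key),
            class = "ld_pair_table")
}

#' Look up r-squared between two variants
#' @param ld an [ld_pair_table].
#' @param a,b variant identifiers (vectorized).
#' @return numeric vector of r2 values; 0 for pairs not in the table, 1 when
#'   `a == b`.
#' @export
ld_r2 <- function(ld, a, b) {
  stopifnot(inherits(ld, "ld_pair_table"))
  k <- ld$key(as.character(a), as.character(b))
  out <- vapply(k, function(kk) {
    v <- get0(kk, envir = ld$env, ifnotfound = NA_real_)
    if (is.na(v)) 0 else v
  }, numeric(1), USE.NAMES = FALSE)
  out[as.character(a) == as.character(b)] <- 1
  out
}

#' Read an LD pair table from TSV (`variant_a variant_b r2`)
#' @param path path to a tab-separated file with a header row.
#' @return an [ld_pair_table].
#' @export
read_ld_pairs <- function(path) {
  ld_pair_table(utils::read.table(path, header = TRUE, sep = "\t",
                                  stringsAsFactors = FALSE))
}

#' Instrument-selection configuration
#'
#' Defaults follow common two-sample MR practice for molecular-trait
#' exposures: genome-wide suggestive threshold p < 1e-5, clumping at
#' r2 < 0.001 within 10,000 kb, and per-SNP F >= 10 to guard against weak
#' instruments.
#'
#' @param pval_threshold association p-value cutoff (strict `<`).
#' @param clump_r2 r-squared above which a variant is clumped away.
#' @param clump_window_kb clumping window in kilobases.
#' @param min_f minimum per-SNP F-statistic (variants with F < `min_f` drop).
#' @param f_literal if `TRUE`, use the non-standard statistic `beta / se^2`
#'   instead of the conventional `(beta / se)^2` (see [f_statistic]).
#' @return object of class `instrument_config`.
#' @export
instrument_config <- function(pval_threshold = 1e-5, clump_r2 = 0.001,
                              clump_window_kb = 10000, min_f = 10,
                              f_literal = FALSE) {
  stopifnot(pval_threshold > 0, pval_threshold <= 1,
            clump_r2 > 0, clump_r2 < 1,
            clump_window_kb > 0, min_f >= 0)
  structure(list(pval_threshold = pval_threshold, clump_r2 = clump_r2,
                 clump_window_kb = clump_window_kb, min_f = min_f,
                 f_literal = isTRUE(f_literal)),
            class = "instrument_config")
}

#' Filter variants by association p-value
#' @param table a [sumstats_table].
#' @param threshold keep records with `pval < threshold` (strict).
#' @return filtered [sumstats_table]; row order preserved.
#' @export
filter_by_pvalue <- function(table, threshold = 1e-5) {
  stopifnot(inherits(table, "sumstats_table"), threshold > 0, threshold <= 1)
  table$records <- table$records[table$records$pval < threshold, , drop = FALSE]
  rownames(table$records) <- NULL
  table
}

#' Per-SNP instrument-strength F-statistic
#'
#' The single-SNP approximation `F = (beta / se)^2`, the square of the
#' association z-score. The scale-dependent variant `beta / se^2` is
#' available behind `literal = TRUE` for auditing analyses that used it,
#' but is not recommended.
#'
#' @param beta,se effect estimate and its standard error (`se > 0`).
#' @param literal use `beta / se^2` instead of `(beta / se)^2`.
#' @return numeric vector of F values (nonnegative unless `literal`).
#' @export
f_statistic <- function(beta, se, literal = FALSE) {
  stopifnot(all(se > 0))
  if (isTRUE(literal)) beta / se^2 else (beta / se)^2
}

#' Filter variants by instrument strength
#' @param table a [sumstats_table].
#' @param min_f keep records with `f_statistic >= min_f` (variants with
#'   F strictly below the cutoff are excluded).
#' @param literal passed to [f_statistic].
#' @return filtered [sumstats_table].
#' @export
filter_by_f <- function(table, min_f = 10, literal = FALSE) {
  stopifnot(inherits(table, "sumstats_table"), min_f >= 0)
  f <- f_statistic(table$records$beta, table$records$se, literal = literal)
  table$records <- table$records[f >= min_f, , drop = FALSE]
  rownames(table$records) <- NULL
  table
}

#' Greedy LD clumping
#'
#' Keeps approximately independent index SNPs: candidates are ranked by
#' ascending p-value (ties broken by `variant_id`, so results do not depend
#' on input row order); the best remaining candidate is retained and every
#' other candidate on the same chromosome within `window_kb` of it with
#' `r2 >= r2_thresh` is removed; repeat until exhausted. Pairs missing from
#' `ld` count as independent.
#'
#' @param table a [sumstats_table]; records need `chrom` and `pos`.
#' @param ld an [ld_pair_table].
#' @param r2_thresh r-squared threshold (default 0.001).
#' @param window_kb window in kilobases (default 10,000).
#' @return clumped [sumstats_table], rows in the original table order.
#' @export
ld_clump <- function(table, ld = ld_pair_table(), r2_thresh = 0.001,
                     window_kb = 10000) {
  stopifnot(inherits(table, "sumstats_table"), inherits(ld, "ld_pair_table"))
  rec <- table$records
  if (nrow(rec) <= 1L) return(table)
  ord <- order(rec$pval, rec$variant_id)
  alive <- rep(TRUE, nrow(rec))
  retained <- logical(nrow(rec))
  for (i in ord) {
    if (!alive[i]) next
    retained[i] <- TRUE
    alive[i] <- FALSE
    cand <- which(alive & rec$chrom == rec$chrom[i] &
                    abs(rec$pos - rec$pos[i]) <= window_kb * 1000)
    if (length(cand) > 0L) {
      r2 <- ld_r2(ld, rec$variant_id[cand], rep(rec$variant_id[i], length(cand)))
      alive[cand[r2 >= r2_thresh]] <- FALSE
    }
  }
  table$records <- rec[retained, , drop = FALSE]
  rownames(table$records) <- NULL
  table
}

#' Select genetic instruments for one exposure
#'
#' Applies, in order: the p-value filter, greedy LD clumping, and the
#' F-statistic filter. The selection log (counts surviving each stage) is
#' attached as attribute `"selection_log"`.
#'
#' @param table a [sumstats_table] for the exposure.
#' @param ld an [ld_pair_table] (empty table = all variants independent).
#' @param cfg an [instrument_config].
#' @return filtered [sumstats_table] with attribute `selection_log`, a
#'   data.frame of `stage` and `n_retained`.
#' @export
select_instruments <- function(table, ld = ld_pair_table(),
                               cfg = instrument_config()) {
  stopifnot(inherits(table, "sumstats_table"), inherits(cfg, "instrument_config"))
  stages <- c("input", "pvalue", "clump", "fstat")
  counts <- integer(4)
  counts[1] <- nrow(table$records)
  out <- filter_by_pvalue(table, cfg$pval_threshold)
  counts[2] <- nrow(out$records)
  if (counts[2] == 0L) stop(no_instruments_error(table$trait_id, "pvalue"))
  out <- ld_clump(out, ld, cfg$clump_r2, cfg$clump_window_kb)
  counts[3] <- nrow(out$records)
  if (counts[3] == 0L) stop(no_instruments_error(table$trait_id, "clump"))
  out <- filter_by_f(out, cfg$min_f, literal = cfg$f_literal)
  counts[4] <- nrow(out$records)
  if (counts[4] == 0L) stop(no_instruments_error(table$trait_id, "fstat"))
  attr(out, "selection_log") <- data.frame(stage = stages, n_retained = counts,
                                           stringsAsFactors = FALSE)
  out
}

no_instruments_error <- function(trait_id, stage) {
  structure(class = c("mrpath_no_instruments", "error", "condition"),
            list(message = sprintf(
              "no instruments for trait '%s': zero survivors at stage '%s'",
              trait_id, stage),
              call = NULL, trait_id = trait_id, stage = stage))
}
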