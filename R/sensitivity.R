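# Heterogeneity, pleiotropy and influence diagnostics.

#' Cochran's Q heterogeneity statistic
#'
#' Weighted sum of squared deviations of per-SNP outcome effects from the
#' fitted values of the named regression (IVW through the origin, or
#' MR-Egger with intercept), weights `1/se_out^2`. Referred to a chi-square
#' distribution with `nsnp - 1` (IVW) or `nsnp - 2` (Egger) degrees of
#' freedom; large Q indicates instrument heterogeneity, a symptom of
#' pleiotropy or of multiple causal pathways.
#'
#' @param set a `harmonized_set`.
#' @param method `"ivw"` (default) or `"egger"`.
#' @return list with `Q`, `df`, `pval`.
#' @export
cochran_q <- function(set, method = c("ivw", "egger")) {
  method <- match.arg(method)
  rows <- hset_rows(set)
  k <- nrow(rows)
  w <- 1 / rows$se_out^2
  if (method == "ivw") {
    if (k < 2L) stop(insufficient_instruments_error("Cochran's Q (IVW)", k, 2L))
    b <- mr_ivw(set, model = "fixed")$b
    fitted <- b * rows$beta_exp
    df <- k - 1L
  } else {
    if (k < 3L) stop(insufficient_instruments_error("Cochran's Q (Egger)", k, 3L))
    rows_o <- orient_positive(rows)
    eg <- mr_egger(set)
    fitted_o <- eg$intercept$estimate + eg$slope$b * rows_o$beta_exp
    # Q is computed on the oriented rows (fit was done there too).
    q <- sum(w * (rows_o$beta_out - fitted_o)^2)
    df <- k - 2L
    return(list(Q = q, df = df, pval = stats::pchisq(q, df, lower.tail = FALSE)))
  }
  q <- sum(w * (rows$beta_out - fitted)^2)
  list(Q = q, df = df, pval = stats::pchisq(q, df, lower.tail = FALSE))
}

#' MR-Egger intercept test for directional pleiotropy
#'
#' The intercept term of the MR-Egger regression with its scaled standard
#' error and two-sided p-value. An intercept away from zero means the
#' average pleiotropic effect of the instruments is directional.
#'
#' @param set a `harmonized_set` with at least 3 instruments.
#' @param t_dist passed to [mr_egger].
#' @return list with `estimate`, `se`, `pval`.
#' @export
egger_intercept_test <- function(set, t_dist = FALSE) {
  mr_egger(set, t_dist = t_dist)$intercept
}

# Leave-one-out fixed-effect IVW estimates for all SNPs at once, from running
# sums (used by MR-PRESSO on observed and simulated data). Inputs are
# matrices (replicates x SNPs) or vectors.
ivw_loo_estimates <- function(beta_exp, beta_out, w) {
  if (is.matrix(beta_exp)) {
    wbe2 <- sweep(beta_exp^2, 2, w, `*`)
    wbeo <- sweep(beta_exp * beta_out, 2, w, `*`)
    (rowSums(wbeo) - wbeo) / (rowSums(wbe2) - wbe2)
  } else {
    wbe2 <- w * beta_exp^2
    wbeo <- w * beta_exp * beta_out
    (sum(wbeo) - wbeo) / (sum(wbe2) - wbe2)
  }
}

#' MR-PRESSO: global heterogeneity, outlier and distortion tests
#'
#' Simulation-based pleiotropy diagnostic. The observed residual sum of
#' squares is `sum_j w_j (beta_out_j - b_(-j) * beta_exp_j)^2`, where
#' `b_(-j)` is the fixed-effect IVW estimate excluding SNP j and
#' `w_j = 1/se_out_j^2`. Its null distribution is built from `n_sim`
#' parametric simulations (`beta_exp* ~ N(beta_exp, se_exp)`,
#' `beta_out* ~ N(b_(-j) beta_exp, se_out)`), each analysed identically.
#' The global p-value uses the add-one estimator `(1 + #{RSS* >= RSS_obs}) /
#' (n_sim + 1)`, so it is never exactly zero. Per-SNP outlier p-values
#' compare each observed weighted squared residual with its simulated
#' distribution, Bonferroni-adjusted by the number of SNPs; SNPs with
#' adjusted p below `outlier_alpha` are flagged. When outliers exist, the
#' distortion test compares the shift in the IVW estimate after removing
#' them with the shifts from removing `n_subsets` random subsets of the
#' same size, and an outlier-corrected IVW estimate is reported.
#'
#' @param set a `harmonized_set` with at least 4 instruments.
#' @param n_sim parametric simulations for the null (default 5000, >= 1000).
#' @param seed integer seed (mandatory).
#' @param outlier_alpha significance level for Bonferroni-adjusted per-SNP
#'   outlier calls (default 0.05).
#' @param n_subsets random subsets for the distortion null (default 1000).
#' @param ivw_model model for the reported corrected estimate.
#' @return list with `global_rss`, `global_p`, `outlier_ids`, `outlier_pvals`
#'   (Bonferroni-adjusted, named by variant), `distortion_p` and
#'   `corrected_estimate` (both `NULL` when no outlier is flagged).
#' @export
mr_presso <- function(set, n_sim = 5000, seed = 1L, outlier_alpha = 0.05,
                      n_subsets = 1000,
                      ivw_model = c("multiplicative_random", "fixed")) {
  ivw_model <- match.arg(ivw_model)
  rows <- hset_rows(set)
  k <- nrow(rows)
  if (k < 4L) stop(insufficient_instruments_error("MR-PRESSO", k, 4L))
  stopifnot(n_sim >= 1000)
  w <- 1 / rows$se_out^2

  b_loo <- ivw_loo_estimates(rows$beta_exp, rows$beta_out, w)
  res_obs <- rows$beta_out - b_loo * rows$beta_exp
  rss_j_obs <- w * res_obs^2
  rss_obs <- sum(rss_j_obs)

  sim <- local_seed(derive_seed(seed, 1L), {
    be <- matrix(stats::rnorm(n_sim * k, mean = rep(rows$beta_exp, each = n_sim),
                              sd = rep(rows$se_exp, each = n_sim)),
                 nrow = n_sim)
    bo <- matrix(stats::rnorm(n_sim * k, mean = rep(b_loo * rows$beta_exp, each = n_sim),
                              sd = rep(rows$se_out, each = n_sim)),
                 nrow = n_sim)
    b_loo_sim <- ivw_loo_estimates(be, bo, w)
    res_sim <- bo - b_loo_sim * be
    sweep(res_sim^2, 2, w, `*`)   # n_sim x k matrix of weighted sq residuals
  })
  rss_sim <- rowSums(sim)
  global_p <- (1 + sum(rss_sim >= rss_obs)) / (n_sim + 1)

  p_snp <- vapply(seq_len(k), function(j) {
    (1 + sum(sim[, j] >= rss_j_obs[j])) / (n_sim + 1)
  }, numeric(1))
  p_adj <- pmin(1, p_snp * k)
  names(p_adj) <- rows$variant_id
  outliers <- rows$variant_id[p_adj < outlier_alpha]

  distortion_p <- NULL
  corrected <- NULL
  if (length(outliers) > 0L && length(outliers) < k - 1L) {
    full <- mr_ivw(set, model = "fixed")$b
    keep <- !(rows$variant_id %in% outliers)
    sub <- set
    sub$rows <- rows[keep, , drop = FALSE]
    d_obs <- mr_ivw(sub, model = "fixed")$b - full
    n_out <- length(outliers)
    d_null <- local_seed(derive_seed(seed, 2L), {
      vapply(seq_len(n_subsets), function(i) {
        drop <- sample.int(k, n_out)
        s <- set
        s$rows <- rows[-drop, , drop = FALSE]
        mr_ivw(s, model = "fixed")$b - full
      }, numeric(1))
    })
    distortion_p <- (1 + sum(abs(d_null) >= abs(d_obs))) / (n_subsets + 1)
    corrected <- mr_ivw(sub, model = ivw_model)
  }

  list(global_rss = rss_obs, global_p = global_p,
       outlier_ids = outliers, outlier_pvals = p_adj,
       distortion_p = distortion_p, corrected_estimate = corrected)
}

#' Leave-one-out IVW analysis
#'
#' Recomputes the IVW estimate with each instrument removed in turn, to
#' expose single variants that drive the causal estimate. A SNP is flagged
#' when its removal flips the estimate's sign or moves the p-value across
#' `sig_threshold`.
#'
#' @param set a `harmonized_set` with at least 3 instruments.
#' @param ivw_model passed to [mr_ivw].
#' @param sig_threshold significance threshold for the crossing flag
#'   (default 0.05).
#' @return data.frame with one row per SNP: `variant_id`, `beta_without`,
#'   `se_without`, `p_without`, `influential`; the full-set estimate is
#'   attached as attribute `"full_estimate"`.
#' @export
leave_one_out <- function(set, ivw_model = c("multiplicative_random", "fixed"),
                          sig_threshold = 0.05) {
  ivw_model <- match.arg(ivw_model)
  rows <- hset_rows(set)
  k <- nrow(rows)
  if (k < 3L) stop(insufficient_instruments_error("leave-one-out", k, 3L))
  full <- mr_ivw(set, model = ivw_model)
  est <- lapply(seq_len(k), function(j) {
    s <- set
    s$rows <- rows[-j, , drop = FALSE]
    mr_ivw(s, model = ivw_model)
  })
  out <- data.frame(
    variant_id = rows$variant_id,
    beta_without = vapply(est, `[[`, numeric(1), "b"),
    se_without = vapply(est, `[[`, numeric(1), "se"),
    p_without = vapply(est, `[[`, numeric(1), "pval"),
    stringsAsFactors = FALSE
  )
  out$influential <- sign(out$beta_without) != sign(full$b) |
    ((out$p_without < sig_threshold) != (full$pval < sig_threshold))
  attr(out, "full_estimate") <- full
  out
}

#' Full sensitivity report for one instrument set
#'
#' Bundles Cochran's Q (IVW and Egger), the Egger intercept test, MR-PRESSO
#' and the leave-one-out table. Components whose instrument-count
#' precondition fails are `NULL` with the reason recorded in `skipped`.
#'
#' @param set a `harmonized_set`.
#' @param n_sim,seed,outlier_alpha passed to [mr_presso].
#' @param sig_threshold passed to [leave_one_out].
#' @return object of class `sensitivity_report`: list with `q_ivw`,
#'   `q_egger`, `egger_intercept`, `presso`, `loo`, `skipped`.
#' @export
sensitivity_report <- function(set, n_sim = 5000, seed = 1L,
                               outlier_alpha = 0.05, sig_threshold = 0.05) {
  k <- nrow(hset_rows(set))
  skipped <- character()
  try_or_skip <- function(label, need, expr) {
    if (k < need) {
      skipped[[length(skipped) + 1L]] <<- sprintf("%s: needs >= %d instruments, got %d",
                                                  label, need, k)
      NULL
    } else expr
  }
  out <- list(
    q_ivw = try_or_skip("q_ivw", 2L, cochran_q(set, "ivw")),
    q_egger = try_or_skip("q_egger", 3L, cochran_q(set, "egger")),
    egger_intercept = try_or_skip("egger_intercept", 3L, egger_intercept_test(set)),
    presso = try_or_skip("presso", 4L,
                         mr_presso(set, n_sim = n_sim, seed = seed,
                                   outlier_alpha = outlier_alpha)),
    loo = try_or_skip("loo", 3L, leave_one_out(set, sig_threshold = sig_threshold)),
    skipped = unlist(skipped) %||% character()
  )
  class(out) <- "sensitivity_report"
  out
}

#' @export
print.sensitivity_report <- function(x, ...) {
  cat("<sensitivity_report>\n")
  if (!is.null(x$q_ivw))
    cat(sprintf("  Q (IVW):   %.3f on %d df, p = %.3g\n",
                x$q_ivw$Q, x$q_ivw$df, x$q_ivw$pval))
  if (!is.null(x$q_egger))
    cat(sprintf("  Q (Egger): %.3f on %d df, p = %.3g\n",
                x$q_egger$Q, x$q_egger$df, x$q_egger$pval))
  if (!is.null(x$egger_intercept))
    cat(sprintf("  Egger intercept: %.4f (se %.4f), p = %.3g\n",
                x$egger_intercept$estimate, x$egger_intercept$se,
                x$egger_intercept$pval))
  if (!is.null(x$presso))
    cat(sprintf("  MR-PRESSO global p = %.3g; %d outlier(s)\n",
                x$presso$global_p, length(x$presso$outlier_ids)))
  if (length(x$skipped)) cat("  skipped:", paste(x$skipped, collapse = "; "), "\n")
  invisible(x)
}
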