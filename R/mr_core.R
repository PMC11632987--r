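# Causal estimators for a harmonized instrument set: Wald ratio, IVW,
# MR-Egger, weighted median, and mode-based (simple/weighted) methods.
#
# All estimates live on the log-odds (beta) scale for binary outcomes and are
# exponentiated into odds ratios for reporting; 95% intervals are normal-based
# (b +/- 1.96 se), matching how two-sample MR results are conventionally
# tabulated.

mr_estimate <- function(method, nsnp, b, se, pval = NULL) {
  if (is.null(pval)) pval <- 2 * stats::pnorm(-abs(b / se))
  z <- stats::qnorm(0.975)
  data.frame(method = method, nsnp = as.integer(nsnp), b = b, se = se,
             ci_low = b - z * se, ci_high = b + z * se,
             or = exp(b), or_lci95 = exp(b - z * se), or_uci95 = exp(b + z * se),
             pval = pval, stringsAsFactors = FALSE)
}

insufficient_instruments_error <- function(method, nsnp, need, hint = NULL) {
  msg <- sprintf("%s requires at least %d instruments (got %d)", method, need, nsnp)
  if (!is.null(hint)) msg <- paste0(msg, "; ", hint)
  structure(class = c("mrpath_insufficient_instruments", "error", "condition"),
            list(message = msg, call = NULL, method = method, nsnp = nsnp))
}

hset_rows <- function(set) {
  stopifnot(inherits(set, "harmonized_set"))
  set$rows
}

#' Wald ratio estimate from a single instrument
#'
#' The base-case causal estimate: `beta_out / beta_exp`, with the first-order
#' delta-method standard error `se_out / |beta_exp|` (uncertainty in the
#' SNP-exposure association is ignored, as is conventional for strong
#' instruments).
#'
#' @param beta_exp,se_exp SNP-exposure association and its standard error.
#' @param beta_out,se_out SNP-outcome association and its standard error.
#' @return one-row data.frame (`method`, `nsnp`, `b`, `se`, `ci_low`,
#'   `ci_high`, `or`, `or_lci95`, `or_uci95`, `pval`).
#' @export
mr_wald_ratio <- function(beta_exp, se_exp, beta_out, se_out) {
  stopifnot(length(beta_exp) == 1L, se_out > 0)
  if (beta_exp == 0) {
    stop("Wald ratio undefined: beta_exp is zero", call. = FALSE)
  }
  mr_estimate("wald_ratio", 1L, beta_out / beta_exp, se_out / abs(beta_exp))
}

# Per-SNP Wald ratios and their delta-method variances (second-order,
# propagating both se_out and se_exp), used by median- and mode-based methods.
wald_ratios <- function(rows) {
  ratio <- rows$beta_out / rows$beta_exp
  var <- rows$se_out^2 / rows$beta_exp^2 +
    rows$beta_out^2 * rows$se_exp^2 / rows$beta_exp^4
  list(ratio = ratio, var = var)
}

#' Inverse-variance-weighted (IVW) estimate
#'
#' Weighted regression of outcome betas on exposure betas through the origin
#' with weights `1/se_out^2`; equivalently the inverse-variance-weighted
#' average of per-SNP Wald ratios. Under `"fixed"` the standard error is
#' `sqrt(1 / sum(w * beta_exp^2))`; under `"multiplicative_random"` (the
#' default, matching common MR software) it is inflated by
#' `sqrt(max(1, Q / (k - 1)))` where Q is Cochran's heterogeneity statistic,
#' so heterogeneous instruments widen the interval but can never shrink it
#' below the fixed-effect width.
#'
#' @param set a `harmonized_set` with at least 2 instruments.
#' @param model `"multiplicative_random"` (default) or `"fixed"`.
#' @return one-row data.frame as in [mr_wald_ratio], `method` set to
#'   `"ivw_mre"` or `"ivw_fe"`.
#' @export
mr_ivw <- function(set, model = c("multiplicative_random", "fixed")) {
  model <- match.arg(model)
  rows <- hset_rows(set)
  k <- nrow(rows)
  if (k < 2L) {
    stop(insufficient_instruments_error(
      "IVW", k, 2L, hint = "use mr_wald_ratio for a single instrument"))
  }
  w <- 1 / rows$se_out^2
  sxx <- sum(w * rows$beta_exp^2)
  b <- sum(w * rows$beta_exp * rows$beta_out) / sxx
  se <- sqrt(1 / sxx)
  method <- "ivw_fe"
  if (model == "multiplicative_random") {
    q <- sum(w * (rows$beta_out - b * rows$beta_exp)^2)
    se <- se * sqrt(max(1, q / (k - 1)))
    method <- "ivw_mre"
  }
  mr_estimate(method, k, b, se)
}

# Orient instruments so all beta_exp >= 0 (joint sign flip per row); Egger's
# intercept is only interpretable under a consistent exposure orientation.
orient_positive <- function(rows) {
  neg <- rows$beta_exp < 0
  rows$beta_exp[neg] <- -rows$beta_exp[neg]
  rows$beta_out[neg] <- -rows$beta_out[neg]
  rows
}

#' MR-Egger regression
#'
#' Weighted linear regression of outcome betas on exposure betas *with* an
#' intercept (weights `1/se_out^2`), after orienting all instruments to
#' positive exposure effects. The slope is a pleiotropy-adjusted causal
#' estimate; a nonzero intercept indicates directional pleiotropy. Both
#' standard errors are scaled by `sqrt(max(1, RSS_w / (k - 2)))`, the usual
#' underdispersion guard.
#'
#' @param set a `harmonized_set` with at least 3 instruments.
#' @param t_dist if `TRUE`, p-values use the t distribution with `k - 2`
#'   degrees of freedom instead of the normal.
#' @return list with `slope` (one-row estimate data.frame, method
#'   `"egger"`) and `intercept` (list: `estimate`, `se`, `pval`).
#' @export
mr_egger <- function(set, t_dist = FALSE) {
  rows <- hset_rows(set)
  k <- nrow(rows)
  if (k < 3L) stop(insufficient_instruments_error("MR-Egger", k, 3L))
  rows <- orient_positive(rows)
  w <- 1 / rows$se_out^2
  fit <- stats::lm.wfit(x = cbind(intercept = 1, slope = rows$beta_exp),
                        y = rows$beta_out, w = w)
  coefs <- fit$coefficients
  rss_w <- sum(w * fit$residuals^2)
  phi <- max(1, rss_w / (k - 2))
  xtx_inv <- chol2inv(chol(crossprod(cbind(1, rows$beta_exp) * sqrt(w))))
  ses <- sqrt(phi * diag(xtx_inv))
  pfun <- if (t_dist) {
    function(z) 2 * stats::pt(-abs(z), df = k - 2)
  } else {
    function(z) 2 * stats::pnorm(-abs(z))
  }
  slope <- mr_estimate("egger", k, coefs[["slope"]], ses[2],
                       pval = pfun(coefs[["slope"]] / ses[2]))
  intercept <- list(estimate = coefs[["intercept"]], se = ses[1],
                    pval = pfun(coefs[["intercept"]] / ses[1]))
  list(slope = slope, intercept = intercept)
}

# Weighted median of `x` with weights `w`: sort x, form standardized
# cumulative weights (cumsum(w) - w/2) / sum(w), and interpolate x linearly
# where they cross 0.5.
weighted_median_value <- function(x, w) {
  ord <- order(x)
  x <- x[ord]; w <- w[ord]
  cw <- (cumsum(w) - 0.5 * w) / sum(w)
  idx <- which(cw < 0.5)
  if (length(idx) == 0L) return(x[1])
  below <- max(idx)
  if (below == length(x)) return(x[length(x)])
  x[below] + (x[below + 1] - x[below]) * (0.5 - cw[below]) / (cw[below + 1] - cw[below])
}

# Parametric bootstrap SE for ratio-based estimators: redraw each beta from
# its normal sampling distribution and recompute the estimator.
bootstrap_se <- function(rows, statistic, n_boot, seed) {
  stopifnot(!is.null(seed))
  k <- nrow(rows)
  reps <- local_seed(seed, {
    be <- matrix(stats::rnorm(n_boot * k, rows$beta_exp, rows$se_exp),
                 nrow = n_boot, byrow = TRUE)
    bo <- matrix(stats::rnorm(n_boot * k, rows$beta_out, rows$se_out),
                 nrow = n_boot, byrow = TRUE)
    vapply(seq_len(n_boot), function(i) {
      r <- rows
      r$beta_exp <- be[i, ]; r$beta_out <- bo[i, ]
      statistic(r)
    }, numeric(1))
  })
  stats::sd(reps)
}

#' Weighted median estimate
#'
#' The weighted median of per-SNP Wald ratios, weights proportional to each
#' ratio's inverse variance. Consistent when instruments contributing at
#' least half the weight are valid. The standard error comes from a seeded
#' parametric bootstrap (each beta redrawn from its sampling distribution).
#'
#' @param set a `harmonized_set` with at least 3 instruments.
#' @param n_boot bootstrap replicates (default 1000).
#' @param seed integer seed for the bootstrap (mandatory).
#' @return one-row estimate data.frame, method `"weighted_median"`.
#' @export
mr_weighted_median <- function(set, n_boot = 1000, seed = 1L) {
  rows <- hset_rows(set)
  k <- nrow(rows)
  if (k < 3L) stop(insufficient_instruments_error("weighted median", k, 3L))
  stat <- function(r) {
    wr <- wald_ratios(r)
    weighted_median_value(wr$ratio, 1 / wr$var)
  }
  b <- stat(rows)
  se <- bootstrap_se(rows, stat, n_boot, seed)
  mr_estimate("weighted_median", k, b, se)
}

# Gaussian-kernel density argmax over Wald ratios on a fixed grid.
mode_value <- function(ratio, w, bandwidth_factor, grid_n = 10000L) {
  h <- bandwidth_factor * stats::mad(ratio, constant = 1.4826)
  if (h == 0) return(ratio[1])   # zero spread: all ratios (near-)identical
  grid <- seq(min(ratio) - 3 * h, max(ratio) + 3 * h, length.out = grid_n)
  dens <- vapply(grid, function(x) sum(w * stats::dnorm((x - ratio) / h)),
                 numeric(1))
  grid[which.max(dens)]
}

#' Mode-based estimate (simple or weighted)
#'
#' The argmax of a gaussian kernel density over per-SNP Wald ratios,
#' evaluated on a fixed grid of 10,000 points spanning the ratios plus/minus
#' three bandwidths. Bandwidth is `bandwidth_factor` times the
#' normal-consistent median absolute deviation of the ratios. The simple
#' mode weights every ratio equally; the weighted mode weights each kernel
#' by the ratio's normalized inverse variance. Consistent when the largest
#' group of instruments sharing a causal estimate is valid. Standard error
#' by seeded parametric bootstrap.
#'
#' @param set a `harmonized_set` with at least 3 instruments.
#' @param weighted use inverse-variance kernel weights (default `FALSE`).
#' @param bandwidth_factor multiplier on the robust spread (default 1).
#' @param n_boot bootstrap replicates (default 1000).
#' @param seed integer seed (mandatory).
#' @return one-row estimate data.frame, method `"simple_mode"` or
#'   `"weighted_mode"`.
#' @export
mr_mode <- function(set, weighted = FALSE, bandwidth_factor = 1,
                    n_boot = 1000, seed = 1L) {
  rows <- hset_rows(set)
  k <- nrow(rows)
  if (k < 3L) stop(insufficient_instruments_error("mode-based estimator", k, 3L))
  stat <- function(r) {
    wr <- wald_ratios(r)
    w <- if (weighted) (1 / wr$var) / sum(1 / wr$var) else rep(1 / k, k)
    mode_value(wr$ratio, w, bandwidth_factor)
  }
  b <- stat(rows)
  se <- bootstrap_se(rows, stat, n_boot, seed)
  mr_estimate(if (weighted) "weighted_mode" else "simple_mode", k, b, se)
}

#' Run all applicable MR methods on one instrument set
#'
#' Applies the five standard estimators (IVW as the primary method, MR-Egger,
#' weighted median, simple mode, weighted mode), falling back to the Wald
#' ratio for a single instrument. Methods whose instrument-count
#' precondition fails are skipped with a logged reason.
#'
#' @param set a nonempty `harmonized_set`.
#' @param ivw_model passed to [mr_ivw].
#' @param n_boot,seed bootstrap controls for median/mode methods.
#' @param bandwidth_factor passed to [mr_mode].
#' @return data.frame of estimates (one row per method run) with attributes
#'   `"skipped"` (data.frame `method`, `reason`) and `"primary"` (the primary
#'   method's name).
#' @export
mr_run_all <- function(set, ivw_model = c("multiplicative_random", "fixed"),
                       n_boot = 1000, seed = 1L, bandwidth_factor = 1) {
  ivw_model <- match.arg(ivw_model)
  rows <- hset_rows(set)
  k <- nrow(rows)
  if (k < 1L) stop("empty instrument set", call. = FALSE)
  out <- list()
  skipped <- list()
  skip <- function(method, need) {
    data.frame(method = method,
               reason = sprintf("needs >= %d instruments, got %d", need, k),
               stringsAsFactors = FALSE)
  }
  if (k == 1L) {
    out$wald <- mr_wald_ratio(rows$beta_exp, rows$se_exp,
                              rows$beta_out, rows$se_out)
    skipped <- list(skip("ivw", 2L), skip("egger", 3L),
                    skip("weighted_median", 3L), skip("simple_mode", 3L),
                    skip("weighted_mode", 3L))
    primary <- "wald_ratio"
  } else {
    out$ivw <- mr_ivw(set, model = ivw_model)
    primary <- out$ivw$method
    if (k >= 3L) {
      out$egger <- mr_egger(set)$slope
      out$wm <- mr_weighted_median(set, n_boot = n_boot, seed = seed)
      out$sm <- mr_mode(set, weighted = FALSE,
                        bandwidth_factor = bandwidth_factor,
                        n_boot = n_boot, seed = seed)
      out$wmode <- mr_mode(set, weighted = TRUE,
                           bandwidth_factor = bandwidth_factor,
                           n_boot = n_boot, seed = seed)
    } else {
      skipped <- list(skip("egger", 3L), skip("weighted_median", 3L),
                      skip("simple_mode", 3L), skip("weighted_mode", 3L))
    }
  }
  res <- do.call(rbind, unname(out))
  rownames(res) <- NULL
  attr(res, "skipped") <- if (length(skipped)) do.call(rbind, skipped) else
    data.frame(method = character(), reason = character(),
               stringsAsFactors = FALSE)
  attr(res, "primary") <- primary
  res
}
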