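# Two-step mediation: product-of-coefficients mediated effect, mediated
# proportion, delta-method uncertainty, and the reverse-MR screen.
#
# Effects compose on the log-odds / linear beta scale. When a step is
# published as an odds ratio, take its natural log before composing:
# the mediated effect is beta_a * beta_b, the mediated proportion is
# 100 * mediated / total. The proportion is negative when the mediated and
# total effects pull in opposite directions.

#' Mediated (indirect) effect
#'
#' Product of coefficients: the effect of the exposure on the mediator
#' (`beta_a`, direct effect A) times the effect of the mediator on the
#' outcome (`beta_b`, direct effect B), both on the beta scale.
#'
#' @param beta_a exposure-on-mediator effect (log scale for OR inputs).
#' @param beta_b mediator-on-outcome effect.
#' @return the mediated effect `beta_a * beta_b`.
#' @export
mediated_effect <- function(beta_a, beta_b) beta_a * beta_b

#' Mediated proportion
#'
#' Share of the total exposure-on-outcome effect carried by the mediator:
#' `100 * me / beta_total`, in percent.
#'
#' @param me mediated effect (see [mediated_effect]).
#' @param beta_total total exposure-on-outcome effect; must be nonzero.
#' @return mediated proportion in percent.
#' @export
mediated_proportion <- function(me, beta_total) {
  if (any(beta_total == 0)) {
    stop("mediated proportion undefined: total effect is zero", call. = FALSE)
  }
  100 * me / beta_total
}

#' Delta-method standard error of the mediated effect
#'
#' `delta_full` is the Sobel formula
#' `sqrt(beta_a^2 se_b^2 + beta_b^2 se_a^2)`; `delta_b_only` propagates only
#' the step-A uncertainty, `sqrt(beta_b^2 se_a^2)`.
#'
#' @param beta_a,se_a step-A estimate and standard error.
#' @param beta_b,se_b step-B estimate and standard error.
#' @param method `"delta_full"` (default) or `"delta_b_only"`.
#' @return standard error of `beta_a * beta_b`.
#' @export
mediation_se <- function(beta_a, se_a, beta_b, se_b,
                         method = c("delta_full", "delta_b_only")) {
  method <- match.arg(method)
  stopifnot(all(se_a >= 0), all(se_b >= 0))
  if (method == "delta_full") {
    sqrt(beta_a^2 * se_b^2 + beta_b^2 * se_a^2)
  } else {
    sqrt(beta_b^2 * se_a^2)
  }
}

#' Compose a mediation result from three leg estimates
#'
#' @param beta_total,se_total total-effect (exposure on outcome) estimate.
#' @param beta_a,se_a direct effect A (exposure on mediator).
#' @param beta_b,se_b direct effect B (mediator on outcome).
#' @param exposure_id,mediator_id,outcome_id trait identifiers.
#' @param se_method passed to [mediation_se].
#' @return object of class `mediation_result`: list with the three leg
#'   estimates, `me` (mediated effect), `me_se`, `mp` (mediated proportion,
#'   %), and `pval` (two-sided normal on `me / me_se`).
#' @export
mediation_result <- function(beta_total, se_total, beta_a, se_a, beta_b, se_b,
                             exposure_id = "exposure", mediator_id = "mediator",
                             outcome_id = "outcome",
                             se_method = c("delta_full", "delta_b_only")) {
  se_method <- match.arg(se_method)
  me <- mediated_effect(beta_a, beta_b)
  me_se <- mediation_se(beta_a, se_a, beta_b, se_b, method = se_method)
  out <- list(exposure_id = exposure_id, mediator_id = mediator_id,
              outcome_id = outcome_id,
              beta_total = beta_total, se_total = se_total,
              beta_a = beta_a, se_a = se_a, beta_b = beta_b, se_b = se_b,
              me = me, me_se = me_se,
              mp = mediated_proportion(me, beta_total),
              pval = if (me_se > 0) 2 * stats::pnorm(-abs(me / me_se)) else
                as.numeric(me == 0),
              se_method = se_method)
  class(out) <- "mediation_result"
  out
}

#' @export
print.mediation_result <- function(x, ...) {
  cat(sprintf("<mediation_result> %s -> %s -> %s\n", x$exposure_id,
              x$mediator_id, x$outcome_id))
  cat(sprintf("  total effect:      %8.4f (se %.4f)\n", x$beta_total, x$se_total))
  cat(sprintf("  direct effect A:   %8.4f (se %.4f)\n", x$beta_a, x$se_a))
  cat(sprintf("  direct effect B:   %8.4f (se %.4f)\n", x$beta_b, x$se_b))
  cat(sprintf("  mediated effect:   %8.4f (se %.4f), p = %.3g\n",
              x$me, x$me_se, x$pval))
  cat(sprintf("  mediated proportion: %.2f%%\n", x$mp))
  invisible(x)
}

#' @export
as.data.frame.mediation_result <- function(x, ...) {
  data.frame(exposure = x$exposure_id, mediator = x$mediator_id,
             outcome = x$outcome_id, beta_total = x$beta_total,
             beta_a = x$beta_a, beta_b = x$beta_b, me = x$me, me_se = x$me_se,
             mp = x$mp, pval = x$pval, stringsAsFactors = FALSE)
}

# Run one MR leg: select instruments from the leg's exposure, harmonize
# against the leg's outcome, estimate with the primary method, and attach
# diagnostics. Errors from instrument selection are re-raised naming the leg.
mr_leg <- function(exposure, outcome, ld, cfg, leg,
                   with_sensitivity = TRUE) {
  instruments <- tryCatch(
    select_instruments(exposure, ld, cfg$instrument),
    mrpath_no_instruments = function(e) {
      stop(structure(class = c("mrpath_leg_failure", "error", "condition"),
                     list(message = sprintf("leg '%s': %s", leg, conditionMessage(e)),
                          call = NULL, leg = leg)))
    })
  set <- harmonize(instruments, outcome,
                   palindrome_policy = cfg$palindrome_policy,
                   palindrome_threshold = cfg$palindrome_threshold)
  k <- nrow(set$rows)
  if (k == 0L) {
    stop(structure(class = c("mrpath_leg_failure", "error", "condition"),
                   list(message = sprintf("leg '%s': no instruments survive harmonization", leg),
                        call = NULL, leg = leg)))
  }
  estimate <- if (k == 1L) {
    mr_wald_ratio(set$rows$beta_exp, set$rows$se_exp,
                  set$rows$beta_out, set$rows$se_out)
  } else {
    mr_ivw(set, model = cfg$ivw_model)
  }
  sens <- if (with_sensitivity) {
    sensitivity_report(set, n_sim = cfg$presso_n_sim,
                       seed = derive_seed(cfg$seed, nchar(leg)),
                       outlier_alpha = cfg$outlier_alpha,
                       sig_threshold = cfg$screen_p)
  } else NULL
  list(set = set, estimate = estimate, sensitivity = sens,
       selection_log = attr(instruments, "selection_log"))
}

#' Analysis configuration for MR and mediation runs
#'
#' @param instrument an [instrument_config].
#' @param ivw_model primary IVW variant, `"multiplicative_random"` (default)
#'   or `"fixed"`.
#' @param palindrome_policy,palindrome_threshold passed to [harmonize].
#' @param screen_p significance threshold used by the step-1 screen and
#'   the reverse-MR pass/fail flag (default 0.05).
#' @param mediation_p significance threshold for reporting a mediation
#'   pathway (default 0.05).
#' @param se_method mediated-effect variance method (see [mediation_se]).
#' @param n_boot,presso_n_sim,outlier_alpha stochastic-method controls.
#' @param seed integer seed for every stochastic component (mandatory).
#' @return object of class `mr_config`.
#' @export
mr_config <- function(instrument = instrument_config(),
                      ivw_model = c("multiplicative_random", "fixed"),
                      palindrome_policy = c("infer_by_eaf", "drop_all"),
                      palindrome_threshold = 0.08,
                      screen_p = 0.05, mediation_p = 0.05,
                      se_method = c("delta_full", "delta_b_only"),
                      n_boot = 1000, presso_n_sim = 5000,
                      outlier_alpha = 0.05, seed = 1L) {
  structure(list(instrument = instrument,
                 ivw_model = match.arg(ivw_model),
                 palindrome_policy = match.arg(palindrome_policy),
                 palindrome_threshold = palindrome_threshold,
                 screen_p = screen_p, mediation_p = mediation_p,
                 se_method = match.arg(se_method),
                 n_boot = n_boot, presso_n_sim = presso_n_sim,
                 outlier_alpha = outlier_alpha, seed = seed),
            class = "mr_config")
}

#' Two-step Mendelian-randomization mediation analysis
#'
#' Runs three full MR legs, each with instrument selection from the leg's
#' own exposure: total (exposure on outcome), direct effect A (exposure on
#' mediator, instruments from the exposure), and direct effect B (mediator
#' on outcome, instruments from the mediator). The legs compose into the
#' mediated effect `beta_a * beta_b` and mediated proportion
#' `100 * me / beta_total`. Each leg's estimate is the configured primary
#' method (IVW by default; Wald ratio for a single surviving instrument).
#'
#' @param exposure,mediator,outcome [sumstats_table] objects.
#' @param ld an [ld_pair_table].
#' @param cfg an [mr_config].
#' @param with_sensitivity attach a [sensitivity_report] per leg (default
#'   `TRUE`; disable for speed in simulation sweeps).
#' @return a [mediation_result] with an extra element `legs`: the per-leg
#'   harmonized sets, estimates and diagnostics.
#' @export
two_step_mediation <- function(exposure, mediator, outcome,
                               ld = ld_pair_table(), cfg = mr_config(),
                               with_sensitivity = TRUE) {
  total <- mr_leg(exposure, outcome, ld, cfg, "total", with_sensitivity)
  leg_a <- mr_leg(exposure, mediator, ld, cfg, "direct_a", with_sensitivity)
  leg_b <- mr_leg(mediator, outcome, ld, cfg, "direct_b", with_sensitivity)
  out <- mediation_result(
    beta_total = total$estimate$b, se_total = total$estimate$se,
    beta_a = leg_a$estimate$b, se_a = leg_a$estimate$se,
    beta_b = leg_b$estimate$b, se_b = leg_b$estimate$se,
    exposure_id = exposure$trait_id, mediator_id = mediator$trait_id,
    outcome_id = outcome$trait_id, se_method = cfg$se_method)
  out$legs <- list(total = total, direct_a = leg_a, direct_b = leg_b)
  out
}

#' Reverse-MR screen
#'
#' Swaps roles: instruments are selected from the outcome trait and each
#' candidate trait is analysed as the outcome of an outcome-on-trait MR.
#' Under the forward-causal model none of these should be significant; a
#' significant reverse estimate undermines the forward interpretation for
#' that trait. Traits sharing the outcome's identifier are rejected.
#'
#' @param outcome_as_exposure [sumstats_table] for the original outcome.
#' @param traits list of [sumstats_table] objects to screen.
#' @param ld an [ld_pair_table].
#' @param cfg an [mr_config]; `cfg$screen_p` sets the pass/fail flag.
#' @return data.frame with one row per trait: `exposure`, `outcome`,
#'   `method`, `nsnp`, `b`, `se`, `pval`, `significant`.
#' @export
reverse_mr_screen <- function(outcome_as_exposure, traits,
                              ld = ld_pair_table(), cfg = mr_config()) {
  stopifnot(is.list(traits), length(traits) > 0L)
  res <- lapply(traits, function(trait) {
    if (identical(trait$trait_id, outcome_as_exposure$trait_id)) {
      stop("reverse screen: trait and outcome are the same GWAS ('",
           trait$trait_id, "')", call. = FALSE)
    }
    leg <- mr_leg(outcome_as_exposure, trait, ld, cfg,
                  paste0("reverse:", trait$trait_id), with_sensitivity = FALSE)
    est <- leg$estimate
    data.frame(exposure = outcome_as_exposure$trait_id,
               outcome = trait$trait_id, method = est$method,
               nsnp = est$nsnp, b = est$b, se = est$se, pval = est$pval,
               significant = est$pval < cfg$screen_p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
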