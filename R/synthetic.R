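# Seeded generator of three-trait GWAS summary statistics with a latent
# exposure -> mediator -> outcome causal system.
#
# Per-SNP structural model (linear SEM on standardized traits):
#   x_j = gamma_j + r * delta_j            (exposure)
#   m_j = a * x_j + eta_j                  (mediator)
#   y_j = c * x_j + b * m_j + delta_j + alpha_j   (outcome)
# where gamma_j are exposure-instrument effects, eta_j mediator-specific
# effects, delta_j outcome-specific (disease susceptibility) effects used by
# the reverse-MR screen, r an optional true reverse effect, and alpha_j a
# horizontal-pleiotropy contribution on the outcome only. The implied total
# exposure-on-outcome effect is theta = c + a*b and the true mediated
# proportion a*b / theta.
#
# Observed betas are truth plus normal noise with the standardized-trait
# standard error se = 1 / sqrt(2 * maf * (1 - maf) * n); p-values are normal.

#' Simulation configuration
#'
#' Defaults describe a desk-scale but realistic molecular-trait setting:
#' 50 exposure instruments and 50 mediator-specific instruments with
#' per-SNP effects of sd 0.05 on standardized traits, GWAS sample sizes of
#' 100,000, MAF uniform on \[0.05, 0.5\], effect sizes a = 0.3, b = 0.4,
#' c = 0.2 (total effect 0.32, mediated proportion 37.5%), and no
#' pleiotropy, outliers, LD or reverse causation unless requested.
#'
#' @param seed integer seed (mandatory; every draw is reproducible from it).
#' @param n_snps exposure-instrument count.
#' @param n_mediator_snps mediator-specific instrument count.
#' @param n_outcome_snps outcome-specific (susceptibility) instrument count;
#'   needed by the reverse-MR screen, 0 by default.
#' @param n_exposure,n_mediator,n_outcome GWAS sample sizes. For a binary
#'   outcome pass an effective sample size (e.g. `4 / (1/cases + 1/controls)`).
#' @param maf_range minor-allele-frequency interval within (0, 0.5\].
#' @param gamma_sd sd of true SNP-on-exposure effects.
#' @param eta_sd sd of mediator-specific effects (default `gamma_sd`).
#' @param delta_sd sd of outcome-specific effects (default `gamma_sd`).
#' @param a,b,c exposure-on-mediator, mediator-on-outcome and direct
#'   exposure-on-outcome effects.
#' @param reverse_effect true outcome-on-exposure effect (default 0).
#' @param pleiotropy list with `mode` (`"none"`, `"balanced"` or
#'   `"directional"`), `sd`, `mean` (directional only) and `fraction` of
#'   exposure SNPs affected.
#' @param n_outliers number of exposure SNPs turned into gross outliers.
#' @param outlier_scale outlier pleiotropic effect in units of that SNP's
#'   outcome standard error (default 10).
#' @param ld_blocks optional list of `list(size =, r2 =)` entries; each
#'   groups consecutive exposure SNPs into a physically clustered block with
#'   the given pairwise r-squared, to exercise LD clumping.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_snps = 50L, n_mediator_snps = 50L,
                       n_outcome_snps = 0L,
                       n_exposure = 1e5, n_mediator = 1e5, n_outcome = 1e5,
                       maf_range = c(0.05, 0.5), gamma_sd = 0.05,
                       eta_sd = gamma_sd, delta_sd = gamma_sd,
                       a = 0.3, b = 0.4, c = 0.2, reverse_effect = 0,
                       pleiotropy = list(mode = "none", sd = 0, mean = 0,
                                         fraction = 0),
                       n_outliers = 0L, outlier_scale = 10,
                       ld_blocks = NULL) {
  stopifnot(length(maf_range) == 2L, maf_range[1] > 0, maf_range[2] <= 0.5,
            maf_range[1] <= maf_range[2],
            gamma_sd >= 0, eta_sd >= 0, delta_sd >= 0,
            n_snps >= 1L, n_mediator_snps >= 0L, n_outcome_snps >= 0L,
            n_exposure > 0, n_mediator > 0, n_outcome > 0,
            n_outliers >= 0L, outlier_scale >= 0)
  pleiotropy <- utils::modifyList(list(mode = "none", sd = 0, mean = 0,
                                       fraction = 0), pleiotropy)
  stopifnot(pleiotropy$mode %in% c("none", "balanced", "directional"),
            pleiotropy$sd >= 0,
            pleiotropy$fraction >= 0, pleiotropy$fraction <= 1)
  if (n_outliers > n_snps) {
    stop("infeasible config: n_outliers exceeds n_snps", call. = FALSE)
  }
  structure(list(seed = as.integer(seed), n_snps = as.integer(n_snps),
                 n_mediator_snps = as.integer(n_mediator_snps),
                 n_outcome_snps = as.integer(n_outcome_snps),
                 n_exposure = n_exposure, n_mediator = n_mediator,
                 n_outcome = n_outcome, maf_range = maf_range,
                 gamma_sd = gamma_sd, eta_sd = eta_sd, delta_sd = delta_sd,
                 a = a, b = b, c = c, reverse_effect = reverse_effect,
                 pleiotropy = pleiotropy, n_outliers = as.integer(n_outliers),
                 outlier_scale = outlier_scale, ld_blocks = ld_blocks),
            class = "sim_config")
}

# Non-palindromic allele pairs only, so harmonization of the simulated tables
# (which share one variant panel) is lossless regardless of policy.
ALLELE_PAIRS <- matrix(c("A", "G", "A", "C", "G", "A", "C", "A",
                         "T", "G", "T", "C", "G", "T", "C", "T"),
                       ncol = 2, byrow = TRUE)

#' Simulate a three-trait GWAS summary-statistics system
#'
#' Generates exposure, mediator and outcome tables over one shared variant
#' panel, an LD table (empty unless `ld_blocks` is set) and a truth ledger,
#' all reproducible from `cfg$seed`.
#'
#' @param cfg a [sim_config].
#' @return list with `exposure`, `mediator`, `outcome` ([sumstats_table]s),
#'   `ld` ([ld_pair_table]) and `truth` (list: `snps` data.frame of per-SNP
#'   true effects and flags; `a`, `b`, `c`, `theta_total = c + a*b`,
#'   `mp_true = 100 * a*b / theta_total`).
#' @export
simulate_mediation_system <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  local_seed(cfg$seed, {
    k_exp <- cfg$n_snps; k_med <- cfg$n_mediator_snps; k_out <- cfg$n_outcome_snps
    k <- k_exp + k_med + k_out
    role <- rep(c("exposure", "mediator", "outcome"), c(k_exp, k_med, k_out))
    variant_id <- sprintf("rs%05d", seq_len(k))

    # Physical layout: unlinked SNPs spaced far apart across the autosomes;
    # LD blocks overwrite positions so members sit within a few kb.
    chrom <- as.character(1L + (seq_len(k) - 1L) %% 22L)
    pos <- 1e6 + 2e7 * ((seq_len(k) - 1L) %/% 22L)
    ld_pairs <- data.frame(variant_a = character(), variant_b = character(),
                           r2 = numeric(), stringsAsFactors = FALSE)
    if (!is.null(cfg$ld_blocks)) {
      at <- 1L
      for (blk in cfg$ld_blocks) {
        size <- blk$size; r2 <- blk$r2
        if (at + size - 1L > k_exp) {
          stop("infeasible config: ld_blocks cover more SNPs than n_snps",
               call. = FALSE)
        }
        idx <- at:(at + size - 1L)
        chrom[idx] <- chrom[at]
        pos[idx] <- pos[at] + seq.int(0L, by = 2000L, length.out = size)
        prs <- utils::combn(idx, 2)
        ld_pairs <- rbind(ld_pairs, data.frame(
          variant_a = variant_id[prs[1, ]], variant_b = variant_id[prs[2, ]],
          r2 = r2, stringsAsFactors = FALSE))
        at <- at + size
      }
    }

    pair <- ALLELE_PAIRS[sample.int(nrow(ALLELE_PAIRS), k, replace = TRUE), ,
                         drop = FALSE]
    maf <- stats::runif(k, cfg$maf_range[1], cfg$maf_range[2])

    gamma <- ifelse(role == "exposure", stats::rnorm(k, 0, cfg$gamma_sd), 0)
    eta <- ifelse(role == "mediator", stats::rnorm(k, 0, cfg$eta_sd), 0)
    delta <- ifelse(role == "outcome", stats::rnorm(k, 0, cfg$delta_sd), 0)

    alpha <- numeric(k)
    pl <- cfg$pleiotropy
    if (pl$mode != "none" && pl$fraction > 0 && k_exp > 0) {
      n_pl <- round(pl$fraction * k_exp)
      which_pl <- sample(which(role == "exposure"), n_pl)
      alpha[which_pl] <- stats::rnorm(n_pl, 0, pl$sd)
      if (pl$mode == "directional") {
        # Directional pleiotropy is defined relative to the exposure-increasing
        # allele (the orientation MR-Egger uses): its mean adds along
        # sign(gamma), so a fixed per-allele shift does not cancel out when
        # instruments are oriented.
        alpha[which_pl] <- alpha[which_pl] +
          pl$mean * sign(gamma[which_pl])
      }
    }

    se_for <- function(n) 1 / sqrt(2 * maf * (1 - maf) * n)
    se_exp <- se_for(cfg$n_exposure)
    se_med <- se_for(cfg$n_mediator)
    se_out <- se_for(cfg$n_outcome)

    outlier <- rep(FALSE, k)
    if (cfg$n_outliers > 0L) {
      which_out <- sample(which(role == "exposure"), cfg$n_outliers)
      outlier[which_out] <- TRUE
      # Outlier pleiotropy scaled to the SNP's own outcome standard error so
      # the induced residual is outlier_scale standard errors by construction.
      alpha[which_out] <- alpha[which_out] +
        sample(c(-1, 1), cfg$n_outliers, replace = TRUE) *
          cfg$outlier_scale * se_out[which_out]
    }

    x_true <- gamma + cfg$reverse_effect * delta
    m_true <- cfg$a * x_true + eta
    y_true <- cfg$c * x_true + cfg$b * m_true + delta + alpha

    observe <- function(truth, se, n_trait) {
      beta <- truth + stats::rnorm(k, 0, se)
      pval <- pmax(2 * stats::pnorm(-abs(beta / se)), 1e-300)
      data.frame(variant_id = variant_id, chrom = chrom, pos = pos,
                 effect_allele = pair[, 1], other_allele = pair[, 2],
                 eaf = maf, beta = beta, se = se, pval = pval, n = n_trait,
                 stringsAsFactors = FALSE)
    }

    theta <- cfg$c + cfg$a * cfg$b
    out <- list(
      exposure = sumstats_table(observe(x_true, se_exp, cfg$n_exposure),
                                trait_id = "sim_exposure",
                                trait_label = "simulated exposure"),
      mediator = sumstats_table(observe(m_true, se_med, cfg$n_mediator),
                                trait_id = "sim_mediator",
                                trait_label = "simulated mediator"),
      outcome = sumstats_table(observe(y_true, se_out, cfg$n_outcome),
                               trait_id = "sim_outcome",
                               trait_label = "simulated outcome"),
      ld = ld_pair_table(ld_pairs),
      truth = list(snps = data.frame(variant_id = variant_id, role = role,
                                     maf = maf, gamma = gamma, eta = eta,
                                     delta = delta, alpha = alpha,
                                     outlier = outlier,
                                     beta_exposure = x_true,
                                     beta_mediator = m_true,
                                     beta_outcome = y_true,
                                     stringsAsFactors = FALSE),
                   a = cfg$a, b = cfg$b, c = cfg$c,
                   theta_total = theta,
                   mp_true = 100 * cfg$a * cfg$b / theta)
    )
    out
  })
}

#' Write a simulated system to disk
#'
#' Emits the three canonical summary-statistics TSVs, the LD TSV and the
#' truth-ledger TSV under `dir`.
#'
#' @param sim result of [simulate_mediation_system].
#' @param dir output directory (created if absent).
#' @return invisibly, the named vector of written paths.
#' @export
write_simulation <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(exposure = file.path(dir, "exposure.tsv"),
             mediator = file.path(dir, "mediator.tsv"),
             outcome = file.path(dir, "outcome.tsv"),
             ld = file.path(dir, "ld.tsv"),
             truth = file.path(dir, "truth.tsv"))
  write_sumstats(sim$exposure, paths["exposure"])
  write_sumstats(sim$mediator, paths["mediator"])
  write_sumstats(sim$outcome, paths["outcome"])
  utils::write.table(sim$ld$pairs, paths["ld"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(sim$truth$snps, paths["truth"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}
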