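# Worked-example fixture: summary estimates transcribed from a published
# two-step MR study of immune cell traits, plasma metabolites and lung
# adenocarcinoma (LUAD). Values are transcribed as printed, never computed;
# they anchor the mediation arithmetic as a regression surface. ORs from the
# study's step-2 screen are composed on the log scale: the printed mediated
# effects are reproducible as ln(OR_a) * beta_b only on the beta scale.

#' Worked-example fixture: immune cells, plasma metabolites and LUAD
#'
#' Transcribed inverse-variance-weighted estimates from a published two-step
#' Mendelian randomization study: total effects of 14 immune cell traits on
#' lung adenocarcinoma, effects of 21 plasma metabolites on LUAD, the 11
#' significant immune-trait-on-metabolite estimates (step 2, odds-ratio
#' scale), and the 9 reported mediation pathways (mediated effect ME on the
#' log-odds scale, mediated proportion MP in percent). All numbers are
#' transcriptions of printed values and carry printed rounding.
#'
#' @return list of four data.frames: `total_effects` (`exposure`, `nsnp`,
#'   `b`, `se`, `or`, `or_lci95`, `or_uci95`, `pval`), `metabolite_effects`
#'   (same columns), `step2_or` (`exposure`, `mediator`, `or`, `pval`) and
#'   `mediation` (`exposure`, `mediator`, `me`, `mp`, `pval`).
#' @export
luad_mediation_fixture <- function() {
  total_effects <- data.frame(
    exposure = c("Plasmacytoid DC %DC",
                 "CD39+ secreting Treg %secreting Treg",
                 "Naive CD8br %CD8br",
                 "T cell %leukocyte",
                 "Granulocyte %leukocyte",
                 "CD28+ CD45RA+ CD8dim %T cell",
                 "CD28+ CD45RA+ CD8dim AC",
                 "CD28- CD127- CD25++ CD8br %T cell",
                 "CD19 on IgD+ CD38br",
                 "CD19 on IgD- CD27-",
                 "CD25 on CD45RA+ CD4 not Treg",
                 "CD25 on resting Treg",
                 "CD25 on CD4+",
                 "CCR2 on granulocyte"),
    nsnp = c(21L, 20L, 24L, 15L, 21L, 33L, 35L, 14L, 13L, 22L, 20L, 14L, 12L, 16L),
    b =  c(0.10, -0.07, -0.09, -0.10, 0.13, -0.04, -0.03, -0.17, -0.18, -0.16,
           0.12, -0.12, -0.13, 0.15),
    se = c(0.03, 0.03, 0.03, 0.03, 0.05, 0.01, 0.01, 0.06, 0.05, 0.04, 0.04,
           0.04, 0.04, 0.04),
    or = c(1.10, 0.93, 0.91, 0.91, 1.14, 0.96, 0.97, 0.84, 0.83, 0.85, 1.12,
           0.89, 0.88, 1.16),
    or_lci95 = c(1.03, 0.88, 0.85, 0.85, 1.04, 0.94, 0.95, 0.75, 0.75, 0.78,
                 1.05, 0.82, 0.81, 1.08),
    or_uci95 = c(1.18, 0.98, 0.98, 0.97, 1.26, 0.99, 0.99, 0.95, 0.92, 0.93,
                 1.21, 0.96, 0.96, 1.24),
    pval = c(0.0028, 0.0087, 0.0089, 0.0043, 0.0062, 0.0061, 0.0034, 0.0042,
             0.0006, 0.0003, 0.0013, 0.0022, 0.0023, 2.96e-05),
    stringsAsFactors = FALSE)

  metabolite_effects <- data.frame(
    exposure = c("4-methyl-2-oxopentanoate levels",
                 "Gamma-glutamylmethionine levels",
                 "1-arachidonylglycerol (20:4) levels",
                 "Malonylcarnitine levels",
                 "1-arachidonoyl-gpc (20:4n6) levels",
                 "1-arachidonoyl-GPE (20:4n6) levels",
                 "5alpha-androstan-3beta,17alpha-diol disulfate levels",
                 "Indole-3-carboxylate levels",
                 "2-aminophenol sulfate levels",
                 "1H-indole-7-acetic acid levels",
                 "3-hydroxyhexanoate levels",
                 "Linoleoyl ethanolamide levels",
                 "1-stearoyl-2-linoleoyl-gpc (18:0/18:2) levels",
                 "Dibutyl sulfosuccinate levels",
                 "1-palmitoyl-2-linoleoyl-gpc (16:0/18:2) levels",
                 "1-palmitoyl-2-linoleoyl-GPI (16:0/18:2) levels",
                 "Eicosapentaenoate (EPA; 20:5n3) levels",
                 "Methionine levels",
                 "Retinol (Vitamin A) to linoleoyl-arachidonoyl-glycerol (18:2 to 20:4) [1] ratio",
                 "Retinol (Vitamin A) to linoleoyl-arachidonoyl-glycerol (18:2 to 20:4) [2] ratio",
                 "Cholesterol to linoleoyl-arachidonoyl-glycerol (18:2 to 20:4) [1] ratio"),
    nsnp = c(12L, 24L, 17L, 19L, 23L, 29L, 23L, 14L, 25L, 24L, 12L, 20L, 18L,
             28L, 27L, 20L, 22L, 17L, 9L, 12L, 16L),
    b =  c(0.32, -0.20, 0.25, -0.25, 0.12, 0.13, 0.28, 0.24, 0.21, 0.25, 0.26,
           -0.22, -0.25, -0.29, -0.21, -0.22, 0.23, -0.24, -0.26, -0.24, -0.22),
    se = c(0.11, 0.08, 0.07, 0.09, 0.04, 0.05, 0.08, 0.08, 0.08, 0.07, 0.10,
           0.08, 0.09, 0.10, 0.06, 0.07, 0.08, 0.09, 0.10, 0.07, 0.07),
    or = c(1.38, 0.81, 1.28, 0.78, 1.13, 1.14, 1.33, 1.27, 1.23, 1.28, 1.30,
           0.80, 0.78, 0.75, 0.81, 0.80, 1.26, 0.78, 0.77, 0.79, 0.81),
    or_lci95 = c(1.11, 0.70, 1.13, 0.65, 1.04, 1.04, 1.14, 1.09, 1.05, 1.12,
                 1.07, 0.68, 0.65, 0.62, 0.73, 0.69, 1.08, 0.65, 0.64, 0.69, 0.70),
    or_uci95 = c(1.71, 0.95, 1.46, 0.93, 1.22, 1.25, 1.54, 1.48, 1.44, 1.46,
                 1.57, 0.94, 0.94, 0.91, 0.91, 0.93, 1.47, 0.94, 0.94, 0.90, 0.93),
    pval = c(3.45e-03, 9.63e-03, 1.44e-04, 4.87e-03, 3.34e-03, 4.55e-03,
             2.21e-04, 2.62e-03, 8.79e-03, 3.91e-04, 7.11e-03, 6.76e-03,
             8.04e-03, 3.49e-03, 3.67e-04, 2.61e-03, 4.04e-03, 7.45e-03,
             8.47e-03, 4.00e-04, 3.63e-03),
    stringsAsFactors = FALSE)

  step2_or <- data.frame(
    exposure = c("CD39+ secreting Treg %secreting Treg",
                 "CD39+ secreting Treg %secreting Treg",
                 "T cell %leukocyte",
                 "CD28+ CD45RA+ CD8dim %T cell",
                 "CD28+ CD45RA+ CD8dim AC",
                 "CD28- CD127- CD25++ CD8br %T cell",
                 "CD28- CD127- CD25++ CD8br %T cell",
                 "CD19 on IgD+ CD38br",
                 "CD25 on CD45RA+ CD4 not Treg",
                 "CD25 on CD4+",
                 "CCR2 on granulocyte"),
    mediator = c("1-arachidonylglycerol (20:4) levels",
                 "1-stearoyl-2-linoleoyl-gpc (18:0/18:2) levels",
                 "Linoleoyl ethanolamide levels",
                 "Indole-3-carboxylate levels",
                 "Indole-3-carboxylate levels",
                 "3-hydroxyhexanoate levels",
                 "Methionine levels",
                 "Cholesterol to linoleoyl-arachidonoyl-glycerol (18:2 to 20:4) [1] ratio",
                 "Linoleoyl ethanolamide levels",
                 "Methionine levels",
                 "5alpha-androstan-3beta,17alpha-diol disulfate levels"),
    or = c(0.973, 0.974, 1.053, 1.015, 1.014, 1.049, 0.943, 0.947, 1.034,
           1.035, 1.042),
    pval = c(0.036, 0.042, 0.014, 0.046, 0.003, 0.039, 0.023, 0.043, 0.047,
             0.028, 0.036),
    stringsAsFactors = FALSE)

  mediation <- data.frame(
    exposure = c("CD39+ secreting Treg %secreting Treg",
                 "CD39+ secreting Treg %secreting Treg",
                 "T cell %leukocyte",
                 "CD28+ CD45RA+ CD8dim %T cell",
                 "CD28+ CD45RA+ CD8dim AC",
                 "CD28- CD127- CD25++ CD8br %T cell",
                 "CD28- CD127- CD25++ CD8br %T cell",
                 "CD25 on CD4+",
                 "CCR2 on granulocyte"),
    mediator = c("1-arachidonylglycerol (20:4) levels",
                 "1-stearoyl-2-linoleoyl-gpc (18:0/18:2) levels",
                 "Linoleoyl ethanolamide levels",
                 "Indole-3-carboxylate levels",
                 "Indole-3-carboxylate levels",
                 "3-hydroxyhexanoate levels",
                 "Methionine levels",
                 "Methionine levels",
                 "5alpha-androstan-3beta,17alpha-diol disulfate levels"),
    me = c(-0.00693, 0.00642, -0.0114, 0.00354, 0.00336, 0.0125, 0.0143,
           -0.00851, 0.0116),
    mp = c(9.71, -9.00, 11.60, -9.59, -10.00, -7.34, -8.39, 6.77, 7.82),
    pval = c(0.037, 0.043, 0.016, 0.047, 0.004, 0.042, 0.027, 0.030, 0.037),
    stringsAsFactors = FALSE)

  list(total_effects = total_effects, metabolite_effects = metabolite_effects,
       step2_or = step2_or, mediation = mediation)
}

#' Replay the worked-example mediation arithmetic
#'
#' Recomputes, for each reported pathway, the mediated effect and mediated
#' proportion from the printed building blocks alone: `beta_a` is the
#' natural log of the step-2 odds ratio, `beta_b` the printed
#' metabolite-on-LUAD beta, `beta_total` the natural log of the printed
#' total-effect odds ratio. Computed values sit next to the printed ones so
#' the rounding gap is visible.
#'
#' @param fixture result of [luad_mediation_fixture()].
#' @return data.frame with one row per reported pathway: `exposure`,
#'   `mediator`, `beta_total`, `beta_a`, `beta_b`, `me` (computed),
#'   `me_printed`, `mp` (computed, %), `mp_printed`.
#' @export
replay_mediation_fixture <- function(fixture = luad_mediation_fixture()) {
  med <- fixture$mediation
  key <- paste(med$exposure, med$mediator, sep = " | ")
  s2 <- fixture$step2_or
  s2_key <- paste(s2$exposure, s2$mediator, sep = " | ")
  beta_a <- log(s2$or[match(key, s2_key)])
  beta_b <- fixture$metabolite_effects$b[
    match(med$mediator, fixture$metabolite_effects$exposure)]
  beta_total <- log(fixture$total_effects$or[
    match(med$exposure, fixture$total_effects$exposure)])
  stopifnot(!anyNA(beta_a), !anyNA(beta_b), !anyNA(beta_total))
  me <- mediated_effect(beta_a, beta_b)
  data.frame(exposure = med$exposure, mediator = med$mediator,
             beta_total = beta_total, beta_a = beta_a, beta_b = beta_b,
             me = me, me_printed = med$me,
             mp = mediated_proportion(me, beta_total), mp_printed = med$mp,
             stringsAsFactors = FALSE)
}
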