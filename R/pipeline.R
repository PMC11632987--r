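# Orchestration: run configuration, full MR runs, two-step mediation runs,
# report tables, and the command-line entry point.

#' Read and validate a run configuration
#'
#' The run configuration is a JSON file naming the input summary-statistics
#' files and all analysis settings. Recognized keys: `exposure` (path or
#' array of paths), `outcome` (path), `mediator` (path, optional: absent
#' means a plain MR run), `ld` (path, optional), `output_dir`, `seed`
#' (mandatory), `reverse_screen` (logical), `instruments` (object:
#' `pval_threshold`, `clump_r2`, `clump_window_kb`, `min_f`, `f_literal`),
#' `methods` (object: `ivw_model`, `n_boot`, `presso_n_sim`,
#' `outlier_alpha`, `se_method`), `thresholds` (object: `screen_p`,
#' `mediation_p`). Unknown keys are an error; referenced paths must exist.
#'
#' @param path path to the JSON run configuration.
#' @return object of class `run_config`.
#' @export
read_run_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- c("exposure", "outcome", "mediator", "ld", "output_dir", "seed",
             "reverse_screen", "instruments", "methods", "thresholds")
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0L) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  for (req in c("exposure", "outcome", "output_dir", "seed")) {
    if (is.null(raw[[req]])) stop("config missing '", req, "'", call. = FALSE)
  }
  for (p in c(raw$exposure, raw$outcome, raw$mediator, raw$ld)) {
    if (!file.exists(p)) stop("config references missing file: ", p,
                              call. = FALSE)
  }
  ins <- raw$instruments %||% list()
  met <- raw$methods %||% list()
  thr <- raw$thresholds %||% list()
  cfg <- mr_config(
    instrument = instrument_config(
      pval_threshold = ins$pval_threshold %||% 1e-5,
      clump_r2 = ins$clump_r2 %||% 0.001,
      clump_window_kb = ins$clump_window_kb %||% 10000,
      min_f = ins$min_f %||% 10,
      f_literal = ins$f_literal %||% FALSE),
    ivw_model = met$ivw_model %||% "multiplicative_random",
    screen_p = thr$screen_p %||% 0.05,
    mediation_p = thr$mediation_p %||% 0.05,
    se_method = met$se_method %||% "delta_full",
    n_boot = met$n_boot %||% 1000,
    presso_n_sim = met$presso_n_sim %||% 5000,
    outlier_alpha = met$outlier_alpha %||% 0.05,
    seed = raw$seed)
  structure(list(exposure = raw$exposure, outcome = raw$outcome,
                 mediator = raw$mediator, ld = raw$ld,
                 output_dir = raw$output_dir,
                 reverse_screen = isTRUE(raw$reverse_screen),
                 analysis = cfg, source = path),
            class = "run_config")
}

load_ld <- function(config) {
  if (is.null(config$ld)) ld_pair_table() else read_ld_pairs(config$ld)
}

# Multiple-testing columns reported alongside raw p-values; selection rules
# in this package always threshold the raw p, matching the screening
# practice the defaults emulate.
add_p_adjust <- function(df) {
  df$pval_bonferroni <- stats::p.adjust(df$pval, method = "bonferroni")
  df$pval_bh <- stats::p.adjust(df$pval, method = "BH")
  df
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  path
}

sensitivity_row <- function(sens, exposure, outcome) {
  g <- function(x, f) if (is.null(x)) NA_real_ else f(x)
  data.frame(
    exposure = exposure, outcome = outcome,
    q_ivw = g(sens$q_ivw, function(x) x$Q),
    q_ivw_p = g(sens$q_ivw, function(x) x$pval),
    q_egger = g(sens$q_egger, function(x) x$Q),
    q_egger_p = g(sens$q_egger, function(x) x$pval),
    egger_intercept = g(sens$egger_intercept, function(x) x$estimate),
    egger_intercept_p = g(sens$egger_intercept, function(x) x$pval),
    presso_global_p = g(sens$presso, function(x) x$global_p),
    n_outliers = g(sens$presso, function(x) length(x$outlier_ids)),
    distortion_p = g(sens$presso, function(x) x$distortion_p %||% NA_real_),
    stringsAsFactors = FALSE)
}

run_manifest <- function(config, extra = list()) {
  cfg <- config$analysis
  c(list(package = "mrpath",
         version = as.character(utils::packageVersion("mrpath")),
         r_version = as.character(getRversion()),
         config_file = config$source %||% NA_character_,
         inputs = list(exposure = config$exposure, outcome = config$outcome,
                       mediator = config$mediator, ld = config$ld),
         seed = cfg$seed,
         instruments = unclass(cfg$instrument),
         ivw_model = cfg$ivw_model,
         palindrome_policy = cfg$palindrome_policy,
         palindrome_threshold = cfg$palindrome_threshold,
         thresholds = list(screen_p = cfg$screen_p,
                           mediation_p = cfg$mediation_p),
         n_boot = cfg$n_boot, presso_n_sim = cfg$presso_n_sim,
         outlier_alpha = cfg$outlier_alpha,
         se_method = cfg$se_method),
    extra)
}

# Run one exposure -> outcome analysis; returns the in-memory report.
run_pair <- function(exposure_tab, outcome_tab, ld, cfg) {
  instruments <- select_instruments(exposure_tab, ld, cfg$instrument)
  set <- harmonize(instruments, outcome_tab,
                   palindrome_policy = cfg$palindrome_policy,
                   palindrome_threshold = cfg$palindrome_threshold)
  estimates <- mr_run_all(set, ivw_model = cfg$ivw_model, n_boot = cfg$n_boot,
                          seed = cfg$seed)
  sens <- sensitivity_report(set, n_sim = cfg$presso_n_sim, seed = cfg$seed,
                             outlier_alpha = cfg$outlier_alpha,
                             sig_threshold = cfg$screen_p)
  list(exposure_id = exposure_tab$trait_id, outcome_id = outcome_tab$trait_id,
       set = set, estimates = estimates, sensitivity = sens,
       selection_log = attr(instruments, "selection_log"))
}

#' Run a full MR analysis from a configuration
#'
#' For each exposure file (one or many): select instruments, harmonize
#' against the outcome, run every applicable estimator, and run the full
#' sensitivity battery. Writes `estimates.tsv` (with Bonferroni and BH
#' columns), `sensitivity.tsv`, `loo.tsv`, `droplog.tsv`,
#' `selection_log.tsv`, `failures.tsv` and `manifest.json` under the
#' configured output directory. A failing exposure in a batch is recorded
#' in `failures.tsv` and does not abort the batch; if every exposure fails,
#' partial outputs are removed and the first error is re-raised.
#'
#' @param config a `run_config` (see [read_run_config]) or path to one.
#' @return invisibly, a list with `reports` (per-exposure results),
#'   `failures` (data.frame) and `output_dir`.
#' @export
run_mr <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  cfg <- config$analysis
  ld <- load_ld(config)
  outcome_tab <- read_sumstats(config$outcome, trait_id = basename(config$outcome))
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)

  reports <- list()
  failures <- data.frame(exposure = character(), error = character(),
                         stringsAsFactors = FALSE)
  for (path in config$exposure) {
    tab <- read_sumstats(path, trait_id = basename(path))
    res <- tryCatch(run_pair(tab, outcome_tab, ld, cfg), error = function(e) e)
    if (inherits(res, "error")) {
      failures <- rbind(failures, data.frame(exposure = path,
                                             error = conditionMessage(res),
                                             stringsAsFactors = FALSE))
    } else {
      reports[[path]] <- res
    }
  }
  if (length(reports) == 0L) {
    unlink(file.path(config$output_dir,
                     c("estimates.tsv", "sensitivity.tsv", "loo.tsv",
                       "droplog.tsv", "selection_log.tsv", "failures.tsv",
                       "manifest.json")))
    stop("all exposures failed; first error: ", failures$error[1],
         call. = FALSE)
  }

  est <- do.call(rbind, lapply(reports, function(r) {
    cbind(data.frame(exposure = r$exposure_id, outcome = r$outcome_id,
                     stringsAsFactors = FALSE), r$estimates)
  }))
  rownames(est) <- NULL
  write_tsv(add_p_adjust(est), file.path(config$output_dir, "estimates.tsv"))
  write_tsv(do.call(rbind, lapply(reports, function(r)
    sensitivity_row(r$sensitivity, r$exposure_id, r$outcome_id))),
    file.path(config$output_dir, "sensitivity.tsv"))
  loo <- do.call(rbind, lapply(reports, function(r) {
    if (is.null(r$sensitivity$loo)) return(NULL)
    cbind(data.frame(exposure = r$exposure_id, stringsAsFactors = FALSE),
          r$sensitivity$loo)
  }))
  if (!is.null(loo)) write_tsv(loo, file.path(config$output_dir, "loo.tsv"))
  write_tsv(do.call(rbind, lapply(reports, function(r) {
    if (nrow(r$set$dropped) == 0L) return(NULL)
    cbind(data.frame(exposure = r$exposure_id, stringsAsFactors = FALSE),
          r$set$dropped)
  })) %||% data.frame(exposure = character(), variant_id = character(),
                      reason = character()),
  file.path(config$output_dir, "droplog.tsv"))
  write_tsv(do.call(rbind, lapply(reports, function(r)
    cbind(data.frame(exposure = r$exposure_id, stringsAsFactors = FALSE),
          r$selection_log))),
    file.path(config$output_dir, "selection_log.tsv"))
  write_tsv(failures, file.path(config$output_dir, "failures.tsv"))
  jsonlite::write_json(run_manifest(config), auto_unbox = TRUE, digits = NA,
                       path = file.path(config$output_dir, "manifest.json"))
  invisible(list(reports = reports, failures = failures,
                 output_dir = config$output_dir))
}

#' Run a two-step mediation analysis from a configuration
#'
#' Requires `mediator` in the configuration. Runs the three MR legs via
#' [two_step_mediation], optionally the reverse-MR screen
#' (`reverse_screen: true`), and writes `mediation.tsv`, `forest.tsv`
#' (estimate, interval and label per leg plus the mediated effect, ready
#' for forest plotting), `reverse_screen.tsv` (when requested) and
#' `manifest.json`.
#'
#' @param config a `run_config` or path to one.
#' @return invisibly, a list with `mediation` (the [mediation_result]),
#'   `reverse` (data.frame or `NULL`) and `output_dir`.
#' @export
run_two_step <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  if (is.null(config$mediator)) {
    stop("two-step run requires a 'mediator' entry in the config",
         call. = FALSE)
  }
  cfg <- config$analysis
  ld <- load_ld(config)
  exposure <- read_sumstats(config$exposure[1],
                            trait_id = basename(config$exposure[1]))
  mediator <- read_sumstats(config$mediator, trait_id = basename(config$mediator))
  outcome <- read_sumstats(config$outcome, trait_id = basename(config$outcome))
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)

  med <- two_step_mediation(exposure, mediator, outcome, ld, cfg)
  write_tsv(as.data.frame(med), file.path(config$output_dir, "mediation.tsv"))

  z <- stats::qnorm(0.975)
  forest <- data.frame(
    label = c("total effect", "direct effect A", "direct effect B",
              "mediated effect"),
    estimate = c(med$beta_total, med$beta_a, med$beta_b, med$me),
    se = c(med$se_total, med$se_a, med$se_b, med$me_se),
    stringsAsFactors = FALSE)
  forest$ci_low <- forest$estimate - z * forest$se
  forest$ci_high <- forest$estimate + z * forest$se
  write_tsv(forest, file.path(config$output_dir, "forest.tsv"))

  reverse <- NULL
  if (config$reverse_screen) {
    reverse <- reverse_mr_screen(outcome, list(exposure, mediator), ld, cfg)
    write_tsv(reverse, file.path(config$output_dir, "reverse_screen.tsv"))
  }
  jsonlite::write_json(
    run_manifest(config, list(reverse_screen = config$reverse_screen)),
    auto_unbox = TRUE, digits = NA,
    path = file.path(config$output_dir, "manifest.json"))
  invisible(list(mediation = med, reverse = reverse,
                 output_dir = config$output_dir))
}

cli_usage <- function() {
  paste(
    "usage: mrpath <subcommand> [--config FILE] [--seed INT] [--out DIR]",
    "",
    "subcommands:",
    "  simulate            write simulated GWAS tables + truth ledger (--config, --out)",
    "  select-instruments  instrument selection for one sumstats file (--config)",
    "  harmonize           harmonize exposure and outcome files (--config, --out)",
    "  mr                  full MR run (--config)",
    "  sensitivity         sensitivity battery only (--config)",
    "  mediate             two-step mediation run (--config)",
    "  replay-fixture      print the worked-example mediation table",
    sep = "\n")
}

parse_cli_flags <- function(args) {
  flags <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (a %in% c("--config", "--seed", "--out")) {
      if (i == length(args)) stop("flag ", a, " needs a value", call. = FALSE)
      flags[[sub("^--", "", a)]] <- args[i + 1L]
      i <- i + 2L
    } else {
      stop("unknown flag: ", a, call. = FALSE)
    }
  }
  flags
}

#' Command-line entry point
#'
#' Dispatches one subcommand (see the usage string printed on error) to the
#' corresponding package operation. Designed to be called from an Rscript
#' wrapper: `Rscript -e 'quit(status = mrpath::mr_cli())'`. A `--seed` flag
#' overrides the config seed.
#'
#' @param args character vector of CLI arguments (default:
#'   `commandArgs(trailingOnly = TRUE)`).
#' @return integer exit status: 0 on success, 1 on a categorized analysis
#'   error, 2 on a usage error. Never calls `quit()` itself.
#' @export
mr_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0L) {
    message(cli_usage())
    return(2L)
  }
  sub <- args[1]
  known <- c("simulate", "select-instruments", "harmonize", "mr",
             "sensitivity", "mediate", "replay-fixture")
  if (!sub %in% known) {
    message("unknown subcommand: ", sub, "\n\n", cli_usage())
    return(2L)
  }
  flags <- tryCatch(parse_cli_flags(args[-1]), error = function(e) e)
  if (inherits(flags, "error")) {
    message(conditionMessage(flags), "\n\n", cli_usage())
    return(2L)
  }
  need_config <- !sub %in% "replay-fixture"
  if (need_config && is.null(flags$config)) {
    message("subcommand '", sub, "' requires --config\n\n", cli_usage())
    return(2L)
  }
  status <- tryCatch({
    switch(sub,
      "replay-fixture" = {
        df <- replay_mediation_fixture()
        utils::write.table(format(df, digits = 4), sep = "\t", quote = FALSE,
                           row.names = FALSE)
      },
      "simulate" = {
        raw <- jsonlite::read_json(flags$config, simplifyVector = TRUE)
        if (!is.null(flags$seed)) raw$seed <- as.integer(flags$seed)
        if (is.null(raw$seed)) stop("simulate config needs a seed", call. = FALSE)
        keep <- intersect(names(raw), names(formals(sim_config)))
        sim <- simulate_mediation_system(do.call(sim_config, raw[keep]))
        write_simulation(sim, flags$out %||% ".")
      },
      "select-instruments" = {
        config <- read_run_config(flags$config)
        tab <- read_sumstats(config$exposure[1],
                             trait_id = basename(config$exposure[1]))
        sel <- select_instruments(tab, load_ld(config),
                                  config$analysis$instrument)
        dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
        write_sumstats(sel, file.path(config$output_dir, "instruments.tsv"))
        write_tsv(attr(sel, "selection_log"),
                  file.path(config$output_dir, "selection_log.tsv"))
      },
      "harmonize" = {
        config <- read_run_config(flags$config)
        expo <- read_sumstats(config$exposure[1],
                              trait_id = basename(config$exposure[1]))
        outc <- read_sumstats(config$outcome, trait_id = basename(config$outcome))
        set <- harmonize(expo, outc,
                         palindrome_policy = config$analysis$palindrome_policy,
                         palindrome_threshold = config$analysis$palindrome_threshold)
        dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
        write_tsv(set$rows, file.path(config$output_dir, "harmonized.tsv"))
        write_tsv(set$dropped, file.path(config$output_dir, "droplog.tsv"))
      },
      "mr" = ,
      "sensitivity" = {
        config <- read_run_config(flags$config)
        if (!is.null(flags$seed)) config$analysis$seed <- as.integer(flags$seed)
        run_mr(config)
      },
      "mediate" = {
        config <- read_run_config(flags$config)
        if (!is.null(flags$seed)) config$analysis$seed <- as.integer(flags$seed)
        run_two_step(config)
      })
    0L
  }, error = function(e) {
    category <- if (inherits(e, "mrpath_no_instruments") ||
                    inherits(e, "mrpath_leg_failure")) "instrument-selection"
    else if (inherits(e, "mrpath_no_shared_instruments")) "harmonization"
    else if (inherits(e, "mrpath_insufficient_instruments")) "estimation"
    else "error"
    message("[", category, "] ", conditionMessage(e))
    1L
  })
  status
}
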