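# Builders for small in-code fixtures.

# A valid summary-statistics record data.frame; override any column.
make_records <- function(n = 3, ...) {
  out <- data.frame(
    variant_id = sprintf("rs%03d", seq_len(n)),
    chrom = rep("1", n),
    pos = 1000 * seq_len(n),
    effect_allele = rep("A", n),
    other_allele = rep("G", n),
    eaf = rep(0.3, n),
    beta = seq(0.1, by = 0.01, length.out = n),
    se = rep(0.02, n),
    pval = rep(1e-8, n),
    n = rep(10000, n),
    stringsAsFactors = FALSE
  )
  dots <- list(...)
  for (nm in names(dots)) out[[nm]] <- dots[[nm]]
  out
}

make_table <- function(n = 3, trait_id = "trait", ...) {
  sumstats_table(make_records(n, ...), trait_id = trait_id)
}

# Harmonized set whose Wald ratios are exactly `ratios` (beta_exp = 1).
hset_from_ratios <- function(ratios, se_out = 0.1, se_exp = 0.01) {
  harmonized_set(beta_exp = rep(1, length(ratios)),
                 se_exp = rep(se_exp, length(ratios)),
                 beta_out = ratios,
                 se_out = rep(se_out, length.out = length(ratios)))
}

# Random harmonized set for property-style loops.
random_hset <- function(k) {
  harmonized_set(beta_exp = stats::rnorm(k, 0.1, 0.05),
                 se_exp = stats::runif(k, 0.005, 0.02),
                 beta_out = stats::rnorm(k, 0, 0.05),
                 se_out = stats::runif(k, 0.01, 0.1))
}

# Brute-force LD-clumping oracle: enumerate all subsets, keep those with no
# conflicting pair, and return the maximal ones (no valid superset).
clump_oracle_maximal_subsets <- function(records, ld, r2_thresh, window_kb) {
  n <- nrow(records)
  conflict <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j && records$chrom[i] == records$chrom[j] &&
        abs(records$pos[i] - records$pos[j]) <= window_kb * 1000 &&
        ld_r2(ld, records$variant_id[i], records$variant_id[j]) >= r2_thresh) {
      conflict[i, j] <- TRUE
    }
  }
  subsets <- lapply(0:(2^n - 1), function(m) which(bitwAnd(m, 2^(seq_len(n) - 1)) > 0))
  valid <- Filter(function(s) {
    length(s) < 2 || !any(conflict[s, s])
  }, subsets)
  is_maximal <- vapply(valid, function(s) {
    extra <- setdiff(seq_len(n), s)
    !any(vapply(extra, function(e) {
      s2 <- c(s, e)
      !any(conflict[s2, s2])
    }, logical(1)))
  }, logical(1))
  lapply(valid[is_maximal], function(s) sort(records$variant_id[s]))
}
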