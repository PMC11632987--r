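test_that("read_sumstats parses well-formed files and applies column maps", {
  path <- withr::local_tempfile(fileext = ".tsv")
  write_sumstats(make_table(3), path)
  tab <- read_sumstats(path, trait_id = "t")
  expect_equal(n_variants(tab), 3)
  expect_equal(nrow(tab$rejected), 0)

  # foreign header mapped through column_map parses identically
  raw <- utils::read.table(path, header = TRUE, sep = "\t")
  names(raw)[names(raw) == "beta"] <- "b"
  names(raw)[names(raw) == "variant_id"] <- "SNP"
  path2 <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(raw, path2, sep = "\t", quote = FALSE, row.names = FALSE)
  tab2 <- read_sumstats(path2, column_map = c(b = "beta", SNP = "variant_id"),
                        trait_id = "t")
  expect_equal(tab2$records, tab$records)

  # missing mandatory column is a configuration error
  raw$b <- NULL
  utils::write.table(raw, path2, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_sumstats(path2, column_map = c(SNP = "variant_id")),
               "missing mandatory column")
})

test_that("invalid rows are rejected individually with reasons", {
  rec <- make_records(6)
  rec$se[2] <- 0                      # nonpositive se
  rec$beta[3] <- NA                   # unparseable beta
  rec$effect_allele[4] <- "AT"        # indel, rejected in v1
  rec$other_allele[5] <- "A"          # identical alleles
  tab <- sumstats_table(rec)
  expect_equal(n_variants(tab), 2)
  expect_setequal(tab$rejected$reason,
                  c("nonpositive se", "unparseable beta", "non-SNP allele",
                    "identical alleles"))
  expect_equal(tab$rejected$variant_id[tab$rejected$reason == "nonpositive se"],
               "rs002")
})

test_that("write/read round-trips field-for-field, including missing values", {
  rec <- make_records(5)
  rec$eaf[2] <- NA
  rec$n[4] <- NA
  tab <- sumstats_table(rec, trait_id = "rt")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_sumstats(tab, path)
  back <- read_sumstats(path, trait_id = "rt")
  expect_equal(back$records, tab$records)
  expect_true(is.na(back$records$eaf[2]))

  # empty table -> header-only file, still readable
  empty <- tab; empty$records <- tab$records[0, ]
  write_sumstats(empty, path)
  expect_equal(n_variants(read_sumstats(path)), 0)
})

test_that("harmonize keeps matches, flips swapped alleles, drops mismatches", {
  exp_tab <- make_table(4, trait_id = "exp",
                        effect_allele = c("A", "A", "C", "A"),
                        other_allele = c("G", "G", "T", "G"),
                        beta = c(0.1, 0.1, 0.1, 0.1), eaf = 0.3)
  out_rec <- make_records(4, beta = c(0.2, 0.2, 0.2, 0.2), eaf = 0.3)
  out_rec$effect_allele <- c("A", "G", "C", "A")
  out_rec$other_allele <- c("G", "A", "T", "C")   # same, swapped, same, mismatch
  out_rec$eaf <- c(0.3, 0.7, 0.3, 0.3)
  out_tab <- sumstats_table(out_rec, trait_id = "out")

  h <- harmonize(exp_tab, out_tab)
  expect_equal(h$rows$variant_id, c("rs001", "rs002", "rs003"))
  expect_equal(h$rows$beta_out, c(0.2, -0.2, 0.2))
  expect_equal(h$rows$eaf_out, c(0.3, 0.3, 0.3))
  expect_equal(h$dropped$variant_id, "rs004")
  expect_equal(h$dropped$reason, "allele mismatch")
})

test_that("strand-flipped alleles are complemented before matching", {
  exp_tab <- make_table(2, trait_id = "exp", effect_allele = c("A", "A"),
                        other_allele = c("G", "G"), beta = 0.1)
  out_rec <- make_records(2, beta = 0.2)
  out_rec$effect_allele <- c("T", "C")  # complement-same, complement-swapped
  out_rec$other_allele <- c("C", "T")
  out_tab <- sumstats_table(out_rec, trait_id = "out")
  h <- harmonize(exp_tab, out_tab)
  expect_equal(h$rows$beta_out, c(0.2, -0.2))
})

test_that("palindrome policies behave as documented", {
  exp_tab <- make_table(3, trait_id = "exp", effect_allele = "A",
                        other_allele = "T", eaf = c(0.50, 0.2, 0.8))
  out_tab <- make_table(3, trait_id = "out", effect_allele = "A",
                        other_allele = "T", beta = 0.2,
                        eaf = c(0.50, 0.2, 0.2))

  h <- harmonize(exp_tab, out_tab, palindrome_policy = "infer_by_eaf",
                 palindrome_threshold = 0.08)
  expect_equal(h$dropped$variant_id, "rs001")
  expect_equal(h$dropped$reason, "ambiguous palindrome")
  # rs002: eaf sides agree -> kept as-is; rs003: discordant -> strand flip
  expect_equal(h$rows$beta_out, c(0.2, -0.2))
  expect_equal(h$rows$eaf_out, c(0.2, 0.8))

  h2 <- harmonize(exp_tab, out_tab, palindrome_policy = "drop_all")
  expect_equal(nrow(h2$rows), 0)
  expect_true(all(h2$dropped$reason == "palindromic"))
})

test_that("empty intersection raises the typed no-shared-instruments error", {
  a <- make_table(2, trait_id = "a")
  b <- make_table(2, trait_id = "b", variant_id = c("rsX", "rsY"))
  expect_error(harmonize(a, b), class = "mrpath_no_shared_instruments")
})

test_that("harmonization is idempotent and sign-consistent", {
  set.seed(42)
  exp_tab <- make_table(6, trait_id = "exp",
                        effect_allele = c("A", "C", "G", "T", "A", "C"),
                        other_allele = c("G", "A", "T", "C", "C", "T"),
                        beta = rnorm(6, 0, 0.1), eaf = runif(6, 0.1, 0.4))
  out_tab <- make_table(6, trait_id = "out",
                        effect_allele = c("A", "C", "G", "T", "A", "C"),
                        other_allele = c("G", "A", "T", "C", "C", "T"),
                        beta = rnorm(6, 0, 0.1), eaf = runif(6, 0.1, 0.4))
  h1 <- harmonize(exp_tab, out_tab)
  # already aligned: nothing changes
  expect_equal(h1$rows$beta_out, out_tab$records$beta)
  expect_equal(nrow(h1$dropped), 0)

  # flip outcome alleles, negate beta, mirror eaf -> identical harmonized set
  flipped <- out_tab$records
  tmp <- flipped$effect_allele
  flipped$effect_allele <- flipped$other_allele
  flipped$other_allele <- tmp
  flipped$beta <- -flipped$beta
  flipped$eaf <- 1 - flipped$eaf
  h2 <- harmonize(exp_tab, sumstats_table(flipped, trait_id = "out"))
  expect_equal(h2$rows, h1$rows)
})
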