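# Build an allele_counts object directly, bypassing the counter, so the
# filter arithmetic is tested in isolation.
counts_fixture <- function(allele, raw, umi = raw, unique_cdr3 = raw,
                           hists = NULL, total_rows = sum(raw)) {
  if (is.null(hists))
    hists <- lapply(raw, function(r)
      if (r == 0) integer(0) else {
        h <- rep(1L, r); names(h) <- as.character(20 + seq_len(r) * 3); h
      })
  names(hists) <- allele
  igcore:::new_allele_counts(allele, raw, umi, unique_cdr3, hists,
                             total_rows, "V", umis_present = TRUE)
}

test_that("allelic ratio is count over the gene's top allele count", {
  counts <- counts_fixture(c("GA*01", "GA*02", "GA*03"),
                           raw = c(1000L, 150L, 5L))
  gt <- filter_genotype(counts, filter_config(allelic_ratio = 0.1))
  expect_equal(gt$allelic_ratio, c(1, 0.15, 0.005))
  expect_equal(gt$in_genotype, c(TRUE, TRUE, FALSE))
  # exactly one allele of an expressed gene carries ratio 1
  expect_equal(sum(gt$allelic_ratio == 1), 1)
})

test_that("expected-frequency table rescues low-expression alleles but never clones", {
  counts <- counts_fixture(c("GA*01", "GA*02"), raw = c(1000L, 60L),
                           total_rows = 200000L)
  # ratio 0.06 < 0.1, but frequency 3e-4 >= table minimum 1e-4: rescued
  ef <- data.frame(allele = "GA*02", min_freq = 1e-4)
  gt <- filter_genotype(counts, filter_config(expected_freq = ef))
  expect_false(gt$pass_ratio[2])
  expect_true(gt$rescued[2])
  expect_true(gt$in_genotype[2])
  # rescue soundness: a rescued allele always meets its table minimum
  expect_true(all(gt$frequency[gt$rescued] >= 1e-4))

  # below the table minimum: not rescued, and additionally excluded
  ef2 <- data.frame(allele = "GA*02", min_freq = 1e-2)
  gt2 <- filter_genotype(counts, filter_config(expected_freq = ef2))
  expect_false(gt2$in_genotype[2])
  expect_false(gt2$pass_expected[2])

  # rescue never overrides min_count
  counts3 <- counts_fixture(c("GA*01", "GA*02"), raw = c(1000L, 5L),
                            total_rows = 10000L)
  gt3 <- filter_genotype(counts3, filter_config(
    expected_freq = data.frame(allele = "GA*02", min_freq = 1e-5)))
  expect_true(gt3$rescued[2])
  expect_false(gt3$in_genotype[2])

  # unknown table alleles warn
  expect_warning(filter_genotype(counts, filter_config(
    expected_freq = data.frame(allele = "ZZ*99", min_freq = 0.1))),
    "ZZ\\*99")
})

test_that("CDR3 diversity filters remove expanded clones", {
  # 40 matches all sharing one CDR3: modal length share 1 > 0.6 and
  # unique fraction 0.025 < 0.1
  clone_hist <- setNames(40L, "21")
  counts <- counts_fixture(c("GA*01", "GB*01"), raw = c(1000L, 40L),
                           unique_cdr3 = c(1000L, 1L),
                           hists = list(NULL, clone_hist))
  h <- attr(counts, "cdr3_hists")
  h[["GA*01"]] <- setNames(rep(100L, 10), as.character(seq(15, 42, 3)))
  attr(counts, "cdr3_hists") <- h
  gt <- filter_genotype(counts, filter_config())
  expect_true(gt$in_genotype[gt$allele == "GA*01"])
  out <- gt[gt$allele == "GB*01", ]
  expect_false(out$in_genotype)
  expect_false(out$pass_cdr3_len)
  expect_false(out$pass_cdr3_diversity)
  expect_equal(out$modal_cdr3_share, 1)
  expect_equal(out$unique_cdr3_frac, 1 / 40)
})

test_that("raising any threshold never adds alleles to the genotype", {
  sim <- small_sim(n_reads = 3000, seed = 47, per_base_error = 0.003)
  counts <- count_cores(sim$lib$records, derive_v_cores(sim$dbs$v))
  base_in <- genotype_alleles(filter_genotype(counts, filter_config()))
  tighter <- list(
    filter_config(allelic_ratio = 0.3),
    filter_config(min_count = 50),
    filter_config(lenmaxfreq = 0.3),
    filter_config(min_unique_cdr3_frac = 0.5))
  for (cfg in tighter)
    expect_true(all(genotype_alleles(filter_genotype(counts, cfg))
                    %in% base_in))
})

test_that("empty libraries give empty genotypes with zero counts", {
  sim <- small_sim(n_reads = 200, seed = 3)
  fit <- genotype_library(sim$lib$records[0, ], sim$dbs$v)
  expect_equal(sum(fit$genotype$in_genotype), 0)
  expect_true(all(fit$genotype$raw_count == 0))
})

test_that("noiseless simulated libraries are recovered exactly end to end", {
  sim <- small_sim(n_reads = 4000, seed = 11, per_base_error = 0)
  for (seg in c("v", "j")) {
    fit <- genotype_library(sim$lib$records, sim$dbs[[seg]])
    expect_identical(genotype_alleles(fit), true_alleles(sim$genotype[[seg]]))
  }
  fit_d <- genotype_library(sim$lib$records, sim$dbs$d, use_lcs = TRUE)
  expect_identical(genotype_alleles(fit_d), true_alleles(sim$genotype$d))
  # D genotyping defaults to the higher 0.2 allelic ratio
  expect_equal(attr(fit_d$genotype, "allelic_ratio_cutoff"), 0.2)
})

test_that("batch genotyping is per-library consistent and robust to failures", {
  sim1 <- small_sim(n_reads = 2500, seed = 61)
  sim2 <- small_sim(n_reads = 2500, seed = 62)   # same dbs (same db seeds)
  b <- batch_genotype(list(lib1 = sim1$lib$records, lib2 = sim2$lib$records,
                           again = sim1$lib$records), sim1$dbs$v)
  expect_s3_class(b, "ig_genotype_batch")
  # each column equals its single-library genotype
  single <- genotype_library(sim1$lib$records, sim1$dbs$v)
  col_in <- rownames(b$presence)[b$presence[, "lib1"] == "IN"]
  expect_setequal(col_in, genotype_alleles(single))
  # identical library twice: identical columns
  expect_identical(b$presence[, "lib1"], b$presence[, "again"])
  # union equals the union of per-library genotypes
  expect_setequal(b$union_alleles,
                  union(genotype_alleles(b$genotypes$lib1),
                        genotype_alleles(b$genotypes$lib2)))

  # a failing library aborts only itself
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines("not_a_sequence_column\t1", f)
  b2 <- batch_genotype(list(ok = sim1$lib$records, bad = f), sim1$dbs$v)
  expect_null(b2$genotypes$bad)
  expect_named(b2$failures, "bad")
  expect_identical(b2$presence[, "ok"],
                   b$presence[, "lib1"])
  m <- withr::local_tempfile(fileext = ".tsv")
  write_batch_matrix(b2, m)
  expect_true("bad" %in% names(read.delim(m, check.names = FALSE)))
})

test_that("configs read from YAML and expected-frequency TSVs", {
  ef <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("allele\tmin_freq", "GA*02\t0.0001"), ef)
  y <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("allelic_ratio: 0.15", "min_count: 20",
               paste0("expected_freq: ", ef)), y)
  cfg <- read_filter_config(y)
  expect_equal(cfg$allelic_ratio, 0.15)
  expect_equal(cfg$min_count, 20)
  expect_equal(cfg$expected_freq, c("GA*02" = 1e-4))
})
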