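test_that("V cores trim by the default unless a terminal variant intervenes", {
  # single-allele gene: plain default trim from the 3' end
  db <- make_db("GA*01", "AAACCCGGGTTT", "V")
  cores <- derive_v_cores(db, default_trim = 4, variant_window = 6)
  expect_equal(unname(cores$cores["GA*01"]), "AAACCCGG")
  expect_equal(cores$gene_trim$trim3, 4L)

  # alleles differing only at the final nucleotide: zero trim
  db <- make_db(c("GA*01", "GA*02"),
                c("TTTGGGCCCACGTA", "TTTGGGCCCACGTC"), "V")
  cores <- derive_v_cores(db, default_trim = 4, variant_window = 6)
  expect_equal(unname(cores$cores[c("GA*01", "GA*02")]), db$seq)
  expect_equal(cores$gene_trim$trim3, 0L)

  # variant at 5 nt from the end (position L-4): default trim of 4
  # still retains the distinguishing position
  s1 <- "AAACCCGGGTTA"          # L = 12, variant at position 8
  s2 <- "AAACCCGTGTTA"
  cores <- derive_v_cores(make_db(c("GB*01", "GB*02"), c(s1, s2), "V"),
                          default_trim = 4, variant_window = 6)
  expect_equal(cores$gene_trim$trim3, 4L)
  expect_equal(unname(cores$cores["GB*01"]), "AAACCCGG")
  expect_equal(unname(cores$cores["GB*02"]), "AAACCCGT")

  # variant 3 nt from the end: trim reduced to 2 (most-3' rule)
  s1 <- "AAACCCGGGTAG"          # variant at position 10, offset 3
  s2 <- "AAACCCGGGGAG"
  cores <- derive_v_cores(make_db(c("GC*01", "GC*02"), c(s1, s2), "V"),
                          default_trim = 4, variant_window = 6)
  expect_equal(cores$gene_trim$trim3, 2L)

  # allele shorter than the trim errors
  expect_error(derive_v_cores(make_db("GD*01", "ACGT", "V"),
                              default_trim = 4, variant_window = 6),
               "shorter")
  # length-only difference errors with the pair named
  expect_error(derive_v_cores(make_db(c("GE*01", "GE*02"),
                                      c("ACGTACGTAC", "ACGTACGTACGG"), "V"),
                              default_trim = 2, variant_window = 6),
               "GE\\*01")
})

test_that("J cores trim from the 5' end with the mirrored variant rule", {
  db <- make_db("JA*01", "ATTACTACTTTGACTACTGG", "J")
  cores <- derive_j_cores(db, trim5 = 6)
  expect_equal(unname(cores$cores["JA*01"]), "ACTTTGACTACTGG")
  expect_equal(cores$gene_trim$trim5, 6L)

  # variant at 5' position 2 reduces the trim to 1
  db <- make_db(c("JB*01", "JB*02"),
                c("CAGGGACTTTGACTAC", "CTGGGACTTTGACTAC"), "J")
  cores <- derive_j_cores(db, trim5 = 6)
  expect_equal(cores$gene_trim$trim5, 1L)
  expect_equal(unname(cores$cores["JB*01"]), "AGGGACTTTGACTAC")
  expect_equal(unname(cores$cores["JB*02"]), "TGGGACTTTGACTAC")

  # trim >= allele length errors
  expect_error(derive_j_cores(make_db("JC*01", "ACGTA", "J"), trim5 = 5),
               "shorter")
})

test_that("identical cores across genes are merged under a joined name", {
  shared <- "TTTTGGGGCCCCAAAA"
  db <- make_db(c("GA*01", "GB*01", "GC*01"),
                c(paste0(shared, "ACGTCA"), paste0(shared, "ACGTGG"),
                  paste0("AAAACCCCGGGGTTTT", "ACGTCA")), "V")
  cores <- derive_v_cores(db, default_trim = 6, variant_window = 6)
  expect_length(cores$merged_groups, 1)
  expect_setequal(cores$merged_groups[[1]], c("GA*01", "GB*01"))
  expect_true("GA*01/GB*01" %in% names(cores$cores))
  expect_false(anyDuplicated(cores$cores) > 0)
})

test_that("D cores trim both ends, honour per-allele overrides and stay gene specific", {
  db <- make_db("DA*01", "GTGGATATAGTGGCTACGATTAC", "D")
  cores <- derive_d_cores(db, trim5 = 4, trim3 = 4)
  expect_equal(unname(cores$cores["DA*01"]), "ATATAGTGGCTACGA")

  # per-allele table overrides only the listed allele
  db2 <- make_db(c("DA*01", "DB*01"),
                 c("GTGGATATAGTGGCTACGATTAC", "CCAATTGGACGACGTTGTAA"), "D")
  tt <- data.frame(allele = "DB*01", trim5 = 2, trim3 = 2)
  cores2 <- derive_d_cores(db2, trim5 = 4, trim3 = 4, trim_table = tt)
  expect_equal(unname(cores2$cores["DA*01"]), "ATATAGTGGCTACGA")
  expect_equal(unname(cores2$cores["DB*01"]), "AATTGGACGACGTTGT")
  expect_equal(cores2$allele_trim$trim5, c(4L, 2L))

  # trims reducing a short allele below the minimum core length error
  expect_error(derive_d_cores(make_db("DC*01", "GGTATAACTGGA", "D"),
                              trim5 = 4, trim3 = 4), "minimum length")

  # a core contained in another gene's allele is a gene-specificity error
  db3 <- make_db(c("DD*01", "DE*01"),
                 c("AACCGGTTACGTAGCA", "TTAACCGGTTACGTAGCATT"), "D")
  expect_error(derive_d_cores(db3, trim5 = 2, trim3 = 2), "gene specific")

  # unknown allele in the trim table errors
  expect_error(derive_d_cores(db, trim_table = data.frame(
    allele = "DX*01", trim5 = 1, trim3 = 1)), "unknown")
})

test_that("LCS substring sets enumerate exhaustively and keep only allele-specific strings", {
  # single allele of length 10 at fraction 0.5: 6+5+4+3+2+1 = 21 substrings
  db <- make_db("DA*01", "ACGTACGGTT", "D")
  dset <- derive_d_lcs_cores(db, min_fraction = 0.5)
  expect_length(dset$substrings[["DA*01"]], 21)
  expect_equal(dset$min_len[["DA*01"]], 5L)

  # a 7-mer shared between two alleles is excluded from both sets
  shared7 <- "ACGGATC"
  db2 <- make_db(c("DA*01", "DB*01"),
                 c(paste0("TTTT", shared7, "GGG"),    # L = 14, min len 7
                   paste0("CCAA", shared7, "TAA")), "D")
  dset2 <- derive_d_lcs_cores(db2, min_fraction = 0.5)
  for (a in names(dset2$substrings)) {
    expect_false(shared7 %in% dset2$substrings[[a]])
    for (s in dset2$substrings[[a]])
      expect_false(grepl(s, db2$seq[db2$name != a], fixed = TRUE))
  }

  # min_fraction = 1: the full sequence when unique, empty + warning otherwise
  dset3 <- derive_d_lcs_cores(db, min_fraction = 1)
  expect_equal(dset3$substrings[["DA*01"]], "ACGTACGGTT")
  db4 <- make_db(c("DA*01", "DB*01"),
                 c("ACGTACGGTTAA", "TACGTACGGTTAAT"), "D")
  expect_warning(dset4 <- derive_d_lcs_cores(db4, min_fraction = 1),
                 "DA\\*01")
  expect_equal(dset4$excluded, "DA*01")
  expect_false("DA*01" %in% names(dset4$substrings))
})

test_that("core structural properties hold on simulated databases", {
  vdb <- simulate_germline_db(15, c(1, 2), segment = "V", seed = 21)
  jdb <- simulate_germline_db(6, c(1, 2), segment = "J", seed = 22)
  ddb <- simulate_germline_db(6, c(1, 2), segment = "D", seed = 23)
  vc <- derive_v_cores(vdb)
  jc <- derive_j_cores(jdb)

  # prefix property: V core = first (L - trim3) characters of the allele;
  # J core = last (L - trim5); equal trim within each gene by construction
  for (nm in names(vc$cores)) {
    a <- sub("/.*", "", nm)
    trim <- vc$gene_trim$trim3[vc$gene_trim$gene == gene_of(a)]
    full <- vdb$seq[vdb$name == a]
    expect_identical(unname(vc$cores[[nm]]),
                     substr(full, 1, nchar(full) - trim))
  }
  for (nm in names(jc$cores)) {
    a <- sub("/.*", "", nm)
    trim <- jc$gene_trim$trim5[jc$gene_trim$gene == gene_of(a)]
    full <- jdb$seq[jdb$name == a]
    expect_identical(unname(jc$cores[[nm]]),
                     substr(full, trim + 1, nchar(full)))
  }

  # specificity property (brute force): every LCS substring occurs in its
  # own allele and in no other
  dset <- derive_d_lcs_cores(ddb, min_fraction = 0.5)
  for (a in names(dset$substrings)) {
    own <- ddb$seq[ddb$name == a]
    rest <- ddb$seq[ddb$name != a]
    for (s in dset$substrings[[a]]) {
      expect_true(grepl(s, own, fixed = TRUE))
      expect_false(any(grepl(s, rest, fixed = TRUE)))
      expect_gte(nchar(s), dset$min_len[[a]])
    }
  }

  # determinism: identical inputs give identical core databases
  expect_identical(derive_v_cores(vdb), vc)
  expect_identical(derive_d_lcs_cores(ddb, 0.5), dset)
})

test_that("core FASTA and trim report serialise", {
  vdb <- simulate_germline_db(5, 2, segment = "V", seed = 30)
  vc <- derive_v_cores(vdb)
  f1 <- withr::local_tempfile(fileext = ".fasta")
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_core_fasta(vc, f1)
  write_trim_report(vc, f2)
  lines <- readLines(f1)
  expect_true(any(grepl("trim3=", lines)))
  tab <- read.delim(f2)
  expect_equal(nrow(tab), nrow(vc$gene_trim))
})
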