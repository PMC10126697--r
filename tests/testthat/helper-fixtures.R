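# Fixtures built in code: tiny hand-written databases and libraries, plus
# a naive per-record substring-scan oracle kept independent of the
# package's Biostrings-based matching.

make_db <- function(names, seqs, segment) {
  igcore:::new_allele_db(names, seqs, segment)
}

make_records <- function(sequences, umi = NULL, cdr3 = NULL,
                         v_call = NULL, j_call = NULL) {
  n <- length(sequences)
  igcore:::as_rearrangements(data.frame(
    sequence = sequences,
    umi = umi %||% rep("", n),
    cdr3 = cdr3 %||% rep("", n),
    v_call = v_call %||% rep(NA_character_, n),
    d_call = NA_character_,
    j_call = j_call %||% rep(NA_character_, n),
    stringsAsFactors = FALSE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Naive oracle: one grepl per (record, pattern) pair.
naive_match_matrix <- function(sequences, patterns) {
  m <- matrix(FALSE, length(sequences), length(patterns))
  for (i in seq_along(sequences))
    for (j in seq_along(patterns))
      m[i, j] <- grepl(patterns[[j]], sequences[[i]], fixed = TRUE)
  m
}

# Naive LCS counting oracle: per record, scan every substring of every
# allele; one count to the allele with the longest matching substring
# (alphabetical tie-break).
naive_lcs_counts <- function(sequences, substrings_by_allele) {
  counts <- setNames(integer(length(substrings_by_allele)),
                     names(substrings_by_allele))
  for (s in sequences) {
    best_allele <- NA_character_
    best_len <- 0L
    for (a in sort(names(substrings_by_allele))) {
      for (p in substrings_by_allele[[a]]) {
        if (nchar(p) > best_len && grepl(p, s, fixed = TRUE)) {
          best_len <- nchar(p)
          best_allele <- a
        }
      }
    }
    if (!is.na(best_allele))
      counts[[best_allele]] <- counts[[best_allele]] + 1L
  }
  counts
}

# A small diploid simulation bundle used by several test files.
small_sim <- function(n_reads = 4000, seed = 42, per_base_error = 0,
                      v_genes = 8, d_genes = 5, j_genes = 4,
                      span = c(v = 0.5, d = 0.5, j = 0.5), ...) {
  dbs <- list(
    v = simulate_germline_db(v_genes, c(1, 2), segment = "V", seed = seed),
    d = simulate_germline_db(d_genes, c(1, 2), segment = "D", seed = seed + 1),
    j = simulate_germline_db(j_genes, c(1, 2), segment = "J", seed = seed + 2))
  gt <- list(v = simulate_genotype(dbs$v, seed + 3, presence = 1),
             d = simulate_genotype(dbs$d, seed + 4, presence = 1),
             j = simulate_genotype(dbs$j, seed + 5, presence = 1))
  cfg <- sim_config(n_reads = n_reads, usage_span_log10 = span,
                    per_base_error = per_base_error, ...)
  lib <- simulate_library(gt, dbs, cfg, seed = seed + 6)
  list(dbs = dbs, genotype = gt, config = cfg, lib = lib)
}
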