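#' Exact-match core counting
#'
#' A record contributes one raw count to an allele iff the allele's core
#' occurs as an exact contiguous substring anywhere in the record's
#' sequence (reads carry primer/UTR prefixes of varying length, so matching
#' is unanchored; only the plus strand is searched because upstream
#' pipelines emit oriented tables). `N` bases in reads never match a core
#' base. Alongside raw counts, distinct-UMI counts and per-allele CDR3
#' statistics are accumulated; the latter feed the clonal-expansion
#' filters.
#'
#' @name counter
NULL

# Per-allele statistics from the set of matching record indices. Records
# without a UMI each count as their own molecule; non-empty UMIs are
# deduplicated.
allele_stats <- function(records, hit) {
  umis <- records$umi[hit]
  nz <- nzchar(umis)
  cdr3 <- records$cdr3[hit]
  lens <- nchar(cdr3)
  hist <- integer(0)
  if (length(lens)) {
    tb <- table(lens)
    hist <- as.integer(tb)
    names(hist) <- names(tb)
  }
  list(raw = length(umis),
       umi = length(unique(umis[nz])) + sum(!nz),
       unique_cdr3 = length(unique(cdr3)),
       hist = hist)
}

core_gene <- function(name) {
  vapply(strsplit(name, "/", fixed = TRUE), function(parts)
    paste(unique(gene_of(parts)), collapse = "/"), character(1))
}

new_allele_counts <- function(allele, raw, umi, unique_cdr3, hists,
                              total_rows, segment, umis_present, ...) {
  df <- data.frame(allele = allele, gene = core_gene(allele),
                   raw_count = as.integer(raw), umi_count = as.integer(umi),
                   unique_cdr3 = as.integer(unique_cdr3),
                   frequency = if (total_rows > 0) raw / total_rows else 0,
                   stringsAsFactors = FALSE)
  rownames(df) <- NULL
  attr(df, "cdr3_hists") <- hists
  attr(df, "total_rows") <- total_rows
  attr(df, "segment") <- segment
  attr(df, "umis_present") <- umis_present
  extra <- list(...)
  for (nm in names(extra)) attr(df, nm) <- extra[[nm]]
  class(df) <- c("allele_counts", "data.frame")
  df
}

#' Count exact core occurrences in a library
#'
#' @param records a `rearrangements` data frame.
#' @param core_db a `core_db` from [derive_v_cores()], [derive_j_cores()]
#'   or [derive_d_cores()].
#' @return An `allele_counts` data frame with columns `allele`, `gene`,
#'   `raw_count`, `umi_count`, `unique_cdr3`, `frequency`
#'   (= raw_count / total rows), plus attributes `cdr3_hists` (named list
#'   of CDR3 nucleotide-length histograms; empty CDR3s bin at length 0),
#'   `total_rows`, `segment` and `umis_present`.
#' @export
count_cores <- function(records, core_db) {
  stopifnot(inherits(core_db, "core_db"))
  if (length(core_db$cores) == 0L) stop("empty core database")
  n <- nrow(records)
  subject <- Biostrings::DNAStringSet(records$sequence)
  nm <- names(core_db$cores)
  stats <- vector("list", length(nm))
  for (i in seq_along(nm)) {
    hit <- if (n == 0L) logical(0) else
      Biostrings::vcountPattern(core_db$cores[[i]], subject) > 0L
    stats[[i]] <- allele_stats(records, hit)
  }
  hists <- lapply(stats, `[[`, "hist")
  names(hists) <- nm
  new_allele_counts(
    allele = nm,
    raw = vapply(stats, `[[`, 0L, "raw"),
    umi = vapply(stats, `[[`, 0L, "umi"),
    unique_cdr3 = vapply(stats, `[[`, 0L, "unique_cdr3"),
    hists = hists, total_rows = n, segment = core_db$segment,
    umis_present = any(nzchar(records$umi))
  )
}

#' Count LCS D-cores with the one-count-per-read rule
#'
#' Every record is scanned against the full set of allele-specific D
#' substrings. A record can raise at most one D count: when substrings of
#' several alleles match, the allele with the longest matching substring
#' wins; a length tie goes to the alphabetically first allele and the
#' record is flagged ambiguous. Per-substring tallies (each counting
#' record attributed to its longest matching substring of the winning
#' allele) are retained for reporting.
#'
#' @param records a `rearrangements` data frame.
#' @param dcores a `d_core_set` from [derive_d_lcs_cores()].
#' @return An `allele_counts` data frame (see [count_cores()]) with extra
#'   attributes `substring_tallies` (data frame `allele`, `substring`,
#'   `count`) and `n_ambiguous`.
#' @export
count_lcs <- function(records, dcores) {
  stopifnot(inherits(dcores, "d_core_set"))
  n <- nrow(records)
  pat <- unlist(dcores$substrings, use.names = FALSE)
  pal <- rep(names(dcores$substrings), lengths(dcores$substrings))
  widths <- nchar(pat)
  best_allele <- rep(NA_character_, n)
  best_sub <- rep(NA_character_, n)
  ambiguous <- logical(n)
  if (n > 0L && length(pat)) {
    subject <- Biostrings::DNAStringSet(records$sequence)
    unassigned <- rep(TRUE, n)
    for (w in sort(unique(widths), decreasing = TRUE)) {
      if (!any(unassigned)) break
      sel <- which(widths == w)
      pd <- Biostrings::PDict(pat[sel])
      hits <- Biostrings::vwhichPDict(pd, subject)
      idx <- which(unassigned & lengths(hits) > 0L)
      for (i in idx) {
        k <- sel[hits[[i]]]
        al <- unique(pal[k])
        win <- min(al)
        best_allele[i] <- win
        best_sub[i] <- min(pat[k][pal[k] == win])
        ambiguous[i] <- length(al) > 1L
      }
      unassigned[idx] <- FALSE
    }
  }
  nm <- names(dcores$substrings)
  stats <- lapply(nm, function(a)
    allele_stats(records, !is.na(best_allele) & best_allele == a))
  hists <- lapply(stats, `[[`, "hist")
  names(hists) <- nm
  counted <- !is.na(best_allele)
  tal <- if (any(counted)) {
    tb <- table(best_allele[counted], best_sub[counted])
    df <- as.data.frame(tb, stringsAsFactors = FALSE)
    names(df) <- c("allele", "substring", "count")
    df <- df[df$count > 0L, , drop = FALSE]
    df[order(df$allele, -df$count, df$substring), , drop = FALSE]
  } else data.frame(allele = character(0), substring = character(0),
                    count = integer(0))
  rownames(tal) <- NULL
  new_allele_counts(
    allele = nm,
    raw = vapply(stats, `[[`, 0L, "raw"),
    umi = vapply(stats, `[[`, 0L, "umi"),
    unique_cdr3 = vapply(stats, `[[`, 0L, "unique_cdr3"),
    hists = hists, total_rows = n, segment = "D",
    umis_present = any(nzchar(records$umi)),
    substring_tallies = tal, n_ambiguous = sum(ambiguous),
    counting = "lcs"
  )
}

#' Iterative truncation scan of a single allele
#'
#' Counts, for every trim t = 0..`max_trim`, the records containing the
#' allele sequence truncated by t nucleotides from the chosen end. Counts
#' are necessarily non-decreasing in t (a match of the longer string
#' implies a match of every further truncation). The scan localises the
#' recombination-affected region: counts rise while trimming removes
#' recombination-clipped bases and plateau once the core is reached; a
#' heterozygous partner differing near the end produces an abrupt jump at
#' the trim that discards the distinguishing variant.
#'
#' @param records a `rearrangements` data frame.
#' @param allele_seq the full-length allele sequence (single string).
#' @param max_trim largest trim scanned; must be < allele length.
#' @param end `"3prime"` (V-style) or `"5prime"` (J-style).
#' @param name optional allele name for display.
#' @return A `truncation_scan` data frame with columns `trim`, `count`.
#' @export
truncation_scan <- function(records, allele_seq, max_trim,
                            end = c("3prime", "5prime"), name = NULL) {
  end <- match.arg(end)
  stopifnot(length(allele_seq) == 1L, max_trim >= 0,
            max_trim < nchar(allele_seq))
  L <- nchar(allele_seq)
  n <- nrow(records)
  counts <- integer(max_trim + 1L)
  cand <- seq_len(n)
  # Scan from the shortest query (largest trim): matches at trim t-1 are a
  # subset of matches at trim t, so each longer query is searched only
  # within the previous match set.
  for (t in seq(max_trim, 0L)) {
    q <- if (end == "3prime") substr(allele_seq, 1L, L - t)
         else substr(allele_seq, t + 1L, L)
    if (length(cand)) {
      subj <- Biostrings::DNAStringSet(records$sequence[cand])
      cand <- cand[Biostrings::vcountPattern(q, subj) > 0L]
    }
    counts[t + 1L] <- length(cand)
  }
  out <- data.frame(trim = 0:max_trim, count = counts)
  attr(out, "allele") <- name %||% "allele"
  attr(out, "end") <- end
  attr(out, "total_rows") <- n
  class(out) <- c("truncation_scan", "data.frame")
  out
}

#' Locate the largest count jump in a truncation scan
#'
#' Returns the trim at which the count increment over the previous trim is
#' maximal -- the automatic detector for the abrupt combined-count jump
#' seen when truncation passes the variant distinguishing two heterozygous
#' alleles.
#'
#' @param scan a `truncation_scan`.
#' @return The trim (integer) with the largest first difference, or `NA`
#'   if the scan is constant.
#' @export
scan_breakpoint <- function(scan) {
  stopifnot(inherits(scan, "truncation_scan"))
  d <- diff(scan$count)
  if (all(d == 0L)) return(NA_integer_)
  scan$trim[which.max(d) + 1L]
}

#' @export
plot.truncation_scan <- function(x, ...) {
  graphics::plot(x$trim, x$count, type = "b", pch = 19,
                 xlab = sprintf("nucleotides trimmed (%s)", attr(x, "end")),
                 ylab = "records matched",
                 main = attr(x, "allele"), ...)
  invisible(x)
}

#' @export
print.truncation_scan <- function(x, ...) {
  cat(sprintf("<truncation_scan> %s (%s), trims 0-%d of %d records\n",
              attr(x, "allele"), attr(x, "end"), max(x$trim),
              attr(x, "total_rows")))
  print.data.frame(x)
  invisible(x)
}

#' Write an allele count table as TSV
#'
#' @param counts an `allele_counts` data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_counts <- function(counts, path) {
  stopifnot(inherits(counts, "allele_counts"))
  utils::write.table(counts, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @export
print.allele_counts <- function(x, ...) {
  cat(sprintf("<allele_counts> %s segment: %d alleles over %d records%s\n",
              attr(x, "segment"), nrow(x), attr(x, "total_rows"),
              if (identical(attr(x, "counting"), "lcs")) " (LCS counting)"
              else ""))
  print.data.frame(x[order(-x$raw_count), , drop = FALSE], row.names = FALSE)
  invisible(x)
}
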