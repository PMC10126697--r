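#' AIRR rearrangement table input/output
#'
#' Repertoire libraries arrive as AIRR Rearrangement TSV tables (optionally
#' gzip-compressed), one row per read or UMI consensus. Column naming
#' varies between dialects (the AIRR standard uses `sequence`/`junction`;
#' UMI column names differ between pipelines), so a [column_map()] bridges
#' the dialect to the internal record layout.
#'
#' @name rearrangement_io
NULL

#' Column map for an AIRR dialect
#'
#' @param sequence name of the full-length nucleotide sequence column
#'   (always required).
#' @param cdr3 name of the CDR3/junction column, or `NULL` if absent
#'   (CDR3 diversity filters then see empty strings).
#' @param umi name of the UMI/barcode column, or `NULL` if absent (UMI
#'   deduplication then falls back to raw counts).
#' @param v_call,d_call,j_call optional call columns, `NULL` if absent.
#' @return A `column_map` list.
#' @export
column_map <- function(sequence = "sequence", cdr3 = "junction",
                       umi = "umi", v_call = NULL, d_call = NULL,
                       j_call = NULL) {
  structure(list(sequence = sequence, cdr3 = cdr3, umi = umi,
                 v_call = v_call, d_call = d_call, j_call = j_call),
            class = "column_map")
}

as_rearrangements <- function(df) {
  needed <- c("sequence", "umi", "cdr3", "v_call", "d_call", "j_call")
  for (col in needed)
    if (is.null(df[[col]]))
      df[[col]] <- if (col %in% c("sequence", "umi", "cdr3")) "" else NA_character_
  df$row_id <- seq_len(nrow(df))
  df <- df[c("row_id", needed)]
  class(df) <- c("rearrangements", "data.frame")
  df
}

#' Read an AIRR rearrangement table
#'
#' Reads a TSV (gzip transparently supported) and returns the rows in file
#' order as a `rearrangements` data frame with columns `row_id`,
#' `sequence`, `umi`, `cdr3`, `v_call`, `d_call`, `j_call`. Sequences are
#' uppercased; rows with an empty sequence are skipped and counted in the
#' `skipped` attribute. A mapped column missing from the file is a hard
#' error listing the available columns.
#'
#' @param path path to a TSV or TSV.gz file with a header row.
#' @param cmap a [column_map()]; the default expects AIRR-standard
#'   `sequence` and `junction` plus a `umi` column.
#' @return A `rearrangements` data frame.
#' @export
read_rearrangements <- function(path, cmap = column_map()) {
  if (!file.exists(path)) stop("no such file: ", path)
  tab <- utils::read.delim(path, sep = "\t", quote = "",
                           colClasses = "character", check.names = FALSE,
                           stringsAsFactors = FALSE)
  mapped <- Filter(Negate(is.null), unclass(cmap))
  missing <- setdiff(unlist(mapped), names(tab))
  if (length(missing))
    stop("mapped column(s) not in file: ", paste(missing, collapse = ", "),
         "; available: ", paste(names(tab), collapse = ", "))
  pick <- function(field) {
    col <- cmap[[field]]
    if (is.null(col)) NULL else tab[[col]]
  }
  df <- data.frame(sequence = toupper(pick("sequence")),
                   stringsAsFactors = FALSE)
  for (f in c("umi", "cdr3")) {
    v <- pick(f)
    df[[f]] <- if (is.null(v)) "" else toupper(v)
  }
  for (f in c("v_call", "d_call", "j_call")) {
    v <- pick(f)
    df[[f]] <- if (is.null(v)) NA_character_ else v
  }
  keep <- nzchar(df$sequence)
  skipped <- sum(!keep)
  if (skipped > 0L)
    warning(skipped, " row(s) with empty sequence skipped")
  out <- as_rearrangements(df[keep, , drop = FALSE])
  attr(out, "skipped") <- skipped
  out
}

#' Write a rearrangement table as AIRR TSV
#'
#' Columns are written under AIRR-style names (`sequence`, `junction`,
#' `umi`, `v_call`, `d_call`, `j_call`). A `.gz` suffix triggers gzip
#' output.
#'
#' @param records a `rearrangements` data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_rearrangements <- function(records, path) {
  out <- data.frame(sequence = records$sequence, junction = records$cdr3,
                    umi = records$umi, v_call = records$v_call,
                    d_call = records$d_call, j_call = records$j_call,
                    stringsAsFactors = FALSE)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con))
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Subsample a library reproducibly
#'
#' Default is Bernoulli thinning: each record is retained independently
#' with probability `fraction`, so replicate subsamples have binomial size
#' variance, matching the replicate semantics of repeated down-samplings.
#' `method = "exact"` draws exactly `round(n * fraction)` records without
#' replacement instead. Order is preserved and the result is deterministic
#' in `seed`.
#'
#' @param records a `rearrangements` data frame.
#' @param fraction retention probability in (0, 1].
#' @param seed integer RNG seed.
#' @param method `"bernoulli"` (default) or `"exact"`.
#' @return The retained records (class preserved), with attribute
#'   `retained` giving the retained count.
#' @export
subsample <- function(records, fraction, seed,
                      method = c("bernoulli", "exact")) {
  method <- match.arg(method)
  stopifnot(fraction > 0, fraction <= 1)
  n <- nrow(records)
  keep <- with_seed(seed, {
    if (method == "bernoulli") stats::runif(n) < fraction
    else sort(sample.int(n, round(n * fraction)))
  })
  out <- records[keep, , drop = FALSE]
  attr(out, "retained") <- nrow(out)
  class(out) <- c("rearrangements", "data.frame")
  out
}
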