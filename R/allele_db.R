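#' Germline allele databases
#'
#' An allele database holds the full-length germline nucleotide sequences of
#' one segment kind (V, D or J). Allele names follow the standard
#' `GENE*ALLELE` convention (e.g. `IGHV1-2*02`); the gene is everything up to
#' the first `*`. Databases are assumed end-corrected: a reference set
#' containing 3'/5'-truncated alleles is unsuitable for core derivation, and
#' only warnings (not corrections) are issued here.
#'
#' @name allele_db
NULL

new_allele_db <- function(name, seq, segment) {
  db <- data.frame(
    name = as.character(name),
    gene = gene_of(name),
    allele_id = sub("^[^*]*\\*", "", name),
    seq = as.character(seq),
    stringsAsFactors = FALSE
  )
  attr(db, "segment") <- segment
  class(db) <- c("allele_db", "data.frame")
  db
}

#' Read a germline allele FASTA file
#'
#' Reads one FASTA record per allele. The allele name is the first
#' whitespace-delimited token of the header; if that token is
#' `|`-delimited (IMGT-style multi-field headers), the field containing a
#' `*` is used. Sequences are uppercased. Duplicate allele names, empty
#' files and characters other than A/C/G/T are hard errors: exact-match
#' counting requires a fully resolved database, so IUPAC ambiguity codes
#' (including N) are rejected.
#'
#' @param path path to a FASTA file.
#' @param segment segment kind of every record: `"V"`, `"D"` or `"J"`.
#' @return An `allele_db`: a data frame with columns `name`, `gene`,
#'   `allele_id`, `seq` and a `segment` attribute, in file order.
#' @seealso [validate_database()], [write_allele_fasta()]
#' @export
read_allele_fasta <- function(path, segment = c("V", "D", "J")) {
  segment <- match.arg(segment)
  if (!file.exists(path)) stop("no such file: ", path)
  x <- Biostrings::readDNAStringSet(path)
  if (length(x) == 0L) stop("empty allele database: ", path)
  token <- sub("\\s.*$", "", names(x))
  name <- vapply(token, function(tk) {
    if (grepl("|", tk, fixed = TRUE)) {
      fields <- strsplit(tk, "|", fixed = TRUE)[[1L]]
      hit <- fields[grepl("*", fields, fixed = TRUE)]
      if (length(hit) == 0L)
        stop("cannot find an allele-name field in header: ", tk)
      hit[[1L]]
    } else tk
  }, character(1), USE.NAMES = FALSE)
  bad_star <- name[vapply(gregexpr("*", name, fixed = TRUE),
                          function(m) sum(m > 0L), 0L) != 1L]
  if (length(bad_star))
    stop("allele names must contain exactly one '*': ",
         paste(unique(bad_star), collapse = ", "))
  dup <- unique(name[duplicated(name)])
  if (length(dup))
    stop("duplicate allele names in database: ", paste(dup, collapse = ", "))
  seq <- toupper(as.character(x))
  bad <- name[!grepl("^[ACGT]+$", seq)]
  if (length(bad))
    stop("sequences with characters outside A/C/G/T (ambiguity codes are ",
         "not allowed in an exact-match database): ",
         paste(bad, collapse = ", "))
  new_allele_db(name, seq, segment)
}

#' Write an allele database as FASTA
#'
#' @param db an `allele_db`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_allele_fasta <- function(db, path) {
  stopifnot(inherits(db, "allele_db"))
  writeLines(paste0(">", db$name, "\n", db$seq), path)
  invisible(path)
}

#' Validate an allele database
#'
#' Pure report, never an error: duplicate names, identical sequences under
#' different names (legitimate for duplicated IGH genes, but the counter
#' must then merge them), non-A/C/G/T sequences, and -- for J databases --
#' alleles whose 3'-terminal 4-mer differs from the expected motif (all
#' functional human IGHJ alleles end in `TCAG`; a deviation suggests a
#' truncated reference).
#'
#' @param db an `allele_db`.
#' @param j_end_motif expected J 3'-terminal motif (default `"TCAG"`).
#' @return An `allele_db_validation` list with fields `duplicate_names`,
#'   `duplicate_sequences` (list of name groups), `non_acgt`,
#'   `j_end_warnings` and `summary`.
#' @export
validate_database <- function(db, j_end_motif = "TCAG") {
  stopifnot(inherits(db, "allele_db"))
  dup_names <- unique(db$name[duplicated(db$name)])
  grp <- split(db$name, db$seq)
  dup_seq <- unname(grp[lengths(grp) > 1L])
  non_acgt <- db$name[!grepl("^[ACGT]+$", db$seq)]
  j_warn <- character(0)
  if (identical(attr(db, "segment"), "J") && nzchar(j_end_motif)) {
    k <- nchar(j_end_motif)
    tail4 <- substr(db$seq, pmax(1L, nchar(db$seq) - k + 1L), nchar(db$seq))
    j_warn <- db$name[tail4 != j_end_motif]
  }
  rep <- list(
    duplicate_names = dup_names,
    duplicate_sequences = dup_seq,
    non_acgt = non_acgt,
    j_end_warnings = j_warn,
    summary = c(n_alleles = nrow(db),
                n_genes = length(unique(db$gene)),
                duplicate_names = length(dup_names),
                duplicate_sequence_groups = length(dup_seq),
                non_acgt = length(non_acgt),
                j_end_warnings = length(j_warn))
  )
  class(rep) <- "allele_db_validation"
  rep
}

#' Is a validation report clean?
#'
#' @param report an `allele_db_validation`.
#' @return `TRUE` iff no issue of any kind was reported.
#' @export
is_clean <- function(report) {
  stopifnot(inherits(report, "allele_db_validation"))
  length(report$duplicate_names) == 0L &&
    length(report$duplicate_sequences) == 0L &&
    length(report$non_acgt) == 0L &&
    length(report$j_end_warnings) == 0L
}

#' Write a validation report as TSV
#'
#' One row per issue with columns `issue` and `alleles`.
#'
#' @param report an `allele_db_validation`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_validation_report <- function(report, path) {
  stopifnot(inherits(report, "allele_db_validation"))
  rows <- rbind(
    if (length(report$duplicate_names))
      data.frame(issue = "duplicate_name", alleles = report$duplicate_names),
    if (length(report$duplicate_sequences))
      data.frame(issue = "duplicate_sequence",
                 alleles = vapply(report$duplicate_sequences, paste,
                                  character(1), collapse = ",")),
    if (length(report$non_acgt))
      data.frame(issue = "non_acgt", alleles = report$non_acgt),
    if (length(report$j_end_warnings))
      data.frame(issue = "j_end_motif", alleles = report$j_end_warnings)
  )
  if (is.null(rows))
    rows <- data.frame(issue = character(0), alleles = character(0))
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Gene name of an allele
#'
#' The gene is the part of the allele name before the first `*`
#' (`"IGHV1-2*05"` -> `"IGHV1-2"`). Vectorised.
#'
#' @param name character vector of allele names.
#' @return character vector of gene names.
#' @export
gene_of <- function(name) {
  name <- as.character(name)
  bad <- name[!grepl("*", name, fixed = TRUE)]
  if (length(bad))
    stop("not GENE*ALLELE names (missing '*'): ",
         paste(unique(bad), collapse = ", "))
  sub("\\*.*$", "", name)
}

#' @export
print.allele_db <- function(x, ...) {
  cat(sprintf("<allele_db> %s segment: %d alleles, %d genes\n",
              attr(x, "segment"), nrow(x), length(unique(x$gene))))
  lens <- nchar(x$seq)
  cat(sprintf("  sequence length %d-%d nt\n", min(lens), max(lens)))
  invisible(x)
}

#' @export
print.allele_db_validation <- function(x, ...) {
  cat("<allele_db_validation>\n")
  s <- x$summary
  cat(sprintf("  %d alleles, %d genes\n", s[["n_alleles"]], s[["n_genes"]]))
  if (is_clean(x)) {
    cat("  database passes all checks\n")
  } else {
    if (length(x$duplicate_names))
      cat("  duplicate names:", paste(x$duplicate_names, collapse = ", "), "\n")
    if (length(x$duplicate_sequences))
      cat("  identical sequences:",
          paste(vapply(x$duplicate_sequences, paste, character(1),
                       collapse = "="), collapse = "; "), "\n")
    if (length(x$non_acgt))
      cat("  non-ACGT:", paste(x$non_acgt, collapse = ", "), "\n")
    if (length(x$j_end_warnings))
      cat("  J 3'-end motif warnings:",
          paste(x$j_end_warnings, collapse = ", "), "\n")
  }
  invisible(x)
}
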