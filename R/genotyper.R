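#' Germline genotype filtering
#'
#' Raw core counts become an expressed genotype through a filter chain:
#'
#' 1. **Allelic ratio** -- within each gene, an allele's count divided by
#'    the top allele count of that gene must reach a cutoff (default 0.1
#'    for V/J; 0.2 for the shorter, more error-prone D genes).
#'    Heterozygous alleles of one gene are used at similar frequency, so
#'    true alleles sit near 0.5-1 while sequencing-error artifacts sit far
#'    below.
#' 2. **Minimum count** on the chosen count basis (UMI counts when UMIs
#'    are present, raw otherwise).
#' 3. **Expected frequency** -- an optional per-allele minimum library
#'    frequency derived from multiple independent libraries. It removes
#'    alleles appearing only through index hopping, and *rescues* known
#'    low-expression alleles (e.g. IGHV1-2*05) that fail the allelic ratio
#'    against their highly expressed gene partners. Rescue never overrides
#'    the minimum count or the CDR3 filters.
#' 4. **CDR3 diversity** -- genuine germline usage shows diverse
#'    junctions; an expanded clone produces many identical CDR3s. An
#'    allele is dropped when one CDR3 length exceeds `lenmaxfreq` of its
#'    matches, or when distinct CDR3s per match fall below
#'    `min_unique_cdr3_frac`.
#'
#' @name genotyper
NULL

#' Genotype filter configuration
#'
#' @param allelic_ratio within-gene ratio cutoff; `NULL` (default)
#'   resolves by segment at filter time: 0.1 for V/J, 0.2 for D.
#' @param min_count minimum count on the chosen basis (default 10).
#' @param count_basis `"auto"` (UMI counts when present, else raw),
#'   `"umi"` or `"raw"`.
#' @param expected_freq optional expected-frequency table: a named numeric
#'   vector of minimum frequencies, or a data frame with columns `allele`
#'   and `min_freq`.
#' @param lenmaxfreq maximum allowed share of one CDR3 length among an
#'   allele's matches (default 0.6).
#' @param min_unique_cdr3_frac minimum distinct-CDR3 fraction of matches
#'   (default 0.1).
#' @return A `filter_config` list.
#' @export
filter_config <- function(allelic_ratio = NULL, min_count = 10L,
                          count_basis = c("auto", "umi", "raw"),
                          expected_freq = NULL, lenmaxfreq = 0.6,
                          min_unique_cdr3_frac = 0.1) {
  count_basis <- match.arg(count_basis)
  if (!is.null(allelic_ratio))
    stopifnot(allelic_ratio > 0, allelic_ratio <= 1)
  stopifnot(min_count >= 0, lenmaxfreq > 0, lenmaxfreq <= 1,
            min_unique_cdr3_frac >= 0, min_unique_cdr3_frac <= 1)
  if (is.data.frame(expected_freq)) {
    stopifnot(all(c("allele", "min_freq") %in% names(expected_freq)))
    expected_freq <- stats::setNames(as.numeric(expected_freq$min_freq),
                                     expected_freq$allele)
  }
  structure(list(allelic_ratio = allelic_ratio, min_count = min_count,
                 count_basis = count_basis, expected_freq = expected_freq,
                 lenmaxfreq = lenmaxfreq,
                 min_unique_cdr3_frac = min_unique_cdr3_frac),
            class = "filter_config")
}

#' Read a filter configuration from YAML
#'
#' Keys mirror the [filter_config()] arguments; `expected_freq` may name a
#' TSV path (columns `allele`, `min_freq`).
#'
#' @param path YAML file path.
#' @return A `filter_config`.
#' @export
read_filter_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.character(y$expected_freq))
    y$expected_freq <- read_expected_freq(y$expected_freq)
  do.call(filter_config, y)
}

#' Read an expected-frequency table
#'
#' @param path TSV with columns `allele` and `min_freq`.
#' @return Named numeric vector of minimum frequencies.
#' @export
read_expected_freq <- function(path) {
  tab <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  stopifnot(all(c("allele", "min_freq") %in% names(tab)))
  stats::setNames(as.numeric(tab$min_freq), tab$allele)
}

resolve_ratio <- function(config, segment) {
  config$allelic_ratio %||% if (identical(segment, "D")) 0.2 else 0.1
}

#' Apply the germline filter chain to allele counts
#'
#' @param counts an `allele_counts` from [count_cores()] or [count_lcs()].
#' @param config a [filter_config()].
#' @return A `genotype_table` data frame with one row per database allele:
#'   counts, `frequency`, `allelic_ratio` (count / top count of the gene),
#'   per-stage verdicts (`pass_ratio`, `pass_min_count`, `pass_expected`,
#'   `rescued`, `pass_cdr3_len`, `pass_cdr3_diversity`) and the final
#'   `in_genotype` flag.
#' @export
filter_genotype <- function(counts, config = filter_config()) {
  stopifnot(inherits(counts, "allele_counts"),
            inherits(config, "filter_config"))
  segment <- attr(counts, "segment")
  ratio_cut <- resolve_ratio(config, segment)
  basis <- config$count_basis
  if (basis == "auto")
    basis <- if (isTRUE(attr(counts, "umis_present"))) "umi" else "raw"
  df <- as.data.frame(counts)
  n <- nrow(df)
  base <- if (basis == "umi") df$umi_count else df$raw_count
  top <- stats::ave(base, df$gene, FUN = max)
  ratio <- ifelse(top > 0, base / top, 0)
  hists <- attr(counts, "cdr3_hists")[df$allele]
  modal <- vapply(hists, function(h)
    if (length(h) == 0L || sum(h) == 0L) 0 else max(h) / sum(h), 0)
  uniq_frac <- ifelse(df$raw_count > 0, df$unique_cdr3 / df$raw_count, 1)
  ef <- config$expected_freq
  if (!is.null(ef)) {
    unknown <- setdiff(names(ef), df$allele)
    if (length(unknown))
      warning("expected-frequency table names unknown alleles: ",
              paste(unknown, collapse = ", "))
  }
  in_table <- if (is.null(ef)) rep(FALSE, n) else df$allele %in% names(ef)
  freq_ok <- rep(TRUE, n)
  freq_ok[in_table] <- df$frequency[in_table] >= ef[df$allele[in_table]]
  pass_ratio <- top > 0 & ratio >= ratio_cut
  pass_min <- base >= config$min_count
  pass_expected <- !in_table | freq_ok
  rescued <- in_table & freq_ok & !pass_ratio
  pass_len <- modal <= config$lenmaxfreq
  pass_div <- uniq_frac >= config$min_unique_cdr3_frac
  out <- data.frame(
    allele = df$allele, gene = df$gene, raw_count = df$raw_count,
    umi_count = df$umi_count, frequency = df$frequency,
    allelic_ratio = ratio, modal_cdr3_share = modal,
    unique_cdr3_frac = uniq_frac,
    pass_ratio = pass_ratio, pass_min_count = pass_min,
    pass_expected = pass_expected, rescued = rescued,
    pass_cdr3_len = pass_len, pass_cdr3_diversity = pass_div,
    in_genotype = (pass_ratio | rescued) & pass_min & pass_expected &
      pass_len & pass_div,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  attr(out, "segment") <- segment
  attr(out, "count_basis") <- basis
  attr(out, "allelic_ratio_cutoff") <- ratio_cut
  attr(out, "total_rows") <- attr(counts, "total_rows")
  class(out) <- c("genotype_table", "data.frame")
  out
}

derive_cores_for <- function(db, trim = NULL, variant_window = 6L,
                             d_trim_table = NULL) {
  switch(attr(db, "segment"),
    V = derive_v_cores(db, default_trim = trim %||% 6L,
                       variant_window = max(variant_window, trim %||% 6L)),
    J = derive_j_cores(db, trim5 = trim %||% 6L,
                       variant_window = max(variant_window, trim %||% 6L)),
    D = {
      tt <- trim %||% c(4L, 4L)
      if (length(tt) == 1L) tt <- c(tt, tt)
      derive_d_cores(db, trim5 = tt[[1L]], trim3 = tt[[2L]],
                     trim_table = d_trim_table)
    },
    stop("unknown segment"))
}

#' Genotype a repertoire library
#'
#' The end-to-end pipeline for one segment: derive cores from the allele
#' database, count exact occurrences in the library, and filter the counts
#' into an expressed genotype. Deterministic in its inputs.
#'
#' @param library a `rearrangements` data frame, or a path to an AIRR TSV
#'   (read with `cmap`).
#' @param db an `allele_db` (one segment).
#' @param config a [filter_config()].
#' @param trim segment trim override: a single integer for V (3') or J
#'   (5'), or length-2 `c(trim5, trim3)` for D. `NULL` uses the defaults
#'   (V 6, J 6, D 4/4).
#' @param variant_window variant-preservation window for V/J (default 6).
#' @param use_lcs for D databases, use LCS substring counting instead of
#'   the standard dual-trimmed core.
#' @param lcs_min_fraction minimum substring fraction for LCS cores.
#' @param d_trim_table optional per-allele D trimming table.
#' @param cmap [column_map()] used when `library` is a path.
#' @return An `ig_genotype` object: fields `genotype` (the
#'   `genotype_table`), `counts`, `cores`, `segment`, `config`,
#'   `n_records`; with `print`, `summary` and `plot` methods.
#'   [genotype_alleles()] extracts the in-genotype allele names.
#' @export
genotype_library <- function(library, db, config = filter_config(),
                             trim = NULL, variant_window = 6L,
                             use_lcs = FALSE, lcs_min_fraction = 0.5,
                             d_trim_table = NULL, cmap = column_map()) {
  stopifnot(inherits(db, "allele_db"))
  records <- if (is.character(library)) read_rearrangements(library, cmap)
             else library
  segment <- attr(db, "segment")
  if (use_lcs && !identical(segment, "D"))
    stop("LCS counting applies to D databases only")
  if (use_lcs) {
    cores <- derive_d_lcs_cores(db, min_fraction = lcs_min_fraction)
    counts <- count_lcs(records, cores)
  } else {
    cores <- derive_cores_for(db, trim, variant_window, d_trim_table)
    counts <- count_cores(records, cores)
  }
  gt <- filter_genotype(counts, config)
  obj <- list(genotype = gt, counts = counts, cores = cores,
              segment = segment, config = config,
              n_records = nrow(records),
              library = if (is.character(library)) library else NULL)
  class(obj) <- "ig_genotype"
  obj
}

#' Alleles called present by a genotype
#'
#' @param object an `ig_genotype` or `genotype_table`.
#' @return Sorted character vector of in-genotype allele names.
#' @export
genotype_alleles <- function(object) {
  tab <- if (inherits(object, "ig_genotype")) object$genotype else object
  stopifnot(inherits(tab, "genotype_table"))
  sort(tab$allele[tab$in_genotype])
}

#' @export
print.ig_genotype <- function(x, ...) {
  tab <- x$genotype
  cat(sprintf("<ig_genotype> %s segment: %d of %d alleles in genotype (%d records)\n",
              x$segment, sum(tab$in_genotype), nrow(tab), x$n_records))
  cat(sprintf("  basis: %s counts; allelic ratio >= %.2g; min count %d\n",
              attr(tab, "count_basis"), attr(tab, "allelic_ratio_cutoff"),
              x$config$min_count))
  inn <- genotype_alleles(x)
  if (length(inn)) {
    cat("  genotype:", paste(inn, collapse = ", "), "\n")
  } else cat("  genotype: (empty)\n")
  invisible(x)
}

#' @export
summary.ig_genotype <- function(object, ...) {
  tab <- object$genotype
  tab[order(tab$gene, -tab$raw_count), , drop = FALSE]
}

#' @export
plot.ig_genotype <- function(x, ...) {
  tab <- x$genotype
  tab <- tab[order(tab$gene, -tab$raw_count), , drop = FALSE]
  cnt <- if (identical(attr(x$genotype, "count_basis"), "umi"))
    tab$umi_count else tab$raw_count
  col <- ifelse(tab$in_genotype, "steelblue", "grey70")
  op <- graphics::par(mar = c(8, 4, 2, 1))
  on.exit(graphics::par(op))
  graphics::barplot(log10(cnt + 1), names.arg = tab$allele, las = 2,
                    col = col, border = NA, cex.names = 0.55,
                    ylab = "log10(count + 1)",
                    main = sprintf("%s genotype (blue = in)", x$segment), ...)
  invisible(x)
}

#' Write a genotype table as TSV
#'
#' @param genotype an `ig_genotype` or `genotype_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_genotype <- function(genotype, path) {
  tab <- if (inherits(genotype, "ig_genotype")) genotype$genotype
         else genotype
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Genotype a set of libraries
#'
#' Runs [genotype_library()] on every library; a failing library aborts
#' only itself and is recorded in `failures`. The combined presence matrix
#' has one row per allele (union over the database, including merged core
#' names) and one column per library with `"IN"`/`"OUT"` (`NA` for failed
#' libraries).
#'
#' @param libraries a named list of `rearrangements` data frames and/or
#'   file paths (unnamed entries are auto-named).
#' @param db an `allele_db`.
#' @param config a [filter_config()].
#' @param ... passed to [genotype_library()].
#' @return An `ig_genotype_batch`: `genotypes` (list of `ig_genotype` or
#'   `NULL`), `presence` (character matrix), `failures` (named character),
#'   `union_alleles` (alleles in at least one genotype).
#' @export
batch_genotype <- function(libraries, db, config = filter_config(), ...) {
  stopifnot(length(libraries) >= 1L)
  if (is.character(libraries)) libraries <- as.list(libraries)
  nm <- names(libraries)
  if (is.null(nm)) nm <- rep("", length(libraries))
  auto <- !nzchar(nm)
  nm[auto] <- vapply(which(auto), function(i) {
    if (is.character(libraries[[i]])) basename(libraries[[i]])
    else paste0("library", i)
  }, character(1))
  names(libraries) <- nm
  genotypes <- vector("list", length(libraries))
  names(genotypes) <- nm
  failures <- character(0)
  for (i in seq_along(libraries)) {
    genotypes[[i]] <- tryCatch(
      genotype_library(libraries[[i]], db, config, ...),
      error = function(e) {
        failures[[nm[[i]]]] <<- conditionMessage(e)
        NULL
      })
  }
  ok <- !vapply(genotypes, is.null, logical(1))
  alleles <- if (any(ok)) genotypes[[which(ok)[1L]]]$genotype$allele
             else db$name
  presence <- matrix(NA_character_, nrow = length(alleles),
                     ncol = length(libraries),
                     dimnames = list(alleles, nm))
  for (i in which(ok)) {
    tab <- genotypes[[i]]$genotype
    presence[match(tab$allele, alleles), i] <-
      ifelse(tab$in_genotype, "IN", "OUT")
  }
  union_alleles <- sort(unique(unlist(lapply(genotypes[ok],
                                             genotype_alleles))))
  obj <- list(genotypes = genotypes, presence = presence,
              failures = failures, union_alleles = union_alleles)
  class(obj) <- "ig_genotype_batch"
  obj
}

#' @export
print.ig_genotype_batch <- function(x, ...) {
  ok <- sum(!vapply(x$genotypes, is.null, logical(1)))
  cat(sprintf("<ig_genotype_batch> %d libraries (%d ok, %d failed); union genotype %d alleles\n",
              length(x$genotypes), ok, length(x$failures),
              length(x$union_alleles)))
  if (length(x$failures))
    for (nm in names(x$failures))
      cat("  failed:", nm, "-", x$failures[[nm]], "\n")
  invisible(x)
}

#' Write a batch presence matrix as TSV
#'
#' @param batch an `ig_genotype_batch`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_batch_matrix <- function(batch, path) {
  stopifnot(inherits(batch, "ig_genotype_batch"))
  out <- data.frame(allele = rownames(batch$presence), batch$presence,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' End-variant modification test
#'
#' Validates that genotyping resolves a variant at the very end of an
#' allele: every library record containing the *full-length* target allele
#' has the base at `position` (counted from the 3' end; 1 = final
#' nucleotide) substituted by `new_base`, the database is supplemented
#' with the modified variant (named `<target>_<new_base>`), and the
#' library is re-genotyped. Because the gene now holds alleles differing
#' at a terminal nucleotide, core derivation preserves the full length for
#' that gene, so the modified variant -- and not the unmodified target --
#' is recovered.
#'
#' @param records a `rearrangements` data frame.
#' @param target name of the allele to modify (must be in `db`).
#' @param position position from the 3' end (default 1 = final nucleotide).
#' @param new_base replacement base, different from the original.
#' @param db the segment `allele_db`.
#' @param config a [filter_config()].
#' @param ... passed to [genotype_library()].
#' @return An `end_variant_test` list: `genotype` (the `ig_genotype` on
#'   the modified library + database), `variant` (new allele name),
#'   `n_modified` (records modified).
#' @export
end_variant_test <- function(records, target, position = 1L, new_base, db,
                             config = filter_config(), ...) {
  stopifnot(inherits(db, "allele_db"), target %in% db$name,
            new_base %in% c("A", "C", "G", "T"), position >= 1L)
  full <- db$seq[db$name == target]
  L <- nchar(full)
  stopifnot(position <= L)
  idx <- L - position + 1L
  old <- substr(full, idx, idx)
  if (old == new_base)
    stop("new_base equals the original base (", old, ") at position ", idx)
  modified <- full
  substr(modified, idx, idx) <- new_base
  hit <- grepl(full, records$sequence, fixed = TRUE)
  if (!any(hit))
    stop("no record contains the full-length ", target,
         "; end-variant test impossible")
  records$sequence[hit] <- sub(full, modified, records$sequence[hit],
                               fixed = TRUE)
  variant <- paste0(target, "_", new_base)
  db2 <- new_allele_db(c(db$name, variant), c(db$seq, modified),
                       attr(db, "segment"))
  fit <- genotype_library(records, db2, config, ...)
  obj <- list(genotype = fit, variant = variant, target = target,
              n_modified = sum(hit))
  class(obj) <- "end_variant_test"
  obj
}

#' @export
print.end_variant_test <- function(x, ...) {
  inn <- genotype_alleles(x$genotype)
  cat(sprintf("<end_variant_test> %s -> %s (%d records modified)\n",
              x$target, x$variant, x$n_modified))
  cat(sprintf("  variant in genotype: %s; original in genotype: %s\n",
              x$variant %in% inn, x$target %in% inn))
  invisible(x)
}
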