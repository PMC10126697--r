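#' Core search-string derivation
#'
#' VDJ recombination trims nucleotides from the 3' end of V genes, the 5'
#' end of J genes and both ends of D genes before adding untemplated N
#' nucleotides at the junctions. A "core" is the portion of a germline
#' allele minimally affected by this process; exact matches to the core are
#' therefore found even in reads whose recombination removed the terminal
#' germline bases. Cores are derived per gene so that all alleles of one
#' gene are trimmed by the same amount and their counts stay directly
#' comparable.
#'
#' For V (and, mirrored, J) genes the trim is reduced when an
#' allele-distinguishing variant sits near the recombination-proximal end:
#' if any two alleles of a gene differ within `variant_window` nucleotides
#' of that end, the gene is trimmed only down to (and including) the most
#' terminal distinguishing position -- possibly a trim of zero when an
#' allele pair differs at the final nucleotide.
#'
#' @name core_builder
NULL

new_core_db <- function(segment, cores, gene_trim, merged_groups,
                        allele_trim = NULL) {
  obj <- list(segment = segment, cores = cores, gene_trim = gene_trim,
              merged_groups = merged_groups, allele_trim = allele_trim)
  class(obj) <- "core_db"
  obj
}

# Largest 3'-end trim that still leaves two 5'-aligned sequences
# distinguishable. -1L when they differ only by length (one is a prefix of
# the other); Inf when identical.
pair_trim_limit <- function(s1, s2) {
  lmin <- min(nchar(s1), nchar(s2))
  a <- utf8ToInt(substr(s1, 1L, lmin))
  b <- utf8ToInt(substr(s2, 1L, lmin))
  mism <- which(a != b)
  if (length(mism) == 0L) {
    if (nchar(s1) == nchar(s2)) return(Inf)
    return(-1L)
  }
  lmin - max(mism)
}

# Shared V/J engine operating in 3'-trim orientation (J databases are
# reversed before and after).
derive_end_cores <- function(db, default_trim, variant_window, end_label) {
  stopifnot(default_trim >= 0, variant_window >= default_trim)
  genes <- unique(db$gene)
  cores <- character(nrow(db))
  names(cores) <- db$name
  trim_by_gene <- integer(length(genes))
  names(trim_by_gene) <- genes
  for (g in genes) {
    idx <- which(db$gene == g)
    trim <- default_trim
    if (length(idx) > 1L) {
      lim <- Inf
      for (i in seq_along(idx)[-1L]) {
        for (j in seq_len(i - 1L)) {
          a <- idx[i]; b <- idx[j]
          tl <- pair_trim_limit(db$seq[a], db$seq[b])
          if (is.infinite(tl))
            stop("identical sequences within gene ", g, ": ",
                 db$name[a], " and ", db$name[b])
          if (tl < 0)
            stop("alleles of gene ", g, " differ only by length (cores ",
                 "would be prefix-identical): ", db$name[a], " and ",
                 db$name[b])
          lim <- min(lim, tl)
        }
      }
      # Reduce the trim only for variants inside the window; a variant
      # further in never constrains because variant_window >= default_trim.
      if (lim < variant_window) trim <- min(trim, lim)
    }
    short <- idx[nchar(db$seq[idx]) <= trim]
    if (length(short))
      stop("allele(s) of gene ", g, " shorter than the ", end_label,
           " trim of ", trim, " nt: ", paste(db$name[short], collapse = ", "))
    cores[idx] <- substr(db$seq[idx], 1L, nchar(db$seq[idx]) - trim)
    trim_by_gene[[g]] <- as.integer(trim)
    # Defensive: the retained regions must stay pairwise distinct and
    # prefix-free within the gene.
    cg <- cores[idx]
    if (anyDuplicated(cg))
      stop("cores of gene ", g, " collapse after trimming")
  }
  list(cores = cores, trim_by_gene = trim_by_gene)
}

# Merge byte-identical cores (duplicated genes) under a joined name.
merge_identical_cores <- function(cores) {
  grp <- split(names(cores), cores)
  merged_groups <- unname(grp[lengths(grp) > 1L])
  if (length(merged_groups) == 0L)
    return(list(cores = cores, merged_groups = list()))
  out <- cores[!duplicated(cores)]
  key <- match(out, names(grp))
  names(out) <- vapply(grp[key], function(g) paste(sort(g), collapse = "/"),
                       character(1))
  list(cores = out, merged_groups = lapply(merged_groups, sort))
}

#' Derive V cores (3'-trimmed, variant-preserving)
#'
#' All alleles of a gene are shortened from the 3' end by `default_trim`
#' nucleotides unless an allele pair of that gene differs within
#' `variant_window` nucleotides of the 3' end, in which case the whole gene
#' is trimmed only down to the most 3' distinguishing position (zero trim
#' when alleles differ at the final nucleotide). Identical cores arising
#' from duplicated genes are merged under a `name1/name2` joined name.
#'
#' @param db a V `allele_db`.
#' @param default_trim nucleotides trimmed from the 3' end (default 6).
#' @param variant_window window, in nucleotides from the 3' end, scanned
#'   for allele-distinguishing variants (default 6; must be >=
#'   `default_trim`).
#' @return A `core_db`: `cores` (named character), `gene_trim`
#'   (data frame `gene`, `trim5`, `trim3`), `merged_groups`.
#' @export
derive_v_cores <- function(db, default_trim = 6L, variant_window = 6L) {
  stopifnot(inherits(db, "allele_db"), identical(attr(db, "segment"), "V"))
  eng <- derive_end_cores(db, default_trim, variant_window, "3'")
  m <- merge_identical_cores(eng$cores)
  gene_trim <- data.frame(gene = names(eng$trim_by_gene), trim5 = 0L,
                          trim3 = unname(eng$trim_by_gene),
                          stringsAsFactors = FALSE)
  new_core_db("V", m$cores, gene_trim, m$merged_groups)
}

#' Derive J cores (5'-trimmed, variant-preserving)
#'
#' The mirror image of [derive_v_cores()]: J genes lose 5' nucleotides to
#' recombination, so alleles are trimmed from the 5' end, with the same
#' variant-preservation rule applied to 5'-proximal variants.
#'
#' @param db a J `allele_db`.
#' @param trim5 nucleotides trimmed from the 5' end (default 6).
#' @param variant_window variant scan window from the 5' end (default 6).
#' @return A `core_db` (see [derive_v_cores()]).
#' @export
derive_j_cores <- function(db, trim5 = 6L, variant_window = 6L) {
  stopifnot(inherits(db, "allele_db"), identical(attr(db, "segment"), "J"))
  rdb <- db
  rdb$seq <- rev_string(db$seq)
  eng <- derive_end_cores(rdb, trim5, variant_window, "5'")
  cores <- rev_string(eng$cores)
  names(cores) <- names(eng$cores)
  m <- merge_identical_cores(cores)
  gene_trim <- data.frame(gene = names(eng$trim_by_gene),
                          trim5 = unname(eng$trim_by_gene), trim3 = 0L,
                          stringsAsFactors = FALSE)
  new_core_db("J", m$cores, gene_trim, m$merged_groups)
}

#' Derive D cores (dual-end trimmed)
#'
#' Each D allele is trimmed at both ends; a per-allele trimming table can
#' override the global trims for listed alleles (D genes vary widely in
#' length, and the short D1 family tolerates less trimming). Cores must
#' remain gene specific: a core occurring as a substring of another gene's
#' full-length allele is an error, because exact matching could then not
#' tell the genes apart. Within-gene identical cores are merged under a
#' joined name.
#'
#' @param db a D `allele_db`.
#' @param trim5,trim3 global 5'/3' trims in nucleotides (defaults 4/4).
#' @param trim_table optional data frame with columns `allele`, `trim5`,
#'   `trim3` overriding the globals for the listed alleles.
#' @param min_core_len minimum tolerated core length (default 8 nt).
#' @return A `core_db` with an additional `allele_trim` data frame.
#' @export
derive_d_cores <- function(db, trim5 = 4L, trim3 = 4L, trim_table = NULL,
                           min_core_len = 8L) {
  stopifnot(inherits(db, "allele_db"), identical(attr(db, "segment"), "D"),
            trim5 >= 0, trim3 >= 0)
  t5 <- rep(as.integer(trim5), nrow(db))
  t3 <- rep(as.integer(trim3), nrow(db))
  if (!is.null(trim_table)) {
    stopifnot(all(c("allele", "trim5", "trim3") %in% names(trim_table)))
    unknown <- setdiff(trim_table$allele, db$name)
    if (length(unknown))
      stop("trim table names unknown alleles: ",
           paste(unknown, collapse = ", "))
    k <- match(trim_table$allele, db$name)
    t5[k] <- as.integer(trim_table$trim5)
    t3[k] <- as.integer(trim_table$trim3)
  }
  L <- nchar(db$seq)
  cores <- substr(db$seq, t5 + 1L, L - t3)
  names(cores) <- db$name
  short <- db$name[nchar(cores) < min_core_len]
  if (length(short))
    stop("trims reduce core(s) below the minimum length of ", min_core_len,
         " nt: ", paste(short, collapse = ", "))
  # Gene specificity: no core may occur inside a different gene's allele.
  for (i in seq_len(nrow(db))) {
    other <- which(db$gene != db$gene[i])
    hit <- other[grepl(cores[i], db$seq[other], fixed = TRUE)]
    if (length(hit))
      stop("core of ", db$name[i], " is not gene specific: it occurs in ",
           paste(db$name[hit], collapse = ", "))
  }
  m <- merge_identical_cores(cores)
  by_gene <- split(seq_len(nrow(db)), db$gene)
  gene_trim <- data.frame(
    gene = names(by_gene),
    trim5 = vapply(by_gene, function(i)
      if (length(unique(t5[i])) == 1L) t5[i][1L] else NA_integer_, 1L),
    trim3 = vapply(by_gene, function(i)
      if (length(unique(t3[i])) == 1L) t3[i][1L] else NA_integer_, 1L),
    stringsAsFactors = FALSE
  )
  rownames(gene_trim) <- NULL
  allele_trim <- data.frame(allele = db$name, trim5 = t5, trim3 = t3,
                            stringsAsFactors = FALSE)
  new_core_db("D", m$cores, gene_trim, m$merged_groups, allele_trim)
}

#' Derive allele-specific LCS D-core sets
#'
#' The segment of a D gene surviving recombination varies widely and is
#' often biased toward one end, so a single central core undercounts. The
#' LCS procedure instead enumerates, per allele, every contiguous substring
#' whose length is at least `min_fraction` of the full allele and keeps
#' exactly those occurring in no other database allele. Each retained
#' substring is an independent search string; the counter enforces a
#' maximum of one D count per read across the whole set.
#'
#' @param db a D `allele_db`.
#' @param min_fraction minimum substring length as a fraction of the full
#'   allele length (default 0.5).
#' @return A `d_core_set`: `substrings` (named list of character vectors),
#'   `min_fraction`, `min_len` (named integer) and `excluded` (alleles with
#'   no allele-specific substring at this fraction; they are warned about
#'   and left out).
#' @export
derive_d_lcs_cores <- function(db, min_fraction = 0.5) {
  stopifnot(inherits(db, "allele_db"), identical(attr(db, "segment"), "D"),
            min_fraction > 0, min_fraction <= 1)
  subs <- vector("list", nrow(db))
  names(subs) <- db$name
  min_len <- integer(nrow(db))
  names(min_len) <- db$name
  for (i in seq_len(nrow(db))) {
    L <- nchar(db$seq[i])
    ml <- as.integer(ceiling(min_fraction * L))
    min_len[[i]] <- ml
    cand <- character(0)
    for (w in ml:L)
      cand <- c(cand, substring(db$seq[i], 1:(L - w + 1L), w:L))
    cand <- unique(cand)
    other <- db$seq[-i]
    specific <- vapply(cand, function(s)
      !any(grepl(s, other, fixed = TRUE)), logical(1), USE.NAMES = FALSE)
    subs[[i]] <- cand[specific]
  }
  excluded <- db$name[lengths(subs) == 0L]
  if (length(excluded)) {
    warning("no allele-specific substring at fraction ", min_fraction,
            " for: ", paste(excluded, collapse = ", "),
            " (excluded from LCS counting)")
    subs <- subs[lengths(subs) > 0L]
    min_len <- min_len[setdiff(names(min_len), excluded)]
  }
  obj <- list(substrings = subs, min_fraction = min_fraction,
              min_len = min_len, excluded = excluded, segment = "D")
  class(obj) <- "d_core_set"
  obj
}

#' Write a core database as FASTA with trim metadata
#'
#' Headers carry the applied trims as `key=value` suffixes.
#'
#' @param core_db a `core_db`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_core_fasta <- function(core_db, path) {
  stopifnot(inherits(core_db, "core_db"))
  nm <- names(core_db$cores)
  gene1 <- gene_of(sub("/.*$", "", nm))
  k <- match(gene1, core_db$gene_trim$gene)
  hdr <- sprintf(">%s segment=%s trim5=%d trim3=%d", nm, core_db$segment,
                 core_db$gene_trim$trim5[k], core_db$gene_trim$trim3[k])
  writeLines(paste0(hdr, "\n", unname(core_db$cores)), path)
  invisible(path)
}

#' Write the per-gene trim report as TSV
#'
#' @param core_db a `core_db`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trim_report <- function(core_db, path) {
  stopifnot(inherits(core_db, "core_db"))
  utils::write.table(core_db$gene_trim, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @export
print.core_db <- function(x, ...) {
  cat(sprintf("<core_db> %s segment: %d cores over %d genes\n", x$segment,
              length(x$cores), nrow(x$gene_trim)))
  if (length(x$merged_groups))
    cat("  merged identical cores:",
        paste(vapply(x$merged_groups, paste, character(1), collapse = "="),
              collapse = "; "), "\n")
  invisible(x)
}

#' @export
print.d_core_set <- function(x, ...) {
  cat(sprintf(
    "<d_core_set> %d alleles, %d allele-specific substrings (>= %.0f%% of allele length)\n",
    length(x$substrings), sum(lengths(x$substrings)), 100 * x$min_fraction))
  if (length(x$excluded))
    cat("  excluded (nothing specific):",
        paste(x$excluded, collapse = ", "), "\n")
  invisible(x)
}
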